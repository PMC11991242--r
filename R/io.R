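# Persistence: recordings, (quantized) model checkpoints, descriptor tables
# and run configurations. Checkpoints and recordings are JSON containers in
# which bulk numeric arrays are base64-encoded little-endian float64, so
# round trips are bit-exact and no framework-private serialization is used.

b64_encode_num <- function(x) {
  jsonlite::base64_enc(writeBin(as.vector(as.double(x)), raw(),
                                size = 8L, endian = "little"))
}

b64_decode_num <- function(s, n) {
  readBin(jsonlite::base64_dec(s), "double", n = n, size = 8L,
          endian = "little")
}

encode_tree <- function(a) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, encode_tree))
  list(dim = if (is.null(dim(a))) length(a) else dim(a),
       data = b64_encode_num(a))
}

decode_tree <- function(a) {
  if (is.null(a) || (is.list(a) && length(a) == 0)) return(NULL)
  if (is.list(a) && identical(sort(names(a)), c("data", "dim"))) {
    d <- unlist(a$dim)
    x <- b64_decode_num(a$data, prod(d))
    if (length(d) > 1) dim(x) <- d
    return(x)
  }
  lapply(a, decode_tree)
}

#' Persist a recording
#'
#' Writes/reads a `radar_recording` as a JSON container: one object per
#' recording holding the `p` and `q` datasets (dimensions
#' `[time, channel, n_samples]`, base64 float64), scan times, train index,
#' and the label, scene name, seed and full radar configuration as
#' attributes. Round trips are lossless.
#'
#' @param rec A `radar_recording`.
#' @param path Output path (`.json`, or `.json.gz` for gzip compression).
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` returns the `radar_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "radar_recording"))
  obj <- list(
    format = "vitalchirp-recording", version = 1L,
    scene_name = rec$scene_name, label = rec$label, seed = rec$seed,
    duration = rec$duration,
    config = unclass(rec$config),
    n_scans = dim(rec$p)[1], n_channels = dim(rec$p)[2],
    n_samples = dim(rec$p)[3],
    t = encode_tree(rec$t), train = encode_tree(rec$train),
    p = encode_tree(rec$p), q = encode_tree(rec$q)
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @param path Path to a recording container.
#' @rdname write_recording
#' @export
read_recording <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  obj <- jsonlite::fromJSON(paste(readLines(con, warn = FALSE), collapse = ""),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "vitalchirp-recording")) {
    stop("not a vitalchirp recording container: ", path, call. = FALSE)
  }
  for (ds in c("p", "q", "t", "train", "config")) {
    if (is.null(obj[[ds]])) {
      stop("malformed recording container: missing dataset '", ds, "'",
           call. = FALSE)
    }
  }
  cfg <- obj$config
  config <- radar_config(
    carrier_freq = cfg$carrier_freq, n_samples = cfg$n_samples,
    scan_rate = cfg$scan_rate, train_len = cfg$train_len, ts = cfg$ts,
    channels = cfg$channels, noise_sigma = cfg$noise_sigma,
    wave_speed = cfg$wave_speed, chirp_slope = cfg$chirp_slope,
    chirp_duration = cfg$chirp_duration, full_physics = cfg$full_physics
  )
  p <- decode_tree(obj$p)
  q <- decode_tree(obj$q)
  if (dim(p)[2] != length(config$channels)) {
    stop("channel-count attribute (", length(config$channels),
         ") does not match array shape (", dim(p)[2], ")", call. = FALSE)
  }
  structure(
    list(p = p, q = q, t = decode_tree(obj$t),
         train = as.integer(decode_tree(obj$train)),
         config = config, scene_name = obj$scene_name,
         label = as.integer(obj$label), seed = as.integer(obj$seed),
         duration = obj$duration),
    class = "radar_recording"
  )
}

#' Persist a model checkpoint
#'
#' JSON checkpoint holding the architecture string, float parameters
#' (base64 float64, bit-exact) and, for quantized models, the integer
#' weight/scale/offset codes with their per-layer references. Loading a
#' quantized checkpoint verifies codebook membership and refuses codes
#' outside `[-multiplier, multiplier]`.
#'
#' @param fit A `gru_fit`.
#' @param path Output path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `gru_fit`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "gru_fit"))
  obj <- list(
    format = "vitalchirp-model", version = 1L,
    arch = format_arch(fit$config), route = fit$route,
    seed = fit$seed, n_train = fit$n_train,
    schedule = fit$schedule,
    params = encode_tree(fit$params),
    params_float = encode_tree(fit$params_float),
    history = if (!is.null(fit$history)) as.list(fit$history),
    quant = if (!is.null(fit$quant)) list(
      qc = unclass(fit$quant$qc),
      codes = lapply(fit$quant$codes, function(cd) list(
        w = cd$w, k_code = cd$k_code, b_code = cd$b_code,
        k_ref = encode_tree(cd$k_ref), b_ref = encode_tree(cd$b_ref)
      ))
    )
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = ""),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "vitalchirp-model")) {
    stop("not a vitalchirp model checkpoint: ", path, call. = FALSE)
  }
  config <- network_config(obj$arch)
  quant <- NULL
  if (length(obj$quant)) {
    qc <- quant_config(bit_depth = obj$quant$qc$bit_depth,
                       lambda = obj$quant$qc$lambda,
                       activation_epoch = obj$quant$qc$activation_epoch)
    codes <- lapply(obj$quant$codes, function(cd) {
      w_raw <- cd$w
      if (is.list(w_raw)) w_raw <- do.call(rbind, lapply(w_raw, unlist))
      all_codes <- c(w_raw, unlist(cd$k_code), unlist(cd$b_code))
      if (any(abs(all_codes) > qc$multiplier) ||
          any(all_codes != round(all_codes))) {
        stop("checkpoint violates codebook membership: codes must be ",
             "integers in [-", qc$multiplier, ", ", qc$multiplier, "]",
             call. = FALSE)
      }
      w <- matrix(as.integer(w_raw), nrow = nrow(w_raw))
      list(w = w,
           k_code = as.integer(unlist(cd$k_code)),
           b_code = as.integer(unlist(cd$b_code)),
           k_ref = decode_tree(cd$k_ref), b_ref = decode_tree(cd$b_ref))
    })
    quant <- list(codes = codes, qc = qc)
  }
  fit <- structure(
    list(config = config,
         params = decode_tree(obj$params),
         params_float = decode_tree(obj$params_float),
         history = if (length(obj$history)) tibble::as_tibble(obj$history),
         schedule = obj$schedule, seed = obj$seed, n_train = obj$n_train,
         route = obj$route, quant = quant),
    class = "gru_fit"
  )
  fit
}

#' Persist descriptor windows as CSV
#'
#' One row per time step, columns
#' `source_id, window_index, t_s, ch_0 ... ch_{C-1}, label`.
#'
#' @param windows A `descriptor_windows` tibble.
#' @param path CSV path.
#' @return `write_descriptors()` returns `path` invisibly;
#'   `read_descriptors()` a `descriptor_windows` tibble.
#' @export
write_descriptors <- function(windows, path) {
  long <- descriptor_long(windows)
  chans <- attr(windows, "channels")
  long$channel <- factor(long$channel, levels = chans,
                         labels = paste0("ch_", seq_along(chans) - 1))
  wide <- tidyr::pivot_wider(long, names_from = "channel",
                             values_from = "value")
  wide <- dplyr::rename(wide, window_index = "window")
  wide <- wide[c("source_id", "window_index", "t_s",
                 paste0("ch_", seq_along(chans) - 1), "label")]
  hdr <- sprintf("# vitalchirp descriptors delta_t=%g window_s=%g ts=%g channels=%s",
                 attr(windows, "delta_t"), attr(windows, "window_s"),
                 attr(windows, "ts"), paste(chans, collapse = ";"))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(wide, path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  hdr <- readLines(path, n = 1)
  get_num <- function(key) {
    as.numeric(sub(paste0(".*", key, "=([0-9.eE+-]+).*"), "\\1", hdr))
  }
  chans <- strsplit(sub(".*channels=([^ ]+).*", "\\1", hdr), ";")[[1]]
  tbl <- utils::read.csv(path, skip = 1)
  ccols <- paste0("ch_", seq_along(chans) - 1)
  rows <- dplyr::group_by(tbl, .data$source_id, .data$window_index)
  out <- dplyr::summarise(
    rows,
    label = .data$label[1], t_start = min(.data$t_s),
    values = list({
      m <- as.matrix(dplyr::pick(dplyr::all_of(ccols)))
      colnames(m) <- chans
      m
    }),
    .groups = "drop"
  )
  out <- dplyr::rename(out, window = "window_index")
  out <- out[c("source_id", "window", "label", "t_start", "values")]
  new_descriptor_windows(out, get_num("delta_t"), get_num("window_s"),
                         get_num("ts"), chans)
}

#' Load and validate a run configuration
#'
#' One YAML file drives the full pipeline, with sections `simulator`
#' (radar config and preset mix), `extractor` (`delta_t`, `window_s`,
#' `channels`, optional `bandpass`), `model` (`arch`), `training`
#' (schedule and quantization settings) and `output` (paths). Unknown keys
#' are rejected; cross-field validity (delay a multiple of the train
#' interval, channel counts consistent between sections) is enforced.
#'
#' @param path YAML file path.
#' @return A validated nested list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- list(
    simulator = c("preset", "duration", "seed", "n_samples", "scan_rate",
                  "train_len", "ts", "channels", "noise_sigma",
                  "carrier_freq", "full_physics"),
    extractor = c("delta_t", "window_s", "channels", "bandpass",
                  "band_low", "band_high"),
    model = c("arch", "dropout_p"),
    training = c("epochs", "lr", "batch_size", "seed", "bit_depth",
                 "lambda", "activation_epoch", "quantize"),
    output = c("recording", "descriptors", "model", "metrics")
  )
  unknown_top <- setdiff(names(cfg), names(allowed))
  if (length(unknown_top)) {
    stop("unknown config section(s): ", paste(unknown_top, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(cfg)) {
    unknown <- setdiff(names(cfg[[sec]]), allowed[[sec]])
    if (length(unknown)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  ts <- cfg$simulator$ts %||% 0.05
  dt <- cfg$extractor$delta_t
  if (!is.null(dt) && abs(dt / ts - round(dt / ts)) > 1e-9) {
    stop("extractor delta_t (", dt, ") must be an integer multiple of ",
         "simulator ts (", ts, ")", call. = FALSE)
  }
  if (!is.null(cfg$model$arch) && !is.null(cfg$extractor$channels)) {
    C <- network_config(cfg$model$arch)$C
    if (C != cfg$extractor$channels) {
      stop("model input channels (C", C, ") inconsistent with extractor ",
           "channels (", cfg$extractor$channels, ")", call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}
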