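# Detection metrics, recording-level splits, and the hyperparameter grid.

#' Detection metrics
#'
#' Confusion-matrix summary with humans (label 1) as the positive class:
#' accuracy `(TP+TN)/total`, F1 `2TP/(2TP+FP+FN)`, sensitivity `TP/(TP+FN)`
#' and False Rejection Rate `FRR = FN/(TP+FN)` (the fraction of true
#' human-present windows classified as no-human), so
#' `sensitivity + FRR = 1`.
#'
#' @param predictions Predicted 0/1 labels, or a tibble from
#'   [predict.gru_fit()] carrying `.pred_class` and `label`.
#' @param labels True 0/1 labels (ignored when `predictions` is a
#'   prediction tibble with labels).
#' @return One-row tibble: `accuracy`, `f1`, `sensitivity`, `frr`, `tp`,
#'   `fp`, `tn`, `fn`, `n`.
#' @examples
#' detection_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
detection_metrics <- function(predictions, labels = NULL) {
  if (is.data.frame(predictions)) {
    if (is.null(labels)) labels <- predictions$label
    predictions <- predictions$.pred_class
  }
  if (length(predictions) == 0) stop("empty predictions", call. = FALSE)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  if (!all(predictions %in% 0:1) || !all(labels %in% 0:1)) {
    stop("predictions and labels must be binary 0/1", call. = FALSE)
  }
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  tn <- sum(predictions == 0 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  pos <- tp + fn
  tibble::tibble(
    accuracy = (tp + tn) / length(labels),
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    sensitivity = if (pos > 0) tp / pos else NA_real_,
    frr = if (pos > 0) fn / pos else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(labels)
  )
}

#' Split descriptor windows at recording level
#'
#' Windows from one recording never cross the split: source recordings are
#' shuffled within each class (stratified) and assigned whole to the train
#' or test side, so no observation window leaks between sets. Deterministic
#' per seed.
#'
#' @param windows A `descriptor_windows` tibble.
#' @param ratios Numeric `(train, test)` proportions summing to 1.
#' @param seed Integer seed.
#' @param strata Optional character vector, one entry per window row, giving
#'   a finer stratification than the class label (e.g. the scene preset);
#'   must be constant within a recording. Default: stratify by class label.
#' @return List with `train` and `test` `descriptor_windows` tibbles.
#' @export
split_dataset <- function(windows, ratios = c(train = 0.8, test = 0.2),
                          seed = 1L, strata = NULL) {
  stopifnot(length(ratios) == 2, abs(sum(ratios) - 1) < 1e-9, all(ratios > 0))
  src <- tibble::tibble(source_id = windows$source_id,
                        label = windows$label,
                        stratum = if (is.null(strata)) {
                          as.character(windows$label)
                        } else as.character(strata))
  src <- dplyr::distinct(src)
  if (anyDuplicated(src$source_id)) {
    stop("strata must be constant within each recording", call. = FALSE)
  }
  bad <- dplyr::count(src, .data$label)
  if (nrow(bad) < 2) {
    stop("both classes must be present to split", call. = FALSE)
  }
  if (any(table(src$stratum) < 2)) {
    stop("every stratum needs at least two recordings so both splits contain it",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "split"))
  take_train <- unlist(lapply(split(src$source_id, src$stratum), function(ids) {
    ids <- sample(ids)
    n_tr <- min(max(floor(ratios[[1]] * length(ids)), 1L), length(ids) - 1L)
    ids[seq_len(n_tr)]
  }), use.names = FALSE)
  att <- attributes(windows)[c("delta_t", "window_s", "ts", "channels")]
  mk <- function(tbl) {
    new_descriptor_windows(tbl, att$delta_t, att$window_s, att$ts, att$channels)
  }
  list(train = mk(windows[windows$source_id %in% take_train, ]),
       test = mk(windows[!windows$source_id %in% take_train, ]))
}

#' Hyperparameter grid
#'
#' The full experiment grid crosses four chirp-subtraction delays, three
#' observation-window durations and three channel modes (36 combinations);
#' `reduced = TRUE` gives the four-combination comparison set
#' (delays 150/250 ms, windows 6/12 s, three channels).
#'
#' @param delta_t Subtraction delays in seconds.
#' @param window_s Observation window durations in seconds.
#' @param channels Channel modes (1, 3 or 12).
#' @param reduced Use the reduced comparison set.
#' @return A tibble with columns `delta_t_s`, `window_s`, `channels`.
#' @examples
#' nrow(hyper_grid())  # 36
#' @export
hyper_grid <- function(delta_t = c(0.1, 0.15, 0.25, 0.4),
                       window_s = c(2, 6, 12),
                       channels = c(1, 3, 12),
                       reduced = FALSE) {
  if (reduced) {
    delta_t <- c(0.15, 0.25); window_s <- c(6, 12); channels <- 3
  }
  tidyr::crossing(delta_t_s = delta_t, window_s = window_s,
                  channels = as.integer(channels))
}

#' Run the hyperparameter grid
#'
#' For each grid row: extract descriptor windows from every recording at
#' that (delay, window, channel-mode) setting, split at recording level,
#' train the architecture, and report test metrics. Rows whose delay is not
#' an integer multiple of the train interval are skipped with a message.
#' Identical `(recordings, grid, arch, seed)` give identical tables.
#'
#' @param recordings List of `radar_recording` objects (channel superset of
#'   every requested mode).
#' @param grid A [hyper_grid()] tibble.
#' @param arch Architecture string.
#' @param schedule A [train_schedule()].
#' @param qc Optional [quant_config()] for quantization-aware rows.
#' @param ratios Train/test proportions.
#' @param seed Integer seed.
#' @return Tibble with one row per feasible grid row: `arch`, `channels`,
#'   `delta_t_s`, `window_s`, `seed`, `accuracy`, `f1`, `sensitivity`,
#'   `frr`, `quantized`.
#' @export
run_grid <- function(recordings, grid = hyper_grid(), arch = "C3-W8-L3-X",
                     schedule = train_schedule(), qc = NULL,
                     ratios = c(0.8, 0.2), seed = 1L) {
  stopifnot(is.list(recordings), length(recordings) >= 2)
  ts <- recordings[[1]]$config$ts
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    lag <- g$delta_t_s / ts
    if (abs(lag - round(lag)) > 1e-9) {
      message("skipping grid row ", i, ": delta_t = ", g$delta_t_s,
              " s is not a multiple of ts = ", ts, " s")
      next
    }
    base <- network_config(arch)
    row_arch <- paste0("C", g$channels, "-W", base$W, "-L", base$L,
                       if (base$use_bn_dropout) "-X")
    windows <- dplyr::bind_rows(lapply(recordings, function(rec) {
      descriptor_sequence(rec, delta_t = g$delta_t_s, window_s = g$window_s,
                          channels = g$channels)
    }))
    windows <- new_descriptor_windows(windows, g$delta_t_s, g$window_s, ts,
                                      radar_channels(g$channels))
    sp <- split_dataset(windows, c(ratios[1], ratios[2]), seed = seed)
    fit <- train_gru(sp$train, arch = row_arch, schedule = schedule,
                     qc = qc, seed = seed)
    m <- detection_metrics(predict(fit, sp$test))
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(arch = row_arch, channels = g$channels,
                     delta_t_s = g$delta_t_s, window_s = g$window_s,
                     seed = as.integer(seed)),
      m[c("accuracy", "f1", "sensitivity", "frr")],
      tibble::tibble(quantized = !is.null(qc))
    )
  }
  dplyr::bind_rows(rows)
}
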