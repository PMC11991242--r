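#' Quantization configuration
#'
#' Analog synapses store weights at `bit_depth` bits plus sign. The codebook
#' multiplier is `2^B - 1 - (B mod 2)`, giving levels `m / multiplier` for
#' integer `m` in `[-multiplier, multiplier]`: 31 levels (16 distinct
#' non-negative magnitudes) at the default B = 4, and the 7-level
#' `{-1, -2/3, ..., 1}` codebook at B = 2. Odd bit depths are permitted but
#' only even ones are corroborated by hardware; treat odd B as experimental.
#'
#' @param bit_depth Target weight resolution B (without sign), integer >= 2.
#' @param lambda Non-negative weight of the quantization loss in the total
#'   training loss. The penalty's per-weight gradient magnitude is
#'   `multiplier * pi * lambda` regardless of how far a weight is from the
#'   codebook, so `lambda` must sit below typical task-gradient magnitudes
#'   or the pull overrides learning; the default is calibrated for the
#'   package's benchmark scale (see the methods vignette). Weights the
#'   penalty has not fully pulled onto the codebook are still deployable:
#'   the per-neuron renormalization makes the final hard-quantization error
#'   at most half a codebook step times the neuron scale.
#' @param activation_epoch Epoch (1-based) at which the quantization loss is
#'   switched on during training.
#' @return An object of class `quant_config` with the derived `multiplier`.
#' @examples
#' quant_config()$multiplier  # 15
#' @export
quant_config <- function(bit_depth = 4L, lambda = 1e-5,
                         activation_epoch = 6L) {
  stopifnot(bit_depth == round(bit_depth))
  if (bit_depth < 2) stop("bit_depth must be >= 2", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(bit_depth = as.integer(bit_depth), lambda = lambda,
                 activation_epoch = as.integer(activation_epoch),
                 multiplier = quant_multiplier(bit_depth)),
            class = "quant_config")
}

quant_multiplier <- function(B) as.integer(2^B - 1 - (B %% 2))

#' Quantization codebook
#'
#' @param B Bit depth (without sign), >= 2.
#' @return Sorted numeric vector of the `2*multiplier + 1` admissible weight
#'   levels in `[-1, 1]`.
#' @examples
#' quant_grid(2)  # -1, -2/3, -1/3, 0, 1/3, 2/3, 1
#' @export
quant_grid <- function(B) {
  if (B < 2) stop("bit depth must be >= 2", call. = FALSE)
  m <- quant_multiplier(B)
  (-m:m) / m
}

#' Periodic quantization loss
#'
#' `L_Q = sum_i | sin(multiplier * pi * w_i) |` with
#' `multiplier = 2^B - 1 - (B mod 2)`: a periodic penalty whose minima are
#' exactly the codebook levels, pulling weights onto the grid while leaving
#' on-grid weights untouched. Symmetric in `w`, maximal (1 per weight) at
#' grid midpoints.
#'
#' @param weights Numeric vector (or list of arrays) of weights.
#' @param B Bit depth.
#' @return Non-negative scalar.
#' @examples
#' quant_loss(1 / 15, 4)  # 0
#' quant_loss(1 / 30, 4)  # 1
#' @export
quant_loss <- function(weights, B) {
  w <- unlist(weights, use.names = FALSE)
  stopifnot(all(is.finite(w)))
  sum(abs(sin(quant_multiplier(B) * pi * w)))
}

#' Categorical cross-entropy of two-class logits
#'
#' @param logits Numeric `[N x 2]` matrix, columns (no-humans, humans).
#' @param labels Integer vector of 0/1 labels.
#' @return Mean negative log-likelihood.
#' @export
cce_loss <- function(logits, labels) {
  stopifnot(nrow(logits) == length(labels))
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  picked <- logits[cbind(seq_along(labels), labels + 1L)]
  mean(lse - picked)
}

#' Two-component training loss
#'
#' Cross-entropy alone before the activation epoch; cross-entropy plus
#' `lambda * L_Q` from the activation epoch onwards. The quantization loss is
#' evaluated on the supplied (already normalized) weights.
#'
#' @param logits `[N x 2]` logits matrix.
#' @param labels 0/1 labels.
#' @param quantizable_weights Weights entering `L_Q` (vector or list).
#' @param qc A [quant_config()].
#' @param epoch Current epoch (1-based).
#' @return Scalar loss.
#' @export
total_loss <- function(logits, labels, quantizable_weights, qc, epoch) {
  stopifnot(epoch >= 1)
  l <- cce_loss(logits, labels)
  if (epoch >= qc$activation_epoch && qc$lambda > 0) {
    l <- l + qc$lambda * quant_loss(quantizable_weights, qc$bit_depth)
  }
  l
}

#' Per-neuron affine weight renormalization
#'
#' Maps a neuron's weight vector onto `[-1, 1]`:
#' `w_hat_j = (2*w_j - w_max - w_min) / (w_max - w_min)`, with scale
#' `k = (w_max - w_min)/2` and offset `B = (w_max + w_min)/2`, so that
#' `w_j = k * w_hat_j + B` exactly. All neurons can then share one small
#' codebook for `w_hat` while realizing diverse effective weight sets
#' through their individual `(k, B)`. Constant vectors map to
#' `w_hat = 0, k = 0, B = w`.
#'
#' @param w Numeric weight vector (length >= 2 for a meaningful map).
#' @return An object of class `neuron_affine`: list `w_hat`, `scale`,
#'   `offset`.
#' @examples
#' normalize_neuron(c(-2, 0, 2))  # w_hat -1,0,1; scale 2; offset 0
#' @export
normalize_neuron <- function(w) {
  stopifnot(is.numeric(w), all(is.finite(w)))
  wmax <- max(w); wmin <- min(w)
  if (wmax == wmin) {
    out <- list(w_hat = rep(0, length(w)), scale = 0, offset = wmax)
  } else {
    out <- list(w_hat = (2 * w - wmax - wmin) / (wmax - wmin),
                scale = (wmax - wmin) / 2, offset = (wmax + wmin) / 2)
  }
  structure(out, class = "neuron_affine")
}

#' Affine-renormalized dot product
#'
#' The quantized-neuron dataflow: the dot product with the shared-codebook
#' weights, `x' w_hat`, is scaled by the neuron's `k` and shifted by its
#' offset acting on the input sum, `k * (x' w_hat) + offset * sum(x)` --
#' realizable in hardware as a synapse on a constant input -- which equals
#' `x' w` exactly before quantization.
#'
#' @param x Input vector.
#' @param na A `neuron_affine` (from [normalize_neuron()]).
#' @return Scalar.
#' @examples
#' affine_dot(c(1, 1), normalize_neuron(c(1, 3)))  # == sum(c(1, 1) * c(1, 3))
#' @export
affine_dot <- function(x, na) {
  if (length(x) != length(na$w_hat)) stop("length mismatch", call. = FALSE)
  na$scale * sum(x * na$w_hat) + na$offset * sum(x)
}

#' Hard quantization to a codebook
#'
#' Maps each value to the nearest grid level; exact midpoints round away
#' from zero; values beyond the grid ends clamp to the extreme levels.
#' Idempotent.
#'
#' @param values Numeric vector/array.
#' @param grid Sorted numeric codebook (e.g. [quant_grid()]).
#' @return Quantized values, same shape as `values`.
#' @examples
#' hard_quantize(0.09, quant_grid(4))   # 1/15
#' hard_quantize(1 / 30, quant_grid(4)) # 1/15 (tie away from zero)
#' @export
hard_quantize <- function(values, grid) {
  stopifnot(length(grid) >= 1, !is.unsorted(grid))
  shp <- dim(values)
  v <- as.vector(values)
  lo <- findInterval(v, grid)
  lo <- pmin(pmax(lo, 1L), length(grid) - 1L)
  a <- grid[lo]; b <- grid[pmin(lo + 1L, length(grid))]
  da <- abs(v - a); db <- abs(v - b)
  pick_b <- db < da | (db == da & abs(b) > abs(a))
  out <- ifelse(pick_b, b, a)
  out[v <= grid[1]] <- grid[1]
  out[v >= grid[length(grid)]] <- grid[length(grid)]
  if (!is.null(shp)) dim(out) <- shp
  out
}

# ---- neuron-level views of the parameter set -------------------------------

# Each GRU gate neuron's weight vector is the row [W_g | U_g | b_g | c_g]
# (biases treated as weights on constant-1 inputs); each head neuron is
# [W_fc | b_fc]. These matrices are the unit of per-neuron renormalization,
# quantization and the quantization loss.
neuron_matrices <- function(params) {
  out <- list()
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    for (g in c("r", "z", "h")) {
      out[[paste0("layer", l, "_", g)]] <-
        cbind(ly[[paste0("W_", g)]], ly[[paste0("U_", g)]],
              ly[[paste0("b_", g)]], ly[[paste0("c_", g)]])
    }
  }
  out$fc <- cbind(params$fc$W, params$fc$b)
  out
}

# Inverse of neuron_matrices: scatter (possibly modified) rows back.
set_neuron_matrices <- function(params, mats) {
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    I <- ncol(ly$W_r); W <- ncol(ly$U_r)
    for (g in c("r", "z", "h")) {
      M <- mats[[paste0("layer", l, "_", g)]]
      params$layers[[l]][[paste0("W_", g)]] <- M[, seq_len(I), drop = FALSE]
      params$layers[[l]][[paste0("U_", g)]] <- M[, I + seq_len(W), drop = FALSE]
      params$layers[[l]][[paste0("b_", g)]] <- M[, I + W + 1]
      params$layers[[l]][[paste0("c_", g)]] <- M[, I + W + 2]
    }
  }
  M <- mats$fc
  params$fc$W <- M[, -ncol(M), drop = FALSE]
  params$fc$b <- M[, ncol(M)]
  params
}

# Row-wise normalization of a neuron matrix; returns w_hat matrix plus
# per-row scale/offset. Degenerate (constant) rows give scale 0.
normalize_rows <- function(M) {
  wmax <- apply(M, 1, max); wmin <- apply(M, 1, min)
  rng <- wmax - wmin
  ok <- rng > 0
  what <- M
  what[ok, ] <- (2 * M[ok, , drop = FALSE] - wmax[ok] - wmin[ok]) / rng[ok]
  what[!ok, ] <- 0
  list(w_hat = what, scale = rng / 2, offset = (wmax + wmin) / 2)
}

# Quantization loss (and its gradient wrt the raw weights) over all neuron
# matrices, evaluated on the row-normalized weights with a straight-through
# treatment of the per-row max/min.
quant_loss_grad <- function(params, B) {
  mats <- neuron_matrices(params)
  mult <- quant_multiplier(B)
  loss <- 0
  grads <- lapply(mats, function(M) {
    nr <- normalize_rows(M)
    s <- sin(mult * pi * nr$w_hat)
    loss <<- loss + sum(abs(s))
    # |sin| has a kink at the codebook levels; weights already on a level
    # (within fp noise of a zero crossing) get the subgradient 0 there,
    # avoiding spurious +/- mult*pi pulls on the row extrema w_hat = +/-1
    sg <- sign(s)
    sg[abs(s) < 1e-9] <- 0
    g <- mult * pi * sg * cos(mult * pi * nr$w_hat)
    scale2 <- ifelse(nr$scale > 0, 1 / nr$scale, 0)  # d w_hat / d w = 1/scale
    g * scale2
  })
  list(loss = loss, grads = grads)
}

#' Quantize a trained network for analog deployment
#'
#' Per neuron (each GRU gate row and each head row, biases appended as
#' weights on constant inputs): renormalize with [normalize_neuron()], hard
#' quantize the normalized weights on the B-bit codebook, and hard quantize
#' the neuron scale and offset as codes against per-layer references
#' (`k_ref = max |k|`, `B_ref = max |offset|` over the layer's neurons).
#' Input batch normalization, if present, is folded into the first layer's
#' input weights and biases before quantization, so the quantized forward
#' pass uses only quantized quantities. Idempotent.
#'
#' @param fit A `gru_fit` (see [train_gru()]) or a list with `config` and
#'   `params`.
#' @param qc A [quant_config()].
#' @return A `gru_fit` whose `params` are the reconstructed quantized
#'   parameters (`bn = NULL`), with a `quant` element holding the integer
#'   codes (`w` in `[-multiplier, multiplier]` per neuron matrix, `k_code`,
#'   `b_code`, per-matrix `k_ref`, `b_ref`) and the `quant_config`.
#' @export
quantize_network <- function(fit, qc = quant_config()) {
  params <- fold_bn(fit$params)
  grid <- quant_grid(qc$bit_depth)
  mult <- qc$multiplier
  mats <- neuron_matrices(params)
  codes <- list()
  qmats <- list()
  for (nm in names(mats)) {
    nr <- normalize_rows(mats[[nm]])
    what_q <- hard_quantize(nr$w_hat, grid)
    k_ref <- max(abs(nr$scale))
    b_ref <- max(abs(nr$offset))
    k_q <- if (k_ref > 0) hard_quantize(nr$scale / k_ref, grid) * k_ref else nr$scale * 0
    b_q <- if (b_ref > 0) hard_quantize(nr$offset / b_ref, grid) * b_ref else nr$offset * 0
    qmats[[nm]] <- what_q * k_q + b_q  # reconstructed effective weights
    codes[[nm]] <- list(
      w = matrix(as.integer(round(what_q * mult)), nrow(what_q)),
      k_code = as.integer(round(if (k_ref > 0) hard_quantize(nr$scale / k_ref, grid) * mult else nr$scale * 0)),
      b_code = as.integer(round(if (b_ref > 0) hard_quantize(nr$offset / b_ref, grid) * mult else nr$offset * 0)),
      k_ref = k_ref, b_ref = b_ref
    )
  }
  out <- fit
  out$params <- set_neuron_matrices(params, qmats)
  out$params$bn <- NULL
  out$quant <- list(codes = codes, qc = qc)
  out$route <- if (identical(fit$route, "qat")) "qat" else paste0(fit$route %||% "float", "+diversified")
  class(out) <- "gru_fit"
  out
}

#' Naive post-hoc quantization
#'
#' The baseline the diversified scheme is measured against: every weight of
#' a float-trained model is forced directly to the nearest level of the
#' shared `[-1, 1]` codebook, with no per-neuron renormalization (batch
#' normalization, if present, is folded first so both routes quantize the
#' same effective parameters).
#'
#' @inheritParams quantize_network
#' @return A `gru_fit` with directly quantized parameters.
#' @export
naive_quantize <- function(fit, qc = quant_config()) {
  params <- fold_bn(fit$params)
  grid <- quant_grid(qc$bit_depth)
  mats <- neuron_matrices(params)
  qmats <- lapply(mats, hard_quantize, grid = grid)
  out <- fit
  out$params <- set_neuron_matrices(params, qmats)
  out$params$bn <- NULL
  out$route <- "naive"
  class(out) <- "gru_fit"
  out
}

# Effective parameters with hard-quantized neuron scales and offsets (the
# per-neuron affine references), used in the forward pass during the
# quantization-aware training phase with a straight-through gradient: the
# normalized weights stay continuous (the periodic loss pulls them to the
# codebook), while each neuron's scale/offset is already the deployable
# codebook code times the layer reference, so cross-entropy training
# compensates the scale rounding.
quantize_scales <- function(params, qc) {
  grid <- quant_grid(qc$bit_depth)
  mats <- neuron_matrices(params)
  qmats <- lapply(mats, function(M) {
    nr <- normalize_rows(M)
    k_ref <- max(abs(nr$scale))
    b_ref <- max(abs(nr$offset))
    k_q <- if (k_ref > 0) hard_quantize(nr$scale / k_ref, grid) * k_ref else nr$scale
    b_q <- if (b_ref > 0) hard_quantize(nr$offset / b_ref, grid) * b_ref else nr$offset
    nr$w_hat * k_q + b_q
  })
  set_neuron_matrices(params, qmats)
}

# Fold input batch normalization into the first GRU layer: per input channel
# c, BN computes g_c * x_c + s_c with g = gamma/sqrt(var + eps) and
# s = beta - gamma * mean / sqrt(var + eps); the first layer's input weight
# columns absorb g and the biases absorb W %*% s.
fold_bn <- function(params, eps = 1e-5) {
  if (is.null(params$bn)) return(params)
  g <- params$bn$gamma / sqrt(params$bn$var + eps)
  s <- params$bn$beta - params$bn$mean * g
  ly <- params$layers[[1]]
  for (gate in c("r", "z", "h")) {
    Wg <- ly[[paste0("W_", gate)]]
    ly[[paste0("b_", gate)]] <- ly[[paste0("b_", gate)]] + drop(Wg %*% s)
    ly[[paste0("W_", gate)]] <- sweep(Wg, 2, g, `*`)
  }
  params$layers[[1]] <- ly
  params$bn <- NULL
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a
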