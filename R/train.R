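# Training machinery: backpropagation through time for the stacked GRU,
# Adam, the two-phase (cross-entropy then cross-entropy + quantization)
# schedule, and the fitted-model class.

# ---- parameter-tree utilities ----------------------------------------------

tree_map <- function(f, a) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    return(stats::setNames(
      lapply(seq_along(a), function(i) tree_map2(f, a[[i]], b[[i]])),
      names(a)))
  }
  f(a, b)
}

zeros_like <- function(a) tree_map(function(x) x * 0, a)

tree_sum <- function(f, a) {
  s <- 0
  walk <- function(x) {
    if (is.null(x)) return(invisible())
    if (is.list(x)) { lapply(x, walk); return(invisible()) }
    s <<- s + f(x)
    invisible()
  }
  walk(a)
  s
}

# ---- backward pass ---------------------------------------------------------

# Gradient of the scalar loss wrt all parameters, given dlogits [N x 2]
# (softmax - onehot, already averaged). Mirrors gru_forward_array with
# keep_cache = TRUE.
gru_backward <- function(config, params, cache, dlogits) {
  grads <- zeros_like(params)
  N <- cache$dims[["N"]]; T <- cache$dims[["T"]]
  W <- config$W

  grads$fc$W <- t(dlogits) %*% cache$Hlast
  grads$fc$b <- colSums(dlogits)
  dTop <- dlogits %*% params$fc$W               # [N x W]

  dNext <- NULL  # gradient wrt the current layer's full output [N, T, W]
  for (l in rev(seq_len(config$L))) {
    ly <- params$layers[[l]]
    lc <- cache$layers[[l]]
    I <- ncol(ly$W_r)
    dOut <- if (l == config$L) {
      a <- array(0, dim = c(N, T, W)); a[, T, ] <- dTop; a
    } else {
      d <- dNext
      if (!is.null(cache$drop_masks[[l]])) d <- d * cache$drop_masks[[l]]
      d
    }
    res <- gru_layer_backward_cpp(
      matrix(dOut, N * T, W), lc$Xflat,
      rbind(ly$W_r, ly$W_z, ly$W_h), rbind(ly$U_r, ly$U_z, ly$U_h),
      lc$r, lc$z, lc$u, lc$hc, lc$hprev, N, T
    )
    ir <- seq_len(W); iz <- W + ir; ih <- 2 * W + ir
    grads$layers[[l]] <- list(
      W_r = res$GW[ir, , drop = FALSE], U_r = res$GU[ir, , drop = FALSE],
      b_r = res$bx[ir], c_r = res$bu[ir],
      W_z = res$GW[iz, , drop = FALSE], U_z = res$GU[iz, , drop = FALSE],
      b_z = res$bx[iz], c_z = res$bu[iz],
      W_h = res$GW[ih, , drop = FALSE], U_h = res$GU[ih, , drop = FALSE],
      b_h = res$bx[ih], c_h = res$bu[ih]
    )
    dNext <- array(res$dX, dim = c(N, T, I))
  }

  if (!is.null(params$bn)) {
    # only the gain/shift are trainable; dNext here is the gradient wrt the
    # batch-normalized input
    bnc <- cache$bn
    C <- config$C
    dgamma <- numeric(C); dbeta <- numeric(C)
    for (c in seq_len(C)) {
      dy <- dNext[, , c]
      dgamma[c] <- sum(dy * bnc$xn[, , c])
      dbeta[c] <- sum(dy)
    }
    grads$bn$gamma <- dgamma
    grads$bn$beta <- dbeta
    grads$bn$mean <- numeric(C)
    grads$bn$var <- numeric(C)
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# ---- training schedule -----------------------------------------------------

#' Training schedule
#'
#' @param epochs Number of epochs (default 20).
#' @param lr Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 64).
#' @param clip Global L2 gradient-norm clip (standard recurrent-network
#'   practice; `Inf` disables).
#' @return A list of schedule settings.
#' @export
train_schedule <- function(epochs = 20L, lr = 1e-3, batch_size = 64L,
                           clip = 5) {
  stopifnot(epochs >= 1, lr > 0, batch_size >= 1, clip > 0)
  list(epochs = as.integer(epochs), lr = lr,
       batch_size = as.integer(batch_size), clip = clip)
}

clip_grads <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  nrm <- sqrt(tree_sum(function(g) sum(g^2), grads))
  if (nrm > clip) grads <- tree_map(function(g) g * (clip / nrm), grads)
  grads
}

#' Train a GRU detector
#'
#' Minimizes categorical cross-entropy over the descriptor windows with
#' Adam. When a [quant_config()] is supplied the training is two-phase:
#' cross-entropy only before the activation epoch, cross-entropy plus
#' `lambda * L_Q` (the periodic quantization loss on the per-neuron
#' renormalized weights, straight-through gradient for the row extrema)
#' afterwards, and the network is hard quantized once after the final epoch
#' via [quantize_network()]. Dropout between GRU layers and input batch
#' normalization are active when the architecture carries the `-X` flag.
#' The whole run is a deterministic function of `(windows, arch, schedule,
#' qc, seed)`.
#'
#' @param windows A `descriptor_windows` tibble (both classes present).
#' @param arch Architecture string or [network_config()].
#' @param schedule A [train_schedule()].
#' @param qc `NULL` for an unconstrained float model, or a [quant_config()]
#'   for quantization-aware training.
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @return An object of class `gru_fit`: `config`, `params` (quantized when
#'   `qc` was given, with `params_float` keeping the pre-quantization
#'   state), `history` (per-epoch tibble with `cce`, `lq`, `total`,
#'   `train_accuracy`), `route` (`"float"` or `"qat"`), `quant` codes when
#'   quantized.
#' @export
train_gru <- function(windows, arch = "C3-W8-L3-X",
                      schedule = train_schedule(), qc = NULL, seed = 1L) {
  config <- if (is.character(arch)) network_config(arch) else arch
  da <- windows_array(windows)
  x <- da$x; labels <- da$labels
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (!is.null(qc) && qc$activation_epoch > schedule$epochs) {
    stop("activation_epoch exceeds the number of epochs", call. = FALSE)
  }

  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "train"))

  params <- init_params(config, seed = seed)
  opt <- adam_init(params)
  N <- dim(x)[1]
  history <- vector("list", schedule$epochs)

  for (epoch in seq_len(schedule$epochs)) {
    idx <- sample.int(N)
    batches <- split(idx, ceiling(seq_along(idx) / schedule$batch_size))
    cce_sum <- 0; acc_sum <- 0
    lq_on <- !is.null(qc) && qc$lambda > 0 && epoch >= qc$activation_epoch
    for (b in batches) {
      xb <- x[b, , , drop = FALSE]
      yb <- labels[b]
      # during the quantization phase the forward pass runs on the
      # deployable affine form (codebook-coded neuron scales/offsets);
      # gradients pass straight through to the raw weights
      params_fw <- if (lq_on) quantize_scales(params, qc) else params
      fw <- gru_forward_array(config, params_fw, xb, training = TRUE,
                              keep_cache = TRUE)
      loss_b <- cce_loss(fw$logits, yb)
      if (!is.finite(loss_b)) {
        stop("training aborted: non-finite cross-entropy at epoch ", epoch,
             " (logit range ", paste(range(fw$logits), collapse = " .. "),
             ")", call. = FALSE)
      }
      cce_sum <- cce_sum + loss_b * length(b)
      acc_sum <- acc_sum + sum(max.col(fw$logits, ties.method = "first") - 1L == yb)
      sm <- exp(fw$logits - apply(fw$logits, 1, max))
      sm <- sm / rowSums(sm)
      onehot <- matrix(0, length(b), 2)
      onehot[cbind(seq_along(yb), yb + 1L)] <- 1
      dlogits <- (sm - onehot) / length(b)
      grads <- gru_backward(config, params_fw, fw$cache, dlogits)
      grads <- clip_grads(grads, schedule$clip %||% Inf)
      if (lq_on) {
        qg <- quant_loss_grad(params, qc$bit_depth)
        mats_g <- lapply(qg$grads, function(g) qc$lambda * g)
        gq <- set_neuron_matrices(zeros_like(params), mats_g)
        grads <- tree_map2(`+`, grads, gq)
      }
      if (!is.null(params$bn)) {
        # running statistics (momentum 0.1) for inference
        mu_b <- apply(xb, 3, mean)
        v_b <- apply(xb, 3, function(a) mean((a - mean(a))^2))
        params$bn$mean <- 0.9 * params$bn$mean + 0.1 * mu_b
        params$bn$var <- 0.9 * params$bn$var + 0.1 * v_b
      }
      st <- adam_step(params, grads, opt, lr = schedule$lr)
      bn_stats <- params$bn[c("mean", "var")]
      params <- st$params
      if (!is.null(params$bn)) params$bn[c("mean", "var")] <- bn_stats
      opt <- st$state
    }
    lq_val <- if (is.null(qc)) NA_real_ else {
      quant_loss_grad(params, qc$bit_depth)$loss
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      cce = cce_sum / N,
      lq = lq_val,
      lq_weight = if (lq_on) qc$lambda else 0,
      total = cce_sum / N + (if (lq_on) qc$lambda * lq_val else 0),
      train_accuracy = acc_sum / N
    )
  }

  fit <- structure(
    list(config = config, params = params,
         history = dplyr::bind_rows(history),
         schedule = schedule, qc = qc, seed = as.integer(seed),
         route = if (is.null(qc)) "float" else "qat",
         n_train = N),
    class = "gru_fit"
  )
  if (!is.null(qc)) {
    q <- quantize_network(fit, qc)
    q$params_float <- fit$params
    q$route <- "qat"
    fit <- q
  }
  fit
}

#' @export
print.gru_fit <- function(x, ...) {
  cat("<gru_fit ", format_arch(x$config), "> route ", x$route,
      ", trained on ", x$n_train, " windows, ",
      nrow(x$history), " epochs",
      if (!is.null(x$quant)) paste0(", quantized (B = ", x$quant$qc$bit_depth, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Predict human presence from descriptor windows
#'
#' @param object A `gru_fit`.
#' @param windows A `descriptor_windows` tibble (or `[T x C]` matrix /
#'   `[N, T, C]` array).
#' @param ... Unused.
#' @return A tibble with columns `.pred_class` (0/1), `.prob_humans`, and
#'   the window `label` when available.
#' @export
predict.gru_fit <- function(object, windows, ...) {
  logits <- gru_forward(object$config, object$params, windows)
  sm <- exp(logits - apply(logits, 1, max))
  sm <- sm / rowSums(sm)
  out <- tibble::tibble(
    .pred_class = as.integer(max.col(logits, ties.method = "first") - 1L),
    .prob_humans = sm[, 2]
  )
  if (inherits(windows, "descriptor_windows")) out$label <- as.integer(windows$label)
  out
}
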