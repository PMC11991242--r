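#' Network architecture configuration
#'
#' Architectures are encoded as `"C{c}-W{w}-L{l}[-X]"`: `C` input descriptor
#' channels, `W` GRU units per layer, `L` stacked GRU layers, and a trailing
#' `X` marking the use of input batch normalization and inter-layer dropout
#' during training. A two-neuron fully connected head reads the final time
#' step of the top layer and produces the (no-humans, humans) logits.
#'
#' @param arch Architecture string, e.g. `"C3-W8-L3-X"`.
#' @param dropout_p Neuron exclusion probability used when the `X` flag is
#'   set (default 0.3).
#' @return An object of class `network_config` with fields `C`, `W`, `L`,
#'   `use_bn_dropout`, `dropout_p`.
#' @examples
#' network_config("C3-W8-L3-X")
#' @export
network_config <- function(arch, dropout_p = 0.3) {
  m <- regmatches(arch, regexec("^C([0-9]+)-W([0-9]+)-L([0-9]+)(-X)?$", arch))[[1]]
  if (length(m) == 0) {
    stop("cannot parse architecture string '", arch,
         "' (expected \"C{c}-W{w}-L{l}[-X]\")", call. = FALSE)
  }
  C <- as.integer(m[2]); W <- as.integer(m[3]); L <- as.integer(m[4])
  if (W < 1 || L < 1 || C < 1) stop("degenerate architecture: ", arch, call. = FALSE)
  structure(list(C = C, W = W, L = L, use_bn_dropout = m[5] == "-X",
                 dropout_p = dropout_p, arch = arch),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config ", format_arch(x), "> ", count_params(x),
      " parameters\n", sep = "")
  invisible(x)
}

format_arch <- function(config) {
  paste0("C", config$C, "-W", config$W, "-L", config$L,
         if (config$use_bn_dropout) "-X" else "")
}

#' Count trainable parameters
#'
#' Counting convention: every GRU gate neuron processes its layer input
#' (`I` values), the recurrent state (`W` values) and two biases, giving
#' `3 * W * (I + W + 2)` parameters per layer; the fully connected head has
#' `2 * (W + 1)`; input batch normalization adds `2 * C` (gain and shift per
#' channel). The convention is fixed here and verified against enumeration
#' of the actual parameter containers.
#'
#' @param config A [network_config()] or architecture string.
#' @return Integer parameter count.
#' @examples
#' count_params(network_config("C1-W6-L3"))  # 680
#' @export
count_params <- function(config) {
  if (is.character(config)) config <- network_config(config)
  W <- config$W; L <- config$L; C <- config$C
  ins <- c(C, rep(W, L - 1))
  n <- sum(3 * W * (ins + W + 2)) + 2 * (W + 1)
  if (config$use_bn_dropout) n <- n + 2 * C
  as.integer(n)
}

#' Initialize network parameters
#'
#' Weights drawn uniformly in `+/- 1/sqrt(fan-in)` per matrix; biases zero;
#' batch-norm gain 1, shift 0, running statistics (0, 1).
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return Nested parameter list: `bn` (or `NULL`), `layers` (each with
#'   `W_r, U_r, b_r, c_r, W_z, U_z, b_z, c_z, W_h, U_h, b_h, c_h`), `fc`
#'   (`W`, `b`).
#' @export
init_params <- function(config, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "init"))
  W <- config$W
  umat <- function(nr, nc) {
    b <- 1 / sqrt(nc)
    matrix(stats::runif(nr * nc, -b, b), nr, nc)
  }
  layers <- lapply(seq_len(config$L), function(l) {
    I <- if (l == 1) config$C else W
    g <- function() list(W = umat(W, I), U = umat(W, W),
                         b = numeric(W), c = numeric(W))
    r <- g(); z <- g(); h <- g()
    list(W_r = r$W, U_r = r$U, b_r = r$b, c_r = r$c,
         W_z = z$W, U_z = z$U, b_z = z$b, c_z = z$c,
         W_h = h$W, U_h = h$U, b_h = h$b, c_h = h$c)
  })
  bn <- if (config$use_bn_dropout) {
    list(gamma = rep(1, config$C), beta = numeric(config$C),
         mean = numeric(config$C), var = rep(1, config$C))
  }
  list(bn = bn, layers = layers,
       fc = list(W = umat(2, W), b = numeric(2)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One GRU cell step
#'
#' Gate convention (two bias vectors per gate, reset gate applied to the
#' recurrent contribution inside the candidate):
#' \deqn{r = \sigma(W_r x + b_r + U_r h + c_r)}
#' \deqn{z = \sigma(W_z x + b_z + U_z h + c_z)}
#' \deqn{\tilde h = \tanh(W_h x + b_h + r \odot (U_h h + c_h))}
#' \deqn{h' = (1 - z) \odot h + z \odot \tilde h}
#' Every component of `h'` is a convex combination of a `tanh` output and the
#' previous state, so hidden activations stay inside `(-1, 1)`.
#'
#' @param layer One layer's parameter list (see [init_params()]).
#' @param x Input vector (length `I`).
#' @param h State vector (length `W`).
#' @return New state vector.
#' @export
gru_cell_step <- function(layer, x, h) {
  if (length(x) != ncol(layer$W_r) || length(h) != ncol(layer$U_r)) {
    stop("shape mismatch in gru_cell_step", call. = FALSE)
  }
  r <- sigmoid(drop(layer$W_r %*% x) + layer$b_r + drop(layer$U_r %*% h) + layer$c_r)
  z <- sigmoid(drop(layer$W_z %*% x) + layer$b_z + drop(layer$U_z %*% h) + layer$c_z)
  hc <- tanh(drop(layer$W_h %*% x) + layer$b_h + r * (drop(layer$U_h %*% h) + layer$c_h))
  (1 - z) * h + z * hc
}

# Batched forward pass over an [N, T, C] array. Returns logits [N, 2]; with
# training = TRUE applies batch statistics + dropout masks and, with
# keep_cache = TRUE, returns everything the backward pass needs.
gru_forward_array <- function(config, params, x, training = FALSE,
                              keep_cache = FALSE, bn_eps = 1e-5) {
  stopifnot(length(dim(x)) == 3)
  N <- dim(x)[1]; T <- dim(x)[2]; C <- dim(x)[3]
  if (C != config$C) {
    stop("window channel count ", C, " does not match config C = ",
         config$C, call. = FALSE)
  }
  cache <- list()
  if (!is.null(params$bn)) {
    if (training) {
      mu <- apply(x, 3, mean)
      v <- apply(x, 3, function(a) mean((a - mean(a))^2))
    } else {
      mu <- params$bn$mean
      v <- params$bn$var
    }
    xn <- x
    for (c in seq_len(C)) {
      xn[, , c] <- (x[, , c] - mu[c]) / sqrt(v[c] + bn_eps)
    }
    y <- xn
    for (c in seq_len(C)) {
      y[, , c] <- params$bn$gamma[c] * xn[, , c] + params$bn$beta[c]
    }
    if (keep_cache) cache$bn <- list(xn = xn, mu = mu, var = v, eps = bn_eps)
    x <- y
  }

  inp <- x
  layer_caches <- vector("list", config$L)
  drop_masks <- vector("list", config$L)
  for (l in seq_len(config$L)) {
    ly <- params$layers[[l]]
    W <- config$W
    I <- dim(inp)[3]
    Xflat <- matrix(inp, N * T, I)                  # [N*T, I], t-major blocks
    res <- gru_layer_forward_cpp(
      Xflat, rbind(ly$W_r, ly$W_z, ly$W_h), rbind(ly$U_r, ly$U_z, ly$U_h),
      c(ly$b_r, ly$b_z, ly$b_h), c(ly$c_r, ly$c_z, ly$c_h),
      N, T, keep_cache
    )
    out <- array(res$out, dim = c(N, T, W))
    if (training && config$use_bn_dropout && l < config$L &&
        config$dropout_p > 0) {
      mask <- array(stats::rbinom(N * T * W, 1, 1 - config$dropout_p),
                    dim = c(N, T, W)) / (1 - config$dropout_p)
      out <- out * mask
      drop_masks[[l]] <- mask
    }
    if (keep_cache) {
      res$out <- NULL
      res$Xflat <- Xflat
      layer_caches[[l]] <- res
    }
    inp <- out
  }
  Hlast <- matrix(inp[, T, ], N, config$W)
  logits <- sweep(Hlast %*% t(params$fc$W), 2, params$fc$b, `+`)
  if (!keep_cache) return(logits)
  cache$layers <- layer_caches
  cache$drop_masks <- drop_masks
  cache$Hlast <- Hlast
  cache$dims <- c(N = N, T = T, C = C)
  list(logits = logits, cache = cache)
}

#' Forward pass on descriptor windows
#'
#' Applies input batch normalization (inference statistics), the stacked GRU
#' layers from zero initial state, and the two-neuron head to each window.
#'
#' @param config A [network_config()].
#' @param params Parameter list (see [init_params()]).
#' @param windows A `descriptor_windows` tibble, a single `[T x C]` matrix,
#'   or an `[N, T, C]` array.
#' @return Numeric logits matrix `[N x 2]`, columns
#'   `(no_humans, humans)`.
#' @export
gru_forward <- function(config, params, windows) {
  x <- windows_to_x(windows, config$C)
  gru_forward_array(config, params, x, training = FALSE)
}

windows_to_x <- function(windows, C) {
  if (inherits(windows, "descriptor_windows")) {
    windows_array(windows)$x
  } else if (is.matrix(windows)) {
    array(windows, dim = c(1, nrow(windows), ncol(windows)))
  } else if (is.array(windows) && length(dim(windows)) == 3) {
    windows
  } else {
    stop("cannot interpret `windows` as descriptor input", call. = FALSE)
  }
}

#' Fan-in-limited dot-product decomposition
#'
#' Physical neurons admit at most `max_fanin` inputs, so a wide dot product
#' is distributed over a tree of partial-sum units: level-1 units each take
#' at most `max_fanin` of the original weighted inputs, and combiner levels
#' sum partial results (unit weights) until one output remains. Whenever
#' `ceil(n_inputs / max_fanin) <= max_fanin` the tree has at most two
#' levels. The composed linear map reproduces the original dot product.
#'
#' @param n_inputs Number of inputs (>= 1).
#' @param max_fanin Hardware fan-in limit (>= 2), default 6.
#' @return An object of class `fanin_plan`: a list of levels, each a list of
#'   integer index vectors into the previous level's outputs.
#' @examples
#' fanin_plan(14)  # units of fan-in 6, 6, 2 plus one 3-input combiner
#' @export
fanin_plan <- function(n_inputs, max_fanin = 6L) {
  stopifnot(n_inputs >= 1, max_fanin >= 2)
  levels <- list()
  n <- as.integer(n_inputs)
  repeat {
    groups <- split(seq_len(n), ceiling(seq_len(n) / max_fanin))
    names(groups) <- NULL
    levels[[length(levels) + 1]] <- groups
    n <- length(groups)
    if (n == 1) break
  }
  structure(list(levels = levels, n_inputs = as.integer(n_inputs),
                 max_fanin = as.integer(max_fanin)),
            class = "fanin_plan")
}

#' @export
print.fanin_plan <- function(x, ...) {
  cat("<fanin_plan ", x$n_inputs, " inputs, max fan-in ", x$max_fanin, ">\n",
      sep = "")
  for (i in seq_along(x$levels)) {
    cat("  level ", i, ": fan-ins ",
        paste(lengths(x$levels[[i]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Apply a fan-in plan
#'
#' Evaluates the decomposed dot product: level-1 units compute weighted
#' partial sums of the inputs; higher levels sum their children.
#'
#' @param plan A [fanin_plan()].
#' @param w Weight vector of length `n_inputs`.
#' @param x Input vector of length `n_inputs`.
#' @return Scalar equal to `sum(w * x)` up to floating-point summation order.
#' @export
fanin_apply <- function(plan, w, x) {
  stopifnot(length(w) == plan$n_inputs, length(x) == plan$n_inputs)
  vals <- w * x
  for (groups in plan$levels) {
    vals <- vapply(groups, function(idx) sum(vals[idx]), 0)
  }
  vals[[1]]
}

#' Maximum fan-in used by a plan
#' @param plan A [fanin_plan()].
#' @return Integer, the largest unit fan-in over all levels.
#' @export
fanin_max <- function(plan) {
  max(vapply(plan$levels, function(g) max(lengths(g)), 0L))
}

#' Fan-in plans for a whole architecture
#'
#' Every GRU gate neuron of layer `l` processes `I_l + W + 2` values (layer
#' input, recurrent state, two biases on constant inputs) and every head
#' neuron `W + 1`; each distinct input size gets one decomposition plan.
#'
#' @param config A [network_config()] or architecture string.
#' @param max_fanin Hardware fan-in limit.
#' @return Named list of [fanin_plan()]s keyed by input size.
#' @export
fanin_plan_network <- function(config, max_fanin = 6L) {
  if (is.character(config)) config <- network_config(config)
  ins <- c(config$C, rep(config$W, config$L - 1))
  sizes <- sort(unique(c(ins + config$W + 2, config$W + 1)))
  stats::setNames(lapply(sizes, fanin_plan, max_fanin = max_fanin),
                  as.character(sizes))
}
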