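#' Encode a cultivation design for the surrogate network
#'
#' Plant spacing is min-max scaled from \[30, 80\] cm to \[-1, 1\]; the
#' pruning method enters as its ordinal code 1..4 scaled with the same
#' min-max rule (`"ordinal"` encoding, the default), or as four 0/1
#' indicator columns (`"onehot"`).
#'
#' @param spacing numeric vector of spacings (cm), or a data.frame with
#'   `spacing` and `pruning_code` columns.
#' @param pruning_code integer vector of codes in 1..4.
#' @param encoding `"ordinal"` or `"onehot"`.
#' @return numeric feature matrix (one row per design).
#' @examples
#' encode_design(55, 4)  # c(0, 1)
#' @export
encode_design <- function(spacing, pruning_code = NULL,
                          encoding = c("ordinal", "onehot")) {
  encoding <- match.arg(encoding)
  if (is.data.frame(spacing)) {
    pruning_code <- spacing$pruning_code
    spacing <- spacing$spacing
  }
  if (any(spacing < SPACING_MIN | spacing > SPACING_MAX)) {
    stop("spacing outside the feasible [", SPACING_MIN, ", ", SPACING_MAX,
         "] cm bounds")
  }
  if (!all(pruning_code %in% 1:4)) stop("pruning code outside 1..4")
  sp <- 2 * (spacing - SPACING_MIN) / (SPACING_MAX - SPACING_MIN) - 1
  if (encoding == "ordinal") {
    pr <- 2 * (pruning_code - 1) / 3 - 1
    cbind(spacing = sp, pruning = pr)
  } else {
    oh <- matrix(0, length(pruning_code), 4,
                 dimnames = list(NULL, paste0("pruning", 1:4)))
    oh[cbind(seq_along(pruning_code), pruning_code)] <- 1
    cbind(spacing = sp, oh)
  }
}

#' Surrogate training configuration
#'
#' Defaults follow the training contract of the cultivation surrogate: two
#' hidden layers of 12 and 8 units, at most 2000 epochs, damping/learning
#' rate 0.05, MSE target 1e-8 (on min-max scaled outputs), 10 random
#' restarts, and a 70/15/15 train/validation/test split.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param max_epochs maximum optimizer iterations per restart.
#' @param learning_rate initial Levenberg-Marquardt damping factor (and the
#'   step size of the gradient-descent fallback).
#' @param mse_target stop when training MSE (scaled space) falls below this.
#' @param restarts number of seeded re-initializations; the restart with
#'   the lowest validation MSE is kept.
#' @param split_fractions train/validation/test fractions (sum to 1); used
#'   when `split_mode = "random"`.
#' @param split_mode `"random"`, `"loo"` (one held-out validation sample,
#'   rotating across restarts), or `"none"` (train on everything;
#'   validation = training set).
#' @param method `"lm"` (damped second-order full-batch updates) or `"gd"`
#'   (full-batch gradient descent).
#' @param encoding design encoding, see [encode_design()].
#' @param seed integer seed controlling splits and initializations.
#' @return list of class `surrogate_config`.
#' @export
surrogate_config <- function(hidden_sizes = c(12, 8), max_epochs = 2000,
                             learning_rate = 0.05, mse_target = 1e-8,
                             restarts = 10,
                             split_fractions = c(0.7, 0.15, 0.15),
                             split_mode = c("random", "loo", "none"),
                             method = c("lm", "gd"),
                             encoding = c("ordinal", "onehot"),
                             seed = 1L) {
  split_mode <- match.arg(split_mode)
  method <- match.arg(method)
  encoding <- match.arg(encoding)
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            max_epochs >= 1, learning_rate > 0, mse_target >= 0,
            restarts >= 1, length(split_fractions) == 3,
            all(split_fractions >= 0),
            abs(sum(split_fractions) - 1) < 1e-8)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, mse_target = mse_target,
                 restarts = as.integer(restarts),
                 split_fractions = split_fractions, split_mode = split_mode,
                 method = method, encoding = encoding,
                 seed = as.integer(seed)),
            class = "surrogate_config")
}

# ---- network internals ------------------------------------------------------

# Layer sizes (input, hidden..., output) -> parameter count
mlp_layout <- function(sizes) {
  n <- length(sizes) - 1
  shapes <- vector("list", n)
  for (l in seq_len(n)) {
    shapes[[l]] <- c(sizes[l + 1], sizes[l])  # W_l is out x in
  }
  list(sizes = sizes, shapes = shapes,
       count = sum(vapply(shapes, prod, 0)) + sum(sizes[-1]))
}

mlp_unflatten <- function(theta, layout) {
  out <- list()
  pos <- 0
  for (l in seq_along(layout$shapes)) {
    sh <- layout$shapes[[l]]
    out[[paste0("W", l)]] <- matrix(theta[pos + seq_len(prod(sh))], sh[1], sh[2])
    pos <- pos + prod(sh)
    out[[paste0("b", l)]] <- theta[pos + seq_len(sh[1])]
    pos <- pos + sh[1]
  }
  out
}

# Forward pass; tanh on hidden layers, identity output. Returns activations
# per layer when `keep = TRUE` (needed for the Jacobian).
mlp_forward <- function(theta, layout, X, keep = FALSE) {
  par <- mlp_unflatten(theta, layout)
  nl <- length(layout$shapes)
  A <- X
  acts <- if (keep) list(A) else NULL
  for (l in seq_len(nl)) {
    Z <- A %*% t(par[[paste0("W", l)]]) +
      matrix(par[[paste0("b", l)]], nrow(A), layout$sizes[l + 1], byrow = TRUE)
    A <- if (l < nl) tanh(Z) else Z
    if (keep) acts[[l + 1]] <- A
  }
  if (keep) list(out = A, acts = acts, par = par) else A
}

# Jacobian of the stacked residual vector (output-major: all samples of
# output 1, then output 2, ...) with respect to the flattened parameters.
# Backpropagation vectorized over the whole batch, one pass per output
# unit; row order matches `as.vector(pred - Y)`.
mlp_jacobian <- function(theta, layout, X) {
  fw <- mlp_forward(theta, layout, X, keep = TRUE)
  par <- fw$par
  nl <- length(layout$shapes)
  n <- nrow(X)
  K <- layout$sizes[length(layout$sizes)]
  kblocks <- vector("list", K)
  for (k in seq_len(K)) {
    # M[[l]][s, ] = d out_k / d z_l for sample s
    M <- vector("list", nl)
    Mk <- matrix(0, n, K)
    Mk[, k] <- 1
    M[[nl]] <- Mk
    if (nl >= 2) {
      for (l in seq(nl - 1, 1)) {
        M[[l]] <- (M[[l + 1]] %*% par[[paste0("W", l + 1)]]) *
          (1 - fw$acts[[l + 1]]^2)
      }
    }
    blocks <- vector("list", 2 * nl)
    for (l in seq_len(nl)) {
      a_prev <- fw$acts[[l]]
      in_w <- ncol(a_prev)
      out_w <- ncol(M[[l]])
      # d r / d vec(W_l), vec() column-major: khatri-rao style expansion
      blocks[[2 * l - 1]] <-
        a_prev[, rep(seq_len(in_w), each = out_w), drop = FALSE] *
        M[[l]][, rep(seq_len(out_w), in_w), drop = FALSE]
      blocks[[2 * l]] <- M[[l]]  # d r / d b_l
    }
    kblocks[[k]] <- do.call(cbind, blocks)
  }
  list(J = do.call(rbind, kblocks), pred = fw$out)
}

# Damped second-order (Levenberg-Marquardt) full-batch trainer on scaled
# data. Returns theta, epoch history of train/val MSE, and stop reason.
train_lm <- function(theta, layout, Xtr, Ytr, Xval, Yval, cfg) {
  lambda <- cfg$learning_rate
  n_res <- length(Ytr)
  mse_of <- function(pred, Y) mean((pred - Y)^2)
  pred <- mlp_forward(theta, layout, Xtr)
  mse <- mse_of(pred, Ytr)
  val_hist <- numeric(0)
  epoch <- 0
  reason <- "max_epochs"
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1
    jb <- mlp_jacobian(theta, layout, Xtr)
    r <- as.vector(jb$pred - Ytr)
    g <- crossprod(jb$J, r)
    A <- crossprod(jb$J)
    improved <- FALSE
    for (try in 1:30) {
      delta <- tryCatch(
        solve(A + diag(lambda, nrow(A)), -g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.vector(delta)
        pred_c <- mlp_forward(cand, layout, Xtr)
        mse_c <- mse_of(pred_c, Ytr)
        if (is.finite(mse_c) && mse_c < mse) {
          theta <- cand
          rel <- (mse - mse_c) / max(mse, .Machine$double.eps)
          mse <- mse_c
          lambda <- max(lambda / 10, 1e-12)
          improved <- TRUE
          if (rel < 1e-12) reason <- "converged"
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    val_hist[epoch] <- mse_of(mlp_forward(theta, layout, Xval), Yval)
    if (!improved) { reason <- "stalled"; break }
    if (mse <= cfg$mse_target) { reason <- "mse_target"; break }
    if (reason == "converged") break
  }
  if (!is.finite(mse)) stop("training diverged (non-finite loss)")
  list(theta = theta, train_mse = mse, val_hist = val_hist,
       epochs = epoch, reason = reason)
}

# Full-batch gradient-descent fallback behind the same interface.
train_gd <- function(theta, layout, Xtr, Ytr, Xval, Yval, cfg) {
  mse_of <- function(pred, Y) mean((pred - Y)^2)
  val_hist <- numeric(0)
  mse <- mse_of(mlp_forward(theta, layout, Xtr), Ytr)
  reason <- "max_epochs"
  for (epoch in seq_len(cfg$max_epochs)) {
    jb <- mlp_jacobian(theta, layout, Xtr)
    r <- as.vector(jb$pred - Ytr)
    g <- 2 * crossprod(jb$J, r) / length(r)
    theta <- theta - cfg$learning_rate * as.vector(g)
    mse <- mse_of(mlp_forward(theta, layout, Xtr), Ytr)
    val_hist[epoch] <- mse_of(mlp_forward(theta, layout, Xval), Yval)
    if (!is.finite(mse)) stop("training diverged (non-finite loss)")
    if (mse <= cfg$mse_target) { reason <- "mse_target"; break }
  }
  list(theta = theta, train_mse = mse, val_hist = val_hist,
       epochs = length(val_hist), reason = reason)
}

# Min-max scale targets to [-1, 1]; constant columns map to 0 and descale
# back to the constant.
make_yscaler <- function(Y) {
  lo <- apply(Y, 2, min)
  hi <- apply(Y, 2, max)
  rng <- hi - lo
  list(lo = lo, hi = hi, rng = rng)
}
scale_y <- function(Y, sc) {
  out <- Y
  for (j in seq_len(ncol(Y))) {
    out[, j] <- if (sc$rng[j] > 0)
      2 * (Y[, j] - sc$lo[j]) / sc$rng[j] - 1 else 0
  }
  out
}
descale_y <- function(Ys, sc) {
  out <- Ys
  for (j in seq_len(ncol(Ys))) {
    out[, j] <- if (sc$rng[j] > 0)
      (Ys[, j] + 1) / 2 * sc$rng[j] + sc$lo[j] else sc$lo[j]
  }
  out
}

split_indices <- function(n, cfg, restart) {
  if (cfg$split_mode == "none") {
    return(list(train = seq_len(n), val = seq_len(n), test = integer(0)))
  }
  if (cfg$split_mode == "loo") {
    hold <- ((restart - 1) %% n) + 1
    return(list(train = setdiff(seq_len(n), hold), val = hold,
                test = integer(0)))
  }
  idx <- sample.int(n)
  n_tr <- max(2, round(cfg$split_fractions[1] * n))
  n_val <- max(1, round(cfg$split_fractions[2] * n))
  n_tr <- min(n_tr, n - 1)
  n_val <- min(n_val, n - n_tr)
  list(train = sort(idx[seq_len(n_tr)]),
       val = if (n_val > 0) sort(idx[n_tr + seq_len(n_val)]) else
         sort(idx[seq_len(n_tr)]),
       test = if (n - n_tr - n_val > 0) sort(idx[(n_tr + n_val + 1):n]) else
         integer(0))
}

#' Train the cultivation surrogate network
#'
#' Fits a small feed-forward regression network (default 2-12-8-3, tanh
#' hidden layers, identity output) mapping the encoded design (spacing,
#' pruning) to the three objectives (total growth duration, yield, quality
#' closeness Ci), by seeded multi-restart full-batch Levenberg-Marquardt on
#' min-max scaled inputs and outputs. The restart with the lowest
#' validation MSE is kept.
#'
#' @param ds a [trial_dataset()] whose `responses` hold complete
#'   `duration`, `yield`, `ci` for at least 6 treatments.
#' @param cfg a [surrogate_config()].
#' @return list with `model` (class `melon_surrogate`) and `report` (class
#'   `surrogate_fit_report`: per-split MSE and goodness-of-fit R, epoch of
#'   minimum validation MSE, restart chosen, stop reason).
#' @export
train_surrogate <- function(ds, cfg = surrogate_config()) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(cfg, "surrogate_config"))
  tr <- ds$treatments
  resp <- ds$responses
  if (is.null(resp)) stop("dataset has no responses table")
  resp <- resp[match(tr$label, resp$label), ]
  need <- c("duration", "yield", "ci")
  miss <- setdiff(need, names(resp))
  if (length(miss)) stop("responses missing column(s): ",
                         paste(miss, collapse = ", "))
  incomplete <- tr$label[!stats::complete.cases(resp[, need])]
  if (length(incomplete)) {
    stop("incomplete (duration, yield, ci) responses for treatment(s): ",
         paste(incomplete, collapse = ", "))
  }
  if (nrow(resp) < 6) stop("need responses for at least 6 treatments")

  X <- encode_design(tr$spacing, tr$pruning_code, cfg$encoding)
  Y <- as.matrix(resp[, need])
  ysc <- make_yscaler(Y)
  Ys <- scale_y(Y, ysc)
  layout <- mlp_layout(c(ncol(X), cfg$hidden_sizes, ncol(Y)))
  trainer <- if (cfg$method == "lm") train_lm else train_gd

  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    fit <- with_seed(derive_seed(cfg$seed, r), {
      sp <- split_indices(nrow(X), cfg, r)
      theta0 <- stats::runif(layout$count, -0.5, 0.5)
      f <- trainer(theta0, layout, X[sp$train, , drop = FALSE],
                   Ys[sp$train, , drop = FALSE],
                   X[sp$val, , drop = FALSE], Ys[sp$val, , drop = FALSE],
                   cfg)
      f$split <- sp
      f
    })
    fit$val_mse <- if (length(fit$val_hist)) fit$val_hist[fit$epochs] else Inf
    fit$restart <- r
    if (is.null(best) || fit$val_mse < best$val_mse) best <- fit
  }

  model <- structure(list(
    theta = best$theta, layout = layout, encoding = cfg$encoding,
    yscale = ysc, outputs = need, config = cfg,
    meta = list(seed = cfg$seed, restart = best$restart,
                epochs = best$epochs, train_mse = best$train_mse,
                val_mse = best$val_mse, stop_reason = best$reason)
  ), class = "melon_surrogate")

  split_stats <- function(idx) {
    if (!length(idx)) return(list(mse = NA_real_, r = NA_real_,
                                  r_defined = FALSE))
    pred <- mlp_forward(best$theta, layout, X[idx, , drop = FALSE])
    obs <- Ys[idx, , drop = FALSE]
    r <- tryCatch(goodness_of_fit(as.vector(pred), as.vector(obs)),
                  error = function(e) NA_real_)
    list(mse = mean((pred - obs)^2), r = r, r_defined = !is.na(r))
  }
  report <- structure(list(
    train = split_stats(best$split$train),
    validation = split_stats(best$split$val),
    test = split_stats(best$split$test),
    epoch_min_val = if (length(best$val_hist)) which.min(best$val_hist)
      else NA_integer_,
    epochs = best$epochs, restart = best$restart,
    stop_reason = best$reason, split = best$split
  ), class = "surrogate_fit_report")
  list(model = model, report = report)
}

#' @export
print.melon_surrogate <- function(x, ...) {
  cat("Feed-forward cultivation surrogate",
      paste(x$layout$sizes, collapse = "-"), "\n")
  cat(sprintf("  restart %d, %d epochs, train MSE %.3g (scaled), stop: %s\n",
              x$meta$restart, x$meta$epochs, x$meta$train_mse,
              x$meta$stop_reason))
  invisible(x)
}

#' @export
print.surrogate_fit_report <- function(x, ...) {
  f <- function(s) sprintf("MSE %.3g, R %.4f", s$mse, s$r)
  cat("Surrogate fit (scaled space):\n")
  cat("  train:     ", f(x$train), "\n")
  cat("  validation:", f(x$validation), "\n")
  if (!is.na(x$test$mse)) cat("  test:      ", f(x$test), "\n")
  cat("  epoch of min validation MSE:", x$epoch_min_val, "\n")
  invisible(x)
}

#' Predict objectives for cultivation designs
#'
#' Deterministic forward pass through a trained surrogate, descaled to
#' physical units. Ci predictions are clamped to \[0, 1\]; whether any
#' clamping occurred is recorded in the `"ci_clamped"` attribute.
#'
#' @param object a `melon_surrogate` from [train_surrogate()].
#' @param newdata data.frame with `spacing` and `pruning_code` columns (or
#'   a `trial_dataset`).
#' @param ... unused.
#' @return data.frame with columns `spacing`, `pruning_code`, `duration`
#'   (days), `yield` (t/hm^2), `ci`.
#' @export
predict.melon_surrogate <- function(object, newdata, ...) {
  if (inherits(newdata, "trial_dataset")) newdata <- newdata$treatments
  stopifnot(all(c("spacing", "pruning_code") %in% names(newdata)))
  X <- encode_design(newdata$spacing, newdata$pruning_code, object$encoding)
  pred <- descale_y(mlp_forward(object$theta, object$layout, X),
                    object$yscale)
  colnames(pred) <- object$outputs
  clamped <- any(pred[, "ci"] < 0 | pred[, "ci"] > 1)
  pred[, "ci"] <- pmin(pmax(pred[, "ci"], 0), 1)
  out <- data.frame(spacing = newdata$spacing,
                    pruning_code = newdata$pruning_code, pred,
                    stringsAsFactors = FALSE)
  attr(out, "ci_clamped") <- clamped
  out
}

#' Serialize / restore a trained surrogate as JSON
#'
#' @param model a `melon_surrogate`.
#' @param path JSON file path.
#' @return `read_surrogate()` returns the restored `melon_surrogate`;
#'   predictions are bit-identical to the saved model's.
#' @export
write_surrogate <- function(model, path) {
  stopifnot(inherits(model, "melon_surrogate"))
  payload <- list(theta = model$theta, sizes = model$layout$sizes,
                  encoding = model$encoding,
                  yscale = model$yscale[c("lo", "hi", "rng")],
                  outputs = model$outputs, meta = model$meta)
  # digits = I(17): significant digits, enough for exact double round-trip
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17)),
             path)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  p <- jsonlite::fromJSON(path)
  structure(list(
    theta = as.numeric(p$theta), layout = mlp_layout(as.integer(p$sizes)),
    encoding = p$encoding,
    yscale = list(lo = as.numeric(p$yscale$lo), hi = as.numeric(p$yscale$hi),
                  rng = as.numeric(p$yscale$rng)),
    outputs = p$outputs, config = NULL, meta = p$meta
  ), class = "melon_surrogate")
}
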