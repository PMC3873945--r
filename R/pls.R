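#' Multi-response partial least squares decoder
#'
#' Fits a PLS2 regression of the 3-D hand position on the lag-embedded
#' feature matrix. Factors are extracted sequentially: each weight vector
#' is the dominant left singular vector of the current X'Y cross-covariance
#' (the fixed point of the classical NIPALS inner iteration), scores are
#' mutually orthogonal, and deflation is carried on the cross-covariance
#' (kernel formulation), which is algebraically identical to NIPALS PLS2
#' with joint deflation but runs off the crossproduct matrices. X and Y are
#' centered only — features are already dimensionless z-scores, and Y keeps
#' its physical units.
#'
#' @param X numeric matrix (rows = time points, columns = features) or a
#'   `design_matrix` from [lag_embed()].
#' @param Y numeric matrix of targets (rows matching `X`); taken from the
#'   design when `X` is a `design_matrix`.
#' @param n_latent number of latent variables to extract.
#' @return a `pls_model`: list with `B` (features x outputs coefficients),
#'   `intercept`, `x_mean`, `y_mean`, `R` (weight directions in original X
#'   coordinates), `P`, `Q` (X/Y loadings), `t_sq` (score norms),
#'   `n_latent`, and `index` (column bijection, when fitted on a design).
#' @export
fit_pls <- function(X, Y = NULL, n_latent) {
  index <- NULL
  if (inherits(X, "design_matrix")) {
    if (is.null(Y)) Y <- X$Y
    index <- X$index
    X <- X$X
  }
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_invalid("X and Y row counts differ")
  if (n_latent < 0) stop_invalid("n_latent must be >= 0 (0 = intercept-only model)")
  if (n_latent > min(nrow(X) - 1L, ncol(X)))
    stop_invalid("n_latent = ", n_latent, " exceeds feasible factors for a ",
                 nrow(X), " x ", ncol(X), " design")
  if (all(X == 0)) stop_invalid("design matrix is identically zero")
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2L, x_mean); Yc <- sweep(Y, 2L, y_mean)
  core <- pls_kernel_core(crossprod(Xc), crossprod(Xc, Yc), n_latent)
  new_pls_model(core, x_mean, y_mean, index)
}

new_pls_model <- function(core, x_mean, y_mean, index) {
  B <- core$R %*% t(core$Q)
  structure(list(B = B,
                 intercept = as.numeric(y_mean - x_mean %*% B),
                 x_mean = x_mean, y_mean = y_mean,
                 R = core$R, P = core$P, Q = core$Q, t_sq = core$t_sq,
                 n_latent = ncol(core$R), index = index),
            class = "pls_model")
}

# Kernel PLS2 core (cross-covariance deflation only). Cxx and Cxy are the
# *centered* crossproduct matrices t(Xc) Xc and t(Xc) Yc. Returns weight
# directions R such that scores t_h = Xc R[, h] are mutually orthogonal with
# squared norms t_sq, plus loadings P, Q.
pls_kernel_core <- function(Cxx, Cxy, n_latent) {
  p <- nrow(Cxx); q <- ncol(Cxy)
  R <- matrix(0, p, n_latent); P <- matrix(0, p, n_latent)
  Q <- matrix(0, q, n_latent); t_sq <- numeric(n_latent)
  if (n_latent == 0L) return(list(R = R, P = P, Q = Q, t_sq = t_sq))
  scale0 <- sqrt(sum(Cxy^2))
  if (scale0 == 0) stop_invalid("X and Y are uncorrelated (zero cross-covariance); no factor can be extracted")
  M <- Cxy
  for (h in seq_len(n_latent)) {
    sv <- svd(M, nu = 1L, nv = 0L)
    if (sv$d[1L] <= 1e-12 * scale0)
      stop_invalid("n_latent = ", n_latent, " exceeds the ", h - 1L,
                   " extractable factor(s) (residual cross-covariance is zero)")
    w <- sv$u[, 1L]
    r <- if (h == 1L) w else
      w - R[, seq_len(h - 1L), drop = FALSE] %*%
        crossprod(P[, seq_len(h - 1L), drop = FALSE], w)
    cr <- Cxx %*% r
    tsq <- as.numeric(crossprod(r, cr))
    if (tsq <= .Machine$double.eps * sum(diag_of(Cxx)))
      stop_invalid("degenerate factor ", h, ": score variance is zero")
    ph <- cr / tsq
    qh <- as.numeric(crossprod(M, r)) / tsq
    M <- M - tsq * ph %*% t(qh)
    R[, h] <- r; P[, h] <- ph; Q[, h] <- qh; t_sq[h] <- tsq
  }
  list(R = R, P = P, Q = Q, t_sq = t_sq)
}

diag_of <- function(M) M[cbind(seq_len(nrow(M)), seq_len(nrow(M)))]

#' Predict hand position from a fitted PLS model
#'
#' `Yhat = (X - x_mean) B + y_mean`; affine in X, and evaluating the model
#' at the training feature means returns the training target means.
#'
#' @param object a `pls_model`.
#' @param X feature matrix (or `design_matrix`) with the model's columns.
#' @param ... unused.
#' @return matrix of predicted positions, rows matching `X`.
#' @export
predict.pls_model <- function(object, X, ...) {
  if (inherits(X, "design_matrix")) X <- X$X
  if (ncol(X) != nrow(object$B))
    stop_invalid("X has ", ncol(X), " columns but the model expects ", nrow(object$B))
  sweep(X, 2L, object$x_mean) %*% object$B +
    matrix(object$y_mean, nrow(X), length(object$y_mean), byrow = TRUE)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d features -> %d outputs\n",
              x$n_latent, nrow(x$B), ncol(x$B)))
  invisible(x)
}

#' Reshape model coefficients to the weight tensor w(channel, band, lag)
#'
#' Uses the design's column bijection to address every coefficient by
#' (channel i, band j, lag k) for one output axis, so the decoder can be
#' written and evaluated as the explicit lag sum.
#'
#' @param model a `pls_model` fitted on a `design_matrix`.
#' @param axis output axis (1 = x, 2 = y, 3 = z).
#' @return 3-D array channels x bands x lags with dimnames.
#' @export
weight_tensor <- function(model, axis = 1L) {
  if (is.null(model$index)) stop_invalid("model was not fitted on a design_matrix")
  idx <- model$index
  channels <- unique(idx$channel); bands <- unique(idx$band)
  n_lags <- max(idx$lag)
  w <- array(NA_real_, dim = c(length(channels), length(bands), n_lags),
             dimnames = list(channel = as.character(channels), band = bands,
                             lag = as.character(seq_len(n_lags))))
  w[cbind(match(idx$channel, channels), match(idx$band, bands), idx$lag)] <-
    model$B[idx$column, axis]
  w
}

#' Predictive error sum of squares
#'
#' Sum of squared differences between predicted and observed positions over
#' all samples and the three coordinate axes.
#'
#' @param Y,Yhat matrices of identical shape.
#' @return nonnegative scalar.
#' @export
press <- function(Y, Yhat) {
  if (!all(dim(as.matrix(Y)) == dim(as.matrix(Yhat))))
    stop_invalid("Y and Yhat shapes differ")
  sum((as.matrix(Y) - as.matrix(Yhat))^2)
}

#' Coefficient of determination per axis
#'
#' `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` about the observed mean of the
#' evaluation segment, computed per axis; the mean of the three axes is the
#' summary used throughout. Negative values are possible (and reported) out
#' of sample; this is the coefficient of determination, not a squared
#' correlation.
#'
#' @param Y,Yhat observed and predicted matrices, identical shape.
#' @return list with `per_axis` (named numeric) and `mean`.
#' @export
r_squared <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop_invalid("Y and Yhat shapes differ")
  ss_tot <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  if (any(ss_tot == 0)) stop_invalid("zero-variance target axis: R^2 undefined")
  ss_res <- colSums((Y - Yhat)^2)
  per_axis <- 1 - ss_res / ss_tot
  names(per_axis) <- if (ncol(Y) == 3L) c("x", "y", "z") else colnames(Y)
  list(per_axis = per_axis, mean = mean(per_axis))
}

#' Cross-validated PRESS curve over latent counts
#'
#' Partitions rows into `k_folds` contiguous temporal blocks (no shuffling:
#' the rows are an autocorrelated time series) and, for every latent count
#' `1..max_latent`, accumulates the predictive error sum of squares and the
#' mean held-out R-squared over folds. Deterministic: fold assignment is a
#' pure function of the row count.
#'
#' @param X feature matrix or `design_matrix`; @param Y targets (from the
#'   design when omitted).
#' @param max_latent largest latent count to evaluate.
#' @param k_folds number of folds (default 10).
#' @return a `cv_curve`: data.frame with `n_latent`, `press`, `r2_mean`,
#'   plus attributes `folds` (row index list), `k_folds`, and the
#'   intercept-only baseline `press0` / `r2_0`.
#' @export
cross_validate <- function(X, Y = NULL, max_latent = 20L, k_folds = 10L) {
  if (inherits(X, "design_matrix")) { if (is.null(Y)) Y <- X$Y; X <- X$X }
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (k_folds < 2L) stop_invalid("k_folds must be >= 2")
  if (n < 2L * k_folds) stop_insufficient("too few rows (", n, ") for ", k_folds, " folds")
  fold_id <- contiguous_folds(n, k_folds)
  folds <- split(seq_len(n), fold_id)
  max_latent <- as.integer(max_latent)
  # raw (uncentered) totals; per-fold train statistics by subtraction
  sx_tot <- colSums(X); sy_tot <- colSums(Y)
  Sxy_tot <- crossprod(X, Y)
  Sxx_tot <- matrix(0, ncol(X), ncol(X))
  for (f in folds) Sxx_tot <- Sxx_tot + crossprod(X[f, , drop = FALSE])
  press_fk <- matrix(0, length(folds), max_latent)
  r2_k <- matrix(0, max_latent, length(folds))
  press_f0 <- numeric(length(folds)); r2_0 <- numeric(length(folds))
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    Xf <- X[f, , drop = FALSE]; Yf <- Y[f, , drop = FALSE]
    n_tr <- n - length(f)
    sx <- sx_tot - colSums(Xf); sy <- sy_tot - colSums(Yf)
    xm <- sx / n_tr; ym <- sy / n_tr
    Cxx <- (Sxx_tot - crossprod(Xf)) - tcrossprod(sx) / n_tr
    Cxy <- (Sxy_tot - crossprod(Xf, Yf)) - tcrossprod(sx, sy) / n_tr
    A_f <- min(max_latent, n_tr - 1L, ncol(X))
    core <- pls_kernel_core(Cxx, Cxy, A_f)
    Tf <- sweep(Xf, 2L, xm) %*% core$R
    yhat <- matrix(ym, nrow(Xf), ncol(Y), byrow = TRUE)
    # intercept-only baseline: does any latent variable beat the mean?
    press_f0[fi] <- press(Yf, yhat)
    r2_0[fi] <- r_squared(Yf, yhat)$mean
    for (h in seq_len(max_latent)) {
      if (h <= A_f) yhat <- yhat + Tf[, h] %*% t(core$Q[, h])
      press_fk[fi, h] <- press(Yf, yhat)
      r2_k[h, fi] <- r_squared(Yf, yhat)$mean
    }
  }
  curve <- data.frame(n_latent = seq_len(max_latent),
                      press = colSums(press_fk),
                      r2_mean = rowMeans(r2_k))
  structure(curve, class = c("cv_curve", "data.frame"),
            folds = folds, k_folds = k_folds,
            press0 = sum(press_f0), r2_0 = mean(r2_0),
            press_folds = press_fk, press0_folds = press_f0)
}

contiguous_folds <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Choose the number of latent variables from a PRESS curve
#'
#' Picks the smallest latent count whose PRESS lies within `plateau_tol`
#' (relative) of the curve minimum — the start of the plateau — capped at
#' `cap`. If the curve records an intercept-only baseline (`press0`
#' attribute from [cross_validate()]) and no latent count beats it, 0 is
#' returned: the honest model for data with no decodable signal is the
#' training mean. Pass `fixed` to bypass the rule with a predetermined
#' count.
#'
#' @param curve a `cv_curve` from [cross_validate()].
#' @param plateau_tol relative tolerance defining the plateau (default 1%).
#' @param cap upper bound on the selected count (default 20).
#' @param fixed optional predetermined count overriding the rule.
#' @return integer latent count.
#' @export
select_n_latent <- function(curve, plateau_tol = 0.01, cap = 20L, fixed = NULL) {
  if (!is.null(fixed)) return(min(as.integer(fixed), max(curve$n_latent)))
  if (nrow(curve) == 0L) stop_invalid("empty CV curve")
  pmin_ <- min(curve$press)
  # one-SE guard against the intercept baseline: unless the best latent
  # count beats the mean predictor by more than one standard error of the
  # paired per-fold PRESS difference, keep the intercept-only model — the
  # data carry no decodable signal. Autocorrelated sessions can otherwise
  # hand a spurious factor a small, unreliable CV gain.
  press0 <- attr(curve, "press0")
  if (!is.null(press0)) {
    pf <- attr(curve, "press_folds"); p0f <- attr(curve, "press0_folds")
    se <- if (!is.null(pf)) {
      d <- pf[, which.min(curve$press)] - p0f
      stats::sd(d) * sqrt(length(d))
    } else 0
    if (press0 - pmin_ <= se) return(0L)
  }
  knee <- curve$n_latent[which(curve$press <= pmin_ * (1 + plateau_tol))[1L]]
  as.integer(min(knee, cap))
}
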