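test_that("full-rank PLS reproduces least squares and the NIPALS reference", {
  set.seed(10)
  X <- matrix(rnorm(50 * 5), 50, 5)
  Y <- X %*% matrix(rnorm(15), 5, 3) + 0.2 * matrix(rnorm(150), 50, 3)
  m <- fit_pls(X, Y, 5)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_lt(max(abs(m$B - ols)) / max(abs(ols)), 1e-6)
  # independent reference implementation agrees in the rank-deficient regime
  Xw <- matrix(rnorm(60 * 30), 60, 30); colnames(Xw) <- paste0("v", 1:30)
  Yw <- Xw[, 1:4] %*% matrix(rnorm(12), 4, 3) + 0.3 * matrix(rnorm(180), 60, 3)
  mw <- fit_pls(Xw, Yw, 6)
  ref <- mixOmics::pls(Xw, Yw, ncomp = 6, mode = "regression", scale = FALSE)
  expect_equal(unname(predict(ref, Xw)$predict[, , 6]),
               unname(predict(mw, Xw)), tolerance = 1e-8)
})

test_that("noiseless realizable targets are fitted essentially exactly", {
  set.seed(11)
  X <- matrix(rnorm(200 * 8), 200, 8)
  Y <- X %*% matrix(rnorm(24), 8, 3)
  m <- fit_pls(X, Y, 8)
  expect_gt(r_squared(Y, predict(m, X))$mean, 0.999)
})

test_that("a single informative column reduces to its univariate regression", {
  set.seed(12)
  x <- rnorm(80)
  X <- cbind(x, 0, 0)
  Y <- cbind(2 * x + rnorm(80, 0, 0.1), -x + rnorm(80, 0, 0.1),
             0.5 * x + rnorm(80, 0, 0.1))
  m <- fit_pls(X, Y, 1)
  for (a in 1:3) {
    slope <- cov(x, Y[, a]) / var(x)
    expect_equal(m$B[1, a], slope, tolerance = 1e-10)
    expect_equal(m$B[2:3, a], c(0, 0))
  }
})

test_that("prediction is an affine map with centering consistency", {
  set.seed(13)
  X <- matrix(rnorm(100 * 6), 100, 6)
  Y <- X %*% matrix(rnorm(18), 6, 3) + matrix(rnorm(300), 100, 3)
  m <- fit_pls(X, Y, 3)
  expect_equal(as.numeric(predict(m, matrix(colMeans(X), 1))),
               unname(colMeans(Y)), tolerance = 1e-10)
  X1 <- matrix(rnorm(30), 5, 6); X2 <- matrix(rnorm(30), 5, 6)
  a <- 0.3
  expect_equal(predict(m, a * X1 + (1 - a) * X2),
               a * predict(m, X1) + (1 - a) * predict(m, X2), tolerance = 1e-10)
  expect_error(predict(m, matrix(0, 2, 5)), "columns")
})

test_that("the reshaped weight tensor evaluated as the explicit lag sum matches predict", {
  ft <- fake_tensor(3, 2, 200, fs = 100,
                    fill = function(i, b, t) sin(0.3 * i * t / (b + 2)))
  traj <- fake_trajectory(200, 100)
  d <- lag_embed(ft, traj, lag_spec(0.05, 4), stride_s = 0.1)
  m <- fit_pls(d, n_latent = 5)
  rows <- c(1, 7, nrow(d$X))
  t_idx <- round(d$times_s[rows] * 100) + 1
  direct <- eq2_predict(m, ft, t_idx, step_n = 5)
  expect_equal(direct, unname(predict(m, d$X[rows, , drop = FALSE])),
               tolerance = 1e-10)
})

test_that("PRESS is the summed squared prediction error", {
  Y <- matrix(rnorm(30), 10, 3)
  expect_equal(press(Y, Y), 0)
  expect_equal(press(matrix(0, 2, 3), matrix(1, 2, 3)), 6)
  Yh <- matrix(rnorm(30), 10, 3)
  expect_equal(press(Y, Yh), sum((Y - Yh)^2), tolerance = 1e-12)
  expect_error(press(Y, matrix(0, 2, 3)), "shapes")
})

test_that("R-squared follows the coefficient-of-determination definition", {
  set.seed(14)
  Y <- matrix(rnorm(60), 20, 3)
  expect_equal(r_squared(Y, Y)$per_axis, c(x = 1, y = 1, z = 1))
  mean_pred <- matrix(colMeans(Y), 20, 3, byrow = TRUE)
  expect_equal(r_squared(Y, mean_pred)$per_axis, c(x = 0, y = 0, z = 0))
  Y0 <- sweep(Y, 2, colMeans(Y))
  # anti-predictions: R^2 = -3 per axis; negative values are meaningful
  expect_equal(unname(r_squared(Y0, -Y0)$per_axis), c(-3, -3, -3))
  expect_error(r_squared(matrix(1, 5, 3), matrix(0, 5, 3)), "zero-variance")
})

test_that("cross-validation partitions time contiguously and is deterministic", {
  set.seed(15)
  X <- matrix(rnorm(1000 * 8), 1000, 8)
  Y <- X %*% matrix(rnorm(24), 8, 3) + 0.5 * matrix(rnorm(3000), 1000, 3)
  cv <- cross_validate(X, Y, max_latent = 8, k_folds = 10)
  folds <- attr(cv, "folds")
  expect_equal(lengths(folds), rep(100, 10), ignore_attr = TRUE)
  expect_equal(sort(unname(unlist(folds))), 1:1000)
  expect_true(all(vapply(folds, function(f) all(diff(f) == 1), logical(1))))
  # PRESS decreases to the true rank then flattens; never increases much after
  expect_lt(cv$press[8], cv$press[1])
  expect_lt(abs(cv$press[8] - cv$press[7]) / cv$press[7], 0.05)
  cv2 <- cross_validate(X, Y, max_latent = 8, k_folds = 10)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
  expect_error(cross_validate(X[1:15, ], Y[1:15, ], 2, 10), "too few rows")
})

test_that("latent-count selection finds the PRESS plateau knee", {
  mk_curve <- function(press) structure(
    data.frame(n_latent = seq_along(press), press = press,
               r2_mean = 1 - press / max(press)),
    class = c("cv_curve", "data.frame"))
  knee <- mk_curve(c(100, 60, 30, 15, 8, 5, 3.5, 3.02, 3.01, 3.0, 3.0, 3.0))
  expect_equal(select_n_latent(knee, plateau_tol = 0.01), 8)
  steep <- mk_curve(100 * 0.5^(1:30))
  expect_equal(select_n_latent(steep, cap = 20), 20)
  flat <- mk_curve(rep(7, 10))
  expect_equal(select_n_latent(flat), 1)
  expect_equal(select_n_latent(steep, fixed = 20), 20)
})

test_that("the intercept baseline guards against fitting pure noise", {
  set.seed(16)
  X <- matrix(rnorm(400 * 30), 400, 30)
  Y <- matrix(rnorm(1200), 400, 3)  # no relationship at all
  cv <- cross_validate(X, Y, max_latent = 6, k_folds = 10)
  expect_equal(select_n_latent(cv), 0)
  m0 <- fit_pls(X, Y, 0)
  expect_equal(unname(predict(m0, X[1:4, ])),
               matrix(colMeans(Y), 4, 3, byrow = TRUE))
  # with real structure the guard does not bite
  Ys <- X %*% matrix(rnorm(90), 30, 3) + 0.3 * matrix(rnorm(1200), 400, 3)
  cvs <- cross_validate(X, Ys, max_latent = 6, k_folds = 10)
  expect_gte(select_n_latent(cvs), 1)
})

test_that("X-scores are mutually orthogonal", {
  set.seed(17)
  X <- matrix(rnorm(120 * 40), 120, 40)
  Y <- X[, 1:6] %*% matrix(rnorm(18), 6, 3) + 0.5 * matrix(rnorm(360), 120, 3)
  m <- fit_pls(X, Y, 8)
  scores <- sweep(X, 2, m$x_mean) %*% m$R
  G <- crossprod(scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  expect_equal(unname(diag(G)), m$t_sq, tolerance = 1e-8)
})

test_that("R-squared and PRESS agree through the variance identity", {
  set.seed(18)
  Y <- matrix(rnorm(90), 30, 3)
  Yh <- Y + 0.4 * matrix(rnorm(90), 30, 3)
  r2 <- r_squared(Y, Yh)
  ss_tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  per_axis_press <- colSums((Y - Yh)^2)
  expect_equal(unname(r2$per_axis), unname(1 - per_axis_press / ss_tot))
  expect_equal(press(Y, Yh), sum(per_axis_press))
})

test_that("held-out accuracy rises with the planted signal-to-noise ratio", {
  r2s <- vapply(c(0.5, 4, 25), function(snr) {
    ds <- make_dataset(list(duration_s = 60, fs = 500, n_rows = 4L, n_cols = 2L,
                            truth = ground_truth(informative_channels = 1:3,
                                                 snr = snr),
                            seed = 21L))
    ctx <- prepare_decoding(ds, small_cfg())
    decode_full(ctx, 8)$r2$mean
  }, numeric(1))
  expect_true(all(diff(r2s) > 0))
})
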