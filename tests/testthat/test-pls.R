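test_that("a rank-one problem is solved exactly with one factor", {
  set.seed(1)
  t_ <- rnorm(12)
  p_ <- rnorm(6)
  X <- outer(t_, p_)
  y <- drop(X %*% rnorm(6))
  fit <- fit_pls(X, y, 1)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  for (seed in 1:10) {
    prob <- make_pls_problem(20, 10, seed)
    fit <- fit_pls(prob$X, prob$y, 10)
    ols <- stats::lm.fit(cbind(1, prob$X), prob$y)$fitted.values
    expect_equal(predict(fit, prob$X), unname(ols), tolerance = 1e-6)
  }
})

test_that("the fit is invariant to sample order", {
  prob <- make_pls_problem(15, 8, 42)
  fit <- fit_pls(prob$X, prob$y, 4)
  set.seed(99)
  perm <- sample(15)
  fit_p <- fit_pls(prob$X[perm, ], prob$y[perm], 4)
  expect_equal(fit_p$W, fit$W, tolerance = 1e-8)
  expect_equal(fit_p$q, fit$q, tolerance = 1e-8)
  xnew <- matrix(rnorm(8), 1)
  expect_equal(predict(fit_p, xnew), predict(fit, xnew),
               tolerance = 1e-8)
})

test_that("NIPALS score vectors are mutually orthogonal", {
  prob <- make_pls_problem(25, 12, 7)
  fit <- fit_pls(prob$X, prob$y, 8)
  Tm <- fit$scores
  for (i in 1:7) for (j in (i + 1):8) {
    cosine <- abs(sum(Tm[, i] * Tm[, j])) /
      (sqrt(sum(Tm[, i]^2)) * sqrt(sum(Tm[, j]^2)))
    expect_lt(cosine, 1e-8)
  }
})

test_that("training error is non-increasing in the factor count", {
  prob <- make_pls_problem(30, 10, 3, noise = 1)
  fit <- fit_pls(prob$X, prob$y, 10)
  rmse <- vapply(1:10, function(k)
    sqrt(mean((predict(fit, prob$X, n_factors = k) - prob$y)^2)),
    numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("predictions and RMSECV scale exactly with the response", {
  prob <- make_pls_problem(12, 6, 5)
  c_ <- 137.5
  f1 <- fit_pls(prob$X, prob$y, 4)
  f2 <- fit_pls(prob$X, c_ * prob$y, 4)
  xnew <- matrix(rnorm(6), 1)
  expect_equal(predict(f2, xnew), c_ * predict(f1, xnew),
               tolerance = 1e-10)
  cv1 <- loocv(prob$X, prob$y, 4)
  cv2 <- loocv(prob$X, c_ * prob$y, 4)
  expect_equal(cv2$rmsecv_by_factor, c_ * cv1$rmsecv_by_factor,
               tolerance = 1e-10)
})

test_that("predicting the training centre returns the response mean", {
  prob <- make_pls_problem(10, 5, 2)
  fit <- fit_pls(prob$X, prob$y, 3)
  expect_equal(predict(fit, matrix(fit$x_mean, 1)), mean(prob$y),
               tolerance = 1e-10)
})

test_that("LOOCV matches the brute-force refit oracle", {
  for (case in list(c(n = 8, p = 5, k = 3, seed = 1),
                    c(n = 10, p = 6, k = 4, seed = 2),
                    c(n = 12, p = 7, k = 5, seed = 3))) {
    prob <- make_pls_problem(case["n"], case["p"], case["seed"],
                             noise = 0.5)
    cv <- loocv(prob$X, prob$y, case["k"])
    oracle <- oracle_loocv_rmsecv(prob$X, prob$y, case["k"])
    expect_equal(unname(cv$rmsecv_by_factor), oracle, tolerance = 1e-9)
  }
})

test_that("duplicating every sample cannot worsen LOOCV", {
  prob <- make_pls_problem(8, 5, 13, noise = 0.5)
  cv1 <- loocv(prob$X, prob$y, 3)
  X2 <- rbind(prob$X, prob$X); y2 <- c(prob$y, prob$y)
  cv2 <- loocv(X2, y2, 3)
  expect_true(all(cv2$rmsecv_by_factor <= cv1$rmsecv_by_factor + 1e-10))
})

test_that("a constant response gives undefined r2 and zero RMSECV", {
  set.seed(21)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- rep(42, 8)
  cv <- loocv(X, y, 2)
  expect_true(all(is.na(cv$r2_by_factor)))
  expect_equal(unname(cv$rmsecv_by_factor), rep(0, 2), tolerance = 1e-10)
})

test_that("factor selection takes the smallest RMSECV argmin", {
  fake <- function(r) structure(list(rmsecv_by_factor = r),
                                class = "pls_cv")
  expect_equal(select_factors(fake(c(5, 3, 1, 2, 4))), 3L)
  expect_equal(select_factors(fake(c(5, 3, 1, 3, 1))), 3L)
  expect_equal(select_factors(fake(c(5, 4, 3, 2, 1))), 5L)
})

test_that("regression metrics match hand arithmetic", {
  y <- c(1, 2, 3, 4)
  expect_equal(regression_metrics(y, y), list(r2 = 1, rmse = 0))
  off <- regression_metrics(y, y + 2.5)
  expect_equal(off$rmse, 2.5)
  expect_equal(off$r2, 1)
  p <- c(1.1, 1.9, 3.2, 3.6)
  m <- regression_metrics(y, p)
  expect_equal(m$rmse, sqrt(mean((y - p)^2)))
  expect_equal(m$r2, cor(y, p)^2)
  expect_true(is.na(regression_metrics(y, rep(1, 4))$r2))
})

test_that("reference summaries use sample statistics", {
  tbl <- data.frame(nitrate_mg_per_kg = c(1, 2, 3))
  s <- summarize_references(tbl)
  expect_equal(s[c("n", "min", "max", "mean", "median", "sd")],
               list(n = 3L, min = 1, max = 3, mean = 2, median = 2,
                    sd = 1))
  one <- summarize_references(data.frame(nitrate_mg_per_kg = 5))
  expect_equal(one$sd, 0)
})

test_that("models round-trip through JSON with recipe intact", {
  cfg <- test_phantom_config()
  cal <- generate_calibration_set(cfg, 25, seed = 6)
  rec <- preprocess_recipe(step_snv(), step_derivative(1, 2))
  sm <- apply_recipe(cal$spectra, rec)
  fit <- fit_pls(sm, cal$table$nitrate_mg_per_kg, 3, recipe = rec)
  path <- file.path(tempdir(), "model.json")
  write_pls_model(fit, path)
  back <- read_pls_model(path)
  expect_equal(predict(back, sm), predict(fit, sm), tolerance = 1e-12)
  raw_new <- generate_calibration_set(cfg, 5, seed = 7)$spectra
  sm_new <- apply_recipe(raw_new, back$recipe)
  expect_equal(predict(back, sm_new),
               predict(fit, apply_recipe(raw_new, rec)),
               tolerance = 1e-12)
})
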