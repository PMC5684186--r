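#' Fit a PLS1 regression model by NIPALS
#'
#' Classical NIPALS partial least squares for a single response: X and y
#' are mean-centred (never variance-scaled), then factors are extracted
#' one at a time — weight vector from the X/y covariance, scores,
#' X-loadings, y-loading — with deflation of X and y after each factor.
#' The iteration for each factor starts from the maximal-variance X
#' column, making the fit fully deterministic, and stops when the relative
#' change of the score vector falls below `tol` (for a single response
#' this converges in one pass; the loop guards the general case).
#'
#' @param X a [spectrum_matrix()] or numeric matrix, samples x bands.
#' @param y numeric response vector (here nitrate content, mg/kg).
#' @param n_factors number of latent factors, `1 <= n_factors <=
#'   min(n_samples - 1, n_bands)`.
#' @param recipe optional [preprocess_recipe()] already applied to `X`;
#'   stored in the model and re-applied by the pixel mapper.
#' @param tol relative score-change convergence tolerance (default 1e-10).
#' @param max_iter iteration cap per factor (default 500).
#' @return An object of class `pls_model` with centring vectors, weights
#'   `W`, X-loadings `P`, y-loadings `q`, and the training wavelength axis.
#' @export
fit_pls <- function(X, y, n_factors, recipe = NULL, tol = 1e-10,
                    max_iter = 500L) {
  wl <- if (inherits(X, "spectrum_matrix")) wavelengths(X) else
    seq_len(ncol(X))
  X <- unclass(X); class(X) <- NULL
  X <- matrix(as.numeric(X), nrow(X), ncol(X))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  n_factors <- as.integer(n_factors)
  if (n_factors < 1L || n_factors > min(n - 1L, p))
    stop("`n_factors` must lie in 1..min(n_samples - 1, n_bands) = ",
         min(n - 1L, p), call. = FALSE)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  Tsc <- matrix(0, n, n_factors)
  for (a in seq_len(n_factors)) {
    # NIPALS inner loop. The y-side score starts from the deflated
    # response; with a single response the direction is stationary, so the
    # loop converges on its second pass, but convergence is still checked.
    css <- colSums(Xc^2)          # columns stay centred under deflation
    u <- yc
    if (sum(u^2) == 0) {
      # response fully deflated: continue along the dominant X column so
      # later factors stay well defined (their y-loadings are ~0)
      u <- Xc[, which.max(css)]
      if (sum(u^2) == 0)
        stop("NIPALS breakdown at factor ", a, ": X fully deflated",
             call. = FALSE)
    }
    t_old <- Xc[, which.max(css)]
    t_ <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("NIPALS breakdown at factor ", a,
                        ": zero weight vector", call. = FALSE)
      w <- w / nw
      t_ <- (Xc %*% w)[, 1]
      delta <- sqrt(sum((t_ - t_old)^2)) /
        max(sqrt(sum(t_^2)), .Machine$double.eps)
      t_old <- t_
      if (delta < tol) { converged <- TRUE; break }
      qa <- sum(yc * t_) / sum(t_^2)
      u <- if (qa != 0) yc / qa else u
    }
    if (!converged)
      stop("NIPALS did not converge at factor ", a, " after ", max_iter,
           " iterations", call. = FALSE)
    tt <- sum(t_^2)
    if (tt < .Machine$double.eps)
      stop("NIPALS breakdown at factor ", a, ": degenerate score vector",
           call. = FALSE)
    p_ <- crossprod(Xc, t_)[, 1] / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q_ * t_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_; Tsc[, a] <- t_
  }
  structure(list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
                 scores = Tsc, n_factors = n_factors, recipe = recipe,
                 wavelengths = wl),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d factors, %d bands\n", x$n_factors,
              length(x$x_mean)))
  if (!is.null(x$recipe)) print(x$recipe)
  invisible(x)
}

#' Predict responses from a fitted PLS model
#'
#' Centres the new spectra with the training means, projects them through
#' the weight/loading sequence (reproducing the training deflation), and
#' restores the response mean.
#'
#' @param object a `pls_model` from [fit_pls()].
#' @param newdata a [spectrum_matrix()] or numeric matrix whose band axis
#'   matches the model's training axis.
#' @param n_factors number of factors to use (default: all fitted).
#' @param ... unused.
#' @return Numeric vector of predictions (mg/kg).
#' @export
predict.pls_model <- function(object, newdata, n_factors = NULL, ...) {
  if (inherits(newdata, "spectrum_matrix")) {
    wl <- wavelengths(newdata)
    if (length(wl) != length(object$wavelengths) ||
        max(abs(wl - object$wavelengths)) > 1e-6)
      stop("band axis of `newdata` does not match the model's training axis",
           call. = FALSE)
  }
  X <- matrix(as.numeric(newdata), nrow(newdata), ncol(newdata))
  if (ncol(X) != length(object$x_mean))
    stop("`newdata` has ", ncol(X), " bands; model expects ",
         length(object$x_mean), call. = FALSE)
  k <- if (is.null(n_factors)) object$n_factors else as.integer(n_factors)
  if (k < 1L || k > object$n_factors)
    stop("`n_factors` out of range 1..", object$n_factors, call. = FALSE)
  Xc <- sweep(X, 2, object$x_mean)
  yhat <- rep(object$y_mean, nrow(X))
  for (a in seq_len(k)) {
    t_ <- Xc %*% object$W[, a]
    yhat <- yhat + t_[, 1] * object$q[a]
    Xc <- Xc - tcrossprod(t_[, 1], object$P[, a])
  }
  yhat
}

#' Leave-one-out cross-validation of a PLS calibration
#'
#' For each sample the model is refit on the remaining `n - 1` samples and
#' the held-out spectrum predicted at every factor count `1..max_factors`.
#' RMSECV per factor count is the root mean squared held-out error; the
#' cross-validated coefficient of determination is the squared Pearson
#' correlation between reference values and held-out predictions (an
#' `1 - SSE/SST` variant is reported alongside).
#'
#' @param X spectra, samples x bands (a [spectrum_matrix()] or matrix).
#' @param y reference values.
#' @param max_factors largest factor count examined,
#'   `<= n_samples - 2` (default 20, capped at the data's limit).
#' @return An object of class `pls_cv` with `rmsecv_by_factor`,
#'   `r2_by_factor`, `r2_1msst_by_factor`, `chosen_factors` (smallest
#'   argmin of RMSECV) and `predictions` (held-out, at the chosen count).
#' @export
loocv <- function(X, y, max_factors = 20L) {
  Xm <- matrix(as.numeric(X), nrow(X), ncol(X))
  y <- as.numeric(y)
  n <- nrow(Xm)
  if (n < 3L) stop("LOOCV needs at least 3 samples", call. = FALSE)
  max_factors <- min(as.integer(max_factors), n - 2L, ncol(Xm))
  if (max_factors < 1L) stop("`max_factors` must be >= 1", call. = FALSE)
  pred <- matrix(NA_real_, n, max_factors)
  for (i in seq_len(n)) {
    fit <- fit_pls(Xm[-i, , drop = FALSE], y[-i], max_factors)
    for (k in seq_len(max_factors))
      pred[i, k] <- predict(fit, Xm[i, , drop = FALSE], n_factors = k)
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  r2 <- apply(pred, 2, function(p) {
    if (stats::sd(p) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(y, p)^2
  })
  r2_alt <- apply(pred, 2, function(p) {
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((y - p)^2) / sst
  })
  chosen <- which.min(rmsecv)     # which.min takes the first (smallest k)
  structure(list(rmsecv_by_factor = rmsecv, r2_by_factor = r2,
                 r2_1msst_by_factor = r2_alt,
                 chosen_factors = as.integer(chosen),
                 predictions = pred[, chosen], max_factors = max_factors),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf(
    "<pls_cv> %d factor counts; chosen %d (RMSECV %.4g, r2 %.4f)\n",
    x$max_factors, x$chosen_factors, x$rmsecv_by_factor[x$chosen_factors],
    x$r2_by_factor[x$chosen_factors]))
  invisible(x)
}

#' Select the PLS factor count from a cross-validation result
#'
#' Returns the smallest factor count attaining the minimum RMSECV
#' (ties break toward fewer factors).
#'
#' @param cv a `pls_cv` from [loocv()].
#' @return Integer factor count.
#' @export
select_factors <- function(cv) {
  stopifnot(inherits(cv, "pls_cv"))
  r <- cv$rmsecv_by_factor
  as.integer(which(r == min(r))[1])
}

#' Regression agreement metrics
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return List with `r2` (squared Pearson correlation; `NA` when either
#'   vector has zero variance) and `rmse`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stop("`y_true` and `y_pred` must have equal length >= 2", call. = FALSE)
  r2 <- if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) NA_real_
        else stats::cor(y_true, y_pred)^2
  list(r2 = r2, rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Summarise reference values of a calibration table
#'
#' @param table a calibration table from
#'   [generate_calibration_set()] or a data frame with a
#'   `nitrate_mg_per_kg` column.
#' @return List with `n`, `min`, `max`, `mean`, `median`, `sd`
#'   (sample sd; 0 for a single value).
#' @export
summarize_references <- function(table) {
  v <- if (inherits(table, "calibration_table")) table$table$nitrate_mg_per_kg
       else table$nitrate_mg_per_kg
  if (is.null(v) || length(v) == 0L)
    stop("no nitrate reference values found", call. = FALSE)
  list(n = length(v), min = min(v), max = max(v), mean = mean(v),
       median = stats::median(v),
       sd = if (length(v) > 1L) stats::sd(v) else 0)
}

#' Save / load a PLS model as JSON
#'
#' The JSON artifact embeds the centring vectors, weights and loadings,
#' the training wavelength axis and the preprocessing recipe, so a saved
#' model is sufficient to map a new cube.
#'
#' @param model a `pls_model`.
#' @param path output / input file path.
#' @return `write_pls_model` returns the path invisibly;
#'   `read_pls_model` returns the `pls_model`.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(x_mean = model$x_mean, y_mean = model$y_mean,
              W = model$W, P = model$P, q = model$q,
              n_factors = model$n_factors,
              wavelengths = model$wavelengths,
              recipe = if (is.null(model$recipe)) NULL else
                recipe_to_list(model$recipe))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor", null = "null")
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$x_mean); k <- as.integer(obj$n_factors)
  # write_json stores matrices column-major; read_json rebuilds row-major
  as_mat <- function(x) {
    if (is.matrix(x)) t(x) else matrix(as.numeric(x), p, k)
  }
  structure(list(
    x_mean = as.numeric(obj$x_mean), y_mean = as.numeric(obj$y_mean),
    W = as_mat(obj$W),
    P = as_mat(obj$P),
    q = as.numeric(obj$q), scores = NULL,
    n_factors = as.integer(obj$n_factors),
    recipe = if (is.null(obj$recipe)) NULL else {
      steps <- if (is.data.frame(obj$recipe))
        lapply(seq_len(nrow(obj$recipe)), function(i)
          as.list(obj$recipe[i, , drop = FALSE]))
      else obj$recipe
      recipe_from_list(steps)
    },
    wavelengths = as.numeric(obj$wavelengths)),
    class = "pls_model")
}
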