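# Radiomic feature pre-selection: standardized L1-penalized logistic
# regression, with the penalty weight chosen by minimum mean leave-one-out
# cross-validated binomial deviance. The path is fitted by glmnet's
# cyclic coordinate descent; grid construction, standardization and the
# LOOCV fold layout are fixed here so the selection is fully reproducible.

#' Standardize covariate columns
#'
#' Centres each column to mean 0 and scales to standard deviation 1 using
#' the population (n-denominator) convention, retaining the scaling
#' factors for back-transformation. Constant columns are an error.
#'
#' @param x numeric matrix or data.frame of covariates.
#' @return A list `list(x, center, scale)`; `x` has attribute
#'   `"sd_convention" = "population"`.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  bad <- scale <= 0
  if (any(bad))
    stop("constant column(s): ", paste(colnames(x)[bad], collapse = ", "),
         call. = FALSE)
  z <- sweep(sweep(x, 2, center), 2, scale, `/`)
  attr(z, "sd_convention") <- "population"
  list(x = z, center = center, scale = scale)
}

#' Back-transform standardized columns
#' @param z standardized matrix.
#' @param center,scale factors returned by [standardize()].
#' @return The matrix on the original scale.
#' @export
unstandardize <- function(z, center, scale) {
  sweep(sweep(z, 2, scale, `*`), 2, center, `+`)
}

# Penalty grid: nlambda log-spaced values from the analytic lambda_max
# (smallest penalty with an all-zero solution, max_j |X_j' (y - ybar)| / n)
# down to min_ratio * lambda_max.
lasso_lambda_grid <- function(x, y, nlambda = 100, min_ratio = 1e-3) {
  lmax <- max(abs(crossprod(x, y - mean(y)))) / length(y)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Fit an L1-penalized logistic path
#'
#' Minimizes `(1/n) * binomial negative log-likelihood + lambda * sum|beta|`
#' (intercept unpenalized) over a decreasing penalty grid, by cyclic
#' coordinate descent with warm starts (via \pkg{glmnet}). Covariates are
#' standardized internally with [standardize()]; coefficients are reported
#' on the standardized scale.
#'
#' @param x covariate matrix (n >= 10 rows, no missing values).
#' @param y binary 0/1 outcome.
#' @param lambda optional penalty grid; by default 100 log-spaced values
#'   from the analytic `lambda_max` down to `1e-3 * lambda_max`.
#' @param nlambda,min_ratio grid shape when `lambda` is `NULL`.
#' @return A `lasso_path`: `lambda`, `beta` (p x nlambda, standardized
#'   scale), `a0` (intercepts), `scaling`, and the feature names.
#' @export
fit_lasso_logistic_path <- function(x, y, lambda = NULL, nlambda = 100,
                                    min_ratio = 1e-3) {
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need n >= 10", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (any(!y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  sc <- standardize(x)
  lambda <- lambda %||% lasso_lambda_grid(sc$x, y, nlambda, min_ratio)
  lambda <- sort(lambda, decreasing = TRUE)
  fit <- glmnet::glmnet(sc$x, y, family = "binomial", lambda = lambda,
                        standardize = FALSE, thresh = 1e-10)
  structure(list(lambda = fit$lambda,
                 beta = as.matrix(fit$beta),
                 a0 = fit$a0,
                 scaling = sc[c("center", "scale")],
                 features = colnames(x)),
            class = "lasso_path")
}

#' Select the penalty by leave-one-out cross-validated deviance
#'
#' For each left-out subject the path is refitted on the remaining n - 1
#' and the held-out binomial deviance `-2 log L` is evaluated per lambda;
#' `lambda_min` minimizes the mean curve (strictly the minimizer — no
#' one-standard-error rule).
#'
#' @inheritParams fit_lasso_logistic_path
#' @param lambda penalty grid shared by all folds; defaults as in
#'   [fit_lasso_logistic_path()].
#' @return A list `lambda_min`, `cv_deviance` (mean per lambda), `lambda`.
#' @export
select_lambda_loocv <- function(x, y, lambda = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10) stop("need n >= 10", call. = FALSE)
  sc <- standardize(x)
  lambda <- lambda %||% lasso_lambda_grid(sc$x, y, 100, 1e-3)
  lambda <- sort(lambda, decreasing = TRUE)
  cv <- glmnet::cv.glmnet(sc$x, y, family = "binomial", lambda = lambda,
                          foldid = seq_len(n), type.measure = "deviance",
                          standardize = FALSE, thresh = 1e-10,
                          grouped = FALSE)
  list(lambda_min = cv$lambda.min, cv_deviance = cv$cvm, lambda = cv$lambda)
}

#' Features selected at the LOOCV-optimal penalty
#'
#' Convenience wrapper: fits the path, selects `lambda_min` by LOOCV and
#' returns the covariates with nonzero coefficients there.
#'
#' @inheritParams fit_lasso_logistic_path
#' @return A list: `selected` (character vector), `lambda_min`, `path`,
#'   `cv` (the LOOCV curve).
#' @export
lasso_reduce <- function(x, y, lambda = NULL) {
  path <- fit_lasso_logistic_path(x, y, lambda = lambda)
  cv <- select_lambda_loocv(x, y, lambda = path$lambda)
  list(selected = selected_features(path, cv$lambda_min),
       lambda_min = cv$lambda_min, path = path, cv = cv)
}

#' @rdname lasso_reduce
#' @param path a `lasso_path`.
#' @param lambda_min the selected penalty (a grid value).
#' @export
selected_features <- function(path, lambda_min) {
  stopifnot(inherits(path, "lasso_path"))
  i <- which.min(abs(path$lambda - lambda_min))
  path$features[path$beta[, i] != 0]
}
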