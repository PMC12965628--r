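# Healthy-control normative model: per-region OLS of the morphometric value
# on age, sex and ICV, with residual mean/SD defining the z-scoring used for
# every subject (controls, patient baseline and follow-up alike).

#' Fit the HC normative model
#'
#' For each of the 82 regions, fits ordinary least squares of the region
#' value on (intercept, age, sex, icv) over the healthy-control rows, and
#' records the residual mean `mu` (zero to numerical precision, retained
#' because the z-score is defined as `(residual - mu) / sigma`) and the
#' residual SD `sigma` (unbiased, n-1 denominator).
#'
#' @param hc `morphometry_table` rows with `group == "HC"` (rows of other
#'   groups are rejected).
#' @param registry a `roi_registry`.
#' @return an object of class `normative_model`: list with `coef` (4 x 82
#'   matrix), `mu`, `sigma` (length-82), `n_hc`, `registry`.
#' @export
fit_normative_model <- function(hc, registry = build_dk_registry()) {
  stopifnot(is.data.frame(hc))
  if (any(hc$group != "HC"))
    stop("normative model must be fitted on HC rows only", call. = FALSE)
  if (nrow(hc) < 4)
    stop("need at least 4 HC subjects to fit intercept + 3 covariates",
         call. = FALSE)
  X <- cbind(intercept = 1, age = hc$age, sex = hc$sex, icv = hc$icv)
  if (any(!is.finite(X)))
    stop("non-finite covariate (age/sex/icv) in HC rows", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient HC covariates (age/sex/icv collinear or constant)",
         call. = FALSE)
  Y <- roi_matrix(hc, registry)
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  mu <- colMeans(res)
  sigma <- apply(res, 2, stats::sd)
  # a residual SD at numerical-noise scale means the ROI is constant (or an
  # exact function of the covariates) across HC - z-scores would explode
  tol <- 1e-10 * pmax(1, abs(colMeans(Y)))
  zero <- which(sigma <= tol | !is.finite(sigma))
  if (length(zero))
    stop("zero residual SD at ROI '", registry$name[zero[1]],
         "' (constant across HC subjects)", call. = FALSE)
  structure(list(coef = as.matrix(fit$coefficients), mu = mu, sigma = sigma,
                 n_hc = nrow(hc), registry = registry),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("Normative model: 82-region OLS (age, sex, ICV) on", x$n_hc,
      "HC subjects\n")
  invisible(x)
}

#' Compute per-subject deviation profiles (z-scores)
#'
#' For each row, subtracts the covariate-predicted normative value, then
#' z-scores the residual against the HC residual distribution:
#' `z = (residual - mu) / sigma`. A positive z means the subject's
#' measurement exceeds the HC-adjusted expectation. All groups (HC,
#' patient baseline, patient follow-up) are scored against the same HC
#' model.
#'
#' @param table a `morphometry_table` (one or more rows).
#' @param model a fitted `normative_model`.
#' @return a numeric matrix, subjects x 82 regions, of z-scores; row names
#'   are `subject_id:timepoint`.
#' @export
compute_deviation <- function(table, model) {
  stopifnot(inherits(model, "normative_model"))
  registry <- model$registry
  X <- cbind(1, table$age, table$sex, table$icv)
  if (any(!is.finite(X)))
    stop("missing covariate (age/sex/icv) in table", call. = FALSE)
  Y <- roi_matrix(table, registry)
  resid <- Y - X %*% model$coef
  z <- sweep(sweep(resid, 2, model$mu, "-"), 2, model$sigma, "/")
  if (any(!is.finite(z)))
    stop("non-finite z-score produced", call. = FALSE)
  rownames(z) <- paste(table$subject_id, table$timepoint, sep = ":")
  colnames(z) <- registry$name
  z
}
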