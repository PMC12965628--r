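# Covariate-adjusted permutation inference, FDR correction and partial
# correlation with treatment response.

# t statistic of the group term in OLS of each column of Y on [1, g, Z].
# Y: n x m matrix; returns length-m vector (NaN where outcome is constant).
group_t_stats <- function(Y, X, g_col) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  beta <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  se <- sqrt(sigma2 * XtXi[g_col, g_col])
  as.numeric(beta[g_col, ] / se)
}

#' Covariate-adjusted two-sample permutation test (Freedman-Lane)
#'
#' Tests a group difference in `y` while holding nuisance covariates fixed:
#' the outcome is regressed on the covariates alone (reduced model), the
#' reduced-model residuals are permuted and re-added to the fitted values,
#' and the group t statistic of the full model is recomputed on each
#' permuted outcome. Two-sided p with the add-one convention,
#' `p = (#(|t*| >= |t|) + 1) / (n_perm + 1)`, so p is never 0.
#'
#' @param values_a,values_b outcome values in groups a and b (>= 3 each).
#' @param covariates_a,covariates_b matrices (or NULL) of nuisance
#'   covariates per group, same columns.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `statistic` (observed group t), `p`, `n_perm`, `seed`.
#' @export
permutation_test_covadj <- function(values_a, values_b,
                                    covariates_a = NULL, covariates_b = NULL,
                                    n_perm = 10000L, seed = 1L) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 3 || nb < 3) stop("need >= 3 observations per group", call. = FALSE)
  y <- c(values_a, values_b)
  g <- c(rep(0, na), rep(1, nb))
  Z <- NULL
  if (!is.null(covariates_a) || !is.null(covariates_b)) {
    Z <- rbind(as.matrix(covariates_a), as.matrix(covariates_b))
    if (nrow(Z) != na + nb)
      stop("covariate rows must match outcome length", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    warning("constant outcome: p = 1")
    return(list(statistic = 0, p = 1, n_perm = n_perm, seed = seed))
  }
  X0 <- cbind(rep(1, na + nb), Z)   # reduced model
  X <- cbind(rep(1, na + nb), g, Z) # full model
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient covariates in permutation test", call. = FALSE)
  fit0 <- stats::lm.fit(X0, y)
  r0 <- fit0$residuals
  f0 <- fit0$fitted.values
  t_obs <- group_t_stats(matrix(y, ncol = 1), X, g_col = 2L)

  set.seed(as.integer(seed))
  n <- na + nb
  perms <- replicate(n_perm, sample.int(n))
  Ystar <- matrix(f0, n, n_perm) + matrix(r0[perms], n, n_perm)
  t_star <- group_t_stats(Ystar, X, g_col = 2L)
  p <- (sum(abs(t_star) >= abs(t_obs), na.rm = TRUE) + 1) / (n_perm + 1)
  list(statistic = t_obs, p = p, n_perm = n_perm, seed = seed)
}

#' Paired sign-flip permutation test
#'
#' Tests whether within-pair differences `post - pre` are centred at zero by
#' randomly flipping the sign of each pair's difference. Two-sided p with
#' the add-one convention.
#'
#' @param pre_values,post_values paired vectors (n >= 3).
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed.
#' @return list with `statistic` (paired t of the differences), `p`,
#'   `n_perm`, `seed`.
#' @export
paired_permutation_test <- function(pre_values, post_values,
                                    n_perm = 10000L, seed = 1L) {
  stopifnot(length(pre_values) == length(post_values))
  n <- length(pre_values)
  if (n < 3) stop("need >= 3 pairs", call. = FALSE)
  d <- post_values - pre_values
  if (all(d == 0)) {
    warning("all differences zero: p = 1")
    return(list(statistic = 0, p = 1, n_perm = n_perm, seed = seed))
  }
  tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(n))
  t_obs <- tstat(d)
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  D <- signs * d
  means <- colMeans(D)
  sds <- sqrt((colSums(D^2) - n * means^2) / (n - 1))
  t_star <- means / (sds / sqrt(n))
  p <- (sum(abs(t_star) >= abs(t_obs), na.rm = TRUE) + 1) / (n_perm + 1)
  list(statistic = t_obs, p = p, n_perm = n_perm, seed = seed)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values via [stats::p.adjust()] plus the rejection set at the
#' given level.
#'
#' @param p_values vector of p-values in [0, 1] (NA allowed, carried
#'   through).
#' @param alpha FDR level.
#' @return list with `q` (same length/names as input) and `rejected`
#'   (logical, `q <= alpha`).
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(list(q = numeric(0), rejected = logical(0)))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, rejected = !is.na(q) & q <= alpha)
}

#' Percent change in VAS pain score
#'
#' Oriented so that larger values mean more pain relief:
#' `100 * (pre - post) / pre`.
#'
#' @param vas_pre,vas_post VAS scores before/after treatment; `vas_pre` must
#'   be > 0.
#' @return percent change vector (0-100 when post <= pre).
#' @export
vas_percent_change <- function(vas_pre, vas_post) {
  if (any(!is.finite(vas_pre)) || any(vas_pre <= 0))
    stop("vas_pre must be finite and > 0", call. = FALSE)
  100 * (vas_pre - vas_post) / vas_pre
}

#' Covariate-adjusted partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed (with intercept) on the covariates; p from the t transform
#' with `df = n - 2 - k` covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates matrix/data.frame of confounders, or NULL (plain
#'   Pearson correlation).
#' @return list with `r`, `p`, `df`, `n`, `covariates` (column names).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= 2 + k)
    stop("need n > 2 + number of covariates", call. = FALSE)
  X <- cbind(rep(1, n), if (k) as.matrix(covariates))
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant residuals: partial correlation undefined")
    return(list(r = NA_real_, p = NA_real_, df = n - 2L - k, n = n,
                covariates = colnames(as.matrix(covariates))))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, n = n,
       covariates = if (k) colnames(as.matrix(covariates)) else character(0))
}

# run one FDR family of covariate-adjusted group contrasts:
# values: subjects x features; returns a data.frame
contrast_family <- function(values_a, values_b, covariates_a, covariates_b,
                            family, n_perm, alpha, seed) {
  features <- colnames(values_a)
  stats_p <- vapply(seq_along(features), function(j) {
    res <- permutation_test_covadj(
      values_a[, j], values_b[, j], covariates_a, covariates_b,
      n_perm = n_perm, seed = derive_seed(seed, family, features[j]))
    c(res$statistic, res$p)
  }, numeric(2))
  fdr <- fdr_bh(stats_p[2, ], alpha)
  data.frame(feature = features, family = family,
             statistic = stats_p[1, ], p = stats_p[2, ], q = fdr$q,
             significant = fdr$rejected, stringsAsFactors = FALSE)
}

# subjects x nodes AUC matrix for one nodal metric
nodal_auc_matrix <- function(curvesets, metric) {
  t(vapply(curvesets, function(cs) cs$nodal_auc[[metric]],
           numeric(length(curvesets[[1]]$nodal_auc[[metric]]))))
}

global_auc_matrix <- function(curvesets) {
  t(vapply(curvesets, function(cs) cs$global_auc,
           numeric(length(curvesets[[1]]$global_auc))))
}

#' Run the full group analysis
#'
#' Executes the study's inference plan on a cohort table and its per-subject
#' metric curve sets: (a) per-region morphometry contrasts (HC vs patient
#' baseline, HC vs patient follow-up), (b) per-node AUC contrasts for each
#' nodal metric, (c) global-metric AUC contrasts, (d) paired
#' baseline-vs-follow-up sign-flip tests on the features significant in
#' (a)/(b), and (e) partial correlation (age, sex, pain-duration adjusted)
#' of significant baseline nodal AUC features with percent VAS change.
#' Every contrast family (one metric x one comparison; morphometry per
#' comparison; global metrics per comparison) is FDR-corrected separately.
#'
#' @param table a `morphometry_table` containing HC, patient baseline and
#'   patient follow-up rows.
#' @param curvesets named list of `metric_curves`, names
#'   `subject_id:timepoint` as produced by the pipeline.
#' @param registry a `roi_registry`.
#' @param n_perm permutations per test.
#' @param alpha FDR level.
#' @param include_icv_morphometry also covary ICV in the morphometry
#'   contrasts (off by default; network contrasts always adjust age + sex).
#' @param seed master seed (per-family seeds derived from it).
#' @return list of class `iscn_inference` with data.frames `morphometry`,
#'   `nodal_auc`, `global_auc`, `paired`, `correlation`.
#' @export
run_group_analysis <- function(table, curvesets,
                               registry = build_dk_registry(),
                               n_perm = 10000L, alpha = 0.05,
                               include_icv_morphometry = FALSE, seed = 1L) {
  hc <- cohort_rows(table, "HC")
  bl <- cohort_rows(table, "patient", "baseline")
  fu <- cohort_rows(table, "patient", "followup")
  if (!nrow(hc)) stop("missing cohort: HC", call. = FALSE)
  if (!nrow(bl)) stop("missing cohort: patient baseline", call. = FALSE)
  if (!nrow(fu)) stop("missing cohort: patient followup", call. = FALSE)
  fu <- fu[match(bl$subject_id, fu$subject_id), , drop = FALSE]

  cov_cols <- c("age", "sex")
  cov_of <- function(rows, icv = FALSE) {
    m <- as.matrix(rows[, c(cov_cols, if (icv) "icv")])
    rownames(m) <- NULL
    m
  }
  key <- function(rows) paste(rows$subject_id, rows$timepoint, sep = ":")
  cs_of <- function(rows) curvesets[key(rows)]

  # (a) morphometry
  icv <- include_icv_morphometry
  morph <- rbind(
    cbind(comparison = "HC_vs_baseline",
          contrast_family(roi_matrix(hc, registry), roi_matrix(bl, registry),
                          cov_of(hc, icv), cov_of(bl, icv),
                          "morphometry", n_perm, alpha,
                          derive_seed(seed, "morph", "bl"))),
    cbind(comparison = "HC_vs_followup",
          contrast_family(roi_matrix(hc, registry), roi_matrix(fu, registry),
                          cov_of(hc, icv), cov_of(fu, icv),
                          "morphometry", n_perm, alpha,
                          derive_seed(seed, "morph", "fu"))))

  # (b) nodal AUC families
  nodal_metrics <- names(curvesets[[1]]$nodal_auc)
  nodal <- do.call(rbind, lapply(nodal_metrics, function(metric) {
    a <- nodal_auc_matrix(cs_of(hc), metric)
    colnames(a) <- registry$name
    b <- nodal_auc_matrix(cs_of(bl), metric); colnames(b) <- registry$name
    f <- nodal_auc_matrix(cs_of(fu), metric); colnames(f) <- registry$name
    rbind(
      cbind(comparison = "HC_vs_baseline",
            contrast_family(a, b, cov_of(hc), cov_of(bl), metric, n_perm,
                            alpha, derive_seed(seed, "nodal", metric, "bl"))),
      cbind(comparison = "HC_vs_followup",
            contrast_family(a, f, cov_of(hc), cov_of(fu), metric, n_perm,
                            alpha, derive_seed(seed, "nodal", metric, "fu"))))
  }))

  # (c) global AUC family
  ga <- global_auc_matrix(cs_of(hc))
  gb <- global_auc_matrix(cs_of(bl))
  gf <- global_auc_matrix(cs_of(fu))
  keep <- colnames(ga)[colSums(is.na(rbind(ga, gb, gf))) == 0]
  globalr <- rbind(
    cbind(comparison = "HC_vs_baseline",
          contrast_family(ga[, keep, drop = FALSE], gb[, keep, drop = FALSE],
                          cov_of(hc), cov_of(bl), "global", n_perm, alpha,
                          derive_seed(seed, "global", "bl"))),
    cbind(comparison = "HC_vs_followup",
          contrast_family(ga[, keep, drop = FALSE], gf[, keep, drop = FALSE],
                          cov_of(hc), cov_of(fu), "global", n_perm, alpha,
                          derive_seed(seed, "global", "fu"))))

  # (d) paired baseline vs follow-up on significant baseline features
  sig_nodal <- nodal[nodal$comparison == "HC_vs_baseline" & nodal$significant,
                     c("family", "feature")]
  sig_morph <- morph[morph$comparison == "HC_vs_baseline" & morph$significant,
                     c("family", "feature")]
  paired_feats <- rbind(sig_morph, sig_nodal)
  paired <- if (nrow(paired_feats)) {
    do.call(rbind, lapply(seq_len(nrow(paired_feats)), function(i) {
      fam <- paired_feats$family[i]; feat <- paired_feats$feature[i]
      if (fam == "morphometry") {
        pre <- bl[[feat]]; post <- fu[[feat]]
      } else {
        mb <- nodal_auc_matrix(cs_of(bl), fam); colnames(mb) <- registry$name
        mf <- nodal_auc_matrix(cs_of(fu), fam); colnames(mf) <- registry$name
        pre <- mb[, feat]; post <- mf[, feat]
      }
      res <- paired_permutation_test(
        pre, post, n_perm = n_perm,
        seed = derive_seed(seed, "paired", fam, feat))
      data.frame(feature = feat, family = fam, statistic = res$statistic,
                 p = res$p, mean_change = mean(post - pre),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(feature = character(0), family = character(0),
               statistic = numeric(0), p = numeric(0),
               mean_change = numeric(0))
  }

  # (e) partial correlation of significant baseline nodal AUCs with VAS
  pc_change <- vas_percent_change(bl$vas_pre, bl$vas_post)
  conf <- as.matrix(bl[, c("age", "sex", "pain_duration")])
  correlation <- if (nrow(sig_nodal)) {
    out <- do.call(rbind, lapply(seq_len(nrow(sig_nodal)), function(i) {
      fam <- sig_nodal$family[i]; feat <- sig_nodal$feature[i]
      mb <- nodal_auc_matrix(cs_of(bl), fam); colnames(mb) <- registry$name
      res <- partial_correlation(mb[, feat], pc_change, conf)
      data.frame(feature = feat, family = fam, r = res$r, p = res$p,
                 n = res$n, covariates = paste(res$covariates,
                                               collapse = "+"),
                 stringsAsFactors = FALSE)
    }))
    fdr <- fdr_bh(out$p, alpha)
    out$q <- fdr$q
    out$significant <- fdr$rejected
    out
  } else {
    data.frame(feature = character(0), family = character(0), r = numeric(0),
               p = numeric(0), n = integer(0), covariates = character(0),
               q = numeric(0), significant = logical(0))
  }

  structure(list(morphometry = morph, nodal_auc = nodal,
                 global_auc = globalr, paired = paired,
                 correlation = correlation,
                 settings = list(n_perm = n_perm, alpha = alpha,
                                 seed = seed)),
            class = "iscn_inference")
}

#' @export
print.iscn_inference <- function(x, ...) {
  cat("ISCN group inference (", x$settings$n_perm, "permutations, FDR alpha",
      x$settings$alpha, ")\n")
  cat(" significant morphometry features:",
      sum(x$morphometry$significant), "\n")
  cat(" significant nodal AUC features:  ",
      sum(x$nodal_auc$significant), "\n")
  cat(" significant global AUC features: ",
      sum(x$global_auc$significant), "\n")
  invisible(x)
}
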