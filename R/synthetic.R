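# Synthetic patient/control morphometry cohorts. The generator emulates the
# statistical structure the ISCN analysis assumes: a healthy-control norm
# with age/sex/ICV effects, a shared within-subject factor that couples
# deviations across regions (which is what makes deviation-similarity
# networks dense in controls), regional cortical thinning in patients, extra
# idiosyncratic deviation ("decoupling") at one target node that lowers its
# centrality, partial longitudinal recovery, and a planted link between
# baseline target-node coupling and treatment response.

# the 12 regions showing patient cortical thinning in the emulated study
ATROPHY_ROIS_DEFAULT <- c(
  "lh_bankssts", "lh_inferiorparietal", "lh_isthmuscingulate",
  "lh_medialorbitofrontal", "lh_posteriorcingulate", "lh_superiortemporal",
  "lh_supramarginal", "rh_fusiform", "rh_isthmuscingulate",
  "rh_postcentral", "rh_superiortemporal", "rh_supramarginal")

#' Synthetic cohort configuration
#'
#' Builds the parameter list for [generate_cohort()]. Defaults reproduce the
#' demographic and clinical profile of the emulated study (25 patients / 25
#' controls; patient age 48.38 +/- 6.84 y, control age 46.35 +/- 8.76 y;
#' VAS 6.25 +/- 1.12 before treatment with ~64% mean relief; pain duration
#' 37.35 +/- 16.54 months) and effect sizes chosen to be detectable at that
#' sample size.
#'
#' @param n_hc,n_patient cohort sizes (>= 2).
#' @param seed master seed; every subject draws from a sub-stream derived
#'   from it, so existing subjects are unchanged when `n` grows.
#' @param age_mean,age_sd patient age distribution (years).
#' @param age_mean_hc,age_sd_hc control age distribution (years).
#' @param male_prob probability of sex = 1 (male).
#' @param icv_mean,icv_sd intracranial volume (mm^3).
#' @param thickness_mean mean cortical thickness (mm) around which per-region
#'   baseline means are spread.
#' @param thickness_sd residual (subject) SD of cortical thickness (mm).
#' @param volume_means named per-structure subcortical volume means (mm^3).
#' @param volume_cv residual coefficient of variation of subcortical volumes.
#' @param age_slope cortical thinning with age (mm/year, negative).
#' @param age_slope_vol fractional subcortical volume loss with age
#'   (per year, e.g. -0.002 = -0.2%/year, applied to each structure's mean).
#' @param sex_offset additive male-female thickness offset (mm).
#' @param sex_offset_vol fractional male-female volume offset.
#' @param icv_scaling elasticity of subcortical volume with respect to ICV
#'   (fractional volume change per fractional ICV change).
#' @param shared_factor_sd SD (z-units) of the per-subject factor shared by
#'   all regions; the source of cross-region deviation similarity.
#' @param roi_noise_sd SD (z-units) of independent per-region noise.
#' @param atrophy_rois registry names of regions thinned in patients.
#' @param atrophy_effect patient cortical thinning (mm) in `atrophy_rois`.
#' @param target_node registry name of the node receiving idiosyncratic
#'   decoupling in patients.
#' @param target_decoupling_sd SD (z-units) of the extra independent
#'   deviation at `target_node`; decoupling (not a mean shift) is what the
#'   similarity kernel is sensitive to, so this is what lowers the target's
#'   degree centrality and nodal efficiency.
#' @param recovery_fraction fraction of both patient effects removed at
#'   follow-up (0 = none, 1 = full normalization).
#' @param vas_pre_mean,vas_pre_sd baseline VAS distribution (0-10 scale).
#' @param vas_change_mean,vas_change_sd percent VAS reduction distribution
#'   (0-100 scale, truncated).
#' @param vas_link_strength correlation-scale coupling (negative) between a
#'   subject's baseline target-node coupling and their percent VAS change;
#'   with the convention "percent change = relief", more baseline decoupling
#'   (lower centrality) yields more relief.
#' @param pain_duration_mean,pain_duration_sd pain duration (months).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_hc = 25, n_patient = 25, seed = 20260220,
                             age_mean = 48.38, age_sd = 6.84,
                             age_mean_hc = 46.35, age_sd_hc = 8.76,
                             male_prob = 12 / 25,
                             icv_mean = 1.5e6, icv_sd = 1.3e5,
                             thickness_mean = 2.5, thickness_sd = 0.12,
                             volume_means = c(thalamus = 7500, caudate = 3600,
                                              putamen = 5200, pallidum = 1800,
                                              hippocampus = 4100,
                                              amygdala = 1600,
                                              accumbens = 550),
                             volume_cv = 0.06,
                             age_slope = -0.005, age_slope_vol = -0.002,
                             sex_offset = 0.03, sex_offset_vol = 0.05,
                             icv_scaling = 0.8,
                             shared_factor_sd = 0.6, roi_noise_sd = 0.8,
                             atrophy_rois = ATROPHY_ROIS_DEFAULT,
                             atrophy_effect = 0.15,
                             target_node = "rh_parstriangularis",
                             target_decoupling_sd = 2.5,
                             recovery_fraction = 0.8,
                             vas_pre_mean = 6.25, vas_pre_sd = 1.12,
                             vas_change_mean = 63.84, vas_change_sd = 12,
                             vas_link_strength = -0.6,
                             pain_duration_mean = 37.35,
                             pain_duration_sd = 16.54) {
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid synthetic config field '", field, "': ", what,
                  call. = FALSE)
  }
  chk(cfg$n_hc >= 2, "n_hc", "must be >= 2")
  chk(cfg$n_patient >= 2, "n_patient", "must be >= 2")
  for (f in c("age_sd", "age_sd_hc", "icv_sd", "thickness_sd", "volume_cv",
              "shared_factor_sd", "roi_noise_sd", "target_decoupling_sd",
              "vas_pre_sd", "vas_change_sd", "pain_duration_sd"))
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0, f, "must be a SD >= 0")
  chk(cfg$recovery_fraction >= 0 && cfg$recovery_fraction <= 1,
      "recovery_fraction", "must be in [0, 1]")
  chk(cfg$male_prob >= 0 && cfg$male_prob <= 1, "male_prob",
      "must be in [0, 1]")
  reg <- build_dk_registry()
  bad <- setdiff(cfg$atrophy_rois, reg$name)
  chk(!length(bad), "atrophy_rois",
      paste("unknown region(s):", paste(bad, collapse = ", ")))
  chk(cfg$target_node %in% reg$name, "target_node", "unknown region")
  chk(all(names(SUBCORTICAL_MAP) %in% names(cfg$volume_means)),
      "volume_means", "must name all 7 subcortical structures")
  invisible(cfg)
}

# Deterministic per-region baseline means: spread cortical means around
# thickness_mean so regions differ (as in real atlases) but reproducibly.
region_baseline_means <- function(cfg, registry) {
  n_cort <- sum(registry$kind == "cortical")
  spread <- 0.25 * sin(seq_len(n_cort))   # fixed +/-0.25 mm pattern
  means <- numeric(nrow(registry))
  means[registry$kind == "cortical"] <- cfg$thickness_mean + spread
  sub <- registry$kind == "subcortical"
  means[sub] <- cfg$volume_means[registry$atlas_label[sub]]
  means
}

# per-region residual scale (mm for cortical, mm^3 for subcortical)
region_scales <- function(cfg, registry) {
  sc <- numeric(nrow(registry))
  sc[registry$kind == "cortical"] <- cfg$thickness_sd
  sub <- registry$kind == "subcortical"
  sc[sub] <- cfg$volume_cv * cfg$volume_means[registry$atlas_label[sub]]
  sc
}

#' Generate a synthetic HC + patient cohort
#'
#' Draws `n_hc` control rows, `n_patient` patient baseline rows and the
#' paired follow-up rows under the generative model described in
#' [synthetic_config()]:
#' `value = mean(roi) + covariate effects + (shared_factor + noise) * scale`,
#' with patients additionally thinned by `atrophy_effect` in `atrophy_rois`
#' and decoupled at `target_node` by an independent normal deviation; at
#' follow-up both patient effects are multiplied by
#' `1 - recovery_fraction` and the per-region measurement noise is redrawn
#' (the shared factor is a stable subject trait). Percent VAS change is
#' generated with correlation `vas_link_strength` to the subject's baseline
#' target-node coupling.
#'
#' @param cfg a `synthetic_config`.
#' @param registry a `roi_registry`.
#' @return a `morphometry_table` with `n_hc + 2 * n_patient` rows.
#' @export
generate_cohort <- function(cfg = synthetic_config(),
                            registry = build_dk_registry()) {
  validate_synthetic_config(cfg)
  means <- region_baseline_means(cfg, registry)
  scales <- region_scales(cfg, registry)
  n_roi <- nrow(registry)
  cortical <- registry$kind == "cortical"
  target_idx <- match(cfg$target_node, registry$name)
  atrophy_idx <- match(cfg$atrophy_rois, registry$name)

  draw_subject <- function(id, group) {
    set.seed(derive_seed(cfg$seed, "subject", id))
    if (group == "HC") {
      age <- stats::rnorm(1, cfg$age_mean_hc, cfg$age_sd_hc)
    } else {
      age <- stats::rnorm(1, cfg$age_mean, cfg$age_sd)
    }
    age <- max(20, min(70, age))
    sex <- stats::rbinom(1, 1, cfg$male_prob)
    icv <- stats::rnorm(1, cfg$icv_mean, cfg$icv_sd)
    f <- stats::rnorm(1, 0, cfg$shared_factor_sd)
    eps_bl <- stats::rnorm(n_roi, 0, cfg$roi_noise_sd)
    eps_fu <- stats::rnorm(n_roi, 0, cfg$roi_noise_sd)
    decoupling <- stats::rnorm(1, 0, cfg$target_decoupling_sd)
    vas_noise <- stats::rnorm(1)
    vas_pre <- min(10, max(1, stats::rnorm(1, cfg$vas_pre_mean,
                                           cfg$vas_pre_sd)))
    duration <- max(3, stats::rnorm(1, cfg$pain_duration_mean,
                                    cfg$pain_duration_sd))
    list(id = id, group = group, age = age, sex = sex, icv = icv, f = f,
         eps_bl = eps_bl, eps_fu = eps_fu, decoupling = decoupling,
         vas_noise = vas_noise, vas_pre = vas_pre, duration = duration)
  }

  covariate_part <- function(s) {
    base <- means
    base[cortical] <- base[cortical] +
      cfg$age_slope * (s$age - cfg$age_mean) + cfg$sex_offset * s$sex
    base[!cortical] <- base[!cortical] * (
      1 + cfg$age_slope_vol * (s$age - cfg$age_mean) +
        cfg$sex_offset_vol * s$sex +
        cfg$icv_scaling * (s$icv / cfg$icv_mean - 1))
    base
  }

  make_row <- function(s, timepoint, eps, effect_scale) {
    vals <- covariate_part(s) + (s$f + eps) * scales
    if (s$group == "patient") {
      vals[atrophy_idx] <- vals[atrophy_idx] -
        cfg$atrophy_effect * effect_scale
      vals[target_idx] <- vals[target_idx] +
        s$decoupling * effect_scale * scales[target_idx]
    }
    vals
  }

  rows <- list()
  add_row <- function(s, timepoint, vals, vas_pre, vas_post, duration) {
    r <- data.frame(subject_id = s$id, group = s$group, timepoint = timepoint,
                    age = s$age, sex = s$sex, icv = s$icv,
                    vas_pre = vas_pre, vas_post = vas_post,
                    pain_duration = duration, stringsAsFactors = FALSE)
    r[registry$name] <- as.list(vals)
    rows[[length(rows) + 1]] <<- r
  }

  for (i in seq_len(cfg$n_hc)) {
    s <- draw_subject(sprintf("HC%03d", i), "HC")
    add_row(s, "baseline", make_row(s, "baseline", s$eps_bl, 1),
            NA_real_, NA_real_, NA_real_)
  }

  # standardized coupling score: high |decoupling| = low coupling
  half_m <- sqrt(2 / pi)
  for (i in seq_len(cfg$n_patient)) {
    s <- draw_subject(sprintf("P%03d", i), "patient")
    tau <- cfg$target_decoupling_sd
    z_coupling <- if (tau > 0) {
      -(abs(s$decoupling) - tau * half_m) / (tau * sqrt(1 - half_m^2))
    } else 0
    rho <- cfg$vas_link_strength
    pc <- cfg$vas_change_mean + cfg$vas_change_sd *
      (rho * z_coupling + sqrt(max(0, 1 - rho^2)) * s$vas_noise)
    pc <- min(100, max(0, pc))
    vas_post <- s$vas_pre * (1 - pc / 100)
    add_row(s, "baseline", make_row(s, "baseline", s$eps_bl, 1),
            s$vas_pre, vas_post, s$duration)
    add_row(s, "followup",
            make_row(s, "followup", s$eps_fu, 1 - cfg$recovery_fraction),
            s$vas_pre, vas_post, s$duration)
  }

  as_morphometry_table(do.call(rbind, rows), registry)
}
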