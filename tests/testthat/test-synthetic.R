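test_that("cohort generation is deterministic and per-subject stable", {
  a <- tiny_cohort(n_hc = 5, n_patient = 3, seed = 9)
  b <- tiny_cohort(n_hc = 5, n_patient = 3, seed = 9)
  expect_identical(a, b)
  # sub-streams: growing the cohort leaves existing subjects untouched
  big <- tiny_cohort(n_hc = 8, n_patient = 3, seed = 9)
  shared <- as.data.frame(big[big$subject_id %in% a$subject_id, ])
  rownames(shared) <- NULL
  expect_identical(shared, as.data.frame(a))
  expect_false(identical(tiny_cohort(n_hc = 5, n_patient = 3, seed = 10), a))
})

test_that("cohort layout and clinical profile match the configured study", {
  cfg <- synthetic_config(n_hc = 40, n_patient = 40, seed = 5)
  tab <- generate_cohort(cfg)
  expect_s3_class(tab, "morphometry_table")
  expect_equal(sum(tab$group == "HC"), 40)
  expect_equal(sum(tab$group == "patient" & tab$timepoint == "baseline"), 40)
  expect_equal(sum(tab$group == "patient" & tab$timepoint == "followup"), 40)
  bl <- tab[tab$group == "patient" & tab$timepoint == "baseline", ]
  expect_equal(mean(bl$vas_pre), cfg$vas_pre_mean, tolerance = 0.15)
  expect_true(all(bl$vas_post < bl$vas_pre))
  expect_equal(mean(bl$age), cfg$age_mean, tolerance = 0.1)
  expect_true(all(is.na(tab$vas_pre[tab$group == "HC"])))
})

test_that("invalid config fails naming the offending field", {
  expect_error(synthetic_config(n_hc = 1), "n_hc")
  expect_error(synthetic_config(recovery_fraction = 1.5), "recovery_fraction")
  expect_error(synthetic_config(roi_noise_sd = -1), "roi_noise_sd")
  expect_error(synthetic_config(target_node = "nonexistent"), "target_node")
  expect_error(synthetic_config(atrophy_rois = c("lh_bankssts", "bogus")),
               "bogus")
})

test_that("with effects disabled, patients and controls are exchangeable", {
  # covariate-free generator, no atrophy/decoupling: the group label carries
  # no signal, so covariate-adjusted permutation p-values are ~ uniform
  reps <- 60
  pvals <- vapply(seq_len(reps), function(r) {
    cfg <- synthetic_config(n_hc = 8, n_patient = 8, seed = 1000 + r,
                            atrophy_effect = 0, target_decoupling_sd = 0)
    tab <- generate_cohort(cfg)
    hc <- tab[tab$group == "HC", ]
    bl <- tab[tab$group == "patient" & tab$timepoint == "baseline", ]
    roi <- sample(build_dk_registry()$name, 1)
    permutation_test_covadj(hc[[roi]], bl[[roi]],
                            cbind(hc$age, hc$sex), cbind(bl$age, bl$sex),
                            n_perm = 199, seed = r)$p
  }, numeric(1))
  # empirical rejection rate at alpha = 0.2 within binomial 99% CI
  alpha <- 0.2
  rate <- mean(pvals <= alpha)
  ci <- qnorm(0.995) * sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(rate - alpha), ci + 1e-9)
})

test_that("planted atrophy shifts group mean thickness by the set amount", {
  cfg <- synthetic_config(n_hc = 60, n_patient = 60, seed = 77,
                          atrophy_effect = 0.2, target_decoupling_sd = 0)
  tab <- generate_cohort(cfg)
  hc <- tab[tab$group == "HC", ]
  bl <- tab[tab$group == "patient" & tab$timepoint == "baseline", ]
  # compare HC-model-adjusted residual means so age differences don't bias
  m <- fit_normative_model(hc)
  z_hc <- compute_deviation(hc, m)
  z_bl <- compute_deviation(bl, m)
  sc <- cfg$thickness_sd   # z-units -> mm for cortical regions
  gap_mm <- (colMeans(z_hc) - colMeans(z_bl)) * sc
  mc_err <- 3 * sc / sqrt(60)
  expect_true(all(abs(gap_mm[cfg$atrophy_rois] - 0.2) < mc_err + 0.05))
  untouched <- setdiff(names(gap_mm)[1:68],
                       c(cfg$atrophy_rois, cfg$target_node))
  expect_lt(max(abs(gap_mm[untouched])), mc_err + 0.05)
})

test_that("follow-up shrinks patient effects by the recovery fraction", {
  cfg <- synthetic_config(n_hc = 50, n_patient = 50, seed = 31,
                          atrophy_effect = 0.3, target_decoupling_sd = 0,
                          recovery_fraction = 0.8)
  tab <- generate_cohort(cfg)
  m <- fit_normative_model(tab[tab$group == "HC", ])
  bl <- compute_deviation(tab[tab$group == "patient" &
                                tab$timepoint == "baseline", ], m)
  fu <- compute_deviation(tab[tab$group == "patient" &
                                tab$timepoint == "followup", ], m)
  sc <- cfg$thickness_sd
  gap_bl <- -mean(colMeans(bl[, cfg$atrophy_rois])) * sc
  gap_fu <- -mean(colMeans(fu[, cfg$atrophy_rois])) * sc
  # Monte-Carlo error: factor + noise SE of the ROI-block mean is ~0.012 mm
  expect_lt(abs(gap_bl - 0.3), 0.04)
  expect_lt(abs(gap_fu - 0.3 * (1 - 0.8)), 0.04)
})

test_that("target decoupling monotonically lowers target-node similarity", {
  mean_target_weight <- function(tau) {
    cfg <- synthetic_config(n_hc = 20, n_patient = 20, seed = 55,
                            target_decoupling_sd = tau)
    tab <- generate_cohort(cfg)
    m <- fit_normative_model(tab[tab$group == "HC", ])
    bl <- tab[tab$group == "patient" & tab$timepoint == "baseline", ]
    z <- compute_deviation(bl, m)
    mean(vapply(seq_len(nrow(z)), function(i) {
      w <- build_similarity_network(z[i, ])
      mean(w[cfg$target_node, -match(cfg$target_node, colnames(w))])
    }, numeric(1)))
  }
  ws <- vapply(c(0, 1, 2.5), mean_target_weight, numeric(1))
  expect_true(all(diff(ws) < 0))
})

test_that("full recovery makes follow-up rows free of patient effects", {
  # recovery_fraction = 1 scales both planted effects to zero: follow-up
  # rows must be bit-identical to a generator with the effects disabled
  with_fx <- generate_cohort(synthetic_config(
    n_hc = 4, n_patient = 6, seed = 14, atrophy_effect = 0.3,
    target_decoupling_sd = 3, recovery_fraction = 1))
  no_fx <- generate_cohort(synthetic_config(
    n_hc = 4, n_patient = 6, seed = 14, atrophy_effect = 0,
    target_decoupling_sd = 0, recovery_fraction = 1))
  reg <- build_dk_registry()
  fu1 <- with_fx[with_fx$timepoint == "followup", reg$name]
  fu2 <- no_fx[no_fx$timepoint == "followup", reg$name]
  expect_identical(fu1, fu2)
  # while baseline rows do carry the effects
  bl1 <- with_fx[with_fx$group == "patient" &
                   with_fx$timepoint == "baseline", reg$name]
  bl2 <- no_fx[no_fx$group == "patient" &
                 no_fx$timepoint == "baseline", reg$name]
  expect_false(identical(bl1, bl2))
})

test_that("with full recovery follow-up patients match HC at the target", {
  # run at the study scale: with very small control cohorts the per-region
  # sigma-hat noise makes out-of-sample z-fields region-heteroscedastic
  # relative to the in-sample controls, which genuinely perturbs network
  # statistics - a property of normative z-scoring, not of the test
  reps <- 20
  target <- "rh_parstriangularis"
  pvals <- vapply(seq_len(reps), function(r) {
    cfg <- synthetic_config(n_hc = 25, n_patient = 25, seed = 7000 + r,
                            recovery_fraction = 1)
    tab <- generate_cohort(cfg)
    hc <- tab[tab$group == "HC", ]
    fu <- tab[tab$group == "patient" & tab$timepoint == "followup", ]
    m <- fit_normative_model(hc)
    grid <- density_grid_default(0.09)
    auc_target <- function(rows) {
      z <- compute_deviation(rows, m)
      vapply(seq_len(nrow(z)), function(i) {
        st <- build_graph_stack(build_similarity_network(z[i, ]), grid)
        auc(vapply(st$adjacency, function(a) sum(a[target, ]), numeric(1)),
            grid)
      }, numeric(1))
    }
    permutation_test_covadj(auc_target(hc), auc_target(fu),
                            cbind(hc$age, hc$sex), cbind(fu$age, fu$sex),
                            n_perm = 199, seed = r)$p
  }, numeric(1))
  # a 5%-level test should reject rarely; P(X > 4 | Bin(20, 0.05)) < 0.003
  expect_lte(sum(pvals <= 0.05), 4)
})
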