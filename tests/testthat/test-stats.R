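test_that("mixed model F tests match classical repeated-measures ANOVA", {
  d <- balanced_2x2(n_per_geno = 6, seed = 4, delta_geno = 0.8,
                    delta_time = -0.4, delta_int = 0.6)
  fit <- fit_lme_2x2(d)
  # independent oracle: aov with subject error stratum on the same data
  a <- summary(stats::aov(value ~ genotype * timepoint + Error(subject),
                          data = d))
  between <- a[["Error: subject"]][[1]]
  within <- a[["Error: Within"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  f_between <- between["genotype", "F value"]
  f_within <- within[c("timepoint", "genotype:timepoint"), "F value"]
  names(f_within) <- c("timepoint", "genotype:timepoint")
  eff <- fit$effects
  expect_equal(eff$F[eff$effect == "genotype"], f_between, tolerance = 1e-6)
  expect_equal(eff$F[eff$effect == "time"], f_within[["timepoint"]],
               tolerance = 1e-6)
  expect_equal(eff$F[eff$effect == "genotype x time"],
               f_within[["genotype:timepoint"]], tolerance = 1e-6)
  # Satterthwaite df on balanced data equal the classical strata df
  expect_equal(eff$df2[eff$effect == "genotype"], 10, tolerance = 1e-6)
  expect_equal(eff$df2[eff$effect == "time"], 10, tolerance = 1e-6)
})

test_that("a pure cell shift is recovered exactly with zero residual noise", {
  d <- balanced_2x2(n_per_geno = 4, seed = 2, sd_b = 1, sd_e = 0)
  d$value[d$genotype == "KO" & d$timepoint == "final"] <-
    d$value[d$genotype == "KO" & d$timepoint == "final"] + 3
  fit <- suppressWarnings(fit_lme_2x2(d))
  ls <- fit$lsmeans
  ko_shift <- ls$lsmean[ls$genotype == "KO" & ls$timepoint == "final"] -
    ls$lsmean[ls$genotype == "KO" & ls$timepoint == "baseline"]
  expect_equal(ko_shift, 3, tolerance = 1e-8)
})

test_that("unbalanced designs with a missing cell still fit and flag", {
  cohort <- generate_cohort(cohort_design(), seed = 11)
  up <- simulate_uptake(cohort, seed = 12)
  d <- up[up$region == "Striatum", ]
  # drop the WT baseline scans of group 1 already absent by design; also
  # verify the model runs on the study's actual unbalanced layout
  fit <- fit_lme_2x2(d, "suvr")
  expect_true(all(is.finite(fit$effects$F)))
  expect_true(all(fit$effects$p >= 0 & fit$effects$p <= 1))
  expect_equal(nrow(fit$lsmeans), 4L)
  expect_error(fit_lme_2x2(d[d$subject %in% c("KO01", "WT01"), ], "suvr"),
               "2 subjects")
})

test_that("Tukey post-hoc reduces to a t-test for two cells and is flat under equality", {
  d <- balanced_2x2(n_per_geno = 5, seed = 6, sd_b = 0, sd_e = 1)
  fit <- fit_lme_2x2(d)
  ph <- tukey_posthoc(fit)
  expect_equal(nrow(ph), 6L)  # all pairwise contrasts of 4 cells
  # equal cell means: adjusted p values are large
  expect_true(all(ph$p.value > 0.2))

  # two-group reduction: Tukey on k = 2 equals the unadjusted two-sample t
  set.seed(8)
  g1 <- rnorm(8, 0, 1); g2 <- rnorm(8, 1, 1)
  d2 <- data.frame(x = c(g1, g2), g = rep(c("a", "b"), each = 8))
  em <- emmeans::emmeans(stats::lm(x ~ g, data = d2), ~g)
  tk <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(tk$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("brain-behavior model recovers null slopes and genotype lines", {
  set.seed(10)
  design <- cohort_design(10, 10, "none")
  cohort <- generate_cohort(design, seed = 20)
  up <- simulate_uptake(cohort, seed = 21)
  beh <- generate_behavior(design, measures = "Rears", seed = 22)
  fit <- brain_behavior_model(beh, up, "Striatum", "Rears")
  # behavior was generated independently of SUVr: slopes near zero relative
  # to their scale, and the interaction should not be overwhelmingly strong
  expect_true(all(c("region x genotype", "region", "genotype") %in%
                  fit$effects$effect))
  expect_equal(nrow(fit$lines), 2L)
  expect_true(all(is.finite(fit$lines$slope)))

  # built-in opposite-sign slopes are detected
  up2 <- up
  str <- up2$region == "Striatum"
  beh2 <- beh
  key <- paste(beh2$subject, beh2$timepoint)
  ukey <- paste(up2$subject[str], up2$timepoint[str])
  slope <- ifelse(beh2$genotype == "KO", 80, -80)
  beh2$value <- beh2$value + slope * (up2$suvr[str][match(key, ukey)] - 1.15)
  fit2 <- brain_behavior_model(beh2, up2, "Striatum", "Rears")
  expect_lt(fit2$effects$p[fit2$effects$effect == "region x genotype"], 0.01)
  expect_gt(fit2$lines$slope[fit2$lines$genotype == "KO"],
            fit2$lines$slope[fit2$lines$genotype == "WT"])
})

test_that("exploratory scan enumerates the full measure-by-region cross", {
  design <- cohort_design(6, 6, "none")
  cohort <- generate_cohort(design, seed = 30)
  up <- simulate_uptake(cohort, seed = 31)
  beh <- generate_behavior(design, measures = c("Rears", "Lands"), seed = 32)
  scan <- exploratory_scan(beh, up, regions = c("Striatum", "Thalamus",
                                                "Cerebellum"))
  expect_equal(scan$summary$n_tests, c(6L, 6L))
  expect_equal(scan$summary$expected_by_chance, round(6 * c(0.05, 0.005)))
  expect_equal(nrow(scan$results), 6L * 3L)  # three effects per fit
  # alpha = 0 expects zero by chance
  s0 <- exploratory_scan(beh, up, regions = "Striatum", alphas = 0)
  expect_equal(s0$summary$expected_by_chance, 0L)
})

test_that("voxelwise t map equals the per-voxel scalar t-test", {
  set.seed(12)
  mk <- function(mu) image3(array(rnorm(27, mu, 0.05), c(3, 3, 3)), 1)
  ko <- lapply(rep(1.0, 5), mk); wt <- lapply(rep(1.1, 7), mk)
  mask <- array(TRUE, c(3, 3, 3))
  res <- voxelwise_ttest(ko, wt, mask, normalize = FALSE)
  for (v in c(1, 13, 27)) {
    a <- vapply(ko, function(im) im$voxels[v], numeric(1))
    b <- vapply(wt, function(im) im$voxels[v], numeric(1))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(as.vector(res$t$voxels)[v], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(as.vector(res$p$voxels)[v], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(res$df, 10)

  # constructed voxel: means 1.1 vs 1.0, equal SD 0.05, n = 11 vs 7
  sp <- 0.05; n1 <- 11; n2 <- 7
  t_hand <- (1.1 - 1.0) / (sp * sqrt(1 / n1 + 1 / n2))
  # exact construction: center and rescale draws to hit mean/sd exactly
  set.seed(1)
  mk_exact <- function(n, mu, s) {
    x <- rnorm(n); x <- (x - mean(x)) / sd(x) * s + mu
    lapply(x, function(v) image3(array(v, c(1, 1, 1)), 1))
  }
  res2 <- voxelwise_ttest(mk_exact(n1, 1.1, 0.05), mk_exact(n2, 1.0, 0.05),
                          array(TRUE, c(1, 1, 1)), normalize = FALSE)
  expect_equal(as.vector(res2$t$voxels), t_hand, tolerance = 1e-10)

  # identical groups give t = 0 everywhere
  same <- lapply(1:3, function(i) image3(array(1:27, c(3, 3, 3)), 1))
  res3 <- voxelwise_ttest(same, same, mask, normalize = FALSE)
  expect_true(all(res3$t$voxels == 0))
})

test_that("t-map normalization and significance bands behave", {
  set.seed(14)
  mk <- function(scale) image3(array(rnorm(27, 1, 0.02) * scale, c(3, 3, 3)), 1)
  ko <- lapply(c(10, 20, 15, 12), mk); wt <- lapply(c(1, 2, 1.5, 1.8), mk)
  mask <- array(TRUE, c(3, 3, 3))
  res <- voxelwise_ttest(ko, wt, mask, normalize = TRUE)
  # global scaling carries no signal once whole-brain normalized
  expect_lt(max(abs(res$t$voxels)), 10)
  expect_true(all(res$bands$voxels %in% c(-2L, -1L, 0L, 1L, 2L)))
  expect_true(all(abs(res$bands$voxels[res$p$voxels > 0.10]) == 0))
})
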