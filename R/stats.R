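## Repeated-measures inference. Estimation is by REML with Satterthwaite
## denominator df and type-III F tests; this approximates, but does not
## exactly reproduce, SAS containment df on unbalanced designs (documented
## in the methods vignette), so df are always reported alongside F and p.

prep_2x2 <- function(data) {
  data$genotype <- factor(data$genotype, levels = c("WT", "KO"))
  data$timepoint <- factor(data$timepoint, levels = c("baseline", "final"))
  data$subject <- factor(data$subject)
  stats::na.omit(data)
}

#' Two-by-two genotype-by-time mixed model
#'
#' Fits `value ~ genotype * timepoint + (1 | subject)` by REML and reports
#' type-III F tests (Satterthwaite df) for the interaction and both main
#' effects, plus least-squares cell means with SE. Handles unbalanced data
#' and missing cells. A singular random-intercept fit is flagged and refit
#' as ordinary least squares with a warning.
#'
#' @param data data.frame with `subject`, `genotype` (WT/KO), `timepoint`
#'   (baseline/final), and the outcome column.
#' @param outcome Name of the outcome column (default `"value"`).
#' @return An object of class `mm2x2`: list with `effects` (term, F, df1,
#'   df2, p), `lsmeans`, `fit`, `singular`, `method`, `outcome`.
#' @export
fit_lme_2x2 <- function(data, outcome = "value") {
  data$value <- data[[outcome]]
  data <- prep_2x2(data)
  if (length(unique(data$subject[data$genotype == "WT"])) < 2 ||
      length(unique(data$subject[data$genotype == "KO"])) < 2)
    stop("need at least 2 subjects per genotype")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  singular <- FALSE
  method <- "lmm"
  fit <- suppressMessages(
    lmerTest::lmer(value ~ genotype * timepoint + (1 | subject), data = data))
  if (lme4::isSingular(fit, tol = 1e-5)) singular <- TRUE
  aov3 <- tryCatch(stats::anova(fit, type = 3), error = function(e) NULL)
  if (is.null(aov3) || any(!is.finite(aov3$`F value`))) {
    warning("mixed model failed; falling back to OLS")
    method <- "ols"
    fit <- stats::lm(value ~ genotype * timepoint, data = data)
    a <- stats::drop1(fit, ~., test = "F")
    aov3 <- data.frame(`F value` = a$`F value`[-1], NumDF = a$Df[-1],
                       DenDF = stats::df.residual(fit),
                       `Pr(>F)` = a$`Pr(>F)`[-1], check.names = FALSE,
                       row.names = rownames(a)[-1])
  }
  terms_map <- c("genotype:timepoint" = "genotype x time",
                 "genotype" = "genotype", "timepoint" = "time")
  rn <- rownames(aov3)
  eff <- data.frame(
    effect = unname(terms_map[rn]),
    F = aov3$`F value`, df1 = aov3$NumDF, df2 = aov3$DenDF,
    p = aov3$`Pr(>F)`, stringsAsFactors = FALSE)
  eff <- eff[match(c("genotype x time", "genotype", "time"), eff$effect), ]
  rownames(eff) <- NULL

  em <- emmeans::emmeans(fit, ~ genotype * timepoint,
                         lmer.df = "satterthwaite")
  ls <- as.data.frame(em)
  names(ls)[names(ls) == "emmean"] <- "lsmean"
  cells_present <- nrow(unique(data[, c("genotype", "timepoint")]))
  structure(list(effects = eff, lsmeans = ls, fit = fit, emm = em,
                 singular = singular, method = method, outcome = outcome,
                 missing_cells = 4L - cells_present),
            class = "mm2x2")
}

#' @export
print.mm2x2 <- function(x, ...) {
  cat(sprintf("<mm2x2> outcome '%s' (%s%s)\n", x$outcome, x$method,
              if (x$singular) ", singular random effect" else ""))
  print(transform(x$effects, F = round(F, 2), df2 = round(df2, 1),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Tukey post-hoc contrasts of the four cells
#'
#' All pairwise cell contrasts with studentized-range (Tukey) adjusted p
#' values; intended as the follow-up to a significant interaction.
#'
#' @param result An `mm2x2` from [fit_lme_2x2()].
#' @return data.frame of contrasts: `contrast`, `estimate`, `SE`, `df`,
#'   `t.ratio`, `p.value` (Tukey-adjusted).
#' @export
tukey_posthoc <- function(result) {
  as.data.frame(emmeans::contrast(result$emm, method = "pairwise",
                                  adjust = "tukey"))
}

#' Brain-behavior mixed model
#'
#' Behavior is the dependent variable in a genotype-by-regional-uptake
#' model: `behavior ~ suvr * genotype + (1 | subject)`, pooling both
#' timepoints with a subject random intercept. Reports the
#' region-by-genotype interaction, the region (SUVr slope) main effect and
#' the genotype main effect, plus per-genotype regression lines for
#' plotting.
#'
#' @param behavior Behavior table ([generate_behavior()] layout).
#' @param uptake Uptake table ([uptake_table()] / [simulate_uptake()] layout).
#' @param region Region name to use as the uptake predictor.
#' @param measure Behavioral measure name.
#' @return `mm2x2`-like object with `effects`, `lines` (per-genotype
#'   intercept/slope), `fit`, `n`.
#' @export
brain_behavior_model <- function(behavior, uptake, region, measure) {
  b <- behavior[behavior$measure == measure, ]
  u <- uptake[uptake$region == region, ]
  d <- merge(b, u[, c("subject", "timepoint", "suvr")],
             by = c("subject", "timepoint"))
  if (nrow(d) < 6) stop("too few matched observations")
  d$genotype <- factor(d$genotype, levels = c("WT", "KO"))
  d$subject <- factor(d$subject)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  singular <- FALSE
  method <- "lmm"
  fit <- suppressMessages(
    lmerTest::lmer(value ~ suvr * genotype + (1 | subject), data = d))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  aov3 <- tryCatch(stats::anova(fit, type = 3), error = function(e) NULL)
  if (is.null(aov3) || any(!is.finite(aov3$`F value`))) {
    method <- "ols"
    fit <- stats::lm(value ~ suvr * genotype, data = d)
    a <- stats::drop1(fit, ~., test = "F")
    aov3 <- data.frame(`F value` = a$`F value`[-1], NumDF = a$Df[-1],
                       DenDF = stats::df.residual(fit),
                       `Pr(>F)` = a$`Pr(>F)`[-1], check.names = FALSE,
                       row.names = rownames(a)[-1])
  }
  terms_map <- c("suvr:genotype" = "region x genotype", "suvr" = "region",
                 "genotype" = "genotype")
  eff <- data.frame(effect = unname(terms_map[rownames(aov3)]),
                    F = aov3$`F value`, df1 = aov3$NumDF, df2 = aov3$DenDF,
                    p = aov3$`Pr(>F)`, stringsAsFactors = FALSE)
  eff <- eff[match(c("region x genotype", "region", "genotype"), eff$effect), ]
  rownames(eff) <- NULL
  fe <- if (method == "lmm") lme4::fixef(fit) else stats::coef(fit)
  ## contr.sum: genotype1 codes WT = +1, KO = -1
  lines <- data.frame(
    genotype = c("WT", "KO"),
    intercept = c(fe[["(Intercept)"]] + fe[["genotype1"]],
                  fe[["(Intercept)"]] - fe[["genotype1"]]),
    slope = c(fe[["suvr"]] + fe[["suvr:genotype1"]],
              fe[["suvr"]] - fe[["suvr:genotype1"]]),
    stringsAsFactors = FALSE)
  structure(list(effects = eff, lines = lines, fit = fit,
                 singular = singular, method = method, n = nrow(d),
                 region = region, measure = measure),
            class = "brain_behavior")
}

#' @export
print.brain_behavior <- function(x, ...) {
  cat(sprintf("<brain_behavior> '%s' ~ %s SUVr x genotype (n = %d, %s)\n",
              x$measure, x$region, x$n, x$method))
  print(transform(x$effects, F = round(F, 2), df2 = round(df2, 1),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Exploratory brain-behavior screen with multiplicity accounting
#'
#' One [brain_behavior_model()] per (measure, region) pair — 23 x 18 = 414
#' tests for the full default catalogues — with summary counts of
#' interaction and region main-effect hits at each alpha and the number of
#' hits expected by chance (`round(n_tests * alpha)`).
#'
#' @param behavior,uptake As in [brain_behavior_model()].
#' @param measures,regions Character vectors (defaults: all measures in
#'   `behavior`, all regions in `uptake` except whole brain).
#' @param alphas Screening thresholds (default 0.05 and the stricter 0.005).
#' @return List with `results` (one row per test and effect) and `summary`.
#' @export
exploratory_scan <- function(behavior, uptake, measures = NULL,
                             regions = NULL, alphas = c(0.05, 0.005)) {
  if (is.null(measures)) measures <- unique(behavior$measure)
  if (is.null(regions))
    regions <- setdiff(unique(uptake$region), "Whole brain")
  res <- list()
  for (m in measures) for (r in regions) {
    f <- tryCatch(brain_behavior_model(behavior, uptake, r, m),
                  error = function(e) NULL)
    if (is.null(f)) next
    e <- f$effects
    e$measure <- m
    e$region <- r
    res[[paste(m, r)]] <- e
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  n_tests <- length(measures) * length(regions)
  summ <- do.call(rbind, lapply(alphas, function(a) data.frame(
    alpha = a,
    n_tests = n_tests,
    interaction_hits = sum(results$p[results$effect == "region x genotype"] < a,
                           na.rm = TRUE),
    region_hits = sum(results$p[results$effect == "region"] < a,
                      na.rm = TRUE),
    expected_by_chance = round(n_tests * a))))
  list(results = results, summary = summ)
}

#' Voxel-wise two-sample t map
#'
#' Whole-brain-normalizes each image (divides by its mean over the mask),
#' then computes a pooled-variance two-sample t per voxel with sign
#' convention KO - WT, a two-sided p map, and overlay bands for p in
#' (0, 0.05] and (0.05, 0.10].
#'
#' @param group_ko,group_wt Lists of [image3()] on a common grid.
#' @param mask Logical/0-1 array (or [image3()]) of brain voxels.
#' @param normalize Divide each image by its within-mask mean first
#'   (default TRUE).
#' @return List with `t` ([image3()]), `p` ([image3()], NA outside mask),
#'   `bands` (integer [image3()]: 0 none, 1 for p <= 0.05, 2 for
#'   0.05 < p <= 0.10, signed by direction), `n_ko`, `n_wt`, `df`.
#' @export
voxelwise_ttest <- function(group_ko, group_wt, mask, normalize = TRUE) {
  stopifnot(length(group_ko) >= 2, length(group_wt) >= 2)
  if (is.list(mask) && !is.null(mask$voxels)) mask <- mask$voxels
  mask <- mask > 0
  ref <- group_ko[[1]]
  stack <- function(gr) {
    cols <- lapply(gr, function(im) {
      v <- im$voxels
      if (normalize) v <- v / mean(v[mask])
      as.vector(v)
    })
    matrix(unlist(cols), nrow = length(mask))
  }
  A <- stack(group_ko); B <- stack(group_wt)
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  tval[!is.finite(tval)] <- 0
  df <- n1 + n2 - 2
  pval <- 2 * stats::pt(-abs(tval), df)
  tval[!mask] <- 0
  pval[!mask] <- NA
  bands <- integer(length(tval))
  bands[!is.na(pval) & pval <= 0.05] <- 1L
  bands[!is.na(pval) & pval > 0.05 & pval <= 0.10] <- 2L
  bands <- bands * sign(tval)
  d3 <- dim(ref$voxels)
  list(t = image3(array(tval, d3), ref$voxel_size, ref$origin),
       p = image3(array(pval, d3), ref$voxel_size, ref$origin),
       bands = image3(array(bands, d3), ref$voxel_size, ref$origin),
       n_ko = n1, n_wt = n2, df = df)
}
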