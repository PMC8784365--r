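# Group comparison statistics.
#
# Suture-level outcomes (similarity difference, S_eff, B_eff) are compared
# between skill groups with a linear mixed-effects model containing a fixed
# skill effect and a random intercept per participant (repeated sutures), the
# novice-vs-expert contrast tested by a t test with Satterthwaite degrees of
# freedom. Segment-level outcomes are modelled with a skill-by-segment
# interaction, a participant random intercept, and residual variances allowed
# to differ by segment-by-skill cell; hypothesis tests are type III F tests.

#' Suture-level linear mixed model for a group contrast
#'
#' Fits `outcome ~ group + (1 | participant_id)` by REML and reports the
#' novice-vs-expert fixed effect with a Satterthwaite t test and a t-based
#' 95% confidence interval. A negative estimate means novices score lower.
#'
#' @param table Data frame with `participant_id`, `group` and the outcome
#'   column; at least 2 participants per group.
#' @param outcome Name of the numeric outcome column.
#' @param bounds Optional length-2 numeric. Outcomes on a bounded scale can
#'   misbehave near the bounds; values within 0.01 of either bound trigger a
#'   warning (the models here analyse outcomes untransformed).
#' @return One-row tibble of class `spm_lmm`: `outcome, estimate, ci_low,
#'   ci_high, se, df, t, p_value, random_intercept_sd,
#'   random_intercept_variance, residual_sd, n_obs, n_participants, singular`.
#' @export
suture_level_lmm <- function(table, outcome, bounds = NULL) {
  d <- as.data.frame(table)
  if (!outcome %in% names(d)) stop("no column '", outcome, "'", call. = FALSE)
  d$.y <- as.numeric(d[[outcome]])
  d$group <- factor(d$group, levels = SPM_GROUPS)
  npp <- table(unique(d[c("participant_id", "group")])$group)
  if (any(npp < 2)) {
    stop("need at least 2 participants per group; got ",
         paste(sprintf("%s=%d", names(npp), npp), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(bounds)) {
    near <- d$.y < bounds[1] + 0.01 | d$.y > bounds[2] - 0.01
    if (any(near)) {
      warning(sprintf(
        "%d of %d '%s' values lie within 0.01 of a bound [%g, %g]; a bounded-outcome transform may be warranted",
        sum(near), length(near), outcome, bounds[1], bounds[2]))
    }
  }
  fit <- suppressMessages(lmerTest::lmer(
    .y ~ group + (1 | participant_id), data = d, REML = TRUE))
  co <- stats::coef(summary(fit))["groupnovice", ]
  est <- co[["Estimate"]]; se <- co[["Std. Error"]]; df <- co[["df"]]
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == "participant_id"]
  tibble::new_tibble(tibble::tibble(
    outcome = outcome,
    estimate = est,
    ci_low = est - stats::qt(0.975, df) * se,
    ci_high = est + stats::qt(0.975, df) * se,
    se = se, df = df, t = co[["t value"]], p_value = co[["Pr(>|t|)"]],
    random_intercept_sd = ri_sd,
    random_intercept_variance = ri_sd^2,
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    n_obs = nrow(d),
    n_participants = length(unique(d$participant_id)),
    singular = lme4::isSingular(fit)
  ), class = "spm_lmm")
}

#' Segment-level type III ANOVA with cell-dependent variances
#'
#' Fits `outcome ~ group * segment` with a random intercept per participant
#' and residual variances differing by segment-by-skill cell (a `varIdent`
#' structure), using sum-to-zero contrasts, and reports marginal (type III)
#' F tests for skill, segment and their interaction. If the heteroscedastic
#' fit does not converge the model is refitted with a common residual
#' variance and flagged.
#'
#' @param table Data frame with `participant_id`, `group`, `segment` and the
#'   outcome column; at least 2 segment types and 2 participants per group.
#' @param outcome Name of the numeric outcome column.
#' @return Tibble of class `spm_anova` with one row per term
#'   (`skill`, `segment`, `skill:segment`): `F`, `num_df`, `den_df`, `p_value`;
#'   attribute `heteroscedastic` says whether the cell-variance fit was used.
#' @export
segment_level_anova <- function(table, outcome) {
  d <- as.data.frame(table)
  if (!outcome %in% names(d)) stop("no column '", outcome, "'", call. = FALSE)
  d$.y <- as.numeric(d[[outcome]])
  if (length(unique(d$segment)) < 2) {
    stop("need at least 2 segment types for a segment-level model", call. = FALSE)
  }
  npp <- table(unique(d[c("participant_id", "group")])$group)
  if (any(npp < 2)) {
    stop("need at least 2 participants per group", call. = FALSE)
  }
  d$group <- factor(d$group, levels = SPM_GROUPS)
  d$segment <- factor(d$segment, levels = SPM_SEGMENTS)
  d$segment <- droplevels(d$segment)
  contrasts(d$group) <- stats::contr.sum(nlevels(d$group))
  contrasts(d$segment) <- stats::contr.sum(nlevels(d$segment))
  d$cell <- interaction(d$group, d$segment, drop = TRUE)

  fit_het <- tryCatch(
    nlme::lme(.y ~ group * segment, random = ~ 1 | participant_id,
              weights = nlme::varIdent(form = ~ 1 | cell), data = d,
              method = "REML",
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                         opt = "optim", returnObject = FALSE)),
    error = function(e) NULL)
  heteroscedastic <- !is.null(fit_het)
  fit <- if (heteroscedastic) fit_het else {
    nlme::lme(.y ~ group * segment, random = ~ 1 | participant_id,
              data = d, method = "REML")
  }
  an <- stats::anova(fit, type = "marginal")
  rows <- c("group", "segment", "group:segment")
  out <- tibble::new_tibble(tibble::tibble(
    term = c("skill", "segment", "skill:segment"),
    F = an[rows, "F-value"],
    num_df = an[rows, "numDF"],
    den_df = an[rows, "denDF"],
    p_value = an[rows, "p-value"]
  ), class = "spm_anova")
  attr(out, "heteroscedastic") <- heteroscedastic
  out
}

#' Brown-Forsythe (median-centred Levene) homogeneity check
#'
#' Tests equality of spread across groups of residuals via absolute
#' deviations from group medians — the diagnostic used alongside the mixed
#' models to judge whether the untransformed bounded outcomes misbehave.
#'
#' @param residuals Numeric vector of residuals.
#' @param groups Grouping vector (e.g. segment-by-skill cell); at least 2
#'   groups with at least 2 residuals each.
#' @return List with `statistic` (F), `df`, `p_value`.
#' @export
variance_homogeneity_check <- function(residuals, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 residuals", call. = FALSE)
  }
  lt <- car::leveneTest(residuals, groups, center = stats::median)
  list(statistic = lt[1, "F value"],
       df = c(lt[1, "Df"], lt[2, "Df"]),
       p_value = lt[1, "Pr(>F)"])
}
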