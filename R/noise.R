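# Label-noise robustness study.
#
# Annotating the *target* of an action leaves more room for interpretation
# than the action itself, so robustness is probed by switching target labels
# with probability p over a 0-1 grid and re-running the analyses. Actions and
# the special labels (idle, not_visible) are never touched, so the efficiency
# measures are exactly invariant under this corruption — a switched target is
# still a target. An optional mode that relabels a targeted interval as idle
# instead is provided to emulate corruption that moves time into the
# no-target class; it is off by default.

#' Inject target-label noise
#'
#' Each interval carrying an `<action;target>` label independently, with
#' probability `p`, has its target replaced by one drawn uniformly from the
#' three *other* targets (so at `p = 1` every targeted interval's target has
#' changed). Idle and not-visible intervals, and all actions, are untouched.
#' Deterministic given `seed`; the global RNG state is left unchanged.
#'
#' @param dataset An `annotation_dataset`.
#' @param p Corruption probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param mode `"switch"` (default) as above; `"idle"` instead relabels the
#'   selected intervals as `idle`, emulating annotation noise that moves time
#'   into the no-target class (and therefore *does* perturb efficiency).
#' @return A corrupted `annotation_dataset` of the same shape.
#' @export
inject_target_noise <- function(dataset, p, seed, mode = c("switch", "idle")) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("p must be a probability in [0, 1]", call. = FALSE)
  }
  d <- tibble::as_tibble(dataset)
  targeted <- which(!is_nonproductive(d$action))
  withr::with_seed(seed, {
    hit <- targeted[stats::runif(length(targeted)) < p]
    if (length(hit) > 0) {
      if (mode == "switch") {
        d$target[hit] <- vapply(d$target[hit], function(t) {
          sample(setdiff(SPM_TARGETS, t), 1)
        }, "")
      } else {
        d$action[hit] <- "idle"
        d$target[hit] <- "none"
      }
    }
  })
  as_annotation_dataset(d, validate = FALSE)
}

fit_or_na <- function(expr) {
  tryCatch(expr, error = function(e) NULL, warning = function(w) {
    tryCatch(suppressWarnings(expr), error = function(e) NULL)
  })
}

# run one analysis on one (possibly corrupted) dataset -> long rows
run_noise_analyses <- function(dataset, analyses, vocabulary) {
  rows <- list()
  add <- function(analysis, hand, term, estimate, statistic, p_value) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      analysis = analysis, hand = hand, term = term,
      estimate = estimate, statistic = statistic, p_value = p_value)
  }
  if (any(c("s_eff", "b_eff") %in% analyses)) {
    eff <- fit_or_na(efficiency_table(dataset, level = "suture"))
  }
  for (analysis in analyses) {
    if (analysis == "similarity_suture") {
      for (h in SPM_HANDS) {
        st <- fit_or_na(similarity_table(dataset, level = "suture", hand = h,
                                         vocabulary = vocabulary))
        fit <- if (!is.null(st)) {
          fit_or_na(suture_level_lmm(st, "difference"))
        }
        if (is.null(fit)) add(analysis, h, "skill", NA, NA, NA)
        else add(analysis, h, "skill", fit$estimate, fit$t, fit$p_value)
      }
    } else if (analysis == "similarity_segment") {
      for (h in SPM_HANDS) {
        st <- fit_or_na(similarity_table(dataset, level = "segment", hand = h,
                                         vocabulary = vocabulary))
        an <- if (!is.null(st)) fit_or_na(segment_level_anova(st, "difference"))
        if (is.null(an)) add(analysis, h, "skill", NA, NA, NA)
        else for (i in seq_len(nrow(an))) {
          add(analysis, h, an$term[i], NA, an$F[i], an$p_value[i])
        }
      }
    } else if (analysis == "s_eff") {
      for (h in SPM_HANDS) {
        col <- paste0("s_eff_", h)
        fit <- if (!is.null(eff)) fit_or_na(suture_level_lmm(eff, col))
        if (is.null(fit)) add(analysis, h, "skill", NA, NA, NA)
        else add(analysis, h, "skill", fit$estimate, fit$t, fit$p_value)
      }
    } else if (analysis == "b_eff") {
      fit <- if (!is.null(eff)) fit_or_na(suture_level_lmm(eff, "b_eff"))
      if (is.null(fit)) add(analysis, "both", "skill", NA, NA, NA)
      else add(analysis, "both", "skill", fit$estimate, fit$t, fit$p_value)
    } else {
      stop("unknown analysis '", analysis, "'", call. = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Target-noise sweep
#'
#' Corrupts the dataset at each probability of `p_grid`, `replicates` times
#' each, re-runs the selected analyses, and records every statistic together
#' with the seed that produced it. Analysis failures in single cells are
#' recorded as `NA` rows without aborting the sweep.
#'
#' @param dataset An `annotation_dataset`.
#' @param p_grid Noise probabilities (default 0, 0.1, ..., 1).
#' @param replicates Corruption replicates per probability (default 20).
#' @param analyses Subset of `c("similarity_suture", "similarity_segment",
#'   "s_eff", "b_eff")`.
#' @param seed Integer master seed; per-cell seeds are derived from it.
#' @param vocabulary Vocabulary for the similarity analyses.
#' @param alpha Significance level for the survival summary.
#' @param mode Passed to [inject_target_noise()].
#' @return Long tibble with columns `p, replicate, seed, analysis, hand,
#'   term, estimate, statistic, p_value`. Attribute `survival`: per
#'   (analysis, hand, term), the largest grid `p` up to which the contrast
#'   stays significant at `alpha` in a majority of replicates at every
#'   smaller grid point.
#' @export
noise_sweep <- function(dataset, p_grid = seq(0, 1, by = 0.1), replicates = 20,
                        analyses = c("similarity_suture", "s_eff", "b_eff"),
                        seed, vocabulary = "full18", alpha = 0.05,
                        mode = "switch") {
  stopifnot(all(p_grid >= 0), all(p_grid <= 1), replicates >= 1)
  analyses <- match.arg(
    analyses, c("similarity_suture", "similarity_segment", "s_eff", "b_eff"),
    several.ok = TRUE)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  out <- list()
  counter <- 0L
  for (p in p_grid) {
    for (r in seq_len(replicates)) {
      counter <- counter + 1L
      cell_seed <- (as.integer(seed) + 7919L * counter) %% .Machine$integer.max
      noisy <- if (p == 0) dataset else {
        inject_target_noise(dataset, p, seed = cell_seed, mode = mode)
      }
      res <- run_noise_analyses(noisy, analyses, vocabulary)
      out[[counter]] <- tibble::tibble(p = p, replicate = r, seed = cell_seed, res)
      if (p == 0) break  # corruption-free runs are deterministic
    }
  }
  out <- dplyr::bind_rows(out)
  surv <- dplyr::summarise(
    dplyr::group_by(out, .data$analysis, .data$hand, .data$term, .data$p),
    sig = mean(.data$p_value < alpha, na.rm = TRUE) >= 0.5, .groups = "drop_last")
  surv <- dplyr::summarise(
    surv,
    largest_surviving_p = {
      ps <- sort(unique(.data$p))
      ok <- vapply(ps, function(pp) all(.data$sig[.data$p <= pp]), logical(1))
      if (!any(ok)) NA_real_ else max(ps[ok])
    },
    .groups = "drop")
  attr(out, "survival") <- surv
  out
}

#' Re-run the similarity analysis under a reduced vocabulary
#'
#' Rebuilds suture-level similarity tables under `actions_special6` (targets
#' collapsed) or `actions_only4` (idle and not-visible time also dropped) and
#' refits the suture-level skill model per hand — the check of how much of
#' the expert/novice signal survives without target information. Items with
#' no in-vocabulary time are skipped and counted; if more than half of the
#' items are skipped the analysis aborts with a diagnostic.
#'
#' @param dataset An `annotation_dataset`.
#' @param variant `"actions_special6"` or `"actions_only4"`.
#' @return List with `similarity` (per-hand suture score table), `lmm`
#'   (per-hand skill contrast), `n_skipped`, `n_items`.
#' @export
reduced_vocabulary_analysis <- function(dataset,
                                        variant = c("actions_special6", "actions_only4")) {
  variant <- match.arg(variant)
  n_skipped <- 0L; n_items <- 0L
  for (h in SPM_HANDS) {
    v <- build_vectors(dataset, level = "suture", hand = h, vocabulary = variant)
    sk <- attr(v, "skipped")
    n_skipped <- n_skipped + if (is.null(sk)) 0L else nrow(sk)
    n_items <- n_items + nrow(v) + if (is.null(sk)) 0L else nrow(sk)
  }
  if (n_items > 0 && n_skipped / n_items > 0.5) {
    stop(sprintf(
      "reduced vocabulary '%s' leaves %d of %d items with no in-vocabulary time",
      variant, n_skipped, n_items), call. = FALSE)
  }
  sim <- similarity_table(dataset, level = "suture", hand = "both",
                          vocabulary = variant)
  lmm <- dplyr::bind_rows(lapply(stats::setNames(SPM_HANDS, SPM_HANDS), function(h) {
    fit <- suture_level_lmm(sim[sim$hand == h, ], "difference")
    tibble::tibble(hand = h, fit)
  }))
  list(similarity = sim, lmm = lmm, n_skipped = n_skipped, n_items = n_items)
}
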