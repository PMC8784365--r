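# Cosine-similarity skill scoring.
#
# The similarity between two sutures (or two same-type segments) of the same
# hand is the cosine of the angle between their activity vectors; since the
# vectors are unit length and nonnegative it is their dot product, in [0, 1].
# Each item is scored against the expert and the novice pool with the item's
# own participant excluded, and the difference (expert minus novice mean
# similarity) is the skill score: positive = expert-like.

#' Cosine similarity between two activity vectors
#'
#' @param v1,v2 Numeric vectors on the same vocabulary (if named, the names
#'   must agree — a disagreement signals a vocabulary mismatch).
#' @return The cosine of the angle between them; for unit vectors, the dot
#'   product. Nonnegative inputs give a value in `[0, 1]`.
#' @examples
#' cosine_similarity(c(3, 4), c(3, 4))  # 1
#' cosine_similarity(c(1, 0), c(0, 1))  # 0
#' @export
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop("vectors have different lengths (vocabulary mismatch)", call. = FALSE)
  }
  if (!is.null(names(v1)) && !is.null(names(v2)) &&
      !identical(names(v1), names(v2))) {
    stop("vector label names disagree (vocabulary mismatch)", call. = FALSE)
  }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 <= 0 || n2 <= 0) stop("zero-length vector", call. = FALSE)
  sum(v1 * v2) / (n1 * n2)
}

#' Leave-own-participant-out group similarity of one vector
#'
#' Mean cosine similarity of `target_vector` to every expert pool vector and
#' to every novice pool vector, always excluding vectors from
#' `exclude_participant` (the item's own participant), and their difference.
#'
#' @param target_vector Numeric activity vector (unit length not required).
#' @param pool Matrix of pool vectors (rows) on the same vocabulary.
#' @param pool_group Character vector, `"expert"`/`"novice"` per pool row.
#' @param pool_participant Participant id per pool row.
#' @param exclude_participant Participant id to exclude from both pools.
#' @return List with `mean_expert_sim`, `mean_novice_sim`, `difference`.
#' @export
group_similarity <- function(target_vector, pool, pool_group, pool_participant,
                             exclude_participant) {
  stopifnot(nrow(pool) == length(pool_group),
            nrow(pool) == length(pool_participant))
  eligible <- pool_participant != exclude_participant
  sims <- as.numeric(pool %*% target_vector) /
    (sqrt(rowSums(pool^2)) * sqrt(sum(target_vector^2)))
  means <- vapply(SPM_GROUPS, function(g) {
    idx <- eligible & pool_group == g
    if (!any(idx)) {
      stop(sprintf(
        "no eligible %s vectors remain after excluding participant '%s'",
        g, exclude_participant), call. = FALSE)
    }
    mean(sims[idx])
  }, numeric(1))
  list(mean_expert_sim = unname(means["expert"]),
       mean_novice_sim = unname(means["novice"]),
       difference = unname(means["expert"] - means["novice"]))
}

#' Similarity score table for a dataset
#'
#' Builds activity vectors and scores every one against the expert and novice
#' pools drawn from the same dataset (in-sample, with the item's own
#' participant excluded — the only leakage control, matching how the scoring
#' is defined). At segment level only same-type segments are compared
#' (knot1 with knot1, and so on), so phase differences are not conflated with
#' skill differences.
#'
#' @inheritParams build_vectors
#' @return Tibble with one row per vector: metadata columns, then
#'   `mean_expert_sim`, `mean_novice_sim`, `difference`, `level`,
#'   `vocabulary`.
#' @export
similarity_table <- function(dataset, level = c("suture", "segment"),
                             hand = "both", vocabulary = "full18") {
  level <- match.arg(level)
  vocabulary <- as_vocabulary(vocabulary)
  hands <- if (hand == "both") SPM_HANDS else hand
  out <- list()
  for (h in hands) {
    vecs <- build_vectors(dataset, level = level, hand = h,
                          vocabulary = vocabulary)
    if (nrow(vecs) == 0) next
    m <- vector_matrix(vecs)
    strata <- if (level == "segment") vecs$segment else rep("all", nrow(vecs))
    res <- vector("list", nrow(vecs))
    for (i in seq_len(nrow(vecs))) {
      in_stratum <- strata == strata[i]
      gs <- group_similarity(
        m[i, ], m[in_stratum, , drop = FALSE],
        vecs$group[in_stratum], vecs$participant_id[in_stratum],
        exclude_participant = vecs$participant_id[i]
      )
      res[[i]] <- tibble::as_tibble_row(gs)
    }
    keys <- c("participant_id", "group", "suture",
              if (level == "segment") "segment", "hand")
    out[[h]] <- tibble::tibble(vecs[keys], dplyr::bind_rows(res),
                               level = level, vocabulary = vocabulary$variant)
  }
  dplyr::bind_rows(out)
}
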