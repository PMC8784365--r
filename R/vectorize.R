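# Activity-duration vectors.
#
# Each suture (or segment) of each hand is summarised as a vector whose
# components are the total seconds spent on each activity label, normalized
# to unit Euclidean length so that vectors describe the *composition* of the
# movement, independent of its absolute duration.

#' Accumulate per-label durations
#'
#' Sums interval durations onto the labels of a vocabulary. Labels the
#' vocabulary excludes (under `actions_only4`, idle and not-visible time)
#' contribute nothing. An empty interval list yields the zero vector.
#'
#' @param intervals Data frame with `start_s, end_s, action, target`.
#' @param vocabulary An [activity_vocabulary()] or variant name.
#' @return Named numeric vector of raw durations (seconds), one component per
#'   vocabulary label, in canonical order.
#' @export
accumulate_durations <- function(intervals, vocabulary = "full18") {
  vocabulary <- as_vocabulary(vocabulary)
  raw <- stats::setNames(numeric(length(vocabulary$labels)), vocabulary$labels)
  if (nrow(intervals) == 0) return(raw)
  lab <- project_labels(intervals$action, intervals$target, vocabulary)
  keep <- !is.na(lab)
  if (any(keep)) {
    sums <- tapply(intervals$end_s[keep] - intervals$start_s[keep], lab[keep], sum)
    raw[names(sums)] <- sums
  }
  raw
}

#' Normalize a raw duration vector to unit Euclidean length
#'
#' @param raw Nonnegative numeric vector with at least one positive component.
#' @return `raw / sqrt(sum(raw^2))`.
#' @export
unit_normalize <- function(raw) {
  if (any(raw < 0)) stop("duration vector has negative components", call. = FALSE)
  n <- sqrt(sum(raw^2))
  if (n <= 0) {
    stop("no in-vocabulary activity time: cannot normalize an all-zero vector",
         call. = FALSE)
  }
  raw / n
}

#' Build unit activity vectors for a dataset
#'
#' One vector per (participant, suture, hand) at suture level — durations
#' pooled across the suture's segments before normalization — or per
#' (participant, suture, segment, hand) at segment level. Items with no
#' in-vocabulary time (possible under `actions_only4` when a segment is
#' entirely idle/not visible) are skipped and recorded in the `skipped`
#' attribute.
#'
#' @param dataset An `annotation_dataset`.
#' @param level `"suture"` or `"segment"`.
#' @param hand `"left"`, `"right"`, or `"both"` (stacked).
#' @param vocabulary An [activity_vocabulary()] or variant name.
#' @return A tibble of class `activity_vectors`: metadata columns
#'   (`participant_id, group, suture, hand`, and `segment` at segment level)
#'   followed by one unit-normalized column per vocabulary label. Attributes:
#'   `vocabulary`, `level`, `skipped` (tibble of skipped items with reasons).
#' @export
build_vectors <- function(dataset, level = c("suture", "segment"),
                          hand = "both", vocabulary = "full18") {
  level <- match.arg(level)
  stopifnot(hand %in% c(SPM_HANDS, "both"))
  vocabulary <- as_vocabulary(vocabulary)
  d <- tibble::as_tibble(dataset)
  if (hand != "both") d <- d[d$hand == hand, ]
  keys <- c("participant_id", "group", "suture",
            if (level == "segment") "segment", "hand")
  parts <- dplyr::group_split(dplyr::group_by(d, dplyr::across(dplyr::all_of(keys))))
  rows <- list(); skipped <- list()
  for (s in parts) {
    meta <- s[1, keys]
    raw <- accumulate_durations(s, vocabulary)
    if (sum(raw) <= 0) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        meta, reason = "no in-vocabulary activity time")
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      meta, tibble::as_tibble_row(as.list(unit_normalize(raw))))
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(keys) + length(vocabulary$labels)),
      c(keys, vocabulary$labels)))
  }
  structure(out,
            class = c("activity_vectors", class(tibble::tibble())),
            vocabulary = vocabulary, level = level,
            skipped = if (length(skipped) > 0) dplyr::bind_rows(skipped) else NULL)
}

# numeric matrix of the label columns of an activity_vectors tibble
vector_matrix <- function(vectors) {
  labs <- attr(vectors, "vocabulary")$labels
  as.matrix(as.data.frame(vectors)[labs])
}
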