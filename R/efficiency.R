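# Uni- and bimanual efficiency from interval algebra.
#
# A hand's suturing efficiency is S_eff = (T - t_w) / T, where T is the total
# annotated duration and t_w the nonproductive time (idle or tool not
# visible). Bimanual efficiency is B_eff = t_B / T, where t_B is the measure
# of time during which *both* hands simultaneously carry a productive label —
# computed by exact intersection of the two hands' productive interval sets,
# never by sampling. Any of the 16 <action;target> labels is productive,
# including hold_still with a target (actively supporting a structure).

#' Nonproductive time of one hand's intervals
#'
#' @param intervals Data frame with `start_s, end_s, action`.
#' @return Total seconds labelled `idle` or `not_visible`.
#' @export
nonproductive_time <- function(intervals) {
  np <- is_nonproductive(intervals$action)
  sum(intervals$end_s[np] - intervals$start_s[np])
}

#' Suturing efficiency of one hand's intervals
#'
#' @param intervals Data frame with `start_s, end_s, action`; total duration
#'   must be positive.
#' @return `(T - t_w) / T`, the fraction of time on productive movements.
#' @export
suturing_efficiency <- function(intervals) {
  total <- sum(intervals$end_s - intervals$start_s)
  if (total <= 0) stop("total annotated time is zero", call. = FALSE)
  (total - nonproductive_time(intervals)) / total
}

# total overlap length between two sets of disjoint sorted intervals
intersect_length <- function(s1, e1, s2, e2) {
  if (length(s1) == 0 || length(s2) == 0) return(0)
  tot <- 0; i <- 1L; j <- 1L
  while (i <= length(s1) && j <= length(s2)) {
    lo <- max(s1[i], s2[j]); hi <- min(e1[i], e2[j])
    if (hi > lo) tot <- tot + (hi - lo)
    if (e1[i] <= e2[j]) i <- i + 1L else j <- j + 1L
  }
  tot
}

productive_set <- function(intervals) {
  p <- intervals[!is_nonproductive(intervals$action), , drop = FALSE]
  p <- p[order(p$start_s), , drop = FALSE]
  list(start = p$start_s, end = p$end_s)
}

#' Time both hands are simultaneously productive
#'
#' Exact intersection (event-boundary sweep) of the two hands' productive
#' interval sets over a shared time span.
#'
#' @param left,right Data frames of one segment's (or suture's) intervals for
#'   each hand; both must span the same time range.
#' @param tol Maximum allowed span mismatch in seconds.
#' @return Seconds during which both hands carry a productive label.
#' @examples
#' li <- tibble::tibble(start_s = 0, end_s = 10, action = "move", target = "needle")
#' ri <- tibble::tibble(
#'   start_s = c(0, 5), end_s = c(5, 15),
#'   action = c("idle", "transport"), target = c("none", "incision")
#' )
#' # right productive only on [5, 15) but spans must match; trim to [0, 10):
#' ri$end_s[2] <- 10
#' bimanual_productive_time(li, ri)  # 5
#' @export
bimanual_productive_time <- function(left, right, tol = 1e-6) {
  span <- function(x) c(min(x$start_s), max(x$end_s))
  if (nrow(left) == 0 || nrow(right) == 0) {
    stop("both hands need at least one interval", call. = FALSE)
  }
  if (any(abs(span(left) - span(right)) > tol)) {
    stop(sprintf(
      "left hand spans [%g, %g] but right hand spans [%g, %g]",
      span(left)[1], span(left)[2], span(right)[1], span(right)[2]),
      call. = FALSE)
  }
  l <- productive_set(left); r <- productive_set(right)
  intersect_length(l$start, l$end, r$start, r$end)
}

#' Efficiency table for a dataset
#'
#' One record per suture (durations and nonproductive/bimanual times summed
#' over the suture's segments) or per segment, with each hand's suturing
#' efficiency and the bimanual efficiency over the shared span.
#'
#' @param dataset An `annotation_dataset`.
#' @param level `"suture"` or `"segment"`.
#' @return Tibble with columns `participant_id, group, suture`
#'   (`segment` at segment level), `s_eff_left`, `s_eff_right`, `b_eff`,
#'   `total_time_s`, `level`. Invariant: `b_eff <= min(s_eff_left,
#'   s_eff_right)`.
#' @export
efficiency_table <- function(dataset, level = c("suture", "segment")) {
  level <- match.arg(level)
  d <- tibble::as_tibble(dataset)
  segs <- dplyr::group_split(dplyr::group_by(
    d, .data$participant_id, .data$group, .data$suture, .data$segment))
  per_seg <- dplyr::bind_rows(lapply(segs, function(s) {
    left <- s[s$hand == "left", ]; right <- s[s$hand == "right", ]
    total <- sum(left$end_s - left$start_s)
    tibble::tibble(
      participant_id = s$participant_id[1], group = s$group[1],
      suture = s$suture[1], segment = s$segment[1],
      total_time_s = total,
      t_w_left = nonproductive_time(left),
      t_w_right = nonproductive_time(right),
      t_b = bimanual_productive_time(left, right)
    )
  }))
  if (level == "suture") {
    per_seg <- dplyr::summarise(
      dplyr::group_by(per_seg, .data$participant_id, .data$group, .data$suture),
      dplyr::across(dplyr::all_of(c("total_time_s", "t_w_left", "t_w_right", "t_b")), sum),
      .groups = "drop")
  }
  out <- dplyr::mutate(
    per_seg,
    s_eff_left = (.data$total_time_s - .data$t_w_left) / .data$total_time_s,
    s_eff_right = (.data$total_time_s - .data$t_w_right) / .data$total_time_s,
    b_eff = .data$t_b / .data$total_time_s,
    level = level
  )
  dplyr::select(out, dplyr::all_of(c(
    "participant_id", "group", "suture", if (level == "segment") "segment",
    "s_eff_left", "s_eff_right", "b_eff", "total_time_s", "level")))
}
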