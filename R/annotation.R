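# Annotation datasets: flat interval tables with strict validation.
#
# A dataset is one row per annotated interval of one hand:
#   participant_id, group, handedness, suture, segment, hand,
#   start_s, end_s, action, target
# Within one (participant, suture, segment, hand) the intervals must tile the
# segment's time span contiguously — gaps must be labelled idle/not_visible by
# the annotator, never inferred — and both hands must span the same range.
# Segment types appear in the fixed order needle_transport, piercing, knot1,
# knot2, knot3; trailing knots may be absent (incomplete sutures).

ANNOTATION_COLS <- c(
  "participant_id", "group", "handedness", "suture", "segment", "hand",
  "start_s", "end_s", "action", "target"
)

#' Coerce and validate an annotation data frame
#'
#' Normalizes tokens (the input alias `grab` is accepted for `grasp`), orders
#' rows by participant, suture, canonical segment order, hand and start time,
#' validates every structural invariant, and stamps the class
#' `annotation_dataset`.
#'
#' @param x A data frame with the columns
#'   `participant_id, group, handedness, suture, segment, hand, start_s,
#'   end_s, action, target`.
#' @param validate Run full validation (default `TRUE`).
#' @return A tibble of class `annotation_dataset`.
#' @seealso [read_annotations()], [validate_annotations()]
#' @export
as_annotation_dataset <- function(x, validate = TRUE) {
  missing_cols <- setdiff(ANNOTATION_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(x)[ANNOTATION_COLS]
  for (col in c("participant_id", "group", "handedness", "segment", "hand",
                "action", "target")) {
    d[[col]] <- trimws(as.character(d[[col]]))
  }
  d$action[d$action == "grab"] <- "grasp"
  d$suture <- as.integer(d$suture)
  d$start_s <- as.numeric(d$start_s)
  d$end_s <- as.numeric(d$end_s)
  if (validate) validate_annotations(d)
  d <- d[order(d$participant_id, d$suture,
               match(d$segment, SPM_SEGMENTS), d$hand, d$start_s), ]
  structure(d, class = c("annotation_dataset", class(tibble::tibble())))
}

#' Validate annotation invariants
#'
#' Checks token vocabularies, the target/special-label consistency rule
#' (`target == "none"` if and only if the action is `idle` or `not_visible`),
#' positive durations, per-hand non-overlap and contiguity (no gaps — idle
#' time must be labelled explicitly), equal left/right spans per segment, the
#' canonical segment order (present segments must be a prefix of
#' needle_transport, piercing, knot1, knot2, knot3), and one group/handedness
#' per participant. All violations are collected and reported together with
#' 1-based data row numbers (in the row order of `x`).
#'
#' @param x A data frame with the annotation columns.
#' @param tol Time tolerance in seconds for gap/overlap/span checks.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_annotations <- function(x, tol = 1e-6) {
  d <- x
  d$.row <- seq_len(nrow(d))
  problems <- character()
  note <- function(rows, why) {
    problems[[length(problems) + 1L]] <<-
      sprintf("row %s: %s", paste(rows, collapse = ","), why)
  }

  bad <- d$.row[!d$group %in% SPM_GROUPS]
  for (r in bad) note(r, sprintf("unknown group '%s'", d$group[d$.row == r]))
  bad <- d$.row[!d$handedness %in% SPM_HANDS]
  for (r in bad) note(r, sprintf("unknown handedness '%s'", d$handedness[d$.row == r]))
  bad <- d$.row[!d$segment %in% SPM_SEGMENTS]
  for (r in bad) note(r, sprintf("unknown segment '%s'", d$segment[d$.row == r]))
  bad <- d$.row[!d$hand %in% SPM_HANDS]
  for (r in bad) note(r, sprintf("unknown hand '%s'", d$hand[d$.row == r]))
  bad <- d$.row[!d$action %in% c(SPM_ACTIONS, SPM_SPECIALS)]
  for (r in bad) note(r, sprintf("unknown action '%s'", d$action[d$.row == r]))
  bad <- d$.row[!d$target %in% c(SPM_TARGETS, "none")]
  for (r in bad) note(r, sprintf("unknown target '%s'", d$target[d$.row == r]))
  bad <- d$.row[is.na(d$suture) | d$suture < 1L]
  for (r in bad) note(r, "suture must be a positive integer")
  bad <- d$.row[!is.finite(d$start_s) | !is.finite(d$end_s)]
  for (r in bad) note(r, "start_s/end_s must be finite numbers")

  if (length(problems) == 0) {
    ok_tok <- TRUE
    special <- d$action %in% SPM_SPECIALS
    bad <- d$.row[special & d$target != "none"]
    for (r in bad) {
      note(r, sprintf(
        "action '%s' must have target 'none' (special labels carry no target)",
        d$action[d$.row == r]))
    }
    bad <- d$.row[!special & d$target == "none"]
    for (r in bad) {
      note(r, sprintf("action '%s' requires a real target, got 'none'",
                      d$action[d$.row == r]))
    }
    bad <- d$.row[d$end_s <= d$start_s]
    for (r in bad) note(r, "end_s must be strictly greater than start_s")
  } else {
    ok_tok <- FALSE
  }

  if (ok_tok && length(problems) == 0) {
    # one group/handedness per participant
    per_p <- dplyr::summarise(
      dplyr::group_by(d, .data$participant_id),
      n_group = dplyr::n_distinct(.data$group),
      n_handed = dplyr::n_distinct(.data$handedness),
      .groups = "drop"
    )
    for (p in per_p$participant_id[per_p$n_group > 1]) {
      note(d$.row[d$participant_id == p][1],
           sprintf("participant '%s' appears in more than one group", p))
    }
    for (p in per_p$participant_id[per_p$n_handed > 1]) {
      note(d$.row[d$participant_id == p][1],
           sprintf("participant '%s' has inconsistent handedness", p))
    }

    # per-hand sequences: sorted, non-overlapping, contiguous
    seqs <- split(d, interaction(d$participant_id, d$suture, d$segment, d$hand,
                                 drop = TRUE))
    for (s in seqs) {
      s <- s[order(s$start_s), ]
      if (nrow(s) > 1) {
        gap <- s$start_s[-1] - s$end_s[-nrow(s)]
        over <- which(gap < -tol)
        for (i in over) {
          note(s$.row[i + 1], sprintf(
            "interval [%g,%g) overlaps the previous interval ending at %g (%s hand, %s, suture %d)",
            s$start_s[i + 1], s$end_s[i + 1], s$end_s[i], s$hand[1],
            s$segment[1], s$suture[1]))
        }
        gaps <- which(gap > tol)
        for (i in gaps) {
          note(s$.row[i + 1], sprintf(
            "gap of %.3f s before interval starting at %g (%s hand, %s, suture %d); gaps must be labelled idle or not_visible",
            gap[i], s$start_s[i + 1], s$hand[1], s$segment[1], s$suture[1]))
        }
      }
    }

    # both hands tile the same span; segment order is a prefix of the canon
    segs <- split(d, interaction(d$participant_id, d$suture, d$segment,
                                 drop = TRUE))
    for (s in segs) {
      hands <- unique(s$hand)
      if (length(hands) == 2) {
        spans <- vapply(SPM_HANDS, function(h) {
          range(c(s$start_s[s$hand == h], s$end_s[s$hand == h]))
        }, numeric(2))
        if (any(abs(spans[, 1] - spans[, 2]) > tol)) {
          note(s$.row[1], sprintf(
            "left and right hands span different time ranges in %s of suture %d (participant %s)",
            s$segment[1], s$suture[1], s$participant_id[1]))
        }
      } else {
        note(s$.row[1], sprintf(
          "segment %s of suture %d (participant %s) has annotations for only the %s hand",
          s$segment[1], s$suture[1], s$participant_id[1], hands))
      }
    }

    sut <- dplyr::distinct(d, .data$participant_id, .data$suture, .data$segment)
    sut <- split(sut, interaction(sut$participant_id, sut$suture, drop = TRUE))
    for (s in sut) {
      present <- SPM_SEGMENTS %in% s$segment
      k <- sum(present)
      if (!all(present[seq_len(k)])) {
        note(d$.row[d$participant_id == s$participant_id[1] &
                      d$suture == s$suture[1]][1], sprintf(
          "suture %d of participant %s has segments {%s}; segments must form a prefix of %s",
          s$suture[1], s$participant_id[1], paste(s$segment, collapse = ", "),
          paste(SPM_SEGMENTS, collapse = " < ")))
      }
    }
  }

  if (length(problems) > 0) {
    stop("invalid annotation data:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "),
         if (length(problems) > 20) sprintf("\n  ... and %d more", length(problems) - 20),
         call. = FALSE)
  }
  invisible(TRUE)
}

detect_delim <- function(header) if (grepl("\t", header)) "\t" else ","

#' Read an annotation file
#'
#' Reads the UTF-8 delimited annotation format: one interval per row, header
#' `participant_id,group,handedness,suture,segment,hand,start_s,end_s,action,target`,
#' comma- or tab-separated (auto-detected from the header line), `#` comment
#' lines ignored. Row numbers in error messages are 1-based data rows, i.e.
#' the header and comment lines are not counted.
#'
#' @param source Path to a file, or a character vector of lines.
#' @return An [as_annotation_dataset()] tibble, rows within each
#'   (participant, suture, segment, hand) ordered by start time.
#' @examples
#' lines <- c(
#'   "participant_id,group,handedness,suture,segment,hand,start_s,end_s,action,target",
#'   "E1,expert,right,1,needle_transport,left,0,4,hold_still,incision",
#'   "E1,expert,right,1,needle_transport,right,0,4,transport,needle"
#' )
#' read_annotations(lines)
#' @export
read_annotations <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE, encoding = "UTF-8")
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty annotation source", call. = FALSE)
  delim <- detect_delim(lines[1])
  header <- trimws(strsplit(lines[1], delim, fixed = TRUE)[[1]])
  if (!identical(header, ANNOTATION_COLS)) {
    stop("unexpected header; expected exactly: ",
         paste(ANNOTATION_COLS, collapse = ","), call. = FALSE)
  }
  if (length(lines) == 1) {
    d <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(ANNOTATION_COLS)), ANNOTATION_COLS))
    d$suture <- integer(0); d$start_s <- numeric(0); d$end_s <- numeric(0)
    return(as_annotation_dataset(d, validate = FALSE))
  }
  d <- utils::read.delim(
    text = paste(lines, collapse = "\n"), sep = delim,
    colClasses = "character", strip.white = TRUE, check.names = FALSE
  )
  nf <- which(lengths(strsplit(lines[-1], delim, fixed = TRUE)) != length(ANNOTATION_COLS))
  if (length(nf) > 0) {
    stop(sprintf("row %d: malformed row (wrong number of fields)", nf[1]),
         call. = FALSE)
  }
  bad_num <- which(is.na(suppressWarnings(as.numeric(d$start_s))) |
                     is.na(suppressWarnings(as.numeric(d$end_s))) |
                     is.na(suppressWarnings(as.integer(d$suture))))
  if (length(bad_num) > 0) {
    stop(sprintf("row %d: malformed row (non-numeric suture/start_s/end_s)",
                 bad_num[1]), call. = FALSE)
  }
  as_annotation_dataset(d)
}

#' Write an annotation file
#'
#' Inverse of [read_annotations()]: `read_annotations(write_annotations(d, f))`
#' reproduces `d` up to row order. An empty dataset yields a header-only file.
#'
#' @param dataset An `annotation_dataset`.
#' @param sink File path.
#' @param delim `","` (default) or `"\t"`.
#' @return Invisibly, `sink`.
#' @export
write_annotations <- function(dataset, sink, delim = ",") {
  stopifnot(delim %in% c(",", "\t"))
  d <- as.data.frame(dataset)[ANNOTATION_COLS]
  d$start_s <- format(d$start_s, digits = 15, trim = TRUE, scientific = FALSE)
  d$end_s <- format(d$end_s, digits = 15, trim = TRUE, scientific = FALSE)
  con <- file(sink, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(ANNOTATION_COLS, collapse = delim), con)
  if (nrow(d) > 0) {
    utils::write.table(d, con, sep = delim, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(sink)
}

# Merge one hand's sequence: absorb sub-threshold intervals into the previous
# interval (a short leader is absorbed by its successor), coalescing adjacent
# equal labels, until no interval is shorter than min_duration or only one
# interval remains. Total covered time is conserved exactly.
merge_sequence <- function(dur, lab, min_duration) {
  repeat {
    if (length(dur) > 1) {
      same <- which(lab[-1] == lab[-length(lab)])
      while (length(same) > 0) {
        i <- same[1]
        dur[i] <- dur[i] + dur[i + 1]
        dur <- dur[-(i + 1)]
        lab <- lab[-(i + 1)]
        same <- which(lab[-1] == lab[-length(lab)])
      }
    }
    if (length(dur) <= 1) break
    short <- which(dur < min_duration)
    if (length(short) == 0) break
    i <- short[1]
    if (i == 1) {
      dur[2] <- dur[2] + dur[1]
      dur <- dur[-1]; lab <- lab[-1]
    } else {
      dur[i - 1] <- dur[i - 1] + dur[i]
      dur <- dur[-i]; lab <- lab[-i]
    }
  }
  list(dur = dur, lab = lab)
}

#' Merge very short activities into their neighbours
#'
#' Annotation preprocessing: intervals shorter than `min_duration` (default
#' 0.5 s — e.g. a brief pause during a transport) are merged into the previous
#' activity; a short leading interval, having no predecessor, is absorbed by
#' its successor. Adjacent intervals sharing a label are coalesced, and the
#' rule is applied until stable, so no sub-threshold interval remains unless a
#' whole sequence reduces to a single interval. Total annotated time per
#' (suture, segment, hand) is conserved exactly; interval boundaries are
#' recomputed from the conserved durations.
#'
#' @param x An `annotation_dataset`, or a data frame holding one hand's
#'   interval sequence (columns `start_s, end_s, action, target`).
#' @param min_duration Threshold in seconds; default 0.5.
#' @return The same type as `x`, with merged intervals.
#' @examples
#' seq <- tibble::tibble(
#'   start_s = c(0, 2, 2.3), end_s = c(2, 2.3, 3.3),
#'   action = c("move", "grasp", "move"),
#'   target = c("needle", "thread", "needle")
#' )
#' merge_short_activities(seq)  # one 3.3 s <move;needle> interval
#' @export
merge_short_activities <- function(x, min_duration = 0.5) {
  merge_one <- function(s) {
    if (nrow(s) == 0) return(s)
    s <- s[order(s$start_s), ]
    m <- merge_sequence(s$end_s - s$start_s,
                        paste(s$action, s$target, sep = ";"), min_duration)
    at <- strsplit(m$lab, ";", fixed = TRUE)
    ends <- s$start_s[1] + cumsum(m$dur)
    out <- s[rep(1, length(m$dur)), , drop = FALSE]
    out$start_s <- c(s$start_s[1], ends[-length(ends)])
    out$end_s <- ends
    out$action <- vapply(at, `[`, "", 1)
    out$target <- vapply(at, `[`, "", 2)
    out
  }
  if (inherits(x, "annotation_dataset")) {
    parts <- split(tibble::as_tibble(x),
                   interaction(x$participant_id, x$suture, x$segment, x$hand,
                               drop = TRUE))
    as_annotation_dataset(dplyr::bind_rows(lapply(parts, merge_one)))
  } else {
    if (nrow(x) == 0) return(x)
    merge_one(tibble::as_tibble(x))
  }
}
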