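# Activity vocabulary: the movement-level alphabet of the process model.
#
# An elementary activity of one hand is an <action;target> tuple — one of four
# actions (move, transport, hold_still, grasp) applied to one of four targets
# of interest (needle, incision, thread, tool) — or one of two special labels:
# idle (nonproductive movement, no definable target) and not_visible (tool out
# of the camera's field of view). 4 x 4 + 2 = 18 activities in total.

SPM_ACTIONS  <- c("move", "transport", "hold_still", "grasp")
SPM_TARGETS  <- c("needle", "incision", "thread", "tool")
SPM_SPECIALS <- c("idle", "not_visible")
SPM_SEGMENTS <- c("needle_transport", "piercing", "knot1", "knot2", "knot3")
SPM_HANDS    <- c("left", "right")
SPM_GROUPS   <- c("expert", "novice")

#' Elementary actions, targets and segment types of the process model
#'
#' The model describes each hand's behaviour as `<action;target>` tuples over
#' four elementary actions and four targets of interest, plus two special
#' labels (`idle` for nonproductive movement, `not_visible` when the tool is
#' outside the field of view). A suture is divided into five ordered segments:
#' needle transport, piercing, and three knots.
#'
#' @return Character vectors of the canonical tokens.
#' @export
activity_actions <- function() SPM_ACTIONS

#' @rdname activity_actions
#' @export
activity_targets <- function() SPM_TARGETS

#' @rdname activity_actions
#' @export
special_labels <- function() SPM_SPECIALS

#' @rdname activity_actions
#' @export
segment_types <- function() SPM_SEGMENTS

#' Canonical activity label list for a vocabulary variant
#'
#' @param variant `"full18"` (16 action-by-target labels in action-major
#'   order, then `idle`, then `not_visible`), `"actions_special6"` (targets
#'   collapsed: the four actions plus `not_visible` and `idle`), or
#'   `"actions_only4"` (the four actions; idle and not-visible time is dropped
#'   before normalization).
#' @return Character vector of labels in canonical order. Tuple labels are
#'   written `"action;target"`, e.g. `"transport;incision"`.
#' @examples
#' activity_labels()              # 18 labels
#' activity_labels("actions_only4")
#' @export
activity_labels <- function(variant = c("full18", "actions_special6", "actions_only4")) {
  variant <- match.arg(variant)
  switch(variant,
    full18 = c(
      as.vector(t(outer(SPM_ACTIONS, SPM_TARGETS, paste, sep = ";"))),
      SPM_SPECIALS
    ),
    actions_special6 = c(SPM_ACTIONS, "not_visible", "idle"),
    actions_only4 = SPM_ACTIONS
  )
}

#' Construct an activity vocabulary
#'
#' A vocabulary fixes the basis on which duration vectors are built: which
#' labels are distinguished and in what order. The reduced variants are used
#' for the robustness re-analysis that asks how much of the expert/novice
#' signal lives in the targets versus the actions.
#'
#' @inheritParams activity_labels
#' @return An object of class `activity_vocabulary` with elements `variant`
#'   and `labels`.
#' @export
activity_vocabulary <- function(variant = c("full18", "actions_special6", "actions_only4")) {
  variant <- match.arg(variant)
  structure(
    list(variant = variant, labels = activity_labels(variant)),
    class = "activity_vocabulary"
  )
}

#' @export
print.activity_vocabulary <- function(x, ...) {
  cat("<activity_vocabulary> variant:", x$variant,
      "(", length(x$labels), "labels )\n")
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

as_vocabulary <- function(x) {
  if (inherits(x, "activity_vocabulary")) return(x)
  activity_vocabulary(x)
}

# Project (action, target) pairs onto a vocabulary. Returns NA for labels the
# variant excludes (actions_only4 drops idle/not_visible time entirely).
project_labels <- function(action, target, vocabulary) {
  vocabulary <- as_vocabulary(vocabulary)
  special <- action %in% SPM_SPECIALS
  out <- switch(vocabulary$variant,
    full18 = ifelse(special, action, paste(action, target, sep = ";")),
    actions_special6 = action,
    actions_only4 = ifelse(special, NA_character_, action)
  )
  out
}

is_nonproductive <- function(action) action %in% SPM_SPECIALS
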