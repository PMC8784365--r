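test_that("reading a minimal file builds the expected dataset", {
  lines <- c(
    "participant_id,group,handedness,suture,segment,hand,start_s,end_s,action,target",
    "# a comment",
    "E1,expert,right,1,needle_transport,left,0,4,hold_still,incision",
    "E1,expert,right,1,needle_transport,right,0,4,transport,needle"
  )
  d <- read_annotations(lines)
  expect_s3_class(d, "annotation_dataset")
  expect_equal(nrow(d), 2)
  expect_equal(length(unique(d$participant_id)), 1)
  expect_equal(length(unique(d$suture)), 1)
  expect_setequal(d$hand, c("left", "right"))
})

test_that("tab-delimited files are auto-detected and 'grab' is aliased to grasp", {
  lines <- c(
    paste(c("participant_id", "group", "handedness", "suture", "segment",
            "hand", "start_s", "end_s", "action", "target"), collapse = "\t"),
    "E1\texpert\tright\t1\tneedle_transport\tleft\t0\t3\tgrab\ttool",
    "E1\texpert\tright\t1\tneedle_transport\tright\t0\t3\tmove\tneedle"
  )
  d <- read_annotations(lines)
  expect_equal(d$action[d$hand == "left"], "grasp")
})

test_that("validation rejects targets on special labels, overlaps and gaps with row numbers", {
  base <- c(
    "participant_id,group,handedness,suture,segment,hand,start_s,end_s,action,target")
  expect_error(
    read_annotations(c(base,
      "E1,expert,right,1,piercing,left,0,5,idle,incision",
      "E1,expert,right,1,piercing,right,0,5,move,needle")),
    "row 1.*idle.*target 'none'")
  expect_error(
    read_annotations(c(base,
      "E1,expert,right,1,piercing,left,0,5,move,needle",
      "E1,expert,right,1,piercing,left,4,9,idle,none",
      "E1,expert,right,1,piercing,right,0,9,move,needle")),
    "row 2.*overlap")
  expect_error(
    read_annotations(c(base,
      "E1,expert,right,1,piercing,left,0,4,move,needle",
      "E1,expert,right,1,piercing,left,5,9,idle,none",
      "E1,expert,right,1,piercing,right,0,9,move,needle")),
    "gap")
  expect_error(
    read_annotations(c(base,
      "E1,expert,right,1,piercing,left,0,5,swing,needle",
      "E1,expert,right,1,piercing,right,0,5,move,needle")),
    "unknown action 'swing'")
})

test_that("hands must span the same range and segments must be a prefix of the canon", {
  expect_error(make_dataset(list(list(
    participant_id = "E1", group = "expert", suture = 1, segment = "piercing",
    left = list(durations = 5, labels = "move;needle"),
    right = list(durations = 7, labels = "move;needle")
  ))), "span different time ranges")
  expect_error(make_dataset(list(
    list(participant_id = "E1", group = "expert", suture = 1,
         segment = "needle_transport",
         left = list(durations = 5, labels = "move;needle"),
         right = list(durations = 5, labels = "move;needle")),
    list(participant_id = "E1", group = "expert", suture = 1, segment = "knot2",
         left = list(durations = 5, labels = "move;needle"),
         right = list(durations = 5, labels = "move;needle"))
  )), "prefix")
})

test_that("write/read round-trips randomly generated datasets and preserves counts", {
  for (seed in 1:3) {
    d <- generate_dataset(small_config(seed))
    f <- withr::local_tempfile(fileext = ".csv")
    write_annotations(d, f)
    d2 <- read_annotations(f)
    expect_equal(nrow(d2), nrow(d))
    expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
  }
  # empty dataset -> header-only file
  empty <- read_annotations(
    "participant_id,group,handedness,suture,segment,hand,start_s,end_s,action,target")
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(empty, f)
  expect_length(readLines(f), 1)
})

test_that("short activities merge into the previous interval, leaders into their successor", {
  s <- make_sequence(c(2, 0.3, 1), c("move;needle", "grasp;thread", "move;needle"))
  m <- merge_short_activities(s)
  expect_equal(nrow(m), 1)
  expect_equal(m$end_s - m$start_s, 3.3)
  expect_equal(m$action, "move")

  s <- make_sequence(c(0.2, 5), c("grasp;thread", "move;needle"))
  m <- merge_short_activities(s)
  expect_equal(nrow(m), 1)
  expect_equal(m$action, "move")
  expect_equal(m$end_s - m$start_s, 5.2)

  # all long, distinct labels: unchanged
  s <- make_sequence(c(1, 2, 3), c("move;needle", "idle", "grasp;thread"))
  expect_equal(merge_short_activities(s), s)

  # empty sequence passes through
  expect_equal(nrow(merge_short_activities(s[0, ])), 0)
})

test_that("merging conserves covered time and leaves no sub-threshold interval", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:12, 1)
    labs <- sample(c("move;needle", "idle", "grasp;thread", "hold_still;incision"),
                   n, replace = TRUE)
    s <- make_sequence(stats::runif(n, 0.05, 3), labs)
    m <- merge_short_activities(s)
    expect_equal(sum(m$end_s - m$start_s), sum(s$end_s - s$start_s),
                 tolerance = 1e-9)
    if (nrow(m) > 1) expect_true(all(m$end_s - m$start_s >= 0.5))
    # adjacent intervals never share a label after merging
    if (nrow(m) > 1) {
      lab <- paste(m$action, m$target)
      expect_false(any(lab[-1] == lab[-length(lab)]))
    }
  }
  d <- generate_dataset(small_config(11))
  md <- merge_short_activities(d)
  tot <- function(x) sum(x$end_s - x$start_s)
  expect_equal(tot(md), tot(d), tolerance = 1e-9)
  expect_s3_class(md, "annotation_dataset")
})
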