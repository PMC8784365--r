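test_that("nonproductive time sums idle and not-visible durations", {
  s <- make_sequence(c(3, 2, 1), c("move;needle", "idle", "not_visible"))
  expect_equal(nonproductive_time(s), 3)
  expect_equal(nonproductive_time(make_sequence(c(2, 2), c("move;needle", "grasp;thread"))), 0)
  expect_equal(nonproductive_time(make_sequence(4, "idle")), 4)
})

test_that("suturing efficiency is (T - t_w)/T with the documented bounds", {
  s <- make_sequence(c(68, 32), c("move;needle", "idle"))
  expect_equal(suturing_efficiency(s), 0.68)
  expect_equal(suturing_efficiency(make_sequence(5, "move;needle")), 1)
  expect_equal(suturing_efficiency(make_sequence(5, "idle")), 0)
  expect_error(suturing_efficiency(s[0, ]), "zero")
})

test_that("bimanual productive time is the exact intersection of productive sets", {
  left <- make_sequence(c(10, 5), c("move;needle", "idle"))
  right <- make_sequence(c(5, 10), c("idle", "transport;incision"))
  expect_equal(bimanual_productive_time(left, right), 5)

  # disjoint productive windows
  left <- make_sequence(c(5, 5), c("move;needle", "idle"))
  right <- make_sequence(c(5, 5), c("idle", "move;needle"))
  expect_equal(bimanual_productive_time(left, right), 0)

  # both fully productive
  left <- make_sequence(10, "hold_still;incision")
  right <- make_sequence(c(4, 6), c("move;needle", "grasp;thread"))
  expect_equal(bimanual_productive_time(left, right), 10)

  expect_error(
    bimanual_productive_time(make_sequence(10, "idle"),
                             make_sequence(12, "idle")),
    "span")
})

test_that("hold_still with a target counts as productive", {
  left <- make_sequence(10, "hold_still;incision")
  expect_equal(suturing_efficiency(left), 1)
})

test_that("efficiency tables match the 1 ms timeline-sampling oracle", {
  for (seed in 1:2) {
    d <- generate_dataset(small_config(seed))
    for (lvl in c("suture", "segment")) {
      got <- efficiency_table(d, level = lvl)
      want <- oracle_efficiency(d, level = lvl)
      key <- function(x) {
        if (lvl == "segment") paste(x$participant_id, x$suture, x$segment)
        else paste(x$participant_id, x$suture)
      }
      want <- want[match(key(got), key(want)), ]
      tol <- pmax(2e-3, 1.5e-3 * want$n_ints) / got$total_time_s
      expect_true(all(abs(got$s_eff_left - want$s_eff_left) <= tol))
      expect_true(all(abs(got$s_eff_right - want$s_eff_right) <= tol))
      expect_true(all(abs(got$b_eff - want$b_eff) <= tol))
    }
  }
})

test_that("efficiency records respect their ordering and additivity invariants", {
  d <- generate_dataset(small_config(9, n = 3, sutures = 2))
  sut <- efficiency_table(d, "suture")
  seg <- efficiency_table(d, "segment")
  expect_true(all(sut$b_eff <= pmin(sut$s_eff_left, sut$s_eff_right) + 1e-12))
  expect_true(all(seg$b_eff <= pmin(seg$s_eff_left, seg$s_eff_right) + 1e-12))
  expect_true(all(sut$s_eff_left >= 0 & sut$s_eff_left <= 1))
  expect_true(all(sut$b_eff >= 0 & sut$b_eff <= 1))

  # suture T and per-hand nonproductive time add over segments
  agg <- dplyr::summarise(
    dplyr::group_by(seg, participant_id, suture),
    w_left = sum((1 - s_eff_left) * total_time_s),
    total_time_s = sum(total_time_s),
    .groups = "drop")
  agg <- agg[order(agg$participant_id, agg$suture), ]
  sut <- sut[order(sut$participant_id, sut$suture), ]
  expect_equal(sut$total_time_s, agg$total_time_s, tolerance = 1e-9)
  expect_equal((1 - sut$s_eff_left) * sut$total_time_s, agg$w_left,
               tolerance = 1e-9)

  # efficiency is invariant under uniform time rescaling
  d2 <- d; d2$start_s <- d2$start_s * 2.5; d2$end_s <- d2$end_s * 2.5
  sut2 <- efficiency_table(as_annotation_dataset(d2), "suture")
  expect_equal(sut2$s_eff_left, sut$s_eff_left, tolerance = 1e-9)
  expect_equal(sut2$b_eff, sut$b_eff, tolerance = 1e-9)
})

test_that("hand-constructed efficiency cases are exact", {
  d <- make_dataset(list(list(
    participant_id = "E1", group = "expert", suture = 1,
    segment = "needle_transport",
    left = list(durations = c(5, 5), labels = c("idle", "move;needle")),
    right = list(durations = 10, labels = "transport;incision")
  )))
  e <- efficiency_table(d, "suture")
  expect_equal(e$s_eff_left, 0.5)
  expect_equal(e$s_eff_right, 1)
  expect_equal(e$b_eff, 0.5)
  expect_equal(e$total_time_s, 10)
})
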