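test_that("noise at p=0 is the identity and at p=1 changes every target", {
  d <- generate_dataset(small_config(2))
  d0 <- inject_target_noise(d, 0, seed = 99)
  expect_equal(as.data.frame(d0), as.data.frame(d))

  d1 <- inject_target_noise(d, 1, seed = 99)
  targeted <- !d$action %in% c("idle", "not_visible")
  expect_true(all(d1$target[targeted] != d$target[targeted]))
  expect_true(all(d1$target[targeted] %in% activity_targets()))
  expect_equal(d1$target[!targeted], d$target[!targeted])
  expect_equal(d1$action, d$action)  # actions never change
  expect_error(inject_target_noise(d, 1.2, seed = 1), "probability")
})

test_that("the switch probability is honoured in a Monte-Carlo binomial check", {
  n <- 10000
  d <- make_dataset(list(list(
    participant_id = "E1", group = "expert", suture = 1,
    segment = "needle_transport",
    left = list(durations = rep(1, n), labels = rep("move;needle", n)),
    right = list(durations = rep(1, n), labels = rep("grasp;thread", n))
  )))
  d5 <- inject_target_noise(d, 0.5, seed = 17)
  changed <- mean(d5$target != d$target)
  expect_equal(changed, 0.5, tolerance = 0.02)
})

test_that("target switching is deterministic given the seed and leaves efficiency untouched", {
  d <- generate_dataset(small_config(6))
  a <- inject_target_noise(d, 0.4, seed = 123)
  b <- inject_target_noise(d, 0.4, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- inject_target_noise(d, 0.4, seed = 124)
  expect_false(identical(a$target, c2$target))

  for (p in c(0.3, 1)) {
    noisy <- inject_target_noise(d, p, seed = 5)
    expect_identical(efficiency_table(noisy, "suture"),
                     efficiency_table(d, "suture"))
  }
  # the optional idle-relabel mode does perturb efficiency
  idled <- inject_target_noise(d, 0.5, seed = 5, mode = "idle")
  expect_gt(mean(efficiency_table(d, "suture")$s_eff_left),
            mean(efficiency_table(idled, "suture")$s_eff_left))
})

test_that("a small sweep is reproducible and returns the uncorrupted run at p=0", {
  d <- generate_dataset(synthetic_config(n_experts = 3, n_novices = 3,
                                         sutures_per_participant = 3,
                                         segments = segment_types()[1:2],
                                         seed = 4))
  sw1 <- noise_sweep(d, p_grid = c(0, 1), replicates = 2,
                     analyses = c("similarity_suture", "b_eff"), seed = 11)
  sw2 <- noise_sweep(d, p_grid = c(0, 1), replicates = 2,
                     analyses = c("similarity_suture", "b_eff"), seed = 11)
  expect_equal(as.data.frame(sw1), as.data.frame(sw2), tolerance = 1e-12)

  base <- similarity_table(d, "suture", hand = "left")
  fit <- suture_level_lmm(base, "difference")
  p0 <- sw1[sw1$p == 0 & sw1$analysis == "similarity_suture" & sw1$hand == "left", ]
  expect_equal(p0$estimate, fit$estimate, tolerance = 1e-9)
  expect_s3_class(attr(sw1, "survival"), "data.frame")
})

test_that("reduced vocabularies behave as the collapse dictates", {
  # all targets equal: full18 and actions_special6 give identical similarities
  seg <- function(pid, grp, labs, durs) {
    list(participant_id = pid, group = grp, suture = 1,
         segment = "needle_transport",
         left = list(durations = durs, labels = labs),
         right = list(durations = sum(durs), labels = "transport;needle"))
  }
  d <- make_dataset(list(
    seg("E1", "expert", c("move;needle", "hold_still;needle", "idle"), c(4, 2, 1)),
    seg("E2", "expert", c("move;needle", "hold_still;needle", "idle"), c(3, 3, 2)),
    seg("N1", "novice", c("move;needle", "idle"), c(2, 5)),
    seg("N2", "novice", c("grasp;needle", "idle"), c(4, 4))
  ))
  full <- similarity_table(d, "suture", hand = "left", vocabulary = "full18")
  coll <- similarity_table(d, "suture", hand = "left",
                           vocabulary = "actions_special6")
  expect_equal(full$mean_expert_sim, coll$mean_expert_sim, tolerance = 1e-9)
  expect_equal(full$difference, coll$difference, tolerance = 1e-9)

  # groups with identical compositions: zero difference in every variant
  d2 <- make_dataset(list(
    seg("E1", "expert", c("move;needle", "idle"), c(3, 1)),
    seg("E2", "expert", c("move;needle", "idle"), c(3, 1)),
    seg("N1", "novice", c("move;needle", "idle"), c(3, 1)),
    seg("N2", "novice", c("move;needle", "idle"), c(3, 1))
  ))
  for (voc in c("full18", "actions_special6", "actions_only4")) {
    st <- similarity_table(d2, "suture", hand = "left", vocabulary = voc)
    expect_equal(st$difference, rep(0, nrow(st)), tolerance = 1e-12)
  }
})

test_that("reduced-vocabulary reanalysis skips empty items and aborts past 50%", {
  d <- generate_dataset(small_config(3, n = 3, sutures = 3))
  res <- reduced_vocabulary_analysis(d, "actions_only4")
  expect_true(all(c("similarity", "lmm") %in% names(res)))
  expect_equal(nrow(res$lmm), 2)

  idle_seg <- function(pid, grp, sut) {
    list(participant_id = pid, group = grp, suture = sut,
         segment = "needle_transport",
         left = list(durations = 5, labels = "idle"),
         right = list(durations = 5, labels = "idle"))
  }
  mostly_idle <- make_dataset(c(
    lapply(1:3, function(s) idle_seg("E1", "expert", s)),
    lapply(1:3, function(s) idle_seg("N1", "novice", s))
  ))
  expect_error(reduced_vocabulary_analysis(mostly_idle, "actions_only4"),
               "no in-vocabulary time")
})
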