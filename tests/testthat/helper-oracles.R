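# Independent oracles and small fixture builders used across the suite.

# Build one hand's contiguous interval sequence from durations and labels.
# Labels are "action;target" strings or "idle"/"not_visible".
make_sequence <- function(durations, labels, start = 0) {
  at <- strsplit(labels, ";", fixed = TRUE)
  ends <- start + cumsum(durations)
  tibble::tibble(
    start_s = c(start, ends[-length(ends)]),
    end_s = ends,
    action = vapply(at, `[`, "", 1),
    target = vapply(at, function(x) if (length(x) > 1) x[2] else "none", "")
  )
}

# Assemble a validated dataset from per-(participant, suture, segment, hand)
# sequences given as a list of lists: list(list(participant_id=, group=,
# suture=, segment=, left=<durations/labels>, right=<...>), ...)
make_dataset <- function(specs) {
  rows <- lapply(specs, function(s) {
    dplyr::bind_rows(lapply(c("left", "right"), function(h) {
      seq <- make_sequence(s[[h]]$durations, s[[h]]$labels,
                           start = if (is.null(s$start)) 0 else s$start)
      tibble::tibble(
        participant_id = s$participant_id, group = s$group,
        handedness = "right", suture = s$suture, segment = s$segment,
        hand = h, seq
      )
    }))
  })
  as_annotation_dataset(dplyr::bind_rows(rows))
}

# A small deterministic two-per-group dataset with clearly separated groups.
toy_dataset <- function() {
  seg <- function(pid, grp, sut, main_label, np) {
    list(participant_id = pid, group = grp, suture = sut,
         segment = "needle_transport",
         left = list(durations = c(4, np, 3),
                     labels = c(main_label, "idle", main_label)),
         right = list(durations = c(5, np + 2),
                      labels = c("transport;needle", main_label)))
  }
  make_dataset(list(
    seg("E1", "expert", 1, "hold_still;incision", 1),
    seg("E1", "expert", 2, "hold_still;incision", 2),
    seg("E2", "expert", 1, "hold_still;incision", 1.5),
    seg("N1", "novice", 1, "move;tool", 4),
    seg("N1", "novice", 2, "move;tool", 5),
    seg("N2", "novice", 1, "move;tool", 4.5)
  ))
}

# Brute-force leave-own-participant-out group similarity: explicit double
# loop over vector pairs, independent of the package's pooled matrix code.
oracle_similarity_scores <- function(vectors) {
  labs <- attr(vectors, "vocabulary")$labels
  lvl <- attr(vectors, "level")
  m <- as.matrix(as.data.frame(vectors)[labs])
  n <- nrow(vectors)
  out <- vectors[c("participant_id", "group", "suture")]
  out$mean_expert_sim <- NA_real_; out$mean_novice_sim <- NA_real_
  for (i in seq_len(n)) {
    sims <- list(expert = c(), novice = c())
    for (j in seq_len(n)) {
      if (vectors$participant_id[j] == vectors$participant_id[i]) next
      if (lvl == "segment" && vectors$segment[j] != vectors$segment[i]) next
      cs <- sum(m[i, ] * m[j, ]) / (sqrt(sum(m[i, ]^2)) * sqrt(sum(m[j, ]^2)))
      sims[[vectors$group[j]]] <- c(sims[[vectors$group[j]]], cs)
    }
    out$mean_expert_sim[i] <- mean(sims$expert)
    out$mean_novice_sim[i] <- mean(sims$novice)
  }
  out$difference <- out$mean_expert_sim - out$mean_novice_sim
  out
}

# Timeline-sampling efficiency oracle: sample each segment at 1 ms midpoints
# and count grid points. Returns per-suture or per-segment records.
oracle_efficiency <- function(dataset, level = "suture", step = 1e-3) {
  d <- tibble::as_tibble(dataset)
  keys <- interaction(d$participant_id, d$suture, d$segment, drop = TRUE)
  per_seg <- dplyr::bind_rows(lapply(split(d, keys), function(s) {
    t0 <- min(s$start_s); t1 <- max(s$end_s)
    grid <- seq(t0 + step / 2, t1, by = step)
    state <- function(h) {
      hs <- s[s$hand == h, ]; hs <- hs[order(hs$start_s), ]
      idx <- findInterval(grid, hs$start_s)
      !(hs$action[pmax(idx, 1)] %in% c("idle", "not_visible"))
    }
    pl <- state("left"); pr <- state("right")
    tibble::tibble(
      participant_id = s$participant_id[1], group = s$group[1],
      suture = s$suture[1], segment = s$segment[1],
      n_grid = length(grid), n_left = sum(pl), n_right = sum(pr),
      n_both = sum(pl & pr), n_ints = nrow(s)
    )
  }))
  if (level == "suture") {
    per_seg <- dplyr::summarise(
      dplyr::group_by(per_seg, participant_id, group, suture),
      dplyr::across(dplyr::all_of(c("n_grid", "n_left", "n_right", "n_both",
                                    "n_ints")), sum),
      .groups = "drop")
  }
  dplyr::mutate(per_seg,
                s_eff_left = n_left / n_grid,
                s_eff_right = n_right / n_grid,
                b_eff = n_both / n_grid)
}

# small fast synthetic cohorts for property tests
small_config <- function(seed, n = 2, sutures = 2, ...) {
  synthetic_config(n_experts = n, n_novices = n,
                   sutures_per_participant = sutures,
                   segments = segment_types()[1:2], seed = seed, ...)
}
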