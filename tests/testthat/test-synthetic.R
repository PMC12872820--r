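test_that("generator_config enforces the time-scale and separability invariants", {
  expect_error(generator_config(3, mean_dwell_steps = 5, escape_steps = 2),
               "separation of time scales")
  expect_error(generator_config(2, centers = matrix(c(0, 0, 10, 0), 2, 2,
                                                    byrow = TRUE),
                                D = 2, noise_sd = 5),
               "6 \\* noise_sd")
  bad_tm <- matrix(c(0, 0.5, 1, 0), 2, 2, byrow = TRUE)
  expect_error(generator_config(2, D = 2, transition_matrix = bad_tm,
                                centers = matrix(c(0, 0, 900, 0), 2, 2,
                                                 byrow = TRUE),
                                noise_sd = 10),
               "sum to 1")
  cfg <- generator_config(3, seed = 9)
  expect_true(all(rowSums(cfg$transition_matrix) == 1))
  expect_true(all(diag(cfg$transition_matrix) == 0))
  expect_gte(cfg$min_separation, 6 * cfg$noise_sd)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- preset_config("easy-3-state", seed = 123, T_points = 400)$config
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$session$values, b$session$values)
  expect_identical(a$ground_truth$state_labels, b$ground_truth$state_labels)
  # a different seed changes the realization
  cfg2 <- preset_config("easy-3-state", seed = 124, T_points = 400)$config
  expect_false(identical(simulate_session(cfg2)$session$values,
                         a$session$values))
})

test_that("m = 1 with zero noise is constant and collapses under the union pipeline", {
  cfg <- generator_config(1, D = 2, T_points = 50,
                          centers = matrix(c(100, -40), 1, 2),
                          noise_sd = 0, mean_dwell_steps = 100,
                          escape_steps = 2, seed = 5)
  sim <- simulate_session(cfg)
  expect_equal(unname(unique(sim$session$values)),
               matrix(c(100, -40), 1, 2))
  net <- contract(build_stknn(sim$session, k = 3, knn_rule = "union"), 3)
  expect_equal(n_nodes(net), 1L)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(length(sim$ground_truth$visit_sequence), 1L)
})

test_that("deterministic 2-state alternation realizes off-diagonal counts only", {
  tm <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  cfg <- generator_config(2, D = 2, T_points = 800,
                          centers = matrix(c(-500, 0, 500, 0), 2, 2,
                                           byrow = TRUE),
                          transition_matrix = tm, mean_dwell_steps = 100,
                          escape_steps = 2, noise_sd = 20, seed = 8)
  sim <- simulate_session(cfg)
  gt <- sim$ground_truth
  vs <- gt$visit_sequence
  expect_true(all(abs(diff(vs)) == 1))   # strict alternation
  expect_equal(sum(diag(gt$transition_counts)), 0L)
  expect_equal(sum(gt$transition_counts), length(vs) - 1L)
  # realized counts consistent with the visit sequence
  recount <- matrix(0L, 2, 2)
  for (i in seq_len(length(vs) - 1)) {
    recount[vs[i], vs[i + 1]] <- recount[vs[i], vs[i + 1]] + 1L
  }
  expect_identical(gt$transition_counts, recount)
})

test_that("dwell/escape labels alternate and occupancy approaches stationarity", {
  cfg <- preset_config("easy-3-state", seed = 31, T_points = 12000)$config
  sim <- simulate_session(cfg)
  gt <- sim$ground_truth
  runs <- rle(ifelse(is.na(gt$state_labels), -1L, gt$state_labels))
  dwell_runs <- runs$values > 0
  expect_false(any(diff(which(dwell_runs)) == 0))
  # a cyclic uniform chain with equal mean dwell: stationary occupancy 1/3;
  # tolerance 3 standard errors of the visit-count estimate
  occ <- table(factor(gt$state_labels, levels = 1:3)) / sum(!is.na(gt$state_labels))
  n_vis <- length(gt$visit_sequence)
  se <- sqrt(1 / 3 * 2 / 3 / n_vis)
  expect_true(all(abs(occ - 1 / 3) < 3 * se + 0.02))
})

test_that("escape steps are measurably faster than within-dwell drift", {
  cfg <- preset_config("easy-3-state", seed = 17)$config
  sim <- simulate_session(cfg)
  lab <- sim$ground_truth$state_labels
  steps <- sqrt(rowSums(diff(sim$session$values)^2))
  within <- !is.na(lab[-length(lab)]) & !is.na(lab[-1]) &
    lab[-length(lab)] == lab[-1]
  crossing <- is.na(lab[-length(lab)]) | is.na(lab[-1])
  ratio <- stats::median(steps[within]) / stats::median(steps[crossing])
  expect_lt(ratio, 0.8)
})

test_that("coupled_annotation maps state occupancy to interval ratings", {
  # noise 0, one state per interval: rating equals that state's level
  labels <- rep(c(1L, 2L), each = 60)   # dt 0.5 -> two 30 s intervals
  session <- time_series_session(matrix(0, 120, 1), dt = 0.5)
  gt <- structure(list(state_labels = labels, visit_sequence = c(1L, 2L),
                       transition_counts = matrix(c(0L, 1L, 0L, 0L), 2, 2,
                                                  byrow = TRUE), m = 2L),
                  class = "synthetic_ground_truth")
  tr <- coupled_annotation(gt, session, per_state_level = c(1, 5),
                           interval_length = 30, noise_sd = 0)
  expect_equal(tr$ratings, c(1, 5))

  # interval straddling two states equally: midpoint rating
  labels2 <- rep(c(1L, 2L), each = 30)   # switch at 15 s inside one interval
  session2 <- time_series_session(matrix(0, 60, 1), dt = 0.5)
  gt2 <- gt; gt2$state_labels <- labels2
  tr2 <- coupled_annotation(gt2, session2, per_state_level = c(1, 5),
                            interval_length = 30, noise_sd = 0)
  expect_equal(tr2$ratings, 3)

  # random placement: rating equals the occupancy-weighted mean
  set.seed(61)
  cfg <- preset_config("easy-3-state", seed = 77, T_points = 900)$config
  sim <- simulate_session(cfg)
  levels <- c(1, 3, 5)
  tr3 <- coupled_annotation(sim$ground_truth, sim$session, levels,
                            interval_length = 30, noise_sd = 0)
  eff <- temporalmapper:::fill_forward(sim$ground_truth$state_labels)
  expected <- tapply(levels[eff],
                     rep(seq_along(tr3$ratings),
                         each = 60)[seq_len(900)], mean)
  expect_equal(unname(tr3$ratings), unname(as.vector(expected)))
  # ratings stay within the scale
  expect_true(all(tr3$ratings >= 1 & tr3$ratings <= 5))
})

test_that("recovery_score is 1 for a perfect partition and ~0 for random labels", {
  labels <- rep(c(1L, 2L), each = 50)
  gt <- structure(list(state_labels = labels, visit_sequence = c(1L, 2L),
                       transition_counts = matrix(c(0L, 1L, 0L, 0L), 2, 2,
                                                  byrow = TRUE), m = 2L),
                  class = "synthetic_ground_truth")
  net <- manual_network(nodes = list(1:50, 51:100),
                        edges = list(from = 1, to = 2))
  rs <- recovery_score(net, gt)
  expect_equal(rs$ari, 1)
  expect_equal(rs$edge_recall, 1)

  # chance-corrected: random membership scores near zero
  set.seed(91)
  big_labels <- sample(1:2, 2000, replace = TRUE)
  gt_big <- structure(list(state_labels = big_labels,
                           visit_sequence = c(1L, 2L),
                           transition_counts = matrix(0L, 2, 2), m = 2L),
                      class = "synthetic_ground_truth")
  shuffled <- sample(2000)
  net_big <- manual_network(nodes = list(sort(shuffled[1:1000]),
                                         sort(shuffled[1001:2000])),
                            edges = list(from = 1, to = 2))
  expect_lt(abs(recovery_score(net_big, gt_big)$ari), 0.05)
})

test_that("simulated pipeline recovers the planted 3-state structure on one seed", {
  ps <- preset_config("easy-3-state", seed = 1)
  sim <- simulate_session(ps$config, "cal")
  net <- contract(build_stknn(sim$session, k = 7), 3)
  rs <- recovery_score(net, sim$ground_truth)
  expect_gte(rs$ari, 0.9)
  expect_equal(rs$edge_recall, 1)
})
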