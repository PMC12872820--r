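test_that("spearman_cor: perfect monotone, reversed, and the rank-discordant quad", {
  x <- c(2, 5, 9, 14, 20)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  sc <- spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(sc$rho, 0.6)
  expect_equal(sc$method, "permutation")
})

test_that("spearman_cor agrees with cor.test on rho and exact p", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    x <- rnorm(n); y <- rnorm(n)
    sc <- spearman_cor(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(sc$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(sc$p, ct$p.value, tolerance = 1e-9)
  }
  # large-n t-approximation path
  set.seed(22)
  x <- rnorm(30); y <- x + rnorm(30, 0, 2)
  sc <- spearman_cor(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  expect_equal(sc$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(sc$method, "t-approximation")
})

test_that("spearman_cor is invariant under strictly monotone transforms", {
  set.seed(23)
  x <- rnorm(12); y <- rnorm(12)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
  expect_equal(spearman_cor(x, 3 * y - 100)$rho, base$rho)
  expect_equal(spearman_cor(rank(x), y^3 + y)$rho,
               spearman_cor(x, y)$rho)
})

test_that("spearman_cor flags constant input instead of propagating NaN", {
  sc <- spearman_cor(rep(1, 5), rnorm(5))
  expect_false(sc$defined)
  expect_true(is.na(sc$rho))
  expect_error(spearman_cor(1:3, 1:4), "equal length")
  expect_error(spearman_cor(1:2, 2:1), "n >= 3")
})

test_that("signed-rank: sign-symmetric vectors give z = 0, p = 1 exactly", {
  wt <- wilcoxon_signed_rank(c(-0.2, 0.2, -0.5, 0.5, -0.9, 0.9))
  expect_equal(wt$z, 0)
  expect_equal(wt$p, 1)
  expect_equal(wt$method, "exact")
})

test_that("signed-rank: all-positive n = 16 gives the extreme exact p", {
  coeffs <- seq(0.1, 1.6, by = 0.1)
  wt <- wilcoxon_signed_rank(coeffs, exact = TRUE)
  expect_equal(wt$statistic, 16 * 17 / 2)
  expect_equal(wt$p, 2 * 2^-16)
  expect_gt(wt$z, 3)
})

test_that("signed-rank exact p matches full 2^n sign enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5) * 0.1)$p,
               oracle_signed_rank_p(c(1, 2, 3, 4, 5) * 0.1))
  set.seed(31)
  for (rep in 1:8) {
    x <- round(rnorm(sample(5:11, 1)), 2)
    x <- x[x != 0]
    if (length(x) < 5) next
    expect_equal(wilcoxon_signed_rank(x)$p, oracle_signed_rank_p(x))
  }
})

test_that("signed-rank agrees with wilcox.test statistic and normal p", {
  set.seed(32)
  x <- rnorm(20, 0.3)
  wt <- wilcoxon_signed_rank(x, exact = FALSE)
  ref <- stats::wilcox.test(x, mu = 0, exact = FALSE, correct = TRUE)
  expect_equal(wt$statistic, unname(ref$statistic))
  expect_equal(wt$p, ref$p.value, tolerance = 1e-12)
})

test_that("exact and normal-approximation p agree within 0.02 at n = 16", {
  set.seed(33)
  for (rep in 1:25) {
    x <- rnorm(16, mean = runif(1, -0.3, 0.3))
    x <- x[x != 0]
    p_exact <- wilcoxon_signed_rank(x, exact = TRUE)$p
    p_norm <- wilcoxon_signed_rank(x, exact = FALSE)$p
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("signed-rank drops zeros and flags degenerate input", {
  wt <- wilcoxon_signed_rank(c(0, 0, 0.1, 0.2, -0.3, 0.4, 0.5))
  expect_equal(wt$n, 5L)
  expect_equal(wt$n_zero, 2L)
  expect_false(wilcoxon_signed_rank(rep(0, 6))$defined)
  expect_error(wilcoxon_signed_rank(c(0, 0, 1, 2, 3)), "at least 5")
})

test_that("within_session_analysis correlates sizes with overlays and tests the group", {
  set.seed(44)
  make_tab <- function(sid, rho_sign = 1) {
    n <- sample(6:10, 1)
    size <- sample(10:100, n)
    data.frame(session_id = sid, size = size,
               warmth = rho_sign * size + rnorm(n, 0, 5),
               noise = rnorm(n))
  }
  tabs <- lapply(1:8, function(i) make_tab(paste0("s", i)))
  names(tabs) <- paste0("s", 1:8)
  res <- within_session_analysis(tabs, c("warmth", "noise"))
  w <- res$correlations[res$correlations$variable == "warmth", ]
  expect_equal(nrow(w), 8L)
  expect_true(all(w$rho > 0.8))
  grp <- res$group[res$group$variable == "warmth", ]
  expect_gt(grp$z, 0)
  expect_lt(grp$p, 0.05)

  # constant overlays define no coefficient and are excluded with a reason
  tabs_const <- lapply(tabs, function(tb) { tb$warmth <- 3; tb })
  expect_warning(res2 <- within_session_analysis(tabs_const, "warmth"),
                 "group test skipped")
  expect_equal(nrow(res2$correlations), 0L)
  expect_true(all(res2$excluded$reason == "zero rank variance"))

  # sessions with < 3 nodes contribute no coefficient
  tabs3 <- tabs
  tabs3[["s1"]] <- tabs3[["s1"]][1:2, ]
  res3 <- within_session_analysis(tabs3, "warmth")
  expect_equal(nrow(res3$correlations[res3$correlations$variable == "warmth", ]), 7L)
  expect_true("fewer than 3 nodes" %in% res3$excluded$reason)
})

test_that("between_session_analysis recovers planted signs and excludes pairwise", {
  set.seed(55)
  n <- 16
  rupture <- runif(n, 1, 5)
  summaries <- data.frame(
    session_id = paste0("s", 1:n),
    mean_node_size = 100 - 15 * rupture + rnorm(n, 0, 3),
    mean_loop_length = 2 + rupture + rnorm(n, 0, 0.3),
    mean_rupture = rupture
  )
  res <- between_session_analysis(summaries, "rupture")
  rs <- res[res$feature == "mean_node_size", ]
  rl <- res[res$feature == "mean_loop_length", ]
  expect_lt(rs$rho, -0.5)
  expect_lt(rs$p, 0.05)
  expect_gt(rl$rho, 0.5)
  expect_equal(rs$n_sessions, 16L)

  # undefined loop length sessions drop pairwise
  summaries$mean_loop_length[1:3] <- NA
  res2 <- between_session_analysis(summaries, "rupture")
  expect_equal(res2$n_sessions[res2$feature == "mean_loop_length"], 13L)

  # identical feature across sessions: flagged undefined
  summaries$mean_node_size <- 50
  res3 <- between_session_analysis(summaries, "rupture")
  expect_false(res3$defined[res3$feature == "mean_node_size"])

  expect_error(between_session_analysis(summaries[1:3, ], "rupture"),
               "need >= 4")
})
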