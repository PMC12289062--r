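test_that("monotonicity hits its closed-form values", {
  expect_equal(monotonicity(score_map("x", c(a = 3, b = 2, c = 1))), 1)
  expect_equal(monotonicity(score_map("x", c(a = 1, b = 1, c = 1))), 0)
  # N=3, group sizes {2,1}: (1 - 2/6)^2
  expect_equal(monotonicity(score_map("x", c(a = 2, b = 2, c = 1))), 4 / 9)
  expect_error(monotonicity(score_map("x", c(a = 1))), "at least 2")
})

test_that("monotonicity is invariant under monotone transforms and shrinks on merges", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    scores <- setNames(sample(1:8, n, replace = TRUE), paste0("v", 1:n))
    m <- monotonicity(score_map("x", scores))
    expect_gte(m, 0); expect_lte(m, 1)
    expect_equal(monotonicity(score_map("x", exp(scores))), m)
    expect_equal(monotonicity(score_map("x", rank(scores, ties.method = "min"))), m)
    # merging two adjacent levels never increases M
    if (length(unique(scores)) >= 2) {
      lv <- sort(unique(scores))
      merged <- scores
      merged[merged == lv[2]] <- lv[1]
      expect_lt(monotonicity(score_map("x", merged)), m + 1e-12)
    }
  }
})

test_that("kendall tau matches enumerated and oracle pair counts", {
  expect_equal(kendall_tau(1:10, 1:10, "tau_a"), 1)
  expect_equal(kendall_tau(1:10, 10:1, "tau_a"), -1)
  # 6 pairs: 5 concordant, 1 discordant
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4), "tau_a"), 2 * 4 / 12)

  set.seed(7)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    x <- sample(1:10, n, replace = TRUE) # heavy ties
    y <- x + sample(-2:2, n, replace = TRUE)
    expect_equal(kendall_tau(x, y, "tau_a"), brute_kendall(x, y, "tau_a"))
    expect_equal(kendall_tau(x, y, "tau_b"), brute_kendall(x, y, "tau_b"))
    # cross-check tau-b against the standard library implementation
    expect_equal(kendall_tau(x, y, "tau_b"),
                 suppressWarnings(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
  }
})

test_that("tau variants agree on tie-free data and validate inputs", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(kendall_tau(x, y, "tau_a"), kendall_tau(x, y, "tau_b"))
  }
  expect_error(kendall_tau(1:4, 1:5), "equal length")
  expect_error(kendall_tau(c(1, 1, 1), c(1, 2, 3), "tau_b"), "constant")
})

test_that("ccdf and rank frequency describe the dense ranking", {
  distinct <- score_map("x", setNames(10:1, letters[1:10]))
  cc <- ccdf(distinct)
  expect_equal(cc$ccdf, (10:1) / 10) # straight diagonal decay
  rf <- rank_frequency(distinct)
  expect_true(all(rf$count == 1))

  tied <- score_map("x", setNames(rep(5, 6), letters[1:6]))
  expect_equal(ccdf(tied), data.frame(rank_level = 1, ccdf = 1))
  expect_equal(rank_frequency(tied)$count, 6)

  set.seed(11)
  for (i in 1:20) {
    s <- setNames(sample(1:6, 30, replace = TRUE), paste0("v", 1:30))
    sm <- score_map("x", s)
    expect_equal(sum(rank_frequency(sm)$count), 30)
    expect_true(all(diff(ccdf(sm)$ccdf) <= 0))
    expect_equal(ccdf(sm)$ccdf[1], 1)
    # merging two adjacent groups never makes the curve drop earlier
    lv <- sort(unique(s))
    if (length(lv) >= 2) {
      merged <- s; merged[merged == lv[2]] <- lv[1]
      c1 <- ccdf(sm)$ccdf
      c2 <- ccdf(score_map("x", merged))$ccdf
      expect_true(all(c2 >= c1[seq_along(c2)] - 1e-12))
    }
  }
})

test_that("karate rank counts follow the shell structure", {
  g <- karate_graph()
  rf <- rank_frequency(baseline_scores(g, "ks"))
  expect_equal(nrow(rf), 4) # Ksmax levels
  expect_equal(sum(rf$count), 34)
})

test_that("compare_methods produces a coherent in-range report", {
  g <- synth_graph("er", 30, p = 0.15, seed = 21)
  cfg <- sir_config(beta = 0.3, gamma = 1, reps = 40, seed = 2)
  rep1 <- compare_methods(g, c("KTD", "dc", "ks"), cfg)
  expect_equal(rep1$method, c("KTD", "dc", "ks"))
  expect_true(all(rep1$monotonicity >= 0 & rep1$monotonicity <= 1))
  expect_true(all(abs(rep1$tau_a) <= 1) && all(abs(rep1$tau_b) <= 1))
  # reproducible end to end under a fixed seed
  rep2 <- compare_methods(g, c("KTD", "dc", "ks"), cfg)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  expect_error(compare_methods(g, "dc", sir_config(beta = 0)), "beta > 0")
})

test_that("fully symmetric graphs defeat every method equally", {
  g <- synth_graph("clique", 7)
  cfg <- sir_config(beta = 0.3, gamma = 1, reps = 20, seed = 6)
  rep1 <- compare_methods(g, c("KTD", "dc", "ks"), cfg)
  expect_true(all(rep1$monotonicity == 0))
})
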