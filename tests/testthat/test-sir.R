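test_that("epidemic threshold matches closed forms", {
  # k-regular: <k>/<k^2> = 1/k
  expect_equal(epidemic_threshold(synth_graph("cycle", 8)), 1 / 2)
  expect_equal(epidemic_threshold(synth_graph("clique", 6)), 1 / 5)
  # star with n leaves: <k> = 2n/(n+1), <k^2> = (n^2+n)/(n+1) = n
  for (n in c(4, 9, 25)) {
    expect_equal(epidemic_threshold(synth_graph("star", n + 1)), 2 / (n + 1))
  }
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  expect_error(epidemic_threshold(g0), "edgeless")
})

test_that("degenerate transmission limits are exact", {
  set.seed(1)
  for (i in 1:10) {
    g <- synth_graph("er", 30, p = 0.12, seed = 100 + i)
    run <- sir_run(g, sources = "1", sir_config(beta = 0, gamma = 0.5, seed = i))
    expect_equal(run$final_recovered, 1)
  }
  # beta=1, gamma=1 on a connected graph is a BFS wave reaching everyone
  for (i in 1:10) {
    g <- synth_graph("ba", 40, m = 2, seed = 200 + i) # BA graphs are connected
    run <- sir_run(g, sources = "3", sir_config(beta = 1, gamma = 1, seed = i))
    expect_equal(run$final_recovered, 40)
    # wave cannot outrun graph eccentricity
    ecc <- max(igraph::distances(g, v = "3"))
    expect_lte(run$steps_to_absorption, ecc + 1)
  }
})

test_that("every run conserves N and moves monotonically", {
  for (i in 1:10) {
    g <- synth_graph("er", 40, p = 0.1, seed = 300 + i)
    run <- sir_run(g, sources = c("1", "2"),
                   sir_config(beta = 0.3, gamma = 0.4, seed = i))
    ps <- run$per_step
    expect_true(all(ps$S + ps$I + ps$R == 40))
    expect_true(all(diff(ps$R) >= 0))
    expect_true(all(diff(ps$S) <= 0))
    expect_equal(ps$I[nrow(ps)], 0)
    expect_equal(run$final_recovered, ps$R[nrow(ps)])
  }
  expect_error(sir_run(synth_graph("path", 3), character(0)), "non-empty")
  expect_error(sir_run(synth_graph("path", 3), "nope"), "unknown source")
})

test_that("single-edge mean outbreak matches the 1+beta closed form", {
  g <- synth_graph("path", 2)
  beta <- 0.37
  cfg <- sir_config(beta = beta, gamma = 1, reps = 20000, seed = 77)
  sp <- spreading_power(g, cfg)
  se <- sqrt(beta * (1 - beta) / cfg$reps)
  expect_true(all(abs(sp$mean_final_R - (1 + beta)) < 3 * se))
})

test_that("spreading power is reproducible and order-independent in expectation", {
  g <- synth_graph("er", 25, p = 0.15, seed = 9)
  cfg <- sir_config(beta = 0.2, gamma = 1, reps = 50, seed = 123)
  a <- spreading_power(g, cfg)
  b <- spreading_power(g, cfg)
  expect_identical(a$mean_final_R, b$mean_final_R)
  expect_true(all(a$mean_final_R >= 1 & a$mean_final_R <= 25))
})

test_that("clique symmetry bounds Monte-Carlo spread between nodes", {
  g <- synth_graph("clique", 8)
  cfg <- sir_config(beta = 0.25, gamma = 1, reps = 3000, seed = 5)
  sp <- spreading_power(g, cfg)
  sds <- 8 / sqrt(cfg$reps) # crude bound: outbreak size sd < N
  expect_lt(max(sp$mean_final_R) - min(sp$mean_final_R), 3 * sds)
})

test_that("mean outbreak size grows with beta at fixed gamma", {
  g <- synth_graph("ba", 60, m = 2, seed = 17)
  betas <- c(0.05, 0.2, 0.5, 0.9)
  means <- vapply(betas, function(b) {
    sp <- spreading_power(g, sir_config(beta = b, gamma = 1, reps = 60, seed = 11))
    mean(sp$mean_final_R)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("top-k spread curves are monotone and hit their limits", {
  g <- synth_graph("ba", 50, m = 2, seed = 23)
  flat <- topk_spread_curve(g, seeds = c("1", "2", "3"),
                            sir_config(beta = 0, gamma = 0.5, reps = 30, seed = 4))
  expect_true(all(diff(flat$mean_R) >= 0))
  expect_equal(flat$mean_R[nrow(flat)], 3)

  wave <- topk_spread_curve(g, seeds = "1",
                            sir_config(beta = 1, gamma = 1, reps = 5, seed = 4))
  expect_equal(wave$mean_R[nrow(wave)], 50)

  # a superset of seeds dominates pointwise in expectation
  cfgA <- sir_config(beta = 0.15, gamma = 0.5, reps = 400, seed = 8)
  cA <- topk_spread_curve(g, seeds = as.character(1:6), cfgA)
  cB <- topk_spread_curve(g, seeds = as.character(1:3), cfgA)
  len <- min(nrow(cA), nrow(cB))
  expect_true(all(cA$mean_R[seq_len(len)] >= cB$mean_R[seq_len(len)] - 1.5))
  expect_gt(cA$mean_R[len], cB$mean_R[len])
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sir_config(beta = 1.2), "beta")
  expect_error(sir_config(gamma = 0), "gamma")
  expect_error(sir_config(reps = 0), "reps")
})
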