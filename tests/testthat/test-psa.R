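fx <- builtin_fixture()

# central moments of the matched distributions, for moment-recovery checks
beta_moments <- function(a, b) {
  raw <- function(k) prod((a + seq_len(k) - 1) / (a + b + seq_len(k) - 1))
  m <- raw(1)
  v <- raw(2) - m^2
  mu4 <- raw(4) - 4 * m * raw(3) + 6 * m^2 * raw(2) - 3 * m^4
  list(mean = m, var = v, mu4 = mu4)
}
gamma_moments <- function(shape, scale) {
  v <- shape * scale^2
  list(mean = shape * scale, var = v, mu4 = v^2 * (3 + 6 / shape))
}
expect_moments_within_3se <- function(x, mom) {
  n <- length(x)
  expect_lt(abs(mean(x) - mom$mean), 3 * sqrt(mom$var / n))
  se_var <- sqrt((mom$mu4 - mom$var^2 * (n - 3) / (n - 1)) / n)
  expect_lt(abs(stats::var(x) - mom$var), 3 * se_var)
}

test_that("moment matching recovers the stated closed forms", {
  g <- moment_match("gamma", 100, 0.1)
  expect_equal(g$shape, 100)
  expect_equal(g$scale, 1)
  b <- moment_match("beta", 0.5, 0.1)
  expect_equal(b$shape1, 49.5)
  expect_equal(b$shape2, 49.5)
  # first two moments reproduce the inputs
  for (m in c(0.1, 0.5, 0.93)) {
    p <- moment_match("beta", m, 0.1)
    expect_equal(p$shape1 / (p$shape1 + p$shape2), m, tolerance = 1e-10)
    v <- p$shape1 * p$shape2 /
      ((p$shape1 + p$shape2)^2 * (p$shape1 + p$shape2 + 1))
    expect_equal(v, (0.1 * m)^2, tolerance = 1e-10)
  }
  expect_error(moment_match("beta", 0.9, 1.0), "infeasible variance")
  expect_error(moment_match("beta", 1.2, 0.1), "in \\(0, 1\\)")
  expect_error(moment_match("gamma", -1, 0.1), "> 0")
})

test_that("sampled inputs are valid, seed-reproducible, and degenerate at cv -> 0", {
  set.seed(11)
  a <- sample_inputs(fx)
  set.seed(11)
  b <- sample_inputs(fx)
  expect_identical(a, b)
  expect_s3_class(validate_inputs(a), "art_inputs")
  expect_true(all(unlist(a$rates) >= 0 & unlist(a$rates) <= 1))
  expect_true(all(a$costs$out_of_pocket >= 0))
  # zero-mean components stay zero
  expect_equal(a$costs$medicare_rebate[a$costs$item == "pgta"], 0)

  set.seed(12)
  tight <- sample_inputs(fx, prob_cv = 1e-8, cost_cv = 1e-8)
  expect_equal(tight$rates, fx$rates, tolerance = 1e-4)
  expect_equal(tight$costs$out_of_pocket, fx$costs$out_of_pocket,
               tolerance = 1e-4)
})

test_that("sample moments match the matched beta distribution", {
  set.seed(3)
  n <- 10000
  for (m in c(0.325, 0.93, 0.014)) {
    par <- moment_match("beta", m, 0.1)
    expect_moments_within_3se(stats::rbeta(n, par$shape1, par$shape2),
                              beta_moments(par$shape1, par$shape2))
  }
  par <- moment_match("gamma", 11720, 0.1)
  expect_moments_within_3se(stats::rgamma(n, par$shape, scale = par$scale),
                            gamma_moments(par$shape, par$scale))
})

test_that("the PSA is reproducible and collapses to the deterministic model", {
  p1 <- run_psa(fx, ages = 40:42, n_replicates = 200, seed = 7)
  p2 <- run_psa(fx, ages = 40:42, n_replicates = 200, seed = 7)
  expect_identical(p1$effect, p2$effect)
  expect_identical(p1$cost, p2$cost)

  tiny <- run_psa(fx, ages = c(35, 45), n_replicates = 1, seed = 5,
                  prob_cv = 1e-8, cost_cv = 1e-8)
  for (age in c(35, 45)) {
    for (strat in c("standard", "pgta", "donor")) {
      o <- strategy_outcome(strat, age, fx)
      expect_equal(tiny$effect[1, as.character(age), strat], o$clbr,
                   tolerance = 1e-4, ignore_attr = TRUE)
      expect_equal(tiny$cost[1, as.character(age), strat],
                   o$cost[["societal"]], tolerance = 1e-4, ignore_attr = TRUE)
    }
  }
})

test_that("one PSA replicate equals the model rebuilt from the same sampled inputs", {
  set.seed(99)
  drawn <- sample_inputs(fx)
  psa <- run_psa(fx, ages = 41, n_replicates = 1, seed = 99)
  for (strat in ART_STRATEGIES) {
    o <- strategy_outcome(strat, 41, drawn)
    expect_equal(psa$effect[1, "41", strat], o$clbr, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(psa$cost[1, "41", strat], o$cost[["societal"]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("percentile intervals follow the linear-interpolation convention", {
  expect_equal(percentile_ci(rep(4.2, 10)), c(4.2, 4.2))
  expect_equal(percentile_ci(1:1000), c(25.975, 975.025))
  expect_error(percentile_ci(numeric(0)), "empty")
})

test_that("deterministic increments lie inside the PSA percentile interval", {
  psa <- run_psa(fx, n_replicates = 2000, seed = 1)
  det <- cost_effectiveness_table(fx)
  for (i in seq_len(nrow(det))) {
    d <- artcea:::psa_deltas(psa, det$age[i], det$alternative[i])
    ci_c <- percentile_ci(d$delta_cost)
    ci_e <- percentile_ci(d$delta_effect)
    expect_gte(det$delta_cost[i], ci_c[1])
    expect_lte(det$delta_cost[i], ci_c[2])
    expect_gte(det$delta_effect[i], ci_e[1])
    expect_lte(det$delta_effect[i], ci_e[2])
  }
})

test_that("the CE plane has one row per replicate with the stated orientation", {
  psa <- run_psa(fx, ages = 45, n_replicates = 3, seed = 2)
  pl <- ce_plane(psa, 45, "social_freezing")
  expect_equal(nrow(pl), 3)
  expect_named(pl, c("replicate", "delta_effect", "delta_cost"))
  expect_error(ce_plane(psa, 45, "standard"), "differ from standard")

  big <- run_psa(fx, ages = 45, n_replicates = 1000, seed = 3)
  pts <- ce_plane(big, 45, "social_freezing")
  expect_gt(mean(pts$delta_effect > 0), 0.5) # majority more effective
  # summary quadrant shares agree with the raw points
  sm <- psa_summary(big)
  row <- sm[sm$alternative == "social_freezing", ]
  expect_equal(row$frac_dominant,
               mean(pts$delta_effect > 0 & pts$delta_cost < 0))
})

test_that("cost-effectiveness probability is the net-monetary-benefit rule", {
  # hand-built two-replicate set: dE = 0.1 with dC = 1,000 and 10,000
  dn <- list(NULL, "40", ART_STRATEGIES)
  eff <- array(NA_real_, c(2, 1, 4), dimnames = dn)
  cst <- array(NA_real_, c(2, 1, 4), dimnames = dn)
  eff[, 1, "standard"] <- 0.2; cst[, 1, "standard"] <- 5000
  eff[, 1, "pgta"] <- 0.3; cst[, 1, "pgta"] <- c(6000, 15000)
  toy <- structure(list(effect = eff, cost = cst, ages = 40,
                        perspective = "societal", n_replicates = 2, seed = 1,
                        prob_cv = 0.1, cost_cv = 0.1), class = "art_psa")
  # NMB at 50,000: 5,000 - 1,000 > 0 but 5,000 - 10,000 < 0 -> half the draws
  expect_equal(prob_cost_effective(toy, 50000)$probability, 0.5)
  expect_equal(prob_cost_effective(toy, 20000)$probability, 0.5)
  expect_equal(prob_cost_effective(toy, 110000)$probability, 1)
  expect_equal(prob_cost_effective(toy, 0)$probability, 0) # all cost-increasing
  # all-dominant draws are cost-effective at any threshold
  cst[, 1, "pgta"] <- c(4000, 4500)
  toy$cost <- cst
  expect_equal(prob_cost_effective(toy, 0)$probability, 1)
  expect_error(prob_cost_effective(toy, -5), ">= 0")
})

test_that("acceptability is non-decreasing in WTP when all effect draws are positive", {
  psa <- run_psa(fx, ages = 45, n_replicates = 500, seed = 4)
  d <- artcea:::psa_deltas(psa, 45, "social_freezing")
  expect_true(all(d$delta_effect > 0))
  tab <- ceac(psa, wtp_grid = seq(0, 100000, by = 5000))
  probs <- tab$probability[tab$alternative == "social_freezing"]
  expect_true(all(diff(probs) >= 0))
})
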