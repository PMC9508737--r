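# Probabilistic sensitivity analysis. Every probability parameter gets a beta
# distribution and every nonzero cost component a gamma distribution, moment-
# matched to the point estimate with a coefficient of variation (default 0.10
# for both; the sources publish no standard errors). Draws are independent
# across parameters and shared across strategies within a replicate (common
# random numbers), so incremental pairs are coherent.

#' Moment-match a beta or gamma distribution
#'
#' Returns the distribution whose first two moments equal `mean` and
#' `(cv * mean)^2`. Beta: `alpha = m (m(1-m)/v - 1)`, `beta = (1-m) (m(1-m)/v
#' - 1)`; gamma: `shape = 1/cv^2`, `scale = m cv^2`.
#'
#' @param family `"beta"` or `"gamma"`.
#' @param mean target mean; in (0, 1) for beta, > 0 for gamma.
#' @param cv coefficient of variation, > 0.
#' @return For beta, `list(shape1, shape2)`; for gamma, `list(shape, scale)`.
#' @examples
#' moment_match("gamma", 100, 0.1) # shape 100, scale 1
#' moment_match("beta", 0.5, 0.1)  # shape1 = shape2 = 49.5
#' @export
moment_match <- function(family = c("beta", "gamma"), mean, cv) {
  family <- match.arg(family)
  if (cv <= 0) stop("cv must be > 0")
  v <- (cv * mean)^2
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) stop("beta mean must be in (0, 1)")
    if (v >= mean * (1 - mean)) {
      stop("infeasible variance for beta: cv ", cv, " at mean ", mean,
           " implies variance ", signif(v, 4), " >= m(1-m) = ",
           signif(mean * (1 - mean), 4))
    }
    nu <- mean * (1 - mean) / v - 1
    list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
  } else {
    if (mean <= 0) stop("gamma mean must be > 0")
    list(shape = 1 / cv^2, scale = mean * cv^2)
  }
}

# n draws per parameter, fixed iteration order (rate tables, then OPU and
# progression bands, then cost components item by item) so that a given seed
# pins every draw.
sample_param_matrix <- function(inputs, n, prob_cv, cost_cv) {
  draw_beta <- function(m) {
    if (m <= 0 || m >= 1) return(rep(m, n)) # degenerate bounds stay fixed
    par <- moment_match("beta", m, prob_cv)
    stats::rbeta(n, par$shape1, par$shape2)
  }
  draw_gamma <- function(m) {
    if (m <= 0) return(rep(m, n))
    par <- moment_match("gamma", m, cost_cv)
    stats::rgamma(n, shape = par$shape, scale = par$scale)
  }
  rates <- lapply(stats::setNames(RATE_TABLES, RATE_TABLES), function(tab) {
    r <- inputs$rates[[tab]]
    m <- vapply(r, function(mi) draw_beta(mi), numeric(n))
    m <- matrix(m, nrow = n, dimnames = list(NULL, names(r)))
    m
  })
  opu <- vapply(inputs$procedures$opu, draw_beta, numeric(n))
  opu <- matrix(opu, nrow = n, dimnames = list(NULL, names(inputs$procedures$opu)))
  progression <- vapply(inputs$procedures$progression, draw_beta, numeric(n))
  progression <- matrix(progression, nrow = n,
                        dimnames = list(NULL, names(inputs$procedures$progression)))
  items <- inputs$costs$item
  rebate <- matrix(0, n, length(items), dimnames = list(NULL, items))
  oop <- matrix(0, n, length(items), dimnames = list(NULL, items))
  for (i in seq_along(items)) {
    rebate[, i] <- draw_gamma(inputs$costs$medicare_rebate[i])
    oop[, i] <- draw_gamma(inputs$costs$out_of_pocket[i])
  }
  list(rates = rates, opu = opu, progression = progression,
       rebate = rebate, oop = oop)
}

#' Draw one coherent set of model inputs
#'
#' Samples every rate and procedure probability from its moment-matched beta
#' distribution and every nonzero cost component from its gamma distribution,
#' leaving structural settings unchanged. Uses the current RNG state; seed
#' with `set.seed()` for reproducibility.
#'
#' @param inputs an `art_inputs` object holding the means.
#' @param prob_cv,cost_cv coefficients of variation; default to
#'   `inputs$settings`.
#' @return A new validated `art_inputs` object.
#' @export
sample_inputs <- function(inputs = builtin_fixture(),
                          prob_cv = inputs$settings$probability_cv,
                          cost_cv = inputs$settings$cost_cv) {
  d <- sample_param_matrix(inputs, 1L, prob_cv, cost_cv)
  out <- inputs
  for (tab in RATE_TABLES) out$rates[[tab]][] <- d$rates[[tab]][1, ]
  out$procedures$opu[] <- d$opu[1, ]
  out$procedures$progression[] <- d$progression[1, ]
  out$costs$medicare_rebate <- unname(d$rebate[1, ])
  out$costs$out_of_pocket <- unname(d$oop[1, ])
  validate_inputs(out)
  out
}

# Replicate-vectorised outcome of one strategy at one age given sampled
# parameter matrices; mirrors build_strategy()/run_cohort()/expected_cost()
# on vectors.
eval_strategy_draws <- function(name, age, d, inputs, perspective) {
  set <- inputs$settings
  band <- age_band(age)
  n <- nrow(d$opu)
  q <- d$opu[, band]
  g <- d$progression[, band]
  cost_of <- function(items) {
    if (!length(items)) return(rep(0, n))
    tot <- rep(0, n)
    for (it in items) {
      tot <- tot + d$oop[, it] +
        (if (perspective == "societal") d$rebate[, it] else 0)
    }
    tot
  }
  key <- as.character(age)
  zero <- rep(0, n); one <- rep(1, n)
  if (name == "standard") {
    p <- d$rates$autologous[, key]
    Q <- cbind(q, q); P <- cbind(p, p); CF <- cbind(g, g); CC <- cbind(g, g)
    ac <- cost_of("complete_fresh_fet_autologous")
    AC <- cbind(ac, ac); XC <- cbind(cost_of("cancelled_cycle"),
                                     cost_of("cancelled_cycle"))
    upfront <- zero; entry <- 1
  } else if (name == "pgta") {
    p <- d$rates$pgta[, key]
    Q <- cbind(q, q); P <- cbind(p, p * set$pgta_subsequent_cycle_multiplier)
    CF <- cbind(g, g); CC <- cbind(g, g)
    ac <- cost_of(c("complete_fresh_fet_autologous", "pgta"))
    xc <- cost_of("cancelled_cycle")
    AC <- cbind(ac, ac); XC <- cbind(xc, xc)
    upfront <- zero; entry <- 1
  } else if (name == "donor") {
    p <- d$rates$autologous[, key]
    pd <- d$rates$donor[, key]
    Q <- cbind(q, q, one, one); P <- cbind(p, p, pd, pd)
    CF <- cbind(g, g, g, g); CC <- cbind(g, g, zero, zero)
    ac <- cost_of("complete_fresh_fet_autologous")
    dc <- cost_of("complete_donor_cycle")
    xc <- cost_of("cancelled_cycle")
    AC <- cbind(ac, ac, dc, dc); XC <- cbind(xc, xc, zero, zero)
    upfront <- zero; entry <- 1
  } else { # social_freezing
    if (age < 40) return(list(effect = rep(NA_real_, n), cost = rep(NA_real_, n)))
    p <- 1 - sqrt(pmax(1 - d$rates$social_freezing[, key], 0))
    Q <- cbind(one, one); P <- cbind(p, p)
    CF <- cbind(g, g); CC <- cbind(zero, zero)
    AC <- cbind(zero, zero); XC <- cbind(zero, zero)
    upfront <- cost_of("social_freezing_banking") +
      cost_of("social_freezing_thaw_total") +
      (age - set$freeze_age) * cost_of("oocyte_storage_per_year")
    entry <- set$return_rate
  }
  core <- cohort_core(Q, P, CF, CC, entry = entry)
  list(effect = rowSums(core$live_birth),
       cost = upfront + rowSums(core$opu_events * AC + core$cancel_events * XC))
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_replicates` coherent parameter sets, rebuilds every strategy at
#' every age from each draw, and records the replicate cost (under the chosen
#' perspective) and cumulative live-birth rate, plus incremental pairs versus
#' standard care. A fixed seed makes the whole result reproducible.
#'
#' @param inputs an `art_inputs` object.
#' @param ages integer ages (subset of 35-45).
#' @param perspective `"societal"` or `"patient"`.
#' @param n_replicates number of Monte Carlo replicates (default from
#'   settings: 10,000).
#' @param seed integer seed (default from settings).
#' @param prob_cv,cost_cv coefficients of variation for probabilities and
#'   costs.
#' @return An object of class `art_psa`: list with `effect` and `cost` arrays
#'   (replicate x age x strategy), the ages, perspective, seed and sizes.
#' @export
run_psa <- function(inputs = builtin_fixture(), ages = 35:45,
                    perspective = c("societal", "patient"),
                    n_replicates = inputs$settings$psa_replicates,
                    seed = inputs$settings$psa_seed,
                    prob_cv = inputs$settings$probability_cv,
                    cost_cv = inputs$settings$cost_cv) {
  perspective <- match.arg(perspective)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  set.seed(seed, kind = "Mersenne-Twister")
  d <- sample_param_matrix(inputs, n_replicates, prob_cv, cost_cv)
  dn <- list(NULL, as.character(ages), ART_STRATEGIES)
  effect <- array(NA_real_, c(n_replicates, length(ages), length(ART_STRATEGIES)),
                  dimnames = dn)
  cost <- array(NA_real_, dim(effect), dimnames = dn)
  for (j in seq_along(ages)) {
    for (strat in ART_STRATEGIES) {
      r <- eval_strategy_draws(strat, ages[j], d, inputs, perspective)
      effect[, j, strat] <- r$effect
      cost[, j, strat] <- r$cost
    }
  }
  structure(
    list(effect = effect, cost = cost, ages = ages, perspective = perspective,
         n_replicates = n_replicates, seed = seed,
         prob_cv = prob_cv, cost_cv = cost_cv),
    class = "art_psa"
  )
}

#' @export
print.art_psa <- function(x, ...) {
  cat(sprintf("ART PSA: %d replicates, ages %d-%d, %s perspective, seed %s\n",
              x$n_replicates, min(x$ages), max(x$ages), x$perspective,
              format(x$seed)))
  invisible(x)
}

#' Empirical percentile interval
#'
#' The 2.5th and 97.5th percentiles (by default) of a replicate statistic,
#' the borders of the Monte Carlo 95\% interval. Uses the standard linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param values numeric vector (at least one value).
#' @param low,high percentiles in \[0, 100\].
#' @return Numeric vector `c(low_bound, high_bound)`.
#' @examples
#' percentile_ci(1:1000) # 25.975, 975.025
#' @export
percentile_ci <- function(values, low = 2.5, high = 97.5) {
  if (!length(values)) stop("percentile_ci: empty value list")
  unname(stats::quantile(values, c(low, high) / 100, type = 7, names = FALSE))
}

psa_deltas <- function(psa, age, alternative) {
  j <- match(as.character(age), as.character(psa$ages))
  if (is.na(j)) stop("age ", age, " not in the PSA")
  if (alternative == "standard") stop("alternative must differ from standard")
  list(
    delta_effect = psa$effect[, j, alternative] - psa$effect[, j, "standard"],
    delta_cost = psa$cost[, j, alternative] - psa$cost[, j, "standard"]
  )
}

#' Cost-effectiveness plane points
#'
#' One row per replicate: incremental effectiveness (additional live births,
#' x-axis) and incremental cost (y-axis) of an alternative versus standard
#' care at one age.
#'
#' @param psa an `art_psa` object.
#' @param age one of the PSA ages.
#' @param alternative `"pgta"`, `"social_freezing"` or `"donor"`.
#' @return A data.frame with columns `replicate`, `delta_effect`,
#'   `delta_cost`.
#' @export
ce_plane <- function(psa, age, alternative) {
  d <- psa_deltas(psa, age, alternative)
  data.frame(replicate = seq_len(psa$n_replicates),
             delta_effect = d$delta_effect, delta_cost = d$delta_cost)
}

#' Probability that an alternative is cost-effective
#'
#' Fraction of replicates with positive net monetary benefit,
#' `wtp * delta_effect - delta_cost > 0`, per (age, alternative).
#'
#' @param psa an `art_psa` object.
#' @param wtp willingness-to-pay per additional live birth (>= 0).
#' @return A data.frame with columns `age`, `alternative`, `wtp`,
#'   `probability`.
#' @export
prob_cost_effective <- function(psa, wtp) {
  if (wtp < 0) stop("wtp must be >= 0")
  rows <- list()
  for (age in psa$ages) {
    for (alt in setdiff(ART_STRATEGIES, "standard")) {
      if (alt == "social_freezing" && age < 40) next
      d <- psa_deltas(psa, age, alt)
      if (all(is.na(d$delta_effect))) next
      rows[[length(rows) + 1L]] <- data.frame(
        age = age, alternative = alt, wtp = wtp,
        probability = mean(wtp * d$delta_effect - d$delta_cost > 0)
      )
    }
  }
  do.call(rbind, rows)
}

#' Cost-effectiveness acceptability curve table
#'
#' [prob_cost_effective()] evaluated over a grid of willingness-to-pay
#' values.
#'
#' @param psa an `art_psa` object.
#' @param wtp_grid numeric vector of thresholds.
#' @return A long data.frame (`age`, `alternative`, `wtp`, `probability`).
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 10000)) {
  do.call(rbind, lapply(wtp_grid, function(w) prob_cost_effective(psa, w)))
}

#' Summarise a PSA by Table-3 cell
#'
#' Per (age, alternative): mean incremental cost and effect, the ICER of the
#' mean increments, the mean of the replicate ratios, a percentile interval,
#' and the quadrant shares. `ci_mode = "raw"` (default) takes percentiles of
#' the raw replicate ratio, whose interval may span negative to positive when
#' draws straddle quadrants; `"ratio_only"` restricts to draws classified as
#' a ratio, with the dominant/dominated shares reported alongside.
#'
#' @param psa an `art_psa` object.
#' @param ci_mode `"raw"` or `"ratio_only"`.
#' @return A data.frame, one row per cell.
#' @export
psa_summary <- function(psa, ci_mode = c("raw", "ratio_only")) {
  ci_mode <- match.arg(ci_mode)
  rows <- list()
  for (age in psa$ages) {
    for (alt in setdiff(ART_STRATEGIES, "standard")) {
      if (alt == "social_freezing" && age < 40) next
      d <- psa_deltas(psa, age, alt)
      if (all(is.na(d$delta_effect))) next
      ratio <- d$delta_cost / d$delta_effect
      dominant <- d$delta_effect > 0 & d$delta_cost < 0
      dominated <- d$delta_effect < 0 & d$delta_cost > 0
      keep <- if (ci_mode == "raw") is.finite(ratio) else
        is.finite(ratio) & !dominant & !dominated
      ci <- if (any(keep)) percentile_ci(ratio[keep]) else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        age = age, alternative = alt,
        mean_delta_cost = mean(d$delta_cost),
        mean_delta_effect = mean(d$delta_effect),
        icer_of_means = mean(d$delta_cost) / mean(d$delta_effect),
        mean_ratio = mean(ratio[is.finite(ratio)]),
        ci_low = ci[1], ci_high = ci[2],
        frac_dominant = mean(dominant), frac_dominated = mean(dominated),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
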