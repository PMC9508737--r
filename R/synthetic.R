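# Synthetic scenarios: structurally valid random model inputs and toy
# strategies with analytically known outcomes, for property-based testing and
# for exercising the pipeline without the built-in parameter set.

#' Configuration for a synthetic scenario
#'
#' Describes a random but structurally valid parameter set: per-strategy age
#' schedules declining logistically with age (a constant per-year
#' multiplicative decline in the odds of success, mirroring how banded
#' published rates are interpolated), age-band procedure probabilities, and
#' two-payer costs on a common scale.
#'
#' @param seed integer seed.
#' @param n_ages number of ages starting at 35 (1-11).
#' @param rate_decline per-year multiplicative decline in the odds of
#'   success, in (0, 1\]; 1 gives flat schedules.
#' @param base_rates named starting probabilities at age 35 (40 for the
#'   social-freezing table) for tables `autologous`, `pgta`,
#'   `social_freezing`, `donor`.
#' @param cost_scale typical magnitude of a cost item.
#' @param probability_cv,cost_cv PSA coefficients of variation.
#' @return A list of class `art_scenario_config`.
#' @export
scenario_config <- function(seed = 1L, n_ages = 11, rate_decline = 0.85,
                            base_rates = c(autologous = 0.33, pgta = 0.34,
                                           social_freezing = 0.35,
                                           donor = 0.38),
                            cost_scale = 10000,
                            probability_cv = 0.10, cost_cv = 0.10) {
  stopifnot(n_ages >= 1, n_ages <= 11,
            rate_decline > 0, rate_decline <= 1,
            all(base_rates > 0), all(base_rates < 1),
            cost_scale > 0)
  if (!all(RATE_TABLES %in% names(base_rates))) {
    stop("base_rates must name all of: ", paste(RATE_TABLES, collapse = ", "))
  }
  structure(
    list(seed = as.integer(seed), n_ages = n_ages,
         rate_decline = rate_decline, base_rates = base_rates,
         cost_scale = cost_scale, probability_cv = probability_cv,
         cost_cv = cost_cv),
    class = "art_scenario_config"
  )
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Generate synthetic model inputs
#'
#' Deterministic given the config's seed. Age schedules decline in the odds
#' by `rate_decline` per year (monotone non-increasing whenever
#' `rate_decline < 1`); costs are positive draws around `cost_scale` with the
#' fixture's zero-rebate pattern preserved. The result passes
#' [validate_inputs()] and can be fed anywhere the built-in fixture can.
#'
#' @param config an `art_scenario_config`.
#' @return A validated `art_inputs` object.
#' @export
generate_inputs <- function(config = scenario_config()) {
  with_local_seed(config$seed, {
    ages <- 35:(34 + config$n_ages)
    odds <- function(p) p / (1 - p)
    sched <- function(base, first_age, span) {
      o <- odds(base) * config$rate_decline^(span - first_age)
      stats::setNames(o / (1 + o), as.character(span))
    }
    sf_ages <- ages[ages >= 40]
    if (!length(sf_ages)) sf_ages <- 40 # table must exist even on short spans
    rates <- list(
      autologous = sched(config$base_rates[["autologous"]], 35, ages),
      pgta = sched(config$base_rates[["pgta"]], 35, ages),
      social_freezing = sched(config$base_rates[["social_freezing"]], sf_ages[1],
                              sf_ages),
      donor = sched(config$base_rates[["donor"]], 35, ages)
    )
    procedures <- list(
      opu = stats::setNames(sort(stats::runif(3, 0.8, 0.99), decreasing = TRUE),
                            c("35-39", "40-44", "45")),
      progression = stats::setNames(sort(stats::runif(3, 0.6, 0.85),
                                         decreasing = TRUE),
                                    c("35-39", "40-44", "45"))
    )
    fixture <- builtin_fixture()
    rebate_zero <- fixture$costs$medicare_rebate == 0
    costs <- data.frame(
      item = COST_ITEMS,
      medicare_rebate = ifelse(
        rebate_zero, 0,
        config$cost_scale * stats::runif(length(COST_ITEMS), 0.3, 0.8)),
      out_of_pocket = config$cost_scale *
        stats::runif(length(COST_ITEMS), 0.05, 0.6),
      stringsAsFactors = FALSE
    )
    settings <- default_settings()
    settings$psa_seed <- config$seed
    settings$probability_cv <- config$probability_cv
    settings$cost_cv <- config$cost_cv
    new_inputs(rates, procedures, costs, settings)
  })
}

#' Random toy strategy with matching inputs
#'
#' A small strategy (1-4 stages) with uniformly drawn stage probabilities and
#' a minimal cost table, for stress-testing the engine against the
#' enumeration oracle. Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param max_stages upper bound on stage count.
#' @return List with elements `spec` (an `art_strategy`) and `inputs`.
#' @export
generate_toy_strategy <- function(seed = 1L, max_stages = 4) {
  with_local_seed(seed, {
    k <- sample(seq_len(max_stages), 1)
    stages <- lapply(seq_len(k), function(i) {
      new_stage("fresh_autologous",
                p_reach_opu = stats::runif(1),
                p_live_birth = stats::runif(1),
                p_continue_failure = stats::runif(1),
                p_continue_cancel = stats::runif(1),
                items_attempt = "complete_fresh_fet_autologous",
                items_cancel = "cancelled_cycle")
    })
    upfront <- if (stats::runif(1) < 0.3) c(social_freezing_banking = 1) else numeric(0)
    entry <- if (stats::runif(1) < 0.2) stats::runif(1) else 1
    inputs <- builtin_fixture()
    inputs$costs$medicare_rebate <- round(stats::runif(nrow(inputs$costs), 0, 5000))
    inputs$costs$out_of_pocket <- round(stats::runif(nrow(inputs$costs), 1, 5000))
    list(spec = new_strategy("standard", 35, stages, upfront, entry),
         inputs = inputs)
  })
}

#' Toy strategy with closed-form outcome
#'
#' Builds a strategy of `n_stages` identical stages (OPU probability
#' `p_opu`, live-birth probability `p_lb`, continuation probability `p_cont`
#' after both failure and cancellation, one cost item of `unit_cost` accrued
#' per OPU, nothing on cancellation) together with its analytically derived
#' cumulative live-birth rate and expected cost:
#' with `o = p_opu (1 + (1 - p_opu) p_cont)` expected OPU events per entering
#' unit and `f = o (1 - p_lb) p_cont` the mass continuing per stage, the
#' entries form a geometric series, so `CLBR = o p_lb (1 - f^n) / (1 - f)`
#' and `cost = unit_cost * o (1 - f^n) / (1 - f)`.
#'
#' @param p_opu,p_lb,p_cont probabilities in \[0, 1\].
#' @param n_stages 1-4 stages.
#' @param unit_cost cost accrued per OPU event (same under both
#'   perspectives: carried as out-of-pocket with zero rebate).
#' @return List with `spec`, `inputs`, `expected_clbr`, `expected_cost`.
#' @examples
#' closed_form_toy(1, 0.3, 1, 2, 0)$expected_clbr # 1 - 0.7^2 = 0.51
#' @export
closed_form_toy <- function(p_opu, p_lb, p_cont, n_stages, unit_cost) {
  stopifnot(p_opu >= 0, p_opu <= 1, p_lb >= 0, p_lb <= 1,
            p_cont >= 0, p_cont <= 1, n_stages >= 1, n_stages <= 4)
  stage <- new_stage("fresh_autologous", p_opu, p_lb, p_cont, p_cont,
                     "fet_cycle", character(0))
  spec <- new_strategy("standard", 35, rep(list(stage), n_stages))
  inputs <- builtin_fixture()
  inputs$costs$medicare_rebate[] <- 0
  inputs$costs$out_of_pocket[] <- 0
  inputs$costs$out_of_pocket[inputs$costs$item == "fet_cycle"] <- unit_cost
  o <- p_opu * (1 + (1 - p_opu) * p_cont)
  f <- o * (1 - p_lb) * p_cont
  entries <- if (f == 1) n_stages else (1 - f^n_stages) / (1 - f)
  list(spec = spec, inputs = inputs,
       expected_clbr = o * p_lb * entries,
       expected_cost = unit_cost * o * entries)
}
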