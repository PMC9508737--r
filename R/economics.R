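# Cost accrual and cost-effectiveness measures. Societal perspective counts
# rebate + out-of-pocket; patient perspective out-of-pocket only. Nothing is
# discounted (every strategy completes within a year) and nothing is rounded
# before report time.

#' Expected cost of a strategy under a perspective
#'
#' Accrues each stage's attempt items per expected OPU event and cancellation
#' items per expected cancellation, plus any upfront items (oocyte banking,
#' storage years, thaw bundle) once. Identical, to numerical precision, to
#' probability-weighting the accrued items of every enumerated pathway.
#'
#' @param spec an `art_strategy`.
#' @param inputs the `art_inputs` the strategy was built from.
#' @param perspective `"societal"` or `"patient"`.
#' @param method `"cohort"` (default) or `"enumeration"` (the brute-force
#'   oracle).
#' @return Expected cost in the analysis currency.
#' @export
expected_cost <- function(spec, inputs = builtin_fixture(),
                          perspective = c("societal", "patient"),
                          method = c("cohort", "enumeration")) {
  perspective <- match.arg(perspective)
  method <- match.arg(method)
  if (method == "cohort") {
    counts <- expected_item_counts(spec)
    sum(vapply(names(counts), function(it) {
      counts[[it]] * item_cost(inputs, it, perspective)
    }, numeric(1)))
  } else {
    pw <- enumerate_pathways(spec)
    item_cols <- grep("^n_", names(pw), value = TRUE)
    if (!length(item_cols)) return(0)
    unit <- vapply(sub("^n_", "", item_cols), function(it) {
      item_cost(inputs, it, perspective)
    }, numeric(1))
    sum(pw$probability * (as.matrix(pw[item_cols]) %*% unit))
  }
}

#' Upfront cost of a strategy
#'
#' Cost of the items accrued deterministically before the first treatment
#' stage (for social freezing: banking, the thaw-cycle bundle, and per-year
#' storage). Other strategies have none.
#'
#' @inheritParams expected_cost
#' @param include_storage if `FALSE`, storage-per-year items are excluded,
#'   leaving the procedure bundle alone.
#' @return Cost in the analysis currency.
#' @export
upfront_cost <- function(spec, inputs = builtin_fixture(),
                         perspective = c("societal", "patient"),
                         include_storage = TRUE) {
  perspective <- match.arg(perspective)
  up <- spec$upfront
  if (!include_storage) up <- up[names(up) != "oocyte_storage_per_year"]
  if (!length(up)) return(0)
  sum(vapply(names(up), function(it) {
    up[[it]] * item_cost(inputs, it, perspective)
  }, numeric(1)))
}

#' Deterministic outcome of one strategy at one start age
#'
#' Builds the strategy, runs the cohort, and returns its cumulative
#' live-birth rate, expected cost under both perspectives, and cost per live
#' birth.
#'
#' @param name strategy name.
#' @param start_age integer start age.
#' @param inputs an `art_inputs` object.
#' @return An object of class `art_outcome`: list with `strategy`,
#'   `start_age`, `clbr`, `cost` (named societal/patient), and
#'   `cost_per_live_birth`.
#' @export
strategy_outcome <- function(name, start_age, inputs = builtin_fixture()) {
  spec <- build_strategy(name, start_age, inputs)
  eff <- clbr(spec)
  cost <- c(societal = expected_cost(spec, inputs, "societal"),
            patient = expected_cost(spec, inputs, "patient"))
  structure(
    list(strategy = name, start_age = start_age, clbr = eff, cost = cost,
         cost_per_live_birth = if (eff > 0) cost / eff else c(
           societal = NA_real_, patient = NA_real_)),
    class = "art_outcome"
  )
}

#' @export
print.art_outcome <- function(x, ...) {
  cat(sprintf("%s @ age %d: CLBR %.4f, cost %0.0f (societal) / %0.0f (patient)\n",
              x$strategy, x$start_age, x$clbr,
              x$cost[["societal"]], x$cost[["patient"]]))
  invisible(x)
}

#' Classify an incremental cost/effect pair
#'
#' Quadrant logic on (Delta-effect, Delta-cost): more effective and cost
#' saving is `"dominant"`; less effective and more costly is `"dominated"`;
#' both deltas zero is `"identical"`; zero effect difference with nonzero
#' cost difference has no defined ratio (`"undefined"`); anything else is a
#' `"ratio"` with ICER = Delta-cost / Delta-effect.
#'
#' @param delta_cost incremental cost (alternative minus reference).
#' @param delta_effect incremental effect.
#' @return List with `classification` and `icer` (NA unless a ratio).
#' @export
classify_icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0 && delta_cost == 0) {
    list(classification = "identical", icer = NA_real_)
  } else if (delta_effect == 0) {
    list(classification = "undefined", icer = NA_real_)
  } else if (delta_effect > 0 && delta_cost < 0) {
    list(classification = "dominant", icer = NA_real_)
  } else if (delta_effect < 0 && delta_cost > 0) {
    list(classification = "dominated", icer = NA_real_)
  } else {
    list(classification = "ratio", icer = delta_cost / delta_effect)
  }
}

#' Incremental cost-effectiveness of one strategy versus another
#'
#' The ICER is the extra cost per additional live birth of adopting the
#' alternative over the reference strategy; dominance ("more effective and
#' cost saving") and its converse are reported as classifications instead of
#' a ratio.
#'
#' @param reference,alternative `art_outcome` objects at the same start age.
#' @param perspective `"societal"` or `"patient"`.
#' @return An object of class `art_icer`: list with `reference`,
#'   `alternative`, `start_age`, `perspective`, `delta_cost`, `delta_effect`,
#'   `classification`, `icer`.
#' @export
icer <- function(reference, alternative,
                 perspective = c("societal", "patient")) {
  perspective <- match.arg(perspective)
  if (reference$start_age != alternative$start_age) {
    stop("reference and alternative must share a start age")
  }
  dc <- alternative$cost[[perspective]] - reference$cost[[perspective]]
  de <- alternative$clbr - reference$clbr
  cl <- classify_icer(dc, de)
  structure(
    list(reference = reference$strategy, alternative = alternative$strategy,
         start_age = reference$start_age, perspective = perspective,
         delta_cost = dc, delta_effect = de,
         classification = cl$classification, icer = cl$icer),
    class = "art_icer"
  )
}

#' @export
print.art_icer <- function(x, ...) {
  lab <- switch(x$classification,
                dominant = "more effective and cost saving",
                dominated = "less effective and more costly",
                identical = "identical outcomes",
                undefined = "undefined ratio (no effect difference)",
                sprintf("ICER %0.0f per additional live birth", x$icer))
  cat(sprintf("%s vs %s @ age %d (%s): dC=%0.0f dE=%+.4f -> %s\n",
              x$alternative, x$reference, x$start_age, x$perspective,
              x$delta_cost, x$delta_effect, lab))
  invisible(x)
}

#' Convert an amount between the analysis currency and USD
#'
#' Purchasing-power-parity conversion at `settings$ppp_aud_per_usd` (default
#' 1.41 AUD per USD): converting to USD divides, converting to AUD
#' multiplies. Round only at report time.
#'
#' @param amount numeric amount(s).
#' @param to `"USD"` or `"AUD"`.
#' @param settings a settings list (from `art_inputs$settings`).
#' @return Converted amount(s).
#' @examples
#' convert_currency(141, "USD", builtin_fixture()$settings) # 100
#' @export
convert_currency <- function(amount, to = c("USD", "AUD"),
                             settings = builtin_fixture()$settings) {
  to <- match.arg(to)
  if (to == "USD") amount / settings$ppp_aud_per_usd
  else amount * settings$ppp_aud_per_usd
}

#' Deterministic outcome table over strategies and ages
#'
#' One row per valid (strategy, age) pair with CLBR, costs under both
#' perspectives, and cost per live birth; the data behind the per-age outcome
#' figures.
#'
#' @param inputs an `art_inputs` object.
#' @param ages integer ages (subset of 35-45).
#' @param currency `"AUD"` (analysis currency, default) or `"USD"`.
#' @return A data.frame.
#' @export
outcome_table <- function(inputs = builtin_fixture(), ages = 35:45,
                          currency = c("AUD", "USD")) {
  currency <- match.arg(currency)
  conv <- function(x) if (currency == "USD") {
    convert_currency(x, "USD", inputs$settings)
  } else x
  rows <- list()
  for (age in ages) {
    for (strat in ART_STRATEGIES) {
      if (strat == "social_freezing" && age < 40) next
      o <- strategy_outcome(strat, age, inputs)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strat, age = age, clbr = o$clbr,
        cost_societal = conv(o$cost[["societal"]]),
        cost_patient = conv(o$cost[["patient"]]),
        cost_per_live_birth_societal = conv(o$cost_per_live_birth[["societal"]]),
        cost_per_live_birth_patient = conv(o$cost_per_live_birth[["patient"]]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "currency") <- currency
  out
}

#' Deterministic ICER table versus standard care
#'
#' One row per (age, alternative strategy) with the incremental cost, effect,
#' classification and ICER relative to standard autologous ART; the
#' social-freezing rows are absent below age 40.
#'
#' @inheritParams outcome_table
#' @param perspective `"societal"` or `"patient"`.
#' @return A data.frame.
#' @export
cost_effectiveness_table <- function(inputs = builtin_fixture(), ages = 35:45,
                                     perspective = c("societal", "patient"),
                                     currency = c("AUD", "USD")) {
  perspective <- match.arg(perspective)
  currency <- match.arg(currency)
  conv <- function(x) if (currency == "USD") {
    convert_currency(x, "USD", inputs$settings)
  } else x
  alts <- setdiff(ART_STRATEGIES, "standard")
  rows <- list()
  for (age in ages) {
    ref <- strategy_outcome("standard", age, inputs)
    for (alt in alts) {
      if (alt == "social_freezing" && age < 40) next
      res <- icer(ref, strategy_outcome(alt, age, inputs), perspective)
      rows[[length(rows) + 1L]] <- data.frame(
        age = age, alternative = alt, perspective = perspective,
        delta_cost = conv(res$delta_cost), delta_effect = res$delta_effect,
        classification = res$classification, icer = conv(res$icer),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "currency") <- currency
  out
}
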