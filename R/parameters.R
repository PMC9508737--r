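# Model inputs: age-specific success probabilities, procedure probabilities,
# two-payer cost items, and global settings. All money is in the 2019 analysis
# currency of the cost tables; conversion happens only at report time.

#' Strategy names recognised by the model
#' @export
ART_STRATEGIES <- c("standard", "pgta", "social_freezing", "donor")

# Rate tables are keyed by the oocyte source, so the two autologous strategies
# (standard, donor prefix) share one schedule.
RATE_TABLES <- c("autologous", "pgta", "social_freezing", "donor")

#' Cost item names recognised by the model
#' @export
COST_ITEMS <- c(
  "cancelled_cycle",
  "complete_fresh_fet_autologous",
  "fet_cycle",
  "pgta",
  "complete_donor_cycle",
  "oocyte_storage_per_year",
  "social_freezing_banking",
  "social_freezing_thaw_total"
)

default_settings <- function() {
  list(
    ppp_aud_per_usd = 1.41,
    wtp_threshold = 50000,
    psa_replicates = 10000,
    psa_seed = 1L,
    probability_cv = 0.10,
    cost_cv = 0.10,
    pgta_subsequent_cycle_multiplier = 0.90,
    freeze_age = 32,
    return_rate = 1.0
  )
}

#' Built-in model inputs
#'
#' Returns the full parameter set used by the base-case analysis: age-specific
#' cumulative live-birth rates per complete cycle for each oocyte source,
#' age-band probabilities of an initiated cycle reaching oocyte pick-up (OPU)
#' and of progressing to a further fresh cycle, the two-payer (public rebate /
#' out-of-pocket) cost of each procedure bundle, and global settings
#' (purchasing-power-parity rate, willingness-to-pay threshold, PSA defaults).
#'
#' Rates are probabilities per complete cycle except for the social-freezing
#' schedule, which is cumulative over the strategy's two thaw cycles and is
#' backed out to a per-cycle rate when a strategy is built.
#'
#' @return An object of class `art_inputs`: a list with elements `rates`,
#'   `procedures`, `costs` and `settings`.
#' @seealso [load_inputs()], [build_strategy()]
#' @examples
#' fx <- builtin_fixture()
#' fx$rates$autologous[["35"]] # 0.325
#' @export
builtin_fixture <- function() {
  rates <- list(
    autologous = stats::setNames(
      c(0.325, 0.286, 0.249, 0.213, 0.179, 0.160, 0.142, 0.107, 0.074, 0.043, 0.014),
      as.character(35:45)
    ),
    pgta = stats::setNames(
      c(0.337, 0.295, 0.244, 0.194, 0.166, 0.153, 0.149, 0.147, 0.140, 0.120, 0.082),
      as.character(35:45)
    ),
    social_freezing = stats::setNames(
      c(0.351, 0.338, 0.325, 0.313, 0.300, 0.287),
      as.character(40:45)
    ),
    donor = stats::setNames(
      c(0.380, 0.380, 0.380, 0.317, 0.317, 0.317, 0.329, 0.329, 0.378, 0.378, 0.333),
      as.character(35:45)
    )
  )
  procedures <- list(
    opu = c("35-39" = 0.93, "40-44" = 0.90, "45" = 0.85),
    progression = c("35-39" = 0.765, "40-44" = 0.707, "45" = 0.707)
  )
  costs <- data.frame(
    item = COST_ITEMS,
    medicare_rebate = c(1463, 6522, 626, 0, 0, 0, 0, 0),
    out_of_pocket = c(1909, 4325, 1023, 1813, 11720, 260, 9305, 3300),
    stringsAsFactors = FALSE
  )
  new_inputs(rates, procedures, costs, default_settings())
}

new_inputs <- function(rates, procedures, costs, settings) {
  x <- structure(
    list(rates = rates, procedures = procedures, costs = costs,
         settings = settings),
    class = "art_inputs"
  )
  validate_inputs(x)
}

#' Validate a set of model inputs
#'
#' Checks structural invariants: all four rate tables present with contiguous
#' integer age spans and rates in \[0, 1\], age-band procedure probabilities in
#' \[0, 1\], all cost items present with nonnegative components, and settings
#' within their domains. Errors name the offending key.
#'
#' @param x an `art_inputs` object (or bare list with the same shape).
#' @return `x`, invisibly classed as `art_inputs`, if valid.
#' @export
validate_inputs <- function(x) {
  for (f in c("rates", "procedures", "costs", "settings")) {
    if (is.null(x[[f]])) stop("inputs: missing section '", f, "'")
  }
  for (tab in RATE_TABLES) {
    r <- x$rates[[tab]]
    if (is.null(r)) stop("rates: missing table '", tab, "'")
    ages <- suppressWarnings(as.integer(names(r)))
    if (anyNA(ages)) stop("rates$", tab, ": ages must be integer-named")
    if (length(ages) > 1 && !all(diff(sort(ages)) == 1)) {
      stop("rates$", tab, ": ages must form a contiguous integer range")
    }
    bad <- which(r < 0 | r > 1)
    if (length(bad)) {
      stop("rates$", tab, "[", names(r)[bad[1]], "]: rate ", r[bad[1]],
           " outside [0,1]")
    }
  }
  for (p in c("opu", "progression")) {
    v <- x$procedures[[p]]
    if (is.null(v)) stop("procedures: missing '", p, "'")
    if (!all(c("35-39", "40-44", "45") %in% names(v))) {
      stop("procedures$", p, ": age bands must cover 35-39, 40-44, 45")
    }
    bad <- which(v < 0 | v > 1)
    if (length(bad)) {
      stop("procedures$", p, "[", names(v)[bad[1]], "]: probability outside [0,1]")
    }
  }
  co <- x$costs
  if (!all(c("item", "medicare_rebate", "out_of_pocket") %in% names(co))) {
    stop("costs: need columns item, medicare_rebate, out_of_pocket")
  }
  missing_items <- setdiff(COST_ITEMS, co$item)
  if (length(missing_items)) {
    stop("costs: missing item '", missing_items[1], "'")
  }
  for (col in c("medicare_rebate", "out_of_pocket")) {
    bad <- which(co[[col]] < 0)
    if (length(bad)) {
      stop("costs$", col, "[", co$item[bad[1]], "]: must be >= 0")
    }
  }
  s <- x$settings
  chk <- function(cond, key, msg) if (!isTRUE(cond)) stop("settings$", key, ": ", msg)
  chk(s$ppp_aud_per_usd > 0, "ppp_aud_per_usd", "must be > 0")
  chk(s$probability_cv > 0, "probability_cv", "must be > 0")
  chk(s$cost_cv > 0, "cost_cv", "must be > 0")
  chk(s$pgta_subsequent_cycle_multiplier > 0 &&
        s$pgta_subsequent_cycle_multiplier <= 1,
      "pgta_subsequent_cycle_multiplier", "must be in (0,1]")
  chk(s$return_rate >= 0 && s$return_rate <= 1, "return_rate", "must be in [0,1]")
  chk(s$psa_replicates >= 1, "psa_replicates", "must be >= 1")
  class(x) <- "art_inputs"
  invisible(x)
}

#' @export
print.art_inputs <- function(x, ...) {
  cat("ART model inputs\n")
  for (tab in names(x$rates)) {
    ages <- names(x$rates[[tab]])
    cat(sprintf("  rates$%-16s ages %s-%s\n", tab, ages[1], ages[length(ages)]))
  }
  cat("  cost items:", nrow(x$costs), " settings:", length(x$settings), "\n")
  invisible(x)
}

#' Load model inputs from a YAML configuration
#'
#' The document has four flat sections mirroring [builtin_fixture()]:
#' `rates` (named tables of age -> rate), `procedures` (`opu`, `progression`
#' keyed by age band), `costs` (item -> `{medicare_rebate, out_of_pocket}`),
#' and `settings`. Every section and key is optional; anything absent is filled
#' from the built-in fixture, so a minimal file may override a single setting.
#'
#' @param path path to a YAML file.
#' @return A validated `art_inputs` object.
#' @seealso [save_inputs()]
#' @export
load_inputs <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  base <- builtin_fixture()
  known <- c("rates", "procedures", "costs", "settings")
  extra <- setdiff(names(doc), known)
  if (length(extra)) stop("config: unknown section '", extra[1], "'")
  if (!is.null(doc$rates)) {
    for (tab in names(doc$rates)) {
      if (!tab %in% RATE_TABLES) stop("rates: unknown table '", tab, "'")
      base$rates[[tab]] <- unlist(doc$rates[[tab]])
    }
  }
  if (!is.null(doc$procedures)) {
    for (p in names(doc$procedures)) {
      if (!p %in% c("opu", "progression")) stop("procedures: unknown key '", p, "'")
      base$procedures[[p]] <- unlist(doc$procedures[[p]])
    }
  }
  if (!is.null(doc$costs)) {
    for (it in names(doc$costs)) {
      if (!it %in% COST_ITEMS) stop("costs: unknown item '", it, "'")
      row <- match(it, base$costs$item)
      for (comp in names(doc$costs[[it]])) {
        if (!comp %in% c("medicare_rebate", "out_of_pocket")) {
          stop("costs$", it, ": unknown component '", comp, "'")
        }
        base$costs[[comp]][row] <- doc$costs[[it]][[comp]]
      }
    }
  }
  if (!is.null(doc$settings)) {
    unknown <- setdiff(names(doc$settings), names(base$settings))
    if (length(unknown)) stop("settings: unknown key '", unknown[1], "'")
    base$settings[names(doc$settings)] <- doc$settings
  }
  validate_inputs(base)
  base
}

#' Write model inputs to a YAML configuration
#'
#' Serialises an `art_inputs` object to the format read by [load_inputs()];
#' the round trip is lossless.
#'
#' @param x an `art_inputs` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_inputs <- function(x, path) {
  validate_inputs(x)
  doc <- list(
    rates = lapply(x$rates, as.list),
    procedures = lapply(x$procedures, as.list),
    costs = stats::setNames(lapply(seq_len(nrow(x$costs)), function(i) {
      list(medicare_rebate = x$costs$medicare_rebate[i],
           out_of_pocket = x$costs$out_of_pocket[i])
    }), x$costs$item),
    settings = x$settings
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Interpolate an age-rate schedule with a logistic curve
#'
#' Success rates for ART are often published by 5-year age band; a per-age
#' schedule is obtained by fitting `rate = plogis(a + b * age)` by least
#' squares on the logit scale and predicting at the target ages. With exactly
#' two distinct anchor points the curve passes through both.
#'
#' @param ages numeric vector of anchor ages.
#' @param rates rates in (0, 1) observed at `ages`.
#' @param target_ages ages at which to predict.
#' @return Named numeric vector of predicted rates at `target_ages`, clipped
#'   to (0, 1).
#' @examples
#' interpolate_age_rates(c(35, 45), c(0.5, 0.5), 35:45) # flat at 0.5
#' @export
interpolate_age_rates <- function(ages, rates, target_ages) {
  if (length(ages) != length(rates)) stop("ages and rates must have equal length")
  if (length(unique(ages)) < 2) {
    stop("interpolation needs at least 2 distinct ages")
  }
  if (any(rates <= 0 | rates >= 1)) {
    stop("anchor rates must lie strictly inside (0, 1)")
  }
  fit <- stats::lm(stats::qlogis(rates) ~ ages)
  pred <- stats::plogis(stats::predict(fit, newdata = list(ages = target_ages)))
  eps <- .Machine$double.eps
  stats::setNames(pmin(pmax(pred, eps), 1 - eps), as.character(target_ages))
}

#' Age band for procedure probabilities
#'
#' Maps an integer start age to the age band used by the OPU and progression
#' probability tables.
#'
#' @param age integer age in 35-45.
#' @return One of `"35-39"`, `"40-44"`, `"45"`.
#' @export
age_band <- function(age) {
  if (age >= 35 && age <= 39) "35-39"
  else if (age >= 40 && age <= 44) "40-44"
  else if (age == 45) "45"
  else stop("age ", age, " outside the modelled range 35-45")
}

#' Cost of one or more items under a perspective
#'
#' The societal perspective counts the full direct cost (public rebate plus
#' out-of-pocket); the patient perspective counts out-of-pocket only.
#'
#' @param inputs an `art_inputs` object.
#' @param items character vector of cost item names (repeats allowed and
#'   counted).
#' @param perspective `"societal"` or `"patient"`.
#' @return Total cost of the listed items.
#' @export
item_cost <- function(inputs, items, perspective = c("societal", "patient")) {
  perspective <- match.arg(perspective)
  if (!length(items)) return(0)
  idx <- match(items, inputs$costs$item)
  if (anyNA(idx)) stop("unknown cost item '", items[which(is.na(idx))[1]], "'")
  oop <- inputs$costs$out_of_pocket[idx]
  if (perspective == "patient") sum(oop)
  else sum(inputs$costs$medicare_rebate[idx] + oop)
}

#' Export the per-age rate tables as a data frame
#'
#' One row per (table, age) pair, suitable for writing to CSV.
#'
#' @param inputs an `art_inputs` object.
#' @return A data.frame with columns `table`, `age`, `rate`.
#' @export
rate_table_frame <- function(inputs) {
  do.call(rbind, lapply(names(inputs$rates), function(tab) {
    data.frame(table = tab,
               age = as.integer(names(inputs$rates[[tab]])),
               rate = unname(inputs$rates[[tab]]),
               stringsAsFactors = FALSE)
  }))
}
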