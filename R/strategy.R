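# Strategy pathways as finite absorbing-state processes. One stage is one
# "complete cycle" (an ovarian-stimulation episode with its bundled embryo
# transfers); live birth and end are absorbing.

new_stage <- function(kind, p_reach_opu, p_live_birth, p_continue_failure,
                      p_continue_cancel, items_attempt, items_cancel) {
  stopifnot(
    p_reach_opu >= 0, p_reach_opu <= 1,
    p_live_birth >= 0, p_live_birth <= 1,
    p_continue_failure >= 0, p_continue_failure <= 1,
    p_continue_cancel >= 0, p_continue_cancel <= 1
  )
  list(kind = kind,
       p_reach_opu = p_reach_opu,
       p_live_birth = p_live_birth,
       p_continue_failure = p_continue_failure,
       p_continue_cancel = p_continue_cancel,
       items_attempt = items_attempt,
       items_cancel = items_cancel)
}

new_strategy <- function(name, start_age, stages, upfront = numeric(0),
                         entry_prob = 1) {
  structure(
    list(name = name, start_age = start_age, stages = stages,
         upfront = upfront, entry_prob = entry_prob),
    class = "art_strategy"
  )
}

#' Back out a per-cycle rate from a cumulative rate over k cycles
#'
#' Solves `1 - (1 - p)^k = clbr` for `p`. Used when a published live-birth
#' rate is cumulative over a strategy's full cycle count rather than per cycle
#' (the social-freezing schedule, cumulative over its two thaw cycles).
#'
#' @param clbr cumulative rate in \[0, 1).
#' @param k number of cycles the rate accumulates over.
#' @return Per-cycle probability.
#' @export
per_cycle_rate <- function(clbr, k) {
  stopifnot(clbr >= 0, clbr < 1, k >= 1)
  1 - (1 - clbr)^(1 / k)
}

#' Build a treatment-strategy specification
#'
#' Encodes one of the four ART strategies at one start age as an ordered list
#' of attempt stages with per-stage probabilities and cost items:
#'
#' * `standard` — two complete autologous cycles (fresh transfer plus two
#'   bundled frozen-embryo transfers per stimulation episode).
#' * `pgta` — two complete autologous cycles with aneuploidy screening (fresh
#'   plus one bundled FET); the second cycle's live-birth rate is multiplied
#'   by `settings$pgta_subsequent_cycle_multiplier` (default 0.90).
#' * `donor` — two complete autologous cycles followed by up to two
#'   donor-oocyte transfer cycles (no cancellation step for the recipient).
#' * `social_freezing` — oocytes banked at `settings$freeze_age` (two OPU
#'   procedures, modelled as a certain upfront cost), with the woman returning
#'   at `start_age` (40-45) for two thaw transfer cycles; the published
#'   cumulative rate over both cycles is backed out to a per-cycle rate.
#'
#' Within every stage a cycle reaches oocyte pick-up with the age-band OPU
#' probability, otherwise it is cancelled; a cancelled cycle may be
#' re-attempted once (with the age-band progression probability) before
#' treatment ends. After a failed complete cycle the woman proceeds to the
#' next stage with the same progression probability.
#'
#' @param name one of `"standard"`, `"pgta"`, `"social_freezing"`, `"donor"`.
#' @param start_age integer age at treatment start, 35-45 (40-45 for
#'   social freezing).
#' @param inputs an `art_inputs` object; defaults to [builtin_fixture()].
#' @return An object of class `art_strategy`.
#' @examples
#' spec <- build_strategy("standard", 35)
#' spec$stages[[1]]$p_live_birth # 0.325
#' @export
build_strategy <- function(name = ART_STRATEGIES, start_age,
                           inputs = builtin_fixture()) {
  name <- match.arg(name)
  if (start_age != round(start_age)) stop("start_age must be an integer age")
  lo <- if (name == "social_freezing") 40 else 35
  if (start_age < lo || start_age > 45) {
    stop("start_age ", start_age, " outside ", lo, "-45 for strategy '",
         name, "'")
  }
  band <- age_band(start_age)
  q <- unname(inputs$procedures$opu[band])
  g <- unname(inputs$procedures$progression[band])
  set <- inputs$settings
  age_key <- as.character(start_age)
  rate_of <- function(tab) {
    r <- inputs$rates[[tab]][age_key]
    if (is.na(r)) stop("rates$", tab, " has no entry for age ", start_age)
    unname(r)
  }

  if (name == "standard") {
    p <- rate_of("autologous")
    stages <- list(
      new_stage("fresh_autologous", q, p, g, g,
                "complete_fresh_fet_autologous", "cancelled_cycle"),
      new_stage("fresh_autologous", q, p, g, g,
                "complete_fresh_fet_autologous", "cancelled_cycle")
    )
    new_strategy(name, start_age, stages)
  } else if (name == "pgta") {
    p <- rate_of("pgta")
    items <- c("complete_fresh_fet_autologous", "pgta")
    stages <- list(
      new_stage("fresh_autologous_pgta", q, p, g, g, items, "cancelled_cycle"),
      new_stage("fresh_autologous_pgta", q,
                p * set$pgta_subsequent_cycle_multiplier, g, g,
                items, "cancelled_cycle")
    )
    new_strategy(name, start_age, stages)
  } else if (name == "donor") {
    p <- rate_of("autologous")
    pd <- rate_of("donor")
    auto <- new_stage("fresh_autologous", q, p, g, g,
                      "complete_fresh_fet_autologous", "cancelled_cycle")
    don <- new_stage("donor_fet", 1, pd, g, 0,
                     "complete_donor_cycle", character(0))
    new_strategy(name, start_age, list(auto, auto, don, don))
  } else { # social_freezing
    p <- per_cycle_rate(rate_of("social_freezing"), 2)
    thaw <- new_stage("stored_oocyte_fet", 1, p, g, 0,
                      character(0), character(0))
    years <- start_age - set$freeze_age
    upfront <- c(social_freezing_banking = 1,
                 social_freezing_thaw_total = 1,
                 oocyte_storage_per_year = years)
    new_strategy(name, start_age, list(thaw, thaw), upfront,
                 entry_prob = set$return_rate)
  }
}

#' @export
print.art_strategy <- function(x, ...) {
  cat(sprintf("ART strategy '%s', start age %d, %d stage(s)\n",
              x$name, x$start_age, length(x$stages)))
  for (i in seq_along(x$stages)) {
    s <- x$stages[[i]]
    cat(sprintf("  stage %d [%s]: P(OPU)=%.3f P(LB|OPU)=%.4f P(cont)=%.3f\n",
                i, s$kind, s$p_reach_opu, s$p_live_birth, s$p_continue_failure))
  }
  if (length(x$upfront)) {
    cat("  upfront:", paste(names(x$upfront), x$upfront, sep = "x",
                            collapse = ", "), "\n")
  }
  if (x$entry_prob < 1) cat("  entry probability:", x$entry_prob, "\n")
  invisible(x)
}
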