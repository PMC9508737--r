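# Cohort engine. Within a stage, entering mass splits as:
#   reach OPU (q)            -> live birth (p) | failure -> continue (cf) | end
#   cancelled (1 - q)        -> re-attempt once (cc) | end
#   re-attempt: reach OPU (q) as above; cancelled again -> end (cap of one
#   re-attempt keeps the tree finite).
# Per entering unit this gives expected OPU events o = q (1 + (1-q) cc) and
# expected cancellations x = (1-q)(1 + cc (1-q)); live-birth mass o*p;
# mass continuing to the next stage o*(1-p)*cf. The same formulas run on
# replicate vectors for the PSA (all arguments n x k matrices).

cohort_core <- function(Q, P, CF, CC, entry = 1) {
  Q <- as.matrix(Q); P <- as.matrix(P); CF <- as.matrix(CF); CC <- as.matrix(CC)
  k <- ncol(Q)
  n <- nrow(Q)
  m <- rep_len(entry, n)
  out <- list(
    entering = matrix(0, n, k), live_birth = matrix(0, n, k),
    end_failure = matrix(0, n, k), end_cancel = matrix(0, n, k),
    continuing = matrix(0, n, k), opu_events = matrix(0, n, k),
    cancel_events = matrix(0, n, k)
  )
  for (s in seq_len(k)) {
    q <- Q[, s]; p <- P[, s]; cc <- CC[, s]
    cf <- if (s == k) 0 else CF[, s] # pathway ends after the last stage
    o <- q * (1 + (1 - q) * cc)
    x <- (1 - q) * (1 + cc * (1 - q))
    fail <- m * o * (1 - p)
    out$entering[, s] <- m
    out$live_birth[, s] <- m * o * p
    out$continuing[, s] <- fail * cf
    out$end_failure[, s] <- fail * (1 - cf)
    out$end_cancel[, s] <- m * ((1 - q) * (1 - cc) + (1 - q) * cc * (1 - q))
    out$opu_events[, s] <- m * o
    out$cancel_events[, s] <- m * x
    m <- out$continuing[, s]
  }
  out
}

stage_matrix <- function(spec, field) {
  matrix(vapply(spec$stages, `[[`, numeric(1), field), nrow = 1)
}

#' Run the cohort model for a strategy
#'
#' Propagates a unit cohort through the strategy's stages and records, per
#' stage, the mass entering, achieving a live birth, ending after a failed
#' complete cycle, ending after cancellation, and continuing, together with
#' the expected number of OPU (cost-bearing attempt) and cancellation events.
#' Masses are conserved at every stage and the cumulative live-birth mass is
#' non-decreasing.
#'
#' @param spec an `art_strategy` from [build_strategy()].
#' @return A data.frame of class `art_trace`, one row per stage, with
#'   attribute `clbr` (total live-birth mass) and `entry_prob`.
#' @export
run_cohort <- function(spec) {
  core <- cohort_core(
    stage_matrix(spec, "p_reach_opu"),
    stage_matrix(spec, "p_live_birth"),
    stage_matrix(spec, "p_continue_failure"),
    stage_matrix(spec, "p_continue_cancel"),
    entry = spec$entry_prob
  )
  tr <- data.frame(
    stage = seq_along(spec$stages),
    kind = vapply(spec$stages, `[[`, character(1), "kind"),
    entering = core$entering[1, ],
    live_birth = core$live_birth[1, ],
    end_failure = core$end_failure[1, ],
    end_cancel = core$end_cancel[1, ],
    continuing = core$continuing[1, ],
    opu_events = core$opu_events[1, ],
    cancel_events = core$cancel_events[1, ],
    stringsAsFactors = FALSE
  )
  tr$cum_live_birth <- cumsum(tr$live_birth)
  attr(tr, "clbr") <- sum(tr$live_birth)
  attr(tr, "entry_prob") <- spec$entry_prob
  class(tr) <- c("art_trace", "data.frame")
  tr
}

#' Cumulative live-birth rate of a strategy
#'
#' Total live-birth mass over the whole pathway, the model's primary clinical
#' outcome.
#'
#' @param spec an `art_strategy`.
#' @return Probability in \[0, 1\].
#' @export
clbr <- function(spec) {
  attr(run_cohort(spec), "clbr")
}

#' Exhaustively enumerate the pathways of a strategy
#'
#' Walks the finite outcome tree (every stage branches over OPU/cancellation,
#' live birth/failure, continue/end, with one re-attempt after cancellation)
#' and returns every mutually exclusive pathway with its probability, live
#' birth indicator, and accrued cost-item counts. Probabilities sum to 1.
#' This is the brute-force oracle against which the cohort recursion is
#' verified; the two are independent implementations.
#'
#' @param spec an `art_strategy`.
#' @return A data.frame with columns `pathway`, `probability`, `live_birth`,
#'   and one count column `n_<item>` per cost item appearing in the strategy
#'   (upfront items included in every pathway).
#' @export
enumerate_pathways <- function(spec) {
  items <- unique(c(
    unlist(lapply(spec$stages, function(s) c(s$items_attempt, s$items_cancel))),
    names(spec$upfront)
  ))
  base_counts <- stats::setNames(numeric(length(items)), items)
  if (length(spec$upfront)) {
    base_counts[names(spec$upfront)] <- spec$upfront
  }
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 256)
  acc$i <- 0L
  emit <- function(path, prob, lb, counts) {
    if (prob == 0) return(invisible())
    acc$i <- acc$i + 1L
    if (acc$i > length(acc$rows)) {
      acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
    }
    acc$rows[[acc$i]] <- list(pathway = path, probability = prob,
                              live_birth = lb, counts = counts)
  }
  k <- length(spec$stages)
  add <- function(counts, its) {
    if (length(its)) counts[its] <- counts[its] + 1
    counts
  }
  recurse <- function(s, path, prob, counts) {
    st <- spec$stages[[s]]
    q <- st$p_reach_opu; p <- st$p_live_birth
    cf <- if (s == k) 0 else st$p_continue_failure
    cc <- st$p_continue_cancel
    att <- add(counts, st$items_attempt)
    can <- add(counts, st$items_cancel)
    tag <- function(x) paste0(path, "s", s, ":", x)
    # first attempt reaches OPU
    emit(tag("LB"), prob * q * p, TRUE, att)
    fail <- prob * q * (1 - p)
    emit(tag("F.end"), fail * (1 - cf), FALSE, att)
    if (s < k) recurse(s + 1, paste0(tag("F"), ">"), fail * cf, att)
    # cancelled
    emit(tag("C.end"), prob * (1 - q) * (1 - cc), FALSE, can)
    re <- prob * (1 - q) * cc
    can_att <- add(can, st$items_attempt)
    emit(tag("C.LB"), re * q * p, TRUE, can_att)
    refail <- re * q * (1 - p)
    emit(tag("C.F.end"), refail * (1 - cf), FALSE, can_att)
    if (s < k) recurse(s + 1, paste0(tag("C.F"), ">"), refail * cf, can_att)
    emit(tag("C.C.end"), re * (1 - q), FALSE, add(can, st$items_cancel))
  }
  if (spec$entry_prob < 1) {
    emit("not_started", 1 - spec$entry_prob, FALSE, base_counts)
  }
  if (spec$entry_prob > 0) recurse(1, "", spec$entry_prob, base_counts)
  rows <- acc$rows[seq_len(acc$i)]
  cnt <- do.call(rbind, lapply(rows, `[[`, "counts"))
  if (is.null(cnt)) cnt <- matrix(0, 0, length(items),
                                  dimnames = list(NULL, items))
  out <- data.frame(
    pathway = vapply(rows, `[[`, character(1), "pathway"),
    probability = vapply(rows, `[[`, numeric(1), "probability"),
    live_birth = vapply(rows, `[[`, logical(1), "live_birth"),
    stringsAsFactors = FALSE
  )
  if (length(items)) {
    colnames(cnt) <- paste0("n_", items)
    out <- cbind(out, as.data.frame(cnt))
  }
  out
}

#' Expected cost-item counts for a strategy
#'
#' Expected number of accruals of every cost item over the whole pathway,
#' from the cohort recursion (attempt items per OPU event, cancellation items
#' per cancellation event, upfront items once).
#'
#' @param spec an `art_strategy`.
#' @return Named numeric vector of expected counts.
#' @export
expected_item_counts <- function(spec) {
  tr <- run_cohort(spec)
  counts <- numeric(0)
  bump <- function(counts, its, n) {
    for (it in its) {
      counts[it] <- (if (is.na(counts[it])) 0 else counts[it]) + n
    }
    counts
  }
  for (s in seq_along(spec$stages)) {
    st <- spec$stages[[s]]
    counts <- bump(counts, st$items_attempt, tr$opu_events[s])
    counts <- bump(counts, st$items_cancel, tr$cancel_events[s])
  }
  counts <- bump(counts, names(spec$upfront), 0) # ensure presence
  if (length(spec$upfront)) {
    counts[names(spec$upfront)] <- counts[names(spec$upfront)] + spec$upfront
  }
  counts[!is.na(counts)]
}
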