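# Report generation: plain-CSV outputs (comma-separated, UTF-8, header row,
# '.' decimal, no thousands separators) plus a JSON run manifest recording the
# configuration, seed and files written. Money column headers carry the
# currency code.

currency_headers <- function(df, currency) {
  money <- c("cost_societal", "cost_patient", "cost_per_live_birth_societal",
             "cost_per_live_birth_patient", "delta_cost", "icer",
             "mean_delta_cost", "icer_of_means", "mean_ratio", "ci_low",
             "ci_high")
  idx <- names(df) %in% money
  names(df)[idx] <- paste0(names(df)[idx], "_", tolower(currency))
  df
}

write_report_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

resolve_inputs <- function(config) {
  if (is.null(config)) builtin_fixture() else load_inputs(config)
}

write_manifest <- function(outdir, files, inputs, extra = list()) {
  manifest <- c(list(
    package = "artcea",
    version = as.character(utils::packageVersion("artcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(files),
    config = list(settings = inputs$settings)
  ), extra)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Write the deterministic outcome and ICER reports
#'
#' Runs the cohort model for every strategy and age and writes
#' `outcomes.csv` (CLBR and costs per strategy/age) and `icer_table.csv`
#' (incremental results versus standard care), plus `manifest.json`.
#'
#' @param config path to a YAML configuration, or `NULL` for the built-in
#'   parameter set.
#' @param ages integer ages.
#' @param perspective `"societal"` or `"patient"` (ICER table).
#' @param currency `"AUD"` (analysis currency) or `"USD"`.
#' @param outdir output directory, created if needed.
#' @return Invisibly, the list of files written.
#' @export
cmd_deterministic <- function(config = NULL, ages = 35:45,
                              perspective = c("societal", "patient"),
                              currency = c("AUD", "USD"), outdir = ".") {
  perspective <- match.arg(perspective)
  currency <- match.arg(currency)
  inputs <- resolve_inputs(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    write_report_csv(
      currency_headers(outcome_table(inputs, ages, currency), currency),
      file.path(outdir, "outcomes.csv")),
    write_report_csv(
      currency_headers(
        cost_effectiveness_table(inputs, ages, perspective, currency),
        currency),
      file.path(outdir, "icer_table.csv"))
  )
  files <- c(files, write_manifest(outdir, files, inputs,
                                   list(mode = "deterministic",
                                        perspective = perspective,
                                        currency = currency,
                                        ages = range(ages))))
  stopifnot(all(file.exists(files)))
  invisible(files)
}

#' Write the probabilistic sensitivity analysis reports
#'
#' Runs the PSA and writes `psa_summary.csv` (one row per age and
#' alternative, with mean increments, both ICER conventions and percentile
#' intervals), one `ce_plane_<age>.csv` per age with the replicate
#' (incremental effect, incremental cost) pairs per alternative, `ceac.csv`
#' (acceptability over a willingness-to-pay grid), and `manifest.json`
#' recording the seed.
#'
#' @inheritParams cmd_deterministic
#' @param n number of replicates.
#' @param seed integer seed.
#' @param wtp willingness-to-pay threshold anchoring the CEAC grid.
#' @return Invisibly, the list of files written.
#' @export
cmd_psa <- function(config = NULL, ages = 35:45,
                    perspective = c("societal", "patient"),
                    n = NULL, seed = NULL, wtp = NULL, outdir = ".") {
  perspective <- match.arg(perspective)
  inputs <- resolve_inputs(config)
  if (is.null(n)) n <- inputs$settings$psa_replicates
  if (is.null(seed)) seed <- inputs$settings$psa_seed
  if (is.null(wtp)) wtp <- inputs$settings$wtp_threshold
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(inputs, ages, perspective, n_replicates = n, seed = seed)
  files <- write_report_csv(
    currency_headers(psa_summary(psa), "AUD"),
    file.path(outdir, "psa_summary.csv"))
  for (age in ages) {
    planes <- list()
    for (alt in setdiff(ART_STRATEGIES, "standard")) {
      if (alt == "social_freezing" && age < 40) next
      pl <- ce_plane(psa, age, alt)
      pl$alternative <- alt
      planes[[alt]] <- pl
    }
    files <- c(files, write_report_csv(
      do.call(rbind, planes),
      file.path(outdir, sprintf("ce_plane_%d.csv", age))))
  }
  grid <- sort(unique(c(seq(0, 2 * wtp, length.out = 11), wtp)))
  files <- c(files, write_report_csv(ceac(psa, grid),
                                     file.path(outdir, "ceac.csv")))
  files <- c(files, write_manifest(outdir, files, inputs,
                                   list(mode = "psa", perspective = perspective,
                                        n_replicates = n, seed = seed,
                                        wtp = wtp, ages = range(ages))))
  stopifnot(all(file.exists(files)))
  invisible(files)
}
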