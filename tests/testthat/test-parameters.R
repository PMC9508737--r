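test_that("built-in fixture reproduces the published probability tables", {
  fx <- builtin_fixture()
  expect_equal(
    unname(fx$rates$autologous),
    c(0.325, 0.286, 0.249, 0.213, 0.179, 0.160, 0.142, 0.107, 0.074, 0.043, 0.014)
  )
  expect_equal(names(fx$rates$autologous), as.character(35:45))
  expect_equal(
    unname(fx$rates$pgta),
    c(0.337, 0.295, 0.244, 0.194, 0.166, 0.153, 0.149, 0.147, 0.140, 0.120, 0.082)
  )
  expect_equal(unname(fx$rates$social_freezing),
               c(0.351, 0.338, 0.325, 0.313, 0.300, 0.287))
  expect_equal(names(fx$rates$social_freezing), as.character(40:45))
  expect_equal(
    unname(fx$rates$donor),
    c(0.380, 0.380, 0.380, 0.317, 0.317, 0.317, 0.329, 0.329, 0.378, 0.378, 0.333)
  )
  expect_equal(fx$procedures$opu,
               c("35-39" = 0.93, "40-44" = 0.90, "45" = 0.85))
  expect_equal(fx$procedures$progression,
               c("35-39" = 0.765, "40-44" = 0.707, "45" = 0.707))
})

test_that("built-in fixture reproduces the published cost table and settings", {
  fx <- builtin_fixture()
  co <- fx$costs
  row <- function(it) co[co$item == it, ]
  expect_equal(row("cancelled_cycle")$medicare_rebate, 1463)
  expect_equal(row("cancelled_cycle")$out_of_pocket, 1909)
  expect_equal(row("complete_fresh_fet_autologous")$medicare_rebate, 6522)
  expect_equal(row("complete_fresh_fet_autologous")$out_of_pocket, 4325)
  expect_equal(row("fet_cycle")$medicare_rebate, 626)
  expect_equal(row("fet_cycle")$out_of_pocket, 1023)
  expect_equal(row("pgta")$out_of_pocket, 1813)
  expect_equal(row("pgta")$medicare_rebate, 0)
  expect_equal(row("complete_donor_cycle")$out_of_pocket, 11720)
  expect_equal(row("oocyte_storage_per_year")$out_of_pocket, 260)
  expect_equal(row("social_freezing_banking")$out_of_pocket, 9305)
  expect_equal(row("social_freezing_thaw_total")$out_of_pocket, 3300)
  expect_equal(fx$settings$ppp_aud_per_usd, 1.41)
  expect_equal(fx$settings$wtp_threshold, 50000)
  expect_equal(fx$settings$psa_replicates, 10000)
  expect_equal(fx$settings$pgta_subsequent_cycle_multiplier, 0.90)
  expect_equal(fx$settings$freeze_age, 32)
  expect_equal(fx$settings$return_rate, 1.0)
})

test_that("item_cost applies the perspective rule", {
  fx <- builtin_fixture()
  expect_equal(item_cost(fx, "complete_fresh_fet_autologous", "societal"),
               6522 + 4325)
  expect_equal(item_cost(fx, "complete_fresh_fet_autologous", "patient"), 4325)
  expect_equal(item_cost(fx, c("cancelled_cycle", "cancelled_cycle"), "societal"),
               2 * (1463 + 1909))
  expect_equal(item_cost(fx, character(0)), 0)
  expect_error(item_cost(fx, "no_such_item"), "unknown cost item")
})

test_that("YAML round trip is lossless and overrides merge onto defaults", {
  fx <- builtin_fixture()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_inputs(fx, path)
  back <- load_inputs(path)
  expect_equal(back$rates, fx$rates)
  expect_equal(back$procedures, fx$procedures)
  expect_equal(back$costs, fx$costs)
  expect_equal(back$settings, fx$settings)

  minimal <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(settings = list(psa_seed = 99L)), minimal)
  got <- load_inputs(minimal)
  expect_equal(got$settings$psa_seed, 99L)
  got$settings$psa_seed <- fx$settings$psa_seed
  expect_equal(got$rates, fx$rates)
  expect_equal(got$settings, fx$settings)
})

test_that("validation rejects out-of-range and unknown keys by name", {
  fx <- builtin_fixture()
  bad <- fx
  bad$rates$autologous[["37"]] <- 1.2
  expect_error(validate_inputs(bad), "autologous.*37.*outside")
  bad <- fx
  bad$costs$out_of_pocket[2] <- -5
  expect_error(validate_inputs(bad), "out_of_pocket")
  bad <- fx
  bad$settings$return_rate <- 1.5
  expect_error(validate_inputs(bad), "return_rate")

  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(rates = list(autologous = list(`35` = 1.2))), path)
  expect_error(load_inputs(path), "outside \\[0,1\\]")
  yaml::write_yaml(list(settings = list(not_a_key = 1)), path)
  expect_error(load_inputs(path), "not_a_key")
})

test_that("logistic age interpolation is exact on logistic data and monotone", {
  # flat input: slope zero
  flat <- interpolate_age_rates(c(35, 45), c(0.5, 0.5), 35:45)
  expect_equal(unname(flat), rep(0.5, 11), tolerance = 1e-12)

  # generate-then-refit: rates sampled exactly from plogis(10 - 0.3 * age)
  ages <- 35:45
  truth <- stats::plogis(10 - 0.3 * ages)
  fit <- interpolate_age_rates(ages, truth, ages)
  expect_equal(unname(fit), unname(truth), tolerance = 1e-6)

  # value between two anchors lies strictly between them
  mid <- interpolate_age_rates(c(35, 39), c(0.337, 0.166), 37)
  expect_gt(mid[["37"]], 0.166)
  expect_lt(mid[["37"]], 0.337)

  # monotone anchors give a monotone schedule
  dec <- interpolate_age_rates(c(35, 40, 45), c(0.4, 0.2, 0.1), 35:45)
  expect_true(all(diff(dec) < 0))

  expect_error(interpolate_age_rates(35, 0.5, 35:45), "2 distinct ages")
  expect_error(interpolate_age_rates(c(35, 35), c(0.4, 0.5), 36), "2 distinct ages")
  expect_error(interpolate_age_rates(c(35, 40), c(0, 0.5), 36), "inside \\(0, 1\\)")
})

test_that("age bands cover the modelled range without overlap", {
  expect_equal(age_band(35), "35-39")
  expect_equal(age_band(39), "35-39")
  expect_equal(age_band(40), "40-44")
  expect_equal(age_band(44), "40-44")
  expect_equal(age_band(45), "45")
  expect_error(age_band(34), "outside")
  expect_error(age_band(46), "outside")
})

test_that("rate table export has one row per (table, age)", {
  tf <- rate_table_frame(builtin_fixture())
  expect_equal(nrow(tf), 11 + 11 + 6 + 11)
  expect_true(all(tf$rate >= 0 & tf$rate <= 1))
})
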