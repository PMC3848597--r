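# Synthetic survey generator: conservation, determinism, error channels.

small_market <- function(seed = 1, ...) {
  market_config(
    n_outlets = c(wholesale = 15, retail = 20),
    n_incomputable = 0,
    seed = seed,
    ...
  )
}

test_that("truth ledgers satisfy the stock-flow identity exactly", {
  for (seed in c(1, 7, 1234)) {
    truth <- simulate_truth(small_market(seed))
    ra <- ra_estimate(
      truth$stock1_units, truth$delivered_units,
      truth$disposed_units, truth$stock2_units
    )
    expect_identical(ra, truth$true_sales_units)
    expect_true(all(truth$stock2_units >= 0))
    expect_true(all(truth$stock1_units >= 0))
  }
})

test_that("full zero inflation yields an all-zero sales ledger", {
  zero_sales <- lapply(
    market_config()$sales,
    function(lv) lapply(lv, function(s) list(pi0 = 1, mu = s$mu, k = s$k))
  )
  truth <- simulate_truth(small_market(3, sales = zero_sales, outlier = c(p = 0, multiplier = 10)))
  expect_true(all(truth$true_sales_units == 0))
})

test_that("the same seed reproduces the ledger and records exactly", {
  t1 <- simulate_truth(small_market(42))
  t2 <- simulate_truth(small_market(42))
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  s1 <- apply_measurement(t1, measurement_config())
  s2 <- apply_measurement(t2, measurement_config())
  expect_identical(s1, s2)
  t3 <- simulate_truth(small_market(43))
  expect_false(identical(t1$true_sales_units, t3$true_sales_units))
})

test_that("identity measurement reproduces truth; pipeline bias and sd are 0", {
  truth <- simulate_truth(small_market(11))
  survey <- apply_measurement(truth, measurement_identity())
  bp <- build_pairs(survey, attr(truth, "products"))
  expect_true(all(bp$pairs$included))
  scale <- ifelse(truth$category == "rdt", 1, truth$units_per_aetd)
  expect_identical(bp$pairs$ra_volume, truth$true_sales_units / scale)
  expect_identical(bp$pairs$rc_volume, bp$pairs$ra_volume)
  d <- make_differences(aggregate_outlets(bp$pairs))
  bs <- bias_sd(d$d)
  expect_identical(bs$bias, 0)
  expect_identical(bs$sd, 0)
})

test_that("pure multiplicative under-recall recovers the analytic bias", {
  # rc = beta * v exactly (no noise, no truncation, no heaping), so the
  # outlet-level difference is (1 - beta) * total true volume
  market <- market_config(
    n_outlets = c(wholesale = 0, retail = 500),
    n_incomputable = 0,
    outlier = c(p = 0, multiplier = 10),
    seed = 8
  )
  meas <- measurement_identity()
  meas$beta <- 0.7
  truth <- simulate_truth(market)
  survey <- apply_measurement(truth, meas)
  bp <- build_pairs(survey, attr(truth, "products"))
  agg <- aggregate_outlets(bp$pairs)
  am <- agg[agg$category == "antimalarial", ]
  bs <- bias_sd(make_differences(am)$d)
  scale <- ifelse(truth$category == "rdt", 1, truth$units_per_aetd)
  vol <- truth$true_sales_units / scale
  truth_am <- tapply(
    vol[truth$category == "antimalarial"],
    truth$outlet_id[truth$category == "antimalarial"], sum
  )
  expect_gt(bs$bias, 0) # RA exceeds RC under under-recall
  expect_equal(bs$bias, 0.3 * mean(truth_am), tolerance = 1e-10)
})

test_that("nonresponse rates match configured probabilities within 99% bounds", {
  market <- market_config(
    n_outlets = c(wholesale = 150, retail = 150),
    n_incomputable = 0, seed = 5
  )
  meas <- measurement_identity()
  meas$p_not_remembered <- c(wholesale = 0.2, retail = 0.2)
  meas$p_stock_refused <- c(wholesale = 0.1, retail = 0.1)
  truth <- simulate_truth(market)
  survey <- apply_measurement(truth, meas)
  n <- nrow(survey)
  expect_gte(n, 1000)
  binom_bounds <- function(p) p + c(-1, 1) * qnorm(0.995) * sqrt(p * (1 - p) / n)
  rate_nr <- mean(survey$rc_status == "not_remembered")
  b <- binom_bounds(0.2)
  expect_gt(rate_nr, b[1])
  expect_lt(rate_nr, b[2])
  rate_sr <- mean(survey$stock1_status == "refused")
  b <- binom_bounds(0.1)
  expect_gt(rate_sr, b[1])
  expect_lt(rate_sr, b[2])
})

test_that("more recall noise never shrinks the sd of differences (common draws)", {
  # high-volume market so zero-truncation of recall never binds
  market <- market_config(
    n_outlets = c(wholesale = 0, retail = 80),
    sales = list(
      wholesale = list(
        antimalarial = list(pi0 = 0, mu = 30, k = 10),
        rdt = list(pi0 = 0, mu = 30, k = 10)
      ),
      retail = list(
        antimalarial = list(pi0 = 0, mu = 30, k = 10),
        rdt = list(pi0 = 0, mu = 30, k = 10)
      )
    ),
    n_incomputable = 0,
    outlier = c(p = 0, multiplier = 10),
    seed = 17
  )
  truth <- simulate_truth(market)
  sds <- vapply(c(0, 0.5, 1, 2, 4, 8), function(sig) {
    meas <- measurement_identity()
    meas$sigma_rc <- sig
    survey <- apply_measurement(truth, meas)
    bp <- build_pairs(survey, attr(truth, "products"))
    agg <- aggregate_outlets(bp$pairs)
    bias_sd(make_differences(agg[agg$category == "antimalarial", ])$d)$sd
  }, numeric(1))
  expect_true(all(diff(sds) >= 0))
})

test_that("generate_survey writes a self-consistent, reproducible bundle", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- generate_survey(small_market(9), measurement_config(), dir1)
  m2 <- generate_survey(small_market(9), measurement_config(), dir2)
  for (f in c("products.csv", "survey.csv", "truth.csv", "manifest.json")) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(
      readLines(file.path(dir1, f)), readLines(file.path(dir2, f))
    )
  }
  expect_identical(m1$config_hash, m2$config_hash)

  survey <- readr::read_csv(
    file.path(dir1, "survey.csv"),
    show_col_types = FALSE
  )
  truth <- readr::read_csv(
    file.path(dir1, "truth.csv"),
    show_col_types = FALSE
  )
  # truth covers every survey record one-to-one
  expect_equal(
    sort(paste(survey$outlet_id, survey$product_id)),
    sort(paste(truth$outlet_id, truth$product_id))
  )
  # the analysis path round-trips from the files alone
  analysis <- suppressMessages(analyze_survey(
    file.path(dir1, "survey.csv"), file.path(dir1, "products.csv")
  ))
  expect_s3_class(analysis, "sls_analysis")
  expect_equal(analysis$manifest$n_records_read, m1$n_records)
})
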