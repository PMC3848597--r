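# Stock-flow estimation, pairing, exclusion rules, response accounting.

test_that("stock-flow estimate is opening + delivered - disposed - closing", {
  expect_equal(ra_estimate(10, 5, 1, 8), 6)
  expect_equal(ra_estimate(7, 0, 0, 7), 0)
  expect_equal(ra_estimate(2, 0, 0, 5), -3)
})

test_that("sign screening keeps zero and excludes strictly negative estimates", {
  expect_equal(screen_ra(6), "valid")
  expect_equal(screen_ra(0), "valid")
  expect_equal(screen_ra(-3), "negative_excluded")
  expect_equal(screen_ra(c(1, 0, -0.001)), c("valid", "valid", "negative_excluded"))
})

test_that("a fully observed record yields an analyzable pair in AETDs", {
  bp <- build_pairs(fixture_record(), fixture_products())
  p <- bp$pairs
  expect_equal(nrow(p), 1)
  # stocks 27 and 12 units, no flow: RA = 15 units = 0.625 AETD; RC = 15 units
  expect_equal(p$ra_volume, 0.625)
  expect_equal(p$rc_volume, 0.625)
  expect_equal(p$ra_status, "valid")
  expect_equal(p$rc_status, "valid")
  expect_true(p$included)
  expect_equal(nrow(bp$exclusions), 0)
})

test_that("tin-held stock flows into the audit estimate", {
  rec <- fixture_record(
    s1_packs = 0, s1_loose = 0, s1_tin = c(2.5, 5, 100), # 50 units
    s2_packs = 0, s2_loose = 2, rc = 48
  )
  bp <- build_pairs(rec, fixture_products())
  expect_equal(bp$pairs$ra_volume, (50 - 2) / 24)
  expect_equal(bp$pairs$rc_volume, 2)
})

test_that("a nonresponse code in any RA component voids the RA estimate", {
  for (field in c(
    "stock1_status", "stock2_status", "delivered_status", "disposed_status"
  )) {
    args <- list()
    args[[field]] <- "refused"
    rec <- do.call(fixture_record, args)
    bp <- build_pairs(rec, fixture_products())
    expect_equal(bp$pairs$ra_status, "unavailable")
    expect_equal(bp$pairs$rc_status, "valid")
    expect_false(bp$pairs$included)
    expect_equal(bp$exclusions$reason, "ra_unavailable")
  }
})

test_that("a not-remembered recall voids RC but keeps the RA side countable", {
  rec <- fixture_record(rc_status = "not_remembered")
  bp <- build_pairs(rec, fixture_products())
  expect_equal(bp$pairs$ra_status, "valid")
  expect_equal(bp$pairs$rc_status, "unavailable")
  expect_false(bp$pairs$included)
  expect_equal(bp$exclusions$reason, "rc_unavailable")
})

test_that("negative RA estimates are excluded with the value retained in the log", {
  rec <- fixture_record(s1_packs = 0, s1_loose = 2, s2_packs = 0, s2_loose = 5)
  bp <- build_pairs(rec, fixture_products())
  expect_equal(bp$pairs$ra_status, "negative_excluded")
  expect_false(bp$pairs$included)
  expect_equal(bp$exclusions$reason, "negative_ra")
  expect_equal(bp$exclusions$ra_value, -3 / 24)
})

test_that("an AETD-incomputable product is excluded exactly once and never analyzed", {
  rec <- fixture_record(product_id = "AM-NA")
  bp <- build_pairs(rec, fixture_products())
  expect_false(bp$pairs$included)
  expect_true(is.na(bp$pairs$ra_volume))
  log_rows <- bp$exclusions[bp$exclusions$reason == "aetd_incomputable", ]
  expect_equal(nrow(log_rows), 1)
  expect_equal(log_rows$product_id, "AM-NA")
  expect_equal(nrow(aggregate_outlets(bp$pairs)), 0)
})

test_that("unknown products and duplicate outlet x product records are hard errors", {
  rec <- fixture_record(product_id = "NOPE")
  expect_error(build_pairs(rec, fixture_products()), "unknown product_id")
  recs <- dplyr::bind_rows(fixture_record(), fixture_record())
  expect_error(build_pairs(recs, fixture_products()), "duplicate")
})

test_that("every record lands exactly once in analyzed or excluded-with-reason", {
  recs <- dplyr::bind_rows(
    fixture_record("O1"),
    fixture_record("O2", rc_status = "refused"),
    fixture_record("O3", stock2_status = "missing"),
    fixture_record("O4", product_id = "AM-NA"),
    fixture_record("O5", s1_packs = 0, s1_loose = 0, s2_packs = 1),
    fixture_record("O6", product_id = "RDT-1", s1_packs = 9, s1_loose = 0,
                   s2_packs = 2, s2_loose = 0, rc = 7)
  )
  bp <- build_pairs(recs, fixture_products())
  expect_equal(sum(bp$pairs$included) + nrow(bp$exclusions), nrow(recs))
  expect_true(all(!is.na(bp$exclusions$reason)))
})

test_that("outlet aggregation sums per category and never pools categories", {
  pairs <- tibble::tibble(
    outlet_id = c("O1", "O1", "O1", "O2"),
    outlet_level = "wholesale",
    product_id = c("AM-CQ", "AM-AS", "RDT-1", "AM-CQ"),
    category = c("antimalarial", "antimalarial", "rdt", "antimalarial"),
    ra_volume = c(2, 3, 10, 1),
    rc_volume = c(1, 3, 9, 2),
    ra_status = "valid",
    rc_status = "valid",
    included = TRUE,
    exclusion_reason = NA_character_
  )
  agg <- aggregate_outlets(pairs)
  expect_equal(nrow(agg), 3)
  o1am <- agg[agg$outlet_id == "O1" & agg$category == "antimalarial", ]
  expect_equal(o1am$ra_total, 5)
  expect_equal(o1am$rc_total, 4)
  expect_equal(o1am$n_products, 2L)
  expect_equal(agg[agg$category == "rdt", ]$ra_total, 10)

  # permutation invariance of the input order
  perm <- pairs[sample(nrow(pairs)), ]
  expect_equal(aggregate_outlets(perm), agg)
})

test_that("response accounting reproduces survey-report percentages and closure", {
  n <- 104
  status <- rep(c("collected", "not_remembered", "refused"), c(76, 17, 11))
  recs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    fixture_record(outlet_id = sprintf("W%03d", i), rc_status = status[i])
  }))
  bp <- build_pairs(recs, fixture_products())
  acc <- response_accounting(recs, bp$pairs)
  get <- function(meas) acc[acc$measure == meas, ]
  expect_equal(get("surveyed")$n, 104)
  expect_equal(get("rc_collected")$n, 76)
  expect_equal(get("rc_collected")$pct, 73.1)
  expect_equal(get("rc_not_remembered")$pct, 16.3)
  expect_equal(get("rc_refused")$pct, 10.6)
  # closure: RC status counts sum to the surveyed total
  rc_rows <- acc[grepl("^rc_", acc$measure), ]
  expect_equal(sum(rc_rows$n), 104)
  # all RA components collected here, so both RA rows equal the total
  expect_equal(get("ra_calculated_nonneg")$n, 104)
  expect_equal(get("ra_calculated_incl_neg")$n, 104)
})

test_that("RA accounting with negatives dominates the nonnegative count", {
  recs <- dplyr::bind_rows(
    fixture_record("O1"),
    fixture_record("O2", s1_packs = 0, s1_loose = 0, s2_packs = 1),
    fixture_record("O3", stock1_status = "refused")
  )
  bp <- build_pairs(recs, fixture_products())
  acc <- response_accounting(recs, bp$pairs)
  n_nonneg <- acc$n[acc$measure == "ra_calculated_nonneg"]
  n_incl <- acc$n[acc$measure == "ra_calculated_incl_neg"]
  expect_equal(n_nonneg, 1)
  expect_equal(n_incl, 2)
  expect_true(n_incl >= n_nonneg)
  # stock refusal at either visit voids the stock component
  expect_equal(acc$n[acc$measure == "stock_refused"], 1)
  expect_equal(acc$n[acc$measure == "stock_collected"], 2)
})
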