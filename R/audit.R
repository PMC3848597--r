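#' Retail-audit (stock-flow) sales estimate
#'
#' Sales over the inter-visit interval inferred from the stock-flow
#' identity: opening stock, plus deliveries received between the two
#' visits, minus quantities disposed of (thrown away, transferred, sent
#' back or confiscated), minus closing stock. All four terms must be on the
#' same scale (base units, AETDs or tests); the result is on that scale.
#'
#' The estimate may be negative — stock that grew with no recorded
#' delivery — which indicates a data-collection error. Sign screening is a
#' separate step ([screen_ra()]); this function never drops values.
#'
#' @param stock1 Stock at the first visit (SLS1).
#' @param delivered Quantities delivered between visits.
#' @param disposed Quantities disposed of between visits.
#' @param stock2 Stock at the second visit (SLS2).
#' @return Signed numeric vector `stock1 + delivered - disposed - stock2`.
#' @examples
#' ra_estimate(10, 5, 1, 8) # 6
#' ra_estimate(2, 0, 0, 5) # -3: flagged downstream, never analyzed
#' @export
ra_estimate <- function(stock1, delivered, disposed, stock2) {
  stock1 + delivered - disposed - stock2
}

#' Screen a retail-audit estimate for sign
#'
#' Negative stock-flow estimates indicate data-collection errors and are
#' excluded from the analysis (the value is retained in the exclusion log).
#' Zero is a legitimate estimate: an outlet may simply have sold nothing.
#'
#' @param value Signed volume(s) from [ra_estimate()].
#' @return Character vector: `"valid"` (>= 0) or `"negative_excluded"`.
#' @export
screen_ra <- function(value) {
  ifelse(value < 0, "negative_excluded", "valid")
}

# Measurement-field status codes. "collected" marks an observed quantity;
# the other three are the item-nonresponse codes tracked in the response
# accounting.
sls_status_codes <- c("collected", "refused", "not_remembered", "missing")

survey_required_cols <- c(
  "outlet_id", "outlet_level", "outlet_type", "product_id",
  "stock1_packs", "stock1_loose", "stock1_tin_height",
  "stock1_tin_height_full", "stock1_tin_units", "stock1_counted",
  "stock1_status",
  "stock2_packs", "stock2_loose", "stock2_tin_height",
  "stock2_tin_height_full", "stock2_tin_units", "stock2_counted",
  "stock2_status",
  "delivered_units", "delivered_status",
  "disposed_units", "disposed_status",
  "rc_sold_units", "rc_status"
)

#' Read and validate sales-level-survey records
#'
#' One row per outlet x product. Each of the five measurement fields
#' (stock at SLS1, stock at SLS2, delivered, disposed, recalled sales) is
#' either a quantity or exactly one status code in
#' `refused` / `not_remembered` / `missing`; a field with neither a
#' quantity nor a recognized status is a hard validation error, as is a
#' negative recalled quantity.
#'
#' @param path CSV file path or a data frame.
#' @return A validated tibble of survey records.
#' @export
read_survey <- function(path) {
  rec <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  missing_cols <- setdiff(survey_required_cols, names(rec))
  if (length(missing_cols) > 0) {
    stop("survey table lacks columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(rec$outlet_level %in% c("wholesale", "retail"))) {
    stop("survey: outlet_level must be 'wholesale' or 'retail'",
      call. = FALSE
    )
  }
  for (st in grep("_status$", survey_required_cols, value = TRUE)) {
    bad <- !rec[[st]] %in% sls_status_codes
    if (any(bad)) {
      stop("survey: ", st, " contains values outside {",
        paste(sls_status_codes, collapse = ", "), "}",
        call. = FALSE
      )
    }
  }
  chk_quantity <- function(status_col, value_cols) {
    coll <- rec[[status_col]] == "collected"
    for (v in value_cols) {
      if (any(coll & is.na(rec[[v]]))) {
        stop("survey: ", v, " is missing on rows where ", status_col,
          " = 'collected'",
          call. = FALSE
        )
      }
    }
  }
  chk_quantity("stock1_status", c("stock1_packs", "stock1_loose"))
  chk_quantity("stock2_status", c("stock2_packs", "stock2_loose"))
  chk_quantity("delivered_status", "delivered_units")
  chk_quantity("disposed_status", "disposed_units")
  chk_quantity("rc_status", "rc_sold_units")
  rc_ok <- rec$rc_status == "collected"
  if (any(rc_ok & rec$rc_sold_units < 0)) {
    stop("survey: recalled sales (rc_sold_units) cannot be negative",
      call. = FALSE
    )
  }
  rec
}

stock_units <- function(rec, visit) {
  p <- function(col) rec[[paste0(visit, "_", col)]]
  collected <- p("status") == "collected"
  out <- rep(NA_real_, nrow(rec))
  if (any(collected)) {
    out[collected] <- total_units(
      full_packs = p("packs")[collected],
      pack_size = rec$pack_size[collected],
      loose_units = p("loose")[collected],
      tin_height_measured = p("tin_height")[collected],
      tin_height_full = p("tin_height_full")[collected],
      tin_units_full = p("tin_units")[collected]
    )
  }
  out
}

#' Pair retail-audit and recall estimates per outlet x product
#'
#' The core record-level step: standardizes stock, delivery, disposal and
#' recall quantities, computes the stock-flow (RA) estimate, screens its
#' sign, and decides for every record whether it enters the agreement
#' analysis. A record is analyzable only when both methods yield a valid
#' estimate: a nonresponse code in any of the four RA components voids the
#' RA estimate, a nonresponse code on the recall question voids the RC
#' estimate, anti-malarials that cannot be expressed in AETDs are excluded,
#' and strictly negative RA estimates are excluded as data-collection
#' errors. Every exclusion is logged with its reason, so each input record
#' is accounted for exactly once across analyzed / excluded.
#'
#' The stock-flow difference is computed on base units and converted to
#' volume once: the AETD divisor is constant within a product, so this is
#' algebraically identical to converting each term first, and it keeps the
#' conservation identity exact in floating point.
#'
#' @param records Survey records from [read_survey()] (or a conforming data
#'   frame).
#' @param products Product catalogue from [read_products()].
#' @return A list with `pairs` (one row per record: volumes, method
#'   statuses, `included` flag) and `exclusions` (one row per excluded
#'   record: `outlet_id`, `product_id`, `reason`, `ra_value`).
#' @export
build_pairs <- function(records, products) {
  records <- read_survey(records)
  products <- read_products(products)

  unknown <- setdiff(records$product_id, products$product_id)
  if (length(unknown) > 0) {
    stop("build_pairs: unknown product_id: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  key <- paste(records$outlet_id, records$product_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("build_pairs: duplicate outlet x product records", call. = FALSE)
  }

  rec <- dplyr::left_join(
    records,
    products[, c(
      "product_id", "category", "pack_size", "units_per_aetd",
      "incomputable"
    )],
    by = "product_id"
  )

  s1 <- stock_units(rec, "stock1")
  s2 <- stock_units(rec, "stock2")
  del <- ifelse(rec$delivered_status == "collected", rec$delivered_units,
    NA_real_
  )
  dis <- ifelse(rec$disposed_status == "collected", rec$disposed_units,
    NA_real_
  )
  rc_units <- ifelse(rec$rc_status == "collected", rec$rc_sold_units,
    NA_real_
  )

  ra_present <- !is.na(s1) & !is.na(s2) & !is.na(del) & !is.na(dis)
  rc_present <- !is.na(rc_units)

  ra_units <- ifelse(ra_present, ra_estimate(s1, del, dis, s2), NA_real_)
  computable <- !rec$incomputable

  divisor <- ifelse(rec$category == "rdt", 1, rec$units_per_aetd)
  ra_volume <- ifelse(computable & ra_present, ra_units / divisor, NA_real_)
  rc_volume <- ifelse(computable & rc_present, rc_units / divisor, NA_real_)

  ra_status <- dplyr::case_when(
    !ra_present | !computable ~ "unavailable",
    ra_volume < 0 ~ "negative_excluded",
    TRUE ~ "valid"
  )
  rc_status <- ifelse(rc_present & computable, "valid", "unavailable")
  included <- ra_status == "valid" & rc_status == "valid"

  reason <- dplyr::case_when(
    included ~ NA_character_,
    rec$incomputable ~ "aetd_incomputable",
    !ra_present & !rc_present ~ "ra_and_rc_unavailable",
    !ra_present ~ "ra_unavailable",
    ra_status == "negative_excluded" ~ "negative_ra",
    !rc_present ~ "rc_unavailable"
  )

  pairs <- tibble::tibble(
    outlet_id = rec$outlet_id,
    outlet_level = rec$outlet_level,
    product_id = rec$product_id,
    category = rec$category,
    ra_volume = ra_volume,
    rc_volume = rc_volume,
    ra_status = ra_status,
    rc_status = rc_status,
    included = included,
    exclusion_reason = reason
  )
  exclusions <- tibble::tibble(
    outlet_id = rec$outlet_id[!included],
    product_id = rec$product_id[!included],
    reason = reason[!included],
    ra_value = ra_volume[!included]
  )
  list(pairs = pairs, exclusions = exclusions)
}

#' Sum paired estimates to single per-outlet totals
#'
#' In outlets selling more than one anti-malarial (or more than one RDT
#' product), the valid product-level RA estimates are summed, and likewise
#' the RC estimates, giving one total sales volume per outlet and method.
#' Anti-malarials (AETDs) and RDTs (tests) are never pooled: an outlet
#' yields at most one row per category. Only records where both methods are
#' valid contribute, so the two totals always describe the same products.
#'
#' @param pairs The `pairs` tibble from [build_pairs()].
#' @return Tibble with one row per outlet x category that has at least one
#'   analyzable pair: `outlet_id`, `outlet_level`, `category`, `ra_total`,
#'   `rc_total`, `n_products`.
#' @export
aggregate_outlets <- function(pairs) {
  kept <- dplyr::filter(pairs, .data$included)
  out <- dplyr::summarise(
    dplyr::group_by(
      kept, .data$outlet_id, .data$outlet_level, .data$category
    ),
    ra_total = sum(.data$ra_volume),
    rc_total = sum(.data$rc_volume),
    n_products = dplyr::n(),
    .groups = "drop"
  )
  stopifnot(all(out$ra_total >= 0), all(out$rc_total >= 0))
  dplyr::arrange(out, .data$outlet_level, .data$category, .data$outlet_id)
}

combine_stock_status <- function(s1, s2) {
  dplyr::case_when(
    s1 == "refused" | s2 == "refused" ~ "refused",
    s1 == "not_remembered" | s2 == "not_remembered" ~ "not_remembered",
    s1 == "missing" | s2 == "missing" ~ "missing",
    TRUE ~ "collected"
  )
}

#' Response accounting per stratum and method component
#'
#' Tabulates, for each outlet level x product category, how many surveyed
#' product observations yielded data under each method and how many were
#' lost to each nonresponse code: recalled sales (collected / not
#' remembered / refused / missing), stock data over both visits (a refusal
#' or gap at either visit voids the component), received and disposed
#' quantities, and the two audit rows — RA estimates calculable excluding
#' and including negative values. Percentages are of the products surveyed
#' in the stratum, to one decimal place. Each code group closes exactly:
#' counts sum to the surveyed total.
#'
#' @param records Survey records (validated or conforming).
#' @param pairs The `pairs` tibble from [build_pairs()] on the same records.
#' @return Long tibble: `outlet_level`, `category`, `measure`, `n`, `pct`.
#' @export
response_accounting <- function(records, pairs) {
  records <- tibble::as_tibble(records)
  rec <- dplyr::left_join(
    records,
    pairs[, c("outlet_id", "product_id", "category", "ra_status")],
    by = c("outlet_id", "product_id")
  )
  rec$stock_status <- combine_stock_status(rec$stock1_status, rec$stock2_status)

  count_block <- function(status, prefix) {
    lv <- factor(status, levels = sls_status_codes)
    tab <- table(lv)
    tibble::tibble(
      measure = paste0(prefix, "_", names(tab)),
      n = as.integer(tab)
    )
  }

  one_stratum <- function(df) {
    n_surv <- nrow(df)
    rows <- dplyr::bind_rows(
      tibble::tibble(measure = "surveyed", n = n_surv),
      count_block(df$rc_status, "rc"),
      tibble::tibble(
        measure = c("ra_calculated_nonneg", "ra_calculated_incl_neg"),
        n = c(
          sum(df$ra_status == "valid"),
          sum(df$ra_status %in% c("valid", "negative_excluded"))
        )
      ),
      count_block(df$stock_status, "stock"),
      count_block(df$delivered_status, "received"),
      count_block(df$disposed_status, "disposed")
    )
    rows$pct <- if (n_surv > 0) round(100 * rows$n / n_surv, 1) else 0
    rows
  }

  grp <- dplyr::group_by(rec, .data$outlet_level, .data$category)
  out <- dplyr::reframe(grp, one_stratum(dplyr::pick(dplyr::everything())))
  tibble::as_tibble(out)
}
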