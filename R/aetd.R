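#' Round half away from zero
#'
#' Commercial rounding for physical counts: .5 always rounds up, unlike
#' [base::round()]'s round-half-even. Used only where a fractional estimate
#' must become an integer count of physical units.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @return Integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Estimate loose tablets in a partially full tin
#'
#' Tablets kept loose in tins or pots cannot always be counted one by one in
#' the field; instead the height of the tablet column is measured with a
#' ruler and compared with the height and content of a full tin. The count
#' is estimated by linear proportion and rounded half-up to a whole tablet,
#' since physical stock is integer.
#'
#' @param height_measured Measured height of the tablets in the tin, in the
#'   same length unit as `height_full`. May be zero (empty tin).
#' @param height_full Height of the tablet column in a full tin. Must be
#'   strictly positive.
#' @param units_full Number of tablets in a full tin (integer >= 1).
#' @return Estimated tablet count, an integer in `[0, units_full]`.
#'   Vectorized over all three arguments.
#' @examples
#' estimate_tin_units(2.5, 5, 100) # half a tin of 100 -> 50
#' @export
estimate_tin_units <- function(height_measured, height_full, units_full) {
  n <- max(length(height_measured), length(height_full), length(units_full))
  height_measured <- rep_len(height_measured, n)
  height_full <- rep_len(height_full, n)
  units_full <- rep_len(units_full, n)

  ok <- !is.na(height_measured) & !is.na(height_full) & !is.na(units_full)
  if (any(ok & height_full <= 0)) {
    stop("estimate_tin_units: 'height_full' must be > 0", call. = FALSE)
  }
  if (any(ok & height_measured < 0)) {
    stop("estimate_tin_units: 'height_measured' must be >= 0", call. = FALSE)
  }
  if (any(ok & height_measured > height_full)) {
    stop("estimate_tin_units: 'height_measured' exceeds 'height_full'",
      call. = FALSE
    )
  }
  if (any(ok & units_full < 1)) {
    stop("estimate_tin_units: 'units_full' must be >= 1", call. = FALSE)
  }
  out <- round_half_up(height_measured / height_full * units_full)
  pmin(out, units_full)
}

#' Total base units in a stock observation
#'
#' A stock observation arrives through up to three channels: full packs,
#' loose units, and tablets in a partially full tin. This collapses them to
#' a single count of base units (tablets, ampoules or tests).
#'
#' All arguments are vectorized. Tin fields must be all present or all
#' absent (`NA`) within an element; a partially specified tin is an error.
#'
#' @param full_packs Count of unopened packs (>= 0).
#' @param pack_size Base units per pack (integer >= 1).
#' @param loose_units Count of loose units outside packs and tins (>= 0).
#' @param tin_height_measured,tin_height_full,tin_units_full Tin channel as
#'   in [estimate_tin_units()]; all `NA` when there is no tin.
#' @return Numeric vector of total base units.
#' @export
total_units <- function(full_packs, pack_size, loose_units = 0,
                        tin_height_measured = NA_real_,
                        tin_height_full = NA_real_,
                        tin_units_full = NA_real_) {
  n <- max(
    length(full_packs), length(pack_size), length(loose_units),
    length(tin_height_measured), length(tin_height_full),
    length(tin_units_full)
  )
  full_packs <- rep_len(full_packs, n)
  pack_size <- rep_len(pack_size, n)
  loose_units <- rep_len(loose_units, n)
  tin_height_measured <- rep_len(tin_height_measured, n)
  tin_height_full <- rep_len(tin_height_full, n)
  tin_units_full <- rep_len(tin_units_full, n)

  if (any(full_packs < 0 | loose_units < 0, na.rm = TRUE)) {
    stop("total_units: pack and loose counts must be >= 0", call. = FALSE)
  }
  if (any(pack_size < 1, na.rm = TRUE)) {
    stop("total_units: 'pack_size' must be >= 1", call. = FALSE)
  }
  tin_na <- cbind(
    is.na(tin_height_measured), is.na(tin_height_full), is.na(tin_units_full)
  )
  mixed <- rowSums(tin_na) %in% c(1L, 2L)
  if (any(mixed)) {
    stop("total_units: tin fields must be all present or all absent",
      call. = FALSE
    )
  }
  has_tin <- rowSums(tin_na) == 0L
  tin <- numeric(n)
  if (any(has_tin)) {
    tin[has_tin] <- estimate_tin_units(
      tin_height_measured[has_tin], tin_height_full[has_tin],
      tin_units_full[has_tin]
    )
  }
  full_packs * pack_size + loose_units + tin
}

#' Convert base units to standardized volume
#'
#' Anti-malarial volumes are expressed in adult equivalent treatment doses
#' (AETDs): one AETD is the quantity of a drug making up one full adult
#' treatment course, so `units / units_per_aetd`. RDT volumes stay in
#' single-test units. Volumes are real-valued: a sold quantity may be a
#' fraction of a course, and no rounding is applied at the volume level.
#'
#' Anti-malarial products whose `units_per_aetd` is unknown cannot be
#' standardized ("AETD-incomputable"); converting them is an error, and
#' callers are expected to screen with [aetd_incomputable()] and log the
#' exclusion instead.
#'
#' @param units Count of base units (vectorized).
#' @param category `"antimalarial"` or `"rdt"` (vectorized).
#' @param units_per_aetd Base units per adult course; ignored for RDTs.
#' @return Numeric volume: AETDs for anti-malarials, tests for RDTs.
#' @seealso [aetd_incomputable()]
#' @export
to_aetd <- function(units, category, units_per_aetd = NA_real_) {
  n <- max(length(units), length(category), length(units_per_aetd))
  units <- rep_len(units, n)
  category <- rep_len(category, n)
  units_per_aetd <- rep_len(units_per_aetd, n)

  bad_cat <- !category %in% c("antimalarial", "rdt")
  if (any(bad_cat)) {
    stop("to_aetd: unknown category ",
      paste(unique(category[bad_cat]), collapse = ", "),
      call. = FALSE
    )
  }
  incomputable <- aetd_incomputable(category, units_per_aetd)
  if (any(incomputable & !is.na(units))) {
    stop(
      "to_aetd: anti-malarial without 'units_per_aetd' is AETD-incomputable; ",
      "screen with aetd_incomputable() and exclude",
      call. = FALSE
    )
  }
  ifelse(category == "rdt", units, units / units_per_aetd)
}

#' Flag products whose volumes cannot be standardized
#'
#' An anti-malarial with no usable `units_per_aetd` (missing or
#' non-positive) cannot be expressed in AETDs and must leave the sales
#' volume estimation, with the exclusion logged. RDTs are never flagged:
#' their volumes are test counts and need no conversion.
#'
#' @param category `"antimalarial"` or `"rdt"` (vectorized).
#' @param units_per_aetd Base units per adult course, `NA` when unknown.
#' @return Logical vector.
#' @export
aetd_incomputable <- function(category, units_per_aetd) {
  n <- max(length(category), length(units_per_aetd))
  category <- rep_len(category, n)
  units_per_aetd <- rep_len(units_per_aetd, n)
  category == "antimalarial" &
    (is.na(units_per_aetd) | units_per_aetd <= 0)
}

#' Read and validate a product catalogue
#'
#' The catalogue holds product identity plus the quantities needed to
#' express volumes in AETDs (or tests): one row per product with columns
#' `product_id`, `category` (`antimalarial`/`rdt`), `drug_name`,
#' `strength_mg` (may be blank), `form` (`tablet`/`injectable`/`test`),
#' `pack_size`, and `units_per_aetd` (blank means the product is
#' AETD-incomputable). `units_per_aetd` is deliberately user-supplied —
#' typically derived from WHO treatment guidelines or the literature —
#' rather than embedded in the package.
#'
#' @param path CSV file path, or a data frame already in memory.
#' @return A tibble with one row per product and an added logical column
#'   `incomputable`.
#' @export
read_products <- function(path) {
  prod <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  required <- c(
    "product_id", "category", "drug_name", "strength_mg", "form",
    "pack_size", "units_per_aetd"
  )
  missing_cols <- setdiff(required, names(prod))
  if (length(missing_cols) > 0) {
    stop("products table lacks columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(prod$product_id)) {
    stop("products table has duplicated product_id", call. = FALSE)
  }
  if (!all(prod$category %in% c("antimalarial", "rdt"))) {
    stop("products: category must be 'antimalarial' or 'rdt'", call. = FALSE)
  }
  if (!all(prod$form %in% c("tablet", "injectable", "test"))) {
    stop("products: form must be tablet, injectable or test", call. = FALSE)
  }
  if (any(is.na(prod$pack_size) | prod$pack_size < 1)) {
    stop("products: pack_size must be >= 1", call. = FALSE)
  }
  prod$incomputable <- aetd_incomputable(prod$category, prod$units_per_aetd)
  prod
}
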