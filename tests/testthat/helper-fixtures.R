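# Shared fixtures: a minimal product catalogue and a survey-record builder.

fixture_products <- function() {
  tibble::tibble(
    product_id = c("AM-CQ", "AM-AS", "AM-NA", "RDT-1"),
    category = c("antimalarial", "antimalarial", "antimalarial", "rdt"),
    drug_name = c("chloroquine", "artesunate", "quinine", "malaria-rdt"),
    strength_mg = c(150, 50, NA, NA),
    form = c("tablet", "tablet", "tablet", "test"),
    pack_size = c(12L, 10L, 8L, 1L),
    units_per_aetd = c(24, 6, NA, NA)
  )
}

# One outlet x product survey record, all fields collected by default.
# Quantities are in the packs/loose representation; setting a *_status
# other than "collected" blanks the corresponding quantities.
fixture_record <- function(outlet_id = "O1",
                           product_id = "AM-CQ",
                           outlet_level = "wholesale",
                           outlet_type = "pharmacy",
                           s1_packs = 2, s1_loose = 3,
                           s2_packs = 1, s2_loose = 0,
                           delivered = 0, disposed = 0, rc = 15,
                           stock1_status = "collected",
                           stock2_status = "collected",
                           delivered_status = "collected",
                           disposed_status = "collected",
                           rc_status = "collected",
                           s1_tin = c(NA_real_, NA_real_, NA_real_),
                           s2_tin = c(NA_real_, NA_real_, NA_real_)) {
  blank <- function(x, status) if (status == "collected") x else NA_real_
  tibble::tibble(
    outlet_id = outlet_id,
    outlet_level = outlet_level,
    outlet_type = outlet_type,
    product_id = product_id,
    stock1_packs = blank(s1_packs, stock1_status),
    stock1_loose = blank(s1_loose, stock1_status),
    stock1_tin_height = blank(s1_tin[1], stock1_status),
    stock1_tin_height_full = blank(s1_tin[2], stock1_status),
    stock1_tin_units = blank(s1_tin[3], stock1_status),
    stock1_counted = if (stock1_status == "collected") "counted" else NA_character_,
    stock1_status = stock1_status,
    stock2_packs = blank(s2_packs, stock2_status),
    stock2_loose = blank(s2_loose, stock2_status),
    stock2_tin_height = blank(s2_tin[1], stock2_status),
    stock2_tin_height_full = blank(s2_tin[2], stock2_status),
    stock2_tin_units = blank(s2_tin[3], stock2_status),
    stock2_counted = if (stock2_status == "collected") "counted" else NA_character_,
    stock2_status = stock2_status,
    delivered_units = blank(delivered, delivered_status),
    delivered_status = delivered_status,
    disposed_units = blank(disposed, disposed_status),
    disposed_status = disposed_status,
    rc_sold_units = blank(rc, rc_status),
    rc_status = rc_status
  )
}

# Per-outlet totals with given RA/RC values, for agreement-level tests.
fixture_totals <- function(ra, rc, level = "wholesale",
                           category = "antimalarial") {
  tibble::tibble(
    outlet_id = sprintf("T%03d", seq_along(ra)),
    outlet_level = level,
    category = category,
    ra_total = ra,
    rc_total = rc,
    n_products = 1L
  )
}
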