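#' Market configuration for the synthetic survey generator
#'
#' Describes the outlet population and the true sales process the
#' stock-flow audit presumes. Per-product sales over the two-week
#' inter-visit interval are drawn from a zero-inflated negative binomial —
#' anti-malarial sales in this market are heavily zero-inflated with a long
#' right tail — parameterized per outlet level and product category by
#' `pi0` (probability of a structural zero), `mu` (negative-binomial mean
#' on the volume scale: AETDs for anti-malarials, tests for RDTs) and `k`
#' (dispersion). Defaults emulate a low-volume anti-malarial market:
#' retail outlet totals fall mostly between 0 and 20 AETDs, with rare
#' order-of-magnitude outlier outlets (~100+ AETDs).
#'
#' @param n_outlets Named integer vector, outlets per level.
#' @param n_products Named integer vector, catalogue size per category.
#' @param products_per_outlet Mean extra products stocked per outlet and
#'   category beyond the first (Poisson).
#' @param sales Nested list `sales[[level]][[category]]` with `pi0`, `mu`,
#'   `k`.
#' @param p_delivery Probability a product receives a delivery in the
#'   interval.
#' @param p_dispose Probability of any disposal; near zero by default —
#'   providers in this market essentially never throw products away or send
#'   them back.
#' @param dispose_mu Mean disposed volume when a disposal occurs.
#' @param outlier Named vector `c(p, multiplier)`: per-outlet probability
#'   of a dominant-volume outlet and the factor applied to its sales.
#' @param n_incomputable Number of anti-malarial catalogue products with no
#'   usable `units_per_aetd` (AETD-incomputable).
#' @param seed Master seed; all randomness in [simulate_truth()] and
#'   [apply_measurement()] derives from it through fixed per-channel
#'   substreams.
#' @return A validated list of class `sls_market_config`.
#' @export
market_config <- function(n_outlets = c(wholesale = 39, retail = 66),
                          n_products = c(antimalarial = 12, rdt = 4),
                          products_per_outlet = 1.5,
                          sales = list(
                            wholesale = list(
                              antimalarial = list(pi0 = 0.5, mu = 10, k = 0.5),
                              rdt = list(pi0 = 0.4, mu = 8, k = 0.8)
                            ),
                            retail = list(
                              antimalarial = list(pi0 = 0.5, mu = 2, k = 0.6),
                              rdt = list(pi0 = 0.5, mu = 5, k = 0.8)
                            )
                          ),
                          p_delivery = 0.3,
                          p_dispose = 0.01,
                          dispose_mu = 0.5,
                          outlier = c(p = 0.01, multiplier = 10),
                          n_incomputable = 1,
                          seed = 1L) {
  cfg <- list(
    n_outlets = n_outlets, n_products = n_products,
    products_per_outlet = products_per_outlet, sales = sales,
    p_delivery = p_delivery, p_dispose = p_dispose,
    dispose_mu = dispose_mu, outlier = outlier,
    n_incomputable = n_incomputable, seed = as.integer(seed)
  )
  stopifnot(
    all(c("wholesale", "retail") %in% names(n_outlets)),
    all(n_outlets >= 0),
    all(c("antimalarial", "rdt") %in% names(n_products)),
    p_delivery >= 0, p_delivery <= 1,
    p_dispose >= 0, p_dispose <= 1,
    outlier[["p"]] >= 0, outlier[["p"]] <= 1,
    n_incomputable >= 0, n_incomputable <= n_products[["antimalarial"]]
  )
  for (lv in c("wholesale", "retail")) {
    for (ct in c("antimalarial", "rdt")) {
      s <- sales[[lv]][[ct]]
      stopifnot(s$pi0 >= 0, s$pi0 <= 1, s$mu > 0, s$k > 0)
    }
  }
  structure(cfg, class = "sls_market_config")
}

#' Measurement configuration for the synthetic survey generator
#'
#' Encodes the error mechanisms hypothesized for the two methods. The
#' recalled quantity for a product with true volume `v` (AETDs or tests) is
#' `max(0, delta + beta * v * (1 - gamma * v) + e)`, `e ~ N(0, sigma_rc^2)`:
#' `delta` shifts recall additively (negative = under-recall on the RA - RC
#' scale), `beta` scales it, and `gamma` attenuates large volumes, which is
#' what induces proportional bias. Recall is truncated at zero — providers
#' cannot recall negative sales — and optionally heaped to whole base
#' units. Stocks are either physically counted or stated from memory, with
#' distinct error scales; nonresponse (refusals, not-remembered recalls,
#' whole-record gaps) is injected at configurable per-level rates.
#'
#' Default nonresponse and counted-share rates mirror a field survey of
#' this market: at wholesale, recall not remembered 16.3% and refused
#' 10.6%, stock refused 7.7%, received/disposed refused 1.0%/2.9%, 51% of
#' stocks counted; at retail, recall not remembered 2.8%, stock refused
#' 8.4%, whole-record missingness 7.0%, 97% counted. Default bias settings
#' (`beta = 0.85`, `gamma = 0.005`, `sigma_rc = 2`) give mild under-recall
#' that grows with volume.
#'
#' @param delta Additive recall shift, volume units (AETD/tests).
#' @param beta Multiplicative recall factor (`beta < 1` = under-recall).
#' @param gamma Volume-dependent attenuation per unit volume; drives
#'   proportional bias.
#' @param sigma_rc SD of recall noise, volume units.
#' @param heaping Round recalled quantities to whole base units.
#' @param p_not_remembered,p_rc_refused Per-level recall nonresponse rates.
#' @param p_record_missing Per-level probability that an entire record's
#'   five measurement fields are missing.
#' @param p_counted Per-level probability stock is physically counted
#'   rather than stated.
#' @param sigma_count,sigma_stated SD of stock observation error (volume
#'   units) for counted resp. stated stocks; stated error is the larger.
#' @param p_stock_refused Per-level probability the provider refuses stock
#'   counting (voids both visits).
#' @param p_received_refused,p_disposed_refused Per-level refusal rates for
#'   the delivery and disposal questions.
#' @param sigma_flow SD of recall error on delivered/disposed quantities.
#' @param p_tin Probability that loose retail tablets are held in a tin and
#'   measured by height rather than counted individually.
#' @return A validated list of class `sls_measurement_config`.
#' @export
measurement_config <- function(delta = 0,
                               beta = 0.85,
                               gamma = 0.005,
                               sigma_rc = 2,
                               heaping = TRUE,
                               p_not_remembered = c(
                                 wholesale = 0.163, retail = 0.028
                               ),
                               p_rc_refused = c(
                                 wholesale = 0.106, retail = 0
                               ),
                               p_record_missing = c(
                                 wholesale = 0, retail = 0.07
                               ),
                               p_counted = c(
                                 wholesale = 0.51, retail = 0.97
                               ),
                               sigma_count = 0.25,
                               sigma_stated = 2,
                               p_stock_refused = c(
                                 wholesale = 0.077, retail = 0.084
                               ),
                               p_received_refused = c(
                                 wholesale = 0.010, retail = 0
                               ),
                               p_disposed_refused = c(
                                 wholesale = 0.029, retail = 0
                               ),
                               sigma_flow = 0.5,
                               p_tin = 0.05) {
  cfg <- list(
    delta = delta, beta = beta, gamma = gamma, sigma_rc = sigma_rc,
    heaping = heaping, p_not_remembered = p_not_remembered,
    p_rc_refused = p_rc_refused, p_record_missing = p_record_missing,
    p_counted = p_counted, sigma_count = sigma_count,
    sigma_stated = sigma_stated, p_stock_refused = p_stock_refused,
    p_received_refused = p_received_refused,
    p_disposed_refused = p_disposed_refused, sigma_flow = sigma_flow,
    p_tin = p_tin
  )
  probs <- c(
    p_not_remembered, p_rc_refused, p_record_missing, p_counted,
    p_stock_refused, p_received_refused, p_disposed_refused, p_tin
  )
  stopifnot(
    all(probs >= 0), all(probs <= 1),
    sigma_rc >= 0, sigma_count >= 0, sigma_stated >= 0, sigma_flow >= 0,
    beta >= 0
  )
  structure(cfg, class = "sls_measurement_config")
}

#' Identity measurement: no error, no nonresponse
#'
#' Convenience configuration under which the survey records reproduce the
#' ground truth exactly, so the full pipeline returns bias 0 and sd 0.
#' Used by conservation oracles.
#'
#' @return An `sls_measurement_config`.
#' @export
measurement_identity <- function() {
  zero2 <- c(wholesale = 0, retail = 0)
  measurement_config(
    delta = 0, beta = 1, gamma = 0, sigma_rc = 0, heaping = FALSE,
    p_not_remembered = zero2, p_rc_refused = zero2,
    p_record_missing = zero2, p_counted = c(wholesale = 1, retail = 1),
    sigma_count = 0, sigma_stated = 0, p_stock_refused = zero2,
    p_received_refused = zero2, p_disposed_refused = zero2,
    sigma_flow = 0, p_tin = 0
  )
}

rzinb <- function(n, pi0, mu, k) {
  z <- stats::rbinom(n, 1, pi0)
  ifelse(z == 1, 0, stats::rnbinom(n, mu = mu, size = k))
}

# Fixed per-channel substream seeds derived from the master seed, so that a
# single error channel can be re-scaled without perturbing the draws of any
# other channel (common random numbers).
channel_seed <- function(seed, channel) {
  offs <- c(
    truth = 11L, status = 23L, rc = 37L, stock = 53L, flow = 71L,
    tin = 89L, counted = 101L
  )
  (as.integer(seed) + offs[[channel]]) %% .Machine$integer.max
}

build_catalogue <- function(market) {
  n_am <- market$n_products[["antimalarial"]]
  n_rdt <- market$n_products[["rdt"]]
  drugs <- c(
    "chloroquine", "artesunate", "mefloquine", "quinine",
    "artemether-lumefantrine", "primaquine", "artemisinin-piperaquine",
    "sulfadoxine-pyrimethamine"
  )
  form <- rep(c("tablet", "injectable"), length.out = n_am)
  form[seq_len(min(3, n_am))] <- "tablet" # tins occur for tablets only
  pack_choices <- c(8L, 10L, 12L, 16L, 20L, 24L)
  upa_tab <- c(4, 6, 8, 12, 16, 24)
  am <- tibble::tibble(
    product_id = sprintf("AM%02d", seq_len(n_am)),
    category = "antimalarial",
    drug_name = rep_len(drugs, n_am),
    strength_mg = rep_len(c(150, 50, 250, 300, 20, 15, 500, 525), n_am),
    form = form,
    pack_size = ifelse(
      form == "injectable", 1L,
      rep_len(pack_choices, n_am)
    ),
    units_per_aetd = ifelse(
      form == "injectable", rep_len(c(2, 4, 6), n_am),
      rep_len(upa_tab, n_am)
    )
  )
  if (market$n_incomputable > 0) {
    idx <- seq_len(market$n_incomputable)
    am$units_per_aetd[idx] <- NA_real_
    am$strength_mg[idx] <- NA_real_
  }
  rdt <- tibble::tibble(
    product_id = sprintf("RDT%02d", seq_len(n_rdt)),
    category = "rdt",
    drug_name = "malaria-rdt",
    strength_mg = NA_real_,
    form = "test",
    pack_size = rep_len(c(1L, 25L, 1L, 1L), n_rdt),
    units_per_aetd = NA_real_
  )
  dplyr::bind_rows(am, rdt)
}

#' Simulate the ground-truth stock-flow ledger
#'
#' Draws a product catalogue and, per outlet x stocked product, a true
#' sales volume, deliveries and disposals over the two-week interval, and
#' stock levels at the two visits constructed so that the stock-flow
#' identity `stock2 = stock1 + delivered - disposed - true_sales` holds
#' exactly with `stock2 >= 0`. The ledger is the oracle for the audit
#' estimator: on error-free measurements the RA estimate recovers
#' `true_sales` exactly, row by row.
#'
#' All quantities in the ledger are in base units (tablets, ampoules,
#' tests). Products with unknown AETD conversion are generated on a nominal
#' 24-units-per-course scale; downstream analysis excludes them.
#'
#' @param market An [market_config()] object.
#' @return Tibble with one row per outlet x product:
#'   outlet/product identity, `true_sales_units`, `stock1_units`,
#'   `delivered_units`, `disposed_units`, `stock2_units`. The catalogue and
#'   configuration ride along as attributes `products` and `market`.
#' @export
simulate_truth <- function(market = market_config()) {
  stopifnot(inherits(market, "sls_market_config"))
  products <- build_catalogue(market)
  set.seed(channel_seed(market$seed, "truth"))

  outlets <- dplyr::bind_rows(lapply(c("wholesale", "retail"), function(lv) {
    n <- market$n_outlets[[lv]]
    if (n == 0) {
      return(NULL)
    }
    types <- if (lv == "wholesale") {
      rep("other", n)
    } else {
      sample(
        c("pharmacy", "drug_shop", "mobile", "grocery", "village_shop"),
        n,
        replace = TRUE, prob = c(0.13, 0.21, 0.20, 0.26, 0.20)
      )
    }
    tibble::tibble(
      outlet_id = sprintf("%s%03d", toupper(substr(lv, 1, 1)), seq_len(n)),
      outlet_level = lv, outlet_type = types
    )
  }))

  is_outlier <- stats::runif(nrow(outlets)) < market$outlier[["p"]]

  # one cell per outlet x category; draw how many and which products it stocks
  cells <- tidyr::expand_grid(
    oi = seq_len(nrow(outlets)), category = c("antimalarial", "rdt")
  )
  cat_size <- vapply(
    cells$category, function(ct) sum(products$category == ct), integer(1)
  )
  n_stock <- pmin(
    cat_size, 1 + stats::rpois(nrow(cells), market$products_per_outlet)
  )
  cat_idx <- split(seq_len(nrow(products)), products$category)
  pick <- unlist(Map(
    function(ct, k) cat_idx[[ct]][sample.int(length(cat_idx[[ct]]), k)],
    cells$category, n_stock
  ), use.names = FALSE)

  row_cell <- rep(seq_len(nrow(cells)), n_stock)
  oi <- cells$oi[row_cell]
  lv <- outlets$outlet_level[oi]
  ct <- cells$category[row_cell]
  prod <- products[pick, ]
  upa <- ifelse(is.na(prod$units_per_aetd), 24, prod$units_per_aetd)
  scale <- ifelse(ct == "rdt", 1, upa)
  par_of <- function(field) {
    mapply(function(l, c) market$sales[[l]][[c]][[field]], lv, ct,
      USE.NAMES = FALSE
    )
  }
  mu <- par_of("mu") * scale
  sales <- rzinb(length(pick), par_of("pi0"), mu, par_of("k"))
  sales <- sales * ifelse(is_outlier[oi], market$outlier[["multiplier"]], 1)
  n <- length(sales)
  delivered <- stats::rbinom(n, 1, market$p_delivery) *
    stats::rnbinom(n, mu = mu, size = 1)
  disposed <- stats::rbinom(n, 1, market$p_dispose) *
    stats::rpois(n, market$dispose_mu * scale)
  buffer <- stats::rnbinom(n, mu = 0.5 * mu, size = 1)
  stock1 <- pmax(0, sales + disposed - delivered) + buffer
  stock2 <- stock1 + delivered - disposed - sales

  truth <- tibble::tibble(
    outlet_id = outlets$outlet_id[oi],
    outlet_level = lv,
    outlet_type = outlets$outlet_type[oi],
    product_id = prod$product_id,
    category = ct,
    pack_size = prod$pack_size,
    units_per_aetd = prod$units_per_aetd,
    form = prod$form,
    true_sales_units = sales,
    stock1_units = stock1,
    delivered_units = delivered,
    disposed_units = disposed,
    stock2_units = stock2
  )
  truth <- dplyr::arrange(truth, .data$outlet_id, .data$category,
    .data$product_id
  )
  stopifnot(all(
    truth$stock2_units ==
      truth$stock1_units + truth$delivered_units -
        truth$disposed_units - truth$true_sales_units
  ), all(truth$stock2_units >= 0))
  attr(truth, "products") <- products
  attr(truth, "market") <- market
  truth
}

per_level <- function(p, level) unname(p[level])

represent_stock <- function(units, pack_size, allow_tin, p_tin) {
  n <- length(units)
  packs <- units %/% pack_size
  loose <- units %% pack_size
  tin_h <- rep(NA_real_, n)
  tin_hf <- rep(NA_real_, n)
  tin_n <- rep(NA_real_, n)
  use_tin <- allow_tin & loose > 0 & stats::runif(n) < p_tin
  if (any(use_tin)) {
    # tin geometry chosen so the ruler estimate round-trips exactly
    tin_n[use_tin] <- pmax(pack_size[use_tin], 20)
    tin_hf[use_tin] <- 10
    tin_h[use_tin] <- 10 * loose[use_tin] / tin_n[use_tin]
    loose[use_tin] <- 0
  }
  list(packs = packs, loose = loose, tin_h = tin_h, tin_hf = tin_hf,
       tin_n = tin_n)
}

#' Overlay measurement error and nonresponse on a truth ledger
#'
#' Produces survey records in the layout [read_survey()] expects, by
#' passing every true quantity through the configured observation channels:
#' recall bias/noise/heaping/zero-truncation for the RC question, distinct
#' counted-vs-stated perturbation of stocks at each visit, recall noise on
#' delivered/disposed quantities, tin representation of loose retail
#' tablets, and status-code injection for refusals, not-remembered recalls
#' and whole-record missingness. Each channel draws from its own substream
#' of the master seed, so error scales can be varied one at a time under
#' common random numbers.
#'
#' @param truth Ledger from [simulate_truth()].
#' @param meas An [measurement_config()] object.
#' @return Tibble of survey records (validated by [read_survey()]).
#' @export
apply_measurement <- function(truth, meas = measurement_config()) {
  stopifnot(inherits(meas, "sls_measurement_config"))
  market <- attr(truth, "market")
  seed <- if (is.null(market)) 1L else market$seed
  n <- nrow(truth)
  lv <- truth$outlet_level
  upa <- ifelse(is.na(truth$units_per_aetd), 24, truth$units_per_aetd)
  scale <- ifelse(truth$category == "rdt", 1, upa)

  # recall channel
  set.seed(channel_seed(seed, "rc"))
  z_rc <- stats::rnorm(n)
  v <- truth$true_sales_units / scale
  rc_vol <- meas$delta + meas$beta * v * (1 - meas$gamma * v) +
    meas$sigma_rc * z_rc
  rc_units <- pmax(0, rc_vol * scale)
  if (meas$heaping) rc_units <- round_half_up(rc_units)

  # stock channel: counted vs stated, independent error per visit
  set.seed(channel_seed(seed, "counted"))
  counted <- stats::runif(n) < per_level(meas$p_counted, lv)
  set.seed(channel_seed(seed, "stock"))
  z_s1 <- stats::rnorm(n)
  z_s2 <- stats::rnorm(n)
  sig_stock <- ifelse(counted, meas$sigma_count, meas$sigma_stated)
  s1_obs <- pmax(0, round_half_up(truth$stock1_units + sig_stock * scale * z_s1))
  s2_obs <- pmax(0, round_half_up(truth$stock2_units + sig_stock * scale * z_s2))

  # delivered/disposed recall channel
  set.seed(channel_seed(seed, "flow"))
  z_del <- stats::rnorm(n)
  z_dis <- stats::rnorm(n)
  del_obs <- pmax(0, round_half_up(
    truth$delivered_units + meas$sigma_flow * scale * z_del
  ))
  dis_obs <- pmax(0, round_half_up(
    truth$disposed_units + meas$sigma_flow * scale * z_dis
  ))

  # representation of stocks as packs / loose / tins
  set.seed(channel_seed(seed, "tin"))
  allow_tin <- lv == "retail" & truth$form == "tablet"
  r1 <- represent_stock(s1_obs, truth$pack_size, allow_tin, meas$p_tin)
  r2 <- represent_stock(s2_obs, truth$pack_size, allow_tin, meas$p_tin)

  # nonresponse channel
  set.seed(channel_seed(seed, "status"))
  rec_missing <- stats::runif(n) < per_level(meas$p_record_missing, lv)
  u_rc <- stats::runif(n)
  rc_status <- dplyr::case_when(
    rec_missing ~ "missing",
    u_rc < per_level(meas$p_rc_refused, lv) ~ "refused",
    u_rc < per_level(meas$p_rc_refused, lv) +
      per_level(meas$p_not_remembered, lv) ~ "not_remembered",
    TRUE ~ "collected"
  )
  stock_refused <- stats::runif(n) < per_level(meas$p_stock_refused, lv)
  stock_status <- dplyr::case_when(
    rec_missing ~ "missing",
    stock_refused ~ "refused",
    TRUE ~ "collected"
  )
  del_status <- dplyr::case_when(
    rec_missing ~ "missing",
    stats::runif(n) < per_level(meas$p_received_refused, lv) ~ "refused",
    TRUE ~ "collected"
  )
  dis_status <- dplyr::case_when(
    rec_missing ~ "missing",
    stats::runif(n) < per_level(meas$p_disposed_refused, lv) ~ "refused",
    TRUE ~ "collected"
  )

  blank <- function(x, status) ifelse(status == "collected", x, NA_real_)
  rec <- tibble::tibble(
    outlet_id = truth$outlet_id,
    outlet_level = lv,
    outlet_type = truth$outlet_type,
    product_id = truth$product_id,
    stock1_packs = blank(r1$packs, stock_status),
    stock1_loose = blank(r1$loose, stock_status),
    stock1_tin_height = blank(r1$tin_h, stock_status),
    stock1_tin_height_full = blank(r1$tin_hf, stock_status),
    stock1_tin_units = blank(r1$tin_n, stock_status),
    stock1_counted = ifelse(
      stock_status == "collected", ifelse(counted, "counted", "stated"),
      NA_character_
    ),
    stock1_status = stock_status,
    stock2_packs = blank(r2$packs, stock_status),
    stock2_loose = blank(r2$loose, stock_status),
    stock2_tin_height = blank(r2$tin_h, stock_status),
    stock2_tin_height_full = blank(r2$tin_hf, stock_status),
    stock2_tin_units = blank(r2$tin_n, stock_status),
    stock2_counted = ifelse(
      stock_status == "collected", ifelse(counted, "counted", "stated"),
      NA_character_
    ),
    stock2_status = stock_status,
    delivered_units = blank(del_obs, del_status),
    delivered_status = del_status,
    disposed_units = blank(dis_obs, dis_status),
    disposed_status = dis_status,
    rc_sold_units = blank(rc_units, rc_status),
    rc_status = rc_status
  )
  read_survey(rec)
}

config_hash <- function(...) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(...), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Generate a complete synthetic survey on disk
#'
#' Runs [simulate_truth()] and [apply_measurement()] and writes
#' `products.csv`, `survey.csv` and `truth.csv` (the ground-truth ledger,
#' for validation only — the analysis path never reads it) to `out_dir`,
#' plus a `manifest.json` recording the seed, a configuration hash and
#' record counts. Same configurations and seed give identical files.
#'
#' @param market An [market_config()].
#' @param meas An [measurement_config()].
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly.
#' @export
generate_survey <- function(market = market_config(),
                            meas = measurement_config(),
                            out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  truth <- simulate_truth(market)
  survey <- apply_measurement(truth, meas)
  products <- attr(truth, "products")

  readr::write_csv(products, file.path(out_dir, "products.csv"))
  readr::write_csv(survey, file.path(out_dir, "survey.csv"))
  readr::write_csv(
    tibble::as_tibble(truth),
    file.path(out_dir, "truth.csv")
  )
  manifest <- list(
    seed = market$seed,
    config_hash = config_hash(
      market = unclass(market), measurement = unclass(meas)
    ),
    n_products = nrow(products),
    n_records = nrow(survey)
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
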