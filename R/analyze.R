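#' Full agreement analysis of a sales-level survey
#'
#' Orchestrates the whole method-comparison sequence: validate records,
#' standardize volumes and build method pairs with exclusion logging,
#' aggregate to per-outlet totals, screen dominant outliers, and run the
#' Bland-Altman analysis separately for every outlet level x product
#' category present (strata are never pooled: anti-malarial AETDs and RDT
#' test counts are different units, and wholesale and retail markets are
#' different populations). When outlets are flagged by the outlier screen
#' the stratum is analyzed both without and with them, so the sensitivity
#' of the agreement statistics to the flagged outlets is always visible.
#'
#' @param survey Survey records: path to `survey.csv` or a data frame.
#' @param products Product catalogue: path to `products.csv` or a data
#'   frame.
#' @param outlier_k Dominance multiplier for [outlier_screen()].
#' @param screen_outliers Set `FALSE` to disable the screen (single variant
#'   per stratum).
#' @param ci_level Confidence level for bias and LoA intervals.
#' @return An object of class `sls_analysis`: list with `strata` (named
#'   list per stratum holding `result`, optionally `result_with_outliers`,
#'   and `flagged`), `totals`, `pairs`, `exclusions`, `accounting` and
#'   `manifest`.
#' @export
analyze_survey <- function(survey, products, outlier_k = 3,
                           screen_outliers = TRUE, ci_level = 0.95) {
  records <- read_survey(survey)
  products <- read_products(products)
  bp <- build_pairs(records, products)
  totals <- aggregate_outlets(bp$pairs)
  accounting <- response_accounting(records, bp$pairs)

  strata <- list()
  combos <- unique(totals[, c("outlet_level", "category")])
  for (i in seq_len(nrow(combos))) {
    lv <- combos$outlet_level[i]
    ct <- combos$category[i]
    name <- paste(lv, ct, sep = "_")
    sub <- totals[totals$outlet_level == lv & totals$category == ct, ]
    if (nrow(sub) < 2) {
      warning(
        "stratum ", name, " has fewer than 2 analyzable outlets; skipped",
        call. = FALSE
      )
      next
    }
    scr <- if (screen_outliers) {
      outlier_screen(sub, k = outlier_k)
    } else {
      list(kept = sub, flagged = sub[0, ])
    }
    entry <- list(
      outlet_level = lv, category = ct,
      unit = if (ct == "rdt") "tests" else "AETD",
      flagged = scr$flagged
    )
    if (nrow(scr$kept) >= 2) {
      entry$result <- bland_altman(scr$kept, level = ci_level)
    } else {
      warning(
        "stratum ", name,
        " has fewer than 2 outlets after outlier screening; skipped",
        call. = FALSE
      )
      next
    }
    if (nrow(scr$flagged) > 0) {
      entry$result_with_outliers <- bland_altman(sub, level = ci_level)
    }
    strata[[name]] <- entry
  }

  n_read <- nrow(records)
  n_analyzed <- sum(bp$pairs$included)
  by_reason <- table(bp$exclusions$reason)
  manifest <- list(
    package_version = as.character(utils::packageVersion("slsagree")),
    n_records_read = n_read,
    n_records_analyzed = n_analyzed,
    n_records_excluded = nrow(bp$exclusions),
    excluded_by_reason = as.list(by_reason),
    n_outlet_pairs = nrow(totals),
    outlier_k = if (screen_outliers) outlier_k else Inf,
    ci_level = ci_level
  )
  stopifnot(n_read == n_analyzed + nrow(bp$exclusions))
  for (rs in names(by_reason)) {
    message("excluded ", by_reason[[rs]], " record(s): ", rs)
  }

  structure(
    list(
      strata = strata, totals = totals, pairs = bp$pairs,
      exclusions = bp$exclusions, accounting = accounting,
      manifest = manifest
    ),
    class = "sls_analysis"
  )
}

#' @export
print.sls_analysis <- function(x, ...) {
  m <- x$manifest
  cat("Sales-level survey agreement analysis\n")
  cat(sprintf(
    "  records: %d read = %d analyzed + %d excluded\n",
    m$n_records_read, m$n_records_analyzed, m$n_records_excluded
  ))
  for (name in names(x$strata)) {
    st <- x$strata[[name]]
    cat(sprintf(
      "\n-- %s %s (%s)%s --\n",
      st$outlet_level, st$category, st$unit,
      if (nrow(st$flagged) > 0) {
        sprintf(
          " [%d outlier outlet(s) excluded: %s]",
          nrow(st$flagged), paste(st$flagged$outlet_id, collapse = ", ")
        )
      } else {
        ""
      }
    ))
    print(st$result)
    if (!is.null(st$result_with_outliers)) {
      cat("  including flagged outlet(s):\n")
      print(st$result_with_outliers)
    }
  }
  invisible(x)
}

agreement_row <- function(st, res, variant) {
  tibble::tibble(
    outlet_level = st$outlet_level,
    category = st$category,
    variant = variant,
    unit = st$unit,
    n = res$n,
    bias = res$bias,
    sd = res$sd,
    bias_ci_lower = res$bias_ci[["lower"]],
    bias_ci_upper = res$bias_ci[["upper"]],
    loa_lower = res$loa[["lower"]],
    loa_upper = res$loa[["upper"]],
    loa_lower_ci_lower = res$loa_ci_lower[["lower"]],
    loa_lower_ci_upper = res$loa_ci_lower[["upper"]],
    loa_upper_ci_lower = res$loa_ci_upper[["lower"]],
    loa_upper_ci_upper = res$loa_ci_upper[["upper"]],
    r = res$r,
    r_p = res$r_p,
    shapiro_p = res$normality$shapiro_p,
    n_flagged_outliers = nrow(st$flagged)
  )
}

#' Tabulate agreement results across strata
#'
#' One row per outlet level x category x outlier-handling variant with all
#' agreement statistics, suitable for `results.csv`.
#'
#' @param analysis An `sls_analysis` from [analyze_survey()].
#' @return A tibble.
#' @export
results_table <- function(analysis) {
  rows <- list()
  for (st in analysis$strata) {
    rows[[length(rows) + 1]] <- agreement_row(st, st$result, "screened")
    if (!is.null(st$result_with_outliers)) {
      rows[[length(rows) + 1]] <- agreement_row(
        st, st$result_with_outliers, "with_outliers"
      )
    }
  }
  dplyr::bind_rows(rows)
}

table1_layout <- c(
  surveyed = "Total products surveyed",
  rc_collected = "Sales volume data collected (RC)",
  rc_not_remembered = "- Not remembered",
  rc_refused = "- Refused",
  rc_missing = "- Missing",
  ra_calculated_nonneg = "Sales volumes calculated, excl. negatives (RA)",
  ra_calculated_incl_neg = "Sales volumes calculated, incl. negatives (RA)",
  stock_collected = "Stock data collected",
  stock_refused = "- Refused (stock)",
  stock_not_remembered = "- Not remembered (stock)",
  stock_missing = "- Missing (stock)",
  received_collected = "Received quantities collected",
  received_refused = "- Refused (received)",
  received_not_remembered = "- Not remembered (received)",
  received_missing = "- Missing (received)",
  disposed_collected = "Disposed quantities collected",
  disposed_refused = "- Refused (disposed)",
  disposed_not_remembered = "- Not remembered (disposed)",
  disposed_missing = "- Missing (disposed)"
)

#' Render the response-accounting table
#'
#' Lays the long accounting tibble out as a survey-report table: one column
#' per outlet level x category, one row per response measure, each cell
#' `"n (pct%)"` with the percentage of products surveyed to one decimal
#' place. Strata with zero surveyed products render as dashes.
#'
#' @param acc Accounting tibble from [response_accounting()].
#' @return A data frame of character cells with a leading `measure` column.
#' @export
render_table1 <- function(acc) {
  acc <- tibble::as_tibble(acc)
  acc$cell <- sprintf("%d (%.1f%%)", acc$n, acc$pct)
  surveyed0 <- acc$measure == "surveyed" & acc$n == 0
  if (any(surveyed0)) {
    zero_strata <- paste(
      acc$outlet_level[surveyed0], acc$category[surveyed0]
    )
    acc$cell[paste(acc$outlet_level, acc$category) %in% zero_strata] <- "-"
  }
  acc$column <- paste(acc$outlet_level, acc$category, sep = "_")
  wide <- tidyr::pivot_wider(
    acc[, c("measure", "column", "cell")],
    names_from = "column", values_from = "cell"
  )
  wide <- wide[match(names(table1_layout), wide$measure), ]
  wide <- wide[!is.na(wide$measure), ]
  wide$measure <- unname(table1_layout[wide$measure])
  as.data.frame(wide)
}

#' Write all analysis outputs to a directory
#'
#' Writes `results.csv` (agreement statistics per stratum and variant),
#' `accounting.csv` (rendered response accounting), `exclusions.csv`,
#' `manifest.json`, and one mean-difference plot per stratum and variant,
#' named `ba_<level>_<category>[_with_outliers].<format>`.
#'
#' @param analysis An `sls_analysis`.
#' @param out_dir Output directory, created if needed.
#' @param plot_format Image format extension, default `"png"`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(analysis, out_dir, plot_format = "png") {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  paths <- c(
    results = file.path(out_dir, "results.csv"),
    accounting = file.path(out_dir, "accounting.csv"),
    exclusions = file.path(out_dir, "exclusions.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(results_table(analysis), paths[["results"]])
  readr::write_csv(render_table1(analysis$accounting), paths[["accounting"]])
  readr::write_csv(analysis$exclusions, paths[["exclusions"]])
  jsonlite::write_json(
    analysis$manifest, paths[["manifest"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  for (name in names(analysis$strata)) {
    st <- analysis$strata[[name]]
    f <- file.path(out_dir, sprintf("ba_%s.%s", name, plot_format))
    ba_plot(
      st$result,
      unit = st$unit,
      title = sprintf("%s %s", st$outlet_level, st$category), file = f
    )
    paths <- c(paths, f)
    if (!is.null(st$result_with_outliers)) {
      f2 <- file.path(
        out_dir, sprintf("ba_%s_with_outliers.%s", name, plot_format)
      )
      ba_plot(
        st$result_with_outliers,
        unit = st$unit,
        title = sprintf(
          "%s %s (incl. flagged outlets)", st$outlet_level, st$category
        ),
        file = f2
      )
      paths <- c(paths, f2)
    }
  }
  invisible(paths)
}

#' Read a simulation configuration file
#'
#' Reads a YAML or JSON file with optional top-level `market` and
#' `measurement` blocks whose entries override the corresponding
#' [market_config()] / [measurement_config()] defaults.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return List with validated `market` and `measurement` configs.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  as_named <- function(x) {
    if (is.list(x) && !is.null(names(x)) &&
      all(vapply(x, is.numeric, logical(1)))) {
      unlist(x)
    } else {
      x
    }
  }
  market_args <- lapply(raw$market %||% list(), as_named)
  meas_args <- lapply(raw$measurement %||% list(), as_named)
  list(
    market = do.call(market_config, market_args),
    measurement = do.call(measurement_config, meas_args)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
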