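#' Per-outlet differences and means of the paired totals
#'
#' For each outlet the between-method difference `d = RA - RC` and the pair
#' mean `m = (RA + RC) / 2` are formed. In the absence of a gold standard
#' for sales volumes, the pair mean proxies the outlet's true total volume
#' sold; the Bland-Altman analysis studies `d` against `m`.
#'
#' @param pairs Tibble of per-outlet totals with columns `ra_total` and
#'   `rc_total` (from [aggregate_outlets()]), or any data frame carrying
#'   them. Order is preserved.
#' @return Tibble with `outlet_id` (if present), `d` and `m`.
#' @export
make_differences <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  out <- tibble::tibble(
    d = pairs$ra_total - pairs$rc_total,
    m = (pairs$ra_total + pairs$rc_total) / 2
  )
  if ("outlet_id" %in% names(pairs)) {
    out <- tibble::add_column(out, outlet_id = pairs$outlet_id, .before = 1)
  }
  out
}

#' Bias of measurement and its standard deviation
#'
#' The bias between the two methods is the mean of the per-outlet
#' differences; its spread is the sample standard deviation with the
#' `n - 1` denominator.
#'
#' @param d Numeric vector of differences, or a data frame with a `d`
#'   column.
#' @return List with `bias`, `sd`, `n`.
#' @export
bias_sd <- function(d) {
  if (is.data.frame(d)) d <- d$d
  n <- length(d)
  if (n < 2) stop("insufficient pairs: need n >= 2", call. = FALSE)
  list(bias = mean(d), sd = stats::sd(d), n = n)
}

#' Limits of agreement
#'
#' The interval expected to contain 95% of paired between-method
#' differences: `bias +/- 1.96 * sd`. The multiplier is the literal 1.96
#' normal quantile, not a t quantile, so the limits are symmetric about the
#' bias by construction (`upper + lower = 2 * bias` exactly).
#'
#' @param bias Mean difference.
#' @param sd Standard deviation of the differences (>= 0).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
limits_of_agreement <- function(bias, sd) {
  stopifnot(sd >= 0)
  c(lower = bias - 1.96 * sd, upper = bias + 1.96 * sd)
}

#' Confidence interval for the bias
#'
#' `bias +/- t(n-1) * sd / sqrt(n)`. The t distribution is the
#' small-sample-safe convention; published agreement analyses vary between
#' z and t, so printed intervals from other software are matched only
#' approximately.
#'
#' @param bias Mean difference.
#' @param sd Standard deviation of the differences.
#' @param n Number of outlet pairs (>= 2).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bias_ci <- function(bias, sd, n, level = 0.95) {
  if (n < 2) stop("insufficient pairs: need n >= 2", call. = FALSE)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  c(lower = bias - half, upper = bias + half)
}

#' Confidence intervals for the limits of agreement
#'
#' Each limit's sampling variance is approximated by `3 * sd^2 / n`
#' (Bland & Altman 1986), giving
#' `limit +/- t(n-1) * sd * sqrt(3 / n)`.
#'
#' @inheritParams bias_ci
#' @return List with `lower` and `upper`, each a `c(lower, upper)` interval
#'   for the corresponding limit of agreement.
#' @export
loa_ci <- function(bias, sd, n, level = 0.95) {
  if (n < 2) stop("insufficient pairs: need n >= 2", call. = FALSE)
  loa <- limits_of_agreement(bias, sd)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd * sqrt(3 / n)
  list(
    lower = c(lower = loa[["lower"]] - half, upper = loa[["lower"]] + half),
    upper = c(lower = loa[["upper"]] - half, upper = loa[["upper"]] + half)
  )
}

#' Proportional-bias check
#'
#' For the bias to summarize agreement meaningfully it must be constant
#' over the measurement range. Dependence of the differences on the volume
#' measured is detected as the Pearson correlation between `d` and the pair
#' mean `m`, with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom — the
#' correlation reported alongside classic mean-difference plots.
#'
#' @param diffs Tibble from [make_differences()] (columns `d`, `m`).
#' @return List with `r`, `p`, `n` and `status` (`"ok"` or `"degenerate"`
#'   when either variable has zero variance or `n < 3`; then `r` and `p`
#'   are `NA`, never silent `NaN`s).
#' @export
proportional_bias <- function(diffs) {
  d <- diffs$d
  m <- diffs$m
  n <- length(d)
  if (n < 3 || stats::sd(d) == 0 || stats::sd(m) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, status = "degenerate"))
  }
  r <- stats::cor(d, m)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, status = "ok")
}

#' Normality diagnostic for the differences
#'
#' The Bland-Altman limits presume approximately normal differences. This
#' returns histogram bins for visual inspection plus a Shapiro-Wilk
#' statistic as an advisory annotation; it never blocks the analysis.
#'
#' @param diffs Tibble with a `d` column, or a numeric vector.
#' @param alpha Advisory significance level for the note, default 0.05.
#' @return List with `histogram` (breaks and counts), `shapiro_w`,
#'   `shapiro_p` and `note`.
#' @export
normality_check <- function(diffs, alpha = 0.05) {
  d <- if (is.data.frame(diffs)) diffs$d else diffs
  n <- length(d)
  if (n < 3 || stats::sd(d) == 0) {
    return(list(
      histogram = NULL, shapiro_w = NA_real_, shapiro_p = NA_real_,
      note = "degenerate: fewer than 3 differences or zero variance"
    ))
  }
  h <- graphics::hist(d, plot = FALSE)
  sw <- stats::shapiro.test(if (n > 5000) d[seq_len(5000)] else d)
  note <- if (sw$p.value < alpha) {
    sprintf(
      "departure from normality flagged (Shapiro-Wilk p = %.3g); advisory only",
      sw$p.value
    )
  } else {
    "no departure from normality detected"
  }
  list(
    histogram = list(breaks = h$breaks, counts = h$counts),
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value, note = note
  )
}

#' Screen per-outlet totals for dominant outliers
#'
#' An outlet whose volume dwarfs every other outlet's can obscure the
#' interpretation of the agreement statistics. An outlet is flagged when
#' its pair mean `m` exceeds `k` times the largest `m` among the remaining
#' outlets; flagging repeats on the reduced set until stable, so a run of
#' several extreme outlets is caught. The rule is explicit and configurable
#' (`k = Inf` disables it); downstream reporting always runs the analysis
#' both with and without flagged outlets.
#'
#' @param pairs Per-outlet totals (from [aggregate_outlets()]).
#' @param k Dominance multiplier, default 3.
#' @return List with `kept` and `flagged` subsets of `pairs`.
#' @export
outlier_screen <- function(pairs, k = 3) {
  pairs <- tibble::as_tibble(pairs)
  m <- (pairs$ra_total + pairs$rc_total) / 2
  flagged <- rep(FALSE, nrow(pairs))
  if (is.finite(k) && nrow(pairs) >= 2) {
    repeat {
      idx <- which(!flagged)
      if (length(idx) < 2) break
      mi <- m[idx]
      top <- idx[which.max(mi)]
      second <- max(mi[-which.max(mi)])
      if (m[top] > k * second) flagged[top] <- TRUE else break
    }
  }
  list(kept = pairs[!flagged, ], flagged = pairs[flagged, ])
}

#' Bland-Altman agreement analysis of paired outlet totals
#'
#' Runs the full agreement procedure on one stratum's per-outlet totals:
#' differences and pair means, bias and its standard deviation, the 95%
#' limits of agreement with confidence intervals, the proportional-bias
#' correlation, and the normality diagnostic.
#'
#' @param pairs Per-outlet totals with `ra_total` and `rc_total` columns,
#'   or a tibble of precomputed differences (columns `d`, `m`).
#' @param level Confidence level for the bias and LoA intervals.
#' @return An object of class `sls_agreement`: a list with `n`, `bias`,
#'   `sd`, `bias_ci`, `loa`, `loa_ci_lower`, `loa_ci_upper`, `r`, `r_p`,
#'   `r_status`, `normality`, `diffs` and `level`.
#' @export
bland_altman <- function(pairs, level = 0.95) {
  diffs <- if (all(c("d", "m") %in% names(pairs))) {
    tibble::as_tibble(pairs)
  } else {
    make_differences(pairs)
  }
  bs <- bias_sd(diffs$d)
  loa <- limits_of_agreement(bs$bias, bs$sd)
  ci <- loa_ci(bs$bias, bs$sd, bs$n, level)
  pb <- proportional_bias(diffs)
  structure(
    list(
      n = bs$n,
      bias = bs$bias,
      sd = bs$sd,
      bias_ci = bias_ci(bs$bias, bs$sd, bs$n, level),
      loa = loa,
      loa_ci_lower = ci$lower,
      loa_ci_upper = ci$upper,
      r = pb$r,
      r_p = pb$p,
      r_status = pb$status,
      normality = normality_check(diffs),
      diffs = diffs,
      level = level
    ),
    class = "sls_agreement"
  )
}

#' @export
print.sls_agreement <- function(x, ...) {
  cat("Bland-Altman agreement (RA - RC), n =", x$n, "outlets\n")
  cat(sprintf(
    "  bias: %.2f (%.0f%% CI %.2f to %.2f)\n",
    x$bias, 100 * x$level, x$bias_ci[["lower"]], x$bias_ci[["upper"]]
  ))
  cat(sprintf(
    "  limits of agreement: %.2f to %.2f\n",
    x$loa[["lower"]], x$loa[["upper"]]
  ))
  cat(sprintf(
    "    lower LoA CI: %.2f to %.2f; upper LoA CI: %.2f to %.2f\n",
    x$loa_ci_lower[["lower"]], x$loa_ci_lower[["upper"]],
    x$loa_ci_upper[["lower"]], x$loa_ci_upper[["upper"]]
  ))
  if (x$r_status == "ok") {
    cat(sprintf(
      "  proportional bias: r = %.3f (p = %.3g)\n", x$r, x$r_p
    ))
  } else {
    cat("  proportional bias: degenerate (zero variance or n < 3)\n")
  }
  cat(" ", x$normality$note, "\n")
  invisible(x)
}

#' Mean-difference (Bland-Altman) plot
#'
#' Scatter of the between-method differences against the pair means, with
#' the line of equality at zero (dashed blue), the bias (solid red) and the
#' limits of agreement (dashed red). Axis labels carry the volume unit.
#'
#' @param result An `sls_agreement` object from [bland_altman()].
#' @param unit Volume unit for the axis labels, e.g. `"AETD"` or `"tests"`.
#' @param title Optional plot title.
#' @param file Optional path; when given the plot is also written there
#'   (format from the extension, e.g. `.png` or `.svg`).
#' @return A ggplot object, invisibly when `file` is given.
#' @export
ba_plot <- function(result, unit = "AETD", title = NULL, file = NULL) {
  stopifnot(inherits(result, "sls_agreement"))
  diffs <- result$diffs
  if (nrow(diffs) == 0) stop("ba_plot: no differences to plot", call. = FALSE)
  p <- ggplot2::ggplot(diffs, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_hline(yintercept = 0, colour = "blue", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = result$bias, colour = "red") +
    ggplot2::geom_hline(
      yintercept = result$loa[["lower"]], colour = "red", linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = result$loa[["upper"]], colour = "red", linetype = "dashed"
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("Mean of RA and RC estimates (%s)", unit),
      y = sprintf("Difference RA - RC (%s)", unit),
      title = title
    ) +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4.5, dpi = 150)
    return(invisible(p))
  }
  p
}
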