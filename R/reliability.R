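# Reliability of urine-based exposure estimates against the internal-dose
# AUC: regression R^2, quantile classification, and the one-way ANOVA ICC.

#' R-squared of log AUC against log pooled concentration, by pool size
#'
#' For each pool size n, the squared Pearson correlation between
#' log-transformed internal-dose AUCs and log-transformed pooled mean
#' concentrations across individuals (equal to the R^2 of the simple linear
#' regression in either direction; natural logs, to which R^2 is
#' invariant).
#'
#' @param pools Tibble with columns `individual`, `n`, `pooled` (from
#'   nested pooling of each individual's samples).
#' @param aucs Tibble with columns `individual`, `auc`.
#' @return A tibble with columns `n`, `r2`. Pool sizes with zero variance
#'   in either variable get `NA` with a warning.
#' @export
r2_curve <- function(pools, aucs) {
  df <- dplyr::inner_join(pools, aucs, by = "individual")
  if (any(df$pooled <= 0) || any(df$auc <= 0)) {
    stop(paste("Non-positive AUC or pooled concentration encountered;",
               "lengthen the accumulation period or check the exposure pattern."),
         call. = FALSE)
  }
  out <- df |>
    dplyr::group_by(n = .data$n) |>
    dplyr::summarise(r2 = {
      la <- log(.data$auc); lp <- log(.data$pooled)
      if (stats::sd(la) == 0 || stats::sd(lp) == 0) NA_real_
      else stats::cor(la, lp)^2
    }, .groups = "drop")
  if (anyNA(out$r2)) {
    warning("R^2 undefined (zero variance) for some pool sizes; reported as NA.",
            call. = FALSE)
  }
  out
}

# Equal-count quantile groups by rank; remainder spread over the lower
# groups, ties broken by the stable index.
quantile_groups <- function(x, n_quantiles, index = seq_along(x)) {
  n <- length(x)
  ord <- order(x, index)
  sizes <- rep(n %/% n_quantiles, n_quantiles) +
    as.integer(seq_len(n_quantiles) <= n %% n_quantiles)
  g <- integer(n)
  g[ord] <- rep.int(seq_len(n_quantiles), sizes)
  g
}

#' Percent of individuals classified into the same exposure quantile
#'
#' Ranks individuals separately by the true metric and the estimate, cuts
#' both rankings into `n_quantiles` equal-count groups, and returns the
#' percentage landing in the same group. Random, unrelated rankings give
#' about `100/n_quantiles` percent.
#'
#' @param truth,estimate Numeric vectors over the same individuals.
#' @param n_quantiles 3 (tertiles) or 4 (quartiles), or any count >= 2.
#' @return Percent correctly classified, 0-100.
#' @export
quantile_accuracy <- function(truth, estimate, n_quantiles) {
  stopifnot(length(truth) == length(estimate))
  if (length(truth) < n_quantiles) {
    stop("Need at least as many individuals as quantile groups.",
         call. = FALSE)
  }
  idx <- seq_along(truth)
  100 * mean(quantile_groups(truth, n_quantiles, idx) ==
               quantile_groups(estimate, n_quantiles, idx))
}

#' @rdname quantile_accuracy
#' @param pools,aucs As in [r2_curve()].
#' @return `quantile_accuracy_curve()`: a tibble with columns `n`,
#'   `tertile_accuracy`, `quartile_accuracy` (percent).
#' @export
quantile_accuracy_curve <- function(pools, aucs) {
  df <- dplyr::inner_join(pools, aucs, by = "individual")
  df |>
    dplyr::group_by(n = .data$n) |>
    dplyr::summarise(
      tertile_accuracy = quantile_accuracy(.data$auc, .data$pooled, 3L),
      quartile_accuracy = quantile_accuracy(.data$auc, .data$pooled, 4L),
      .groups = "drop"
    )
}

#' One-way random-effects ANOVA intraclass correlation coefficient
#'
#' Treats individuals as the random grouping factor of a balanced one-way
#' ANOVA on (by default) log-transformed concentrations and returns
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)`, the proportion of total
#' variance attributable to between-person differences. Negative estimates
#' are clipped to 0 with a warning; the raw value is retained.
#'
#' @param samples Tibble with columns `individual` and `concentration`;
#'   every individual must contribute the same number k >= 2 of samples.
#' @param log_scale Analyse log concentrations (default TRUE, the standard
#'   choice for log-normal biomarkers).
#' @param clip Clip negative estimates to 0 (default TRUE).
#' @return A one-row tibble: `icc`, `icc_raw`, `msb`, `msw`, `k`,
#'   `n_individuals`.
#' @export
anova_icc <- function(samples, log_scale = TRUE, clip = TRUE) {
  stopifnot(all(c("individual", "concentration") %in% names(samples)))
  counts <- table(samples$individual)
  k <- unique(as.integer(counts))
  if (length(k) != 1L) {
    stop("Unbalanced design: every individual must have the same number of samples.",
         call. = FALSE)
  }
  if (k < 2L) stop("ICC needs at least 2 samples per individual.", call. = FALSE)
  m <- length(counts)
  if (m < 2L) stop("ICC needs at least 2 individuals.", call. = FALSE)
  y <- if (log_scale) log(samples$concentration) else samples$concentration
  if (log_scale && any(samples$concentration <= 0)) {
    stop("Non-positive concentrations cannot be log-transformed for the ICC.",
         call. = FALSE)
  }
  g <- as.factor(samples$individual)
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ssb <- k * sum((means - grand)^2)
  ssw <- sum((y - means[g])^2)
  msb <- ssb / (m - 1)
  msw <- ssw / (m * (k - 1))
  icc_raw <- (msb - msw) / (msb + (k - 1) * msw)
  icc <- icc_raw
  if (clip && !is.na(icc) && icc < 0) {
    warning(sprintf("Negative ANOVA ICC (%.4f) clipped to 0.", icc_raw),
            call. = FALSE)
    icc <- 0
  }
  tibble::tibble(icc = icc, icc_raw = icc_raw, msb = msb, msw = msw,
                 k = k, n_individuals = m)
}

#' Assemble the reliability report
#'
#' Combines the per-individual AUCs and collected samples into the three
#' output surfaces: the R^2-vs-n curve, the tertile/quartile classification
#' curves, the ANOVA ICC at k = `max_samples` individual samples, and the
#' scatter of AUC against the maximum-size pooled concentration.
#'
#' @param aucs Tibble `individual`, `auc`.
#' @param samples Tibble of collected samples (`individual`, `sample`,
#'   `day`, `concentration`).
#' @param config The [scenario()].
#' @return A `reliability_report` object: list with tibbles `curves`
#'   (`n`, `r2`, `tertile_accuracy`, `quartile_accuracy`), `icc`, `scatter`
#'   (`individual`, `auc`, `pooled`), and the `config`.
#' @export
build_report <- function(aucs, samples, config) {
  pools <- samples |>
    dplyr::group_by(.data$individual) |>
    dplyr::group_modify(~ pool_curve(.x)) |>
    dplyr::ungroup()
  curves <- dplyr::inner_join(r2_curve(pools, aucs),
                              quantile_accuracy_curve(pools, aucs),
                              by = "n")
  icc <- if (config$max_samples >= 2L) {
    anova_icc(samples)
  } else {
    tibble::tibble(icc = NA_real_, icc_raw = NA_real_, msb = NA_real_,
                   msw = NA_real_, k = 1L,
                   n_individuals = config$n_individuals)
  }
  nmax <- max(pools$n)
  scatter <- pools |>
    dplyr::filter(.data$n == nmax) |>
    dplyr::inner_join(aucs, by = "individual") |>
    dplyr::select("individual", "auc", "pooled")
  structure(list(curves = curves, icc = icc, scatter = scatter,
                 config = config),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>\n")
  cat(sprintf("  %d individuals, %d samples (%s, %s)\n",
              x$config$n_individuals, x$config$max_samples,
              x$config$sample_timing, x$config$standardization))
  nmax <- max(x$curves$n)
  last <- x$curves[x$curves$n == nmax, ]
  first <- x$curves[x$curves$n == 1L, ]
  cat(sprintf("  R^2        : %.3f (n=1) -> %.3f (n=%d)\n",
              first$r2, last$r2, nmax))
  cat(sprintf("  tertiles   : %.1f%% (n=1) -> %.1f%% (n=%d)\n",
              first$tertile_accuracy, last$tertile_accuracy, nmax))
  cat(sprintf("  quartiles  : %.1f%% (n=1) -> %.1f%% (n=%d)\n",
              first$quartile_accuracy, last$quartile_accuracy, nmax))
  cat(sprintf("  ANOVA ICC  : %s (k = %d)\n",
              ifelse(is.na(x$icc$icc), "NA", sprintf("%.3f", x$icc$icc)),
              x$icc$k))
  invisible(x)
}
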