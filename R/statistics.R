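## Paired nonparametric comparison harness: Wilcoxon signed-rank tests,
## rank-biserial effect sizes (in both the z/N form used in the source
## tables and the conventional z/sqrt(N)), Benjamini-Hochberg adjustment,
## and threshold success-rate summaries.

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences are `x - y` (or `x` directly when `y` is `NULL`).
#' Zero differences are dropped (Wilcoxon's original treatment; the count
#' is reported). Tied absolute differences are mid-ranked. The two-sided
#' p-value is exact (signed-rank null distribution) when `N <= 15` and
#' there are no ties; otherwise a tie-corrected normal approximation with
#' continuity correction is used. The z score is positive when `x` tends to
#' exceed `y`.
#'
#' @param x numeric vector (reference method's per-micrograph values, or
#'   precomputed differences).
#' @param y optional numeric vector paired with `x`.
#' @return an object of class `wsr_test`: `W` (sum of positive ranks), `z`,
#'   `p`, `n` (pairs after zero removal), `n_dropped`, `method`, and
#'   `no_information = TRUE` when every difference is zero (no p-value is
#'   produced in that case).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else {
    if (length(x) != length(y)) stopf("wilcoxon_signed_rank: unequal lengths")
    as.numeric(x) - as.numeric(y)
  }
  if (length(d) < 1) stopf("wilcoxon_signed_rank: empty sample")
  if (any(!is.finite(d))) stopf("wilcoxon_signed_rank: non-finite differences")
  n_dropped <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(W = NA_real_, z = NA_real_, p = NA_real_, n = 0L,
                          n_dropped = n_dropped, method = "no-information",
                          no_information = TRUE),
                     class = "wsr_test"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  num <- W - mu
  z <- if (num == 0 || sigma2 <= 0) 0 else (num - 0.5 * sign(num)) / sqrt(sigma2)
  if (!ties && n <= 15) {
    p <- min(1, 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n)))
    method <- "exact"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  structure(list(W = W, z = z, p = p, n = as.integer(n),
                 n_dropped = as.integer(n_dropped), method = method,
                 no_information = FALSE),
            class = "wsr_test")
}

#' @export
print.wsr_test <- function(x, ...) {
  if (isTRUE(x$no_information)) {
    cat("<wsr_test> all differences zero: no information\n")
  } else {
    cat(sprintf("<wsr_test> W = %g, z = %.3f, p = %.4g (n = %d, %s)\n",
                x$W, x$z, x$p, x$n, x$method))
  }
  invisible(x)
}

#' Rank-biserial effect sizes for a signed-rank z score
#'
#' Reports both conventions: `r_paper = z / N` (the form printed in the
#' source comparison tables) and the conventional `r_conventional =
#' z / sqrt(N)`. The two disagree except at N = 1; both are returned and
#' labeled, and neither is claimed to be the canonical rank-biserial
#' correlation (`1 - 2 W- / S`), which is a third convention.
#'
#' @param z signed-rank z score (see [wilcoxon_signed_rank()]).
#' @param n number of paired observations.
#' @return list with `r_paper` and `r_conventional`.
#' @export
effect_size <- function(z, n) {
  if (n < 1) stopf("effect_size: n must be >= 1")
  list(r_paper = z / n, r_conventional = z / sqrt(n))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1, returned
#' in input order.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]` (`NA`s pass
#'   through).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) {
    stopf("bh_adjust: p-values outside [0, 1] at position(s) %s",
          paste(which(!ok), collapse = ", "))
  }
  p.adjust(p_values, method = "BH")
}

#' Fraction of micrographs reaching each metric threshold
#'
#' @param values per-micrograph metric values in `[0, 1]`.
#' @param thresholds vector of thresholds.
#' @return named numeric vector: for each threshold `t`, the fraction of
#'   values `>= t`.
#' @export
threshold_success_rate <- function(values, thresholds) {
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stopf("threshold_success_rate: values must lie in [0, 1]")
  }
  out <- vapply(thresholds, function(t) mean(values >= t), numeric(1))
  names(out) <- format(thresholds)
  out
}

#' Paired comparison of picking methods across datasets
#'
#' For every metric and every (competitor, dataset) cell, runs a paired
#' Wilcoxon signed-rank test of the reference method against the competitor
#' on per-micrograph values (aligned by micrograph id), computes both
#' effect-size forms from the z score, and applies Benjamini-Hochberg
#' adjustment across all tests of the same metric family. Two-sided tests;
#' z > 0 means the reference method's values tend to be higher.
#'
#' @param data long-format data frame with columns `method`, `dataset`,
#'   `micrograph`, `metric`, `value`.
#' @param reference name of the reference method (must appear in `method`).
#' @return an object of class `stats_report`: a data frame with one row per
#'   (competitor, dataset, metric) carrying medians, `W`, `z`, raw and
#'   adjusted p, both effect sizes, and the dropped-zero count.
#' @export
compare_methods <- function(data, reference) {
  need <- c("method", "dataset", "micrograph", "metric", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("compare_methods: missing column(s) %s",
                          paste(miss, collapse = ", "))
  if (!reference %in% data$method) {
    stopf("compare_methods: reference method '%s' not present", reference)
  }
  competitors <- setdiff(unique(data$method), reference)
  rows <- list()
  for (met in unique(data$metric)) {
    dm <- data[data$metric == met, ]
    for (comp in competitors) {
      for (ds in unique(dm$dataset)) {
        ref_rows <- dm[dm$method == reference & dm$dataset == ds, ]
        cmp_rows <- dm[dm$method == comp & dm$dataset == ds, ]
        if (!setequal(ref_rows$micrograph, cmp_rows$micrograph) ||
            nrow(ref_rows) != nrow(cmp_rows)) {
          stopf("compare_methods: micrograph sets differ for dataset '%s' (%s vs %s)",
                ds, reference, comp)
        }
        ref_v <- ref_rows$value[order(ref_rows$micrograph)]
        cmp_v <- cmp_rows$value[order(cmp_rows$micrograph)]
        ts <- wilcoxon_signed_rank(ref_v, cmp_v)
        es <- if (ts$no_information) list(r_paper = NA_real_,
                                          r_conventional = NA_real_)
              else effect_size(ts$z, ts$n)
        rows[[length(rows) + 1]] <- data.frame(
          method = comp, dataset = ds, metric = met,
          n = length(ref_v), n_zero_dropped = ts$n_dropped,
          median_ref = median(ref_v), median_comp = median(cmp_v),
          W = if (ts$no_information) NA_real_ else ts$W,
          z = if (ts$no_information) NA_real_ else ts$z,
          p_raw = if (ts$no_information) NA_real_ else ts$p,
          r_paper = es$r_paper, r_conventional = es$r_conventional,
          no_information = ts$no_information)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (met in unique(out$metric)) {
    sel <- out$metric == met
    out$p_adj[sel] <- bh_adjust(out$p_raw[sel])
  }
  out <- out[, c("method", "dataset", "metric", "n", "n_zero_dropped",
                 "median_ref", "median_comp", "W", "z", "p_raw", "p_adj",
                 "r_paper", "r_conventional", "no_information")]
  class(out) <- c("stats_report", "data.frame")
  out
}
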