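#' Percentage change
#'
#' `100 * (new - ref) / ref`, the endpoint used in all paired comparisons.
#'
#' @param new,ref Numeric vectors (recycled); `ref` must be non-zero.
#' @return Percentage change(s).
#' @examples
#' percent_change(113.7, 100)  # 13.7
#' @export
percent_change <- function(new, ref) {
  if (any(ref == 0)) stop("reference value must be non-zero")
  100 * (new - ref) / ref
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normalizing transforms of the sample skewness and kurtosis
#' into the omnibus statistic `K^2 = Z1(sqrt(b1))^2 + Z2(b2)^2`, referred to
#' a chi-square distribution with 2 degrees of freedom. Requires n >= 8 for
#' the kurtosis transform.
#'
#' @param values Numeric sample (n >= 8, non-constant).
#' @return List with `statistic` (K^2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  if (stats::sd(values) == 0) stop("sample is constant")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  x <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1_b2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1_b2 * (2 / sqrt_b1_b2 + sqrt(1 + 4 / sqrt_b1_b2^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + x * sqrt(2 / (a - 4))))^(1 / 3)) *
    sqrt(9 * a / 2)

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped before
#' ranking (Wilcoxon's original procedure); ties receive average ranks. For
#' n <= `exact_max` (default 25) after zero removal, the exact two-sided p
#' is computed from the full null distribution of the positive-rank sum
#' (dynamic programming over all 2^n sign assignments, valid with ties);
#' otherwise a normal approximation with tie-corrected variance is used,
#' `p = 2 * min(P(W <= w), P(W >= w))` in both branches, capped at 1.
#'
#' @param diffs Numeric vector of paired differences, or `new` values when
#'   `ref` is given.
#' @param ref Optional reference values (`diffs - ref` is tested).
#' @param exact_max Largest n for the exact branch (default 25).
#' @return List with `statistic` (positive-rank sum W+), `p_value`, `n`
#'   (non-zero pairs), `method` ("exact" or "approx").
#' @export
wilcoxon_signed_rank <- function(diffs, ref = NULL, exact_max = 25L) {
  if (!is.null(ref)) diffs <- diffs - ref
  diffs <- diffs[is.finite(diffs)]
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  if (n < 1L) stop("no non-zero differences")
  r <- rank(abs(diffs))
  w <- sum(r[diffs > 0])
  if (n <= exact_max) {
    p <- exact_signed_rank_p(r, w)
    return(list(statistic = w, p_value = p, n = n, method = "exact"))
  }
  ew <- n * (n + 1) / 4
  tie_tab <- table(r)
  varw <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w - ew) / sqrt(varw)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = w, p_value = p, n = n, method = "approx")
}

# exact null distribution of W+ over all 2^n sign assignments via dynamic
# programming on doubled ranks (average ranks are half-integers)
exact_signed_rank_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # counts over achievable doubled sums 0..total
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  w2 <- round(2 * w)
  p_le <- sum(probs[seq_len(w2 + 1L)])
  p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the declared family size `m` (default: the
#' number of p-values) and caps at 1. Uses `stats::p.adjust` when `m` equals
#' the vector length.
#'
#' @param p_values Numeric p-values.
#' @param m Family size (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(m >= 1)
  if (m == length(p_values)) {
    return(stats::p.adjust(p_values, method = "bonferroni"))
  }
  pmin(1, p_values * m)
}

#' Paired comparison of lesion metrics across reconstructions
#'
#' For each requested comparison the per-lesion percentage change of a
#' metric is computed between two reconstruction variants, screened for
#' normality (when n >= 8), tested with the two-sided Wilcoxon signed-rank
#' test and Bonferroni-adjusted over the declared family.
#'
#' @param measurements Tibble with columns `lesion_id`, `recon_id` and the
#'   metric column.
#' @param metric Metric column name (e.g. `"suv_max"`, `"cnr"`).
#' @param comparisons List of `c(new, ref)` recon-id pairs.
#' @param m Bonferroni family size; default the number of comparisons.
#' @param alpha Significance level (default 0.05).
#' @return A tibble (`paired_change_result`): one row per comparison with
#'   `metric`, `comparison`, `n`, `median_change_pct`, `normality_p`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
paired_change_table <- function(measurements, metric, comparisons,
                                m = length(comparisons), alpha = 0.05) {
  rows <- lapply(comparisons, function(cp) {
    new_v <- measurements[measurements$recon_id == cp[1L], ]
    ref_v <- measurements[measurements$recon_id == cp[2L], ]
    common <- intersect(new_v$lesion_id, ref_v$lesion_id)
    nv <- new_v[[metric]][match(common, new_v$lesion_id)]
    rv <- ref_v[[metric]][match(common, ref_v$lesion_id)]
    chg <- percent_change(nv, rv)
    norm_p <- if (length(chg) >= 8L && stats::sd(chg) > 0) {
      dagostino_pearson(chg)$p_value
    } else NA_real_
    wt <- if (any(chg != 0)) wilcoxon_signed_rank(chg)$p_value else 1
    tibble::tibble(
      metric = metric,
      comparison = paste(cp[1L], "vs", cp[2L]),
      n = length(chg),
      median_change_pct = stats::median(chg),
      normality_p = norm_p,
      p_value = wt
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_value, m = m)
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("paired_change_result", class(out))
  out
}
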