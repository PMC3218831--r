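# ---------------------------------------------------------------------------
# Differential statistics: minimize-significant-changes normalization,
# binomial change test, Fisher / chi-squared event tests, significance calls
# and related helpers.
# ---------------------------------------------------------------------------

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes Number of successes (vectorized).
#' @param trials Number of trials (vectorized).
#' @param conf Confidence level (default 0.95).
#' @return A two-column matrix `lo`, `hi`. `trials = 0` gives `[0, 1]` by
#'   convention.
#' @export
wilson_interval <- function(successes, trials, conf = 0.95) {
  n <- max(length(successes), length(trials))
  successes <- rep_len(successes, n); trials <- rep_len(trials, n)
  if (any(successes < 0) || any(successes > trials))
    stop("need 0 <= successes <= trials")
  z <- qnorm(1 - (1 - conf) / 2)
  lo <- numeric(n); hi <- numeric(n)
  zero <- trials == 0
  lo[zero] <- 0; hi[zero] <- 1
  if (any(!zero)) {
    nn <- trials[!zero]
    p <- successes[!zero] / nn
    denom <- 1 + z^2 / nn
    center <- (p + z^2 / (2 * nn)) / denom
    half <- z * sqrt(p * (1 - p) / nn + z^2 / (4 * nn^2)) / denom
    lo[!zero] <- pmax(0, center - half)
    hi[!zero] <- pmin(1, center + half)
  }
  cbind(lo = lo, hi = hi)
}

#' Minimize-significant-changes estimate of effective library sizes
#'
#' Estimates the fraction `q2` of reads belonging to the second sample so as
#' to (approximately) minimize the number of significantly changed genes:
#' for every gene with at least one read a Wilson confidence interval for
#' `q2` is computed from its two counts (the range of `q2` for which that
#' gene is not significantly changed); the interval `[0, 1]` is split into
#' windows of width `1e-4` and each window is voted for by every interval
#' overlapping it. `q2` is the midpoint of the most-voted window, or the
#' mean of the midpoints when several windows tie. Effective totals are then
#' `n2 = q2 * N` and `n1 = N - n2`.
#'
#' @param g1,g2 Per-gene read counts in sample 1 and sample 2.
#' @param conf Confidence level for the per-gene intervals (default 0.95;
#'   the estimate is very robust to this choice).
#' @param N Total uniquely aligning reads from both samples; defaults to
#'   `sum(g1 + g2)`.
#' @param window_width Voting window width (default 1e-4).
#' @return An object of class `msc_norm` with fields `q2`, `N`, `n1`, `n2`,
#'   `window_width`, `max_count` (votes in the winning window) and `n_tied`.
#' @export
minimize_significant_changes <- function(g1, g2, conf = 0.95, N = NULL,
                                         window_width = 1e-4) {
  stopifnot(length(g1) == length(g2))
  if (any(g1 < 0) || any(g2 < 0)) stop("negative counts")
  g <- g1 + g2
  keep <- g >= 1
  if (!any(keep)) stop("no genes with at least one read")
  ci <- wilson_interval(g2[keep], g[keep], conf)
  nw <- as.integer(round(1 / window_width))
  # window k covers [k*w, (k+1)*w); an interval [lo, hi] votes for windows
  # floor(lo/w) .. floor(hi/w) (clamped)
  ks <- pmin(nw - 1L, as.integer(floor(ci[, "lo"] / window_width)))
  ke <- pmin(nw - 1L, as.integer(floor(ci[, "hi"] / window_width)))
  d <- integer(nw + 1L)
  ad <- tabulate(ks + 1L, nbins = nw)
  sub <- tabulate(ke + 2L, nbins = nw + 1L)
  votes <- cumsum(ad - sub[seq_len(nw)])
  mx <- max(votes)
  winners <- which(votes == mx)
  q2 <- mean((winners - 1L + 0.5) * window_width)
  if (is.null(N)) N <- sum(g)
  structure(list(q2 = q2, N = N, n2 = q2 * N, n1 = (1 - q2) * N,
                 window_width = window_width, max_count = mx,
                 n_tied = length(winners), conf = conf),
            class = "msc_norm")
}

#' @export
print.msc_norm <- function(x, ...) {
  cat("<msc_norm> q2 = ", format(x$q2, digits = 6), " (", x$max_count,
      " votes, ", x$n_tied, " tied window(s) of width ", x$window_width,
      ")\n  N = ", format(x$N, digits = 12), ", n1 = ",
      format(x$n1, digits = 8), ", n2 = ", format(x$n2, digits = 8),
      "\n", sep = "")
  invisible(x)
}

#' Two-tailed binomial test for a change in gene-level read counts
#'
#' Models the count in sample 2 as binomial with size `g = g1 + g2` and
#' success probability `q2 = n2 / (n1 + n2)`. The two-tailed P-value sums
#' the probabilities of all outcomes no more likely than the observed one
#' (relative tolerance `1 + 1e-7`); `g = 0` gives `p = 1`.
#'
#' @param g1,g2 Gene read counts in the two samples (vectorized).
#' @param n1,n2 Effective total read counts of the two samples.
#' @return Vector of two-tailed P-values.
#' @export
binomial_change_test <- function(g1, g2, n1, n2) {
  if (any(g1 < 0) || any(g2 < 0)) stop("negative counts")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("effective totals must be positive")
  n <- max(length(g1), length(g2))
  g1 <- rep_len(g1, n); g2 <- rep_len(g2, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  q2 <- n2 / (n1 + n2)
  vapply(seq_len(n), function(i) {
    g <- g1[i] + g2[i]
    if (g == 0) return(1)
    d <- dbinom(0:g, g, q2[i])
    min(1, sum(d[d <= d[g2[i] + 1L] * (1 + 1e-7)]))
  }, 1)
}

#' Fisher / chi-squared test for a two-by-two event contingency table
#'
#' Tests the table `rbind(c(a1, b1), c(a2, b2))` of reads supporting the two
#' isoforms in the two samples. When all four expected values exceed 5 the
#' chi-squared test with a capped continuity correction
#' (`min(0.5, |O - E|)`) is used; otherwise the two-sided Fisher exact test
#' (sum over tables no more probable than the observed one, relative
#' tolerance `1 + 1e-7`).
#'
#' @param a1,b1 Isoform A / B counts in sample 1.
#' @param a2,b2 Isoform A / B counts in sample 2.
#' @return list with `p` and `method` (`"fisher"` or `"chisq"`).
#' @export
event_test <- function(a1, b1, a2, b2) {
  if (any(c(a1, b1, a2, b2) < 0)) stop("negative counts")
  tot <- a1 + b1 + a2 + b2
  if (tot == 0) return(list(p = 1, method = "fisher"))
  r1 <- a1 + b1; r2 <- a2 + b2
  cA <- a1 + a2; cB <- b1 + b2
  e <- outer(c(r1, r2), c(cA, cB)) / tot
  if (all(e > 5)) {
    o <- matrix(c(a1, a2, b1, b2), 2)
    corr <- min(0.5, abs(a1 - e[1, 1]))
    stat <- sum((abs(o - e) - corr)^2 / e)
    return(list(p = pchisq(stat, df = 1, lower.tail = FALSE),
                method = "chisq"))
  }
  # hypergeometric enumeration over a1 with fixed margins
  k <- max(0, r1 - cB):min(r1, cA)
  d <- stats::dhyper(k, cA, cB, r1)
  p <- min(1, sum(d[d <= stats::dhyper(a1, cA, cB, r1) * (1 + 1e-7)]))
  list(p = p, method = "fisher")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (reported P-values are unadjusted
#' by default; this is opt-in downstream).
#'
#' @param p Vector of P-values.
#' @return Adjusted P-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold change on effective library sizes
#'
#' `(g2/n2) / (g1/n1)` with explicit markers for empty counts: `Inf` when
#' only sample 2 has reads, `0` when only sample 1 has reads, `NA` when
#' neither does.
#'
#' @param g1,g2 Gene counts.
#' @param n1,n2 Effective totals.
#' @return Numeric vector of fold changes.
#' @export
fold_change <- function(g1, g2, n1, n2) {
  fc <- (g2 / n2) / (g1 / n1)
  fc[g1 == 0 & g2 > 0] <- Inf
  fc[g2 == 0 & g1 > 0] <- 0
  fc[g1 == 0 & g2 == 0] <- NA_real_
  fc
}

#' Significance calls from P-values and fold changes
#'
#' `up` requires `p <= p_cutoff` and `fold >= fold_cutoff`; `down` requires
#' `p <= p_cutoff` and `fold <= 1/fold_cutoff`; everything else (including
#' missing folds) is `unchanged`. Infinite folds compare as expected.
#'
#' @param p P-values.
#' @param fold Fold (or ratio) changes.
#' @param p_cutoff,fold_cutoff Significance cutoffs.
#' @return Character vector in `{"up", "down", "unchanged"}`.
#' @export
call_changes <- function(p, fold, p_cutoff = 1e-4, fold_cutoff = 2) {
  stopifnot(p_cutoff > 0, p_cutoff <= 1, fold_cutoff >= 1)
  out <- rep("unchanged", length(p))
  sig <- !is.na(p) & p <= p_cutoff & !is.na(fold)
  out[sig & fold >= fold_cutoff] <- "up"
  out[sig & fold <= 1 / fold_cutoff] <- "down"
  out
}

#' Expected false positives under the global null
#'
#' Upper bound on the expected number of false positives when testing
#' `n_tests` null hypotheses at `p_cutoff` (e.g. 27,389 genes at 1e-4 gives
#' 2.7389, i.e. no more than 3).
#'
#' @param n_tests Number of tests.
#' @param p_cutoff P-value cutoff.
#' @return The expectation `n_tests * p_cutoff`.
#' @export
expected_false_positives <- function(n_tests, p_cutoff) {
  stopifnot(n_tests >= 1, p_cutoff > 0, p_cutoff <= 1)
  n_tests * p_cutoff
}

#' Gene-level change table for a two-sample comparison
#'
#' Applies the binomial change test with MSC-normalized effective totals to
#' every gene and attaches fold changes, optional BH-adjusted P-values and
#' significance calls. Counts for a group of lanes are the sums of the
#' member lanes' counts.
#'
#' @param g1,g2 Named per-gene counts for the two samples (or pooled
#'   groups).
#' @param norm An `msc_norm`; computed from the counts when `NULL`.
#' @param p_cutoff,fold_cutoff Significance cutoffs for the call column.
#' @param bh Attach BH-adjusted P-values?
#' @return data.frame `gene_id`, `g1`, `g2`, `fold_change`, `p`,
#'   (`p_bh`,) `call`, classed `gene_test_table` with the normalization in
#'   `attr(, "norm")`.
#' @export
gene_test <- function(g1, g2, norm = NULL, p_cutoff = 1e-4,
                      fold_cutoff = 2, bh = FALSE) {
  stopifnot(length(g1) == length(g2))
  ids <- names(g1)
  if (is.null(ids)) ids <- paste0("gene", seq_along(g1))
  if (is.null(norm)) norm <- minimize_significant_changes(g1, g2)
  p <- binomial_change_test(g1, g2, norm$n1, norm$n2)
  fc <- fold_change(g1, g2, norm$n1, norm$n2)
  out <- data.frame(gene_id = ids, g1 = g1, g2 = g2, fold_change = fc,
                    p = p, row.names = NULL, stringsAsFactors = FALSE)
  if (bh) out$p_bh <- bh_adjust(p)
  out$call <- call_changes(p, fc, p_cutoff, fold_cutoff)
  attr(out, "norm") <- norm
  attr(out, "cutoffs") <- c(p = p_cutoff, fold = fold_cutoff)
  class(out) <- c("gene_test_table", "data.frame")
  out
}

#' Event-level change table for a two-sample comparison
#'
#' Builds the 2x2 contingency table of isoform evidence counts for every
#' event and tests it with [event_test()]. The ratio change is
#' `(a2/b2)/(a1/b1)` with infinity markers for empty denominators.
#'
#' @param ect An `event_count_table` ([count_events()]), or a data.frame
#'   with columns `event_id`, `a1`, `b1`, `a2`, `b2`.
#' @param sample1,sample2 Column names (or index vectors, summed for lane
#'   groups) selecting the two samples when `ect` is an
#'   `event_count_table`.
#' @param p_cutoff,ratio_cutoff Significance cutoffs for the call column.
#' @param bh Attach BH-adjusted P-values?
#' @return data.frame with counts, ratios, `p`, `method`, and `call`.
#' @export
event_change_test <- function(ect, sample1 = 1, sample2 = 2,
                              p_cutoff = 1e-4, ratio_cutoff = 2,
                              bh = FALSE) {
  if (inherits(ect, "event_count_table")) {
    a1 <- .pool_cols(ect$a, sample1); b1 <- .pool_cols(ect$b, sample1)
    a2 <- .pool_cols(ect$a, sample2); b2 <- .pool_cols(ect$b, sample2)
    df <- data.frame(event_id = rownames(ect$a),
                     event_type = ect$events$event_type,
                     gene_id = ect$events$gene_id,
                     a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                     stringsAsFactors = FALSE, row.names = NULL)
  } else {
    df <- as.data.frame(ect)
  }
  res <- lapply(seq_len(nrow(df)),
                function(i) event_test(df$a1[i], df$b1[i], df$a2[i],
                                       df$b2[i]))
  df$ratio1 <- ifelse(df$b1 > 0, df$a1 / df$b1,
                      ifelse(df$a1 > 0, Inf, NA_real_))
  df$ratio2 <- ifelse(df$b2 > 0, df$a2 / df$b2,
                      ifelse(df$a2 > 0, Inf, NA_real_))
  rc <- df$ratio2 / df$ratio1
  rc[is.nan(rc)] <- NA_real_
  df$ratio_change <- rc
  df$p <- vapply(res, `[[`, 1, "p")
  df$method <- vapply(res, `[[`, "", "method")
  if (bh) df$p_bh <- bh_adjust(df$p)
  df$call <- call_changes(df$p, df$ratio_change, p_cutoff, ratio_cutoff)
  attr(df, "cutoffs") <- c(p = p_cutoff, fold = ratio_cutoff)
  class(df) <- c("event_test_table", "data.frame")
  df
}

.pool_cols <- function(m, j) {
  sub <- m[, j, drop = FALSE]
  as.integer(rowSums(sub))
}

#' Pairwise expression correlation matrix with clustering order
#'
#' Pearson correlation of `log2(RPKM + 1)` expression profiles between all
#' sample pairs, plus an average-linkage clustering order on distance
#' `1 - r`.
#'
#' @param rpkm_mat Gene x sample RPKM matrix.
#' @return list with `r` (correlation matrix; `NA` for zero-variance
#'   samples) and `order` (sample ordering from average-linkage clustering;
#'   `NULL` when correlations are undefined).
#' @export
correlation_matrix <- function(rpkm_mat) {
  stopifnot(ncol(rpkm_mat) >= 2, nrow(rpkm_mat) >= 2)
  lg <- log2(rpkm_mat + 1)
  sds <- apply(lg, 2, stats::sd)
  r <- suppressWarnings(stats::cor(lg))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  ord <- NULL
  if (all(sds > 0)) {
    hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
    ord <- hc$order
  }
  list(r = r, order = ord)
}

#' Expression-matched background gene set
#'
#' Greedily matches each changed (target) gene, in descending count order,
#' to the unchanged candidate gene with the closest count on the log scale
#' (`|log((c+1)/(t+1))|`), without replacement; ties break to the
#' lexicographically smaller gene id. Matching on raw read counts (rather
#' than RPKM) avoids transcript-length bias.
#'
#' @param candidates Named numeric vector: counts of unchanged genes.
#' @param targets Named numeric vector: counts of changed genes.
#' @return Character vector of matched background gene ids, parallel to
#'   `targets` sorted by descending count.
#' @export
background_set <- function(candidates, targets) {
  if (length(candidates) < length(targets))
    stop("candidate pool smaller than target set")
  ord <- order(-targets, names(targets))
  pool <- candidates[order(names(candidates))]
  out <- character(length(targets))
  for (i in seq_along(ord)) {
    t <- targets[ord[i]]
    d <- abs(log((pool + 1) / (t + 1)))
    best <- which(d == min(d))[1L]  # pool is id-sorted: first hit = lexicographic tie-break
    out[i] <- names(pool)[best]
    pool <- pool[-best]
  }
  setNames(out, names(targets)[ord])
}

#' Summarize microarray probe intensities to gene levels
#'
#' Detected probes are probes with positive background-subtracted intensity
#' in every array; each gene's level per array is the median intensity of
#' its detected probes. Genes without any detected probe get `NA` levels.
#'
#' @param intensities Probe x array numeric matrix (background-subtracted;
#'   may be negative).
#' @param probe_gene Named character vector mapping probe (name) to gene id;
#'   probes mapping to no gene are ignored.
#' @return Gene x array matrix of median detected-probe intensities.
#' @export
summarize_probes <- function(intensities, probe_gene) {
  probes <- intersect(rownames(intensities), names(probe_gene))
  genes <- unique(unname(probe_gene[probes]))
  out <- matrix(NA_real_, length(genes), ncol(intensities),
                dimnames = list(genes, colnames(intensities)))
  detected <- rowSums(intensities[probes, , drop = FALSE] > 0) ==
    ncol(intensities)
  for (g in genes) {
    pr <- probes[probe_gene[probes] == g & detected[probes]]
    if (length(pr))
      out[g, ] <- apply(intensities[pr, , drop = FALSE], 2, median)
  }
  out
}

#' Welch two-sample t-test on log-level vectors
#'
#' @param x,y Numeric vectors (log levels) with at least two values each.
#' @return Two-sided P-value. Degenerate zero-variance input returns 1 for
#'   equal means and 0 otherwise.
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}
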