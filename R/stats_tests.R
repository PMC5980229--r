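#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic sum((O - E)^2 / E) without continuity correction,
#' df = (r - 1)(c - 1), p from the chi-square distribution. No correction
#' is applied anywhere in the package: the population comparisons of unit
#' proportions (e.g. inhibited by training group) reproduce only without
#' it.
#'
#' @param table integer matrix of counts, at least 2 x 2, non-negative.
#' @return List: \code{statistic}, \code{df}, \code{p}.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0))
    stop(sprintf("zero marginal: row %d has no observations",
                 which(rs == 0)[1L]))
  if (any(cs == 0))
    stop(sprintf("zero marginal: column %d has no observations",
                 which(cs == 0)[1L]))
  E <- outer(rs, cs) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Exact two-tailed p-value from the hypergeometric distribution over
#' tables with the observed margins: the sum of the probabilities of all
#' tables no more probable than the observed one (with a small relative
#' tolerance against floating-point ties, as is conventional).
#'
#' @param table 2 x 2 integer matrix of counts.
#' @return List: \code{p}, \code{odds_ratio} (sample OR, for direction).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0))
  m <- sum(table[1L, ]); n <- sum(table[2L, ]); k <- sum(table[, 1L])
  x <- table[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p <- sum(dens[dens <= dens[support == x] * (1 + 1e-7)])
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(p = min(1, p), odds_ratio = or)
}

# Distribution of the doubled-rank sum over size-k subsets of `dranks`
# (integer doubled midranks): counts[k+1, s+1] = number of subsets of size
# k with doubled sum s. Exact dynamic programme; counts held as doubles.
subset_rank_sum_counts <- function(dranks, kmax) {
  smax <- sum(dranks)
  counts <- matrix(0, nrow = kmax + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  for (r in dranks) {
    for (k in kmax:1) {
      # shift row k-1 by r and add into row k
      src <- counts[k, seq_len(smax + 1L - r)]
      counts[k + 1L, (r + 1L):(smax + 1L)] <-
        counts[k + 1L, (r + 1L):(smax + 1L)] + src
    }
  }
  counts
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. For small samples (both groups at
#' most 12) the p-value is exact, computed from the full permutation
#' distribution of the rank sum over subsets of the pooled ranks (a
#' dynamic programme equivalent to enumerating every assignment, and valid
#' under ties). Larger samples use the normal approximation with the tie
#' correction and no continuity correction. Two-tailed throughout.
#'
#' @param a,b numeric samples.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) enumeration;
#'   default chooses by sample size.
#' @return List: \code{U} (statistic for sample \code{a}), \code{p},
#'   \code{exact}.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  use_exact <- exact %||% (max(n1, n2) <= 12L)
  if (use_exact) {
    dr <- as.integer(round(2 * r))
    counts <- subset_rank_sum_counts(dr, n1)[n1 + 1L, ]
    total <- choose(N, n1)
    dR1 <- as.integer(round(2 * R1))
    sums <- seq_along(counts) - 1L
    p_le <- sum(counts[sums <= dR1]) / total
    p_ge <- sum(counts[sums >= dR1]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = p, exact = use_exact)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; absolute differences are midranked and
#' W+ is the rank sum of the positive ones. For n <= 15 non-zero
#' differences the p-value is exact over all 2^n sign assignments
#' (dynamic programme over the doubled ranks); beyond that, normal
#' approximation with tie correction, no continuity correction. Two-tailed.
#' All-zero input abstains (no direction can be tested).
#'
#' @param diffs numeric vector of paired differences.
#' @return List: \code{W} (positive-rank sum), \code{n} (non-zero
#'   differences), \code{p} (NA when abstaining), \code{exact}.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0 & !is.na(diffs)]
  n <- length(d)
  if (n == 0L)
    return(list(W = NA_real_, n = 0L, p = NA_real_, exact = NA))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  use_exact <- n <= 15L
  if (use_exact) {
    dr <- as.integer(round(2 * r))
    smax <- sum(dr)
    # g[s+1] = number of sign assignments whose positive doubled-rank sum = s
    g <- numeric(smax + 1L); g[1L] <- 1
    for (rr in dr) {
      shifted <- c(numeric(rr), g[seq_len(smax + 1L - rr)])
      g <- g + shifted
    }
    dW <- as.integer(round(2 * W))
    sums <- seq_along(g) - 1L
    total <- 2^n
    p_le <- sum(g[sums <= dW]) / total
    p_ge <- sum(g[sums >= dW]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - n * (n + 1) / 4) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(W = W, n = n, p = p, exact = use_exact)
}

laser_protocols <- list(
  ArchT = list(off_s = 10, on_s = 10),
  ChR2 = list(off_s = 30, on_s = 30)
)

#' Classify a unit's laser modulation (optrode protocol)
#'
#' Compares firing during laser OFF and laser ON epochs in 1-s bins.
#' ArchT protocol: 10 s OFF then 10 s ON per trial (constant green light);
#' ChR2: 30 s OFF then 30 s ON (pulsed blue light at 2 or 4 Hz). Per 1-s
#' bin index, rates are averaged across trials; the OFF and ON bin
#' profiles are then compared with a Wilcoxon signed-rank test. p below
#' \code{alpha} calls an increase or decrease by the sign of the mean
#' difference; otherwise no change.
#'
#' @param unit a \code{unit_recording} or a numeric vector of spike times.
#' @param laser_onsets_s times at which the laser turns on, one per trial;
#'   the OFF epoch is the window of equal length immediately preceding.
#' @param protocol \code{"ArchT"} or \code{"ChR2"}.
#' @param alpha significance level.
#' @return List: \code{label} (\code{"increase"}, \code{"decrease"},
#'   \code{"none"}), \code{p}, \code{off_rate_hz}, \code{on_rate_hz}.
#' @export
classify_laser_modulation <- function(unit, laser_onsets_s,
                                      protocol = c("ArchT", "ChR2"),
                                      alpha = 0.05) {
  protocol <- match.arg(protocol)
  st <- if (inherits(unit, "unit_recording")) unit$spike_times_s
        else as.numeric(unit)
  pr <- laser_protocols[[protocol]]
  stopifnot(pr$off_s == pr$on_s)
  D <- as.integer(pr$on_s)
  count_bins <- function(start) {
    edges <- start + 0:D
    tabulate(findInterval(st, edges), nbins = D + 1L)[seq_len(D)]
  }
  off <- sapply(laser_onsets_s, function(o) count_bins(o - D))
  on <- sapply(laser_onsets_s, function(o) count_bins(o))
  off_mean <- rowMeans(matrix(off, nrow = D))
  on_mean <- rowMeans(matrix(on, nrow = D))
  wt <- wilcoxon_signed_rank(on_mean - off_mean)
  label <- "none"
  if (!is.na(wt$p) && wt$p < alpha)
    label <- if (mean(on_mean - off_mean) > 0) "increase" else "decrease"
  list(label = label, p = wt$p, off_rate_hz = mean(off_mean),
       on_rate_hz = mean(on_mean))
}
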