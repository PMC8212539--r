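# Statistical core: exact binomial allele-dosage test with Bonferroni
# control, the two-proportion z-test for pairwise mutation-count
# comparisons, and an exact Fisher test for 2 x k spectrum tables.

#' Exact lower-tail binomial probability
#'
#' \eqn{P(X \le x)} for \eqn{X \sim Binomial(n, p_0)}, computed by exact
#' term-by-term summation of the probability mass function in log space, so
#' the tail stays accurate for depths in the thousands.
#'
#' @param x Observed count (vectorised); \code{0 <= x <= n}.
#' @param n Number of trials; \code{n >= 1}.
#' @param p0 Null success probability (default 0.5, the expectation for a
#'   heterozygous site).
#' @return Lower-tail p-value(s).
#' @examples
#' binomial_lower_p(10, 60)   # the 10:50 allele-depth case
#' @export
binomial_lower_p <- function(x, n, p0 = 0.5) {
  if (length(n) == 1L) n <- rep(n, length(x))
  if (length(x) != length(n)) stop("x and n lengths differ")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(x < 0) || any(x > n)) stop("x must satisfy 0 <= x <= n")
  lp <- log(p0); lq <- log1p(-p0)
  vapply(seq_along(x), function(i) {
    k <- 0:x[i]
    terms <- lchoose(n[i], k) + k * lp + (n[i] - k) * lq
    min(exp(logsumexp(terms)), 1)
  }, numeric(1))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error level.
#' @param m Number of tests; \code{m >= 1}.
#' @return \code{alpha / m}.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Configuration for the dosage and group tests
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Bonferroni family size. Defaults to 1 (a standalone test);
#'   pipeline runs set it to the number of dosage tests performed.
#' @param p0 Null allele dosage (default 0.5).
#' @param continuity Use the continuity correction in the two-proportion
#'   z-test (default \code{TRUE}).
#' @param hom_error_rate Per-read miscall probability used for the
#'   homozygous-alternate consistency check (default 0.01).
#' @param two_sided Use a two-sided dosage test ("statistically equivalent
#'   to 0.5") instead of the one-sided lower-tail mosaic test.
#' @export
test_config <- function(alpha = 0.05, m = 1L, p0 = 0.5, continuity = TRUE,
                        hom_error_rate = 0.01, two_sided = FALSE) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  structure(list(alpha = alpha, m = m, p0 = p0, continuity = continuity,
                 hom_error_rate = hom_error_rate, two_sided = two_sided),
            class = "test_config")
}

#' Classify allele dosage as heterozygous, mosaic, or homozygous-alternate
#'
#' Allele dosage is the alternate read count divided by total depth. For
#' heterozygous calls (code 2), a dosage significantly below 0.5 under the
#' exact binomial test at the Bonferroni-corrected level marks the variant
#' mosaic (arisen after the first cell division); otherwise it is a true
#' heterozygous variant. Homozygous-alternate calls (code 3) are checked
#' for consistency with dosage 1 given a per-read error rate; failures are
#' labelled \code{inconsistent}.
#'
#' @param alt_reads,ref_reads Integer vectors of per-sample read counts.
#' @param code Genotype codes (2 or 3) for the same sites.
#' @param cfg A \code{\link{test_config}}.
#' @return Data frame with \code{x}, \code{n}, \code{dosage},
#'   \code{p_lower}, \code{label} (one of heterozygous, mosaic,
#'   homozygous_alt, inconsistent).
#' @export
classify_dosage <- function(alt_reads, ref_reads, code, cfg = test_config()) {
  stopifnot(length(alt_reads) == length(ref_reads),
            length(code) == length(alt_reads))
  if (!all(code %in% c(2L, 3L))) stop("classify_dosage expects codes 2 or 3")
  n <- alt_reads + ref_reads
  thr <- bonferroni_alpha(cfg$alpha, cfg$m)
  out <- data.frame(x = alt_reads, n = n, dosage = NA_real_,
                    p_lower = NA_real_, label = NA_character_,
                    stringsAsFactors = FALSE)
  zero <- is.na(n) | n < 1
  if (any(zero)) {
    warning(sum(zero), " call(s) with zero depth labelled inconsistent")
    out$label[zero] <- "inconsistent"
  }
  ok <- !zero
  if (any(ok)) {
    out$dosage[ok] <- alt_reads[ok] / n[ok]
    out$p_lower[ok] <- binomial_lower_p(alt_reads[ok], n[ok], cfg$p0)
    het <- ok & code == 2L
    if (any(het)) {
      pl <- out$p_lower[het]
      pu <- 1 - pl + stats::dbinom(alt_reads[het], n[het], cfg$p0)
      sig <- if (cfg$two_sided) pmin(2 * pmin(pl, pu), 1) < thr else pl < thr
      out$label[het] <- ifelse(sig, "mosaic", "heterozygous")
    }
    hom <- ok & code == 3L
    if (any(hom)) {
      # P(ref reads >= observed | per-read error): small p means too many
      # reference reads for a genuine homozygous-alternate genotype
      p_hom <- 1 - binomial_lower_p(pmax(ref_reads[hom] - 1L, 0L), n[hom],
                                    cfg$hom_error_rate)
      p_hom[ref_reads[hom] == 0L] <- 1
      out$label[hom] <- ifelse(p_hom >= thr, "homozygous_alt", "inconsistent")
    }
  }
  out
}

#' Two-proportion z-test
#'
#' Pooled two-proportion z-test with optional continuity correction,
#' two-sided. Used for pairwise comparisons of de novo mutation counts
#' between cloned calves against a common denominator of tested sites.
#'
#' @param x1,n1,x2,n2 Successes and trials per group.
#' @param continuity Apply the correction \eqn{(1/n_1 + 1/n_2)/2} to the
#'   absolute difference (floored at zero).
#' @return List with \code{z}, \code{p} (two-sided), and \code{degenerate}
#'   (\code{TRUE} when the pooled proportion is 0 or 1, in which case
#'   \code{p = 1}).
#' @export
two_proportion_test <- function(x1, n1, x2, n2, continuity = TRUE) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2, n1 > 0, n2 > 0)
  phat <- (x1 + x2) / (n1 + n2)
  if (phat <= 0 || phat >= 1)
    return(list(z = 0, p = 1, degenerate = TRUE))
  cc <- if (continuity) (1 / n1 + 1 / n2) / 2 else 0
  num <- max(abs(x1 / n1 - x2 / n2) - cc, 0)
  z <- num / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  list(z = z, p = min(2 * stats::pnorm(-z), 1), degenerate = FALSE)
}

# enumerate the log-probabilities of all 2 x k tables with the observed
# margins under the multivariate hypergeometric null; returns the matrix of
# first-row vectors and their log-probabilities
enumerate_2xk <- function(col_totals, r1) {
  k <- length(col_totals)
  N <- sum(col_totals)
  grid <- list(0:min(r1, col_totals[1]))
  for (j in seq_len(k - 1)[-1]) grid[[j]] <- 0:min(r1, col_totals[j])
  if (k == 2) {
    a1 <- grid[[1]]
    a1 <- a1[r1 - a1 >= 0 & r1 - a1 <= col_totals[2]]
    rows <- cbind(a1, r1 - a1)
  } else {
    ex <- expand.grid(grid[seq_len(k - 1)])
    last <- r1 - rowSums(ex)
    ok <- last >= 0 & last <= col_totals[k]
    rows <- cbind(as.matrix(ex[ok, , drop = FALSE]), last[ok])
  }
  lp <- -lchoose(N, r1)
  for (j in seq_len(k)) lp <- lp + lchoose(col_totals[j], rows[, j])
  list(rows = rows, logp = lp)
}

#' Exact Fisher test for a 2 x k contingency table
#'
#' Exact conditional test with both margins fixed: enumerates every 2 x k
#' table with the observed margins and sums the multivariate hypergeometric
#' probabilities of tables no more probable than the observed one (ties
#' included at relative tolerance 1e-12). For k = 2 this is the classical
#' two-sided Fisher exact test.
#'
#' @param counts A 2 x k matrix (k in 2..4) of non-negative counts.
#' @return The exact p-value; 1 when any margin is zero.
#' @export
fisher_exact_2xk <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop("counts must have 2 rows")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0 || any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    return(1)
  col_totals <- colSums(counts)
  r1 <- sum(counts[1, ])
  en <- enumerate_2xk(col_totals, r1)
  obs <- -lchoose(sum(col_totals), r1) +
    sum(lchoose(col_totals, counts[1, ]))
  keep <- en$logp <= obs + log1p(1e-12)
  if (all(keep)) return(1)
  min(sum(exp(en$logp[keep])), 1)
}
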