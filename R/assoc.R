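# log(sum(exp(x))) without leaving log space
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

as_table4 <- function(x) {
  if (is.matrix(x) && all(dim(x) == c(2L, 2L)))
    x <- matrix(c(x[1, 1], x[1, 2], x[2, 1], x[2, 2]), nrow = 1L)
  else if (is.numeric(x) && length(x) == 4L && !is.matrix(x))
    x <- matrix(x, nrow = 1L)
  else if (!(is.matrix(x) && ncol(x) == 4L))
    stop("expected a 2x2 matrix, a length-4 vector (a,b,c,d), or an n x 4 matrix")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  x
}

#' Two-sided Fisher's exact test for 2x2 tables
#'
#' Point-probability convention: with row and column margins fixed, the
#' two-sided p-value is the sum of hypergeometric probabilities of all
#' tables whose point probability does not exceed that of the observed
#' table (ties resolved with a relative tolerance of 1e-7, the convention
#' of standard statistics environments). All probabilities are computed
#' and summed in log space, so extreme tables yield accurate tail
#' p-values far below double-precision underflow of the naive sum.
#'
#' @param x a 2x2 matrix, a length-4 vector (a, b, c, d read row-wise), or
#'   an n x 4 matrix of tables (one per row) for vectorised use.
#' @param log10_p return log10(p) instead of p.
#' @return numeric vector of two-sided p-values (or their log10).
#' @export
fisher_exact <- function(x, log10_p = FALSE) {
  x <- as_table4(x)
  one <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    if (n == 0L) return(if (log10_p) 0 else 1)
    lo <- max(0L, c1 - r2); hi <- min(r1, c1)
    k <- lo:hi
    lp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
    lobs <- lp[k == a]
    keep <- lp <= lobs + log(1 + 1e-7)
    lpv <- min(logsumexp(lp[keep]), 0)
    if (log10_p) lpv / log(10) else exp(lpv)
  }
  vapply(seq_len(nrow(x)),
         function(i) one(x[i, 1], x[i, 2], x[i, 3], x[i, 4]),
         numeric(1))
}

#' Chi-squared test with Yates continuity correction for 2x2 tables
#'
#' The statistic is \eqn{\sum (\max(|O - E| - 0.5, 0))^2 / E} over the
#' four cells, with expected counts from the margins; the p-value is the
#' upper tail of the chi-square distribution with one degree of freedom,
#' computed in log space so bounds such as p < 2.2e-16 can be verified on
#' log-p rather than on an underflowed double. A zero expected count
#' leaves the statistic undefined (NA) with p = 1 and a warning.
#'
#' @inheritParams fisher_exact
#' @param correct apply the continuity correction (default TRUE; the
#'   uncorrected statistic is available with \code{correct = FALSE}).
#' @return for a single table, a list with \code{statistic},
#'   \code{p.value} and \code{log10_p}; for an n x 4 matrix, a
#'   \code{data.table} with those columns.
#' @export
chisq_yates <- function(x, correct = TRUE) {
  x <- as_table4(x)
  one <- function(a, b, c, d) {
    O <- matrix(c(a, b, c, d), 2L, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    if (any(E == 0)) {
      warning("zero expected count; statistic undefined, p set to 1")
      return(c(NA_real_, 1, 0))
    }
    adj <- if (correct) pmax(abs(O - E) - 0.5, 0) else abs(O - E)
    stat <- sum(adj^2 / E)
    c(stat, pchisq(stat, df = 1, lower.tail = FALSE),
      pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10))
  }
  res <- t(vapply(seq_len(nrow(x)),
                  function(i) one(x[i, 1], x[i, 2], x[i, 3], x[i, 4]),
                  numeric(3)))
  if (nrow(res) == 1L)
    list(statistic = res[1, 1], p.value = res[1, 2], log10_p = res[1, 3])
  else
    data.table::data.table(statistic = res[, 1], p.value = res[, 2],
                           log10_p = res[, 3])
}

#' Manhattan-plot table from per-marker test results
#'
#' Sorts per-marker p-values by genomic position and adds
#' \eqn{-\log_{10} p}. P-values that underflowed to exactly 0 in double
#' precision are reported at a documented cap of 320 with the
#' \code{capped} flag set; finite values above the cap are capped too.
#'
#' @param tests data frame with columns contig, pos, p.
#' @param cap cap on \eqn{-\log_{10} p} (default 320, just above the
#'   smallest positive double).
#' @return \code{data.table}: contig, pos, p, neg_log10_p, capped, sorted
#'   by (contig, pos).
#' @export
manhattan_table <- function(tests, cap = 320) {
  p <- tests$p
  if (any(is.na(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1] (0 only by documented underflow)")
  nl <- ifelse(p == 0, Inf, -log10(p))
  out <- data.table::data.table(contig = tests$contig, pos = tests$pos, p = p,
                                neg_log10_p = pmin(nl, cap),
                                capped = nl > cap)
  data.table::setorder(out, contig, pos)
  out[]
}
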