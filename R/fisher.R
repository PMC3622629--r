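# Strand bias statistics. The central object is the 2x2 contingency table
#
#              match  mismatch  | total
#   forward      a       b      |   f
#   backward     c       d      |   k
#   ------------------------------------
#   total        m       s      |   n
#
# where "forward"/"backward" refer to the context read direction after the
# F-/R-position bookkeeping of accumulate_tables(). Fisher's exact test is
# computed under the probability-ordering two-sided definition ("more
# extreme" = lower null probability) entirely in log space, so that the
# strand bias score -log10(p) stays finite even when p underflows double
# precision (scores of several hundred are routine on real data).

.as_abcd <- function(table) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L)))
      stop("'table' must be 2x2", call. = FALSE)
    # rows = direction, columns = match/mismatch
    table <- c(table[1L, 1L], table[1L, 2L], table[2L, 1L], table[2L, 2L])
  }
  if (length(table) != 4L || any(is.na(table)) || any(table < 0) ||
      any(table != floor(table)))
    stop("'table' must hold four non-negative integer counts a,b,c,d",
         call. = FALSE)
  table <- as.numeric(table)
  names(table) <- c("a", "b", "c", "d")
  table
}

# log hypergeometric point probability of table entry a' given marginals
.log_null_prob <- function(a, f, k, m) {
  lchoose(f, a) + lchoose(k, m - a) - lchoose(f + k, m)
}

#' Null (hypergeometric) probability of a contingency table
#'
#' Probability of observing table entry `a` under the independence null with
#' all marginals `M = (f, k, m, s, n)` fixed:
#' \deqn{Pr_{H0}(a | M) = \binom{a+b}{a}\binom{c+d}{c} / \binom{n}{a+c}.}
#' Computed via log-factorials for numerical range.
#'
#' @param a Observed count of forward-direction matches.
#' @param marginals Numeric vector `c(f, k, m, s)` or `c(f, k, m, s, n)` of
#'   row sums `f, k` and column sums `m, s` (and optionally the total `n`).
#' @return List with elements `prob` and `log_prob` (natural log).
#' @examples
#' null_probability(3, c(3, 3, 3, 3))$prob # 1/20
#' @export
null_probability <- function(a, marginals) {
  if (!length(marginals) %in% c(4L, 5L))
    stop("'marginals' must be c(f, k, m, s) or c(f, k, m, s, n)",
         call. = FALSE)
  f <- marginals[[1L]]; k <- marginals[[2L]]
  m <- marginals[[3L]]; s <- marginals[[4L]]
  n <- if (length(marginals) == 5L) marginals[[5L]] else f + k
  if (any(c(f, k, m, s, n) < 0) || f + k != n || m + s != n)
    stop("inconsistent marginals: need f + k = m + s = n", call. = FALSE)
  if (length(a) != 1L || is.na(a) || a != floor(a) ||
      a < max(0, m - k) || a > min(f, m))
    stop("'a' outside the feasible range [max(0, m - k), min(f, m)]",
         call. = FALSE)
  lp <- .log_null_prob(a, f, k, m)
  list(prob = exp(lp), log_prob = lp)
}

# Core: natural-log two-sided p-value of (a, b, c, d). The extreme set is
# {a' : Pr(a'|M) <= Pr(a|M)}, with ties admitted at relative tolerance 1e-12.
# Chunked so that tables with huge marginals never materialize the full
# feasible range at once.
.fisher_log_p <- function(a, b, c, d, chunk = 1e6) {
  f <- a + b; k <- c + d; m <- a + c; n <- f + k
  if (n == 0) return(0) # empty table: no evidence, p = 1
  lo <- max(0, m - k); hi <- min(f, m)
  lp_obs <- .log_null_prob(a, f, k, m)
  thresh <- lp_obs + log1p(1e-12)
  best <- -Inf; acc <- 0
  from <- lo
  while (from <= hi) {
    to <- min(from + chunk - 1, hi)
    lp <- .log_null_prob(seq(from, to), f, k, m)
    lp <- lp[lp <= thresh]
    if (length(lp)) {
      mx <- max(lp)
      if (mx > best) {
        acc <- acc * exp(best - mx) + sum(exp(lp - mx))
        best <- mx
      } else {
        acc <- acc + sum(exp(lp - best))
      }
    }
    from <- to + 1
  }
  min(0, best + log(acc))
}

#' Fisher's exact test and strand bias score, in log space
#'
#' Two-sided Fisher's exact p-value of a 2x2 match/mismatch-by-direction
#' table under the probability-ordering definition: the p-value sums
#' `Pr(a'|M)` over all tables whose null probability does not exceed that of
#' the observed one. The summation is carried out in log space, so the
#' strand bias score `-log10(p)` remains finite for arbitrarily significant
#' tables even though `p` itself may underflow to 0 in double precision.
#'
#' @param table 2x2 matrix (rows = forward/backward direction, columns =
#'   match/mismatch) or a length-4 vector `c(a, b, c, d)`.
#' @return List with `p_value` (may underflow to 0 for extreme tables),
#'   `log10_p` (exact, finite), and `score = -log10_p`, the strand bias
#'   score.
#' @examples
#' fisher_log10_p(c(731, 169, 1330, 7))$score # about 60.7
#' fisher_log10_p(c(5, 5, 5, 5))$score        # 0: no strand bias
#' @export
fisher_log10_p <- function(table) {
  t4 <- .as_abcd(table)
  lp <- .fisher_log_p(t4[["a"]], t4[["b"]], t4[["c"]], t4[["d"]])
  l10 <- lp / log(10)
  list(p_value = exp(lp), log10_p = l10, score = -l10)
}

#' Chi-squared alternative to the exact test
#'
#' One-degree-of-freedom chi-squared test of independence on the 2x2 table,
#' offered as a fast approximation for tables with large entries. The exact
#' Fisher computation is always the package default; the chi-squared path is
#' strictly opt-in.
#'
#' @inheritParams fisher_log10_p
#' @param correct Apply the Yates continuity correction (default `TRUE`,
#'   matching [stats::chisq.test()]).
#' @return The chi-squared p-value.
#' @export
chi2_p <- function(table, correct = TRUE) {
  t4 <- .as_abcd(table)
  f <- t4[["a"]] + t4[["b"]]; k <- t4[["c"]] + t4[["d"]]
  m <- t4[["a"]] + t4[["c"]]; s <- t4[["b"]] + t4[["d"]]
  if (any(c(f, k, m, s) == 0))
    stop("chi-squared test undefined for tables with a zero marginal",
         call. = FALSE)
  mat <- matrix(t4, nrow = 2L, byrow = TRUE)
  suppressWarnings(stats::chisq.test(mat, correct = correct)$p.value)
}

#' Bonferroni-corrected significance threshold for motif discovery
#'
#' Per-test p-value cutoff `T = alpha / |S(q, n)|` controlling the
#' family-wise error rate over all motif hypotheses in the space `S(q, n)`.
#'
#' @param alpha Family-wise error rate level in (0, 1].
#' @inheritParams motif_space_size
#' @return The p-value cutoff.
#' @examples
#' bonferroni_threshold(0.05, 4, 1) # 0.05 / 512
#' @export
bonferroni_threshold <- function(alpha, q, n) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be in (0, 1]", call. = FALSE)
  alpha / motif_space_size(q, n)
}
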