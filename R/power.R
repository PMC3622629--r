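# Empirical power of position-wise strand-bias testing. At a single genome
# position with coverage n (n/2 reads per direction), a context-specific
# error rate e on the forward row and a background rate on the reverse row,
# how often does Fisher's exact test reject at a Bonferroni-corrected level?
# Sampling restricts tables to equal row sums, which suffices for the
# illustration; rejection always uses the exact log-space Fisher test,
# never the chi-squared approximation.

#' Sample strand-biased contingency tables
#'
#' Draws tables with equal row sums `coverage/2`: forward mismatches
#' `b ~ Binomial(coverage/2, e)`, reverse mismatches
#' `d ~ Binomial(coverage/2, background_rate)`, matches as complements.
#' Uses the current R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param e Position-specific forward mismatch probability in \[0, 1\].
#' @param background_rate Context-unrelated background mismatch probability
#'   in \[0, 1\] (applied to the reverse row).
#' @param coverage Total reads covering the position (even, positive).
#' @param reps Number of tables to draw.
#' @return A data.frame with columns `a`, `b`, `c`, `d`, one row per table.
#' @examples
#' set.seed(7)
#' sample_table(e = 0.5, background_rate = 0.01, coverage = 100, reps = 3)
#' @export
sample_table <- function(e, background_rate = 0.01, coverage, reps = 1L) {
  .check_rate(e, "e"); .check_rate(background_rate, "background_rate")
  if (length(coverage) != 1L || is.na(coverage) || coverage <= 0 ||
      coverage %% 2 != 0)
    stop("'coverage' must be a positive even integer", call. = FALSE)
  n2 <- coverage / 2
  b <- stats::rbinom(reps, n2, e)
  d <- stats::rbinom(reps, n2, background_rate)
  data.frame(a = n2 - b, b = b, c = n2 - d, d = d)
}

.check_rate <- function(x, nm) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", nm, "' must be a probability in [0, 1]", call. = FALSE)
}

#' Empirical power of the position-wise strand bias test
#'
#' Fraction of `reps` sampled tables (see [sample_table()]) whose exact
#' two-sided Fisher p-value is `<= alpha`. With the default
#' `alpha = 0.05 / 5e7` -- a Bonferroni-corrected level for testing every
#' position of a human exome -- even extreme per-position error rates are
#' hard to detect at moderate coverage, which is the motivation for pooling
#' positions by motif instead of testing them one by one.
#'
#' @inheritParams sample_table
#' @param alpha Rejection level for the exact test.
#' @return List with `power` (rejection fraction), `se` (binomial standard
#'   error `sqrt(p(1-p)/reps)`), `rejected`, and `reps`.
#' @examples
#' set.seed(1)
#' estimate_power(e = 0.9, coverage = 60, alpha = 1e-6, reps = 200)$power
#' @export
estimate_power <- function(e, background_rate = 0.01, coverage,
                           alpha = 0.05 / 5e7, reps = 3000L) {
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]",
                                    call. = FALSE)
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  tabs <- sample_table(e, background_rate, coverage, reps = reps)
  # the p-value depends only on (b, d); cache over distinct mismatch pairs
  key <- paste(tabs$b, tabs$d)
  uk <- !duplicated(key)
  lp <- vapply(which(uk), function(i)
    .fisher_log_p(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]), numeric(1L))
  names(lp) <- key[uk]
  rejected <- sum(lp[key] <= log(alpha))
  p_hat <- rejected / reps
  list(power = p_hat, se = sqrt(p_hat * (1 - p_hat) / reps),
       rejected = rejected, reps = as.integer(reps))
}

#' Power across a coverage-by-error-rate grid
#'
#' One [estimate_power()] call per grid cell. The default grids span
#' coverages 2--200 in steps of 2 and error rates 0.1--0.9, with 3000
#' repetitions per cell; shrink `reps` or the grids for quick runs.
#'
#' @inheritParams estimate_power
#' @param e Vector of position-specific error rates.
#' @param coverage Vector of (even) coverages.
#' @param seed Optional integer seed set once before the sweep; recorded in
#'   the result's `seed` attribute.
#' @return data.frame with columns `coverage`, `e`, `power`, `stderr`.
#' @export
power_curve <- function(e = seq(0.1, 0.9, by = 0.1),
                        coverage = seq(2L, 200L, by = 2L),
                        background_rate = 0.01, alpha = 0.05 / 5e7,
                        reps = 3000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(coverage = coverage, e = e)
  est <- lapply(seq_len(nrow(grid)), function(i)
    estimate_power(grid$e[i], background_rate, grid$coverage[i], alpha, reps))
  out <- data.frame(coverage = grid$coverage, e = grid$e,
                    power = vapply(est, `[[`, numeric(1L), "power"),
                    stderr = vapply(est, `[[`, numeric(1L), "se"))
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  attr(out, "background_rate") <- background_rate
  attr(out, "reps") <- as.integer(reps)
  out
}

#' Plot a power curve
#'
#' Power against coverage, one colored line per position-specific error
#' rate. Requires ggplot2.
#'
#' @param curve Output of [power_curve()].
#' @return A ggplot object.
#' @export
plot_power_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_power_curve() requires the ggplot2 package", call. = FALSE)
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = coverage, y = power, colour = factor(e))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "read coverage", y = "statistical power",
                  colour = "error rate e") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
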