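# End-to-end context discovery: aggregate q-gram tables into motif tables,
# test each motif's pooled table for strand bias, apply the
# significance -> RER -> ERD filter cascade, and rank survivors by
# decreasing error rate difference.

#' Discovery parameter set
#'
#' Validates and bundles the discovery parameters: motif length `q`,
#' maximum wildcards `n`, family-wise error level `alpha`, background
#' (reverse) error rate ceiling `epsilon`, and error-rate-difference cutoff
#' `delta`. Typical settings are `q <= 10`, `n <= q/2`, `alpha = 0.05`,
#' `epsilon = 0.03`, `delta = 0.05`; for long motifs such as `(q, n) =
#' (8, 4)` a stricter `delta = 0.1` concentrates reporting on
#' high-error-rate contexts.
#'
#' @inheritParams motif_space_size
#' @param alpha Family-wise error rate in (0, 1].
#' @param epsilon Motifs whose reverse error rate `RER >= epsilon` are
#'   discarded as background-noisy; in (0, 1).
#' @param delta Minimum error rate difference `ERD = FER - RER` for a motif
#'   to be reported; in (0, 1).
#' @return A `cse_config` list.
#' @export
discovery_config <- function(q, n, alpha = 0.05, epsilon = 0.03,
                             delta = 0.05) {
  .check_q_n(q, n)
  if (q > 12) stop("'q' must be <= 12 (q-gram map memory bound)",
                   call. = FALSE)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be in (0, 1]", call. = FALSE)
  for (nm in c("epsilon", "delta")) {
    v <- get(nm)
    if (length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      stop("'", nm, "' must be in (0, 1)", call. = FALSE)
  }
  structure(list(q = as.integer(q), n = as.integer(n), alpha = alpha,
                 epsilon = epsilon, delta = delta),
            class = "cse_config")
}

#' Aggregate q-gram tables into a motif table
#'
#' The contingency table of a wildcard motif is the cellwise sum of the
#' tables of all concrete q-grams it matches; its occurrence count is the
#' corresponding sum of F- plus R-positions.
#'
#' @param motif Motif string over `{A,C,G,T,N}`.
#' @param map A `qgram_table_map` from [accumulate_tables()].
#' @return List with `table` (named `a`,`b`,`c`,`d`), `occurrences`, and
#'   `present` (`FALSE` when the motif matches no q-gram occurring in the
#'   reference; such motifs are excluded from testing).
#' @export
aggregate_motif_table <- function(motif, map) {
  stopifnot(inherits(map, "qgram_table_map"))
  .check_alphabet(motif, .MOTIF_CHARS, "'motif'")
  if (nchar(motif) != map$q)
    stop("motif length does not match the map's q", call. = FALSE)
  hit <- motif_matches(motif, map$tables$qgram)
  if (!any(hit))
    return(list(table = c(a = 0, b = 0, c = 0, d = 0), occurrences = 0L,
                present = FALSE))
  tb <- map$tables[hit, , drop = FALSE]
  list(table = c(a = sum(tb$a), b = sum(tb$b), c = sum(tb$c), d = sum(tb$d)),
       occurrences = as.integer(sum(tb$f_occ) + sum(tb$r_occ)),
       present = TRUE)
}

#' Forward/reverse error rates and their difference
#'
#' `FER = b / (a + b)`, `RER = d / (c + d)`, `ERD = FER - RER`. A rate with
#' zero denominator is undefined and returned as `NA` (motifs with an empty
#' table row are excluded from discovery upstream).
#'
#' @inheritParams fisher_log10_p
#' @return Named numeric vector `c(FER, RER, ERD)` (fractions, not
#'   percentages).
#' @examples
#' compute_rates(c(731, 169, 1330, 7)) # FER 0.188, RER 0.005
#' @export
compute_rates <- function(table) {
  t4 <- .as_abcd(table)
  fer <- if (t4[["a"]] + t4[["b"]] > 0) t4[["b"]] / (t4[["a"]] + t4[["b"]])
         else NA_real_
  rer <- if (t4[["c"]] + t4[["d"]] > 0) t4[["d"]] / (t4[["c"]] + t4[["d"]])
         else NA_real_
  c(FER = fer, RER = rer, ERD = fer - rer)
}

#' Discover context-specific error motifs
#'
#' Runs the full discovery pipeline: accumulate per-q-gram contingency
#' tables ([accumulate_tables()]), aggregate them over every motif of
#' `S(q, n)` occurring in the reference, score each pooled table with the
#' log-space Fisher test, keep motifs with `p <= alpha / |S(q, n)|`
#' (Bonferroni), drop motifs with `RER >= epsilon`, drop motifs with
#' `ERD < delta`, and rank the survivors by decreasing ERD. All surviving
#' motifs are reported; similar motifs are not merged. Ranking is by ERD
#' rather than by score, because a large score may only reflect many
#' occurrences or deep coverage, not a high error rate.
#'
#' @inheritParams accumulate_tables
#' @param n Maximum number of `N` wildcards per motif.
#' @param alpha,epsilon,delta See [discovery_config()].
#' @param config Optionally a ready-made [discovery_config()]; overrides
#'   `q`, `n`, `alpha`, `epsilon`, `delta`.
#' @return A `cse_result` data.frame, one row per reported motif, ordered by
#'   rank: columns `motif`, `rank`, `occurrences`, `a`, `c`, `b`, `d`
#'   (forward/reverse matches then mismatches), `score`, `p_value`, `FER`,
#'   `RER`, `ERD` (fractions). Attributes `config` and `filter_counts`
#'   (tested / significant / after RER / after ERD, plus motifs excluded
#'   for an empty table row) document the cascade. Zero rows is a valid
#'   outcome.
#' @export
discover_cse <- function(reference, alignments, q = NULL, n = NULL,
                         alpha = 0.05, epsilon = 0.03, delta = 0.05,
                         config = NULL,
                         n_as_mismatch = TRUE, exclude_duplicates = FALSE,
                         verbose = TRUE) {
  if (is.null(config)) config <- discovery_config(q, n, alpha, epsilon, delta)
  stopifnot(inherits(config, "cse_config"))

  map <- accumulate_tables(reference, alignments, config$q,
                           n_as_mismatch = n_as_mismatch,
                           exclude_duplicates = exclude_duplicates,
                           verbose = verbose)
  res <- .test_motifs(map, config, verbose = verbose)
  attr(res, "map") <- map
  res
}

# motif aggregation + testing + filtering, separated so that null-data
# simulations can reuse an existing map
.test_motifs <- function(map, config, verbose = TRUE) {
  tabs <- as.data.table(map$tables)
  pairs <- .motif_generalizations(tabs$qgram, config$n)
  mt <- pairs[tabs, on = "qgram"][
    , .(a = sum(a), b = sum(b), c = sum(c), d = sum(d),
        occurrences = sum(f_occ + r_occ)), by = motif]

  n_present <- nrow(mt)
  mt <- mt[a + b > 0 & c + d > 0]
  n_zero_row <- n_present - nrow(mt)
  if (verbose && n_zero_row > 0)
    message(n_zero_row,
            " motif(s) excluded for zero coverage in one context direction")

  mt[, p_log := vapply(seq_len(.N),
                       function(i) .fisher_log_p(a[i], b[i], c[i], d[i]),
                       numeric(1L))]
  mt[, score := -p_log / log(10)]
  mt[, fer := b / (a + b)]
  mt[, rer := d / (c + d)]
  mt[, erd := fer - rer]

  threshold <- bonferroni_threshold(config$alpha, config$q, config$n)
  sig <- mt[p_log <= log(threshold)]
  rer_ok <- sig[rer < config$epsilon]
  erd_ok <- rer_ok[erd >= config$delta]

  # rank by decreasing ERD; ties broken by score, then motif string, for
  # byte-identical reports run to run
  setorderv(erd_ok, c("erd", "score", "motif"), order = c(-1L, -1L, 1L))
  res <- data.frame(motif = erd_ok$motif,
                    rank = seq_len(nrow(erd_ok)),
                    occurrences = as.integer(erd_ok$occurrences),
                    a = erd_ok$a, c = erd_ok$c, b = erd_ok$b, d = erd_ok$d,
                    score = erd_ok$score,
                    p_value = exp(erd_ok$p_log),
                    FER = erd_ok$fer, RER = erd_ok$rer, ERD = erd_ok$erd,
                    stringsAsFactors = FALSE)
  attr(res, "config") <- config
  attr(res, "filter_counts") <- c(tested = nrow(mt),
                                  excluded_zero_row = n_zero_row,
                                  significant = nrow(sig),
                                  after_rer = nrow(rer_ok),
                                  after_erd = nrow(erd_ok))
  attr(res, "bonferroni_threshold") <- threshold
  class(res) <- c("cse_result", "data.frame")
  res
}

#' @export
print.cse_result <- function(x, ...) {
  cfg <- attr(x, "config")
  fc <- attr(x, "filter_counts")
  cat(sprintf("CSE motif discovery, (q, n) = (%d, %d), alpha = %g, epsilon = %g, delta = %g\n",
              cfg$q, cfg$n, cfg$alpha, cfg$epsilon, cfg$delta))
  cat(sprintf("  motifs tested: %d | significant: %d | RER < %g: %d | ERD >= %g: %d\n",
              fc[["tested"]], fc[["significant"]], cfg$epsilon,
              fc[["after_rer"]], cfg$delta, fc[["after_erd"]]))
  if (nrow(x) == 0L) {
    cat("  no motifs passed the filters\n")
    return(invisible(x))
  }
  shown <- data.frame(motif = x$motif, rank = x$rank, occ = x$occurrences,
                      a = x$a, c = x$c, b = x$b, d = x$d,
                      score = sprintf("%.1f", x$score),
                      `FER%` = sprintf("%.1f", 100 * x$FER),
                      `RER%` = sprintf("%.1f", 100 * x$RER),
                      `ERD%` = sprintf("%.1f", 100 * x$ERD),
                      check.names = FALSE)
  print(utils::head(shown, 25L), row.names = FALSE)
  if (nrow(x) > 25L) cat("  ... and", nrow(x) - 25L, "more motifs\n")
  invisible(x)
}

#' Write discovery reports
#'
#' Writes the ranked motif list as a TSV (Table-style column order: motif,
#' rank, occurrences, forward/reverse matches `FM`/`RM`, mismatches
#' `FMM`/`RMM`, score and percentage rates at one decimal) and/or as JSON
#' with unrounded values and the full configuration echoed.
#'
#' @param results A `cse_result` from [discover_cse()].
#' @param tsv,json Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_cse_report <- function(results, tsv = NULL, json = NULL) {
  stopifnot(inherits(results, "cse_result"))
  out <- character(0)
  if (!is.null(tsv)) {
    hu <- data.frame(motif = results$motif, rank = results$rank,
                     occurrences = results$occurrences,
                     FM = results$a, RM = results$c,
                     FMM = results$b, RMM = results$d,
                     score = sprintf("%.1f", results$score),
                     FER_pct = sprintf("%.1f", 100 * results$FER),
                     RER_pct = sprintf("%.1f", 100 * results$RER),
                     ERD_pct = sprintf("%.1f", 100 * results$ERD),
                     stringsAsFactors = FALSE)
    utils::write.table(hu, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, tsv)
  }
  if (!is.null(json)) {
    cfg <- attr(results, "config")
    payload <- list(
      config = unclass(cfg),
      bonferroni_threshold = attr(results, "bonferroni_threshold"),
      filter_counts = as.list(attr(results, "filter_counts")),
      motifs = results[, c("motif", "rank", "occurrences", "a", "c", "b",
                           "d", "score", "p_value", "FER", "RER", "ERD")])
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    out <- c(out, json)
  }
  invisible(out)
}
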