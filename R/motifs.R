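# Generalized-string motifs over {A,C,G,T,N}. A motif of length q with up to
# n wildcard positions denotes the set of concrete q-grams obtained by
# substituting each N with any base. Motifs are plain uppercase character
# strings throughout, so they can serve directly as hash keys.

.MOTIF_CHARS <- c("A", "C", "G", "T", "N")

.check_q_n <- function(q, n) {
  if (length(q) != 1L || is.na(q) || q < 1 || q != floor(q))
    stop("'q' must be a single positive integer", call. = FALSE)
  if (length(n) != 1L || is.na(n) || n < 0 || n > q || n != floor(n))
    stop("'n' must be a single integer with 0 <= n <= q", call. = FALSE)
  invisible(NULL)
}

.check_alphabet <- function(x, allowed, what) {
  bad <- !grepl(sprintf("^[%s]+$", paste(allowed, collapse = "")), x)
  if (any(bad))
    stop(what, " may only contain ", paste(allowed, collapse = ","),
         " (offending value: ", x[which(bad)[1L]], ")", call. = FALSE)
  invisible(NULL)
}

#' Size of the wildcard motif space S(q, n)
#'
#' Number of generalized strings of length `q` over `{A,C,G,T,N}` with at
#' most `n` wildcard (`N`) positions:
#' \deqn{|S(q,n)| = \sum_{i=0}^{n} \binom{q}{i} 4^{q-i},}
#' the i-th term counting the motifs with exactly i Ns. This is the number
#' of strand-bias hypotheses tested at a given parameter setting, and the
#' denominator of the Bonferroni threshold.
#'
#' @param q Motif length (positive integer).
#' @param n Maximum number of `N` wildcards, `0 <= n <= q`.
#' @return The motif-space size as a numeric scalar.
#' @examples
#' motif_space_size(4, 1) # 512
#' motif_space_size(8, 4) # 386560
#' @export
motif_space_size <- function(q, n) {
  .check_q_n(q, n)
  i <- 0:n
  sum(choose(q, i) * 4^(q - i))
}

#' Enumerate the motif space S(q, n)
#'
#' Generates every generalized string of length `q` with at most `n` `N`
#' wildcards, exactly once, in a fixed deterministic order: lexicographic
#' with the alphabet ordered A < C < G < T < N.
#'
#' @inheritParams motif_space_size
#' @return Character vector of length `motif_space_size(q, n)`.
#' @examples
#' enumerate_motifs(1, 1) # "A" "C" "G" "T" "N"
#' length(enumerate_motifs(4, 1)) # 512
#' @export
enumerate_motifs <- function(q, n) {
  .check_q_n(q, n)
  if (motif_space_size(q, n) > 5e6)
    stop("refusing to materialize a motif space larger than 5e6", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  out <- vector("list", n + 1L)
  for (i in 0:n) {
    combos <- if (i == 0L) matrix(integer(0), nrow = 0L, ncol = 1L)
              else utils::combn(q, i)
    if (i == 0L) {
      grids <- do.call(expand.grid,
                       c(rep(list(bases), q), stringsAsFactors = FALSE))
      out[[1L]] <- do.call(paste0, grids)
    } else {
      per_combo <- vector("list", ncol(combos))
      for (j in seq_len(ncol(combos))) {
        npos <- combos[, j]
        free <- setdiff(seq_len(q), npos)
        if (length(free) == 0L) {
          per_combo[[j]] <- strrep("N", q)
          next
        }
        grids <- do.call(expand.grid,
                         c(rep(list(bases), length(free)),
                           stringsAsFactors = FALSE))
        cols <- rep(list(rep("N", nrow(grids))), q)
        for (col in seq_along(free)) cols[[free[col]]] <- grids[[col]]
        per_combo[[j]] <- do.call(paste0, cols)
      }
      out[[i + 1L]] <- unlist(per_combo, use.names = FALSE)
    }
  }
  motifs <- unlist(out, use.names = FALSE)
  # A<C<G<T<N collation via a strictly increasing proxy alphabet
  motifs[order(chartr("ACGTN", "ABCDE", motifs), method = "radix")]
}

#' Does a motif match a concrete q-gram?
#'
#' A motif matches a q-gram of the same length iff at every position the
#' motif symbol is `N` or equals the q-gram symbol. For example, `GNT`
#' matches `GAT`, `GCT`, `GGT` and `GTT`.
#'
#' @param motif Motif string(s) over `{A,C,G,T,N}`.
#' @param qgram Concrete DNA string(s) over `{A,C,G,T}`, same length as
#'   `motif`. `motif` and `qgram` are recycled against each other.
#' @return Logical vector.
#' @examples
#' motif_matches("GNT", c("GAT", "GAC")) # TRUE FALSE
#' @export
motif_matches <- function(motif, qgram) {
  .check_alphabet(motif, .MOTIF_CHARS, "'motif'")
  .check_alphabet(qgram, c("A", "C", "G", "T"), "'qgram'")
  r <- vctrs_recycle2(motif, qgram)
  motif <- r[[1L]]; qgram <- r[[2L]]
  if (any(nchar(motif) != nchar(qgram)))
    stop("'motif' and 'qgram' must have equal lengths", call. = FALSE)
  out <- logical(length(motif))
  for (m in unique(motif)) {
    idx <- motif == m
    pat <- sprintf("^%s$", gsub("N", "[ACGT]", m, fixed = TRUE))
    out[idx] <- grepl(pat, qgram[idx])
  }
  out
}

# minimal common-length recycling (base R has no exported helper)
vctrs_recycle2 <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == ny) return(list(x, y))
  if (nx == 1L) return(list(rep(x, ny), y))
  if (ny == 1L) return(list(x, rep(y, nx)))
  stop("incompatible lengths", call. = FALSE)
}

#' Reverse complement of DNA strings or motifs
#'
#' Reverses the string and complements A<->T, C<->G; the wildcard `N` is
#' self-complementary. Only `{A,C,G,T,N}` are accepted; other IUPAC codes
#' are rejected rather than silently complemented.
#'
#' @param x Character vector of DNA/motif strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement(c("GGT", "GNT")) # "ACC" "ANC"
#' @export
reverse_complement <- function(x) {
  if (!is.character(x)) stop("'x' must be a character vector", call. = FALSE)
  .check_alphabet(x, .MOTIF_CHARS, "'x'")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All motifs with <= n wildcards that match each q-gram in `qgrams`.
# Returns a data.table (qgram, motif); each q-gram contributes
# sum_{i=0..n} C(q,i) rows. Used to aggregate q-gram tables into motif
# tables by going from present q-grams to their generalizations, which is
# linear in the number of *present* q-grams rather than in |S(q,n)|.
.motif_generalizations <- function(qgrams, n) {
  if (length(qgrams) == 0L)
    return(data.table(qgram = character(0), motif = character(0)))
  q <- nchar(qgrams[1L])
  chars <- matrix(unlist(strsplit(qgrams, "", fixed = TRUE), use.names = FALSE),
                  ncol = q, byrow = TRUE)
  pieces <- list(data.table(qgram = qgrams, motif = qgrams))
  for (i in seq_len(n)) {
    combos <- utils::combn(q, i)
    for (j in seq_len(ncol(combos))) {
      cm <- chars
      cm[, combos[, j]] <- "N"
      pieces[[length(pieces) + 1L]] <-
        data.table(qgram = qgrams,
                   motif = do.call(paste0, lapply(seq_len(q),
                                                 function(cc) cm[, cc])))
    }
  }
  rbindlist(pieces)
}
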