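# Independent oracles used to validate the package's optimized paths.
# Everything here recomputes from first principles (direct binomial
# coefficients, per-position re-scans, regex matching) and shares no code
# with the implementation under test.

# reverse complement by an explicit per-character map, then reversal
oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(map[strsplit(s, "")[[1L]]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# two-sided probability-ordering Fisher p by direct choose() arithmetic in
# linear (non-log) space; valid for n up to a few hundred
oracle_fisher_p <- function(a, b, c, d) {
  f <- a + b; k <- c + d; m <- a + c; n <- f + k
  if (n == 0) return(1)
  pr <- function(x) choose(f, x) * choose(k, m - x) / choose(n, m)
  support <- max(0, m - k):min(f, m)
  probs <- vapply(support, pr, numeric(1L))
  sum(probs[probs <= pr(a) * (1 + 1e-12)])
}

# occurrence count of a wildcard motif on both strands via regex with
# lookahead (overlapping matches count)
oracle_occurrences <- function(ref, motif) {
  pat <- sprintf("(?=%s)", gsub("N", "[ACGT]", motif, fixed = TRUE))
  count1 <- function(seq, p) {
    hits <- gregexpr(p, seq, perl = TRUE)[[1L]]
    sum(hits > 0)
  }
  rcm <- oracle_revcomp(motif)
  sum(vapply(ref, count1, numeric(1L), p = pat)) +
    sum(vapply(ref, count1, numeric(1L),
               p = sprintf("(?=%s)", gsub("N", "[ACGT]", rcm, fixed = TRUE))))
}

# naive accumulator: for every position and read independently re-derive
# pileup membership, strand role windows, and match status
oracle_accumulate <- function(ref, reads, q, n_as_mismatch = TRUE) {
  tabs <- new.env(parent = emptyenv())
  add <- function(g, v) {
    cur <- if (is.null(tabs[[g]])) c(0, 0, 0, 0) else tabs[[g]]
    assign(g, cur + v, envir = tabs)
  }
  pure <- function(w) grepl("^[ACGT]+$", w)
  for (contig in names(ref)) {
    sq <- ref[[contig]]
    len <- nchar(sq)
    rr <- reads[reads$contig == contig, , drop = FALSE]
    for (p in seq_len(len)) {
      fb <- character(0); rb <- character(0)
      for (i in seq_len(nrow(rr))) {
        s <- rr$pos[i]; L <- nchar(rr$seq[i])
        if (p >= s && p <= s + L - 1) {
          base <- substr(rr$seq[i], p - s + 1, p - s + 1)
          if (bitwAnd(rr$flag[i], 16L)) rb <- c(rb, base)
          else fb <- c(fb, base)
        }
      }
      refb <- substr(sq, p, p)
      if (!refb %in% c("A", "C", "G", "T")) next
      if (!n_as_mismatch) {
        fb <- fb[fb != "N"]; rb <- rb[rb != "N"]
      }
      mf <- sum(fb == refb); xf <- length(fb) - mf
      mr <- sum(rb == refb); xr <- length(rb) - mr
      if (p >= q) {
        w <- substr(sq, p - q + 1, p)
        if (pure(w)) add(w, c(mf, xf, mr, xr))
      }
      if (p + q - 1 <= len) {
        w <- oracle_revcomp(substr(sq, p, p + q - 1))
        if (pure(w)) add(w, c(mr, xr, mf, xf))
      }
    }
  }
  keys <- sort(ls(tabs))
  out <- data.frame(qgram = keys,
                    a = vapply(keys, function(g) tabs[[g]][1L], numeric(1L)),
                    b = vapply(keys, function(g) tabs[[g]][2L], numeric(1L)),
                    c = vapply(keys, function(g) tabs[[g]][3L], numeric(1L)),
                    d = vapply(keys, function(g) tabs[[g]][4L], numeric(1L)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# minimal SAM writer for fixtures (all-match CIGAR, fixed quality)
write_sam_fixture <- function(reads, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  o <- order(reads$contig, reads$pos)
  reads <- reads[o, , drop = FALSE]
  body <- if (nrow(reads)) sprintf(
    "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
    reads$qname, reads$flag, reads$contig, reads$pos, nchar(reads$seq),
    reads$seq, strrep("I", nchar(reads$seq))) else character(0)
  writeLines(c(hdr, body), path)
  path
}

# random small aligned dataset over a random reference (uniform errors)
random_dataset <- function(ref_len = 300, n_reads = 120, read_len = 40,
                           err = 0.02, contig = "ctg") {
  sq <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
              collapse = "")
  starts <- sample.int(ref_len - read_len + 1L, n_reads, replace = TRUE)
  flags <- sample(c(0L, 16L), n_reads, replace = TRUE)
  seqs <- vapply(starts, function(s) {
    b <- strsplit(substr(sq, s, s + read_len - 1L), "")[[1L]]
    hit <- which(runif(read_len) < err)
    for (h in hit) b[h] <- sample(setdiff(c("A", "C", "G", "T"), b[h]), 1L)
    paste(b, collapse = "")
  }, character(1L))
  list(ref = stats::setNames(sq, contig),
       reads = data.frame(qname = sprintf("r%04d", seq_len(n_reads)),
                          flag = flags, contig = contig, pos = starts,
                          seq = seqs, stringsAsFactors = FALSE))
}

# reverse-complement an entire dataset: flip the reference, every read's
# direction, coordinates, and sequence
flip_dataset <- function(ref, reads) {
  lens <- nchar(ref)
  ref2 <- stats::setNames(oracle_revcomp(unname(ref)), names(ref))
  L <- nchar(reads$seq)
  reads2 <- reads
  reads2$flag <- bitwXor(reads$flag, 16L)
  reads2$pos <- lens[reads$contig] - (reads$pos + L - 1L) + 1L
  reads2$seq <- oracle_revcomp(reads$seq)
  list(ref = ref2, reads = reads2)
}

# map-to-data.frame convenience for comparisons against oracles
map_counts <- function(map) {
  df <- map$tables[, c("qgram", "a", "b", "c", "d")]
  df <- df[order(df$qgram), , drop = FALSE]
  row.names(df) <- NULL
  df
}
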