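# One linear pass over reference + alignments producing a 2x2 contingency
# table per concrete q-gram. A genome position p (0-based, forward
# coordinates) plays up to two strand roles:
#
#   * F-position of g_F = ref[p-q+1 .. p]            (window ends at p)
#   * R-position of g_R = revcomp(ref[p .. p+q-1])   (window starts at p)
#
# The pileup column at p is classified into forward-read and reverse-read
# matches/mismatches against the forward reference (reverse-read bases are
# stored in forward convention in SAM/BAM, so no re-complementing is
# needed). F-positions contribute (a,b,c,d) += (Fmatch, Fmm, Rmatch, Rmm);
# R-positions contribute with the direction roles swapped, so that row one
# of every table always counts the reads whose own sequencing direction
# passes through the context before the potential error site.

.load_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- reference
  } else if (is.character(reference) && length(reference) == 1L &&
             is.null(names(reference)) && file.exists(reference)) {
    seqs <- Biostrings::readDNAStringSet(reference)
  } else if (is.character(reference)) {
    if (is.null(names(reference)))
      stop("character 'reference' must be a FASTA path or named sequences",
           call. = FALSE)
    seqs <- Biostrings::DNAStringSet(reference)
  } else {
    stop("'reference' must be a FASTA path, named character vector, ",
         "or DNAStringSet", call. = FALSE)
  }
  if (length(seqs) == 0L) stop("empty reference", call. = FALSE)
  # FASTA headers: contig name is the first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

# Returns the path to a coordinate-sorted, indexed BAM, converting from SAM
# and (re-)sorting as needed.
.prepare_bam <- function(alignments) {
  if (!is.character(alignments) || length(alignments) != 1L ||
      !file.exists(alignments))
    stop("'alignments' must be the path to an existing SAM or BAM file",
         call. = FALSE)
  ext <- tolower(tools::file_ext(alignments))
  dest <- tempfile(fileext = "")
  if (ext == "sam") {
    bam <- Rsamtools::asBam(alignments, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (ext == "bam") {
    bam <- Rsamtools::sortBam(alignments, dest)
    Rsamtools::indexBam(bam)
  } else {
    stop("'alignments' must end in .sam or .bam", call. = FALSE)
  }
  bam
}

#' Classify one pileup column into per-direction match/mismatch counts
#'
#' Compares the read bases covering a single genomic position with the
#' forward-reference base. Reverse-read bases are assumed to follow the
#' forward convention (already complemented, as in SAM/BAM pileups).
#'
#' @param bases Character vector of read bases (`A`,`C`,`G`,`T`,`N`), one
#'   per read covering the column.
#' @param directions Parallel vector of read directions: `"F"`/`"+"` for
#'   forward reads, `"R"`/`"-"` for reverse reads.
#' @param ref_base The forward-reference base at the column (`A`,`C`,`G`,`T`).
#' @param n_as_mismatch Count read-base `N` as a mismatch (default `TRUE`:
#'   an uncalled base is a miscall); if `FALSE`, `N` bases are dropped.
#' @return Named integer vector
#'   `c(f_match, f_mismatch, r_match, r_mismatch)`.
#' @examples
#' classify_column(c("A", "A", "G"), c("F", "F", "R"), "A")
#' @export
classify_column <- function(bases, directions, ref_base,
                            n_as_mismatch = TRUE) {
  if (length(ref_base) != 1L || !ref_base %in% c("A", "C", "G", "T"))
    stop("'ref_base' must be one of A,C,G,T", call. = FALSE)
  if (length(bases) != length(directions))
    stop("'bases' and 'directions' must be parallel", call. = FALSE)
  if (length(bases) == 0L)
    return(c(f_match = 0L, f_mismatch = 0L, r_match = 0L, r_mismatch = 0L))
  if (!all(bases %in% c("A", "C", "G", "T", "N")))
    stop("'bases' may only contain A,C,G,T,N", call. = FALSE)
  dirF <- directions %in% c("F", "+")
  if (!all(dirF | directions %in% c("R", "-")))
    stop("'directions' must be F/+ or R/-", call. = FALSE)
  keep <- if (n_as_mismatch) rep(TRUE, length(bases)) else bases != "N"
  match <- bases == ref_base
  c(f_match    = sum(keep & dirF & match),
    f_mismatch = sum(keep & dirF & !match),
    r_match    = sum(keep & !dirF & match),
    r_mismatch = sum(keep & !dirF & !match))
}

#' Accumulate per-q-gram strand bias contingency tables
#'
#' Single pass over the reference and a coordinate-addressable read set,
#' producing one 2x2 contingency table per concrete q-gram, keyed by the
#' q-gram string. Every covered position contributes to the table of the
#' q-gram whose occurrence it terminates on the forward strand (F-position)
#' and/or to the table of the reverse-complement q-gram whose occurrence it
#' starts (R-position); windows extending past contig ends or containing
#' non-ACGT reference symbols are skipped. Only primary, mapped,
#' QC-passing alignments are counted, and only CIGAR-aligned bases
#' (substitution-only match/mismatch; indels and clips contribute nothing).
#'
#' @param reference FASTA path, named character vector, or
#'   `Biostrings::DNAStringSet`.
#' @param alignments Path to a SAM or BAM file aligned against `reference`
#'   (contig names matched by exact string equality).
#' @param q Motif/q-gram length (1--12).
#' @param n_as_mismatch Count read-base `N` as mismatch (see
#'   [classify_column()]).
#' @param exclude_duplicates Drop reads flagged as PCR/optical duplicates
#'   (default `FALSE`: discovery operates on the raw mapping).
#' @param min_mapq,max_depth Pileup bounds; defaults impose no mapping
#'   quality cutoff and a depth cap far above short-read coverages.
#' @param verbose Log the number of skipped unmapped reads.
#' @return Object of class `qgram_table_map`: a list with `q` and `tables`,
#'   a data.frame with one row per q-gram occurring in the reference (on
#'   either strand) and columns `qgram`, `a`, `b`, `c`, `d` (table cells),
#'   `f_occ`, `r_occ` (number of F-/R-positions of the q-gram).
#' @export
accumulate_tables <- function(reference, alignments, q,
                              n_as_mismatch = TRUE,
                              exclude_duplicates = FALSE,
                              min_mapq = 0L, max_depth = 250000L,
                              verbose = TRUE) {
  .check_q_n(q, 0L)
  if (q > 12) stop("'q' must be <= 12 (q-gram map memory bound)",
                   call. = FALSE)
  seqs <- .load_reference(reference)
  bam <- .prepare_bam(alignments)

  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (length(hdr)) {
    unknown <- setdiff(names(hdr), names(seqs))
    if (length(unknown))
      stop("alignment contigs absent from reference: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad_len <- names(hdr)[hdr != Biostrings::width(seqs)[match(names(hdr),
                                                               names(seqs))]]
    if (length(bad_len))
      stop("contig length mismatch between header and reference: ",
           paste(bad_len, collapse = ", "), call. = FALSE)
  }

  n_unmapped <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))$records
  if (verbose && n_unmapped > 0)
    message("skipping ", n_unmapped, " unmapped read(s)")

  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isUnmappedQuery = FALSE, isNotPassingQualityControls = FALSE,
    isDuplicate = if (exclude_duplicates) FALSE else NA)
  pp <- Rsamtools::PileupParam(
    max_depth = as.integer(max_depth), min_base_quality = 0L,
    min_mapq = as.integer(min_mapq), min_nucleotide_depth = 1L,
    distinguish_strands = TRUE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = FALSE,
    include_deletions = FALSE, include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam, scanBamParam = Rsamtools::ScanBamParam(flag = flag),
                          pileupParam = pp)

  contribs <- .pileup_contributions(pu, seqs, q, n_as_mismatch)
  occ <- .qgram_occurrences(seqs, q)

  tables <- merge(occ, contribs, by = "qgram", all.x = TRUE)
  for (col in c("a", "b", "c", "d")) {
    v <- as.numeric(tables[[col]])
    v[is.na(v)] <- 0
    set(tables, j = col, value = v)
  }
  setcolorder(tables, c("qgram", "a", "b", "c", "d", "f_occ", "r_occ"))
  setkey(tables, qgram)

  structure(list(q = as.integer(q),
                 tables = as.data.frame(tables),
                 contigs = stats::setNames(Biostrings::width(seqs),
                                           names(seqs)),
                 n_unmapped = n_unmapped),
            class = "qgram_table_map")
}

# classify pileup columns and attach them to F-/R-window q-grams
.pileup_contributions <- function(pu, seqs, q, n_as_mismatch) {
  empty <- data.table(qgram = character(0), a = numeric(0), b = numeric(0),
                      c = numeric(0), d = numeric(0))
  if (nrow(pu) == 0L) return(empty)
  dt <- as.data.table(pu)
  dt <- dt[nucleotide %in% c("A", "C", "G", "T", "N")]
  if (!n_as_mismatch) dt <- dt[nucleotide != "N"]
  if (nrow(dt) == 0L) return(empty)
  dt[, seqnames := as.character(seqnames)]

  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    contig <- names(seqs)[i]
    sq <- as.character(seqs[[i]])
    len <- nchar(sq)
    sub <- dt[seqnames == contig]
    if (nrow(sub) == 0L) next
    sub[, ref_base := substring(sq, pos, pos)]
    sub <- sub[ref_base %in% c("A", "C", "G", "T")]
    if (nrow(sub) == 0L) next
    sub[, is_match := as.character(nucleotide) == ref_base]
    col <- sub[, .(
      f_match    = sum(count[strand == "+" & is_match]),
      f_mismatch = sum(count[strand == "+" & !is_match]),
      r_match    = sum(count[strand == "-" & is_match]),
      r_mismatch = sum(count[strand == "-" & !is_match])
    ), by = pos]

    # F-window ends at pos, R-window starts at pos (1-based arithmetic here)
    fg <- col[pos >= q]
    fg_win <- substring(sq, fg$pos - q + 1L, fg$pos)
    f_ok <- grepl("^[ACGT]+$", fg_win)
    rg <- col[pos <= len - q + 1L]
    rg_win <- substring(sq, rg$pos, rg$pos + q - 1L)
    r_ok <- grepl("^[ACGT]+$", rg_win)

    parts <- list()
    if (any(f_ok))
      parts$f <- data.table(qgram = fg_win[f_ok],
                            a = fg$f_match[f_ok], b = fg$f_mismatch[f_ok],
                            c = fg$r_match[f_ok], d = fg$r_mismatch[f_ok])
    if (any(r_ok))
      parts$r <- data.table(qgram = reverse_complement(rg_win[r_ok]),
                            a = rg$r_match[r_ok], b = rg$r_mismatch[r_ok],
                            c = rg$f_match[r_ok], d = rg$f_mismatch[r_ok])
    if (length(parts)) out[[i]] <- rbindlist(parts)
  }
  allc <- rbindlist(out[!vapply(out, is.null, logical(1L))])
  if (nrow(allc) == 0L) return(empty)
  allc[, .(a = sum(a), b = sum(b), c = sum(c), d = sum(d)), by = qgram]
}

# Forward-strand q-gram occurrence counts, pooled over contigs; a q-gram is
# a key of the map iff it has at least one F-interval (forward occurrence)
# or one R-interval (its reverse complement occurs forward).
.qgram_occurrences <- function(seqs, q) {
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = q,
                                                 simplify.as = "collapsed")
  nz <- counts[counts > 0]
  keys <- union(names(nz), reverse_complement(names(nz)))
  fwd <- counts[keys]
  data.table(qgram = keys,
             f_occ = as.numeric(fwd),
             r_occ = as.numeric(counts[reverse_complement(keys)]))
}

#' @export
print.qgram_table_map <- function(x, ...) {
  cat(sprintf("q-gram contingency map (q = %d): %d q-grams over %d contig(s)\n",
              x$q, nrow(x$tables), length(x$contigs)))
  cat(sprintf("  total counted bases (a+b+c+d): %.0f; unmapped reads skipped: %d\n",
              sum(x$tables$a + x$tables$b + x$tables$c + x$tables$d),
              x$n_unmapped))
  invisible(x)
}

#' Count genomic occurrences of a motif
#'
#' Number of F-positions plus R-positions of a wildcard motif over all
#' contigs: occurrences of the motif on the forward reference plus
#' occurrences of its reverse complement on the forward reference. Windows
#' containing non-ACGT reference symbols are skipped. A position whose
#' context matches on both strands counts once per strand role.
#'
#' @inheritParams accumulate_tables
#' @param motif Motif string over `{A,C,G,T,N}`.
#' @return Integer occurrence count (read-independent).
#' @export
count_occurrences <- function(reference, motif) {
  seqs <- .load_reference(reference)
  .check_alphabet(motif, .MOTIF_CHARS, "'motif'")
  nrow(motif_positions(seqs, motif))
}
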