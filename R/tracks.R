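# Annotation tracks of CSE-prone genomic positions. The error-prone
# position of a motif occurrence is its pileup position: the last position
# of an F-interval (forward match, strand role F) or the first position of
# an R-interval (reverse-complement match, strand role R), both in 0-based
# forward coordinates. Tracks are written as BED6 and can be used to flag
# externally called variants that fall on error-prone positions.

# F- and R-interval start positions (0-based) of one motif on one contig,
# skipping windows containing non-ACGT reference symbols
.scan_contig <- function(subject, motif) {
  q <- nchar(motif)
  find <- function(pat) {
    hits <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    st <- BiocGenerics::start(hits)
    if (length(st) == 0L) return(integer(0))
    win <- as.character(Biostrings::extractAt(
      subject, IRanges::IRanges(st, width = q)))
    st[grepl("^[ACGT]+$", win)] - 1L
  }
  list(f_start = find(motif), r_start = find(reverse_complement(motif)))
}

#' Genomic positions matching CSE motifs
#'
#' Emits every F-position (last base of a forward-strand motif match) and
#' R-position (first base of a reverse-strand motif match) of each motif,
#' in 0-based forward coordinates. A position hit by several motifs is
#' emitted once per motif.
#'
#' @inheritParams accumulate_tables
#' @param motifs Character vector of motif strings over `{A,C,G,T,N}`.
#' @return data.frame with columns `contig`, `position` (0-based error-site
#'   coordinate), `role` (`"F"` or `"R"`), `motif`.
#' @examples
#' motif_positions(c(chr = "AGGTA"), "GGT") # F-position at the T (3)
#' @export
motif_positions <- function(reference, motifs) {
  seqs <- .load_reference(reference)
  if (length(motifs)) .check_alphabet(motifs, .MOTIF_CHARS, "'motifs'")
  out <- list()
  for (i in seq_along(seqs)) {
    subject <- seqs[[i]]
    for (m in motifs) {
      q <- nchar(m)
      hits <- .scan_contig(subject, m)
      if (length(hits$f_start))
        out[[length(out) + 1L]] <- data.frame(
          contig = names(seqs)[i], position = hits$f_start + q - 1L,
          role = "F", motif = m, stringsAsFactors = FALSE)
      if (length(hits$r_start))
        out[[length(out) + 1L]] <- data.frame(
          contig = names(seqs)[i], position = hits$r_start,
          role = "R", motif = m, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), position = integer(0),
                      role = character(0), motif = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$contig, res$position, res$role, res$motif), , drop = FALSE]
}

#' Write CSE-prone positions as a BED6 track
#'
#' One single-base, 0-based half-open interval per error-prone position.
#' The strand column records the strand role (`F` as `+`, `R` as `-`); the
#' name column carries the motif. Records sharing contig, position and
#' strand are collapsed into one line with comma-joined motif names. Output
#' is sorted by (contig, start).
#'
#' @param positions data.frame as returned by [motif_positions()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(positions, path) {
  req <- c("contig", "position", "role", "motif")
  if (!all(req %in% names(positions)))
    stop("'positions' must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  dt <- as.data.table(positions)
  if (nrow(dt) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  dt[, strand := ifelse(role %in% c("F", "+"), "+", "-")]
  bed <- dt[, .(name = paste(sort(unique(motif)), collapse = ",")),
            by = .(contig, position, strand)]
  setorder(bed, contig, position, strand)
  out <- bed[, .(contig, start = position, end = position + 1L, name,
                 score = 0L, strand)]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED track back into a position table
#'
#' Inverse of [write_bed()]: expands comma-joined motif names back into one
#' row per (position, motif).
#'
#' @param path BED file path (plain or gzip).
#' @return data.frame with columns `contig`, `position`, `role`, `motif`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L)
    return(data.frame(contig = character(0), position = integer(0),
                      role = character(0), motif = character(0),
                      stringsAsFactors = FALSE))
  nm <- if (!is.null(gr$name)) gr$name else ""
  motifs <- strsplit(nm, ",", fixed = TRUE)
  reps <- lengths(motifs)
  res <- data.frame(
    contig = rep(as.character(GenomeInfoDb::seqnames(gr)), reps),
    position = rep(BiocGenerics::start(gr) - 1L, reps),
    role = rep(ifelse(as.character(BiocGenerics::strand(gr)) == "-",
                      "R", "F"), reps),
    motif = unlist(motifs, use.names = FALSE),
    stringsAsFactors = FALSE)
  res[order(res$contig, res$position, res$role, res$motif), , drop = FALSE]
}

#' Flag variant positions lying on CSE-prone sites
#'
#' Checks each supplied variant position for membership in a track of
#' error-prone positions. Variants are accepted as a data.frame with
#' columns `contig` and `pos` (1-based), as a TSV path with those two
#' columns, or as a VCF path (genotype fields ignored; requires the vcfR
#' package). Malformed records are skipped with a warning.
#'
#' @param variants Variant positions (see Details above).
#' @param track A position data.frame ([motif_positions()] / [read_bed()])
#'   or a BED file path.
#' @return data.frame with columns `contig`, `pos` (1-based) and
#'   `cse_prone` (logical).
#' @export
annotate_variants <- function(variants, track) {
  if (is.character(track) && length(track) == 1L) track <- read_bed(track)
  req <- c("contig", "position")
  if (!all(req %in% names(track)))
    stop("'track' must have columns contig and position", call. = FALSE)

  if (is.character(variants) && length(variants) == 1L) {
    if (grepl("\\.vcf(\\.gz)?$", variants, ignore.case = TRUE)) {
      if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF input requires the vcfR package", call. = FALSE)
      fix <- vcfR::getFIX(vcfR::read.vcfR(variants, verbose = FALSE))
      variants <- data.frame(contig = fix[, "CHROM"],
                             pos = suppressWarnings(as.numeric(fix[, "POS"])),
                             stringsAsFactors = FALSE)
    } else {
      variants <- utils::read.table(variants, header = FALSE, sep = "\t",
                                    col.names = c("contig", "pos"),
                                    colClasses = c("character", "numeric"))
    }
  }
  if (!all(c("contig", "pos") %in% names(variants)))
    stop("'variants' must have columns contig and pos (1-based)",
         call. = FALSE)
  ok <- !is.na(variants$contig) & !is.na(variants$pos) &
    variants$pos == floor(variants$pos) & variants$pos >= 1
  if (any(!ok)) {
    warning(sum(!ok), " malformed variant record(s) skipped")
    variants <- variants[ok, , drop = FALSE]
  }
  key <- paste(track$contig, track$position)
  data.frame(contig = variants$contig, pos = variants$pos,
             cse_prone = paste(variants$contig, variants$pos - 1) %in% key,
             stringsAsFactors = FALSE, row.names = NULL)
}
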