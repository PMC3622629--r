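# Synthetic references and aligned reads with planted context-specific
# errors. The generator emulates the defining CSE signature: at every
# genomic position whose preceding context matches a planted motif, reads
# whose own sequencing direction passes through the context before the
# site miscall the site base at an elevated rate, while all other bases of
# all reads carry a uniform low background substitution rate. Reads are
# emitted pre-aligned at their true coordinates (read mapping is outside
# the scope of the generator), with all-match CIGARs, and the full injected
# truth is recorded so that downstream counts can be checked exactly.

.BASES <- c("A", "C", "G", "T")

#' Generate a reference sequence with planted motif occurrences
#'
#' Builds an i.i.d. random background sequence with a chosen GC fraction
#' and embeds the requested number of non-overlapping occurrences of each
#' motif at recorded positions, each on a randomly chosen strand. Wildcard
#' (`N`) motif positions are instantiated with a random base per
#' occurrence. Additional chance occurrences of the motifs can arise in the
#' background; scan the returned sequence (e.g. with [motif_positions()])
#' when the complete occurrence list matters.
#'
#' @param length Contig length in bp.
#' @param gc GC fraction of the background sequence in \[0, 1\].
#' @param motifs Named integer vector: `c(GGGT = 55)` plants 55 occurrences
#'   of GGGT. May be empty.
#' @param seed Optional integer seed (set once at entry).
#' @param contig_name Name of the single generated contig.
#' @return List with `sequences` (a `Biostrings::DNAStringSet`) and
#'   `occurrences`, a data.frame of planted sites: `contig`, `start`
#'   (0-based), `strand` (`+`/`-`), `motif`, `instance` (the concrete
#'   planted q-gram on the forward strand).
#' @export
generate_reference <- function(length, gc = 0.5, motifs = integer(0),
                               seed = NULL, contig_name = "synthetic_1") {
  if (!is.null(seed)) set.seed(seed)
  if (length < 1) stop("'length' must be positive", call. = FALSE)
  .check_rate(gc, "gc")
  if (base::length(motifs) && is.null(names(motifs)))
    stop("'motifs' must be named by motif string", call. = FALSE)
  if (base::length(motifs)) {
    .check_alphabet(names(motifs), .MOTIF_CHARS, "'motifs' names")
    if (any(motifs < 0) || any(nchar(names(motifs)) > length))
      stop("infeasible motif plant request", call. = FALSE)
  }

  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chars <- sample(.BASES, length, replace = TRUE, prob = prob)

  occ <- list()
  occupied <- integer(0) # 1-based positions already claimed by a plant
  for (m in names(motifs)) {
    q <- nchar(m)
    for (j in seq_len(motifs[[m]])) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        st <- sample.int(length - q + 1L, 1L)
        span <- st:(st + q - 1L)
        if (any(span %in% occupied)) next
        inst <- .instantiate_motif(m)
        strand <- sample(c("+", "-"), 1L)
        fwd <- if (strand == "+") inst else reverse_complement(inst)
        chars[span] <- strsplit(fwd, "")[[1L]]
        occupied <- c(occupied, span)
        occ[[base::length(occ) + 1L]] <- data.frame(
          contig = contig_name, start = st - 1L, strand = strand,
          motif = m, instance = fwd, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", motifs[[m]], " non-overlapping occurrences",
             " of ", m, " in ", length, " bp", call. = FALSE)
    }
  }
  occurrences <- if (base::length(occ)) do.call(rbind, occ)
    else data.frame(contig = character(0), start = integer(0),
                    strand = character(0), motif = character(0),
                    instance = character(0), stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(stats::setNames(
    paste(chars, collapse = ""), contig_name))
  list(sequences = seqs, occurrences = occurrences)
}

.instantiate_motif <- function(m) {
  ch <- strsplit(m, "")[[1L]]
  ch[ch == "N"] <- sample(.BASES, sum(ch == "N"), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate aligned reads with planted context-specific errors
#'
#' Draws reads uniformly over each contig with random direction and writes
#' them as a coordinate-sorted SAM file with true coordinates and all-match
#' CIGARs. Every read base is substituted with probability
#' `background_rate` (target base uniform over the three alternatives). In
#' addition, the reference is scanned for all error sites of the motifs in
#' `planted_rates` (every F- and R-position, including chance occurrences);
#' at such a site, a read whose direction reads through the full context
#' before the site substitutes with the planted rate instead of the
#' background rate, producing the strand-biased error signature.
#'
#' @param reference Output of [generate_reference()], or a
#'   `Biostrings::DNAStringSet` / named character vector / FASTA path.
#' @param planted_rates Named numeric vector of per-motif forward error
#'   rates, e.g. `c(GGGT = 0.25)`. May be empty for pure-background reads.
#' @param coverage Mean read coverage per contig.
#' @param read_length Read length in bp (must not exceed contig length).
#' @param background_rate Uniform per-base background substitution rate.
#' @param seed Optional integer seed (set once at entry).
#' @param sam_path Output SAM path; default a tempfile.
#' @return List with `sam` (path), `reads` (data.frame of qname, flag,
#'   contig, pos (1-based), seq), and `truth`: generator parameters, the
#'   scanned error-site list, and every injected error (read, contig,
#'   0-based position, read direction, reference and read base, cause
#'   `"context"` or `"background"`, and motif for context errors).
#' @export
generate_reads <- function(reference, planted_rates = numeric(0),
                           coverage = 60, read_length = 50,
                           background_rate = 0.005, seed = NULL,
                           sam_path = tempfile(fileext = ".sam")) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- if (is.list(reference) && !is.null(reference$sequences))
    reference$sequences else .load_reference(reference)
  .check_rate(background_rate, "background_rate")
  if (length(planted_rates)) {
    .check_alphabet(names(planted_rates), .MOTIF_CHARS,
                    "'planted_rates' names")
    for (r in planted_rates) .check_rate(r, "planted_rates")
  }
  if (coverage <= 0 || read_length < 1)
    stop("'coverage' and 'read_length' must be positive", call. = FALSE)
  if (any(Biostrings::width(seqs) < read_length))
    stop("'read_length' exceeds a contig length", call. = FALSE)

  sites <- motif_positions(seqs, names(planted_rates))
  if (nrow(sites)) sites$rate <- planted_rates[sites$motif]

  # substitution targets: row = reference base, columns = the 3 alternatives
  alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
               c("A", "C", "T"), c("A", "C", "G"))

  reads_parts <- list(); error_parts <- list(); rid0 <- 0L
  for (ci in seq_along(seqs)) {
    contig <- names(seqs)[ci]
    chars <- strsplit(as.character(seqs[[ci]]), "")[[1L]]
    len <- length(chars)
    n_reads <- max(1L, round(coverage * len / read_length))
    start0 <- sample.int(len - read_length + 1L, n_reads,
                         replace = TRUE) - 1L
    dirR <- stats::runif(n_reads) < 0.5

    # n_reads x read_length matrix of covered reference bases
    idx <- outer(start0 + 1L, seq_len(read_length) - 1L, `+`)
    refM <- matrix(chars[idx], nrow = n_reads)
    bg <- matrix(stats::runif(n_reads * read_length) < background_rate,
                 nrow = n_reads)

    # (read, column) cells read at the planted rate: read direction passes
    # through the full context (inside the read) before the error site
    csites <- if (nrow(sites)) sites[sites$contig == contig, , drop = FALSE]
              else sites
    elev <- list()
    for (k in seq_len(nrow(csites))) {
      p <- csites$position[k]; q <- nchar(csites$motif[k])
      elig <- if (csites$role[k] == "F")
        which(!dirR & start0 <= p - q + 1L & p <= start0 + read_length - 1L)
      else
        which(dirR & start0 <= p & p + q - 1L <= start0 + read_length - 1L)
      if (length(elig))
        elev[[length(elev) + 1L]] <- data.table(
          read = elig, col = p - start0[elig] + 1L,
          motif = csites$motif[k], rate = csites$rate[k])
    }
    ctx_cell <- integer(0); ctx_motif <- character(0)
    if (length(elev)) {
      ed <- unique(rbindlist(elev), by = c("read", "col"))
      cell <- (ed$col - 1L) * n_reads + ed$read
      bg[cell] <- FALSE # planted rate replaces, not augments, background
      hit <- stats::runif(nrow(ed)) < ed$rate
      ctx_cell <- cell[hit]; ctx_motif <- ed$motif[hit]
    }
    bg_cell <- which(bg)
    all_cell <- c(bg_cell, ctx_cell)
    # reference bases outside ACGT are never substituted
    ok <- refM[all_cell] %in% .BASES
    all_cell <- all_cell[ok]
    cause <- c(rep("background", length(bg_cell)),
               rep("context", length(ctx_cell)))[ok]
    motif_of <- c(rep(NA_character_, length(bg_cell)), ctx_motif)[ok]

    readM <- refM
    if (length(all_cell))
      readM[all_cell] <- alt[cbind(match(refM[all_cell], .BASES),
                                   sample.int(3L, length(all_cell),
                                              replace = TRUE))]

    qnames <- sprintf("sr%06d", rid0 + seq_len(n_reads))
    rid0 <- rid0 + n_reads
    reads_parts[[ci]] <- data.table(
      qname = qnames, flag = ifelse(dirR, 16L, 0L), contig = contig,
      pos = start0 + 1L,
      seq = do.call(paste0, lapply(seq_len(read_length),
                                   function(j) readM[, j])))
    if (length(all_cell)) {
      rr <- (all_cell - 1L) %% n_reads + 1L
      cc <- (all_cell - 1L) %/% n_reads + 1L
      error_parts[[length(error_parts) + 1L]] <- data.table(
        qname = qnames[rr], contig = contig,
        position = start0[rr] + cc - 1L,
        direction = ifelse(dirR[rr], "R", "F"),
        ref_base = refM[all_cell], read_base = readM[all_cell],
        cause = cause, motif = motif_of)
    }
  }
  reads <- rbindlist(reads_parts)
  setorder(reads, contig, pos, qname)
  reads <- as.data.frame(reads)
  errors <- if (length(error_parts)) {
    ep <- rbindlist(error_parts)
    setorder(ep, contig, position, qname)
    as.data.frame(ep)
  } else data.frame(qname = character(0), contig = character(0),
                    position = integer(0), direction = character(0),
                    ref_base = character(0), read_base = character(0),
                    cause = character(0), motif = character(0),
                    stringsAsFactors = FALSE)

  .write_sam(reads, stats::setNames(Biostrings::width(seqs), names(seqs)),
             sam_path)
  truth <- list(planted_rates = as.list(planted_rates),
                coverage = coverage, read_length = read_length,
                background_rate = background_rate,
                error_sites = sites, injected_errors = errors)
  list(sam = sam_path, reads = reads, truth = truth)
}

.write_sam <- function(reads, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   contig_lengths))
  body <- if (nrow(reads)) sprintf(
    "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
    reads$qname, reads$flag, reads$contig, reads$pos, nchar(reads$seq),
    reads$seq, strrep("I", nchar(reads$seq))) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a complete CSE benchmark dataset
#'
#' Convenience wrapper: one seeded run of [generate_reference()] plus
#' [generate_reads()], with the reference written as FASTA, reads as SAM,
#' and the ground truth as JSON next to them. The defaults describe the
#' validation conditions used throughout the package's tests: a 4 kb
#' contig, 55 planted occurrences of GGGT with a forward error rate of
#' 0.25, background substitution rate 0.005, 60x coverage with 50 bp reads.
#'
#' @param dir Output directory (created if needed).
#' @param reference_length,gc See [generate_reference()].
#' @param planted_rates Named per-motif context error rates.
#' @param occurrences Planted occurrence count, recycled over motifs.
#' @param coverage,read_length,background_rate See [generate_reads()].
#' @param seed Integer seed for the whole dataset.
#' @return List with paths `fasta`, `sam`, `truth_json`, plus the in-memory
#'   `reference`, `reads` and `truth` objects.
#' @export
simulate_cse_dataset <- function(dir = tempfile("cse_sim_"),
                                 reference_length = 4000, gc = 0.5,
                                 planted_rates = c(GGGT = 0.25),
                                 occurrences = 55L,
                                 coverage = 60, read_length = 50,
                                 background_rate = 0.005, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  counts <- stats::setNames(rep(as.integer(occurrences),
                                length.out = length(planted_rates)),
                            names(planted_rates))
  ref <- generate_reference(reference_length, gc = gc, motifs = counts)
  fasta <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(ref$sequences, fasta)
  sim <- generate_reads(ref, planted_rates = planted_rates,
                        coverage = coverage, read_length = read_length,
                        background_rate = background_rate,
                        sam_path = file.path(dir, "reads.sam"))
  truth <- c(sim$truth, list(seed = seed, planted_occurrences = ref$occurrences))
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  list(fasta = fasta, sam = sim$sam, truth_json = truth_json,
       reference = ref, reads = sim$reads, truth = truth)
}
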