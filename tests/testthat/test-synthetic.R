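test_that("generated references plant the requested occurrences", {
  set.seed(71)
  ref <- generate_reference(500, motifs = c(GGTA = 7L))
  expect_identical(nrow(ref$occurrences), 7L)
  sq <- as.character(ref$sequences[[1]])
  for (i in seq_len(7)) {
    o <- ref$occurrences[i, ]
    expect_identical(substr(sq, o$start + 1, o$start + 4), o$instance)
    # the forward-strand instance is the motif or its reverse complement
    expect_true(o$instance %in% c("GGTA", reverse_complement("GGTA")))
  }
  # no-plant request yields a plain random sequence of the right length
  ref0 <- generate_reference(200)
  expect_identical(nrow(ref0$occurrences), 0L)
  expect_identical(Biostrings::width(ref0$sequences), 200L)
  # extreme GC skews composition outside planted motifs
  ref_gc <- generate_reference(300, gc = 1)
  expect_true(grepl("^[GC]+$", as.character(ref_gc$sequences[[1]])))
  expect_error(generate_reference(3, motifs = c(GGTA = 1L)), "infeasible")
})

test_that("wildcard plants are instantiated and recorded per occurrence", {
  set.seed(72)
  ref <- generate_reference(600, motifs = c(GGN = 5L))
  expect_identical(nrow(ref$occurrences), 5L)
  expect_true(all(grepl("^[ACGT]{3}$", ref$occurrences$instance)))
  fwd <- ifelse(ref$occurrences$strand == "+", ref$occurrences$instance,
                reverse_complement(ref$occurrences$instance))
  expect_true(all(motif_matches("GGN", fwd)))
})

test_that("error-free generation reproduces reference substrings exactly", {
  set.seed(73)
  ref <- generate_reference(400)
  sim <- generate_reads(ref, coverage = 10, read_length = 40,
                        background_rate = 0)
  expect_identical(nrow(sim$truth$injected_errors), 0L)
  sq <- as.character(ref$sequences[[1]])
  for (i in seq_len(nrow(sim$reads)))
    expect_identical(sim$reads$seq[i],
                     substr(sq, sim$reads$pos[i], sim$reads$pos[i] + 39L))
})

test_that("a planted rate of 1 makes every context-direction read mismatch", {
  set.seed(74)
  ref <- generate_reference(1000, motifs = c(GGTAC = 10L))
  sim <- generate_reads(ref, planted_rates = c(GGTAC = 1),
                        coverage = 40, read_length = 50,
                        background_rate = 0)
  map <- accumulate_tables(ref$sequences, sim$sam, q = 5, verbose = FALSE)
  agg <- aggregate_motif_table("GGTAC", map)
  # every context-direction read that read through the full context erred;
  # opposite-direction reads are error-free
  expect_identical(agg$table[["d"]], 0)
  expect_gt(agg$table[["b"]], 0)
  # cell a counts only context-direction reads that covered the site
  # without reading the full context (no elevated rate applied)
  errs <- sim$truth$injected_errors
  expect_true(all(errs$cause == "context"))
  score <- fisher_log10_p(agg$table)$score
  expect_gt(score, 10)
})

test_that("accumulated counts reproduce the injected-error bookkeeping exactly", {
  sim <- simulate_cse_dataset(seed = 75L, reference_length = 2000,
                              coverage = 30)
  map <- accumulate_tables(sim$fasta, sim$sam, q = 4, verbose = FALSE)
  agg <- aggregate_motif_table("GGGT", map)
  errs <- sim$truth$injected_errors
  sites <- sim$truth$error_sites
  # forward-context mismatches at GGGT sites: context errors plus any
  # background errors hitting a site from a non-reading-through read
  site_key <- paste(sites$contig, sites$position,
                    ifelse(sites$role == "F", "F", "R"))
  err_key <- paste(errs$contig, errs$position, errs$direction)
  b_expected <- sum(err_key %in% site_key)
  expect_identical(agg$table[["b"]], as.numeric(b_expected))
  # total context-direction depth at the sites fixes a + b
  reads <- sim$reads
  cover_ct <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    dirR <- bitwAnd(reads$flag, 16L) > 0L
    covers <- reads$pos - 1L <= s$position &
      s$position <= reads$pos + nchar(reads$seq) - 2L
    cover_ct <- cover_ct + sum(covers & (dirR == (s$role == "R")))
  }
  expect_identical(agg$table[["a"]] + agg$table[["b"]],
                   as.numeric(cover_ct))
})

test_that("background mismatch rate lands near its configured value", {
  sim <- simulate_cse_dataset(seed = 76L, reference_length = 3000,
                              planted_rates = numeric(0), coverage = 30,
                              background_rate = 0.01)
  errs <- sim$truth$injected_errors
  n_bases <- sum(nchar(sim$reads$seq))
  p_hat <- nrow(errs) / n_bases
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(p_hat - 0.01), 3 * se)
  # and the read-level mismatch count agrees with an alignment re-scan
  sq <- as.character(Biostrings::readDNAStringSet(sim$fasta)[[1]])
  mm <- 0L
  for (i in seq_len(nrow(sim$reads))) {
    r <- sim$reads[i, ]
    ref_piece <- substr(sq, r$pos, r$pos + nchar(r$seq) - 1L)
    mm <- mm + sum(strsplit(r$seq, "")[[1]] != strsplit(ref_piece, "")[[1]])
  }
  expect_identical(mm, nrow(errs))
})

test_that("datasets serialize reference, reads and truth side by side", {
  sim <- simulate_cse_dataset(seed = 77L, reference_length = 1000,
                              coverage = 10)
  expect_true(file.exists(sim$fasta))
  expect_true(file.exists(sim$sam))
  expect_true(file.exists(sim$truth_json))
  truth <- jsonlite::read_json(sim$truth_json, simplifyVector = TRUE)
  expect_equal(truth$background_rate, 0.005)
  expect_equal(truth$planted_rates$GGGT, 0.25)
  expect_identical(nrow(truth$planted_occurrences), 55L)
  # SAM is body-sorted by coordinate and declares it
  lines <- readLines(sim$sam)
  expect_identical(lines[1], "@HD\tVN:1.6\tSO:coordinate")
  pos <- as.integer(vapply(strsplit(grep("^[^@]", lines, value = TRUE),
                                    "\t"), `[[`, character(1), 4L))
  expect_true(!is.unsorted(pos))
})
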