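# Published benchmark of CSE motifs discovered on Illumina GAIIx / HiSeq /
# MiSeq datasets: per-motif contingency tables (a, c, b, d in
# forward-match, reverse-match, forward-mismatch, reverse-mismatch order),
# occurrence counts, strand bias scores (NA where the original report
# printed an overflowed value) and one-decimal percentage rates.
load_benchmark <- function() {
  path <- system.file("extdata", "illumina_cse_benchmark.tsv",
                      package = "cseMotifs")
  read.delim(path, stringsAsFactors = FALSE)
}
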