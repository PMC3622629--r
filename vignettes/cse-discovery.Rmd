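---
title: "Discovering context-specific sequencing error motifs"
author: "cseMotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering context-specific sequencing error motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cseMotifs)
```

## The problem

Illumina-style sequencing-by-synthesis proceeds in cycles, and the
chemistry can lose synchrony (*dephasing*) in ways that depend on the
sequence just read. The result is a class of systematic base-calling
errors — *context-specific errors* (CSEs) — in which a specific sequence
pattern immediately preceding a position induces miscalls at that
position. Because the inducing context precedes the error *on the read's
own strand*, the miscalls pile up in reads of one direction only, while
reads of the opposite direction (which approach the position through a
different context) are clean. This *strand bias* is the signature that
separates a CSE from a true heterozygous variant, which distributes its
non-reference allele evenly over both read directions.

Testing each genome position for strand bias individually has little
power at realistic coverage. This package therefore pools positions by
*motif*: all positions whose preceding context matches the same pattern
contribute to one pooled contingency table, and the test is performed
once per motif.

## The model

### Motif space

Motifs are generalized strings over `{A, C, G, T, N}` of length $q$, with
at most $n$ wildcard (`N`) positions; `N` matches any base, and no other
IUPAC codes are admitted (they are rejected, not silently accepted). The
motif space $S(q, n)$ has size

$$|S(q,n)| = \sum_{i=0}^{n} \binom{q}{i}\, 4^{\,q-i},$$

which is also the number of hypotheses for multiple-testing correction:

```{r}
motif_space_size(4, 1)
motif_space_size(8, 4)
```

The error-prone position of a motif occurrence is always the *last*
position of the match — the context lies before the potential error site
inside the motif.

### Contingency accumulation

For every genomic position $p$ (0-based, forward coordinates) two strand
roles are considered. If the reference window ending at $p$ is the
concrete q-gram $g$, then $p$ is an *F-position* of $g$; if the window
starting at $p$ is the reverse complement of $g$, then $p$ is an
*R-position* of $g$. The pileup column at $p$ (with reverse-read bases in
forward convention, as SAM/BAM stores them) is split into forward-read
and reverse-read matches and mismatches against the forward reference;
F-positions add these counts as $(a, b, c, d)$, R-positions add them with
the direction roles swapped. Row one of the pooled table therefore always
counts the reads whose own sequencing direction passes through the
context before the site. A position may hold both roles at once (for
different q-grams, e.g. the `A` in `GGACC` for windows `GGA` and `ACC`)
and then contributes to both tables.

One linear pass accumulates a table per concrete q-gram into a hash map
(at most $4^q$ keys; `q <= 12` is enforced); the table of any motif is
then the cellwise sum over the q-grams it matches. Windows containing
non-ACGT reference symbols are skipped, q-grams never span contig
boundaries, and only primary, mapped, QC-passing alignments with
CIGAR-aligned bases are counted (substitution-only match/mismatch; indels
and clips contribute nothing). Duplicates and base/mapping quality are
*not* filtered by default — discovery operates on the raw mapping, and
duplicate exclusion is an explicit switch. Read bases of `N` count as
mismatches by default (an uncalled base is a miscall); this too is a
switch.

### The strand bias test

For a 2x2 table with fixed marginals $M = (f, k, m, s, n)$, the null
probability of entry $a$ is hypergeometric,

$$\Pr\nolimits_{H_0}(a \mid M) =
  \binom{a+b}{a}\binom{c+d}{c}\Big/\binom{n}{a+c},$$

and the two-sided p-value sums $\Pr_{H_0}(a' \mid M)$ over all tables at
most as probable as the observed one (the probability-ordering
definition; ties admitted at relative tolerance $10^{-12}$). The *strand
bias score* is $-\log_{10}(\text{p-value})$.

The summation runs entirely in log space via `lchoose()`, in chunks over
the feasible range, so the score stays exact and finite even when the
p-value underflows double precision — pooled tables from real data
routinely reach scores of several hundred:

```{r}
fisher_log10_p(c(731, 169, 1330, 7))$score
fisher_log10_p(c(500000, 100000, 599000, 1000))$score
```

A Yates-corrected $\chi^2$ path (`chi2_p()`) is available as a fast
approximation for very large tables, but it is strictly opt-in: the exact
computation is always the default, and reported scores are always finite
log-scale values (display rounding to one decimal happens only in
formatted reports). Tooling that switches to $\chi^2$ for large tables
produces visibly different scores there, which is worth keeping in mind
when comparing against other implementations.

### Filtering and ranking

Significance is controlled family-wise with Bonferroni: a motif is
significant when its p-value is at most $\alpha / |S(q,n)|$. Significant
motifs are then filtered in a fixed cascade:

1. **RER filter** — drop motifs with reverse error rate
   $\mathrm{RER} = d/(c+d) \ge \varepsilon$: a noisy opposite-direction
   context is background, not a CSE.
2. **ERD filter** — drop motifs with error rate difference
   $\mathrm{ERD} = \mathrm{FER} - \mathrm{RER} < \delta$ (with
   $\mathrm{FER} = b/(a+b)$): too small an excess to matter.

Survivors are ranked by *decreasing ERD*, not by score: a larger score
may only reflect more occurrences or deeper coverage, not a higher error
rate. Ties are broken by score (descending) and then by motif string, so
identical inputs give byte-identical reports. All surviving motifs are
reported; merging near-duplicate motifs is deliberately left to
postprocessing. Motifs with zero coverage in either context direction are
excluded before testing, with a logged count.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `q` | motif length (bp) | — | `<= 12` enforced (map memory) |
| `n` | max wildcards | — | typically `<= q/2` |
| `alpha` | family-wise error level | 0.05 | Bonferroni over $|S(q,n)|$ |
| `epsilon` | RER ceiling | 0.03 | a "normal" background error rate |
| `delta` | minimum ERD | 0.05 | 0.1 is a good choice for long motifs such as (8,4); short-motif spaces like (4,1) need a lenient 0.01 to report anything |

## Statistical power of position-wise testing

`estimate_power()` and `power_curve()` quantify why pooling is needed.
At a single position with total coverage $n$, split $n/2$ per direction,
forward mismatches are drawn $b \sim \mathrm{Bin}(n/2, e)$ and reverse
mismatches $d \sim \mathrm{Bin}(n/2, \varepsilon_{bg})$ (equal row sums —
sufficient for illustration), and the rejection fraction of the exact
test at a Bonferroni-corrected level (default $0.05/5\times10^7$, an
exome-scale correction) is reported with its binomial standard error.
Rejection always uses the exact two-sided test, never the $\chi^2$ path.

Even at an extreme per-position error rate of 0.5 against a background
of 0.01, coverage 100 yields an empirical discovery chance of only about
a third (the package's acceptance script recomputes this number); at low
coverages detection is essentially impossible. Two remarks on this
number. First, the discrete test makes the true power oscillate with
coverage, so nearby even coverages differ by several percentage points
and readings off a simulated curve are easily a grid point off. Second,
a one-sided rejection rule (which a directional alternative might
suggest) rejects at one fewer mismatch and sits several points higher;
this package keeps the two-sided probability-ordering definition
throughout, since it is the same statistic used for discovery and by
standard variant-calling strand-bias annotations.

## The synthetic data generator

`simulate_cse_dataset()` (and the underlying `generate_reference()` /
`generate_reads()`) provides ground-truthed data for validation:

* an i.i.d. background sequence with configurable GC content, with
  non-overlapping motif occurrences planted at recorded positions on
  random strands (wildcards instantiated per occurrence);
* reads drawn uniformly with random direction, emitted *pre-aligned* at
  their true coordinates with all-match CIGARs — read mapping is out of
  scope, so the generator bypasses it honestly rather than imitating a
  mapper;
* a uniform background substitution rate on every base, and an elevated
  context rate at every error site of a planted motif (*including* chance
  occurrences of the motif arising in the background, which the generator
  locates by scanning its own output) for reads whose direction passes
  through the full context within the read;
* substitution targets uniform over the three non-reference bases; all
  randomness from a single seeded generator; every injected error
  recorded in a JSON truth file next to the FASTA/SAM.

The defaults are the package's standing validation conditions: a 4 kb
contig, 55 planted occurrences of `GGGT` at context error rate 0.25,
background rate 0.005, 60x coverage with 50 bp reads. Under these
conditions discovery recovers the planted motif at rank 1 with its error
rate estimated to within 0.05, across seeds, and on null data (uniform
error rate both directions) the family-wise false-discovery fraction
stays below $\alpha$ — both properties are exercised by the test suite
at exactly these sizes (40 recovery seeds; 200 null runs at a reduced
500 bp / 20x scale; accumulator-vs-oracle checks up to 2 kb and 500
reads).

What the generator does **not** emulate: indel errors, quality-score
structure, mapper artifacts (soft-clipping, mismapping near repeats),
GC-coverage bias, and inverted-repeat backfolding. Passing tests on this
generator therefore validate the counting, testing and ranking machinery
— not robustness to alignment noise in real data.

## Numerical and design notes

* **Coordinates.** Internally 0-based half-open; SAM's 1-based input is
  converted at the boundary; BED output is natively 0-based. Variant
  input for annotation is 1-based (VCF convention).
* **Log-space Fisher.** `lchoose()`-based; chunked enumeration of the
  feasible range (chunk size $10^6$) bounds memory for tables with huge
  marginals; p-values of empty tables are defined as 1 (score 0).
* **Tie handling.** Tables whose null probability equals the observed one
  within relative $10^{-12}$ join the extreme set, matching the `<=` in
  the probability-ordering definition.
* **Enumeration order.** `enumerate_motifs()` is lexicographic with `N`
  collating after `T`, fixed so outputs are reproducible run to run.
* **Occurrence counting.** The occurrence count of a motif is its number
  of F-positions plus R-positions; a palindromic-context position counts
  once per strand role. This makes the count read-independent and
  identical across read sets on the same genome.
* **BED schema.** BED6, one single-base interval per error-prone
  position, strand `+`/`-` recording the F/R strand role, motif names
  comma-joined when several motifs hit one position; idempotent under
  re-sorting and re-merging.
* **Degenerate inputs.** Empty alignment sets give all-zero tables; an
  empty survivor set is a valid discovery result; `compute_rates()`
  returns `NA` for a zero denominator (such motifs never reach testing).

## A worked run

```{r, eval = FALSE}
sim <- simulate_cse_dataset(seed = 42)
res <- discover_cse(sim$fasta, sim$sam, q = 4, n = 1)
res
# rank 1: GGGT, FER about 0.24, RER about 0.005, score in the hundreds
write_cse_report(res, tsv = "cse.tsv", json = "cse.json")
write_bed(motif_positions(sim$fasta, res$motif), "cse_track.bed")
annotate_variants(data.frame(contig = "synthetic_1", pos = 14),
                  read_bed("cse_track.bed"))
```

## Limitations

* Contexts are one-sided (before the error site) and the error site is
  pinned to the motif's last position; two-sided contexts and
  inverted-repeat models are out of scope.
* Only the `N` wildcard is supported; richer IUPAC alphabets multiply
  the hypothesis space and are rejected by design.
* Reported motif lists are redundant by construction (a strong concrete
  motif drags its generalizations along); downstream merging is the
  user's choice.
* FWER control is Bonferroni only — with pooling, significant p-values
  are so small that the conservativeness costs little; FDR control is
  intentionally not offered.
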