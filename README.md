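# cseMotifs

Motif-based discovery of **context-specific sequencing errors** (CSEs) in
aligned short-read data.

Certain sequence patterns — `GGC`/`GGT`-like contexts on Illumina
instruments — systematically induce base-calling errors at the position
they precede. Because the inducing context precedes the error on the
read's own strand, the miscalls appear almost exclusively in reads of one
direction: **strand bias**, the signature that separates a CSE from a true
heterozygous SNP. Position-by-position strand-bias testing has little
power at realistic coverage, so this package pools genomic positions by
wildcard **motif** and tests each motif's pooled counts once. It is aimed
at people building or auditing variant-calling pipelines who want to know
which sequence contexts their platform miscalls, and which putative SNPs
sit on error-prone positions.

## The statistic

For a motif $m$ (a string over `{A,C,G,T,N}` of length $q$, at most $n$
wildcards), every occurrence on either genome strand defines an
error-prone position (the last base of the match on the occurrence's own
strand). Pooling the pileups of all those positions gives a 2x2 table

|            | match | mismatch |
|------------|-------|----------|
| context direction  | $a$ | $b$ |
| opposite direction | $c$ | $d$ |

tested with Fisher's exact test under the probability-ordering two-sided
definition, computed **in log space** so the strand bias score
$-\log_{10} p$ stays finite for arbitrarily extreme tables. Significance
is Bonferroni-controlled over the motif space
$|S(q,n)| = \sum_{i=0}^{n}\binom{q}{i}4^{q-i}$; significant motifs with a
clean opposite-direction error rate ($\mathrm{RER} = d/(c+d) <
\varepsilon$) and a material error-rate difference ($\mathrm{ERD} =
\mathrm{FER}-\mathrm{RER} \ge \delta$, $\mathrm{FER}=b/(a+b)$) are
reported, ranked by decreasing ERD.

## Worked example

Simulate a ground-truthed dataset (4 kb reference, 55 planted `GGGT`
occurrences erring at rate 0.25 in context-direction reads, 0.005
background, 60x coverage) and run discovery:

```r
library(cseMotifs)
sim <- simulate_cse_dataset(seed = 42)
res <- discover_cse(sim$fasta, sim$sam, q = 4, n = 1)
res
#> CSE motif discovery, (q, n) = (4, 1), alpha = 0.05, epsilon = 0.03, delta = 0.05
#>   motifs tested: 512 | significant: 47 | RER < 0.03: 44 | ERD >= 0.05: 5
#>  motif rank occ    a    c   b  d score FER% RER% ERD%
#>   GGGT    1  87 1969 2486 612 12 175.7 23.7  0.5 23.2
#>   GNGT    2 168 4329 4892 631 19 166.8 12.7  0.4 12.3
#>   NGGT    3 178 4668 5220 619 25 155.6 11.7  0.5 11.2
#>   GGGN    4 185 5047 5331 622 37 137.2 11.0  0.7 10.3
#>   GGNT    5 203 5467 5999 632 31 151.5 10.4  0.5  9.8
```

The planted motif is recovered at rank 1: of the 2581 context-direction
read bases at its 87 genomic occurrences, 612 mismatch (FER 23.7%,
estimating the planted 25%), against 12 mismatches in 2498
opposite-direction bases (RER 0.5%, the background). Its wildcard
generalizations follow with diluted error rates — ranking by ERD, not by
score, is what puts the causal context on top. Reports, annotation tracks
and variant flagging:

```r
write_cse_report(res, tsv = "cse.tsv", json = "cse.json")
write_bed(motif_positions(sim$fasta, res$motif), "cse_track.bed")
annotate_variants(my_vcf_or_positions, "cse_track.bed")
```

A command-line front end with `discover`, `power`, `simulate` and `bed`
subcommands is installed at
`system.file("scripts", "cse.R", package = "cseMotifs")`.

`estimate_power()` / `power_curve()` reproduce the statistical argument
for pooling: at a single position with coverage 100 and an extreme
per-position error rate of 0.5, the exome-Bonferroni-corrected exact test
detects the bias only about a third of the time.

See the vignette (`vignettes/cse-discovery.Rmd`) for the model,
parameter guidance, generator details and numerical choices.

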