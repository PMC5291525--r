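# zccurve

Quantifying how AT and GC compositional biases co-vary along bacterial
chromosomes, without windows.

## The problem

Bacterial chromosomes are replicated bidirectionally from a single origin
(*oriC*) as two replichores, and the leading and lagging strands accumulate
different base compositions. In most bacteria the leading strand is enriched
in G and T; in Firmicutes-like genomes it is instead enriched in both purines
(A and G), a pattern that travels with the PolC replicative polymerase and
with a strong preference of genes for the leading strand. Window-based skew
measures blur these patterns at small window sizes and hide polarity switches
at large ones.

`zccurve` implements a windowless statistic for this question, the **Z-curve
correlation coefficient (ZCC)**, plus everything needed around it: origin and
terminus inference from disparity-curve extrema, leading/lagging strand
assignment of genes, phylum-level cohort summaries, and a synthetic generator
of strand-asymmetric genomes with known truth. It is aimed at comparative
genomicists studying replication-associated mutational and selective
pressure.

## The statistic

For a sequence of length *N*, with cumulative base counts
*A<sub>n</sub>, C<sub>n</sub>, G<sub>n</sub>, T<sub>n</sub>* over the first
*n* residues, the Z-curve components are

    x_n = (A_n + G_n) − (C_n + T_n)     (purine − pyrimidine)
    y_n = (A_n + C_n) − (G_n + T_n)     (amino − keto)
    z_n = (A_n + T_n) − (C_n + G_n)     (weak − strong H-bonds)

The AT and GC disparity tracks are

    a_n = (x_n + y_n)/2 = A_n − T_n
    b_n = (x_n − y_n)/2 = G_n − C_n

and the ZCC index is the Pearson correlation *r(a, b)* over *n* = 1…*N*.
A positive index means the A-over-T and G-over-C excesses rise and fall
together (purine asymmetry, the Firmicutes-like regime); a negative index
means they move oppositely (the common G+T-rich leading strand regime). The
analogous correlation between *x* and *y* is exposed as the RY–MK index.

## Worked example

Simulate a 200 kb circular chromosome whose leading strands are A/G-enriched
(per-base enrichment 0.05), with 200 genes placed on the leading strand with
probability 0.78, then analyze it blind:

```r
library(zccurve)
spec <- skew_spec(N = 200000, ori = 50000, seed = 11)
g    <- generate_genome(spec)
ann  <- generate_genes(spec, g$truth)
fit  <- zcc_genome(g$seq, genes = ann$genes)
fit
#> <zcc_genome> synth_1 (200000 bp)
#>   ZCC = 0.9988, RY-MK = 0.8105, GC = 49.9%
#>   ori = 49984, ter = 150014 (extrema, confidence 0.049)
#>   SGD: 79.0% of 200 genes on the leading strand
```

Reading the output: the ZCC index of 0.9988 identifies the purine-asymmetry
regime that was simulated; the origin placed at 50,000 is recovered at
49,984 (within 16 bp) from the detrended GC-disparity minimum, with the
terminus opposite; and 79.0% of genes are found on the leading strand,
matching the designed placement probability of 0.78. On a real genome the
same call takes a `read_fasta()` record plus optional `read_genes()` /
`read_oric_table()` inputs, and `zcc_scan_fasta()` maps it over a
multi-record file into a results table.

Tiny sequences work too, and exactly:

```r
zcc_index("AGAGCTCT")
#> <ZCC index> seq: r = 0.714286, n = 8
```

Cohort-level tools (`summarize_phylum()`, `tukey_outliers()`,
`polymerase_crosstab()`, `sgd_by_sign()`) aggregate a results table joined
with per-genome metadata into per-phylum sign percentages, majority-sign
P-ZCC/N-ZCC group labels, boxplot outliers and DE/PC polymerase
cross-tabulations. A command-line front end for the whole pipeline is
installed at `system.file("cli", "zcc.R", package = "zccurve")` with
subcommands `compute`, `cohort`, `simulate` and `plot`.

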