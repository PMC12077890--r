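# minorflux

Quantification of **minor (U12-type) versus major (U2-type) intron
retention** from RNA-seq, and **[U-13C]glutamine tracer analysis** of the
lipogenic program that retention unleashes in the liver.

Loss of minor-spliceosome function (e.g. the ZRSR1/ZRSR2 splicing factors)
leaves U12 introns unspliced far more often than U2 introns. Retained minor
introns in *Insig1*/*Insig2* carry premature termination codons (PTCs) that
truncate the INSIG proteins, de-repressing SREBP1c and switching on de novo
lipogenesis fed by IDH1-mediated reductive carboxylation of
glutamine-derived alpha-ketoglutarate. This package implements both
quantitative arms of that analysis for anyone studying intron retention or
glutamine-driven lipogenesis:

**Retention arm**

- intron catalog from GTF/BED12 + FASTA, classified by terminal
  dinucleotides (AT-AC → U12; GT-AG/GC-AG → U2) with curated-table
  (IAOD-style) override;
- fragment counting over intron bodies, flanking exons, and exact splice
  junctions from indexed BAM/SAM;
- retention index `RI = (intron reads/length) / (flank reads/length)`,
  retained calls (`RI ≥ 0.1` and `reads ≥ 10` by default), per-class
  percent-retained summaries;
- differential retention screen on log2 CPM with variance moderation and
  Benjamini–Hochberg control (volcano + gene roll-up);
- PTC scan of intron-retained coding sequences (first in-frame stop,
  truncated-protein length, frameshift flag).

**Tracing arm**

- natural 13C-abundance correction of mass-isotopologue distributions
  (binomial correction matrix + non-negative least squares);
- oxidative (M+4) vs reductive (M+5) citrate partition with the M+5/M+4
  ratio and reductive fraction `f_red = x5 / (x4 + x5 + x6)` under the
  one-turn glutamine model;
- isotopomer spectral analysis (ISA) of fatty acids:
  `x_{2k} = (1−g)·1[k=0] + g·C(n,k)·D^k(1−D)^{n−k}`, estimating the
  lipogenic acetyl-CoA labeled fraction `D` and the newly synthesised
  fraction `g`.

Synthetic-data generators with recorded ground truth (class-specific
retention probabilities, negative-binomial counts, one-turn tracing MIDs)
support calibration, power studies, and end-to-end testing, including SAM
emission for the alignment-counting path.

## Worked example

Simulate the knockout-like design (657 U12 / 211,005 U2 introns, U12
retention probability 0.56 vs U2 0.003 in the knockout arm, n = 4 per
arm), summarise retention, and run the differential screen:

```r
library(minorflux)

sim <- simulate_retention_dataset(retention_sim_config("zlko", seed = 42))
class_retention_summary(sim$samples)
#>   condition intron_class n_evaluable n_retained n_undefined percent_retained
#> 1       CTR          U12         657         33           0            5.023
#> 2       CTR           U2      211005        627           0            0.297
#> 3        KO          U12         657        391           0           59.513
#> 4        KO           U2      211005        619           0            0.293

a <- Filter(function(x) x$condition == "CTR", sim$samples)
b <- Filter(function(x) x$condition == "KO", sim$samples)
differential_retention(a, b)
#> differential_retention (moderated): 211662 introns tested,
#>   1662 significant at q<0.05, |log2FC|>=0.485
```

The class summary reproduces the planted contrast — around 60% of minor
introns retained in the knockout against ~0.3% of major introns — and the
screen recovers the retention shift intron by intron.

Tracing arm at a reductive fraction of 0.6:

```r
simt <- simulate_tracing_mids(tracing_sim_config(f_red = 0.6, seed = 42))
pick <- function(met) correct_mid(simt$mids[[paste0("rep1.", met)]])
flux_partition(pick("citrate"), pick("fumarate"), pick("malate"))
#> flux_partition (one-turn glutamine model)
#>   citrate M+4 = 0.2046  M+5 = 0.3826  M+6 = 0.0515
#>   M+5/M+4 ratio = 1.870
#>   estimated reductive fraction = 0.599

isa_fit(pick("palmitate"), 8)
#> ISA fit palmitate (n = 8 acetyl units): D = 0.199, g = 0.304 (SS = 1.11e-06)
```

The M+5/M+4 citrate ratio and `f_red` track the planted reductive flux,
and the ISA fit recovers the generating `(D, g)` to the third decimal at
0.5% measurement noise.

A thin command-line front end over the same functions lives at
`inst/cli/minorflux.R` (`catalog`, `quantify`, `retention-stats`,
`volcano`, `ptc-scan`, `mid-correct`, `flux-partition`, `isa-fit`,
`simulate`, `pipeline`); `run_pipeline()` orchestrates the stages with
provenance records and up-to-date skipping.

## Documentation

The methods vignette (`vignettes/minorflux-methods.Rmd`) describes the
retention index and its thresholds, the moderated differential screen, the
one-turn tracing model, the ISA fit, what the simulators do and do not
emulate, and known limitations.
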