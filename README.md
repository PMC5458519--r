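# trisplice

Splicing modulators of the pladienolide/herboxidiene class bind the SF3b
complex and perturb branch-point recognition, shifting splicing outcomes
toward intron retention (IR) and exon skipping (ES). Resistance point
mutations in SF3b components (e.g. in PHF5A or SF3B1) blunt that action
and can qualitatively redirect it: a 3′ splice site that retains its
intron in drug-treated wild-type cells may instead skip the upstream
cassette exon in a resistant mutant, with the balance tracking the GC
content of the neighbouring introns and exons.

`trisplice` is an R package for analysing exactly this kind of
experiment. It takes splice-junction count tables (the 9-column
`SJ.out.tab` dialect written by STAR), per-3′-splice-site exon–intron
boundary read counts, a transcript annotation (BED12 or minimal GTF) and
a genome FASTA, and provides:

- **Junction-level PSI** (percent spliced in): a junction's unique read
  count divided by the summed counts of all junctions sharing the same
  donor or acceptor splice site.
- **The 3′-splice-site trifurcation**: at a shared acceptor, reads split
  into ES (junction skipping the cassette exon), exon inclusion (the
  intron's own junction) and IR (reads crossing the exon–intron
  boundary); PSIs are the three counts as fractions of their sum,
  averaged over replicates per condition.
- **Moderated-t differential PSI** between sample groups, with the
  empirical-Bayes variance shrinkage implemented from first principles:
  per-event variances are modelled as *s*² ~ *s₀*² F(d, d₀), the prior
  (d₀, *s₀*²) is fitted by matching the mean and variance of log *s*²
  through digamma/trigamma identities, the posterior variance is
  (d₀ *s₀*² + d *s*²)/(d₀ + d), and the statistic gains d₀ degrees of
  freedom. P-values are Benjamini–Hochberg corrected; q ≤ 0.05 is the
  default significance threshold.
- **Event classification** against the annotation (canonical, ES, alt5,
  alt3, IR, other) and per-category count/fraction/log₂ fold-change
  summaries.
- **GC metagene profiles**: significant retained introns (length ≥ 100)
  paired with a downstream exon (length ≥ 50), and significant skipped
  exons with both flanking introns, are rescaled to fixed bins
  (intron → 100, exon → 50), and per-bin mean GC is reported with a 95%
  percentile interval from 100 bootstraps over pairs, against a matched
  random background of 10,000 annotation pairs passing the same filters.
- **ES/IR switch analysis**: for significant ES sites in one genotype,
  the replicate-averaged trifurcation PSIs are compared across
  genotypes; a site switches when the comparison condition shows
  strictly lower ES PSI and strictly higher IR PSI, and sites are
  reported in waterfall order (descending ES PSI).
- **A resistant-clone variant filter**: non-silent variants in a curated
  gene list with allele frequency strictly above 0.2, reported by
  recurrence across clones (default: genes hit in ≥ 3 distinct clones).
- **A synthetic-data generator** that emits a genome with controlled
  per-feature GC, cassette-exon gene models on both strands, junction
  and boundary counts under a 2 genotype × 2 treatment × 6 replicate
  design (negative-binomial depth, Dirichlet-multinomial trifurcation),
  and clone variant tables — all with exported planted truth, so every
  stage can be validated against known effects.

## Worked example

Simulate a 500-locus study and run the full pipeline:

```r
library(trisplice)

cfg   <- sim_config(n_loci = 500, master_seed = 42)
study <- simulate_study(cfg, "demo_study")
res   <- run_end_to_end("demo_study", "demo_out",
                        n_background = 900, seed = 42)
```

The run logs each stage:

```
[trisplice] psi: 500 cassette 3' splice sites, 24 samples
[trisplice] differential WT_compound_vs_control psi_ir: 500/500 testable, 175 significant at q<=0.05
[trisplice] differential MUT_compound_vs_control psi_es: 500/500 testable, 128 significant at q<=0.05
[trisplice] gc: IR profile over 128 intron/exon pairs
[trisplice] gc: ES profile over 117 triplets
[trisplice] switch: 81/126 sites switch (fraction 0.643; 0 excluded undefined)
[trisplice] variants: 16/52 kept by filter, 2 recurrent genes
```

With the default generator, one quarter of loci respond to the compound
(IR in the wild type, ES in the mutant at 64% of the ES-responsive
sites), so the treated wild type shows mostly IR gains (175 significant
IR sites), the treated mutant mostly ES gains (128 significant ES
sites), and 81/126 = 0.643 of the mutant's significant ES sites switch
to IR in the treated wild type — recovering the planted fraction.

```r
res$switch_counts
#> $n_switch [1] 81    $n_total [1] 126    $fraction [1] 0.6428571

res$recurrence
#> Recurrently mutated genes (>= 3 clones):
#>   DRIVER1: 7 clones
#>   DRIVER2: 5 clones

head(res$differential[["WT_compound_vs_control.psi_ir"]][,
       c("event_key", "delta_psi", "t_mod", "q")], 3)
#>                     event_key   delta_psi      t_mod            q
#> simchr1:1119:+ simchr1:1119:+ 0.005965374  0.4764215 8.127857e-01
#> simchr1:1612:- simchr1:1612:- 0.424480781 37.7846353 8.813042e-15
#> simchr1:4076:+ simchr1:4076:+ 0.405669958 21.3041029 1.902457e-12
```

`delta_psi` is the change in IR PSI (compound − control): null loci sit
near 0, planted loci near the +0.4 effect. The responsive loci carry
GC-rich introns by design, and the GC metagene stage makes that visible:

```
intron GC, IR foreground vs background: 0.554 vs 0.453
```

All outputs are also written as TSV under `demo_out/` (trifurcation
PSIs, per-comparison differential tables, event summaries, GC profiles,
the ordered switch table and the recurrence report), with a manifest
recording file checksums, the seed and a config hash.

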