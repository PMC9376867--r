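# corepan

Completeness-aware Bayesian partitioning of pan-genomes into core and
accessory traits.

## The problem

Core-genome analysis classically calls a gene cluster "core" when it is
present in (nearly) 100% of a set of genomes. On metagenome-assembled
genomes (MAGs) and single-cell genomes (SAGs) — which typically recover
only 30–90% of their true gene content — that rule collapses: a core gene
absent from one 50%-complete MAG leaves the strict core, and with many
incomplete genomes almost nothing survives. `corepan` is for
microbiologists and microbiome researchers who want core/pan-genome
structure out of MAG and SAG collections rather than only finished
isolates.

## The model

Each trait (gene cluster, COG, any discrete genome-encoded feature) is
scored by a log-likelihood ratio between two hypotheses, given per-genome
completeness estimates *c<sub>g</sub>*:

* **core** — the trait is in every genome and observed in *g* with
  probability *c<sub>g</sub>*:
  *p*<sub>core</sub> = ∏<sub>trait∈g</sub> *c<sub>g</sub>*
  ∏<sub>trait∉g</sub> (1 − *c<sub>g</sub>*);
* **accessory** — traits are independent with pool frequency
  *f* = |trait|/|T|; genome *g* makes
  *e<sub>g</sub>* = max(0, |g| − *c<sub>g</sub>*·|core|) accessory draws,
  so the trait misses *g* with probability (1 − *f*)<sup>*e<sub>g</sub>*</sup>.

LLHR = log *p*<sub>core</sub> − log *p*<sub>accessory</sub> > 0 calls the
trait core. Completeness is then re-estimated as the fraction of the core
each genome carries, and the loop repeats until the core set is stable. A
bootstrap rebuilds synthetic genome sets from the fitted partition,
reclassifies them, and reports a false discovery rate and sensitivity for
the partition. See the vignette
(`vignettes/core-accessory-partitioning.Rmd`) for the full account.

## Worked example

```r
library(corepan)

## a synthetic species: 40 genomes, true core 800, accessory pool 1600,
## completeness uniform on (0.5, 1) — i.e. a typical MAG collection
pg  <- generate_pangenome(n_genomes = 40, core_size = 800,
                          accessory_pool_size = 1600, seed = 42)
fit <- corepan(pg$matrix, completeness = pg$completeness)
fit
#> Bayesian core/accessory partition
#>   40 genomes x 2213 traits; core 821, accessory 1392
#>   2 pass(es); converged
#>   completeness: mean prior 0.795 -> mean posterior 0.788

bootstrap_rates(fit, n_reps = 5, seed = 1)
#> bootstrap partition QC (5 replicate(s), seed 1)
#>   false discovery rate: 0.0179
#>   sensitivity:          1.0000

length(intersect(fit$core, pg$true_core)) / 800   # true-core recovery
#> [1] 1
length(strict_core(pg$matrix))                    # 100%-presence baseline
#> [1] 0
```

The fit recovers the entire constructed core (821 calls, of which the
bootstrap estimates ~2% false discoveries) from genomes that are on
average 80% complete, while the strict 100%-presence rule returns an
empty core on the same matrix. Real inputs come in through
`read_roary()` (Roary `gene_presence_absence.csv`), `read_clusters_tsv()`
(mmseqs2-style representative/member pairs), `read_trait_pairs()`
(generic `genome<TAB>trait`), and `read_checkm()` for completeness
priors; `write_partition()` writes per-trait, per-genome and summary
tables. `motu_components()` groups genomes into species-level clusters
(mOTUs) from a pairwise ANI table at a 95% threshold before
partitioning.

A thin command-line wrapper is installed at
`inst/scripts/corepan` (subcommands `partition`, `bootstrap`, `motuize`,
`simulate`).

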