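---
title: "Completeness-aware core/accessory partitioning of pan-genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completeness-aware core/accessory partitioning of pan-genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corepan)
```

## The problem

The core genome of a bacterial or archaeal species — the traits shared by
all of its members — is classically computed with a hard presence
threshold: a gene cluster is core if it appears in (nearly) 100% of the
genomes. That rule works on finished isolate genomes and fails badly on
metagenome-assembled genomes (MAGs) and single-cell amplified genomes
(SAGs), which routinely recover only 30–90% of a genome's true gene
content. A genuinely core gene missing from a single 50%-complete MAG
leaves the strict core; with dozens of incomplete genomes the strict core
collapses toward the empty set, and most of the genomic diversity sitting
in MAG collections becomes unusable for pan-genome analysis.

`corepan` treats incompleteness as part of the observation model rather
than as noise to filter away. It takes (i) a binary genome × trait
incidence matrix — traits can be gene clusters from any clusterer, COGs,
or any other discrete genome-encoded feature; the package never touches
sequences — and (ii) a per-genome completeness estimate (e.g. from CheckM,
or a fixed value), and classifies each trait as *core* or *accessory* by a
likelihood ratio between two generative stories of its presence/absence
pattern.

## The model

Write $c_g$ for the completeness of genome $g$, $|g|$ for its observed
trait count, $|\mathrm{trait}|$ for the number of genomes carrying a
trait, and $|T| = \sum_{\mathrm{traits}} |\mathrm{trait}|$ for the total
observation pool.

**Core hypothesis.** A core trait belongs to every genome of the set, so
it is *observed* in genome $g$ with probability exactly $c_g$:

$$p_{\mathrm{core}} = \prod_{g \,:\, \mathrm{trait} \in g} c_g
  \prod_{g \,:\, \mathrm{trait} \notin g} (1 - c_g).$$

**Accessory hypothesis.** Accessory traits are modelled as independent,
each with pool frequency $f = |\mathrm{trait}|/|T|$. A genome's accessory
complement is imagined as $e_g = \max(0,\, |g| - c_g\,|\mathrm{core}|)$
draws from that pool, so a given accessory trait misses genome $g$ with
probability $\bar p_g = (1-f)^{e_g}$ and

$$p_{\mathrm{acc}} = \prod_{g \,:\, \mathrm{trait} \in g} (1 - \bar p_g)
  \prod_{g \,:\, \mathrm{trait} \notin g} \bar p_g.$$

The decision statistic is the log-likelihood ratio
$\mathrm{LLHR} = \log p_{\mathrm{core}} - \log p_{\mathrm{acc}}$ (natural
logarithms; reported in nats): positive means core. Given a classification,
completeness is re-estimated as the fraction of the core each genome
carries, $c_g = |\mathrm{core} \cap g| / |\mathrm{core}|$, and the
classify → re-estimate loop repeats until the core set is identical
between two successive passes. Trait frequencies $f$ are computed once
from the observed matrix and never updated — they are observational,
whereas $c_g$ and $|\mathrm{core}|$ are model state.

## Tunable parameters

* **`completeness`** — priors as fractions in (0, 1] or CheckM-style
  percentages in (1, 100]; a single value applies to all genomes. This is
  the only biological input besides the matrix.
* **`clamp`** (default `c(0.01, 0.99)`) — working completeness values are
  clipped into this interval. Without the upper clip, a genome with
  $c_g = 1$ vetoes any trait it lacks ($\log(1 - c_g) = -\infty$), which
  is precisely the hard-threshold behaviour the model exists to avoid;
  without the lower clip a hopeless genome would contribute nothing.
  Posteriors re-entering the next iteration are clipped the same way.
* **`max_iter`** (default 100) — convergence typically takes a handful of
  passes. `max_iter = 1` disables completeness re-estimation entirely:
  the priors are used for the single classification pass, and the
  posterior is computed once for reporting only. Use this when the genome
  set is not a species-like cluster (genomes grouped by niche, host,
  etc.), where "every genome holds the full core" is not a belief you
  want the completeness update to enforce.
* **`seed_core`** (default `"half-mean-prior"`) — the first pass needs a
  provisional $|\mathrm{core}|$. The default seeds with traits whose
  prevalence is at least half the mean prior completeness: a core trait
  is expected in a fraction $\approx \overline{c}$ of genomes, so half
  that admits every plausible candidate and lets the iteration prune.
  On well-separated data the converged partition is identical under the
  `"mean-prior"` rule (verified by test). The `"all"` option is
  deliberately degenerate and kept only as a diagnostic: with every trait
  in the core, the posterior becomes $|g|/|\mathrm{core}|$ and the
  accessory exponent $|g| - c_g|\mathrm{core}|$ vanishes for every
  genome, so the accessory model can explain nothing and the all-core
  state is a fixed point from which nothing is ever pruned.
* **`drop_warn`** (default 0.15) — if the mean posterior completeness
  falls more than this below the mean prior, the fit carries a warning:
  the genome set likely merges several clades, and the "core" recovered
  is the dominant subclade's, with the other clade's genomes scored as
  very incomplete. Partition such sets first (`motu_components()`, 95%
  ANI) or fall back to `max_iter = 1`.

## Numerical choices

All probability products are evaluated in log space; an absent trait
contributes $e_g \log(1-f)$ directly and a present one
$\log(1 - e^{e_g \log(1-f)})$ via `expm1`, so patterns hundreds of
genomes long cannot underflow. When $e_g = 0$ the presence of an
accessory trait in $g$ has probability zero and the term is $-\infty$;
a finite core likelihood then makes the trait core with infinite LLHR,
and the (measure-zero) $-\infty$ vs $-\infty$ comparison is resolved to
*accessory* with a recorded diagnostic — no evidence either way, so the
conservative class wins. An LLHR of exactly zero is likewise classified
accessory. A single-trait matrix makes the accessory model degenerate
($f = 1$) and is rejected with a validation error. Should the iteration
enter a two-cycle between two core sets, the fit stops, reports
`converged = FALSE`, and returns the smaller of the two sets with a
diagnostic; in practice we have only observed plain convergence, but the
loop must terminate sensibly either way. Identical inputs give identical
outputs — there is no randomness in the fit.

## Bootstrap quality control

`bootstrap_rates()` estimates how much of a fitted core to believe.
Synthetic genome sets are rebuilt *from the partition itself*
(`simulate()` on the fit): each synthetic genome receives the full
predicted core plus `round(G - |core|)` accessory traits drawn without
replacement, weighted by observed trait counts (preserving the frequency
structure the accessory model assumes), where `G` is the mean of genome
size over posterior completeness; the complete synthetic genome is then
rarefied by keeping each trait with probability equal to that genome's
posterior completeness. Re-running the classifier on the rebuilt set and
comparing against the construction labels yields, per replicate, a false
discovery rate (constructed-accessory called core, over predicted core
size) and a sensitivity (constructed core recovered); estimates are means
over replicates. The synthetic refits reuse the original posteriors as
priors — the rarefaction was performed at exactly those rates, so they
are legitimately known. Rarefaction removes core and accessory traits
alike, since real incompleteness does not spare core genes. Each
replicate derives its own seed from the report seed, so any single
replicate can be reproduced in isolation.

## The synthetic generator, and what passing tests mean

`generate_pangenome()` builds the ground-truth sets used by the test
suite and the acceptance script: every full genome carries all
`core_size` core traits plus independent accessory draws (trait $j$ with
probability `carriage[j]`), then loses each trait independently with
probability $1 - c_g$. The default carriage profile decays geometrically
over ranked accessory traits ($0.5 \times 0.998^{\,\mathrm{rank}}$,
floored at 0.01): a few near-common accessory traits and a long tail of
rare ones, which is the qualitative shape of prokaryote accessory
genomes. The default conditions — 50 genomes, core 1000, accessory pool
2000, completeness uniform on (0.5, 1) — give complete genomes of about
1240 traits, a species-sized set with the completeness spread typical of
MAG collections.

The generator matches the accessory model's independence assumption, so
recovery results on it are a *best case*: they show the estimator is
correct under its own assumptions and robust to severe incompleteness.
Real accessory genomes are correlated (operons, plasmids, phage), real
completeness estimates are themselves noisy, and contamination can add
foreign traits; none of these are simulated, and the package deliberately
models contamination no further than the completeness clamp. The
completeness-stratified and good/bad-genome harnesses
(`robustness_experiment()`) probe degradation as completeness falls. One
qualitative expectation did not survive contact with this generator:
adding many very incomplete genomes to one good genome improves
sensitivity markedly but nudges the empirical false discovery rate
slightly *up* rather than down on our synthetic design; the property
test asserts the directions that hold robustly (sensitivity improves,
FDR stays bounded).

## Problem sizes in the checks

The test suite and `scripts/acceptance.R` run the study conditions above
at 10 generator seeds for recovery and bootstrap calibration (3 bootstrap
replicates per set), 30 runs per completeness stratum for the ordering
check, and 1000 small random matrices (≤ 8 × 25) for exact agreement
between the log-space scorer and a naive product-space oracle. These
sizes give stable means while keeping a full run in tens of seconds;
the robustness harness scales to paper-sized grids (thousands of runs)
by changing `n_runs`.

## Known limitations

* Completeness priors are trusted up to the clamp; systematically biased
  priors bias the first pass, although the posterior update largely
  forgets them on species-like sets.
* Contamination is read from CheckM tables and reported, never modelled:
  a heavily contaminated genome inflates $|g|$ and its accessory
  exponent.
* The accessory null assumes trait independence; tightly linked accessory
  blocks shared by many genomes can score as core (they are, in effect,
  core to a subpopulation).
* mOTU clustering consumes a precomputed ANI table (fastANI, mash, etc.);
  the package does not compute ANI from sequences, and the 95% threshold
  is applied to the better of the two reported orientations by default.
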