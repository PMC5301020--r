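---
title: "Methods: karyotype parsimony, class-partitioned divergence, and coalescent validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: karyotype parsimony, class-partitioned divergence, and coalescent validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromospec)
```

`chromospec` implements a three-part analysis for chromosomally diverse
radiations — ancestral karyotype reconstruction, chromosome-class-partitioned
divergence, and gene-tree/partition-tree concordance — together with a
coalescent generator that produces data with the same statistical structure
plus the ground truth needed to validate every stage. This vignette is the
package's account of the models, the defaults, and the choices made where
the design was genuinely open.

## Karyotype parsimony

Karyotypes are coded as a taxa × characters matrix: one character per
chromosome (or named rearrangement), with unordered morphology states
(`a` acrocentric, `m` metacentric, `sm` submetacentric, `i` inversion) and
`"5-10"`-style tokens for centric fusions. Missing entries (`?`) contribute
the full alphabet at zero cost.

Reconstruction on a fixed rooted species tree uses unordered, equally
weighted parsimony. The dynamic programme is Sankoff's over an arbitrary
step-cost matrix, which with the default uniform costs reduces to
Fitch/Hartigan counting; polytomies need no special casing because each
child contributes its own minimum. A cost-matrix hook is exposed for users
who want weighted steps, but the default is deliberately uniform: the
analysis this package supports treats all rearrangement transitions as
exchangeable, and nothing in typical G-banding data justifies a particular
step matrix.

Two reporting decisions matter:

* **Ambiguity is reported, not resolved.** For each state we compute the
  minimum and maximum number of independent origins (an origin is a branch
  whose parent lacks the state and whose child has it) over *all*
  most-parsimonious reconstructions, by a second dynamic programme over the
  optimal-choice sets of the first. Nodes whose MPR-consistent state set has
  more than one element are listed as unresolved. ACCTRAN- and DELTRAN-style
  single-reconstruction placements are available (`resolve = "acctran"` /
  `"deltran"`, operationalised as preferring or delaying change at ties),
  but the default event table is compiled over the full MPR set (capped at
  `enumerate_limit`, default 1e5; beyond the cap a canonical reconstruction
  is used and every row of an ambiguous state is flagged).
* **Reversal vs. independent origin is not adjudicated.** An edge regaining
  the reconstruction's root state is labelled a reversal, all other gains
  origins, and both are counted; deciding between convergent origin,
  reversal and chromosomal introgression requires evidence (e.g. breakpoint
  sequences) outside the scope of tip-state parsimony.
* **Fusions are censused by token.** The same fusion may legitimately
  appear in the columns of both participating chromosomes;
  `fusion_census()` deduplicates by token so each fusion counts once.

An optional `root_state` constraint restricts attention to MPRs with a given
ancestral state (e.g. an outgroup-supported ancestral morphology); a
constraint no MPR can satisfy is an error rather than a silent
re-optimisation. Whether to constrain the root is left to the user — the
package takes no position on whether the radiation's ancestor must carry
the ancestral karyotype.

Correctness is anchored by an independent oracle: a brute-force enumerator
of all ancestral assignments, against which scores and origin ranges are
checked exactly on 100 random trees (≤ 8 leaves) × random characters (≤ 4
states, 15% missing) in the test suite.

## Net divergence partitioned by chromosome class

Loci are assigned to classes `X`, `rearranged`, `non_rearranged` (or
`unassigned`) via a locus→class map; taxa belong to chromosomal groups via
an individual→taxon→group map. For taxa X, Y at one locus we report Nei's
net divergence

$$ d_A = d_{XY} - \tfrac{1}{2}(d_X + d_Y), $$

which discounts the ancestral diversity shared at speciation; it may be
negative at individual loci.

Numerical conventions:

* **Distance.** Uncorrected p-distance by default; JC69
  ($-\tfrac34\log(1-\tfrac43 p)$) optional, with an explicit saturation
  error at $p \ge 0.75$. Divergences between recently diverged taxa are
  small enough that the two nearly coincide; the default avoids implying a
  correction model the data cannot distinguish.
* **Missing data.** Gaps, `?` and IUPAC ambiguity codes are all treated as
  missing at a site, and sites are dropped pairwise (a site counts only when
  both sequences carry an unambiguous base). This is the simplest defensible
  convention; ambiguity codes are rare in exon capture consensus sequences
  and carry little distance information.
* **Length weighting.** "Accounting for sequence length" is implemented by
  pooling mismatch and compared-site counts across loci before forming
  distances — exactly concatenation under pairwise-deletion p-distance —
  then averaging per-pair $d_A$ over all unordered taxon pairs within a
  group. The tests verify the concatenation identity on random gapped
  fixtures.
* **Single-individual taxa.** A taxon sampled once cannot estimate
  within-taxon diversity; its term is set to 0 and the record flagged
  (`single_individual`) rather than silently dropped, so $d_A$ degrades to
  $d_{XY}$ visibly.
* **Uncertainty.** A nonparametric percentile bootstrap resamples loci (the
  exchangeable unit of an exon-capture design) with replacement; seeds are
  mandatory, and no p-values are attached — the comparisons this analysis
  supports are descriptive.

How to average over taxon pairs within a group is genuinely open (all
unordered pairs vs. selected contrasts); the package defaults to all pairs
and exposes `pairs =` for any other choice.

## Monophyly and incongruence

For each partition tree, each taxon with sampled leaves is tested for
exclusivity — as a clade on rooted trees, as a split on unrooted ones (so an
arbitrary stored rooting cannot break the answer). Taxa with one sampled
individual are trivially monophyletic and excluded from the summary
fraction by default, matching a two-individuals-per-taxon design where only
multi-individual taxa are informative. Support values are ignored: applying
a support threshold would silently change the statistic's meaning, and no
threshold is obviously right.

Between-tree incongruence is the unrooted Robinson–Foulds distance on
nontrivial splits after pruning to the common leaf set, with the shared
count and the conflicting splits themselves (reported by minority side)
returned, and `rf / (2(n-3))` as the normalisation. The implementation
computes split sets directly (it needs the conflict lists); tests
cross-check the distance against an independent library implementation on
random tree pairs.

## The synthetic-data generator

The generator exists so that the pipeline's inferences can be checked
against known truth. It emulates the case-study design: a species tree
with ~20 taxa in four chromosomal groups, two individuals per taxon, and an
exon set partitioned as 21 X loci (426 bp), 160 rearranged loci (226 bp)
and 140 non-rearranged loci (538 bp) — counts and mean lengths matching the
partition sizes of the motivating dataset. Defaults:

* **Time and rates.** Branch lengths are coalescent units (2N generations);
  `mu = 0.002` substitutions/site/unit by default, chosen so that pairwise
  divergences across the default tree (splits at 0.5–5 units) fall in the
  sub-percent to few-percent range typical of a recent radiation. No
  calendar-year calibration is attempted.
* **Effective sizes.** `ne_scale = c(X = 0.75, autosomes = 1)`: the X's
  hemizygosity gives it three quarters of the autosomal effective size,
  which accelerates lineage sorting on the X.
* **Introgression as pulses.** Each event reroutes, with a class-specific
  probability, *all* sampled lineages of the recipient into the donor
  population at the event time — a replacement pulse. This matches a framing
  of discrete introgression episodes and keeps the generator analyzable
  (e.g. with a certain pulse at time $t_0$, a recipient/donor lineage pair
  coalesces like two lineages of one population, $E[T] = t_0 + n_e$, which
  the tests verify). No quantitative introgression rates are available to
  copy, so scenario magnitudes (e.g. 0.8 vs 0 across classes) are chosen
  for statistical power and documented as such, not as biological
  estimates.
* **Free recombination between loci, none within** — the standard
  exon-capture assumption; gene trees are drawn independently per locus.
* **Reproducibility.** Every locus has an RNG stream derived from
  `(seed, class, locus index)`, so bundles regenerate byte-identically and
  any single locus can be re-simulated in isolation.
* **Karyotype layer.** Characters evolve by a Poisson process on branches
  (`base_rate = 0.005` events/unit, ≈ 0.3 expected events per character on
  the default tree, so most characters change 0–1 times as in real
  karyotype matrices); a `hotspot_fraction` (0.2) of characters evolve 10×
  faster, generating the recurrent, convergent rearrangements that the
  parsimony module should flag as homoplasy. The event log is replayable:
  re-applying it reproduces the tip matrix exactly, and parsimony's minimum
  change count is verified to lower-bound the true event count character by
  character.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: selection (including divergent selection on the X and
meiotic drive), recombination suppression within rearrangements as a
*mechanism* (class-specific pulse probabilities impose its predicted
*consequence* directly), within-locus recombination, substitution-model
misspecification beyond JC69, alignment error, and missing data. Validation
against this generator demonstrates that the statistics recover the
signal they are designed for when it is present, not that any particular
empirical dataset contains that signal.

## Validation scenarios and problem sizes

The test suite runs (sizes chosen as a balance of statistical power and a
test run a maintainer will actually wait for):

* **Recovery**: 20 replicate datasets of the two-group, eight-taxon
  scenario (`introgression_scenario()`), 200 loci/class × 500 bp, pulse
  probability 0.8 on non-rearranged vs 0 elsewhere; net divergence for the
  admixed pair must order rearranged > non-rearranged in ≥ 19/20
  replicates, and the monophyly fraction of the rearranged partition tree
  must be ≥ the non-rearranged one in ≥ 18/20.
* **Null calibration**: 50 replicates with equal pulses (0.4/0.4) and 50
  loci/class × 300 bp; the class contrast in dA must sit within two
  Monte-Carlo standard errors of zero.
* **Closed form**: with constant population sizes, ancestral diversity
  cancels and $E[d_A] = 2\mu\tau$; at $\tau = 4$, $\mu = 0.00125$
  (so $2\mu\tau = 0.01$), 200 loci × 1 kb must land within 10%.
* **Sorting**: deep splits (≥ 5 units) with 5 kb of concatenated sequence
  drive the monophyly fraction to ≥ 0.95 over 20 replicates; with no
  introgression, the 3/4-Nₑ X sorts at least as fast as the autosomes in
  ≥ 16/20 replicates.
* **Hotspots**: 1000 characters at hotspot multiplier 10 (seed 1); hotspot
  characters must show multiple-origin states significantly more often
  (Fisher test, α = 0.01).

`scripts/acceptance.R --seed S --out f.json` re-runs all of the above from
scratch plus a case-study-scale pipeline (20 taxa, 321 loci) and writes the
resulting numbers.

## Pipeline conventions and limitations

`run_pipeline()` validates before computing (missing config fields and
unresolvable leaves fail by name; a locus without a class entry is a
warning and analyses as `unassigned`), logs stage progress to stderr,
writes reports with fixed column order and six-decimal floats so reruns
are byte-identical, and emits a manifest with package version, seed and
input checksums. When no partition trees are supplied it falls back to
neighbour-joining on concatenated p-distances — adequate for smoke tests
and the bundled toy fixture, and clearly not a substitute for model-based
inference; tree estimation is out of scope by design, as are network
inference, ABBA-BABA-style tests, dN/dS, and read processing. p-distance
after pairwise deletion is not a metric (masking differs by pair), so no
triangle inequality is asserted anywhere.
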