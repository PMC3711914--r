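---
title: "Divergence partitioning and refugial-origin testing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence partitioning and refugial-origin testing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divpart)
```

## The problem

Widespread European taxa are classically thought to have survived
Pleistocene glaciations in the Mediterranean peninsulas and recolonised
central Europe afterwards ("southern richness, northern purity"). For a
species with many allo-/parapatric mitochondrial clades, that hypothesis
makes a testable prediction: populations north of the major biogeographic
barriers (Pyrenees, Alps, Apennines, central Balkans) should belong to the
same genetic pool as some southern region, so their sequence divergence
from the south should sit at the *within*-clade level. The alternative —
survival in northern, extra-Mediterranean refugia — predicts independent
northern lineages whose divergence from southern populations sits at the
*between*-clade level.

`divpart` implements the statistical machinery for this comparison on
per-locus multiple sequence alignments plus a specimen/locality/clade
metadata table: uncorrected p-distances, standard diversity summaries with
a resampling correction for unequal sample sizes, distance-based AMOVA
$\Phi_{ST}$, and the permutation tests that place each northern locality on
the within/between divergence scale. A clade-structured sequence simulator
with known ground truth makes every stage testable without any sequence
download.

## Distances

All distances are uncorrected p-distances with **pairwise deletion**: for a
pair of sequences, a site contributes only when both carry an unambiguous
base (`A/C/G/T`); gaps, `N` and IUPAC ambiguity codes are unresolved and
excluded for that pair only. Ambiguity codes are never scored as partial
matches — "uncorrected" distance semantics, and no fractional-mismatch rule
has to be invented. A pair sharing no resolved site has an *undefined*
distance: it is flagged and excluded from downstream means with a warning,
never silently zeroed. `distance_matrix()` computes mismatch counts through
per-base indicator-matrix products, so results are exact integer arithmetic
identical to the naive per-pair loop (asserted without tolerance in the
tests).

Between-group summaries exist in two deliberately distinct dialects:

* `clade_distance_table()` — the **unweighted mean over clade pairs** of the
  per-pair group means (the convention of MEGA's between-group mean
  distances), used for describing inter-clade divergence;
* `bc_wc_statistics()` — the **pooled individual-pair means** $D_{bc}$
  (all pairs in different clades) and $D_{wc}$ (all pairs in the same
  clade), used by the permutation tests.

Both are exposed because published between-clade summaries do not always
say which convention they use; on balanced designs they coincide, on
unbalanced ones they do not.

## Diversity statistics and rarefaction

Per group: segregating sites $S$ (columns with at least two distinct
resolved bases among the rows resolved there), nucleotide diversity
$\pi = \frac{2}{N(N-1)}\sum_{i<j} d_{ij}$ (identically the mean pairwise
p-distance, asserted by cross-check), haplotype number $h$, and haplotype
diversity $Hd = \frac{N}{N-1}(1-\sum_k p_k^2)$. Haplotypes are equivalence
classes of exact identity over the columns fully resolved in *every*
sequence of the group (complete deletion within the group): with missing
data, per-pair comparison would not induce a well-defined equivalence
relation, and this matches the default behaviour of the standard haplotype
software. `sites_used` reports the number of columns that survive this
within-group deletion.

Groups of unequal size are compared after **rarefaction**: with $s$ the
smallest size among the groups compared (sizes 0 and 1 ignored), each
larger group is summarised by the average of $S$, $h$, $Hd$, $\pi$ over 100
random subsets of $s$ sequences drawn **without replacement** — the
statistic is a subsample mean, not a bootstrap (a bootstrap mode exists as
an option, and an exhaustive mode enumerates all $\binom{N}{s}$ subsets for
small groups; the tests verify the random mode against the exhaustive one).
$s$ is computed per locus across the compared groups, since different loci
have different coverage. Each group draws from its own RNG substream
derived from the top-level seed and a hash of the group id, so adding or
removing a group never changes another group's draws.

## AMOVA $\Phi_{ST}$

Genetic differentiation between clades is the distance-based analysis of
molecular variance on squared p-distances. With $N$ sequences in $G$
groups of sizes $n_g$:

$$SS_{tot} = \tfrac{1}{N}\sum_{i<j} d_{ij}^2,\qquad
  SS_w = \sum_g \tfrac{1}{n_g}\sum_{i<j\in g} d_{ij}^2,\qquad
  SS_a = SS_{tot}-SS_w$$

$$\sigma_w^2 = \frac{SS_w}{N-G},\qquad
  \sigma_a^2 = \frac{SS_a/(G-1)-\sigma_w^2}{\bar n},\qquad
  \bar n = \frac{N-\sum_g n_g^2/N}{G-1},\qquad
  \Phi_{ST} = \frac{\sigma_a^2}{\sigma_a^2+\sigma_w^2}$$

Groups with fewer than two members are dropped with a warning (they carry
no within-group information). When all distances are zero the statistic is
undefined and returned as `NA` rather than an arbitrary value. Significance
comes from shuffling individuals among groups with group sizes held fixed.

## The permutation framework

All tests share one p-value convention:
$p = (\#\{T_{perm} \ge T_{obs}\} + 1)/(n_{perm}+1)$, so the smallest
reportable p at 1000 permutations is 0.001; ties count as exceedances
(conservative). A raw-proportion mode (`plus_one = FALSE`) exists for
comparison against exhaustive enumeration, which the tests perform on small
cases. All permutation results are bit-reproducible given `seed` and
`n_perm`, and observed statistics are computed before and independently of
the permutation stream.

**Between- vs within-clade divergence** (`test_bc_vs_wc`): the statistic is
$T = D_{bc}-D_{wc}$; individuals are shuffled among clade slots. Clades
with one member contribute between-pairs but no within-pairs, which
implements the rule that sub-2 groups carry no within-clade information.

**Northern-locality origin tests** (`northern_origin_test`): for northern
locality $i$ and a southern reference set, $D_i$ is the mean p-distance
between the locality's individuals and the reference individuals.
Individuals are shuffled among *locality* slots (locality sizes fixed);
clade labels follow localities through the locality-to-clade map — the
shuffling unit is the locality, and clades are recomputed as unions of
localities, which is the only reading under which between/within-clade
statistics remain defined during the shuffle. Two one-sided p-values
result: `p_bc` compares $(D_{bc}-D_i)$ and is small when $D_i$ sits
significantly *below* the between-clade level; `p_wc` compares
$(D_i-D_{wc})$ and is small when $D_i$ sits significantly *above* the
within-clade level. `classify_origin()` reads them at $\alpha = 0.05$:
`p_wc` non-significant → the locality is indistinguishable from a southern
pool (*recent expansion*); `p_wc` significant and `p_bc` non-significant →
the locality diverges like an independent clade (*in-situ* survival); both
significant → intermediate divergence, reported as *ambiguous*.

For phased nuclear data each individual contributes two haplotype rows.
The exchangeable unit is the **individual**: both rows travel together
during permutation (`individuals` argument / scheme field), avoiding
pseudo-replication.

`run_origin_battery()` runs every northern locality against the
all-southern set and against each contiguous-southern block it belongs to
(the default scheme compares the trans-Pyrenean locality with Iberia, the
west-Alpine localities with peninsular Italy, the Slovenian localities with
both Italy and the southern Balkans, and the central-Balkan localities with
the southern Balkans). The two reference families answer different
questions: the all-southern comparison measures divergence from the
species' southern pool at large, while the contiguous comparison is the
sharp instrument for the colonisation hypothesis — a recently expanded
locality is only expected to sit at within-clade distance from its *source*
region, not from every southern clade.

## The synthetic-data generator

`simulate_dataset()` emulates the study system: $K$ clades of haplotypes
with inter-clade divergence on the order of 1–7% and within-clade diversity
0.1–1.4%, unequal group sizes, optional missing data, and the two
contrasting histories for a flagged northern locality. Per locus:

* a root sequence is uniform over `A/C/G/T`;
* each clade ancestor mutates $k$ uniformly chosen sites of the root
  (uniform choice among the three alternative bases), with
  $k = \tfrac{3L}{4}\bigl(1-\sqrt{1-\tfrac{4d}{3}}\bigr)$ per branch
  (stochastically rounded) so that the **expected observed
  ancestor-to-ancestor p-distance equals the configured `d` exactly**,
  after correcting for the chance that both branches hit the same site.
  Conditioning on the substitution count rather than drawing per-site
  Bernoulli mutations is intentional: it removes realization variance in
  the inter-ancestor distances, so every replicate carries the configured
  divergence rather than a noisy draw around it. This matters for the
  origin tests — inter-ancestor realization noise is invisible to a
  permutation null (which only resamples individuals) and would otherwise
  make `p_bc` anticonservative on perfectly in-situ data;
* each individual receives $\mathrm{Poisson}(\theta L/2)$ point mutations
  from its clade ancestor (star genealogy), giving expected within-clade
  pairwise diversity $\approx \theta$;
* scenario modifiers: `panmixia` collapses every clade onto the root;
  `northern_recent_expansion` draws the northern locality's individuals
  from the designated source clade's pool (and the emitted sample table
  assigns them to that clade, as a phylogeny-based delimitation would);
  `northern_in_situ` gives the northern locality its own ancestor at
  divergence `d`;
* missing data are masked to `N` i.i.d. at `missing_rate`.

Defaults mirror the study conditions: `d = 0.03` (the combined-mtDNA
pooled between-clade mean was ≈ 0.035), `theta = 0.005` (pooled
within-clade mean ≈ 0.005), 1284 bp (the combined mtDNA length), and the
fixed `scenario_suite()` reproduces the study scale with 17 clades whose
sizes follow the per-clade sample sizes of the real data — except that the
two singleton clades are raised to two members so all 17 clades can enter
the variance analyses (the study excludes sub-2 clades); the suite
therefore holds 81 rather than 79 sequences.

**What the generator does not emulate.** Star genealogies have no
within-clade substructure: distances decompose additively into per-tip
mutation loads. Two consequences worth knowing. First, real panmictic
data (with coalescent genealogy) produce correlated distances; the star
model's null is *more* discrete. In particular, with perfectly equal group
sizes every individual appears in the same number of within-group pairs, so
$D_{wc}$ is nearly invariant under permutation and the between/within test
becomes extremely conservative — a degenerate corner, not a bug, and
irrelevant to the study system whose group sizes range from 2 to 28.
Calibration is therefore assessed on unequal pseudo-clades, where the test
holds its nominal level. Second, simulated clades are "cleaner" than real
ones (no internal geographic structure, no migration), so simulated
$\Phi_{ST}$ at the study scale (≈ 0.98) exceeds the study's observed values
(0.86/0.83); passing tests demonstrate correctness of the machinery, not
that real data will be as crisp.

## Numerical and design choices

* Distances live in exact integer arithmetic until the final division;
  matrix symmetry holds by construction.
* Undefined quantities (no resolved sites, no within-pairs, zero total
  variance) are `NA` flags propagated with warnings, never exceptions —
  except where an operation is meaningless (empty subsets, fewer than two
  clades), which raise typed conditions (`data_error`, `config_error`, ...).
* Internal column coordinates are 0-based half-open (`ranges` attribute of
  a concatenated alignment); FASTA ids are the header token up to the first
  whitespace; parsing is case-insensitive and maps `U` to `T`.
* Combined-mtDNA membership is the intersection of loci — specimens
  lacking a fragment are dropped, no `N`-padding — matching how the study's
  75-of-86 combined set arises from 82 cytb and 79 nd4 records.
* Region lists (which locality codes count as northern vs southern) are
  data, not code: `default_regions()` encodes the study's lists, a
  `region` column or YAML config overrides them, and unlisted localities
  are unassigned and excluded from origin tests.
* The rarefaction size $s$ excludes groups of 0 or 1; groups of exactly
  $s$ keep raw values (their only subset is the full set).
* Ties in permutation tests count as exceedances; with `plus_one = TRUE`
  (default) the attainable p-value floor is $1/(n_{perm}+1)$.

## Limitations

* No model-corrected distances (JC/K2P/TN) and no tree inference: the
  framework is deliberately distance-based and uncorrected.
* The simulator is not a coalescent: within-clade genealogies are stars,
  adequate for realizing a target $\pi$ and for testing the permutation
  machinery, but not for studying estimator variance under realistic
  genealogical correlation. A coalescent backend would slot in at
  `simulate_dataset()` without interface changes.
* Replicating the study's printed numbers requires the deposited sequences
  (GenBank accessions), which are not shipped; the package ships the
  specimen/locality/clade metadata and the full analysis path, so the
  replication is one FASTA download away (`run_pipeline()` with an
  `inputs:` block).
* Problem sizes in the test suite (e.g. 200 null datasets at 20 sequences,
  100 structured datasets at 24–30 sequences, permutation counts of
  400–10,000) were chosen to bound Monte-Carlo error at the level the
  assertions need; they are stated in the tests themselves.
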