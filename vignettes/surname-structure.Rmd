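---
title: "Surname isonymy, distance trees, and robustness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surname isonymy, distance trees, and robustness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`isonymia` analyses the population structure carried by surnames in a
double-surname census register: every resident contributes a paternal and
(usually) a maternal surname, which are treated as independent
single-surname *tokens*. From regional token frequencies the package
computes isonymy-based similarity coefficients, turns them into distance
matrices, builds neighbor-joining trees, and measures how robust the
resulting classification is. This vignette explains the model and the
choices behind each step.

```{r setup}
library(isonymia)
```

## Tokens, cutoffs, and frequencies

A roster record with surnames *Rodriguez Diaz* contributes two tokens
(`RODRIGUEZ`, `DIAZ`); a single-surname bearer contributes one. Surname
strings are canonicalised (uppercase, collapsed whitespace) with
diacritics preserved; an optional accent-stripping mode exists for
inconsistently digitised inputs, but no fuzzy matching is attempted —
misspellings are the data provider's problem, not something a frequency
analysis should guess at.

Two frequency cutoffs mirror how register extracts are typically
released and processed:

* **municipal cutoff** (default ≥ 5 bearers per municipality): registry
  offices anonymise rare surnames at the municipality level, so the
  pipeline reproduces that censoring on synthetic data; surviving counts
  are kept unchanged and censored cells become structural zeros;
* **global cutoff** (default: keep surnames with ≥ 20 occurrences
  nationwide, applied after aggregating municipalities to regions). The
  convention is *at or above* 20; the threshold is a parameter.

Both cutoffs barely disturb isonymy-type statistics, which weight
surnames by squared frequency: rare names carry almost no weight. The
relative frequency of surname $s$ in region $i$ is
$n_{si} = c_{si} / N_i$ with $N_i$ the region's token total.

## Similarity coefficients and distances

Between regions $i$ and $j$ the package computes:

* **isonymy** $I_{ij} = \sum_s n_{si} n_{sj}$, the probability that one
  token drawn in each region is the same surname; within a region,
  *random isonymy* $\sum_s n_{si}^2$ is the classical proxy for random
  inbreeding, and its plug-in form is used by default (the unbiased
  $\sum_s c_s(c_s-1)/(N(N-1))$ variant is available behind a flag — at
  census sample sizes the two are indistinguishable);
* **Hedrick's** $H_{ij} = I_{ij} / \tfrac12(I_{ii} + I_{jj})$
  (arithmetic-mean normalisation; *not* scale invariant, so it must be
  fed relative frequencies);
* **Nei's** $N_{ij} = I_{ij} / \sqrt{I_{ii} I_{jj}}$, the cosine of the
  two frequency vectors (scale invariant).

Distances are $d = -\log(\text{similarity})$. The logarithm base is a
parameter (natural log by default): it rescales all distances by a
common factor and therefore cannot change tree topologies or Mantel
correlations. A zero similarity (fully disjoint surname sets) maps to an
*infinite* distance, which is propagated as a flag; tree construction
refuses such matrices instead of silently capping them, because any cap
would be an arbitrary topological decision.

Surname **entropy** $-\sum_s n_{si}\log n_{si}$ (natural log) summarises
regional diversity from the other side: across regions it is strongly
anti-correlated with random isonymy.

## Neighbor joining

`neighbor_joining()` implements the standard agglomeration: join the
pair minimising $Q_{ij} = (n-2)d_{ij} - r_i - r_j$, assign limb lengths
by the usual formulas, reduce the matrix with
$d_{uk} = (d_{ik}+d_{jk}-d_{ij})/2$. Additive matrices are recovered
exactly. Two details are pinned down because they affect
reproducibility:

* **ties** on $Q$ are broken by joining the pair whose smallest-member
  labels sort first — runs are bit-for-bit deterministic;
* **negative limb lengths** are clamped to zero with the deficit
  transferred to the sister limb, preserving the pair's path length (a
  common convention for non-additive inputs).

## Bootstrap and noisy clustering

Surname classifications are notoriously unstable: many region pairs sit
at nearly equal distances, so small input changes flip clusters. Two
replicate generators probe this instability; both feed the same
NJ-plus-consensus machinery.

**Surname-type bootstrap** (`bootstrap_tables()`): each replicate draws
the $S$ surname *types* with replacement and multiplies each drawn
surname's count column by its multiplicity. This reweights surnames
rather than resampling tokens — with $N$ in the tens of millions,
token-level resampling would reproduce the same frequencies to five
digits and test nothing. Replicates whose distance matrix contains an
infinite entry are rejected, redrawn and counted; a corpus rejecting
more than half its replicates errors out as unstable.

**Noisy clustering** (`noisy_matrices()`): when only a distance matrix
is available (e.g. a dialectometric similarity matrix whose raw feature
data are unpublished), bootstrap is impossible. Instead each replicate
adds independent uniform noise $\varepsilon_{ij} \sim U(-a, a)$ with
$a = \text{noise level} \times \text{mean off-diagonal distance}$ to the
off-diagonal entries (symmetrically; clamped at zero; diagonal kept at
0). The noise level 0.5 is the conventional default; the cited method's
original run count is an internal parameter of that software, so here
the replicate count (default 100) is the explicit knob.

**Majority-rule consensus** (`majority_consensus()`): every nontrivial
bipartition is scored by the percentage of replicate trees containing
it (integer 0–100 regardless of replicate count) and retained at or
above the collapse cutoff — 50 by convention for bootstrap, 90 for noisy
clustering of linguistic matrices, whose structures are typically more
stable. At cutoffs ≥ 50 retained splits are automatically compatible;
below 50 they are admitted greedily by decreasing support. One subtlety:
replicate trees have their near-zero internal edges (tolerance 1e-10)
collapsed into polytomies *before* counting. Without this, a corpus of
regions with exactly identical frequency vectors would give the same
deterministically tie-broken binary tree in every replicate and
manufacture 100% support for arbitrary splits.

A caution on interpretation: bootstrap support measures the *stability*
of a split under surname reweighting, not its significance against a
no-structure null. A label-permuted corpus reliably loses all support
for genuine clades, but chance count correlations — fixed in the table —
can still yield some stable splits. Supports should be read as
robustness scores, never as p-values.

## Mantel tests and the representativeness regression

`mantel_test()` correlates the strictly-lower triangles of two labeled
distance matrices and assesses significance by jointly permuting the
rows and columns of the second matrix: two-sided, add-one convention
$p = (1 + \#\{|r^\ast| \ge |r|\})/(1 + \text{permutations})$, 9999
permutations by default, seeded. The permutation test is exact in level;
its type-I error at $\alpha = 0.05$ is verified by simulation in the
test suite.

`linear_regression()` is ordinary least squares with an intercept and an
optional label exclusion list. It reports both $R^2$ and adjusted
$R^2$: for the packaged province table, the published value of the
tokens-per-capita–on–municipalities fit corresponds to the adjusted
form (the slope p-value reproduces the published one exactly, which
pins down both the fixture and the fitted specification). Provinces
whose ratio collapses because their dominant municipality loses many
rare surnames to the municipal cutoff (the three largest agglomerations)
are excluded from the fit, as in the published analysis.

`riw_similarity()` is the dialectometric percent-agreement measure
(share of jointly observed items on which two varieties agree, 0–100);
`riw_to_distance()` rescales it to $[0,1]$ before complementing, so
linguistic distances are $1 - \text{RIW}/100$ — the literal $1 -
\text{RIW}$ on a percentage scale would produce distances in $[-99, 1]$.

## The synthetic scenario generator

Real census rosters cannot be redistributed, so every stage is exercised
on synthetic rosters with planted structure (`generate_scenario()`).
The generator emulates the features that matter for the analysis:

* **kingdom pools**: each of $K$ kingdoms (default 3, of 4 regions each)
  has its own surname pool with Zipf rank-frequency weights
  $w_r \propto r^{-1.5}$ (heavy-tailed surname abundance is a classic
  empirical regularity; the exponent is a parameter);
* **random mating**: paternal and maternal surnames are drawn
  independently;
* **migration** (default 5%): a native's surname draw comes, with this
  probability, from a uniformly chosen other kingdom;
* **castilianization** (default 0.2): pool merging. The minimal top
  prefix of rank slots covering a fraction `cast` of the pool's mass is
  replaced — identically in every kingdom — by prototype shared-pool
  names, with two rank slots compressed onto one shared name. Merging
  distinct common names onto the same prototypes is what drives
  diversity down (isonymy up, entropy down) monotonically in `cast`,
  erases between-kingdom distinctions as `cast` grows, and leaves rare
  local surnames in the tail — the historically plausible pattern, since
  normalisation pushed the same few prototypical surnames everywhere.
  Alternatives were considered and rejected: replacing a fraction of
  *draw mass* (a mixture) keeps every distinctive name at a scaled-down
  frequency, so the top names remain decisive cosine markers and
  kingdoms stay recoverable even at 95% castilianization, while mixing
  two disjoint pools first *raises* diversity mid-range; replacing
  random rank slots makes erasure a lottery over which kingdom happens
  to keep a top name.
* **immigrants** (default 11.3% of residents, matching the 2008 census
  share): drawn from a disjoint foreign pool; 66% of them carry a single
  surname (the census share of immigrants from single-surname
  countries), and a 34% "Latin-American overlap" carries native-style
  shared-pool surnames and is therefore undetectable by surname — the
  share of American-origin immigrants in the census composition table.

`generate_geography()` places kingdom centres 8° of longitude apart and
jitters regions within ±1°, so between-kingdom great-circle distances
always exceed within-kingdom ones; `generate_dialect_features()` builds
categorical survey items with one variant per kingdom plus a 5%
idiosyncratic deviation rate, giving the linguistic side of the analysis
a matrix with the same planted structure.

What the generator does *not* emulate: surname drift and extinction over
generations, realistic geography and road networks, municipality size
heterogeneity, or spelling variation. Passing tests therefore show that
the pipeline recovers planted structure of realistic strength and shape
— not that any particular real-world classification is correct.

### Reference conditions

The defaults are the package's study conditions and are used by the
tests, the analysis scripts, and `scripts/acceptance.R`: 3 kingdoms × 4
regions × 5 municipalities, 10,000 individuals per region (~231,000
tokens), pools of 200 surnames per kingdom plus 100 shared and 100
foreign names. Under them:

* the 100-replicate bootstrap NJ consensus of the Nei distance retains
  all three kingdom clades with support ≥ 90 (typically 100);
* at castilianization ≥ 0.95 no planted clade reaches support 50;
* mean random isonymy rises and mean entropy falls strictly
  monotonically over the castilianization grid {0, 0.25, 0.5, 0.75, 1}
  (measured on raw aggregated tables — the cutoffs censor rare
  distinctive names non-uniformly across the grid and would mask the
  generator's own response);
* surname distance and planted geography give Mantel $p \le 0.05$.

## Numerical choices and degenerate inputs

* All randomness flows from a single seed, split deterministically per
  stage; seeded runs are byte-identical.
* Frequency vectors must sum to 1 within 1e-8; all-zero vectors and
  negative entries are classed errors, not silent NaNs.
* NJ refuses matrices with non-finite entries, asymmetry above 1e-9, or
  fewer than 3 taxa; a 2-region bootstrap pipeline returns the trivial
  consensus directly.
* Consensus supports are integer percentages; a 2/3 split is 67.
* PHYLIP square matrices are written with 10 significant digits; Newick
  export stores consensus supports as internal node labels.

## Limitations

The published per-province isonymy and entropy values, the real
bootstrap trees, and the real Mantel table cannot be recomputed here:
they require the full individual-level register and the original
dialectometric matrix, neither of which is redistributable. The package
ships the published per-province summary table as a fixture and audits
every derived column of it; everything beyond that is validated on
synthetic data against planted ground truth, plus exact recovery checks
(additive matrices for NJ, closed-form similarity values, permutation
calibration for Mantel).
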