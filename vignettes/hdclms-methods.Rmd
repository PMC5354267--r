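---
title: "Models and methods behind hdclms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdclms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdclms)
```

This vignette explains the statistical model and the design choices in
`hdclms` the way a maintainer would want them written down: what is
assumed, which knobs matter, what the synthetic data does and does not
emulate, and where the genuinely open decisions were made.

## 1. The identification model

A cross-link search yields peptide-spectrum matches (PSMs): a spectrum, a
pair of peptides, link positions inside each peptide and therefore a pair
of protein positions, a score, and a decoy flag per peptide end. The
object of scientific interest is the **unique residue pair** — the two
linked protein positions — because that is what a distance restraint is.

Supporting PSM scores are aggregated with the root-sum-of-squares

$$\mathrm{score}_{\text{pair}} = \sqrt{\sum_i \mathrm{score}_{\mathrm{PSM},i}^2}.$$

Properties that matter: the aggregate is permutation-invariant, strictly
increasing in every support, never below the largest single support, and
stays on the PSM score scale. A plain sum-of-squares variant
(`method = "sum_sq"` in `aggregate_score()`) is rank-equivalent for a
fixed support set and is provided because the root is a convention, not a
necessity; we default to the root precisely because it preserves scale,
which makes score cut-offs comparable across levels.

### Target–decoy FDR

Matches are classed by their decoy flags: TT (both ends target), TD (one
decoy), DD (both decoy). For entities scoring at least $s$,

$$\widehat{\mathrm{FDR}}(s) = \frac{\max(0,\ \mathrm{TD}(s) - \mathrm{DD}(s))}{\mathrm{TT}(s)},$$

capped at 1, with $\widehat{\mathrm{FDR}} = 0$ when no targets remain.
The subtraction corrects for the fact that a random (false) match has two
chances to hit the decoy database: with a decoy database the same size as
the target, false matches distribute over TT : TD : DD as 1 : 2 : 1, so
$\mathrm{TD} - \mathrm{DD}$ estimates the number of false TT matches.
q-values are the running minimum of $\widehat{\mathrm{FDR}}$ over all
thresholds at or below an entity's score, which makes them non-increasing
in score. Entities tied on score are counted together at their shared
threshold; this places decoys before targets at that threshold, the
conservative convention.

**Hierarchical filtering.** `hierarchical_fdr()` applies an FDR-based
score cut-off at the PSM level, re-groups survivors into unique peptide
pairs and cuts again, then groups into residue pairs for the final FDR.
Pre-filter stages retain decoy matches above their cut-offs — without
them the next level could not estimate its own FDR. Removing low-score
noise before aggregation can *increase* the number of residue pairs
passing a given FDR, because noise PSMs inflate decoy-rich score strata;
`optimize_prefilters()` searches a grid (default
1, 0.5, 0.2, 0.1, 0.05, 0.01 at both levels) for the combination
maximizing accepted residue pairs, breaking ties toward least filtering.

## 2. The synthetic-data generator

The generator exists so that calibration claims can be tested against a
*known* truth. It emulates the study design this pipeline addresses: one
target protein per dataset, several LC-MS runs with partially overlapping
identifications, SDA chemistry (one link end at K/S/T/Y or the
N-terminus), and a 25 Å Cα–Cα linkability bound.

* **Structures.** Toy folds are built from ideal secondary-structure
  geometry: helices rise 1.5 Å/residue with a 100° twist on a 2.3 Å
  radius; strands rise 3.3 Å/residue with a zigzag offset chosen so the
  virtual Cα–Cα bond is exactly 3.8 Å; segments are connected by
  semicircular turns whose chords are also 3.8 Å, packing the chain into
  a compact serpentine. `round(unresolved_fraction * n)` randomly chosen
  residues keep their numbering but lose coordinates, matching PDB
  semantics for disordered residues.
* **Scores.** True PSMs draw from a Gaussian truncated at 0 with mean 12,
  SD 2; false and decoy PSMs from mean 6, SD 2. This overlap is
  deliberate: it makes FDR calibration non-trivial (a perfectly separable
  mixture would pass any estimator).
* **Decoys.** For every false target–target PSM the generator emits, in
  expectation, `decoy_ratio = 3` decoy-flagged PSMs split 2 : 1 between
  TD and DD. This reproduces the 1 : 2 : 1 TT : TD : DD proportion of a
  same-size decoy database, under which the estimator above is unbiased.
  We settled on this after working through the estimator's algebra: with
  decoys generated merely *equal in number* to false PSMs and split,
  say, 80/20, $E[\mathrm{TD} - \mathrm{DD}] = 0.6\,N_{\text{false}}$ and
  every nominal FDR would be understated by a factor 0.6. The ratio and
  split remain configurable for studying exactly such mis-specification.
* **Runs.** Each PSM is assigned to one run uniformly at random; run
  overlap at the residue-pair level emerges from pairs with several
  supporting PSMs. Per-run capture rates are a free parameter of the
  design, not calibrated to any dataset.

What the generator does **not** emulate: spectra, retention times,
charge states, site-assignment ambiguity (each reported position pair is
taken literally), inter-protein links, and the mass-dependent
detectability of long peptides. Passing tests on synthetic data therefore
demonstrate the *statistical* correctness of the pipeline, not the
behaviour of any particular spectrometer or search engine.

## 3. Structural validation

Accepted pairs are checked against a structure by Euclidean Cα–Cα
distance. The default bound is 25 Å — the distance at which observed
SDA-link distance distributions merge with random background — and is
configurable. Pairs with an unresolved end are a separate *unverifiable*
class and are excluded from the denominator of the over-bound
percentage (reported as not-determined when nothing is verifiable). The
null distribution for comparison is a uniform sample, with replacement,
of SDA-linkable resolved pairs; sampled rather than exhaustive so it
scales to large structures, exhaustive agreement being covered by tests.

PDB handling: first chain by default; alternate locations resolved by
highest occupancy (first record on ties); files with insertion codes are
rejected with an explicit error rather than silently renumbered;
sequence-to-structure mapping uses a single exact offset between author
numbering and the supplied sequence (gapped alignment is out of scope —
these are single-domain use cases).

## 4. Digestion and observability

Cleavage rules are classical: trypsin after K/R (blocked before proline
by default, switchable, since both conventions are in active use), Glu-C
after E (D optional). Co-digestion unions cleavage sites. A residue is
*theoretically observable* if it lies on at least one peptide, within the
missed-cleavage allowance (default 4), whose length falls in a window
defaulting to 5–45 residues. The window is a parameter, not a law of
nature: the lower end reflects minimum informative peptide length, the
upper end the practical limit for identifying cross-linked peptides by
MS. Counts of "inaccessible" residues should always be quoted together
with the window that produced them.

Reported densities use commercial rounding (half away from zero; two
decimals for links-per-residue, integer percentages), implemented with a
small epsilon so exact halves survive binary floating point. Region link
densities count a pair once if *either* end falls in the region (a
both-ends mode exists), because restraint coverage of a domain includes
links anchoring it to the rest of the protein.

## 5. Saturation analysis

`saturation_curve()` averages cumulative unique-pair counts over
permuted run orders: exhaustive over all $m!$ orders for $m \le 7$ runs
(exact expectation, no Monte Carlo noise), 100 sampled orders otherwise
(matching common practice). An independent analytic cross-check is
available: under a uniformly random order, an identification seen in $k$
of $m$ runs is covered after $r$ runs with probability
$1 - \binom{m-k}{r}/\binom{m}{r}$, and `expected_accumulation()` sums
this over identifications. The saturation flag compares the final
marginal gain against 1% of the total by default.

## 6. Secondary structure and accessibility

External per-residue annotations (two-column, DSSP-style codes collapsed
to E/H/C) are canonical. The built-in fallback (`assign_ss()`) works from
Cα geometry alone: windows $i \ldots i{+}3$ vote helix when the
Cα$_i$–Cα$_{i+3}$ distance is 5.0–6.5 Å and extended when 9.9–11.0 Å, and
a residue takes a label only with at least two concordant votes. The
extended band starts at 9.9 Å because tight-turn chords reach
9.2–9.8 Å and a wider band systematically mislabels loops as strand;
with ideal-geometry toys this assigner recovers the generator's β-residue
fraction to within ten percentage points, which is all it is for.

The unbiased expectation for β-contact among cross-linked pairs uses the
closed form $1 - \binom{n-b}{2}/\binom{n}{2}$ over all unordered pairs
(default), or exact enumeration over SDA-linkable pairs. The default
universe is all pairs because that is the conventional baseline quoted
alongside observed fractions; the linkable universe is the sharper null
and is what the package's own bias tests use.

RSA is computed by Shrake–Rupley-style dot sampling (960 deterministic
golden-spiral dots per atom by default, probe 1.4 Å) over heavy atoms
when present, normalized by theoretical Gly-X-Gly maximum accessibilities
shipped as a plain-text table (`inst/extdata/max_asa_theoretical.csv`) so
it is auditable and swappable. Cα-only structures fall back to one sphere
per residue whose radius is chosen so an isolated residue scores RSA 1
under the same normalization; results carry an `approximate` flag. Values
are capped at 1.5 (exposed termini can exceed 1). The fallback ranks
burial correctly on compact toys (core residues score lower than surface
residues) but is not a substitute for full-atom SASA on real structures.

## 7. Problem sizes and numerical conventions

The package's own validation uses synthetic datasets of 120–300 residues
with roughly 1 500–4 000 PSMs per dataset; FDR calibration is averaged
over 20 seeds at ≥ 2 000 scored entities per seed, where the realized
false fraction at nominal 5% FDR lands within two percentage points of
nominal. These sizes give stable statistics while keeping the whole suite
fast enough to run habitually; all quantitative claims above are
recomputed, not quoted, by the test suite and `scripts/acceptance.R`.

Degenerate inputs are defined rather than accidental: empty survivor sets
propagate as empty results with diagnostics; an all-unverifiable link set
reports a not-determined error percentage; zero-length regions and empty
annotations raise errors; all randomness flows from explicit seeds and
repeated calls are bit-identical.

## 8. Known limitations

* No site-assignment ambiguity model: nearby residue pairs are not
  collapsed before FDR, which can inflate unique-pair counts on real
  data.
* Single-chain, single-protein scope; no inter-protein or
  assembly-aware distance handling, and no solvent-accessible surface
  distance (Euclidean Cα–Cα only).
* The digestion model is about cleavage patterns and peptide lengths
  only — no mass, charge or retention modelling.
* The geometric secondary-structure assigner is a fallback for toys and
  smoke tests; use a hydrogen-bond-based assignment for real structures.
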