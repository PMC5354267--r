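# hdclms

Downstream analysis of **high-density cross-linking/mass spectrometry
(HD-CLMS)** identifications in R.

Photoactivatable cross-linkers such as sulfo-SDA react with lysine,
serine, threonine, tyrosine or the protein N-terminus on one end and with
any residue on the other, producing dense residue–residue distance
restraints (a Cα–Cα bound of ~25 Å) that can drive protein structure
modelling. Between the search engine's peptide-spectrum matches (PSMs)
and a usable restraint list sits a chain of analyses that this package
implements as tested, reusable functions:

* **Hierarchical target–decoy FDR** for cross-linked residue pairs:
  PSM-level and unique-peptide-pair-level score pre-filters followed by
  false-discovery-rate control at the unique-residue-pair level, with
  automatic pre-filter optimization.
* **Structural validation**: mapping accepted residue pairs onto crystal
  structures, Cα–Cα distances, classification against the 25 Å bound
  (within / over / unverifiable) and observed-versus-random distance
  distributions.
* **Saturation analysis**: accumulation of unique residue pairs over
  permuted LC-MS run orders (exact enumeration for few runs, Monte Carlo
  otherwise).
* **In-silico digestion**: trypsin / Glu-C cleavage, missed cleavages,
  and the set of residues theoretically observable under a peptide-length
  window — which explains uneven cross-link coverage along the sequence.
* **Secondary-structure and accessibility bias**: β-strand content of
  observed versus combinatorially expected residue pairs, K/R content by
  structure class, and relative solvent accessibility (RSA) from
  Shrake–Rupley-style dot sampling.
* A fully seeded **synthetic-data generator** (toy folds with ideal
  secondary-structure geometry, ground-truth links, scored target/decoy
  PSM tables with a known true/false mixture) so every stage is testable
  without external data.

## The statistics at the core

A unique residue pair (or peptide pair) aggregates its supporting PSM
scores as a root-sum-of-squares,

```
score_pair = sqrt( sum_i score_PSM,i^2 ),
```

so the aggregate stays on the PSM score scale, never falls below the best
supporting PSM, and grows with every additional observation. Matches are
classed TT/TD/DD by how many ends hit the decoy database, and the false
discovery rate among targets scoring at least `s` is estimated by the
classical cross-link estimator

```
FDR(s) = max(0, TD(s) - DD(s)) / TT(s),
```

with q-values taken as the running minimum over thresholds (entities tied
on score are counted together, decoys first). With a decoy database the
same size as the target database, false matches fall into TT : TD : DD
roughly as 1 : 2 : 1, which is exactly the proportion under which
`TD - DD` is an unbiased estimate of the false TT count — and the
proportion the synthetic generator reproduces.

## Worked example

```r
library(hdclms)

cfg <- synthetic_config(n_residues = 150, fold_spec = "mixed",
                        n_true_psms = 800, n_false_psms = 300,
                        n_runs = 4, seed = 42)
ds    <- simulate_dataset(cfg)
paths <- write_synthetic_bundle(ds, tempfile())

pc  <- pipeline_config(psm_table = paths[["psms"]], fasta = paths[["fasta"]],
                       pdb = paths[["pdb"]], ss_file = paths[["ss"]], seed = 1)
rep <- run_pipeline(pc)
print(rep)
#> HD-CLMS downstream analysis report
#> ----------------------------------
#>  fdr_level n_residue_pairs links_per_residue score_cutoff
#>       0.05             524              3.49     9.659739
#>       0.10             593              3.95     8.436302
#>       0.20             674              4.49     6.768113
#>
#> Distance validation (<= 25 A): 511 within, 13 over, 0 unverifiable (2% over)
#> Saturation: 4 runs, final mean 524.0 of 524 unique pairs
```

Reading the output: 524 unique residue pairs pass 5% FDR (3.49 links per
residue of the 150-residue toy protein); relaxing to 20% FDR admits 674.
Of the 524, only 2% exceed the 25 Å Cα–Cα bound when checked against the
structure the links were generated from — the accepted list is dominated
by genuine restraints, and the handful of over-bound pairs are the
accepted false identifications. The saturation curve
(`rep$saturation$mean_cumulative`, here 172 → 313 → 429 → 524) still
climbs at the last run, i.e. further acquisitions would keep adding
unique pairs. The bias block compares the β-strand content of observed
pairs (43%) with the unbiased combinatorial expectation (48.3%) computed
from the same annotation.

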