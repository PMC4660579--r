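---
title: "Detecting the histidine wafer interface motif in GST dimers"
author: "wafermotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the histidine wafer interface motif in GST dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wafermotif)
```

## The problem

Glutathione transferases (GSTs) are dimeric detoxication enzymes. In the
arthropod-specific Delta class, the two subunits are locked together by a
"clasp": equivalent residues from each subunit wrap around one another at
the dimer interface. Epsilon-class GSTs carry an extended version of this
arrangement — a *wafer* of four histidines, two contributed by each
subunit, stacked across the interface and buttressed by conserved serines.
The motif is not merely structural: its outer histidines sit in the
glutathione (GSH) binding sites, so the motif physically connects the two
active sites of the dimer.

`wafermotif` turns the structural analysis behind that observation into a
reusable, tested pipeline: given any coordinate file it detects interface
residues, classifies His–His stacking geometry, finds the clasp and its
flanking interactions, identifies the supporting serines, classifies
protein–GSH contacts by tripeptide moiety, measures whole-structure RMSD
against homologs, and reads per-column conservation out of a sequence
alignment, mapped onto author residue numbering.

## Geometric model and assumptions

All geometry is heavy-atom only. Deposited crystal structures at typical
resolution carry no meaningful hydrogen positions, so hydrogens are
dropped on read and no donor–H–acceptor angle is evaluated; a *polar
contact* is any N/O/S–N/O/S pair within the polar cutoff.

Aromatic rings are summarized by their centroid (unweighted mean of the
ring atoms: His imidazole `CG ND1 CE1 NE2 CD2`; Phe/Tyr phenyl; Trp
six-membered ring) and the least-squares plane normal (smallest principal
component of the centered ring coordinates). A pair of rings is classified
from three numbers — centroid separation $d$, interplanar angle
$\theta \in [0^\circ, 90^\circ]$ (folded, so normal sign never matters),
and the in-plane offset of one centroid from the other ring's axis:

* **parallel**: $d \le 4.5$ Å, $\theta \le 30^\circ$, offset $\le 2.0$ Å;
* **t-shaped**: $d \le 5.5$ Å, $\theta \ge 60^\circ$;
* **none** otherwise.

These stacking thresholds are standard literature geometry; they are this
package's choice (configurable through `wafer_params()`), since no
explicit stacking cutoffs accompany the original distance observations.

The motif detector then proceeds in three steps:

1. **Clasp**: among all cross-chain His–His pairs with a stacking class,
   pairs of *equivalent* residues (the same author number in both
   subunits) take precedence — that symmetry is the defining property of
   an interface clasp — and ring-centroid distance breaks ties.
2. **Flanks**: the remaining cross-chain His–His pairs involving a clasp
   histidine, accepted on either stacking evidence or any ring-nitrogen
   to ring-atom distance $\le 4.0$ Å. Both routes are admitted because the
   flank interaction is described in the literature without an explicit
   geometry.
3. **Supporting serines**: serines whose OG makes a polar contact
   ($\le 3.5$ Å) to a nitrogen or oxygen of any motif histidine. Support
   is evaluated from OG only, not the serine backbone.

Whether the motif *connects the two active sites* is decided on a contact
graph: nodes are the motif residues plus the two GSH ligands, edges are
stacking pairs and polar contacts; the question reduces to path existence
between the two ligands (delegated to igraph).

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `polar_cutoff` | 3.5 | Å | heavy-atom hydrogen-bond distance |
| `nonpolar_cutoff` | 4.0 | Å | C–C hydrophobic contact |
| `stack_parallel_dist` / `_angle` / `_offset` | 4.5 / 30 / 2.0 | Å / ° / Å | parallel stacking class |
| `stack_tshape_dist` / `_angle` | 5.5 / 60 | Å / ° | T-shaped class |
| `interface_cutoff` | 4.5 | Å | cross-chain residue contact |
| `flank_atom_cutoff` | 4.0 | Å | polar route for flank His–His |
| `domain_boundary` | 80 | author numbering | last N-terminal-domain residue |

The domain boundary separates the thioredoxin-like N-terminal domain from
the all-helical C-terminal domain when tagging GSH-contacting residues
("C-terminal domain interactors" such as an arginine on helix 4 are a
class-distinguishing feature). The GST fold fixes the architecture but
not a universal residue number, so the boundary defaults to 80 and should
be overridden per structure when the domain limits are known.

GSH atoms are partitioned by the standard chemical-component suffixes:
`*1` γ-glutamyl (`N1 CA1 C1 O11 O12 CB1 CG1 CD1 OE1`), `*2` cysteinyl
(`N2 CA2 C2 O2 CB2 SG2`), `*3` glycyl (`N3 CA3 C3 O31 O32`); every
protein–GSH contact lands in exactly one moiety group.

## Counting conventions

`count_atoms()` counts every atom record, including alternate-location
duplicates, matching the bookkeeping convention of refinement tables.
Geometry, by contrast, always uses a single conformer: the
highest-occupancy altloc, ties broken by altloc letter. Waters are
recognized by component id `HOH`/`WAT` only; `protein + water + hetero =
all` holds on every model. Author residue numbering is used everywhere
(it is what the literature's residue labels refer to), and only the first
model of a multi-model file is read.

## Superposition

`kabsch()` is the closed-form least-squares rotation fit; reflections are
excluded by the determinant correction, inputs with fewer than three
pairs or collinear geometry are rejected. `match_atoms()` produces the
atom pairing: `identity` matches by chain/number/name; `align` first
pairs chains by global sequence alignment (BLOSUM62, gap open 10, gap
extension 0.5 — pinned so pairing is reproducible) and then matches
common atom names within aligned residue pairs. Whole-structure RMSD is
computed over polymer heavy atoms with no outlier rejection — deliberately
simpler than viewers that iteratively prune, so the reported number is a
property of the structures, not of a pruning schedule. `motif_spread()`
superposes on motif Cα atoms and reports per-residue root-mean-square
side-chain deviation, the quantitative version of "sequence conservation
translates into side-chain position conservation".

## Conservation profiles

Per alignment column, with $f_i$ the residue frequencies over the $n$
non-gap letters:

$$H = -\sum_i f_i \log_2 f_i, \qquad
  R = \log_2 20 - \left(H + \frac{19}{2 n \ln 2}\right),$$

clamped at zero; letter heights are $f_i R$. This is the WebLogo
convention, including the small-sample correction $e_n$ (switchable).
Gap-only columns are reported as *missing*, not zero — an absent signal is
not the same as an unconserved one — and columns over half gaps are
flagged low-confidence. Column indices are 1-based throughout, the R
convention. `map_columns_to_structure()` aligns an alignment row to a
chain's observed sequence allowing terminal truncation (crystallized
constructs routinely lack termini) and tolerating a configurable number
of mismatches (default 0).

## The synthetic dimer: what it emulates and what it does not

`make_toy_dimer()` builds chain A explicitly and chain B as its exact
two-fold image, so the dimer has a crystallographic-style C2 axis. The
four imidazole rings are coaxial and parallel — a literal wafer: clasp
rings separated by 3.2 Å, each flank ring 3.4 Å from the partner clasp
ring. Each supporting serine's OG sits on an in-plane radial 2.55 Å from
a His ring nitrogen. A name-complete GSH decoy occupies each subunit's
site with its glutamyl carboxylate planted at hydrogen-bond distances:
OG–O11 = 2.9 Å, N–O11 = 3.0 Å, ND1–O12 ≈ 2.9 Å.

Distances sit deliberately at the short end of the physical range. The
generator's contract is that the planted motif stays detectable across
its supported noise range, so every planted contact needs a detection
margin of several standard deviations of the distance jitter; with
centroid-to-cutoff margins of 1.1–1.3 Å and hydrogen-bond margins of
~0.95 Å against a jitter of $\sigma\sqrt{2}$ per contact, full recovery
is effectively deterministic at $\sigma \le 0.15$ Å and clasp-level
detection remains so at $\sigma = 0.3$ Å.

Noise is applied to each residue (and each ligand and water) as a rigid
unit: an isotropic Gaussian displacement with standard deviation `sigma`
per coordinate. Rigid-unit noise mimics positional disorder while
preserving internal stereochemistry, as real coordinate uncertainty does.
Independent per-atom noise would instead tilt the 1.17 Å-radius imidazole
planes by ~9° RMS per ring at σ = 0.3 Å, randomly destroying the
interplanar-angle criterion for any planted geometry — a property of the
noise model, not of the detector. `make_homolog_ensemble()` is the
complement: it *does* apply i.i.d. per-atom, per-coordinate noise, which
is the right model for superposition calibration (base-vs-copy RMSD
$= \sigma\sqrt 3$, copy-vs-copy $= \sigma\sqrt 6$ in expectation).

Toy residues are chemically minimal but name-complete (full imidazole
rings, serine OG, the complete 20-atom GSH name set), because every
operation in the package consumes only names and coordinates. The
backbone is idealized: bond geometry is approximate, sterics are not
validated, the GSH conformer is not chemically valid, and filler glycines
sit on a distant spiral rather than forming a fold. Consequently, passing
synthetic tests demonstrates the *detectors and estimators* are correct
(geometry, classification, bookkeeping, calibration) — it does not
demonstrate robustness to real-data pathologies such as alternate
conformations of motif residues, missing side-chain atoms, or genuinely
ambiguous dimer pairings. Those paths are exercised separately (altloc
policy, incomplete-ring errors, multi-chain dimer selection), and the
accession-based checks below close the loop on real data.

```{r toy-example}
toy <- make_toy_dimer(dimer_spec(seed = 7))
detect_wafer_motif(toy$model, "A", "B")
```

## Numerical choices

* Ring normals are canonicalized toward positive z (first-atom direction
  on ties); every consumer treats normals as axial, so the sign never
  carries meaning.
* The interplanar angle uses `acos` of a clamped dot product; its
  precision near 0° is therefore ~`sqrt(.Machine$double.eps)` radians,
  which the tests respect.
* Clasp selection tie-break: symmetric (equivalent-residue) pairs first,
  then centroid distance, then residue number — deterministic under any
  input order, and stable under noise that can swap raw distances of
  near-equidistant pairs.
* Chain pairing for `align` is greedy on alignment score with a fixed
  substitution matrix and gap penalties; for a homodimer the two
  assignments are related by the dimer symmetry and give the same RMSD.
* Ligand-site ownership is the chain with minimum heavy-atom distance —
  a purely geometric criterion, invariant to chain relabeling.
* Exact frequency planting in `make_alignment()` uses largest-remainder
  apportionment, so requested 60/40-style columns are exact whenever
  $f \cdot n$ is integral.
* All generators take a required seed, restore the caller's RNG state,
  and are byte-reproducible.

## Reproducing measurements on deposited structures

The package ships no coordinate files. To rerun the deposited-structure
checks (atom bookkeeping 7120 protein / 979 water for the Epsilon
structure; the active-site distances Phe108 CE1–GSH CB1 = 3.5 Å and the
Ser68/His69 hydrogen-bond network; the Delta-class comparator Tyr106
CE2–GSH OE1 = 5.6 Å; the four-His/six-Ser motif; and the ~0.24 Å RMSD
over one dimer, ~2840 atoms, against the independently deposited
re-determination), download the entries (4YH2, 3MAK, 4PNF) as mmCIF into
`inst/extdata/accessions/` (lower-case names, e.g. `4yh2.cif`) and run
the test suite; the corresponding acceptance tests pick them up from
there. The exact atom set behind the published "2840 atoms" is not
recoverable from the text, so the pairing count is matched only to ±15%,
using the align policy over all common polymer heavy atoms of one dimer
with no outlier rejection.

## Problem sizes used by the automated experiments

The test suite and `scripts/acceptance.R` use: 50 replicate dimers per
noise level for detector operating characteristics (true-positive rate at
σ = 0.3 Å; false positives on motif-free decoys); 50 seeds at σ = 0.15 Å
for full clasp+flank+serine recovery; ≥1000-atom models for RMSD–noise
calibration at σ ∈ {0.1, 0.2, 0.5} Å (5% band around $\sigma\sqrt3$);
10^6-rotation quaternion grids for Kabsch optimality on 100 small
instances; 50 random models for the brute-force contact cross-check; and
columns of up to 2000 rows for the information-content formulas. These
sizes make every estimate's sampling error small against its acceptance
band.

## Known limitations

* No buried-surface-area or energetic characterization of the interface;
  contacts and stacking are purely distance/angle-based.
* No cation–π detection, although protonated histidine pairs could in
  principle interact that way.
* The HNE-substrate pocket is reported only as a residue listing around a
  probe (`pocket_residues()`), not by docking.
* Sequence alignments are consumed, never computed; phylogenetic
  weighting of alignment rows is not applied.
* `read.cif` support rests on bio3d's mmCIF reader; exotic mmCIF
  constructs may need conversion to PDB first.
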