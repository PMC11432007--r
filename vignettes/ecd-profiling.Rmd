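---
title: "Profiling Cys-loop receptor ECD fragments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling Cys-loop receptor ECD fragments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdprofiler)
```

## Scope and model

This package analyses extracellular-domain (ECD) fragments of pentameric
ligand-gated ion channel subunits — concretely the GABA-A receptor α1
(Gln28–Arg248 of UniProt P14867), β2 (Gln25–Gly243, P47870) and γ2
(Gln40–Gly273, P18507) constructs shipped in `inst/extdata` — and the
atomic structures (deposited cryo-EM entries or predicted pentamer
models) that contain them. Everything is organised around a *fragment
coordinate system*: position 1 is the first residue of the expressed
construct (a glutamine in all three subunits), and `numbering_map` /
`locate_fragment` translate between fragment coordinates and the author
numbering of any particular structure file. This indirection absorbs the
usual one-off discrepancies between numbering conventions (signal
peptide included or not): all landmark positions in this package are
fragment coordinates anchored at the stated origin residue, never at a
fixed offset.

### Sequence landmarks

Three conserved motifs are scanned with fixed patterns: `W.D` (WxD),
`W.PD` (WxPD) and `GYD`. Matching is exhaustive (overlaps allowed); when
a WxPD starts at the same tryptophan as a WxD, only the longer motif is
reported, so one Trp never yields two hits. In all three packaged
fragments the WxD and WxPD tryptophans are exactly 25 residues apart
(fragment 70/95, 67/92, 82/107); the γ2 fragment additionally contains
one chance `W.D` match (Trp134), which the landmark table resolves by
preferring the WxD whose Trp lies 25 before the WxPD Trp.

The Cys-loop is defined as the first cysteine pair with exactly 13
intervening residues — the canonical loop span in this receptor
superfamily; the sequences themselves never make the span ambiguous
(fragment 139/153, 136/150, 151/165). The ECD splits into its two
β-rich domains at the first loop cysteine (`two_domain_split`), and a
conserved tryptophan is checked 18 residues C-terminal of the second
cysteine.

One genuinely open point was which tyrosine to treat as the
"Cys-loop-packed" residue. The conserved GYD tripeptide (fragment
25/22/37) contains a tyrosine, but the tyrosine that actually packs
against the disulfide in the deposited structures is the one at fragment
60/57/72, whose conserved context is [ED]YT. The package therefore
configures the packed-Tyr position per subunit (defaults 60/57/72) and
treats GYD as an ordinary sequence motif; for unfamiliar fragments the
landmark table falls back to the GYD tyrosine, and callers can always
pass an explicit position.

### Aromatic geometry

All aromatic measurements go through pseudo-atoms. A ring centroid is
the unweighted mean of a fixed heavy-atom set; the default Trp
definition is `trp_indole9` (all nine indole ring atoms: CG, CD1, NE1,
CE2, CD2, CE3, CZ2, CZ3, CH2), with the six- and five-membered subrings
available (`trp_six`, `trp_five`) because centroid conventions differ
between visualisation tools. The Tyr ring is always the phenol six-ring.
The disulfide endpoint is the midpoint of the two SG atoms, which must
lie within 2.5 Å of each other to count as bonded. A π-stack or S–π
record carries a `within_contact` flag evaluated **strictly below** the
6.0 Å threshold — 6.00 Å itself is not a contact — because the
structural-contact rule is stated as "less than 6 Å".

### Hydrogen bonds

Interface hydrogen bonds are detected with heavy-atom geometric
criteria: every donor/acceptor pair across a chain–chain interface with
donor–acceptor distance ≤ 3.5 Å, where donors are backbone N (except
proline) plus the standard side-chain set (Arg NE/NH1/NH2, Lys NZ, Asn
ND2, Gln NE2, His ND1/NE2, Trp NE1, Ser OG, Thr OG1, Tyr OH) and
acceptors are backbone O/OXT plus Asp OD1/OD2, Glu OE1/OE2, Asn OD1,
Gln OE1, His ND1/NE2 and the hydroxyls. When the file contains an
explicit hydrogen bonded to the donor (within 1.3 Å), the D–H…A angle
must reach 120°; hydrogen-free models — the norm for cryo-EM and
predicted structures — are judged on distance alone. These are
deliberately permissive, Mills–Dean-style defaults; both cutoffs are
arguments. Bond sets from two structures are compared by their (donor
residue, acceptor residue) keys after mapping both to fragment
numbering.

### Distance tables

Per-structure, per-subunit distances aggregate into the summary block
mean / SEM / max / min, with SEM defined as the sample standard
deviation over √n and at least two values required per column. Printed
tables round distances to 0.01 Å; note that recomputing an SEM from
2-decimal cells can differ from an SEM computed on unrounded
measurements by up to about 0.002, which is why the bundled reference
tables agree with their published summary rows exactly on mean/max/min
but only to that bound on one SEM row.

### Hydropathy

Kyte–Doolittle profiles use unweighted sliding windows and report full
windows only (centres (w+1)/2 … n−(w−1)/2), the ProtScale plotting
convention. Window 7 is the surface/antigenicity setting used for the
ECD fragments; window 19 is the transmembrane setting, with the
conventional +1.6 threshold marking TM candidates (`tm_candidates`
returns maximal runs of centres at or above threshold). Two segment
summaries exist deliberately: `segment_mean` is the raw per-residue mean
over a range, while `profile_segment_mean` averages the windowed scores
whose centres fall in the range — the latter is what one reads off a
plotted profile, and for the TM1 segment of the extended α1 construct
the two differ substantially (≈1.47 raw versus ≈0.95 windowed), so
plot-derived reference values must be compared against the windowed
quantity.

### Secondary structure, superposition, density

`assign_ss` is a reduced Kabsch–Sander assigner: backbone H-bonds are
scored with the electrostatic energy
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol, the amide
hydrogen placed 1 Å from N anti-parallel to the preceding carbonyl, and
a bond called at E < −0.5. Helices are residues inside two consecutive
i→i+4 turns; strands are residues in parallel/antiparallel bridges;
everything else is coil. No 3₁₀/π helices, no turn/bend classes, and
bridges are intra-chain only — sufficient for H/E/C content summaries,
but β content will read slightly low on sheets that span chain
boundaries, and different assigners legitimately disagree by a few
percentage points.

`superpose` implements the Kabsch least-squares fit (SVD with reflection
correction, rotation determinant +1). The all-pairs RMSD is the headline
number; an optional matchmaker-style refinement iteratively drops pairs
further than 2.0 Å and refits, reporting the pruned RMSD alongside.
Pairings come from `ca_pairs_from_alignment`, which matches CA atoms
through a global sequence alignment.

`synthesize_density` follows the molmap convention: each atom
contributes an isotropic 3-D Gaussian with σ = 0.225 × resolution,
normalised to integrate to its atomic number, sampled on a cubic grid of
spacing resolution/3 padded 3σ beyond the bounding box. Map integrals
are therefore conserved across resolutions (to discretisation), which
the tests check at 1 %. `map_correlation` resamples one map onto the
other's grid by trilinear interpolation and reports the Pearson
correlation of overlapping voxels. Maps live as plain R arrays; no
CCP4/MRC file writer is provided.

## Alignment and identity conventions

`global_align` is a Needleman–Wunsch global alignment with affine gaps
under the EMBOSS defaults (BLOSUM62, open 10, extend 0.5; a gap of
length L costs 10 + 0.5·L), delegated to Biostrings; its optimality is
cross-checked in the tests against exhaustive enumeration of all
alignments of short sequences. Percent identity counts identical columns
over residue–residue columns only (the Clustal convention). Reference
identity values produced by progressive aligners (e.g. MAFFT) differ
from pairwise Needleman–Wunsch values by up to about 2 percentage
points, and comparisons in the tests use that band; on the packaged
fragments the α1–γ2 identity lands at 51.83 % with the published
ordering α1–γ2 > β2–γ2 > α1–β2. Fragment masses are sums of average
free-residue masses minus one water per peptide bond, reported
unrounded in kDa (the packaged fragments come to 25.5, 25.2 and
27.5 kDa).

## The synthetic-data generators

`make_motif_sequence` plants a WxD/WxPD pair at an exact Trp spacing, a
C-x13-C loop, an optional GYD, and an optional inserted segment
(emulating the γ2-like N-terminal insertion) into a uniform-random
background, returning all planted coordinates as ground truth. The
background is genuinely uniform over the 20 residues, so chance motif
matches and chance cysteine pairs can and do occur; detector tests
therefore compare against an independent full-sequence scan rather than
assuming only the planted hits exist. `make_planted_pentamer` builds a
C5-symmetric arrangement of identical chains carrying idealized rings
(planar, 1.39 Å bonds) whose centroid separations, disulfide-midpoint
distance, and interface donor–acceptor distances are exact by
construction (planted to ~1e-6 Å), plus a decoy donor/acceptor pair
beyond the detection cutoff. Fixed seeds give byte-identical FASTA/PDB
output.

What these fixtures do show: that every detector recovers planted
geometry exactly, respects its thresholds, and is invariant under rigid
motion. What they do not show: robustness to the messiness of real
data — missing atoms, alternate conformations, non-ideal ring geometry,
crystallographic/cryo-EM noise. The structure-level tests on real
deposited entries require the user to supply those files, since the
package bundles no coordinates beyond its synthetic fixtures.

## Numerical and degenerate-input choices

- Alternate locations: the highest-occupancy altloc is kept at read
  time; multi-model files keep model 1 only.
- Insertion codes ride along with author numbers; fragment numbering is
  gap-free and sequential.
- Waters and heteroatoms never enter the protein atom table (they are
  retained in metadata).
- Residues lacking backbone atoms, chains shorter than three residues,
  and CA-only traces are assigned coil rather than erroring.
- Ties in subunit assignment (two references equally close) are an
  error, not an arbitrary choice; chains under 30 % identity to every
  reference are labelled `unknown`.
- Degenerate requests error early with the offending name in the
  message: missing ring atoms, unbonded "disulfides" (S–S > 2.5 Å),
  empty alignment columns, SEM over fewer than two values, windows
  longer than the sequence or even-sized, superposition with fewer than
  three pairs.

## Problem sizes

The test suite runs entirely on generated fixtures: fragments of
150–270 residues, pentamer fixtures of 5 × 12 residues (~210 atoms),
density grids at 10–15 Å resolution, and brute-force alignment oracles
on sequences of up to six residues, chosen so the full suite completes
in seconds while still exercising every code path. The distance-table
aggregation runs on the bundled 8-structure reference tables.

## Known limitations

- The deposited cryo-EM entries must be supplied by the user; nothing is
  downloaded.
- Confidence metadata of predicted models (pLDDT in the B-factor column)
  is carried through but never recomputed, and any published numbers
  that depend on regenerating predicted models (confidence scores,
  model-derived distances and RMSDs, β-sheet content of predicted
  chains) are inherently run-dependent and are only checked as
  tolerance bands when such a model file is provided.
- The secondary-structure assigner is intra-chain and three-state.
- mmCIF reading uses author chain identifiers and numbering.
- No hydrogens are ever added; angle criteria apply only where the
  input file already contains them.
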