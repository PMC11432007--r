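# ecdprofiler

Sequence- and structure-level profiling of pentameric ligand-gated ion
channel (pLGIC) extracellular domains, built around the extracellular
domain (ECD) fragments of the human GABA-A receptor α1, β2 and γ2
subunits (UniProt P14867 Gln28–Arg248, P47870 Gln25–Gly243, P18507
Gln40–Gly273).

## The problem

pLGIC subunits assemble into pentamers whose ECDs carry a set of
conserved landmarks implicated in folding and assembly:

- a conserved tryptophan pair on the **WxD** and **WxPD** motifs, whose
  indole rings pack face-to-face; the package measures their separation
  as the distance between ring-centroid *pseudo-atoms*
  (`d = |c₁ − c₂|`, `cᵢ` the unweighted mean of the nine indole ring
  heavy atoms), with a strict `d < 6 Å` structural-contact rule;
- the **Cys-loop**, a disulfide-bonded C-x13-C pair, against which a
  conserved tyrosine packs (an S–π interaction), measured from the
  Tyr ring centroid to the S–S bond midpoint;
- a conserved Trp 18 residues C-terminal of the second loop cysteine,
  and a two-domain split of the ECD at the first loop cysteine.

Around those measurements the package provides the standard supporting
analyses: Needleman–Wunsch percent-identity matrices (BLOSUM62, affine
gaps 10/0.5), Kyte–Doolittle hydropathy profiles (windows 7 and 19,
+1.6 transmembrane rule), inter-chain hydrogen-bond detection
(heavy-atom D–A ≤ 3.5 Å, D–H…A ≥ 120° when hydrogens exist), per-subunit
distance tables with mean / SEM (sample SD/√n) / max / min aggregation,
a reduced Kabsch–Sander H/E/C secondary-structure assigner, Kabsch
least-squares superposition with optional 2 Å matchmaker-style pruning,
and simulated density maps (per-atom Gaussians, σ = 0.225 × resolution)
for comparing models against low-resolution EM shapes. A synthetic-data
module generates sequences and C5 pentamers with *planted, exactly known*
motifs and distances so the whole pipeline is testable without any
downloads.

It is aimed at structural biologists and bioinformaticians who work with
Cys-loop receptor ECD constructs, predicted pentamer models, and
deposited cryo-EM structures.

## Worked example

```r
library(ecdprofiler)

fr <- ecd_fragments()
scan_motifs(fr$alpha1)
#>   motif start matched
#> 1   GYD    25     GYD
#> 2   WxD    70     WKD
#> 3  WxPD    95    WTPD

find_cys_loop(fr$alpha1)
#> <cys_loop> Cys139-Cys153 (13 intervening residues)

round(identity_matrix(fr), 2)
#>        alpha1  beta2 gamma2
#> alpha1 100.00  37.04  51.83
#> beta2   37.04 100.00  37.96
#> gamma2  51.83  37.96 100.00

aggregate_distances(published_distance_tables("trp_pair"))
#> <distance_table> (Angstroms)
#> ...
#> Max               6.02  5.90  5.99
#> Min               5.73  5.66  5.87
#> Average (± SEM)   5.95 (±0.0334)  5.77 (±0.0309)  5.92 (±0.0161)
```

The motif scan places the conserved Trp pair at fragment positions
70/95 (α1), always 25 residues apart across the three subunits; the
identity matrix shows α1–γ2 as the closest pair (51.83 %); and the
aggregated Trp–Trp ring-centroid distances of the eight deposited
structures all fall at or just below the 6 Å contact threshold.

On a structure (deposited entry or predicted model file):

```r
s <- read_structure("model.pdb")
assign_subunits(s)                  # chains -> alpha1/beta2/gamma2 by identity
measure_trp_pairs(s)                # WxD/WxPD ring-centroid distance per subunit
measure_tyr_cysloop(s)              # Tyr centroid to Cys-loop S-S midpoint
run_report(structures = "model.pdb", out_dir = "report")  # full TSV bundle
```

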