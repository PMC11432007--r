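## Amino-acid constants shared across modules.

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values on the Kyte-Doolittle scale, from +4.5
#' (Ile, most hydrophobic) to -4.5 (Arg, most hydrophilic). Named by
#' one-letter amino-acid code.
#'
#' @format Named numeric vector of length 20.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

## average (isotope-averaged) masses of the free amino acids, Da
.aa_avg_mass <- c(
  G =  75.07, A =  89.09, S = 105.09, P = 115.13, V = 117.15,
  T = 119.12, C = 121.16, L = 131.17, I = 131.17, N = 132.12,
  D = 133.10, Q = 146.15, K = 146.19, E = 147.13, M = 149.21,
  H = 155.15, F = 165.19, R = 174.20, Y = 181.19, W = 204.23
)
.water_mass <- 18.02

.aa1 <- names(kyte_doolittle)

.aa_3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.aa_1to3 <- stats::setNames(names(.aa_3to1), unname(.aa_3to1))

## ring pseudo-atom definitions (heavy-atom names)
.ring_defs <- list(
  trp_indole9 = list(resid = "TRP",
                     atoms = c("CG", "CD1", "NE1", "CE2", "CD2",
                               "CE3", "CZ2", "CZ3", "CH2")),
  trp_six     = list(resid = "TRP",
                     atoms = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  trp_five    = list(resid = "TRP",
                     atoms = c("CG", "CD1", "NE1", "CE2", "CD2")),
  tyr_six     = list(resid = "TYR",
                     atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
)

## heavy-atom hydrogen-bond donors/acceptors per residue type.
## Backbone N is a donor for every residue except proline; backbone O
## (and OXT) is always an acceptor.  Hydroxyls act as both.
.hb_sidechain_donors <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1", SER = "OG", THR = "OG1", TYR = "OH"
)
.hb_sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH"
)

## atomic numbers for density synthesis
.element_z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

.validate_residue_string <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), .aa1)
  if (length(bad) > 0L) {
    stop(what, " contains non-standard letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}
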