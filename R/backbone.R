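## Internal-coordinate peptide backbone construction (used by the
## synthetic generators and secondary-structure fixtures).

#' Place an atom from internal coordinates
#'
#' Natural extension reference frame (NeRF) placement: returns the position
#' of atom D given the three preceding atoms A-B-C, the C-D bond length,
#' the B-C-D bond angle, and the A-B-C-D torsion.
#'
#' @param a,b,c length-3 coordinates of the three reference atoms.
#' @param length C-D bond length (Angstroms).
#' @param angle B-C-D angle (degrees).
#' @param torsion A-B-C-D dihedral (degrees).
#' @return Length-3 numeric position of D.
#' @export
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an ideal peptide backbone
#'
#' Constructs an N/CA/C/O backbone with standard bond lengths and angles at
#' the requested phi/psi torsions (omega fixed trans). Useful for generating
#' ideal helices (phi = -57, psi = -47) and strands (phi = -139, psi = 135)
#' with exactly known geometry.
#'
#' @param n number of residues.
#' @param phi,psi backbone torsions in degrees (recycled to length `n`).
#' @param chain chain id for the result.
#' @param resid residue name used for every residue.
#' @return An [ecd_structure()] with `n` residues of N, CA, C, O atoms.
#' @export
build_backbone <- function(n, phi = -57, psi = -47, chain = "A",
                           resid = "ALA") {
  stopifnot(n >= 1)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCaC <- 111.0; a_CaCN <- 116.2; a_CNCa <- 121.7; omega <- 180
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCa, 0, 0)
  th <- (180 - a_NCaC) * pi / 180
  C[1, ] <- CA[1, ] + b_CaC * c(cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         b_CN, a_CaCN, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          b_NCa, a_CNCa, omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         b_CaC, a_NCaC, phi[i])
  }
  for (i in seq_len(n)) {
    if (i < n) {
      ## sp2 carbonyl: O opposite the CA/N(i+1) bisector
      u <- C[i, ] - CA[i, ]; u <- u / sqrt(sum(u^2))
      v <- C[i, ] - N[i + 1, ]; v <- v / sqrt(sum(v^2))
      w <- u + v; w <- w / sqrt(sum(w^2))
      O[i, ] <- C[i, ] + b_CO * w
    } else {
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_CO, 120.8,
                           psi[i] + 180)
    }
  }
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = chain, resno = i, insert = "", resid = resid,
               elety = c("N", "CA", "C", "O"),
               elesy = c("N", "C", "C", "O"),
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               stringsAsFactors = FALSE)
  }))
  ecd_structure(atoms, metadata = list(source_format = "synthetic"))
}

## rigid-motion helpers shared by generators and tests
.rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

#' Apply a rigid motion to a structure
#'
#' @param s an [ecd_structure()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return The transformed structure.
#' @export
transform_structure <- function(s, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rotation)
  s$atoms$x <- xyz[, 1] + translation[1]
  s$atoms$y <- xyz[, 2] + translation[2]
  s$atoms$z <- xyz[, 3] + translation[3]
  s
}
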