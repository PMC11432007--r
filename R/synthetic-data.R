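## Seeded synthetic fixtures with planted, exactly-known ground truth.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a sequence with planted conserved motifs
#'
#' A uniform-random background sequence carrying a WxD/WxPD tryptophan
#' pair at an exact spacing, a Cys-loop (C-x13-C), a GYD tripeptide, and
#' optionally an inserted segment (emulating the gamma2-like N-terminal
#' insertion). All planted coordinates are returned as ground truth;
#' background positions may still produce chance motif matches, so
#' detector tests should compare against a full regular-expression scan.
#'
#' @param length background length before insertion.
#' @param wxd fragment position of the WxD tryptophan.
#' @param spacing offset from the WxD Trp to the WxPD Trp.
#' @param cys1 position of the first Cys-loop cysteine (second is
#'   `cys1 + 14`).
#' @param gyd position of the GYD glycine, or `NA` to omit.
#' @param insertion_pos,insertion_length optional inserted random segment
#'   (the insertion point must not split a planted motif).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return List with `sequence` (a [fragment_sequence()]), `base`
#'   (the sequence without the insertion, or `NULL`), and `truth`
#'   (planted coordinates, on `sequence`'s numbering).
#' @export
make_motif_sequence <- function(length = 200L, wxd = 30L, spacing = 25L,
                                cys1 = 120L, gyd = 60L,
                                insertion_pos = NA, insertion_length = 0L,
                                seed = 1L) {
  wxpd <- wxd + spacing
  spans <- list(WxD = c(wxd, wxd + 2L), WxPD = c(wxpd, wxpd + 3L),
                cys_loop = c(cys1, cys1 + 14L))
  if (!is.na(gyd)) spans$GYD <- c(gyd, gyd + 2L)
  for (sp in spans) if (sp[1] < 1L || sp[2] > length)
    stop("planted motif extends outside the sequence", call. = FALSE)
  for (i in seq_along(spans)) for (j in seq_along(spans)) {
    if (i < j && spans[[i]][1] <= spans[[j]][2] &&
        spans[[j]][1] <= spans[[i]][2])
      stop("planted motifs overlap: ", names(spans)[i], " and ",
           names(spans)[j], call. = FALSE)
  }
  .with_seed(seed, {
    ch <- sample(.aa1, length, replace = TRUE)
    filler <- function(n) sample(setdiff(.aa1, c("W", "C", "D", "P")), n,
                                 replace = TRUE)
    ch[wxd:(wxd + 2L)] <- c("W", filler(1), "D")
    ch[wxpd:(wxpd + 3L)] <- c("W", filler(1), "P", "D")
    ch[cys1] <- "C"; ch[cys1 + 14L] <- "C"
    if (!is.na(gyd)) ch[gyd:(gyd + 2L)] <- c("G", "Y", "D")
    base <- paste(ch, collapse = "")
    shift <- 0L
    inserted <- base
    if (!is.na(insertion_pos) && insertion_length > 0L) {
      for (sp in spans) if (insertion_pos > sp[1] && insertion_pos <= sp[2])
        stop("insertion point splits a planted motif", call. = FALSE)
      seg <- paste(sample(.aa1, insertion_length, replace = TRUE),
                   collapse = "")
      inserted <- paste0(substr(base, 1, insertion_pos - 1L), seg,
                         substr(base, insertion_pos, nchar(base)))
      shift <- as.integer(ifelse(c(wxd, wxpd, cys1, gyd) >= insertion_pos,
                                 insertion_length, 0L))
    } else shift <- c(0L, 0L, 0L, 0L)
    truth <- list(wxd = as.integer(wxd + shift[1]),
                  wxpd = as.integer(wxpd + shift[2]),
                  trp_positions = as.integer(c(wxd + shift[1],
                                               wxpd + shift[2])),
                  spacing = as.integer(spacing),
                  cys_loop = as.integer(c(cys1 + shift[3],
                                          cys1 + 14L + shift[3])),
                  gyd = if (is.na(gyd)) NA else as.integer(gyd + shift[4]),
                  insertion = if (is.na(insertion_pos)) NULL else
                    c(pos = insertion_pos, length = insertion_length))
    list(sequence = fragment_sequence("synthetic", inserted),
         base = if (identical(base, inserted)) NULL else
           fragment_sequence("synthetic_base", base),
         truth = truth)
  })
}

## ideal planar rings (1.39 A bonds), centred at the origin, normal +z
.ideal_hexagon <- function(names6) {
  th <- (0:5) * 60 * pi / 180
  m <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  rownames(m) <- names6
  m
}

.ideal_indole <- function() {
  hexnames <- c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")  # 60..360 deg
  th <- (1:6) * 60 * pi / 180
  hex <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  rownames(hex) <- hexnames
  ## fused pentagon on the CD2-CE2 edge, outside the hexagon
  rp <- 1.39 / (2 * sin(36 * pi / 180))        # pentagon circumradius
  ap <- 1.39 / (2 * tan(36 * pi / 180))        # apothem
  mid <- (hex["CE2", ] + hex["CD2", ]) / 2
  p0 <- mid + c(0, ap, 0) * sign(mid[2])
  angs <- c(NE1 = 18, CD1 = 90, CG = 162) * pi / 180
  pent <- t(vapply(angs, function(a) p0 + rp * c(cos(a), sin(a), 0),
                   numeric(3)))
  m <- rbind(hex, pent)
  sweep(m, 2, colMeans(m))   # centre the 9-atom centroid at the origin
}

.ring_atoms_df <- function(chain, resno, resid, ring, center,
                           elesy_override = NULL) {
  m <- sweep(ring, 2, center, "+")
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = rownames(m),
             elesy = if (is.null(elesy_override))
               substr(gsub("[0-9]", "", rownames(m)), 1, 1) else elesy_override,
             x = m[, 1], y = m[, 2], z = m[, 3], stringsAsFactors = FALSE)
}

.atom_df <- function(chain, resno, resid, elety, elesy, pos) {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, elesy = elesy,
             x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
}

#' Generate a C5-symmetric pentamer with planted interactions
#'
#' Builds `n_chains` identical chains arranged with C-n symmetry about the
#' z axis. Each chain carries two idealized tryptophan indole rings whose
#' 9-atom centroids are separated by exactly `pi_distance`, a tyrosine
#' ring and bonded cysteine pair whose ring-centroid-to-disulfide-midpoint
#' distance is exactly `s_pi_distance`, one donor/acceptor atom pair per
#' adjacent chain interface at exactly `hbond_distance`, one decoy
#' donor/acceptor pair at `decoy_distance`, and a short poly-Ala filler.
#' All planted distances are exact to numerical precision and returned as
#' ground truth.
#'
#' @param n_chains number of chains (5 for C5).
#' @param radius placement radius from the symmetry axis, Angstroms.
#' @param pi_distance planted Trp-Trp centroid separation.
#' @param s_pi_distance planted Tyr-centroid-to-disulfide-midpoint
#'   distance.
#' @param hbond_distance planted donor-acceptor distance (within bonding
#'   range).
#' @param decoy_distance planted decoy donor-acceptor distance (beyond the
#'   detection cutoff in margin-respecting specs).
#' @param seed stored in metadata; the construction is deterministic.
#' @return List with `structure` (an [ecd_structure()]) and `truth`
#'   (data.frames `pi_pairs`, `s_pi`, `hbonds`, `decoys`).
#' @export
make_planted_pentamer <- function(n_chains = 5L, radius = 20,
                                  pi_distance = 5.85, s_pi_distance = 4.5,
                                  hbond_distance = 2.9,
                                  decoy_distance = 4.2, seed = 1L) {
  stopifnot(n_chains >= 2L, pi_distance > 0, s_pi_distance > 0,
            hbond_distance > 0, decoy_distance > 0)
  step <- 360 / n_chains
  chains <- LETTERS[seq_len(n_chains)]
  indole <- .ideal_indole()
  hexR <- .ideal_hexagon(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
  c1 <- c(radius, -4, 0)
  c2 <- c1 + c(0, 0, pi_distance)
  c3 <- c(radius + 4, 4, 0)
  mid <- c3 + c(s_pi_distance, 0, 0)
  sg1 <- mid + c(0, -1.015, 0); sg2 <- mid + c(0, 1.015, 0)
  v_acc <- as.numeric(.rotz(step / 2) %*% c(radius, 0, -6))
  u_don <- as.numeric(.rotz(-step) %*% (v_acc + c(0, 0, hbond_distance)))
  v_acc2 <- as.numeric(.rotz(step / 2) %*% c(radius + 6, 0, -6))
  u_don2 <- as.numeric(.rotz(-step) %*% (v_acc2 + c(0, 0, decoy_distance)))
  template <- rbind(
    .ring_atoms_df("A", 1L, "TRP", indole, c1),
    .ring_atoms_df("A", 2L, "TRP", indole, c2),
    .ring_atoms_df("A", 3L, "TYR", hexR, c3),
    .atom_df("A", 4L, "CYS", "SG", "S", sg1),
    .atom_df("A", 5L, "CYS", "SG", "S", sg2),
    .atom_df("A", 6L, "GLY", "N", "N", u_don),
    .atom_df("A", 7L, "ALA", "O", "O", v_acc),
    .atom_df("A", 8L, "GLY", "N", "N", u_don2),
    .atom_df("A", 9L, "ALA", "O", "O", v_acc2),
    do.call(rbind, lapply(10:12, function(r) {
      base <- c(radius, -8 + 2 * (r - 10), 9)
      rbind(.atom_df("A", r, "ALA", "N", "N", base),
            .atom_df("A", r, "ALA", "CA", "C", base + c(0.8, 0.8, 0.5)),
            .atom_df("A", r, "ALA", "C", "C", base + c(1.6, 0, 1.0)),
            .atom_df("A", r, "ALA", "O", "O", base + c(1.6, -1.2, 1.0)))
    }))
  )
  atoms <- do.call(rbind, lapply(seq_len(n_chains), function(k) {
    R <- .rotz(step * (k - 1))
    m <- as.matrix(template[, c("x", "y", "z")]) %*% t(R)
    out <- template
    out$chain <- chains[k]
    out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
    out
  }))
  s <- ecd_structure(atoms, metadata = list(source_format = "synthetic",
                                            symmetry = paste0("C", n_chains),
                                            seed = seed))
  nxt <- c(chains[-1], chains[1])
  truth <- list(
    pi_pairs = data.frame(chain = chains, resno_a = 1L, resno_b = 2L,
                          distance = pi_distance, stringsAsFactors = FALSE),
    s_pi = data.frame(chain = chains, tyr_resno = 3L, cys1_resno = 4L,
                      cys2_resno = 5L, distance = s_pi_distance,
                      stringsAsFactors = FALSE),
    hbonds = data.frame(donor_chain = nxt, donor_resno = 6L,
                        acceptor_chain = chains, acceptor_resno = 7L,
                        distance = hbond_distance, stringsAsFactors = FALSE),
    decoys = data.frame(donor_chain = nxt, donor_resno = 8L,
                        acceptor_chain = chains, acceptor_resno = 9L,
                        distance = decoy_distance, stringsAsFactors = FALSE)
  )
  list(structure = s, truth = truth)
}
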