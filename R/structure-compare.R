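## Secondary-structure content, alignment-guided superposition, and
## Gaussian density synthesis for model-versus-EM shape comparison.

#' Assign secondary structure (reduced Kabsch-Sander)
#'
#' Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
#' energy `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol,
#' with the amide hydrogen inferred from backbone geometry (1 Angstrom from
#' N, anti-parallel to the preceding carbonyl); a bond is called when
#' `E < -0.5`. Helices (H) are residues inside consecutive i+4 turns;
#' strands (E) are residues in parallel or antiparallel bridges; all else,
#' including residues lacking backbone atoms and chains of fewer than three
#' residues, is coil (C). A reduced assigner: no 3-10/pi helices, no turn
#' or bend classes, intra-chain bridges only.
#'
#' @param s an [ecd_structure()].
#' @return Named list (one element per chain) of per-residue labels
#'   `H`/`E`/`C` named by author residue number; class `ss_assignment`.
#' @export
assign_ss <- function(s) {
  out <- lapply(chain_ids(s), function(cc) .assign_ss_chain(s, cc))
  names(out) <- chain_ids(s)
  class(out) <- "ss_assignment"
  out
}

.assign_ss_chain <- function(s, cc) {
  at <- s$atoms[s$atoms$chain == cc, , drop = FALSE]
  res <- unique(at[, c("resno", "insert")])
  n <- nrow(res)
  labels <- rep("C", n)
  names(labels) <- paste0(res$resno, res$insert)
  if (n < 3L) return(labels)
  get_bb <- function(i, name) {
    r <- at[at$resno == res$resno[i] & at$insert == res$insert[i] &
              at$elety == name, , drop = FALSE]
    if (nrow(r) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(r$x[1], r$y[1], r$z[1])
  }
  Nm <- t(vapply(seq_len(n), get_bb, numeric(3), name = "N"))
  CAm <- t(vapply(seq_len(n), get_bb, numeric(3), name = "CA"))
  Cm <- t(vapply(seq_len(n), get_bb, numeric(3), name = "C"))
  Om <- t(vapply(seq_len(n), get_bb, numeric(3), name = "O"))
  ok <- stats::complete.cases(Nm) & stats::complete.cases(CAm) &
    stats::complete.cases(Cm) & stats::complete.cases(Om)
  ## amide H: 1 A from N, anti-parallel to previous C=O
  Hm <- matrix(NA_real_, n, 3)
  resid_of <- vapply(seq_len(n), function(i)
    at$resid[at$resno == res$resno[i] & at$insert == res$insert[i]][1], "")
  for (i in 2:n) {
    if (ok[i] && ok[i - 1] && resid_of[i] != "PRO") {
      v <- Cm[i - 1, ] - Om[i - 1, ]
      Hm[i, ] <- Nm[i, ] + v / sqrt(sum(v^2))
    }
  }
  ## donor i (N-H) -> acceptor j (C=O) energy
  hb <- matrix(FALSE, n, n)
  don <- which(ok & stats::complete.cases(Hm))
  acc <- which(ok)
  for (i in don) for (j in acc) {
    if (abs(i - j) < 2L) next
    rON <- .dist3(Nm[i, ], Om[j, ]); rCH <- .dist3(Cm[j, ], Hm[i, ])
    rOH <- .dist3(Om[j, ], Hm[i, ]); rCN <- .dist3(Cm[j, ], Nm[i, ])
    if (min(rON, rCH, rOH, rCN) < 0.5) next   # clashing/degenerate
    E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    if (E < -0.5) hb[i, j] <- TRUE
  }
  turn4 <- function(i) i >= 1 && i + 4 <= n && hb[i + 4, i]
  for (i in seq_len(n)) {
    if (turn4(i) && i + 1 <= n && turn4(i + 1)) {
      labels[(i + 1):(i + 4)] <- "H"
    }
  }
  hbond <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 3L) next
    par <- (hbond(i - 1, j) && hbond(j, i + 1)) ||
      (hbond(j - 1, i) && hbond(i, j + 1))
    anti <- (hbond(i, j) && hbond(j, i)) ||
      (hbond(i - 1, j + 1) && hbond(j - 1, i + 1))
    if (par || anti) {
      if (labels[i] != "H") labels[i] <- "E"
      if (labels[j] != "H") labels[j] <- "E"
    }
  }
  labels
}

#' Beta-strand content of a chain
#'
#' @param ss an [assign_ss()] result.
#' @param chain chain id.
#' @return Percent of residues labelled `E`, to 1 decimal.
#' @export
beta_content <- function(ss, chain) {
  if (!chain %in% names(ss)) stop("chain '", chain, "' not in assignment",
                                  call. = FALSE)
  v <- ss[[chain]]
  if (length(v) == 0L) stop("chain '", chain, "' is empty", call. = FALSE)
  round(100 * mean(v == "E"), 1)
}

#' Secondary-structure composition summary
#'
#' @param ss an [assign_ss()] result.
#' @return data.frame with per-chain residue counts and percent H/E/C.
#' @export
ss_summary <- function(ss) {
  do.call(rbind, lapply(names(ss), function(cc) {
    v <- ss[[cc]]
    data.frame(chain = cc, n_residues = length(v),
               pct_helix = round(100 * mean(v == "H"), 1),
               pct_strand = round(100 * mean(v == "E"), 1),
               pct_coil = round(100 * mean(v == "C"), 1),
               stringsAsFactors = FALSE)
  }))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation/translation of `mobile` onto `fixed` over paired
#' coordinates, by singular value decomposition with reflection correction.
#' Optionally iterates matchmaker-style pruning: pairs further apart than
#' `prune_cutoff` after fitting are dropped and the fit repeated, with the
#' pruned RMSD reported alongside the all-pairs RMSD (the headline value).
#'
#' @param fixed,mobile n x 3 coordinate matrices, row i of one paired with
#'   row i of the other; at least 3 pairs.
#' @param prune_cutoff pruning distance in Angstroms, or `NA` to skip.
#' @param max_iter maximum pruning iterations.
#' @return List of class `superposition`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd_all_pairs`, `n_pairs`, and when pruning ran,
#'   `rmsd_pruned` and `n_pruned`.
#' @export
superpose <- function(fixed, mobile, prune_cutoff = NA, max_iter = 10L) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  if (!all(dim(fixed) == dim(mobile)) || ncol(fixed) != 3L)
    stop("fixed and mobile must be equal-sized n x 3 matrices", call. = FALSE)
  if (nrow(fixed) < 3L)
    stop("need at least 3 paired positions", call. = FALSE)
  fit <- .kabsch(fixed, mobile)
  moved <- sweep(mobile %*% t(fit$R), 2, fit$t, "+")
  d <- sqrt(rowSums((moved - fixed)^2))
  out <- list(rotation = fit$R, translation = fit$t,
              rmsd_all_pairs = sqrt(mean(d^2)), n_pairs = nrow(fixed))
  if (!is.na(prune_cutoff)) {
    keep <- rep(TRUE, nrow(fixed))
    for (it in seq_len(max_iter)) {
      drop <- keep & (d > prune_cutoff)
      if (!any(drop) || sum(keep) - sum(drop) < 3L) break
      keep[drop] <- FALSE
      fit <- .kabsch(fixed[keep, , drop = FALSE], mobile[keep, , drop = FALSE])
      moved <- sweep(mobile %*% t(fit$R), 2, fit$t, "+")
      d <- sqrt(rowSums((moved - fixed)^2))
    }
    out$rotation <- fit$R; out$translation <- fit$t
    out$rmsd_pruned <- sqrt(mean(d[keep]^2))
    out$n_pruned <- sum(keep)
  }
  class(out) <- "superposition"
  out
}

.kabsch <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cf - R %*% cm))
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, RMSD (all pairs) %.3f A",
              x$n_pairs, x$rmsd_all_pairs))
  if (!is.null(x$rmsd_pruned))
    cat(sprintf("; %.3f A over %d retained pairs", x$rmsd_pruned, x$n_pruned))
  cat("\n")
  invisible(x)
}

#' Alignment-derived CA atom pairing of two chains
#'
#' Globally aligns the two chain sequences and pairs the CA atoms of
#' residues matched in residue-residue columns, for use with
#' [superpose()].
#'
#' @param s_a,s_b [ecd_structure()] objects.
#' @param chain_a,chain_b chain ids.
#' @return List with matrices `a` and `b` (paired CA coordinates) and the
#'   number of pairs `n`.
#' @export
ca_pairs_from_alignment <- function(s_a, chain_a, s_b, chain_b) {
  qa <- chain_sequence(s_a, chain_a); qb <- chain_sequence(s_b, chain_b)
  al <- global_align(qa, qb)
  ga <- strsplit(al$gapped_a, "")[[1]]; gb <- strsplit(al$gapped_b, "")[[1]]
  ia <- cumsum(ga != "-"); ib <- cumsum(gb != "-")
  both <- ga != "-" & gb != "-"
  ca_of <- function(s, cc, resno, insert) {
    at <- s$atoms[s$atoms$chain == cc & s$atoms$elety == "CA", , drop = FALSE]
    i <- match(paste(resno, insert), paste(at$resno, at$insert))
    cbind(at$x[i], at$y[i], at$z[i])
  }
  ra <- attr(qa, "resno")[ia[both]]; ja <- attr(qa, "insert")[ia[both]]
  rb <- attr(qb, "resno")[ib[both]]; jb <- attr(qb, "insert")[ib[both]]
  A <- ca_of(s_a, chain_a, ra, ja); B <- ca_of(s_b, chain_b, rb, jb)
  keep <- stats::complete.cases(A) & stats::complete.cases(B)
  list(a = A[keep, , drop = FALSE], b = B[keep, , drop = FALSE],
       n = sum(keep))
}

#' Synthesize a Gaussian density map from a structure
#'
#' Sum of per-atom isotropic 3-D Gaussians with sigma = 0.225 x resolution
#' and amplitude proportional to atomic number (each atom integrates to its
#' atomic number), sampled on a cubic grid padded 3 sigma beyond the atom
#' bounding box - the molmap convention for simulating a map at a target
#' resolution.
#'
#' @param s an [ecd_structure()] (must contain atoms).
#' @param resolution target resolution in Angstroms.
#' @param spacing grid spacing in Angstroms (default `resolution / 3`).
#' @return List of class `density_map`: `origin`, `spacing`, `values`
#'   (3-D array), `resolution`.
#' @export
synthesize_density <- function(s, resolution, spacing = resolution / 3) {
  at <- s$atoms
  if (nrow(at) == 0L) stop("empty structure", call. = FALSE)
  stopifnot(resolution > 0, spacing > 0)
  sigma <- 0.225 * resolution
  pad <- 3 * sigma
  z <- .element_z[toupper(at$elesy)]
  if (anyNA(z)) {
    warning("unknown element(s) ",
            paste(unique(at$elesy[is.na(z)]), collapse = ", "),
            "; treating as carbon", call. = FALSE)
    z[is.na(z)] <- 6
  }
  gx <- seq(min(at$x) - pad, max(at$x) + pad, by = spacing)
  gy <- seq(min(at$y) - pad, max(at$y) + pad, by = spacing)
  gz <- seq(min(at$z) - pad, max(at$z) + pad, by = spacing)
  vals <- array(0, dim = c(length(gx), length(gy), length(gz)))
  amp <- z / ((2 * pi)^1.5 * sigma^3)
  for (k in seq_len(nrow(at))) {
    ex <- exp(-((gx - at$x[k])^2) / (2 * sigma^2))
    ey <- exp(-((gy - at$y[k])^2) / (2 * sigma^2))
    ez <- exp(-((gz - at$z[k])^2) / (2 * sigma^2))
    vals <- vals + amp[k] * (ex %o% ey %o% ez)
  }
  structure(list(origin = c(gx[1], gy[1], gz[1]), spacing = spacing,
                 values = vals, resolution = resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s grid, spacing %.2f A, resolution %.1f A, integral %.1f\n",
              paste(dim(x$values), collapse = "x"), x$spacing, x$resolution,
              map_integral(x)))
  invisible(x)
}

#' Integral of a density map
#'
#' @param map a [synthesize_density()] result.
#' @return `sum(values) * spacing^3`; with atomic-number-normalised
#'   Gaussians this approximates the total atomic number of the model.
#' @export
map_integral <- function(map) sum(map$values) * map$spacing^3

#' Resample a density map onto another map's grid
#'
#' Trilinear interpolation of `map` at the voxel centres of `grid_of`;
#' points outside `map` become `NA`.
#'
#' @param map,grid_of [synthesize_density()] results.
#' @return A `density_map` on `grid_of`'s grid.
#' @export
resample_map <- function(map, grid_of) {
  dims <- dim(grid_of$values)
  ax <- grid_of$origin[1] + (seq_len(dims[1]) - 1) * grid_of$spacing
  ay <- grid_of$origin[2] + (seq_len(dims[2]) - 1) * grid_of$spacing
  az <- grid_of$origin[3] + (seq_len(dims[3]) - 1) * grid_of$spacing
  sd_ <- dim(map$values)
  interp1 <- function(coord, origin, nmax) {
    u <- (coord - origin) / map$spacing
    i0 <- floor(u)
    list(i0 = i0, w = u - i0, ok = i0 >= 0 & i0 <= nmax - 2)
  }
  X <- interp1(ax, map$origin[1], sd_[1])
  Y <- interp1(ay, map$origin[2], sd_[2])
  Z <- interp1(az, map$origin[3], sd_[3])
  vals <- array(NA_real_, dims)
  for (i in seq_len(dims[1])) {
    if (!X$ok[i]) next
    for (j in seq_len(dims[2])) {
      if (!Y$ok[j]) next
      for (k in seq_len(dims[3])) {
        if (!Z$ok[k]) next
        i0 <- X$i0[i] + 1L; j0 <- Y$i0[j] + 1L; k0 <- Z$i0[k] + 1L
        wx <- X$w[i]; wy <- Y$w[j]; wz <- Z$w[k]
        c00 <- map$values[i0, j0, k0] * (1 - wx) + map$values[i0 + 1, j0, k0] * wx
        c10 <- map$values[i0, j0 + 1, k0] * (1 - wx) + map$values[i0 + 1, j0 + 1, k0] * wx
        c01 <- map$values[i0, j0, k0 + 1] * (1 - wx) + map$values[i0 + 1, j0, k0 + 1] * wx
        c11 <- map$values[i0, j0 + 1, k0 + 1] * (1 - wx) + map$values[i0 + 1, j0 + 1, k0 + 1] * wx
        vals[i, j, k] <- (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
          (c01 * (1 - wy) + c11 * wy) * wz
      }
    }
  }
  structure(list(origin = grid_of$origin, spacing = grid_of$spacing,
                 values = vals, resolution = map$resolution),
            class = "density_map")
}

#' Real-space correlation of two density maps
#'
#' Pearson correlation over overlapping voxels; `b` is resampled onto
#' `a`'s grid when the grids differ.
#'
#' @param a,b [synthesize_density()] results.
#' @return Correlation in `[-1, 1]`.
#' @export
map_correlation <- function(a, b) {
  same_grid <- all(dim(a$values) == dim(b$values)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing))
  vb <- if (same_grid) as.numeric(b$values)
        else as.numeric(resample_map(b, a)$values)
  va <- as.numeric(a$values)
  keep <- !is.na(vb)
  va <- va[keep]; vb <- vb[keep]
  if (length(va) < 2L || stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("map correlation undefined (zero variance or no overlap)",
         call. = FALSE)
  stats::cor(va, vb)
}
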