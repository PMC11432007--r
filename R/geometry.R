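## Ring-centroid pseudo-atoms, aromatic interaction distances, interface
## hydrogen bonds, and distance-table aggregation.

.res_atoms <- function(s, chain, resno, insert = "") {
  at <- s$atoms[s$atoms$chain == chain & s$atoms$resno == resno &
                  s$atoms$insert == insert, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no residue ", resno, insert, " in chain '", chain, "'",
         call. = FALSE)
  at
}

.atom_xyz <- function(at, name) {
  row <- at[at$elety == name, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  c(row$x[1], row$y[1], row$z[1])
}

.dist3 <- function(p, q) sqrt(sum((p - q)^2))

#' Aromatic ring centroid pseudo-atom
#'
#' Unweighted mean position of a residue's ring heavy atoms. Available ring
#' definitions: `"trp_indole9"` (all nine indole ring atoms, the default
#' used for Trp-Trp stacking), `"trp_six"`, `"trp_five"`, and `"tyr_six"`
#' (the tyrosine phenol ring).
#'
#' @param s an [ecd_structure()].
#' @param chain,resno,insert residue address (author numbering).
#' @param ring_def ring definition name.
#' @return List of class `pseudo_atom`: `position` (length-3, Angstroms),
#'   `definition`, and the source residue address.
#' @export
ring_centroid <- function(s, chain, resno, ring_def = "trp_indole9",
                          insert = "") {
  def <- .ring_defs[[ring_def]]
  if (is.null(def)) stop("unknown ring definition '", ring_def, "'",
                         call. = FALSE)
  at <- .res_atoms(s, chain, resno, insert)
  if (at$resid[1] != def$resid)
    stop("residue ", chain, ":", resno, " is ", at$resid[1], ", not ",
         def$resid, " as required by '", ring_def, "'", call. = FALSE)
  rows <- at[match(def$atoms, at$elety), , drop = FALSE]
  miss <- def$atoms[is.na(rows$x)]
  if (length(miss) > 0L)
    stop("residue ", chain, ":", resno, " is missing ring atom(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(position = c(mean(rows$x), mean(rows$y), mean(rows$z)),
                 definition = ring_def,
                 chain = chain, resno = resno, insert = insert,
                 resid = at$resid[1]),
            class = "pseudo_atom")
}

#' @export
print.pseudo_atom <- function(x, ...) {
  cat(sprintf("<pseudo_atom> %s %s %s:%d at (%.3f, %.3f, %.3f)\n",
              x$definition, x$resid, x$chain, x$resno,
              x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

.interaction_record <- function(kind, chain_a, resno_a, chain_b, resno_b,
                                distance, contact_threshold) {
  data.frame(kind = kind, chain_a = chain_a, resno_a = resno_a,
             chain_b = chain_b, resno_b = resno_b,
             distance = distance,
             within_contact = distance < contact_threshold,
             stringsAsFactors = FALSE)
}

#' Trp-Trp pi-stacking distance
#'
#' Euclidean distance between the ring centroids of two tryptophans, with
#' the structural-contact call made against a strict `< threshold` rule
#' (6 Angstroms by default).
#'
#' @param s an [ecd_structure()].
#' @param chain_a,resno_a,chain_b,resno_b the two Trp residues.
#' @param ring_def ring definition (see [ring_centroid()]).
#' @param contact_threshold contact distance in Angstroms.
#' @return One-row data.frame: `kind = "pi_stack"`, residue addresses,
#'   `distance`, `within_contact`.
#' @export
pi_stack_distance <- function(s, chain_a, resno_a, chain_b, resno_b,
                              ring_def = "trp_indole9",
                              contact_threshold = 6.0) {
  if (identical(chain_a, chain_b) && identical(resno_a, resno_b))
    stop("the two residues must be distinct", call. = FALSE)
  ca <- ring_centroid(s, chain_a, resno_a, ring_def)
  cb <- ring_centroid(s, chain_b, resno_b, ring_def)
  .interaction_record("pi_stack", chain_a, resno_a, chain_b, resno_b,
                      .dist3(ca$position, cb$position), contact_threshold)
}

#' Disulfide-bond midpoint pseudo-atom
#'
#' Midpoint of the two SG atoms of a bonded cysteine pair.
#'
#' @param s an [ecd_structure()].
#' @param chain1,resno1,chain2,resno2 the two cysteines.
#' @param max_ss maximum SG-SG separation still treated as bonded.
#' @return A `pseudo_atom` (`definition = "disulfide_midpoint"`).
#' @export
disulfide_midpoint <- function(s, chain1, resno1, chain2, resno2,
                               max_ss = 2.5) {
  a1 <- .res_atoms(s, chain1, resno1)
  a2 <- .res_atoms(s, chain2, resno2)
  for (at in list(a1, a2)) if (at$resid[1] != "CYS")
    stop("disulfide endpoints must be CYS (got ", at$resid[1], ")",
         call. = FALSE)
  s1 <- .atom_xyz(a1, "SG"); s2 <- .atom_xyz(a2, "SG")
  if (is.null(s1) || is.null(s2))
    stop("cysteine missing its SG atom", call. = FALSE)
  d <- .dist3(s1, s2)
  if (d > max_ss)
    stop(sprintf("SG-SG separation %.2f A exceeds %.2f A: not disulfide-bonded",
                 d, max_ss), call. = FALSE)
  structure(list(position = (s1 + s2) / 2, definition = "disulfide_midpoint",
                 chain = chain1, resno = resno1, insert = "",
                 resid = "CYS"),
            class = "pseudo_atom")
}

#' Tyr-ring to Cys-loop disulfide (S-pi) distance
#'
#' Distance from a tyrosine's phenol-ring centroid to the midpoint of the
#' Cys-loop disulfide bond.
#'
#' @param s an [ecd_structure()].
#' @param tyr_chain,tyr_resno the packed tyrosine.
#' @param cys_chain,cys1_resno,cys2_resno the Cys-loop cysteine pair.
#' @param contact_threshold contact distance in Angstroms.
#' @return One-row data.frame (`kind = "s_pi"`).
#' @export
s_pi_distance <- function(s, tyr_chain, tyr_resno,
                          cys_chain, cys1_resno, cys2_resno,
                          contact_threshold = 6.0) {
  ty <- ring_centroid(s, tyr_chain, tyr_resno, "tyr_six")
  mid <- disulfide_midpoint(s, cys_chain, cys1_resno, cys_chain, cys2_resno)
  .interaction_record("s_pi", tyr_chain, tyr_resno, cys_chain, cys1_resno,
                      .dist3(ty$position, mid$position), contact_threshold)
}

.hb_atoms <- function(at_chain, role) {
  tab <- if (role == "donor") .hb_sidechain_donors else .hb_sidechain_acceptors
  res <- unique(at_chain[, c("resno", "insert", "resid")])
  unknown <- setdiff(unique(res$resid), .aa_protein3)
  if (length(unknown) > 0L)
    warning("skipping residues of unknown type: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  keep <- logical(nrow(at_chain))
  bb <- if (role == "donor") "N" else c("O", "OXT")
  keep <- at_chain$elety %in% bb & at_chain$resid %in% .aa_protein3
  if (role == "donor") keep <- keep & at_chain$resid != "PRO"
  for (rr in names(tab)) {
    keep <- keep | (at_chain$resid == rr & at_chain$elety %in% tab[[rr]])
  }
  at_chain[keep, , drop = FALSE]
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect inter-chain hydrogen bonds
#'
#' Heavy-atom geometric criteria across one chain-chain interface: every
#' donor/acceptor pair (fixed per-residue donor and acceptor tables;
#' backbone N and O plus the standard side-chain sets) with donor-acceptor
#' distance at most `max_da`. When an explicit hydrogen bonded to the donor
#' is present in the file, the D-H...A angle must also reach `min_angle`;
#' hydrogen-free models (the cryo-EM/predicted-model norm) are judged on
#' distance alone.
#'
#' @param s an [ecd_structure()].
#' @param chain_a,chain_b distinct chain ids.
#' @param max_da donor-acceptor heavy-atom distance cutoff, Angstroms.
#' @param min_angle minimum D-H...A angle in degrees (applied only when a
#'   donor hydrogen exists).
#' @return data.frame sorted by donor residue number: donor and acceptor
#'   chain/residue/atom columns, `distance`, `angle` (`NA` without H),
#'   `kind = "hbond"`.
#' @export
detect_hbonds <- function(s, chain_a, chain_b, max_da = 3.5,
                          min_angle = 120) {
  if (identical(chain_a, chain_b))
    stop("chains must be distinct", call. = FALSE)
  at <- s$atoms
  A <- at[at$chain == chain_a, , drop = FALSE]
  B <- at[at$chain == chain_b, , drop = FALSE]
  one_direction <- function(don, acc, dchain, achain) {
    D <- .hb_atoms(don, "donor"); Ac <- .hb_atoms(acc, "acceptor")
    if (nrow(D) == 0L || nrow(Ac) == 0L) return(NULL)
    dx <- outer(D$x, Ac$x, "-"); dy <- outer(D$y, Ac$y, "-")
    dz <- outer(D$z, Ac$z, "-")
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    hit <- which(dist <= max_da, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    recs <- lapply(seq_len(nrow(hit)), function(k) {
      i <- hit[k, 1]; j <- hit[k, 2]
      ang <- NA_real_
      ## explicit hydrogen on the donor, if any
      dres <- don[don$resno == D$resno[i] & don$insert == D$insert[i], ,
                  drop = FALSE]
      hyd <- dres[dres$elesy == "H", , drop = FALSE]
      if (nrow(hyd) > 0L) {
        dpos <- c(D$x[i], D$y[i], D$z[i])
        hd <- sqrt((hyd$x - dpos[1])^2 + (hyd$y - dpos[2])^2 +
                     (hyd$z - dpos[3])^2)
        hyd <- hyd[hd < 1.3, , drop = FALSE]
        if (nrow(hyd) > 0L) {
          apos <- c(Ac$x[j], Ac$y[j], Ac$z[j])
          angs <- vapply(seq_len(nrow(hyd)), function(m)
            .angle_deg(dpos, c(hyd$x[m], hyd$y[m], hyd$z[m]), apos), 0)
          ang <- max(angs)
          if (ang < min_angle) return(NULL)
        }
      }
      data.frame(kind = "hbond",
                 donor_chain = dchain, donor_resno = D$resno[i],
                 donor_resid = D$resid[i], donor_atom = D$elety[i],
                 acceptor_chain = achain, acceptor_resno = Ac$resno[j],
                 acceptor_resid = Ac$resid[j], acceptor_atom = Ac$elety[j],
                 distance = dist[i, j], angle = ang,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  }
  out <- rbind(one_direction(A, B, chain_a, chain_b),
               one_direction(B, A, chain_b, chain_a))
  if (is.null(out))
    return(data.frame(kind = character(), donor_chain = character(),
                      donor_resno = integer(), donor_resid = character(),
                      donor_atom = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_resid = character(),
                      acceptor_atom = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE))
  out <- out[order(out$donor_resno, out$acceptor_resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two hydrogen-bond sets
#'
#' Partitions bond records by their (donor residue, acceptor residue) key
#' into shared bonds and bonds unique to either set. Callers should supply
#' records whose residue numbers are on a common (fragment) numbering.
#'
#' @param set_a,set_b data.frames as returned by [detect_hbonds()] (only
#'   `donor_resno` and `acceptor_resno` are required).
#' @return List with `shared`, `only_a`, `only_b` (data.frames of unique
#'   residue-pair keys).
#' @export
compare_bond_sets <- function(set_a, set_b) {
  keyify <- function(d) {
    if (nrow(d) == 0L) return(d[, intersect(c("donor_resno", "acceptor_resno"),
                                            names(d)), drop = FALSE])
    unique(d[, c("donor_resno", "acceptor_resno"), drop = FALSE])
  }
  ka <- keyify(set_a); kb <- keyify(set_b)
  sa <- paste(ka$donor_resno, ka$acceptor_resno)
  sb <- paste(kb$donor_resno, kb$acceptor_resno)
  list(shared = ka[sa %in% sb, , drop = FALSE],
       only_a = ka[!(sa %in% sb), , drop = FALSE],
       only_b = kb[!(sb %in% sa), , drop = FALSE])
}

#' Aggregate per-structure distances into a distance table
#'
#' Builds the per-subunit summary block used for aromatic-distance tables:
#' column means, standard errors (sample SD over the square root of n),
#' maxima and minima.
#'
#' @param cells data.frame or matrix of distances; rows are structures
#'   (row names or a `PDB ID` column), columns subunits.
#' @return List of class `distance_table`: `cells`, `mean`, `sem`, `max`,
#'   `min` (each named by subunit).
#' @export
aggregate_distances <- function(cells) {
  df <- as.data.frame(cells)
  idcol <- which(names(df) %in% c("PDB ID", "pdb_id", "structure"))
  ids <- if (length(idcol) > 0) as.character(df[[idcol[1]]]) else rownames(df)
  if (length(idcol) > 0) df <- df[, -idcol[1], drop = FALSE]
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("distance cells must be numeric", call. = FALSE)
  rownames(m) <- ids
  ns <- colSums(!is.na(m))
  if (any(ns < 2L))
    stop("column(s) ", paste(colnames(m)[ns < 2L], collapse = ", "),
         " have fewer than 2 values: SEM undefined", call. = FALSE)
  structure(list(cells = m,
                 mean = colMeans(m, na.rm = TRUE),
                 sem = apply(m, 2, function(v)
                   stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
                 max = apply(m, 2, max, na.rm = TRUE),
                 min = apply(m, 2, min, na.rm = TRUE)),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("<distance_table> (Angstroms)\n")
  print(round(x$cells, 2))
  cat("Max              ", paste(sprintf("%.2f", x$max), collapse = "  "), "\n")
  cat("Min              ", paste(sprintf("%.2f", x$min), collapse = "  "), "\n")
  cat("Average (± SEM)  ",
      paste(sprintf("%.2f (±%s)", x$mean, signif(x$sem, 3)), collapse = "  "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.distance_table <- function(x, ...) {
  cells <- as.data.frame(x$cells)
  agg <- rbind(Max = x$max, Min = x$min, `Average` = x$mean, SEM = x$sem)
  out <- rbind(cells, as.data.frame(agg))
  cbind(`PDB ID` = rownames(out), out, row.names = NULL)
}
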