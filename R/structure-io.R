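#' Atomic structure container
#'
#' A light hierarchical container for a protein structure: a flat atom table
#' ordered by chain and residue, plus free-form metadata. Protein chains
#' only; heteroatoms and waters read from files are kept in
#' `metadata$het` rather than in the atom table.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer author
#'   number), `insert` (insertion code, `""` when absent), `resid`
#'   (3-letter residue name), `elety` (atom name), `elesy` (element
#'   symbol), `x`, `y`, `z` (Angstroms), and optionally `o` (occupancy)
#'   and `b` (B-factor or model confidence).
#' @param metadata named list; `source_format` is filled by
#'   [read_structure()].
#' @return Object of class `ecd_structure`.
#' @export
ecd_structure <- function(atoms, metadata = list()) {
  req <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L) stop("atoms is missing columns: ",
                              paste(miss, collapse = ", "), call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite", call. = FALSE)
  if (any(!nzchar(atoms$elesy)))
    stop("every atom needs a non-empty element symbol", call. = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$insert)) atoms$insert <- character(n)
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$o)) atoms$o <- rep(1, n)
  if (is.null(atoms$b)) atoms$b <- rep(0, n)
  atoms$resid <- toupper(atoms$resid)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "ecd_structure")
}

#' @export
print.ecd_structure <- function(x, ...) {
  ch <- chain_ids(x)
  nres <- vapply(ch, function(cc) nrow(unique(
    x$atoms[x$atoms$chain == cc, c("resno", "insert")])), 0L)
  cat(sprintf("<ecd_structure> %d chains, %d atoms (%s)\n",
              length(ch), nrow(x$atoms),
              paste(sprintf("%s: %d res", ch, nres), collapse = ", ")))
  invisible(x)
}

#' Chain identifiers of a structure
#' @param s an [ecd_structure()].
#' @return Character vector of chain ids in file order.
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' One-letter sequence of a chain
#'
#' @param s an [ecd_structure()].
#' @param chain chain id.
#' @param drop_unknown drop residues whose 3-letter code is not one of the
#'   20 standard amino acids (otherwise they appear as `"X"`).
#' @return Character scalar with attributes `resno` and `insert` giving the
#'   author numbering of each retained residue.
#' @export
chain_sequence <- function(s, chain, drop_unknown = TRUE) {
  at <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no chain '", chain, "' in structure", call. = FALSE)
  res <- unique(at[, c("resno", "insert", "resid")])
  letters1 <- .aa_3to1[res$resid]
  letters1[is.na(letters1)] <- "X"
  keep <- if (drop_unknown) letters1 != "X" else rep(TRUE, length(letters1))
  out <- paste(letters1[keep], collapse = "")
  attr(out, "resno") <- res$resno[keep]
  attr(out, "insert") <- res$insert[keep]
  out
}

.aa_protein3 <- names(.aa_3to1)

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses the file with bio3d, keeps the first model, drops waters and
#' heteroatoms from the atom table (they are retained in `metadata$het`),
#' and collapses alternate locations to the highest-occupancy copy.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension:
#'   `.cif`/`.mmcif` is mmCIF, anything else PDB).
#' @return An [ecd_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  is_protein <- at$resid %in% .aa_protein3 & at$type == "ATOM"
  het <- at[!is_protein, , drop = FALSE]
  at <- at[is_protein, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no protein chains found in ", path, call. = FALSE)
  ## highest-occupancy altloc only
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    at$o[is.na(at$o)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(match(key, unique(key)), -at$o)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "\r")), , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety,
                      elesy = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                                     substr(gsub("[0-9']", "", at$elety), 1, 1),
                                     at$elesy),
                      x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      b = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  ecd_structure(atoms, metadata = list(source_format = format, path = path,
                                       het = het))
}

#' Write a structure as a PDB file
#'
#' Standard fixed-column ATOM records with 3-decimal coordinates; chain ids,
#' author numbering, insertion codes, occupancy and B-factors are preserved.
#'
#' @param s an [ecd_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  if (nrow(at) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  if (nrow(at) > 99999L)
    stop("PDB format cannot hold more than 99999 atoms (got ",
         nrow(at), ")", call. = FALSE)
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
    stop("coordinates must be finite", call. = FALSE)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = at$resid, eleno = seq_len(nrow(at)),
                   elety = at$elety, chain = at$chain, insert = at$insert,
                   o = at$o, b = at$b, elesy = at$elesy, verbose = FALSE)
  invisible(path)
}

#' Assign chains to subunits by sequence identity
#'
#' Each chain is labelled with the reference fragment to which its sequence
#' has the highest global-alignment percent identity; chains below
#' `min_identity` are labelled `"unknown"`. A tie between the best
#' references is an error (the candidates are listed).
#'
#' @param s an [ecd_structure()].
#' @param references named list of [fragment_sequence()] objects (or named
#'   character vector of sequences); defaults to the packaged
#'   alpha1/beta2/gamma2 ECD fragments.
#' @param min_identity percent identity below which a chain is `"unknown"`.
#' @return data.frame (class `subunit_assignment`) with columns `chain`,
#'   `subunit`, `identity`; subunit counts in attribute `counts`.
#' @export
assign_subunits <- function(s, references = ecd_fragments(),
                            min_identity = 30) {
  if (length(references) == 0L) stop("no reference sequences", call. = FALSE)
  refs <- lapply(references, as_fragment_chr)
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("references must be named", call. = FALSE)
  ch <- chain_ids(s)
  res <- lapply(ch, function(cc) {
    sq <- chain_sequence(s, cc)
    ids <- vapply(refs, function(r)
      percent_identity(global_align(sq, r)), 0)
    best <- max(ids)
    if (best < min_identity)
      return(list(subunit = "unknown", identity = best))
    hits <- names(ids)[abs(ids - best) < 1e-9]
    if (length(hits) > 1L)
      stop("chain '", cc, "' ties between references: ",
           paste(hits, collapse = ", "), call. = FALSE)
    list(subunit = hits, identity = best)
  })
  out <- data.frame(chain = ch,
                    subunit = vapply(res, `[[`, "", "subunit"),
                    identity = vapply(res, `[[`, 0, "identity"),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$subunit)
  class(out) <- c("subunit_assignment", class(out))
  out
}

#' Map between author and fragment numbering
#'
#' Builds a bijection between a chain's author residue numbers and gap-free
#' fragment coordinates in which the stated origin residue is position 1.
#' Insertion-coded residues keep their place in the sequence (fragment
#' numbering is sequential), and queries outside the mapped range raise
#' errors.
#'
#' @param author integer vector of author residue numbers in chain order
#'   (duplicates allowed only via distinct insertion codes in `insert`).
#' @param origin author number that becomes fragment position 1.
#' @param insert optional insertion codes aligned with `author`.
#' @param length optional number of residues covered from the origin.
#' @return Object of class `numbering_map`.
#' @seealso [frag_to_author()], [author_to_frag()]
#' @export
numbering_map <- function(author, origin, insert = NULL, length = NA) {
  if (is.null(insert)) insert <- rep("", base::length(author))
  key <- paste0(author, insert)
  if (anyDuplicated(key))
    stop("author numbering is not unique (duplicate residue numbers without ",
         "insertion codes)", call. = FALSE)
  i0 <- match(as.character(origin), key)
  if (is.na(i0)) stop("origin residue ", origin,
                      " absent from author numbering", call. = FALSE)
  idx <- i0:base::length(author)
  if (!is.na(length)) {
    if (length < 1L || length > base::length(idx))
      stop("requested range extends beyond the chain", call. = FALSE)
    idx <- idx[seq_len(length)]
  }
  structure(list(author = author[idx], insert = insert[idx],
                 fragment = seq_along(idx), origin = origin),
            class = "numbering_map")
}

#' @export
print.numbering_map <- function(x, ...) {
  cat(sprintf("<numbering_map> fragment 1..%d = author %s..%s\n",
              length(x$fragment),
              paste0(x$author[1], x$insert[1]),
              paste0(x$author[length(x$author)],
                     x$insert[length(x$insert)])))
  invisible(x)
}

#' @rdname numbering_map
#' @param map a `numbering_map`.
#' @param fragment fragment positions to convert.
#' @return `frag_to_author()`: author numbers (character when insertion
#'   codes are present, integer otherwise).
#' @export
frag_to_author <- function(map, fragment) {
  i <- match(fragment, map$fragment)
  if (anyNA(i)) stop("fragment position(s) ",
                     paste(fragment[is.na(i)], collapse = ", "),
                     " outside the mapped range", call. = FALSE)
  if (any(nzchar(map$insert[i]))) paste0(map$author[i], map$insert[i])
  else map$author[i]
}

#' @rdname numbering_map
#' @param author_q author numbers to convert (insertion code appended, e.g.
#'   `"100A"`).
#' @export
author_to_frag <- function(map, author_q) {
  key <- paste0(map$author, map$insert)
  i <- match(as.character(author_q), key)
  if (anyNA(i)) stop("author residue(s) ",
                     paste(author_q[is.na(i)], collapse = ", "),
                     " outside the mapped range", call. = FALSE)
  map$fragment[i]
}

#' Locate a fragment on a structure chain
#'
#' Globally aligns the chain sequence to a reference fragment and returns
#' the numbering map that sends fragment coordinates to the chain's author
#' numbers (anchored at the chain residue aligned to fragment position 1).
#'
#' @param s an [ecd_structure()].
#' @param chain chain id.
#' @param fragment a [fragment_sequence()] (or residue string).
#' @return A [numbering_map()] covering the chain from the fragment origin.
#' @export
locate_fragment <- function(s, chain, fragment) {
  sq <- chain_sequence(s, chain)
  al <- global_align(sq, fragment)
  ga <- strsplit(al$gapped_a, "")[[1]]
  gb <- strsplit(al$gapped_b, "")[[1]]
  ia <- cumsum(ga != "-")   # index into chain residues
  ib <- cumsum(gb != "-")   # index into fragment positions
  hit <- which(gb != "-" & ga != "-" & ib == 1L)
  if (length(hit) == 0L) {
    ## fragment position 1 aligned to a gap; anchor at first aligned pair
    hit <- which(gb != "-" & ga != "-")[1]
    if (is.na(hit)) stop("fragment does not align to chain '", chain, "'",
                         call. = FALSE)
  }
  offset <- ib[hit] - 1L
  resno <- attr(sq, "resno"); insert <- attr(sq, "insert")
  i0 <- ia[hit]
  map <- numbering_map(resno[i0:length(resno)], origin = resno[i0],
                       insert = insert[i0:length(insert)])
  ## shift fragment coordinates when anchor was not fragment position 1
  map$fragment <- map$fragment + offset
  map
}
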