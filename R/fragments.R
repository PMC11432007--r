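#' Construct a subunit fragment sequence
#'
#' A fragment sequence is a one-letter amino-acid string expressed in
#' *fragment coordinates*: position 1 is the first residue of the expressed
#' fragment (e.g. the mature-start glutamine of an ECD construct), and
#' `precursor_origin` records which precursor (UniProt) residue number that
#' position corresponds to, so positions can be mapped back to precursor
#' numbering as `precursor = fragment + precursor_origin - 1`.
#'
#' @param label character scalar naming the fragment (e.g. `"alpha1"`).
#' @param residues one-letter residue string (20 standard letters only).
#' @param precursor_origin integer precursor number of fragment position 1.
#' @return An object of class `fragment_sequence`.
#' @examples
#' fr <- fragment_sequence("toy", "QWERTY", precursor_origin = 28)
#' seq_length(fr)
#' @export
fragment_sequence <- function(label, residues, precursor_origin = 1L) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.character(residues), length(residues) == 1L)
  residues <- .validate_residue_string(residues, paste0("fragment '", label, "'"))
  if (nchar(residues) == 0L) stop("fragment '", label, "' is empty", call. = FALSE)
  structure(list(label = label, residues = residues,
                 precursor_origin = as.integer(precursor_origin)),
            class = "fragment_sequence")
}

#' @export
print.fragment_sequence <- function(x, ...) {
  cat(sprintf("<fragment_sequence> %s: %d aa (fragment 1 = precursor %d)\n",
              x$label, nchar(x$residues), x$precursor_origin))
  invisible(x)
}

#' @export
as.character.fragment_sequence <- function(x, ...) x$residues

#' Fragment length
#' @param x a [fragment_sequence()].
#' @return Integer number of residues.
#' @export
seq_length <- function(x) nchar(as_fragment_chr(x))

## accept fragment_sequence or plain character
as_fragment_chr <- function(x) {
  if (inherits(x, "fragment_sequence")) x$residues
  else if (is.character(x) && length(x) == 1L) .validate_residue_string(x)
  else stop("expected a fragment_sequence or a single residue string",
            call. = FALSE)
}

.seq_chars <- function(x) strsplit(as_fragment_chr(x), "")[[1]]

#' GABA-A receptor ECD fragment sequences
#'
#' Loads the packaged extracellular-domain fragment sequences of the human
#' GABA-A receptor alpha1 (Gln28-Arg248 of UniProt P14867), beta2
#' (Gln25-Gly243, P47870) and gamma2 (Gln40-Gly273, P18507) subunits, plus
#' an extended alpha1 construct (Gln28-Leu296) that reaches into the first
#' two transmembrane segments and is used for hydropathy checks.
#'
#' @param extended logical; include the extended `alpha1_ecd_tm` fragment.
#' @return Named list of [fragment_sequence()] objects
#'   (`alpha1`, `beta2`, `gamma2`, and optionally `alpha1_tm`).
#' @export
ecd_fragments <- function(extended = FALSE) {
  path <- system.file("extdata", "gabaa_ecd_fragments.fasta",
                      package = "ecdprofiler", mustWork = TRUE)
  fa <- read_fasta(path)
  out <- list(
    alpha1 = fragment_sequence("alpha1", fa[["alpha1_ecd"]]$seq,
                               fa[["alpha1_ecd"]]$origin),
    beta2  = fragment_sequence("beta2", fa[["beta2_ecd"]]$seq,
                               fa[["beta2_ecd"]]$origin),
    gamma2 = fragment_sequence("gamma2", fa[["gamma2_ecd"]]$seq,
                               fa[["gamma2_ecd"]]$origin)
  )
  if (extended) {
    out$alpha1_tm <- fragment_sequence("alpha1_tm", fa[["alpha1_ecd_tm"]]$seq,
                                       fa[["alpha1_ecd_tm"]]$origin)
  }
  out
}

#' Read a protein FASTA file
#'
#' Minimal reader returning sequences keyed by the first word of each
#' header; an `origin=<n>` token in the header, if present, is parsed into
#' the `origin` field (used by the packaged fragment fixtures).
#'
#' @param path FASTA file path.
#' @return Named list with elements `seq` (character) and `origin` (integer,
#'   1 when absent).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(hdr)) {
    header <- sub("^>", "", lines[hdr[k]])
    name <- strsplit(header, "\\s+")[[1]][1]
    origin <- 1L
    m <- regmatches(header, regexec("origin=([0-9]+)", header))[[1]]
    if (length(m) == 2L) origin <- as.integer(m[2])
    body <- if (hdr[k] + 1L > ends[k]) "" else
      paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    out[[name]] <- list(seq = gsub("\\s", "", body), origin = origin)
  }
  out
}

#' Published per-structure aromatic distance tables
#'
#' The per-structure, per-subunit pseudo-atom distances reported for eight
#' deposited cryo-EM structures of the alpha1/beta2/gamma2 receptor: the
#' Trp-Trp ring-centroid separations of the WxD/WxPD motif pair
#' (`"trp_pair"`) and the Tyr-ring-to-Cys-loop-disulfide distances
#' (`"tyr_cysloop"`), in Angstroms. These serve as reference input for
#' [aggregate_distances()] and for tolerance checks of newly measured
#' structures.
#'
#' @param which `"trp_pair"` or `"tyr_cysloop"`.
#' @return data.frame with column `PDB ID` and one numeric column per
#'   subunit (`alpha1`, `beta2`, `gamma2`).
#' @export
published_distance_tables <- function(which = c("trp_pair", "tyr_cysloop")) {
  which <- match.arg(which)
  fn <- switch(which,
               trp_pair = "table_trp_pair_distances.tsv",
               tyr_cysloop = "table_tyr_cysloop_distances.tsv")
  path <- system.file("extdata", fn, package = "ecdprofiler", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}
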