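## Global pairwise alignment, identity matrices, and conserved-motif scans.

.load_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise alignment of two fragment sequences
#'
#' Optimal Needleman-Wunsch global alignment with affine gap penalties
#' (a gap of length L costs `gap_open + L * gap_extend`), computed with
#' Biostrings. Defaults follow the EMBOSS convention: BLOSUM62, gap open
#' 10, gap extend 0.5.
#'
#' @param a,b [fragment_sequence()] objects or residue strings.
#' @param substitution substitution matrix name (a Biostrings data set) or
#'   a numeric matrix.
#' @param gap_open,gap_extend affine gap penalties (non-negative).
#' @return Object of class `ecd_alignment`: `gapped_a`, `gapped_b`
#'   (equal-length strings with `-` gaps) and `score`.
#' @examples
#' al <- global_align("HEAGAWGHEE", "PAWHEAE")
#' percent_identity(al)
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  sa <- as_fragment_chr(a); sb <- as_fragment_chr(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("cannot align an empty sequence", call. = FALSE)
  sm <- if (is.character(substitution)) .load_submat(substitution) else substitution
  al <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  out <- list(gapped_a = as.character(Biostrings::pattern(al)),
              gapped_b = as.character(Biostrings::subject(al)),
              score = Biostrings::score(al))
  stopifnot(nchar(out$gapped_a) == nchar(out$gapped_b))
  class(out) <- "ecd_alignment"
  out
}

#' @export
print.ecd_alignment <- function(x, ...) {
  cat(sprintf("<ecd_alignment> %d columns, score %.1f\n",
              nchar(x$gapped_a), x$score))
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' Identity over residue-residue columns only (the Clustal convention):
#' `100 * identical / aligned`, where `aligned` counts columns in which
#' neither sequence has a gap.
#'
#' @param al an `ecd_alignment` from [global_align()].
#' @return Percent in `[0, 100]`.
#' @export
percent_identity <- function(al) {
  ca <- strsplit(al$gapped_a, "")[[1]]
  cb <- strsplit(al$gapped_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both))
    stop("alignment has no residue-residue columns; identity undefined",
         call. = FALSE)
  100 * sum(ca[both] == cb[both]) / sum(both)
}

#' All-pairs percent identity matrix
#'
#' @param seqs list of [fragment_sequence()] objects (or a named character
#'   vector); labels must be unique.
#' @param ... passed to [global_align()].
#' @return Symmetric numeric matrix (percent), 100 on the diagonal, with
#'   sequence labels as dimnames.
#' @export
identity_matrix <- function(seqs, ...) {
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  labels <- if (!is.null(names(seqs)) && all(nzchar(names(seqs)))) names(seqs)
            else vapply(seqs, function(s)
              if (inherits(s, "fragment_sequence")) s$label else NA_character_, "")
  if (anyNA(labels)) stop("sequences must be labelled", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate sequence labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pid <- percent_identity(global_align(seqs[[i]], seqs[[j]], ...))
    m[i, j] <- m[j, i] <- pid
  }
  m
}

#' Scan a fragment for conserved tripeptide/tetrapeptide motifs
#'
#' Finds all (possibly overlapping) matches of the WxD, WxPD and GYD
#' patterns. When a WxPD match starts at the same Trp as a WxD match the
#' longer motif wins and the WxD hit is suppressed, so the two Trp motifs
#' are never double-reported for one tryptophan.
#'
#' @param seq a [fragment_sequence()] or residue string.
#' @param patterns named character vector of regular expressions.
#' @return data.frame with columns `motif`, `start` (fragment position),
#'   `matched`, sorted by `start`.
#' @examples
#' scan_motifs("WADXXWQPD")
#' @export
scan_motifs <- function(seq, patterns = c(WxPD = "W.PD", WxD = "W.D",
                                          GYD = "GYD")) {
  ## scanning places no alphabet restriction (placeholder letters allowed)
  s <- if (inherits(seq, "fragment_sequence")) seq$residues
       else toupper(as.character(seq))
  hits <- do.call(rbind, lapply(names(patterns), function(nm) {
    m <- gregexpr(paste0("(?=(", patterns[[nm]], "))"), s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    starts <- as.integer(m)
    len <- attr(m, "capture.length")[, 1]
    data.frame(motif = nm, start = starts,
               matched = substring(s, starts, starts + len - 1L),
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) return(data.frame(motif = character(), start = integer(),
                                       matched = character()))
  ## longest pattern wins at a shared start
  hits <- hits[order(hits$start, -nchar(hits$matched)), , drop = FALSE]
  drop <- hits$motif == "WxD" &
    hits$start %in% hits$start[hits$motif == "WxPD"]
  hits <- hits[!drop, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Locate the Cys-loop
#'
#' The canonical pLGIC Cys-loop is a disulfide-bonded cysteine pair with
#' exactly 13 intervening residues. Returns the first such pair in
#' fragment coordinates.
#'
#' @param seq a [fragment_sequence()] or residue string.
#' @param span required number of intervening residues.
#' @return List of class `cys_loop` with `cys1`, `cys2`, `span`.
#' @export
find_cys_loop <- function(seq, span = 13L) {
  ch <- .seq_chars(seq)
  cys <- which(ch == "C")
  if (length(cys) < 2L)
    stop("sequence has fewer than two cysteines", call. = FALSE)
  c1 <- cys[(cys + span + 1L) %in% cys]
  if (length(c1) == 0L)
    stop("no cysteine pair with exactly ", span, " intervening residues",
         call. = FALSE)
  structure(list(cys1 = c1[1], cys2 = c1[1] + span + 1L, span = as.integer(span)),
            class = "cys_loop")
}

#' @export
print.cys_loop <- function(x, ...) {
  cat(sprintf("<cys_loop> Cys%d-Cys%d (%d intervening residues)\n",
              x$cys1, x$cys2, x$span))
  invisible(x)
}

#' Check for the conserved Trp C-terminal of the Cys-loop
#'
#' Cys-loop receptor ECDs carry a conserved tryptophan at a fixed offset
#' (18 residues) C-terminal of the loop's second cysteine. Returns that
#' fragment position when the residue there is Trp, `NA` otherwise.
#'
#' @param seq a [fragment_sequence()] or residue string.
#' @param loop a [find_cys_loop()] result valid for `seq`.
#' @param offset residues C-terminal of the second cysteine.
#' @return Integer fragment position, or `NA_integer_` when absent.
#' @export
conserved_trp_check <- function(seq, loop, offset = 18L) {
  ch <- .seq_chars(seq)
  pos <- loop$cys2 + offset
  if (pos > length(ch))
    stop("position ", pos, " beyond sequence end (", length(ch), ")",
         call. = FALSE)
  if (ch[pos] == "W") as.integer(pos) else NA_integer_
}

#' Tryptophan composition of a fragment
#'
#' @param seq a [fragment_sequence()] or residue string.
#' @return List with `count` and `percent` (of fragment length, 2 dp).
#' @export
trp_composition <- function(seq) {
  ch <- .seq_chars(seq)
  n <- sum(ch == "W")
  list(count = n, percent = round(100 * n / length(ch), 2))
}

#' Split a fragment into its two beta-rich domains
#'
#' pLGIC ECD fragments split into an N-terminal domain and a
#' membrane-proximal beta-rich (MPB) domain at the first Cys-loop
#' cysteine: domain 1 is `[1, cys1 - 1]`, domain 2 `[cys1, end]`.
#'
#' @param seq a [fragment_sequence()] or residue string.
#' @param loop a [find_cys_loop()] result valid for `seq`.
#' @return List with `domain1` and `domain2`, each `c(start, end)` in
#'   fragment coordinates.
#' @export
two_domain_split <- function(seq, loop) {
  n <- length(.seq_chars(seq))
  if (loop$cys1 <= 1L)
    stop("first Cys-loop cysteine at position 1: degenerate N-terminal domain",
         call. = FALSE)
  list(domain1 = c(1L, loop$cys1 - 1L), domain2 = c(loop$cys1, n))
}

#' Average mass of a peptide fragment
#'
#' Sum of the average (isotope-averaged) free amino-acid masses minus one
#' water per peptide bond, in kDa. No tags or modifications.
#'
#' @param seq a [fragment_sequence()] or residue string.
#' @return Mass in kDa (unrounded).
#' @examples
#' fragment_mass("G")   # free glycine, 0.07507 kDa
#' @export
fragment_mass <- function(seq) {
  ch <- .seq_chars(seq)
  (sum(.aa_avg_mass[ch]) - (length(ch) - 1L) * .water_mass) / 1000
}
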