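## Independent oracles and fixture builders shared across test files.

.blosum62 <- local({
  e <- new.env()
  utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

## Exhaustive enumeration of all global alignments as move strings
## (M = match column, A = gap in b, B = gap in a); a gap run of length L
## costs open + extend * L.  Independent of the package's aligner.
brute_force_align_score <- function(a, b, open = 10, extend = 0.5,
                                    sm = .blosum62) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > na && j > nb) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, sc + sm[A[i], B[j]], "M")
    if (i <= na)
      rec(i + 1L, j, sc - extend - if (last == "A") 0 else open, "A")
    if (j <= nb)
      rec(i, j + 1L, sc - extend - if (last == "B") 0 else open, "B")
  }
  rec(1L, 1L, 0, "M")
  best
}

## two-pass mean / sample-SD / SEM oracle
naive_mean_sem <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  ss <- sum((v - m)^2)
  list(mean = m, sem = sqrt(ss / (n - 1)) / sqrt(n))
}

## uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_aa <- function(n) {
  paste(sample(names(ecdprofiler::kyte_doolittle), n, replace = TRUE),
        collapse = "")
}

## minimal hand-written PDB text for one glycine
write_tiny_gly_pdb <- function(path) {
  fmt <- "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, 1, "N", "GLY", "A", 1, 0.0, 0.0, 0.0, 1.00, 0.00, "N"),
    sprintf(fmt, 2, "CA", "GLY", "A", 1, 1.458, 0.0, 0.0, 1.00, 0.00, "C"),
    sprintf(fmt, 3, "C", "GLY", "A", 1, 2.0, 1.4, 0.0, 1.00, 0.00, "C"),
    sprintf(fmt, 4, "O", "GLY", "A", 1, 1.6, 2.5, 0.0, 1.00, 0.00, "O"),
    "END")
  writeLines(lines, path)
  path
}

## one CA atom per residue, so a chain carries an arbitrary sequence
seq_to_ca_structure <- function(seqs) {
  aa13 <- stats::setNames(names(ecdprofiler:::.aa_3to1),
                          unname(ecdprofiler:::.aa_3to1))
  atoms <- do.call(rbind, lapply(seq_along(seqs), function(k) {
    ch <- strsplit(seqs[[k]], "")[[1]]
    data.frame(chain = names(seqs)[k], resno = seq_along(ch), insert = "",
               resid = aa13[ch], elety = "CA", elesy = "C",
               x = 3.8 * seq_along(ch), y = 40 * k, z = 0,
               stringsAsFactors = FALSE)
  }))
  ecd_structure(atoms)
}

## a regular hexagon ring residue (TYR by default) centred at `center`
hexagon_residue <- function(chain, resno, center, resid = "TYR",
                            names6 = c("CG", "CD1", "CE1", "CZ",
                                       "CE2", "CD2")) {
  th <- (0:5) * 60 * pi / 180
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = names6, elesy = "C",
             x = center[1] + 1.39 * cos(th),
             y = center[2] + 1.39 * sin(th),
             z = center[3], stringsAsFactors = FALSE)
}

## structure whose chains carry a motif-bearing sequence (CA trace) plus
## exact planted ring/disulfide geometry for the pipeline to measure
motif_pentamer_structure <- function(ms, chains = c("A", "B"),
                                     pi_distance = 5.85,
                                     s_pi_distance = 4.5) {
  sq <- as.character(ms$sequence)
  ch <- strsplit(sq, "")[[1]]
  truth <- ms$truth
  ## the loop the sequence itself yields (a chance background C-x13-C can
  ## precede the planted one; the geometry must follow the sequence)
  loop <- ecdprofiler::find_cys_loop(ms$sequence)
  loop_res <- c(loop$cys1, loop$cys2)
  aa13 <- stats::setNames(names(ecdprofiler:::.aa_3to1),
                          unname(ecdprofiler:::.aa_3to1))
  indole <- ecdprofiler:::.ideal_indole()
  one_chain <- function(cc, zoff) {
    base <- data.frame(chain = cc, resno = seq_along(ch), insert = "",
                       resid = aa13[ch], elety = "CA", elesy = "C",
                       x = 3.8 * seq_along(ch), y = 0, z = zoff,
                       stringsAsFactors = FALSE)
    ring <- function(resno, center) {
      m <- sweep(indole, 2, center, "+")
      data.frame(chain = cc, resno = resno, insert = "", resid = "TRP",
                 elety = rownames(m), elesy = substr(rownames(m), 1, 1),
                 x = m[, 1], y = m[, 2], z = m[, 3],
                 stringsAsFactors = FALSE)
    }
    mid <- c(0, 30, zoff)
    extra <- rbind(
      ring(truth$wxd, c(0, 15, zoff)),
      ring(truth$wxpd, c(pi_distance, 15, zoff)),
      hexagon_residue(cc, truth$gyd + 1L, mid - c(0, s_pi_distance, 0)),
      data.frame(chain = cc, resno = loop_res, insert = "",
                 resid = "CYS", elety = "SG", elesy = "S",
                 x = mid[1] + c(-1.015, 1.015), y = mid[2], z = mid[3],
                 stringsAsFactors = FALSE))
    rbind(base[!(base$resno %in% extra$resno), ], extra)
  }
  atoms <- do.call(rbind, lapply(seq_along(chains),
                                 function(k) one_chain(chains[k],
                                                       200 * (k - 1))))
  atoms <- atoms[order(match(atoms$chain, chains), atoms$resno), ]
  ecd_structure(atoms)
}
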