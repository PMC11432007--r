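## Orchestration: run the full fragment/structure analysis and emit
## machine-readable reports.

#' Fragment-level motif landmarks
#'
#' Derives, per reference fragment, the sequence coordinates every
#' structural measurement needs: the WxD/WxPD tryptophan pair, the
#' Cys-loop cysteines, the conserved post-loop tryptophan, and the
#' Cys-loop-packed tyrosine. The packed Tyr is a 3-D property, so it is
#' configured per subunit (fragment 60/57/72 for the packaged
#' alpha1/beta2/gamma2 references); fragments without a configured
#' position fall back to the GYD-motif tyrosine when one exists.
#'
#' @param fragments named list of [fragment_sequence()] objects.
#' @param packed_tyr named integer vector of packed-Tyr fragment
#'   positions; defaults cover the packaged subunits.
#' @return Named list per fragment: `trp_pair`, `cys_loop`,
#'   `conserved_trp`, `packed_tyr` (fragment coordinates).
#' @export
fragment_landmarks <- function(fragments = ecd_fragments(),
                               packed_tyr = c(alpha1 = 60L, beta2 = 57L,
                                              gamma2 = 72L)) {
  lapply(stats::setNames(names(fragments), names(fragments)), function(nm) {
    fr <- fragments[[nm]]
    hits <- scan_motifs(fr)
    wxd <- hits$start[hits$motif == "WxD"]
    wxpd <- hits$start[hits$motif == "WxPD"]
    ## prefer the conserved pair: the WxD whose Trp is 25 residues before
    ## the WxPD Trp (chance WxD matches can occur elsewhere)
    if (length(wxpd) > 0L && any(wxd == wxpd[1] - 25L))
      wxd <- wxd[wxd == wxpd[1] - 25L]
    loop <- tryCatch(find_cys_loop(fr), error = function(e) NULL)
    ty <- if (nm %in% names(packed_tyr)) packed_tyr[[nm]] else NA_integer_
    if (is.na(ty) && any(hits$motif == "GYD"))
      ty <- hits$start[hits$motif == "GYD"][1] + 1L
    if (!is.na(ty) && .seq_chars(fr)[ty] != "Y") ty <- NA_integer_
    list(trp_pair = c(wxd[1], wxpd[1]),
         cys_loop = if (is.null(loop)) NULL else c(loop$cys1, loop$cys2),
         conserved_trp = if (is.null(loop)) NA_integer_ else
           tryCatch(conserved_trp_check(fr, loop), error = function(e) NA_integer_),
         packed_tyr = ty)
  })
}

.chain_for_subunit <- function(assignment, subunit) {
  ch <- assignment$chain[assignment$subunit == subunit]
  if (length(ch) == 0L) NA_character_ else ch[1]
}

#' Measure the WxD/WxPD Trp-pair distance per subunit
#'
#' For one structure: assigns chains to subunits, maps fragment coordinates
#' onto each chain's author numbering, and measures the ring-centroid
#' separation of the conserved tryptophan pair for one representative
#' chain per subunit.
#'
#' @param s an [ecd_structure()].
#' @param fragments reference fragments (see [ecd_fragments()]).
#' @param ring_def Trp ring definition (see [ring_centroid()]).
#' @param assignment optional precomputed [assign_subunits()] result.
#' @return Named numeric vector of distances (Angstroms), one per subunit
#'   found; `NA` where measurement failed.
#' @export
measure_trp_pairs <- function(s, fragments = ecd_fragments(),
                              ring_def = "trp_indole9",
                              assignment = NULL) {
  if (is.null(assignment)) assignment <- assign_subunits(s, fragments)
  lm <- fragment_landmarks(fragments)
  out <- stats::setNames(rep(NA_real_, length(fragments)), names(fragments))
  for (nm in names(fragments)) {
    cc <- .chain_for_subunit(assignment, nm)
    if (is.na(cc)) next
    out[nm] <- tryCatch({
      map <- locate_fragment(s, cc, fragments[[nm]])
      tp <- frag_to_author(map, lm[[nm]]$trp_pair)
      pi_stack_distance(s, cc, as.integer(tp[1]), cc, as.integer(tp[2]),
                        ring_def = ring_def)$distance
    }, error = function(e) NA_real_)
  }
  out
}

#' Measure the Tyr/Cys-loop S-pi distance per subunit
#'
#' Companion to [measure_trp_pairs()]: distance from the packed tyrosine's
#' ring centroid to the Cys-loop disulfide midpoint, per subunit.
#'
#' @inheritParams measure_trp_pairs
#' @return Named numeric vector of distances (Angstroms).
#' @export
measure_tyr_cysloop <- function(s, fragments = ecd_fragments(),
                                assignment = NULL) {
  if (is.null(assignment)) assignment <- assign_subunits(s, fragments)
  lm <- fragment_landmarks(fragments)
  out <- stats::setNames(rep(NA_real_, length(fragments)), names(fragments))
  for (nm in names(fragments)) {
    cc <- .chain_for_subunit(assignment, nm)
    if (is.na(cc) || is.na(lm[[nm]]$packed_tyr) || is.null(lm[[nm]]$cys_loop))
      next
    out[nm] <- tryCatch({
      map <- locate_fragment(s, cc, fragments[[nm]])
      ty <- as.integer(frag_to_author(map, lm[[nm]]$packed_tyr))
      cy <- as.integer(frag_to_author(map, lm[[nm]]$cys_loop))
      s_pi_distance(s, cc, ty, cc, cy[1], cy[2])$distance
    }, error = function(e) NA_real_)
  }
  out
}

#' Run the full analysis and write a report bundle
#'
#' Orchestrates the sequence- and structure-level analyses and writes
#' tab-separated reports plus a JSON manifest to `out_dir`:
#' `identity_matrix.tsv`, `motifs.tsv`, `hydropathy.tsv`,
#' `trp_pair_distances.tsv` and `tyr_cysloop_distances.tsv` (per-structure
#' rows plus `Max`/`Min`/`Average (± SEM)` aggregate rows when two or more
#' structures are supplied), `hbonds.tsv`, `ss_summary.tsv`, and
#' `manifest.json`. When no structures are given, the geometry and
#' secondary-structure reports are skipped with a warning and flagged in
#' the manifest.
#'
#' @param structures character vector of structure file paths, or a list
#'   of [ecd_structure()] objects (named by structure id).
#' @param fragments reference fragments (see [ecd_fragments()]).
#' @param out_dir output directory (created if needed).
#' @param ring_def Trp ring definition.
#' @param contact_threshold structural-contact distance, Angstroms.
#' @param hbond_criteria list with `max_da` and `min_angle`.
#' @param kd_windows hydropathy window sizes.
#' @param seed optional integer recorded in the manifest and set before
#'   any randomized step.
#' @return Invisibly, a list with the written file paths and the computed
#'   tables.
#' @export
run_report <- function(structures = character(), fragments = ecd_fragments(),
                       out_dir = "ecd_report", ring_def = "trp_indole9",
                       contact_threshold = 6.0,
                       hbond_criteria = list(max_da = 3.5, min_angle = 120),
                       kd_windows = c(7L, 19L), seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  paths <- list(); skipped <- character()
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  ## sequence-level reports
  im <- NULL
  if (length(fragments) >= 2L) {
    im <- identity_matrix(fragments)
    tsv(cbind(fragment = rownames(im),
              as.data.frame(round(im, 2), check.names = FALSE)),
        "identity_matrix.tsv")
  } else skipped <- c(skipped, "identity_matrix.tsv")
  motifs <- do.call(rbind, lapply(names(fragments), function(nm) {
    h <- scan_motifs(fragments[[nm]])
    if (nrow(h) == 0L) return(NULL)
    cbind(fragment = nm, h)
  }))
  tsv(motifs, "motifs.tsv")
  hyd <- do.call(rbind, lapply(names(fragments), function(nm) {
    do.call(rbind, lapply(kd_windows, function(w) {
      if (w > seq_length(fragments[[nm]])) return(NULL)
      pr <- kd_profile(fragments[[nm]], w)
      data.frame(fragment = nm, window = w, position = pr$position,
                 score = round(pr$score, 3))
    }))
  }))
  tsv(hyd, "hydropathy.tsv")
  ## structure-level reports
  structs <- list()
  if (length(structures) > 0L) {
    if (is.character(structures)) {
      ids <- sub("\\.[^.]*$", "", basename(structures))
      structs <- stats::setNames(lapply(structures, read_structure), ids)
    } else {
      structs <- structures
      if (is.null(names(structs)))
        names(structs) <- paste0("model", seq_along(structs))
    }
  }
  geom <- NULL
  if (length(structs) == 0L) {
    warning("no structures supplied: geometry and secondary-structure ",
            "reports skipped", call. = FALSE)
    skipped <- c("trp_pair_distances.tsv", "tyr_cysloop_distances.tsv",
                 "hbonds.tsv", "ss_summary.tsv")
  } else {
    assignments <- lapply(structs, assign_subunits, references = fragments)
    trp <- do.call(rbind, lapply(names(structs), function(id)
      measure_trp_pairs(structs[[id]], fragments, ring_def,
                        assignments[[id]])))
    tyr <- do.call(rbind, lapply(names(structs), function(id)
      measure_tyr_cysloop(structs[[id]], fragments, assignments[[id]])))
    rownames(trp) <- rownames(tyr) <- names(structs)
    fmt_dist <- function(m) {
      df <- data.frame(`PDB ID` = rownames(m), check.names = FALSE)
      df <- cbind(df, as.data.frame(round(m, 2)))
      keep <- colSums(!is.na(m)) >= 2L
      if (nrow(m) >= 2L && any(keep)) {
        ag <- aggregate_distances(m[, keep, drop = FALSE])
        pad <- function(label, vals) {
          row <- stats::setNames(rep(NA, ncol(m)), colnames(m))
          row[names(vals)] <- vals
          c(`PDB ID` = label, round(row, 4))
        }
        extra <- rbind(pad("Max", ag$max), pad("Min", ag$min),
                       pad("Average", ag$mean), pad("SEM", ag$sem))
        df <- rbind(df, as.data.frame(extra, check.names = FALSE))
      }
      df
    }
    tsv(fmt_dist(trp), "trp_pair_distances.tsv")
    tsv(fmt_dist(tyr), "tyr_cysloop_distances.tsv")
    geom <- list(trp = trp, tyr = tyr)
    hb <- do.call(rbind, lapply(names(structs), function(id) {
      s <- structs[[id]]
      ch <- chain_ids(s)
      if (length(ch) < 2L) return(NULL)
      pairs <- cbind(ch, c(ch[-1], ch[1]))
      if (length(ch) == 2L) pairs <- pairs[1, , drop = FALSE]
      do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
        b <- detect_hbonds(s, pairs[k, 1], pairs[k, 2],
                           max_da = hbond_criteria$max_da,
                           min_angle = hbond_criteria$min_angle)
        if (nrow(b) == 0L) return(NULL)
        cbind(structure = id, b)
      }))
    }))
    if (is.null(hb)) {
      skipped <- c(skipped, "hbonds.tsv")
    } else tsv(cbind(hb[1], kind = hb$kind, hb[-(1:2)]), "hbonds.tsv")
    sstab <- do.call(rbind, lapply(names(structs), function(id)
      cbind(structure = id, ss_summary(assign_ss(structs[[id]])))))
    tsv(sstab, "ss_summary.tsv")
  }
  manifest <- list(
    package = "ecdprofiler",
    version = as.character(utils::packageVersion("ecdprofiler")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = seed,
    config = list(ring_def = ring_def, contact_threshold = contact_threshold,
                  hbond_criteria = hbond_criteria, kd_windows = kd_windows,
                  fragments = names(fragments),
                  structures = names(structs)),
    outputs = names(paths),
    skipped = skipped)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  paths[["manifest.json"]] <- mp
  invisible(list(paths = paths, identity = im, motifs = motifs,
                 geometry = geom, skipped = skipped))
}
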