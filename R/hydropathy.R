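## Kyte-Doolittle hydropathy profiling.

#' Windowed Kyte-Doolittle hydropathy profile
#'
#' Sliding unweighted mean of per-residue Kyte-Doolittle values. Only full
#' windows are reported (the ProtScale convention), so the profile covers
#' window centres `(w+1)/2 .. n-(w-1)/2` in fragment coordinates.
#'
#' @param seq a [fragment_sequence()] or residue string.
#' @param window odd window size, at most the sequence length. 7 suits
#'   surface/antigenic regions; 19 suits transmembrane detection.
#' @return data.frame of class `hydropathy_profile` with columns
#'   `position` (window centre) and `score`; window size in
#'   `attr(, "window")`.
#' @export
kd_profile <- function(seq, window = 7L) {
  ch <- .seq_chars(seq)
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  if (window > length(ch))
    stop("window (", window, ") exceeds sequence length (", length(ch), ")",
         call. = FALSE)
  vals <- unname(kyte_doolittle[ch])
  sc <- as.numeric(stats::filter(vals, rep(1 / window, window), sides = 2))
  half <- (window - 1L) %/% 2L
  pos <- (half + 1L):(length(ch) - half)
  out <- data.frame(position = pos, score = sc[pos])
  attr(out, "window") <- as.integer(window)
  class(out) <- c("hydropathy_profile", class(out))
  out
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("<hydropathy_profile> window %d, centres %d..%d, mean %.3f\n",
              attr(x, "window"), min(x$position), max(x$position),
              mean(x$score)))
  invisible(x)
}

#' @export
plot.hydropathy_profile <- function(x, ...) {
  graphics::plot(x$position, x$score, type = "l",
                 xlab = "fragment position", ylab = "Kyte-Doolittle score",
                 ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Mean raw hydropathy over a residue range
#'
#' @param seq a [fragment_sequence()] or residue string.
#' @param range `c(start, end)` in fragment coordinates.
#' @return Mean Kyte-Doolittle value of the residues in the range.
#' @seealso [profile_segment_mean()] for the windowed-profile average that
#'   plot-read segment values correspond to.
#' @export
segment_mean <- function(seq, range) {
  ch <- .seq_chars(seq)
  range <- as.integer(range)
  if (length(range) != 2L || range[1] > range[2] ||
      range[1] < 1L || range[2] > length(ch))
    stop("range must be c(start, end) within the sequence", call. = FALSE)
  mean(kyte_doolittle[ch[range[1]:range[2]]])
}

#' Mean windowed hydropathy over a segment of a profile
#'
#' Average of the windowed profile scores whose centres fall inside the
#' range - the quantity one reads off a plotted hydropathy profile for a
#' segment (e.g. a transmembrane stretch).
#'
#' @param profile a [kd_profile()] result.
#' @param range `c(start, end)` in fragment coordinates.
#' @return Mean windowed score over the covered centres.
#' @export
profile_segment_mean <- function(profile, range) {
  keep <- profile$position >= range[1] & profile$position <= range[2]
  if (!any(keep))
    stop("no profile window centres inside the range", call. = FALSE)
  mean(profile$score[keep])
}

#' Transmembrane-candidate segments of a hydropathy profile
#'
#' Maximal runs of consecutive window centres at or above the threshold
#' (+1.6 on the Kyte-Doolittle scale is the conventional transmembrane
#' indication).
#'
#' @param profile a [kd_profile()] result.
#' @param threshold score threshold.
#' @return data.frame with columns `start`, `end` (window centres) and
#'   `length`; zero rows when nothing reaches the threshold.
#' @export
tm_candidates <- function(profile, threshold = 1.6) {
  above <- profile$score >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = profile$position[starts[keep]],
             end = profile$position[ends[keep]],
             length = r$lengths[keep])
}
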