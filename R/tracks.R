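# Midpoint tracks: the per-experiment container of inferred nucleosome
# midpoint coordinates used by every downstream statistic.

#' Construct a nucleosome midpoint track
#'
#' @param midpoints Either a named list of integer coordinate vectors (one
#'   per chromosome) or a data.frame with columns `chrom` and `pos`.
#' @param label Experiment label, e.g. `"HMGD1"`, `"H1"` or `"total"`.
#' @return An object of class `midpoint_track`: a list with elements
#'   `label`, `midpoints` (named list of sorted integer vectors) and
#'   `n_total` (total mapped midpoints).
#' @export
midpoint_track <- function(midpoints, label = "total") {
  if (is.data.frame(midpoints)) {
    stopifnot(all(c("chrom", "pos") %in% names(midpoints)))
    midpoints <- split(as.integer(midpoints$pos), midpoints$chrom)
  }
  midpoints <- lapply(midpoints, function(x) sort(as.integer(x)))
  if (length(midpoints)) midpoints <- midpoints[order(names(midpoints))]
  structure(list(label = label, midpoints = midpoints,
                 n_total = sum(lengths(midpoints))),
            class = "midpoint_track")
}

#' @export
print.midpoint_track <- function(x, ...) {
  cat("<midpoint_track> label=", x$label, ", ", x$n_total, " midpoints on ",
      length(x$midpoints), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.midpoint_track <- function(x, ...) {
  data.frame(chrom = rep(names(x$midpoints), lengths(x$midpoints)),
             pos = unlist(x$midpoints, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Write a midpoint track as BED3
#'
#' Each midpoint is emitted as a 1-bp interval `chrom<TAB>pos<TAB>pos+1`,
#' chromosomes in sorted order, coordinates ascending.  The file
#' round-trips losslessly through [read_intervals()].
#'
#' @param track A [midpoint_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_midpoints <- function(track, path) {
  stopifnot(inherits(track, "midpoint_track"))
  df <- as.data.frame(track)
  df$end <- df$pos + 1L
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df)) {
    writeLines(paste(df$chrom, df$pos, df$end, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a midpoint track from a BED3 file of 1-bp intervals
#'
#' @param path Path to a BED file written by [write_midpoints()] (any BED
#'   works; the interval start is taken as the midpoint coordinate).
#' @param label Experiment label.
#' @return A [midpoint_track].
#' @export
read_midpoints <- function(path, label = "total") {
  iv <- read_intervals(path)
  midpoint_track(data.frame(chrom = iv$chrom, pos = iv$start,
                            stringsAsFactors = FALSE), label = label)
}
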