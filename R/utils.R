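# Internal helpers shared across modules.

#' Pseudocount-guarded log2 ratio
#'
#' Computes `log2((a + pseudo) / (b + pseudo))`.  A pseudocount of 1 is used
#' throughout the package wherever counts are log-transformed, so that
#' empty windows yield finite values.
#'
#' @param a,b Non-negative numeric vectors (counts or mean depths).
#' @param pseudo Pseudocount added to both numerator and denominator.
#' @return Numeric vector of log2 ratios.
#' @export
#' @examples
#' log2_ratio(20, 40)        # log2(21/41)
#' log2_ratio(0, 0)          # 0: pseudocount on both sides
log2_ratio <- function(a, b, pseudo = 1) {
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE), pseudo > 0)
  log2((a + pseudo) / (b + pseudo))
}

# Tile one chromosome into non-overlapping fixed-width windows.
# Trailing partial windows are dropped.  Returns a data.frame with
# 0-based half-open start/end.
tile_windows <- function(chrom, chrom_length, width) {
  n <- floor(chrom_length / width)
  if (n < 1L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(seq.int(0L, by = width, length.out = n))
  data.frame(chrom = rep(chrom, n), start = start, end = start + as.integer(width),
             stringsAsFactors = FALSE)
}

# Tile a whole genome (named vector of chromosome lengths).
tile_genome <- function(genome, width) {
  out <- lapply(names(genome), function(ch) tile_windows(ch, genome[[ch]], width))
  do.call(rbind, out)
}

# Count sorted points falling in [start, end) for each of a set of windows
# on the same chromosome.  `points` must be sorted ascending.
count_in_windows <- function(points, start, end) {
  if (length(points) == 0L) return(integer(length(start)))
  lo <- findInterval(start - 0.5, points)   # points < start
  hi <- findInterval(end - 0.5, points)     # points < end
  as.integer(hi - lo)
}

# Extract the points of a sorted vector lying in [start, end) (scalar window).
points_in_window <- function(points, start, end) {
  if (length(points) == 0L) return(integer(0))
  lo <- findInterval(start - 0.5, points)
  hi <- findInterval(end - 0.5, points)
  if (hi <= lo) return(integer(0))
  points[(lo + 1L):hi]
}

# Split sizes for rank-based grouping: `n` items into `k` groups whose sizes
# differ by at most one, remainder assigned to the lowest-ranked groups first.
rank_group_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  base + as.integer(seq_len(k) <= rem)
}

# Standardize a numeric vector (guarding zero variance).
standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Validate a genome specification: named vector of positive lengths.
check_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome must be a named vector of chromosome lengths")
  }
  if (any(genome <= 0)) stop("chromosome lengths must be positive")
  invisible(genome)
}
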