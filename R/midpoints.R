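# Nucleosome midpoint inference.
#
# Single-end libraries: the mean fragment length is estimated from the
# lag that maximizes the covariation (Pearson correlation) of per-base 5'
# read-depth between the forward and reverse strands, and each read is
# shifted by half that length towards the dyad.  Paired-end libraries:
# fragments are filtered to the central 95% of the length distribution
# and midpoints taken between the pair ends.

# Split reads into 5'-end coordinates per strand.
# Forward reads: 5' end = start.  Reverse reads: 5' end = end - 1
# (the rightmost base in 0-based half-open coordinates).
five_prime_ends <- function(reads) {
  fwd <- reads[reads$strand == "+", , drop = FALSE]
  rev <- reads[reads$strand == "-", , drop = FALSE]
  list(fwd = data.frame(chrom = fwd$chrom, pos = fwd$start, stringsAsFactors = FALSE),
       rev = data.frame(chrom = rev$chrom, pos = rev$end - 1L, stringsAsFactors = FALSE))
}

#' Estimate the fragment-length offset from strand covariation
#'
#' Builds per-base 5'-end depth tracks for each strand and, for every lag
#' `d` in `0..max_lag`, scores the Pearson correlation between forward
#' depth at `x` and reverse depth at `x + d`, pooled across chromosomes.
#' The best lag estimates the distance between the outermost fragment
#' bases, so the mean fragment length is `best_lag + 1` and the dyad
#' shift is half of it.
#'
#' @param fwd_starts,rev_starts 5'-end coordinates: either numeric
#'   vectors (single chromosome) or data.frames with `chrom`, `pos`.
#' @param max_lag Largest lag scanned (bp).
#' @return An object of class `offset_estimate`: list with `best_lag`,
#'   `fragment_length_hat` (= `best_lag + 1`), `shift`
#'   (= `round(fragment_length_hat / 2)`) and `profile` (data.frame
#'   `lag`, `score`).
#' @export
estimate_strand_offset <- function(fwd_starts, rev_starts, max_lag = 400L) {
  stopifnot(max_lag >= 1L)
  if (length(fwd_starts) == 0L || length(rev_starts) == 0L) {
    stop("cannot estimate offset: one strand has no reads")
  }
  if (is.numeric(fwd_starts)) {
    fwd_starts <- data.frame(chrom = "chr", pos = fwd_starts, stringsAsFactors = FALSE)
  }
  if (is.numeric(rev_starts)) {
    rev_starts <- data.frame(chrom = "chr", pos = rev_starts, stringsAsFactors = FALSE)
  }
  if (nrow(fwd_starts) == 0L || nrow(rev_starts) == 0L) {
    stop("cannot estimate offset: one strand has no reads")
  }
  max_lag <- as.integer(max_lag)
  lags <- 0:max_lag
  nl <- length(lags)
  # pooled per-lag sufficient statistics
  n_d <- Sf <- Sf2 <- Sr <- Sr2 <- Sfr <- numeric(nl)
  chroms <- intersect(unique(fwd_starts$chrom), unique(rev_starts$chrom))
  for (ch in chroms) {
    fp <- fwd_starts$pos[fwd_starts$chrom == ch]
    rp <- rev_starts$pos[rev_starts$chrom == ch]
    lo <- min(fp, rp); hi <- max(fp, rp) + max_lag  # pad so no lag clips a read
    L <- hi - lo + 1L
    f <- tabulate(fp - lo + 1L, nbins = L)
    r <- tabulate(rp - lo + 1L, nbins = L)
    csf <- cumsum(f); csf2 <- cumsum(f^2)
    csr <- c(0, cumsum(r)); csr2 <- c(0, cumsum(r^2))
    for (k in seq_len(nl)) {
      d <- lags[k]
      m <- L - d
      if (m < 2L) next
      n_d[k] <- n_d[k] + m
      Sf[k] <- Sf[k] + csf[m]
      Sf2[k] <- Sf2[k] + csf2[m]
      Sr[k] <- Sr[k] + csr[L + 1L] - csr[d + 1L]
      Sr2[k] <- Sr2[k] + csr2[L + 1L] - csr2[d + 1L]
      Sfr[k] <- Sfr[k] + sum(f[1:m] * r[(d + 1L):L])
    }
  }
  vf <- Sf2 - Sf^2 / n_d
  vr <- Sr2 - Sr^2 / n_d
  score <- ifelse(n_d >= 2L & vf > 1e-12 & vr > 1e-12,
                  (Sfr - Sf * Sr / n_d) / sqrt(vf * vr), NA_real_)
  if (all(is.na(score))) stop("cannot estimate offset: flat read depth")
  best_lag <- lags[which.max(score)]
  flh <- best_lag + 1L
  structure(list(best_lag = best_lag, fragment_length_hat = flh,
                 shift = as.integer(round(flh / 2)),
                 profile = data.frame(lag = lags, score = score)),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat("<offset_estimate> best_lag=", x$best_lag, " bp, fragment_length_hat=",
      x$fragment_length_hat, " bp, shift=", x$shift, " bp\n", sep = "")
  invisible(x)
}

#' @export
plot.offset_estimate <- function(x, ...) {
  plot(x$profile$lag, x$profile$score, type = "l", xlab = "lag (bp)",
       ylab = "forward/reverse depth correlation", ...)
  graphics::abline(v = x$best_lag, lty = 2)
  invisible(x)
}

#' Infer midpoints from single-end reads
#'
#' Forward reads map to `5' start + shift`; reverse reads to
#' `5' end - shift`.  Reads with unknown strand are skipped and counted;
#' midpoints falling outside the chromosome are dropped and counted.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param shift Dyad shift in bp (typically `offset_estimate$shift`).
#' @param genome Optional named vector of chromosome lengths used to drop
#'   out-of-range midpoints (negative coordinates are always dropped).
#' @param label Track label.
#' @return A [midpoint_track]; attributes `n_skipped_strand` and
#'   `n_dropped` count discarded reads.
#' @export
midpoints_from_single_end <- function(reads, shift, genome = NULL, label = "total") {
  stopifnot(shift >= 0)
  known <- reads$strand %in% c("+", "-")
  n_skipped <- sum(!known)
  reads <- reads[known, , drop = FALSE]
  mid <- ifelse(reads$strand == "+",
                reads$start + shift,
                (reads$end - 1L) - shift)
  keep <- mid >= 0
  if (!is.null(genome)) keep <- keep & mid < as.numeric(genome[reads$chrom])
  n_dropped <- sum(!keep)
  track <- midpoint_track(data.frame(chrom = reads$chrom[keep],
                                     pos = as.integer(mid[keep]),
                                     stringsAsFactors = FALSE), label = label)
  attr(track, "n_skipped_strand") <- n_skipped
  attr(track, "n_dropped") <- n_dropped
  track
}

#' Filter read pairs to the central mass of the fragment-length distribution
#'
#' Bounds are the empirical nearest-rank quantiles at
#' `(1 - central_mass)/2` and `1 - (1 - central_mass)/2`, rounded outward
#' to integers; pairs whose length lies in `[low, high]` (boundaries
#' inclusive) are kept.
#'
#' @param pairs data.frame of fragments with `fragment_length` (or
#'   `start`/`end`, from which lengths are computed).
#' @param central_mass Fraction of the distribution to keep (default
#'   0.95, the conventional central-95% filter).
#' @return A list: `pairs` (kept rows), `bounds` (`c(low, high)`),
#'   `kept_fraction`.
#' @export
fragment_size_filter <- function(pairs, central_mass = 0.95) {
  if (central_mass <= 0 || central_mass >= 1) stop("central_mass must be in (0, 1)")
  len <- if (!is.null(pairs$fragment_length) && !all(is.na(pairs$fragment_length))) {
    pairs$fragment_length
  } else {
    pairs$end - pairs$start
  }
  n <- length(len)
  if (n < 40L) stop("too few pairs (", n, ") for stable quantile bounds")
  s <- sort(len)
  p_lo <- (1 - central_mass) / 2
  p_hi <- 1 - p_lo
  low <- floor(s[max(1L, ceiling(p_lo * n))])
  high <- ceiling(s[max(1L, ceiling(p_hi * n))])
  keep <- len >= low & len <= high
  list(pairs = pairs[keep, , drop = FALSE],
       bounds = c(low = as.integer(low), high = as.integer(high)),
       kept_fraction = mean(keep))
}

#' Infer midpoints from read pairs
#'
#' The midpoint of a fragment `[start, end)` is
#' `floor((start + end - 1) / 2)` (even-length fragments round down).
#'
#' @param pairs data.frame of fragments with `chrom`, `start`, `end`.
#' @param label Track label.
#' @return A [midpoint_track].
#' @export
midpoints_from_pairs <- function(pairs, label = "total") {
  mid <- (pairs$start + pairs$end - 1L) %/% 2L
  midpoint_track(data.frame(chrom = pairs$chrom, pos = mid,
                            stringsAsFactors = FALSE), label = label)
}
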