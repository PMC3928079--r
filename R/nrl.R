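# Phasogram-based nucleosome repeat length (NRL) estimation stratified by
# HMGD1/H1 ratio quintile, and the MNase gel-ladder NRL regression with
# extrapolation to digestion time zero.

#' Stratify tiling regions into HMGD1/H1 ratio quintiles
#'
#' The genome is tiled into non-overlapping regions; each carries the
#' pseudocount-guarded log2 ratio of HMGD1 to H1 ChIP midpoints.  Regions
#' with no reads from either track are excluded before ranking.  Quintile
#' 1 holds the lowest ratios and quintile 5 the highest; ties break by
#' genomic order and sizes differ by at most one (remainder to the lower
#' quintiles).
#'
#' @param hmgd,h1 [midpoint_track]s.
#' @param genome Named vector of chromosome lengths.
#' @param region_size Region width (bp), default 2000.
#' @param pseudo Pseudocount.
#' @return data.frame of regions: `chrom`, `start`, `end`, `hmgd`, `h1`,
#'   `log_ratio`, `quintile`.
#' @export
ratio_quintiles <- function(hmgd, h1, genome, region_size = 2000L, pseudo = 1) {
  stopifnot(inherits(hmgd, "midpoint_track"), inherits(h1, "midpoint_track"))
  if (hmgd$n_total == 0L || h1$n_total == 0L) stop("empty midpoint track")
  check_genome(genome)
  reg <- tile_genome(genome, region_size)
  nh <- n1 <- integer(nrow(reg))
  for (ch in names(genome)) {
    ri <- which(reg$chrom == ch)
    if (!length(ri)) next
    nh[ri] <- count_in_windows(hmgd$midpoints[[ch]], reg$start[ri], reg$end[ri])
    n1[ri] <- count_in_windows(h1$midpoints[[ch]], reg$start[ri], reg$end[ri])
  }
  reg$hmgd <- nh
  reg$h1 <- n1
  reg <- reg[nh + n1 > 0L, , drop = FALSE]
  if (nrow(reg) < 5L) stop("fewer than 5 regions with reads")
  reg$log_ratio <- log2_ratio(reg$hmgd, reg$h1, pseudo)
  n <- nrow(reg)
  sizes <- rank_group_sizes(n, 5L)
  q <- integer(n)
  q[order(reg$log_ratio, seq_len(n))] <- rep.int(1:5, sizes)
  reg$quintile <- q
  rownames(reg) <- NULL
  reg
}

#' Phasogram: anchor-to-midpoint separation histogram
#'
#' Within each region, every ordered pair of total-track midpoints
#' `(a, m)` with `1 <= m - a <= max_distance` increments the count at
#' separation `m - a`; pairs never cross region boundaries.  One
#' phasogram is returned per quintile present in `regions` (regions
#' lacking a `quintile` column form a single stratum).
#'
#' @param total A [midpoint_track] of total nucleosome midpoints.
#' @param regions data.frame of regions (`chrom`, `start`, `end`,
#'   optional `quintile`).
#' @param max_distance Largest separation (bp); must be smaller than the
#'   region width.
#' @return Named list of `phasogram` objects (one per quintile), each a
#'   list with `quintile`, `counts` (integer vector indexed by distance
#'   `1..max_distance`) and `max_distance`.
#' @export
phasogram <- function(total, regions, max_distance = 1200L) {
  stopifnot(inherits(total, "midpoint_track"))
  if (is.null(regions$quintile)) regions$quintile <- 1L
  if (any(max_distance >= regions$end - regions$start)) {
    stop("max_distance must be smaller than the region size")
  }
  max_distance <- as.integer(max_distance)
  quintiles <- sort(unique(regions$quintile))
  counts <- lapply(quintiles, function(q) integer(max_distance))
  names(counts) <- as.character(quintiles)
  for (i in seq_len(nrow(regions))) {
    m <- points_in_window(total$midpoints[[regions$chrom[i]]],
                          regions$start[i], regions$end[i])
    if (length(m) < 2L) next
    d <- as.vector(outer(m, m, "-"))
    d <- d[d >= 1L & d <= max_distance]
    if (length(d)) {
      q <- as.character(regions$quintile[i])
      counts[[q]] <- counts[[q]] + tabulate(d, nbins = max_distance)
    }
  }
  out <- lapply(quintiles, function(q) {
    structure(list(quintile = q, counts = counts[[as.character(q)]],
                   max_distance = max_distance),
              class = "phasogram")
  })
  names(out) <- paste0("Q", quintiles)
  out
}

#' @export
print.phasogram <- function(x, ...) {
  cat("<phasogram> quintile ", x$quintile, ", ", sum(x$counts),
      " pairs, max distance ", x$max_distance, " bp\n", sep = "")
  invisible(x)
}

#' @export
plot.phasogram <- function(x, ...) {
  plot(seq_along(x$counts), x$counts, type = "l",
       xlab = "anchor distance (bp)", ylab = "pair count", ...)
  invisible(x)
}

# Edge-renormalized Gaussian smoothing of a non-negative count vector.
gaussian_smooth <- function(x, sd, trunc = 3) {
  if (sd <= 0) return(as.numeric(x))
  h <- ceiling(trunc * sd)
  k <- dnorm(-h:h, sd = sd)
  n <- length(x)
  xp <- c(rep(0, h), x, rep(0, h))
  op <- c(rep(0, h), rep(1, n), rep(0, h))
  num <- stats::filter(xp, k, sides = 2)
  den <- stats::filter(op, k, sides = 2)
  as.numeric(num[(h + 1):(h + n)] / den[(h + 1):(h + n)])
}

#' Detect phasing peaks in a phasogram
#'
#' Counts are smoothed with a truncated Gaussian kernel
#' (edge-renormalized, so total mass is preserved away from the ends);
#' local maxima within `[min_separation, max_distance - 3 * smooth_sd]`
#' are kept greedily in decreasing height subject to a mutual distance of
#' at least `min_separation`, then returned sorted ascending and numbered
#' `1..k`.  `min_separation` of 120 bp excludes the sub-nucleosomal
#' shoulder.
#'
#' @param phas A `phasogram`.
#' @param smooth_sd Gaussian kernel SD (bp).
#' @param min_separation Minimum distance between reported peaks (bp);
#'   also the lower bound of the search window.
#' @param min_peaks Minimum number of peaks required.
#' @return data.frame with `index` (1..k) and `position` (bp).
#' @export
detect_peaks <- function(phas, smooth_sd = 5, min_separation = 120L,
                         min_peaks = 2L) {
  stopifnot(inherits(phas, "phasogram"), length(phas$counts) > 0L)
  s <- gaussian_smooth(phas$counts, smooth_sd)
  n <- length(s)
  lo <- max(2L, as.integer(min_separation))
  hi <- min(n - 1L, as.integer(phas$max_distance - 3 * smooth_sd))
  if (hi <= lo) stop("insufficient phasing: empty search window")
  idx <- lo:hi
  is_max <- s[idx] > s[idx - 1L] & s[idx] >= s[idx + 1L]
  cand <- idx[is_max]
  cand <- cand[order(-s[cand])]
  picked <- integer(0)
  for (p in cand) {
    if (all(abs(picked - p) >= min_separation)) picked <- c(picked, p)
  }
  picked <- sort(picked)
  if (length(picked) < min_peaks) stop("insufficient phasing: fewer than ",
                                       min_peaks, " peaks detected")
  data.frame(index = seq_along(picked), position = picked)
}

#' Fit the nucleosome repeat length from phasing peaks
#'
#' Ordinary least squares of peak position on peak index; the slope is
#' the NRL.  Exact (r-squared 1) on arithmetic-progression peaks.
#'
#' @param peaks data.frame from [detect_peaks()] (`index`, `position`).
#' @param intercept Include an intercept (default TRUE); the no-intercept
#'   variant forces the regression line through the origin.
#' @return Object of class `nrl_fit`: list with `nrl` (slope, bp),
#'   `intercept`, `r_squared`, `peaks`.
#' @export
fit_nrl <- function(peaks, intercept = TRUE) {
  if (nrow(peaks) < 2L) stop("need at least 2 peaks to fit an NRL")
  fit <- if (intercept) lm(position ~ index, data = peaks)
         else lm(position ~ index - 1, data = peaks)
  co <- coef(fit)
  slope <- unname(co[["index"]])
  icpt <- if (intercept) unname(co[["(Intercept)"]]) else 0
  ssr <- sum(residuals(fit)^2)
  sst <- sum((peaks$position - mean(peaks$position))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  structure(list(nrl = slope, intercept = icpt, r_squared = r2, peaks = peaks),
            class = "nrl_fit")
}

#' @export
print.nrl_fit <- function(x, digits = 4, ...) {
  cat("NRL = ", format(x$nrl, digits = digits), " bp (",
      nrow(x$peaks), " peaks, r^2 = ", format(x$r_squared, digits = digits),
      ")\n", sep = "")
  invisible(x)
}

#' @export
plot.nrl_fit <- function(x, ...) {
  plot(x$peaks$index, x$peaks$position, xlab = "peak number",
       ylab = "peak position (bp)", ...)
  graphics::abline(x$intercept, x$nrl, lty = 2)
  invisible(x)
}

#' Estimate per-quintile NRLs with the full phasogram pipeline
#'
#' Convenience wrapper: phasogram per quintile, peak detection and
#' least-squares NRL fit.
#'
#' @param total A [midpoint_track] of total nucleosome midpoints.
#' @param regions Output of [ratio_quintiles()] (or any region table with
#'   a `quintile` column).
#' @param max_distance,smooth_sd,min_separation,min_peaks Passed through.
#' @param intercept Passed to [fit_nrl()].
#' @return data.frame with `quintile`, `nrl`, `n_peaks`, `r_squared`.
#' @export
estimate_nrl_by_quintile <- function(total, regions, max_distance = 1200L,
                                     smooth_sd = 5, min_separation = 120L,
                                     min_peaks = 2L, intercept = TRUE) {
  ph <- phasogram(total, regions, max_distance)
  rows <- lapply(ph, function(p) {
    pk <- detect_peaks(p, smooth_sd, min_separation, min_peaks)
    fit <- fit_nrl(pk, intercept)
    data.frame(quintile = p$quintile, nrl = fit$nrl, n_peaks = nrow(pk),
               r_squared = fit$r_squared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' NRL from MNase gel ladders, extrapolated to digestion time zero
#'
#' For each digestion time point the NRL is the OLS slope of polynucleosome
#' band size on band number; the NRL at time zero is the intercept of the
#' OLS regression of those per-time NRLs on time.  Time points with a
#' single band are dropped with a warning; with a single usable time point
#' no extrapolation is performed.
#'
#' @param bands data.frame with `time` (minutes), `band` (number) and
#'   `size` (bp).
#' @return Object of class `ladder_nrl`: list with `nrl0` (bp),
#'   `per_time` (data.frame `time`, `nrl`) and `extrapolated` (logical).
#' @export
nrl_from_ladder <- function(bands) {
  stopifnot(all(c("time", "band", "size") %in% names(bands)))
  per <- lapply(split(bands, bands$time), function(b) {
    if (nrow(b) < 2L) return(NULL)
    data.frame(time = b$time[1L],
               nrl = unname(coef(lm(size ~ band, data = b))[["band"]]))
  })
  dropped <- sum(vapply(per, is.null, TRUE))
  if (dropped) warning(dropped, " time point(s) with a single band dropped")
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0L) stop("no time point with >= 2 bands")
  rownames(per) <- NULL
  if (nrow(per) == 1L) {
    return(structure(list(nrl0 = per$nrl[1L], per_time = per,
                          extrapolated = FALSE), class = "ladder_nrl"))
  }
  fit <- lm(nrl ~ time, data = per)
  structure(list(nrl0 = unname(coef(fit)[["(Intercept)"]]), per_time = per,
                 extrapolated = TRUE), class = "ladder_nrl")
}

#' @export
print.ladder_nrl <- function(x, digits = 4, ...) {
  cat("NRL at time 0 = ", format(x$nrl0, digits = digits), " bp",
      if (!x$extrapolated) " (single time point, no extrapolation)", "\n",
      sep = "")
  invisible(x)
}
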