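# Correlation and model-comparison statistics: occupancy rates vs
# expression, DHS-distance window statistics, and PTM correlation
# clustering.

#' Pearson correlation with Fisher-z confidence interval
#'
#' The confidence interval is `tanh(atanh(R) +/- z* / sqrt(n - 3))`; the
#' two-sided p-value comes from the t distribution with `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, non-degenerate.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `cor_ci`: list with `R`, `n`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate input: zero variance")
  R <- cor(x, y)
  zcrit <- qnorm((1 + conf) / 2)
  if (abs(R) >= 1) {
    ci <- c(R, R)
  } else {
    z <- atanh(R)
    ci <- tanh(z + c(-1, 1) * zcrit / sqrt(n - 3))
  }
  tstat <- R * sqrt((n - 2) / max(1 - R^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  structure(list(R = R, n = n, ci_low = ci[1], ci_high = ci[2], p = p),
            class = "cor_ci")
}

#' @export
print.cor_ci <- function(x, digits = 3, ...) {
  cat("Pearson R = ", format(x$R, digits = digits),
      "  95% CI [", format(x$ci_low, digits = digits), ", ",
      format(x$ci_high, digits = digits), "]  n = ", x$n,
      "  p = ", format(x$p, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Nested linear-model F-test for a second predictor
#'
#' Compares the full model `response ~ predictor_a + predictor_b` with
#' the reduced model `response ~ predictor_a` by the usual extra
#' sum-of-squares F statistic with 1 numerator df:
#' `F = (sse_reduced - sse_full) / (sse_full / (n - 3))`.
#' A perfectly fitting full model reports `F = Inf`, `p = 0`; a collinear
#' second predictor (no SSE reduction possible) reports `F = 0`.
#'
#' @param response,predictor_a,predictor_b Numeric vectors, n > 3.
#' @return Object of class `model_comparison`: list with `F`, `df_num`,
#'   `df_den`, `p`, `sse_full`, `sse_reduced`.
#' @export
nested_f_test <- function(response, predictor_a, predictor_b) {
  n <- length(response)
  stopifnot(length(predictor_a) == n, length(predictor_b) == n)
  if (n <= 3L) stop("need more than 3 observations")
  if (sd(predictor_a) == 0) stop("reduced-model design matrix is rank deficient")
  full <- lm(response ~ predictor_a + predictor_b)
  reduced <- lm(response ~ predictor_a)
  sse_full <- sum(residuals(full)^2)
  sse_reduced <- sum(residuals(reduced)^2)
  df_den <- n - 3L
  num <- max(sse_reduced - sse_full, 0)
  if (sse_full <= .Machine$double.eps * sse_reduced) {
    Fstat <- if (num > 0) Inf else 0
  } else {
    Fstat <- num / (sse_full / df_den)
  }
  p <- if (is.infinite(Fstat)) 0 else pf(Fstat, 1, df_den, lower.tail = FALSE)
  structure(list(F = Fstat, df_num = 1L, df_den = df_den, p = p,
                 sse_full = sse_full, sse_reduced = sse_reduced),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("F(", x$df_num, ", ", x$df_den, ") = ", format(x$F, digits = digits),
      ",  p = ", format(x$p, digits = digits), "\n", sep = "")
  invisible(x)
}

# Per-base distance to the nearest DHS for every position of a
# chromosome (0 inside a DHS, nearest-edge distance outside).
dhs_distance_per_base <- function(chrom_length, dhs_start, dhs_end) {
  pos <- seq.int(0L, chrom_length - 1L)
  if (length(dhs_start) == 0L) return(rep(Inf, chrom_length))
  ir <- IRanges::reduce(IRanges::IRanges(dhs_start + 1L, dhs_end))
  s <- IRanges::start(ir) - 1L; e <- IRanges::end(ir)
  i <- findInterval(pos, s)                 # last DHS starting at or before pos
  # distance past the end of the previous DHS (<= 0 means inside it)
  d_prev <- ifelse(i >= 1L, pos - (e[pmax(i, 1L)] - 1L), Inf)
  d_next <- ifelse(i < length(s), s[pmin(i + 1L, length(s))] - pos, Inf)
  pmin(pmax(d_prev, 0), d_next)
}

#' Window statistics relative to DNase I hypersensitive sites
#'
#' The genome is tiled into non-overlapping fixed-width windows.  Each
#' window carries `dhs_dist = log2(mean per-base distance to the nearest
#' DHS + 1)` (0 inside a DHS), `hmgd_val`/`h1_val = log2(mean midpoint
#' depth + pseudo)` and `tss_dist`, the distance from the window midpoint
#' to the nearest TSS (Inf when the annotation is empty).
#'
#' @param dhs data.frame of DHS intervals (`chrom`, `start`, `end`).
#' @param hmgd,h1 [midpoint_track]s.
#' @param genes A [gene_models] (may have zero rows).
#' @param genome Named vector of chromosome lengths.
#' @param window Window width (bp), default 1000.
#' @param pseudo Pseudocount on mean depths.
#' @return data.frame of window statistics with `ratio =
#'   hmgd_val - h1_val`.
#' @export
dhs_window_stats <- function(dhs, hmgd, h1, genes, genome, window = 1000L,
                             pseudo = 1) {
  if (nrow(dhs) == 0L) stop("DHS set is empty")
  check_genome(genome)
  wins <- tile_genome(genome, window)
  n <- nrow(wins)
  dd <- hv <- ov <- td <- numeric(n)
  for (ch in names(genome)) {
    wi <- which(wins$chrom == ch)
    if (!length(wi)) next
    di <- dhs[dhs$chrom == ch, , drop = FALSE]
    pb <- dhs_distance_per_base(genome[[ch]], di$start, di$end)
    csum <- c(0, cumsum(pb))
    mean_dist <- (csum[wins$end[wi] + 1L] - csum[wins$start[wi] + 1L]) / window
    dd[wi] <- log2(mean_dist + 1)
    hv[wi] <- log2(count_in_windows(hmgd$midpoints[[ch]], wins$start[wi],
                                    wins$end[wi]) / window + pseudo)
    ov[wi] <- log2(count_in_windows(h1$midpoints[[ch]], wins$start[wi],
                                    wins$end[wi]) / window + pseudo)
    gi <- which(genes$chrom == ch)
    if (length(gi)) {
      tss <- sort(genes$tss[gi])
      centre <- wins$start[wi] + window %/% 2L
      right <- findInterval(centre, tss)
      d_prev <- ifelse(right >= 1L, centre - tss[pmax(right, 1L)], Inf)
      d_next <- ifelse(right < length(tss), tss[pmin(right + 1L, length(tss))] - centre, Inf)
      td[wi] <- pmin(d_prev, d_next)
    } else {
      td[wi] <- Inf
    }
  }
  wins$dhs_dist <- dd
  wins$hmgd_val <- hv
  wins$h1_val <- ov
  wins$ratio <- hv - ov
  wins$tss_dist <- td
  wins
}

#' Drop TSS-proximal windows
#'
#' Keeps windows whose `tss_dist` is at least `cutoff` bp (the boundary
#' itself is kept).  With no genes all windows survive.
#'
#' @param stats Output of [dhs_window_stats()].
#' @param cutoff Minimum TSS distance (bp).
#' @return Filtered data.frame.
#' @export
exclude_tss_proximal <- function(stats, cutoff = 2000L) {
  stopifnot(!is.null(stats$tss_dist))
  stats[stats$tss_dist >= cutoff, , drop = FALSE]
}

# Mean track value per window (overlap-weighted); NA when nothing overlaps.
mean_track_in_windows <- function(track_df, wins) {
  out <- rep(NA_real_, nrow(wins))
  for (ch in unique(wins$chrom)) {
    wi <- which(wins$chrom == ch)
    ti <- which(track_df$chrom == ch)
    if (!length(ti)) next
    wr <- IRanges::IRanges(wins$start[wi] + 1L, wins$end[wi])
    tr <- IRanges::IRanges(track_df$start[ti] + 1L, track_df$end[ti])
    hits <- IRanges::findOverlaps(wr, tr)
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(wr[q], tr[s]))
    v <- track_df$value[ti][s]
    num <- tapply(ov * v, q, sum)
    den <- tapply(ov, q, sum)
    out[wi[as.integer(names(num))]] <- num / den
  }
  out
}

#' Cluster CAP occupancy with histone-PTM tracks at TSSs
#'
#' Takes fixed-width windows around every TSS, computes the mean signal
#' of each PTM track and the pseudocount-guarded log2 ratio of each ChIP
#' track to total nucleosomes per window, then the pairwise Pearson
#' correlation matrix across windows and an average-linkage hierarchical
#' clustering with distance `1 - R`.
#'
#' @param ptm_tracks Named list of bedGraph-style data.frames.
#' @param hmgd,h1,total [midpoint_track]s.
#' @param genes A [gene_models] with at least 3 genes.
#' @param genome Named vector of chromosome lengths.
#' @param width TSS window width (bp), default 2000.
#' @param pseudo Pseudocount.
#' @return Object of class `ptm_clustering`: list with `values` (windows
#'   x experiments matrix), `correlation`, `hclust` and `excluded`
#'   (constant experiments dropped with a warning).
#' @export
ptm_cluster <- function(ptm_tracks, hmgd, h1, total, genes, genome,
                        width = 2000L, pseudo = 1) {
  stopifnot(length(ptm_tracks) >= 1L, nrow(genes) >= 3L)
  check_genome(genome)
  half <- width %/% 2L
  chrlen <- as.integer(genome[genes$chrom])
  wins <- data.frame(chrom = genes$chrom,
                     start = pmax(0L, genes$tss - half),
                     end = pmin(chrlen, genes$tss + half),
                     stringsAsFactors = FALSE)
  vals <- sapply(ptm_tracks, mean_track_in_windows, wins = wins)
  cap_val <- function(track) {
    cnt <- numeric(nrow(wins))
    tot <- numeric(nrow(wins))
    for (ch in unique(wins$chrom)) {
      wi <- which(wins$chrom == ch)
      cnt[wi] <- count_in_windows(track$midpoints[[ch]], wins$start[wi], wins$end[wi])
      tot[wi] <- count_in_windows(total$midpoints[[ch]], wins$start[wi], wins$end[wi])
    }
    log2_ratio(cnt, tot, pseudo)
  }
  mat <- cbind(vals, HMGD1 = cap_val(hmgd), H1 = cap_val(h1))
  keep_rows <- stats::complete.cases(mat)
  mat <- mat[keep_rows, , drop = FALSE]
  if (ncol(mat) < 2L) stop("need at least 2 experiments")
  if (nrow(mat) < 3L) stop("need at least 3 TSS windows")
  sds <- apply(mat, 2L, sd)
  excluded <- colnames(mat)[sds == 0]
  if (length(excluded)) {
    warning("excluding constant experiment(s): ", paste(excluded, collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  C <- cor(mat)
  D <- stats::as.dist(1 - C)
  hc <- stats::hclust(D, method = "average")
  structure(list(values = mat, correlation = C, hclust = hc,
                 excluded = excluded),
            class = "ptm_clustering")
}

#' @export
print.ptm_clustering <- function(x, ...) {
  cat("<ptm_clustering> ", ncol(x$values), " experiments over ",
      nrow(x$values), " TSS windows\n", sep = "")
  print(x$hclust)
  invisible(x)
}

#' @export
plot.ptm_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", main = "1 - R, average linkage", ...)
  invisible(x)
}
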