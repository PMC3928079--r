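# Expression quantification, genomic feature classification, midpoint
# densities, strand-oriented TSS aggregate profiles and per-promoter
# occupancy rates.

#' Reads per kilobase of exonic length per million mapped reads
#'
#' `RPKM = (count + 1) / ((exonic_length/1000) * (mapped_total/1e6))`.
#' The pseudocount keeps log-expression finite for unexpressed genes.
#'
#' @param count Exon tag count (vectorized).
#' @param exonic_length Merged exonic length in bp.
#' @param mapped_total Total mapped tags in the library.
#' @return Numeric vector of RPKM values.
#' @export
#' @examples
#' compute_rpkm(0, 1000, 1e6)   # 1: pseudocount only
#' compute_rpkm(99, 2000, 1e7)  # 5
compute_rpkm <- function(count, exonic_length, mapped_total) {
  if (any(exonic_length <= 0)) stop("exonic_length must be positive")
  if (any(mapped_total <= 0)) stop("mapped_total must be positive")
  (count + 1) / ((exonic_length / 1000) * (mapped_total / 1e6))
}

#' Build an expression table from tag counts
#'
#' @param counts data.frame with `gene_id`, `count`, `exonic_length`.
#' @param mapped_total Library size; defaults to `sum(count)`.
#' @return data.frame with added `rpkm`, `log_expr` (= log2 RPKM) and
#'   `group` (see [assign_expression_groups()]).
#' @export
expression_table <- function(counts, mapped_total = sum(counts$count)) {
  counts$rpkm <- compute_rpkm(counts$count, counts$exonic_length, mapped_total)
  counts$log_expr <- log2(counts$rpkm)
  assign_expression_groups(counts)
}

#' Assign expression tertile groups
#'
#' Genes are ranked by `log_expr` (ties broken by `gene_id` lexicographic
#' order) and split into `"low"`, `"medium"`, `"high"` thirds whose sizes
#' differ by at most one; remainder genes go to the lower groups first
#' (7 genes split 3/2/2).
#'
#' @param records data.frame with `log_expr` and `gene_id`.
#' @return `records` with an added `group` factor.
#' @export
assign_expression_groups <- function(records) {
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 genes to form expression groups")
  ord <- order(records$log_expr, records$gene_id)
  sizes <- rank_group_sizes(n, 3L)
  grp <- character(n)
  grp[ord] <- rep.int(c("low", "medium", "high"), sizes)
  records$group <- factor(grp, levels = c("low", "medium", "high"))
  records
}

#' Classify genomic positions against an annotation
#'
#' Precedence: promoter > exon > intron > intergenic.  A position is a
#' promoter when its strand-oriented offset from the *nearest* TSS is at
#' most `promoter_bp` in absolute value; the sign of that offset gives
#' the `upstream`/`downstream` sub-label (offset 0, the TSS itself, is
#' downstream).
#'
#' @param chrom,pos Vectors of positions (0-based).
#' @param annotation A [gene_models].
#' @param promoter_bp Promoter half-width (bp) around the TSS.
#' @return data.frame with `class` and `sub` (`NA` outside promoters).
#' @export
classify_position <- function(chrom, pos, annotation, promoter_bp = 1000L) {
  n <- length(pos)
  cls <- rep("intergenic", n)
  sub <- rep(NA_character_, n)
  ex <- attr(annotation, "exons")
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    p <- pos[qi]
    gi <- which(annotation$chrom == ch)
    if (!length(gi)) next
    # intron: inside a gene body (refined to exon below)
    bodies <- IRanges::reduce(IRanges::IRanges(annotation$start[gi] + 1L,
                                               annotation$end[gi]))
    inside_gene <- IRanges::overlapsAny(IRanges::IRanges(p + 1L, p + 1L), bodies)
    cls[qi[inside_gene]] <- "intron"
    # exon
    tx <- annotation$transcript_id[gi]
    ee <- ex[ex$transcript_id %in% tx, , drop = FALSE]
    if (nrow(ee)) {
      er <- IRanges::reduce(IRanges::IRanges(ee$start + 1L, ee$end))
      in_exon <- IRanges::overlapsAny(IRanges::IRanges(p + 1L, p + 1L), er)
      cls[qi[in_exon]] <- "exon"
    }
    # promoter (highest precedence): nearest TSS within promoter_bp
    ord <- gi[order(annotation$tss[gi])]
    tss <- annotation$tss[ord]
    str <- annotation$strand[ord]
    right <- findInterval(p, tss)
    left_i <- pmax(right, 1L)
    right_i <- pmin(right + 1L, length(tss))
    d_left <- abs(p - tss[left_i])
    d_right <- abs(p - tss[right_i])
    nearest <- ifelse(d_left <= d_right, left_i, right_i)
    dist <- pmin(d_left, d_right)
    orient <- ifelse(str[nearest] == "+", p - tss[nearest], tss[nearest] - p)
    in_prom <- dist <= promoter_bp
    cls[qi[in_prom]] <- "promoter"
    sub[qi[in_prom]] <- ifelse(orient[in_prom] < 0, "upstream", "downstream")
  }
  data.frame(class = cls, sub = sub, stringsAsFactors = FALSE)
}

# Build the per-chromosome feature partition (promoter/exon/intron/
# intergenic) as IRanges, honouring the classification precedence.
feature_partition <- function(annotation, genome, promoter_bp = 1000L) {
  ex <- attr(annotation, "exons")
  out <- list()
  for (ch in names(genome)) {
    L <- genome[[ch]]
    chr_all <- IRanges::IRanges(1L, L)
    gi <- which(annotation$chrom == ch)
    if (length(gi)) {
      tss <- annotation$tss[gi]
      prom <- IRanges::reduce(IRanges::IRanges(pmax(1L, tss - promoter_bp + 1L),
                                               pmin(L, tss + promoter_bp + 1L)))
      tx <- annotation$transcript_id[gi]
      ee <- ex[ex$transcript_id %in% tx, , drop = FALSE]
      exon <- if (nrow(ee)) IRanges::reduce(IRanges::IRanges(ee$start + 1L, ee$end))
              else IRanges::IRanges()
      body <- IRanges::reduce(IRanges::IRanges(annotation$start[gi] + 1L,
                                               annotation$end[gi]))
      exon2 <- IRanges::setdiff(exon, prom)
      intron <- IRanges::setdiff(IRanges::setdiff(body, exon), prom)
      inter <- IRanges::setdiff(IRanges::setdiff(IRanges::setdiff(chr_all, prom),
                                                 exon), body)
      out[[ch]] <- list(promoter = prom, exon = exon2, intron = intron,
                        intergenic = inter)
    } else {
      out[[ch]] <- list(promoter = IRanges::IRanges(), exon = IRanges::IRanges(),
                        intron = IRanges::IRanges(), intergenic = chr_all)
    }
  }
  out
}

#' Midpoint density per genomic feature class and per chromosome
#'
#' For each feature class (promoter, exon, intron, intergenic) and each
#' chromosome the density is the read fraction per unit length:
#' `(midpoints in class / n_total) / (bp in class / genome bp)`.  Uniform
#' midpoints therefore give density ~1 everywhere.  Classes with zero bp
#' are excluded with a warning.
#'
#' @param track A [midpoint_track].
#' @param annotation A [gene_models].
#' @param genome Named vector of chromosome lengths.
#' @param promoter_bp Promoter half-width (bp).
#' @return data.frame with rows per (class, chromosome) plus pooled
#'   `"all"` rows: `bp`, `n_midpoints`, `read_fraction`, `density`.
#' @export
region_density_table <- function(track, annotation, genome, promoter_bp = 1000L) {
  stopifnot(inherits(track, "midpoint_track"))
  if (track$n_total == 0L) stop("empty midpoint track")
  check_genome(genome)
  part <- feature_partition(annotation, genome, promoter_bp)
  classes <- c("promoter", "exon", "intron", "intergenic")
  rows <- list()
  for (ch in names(genome)) {
    mp <- track$midpoints[[ch]]
    for (cl in classes) {
      ir <- part[[ch]][[cl]]
      bp <- sum(IRanges::width(ir))
      nm <- if (length(ir) && length(mp)) {
        sum(count_in_windows(mp, IRanges::start(ir) - 1L, IRanges::end(ir)))
      } else 0L
      rows[[paste(ch, cl)]] <- data.frame(chrom = ch, class = cl, bp = bp,
                                          n_midpoints = nm,
                                          stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  genome_bp <- sum(as.numeric(genome))
  pooled <- do.call(rbind, lapply(classes, function(cl) {
    sub <- df[df$class == cl, ]
    data.frame(chrom = "all", class = cl, bp = sum(sub$bp),
               n_midpoints = sum(sub$n_midpoints), stringsAsFactors = FALSE)
  }))
  df <- rbind(df, pooled)
  zero <- df$bp == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " feature class(es) with zero bp")
    df <- df[!zero, , drop = FALSE]
  }
  df$read_fraction <- df$n_midpoints / track$n_total
  df$density <- df$read_fraction / (df$bp / genome_bp)
  df
}

#' Strand-oriented aggregate midpoint profile around TSSs
#'
#' For each gene, midpoint offsets from the TSS are computed
#' strand-aware (negative = upstream of transcription); per-offset counts
#' are summed within each expression group, divided by the group's gene
#' count, then by the track's genome-wide mean per-bp midpoint density,
#' and optionally smoothed with a centred moving average.
#'
#' @param track A [midpoint_track].
#' @param genes A [gene_models].
#' @param genome Named vector of chromosome lengths.
#' @param flank Half-width of the profile (bp).
#' @param groups Optional data.frame `gene_id`, `group`; absent, all
#'   genes form one `"all"` group.
#' @param smooth Moving-average window (bp); `0` disables smoothing.
#' @return An object of class `tss_profile`: data.frame with `offset`,
#'   `group`, `density`; attribute `n_truncated` counts genes whose
#'   flank exceeded the chromosome.
#' @export
tss_aggregate_profile <- function(track, genes, genome, flank = 1000L,
                                  groups = NULL, smooth = 25L) {
  stopifnot(inherits(track, "midpoint_track"), flank > 0)
  check_genome(genome)
  if (is.null(groups)) {
    groups <- data.frame(gene_id = genes$gene_id, group = "all",
                         stringsAsFactors = FALSE)
  }
  grp <- as.character(groups$group[match(genes$gene_id, groups$gene_id)])
  levels_ <- unique(grp[!is.na(grp)])
  offsets <- (-flank):flank
  width <- length(offsets)
  counts <- matrix(0, nrow = width, ncol = length(levels_),
                   dimnames = list(NULL, levels_))
  group_n <- setNames(numeric(length(levels_)), levels_)
  n_trunc <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- grp[i]
    if (is.na(g)) next
    group_n[g] <- group_n[g] + 1
    tss <- genes$tss[i]
    ch <- genes$chrom[i]
    if (tss - flank < 0 || tss + flank >= genome[[ch]]) n_trunc <- n_trunc + 1L
    mp <- points_in_window(track$midpoints[[ch]], tss - flank, tss + flank + 1L)
    if (!length(mp)) next
    off <- if (genes$strand[i] == "+") mp - tss else tss - mp
    tab <- tabulate(off + flank + 1L, nbins = width)
    counts[, g] <- counts[, g] + tab
  }
  mean_density <- track$n_total / sum(as.numeric(genome))
  dens <- sweep(counts, 2L, pmax(group_n, 1), "/") / mean_density
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    dens <- apply(dens, 2L, function(v) {
      s <- stats::filter(v, k, sides = 2)
      as.numeric(ifelse(is.na(s), v, s))
    })
    dens <- matrix(dens, nrow = width, dimnames = list(NULL, levels_))
  }
  out <- data.frame(offset = rep(offsets, times = length(levels_)),
                    group = rep(levels_, each = width),
                    density = as.vector(dens), stringsAsFactors = FALSE)
  structure(out, n_truncated = n_trunc, class = c("tss_profile", "data.frame"))
}

#' @export
plot.tss_profile <- function(x, ...) {
  groups <- unique(x$group)
  rng <- range(x$density, finite = TRUE)
  plot(NULL, xlim = range(x$offset), ylim = rng,
       xlab = "offset from TSS (bp)", ylab = "normalized midpoint density", ...)
  for (i in seq_along(groups)) {
    sub <- x[x$group == groups[i], ]
    graphics::lines(sub$offset, sub$density, col = i)
  }
  graphics::legend("topright", legend = groups, col = seq_along(groups), lty = 1)
  invisible(x)
}

#' Default promoter segments for per-segment correlation analysis
#'
#' Strand-oriented windows (bp relative to the TSS) roughly covering the
#' nucleosome-depleted region and the typical positions of the -3..-1 and
#' +1..+4 nucleosomes.  These boundaries are this package's choices for a
#' positioned-nucleosome segmentation; they are fully configurable.
#'
#' @return Named list of `c(from, to)` half-open oriented windows.
#' @export
default_promoter_segments <- function() {
  list(m3 = c(-675, -500), m2 = c(-500, -325), m1 = c(-325, -150),
       NDR = c(-150, 0), p1 = c(0, 175), p2 = c(175, 350),
       p3 = c(350, 525), p4 = c(525, 700))
}

# Count track midpoints whose strand-oriented offset from each gene's TSS
# lies in [from, to).  Returns an integer vector over genes.
count_oriented_window <- function(track, genes, from, to) {
  n <- nrow(genes)
  out <- integer(n)
  for (i in seq_len(n)) {
    tss <- genes$tss[i]
    mp <- track$midpoints[[genes$chrom[i]]]
    if (is.null(mp)) next
    if (genes$strand[i] == "+") {
      out[i] <- length(points_in_window(mp, tss + from, tss + to))
    } else {
      # oriented offset o = tss - pos in [from, to)  <=>  pos in (tss-to, tss-from]
      out[i] <- length(points_in_window(mp, tss - to + 1L, tss - from + 1L))
    }
  }
  out
}

#' Per-promoter HMGD1 and H1 occupancy rates
#'
#' The HMGD1 rate of a gene is the log2 ratio of HMGD1 ChIP midpoints to
#' total nucleosome midpoints over the oriented promoter window
#' \[-100, +500) bp around the TSS; the H1 rate uses \[-550, +50).  Both
#' ratios carry a pseudocount.  Per-segment log2 rates (HMGD1/total,
#' H1/total and HMGD1/H1) are computed for each configured segment.
#'
#' @param hmgd,h1,total [midpoint_track]s sharing chromosome naming.
#' @param genes A [gene_models].
#' @param segments Named list of oriented windows, as
#'   [default_promoter_segments()].
#' @param hmgd_window,h1_window Oriented windows for the headline rates.
#' @param pseudo Pseudocount.
#' @return data.frame per gene: `gene_id`, `hmgd_rate`, `h1_rate`,
#'   `ratio_rate` (HMGD1/H1 over the HMGD1 window) and per-segment
#'   columns `hmgd_<seg>`, `h1_<seg>`, `ratio_<seg>`.
#' @export
promoter_rates <- function(hmgd, h1, total, genes,
                           segments = default_promoter_segments(),
                           hmgd_window = c(-100, 500),
                           h1_window = c(-550, 50),
                           pseudo = 1) {
  stopifnot(inherits(hmgd, "midpoint_track"), inherits(h1, "midpoint_track"),
            inherits(total, "midpoint_track"))
  ch_h <- count_oriented_window(hmgd, genes, hmgd_window[1], hmgd_window[2])
  ct_h <- count_oriented_window(total, genes, hmgd_window[1], hmgd_window[2])
  c1_1 <- count_oriented_window(h1, genes, h1_window[1], h1_window[2])
  ct_1 <- count_oriented_window(total, genes, h1_window[1], h1_window[2])
  c1_h <- count_oriented_window(h1, genes, hmgd_window[1], hmgd_window[2])
  out <- data.frame(gene_id = genes$gene_id,
                    hmgd_rate = log2_ratio(ch_h, ct_h, pseudo),
                    h1_rate = log2_ratio(c1_1, ct_1, pseudo),
                    ratio_rate = log2_ratio(ch_h, c1_h, pseudo),
                    stringsAsFactors = FALSE)
  for (nm in names(segments)) {
    w <- segments[[nm]]
    h <- count_oriented_window(hmgd, genes, w[1], w[2])
    o <- count_oriented_window(h1, genes, w[1], w[2])
    t <- count_oriented_window(total, genes, w[1], w[2])
    out[[paste0("hmgd_", nm)]] <- log2_ratio(h, t, pseudo)
    out[[paste0("h1_", nm)]] <- log2_ratio(o, t, pseudo)
    out[[paste0("ratio_", nm)]] <- log2_ratio(h, o, pseudo)
  }
  out
}
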