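# Ground-truthed synthetic data: nucleosome arrays with region-specific
# repeat length, competitive HMGD1/H1 linker labelling coupled to gene
# activity, MNase-like fragment libraries, expression counts, DHSs and
# histone-PTM tracks.  Every generated read derives from exactly one
# recorded nucleosome, so each pipeline stage can be validated against
# known truth.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with the study
#' conditions as defaults.
#'
#' @param seed Integer RNG seed.
#' @param genome Named vector of chromosome lengths (bp).
#' @param n_genes Number of genes to place.
#' @param region_size Width (bp) of the non-overlapping regions used for
#'   ratio stratification and truth bookkeeping.
#' @param nrl_by_quintile Five true nucleosome repeat lengths (bp),
#'   ordered from the highest HMGD1/H1-ratio quintile (Q5, shortest
#'   spacing) down to the lowest (Q1, longest): element `i` applies to
#'   quintile `6 - i`.  Defaults span the 174-187 bp range with a wider
#'   165-195 grid available for recovery studies.
#' @param spacing_jitter_sd SD (bp) of nucleosome spacing around the NRL.
#' @param fraglen_mean,fraglen_sd Mean and SD (bp) of MNase fragment
#'   lengths in paired-end libraries; the defaults (146, 23) put the
#'   central 95% of the length distribution at 101-191 bp.
#' @param fraglen_sd_single SD (bp) of fragment lengths in single-end
#'   libraries, which model gel size-selected ChIP libraries and are
#'   therefore much tighter than the bulk MNase digest.
#' @param depth Mean sequenced fragments per nucleosome (Poisson).
#' @param ratio_slope Coupling of the HMGD1-labelling log-odds to
#'   standardized log-expression (unitless).
#' @param noise_sd SD of the additive noise on synthetic PTM tracks.
#' @param gene_length Gene body length (bp).
#' @param read_length Sequenced read length (bp) for single-end output.
#' @param dhs_width Width (bp) of the DHS emitted at active promoters.
#' @param midpoint_blur_sd SD (bp) of the fragment-midpoint displacement
#'   around the true dyad, modelling MNase trimming.
#' @param baseline_nrl NRL (bp) used when spacing is not ratio-coupled.
#' @param expr_mean,expr_sd Mean and SD of true log2-RPKM expression.
#' @param tss_coupling_bp Distance (bp) from a TSS within which a
#'   nucleosome's labelling odds follow that gene's expression.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chrA = 400000L, chrB = 400000L),
                       n_genes = 200L,
                       region_size = 2000L,
                       nrl_by_quintile = c(174, 177, 180, 184, 187),
                       spacing_jitter_sd = 5,
                       fraglen_mean = 146,
                       fraglen_sd = 23,
                       fraglen_sd_single = 4,
                       depth = 20,
                       ratio_slope = 1,
                       noise_sd = 0.5,
                       gene_length = 2000L,
                       read_length = 35L,
                       dhs_width = 200L,
                       midpoint_blur_sd = 3,
                       baseline_nrl = 180,
                       expr_mean = 2,
                       expr_sd = 2,
                       tss_coupling_bp = 1000L) {
  check_genome(genome)
  stopifnot(n_genes >= 0, region_size > 0, length(nrl_by_quintile) == 5,
            all(nrl_by_quintile > 147), spacing_jitter_sd >= 0,
            fraglen_mean > 0, fraglen_sd >= 0, fraglen_sd_single >= 0,
            depth > 0, noise_sd >= 0, gene_length > 0, read_length > 0,
            dhs_width > 0, midpoint_blur_sd >= 0, baseline_nrl > 147)
  structure(list(seed = as.integer(seed), genome = genome,
                 n_genes = as.integer(n_genes),
                 region_size = as.integer(region_size),
                 nrl_by_quintile = nrl_by_quintile,
                 spacing_jitter_sd = spacing_jitter_sd,
                 fraglen_mean = fraglen_mean, fraglen_sd = fraglen_sd,
                 fraglen_sd_single = fraglen_sd_single, depth = depth,
                 ratio_slope = ratio_slope, noise_sd = noise_sd,
                 gene_length = as.integer(gene_length),
                 read_length = as.integer(read_length),
                 dhs_width = as.integer(dhs_width),
                 midpoint_blur_sd = midpoint_blur_sd,
                 baseline_nrl = baseline_nrl,
                 expr_mean = expr_mean, expr_sd = expr_sd,
                 tss_coupling_bp = as.integer(tss_coupling_bp)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed=", x$seed, ", genome=", sum(x$genome), " bp (",
      length(x$genome), " chrom), n_genes=", x$n_genes, "\n", sep = "")
  invisible(x)
}

#' Simulate a gene annotation with expression and DHSs
#'
#' Genes of fixed length are placed uniformly without overlap on each
#' chromosome (allocated proportionally to chromosome length), with
#' alternating strands.  True log2 expression is drawn from
#' Normal(`expr_mean`, `expr_sd`).  Each gene gets two exons separated by
#' an intron.  A DHS of width `dhs_width` centred on the TSS is emitted
#' for the top `ceiling(n_genes/3)` genes by expression.
#'
#' @param config A [sim_config]; `config$seed` seeds the RNG.
#' @return A list with elements `genes` (a [gene_models]), `expression`
#'   (data.frame `gene_id`, `log_expr`) and `dhs` (data.frame `chrom`,
#'   `start`, `end`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  simulate_annotation_impl(config)
}

# RNG-state-consuming implementation (no reseeding) so that orchestrators
# can compose generator stages under one seed.
simulate_annotation_impl <- function(config) {
  genome <- config$genome
  n <- config$n_genes
  glen <- config$gene_length
  empty <- list(
    genes = gene_models(
      data.frame(gene_id = character(), transcript_id = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE),
      data.frame(transcript_id = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)),
    expression = data.frame(gene_id = character(), log_expr = numeric(),
                            stringsAsFactors = FALSE),
    dhs = data.frame(chrom = character(), start = integer(), end = integer(),
                     stringsAsFactors = FALSE))
  if (n == 0L) return(empty)
  # allocate genes to chromosomes proportionally (largest remainder)
  frac <- genome / sum(genome) * n
  n_per <- floor(frac)
  rem <- n - sum(n_per)
  if (rem > 0) {
    extra <- order(frac - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1
  }
  if (any(n_per * glen > genome)) {
    stop("genome too small for ", n, " non-overlapping genes of length ", glen)
  }
  rows <- list(); exon_rows <- list()
  gid <- 0L
  for (ci in seq_along(genome)) {
    nc <- n_per[ci]
    if (nc == 0L) next
    L <- genome[[ci]]
    free <- L - nc * glen
    gaps <- sort(runif(nc, 0, free))
    starts <- as.integer(floor(gaps + (seq_len(nc) - 1L) * glen))
    ids <- sprintf("gene%04d", gid + seq_len(nc))
    gid <- gid + nc
    strand <- rep(c("+", "-"), length.out = nc)
    rows[[ci]] <- data.frame(gene_id = ids, transcript_id = paste0(ids, ".t1"),
                             chrom = names(genome)[ci], start = starts,
                             end = starts + glen, strand = strand,
                             stringsAsFactors = FALSE)
    # two exons with an intron between them
    e1 <- as.integer(round(0.4 * glen)); e2 <- as.integer(round(0.6 * glen))
    exon_rows[[ci]] <- data.frame(
      transcript_id = rep(paste0(ids, ".t1"), each = 2L),
      start = as.vector(rbind(starts, starts + e2)),
      end = as.vector(rbind(starts + e1, starts + glen)),
      stringsAsFactors = FALSE)
  }
  genes_df <- do.call(rbind, rows)
  genes <- gene_models(genes_df, do.call(rbind, exon_rows))
  expr <- data.frame(gene_id = genes$gene_id,
                     log_expr = rnorm(n, config$expr_mean, config$expr_sd),
                     stringsAsFactors = FALSE)
  # DHS at the promoters of the top third of genes by expression
  n_top <- as.integer(ceiling(n / 3))
  top <- order(-expr$log_expr, expr$gene_id)[seq_len(n_top)]
  half <- config$dhs_width %/% 2L
  dstart <- pmax(0L, genes$tss[top] - half)
  dend <- pmin(as.integer(config$genome[genes$chrom[top]]),
               dstart + config$dhs_width)
  dhs <- data.frame(chrom = genes$chrom[top], start = dstart, end = dend,
                    stringsAsFactors = FALSE)
  ord <- order(dhs$chrom, dhs$start)
  dhs <- dhs[ord, , drop = FALSE]
  rownames(dhs) <- NULL
  list(genes = genes, expression = expr, dhs = dhs)
}

#' Simulate one nucleosome array by a renewal process
#'
#' The first midpoint falls at `region$start + U`, `U ~ Uniform(0, nrl)`;
#' successive spacings are Normal(`nrl`, `jitter_sd`) truncated below at
#' 148 bp (adjacent nucleosomes cannot overlap).  Midpoints beyond
#' `region$end` are discarded.
#'
#' @param region A list or one-row data.frame with `start` and `end`
#'   (0-based half-open).
#' @param nrl True nucleosome repeat length (bp); must exceed 147.
#' @param jitter_sd Spacing SD (bp).
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return Integer vector of midpoint coordinates (possibly empty).
#' @export
simulate_nucleosome_array <- function(region, nrl, jitter_sd, seed = NULL) {
  if (nrl <= 147) stop("nrl must exceed 147 bp (nucleosomes would overlap)")
  stopifnot(jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  start <- as.numeric(region$start); end <- as.numeric(region$end)
  first <- start + floor(runif(1, 0, nrl))
  if (first >= end) return(integer(0))
  n_max <- ceiling((end - first) / 148) + 2L
  sp <- rnorm(n_max, nrl, jitter_sd)
  while (any(sp < 148)) sp[sp < 148] <- rnorm(sum(sp < 148), nrl, jitter_sd)
  pos <- round(first + c(0, cumsum(sp)))
  as.integer(pos[pos < end])
}

#' Assign competitive CAP labels to nucleosomes
#'
#' Each nucleosome is labelled HMGD1 with probability
#' `plogis(ratio_slope * z)`, where `z` is the standardized log-expression
#' of the nearest gene when the nucleosome lies within
#' `tss_coupling_bp` of that gene's TSS, and `z = -1` (intergenic
#' baseline) otherwise; it is labelled H1 with the complementary
#' probability.  Labels partition nucleosomes: binding is mutually
#' exclusive.
#'
#' @param midpoints data.frame with columns `chrom`, `pos`.
#' @param genes A [gene_models].
#' @param expression data.frame with `gene_id`, `log_expr` covering every
#'   gene.
#' @param config A [sim_config] (uses `ratio_slope`, `region_size`,
#'   `tss_coupling_bp`, `genome`).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A list: `midpoints` (input plus `p_hmgd` and `label`) and
#'   `regions` (tiling regions of `region_size` bp with the expected true
#'   log2 HMGD1/H1 ratio `true_log_ratio`).
#' @export
assign_cap_labels <- function(midpoints, genes, expression, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(genes) && !all(genes$gene_id %in% expression$gene_id)) {
    stop("expression must be defined for every gene")
  }
  n <- nrow(midpoints)
  z_mid <- rep(-1, n)
  if (nrow(genes)) {
    z_gene <- standardize(expression$log_expr)
    names(z_gene) <- expression$gene_id
    for (ch in unique(midpoints$chrom)) {
      gi <- which(genes$chrom == ch)
      if (!length(gi)) next
      ord <- gi[order(genes$tss[gi])]
      tss <- genes$tss[ord]
      mi <- which(midpoints$chrom == ch)
      pos <- midpoints$pos[mi]
      right <- findInterval(pos, tss) # index of last tss <= pos
      left_i <- pmax(right, 1L)
      right_i <- pmin(right + 1L, length(tss))
      d_left <- abs(pos - tss[left_i])
      d_right <- abs(pos - tss[right_i])
      nearest <- ifelse(d_left <= d_right, left_i, right_i)
      dist <- pmin(d_left, d_right)
      within <- dist <= config$tss_coupling_bp
      z_mid[mi[within]] <- z_gene[genes$gene_id[ord][nearest[within]]]
    }
  }
  p <- plogis(config$ratio_slope * z_mid)
  label <- ifelse(runif(n) < p, "HMGD1", "H1")
  out <- midpoints
  out$p_hmgd <- p
  out$label <- label
  regions <- tile_genome(config$genome, config$region_size)
  tlr <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    mi <- which(out$chrom == ch)
    pos <- sort_order <- order(out$pos[mi])
    pos <- out$pos[mi][sort_order]
    pv <- out$p_hmgd[mi][sort_order]
    csum <- c(0, cumsum(pv)); cnt <- c(0, seq_along(pv))
    lo <- findInterval(regions$start[ri] - 0.5, pos)
    hi <- findInterval(regions$end[ri] - 0.5, pos)
    sum_p <- csum[hi + 1L] - csum[lo + 1L]
    n_in <- hi - lo
    tlr[ri] <- log2_ratio(sum_p, n_in - sum_p)
  }
  regions$true_log_ratio <- tlr
  list(midpoints = out, regions = regions)
}

#' Simulate sequenced fragments from labelled nucleosomes
#'
#' Each selected nucleosome sheds `Poisson(depth)` fragments.  Fragment
#' lengths are rounded Normal draws clamped to \[50, 400\] bp (SD
#' `fraglen_sd` for paired libraries, `fraglen_sd_single` for gel
#' size-selected single-end libraries); the fragment midpoint is the
#' nucleosome midpoint plus rounded Normal(0, `midpoint_blur_sd`) MNase
#' trimming noise.  ChIP experiments sample only nucleosomes carrying the
#' matching label; `"total"` samples all.
#'
#' @param nucleosomes data.frame with `chrom`, `pos` and (for ChIP
#'   experiments) `label`.
#' @param config A [sim_config].
#' @param experiment `"total"`, `"HMGD1"` or `"H1"`.
#' @param mode `"paired"` (full fragments with `fragment_length`) or
#'   `"single"` (one read end per fragment, strand chosen with equal
#'   probability).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return data.frame of reads: `chrom`, `start`, `end`, `strand`,
#'   `fragment_length` (`NA` in single-end mode) and `true_mid` (the
#'   originating nucleosome midpoint, for validation).
#' @export
simulate_reads <- function(nucleosomes, config,
                           experiment = c("total", "HMGD1", "H1"),
                           mode = c("paired", "single"), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  experiment <- match.arg(experiment)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  nuc <- nucleosomes
  if (experiment != "total") {
    if (is.null(nuc$label)) stop("ChIP experiment requires labelled nucleosomes")
    nuc <- nuc[nuc$label == experiment, , drop = FALSE]
  }
  nn <- nrow(nuc)
  counts <- rpois(nn, config$depth)
  N <- sum(counts)
  if (N == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), fragment_length = integer(),
                      true_mid = integer(), stringsAsFactors = FALSE))
  }
  idx <- rep.int(seq_len(nn), counts)
  sdlen <- if (mode == "single") config$fraglen_sd_single else config$fraglen_sd
  len <- as.integer(pmax(50, pmin(400, round(rnorm(N, config$fraglen_mean, sdlen)))))
  fmid <- nuc$pos[idx] + as.integer(round(rnorm(N, 0, config$midpoint_blur_sd)))
  fstart <- fmid - (len - 1L) %/% 2L
  fend <- fstart + len
  chrom <- nuc$chrom[idx]
  chrlen <- as.numeric(config$genome[chrom])
  keep <- fstart >= 0L & fend <= chrlen
  chrom <- chrom[keep]; fstart <- fstart[keep]; fend <- fend[keep]
  len <- len[keep]; true_mid <- nuc$pos[idx][keep]
  if (mode == "paired") {
    data.frame(chrom = chrom, start = fstart, end = fend, strand = ".",
               fragment_length = len, true_mid = true_mid,
               stringsAsFactors = FALSE)
  } else {
    M <- length(fstart)
    strand <- sample(c("+", "-"), M, replace = TRUE)
    rl <- pmin(config$read_length, len)
    rstart <- ifelse(strand == "+", fstart, fend - rl)
    rend <- ifelse(strand == "+", fstart + rl, fend)
    data.frame(chrom = chrom, start = as.integer(rstart), end = as.integer(rend),
               strand = strand, fragment_length = NA_integer_,
               true_mid = true_mid, stringsAsFactors = FALSE)
  }
}

#' Simulate histone-PTM signal tracks
#'
#' Produces two track families over 2-kb TSS windows: activating tracks
#' equal `amplitude * z + noise` and repressive tracks
#' `-amplitude * z + noise`, where `z` is the standardized true
#' log-expression of the gene and the noise is Normal(0, `noise_sd`).
#'
#' @param genes A [gene_models].
#' @param expression data.frame with `gene_id`, `log_expr`.
#' @param config A [sim_config].
#' @param n_per_family Tracks per family (at least 3).
#' @param amplitude Signal amplitude `a`.
#' @param window Window width (bp) centred on each TSS.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Named list of bedGraph-style data.frames (`chrom`, `start`,
#'   `end`, `value`), names `act1..actN` and `rep1..repN`.
#' @export
simulate_ptm_tracks <- function(genes, expression, config, n_per_family = 3L,
                                amplitude = 1, window = 2000L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_per_family >= 1L)
  if (!is.null(seed)) set.seed(seed)
  z <- standardize(expression$log_expr[match(genes$gene_id, expression$gene_id)])
  half <- window %/% 2L
  chrlen <- as.integer(config$genome[genes$chrom])
  ws <- pmax(0L, genes$tss - half)
  we <- pmin(chrlen, genes$tss + half)
  make <- function(sign) {
    data.frame(chrom = genes$chrom, start = ws, end = we,
               value = sign * amplitude * z + rnorm(nrow(genes), 0, config$noise_sd),
               stringsAsFactors = FALSE)
  }
  act <- lapply(seq_len(n_per_family), function(i) make(1))
  rep_ <- lapply(seq_len(n_per_family), function(i) make(-1))
  out <- c(act, rep_)
  names(out) <- c(paste0("act", seq_len(n_per_family)),
                  paste0("rep", seq_len(n_per_family)))
  out
}

#' Simulate exon tag counts from true expression
#'
#' Per-gene counts are Poisson with mean `total_reads * w`, where the
#' weight `w` is proportional to `2^log_expr * exonic_length` and
#' normalized to sum to one.
#'
#' @param genes A [gene_models].
#' @param expression data.frame with `gene_id`, `log_expr`.
#' @param total_reads Library size (tags).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return data.frame with `gene_id`, `count`, `exonic_length`.
#' @export
simulate_expression_counts <- function(genes, expression, total_reads, seed = NULL) {
  stopifnot(total_reads > 0)
  if (!is.null(seed)) set.seed(seed)
  le <- expression$log_expr[match(genes$gene_id, expression$gene_id)]
  w <- 2^le * genes$exonic_length
  w <- w / sum(w)
  data.frame(gene_id = genes$gene_id,
             count = rpois(nrow(genes), total_reads * w),
             exonic_length = genes$exonic_length,
             stringsAsFactors = FALSE)
}

#' Simulate a full regulatory genome
#'
#' Orchestrates annotation, nucleosome arrays at a constant baseline NRL,
#' competitive CAP labelling driven by gene expression, sequencing of the
#' HMGD1-ChIP, H1-ChIP and total libraries, PTM tracks and RNA-seq tag
#' counts, all under `config$seed`.
#'
#' @param config A [sim_config].
#' @param rnaseq_reads RNA-seq library size for tag counts.
#' @return A list with `config`, `genes`, `expression`, `dhs`, `ptm`,
#'   `nucleosomes` (labelled), `regions` (truth log-ratio per tiling
#'   region), `reads` (list `hmgd`, `h1`, `total` of paired fragments) and
#'   `counts` (tag counts).
#' @export
simulate_regulatory_genome <- function(config = sim_config(), rnaseq_reads = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ann <- simulate_annotation_impl(config)
  nuc <- do.call(rbind, lapply(names(config$genome), function(ch) {
    pos <- simulate_nucleosome_array(list(start = 0L, end = config$genome[[ch]]),
                                     config$baseline_nrl, config$spacing_jitter_sd)
    if (!length(pos)) return(NULL)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  lab <- assign_cap_labels(nuc, ann$genes, ann$expression, config)
  reads <- list(
    hmgd = simulate_reads(lab$midpoints, config, "HMGD1", "paired"),
    h1 = simulate_reads(lab$midpoints, config, "H1", "paired"),
    total = simulate_reads(lab$midpoints, config, "total", "paired"))
  ptm <- simulate_ptm_tracks(ann$genes, ann$expression, config)
  counts <- simulate_expression_counts(ann$genes, ann$expression, rnaseq_reads)
  list(config = config, genes = ann$genes, expression = ann$expression,
       dhs = ann$dhs, ptm = ptm, nucleosomes = lab$midpoints,
       regions = lab$regions, reads = reads, counts = counts)
}

#' Simulate a genome with ratio-coupled nucleosome spacing
#'
#' Tiles the genome into `region_size` regions, draws a true HMGD1/H1
#' log2 ratio per region, stratifies regions into rank quintiles and
#' generates one nucleosome array per region whose true NRL is the
#' configured value for that quintile (`nrl_by_quintile`, highest-ratio
#' quintile first).  Nucleosomes are labelled HMGD1 with probability
#' `plogis(log(2) * r)` so the expected log2 count ratio matches the true
#' region ratio, and the three libraries are sequenced as paired
#' fragments.
#'
#' @param config A [sim_config].
#' @param ratio_sd SD of the true per-region log2 ratio.
#' @return A list with `config`, `regions` (truth: `true_log_ratio`,
#'   `quintile`, `true_nrl`), `nucleosomes` (labelled) and `reads` (list
#'   `hmgd`, `h1`, `total`).
#' @export
simulate_spaced_genome <- function(config = sim_config(), ratio_sd = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  regions <- tile_genome(config$genome, config$region_size)
  n <- nrow(regions)
  if (n < 5L) stop("genome too small: fewer than 5 regions")
  r <- rnorm(n, 0, ratio_sd)
  sizes <- rank_group_sizes(n, 5L)
  quintile <- integer(n)
  quintile[order(r, seq_len(n))] <- rep.int(1:5, sizes)
  regions$true_log_ratio <- r
  regions$quintile <- quintile
  regions$true_nrl <- config$nrl_by_quintile[6L - quintile]
  nuc <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- simulate_nucleosome_array(regions[i, ], regions$true_nrl[i],
                                     config$spacing_jitter_sd)
    if (length(pos)) {
      p <- plogis(log(2) * r[i])
      nuc[[i]] <- data.frame(chrom = regions$chrom[i], pos = pos,
                             label = ifelse(runif(length(pos)) < p, "HMGD1", "H1"),
                             region = i, stringsAsFactors = FALSE)
    }
  }
  nuc <- do.call(rbind, nuc)
  reads <- list(
    hmgd = simulate_reads(nuc, config, "HMGD1", "paired"),
    h1 = simulate_reads(nuc, config, "H1", "paired"),
    total = simulate_reads(nuc, config, "total", "paired"))
  list(config = config, regions = regions, nucleosomes = nuc, reads = reads)
}

#' Simulate gene-level occupancy rates with ratio-driven expression
#'
#' Rate-level counterpart of the competitive-binding model, used for
#' power studies that would be wasteful at read level: per gene, log2
#' HMGD1 and H1 promoter rates are independent standard normals, and
#' log-expression is `ratio_slope * (hmgd - h1)` plus Normal(0,
#' `noise_sd`) noise, so the occupancy log-ratio drives expression.
#'
#' @param n_genes Number of genes.
#' @param ratio_slope Coupling of expression to the log-ratio.
#' @param noise_sd Residual expression noise SD.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return data.frame with `hmgd`, `h1`, `ratio` (= hmgd - h1), `expr`.
#' @export
simulate_gene_rates <- function(n_genes = 2000L, ratio_slope = 1,
                                noise_sd = 0.5, seed = NULL) {
  stopifnot(n_genes >= 4L, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  hmgd <- rnorm(n_genes)
  h1 <- rnorm(n_genes)
  ratio <- hmgd - h1
  expr <- ratio_slope * ratio + rnorm(n_genes, 0, noise_sd)
  data.frame(hmgd = hmgd, h1 = h1, ratio = ratio, expr = expr)
}
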