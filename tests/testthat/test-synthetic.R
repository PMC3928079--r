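test_that("annotation generator is deterministic and respects its contracts", {
  cfg <- sim_config(seed = 42, genome = c(chrA = 100000L, chrB = 60000L),
                    n_genes = 30L)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)

  # non-overlapping gene bodies, in-bounds
  for (ch in names(cfg$genome)) {
    g <- a1$genes[a1$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L) expect_true(all(g$start[-1L] >= g$end[-nrow(g)]))
    expect_true(all(g$start >= 0L & g$end <= cfg$genome[[ch]]))
  }
  # one DHS per top-third gene
  expect_equal(nrow(a1$dhs), ceiling(cfg$n_genes / 3))

  # empty and impossible configurations
  empty <- simulate_annotation(sim_config(seed = 1, n_genes = 0L))
  expect_equal(nrow(empty$genes), 0L)
  expect_equal(nrow(empty$dhs), 0L)
  expect_error(simulate_annotation(
    sim_config(seed = 1, genome = c(chrA = 5000L), n_genes = 10L)),
    "too small")
})

test_that("nucleosome arrays follow the renewal spacing model", {
  # degenerate jitter: exact spacings
  pos <- simulate_nucleosome_array(list(start = 0L, end = 1000L), 180, 0, seed = 1)
  expect_true(all(diff(pos) == 180L))
  expect_true(all(pos < 1000L))

  # law of large numbers on the mean spacing
  pos <- simulate_nucleosome_array(list(start = 0L, end = 2000000L), 180, 5, seed = 2)
  expect_gt(length(pos), 10000L)
  expect_lt(abs(mean(diff(pos)) - 180), 0.2)

  # short region: at most one midpoint; invalid nrl errors
  expect_lte(length(simulate_nucleosome_array(list(start = 0L, end = 100L),
                                              180, 5, seed = 3)), 1L)
  expect_error(simulate_nucleosome_array(list(start = 0L, end = 1000L), 147, 5),
               "147")
})

test_that("competitive labelling follows the logistic model and partitions", {
  cfg <- sim_config(seed = 5, genome = c(chrA = 50000L), n_genes = 10L)
  ann <- simulate_annotation(cfg)
  nuc <- data.frame(chrom = "chrA", pos = seq(100L, 49900L, by = 180L))
  lab <- assign_cap_labels(nuc, ann$genes, ann$expression, cfg, seed = 6)
  expect_true(all(lab$midpoints$label %in% c("HMGD1", "H1")))

  # ratio_slope = 0: p exactly 1/2 everywhere
  cfg0 <- sim_config(seed = 5, genome = c(chrA = 50000L), n_genes = 10L,
                     ratio_slope = 0)
  lab0 <- assign_cap_labels(nuc, ann$genes, ann$expression, cfg0, seed = 6)
  expect_true(all(lab0$midpoints$p_hmgd == 0.5))

  # logistic closed form at z = +/- 3 with slope 1
  expect_equal(plogis(3), 0.9526, tolerance = 1e-3)
  near_tss <- abs(nuc$pos - ann$genes$tss[1L]) <= 1000L
  z <- (ann$expression$log_expr - mean(ann$expression$log_expr)) /
    sd(ann$expression$log_expr)
  expect_equal(unname(lab$midpoints$p_hmgd[which(near_tss)[1L]]),
               plogis(z[1L]), tolerance = 1e-12)
  # intergenic baseline z = -1
  far <- which(!sapply(nuc$pos, function(p) any(abs(p - ann$genes$tss) <= 1000L)))
  expect_true(all(lab$midpoints$p_hmgd[far] == plogis(-1)))
})

test_that("fragment library reproduces the configured length and blur structure", {
  cfg <- sim_config(seed = 9, genome = c(chrA = 2000000L), n_genes = 0L)
  nuc <- data.frame(chrom = "chrA", pos = seq(1000L, 1999000L, by = 400L))
  reads <- simulate_reads(nuc, cfg, "total", "paired", seed = 10)
  expect_gt(nrow(reads), 50000L)

  # central 95% of lengths ~ 146 +/- 1.96 * 23 = [101, 191]
  q <- unname(quantile(reads$fragment_length, c(0.025, 0.975), type = 1))
  expect_lte(abs(q[1L] - 101), 1)
  expect_lte(abs(q[2L] - 191), 1)

  # pair midpoint vs true nucleosome midpoint: RMS ~ blur sd (3 bp)
  mid <- (reads$start + reads$end - 1L) %/% 2L
  rms <- sqrt(mean((mid - reads$true_mid)^2))
  expect_lt(abs(rms - cfg$midpoint_blur_sd), 0.35)

  # degenerate length noise
  cfg0 <- sim_config(seed = 9, genome = c(chrA = 100000L), n_genes = 0L,
                     fraglen_sd = 0)
  nuc0 <- data.frame(chrom = "chrA", pos = seq(1000L, 99000L, by = 400L))
  r0 <- simulate_reads(nuc0, cfg0, "total", "paired", seed = 11)
  expect_true(all(r0$fragment_length == 146L))

  # ChIP experiments only sample matching labels
  nuc$label <- rep(c("HMGD1", "H1"), length.out = nrow(nuc))
  rh <- simulate_reads(nuc, cfg, "HMGD1", "paired", seed = 12)
  expect_true(all(rh$true_mid %in% nuc$pos[nuc$label == "HMGD1"]))
})

test_that("PTM tracks carry the designed correlation structure", {
  cfg <- sim_config(seed = 21, genome = c(chrA = 500000L), n_genes = 120L,
                    noise_sd = 0)
  ann <- simulate_annotation(cfg)
  tr <- simulate_ptm_tracks(ann$genes, ann$expression, cfg, seed = 22)
  expect_equal(cor(tr$act1$value, tr$act2$value), 1)
  expect_equal(cor(tr$act1$value, tr$rep1$value), -1)

  # a = 1, noise sd = 1: within-family R ~ a^2/(a^2+sd^2) = 0.5
  cfg1 <- sim_config(seed = 21, genome = c(chrA = 500000L), n_genes = 120L,
                     noise_sd = 1)
  tr1 <- simulate_ptm_tracks(ann$genes, ann$expression, cfg1, seed = 23)
  rs <- c(cor(tr1$act1$value, tr1$act2$value),
          cor(tr1$act1$value, tr1$act3$value),
          cor(tr1$act2$value, tr1$act3$value))
  expect_lt(abs(mean(rs) - 0.5), 0.12)
})

test_that("expression counts recover true expression at deep coverage", {
  cfg <- sim_config(seed = 31, genome = c(chrA = 3000000L), n_genes = 500L)
  ann <- simulate_annotation(cfg)
  counts <- simulate_expression_counts(ann$genes, ann$expression, 1e6, seed = 32)
  tab <- expression_table(counts)
  r <- cor(tab$log_expr, ann$expression$log_expr[match(tab$gene_id,
                                                       ann$expression$gene_id)])
  expect_gt(r, 0.95)
})

test_that("spaced-genome truth couples NRL to ratio quintile as configured", {
  cfg <- sim_config(seed = 41, genome = c(chrA = 200000L), n_genes = 0L)
  sg <- simulate_spaced_genome(cfg)
  expect_equal(sort(unique(sg$regions$quintile)), 1:5)
  agg <- tapply(sg$regions$true_nrl, sg$regions$quintile, unique)
  expect_equal(unname(agg[["5"]]), 174)
  expect_equal(unname(agg[["1"]]), 187)
  # higher quintile = higher true ratio, shorter spacing
  m <- tapply(sg$regions$true_log_ratio, sg$regions$quintile, mean)
  expect_true(all(diff(m) > 0))
  # determinism
  sg2 <- simulate_spaced_genome(cfg)
  expect_identical(sg$regions, sg2$regions)
  expect_identical(sg$reads, sg2$reads)
})
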