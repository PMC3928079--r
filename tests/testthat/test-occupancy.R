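test_that("RPKM matches hand-computed values and guards its domain", {
  # (0+1) / ((1000/1000) * (1e6/1e6)) = 1
  expect_equal(compute_rpkm(0, 1000, 1e6), 1)
  # (99+1) / ((2000/1000) * (1e7/1e6)) = 100 / 20 = 5
  expect_equal(compute_rpkm(99, 2000, 1e7), 5)
  expect_error(compute_rpkm(10, 0, 1e6), "exonic_length")
  expect_error(compute_rpkm(10, 1000, 0), "mapped_total")
})

test_that("expression tertiles split with remainder to the low groups", {
  mk <- function(n) data.frame(gene_id = sprintf("g%02d", 1:n),
                               log_expr = as.numeric(1:n),
                               stringsAsFactors = FALSE)
  g6 <- assign_expression_groups(mk(6))
  expect_equal(as.vector(table(g6$group)), c(2L, 2L, 2L))
  g7 <- assign_expression_groups(mk(7))
  expect_equal(as.vector(table(g7$group)), c(3L, 2L, 2L))
  # ordering: lowest log_expr -> "low"
  expect_equal(as.character(g7$group[g7$log_expr == 1]), "low")
  expect_equal(as.character(g7$group[g7$log_expr == 7]), "high")
  # ties broken deterministically by gene_id
  tied <- data.frame(gene_id = c("b", "a", "c"), log_expr = c(1, 1, 1),
                     stringsAsFactors = FALSE)
  gt <- assign_expression_groups(tied)
  expect_equal(as.character(gt$group[gt$gene_id == "a"]), "low")
  expect_equal(as.character(gt$group[gt$gene_id == "c"]), "high")
  expect_error(assign_expression_groups(mk(2)), "at least 3")
})

test_that("position classification honours precedence and strand", {
  gm <- toy_genes()
  # geneP: "+", TSS 2000, exons [2000,3000)+[4000,5000), intron [3000,4000)
  q <- classify_position(rep("chrA", 7),
                         c(2000L, 1500L, 2500L, 3500L, 4500L, 10000L, 3100L),
                         gm)
  expect_equal(q$class,
               c("promoter", "promoter", "promoter", "intron", "exon",
                 "intergenic", "intron"))
  # oriented sub-label: 1500 is upstream of the + TSS; 2500 downstream
  expect_equal(q$sub[1:3], c("downstream", "upstream", "downstream"))
  # geneM: "-", TSS 14999; 15500 is genomically right = upstream
  qm <- classify_position(c("chrA", "chrA"), c(15500L, 14500L), gm)
  expect_equal(qm$class, c("promoter", "promoter"))
  expect_equal(qm$sub, c("upstream", "downstream"))
  # promoter beats intron exactly at the boundary distance, not beyond
  qb <- classify_position("chrA", 2000L + 1000L, gm)
  expect_equal(qb$class, "promoter")
  qb2 <- classify_position("chrA", 2000L + 1001L, gm)
  expect_equal(qb2$class, "intron")
})

test_that("region densities are ~1 under uniform midpoints and sum to whole", {
  gm <- toy_genes()
  trk <- track_from(seq(0L, 19999L, by = 1L))  # perfectly uniform
  tab <- region_density_table(trk, gm, toy_genome)
  pooled <- tab[tab$chrom == "all", ]
  expect_equal(sum(pooled$bp), 20000L)
  expect_equal(sum(pooled$n_midpoints), 20000L)
  expect_true(all(abs(pooled$density - 1) < 1e-9))

  # doubling promoter reads doubles promoter density
  prom_pos <- which(classify_position(rep("chrA", 20000L), 0:19999L,
                                      gm)$class == "promoter") - 1L
  trk2 <- track_from(c(0:19999L, prom_pos))
  tab2 <- region_density_table(trk2, gm, toy_genome)
  p2 <- tab2[tab2$chrom == "all" & tab2$class == "promoter", ]
  frac_prom <- p2$bp / 20000
  expected <- (2 * frac_prom / (1 + frac_prom)) / frac_prom
  expect_equal(p2$density, expected, tolerance = 1e-9)
})

test_that("TSS profiles are strand-oriented and density-normalized", {
  gm <- toy_genes()
  # one midpoint 100 bp downstream of each TSS (strand-aware)
  trk <- track_from(c(2100L, 14899L))
  prof <- tss_aggregate_profile(trk, gm, toy_genome, flank = 200L, smooth = 0L)
  peak <- prof$offset[which.max(prof$density)]
  expect_equal(peak, 100L)
  # both genes contribute to the same oriented offset
  mean_density <- trk$n_total / 20000
  expect_equal(max(prof$density), (2 / 2) / mean_density)

  # smoothing spreads mass but preserves the window total
  prof_s <- tss_aggregate_profile(trk, gm, toy_genome, flank = 200L, smooth = 25L)
  expect_equal(sum(prof_s$density), sum(prof$density), tolerance = 1e-6)
  expect_lt(max(prof_s$density), max(prof$density))

  # grouping: per-group gene-count normalization
  groups <- data.frame(gene_id = c("geneP", "geneM"),
                       group = c("high", "low"), stringsAsFactors = FALSE)
  pg <- tss_aggregate_profile(trk, gm, toy_genome, flank = 200L,
                              groups = groups, smooth = 0L)
  hi <- pg[pg$group == "high" & pg$offset == 100L, "density"]
  expect_equal(hi, (1 / 1) / mean_density)
})

test_that("promoter rates recover a designed HMGD1/H1 asymmetry", {
  gm <- toy_genes()
  # 20 HMGD1 midpoints inside geneP's [-100,500) window, 5 H1 there;
  # reversed at geneM (strand-oriented placement)
  hm_p <- seq(2000L, 2380L, by = 20L)            # offsets 0..380 on "+"
  h1_p <- seq(2000L, 2080L, by = 20L)
  hm_m <- 14999L - seq(0L, 80L, by = 20L)        # few HMGD1 at geneM
  h1_m <- 14999L - seq(0L, 380L, by = 20L)
  hmgd <- track_from(c(hm_p, hm_m), label = "HMGD1")
  h1 <- track_from(c(h1_p, h1_m), label = "H1")
  total <- track_from(c(hm_p, hm_m, h1_p, h1_m))
  rates <- promoter_rates(hmgd, h1, total, gm)
  rp <- rates[rates$gene_id == "geneP", ]
  rm_ <- rates[rates$gene_id == "geneM", ]
  # geneP: HMGD1-window counts hmgd 20, h1 5 -> ratio log2(21/6)
  expect_equal(rp$ratio_rate, log2(21 / 6))
  expect_equal(rm_$ratio_rate, log2(6 / 21))
  expect_gt(rp$hmgd_rate, rm_$hmgd_rate)
  # h1 window [-550, 50): both genes hold 3 H1 and 3 HMGD1 midpoints there
  expect_equal(rp$h1_rate, log2(4 / 7))
  expect_equal(rm_$h1_rate, log2(4 / 7))
  # per-segment columns exist for every default segment
  segs <- names(default_promoter_segments())
  expect_true(all(paste0("ratio_", segs) %in% names(rates)))
  # p1 segment [0,175) on geneP: hmgd 9, h1 5 -> log2(10/6)
  expect_equal(rp$ratio_p1, log2(10 / 6))
})

test_that("oriented windows agree between strands under mirror symmetry", {
  gm <- toy_genes()
  # mirror-symmetric placements around the two TSSs
  off <- c(-90L, -30L, 10L, 250L, 499L)
  hmgd <- track_from(c(2000L + off, 14999L - off), label = "HMGD1")
  h1 <- hmgd; h1$label <- "H1"
  total <- hmgd
  rates <- promoter_rates(hmgd, h1, total, gm)
  expect_equal(rates$hmgd_rate[rates$gene_id == "geneP"],
               rates$hmgd_rate[rates$gene_id == "geneM"])
  expect_equal(rates$h1_rate[rates$gene_id == "geneP"],
               rates$h1_rate[rates$gene_id == "geneM"])
})
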