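test_that("Pearson correlation matches a small hand-checked example", {
  # x = 1:4, y = (2,1,4,3): R = 0.6 exactly
  out <- pearson_with_ci(1:4, c(2, 1, 4, 3))
  expect_equal(out$R, 0.6)
  expect_equal(out$n, 4L)
  # Fisher-z interval: tanh(atanh(0.6) +/- 1.96 / sqrt(1))
  z <- atanh(0.6); zc <- qnorm(0.975)
  expect_equal(out$ci_low, tanh(z - zc))
  expect_equal(out$ci_high, tanh(z + zc))
  # t-based p-value oracle via cor.test
  ct <- cor.test(1:4, c(2, 1, 4, 3))
  expect_equal(out$p, unname(ct$p.value))

  # perfect correlation: degenerate interval, p = 0
  pc <- pearson_with_ci(1:10, 2 * (1:10) + 5)
  expect_equal(pc$R, 1)
  expect_equal(c(pc$ci_low, pc$ci_high), c(1, 1))
  expect_lt(pc$p, 1e-12)

  expect_error(pearson_with_ci(1:3, 1:3), "at least 4")
  expect_error(pearson_with_ci(rep(1, 5), 1:5), "zero variance")
})

test_that("interval coverage of the Fisher-z CI is near nominal", {
  set.seed(201)
  hits <- 0L
  n_rep <- 400L
  for (i in seq_len(n_rep)) {
    x <- rnorm(50); y <- 0.5 * x + rnorm(50)
    true_R <- 0.5 / sqrt(0.25 + 1)
    ci <- pearson_with_ci(x, y)
    if (ci$ci_low <= true_R && true_R <= ci$ci_high) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.90)
  expect_lt(hits / n_rep, 0.99)
})

test_that("nested F-test matches the normal-equations oracle", {
  # brute-force oracle: solve both least-squares problems directly
  oracle <- function(y, a, b) {
    Xf <- cbind(1, a, b); Xr <- cbind(1, a)
    bf <- solve(crossprod(Xf), crossprod(Xf, y))
    br <- solve(crossprod(Xr), crossprod(Xr, y))
    sf <- sum((y - Xf %*% bf)^2); sr <- sum((y - Xr %*% br)^2)
    Fs <- (sr - sf) / (sf / (length(y) - 3))
    list(F = Fs, p = pf(Fs, 1, length(y) - 3, lower.tail = FALSE))
  }
  set.seed(202)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    a <- rnorm(n); b <- rnorm(n)
    y <- rnorm(n) + runif(1, -2, 2) * a + runif(1, -2, 2) * b
    got <- nested_f_test(y, a, b)
    want <- oracle(y, a, b)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_equal(got$df_den, n - 3L)
  }
  # agreement with R's own anova() on one instance
  set.seed(203)
  a <- rnorm(30); b <- rnorm(30); y <- a + 2 * b + rnorm(30)
  got <- nested_f_test(y, a, b)
  an <- anova(lm(y ~ a), lm(y ~ a + b))
  expect_equal(got$F, an$F[2], tolerance = 1e-10)
  expect_equal(got$p, an$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("nested F-test handles collinear and perfectly fitting designs", {
  a <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  col <- nested_f_test(y, a, 2 * a)       # b adds nothing
  expect_equal(col$F, 0)
  expect_equal(col$p, 1)
  b <- c(0, 1, 0, 1, 0, 1)
  perf <- nested_f_test(3 + a - 2 * b, a, b)  # full model exact
  expect_equal(perf$F, Inf)
  expect_equal(perf$p, 0)
  expect_error(nested_f_test(y, rep(1, 6), a), "rank deficient")
})

test_that("DHS distance track matches an exhaustive per-base oracle", {
  dhs <- data.frame(chrom = "chrA", start = c(3000L, 9000L),
                    end = c(3200L, 9400L), stringsAsFactors = FALSE)
  hmgd <- track_from(c(3100L, 3150L, 16000L), label = "HMGD1")
  h1 <- track_from(c(500L, 16000L, 16500L), label = "H1")
  st <- dhs_window_stats(dhs, hmgd, h1, toy_genes(), toy_genome)
  expect_equal(nrow(st), 20L)

  # exhaustive oracle: 0 inside a DHS; otherwise bp to the closest covered base
  cov <- c(3000:3199, 9000:9399)
  d_oracle <- sapply(0:19999, function(p) {
    if (p %in% cov) 0 else min(abs(p - cov))
  })
  for (w in c(1, 4, 10, 17)) {
    lo <- st$start[w]; hi <- st$end[w]
    expect_equal(st$dhs_dist[w], log2(mean(d_oracle[(lo + 1):hi]) + 1),
                 tolerance = 1e-9)
  }
  # window fully inside a DHS neighbourhood: window 4 covers [3000,4000)
  expect_equal(st$hmgd_val[4], log2(2 / 1000 + 1))
  expect_equal(st$ratio[4], st$hmgd_val[4] - st$h1_val[4])

  # TSS-proximal exclusion keeps the boundary and drops near windows
  kept <- exclude_tss_proximal(st, cutoff = 2000L)
  expect_true(all(kept$tss_dist >= 2000))
  expect_true(nrow(kept) < nrow(st))
})

test_that("distal DHS windows anticorrelate with HMGD1 in the generator", {
  sim <- simulate_regulatory_genome(sim_config(seed = 3))
  hmgd <- midpoints_from_pairs(sim$reads$hmgd, label = "HMGD1")
  h1 <- midpoints_from_pairs(sim$reads$h1, label = "H1")
  st <- dhs_window_stats(sim$dhs, hmgd, h1, sim$genes, sim$config$genome)
  # signs computed over all windows: the generator couples occupancy to
  # DHSs through promoter activity, so distal windows carry no gradient
  r_h <- pearson_with_ci(st$dhs_dist, st$hmgd_val)
  r_1 <- pearson_with_ci(st$dhs_dist, st$h1_val)
  expect_lt(r_h$R, 0)
  expect_gt(r_1$R, 0)
  expect_lt(r_h$ci_high, 0)
  expect_gt(r_1$ci_low, 0)
})

test_that("PTM clustering separates activating and repressive families", {
  sim <- simulate_regulatory_genome(sim_config(seed = 11))
  hmgd <- midpoints_from_pairs(sim$reads$hmgd, label = "HMGD1")
  h1 <- midpoints_from_pairs(sim$reads$h1, label = "H1")
  total <- midpoints_from_pairs(sim$reads$total, label = "total")
  cl <- ptm_cluster(sim$ptm, hmgd, h1, total, sim$genes, sim$config$genome)
  expect_equal(sort(colnames(cl$values)),
               sort(c("act1", "act2", "act3", "rep1", "rep2", "rep3",
                      "HMGD1", "H1")))
  k2 <- cutree(cl$hclust, k = 2)
  expect_equal(k2[["HMGD1"]], k2[["act1"]])
  expect_equal(k2[["H1"]], k2[["rep1"]])
  expect_false(k2[["HMGD1"]] == k2[["H1"]])
  expect_true(all(k2[c("act1", "act2", "act3")] == k2[["act1"]]))
  expect_true(all(k2[c("rep1", "rep2", "rep3")] == k2[["rep1"]]))
  # correlation matrix structure: within-family positive, cross negative
  expect_gt(cl$correlation["act1", "act2"], 0)
  expect_lt(cl$correlation["act1", "rep1"], 0)
  expect_lt(cl$correlation["HMGD1", "H1"], 0)

  # constant experiment excluded with a warning
  flat <- sim$ptm
  flat$act1$value <- 1
  expect_warning(
    cl2 <- ptm_cluster(flat, hmgd, h1, total, sim$genes, sim$config$genome),
    "constant")
  expect_equal(cl2$excluded, "act1")
})
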