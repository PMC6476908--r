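test_that("median-of-ratios size factors recover known scalings", {
  set.seed(20)
  base <- matrix(rnbinom(200 * 4, mu = 100, size = 5), 200,
                 dimnames = list(NULL, paste0("s", 1:4)))
  base[base == 0] <- 1
  # identical columns -> all factors 1
  same <- cbind(s1 = base[, 1], s2 = base[, 1], s3 = base[, 1])
  expect_equal(unname(size_factors(same)), rep(1, 3))
  # one column exactly doubled -> factor ratio 2
  two <- cbind(a = base[, 1], b = 2L * base[, 1])
  sf <- size_factors(two)
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  expect_equal(exp(mean(log(sf))), 1)       # geometric mean 1
  # single sample
  one <- base[, 1, drop = FALSE]
  expect_equal(unname(size_factors(one)), 1)
  # every feature has a zero somewhere -> total-count fallback
  z <- rbind(c(5L, 0L), c(0L, 5L))
  colnames(z) <- c("s1", "s2")
  expect_warning(sfz <- size_factors(z), "total-count")
  expect_equal(unname(sfz), c(1, 1))
})

test_that("dispersion estimation tracks Poisson, NB and constant features", {
  set.seed(21)
  # Poisson features: variance ~ mean, estimates hug the floor
  pois <- matrix(rpois(500 * 10, 100), 500,
                 dimnames = list(sprintf("f%03d", 1:500), paste0("s", 1:10)))
  a <- estimate_dispersion(pois, rep(1, 10))
  expect_lt(median(a), 0.02)

  # constant counts: s^2 = 0 -> floor exactly
  const <- matrix(50L, 5, 10, dimnames = list(paste0("c", 1:5),
                                              paste0("s", 1:10)))
  expect_equal(unname(estimate_dispersion(const, rep(1, 10))),
               rep(1e-4, 5))

  # NB with alpha = 0.5, n = 50: estimate lands in (0.25, 0.9) most of the time
  hits <- vapply(1:40, function(i) {
    y <- matrix(rnbinom(50, mu = 200, size = 2), 1,
                dimnames = list("f", paste0("s", 1:50)))
    est <- estimate_dispersion(rbind(y, y + 0L), rep(1, 50))[1]
    est > 0.25 && est < 0.9
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  # all-zero feature excluded as NA
  withz <- rbind(pois[1:20, ], zero = rep(0L, 10))
  az <- estimate_dispersion(withz, rep(1, 10))
  expect_true(is.na(az["zero"]))
})

test_that("the NB Wald test is symmetric, null-stable and recovers planted effects", {
  cfg <- sim_config(seed = 23, n_features = 300L,
                    planted_log2fc = setNames(5, "feat_0001"))
  cts <- simulate_counts(cfg)
  de <- run_seasonal_de(cts$counts, cts$design)
  expect_true(de$significant[1])
  expect_gt(de$log2fc[1], 2)

  # identical counts in both groups: log2fc ~ 0, p ~ 1
  flat <- matrix(80L, 3, 10, dimnames = list(paste0("f", 1:3),
                                             cts$design$sample_id))
  res <- nb_wald_test(flat, rep(1, 10),
                      setNames(rep(0.1, 3), rownames(flat)), cts$design)
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-6)
  expect_equal(res$p, rep(1, 3), tolerance = 1e-6)

  # season label swap flips the sign of log2fc and keeps p
  sf <- size_factors(cts$counts)
  disp <- estimate_dispersion(cts$counts, sf, group = cts$design$season)
  fwd <- nb_wald_test(cts$counts, sf, disp, cts$design)
  swapped <- cts$design
  swapped$season <- ifelse(swapped$season == "summer", "winter", "summer")
  rev <- nb_wald_test(cts$counts, sf, disp, swapped)
  expect_equal(rev$log2fc, -fwd$log2fc, tolerance = 1e-6)
  expect_equal(rev$p, fwd$p, tolerance = 1e-6)

  # sample reordering leaves results unchanged
  ord <- c(7, 2, 9, 1, 5, 3, 10, 4, 8, 6)
  perm <- nb_wald_test(cts$counts[, ord], sf[ord], disp, cts$design[ord, ])
  expect_equal(perm$log2fc, fwd$log2fc, tolerance = 1e-8)
  expect_equal(perm$p, fwd$p, tolerance = 1e-8)

  # confounded design is rejected
  bad <- cts$design
  bad$batch <- ifelse(bad$season == "summer", "b1", "b2")
  expect_error(nb_wald_test(cts$counts, sf, disp, bad), "confounded")
})

test_that("modelling the batch covariate does not inflate false positives", {
  fp <- vapply(1:3, function(s) {
    cfg <- sim_config(seed = 100 + s, n_features = 500L, batch_effect = 2)
    cts <- simulate_counts(cfg)
    with_batch <- run_seasonal_de(cts$counts, cts$design)
    no_batch <- cts$design
    no_batch$batch <- "b1"
    without <- run_seasonal_de(cts$counts, no_batch)
    c(sum(with_batch$significant), sum(without$significant))
  }, numeric(2))
  expect_lte(mean(fp[1, ]), mean(fp[2, ]))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(24)
  for (n in c(2, 5, 12)) {
    p <- runif(n)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("the significance filter applies strict FDR and fold-change bounds", {
  res <- data.frame(feature_id = c("MCM8-like", "small-fc", "weak-q",
                                   "at-boundary"),
                    log2fc = c(5.15, 0.3, -2, 1),
                    p = c(1.68e-20, 1e-5, 0.1, 0.01),
                    q = c(3.13e-16, 0.001, 0.2, 0.05))
  out <- filter_de(res)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$direction[1], "up_summer")
  # a negative effect passing both bounds is down-regulated in summer
  neg <- filter_de(data.frame(feature_id = "x", log2fc = -2, p = 1e-6,
                              q = 1e-4))
  expect_equal(neg$direction, "down_summer")
})

test_that("results track an established NB differential pipeline", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(seed = 29, n_features = 400L,
                    planted_log2fc = setNames(c(3, -3, 2, -2),
                                              sprintf("feat_%04d", 1:4)))
  cts <- simulate_counts(cfg)
  mine <- run_seasonal_de(cts$counts, cts$design)

  suppressPackageStartupMessages(library(DESeq2))
  coldata <- data.frame(season = factor(cts$design$season,
                                        levels = c("winter", "summer")),
                        batch = factor(cts$design$batch))
  dds <- DESeqDataSetFromMatrix(cts$counts, coldata, ~ batch + season)
  dds <- suppressMessages(DESeq(dds, quiet = TRUE))
  ref <- results(dds, contrast = c("season", "summer", "winter"))

  # size factors proportional to the reference implementation
  ratio <- size_factors(cts$counts) / sizeFactors(dds)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  # effect estimates agree closely
  ok <- !is.na(ref$log2FoldChange)
  expect_gt(cor(mine$log2fc[ok], ref$log2FoldChange[ok]), 0.9)
  # the strong planted effects (|log2fc| = 3) are found by both; the weaker
  # pair is borderline at this cohort size for either pipeline
  expect_true(all(mine$significant[1:2]))
  expect_true(all(ref$padj[1:2] < 0.05))
})
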