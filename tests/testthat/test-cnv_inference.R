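test_that("preprocess filters, scales to the median total and genome-orders", {
  # 2 spots with totals 100 and 300 -> scale factors 2.0 and 2/3 (median 200)
  m <- matrix(0L, 2, 4, dimnames = list(c("b1", "b2"),
                                        c("gA", "gB", "gC", "gZero")))
  m["b1", ] <- c(40L, 60L, 0L, 0L)
  m["b2", ] <- c(100L, 140L, 60L, 0L)
  pos <- gene_positions(data.frame(gene_id = c("gC", "gB", "gA", "gZero"),
                                   chromosome = "chr1",
                                   start = c(300, 200, 100, 400),
                                   stop = c(301, 201, 101, 401)))
  cfg <- inference_config(smoothing_window_genes = 1)
  expr <- preprocess(make_counts(m), pos, cfg)
  # all-zero gene dropped (mean 0 < 0.1), columns in genome order
  expect_equal(expr$genes$gene_id, c("gA", "gB", "gC"))
  expect_equal(unname(expr$expr["b1", "gB"]), log2(1 + 60 * 2.0))
  expect_equal(unname(expr$expr["b2", "gB"]), log2(1 + 140 * 2 / 3))

  # gene below the expression cutoff is removed on raw means
  pos5 <- gene_positions(data.frame(gene_id = c("gC", "gB", "gA", "gZero", "gLow"),
                                    chromosome = "chr1",
                                    start = c(300, 200, 100, 400, 500),
                                    stop = c(301, 201, 101, 401, 501)))
  m3 <- cbind(m[, 1:3], gLow = as.integer(c(0, 1)))  # mean 0.5 >= 0.1: kept
  expr3 <- preprocess(make_counts(m3), pos5, cfg)
  expect_true("gLow" %in% expr3$genes$gene_id)
  cfg_hi <- inference_config(gene_mean_cutoff = 0.6, smoothing_window_genes = 1)
  expr4 <- preprocess(make_counts(m3), pos5, cfg_hi)
  expect_false("gLow" %in% expr4$genes$gene_id)

  # unmapped genes are dropped with a warning, not an error
  expect_warning(preprocess(make_counts(m3), pos, cfg), "without genome position")
  # window larger than any chromosome is fatal
  expect_error(preprocess(make_counts(m), pos,
                          inference_config(smoothing_window_genes = 101)),
               "smoothing_window_genes")
})

test_that("pyramidal weights form a normalized triangle, also at edges", {
  W <- sicnv:::pyramidal_weight_matrix(5, 3)
  expect_equal(W[, 3], c(0, 1, 2, 1, 0) / 4)   # (1,2,1)/4 around the centre
  expect_equal(W[, 1], c(2, 1, 0, 0, 0) / 3)   # renormalized at the edge
  for (n in c(1, 4, 9)) {
    for (w in c(1, 3, 7)) {
      expect_equal(colSums(sicnv:::pyramidal_weight_matrix(n, w)), rep(1, n))
    }
  }
  # hand value: row (0,0,3,0,0), window 3 -> centre (1*0 + 2*3 + 1*0)/4 = 1.5
  expect_equal(as.numeric(c(0, 0, 3, 0, 0) %*% W)[3], 1.5)
})

test_that("centering leaves the reference at zero and identical spots at zero", {
  set.seed(42)
  m <- matrix(rpois(50 * 40, 20), 50, 40)
  expr <- preprocess(make_counts(m), make_positions(40),
                     inference_config(smoothing_window_genes = 5))
  ref <- paste0("bc", 1:20)
  res <- center_and_smooth(expr, ref, inference_config(smoothing_window_genes = 5))
  ref_means <- colMeans(res$values[ref, ])
  expect_true(all(abs(ref_means) < 1e-8))

  ident <- matrix(rep(c(10L, 20L, 30L, 5L), each = 6), 6, 4,
                  dimnames = list(paste0("s", 1:6), NULL))
  expr_i <- preprocess(make_counts(ident), make_positions(4),
                       inference_config(smoothing_window_genes = 3))
  res_i <- center_and_smooth(expr_i, NULL, inference_config(smoothing_window_genes = 3))
  expect_true(all(abs(res_i$values) < 1e-12))
})

test_that("a single-gene chromosome passes through smoothing unchanged", {
  # two chromosomes: chr1 with 5 genes, chr2 with 1 gene; the singleton
  # column must equal the unsmoothed centred value (window renormalizes to 1)
  genes <- gene_positions(data.frame(
    gene_id = sprintf("g%02d", 1:6),
    chromosome = c(rep("chr1", 5), "chr2"),
    start = c(1:5 * 100, 100), stop = c(1:5 * 100 + 50, 150)))
  set.seed(1)
  m <- matrix(rpois(8 * 6, 50), 8, 6, dimnames = list(paste0("s", 1:8),
                                                      sprintf("g%02d", 1:6)))
  cfg <- inference_config(smoothing_window_genes = 3)
  expr <- preprocess(make_counts(m), genes, cfg)
  centred <- sweep(expr$expr, 2, colMeans(expr$expr))
  centred <- pmin(pmax(centred, -3), 3)
  res <- center_and_smooth(expr, NULL, cfg)
  # undo the row-median and final centering analytically for the comparison
  W <- sicnv:::pyramidal_weight_matrix(5, 3)
  sm <- cbind(centred[, 1:5] %*% W, centred[, 6])
  sm <- sweep(sm, 1, apply(sm, 1, median))
  sm <- sweep(sm, 2, colMeans(sm))
  expect_equal(unname(res$values), unname(sm))
})

test_that("denoise zeroes within the reference-SD band and keeps the rest", {
  ref <- matrix(rep(c(-0.1, 0.1), 10), 2, 10, byrow = TRUE,
                dimnames = list(c("r1", "r2"), NULL))
  obs <- matrix(c(0, 0.12, 0.5, -0.12, -0.5, 0.2, 0, 0.12, -0.2, 0.05), 1,
                dimnames = list("o1", NULL))
  res <- make_residuals(rbind(ref, obs), reference_barcodes = c("r1", "r2"))
  sigma <- sd(as.vector(ref))
  den <- denoise(res, inference_config(denoise_sd_multiplier = 1.5))
  thr <- 1.5 * sigma
  expect_equal(unname(den$values["o1", ]),
               ifelse(abs(obs[1, ]) <= thr, 0, obs[1, ]))
  expect_equal(unname(den$values["o1", 3]), 0.5)   # beyond threshold: kept

  flat <- make_residuals(matrix(0, 3, 4))
  expect_warning(d0 <- denoise(flat), "skipped")
  expect_equal(d0$values, flat$values)
})

test_that("the six-state HMM decodes runs at the state means", {
  # reference rows define sigma ~= 0.1; observation has three 50-gene runs
  set.seed(2)
  ref <- matrix(rnorm(10 * 150, sd = 0.1), 10, 150,
                dimnames = list(paste0("r", 1:10), NULL))
  obs <- c(rep(0, 50), rep(log2(1.5), 50), rep(-1, 50))
  v <- rbind(ref, o1 = obs)
  res <- make_residuals(v, reference_barcodes = paste0("r", 1:10))
  st <- hmm_states(res)
  expect_equal(st$mode, "cells")
  expect_equal(unname(st$states["o1", 1:50]), rep(3L, 50))
  expect_equal(unname(st$states["o1", 51:100]), rep(4L, 50))
  expect_equal(unname(st$states["o1", 101:150]), rep(2L, 50))

  zero <- make_residuals(matrix(0, 4, 30))
  expect_true(all(hmm_states(zero)$states == 3L))

  # group mode averages member profiles
  grp <- stats::setNames(c(rep("ref", 10), "tum"), rownames(v))
  stg <- hmm_states(res, groups = grp)
  expect_equal(stg$mode, "samples")
  expect_equal(unname(stg$states["tum", 51:100]), rep(4L, 50))
  expect_true(mean(stg$states["ref", ] == 3L) > 0.99)
  expect_error(hmm_states(res, groups = c(bogus = "g")), "missing")
})

test_that("region events are maximal non-neutral runs", {
  st <- make_hmm(matrix(c(3, 3, 4, 4, 3), 1, dimnames = list("c1", NULL)))
  ev <- call_region_events(st)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_genes, 2)
  expect_equal(ev$direction, "gain")
  expect_equal(ev$rank_start, 3)
  expect_equal(ev$rank_end, 4)

  expect_equal(nrow(call_region_events(make_hmm(matrix(3, 2, 6)))), 0)

  ev2 <- call_region_events(make_hmm(matrix(c(2, 2, 3, 6, 6, 6), 1,
                                            dimnames = list("c1", NULL))))
  expect_equal(ev2$direction, c("loss", "gain"))
  expect_equal(ev2$n_genes, c(2, 3))
  expect_equal(ev2$state, c(2, 6))
})

test_that("residual magnitude grows monotonically with copy number", {
  # three clones carrying 2, 3 and 4 copies of a 25-gene segment
  cfg <- simulation_config(domain_size = c(120, 20), spot_pitch = 20,
                           spot_diameter = 16, n_genes = 120,
                           mean_spot_depth = 5e4, depth_dispersion = 1e6,
                           seed = 5)
  seg <- 41:65
  genotypes <- rbind(rep(2L, 120), rep(2L, 120), rep(2L, 120))
  genotypes[2, seg] <- 3L
  genotypes[3, seg] <- 4L
  xy <- rbind(matrix(rep(c(10, 10), 6), ncol = 2, byrow = TRUE),
              matrix(rep(c(50, 10), 6), ncol = 2, byrow = TRUE),
              matrix(rep(c(90, 10), 6), ncol = 2, byrow = TRUE))
  tis <- bin_cells_to_spots(make_tissue(xy, rep(1:3, each = 6), genotypes, cfg))
  set.seed(8)
  cnt <- sample_expression(tis)
  cfg_i <- inference_config(smoothing_window_genes = 11)
  res <- infer_residuals(cnt, simulated_gene_positions(cfg), "s1_1", cfg_i)
  seg_cols <- colnames(res$values) %in% sprintf("g%04d", seg)
  m2 <- mean(res$values["s1_1", seg_cols])
  m3 <- mean(res$values["s3_1", seg_cols])
  m4 <- mean(res$values["s5_1", seg_cols])
  expect_lt(m2, m3)
  expect_lt(m3, m4)
})
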