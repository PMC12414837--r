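test_that("feature filtering applies the inclusive prevalence rule", {
  # 20 samples, 95% -> need >= 19 samples at count >= 10
  vals <- rbind(c(rep(10, 19), 0),       # boundary: exactly 19 -> retained
                rep(9, 20),              # never reaches 10 -> removed
                rep(500, 20),            # passes everywhere
                c(rep(10, 18), 0, 0),    # 18 < 19 -> removed
                rep(0, 20))              # all-zero -> removed
  cm <- counts_fixture(vals)
  out <- filter_features(cm)
  expect_equal(rownames(out), c("f1", "f3"))
  # idempotent
  expect_equal(unclass(filter_features(out)), unclass(out))
  expect_error(filter_features(cm, min_frac = 0), "min_frac")
  expect_error(filter_features(cm, min_frac = 1.2), "min_frac")
})

test_that("logCPM matches its closed form and is monotone within a sample", {
  # one sample with library size 999,999: forced values
  vals <- matrix(c(10L, 0L, 999989L), ncol = 1)
  cm <- counts_fixture(vals)
  lc <- logcpm(cm, prior_count = 0.5)
  expect_equal(lc["f1", 1], log2(10.5), tolerance = 1e-12)
  expect_equal(lc["f2", 1], -1)          # log2(0.5)
  set.seed(1)
  vals2 <- matrix(rpois(300, 50), nrow = 30)
  lc2 <- logcpm(counts_fixture(vals2))
  for (s in seq_len(ncol(vals2))) {
    o <- order(vals2[, s])
    expect_true(all(diff(unclass(lc2)[o, s]) >= 0))
  }
})

test_that("residualization removes modelled covariates and is idempotent", {
  set.seed(7)
  samples <- sample_fixture(50, 50)
  batch_num <- as.numeric(samples$batch == "b2")
  vals <- rbind(5 * batch_num + 3,                       # pure batch effect
                2 * samples$age + rnorm(100, sd = 0.1),  # age effect
                rnorm(100))
  ex <- expr_fixture(vals, stage = "raw-logcpm")
  colnames(ex) <- samples$sample_id
  corr <- residualize(ex, samples, c("batch", "age"))
  # batch-wise means equal after correction
  m1 <- mean(corr["f1", batch_num == 1])
  m0 <- mean(corr["f1", batch_num == 0])
  expect_lt(abs(m1 - m0), 1e-8)
  expect_lt(abs(stats::cor(corr["f2", ], samples$age)), 0.1)
  # empty covariate list is the identity on the values
  ident <- residualize(ex, samples, character(0))
  expect_equal(as.vector(ident), as.vector(unclass(ex)))
  expect_equal(attr(ident, "stage"), "corrected")
  # idempotent for a fixed design
  twice <- residualize(corr, samples, c("batch", "age"))
  expect_lt(max(abs(unclass(twice) - unclass(corr))), 1e-8)
  # group must never be residualized; collinear designs are named
  expect_error(residualize(ex, samples, c("batch", "group")), "group")
  samples$batch2 <- samples$batch
  expect_error(residualize(ex, samples, c("batch", "batch2")),
               "collinear.*batch2")
})

test_that("features with any negative corrected value are dropped", {
  vals <- rbind(c(1, 2, 3), c(1, -0.01, 3), c(0, 0, 0), c(-5, 1, 1),
                c(2, 2, 2))
  ex <- expr_fixture(vals, stage = "corrected")
  out <- drop_negative_features(ex)
  expect_equal(rownames(out), c("f1", "f3", "f5"))
  pos <- expr_fixture(matrix(1:6, 2), stage = "corrected")
  expect_equal(unclass(drop_negative_features(pos)), unclass(pos))
  raw <- expr_fixture(vals, stage = "raw-logcpm")
  expect_error(drop_negative_features(raw), "corrected")
})

test_that("isoform ratios divide transcript by gene values with 0/0 imputation", {
  genes <- expr_fixture(rbind(g1 = c(4, 2, 0), g2 = c(2, 2, 2)),
                        stage = "corrected")
  tx <- expr_fixture(rbind(`g1-t1` = c(2, 1, 0),
                           `g1-t2` = c(1, 0.4, 0),
                           `g2-t1` = c(2, 2, 2)),
                     level = "transcript", stage = "corrected")
  map <- data.frame(transcript_id = c("g1-t1", "g1-t2", "g2-t1"),
                    gene_id = c("g1", "g1", "g2"))
  ir <- compute_isoform_ratios(tx, genes, map)
  expect_equal(unname(ir["g1-t1", ]), c(0.5, 0.5, 0.5))     # 0/0 -> mean(0.5, 0.5)
  expect_equal(unname(ir["g1-t2", ]), c(0.25, 0.2, 0.225))  # imputed mean 0.225
  # single-isoform gene with tx == gene everywhere
  expect_equal(unname(ir["g2-t1", ]), c(1, 1, 1))
  expect_true(all(is.finite(unclass(ir))))
  # 0 denominator with non-zero numerator is an error naming the pair
  tx2 <- expr_fixture(rbind(`g1-t1` = c(2, 1, 1)), level = "transcript",
                      stage = "corrected")
  expect_error(compute_isoform_ratios(tx2, genes, map), "g1-t1.*s3")
  # unmapped transcript
  expect_error(compute_isoform_ratios(tx, genes, map[-1, ]), "g1-t1")
})

test_that("transcripts of filtered genes are excluded, not errors", {
  genes <- expr_fixture(rbind(g1 = c(4, 2, 1)), stage = "corrected")
  tx <- expr_fixture(rbind(`g1-t1` = c(2, 1, 1), `gX-t1` = c(1, 1, 1)),
                     level = "transcript", stage = "corrected")
  map <- data.frame(transcript_id = c("g1-t1", "gX-t1"),
                    gene_id = c("g1", "gX"))
  ir <- compute_isoform_ratios(tx, genes, map)
  expect_equal(rownames(ir), "g1-t1")
})

test_that("PCA outlier detection flags a planted outlier and nothing else", {
  set.seed(9)
  n <- 50
  vals <- matrix(rnorm(40 * n), 40, n)
  sds <- apply(vals, 1, sd)
  vals[, 7] <- vals[, 7] + 10 * sds          # shifted by 10 SD on all features
  ex <- expr_fixture(vals, stage = "corrected")
  out <- detect_outlier_samples(ex, NULL, sd_mult = 2)
  expect_true("s7" %in% out)
  # a huge multiplier flags nothing
  expect_length(detect_outlier_samples(ex, NULL, sd_mult = 1e6), 0)
  # duplicated identical samples: no variance, no outliers
  dup <- expr_fixture(matrix(rep(c(1, 2, 3, 4), 5), 4, 5), stage = "corrected")
  expect_length(detect_outlier_samples(dup, NULL), 0)
  expect_error(detect_outlier_samples(ex, NULL, sd_mult = 0), "sd_mult")
  # union over gene and IR matrices
  irv <- matrix(rnorm(20 * n), 20, n,
                dimnames = list(paste0("g", 1:20, "-t1"), colnames(ex)))
  irv[, 12] <- irv[, 12] + 10 * apply(irv, 1, sd)
  ir <- ir_matrix(irv, structure(paste0("g", 1:20),
                                 names = paste0("g", 1:20, "-t1")))
  both <- detect_outlier_samples(ex, ir, sd_mult = 2)
  expect_true(all(c("s7", "s12") %in% both))
})
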