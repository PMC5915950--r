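test_that("BH adjustment matches the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_lt(max(abs(bh_adjust(p) - p.adjust(p, "BH"))), 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("relations use an inclusive FDR threshold and fixed orientation", {
  expect_identical(relation_of(0.05, 2), "EQ")
  # log2fc is second-over-first, so a significant positive value means
  # the first-named group is lower
  expect_identical(relation_of(0.0005, 2), "LT")
  expect_identical(relation_of(0.0005, -2), "GT")
  expect_identical(relation_of(0.001, 1), "LT")  # boundary is significant
  expect_identical(relation_of(0.0011, 1), "EQ")
})

test_that("the NB Wald test is symmetric, calibrated, and powered", {
  genes <- sprintf("g%04d", 1:400)
  set.seed(5)
  a <- matrix(rnbinom(1200, mu = 50, size = 20), 400, 3,
              dimnames = list(genes, NULL))
  # identical columns: zero fold change, all EQ
  res <- nb_wald_test(a, a)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$relation[res$tested] == "EQ"))
  # antisymmetry of the statistic under group swap
  b <- matrix(rnbinom(1200, mu = 50, size = 20), 400, 3,
              dimnames = list(genes, NULL))
  fwd <- nb_wald_test(a, b)
  rev <- nb_wald_test(b, a)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  # all-zero genes are skipped, not called EQ
  a0 <- a; a0[1, ] <- 0
  b0 <- b; b0[1, ] <- 0
  res0 <- nb_wald_test(a0, b0)
  expect_false(res0$tested[1])
  expect_true(is.na(res0$relation[1]))
  expect_error(nb_wald_test(a[, 1, drop = FALSE], b), "replicates")
})

test_that("additivity categories partition all relation triples", {
  rels <- c("EQ", "GT", "LT")
  grid <- expand.grid(mav = rels, bd = rels, bs = rels,
                      stringsAsFactors = FALSE)
  out <- classify_additivity(grid$mav, grid$bd, grid$bs)
  expect_false(any(is.na(out)))
  expect_true(all(out[grid$mav == "EQ"] == "ADDITIVE"))
  non <- grid$mav != "EQ"
  expect_true(all(out[non & grid$bd == "EQ" & grid$bs != "EQ"] ==
                    "ELD_BD"))
  expect_true(all(out[non & grid$bs == "EQ" & grid$bd != "EQ"] ==
                    "ELD_BS"))
  expect_true(all(out[non & grid$bd == "GT" & grid$bs == "GT"] ==
                    "TRANSGRESSIVE_UP"))
  expect_true(all(out[non & grid$bd == "LT" & grid$bs == "LT"] ==
                    "TRANSGRESSIVE_DOWN"))
  # the residual class: opposite inequalities, or EQ to both parents
  # while differing from their mid-value
  expect_identical(unname(classify_additivity("GT", "GT", "LT")),
                   "OTHER_NONADDITIVE")
  expect_identical(unname(classify_additivity("GT", "EQ", "EQ")),
                   "OTHER_NONADDITIVE")
})

test_that("bias categories map the nine relation pairs exhaustively", {
  rels <- c("EQ", "GT", "LT")
  grid <- expand.grid(anc = rels, hyb = rels, stringsAsFactors = FALSE)
  out <- classify_bias(grid$anc, grid$hyb)
  want <- c(EQ.EQ = "NO_BIAS", GT.EQ = "BIAS_LOST", LT.EQ = "BIAS_LOST",
            EQ.GT = "BIAS_GAINED", GT.GT = "BIAS_RETAINED",
            LT.GT = "BIAS_REVERSED", EQ.LT = "BIAS_GAINED",
            GT.LT = "BIAS_REVERSED", LT.LT = "BIAS_RETAINED")
  expect_identical(out$category,
                   unname(want[paste(grid$anc, grid$hyb, sep = ".")]))
  expect_identical(out$pattern_class,
                   ifelse(out$category %in% c("NO_BIAS", "BIAS_RETAINED"),
                          "ANCESTRAL", "NONANCESTRAL"))
})

test_that("transcriptome classification respects filter and symmetry", {
  cfg <- sim_config(seed = 31, dispersion = 0.02, fold_change = 4,
                    min_fraction = 2e-4)
  sim <- simulate_counts(sprintf("g%03d", 1:200), cfg)
  cs <- sim$count_set
  cls <- classify_transcriptome(cs, alpha = 0.001)
  # expressed filter: genes below threshold in any MAV/BH replicate are
  # absent from the output
  mav_rpm <- compute_rpm(compute_mav(cs))
  bh_rpm <- compute_rpm(compute_bh_total(cs))
  expressed <- rowSums(mav_rpm < 1) == 0 & rowSums(bh_rpm < 1) == 0
  expect_setequal(cls$gene, rownames(cs$counts)[expressed])

  # swapping the two ancestors (and the two homoeolog columns) swaps
  # ELD labels and leaves additive/transgressive counts unchanged
  swap_group <- c(BD = "BS", BS = "BD", BH_BD = "BH_BS", BH_BS = "BH_BD")
  s2 <- cs$samples
  s2$group <- unname(swap_group[s2$group])
  s2$sample_id <- sprintf("%s_%s_r%d", s2$group, s2$condition,
                          s2$replicate)
  counts2 <- cs$counts
  colnames(counts2) <- s2$sample_id
  cs2 <- count_set(counts2, s2, setNames(cs$library_sizes, s2$sample_id))
  cls2 <- classify_transcriptome(cs2, alpha = 0.001)
  m <- merge(cls, cls2, by = "gene")
  swap_cat <- c(ADDITIVE = "ADDITIVE", ELD_BD = "ELD_BS",
                ELD_BS = "ELD_BD", TRANSGRESSIVE_UP = "TRANSGRESSIVE_UP",
                TRANSGRESSIVE_DOWN = "TRANSGRESSIVE_DOWN",
                OTHER_NONADDITIVE = "OTHER_NONADDITIVE")
  expect_identical(m$additivity.y, unname(swap_cat[m$additivity.x]))
  swap_rel <- c(EQ = "EQ", GT = "LT", LT = "GT")
  expect_identical(m$rel_bd_vs_bs.y, unname(swap_rel[m$rel_bd_vs_bs.x]))

  expect_error(classify_transcriptome(
    hand_count_set(list(BD = matrix(5, 1, 3,
                                    dimnames = list("g", NULL))))),
    "lacks group")
})

test_that("an all-additive unbiased simulation yields few false calls", {
  cfg <- sim_config(seed = 41, dispersion = 0.05,
                    category_proportions = c(ADDITIVE = 1),
                    bias_proportions = c(NO_BIAS = 1))
  sim <- simulate_counts(sprintf("g%04d", 1:2000), cfg)
  cls <- classify_transcriptome(sim$count_set, alpha = 0.001)
  expect_lt(mean(cls$additivity != "ADDITIVE"), 0.01)
  expect_lt(mean(cls$bias != "NO_BIAS"), 0.01)
})
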