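test_that("config invariants are enforced", {
  expect_error(sim_config(divergence_rate = 1.5), "divergence_rate")
  expect_error(sim_config(fold_change = 1), "fold_change")
  expect_error(sim_config(cds_length = 100), "multiple of 3")
  expect_error(sim_config(category_proportions = c(ADDITIVE = 0.5)),
               "summing to 1")
})

test_that("ancestral genome pair realizes the divergence model", {
  # zero divergence: identical genomes, empty truth
  g0 <- simulate_ancestral_genomes(tiny_config(divergence_rate = 0))
  expect_identical(g0$genome_a, setNames(g0$genome_b, names(g0$genome_a)))
  expect_equal(nrow(g0$snp_truth), 0)

  # d = 0.01 on 100 kb: SNP count within 4 binomial SDs of 1000
  g1 <- simulate_ancestral_genomes(
    sim_config(seed = 5, genome_length = 100000L, n_genes = 10L,
               divergence_rate = 0.01))
  sd4 <- 4 * sqrt(100000 * 0.01 * 0.99)
  expect_lt(abs(nrow(g1$snp_truth) - 1000), sd4)

  # construction invariant: Hamming distance equals the truth size,
  # and every truth allele is placed as recorded
  for (seed in c(1, 2, 3)) {
    g <- simulate_ancestral_genomes(tiny_config(seed = seed))
    expect_equal(hamming(g$genome_a[[1]], g$genome_b[[1]]),
                 nrow(g$snp_truth))
    a <- strsplit(g$genome_a[[1]], "")[[1]]
    b <- strsplit(g$genome_b[[1]], "")[[1]]
    expect_identical(a[g$snp_truth$pos], g$snp_truth$allele_a)
    expect_identical(b[g$snp_truth$pos], g$snp_truth$allele_b)
    expect_false(anyDuplicated(g$snp_truth$pos) > 0)
  }

  expect_error(
    simulate_ancestral_genomes(
      sim_config(genome_length = 1000L, n_genes = 10L)),
    "too small")
})

test_that("gene models have valid coding structure on both strands", {
  g <- simulate_ancestral_genomes(tiny_config())
  code <- Biostrings::GENETIC_CODE
  for (gid in unique(g$gene_models$gene_id)) {
    pair <- extract_cds_pair(gid, g$gene_models, g$genome_a, g$genome_a)
    cds <- pair$cds_a
    expect_equal(nchar(cds) %% 3, 0)
    expect_identical(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- unname(code[codons])
    expect_identical(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
  strands <- tapply(g$gene_models$strand, g$gene_models$gene_id,
                    function(s) s[1])
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("simulated reads carry the planted mismatch structure", {
  cfg <- tiny_config(error_rate = 0)
  g <- simulate_ancestral_genomes(cfg)
  r <- simulate_reads(g$genome_a, g$genome_b, cfg)
  L <- cfg$read_length
  spanned <- vapply(seq_len(nrow(r$reads)), function(i) {
    sum(g$snp_truth$pos >= r$reads$pos[i] &
          g$snp_truth$pos <= r$reads$pos[i] + L - 1)
  }, 1)
  to_a <- vapply(seq_len(nrow(r$reads)), function(i)
    oracle_hamming(r$reads$seq[i],
                   substr(g$genome_a[[1]], r$reads$pos[i],
                          r$reads$pos[i] + L - 1)), 1)
  to_b <- vapply(seq_len(nrow(r$reads)), function(i)
    oracle_hamming(r$reads$seq[i],
                   substr(g$genome_b[[1]], r$reads$pos[i],
                          r$reads$pos[i] + L - 1)), 1)
  from_b <- r$reads$origin == "B"
  # error-free: distance 0 to the origin genome, = spanned SNPs to the other
  expect_true(all(to_b[from_b] == 0))
  expect_true(all(to_a[!from_b] == 0))
  expect_identical(to_a[from_b], spanned[from_b])
  expect_identical(to_b[!from_b], spanned[!from_b])
  # reads spanning no SNP are equidistant (0) from both genomes
  none <- spanned == 0
  expect_true(all(to_a[none] == 0 & to_b[none] == 0))

  # with errors: mean mismatches to the origin genome ~ L * e
  cfg2 <- tiny_config(seed = 202L, error_rate = 0.01, n_reads = 4000L)
  g2 <- simulate_ancestral_genomes(cfg2)
  r2 <- simulate_reads(g2$genome_a, g2$genome_b, cfg2)
  aln <- align_reads_naive(
    r2$reads[r2$reads$origin == "A", , drop = FALSE], g2$genome_a)
  expect_equal(mean(aln$nm), cfg2$read_length * 0.01, tolerance = 0.1)

  expect_error(
    simulate_reads(c(c1 = "ACGT"), c(c1 = "ACGT"), tiny_config()),
    "shortest contig")
})

test_that("oracle aligner reports true-locus Hamming distances", {
  cfg <- tiny_config(n_reads = 300L)
  g <- simulate_ancestral_genomes(cfg)
  r <- simulate_reads(g$genome_a, g$genome_b, cfg)
  for (genome in list(g$genome_a, g$genome_b)) {
    aln <- align_reads_naive(r$reads, genome)
    brute <- vapply(seq_len(nrow(r$reads)), function(i)
      oracle_hamming(r$reads$seq[i],
                     substr(genome[[r$reads$contig[i]]], r$reads$pos[i],
                            r$reads$pos[i] + nchar(r$reads$seq[i]) - 1)),
      1)
    expect_identical(aln$nm, as.integer(brute))
  }
})

test_that("emitted SNP calls realize homogenic/heterogenic structure", {
  cfg <- tiny_config()
  g <- simulate_ancestral_genomes(cfg)
  calls <- emit_snp_calls(g$genome_a, g$genome_b, g$snp_truth, cfg)
  expect_identical(sort(calls$calls_b$pos), sort(g$snp_truth$pos))
  expect_identical(sort(calls$calls_h$pos), sort(g$snp_truth$pos))
  expect_true(all(calls$calls_b$var_freq >= 0.9))
  expect_true(all(calls$calls_h$var_freq >= 0.3 &
                    calls$calls_h$var_freq <= 0.7))
  expect_true(all(calls$calls_b$depth == cfg$call_depth))

  cfgn <- tiny_config(noise_rate = 0.001)
  gn <- simulate_ancestral_genomes(cfgn)
  noisy <- emit_snp_calls(gn$genome_a, gn$genome_b, gn$snp_truth, cfgn)
  expect_gt(nrow(noisy$calls_b) + nrow(noisy$calls_h),
            2 * nrow(gn$snp_truth))
})

test_that("deterministic count mode plants exact category structure", {
  cfg <- sim_config(seed = 3, dispersion = 0, library_size = 1e6,
                    fold_change = 4)
  sim <- simulate_counts(sprintf("g%03d", 1:300), cfg,
                         mode = "deterministic")
  cs <- sim$count_set
  tr <- sim$gene_truth
  bh <- compute_bh_total(cs)
  mav <- compute_mav(cs)
  # additive genes: hybrid total equals the mid-ancestral expectation
  add <- tr$additivity == "ADDITIVE"
  expect_equal(unname(bh$counts[add, 1]),
               unname(round(tr$f_bhbd * 1e6) + round(tr$f_bhbs * 1e6))[add])
  expect_true(all(abs((tr$f_bhbd + tr$f_bhbs) -
                        (tr$f_bd + tr$f_bs) / 2)[add] < 1e-12))
  # ELD: hybrid total copies one ancestor, ancestors a fold apart
  eld_bd <- tr$additivity == "ELD_BD"
  expect_true(all(abs((tr$f_bhbd + tr$f_bhbs - tr$f_bd))[eld_bd] < 1e-12))
  ratio <- pmax(tr$f_bd, tr$f_bs) / pmin(tr$f_bd, tr$f_bs)
  expect_true(all(abs(ratio[eld_bd] - cfg$fold_change) < 1e-9))
  # transgressive up: total is F x the larger ancestor
  tg <- tr$additivity == "TRANSGRESSIVE_UP"
  expect_true(all(abs((tr$f_bhbd + tr$f_bhbs) -
                        cfg$fold_change * pmax(tr$f_bd, tr$f_bs))[tg] <
                    1e-12))
  # spec worked example: f = 1e-5 additive unbiased gene at N = 1e6
  # yields hybrid-total count 10 in deterministic mode
  expect_equal(unname(round(1e-5 * 1e6)), 10)
  # per-sample fraction conservation
  expect_true(all(colSums(cs$counts) <= 1e6))
})

test_that("NB counts concentrate around the planted means", {
  cfg <- sim_config(seed = 9, dispersion = 0.05, library_size = 1e6,
                    n_replicates = 50L,
                    category_proportions = c(ADDITIVE = 1),
                    bias_proportions = c(NO_BIAS = 1))
  sim <- simulate_counts(sprintf("g%03d", 1:100), cfg)
  cs <- sim$count_set
  mu <- sim$gene_truth$f_bd * 1e6
  cols <- cs$samples$group == "BD"
  m <- rowMeans(cs$counts[, cols])
  se <- sqrt((mu + 0.05 * mu^2) / 50)
  # ~99.7% of genes inside 3 SEs; allow a small margin at n = 100
  expect_gte(mean(abs(m - mu) <= 3 * se), 0.95)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_config(noise_rate = 0.001)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genome_b, s2$genome_b)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$calls_h, s2$calls_h)
  expect_identical(s1$count_set$counts, s2$count_set$counts)
  expect_identical(s1$gene_truth, s2$gene_truth)
})
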