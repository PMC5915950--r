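call_df <- function(pos, ref, var, depth, freq, contig = "chr1") {
  data.frame(contig = contig, pos = pos, ref_base = ref, var_base = var,
             depth = depth, var_freq = freq, stringsAsFactors = FALSE)
}

test_that("calls classify by depth and variant frequency", {
  calls <- call_df(c(100, 101, 102, 103, 104),
                   "C", "T", c(20, 20, 5, 20, 20),
                   c(0.98, 0.52, 0.98, 0.8, 0.25))
  expect_identical(classify_call(calls),
                   c("HOMOGENIC", "HETEROGENIC", "AMBIGUOUS",
                     "AMBIGUOUS", "AMBIGUOUS"))
  # depth floor of 8: a depth-8 call is deep enough, depth-7 is not
  edge <- call_df(c(1, 2), "A", "G", c(8, 7), c(0.95, 0.95))
  expect_identical(classify_call(edge), c("HOMOGENIC", "AMBIGUOUS"))
  expect_error(classify_call(calls, list(min_depth = 8, homo_freq = 0.4,
                                         het_low = 0.3, het_high = 0.7)),
               "invalid thresholds")
  expect_error(classify_call(calls, list(min_depth = 8, homo_freq = 0.9,
                                         het_low = 0.7, het_high = 0.3)),
               "invalid thresholds")
})

test_that("homoeologous SNPs are the allele-matched intersection", {
  b <- call_df(c(100, 200, 300), "C", c("T", "G", "A"), 20,
               c(0.98, 0.97, 0.99))
  h <- call_df(c(100, 300, 400), "C", c("T", "C", "G"), 30,
               c(0.52, 0.48, 0.51))
  h$var_base[2] <- "T"  # different var allele than B at 300 ("A")
  out <- identify_homoeologous_snps(b, h)
  expect_equal(nrow(out), 1)
  expect_identical(out$pos, 100)
  expect_identical(out$allele_ref, "C")
  expect_identical(out$allele_alt, "T")

  dup <- rbind(b, b[1, ])
  expect_error(identify_homoeologous_snps(dup, h), "duplicate")
})

test_that("simulator truth round-trips through the SNP map", {
  cfg <- tiny_config()
  g <- simulate_ancestral_genomes(cfg)
  calls <- emit_snp_calls(g$genome_a, g$genome_b, g$snp_truth, cfg)
  map <- identify_homoeologous_snps(calls$calls_b, calls$calls_h)
  expect_identical(map$pos, g$snp_truth$pos)
  expect_identical(map$allele_ref, g$snp_truth$allele_a)
  expect_identical(map$allele_alt, g$snp_truth$allele_b)
})

test_that("classification is monotone in its thresholds", {
  set.seed(42)
  calls <- call_df(seq_len(500), "A", "C",
                   sample(0:40, 500, replace = TRUE), runif(500))
  base <- snp_thresholds()
  homo0 <- classify_call(calls, base) == "HOMOGENIC"
  het0 <- classify_call(calls, base) == "HETEROGENIC"
  for (hf in c(0.92, 0.95, 0.99)) {
    th <- base; th$homo_freq <- hf
    expect_true(all((classify_call(calls, th) == "HOMOGENIC") <= homo0))
  }
  wide <- base; wide$het_low <- 0.2; wide$het_high <- 0.8
  expect_true(all(het0 <= (classify_call(calls, wide) == "HETEROGENIC")))
})

test_that("coding effects follow the genetic code on a hand-built gene", {
  hg <- hand_gene()
  snp <- function(pos, ref, alt)
    data.frame(contig = "chr1", pos = pos, allele_ref = ref,
               allele_alt = alt, stringsAsFactors = FALSE)
  eff <- function(...) annotate_effect(snp(...), hg$models, hg$genome)
  # codon 2 TTT (genomic 7-9): TTT -> TTC is synonymous
  expect_identical(eff(9, "T", "C")$coding_effect, "SYNONYMOUS")
  # ATG -> ATA start loss (CDS pos 3 = genomic 6)
  expect_identical(eff(6, "G", "A")$coding_effect, "START_LOST")
  # codon 3 TGG (genomic 10-12) -> TGA stop gained
  expect_identical(eff(12, "G", "A")$coding_effect, "STOP_GAINED")
  # terminal TAA -> CAA stop lost (first stop base = genomic 28)
  expect_identical(eff(28, "T", "C")$coding_effect, "STOP_LOST")
  # TTT -> CTT nonsynonymous (genomic 7)
  expect_identical(eff(7, "T", "C")$coding_effect, "NONSYNONYMOUS")
  # intron is genomic 19-24: 2 bp from a boundary is splice site,
  # deeper inside is intron
  expect_identical(eff(20, "T", "C")$region, "SPLICE_SITE")
  expect_identical(eff(21, "A", "C")$region, "INTRON")
  expect_identical(eff(2, "C", "A")$region, "UTR")
  expect_identical(eff(40, "T", "A")$region, "INTERGENIC")
  expect_error(eff(12, "T", "C"), "disagrees")
})

test_that("effect calls agree with a full-CDS translation oracle", {
  cfg <- tiny_config(seed = 77L, divergence_rate = 0.01)
  g <- simulate_ancestral_genomes(cfg)
  eff <- annotate_effect(g$snp_truth[, c("contig", "pos")] |>
                           cbind(allele_ref = g$snp_truth$allele_a,
                                 allele_alt = g$snp_truth$allele_b),
                         g$gene_models, g$genome_a)
  in_cds <- which(eff$region == "EXON_CDS")
  expect_gt(length(in_cds), 10)
  code <- Biostrings::GENETIC_CODE
  translate <- function(cds) {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    paste(code[codons], collapse = "")
  }
  for (i in sample(in_cds, min(100, length(in_cds)))) {
    one <- eff[i, ]
    mutant <- build_virtual_genome(
      g$genome_a, data.frame(contig = one$contig, pos = one$pos,
                             allele_ref = one$allele_ref,
                             allele_alt = one$allele_alt))
    pair <- extract_cds_pair(one$gene_id, g$gene_models, g$genome_a,
                             mutant)
    p_ref <- translate(pair$cds_a); p_alt <- translate(pair$cds_b)
    expected <-
      if (substr(pair$cds_b, 1, 3) != "ATG") "START_LOST"
      else if (endsWith(p_ref, "*") && !endsWith(p_alt, "*")) "STOP_LOST"
      else if (grepl("*", substr(p_alt, 1, nchar(p_alt) - 1),
                     fixed = TRUE)) "STOP_GAINED"
      else if (p_ref == p_alt) "SYNONYMOUS"
      else "NONSYNONYMOUS"
    expect_identical(one$coding_effect, expected)
  }
})

test_that("effect summaries partition the input", {
  empty <- summarize_effects(
    data.frame(region = character(), coding_effect = character(),
               gene_id = character()))
  expect_true(all(empty$region_counts == 0))
  eff <- data.frame(
    region = c("INTRON", "EXON_CDS", "INTERGENIC", "EXON_CDS"),
    coding_effect = c("NONE", "SYNONYMOUS", "NONE", "NONSYNONYMOUS"),
    gene_id = c("g1", "g1", NA, "g2"), stringsAsFactors = FALSE)
  s <- summarize_effects(eff)
  expect_equal(unname(s$region_counts[c("INTRON", "EXON_CDS",
                                        "INTERGENIC")]), c(1, 2, 1))
  expect_equal(sum(s$region_counts), nrow(eff))
  expect_equal(sum(s$effect_counts), nrow(eff))
  expect_identical(
    s$gene_flags$has_nonsynonymous[s$gene_flags$gene_id == "g2"], TRUE)
  expect_identical(
    s$gene_flags$has_nonsynonymous[s$gene_flags$gene_id == "g1"], FALSE)
})
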