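# Homoeologous SNP identification. A reference position is a homoeologous
# SNP when the second ancestor's reads are uniformly variant there
# (homogenic call) and the hybrid's reads carry both alleles (heterogenic
# call, the two subgenomes differing), with the same variant base in both
# call sets.

#' Default call-classification thresholds
#'
#' `min_depth` follows the pileup caller's default depth floor of 8 reads;
#' the homogenic frequency cutoff (0.9) and heterogenic window (0.3-0.7)
#' are configurable package defaults.
#'
#' @return named list of thresholds.
#' @export
snp_thresholds <- function() {
  list(min_depth = 8, homo_freq = 0.9, het_low = 0.3, het_high = 0.7)
}

validate_thresholds <- function(th) {
  need <- c("min_depth", "homo_freq", "het_low", "het_high")
  if (!all(need %in% names(th)))
    stop("thresholds must contain: ", paste(need, collapse = ", "))
  if (!(th$homo_freq > 0.5 && th$homo_freq <= 1))
    stop("invalid thresholds: need 0.5 < homo_freq <= 1")
  if (!(th$het_low < th$het_high && th$het_high < th$homo_freq))
    stop("invalid thresholds: need het_low < het_high < homo_freq")
  invisible(th)
}

#' Classify SNP calls as homogenic, heterogenic, or ambiguous
#'
#' A call is HOMOGENIC when its depth reaches `min_depth` and its variant
#' frequency is at least `homo_freq`; HETEROGENIC when depth reaches
#' `min_depth` and the frequency falls inside `[het_low, het_high]`;
#' otherwise AMBIGUOUS.
#'
#' @param calls SNP call data frame (see [read_snp_calls()]).
#' @param thresholds threshold list, default [snp_thresholds()].
#' @return character vector of classes, one per call.
#' @export
classify_call <- function(calls, thresholds = snp_thresholds()) {
  validate_thresholds(thresholds)
  deep <- calls$depth >= thresholds$min_depth
  cls <- rep("AMBIGUOUS", nrow(calls))
  cls[deep & calls$var_freq >= thresholds$homo_freq] <- "HOMOGENIC"
  cls[deep & calls$var_freq >= thresholds$het_low &
        calls$var_freq <= thresholds$het_high] <- "HETEROGENIC"
  cls
}

#' Identify homoeologous SNPs
#'
#' Intersects homogenic second-ancestor-vs-reference calls with
#' heterogenic hybrid-vs-reference calls: positions sharing contig,
#' position, and variant base in both sets become homoeologous SNPs.
#'
#' @param calls_b ancestor-vs-reference calls.
#' @param calls_h hybrid-vs-reference calls.
#' @param thresholds threshold list, default [snp_thresholds()].
#' @return data frame map with `contig`, `pos`, `allele_ref`,
#'   `allele_alt`, sorted by contig then position.
#' @export
identify_homoeologous_snps <- function(calls_b, calls_h,
                                       thresholds = snp_thresholds()) {
  validate_thresholds(thresholds)
  for (nm in c("calls_b", "calls_h")) {
    calls <- get(nm)
    key <- paste(calls$contig, calls$pos)
    if (anyDuplicated(key))
      stop("duplicate position in ", nm, ": ", key[duplicated(key)][1])
  }
  b <- calls_b[classify_call(calls_b, thresholds) == "HOMOGENIC", ]
  h <- calls_h[classify_call(calls_h, thresholds) == "HETEROGENIC", ]
  m <- merge(b[, c("contig", "pos", "ref_base", "var_base")],
             h[, c("contig", "pos", "ref_base", "var_base")],
             by = c("contig", "pos", "ref_base", "var_base"))
  out <- data.frame(contig = m$contig, pos = m$pos,
                    allele_ref = m$ref_base, allele_alt = m$var_base,
                    stringsAsFactors = FALSE)
  out[order(out$contig, out$pos), , drop = FALSE]
}

REGION_LEVELS <- c("INTERGENIC", "INTRON", "EXON_CDS", "UTR", "SPLICE_SITE")
EFFECT_LEVELS <- c("NONE", "SYNONYMOUS", "NONSYNONYMOUS", "START_LOST",
                   "STOP_GAINED", "STOP_LOST")

# transcript-ordered CDS genomic positions for one gene
cds_positions <- function(feat) {
  cds <- feat[feat$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  pos <- unlist(Map(seq.int, cds$start, cds$end), use.names = FALSE)
  if (feat$strand[1] == "-") rev(pos) else pos
}

#' Predict the genomic location and coding effect of homoeologous SNPs
#'
#' Assigns each SNP a region (intergenic, intron, CDS exon, UTR, or splice
#' site: within 2 bp of an intron boundary, taking precedence over intron)
#' and, for CDS positions, a coding effect obtained by substituting the
#' alternative allele into its codon (strand-aware) and translating with
#' the standard genetic code. The first CDS codon ceasing to be ATG is
#' START_LOST; a non-terminal codon becoming a stop is STOP_GAINED; the
#' terminal stop becoming a non-stop is STOP_LOST.
#'
#' @param snps homoeologous SNP map data frame.
#' @param gene_models gene-model data frame.
#' @param genome reference genome (allele_ref must match it).
#' @return data frame: map columns plus `region`, `coding_effect`,
#'   `gene_id` (NA outside genes).
#' @export
annotate_effect <- function(snps, gene_models, genome) {
  validate_genome(genome)
  code <- Biostrings::GENETIC_CODE
  n <- nrow(snps)
  region <- rep("INTERGENIC", n)
  effect <- rep("NONE", n)
  gene_id <- rep(NA_character_, n)
  spans <- do.call(rbind, lapply(split(gene_models, gene_models$gene_id),
    function(f) data.frame(gene_id = f$gene_id[1], contig = f$contig[1],
                           start = min(f$start), end = max(f$end),
                           stringsAsFactors = FALSE)))
  for (i in seq_len(n)) {
    ctg <- snps$contig[i]; p <- snps$pos[i]
    if (substr(genome[[ctg]], p, p) != snps$allele_ref[i])
      stop("allele_ref disagrees with genome at ", ctg, ":", p)
    hit <- spans[spans$contig == ctg & spans$start <= p & spans$end >= p, ]
    if (!nrow(hit)) next
    g <- hit$gene_id[1]
    gene_id[i] <- g
    feat <- gene_models[gene_models$gene_id == g, , drop = FALSE]
    in_type <- function(tp) {
      ft <- feat[feat$type == tp, , drop = FALSE]
      any(ft$start <= p & ft$end >= p)
    }
    if (in_type("CDS")) {
      region[i] <- "EXON_CDS"
      tx <- cds_positions(feat)
      idx <- match(p, tx)
      codon_i <- (idx - 1L) %/% 3L + 1L
      within <- (idx - 1L) %% 3L + 1L
      n_codons <- length(tx) / 3L
      minus <- feat$strand[1] == "-"
      cpos <- tx[(codon_i - 1L) * 3L + 1:3]
      bases <- vapply(cpos, function(q) substr(genome[[ctg]], q, q), "")
      if (minus) bases <- unname(COMPLEMENT[bases])
      ref_codon <- paste(bases, collapse = "")
      alt_base <- if (minus) COMPLEMENT[[snps$allele_alt[i]]]
                  else snps$allele_alt[i]
      bases[within] <- alt_base
      alt_codon <- paste(bases, collapse = "")
      ref_aa <- code[[ref_codon]]; alt_aa <- code[[alt_codon]]
      effect[i] <-
        if (codon_i == 1L && ref_codon == "ATG" && alt_codon != "ATG")
          "START_LOST"
        else if (codon_i == n_codons && ref_aa == "*" && alt_aa != "*")
          "STOP_LOST"
        else if (alt_aa == "*" && ref_aa != "*") "STOP_GAINED"
        else if (ref_aa == alt_aa) "SYNONYMOUS"
        else "NONSYNONYMOUS"
    } else if (in_type("five_prime_UTR") || in_type("three_prime_UTR")) {
      region[i] <- "UTR"
    } else if (in_type("exon")) {
      region[i] <- "UTR"  # exonic non-CDS in these models is UTR
    } else {
      # intron: distance to the nearest exon boundary decides splice site
      ex <- feat[feat$type == "exon", , drop = FALSE]
      d5 <- p - max(ex$end[ex$end < p])
      d3 <- min(ex$start[ex$start > p]) - p
      region[i] <- if (min(d5, d3) <= 2L) "SPLICE_SITE" else "INTRON"
    }
  }
  data.frame(snps, region = region, coding_effect = effect,
             gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Tally variant effects by region and coding effect
#'
#' @param effects output of [annotate_effect()].
#' @return list with `region_counts`, `effect_counts` (named integer
#'   vectors partitioning the input), and `gene_flags` (per-gene logical
#'   flags for containing nonsynonymous / start-lost / stop-gained /
#'   stop-lost variants).
#' @export
summarize_effects <- function(effects) {
  region_counts <- setNames(integer(length(REGION_LEVELS)), REGION_LEVELS)
  tab <- table(effects$region)
  region_counts[names(tab)] <- as.integer(tab)
  effect_counts <- setNames(integer(length(EFFECT_LEVELS)), EFFECT_LEVELS)
  tab <- table(effects$coding_effect)
  effect_counts[names(tab)] <- as.integer(tab)
  genic <- effects[!is.na(effects$gene_id), , drop = FALSE]
  gene_flags <- do.call(rbind, lapply(split(genic, genic$gene_id),
    function(e) data.frame(
      gene_id = e$gene_id[1],
      has_nonsynonymous = any(e$coding_effect == "NONSYNONYMOUS"),
      has_start_lost = any(e$coding_effect == "START_LOST"),
      has_stop_gained = any(e$coding_effect == "STOP_GAINED"),
      has_stop_lost = any(e$coding_effect == "STOP_LOST"),
      stringsAsFactors = FALSE)))
  if (is.null(gene_flags))
    gene_flags <- data.frame(gene_id = character(),
                             has_nonsynonymous = logical(),
                             has_start_lost = logical(),
                             has_stop_gained = logical(),
                             has_stop_lost = logical())
  rownames(gene_flags) <- NULL
  list(region_counts = region_counts, effect_counts = effect_counts,
       gene_flags = gene_flags)
}
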