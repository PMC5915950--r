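# Small shared fixtures, built in code at test time.

substitute_bases_test <- function(s, pos, base) {
  x <- strsplit(s, "")[[1]]
  x[pos] <- base
  paste(x, collapse = "")
}

tiny_config <- function(seed = 101L, n_reads = 1000L, ...) {
  sim_config(seed = seed, genome_length = 30000L, n_genes = 8L,
             n_reads = n_reads, ...)
}

# a hand-built plus-strand gene on a tiny contig, for effect annotation:
#   1-3   5'UTR          (exon 1)
#   4-18  CDS part 1     (exon 1, 15 nt)
#   19-24 intron
#   25-30 CDS part 2     (exon 2, 6 nt)
#   31-36 3'UTR          (exon 2)
# CDS = ATG TTT TGG GGA AAA CAA TAA (21 nt, 7 codons)
hand_gene <- function() {
  cds <- "ATGTTTTGGGGAAAACAATAA"
  seq <- paste0("CCC", substr(cds, 1, 15), "GTAAAG", substr(cds, 16, 21),
                "TTTTTT", "ACGTACGTAC")
  genome <- c(chr1 = seq)
  models <- data.frame(
    gene_id = "g1", contig = "chr1", strand = "+",
    type = c("exon", "exon", "five_prime_UTR", "CDS", "CDS",
             "three_prime_UTR"),
    start = c(1L, 25L, 1L, 4L, 25L, 31L),
    end = c(18L, 36L, 3L, 18L, 30L, 36L),
    stringsAsFactors = FALSE)
  list(genome = genome, models = models, cds = cds)
}

# a deterministic four-group count set built by hand
hand_count_set <- function(counts_by_group, library_size = 1e6,
                           condition = "normal") {
  groups <- names(counts_by_group)
  mats <- lapply(counts_by_group, as.matrix)
  samples <- do.call(rbind, lapply(groups, function(g) {
    n_rep <- ncol(mats[[g]])
    data.frame(sample_id = sprintf("%s_%s_r%d", g, condition,
                                   seq_len(n_rep)),
               group = g, condition = condition,
               replicate = seq_len(n_rep), stringsAsFactors = FALSE)
  }))
  counts <- do.call(cbind, mats)
  colnames(counts) <- samples$sample_id
  count_set(counts, samples,
            setNames(rep(library_size, nrow(samples)),
                     samples$sample_id))
}
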