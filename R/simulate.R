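# Synthetic allopolyploid study generator. Emulates the data layout of a
# diploid-ancestor-pair + allopolyploid sequencing study: two genomes
# diverged by point substitutions, gene models with exon/intron/UTR/CDS
# structure, reads of known subgenome origin, pileup-style SNP calls
# (homogenic for the second ancestor, heterogenic for the hybrid), and
# negative-binomial count matrices with planted additivity and bias
# categories. Every output is accompanied by its ground truth.

ADDITIVITY_CATEGORIES <- c("ADDITIVE", "ELD_BD", "ELD_BS",
                           "TRANSGRESSIVE_UP", "TRANSGRESSIVE_DOWN")
BIAS_CATEGORIES <- c("NO_BIAS", "BIAS_RETAINED", "BIAS_LOST",
                     "BIAS_GAINED", "BIAS_REVERSED")
# bias categories whose ancestral homoeolog ratio differs from 1; ELD
# planting needs the two ancestors a fold apart, so ELD genes draw their
# bias category from this set
BIAS_UNEQUAL_ANCESTORS <- c("BIAS_RETAINED", "BIAS_LOST", "BIAS_REVERSED")

#' Configuration for the synthetic allopolyploid study
#'
#' Defaults state the simulated world once: a 200-kb single-contig genome
#' pair diverged at 5 substitutions/kb (the order of divergence between
#' closely related congeneric grasses), 150-bp reads at a 0.2% error rate,
#' and library fractions drawn log-normally so that a nominal
#' 10^6-read library yields mean counts of a few tens per gene, with
#' negative-binomial dispersion 0.05 typical of bulk RNA-seq replicates.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param genome_length total bp of the single simulated contig.
#' @param n_genes number of gene models tiled onto the genome.
#' @param divergence_rate per-site probability that the second ancestor
#'   differs from the first.
#' @param read_length read length (bp).
#' @param n_reads number of hybrid reads to simulate.
#' @param error_rate per-base sequencing error probability.
#' @param n_replicates biological replicates per group.
#' @param library_size nominal mapped reads per sample.
#' @param baseline_mu_log,baseline_sigma_log log-normal parameters of the
#'   per-gene expression fraction (fraction of the library).
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @param fold_change multiplier used to plant non-null categories (> 1).
#' @param category_proportions named fractions over the additivity
#'   categories `ADDITIVE`, `ELD_BD`, `ELD_BS`, `TRANSGRESSIVE_UP`,
#'   `TRANSGRESSIVE_DOWN`; must sum to 1.
#' @param bias_proportions named fractions over the bias categories
#'   `NO_BIAS`, `BIAS_RETAINED`, `BIAS_LOST`, `BIAS_GAINED`,
#'   `BIAS_REVERSED`; must sum to 1.
#' @param noise_rate per-site rate of spurious SNP calls at non-divergent
#'   positions.
#' @param call_depth read depth reported on emitted SNP calls.
#' @param cds_length CDS length per gene (bp, multiple of 3).
#' @param utr_length length of each UTR (bp).
#' @param intron_length intron length (bp).
#' @param min_fraction floor applied to baseline expression fractions
#'   (0 disables); raising it guarantees a minimum planted mean count.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_genes = 40L,
                       divergence_rate = 0.005,
                       read_length = 150L,
                       n_reads = 20000L,
                       error_rate = 0.002,
                       n_replicates = 3L,
                       library_size = 1e6,
                       baseline_mu_log = log(1e-5),
                       baseline_sigma_log = 1,
                       dispersion = 0.05,
                       fold_change = 4,
                       category_proportions = c(
                         ADDITIVE = 0.6, ELD_BD = 0.1, ELD_BS = 0.1,
                         TRANSGRESSIVE_UP = 0.1, TRANSGRESSIVE_DOWN = 0.1),
                       bias_proportions = c(
                         NO_BIAS = 0.5, BIAS_RETAINED = 0.2, BIAS_LOST = 0.1,
                         BIAS_GAINED = 0.1, BIAS_REVERSED = 0.1),
                       noise_rate = 0,
                       call_depth = 20L,
                       cds_length = 300L,
                       utr_length = 30L,
                       intron_length = 60L,
                       min_fraction = 0) {
  cfg <- as.list(environment())
  if (cfg$divergence_rate < 0 || cfg$divergence_rate > 1)
    stop("divergence_rate must be in [0, 1]")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop("error_rate must be in [0, 1]")
  if (cfg$read_length < 1) stop("read_length must be >= 1")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$fold_change <= 1) stop("fold_change must be > 1")
  if (cfg$cds_length %% 3L != 0L) stop("cds_length must be a multiple of 3")
  for (nm in c("category_proportions", "bias_proportions")) {
    p <- cfg[[nm]]
    want <- if (nm == "category_proportions") ADDITIVITY_CATEGORIES
            else BIAS_CATEGORIES
    if (!all(names(p) %in% want) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8)
      stop(nm, " must be non-negative fractions over ",
           paste(want, collapse = "/"), " summing to 1")
    full <- setNames(numeric(length(want)), want)
    full[names(p)] <- p
    cfg[[nm]] <- full
  }
  class(cfg) <- "sim_config"
  cfg
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a diverged ancestral genome pair with gene models
#'
#' Generates genome A, tiles `n_genes` two-exon gene models (5'UTR,
#' split CDS, intron, 3'UTR; CDS starts ATG, ends with a stop, no internal
#' stops; strands alternate), and derives genome B by substituting each
#' site independently with probability `divergence_rate` (uniform choice
#' among the three alternative bases).
#'
#' @param config a [sim_config()].
#' @return list with `genome_a`, `genome_b` (named character vectors),
#'   `gene_models` (data frame), and `snp_truth` (data frame with `contig`,
#'   `pos`, `allele_a`, `allele_b`).
#' @export
simulate_ancestral_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  u <- config$utr_length; ilen <- config$intron_length
  cdsl <- config$cds_length
  glen <- 2L * u + cdsl + ilen
  gap <- floor((config$genome_length - config$n_genes * glen) /
                 (config$n_genes + 1L))
  if (config$n_genes > 0L && gap < 1L)
    stop("genome_length too small to host n_genes gene models")

  genome_a <- random_dna(config$genome_length)
  c1 <- floor(cdsl / 2) + 1L  # deliberately not codon-aligned
  c2 <- cdsl - c1
  sense_codons <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    STOP_CODONS)

  models <- list()
  for (i in seq_len(config$n_genes)) {
    s <- gap + (i - 1L) * (glen + gap) + 1L
    strand <- if (i %% 2L == 1L) "+" else "-"
    cds <- paste0("ATG",
                  paste(sample(sense_codons, cdsl / 3L - 2L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1L))
    sense <- paste0(random_dna(u), substr(cds, 1L, c1), random_dna(ilen),
                    substr(cds, c1 + 1L, cdsl), random_dna(u))
    rel <- data.frame(
      type = c("exon", "exon", "five_prime_UTR", "CDS", "CDS",
               "three_prime_UTR"),
      start = c(1L, u + c1 + ilen + 1L, 1L, u + 1L, u + c1 + ilen + 1L,
                glen - u + 1L),
      end = c(u + c1, glen, u, u + c1, u + c1 + ilen + c2, glen))
    if (strand == "-") {
      geno_seq <- revcomp(sense)
      new_start <- glen - rel$end + 1L
      new_end <- glen - rel$start + 1L
      rel$start <- new_start; rel$end <- new_end
    } else {
      geno_seq <- sense
    }
    genome_a <- paste0(substr(genome_a, 1L, s - 1L), geno_seq,
                       substr(genome_a, s + glen, config$genome_length))
    models[[i]] <- data.frame(
      gene_id = sprintf("gene%04d", i), contig = "chr1", strand = strand,
      type = rel$type, start = rel$start + s - 1L, end = rel$end + s - 1L,
      stringsAsFactors = FALSE)
  }
  gene_models <- if (length(models)) do.call(rbind, models) else
    data.frame(gene_id = character(), contig = character(),
               strand = character(), type = character(),
               start = integer(), end = integer())

  pos <- which(runif(config$genome_length) < config$divergence_rate)
  a_chars <- strsplit(genome_a, "", fixed = TRUE)[[1]]
  alleles_b <- character(length(pos))
  if (length(pos)) {
    for (j in seq_along(pos)) {
      alleles_b[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                     a_chars[pos[j]]), 1L)
    }
  }
  genome_b <- if (length(pos)) substitute_bases(genome_a, pos, alleles_b)
              else genome_a
  snp_truth <- data.frame(contig = rep("chr1", length(pos)), pos = pos,
                          allele_a = a_chars[pos], allele_b = alleles_b,
                          stringsAsFactors = FALSE)
  list(genome_a = c(chr1 = genome_a), genome_b = c(chr1 = genome_b),
       gene_models = gene_models, snp_truth = snp_truth)
}

#' Simulate hybrid reads of known subgenome origin
#'
#' Each read is an ungapped `read_length`-mer drawn uniformly from one of
#' the two genomes (origin recorded) with i.i.d. base errors at
#' `error_rate` (uniform choice among the three alternative bases).
#'
#' @param genome_a,genome_b ancestral genomes (shared coordinates).
#' @param config a [sim_config()].
#' @return list with `reads` (data frame: `read_id`, `origin` "A"/"B",
#'   `contig`, `pos`, `seq`) and `read_truth` (named origin vector).
#' @export
simulate_reads <- function(genome_a, genome_b, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_genome(genome_a); validate_genome(genome_b)
  L <- config$read_length
  if (L > min(nchar(genome_a)))
    stop("read_length exceeds the shortest contig")
  set.seed(config$seed + 1L)
  n <- config$n_reads
  contigs <- names(genome_a)
  lens <- nchar(genome_a)
  ctg <- sample(contigs, n, replace = TRUE, prob = lens / sum(lens))
  origin <- sample(c("A", "B"), n, replace = TRUE)
  pos <- vapply(ctg, function(cc) sample.int(lens[[cc]] - L + 1L, 1L), 1L)
  src <- ifelse(origin == "A", genome_a[ctg], genome_b[ctg])
  seqs <- substring(src, pos, pos + L - 1L)
  n_err <- rbinom(n, L, config$error_rate)
  for (i in which(n_err > 0L)) {
    at <- sample.int(L, n_err[i])
    x <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (j in at) x[j] <- sample(setdiff(c("A", "C", "G", "T"), x[j]), 1L)
    seqs[i] <- paste(x, collapse = "")
  }
  reads <- data.frame(read_id = sprintf("read%06d", seq_len(n)),
                      origin = origin, contig = unname(ctg),
                      pos = unname(pos), seq = unname(seqs),
                      stringsAsFactors = FALSE)
  list(reads = reads, read_truth = setNames(origin, reads$read_id))
}

#' Oracle aligner for simulated reads
#'
#' Places each read at its true locus (known to the simulator) and reports
#' NM as the Hamming distance between the read and the target genome at
#' that locus. Stands in for a real aligner so that downstream mismatch
#' logic is exact.
#'
#' @param reads read data frame from [simulate_reads()].
#' @param genome the genome to "align" against.
#' @return alignment data frame: `read_id`, `contig`, `pos`, `mapped`, `nm`.
#' @export
align_reads_naive <- function(reads, genome) {
  validate_genome(genome)
  L <- nchar(reads$seq[1] %||% "")
  lens <- nchar(genome)
  if (nrow(reads) && any(reads$pos + nchar(reads$seq) - 1L >
                         lens[reads$contig]))
    stop("read locus outside genome")
  ref <- substring(genome[reads$contig], reads$pos,
                   reads$pos + nchar(reads$seq) - 1L)
  nm <- vapply(seq_len(nrow(reads)),
               function(i) hamming(reads$seq[i], ref[i]), 1L)
  data.frame(read_id = reads$read_id, contig = reads$contig,
             pos = reads$pos, mapped = TRUE, nm = nm,
             stringsAsFactors = FALSE)
}

#' Emit pileup-style SNP calls for the ancestor pair and the hybrid
#'
#' For each true divergent site, the second-ancestor-vs-reference call
#' carries a variant frequency near 1 (homogenic: essentially all reads
#' carry the variant) and the hybrid-vs-reference call near 0.5
#' (heterogenic: the two subgenomes contribute each allele). Optional
#' spurious calls at non-divergent sites model caller noise.
#'
#' @param genome_a,genome_b ancestral genomes.
#' @param snp_truth truth table from [simulate_ancestral_genomes()].
#' @param config a [sim_config()].
#' @return list with `calls_b` (ancestor B vs reference) and `calls_h`
#'   (hybrid vs reference), both in the [read_snp_calls()] layout.
#' @export
emit_snp_calls <- function(genome_a, genome_b, snp_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(snp_truth)
  calls_b <- data.frame(contig = snp_truth$contig, pos = snp_truth$pos,
                        ref_base = snp_truth$allele_a,
                        var_base = snp_truth$allele_b,
                        depth = rep(config$call_depth, n),
                        var_freq = runif(n, 0.93, 1.0),
                        stringsAsFactors = FALSE)
  calls_h <- data.frame(contig = snp_truth$contig, pos = snp_truth$pos,
                        ref_base = snp_truth$allele_a,
                        var_base = snp_truth$allele_b,
                        depth = rep(config$call_depth, n),
                        var_freq = runif(n, 0.40, 0.60),
                        stringsAsFactors = FALSE)
  if (config$noise_rate > 0) {
    glen <- nchar(genome_a[[1]])
    free <- setdiff(seq_len(glen), snp_truth$pos)
    n_noise <- rbinom(1L, length(free), config$noise_rate)
    if (n_noise > 0L) {
      at <- sort(sample(free, n_noise))
      a_chars <- strsplit(genome_a[[1]], "", fixed = TRUE)[[1]]
      mk <- function(p) data.frame(
        contig = names(genome_a)[1], pos = p, ref_base = a_chars[p],
        var_base = vapply(a_chars[p], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), ""),
        depth = config$call_depth, var_freq = runif(length(p)),
        stringsAsFactors = FALSE)
      to_b <- runif(n_noise) < 0.5
      if (any(to_b)) calls_b <- rbind(calls_b, mk(at[to_b]))
      if (any(!to_b)) calls_h <- rbind(calls_h, mk(at[!to_b]))
    }
  }
  list(calls_b = calls_b[order(calls_b$contig, calls_b$pos), ],
       calls_h = calls_h[order(calls_h$contig, calls_h$pos), ])
}

# Draw the per-gene truth plan: additivity category, bias category, and
# the four group expression fractions they imply.
plan_gene_truth <- function(genes, config) {
  n <- length(genes)
  F <- config$fold_change
  addv <- sample(ADDITIVITY_CATEGORIES, n, replace = TRUE,
                 prob = config$category_proportions[ADDITIVITY_CATEGORIES])
  bias <- character(n)
  bp <- config$bias_proportions[BIAS_CATEGORIES]
  for (i in seq_len(n)) {
    if (addv[i] %in% c("ELD_BD", "ELD_BS")) {
      p <- bp[BIAS_UNEQUAL_ANCESTORS]
      bias[i] <- sample(BIAS_UNEQUAL_ANCESTORS, 1L, prob = p + 1e-12)
    } else {
      bias[i] <- sample(BIAS_CATEGORIES, 1L, prob = bp + 1e-12)
    }
  }
  f_base <- pmax(exp(rnorm(n, config$baseline_mu_log,
                           config$baseline_sigma_log)),
                 config$min_fraction)
  r_anc <- ifelse(bias %in% BIAS_UNEQUAL_ANCESTORS,
                  ifelse(runif(n) < 0.5, F, 1 / F), 1)
  f_bd <- f_base * sqrt(r_anc)
  f_bs <- f_base / sqrt(r_anc)
  total <- numeric(n)
  total[addv == "ADDITIVE"] <- ((f_bd + f_bs) / 2)[addv == "ADDITIVE"]
  total[addv == "ELD_BD"] <- f_bd[addv == "ELD_BD"]
  total[addv == "ELD_BS"] <- f_bs[addv == "ELD_BS"]
  total[addv == "TRANSGRESSIVE_UP"] <-
    (F * pmax(f_bd, f_bs))[addv == "TRANSGRESSIVE_UP"]
  total[addv == "TRANSGRESSIVE_DOWN"] <-
    (pmin(f_bd, f_bs) / F)[addv == "TRANSGRESSIVE_DOWN"]
  r_hyb <- rep(1, n)
  r_hyb[bias == "BIAS_RETAINED"] <- r_anc[bias == "BIAS_RETAINED"]
  r_hyb[bias == "BIAS_REVERSED"] <- 1 / r_anc[bias == "BIAS_REVERSED"]
  gained <- bias == "BIAS_GAINED"
  r_hyb[gained] <- ifelse(runif(sum(gained)) < 0.5, F, 1 / F)
  f_bhbd <- total * r_hyb / (1 + r_hyb)
  f_bhbs <- total / (1 + r_hyb)
  data.frame(gene_id = genes, additivity = addv, bias = bias,
             f_bd = f_bd, f_bs = f_bs, f_bhbd = f_bhbd, f_bhbs = f_bhbs,
             stringsAsFactors = FALSE)
}

#' Simulate replicate count matrices with planted categories
#'
#' Samples are the four groups BD (first ancestor), BS (second ancestor),
#' BH_BD and BH_BS (the hybrid's two homoeolog read sets) times
#' `n_replicates`. Counts are negative binomial with mean
#' `fraction x library_size` and dispersion `phi`. The planted fractions
#' realize the classification definitions: an additive gene's hybrid total
#' equals the mid-ancestral value, expression-level dominance copies one
#' ancestor while the ancestors sit a fold apart, transgressive genes
#' exceed (or fall below) both ancestors by the fold change, and the bias
#' plan sets the hybrid homoeolog ratio relative to the ancestral ratio
#' (retained / lost / gained / reversed).
#'
#' @param genes character vector of gene identifiers, or a gene-model data
#'   frame (its unique `gene_id`s are used).
#' @param config a [sim_config()].
#' @param mode `"nb"` for negative-binomial sampling, `"deterministic"` to
#'   emit rounded means (exact assertions in tests).
#' @param conditions character vector of condition labels.
#' @return list with `count_set` (a [count_set()]) and `gene_truth`
#'   (planted categories and fractions per gene).
#' @export
simulate_counts <- function(genes, config, mode = c("nb", "deterministic"),
                            conditions = "normal") {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (is.data.frame(genes)) genes <- unique(genes$gene_id)
  set.seed(config$seed + 3L)
  truth <- plan_gene_truth(genes, config)
  frac <- as.matrix(truth[, c("f_bd", "f_bs", "f_bhbd", "f_bhbs")])
  colnames(frac) <- c("BD", "BS", "BH_BD", "BH_BS")
  sums <- colSums(frac)
  # hybrid fractions are fractions of the full hybrid library but each
  # sorted pseudo-sample carries only half of it, so their load doubles
  load <- c(sums[["BD"]], sums[["BS"]],
            2 * sums[["BH_BD"]], 2 * sums[["BH_BS"]])
  if (max(load) > 1) {
    warning("planted fractions exceed 1; renormalizing by ",
            signif(max(load), 4))
    frac <- frac / max(load)
    truth[, c("f_bd", "f_bs", "f_bhbd", "f_bhbs")] <- frac
  }
  groups <- c("BD", "BS", "BH_BD", "BH_BS")
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = conditions, group = groups,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("group", "condition", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$group,
                               samples$condition, samples$replicate)
  N <- config$library_size
  phi <- config$dispersion
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- frac[, samples$group[j]] * N
    counts[, j] <- if (mode == "deterministic") as.integer(round(mu))
      else if (phi == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / phi)
  }
  # BD/BS samples are whole libraries of N mapped reads; the hybrid's
  # two sorted read sets are halves of one N-read library, so each
  # carries N/2 and their sum restores the hybrid's library. This makes
  # the mid-ancestral RPM and the hybrid-total RPM directly comparable.
  lib <- ifelse(samples$group %in% c("BH_BD", "BH_BS"), N / 2, N)
  cs <- count_set(counts, samples[, c("sample_id", "group", "condition",
                                      "replicate")],
                  setNames(lib, samples$sample_id))
  list(count_set = cs, gene_truth = truth)
}

#' Generate the full synthetic study in one call
#'
#' Convenience wrapper chaining [simulate_ancestral_genomes()],
#' [simulate_reads()], [align_reads_naive()] against both genomes,
#' [emit_snp_calls()], and [simulate_counts()].
#'
#' @param config a [sim_config()].
#' @param count_mode passed to [simulate_counts()].
#' @return list with all simulator outputs and truth tables.
#' @export
simulate_study <- function(config, count_mode = "nb") {
  g <- simulate_ancestral_genomes(config)
  r <- simulate_reads(g$genome_a, g$genome_b, config)
  aln_a <- align_reads_naive(r$reads, g$genome_a)
  aln_b <- align_reads_naive(r$reads, g$genome_b)
  calls <- emit_snp_calls(g$genome_a, g$genome_b, g$snp_truth, config)
  cnt <- simulate_counts(g$gene_models, config, mode = count_mode)
  c(g, r, list(aln_a = aln_a, aln_b = aln_b), calls, cnt)
}
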