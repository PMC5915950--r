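# Homoeolog divergence dating. Because the virtual second-ancestor genome
# shares coordinates with the reference, each gene model splices a CDS
# pair at identical positions; Ka and Ks between the pair follow the
# Nei-Gojobori (1986) counting method with Jukes-Cantor correction, and
# the mean Ks converts to a divergence time via T = Ks / (2 lambda).

BASES <- c("A", "C", "G", "T")

# per-codon fraction of synonymous sites (sum over the 3 positions of the
# fraction of the 3 alternative bases whose substitution preserves the
# amino acid; changes to or from stop count as nonsynonymous)
codon_syn_sites <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    code <- Biostrings::GENETIC_CODE
    codons <- names(code)
    out <- setNames(numeric(length(codons)), codons)
    for (cod in codons) {
      s <- 0
      for (pos in 1:3) {
        for (b in setdiff(BASES, substr(cod, pos, pos))) {
          alt <- cod
          substr(alt, pos, pos) <- b
          if (code[[alt]] == code[[cod]] && code[[alt]] != "*")
            s <- s + 1 / 3
        }
      }
      out[cod] <- s
    }
    tbl <<- out
    tbl
  }
})

perms_of <- function(k) {
  if (k == 1) return(list(1L))
  if (k == 2) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

# pathway-averaged synonymous/nonsynonymous difference counts for one
# codon pair; pathways through stop codons are skipped (all-blocked pairs
# fall back to averaging over every pathway)
codon_differences <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  paths <- perms_of(k)
  tally <- function(order_idx, allow_stop) {
    cur <- c1
    sd <- 0; nd <- 0
    for (j in order_idx) {
      pos <- diff_pos[j]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (!allow_stop && code[[nxt]] == "*" && nxt != c2) return(NULL)
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stop = FALSE))
  if (!length(res)) res <- lapply(paths, tally, allow_stop = TRUE)
  counts <- do.call(rbind, res)
  c(sd = mean(counts[, "sd"]), nd = mean(counts[, "nd"]))
}

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Extract the homoeologous CDS pair for one gene
#'
#' Splices the CDS from both genomes at the gene model's (shared)
#' coordinates, strand-aware; minus-strand genes are reverse-complemented
#' so translation starts at ATG. Codons containing N in either sequence
#' are masked from both.
#'
#' @param gene_id gene identifier.
#' @param gene_models gene-model data frame.
#' @param genome_a,genome_b the reference and the virtual genome.
#' @return list with `cds_a`, `cds_b` (equal-length codon sequences;
#'   masked codons removed) and `n_masked`.
#' @export
extract_cds_pair <- function(gene_id, gene_models, genome_a, genome_b) {
  feat <- gene_models[gene_models$gene_id == gene_id, , drop = FALSE]
  if (!nrow(feat)) stop("unknown gene: ", gene_id)
  cds <- feat[feat$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  ctg <- cds$contig[1]
  splice <- function(genome) {
    paste(substring(genome[[ctg]], cds$start, cds$end), collapse = "")
  }
  a <- splice(genome_a); b <- splice(genome_b)
  if (feat$strand[1] == "-") { a <- revcomp(a); b <- revcomp(b) }
  if (nchar(a) %% 3L != 0L)
    stop("CDS length of ", gene_id, " is not a multiple of 3")
  ca <- split_codons(a); cb <- split_codons(b)
  masked <- grepl("N", ca) | grepl("N", cb)
  list(cds_a = paste(ca[!masked], collapse = ""),
       cds_b = paste(cb[!masked], collapse = ""),
       n_masked = sum(masked))
}

#' Nei-Gojobori (1986) Ka/Ks between two coding sequences
#'
#' Synonymous site counts are per-codon fractions from the standard
#' genetic code, averaged over both sequences; differences are
#' pathway-averaged over substitution orderings for multi-hit codons
#' (pathways through stop codons skipped); proportions are
#' Jukes-Cantor-corrected, `d = -(3/4) ln(1 - (4/3) p)`. A proportion at
#' or beyond 3/4 is reported as saturated (NA estimate). Codons with an
#' internal stop in either sequence are masked with a warning; a trailing
#' stop codon pair is excluded from the counts.
#'
#' @param cds_a,cds_b equal-length coding sequences (multiple of 3);
#'   `cds_a` must be free of internal stop codons.
#' @return one-row data frame: `s_sites`, `n_sites`, `sd`, `nd`, `ka`,
#'   `ks`, `omega` (`NA` when `ks` is 0 or saturated), `ka_saturated`,
#'   `ks_saturated`, `n_codons` (used codons).
#' @export
ng86_ka_ks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("coding sequences must have equal length")
  if (nchar(cds_a) %% 3L != 0L)
    stop("coding sequence length must be a multiple of 3")
  code <- Biostrings::GENETIC_CODE
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  n <- length(ca)
  # drop a trailing stop pair; mask internal stops
  if (n > 0 && code[[ca[n]]] == "*") { ca <- ca[-n]; cb <- cb[-n] }
  stops <- vapply(ca, function(x) code[[x]] == "*", TRUE) |
    vapply(cb, function(x) code[[x]] == "*", TRUE)
  if (any(stops)) {
    warning("masking ", sum(stops), " codon(s) with internal stops")
    ca <- ca[!stops]; cb <- cb[!stops]
  }
  syn <- codon_syn_sites()
  s_sites <- sum((syn[ca] + syn[cb]) / 2)
  n_sites <- 3 * length(ca) - s_sites
  diffs <- mapply(codon_differences, ca, cb)
  sd <- sum(diffs["sd", ]); nd <- sum(diffs["nd", ])
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  data.frame(s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
             ka = ka, ks = ks, omega = omega,
             ka_saturated = pn >= 0.75, ks_saturated = ps >= 0.75,
             n_codons = length(ca))
}

#' Ka/Ks table over all gene models
#'
#' @param gene_models gene-model data frame.
#' @param genome_a,genome_b reference and virtual genome.
#' @return data frame, one row per gene, columns of [ng86_ka_ks()] plus
#'   `gene`.
#' @export
kaks_table <- function(gene_models, genome_a, genome_b) {
  genes <- unique(gene_models$gene_id)
  rows <- lapply(genes, function(g) {
    pair <- extract_cds_pair(g, gene_models, genome_a, genome_b)
    cbind(gene = g, ng86_ka_ks(pair$cds_a, pair$cds_b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Divergence time from synonymous substitution rates
#'
#' `T = mean(Ks) / (2 lambda)`, with saturated or missing Ks values
#' excluded from the mean. The default substitution rate is the grass
#' synonymous clock `lambda = 6.1e-9` substitutions/site/year.
#'
#' @param ks_values vector of Ks estimates.
#' @param lambda substitutions/site/year (> 0).
#' @return divergence time in years.
#' @export
divergence_time <- function(ks_values, lambda = 6.1e-9) {
  if (lambda <= 0) stop("lambda must be > 0")
  ks <- ks_values[is.finite(ks_values)]
  if (!length(ks)) stop("no usable Ks values")
  mean(ks) / (2 * lambda)
}
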