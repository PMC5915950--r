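# Expression quantification: per-gene read counting, reads-per-million,
# the expressed-gene filter, mid-ancestral pseudo-samples, and sample
# correlation matrices.

#' Construct a count set
#'
#' A count set bundles a gene x sample count matrix with sample metadata
#' (group, condition, replicate index) and per-sample library sizes
#' (mapped reads), the denominators for RPM.
#'
#' @param counts integer-like matrix, genes in rows (rownames), samples in
#'   columns (colnames = `samples$sample_id`).
#' @param samples data frame with `sample_id`, `group`, `condition`,
#'   `replicate`.
#' @param library_sizes named numeric, one per sample.
#' @return object of class `count_set`.
#' @export
count_set <- function(counts, samples, library_sizes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (!identical(colnames(counts), samples$sample_id))
    stop("counts columns must match samples$sample_id in order")
  if (!all(samples$sample_id %in% names(library_sizes)))
    stop("library_sizes must cover every sample")
  if (any(counts < 0)) stop("counts must be non-negative")
  library_sizes <- library_sizes[samples$sample_id]
  if (any(colSums(counts) > library_sizes + 1e-9))
    stop("per-sample gene counts exceed the library size")
  key <- paste(samples$group, samples$condition, samples$replicate)
  if (anyDuplicated(key))
    stop("replicate indices must be unique within group x condition")
  structure(list(counts = counts, samples = samples,
                 library_sizes = library_sizes), class = "count_set")
}

#' @export
print.count_set <- function(x, ...) {
  cat("count_set:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "),
      "\n")
  invisible(x)
}

# column indices of one group (optionally one condition), ordered by
# replicate index
cs_columns <- function(cs, group, condition = NULL) {
  sel <- cs$samples$group == group
  if (!is.null(condition)) sel <- sel & cs$samples$condition == condition
  idx <- which(sel)
  idx[order(cs$samples$replicate[idx])]
}

#' Count sorted reads per gene
#'
#' A read increments a gene when its alignment interval overlaps the
#' union of that gene's exons and of no other gene's; reads overlapping
#' zero or two or more genes are left uncounted (unassigned/ambiguous).
#'
#' @param alignments data frame with `contig`, `pos`, and either `width`
#'   or `seq` (width taken from nchar).
#' @param gene_models gene-model data frame.
#' @return list with `counts` (named integer vector over genes),
#'   `n_assigned`, `n_ambiguous`, `n_unassigned`; the three tallies
#'   partition the input reads.
#' @export
count_reads <- function(alignments, gene_models) {
  width <- alignments$width %||% nchar(alignments$seq)
  if (is.null(width)) stop("alignments need a width or seq column")
  if (!all(alignments$contig %in% gene_models$contig) &&
      nrow(alignments) > 0 &&
      !all(alignments$contig %in% unique(gene_models$contig)))
    stop("unknown contig in alignments")
  genes <- unique(gene_models$gene_id)
  exons <- gene_models[gene_models$type == "exon", , drop = FALSE]
  exon_gr <- GenomicRanges::GRanges(
    exons$contig, IRanges::IRanges(exons$start, exons$end),
    gene_id = exons$gene_id)
  exon_by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(exon_gr, exon_gr$gene_id))
  read_gr <- GenomicRanges::GRanges(
    alignments$contig, IRanges::IRanges(alignments$pos,
                                        alignments$pos + width - 1L))
  ov <- GenomicRanges::findOverlaps(read_gr, exon_by_gene)
  hit_gene <- names(exon_by_gene)[S4Vectors::subjectHits(ov)]
  hit_read <- S4Vectors::queryHits(ov)
  per_read <- tapply(hit_gene, hit_read, function(g) unique(g))
  n_hits <- lengths(per_read)
  uniq <- unlist(per_read[n_hits == 1L], use.names = FALSE)
  counts <- setNames(integer(length(genes)), genes)
  if (length(uniq)) {
    tab <- table(uniq)
    counts[names(tab)] <- as.integer(tab)
  }
  n_ambiguous <- sum(n_hits > 1L)
  n_assigned <- sum(n_hits == 1L)
  list(counts = counts, n_assigned = n_assigned,
       n_ambiguous = n_ambiguous,
       n_unassigned = nrow(alignments) - n_assigned - n_ambiguous)
}

#' Reads per million mapped reads
#'
#' @param cs a [count_set()].
#' @return matrix of `10^6 x count / library_size`, same dimensions as the
#'   count matrix.
#' @export
compute_rpm <- function(cs) {
  if (any(cs$library_sizes <= 0)) stop("library sizes must be > 0")
  sweep(cs$counts, 2, cs$library_sizes, "/") * 1e6
}

#' Expressed-gene filter
#'
#' A gene is expressed in a group when its RPM reaches the threshold in
#' every biological replicate (inclusive).
#'
#' @param rpm_values per-replicate RPM values for one gene in one group.
#' @param threshold RPM threshold, default 1.
#' @return logical flag.
#' @export
flag_expressed <- function(rpm_values, threshold = 1) {
  if (!length(rpm_values)) stop("flag_expressed(): empty replicate list")
  all(rpm_values >= threshold)
}

#' Combine two groups into pseudo-samples by summed counts
#'
#' Replicates are paired by condition and replicate index; each combined
#' replicate has the summed counts and the summed library sizes, so its
#' RPM is the library-size-weighted mean of the two sources. Used both for
#' the mid-ancestral value (BD + BS) and the hybrid total (BH_BD + BH_BS),
#' through one shared code path.
#'
#' @param cs a [count_set()].
#' @param groups the two source group labels.
#' @param new_group label of the combined group.
#' @return a [count_set()] holding only the combined samples.
#' @export
combine_groups <- function(cs, groups, new_group) {
  stopifnot(length(groups) == 2L)
  s <- cs$samples
  out_counts <- list(); out_samples <- list(); out_lib <- numeric(0)
  for (cond in unique(s$condition)) {
    r1 <- cs_columns(cs, groups[1], cond)
    r2 <- cs_columns(cs, groups[2], cond)
    if (length(r1) != length(r2))
      stop("unequal replicate counts between ", groups[1], " and ",
           groups[2], " in condition ", cond)
    if (!identical(s$replicate[r1], s$replicate[r2]))
      stop("replicate indices do not pair between groups")
    for (k in seq_along(r1)) {
      sid <- sprintf("%s_%s_r%d", new_group, cond, s$replicate[r1[k]])
      out_counts[[sid]] <- cs$counts[, r1[k]] + cs$counts[, r2[k]]
      out_lib[sid] <- cs$library_sizes[r1[k]] + cs$library_sizes[r2[k]]
      out_samples[[sid]] <- data.frame(
        sample_id = sid, group = new_group, condition = cond,
        replicate = s$replicate[r1[k]], stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, out_counts)
  rownames(counts) <- rownames(cs$counts)
  count_set(counts, do.call(rbind, out_samples), out_lib)
}

#' Mid-ancestral value pseudo-samples
#'
#' The additivity baseline: per replicate, the summed ancestor counts with
#' summed library sizes (RPM equal to the ancestors' weighted mean RPM,
#' and to their arithmetic mean when library sizes match).
#'
#' @param cs a [count_set()] containing `BD` and `BS` groups.
#' @return a [count_set()] of `MAV` pseudo-samples.
#' @export
compute_mav <- function(cs) combine_groups(cs, c("BD", "BS"), "MAV")

#' Hybrid total pseudo-samples
#'
#' Sum of the two homoeolog read sets per replicate (same code path as
#' [compute_mav()]).
#'
#' @param cs a [count_set()] containing `BH_BD` and `BH_BS` groups.
#' @return a [count_set()] of `BH_TOTAL` pseudo-samples.
#' @export
compute_bh_total <- function(cs) {
  combine_groups(cs, c("BH_BD", "BH_BS"), "BH_TOTAL")
}

#' Pearson correlation matrix between samples
#'
#' Correlations are computed over genes, by default on `log2(RPM + 1)`.
#' A sample with a constant profile yields `NA` correlations (with a
#' warning), never a silent zero.
#'
#' @param rpm RPM matrix (genes x samples).
#' @param sample_ids columns to include (default all).
#' @param log2 transform to `log2(RPM + 1)` before correlating.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pcc_matrix <- function(rpm, sample_ids = colnames(rpm), log2 = TRUE) {
  m <- rpm[, sample_ids, drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 genes for correlations")
  if (log2) m <- log2(m + 1)
  sds <- apply(m, 2, stats::sd)
  out <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    warning("constant expression profile; correlations undefined for: ",
            paste(sample_ids[sds == 0], collapse = ", "))
    out[sds == 0, ] <- NA_real_
    out[, sds == 0] <- NA_real_
  }
  diag(out) <- 1
  out
}
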