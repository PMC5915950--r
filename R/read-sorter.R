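# Subgenome read sorting. A hybrid read aligned against both ancestral
# genomes is attributed to the genome it matches better: strictly fewer
# mismatches wins, ties and doubly-unmapped reads stay unclassified.

#' Assign a read to a subgenome from its two mismatch counts
#'
#' `NA` means the read did not map to that genome. ORIGIN_A when mapped to
#' A and either unmapped to B or strictly fewer mismatches against A;
#' ORIGIN_B symmetrically; otherwise UNCLASSIFIED (tie, or unmapped to
#' both).
#'
#' @param nm_a,nm_b mismatch counts against genome A and B (vectors;
#'   `NA` = unmapped).
#' @return character vector: "ORIGIN_A", "ORIGIN_B", or "UNCLASSIFIED".
#' @export
sort_read <- function(nm_a, nm_b) {
  if (any(nm_a < 0, na.rm = TRUE) || any(nm_b < 0, na.rm = TRUE))
    stop("negative mismatch count")
  n <- max(length(nm_a), length(nm_b))
  nm_a <- rep_len(nm_a, n); nm_b <- rep_len(nm_b, n)
  out <- rep("UNCLASSIFIED", n)
  out[!is.na(nm_a) & (is.na(nm_b) | nm_a < nm_b)] <- "ORIGIN_A"
  out[!is.na(nm_b) & (is.na(nm_a) | nm_b < nm_a)] <- "ORIGIN_B"
  out
}

# collapse multi-mapped records to one primary alignment per read:
# lowest nm wins; an exact tie among a read's own records is flagged by
# returning NA (the read is dropped to unclassified for that genome)
primary_nm <- function(aln) {
  aln <- aln[aln$mapped & !is.na(aln$nm), , drop = FALSE]
  if (!nrow(aln))
    return(setNames(integer(0), character(0)))
  best <- tapply(aln$nm, aln$read_id, function(v) {
    m <- min(v)
    if (sum(v == m) > 1L) NA_integer_ else m
  })
  setNames(as.integer(best), names(best))
}

#' Sort hybrid reads between the two subgenomes
#'
#' Takes the alignments of the same read set against genome A and genome
#' B, keeps one primary alignment per read per genome (lowest mismatch
#' count; an exact multi-mapping tie drops the read to unclassified for
#' that genome), and classifies every read by [sort_read()].
#'
#' @param aln_a,aln_b alignment data frames (`read_id`, `mapped`, `nm`),
#'   e.g. from [read_sam()] or [align_reads_naive()].
#' @param max_nm optional mismatch cap: alignments with `nm > max_nm` are
#'   treated as unmapped (default `Inf`, off).
#' @return list with `reads` (data frame `read_id`, `nm_a`, `nm_b`,
#'   `origin`) and `summary` (fractions of the three classes; they sum
#'   to 1).
#' @export
sort_reads <- function(aln_a, aln_b, max_nm = Inf) {
  pa <- primary_nm(aln_a)
  pb <- primary_nm(aln_b)
  ids <- sort(unique(c(aln_a$read_id, aln_b$read_id)))
  nm_a <- unname(pa[ids]); nm_b <- unname(pb[ids])
  nm_a[!is.na(nm_a) & nm_a > max_nm] <- NA_integer_
  nm_b[!is.na(nm_b) & nm_b > max_nm] <- NA_integer_
  origin <- sort_read(nm_a, nm_b)
  reads <- data.frame(read_id = ids, nm_a = nm_a, nm_b = nm_b,
                      origin = origin, stringsAsFactors = FALSE)
  n <- length(ids)
  summary <- list(
    n_reads = n,
    fraction_a = sum(origin == "ORIGIN_A") / n,
    fraction_b = sum(origin == "ORIGIN_B") / n,
    fraction_unclassified = sum(origin == "UNCLASSIFIED") / n)
  list(reads = reads, summary = summary)
}
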