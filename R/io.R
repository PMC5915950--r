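# File-format readers and writers. Genomes travel as FASTA (via Biostrings),
# gene models as GFF3, SNP calls and maps as TSV, alignments as a SAM subset
# carrying the NM tag, and count matrices as TSV with a sample-metadata
# sidecar.

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences (upper case).
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  validate_genome(out)
  out
}

#' Write a genome to FASTA (60-column wrap)
#'
#' @param genome named character vector of contig sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Gene models are a data frame with columns `gene_id`, `contig`, `strand`,
#' `type` (exon, CDS, five_prime_UTR, three_prime_UTR), `start`, `end`
#' (1-based, inclusive). The writer adds enclosing gene and mRNA records
#' with `ID`/`Parent` attributes.
#'
#' @param gene_models gene-model data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gene_models, path) {
  stopifnot(all(c("gene_id", "contig", "strand", "type", "start", "end") %in%
                  names(gene_models)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in unique(gene_models$gene_id)) {
    feat <- gene_models[gene_models$gene_id == g, , drop = FALSE]
    s <- min(feat$start); e <- max(feat$end)
    ctg <- feat$contig[1]; str <- feat$strand[1]
    mrna <- paste0(g, ".1")
    writeLines(c(
      paste(ctg, "homeokit", "gene", s, e, ".", str, ".",
            paste0("ID=", g), sep = "\t"),
      paste(ctg, "homeokit", "mRNA", s, e, ".", str, ".",
            paste0("ID=", mrna, ";Parent=", g), sep = "\t")
    ), con)
    phase_counter <- 0L
    feat <- feat[order(if (str == "+") feat$start else -feat$start), ]
    for (i in seq_len(nrow(feat))) {
      phase <- "."
      if (feat$type[i] == "CDS") {
        phase <- as.character(phase_counter %% 3L)
        phase_counter <- (phase_counter +
                            (3L - (feat$end[i] - feat$start[i] + 1L) %% 3L)) %% 3L
      }
      writeLines(paste(ctg, "homeokit", feat$type[i], feat$start[i],
                       feat$end[i], ".", str, phase,
                       paste0("ID=", mrna, ".", feat$type[i], ".", i,
                              ";Parent=", mrna), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts GFF3 with gene/mRNA/exon/CDS/UTR records where features carry a
#' `Parent` attribute pointing at an mRNA whose `Parent` is the gene.
#' Parsing is delegated to `rtracklayer::import()`.
#'
#' @param path GFF3 file.
#' @return gene-model data frame (see [write_gene_models()]).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  first_or_na <- function(x) {
    vapply(x, function(v) if (length(v)) as.character(v)[1]
           else NA_character_, "")
  }
  parent <- first_or_na(df$Parent)
  mrna <- df$type == "mRNA"
  mrna_parent <- setNames(parent[mrna], df$ID[mrna])
  keep <- df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  feat <- df[keep, , drop = FALSE]
  fp <- parent[keep]
  gene <- ifelse(fp %in% names(mrna_parent), mrna_parent[fp], fp)
  out <- data.frame(gene_id = unname(gene),
                    contig = as.character(feat$seqnames),
                    strand = as.character(feat$strand),
                    type = as.character(feat$type),
                    start = feat$start, end = feat$end,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$start), ]
}

#' Read/write SNP call tables
#'
#' SNP calls are TSV with columns `contig`, `pos`, `ref_base`, `var_base`,
#' `depth`, `var_freq` (variant allele frequency in `[0, 1]`), as produced
#' by pileup-based callers.
#'
#' @param path TSV file.
#' @return data frame of calls.
#' @export
read_snp_calls <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref_base", "var_base", "depth", "var_freq")
  if (!all(need %in% names(df)))
    stop("SNP call table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_snp_calls
#' @param calls data frame of calls.
#' @export
write_snp_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP calls from a minimal VCF v4 file
#'
#' Accepts uncompressed single-sample VCF with bi-allelic SNV records.
#' Depth is taken from FORMAT `DP` (or INFO `DP`), and variant frequency
#' from FORMAT `AD` (alt/(ref+alt)) or FORMAT `FREQ` (percentage or
#' fraction). Records without usable depth/frequency are dropped.
#'
#' @param path VCF file.
#' @return data frame in the [read_snp_calls()] layout.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) next
    ref <- f[4]; alt <- f[5]
    if (nchar(ref) != 1L || nchar(alt) != 1L || alt == ".") next
    depth <- NA_real_; freq <- NA_real_
    info <- f[8]
    m <- regmatches(info, regexec("(^|;)DP=([0-9]+)", info))[[1]]
    if (length(m) >= 3) depth <- as.numeric(m[3])
    if (length(f) >= 10) {
      keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      vals <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      fmt <- setNames(as.list(vals), keys)
      if (!is.null(fmt$DP)) depth <- as.numeric(fmt$DP)
      if (!is.null(fmt$AD)) {
        ad <- as.numeric(strsplit(fmt$AD, ",", fixed = TRUE)[[1]])
        if (length(ad) >= 2 && sum(ad[1:2]) > 0) {
          freq <- ad[2] / sum(ad[1:2])
          if (is.na(depth)) depth <- sum(ad)
        }
      } else if (!is.null(fmt$FREQ)) {
        fr <- sub("%$", "", fmt$FREQ)
        freq <- as.numeric(fr)
        if (grepl("%$", fmt$FREQ) || freq > 1) freq <- freq / 100
      }
    }
    if (is.na(depth) || is.na(freq)) next
    out[[length(out) + 1L]] <- data.frame(
      contig = f[1], pos = as.integer(f[2]), ref_base = ref, var_base = alt,
      depth = depth, var_freq = freq, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(contig = character(), pos = integer(),
                      ref_base = character(), var_base = character(),
                      depth = numeric(), var_freq = numeric()))
  }
  do.call(rbind, out)
}

#' Read/write a homoeologous SNP map
#'
#' TSV with columns `contig`, `pos`, `allele_ref`, `allele_alt`.
#'
#' @param path TSV file.
#' @return data frame map.
#' @export
read_homoeosnp_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("contig", "pos", "allele_ref", "allele_alt")
  if (!all(need %in% names(df)))
    stop("homoeologous SNP map must have columns: ",
         paste(need, collapse = ", "))
  df
}

#' @rdname read_homoeosnp_map
#' @param map data frame map.
#' @export
write_homoeosnp_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Emits the SAM subset this package consumes: header `@SQ` lines, and per
#' read QNAME/FLAG/RNAME/POS/MAPQ/CIGAR (ungapped `<L>M`), `*` mate fields,
#' SEQ, `*` QUAL, and the `NM:i:` tag. Unmapped reads get flag 4.
#'
#' @param alignments data frame with `read_id`, `contig`, `pos`, `mapped`,
#'   `nm` as produced by [align_reads_naive()].
#' @param reads data frame with `read_id` and `seq` (may be `NULL`; SEQ is
#'   then `*`).
#' @param genome genome the alignments refer to (for `@SQ` lengths).
#' @param path output SAM file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, genome, path) {
  validate_genome(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ctg in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg, nchar(genome[[ctg]])), con)
  seqs <- if (is.null(reads)) NULL else setNames(reads$seq, reads$read_id)
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    sq <- if (is.null(seqs)) "*" else unname(seqs[a$read_id])
    if (isTRUE(a$mapped)) {
      cigar <- if (sq == "*") "*" else paste0(nchar(sq), "M")
      writeLines(paste(a$read_id, 0L, a$contig, a$pos, 60L, cigar,
                       "*", 0L, 0L, sq, "*", paste0("NM:i:", a$nm),
                       sep = "\t"), con)
    } else {
      writeLines(paste(a$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       sq, "*", sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read alignments from SAM
#'
#' Honors the unmapped flag (0x4) and requires the `NM:i:` tag on mapped
#' records.
#'
#' @param path SAM file.
#' @return data frame with `read_id`, `contig`, `pos`, `mapped`, `nm`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(f)
  read_id <- vapply(f, `[`, "", 1L)
  flag <- as.integer(vapply(f, `[`, "", 2L))
  contig <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L))
  mapped <- bitwAnd(flag, 4L) == 0L
  nm <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!mapped[i]) next
    tags <- f[[i]][-(1:11)]
    hit <- grep("^NM:i:", tags, value = TRUE)
    if (!length(hit))
      stop("mapped SAM record without NM tag: ", read_id[i])
    nm[i] <- as.integer(sub("^NM:i:", "", hit[1]))
  }
  data.frame(read_id = read_id, contig = ifelse(mapped, contig, NA),
             pos = ifelse(mapped, pos, NA_integer_), mapped = mapped,
             nm = nm, stringsAsFactors = FALSE)
}

#' Write/read a count set as TSV plus sample-metadata sidecar
#'
#' The count matrix is written as genes x samples TSV with a `gene_id`
#' first column; the sidecar (`<path>.samples.tsv`) holds `sample_id`,
#' `group`, `condition`, `replicate`, `library_size`.
#'
#' @param cs a [count_set()].
#' @param path output TSV for the matrix.
#' @return `path`, invisibly.
#' @export
write_count_set <- function(cs, path) {
  m <- data.frame(gene_id = rownames(cs$counts), cs$counts,
                  check.names = FALSE)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- cs$samples
  meta$library_size <- unname(cs$library_sizes[meta$sample_id])
  write.table(meta, paste0(path, ".samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_set
#' @export
read_count_set <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  counts <- as.matrix(m[, -1, drop = FALSE])
  rownames(counts) <- m$gene_id
  meta <- read.table(paste0(path, ".samples.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  count_set(counts, meta[, c("sample_id", "group", "condition", "replicate")],
            setNames(meta$library_size, meta$sample_id))
}

#' Read a gene-to-term annotation table
#'
#' Two-column TSV (`gene`, `term`), one pair per line, optionally with a
#' header.
#'
#' @param path TSV file.
#' @return data frame with columns `term`, `gene`.
#' @export
read_term_annotations <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (identical(tolower(unlist(df[1, ])), c("gene", "term")) ||
      identical(tolower(unlist(df[1, ])), c("term", "gene")))
    df <- df[-1, , drop = FALSE]
  names(df) <- c("gene", "term")
  data.frame(term = df$term, gene = df$gene, stringsAsFactors = FALSE)
}
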