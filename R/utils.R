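COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Hamming distance between two equal-length strings
#'
#' Counts positions at which the two strings differ. Used both by the
#' simulator's oracle aligner and by construction checks on the virtual
#' genome.
#'
#' @param a,b character scalars of equal nchar.
#' @return integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): strings differ in length")
  sum(charToRaw(a) != charToRaw(b))
}

revcomp <- function(s) {
  x <- rev(strsplit(s, "", fixed = TRUE)[[1]])
  paste(COMPLEMENT[x], collapse = "")
}

#' Validate a genome object
#'
#' A genome is represented as a named character vector: one element per
#' contig, values are upper-case nucleotide strings (A/C/G/T/N).
#'
#' @param genome named character vector of contig sequences.
#' @return the genome, invisibly, after validation.
#' @export
validate_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector of contig sequences")
  if (anyDuplicated(names(genome)))
    stop("genome contig identifiers must be unique")
  if (any(nchar(genome) == 0L))
    stop("genome contigs must be non-empty")
  invisible(genome)
}

# substitute single bases at 1-based positions within one contig string
substitute_bases <- function(seq, pos, base) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  x[pos] <- base
  paste(x, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
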