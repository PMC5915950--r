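# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they
# verify.

# character-by-character Hamming distance (vs the rawToChar-based one)
oracle_hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  sum(x != y)
}

# brute-force read sorting: recompute both distances from the read
# sequence and the genomes, then apply "strictly fewer mismatches wins"
oracle_sort <- function(reads, genome_a, genome_b) {
  vapply(seq_len(nrow(reads)), function(i) {
    L <- nchar(reads$seq[i])
    loc_a <- substr(genome_a[[reads$contig[i]]], reads$pos[i],
                    reads$pos[i] + L - 1)
    loc_b <- substr(genome_b[[reads$contig[i]]], reads$pos[i],
                    reads$pos[i] + L - 1)
    da <- oracle_hamming(reads$seq[i], loc_a)
    db <- oracle_hamming(reads$seq[i], loc_b)
    if (da < db) "ORIGIN_A" else if (db < da) "ORIGIN_B"
    else "UNCLASSIFIED"
  }, "")
}

# hypergeometric upper-tail P(X >= k) by explicit summation
oracle_fisher_tail <- function(k, K, n, N) {
  i <- seq.int(max(k, 0L), min(n, K))
  if (!length(i)) return(1)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# --- independent Nei-Gojobori 1986 oracle --------------------------------
# Site fractions by explicit mutation enumeration, pathway counts by
# recursive enumeration of substitution orders; conventions mirrored:
# stop-codon changes are nonsynonymous in site counting, pathways through
# intermediate stops are skipped (falling back to all pathways when every
# one is blocked), the trailing stop pair is excluded.
oracle_ng86 <- function(cds_a, cds_b) {
  gc <- Biostrings::GENETIC_CODE
  codons <- function(s) substring(s, seq(1, nchar(s), 3),
                                  seq(3, nchar(s), 3))
  ca <- codons(cds_a); cb <- codons(cds_b)
  if (gc[[ca[length(ca)]]] == "*") {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  keep <- !(vapply(ca, function(x) gc[[x]] == "*", TRUE) |
              vapply(cb, function(x) gc[[x]] == "*", TRUE))
  ca <- ca[keep]; cb <- cb[keep]
  syn_frac <- function(cod) {
    s <- 0
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == substr(cod, p, p)) next
      mut <- cod; substr(mut, p, p) <- b
      if (gc[[mut]] != "*" && gc[[mut]] == gc[[cod]]) s <- s + 1 / 3
    }
    s
  }
  paths <- function(cur, target, skip_stops) {
    # returns list of c(sd, nd) for each admissible substitution order
    dp <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dp)) return(list(c(0, 0)))
    out <- list()
    for (p in dp) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      if (skip_stops && gc[[nxt]] == "*" && nxt != target) next
      step <- if (gc[[nxt]] == gc[[cur]]) c(1, 0) else c(0, 1)
      for (tail in paths(nxt, target, skip_stops))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (syn_frac(ca[i]) + syn_frac(cb[i])) / 2
    pp <- paths(ca[i], cb[i], skip_stops = TRUE)
    if (!length(pp)) pp <- paths(ca[i], cb[i], skip_stops = FALSE)
    m <- do.call(rbind, pp)
    Sd <- Sd + mean(m[, 1]); Nd <- Nd + mean(m[, 2])
  }
  N <- 3 * length(ca) - S
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

# random codon sequence free of stop codons, ending in a stop
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(c(sample(sense, n_codons - 1, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}

# mutate a CDS at random positions (point substitutions, may hit stops)
mutate_cds <- function(cds, n_mut) {
  x <- strsplit(cds, "")[[1]]
  at <- sample(length(x), min(n_mut, length(x)))
  for (p in at) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}
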