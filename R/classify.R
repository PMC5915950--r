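# Differential expression and category calls. Group comparisons use an
# explicit negative-binomial Wald test (median-of-ratios size factors,
# per-gene moment dispersion, delta-method standard error); significance
# relations at FDR <= alpha are then mapped to the additivity taxonomy
# (additive / expression-level dominance / transgressive) and the
# homoeolog-bias taxonomy (retained / lost / gained / reversed).

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving
#' with the input.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Convert a test outcome into a significance relation
#'
#' Relations are reported for "first group vs second group": `GT` means
#' the first-named group is significantly higher, `LT` lower, `EQ` not
#' significantly different. The threshold is inclusive (`fdr <= alpha` is
#' significant).
#'
#' @param fdr BH-adjusted p-values.
#' @param log2fc log2 fold change of the second group over the first (the
#'   scale [nb_wald_test()] reports).
#' @param alpha FDR threshold, default 0.001.
#' @return character vector of "EQ"/"GT"/"LT".
#' @export
relation_of <- function(fdr, log2fc, alpha = 0.001) {
  out <- rep("EQ", length(fdr))
  sig <- !is.na(fdr) & fdr <= alpha
  out[sig & log2fc < 0] <- "GT"
  out[sig & log2fc > 0] <- "LT"
  out[is.na(fdr)] <- NA_character_
  out
}

#' Negative-binomial Wald test between two groups
#'
#' Explicit construction: (1) size factors by median-of-ratios across all
#' samples of the pair (geometric-mean reference over genes with
#' all-positive counts); (2) normalized group means; (3) per-gene
#' dispersion by method of moments, pooling the within-group variances of
#' both groups (ANOVA pooled variance), floored at 1e-8; (4) Wald
#' statistic `z = ln((mu_B + c) / (mu_A + c)) / SE` with
#' `SE^2 = (1/n_A)(1/(mu_A + c) + phi) + (1/n_B)(1/(mu_B + c) + phi)` and
#' pseudo-count `c = 0.5`; two-sided normal p-value, BH adjustment.
#' Genes with zero counts in every sample of the pair are skipped
#' (`tested = FALSE`), not called EQ.
#'
#' This is deliberately simpler than shrinkage-based packages (no
#' dispersion moderation); it is calibrated by simulation, not by
#' matching any external tool.
#'
#' @param counts_a,counts_b count matrices (genes x replicates) for the
#'   first and second group, same genes in the same order.
#' @param lib_a,lib_b library sizes (used only for validity checks;
#'   normalization is by median-of-ratios).
#' @param alpha FDR threshold for the reported relation.
#' @return data frame: `gene`, `mu_a`, `mu_b` (normalized means),
#'   `log2fc` (second over first), `se` (of the natural-log fold change),
#'   `stat`, `p`, `fdr`, `relation` (first vs second), `tested`.
#' @export
nb_wald_test <- function(counts_a, counts_b, lib_a = NULL, lib_b = NULL,
                         alpha = 0.001) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b))
    stop("count matrices must have the same genes")
  n_a <- ncol(counts_a); n_b <- ncol(counts_b)
  if (n_a < 2 || n_b < 2) stop("need >= 2 replicates per group")
  if (!is.null(lib_a) && all(lib_a == 0)) stop("group A has zero library")
  if (!is.null(lib_b) && all(lib_b == 0)) stop("group B has zero library")
  x <- cbind(counts_a, counts_b)
  lg <- rowMeans(log(x))
  ok <- is.finite(lg)
  if (!any(ok))
    stop("cannot compute size factors: no gene has all-positive counts")
  sf <- apply(x, 2, function(col) exp(median(log(col[ok]) - lg[ok])))
  xn <- sweep(x, 2, sf, "/")
  an <- xn[, seq_len(n_a), drop = FALSE]
  bn <- xn[, n_a + seq_len(n_b), drop = FALSE]
  mu_a <- rowMeans(an); mu_b <- rowMeans(bn)
  s2 <- ((n_a - 1) * apply(an, 1, var) + (n_b - 1) * apply(bn, 1, var)) /
    (n_a + n_b - 2)
  mu_pool <- (n_a * mu_a + n_b * mu_b) / (n_a + n_b)
  phi <- pmax((s2 - mu_pool) / mu_pool^2, 1e-8)
  cc <- 0.5
  lfc <- log((mu_b + cc) / (mu_a + cc))
  se <- sqrt((1 / n_a) * (1 / (mu_a + cc) + phi) +
             (1 / n_b) * (1 / (mu_b + cc) + phi))
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  tested <- rowSums(x) > 0
  p[!tested] <- NA
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- bh_adjust(p[tested])
  genes <- rownames(counts_a) %||% as.character(seq_len(nrow(counts_a)))
  out <- data.frame(
    gene = genes, mu_a = mu_a, mu_b = mu_b, log2fc = lfc / log(2),
    se = se, stat = stat, p = p, fdr = fdr,
    relation = relation_of(fdr, lfc / log(2), alpha), tested = tested,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Additivity classification from three relations
#'
#' A homoeolog group whose hybrid total is indistinguishable from the
#' mid-ancestral value is ADDITIVE. Otherwise: equal to one ancestor and
#' different from the other is expression-level dominance (ELD_BD /
#' ELD_BS); above both ancestors is TRANSGRESSIVE_UP, below both
#' TRANSGRESSIVE_DOWN; every remaining nonadditive pattern (including a
#' hybrid equal to both ancestors but not to their mid-value) is
#' OTHER_NONADDITIVE.
#'
#' @param rel_bh_vs_mav,rel_bh_vs_bd,rel_bh_vs_bs relation vectors
#'   ("EQ"/"GT"/"LT", hybrid named first).
#' @return character vector of category labels.
#' @export
classify_additivity <- function(rel_bh_vs_mav, rel_bh_vs_bd,
                                rel_bh_vs_bs) {
  n <- length(rel_bh_vs_mav)
  out <- rep(NA_character_, n)
  done <- is.na(rel_bh_vs_mav) | is.na(rel_bh_vs_bd) | is.na(rel_bh_vs_bs)
  add <- !done & rel_bh_vs_mav == "EQ"
  out[add] <- "ADDITIVE"
  rest <- !done & !add
  out[rest & rel_bh_vs_bd == "EQ" & rel_bh_vs_bs != "EQ"] <- "ELD_BD"
  out[rest & rel_bh_vs_bs == "EQ" & rel_bh_vs_bd != "EQ"] <- "ELD_BS"
  out[rest & rel_bh_vs_bd == "GT" & rel_bh_vs_bs == "GT"] <-
    "TRANSGRESSIVE_UP"
  out[rest & rel_bh_vs_bd == "LT" & rel_bh_vs_bs == "LT"] <-
    "TRANSGRESSIVE_DOWN"
  out[rest & is.na(out)] <- "OTHER_NONADDITIVE"
  out
}

#' Homoeolog-bias classification from two relations
#'
#' Compares the ancestral relation (BD vs BS) with the hybrid homoeolog
#' relation (BH_BD vs BH_BS): equal everywhere is NO_BIAS; the same
#' inequality on both sides is BIAS_RETAINED; an ancestral inequality
#' vanishing in the hybrid is BIAS_LOST; a new hybrid inequality is
#' BIAS_GAINED; opposite inequalities are BIAS_REVERSED. NO_BIAS and
#' BIAS_RETAINED form the ancestral pattern class; the rest are
#' nonancestral.
#'
#' @param rel_bd_vs_bs,rel_bhbd_vs_bhbs relation vectors.
#' @return data frame with `category` and `pattern_class`.
#' @export
classify_bias <- function(rel_bd_vs_bs, rel_bhbd_vs_bhbs) {
  n <- length(rel_bd_vs_bs)
  cat <- rep(NA_character_, n)
  a <- rel_bd_vs_bs; h <- rel_bhbd_vs_bhbs
  ok <- !is.na(a) & !is.na(h)
  cat[ok & a == "EQ" & h == "EQ"] <- "NO_BIAS"
  cat[ok & a != "EQ" & a == h] <- "BIAS_RETAINED"
  cat[ok & a != "EQ" & h == "EQ"] <- "BIAS_LOST"
  cat[ok & a == "EQ" & h != "EQ"] <- "BIAS_GAINED"
  cat[ok & a != "EQ" & h != "EQ" & a != h] <- "BIAS_REVERSED"
  data.frame(
    category = cat,
    pattern_class = ifelse(is.na(cat), NA_character_,
                           ifelse(cat %in% c("NO_BIAS", "BIAS_RETAINED"),
                                  "ANCESTRAL", "NONANCESTRAL")),
    stringsAsFactors = FALSE)
}

#' Classify a whole transcriptome
#'
#' Derives the mid-ancestral value and hybrid-total pseudo-samples,
#' applies the expressed filter (MAV RPM and hybrid-total RPM at or above
#' the threshold in every replicate), runs the five pairwise tests
#' (hybrid total vs MAV, vs BD, vs BS; BD vs BS; BH_BD vs BH_BS), and
#' reports one row per expressed homoeolog group with all relations,
#' FDRs, the additivity category, and the bias category.
#'
#' @param cs a [count_set()] with groups BD, BS, BH_BD, BH_BS.
#' @param alpha FDR threshold (inclusive), default 0.001.
#' @param rpm_threshold expressed filter threshold, default 1.
#' @param condition condition label to analyse (default: the first).
#' @return wide data frame, one row per expressed gene.
#' @export
classify_transcriptome <- function(cs, alpha = 0.001, rpm_threshold = 1,
                                   condition = NULL) {
  stopifnot(inherits(cs, "count_set"))
  need <- c("BD", "BS", "BH_BD", "BH_BS")
  missing <- setdiff(need, unique(cs$samples$group))
  if (length(missing))
    stop("count set lacks group(s): ", paste(missing, collapse = ", "))
  condition <- condition %||% cs$samples$condition[1]
  keep <- cs$samples$condition == condition
  cs <- count_set(cs$counts[, keep, drop = FALSE],
                  cs$samples[keep, , drop = FALSE], cs$library_sizes[keep])
  mav <- compute_mav(cs)
  bht <- compute_bh_total(cs)

  expressed <- rowSums(compute_rpm(mav) < rpm_threshold) == 0 &
    rowSums(compute_rpm(bht) < rpm_threshold) == 0
  genes <- rownames(cs$counts)[expressed]
  if (!length(genes)) stop("no gene passes the expressed filter")
  sub <- function(x) x$counts[genes, , drop = FALSE]
  lib <- function(x) x$library_sizes
  cols <- function(g) {
    idx <- cs_columns(cs, g)
    cs$counts[genes, idx, drop = FALSE]
  }
  t_bh_mav <- nb_wald_test(sub(bht), sub(mav), lib(bht), lib(mav), alpha)
  t_bh_bd <- nb_wald_test(sub(bht), cols("BD"), lib(bht), NULL, alpha)
  t_bh_bs <- nb_wald_test(sub(bht), cols("BS"), lib(bht), NULL, alpha)
  t_bd_bs <- nb_wald_test(cols("BD"), cols("BS"), NULL, NULL, alpha)
  t_hd_hs <- nb_wald_test(cols("BH_BD"), cols("BH_BS"), NULL, NULL, alpha)

  bias <- classify_bias(t_bd_bs$relation, t_hd_hs$relation)
  data.frame(
    gene = genes,
    condition = condition,
    rel_bh_vs_mav = t_bh_mav$relation,
    rel_bh_vs_bd = t_bh_bd$relation,
    rel_bh_vs_bs = t_bh_bs$relation,
    rel_bd_vs_bs = t_bd_bs$relation,
    rel_bhbd_vs_bhbs = t_hd_hs$relation,
    fdr_bh_vs_mav = t_bh_mav$fdr,
    fdr_bh_vs_bd = t_bh_bd$fdr,
    fdr_bh_vs_bs = t_bh_bs$fdr,
    fdr_bd_vs_bs = t_bd_bs$fdr,
    fdr_bhbd_vs_bhbs = t_hd_hs$fdr,
    log2fc_bh_vs_mav = t_bh_mav$log2fc,
    log2fc_bd_vs_bs = t_bd_bs$log2fc,
    log2fc_bhbd_vs_bhbs = t_hd_hs$log2fc,
    additivity = classify_additivity(t_bh_mav$relation, t_bh_bd$relation,
                                     t_bh_bs$relation),
    bias = bias$category,
    pattern_class = bias$pattern_class,
    stringsAsFactors = FALSE)
}
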