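# End-to-end orchestration on the synthetic study:
# simulate -> snpmap -> virtualize -> sort -> count -> classify -> kaks
# -> enrich. Every stage writes text artifacts under the output
# directory; a manifest records parameters and md5 checksums so that
# reruns with the same configuration are byte-identical.

PIPELINE_STAGES <- c("simulate", "snpmap", "virtualize", "sort", "count",
                     "classify", "kaks", "enrich")

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; all stage randomness derives from it.
#' @param alpha FDR threshold for classification (inclusive).
#' @param rpm_threshold expressed-filter threshold.
#' @param lambda synonymous substitution rate (subs/site/year).
#' @param thresholds homoeologous-SNP call thresholds.
#' @param max_term_genes large-term exclusion bound for enrichment.
#' @param sim arguments forwarded to [sim_config()] (list).
#' @param stages stages to run, in dependency order.
#' @return validated config list.
#' @export
run_config <- function(out_dir, seed = 1L, alpha = 0.001,
                       rpm_threshold = 1, lambda = 6.1e-9,
                       thresholds = snp_thresholds(),
                       max_term_genes = 3000,
                       sim = list(), stages = PIPELINE_STAGES) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  sim$seed <- sim$seed %||% seed
  list(out_dir = out_dir, seed = seed, alpha = alpha,
       rpm_threshold = rpm_threshold, lambda = lambda,
       thresholds = thresholds, max_term_genes = max_term_genes,
       sim = sim, stages = stages)
}

#' Read a pipeline configuration from JSON
#'
#' Flat JSON object whose keys mirror the arguments of [run_config()];
#' the `sim` sub-object is forwarded to [sim_config()].
#'
#' @param path JSON file.
#' @param out_dir overrides the configured output directory if non-NULL.
#' @return validated config list.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$out_dir <- out_dir %||% j$out_dir
  if (is.null(j$out_dir)) stop("config needs an out_dir")
  do.call(run_config, j[intersect(names(j), names(formals(run_config)))])
}

#' Run the analysis pipeline on a synthetic study
#'
#' Stages run in dependency order; each writes its outputs and a log
#' entry with the parameters used. A stage failure stops the run naming
#' the stage. The manifest lists every artifact with its md5 checksum.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `manifest` (data frame stage/file/md5)
#'   and `summary` (per-stage key numbers), also written as JSON.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(config$out_dir, ...)
  artifacts <- list()
  summary <- list()
  log_lines <- character(0)
  note <- function(stage, ...) {
    log_lines <<- c(log_lines, paste0("[", stage, "] ", ...))
  }
  add <- function(stage, files) {
    artifacts[[stage]] <<- c(artifacts[[stage]] %||% character(0), files)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cfg <- do.call(sim_config, config$sim)
  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    study <- simulate_study(cfg)
    state$study <- study
    write_genome(study$genome_a, path("genome_a.fasta"))
    write_genome(study$genome_b, path("genome_b_truth.fasta"))
    write_gene_models(study$gene_models, path("gene_models.gff3"))
    write_snp_calls(study$calls_b, path("calls_b_vs_a.tsv"))
    write_snp_calls(study$calls_h, path("calls_h_vs_a.tsv"))
    write_sam(study$aln_a, study$reads, study$genome_a, path("aln_a.sam"))
    write_sam(study$aln_b, study$reads, study$genome_b, path("aln_b.sam"))
    write_count_set(study$count_set, path("counts.tsv"))
    jsonlite::write_json(
      list(snp_truth = study$snp_truth,
           read_truth = as.list(study$read_truth),
           gene_truth = study$gene_truth),
      path("truth.json"), auto_unbox = TRUE, digits = NA)
    add("simulate", path(c("genome_a.fasta", "genome_b_truth.fasta",
                           "gene_models.gff3", "calls_b_vs_a.tsv",
                           "calls_h_vs_a.tsv", "aln_a.sam", "aln_b.sam",
                           "counts.tsv", "counts.tsv.samples.tsv",
                           "truth.json")))
    summary$simulate <<- list(n_truth_snps = nrow(study$snp_truth),
                              n_reads = nrow(study$reads),
                              n_genes = length(unique(
                                study$gene_models$gene_id)))
    note("simulate", "seed=", cfg$seed, " d=", cfg$divergence_rate,
         " e=", cfg$error_rate)
  })

  run_stage("snpmap", function() {
    st <- state$study
    map <- identify_homoeologous_snps(st$calls_b, st$calls_h,
                                      config$thresholds)
    state$map <- map
    write_homoeosnp_map(map, path("homoeosnp_map.tsv"))
    eff <- annotate_effect(map, st$gene_models, st$genome_a)
    write.table(eff, path("snp_effects.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add("snpmap", path(c("homoeosnp_map.tsv", "snp_effects.tsv")))
    smry <- summarize_effects(eff)
    summary$snpmap <<- list(n_snps = nrow(map),
                            region_counts = as.list(smry$region_counts))
    note("snpmap", "thresholds: min_depth=", config$thresholds$min_depth,
         " homo_freq=", config$thresholds$homo_freq,
         " het=[", config$thresholds$het_low, ",",
         config$thresholds$het_high, "]")
  })

  run_stage("virtualize", function() {
    st <- state$study
    virtual <- build_virtual_genome(st$genome_a, state$map)
    state$virtual <- virtual
    write_genome(virtual, path("genome_b_virtual.fasta"))
    rep <- verify_substitutions(st$genome_a, virtual, state$map)
    add("virtualize", path("genome_b_virtual.fasta"))
    summary$virtualize <<- list(n_expected = rep$n_expected,
                                n_applied = rep$n_applied,
                                n_mismatches = nrow(rep$mismatches))
    note("virtualize", "applied ", rep$n_applied, "/", rep$n_expected)
  })

  run_stage("sort", function() {
    st <- state$study
    sorted <- sort_reads(st$aln_a, st$aln_b)
    state$sorted <- sorted
    write.table(sorted$reads, path("sorted_reads.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(sorted$summary, path("sort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    add("sort", path(c("sorted_reads.tsv", "sort_summary.json")))
    summary$sort <<- sorted$summary
    note("sort", "fraction classified = ",
         signif(1 - sorted$summary$fraction_unclassified, 4))
  })

  run_stage("count", function() {
    st <- state$study
    sorted <- state$sorted$reads
    loci <- st$reads[match(sorted$read_id, st$reads$read_id),
                     c("contig", "pos", "seq")]
    per_origin <- lapply(c(ORIGIN_A = "ORIGIN_A", ORIGIN_B = "ORIGIN_B"),
      function(o) {
        sel <- sorted$origin == o
        count_reads(loci[sel, , drop = FALSE], st$gene_models)$counts
      })
    tab <- data.frame(gene_id = names(per_origin$ORIGIN_A),
                      bh_bd_reads = unname(per_origin$ORIGIN_A),
                      bh_bs_reads = unname(per_origin$ORIGIN_B))
    write.table(tab, path("sorted_read_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add("count", path("sorted_read_counts.tsv"))
    summary$count <<- list(reads_counted = sum(tab$bh_bd_reads) +
                             sum(tab$bh_bs_reads))
    note("count", "exon-union single-gene overlap rule")
  })

  run_stage("classify", function() {
    st <- state$study
    cls <- classify_transcriptome(st$count_set, alpha = config$alpha,
                                  rpm_threshold = config$rpm_threshold)
    state$classified <- cls
    write.table(cls, path("classification.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add("classify", path("classification.tsv"))
    summary$classify <<- list(
      n_analyzed = nrow(cls),
      additivity = as.list(table(cls$additivity)),
      bias = as.list(table(cls$bias)))
    note("classify", "alpha=", config$alpha, " rpm_threshold=",
         config$rpm_threshold, " pseudo_count=0.5 dispersion_floor=1e-8")
  })

  run_stage("kaks", function() {
    st <- state$study
    genome_b <- state$virtual %||% st$genome_b
    kk <- kaks_table(st$gene_models, st$genome_a, genome_b)
    write.table(kk, path("kaks.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    tt <- divergence_time(kk$ks, config$lambda)
    jsonlite::write_json(list(mean_ks = mean(kk$ks[is.finite(kk$ks)]),
                              lambda = config$lambda, t_years = tt),
                         path("kaks_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    add("kaks", path(c("kaks.tsv", "kaks_summary.json")))
    summary$kaks <<- list(mean_ks = mean(kk$ks[is.finite(kk$ks)]),
                          t_years = tt)
    note("kaks", "NG86 with Jukes-Cantor correction; lambda=",
         config$lambda)
  })

  run_stage("enrich", function() {
    st <- state$study
    # demonstration annotation: genes assigned round-robin to terms
    genes <- unique(st$gene_models$gene_id)
    ann <- data.frame(
      term = sprintf("T%03d", (seq_along(genes) - 1L) %% 8L + 1L),
      gene = genes, stringsAsFactors = FALSE)
    write.table(ann, path("term_annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cls <- state$classified
    study_set <- cls$gene[cls$additivity != "ADDITIVE"]
    ann <- filter_large_terms(ann, config$max_term_genes)
    enr <- fisher_enrichment(study_set, ann, genes)
    write.table(enr, path("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add("enrich", path(c("term_annotations.tsv", "enrichment.tsv")))
    summary$enrich <<- list(n_terms = nrow(enr),
                            n_study = length(study_set))
    note("enrich", "one-sided Fisher; max_term_genes=",
         config$max_term_genes)
  })

  files <- unlist(artifacts, use.names = FALSE)
  manifest <- data.frame(
    stage = rep(names(artifacts), lengths(artifacts)),
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, path("manifest.json"), digits = NA)
  jsonlite::write_json(summary, path("run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, path("run_log.txt"))
  invisible(list(manifest = manifest, summary = summary))
}
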