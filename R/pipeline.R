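#' Pipeline configuration
#'
#' Builds a validated configuration for [run_all()]. Either pass a
#' `sim_config` under `simulate` (synthetic mode) or paths to genotype,
#' evaluation, annotation and QTL files. Stage seeds are derived from the
#' global seed by fixed offsets, so one seed determines the whole run.
#'
#' @param simulate Optional [sim_config()] for synthetic input.
#' @param paths Optional named list with `genotypes_raw`, `genotypes_map`,
#'   `evaluations`, `pedigree`, `genes`, `qtl`.
#' @param output_dir Directory for output tables (created if needed).
#' @param seed Global integer seed.
#' @param h2_proxy Named per-trait heritability proxies for de-regression.
#' @param min_rel Reliability filter threshold (default 0.2).
#' @param gwas Named list of [bayesb()] settings for the full-data GWAS.
#' @param cv Named list: `models`, `k`, `gwas_control`, `gblup_control`,
#'   or `NULL` to skip cross-validation.
#' @param percentile Marker retention percentile (default 75).
#' @param trim_threshold Network trimming threshold (default 0.98).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            output_dir = tempfile("dystnet_run_"),
                            seed = 1L,
                            h2_proxy = c(DCD = 0.1, MCD = 0.1, GL = 0.5,
                                         STAT = 0.4, STR = 0.4, RW = 0.4),
                            min_rel = 0.2,
                            gwas = list(chain_length = 4000, burn_in = 800),
                            cv = list(models = 1:7, k = 4,
                                      gwas_control = list(chain_length = 1500,
                                                          burn_in = 300),
                                      gblup_control = list(chain_length = 2000,
                                                           burn_in = 500)),
                            percentile = 75, trim_threshold = 0.98) {
  if (is.null(simulate) && is.null(paths))
    stop("either `simulate` or `paths` must be provided")
  if (!is.null(paths)) {
    need <- c("genotypes_raw", "genotypes_map", "evaluations", "pedigree",
              "genes", "qtl")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("missing path(s): ", paste(miss, collapse = ", "))
    absent <- !vapply(paths[need], file.exists, TRUE)
    if (any(absent))
      stop("input file(s) not found: ",
           paste(unlist(paths[need])[absent], collapse = ", "))
  }
  cfg <- list(simulate = simulate, paths = paths, output_dir = output_dir,
              seed = as.integer(seed), h2_proxy = h2_proxy,
              min_rel = min_rel, gwas = gwas, cv = cv,
              percentile = percentile, trim_threshold = trim_threshold)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments; a `simulate` block is converted via [sim_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    if (!is.null(sim_args$genome))
      sim_args$genome <- as.data.frame(sim_args$genome)
    if (!is.null(sim_args$heritabilities))
      sim_args$heritabilities <- unlist(sim_args$heritabilities)
    if (!is.null(sim_args$genetic_correlations))
      sim_args$genetic_correlations <-
        do.call(rbind, sim_args$genetic_correlations)
    y$simulate <- do.call(sim_config, sim_args)
  }
  if (!is.null(y$h2_proxy)) y$h2_proxy <- unlist(y$h2_proxy)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) -> marker QC -> de-regression and filtering ->
#' per-trait Bayes-B GWAS -> SNP-to-gene mapping -> AWM -> PCIT network
#' and trimming -> network statistics and QTL-anchored hub report ->
#' relationship matrices -> cross-validated prediction. All tables are
#' written to `config$output_dir` together with a manifest of file
#' hashes; a rerun under the same config and seed reproduces identical
#' hashes.
#'
#' @param config A `pipeline_config`.
#' @return List of class `pipeline_report` with every stage's outputs and
#'   the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outdir <- config$output_dir

  ## stage: input
  if (!is.null(config$simulate)) {
    pop <- simulate_population(config$simulate)
    genotypes_raw <- pop$genotypes
    evaluations <- pop$evaluations
    pedigree <- pop$pedigree
    genes <- pop$genes
    qtl <- pop$qtl
  } else {
    genotypes_raw <- read_genotypes(config$paths$genotypes_raw,
                                    config$paths$genotypes_map)
    evaluations <- read_evaluations(config$paths$evaluations)
    pedigree <- read_pedigree(config$paths$pedigree)
    genes <- read_intervals(config$paths$genes)
    qtl <- read_intervals(config$paths$qtl)
    pop <- NULL
  }
  traits <- unique(evaluations$trait)

  ## stage: QC
  genotypes <- qc_markers(genotypes_raw)

  ## stage: de-regression
  dereg <- deregress(evaluations, h2 = config$h2_proxy)
  records <- filter_records(dereg, min_rel = config$min_rel,
                            traits = traits)
  write_evaluations(records, file.path(outdir, "deregressed.tsv"))

  ## stage: full-data GWAS + AWM + network
  wide <- eval_wide(records, traits)
  bulls <- intersect(rownames(genotypes$codes), wide$bulls)
  analysis <- training_analysis(genotypes, wide$dpta, wide$w, bulls,
                                genes, qtl, trait_groups(),
                                config$gwas, config$percentile,
                                config$trim_threshold, need_awm = TRUE,
                                seed = config$seed + 10L)
  gwas_tab <- do.call(rbind, lapply(traits, function(t) {
    fit <- analysis$gwas[[t]]
    data.frame(trait = t, marker = names(fit$abar),
               chrom = genotypes$map$chrom, bp = genotypes$map$bp,
               abar = unname(fit$abar),
               inclusion_freq = unname(fit$inclusion_freq),
               pvg = unname(fit$pvg),
               significant = names(fit$abar) %in% analysis$significant[[t]],
               stringsAsFactors = FALSE)
  }))
  write_tsv(gwas_tab, file.path(outdir, "gwas.tsv"))

  network_stats <- NULL
  hubs <- NULL
  gene_qtl <- genes_in_qtl(genes, qtl)
  if (!is.null(analysis$trimmed)) {
    write_network(analysis$trimmed, file.path(outdir, "network.tsv"))
    deg <- network_degrees(analysis$trimmed)
    network_stats <- list(
      n_nodes = length(analysis$trimmed$nodes),
      n_edges = nrow(analysis$trimmed$edges),
      powerlaw = tryCatch(powerlaw_ks_test(deg), error = function(e) NULL))
    hubs <- hub_report(analysis$trimmed, gene_qtl)
    write_tsv(hubs, file.path(outdir, "hubs.tsv"))
  }

  ## stage: cross-validated prediction
  cv_result <- NULL
  if (!is.null(config$cv)) {
    cv_result <- run_cross_validation(
      genotypes, records, pedigree, genes, qtl,
      models = config$cv$models, k = config$cv$k,
      seed = config$seed + 20L,
      gwas_control = config$cv$gwas_control,
      gblup_control = config$cv$gblup_control,
      percentile = config$percentile,
      trim_threshold = config$trim_threshold)
    write_tsv(cv_result$summary, file.path(outdir, "accuracy.tsv"))
    write_tsv(cv_result$varcomp, file.path(outdir, "varcomp.tsv"))
  }

  files <- list.files(outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))

  out <- list(config = config, population = pop, genotypes = genotypes,
              records = records, analysis = analysis,
              gene_qtl = gene_qtl, network_stats = network_stats,
              hubs = hubs, cv = cv_result, manifest = manifest,
              output_dir = outdir)
  class(out) <- "pipeline_report"
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("dystnet pipeline report\n")
  cat(sprintf("  bulls analysed: %d; markers post-QC: %d\n",
              length(unique(x$records$bull)), ncol(x$genotypes$codes)))
  if (!is.null(x$analysis$trimmed))
    cat(sprintf("  trimmed network: %d genes, %d edges\n",
                length(x$analysis$trimmed$nodes),
                nrow(x$analysis$trimmed$edges)))
  if (!is.null(x$cv)) print(x$cv)
  cat(sprintf("  outputs: %s\n", x$output_dir))
  invisible(x)
}
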