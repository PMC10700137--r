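#' Run the full allele-specific analysis pipeline
#'
#' Chains the stages on synthetic (or previously written) data: simulate ->
#' differential expression suite per clone -> categorization -> cross-clone
#' consistency -> escapee detection -> promoter methylation and DML ->
#' copy-number QC, writing one TSV per output plus a JSON run manifest with
#' the package version, seeds, thresholds and md5 checksums of every file.
#' Rerunning with the same config reproduces the outputs byte-identically.
#'
#' @param config Named list (or path to a JSON file): \code{out_dir}
#'   (required), \code{seed} (default 1), \code{sim} (list of
#'   \code{\link{sim_config}} arguments; omit to read \code{counts} TSV
#'   instead), \code{thresholds} (list of \code{\link{ase_thresholds}}
#'   arguments), \code{stages} (subset of de, categorize, consistency,
#'   escapees, methylation, qc; default all).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages)) {
    stages <- c("de", "categorize", "consistency", "escapees",
                "methylation", "qc")
  }
  th <- do.call(ase_thresholds, as.list(config$thresholds))
  log_stage <- function(...) message("[asekit] ", ...)
  files <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    files <<- c(files, p)
  }

  sim_args <- as.list(config$sim)
  sim_args$seed <- seed
  log_stage("simulate: generating synthetic experiment")
  sim <- simulate_experiment(do.call(sim_config, sim_args))
  truth <- sim$truth
  for (cl in names(sim$tables)) {
    p <- file.path(out_dir, paste0("counts_", cl, ".tsv"))
    write_counts(sim$tables[[cl]], p)
    files <- c(files, p)
  }
  emit(truth$genes, "truth_genes.tsv")
  emit(truth$clone_effects, "truth_clone_effects.tsv")

  results <- list(sim = sim, suites = list(), calls = list())
  crosses <- sim$config$crosses
  names(crosses) <- vapply(crosses, `[[`, "", "clone_id")

  if ("de" %in% stages) {
    for (cl in names(sim$tables)) {
      log_stage("de: clone ", cl)
      suite <- run_de_suite(sim$tables[[cl]])
      results$suites[[cl]] <- suite
      for (mode in c("standard", "allele1", "allele2", "allele_specific")) {
        emit(suite[[mode]], paste0("de_", mode, "_", cl, ".tsv"))
      }
    }
  }
  if ("categorize" %in% stages && length(results$suites)) {
    for (cl in names(results$suites)) {
      log_stage("categorize: clone ", cl)
      wt <- compute_wt_allele_stats(sim$tables[[cl]],
                                    results$suites[[cl]]$size_factors$allelic,
                                    pseudocount = th$pseudocount)
      calls <- assign_categories(results$suites[[cl]], wt, th)
      results$calls[[cl]] <- calls
      emit(as.data.frame(calls), paste0("categories_", cl, ".tsv"))
    }
  }
  if ("consistency" %in% stages && length(results$calls) >= 2L) {
    cls <- names(results$calls)[1:2]
    log_stage("consistency: ", cls[1L], " vs ", cls[2L])
    cons <- classify_cross_clone_consistency(
      results$calls[[cls[1L]]], results$calls[[cls[2L]]],
      crosses[[cls[1L]]], crosses[[cls[2L]]])
    results$consistency <- cons
    emit(cons, "consistency.tsv")
  }
  if ("escapees" %in% stages && length(results$suites)) {
    for (cl in names(results$suites)) {
      if (crosses[[cl]]$xi_allele == "none") next
      log_stage("escapees: clone ", cl)
      esc <- identify_escapees(sim$tables[[cl]], results$suites[[cl]],
                               crosses[[cl]], truth$genes, th)
      results$escapees[[cl]] <- esc
      emit(as.data.frame(esc), paste0("escapees_", cl, ".tsv"))
    }
  }
  if ("methylation" %in% stages) {
    cl <- names(sim$tables)[1L]
    log_stage("methylation: clone ", cl)
    meth <- simulate_methylation(sim, clone_id = cl, seed = seed + 1L)
    dml <- call_dml(meth[meth$condition == "WT", ],
                    meth[meth$condition == "KO", ])
    results$dml <- dml
    emit(meth, "methylation_cpgs.tsv")
    emit(dml, "dml.tsv")
  }
  if ("qc" %in% stages) {
    log_stage("qc: chromosome coverage flags")
    for (cl in names(sim$tables)) {
      tab <- sim$tables[[cl]]
      chrom <- truth$genes$chrom[match(tab$gene_id, truth$genes$gene_id)]
      cov <- rbind(
        data.frame(chrom = chrom, allele = "a1", count = rowSums(tab$a1)),
        data.frame(chrom = chrom, allele = "a2", count = rowSums(tab$a2)))
      cov <- stats::aggregate(count ~ chrom + allele, cov, sum)
      flags <- chromosome_cpm_flags(cov)
      results$qc[[cl]] <- flags
      emit(flags, paste0("qc_cpm_", cl, ".tsv"))
    }
  }

  manifest <- list(
    package = "asekit",
    version = as.character(utils::packageVersion("asekit")),
    r_version = R.version.string,
    seed = seed,
    stages = stages,
    thresholds = unclass(th),
    sim = sim_args[setdiff(names(sim_args), "crosses")],
    files = lapply(stats::setNames(files, basename(files)),
                   function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}
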