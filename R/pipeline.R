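# End-to-end drivers tying the modules into the design -> evaluate -> rank
# -> pleiotropy flow, with exit-status contracts for the command-line
# wrapper: 0 success, 1 usage/configuration error, 2 data error.

.writeRunConfig <- function(config, outDir) {
  yaml::write_yaml(config, file.path(outDir, "run_config.yaml"))
}

#' Run the full gRNA design pipeline
#'
#' Loads the genome, target sites and optional SNP track, screens and ranks
#' every site with the chosen editor, and writes `report.tsv` (one row per
#' site x candidate), `summary_feasible.tsv` and `summary_failures.tsv`,
#' `best_guides.tsv`, `skipped_sites.tsv` (sites that failed loading, with
#' reasons) and `run_config.yaml` (the fully resolved configuration, for
#' provenance) into `outDir`.
#'
#' @param genomePath FASTA genome.
#' @param sitesPath VCF or TSV site list.
#' @param editorName editor to use (looked up case-insensitively).
#' @param editorsConfig optional YAML overriding/extending the shipped
#'   editor registry.
#' @param snpsPath optional VCF of background SNPs.
#' @param maxMismatch,pamPolicy,cfdTablePath off-target scan settings.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with `status` (0/1/2), the `report`
#'   data.frame, the two summary tables and the `skipped` sites.
#' @export
runDesign <- function(genomePath, sitesPath, editorName,
                      editorsConfig = NULL, snpsPath = NULL,
                      maxMismatch = 4L, pamPolicy = "strict",
                      cfdTablePath = NULL, outDir = ".") {
  usage <- function(msg) {
    message("error: ", msg)
    return(invisible(list(status = 1L)))
  }
  if (!file.exists(genomePath)) return(usage(paste0("genome file not found: ",
                                                    genomePath)))
  if (!file.exists(sitesPath)) return(usage(paste0("sites file not found: ",
                                                   sitesPath)))
  registry <- tryCatch(loadEditors(editorsConfig),
                       error = function(e) e)
  if (inherits(registry, "error")) return(usage(conditionMessage(registry)))
  editor <- tryCatch(getEditor(registry, editorName), error = function(e) e)
  if (inherits(editor, "error")) return(usage(conditionMessage(editor)))
  cfdTable <- if (is.null(cfdTablePath)) defaultCfdTable(pamPattern(editor))
              else readCfdTable(cfdTablePath)

  genome <- readGenome(genomePath)
  sites <- readSites(sitesPath, genome)
  snpTrack <- if (!is.null(snpsPath)) readSnpTrack(snpsPath) else NULL

  skipped <- sites[!is.na(sites$load_error), , drop = FALSE]
  for (i in seq_len(nrow(skipped)))
    message("skipping site ", skipped$site_id[i], ": ",
            skipped$load_error[i])
  report <- designGuides(sites, editor, genome, snpTrack = snpTrack,
                         maxMismatch = maxMismatch, cfdTable = cfdTable,
                         pamPolicy = pamPolicy)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeReport(report, file.path(outDir, "report.tsv"))
  editable <- report[report$status == "editable", , drop = FALSE]
  feasible <- NULL
  if (nrow(editable)) {
    feasible <- summarizeFeasibleCounts(as.integer(table(editable$site_id)))
    write.table(feasible, file.path(outDir, "summary_feasible.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    best <- editable[editable$is_best, , drop = FALSE]
    writeReport(best, file.path(outDir, "best_guides.tsv"))
  }
  failures <- NULL
  failed <- report[report$status == "failed", , drop = FALSE]
  if (nrow(failed)) {
    failures <- summarizeFailures(failed$fail_reason)
    write.table(failures, file.path(outDir, "summary_failures.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(skipped, file.path(outDir, "skipped_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeRunConfig(list(
    command = "design", genome = genomePath, sites = sitesPath,
    editor = editorName,
    editors_config = if (is.null(editorsConfig)) "" else editorsConfig,
    snps = if (is.null(snpsPath)) "" else snpsPath,
    max_mismatch = as.integer(maxMismatch), pam_policy = pamPolicy,
    cfd_table = if (is.null(cfdTablePath)) "" else cfdTablePath),
    outDir)
  status <- if (nrow(skipped) > 0L) 2L else 0L
  invisible(list(status = status, report = report, feasible = feasible,
                 failures = failures, skipped = skipped))
}

#' Run the pleiotropy assessment
#'
#' Reads GWAS summary tables, profiles each requested SNP, bins pleiotropy
#' strength, screens the weak-pleiotropy set and writes `profiles.tsv`,
#' `strength_bins.tsv`, `weak_snps.tsv`, per-SNP QQ tables under `qq/` and
#' `run_config.yaml` into `outDir`.
#'
#' @param gwasPath GWAS TSV file or directory of per-phenotype TSVs.
#' @param snpIds optional character vector restricting the profiled SNPs.
#' @param alpha significance threshold (default 0.05).
#' @param maxSignificant weak-pleiotropy criterion: largest number of
#'   significant phenotypes still called weak (default 1; reported in the
#'   output header).
#' @param outDir output directory.
#' @return invisibly, list with `status`, `profiles`, `bins`, `weak`.
#' @export
runPleiotropy <- function(gwasPath, snpIds = NULL, alpha = 0.05,
                          maxSignificant = 1L, outDir = ".") {
  if (!file.exists(gwasPath) && !dir.exists(gwasPath)) {
    message("error: GWAS input not found: ", gwasPath)
    return(invisible(list(status = 1L)))
  }
  gwas <- readGwas(gwasPath)
  profiles <- pleiotropyProfiles(gwas, snpIds = snpIds, alpha = alpha)
  bins <- binStrength(profiles)
  weak <- screenWeak(profiles, maxSignificant = maxSignificant)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  write.table(profiles, file.path(outDir, "profiles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bins, file.path(outDir, "strength_bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  weakCon <- file(file.path(outDir, "weak_snps.tsv"), "wt")
  writeLines(c(sprintf("# weak pleiotropy criterion: n_significant <= %d",
                       maxSignificant), "snp_id", weak), weakCon)
  close(weakCon)
  qqDir <- file.path(outDir, "qq")
  dir.create(qqDir, showWarnings = FALSE)
  for (snp in unique(profiles$snp_id)) {
    qq <- qqPoints(gwas$p_value[gwas$snp_id == snp])
    write.table(qq, file.path(qqDir, paste0(snp, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  .writeRunConfig(list(command = "pleiotropy", gwas = gwasPath,
                       alpha = alpha,
                       max_significant = as.integer(maxSignificant)),
                  outDir)
  invisible(list(status = 0L, profiles = profiles, bins = bins,
                 weak = weak))
}

#' Summarize an existing design report
#'
#' @param reportPath a `report.tsv` written by [runDesign()].
#' @param outDir output directory for `summary_feasible.tsv` and
#'   `summary_failures.tsv`.
#' @return invisibly, list with `status`, `feasible`, `failures`.
#' @export
runSummarize <- function(reportPath, outDir = ".") {
  if (!file.exists(reportPath)) {
    message("error: report not found: ", reportPath)
    return(invisible(list(status = 1L)))
  }
  report <- readReport(reportPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  editable <- report[report$status == "editable", , drop = FALSE]
  feasible <- NULL
  if (nrow(editable)) {
    feasible <- summarizeFeasibleCounts(as.integer(table(editable$site_id)))
    write.table(feasible, file.path(outDir, "summary_feasible.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  failed <- report[report$status == "failed", , drop = FALSE]
  failures <- NULL
  if (nrow(failed)) {
    failures <- summarizeFailures(failed$fail_reason)
    write.table(failures, file.path(outDir, "summary_failures.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(status = 0L, feasible = feasible, failures = failures))
}

#' Generate a synthetic fixture from the command line
#'
#' @param specPath optional YAML file overriding [plantSpec()] defaults
#'   (top-level keys matching the `plantSpec` arguments).
#' @param outDir output directory.
#' @param seed seed overriding the spec's.
#' @return invisibly, list with `status` and the fixture objects.
#' @export
runSimulate <- function(specPath = NULL, outDir = ".", seed = NULL) {
  args <- list()
  if (!is.null(specPath)) {
    if (!file.exists(specPath)) {
      message("error: spec file not found: ", specPath)
      return(invisible(list(status = 1L)))
    }
    args <- yaml::read_yaml(specPath)
  }
  if (!is.null(seed)) args$seed <- as.integer(seed)
  spec <- do.call(plantSpec, args)
  fixture <- simulateFixture(spec, outDir)
  invisible(c(list(status = 0L), fixture))
}
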