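# Every pipeline output starts with a header recording provenance, so
# outputs are auditable and reruns are comparable bit-for-bit.
.outputHeader <- function(config) {
  cfg <- paste(names(config), unlist(lapply(config, paste, collapse = ",")),
               sep = "=", collapse = " ")
  c(sprintf("# awbox %s", as.character(packageVersion("awbox"))),
    sprintf("# config %s", cfg))
}

.writeWithHeader <- function(df, file, config) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(.outputHeader(config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Reproduce the full AW-box analysis from the packaged inventory
#'
#' Runs the complete pipeline on the packaged sunflower AW-box records:
#' builds the PFM/PPM/PWM from the bound training set, derives the
#' forbidden-base and bias report and the IUPAC consensus, fits the
#' classifier, classifies all EMSA-tested canonical boxes, and writes the
#' matrices, reports and summary to `outDir`. Deterministic and
#' idempotent: reruns produce byte-identical outputs.
#'
#' @param outDir Output directory (created if needed).
#' @param pseudocount Pseudocount for the PPM/PWM stage.
#' @param background Background base frequencies for the PWM.
#' @param includeThreshold,collapseThreshold Consensus thresholds (see
#'   [iupacConsensus()]).
#' @param maxDistance Distance gate for the classifier profile.
#' @param records Fixture records; defaults to the packaged inventory.
#' @return Invisibly, a list with the fitted objects and the summary.
#' @examples
#' res <- runReproduction(tempfile("awbox-run-"))
#' res$summary$consensus
#' @export
runReproduction <- function(outDir,
                            pseudocount = 0.5,
                            background = rep(0.25, 4),
                            includeThreshold = 0.2,
                            collapseThreshold = 0.6,
                            maxDistance = 500,
                            records = loadAWBoxFixtures()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  config <- list(pseudocount = pseudocount, background = background,
                 includeThreshold = includeThreshold,
                 collapseThreshold = collapseThreshold,
                 maxDistance = maxDistance)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  bound <- stage("training-set", boundSequences(records))
  pfm <- stage("pfm", buildPFM(bound))
  report <- stage("forbidden", forbiddenAndBias(pfm))
  ppmRaw <- stage("ppm", buildPPM(pfm, pseudocount = 0))
  ppm <- stage("ppm", buildPPM(pfm, pseudocount = pseudocount))
  pwm <- stage("pwm", buildPWM(ppm, background))
  consensus <- stage("consensus",
                     iupacConsensus(ppmRaw,
                                    includeThreshold = includeThreshold,
                                    collapseThreshold = collapseThreshold))
  profile <- stage("profile",
                   fitProfile(bound, maxDistance = maxDistance,
                              pseudocount = pseudocount,
                              background = background))
  evalRes <- stage("evaluate", evaluateProfile(profile, records))

  stage("write", {
    .writeWithHeader(as.data.frame(pfm@counts), file.path(outDir, "pfm.tsv"),
                     config)
    .writeWithHeader(as.data.frame(ppm@probs), file.path(outDir, "ppm.tsv"),
                     config)
    .writeWithHeader(as.data.frame(pwm@weights), file.path(outDir, "pwm.tsv"),
                     config)
    forbDf <- data.frame(
      position = names(report@forbidden),
      forbidden = vapply(report@forbidden, paste, "", collapse = ","),
      bias_base = vapply(report@bias, function(b)
        paste(b$base, collapse = ","), ""),
      bias_prob = vapply(report@bias, function(b) b$prob, numeric(1))
    )
    .writeWithHeader(forbDf, file.path(outDir, "forbidden.tsv"), config)
    writeLines(c(.outputHeader(config), consensus),
               file.path(outDir, "consensus.txt"))
    .writeWithHeader(evalRes$table, file.path(outDir, "classification.tsv"),
                     config)
    writeMEME(ppm, file.path(outDir, "awbox.meme"), name = "AWbox-sunflower")
    writeProfileJSON(profile, file.path(outDir, "profile.json"))
  })

  tested <- selectBoxes(records, testedOnly = TRUE, canonicalOnly = TRUE)
  summary <- list(
    n_tested_canonical = nrow(tested),
    n_bound = length(bound),
    genes_two_bound = genesWithBoundBoxes(records, 2),
    consensus = consensus,
    confusion = evalRes$confusion
  )
  jsonlite::write_json(
    list(n_tested_canonical = summary$n_tested_canonical,
         n_bound = summary$n_bound,
         genes_two_bound = summary$genes_two_bound,
         consensus = summary$consensus),
    file.path(outDir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(list(pfm = pfm, ppm = ppm, pwm = pwm, report = report,
                 consensus = consensus, profile = profile,
                 evaluation = evalRes, summary = summary))
}

#' Pipeline stage drivers
#'
#' Thin wrappers over the module operations for file-based runs:
#' `runScan` scans promoters from FASTA + TIS sidecar and writes TSV/BED
#' hits; `runSimulate` writes a simulated promoter set with its truth
#' table; `runClassify` classifies scanner hits with a serialised profile.
#'
#' @param fasta,tisTable Promoter inputs (see [readPromoters()]).
#' @param outDir Output directory.
#' @param maxInsertions,strands Scanner options (see [scanAWBox()]).
#' @return Invisibly, the main result object of the stage.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
runScan <- function(fasta, tisTable, outDir, maxInsertions = 1,
                    strands = "both") {
  if (!file.exists(fasta)) stop("missing input FASTA: ", fasta)
  if (!file.exists(tisTable)) stop("missing TIS sidecar: ", tisTable)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  promoters <- readPromoters(fasta, tisTable)
  hits <- scanAWBox(promoters, strands = strands,
                    maxInsertions = maxInsertions)
  writeHitsTSV(hits, file.path(outDir, "hits.tsv"))
  writeHitsBED(hits, file.path(outDir, "hits.bed"))
  invisible(hits)
}

#' @rdname pipeline-stages
#' @param ... Arguments passed to [simulatePromoters()].
#' @export
runSimulate <- function(outDir, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulatePromoters(...)
  writePromoters(sim$promoters, file.path(outDir, "promoters.fa"),
                 file.path(outDir, "tis.tsv"))
  write.table(sim$truth, file.path(outDir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sim)
}

#' @rdname pipeline-stages
#' @param profileFile JSON profile from [writeProfileJSON()].
#' @param hitsFile Hit TSV from [runScan()] (TIS-relative columns).
#' @export
runClassify <- function(profileFile, hitsFile, outDir) {
  if (!file.exists(profileFile))
    stop("no fitted profile at ", profileFile, "; run fitProfile first")
  if (!file.exists(hitsFile)) stop("missing hits file: ", hitsFile)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  profile <- readProfileJSON(profileFile)
  hits <- read.delim(hitsFile, comment.char = "#",
                     stringsAsFactors = FALSE)
  preds <- lapply(seq_len(nrow(hits)), function(r)
    predictBinding(profile, hits$matched_seq[r],
                   tisStart = hits$tis_start[r]))
  out <- cbind(hits,
               label = vapply(preds, `[[`, "", "label"),
               reasons = vapply(preds, function(p)
                 paste(p$reasons, collapse = "; "), ""))
  write.table(out, file.path(outDir, "classified.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out)
}
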