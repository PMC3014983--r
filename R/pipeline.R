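## End-to-end orchestration: simulate (or load) -> graph -> variants ->
## sex -> homology, with a run report and ground-truth recovery scoring.

#' Pipeline configuration
#'
#' Collects every stage threshold (defaulted to the package's standard
#' values), the input source (a directory of input files, or a
#' simulation parameter block) and the seed. `dupIdLow < alleleId` is
#' enforced, as are positive cut-offs.
#'
#' @param inputDir directory with input files (`contigs.fasta`,
#'   `read_status.tsv`, `variants.tsv`, `blast.tsv`, optionally
#'   `singletons.fasta`, `orfs.bed`, `go_map.tsv`); `NULL` to simulate.
#' @param sim a [simParams()] block used when `inputDir` is `NULL`.
#' @param alleleId,dupIdLow,minOverlap,minEdgeSupport graph-stage
#'   settings.
#' @param minCov,maxCov,minProb,homopolymerLen,percentile,orfMinLen
#'   variant-stage settings.
#' @param strictCutoff,screenCutoff sex-calling e-value ladder.
#' @param blastDb database used for component summaries, sex calls and
#'   chimera detection.
#' @param chimeraEvalue,chimeraOverlapFrac,chimeraWhitelist chimera
#'   settings.
#' @param mapIdentity,mapUnaligned singleton-rescue settings.
#' @param cutoffs e-value ladder for unique-homologue counting.
#' @param seed integer; overrides `sim$seed` so one value drives the
#'   whole run.
#' @return a validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(inputDir = NULL, sim = simParams(),
                           alleleId = 0.95, dupIdLow = 0.80,
                           minOverlap = 40, minEdgeSupport = 1,
                           minCov = 5, maxCov = 100, minProb = 0.9,
                           homopolymerLen = 3, percentile = 0.99,
                           orfMinLen = 30, strictCutoff = 1e-50,
                           screenCutoff = 1e-5, blastDb = "NR",
                           chimeraEvalue = 1e-20,
                           chimeraOverlapFrac = 0.2,
                           chimeraWhitelist = NULL, mapIdentity = 95,
                           mapUnaligned = 10,
                           cutoffs = c(1e-5, 1e-10, 1e-20, 1e-50),
                           seed = 1) {
  cfg <- as.list(environment())
  if (cfg$dupIdLow >= cfg$alleleId)
    stop("config error: dupIdLow must be below alleleId")
  if (any(c(cfg$strictCutoff, cfg$screenCutoff, cfg$cutoffs,
            cfg$chimeraEvalue) <= 0))
    stop("config error: e-value cut-offs must be positive")
  if (cfg$minCov > cfg$maxCov)
    stop("config error: minCov must not exceed maxCov")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipelineConfig"
  cfg
}

.load_inputs <- function(dir) {
  need <- c("contigs.fasta", "read_status.tsv", "variants.tsv", "blast.tsv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing input file: ", file.path(dir, f))
  opt <- function(f, reader, default)
    if (file.exists(file.path(dir, f))) reader(file.path(dir, f)) else default
  list(contigs = readFasta(file.path(dir, "contigs.fasta")),
       singletons = opt("singletons.fasta", readFasta,
                        Biostrings::DNAStringSet()),
       readStatus = readReadStatus(file.path(dir, "read_status.tsv")),
       variants = readTabular(file.path(dir, "variants.tsv"), "variant"),
       hits = readTabular(file.path(dir, "blast.tsv"), "blast"),
       orfs = opt("orfs.bed", function(f) readTabular(f, "orf"), NULL),
       goMap = opt("go_map.tsv", function(f) readTabular(f, "go"), NULL),
       truth = NULL)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order -- simulate (or load inputs),
#' split-read graph clustering and component calling, variant filtering
#' and selection screens, sex classification and sex-specific gene
#' calling with GO enrichment, homology clustering / chimera detection /
#' singleton rescue -- writes every output table under `outDir` (when
#' given) and returns a run report. Deterministic for a fixed
#' configuration: the serialized `report.json` is byte-identical across
#' repeated runs with the same seed (wall-clock timings are reported only
#' in the text log).
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory; when `NULL` nothing is
#'   written.
#' @return a list of class `runReport`; its `results` attribute carries
#'   the full stage objects (graph analysis, summaries, calls, recovery).
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    val <- force(expr)
    timings[[name]] <<- round(tic() - t0, 2)
    val
  }

  inputs <- stage("inputs", {
    if (is.null(config$inputDir)) {
      sp <- config$sim
      sp$seed <- config$seed
      study <- simulateStudy(sp)
      list(contigs = studyContigs(study),
           singletons = studySingletons(study),
           readStatus = studyReadStatus(study),
           variants = studyVariants(study), hits = studyBlastHits(study),
           orfs = studyOrfs(study), goMap = studyGoMap(study),
           truth = groundTruth(study), study = study)
    } else .load_inputs(config$inputDir)
  })

  graph <- stage("graph", analyzeGraphClusters(
    inputs$readStatus, inputs$contigs, inputs$hits,
    minEdgeSupport = config$minEdgeSupport, alleleId = config$alleleId,
    dupIdLow = config$dupIdLow, minOverlap = config$minOverlap,
    blastDb = config$blastDb, blastCutoff = config$screenCutoff))

  varres <- stage("variants", {
    filtered <- filterVariants(inputs$variants, inputs$contigs,
                               config$minCov, config$maxCov,
                               config$minProb, config$homopolymerLen)
    orfs <- if (is.null(inputs$orfs))
      findLongestOrfs(inputs$contigs, config$orfMinLen) else inputs$orfs
    summaries <- summarizeContigs(inputs$contigs, filtered, orfs)
    summaries <- tryCatch(flagHighlyVariable(summaries, config$percentile),
                          error = function(e) summaries)
    reg <- tryCatch(regressVariantsOnLength(summaries),
                    error = function(e) NULL)
    cand <- tryCatch(selectionCandidates(summaries),
                     error = function(e) character())
    list(filtered = filtered, orfs = orfs, summaries = summaries,
         regression = reg, candidates = cand)
  })

  sexres <- stage("sex", {
    classes <- classifySequences(inputs$readStatus)
    hits_db <- inputs$hits[inputs$hits$db_name == config$blastDb, ,
                           drop = FALSE]
    calls <- callSexSpecific(hits_db, classes, config$strictCutoff,
                             config$screenCutoff)
    enr <- NULL
    if (!is.null(inputs$goMap)) {
      fs <- calls[calls$call == "female_specific", , drop = FALSE]
      ms <- calls[calls$call == "male_specific", , drop = FALSE]
      fseq <- unlist(strsplit(c(fs$female_seqs, fs$both_seqs), ","))
      mseq <- unlist(strsplit(c(ms$male_seqs, ms$both_seqs), ","))
      enr <- tryCatch(
        goEnrichment(fseq[nzchar(fseq)], mseq[nzchar(mseq)], inputs$goMap),
        error = function(e) NULL)
    }
    list(classes = classes, calls = calls, enrichment = enr)
  })

  homres <- stage("homology", {
    hclust <- clusterByHomolog(inputs$hits, config$blastDb, 1e-20)
    ucounts <- uniqueHomologCounts(inputs$hits, config$cutoffs)
    venn <- presenceVenn(inputs$hits, cutoff = config$screenCutoff)
    qlen <- stats::setNames(
      c(Biostrings::width(inputs$contigs),
        Biostrings::width(inputs$singletons)),
      c(names(inputs$contigs), names(inputs$singletons)))
    chim <- detectChimeras(inputs$hits, qlen, config$blastDb,
                           config$chimeraEvalue, config$chimeraOverlapFrac,
                           config$chimeraWhitelist)
    rescued <- if (length(inputs$singletons))
      mapSingletons(inputs$singletons, inputs$contigs, config$mapIdentity,
                    config$mapUnaligned)
    else data.frame(read_id = character(), contig_id = character())
    list(clusters = hclust, uniqueCounts = ucounts, venn = venn,
         chimeras = chim, rescued = rescued)
  })

  recovery <- if (!is.null(inputs$truth))
    stage("recovery", evaluateRecovery(
      list(graph = graph, variants = varres, sex = sexres,
           homology = homres, config = config), inputs$truth))
  else NULL

  report <- .build_report(config, inputs, graph, varres, sexres, homres,
                          recovery)
  attr(report, "timings") <- timings
  attr(report, "results") <- list(inputs = inputs, graph = graph,
                                  variants = varres, sex = sexres,
                                  homology = homres, recovery = recovery)
  class(report) <- "runReport"
  if (!is.null(outDir)) writeRunOutputs(report, outDir)
  report
}

.build_report <- function(config, inputs, graph, varres, sexres, homres,
                          recovery) {
  rs <- inputs$readStatus
  st <- table(factor(rs$status, levels = .STATUSES))
  comp <- graph$components
  summaries <- varres$summaries
  has_var <- summaries$n_snp + summaries$n_indel >= 1
  cls <- table(factor(sexres$classes$contigs$class,
                      levels = c("FC", "MC", "BC")))
  calls <- table(factor(sexres$calls$call,
                        levels = c("female_specific", "male_specific",
                                   "shared", "insufficient")))
  cluster_sizes <- table(graph$clusters$cluster_id)
  echo <- unclass(config)
  echo$sim <- unclass(echo$sim)
  report <- list(
    reads = list(total = nrow(rs), assembled = as.integer(st[["assembled"]]),
                 partially_assembled =
                   as.integer(st[["partially_assembled"]]),
                 singleton = as.integer(st[["singleton"]]),
                 discarded = as.integer(st[["discarded"]])),
    contigs = list(total = length(inputs$contigs),
                   in_graph = length(graphNodes(graph$graph))),
    graph = list(
      n_edges = nrow(graphEdges(graph$graph)),
      n_clusters = length(cluster_sizes),
      mean_cluster_size = if (length(cluster_sizes))
        round(mean(cluster_sizes), 3) else NA,
      max_cluster_size = if (length(cluster_sizes))
        max(cluster_sizes) else NA,
      components = as.list(table(factor(comp$ctype, levels = c(
        "merged_alleles", "duplicate_pair", "alt_splice", "unresolved"))))),
    variants = list(
      called = nrow(inputs$variants), pass_filter = nrow(varres$filtered),
      n_snp = sum(summaries$n_snp), n_indel = sum(summaries$n_indel),
      ts_total = sum(summaries$ts), tv_total = sum(summaries$tv),
      pooled_tstv = if (sum(summaries$tv))
        round(sum(summaries$ts) / sum(summaries$tv), 4) else NA,
      ka_total = sum(summaries$ka, na.rm = TRUE),
      ks_total = sum(summaries$ks, na.rm = TRUE),
      contigs_with_variants = sum(has_var),
      highly_variable = sum(summaries$highly_variable, na.rm = TRUE),
      candidates = length(varres$candidates),
      regression = if (!is.null(varres$regression))
        lapply(varres$regression, function(x)
          if (is.numeric(x)) signif(x, 6) else x)
      else NULL),
    sex = list(FC = as.integer(cls[["FC"]]), MC = as.integer(cls[["MC"]]),
               BC = as.integer(cls[["BC"]]),
               female_specific = as.integer(calls[["female_specific"]]),
               male_specific = as.integer(calls[["male_specific"]]),
               shared = as.integer(calls[["shared"]]),
               insufficient = as.integer(calls[["insufficient"]]),
               top_enriched_term = if (!is.null(sexres$enrichment) &&
                                       nrow(sexres$enrichment))
                 sexres$enrichment$term_id[1] else NA),
    homology = list(
      clusters_1e20 = nrow(homres$clusters$clusters),
      multi_membership = nrow(homres$clusters$multiMembership),
      unique_counts = homres$uniqueCounts,
      venn_regions = homres$venn$regions,
      chimeras = nrow(homres$chimeras),
      rescued_singletons = nrow(homres$rescued)),
    recovery = recovery,
    config = echo)
  report
}

#' Score pipeline outputs against the ground truth
#'
#' Compares a pipeline run on simulated data with the simulation ledger:
#' per-type precision/recall of component calls (a truth component is
#' recovered when a call with the same ctype carries exactly its member
#' set), the sex-call confusion matrix and precision/recall of
#' sex-specific calls, chimera precision/recall, and the variant-filter
#' confusion (true vs injected calls retained/removed).
#'
#' @param results a list with stage objects (`graph`, `variants`, `sex`,
#'   `homology`, `config`) as assembled by [runPipeline()].
#' @param truth the ground-truth ledger of a [SimulatedAssembly-class].
#' @return a list of recovery metrics.
#' @export
evaluateRecovery <- function(results, truth) {
  if (is.null(truth) || !nrow(truth$genes)) stop("empty ground truth")
  comp <- results$graph$components
  tcomp <- truth$components
  canon <- function(x) vapply(strsplit(x, ",", fixed = TRUE),
                              function(v) paste(sort(v), collapse = ","),
                              "")
  known <- unique(unlist(strsplit(truth$contigs$contig_id, ",")))
  called_in <- unique(unlist(strsplit(comp$members, ",")))
  if (length(setdiff(called_in, known)))
    stop("component calls reference contigs absent from the ledger")
  comp_key <- paste(comp$ctype, canon(comp$members))
  truth_key <- paste(tcomp$ctype, canon(tcomp$members))
  recovered <- truth_key %in% comp_key
  by_type <- lapply(split(recovered, tcomp$ctype), function(x)
    list(n = length(x), recovered = sum(x), recall = mean(x)))
  precision_by_type <- lapply(
    split(comp_key %in% truth_key, comp$ctype),
    function(x) list(n_calls = length(x), matching = sum(x),
                     precision = mean(x)))
  component_accuracy <- if (nrow(tcomp)) mean(recovered) else NA

  ## sex calls, on the component database's accessions
  cfg <- results$config
  db <- if (!is.null(cfg)) cfg$blastDb else "NR"
  calls <- results$sex$calls
  genes <- truth$genes
  genes <- genes[!is.na(genes$homolog), , drop = FALSE]
  subj <- paste0(db, "_", genes$homolog,
                 ifelse(genes$category == "duplicate_pair", "a", ""))
  expected <- c(none = "not_specific", female_only = "female_specific",
                male_only = "male_specific")[genes$sex_bias]
  got <- calls$call[match(subj, calls$subject_id)]
  got[is.na(got)] <- "no_call"
  got_simple <- ifelse(got %in% c("female_specific", "male_specific"),
                       got, "not_specific")
  confusion <- table(expected = expected, called = got_simple)
  tp <- sum(expected == got_simple & expected != "not_specific")
  fp <- sum(got_simple != "not_specific" & expected != got_simple)
  fn <- sum(expected != "not_specific" & got_simple != expected)
  sex_metrics <- list(
    confusion = as.data.frame(confusion),
    true_specific = sum(expected != "not_specific"),
    called_specific = sum(got_simple != "not_specific"),
    false_specific = fp,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA)

  chim_called <- results$homology$chimeras$seq_id
  chim_true <- truth$chimeras$contig_id
  ## a planted chimera is detectable only if both source genes have a
  ## homologue to hit
  has_hom <- !is.na(truth$genes$homolog[
    match(truth$chimeras$gene_a, truth$genes$gene_id)]) &
    !is.na(truth$genes$homolog[
      match(truth$chimeras$gene_b, truth$genes$gene_id)])
  chim_det <- chim_true[has_hom]
  chimera_metrics <- list(
    planted = length(chim_true), detectable = length(chim_det),
    recalled = sum(chim_true %in% chim_called),
    recall = if (length(chim_true)) mean(chim_true %in% chim_called)
      else NA,
    recall_detectable = if (length(chim_det))
      mean(chim_det %in% chim_called) else NA,
    false_positives = length(setdiff(chim_called, chim_true)))

  filt <- results$variants$filtered
  tv <- truth$variants
  key <- function(d) paste(d$contig_id, d$position, d$var_type)
  kept <- key(tv) %in% key(filt)
  variant_metrics <- list(
    true_total = sum(tv$is_true), false_total = sum(!tv$is_true),
    true_retained = sum(kept & tv$is_true),
    false_retained = sum(kept & !tv$is_true),
    true_removed = sum(!kept & tv$is_true),
    false_removed = sum(!kept & !tv$is_true))

  list(component_accuracy = component_accuracy,
       component_recall_by_type = by_type,
       component_precision_by_type = precision_by_type,
       sex = sex_metrics, chimeras = chimera_metrics,
       variant_filter = variant_metrics)
}

#' Write pipeline outputs and the run report
#'
#' Writes every stage table (`clusters.tsv`, `components.tsv`,
#' `merged_consensus.fasta`, `variant_summary.tsv`, `candidates.tsv`,
#' `sex_classes.tsv`, `sex_specific_genes.tsv`, `enrichment.tsv`,
#' `homolog_clusters.tsv`, `unique_counts.tsv`, `venn_regions.tsv`,
#' `chimeras.tsv`, `singleton_map.tsv`), the deterministic
#' `report.json`, and a human-readable `report.txt` that also carries
#' per-stage wall-clock times.
#'
#' @param report a `runReport` from [runPipeline()].
#' @param dir output directory.
#' @export
writeRunOutputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- attr(report, "results")
  wt <- function(df, f)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$graph$clusters, "clusters.tsv")
  wt(res$graph$components, "components.tsv")
  if (length(res$graph$consensus))
    writeFasta(res$graph$consensus, file.path(dir,
                                              "merged_consensus.fasta"))
  wt(res$variants$summaries, "variant_summary.tsv")
  wt(data.frame(contig_id = res$variants$candidates), "candidates.tsv")
  wt(res$sex$classes$contigs, "sex_classes.tsv")
  wt(res$sex$calls, "sex_specific_genes.tsv")
  if (!is.null(res$sex$enrichment)) wt(res$sex$enrichment,
                                       "enrichment.tsv")
  wt(res$homology$clusters$clusters, "homolog_clusters.tsv")
  wt(res$homology$uniqueCounts, "unique_counts.tsv")
  wt(res$homology$venn$regions, "venn_regions.tsv")
  wt(res$homology$chimeras, "chimeras.tsv")
  wt(res$homology$rescued, "singleton_map.tsv")
  rep_clean <- unclass(report)
  attr(rep_clean, "timings") <- NULL
  attr(rep_clean, "results") <- NULL
  jsonlite::write_json(rep_clean, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  tm <- attr(report, "timings")
  writeLines(c("", "wall-clock (s) per stage:",
               paste0("  ", names(tm), ": ", unlist(tm))), con)
  invisible(dir)
}

#' @export
print.runReport <- function(x, ...) {
  cat("== pipeline run report ==\n")
  cat("reads:", x$reads$total,
      sprintf("(assembled %d, split %d, singleton %d, discarded %d)\n",
              x$reads$assembled, x$reads$partially_assembled,
              x$reads$singleton, x$reads$discarded))
  cat("contigs:", x$contigs$total, "| in graph:", x$contigs$in_graph, "\n")
  cat("graph-clusters:", x$graph$n_clusters, "| mean size",
      x$graph$mean_cluster_size, "| components:",
      paste(names(x$graph$components), unlist(x$graph$components),
            sep = "=", collapse = ", "), "\n")
  cat("variants:", x$variants$called, "called,", x$variants$pass_filter,
      "pass filter | TS", x$variants$ts_total, "TV", x$variants$tv_total,
      "| Ka", x$variants$ka_total, "Ks", x$variants$ks_total, "\n")
  cat("sex classes: FC", x$sex$FC, "MC", x$sex$MC, "BC", x$sex$BC,
      "| sex-specific genes:", x$sex$female_specific, "F /",
      x$sex$male_specific, "M\n")
  cat("homology clusters (1e-20):", x$homology$clusters_1e20,
      "| chimeras:", x$homology$chimeras, "| rescued singletons:",
      x$homology$rescued_singletons, "\n")
  if (!is.null(x$recovery)) {
    cat("recovery: component accuracy",
        round(x$recovery$component_accuracy, 4), "| sex P/R",
        round(x$recovery$sex$precision, 4),
        round(x$recovery$sex$recall, 4), "| chimera recall",
        round(x$recovery$chimeras$recall, 4), "\n")
  }
  invisible(x)
}
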