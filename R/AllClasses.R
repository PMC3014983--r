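#' Split-read contig graph
#'
#' Contigs are nodes; an edge joins two contigs whenever at least one read
#' was split between them during assembly, weighted by the number of such
#' supporting split reads. Nodes with no surviving edge are excluded, so
#' every node participates in at least one edge.
#'
#' @slot edges a `data.frame` with columns `a`, `b` (contig ids of the
#'   unordered pair, with `a < b` lexicographically) and integer `weight`
#'   (number of supporting split reads).
#'
#' @seealso [buildGraph()], [findClusters()]
#' @export
setClass("ContigGraph", representation(edges = "data.frame"))

setValidity("ContigGraph", function(object) {
  e <- object@edges
  msgs <- character()
  if (!all(c("a", "b", "weight") %in% names(e)))
    msgs <- c(msgs, "edges must have columns a, b, weight")
  else {
    if (any(e$a == e$b)) msgs <- c(msgs, "self-loops are not allowed")
    if (any(e$a > e$b)) msgs <- c(msgs, "edge pairs must be ordered a < b")
    if (anyDuplicated(paste(e$a, e$b))) msgs <- c(msgs, "duplicate edges")
    if (any(e$weight < 1)) msgs <- c(msgs, "edge weights must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ContigGraph the contig ids participating in at least one edge
#' @param x,object a `ContigGraph`
#' @export
graphNodes <- function(x) {
  stopifnot(is(x, "ContigGraph"))
  sort(unique(c(x@edges$a, x@edges$b)))
}

#' @describeIn ContigGraph the edge table (`a`, `b`, `weight`)
#' @export
graphEdges <- function(x) {
  stopifnot(is(x, "ContigGraph"))
  x@edges
}

setMethod("show", "ContigGraph", function(object) {
  cat("ContigGraph with", length(graphNodes(object)), "contigs and",
      nrow(object@edges), "split-read edges\n")
  if (nrow(object@edges)) {
    cat("  total split-read support:", sum(object@edges$weight), "\n")
  }
})

#' Simulated study: emulated assembler outputs plus ground truth
#'
#' The bundle produced by [simulateStudy()]: every on-disk artifact the
#' pipeline consumes (contigs, singletons, read-status records, variant
#' calls, homology hits, ORFs, GO map) together with the ground-truth
#' ledger that maps each emitted contig, read and variant back to its
#' generating gene.
#'
#' @slot contigs,singletons `Biostrings::DNAStringSet`
#' @slot readStatus,variants,blastHits,orfs,goMap `data.frame`s in the
#'   package's tabular layouts (see [readReadStatus()], [readTabular()]).
#' @slot truth a named list of ground-truth tables (`genes`, `contigs`,
#'   `reads`, `variants`, `components`, `chimeras`).
#' @slot params the [simParams()] list used to generate the study.
#'
#' @seealso [simulateStudy()], [writeStudy()], [evaluateRecovery()]
#' @export
setClass("SimulatedAssembly", representation(
  contigs = "DNAStringSet", singletons = "DNAStringSet",
  readStatus = "data.frame", variants = "data.frame",
  blastHits = "data.frame", orfs = "data.frame", goMap = "data.frame",
  truth = "list", params = "list"))

setValidity("SimulatedAssembly", function(object) {
  msgs <- character()
  tr <- object@truth
  need <- c("genes", "contigs", "reads", "variants")
  if (!all(need %in% names(tr)))
    msgs <- c(msgs, paste("truth must contain:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(tr$contigs$contig_id))
      msgs <- c(msgs, "ledger lists a contig more than once")
    if (anyDuplicated(tr$reads$read_id))
      msgs <- c(msgs, "ledger lists a read more than once")
    if (!setequal(names(object@contigs), tr$contigs$contig_id))
      msgs <- c(msgs, "contig set and ledger disagree")
    if (nrow(object@readStatus) != nrow(tr$reads))
      msgs <- c(msgs, "read-status rows and ledger reads disagree")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SimulatedAssembly accessor for the contig sequences
#' @param x,object a `SimulatedAssembly`
#' @export
studyContigs <- function(x) { stopifnot(is(x, "SimulatedAssembly")); x@contigs }

#' @describeIn SimulatedAssembly accessor for the singleton sequences
#' @export
studySingletons <- function(x) { stopifnot(is(x, "SimulatedAssembly")); x@singletons }

#' @describeIn SimulatedAssembly accessor for the read-status table
#' @export
studyReadStatus <- function(x) { stopifnot(is(x, "SimulatedAssembly")); x@readStatus }

#' @describeIn SimulatedAssembly accessor for the variant table
#' @export
studyVariants <- function(x) { stopifnot(is(x, "SimulatedAssembly")); x@variants }

#' @describeIn SimulatedAssembly accessor for the homology hit table
#' @export
studyBlastHits <- function(x) { stopifnot(is(x, "SimulatedAssembly")); x@blastHits }

#' @describeIn SimulatedAssembly accessor for the ORF table
#' @export
studyOrfs <- function(x) { stopifnot(is(x, "SimulatedAssembly")); x@orfs }

#' @describeIn SimulatedAssembly accessor for the GO annotation map
#' @export
studyGoMap <- function(x) { stopifnot(is(x, "SimulatedAssembly")); x@goMap }

#' @describeIn SimulatedAssembly accessor for the ground-truth ledger
#' @export
groundTruth <- function(x) { stopifnot(is(x, "SimulatedAssembly")); x@truth }

setMethod("show", "SimulatedAssembly", function(object) {
  st <- table(object@readStatus$status)
  cat("SimulatedAssembly\n")
  cat("  genes:     ", nrow(object@truth$genes), " (",
      paste(names(table(object@truth$genes$category)),
            table(object@truth$genes$category), sep = "=", collapse = ", "),
      ")\n", sep = "")
  cat("  contigs:   ", length(object@contigs), "\n", sep = "")
  cat("  reads:     ", nrow(object@readStatus), " (",
      paste(names(st), as.integer(st), sep = "=", collapse = ", "),
      ")\n", sep = "")
  cat("  variants:  ", nrow(object@variants), "\n", sep = "")
  cat("  blast hits:", nrow(object@blastHits), "\n")
})
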