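## Split-read contig graph: construction, connected components
## ("graph-clusters"), similarity labelling of within-cluster contig
## pairs, allele contraction and component typing.
##
## Similarity relations (allele / duplicate) are evaluated over *all*
## unordered contig pairs within a graph-cluster, not only pairs joined by
## a split read: two divergent allele contigs both link to their shared
## contig by split reads but are themselves connected only through
## sequence homology, so the allele band must be tested on the pair
## directly. Split-read edges whose endpoints fall in no similarity band
## are splice edges (exon-to-exon connections).

#' Build the split-read contig graph
#'
#' Every read with two placements contributes one unit of support to the
#' unordered pair of contigs it was split between. Pairs with support
#' below `minEdgeSupport` are dropped, and contigs left without any
#' surviving edge are excluded from the graph.
#'
#' @param readStatus read-status data.frame ([readReadStatus()]).
#' @param minEdgeSupport minimum number of supporting split reads per
#'   edge (default 1; one split read is weak evidence under noise, so
#'   this is configurable).
#' @return a [ContigGraph-class] object.
#' @export
buildGraph <- function(readStatus, minEdgeSupport = 1) {
  split <- readStatus[readStatus$n_placements == 2, , drop = FALSE]
  if (!nrow(split)) {
    return(new("ContigGraph", edges = data.frame(
      a = character(), b = character(), weight = integer(),
      stringsAsFactors = FALSE)))
  }
  a <- pmin(split$contig1, split$contig2)
  b <- pmax(split$contig1, split$contig2)
  key <- paste(a, b, sep = "\r")
  tab <- table(key)
  keep <- tab >= minEdgeSupport
  parts <- strsplit(names(tab)[keep], "\r", fixed = TRUE)
  edges <- data.frame(
    a = vapply(parts, `[`, "", 1), b = vapply(parts, `[`, "", 2),
    weight = as.integer(tab[keep]), stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  new("ContigGraph", edges = edges)
}

#' Find graph-clusters (connected components)
#'
#' Connected components of the split-read contig graph. Clusters are
#' sorted by decreasing member count, ties broken by the
#' lexicographically smallest member, and assigned ids `GC00001`,
#' `GC00002`, ... Members partition the set of non-isolated contigs.
#'
#' @param graph a [ContigGraph-class].
#' @return a data.frame with columns `cluster_id`, `contig_id`.
#' @export
findClusters <- function(graph) {
  edges <- graphEdges(graph)
  if (!nrow(edges)) {
    return(data.frame(cluster_id = character(), contig_id = character(),
                      stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  ord <- order(-lengths(members), vapply(members, `[`, "", 1))
  members <- members[ord]
  data.frame(
    cluster_id = rep(sprintf("GC%05d", seq_along(members)),
                     lengths(members)),
    contig_id = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Label a contig pair from its overlap identity
#'
#' The similarity bands that separate the three relationships a
#' within-cluster contig pair can have: identity of at least `alleleId`
#' (default 0.95) means divergent alleles of one gene; identity in
#' `[dupIdLow, alleleId)` (default `[0.80, 0.95)`) means the diverged
#' regions of a duplicated gene pair; anything lower -- including an
#' undefined identity from insufficient overlap -- is a splice
#' relationship (distinct exons of one gene). Both boundaries are closed
#' on the left.
#'
#' @param identity identity fraction or `NA` (see [overlapIdentity()]).
#' @param alleleId,dupIdLow band boundaries.
#' @return `"allele"`, `"duplicate"` or `"splice"` (vectorised).
#' @export
labelEdge <- function(identity, alleleId = 0.95, dupIdLow = 0.80) {
  out <- rep("splice", length(identity))
  out[!is.na(identity) & identity >= dupIdLow] <- "duplicate"
  out[!is.na(identity) & identity >= alleleId] <- "allele"
  out
}

## all unordered pairs within each cluster, labelled; split-read edges
## keep their weight, similarity-only pairs carry weight NA and are
## retained only when they fall in the allele or duplicate band
.label_cluster_pairs <- function(clusters, edges, seqs, alleleId, dupIdLow,
                                 minOverlap) {
  edge_key <- paste(edges$a, edges$b, sep = "\r")
  res <- lapply(split(clusters$contig_id, clusters$cluster_id), function(mem) {
    mem <- sort(mem)
    if (length(mem) < 2) return(NULL)
    pairs <- utils::combn(mem, 2)
    a <- pairs[1, ]; b <- pairs[2, ]
    key <- paste(a, b, sep = "\r")
    w <- edges$weight[match(key, edge_key)]
    ident <- vapply(seq_along(a), function(i) {
      overlapIdentity(seqs[[a[i]]], seqs[[b[i]]], minOverlap)
    }, numeric(1))
    lab <- labelEdge(ident, alleleId, dupIdLow)
    keep <- !is.na(w) | lab != "splice"
    data.frame(a = a[keep], b = b[keep], weight = w[keep],
               split_edge = !is.na(w[keep]), identity = ident[keep],
               label = lab[keep], stringsAsFactors = FALSE)
  })
  nonnull <- !vapply(res, is.null, logical(1))
  out <- do.call(rbind, c(res[nonnull], list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(a = character(), b = character(), weight = integer(),
                      split_edge = logical(), identity = numeric(),
                      label = character(), stringsAsFactors = FALSE)
    out$cluster_id <- character()
    return(out)
  }
  out$cluster_id <- rep(names(res)[nonnull],
                        vapply(res[nonnull], nrow, integer(1)))
  out
}

#' Label all contig pairs within each graph-cluster
#'
#' Computes [overlapIdentity()] for every unordered pair of contigs that
#' share a graph-cluster and applies [labelEdge()]. Pairs joined by a
#' split-read edge are always reported (with their edge weight); pairs
#' related only by sequence similarity are reported when they fall in the
#' allele or duplicate band.
#'
#' @param graph a [ContigGraph-class].
#' @param clusters cluster membership from [findClusters()].
#' @param seqs named `DNAStringSet` (or character) of contig sequences.
#' @param alleleId,dupIdLow,minOverlap see [labelEdge()],
#'   [overlapIdentity()].
#' @return a data.frame with columns `cluster_id`, `a`, `b`, `weight`
#'   (`NA` for similarity-only pairs), `split_edge`, `identity`, `label`.
#' @export
labelClusterPairs <- function(graph, clusters, seqs, alleleId = 0.95,
                              dupIdLow = 0.80, minOverlap = 40) {
  .label_cluster_pairs(clusters, graphEdges(graph), .seq_chr(seqs),
                       alleleId, dupIdLow, minOverlap)
}

## union-find over allele-labelled pairs
.allele_groups <- function(nodes, pairLabels) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  ap <- pairLabels[pairLabels$label == "allele", , drop = FALSE]
  for (i in seq_len(nrow(ap))) {
    ra <- find(ap$a[i]); rb <- find(ap$b[i])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  vapply(nodes, find, character(1))
}

#' Contract allele-labelled relations into merged super-nodes
#'
#' Within each graph-cluster, every connected subgraph of allele-labelled
#' pairs is contracted into one super-node whose sequence is the
#' [alleleConsensus()] of its members (disagreement columns become IUPAC
#' ambiguity codes). Labelling and contraction are iterated with the
#' consensus sequences until no allele-band pair remains, so chains of
#' divergent alleles collapse fully. Split-read edges from merged members
#' re-attach to the super-node with weights summed. Each contraction of
#' two or more contigs yields one `merged_alleles` component.
#'
#' @inheritParams labelClusterPairs
#' @param maxIter safety cap on label/contract rounds.
#' @return a list:
#'   \describe{
#'     \item{nodeMap}{data.frame `cluster_id`, `contig_id`, `node_id`
#'       mapping original contigs to post-contraction nodes.}
#'     \item{nodeSeqs}{named character vector of node sequences (consensus
#'       for super-nodes).}
#'     \item{edges}{contracted split-read edge table with recomputed
#'       identity and label columns.}
#'     \item{components}{`merged_alleles` component calls (`component_id`,
#'       `cluster_id`, `ctype`, `members`, `n_members`, `identity`).}
#'     \item{consensus}{`DNAStringSet` of merged consensus sequences named
#'       by `component_id`.}
#'   }
#' @export
mergeAlleles <- function(graph, clusters, seqs, alleleId = 0.95,
                         dupIdLow = 0.80, minOverlap = 40, maxIter = 10) {
  seqs <- .seq_chr(seqs)
  edges <- graphEdges(graph)
  node_of <- stats::setNames(clusters$contig_id, clusters$contig_id)
  node_seqs <- seqs[unique(clusters$contig_id)]
  node_cluster <- stats::setNames(clusters$cluster_id, clusters$contig_id)
  merge_counter <- 0L

  for (iter in seq_len(maxIter)) {
    ncl <- data.frame(cluster_id = node_cluster[names(node_seqs)],
                      contig_id = names(node_seqs),
                      stringsAsFactors = FALSE)
    pl <- .label_cluster_pairs(ncl, .contract_edges(edges, node_of),
                               node_seqs, alleleId, dupIdLow, minOverlap)
    if (!any(pl$label == "allele")) break
    groups <- .allele_groups(names(node_seqs), pl)
    changed <- names(groups)[groups != names(groups)]
    roots <- unique(groups[changed])
    for (r in roots) {
      mem <- names(groups)[groups == r]
      merge_counter <- merge_counter + 1L
      super <- sprintf("MRG%05d", merge_counter)
      cons <- alleleConsensus(stats::setNames(node_seqs[mem], mem))
      node_seqs <- node_seqs[setdiff(names(node_seqs), mem)]
      node_seqs[super] <- cons
      node_cluster[super] <- node_cluster[[r]]
      node_of[node_of %in% mem] <- super
    }
  }

  node_map <- data.frame(cluster_id = unname(node_cluster[clusters$contig_id]),
                         contig_id = clusters$contig_id,
                         node_id = unname(node_of[clusters$contig_id]),
                         stringsAsFactors = FALSE)
  super <- grep("^MRG", unique(node_map$node_id), value = TRUE)
  comps <- lapply(sort(super), function(s) {
    mem <- sort(node_map$contig_id[node_map$node_id == s])
    idents <- utils::combn(mem, 2)
    mid <- mean(vapply(seq_len(ncol(idents)), function(i) {
      v <- overlapIdentity(seqs[[idents[1, i]]], seqs[[idents[2, i]]],
                           minOverlap)
      if (is.na(v)) 0 else v
    }, numeric(1)))
    data.frame(component_id = sub("^MRG", "CMP", s),
               cluster_id = node_map$cluster_id[node_map$node_id == s][1],
               ctype = "merged_alleles",
               members = paste(mem, collapse = ","),
               n_members = length(mem), identity = mid,
               stringsAsFactors = FALSE)
  })
  components <- if (length(comps)) {
    do.call(rbind, c(comps, list(make.row.names = FALSE)))
  } else {
    data.frame(component_id = character(), cluster_id = character(),
               ctype = character(), members = character(),
               n_members = integer(), identity = numeric(),
               stringsAsFactors = FALSE)
  }
  consensus <- Biostrings::DNAStringSet(stats::setNames(
    unname(node_seqs[sub("^CMP", "MRG", components$component_id)]),
    components$component_id))

  cedges <- .contract_edges(edges, node_of)
  ncl <- data.frame(cluster_id = node_cluster[names(node_seqs)],
                    contig_id = names(node_seqs), stringsAsFactors = FALSE)
  pl <- .label_cluster_pairs(ncl, cedges, node_seqs, alleleId, dupIdLow,
                             minOverlap)
  list(nodeMap = node_map, nodeSeqs = node_seqs, edges = pl,
       components = components, consensus = consensus)
}

## re-attach split-read edges to (super-)nodes: endpoints mapped, self
## loops dropped, parallel edges summed
.contract_edges <- function(edges, node_of) {
  if (!nrow(edges)) return(edges)
  a <- unname(node_of[edges$a]); b <- unname(node_of[edges$b])
  a[is.na(a)] <- edges$a[is.na(a)]
  b[is.na(b)] <- edges$b[is.na(b)]
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  w <- edges$weight[keep]
  key <- paste(a2, b2, sep = "\r")
  agg <- rowsum(w, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(a = vapply(parts, `[`, "", 1),
                    b = vapply(parts, `[`, "", 2),
                    weight = as.integer(agg[, 1]), stringsAsFactors = FALSE)
  out[order(out$a, out$b), , drop = FALSE]
}

#' Call duplicate-pair and alternative-splicing components
#'
#' After allele contraction, every duplicate-labelled pair yields one
#' `duplicate_pair` component (its two nodes). Setting those pairs aside,
#' each residual connected subgraph of two or more nodes joined by
#' splice-labelled split-read edges yields one `alt_splice` component. A
#' node may participate in both structures: the duplicate pair is still
#' emitted, and the overlapping splice component is flagged by setting
#' its ctype to `unresolved`.
#'
#' @param merged the result of [mergeAlleles()].
#' @return a data.frame of component calls with the same columns as
#'   `merged$components` (`component_id` values continue `CMP` numbering
#'   after the merged components).
#' @export
callComponents <- function(merged) {
  pl <- merged$edges
  node_map <- merged$nodeMap
  expand <- function(nodes) {
    mem <- sort(unique(node_map$contig_id[node_map$node_id %in% nodes]))
    paste(mem, collapse = ",")
  }
  n_orig <- function(nodes)
    sum(node_map$node_id %in% nodes)
  counter <- nrow(merged$components)
  rows <- list()

  dup <- pl[pl$label == "duplicate", , drop = FALSE]
  dup_nodes <- unique(c(dup$a, dup$b))
  for (i in seq_len(nrow(dup))) {
    counter <- counter + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      component_id = sprintf("CMP%05d", counter),
      cluster_id = dup$cluster_id[i], ctype = "duplicate_pair",
      members = expand(c(dup$a[i], dup$b[i])),
      n_members = n_orig(c(dup$a[i], dup$b[i])),
      identity = dup$identity[i], stringsAsFactors = FALSE)
  }

  sp <- pl[pl$label == "splice" & pl$split_edge, , drop = FALSE]
  if (nrow(sp)) {
    g <- igraph::graph_from_data_frame(sp[, c("a", "b")], directed = FALSE)
    comp <- igraph::components(g)
    for (grp in split(names(comp$membership), comp$membership)) {
      if (length(grp) < 2) next
      counter <- counter + 1L
      cl <- sp$cluster_id[sp$a %in% grp | sp$b %in% grp][1]
      ctype <- if (any(grp %in% dup_nodes)) "unresolved" else "alt_splice"
      rows[[length(rows) + 1L]] <- data.frame(
        component_id = sprintf("CMP%05d", counter), cluster_id = cl,
        ctype = ctype, members = expand(grp), n_members = n_orig(grp),
        identity = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    merged$components[0, ]
  }
  rbind(merged$components, out)
}

#' Five-way homology summary of a component
#'
#' Classifies a component from the homology-hit pattern of its member
#' contigs against one database at one e-value cut-off ("same file" means
#' same subject accession): 1 = no member has a hit; 2 = some (not all)
#' members have hits, to differing subjects; 3 = some (not all) members
#' have hits, all to one subject; 4 = all members have hits, to differing
#' subjects; 5 = all members have hits, all to one subject.
#'
#' @param members character vector of member contig ids.
#' @param hits blast-hit data.frame ([readTabular()]).
#' @param db database name to restrict to.
#' @param cutoff e-value cut-off (hits with `evalue <= cutoff` qualify).
#' @return an integer in 1..5.
#' @export
blastCategory <- function(members, hits, db = "NR", cutoff = 1e-5) {
  stopifnot(length(members) >= 1)
  h <- hits[hits$db_name == db & hits$evalue <= cutoff &
            hits$query_id %in% members, , drop = FALSE]
  with_hit <- unique(h$query_id)
  subjects <- unique(h$subject_id)
  if (!length(with_hit)) return(1L)
  all_hit <- length(with_hit) == length(unique(members))
  one_subject <- length(subjects) == 1
  if (all_hit) { if (one_subject) 5L else 4L }
  else { if (one_subject) 3L else 2L }
}

#' @describeIn blastCategory vectorised over a component table: adds a
#'   `blast_category` column.
#' @param components component data.frame from [callComponents()].
#' @export
componentBlastCategories <- function(components, hits, db = "NR",
                                     cutoff = 1e-5) {
  components$blast_category <- vapply(
    strsplit(components$members, ",", fixed = TRUE),
    blastCategory, integer(1), hits = hits, db = db, cutoff = cutoff)
  components
}

#' One-call graph-cluster analysis
#'
#' Runs the full graph stage: build the split-read graph, find
#' graph-clusters, label within-cluster pairs, contract allele relations,
#' call duplicate/splice components and (optionally) attach the five-way
#' homology summary.
#'
#' @inheritParams buildGraph
#' @param seqs named contig sequences.
#' @param hits optional blast-hit data.frame for
#'   [componentBlastCategories()].
#' @param alleleId,dupIdLow,minOverlap band and overlap settings.
#' @param blastDb,blastCutoff database/cut-off for the homology summary.
#' @return a list with `graph`, `clusters`, `merged` (see
#'   [mergeAlleles()]), `components`, `consensus`.
#' @export
analyzeGraphClusters <- function(readStatus, seqs, hits = NULL,
                                 minEdgeSupport = 1, alleleId = 0.95,
                                 dupIdLow = 0.80, minOverlap = 40,
                                 blastDb = "NR", blastCutoff = 1e-5) {
  graph <- buildGraph(readStatus, minEdgeSupport)
  clusters <- findClusters(graph)
  merged <- mergeAlleles(graph, clusters, seqs, alleleId, dupIdLow,
                         minOverlap)
  components <- callComponents(merged)
  if (!is.null(hits) && nrow(components))
    components <- componentBlastCategories(components, hits, blastDb,
                                           blastCutoff)
  list(graph = graph, clusters = clusters, merged = merged,
       components = components, consensus = merged$consensus)
}
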