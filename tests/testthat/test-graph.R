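mk_rs <- function(pairs) {
  # build a minimal read-status table whose split reads realize `pairs`
  n <- length(pairs)
  data.frame(
    read_id = sprintf("r%03d", seq_len(n)), sex = "F",
    status = "partially_assembled", n_placements = 2L,
    contig1 = vapply(pairs, `[`, "", 1), read_start1 = 1L,
    read_end1 = 100L, strand1 = "+", contig_start1 = 1L,
    contig2 = vapply(pairs, `[`, "", 2), read_start2 = 101L,
    read_end2 = 200L, strand2 = "+", contig_start2 = 1L,
    stringsAsFactors = FALSE)
}

test_that("split reads aggregate into weighted edges", {
  g <- buildGraph(mk_rs(list(c("c1", "c2"), c("c2", "c3"))))
  e <- graphEdges(g)
  expect_equal(nrow(e), 2)
  expect_equal(e$weight, c(1L, 1L))

  g3 <- buildGraph(mk_rs(list(c("c1", "c2"), c("c2", "c1"),
                              c("c1", "c2"))))
  expect_equal(graphEdges(g3)$weight, 3L)

  rs <- mk_rs(list(c("c1", "c2")))
  rs$status <- "assembled"; rs$n_placements <- 1L
  rs$contig2 <- NA; rs$read_start2 <- NA; rs$read_end2 <- NA
  rs$strand2 <- NA; rs$contig_start2 <- NA
  expect_equal(nrow(graphEdges(buildGraph(rs))), 0)

  weak <- buildGraph(mk_rs(list(c("c1", "c2"), c("c3", "c4"),
                                c("c3", "c4"))), minEdgeSupport = 2)
  expect_equal(graphEdges(weak)$a, "c3")
})

test_that("clusters are connected components sorted by size then member", {
  g <- buildGraph(mk_rs(list(c("c1", "c2"), c("c2", "c3"),
                             c("x1", "x2"))))
  cl <- findClusters(g)
  expect_equal(unique(cl$cluster_id), c("GC00001", "GC00002"))
  expect_setequal(cl$contig_id[cl$cluster_id == "GC00001"],
                  c("c1", "c2", "c3"))
  expect_setequal(cl$contig_id[cl$cluster_id == "GC00002"],
                  c("x1", "x2"))
})

test_that("clusters partition non-isolated nodes on random graphs", {
  set.seed(11)
  nodes <- sprintf("n%03d", 1:60)
  pairs <- lapply(1:50, function(i) sample(nodes, 2))
  g <- buildGraph(mk_rs(pairs))
  cl <- findClusters(g)
  expect_setequal(cl$contig_id, graphNodes(g))
  expect_equal(anyDuplicated(cl$contig_id), 0)
  # membership agrees with the brute-force transitive closure
  oc <- oracle_components(graphNodes(g), graphEdges(g)$a, graphEdges(g)$b)
  names(oc) <- graphNodes(g)
  impl_label <- ave(cl$contig_id, cl$cluster_id, FUN = min)
  names(impl_label) <- cl$contig_id
  expect_identical(unname(impl_label[graphNodes(g)]),
                   unname(oc[graphNodes(g)]))
})

test_that("edge labels follow the identity bands with closed boundaries", {
  expect_equal(labelEdge(0.96), "allele")
  expect_equal(labelEdge(0.95), "allele")     # boundary: closed left
  expect_equal(labelEdge(0.949), "duplicate")
  expect_equal(labelEdge(0.87), "duplicate")
  expect_equal(labelEdge(0.80), "duplicate")  # boundary: closed left
  expect_equal(labelEdge(0.60), "splice")
  expect_equal(labelEdge(NA), "splice")       # insufficient overlap
})

test_that("allele pairs are contracted with an IUPAC-tie consensus", {
  set.seed(12)
  shared <- rand_dna(200)
  va <- rand_dna(200)
  vb <- mutateSequence(va, 0.04, seed = 13)
  seqs <- c(cS = shared, cA = va, cB = vb)
  rs <- mk_rs(list(c("cS", "cA"), c("cS", "cB")))
  g <- buildGraph(rs)
  cl <- findClusters(g)
  merged <- mergeAlleles(g, cl, seqs)
  expect_equal(nrow(merged$components), 1)
  expect_equal(merged$components$ctype, "merged_alleles")
  expect_equal(merged$components$members, "cA,cB")
  cons <- as.character(merged$consensus[[1]])
  # consensus length equals the allele length; mismatch columns ambiguous
  expect_equal(nchar(cons), 200)
  n_amb <- sum(!strsplit(cons, "")[[1]] %in% c("A", "C", "G", "T"))
  expect_equal(n_amb, round(0.04 * 200))

  # no allele edges: nothing contracted
  seqs2 <- c(cS = shared, cA = va, cB = rand_dna(200))
  m2 <- mergeAlleles(g, cl, seqs2)
  expect_equal(nrow(m2$components), 0)
})

test_that("components are typed per the decomposition rules", {
  set.seed(14)
  # pure allele pair cluster: one merged component, no others
  shared <- rand_dna(200); va <- rand_dna(200)
  vb <- mutateSequence(va, 0.03, seed = 15)
  seqs <- c(cS = shared, cA = va, cB = vb)
  g <- buildGraph(mk_rs(list(c("cS", "cA"), c("cS", "cB"))))
  res <- callComponents(mergeAlleles(g, findClusters(g), seqs))
  expect_equal(sum(res$ctype == "merged_alleles"), 1)
  expect_equal(sum(res$ctype == "duplicate_pair"), 0)

  # two contigs at identity 0.88: one duplicate pair
  da <- rand_dna(300)
  db <- mutateSequence(da, 0.12, seed = 16)
  seqs <- c(cS = shared, cA = da, cB = db)
  res <- callComponents(mergeAlleles(g, findClusters(g), seqs))
  dup <- res[res$ctype == "duplicate_pair", ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$members, "cA,cB")
  expect_true(dup$identity >= 0.80 && dup$identity < 0.95)

  # three unrelated exon contigs joined by splice edges: one alt_splice
  seqs <- c(e1 = rand_dna(250), e2 = rand_dna(250), e3 = rand_dna(250))
  g3 <- buildGraph(mk_rs(list(c("e1", "e2"), c("e2", "e3"),
                              c("e1", "e3"))))
  res <- callComponents(mergeAlleles(g3, findClusters(g3), seqs))
  expect_equal(res$ctype, "alt_splice")
  expect_equal(res$members, "e1,e2,e3")
})

test_that("contigs are conserved across component calls plus singles", {
  study <- simulateStudy(tiny_params())
  res <- analyzeGraphClusters(studyReadStatus(study), studyContigs(study))
  in_calls <- unique(unlist(strsplit(res$components$members, ",")))
  clustered <- res$clusters$contig_id
  expect_true(all(in_calls %in% clustered))
  # contraction never increases node count
  expect_true(length(unique(res$merged$nodeMap$node_id)) <=
                length(clustered))
  # node map covers every clustered contig exactly once
  expect_setequal(res$merged$nodeMap$contig_id, clustered)
})

test_that("five-way homology categories follow the hit pattern", {
  hit <- function(q, s) data.frame(
    db_name = "NR", query_id = q, subject_id = s, percent_identity = 95,
    align_length = 100L, mismatches = 0L, gap_opens = 0L,
    query_start = 1L, query_end = 100L, subject_start = 1L,
    subject_end = 100L, evalue = 1e-30, bitscore = 190,
    stringsAsFactors = FALSE)
  none <- hit("cX", "s")[0, ]
  expect_equal(blastCategory(c("c1", "c2"), none), 1L)
  expect_equal(blastCategory(c("c1", "c2", "c3"),
                             rbind(hit("c1", "X"), hit("c2", "Y"))), 2L)
  expect_equal(blastCategory(c("c1", "c2", "c3"),
                             rbind(hit("c1", "X"), hit("c2", "X"))), 3L)
  expect_equal(blastCategory(c("c1", "c2"),
                             rbind(hit("c1", "X"), hit("c2", "Y"))), 4L)
  expect_equal(blastCategory(c("c1", "c2"),
                             rbind(hit("c1", "X"), hit("c2", "X"))), 5L)
  # cutoff respected
  weak <- hit("c1", "X"); weak$evalue <- 1e-3
  expect_equal(blastCategory("c1", weak, cutoff = 1e-5), 1L)
})
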