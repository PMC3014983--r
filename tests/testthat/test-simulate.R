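test_that("gene set counts and ledger rows are exact and deterministic", {
  p <- simParams(nUnique = 10, nAllelePair = 5, nDuplicatePair = 5,
                 nAltSplice = 5, nChimeraSource = 2, nFemaleOnly = 2,
                 nMaleOnly = 2, seed = 9)
  gs <- generateGeneSet(p)
  expect_equal(length(gs$models), 27)
  expect_equal(nrow(gs$genes), 27)
  expect_equal(as.vector(table(gs$genes$category)[
    c("unique", "allele_pair", "duplicate_pair", "alt_splice",
      "chimera_source")]), c(10, 5, 5, 5, 2))
  gs2 <- generateGeneSet(p)
  expect_identical(gs, gs2)

  empty <- generateGeneSet(simParams(nUnique = 0, nAllelePair = 0,
                                     nDuplicatePair = 0, nAltSplice = 0,
                                     nChimeraSource = 0, nFemaleOnly = 0,
                                     nMaleOnly = 0, seed = 1))
  expect_equal(length(empty$models), 0)
})

test_that("infeasible parameter ranges are rejected", {
  expect_error(simParams(readLenMean = 400, exonLenRange = c(300, 600)),
               "infeasible")
  expect_error(simParams(nFemaleOnly = 100, nUnique = 10), "fit among")
  expect_error(simParams(duplicateIdentity = c(0.7, 0.9)), "0.80")
})

test_that("mutateSequence realizes divergence and the TS bias", {
  s <- rand_dna(1000)
  expect_identical(mutateSequence(s, 0, seed = 1), s)
  m <- mutateSequence(s, 0.05, seed = 2)
  av <- strsplit(s, "")[[1]]; bv <- strsplit(m, "")[[1]]
  expect_true(sum(av != bv) >= 45 && sum(av != bv) <= 55)

  big <- rand_dna(10000)
  mut <- mutateSequence(big, 0.1, tsTvWeight = 2, seed = 3)
  a <- strsplit(big, "")[[1]]; b <- strsplit(mut, "")[[1]]
  diff <- which(a != b)
  ts <- oracle_tstv(a[diff], b[diff])
  tv <- length(diff) - ts
  # P(TS) = 2/3; 1000 draws: binomial 4-sigma band
  phat <- ts / length(diff)
  expect_true(abs(phat - 2 / 3) < 4 * sqrt(2 / 9 / length(diff)))
})

test_that("reads respect sex restriction and Poisson depth", {
  p <- simParams(nUnique = 10, nAllelePair = 0, nDuplicatePair = 0,
                 nAltSplice = 0, nChimeraSource = 0, nFemaleOnly = 10,
                 nMaleOnly = 0, depthMean = 20, seed = 21)
  gs <- generateGeneSet(p)
  reads <- simulateReads(gs$models, p, seed = 22)
  expect_true(all(reads$sex == "F"))
  # 10 genes at depth 20: total within 3 SD of 200
  expect_true(abs(nrow(reads) - 200) <= 3 * sqrt(200))
})

test_that("junction reads are recorded in the ledger", {
  p <- simParams(nUnique = 0, nAllelePair = 0, nDuplicatePair = 0,
                 nAltSplice = 5, nChimeraSource = 0, nFemaleOnly = 0,
                 nMaleOnly = 0, depthMean = 60, seed = 31)
  gs <- generateGeneSet(p)
  reads <- simulateReads(gs$models, p, seed = 32)
  expect_true(any(reads$junction))
  expect_true(any(!reads$junction))
})

test_that("allele pairs split or merge at the assembler identity", {
  # divergence 0.04 < identity 0.97 threshold: shared contig + two
  # allele contigs linked by split reads
  p <- simParams(nUnique = 0, nAllelePair = 1, nDuplicatePair = 0,
                 nAltSplice = 0, nChimeraSource = 0, nFemaleOnly = 0,
                 nMaleOnly = 0, depthMean = 80,
                 alleleDivergence = c(0.04, 0.04), alleleMergedFrac = 0,
                 snpRate = 0, falseVariantRate = 0, seed = 41)
  gs <- generateGeneSet(p)
  reads <- simulateReads(gs$models, p, seed = 42)
  asm <- emulateAssembly(gs$models, reads, p, seed = 43)
  expect_equal(length(asm$contigs), 3)
  expect_setequal(asm$truthContigs$role,
                  c("shared", "variable_A", "variable_B"))
  split <- asm$readStatus[asm$readStatus$n_placements == 2, ]
  expect_true(nrow(split) > 0)
  shared <- asm$truthContigs$contig_id[asm$truthContigs$role == "shared"]
  expect_true(all(split$contig1 == shared | split$contig2 == shared))
  expect_equal(nrow(asm$variants), 0)

  # divergence 0.01 >= identity 0.97: one merged contig + SNP records
  p2 <- simParams(nUnique = 0, nAllelePair = 1, nDuplicatePair = 0,
                  nAltSplice = 0, nChimeraSource = 0, nFemaleOnly = 0,
                  nMaleOnly = 0, depthMean = 80, alleleMergedFrac = 1,
                  mergedAlleleDivergence = c(0.01, 0.01), snpRate = 0,
                  falseVariantRate = 0, seed = 44)
  gs2 <- generateGeneSet(p2)
  reads2 <- simulateReads(gs2$models, p2, seed = 45)
  asm2 <- emulateAssembly(gs2$models, reads2, p2, seed = 46)
  expect_equal(length(asm2$contigs), 2)  # shared + merged variable
  expect_true(all(asm2$variants$var_type == "SNP"))
  vlen <- nchar(gs2$models[[1]]$segments[[2]]$copies$A)
  expect_equal(nrow(asm2$variants), round(0.01 * vlen))
  expect_true(all(asm2$truthVariants$is_true))
})

test_that("alternative splicing yields one contig per exon and the
           expected junction edges", {
  p <- simParams(nUnique = 0, nAllelePair = 0, nDuplicatePair = 0,
                 nAltSplice = 1, nChimeraSource = 0, nFemaleOnly = 0,
                 nMaleOnly = 0, depthMean = 200, nIsoformRange = c(2, 2),
                 snpRate = 0, falseVariantRate = 0, seed = 51)
  gs <- generateGeneSet(p)
  reads <- simulateReads(gs$models, p, seed = 52)
  asm <- emulateAssembly(gs$models, reads, p, seed = 53)
  expect_equal(length(asm$contigs), 3)
  g <- buildGraph(asm$readStatus)
  e <- graphEdges(g)
  cid <- sort(asm$truthContigs$contig_id)
  # isoforms {e1,e2,e3} and {e1,e3}: edges e1-e2, e2-e3 and e1-e3
  expect_setequal(paste(e$a, e$b),
                  c(paste(cid[1], cid[2]), paste(cid[2], cid[3]),
                    paste(cid[1], cid[3])))
})

test_that("duplicate-pair diverged regions realize their identity band", {
  p <- simParams(nUnique = 0, nAllelePair = 0, nDuplicatePair = 6,
                 nAltSplice = 0, nChimeraSource = 0, nFemaleOnly = 0,
                 nMaleOnly = 0, depthMean = 30, seed = 61)
  gs <- generateGeneSet(p)
  reads <- simulateReads(gs$models, p, seed = 62)
  asm <- emulateAssembly(gs$models, reads, p, seed = 63)
  tc <- asm$truthContigs
  seqs <- as.character(asm$contigs)
  for (gid in unique(tc$gene_id)) {
    a <- seqs[tc$contig_id[tc$gene_id == gid & tc$role == "variable_A"]]
    b <- seqs[tc$contig_id[tc$gene_id == gid & tc$role == "variable_B"]]
    ident <- overlapIdentity(a, b)
    expect_true(ident >= 0.80 && ident < 0.95)
  }
})

test_that("simulated homology hits match the ground truth construction", {
  study <- simulateStudy(simParams(
    nUnique = 6, nAllelePair = 2, nDuplicatePair = 2, nAltSplice = 2,
    nChimeraSource = 4, nFemaleOnly = 0, nMaleOnly = 0, depthMean = 40,
    noHomologFrac = 0.4, dbPresence = c(1, 1, 1, 1), seed = 71))
  hits <- studyBlastHits(study)
  tr <- groundTruth(study)
  nr <- hits[hits$db_name == "NR", ]
  # genes flagged no-homolog have no hits at all
  no_hom <- tr$genes$gene_id[is.na(tr$genes$homolog)]
  ctg_no <- tr$contigs$contig_id[tr$contigs$gene_id %in% no_hom]
  expect_false(any(nr$query_id %in% ctg_no))
  # allele contigs of one gene hit a single shared accession
  for (gid in tr$genes$gene_id[tr$genes$category == "allele_pair"]) {
    if (is.na(tr$genes$homolog[tr$genes$gene_id == gid])) next
    ctg <- tr$contigs$contig_id[tr$contigs$gene_id == gid]
    expect_equal(length(unique(nr$subject_id[nr$query_id %in% ctg])), 1)
  }
  # duplicate-pair diverged contigs hit different paralog accessions
  for (gid in tr$genes$gene_id[tr$genes$category == "duplicate_pair"]) {
    if (is.na(tr$genes$homolog[tr$genes$gene_id == gid])) next
    tcg <- tr$contigs[tr$contigs$gene_id == gid, ]
    sa <- nr$subject_id[nr$query_id %in%
                          tcg$contig_id[tcg$role == "variable_A"]]
    sb <- nr$subject_id[nr$query_id %in%
                          tcg$contig_id[tcg$role == "variable_B"]]
    if (length(sa) && length(sb)) expect_false(any(sa %in% sb))
  }
  # chimera contigs: two strong hits on disjoint query halves
  for (cc in tr$chimeras$contig_id) {
    h <- nr[nr$query_id == cc, ]
    if (nrow(h) < 2) next                # a source gene lacks a homologue
    expect_equal(length(unique(h$subject_id)), 2)
    expect_true(all(h$evalue < 1e-20))
    expect_true(max(h$query_start) > min(h$query_end))
  }
})

test_that("ledger is complete: every artifact appears exactly once", {
  study <- simulateStudy(tiny_params())
  tr <- groundTruth(study)
  expect_setequal(names(studyContigs(study)), tr$contigs$contig_id)
  expect_equal(anyDuplicated(tr$contigs$contig_id), 0)
  expect_setequal(studyReadStatus(study)$read_id, tr$reads$read_id)
  expect_equal(anyDuplicated(tr$reads$read_id), 0)
  v <- studyVariants(study)
  expect_equal(paste(v$contig_id, v$position, v$var_type),
               paste(tr$variants$contig_id, tr$variants$position,
                     tr$variants$var_type))
})

test_that("the full simulation is byte-deterministic in its seed", {
  s1 <- simulateStudy(tiny_params())
  s2 <- simulateStudy(tiny_params())
  expect_identical(as.character(studyContigs(s1)),
                   as.character(studyContigs(s2)))
  expect_identical(studyReadStatus(s1), studyReadStatus(s2))
  expect_identical(studyVariants(s1), studyVariants(s2))
  expect_identical(studyBlastHits(s1), studyBlastHits(s2))
  expect_identical(groundTruth(s1), groundTruth(s2))
})
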