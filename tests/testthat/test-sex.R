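mk_hit <- function(q, s, e, db = "NR") {
  data.frame(db_name = db, query_id = q, subject_id = s,
             percent_identity = 95, align_length = 100L, mismatches = 0L,
             gap_opens = 0L, query_start = 1L, query_end = 100L,
             subject_start = 1L, subject_end = 100L, evalue = e,
             bitscore = 190, stringsAsFactors = FALSE)
}

mk_rs_sex <- function(reads) {
  # reads: list of c(read_id, sex, status, contig or NA)
  do.call(rbind, lapply(reads, function(r) {
    placed <- !is.na(r[4])
    data.frame(
      read_id = r[1], sex = r[2], status = r[3],
      n_placements = if (placed) 1L else 0L,
      contig1 = r[4], read_start1 = if (placed) 1L else NA_integer_,
      read_end1 = if (placed) 100L else NA_integer_,
      strand1 = if (placed) "+" else NA_character_,
      contig_start1 = if (placed) 1L else NA_integer_,
      contig2 = NA_character_, read_start2 = NA_integer_,
      read_end2 = NA_integer_, strand2 = NA_character_,
      contig_start2 = NA_integer_, stringsAsFactors = FALSE)
  }))
}

test_that("contigs classify as FC/MC/BC from their reads", {
  rs <- mk_rs_sex(list(c("r1", "F", "assembled", "c1"),
                       c("r2", "F", "assembled", "c1"),
                       c("r3", "F", "assembled", "c1"),
                       c("r4", "F", "assembled", "c2"),
                       c("r5", "M", "assembled", "c2"),
                       c("r6", "M", "assembled", "c3"),
                       c("r7", "F", "singleton", NA)))
  cls <- classifySequences(rs)
  got <- setNames(cls$contigs$class, cls$contigs$contig_id)
  expect_equal(got[["c1"]], "FC")
  expect_equal(got[["c2"]], "BC")
  expect_equal(got[["c3"]], "MC")
  expect_equal(cls$singletons$read_id, "r7")
  expect_equal(cls$singletons$sex, "F")
  expect_error(classifySequences(rs, contigs = c("c1", "c9")),
               "no placed read")
})

test_that("a split read contributes its sex to both linked contigs", {
  rs <- mk_rs_sex(list(c("r1", "F", "assembled", "cA"),
                       c("r2", "M", "assembled", "cB")))
  rs <- rbind(rs, data.frame(
    read_id = "r3", sex = "M", status = "partially_assembled",
    n_placements = 2L, contig1 = "cA", read_start1 = 1L,
    read_end1 = 100L, strand1 = "+", contig_start1 = 1L, contig2 = "cB",
    read_start2 = 101L, read_end2 = 200L, strand2 = "+",
    contig_start2 = 1L, stringsAsFactors = FALSE))
  cls <- classifySequences(rs)
  got <- setNames(cls$contigs$class, cls$contigs$contig_id)
  expect_equal(got[["cA"]], "BC")      # F read + M split read
  expect_equal(got[["cB"]], "MC")      # M read + M split read
})

test_that("sex-specific calls follow the two-cut-off ladder", {
  rs <- mk_rs_sex(list(c("r1", "F", "assembled", "fc1"),
                       c("r2", "M", "assembled", "mc1"),
                       c("r3", "F", "assembled", "bc1"),
                       c("r4", "M", "assembled", "bc1"),
                       c("r5", "M", "singleton", NA)))
  cls <- classifySequences(rs)

  # one FC contig at 1e-60, nothing else: female specific
  calls <- callSexSpecific(mk_hit("fc1", "gene1", 1e-60), cls)
  expect_equal(calls$call, "female_specific")

  # FC at 1e-60 plus an M singleton at 1e-8: weak male homology
  # disqualifies -> shared
  calls <- callSexSpecific(rbind(mk_hit("fc1", "gene1", 1e-60),
                                 mk_hit("r5", "gene1", 1e-8)), cls)
  expect_equal(calls$call, "shared")

  # BC contig only: both sexes contributed -> shared
  calls <- callSexSpecific(mk_hit("bc1", "gene2", 1e-60), cls)
  expect_equal(calls$call, "shared")

  # FC hit at 1e-30 only: too weak for the strict cut-off
  calls <- callSexSpecific(mk_hit("fc1", "gene3", 1e-30), cls)
  expect_equal(calls$call, "insufficient")

  # male-specific symmetric case
  calls <- callSexSpecific(mk_hit("mc1", "gene4", 1e-70), cls)
  expect_equal(calls$call, "male_specific")

  # opposite-sex hit above the screen cut-off does not disqualify
  calls <- callSexSpecific(rbind(mk_hit("fc1", "gene5", 1e-60),
                                 mk_hit("mc1", "gene5", 1e-3)), cls)
  expect_equal(calls$call, "female_specific")

  expect_error(callSexSpecific(rbind(mk_hit("fc1", "g", 1e-60),
                                     mk_hit("fc1", "g", 1e-60,
                                            db = "HomoloGene")), cls),
               "single database")
})

test_that("Fisher exact matches closed forms and the stats oracle", {
  expect_equal(fisherExact(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisherExact(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_error(fisherExact(matrix(0, 2, 2)), "all-zero")
  set.seed(31)
  for (i in 1:100) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisherExact(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(fisherExact(tab, "greater"),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(0.2), 0.2)
  set.seed(32)
  p <- runif(50)
  q <- bhFdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))  # monotone in sorted p
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
})

test_that("GO enrichment tests shared terms and is label-symmetric", {
  ann <- data.frame(
    seq_id = c(paste0("a", 1:5), paste0("b", 1:5), "a1", "b1"),
    term_id = c(rep("GO:X", 5), rep("GO:Y", 5), "GO:Z", "GO:Z"),
    stringsAsFactors = FALSE)
  setA <- paste0("a", 1:5)
  setB <- paste0("b", 1:5)
  res <- goEnrichment(setA, setB, ann)
  # the 5/5 vs 0/5 terms dominate; the balanced term is uninformative
  expect_equal(res$term_id[1:2][order(res$term_id[1:2])],
               c("GO:X", "GO:Y"))
  expect_equal(res$p_value[res$term_id == "GO:Z"], 1)
  # term absent from both sets is not tested
  expect_false("GO:W" %in% res$term_id)
  # two-sided: swapping the sets leaves p-values unchanged
  res2 <- goEnrichment(setB, setA, ann)
  expect_equal(res$p_value[order(res$term_id)],
               res2$p_value[order(res2$term_id)])
  expect_true(all(res$q_value >= res$p_value - 1e-15))
})
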