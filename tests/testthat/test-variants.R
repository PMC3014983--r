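mk_var <- function(contig_id, position, ref = "A", alt = "G",
                   var_type = "SNP", coverage = 20, probability = 0.99) {
  data.frame(contig_id = contig_id, position = as.integer(position),
             ref_allele = ref, alt_allele = alt, var_type = var_type,
             coverage = as.integer(coverage), probability = probability,
             stringsAsFactors = FALSE)
}

test_that("variant filter honours its strict boundaries", {
  ctg <- c(c1 = strrep("ACGT", 50))
  v <- rbind(mk_var("c1", 1, coverage = 4),    # below floor: removed
             mk_var("c1", 2, coverage = 5),    # at floor: retained
             mk_var("c1", 3, coverage = 100),  # at ceiling: retained
             mk_var("c1", 4, coverage = 101),  # above: removed
             mk_var("c1", 5, probability = 0.9),    # at floor: retained
             mk_var("c1", 6, probability = 0.8999)) # below: removed
  out <- filterVariants(v, ctg)
  expect_equal(out$position, c(2L, 3L, 5L))
})

test_that("homopolymer-adjacent INDELs are removed, SNPs kept", {
  ctg <- c(c1 = "ACGTAAAACGTACGTACGTACGT")
  v <- rbind(
    mk_var("c1", 6, ref = "A", alt = "-", var_type = "DEL"),  # inside run
    mk_var("c1", 4, ref = "T", alt = "-", var_type = "DEL"),  # adjacent
    mk_var("c1", 15, ref = "G", alt = "-", var_type = "DEL"), # clear
    mk_var("c1", 6, ref = "A", alt = "G"))                    # SNP in run
  out <- filterVariants(v, ctg)
  expect_equal(out$position, c(15L, 6L))
  expect_equal(out$var_type, c("DEL", "SNP"))
})

test_that("variant filter equals the set-comprehension oracle and is
           idempotent", {
  set.seed(21)
  ctgs <- setNames(vapply(1:20, function(i) rand_dna(300), ""),
                   sprintf("c%02d", 1:20))
  n <- 1000
  v <- mk_var(sample(names(ctgs), n, replace = TRUE),
              sample(300, n, replace = TRUE),
              coverage = sample(0:120, n, replace = TRUE),
              probability = runif(n),
              var_type = sample(c("SNP", "INS", "DEL"), n, replace = TRUE))
  v$ref_allele <- ifelse(v$var_type == "INS", "-",
                         substring(ctgs[v$contig_id], v$position,
                                   v$position))
  v$alt_allele <- ifelse(v$var_type == "DEL", "-", "G")
  snp_bad <- v$var_type == "SNP" & v$ref_allele == "G"
  v$alt_allele[snp_bad] <- "T"
  out <- filterVariants(v, ctgs)
  exp <- oracle_filter(v, make_hp_predicate(ctgs))
  expect_equal(out, exp)
  expect_equal(filterVariants(out, ctgs), out)

  expect_error(filterVariants(mk_var("nope", 1), ctgs), "unknown contig")
})

test_that("all twelve ordered substitutions split 4 TS : 8 TV", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classifySubstitution(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "TS"), 4)
  expect_equal(sum(cls == "TV"), 8)
  expect_equal(classifySubstitution("A", "G"), "TS")
  expect_equal(classifySubstitution("A", "C"), "TV")
  expect_error(classifySubstitution("A", "A"), "differ")
  expect_error(classifySubstitution("A", "N"), "non-ACGT")
})

test_that("coding effects follow the standard genetic code", {
  orf <- list(start = 0L, end = 9L, strand = "+")
  seq <- "GAAGAAGAA"
  # GAA -> GAG at codon position 3: Glu/Glu synonymous
  expect_equal(codingEffect(3, "A", "G", orf, seq), "synonymous")
  # CGA -> AGA at codon position 1: Arg/Arg synonymous
  expect_equal(codingEffect(1, "C", "A", orf, "CGACGACGA"), "synonymous")
  # GAA -> TAA at position 1: Glu -> stop, nonsynonymous state change
  expect_equal(codingEffect(1, "G", "T", orf, seq), "nonsynonymous")
  # outside the ORF window
  orf2 <- list(start = 3L, end = 9L, strand = "+")
  expect_equal(codingEffect(1, "G", "T", orf2, seq), "noncoding")
  # minus strand: read on the reverse complement
  # seq TTCTTCTTC, rc = GAAGAAGAA; forward pos 7 is rc pos 3 (codon 1)
  expect_equal(codingEffect(7, "T", "C", list(start = 0L, end = 9L,
                                              strand = "-"),
                            "TTCTTCTTC"), "synonymous")
  expect_error(codingEffect(1, "G", "T", list(start = 0L, end = 12L,
                                              strand = "+"), seq),
               "exceeds")
})

test_that("per-contig summaries count and smooth as specified", {
  ctgs <- c(c1 = strrep("ACGT", 100), c2 = strrep("GGCA", 100))
  v <- rbind(mk_var("c1", 1, ref = "A", alt = "G"),   # TS
             mk_var("c1", 5, ref = "A", alt = "G"),   # TS
             mk_var("c1", 9, ref = "A", alt = "C"),   # TV
             mk_var("c1", 12, ref = "T", alt = "-", var_type = "DEL"))
  s <- summarizeContigs(ctgs, v)
  expect_equal(s$n_snp, c(3L, 0L))
  expect_equal(s$n_indel, c(1L, 0L))
  expect_equal(s$ts + s$tv, s$n_snp)
  expect_equal(s$tstv_ratio, c((2 + 1) / (1 + 1), 1.0))
  expect_equal(s$density[1], 4 / 400)
  expect_equal(s$density_per_200bp[1], 2)
})

test_that("Ka/Ks per contig equals an independent re-translation", {
  set.seed(22)
  study <- simulateStudy(tiny_params())
  filtered <- filterVariants(studyVariants(study), studyContigs(study))
  orfs <- studyOrfs(study)
  s <- summarizeContigs(studyContigs(study), filtered, orfs)
  snp <- filtered[filtered$var_type == "SNP", ]
  seqs <- as.character(studyContigs(study))
  checked <- 0L
  for (cid in s$contig_id[!is.na(s$ka)]) {
    orf <- orfs[orfs$contig_id == cid, ]
    orf <- orf[which.max(orf$end - orf$start), ]
    expected <- oracle_kaks(snp[snp$contig_id == cid, ], orf, seqs[[cid]])
    expect_equal(s$ka[s$contig_id == cid], unname(expected["ka"]))
    expect_equal(s$ks[s$contig_id == cid], unname(expected["ks"]))
    checked <- checked + 1L
  }
  expect_true(checked > 5)
  # smoothing forced values
  expect_true(all(s$kaks_ratio[!is.na(s$kaks_ratio)] ==
                    (s$ka[!is.na(s$ka)] + 1) / (s$ks[!is.na(s$ks)] + 1)))
})

test_that("percentile flag: nearest-rank on the with-variant subset", {
  ctgs <- setNames(rep(strrep("ACGT", 100), 100), sprintf("c%03d", 1:100))
  v <- do.call(rbind, lapply(1:100, function(i)
    mk_var(sprintf("c%03d", i), seq_len(i), ref = "A", alt = "G")))
  # fake distinct densities via distinct counts on equal lengths
  s <- flagHighlyVariable(summarizeContigs(ctgs, v))
  expect_equal(sum(s$highly_variable), 1)
  expect_true(s$highly_variable[s$contig_id == "c100"])

  # all densities equal: all flagged
  v2 <- do.call(rbind, lapply(1:100, function(i)
    mk_var(sprintf("c%03d", i), 1, ref = "A", alt = "G")))
  s2 <- flagHighlyVariable(summarizeContigs(ctgs, v2))
  expect_true(all(s2$highly_variable))

  # invariant under permutation of input order
  perm <- sample(nrow(v))
  s3 <- flagHighlyVariable(summarizeContigs(ctgs, v[perm, ]))
  expect_equal(s3$highly_variable[order(s3$contig_id)],
               s$highly_variable[order(s$contig_id)])
})

test_that("length regression recovers an exact linear fit", {
  ctgs <- c(a = strrep("A", 100), b = strrep("A", 200),
            c = strrep("A", 300))
  v <- rbind(mk_var("a", 1, ref = "A", alt = "G"),
             mk_var("b", 1, ref = "A", alt = "G"),
             mk_var("b", 2, ref = "A", alt = "G"),
             mk_var("c", 1, ref = "A", alt = "G"),
             mk_var("c", 2, ref = "A", alt = "G"),
             mk_var("c", 3, ref = "A", alt = "G"))
  fit <- regressVariantsOnLength(summarizeContigs(ctgs, v))
  expect_equal(fit$slope, 0.01, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  same <- c(a = strrep("A", 100), b = strrep("A", 100),
            c = strrep("A", 100))
  expect_error(regressVariantsOnLength(summarizeContigs(same, v)),
               "degenerate")
})

test_that("r-squared stays in [0, 1] across random datasets", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    lens <- sample(100:1000, n, replace = TRUE)
    lens[1:2] <- c(100, 900)            # guarantee non-degenerate
    ctgs <- setNames(strrep("A", lens), sprintf("c%02d", 1:n))
    v <- do.call(rbind, lapply(seq_len(n), function(j)
      mk_var(sprintf("c%02d", j), seq_len(sample(1:9, 1)), ref = "A",
             alt = "G")))
    fit <- regressVariantsOnLength(summarizeContigs(ctgs, v))
    expect_true(fit$r2 >= 0 && fit$r2 <= 1)
    expect_true(fit$p_value >= 0 && fit$p_value <= 1)
  }
})

test_that("selection candidates equal the brute-force intersection", {
  set.seed(24)
  study <- simulateStudy(tiny_params())
  filtered <- filterVariants(studyVariants(study), studyContigs(study))
  s <- flagHighlyVariable(summarizeContigs(studyContigs(study), filtered,
                                           studyOrfs(study)))
  cand <- selectionCandidates(s)
  set_a <- s$contig_id[!is.na(s$kaks_ratio) & s$kaks_ratio > 1]
  set_b <- s$contig_id[s$tstv_ratio < 1]
  set_c <- s$contig_id[s$highly_variable]
  expect_setequal(cand, Reduce(intersect, list(set_a, set_b, set_c)))
})

test_that("ORF finder scans all six frames with the 30 bp floor", {
  expect_null(findLongestOrf("ATGAAATAG"))    # 9 bp < 30
  expect_null(findLongestOrf(strrep("N", 200)))
  set.seed(25)
  # planted 60-codon ORF inside random flanks (flanks may extend it; the
  # oracle is the authority)
  core <- paste0("ATG", paste(sample(setdiff(ContigGraphKit:::.CODONS,
                                             "ATG"), 58, replace = TRUE),
                              collapse = ""), "TAA")
  seq <- paste0(rand_dna(37), core, rand_dna(23))
  orf <- findLongestOrf(seq)
  expect_equal(orf$score, oracle_longest_orf_len(seq))
  expect_true(orf$score >= 180)
  # exhaustive-oracle agreement on random sequences, both strands
  for (i in 1:30) {
    s <- rand_dna(sample(60:400, 1))
    got <- findLongestOrf(s)
    expect_equal(if (is.null(got)) 0L else got$score,
                 max(0L, oracle_longest_orf_len(s) *
                       (oracle_longest_orf_len(s) >= 30)))
  }
})

test_that("pooled TS:TV across true simulated SNPs recovers the
           mutation-sampler weight", {
  p <- simParams(nUnique = 60, nAllelePair = 20, nDuplicatePair = 0,
                 nAltSplice = 0, nChimeraSource = 0, nFemaleOnly = 0,
                 nMaleOnly = 0, depthMean = 15, snpRate = 0.02,
                 alleleMergedFrac = 0.5, tsTvWeight = 2, seed = 77)
  study <- simulateStudy(p)
  v <- studyVariants(study)
  tr <- groundTruth(study)$variants
  true_snp <- v[paste(v$contig_id, v$position) %in%
                  paste(tr$contig_id, tr$position)[tr$is_true] &
                  v$var_type == "SNP", ]
  cls <- classifySubstitution(true_snp$ref_allele, true_snp$alt_allele)
  n <- length(cls)
  phat <- mean(cls == "TS")
  expect_true(abs(phat - 2 / 3) < 4 * sqrt(2 / 9 / n))
})
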