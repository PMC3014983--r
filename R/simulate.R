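## Synthetic-data generator: gene families, sex-labelled reads and
## emulated assembler outputs (contigs, split-read records, variants,
## homology hits) with a complete ground-truth ledger.
##
## The emulation follows the assembler's documented behaviour: segment
## pairs at or above the merge identity collapse into one contig and
## their differences surface as variant calls; pairs below it become
## separate contigs; reads spanning a segment boundary are split into two
## placements (one split per spanning read -- reads are never longer than
## the shortest segment, so a read crosses at most one boundary).

.CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

## random stop-free coding sequence of length len (a codon multiple),
## optionally opened with ATG / closed with a stop codon
.rand_cds <- function(len, open = FALSE, close = FALSE) {
  stopifnot(len %% 3 == 0, len >= 9)
  ncod <- len / 3
  codons <- sample(.CODONS, ncod, replace = TRUE)
  if (open) codons[1] <- "ATG"
  if (close) codons[ncod] <- "TAA"
  paste(codons, collapse = "")
}

.codon_len <- function(x) as.integer(round(x / 3) * 3)

#' Simulation parameters
#'
#' Constructs and validates the parameter block for [simulateStudy()].
#' Defaults describe a 200-gene pooled two-sex study at roughly 20,000
#' reads: category counts 140 unique / 20 allele-pair / 10
#' duplicate-pair / 20 alternative-splicing / 10 chimera-source genes;
#' 10 female-only and 10 male-only genes among the unique ones; read
#' length 250 +/- 30 bp at 100 reads per gene with 41% of unbiased reads
#' female; divergent alleles at 3--4.5% divergence (a fraction of pairs
#' instead nearly identical, so they collapse at the 0.97 assembler merge
#' identity and surface as variant calls); duplicated-gene diverged
#' regions at 82--93% identity; 7.5% of reads left as singletons and
#' 5.7% discarded.
#'
#' @param nUnique,nAllelePair,nDuplicatePair,nAltSplice,nChimeraSource
#'   gene counts per category (a duplicate pair or allele pair is one
#'   gene model; two chimera-source genes yield one planted chimera).
#' @param nFemaleOnly,nMaleOnly number of unique genes restricted to one
#'   sex (presence/absence, not quantitative bias).
#' @param exonLenRange exon/segment length range in bp (rounded to codon
#'   multiples).
#' @param altSpliceExons exons per alternative-splicing gene.
#' @param nIsoformRange isoforms per alternative-splicing gene.
#' @param readLenMean,readLenSd,readLenMin read length model (bp);
#'   `readLenMean` must not exceed the shortest segment.
#' @param depthMean mean reads per gene (Poisson).
#' @param sexRatio fraction of reads from the female pool for unbiased
#'   genes.
#' @param alleleDivergence divergence band for split allele pairs.
#' @param alleleMergedFrac fraction of allele pairs drawn instead from
#'   `mergedAlleleDivergence`, so they collapse at assembly and emit
#'   variants.
#' @param mergedAlleleDivergence divergence band for collapsing allele
#'   pairs.
#' @param duplicateIdentity identity band for duplicated-gene diverged
#'   regions (must lie within `[0.80, 0.95)`).
#' @param assemblerMergeIdentity identity at or above which the emulated
#'   assembler collapses two segment copies into one contig.
#' @param tsTvWeight transition:transversion odds of the mutation
#'   sampler.
#' @param indelRate per-site indel rate of [mutateSequence()] (0 =
#'   substitutions only).
#' @param singletonRate,discardRate per-read probabilities of staying a
#'   singleton / being discarded.
#' @param snpRate per-bp rate of true population SNPs planted on contigs.
#' @param falseVariantRate mean injected false calls per contig (low
#'   probability; half are homopolymer-adjacent INDELs).
#' @param varCoverageMean mean read coverage simulated for variant calls.
#' @param noHomologFrac fraction of genes with no homologue in any
#'   reference database (quickly evolving / taxon-specific genes).
#' @param dbNames,dbPresence reference database names and per-database
#'   probability that a gene with a homologue is present in them.
#' @param leakageRate probability that a read from a sex-restricted gene
#'   is mislabelled with the other sex (robustness knob; 0 = absolute
#'   presence/absence).
#' @param goTermPool,goTermsPerGene GO term pool size and per-gene term
#'   count range.
#' @param goFemaleBiasTerm,goFemaleBiasProb,goBackgroundBiasProb the GO
#'   term enriched in female-restricted genes and its attachment
#'   probabilities (female-only vs all other genes).
#' @param seed integer seed; every stage of the simulation is
#'   deterministic given the parameter block.
#' @return a validated list of class `simParams`.
#' @export
simParams <- function(nUnique = 140, nAllelePair = 20, nDuplicatePair = 10,
                      nAltSplice = 20, nChimeraSource = 10,
                      nFemaleOnly = 10, nMaleOnly = 10,
                      exonLenRange = c(300, 600), altSpliceExons = 3,
                      nIsoformRange = c(2, 3), readLenMean = 250,
                      readLenSd = 30, readLenMin = 80, depthMean = 100,
                      sexRatio = 0.41, alleleDivergence = c(0.03, 0.045),
                      alleleMergedFrac = 0.3,
                      mergedAlleleDivergence = c(0.005, 0.02),
                      duplicateIdentity = c(0.82, 0.93),
                      assemblerMergeIdentity = 0.97, tsTvWeight = 2,
                      indelRate = 0, singletonRate = 0.075,
                      discardRate = 0.057, snpRate = 0.003,
                      falseVariantRate = 0.5, varCoverageMean = 20,
                      noHomologFrac = 0.3,
                      dbNames = c("NR", "HomoloGene", "UniGeneChicken",
                                  "AnoCarEnsembl"),
                      dbPresence = c(1, 0.85, 0.75, 0.9),
                      leakageRate = 0, goTermPool = 30,
                      goTermsPerGene = c(1, 4),
                      goFemaleBiasTerm = "GO:0009058",
                      goFemaleBiasProb = 0.8, goBackgroundBiasProb = 0.15,
                      seed = 1) {
  p <- as.list(environment())
  counts <- c(p$nUnique, p$nAllelePair, p$nDuplicatePair, p$nAltSplice,
              p$nChimeraSource, p$nFemaleOnly, p$nMaleOnly)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (p$nFemaleOnly + p$nMaleOnly > p$nUnique)
    stop("sex-restricted genes must fit among the unique genes")
  if (p$assemblerMergeIdentity <= 0 || p$assemblerMergeIdentity > 1)
    stop("assemblerMergeIdentity must be in (0, 1]")
  if (any(p$alleleDivergence <= 0) || any(p$alleleDivergence > 0.20))
    stop("alleleDivergence must lie in (0, 0.20]")
  if (any(p$duplicateIdentity < 0.80) || any(p$duplicateIdentity >= 0.95))
    stop("duplicateIdentity must lie in [0.80, 0.95)")
  if (p$readLenMean > p$exonLenRange[1])
    stop("infeasible: mean read length exceeds the shortest segment")
  if (p$exonLenRange[1] < 90) stop("segments must be at least 90 bp")
  if (length(p$dbPresence) != length(p$dbNames))
    stop("dbPresence must match dbNames")
  if (p$sexRatio < 0 || p$sexRatio > 1 || p$singletonRate < 0 ||
      p$discardRate < 0 || p$singletonRate + p$discardRate >= 1)
    stop("rates must be probabilities with singleton + discard < 1")
  p$seed <- as.integer(p$seed)
  class(p) <- "simParams"
  p
}

#' Mutate a sequence to a target divergence
#'
#' Produces a diverged copy with exactly `round(divergence * L)` distinct
#' substituted sites (so the realized per-site difference is within
#' rounding of the target). Substitutions are transition-biased:
#' a transition is chosen with odds `tsTvWeight : 1` against a
#' transversion (the two transversion targets are then equally likely).
#' With `indelRate > 0`, single-base insertions/deletions are additionally
#' applied at that per-site rate.
#'
#' @param seq sequence (character scalar).
#' @param divergence target per-site difference fraction in `[0, 1)`.
#' @param tsTvWeight transition:transversion odds (> 0, default 2).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param indelRate per-site indel rate (default 0: substitutions only).
#' @return the mutated sequence (character scalar).
#' @export
mutateSequence <- function(seq, divergence, tsTvWeight = 2, seed = NULL,
                           indelRate = 0) {
  stopifnot(divergence >= 0, divergence < 1, tsTvWeight > 0)
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- round(divergence * L)
  if (k > 0) {
    pos <- sample.int(L, k)
    ts_of <- c(A = "G", G = "A", C = "T", T = "C")
    tv_of <- list(A = c("C", "T"), G = c("C", "T"),
                  C = c("A", "G"), T = c("A", "G"))
    is_ts <- runif(k) < tsTvWeight / (tsTvWeight + 1)
    for (i in seq_len(k)) {
      b <- chars[pos[i]]
      chars[pos[i]] <- if (is_ts[i]) ts_of[[b]]
        else sample(tv_of[[b]], 1)
    }
  }
  if (indelRate > 0) {
    n_ind <- rbinom(1, L, indelRate)
    for (i in seq_len(n_ind)) {
      p <- sample.int(length(chars), 1)
      if (runif(1) < 0.5) chars <- chars[-p]
      else chars <- append(chars, sample(c("A", "C", "G", "T"), 1), p)
    }
  }
  paste(chars, collapse = "")
}

#' Generate the gene set and its ground-truth ledger
#'
#' Builds the gene models for every category with exact requested counts:
#' unique genes (one segment), allele pairs (shared segment + two
#' divergent copies of a variable segment), duplicate pairs (shared
#' segment + two paralogous diverged regions), alternatively spliced
#' genes (codon-aligned exons with isoform paths sharing at least one
#' exon) and chimera-source genes. Segment sequences are complete reading
#' frames (ATG-opened, stop-closed, stop-free in between) so that every
#' contig carries a predictable ORF. Deterministic for a fixed seed.
#'
#' @param params a [simParams()] block.
#' @param seed seed (default `params$seed`); `NULL` uses the current RNG
#'   stream.
#' @return a list with `models` (list of gene models) and `genes` (the
#'   gene-level ground-truth data.frame: `gene_id`, `category`,
#'   `sex_bias`, `divergence`, `homolog`, `go_terms`).
#' @export
generateGeneSet <- function(params, seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  cats <- c(rep("unique", p$nUnique), rep("allele_pair", p$nAllelePair),
            rep("duplicate_pair", p$nDuplicatePair),
            rep("alt_splice", p$nAltSplice),
            rep("chimera_source", p$nChimeraSource))
  n <- length(cats)
  bias <- rep("none", n)
  if (p$nFemaleOnly + p$nMaleOnly > 0 && p$nUnique > 0) {
    pick <- sample.int(p$nUnique, p$nFemaleOnly + p$nMaleOnly)
    bias[pick[seq_len(p$nFemaleOnly)]] <- "female_only"
    if (p$nMaleOnly > 0)
      bias[pick[p$nFemaleOnly + seq_len(p$nMaleOnly)]] <- "male_only"
  }
  seg_len <- function() .codon_len(runif(1, p$exonLenRange[1],
                                         p$exonLenRange[2]))
  models <- vector("list", n)
  gene_rows <- vector("list", n)
  go_pool <- sprintf("GO:%07d", 8150 + seq_len(p$goTermPool) * 97)
  for (i in seq_len(n)) {
    gid <- sprintf("g%04d", i)
    cat_i <- cats[i]
    div <- 0
    segments <- list()
    isoforms <- NULL
    if (cat_i %in% c("unique", "chimera_source")) {
      segments[[1]] <- list(role = "single", copies = list(
        X = .rand_cds(seg_len(), open = TRUE, close = TRUE)))
    } else if (cat_i %in% c("allele_pair", "duplicate_pair")) {
      div <- if (cat_i == "duplicate_pair")
        1 - runif(1, p$duplicateIdentity[1], p$duplicateIdentity[2])
      else if (runif(1) < p$alleleMergedFrac)
        runif(1, p$mergedAlleleDivergence[1], p$mergedAlleleDivergence[2])
      else runif(1, p$alleleDivergence[1], p$alleleDivergence[2])
      shared <- .rand_cds(seg_len(), open = TRUE)
      va <- .rand_cds(seg_len(), close = TRUE)
      vb <- mutateSequence(va, div, p$tsTvWeight, seed = NULL,
                           indelRate = p$indelRate)
      segments[[1]] <- list(role = "shared", copies = list(X = shared))
      segments[[2]] <- list(role = "variable", copies = list(A = va, B = vb))
    } else {                            # alt_splice
      ne <- p$altSpliceExons
      for (e in seq_len(ne)) {
        segments[[e]] <- list(role = sprintf("exon%d", e), copies = list(
          X = .rand_cds(seg_len(), open = (e == 1), close = (e == ne))))
      }
      n_iso <- sample(seq(p$nIsoformRange[1], p$nIsoformRange[2]), 1)
      isoforms <- list(seq_len(ne), c(1L, ne))
      if (n_iso >= 3 && ne >= 3) isoforms[[3]] <- c(2L, ne)
      isoforms <- isoforms[seq_len(min(n_iso, length(isoforms)))]
    }
    has_homolog <- runif(1) >= p$noHomologFrac
    n_go <- sample(seq(p$goTermsPerGene[1], p$goTermsPerGene[2]), 1)
    terms <- sample(go_pool, n_go)
    bias_p <- if (bias[i] == "female_only") p$goFemaleBiasProb
      else p$goBackgroundBiasProb
    if (runif(1) < bias_p) terms <- union(terms, p$goFemaleBiasTerm)
    models[[i]] <- list(gene_id = gid, category = cat_i,
                        sex_bias = bias[i], segments = segments,
                        isoforms = isoforms, divergence = div)
    gene_rows[[i]] <- data.frame(
      gene_id = gid, category = cat_i, sex_bias = bias[i],
      divergence = div,
      homolog = if (has_homolog) sprintf("HG%04d", i) else NA_character_,
      go_terms = paste(sort(terms), collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(models = models,
       genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))))
}

## transcripts of a gene model: list of (transcript_id, segment indices,
## copy labels per segment)
.gene_transcripts <- function(model) {
  segs <- model$segments
  if (model$category %in% c("allele_pair", "duplicate_pair")) {
    list(list(id = "A", segs = 1:2, copies = c("X", "A")),
         list(id = "B", segs = 1:2, copies = c("X", "B")))
  } else if (model$category == "alt_splice") {
    lapply(seq_along(model$isoforms), function(k) {
      list(id = sprintf("iso%d", k), segs = model$isoforms[[k]],
           copies = rep("X", length(model$isoforms[[k]])))
    })
  } else {
    list(list(id = "T", segs = 1L, copies = "X"))
  }
}

.transcript_seq <- function(model, tr) {
  paste(vapply(seq_along(tr$segs), function(k)
    model$segments[[tr$segs[k]]]$copies[[tr$copies[k]]], ""),
    collapse = "")
}

#' Simulate sex-labelled reads
#'
#' Draws a Poisson number of reads per gene, placed uniformly along a
#' uniformly chosen transcript (allele copy or isoform), with normal read
#' lengths truncated so a read never exceeds the gene's shortest segment
#' (hence spans at most one segment boundary). Reads from sex-restricted
#' genes carry only that sex (unless `leakageRate > 0`); unbiased genes
#' draw female with probability `sexRatio`.
#'
#' @param models gene models from [generateGeneSet()].
#' @param params a [simParams()] block.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return a data.frame with one row per read: `read_id`, `gene_id`,
#'   `transcript_id`, `tstart`, `tlen`, `sex`, `junction` (does the read
#'   span a segment boundary).
#' @export
simulateReads <- function(models, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  stopifnot(length(models) >= 1)
  per_gene <- vector("list", length(models))
  for (gi in seq_along(models)) {
    model <- models[[gi]]
    trs <- .gene_transcripts(model)
    min_seg <- min(vapply(model$segments, function(s)
      nchar(s$copies[[1]]), integer(1)))
    seg_lens <- lapply(trs, function(tr)
      vapply(seq_along(tr$segs), function(k)
        nchar(model$segments[[tr$segs[k]]]$copies[[tr$copies[k]]]),
        integer(1)))
    n_reads <- rpois(1, p$depthMean)
    if (n_reads == 0) next
    tr_i <- sample.int(length(trs), n_reads, replace = TRUE)
    lens <- pmin(pmax(round(rnorm(n_reads, p$readLenMean, p$readLenSd)),
                      p$readLenMin), min_seg)
    sex <- if (model$sex_bias == "female_only") rep("F", n_reads)
      else if (model$sex_bias == "male_only") rep("M", n_reads)
      else ifelse(runif(n_reads) < p$sexRatio, "F", "M")
    if (model$sex_bias != "none" && p$leakageRate > 0) {
      flip <- runif(n_reads) < p$leakageRate
      sex[flip] <- ifelse(sex[flip] == "F", "M", "F")
    }
    tlen_tot <- vapply(seg_lens, sum, integer(1))
    total <- tlen_tot[tr_i]
    lens <- pmin(lens, total)
    start <- 1L + as.integer(floor(runif(n_reads) * (total - lens + 1)))
    first_bound <- vapply(seq_len(n_reads), function(r) {
      b <- cumsum(seg_lens[[tr_i[r]]])
      b[which(start[r] <= b)[1]]
    }, numeric(1))
    per_gene[[gi]] <- data.frame(
      read_id = NA_character_, gene_id = model$gene_id,
      transcript_id = vapply(trs, `[[`, "", "id")[tr_i],
      tstart = start, tlen = lens, sex = sex,
      junction = (start + lens - 1) > first_bound,
      stringsAsFactors = FALSE)
  }
  per_gene <- per_gene[!vapply(per_gene, is.null, logical(1))]
  if (!length(per_gene))
    stop("no reads generated; increase depthMean")
  out <- do.call(rbind, c(per_gene, list(make.row.names = FALSE)))
  out$read_id <- sprintf("r%06d", seq_len(nrow(out)))
  out
}

## draw an alternate base with transition:transversion odds w
.draw_alt <- function(ref, w) {
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  tv_of <- list(A = c("C", "T"), G = c("C", "T"),
                C = c("A", "G"), T = c("A", "G"))
  ifelse_v <- runif(length(ref)) < w / (w + 1)
  vapply(seq_along(ref), function(i) {
    if (ifelse_v[i]) ts_of[[ref[i]]] else sample(tv_of[[ref[i]]], 1)
  }, character(1))
}

#' Emulate the assembler on simulated reads
#'
#' Applies the emulation rules: (a) segment copy pairs at identity `>=
#' assemblerMergeIdentity` collapse to one contig and their differences
#' become SNP calls with simulated coverage (Poisson) and probability
#' (Beta(20, 1)); (b) pairs below it become separate contigs; (c) a read
#' spanning a boundary between segments is split into two placements;
#' (d) fractions of reads remain singletons or are discarded; (e) each
#' pair of chimera-source genes yields one planted chimera contig
#' concatenating half of each, with its own reads; (f) false variant
#' calls with Beta(2, 2) probability -- half of them homopolymer-adjacent
#' INDELs -- and true population SNPs (transition-biased at `tsTvWeight`)
#' are injected on contigs.
#'
#' @param models,params from [generateGeneSet()] / [simParams()].
#' @param reads read table from [simulateReads()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return a list with `contigs` (`DNAStringSet`), `singletons`
#'   (`DNAStringSet`), `readStatus` (read-status data.frame), `variants`
#'   (variant data.frame), and ground-truth tables `truthContigs`,
#'   `truthReads`, `truthVariants`, `truthComponents`, `truthChimeras`.
#' @export
emulateAssembly <- function(models, reads, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  contig_seqs <- character()
  contig_truth <- list()
  comp_truth <- list()
  counter <- 0L
  next_ctg <- function() {
    counter <<- counter + 1L
    sprintf("ctg%05d", counter)
  }
  ## (gene, segment, copy) -> contig id; copy X/A/B ("M" = merged)
  ctg_of <- new.env(hash = TRUE, parent = emptyenv())
  variants <- list()
  var_truth <- list()
  add_variant <- function(cid, pos, ref, alt, type, cov, prob, truth,
                          origin) {
    variants[[length(variants) + 1L]] <<- data.frame(
      contig_id = cid, position = as.integer(pos), ref_allele = ref,
      alt_allele = alt, var_type = type, coverage = as.integer(cov),
      probability = prob, stringsAsFactors = FALSE)
    var_truth[[length(var_truth) + 1L]] <<- data.frame(
      contig_id = cid, position = as.integer(pos), var_type = type,
      is_true = truth, origin = origin, stringsAsFactors = FALSE)
  }

  for (model in models) {
    gid <- model$gene_id
    for (si in seq_along(model$segments)) {
      seg <- model$segments[[si]]
      if (length(seg$copies) == 1) {
        cid <- next_ctg()
        contig_seqs[cid] <- seg$copies[[1]]
        assign(paste(gid, si, "X"), cid, envir = ctg_of)
        contig_truth[[cid]] <- data.frame(
          contig_id = cid, gene_id = gid, role = seg$role,
          stringsAsFactors = FALSE)
      } else {
        a <- seg$copies$A; b <- seg$copies$B
        ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
        same_len <- length(ca) == length(cb)
        ident <- if (same_len) mean(ca == cb) else
          overlapIdentity(a, b, minOverlap = 40)
        if (!is.na(ident) && ident >= p$assemblerMergeIdentity) {
          cid <- next_ctg()             # rule (a): collapse, emit variants
          contig_seqs[cid] <- a
          for (cp in c("A", "B"))
            assign(paste(gid, si, cp), cid, envir = ctg_of)
          contig_truth[[cid]] <- data.frame(
            contig_id = cid, gene_id = gid, role = "merged_variable",
            stringsAsFactors = FALSE)
          if (same_len) {
            for (pos in which(ca != cb))
              add_variant(cid, pos, ca[pos], cb[pos], "SNP",
                          rpois(1, p$varCoverageMean), rbeta(1, 20, 1),
                          TRUE, "allelic")
          }
        } else {                        # rule (b): separate contigs
          for (cp in c("A", "B")) {
            cid <- next_ctg()
            contig_seqs[cid] <- seg$copies[[cp]]
            assign(paste(gid, si, cp), cid, envir = ctg_of)
            contig_truth[[cid]] <- data.frame(
              contig_id = cid, gene_id = gid,
              role = paste0("variable_", cp), stringsAsFactors = FALSE)
          }
          ctype <- if (model$category == "allele_pair")
            "merged_alleles" else "duplicate_pair"
          comp_truth[[length(comp_truth) + 1L]] <- data.frame(
            gene_id = gid, ctype = ctype,
            members = paste(sort(c(get(paste(gid, si, "A"), ctg_of),
                                   get(paste(gid, si, "B"), ctg_of))),
                            collapse = ","), stringsAsFactors = FALSE)
        }
      }
    }
    if (model$category == "alt_splice") {
      mem <- sort(vapply(seq_along(model$segments), function(si)
        get(paste(gid, si, "X"), ctg_of), ""))
      comp_truth[[length(comp_truth) + 1L]] <- data.frame(
        gene_id = gid, ctype = "alt_splice",
        members = paste(mem, collapse = ","), stringsAsFactors = FALSE)
    }
  }

  ## planted chimeras: consecutive chimera-source gene pairs
  chim_models <- Filter(function(m) m$category == "chimera_source", models)
  chim_truth <- list()
  chim_reads <- list()
  n_chim <- length(chim_models) %/% 2
  read_counter <- nrow(reads)
  for (k in seq_len(n_chim)) {
    g1 <- chim_models[[2 * k - 1]]; g2 <- chim_models[[2 * k]]
    s1 <- g1$segments[[1]]$copies[[1]]; s2 <- g2$segments[[1]]$copies[[1]]
    h1 <- nchar(s1) %/% 2; h2 <- nchar(s2) %/% 2
    cid <- next_ctg()
    contig_seqs[cid] <- paste0(substr(s1, 1, h1),
                               substr(s2, h2 + 1, nchar(s2)))
    contig_truth[[cid]] <- data.frame(
      contig_id = cid, gene_id = sprintf("chimera%02d", k),
      role = "chimera", stringsAsFactors = FALSE)
    chim_truth[[k]] <- data.frame(
      chimera_id = sprintf("chimera%02d", k), contig_id = cid,
      gene_a = g1$gene_id, gene_b = g2$gene_id, breakpoint = h1,
      stringsAsFactors = FALSE)
    n_reads <- rpois(1, max(4, p$depthMean / 4))
    clen <- nchar(contig_seqs[cid])
    for (r in seq_len(n_reads)) {
      read_counter <- read_counter + 1L
      len <- min(clen, max(p$readLenMin,
                           round(rnorm(1, p$readLenMean, p$readLenSd))))
      start <- sample.int(clen - len + 1L, 1)
      chim_reads[[length(chim_reads) + 1L]] <- data.frame(
        read_id = sprintf("r%06d", read_counter),
        gene_id = sprintf("chimera%02d", k), contig_id = cid,
        cstart = start, tlen = len,
        sex = ifelse(runif(1) < p$sexRatio, "F", "M"),
        stringsAsFactors = FALSE)
    }
  }

  ## per-read status and placements (vectorised by gene+transcript group)
  model_of <- stats::setNames(models,
                              vapply(models, `[[`, "", "gene_id"))
  n <- nrow(reads)
  u <- runif(n)
  status <- ifelse(u < p$discardRate, "discarded",
                   ifelse(u < p$discardRate + p$singletonRate,
                          "singleton", "placed"))
  truth_reads <- reads[, c("read_id", "gene_id", "sex", "junction")]
  truth_reads$status <- status
  rs_status <- ifelse(status == "placed", "assembled", status)
  np <- ifelse(status == "placed", 1L, 0L)
  contig1 <- rep(NA_character_, n); contig2 <- rep(NA_character_, n)
  read_start1 <- rep(NA_integer_, n); read_end1 <- rep(NA_integer_, n)
  read_start2 <- rep(NA_integer_, n); read_end2 <- rep(NA_integer_, n)
  contig_start1 <- rep(NA_integer_, n); contig_start2 <- rep(NA_integer_, n)
  strand1 <- rep(NA_character_, n); strand2 <- rep(NA_character_, n)
  singleton_seqs <- character()
  grp <- paste(reads$gene_id, reads$transcript_id)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    model <- model_of[[reads$gene_id[idx[1]]]]
    tr <- NULL
    for (cand in .gene_transcripts(model))
      if (cand$id == reads$transcript_id[idx[1]]) { tr <- cand; break }
    seg_lens <- vapply(seq_along(tr$segs), function(k)
      nchar(model$segments[[tr$segs[k]]]$copies[[tr$copies[k]]]),
      integer(1))
    bounds <- cumsum(seg_lens)
    cids <- vapply(seq_along(tr$segs), function(k)
      get(paste(model$gene_id, tr$segs[k], tr$copies[k]), ctg_of), "")
    sing <- idx[status[idx] == "singleton"]
    if (length(sing)) {
      tseq <- .transcript_seq(model, tr)
      singleton_seqs[reads$read_id[sing]] <-
        substring(tseq, reads$tstart[sing],
                  reads$tstart[sing] + reads$tlen[sing] - 1)
    }
    pl <- idx[status[idx] == "placed"]
    if (!length(pl)) next
    ts <- reads$tstart[pl]; tl <- reads$tlen[pl]
    first_seg <- findInterval(ts - 1L, bounds) + 1L
    seg_start <- ts - c(0L, bounds)[first_seg]
    len1 <- pmin(tl, bounds[first_seg] - ts + 1L)
    contig1[pl] <- cids[first_seg]
    read_start1[pl] <- 1L
    read_end1[pl] <- as.integer(len1)
    strand1[pl] <- "+"
    contig_start1[pl] <- as.integer(seg_start)
    sp <- pl[len1 < tl]                 # rule (c): split reads
    if (length(sp)) {
      sp_len1 <- len1[len1 < tl]
      rs_status[sp] <- "partially_assembled"
      np[sp] <- 2L
      contig2[sp] <- cids[first_seg[len1 < tl] + 1L]
      read_start2[sp] <- as.integer(sp_len1 + 1L)
      read_end2[sp] <- as.integer(tl[len1 < tl])
      strand2[sp] <- "+"
      contig_start2[sp] <- 1L
    }
  }
  read_status <- data.frame(
    read_id = reads$read_id, sex = reads$sex, status = rs_status,
    n_placements = np, contig1 = contig1, read_start1 = read_start1,
    read_end1 = read_end1, strand1 = strand1,
    contig_start1 = contig_start1, contig2 = contig2,
    read_start2 = read_start2, read_end2 = read_end2, strand2 = strand2,
    contig_start2 = contig_start2, stringsAsFactors = FALSE)
  if (length(chim_reads)) {
    cr <- do.call(rbind, c(chim_reads, list(make.row.names = FALSE)))
    read_status <- rbind(read_status, data.frame(
      read_id = cr$read_id, sex = cr$sex, status = "assembled",
      n_placements = 1L, contig1 = cr$contig_id, read_start1 = 1L,
      read_end1 = as.integer(cr$tlen), strand1 = "+",
      contig_start1 = as.integer(cr$cstart), contig2 = NA_character_,
      read_start2 = NA_integer_, read_end2 = NA_integer_,
      strand2 = NA_character_, contig_start2 = NA_integer_,
      stringsAsFactors = FALSE))
    truth_reads <- rbind(truth_reads, data.frame(
      read_id = cr$read_id, gene_id = cr$gene_id, sex = cr$sex,
      junction = FALSE, status = "placed", stringsAsFactors = FALSE))
  }

  ## true population SNPs and injected false calls on every non-chimera
  ## contig
  used_pos <- new.env(hash = TRUE, parent = emptyenv())
  mark <- function(cid, pos) {
    key <- paste(cid, pos)
    if (exists(key, used_pos, inherits = FALSE)) return(FALSE)
    assign(key, TRUE, used_pos)
    TRUE
  }
  for (v in variants) mark(v$contig_id, v$position)
  roles <- vapply(contig_truth, function(x) x$role, "")
  for (ci in seq_along(contig_seqs)) {
    cid <- names(contig_seqs)[ci]
    if (roles[ci] == "chimera") next
    s <- contig_seqs[[cid]]
    len <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    n_true <- rpois(1, p$snpRate * len)
    for (j in seq_len(n_true)) {
      pos <- sample.int(len, 1)
      if (!mark(cid, pos)) next
      add_variant(cid, pos, chars[pos], .draw_alt(chars[pos], p$tsTvWeight),
                  "SNP", rpois(1, p$varCoverageMean), rbeta(1, 20, 1),
                  TRUE, "population")
    }
    n_false <- rpois(1, p$falseVariantRate)
    if (n_false > 0) {
      r <- rle(chars)
      ends <- cumsum(r$lengths)
      hp <- which(r$lengths >= 3)
      for (j in seq_len(n_false)) {
        cov <- if (runif(1) < 0.3) rpois(1, 3) else
          rpois(1, p$varCoverageMean)
        prob <- rbeta(1, 2, 2)
        if (runif(1) < 0.5 && length(hp)) {   # homopolymer-adjacent INDEL
          run <- hp[sample.int(length(hp), 1)]
          pos <- sample(seq(ends[run] - r$lengths[run] + 1, ends[run]), 1)
          if (!mark(cid, pos)) next
          if (runif(1) < 0.5)
            add_variant(cid, pos, chars[pos], "-", "DEL", cov, prob,
                        FALSE, "injected_indel")
          else
            add_variant(cid, pos, "-", chars[pos], "INS", cov, prob,
                        FALSE, "injected_indel")
        } else {
          pos <- sample.int(len, 1)
          if (!mark(cid, pos)) next
          add_variant(cid, pos, chars[pos], .draw_alt(chars[pos], 1),
                      "SNP", cov, prob, FALSE, "injected_snp")
        }
      }
    }
  }

  empty_var <- data.frame(
    contig_id = character(), position = integer(), ref_allele = character(),
    alt_allele = character(), var_type = character(), coverage = integer(),
    probability = numeric(), stringsAsFactors = FALSE)
  list(
    contigs = Biostrings::DNAStringSet(contig_seqs),
    singletons = Biostrings::DNAStringSet(singleton_seqs),
    readStatus = read_status,
    variants = if (length(variants))
      do.call(rbind, c(variants, list(make.row.names = FALSE)))
      else empty_var,
    truthContigs = do.call(rbind, c(contig_truth,
                                    list(make.row.names = FALSE))),
    truthReads = truth_reads,
    truthVariants = if (length(var_truth))
      do.call(rbind, c(var_truth, list(make.row.names = FALSE)))
      else empty_var[, c("contig_id", "position", "var_type")],
    truthComponents = if (length(comp_truth))
      do.call(rbind, c(comp_truth, list(make.row.names = FALSE)))
      else data.frame(gene_id = character(), ctype = character(),
                      members = character(), stringsAsFactors = FALSE),
    truthChimeras = if (length(chim_truth))
      do.call(rbind, c(chim_truth, list(make.row.names = FALSE)))
      else data.frame(chimera_id = character(), contig_id = character(),
                      gene_a = character(), gene_b = character(),
                      breakpoint = integer(), stringsAsFactors = FALSE))
}

#' Simulate homology hits for emulated contigs and singletons
#'
#' Noise-free homology evidence consistent with the ground truth: genes
#' flagged as having no homologue receive no hits; all contigs of one
#' gene (shared, allele copies, exons) hit the same subject accession;
#' the two diverged regions of a duplicate pair hit different paralog
#' accessions; a chimera contig receives two strong hits to its two
#' source genes' accessions on disjoint halves of the query. Singleton
#' reads hit their gene's accession. E-values scale with match length
#' (exponent ~ 0.18 per aligned bp), per database, with genes present in
#' each database per `dbPresence`.
#'
#' @param asm result of [emulateAssembly()].
#' @param genes gene-level ground truth from [generateGeneSet()].
#' @param params a [simParams()] block.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return a blast-hit data.frame ([readTabular()] schema `"blast"`).
#' @export
simulateBlastHits <- function(asm, genes, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  evalue_of <- function(len) 10^(-pmin(180, round(0.18 * len)))
  rows <- list()
  add_hit <- function(db, qid, sid, qs, qe) {
    len <- qe - qs + 1
    rows[[length(rows) + 1L]] <<- data.frame(
      db_name = db, query_id = qid, subject_id = sid,
      percent_identity = round(runif(1, 85, 99.9), 1),
      align_length = as.integer(len), mismatches = 0L, gap_opens = 0L,
      query_start = as.integer(qs), query_end = as.integer(qe),
      subject_start = 1L, subject_end = as.integer(len),
      evalue = evalue_of(len), bitscore = round(1.9 * len, 1),
      stringsAsFactors = FALSE)
  }
  ## per-gene, per-db presence draws (deterministic order)
  pres <- matrix(runif(nrow(genes) * length(p$dbNames)) <
                   rep(p$dbPresence, each = nrow(genes)),
                 nrow = nrow(genes),
                 dimnames = list(genes$gene_id, p$dbNames))
  acc <- function(db, gene_id, paralog = "") {
    base <- genes$homolog[match(gene_id, genes$gene_id)]
    if (is.na(base)) NA_character_
    else paste0(db, "_", base, paralog)
  }
  contig_len <- nchar(as.character(asm$contigs))
  tc <- asm$truthContigs
  gene_cat <- stats::setNames(genes$category, genes$gene_id)
  for (i in seq_len(nrow(tc))) {
    cid <- tc$contig_id[i]
    gid <- tc$gene_id[i]
    clen <- contig_len[[cid]]
    if (tc$role[i] == "chimera") {
      ch <- asm$truthChimeras
      ch <- ch[ch$contig_id == cid, ]
      bp <- ch$breakpoint
      for (db in p$dbNames) {
        sa <- acc(db, ch$gene_a); sb <- acc(db, ch$gene_b)
        if (!is.na(sa) && pres[ch$gene_a, db])
          add_hit(db, cid, sa, 1, bp)
        if (!is.na(sb) && pres[ch$gene_b, db])
          add_hit(db, cid, sb, bp + 1, clen)
      }
      next
    }
    paralog <- if (gene_cat[[gid]] == "duplicate_pair" &&
                   tc$role[i] %in% c("variable_B", "merged_variable"))
      "b" else if (gene_cat[[gid]] == "duplicate_pair") "a" else ""
    for (db in p$dbNames) {
      sid <- acc(db, gid, paralog)
      if (is.na(sid) || !pres[gid, db]) next
      add_hit(db, cid, sid, 1, clen)
    }
  }
  singles <- asm$truthReads[asm$truthReads$status == "singleton", ,
                            drop = FALSE]
  singles <- singles[!grepl("^chimera", singles$gene_id), , drop = FALSE]
  slen <- nchar(as.character(asm$singletons))
  for (i in seq_len(nrow(singles))) {
    gid <- singles$gene_id[i]
    rid <- singles$read_id[i]
    paralog <- if (gene_cat[[gid]] == "duplicate_pair") "a" else ""
    for (db in p$dbNames) {
      sid <- acc(db, gid, paralog)
      if (is.na(sid) || !pres[gid, db]) next
      add_hit(db, rid, sid, 1, slen[[rid]])
    }
  }
  if (!length(rows)) {
    return(data.frame(
      db_name = character(), query_id = character(),
      subject_id = character(), percent_identity = numeric(),
      align_length = integer(), mismatches = integer(),
      gap_opens = integer(), query_start = integer(),
      query_end = integer(), subject_start = integer(),
      subject_end = integer(), evalue = numeric(), bitscore = numeric(),
      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the full simulation
#'
#' Generates the gene set, reads, emulated assembly, homology hits, GO
#' map and ORF records, bundled with the complete ground-truth ledger.
#' Byte-identical output for identical parameters (the seed lives in the
#' parameter block).
#'
#' @param params a [simParams()] block.
#' @return a [SimulatedAssembly-class] object.
#' @examples
#' study <- simulateStudy(simParams(nUnique = 10, nAllelePair = 2,
#'   nDuplicatePair = 1, nAltSplice = 2, nChimeraSource = 2,
#'   nFemaleOnly = 1, nMaleOnly = 1, depthMean = 30, seed = 7))
#' study
#' @export
simulateStudy <- function(params) {
  stopifnot(inherits(params, "simParams"))
  gs <- generateGeneSet(params, seed = params$seed)
  reads <- simulateReads(gs$models, params, seed = NULL)
  asm <- emulateAssembly(gs$models, reads, params, seed = NULL)
  hits <- simulateBlastHits(asm, gs$genes, params, seed = NULL)
  ## GO map: contigs inherit their gene's terms
  tc <- asm$truthContigs
  go_rows <- list()
  terms_of <- strsplit(stats::setNames(gs$genes$go_terms, gs$genes$gene_id),
                       ",", fixed = TRUE)
  for (i in seq_len(nrow(tc))) {
    if (grepl("^chimera", tc$gene_id[i])) next
    tm <- terms_of[[tc$gene_id[i]]]
    if (length(tm))
      go_rows[[length(go_rows) + 1L]] <- data.frame(
        seq_id = tc$contig_id[i], term_id = tm, stringsAsFactors = FALSE)
  }
  go_map <- unique(do.call(rbind, c(go_rows, list(make.row.names = FALSE))))
  orfs <- findLongestOrfs(asm$contigs)
  truth <- list(genes = gs$genes, contigs = asm$truthContigs,
                reads = asm$truthReads, variants = asm$truthVariants,
                components = asm$truthComponents,
                chimeras = asm$truthChimeras)
  new("SimulatedAssembly", contigs = asm$contigs,
      singletons = asm$singletons, readStatus = asm$readStatus,
      variants = asm$variants, blastHits = hits, orfs = orfs,
      goMap = go_map, truth = truth, params = unclass(params))
}

#' Write a simulated study to disk
#'
#' Writes the full input file set ([readFasta()], [readReadStatus()],
#' [readTabular()] formats) plus the ground-truth tables and a YAML echo
#' of the simulation parameters.
#'
#' @param study a [SimulatedAssembly-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  writeFasta(studyContigs(study), fp("contigs.fasta"))
  if (length(studySingletons(study)))
    writeFasta(studySingletons(study), fp("singletons.fasta"))
  writeReadStatus(studyReadStatus(study), fp("read_status.tsv"))
  writeTabular(studyVariants(study), fp("variants.tsv"), "variant")
  writeTabular(studyBlastHits(study), fp("blast.tsv"), "blast")
  writeTabular(studyOrfs(study), fp("orfs.bed"), "orf")
  writeTabular(studyGoMap(study), fp("go_map.tsv"), "go")
  tr <- groundTruth(study)
  for (nm in names(tr))
    write.table(tr[[nm]], fp(paste0("ground_truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(study@params, fp("params.yaml"))
  invisible(dir)
}
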