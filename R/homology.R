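## Homology clustering at e-value cut-offs, unique-homologue counting,
## per-database presence sets, chimera detection, singleton rescue.

#' Cluster sequences by shared homology hits
#'
#' Groups sequences (contigs and singletons) by the subject accession
#' they hit in one database at an e-value cut-off. A sequence joins every
#' cluster it hits, so multi-membership is possible and is reported
#' separately (sequences in two or more clusters typically belong to gene
#' families or carry a strong shared domain).
#'
#' @param hits blast-hit data.frame.
#' @param db database name.
#' @param cutoff qualifying e-value (`evalue <= cutoff`).
#' @return a list with `clusters` (data.frame `subject_id`, `members`
#'   comma-joined, `n_members`) and `multiMembership` (data.frame
#'   `seq_id`, `n_clusters` for sequences in 2+ clusters).
#' @export
clusterByHomolog <- function(hits, db, cutoff) {
  h <- hits[hits$db_name == db & hits$evalue <= cutoff, , drop = FALSE]
  pairs <- unique(h[, c("subject_id", "query_id")])
  cl <- lapply(split(pairs$query_id, pairs$subject_id),
               function(x) sort(unique(x)))
  clusters <- data.frame(
    subject_id = names(cl),
    members = vapply(cl, paste, "", collapse = ","),
    n_members = lengths(cl), stringsAsFactors = FALSE, row.names = NULL)
  clusters <- clusters[order(clusters$subject_id), , drop = FALSE]
  memb <- table(pairs$query_id)
  multi <- memb[memb >= 2]
  list(clusters = clusters,
       multiMembership = data.frame(
         seq_id = names(multi), n_clusters = as.integer(multi),
         stringsAsFactors = FALSE, row.names = NULL))
}

#' Count unique homologues per database and cut-off
#'
#' Number of distinct subject accessions with at least one qualifying hit,
#' for every database and e-value cut-off. Counts are monotone
#' non-increasing as the cut-off tightens.
#'
#' @param hits blast-hit data.frame.
#' @param cutoffs e-value cut-offs (default the ladder
#'   `1e-5, 1e-10, 1e-20, 1e-50`).
#' @return a data.frame with one row per database present in `hits` and
#'   one column per cut-off (named e.g. `"1e-05"`), zero rows allowed.
#' @export
uniqueHomologCounts <- function(hits,
                                cutoffs = c(1e-5, 1e-10, 1e-20, 1e-50)) {
  dbs <- sort(unique(hits$db_name))
  out <- data.frame(db_name = dbs, stringsAsFactors = FALSE)
  for (ct in cutoffs) {
    out[[format(ct)]] <- vapply(dbs, function(db) {
      length(unique(hits$subject_id[hits$db_name == db &
                                    hits$evalue <= ct]))
    }, integer(1))
  }
  out
}

#' Per-sequence database presence sets
#'
#' For each query sequence, the subset of databases in which it has at
#' least one qualifying hit, plus aggregate counts per subset (the
#' regions of a Venn diagram). Regions partition the annotated sequences:
#' the region counts sum to the number of sequences with at least one
#' hit.
#'
#' @param hits blast-hit data.frame.
#' @param dbs databases to consider (default: all present).
#' @param cutoff qualifying e-value.
#' @return a list with `presence` (data.frame `seq_id`, `dbs`
#'   comma-joined) and `regions` (data.frame `region`, `count`).
#' @export
presenceVenn <- function(hits, dbs = NULL, cutoff = 1e-5) {
  if (is.null(dbs)) dbs <- sort(unique(hits$db_name))
  h <- hits[hits$db_name %in% dbs & hits$evalue <= cutoff, , drop = FALSE]
  pres <- lapply(split(h$db_name, h$query_id),
                 function(x) paste(sort(unique(x)), collapse = ","))
  presence <- data.frame(seq_id = names(pres),
                         dbs = unlist(pres, use.names = FALSE),
                         stringsAsFactors = FALSE)
  presence <- presence[order(presence$seq_id), , drop = FALSE]
  reg <- table(presence$dbs)
  list(presence = presence,
       regions = data.frame(region = names(reg), count = as.integer(reg),
                            stringsAsFactors = FALSE, row.names = NULL))
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Detect chimeric contigs from homology hits
#'
#' A sequence is flagged as a putative chimera when it has two highly
#' significant hits (`evalue < evalueMax`, default 1e-20) to *different*
#' subject accessions that align to different ends of the query: the two
#' query intervals overlap by at most `maxOverlapFrac` of the shorter
#' interval and their midpoints fall in opposite halves of the query.
#' Subject-accession pairs on the `whitelist` are never called (adjacent
#' genes co-transcribed in one molecule, e.g. mitochondrial gene pairs,
#' are correct assemblies, not chimeras). One call is emitted per
#' sequence (the pair with the smallest combined e-value).
#'
#' @param hits blast-hit data.frame for one database (rows from other
#'   databases are ignored via `db`).
#' @param queryLengths named integer vector of query sequence lengths.
#' @param db database to use (default `"NR"`).
#' @param evalueMax significance bound (strict `<`).
#' @param maxOverlapFrac maximum mutual overlap as a fraction of the
#'   shorter interval (default 0.2).
#' @param whitelist optional character vector of exempt subject pairs,
#'   each written `"subjA|subjB"` in either order.
#' @return a data.frame with one row per chimeric sequence: `seq_id`,
#'   `subject_a`, `subject_b`, `evalue_a`, `evalue_b`, `qstart_a`,
#'   `qend_a`, `qstart_b`, `qend_b`, `query_gap`, `reason`.
#' @export
detectChimeras <- function(hits, queryLengths, db = "NR",
                           evalueMax = 1e-20, maxOverlapFrac = 0.2,
                           whitelist = NULL) {
  h <- hits[hits$db_name == db & hits$evalue < evalueMax, , drop = FALSE]
  if (!is.null(whitelist)) {
    parts <- strsplit(whitelist, "|", fixed = TRUE)
    whitelist <- vapply(parts, function(p) .pair_key(p[1], p[2]), "")
  }
  rows <- list()
  for (q in sort(unique(h$query_id))) {
    hq <- h[h$query_id == q, , drop = FALSE]
    if (nrow(hq) < 2 || is.na(queryLengths[q])) next
    qlen <- queryLengths[[q]]
    best <- NULL
    for (i in seq_len(nrow(hq) - 1)) for (j in seq(i + 1, nrow(hq))) {
      if (hq$subject_id[i] == hq$subject_id[j]) next
      if (!is.null(whitelist) &&
          .pair_key(hq$subject_id[i], hq$subject_id[j]) %in% whitelist)
        next
      s1 <- hq$query_start[i]; e1 <- hq$query_end[i]
      s2 <- hq$query_start[j]; e2 <- hq$query_end[j]
      ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
      shorter <- min(e1 - s1 + 1, e2 - s2 + 1)
      if (ov > maxOverlapFrac * shorter) next
      mid1 <- (s1 + e1) / 2; mid2 <- (s2 + e2) / 2
      half <- qlen / 2
      opposite <- (min(mid1, mid2) < half) && (max(mid1, mid2) > half)
      if (!opposite) next
      score <- hq$evalue[i] + hq$evalue[j]
      if (is.null(best) || score < best$score)
        best <- list(i = i, j = j, score = score, gap = max(s1, s2) -
                       min(e1, e2) - 1)
    }
    if (!is.null(best)) {
      i <- best$i; j <- best$j
      if (hq$query_start[i] > hq$query_start[j]) { tmp <- i; i <- j; j <- tmp }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = q, subject_a = hq$subject_id[i],
        subject_b = hq$subject_id[j], evalue_a = hq$evalue[i],
        evalue_b = hq$evalue[j], qstart_a = hq$query_start[i],
        qend_a = hq$query_end[i], qstart_b = hq$query_start[j],
        qend_b = hq$query_end[j], query_gap = as.integer(best$gap),
        reason = sprintf(
          "two hits < %g to different subjects at opposite ends",
          evalueMax), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(), subject_a = character(),
                      subject_b = character(), evalue_a = numeric(),
                      evalue_b = numeric(), qstart_a = integer(),
                      qend_a = integer(), qstart_b = integer(),
                      qend_b = integer(), query_gap = integer(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## k-mer seed index: sequences sharing no exact k-mer with a contig are
## never aligned against it
.kmer_index <- function(seqs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (id in names(seqs)) {
    s <- seqs[[id]]
    n <- nchar(s)
    if (n < k) next
    kmers <- unique(substring(s, 1:(n - k + 1), k:n))
    for (km in kmers) {
      if (exists(km, envir = env, inherits = FALSE))
        assign(km, c(get(km, envir = env), id), envir = env)
      else assign(km, id, envir = env)
    }
  }
  env
}

#' Rescue singletons by alignment to contigs
#'
#' Attempts to place each singleton read on a contig: the best local
#' alignment (same scoring as [overlapIdentity()]) must reach
#' `minIdentity` percent identity over the aligned span (gap columns
#' count against identity) and leave fewer than `maxUnaligned` singleton
#' bases unaligned at *both* the 5' and 3' ends. At most one mapping is
#' emitted per singleton: best identity, ties broken by longer aligned
#' span, then lexicographically smallest contig id.
#'
#' Candidate contigs are pre-screened by exact shared `seedK`-mers, so
#' wholly unrelated pairs are never aligned.
#'
#' @param singletons,contigs named sequences (`DNAStringSet` or
#'   character).
#' @param minIdentity percent identity threshold (default 95).
#' @param maxUnaligned maximum unaligned bases tolerated at each end
#'   (strict `<`; default 10).
#' @param seedK seed k-mer length for candidate screening (default 16).
#' @return a data.frame `read_id`, `contig_id`, `identity` (percent),
#'   `unaligned_5p`, `unaligned_3p`, `aligned_cols`.
#' @export
mapSingletons <- function(singletons, contigs, minIdentity = 95,
                          maxUnaligned = 10, seedK = 16) {
  singletons <- .seq_chr(singletons)
  contigs <- .seq_chr(contigs)
  idx <- .kmer_index(contigs, seedK)
  rows <- list()
  for (rid in names(singletons)) {
    s <- singletons[[rid]]
    n <- nchar(s)
    if (n < seedK) next
    pos <- unique(c(seq(1, n - seedK + 1, by = seedK), n - seedK + 1))
    cand <- unique(unlist(lapply(substring(s, pos, pos + seedK - 1),
                                 function(km) {
                                   if (exists(km, envir = idx, inherits = FALSE))
                                     get(km, envir = idx) else NULL
                                 }), use.names = FALSE))
    best <- NULL
    for (cid in sort(cand)) {
      aln <- alignPair(s, contigs[[cid]], "local")
      if (aln$columns == 0) next
      ident <- 100 * aln$matches / aln$columns
      un5 <- aln$a_start - 1
      un3 <- n - aln$a_end
      if (ident < minIdentity || un5 >= maxUnaligned || un3 >= maxUnaligned)
        next
      key <- c(ident, aln$columns)     # larger is better; cid ties by order
      if (is.null(best) || .lex_gt(key, best$key))
        best <- list(key = key, cid = cid, ident = ident, un5 = un5,
                     un3 = un3, cols = aln$columns)
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = rid, contig_id = best$cid, identity = best$ident,
        unaligned_5p = as.integer(best$un5),
        unaligned_3p = as.integer(best$un3),
        aligned_cols = as.integer(best$cols), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(read_id = character(), contig_id = character(),
                      identity = numeric(), unaligned_5p = integer(),
                      unaligned_3p = integer(), aligned_cols = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
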