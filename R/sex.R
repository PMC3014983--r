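## Sex-of-origin classification of contigs and singletons, sex-specific
## gene calling at an e-value ladder, Fisher exact GO enrichment.

#' Classify contigs and singletons by sex-of-origin
#'
#' A contig is a female contig (`FC`) when every read placed on it is
#' female, a male contig (`MC`) when every read is male, and a both
#' contig (`BC`) otherwise. A read split between two contigs contributes
#' its sex to both. Singletons carry the sex of their single read.
#'
#' @param readStatus read-status data.frame ([readReadStatus()]).
#' @param contigs optional character vector of contig ids that must all
#'   be classifiable; a listed contig with no placed read is an error.
#' @return a list with `contigs` (data.frame `contig_id`, `class` in
#'   FC/MC/BC, `n_reads`) and `singletons` (data.frame `read_id`, `sex`).
#' @export
classifySequences <- function(readStatus, contigs = NULL) {
  placed <- readStatus[readStatus$n_placements >= 1, , drop = FALSE]
  cid <- c(placed$contig1, placed$contig2)
  sex <- c(placed$sex, placed$sex)
  keep <- !is.na(cid)
  cid <- cid[keep]; sex <- sex[keep]
  if (!is.null(contigs)) {
    missing <- setdiff(contigs, cid)
    if (length(missing))
      stop("contig(s) with no placed read cannot be classified: ",
           paste(head(missing, 5), collapse = ", "))
  }
  nf <- table(factor(cid)[sex == "F"])
  tot <- table(factor(cid))
  ids <- names(tot)
  f_n <- as.integer(nf[ids]); f_n[is.na(f_n)] <- 0L
  t_n <- as.integer(tot)
  cls <- ifelse(f_n == t_n, "FC", ifelse(f_n == 0L, "MC", "BC"))
  singles <- readStatus[readStatus$status == "singleton", , drop = FALSE]
  list(
    contigs = data.frame(contig_id = ids, class = cls, n_reads = t_n,
                         stringsAsFactors = FALSE),
    singletons = data.frame(read_id = singles$read_id, sex = singles$sex,
                            stringsAsFactors = FALSE))
}

#' Call sex-specific genes from homology evidence
#'
#' A gene (subject accession) is called female-specific when at least one
#' female contig or female singleton hits it at `evalue <= strictCutoff`
#' *and* no male or both-sexes sequence hits it anywhere down the e-value
#' ladder (`evalue <= screenCutoff`); symmetrically for male-specific.
#' Both-sexes contigs carry reads of both sexes, so any BC hit
#' disqualifies specificity and counts as evidence for both sides. A gene
#' with qualifying evidence from both sides is `shared`; a gene whose
#' evidence clears neither rule is `insufficient`.
#'
#' @param hits blast-hit data.frame restricted to one database (rows from
#'   other databases are an error).
#' @param classes result of [classifySequences()].
#' @param strictCutoff e-value a focal-sex hit must reach (default 1e-50).
#' @param screenCutoff loosest e-value at which an opposite-sex hit
#'   disqualifies (default 1e-5).
#' @return a data.frame with one row per subject accession: `subject_id`,
#'   `call` (`female_specific`/`male_specific`/`shared`/`insufficient`),
#'   `female_seqs`, `male_seqs`, `both_seqs` (comma-joined supporting
#'   sequence ids at the screen cut-off), `best_female_evalue`,
#'   `best_male_evalue`.
#' @export
callSexSpecific <- function(hits, classes, strictCutoff = 1e-50,
                            screenCutoff = 1e-5) {
  if (length(unique(hits$db_name)) > 1)
    stop("hits must be restricted to a single database")
  side <- rep(NA_character_, nrow(hits))
  m <- match(hits$query_id, classes$contigs$contig_id)
  side[!is.na(m)] <- c(FC = "F", MC = "M", BC = "B")[
    classes$contigs$class[m[!is.na(m)]]]
  m2 <- match(hits$query_id, classes$singletons$read_id)
  side[is.na(side) & !is.na(m2)] <-
    classes$singletons$sex[m2[is.na(side) & !is.na(m2)]]
  mask <- !is.na(side) & hits$evalue <= screenCutoff
  h <- hits[mask, , drop = FALSE]
  side <- side[mask]
  if (!nrow(h)) {
    return(data.frame(subject_id = character(), call = character(),
                      female_seqs = character(), male_seqs = character(),
                      both_seqs = character(),
                      best_female_evalue = numeric(),
                      best_male_evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(split(seq_len(nrow(h)), h$subject_id), function(idx) {
    s <- side[idx]
    e <- h$evalue[idx]
    q <- h$query_id[idx]
    f_weak <- any(s == "F"); m_weak <- any(s == "M"); b_weak <- any(s == "B")
    f_strong <- any(s == "F" & e <= strictCutoff)
    m_strong <- any(s == "M" & e <= strictCutoff)
    call <- if (f_strong && !m_weak && !b_weak) "female_specific"
      else if (m_strong && !f_weak && !b_weak) "male_specific"
      else if (b_weak || (f_weak && m_weak)) "shared"
      else "insufficient"
    data.frame(
      subject_id = h$subject_id[idx[1]], call = call,
      female_seqs = paste(sort(unique(q[s == "F"])), collapse = ","),
      male_seqs = paste(sort(unique(q[s == "M"])), collapse = ","),
      both_seqs = paste(sort(unique(q[s == "B"])), collapse = ","),
      best_female_evalue = if (f_weak) min(e[s == "F"]) else NA_real_,
      best_male_evalue = if (m_weak) min(e[s == "M"]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out[order(out$subject_id), , drop = FALSE]
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value by the point-probability rule: with margins
#' fixed, the hypergeometric probabilities of all tables whose point
#' probability does not exceed that of the observed table (within
#' relative tolerance 1e-12) are summed. A one-sided variant (upper tail
#' of the first cell) is available.
#'
#' @param table a 2x2 matrix of non-negative integer counts (all-zero
#'   tables are an error).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return the p-value.
#' @examples
#' fisherExact(matrix(c(5, 0, 0, 5), 2))  # 2/choose(10,5)
#' @export
fisherExact <- function(table, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  n <- sum(table)
  if (n == 0) stop("all-zero table")
  m1 <- sum(table[1, ])                 # row 1 margin
  k <- sum(table[, 1])                  # column 1 margin
  x <- table[1, 1]
  support <- max(0, k - (n - m1)):min(k, m1)
  probs <- dhyper(support, m1, n - m1, k)
  if (alternative == "greater")
    return(sum(probs[support >= x]))
  p_obs <- dhyper(x, m1, n - m1, k)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' (`q_(i) = min_{j >= i} m p_(j) / j`, capped at 1), mapped back to the
#' input order. Delegates to [stats::p.adjust()].
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bhFdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' GO-term enrichment between two gene sets
#'
#' One Fisher exact test per GO term annotated to at least one member of
#' either set, on the 2x2 table (annotated-with-term vs other) x (set A
#' vs set B), with Benjamini-Hochberg correction across terms. Two-sided
#' by default, so the results are invariant to swapping the set labels.
#'
#' @param setA,setB character vectors of sequence/gene ids.
#' @param annotations GO map data.frame (`seq_id`, `term_id`;
#'   [readTabular()] schema `"go"`).
#' @param alternative passed to [fisherExact()].
#' @return a data.frame `term_id`, `a_with`, `a_without`, `b_with`,
#'   `b_without`, `p_value`, `q_value`, sorted by q then p.
#' @export
goEnrichment <- function(setA, setB, annotations,
                         alternative = "two.sided") {
  setA <- unique(setA); setB <- unique(setB)
  ann <- annotations[annotations$seq_id %in% c(setA, setB), , drop = FALSE]
  if (!length(intersect(ann$seq_id, setA)) ||
      !length(intersect(ann$seq_id, setB)))
    stop("annotations must cover at least one member of each set")
  terms <- sort(unique(ann$term_id))
  rows <- lapply(terms, function(tm) {
    with_term <- unique(ann$seq_id[ann$term_id == tm])
    aw <- sum(setA %in% with_term); bw <- sum(setB %in% with_term)
    tab <- matrix(c(aw, length(setA) - aw, bw, length(setB) - bw), 2,
                  byrow = FALSE)
    data.frame(term_id = tm, a_with = aw, a_without = length(setA) - aw,
               b_with = bw, b_without = length(setB) - bw,
               p_value = fisherExact(tab, alternative),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q_value <- bhFdr(out$p_value)
  out[order(out$q_value, out$p_value, out$term_id), , drop = FALSE]
}
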