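## Variant filtering and per-contig selection screens: TS/TV, Ka/Ks on
## raw polymorphism counts with +1 smoothing, variant density, percentile
## flagging, length regression, candidate intersection, ORF scanning.

#' Filter variant calls
#'
#' High-confidence filtering of SNP/INDEL calls: a call is removed iff its
#' read coverage is `< minCov` or `> maxCov`, or its posterior probability
#' is `< minProb` (all strict inequalities, so coverage 5 or 100 and
#' probability 0.9 survive). Additionally any INS/DEL whose position lies
#' inside, or immediately adjacent to, a run of at least `homopolymerLen`
#' identical bases is removed -- homopolymer INDELs are the dominant
#' pyrosequencing artefact. The filter is idempotent.
#'
#' @param variants validated variant data.frame ([readTabular()]).
#' @param contigs named contig sequences (`DNAStringSet` or character);
#'   needed for the homopolymer check. A variant referencing an unknown
#'   contig is an error.
#' @param minCov,maxCov coverage bounds (defaults 5 and 100).
#' @param minProb probability floor (default 0.9).
#' @param homopolymerLen minimum run length that defines a homopolymer
#'   region (default 3, the conventional pyrosequencing trouble
#'   threshold).
#' @return the surviving rows of `variants`, order preserved.
#' @export
filterVariants <- function(variants, contigs, minCov = 5, maxCov = 100,
                           minProb = 0.9, homopolymerLen = 3) {
  contigs <- .seq_chr(contigs)
  unknown <- setdiff(unique(variants$contig_id), names(contigs))
  if (length(unknown))
    stop("variant(s) reference unknown contig(s): ",
         paste(unknown, collapse = ", "))
  bad_pos <- variants$position > nchar(contigs)[variants$contig_id]
  if (any(bad_pos))
    stop("variant position beyond contig length (first at row ",
         which(bad_pos)[1], ")")
  keep <- variants$coverage >= minCov & variants$coverage <= maxCov &
    variants$probability >= minProb
  indel <- variants$var_type %in% c("INS", "DEL")
  if (any(keep & indel)) {
    runs <- lapply(contigs[unique(variants$contig_id[keep & indel])],
                   function(s) {
      r <- rle(strsplit(s, "")[[1]])
      ends <- cumsum(r$lengths)
      ok <- r$lengths >= homopolymerLen
      cbind(start = (ends - r$lengths + 1)[ok], end = ends[ok])
    })
    for (i in which(keep & indel)) {
      rr <- runs[[variants$contig_id[i]]]
      p <- variants$position[i]
      if (nrow(rr) && any(rr[, "start"] <= p + 1 & rr[, "end"] >= p - 1))
        keep[i] <- FALSE
    }
  }
  variants[keep, , drop = FALSE]
}

.PURINES <- c("A", "G")

#' Classify a substitution as transition or transversion
#'
#' Transitions exchange a purine for a purine or a pyrimidine for a
#' pyrimidine (`A<->G`, `C<->T`); all other base pairs are transversions.
#'
#' @param ref,alt single distinct bases in `ACGT` (vectorised).
#' @return `"TS"` or `"TV"` per pair.
#' @export
classifySubstitution <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok))
    stop("non-ACGT base in substitution (first at ", which(!ok)[1], ")")
  if (any(ref == alt))
    stop("ref and alt must differ (first at ", which(ref == alt)[1], ")")
  ifelse((ref %in% .PURINES) == (alt %in% .PURINES), "TS", "TV")
}

.GENETIC_CODE <- Biostrings::GENETIC_CODE
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.translate_codon <- function(codon) {
  aa <- .GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

#' Coding effect of a SNP within a predicted ORF
#'
#' Decides whether a SNP is synonymous, nonsynonymous or noncoding with
#' respect to one ORF (0-based half-open coordinates on the contig, length
#' a codon multiple). The containing codon is translated under the
#' standard genetic code once with the reference and once with the
#' alternate allele (for `-` strand ORFs the codon is read on the reverse
#' complement); identical amino acids mean synonymous, and a stop counts
#' as an amino-acid state. SNPs whose codon contains a second SNP are
#' evaluated one at a time against the reference codon (no haplotype
#' phasing).
#'
#' @param position 1-based SNP position on the contig.
#' @param ref,alt single bases.
#' @param orf a list/one-row data.frame with `start`, `end` (0-based
#'   half-open) and `strand`.
#' @param seq the contig sequence (character scalar).
#' @return `"synonymous"`, `"nonsynonymous"` or `"noncoding"`.
#' @export
codingEffect <- function(position, ref, alt, orf, seq) {
  start <- orf$start; end <- orf$end; strand <- orf$strand
  if (end > nchar(seq)) stop("ORF window exceeds contig length")
  if ((end - start) %% 3 != 0) stop("ORF length is not a codon multiple")
  p0 <- position - 1L
  if (p0 < start || p0 >= end) return("noncoding")
  k <- p0 - start                       # offset within ORF, forward strand
  if (strand == "+") {
    cstart <- start + (k %/% 3) * 3
    codon <- substr(seq, cstart + 1, cstart + 3)
    inpos <- k %% 3 + 1
    cref <- codon; substr(cref, inpos, inpos) <- ref
    calt <- codon; substr(calt, inpos, inpos) <- alt
  } else {
    len <- end - start
    kr <- len - 1 - k                   # offset on the reverse complement
    region <- substr(seq, start + 1, end)
    rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(region, "")[[1]]),
                                         collapse = ""))
    cstart <- (kr %/% 3) * 3
    codon <- substr(rc, cstart + 1, cstart + 3)
    inpos <- kr %% 3 + 1
    cref <- codon; substr(cref, inpos, inpos) <- .COMPLEMENT[[ref]]
    calt <- codon; substr(calt, inpos, inpos) <- .COMPLEMENT[[alt]]
  }
  if (.translate_codon(cref) == .translate_codon(calt))
    "synonymous" else "nonsynonymous"
}

#' Per-contig variant summaries
#'
#' For every contig: SNP and INDEL counts, transition/transversion counts
#' and the smoothed ratio `(TS + 1) / (TV + 1)`; for contigs with a
#' predicted ORF, nonsynonymous/synonymous counts and the smoothed ratio
#' `(Ka + 1) / (Ks + 1)` (raw polymorphism counts, not per-site rates);
#' variant density per bp and per 200-bp window. When a contig has more
#' than one ORF record only the longest is used.
#'
#' @param contigs named contig sequences.
#' @param variants filtered variant data.frame; all rows must reference
#'   contigs present in `contigs`.
#' @param orfs optional ORF data.frame ([readTabular()] schema `"orf"`).
#' @return a data.frame with one row per contig: `contig_id`, `length`,
#'   `n_snp`, `n_indel`, `ts`, `tv`, `ka`, `ks`, `tstv_ratio`,
#'   `kaks_ratio` (`NA` without an ORF), `density`, `density_per_200bp`,
#'   `highly_variable` (`NA` until [flagHighlyVariable()]).
#' @export
summarizeContigs <- function(contigs, variants, orfs = NULL) {
  contigs <- .seq_chr(contigs)
  unknown <- setdiff(unique(variants$contig_id), names(contigs))
  if (length(unknown))
    stop("variant(s) reference unknown contig(s): ",
         paste(unknown, collapse = ", "))
  ids <- names(contigs)
  n <- length(ids)
  out <- data.frame(
    contig_id = ids, length = nchar(contigs), n_snp = 0L, n_indel = 0L,
    ts = 0L, tv = 0L, ka = NA_integer_, ks = NA_integer_,
    tstv_ratio = NA_real_, kaks_ratio = NA_real_, density = NA_real_,
    density_per_200bp = NA_real_, highly_variable = NA,
    stringsAsFactors = FALSE, row.names = ids)
  snp <- variants[variants$var_type == "SNP", , drop = FALSE]
  indel <- variants[variants$var_type != "SNP", , drop = FALSE]
  snp_n <- table(snp$contig_id)
  indel_n <- table(indel$contig_id)
  out[names(snp_n), "n_snp"] <- as.integer(snp_n)
  out[names(indel_n), "n_indel"] <- as.integer(indel_n)
  if (nrow(snp)) {
    cls <- classifySubstitution(snp$ref_allele, snp$alt_allele)
    ts_n <- table(snp$contig_id[cls == "TS"])
    tv_n <- table(snp$contig_id[cls == "TV"])
    out[names(ts_n), "ts"] <- as.integer(ts_n)
    out[names(tv_n), "tv"] <- as.integer(tv_n)
  }
  out$tstv_ratio <- (out$ts + 1) / (out$tv + 1)
  if (!is.null(orfs) && nrow(orfs)) {
    orfs <- orfs[order(-(orfs$end - orfs$start)), , drop = FALSE]
    orfs <- orfs[!duplicated(orfs$contig_id), , drop = FALSE]  # longest only
    orf_of <- stats::setNames(seq_len(nrow(orfs)), orfs$contig_id)
    has_orf <- ids[ids %in% names(orf_of)]
    out[has_orf, "ka"] <- 0L
    out[has_orf, "ks"] <- 0L
    csnp <- snp[snp$contig_id %in% has_orf, , drop = FALSE]
    for (i in seq_len(nrow(csnp))) {
      cid <- csnp$contig_id[i]
      eff <- codingEffect(csnp$position[i], csnp$ref_allele[i],
                          csnp$alt_allele[i], orfs[orf_of[[cid]], ],
                          contigs[[cid]])
      if (eff == "nonsynonymous") out[cid, "ka"] <- out[cid, "ka"] + 1L
      else if (eff == "synonymous") out[cid, "ks"] <- out[cid, "ks"] + 1L
    }
    out$kaks_ratio <- (out$ka + 1) / (out$ks + 1)
  }
  out$density <- (out$n_snp + out$n_indel) / out$length
  out$density_per_200bp <- out$density * 200
  rownames(out) <- NULL
  out
}

#' Flag highly variable contigs
#'
#' Computes variants-per-bp over the contigs with at least one variant
#' and flags those at or above the `q` nearest-rank quantile of that set
#' (rank `min(n, floor(q * n) + 1)`), so with 100 distinct densities and
#' `q = 0.99` exactly the maximum is flagged, and exact ties at the
#' threshold are all flagged.
#'
#' @param summaries data.frame from [summarizeContigs()].
#' @param q quantile (default 0.99).
#' @return `summaries` with the `highly_variable` column filled
#'   (`FALSE` for contigs without variants).
#' @export
flagHighlyVariable <- function(summaries, q = 0.99) {
  has <- summaries$n_snp + summaries$n_indel >= 1
  if (!any(has)) stop("no contig has a variant")
  v <- summaries$density[has]
  k <- min(length(v), floor(q * length(v)) + 1)
  thr <- sort(v)[k]
  summaries$highly_variable <- has & summaries$density >= thr
  summaries
}

#' Regress variant count on contig length
#'
#' Ordinary least squares of the number of variants on contig length over
#' the contigs with at least one variant.
#'
#' @param summaries data.frame from [summarizeContigs()].
#' @return a list with `slope`, `intercept`, `r2`, `f_stat`, `df`
#'   (residual degrees of freedom) and `p_value`.
#' @export
regressVariantsOnLength <- function(summaries) {
  sub <- summaries[summaries$n_snp + summaries$n_indel >= 1, , drop = FALSE]
  if (nrow(sub) < 3) stop("need at least 3 contigs with variants")
  if (length(unique(sub$length)) == 1)
    stop("degenerate input: all contig lengths equal")
  fit <- lm(I(n_snp + n_indel) ~ length, data = sub)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate input
  f <- unname(sm$fstatistic)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = sm$r.squared, f_stat = f[1], df = as.integer(f[3]),
       p_value = pf(f[1], f[2], f[3], lower.tail = FALSE))
}

#' Candidate contigs under putative diversifying selection
#'
#' The three-way intersection of the selection screens: smoothed
#' `Ka/Ks > 1`, smoothed `TS/TV < 1`, and membership in the highly
#' variable percentile flag.
#'
#' @param summaries data.frame from [summarizeContigs()] after
#'   [flagHighlyVariable()].
#' @return character vector of candidate contig ids.
#' @export
selectionCandidates <- function(summaries) {
  if (all(is.na(summaries$highly_variable)))
    stop("run flagHighlyVariable() first")
  keep <- !is.na(summaries$kaks_ratio) & summaries$kaks_ratio > 1 &
    summaries$tstv_ratio < 1 & summaries$highly_variable
  summaries$contig_id[keep]
}

.STOPS <- c("TAA", "TAG", "TGA")

## all complete ATG..stop ORFs in one frame of one strand; returns
## matrix of 0-based [start, end) on the scanned strand
.orfs_in_frame <- function(s, frame) {
  n <- nchar(s)
  ncod <- (n - frame) %/% 3
  if (ncod < 2) return(NULL)
  codons <- substring(s, frame + 3 * (seq_len(ncod) - 1) + 1,
                      frame + 3 * seq_len(ncod))
  is_start <- codons == "ATG"
  is_stop <- codons %in% .STOPS
  if (!any(is_start) || !any(is_stop)) return(NULL)
  res <- NULL
  prev_stop <- 0L
  for (st in which(is_stop)) {
    cand <- which(is_start[seq_len(st - 1)])
    cand <- cand[cand > prev_stop]
    if (length(cand)) {
      a <- cand[1]
      res <- rbind(res, c(frame + (a - 1) * 3, frame + st * 3))
    }
    prev_stop <- st
  }
  res
}

#' Find the longest open reading frame
#'
#' Scans all six frames for complete `ATG ... stop` spans (the stop codon
#' counts toward the length) and returns the longest with length at least
#' `minLen` nucleotides. Ties prefer the `+` strand, then the lowest
#' frame index, then the smallest start. Coordinates are reported 0-based
#' half-open on the forward strand of the input sequence.
#'
#' @param seq sequence (character scalar or `DNAString`-coercible) over
#'   `ACGTN`.
#' @param minLen minimum ORF length in nucleotides (default 30).
#' @param contigId id used in the returned record.
#' @return a one-row data.frame in the `orf` schema of [readTabular()],
#'   or `NULL` if no qualifying ORF exists.
#' @export
findLongestOrf <- function(seq, minLen = 30, contigId = "seq") {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]),
                                       collapse = ""))
  best <- NULL                          # (len, strand_pref, frame, start)
  for (strand_i in 1:2) {
    str_s <- if (strand_i == 1) s else rc
    for (frame in 0:2) {
      orfs <- .orfs_in_frame(str_s, frame)
      if (is.null(orfs)) next
      for (r in seq_len(nrow(orfs))) {
        len <- orfs[r, 2] - orfs[r, 1]
        if (len < minLen) next
        key <- c(len, -strand_i, -frame, -orfs[r, 1])
        if (is.null(best) || .lex_gt(key, best$key)) {
          best <- list(key = key, len = len, strand_i = strand_i,
                       start = orfs[r, 1], end = orfs[r, 2])
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (best$strand_i == 1) {
    start <- best$start; end <- best$end; strand <- "+"
  } else {                              # map back from the reverse strand
    start <- n - best$end; end <- n - best$start; strand <- "-"
  }
  data.frame(contig_id = contigId, start = as.integer(start),
             end = as.integer(end), orf_id = paste0(contigId, ".orf1"),
             score = as.integer(best$len), strand = strand,
             stringsAsFactors = FALSE)
}

.lex_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' @describeIn findLongestOrf vectorised over a named sequence set;
#'   sequences without a qualifying ORF are omitted.
#' @param seqs named `DNAStringSet` or character vector.
#' @export
findLongestOrfs <- function(seqs, minLen = 30) {
  seqs <- .seq_chr(seqs)
  rows <- lapply(names(seqs), function(id)
    findLongestOrf(seqs[[id]], minLen, id))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), orf_id = character(),
                      score = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
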