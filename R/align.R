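## Pairwise alignment under the package's fixed scoring:
## match +1, mismatch -1, gap -2 (linear), end gaps free in overlap mode.
## Identity = matches / aligned columns, gap columns counted in the
## denominator.

## name-preserving coercion for sequence sets (as.character drops names
## on plain character vectors)
.seq_chr <- function(x) {
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Align two sequences (overlap or local)
#'
#' Dynamic-programming alignment with the package's fixed scoring scheme
#' (match `+1`, mismatch `-1`, gap `-2`, linear). `mode = "overlap"` is a
#' semi-global alignment with free end gaps on both sequences, the
#' convention used to compare contigs within a graph-cluster;
#' `mode = "local"` is a Smith-Waterman alignment, used for singleton
#' rescue.
#'
#' @param a,b sequences (character scalars or `DNAString`-coercible).
#' @param mode `"overlap"` or `"local"`.
#' @return a list with elements `score`, `matches`, `columns`,
#'   `aligned_a`, `aligned_b` (gapped strings), and 1-based aligned spans
#'   `a_start`, `a_end`, `b_start`, `b_end`.
#' @seealso [overlapIdentity()]
#' @export
alignPair <- function(a, b, mode = c("overlap", "local")) {
  mode <- match.arg(mode)
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == 1, length(b) == 1, nzchar(a), nzchar(b))
  .align_pair_cpp(a, b, mode, 1, -1, -2)
}

#' Overlap identity between two contig sequences
#'
#' Best semi-global (overlap) alignment under match `+1`, mismatch `-1`,
#' gap `-2` with free end gaps; identity is `matches / aligned columns`
#' where gap columns count in the denominator. Returns `NA` when the best
#' alignment spans fewer than `minOverlap` columns (insufficient overlap
#' to judge similarity). The function is symmetric in its arguments and
#' `overlapIdentity(x, x) == 1`.
#'
#' @param a,b sequences.
#' @param minOverlap minimum aligned-column count (default 40, the
#'   assembler's minimum overlap convention).
#' @return identity fraction in `[0, 1]`, or `NA_real_`.
#' @examples
#' overlapIdentity(strrep("ACGT", 25), strrep("ACGT", 25))  # 1
#' @export
overlapIdentity <- function(a, b, minOverlap = 40) {
  a <- as.character(a); b <- as.character(b)
  ## canonical argument order makes traceback tie-breaks symmetric
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  aln <- alignPair(a, b, "overlap")
  if (aln$columns < minOverlap) return(NA_real_)
  aln$matches / aln$columns
}

## column-wise merge of one pairwise overlap alignment:
## agreeing bases kept; disagreements become the IUPAC code of the union
## (majority is impossible in a 2-row column, so a mismatch is a tie);
## a gap column keeps the present base (the consensus spans the union);
## unaligned flanks are appended verbatim.
.merge_aligned_pair <- function(aln, a, b) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  out <- character(length(ca))
  same <- ca == cb
  out[same] <- ca[same]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  out[gap_a] <- cb[gap_a]
  out[gap_b] <- ca[gap_b]
  mism <- !same & !gap_a & !gap_b
  if (any(mism)) {
    pairs <- vapply(which(mism), function(i) {
      paste0(sort(Biostrings::uniqueLetters(Biostrings::DNAStringSet(
        c(ca[i], cb[i])))), collapse = "")
    }, character(1))
    out[mism] <- unname(Biostrings::mergeIUPACLetters(pairs))
  }
  left <- c(substr(a, 1, aln$a_start - 1), substr(b, 1, aln$b_start - 1))
  left <- left[nzchar(left)]
  right <- c(substr(a, aln$a_end + 1, nchar(a)),
             substr(b, aln$b_end + 1, nchar(b)))
  right <- right[nzchar(right)]
  paste0(paste0(left, collapse = ""), paste0(out, collapse = ""),
         paste0(right, collapse = ""))
}

#' Consensus of allele sequences
#'
#' Progressive pairwise consensus over a set of sequences judged to be
#' divergent alleles of one gene: sequences are folded in deterministic
#' (lexicographic id) order using the overlap alignment; at each aligned
#' column agreeing bases are kept, disagreeing bases (a 2-row tie) become
#' the IUPAC ambiguity code of their union, and gap columns keep the
#' present base so the consensus spans the union of the inputs.
#'
#' @param seqs a named character vector or `DNAStringSet` of at least one
#'   sequence.
#' @return a single consensus sequence (character scalar, possibly with
#'   IUPAC ambiguity codes).
#' @export
alleleConsensus <- function(seqs) {
  s <- .seq_chr(seqs)
  stopifnot(length(s) >= 1)
  if (!is.null(names(s))) s <- s[order(names(s))]
  cons <- s[[1]]
  for (x in s[-1]) {
    aln <- alignPair(cons, x, "overlap")
    cons <- .merge_aligned_pair(aln, cons, x)
  }
  cons
}
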