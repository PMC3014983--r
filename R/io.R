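## Readers/writers for the on-disk artifacts the pipeline touches.
##
## Coordinate conventions (stated in every file header written here):
##   * read-status, variant and blast tables: 1-based inclusive
##   * ORF records (BED layout): 0-based half-open
## Tokens (ids, db names) must not contain whitespace or ':'.

.token_ok <- function(x) nzchar(x) & !grepl("[[:space:]:]", x)

#' Read and write FASTA sequence files
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that enforce the package's record
#' invariants: sequence ids (the first whitespace-delimited token of the
#' header) must be unique and every sequence non-empty. Output is wrapped
#' at 80 columns, so `writeFasta()` followed by `readFasta()` is the
#' identity on (id, residues).
#'
#' @param path file path.
#' @param records a named `Biostrings::DNAStringSet` (or named character
#'   vector) for writing.
#' @return `readFasta()` returns a named `DNAStringSet`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeFasta(c(c1 = "ACGT"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("[[:space:]].*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  empty <- ids[Biostrings::width(x) == 0]
  if (length(empty))
    stop("empty sequence for id(s): ", paste(empty, collapse = ", "))
  names(x) <- ids
  x
}

#' @rdname readFasta
#' @export
writeFasta <- function(records, path) {
  if (is.character(records))
    records <- Biostrings::DNAStringSet(records)
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named")
  if (anyDuplicated(names(records)))
    stop("duplicate FASTA id(s): ",
         paste(unique(names(records)[duplicated(names(records))]),
               collapse = ", "))
  if (any(Biostrings::width(records) == 0))
    stop("empty sequence for id(s): ",
         paste(names(records)[Biostrings::width(records) == 0],
               collapse = ", "))
  Biostrings::writeXStringSet(records, path, width = 80L)
  invisible(path)
}

.SEXES <- c("F", "M")
.STATUSES <- c("assembled", "partially_assembled", "singleton", "discarded")

.parse_placement <- function(tok, row) {
  m <- regmatches(tok, regexec(
    "^([^:[:space:]]+):([0-9]+)-([0-9]+):([+-]):([0-9]+)$", tok))[[1]]
  if (length(m) != 6)
    stop("row ", row, ": malformed placement '", tok, "'")
  list(contig_id = m[2], read_start = as.integer(m[3]),
       read_end = as.integer(m[4]), strand = m[5],
       contig_start = as.integer(m[6]))
}

#' Read and write the read-status table
#'
#' One row per sequencing read: its sex-of-origin, placement status and up
#' to two contig placements. Two placements mean the assembler split the
#' read at a variation boundary and assigned each portion to a different
#' contig -- the edge evidence of the contig graph.
#'
#' File layout (tab-separated; `#` lines are comments):
#' `read_id  sex  status  placement [placement]` with
#' `placement = contig_id:read_start-read_end:strand:contig_start`
#' (1-based inclusive coordinates).
#'
#' Invariants enforced: `status` in `assembled`/`partially_assembled` iff
#' at least one placement is present; two placements must name distinct
#' contigs and cover disjoint read intervals; `singleton`/`discarded`
#' reads carry no placement.
#'
#' @param path file path.
#' @param records for writing, a data.frame as returned by
#'   `readReadStatus()`.
#' @return a data.frame with columns `read_id`, `sex`, `status`,
#'   `n_placements`, and per-placement columns `contig1`, `read_start1`,
#'   `read_end1`, `strand1`, `contig_start1` (ditto `...2`), `NA` where
#'   absent.
#' @export
readReadStatus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  out <- data.frame(
    read_id = character(n), sex = character(n), status = character(n),
    n_placements = integer(n),
    contig1 = NA_character_, read_start1 = NA_integer_,
    read_end1 = NA_integer_, strand1 = NA_character_,
    contig_start1 = NA_integer_,
    contig2 = NA_character_, read_start2 = NA_integer_,
    read_end2 = NA_integer_, strand2 = NA_character_,
    contig_start2 = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3 || length(f) > 5)
      stop("row ", i, ": expected 3-5 fields, got ", length(f))
    if (!f[2] %in% .SEXES) stop("row ", i, ": unknown sex '", f[2], "'")
    if (!f[3] %in% .STATUSES)
      stop("row ", i, ": unknown status '", f[3], "'")
    np <- length(f) - 3L
    if (f[3] %in% c("singleton", "discarded") && np > 0)
      stop("row ", i, ": status '", f[3], "' must not carry placements")
    if (f[3] %in% c("assembled", "partially_assembled") && np == 0)
      stop("row ", i, ": status '", f[3], "' requires a placement")
    out$read_id[i] <- f[1]; out$sex[i] <- f[2]; out$status[i] <- f[3]
    out$n_placements[i] <- np
    if (np >= 1) {
      p <- .parse_placement(f[4], i)
      if (p$read_start > p$read_end)
        stop("row ", i, ": read_start > read_end")
      out$contig1[i] <- p$contig_id; out$read_start1[i] <- p$read_start
      out$read_end1[i] <- p$read_end; out$strand1[i] <- p$strand
      out$contig_start1[i] <- p$contig_start
    }
    if (np == 2) {
      p <- .parse_placement(f[5], i)
      if (p$read_start > p$read_end)
        stop("row ", i, ": read_start > read_end")
      if (p$contig_id == out$contig1[i])
        stop("row ", i, ": both placements on contig '", p$contig_id, "'")
      if (p$read_start <= out$read_end1[i] && out$read_start1[i] <= p$read_end)
        stop("row ", i, ": placements cover overlapping read intervals")
      out$contig2[i] <- p$contig_id; out$read_start2[i] <- p$read_start
      out$read_end2[i] <- p$read_end; out$strand2[i] <- p$strand
      out$contig_start2[i] <- p$contig_start
    }
  }
  if (anyDuplicated(out$read_id))
    stop("duplicate read id(s): ",
         paste(unique(out$read_id[duplicated(out$read_id)]), collapse = ", "))
  out
}

.fmt_placement <- function(contig, rs, re, strand, cs)
  paste0(contig, ":", rs, "-", re, ":", strand, ":", cs)

#' @rdname readReadStatus
#' @export
writeReadStatus <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# read-status table: read_id<TAB>sex<TAB>status<TAB>placement[<TAB>placement]",
    "# placement = contig_id:read_start-read_end:strand:contig_start (1-based inclusive)"),
    con)
  lines <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    parts <- c(r$read_id, r$sex, r$status)
    if (r$n_placements >= 1)
      parts <- c(parts, .fmt_placement(r$contig1, r$read_start1, r$read_end1,
                                       r$strand1, r$contig_start1))
    if (r$n_placements == 2)
      parts <- c(parts, .fmt_placement(r$contig2, r$read_start2, r$read_end2,
                                       r$strand2, r$contig_start2))
    lines[i] <- paste(parts, collapse = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

.TAB_SCHEMAS <- list(
  blast = list(
    cols = c("db_name", "query_id", "subject_id", "percent_identity",
             "align_length", "mismatches", "gap_opens", "query_start",
             "query_end", "subject_start", "subject_end", "evalue",
             "bitscore"),
    num = c("percent_identity", "align_length", "mismatches", "gap_opens",
            "query_start", "query_end", "subject_start", "subject_end",
            "evalue", "bitscore")),
  variant = list(
    cols = c("contig_id", "position", "ref_allele", "alt_allele",
             "var_type", "coverage", "probability"),
    num = c("position", "coverage", "probability")),
  orf = list(
    cols = c("contig_id", "start", "end", "orf_id", "score", "strand"),
    num = c("start", "end", "score")),
  go = list(cols = c("seq_id", "term_id"), num = character()))

.validate_tabular <- function(df, schema) {
  rown <- function(i) paste0("row ", i, ": ")
  if (schema == "blast") {
    bad <- which(df$percent_identity < 0 | df$percent_identity > 100)
    if (length(bad)) stop(rown(bad[1]), "percent_identity out of [0,100]")
    bad <- which(df$evalue < 0)
    if (length(bad)) stop(rown(bad[1]), "negative evalue")
    bad <- which(df$query_start > df$query_end)
    if (length(bad)) stop(rown(bad[1]), "query_start > query_end")
    bad <- which(df$bitscore < 0)
    if (length(bad)) stop(rown(bad[1]), "negative bitscore")
  } else if (schema == "variant") {
    bad <- which(df$probability < 0 | df$probability > 1)
    if (length(bad)) stop(rown(bad[1]), "probability out of [0,1]")
    bad <- which(df$coverage < 0)
    if (length(bad)) stop(rown(bad[1]), "negative coverage")
    bad <- which(!df$var_type %in% c("SNP", "INS", "DEL"))
    if (length(bad)) stop(rown(bad[1]), "unknown var_type '",
                          df$var_type[bad[1]], "'")
    snp <- df$var_type == "SNP"
    bad <- which(snp & (nchar(df$ref_allele) != 1 |
                        nchar(df$alt_allele) != 1 |
                        df$ref_allele == df$alt_allele))
    if (length(bad))
      stop(rown(bad[1]), "SNP alleles must be single, distinct bases")
    bad <- which(df$position < 1)
    if (length(bad)) stop(rown(bad[1]), "position must be >= 1")
  } else if (schema == "orf") {
    bad <- which(df$end <= df$start)
    if (length(bad)) stop(rown(bad[1]), "ORF end must exceed start")
    len <- df$end - df$start
    bad <- which(len < 30)
    if (length(bad)) stop(rown(bad[1]), "ORF shorter than 30 bp")
    bad <- which(len %% 3 != 0)
    if (length(bad)) stop(rown(bad[1]), "ORF length not a codon multiple")
    bad <- which(!df$strand %in% c("+", "-"))
    if (length(bad)) stop(rown(bad[1]), "strand must be + or -")
  } else if (schema == "go") {
    if (anyDuplicated(paste(df$seq_id, df$term_id)))
      stop("duplicate (seq_id, term_id) pairs")
  }
  df
}

#' Read and write typed tab-separated tables
#'
#' Four schemas are supported. `blast` mirrors the standard 12-column
#' tabular hit format with a leading `db_name` column. `variant` is the
#' package's variant-call table (per-call coverage and Bayesian
#' probability; see [writeVariantsVcf()] for VCF interchange). `orf` is a
#' BED-style table (0-based half-open coordinates). `go` maps sequence ids
#' to GO terms.
#'
#' All records are validated (probability/identity ranges, coordinate
#' order, SNP allele shape, ORF length a codon multiple of at least
#' 30 bp); violations report the offending row number. Row order is
#' preserved.
#'
#' @param path file path.
#' @param schema one of `"blast"`, `"variant"`, `"orf"`, `"go"`.
#' @param df for writing, a data.frame with the schema's columns.
#' @return a validated data.frame.
#' @export
readTabular <- function(path, schema = c("blast", "variant", "orf", "go")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- .TAB_SCHEMAS[[schema]]
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = sc$cols, colClasses = "character",
                   quote = "", stringsAsFactors = FALSE)
  for (cn in sc$num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && !anyNA(df[[cn]]))
      stop("row ", which(is.na(v))[1], ": non-numeric value in column ", cn)
    df[[cn]] <- if (cn %in% c("position", "coverage", "align_length",
                              "mismatches", "gap_opens", "query_start",
                              "query_end", "subject_start", "subject_end",
                              "start", "end")) as.integer(v) else v
  }
  .validate_tabular(df, schema)
}

#' @rdname readTabular
#' @export
writeTabular <- function(df, path, schema = c("blast", "variant", "orf", "go")) {
  schema <- match.arg(schema)
  sc <- .TAB_SCHEMAS[[schema]]
  stopifnot(all(sc$cols %in% names(df)))
  df <- .validate_tabular(df[, sc$cols, drop = FALSE], schema)
  hdr <- switch(schema,
    blast = "# blast hits: db_name + standard 12 columns (1-based inclusive coords)",
    variant = "# variant calls: 1-based inclusive positions on transcript contigs",
    orf = "# ORF records: BED-style 0-based half-open coordinates",
    go = "# GO map: seq_id<TAB>term_id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, paste0("# ", paste(sc$cols, collapse = "\t"))), con)
  out <- df
  for (cn in names(out))                # full-precision numeric round-trip
    if (is.double(out[[cn]]))
      out[[cn]] <- format(out[[cn]], digits = 15, trim = TRUE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export variant calls as minimal VCF
#'
#' Interchange exporter for the variant table: positions are against
#' transcript contigs (the `CHROM` column holds the contig id) and the
#' per-call read coverage and Bayesian probability are carried in INFO
#' (`DP`, `PROB`). INDEL records are written in the package's native form
#' (`ref_allele`/`alt_allele` as stored, `INS` with empty reference
#' encoded per VCF by left-anchoring is out of scope of this plain
#' exporter and the raw alleles are emitted as-is).
#'
#' @param variants a validated variant data.frame ([readTabular()]).
#' @param path output path.
#' @export
writeVariantsVcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ContigGraphKit",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read coverage\">",
    "##INFO=<ID=PROB,Number=1,Type=Float,Description=\"Posterior probability of a true variant\">",
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant type\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    ref <- ifelse(nzchar(variants$ref_allele), variants$ref_allele, ".")
    alt <- ifelse(nzchar(variants$alt_allele), variants$alt_allele, ".")
    writeLines(paste(variants$contig_id, variants$position, ".", ref, alt,
                     ".", "PASS",
                     sprintf("DP=%d;PROB=%g;VT=%s", variants$coverage,
                             variants$probability, variants$var_type),
                     sep = "\t"), con)
  }
  invisible(path)
}
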