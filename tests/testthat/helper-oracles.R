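# Independent oracles used to cross-check the package implementations.
# These are deliberately plain, full-matrix / enumeration versions that
# share no code with the package internals.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# full-matrix semi-global (free end gaps) alignment oracle under the
# package's documented scoring and tie-break conventions:
# match +1 / mismatch -1 / gap -2; fill ties diag > up > left; alignment
# end = best of last row (smallest column first) then last column
# (smallest row first), strictly-greater replacement.
oracle_overlap <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  Tb <- matrix(0L, n + 1, m + 1)        # 1 diag, 2 up, 3 left
  for (i in 1:n) for (j in 1:m) {
    diag <- S[i, j] + if (av[i] == bv[j]) 1 else -1
    up <- S[i, j + 1] - 2
    left <- S[i + 1, j] - 2
    best <- diag; tb <- 1L
    if (up > best) { best <- up; tb <- 2L }
    if (left > best) { best <- left; tb <- 3L }
    S[i + 1, j + 1] <- best
    Tb[i + 1, j + 1] <- tb
  }
  bi <- 0L; bj <- 0L; bs <- -Inf
  for (j in 1:m) if (S[n + 1, j + 1] > bs) { bs <- S[n + 1, j + 1]; bi <- n; bj <- j }
  for (i in 1:n) if (S[i + 1, m + 1] > bs) { bs <- S[i + 1, m + 1]; bi <- i; bj <- m }
  i <- bi; j <- bj; matches <- 0L; cols <- 0L
  while (i > 0 && j > 0) {
    tb <- Tb[i + 1, j + 1]
    cols <- cols + 1L
    if (tb == 1L) {
      if (av[i] == bv[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (tb == 2L) i <- i - 1L
    else j <- j - 1L
  }
  list(score = bs, matches = matches, columns = cols)
}

# two-sided Fisher p-value by direct enumeration over the hypergeometric
# support with lchoose arithmetic
oracle_fisher2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  lp <- function(x) {
    lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  }
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- exp(vapply(xs, lp, numeric(1)))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-9)])
}

# connected components by boolean transitive closure (matrix powering)
oracle_components <- function(nodes, edge_a, edge_b) {
  n <- length(nodes)
  A <- diag(n) > 0
  ia <- match(edge_a, nodes); ib <- match(edge_b, nodes)
  for (k in seq_along(ia)) {
    A[ia[k], ib[k]] <- TRUE
    A[ib[k], ia[k]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  # canonical membership labels: smallest reachable node id
  vapply(seq_len(n), function(i) min(nodes[A[i, ]]), character(1))
}

# one-line set-comprehension variant filter (no homopolymer handling of
# its own: takes a precomputed is-in-homopolymer predicate)
oracle_filter <- function(variants, in_homopolymer) {
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    v$coverage >= 5 && v$coverage <= 100 && v$probability >= 0.9 &&
      !(v$var_type %in% c("INS", "DEL") && in_homopolymer(v$contig_id,
                                                          v$position))
  }, logical(1))
  variants[keep, , drop = FALSE]
}

# homopolymer predicate built independently with gregexpr
make_hp_predicate <- function(contigs, minRun = 3) {
  contigs <- setNames(as.character(contigs), names(contigs))
  runs <- lapply(contigs, function(s) {
    m <- gregexpr("A{3,}|C{3,}|G{3,}|T{3,}", s)[[1]]
    if (m[1] == -1) return(cbind(integer(), integer()))
    cbind(as.integer(m), as.integer(m) + attr(m, "match.length") - 1L)
  })
  function(cid, pos) {
    r <- runs[[cid]]
    nrow(r) > 0 && any(r[, 1] <= pos + 1 & r[, 2] >= pos - 1)
  }
}

# independent TS/TV recount
oracle_tstv <- function(ref, alt) {
  pur <- c("A", "G")
  sum((ref %in% pur) == (alt %in% pur))
}

# independent Ka/Ks recount: re-translates every codon with
# seqinr::translate
oracle_kaks <- function(snps, orf, seq) {
  ka <- 0L; ks <- 0L
  sv <- strsplit(seq, "")[[1]]
  for (i in seq_len(nrow(snps))) {
    p0 <- snps$position[i] - 1L
    if (p0 < orf$start || p0 >= orf$end) next
    region <- sv[(orf$start + 1):orf$end]
    off <- p0 - orf$start + 1L
    if (orf$strand == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      region <- rev(unname(comp[region]))
      off <- length(region) - off + 1L
      refb <- unname(comp[snps$ref_allele[i]])
      altb <- unname(comp[snps$alt_allele[i]])
    } else {
      refb <- snps$ref_allele[i]; altb <- snps$alt_allele[i]
    }
    cstart <- ((off - 1) %/% 3) * 3 + 1
    codon <- region[cstart:(cstart + 2)]
    cr <- codon; cr[(off - 1) %% 3 + 1] <- refb
    ca <- codon; ca[(off - 1) %% 3 + 1] <- altb
    aar <- seqinr::translate(cr)
    aaa <- seqinr::translate(ca)
    if (aar == aaa) ks <- ks + 1L else ka <- ka + 1L
  }
  c(ka = ka, ks = ks)
}

# exhaustive 6-frame ORF scan oracle (start..stop inclusive spans)
oracle_longest_orf_len <- function(seq) {
  revcomp <- function(s)
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (f in 0:2) {
      i <- f + 1
      while (i + 2 <= n) {
        if (substr(s, i, i + 2) == "ATG") {
          j <- i
          while (j + 2 <= n) {
            cod <- substr(s, j, j + 2)
            if (cod %in% c("TAA", "TAG", "TGA")) {
              best <- max(best, j + 2 - i + 1)
              break
            }
            j <- j + 3
          }
        }
        i <- i + 3
      }
    }
  }
  best
}

# small simulated study used across test files (kept light)
tiny_params <- function(...) {
  simParams(nUnique = 12, nAllelePair = 4, nDuplicatePair = 2,
            nAltSplice = 3, nChimeraSource = 4, nFemaleOnly = 2,
            nMaleOnly = 2, depthMean = 40, noHomologFrac = 0,
            alleleMergedFrac = 0.25, seed = 42, ...)
}
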