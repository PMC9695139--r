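# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they validate: plain string
# operations, exhaustive enumeration, or a different library routine.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracleRevComp <- function(x) {
  paste(rev(COMP[strsplit(x, "")[[1]]]), collapse = "")
}

# --- local alignment oracle (Biostrings dynamic programming) -----------

swOracle <- function(query, subject, match = 1, mismatch = -2, gap = 3) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = gap)
  ind <- sum(Biostrings::nindel(aln)@insertion[, "WidthSum"],
             Biostrings::nindel(aln)@deletion[, "WidthSum"])
  list(score = Biostrings::score(aln),
       s_start = IRanges::start(Biostrings::subject(aln)),
       s_end = IRanges::end(Biostrings::subject(aln)),
       matches = Biostrings::nmatch(aln),
       mismatches = Biostrings::nmismatch(aln),
       gapcols = ind)
}

# --- hammerhead descriptor oracle: exhaustive placement ----------------

hhWc <- function(a, b) !is.na(COMP[a]) && COMP[[a]] == b

hhStem <- function(chars, a5, b3, maxLen = 8L) {
  n <- 0L
  while (n < maxLen) {
    i <- a5 + n; j <- b3 - n
    if (i > j || i < 1 || j > length(chars)) break
    if (!hhWc(chars[i], chars[j])) break
    n <- n + 1L
  }
  n
}

hhCoreSubs <- function(chars, b1, b2) {
  pat1 <- c("C", "T", "G", "A", NA, "G", "A")  # NA = unconstrained N
  pat2 <- c("G", "A", "A", "A")
  n <- 0L
  for (i in 1:7) if (!is.na(pat1[i]) && chars[b1 + i - 1] != pat1[i])
    n <- n + 1L
  for (i in 1:4) if (chars[b2 + i - 1] != pat2[i]) n <- n + 1L
  n
}

# exhaustive enumeration over every (box1, box2, cleavage) placement
# under the published descriptor; returns one row per box-1 position
# (smallest box2, then smallest cleavage site)
hammerheadOracle <- function(seq) {
  chars <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  L <- length(chars)
  res <- list()
  for (b1 in seq_len(max(0, L - 6))) {
    pat1 <- c("C", "T", "G", "A", NA, "G", "A")
    mm1 <- sum(vapply(1:7, function(i)
      !is.na(pat1[i]) && chars[b1 + i - 1] != pat1[i], TRUE))
    if (mm1 > 1) next
    if (b1 < 4) next
    hit <- NULL
    for (b2 in seq_len(max(0, L - 3))) {
      gap <- b2 - (b1 + 6) - 1L
      if (gap < 10 || gap > 60) next
      if (hhCoreSubs(chars, b1, b2) > 1) next
      s2 <- hhStem(chars, b1 + 7L, b2 - 1L, maxLen = min(8L, gap %/% 2L))
      if (s2 < 3) next
      b2e <- b2 + 3L
      for (cs in seq(b2e + 10L, min(L - 2L, b2e + 60L))) {
        if (cs - 3L < 1) next
        if (chars[cs - 2L] != "T") next
        if (!chars[cs - 1L] %in% c("A", "C", "T")) next
        s1 <- hhStem(chars, b2e + 1L, cs - 4L,
                     maxLen = min(8L, (cs - 4L - b2e) %/% 2L))
        if (s1 < 3) next
        s3 <- 0L
        while (s3 < 8L) {
          i <- b1 - 1L - s3; j <- cs + s3
          if (i < 1 || j > L || !hhWc(chars[i], chars[j])) break
          s3 <- s3 + 1L
        }
        if (s3 < 3) next
        hit <- c(b1 = b1, b2 = b2, cleavage = cs)
        break
      }
      if (!is.null(hit)) break
    }
    if (!is.null(hit)) res[[length(res) + 1L]] <- hit
  }
  if (length(res) == 0)
    return(data.frame(b1 = integer(), b2 = integer(),
                      cleavage = integer()))
  as.data.frame(do.call(rbind, res))
}

# --- strict-assembly oracle: exhaustive merge-order search -------------

oracleOverlap <- function(a, b, minOverlap) {
  k <- min(nchar(a), nchar(b))
  while (k >= minOverlap) {
    if (substr(a, nchar(a) - k + 1, nchar(a)) == substr(b, 1, k))
      return(k)
    k <- k - 1L
  }
  0L
}

# a move merges a contig with a single read (either side), the unit the
# extension cap is defined over: overlap >= minOverlap and extension
# <= maxExtension, or containment. state is a list of (seq, n) contigs.
oracleLegalMoves <- function(state, minOverlap, maxExtension) {
  out <- list()
  n <- length(state)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    if (state[[a]]$n != 1 && state[[b]]$n != 1) next
    sa <- state[[a]]$seq; sb <- state[[b]]$seq
    nn <- state[[a]]$n + state[[b]]$n
    if (grepl(sb, sa, fixed = TRUE)) {
      out[[length(out) + 1L]] <- list(a = a, b = b,
                                      merged = list(seq = sa, n = nn))
      next
    }
    ov <- oracleOverlap(sa, sb, minOverlap)
    if (ov > 0) {
      ext <- nchar(sa) + nchar(sb) - ov - max(nchar(sa), nchar(sb))
      if (ext <= maxExtension)
        out[[length(out) + 1L]] <- list(
          a = a, b = b,
          merged = list(seq = paste0(sa, substr(sb, ov + 1, nchar(sb))),
                        n = nn))
    }
  }
  out
}

# minimum reachable contig count over every order of read additions
# (memoized on the sorted contig multiset)
assemblyOracleMinContigs <- function(seqs, minOverlap = 20,
                                     maxExtension = 25) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(state) {
    key <- paste(sort(vapply(state, function(x)
      paste0(x$seq, "#", x$n), "")), collapse = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    moves <- oracleLegalMoves(state, minOverlap, maxExtension)
    best <- if (length(moves) == 0) length(state) else {
      min(vapply(moves, function(m) {
        rec(c(state[-c(m$a, m$b)], list(m$merged)))
      }, 1L))
    }
    memo[[key]] <- best
    best
  }
  rec(lapply(unname(seqs), function(s) list(seq = s, n = 1L)))
}

# --- sliding mismatch oracle ------------------------------------------

slidingMismatchOracle <- function(pat, subj) {
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(subj, "")[[1]]
  n <- length(sc) - length(pc) + 1
  vapply(seq_len(n), function(off)
    sum(pc != sc[off:(off + length(pc) - 1)]), 1L)
}

# --- exact permutation oracle for the rank-sum comparison --------------

permutationRankP <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  stats <- colSums(matrix(r[combos], nrow = nx))
  mu <- nx * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# --- misc --------------------------------------------------------------

randomDna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
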