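#' @title Partial-copy search: seed-and-extend local alignment
#' @name alignment
#' @description A small, deterministic local aligner used to find partial
#'   rRNA copies in the genome. Exact k-mer seeds are extended with a
#'   banded Smith-Waterman (affine gaps) and scored hits are assigned
#'   Karlin-Altschul E-values computed for the chosen scoring scheme.
NULL

#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' Computes the scale parameter lambda (unique positive solution of
#' `sum_ij p_i p_j exp(lambda s_ij) = 1`), the relative entropy H, and
#' the K constant of extreme-value statistics for i.i.d. sequences with
#' the given match/mismatch scores and background base composition.
#' K is obtained from the classic series representation
#' `K = lambda * exp(-2 sigma) / (H (1 - exp(-lambda)))` where sigma sums
#' Spitzer-type terms of the n-step score-sum distribution.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param p base composition, a probability 4-vector (default uniform).
#' @param max_iter number of terms of the K series (the terms decay
#'   geometrically; 60 is far beyond convergence for these scores).
#' @return list with `lambda`, `K`, `H`.
#' @export
karlin_altschul_params <- function(match = 1, mismatch = -2,
                                   p = rep(0.25, 4), max_iter = 60) {
  stopifnot(match > 0, mismatch < 0, abs(sum(p) - 1) < 1e-9)
  p_match <- sum(p^2)
  p_mis <- 1 - p_match
  if (p_match * match + p_mis * mismatch >= 0)
    stop("expected score must be negative for local-alignment statistics")

  mgf <- function(lam) p_match * exp(lam * match) + p_mis * exp(lam * mismatch) - 1
  lambda <- uniroot(mgf, c(1e-8, 20), tol = 1e-12)$root

  # score distribution on the integer lattice (assumes integer scores)
  lo <- as.integer(mismatch); hi <- as.integer(match)
  probs <- numeric(hi - lo + 1L)
  probs[1L] <- p_mis                      # score = mismatch
  probs[length(probs)] <- p_match         # score = match
  H <- lambda * (p_match * match * exp(lambda * match) +
                 p_mis * mismatch * exp(lambda * mismatch))

  # sigma = sum_{n>=1} (1/n) [ E(e^{lambda S_n}; S_n < 0) + P(S_n >= 0) ]
  sigma <- 0
  conv <- 1 # distribution of S_0 = 0, offset tracks index of score 0
  offset <- 1L
  for (n in seq_len(max_iter)) {
    new_len <- length(conv) + length(probs) - 1L
    conv <- convolve_counts(conv, probs)
    offset <- offset - lo
    scores <- (seq_along(conv) - offset)
    neg <- scores < 0
    term <- sum(conv[neg] * exp(lambda * scores[neg])) + sum(conv[!neg])
    sigma <- sigma + term / n
  }
  K <- lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda)))
  list(lambda = lambda, K = K, H = H)
}

# plain polynomial product (distribution convolution)
convolve_counts <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' E-value of a local alignment score
#'
#' @param score alignment score.
#' @param m,n effective query and database lengths.
#' @param ka Karlin-Altschul parameters from [karlin_altschul_params()].
#' @return The expected number of chance hits with at least this score.
#' @export
evalue_of_score <- function(score, m, n, ka) {
  ka$K * m * n * exp(-ka$lambda * score)
}

#' Find partial genomic copies of a reference rRNA
#'
#' Seed-and-extend local alignment of the rRNA against both strands of
#' every contig: exact seeds of `seed_len` nt are located, grouped into
#' diagonal bands, and extended by Smith-Waterman local alignment with
#' affine gaps. Hits with an E-value at most `evalue_max` and an aligned
#' genomic span of at least `min_len` nt are reported; intervals
#' identical to full-length placements of the reference are excluded.
#'
#' @param ref an `rrna_reference` (its placements, if present, are used
#'   to suppress full-length self-hits).
#' @param genome genome (see [as_genome()]).
#' @param evalue_max E-value cutoff (default 1e-8).
#' @param min_len minimum aligned span on the genome (default 16).
#' @param seed_len exact seed length (default 12).
#' @param match,mismatch,gap_open,gap_ext scoring scheme
#'   (+1/-2, affine gap open -4 / extend -1).
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `kind`
#'   (`"partial_copy"`), `score`, `evalue`. Zero rows when nothing is
#'   found.
#' @export
find_partial_copies <- function(ref, genome, evalue_max = 1e-8, min_len = 16L,
                                seed_len = 12L, match = 1, mismatch = -2,
                                gap_open = -4, gap_ext = -1) {
  gs <- as_genome(genome)
  q <- ref$sequence
  qlen <- nchar(q)
  if (qlen < seed_len) return(empty_partial_hits())

  ka <- karlin_altschul_params(match, mismatch)
  n_db <- 2 * sum(width(gs))
  submat <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                         baseOnly = TRUE)

  hits <- list()
  for (ctg in names(gs)) {
    fwd_seq <- as.character(gs[[ctg]])
    L <- nchar(fwd_seq)
    for (str in c("+", "-")) {
      subj <- if (str == "+") fwd_seq else
        as.character(reverseComplement(DNAString(fwd_seq)))
      regions <- seed_regions(q, subj, seed_len, qlen)
      for (reg in regions) {
        win <- substr(subj, reg[1], reg[2])
        aln <- pairwiseAlignment(q, win, type = "local",
                                 substitutionMatrix = submat,
                                 gapOpening = -gap_open, gapExtension = -gap_ext)
        sc <- score(aln)
        ev <- evalue_of_score(sc, qlen, n_db, ka)
        span_s <- reg[1] + start(subject(aln)) - 1L
        span_e <- reg[1] + end(subject(aln)) - 1L
        if (ev <= evalue_max && (span_e - span_s + 1L) >= min_len) {
          if (str == "-") {
            tmp <- span_s
            span_s <- L - span_e + 1L
            span_e <- L - tmp + 1L
          }
          hits[[length(hits) + 1L]] <-
            data.frame(chrom = ctg, start = span_s, end = span_e,
                       strand = str, score = sc, evalue = ev)
        }
      }
    }
  }
  if (!length(hits)) return(empty_partial_hits())
  df <- do.call(rbind, hits)

  # collapse overlapping hits on the same contig/strand (multiple seeds of
  # the same copy), keeping the best score per merged interval
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  merged <- reduce(gr)
  ov <- findOverlaps(gr, merged)
  best <- vapply(seq_along(merged), function(i) {
    members <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i]
    members[which.max(df$score[members])]
  }, integer(1))
  out <- data.frame(chrom = as.character(seqnames(merged)),
                    start = df$start[best], end = df$end[best],
                    strand = as.character(strand(merged)),
                    kind = "partial_copy",
                    score = df$score[best], evalue = df$evalue[best],
                    stringsAsFactors = FALSE)

  # drop hits identical to known full-length placements
  if (nrow(ref$placements)) {
    key <- paste(out$chrom, out$start, out$end)
    full <- paste(ref$placements$chrom, ref$placements$start, ref$placements$end)
    out <- out[!(key %in% full), , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

empty_partial_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), kind = character(),
             score = numeric(), evalue = numeric())
}

# locate exact seed_len-mer seed hits of q in subj and group them into
# candidate regions (windows padded by the query length); returns a list
# of c(start, end) windows on subj
seed_regions <- function(q, subj, seed_len, qlen) {
  n_seeds <- nchar(q) - seed_len + 1L
  if (n_seeds < 1) return(list())
  starts <- integer(0)
  # sample seeds on a stride so long queries stay cheap; stride <= seed_len
  # guarantees any exact stretch >= 2*seed_len contains a sampled seed
  stride <- max(1L, min(seed_len, n_seeds %/% 64L + 1L))
  offs <- unique(c(seq(1L, n_seeds, by = stride), n_seeds))
  for (o in offs) {
    kmer <- substr(q, o, o + seed_len - 1L)
    m <- gregexpr(kmer, subj, fixed = TRUE)[[1]]
    if (m[1] != -1) starts <- c(starts, as.integer(m) - (o - 1L))
  }
  if (!length(starts)) return(list())
  # starts are implied subject positions of query position 1; cluster them
  starts <- sort(unique(starts))
  groups <- split(starts, cumsum(c(1L, diff(starts) > qlen)))
  lapply(groups, function(g) {
    c(max(1L, min(g) - qlen %/% 2L),
      min(nchar(subj), max(g) + qlen + qlen %/% 2L))
  })
}
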