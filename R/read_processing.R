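#' @title Read trimming, exact mapping, and genome instance counting
#' @name read_processing
NULL

#' Construct a sequenced sample from trimmed read sequences
#'
#' @param sample_id sample identifier.
#' @param sequences character vector of trimmed read sequences (one entry
#'   per read; duplicates allowed) or a data.frame with `sequence` and
#'   `count` columns.
#' @param population,sex,facility,kit sample metadata labels.
#' @param read_depth total number of trimmed reads >= the length floor;
#'   defaults to the number of reads supplied.
#' @return An object of class `sequenced_sample` with fields `sample_id`,
#'   `population`, `sex`, `facility`, `kit`, `read_depth` and `reads`
#'   (a data.frame of unique sequences with counts).
#' @export
sequenced_sample <- function(sample_id, sequences, population = NA,
                             sex = NA, facility = NA, kit = NA,
                             read_depth = NULL) {
  if (is.data.frame(sequences)) {
    reads <- data.frame(sequence = normalize_seq(sequences$sequence),
                        count = as.integer(sequences$count))
  } else {
    tab <- table(normalize_seq(sequences))
    reads <- data.frame(sequence = names(tab), count = as.integer(tab))
  }
  reads <- reads[order(-reads$count, reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  depth <- read_depth %||% sum(reads$count)
  structure(list(sample_id = sample_id, population = population, sex = sex,
                 facility = facility, kit = kit,
                 read_depth = as.integer(depth), reads = reads),
            class = "sequenced_sample")
}

#' @export
print.sequenced_sample <- function(x, ...) {
  cat(sprintf("<sequenced_sample> %s: %d reads (%d unique), population %s, sex %s\n",
              x$sample_id, x$read_depth, nrow(x$reads),
              as.character(x$population), as.character(x$sex)))
  invisible(x)
}

#' Quality- and adapter-trim a FASTQ file
#'
#' 3' bases with Phred quality below `min_qual` are removed first; the 3'
#' adapter is then clipped at its leftmost occurrence, allowing up to 10%
#' mismatches over the aligned overlap with a minimum overlap of 3 nt
#' (cutadapt-like semantics). Reads shorter than `min_len` after trimming
#' are discarded; the number surviving is recorded as the sample's read
#' depth.
#'
#' @param fastq path to a FASTQ file (optionally gzipped).
#' @param adapter3 3' adapter sequence (e.g. TruSeq
#'   `TGGAATTCTCGGGTGCCAAGG`, NEBNext `AGATCGGAAGAGCACACGTCT`).
#' @param min_len minimum retained insert length (default 16).
#' @param min_qual Phred floor for 3' quality trimming (default 20).
#' @param sample_id,population,sex,facility,kit metadata passed through to
#'   the returned [sequenced_sample()].
#' @param max_mismatch_rate allowed adapter mismatch fraction (default 0.1).
#' @param min_overlap minimum adapter overlap in nt (default 3).
#' @return A `sequenced_sample`.
#' @export
trim_reads <- function(fastq, adapter3, min_len = 16L, min_qual = 20L,
                       sample_id = basename(fastq), population = NA,
                       sex = NA, facility = NA, kit = NA,
                       max_mismatch_rate = 0.1, min_overlap = 3L) {
  if (!nzchar(adapter3)) stop("adapter3 must be non-empty")
  adapter3 <- normalize_seq(adapter3)
  # structural validation first: Biostrings does not reliably reject
  # truncated records
  bad <- first_bad_fastq_record(fastq, n_records = NA)
  if (!is.na(bad))
    stop("malformed FASTQ '", fastq, "' at record ", bad, call. = FALSE)
  seqs <- tryCatch(
    readDNAStringSet(fastq, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", fastq, "': ",
                             conditionMessage(e), call. = FALSE))
  reads <- as.character(seqs)
  quals <- as(Biostrings::PhredQuality(mcols(seqs)$qualities), "IntegerList")

  # 3' quality trim: drop the trailing run of bases below min_qual
  keep_len <- vapply(quals, function(q) {
    ok <- which(q >= min_qual)
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  reads <- substr(reads, 1L, keep_len)

  ins_len <- adapter_insert_length(reads, adapter3, max_mismatch_rate,
                                   min_overlap)
  inserts <- substr(reads, 1L, ins_len)
  kept <- nchar(inserts) >= min_len
  sequenced_sample(sample_id, inserts[kept], population = population,
                   sex = sex, facility = facility, kit = kit)
}

# index of the first structurally broken 4-line FASTQ record, NA when
# the file is well-formed (parsing itself is done by Biostrings)
first_bad_fastq_record <- function(fastq, n_records = NA) {
  lines <- readLines(fastq, warn = FALSE)
  if (length(lines) %% 4 != 0) return(length(lines) %/% 4 + 1L)
  n_rec <- length(lines) %/% 4
  heads <- lines[seq(1, length(lines), by = 4)]
  seps <- lines[seq(3, length(lines), by = 4)]
  seq_len_ <- nchar(lines[seq(2, length(lines), by = 4)])
  qual_len <- nchar(lines[seq(4, length(lines), by = 4)])
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+") |
                 seq_len_ != qual_len)
  if (length(bad)) bad[1] else NA_integer_
}

# length of the insert preceding the leftmost admissible adapter match;
# vectorized over reads
adapter_insert_length <- function(reads, adapter, max_mismatch_rate = 0.1,
                                  min_overlap = 3L) {
  n <- length(reads)
  if (!n) return(integer(0))
  len <- nchar(reads)
  maxw <- max(len, 1L)
  la <- nchar(adapter)
  achr <- strsplit(adapter, "")[[1]]
  # padded character matrix of reads
  m <- matrix("", nrow = n, ncol = maxw)
  spl <- strsplit(reads, "")
  for (i in seq_len(n)) if (len[i]) m[i, seq_len(len[i])] <- spl[[i]]

  ins <- len # default: no adapter found
  found <- rep(FALSE, n)
  for (s in seq_len(maxw)) {
    active <- !found & (len - s + 1L) >= min_overlap
    if (!any(active)) next
    ov <- pmin(len - s + 1L, la)
    mism <- integer(n)
    for (j in seq_len(min(la, maxw - s + 1L))) {
      pos <- s + j - 1L
      in_win <- active & j <= ov
      mism[in_win] <- mism[in_win] + (m[in_win, pos] != achr[j])
    }
    hit <- active & mism <= floor(max_mismatch_rate * ov)
    ins[hit] <- s - 1L
    found <- found | hit
  }
  ins
}

#' Exhaustively map sample reads onto padded reference rRNAs
#'
#' Every distinct read sequence is searched for exact (possibly
#' overlapping) occurrences in each padded reference. Coordinates are
#' reported so that position 1 is the unpadded 5' terminus of the rRNA:
#' starts <= 0 or ends > L indicate flank overlap (x-type fragments).
#' Alignments falling entirely within a flank are rejected. Reads mapping
#' to more than one rRNA are reported once per parent and flagged
#' `multi_parent`.
#'
#' @param sample a [sequenced_sample()].
#' @param padded_refs list of `rrna_reference` objects with flanks set
#'   (see [pad_reference()]).
#' @return data.frame with `sequence`, `parent`, `start`, `end`,
#'   `copies_in_parent`, `multi_parent`, `count` (read multiplicity in
#'   the sample), one row per (sequence, parent, offset). Unmapped read
#'   sequences are retained in the `"unmapped"` attribute for depth
#'   accounting.
#' @export
map_exact <- function(sample, padded_refs) {
  stopifnot(inherits(sample, "sequenced_sample"))
  pnames <- vapply(padded_refs, function(r) r$name, character(1))
  lens <- sort(unique(nchar(sample$reads$sequence)))
  idx <- exact_match_index(padded_refs, lens)

  hit <- idx[idx$sequence %in% sample$reads$sequence, , drop = FALSE]
  if (nrow(hit)) {
    hit$count <- sample$reads$count[match(hit$sequence,
                                          sample$reads$sequence)]
    key <- paste(hit$sequence, hit$parent, sep = "\r")
    hit$copies_in_parent <- as.integer(ave(seq_len(nrow(hit)), key,
                                           FUN = length))
    n_parents <- tapply(hit$parent, hit$sequence,
                        function(p) length(unique(p)))
    hit$multi_parent <- unname(n_parents[hit$sequence] > 1L)
    out <- hit[order(match(hit$parent, pnames), hit$start, hit$sequence), ,
               drop = FALSE]
  } else {
    out <- data.frame(sequence = character(), parent = character(),
                      start = integer(), end = integer(),
                      count = integer(), copies_in_parent = integer(),
                      multi_parent = logical())
  }
  rownames(out) <- NULL
  attr(out, "unmapped") <-
    sample$reads$sequence[!(sample$reads$sequence %in% out$sequence)]
  attr(out, "sample_id") <- sample$sample_id
  out
}

# enumerate every substring of the padded references at the given lengths
# (keeping those that overlap the unpadded rRNA body); the exhaustive
# exact-match dictionary that makes read mapping a hash lookup
exact_match_index <- function(padded_refs, lengths) {
  rows <- list()
  for (r in padded_refs) {
    pad5 <- nchar(r$flank5)
    L <- r$length
    padded <- padded_sequence(r)
    n <- nchar(padded)
    for (l in lengths) {
      if (n < l) next
      pos <- seq_len(n - l + 1L)
      st <- pos - pad5
      en <- st + l - 1L
      keep <- en >= 1L & st <= L
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substring(padded, pos[keep], pos[keep] + l - 1L),
        parent = r$name, start = st[keep], end = en[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sequence = character(), parent = character(),
                      start = integer(), end = integer()))
  do.call(rbind, rows)
}

#' Count exact genomic instances inside and outside the rRNA space
#'
#' Each sequence is searched for exact occurrences on both strands of the
#' whole genome (brute force). An occurrence counts as "inside" iff its
#' interval lies entirely within the merged rRNA space; occurrences that
#' merely overlap the boundary count as outside.
#'
#' @param sequences character vector of fragment sequences.
#' @param genome genome (see [as_genome()]).
#' @param space an `rrna_space` from [build_rrna_space()].
#' @return data.frame with `sequence`, `inside`, `outside`.
#' @export
count_instances <- function(sequences, genome, space) {
  gs <- as_genome(genome)
  sequences <- normalize_seq(sequences)
  uniq <- unique(sequences)
  res <- lapply(uniq, function(sq) {
    occ <- genome_occurrences(sq, gs)
    if (!nrow(occ)) return(c(inside = 0L, outside = 0L))
    inside <- space_contains(space, occ$chrom, occ$start, occ$end)
    c(inside = sum(inside), outside = sum(!inside))
  })
  tab <- do.call(rbind, res)
  out <- data.frame(sequence = uniq, inside = tab[, "inside"],
                    outside = tab[, "outside"], row.names = NULL)
  out[match(sequences, out$sequence), , drop = FALSE]
}

# all exact occurrences of sq on both strands, forward coordinates;
# a palindromic site is one genomic interval and is counted once
genome_occurrences <- function(sq, gs) {
  pat <- DNAString(sq)
  rc <- reverseComplement(pat)
  palindromic <- as.character(rc) == as.character(pat)
  rows <- list()
  for (ctg in names(gs)) {
    subj <- gs[[ctg]]
    fwd <- matchPattern(pat, subj)
    if (length(fwd))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ctg, start = start(fwd), end = end(fwd), strand = "+")
    if (!palindromic) {
      rev <- matchPattern(rc, subj)
      if (length(rev))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ctg, start = start(rev), end = end(rev), strand = "-")
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  do.call(rbind, rows)
}
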