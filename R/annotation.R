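#' @title Fragment classification and license plates
#' @name rrf_annotation
NULL

#' Classify fragments by position on the parental rRNA
#'
#' Types: `5p` (starts at rRNA position 1, full-span fragments included
#' by the 5p > 3p precedence), `3p` (ends at position L, starts inside),
#' `i` (fully interior), `x` (straddles a terminus into the genomic
#' flank, i.e. start < 1 or end > L).
#'
#' @param start,end 1-based flank-aware coordinates on the parent
#'   (position 1 is the rRNA 5' terminus); vectors are accepted.
#' @param L parental rRNA length (scalar or vector).
#' @param full_span type assigned to fragments spanning exactly 1..L
#'   (default `"5p"`).
#' @return character vector of types in `{5p, i, 3p, x}`.
#' @export
classify_fragment <- function(start, end, L, full_span = c("5p", "3p")) {
  full_span <- match.arg(full_span)
  out <- rep(NA_character_, length(start))
  is_x <- start < 1L | end > L
  out[is_x] <- "x"
  is_full <- !is_x & start == 1L & end == L
  out[is_full] <- full_span
  out[!is_x & !is_full & start == 1L] <- "5p"
  out[!is_x & !is_full & start > 1L & end == L] <- "3p"
  out[is.na(out)] <- "i"
  out
}

#' Sub-type of terminus-straddling fragments
#'
#' @param start,end flank-aware coordinates.
#' @param L parental rRNA length.
#' @return `"x5"` for fragments extending upstream of position 1, `"x3"`
#'   for fragments extending past position L, `"x53"` for both, `NA` for
#'   non-straddling fragments.
#' @export
x_subtype <- function(start, end, L) {
  up <- start < 1L
  dn <- end > L
  out <- rep(NA_character_, length(start))
  out[up & !dn] <- "x5"
  out[!up & dn] <- "x3"
  out[up & dn] <- "x53"
  out
}

# fixed 32-symbol alphabet of the block code (shipped as data so it can
# be swapped for another lookup); digits then unambiguous consonants
PLATE_ALPHABET <- c(0:9, LETTERS[!LETTERS %in% c("A", "E", "G", "I", "O", "T", "U")],
                    "a", "e", "o")

#' Reversible sequence "license plates"
#'
#' A fragment's license plate is `rRF-<length>-<code>` where the code is
#' a deterministic, reversible block encoding of the T-normalized
#' sequence: the sequence is split into blocks of up to 5 nt, each block
#' is read as a base-4 integer (A=0, C=1, G=2, T=3) and written as two
#' symbols of a fixed 32-character alphabet. The length in the label
#' fixes the block structure, so decoding inverts the encoding exactly
#' and every sequence maps to a unique label and vice versa.
#'
#' @param sequence character vector of sequences over `{A,C,G,T,U}`.
#' @return character vector of labels.
#' @seealso [decode_plate()]
#' @export
license_plate <- function(sequence) {
  sequence <- normalize_seq(sequence)
  if (any(grepl("[^ACGT]", sequence)))
    stop("license_plate: sequences must contain only A, C, G, T or U")
  vapply(sequence, function(sq) {
    n <- nchar(sq)
    vals <- match(strsplit(sq, "")[[1]], c("A", "C", "G", "T")) - 1L
    starts <- seq(1L, n, by = 5L)
    code <- vapply(starts, function(s) {
      block <- vals[s:min(s + 4L, n)]
      v <- sum(block * 4L^(rev(seq_along(block)) - 1L))
      paste0(PLATE_ALPHABET[v %/% 32L + 1L], PLATE_ALPHABET[v %% 32L + 1L])
    }, character(1))
    paste0("rRF-", n, "-", paste(code, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname license_plate
#' @param label character vector of labels produced by [license_plate()].
#' @return For `decode_plate`, the original sequences.
#' @export
decode_plate <- function(label) {
  vapply(label, function(lb) {
    m <- regmatches(lb, regexec("^rRF-([0-9]+)-([0-9A-Za-z]+)$", lb))[[1]]
    if (length(m) != 3) stop("not a license plate: '", lb, "'")
    n <- as.integer(m[2])
    code <- strsplit(m[3], "")[[1]]
    n_blocks <- ceiling(n / 5)
    if (length(code) != 2L * n_blocks)
      stop("license plate code length inconsistent with fragment length: '",
           lb, "'")
    block_sizes <- c(rep(5L, n_blocks - 1L), n - 5L * (n_blocks - 1L))
    out <- character(0)
    for (b in seq_len(n_blocks)) {
      d1 <- match(code[2L * b - 1L], PLATE_ALPHABET) - 1L
      d2 <- match(code[2L * b], PLATE_ALPHABET) - 1L
      if (is.na(d1) || is.na(d2)) stop("invalid symbol in plate '", lb, "'")
      v <- d1 * 32L + d2
      sz <- block_sizes[b]
      if (v >= 4L^sz) stop("invalid block value in plate '", lb, "'")
      digits <- integer(sz)
      for (k in sz:1) { digits[k] <- v %% 4L; v <- v %/% 4L }
      out <- c(out, c("A", "C", "G", "T")[digits + 1L])
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Assemble the rRF master table
#'
#' Joins alignments, filtered per-sample abundances, and genomic
#' instance counts into one record per (sequence, parent): type, license
#' plate, coordinates, inside/outside instance counts, and the RPM
#' vector over all samples (0 where a fragment is absent or below
#' threshold in a sample).
#'
#' @param alignments data.frame with `sequence`, `parent`, `start`,
#'   `end` and optional `copies_in_parent`, `multi_parent` (one row per
#'   (sequence, parent); for multi-offset fragments the first offset in
#'   parent order is reported).
#' @param abundances data.frame with `sequence`, `sample_id`, `rpm`
#'   (already filtered).
#' @param instance_counts data.frame with `sequence`, `inside`,
#'   `outside`.
#' @param refs list of `rrna_reference` objects (for parental lengths).
#' @param samples optional character vector fixing the sample column
#'   order (defaults to the samples present in `abundances`).
#' @return data.frame sorted by parent then start: `license_plate`,
#'   `sequence`, `parent`, `rrf_type`, `x_subtype`, `start`, `end`,
#'   `length`, `copies_in_parent`, `multi_parent`, `inside`, `outside`,
#'   `n_samples`, then one `rpm.<sample>` column per sample.
#' @export
assemble_rrf_records <- function(alignments, abundances, instance_counts,
                                 refs, samples = NULL) {
  samples <- samples %||% sort(unique(abundances$sample_id))
  missing <- setdiff(unique(abundances$sequence), unique(alignments$sequence))
  if (length(missing))
    stop("abundance records without alignments for ",
         length(missing), " sequence(s), e.g. ", missing[1])

  # one row per (sequence, parent): keep the first offset in parent order
  key <- paste(alignments$sequence, alignments$parent, sep = "\r")
  aln <- alignments[order(alignments$parent, alignments$start), , drop = FALSE]
  aln <- aln[!duplicated(paste(aln$sequence, aln$parent, sep = "\r")), ,
             drop = FALSE]
  aln <- aln[aln$sequence %in% abundances$sequence, , drop = FALSE]

  L <- setNames(vapply(refs, function(r) r$length, integer(1)),
                vapply(refs, function(r) r$name, character(1)))
  Lv <- L[aln$parent]
  rec <- data.frame(
    license_plate = license_plate(aln$sequence),
    sequence = aln$sequence, parent = aln$parent,
    rrf_type = classify_fragment(aln$start, aln$end, Lv),
    x_subtype = x_subtype(aln$start, aln$end, Lv),
    start = aln$start, end = aln$end, length = nchar(aln$sequence),
    copies_in_parent = if ("copies_in_parent" %in% names(aln))
      aln$copies_in_parent else 1L,
    multi_parent = if ("multi_parent" %in% names(aln))
      aln$multi_parent else FALSE,
    stringsAsFactors = FALSE)

  ic <- instance_counts[!duplicated(instance_counts$sequence), , drop = FALSE]
  idx <- match(rec$sequence, ic$sequence)
  rec$inside <- ic$inside[idx]
  rec$outside <- ic$outside[idx]

  rpm <- matrix(0, nrow = nrow(rec), ncol = length(samples),
                dimnames = list(NULL, paste0("rpm.", samples)))
  ri <- match(abundances$sequence, rec$sequence)
  ci <- match(abundances$sample_id, samples)
  keep <- !is.na(ri) & !is.na(ci)
  # a sequence may map to several parents: fill every matching row
  for (j in which(keep)) {
    rows <- which(rec$sequence == abundances$sequence[j])
    rpm[rows, ci[j]] <- abundances$rpm[j]
  }
  rec$n_samples <- rowSums(rpm > 0)
  out <- cbind(rec, as.data.frame(rpm, check.names = FALSE))
  out <- out[order(match(out$parent, names(L)), out$start, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the RPM expression matrix from a master table
#'
#' @param records master table from [assemble_rrf_records()].
#' @param id row identifier: `"license_plate"` (default) or `"sequence"`.
#' @return numeric matrix fragments x samples, with sample ids as column
#'   names.
#' @export
expression_matrix <- function(records, id = c("license_plate", "sequence")) {
  id <- match.arg(id)
  cols <- grep("^rpm\\.", names(records), value = TRUE)
  m <- as.matrix(records[, cols, drop = FALSE])
  colnames(m) <- sub("^rpm\\.", "", cols)
  rn <- records[[id]]
  # a sequence mapping to several parents appears once per parent; make
  # row names unique by parent suffix where needed
  if (anyDuplicated(rn))
    rn <- ifelse(duplicated(rn) | duplicated(rn, fromLast = TRUE),
                 paste0(rn, "@", records$parent), rn)
  rownames(m) <- rn
  m
}
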