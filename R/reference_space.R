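#' @title Reference rRNAs and the rRNA space
#' @name reference_space
#' @description Functions to load annotated reference rRNAs, pad them with
#'   genomic flanks, locate full-length and partial genomic copies, and
#'   assemble the merged "rRNA space" interval set used for exclusivity
#'   accounting.
NULL

## ---- genome helpers ---------------------------------------------------

#' Coerce a genome to a named DNAStringSet
#'
#' Accepts a `DNAStringSet`, a named character vector of contig sequences,
#' or the path of a FASTA file.
#'
#' @param genome genome in any of the accepted forms.
#' @return A named [Biostrings::DNAStringSet].
#' @export
as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    gs <- readDNAStringSet(genome)
  } else if (is.character(genome)) {
    gs <- DNAStringSet(toupper(genome))
  } else {
    stop("cannot interpret 'genome' (need DNAStringSet, named character, or FASTA path)")
  }
  if (is.null(names(gs)) || any(names(gs) == ""))
    stop("genome contigs must be named")
  # keep only the first whitespace-delimited token of FASTA headers
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

## ---- RRNAReference ----------------------------------------------------

#' Construct a reference rRNA object
#'
#' @param name rRNA name (conventionally one of 5S, 5.8S, 18S, 28S, 12S,
#'   16S, but any label is accepted for synthetic references).
#' @param sequence nucleotide sequence; U is normalized to T, case ignored.
#' @param placements optional data.frame of genomic intervals
#'   (`chrom`, `start`, `end`, `strand`, `kind`) where the full-length
#'   sequence occurs; 1-based inclusive coordinates.
#' @param flank5,flank3 genomic padding sequences (set by [pad_reference()]).
#' @param pad nominal flank size in nt.
#' @return An object of class `rrna_reference` with fields `name`,
#'   `sequence`, `length`, `placements`, `flank5`, `flank3`, `pad`.
#' @export
rrna_reference <- function(name, sequence, placements = NULL,
                           flank5 = "", flank3 = "", pad = 0L) {
  sequence <- normalize_seq(sequence)
  if (!nzchar(sequence))
    stop("reference rRNA '", name, "' has an empty sequence")
  if (grepl("[^ACGTN]", sequence))
    stop("reference rRNA '", name, "' contains characters outside {A,C,G,T,N,U}")
  if (pad < 0) stop("pad must be >= 0")
  if (nchar(flank5) > pad || nchar(flank3) > pad)
    stop("flanks longer than pad")
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence),
         placements = placements %||% empty_placements(),
         flank5 = normalize_seq(flank5), flank3 = normalize_seq(flank3),
         pad = as.integer(pad)),
    class = "rrna_reference")
}

empty_placements <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), kind = character())
}

#' @export
print.rrna_reference <- function(x, ...) {
  cat(sprintf("<rrna_reference> %s: %d nt, %d placement(s), pad %d (5' %d nt / 3' %d nt)\n",
              x$name, x$length, nrow(x$placements), x$pad,
              nchar(x$flank5), nchar(x$flank3)))
  invisible(x)
}

#' Padded sequence of a reference rRNA
#'
#' Concatenates the 5' flank, the rRNA sequence, and the 3' flank.
#'
#' @param ref an `rrna_reference`.
#' @return A single character string.
#' @export
padded_sequence <- function(ref) {
  paste0(ref$flank5, ref$sequence, ref$flank3)
}

## ---- load_references --------------------------------------------------

#' Load annotated reference rRNAs from a FASTA file
#'
#' Each row of `annotation_table` names one rRNA and points at a FASTA
#' record, optionally with a 1-based inclusive sub-interval (used for the
#' 18S/5.8S/28S units annotated inside a single 45S precursor record).
#'
#' @param fasta_path path to the reference FASTA (or a `DNAStringSet`).
#' @param annotation_table data.frame (or TSV path) with columns
#'   `name`, `record`, `start`, `end`. `start`/`end` may be `NA` to take
#'   the whole record.
#' @return A named list of [rrna_reference] objects, in table order.
#' @export
load_references <- function(fasta_path, annotation_table) {
  # read as plain strings: reference records may be RNA (U) or lowercase
  seqs <- if (is(fasta_path, "DNAStringSet")) fasta_path else
    Biostrings::readBStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- annotation_table
  if (is.character(ann) && length(ann) == 1)
    ann <- read.table(ann, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("name", "record")
  if (!all(required %in% names(ann)))
    stop("annotation_table needs columns 'name' and 'record'")
  if (!"start" %in% names(ann)) ann$start <- NA_integer_
  if (!"end" %in% names(ann)) ann$end <- NA_integer_

  missing <- ann$name[!(ann$record %in% names(seqs))]
  if (length(missing))
    stop("reference record(s) missing from FASTA for rRNA(s): ",
         paste(missing, collapse = ", "))

  refs <- lapply(seq_len(nrow(ann)), function(i) {
    rec <- as.character(seqs[[ann$record[i]]])
    L <- nchar(rec)
    if (L == 0)
      stop("reference rRNA '", ann$name[i], "' has an empty sequence")
    s <- ann$start[i]; e <- ann$end[i]
    if (is.na(s)) s <- 1L
    if (is.na(e)) e <- L
    if (s < 1 || e > L || s > e)
      stop("annotated span ", s, "..", e, " for rRNA '", ann$name[i],
           "' lies outside its record (1..", L, ")")
    rrna_reference(ann$name[i], substr(rec, s, e))
  })
  names(refs) <- ann$name
  refs
}

## ---- placements and padding -------------------------------------------

#' Locate exact full-length genomic placements of a reference rRNA
#'
#' Searches both strands of every contig for exact occurrences of the
#' full-length rRNA sequence. Coordinates are 1-based inclusive on the
#' forward strand.
#'
#' @param ref an `rrna_reference`.
#' @param genome genome (see [as_genome()]).
#' @return The reference with its `placements` field filled
#'   (`kind = "full_rRNA"`), sorted in genome order.
#' @export
locate_placements <- function(ref, genome) {
  gs <- as_genome(genome)
  hits <- find_exact_occurrences(ref$sequence, gs)
  hits$kind <- rep("full_rRNA", nrow(hits))
  ref$placements <- hits[order(hits$chrom, hits$start), , drop = FALSE]
  rownames(ref$placements) <- NULL
  ref
}

# exact occurrences of `sequence` on both strands of a DNAStringSet,
# forward-strand coordinates; data.frame(chrom, start, end, strand)
find_exact_occurrences <- function(sequence, gs) {
  sequence <- normalize_seq(sequence)
  pat <- DNAString(sequence)
  rc <- reverseComplement(pat)
  out <- lapply(names(gs), function(ctg) {
    subj <- gs[[ctg]]
    fwd <- matchPattern(pat, subj)
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character())
    if (length(fwd))
      res <- rbind(res, data.frame(chrom = ctg, start = start(fwd),
                                   end = end(fwd), strand = "+"))
    # palindromic sequences must not be double counted
    if (as.character(rc) != as.character(pat)) {
      rev <- matchPattern(rc, subj)
      if (length(rev))
        res <- rbind(res, data.frame(chrom = ctg, start = start(rev),
                                     end = end(rev), strand = "-"))
    }
    res
  })
  do.call(rbind, out)
}

#' Pad a reference rRNA with genomic flanks
#'
#' Takes up to `pad` nt of genomic context on each side of the canonical
#' placement (the first placement in genome order), reverse-complemented
#' for minus-strand placements and truncated at contig ends. If other
#' placements carry different flanking sequence a warning is issued and
#' the canonical placement wins.
#'
#' @param ref an `rrna_reference` with at least one placement (call
#'   [locate_placements()] first, or supply placements directly).
#' @param genome genome (see [as_genome()]).
#' @param pad flank size in nt (default 50).
#' @return The reference with `flank5`, `flank3` and `pad` set.
#' @export
pad_reference <- function(ref, genome, pad = 50L) {
  gs <- as_genome(genome)
  if (nrow(ref$placements) == 0) ref <- locate_placements(ref, gs)
  pl <- ref$placements
  if (nrow(pl) == 0)
    stop("reference rRNA '", ref$name, "' has no genomic placement to pad from")
  pl <- pl[order(pl$chrom, pl$start), , drop = FALSE]

  flanks_of <- function(row) {
    ctg <- as.character(gs[[row$chrom]])
    L <- nchar(ctg)
    up <- substr(ctg, max(1L, row$start - pad), row$start - 1L)
    dn <- substr(ctg, row$end + 1L, min(L, row$end + pad))
    if (identical(row$strand, "-")) {
      list(f5 = as.character(reverseComplement(DNAString(dn))),
           f3 = as.character(reverseComplement(DNAString(up))))
    } else {
      list(f5 = up, f3 = dn)
    }
  }
  all_flanks <- lapply(seq_len(nrow(pl)), function(i) flanks_of(pl[i, ]))
  canon <- all_flanks[[1]]
  if (nrow(pl) > 1) {
    same <- vapply(all_flanks[-1], function(f)
      identical(f$f5, canon$f5) && identical(f$f3, canon$f3), logical(1))
    if (!all(same))
      warning("conflicting flanks across placements of '", ref$name,
              "'; using the canonical (first in genome order) placement")
  }
  ref$pad <- as.integer(pad)
  ref$flank5 <- canon$f5
  ref$flank3 <- canon$f3
  ref$placements <- pl
  ref
}

## ---- rRNA space -------------------------------------------------------

#' Assemble the rRNA space
#'
#' The rRNA space is the merged union of (a) the genomic intervals of the
#' full-length reference rRNAs, (b) annotated rRNA repeats (e.g. from a
#' RepeatMasker-derived BED file), and (c) partial rRNA copies found by
#' [find_partial_copies()]. Membership queries are strand-agnostic.
#'
#' @param refs list of `rrna_reference` objects with placements set.
#' @param repeat_annotations optional: BED file path (0-based half-open,
#'   converted on read) or data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive) and optional `strand`.
#' @param partial_copies optional data.frame of partial-copy intervals as
#'   returned by [find_partial_copies()].
#' @param genome genome, used to validate that intervals lie on known
#'   contigs within their lengths.
#' @return An object of class `rrna_space` wrapping a merged
#'   [GenomicRanges::GRanges] (`$ranges`) plus the contig lengths.
#' @export
build_rrna_space <- function(refs, repeat_annotations = NULL,
                             partial_copies = NULL, genome) {
  gs <- as_genome(genome)
  contig_len <- setNames(width(gs), names(gs))

  pieces <- list()
  for (ref in refs) {
    if (nrow(ref$placements))
      pieces[[length(pieces) + 1L]] <-
        ref$placements[, c("chrom", "start", "end"), drop = FALSE]
  }
  if (!is.null(repeat_annotations)) {
    rep_df <- repeat_annotations
    if (is.character(rep_df) && length(rep_df) == 1) rep_df <- read_bed(rep_df)
    pieces[[length(pieces) + 1L]] <-
      rep_df[, c("chrom", "start", "end"), drop = FALSE]
  }
  if (!is.null(partial_copies) && nrow(partial_copies))
    pieces[[length(pieces) + 1L]] <-
      partial_copies[, c("chrom", "start", "end"), drop = FALSE]

  df <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(), start = integer(), end = integer())

  if (nrow(df)) {
    bad <- !(df$chrom %in% names(contig_len)) |
      df$start < 1 | df$end > contig_len[df$chrom]
    if (any(bad))
      stop("interval(s) off-contig in rRNA space input: ",
           paste(sprintf("%s:%d-%d", df$chrom[bad], df$start[bad], df$end[bad]),
                 collapse = ", "))
  }

  gr <- GRanges(seqnames = df$chrom, ranges = IRanges(df$start, df$end))
  merged <- reduce(gr, ignore.strand = TRUE)
  structure(list(ranges = sort(merged), contig_lengths = contig_len),
            class = "rrna_space")
}

#' @export
print.rrna_space <- function(x, ...) {
  cat(sprintf("<rrna_space> %d merged interval(s), %d nt total, %d contig(s)\n",
              length(x$ranges), sum(width(x$ranges)),
              length(x$contig_lengths)))
  invisible(x)
}

#' Test whether intervals lie entirely inside the rRNA space
#'
#' Strand-agnostic containment: an interval is inside iff it is fully
#' covered by one merged rRNA-space interval. Intervals that only
#' partially overlap the space are counted as outside (conservative
#' exclusivity).
#'
#' @param space an `rrna_space`.
#' @param chrom,start,end vectors describing query intervals (1-based
#'   inclusive).
#' @return Logical vector.
#' @export
space_contains <- function(space, chrom, start, end) {
  if (length(chrom) == 0) return(logical(0))
  q <- GRanges(seqnames = chrom, ranges = IRanges(start, end))
  countOverlaps(q, space$ranges, type = "within", ignore.strand = TRUE) > 0
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open; coordinates are converted to 1-based
#' inclusive on read.
#'
#' @param path BED file path (first three columns chrom, start, end;
#'   optional name, score, strand).
#' @return data.frame with `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = df[[2]] + 1L, end = df[[3]],
                    strand = if (ncol(df) >= 6) df[[6]] else "*")
  out
}

#' Write intervals as a BED file
#'
#' @param df data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and optional `name`, `strand` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = 0L,
                    strand = if ("strand" %in% names(df)) df$strand else "*")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export an rRNA space and its references
#'
#' Writes the merged rRNA-space intervals as BED and a JSON manifest of
#' the references (name, length, placements, flanks).
#'
#' @param space an `rrna_space`.
#' @param refs list of `rrna_reference` objects.
#' @param bed_path,json_path output paths.
#' @return Invisibly, a list with the two paths.
#' @export
export_rrna_space <- function(space, refs, bed_path, json_path) {
  gr <- space$ranges
  write_bed(data.frame(chrom = as.character(seqnames(gr)),
                       start = start(gr), end = end(gr)), bed_path)
  manifest <- lapply(refs, function(r)
    list(name = r$name, length = r$length, pad = r$pad,
         flank5 = r$flank5, flank3 = r$flank3,
         placements = r$placements))
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(bed = bed_path, json = json_path))
}
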