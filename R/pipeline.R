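#' @title End-to-end rRF discovery pipeline
#' @name pipeline
NULL

#' Run the full rRF discovery and filtering pipeline on a cohort
#'
#' Applies, in order: exhaustive exact mapping of every sample's reads
#' onto the padded references; the per-sample adaptive raw-count
#' threshold; RPM normalization against each sample's full read depth
#' and the `min_rpm` floor; genomic instance counting for the surviving
#' fragments; the per-rRNA S/N length cutoffs; and assembly of the rRF
#' master table.
#'
#' @param samples list of [sequenced_sample()] objects (e.g. from
#'   [trim_reads()]).
#' @param refs named list of padded `rrna_reference` objects.
#' @param genome genome (see [as_genome()]).
#' @param space an `rrna_space` from [build_rrna_space()].
#' @param min_rpm RPM floor (default 10).
#' @param sn_min S/N cutoff (default 50).
#' @param threshold_strategy strategy for [adaptive_threshold()].
#' @param lengths fragment lengths considered (default 16:33; fragments
#'   outside the range are discarded at mapping).
#' @param exclusivity also apply the per-fragment exclusivity filter
#'   ([apply_exclusivity_filter()]); default FALSE.
#' @return list of class `rrf_pipeline` with `records` (master table),
#'   `sn_table`, `thresholds` (named per-sample), `abundances` (long
#'   filtered data.frame: `sequence`, `sample_id`, `raw_count`, `rpm`),
#'   `alignments`, `instance_counts`, `samples` (metadata data.frame).
#' @export
run_rrf_pipeline <- function(samples, refs, genome, space, min_rpm = 10,
                             sn_min = 50, threshold_strategy = "cliff",
                             lengths = 16:33, exclusivity = FALSE) {
  stopifnot(length(samples) > 0)
  sample_ids <- vapply(samples, function(s) s$sample_id, character(1))

  aln_list <- list(); ab_rows <- list(); thresholds <- integer(0)
  for (s in samples) {
    aln <- map_exact(s, refs)
    aln <- aln[aln$end - aln$start + 1L >= min(lengths) &
                 aln$end - aln$start + 1L <= max(lengths), , drop = FALSE]
    aln_list[[s$sample_id]] <- aln
    # per-sequence raw counts of mapped fragments (independent of parent)
    useq <- unique(aln[, c("sequence", "count")])
    if (!nrow(useq)) {
      thresholds[s$sample_id] <- NA_integer_
      next
    }
    thr <- adaptive_threshold(useq$count, strategy = threshold_strategy)
    thresholds[s$sample_id] <- thr
    keep <- useq[useq$count >= thr, , drop = FALSE]
    if (!nrow(keep)) next
    ab_rows[[s$sample_id]] <- data.frame(
      sequence = keep$sequence, sample_id = s$sample_id,
      raw_count = keep$count,
      rpm = rpm_normalize(keep$count, s$read_depth),
      stringsAsFactors = FALSE)
  }
  abundances <- if (length(ab_rows)) do.call(rbind, ab_rows) else
    data.frame(sequence = character(), sample_id = character(),
               raw_count = integer(), rpm = numeric())
  abundances <- apply_rpm_filter(abundances, min_rpm = min_rpm)
  rownames(abundances) <- NULL

  retained <- unique(abundances$sequence)
  alignments <- unique(do.call(rbind, aln_list)[, c(
    "sequence", "parent", "start", "end", "copies_in_parent",
    "multi_parent")])
  alignments <- alignments[alignments$sequence %in% retained, , drop = FALSE]

  if (length(retained)) {
    instance_counts <- count_instances(retained, genome, space)
  } else {
    instance_counts <- data.frame(sequence = character(), inside = integer(),
                                  outside = integer())
  }

  frag <- unique(alignments[, c("sequence", "parent")])
  frag$length <- nchar(frag$sequence)
  idx <- match(frag$sequence, instance_counts$sequence)
  frag$inside <- instance_counts$inside[idx]
  frag$outside <- instance_counts$outside[idx]
  sn_table <- compute_sn_table(frag, sn_min = sn_min, lengths = lengths)

  keep_frag <- apply_length_filter(frag, sn_table)
  if (exclusivity) keep_frag <- apply_exclusivity_filter(keep_frag)
  key <- paste(alignments$sequence, alignments$parent)
  alignments <- alignments[key %in% paste(keep_frag$sequence,
                                          keep_frag$parent), , drop = FALSE]
  abundances <- abundances[abundances$sequence %in% keep_frag$sequence, ,
                           drop = FALSE]

  records <- assemble_rrf_records(alignments, abundances, instance_counts,
                                  refs, samples = sample_ids)
  meta <- data.frame(
    sample_id = sample_ids,
    population = vapply(samples, function(s) as.character(s$population),
                        character(1)),
    sex = vapply(samples, function(s) as.character(s$sex), character(1)),
    read_depth = vapply(samples, function(s) s$read_depth, integer(1)),
    stringsAsFactors = FALSE)

  structure(list(records = records, sn_table = sn_table,
                 thresholds = thresholds, abundances = abundances,
                 alignments = alignments, instance_counts = instance_counts,
                 samples = meta),
            class = "rrf_pipeline")
}

#' @export
print.rrf_pipeline <- function(x, ...) {
  cat(sprintf("<rrf_pipeline> %d retained rRF record(s) across %d sample(s)\n",
              nrow(x$records), nrow(x$samples)))
  print(x$sn_table)
  invisible(x)
}

#' Long-format abundance table with parent coordinates
#'
#' Joins the master table's coordinates with its per-sample RPM columns
#' into the long format consumed by the profile and endpoint reports.
#'
#' @param records master table from [assemble_rrf_records()].
#' @return data.frame with `sequence`, `parent`, `start`, `end`,
#'   `length`, `sample_id`, `rpm` (zero-RPM entries omitted).
#' @export
records_to_long <- function(records) {
  cols <- grep("^rpm\\.", names(records), value = TRUE)
  out <- do.call(rbind, lapply(cols, function(cc) {
    sel <- records[[cc]] > 0
    if (!any(sel)) return(NULL)
    data.frame(sequence = records$sequence[sel],
               parent = records$parent[sel],
               start = records$start[sel], end = records$end[sel],
               length = records$length[sel],
               sample_id = sub("^rpm\\.", "", cc),
               rpm = records[[cc]][sel], stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(sequence = character(), parent = character(),
                      start = integer(), end = integer(),
                      length = integer(), sample_id = character(),
                      rpm = numeric())
  rownames(out) <- NULL
  out
}
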