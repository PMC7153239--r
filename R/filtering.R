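#' @title Abundance and exclusivity filters
#' @name rrf_filtering
#' @description The three filter tiers applied to candidate rRFs: a
#'   per-sample adaptive raw-count threshold, a reads-per-million floor,
#'   and per-rRNA minimum fragment lengths derived from a genomic
#'   signal-to-noise criterion.
NULL

#' Per-sample adaptive raw-count threshold
#'
#' Separates the low-count noise regime from genuinely supported
#' fragments by examining the species-survival curve `S(c)` (number of
#' distinct fragments with raw count >= `c`) at the sorted distinct
#' observed counts. The default `"cliff"` strategy locates the single
#' step between consecutive candidate values that eliminates the most
#' species; if that step removes at least `cliff_min` of all species the
#' threshold is the candidate just above the cliff, otherwise the counts
#' are considered inseparable and the threshold is 1. The `"plateau"`
#' strategy instead returns the smallest candidate after which the
#' relative drop in survivors across a window of `w` candidate values
#' falls below `eps`. Both scan the observed count values rather than a
#' fixed additive grid, so the selected fragment set is invariant under
#' rescaling of the count vector. A fixed cutoff is available via
#' `strategy = "fixed"`.
#'
#' @param raw_counts integer vector of per-distinct-fragment raw counts
#'   for one sample.
#' @param strategy `"cliff"` (default), `"plateau"`, or `"fixed"`.
#' @param cliff_min minimum fraction of all species a step must remove
#'   to count as the noise cliff (default 0.5).
#' @param w plateau window width in candidate values (default 5).
#' @param eps plateau relative-drop tolerance (default 0.01).
#' @param fixed cutoff used when `strategy = "fixed"`.
#' @return A single integer threshold; fragments with raw count below it
#'   are discarded for this sample.
#' @export
adaptive_threshold <- function(raw_counts,
                               strategy = c("cliff", "plateau", "fixed"),
                               cliff_min = 0.5, w = 5L, eps = 0.01,
                               fixed = 1L) {
  strategy <- match.arg(strategy)
  raw_counts <- as.integer(raw_counts)
  if (!length(raw_counts) || all(is.na(raw_counts)) || max(raw_counts) < 1L)
    stop("adaptive_threshold: sample has no fragments with count >= 1")
  if (strategy == "fixed") return(as.integer(fixed))

  cand <- sort(unique(raw_counts))
  K <- length(cand)
  surv <- vapply(cand, function(c) sum(raw_counts >= c), numeric(1))

  if (strategy == "cliff") {
    if (K == 1L) return(1L)
    steps <- surv[-K] - surv[-1L]
    j <- which.max(steps)
    if (steps[j] / surv[1L] >= cliff_min) return(cand[j + 1L])
    return(1L)
  }

  for (k in seq_len(K)) {
    k2 <- min(k + w, K)
    drop_rel <- (surv[k] - surv[k2]) / surv[k]
    if (drop_rel < eps) return(cand[k])
  }
  cand[K]
}

#' Reads-per-million normalization
#'
#' @param raw_count fragment read count(s).
#' @param read_depth total trimmed reads of the sample (the RPM
#'   denominator is the sample's full read depth, not its mapped reads).
#' @return `raw_count / read_depth * 1e6`.
#' @export
rpm_normalize <- function(raw_count, read_depth) {
  if (any(read_depth <= 0)) stop("read_depth must be > 0")
  raw_count / read_depth * 1e6
}

#' Apply the minimum-RPM abundance filter
#'
#' A fragment is retained for a sample iff its RPM in that sample is at
#' least `min_rpm`; a fragment is retained at cohort level iff it passes
#' in at least one sample (which row-wise filtering implies).
#'
#' @param records data.frame of per-sample abundance records with an
#'   `rpm` column.
#' @param min_rpm abundance floor (default 10 RPM).
#' @return The surviving rows of `records`.
#' @export
apply_rpm_filter <- function(records, min_rpm = 10) {
  records[records$rpm >= min_rpm, , drop = FALSE]
}

#' Signal-to-noise table and per-rRNA minimum fragment lengths
#'
#' For each parental rRNA and fragment length, the signal-to-noise ratio
#' is the summed count of exact genomic instances falling inside the
#' rRNA space over the summed count falling outside, across all retained
#' fragments of that parent and length. A cell with no outside instances
#' is `Inf` (passes any cutoff); a cell with no fragments is `NA`. The
#' minimum length for a parent is the smallest length whose S/N is at
#' least `sn_min`; fragments shorter than it are discarded downstream.
#'
#' @param fragments data.frame with one row per distinct fragment:
#'   `parent`, `sequence` (or `length`), `inside`, `outside`.
#' @param sn_min S/N cutoff (default 50, i.e. at most ~2% of instances
#'   outside the rRNA space).
#' @param lengths fragment lengths considered (default 16:33).
#' @return An object of class `length_cutoff_table`: list with `sn`
#'   (lengths x parents matrix), `min_length` (named integer vector; `NA`
#'   for parents with no passing length), `sn_min`.
#' @export
compute_sn_table <- function(fragments, sn_min = 50, lengths = 16:33) {
  if (!"length" %in% names(fragments))
    fragments$length <- nchar(fragments$sequence)
  fragments <- fragments[fragments$length %in% lengths, , drop = FALSE]
  parents <- unique(fragments$parent)
  sn <- matrix(NA_real_, nrow = length(lengths), ncol = length(parents),
               dimnames = list(as.character(lengths), parents))
  for (p in parents) {
    for (l in lengths) {
      sel <- fragments$parent == p & fragments$length == l
      if (!any(sel)) next
      inside <- sum(fragments$inside[sel])
      outside <- sum(fragments$outside[sel])
      sn[as.character(l), p] <- if (outside == 0) Inf else inside / outside
    }
  }
  min_length <- vapply(parents, function(p) {
    pass <- which(!is.na(sn[, p]) & sn[, p] >= sn_min)
    if (!length(pass)) NA_integer_ else as.integer(lengths[min(pass)])
  }, integer(1))
  if (any(is.na(min_length)))
    message("no S/N-passing length for parent(s): ",
            paste(parents[is.na(min_length)], collapse = ", "),
            "; they are excluded downstream")
  structure(list(sn = sn, min_length = min_length, sn_min = sn_min,
                 lengths = lengths),
            class = "length_cutoff_table")
}

#' @export
print.length_cutoff_table <- function(x, ...) {
  cat(sprintf("<length_cutoff_table> S/N >= %g minimum lengths:\n", x$sn_min))
  print(x$min_length)
  invisible(x)
}

#' Apply the per-rRNA minimum-length filter
#'
#' @param records data.frame with `parent` and `sequence` (or `length`)
#'   columns.
#' @param cutoffs a `length_cutoff_table` from [compute_sn_table()].
#' @return Rows of `records` whose fragment length reaches the parent's
#'   minimum length; parents without a defined minimum are dropped.
#' @export
apply_length_filter <- function(records, cutoffs) {
  len <- if ("length" %in% names(records)) records$length else
    nchar(records$sequence)
  minl <- cutoffs$min_length[records$parent]
  records[!is.na(minl) & len >= minl, , drop = FALSE]
}

#' Optional per-fragment exclusivity filter
#'
#' Retains fragments whose fraction of genomic instances outside the
#' rRNA space is at most `max_outside_frac`. This per-fragment rule is a
#' stricter companion to the aggregate per-length S/N criterion and is
#' off by default in [run_rrf_pipeline()].
#'
#' @param fragments data.frame with `inside` and `outside` columns.
#' @param max_outside_frac maximum outside fraction (default 0.02).
#' @return The surviving rows.
#' @export
apply_exclusivity_filter <- function(fragments, max_outside_frac = 0.02) {
  tot <- fragments$inside + fragments$outside
  frac <- ifelse(tot == 0, 1, fragments$outside / tot)
  fragments[frac <= max_outside_frac, , drop = FALSE]
}

#' Write a signal-to-noise table as TSV
#'
#' Rows are fragment lengths, columns parental rRNAs; infinite cells
#' (no outside instances) are written as `"inf"`, empty cells as `""`.
#'
#' @param cutoffs a `length_cutoff_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sn_table <- function(cutoffs, path) {
  m <- cutoffs$sn
  chr <- ifelse(is.na(m), "", ifelse(is.infinite(m), "inf",
                                     formatC(m, format = "g")))
  df <- data.frame(length = rownames(m), chr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
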