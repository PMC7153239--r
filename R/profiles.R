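#' @title Descriptive profiles and reports
#' @name profiles_reports
NULL

#' Sample-presence counts
#'
#' For each fragment, the number of samples in which it reaches the
#' abundance floor.
#'
#' @param x fragments x samples RPM matrix.
#' @param min_rpm abundance floor (default 10 RPM).
#' @return named integer vector, one entry per fragment.
#' @export
sample_presence_counts <- function(x, min_rpm = 10) {
  x <- as.matrix(x)
  setNames(as.integer(rowSums(x >= min_rpm)),
           rownames(x) %||% as.character(seq_len(nrow(x))))
}

#' Unique fragments per unit of parental rRNA length
#'
#' @param n_unique_rrfs number of unique fragments from a parent.
#' @param rrna_length parental rRNA length in nt (> 0).
#' @return `n_unique_rrfs / rrna_length`.
#' @export
per_unit_length_yield <- function(n_unique_rrfs, rrna_length) {
  if (any(rrna_length <= 0)) stop("rrna_length must be > 0")
  n_unique_rrfs / rrna_length
}

#' Per-sample length-ratio profile of a parental rRNA
#'
#' For one sample and parent, the fraction of the parent's total RPM
#' contributed by fragments of each length (ratios sum to 1 when the
#' parent has signal in the sample).
#'
#' @param abundances long data.frame with `parent`, `sample_id`, `rpm`
#'   and `sequence` (or `length`).
#' @param sample sample id.
#' @param parent parental rRNA name.
#' @param lengths lengths reported (default 16:33).
#' @return list of class `length_profile` with `sample_id`, `parent`,
#'   `ratio` (named numeric over `lengths`), `total_rpm`, and `empty`
#'   flag (TRUE with a message when the parent has zero RPM in the
#'   sample).
#' @export
length_ratio_profile <- function(abundances, sample, parent,
                                 lengths = 16:33) {
  if (!"length" %in% names(abundances))
    abundances$length <- nchar(abundances$sequence)
  sel <- abundances$sample_id == sample & abundances$parent == parent &
    abundances$length %in% lengths
  ratio <- setNames(numeric(length(lengths)), as.character(lengths))
  tot <- sum(abundances$rpm[sel])
  if (tot > 0) {
    agg <- tapply(abundances$rpm[sel], abundances$length[sel], sum)
    ratio[names(agg)] <- agg / tot
  } else {
    message("length_ratio_profile: no signal for ", parent, " in ", sample)
  }
  structure(list(sample_id = sample, parent = parent, ratio = ratio,
                 total_rpm = tot, empty = tot == 0),
            class = "length_profile")
}

#' Length-ratio matrix over all samples of a cohort
#'
#' @param abundances long data.frame as in [length_ratio_profile()].
#' @param parent parental rRNA name.
#' @param lengths lengths reported (default 16:33).
#' @return samples x lengths matrix of ratios (rows sum to 1 for samples
#'   with signal, and are all-zero otherwise).
#' @export
length_ratio_matrix <- function(abundances, parent, lengths = 16:33) {
  samples <- sort(unique(abundances$sample_id))
  m <- t(vapply(samples, function(s)
    suppressMessages(length_ratio_profile(abundances, s, parent, lengths)$ratio),
    numeric(length(lengths))))
  rownames(m) <- samples
  m
}

#' Endpoint distributions and row-scaled abundance heatmap input
#'
#' Histograms of fragment 5' and 3' positions weighted by RPM, restricted
#' to a coordinate region of the (padded) parent, plus a samples x
#' positions matrix of per-position RPM coverage z-scored within each
#' sample (the row scaling used for relative-abundance heatmaps).
#'
#' @param abundances long data.frame with `parent`, `sample_id`, `rpm`,
#'   `start`, `end` (flank-aware parent coordinates).
#' @param parent parental rRNA name.
#' @param region length-2 integer vector `c(lo, hi)` of parent
#'   coordinates (may extend into the flanks).
#' @return list with `start_hist` and `end_hist` (named RPM-weighted
#'   histograms over positions in `region`), and `heat` (samples x
#'   positions z-scored coverage; rows with zero variance are left as
#'   zeros).
#' @export
endpoint_distributions <- function(abundances, parent, region) {
  lo <- region[1]; hi <- region[2]
  sel <- abundances$parent == parent &
    abundances$end >= lo & abundances$start <= hi
  ab <- abundances[sel, , drop = FALSE]
  pos <- lo:hi
  hist_of <- function(p) {
    h <- setNames(numeric(length(pos)), as.character(pos))
    inreg <- p >= lo & p <= hi
    if (any(inreg)) {
      agg <- tapply(ab$rpm[inreg], p[inreg], sum)
      h[names(agg)] <- agg
    }
    h
  }
  start_hist <- hist_of(ab$start)
  end_hist <- hist_of(ab$end)

  samples <- sort(unique(abundances$sample_id))
  heat <- matrix(0, nrow = length(samples), ncol = length(pos),
                 dimnames = list(samples, as.character(pos)))
  for (i in seq_len(nrow(ab))) {
    cover <- max(ab$start[i], lo):min(ab$end[i], hi)
    heat[ab$sample_id[i], as.character(cover)] <-
      heat[ab$sample_id[i], as.character(cover)] + ab$rpm[i]
  }
  heat <- t(apply(heat, 1, function(r) {
    if (sd(r) == 0) r * 0 else (r - mean(r)) / sd(r)
  }))
  colnames(heat) <- as.character(pos)
  list(start_hist = start_hist, end_hist = end_hist, heat = heat)
}

#' Boundary report: terminus extensions and unvisited terminal runs
#'
#' Summarizes, per parent, how far retained fragments extend beyond the
#' annotated rRNA termini (via x-type fragments) and how many terminal
#' positions are covered by no retained fragment.
#'
#' @param records master table from [assemble_rrf_records()] (needs
#'   `parent`, `start`, `end`).
#' @param refs list of `rrna_reference` objects.
#' @return data.frame with one row per parent: `parent`, `L`,
#'   `min_start`, `max_end`, `upstream_extension`,
#'   `downstream_extension`, `unvisited_5p`, `unvisited_3p` (maximal
#'   uncovered runs at the termini; parents with no retained fragments
#'   get `NA` endpoints and full-length unvisited runs).
#' @export
boundary_report <- function(records, refs) {
  rows <- lapply(refs, function(ref) {
    rec <- records[records$parent == ref$name, , drop = FALSE]
    L <- ref$length
    if (!nrow(rec))
      return(data.frame(parent = ref$name, L = L,
                        min_start = NA_integer_, max_end = NA_integer_,
                        upstream_extension = 0L, downstream_extension = 0L,
                        unvisited_5p = L, unvisited_3p = L))
    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(rec))) {
      s <- max(1L, rec$start[i]); e <- min(L, rec$end[i])
      if (s <= e) covered[s:e] <- TRUE
    }
    un5 <- if (covered[1]) 0L else which(covered)[1] - 1L
    un3 <- if (covered[L]) 0L else L - max(which(covered))
    if (!any(covered)) { un5 <- L; un3 <- L }
    data.frame(parent = ref$name, L = L,
               min_start = min(rec$start), max_end = max(rec$end),
               upstream_extension = max(0L, 1L - min(rec$start)),
               downstream_extension = max(0L, max(rec$end) - L),
               unvisited_5p = un5, unvisited_3p = un3)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation of samples on their top-k fragments
#'
#' Per parent (or globally), selects the `k` fragments with the highest
#' mean RPM across the compared samples and computes the pairwise
#' Pearson correlation matrix of the sample RPM vectors restricted to
#' those fragments.
#'
#' @param x fragments x samples RPM matrix.
#' @param k number of top fragments (default 1000); when fewer are
#'   available all are used (with a message).
#' @param parents optional character vector (one per row of `x`) for
#'   per-parent grouping; `NULL` computes a single global matrix.
#' @return A correlation matrix, or a named list of matrices when
#'   `parents` is given.
#' @export
top_k_correlation <- function(x, k = 1000L, parents = NULL) {
  x <- as.matrix(x)
  corr_of <- function(m) {
    if (nrow(m) < k)
      message("top_k_correlation: only ", nrow(m), " fragments available")
    top <- head(order(rowMeans(m), decreasing = TRUE), k)
    cor(m[top, , drop = FALSE])
  }
  if (is.null(parents)) return(corr_of(x))
  stopifnot(length(parents) == nrow(x))
  lapply(split(seq_len(nrow(x)), parents), function(idx)
    corr_of(x[idx, , drop = FALSE]))
}
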