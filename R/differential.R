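#' @title Differential abundance: SAM-style permutation test, PLS-DA VIP,
#'   and iDARs
#' @name differential_abundance
NULL

#' Two-class SAM-style permutation test
#'
#' Computes the moderated d-statistic of Significance Analysis of
#' Microarrays, `d_i = (mean_A - mean_B) / (s_i + s0)`, where `s_i` is
#' the pooled standard error and the exchangeability constant `s0` is
#' the percentile of the `s_i` distribution that minimizes the
#' coefficient of variation of the d-spread across s-bins (Tusher
#' procedure). False discovery rates are estimated from a permutation
#' null: at each |d| cutoff the expected number of false calls (mean
#' over label permutations) is divided by the observed number of calls,
#' and the resulting ratios are monotonized into q-values.
#'
#' By default abundances are tested on the log2(RPM + pseudo) scale,
#' which stabilizes the variance of overdispersed counts.
#'
#' @param x numeric matrix, fragments x samples (RPM).
#' @param labels factor (or coercible) with exactly two levels giving
#'   each sample's group; at least 2 samples per group.
#' @param n_perm number of label permutations (>= 100); when the number
#'   of distinct label arrangements is at most `n_perm` they are
#'   enumerated exactly.
#' @param fdr q-value cutoff for significance (default 0.01).
#' @param seed integer seed for the permutation sampler.
#' @param log_transform test on log2(x + pseudo) (default TRUE).
#' @param pseudo pseudocount for the log transform (default 0.5 RPM).
#' @return data.frame with `feature`, `d`, `s`, `q_value`, `mean_a`,
#'   `mean_b`, `log2_fc`, `significant`; attributes `s0`, `comparison`,
#'   `n_perm_used`, `exact_enumeration`.
#' @export
sam_two_class <- function(x, labels, n_perm = 1000L, fdr = 0.01,
                          seed = NULL, log_transform = TRUE, pseudo = 0.5) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("sam_two_class needs exactly two groups")
  if (any(table(labels) < 2)) stop("each group needs >= 2 samples")
  if (n_perm < 100) stop("n_perm must be >= 100")
  y <- if (log_transform) log2(x + pseudo) else x
  grpA <- labels == levels(labels)[1]

  ds <- sam_d_stat(y, grpA)
  s0 <- ds$s0

  # permutation null
  n <- ncol(y); nA <- sum(grpA)
  n_arr <- choose(n, nA)
  exact <- n_arr <= n_perm
  if (exact) {
    combos <- combn(n, nA)
    perms <- lapply(seq_len(ncol(combos)), function(j) {
      g <- rep(FALSE, n); g[combos[, j]] <- TRUE; g
    })
  } else {
    if (!is.null(seed)) set.seed(seed)
    perms <- lapply(seq_len(n_perm), function(j) {
      g <- rep(FALSE, n); g[sample.int(n, nA)] <- TRUE; g
    })
  }
  perm_absd <- vapply(perms, function(g)
    abs(sam_d_stat(y, g, s0 = s0)$d), numeric(nrow(y)))
  if (is.null(dim(perm_absd)))
    perm_absd <- matrix(perm_absd, nrow = nrow(y))

  absd <- abs(ds$d)
  ord <- order(absd, decreasing = TRUE)
  # expected false calls at each observed |d| cutoff
  all_perm <- sort(as.vector(perm_absd), decreasing = TRUE)
  B <- length(perms)
  efalse <- vapply(absd[ord], function(c)
    sum(all_perm >= c) / B, numeric(1))
  raw <- pmin(1, efalse / seq_along(ord))
  qv <- numeric(length(raw))
  # monotone non-increasing in |d|: step-up from the smallest |d|
  qv[length(raw)] <- raw[length(raw)]
  for (k in rev(seq_len(length(raw) - 1L))) qv[k] <- min(raw[k], qv[k + 1L])
  q_value <- numeric(length(raw)); q_value[ord] <- qv

  mean_a <- rowMeans(x[, grpA, drop = FALSE])
  mean_b <- rowMeans(x[, !grpA, drop = FALSE])
  out <- data.frame(
    feature = rownames(x) %||% as.character(seq_len(nrow(x))),
    d = ds$d, s = ds$s, q_value = q_value,
    mean_a = mean_a, mean_b = mean_b,
    log2_fc = log2_fold_change(mean_a, mean_b, pseudo),
    significant = q_value <= fdr, row.names = NULL)
  attr(out, "s0") <- s0
  attr(out, "comparison") <- paste(levels(labels), collapse = " vs ")
  attr(out, "n_perm_used") <- B
  attr(out, "exact_enumeration") <- exact
  attr(out, "method") <- "SAM"
  out
}

# d-statistic with Tusher s0 selection; grpA logical over columns
sam_d_stat <- function(y, grpA, s0 = NULL) {
  nA <- sum(grpA); nB <- sum(!grpA)
  mA <- rowMeans(y[, grpA, drop = FALSE])
  mB <- rowMeans(y[, !grpA, drop = FALSE])
  ssA <- rowSums((y[, grpA, drop = FALSE] - mA)^2)
  ssB <- rowSums((y[, !grpA, drop = FALSE] - mB)^2)
  s <- sqrt((1 / nA + 1 / nB) * (ssA + ssB) / (nA + nB - 2))
  r <- mA - mB
  if (is.null(s0)) s0 <- sam_s0(r, s)
  list(d = r / (s + s0), s = s, s0 = s0)
}

# Tusher exchangeability constant: the percentile of s minimizing the
# coefficient of variation of the d-spread across s-quantile bins
sam_s0 <- function(r, s) {
  if (all(s == 0)) return(max(1e-8, stats::mad(r)))
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(s, alphas, names = FALSE)
  n_bins <- max(2L, min(10L, floor(length(s) / 10)))
  bin <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    spread <- vapply(split(d, bin), stats::mad, numeric(1))
    if (mean(spread) == 0) Inf else sd(spread) / mean(spread)
  }, numeric(1))
  s0 <- cand[which.min(cv)]
  if (s0 == 0) s0 <- max(min(s[s > 0], na.rm = TRUE) / 2, 1e-8)
  s0
}

#' PLS-DA with VIP feature scoring
#'
#' Fits a two-class partial least squares discriminant analysis
#' (autoscaled features) and scores every fragment with the variable
#' importance in projection (VIP) cumulated over the fitted components;
#' the mean of squared VIPs equals 1 by construction. Fragments with
#' VIP >= `vip_min` are called significant. The PLS fit and VIP scores
#' are delegated to \pkg{mixOmics}.
#'
#' @param x numeric matrix, fragments x samples (RPM).
#' @param labels two-level factor of sample groups.
#' @param n_components number of PLS components (default 2).
#' @param vip_min VIP cutoff (default 1.5).
#' @param log_transform analyze log2(x + pseudo) (default TRUE, matching
#'   [sam_two_class()]).
#' @param pseudo pseudocount for the log transform.
#' @return data.frame with `feature`, `vip`, `significant`; constant
#'   features are dropped with a warning before autoscaling and returned
#'   with `vip = NA`.
#' @export
plsda_vip <- function(x, labels, n_components = 2L, vip_min = 1.5,
                      log_transform = TRUE, pseudo = 0.5) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("plsda_vip needs exactly two groups")
  if (ncol(x) < n_components + 1)
    stop("need at least n_components + 1 samples")
  y <- if (log_transform) log2(x + pseudo) else x
  feat <- rownames(y) %||% as.character(seq_len(nrow(y)))
  const <- apply(y, 1, function(v) sd(v) == 0)
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped before autoscaling")
    y <- y[!const, , drop = FALSE]
  }
  fit <- mixOmics::plsda(t(y), labels, ncomp = n_components, scale = TRUE)
  vip <- mixOmics::vip(fit)[, n_components]
  out <- data.frame(feature = feat, vip = NA_real_, row.names = NULL)
  out$vip[match(names(vip), feat)] <- unname(vip)
  out$significant <- !is.na(out$vip) & out$vip >= vip_min
  attr(out, "comparison") <- paste(levels(labels), collapse = " vs ")
  attr(out, "method") <- "PLSDA"
  out
}

#' Intersect SAM and PLS-DA calls into iDARs
#'
#' An iDAR ("intersection of differentially abundant rRFs") is a
#' fragment called significant by both methods for the same comparison.
#'
#' @param sam_results output of [sam_two_class()].
#' @param plsda_results output of [plsda_vip()] for the same matrix and
#'   comparison.
#' @return data.frame of iDAR fragments with `feature`, `d`, `q_value`,
#'   `log2_fc`, `vip`, `idar = TRUE` (zero rows when either call set is
#'   empty).
#' @export
intersect_idars <- function(sam_results, plsda_results) {
  ca <- attr(sam_results, "comparison")
  cb <- attr(plsda_results, "comparison")
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb))
    stop("mismatched comparisons: '", ca, "' vs '", cb, "'")
  feats <- intersect(sam_results$feature[sam_results$significant],
                     plsda_results$feature[plsda_results$significant])
  out <- sam_results[match(feats, sam_results$feature),
                     c("feature", "d", "q_value", "log2_fc"), drop = FALSE]
  out$vip <- plsda_results$vip[match(feats, plsda_results$feature)]
  out$idar <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  attr(out, "comparison") <- ca %||% cb
  out
}

#' Jaccard index of two call sets
#'
#' @param a,b vectors interpreted as sets.
#' @return `|intersect| / |union|`, with the empty-vs-empty case defined
#'   as 0 (and flagged with a message).
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (!length(u)) {
    message("jaccard_index: both sets empty; returning 0")
    return(0)
  }
  length(intersect(a, b)) / length(u)
}

#' Run SAM and PLS-DA over a comparison grid
#'
#' In `"population"` mode every pair of populations is compared within
#' each sex (10 pairs x 2 sexes for the five-population design); in
#' `"sex"` mode males and females are compared within each population.
#' Comparisons with fewer than `min_n` samples in a group are skipped
#' with a warning.
#'
#' @param x fragments x samples RPM matrix.
#' @param metadata data.frame with `sample_id`, `population`, `sex`
#'   matching the columns of `x`.
#' @param mode `"population"` or `"sex"`.
#' @param fdr,vip_min,n_perm,seed passed to the two methods.
#' @param min_n minimum group size (default 2).
#' @return list with `comparisons` (per-comparison list of `sam`,
#'   `plsda`, `idars`), `summary` (data.frame of per-comparison counts),
#'   and `unique_fragments` (list of unique significant fragments per
#'   method and for the iDARs, unioned over comparisons).
#' @export
pairwise_comparison_grid <- function(x, metadata, mode = c("population", "sex"),
                                     fdr = 0.01, vip_min = 1.5,
                                     n_perm = 1000L, seed = NULL,
                                     min_n = 2L) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  md <- metadata[match(colnames(x), metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id)))
    stop("metadata missing for some samples in the matrix")

  cells <- list()
  if (mode == "population") {
    pops <- sort(unique(md$population))
    pairs <- combn(pops, 2, simplify = FALSE)
    for (sx in sort(unique(md$sex)))
      for (pr in pairs)
        cells[[length(cells) + 1L]] <- list(
          stratum = sx,
          groups = pr,
          sel_a = md$sex == sx & md$population == pr[1],
          sel_b = md$sex == sx & md$population == pr[2])
  } else {
    sexes <- sort(unique(md$sex))
    if (length(sexes) != 2) stop("sex mode needs exactly two sexes")
    for (pop in sort(unique(md$population)))
      cells[[length(cells) + 1L]] <- list(
        stratum = pop,
        groups = sexes,
        sel_a = md$population == pop & md$sex == sexes[1],
        sel_b = md$population == pop & md$sex == sexes[2])
  }

  comparisons <- list()
  rows <- list()
  for (cell in cells) {
    label <- sprintf("%s vs %s | %s", cell$groups[1], cell$groups[2],
                     cell$stratum)
    if (sum(cell$sel_a) < min_n || sum(cell$sel_b) < min_n) {
      warning("skipping comparison '", label, "' (group with < ",
              min_n, " samples)")
      next
    }
    sel <- cell$sel_a | cell$sel_b
    lab <- factor(ifelse(cell$sel_a[sel], cell$groups[1], cell$groups[2]),
                  levels = cell$groups)
    sub <- x[, sel, drop = FALSE]
    sam <- sam_two_class(sub, lab, n_perm = n_perm, fdr = fdr, seed = seed)
    pls <- plsda_vip(sub, lab, vip_min = vip_min)
    idars <- intersect_idars(sam, pls)
    comparisons[[label]] <- list(sam = sam, plsda = pls, idars = idars,
                                 stratum = cell$stratum, groups = cell$groups)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = label, stratum = cell$stratum,
      n_sam = sum(sam$significant), n_plsda = sum(pls$significant),
      n_idar = nrow(idars))
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(comparison = character(), stratum = character(),
               n_sam = integer(), n_plsda = integer(), n_idar = integer())
  uniq <- list(
    sam = unique(unlist(lapply(comparisons, function(cc)
      cc$sam$feature[cc$sam$significant]))),
    plsda = unique(unlist(lapply(comparisons, function(cc)
      cc$plsda$feature[cc$plsda$significant]))),
    idar = unique(unlist(lapply(comparisons, function(cc)
      cc$idars$feature))))
  list(comparisons = comparisons, summary = summary,
       unique_fragments = uniq, mode = mode)
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around [stats::t.test()] with
#' Welch-Satterthwaite degrees of freedom; the degenerate case of two
#' zero-variance groups with equal means returns `t = 0, p = 1`.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("welch_t needs >= 2 values per group")
  if (sd(a) == 0 && sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_value = 0))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Pseudocounted log2 fold change
#'
#' @param mean_a,mean_b group mean abundances (>= 0).
#' @param pseudo pseudocount (default 0.5 RPM).
#' @return `log2((mean_a + pseudo) / (mean_b + pseudo))`.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudo = 0.5) {
  log2((mean_a + pseudo) / (mean_b + pseudo))
}
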