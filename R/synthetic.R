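#' @title Synthetic mini-genomes and short RNA-seq cohorts
#' @name synthetic_data
#' @description Generators for a mini-genome carrying rRNA cassettes,
#'   partial rRNA copies and decoy plantings, and for cohorts of FASTQ
#'   samples whose reads concentrate at rRNA hotspots with preferred
#'   endpoints, negative-binomial count dispersion, group-specific fold
#'   changes, 3' adapter contamination, and sequencing noise. Every
#'   generated object is accompanied by a ground-truth manifest.
NULL

#' Default hotspot set of the synthetic cohort
#'
#' Ten hotspots emulating the fragment architecture observed in
#' lymphoblastoid short RNA-seq: a bimodal 5S (short 18/19-mers from
#' position 103 vs long 32/33-mers, mutually exclusive per sample), a
#' 5.8S fragment family starting 6 nt upstream of the annotated 5' end,
#' an interior 18S hotspot that avoids the last 24 positions of the
#' rRNA, abundant 28S 5'-fragments plus a short 16-18 nt family used to
#' exercise the S/N length cutoff, 12S fragments that avoid position 1,
#' and two 16S hotspots of which one carries a population effect.
#'
#' Each hotspot is a list with `id`, `parent`, `starts` and `ends`
#' (named probability vectors over 5' and 3' positions, flank-aware),
#' `mean_rpm` (expected total RPM of the hotspot), `dispersion`
#' (negative-binomial), and optional `mode` (`"A"`/`"B"`: per sample one
#' mode per parent is active and the other suppressed).
#'
#' @return list of hotspot definitions.
#' @export
default_hotspots <- function() {
  hs <- function(id, parent, starts, ends, mean_rpm, dispersion = 0.3,
                 mode = NA_character_)
    list(id = id, parent = parent, starts = starts, ends = ends,
         mean_rpm = mean_rpm, dispersion = dispersion, mode = mode)
  list(
    hs("5S_short", "5S", c("103" = 1), c("120" = 2/3, "121" = 1/3),
       2500, mode = "A"),
    # the long mode favors the full-cycle 33-mer: a 32-nt insert leaves
    # 1 adapter nt that no trimmer can call at < 3 nt overlap
    hs("5S_long", "5S", c("89" = 1), c("121" = 0.7, "120" = 0.3),
       2000, mode = "B"),
    # position 0 is the first upstream flank base, so a start of -5
    # covers six upstream nucleotides (-5..0)
    hs("5.8S_x5", "5.8S", c("-5" = 1), c("12" = 0.6, "13" = 0.4), 1500),
    hs("5.8S_core", "5.8S", c("64" = 1), c("82" = 0.7, "84" = 0.3), 2500),
    hs("18S_int", "18S", c("357" = 0.8, "358" = 0.2),
       c("375" = 0.4, "376" = 0.6), 2500),
    hs("28S_5p", "28S", c("1" = 1), c("20" = 0.6, "27" = 0.4), 3000),
    hs("28S_short", "28S", c("30" = 1),
       c("45" = 0.4, "46" = 0.25, "47" = 0.35), 1500),
    hs("12S_start2", "12S", c("2" = 1), c("21" = 0.6, "22" = 0.4), 2000),
    hs("16S_eur", "16S", c("150" = 1), c("176" = 0.4, "177" = 0.6), 2000),
    hs("16S_long", "16S", c("120" = 1), c("147" = 0.6, "148" = 0.4), 1200)
  )
}

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic mini-genome and
#' cohort. The defaults define the package's reference study
#' conditions: a five-population / two-sex cohort, rRNA cassettes with
#' 50-nt flanks in a 30-kb background, 33-cycle reads with TruSeq 3'
#' adapter, negative-binomial fragment counts (dispersion 0.3), and a
#' YRI-vs-European fold change on one 16S hotspot plus a female-biased
#' 5.8S hotspot.
#'
#' @param seed mandatory integer seed; all randomness derives from it.
#' @param populations,sexes,n_per_cell cohort design (samples per
#'   population x sex cell).
#' @param background_length,gc background genome length and GC content.
#' @param ref_lengths named lengths of the synthetic reference rRNAs
#'   (the long rRNAs are represented by scaled-down stand-ins).
#' @param cassette_copies named count of full-length genomic copies per
#'   rRNA.
#' @param pad flank size planted around each cassette (and used for
#'   padding), in nt.
#' @param partial_copies data.frame (`parent`, `length`, `identity`) of
#'   partial rRNA copies planted in the background.
#' @param decoys list of decoy specs (`parent`, `lengths`, `copies`):
#'   exact copies of every hotspot fragment of that parent and length
#'   are planted outside the rRNA regions, to exercise the S/N filter.
#' @param hotspots hotspot list (see [default_hotspots()]).
#' @param effects data.frame (`hotspot`, `axis` in
#'   `{population, sex}`, `group`, `log2fc`): samples in `group` express
#'   the hotspot at `2^log2fc` times the base mean.
#' @param cycles,adapter read length in cycles and 3' adapter sequence.
#' @param error_rate per-base substitution error rate (default 1e-4;
#'   post-filter Illumina-grade calls, keeping insert corruption below
#'   1% of reads).
#' @param low_qual_tail_frac fraction of reads given a low-quality
#'   (Q2) 3-nt 3' tail, exercising quality trimming.
#' @param depth_mean,depth_sd per-sample read depth (normal, truncated
#'   at 1000).
#' @param noise TRUE to fill the depth with background noise reads
#'   (uniform random genomic substrings, 16-33 nt).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       populations = c("CEU", "FIN", "GBR", "TSI", "YRI"),
                       sexes = c("F", "M"),
                       n_per_cell = 4L,
                       background_length = 30000L,
                       gc = 0.41,
                       ref_lengths = c("5S" = 121L, "5.8S" = 157L,
                                       "18S" = 400L, "28S" = 500L,
                                       "12S" = 250L, "16S" = 300L),
                       cassette_copies = c("5S" = 2L, "5.8S" = 1L,
                                           "18S" = 1L, "28S" = 1L,
                                           "12S" = 1L, "16S" = 1L),
                       pad = 50L,
                       partial_copies = data.frame(
                         parent = c("18S", "28S"),
                         length = c(60L, 80L),
                         identity = c(0.90, 0.92)),
                       decoys = list(list(parent = "28S",
                                          lengths = c(16L, 17L),
                                          copies = 3L)),
                       hotspots = default_hotspots(),
                       effects = data.frame(
                         hotspot = c("16S_eur", "5.8S_core"),
                         axis = c("population", "sex"),
                         group = c("YRI", "F"),
                         log2fc = c(-2, 1)),
                       cycles = 33L,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       error_rate = 1e-4,
                       low_qual_tail_frac = 0.01,
                       depth_mean = 20000L,
                       depth_sd = 2000L,
                       noise = TRUE) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  for (h in hotspots) {
    if (abs(sum(h$starts) - 1) > 1e-9 || abs(sum(h$ends) - 1) > 1e-9)
      stop("hotspot '", h$id, "': endpoint probabilities must sum to 1")
    if (!h$parent %in% names(ref_lengths))
      stop("hotspot '", h$id, "': unknown parent ", h$parent)
  }
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  structure(list(seed = as.integer(seed), populations = populations,
                 sexes = sexes, n_per_cell = as.integer(n_per_cell),
                 background_length = as.integer(background_length), gc = gc,
                 ref_lengths = ref_lengths,
                 cassette_copies = cassette_copies, pad = as.integer(pad),
                 partial_copies = partial_copies, decoys = decoys,
                 hotspots = hotspots, effects = effects,
                 cycles = as.integer(cycles),
                 adapter = normalize_seq(adapter),
                 error_rate = error_rate,
                 low_qual_tail_frac = low_qual_tail_frac,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 noise = noise),
            class = "sim_config")
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

mutate_sequence <- function(sq, identity) {
  v <- strsplit(sq, "")[[1]]
  n_mut <- round((1 - identity) * length(v))
  if (n_mut > 0) {
    pos <- sample(length(v), n_mut)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

# enumerate the fragments of a hotspot: all (start, end) combinations of
# length 16..33 with probability p_start * p_end renormalized
hotspot_fragments <- function(h, min_len = 16L, max_len = 33L) {
  st <- as.integer(names(h$starts)); ps <- unname(h$starts)
  en <- as.integer(names(h$ends)); pe <- unname(h$ends)
  grid <- expand.grid(si = seq_along(st), ei = seq_along(en))
  start <- st[grid$si]; end <- en[grid$ei]
  len <- end - start + 1L
  p <- ps[grid$si] * pe[grid$ei]
  ok <- len >= min_len & len <= max_len
  if (!any(ok)) stop("hotspot '", h$id, "' emits no fragment of 16-33 nt")
  data.frame(hotspot = h$id, parent = h$parent, start = start[ok],
             end = end[ok], length = len[ok], prob = p[ok] / sum(p[ok]),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic mini-genome with planted rRNA structure
#'
#' Builds random reference rRNAs at the configured lengths, plants their
#' cassettes (rRNA flanked by `pad` nt of unique context) at
#' non-overlapping random positions in an i.i.d. background contig,
#' plants partial copies at the configured identities and exact decoy
#' copies of selected hotspot fragments, and returns the genome together
#' with padded references and a truth region map.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_genome` with `genome`
#'   ([Biostrings::DNAStringSet], one contig `chrS`), `refs` (named list
#'   of padded [rrna_reference] objects with placements), `regions`
#'   (truth data.frame: `chrom`, `start`, `end`, `kind` in
#'   `{full_rRNA, cassette, partial_copy, decoy}`, `parent`), and
#'   `config`.
#' @export
generate_mini_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  refs_seq <- lapply(config$ref_lengths, function(L) rand_dna(L, 0.52))
  flanks <- lapply(config$ref_lengths, function(L)
    list(f5 = rand_dna(config$pad, config$gc),
         f3 = rand_dna(config$pad, config$gc)))

  # elements to plant: cassettes (flank5+rRNA+flank3), partial copies, decoys
  elements <- list()
  for (nm in names(config$ref_lengths)) {
    cassette <- paste0(flanks[[nm]]$f5, refs_seq[[nm]], flanks[[nm]]$f3)
    for (k in seq_len(config$cassette_copies[[nm]]))
      elements[[length(elements) + 1L]] <-
        list(seq = cassette, kind = "cassette", parent = nm,
             rrna_offset = config$pad)
  }
  if (nrow(config$partial_copies)) {
    for (i in seq_len(nrow(config$partial_copies))) {
      pc <- config$partial_copies[i, ]
      src <- refs_seq[[pc$parent]]
      maxoff <- nchar(src) - pc$length
      off <- sample.int(maxoff + 1L, 1L) - 1L
      sub <- substr(src, off + 1L, off + pc$length)
      elements[[length(elements) + 1L]] <-
        list(seq = mutate_sequence(sub, pc$identity), kind = "partial_copy",
             parent = pc$parent, rrna_offset = 0L)
    }
  }
  for (dc in config$decoys) {
    frags <- do.call(rbind, lapply(
      Filter(function(h) h$parent == dc$parent, config$hotspots),
      hotspot_fragments))
    frags <- frags[frags$length %in% dc$lengths, , drop = FALSE]
    for (i in seq_len(nrow(frags))) {
      padded <- paste0(flanks[[dc$parent]]$f5, refs_seq[[dc$parent]],
                       flanks[[dc$parent]]$f3)
      fseq <- substr(padded, frags$start[i] + config$pad,
                     frags$end[i] + config$pad)
      # guard bases differing from the reference context so the decoy
      # matches exactly the targeted fragment length and no more
      g5 <- setdiff(c("A", "C", "G", "T"),
                    substr(padded, frags$start[i] + config$pad - 1L,
                           frags$start[i] + config$pad - 1L))[1]
      g3 <- setdiff(c("A", "C", "G", "T"),
                    substr(padded, frags$end[i] + config$pad + 1L,
                           frags$end[i] + config$pad + 1L))[1]
      for (k in seq_len(dc$copies))
        elements[[length(elements) + 1L]] <-
          list(seq = paste0(g5, fseq, g3), kind = "decoy",
               parent = dc$parent, rrna_offset = 0L)
    }
  }

  # place elements at non-overlapping random positions over the background
  bg <- strsplit(rand_dna(config$background_length, config$gc), "")[[1]]
  placed <- data.frame(start = integer(), end = integer())
  rows <- list()
  for (el in elements) {
    len <- nchar(el$seq)
    pos <- NA
    for (try in seq_len(200L)) {
      cand <- sample.int(config$background_length - len + 1L, 1L)
      if (!any(cand <= placed$end + 1L & (cand + len - 1L) >= placed$start - 1L)) {
        pos <- cand; break
      }
    }
    if (is.na(pos))
      stop("could not place a ", len, "-nt element after 200 tries; ",
           "increase background_length")
    placed <- rbind(placed, data.frame(start = pos, end = pos + len - 1L))
    bg[pos:(pos + len - 1L)] <- strsplit(el$seq, "")[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = "chrS", start = pos, end = pos + len - 1L,
      kind = el$kind, parent = el$parent, stringsAsFactors = FALSE)
    if (el$kind == "cassette") {
      L <- config$ref_lengths[[el$parent]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chrS", start = pos + el$rrna_offset,
        end = pos + el$rrna_offset + L - 1L,
        kind = "full_rRNA", parent = el$parent, stringsAsFactors = FALSE)
    }
  }
  genome <- DNAStringSet(setNames(paste(bg, collapse = ""), "chrS"))
  regions <- do.call(rbind, rows)

  refs <- lapply(names(config$ref_lengths), function(nm) {
    r <- rrna_reference(nm, refs_seq[[nm]])
    r <- locate_placements(r, genome)
    pad_reference(r, genome, pad = config$pad)
  })
  names(refs) <- names(config$ref_lengths)

  structure(list(genome = genome, refs = refs, regions = regions,
                 config = config),
            class = "sim_genome")
}

#' Build the truth rRNA space of a synthetic genome
#'
#' The rRNA space implied by the truth region map: the full cassette
#' intervals (rRNA plus its planted flanks, mirroring how rDNA repeat
#' annotations cover whole repeat units so that terminus-straddling
#' fragments remain inside the space) plus partial copies. Decoys and
#' plain background stay outside by construction.
#'
#' @param sim a `sim_genome`.
#' @return an `rrna_space`.
#' @export
truth_rrna_space <- function(sim) {
  reg <- sim$regions[sim$regions$kind %in% c("cassette", "partial_copy"), ,
                     drop = FALSE]
  build_rrna_space(sim$refs, repeat_annotations = reg, partial_copies = NULL,
                   genome = sim$genome)
}

#' Generate a synthetic short RNA-seq cohort with ground truth
#'
#' For every sample of the configured design, draws negative-binomial
#' true counts for each hotspot fragment (group-specific means where an
#' effect applies, per-sample mode switching for bimodal parents), fills
#' the remaining depth with uniform background noise reads, appends the
#' 3' adapter, clips to the cycle count, applies substitution errors and
#' low-quality tails, and (optionally) writes FASTQ files.
#'
#' @param config a [sim_config()].
#' @param sim a `sim_genome` from [generate_mini_genome()] (built from
#'   the same config).
#' @param dir output directory for FASTQ files; `NULL` keeps reads in
#'   memory only.
#' @param noiseless convenience switch: disables noise reads,
#'   sequencing errors and low-quality tails (overriding the config)
#'   for exact-recovery experiments.
#' @return list of class `sim_cohort` with `samples` (sample sheet
#'   data.frame: `sample_id`, `population`, `sex`, `facility`, `kit`,
#'   `depth`, `fastq`), `reads` (per-sample character vectors of final
#'   read sequences), `qualities`, and `manifest` (list: `fragments`
#'   truth table, `counts` true per-sample fragment counts, `hotspots`,
#'   `effects`, `modes` per-sample active modes, `regions`).
#' @export
generate_cohort <- function(config, sim, dir = NULL, noiseless = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(sim, "sim_genome"))
  frag_tabs <- lapply(config$hotspots, hotspot_fragments)
  frags <- do.call(rbind, frag_tabs)
  # fragment sequences from the padded references (flank-aware coordinates)
  pads <- vapply(sim$refs, function(r) nchar(r$flank5), integer(1))
  frags$sequence <- vapply(seq_len(nrow(frags)), function(i) {
    padded <- padded_sequence(sim$refs[[frags$parent[i]]])
    substr(padded, frags$start[i] + pads[frags$parent[i]],
           frags$end[i] + pads[frags$parent[i]])
  }, character(1))

  design <- expand.grid(population = config$populations, sex = config$sexes,
                        rep = seq_len(config$n_per_cell),
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_%02d", design$population, design$sex,
                              design$rep)

  hot_by_id <- setNames(config$hotspots,
                        vapply(config$hotspots, `[[`, "", "id"))
  mode_parents <- unique(vapply(
    Filter(function(h) !is.na(h$mode), config$hotspots), `[[`, "", "parent"))

  genome_str <- as.character(sim$genome[[1]])
  glen <- nchar(genome_str)
  error_rate <- if (noiseless) 0 else config$error_rate
  tail_frac <- if (noiseless) 0 else config$low_qual_tail_frac
  with_noise <- if (noiseless) FALSE else config$noise

  # decorrelated per-sample streams: consecutive integer seeds give
  # correlated early Mersenne-Twister output, so sample seeds are drawn
  # from a master stream instead
  set.seed(config$seed)
  sample_seeds <- sample.int(.Machine$integer.max, nrow(design))

  samples <- list(); reads_out <- list(); quals_out <- list()
  counts_rows <- list(); mode_rows <- list()
  for (i in seq_len(nrow(design))) {
    set.seed(sample_seeds[i])
    sid <- design$sample_id[i]
    depth <- max(1000L, round(stats::rnorm(1, config$depth_mean,
                                           config$depth_sd)))
    # per-sample active mode per bimodal parent
    modes <- setNames(sample(c("A", "B"), length(mode_parents),
                             replace = TRUE), mode_parents)
    if (length(mode_parents))
      mode_rows[[i]] <- data.frame(sample_id = sid, parent = mode_parents,
                                   mode = unname(modes))

    # biological variability acts on whole-hotspot activity (negative
    # binomial); the endpoint choice of each molecule is multinomial
    # over the hotspot's stated endpoint probabilities
    counts <- integer(nrow(frags))
    for (h in config$hotspots) {
      m <- h$mean_rpm
      if (!is.na(h$mode) && modes[[h$parent]] != h$mode) m <- m * 0.01
      eff <- config$effects[config$effects$hotspot == h$id, , drop = FALSE]
      if (nrow(eff)) {
        for (k in seq_len(nrow(eff))) {
          grp_val <- if (eff$axis[k] == "population") design$population[i]
                     else design$sex[i]
          if (grp_val == eff$group[k]) m <- m * 2^eff$log2fc[k]
        }
      }
      total <- rnbinom(1, mu = m * depth / 1e6, size = 1 / h$dispersion)
      sel <- which(frags$hotspot == h$id)
      counts[sel] <- as.integer(stats::rmultinom(1, total, frags$prob[sel]))
    }

    true_reads <- rep(frags$sequence, counts)
    n_noise <- if (with_noise) max(0L, depth - length(true_reads)) else 0L
    if (n_noise > 0) {
      nl <- sample(16:33, n_noise, replace = TRUE)
      np <- vapply(nl, function(l) sample.int(glen - l + 1L, 1L), integer(1))
      noise <- substr(rep(genome_str, n_noise), np, np + nl - 1L)
      flip <- runif(n_noise) < 0.5
      if (any(flip))
        noise[flip] <- as.character(reverseComplement(DNAStringSet(noise[flip])))
      true_reads <- c(true_reads, noise)
    }
    # the realized library size is the truth RPM denominator
    depth <- length(true_reads)
    counts_rows[[i]] <- data.frame(sample_id = sid, hotspot = frags$hotspot,
                                   sequence = frags$sequence,
                                   true_count = counts, depth = depth,
                                   stringsAsFactors = FALSE)

    # library construction: adapter, clip to cycles, substitution errors
    raw <- substr(paste0(true_reads, config$adapter,
                         strrep("A", config$cycles)),
                  1L, config$cycles)
    if (error_rate > 0) raw <- apply_substitution_errors(raw, error_rate)
    qual <- strrep("?", config$cycles)  # constant Q30
    quals <- rep(qual, length(raw))
    if (tail_frac > 0) {
      low <- runif(length(raw)) < tail_frac
      quals[low] <- paste0(substr(qual, 1L, config$cycles - 3L), "###")
    }

    fastq <- NA_character_
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      fastq <- file.path(dir, paste0(sid, ".fastq"))
      write_fastq(raw, quals, sid, fastq)
    }
    samples[[i]] <- data.frame(sample_id = sid,
                               population = design$population[i],
                               sex = design$sex[i], facility = "sim",
                               kit = "TruSeq", depth = depth, fastq = fastq,
                               stringsAsFactors = FALSE)
    reads_out[[sid]] <- raw
    quals_out[[sid]] <- quals
  }

  structure(list(
    samples = do.call(rbind, samples),
    reads = reads_out, qualities = quals_out, config = config,
    manifest = list(fragments = frags,
                    counts = do.call(rbind, counts_rows),
                    hotspots = config$hotspots, effects = config$effects,
                    modes = if (length(mode_rows)) do.call(rbind, mode_rows)
                            else NULL,
                    regions = sim$regions)),
    class = "sim_cohort")
}

apply_substitution_errors <- function(reads, rate) {
  n_err <- rbinom(length(reads), nchar(reads), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    v <- strsplit(reads[i], "")[[1]]
    pos <- sample(length(v), n_err[i])
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    reads[i] <- paste(v, collapse = "")
  }
  reads
}

write_fastq <- function(reads, quals, prefix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- sprintf("@%s_read%06d", prefix, seq_along(reads))
  writeLines(paste(ids, reads, "+", quals, sep = "\n"), con)
  invisible(path)
}

#' Simulate an RPM expression matrix with planted effects
#'
#' A counts-level shortcut past read emission: per-fragment baseline
#' abundances are drawn log-uniformly, per-sample counts are negative
#' binomial at the sample's depth, and a chosen fraction of fragments
#' carries a group fold change. Used for statistical calibration and
#' parameter-recovery experiments at realistic group sizes.
#'
#' @param n_fragments number of fragments (rows).
#' @param n_per_group samples per group (two groups, `A` and `B`).
#' @param effect_frac fraction of fragments with a planted effect in
#'   group A.
#' @param log2fc planted log2 fold change (group A relative to B).
#' @param dispersion negative-binomial dispersion (default 0.3).
#' @param base_rpm_range log-uniform range of baseline abundances.
#' @param depth read depth per sample (RPM denominator).
#' @param seed integer seed.
#' @return list with `rpm` (matrix fragments x samples), `labels`
#'   (factor), `effect_features` (character vector of planted rows),
#'   `truth_log2fc`.
#' @export
simulate_expression_matrix <- function(n_fragments = 200L, n_per_group = 40L,
                                       effect_frac = 0, log2fc = 0,
                                       dispersion = 0.3,
                                       base_rpm_range = c(10, 1000),
                                       depth = 1e6, seed = 1L) {
  set.seed(seed)
  base <- exp(runif(n_fragments, log(base_rpm_range[1]),
                    log(base_rpm_range[2])))
  n_eff <- round(effect_frac * n_fragments)
  eff_rows <- if (n_eff > 0) sample.int(n_fragments, n_eff) else integer(0)
  labels <- factor(rep(c("A", "B"), each = n_per_group), levels = c("A", "B"))
  mu <- matrix(base, n_fragments, 2 * n_per_group)
  if (n_eff > 0) mu[eff_rows, labels == "A"] <- mu[eff_rows, labels == "A"] *
    2^log2fc
  counts <- matrix(rnbinom(length(mu), mu = mu * depth / 1e6,
                           size = 1 / dispersion), nrow = n_fragments)
  rpm <- counts / depth * 1e6
  rownames(rpm) <- sprintf("frag%03d", seq_len(n_fragments))
  colnames(rpm) <- sprintf("%s%02d", labels, c(seq_len(n_per_group),
                                               seq_len(n_per_group)))
  list(rpm = rpm, labels = labels,
       effect_features = rownames(rpm)[sort(eff_rows)],
       truth_log2fc = log2fc)
}

#' Compare pipeline output against a cohort's truth manifest
#'
#' @param records rRF master table from [assemble_rrf_records()] (or any
#'   data.frame with `parent`, `start`, `end`, `sequence` and
#'   `rpm.<sample>` columns).
#' @param cohort a `sim_cohort`.
#' @param idar_sequences optional character vector of fragment
#'   sequences called as iDARs, scored against the planted effect
#'   fragments.
#' @param cutoffs optional `length_cutoff_table`: truth modes are then
#'   taken among fragments at observable lengths (at or above the
#'   parent's minimum length), so hotspots whose dominant fragment is
#'   removed by design are compared like with like.
#' @return list with `endpoint_exactness` (fraction of hotspots whose
#'   RPM-weighted modal (start, end) matches the truth mode),
#'   `abundance_rmse` (RMSE of log2(RPM + 0.5) over fragments present
#'   in both), and, when `idar_sequences` is given, `idar_sensitivity`
#'   and `idar_fdp`.
#' @export
evaluate_recovery <- function(records, cohort, idar_sequences = NULL,
                              cutoffs = NULL) {
  man <- cohort$manifest
  frags <- man$fragments
  rpm_cols <- grep("^rpm\\.", names(records), value = TRUE)
  if (!length(rpm_cols)) stop("records carry no rpm.<sample> columns")

  # endpoint exactness per hotspot
  hot_ids <- unique(frags$hotspot)
  # fragments of 31-32 nt are unobservable in a 33-cycle library: the
  # remaining 1-2 adapter nt are below the 3-nt trimming overlap
  if (!is.null(cohort$config)) {
    cyc <- cohort$config$cycles
    frags <- frags[frags$length <= cyc - 3L | frags$length >= cyc, ,
                   drop = FALSE]
  }
  exact <- vapply(hot_ids, function(hid) {
    tf <- frags[frags$hotspot == hid, , drop = FALSE]
    if (!nrow(tf)) return(NA)
    if (!is.null(cutoffs)) {
      minl <- cutoffs$min_length[tf$parent[1]]
      if (!is.na(minl)) tf <- tf[tf$length >= minl, , drop = FALSE]
      if (!nrow(tf)) return(NA)
    }
    truth_mode <- tf[which.max(tf$prob), c("start", "end")]
    obs <- records[records$parent == tf$parent[1] &
                     paste(records$start, records$end) %in%
                     paste(tf$start, tf$end), , drop = FALSE]
    if (!nrow(obs)) return(NA)
    tot <- rowSums(obs[, rpm_cols, drop = FALSE])
    obs_mode <- obs[which.max(tot), c("start", "end")]
    obs_mode$start == truth_mode$start && obs_mode$end == truth_mode$end
  }, logical(1))
  endpoint_exactness <- mean(exact, na.rm = TRUE)

  # abundance RMSE on the log2 scale over (fragment, sample) pairs that
  # carry signal in both the truth and the output
  truth <- man$counts
  truth$rpm_true <- truth$true_count / truth$depth * 1e6
  errs <- c()
  for (s in unique(truth$sample_id)) {
    col <- paste0("rpm.", s)
    if (!col %in% names(records)) next
    tt <- truth[truth$sample_id == s, , drop = FALSE]
    idx <- match(tt$sequence, records$sequence)
    ok <- !is.na(idx) & records[[col]][idx] > 0 & tt$rpm_true > 0
    errs <- c(errs, log2(records[[col]][idx[ok]] + 0.5) -
                log2(tt$rpm_true[ok] + 0.5))
  }
  out <- list(endpoint_exactness = endpoint_exactness,
              abundance_rmse = if (length(errs)) sqrt(mean(errs^2)) else NA,
              hotspot_exact = setNames(exact, hot_ids))
  if (!is.null(idar_sequences)) {
    eff_hot <- unique(man$effects$hotspot)
    truth_seqs <- unique(frags$sequence[frags$hotspot %in% eff_hot])
    called <- unique(idar_sequences)
    out$idar_sensitivity <- if (length(truth_seqs))
      length(intersect(called, truth_seqs)) / length(truth_seqs) else NA
    out$idar_fdp <- if (length(called))
      length(setdiff(called, truth_seqs)) / length(called) else 0
  }
  out
}
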