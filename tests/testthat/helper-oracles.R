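# shared fixtures and independent brute-force oracles

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# naive O(n*m) scan: all (possibly overlapping) exact occurrences of
# pattern in a single subject string, 1-based starts
naive_occurrences <- function(pattern, subject) {
  lp <- nchar(pattern); ls <- nchar(subject)
  if (lp > ls) return(integer(0))
  starts <- integer(0)
  for (s in seq_len(ls - lp + 1L))
    if (substr(subject, s, s + lp - 1L) == pattern)
      starts <- c(starts, s)
  starts
}

# naive both-strand genome instance counter with containment test
naive_instance_count <- function(sequence, genome_str, space_df) {
  hits <- list()
  for (pat in unique(c(sequence, revcomp(sequence)))) {
    st <- naive_occurrences(pat, genome_str)
    if (length(st))
      hits[[pat]] <- data.frame(start = st, end = st + nchar(sequence) - 1L)
  }
  occ <- do.call(rbind, hits)
  if (is.null(occ)) return(c(inside = 0L, outside = 0L))
  inside <- vapply(seq_len(nrow(occ)), function(i)
    any(space_df$start <= occ$start[i] & occ$end[i] <= space_df$end), logical(1))
  c(inside = sum(inside), outside = sum(!inside))
}

# small fully-specified reference/genome fixture: one contig with a
# planted rRNA at a known position
make_toy_locus <- function(seed = 1L, rrna_len = 60L, pad = 50L,
                           lead = 100L, trail = 100L) {
  set.seed(seed)
  rrna <- random_dna(rrna_len)
  pre <- random_dna(lead)
  post <- random_dna(trail)
  genome <- c(chrT = paste0(pre, rrna, post))
  ref <- rrna_reference("5S", rrna)
  ref <- locate_placements(ref, genome)
  ref <- pad_reference(ref, genome, pad = pad)
  list(ref = ref, genome = genome, rrna = rrna,
       rrna_start = lead + 1L, rrna_end = lead + rrna_len)
}

# cached small synthetic cohort runs shared across test files
local_sim_env <- new.env(parent = emptyenv())

noiseless_pipeline_fixture <- function() {
  if (!is.null(local_sim_env$noiseless)) return(local_sim_env$noiseless)
  cfg <- sim_config(seed = 7, n_per_cell = 2,
                    populations = c("CEU", "YRI"))
  sim <- generate_mini_genome(cfg)
  space <- truth_rrna_space(sim)
  cohort <- generate_cohort(cfg, sim, noiseless = TRUE)
  samples <- lapply(seq_len(nrow(cohort$samples)), function(i)
    sample_from_reads(cohort, i, cfg))
  pipe <- run_rrf_pipeline(samples, sim$refs, sim$genome, space)
  local_sim_env$noiseless <- list(cfg = cfg, sim = sim, space = space,
                                  cohort = cohort, samples = samples,
                                  pipe = pipe)
  local_sim_env$noiseless
}

# trim a cohort sample held in memory via a temporary FASTQ
sample_from_reads <- function(cohort, i, cfg) {
  sid <- cohort$samples$sample_id[i]
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  writeLines(paste(sprintf("@%s_r%d", sid, seq_along(cohort$reads[[sid]])),
                   cohort$reads[[sid]], "+", cohort$qualities[[sid]],
                   sep = "\n"), fq)
  trim_reads(fq, cfg$adapter, sample_id = sid,
             population = cohort$samples$population[i],
             sex = cohort$samples$sex[i])
}

write_temp_fastq <- function(reads, quals = strrep("I", nchar(reads))) {
  fq <- tempfile(fileext = ".fastq")
  writeLines(paste(sprintf("@read%d", seq_along(reads)), reads, "+", quals,
                   sep = "\n"), fq)
  fq
}
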