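ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"  # TruSeq small RNA 3' adapter

test_that("adapter and quality trimming recover inserts and drop short reads", {
  set.seed(21)
  ins20 <- random_dna(20)
  ins15 <- random_dna(15)
  ins33 <- random_dna(33)
  reads <- c(paste0(ins20, substr(ADAPTER, 1, 13)),  # 20 + adapter, 33 cycles
             paste0(ins15, substr(ADAPTER, 1, 18)),  # 15-nt insert: discarded
             ins33)                                   # full-cycle read
  fq <- write_temp_fastq(reads)
  s <- trim_reads(fq, ADAPTER, sample_id = "t1")
  expect_s3_class(s, "sequenced_sample")
  expect_equal(sort(s$reads$sequence), sort(c(ins20, ins33)))
  expect_equal(s$read_depth, 2L)

  # one mismatch in a 21-nt adapter occurrence is tolerated (<= 10%)
  adapter_mm <- ADAPTER
  substr(adapter_mm, 5, 5) <- setdiff(BASES, substr(ADAPTER, 5, 5))[1]
  fq2 <- write_temp_fastq(paste0(ins20, substr(adapter_mm, 1, 21)))
  s2 <- trim_reads(fq2, ADAPTER, sample_id = "t2")
  expect_equal(s2$reads$sequence, ins20)

  # low-quality 3' tail is removed before the adapter search
  read <- paste0(ins20, substr(ADAPTER, 1, 10), "TTT")
  qual <- paste0(strrep("I", 30), "###")
  fq3 <- write_temp_fastq(read, qual)
  s3 <- trim_reads(fq3, ADAPTER, sample_id = "t3")
  expect_equal(s3$reads$sequence, ins20)

  # a 31-nt insert leaves a 2-nt adapter remnant below the minimum
  # overlap, so the read is kept untrimmed at full length
  ins31 <- random_dna(31)
  fq4 <- write_temp_fastq(paste0(ins31, substr(ADAPTER, 1, 2)))
  s4 <- trim_reads(fq4, ADAPTER, sample_id = "t4")
  expect_equal(nchar(s4$reads$sequence), 33L)

  expect_error(trim_reads(fq, ""), "non-empty")
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)  # truncated record
  expect_error(trim_reads(bad, ADAPTER), "malformed FASTQ")
})

test_that("synthetic cohort inserts are recovered almost perfectly after trimming", {
  cfg <- sim_config(seed = 31, n_per_cell = 1, populations = "CEU",
                    sexes = "F", depth_mean = 4000, depth_sd = 100)
  sim <- generate_mini_genome(cfg)
  cohort <- generate_cohort(cfg, sim)
  s <- sample_from_reads(cohort, 1, cfg)
  # reconstruct the expected inserts: planted fragments + noise reads,
  # kept when >= 16 nt and observable within the cycle window
  truth <- cohort$manifest$counts
  truth <- truth[truth$sample_id == s$sample_id & truth$true_count > 0, ]
  planted <- rep(truth$sequence, truth$true_count)
  recovered <- rep(s$reads$sequence, s$reads$count)
  # every planted observable fragment should be present at >= 99% fidelity
  obs <- planted[nchar(planted) <= 30 | nchar(planted) == 33]
  n_found <- sum(pmin(table(recovered)[names(table(obs))],
                      table(obs)), na.rm = TRUE)
  expect_gte(n_found / length(obs), 0.99)
})

test_that("exact mapping reports flank-aware coordinates and matches a naive scan", {
  toy <- make_toy_locus(seed = 41, rrna_len = 80, pad = 50)
  ref <- toy$ref
  L <- ref$length

  prefix <- substr(ref$sequence, 1, 20)
  straddle <- paste0(substr(ref$flank5, 41, 50), substr(ref$sequence, 1, 10))
  flank_only <- substr(ref$flank5, 11, 40)
  s <- sequenced_sample("m1", c(prefix, straddle, flank_only))
  aln <- map_exact(s, list(ref))
  expect_equal(aln$start[aln$sequence == prefix], 1L)
  expect_equal(aln$end[aln$sequence == prefix], 20L)
  # straddling alignment: last 10 flank nt are positions -9..0
  expect_equal(aln$start[aln$sequence == straddle], -9L)
  expect_equal(aln$end[aln$sequence == straddle], 10L)
  # flank-only reads are rejected but retained as unmapped
  expect_false(flank_only %in% aln$sequence)
  expect_true(flank_only %in% attr(aln, "unmapped"))
  # conservation: every distinct read is mapped or unmapped, never both
  expect_setequal(c(aln$sequence, attr(aln, "unmapped")),
                  s$reads$sequence)
  expect_length(intersect(unique(aln$sequence), attr(aln, "unmapped")), 0)
})

test_that("mapping agrees with the brute-force substring oracle", {
  set.seed(42)
  refs <- lapply(c("5S", "12S"), function(nm) {
    r <- rrna_reference(nm, random_dna(70))
    r$flank5 <- random_dna(20); r$flank3 <- random_dna(20); r$pad <- 20L
    r
  })
  # reads drawn from the padded references plus decoys, incl. a repeated
  # motif to exercise overlapping matches
  rep_ref <- rrna_reference("16S", paste0(strrep("ACGA", 10)))
  rep_ref$flank5 <- ""; rep_ref$flank3 <- ""; rep_ref$pad <- 0L
  refs <- c(refs, list(rep_ref))
  pool <- c(
    vapply(1:30, function(i) {
      r <- refs[[sample(2, 1)]]
      p <- padded_sequence(r)
      st <- sample(nchar(p) - 20, 1)
      substr(p, st, st + sample(16:20, 1))
    }, character(1)),
    strrep("ACGA", 4), paste0("ACGA", strrep("ACGA", 3)),
    vapply(1:10, function(i) random_dna(18), character(1)))
  s <- sequenced_sample("o1", pool)
  aln <- map_exact(s, refs)

  oracle <- list()
  for (r in refs) {
    p <- padded_sequence(r)
    off <- nchar(r$flank5)
    for (sq in unique(s$reads$sequence)) {
      st <- naive_occurrences(sq, p) - off
      en <- st + nchar(sq) - 1L
      keep <- en >= 1L & st <= r$length
      if (any(keep))
        oracle[[length(oracle) + 1L]] <-
          data.frame(sequence = sq, parent = r$name, start = st[keep],
                     end = en[keep])
    }
  }
  oracle <- do.call(rbind, oracle)
  got <- aln[, c("sequence", "parent", "start", "end")]
  key <- function(d) sort(paste(d$sequence, d$parent, d$start, d$end))
  expect_equal(key(got), key(oracle))
})

test_that("instance counting is strand-symmetric and matches the naive oracle", {
  set.seed(43)
  rrna <- random_dna(60)
  frag <- substr(rrna, 10, 25)      # 16-mer from the rRNA body
  decoy_sites <- replicate(3, random_dna(40))
  genome <- c(chrT = paste0(random_dna(80), rrna, random_dna(40),
                            paste0(decoy_sites, frag, collapse = ""),
                            random_dna(40)))
  ref <- locate_placements(rrna_reference("5S", rrna), genome)
  sp <- build_rrna_space(list(ref), genome = genome)

  ic <- count_instances(frag, genome, sp)
  expect_equal(ic$inside, 1L)
  expect_equal(ic$outside, 3L)

  unique_frag <- substr(rrna, 30, 50)
  ic2 <- count_instances(c(unique_frag, revcomp(unique_frag)), genome, sp)
  expect_equal(ic2$inside, c(1L, 1L))
  expect_equal(ic2$outside, c(0L, 0L))

  # oracle equivalence over a batch of random probes
  gstr <- genome[["chrT"]]
  space_df <- data.frame(start = GenomicRanges::start(sp$ranges),
                         end = GenomicRanges::end(sp$ranges))
  probes <- c(frag, unique_frag,
              vapply(1:10, function(i) {
                st <- sample(nchar(gstr) - 20, 1)
                substr(gstr, st, st + 16)
              }, character(1)))
  got <- count_instances(probes, genome, sp)
  for (i in seq_along(probes)) {
    want <- naive_instance_count(probes[i], gstr, space_df)
    expect_equal(c(inside = got$inside[i], outside = got$outside[i]), want)
  }
})
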