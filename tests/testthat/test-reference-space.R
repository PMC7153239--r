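test_that("annotated references load with spans, normalization and errors", {
  set.seed(11)
  rec1 <- random_dna(100)
  rec2 <- tolower(gsub("T", "U", random_dna(40)))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">recA", rec1, ">recB", rec2), fa)
  ann <- data.frame(name = c("18S", "5.8S", "28S"),
                    record = c("recA", "recA", "recB"),
                    start = c(1L, 31L, NA), end = c(20L, 60L, NA))
  refs <- load_references(fa, ann)
  expect_named(refs, c("18S", "5.8S", "28S"))
  expect_equal(vapply(refs, function(r) r$length, integer(1)),
               c("18S" = 20L, "5.8S" = 30L, "28S" = 40L))
  # independent span extraction
  expect_equal(refs[["18S"]]$sequence, substr(rec1, 1, 20))
  expect_equal(refs[["5.8S"]]$sequence, substr(rec1, 31, 60))
  # U -> T and case normalization
  expect_equal(refs[["28S"]]$sequence,
               gsub("U", "T", toupper(rec2)))

  # all requested names reported when the FASTA lacks their records
  empty_fa <- tempfile(fileext = ".fa")
  writeLines(character(0), empty_fa)
  six <- data.frame(name = c("5S", "5.8S", "18S", "28S", "12S", "16S"),
                    record = paste0("r", 1:6))
  err <- tryCatch(load_references(empty_fa, six), error = conditionMessage)
  for (nm in six$name) expect_match(err, nm, fixed = TRUE)

  ann_bad <- data.frame(name = "18S", record = "recA", start = 90L, end = 120L)
  expect_error(load_references(fa, ann_bad), "18S")
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">recA", ""), fa2)
  expect_error(load_references(fa2, data.frame(name = "5S", record = "recA")),
               "empty")
})

test_that("padding takes genomic flanks, truncates at contig ends, honors strand", {
  toy <- make_toy_locus(seed = 2, rrna_len = 100, lead = 100, trail = 100)
  g <- toy$genome[["chrT"]]
  expect_equal(toy$ref$flank5, substr(g, 51, 100))
  expect_equal(toy$ref$flank3, substr(g, 201, 250))

  # placement near the contig start truncates the 5' flank
  set.seed(3)
  rrna <- random_dna(50)
  genome <- c(c1 = paste0(random_dna(9), rrna, random_dna(60)))
  ref <- pad_reference(locate_placements(rrna_reference("5S", rrna), genome),
                       genome, pad = 50)
  expect_equal(nchar(ref$flank5), 9L)
  expect_equal(ref$flank5, substr(genome[["c1"]], 1, 9))

  # minus-strand placement: flanks are reverse-complemented context
  set.seed(4)
  rrna <- random_dna(40)
  up <- random_dna(20); dn <- random_dna(20)
  genome <- c(c1 = paste0(random_dna(30), revcomp(paste0(up, rrna, dn)),
                          random_dna(30)))
  ref <- pad_reference(locate_placements(rrna_reference("12S", rrna), genome),
                       genome, pad = 20)
  expect_equal(ref$placements$strand, "-")
  expect_equal(ref$flank5, up)
  expect_equal(ref$flank3, dn)

  expect_error(pad_reference(rrna_reference("16S", "ACGTACGTACGTACGTACGT"),
                             c(c1 = random_dna(50))), "no genomic placement")

  # conflicting flanks across placements: canonical wins with a warning
  set.seed(5)
  rrna <- random_dna(30)
  genome <- c(c1 = paste0("AAAAA", rrna, "CCCCC", random_dna(20),
                          "GGGGG", rrna, "TTTTT"))
  ref <- locate_placements(rrna_reference("5S", rrna), genome)
  expect_warning(ref <- pad_reference(ref, genome, pad = 5), "conflicting")
  expect_equal(ref$flank5, "AAAAA")
  expect_equal(ref$flank3, "CCCCC")
})

test_that("rRNA space merges intervals and answers containment queries", {
  genome <- c(c1 = strrep("A", 500))
  ref <- rrna_reference("5S", "ACGT")
  ref$placements <- data.frame(chrom = "c1", start = 100L, end = 200L,
                               strand = "+", kind = "full_rRNA")
  reps <- data.frame(chrom = "c1", start = 150L, end = 250L)
  sp <- build_rrna_space(list(ref), repeat_annotations = reps, genome = genome)
  expect_equal(length(sp$ranges), 1L)
  expect_equal(GenomicRanges::start(sp$ranges), 100L)
  expect_equal(GenomicRanges::end(sp$ranges), 250L)

  # no repeats, no partials: space equals the placements exactly
  sp0 <- build_rrna_space(list(ref), genome = genome)
  expect_equal(GenomicRanges::start(sp0$ranges), 100L)
  expect_equal(GenomicRanges::end(sp0$ranges), 200L)

  expect_true(space_contains(sp, "c1", 100, 200))
  expect_true(space_contains(sp, "c1", 120, 130))
  expect_false(space_contains(sp, "c1", 90, 110))   # straddles: outside
  expect_false(space_contains(sp, "c1", 300, 320))

  expect_error(build_rrna_space(
    list(ref), repeat_annotations = data.frame(chrom = "c1", start = 400L,
                                               end = 600L),
    genome = genome), "off-contig")
})

test_that("merged-space total length is invariant under ordering and duplication", {
  genome <- c(c1 = strrep("A", 1000))
  set.seed(20)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    iv <- data.frame(chrom = "c1",
                     start = sample(1:900, n),
                     end = 0L)
    iv$end <- pmin(1000L, iv$start + sample(10:100, n, replace = TRUE))
    ref <- rrna_reference("5S", "ACGT")
    ref$placements <- cbind(iv[1, ], strand = "+", kind = "full_rRNA")
    total <- function(extra) {
      sp <- build_rrna_space(list(ref), repeat_annotations = extra,
                             genome = genome)
      sum(IRanges::width(sp$ranges))
    }
    base <- total(iv)
    expect_equal(total(iv[sample(nrow(iv)), ]), base)
    expect_equal(total(rbind(iv, iv, iv[rev(seq_len(nrow(iv))), ])), base)
  }
})

test_that("BED IO converts between 0-based half-open and 1-based inclusive", {
  df <- data.frame(chrom = c("c1", "c2"), start = c(101L, 1L),
                   end = c(200L, 50L), strand = c("+", "-"))
  bed <- tempfile(fileext = ".bed")
  write_bed(df, bed)
  raw <- read.table(bed, sep = "\t")
  expect_equal(raw$V2, c(100L, 0L))   # BED starts are 0-based
  expect_equal(raw$V3, c(200L, 50L))
  back <- read_bed(bed)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$strand, df$strand)
})

test_that("Karlin-Altschul parameters match published ungapped constants", {
  ka <- karlin_altschul_params(1, -2)
  # lambda solves the moment condition exactly
  p_match <- 0.25
  expect_equal(p_match * exp(ka$lambda) + (1 - p_match) * exp(-2 * ka$lambda),
               1, tolerance = 1e-9)
  # NCBI BLASTN tables: reward 1 / penalty -2 -> lambda 1.33, K 0.621
  expect_equal(ka$lambda, 1.33, tolerance = 0.01)
  expect_equal(ka$K, 0.621, tolerance = 0.01)
  # reward 1 / penalty -3 -> lambda 1.37, K 0.711
  ka3 <- karlin_altschul_params(1, -3)
  expect_equal(ka3$lambda, 1.37, tolerance = 0.01)
  expect_equal(ka3$K, 0.711, tolerance = 0.01)
})

test_that("partial-copy search finds planted copies and nothing in random sequence", {
  set.seed(3)
  ref5s <- rrna_reference("5S", random_dna(121))

  # i.i.d. 100 kb genome: no hit reaches the E-value threshold
  g1 <- c(chr1 = random_dna(100000))
  expect_equal(nrow(find_partial_copies(ref5s, g1)), 0L)

  # verbatim 80-nt substring: reported, covering the planted interval
  sub80 <- substr(ref5s$sequence, 21, 100)
  g2 <- c(chr1 = paste0(random_dna(5000), sub80, random_dna(5000)))
  h2 <- find_partial_copies(ref5s, g2)
  expect_equal(nrow(h2), 1L)
  expect_lte(h2$start, 5001)
  expect_gte(h2$end, 5080)
  expect_lte(h2$evalue, 1e-8)

  # 90%-identity 60-nt copy: bounds recovered within +/- 2 nt
  v <- strsplit(substr(ref5s$sequence, 31, 90), "")[[1]]
  pos <- sample(60, 6)
  for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1)
  g3 <- c(chr1 = paste0(random_dna(4000), paste(v, collapse = ""),
                        random_dna(4000)))
  h3 <- find_partial_copies(ref5s, g3)
  expect_equal(nrow(h3), 1L)
  expect_lte(abs(h3$start - 4001), 2)
  expect_lte(abs(h3$end - 4060), 2)

  # reverse-complement plantings are found on the minus strand
  g5 <- c(chr1 = paste0(random_dna(3000), revcomp(sub80), random_dna(3000)))
  h5 <- find_partial_copies(ref5s, g5)
  expect_equal(h5$strand, "-")
  expect_equal(h5$start, 3001)
  expect_equal(h5$end, 3080)
})

test_that("a genome made of the references is covered by partial-copy hits", {
  set.seed(9)
  refA <- rrna_reference("18S", random_dna(200))
  refB <- rrna_reference("5S", random_dna(121))
  genome <- c(chr1 = paste0(refA$sequence, refB$sequence))
  hA <- find_partial_copies(refA, genome)
  hB <- find_partial_copies(refB, genome)
  expect_true(any(hA$start <= 1 + 2 & hA$end >= 200 - 2))
  expect_true(any(hB$start <= 201 + 2 & hB$end >= 321 - 2))
  # full-length placements themselves are excluded from the hit list
  refA2 <- locate_placements(refA, genome)
  hA2 <- find_partial_copies(refA2, genome)
  expect_false(any(hA2$start == 1 & hA2$end == 200))
})
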