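test_that("fixture genomes are deterministic and carry exact repeat copies", {
  reps <- data.frame(src_start = 300L, len = 200L, insert_at = 1200L)
  g1 <- fixture_genome(2000L, reps, seed = 4L)
  g2 <- fixture_genome(2000L, reps, seed = 4L)
  g3 <- fixture_genome(2000L, reps, seed = 5L)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, g3$seq))
  expect_identical(substr(g1$seq, 301, 500), substr(g1$seq, 1201, 1400))
  expect_equal(g1$truth$start, c(300L, 1200L))
})

test_that("per-copy mutation makes repeats near-exact", {
  reps <- data.frame(src_start = 100L, len = 300L, insert_at = 800L,
                     mut_rate = 0.05)
  g <- fixture_genome(1500L, reps, seed = 8L)
  src <- strsplit(substr(g$seq, 101, 400), "")[[1]]
  cp <- strsplit(substr(g$seq, 801, 1100), "")[[1]]
  d <- sum(src != cp)
  expect_gt(d, 0L)
  expect_lt(d, 60L)  # ~5% of 300, generously bounded
})

test_that("tiling produces L - k + 1 reads at step 1 with origin-encoding names", {
  g <- fixture_genome(100L, seed = 2L)
  rd <- tile_reads(g, read_length = 50L, step = 1L)
  expect_equal(nrow(rd), 51L)
  expect_equal(rd$start, 0:50)
  expect_equal(rd$seq[10], substr(g$seq, 10, 59))
  # step-1 tiling covers interior positions exactly k deep, edges ramp up
  fx <- exhaustive_align(rd, g)
  rep0 <- coverage_report(fx$records[!fx$records$secondary, ],
                          interior_margin = 10L)
  v <- rep0$coverage$chr1
  expect_equal(v[50], 50L)   # position p (0-based 49) has true coverage p+1
  expect_equal(v[25], 25L)
})

test_that("the exhaustive aligner reports every placement with a correct NM", {
  reps <- data.frame(src_start = 200L, len = 300L, insert_at = 1000L)
  g <- fixture_genome(1600L, reps, seed = 6L)
  rd <- tile_reads(g, read_length = 50L, step = 7L)
  al <- exhaustive_align(rd, g, max_mismatch = 0L)
  x <- al$records
  # reads fully inside either copy have exactly 2 hits, others 1
  in_repeat <- (rd$start >= 200L & rd$start + 50L <= 500L) |
    (rd$start >= 1000L & rd$start + 50L <= 1300L)
  expect_equal(al$truth$n_candidates >= 2L, in_repeat)
  # NM recomputed independently from the genome sequence
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(x))) {
    ref_seg <- substr(g$seq, x$pos[i] + 1L, x$pos[i] + 50L)
    readseq <- x$seq[i]  # already reverse-complemented for minus strand
    expect_equal(sum(strsplit(ref_seg, "")[[1]] != strsplit(readseq, "")[[1]]),
                 x$nm[i])
  }
})

test_that("mismatched placements are found up to the allowance with exact NM", {
  reps <- data.frame(src_start = 100L, len = 200L, insert_at = 700L,
                     mut_rate = 0.01)
  g <- fixture_genome(1000L, reps, seed = 12L)
  rd <- tile_reads(g, read_length = 40L, step = 11L)
  al2 <- exhaustive_align(rd, g, max_mismatch = 2L)
  al0 <- exhaustive_align(rd, g, max_mismatch = 0L)
  expect_gt(nrow(al2$records), nrow(al0$records))  # near-exact hits appear
  expect_true(all(al2$records$nm <= 2L))
  # every exact hit is also reported in the relaxed run
  key <- function(d) paste(d$qname, d$pos, d$strand)
  expect_true(all(key(al0$records) %in% key(al2$records)))
})

test_that("reverse-strand placements are emitted with flipped flag and sequence", {
  g <- list(seq = "ACGTACGTTTTACGT", ref = "chr1")
  rd <- tibble::tibble(qname = "r1", start = 0L, seq = "AAAACGT")
  # revcomp(AAAACGT) = ACGTTTT which occurs at 0-based position 4
  al <- exhaustive_align(rd, g)
  expect_equal(al$records$strand, "-")
  expect_equal(al$records$pos, 4L)
  expect_equal(al$records$seq, "ACGTTTT")
  expect_equal(bitwAnd(al$records$flag, 16L), 16L)
})

test_that("coverage_report demands a resolved input", {
  lines <- c(sam_line("r1", 0L, "chr1", 0L, "10M"),
             sam_line("r1", 256L, "chr1", 50L, "10M"))
  x <- read_sam(write_sam_text(lines))
  expect_error(coverage_report(x), "not resolved")
})

test_that("input-order initialization over-covers the first repeat copy", {
  fx <- tiling_fixture(genome_length = 6000L, repeat_length = 600L, seed = 10L)
  x <- group_reads(fx$records)
  res <- resolve_groups(x, resolver_config(init = "order", iterations = 1L))
  # before any sweep: rebuild the initial map (input-order selections are
  # the first candidate = the leftmost placement)
  first_rows <- which(!duplicated(x$qname[!x$unmapped]))
  map0 <- rebuild_map(x, first_rows)
  v <- cov_state(map0)$chr1
  src <- 6000 * 0.3; ins <- 6000 * 0.7
  expect_gt(mean(v[(src + 100):(src + 500)]), 75)  # first copy over-covered
  expect_lt(mean(v[(ins + 100):(ins + 500)]), 25)  # second copy starved
})

test_that("the spliced fixture exercises junction CIGARs and annotation", {
  fx <- spliced_fixture(seed = 3L)
  x <- fx$records
  junction <- grepl("N", x$cigar)
  expect_true(any(junction))
  fp <- cigar_footprints(x$pos[junction][1], x$cigar[junction][1])[[1]]
  expect_equal(nrow(fp), 2L)
  # end-to-end with annotation: runs, conserves reads
  sam <- tempfile(fileext = ".sam"); write_sam(x, sam)
  gtf <- tempfile(fileext = ".gtf"); write_gtf(fx$exons, gtf)
  out <- tempfile(fileext = ".sam")
  res <- resolve_multimappers(sam, out,
                              resolver_config(init = "order", annotation = gtf))
  y <- read_sam(out)
  expect_equal(sort(unique(y$qname)), sort(unique(x$qname)))
  expect_equal(nrow(y), length(unique(x$qname)))
})

test_that("micro instances have the unique enumerable optimum they advertise", {
  for (s in 1:5) {
    mi <- micro_instance(seed = s)
    opt <- enumerate_optimum(mi$records)
    expect_true(opt$unique)
    expect_equal(unname(opt$positions), mi$truth$optimal_pos)
  }
})

test_that("fixture outputs are byte-deterministic under a fixed seed", {
  f1 <- tiling_fixture(genome_length = 2000L, repeat_length = 200L, seed = 19L)
  f2 <- tiling_fixture(genome_length = 2000L, repeat_length = 200L, seed = 19L)
  p1 <- tempfile(fileext = ".sam"); p2 <- tempfile(fileext = ".sam")
  write_sam(f1$records, p1); write_sam(f2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
  a1 <- tempfile(); a2 <- tempfile()
  write_fasta(f1$genome, a1); write_fasta(f2$genome, a2)
  expect_identical(readLines(a1), readLines(a2))
})
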