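mk_group <- function(nm) {
  tibble::tibble(qname = "r", pos = seq_along(nm) * 100L, nm = nm)
}

test_that("edit-distance filter keeps candidates within delta of the best", {
  expect_equal(nrow(filter_by_edit_delta(mk_group(c(0L, 0L, 2L)), 0L)), 2L)
  expect_equal(nrow(filter_by_edit_delta(mk_group(c(1L, 3L, 2L)), 10L)), 3L)
  g <- filter_by_edit_delta(mk_group(c(2L, 3L, 3L, 5L)), 1L)
  expect_equal(g$nm, c(2L, 3L, 3L))      # min=2, threshold 3, order kept
})

mate_tbl <- function(rname, pos, strand, cigar = "50M") {
  tibble::tibble(rname = rname, pos = as.integer(pos), strand = strand,
                 cigar = cigar)
}

test_that("pair feasibility needs same reference, FR orientation, and proximity", {
  p <- enumerate_pairs(mate_tbl("chr1", 100, "+"), mate_tbl("chr1", 300, "-"),
                       1000L)
  expect_equal(nrow(p), 1L)
  # chromosome mismatch
  p <- enumerate_pairs(mate_tbl("chr1", 100, "+"), mate_tbl("chr2", 300, "-"),
                       1000L)
  expect_equal(nrow(p), 0L)
  # same strand
  p <- enumerate_pairs(mate_tbl("chr1", 100, "+"), mate_tbl("chr1", 300, "+"),
                       1000L)
  expect_equal(nrow(p), 0L)
  # reverse-forward (leftmost on minus) is not proper
  p <- enumerate_pairs(mate_tbl("chr1", 100, "-"), mate_tbl("chr1", 300, "+"),
                       1000L)
  expect_equal(nrow(p), 0L)
  # too far apart
  p <- enumerate_pairs(mate_tbl("chr1", 100, "+"), mate_tbl("chr1", 90000, "-"),
                       1000L)
  expect_equal(nrow(p), 0L)
})

test_that("2x2 candidates with one infeasible combination yield 3 pairs in order", {
  m0 <- mate_tbl("chr1", c(100, 600), "+")
  m1 <- mate_tbl("chr1", c(400, 900), "-")
  p <- enumerate_pairs(m0, m1, 1000L)
  # (2,1) is reverse-forward (600 > 400): infeasible; the rest are feasible
  expect_equal(p$i0, c(1L, 1L, 2L))
  expect_equal(p$i1, c(1L, 2L, 2L))
})

test_that("initialization policies select as documented and build the pileup", {
  lines <- c(
    sam_line("a", 0L, "chr1", 10L, "10M", tags = "NM:i:0\tAS:i:-5"),
    sam_line("a", 256L, "chr1", 200L, "10M", tags = "NM:i:0\tAS:i:-1"),
    sam_line("b", 0L, "chr1", 400L, "10M", tags = "NM:i:0\tAS:i:0")
  )
  x <- group_reads(read_sam(write_sam_text(lines)))
  # best score picks the second candidate of group a
  res <- resolve_groups(x, resolver_config(init = "best", iterations = 1L))
  expect_equal(sort(res$selected_rows), c(2L, 3L))
  # input order picks the first
  res <- resolve_groups(x, resolver_config(init = "order", iterations = 1L))
  expect_true(1L %in% res$selected_rows)
  # the map equals the pileup of the selected footprints
  rebuilt <- rebuild_map(x, res$selected_rows)
  expect_equal(cov_state(res$map), cov_state(rebuilt))
})

test_that("random initialization is deterministic under the seed", {
  fx <- tiling_fixture(genome_length = 3000L, repeat_length = 400L, seed = 9L)
  x <- group_reads(fx$records)
  r1 <- resolve_groups(x, resolver_config(init = "random", seed = 7L,
                                          iterations = 1L))
  r2 <- resolve_groups(x, resolver_config(init = "random", seed = 7L,
                                          iterations = 1L))
  expect_identical(r1$selected_rows, r2$selected_rows)
})

test_that("best-score init falls back to input order with a warning when AS is absent", {
  lines <- c(
    sam_line("a", 0L, "chr1", 10L, "10M"),
    sam_line("a", 256L, "chr1", 200L, "10M")
  )
  x <- group_reads(read_sam(write_sam_text(lines)))
  expect_warning(
    res <- resolve_groups(x, resolver_config(init = "best", iterations = 1L)),
    "input order")
})

swap_fixture <- function() {
  # ten stacked unique reads at 100..150, nothing at 300..350
  map <- coverage_map(c(chr1 = 600L))
  for (i in 1:10) cov_add(map, "chr1", cbind(100L, 150L))
  map
}

test_that("evaluate_swap follows the four-term rule", {
  map <- swap_fixture()
  cur <- candidate("chr1", list(cbind(100L, 150L)))
  alt <- candidate("chr1", list(cbind(300L, 350L)))
  cov_add(map, "chr1", cur$fp)  # current placed on top of the pile
  # identical alternative: strict inequality fails on equality
  expect_false(evaluate_swap(map, cur, cur, 20L))
  # stacked on a pile vs flat empty region: move
  expect_true(evaluate_swap(map, cur, alt, 20L))
  # dip exactly filled by the current read vs a plateau of the same depth
  map2 <- coverage_map(c(chr1 = 600L))
  cov_add(map2, "chr1", cbind(50L, 100L))    # plateau-height background
  cov_add(map2, "chr1", cbind(150L, 200L))
  cov_add(map2, "chr1", cbind(280L, 370L))   # plateau at the alternative
  cur2 <- candidate("chr1", list(cbind(100L, 150L)))  # fills the dip
  cov_add(map2, "chr1", cur2$fp)
  alt2 <- candidate("chr1", list(cbind(300L, 350L)))
  expect_false(evaluate_swap(map2, cur2, alt2, 20L))
})

test_that("a sweep changes selections only when strictly better and reaches a fixpoint", {
  lines <- c(
    # unique pile creating pressure at 100
    unlist(lapply(1:8, function(i) sam_line(sprintf("u%02d", i), 0L, "chr1",
                                            100L, "50M"))),
    # one multi-mapper: first candidate on the pile, second on empty ground
    sam_line("m1", 0L, "chr1", 100L, "50M"),
    sam_line("m1", 256L, "chr1", 400L, "50M")
  )
  x <- group_reads(read_sam(write_sam_text(lines)))
  res <- resolve_groups(x, resolver_config(init = "order", iterations = 4L))
  expect_equal(res$iterations$changes[1], 1L)               # moved off the pile
  expect_equal(res$iterations$changes[nrow(res$iterations)], 0L)  # fixpoint
  expect_true(10L %in% res$selected_rows)                   # candidate at 400
  # map consistency after the run
  rebuilt <- rebuild_map(x, res$selected_rows)
  expect_equal(cov_state(res$map), cov_state(rebuilt))
})

test_that("all-unique input passes through unchanged", {
  fx <- tiling_fixture(genome_length = 2000L, repeat_length = 0L, seed = 5L)
  sam <- tempfile(fileext = ".sam"); write_sam(fx$records, sam)
  out <- tempfile(fileext = ".sam")
  res <- resolve_multimappers(sam, out, resolver_config(init = "order"))
  expect_equal(res$stats$multi_groups, 0L)
  expect_equal(sum(res$iterations$changes), 0L)
  in_body <- grep("^@", readLines(sam), invert = TRUE, value = TRUE)
  out_body <- grep("^@", readLines(out), invert = TRUE, value = TRUE)
  expect_identical(out_body, in_body)
})

test_that("resolution conserves reads and never invents records", {
  fx <- tiling_fixture(genome_length = 4000L, repeat_length = 500L, seed = 21L)
  x <- group_reads(fx$records)
  res <- resolve_groups(x, resolver_config(init = "order"))
  sel <- res$records[res$selected_rows, ]
  # exactly one candidate per read name
  expect_equal(sort(unique(sel$qname)), sort(unique(fx$records$qname)))
  expect_equal(nrow(sel), length(unique(fx$records$qname)))
  # every output record existed among the input candidates
  key <- function(d) paste(d$qname, d$rname, d$pos, d$cigar, d$strand)
  expect_true(all(key(sel) %in% key(fx$records)))
  # unique reads are never altered
  uniq <- fx$truth$qname[fx$truth$n_candidates == 1L]
  sel_u <- sel[sel$qname %in% uniq, c("qname", "pos")]
  in_u <- fx$records[fx$records$qname %in% uniq, c("qname", "pos")]
  expect_equal(dplyr::arrange(sel_u, qname), dplyr::arrange(in_u, qname))
})

test_that("at convergence no selected/alternative pair admits a swap", {
  fx <- tiling_fixture(genome_length = 3000L, repeat_length = 300L, seed = 13L)
  x <- group_reads(fx$records)
  res <- resolve_groups(x, resolver_config(init = "order", iterations = 10L))
  expect_true(res$stats$converged)
  groups <- res$groups; sel <- res$sel; map <- res$map
  for (g in seq_along(groups)) {
    k <- length(groups[[g]]$cands)
    if (k < 2L) next
    for (ci in seq_len(k)) {
      if (ci == sel[g]) next
      expect_false(evaluate_swap(map, groups[[g]]$cands[[sel[g]]],
                                 groups[[g]]$cands[[ci]], 20L))
    }
  }
})

test_that("same input and seed give byte-identical output", {
  fx <- tiling_fixture(genome_length = 3000L, repeat_length = 300L, seed = 17L)
  sam <- tempfile(fileext = ".sam"); write_sam(fx$records, sam)
  o1 <- tempfile(fileext = ".sam"); o2 <- tempfile(fileext = ".sam")
  resolve_multimappers(sam, o1, resolver_config(init = "random", seed = 3L))
  resolve_multimappers(sam, o2, resolver_config(init = "random", seed = 3L))
  l1 <- readLines(o1); l2 <- readLines(o2)
  body <- function(l) grep("^@", l, invert = TRUE, value = TRUE)
  expect_identical(body(l1), body(l2))
})

test_that("supplementary records are dropped from candidacy with a counter", {
  lines <- c(
    sam_line("r1", 0L, "chr1", 10L, "20M"),
    sam_line("r1", 2048L, "chr1", 500L, "20M"),
    sam_line("r2", 0L, "chr1", 100L, "20M")
  )
  x <- group_reads(read_sam(write_sam_text(lines)))
  res <- resolve_groups(x, resolver_config(init = "order"))
  expect_equal(res$stats$supplementary_dropped, 1L)
  expect_equal(sort(res$selected_rows), c(1L, 3L))
})

test_that("unmapped reads pass through by default and can be dropped", {
  lines <- c(
    sam_line("r1", 0L, "chr1", 10L, "20M"),
    sam_line("r9", 4L, "*", -1L, "*", tags = "")
  )
  sam <- write_sam_text(lines)
  out <- tempfile(fileext = ".sam")
  resolve_multimappers(sam, out, resolver_config(init = "order"))
  expect_equal(length(grep("^@", readLines(out), invert = TRUE)), 2L)
  resolve_multimappers(sam, out, resolver_config(init = "order",
                                                 keep_unmapped = FALSE))
  expect_equal(length(grep("^@", readLines(out), invert = TRUE)), 1L)
})

paired_lines <- function() {
  # one unique proper pair and one ambiguous pair with two feasible placements
  c(
    sam_line("p1", 99L, "chr1", 100L, "30M"),    # paired, proper, mate1, +
    sam_line("p1", 147L, "chr1", 300L, "30M"),   # paired, proper, mate2, -
    sam_line("p2", 99L, "chr1", 1000L, "30M"),
    sam_line("p2", 147L, "chr1", 1200L, "30M"),
    sam_line("p2", 355L, "chr1", 3000L, "30M"),  # secondary placements
    sam_line("p2", 403L, "chr1", 3200L, "30M")
  )
}

test_that("paired resolution selects whole pairs", {
  x <- group_reads(read_sam(write_sam_text(paired_lines(),
                                           refs = c(chr1 = 5000L))))
  res <- resolve_groups(x, resolver_config(paired = TRUE, init = "order"))
  expect_equal(res$stats$reads, 2L)          # two pair groups
  expect_equal(res$stats$multi_groups, 1L)
  sel <- res$records[res$selected_rows, ]
  expect_equal(nrow(sel), 4L)                # both mates of both pairs
  # the selected placements of p2 form one feasible pair, never the
  # reverse-forward combination
  p2 <- sort(sel$pos[sel$qname == "p2"])
  expect_true(identical(p2, c(1000L, 1200L)) ||
                identical(p2, c(1000L, 3200L)) ||
                identical(p2, c(3000L, 3200L)))
})

test_that("pairs without any feasible combination fall back to single-end groups", {
  lines <- c(
    sam_line("q1", 67L, "chr1", 100L, "30M"),   # paired, mate1, + (flag 64+2+1)
    sam_line("q1", 131L, "chr1", 200L, "30M")   # paired, mate2, + -> same strand
  )
  x <- group_reads(read_sam(write_sam_text(lines)))
  res <- resolve_groups(x, resolver_config(paired = TRUE, init = "order"))
  expect_equal(res$stats$pair_fallbacks, 1L)
  expect_equal(res$stats$reads, 2L)           # two independent SE groups
  out <- tempfile(fileext = ".sam")
  write_selected(res$records, res$selected_rows, out,
                 improper_rows = res$improper_rows)
  y <- read_sam(out)
  expect_equal(bitwAnd(y$flag, 2L), c(0L, 0L))  # proper-pair flag cleared
})

test_that("missing NM falls back to a CIGAR-derived edit distance", {
  lines <- c(
    sam_line("r1", 0L, "chr1", 10L, "10=2X8=", tags = ""),
    sam_line("r1", 256L, "chr1", 300L, "20=", tags = "")
  )
  x <- group_reads(read_sam(write_sam_text(lines)))
  res <- resolve_groups(x, resolver_config(init = "order", edit_delta = 0L))
  # the X-containing candidate (NM 2) is filtered against the exact one
  expect_equal(res$selected_rows, 2L)
})
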