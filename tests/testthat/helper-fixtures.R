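# Shared builders and independent oracles used across the test files.

# Write handcrafted SAM text and return the path.
write_sam_text <- function(lines, refs = c(chr1 = 1000L)) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tGO:query",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  writeLines(c(hdr, lines), path)
  path
}

# One SAM body line from the minimal fields (pos is 0-based here).
sam_line <- function(qname, flag, rname, pos, cigar, tags = "NM:i:0",
                     mapq = 255L, seq = "*", qual = "*") {
  line <- paste(qname, flag, rname, pos + 1L, mapq, cigar, "*", 0L, 0L,
                seq, qual, sep = "\t")
  if (nzchar(tags)) paste(line, tags, sep = "\t") else line
}

# Independent loss oracle: copy the window values out of the map snapshot,
# edit them position by position, and apply the variance formula directly.
naive_loss <- function(map, cand, flank, present, placed,
                       breakpoints = NULL) {
  state <- cov_state(map)
  ref_len <- map$ref_lengths[[cand$ref]]
  bps <- if (is.null(breakpoints)) NULL else breakpoints[[cand$ref]]
  total <- 0
  for (fp_mate in cand$mates) {
    win <- make_window(fp_mate, flank, ref_len, bps)
    vals <- numeric(0)
    for (i in seq_len(nrow(win))) {
      for (p in win[i, 1L]:(win[i, 2L] - 1L)) {
        v <- if (is.null(state[[cand$ref]])) 0 else state[[cand$ref]][p + 1L]
        covered <- any(cand$fp[, 1L] <= p & p < cand$fp[, 2L])
        if (covered) {
          if (present && !placed) v <- v + 1
          if (!present && placed) v <- v - 1
        }
        vals <- c(vals, v)
      }
    }
    m <- sum(vals) / length(vals)
    total <- total + sum((vals - m)^2) / length(vals)
  }
  total
}

# Rebuild a coverage map from scratch from a set of selected rows.
rebuild_map <- function(records, rows, groups = NULL, sel = NULL) {
  map <- coverage_map(sam_ref_lengths(records))
  if (!is.null(groups)) {
    for (g in seq_along(groups)) {
      cand <- groups[[g]]$cands[[sel[g]]]
      cov_add(map, cand$ref, cand$fp)
    }
  } else {
    fps <- cigar_footprints(records$pos[rows], records$cigar[rows])
    for (i in seq_along(rows)) {
      cov_add(map, records$rname[rows[i]], fps[[i]])
    }
  }
  map
}

# The standard repeat-tiling instance is used by several acceptance
# checks; build and resolve it once per session.
standard_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- tiling_fixture(seed = 42L)
      sam <- tempfile(fileext = ".sam")
      write_sam(fx$records, sam)
      out <- tempfile(fileext = ".sam")
      res <- resolve_multimappers(
        sam, out,
        resolver_config(init = "order", iterations = 4L, audit = TRUE))
      cache <<- list(fx = fx, sam = sam, out = out, res = res)
    }
    cache
  }
})
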