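## Synthetic fixtures with known truth.
##
## Everything needed to validate the resolver without external data:
## repeat-structured random genomes, exhaustive tilings, a brute-force toy
## aligner that reports *all* placements of every read with correct NM
## tags, a coverage reporter, a spliced (two-exon) RNA-seq fixture, and
## small "micro instances" whose globally optimal assignment can be found
## by exhaustive enumeration.

#' Construct an alignment tibble from fields
#'
#' Builds the same tibble [read_sam()] would produce, from vectors, with a
#' minimal header. Used by fixture generators and tests.
#'
#' @param qname,flag,rname,pos,cigar Mandatory fields (`pos` 0-based).
#' @param mapq,seq,qual,tags,rnext,pnext,tlen Optional fields, recycled.
#' @param ref_lengths Named reference lengths for the `@SQ` header lines.
#' @param queryname_grouped Add `GO:query` to the `@HD` line.
#' @return An alignment tibble with header attribute.
#' @export
sam_tibble <- function(qname, flag, rname, pos, cigar, ref_lengths,
                       mapq = 255L, seq = "*", qual = "*", tags = "",
                       rnext = "*", pnext = 0L, tlen = 0L,
                       queryname_grouped = TRUE) {
  n <- length(qname)
  hd <- if (queryname_grouped) "@HD\tVN:1.6\tGO:query" else "@HD\tVN:1.6"
  header <- c(hd, sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                          as.integer(ref_lengths)))
  flag <- as.integer(rep_len(flag, n))
  rec <- tibble(
    qname = qname,
    flag = flag,
    rname = rep_len(rname, n),
    pos = as.integer(pos),
    mapq = as.integer(rep_len(mapq, n)),
    cigar = rep_len(cigar, n),
    rnext = rep_len(rnext, n),
    pnext = as.integer(rep_len(pnext, n)),
    tlen = as.integer(rep_len(tlen, n)),
    seq = rep_len(seq, n),
    qual = rep_len(qual, n),
    tags = rep_len(tags, n),
    nm = extract_int_tag(rep_len(tags, n), "NM"),
    score = as.double(extract_int_tag(rep_len(tags, n), "AS")),
    strand = ifelse(bitwAnd(flag, SAM_FLAG_REVERSE) > 0L, "-", "+"),
    unmapped = bitwAnd(flag, SAM_FLAG_UNMAPPED) > 0L,
    secondary = bitwAnd(flag, SAM_FLAG_SECONDARY) > 0L,
    supplementary = bitwAnd(flag, SAM_FLAG_SUPPLEMENTARY) > 0L,
    paired = bitwAnd(flag, SAM_FLAG_PAIRED) > 0L,
    mate = ifelse(bitwAnd(flag, SAM_FLAG_PAIRED) > 0L,
                  ifelse(bitwAnd(flag, SAM_FLAG_MATE1) > 0L, 0L,
                         ifelse(bitwAnd(flag, SAM_FLAG_MATE2) > 0L, 1L, NA_integer_)),
                  NA_integer_)
  )
  new_covres_sam(rec, header)
}

#' Generate a repeat-structured random genome
#'
#' A uniform-random nucleotide sequence in which chosen segments are
#' copied (optionally point-mutated) to other locations, creating exact or
#' near-exact repeats -- the structure that produces multi-mapping reads.
#' Deterministic under `seed`.
#'
#' @param length Genome length in bp.
#' @param repeats A data frame with columns `src_start` (0-based),
#'   `len`, `insert_at` (0-based), and optionally `copies` (default 1) and
#'   `mut_rate` (per-base substitution probability per copy, default 0).
#'   Consecutive copies are placed end to end from `insert_at`.
#' @param seed Integer seed.
#' @return List with `seq` (character genome), `ref` (`"chr1"`),
#'   `truth` (tibble of source and copy coordinates).
#' @export
fixture_genome <- function(length, repeats = NULL, seed = 1L) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    g <- sample(bases, length, replace = TRUE)
    truth <- tibble(label = character(0), start = integer(0), end = integer(0))
    if (!is.null(repeats) && nrow(repeats) > 0L) {
      repeats <- as.data.frame(repeats)
      if (is.null(repeats$copies)) repeats$copies <- 1L
      if (is.null(repeats$mut_rate)) repeats$mut_rate <- 0
      for (i in seq_len(nrow(repeats))) {
        s <- repeats$src_start[i]; l <- repeats$len[i]
        ins <- repeats$insert_at[i]
        if (s < 0L || s + l > length) abort("repeat source outside genome")
        src <- g[(s + 1L):(s + l)]
        truth <- dplyr::bind_rows(truth, tibble(
          label = paste0("rep", i, "_src"), start = as.integer(s),
          end = as.integer(s + l)))
        for (cp in seq_len(repeats$copies[i])) {
          at <- ins + (cp - 1L) * l
          if (at < 0L || at + l > length) abort("repeat copy outside genome")
          if (at < s + l && at + l > s) abort("repeat copy overlaps its source")
          copy <- src
          mr <- repeats$mut_rate[i]
          if (mr > 0) {
            hit <- which(stats::runif(l) < mr)
            for (h in hit) {
              copy[h] <- sample(setdiff(bases, copy[h]), 1L)
            }
          }
          g[(at + 1L):(at + l)] <- copy
          truth <- dplyr::bind_rows(truth, tibble(
            label = paste0("rep", i, "_copy", cp), start = as.integer(at),
            end = as.integer(at + l)))
        }
      }
    }
    list(seq = paste(g, collapse = ""), ref = "chr1", truth = truth)
  })
}

#' Write a fixture genome as FASTA
#' @param genome A [fixture_genome()] result (or a character sequence).
#' @param path Output path.
#' @param name Sequence name.
#' @export
write_fasta <- function(genome, path, name = "chr1") {
  s <- if (is.list(genome)) genome$seq else genome
  set <- Biostrings::DNAStringSet(s)
  names(set) <- name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Tile a genome with overlapping k-mers
#'
#' One read per start position `0, step, 2*step, ... <= L - k`; the read
#' identifier encodes the true origin. With `step = 1`, interior genome
#' positions have true coverage exactly `k`.
#'
#' @param genome A [fixture_genome()] result or character sequence.
#' @param read_length k-mer length (default 50).
#' @param step Tiling step (default 1).
#' @return Tibble with `qname`, `start` (0-based true origin), `seq`.
#' @export
tile_reads <- function(genome, read_length = 50L, step = 1L) {
  s <- if (is.list(genome)) genome$seq else genome
  L <- nchar(s)
  stopifnot(read_length <= L, step >= 1L)
  starts <- seq.int(0L, L - read_length, by = step)
  tibble(
    qname = sprintf("t%08d", starts),
    start = as.integer(starts),
    seq = substring(s, starts + 1L, starts + read_length)
  )
}

#' Enumerate all placements of every read by brute-force string search
#'
#' A stand-in for an external aligner: every placement of every read with
#' at most `max_mismatch` mismatches, on both strands, is emitted as a SAM
#' record with a correct `NM` tag. Records are grouped by read name and,
#' within a read, ordered by position (forward hits before reverse hits at
#' the same position); all but the first record of a read carry the
#' secondary flag.
#'
#' @param reads Tibble from [tile_reads()] (columns `qname`, `seq`).
#' @param genome A [fixture_genome()] result or character sequence.
#' @param max_mismatch Maximum Hamming distance of a reported placement.
#' @param ref Reference name.
#' @return List with `records` (alignment tibble) and `truth` (tibble
#'   `qname`, `n_candidates`).
#' @export
exhaustive_align <- function(reads, genome, max_mismatch = 0L, ref = "chr1") {
  s <- if (is.list(genome)) genome$seq else genome
  L <- nchar(s)
  subj <- Biostrings::DNAString(s)
  pats <- Biostrings::DNAStringSet(reads$seq)
  rc <- Biostrings::reverseComplement(pats)
  rc_chr <- as.character(rc)
  if (max_mismatch == 0L) {
    fwd <- Biostrings::startIndex(Biostrings::matchPDict(Biostrings::PDict(pats), subj))
    rev <- Biostrings::startIndex(Biostrings::matchPDict(Biostrings::PDict(rc), subj))
    fwd <- lapply(fwd, function(x) if (is.null(x)) integer(0) else x)
    rev <- lapply(rev, function(x) if (is.null(x)) integer(0) else x)
    nm_f <- lapply(lengths(fwd), integer)
    nm_r <- lapply(lengths(rev), integer)
  } else {
    n <- nrow(reads)
    fwd <- rev <- nm_f <- nm_r <- vector("list", n)
    for (i in seq_len(n)) {
      mf <- Biostrings::matchPattern(pats[[i]], subj,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE)
      mr <- Biostrings::matchPattern(rc[[i]], subj,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE)
      fwd[[i]] <- BiocGenerics::start(mf)
      rev[[i]] <- BiocGenerics::start(mr)
      nm_f[[i]] <- vapply(fwd[[i]], function(st)
        Biostrings::neditStartingAt(pats[[i]], subj, starting.at = st,
                                    with.indels = FALSE), integer(1))
      nm_r[[i]] <- vapply(rev[[i]], function(st)
        Biostrings::neditStartingAt(rc[[i]], subj, starting.at = st,
                                    with.indels = FALSE), integer(1))
    }
  }
  nf <- lengths(fwd); nr <- lengths(rev)
  ridx <- c(rep(seq_along(nf), nf), rep(seq_along(nr), nr))
  pos1 <- c(unlist(fwd, use.names = FALSE), unlist(rev, use.names = FALSE))
  strand_rev <- c(rep(FALSE, sum(nf)), rep(TRUE, sum(nr)))
  nm <- c(unlist(nm_f, use.names = FALSE), unlist(nm_r, use.names = FALSE))
  if (length(ridx) == 0L) abort("no placements found for any read")
  ord <- order(ridx, pos1, strand_rev)
  ridx <- ridx[ord]; pos1 <- pos1[ord]; strand_rev <- strand_rev[ord]; nm <- nm[ord]
  first <- !duplicated(ridx)
  flag <- ifelse(strand_rev, SAM_FLAG_REVERSE, 0L) +
    ifelse(first, 0L, SAM_FLAG_SECONDARY)
  k <- nchar(reads$seq[1])
  records <- sam_tibble(
    qname = reads$qname[ridx],
    flag = flag,
    rname = ref,
    pos = pos1 - 1L,
    cigar = paste0(k, "M"),
    ref_lengths = setNames(L, ref),
    mapq = 255L,
    seq = ifelse(strand_rev, rc_chr[ridx], reads$seq[ridx]),
    tags = paste0("NM:i:", nm)
  )
  cnt <- tabulate(ridx, nbins = nrow(reads))
  list(records = records,
       truth = tibble(qname = reads$qname, n_candidates = cnt))
}

#' Per-base coverage of a resolved alignment set
#'
#' Deterministic pileup of the footprints of a resolved file (one
#' alignment per read), with a uniformity summary: coverage histogram,
#' modal coverage, and the fraction of interior positions (at least
#' `interior_margin` bp from the sequence ends) at the modal value.
#'
#' @param x An alignment tibble or a SAM/BAM path.
#' @param interior_margin Positions closer than this to a reference end
#'   are excluded from the uniformity summary (default 50, one read
#'   length).
#' @param allow_pairs Permit up to two records per name (mates).
#' @return A `coverage_report`: list with `coverage` (named list of
#'   integer vectors), `histogram`, `modal`, `frac_at_modal`, `variance`.
#' @export
coverage_report <- function(x, interior_margin = 50L, allow_pairs = FALSE) {
  records <- if (is.character(x)) read_sam(x) else x
  mapped <- records[!records$unmapped, , drop = FALSE]
  tab <- table(mapped$qname)
  limit <- if (allow_pairs) 2L else 1L
  if (any(tab > limit)) {
    abort(paste0("input is not resolved: read '",
                 names(tab)[which(tab > limit)[1]],
                 "' has more than ", limit, " record(s)"))
  }
  ref_lengths <- sam_ref_lengths(records)
  fps <- cigar_footprints(mapped$pos, mapped$cigar)
  nint <- vapply(fps, nrow, integer(1))
  ref_col <- rep(mapped$rname, nint)
  fp_all <- do.call(rbind, fps)
  map <- coverage_map(ref_lengths)
  cov_bulk_add(map, ref_col, fp_all[, 1L], fp_all[, 2L], length(fps))
  coverage <- lapply(setNames(names(ref_lengths), names(ref_lengths)),
                     function(r) {
                       v <- map$env[[r]]
                       if (is.null(v)) integer(ref_lengths[[r]]) else v
                     })
  interior <- unlist(lapply(names(coverage), function(r) {
    v <- coverage[[r]]
    L <- length(v)
    if (L <= 2L * interior_margin) return(integer(0))
    v[(interior_margin + 1L):(L - interior_margin)]
  }), use.names = FALSE)
  if (length(interior) == 0L) abort("no interior positions at this margin")
  tabv <- table(interior)
  modal <- as.integer(names(tabv)[which.max(tabv)])
  hist <- tibble(depth = as.integer(names(tabv)), n = as.integer(tabv))
  structure(list(
    coverage = coverage,
    histogram = hist,
    modal = modal,
    frac_at_modal = max(tabv) / length(interior),
    variance = coverage_variance(as.double(interior)),
    interior_margin = as.integer(interior_margin),
    n_interior = length(interior)
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report>\n")
  cat("  interior positions (margin ", x$interior_margin, "): ",
      x$n_interior, "\n", sep = "")
  cat("  modal coverage: ", x$modal, " (", sprintf("%.2f%%",
      100 * x$frac_at_modal), " of interior positions)\n", sep = "")
  cat("  interior coverage variance: ", sprintf("%.4f", x$variance),
      "\n", sep = "")
  invisible(x)
}

#' Write exon features as GTF
#'
#' @param exons Tibble with columns `ref`, `start`, `end` (0-based
#'   half-open), `gene_id`, `transcript_id`, optionally `strand`.
#' @param path Output path.
#' @export
write_gtf <- function(exons, path) {
  strand <- if ("strand" %in% names(exons)) exons$strand else "+"
  lines <- sprintf(
    '%s\tcovres\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$ref, exons$start + 1L, exons$end, strand,
    exons$gene_id, exons$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Spliced RNA-seq fixture: duplicated two-exon gene
#'
#' A genome containing two genes with identical exonic sequence but
#' different introns. Transcript-tiled reads therefore map ambiguously to
#' both gene copies; junction-spanning reads carry `xMyNzM` CIGARs. The
#' GTF lists all four exons and the truth includes the implied
#' breakpoints.
#'
#' @param seed Integer seed.
#' @param genome_length,exon_length,intron_length,read_length,step
#'   Geometry of the fixture (defaults: 12 kb genome, 200 bp exons,
#'   300 bp intron, 50-mers every 10 bp).
#' @return List with `genome`, `records` (queryname-grouped alignment
#'   tibble), `exons` (tibble for [write_gtf()]), `breakpoints` (truth,
#'   0-based), and `gene_starts`.
#' @export
spliced_fixture <- function(seed = 1L, genome_length = 12000L,
                            exon_length = 200L, intron_length = 300L,
                            read_length = 50L, step = 10L) {
  gene_starts <- c(2000L, 8000L)
  g <- fixture_genome(genome_length, seed = seed)
  s <- strsplit(g$seq, "")[[1]]
  ## make gene B's exons byte-identical to gene A's
  e1a <- gene_starts[1] + seq_len(exon_length)
  e2a <- gene_starts[1] + intron_length + exon_length + seq_len(exon_length)
  e1b <- gene_starts[2] + seq_len(exon_length)
  e2b <- gene_starts[2] + intron_length + exon_length + seq_len(exon_length)
  s[e1b] <- s[e1a]
  s[e2b] <- s[e2a]
  genome <- paste(s, collapse = "")
  tx <- paste(c(s[e1a], s[e2a]), collapse = "")
  starts <- seq.int(0L, 2L * exon_length - read_length, by = step)
  mk_cigar <- function(off) {
    if (off + read_length <= exon_length) {
      list(cigar = paste0(read_length, "M"), gpos = off)
    } else if (off >= exon_length) {
      list(cigar = paste0(read_length, "M"),
           gpos = exon_length + intron_length + (off - exon_length))
    } else {
      m1 <- exon_length - off
      list(cigar = paste0(m1, "M", intron_length, "N", read_length - m1, "M"),
           gpos = off)
    }
  }
  qn <- character(0); fl <- integer(0); po <- integer(0); cg <- character(0)
  sq <- character(0)
  for (i in seq_along(starts)) {
    off <- starts[i]
    cc <- mk_cigar(off)
    rseq <- substring(tx, off + 1L, off + read_length)
    for (gi in 1:2) {
      qn <- c(qn, sprintf("tx%05d", off))
      fl <- c(fl, if (gi == 1L) 0L else SAM_FLAG_SECONDARY)
      po <- c(po, gene_starts[gi] + cc$gpos)
      cg <- c(cg, cc$cigar)
      sq <- c(sq, rseq)
    }
  }
  records <- sam_tibble(qn, fl, g$ref, po, cg,
                        ref_lengths = setNames(genome_length, g$ref),
                        seq = sq, tags = "NM:i:0")
  exons <- tibble(
    ref = g$ref,
    start = c(gene_starts[1], gene_starts[1] + exon_length + intron_length,
              gene_starts[2], gene_starts[2] + exon_length + intron_length),
    end = c(gene_starts[1] + exon_length,
            gene_starts[1] + 2L * exon_length + intron_length,
            gene_starts[2] + exon_length,
            gene_starts[2] + 2L * exon_length + intron_length),
    gene_id = rep(c("geneA", "geneB"), each = 2L),
    transcript_id = rep(c("geneA.1", "geneB.1"), each = 2L)
  )
  list(genome = genome, records = records, exons = exons,
       breakpoints = sort(unique(c(exons$start, exons$end))),
       gene_starts = gene_starts)
}

#' Randomized micro-instance with a unique enumerable optimum
#'
#' Builds a small single-reference instance in which unique reads create,
#' at each candidate locus of each ambiguous read, either a flat coverage
#' background or a background with a one-deep dip exactly the shape of the
#' read footprint. The dip depth is chosen not above any flat depth of the
#' same group, so filling the dip is the unique global minimiser of the
#' total coverage variance, reachable by independent single swaps. Used
#' against [enumerate_optimum()].
#'
#' @param seed Integer seed.
#' @param n_groups Number of ambiguous reads (default: drawn in 2..8).
#' @param read_length Footprint length of the ambiguous reads.
#' @param flank Window flank the instance is designed for.
#' @return List with `records` (alignment tibble), `flank`, and `truth`
#'   (tibble `qname`, `optimal_pos`).
#' @export
micro_instance <- function(seed = 1L, n_groups = NULL, read_length = 20L,
                           flank = 10L) {
  withr::with_seed(seed, {
    if (is.null(n_groups)) n_groups <- sample(2:8, 1L)
    n_cands <- sample(2:3, n_groups, replace = TRUE)
    slot <- read_length + 2L * flank + 20L  # footprint + window + padding
    total_slots <- sum(n_cands)
    L <- as.integer(total_slots * slot + 2L * flank + 40L)
    ref_lengths <- c(chr1 = L)
    qn <- character(0); fl <- integer(0); po <- integer(0); cg <- character(0)
    uq <- 0L
    add_unique <- function(pos, len, times = 1L) {
      for (i in seq_len(times)) {
        uq <<- uq + 1L
        qn <<- c(qn, sprintf("u%05d", uq))
        fl <<- c(fl, 0L)
        po <<- c(po, as.integer(pos))
        cg <<- c(cg, paste0(len, "M"))
      }
    }
    slot_id <- 0L
    group_pos <- vector("list", n_groups)
    truth_pos <- integer(n_groups)
    for (g in seq_len(n_groups)) {
      k <- n_cands[g]
      dip_at <- sample.int(k, 1L)
      b <- sample(1:3, 1L)             # depth at the dip locus
      fps <- integer(k)
      for (ci in seq_len(k)) {
        S <- as.integer(20L + slot_id * slot)
        slot_id <- slot_id + 1L
        fp <- S + flank + 10L          # footprint start inside the slot
        fps[ci] <- fp
        if (ci == dip_at) {
          ## depth b everywhere in the slot except a 1-deep dip at the
          ## footprint
          if (b > 1L) add_unique(S, slot, times = b - 1L)
          add_unique(S, fp - S)
          add_unique(fp + read_length, slot - (fp - S) - read_length)
        } else {
          d <- b + sample(0:3, 1L)     # flat depth, never below b
          if (d > 0L) add_unique(S, slot, times = d)
        }
      }
      truth_pos[g] <- fps[dip_at]
      group_pos[[g]] <- sample(fps)    # candidate order: random permutation
    }
    for (g in seq_len(n_groups)) {
      ps <- group_pos[[g]]
      qn <- c(qn, rep(sprintf("m%05d", g), length(ps)))
      fl <- c(fl, c(0L, rep(SAM_FLAG_SECONDARY, length(ps) - 1L)))
      po <- c(po, ps)
      cg <- c(cg, rep(paste0(read_length, "M"), length(ps)))
    }
    records <- sam_tibble(qn, fl, "chr1", po, cg, ref_lengths = ref_lengths,
                          tags = "NM:i:0")
    list(records = records, flank = flank,
         truth = tibble(qname = sprintf("m%05d", seq_len(n_groups)),
                        optimal_pos = truth_pos))
  })
}

#' Brute-force optimal assignment by exhaustive enumeration
#'
#' Enumerates every combination of candidate selections of the ambiguous
#' reads and returns the one minimising the population variance of the
#' full reference coverage vector. Independent of the iterative resolver;
#' used as its oracle on small instances.
#'
#' @param records Alignment tibble (single reference).
#' @param max_configs Safety cap on the number of enumerated combinations.
#' @return List with `sel` (named integer vector: candidate index per
#'   ambiguous read, in input candidate order), `objective`, `unique`
#'   (was the minimiser unique?), `n_configs`, and `positions` (named
#'   vector of selected footprint starts).
#' @export
enumerate_optimum <- function(records, max_configs = 2e5) {
  mapped <- records[!records$unmapped & !records$supplementary, , drop = FALSE]
  refs <- unique(mapped$rname)
  if (length(refs) != 1L) abort("enumerate_optimum expects a single reference")
  L <- sam_ref_lengths(records)[[refs]]
  fps <- cigar_footprints(mapped$pos, mapped$cigar)
  by_name <- split(seq_len(nrow(mapped)), factor(mapped$qname, levels = unique(mapped$qname)))
  base <- numeric(L)
  idx_of <- function(r) {
    m <- fps[[r]]
    unlist(lapply(seq_len(nrow(m)), function(i) (m[i, 1L] + 1L):m[i, 2L]))
  }
  multi <- list()
  for (nm in names(by_name)) {
    rows <- by_name[[nm]]
    if (length(rows) == 1L) {
      ii <- idx_of(rows)
      base[ii] <- base[ii] + 1
    } else {
      multi[[nm]] <- lapply(rows, idx_of)
    }
  }
  if (length(multi) == 0L) {
    return(list(sel = integer(0), objective = coverage_variance(base),
                unique = TRUE, n_configs = 1L, positions = integer(0)))
  }
  sizes <- lengths(multi)
  n_configs <- prod(sizes)
  if (n_configs > max_configs) abort("too many combinations to enumerate")
  grid <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  best <- Inf; best_i <- NA_integer_; ties <- 0L
  objs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    v <- base
    for (j in seq_along(multi)) {
      ii <- multi[[j]][[grid[i, j]]]
      v[ii] <- v[ii] + 1
    }
    objs[i] <- coverage_variance(v)
  }
  best <- min(objs)
  best_i <- which.min(objs)
  ties <- sum(objs <= best * (1 + 1e-12) + 1e-15)
  sel <- as.integer(grid[best_i, ])
  names(sel) <- names(multi)
  pos <- vapply(seq_along(multi), function(j) {
    rows <- by_name[[names(multi)[j]]]
    mapped$pos[rows[sel[j]]]
  }, integer(1))
  names(pos) <- names(multi)
  list(sel = sel, objective = best, unique = ties == 1L,
       n_configs = nrow(grid), positions = pos)
}
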