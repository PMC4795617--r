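## SAM/BAM input and output.
##
## Records are held as a tibble, one row per alignment, with the eleven
## mandatory SAM fields parsed, optional tags kept verbatim in a single
## string column, and a few derived columns (strand, edit distance, flag
## bits) that the resolver needs. Positions are 0-based half-open
## internally; conversion to/from SAM's 1-based POS happens only here.

SAM_FLAG_PAIRED <- 1L
SAM_FLAG_PROPER <- 2L
SAM_FLAG_UNMAPPED <- 4L
SAM_FLAG_REVERSE <- 16L
SAM_FLAG_MATE1 <- 64L
SAM_FLAG_MATE2 <- 128L
SAM_FLAG_SECONDARY <- 256L
SAM_FLAG_SUPPLEMENTARY <- 2048L

#' Read a SAM or BAM file into an alignment tibble
#'
#' Parses the eleven mandatory fields, keeps all optional tags verbatim, and
#' derives the columns the resolver works with: `pos` (0-based leftmost
#' reference coordinate), `strand`, `nm` (edit distance from the `NM` tag,
#' `NA` when absent), `score` (alignment score from the `AS` tag), and
#' logical flag decompositions. BAM input is converted through
#' \pkg{Rsamtools}.
#'
#' @param path Path to a `.sam` (plain text) or `.bam` file.
#' @return A tibble with one row per record and the SAM header stored in
#'   `attr(x, "sam_header")`. Use [sam_header()] / [sam_ref_lengths()] to
#'   access it.
#' @seealso [write_sam()], [group_reads()]
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) abort(paste0("no such alignment file: ", path))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      abort("BAM input requires the Rsamtools package")
    }
    dest <- tempfile(fileext = ".sam")
    path <- Rsamtools::asSam(path, sub("\\.sam$", "", dest), overwrite = TRUE)
  }
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  if (length(header) == 0L || !any(startsWith(header, "@SQ"))) {
    abort("SAM header missing or truncated: no @SQ lines found")
  }
  if (any(is_hdr & c(FALSE, !is_hdr[-length(is_hdr)]))) {
    abort("SAM header lines found after the first record: truncated file?")
  }
  parse_sam_body(body, header)
}

parse_sam_body <- function(body, header) {
  n <- length(body)
  if (n == 0L) {
    rec <- tibble(
      qname = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      rnext = character(), pnext = integer(), tlen = integer(),
      seq = character(), qual = character(), tags = character(),
      nm = integer(), score = double(), strand = character(),
      unmapped = logical(), secondary = logical(), supplementary = logical(),
      paired = logical(), mate = integer()
    )
    return(new_covres_sam(rec, header))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    abort(sprintf("truncated SAM record at body line %d (fewer than 11 fields)",
                  which(nf < 11L)[1]))
  }
  core <- vapply(parts, function(p) p[1:11], character(11))
  tags <- vapply(parts, function(p) {
    if (length(p) > 11L) paste(p[-(1:11)], collapse = "\t") else ""
  }, character(1))
  flag <- as.integer(core[2L, ])
  rec <- tibble(
    qname = core[1L, ],
    flag = flag,
    rname = core[3L, ],
    pos = as.integer(core[4L, ]) - 1L,
    mapq = as.integer(core[5L, ]),
    cigar = core[6L, ],
    rnext = core[7L, ],
    pnext = as.integer(core[8L, ]),
    tlen = as.integer(core[9L, ]),
    seq = core[10L, ],
    qual = core[11L, ],
    tags = tags,
    nm = extract_int_tag(tags, "NM"),
    score = as.double(extract_int_tag(tags, "AS")),
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

new_covres_sam <- function(rec, header) {
  attr(rec, "sam_header") <- header
  class(rec) <- unique(c("covres_sam", class(rec)))
  rec
}

#' @rdname read_sam
#' @param x An alignment tibble as returned by [read_sam()].
#' @export
sam_header <- function(x) attr(x, "sam_header")

#' Reference sequence lengths from a SAM header
#'
#' @param x An alignment tibble or a character vector of header lines.
#' @return A named integer vector, one element per `@SQ` line.
#' @export
sam_ref_lengths <- function(x) {
  hdr <- if (is.character(x)) x else sam_header(x)
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0L) abort("header has no @SQ lines")
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  if (anyNA(ln)) abort("malformed @SQ line: missing LN field")
  setNames(ln, sn)
}

extract_int_tag <- function(tags, tag) {
  pat <- paste0("(?:^|\t)", tag, ":i:(-?[0-9]+)")
  m <- regexpr(pat, tags, perl = TRUE)
  out <- rep(NA_integer_, length(tags))
  hit <- m > 0L
  if (any(hit)) {
    txt <- regmatches(tags, m)  # only matching elements are returned
    out[hit] <- as.integer(sub(pat, "\\1", txt, perl = TRUE))
  }
  out
}

#' Group adjacent records by read name
#'
#' The resolver requires queryname-grouped input: all records that share a
#' read name must be adjacent (the order produced by
#' `samtools sort -n` / `samtools collate`). This assigns a `group_id`
#' column over mapped records and fails fast when the precondition is
#' violated, naming the offending read.
#'
#' @param records An alignment tibble from [read_sam()].
#' @return The same tibble with an integer `group_id` column (`NA` for
#'   unmapped records).
#' @export
group_reads <- function(records) {
  mapped <- which(!records$unmapped)
  gid <- rep(NA_integer_, nrow(records))
  if (length(mapped) > 0L) {
    qn <- records$qname[mapped]
    r <- rle(qn)
    dup <- r$values[duplicated(r$values)]
    if (length(dup) > 0L) {
      abort(paste0(
        "input is not grouped by read name: read '", dup[1],
        "' reappears after records of a different read; ",
        "sort the file with 'samtools sort -n' (or collate) first"
      ))
    }
    gid[mapped] <- rep.int(seq_along(r$lengths), r$lengths)
  }
  records$group_id <- gid
  records
}

#' Reference footprint of an alignment
#'
#' Computes, for each alignment, the maximal runs of reference positions
#' covered by the read: `M`, `=` and `X` operations consume and cover the
#' reference; `N` (intron skip) and `D` (deletion) consume reference without
#' read coverage and therefore split the footprint; `I`, `S`, `H` and `P`
#' consume no reference.
#'
#' @param pos Integer vector of 0-based leftmost reference positions.
#' @param cigar Character vector of CIGAR strings (same length as `pos`).
#' @return A list of integer matrices with columns `start`, `end`
#'   (0-based, half-open), rows sorted and disjoint.
#' @examples
#' cigar_footprints(100L, "20M1000N30M")[[1]]
#' @export
cigar_footprints <- function(pos, cigar) {
  stopifnot(length(pos) == length(cigar))
  n <- length(cigar)
  out <- vector("list", n)
  simple <- grepl("^[0-9]+M$", cigar)
  if (any(simple)) {
    len <- as.integer(sub("M", "", cigar[simple], fixed = TRUE))
    out[simple] <- Map(function(p, l) {
      cbind(start = p, end = p + l)
    }, pos[simple], len)
  }
  for (i in which(!simple)) {
    out[[i]] <- cigar_footprint_one(pos[i], cigar[i])
  }
  out
}

cigar_footprint_one <- function(pos0, cigar) {
  if (is.na(cigar) || cigar == "*") {
    abort("record without a CIGAR cannot enter loss evaluation")
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    abort(paste0("malformed CIGAR string: ", cigar))
  }
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  cur <- pos0
  starts <- integer(0)
  ends <- integer(0)
  open <- FALSE
  for (i in seq_along(ops)) {
    op <- ops[i]
    len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (!open) {
        starts <- c(starts, cur)
        ends <- c(ends, cur)
        open <- TRUE
      }
      cur <- cur + len
      ends[length(ends)] <- cur
    } else if (op %in% c("D", "N")) {
      cur <- cur + len
      open <- FALSE
    }
    # I, S, H, P: no reference consumption
  }
  if (length(starts) == 0L) {
    abort(paste0("CIGAR consumes no reference: ", cigar))
  }
  cbind(start = starts, end = ends)
}

#' Write an alignment tibble as SAM or BAM
#'
#' Re-emits records losslessly: the parsed mandatory fields plus the
#' verbatim tag string. BAM output is produced through \pkg{Rsamtools}.
#'
#' @param records An alignment tibble.
#' @param path Output path (`.sam` or `.bam`).
#' @param header Header lines; defaults to the header carried by `records`.
#' @return Invisibly, the number of records written.
#' @export
write_sam <- function(records, path, header = sam_header(records)) {
  if (is.null(header)) abort("no SAM header available for output")
  want_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  dest <- if (want_bam) tempfile(fileext = ".sam") else path
  lines <- character(0)
  if (nrow(records) > 0L) {
    lines <- paste(records$qname, records$flag, records$rname,
                   records$pos + 1L, records$mapq, records$cigar,
                   records$rnext, records$pnext, records$tlen,
                   records$seq, records$qual, sep = "\t")
    has_tags <- nzchar(records$tags)
    lines[has_tags] <- paste(lines[has_tags], records$tags[has_tags], sep = "\t")
  }
  con <- file(dest, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(header, lines), con)
  if (want_bam) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      abort("BAM output requires the Rsamtools package")
    }
    close(con)
    on.exit()
    Rsamtools::asBam(dest, sub("\\.bam$", "", path), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  invisible(nrow(records))
}

#' Emit the selected candidate of every read group
#'
#' Writes exactly one alignment per read (both mates for paired
#' candidates): the secondary flag is cleared on promoted records, pairs
#' resolved through the single-end fallback lose their proper-pair flag,
#' and a `@PG` line documenting the run is appended to the header.
#'
#' @param records Grouped alignment tibble ([group_reads()]).
#' @param rows Integer row indices of the selected records.
#' @param path Output path, or `NULL` to return the records invisibly.
#' @param improper_rows Rows whose proper-pair flag must be cleared.
#' @param keep_unmapped Pass unmapped records through unchanged.
#' @param pg_extra Extra text for the `@PG` command-line field.
#' @return Invisibly, the emitted tibble.
#' @export
write_selected <- function(records, rows, path = NULL, improper_rows = integer(0),
                           keep_unmapped = TRUE, pg_extra = "") {
  out_rows <- sort(rows)
  flags <- records$flag
  flags[rows] <- bitwAnd(flags[rows], bitwNot(SAM_FLAG_SECONDARY))
  if (length(improper_rows) > 0L) {
    flags[improper_rows] <- bitwAnd(flags[improper_rows], bitwNot(SAM_FLAG_PROPER))
  }
  if (keep_unmapped) {
    out_rows <- sort(c(out_rows, which(records$unmapped)))
  }
  out <- records[out_rows, , drop = FALSE]
  out$flag <- flags[out_rows]
  out$secondary <- bitwAnd(out$flag, SAM_FLAG_SECONDARY) > 0L
  header <- sam_header(records)
  pg <- paste0("@PG\tID:covres\tPN:covres\tVN:",
               as.character(utils::packageVersion("covres")),
               "\tCL:covres ", pg_extra)
  out <- new_covres_sam(out, c(header, pg))
  if (!is.null(path)) write_sam(out, path)
  invisible(out)
}
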