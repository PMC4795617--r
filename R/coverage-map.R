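## Global coverage map.
##
## One dense integer vector per reference sequence, allocated lazily on
## first touch, holding the pileup of all currently selected alignments
## plus all uniquely mapped reads. The resolver updates it incrementally
## as selections change; tests rebuild it from scratch and compare.

#' Create an empty coverage map
#'
#' @param ref_lengths Named integer vector of reference lengths, as from
#'   [sam_ref_lengths()].
#' @return A `coverage_map` object (environment-backed, updated by
#'   reference).
#' @export
coverage_map <- function(ref_lengths) {
  if (is.null(names(ref_lengths)) || any(!nzchar(names(ref_lengths)))) {
    abort("ref_lengths must be a named vector")
  }
  e <- new.env(parent = emptyenv())
  e$.placed <- 0L
  structure(list(env = e, ref_lengths = ref_lengths), class = "coverage_map")
}

ref_len_of <- function(map, ref) {
  len <- unname(map$ref_lengths[ref])
  if (length(len) != 1L || is.na(len)) {
    abort(paste0("unknown reference: ", ref))
  }
  len
}

cov_vec <- function(map, ref) {
  v <- map$env[[ref]]
  if (is.null(v)) v <- integer(ref_len_of(map, ref))
  v
}

check_fp <- function(map, ref, fp) {
  len <- ref_len_of(map, ref)
  if (any(fp[, 1L] < 0L) || any(fp[, 2L] > len)) {
    abort(sprintf("footprint [%d,%d) outside reference %s of length %d",
                  min(fp[, 1L]), max(fp[, 2L]), ref, len))
  }
  if (any(fp[, 2L] <= fp[, 1L])) abort("empty footprint interval")
}

#' Add or remove an alignment footprint
#'
#' Each reference position covered by the footprint is incremented
#' (decremented) by exactly one. `cov_add` followed by `cov_remove` of the
#' same footprint restores the map bit-exactly; decrementing a cell below
#' zero signals a bookkeeping bug and is an error.
#'
#' @param map A [coverage_map()].
#' @param ref Reference name.
#' @param fp Footprint matrix (`start`,`end` columns, 0-based half-open),
#'   as from [cigar_footprints()].
#' @return The map, invisibly.
#' @export
cov_add <- function(map, ref, fp) {
  check_fp(map, ref, fp)
  v <- cov_vec(map, ref)
  for (i in seq_len(nrow(fp))) {
    idx <- (fp[i, 1L] + 1L):fp[i, 2L]
    v[idx] <- v[idx] + 1L
  }
  map$env[[ref]] <- v
  map$env$.placed <- map$env$.placed + 1L
  invisible(map)
}

#' @rdname cov_add
#' @export
cov_remove <- function(map, ref, fp) {
  check_fp(map, ref, fp)
  v <- cov_vec(map, ref)
  for (i in seq_len(nrow(fp))) {
    idx <- (fp[i, 1L] + 1L):fp[i, 2L]
    v[idx] <- v[idx] - 1L
    if (any(v[idx] < 0L)) {
      abort("coverage underflow: removing a footprint that was never added")
    }
  }
  map$env[[ref]] <- v
  map$env$.placed <- map$env$.placed - 1L
  invisible(map)
}

#' Coverage values over an interval
#'
#' @param map A [coverage_map()].
#' @param ref Reference name.
#' @param start,end 0-based half-open interval bounds.
#' @return Integer vector of length `end - start`.
#' @export
cov_values <- function(map, ref, start, end) {
  len <- ref_len_of(map, ref)
  if (start < 0L || end > len || end <= start) {
    abort(sprintf("bad interval [%d,%d) on %s (length %d)", start, end, ref, len))
  }
  v <- map$env[[ref]]
  if (is.null(v)) return(integer(end - start))
  v[(start + 1L):end]
}

#' Number of footprints currently placed
#' @param map A [coverage_map()].
#' @export
cov_placed <- function(map) map$env$.placed

#' Snapshot of the full map state (for tests and debugging)
#' @param map A [coverage_map()].
#' @return Named list of integer vectors, one per touched reference.
#' @export
cov_state <- function(map) {
  refs <- setdiff(ls(map$env), ".placed")
  setNames(lapply(refs, function(r) map$env[[r]]), refs)
}

#' Bulk-build coverage from footprint intervals
#'
#' Vectorised construction used at initialization: all selected footprints
#' are piled up per reference with a cumulative-sum sweep.
#'
#' @param map A [coverage_map()].
#' @param ref Character vector of reference names, one per interval.
#' @param start,end Integer vectors of interval bounds (0-based half-open).
#' @param n_footprints Number of footprints these intervals represent
#'   (footprints may contribute several intervals).
#' @return The map, invisibly.
#' @export
cov_bulk_add <- function(map, ref, start, end, n_footprints) {
  stopifnot(length(ref) == length(start), length(start) == length(end))
  for (r in unique(ref)) {
    len <- ref_len_of(map, r)
    sel <- ref == r
    s <- start[sel]; e <- end[sel]
    if (any(s < 0L) || any(e > len) || any(e <= s)) {
      abort(paste0("footprint outside reference ", r))
    }
    d <- integer(len + 1L)
    ts <- tabulate(s + 1L, nbins = len + 1L)
    te <- tabulate(e + 1L, nbins = len + 1L)
    v <- cumsum(ts - te)[seq_len(len)]
    old <- map$env[[r]]
    map$env[[r]] <- if (is.null(old)) as.integer(v) else old + as.integer(v)
  }
  map$env$.placed <- map$env$.placed + as.integer(n_footprints)
  invisible(map)
}

#' Run-length encoded coverage (bedGraph-style)
#'
#' @param map A [coverage_map()].
#' @param keep_zero Keep zero-depth runs.
#' @return A tibble with columns `ref`, `start`, `end`, `depth`.
#' @export
cov_as_bedgraph <- function(map, keep_zero = FALSE) {
  refs <- setdiff(ls(map$env), ".placed")
  rows <- lapply(refs, function(r) {
    v <- map$env[[r]]
    rl <- rle(v)
    e <- cumsum(rl$lengths)
    s <- c(0L, e[-length(e)])
    tibble(ref = r, start = s, end = e, depth = rl$values)
  })
  out <- dplyr::bind_rows(rows)
  if (!keep_zero && nrow(out) > 0L) out <- out[out$depth != 0L, , drop = FALSE]
  out
}

#' @export
print.coverage_map <- function(x, ...) {
  refs <- setdiff(ls(x$env), ".placed")
  cat("<coverage_map> ", length(x$ref_lengths), " reference(s), ",
      length(refs), " touched, ", x$env$.placed, " footprints placed\n", sep = "")
  invisible(x)
}
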