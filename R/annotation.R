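## Exon breakpoint index for RNA-seq window trimming.
##
## Annotated exons imply genomic breakpoints (their start and end
## coordinates). Windows used for the variance loss are trimmed so that no
## window interval crosses a breakpoint: coverage on the two sides of an
## exon boundary comes from different transcript contexts and should not
## be pooled into one variance.

#' Build a breakpoint index from a GTF/GFF3 annotation
#'
#' Every `exon` feature contributes its start and end (converted to
#' 0-based half-open coordinates, so an exon `chr1:1001..1200` in 1-based
#' inclusive GTF coordinates yields breakpoints 1000 and 1200).
#' Breakpoints are deduplicated and sorted per reference. Parsing goes
#' through \pkg{rtracklayer}, so both GTF and GFF3 are accepted.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return A `breakpoint_index`: named list of sorted integer vectors.
#' @export
read_breakpoints <- function(path) {
  if (!file.exists(path)) abort(paste0("no such annotation file: ", path))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("annotation parsing requires the rtracklayer package")
  }
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) abort(paste0("cannot parse annotation ",
                                                  path, ": ", conditionMessage(e))))
  df <- as.data.frame(gr)
  if (!"type" %in% names(df)) abort("annotation has no feature type column")
  ex <- df[tolower(as.character(df$type)) == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) abort("no exon features found in annotation")
  breakpoint_index(
    ref = as.character(ex$seqnames),
    start = as.integer(ex$start) - 1L,  # GTF 1-based inclusive -> 0-based
    end = as.integer(ex$end)
  )
}

#' Construct a breakpoint index from exon coordinates
#'
#' @param ref Character vector of reference names, one per exon.
#' @param start,end Exon bounds, 0-based half-open.
#' @return A `breakpoint_index` object.
#' @export
breakpoint_index <- function(ref, start, end) {
  stopifnot(length(ref) == length(start), length(start) == length(end))
  idx <- lapply(split(c(start, end), c(ref, ref)), function(x) sort(unique(as.integer(x))))
  structure(idx, class = "breakpoint_index")
}

breakpoints_for <- function(breakpoints, ref) {
  if (is.null(breakpoints)) return(NULL)
  breakpoints[[ref]]
}

#' @export
print.breakpoint_index <- function(x, ...) {
  cat("<breakpoint_index> ", length(x), " reference(s), ",
      sum(lengths(x)), " breakpoints\n", sep = "")
  invisible(x)
}

#' Trim a window interval at the nearest exon breakpoints
#'
#' The left edge is raised to the largest breakpoint in `(start, fs]` and
#' the right edge lowered to the smallest breakpoint in `[fe, end)`, where
#' `[fs, fe)` is the footprint interval the window extends. The footprint
#' interval itself is never trimmed away; if it spans a breakpoint (a read
#' crossing an annotated boundary unspliced) the interval is returned
#' unchanged.
#'
#' @param interval Length-2 integer vector `[start, end)`.
#' @param fp_interval Length-2 integer vector, the footprint interval.
#' @param breakpoints Sorted integer vector of breakpoints on this
#'   reference.
#' @return Length-2 integer vector, `interval` trimmed.
#' @examples
#' trim_window(c(80L, 170L), c(100L, 150L), c(90L, 160L))
#' @export
trim_window <- function(interval, fp_interval, breakpoints) {
  if (is.null(breakpoints) || length(breakpoints) == 0L) return(interval)
  s <- interval[1L]; e <- interval[2L]
  fs <- fp_interval[1L]; fe <- fp_interval[2L]
  if (any(breakpoints > fs & breakpoints < fe)) {
    return(interval)  # footprint spans a breakpoint: leave untrimmed
  }
  left <- breakpoints[breakpoints > s & breakpoints <= fs]
  if (length(left) > 0L) s <- max(left)
  right <- breakpoints[breakpoints >= fe & breakpoints < e]
  if (length(right) > 0L) e <- min(right)
  c(s, e)
}
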