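## Windows and the coverage-variance loss.
##
## The loss of an alignment is the empirical (population) variance of the
## coverage within a window around it: each footprint interval is extended
## by a flank on both sides, clipped at the reference ends, optionally
## trimmed at annotated exon breakpoints, and intronic gaps are never part
## of the window. A candidate's loss pools all window positions into one
## variance computation (a per-interval sum is available as an option).

#' Merge sorted/unsorted intervals
#'
#' Overlapping or touching `[start, end)` intervals are merged.
#' @param m Integer matrix with two columns.
#' @return Matrix with columns `start`, `end`, rows sorted and disjoint.
#' @keywords internal
merge_intervals <- function(m) {
  if (nrow(m) <= 1L) {
    colnames(m) <- c("start", "end")
    return(m)
  }
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  s <- m[, 1L]; e <- m[, 2L]
  out_s <- s[1L]; out_e <- e[1L]
  for (i in 2L:nrow(m)) {
    if (s[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], e[i])
    } else {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
    }
  }
  cbind(start = out_s, end = out_e)
}

subtract_intervals <- function(m, gaps) {
  if (nrow(gaps) == 0L || nrow(m) == 0L) return(m)
  out <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(nrow(m))) {
    pieces <- cbind(m[i, 1L], m[i, 2L])
    for (j in seq_len(nrow(gaps))) {
      nxt <- matrix(integer(0), ncol = 2L)
      for (k in seq_len(nrow(pieces))) {
        a <- pieces[k, 1L]; b <- pieces[k, 2L]
        gs <- gaps[j, 1L]; ge <- gaps[j, 2L]
        if (ge <= a || gs >= b) {
          nxt <- rbind(nxt, c(a, b))
        } else {
          if (gs > a) nxt <- rbind(nxt, c(a, gs))
          if (ge < b) nxt <- rbind(nxt, c(ge, b))
        }
      }
      pieces <- nxt
    }
    out <- rbind(out, pieces)
  }
  colnames(out) <- c("start", "end")
  out
}

#' Evaluation window around a footprint
#'
#' Each footprint interval is extended by `flank` on both sides and clipped
#' at the reference ends; extensions that touch are merged. Intronic gaps
#' (between split footprint intervals) are never included. When a
#' breakpoint index is given, each flank is trimmed at the nearest
#' annotated exon breakpoint so that no window interval crosses one; a
#' footprint interval that itself spans a breakpoint is left untrimmed.
#'
#' @param fp Footprint matrix from [cigar_footprints()].
#' @param flank Window flank in bp (>= 0).
#' @param ref_length Length of the reference sequence.
#' @param breakpoints Optional sorted integer vector of breakpoints on this
#'   reference (see [read_breakpoints()]).
#' @return Interval matrix (columns `start`, `end`), sorted, disjoint,
#'   total length >= 1.
#' @examples
#' make_window(cbind(start = 100L, end = 150L), 20L, 1000L)
#' @export
make_window <- function(fp, flank, ref_length, breakpoints = NULL) {
  stopifnot(flank >= 0L)
  n <- nrow(fp)
  ext <- cbind(pmax(0L, fp[, 1L] - as.integer(flank)),
               pmin(as.integer(ref_length), fp[, 2L] + as.integer(flank)))
  if (!is.null(breakpoints) && length(breakpoints) > 0L) {
    for (i in seq_len(n)) {
      ext[i, ] <- trim_window(ext[i, ], fp[i, ], breakpoints)
    }
  }
  win <- merge_intervals(ext)
  if (n > 1L) {
    gaps <- cbind(fp[-n, 2L], fp[-1L, 1L])
    gaps <- gaps[gaps[, 2L] > gaps[, 1L], , drop = FALSE]
    win <- subtract_intervals(win, gaps)
  }
  win
}

#' Empirical variance of a coverage slice
#'
#' Population variance: `sum((x - mean(x))^2) / length(x)` over all
#' positions of the window pooled together.
#'
#' @param values Numeric vector of per-base coverage values (non-empty).
#' @export
coverage_variance <- function(values) {
  if (length(values) == 0L) abort("empty window: variance undefined")
  m <- mean(values)
  mean((values - m)^2)
}

## ---- candidates ------------------------------------------------------

#' Build a candidate placement object
#'
#' A candidate is one possible placement of a read (one alignment) or of a
#' read pair (two mate alignments). Its coverage footprint is the union of
#' the mates' footprints (overlap counted once); its loss windows are kept
#' per mate.
#'
#' @param ref Reference name (a feasible pair is always on one reference).
#' @param mates List of footprint matrices, one per mate (length 1 for
#'   single-end).
#' @param rows Optional record row indices carried along for bookkeeping.
#' @param nm Optional edit distance (pair: sum of mates).
#' @param score Optional alignment score (pair: sum of mates).
#' @return A `covres_candidate` list.
#' @export
candidate <- function(ref, mates, rows = integer(0), nm = NA_integer_,
                      score = NA_real_) {
  fp <- merge_intervals(do.call(rbind, mates))
  structure(list(ref = ref, mates = mates, fp = fp, rows = rows,
                 nm = nm, score = score),
            class = "covres_candidate")
}

candidate_windows <- function(cand, flank, ref_length, breakpoints = NULL) {
  lapply(cand$mates, make_window, flank = flank, ref_length = ref_length,
         breakpoints = breakpoints)
}

## values over a set of intervals, concatenated in interval order
region_values <- function(map, ref, region) {
  vals <- vector("list", nrow(region))
  for (i in seq_len(nrow(region))) {
    vals[[i]] <- cov_values(map, ref, region[i, 1L], region[i, 2L])
  }
  as.double(unlist(vals, use.names = FALSE))
}

## indices (into the concatenated region values) covered by footprint fp
region_fp_index <- function(region, fp) {
  widths <- region[, 2L] - region[, 1L]
  offs <- cumsum(c(0L, widths[-length(widths)]))
  idx <- integer(0)
  for (i in seq_len(nrow(region))) {
    for (j in seq_len(nrow(fp))) {
      a <- max(region[i, 1L], fp[j, 1L])
      b <- min(region[i, 2L], fp[j, 2L])
      if (b > a) {
        idx <- c(idx, (offs[i] + (a - region[i, 1L]) + 1L):(offs[i] + (b - region[i, 1L])))
      }
    }
  }
  idx
}

loss_candidate <- function(map, cand, flank, breakpoints = NULL,
                           present, placed, per_interval = FALSE) {
  ref_len <- ref_len_of(map, cand$ref)
  bps <- breakpoints_for(breakpoints, cand$ref)
  wins <- candidate_windows(cand, flank, ref_len, bps)
  delta <- if (present && !placed) 1L else if (!present && placed) -1L else 0L
  total <- 0
  for (w in wins) {
    if (per_interval) {
      for (i in seq_len(nrow(w))) {
        wi <- w[i, , drop = FALSE]
        vals <- region_values(map, cand$ref, wi)
        if (delta != 0L) {
          idx <- region_fp_index(wi, cand$fp)
          vals[idx] <- vals[idx] + delta
        }
        total <- total + coverage_variance(vals)
      }
    } else {
      vals <- region_values(map, cand$ref, w)
      if (delta != 0L) {
        idx <- region_fp_index(w, cand$fp)
        vals[idx] <- vals[idx] + delta
      }
      total <- total + coverage_variance(vals)
    }
  }
  total
}

#' Loss of placing or removing a candidate
#'
#' `loss_with()` is the coverage variance over the candidate's window as if
#' its footprint were present; `loss_without()` as if it were absent. For a
#' paired candidate the two mates' window variances are summed. Neither
#' call mutates the map: the footprint is offset on a temporary copy of the
#' window values only.
#'
#' @param map A [coverage_map()] reflecting the current selections.
#' @param cand A [candidate()].
#' @param flank Window flank in bp.
#' @param breakpoints Optional breakpoint index ([read_breakpoints()]).
#' @param placed Is the candidate's footprint currently contained in the
#'   map (i.e. is it the selected placement of its group)?
#' @param per_interval Compute a per-interval variance sum instead of
#'   pooling a spliced window's intervals.
#' @return The loss (non-negative number).
#' @export
loss_with <- function(map, cand, flank = 20L, breakpoints = NULL,
                      placed = FALSE, per_interval = FALSE) {
  loss_candidate(map, cand, flank, breakpoints, present = TRUE,
                 placed = placed, per_interval = per_interval)
}

#' @rdname loss_with
#' @export
loss_without <- function(map, cand, flank = 20L, breakpoints = NULL,
                         placed = FALSE, per_interval = FALSE) {
  loss_candidate(map, cand, flank, breakpoints, present = FALSE,
                 placed = placed, per_interval = per_interval)
}

## ---- swap rule -------------------------------------------------------

#' Should the current placement be swapped for an alternative?
#'
#' Implements the four-term comparison: the swap is accepted iff
#' `loss_without(current) + loss_with(alt) < loss_with(current) +
#' loss_without(alt)`, strictly (ties keep the incumbent). In the default
#' `"joint"` mode each loss is evaluated as pooled variance over the union
#' of both candidates' windows, with the alternative's terms taken in the
#' context of the current read removed; the four-term rule then reduces to
#' accepting the swap exactly when the pooled variance of the union region
#' would decrease, so a systematic coverage excess at one location relative
#' to the other is visible to the decision and every accepted swap strictly
#' lowers the local restriction of the global objective. In `"independent"`
#' mode each candidate is evaluated over its own window only (that form is
#' blind to level differences between the two windows). The map is never
#' mutated.
#'
#' @param map A [coverage_map()]; must reflect `current` being placed and
#'   `alt` not.
#' @param current,alt [candidate()] objects of the same read group.
#' @param flank Window flank in bp.
#' @param breakpoints Optional breakpoint index.
#' @param loss_mode `"joint"` (default) or `"independent"`.
#' @param per_interval Per-interval spliced-window variance (see
#'   [loss_with()]).
#' @return `TRUE` to swap, `FALSE` to keep the incumbent.
#' @export
evaluate_swap <- function(map, current, alt, flank = 20L, breakpoints = NULL,
                          loss_mode = c("joint", "independent"),
                          per_interval = FALSE) {
  loss_mode <- match.arg(loss_mode)
  if (loss_mode == "independent") {
    lhs <- loss_without(map, current, flank, breakpoints, placed = TRUE,
                        per_interval = per_interval) +
      loss_with(map, alt, flank, breakpoints, placed = FALSE,
                per_interval = per_interval)
    rhs <- loss_with(map, current, flank, breakpoints, placed = TRUE,
                     per_interval = per_interval) +
      loss_without(map, alt, flank, breakpoints, placed = FALSE,
                   per_interval = per_interval)
    return(swap_strictly_better(lhs, rhs))
  }
  cmp <- swap_terms(map, current, alt, flank, breakpoints)
  swap_strictly_better(cmp$lhs, cmp$rhs)
}

## Joint evaluation: pooled variance over the union of both windows.
## lhs is the variance of the region after the swap (current removed, alt
## placed), rhs the variance of the region as it stands; footprints lie
## inside the windows, so the swap changes nothing outside the region.
swap_terms <- function(map, current, alt, flank, breakpoints) {
  refs <- unique(c(current$ref, alt$ref))
  vals <- list(); cur_idx <- list(); alt_idx <- list()
  off <- 0L
  for (r in refs) {
    ref_len <- ref_len_of(map, r)
    bps <- breakpoints_for(breakpoints, r)
    wins <- matrix(integer(0), ncol = 2L)
    if (current$ref == r) {
      wins <- rbind(wins, do.call(rbind, candidate_windows(current, flank, ref_len, bps)))
    }
    if (alt$ref == r) {
      wins <- rbind(wins, do.call(rbind, candidate_windows(alt, flank, ref_len, bps)))
    }
    region <- merge_intervals(wins)
    v <- region_values(map, r, region)
    if (current$ref == r) {
      cur_idx[[r]] <- region_fp_index(region, current$fp) + off
    }
    if (alt$ref == r) {
      alt_idx[[r]] <- region_fp_index(region, alt$fp) + off
    }
    vals[[r]] <- v
    off <- off + length(v)
  }
  base <- unlist(vals, use.names = FALSE)
  ci <- unlist(cur_idx, use.names = FALSE)
  ai <- unlist(alt_idx, use.names = FALSE)
  after <- base
  after[ci] <- after[ci] - 1
  after[ai] <- after[ai] + 1
  list(lhs = coverage_variance(after), rhs = coverage_variance(base))
}

## strict comparison with a tiny relative tolerance so that exact ties
## (equal-loss placements) deterministically keep the incumbent
swap_strictly_better <- function(lhs, rhs) {
  lhs < rhs - 1e-12 * max(1, abs(rhs))
}
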