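## The iterative resolver: candidate filtering, pairing, initialization
## and the swap sweeps.

#' Resolver configuration
#'
#' @param window_flank Window flank in bp around each footprint interval
#'   over which the variance loss is evaluated (default 20).
#' @param iterations Maximum number of sweeps over the file (default 3;
#'   sweeps stop early when one makes no change).
#' @param edit_delta Edit-distance filter: keep only candidates whose `NM`
#'   is at most `min(NM) + edit_delta` within the group. `NULL` disables
#'   the filter.
#' @param init Initial selection policy: `"best"` (best alignment score,
#'   ties broken by input order), `"order"` (first candidate in input
#'   order) or `"random"` (uniform, seeded).
#' @param seed Seed for all randomness (random init).
#' @param paired Resolve read pairs jointly (proper-pair enumeration).
#' @param max_pair_dist Maximum distance between the outermost footprint
#'   ends of a feasible pair (default 400000, spanning long introns).
#' @param annotation Optional GTF/GFF3 path or [breakpoint_index()] used to
#'   trim loss windows at annotated exon boundaries.
#' @param keep_unmapped Pass unmapped records through to the output.
#' @param loss_mode `"joint"` (pooled variance over the union of the two
#'   compared windows; default) or `"independent"` (each candidate scored
#'   in its own window only). See [evaluate_swap()].
#' @param per_interval Spliced windows: sum per-interval variances instead
#'   of pooling (default pooled).
#' @param max_candidates Guard against candidate explosion: groups with
#'   more candidates keep only this many, best edit distance first.
#' @param audit Record the four-term comparison of every accepted swap
#'   (used by invariant tests).
#' @return A `resolver_config` list.
#' @export
resolver_config <- function(window_flank = 20L, iterations = 3L,
                            edit_delta = NULL,
                            init = c("best", "order", "random"),
                            seed = 42L, paired = FALSE,
                            max_pair_dist = 400000L, annotation = NULL,
                            keep_unmapped = TRUE,
                            loss_mode = c("joint", "independent"),
                            per_interval = FALSE,
                            max_candidates = 1000L, audit = FALSE) {
  init <- match.arg(init)
  loss_mode <- match.arg(loss_mode)
  if (iterations < 1L) abort("iterations must be >= 1")
  if (window_flank < 0L) abort("window_flank must be >= 0")
  if (paired && max_pair_dist <= 0L) abort("max_pair_dist must be > 0")
  if (!is.null(edit_delta) && edit_delta < 0L) abort("edit_delta must be >= 0")
  structure(list(window_flank = as.integer(window_flank),
                 iterations = as.integer(iterations),
                 edit_delta = edit_delta, init = init,
                 seed = as.integer(seed), paired = paired,
                 max_pair_dist = as.integer(max_pair_dist),
                 annotation = annotation, keep_unmapped = keep_unmapped,
                 loss_mode = loss_mode, per_interval = per_interval,
                 max_candidates = as.integer(max_candidates), audit = audit),
            class = "resolver_config")
}

#' Filter candidates by excess edit distance
#'
#' Keeps the alignments whose edit distance is within `delta` of the best
#' (smallest) edit distance in the group; with `delta = 0` only alignments
#' with as few edit operations as the best mapping remain. Order is
#' preserved and the result is never empty.
#'
#' @param group A tibble of candidate records with an `nm` column (one
#'   read group), or any data frame slice thereof.
#' @param delta Non-negative integer slack.
#' @return The filtered tibble.
#' @export
filter_by_edit_delta <- function(group, delta) {
  stopifnot(delta >= 0L)
  nm <- group$nm
  if (anyNA(nm)) abort("all candidates need an edit distance (NM) for filtering")
  group[nm <= min(nm) + delta, , drop = FALSE]
}

#' Enumerate feasible mate pairs
#'
#' A pair of mate alignments is feasible iff both are on the same
#' reference, in forward--reverse orientation (the leftmost mate on the
#' plus strand), and the distance between the outermost footprint ends is
#' at most `max_pair_dist`.
#'
#' @param mate0,mate1 Tibbles of candidate records for the first and
#'   second mate (columns `rname`, `pos`, `strand`, `cigar`).
#' @param max_pair_dist Maximum outer distance in bp.
#' @return A tibble with columns `i0`, `i1`: row indices into `mate0` and
#'   `mate1`, ordered by `i0` then `i1`.
#' @export
enumerate_pairs <- function(mate0, mate1, max_pair_dist = 400000L) {
  if (nrow(mate0) == 0L || nrow(mate1) == 0L) {
    return(tibble(i0 = integer(0), i1 = integer(0)))
  }
  end0 <- ref_span_end(mate0)
  end1 <- ref_span_end(mate1)
  g <- expand.grid(i1 = seq_len(nrow(mate1)), i0 = seq_len(nrow(mate0)))
  i0 <- g$i0; i1 <- g$i1
  same_ref <- mate0$rname[i0] == mate1$rname[i1]
  s0 <- mate0$strand[i0]; s1 <- mate1$strand[i1]
  opposite <- s0 != s1
  plus_pos <- ifelse(s0 == "+", mate0$pos[i0], mate1$pos[i1])
  minus_pos <- ifelse(s0 == "+", mate1$pos[i1], mate0$pos[i0])
  fr <- opposite & plus_pos <= minus_pos
  outer <- pmax(end0[i0], end1[i1]) - pmin(mate0$pos[i0], mate1$pos[i1])
  ok <- same_ref & fr & outer <= max_pair_dist
  out <- tibble(i0 = i0[ok], i1 = i1[ok])
  out[order(out$i0, out$i1), , drop = FALSE]
}

ref_span_end <- function(records) {
  fps <- cigar_footprints(records$pos, records$cigar)
  vapply(fps, function(m) m[nrow(m), 2L], integer(1))
}

## ---- group construction ---------------------------------------------

nm_or_fallback <- function(nm, cigar, state) {
  if (!is.na(nm)) return(nm)
  if (grepl("[=X]", cigar)) {
    toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    ops <- sub("^[0-9]+", "", toks)
    return(sum(lens[ops %in% c("X", "I", "D")]))
  }
  if (!state$warned_nm) {
    warn("NM tag absent and CIGAR uses M: treating edit distance as 0")
    state$warned_nm <- TRUE
  }
  0L
}

## Build the per-group candidate structures the sweeps operate on.
build_groups <- function(records, cfg) {
  if (!"group_id" %in% names(records)) records <- group_reads(records)
  state <- new.env(parent = emptyenv())
  state$warned_nm <- FALSE
  usable <- !records$unmapped & !records$supplementary
  n_supp <- sum(!records$unmapped & records$supplementary)
  fps <- vector("list", nrow(records))
  fps[usable] <- cigar_footprints(records$pos[usable], records$cigar[usable])
  nms <- records$nm
  need_nm <- usable & is.na(nms)
  for (i in which(need_nm)) {
    nms[i] <- nm_or_fallback(NA_integer_, records$cigar[i], state)
  }
  groups <- list()
  pair_fallbacks <- 0L
  gids <- records$group_id[usable]
  rows_by_gid <- split(which(usable), gids)
  ## split() orders by factor level; restore input (first-appearance) order
  rows_by_gid <- rows_by_gid[order(vapply(rows_by_gid, min, integer(1)))]
  mk_cand_se <- function(r) {
    candidate(ref = records$rname[r], mates = list(fps[[r]]), rows = r,
              nm = nms[r], score = records$score[r])
  }
  for (rows in rows_by_gid) {
    qn <- records$qname[rows[1]]
    if (cfg$paired && any(records$paired[rows])) {
      r0 <- rows[!is.na(records$mate[rows]) & records$mate[rows] == 0L]
      r1 <- rows[!is.na(records$mate[rows]) & records$mate[rows] == 1L]
      pairs <- enumerate_pairs(records[r0, , drop = FALSE],
                               records[r1, , drop = FALSE],
                               cfg$max_pair_dist)
      if (nrow(pairs) > 0L) {
        cands <- purrr::map2(pairs$i0, pairs$i1, function(a, b) {
          ra <- r0[a]; rb <- r1[b]
          candidate(ref = records$rname[ra],
                    mates = list(fps[[ra]], fps[[rb]]),
                    rows = c(ra, rb),
                    nm = nms[ra] + nms[rb],
                    score = records$score[ra] + records$score[rb])
        })
        groups[[length(groups) + 1L]] <- list(qname = qn, cands = cands,
                                              improper = FALSE)
        next
      }
      ## no feasible pair: fall back to independent single-end groups
      pair_fallbacks <- pair_fallbacks + 1L
      for (side in list(r0, r1)) {
        if (length(side) == 0L) next
        groups[[length(groups) + 1L]] <-
          list(qname = qn, cands = lapply(side, mk_cand_se), improper = TRUE)
      }
    } else {
      groups[[length(groups) + 1L]] <-
        list(qname = qn, cands = lapply(rows, mk_cand_se), improper = FALSE)
    }
  }
  ## edit-distance filter and explosion guard
  capped <- 0L
  for (i in seq_along(groups)) {
    cands <- groups[[i]]$cands
    if (!is.null(cfg$edit_delta) && length(cands) > 1L) {
      nm <- vapply(cands, function(c) as.integer(c$nm), integer(1))
      keep <- nm <= min(nm) + cfg$edit_delta
      cands <- cands[keep]
    }
    if (length(cands) > cfg$max_candidates) {
      capped <- capped + 1L
      nm <- vapply(cands, function(c) as.integer(c$nm), integer(1))
      cands <- cands[order(nm)[seq_len(cfg$max_candidates)]]
    }
    groups[[i]]$cands <- cands
  }
  list(groups = groups, supplementary_dropped = n_supp,
       pair_fallbacks = pair_fallbacks, capped_groups = capped)
}

## ---- initialization --------------------------------------------------

#' Initial candidate selection and coverage map
#'
#' Selects one candidate per group according to the configured policy and
#' builds the global coverage map as the pileup of all selected footprints
#' (uniquely mapping reads are single-candidate groups and are always
#' included).
#'
#' @param groups Group list from the internal builder.
#' @param cfg A [resolver_config()].
#' @param ref_lengths Named reference lengths.
#' @return List with `sel` (integer selections) and `map`
#'   ([coverage_map()]).
#' @keywords internal
initialize_selections <- function(groups, cfg, ref_lengths) {
  n <- length(groups)
  sel <- rep(1L, n)
  if (cfg$init == "best") {
    any_missing <- FALSE
    for (i in seq_len(n)) {
      sc <- vapply(groups[[i]]$cands, function(c) as.double(c$score), double(1))
      if (all(is.na(sc))) {
        any_missing <- any_missing || length(sc) > 1L
      } else {
        sel[i] <- which.max(ifelse(is.na(sc), -Inf, sc))
      }
    }
    if (any_missing) {
      warn("no alignment score (AS) on some multi-candidate groups: using input order there")
    }
  } else if (cfg$init == "random") {
    withr::with_seed(cfg$seed, {
      for (i in seq_len(n)) {
        k <- length(groups[[i]]$cands)
        if (k > 1L) sel[i] <- sample.int(k, 1L)
      }
    })
  }
  map <- coverage_map(ref_lengths)
  refs <- character(0); ss <- integer(0); ee <- integer(0)
  per_ref_s <- list(); per_ref_e <- list()
  all_ref <- character(n); fplist <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- groups[[i]]$cands[[sel[i]]]
    all_ref[i] <- cand$ref
    fplist[[i]] <- cand$fp
  }
  nint <- vapply(fplist, nrow, integer(1))
  ref_col <- rep(all_ref, nint)
  fp_all <- do.call(rbind, fplist)
  cov_bulk_add(map, ref_col, fp_all[, 1L], fp_all[, 2L], n_footprints = n)
  list(sel = sel, map = map)
}

## ---- sweeps ----------------------------------------------------------

## One pass over all multi-candidate groups, in input order. The map is
## updated immediately on every accepted swap and the new selection
## becomes the baseline for the group's remaining candidates.
sweep_once <- function(groups, sel, map, cfg, breakpoints) {
  changes <- 0L
  audit_lhs <- double(0); audit_rhs <- double(0)
  for (g in seq_along(groups)) {
    cands <- groups[[g]]$cands
    k <- length(cands)
    if (k < 2L) next
    cur <- sel[g]
    start_sel <- cur
    for (ci in seq_len(k)) {
      if (ci == cur) next
      accept <- FALSE
      if (cfg$loss_mode == "joint") {
        cmp <- swap_terms(map, cands[[cur]], cands[[ci]], cfg$window_flank,
                          breakpoints)
        accept <- swap_strictly_better(cmp$lhs, cmp$rhs)
        if (accept && cfg$audit) {
          audit_lhs <- c(audit_lhs, cmp$lhs)
          audit_rhs <- c(audit_rhs, cmp$rhs)
        }
      } else {
        accept <- evaluate_swap(map, cands[[cur]], cands[[ci]],
                                cfg$window_flank, breakpoints,
                                loss_mode = "independent",
                                per_interval = cfg$per_interval)
      }
      if (accept) {
        cov_remove(map, cands[[cur]]$ref, cands[[cur]]$fp)
        cov_add(map, cands[[ci]]$ref, cands[[ci]]$fp)
        cur <- ci
      }
    }
    if (cur != start_sel) {
      sel[g] <- cur
      changes <- changes + 1L
    }
  }
  list(sel = sel, changes = changes,
       audit = tibble(lhs = audit_lhs, rhs = audit_rhs))
}

## ---- top level -------------------------------------------------------

#' Resolve multi-mapped reads in an alignment tibble
#'
#' Runs the full resolution pipeline in memory: group, filter, pair,
#' initialize, then up to `iterations` sweeps with immediate map updates,
#' stopping early when a sweep makes no change.
#'
#' @param records Alignment tibble from [read_sam()] (queryname-grouped).
#' @param config A [resolver_config()].
#' @return A `covres_result` with the selected rows, per-iteration change
#'   counts, run statistics and the final [coverage_map()]. Methods:
#'   [tidy()][generics::tidy], [glance()][generics::glance], `print()`.
#' @export
resolve_groups <- function(records, config = resolver_config()) {
  cfg <- config
  ref_lengths <- sam_ref_lengths(records)
  breakpoints <- cfg$annotation
  if (is.character(breakpoints)) breakpoints <- read_breakpoints(breakpoints)
  if (!is.null(breakpoints)) {
    known <- names(breakpoints) %in% names(ref_lengths)
    if (!all(known)) {
      warn(paste0("annotation references absent from the SAM header skipped: ",
                  paste(names(breakpoints)[!known], collapse = ", ")))
      breakpoints <- structure(breakpoints[known], class = "breakpoint_index")
    }
  }
  built <- build_groups(records, cfg)
  groups <- built$groups
  multi <- sum(vapply(groups, function(g) length(g$cands) > 1L, logical(1)))
  ini <- initialize_selections(groups, cfg, ref_lengths)
  sel <- ini$sel; map <- ini$map
  iters <- integer(0)
  audits <- list()
  for (it in seq_len(cfg$iterations)) {
    sw <- sweep_once(groups, sel, map, cfg, breakpoints)
    sel <- sw$sel
    iters <- c(iters, sw$changes)
    audits[[it]] <- sw$audit
    if (sw$changes == 0L) break
  }
  selected_rows <- sort(unlist(lapply(seq_along(groups), function(g) {
    groups[[g]]$cands[[sel[g]]]$rows
  }), use.names = FALSE))
  improper_rows <- sort(unlist(lapply(groups, function(g) {
    if (g$improper) unlist(lapply(g$cands, function(c) c$rows)) else integer(0)
  }), use.names = FALSE))
  improper_rows <- intersect(improper_rows, selected_rows)
  n_unmapped <- sum(records$unmapped)
  structure(list(
    records = records,
    selected_rows = selected_rows,
    improper_rows = improper_rows,
    groups = groups,
    sel = sel,
    map = map,
    config = cfg,
    iterations = tibble(iteration = seq_along(iters), changes = iters),
    audit = dplyr::bind_rows(audits),
    stats = list(
      reads = length(groups),
      multi_groups = multi,
      records_in = nrow(records),
      records_out = length(selected_rows) +
        if (cfg$keep_unmapped) n_unmapped else 0L,
      unmapped = n_unmapped,
      supplementary_dropped = built$supplementary_dropped,
      pair_fallbacks = built$pair_fallbacks,
      capped_groups = built$capped_groups,
      converged = length(iters) > 0L && iters[length(iters)] == 0L
    )
  ), class = "covres_result")
}

#' Resolve multi-mapped reads in a SAM/BAM file
#'
#' File-level wrapper around [resolve_groups()]: reads a
#' queryname-grouped SAM/BAM, resolves every ambiguous read (pair) to a
#' single alignment, and writes the result with one record per read (both
#' mates for pairs), a `@PG` header line, and a machine-readable run
#' manifest sidecar (`<output>.manifest.json`).
#'
#' @param input Input SAM/BAM path (all alignments of a read adjacent).
#' @param output Output SAM/BAM path, or `NULL` to skip writing.
#' @param config A [resolver_config()].
#' @param dump_coverage Optional path for a bedGraph dump of the final
#'   coverage map.
#' @return The `covres_result`, invisibly.
#' @export
resolve_multimappers <- function(input, output = NULL,
                                 config = resolver_config(),
                                 dump_coverage = NULL) {
  manifest_path <- if (!is.null(output)) paste0(output, ".manifest.json")
  res <- tryCatch({
    records <- read_sam(input)
    records <- group_reads(records)
    resolve_groups(records, config)
  }, error = function(e) {
    if (!is.null(manifest_path)) {
      write_manifest(manifest_path, config, input, output, status = "failed",
                     error = conditionMessage(e))
    }
    abort(conditionMessage(e))
  })
  if (!is.null(output)) {
    write_selected(res$records, res$selected_rows, output,
                   improper_rows = res$improper_rows,
                   keep_unmapped = config$keep_unmapped,
                   pg_extra = paste("resolve -i", input, "-o", output))
    write_manifest(manifest_path, config, input, output, status = "completed",
                   result = res)
  }
  if (!is.null(dump_coverage)) {
    bg <- cov_as_bedgraph(res$map)
    utils::write.table(bg, dump_coverage, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(res)
}

write_manifest <- function(path, cfg, input, output, status,
                           result = NULL, error = NULL) {
  m <- list(
    tool = "covres",
    version = as.character(utils::packageVersion("covres")),
    status = status,
    input = input,
    output = output,
    config = cfg[setdiff(names(cfg), "annotation")],
    annotation = if (is.character(cfg$annotation)) cfg$annotation else
      if (!is.null(cfg$annotation)) "<in-memory breakpoint index>" else NULL,
    seed = cfg$seed
  )
  if (!is.null(result)) {
    m$changes_per_iteration <- result$iterations$changes
    m$stats <- result$stats
  }
  if (!is.null(error)) m$error <- error
  jsonlite::write_json(m, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
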