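# Orchestration of full clustering runs: sorting by figures of merit,
# parallel chunked rounds against common references, the switch to the
# sequential algorithm below the Minchunk threshold, full-resolution
# re-merging, and the one-step / two-step protocols.

.default_cores <- function() {
  nc <- tryCatch(parallel::detectCores(logical = FALSE), error = function(e) NA)
  if (is.na(nc) || nc < 2L) return(1L)
  min(nc - 1L, 10L)
}

#' Clustering configuration
#'
#' Collects the tunable parameters of a clustering run.
#'
#' @param tolerance wMPD admission threshold, degrees (default 60).
#' @param tolerance_round2 threshold for the second combination round in the
#'   two-step protocol, degrees (default 87).
#' @param resolution comparison resolution in Angstrom, or \code{NULL} to
#'   choose automatically (4.0, or the more conservative 3.5 in P1 where the
#'   origin is unconstrained in all directions).
#' @param cycles re-referencing cycles per cluster attempt (default 3).
#' @param n_cores worker count for the parallel rounds; defaults to the
#'   number of physical cores minus one, capped at ten.
#' @param minchunk pool size at which clustering switches from parallel
#'   chunked rounds to the sequential algorithm; default \code{2 * n_cores}.
#' @param polar_algorithm origin-shift search for polar groups: "auto"
#'   (FFT in P1, sparse otherwise), "fft" or "sparse".
#' @param fft_grid FFT grid points per polar axis.
#' @param seed integer seed governing synthetic-data generation only; never
#'   used by clustering decisions.
#' @return a list of class \code{"phasemerge_config"}.
#' @export
merge_config <- function(tolerance = 60, tolerance_round2 = 87,
                         resolution = NULL, cycles = 3L,
                         n_cores = 1L, minchunk = NULL,
                         polar_algorithm = c("auto", "fft", "sparse"),
                         fft_grid = 64L, seed = NULL) {
  polar_algorithm <- match.arg(polar_algorithm)
  if (is.null(n_cores)) n_cores <- .default_cores()
  n_cores <- max(1L, as.integer(n_cores))
  if (is.null(minchunk)) minchunk <- 2L * n_cores
  if (!(tolerance > 0 && tolerance <= tolerance_round2 &&
        tolerance_round2 <= 180))
    stop("need 0 < tolerance <= tolerance_round2 <= 180")
  structure(list(tolerance = tolerance, tolerance_round2 = tolerance_round2,
                 resolution = resolution, cycles = as.integer(cycles),
                 n_cores = n_cores, minchunk = as.integer(minchunk),
                 polar_algorithm = polar_algorithm,
                 fft_grid = as.integer(fft_grid), seed = seed),
            class = "phasemerge_config")
}

.comparison_resolution <- function(cfg, sg) {
  if (!is.null(cfg$resolution)) return(cfg$resolution)
  if (all(sg$polar_mask)) 3.5 else 4.0
}

# chunked parallel mapper: contiguous chunks, deterministic chunk-order
# aggregation, one read-only reference shared by all workers (fork)
.chunked_map <- function(n_cores) {
  if (n_cores <= 1L) return(lapply)
  function(xs, f) {
    if (!length(xs)) return(list())
    nch <- min(n_cores, length(xs))
    chunks <- split(seq_along(xs), cut(seq_along(xs), nch, labels = FALSE))
    res <- parallel::mclapply(chunks, function(ix) lapply(xs[ix], f),
                              mc.cores = nch)
    err <- vapply(res, inherits, logical(1), what = "try-error")
    if (any(err)) stop("parallel comparison worker failed: ", res[[which(err)[1]]])
    do.call(c, unname(res))
  }
}

#' Sort solutions by phasing figures of merit
#'
#' Stable descending sort by the meta CC score when present, else LLG, else
#' input order; sets carrying scores come before sets without.
#'
#' @param inputs list of \code{phase_set}s.
#' @return the reordered list.
#' @export
sort_solutions <- function(inputs) {
  score <- vapply(inputs, function(p) {
    if (!is.null(p$meta$CC)) as.numeric(p$meta$CC)
    else if (!is.null(p$meta$LLG)) as.numeric(p$meta$LLG)
    else NA_real_
  }, numeric(1))
  has <- !is.na(score)
  ord <- c(which(has)[order(-score[has])], which(!has))
  inputs[ord]
}

#' Parallel chunked clustering round
#'
#' While the pool is larger than \code{minchunk}, takes the head of the pool
#' as the common reference, compares the remaining sets against it in
#' contiguous chunks distributed over the workers, admits every set below
#' the tolerance, and removes the formed cluster from the pool.  Admission
#' depends only on the (set, reference) pair, so the membership is
#' identical to a single-core sequential run for any chunking.
#'
#' @param pool ordered list of \code{phase_set}s.
#' @param sg \code{space_group} object or symbol.
#' @param cfg a \code{\link{merge_config}}.
#' @return list with \code{clusters} (multi-member \code{merged_phase_set}s),
#'   \code{leftover_ids} (references that attracted no member) and
#'   \code{pool} (the remaining sets).
#' @export
parallel_round <- function(pool, sg, cfg = merge_config()) {
  sg <- .as_space_group(sg)
  mapper <- .chunked_map(cfg$n_cores)
  clusters <- list()
  leftovers <- character()
  while (length(pool) > cfg$minchunk) {
    res <- phase_cluster(pool, sg, tolerance = cfg$tolerance,
                         cycles = cfg$cycles, seq_continue = FALSE,
                         algorithm = cfg$polar_algorithm, grid = cfg$fft_grid,
                         map = mapper)
    cl <- res$clusters[[1]]
    ids <- vapply(pool, function(p) p$id, character(1))
    if (nrow(cl$members) > 1L) clusters <- c(clusters, list(cl))
    else leftovers <- c(leftovers, cl$members$member_id[1])
    pool <- pool[ids %in% res$leftover_ids]
  }
  list(clusters = clusters, leftover_ids = leftovers, pool = pool)
}

#' Sequential clustering round
#'
#' Repeatedly delegates to \code{\link{phase_cluster}} with
#' \code{seq_continue = TRUE} until the pool is exhausted; references that
#' attract no member become leftovers.
#'
#' @inheritParams parallel_round
#' @return list with \code{clusters} and \code{leftover_ids}.
#' @export
sequential_round <- function(pool, sg, cfg = merge_config()) {
  sg <- .as_space_group(sg)
  clusters <- list()
  leftovers <- character()
  while (length(pool)) {
    res <- phase_cluster(pool, sg, tolerance = cfg$tolerance,
                         cycles = cfg$cycles, seq_continue = TRUE,
                         algorithm = cfg$polar_algorithm, grid = cfg$fft_grid)
    leftovers <- c(leftovers, res$singleton_ids)
    ids <- vapply(pool, function(p) p$id, character(1))
    if (length(res$clusters)) {
      cl <- res$clusters[[1]]
      if (nrow(cl$members) > 1L) clusters <- c(clusters, list(cl))
      else leftovers <- c(leftovers, cl$members$member_id[1])
    }
    pool <- pool[ids %in% res$leftover_ids]
  }
  list(clusters = clusters, leftover_ids = leftovers)
}

# re-merge a cluster at full resolution using the recorded shifts and the
# comparison-stage wMPDs as weights; full-resolution wMPD reported per member
.remerge_full <- function(cl, full_by_id, sg, cfg) {
  rec <- cl$members
  ref <- full_by_id[[rec$member_id[1]]]
  members <- lapply(seq_len(nrow(rec))[-1], function(i) {
    sh <- c(rec$shift_a[i], rec$shift_b[i], rec$shift_c[i])
    ps <- apply_origin_shift(full_by_id[[rec$member_id[i]]], sh)
    list(ps = ps, wmpd = rec$wmpd_to_reference[i], shift = sh,
         mapcc = rec$mapcc[i])
  })
  # weights derive from the comparison-stage wMPDs (members were admitted at
  # the comparison resolution); only the phases are re-averaged at full
  # resolution
  merged <- merge_phase_sets(ref, members, cfg$tolerance)
  merged$members$wmpd_full <- c(0, vapply(members, function(m)
    wmpd(ref, m$ps), numeric(1)))
  merged$cycles_run <- cl$cycles_run
  merged
}

#' One-step phase combination
#'
#' The full single-round protocol: solutions are sorted by their figures of
#' merit, compared at the (coarse) comparison resolution through parallel
#' chunked rounds until the pool reaches \code{minchunk}, then through the
#' sequential algorithm; the final clusters are re-merged at full
#' resolution.
#'
#' @param solutions list of \code{phase_set}s sharing cell, space group and
#'   reflection indexing.
#' @param sg \code{space_group} object or symbol.
#' @param cfg a \code{\link{merge_config}}.
#' @return object of class \code{"phasemerge_report"}: list with
#'   \code{clusters} (full-resolution \code{merged_phase_set}s),
#'   \code{leftovers} (unclustered ids), \code{config}, \code{sg} and a
#'   \code{provenance} data.frame.
#' @seealso \code{\link{phasemerge}} for the main entry point.
#' @export
run_one_step <- function(solutions, sg, cfg = merge_config()) {
  sg <- .as_space_group(sg)
  if (!length(solutions))
    return(.report(list(), character(), cfg, sg, round = 1L))
  for (p in solutions) stopifnot(inherits(p, "phase_set"))
  cellref <- solutions[[1]]
  for (p in solutions) .check_same_indexing(cellref, p)
  sorted <- sort_solutions(solutions)
  full_by_id <- stats::setNames(sorted, vapply(sorted, `[[`, "", "id"))
  d_cmp <- .comparison_resolution(cfg, sg)
  pool <- lapply(sorted, cut_resolution, d_cut = d_cmp)
  if (.n_refl(pool[[1]]) == 0L)
    stop("no reflections survive the comparison resolution cutoff of ",
         d_cmp, " A")
  par <- parallel_round(pool, sg, cfg)
  seqr <- sequential_round(par$pool, sg, cfg)
  clusters_cmp <- c(par$clusters, seqr$clusters)
  leftovers <- c(par$leftover_ids, seqr$leftover_ids)
  clusters <- lapply(clusters_cmp, .remerge_full, full_by_id = full_by_id,
                     sg = sg, cfg = cfg)
  .report(clusters, leftovers, cfg, sg, round = 1L)
}

#' Two-step phase combination
#'
#' Runs \code{\link{run_one_step}} within each group (typically one group
#' per rotation cluster, or per monomer hypothesis), then performs a second
#' combination round over all first-round merged sets at the higher
#' tolerance \code{tolerance_round2}, so that clusters carrying
#' complementary information (e.g. different monomers, or fragments of a
#' different structural nature) can join.
#'
#' @param groups list of lists of \code{phase_set}s.
#' @param sg \code{space_group} object or symbol.
#' @param cfg a \code{\link{merge_config}}.
#' @return a \code{"phasemerge_report"}; round-2 clusters record the
#'   first-round cluster ids they joined in \code{provenance}.
#' @export
run_two_step <- function(groups, sg, cfg = merge_config()) {
  if (!length(groups)) stop("`groups` must contain at least one input list")
  sg <- .as_space_group(sg)
  round1 <- lapply(seq_along(groups), function(g) {
    rep1 <- run_one_step(groups[[g]], sg, cfg)
    for (i in seq_along(rep1$clusters)) {
      rep1$clusters[[i]]$id <- sprintf("g%d_c%d", g, i)
      rep1$clusters[[i]]$meta$group <- g
    }
    rep1
  })
  merged1 <- do.call(c, lapply(round1, `[[`, "clusters"))
  leftover1 <- do.call(c, lapply(round1, `[[`, "leftovers"))
  if (length(merged1) < 2L) {
    rep <- .report(merged1, leftover1, cfg, sg, round = 2L)
    rep$round1 <- round1
    return(rep)
  }
  # second round at the higher tolerance over the round-1 merged sets
  cfg2 <- cfg
  cfg2$tolerance <- cfg$tolerance_round2
  pool <- lapply(merged1, function(m) {
    ps <- m
    class(ps) <- "phase_set"
    ps$members <- NULL
    ps
  })
  seqr <- sequential_round(pool, sg, cfg2)
  keep_single <- vapply(merged1, function(m) m$id, character(1)) %in%
    seqr$leftover_ids
  clusters <- c(seqr$clusters, merged1[keep_single])
  rep <- .report(clusters, leftover1, cfg, sg, round = 2L)
  rep$round1 <- round1
  rep
}

.report <- function(clusters, leftovers, cfg, sg, round) {
  prov <- if (length(clusters)) {
    do.call(rbind, lapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      data.frame(cluster = i, reference = cl$members$member_id[1],
                 size = nrow(cl$members), round = round,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(cluster = integer(), reference = character(),
                    size = integer(), round = integer())
  structure(list(clusters = clusters, leftovers = leftovers,
                 config = cfg, sg = sg, provenance = prov),
            class = "phasemerge_report")
}

#' @export
print.phasemerge_report <- function(x, ...) {
  cat("Phase-combination report:", length(x$clusters), "cluster(s),",
      length(x$leftovers), "unclustered solution(s)\n")
  if (length(x$clusters)) {
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      cat(sprintf("  %2d. %-18s size %2d  mean wMPD %5.1f deg\n",
                  i, cl$id, nrow(cl$members),
                  mean(cl$members$wmpd_to_reference[-1])))
    }
  }
  invisible(x)
}

#' @export
summary.phasemerge_report <- function(object, ...) {
  df <- as.data.frame(object)
  cat("Clusters:\n")
  print(df, row.names = FALSE, digits = 4)
  cat("Leftovers:", if (length(object$leftovers))
    paste(object$leftovers, collapse = ", ") else "none", "\n")
  invisible(df)
}

#' @export
as.data.frame.phasemerge_report <- function(x, ...) {
  if (!length(x$clusters))
    return(data.frame(cluster = integer(), id = character(),
                      size = integer(), mean_wmpd = numeric(),
                      top_score = numeric()))
  do.call(rbind, lapply(seq_along(x$clusters), function(i) {
    cl <- x$clusters[[i]]
    top <- if (!is.null(cl$meta$CC)) as.numeric(cl$meta$CC) else NA_real_
    data.frame(cluster = i, id = cl$id, size = nrow(cl$members),
               mean_wmpd = mean(cl$members$wmpd_to_reference[-1]),
               top_score = top, stringsAsFactors = FALSE)
  }))
}

#' @export
plot.phasemerge_report <- function(x, ...) {
  df <- as.data.frame(x)
  if (!nrow(df)) {
    plot.new(); title("no clusters"); return(invisible(x))
  }
  plot(df$size, df$mean_wmpd, pch = 19, cex = 1.2,
       xlab = "cluster size", ylab = "mean wMPD to reference (deg)", ...)
  text(df$size, df$mean_wmpd, labels = df$cluster, pos = 3, cex = 0.8)
  invisible(x)
}

#' Weighted mean phase error table
#'
#' The wMPD of each solution against a reference "truth" phase set at its
#' best allowed origin shift — the weighted mean phase error (wMPE) when
#' the reference holds the true phases.  Solutions with wMPE below 80
#' degrees are flagged as nonrandom.
#'
#' @param solutions list of \code{phase_set}s.
#' @param truth reference \code{phase_set} with the same indexing.
#' @param sg \code{space_group} object or symbol.
#' @param algorithm,grid passed to \code{\link{best_origin_shift}}.
#' @return data.frame with id, wmpe, mapcc, shift components and the
#'   nonrandom flag.
#' @export
wmpe_table <- function(solutions, truth, sg, algorithm = "auto", grid = 64L) {
  sg <- .as_space_group(sg)
  rows <- lapply(solutions, function(ps) {
    cmp <- best_origin_shift(truth, ps, sg, algorithm, grid)
    data.frame(id = ps$id, wmpe = cmp$wmpd, mapcc = cmp$mapcc,
               shift_a = cmp$shift[1], shift_b = cmp$shift[2],
               shift_c = cmp$shift[3], nonrandom = cmp$wmpd < 80,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
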