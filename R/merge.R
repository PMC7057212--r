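# Weighted merging of consistent phase sets and the referential clustering
# engine (iterative re-referencing against the running average).

#' Merge consistent phase sets into an averaged set
#'
#' Builds the weighted vector average of the reference and the (already
#' origin-shifted) member phase sets.  Per reflection, the combined phase is
#' the argument of sum_j omega_j m_jh exp(i phi_jh) and the combined figure
#' of merit its modulus normalized by sum_j omega_j (so merging identical
#' copies preserves the fom, and antipodal phases cancel to fom 0), where
#' the member weight omega_j = (tolerance - wMPD_j) / tolerance is
#' proportional to the member's similarity to the reference and
#' omega_ref = 1.  Amplitudes are copied from the reference.
#'
#' @param reference a \code{phase_set}.
#' @param members list of entries, each a list with elements \code{ps} (the
#'   member \code{phase_set}, shifted to the reference origin), \code{wmpd}
#'   (its wMPD to the reference, <= tolerance), and optionally \code{shift}
#'   and \code{mapcc} for the member record.  May be empty (cluster of one).
#' @param tolerance clustering tolerance in degrees.
#' @return object of class \code{c("merged_phase_set", "phase_set")} with a
#'   \code{members} data.frame (member_id, weight, shift, wmpd) and a
#'   \code{cycles_run} field (set by the clustering engine).
#' @export
merge_phase_sets <- function(reference, members, tolerance) {
  stopifnot(inherits(reference, "phase_set"))
  if (tolerance <= 0) stop("`tolerance` must be positive")
  rec <- data.frame(member_id = reference$id, weight = 1,
                    shift_a = 0, shift_b = 0, shift_c = 0,
                    wmpd_to_reference = 0, mapcc = 1,
                    stringsAsFactors = FALSE)
  num <- exp(1i * reference$phi * pi / 180) * reference$fom
  den <- 1
  for (m in members) {
    .check_same_indexing(reference, m$ps)
    if (m$wmpd > tolerance)
      stop("member '", m$ps$id, "' has wMPD ", round(m$wmpd, 2),
           " above the tolerance ", tolerance)
    omega <- (tolerance - m$wmpd) / tolerance
    if (omega <= 0) omega <- .Machine$double.eps
    sh <- if (!is.null(m$shift)) as.numeric(m$shift) else c(0, 0, 0)
    rec <- rbind(rec, data.frame(
      member_id = m$ps$id, weight = omega,
      shift_a = sh[1], shift_b = sh[2], shift_c = sh[3],
      wmpd_to_reference = m$wmpd,
      mapcc = if (!is.null(m$mapcc)) m$mapcc else NA_real_,
      stringsAsFactors = FALSE))
    num <- num + omega * m$ps$fom * exp(1i * m$ps$phi * pi / 180)
    den <- den + omega
  }
  fom <- pmin(pmax(Mod(num) / den, 0), 1)
  phi <- ifelse(Mod(num) > 1e-12, (Arg(num) * 180 / pi) %% 360, reference$phi)
  out <- phase_set(hkl = reference$hkl, f = reference$f, fom = fom, phi = phi,
                   cell = reference$cell, sg = reference$sg_symbol,
                   id = paste0("cluster_", reference$id),
                   meta = reference$meta)
  out$members <- rec
  out$cycles_run <- 1L
  class(out) <- c("merged_phase_set", "phase_set")
  out
}

#' @export
print.merged_phase_set <- function(x, ...) {
  cat("Merged phase set '", x$id, "': ", nrow(x$members), " members, ",
      nrow(x$hkl), " reflections, ", x$cycles_run, " cycle(s)\n", sep = "")
  print(x$members, row.names = FALSE, digits = 4)
  invisible(x)
}

# one reference attempt: compare every candidate to the running average,
# admit those below tolerance, re-merge, iterate.
.cluster_attempt <- function(ref_ps, candidates, sg, tolerance, cycles,
                             algorithm, grid, map) {
  merged <- merge_phase_sets(ref_ps, list(), tolerance)
  prev_admitted <- integer()
  cycles_run <- 0L
  for (cy in seq_len(cycles)) {
    cycles_run <- cy
    cmps <- map(candidates,
                function(ps) best_origin_shift(merged, ps, sg, algorithm, grid))
    wm <- vapply(cmps, function(r) r$wmpd, numeric(1))
    admitted <- which(wm <= tolerance)
    members <- lapply(admitted, function(j) {
      list(ps = apply_origin_shift(candidates[[j]], cmps[[j]]$shift),
           wmpd = cmps[[j]]$wmpd, shift = cmps[[j]]$shift,
           mapcc = cmps[[j]]$mapcc)
    })
    merged <- merge_phase_sets(ref_ps, members, tolerance)
    if (identical(admitted, prev_admitted)) break
    prev_admitted <- admitted
  }
  merged$cycles_run <- cycles_run
  list(merged = merged, admitted = prev_admitted)
}

#' Referential clustering of phase sets
#'
#' The comparison engine behind clustering.  The first list entry seeds the
#' cluster as the reference; in each cycle every remaining set is compared
#' to the current reference (the weighted average after the first cycle) at
#' its best allowed origin shift, sets with wMPD at or below the tolerance
#' are admitted, and the average is rebuilt.  Iteration stops after
#' \code{cycles} cycles or as soon as the membership is unchanged.  With
#' \code{seq_continue}, a reference that attracts no member is set aside and
#' the next entry seeds a fresh attempt, until a multi-member cluster forms
#' or the list is exhausted.
#'
#' @param inputs ordered list of \code{phase_set}s sharing one reflection
#'   list.
#' @param sg \code{space_group} object or symbol.
#' @param tolerance admission threshold on the wMPD, degrees (default 60).
#' @param cycles maximum re-referencing cycles (default 3).
#' @param seq_continue advance the reference past singleton attempts.
#' @param algorithm origin-shift search algorithm (see
#'   \code{\link{best_origin_shift}}).
#' @param grid FFT grid points per polar axis.
#' @param map a \code{lapply}-like function used for the per-cycle
#'   comparison loop; the parallel round passes a chunked parallel mapper.
#' @return list with \code{clusters} (list of \code{merged_phase_set}; at
#'   most one here), \code{singleton_ids} (references tried and set aside
#'   under \code{seq_continue}) and \code{leftover_ids} (ids never used nor
#'   admitted).
#' @export
phase_cluster <- function(inputs, sg, tolerance = 60, cycles = 3L,
                          seq_continue = FALSE,
                          algorithm = "auto", grid = 64L, map = lapply) {
  if (!length(inputs))
    return(list(clusters = list(), singleton_ids = character(),
                leftover_ids = character()))
  if (cycles < 1L) stop("`cycles` must be >= 1")
  sg <- .as_space_group(sg)
  ids <- vapply(inputs, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("phase-set ids must be unique")
  singles <- character()
  i <- 1L
  pool_idx <- seq_along(inputs)
  repeat {
    ref_idx <- pool_idx[1]
    rest_idx <- pool_idx[-1]
    att <- .cluster_attempt(inputs[[ref_idx]], inputs[rest_idx], sg,
                            tolerance, cycles, algorithm, grid, map)
    if (length(att$admitted) || !seq_continue || length(rest_idx) == 0L) {
      leftover <- setdiff(rest_idx, rest_idx[att$admitted])
      return(list(clusters = list(att$merged),
                  singleton_ids = singles,
                  leftover_ids = ids[leftover]))
    }
    singles <- c(singles, ids[ref_idx])
    pool_idx <- rest_idx
  }
}
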