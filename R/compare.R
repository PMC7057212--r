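# The phase-set comparison engine: weighted mean phase difference, map
# correlation coefficient, and best-origin-shift search by three algorithms
# (discrete enumeration for nonpolar groups; sparse layer-1 estimation and an
# FFT translation function for polar groups).
#
# Conventions used throughout:
#   * phases in degrees, stored mod 360;
#   * shifting a model by +t changes phases as phi' = phi - 360 (h.t);
#   * per-reflection comparison weight w = m1 m2 F1 F2 (fom product times
#     amplitude product; reduces to m1 m2 F^2 when amplitudes are shared);
#   * mapCC = sum(m1 F1 m2 F2 cos dphi) / sqrt(sum((m1 F1)^2) sum((m2 F2)^2)),
#     the reciprocal-space form of the correlation of the two fom-weighted
#     density maps (F000 excluded).

#' Absolute circular phase difference
#'
#' The unsigned difference between two phase angles on the circle, in
#' [0, 180] degrees.
#'
#' @param a,b phases in degrees (vectors recycled).
#' @return numeric vector of differences in degrees.
#' @examples
#' delta_phi(10, 350)  # 20
#' @export
delta_phi <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# fast kernels operating on raw vectors -------------------------------------

.pair_weights <- function(a, b) a$fom * b$fom * a$f * b$f

# weighted mean of wrapped |dphi| given dphi0 in degrees (any real)
.wmpd_from_dphi <- function(dphi, w) {
  d <- abs(dphi) %% 360
  sum(w * pmin(d, 360 - d)) / sum(w)
}

.mapcc_from_dphi <- function(dphi, wa, wb) {
  sum(wa * wb * cos(dphi * pi / 180)) /
    sqrt(sum(wa^2) * sum(wb^2))
}

#' Weighted mean phase difference (wMPD)
#'
#' The weighted average over all common reflections of the circular phase
#' difference, with weights w = m1 m2 F1 F2.  Zero for identical phase sets
#' and about 90 degrees for uncorrelated phases.  Both sets must be indexed
#' over the same reflection list (no origin shift is applied here; see
#' \code{\link{best_origin_shift}}).
#'
#' @param ps1,ps2 \code{phase_set}s sharing the same hkl list.
#' @return wMPD in degrees, in [0, 180].
#' @export
wmpd <- function(ps1, ps2) {
  .check_same_indexing(ps1, ps2)
  if (.n_refl(ps1) == 0L) stop("phase sets have no reflections")
  w <- .pair_weights(ps1, ps2)
  if (sum(w) <= 0) stop("all comparison weights are zero; wMPD is undefined")
  .wmpd_from_dphi(ps1$phi - ps2$phi, w)
}

#' Map correlation coefficient (mapCC)
#'
#' The correlation between the two electron-density maps implied by two
#' phase sets, evaluated in reciprocal space over their shared reflections.
#' Equals 1 for identical phase sets and 0 in expectation for uncorrelated
#' phases.
#'
#' @inheritParams wmpd
#' @return dimensionless correlation in [-1, 1].
#' @export
mapcc <- function(ps1, ps2) {
  .check_same_indexing(ps1, ps2)
  if (.n_refl(ps1) == 0L) stop("phase sets have no reflections")
  wa <- ps1$fom * ps1$f
  wb <- ps2$fom * ps2$f
  if (sum(wa * wb) == 0) stop("all comparison weights are zero")
  .mapcc_from_dphi(ps1$phi - ps2$phi, wa, wb)
}

#' Apply an origin shift to a phase set
#'
#' Re-expresses the phases relative to an origin moved by the fractional
#' vector \code{t}: phi' = (phi - 360 h.t) mod 360.  Amplitudes and figures
#' of merit are unchanged.
#'
#' @param ps a \code{phase_set}.
#' @param t fractional 3-vector.
#' @return the shifted \code{phase_set}.
#' @export
apply_origin_shift <- function(ps, t) {
  stopifnot(inherits(ps, "phase_set"))
  t <- as.numeric(t)
  if (length(t) != 3L) stop("`t` must be a fractional 3-vector")
  ps$phi <- unname((ps$phi - 360 * drop(ps$hkl %*% t)) %% 360)
  ps
}

# comparison-result constructor
.cmp_result <- function(wmpd, mapcc, shift, n_common, algorithm) {
  structure(list(wmpd = wmpd, mapcc = mapcc, shift = as.numeric(shift) %% 1,
                 n_common = n_common, algorithm = algorithm),
            class = "shift_comparison")
}

#' @export
print.shift_comparison <- function(x, ...) {
  cat(sprintf(
    "wMPD %.2f deg, mapCC %.3f at shift (%.4f, %.4f, %.4f) [%s, %d refl]\n",
    x$wmpd, x$mapcc, x$shift[1], x$shift[2], x$shift[3],
    x$algorithm, x$n_common))
  invisible(x)
}

# shared preparation: dphi0 = phi1 - phi2 (degrees), weights
.cmp_prep <- function(ps1, ps2) {
  .check_same_indexing(ps1, ps2)
  if (.n_refl(ps1) == 0L) stop("phase sets have no reflections")
  w <- .pair_weights(ps1, ps2)
  if (sum(w) <= 0) stop("all comparison weights are zero")
  list(hkl = ps1$hkl, dphi0 = ps1$phi - ps2$phi, w = w,
       wa = ps1$fom * ps1$f, wb = ps2$fom * ps2$f)
}

# evaluate wmpd at a single shift given prepared data
.wmpd_at <- function(prep, t) {
  .wmpd_from_dphi(prep$dphi0 + 360 * drop(prep$hkl %*% t), prep$w)
}

.finish_cmp <- function(prep, t, algorithm) {
  dphi <- prep$dphi0 + 360 * drop(prep$hkl %*% t)
  .cmp_result(.wmpd_from_dphi(dphi, prep$w),
              .mapcc_from_dphi(dphi, prep$wa, prep$wb),
              t, length(prep$w), algorithm)
}

#' Best origin shift by discrete enumeration (nonpolar groups)
#'
#' Evaluates the wMPD of \code{ps1} against \code{ps2} shifted by every
#' allowed discrete origin shift of the space group and returns the
#' minimizing shift with its wMPD and mapCC.  Ties are broken in favour of
#' the first shift in the canonical table order.
#'
#' @param ps1,ps2 \code{phase_set}s sharing the same hkl list.
#' @param sg \code{space_group} object or symbol (must be nonpolar).
#' @return a \code{shift_comparison}.
#' @export
best_shift_discrete <- function(ps1, ps2, sg) {
  sg <- .as_space_group(sg)
  if (any(sg$polar_mask))
    stop("space group ", sg$symbol,
         " has polar axes; use the sparse or FFT algorithm")
  prep <- .cmp_prep(ps1, ps2)
  shifts <- sg$discrete_shifts
  # all shifts at once: D[n, s] = dphi0 + 360 h.t_s
  D <- abs(prep$dphi0 + 360 * (prep$hkl %*% t(shifts))) %% 360
  D <- pmin(D, 360 - D)
  scores <- colSums(prep$w * D) / sum(prep$w)
  best <- which.min(scores)
  .finish_cmp(prep, shifts[best, ], "discrete")
}

# weighted circular mean of angles in degrees
.circ_mean_deg <- function(ang, w) {
  z <- sum(w * exp(1i * ang * pi / 180))
  (Arg(z) * 180 / pi) %% 360
}

# 1-D golden-section polish of wmpd along polar axis `axis` around t0
.polish_axis <- function(prep, t0, axis, halfwidth, tol = 1e-5) {
  f <- function(x) { t <- t0; t[axis] <- x; .wmpd_at(prep, t) }
  opt <- stats::optimize(f, lower = t0[axis] - halfwidth,
                         upper = t0[axis] + halfwidth, tol = tol)
  t0[axis] <- opt$minimum %% 1
  t0
}

#' Best origin shift by the sparse (layer-1) algorithm (polar groups)
#'
#' For each allowed discrete (non-polar) shift candidate, estimates the
#' polar origin-shift component from the weighted circular mean of the phase
#' differences over the reflections whose polar-axis index equals 1, then
#' refines it against all reflections by golden-section minimization of the
#' wMPD.  The global best over candidates is returned.
#'
#' @inheritParams best_shift_discrete
#' @param sg \code{space_group} with at least one polar axis.
#' @return a \code{shift_comparison}.
#' @export
best_shift_sparse <- function(ps1, ps2, sg) {
  sg <- .as_space_group(sg)
  axes <- which(sg$polar_mask)
  if (!length(axes)) stop("space group ", sg$symbol,
                          " is nonpolar; use best_shift_discrete()")
  prep <- .cmp_prep(ps1, ps2)
  hkl <- prep$hkl
  # layer-1 selector per polar axis: index 1 on that axis, 0 on other polar axes
  layer <- lapply(axes, function(ax) {
    sel <- hkl[, ax] == 1L
    for (other in setdiff(axes, ax)) sel <- sel & hkl[, other] == 0L
    sel
  })
  if (any(!vapply(layer, any, logical(1))))
    stop("no layer-1 reflections along a polar axis; fall back to the FFT search")

  best <- NULL
  for (i in seq_len(nrow(sg$discrete_shifts))) {
    t0 <- sg$discrete_shifts[i, ]
    dphi_d <- prep$dphi0 + 360 * drop(hkl %*% t0)
    # initial polar estimates from layer 1: dphi + 360 t_ax ~ 0 (mod 360)
    for (k in seq_along(axes)) {
      sel <- layer[[k]]
      est <- (-.circ_mean_deg(dphi_d[sel], prep$w[sel]) / 360) %% 1
      t0[axes[k]] <- est
    }
    # refine each polar axis against all reflections (two sweeps when
    # several axes are free)
    sweeps <- if (length(axes) > 1L) 2L else 1L
    for (s in seq_len(sweeps))
      for (ax in axes)
        t0 <- .polish_axis(prep, t0, ax, halfwidth = 0.06 / s)
    sc <- .wmpd_at(prep, t0)
    if (is.null(best) || sc < best$score) best <- list(score = sc, t = t0)
  }
  .finish_cmp(prep, best$t, "sparse")
}

#' Best origin shift by FFT translation search (polar groups)
#'
#' For each allowed discrete non-polar shift candidate, builds the complex
#' coefficients G_h = w_h exp(i dphi_h) and evaluates the translation
#' function T(t) = Re sum_h G_h exp(2 pi i h.t) on a grid along the polar
#' axes via the fast Fourier transform.  The grid argmax is polished by
#' golden-section refinement of the wMPD within one grid cell per polar
#' axis; the global best over candidates is returned.
#'
#' @inheritParams best_shift_sparse
#' @param grid number of grid points per polar axis (power of two >= 32).
#' @return a \code{shift_comparison}.
#' @export
best_shift_fft <- function(ps1, ps2, sg, grid = 64L) {
  sg <- .as_space_group(sg)
  axes <- which(sg$polar_mask)
  if (!length(axes)) stop("space group ", sg$symbol,
                          " is nonpolar; use best_shift_discrete()")
  grid <- as.integer(grid)
  if (grid < 32L || bitwAnd(grid, grid - 1L) != 0L)
    stop("`grid` must be a power of two >= 32")
  prep <- .cmp_prep(ps1, ps2)
  hkl <- prep$hkl
  idx <- lapply(axes, function(ax) (hkl[, ax] %% grid) + 1L)

  best <- NULL
  for (i in seq_len(nrow(sg$discrete_shifts))) {
    t0 <- sg$discrete_shifts[i, ]
    dphi_d <- (prep$dphi0 + 360 * drop(hkl %*% t0)) * pi / 180
    G <- prep$w * exp(1i * dphi_d)
    # accumulate onto the polar grid and evaluate T(t) by inverse DFT;
    # T(j/grid) = Re sum_h G_h exp(2 pi i sum_ax h_ax j_ax / grid)
    dims <- rep(grid, length(axes))
    A <- array(0 + 0i, dim = dims)
    flat <- idx[[1]]
    if (length(axes) > 1L)
      for (k in 2:length(axes))
        flat <- flat + (idx[[k]] - 1L) * grid^(k - 1L)
    re <- vapply(split(Re(G), flat), sum, numeric(1))
    im <- vapply(split(Im(G), flat), sum, numeric(1))
    at <- as.integer(names(re))
    A[at] <- complex(real = re, imaginary = im)
    Tmap <- Re(stats::fft(A, inverse = TRUE))
    j <- which.max(Tmap) - 1L
    # unravel flat index to per-axis grid coordinates
    tvec <- t0
    for (k in seq_along(axes)) {
      tvec[axes[k]] <- (j %% grid) / grid
      j <- j %/% grid
    }
    # polish within +/- one grid cell, coordinate-wise
    sweeps <- if (length(axes) > 1L) 2L else 1L
    for (s in seq_len(sweeps))
      for (ax in axes)
        tvec <- .polish_axis(prep, tvec, ax, halfwidth = 1 / grid)
    sc <- .wmpd_at(prep, tvec)
    if (is.null(best) || sc < best$score) best <- list(score = sc, t = tvec)
  }
  out <- .finish_cmp(prep, best$t, "fft")
  out
}

#' Best origin shift between two phase sets
#'
#' Dispatcher over the three search algorithms: discrete enumeration for
#' nonpolar groups; for polar groups, \code{"auto"} uses the FFT search in
#' P1 and the sparse layer-1 search otherwise, falling back to FFT when no
#' layer-1 reflections are present.
#'
#' @inheritParams best_shift_discrete
#' @param sg \code{space_group} object or symbol.
#' @param algorithm one of "auto", "discrete", "sparse", "fft".
#' @param grid FFT grid points per polar axis.
#' @return a \code{shift_comparison}.
#' @export
best_origin_shift <- function(ps1, ps2, sg,
                              algorithm = c("auto", "discrete", "sparse", "fft"),
                              grid = 64L) {
  sg <- .as_space_group(sg)
  algorithm <- match.arg(algorithm)
  if (!any(sg$polar_mask)) {
    if (algorithm %in% c("sparse", "fft"))
      stop("space group ", sg$symbol, " is nonpolar; polar search not applicable")
    return(best_shift_discrete(ps1, ps2, sg))
  }
  if (algorithm == "discrete")
    stop("space group ", sg$symbol, " has polar axes; discrete search not applicable")
  if (algorithm == "sparse") return(best_shift_sparse(ps1, ps2, sg))
  if (algorithm == "fft") return(best_shift_fft(ps1, ps2, sg, grid))
  # auto: FFT in P1 (all axes polar); sparse otherwise, unless the layer-1
  # reflections needed by the sparse estimate are missing
  if (all(sg$polar_mask)) return(best_shift_fft(ps1, ps2, sg, grid))
  res <- tryCatch(best_shift_sparse(ps1, ps2, sg), error = function(e) e)
  if (inherits(res, "error")) best_shift_fft(ps1, ps2, sg, grid) else res
}
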