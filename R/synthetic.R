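# Synthetic solution landscapes: toy crystal structures, partial / noisy /
# wrong sub-models with random allowed origin shifts, and figure-of-merit
# metadata, emulating the statistical structure of fragment-phasing runs so
# every stage of the pipeline is testable without external data.

# default cells per supported group, sized so that the 4.0 A comparison
# shell holds on the order of 150-250 unique reflections: below that the
# chance minimum of the null wMPD over the allowed shifts starts dipping
# under the 60 degree tolerance (real data sets carry thousands)
.default_cells <- list(
  "P1"      = c(17.0, 19.0, 21.0, 95.0, 101.5, 86.0),
  "P21"     = c(22.0, 25.0, 26.0, 90, 102.5, 90),
  "C2"      = c(36.0, 22.0, 27.0, 90, 108.0, 90),
  "P212121" = c(26.0, 29.0, 32.0, 90, 90, 90),
  "C2221"   = c(30.0, 34.0, 40.0, 90, 90, 90),
  "F222"    = c(40.0, 44.0, 46.0, 90, 90, 90),
  "F23"     = c(63.0, 63.0, 63.0, 90, 90, 90),
  "P63"     = c(30.0, 30.0, 24.0, 90, 90, 120)
)

#' Default toy cell for a space group
#' @param sg space-group symbol or object.
#' @return numeric(6) unit-cell parameters.
#' @export
default_cell <- function(sg) {
  sg <- .as_space_group(sg)
  .default_cells[[sg$symbol]]
}

# minimum cartesian distance between all symmetry-expanded atoms,
# minimum-image over the 27 neighbouring cells
.min_distance <- function(xyz, cell, sg) {
  ops <- sg$ops
  allx <- do.call(rbind, lapply(ops, function(op)
    (xyz %*% t(op$R) + matrix(op$t, nrow(xyz), 3L, byrow = TRUE)) %% 1))
  M <- frac_to_cart_matrix(cell)
  n <- nrow(allx)
  if (n < 2L) return(Inf)
  d <- allx[rep(seq_len(n), each = n), ] - allx[rep(seq_len(n), n), ]
  d <- d - round(d)                      # minimum image in fractional space
  keep <- rep(seq_len(n), each = n) < rep(seq_len(n), n)
  d <- d[keep, , drop = FALSE]
  # triclinic minimum image: check the 27 lattice neighbours
  best <- rep(Inf, nrow(d))
  for (da in -1:1) for (db in -1:1) for (dc in -1:1) {
    sh <- sweep(d, 2L, c(da, db, dc), "+")
    cart <- sh %*% t(M)
    best <- pmin(best, sqrt(rowSums(cart^2)))
  }
  min(best)
}

#' Random toy crystal structure
#'
#' Atoms drawn uniformly in the cell with unit scattering weights,
#' rejection-sampled so that no two symmetry-expanded atoms come closer
#' than \code{min_dist} Angstrom.  Reproducible by seed.
#'
#' @param sg space-group symbol or object.
#' @param n_atoms number of atoms (>= 1).
#' @param seed integer seed.
#' @param cell unit cell (default: a compact per-group toy cell).
#' @param min_dist minimum inter-atomic distance in Angstrom.
#' @return a \code{toy_model}.
#' @export
make_toy_structure <- function(sg, n_atoms = 30L, seed = 1L,
                               cell = default_cell(sg), min_dist = 0.5) {
  sg <- .as_space_group(sg)
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 1L) stop("`n_atoms` must be >= 1")
  set.seed(seed)
  xyz <- matrix(numeric(0), 0L, 3L)
  tries <- 0L
  while (nrow(xyz) < n_atoms) {
    cand <- matrix(stats::runif(3), 1L, 3L)
    trial <- rbind(xyz, cand)
    if (.min_distance(trial, cell, sg) >= min_dist) xyz <- trial
    tries <- tries + 1L
    if (tries > 200L * n_atoms)
      stop("could not place ", n_atoms, " atoms at min_dist = ", min_dist,
           " A in this cell; reduce n_atoms or min_dist")
  }
  toy_model(xyz, cell, sg)
}

# random allowed origin shift: uniform choice among discrete shifts plus
# uniform continuous components along polar axes
.random_allowed_shift <- function(sg) {
  disc <- sg$discrete_shifts
  t <- disc[sample.int(nrow(disc), 1L), ]
  pol <- which(sg$polar_mask)
  t[pol] <- stats::runif(length(pol))
  t
}

# resolution-dependent figure-of-merit model: a Gaussian fall-off
# exp(-2 pi^2 sigma_eff^2 / d^2) with sigma_eff (A) growing with the
# generator's noise settings; a documented stand-in for SHELXE sigma
# weights, not a fit to any real run
.fom_model <- function(d, coord_noise, phase_noise) {
  sigma_eff <- 0.3 + coord_noise + phase_noise / 240
  pmin(pmax(exp(-2 * pi^2 * sigma_eff^2 / d^2), 1e-3), 1)
}

#' Synthetic partial solution from a toy structure
#'
#' Takes a random atom subset of the model, jitters the coordinates,
#' computes phases by direct summation, optionally blends in a fraction of
#' the true phasor (emulating the pull toward the true map that density
#' modification exerts in real pipelines), adds wrapped Gaussian phase
#' noise, and finally applies a random allowed origin shift, which is
#' recorded.  Figures of merit follow a resolution-dependent fall-off tied
#' to the noise level.
#'
#' @param model a \code{toy_model} (the ground truth).
#' @param d_min resolution limit in Angstrom.
#' @param fraction fraction of atoms retained, in (0, 1].
#' @param coord_noise Gaussian cartesian coordinate jitter, Angstrom.
#' @param phase_noise wrapped Gaussian phase noise, degrees.
#' @param shift_mode "none" or "random_allowed".
#' @param dm_pull fraction in [0, 1) of the true unit phasor blended into
#'   the solution phasor before noise.
#' @param hkl optional shared Miller-index list.
#' @param truth optional pre-computed truth \code{phase_set} (required when
#'   \code{dm_pull > 0}; also supplies \code{hkl}).
#' @param id label.
#' @param seed integer seed (optional; the caller may manage the RNG).
#' @return list with \code{ps} (the \code{phase_set}) and
#'   \code{true_shift} (the fractional shift that maps the solution back
#'   onto the model origin; what a best-shift search recovers).
#' @export
make_partial_solution <- function(model, d_min = 2.5, fraction = 1,
                                  coord_noise = 0, phase_noise = 0,
                                  shift_mode = c("random_allowed", "none"),
                                  dm_pull = 0, hkl = NULL, truth = NULL,
                                  id = "sol", seed = NULL) {
  stopifnot(inherits(model, "toy_model"))
  shift_mode <- match.arg(shift_mode)
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  if (dm_pull < 0 || dm_pull >= 1) stop("`dm_pull` must be in [0, 1)")
  if (dm_pull > 0 && is.null(truth))
    stop("`dm_pull` > 0 requires the truth phase set")
  if (!is.null(seed)) set.seed(seed)
  sg <- space_group(model$sg_symbol)
  if (is.null(hkl))
    hkl <- if (!is.null(truth)) truth$hkl
           else unique_reflections(model$cell, sg, d_min)

  if (fraction == 1 && coord_noise == 0 && !is.null(truth)) {
    # whole-model copy: reuse the truth structure factors
    ps <- truth
    ps$id <- id
    ps$meta <- list()
  } else {
    n <- nrow(model$xyz)
    k <- max(1L, ceiling(fraction * n))
    sub <- sort(sample.int(n, k))
    xyz <- model$xyz[sub, , drop = FALSE]
    if (coord_noise > 0) {
      M <- frac_to_cart_matrix(model$cell)
      jitter <- matrix(stats::rnorm(3L * k, sd = coord_noise), k, 3L)
      xyz <- (xyz + jitter %*% t(solve(M))) %% 1
    }
    part <- toy_model(xyz, model$cell, sg, weights = model$weights[sub])
    ps <- phases_from_model(part, d_min, hkl = hkl, id = id)
  }
  if (dm_pull > 0) {
    u <- (1 - dm_pull) * exp(1i * ps$phi * pi / 180) +
         dm_pull * exp(1i * truth$phi * pi / 180)
    ps$phi <- (Arg(u) * 180 / pi) %% 360
  }
  if (phase_noise > 0)
    ps$phi <- (ps$phi + stats::rnorm(nrow(hkl), sd = phase_noise)) %% 360
  d <- d_spacing(hkl, model$cell)
  ps$fom <- .fom_model(d, coord_noise, phase_noise)
  true_shift <- c(0, 0, 0)
  if (shift_mode == "random_allowed") {
    applied <- .random_allowed_shift(sg)
    ps <- apply_origin_shift(ps, applied)
    # record the inverse: the shift that maps the solution back onto the
    # model origin, which is what a best-shift search recovers
    true_shift <- (-applied) %% 1
  }
  list(ps = ps, true_shift = true_shift)
}

#' Synthetic solution landscape
#'
#' Emulates the landscape of partial solutions produced by fragment-based
#' phasing: a minority of correct solutions derived from the ground-truth
#' structure (noisy atom subsets, optionally phase-noised copies), a
#' majority of wrong solutions built from freshly drawn unrelated atom sets
#' of the same size, all carrying random allowed origin shifts and CC/LLG
#' style meta scores whose correct/wrong distributions overlap.
#'
#' @param model ground-truth \code{toy_model}.
#' @param n_correct,n_wrong population sizes (sum >= 1).
#' @param fraction atom fraction per solution.
#' @param coord_noise coordinate jitter, Angstrom.
#' @param phase_noise wrapped Gaussian phase noise, degrees.
#' @param dm_pull truth-phasor blend fraction for correct solutions.
#' @param d_min resolution limit, Angstrom.
#' @param shift_mode "random_allowed" (default) or "none".
#' @param seed integer seed; the landscape is reproducible from it.
#' @return object of class \code{"solution_landscape"}: list with
#'   \code{truth} (phase set of the full model), \code{solutions},
#'   \code{labels} ("correct"/"wrong"), \code{true_shifts} (matrix),
#'   \code{wmpe} (wMPE of every solution against truth, computed at the
#'   recorded shift) and \code{params}.
#' @export
make_landscape <- function(model, n_correct = 10L, n_wrong = 20L,
                           fraction = 1, coord_noise = 0, phase_noise = 40,
                           dm_pull = 0, d_min = 2.5,
                           shift_mode = "random_allowed", seed = 1L) {
  stopifnot(inherits(model, "toy_model"))
  n_correct <- as.integer(n_correct); n_wrong <- as.integer(n_wrong)
  if (n_correct + n_wrong < 1L) stop("need at least one solution")
  set.seed(seed)
  sg <- space_group(model$sg_symbol)
  hkl <- unique_reflections(model$cell, sg, d_min)
  truth <- phases_from_model(model, d_min, hkl = hkl, id = "truth")

  sols <- vector("list", n_correct + n_wrong)
  shifts <- matrix(0, n_correct + n_wrong, 3L)
  labels <- c(rep("correct", n_correct), rep("wrong", n_wrong))
  n_sub <- max(1L, ceiling(fraction * nrow(model$xyz)))
  for (i in seq_len(n_correct + n_wrong)) {
    if (labels[i] == "correct") {
      out <- make_partial_solution(model, d_min = d_min, fraction = fraction,
                                   coord_noise = coord_noise,
                                   phase_noise = phase_noise,
                                   shift_mode = shift_mode,
                                   dm_pull = dm_pull, hkl = hkl,
                                   truth = truth,
                                   id = sprintf("sol_%03d", i))
      cc <- stats::rnorm(1, 30, 6)
    } else {
      # unrelated structure of the same size; no distance rejection needed
      # for a noise model
      rnd <- toy_model(matrix(stats::runif(3L * n_sub), n_sub, 3L),
                       model$cell, sg)
      out <- make_partial_solution(rnd, d_min = d_min, fraction = 1,
                                   coord_noise = 0, phase_noise = 0,
                                   shift_mode = shift_mode, hkl = hkl,
                                   id = sprintf("sol_%03d", i))
      cc <- stats::rnorm(1, 22, 6)
    }
    out$ps$meta <- list(CC = round(max(cc, 1), 2),
                        LLG = round(max(cc, 1) * 1.5 + stats::rnorm(1, 0, 4), 1))
    sols[[i]] <- out$ps
    shifts[i, ] <- out$true_shift
  }
  # wMPE at the recorded shift (undo the applied origin shift)
  wmpe <- vapply(seq_along(sols), function(i) {
    wmpd(truth, apply_origin_shift(sols[[i]], shifts[i, ]))
  }, numeric(1))
  structure(list(truth = truth, solutions = sols, labels = labels,
                 true_shifts = shifts, wmpe = wmpe,
                 params = list(n_atoms = nrow(model$xyz),
                               n_correct = n_correct, n_wrong = n_wrong,
                               fraction = fraction, coord_noise = coord_noise,
                               phase_noise = phase_noise, dm_pull = dm_pull,
                               d_min = d_min, seed = seed)),
            class = "solution_landscape")
}

#' @export
print.solution_landscape <- function(x, ...) {
  cat("Solution landscape:", length(x$solutions), "solutions (",
      sum(x$labels == "correct"), "correct /", sum(x$labels == "wrong"),
      "wrong ),", nrow(x$truth$hkl), "reflections\n")
  cat(sprintf("  wMPE correct: %.1f deg (mean)   wrong: %.1f deg (mean)\n",
              mean(x$wmpe[x$labels == "correct"]),
              mean(x$wmpe[x$labels == "wrong"])))
  invisible(x)
}

#' Write a landscape to a directory of .phs files
#'
#' One .phs file per solution plus the truth set and a
#' \code{truth.tsv} table (id, label, true shift, wMPE) for benchmarking.
#'
#' @param land a \code{solution_landscape}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_landscape <- function(land, dir) {
  stopifnot(inherits(land, "solution_landscape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phs(land$truth, file.path(dir, "truth.phs"))
  for (ps in land$solutions)
    write_phs(ps, file.path(dir, paste0(ps$id, ".phs")))
  df <- data.frame(id = vapply(land$solutions, `[[`, "", "id"),
                   label = land$labels,
                   shift_a = land$true_shifts[, 1],
                   shift_b = land$true_shifts[, 2],
                   shift_c = land$true_shifts[, 3],
                   wmpe = round(land$wmpe, 3))
  utils::write.table(df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
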