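# Direct structure-factor summation from toy coordinate models.
#
# Point atoms with unit (or supplied) scattering weights and no B factor:
# the phase relationships between partial models, not amplitude realism,
# drive every comparison algorithm here.

#' Toy coordinate model
#'
#' A minimal crystal-structure stand-in: fractional atomic coordinates with
#' per-atom scattering weights in a given cell and space group.
#'
#' @param xyz n x 3 matrix of fractional coordinates (reduced to [0,1)).
#' @param cell numeric(6) unit-cell parameters.
#' @param sg space-group symbol or object.
#' @param weights per-atom scattering weights (> 0), recycled.
#' @return object of class \code{"toy_model"}.
#' @export
toy_model <- function(xyz, cell, sg, weights = 1) {
  xyz <- rbind(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("`xyz` must have three columns")
  weights <- rep_len(as.numeric(weights), nrow(xyz))
  if (any(weights <= 0)) stop("scattering weights must be positive")
  sg <- .as_space_group(sg)
  structure(list(xyz = xyz %% 1, cell = .check_cell(cell),
                 sg_symbol = sg$symbol, weights = weights),
            class = "toy_model")
}

#' @export
print.toy_model <- function(x, ...) {
  cat("Toy model:", nrow(x$xyz), "atoms,", x$sg_symbol, "\n")
  invisible(x)
}

#' Translate a toy model by a fractional shift
#'
#' Moves every atom by +t (reduced mod 1).  Moving the atoms by \code{-t}
#' is equivalent to moving the origin by \code{+t}, i.e. to
#' \code{\link{apply_origin_shift}} on the model's phase set when \code{t}
#' is an allowed origin shift.
#'
#' @param model a \code{toy_model}.
#' @param t fractional 3-vector.
#' @return the translated \code{toy_model}.
#' @export
shift_model <- function(model, t) {
  model$xyz <- sweep(model$xyz, 2L, as.numeric(t), "+") %% 1
  model
}

#' Unique reflections to a resolution limit
#'
#' Enumerates one representative per symmetry orbit (Friedel mates included
#' in the orbit), chosen by lexicographic maximality of (h, k, l), for all
#' reflections with d >= \code{d_min}.  Systematically absent reflections
#' (centring and screw-axis extinctions) are removed; the absence condition
#' is purely symmetry-derived, so every model in the same cell/group/cutoff
#' produces an identical list.
#'
#' @param cell numeric(6) unit-cell parameters.
#' @param sg space-group symbol or object.
#' @param d_min resolution limit in Angstrom.
#' @return n x 3 integer matrix of Miller indices.
#' @export
unique_reflections <- function(cell, sg, d_min) {
  sg <- .as_space_group(sg)
  cell <- .check_cell(cell)
  if (d_min <= 0) stop("`d_min` must be positive")
  hmax <- pmax(1L, as.integer(ceiling(sqrt(diag(cell_metric(cell))) / d_min)) + 1L)
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                                k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  d <- d_spacing(grid, cell)
  grid <- grid[d >= d_min, , drop = FALSE]
  storage.mode(grid) <- "integer"

  # orbit representative = lexicographic max over {h R} U {-h R}
  big <- max(hmax) * 4L + 1L
  key <- function(m) (m[, 1] * big + m[, 2]) * big + m[, 3]
  best <- rep(-Inf, nrow(grid))
  bestm <- grid
  for (op in sg$ops) {
    for (sgn in c(1, -1)) {
      tr <- sgn * (grid %*% op$R)
      kk <- key(tr)
      upd <- kk > best
      best[upd] <- kk[upd]
      bestm[upd, ] <- tr[upd, , drop = FALSE]
    }
  }
  is_rep <- key(grid) == best
  refl <- grid[is_rep, , drop = FALSE]

  # systematic absences: h absent iff sum over ops with hR == h of
  # exp(2 pi i h.t) vanishes
  nops <- length(sg$ops)
  acc <- complex(real = rep(0, nrow(refl)))
  cnt <- numeric(nrow(refl))
  for (op in sg$ops) {
    hr <- refl %*% op$R
    fixed <- rowSums(hr == refl) == 3L
    ph <- 2 * pi * (refl %*% op$t)
    acc[fixed] <- acc[fixed] + exp(1i * ph[fixed])
    cnt <- cnt + fixed
  }
  present <- Mod(acc) > 1e-8
  refl <- refl[present, , drop = FALSE]
  # stable order: by d-spacing descending, then lexicographic
  dref <- d_spacing(refl, cell)
  o <- order(-dref, refl[, 1], refl[, 2], refl[, 3])
  refl <- refl[o, , drop = FALSE]
  dimnames(refl) <- NULL
  refl
}

# complex structure factors for a model on a given hkl list
.structure_factors <- function(model, hkl) {
  sg <- space_group(model$sg_symbol)
  n <- nrow(hkl)
  fc <- complex(real = rep(0, n))
  xt <- t(model$xyz)                       # 3 x m
  for (op in sg$ops) {
    hr <- hkl %*% op$R                     # n x 3
    ph <- 2 * pi * (hr %*% xt +            # n x m
                    drop(hkl %*% op$t))
    fc <- fc + (cos(ph) + 1i * sin(ph)) %*% model$weights
  }
  drop(fc)
}

#' Phases from a coordinate model by direct summation
#'
#' F(h) and phi(h) from the symmetry-expanded point-atom sum
#' F(h) = sum over ops, atoms of w_j exp(2 pi i h.(R x_j + t)), for all
#' unique reflections with d >= \code{d_min}.  Figures of merit are set
#' to 1.
#'
#' @param model a \code{toy_model}.
#' @param d_min resolution limit in Angstrom.
#' @param hkl optional pre-computed Miller-index matrix (to guarantee an
#'   identical reflection list across several models).
#' @param id label for the resulting phase set.
#' @return a \code{phase_set}.
#' @export
phases_from_model <- function(model, d_min, hkl = NULL, id = "model") {
  stopifnot(inherits(model, "toy_model"))
  if (is.null(hkl)) hkl <- unique_reflections(model$cell, model$sg_symbol, d_min)
  if (!nrow(hkl))
    stop("no reflections at or below d_min = ", d_min, " A for this cell")
  fc <- .structure_factors(model, hkl)
  phase_set(hkl = hkl, f = Mod(fc), fom = rep(1, nrow(hkl)),
            phi = (Arg(fc) * 180 / pi) %% 360,
            cell = model$cell, sg = model$sg_symbol, id = id)
}

#' Read a toy model from a PDB file
#'
#' Reads ATOM/HETATM orthogonal coordinates via the bio3d package and
#' converts them to fractional coordinates using the CRYST1 cell if present,
#' else the supplied cell.  All atoms get unit scattering weight.
#'
#' @param path PDB file path.
#' @param sg space-group symbol or object.
#' @param cell optional numeric(6); overrides the CRYST1 record.
#' @return a \code{toy_model}.
#' @export
read_pdb_model <- function(path, sg, cell = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_pdb_model() requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  if (is.null(cell)) {
    cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
    if (!length(cr)) stop("no CRYST1 record and no `cell` supplied")
    cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                         substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                         substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  }
  xyz <- matrix(pdb$xyz, ncol = 3L, byrow = TRUE)
  frac <- t(solve(frac_to_cart_matrix(cell), t(xyz)))
  toy_model(frac, cell, sg)
}
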