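# The phase-set container: per-reflection Miller indices, amplitudes,
# figures of merit and phases, plus the unit-cell / space-group context.

#' Construct a phase set
#'
#' A phase set holds one partial solution's reflections: Miller indices,
#' amplitudes F, per-reflection figures of merit m in [0,1] (SHELXE-style
#' sigma weights) and phases phi in degrees, together with the unit cell and
#' space-group symbol they refer to.  Phases are stored modulo 360.
#'
#' @param hkl n x 3 integer matrix of Miller indices (no duplicates).
#' @param f numeric(n), amplitudes, >= 0.
#' @param fom numeric(n), figures of merit in [0, 1].
#' @param phi numeric(n), phases in degrees (any real; stored mod 360).
#' @param cell numeric(6) unit-cell parameters (Angstrom, degrees).
#' @param sg space-group symbol or \code{space_group} object.
#' @param id character label.
#' @param meta optional named list of solution-level scores (e.g. LLG, ZSCORE,
#'   CC) used only for sorting and reporting.
#' @return object of class \code{"phase_set"}.
#' @export
phase_set <- function(hkl, f, fom, phi, cell, sg, id = "ps", meta = list()) {
  hkl <- rbind(hkl)
  storage.mode(hkl) <- "integer"
  n <- nrow(hkl)
  if (ncol(hkl) != 3L) stop("`hkl` must have three columns")
  f <- as.numeric(f); fom <- as.numeric(fom); phi <- as.numeric(phi)
  if (length(f) != n || length(fom) != n || length(phi) != n)
    stop("hkl, f, fom and phi must have one entry per reflection")
  if (anyNA(f) || any(f < 0)) stop("amplitudes must be non-negative")
  if (anyNA(fom) || any(fom < 0 | fom > 1))
    stop("figures of merit must lie in [0, 1]")
  if (anyDuplicated(paste(hkl[, 1], hkl[, 2], hkl[, 3])))
    stop("duplicate Miller indices in phase set")
  sg <- .as_space_group(sg)
  structure(list(id = as.character(id),
                 cell = .check_cell(cell),
                 sg_symbol = sg$symbol,
                 hkl = hkl,
                 f = f,
                 fom = fom,
                 phi = phi %% 360,
                 meta = meta),
            class = "phase_set")
}

#' @export
print.phase_set <- function(x, ...) {
  cat("Phase set '", x$id, "': ", nrow(x$hkl), " reflections, ",
      x$sg_symbol, ", cell ",
      paste(formatC(x$cell, format = "g"), collapse = " "), "\n", sep = "")
  d <- d_spacing(x$hkl, x$cell)
  cat(sprintf("  resolution %.2f - %.2f A, <fom> = %.3f\n",
              max(d), min(d), mean(x$fom)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

.n_refl <- function(ps) nrow(ps$hkl)

# shared-indexing check used by every pairwise operation
.check_same_indexing <- function(a, b) {
  if (!identical(dim(a$hkl), dim(b$hkl)) || !all(a$hkl == b$hkl))
    stop("phase sets are indexed over different reflection lists; ",
         "comparisons require identical hkl lists in the same order")
  if (!isTRUE(all.equal(a$cell, b$cell, tolerance = 1e-6)) ||
      !identical(a$sg_symbol, b$sg_symbol))
    stop("phase sets carry different cell or space-group context")
  invisible(TRUE)
}

#' Restrict a phase set to low resolution
#'
#' Keeps exactly the reflections with d-spacing >= \code{d_cut} (order
#' preserved).  Used to compare phase sets at a coarse resolution (4.0 A by
#' default in clustering; 3.5 A in P1) while merging at full resolution.
#'
#' @param ps a \code{phase_set}.
#' @param d_cut resolution cutoff in Angstrom (> 0).
#' @return a \code{phase_set} (possibly with zero reflections).
#' @export
cut_resolution <- function(ps, d_cut) {
  stopifnot(inherits(ps, "phase_set"))
  if (!is.numeric(d_cut) || d_cut <= 0) stop("`d_cut` must be positive")
  keep <- d_spacing(ps$hkl, ps$cell) >= d_cut
  out <- ps
  out$hkl <- ps$hkl[keep, , drop = FALSE]
  out$f <- ps$f[keep]
  out$fom <- ps$fom[keep]
  out$phi <- ps$phi[keep]
  out
}

#' Read a SHELXE-style .phs reflection file
#'
#' Parses whitespace-separated records "h k l F fom phi" (an optional seventh
#' column is ignored).  Blank lines and an all-zero terminator record are
#' skipped.  The .phs format carries no cell or symmetry, so both are
#' supplied by the caller and attached to the result.
#'
#' @param path file path.
#' @param cell numeric(6) unit-cell parameters.
#' @param sg space-group symbol or object.
#' @param id label for the phase set (default: file base name).
#' @param meta optional named list of solution scores.
#' @return a \code{phase_set}.
#' @export
read_phs <- function(path, cell, sg, id = NULL, meta = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("empty .phs file: ", path)
  toks <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(toks)
  bad <- which(nf < 6L)
  if (length(bad))
    stop("line ", lineno[bad[1]], " of ", path, ": expected at least 6 fields")
  m <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(toks, `[`, 1:6))), ncol = 6L, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("line ", lineno[bad], " of ", path, ": non-numeric field")
  }
  # drop an all-zero terminator record if present
  zero <- rowSums(abs(m)) == 0
  m <- m[!zero, , drop = FALSE]
  if (!nrow(m)) stop("empty .phs file (only terminator records): ", path)
  if (any(m[, 5] < 0 | m[, 5] > 1)) {
    bad <- which(m[, 5] < 0 | m[, 5] > 1)[1]
    stop("fom outside [0, 1] at record ", bad, " of ", path)
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  phase_set(hkl = m[, 1:3], f = m[, 4], fom = m[, 5], phi = m[, 6],
            cell = cell, sg = sg, id = id, meta = meta)
}

#' Write a phase set in .phs format
#'
#' Fixed-width whitespace-separated "h k l F fom phi" records, one per
#' reflection.  Round-trips through \code{\link{read_phs}} at 1e-4 on all
#' fields.
#'
#' @param ps a \code{phase_set} with at least one reflection.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_phs <- function(ps, path) {
  stopifnot(inherits(ps, "phase_set"))
  if (.n_refl(ps) == 0L) stop("refusing to write an empty phase set")
  rec <- sprintf("%4d %4d %4d %13.4f %7.4f %10.4f",
                 ps$hkl[, 1], ps$hkl[, 2], ps$hkl[, 3],
                 ps$f, ps$fom, ps$phi %% 360)
  writeLines(rec, path)
  invisible(path)
}
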