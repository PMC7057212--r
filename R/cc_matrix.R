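# Pairwise map-correlation matrices between solutions, the text input file
# for external CC-analysis programs, and a spectral embedding in which
# correct solutions attain larger vector norms than noise-level ones.

#' Pairwise map correlation matrix
#'
#' Computes the map correlation coefficient at the best allowed origin
#' shift for every unordered pair of solutions.  The comparisons are
#' independent, so they parallelize trivially; the parallel result equals
#' the serial result exactly.
#'
#' @param solutions list of at least two \code{phase_set}s sharing one
#'   reflection list.
#' @param sg \code{space_group} object or symbol.
#' @param n_cores workers for the pair loop.
#' @param resolution optional comparison resolution in Angstrom (pairs are
#'   compared on the reflections with d >= resolution).
#' @param algorithm,grid passed to \code{\link{best_origin_shift}}.
#' @return object of class \code{"cc_matrix"}: list with \code{n},
#'   \code{labels} and an \code{entries} data.frame (i, j, cc; 1-based,
#'   i < j, complete upper triangle).
#' @export
pairwise_mapcc <- function(solutions, sg, n_cores = 1L, resolution = NULL,
                           algorithm = "auto", grid = 64L) {
  if (length(solutions) < 2L)
    stop("need at least two solutions for a pairwise matrix")
  sg <- .as_space_group(sg)
  if (!is.null(resolution))
    solutions <- lapply(solutions, cut_resolution, d_cut = resolution)
  labels <- vapply(solutions, function(p) p$id, character(1))
  n <- length(solutions)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  one <- function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    best_origin_shift(solutions[[i]], solutions[[j]], sg, algorithm, grid)$mapcc
  }
  cc <- if (n_cores > 1L)
    unlist(parallel::mclapply(seq_len(nrow(pairs)), one, mc.cores = n_cores))
  else vapply(seq_len(nrow(pairs)), one, numeric(1))
  structure(list(n = n, labels = labels,
                 entries = data.frame(i = pairs[, 1], j = pairs[, 2], cc = cc)),
            class = "cc_matrix")
}

#' @export
print.cc_matrix <- function(x, ...) {
  cat("Pairwise mapCC matrix:", x$n, "solutions,",
      nrow(x$entries), "pairs, mean CC",
      sprintf("%.3f", mean(x$entries$cc)), "\n")
  invisible(x)
}

#' Dense symmetric matrix from a cc_matrix
#' @param x a \code{cc_matrix}.
#' @param ... unused.
#' @return n x n numeric matrix with unit diagonal.
#' @export
as.matrix.cc_matrix <- function(x, ...) {
  m <- x
  out <- diag(1, m$n)
  out[cbind(m$entries$i, m$entries$j)] <- m$entries$cc
  out[cbind(m$entries$j, m$entries$i)] <- m$entries$cc
  dimnames(out) <- list(m$labels, m$labels)
  out
}

#' Write a CC matrix in the external CC-analysis input format
#'
#' One line per pair, "i j cc" with 1-based indices and fixed decimal
#' precision, plus a two-column sidecar TSV mapping indices to solution
#' ids.
#'
#' @param m a \code{cc_matrix}.
#' @param path output path for the matrix file.
#' @param sidecar path for the index-to-id table (default:
#'   \code{paste0(path, ".ids.tsv")}).
#' @return \code{path}, invisibly.
#' @export
write_cc_input <- function(m, path, sidecar = paste0(path, ".ids.tsv")) {
  stopifnot(inherits(m, "cc_matrix"))
  if (!nrow(m$entries)) stop("empty CC matrix")
  writeLines(sprintf("%5d %5d %8.4f", m$entries$i, m$entries$j, m$entries$cc),
             path)
  utils::write.table(data.frame(index = seq_len(m$n), id = m$labels),
                     sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a CC-analysis input file
#' @param path matrix file written by \code{\link{write_cc_input}}.
#' @param labels optional solution ids.
#' @return a \code{cc_matrix}.
#' @export
read_cc_input <- function(path, labels = NULL) {
  df <- utils::read.table(path, col.names = c("i", "j", "cc"))
  n <- max(df$i, df$j)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  structure(list(n = n, labels = labels, entries = df), class = "cc_matrix")
}

#' Spectral embedding of a CC matrix
#'
#' Top-eigenpair embedding of the pairwise CC matrix, scaled so that dot
#' products of the embedded vectors approximate the CCs (negative
#' eigenvalues are clipped to zero).  In a landscape of partial solutions,
#' mutually consistent (correct) solutions attain vector norms approaching
#' 1 while noise-level solutions concentrate near the origin.
#'
#' @param m a \code{cc_matrix}.
#' @param ndim embedding dimension (>= 2).
#' @return list with \code{coords} (n x ndim matrix), \code{norms},
#'   \code{eigenvalues} and the least-squares \code{residual} between
#'   embedded dot products and the input CCs.
#' @export
cc_embed <- function(m, ndim = 2L) {
  stopifnot(inherits(m, "cc_matrix"))
  ndim <- as.integer(ndim)
  if (ndim < 2L) stop("`ndim` must be >= 2")
  M <- as.matrix(m)
  diag(M) <- 1
  eg <- eigen(M, symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(ndim)], 0)
  coords <- eg$vectors[, seq_len(ndim), drop = FALSE] %*% diag(sqrt(lam), ndim)
  rownames(coords) <- m$labels
  approx <- coords %*% t(coords)
  ut <- upper.tri(M)
  list(coords = coords,
       norms = sqrt(rowSums(coords^2)),
       eigenvalues = eg$values,
       residual = sqrt(mean((approx[ut] - M[ut])^2)))
}
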