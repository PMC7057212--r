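# Space-group symmetry: operators, polar-axis masks and allowed origin shifts.
#
# Only the groups needed for fragment-phasing comparisons are tabulated.
# The discrete origin shifts are the translations of the Euclidean normalizer
# on the non-polar axes (one representative per coset of the centring
# translations); along polar axes the origin is continuously free and the
# shift tables carry a zero component.

# parse "x,y,z"-style symmetry operator strings into rotation + translation
.parse_symop <- function(s) {
  parts <- strsplit(gsub(" ", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3L) stop("bad symmetry operator string: ", s)
  rot <- matrix(0L, 3L, 3L)
  tra <- numeric(3L)
  for (i in 1:3) {
    p <- parts[i]
    # variable terms
    for (j in 1:3) {
      v <- c("x", "y", "z")[j]
      if (grepl(paste0("-", v), p, fixed = TRUE)) rot[i, j] <- -1L
      else if (grepl(v, p, fixed = TRUE)) rot[i, j] <- 1L
    }
    # fractional translation term like 1/2, 1/4, 2/3
    m <- regmatches(p, regexpr("[0-9]+/[0-9]+", p))
    if (length(m) && nzchar(m)) {
      num <- as.numeric(strsplit(m, "/")[[1]])
      tra[i] <- num[1] / num[2]
      if (grepl(paste0("-", m), p, fixed = TRUE)) tra[i] <- -tra[i]
    }
  }
  list(R = rot, t = tra %% 1)
}

.expand_ops <- function(gp, centring) {
  ops <- lapply(gp, .parse_symop)
  out <- list()
  for (cv in centring)
    for (op in ops)
      out[[length(out) + 1L]] <- list(R = op$R, t = (op$t + cv) %% 1)
  out
}

.half <- c(0, 0.5)

.sg_defs <- list(
  "P1" = list(
    gp = "x,y,z",
    centring = list(c(0, 0, 0)),
    polar = c(TRUE, TRUE, TRUE),
    shifts = matrix(0, 1L, 3L)),
  "P21" = list(  # b unique
    gp = c("x,y,z", "-x,y+1/2,-z"),
    centring = list(c(0, 0, 0)),
    polar = c(FALSE, TRUE, FALSE),
    shifts = as.matrix(expand.grid(.half, 0, .half))),
  "C2" = list(   # b unique
    gp = c("x,y,z", "-x,y,-z"),
    centring = list(c(0, 0, 0), c(0.5, 0.5, 0)),
    polar = c(FALSE, TRUE, FALSE),
    shifts = as.matrix(expand.grid(.half, 0, .half))),
  "P212121" = list(
    gp = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
    centring = list(c(0, 0, 0)),
    polar = c(FALSE, FALSE, FALSE),
    shifts = as.matrix(expand.grid(.half, .half, .half))),
  "C2221" = list(
    gp = c("x,y,z", "-x,-y,z+1/2", "-x,y,-z+1/2", "x,-y,-z"),
    centring = list(c(0, 0, 0), c(0.5, 0.5, 0)),
    polar = c(FALSE, FALSE, FALSE),
    # (0,1/2,0)-type shifts are the centring images of the (1/2,0,0) ones
    shifts = as.matrix(expand.grid(.half, 0, .half))),
  "F222" = list(
    gp = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z"),
    centring = list(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)),
    polar = c(FALSE, FALSE, FALSE),
    shifts = cbind(c(0, .25, .5, .75), c(0, .25, .5, .75), c(0, .25, .5, .75))),
  "F23" = list(
    gp = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z",
           "z,x,y", "z,-x,-y", "-z,-x,y", "-z,x,-y",
           "y,z,x", "-y,z,-x", "y,-z,-x", "-y,-z,x"),
    centring = list(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)),
    polar = c(FALSE, FALSE, FALSE),
    shifts = cbind(c(0, .25, .5, .75), c(0, .25, .5, .75), c(0, .25, .5, .75))),
  "P63" = list(
    gp = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
           "-x,-y,z+1/2", "y,-x+y,z+1/2", "x-y,x,z+1/2"),
    centring = list(c(0, 0, 0)),
    polar = c(FALSE, FALSE, TRUE),
    shifts = matrix(0, 1L, 3L))
)

# accepts "P 21 21 21", "P212121" and unicode-subscript variants
.normalize_symbol <- function(symbol) {
  # map unicode subscript digits to plain digits
  s <- symbol
  subs <- c("₀" = "0", "₁" = "1", "₂" = "2", "₃" = "3",
            "₄" = "4", "₅" = "5", "₆" = "6", "₇" = "7",
            "₈" = "8", "₉" = "9")
  for (i in seq_along(subs)) s <- gsub(names(subs)[i], subs[[i]], s, fixed = TRUE)
  toupper(gsub("[ _()]", "", s))
}

#' Space-group symmetry information
#'
#' Builds the symmetry context used by every origin-shift search: the full
#' list of symmetry operators (centring included), the polar-axis mask (axes
#' along which the origin is continuously free), and the table of allowed
#' discrete origin shifts (one representative per coset of the centring
#' translations, components on non-polar axes only).
#'
#' Supported groups: P1, P21, C2, P212121, C2221, F222, F23, P63.  Symbols
#' are accepted in compact ("P212121") or spaced ("P 21 21 21") form.
#'
#' @param symbol Hermann-Mauguin symbol.
#' @return An object of class \code{"space_group"}: a list with elements
#'   \code{symbol}, \code{ops} (list of \code{list(R, t)}), \code{polar_mask}
#'   (logical(3)) and \code{discrete_shifts} (matrix, one shift per row).
#' @examples
#' sg <- space_group("P 21 21 21")
#' nrow(sg$discrete_shifts)  # 8
#' @export
space_group <- function(symbol) {
  key <- .normalize_symbol(symbol)
  def <- .sg_defs[[key]]
  if (is.null(def))
    stop("unsupported space group: '", symbol, "' (supported: ",
         paste(names(.sg_defs), collapse = ", "), ")")
  shifts <- def$shifts
  dimnames(shifts) <- NULL
  structure(list(symbol = key,
                 ops = .expand_ops(def$gp, def$centring),
                 polar_mask = def$polar,
                 discrete_shifts = shifts),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat("Space group", x$symbol, "-", length(x$ops), "symmetry operators\n")
  pol <- c("a", "b", "c")[x$polar_mask]
  cat("  polar axes:",
      if (length(pol)) paste(pol, collapse = ", ") else "none", "\n")
  cat("  allowed discrete origin shifts:", nrow(x$discrete_shifts), "\n")
  invisible(x)
}

.is_space_group <- function(x) inherits(x, "space_group")

.as_space_group <- function(sg) {
  if (.is_space_group(sg)) sg else space_group(sg)
}

#' Enumerate allowed origin shifts
#'
#' Combines the discrete origin-shift table with a sampling grid along the
#' polar axes.  For nonpolar groups the grid is ignored and exactly the
#' discrete shifts are returned.
#'
#' @param sg a \code{space_group} object or symbol.
#' @param polar_grid number of grid points per polar axis (>= 1).
#' @return matrix of fractional shifts, one per row.
#' @examples
#' nrow(allowed_origin_shifts(space_group("C2"), polar_grid = 8))  # 32
#' @export
allowed_origin_shifts <- function(sg, polar_grid = 1L) {
  sg <- .as_space_group(sg)
  polar_grid <- as.integer(polar_grid)
  if (is.na(polar_grid) || polar_grid < 1L) stop("`polar_grid` must be >= 1")
  disc <- sg$discrete_shifts
  if (!any(sg$polar_mask) || polar_grid == 1L) return(disc)
  axes <- which(sg$polar_mask)
  grid1 <- seq(0, 1, length.out = polar_grid + 1L)[seq_len(polar_grid)]
  combos <- as.matrix(expand.grid(rep(list(grid1), length(axes))))
  out <- matrix(0, nrow(disc) * nrow(combos), 3L)
  k <- 0L
  for (i in seq_len(nrow(disc))) {
    for (j in seq_len(nrow(combos))) {
      k <- k + 1L
      row <- disc[i, ]
      row[axes] <- combos[j, ]
      out[k, ] <- row
    }
  }
  out
}
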