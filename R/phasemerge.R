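#' phasemerge: clustering and merging of crystallographic phase sets
#'
#' Compares partial-solution phase sets in reciprocal space under the origin
#' shifts allowed by the space group, clusters consistent solutions by
#' referential clustering on the weighted mean phase difference, and merges
#' each cluster into an averaged phase set.  See \code{\link{phasemerge}}
#' for the main entry point and the package vignette for the method.
#'
#' @keywords internal
#' @importFrom graphics plot.new text title
#' @importFrom stats fft optimize rnorm runif setNames
#' @importFrom utils read.table write.table
"_PACKAGE"

#' Cluster and merge partial-solution phase sets
#'
#' The main entry point.  Takes the phase sets of many partial solutions
#' (one per placed-fragment hypothesis), clusters them by referential
#' clustering on the weighted mean phase difference at the best allowed
#' origin shift, and merges every cluster into an averaged phase set with a
#' combined figure of merit per reflection.  With a list of lists the
#' two-step protocol is used: combination within each group at
#' \code{cfg$tolerance}, then a second round across the group clusters at
#' \code{cfg$tolerance_round2}.
#'
#' @param solutions a list of \code{\link{phase_set}}s (one-step protocol)
#'   or a list of such lists (two-step protocol, one inner list per group,
#'   e.g. per rotation cluster).
#' @param sg \code{\link{space_group}} object or Hermann-Mauguin symbol.
#' @param cfg a \code{\link{merge_config}}.
#' @return an object of class \code{"phasemerge_report"} with print,
#'   summary, plot and as.data.frame methods; its \code{clusters} element
#'   holds the merged phase sets (writable with \code{\link{write_phs}}).
#' @examples
#' model <- make_toy_structure("P212121", n_atoms = 20, seed = 7)
#' land <- make_landscape(model, n_correct = 6, n_wrong = 4,
#'                        phase_noise = 30, d_min = 3.0, seed = 7)
#' rep <- phasemerge(land$solutions, space_group("P212121"),
#'                   merge_config(resolution = 4.0))
#' rep
#' @export
phasemerge <- function(solutions, sg, cfg = merge_config()) {
  if (length(solutions) && is.list(solutions[[1]]) &&
      !inherits(solutions[[1]], "phase_set"))
    run_two_step(solutions, sg, cfg)
  else
    run_one_step(solutions, sg, cfg)
}
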