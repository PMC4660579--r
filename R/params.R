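#' Geometry and detection parameters
#'
#' Central container for every distance/angle threshold used by the contact,
#' stacking, interface and ligand-classification operations. All values are
#' in angstroms (distances) or degrees (angles).
#'
#' Defaults: the polar-contact cutoff of 3.5 A is the conventional heavy-atom
#' hydrogen-bond interaction distance; stacking and interface cutoffs follow
#' common literature geometry (parallel pi-stacks: centroid separation
#' <= 4.5 A, interplanar angle <= 30 deg, in-plane centroid offset <= 2 A;
#' T-shaped: centroid separation <= 5.5 A, angle >= 60 deg; interface
#' residues: any cross-chain heavy-atom pair <= 4.5 A). No angular
#' donor-H-acceptor criterion is applied because hydrogens are dropped on
#' read. The N-/C-terminal domain boundary (thioredoxin-fold domain vs the
#' all-helical domain of a GST subunit) defaults to author residue 80 and
#' should be overridden per structure when known.
#'
#' @param polar_cutoff heavy-atom N/O/S--N/O/S contact cutoff (A).
#' @param nonpolar_cutoff C--C hydrophobic contact cutoff (A).
#' @param stack_parallel_dist,stack_parallel_angle,stack_parallel_offset
#'   centroid distance (A), interplanar angle (deg) and in-plane offset (A)
#'   limits for the parallel stacking class.
#' @param stack_tshape_dist,stack_tshape_angle centroid distance (A) and
#'   minimum interplanar angle (deg) for the T-shaped class.
#' @param interface_cutoff cross-chain heavy-atom cutoff defining interface
#'   residues (A).
#' @param flank_atom_cutoff ring-atom N--N / N--C cutoff admitting a His-His
#'   flank interaction on polar rather than stacking evidence (A).
#' @param domain_boundary last author residue number of the N-terminal
#'   domain; larger numbers are tagged C-terminal.
#' @return A named list of class `wafer_params`.
#' @export
#' @examples
#' p <- wafer_params(polar_cutoff = 3.2)
#' p$polar_cutoff
wafer_params <- function(polar_cutoff = 3.5,
                         nonpolar_cutoff = 4.0,
                         stack_parallel_dist = 4.5,
                         stack_parallel_angle = 30,
                         stack_parallel_offset = 2.0,
                         stack_tshape_dist = 5.5,
                         stack_tshape_angle = 60,
                         interface_cutoff = 4.5,
                         flank_atom_cutoff = 4.0,
                         domain_boundary = 80) {
  p <- list(
    polar_cutoff = polar_cutoff,
    nonpolar_cutoff = nonpolar_cutoff,
    stack_parallel_dist = stack_parallel_dist,
    stack_parallel_angle = stack_parallel_angle,
    stack_parallel_offset = stack_parallel_offset,
    stack_tshape_dist = stack_tshape_dist,
    stack_tshape_angle = stack_tshape_angle,
    interface_cutoff = interface_cutoff,
    flank_atom_cutoff = flank_atom_cutoff,
    domain_boundary = domain_boundary
  )
  stopifnot(all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && x > 0, TRUE)))
  class(p) <- "wafer_params"
  p
}

# classed error helper so callers can condition on failure modes
wafer_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "wafer_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
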