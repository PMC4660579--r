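# Metric primitives: distances, aromatic ring planes, pi-stacking classes,
# and heavy-atom polar contacts. Everything here is exact Euclidean geometry
# on the atom table; no energies, no electrostatics.

# ring atom sets used for plane fitting (His imidazole; Phe/Tyr phenyl;
# Trp six-membered ring)
RING_ATOMS <- list(
  HIS = c("CG", "ND1", "CE1", "NE2", "CD2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

POLAR_ELEMENTS <- c("N", "O", "S")

# full n_a x n_b Euclidean distance matrix between two coordinate matrices
cross_dist <- function(xa, xb) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

atom_xyz <- function(a) {
  if (is.data.frame(a)) as.numeric(a[1, c("x", "y", "z")]) else as.numeric(a)
}

#' Euclidean distance between two atoms
#'
#' @param a,b atoms as one-row data.frames (e.g. from [select_atom()]) or
#'   numeric xyz vectors.
#' @return distance in angstroms (full precision; round to 1 decimal for
#'   reporting).
#' @export
#' @examples
#' atom_distance(c(0, 0, 0), c(3, 4, 0)) # 5
atom_distance <- function(a, b) {
  pa <- atom_xyz(a); pb <- atom_xyz(b)
  stopifnot(length(pa) == 3, length(pb) == 3, all(is.finite(c(pa, pb))))
  sqrt(sum((pa - pb)^2))
}

#' Aromatic ring centroid and plane normal
#'
#' The centroid is the unweighted mean of the ring atoms; the normal is the
#' unit eigenvector of the smallest principal component of the centered ring
#' coordinates (i.e. the least-squares plane normal), with its sign
#' canonicalized toward positive z (first-atom convention on ties).
#'
#' @param res atom table (data.frame rows) of a single His/Phe/Tyr/Trp
#'   residue; alternate locations are reduced to the best conformer.
#' @return list with `centroid`, `normal`, `atoms_used`, `res_name`,
#'   `chain_id`, `seq_id`.
#' @export
ring_geometry <- function(res) {
  stopifnot(is.data.frame(res), nrow(res) > 0)
  res <- best_altloc(res)
  rn <- res$res_name[1]
  ring <- RING_ATOMS[[rn]]
  if (is.null(ring)) {
    wafer_stop("wafer_error_usage",
               "residue %s has no defined aromatic ring", rn)
  }
  idx <- match(ring, res$atom_name)
  if (anyNA(idx)) {
    wafer_stop("wafer_error_incomplete_ring",
               "%s %s:%s is missing ring atom(s): %s", rn,
               res$chain_id[1], res$seq_id[1],
               paste(ring[is.na(idx)], collapse = ", "))
  }
  xyz <- as.matrix(res[idx, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  sv <- svd(centered)
  normal <- sv$v[, 3]
  # sign convention: positive z component, else toward the first ring atom
  if (abs(normal[3]) > 1e-12) {
    if (normal[3] < 0) normal <- -normal
  } else if (sum(normal * centered[1, ]) < 0) {
    normal <- -normal
  }
  list(centroid = as.numeric(centroid), normal = as.numeric(normal),
       atoms_used = ring, res_name = rn,
       chain_id = res$chain_id[1], seq_id = res$seq_id[1])
}

#' Classify the stacking geometry of two aromatic residues
#'
#' Computes centroid separation, interplanar angle (folded into 0-90 deg so
#' normal sign never matters) and the in-plane offset of ring b's centroid
#' from ring a's axis, then classifies: `parallel` when separation, angle
#' and offset are all within the parallel thresholds; `t-shaped` when
#' separation is within the T-shape threshold and the angle at least the
#' T-shape minimum; otherwise `none`.
#'
#' @param res_a,res_b atom tables of two aromatic residues.
#' @param params a [wafer_params()] list.
#' @return `stacking_pair` list: `a`, `b` (residue addresses), `distance`,
#'   `angle`, `offset`, `class`.
#' @export
detect_stacking <- function(res_a, res_b, params = wafer_params()) {
  ga <- ring_geometry(res_a)
  gb <- ring_geometry(res_b)
  v <- gb$centroid - ga$centroid
  d <- sqrt(sum(v^2))
  cosang <- abs(sum(ga$normal * gb$normal))
  angle <- acos(min(1, max(-1, cosang))) * 180 / pi # folded to [0, 90]
  axial <- abs(sum(v * ga$normal))
  offset <- sqrt(max(0, d^2 - axial^2))

  cls <- "none"
  if (d <= params$stack_parallel_dist && angle <= params$stack_parallel_angle &&
      offset <= params$stack_parallel_offset) {
    cls <- "parallel"
  } else if (d <= params$stack_tshape_dist && angle >= params$stack_tshape_angle) {
    cls <- "t-shaped"
  }
  structure(
    list(
      a = list(chain_id = ga$chain_id, seq_id = ga$seq_id, res_name = ga$res_name),
      b = list(chain_id = gb$chain_id, seq_id = gb$seq_id, res_name = gb$res_name),
      distance = d, angle = angle, offset = offset, class = cls
    ),
    class = "stacking_pair"
  )
}

#' @export
print.stacking_pair <- function(x, ...) {
  cat(sprintf("<stacking_pair> %s%s:%s x %s%s:%s  d=%.2f A angle=%.1f deg offset=%.2f A  [%s]\n",
              x$a$res_name, x$a$chain_id, x$a$seq_id,
              x$b$res_name, x$b$chain_id, x$b$seq_id,
              x$distance, x$angle, x$offset, x$class))
  invisible(x)
}

# element vector with fallback inference from atom names
element_of <- function(atoms) {
  el <- atoms$element
  miss <- is.na(el) | el == ""
  el[miss] <- infer_element(atoms$atom_name[miss])
  el
}

#' Polar contacts between two atom groups
#'
#' All N/O/S--N/O/S atom pairs across the two groups at heavy-atom distance
#' `cutoff` or less, sorted ascending by distance. No donor/acceptor angular
#' criterion is applied (hydrogens are not kept).
#'
#' @param group_a,group_b atom tables (data.frame rows of a
#'   [structure_model][read_structure]).
#' @param cutoff maximum heavy-atom distance (A).
#' @return data.frame of contact records: address and name columns for both
#'   atoms, `distance`, `kind = "polar"`. Zero rows when no contact.
#' @export
polar_contacts <- function(group_a, group_b, cutoff = 3.5) {
  stopifnot(cutoff > 0)
  contact_pairs(group_a, group_b, cutoff,
                POLAR_ELEMENTS, POLAR_ELEMENTS, kind = "polar")
}

# shared pair scan; elements_* filter each side
contact_pairs <- function(group_a, group_b, cutoff, elements_a, elements_b,
                          kind) {
  empty <- data.frame(
    chain_a = character(), seq_a = integer(), res_a = character(),
    atom_a = character(), chain_b = character(), seq_b = integer(),
    res_b = character(), atom_b = character(), distance = numeric(),
    kind = character(), stringsAsFactors = FALSE
  )
  if (is.null(group_a) || is.null(group_b) ||
      nrow(group_a) == 0 || nrow(group_b) == 0) return(empty)
  ga <- group_a[element_of(group_a) %in% elements_a, , drop = FALSE]
  gb <- group_b[element_of(group_b) %in% elements_b, , drop = FALSE]
  if (nrow(ga) == 0 || nrow(gb) == 0) return(empty)

  dm <- cross_dist(ga[, c("x", "y", "z")], gb[, c("x", "y", "z")])
  hit <- which(dm <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  out <- data.frame(
    chain_a = ga$chain_id[hit[, 1]], seq_a = ga$seq_id[hit[, 1]],
    res_a = ga$res_name[hit[, 1]], atom_a = ga$atom_name[hit[, 1]],
    chain_b = gb$chain_id[hit[, 2]], seq_b = gb$seq_id[hit[, 2]],
    res_b = gb$res_name[hit[, 2]], atom_b = gb$atom_name[hit[, 2]],
    distance = dm[hit], kind = kind, stringsAsFactors = FALSE
  )
  out <- out[order(out$distance, out$chain_a, out$seq_a, out$atom_a,
                   out$chain_b, out$seq_b, out$atom_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# nonpolar (C-C) contacts, used for hydrophobic-interaction claims
nonpolar_contacts <- function(group_a, group_b, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  contact_pairs(group_a, group_b, cutoff, "C", "C", kind = "nonpolar")
}
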