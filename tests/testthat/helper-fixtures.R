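# Shared fixtures and independent oracles for the suite.

# one toy dimer reused across files (noise-free, fixed seed)
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_dimer(dimer_spec(seed = 42))
    cache
  }
})

GLY_PDB <- paste(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
  "END", sep = "\n")

# two single-glycine chains 60 A apart
FAR_CHAINS_PDB <- paste(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  N   GLY B   1      60.000   0.000   0.000  1.00  0.00           N",
  "ATOM      5  CA  GLY B   1      61.458   0.000   0.000  1.00  0.00           C",
  "ATOM      6  C   GLY B   1      62.009   1.420   0.000  1.00  0.00           C",
  "END", sep = "\n")

# minimal mmCIF with auth numbering differing from label numbering
MINI_CIF <- paste(c(
  "data_TOY",
  "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
  "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
  "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 N N . GLY A 1 1 ? 0.000 0.000 0.000 1.00 10.0 ? 5 GLY A N 1",
  "ATOM 2 C CA . GLY A 1 1 ? 1.458 0.000 0.000 1.00 10.0 ? 5 GLY A CA 1",
  "ATOM 3 C C . GLY A 1 1 ? 2.009 1.420 0.000 1.00 10.0 ? 5 GLY A C 1"),
  collapse = "\n")

# build an atom table row block (for synthetic geometry fixtures)
mk_atoms_df <- function(names, xyz, res_name, chain = "A", seq_id = 1L,
                        record = "ATOM") {
  data.frame(
    record = record, atom_name = names, altloc = "", res_name = res_name,
    chain_id = chain, seq_id = as.integer(seq_id), ins_code = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    element = wafermotif:::infer_element(names),
    is_hetero = record == "HETATM", stringsAsFactors = FALSE
  )
}

# regular planar ring with Phe naming, radius r, in the z = zc plane
hexagon_res <- function(center = c(0, 0, 0), r = 1.39, seq_id = 1L,
                        chain = "A") {
  ang <- seq(0, 300, by = 60) * pi / 180
  xyz <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang),
               center[3])
  mk_atoms_df(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), xyz, "PHE",
              chain = chain, seq_id = seq_id)
}

# random proper rotation matrix from a normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_rot(q)
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

apply_rigid <- function(xyz, rot, shift) {
  sweep(as.matrix(xyz) %*% t(rot), 2, shift, "+")
}

# rigidly move every atom of a structure model
transform_model <- function(model, rot, shift) {
  xyz <- apply_rigid(as.matrix(model$atoms[, c("x", "y", "z")]), rot, shift)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# independent brute-force polar-contact oracle: plain double loop
brute_polar <- function(ga, gb, cutoff) {
  pol <- c("N", "O", "S")
  out <- NULL
  for (i in seq_len(nrow(ga))) {
    if (!ga$element[i] %in% pol) next
    for (j in seq_len(nrow(gb))) {
      if (!gb$element[j] %in% pol) next
      d <- sqrt(sum((as.numeric(ga[i, c("x", "y", "z")]) -
                       as.numeric(gb[j, c("x", "y", "z")]))^2))
      if (d <= cutoff) {
        out <- rbind(out, data.frame(
          atom_a = ga$atom_name[i], seq_a = ga$seq_id[i],
          atom_b = gb$atom_name[j], seq_b = gb$seq_id[j], distance = d,
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# random atom group with mixed elements scattered in a box
random_group <- function(n, chain = "A", box = 12) {
  els <- sample(c("N", "O", "S", "C"), n, replace = TRUE)
  names_ <- paste0(els, seq_len(n))
  mk_atoms_df(names_, matrix(stats::runif(3 * n, 0, box), ncol = 3),
              res_name = "LIG", chain = chain,
              seq_id = sample(1:50, n, replace = TRUE))
}
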