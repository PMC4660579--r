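# Deterministic synthetic fixtures: a toy GST-like homodimer with a planted
# histidine wafer motif and GSH-named ligands, noisy homolog ensembles, and
# alignments with controlled per-column conservation.
#
# Toy residues are chemically minimal but name-complete (full imidazole ring
# for His, OG for Ser, the complete GSH chemical-component atom-name set),
# because every geometric operation in this package consumes only names and
# coordinates. Backbone geometry is idealized and not sterically valid.

#' Specification for a planted toy dimer
#'
#' Defines the geometry [make_toy_dimer()] plants. Defaults describe a
#' tight, idealized wafer: four coaxial parallel imidazole rings (clasp
#' His101 pair in the middle, flank His69 rings outside), each supporting
#' serine's OG on an in-plane radial 2.55 A from a His ring nitrogen, and a
#' GSH-named ligand per subunit whose glutamyl carboxylate is planted at
#' hydrogen-bond distance of Ser68 (OG--O11 = `gsh_o11_distance`, N--O11 =
#' 3.0 A) and His69 (ND1--O12 ~ 2.9 A). Distances sit at the short end of
#' the physical range so that planted contacts keep a detection margin of
#' several standard deviations of the distance jitter across the
#' generator's supported noise range (sigma <= 0.3 A).
#'
#' @param clasp_seq,flank_seq author numbers of the clasp and flank
#'   histidines (His101 / His69 equivalents).
#' @param ser_seq author numbers of the three supporting serines; the first
#'   supports the flank His and anchors the GSH site.
#' @param clasp_separation,flank_separation ring-plane separations (A).
#' @param ser_og_distance Ser OG to His ring-nitrogen distance (A).
#' @param gsh_o11_distance Ser OG to GSH O11 distance (A).
#' @param n_filler glycine filler residues per chain, placed on a distant
#'   spiral so they never touch the interface.
#' @param n_waters water (HOH) oxygens, far from both chains.
#' @param sigma coordinate noise: each residue (and each ligand/water) is
#'   displaced as a rigid unit by an isotropic Gaussian with this standard
#'   deviation per coordinate. Rigid-unit noise preserves internal
#'   stereochemistry (ring planarity in particular), as real coordinate
#'   error does.
#' @param with_motif `FALSE` relocates the motif residues and ligands onto
#'   the distant spiral, yielding a motif-free dimer with the same
#'   composition.
#' @param seed integer; fully determines the output.
#' @return a `dimer_spec` list.
#' @export
dimer_spec <- function(clasp_seq = 101L, flank_seq = 69L,
                       ser_seq = c(68L, 104L, 163L),
                       clasp_separation = 3.2, flank_separation = 3.4,
                       ser_og_distance = 2.55, gsh_o11_distance = 2.9,
                       n_filler = 20L, n_waters = 6L,
                       sigma = 0, with_motif = TRUE, seed = 1L) {
  stopifnot(length(ser_seq) == 3, sigma >= 0, n_filler >= 0, n_waters >= 0)
  structure(
    list(clasp_seq = as.integer(clasp_seq), flank_seq = as.integer(flank_seq),
         ser_seq = as.integer(ser_seq),
         clasp_separation = clasp_separation,
         flank_separation = flank_separation,
         ser_og_distance = ser_og_distance,
         gsh_o11_distance = gsh_o11_distance,
         n_filler = as.integer(n_filler), n_waters = as.integer(n_waters),
         sigma = sigma, with_motif = isTRUE(with_motif),
         seed = as.integer(seed)),
    class = "dimer_spec"
  )
}

# run code with a private RNG state
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

mk_res <- function(names, xyz, res_name, chain, seq_id, record = "ATOM") {
  data.frame(
    record = record, atom_name = names, altloc = "",
    res_name = res_name, chain_id = chain, seq_id = as.integer(seq_id),
    ins_code = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = infer_element(names),
    is_hetero = record == "HETATM", stringsAsFactors = FALSE
  )
}

# idealized histidine: imidazole ring of radius 1.17 in the z = zc plane,
# centered on the z axis, backbone trailing off on the `up` side
toy_his <- function(seq_id, zc, phase, up, chain = "A") {
  r <- 1.17
  ring_names <- c("CG", "ND1", "CE1", "NE2", "CD2")
  ang <- (phase + c(0, 72, 144, 216, 288)) * pi / 180
  ring <- cbind(r * cos(ang), r * sin(ang), zc)
  rad <- function(radius, theta_deg, dz) {
    th <- theta_deg * pi / 180
    c(radius * cos(th), radius * sin(th), zc + dz * up)
  }
  xyz <- rbind(
    rad(4.6, phase + 15, 2.0),  # N
    rad(3.8, phase, 1.3),       # CA
    rad(4.6, phase - 15, 2.0),  # C
    rad(5.5, phase - 18, 2.3),  # O
    rad(2.69, phase, 0.5),      # CB
    ring
  )
  mk_res(c("N", "CA", "C", "O", "CB", ring_names), xyz, "HIS", chain, seq_id)
}

# ring-nitrogen position and outward radial of a toy_his residue
his_anchor <- function(his, atom) {
  n <- as.numeric(his[his$atom_name == atom, c("x", "y", "z")])
  centroid <- colMeans(as.matrix(
    his[his$atom_name %in% RING_ATOMS$HIS, c("x", "y", "z")]))
  u <- n - centroid
  u <- u / sqrt(sum(u^2))
  list(n = n, u = u, t = c(-u[2], u[1], 0), centroid = centroid)
}

# supporting serine: OG on the in-plane radial of one His ring nitrogen,
# backbone climbing away on the `up` side
toy_ser <- function(seq_id, his, atom, up, d_og, chain = "A") {
  a <- his_anchor(his, atom)
  og <- a$n + d_og * a$u
  zhat <- c(0, 0, 1)
  xyz <- rbind(
    og + 2.40 * a$u + 1.50 * up * zhat,            # N
    og + 2.40 * a$u + 0.55 * up * zhat,            # CA
    og + 2.40 * a$u + 0.55 * up * zhat + 1.3 * a$t, # C
    og + 3.00 * a$u + 0.90 * up * zhat + 1.9 * a$t, # O
    og + 1.30 * a$u + 0.55 * up * zhat,            # CB
    og                                             # OG
  )
  mk_res(c("N", "CA", "C", "O", "CB", "OG"), xyz, "SER", chain, seq_id)
}

GSH_TAIL <- c("CA1", "N1", "CB1", "CG1", "CD1", "OE1", "N2", "CA2", "CB2",
              "SG2", "C2", "O2", "N3", "CA3", "C3", "O31", "O32")

# Ser68 plus the GSH ligand, built in the local frame of the flank His ND1:
# OG = ND1 + d_og*u; O11 = OG + d_o11*t; O12 = O11 - 2.2*u (placing O12
# ~2.9 A from ND1); Ser N = O11 + 3.0*(0.6t + 0.8*away); the remaining 17
# GSH atoms zigzag away from the interface.
toy_gsh_site <- function(ser_seq, his, up, d_og, d_o11, chain = "A",
                         gsh_seq = 301L) {
  a <- his_anchor(his, "ND1")
  aw <- c(0, 0, up) # away from the interface plane
  og <- a$n + d_og * a$u
  o11 <- og + d_o11 * a$t
  o12 <- o11 - 2.2 * a$u
  # serine N planted 3.0 A from O11, on the opposite side of the ligand tail
  n_ser <- o11 + 3.0 * (0.8 * a$u - 0.6 * aw)
  ser_xyz <- rbind(
    n_ser,                              # N
    og + 2.80 * (0.85 * a$u + 0.53 * aw), # CA
    og + 2.80 * (0.85 * a$u + 0.53 * aw) + 1.3 * a$u, # C
    og + 2.80 * (0.85 * a$u + 0.53 * aw) + 2.0 * a$u + 0.6 * aw, # O
    og + 1.43 * (0.90 * a$u + 0.44 * aw), # CB
    og                                  # OG
  )
  ser <- mk_res(c("N", "CA", "C", "O", "CB", "OG"), ser_xyz, "SER",
                chain, ser_seq)

  c1 <- (o11 + o12) / 2 + 0.59 * aw
  w <- 0.5 * a$t + 0.866 * aw
  k <- seq_along(GSH_TAIL)
  tail_xyz <- t(vapply(k, function(i) {
    c1 + 1.35 * i * w + 0.55 * (i %% 2) * a$u
  }, numeric(3)))
  gsh <- mk_res(c("O11", "O12", "C1", GSH_TAIL),
                rbind(o11, o12, c1, tail_xyz),
                "GSH", chain, gsh_seq, record = "HETATM")
  list(ser = ser, gsh = gsh,
       planted = data.frame(
         protein_res = c("SER", "SER", "HIS"),
         protein_seq = c(ser_seq, ser_seq, his$seq_id[1]),
         protein_atom = c("OG", "N", "ND1"),
         gsh_atom = c("O11", "O11", "O12"),
         distance = c(d_o11, 3.0, sqrt(sum((o12 - a$n)^2))),
         stringsAsFactors = FALSE))
}

# distant spiral positions used for filler residues (and, in motif-free
# dimers, for the displaced motif residues)
spiral_centers <- function(n, radius = 16, z_range = c(-20, -4)) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  th <- (seq_len(n) * 137.5) * pi / 180
  z <- seq(z_range[1], z_range[2], length.out = max(n, 2))[seq_len(n)]
  cbind(radius * cos(th), radius * sin(th), z)
}

toy_gly <- function(seq_id, center, chain = "A") {
  radial <- c(center[1], center[2], 0)
  radial <- radial / sqrt(sum(radial^2))
  xyz <- rbind(
    center + 1.45 * radial,          # N
    center,                          # CA
    center - 1.50 * radial,          # C
    center - 2.10 * radial + c(0, 0, 0.8) # O
  )
  mk_res(c("N", "CA", "C", "O"), xyz, "GLY", chain, seq_id)
}

#' Generate a toy homodimer with a planted wafer motif
#'
#' Builds chain A explicitly, chain B as its exact two-fold image (rotation
#' by 180 deg about the x axis), so the dimer carries a crystallographic-style
#' C2 axis: the two clasp His rings stack across the interface at
#' `clasp_separation`, each flank His stacks against the partner clasp at
#' `flank_separation`, three serines per chain hold OG at `ser_og_distance`
#' from a motif His ring nitrogen, and a GSH-named ligand sits in each
#' subunit's site at the planted hydrogen-bond distances. Gaussian
#' rigid-residue noise `sigma` is then applied (see [dimer_spec()]).
#'
#' @param spec a [dimer_spec()].
#' @return list with `model` (a [structure_model][read_structure]) and
#'   `manifest`: the construction bookkeeping (planted clasp/flank pairs,
#'   serine supports, GSH contacts, interface residues, atom counts).
#' @export
#' @examples
#' toy <- make_toy_dimer(dimer_spec(seed = 7))
#' toy$manifest$counts$protein
make_toy_dimer <- function(spec = dimer_spec()) {
  stopifnot(inherits(spec, "dimer_spec"))
  local_seed(spec$seed, {
    z_clasp <- spec$clasp_separation / 2
    z_flank <- -z_clasp - spec$flank_separation

    if (spec$with_motif) {
      # ring phases park each ring's serine/ligand cluster in an angular
      # sector clear of the partner chain's descending backbones
      his_clasp <- toy_his(spec$clasp_seq, z_clasp, phase = 0, up = +1)
      his_flank <- toy_his(spec$flank_seq, z_flank, phase = 113, up = -1)
      site <- toy_gsh_site(spec$ser_seq[1], his_flank, up = -1,
                           d_og = spec$ser_og_distance,
                           d_o11 = spec$gsh_o11_distance)
      ser_b104 <- toy_ser(spec$ser_seq[2], his_clasp, "NE2", up = +1,
                          d_og = spec$ser_og_distance)
      ser_b163 <- toy_ser(spec$ser_seq[3], his_clasp, "ND1", up = +1,
                          d_og = spec$ser_og_distance)
      motif_res <- list(his_clasp, his_flank, site$ser, ser_b104, ser_b163)
      ligand <- site$gsh
      planted_gsh <- site$planted
    } else {
      # same composition, but everything scattered far from the interface
      centers <- spiral_centers(6, radius = 24, z_range = c(-26, -6))
      his_clasp <- toy_his(spec$clasp_seq, centers[1, 3], phase = 30, up = -1)
      his_clasp[, c("x", "y")] <- sweep(his_clasp[, c("x", "y")], 2,
                                        centers[1, 1:2], "+")
      his_flank <- toy_his(spec$flank_seq, centers[2, 3], phase = 75, up = -1)
      his_flank[, c("x", "y")] <- sweep(his_flank[, c("x", "y")], 2,
                                        centers[2, 1:2], "+")
      sers <- lapply(1:3, function(i) {
        g <- toy_gly(spec$ser_seq[i], centers[2 + i, ])
        g$res_name <- "SER"
        g
      })
      motif_res <- c(list(his_clasp, his_flank), sers)
      site <- toy_gsh_site(999L, his_flank, up = -1,
                           d_og = spec$ser_og_distance,
                           d_o11 = spec$gsh_o11_distance)
      ligand <- site$gsh
      planted_gsh <- NULL
      motif_res <- lapply(motif_res, function(r) r) # keep list shape
    }

    filler_ids <- setdiff(seq_len(spec$n_filler + 5L),
                          c(spec$clasp_seq, spec$flank_seq,
                            spec$ser_seq))[seq_len(spec$n_filler)]
    centers <- spiral_centers(spec$n_filler)
    filler <- lapply(seq_along(filler_ids), function(i) {
      toy_gly(filler_ids[i], centers[i, ])
    })

    chain_a <- do.call(rbind, c(motif_res, filler, list(ligand)))
    flip <- function(df) {
      df$y <- -df$y; df$z <- -df$z; df$chain_id <- "B"; df
    }
    chain_b <- flip(chain_a)

    waters <- if (spec$n_waters > 0) {
      th <- seq_len(spec$n_waters) * 77 * pi / 180
      mk_res(rep("O", spec$n_waters),
             cbind(30 * cos(th), 30 * sin(th),
                   -10 + 2 * seq_len(spec$n_waters)),
             "HOH", "S", 400L, record = "HETATM") -> w
      w$seq_id <- 400L + seq_len(spec$n_waters)
      w
    } else NULL

    atoms <- rbind(chain_a, chain_b, waters)
    rownames(atoms) <- NULL

    if (spec$sigma > 0) {
      keys <- residue_key(atoms)
      for (k in unique(keys)) {
        idx <- keys == k
        shift <- stats::rnorm(3, 0, spec$sigma)
        atoms$x[idx] <- atoms$x[idx] + shift[1]
        atoms$y[idx] <- atoms$y[idx] + shift[2]
        atoms$z[idx] <- atoms$z[idx] + shift[3]
      }
    }

    ord <- order(atoms$chain_id, atoms$is_hetero, atoms$seq_id)
    atoms <- atoms[ord, , drop = FALSE]
    rownames(atoms) <- NULL
    model <- new_structure_model("TOY-DIMER", "pdb", atoms)

    manifest <- list(
      spec = spec,
      counts = list(
        protein = sum(!atoms$is_hetero),
        water = sum(atoms$res_name %in% WATER_NAMES),
        hetero = sum(atoms$is_hetero & !atoms$res_name %in% WATER_NAMES),
        all = nrow(atoms)
      ),
      ligands = data.frame(comp_id = "GSH", owner_chain = c("A", "B"),
                           seq_id = 301L, stringsAsFactors = FALSE)
    )
    if (spec$with_motif) {
      manifest$planted <- list(
        clasp = list(seq_id = spec$clasp_seq,
                     separation = spec$clasp_separation),
        flanks = data.frame(
          his_a_chain = c("A", "B"), his_a_seq = spec$flank_seq,
          his_b_chain = c("B", "A"), his_b_seq = spec$clasp_seq,
          separation = spec$flank_separation, stringsAsFactors = FALSE),
        serines = data.frame(
          chain = rep(c("A", "B"), each = 3),
          seq_id = rep(spec$ser_seq, 2),
          supports_seq = rep(c(spec$flank_seq, spec$clasp_seq,
                               spec$clasp_seq), 2),
          distance = spec$ser_og_distance, stringsAsFactors = FALSE),
        gsh_contacts = planted_gsh,
        interface = data.frame(
          chain = rep(c("A", "B"), each = 5),
          seq_id = rep(c(spec$flank_seq, spec$clasp_seq, spec$ser_seq), 2),
          stringsAsFactors = FALSE)
      )
    } else {
      manifest$planted <- list(clasp = NULL, flanks = NULL, serines = NULL,
                               gsh_contacts = NULL,
                               interface = data.frame(chain = character(),
                                                      seq_id = integer()))
    }
    list(model = model, manifest = manifest)
  })
}

#' Perturbed copies of a structure
#'
#' Each copy displaces every heavy atom by i.i.d. Gaussian noise with
#' standard deviation `sigma` per coordinate, so the expected base-vs-copy
#' RMSD is `sigma * sqrt(3)` and the expected copy-vs-copy RMSD is
#' `sigma * sqrt(6)`.
#'
#' @param base a [structure_model][read_structure].
#' @param n number of copies.
#' @param sigma per-coordinate noise standard deviation (A).
#' @param seed integer seed; fully determines the ensemble.
#' @return list of `n` structure models.
#' @export
make_homolog_ensemble <- function(base, n, sigma, seed = 1L) {
  stopifnot(inherits(base, "structure_model"), n >= 1, sigma >= 0)
  local_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- base$atoms
      m <- nrow(a)
      a$x <- a$x + stats::rnorm(m, 0, sigma)
      a$y <- a$y + stats::rnorm(m, 0, sigma)
      a$z <- a$z + stats::rnorm(m, 0, sigma)
      new_structure_model(sprintf("%s-copy%d", base$structure_id, i),
                          base$source_format, a)
    })
  })
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate an alignment with controlled per-column conservation
#'
#' Background columns are drawn uniformly from the 20 amino acids.
#' `conserved` pins chosen columns: a single letter fixes the whole column;
#' a named frequency vector (summing to 1) plants exact letter counts by
#' largest-remainder apportionment, shuffled down the column.
#'
#' @param n_rows,n_cols alignment dimensions.
#' @param conserved named list: names are column indices (1-based), values
#'   single letters or named frequency vectors.
#' @param seed integer seed.
#' @return an `aa_alignment` (see [read_alignment()]).
#' @export
#' @examples
#' aln <- make_alignment(10, 6, conserved = list(`3` = "H",
#'                                               `5` = c(H = 0.6, N = 0.4)))
make_alignment <- function(n_rows, n_cols, conserved = list(), seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  local_seed(seed, {
    m <- matrix(sample(AA20, n_rows * n_cols, replace = TRUE),
                nrow = n_rows, ncol = n_cols)
    for (cn in names(conserved)) {
      j <- as.integer(cn)
      stopifnot(j >= 1, j <= n_cols)
      v <- conserved[[cn]]
      if (is.character(v) && length(v) == 1) {
        m[, j] <- v
      } else {
        stopifnot(is.numeric(v), !is.null(names(v)),
                  abs(sum(v) - 1) < 1e-9)
        counts <- floor(v * n_rows)
        rem <- v * n_rows - counts
        short <- n_rows - sum(counts)
        if (short > 0) {
          bump <- order(rem, decreasing = TRUE)[seq_len(short)]
          counts[bump] <- counts[bump] + 1
        }
        m[, j] <- sample(rep(names(v), counts))
      }
    }
    new_alignment(sprintf("seq%03d", seq_len(n_rows)), m)
  })
}
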