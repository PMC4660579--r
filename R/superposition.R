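# Rigid-body least-squares superposition (Kabsch), atom pairing between
# homologous structures, whole-structure RMSD, and motif side-chain spread
# across a superposed ensemble.

#' Kabsch superposition of two matched point sets
#'
#' Closed-form least-squares fit of `coords_b` onto `coords_a` over proper
#' rotations and translation. Reflections are excluded by the determinant
#' correction, so the returned rotation always has det +1. With weights the
#' weighted RMSD is minimized.
#'
#' @param coords_a,coords_b n x 3 matrices of matched coordinates (rows
#'   correspond).
#' @param weights optional nonnegative weights, length n.
#' @return `superposition_result`: list with `rotation` (3 x 3, proper
#'   orthonormal), `translation` (length 3), `rmsd`, `n_pairs`. The fitted
#'   copy of b is `coords_b %*% t(rotation) + translation` (rows).
#' @export
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' kabsch(a, a)$rmsd # 0
kabsch <- function(coords_a, coords_b, weights = NULL) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3) {
    wafer_stop("wafer_error_usage",
               "coordinate sets must be equal-size n x 3 matrices")
  }
  n <- nrow(a)
  if (n < 3) {
    wafer_stop("wafer_error_degenerate",
               "need at least 3 point pairs, got %d", n)
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  wn <- w / sum(w)

  ca <- colSums(a * wn); cb <- colSums(b * wn)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)

  # degeneracy: all points (near-)collinear leaves the rotation underdetermined
  spread <- svd(ac * sqrt(wn))$d
  if (spread[2] < 1e-8 * max(spread[1], 1e-12)) {
    wafer_stop("wafer_error_degenerate",
               "reference points are collinear; rotation underdetermined")
  }

  h <- crossprod(bc * wn, ac) # 3x3 covariance, maps b-frame to a-frame
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)

  fitted <- bc %*% t(rot)
  rmsd <- sqrt(sum(wn * rowSums((fitted - ac)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(ca - cb %*% t(rot)),
         rmsd = rmsd, n_pairs = n),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> rmsd = %.3f A over %d pairs\n",
              x$rmsd, x$n_pairs))
  invisible(x)
}

# apply a superposition transform to an n x 3 matrix (row coordinates)
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

# pin the pairwise-alignment parameters so chain pairing is reproducible
ALIGN_GAP_OPEN <- 10
ALIGN_GAP_EXT <- 0.5

align_chain_pair <- function(seq_a, seq_b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXT,
    type = "global"
  )
}

#' Pair atoms between two structures
#'
#' Produces a deterministic one-to-one pairing of polymer heavy atoms
#' (alternate locations reduced to the highest-occupancy conformer).
#' Policies: `identity` pairs atoms sharing chain id, author residue
#' number, insertion code and atom name; `align` first pairs polymer
#' chains by global sequence alignment score (BLOSUM62, affine gaps with
#' fixed penalties), then pairs common atom names within each aligned,
#' non-gap residue pair.
#'
#' @param model_a,model_b two [structure_model][read_structure]s.
#' @param policy `"identity"` or `"align"`.
#' @return `atom_pairing`: list with `pairs` (data.frame of matched atom
#'   addresses), `policy`, `n_pairs`, `chain_map`.
#' @export
match_atoms <- function(model_a, model_b, policy = c("identity", "align")) {
  policy <- match.arg(policy)
  pa <- best_altloc(polymer_atoms(model_a))
  pb <- best_altloc(polymer_atoms(model_b))
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    wafer_stop("wafer_error_empty_pairing", "a model has no polymer atoms")
  }

  if (policy == "identity") {
    key_a <- paste(pa$chain_id, pa$seq_id, pa$ins_code, pa$atom_name, sep = "|")
    key_b <- paste(pb$chain_id, pb$seq_id, pb$ins_code, pb$atom_name, sep = "|")
    ia <- match(key_b, key_a)
    keep <- !is.na(ia)
    pairs <- cbind(
      stats::setNames(pa[ia[keep], c("chain_id", "seq_id", "ins_code",
                                     "atom_name")],
                      c("chain_a", "seq_a", "ins_a", "atom")),
      stats::setNames(pb[keep, c("chain_id", "seq_id", "ins_code")],
                      c("chain_b", "seq_b", "ins_b"))
    )
    chain_map <- unique(pairs[, c("chain_a", "chain_b")])
  } else {
    chains_a <- polymer_chain_ids(model_a)
    chains_b <- polymer_chain_ids(model_b)
    seqs_a <- lapply(chains_a, function(ch) chain_sequence(model_a, ch))
    seqs_b <- lapply(chains_b, function(ch) chain_sequence(model_b, ch))
    names(seqs_a) <- chains_a; names(seqs_b) <- chains_b

    score <- matrix(-Inf, length(chains_a), length(chains_b),
                    dimnames = list(chains_a, chains_b))
    alns <- list()
    for (i in chains_a) {
      for (j in chains_b) {
        al <- align_chain_pair(seqs_a[[i]]$sequence, seqs_b[[j]]$sequence)
        score[i, j] <- Biostrings::score(al)
        alns[[paste(i, j)]] <- al
      }
    }
    # greedy assignment by descending score
    chain_map <- NULL
    sc <- score
    while (any(is.finite(sc))) {
      k <- which(sc == max(sc), arr.ind = TRUE)[1, , drop = FALSE]
      chain_map <- rbind(chain_map, data.frame(
        chain_a = rownames(sc)[k[1]], chain_b = colnames(sc)[k[2]],
        stringsAsFactors = FALSE))
      sc[k[1], ] <- -Inf
      sc[, k[2]] <- -Inf
    }

    pairs <- NULL
    for (r in seq_len(nrow(chain_map))) {
      i <- chain_map$chain_a[r]; j <- chain_map$chain_b[r]
      al <- alns[[paste(i, j)]]
      res_pairs <- aligned_residue_pairs(al, seqs_a[[i]], seqs_b[[j]])
      if (nrow(res_pairs) == 0) next
      ai <- pa[pa$chain_id == i, , drop = FALSE]
      bj <- pb[pb$chain_id == j, , drop = FALSE]
      key_ai <- paste(ai$seq_id, ai$ins_code, sep = "|")
      key_bj <- paste(bj$seq_id, bj$ins_code, sep = "|")
      for (q in seq_len(nrow(res_pairs))) {
        ra <- ai[key_ai == paste(res_pairs$seq_a[q], res_pairs$ins_a[q],
                                 sep = "|"), , drop = FALSE]
        rb <- bj[key_bj == paste(res_pairs$seq_b[q], res_pairs$ins_b[q],
                                 sep = "|"), , drop = FALSE]
        common <- intersect(ra$atom_name, rb$atom_name)
        if (length(common) == 0) next
        pairs <- rbind(pairs, data.frame(
          chain_a = i, seq_a = res_pairs$seq_a[q], ins_a = res_pairs$ins_a[q],
          atom = common,
          chain_b = j, seq_b = res_pairs$seq_b[q], ins_b = res_pairs$ins_b[q],
          stringsAsFactors = FALSE))
      }
    }
  }

  if (is.null(pairs) || nrow(pairs) == 0) {
    wafer_stop("wafer_error_empty_pairing",
               "no common atoms between %s and %s",
               model_a$structure_id, model_b$structure_id)
  }
  pairs <- pairs[order(pairs$chain_a, pairs$seq_a, pairs$ins_a, pairs$atom), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, policy = policy, n_pairs = nrow(pairs),
                 chain_map = chain_map),
            class = "atom_pairing")
}

polymer_atoms <- function(model) {
  a <- model$atoms
  a[!a$is_hetero & !is_water(a) & a$res_name %in% STANDARD_AA, , drop = FALSE]
}

# non-gap aligned residue pairs from a Biostrings global alignment
aligned_residue_pairs <- function(al, seq_a, seq_b) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- 0L; ib <- 0L
  out_a <- integer(0); out_b <- integer(0)
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ia <- ia + 1L
    if (sub[k] != "-") ib <- ib + 1L
    if (pat[k] != "-" && sub[k] != "-") {
      out_a <- c(out_a, ia); out_b <- c(out_b, ib)
    }
  }
  data.frame(seq_a = seq_a$seq_id[out_a], ins_a = seq_a$ins_code[out_a],
             seq_b = seq_b$seq_id[out_b], ins_b = seq_b$ins_code[out_b],
             stringsAsFactors = FALSE)
}

#' Whole-structure RMSD between two homologs
#'
#' Kabsch superposition over the atom pairing produced by [match_atoms()];
#' reports `n_pairs` alongside the RMSD.
#'
#' @inheritParams match_atoms
#' @return a [superposition_result][kabsch] (with the pairing attached as
#'   attribute `pairing`).
#' @export
structure_rmsd <- function(model_a, model_b, policy = c("identity", "align")) {
  pairing <- match_atoms(model_a, model_b, policy)
  xa <- pairing_coords(model_a, pairing$pairs, side = "a")
  xb <- pairing_coords(model_b, pairing$pairs, side = "b")
  fit <- kabsch(xa, xb)
  attr(fit, "pairing") <- pairing
  fit
}

pairing_coords <- function(model, pairs, side) {
  a <- best_altloc(polymer_atoms(model))
  key <- paste(a$chain_id, a$seq_id, a$ins_code, a$atom_name, sep = "|")
  want <- if (side == "a") {
    paste(pairs$chain_a, pairs$seq_a, pairs$ins_a, pairs$atom, sep = "|")
  } else {
    paste(pairs$chain_b, pairs$seq_b, pairs$ins_b, pairs$atom, sep = "|")
  }
  idx <- match(want, key)
  stopifnot(!anyNA(idx))
  as.matrix(a[idx, c("x", "y", "z")])
}

#' Side-chain positional spread of motif residues across structures
#'
#' Superposes every model onto the reference using the C-alpha atoms of the
#' given motif residues, then reports, per residue and model, the
#' root-mean-square deviation of side-chain heavy atoms (other than
#' N/CA/C/O, matched
#' by name) from the reference — a quantitative reading of how well
#' sequence conservation translates into side-chain position conservation.
#'
#' @param models list of [structure_model][read_structure]s.
#' @param motif data.frame with columns `chain_id`, `seq_id` (applied to
#'   every model), or a list of such data.frames, one per model.
#' @param reference index of the reference model.
#' @return data.frame: `chain_id`, `seq_id`, `model`, `rms_deviation` (A),
#'   one row per motif residue and non-reference model.
#' @export
motif_spread <- function(models, motif, reference = 1L) {
  stopifnot(length(models) >= 2)
  motifs <- if (is.data.frame(motif)) {
    rep(list(motif), length(models))
  } else {
    stopifnot(length(motif) == length(models))
    motif
  }
  get_res <- function(model, mt, i) {
    residue_atoms(model, mt$chain_id[i], mt$seq_id[i])
  }
  ref_mt <- motifs[[reference]]
  n_res <- nrow(ref_mt)
  ref_res <- lapply(seq_len(n_res), function(i) {
    get_res(models[[reference]], ref_mt, i)
  })
  ref_ca <- t(vapply(ref_res, function(r) {
    as.numeric(r[r$atom_name == "CA", c("x", "y", "z")][1, ])
  }, numeric(3)))

  out <- NULL
  for (m in seq_along(models)) {
    if (m == reference) next
    mt <- motifs[[m]]
    stopifnot(nrow(mt) == n_res)
    res_m <- lapply(seq_len(n_res), function(i) get_res(models[[m]], mt, i))
    ca_m <- t(vapply(res_m, function(r) {
      as.numeric(r[r$atom_name == "CA", c("x", "y", "z")][1, ])
    }, numeric(3)))
    fit <- kabsch(ref_ca, ca_m)
    for (i in seq_len(n_res)) {
      ra <- ref_res[[i]]
      rm_ <- res_m[[i]]
      side <- setdiff(intersect(ra$atom_name, rm_$atom_name),
                      c("N", "CA", "C", "O"))
      if (length(side) == 0) next
      pa <- as.matrix(ra[match(side, ra$atom_name), c("x", "y", "z")])
      pb <- apply_transform(
        as.matrix(rm_[match(side, rm_$atom_name), c("x", "y", "z")]), fit)
      out <- rbind(out, data.frame(
        seq_id = ref_mt$seq_id[i], chain_id = ref_mt$chain_id[i],
        model = m, rms_deviation = sqrt(mean(rowSums((pa - pb)^2))),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
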