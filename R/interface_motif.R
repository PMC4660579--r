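# Subunit-interface residue detection and the Epsilon wafer motif: a
# cross-interface stacked His-His "clasp" pair, flanking His-His
# interactions, and the serines whose OG hydrogen-bonds the motif.

# atoms of one residue, reduced to the best altloc conformer
residue_atoms <- function(model, chain_id, seq_id, ins_code = "") {
  a <- model$atoms
  r <- a[a$chain_id == chain_id & a$seq_id == seq_id &
           a$ins_code == ins_code, , drop = FALSE]
  if (nrow(r) == 0) {
    wafer_stop("wafer_error_lookup", "no residue %s:%s%s in %s",
               chain_id, seq_id, ins_code, model$structure_id)
  }
  best_altloc(r)
}

# unique residue addresses of an atom table
residue_index <- function(atoms) {
  first <- !duplicated(residue_key(atoms))
  data.frame(chain_id = atoms$chain_id[first], seq_id = atoms$seq_id[first],
             ins_code = atoms$ins_code[first],
             res_name = atoms$res_name[first], stringsAsFactors = FALSE)
}

#' Residues at a two-chain interface
#'
#' A residue belongs to the interface when any of its heavy atoms lies
#' within `cutoff` of any heavy atom of the partner chain. Only polymer
#' residues are considered; the result is symmetric under swapping the two
#' chains.
#'
#' @param model a [structure_model][read_structure].
#' @param chain_a,chain_b polymer chain ids.
#' @param cutoff heavy-atom distance cutoff (A).
#' @return `interface_set`: list with `chain_a`, `chain_b`, `cutoff`, and
#'   `residues_a`/`residues_b` data.frames (residue address plus
#'   `min_distance` to the partner chain).
#' @export
interface_residues <- function(model, chain_a, chain_b,
                               cutoff = wafer_params()$interface_cutoff) {
  stopifnot(inherits(model, "structure_model"))
  poly <- polymer_chain_ids(model)
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% poly) {
      wafer_stop("wafer_error_lookup", "no polymer chain '%s' in %s",
                 ch, model$structure_id)
    }
  }
  aa <- chain_atoms(model, chain_a)
  ab <- chain_atoms(model, chain_b)
  dm <- cross_dist(aa[, c("x", "y", "z")], ab[, c("x", "y", "z")])

  side <- function(atoms, dmin) {
    res <- residue_index(atoms)
    key <- residue_key(atoms)
    res$min_distance <- as.numeric(tapply(dmin, key, min)[
      paste(res$chain_id, res$seq_id, res$ins_code, sep = "|")])
    res <- res[res$min_distance <= cutoff, , drop = FALSE]
    res[order(res$seq_id, res$ins_code), , drop = FALSE]
  }
  structure(
    list(chain_a = chain_a, chain_b = chain_b, cutoff = cutoff,
         residues_a = side(aa, apply(dm, 1, min)),
         residues_b = side(ab, apply(dm, 2, min))),
    class = "interface_set"
  )
}

#' @export
print.interface_set <- function(x, ...) {
  cat(sprintf("<interface_set> %s/%s at %.1f A: %d + %d residues\n",
              x$chain_a, x$chain_b, x$cutoff,
              nrow(x$residues_a), nrow(x$residues_b)))
  invisible(x)
}

# all His residues of a chain that carry a complete imidazole ring
complete_his <- function(model, chain_id) {
  a <- chain_atoms(model, chain_id)
  h <- a[a$res_name == "HIS", , drop = FALSE]
  if (nrow(h) == 0) return(data.frame())
  idx <- residue_index(h)
  ok <- vapply(seq_len(nrow(idx)), function(i) {
    r <- best_altloc(h[h$seq_id == idx$seq_id[i] &
                         h$ins_code == idx$ins_code[i], , drop = FALSE])
    all(RING_ATOMS$HIS %in% r$atom_name)
  }, logical(1))
  idx[ok, , drop = FALSE]
}

#' Detect the histidine wafer interface motif
#'
#' Scans all cross-chain His-His pairs: the *clasp* is the best stacked
#' (class != none) pair, where pairs of equivalent residues (same author
#' number from the two subunits, the defining arrangement of an interface
#' clasp) take precedence and ring-centroid separation breaks ties;
#' *flanks* are the remaining cross-chain His-His pairs that involve a
#' clasp histidine and interact either by stacking class or by any
#' ring-nitrogen to ring-atom distance within `params$flank_atom_cutoff`
#' (the flank interaction is admitted on either pi or polar evidence);
#' *supporting serines* are serines whose OG makes a polar contact
#' (<= `params$polar_cutoff`) with any nitrogen/oxygen atom of a motif
#' histidine. An empty motif (no clasp) is a valid result, not an error.
#'
#' @param model a [structure_model][read_structure].
#' @param chain_a,chain_b polymer chain ids of the dimer.
#' @param params a [wafer_params()] list.
#' @return `wafer_motif`: list with `clasp` ([stacking_pair][detect_stacking]
#'   or `NULL`), `flanks` (list of stacking pairs with polar evidence),
#'   `histidines` (data.frame of motif His addresses), `serines`
#'   (data.frame with the His each OG supports and the contact distance),
#'   `evidence` (all stacking pairs and contact records considered) and
#'   `complete` (two His per chain).
#' @export
detect_wafer_motif <- function(model, chain_a, chain_b,
                               params = wafer_params()) {
  his_a <- complete_his(model, chain_a)
  his_b <- complete_his(model, chain_b)
  empty <- structure(
    list(chain_a = chain_a, chain_b = chain_b, clasp = NULL, flanks = list(),
         histidines = data.frame(chain_id = character(), seq_id = integer()),
         serines = data.frame(), evidence = list(stacking = list(),
                                                 contacts = NULL),
         complete = FALSE, params = params),
    class = "wafer_motif"
  )
  if (nrow(his_a) == 0 || nrow(his_b) == 0) return(empty)

  pairs <- expand.grid(ia = seq_len(nrow(his_a)), ib = seq_len(nrow(his_b)))
  stacks <- lapply(seq_len(nrow(pairs)), function(k) {
    ra <- residue_atoms(model, chain_a, his_a$seq_id[pairs$ia[k]],
                        his_a$ins_code[pairs$ia[k]])
    rb <- residue_atoms(model, chain_b, his_b$seq_id[pairs$ib[k]],
                        his_b$ins_code[pairs$ib[k]])
    detect_stacking(ra, rb, params)
  })

  stacked <- Filter(function(s) s$class != "none", stacks)
  if (length(stacked) == 0) return(empty)
  # a clasp is, by definition, equivalent residues from the two subunits
  # wrapping around each other, so symmetric pairs (same author number)
  # take precedence; centroid distance breaks ties
  dist_of <- vapply(stacked, function(s) s$distance, numeric(1))
  asym <- vapply(stacked, function(s) s$a$seq_id != s$b$seq_id, logical(1))
  ord <- order(asym, dist_of,
               vapply(stacked, function(s) s$a$seq_id, 1L),
               vapply(stacked, function(s) s$b$seq_id, 1L))
  clasp <- stacked[[ord[1]]]
  clasp_seqs <- list(a = clasp$a$seq_id, b = clasp$b$seq_id)

  involves_clasp <- function(s) {
    s$a$seq_id == clasp_seqs$a || s$b$seq_id == clasp_seqs$b
  }
  is_clasp <- function(s) {
    s$a$seq_id == clasp_seqs$a && s$b$seq_id == clasp_seqs$b
  }
  ring_n_polar <- function(s) {
    ra <- residue_atoms(model, chain_a, s$a$seq_id)
    rb <- residue_atoms(model, chain_b, s$b$seq_id)
    ring_a <- ra[ra$atom_name %in% RING_ATOMS$HIS, , drop = FALSE]
    ring_b <- rb[rb$atom_name %in% RING_ATOMS$HIS, , drop = FALSE]
    dm <- cross_dist(ring_a[, c("x", "y", "z")], ring_b[, c("x", "y", "z")])
    n_a <- element_of(ring_a) == "N"
    n_b <- element_of(ring_b) == "N"
    keep <- outer(n_a, n_b, "|") & dm <= params$flank_atom_cutoff
    if (!any(keep)) return(NULL)
    hit <- which(keep, arr.ind = TRUE)
    data.frame(atom_a = ring_a$atom_name[hit[, 1]],
               atom_b = ring_b$atom_name[hit[, 2]],
               distance = dm[hit], stringsAsFactors = FALSE)
  }

  flanks <- list()
  for (s in stacks) {
    if (is_clasp(s) || !involves_clasp(s)) next
    polar_ev <- ring_n_polar(s)
    if (s$class != "none" || !is.null(polar_ev)) {
      flanks[[length(flanks) + 1]] <- list(pair = s, polar_evidence = polar_ev)
    }
  }

  his_tab <- unique(rbind(
    data.frame(chain_id = chain_a, seq_id = clasp$a$seq_id),
    data.frame(chain_id = chain_b, seq_id = clasp$b$seq_id),
    do.call(rbind, lapply(flanks, function(f) rbind(
      data.frame(chain_id = chain_a, seq_id = f$pair$a$seq_id),
      data.frame(chain_id = chain_b, seq_id = f$pair$b$seq_id))))
  ))
  his_tab <- his_tab[order(his_tab$chain_id, his_tab$seq_id), , drop = FALSE]
  rownames(his_tab) <- NULL

  # serine support: OG against N/O atoms of every motif histidine
  motif_his_atoms <- do.call(rbind, lapply(seq_len(nrow(his_tab)), function(i) {
    residue_atoms(model, his_tab$chain_id[i], his_tab$seq_id[i])
  }))
  ser <- NULL
  for (ch in c(chain_a, chain_b)) {
    a <- chain_atoms(model, ch)
    og <- best_altloc(a[a$res_name == "SER" & a$atom_name == "OG", ,
                        drop = FALSE])
    if (nrow(og) == 0) next
    cc <- polar_contacts(og, motif_his_atoms, params$polar_cutoff)
    ser <- rbind(ser, cc)
  }
  serines <- data.frame(chain_id = character(), seq_id = integer(),
                        his_chain = character(), his_seq = integer(),
                        distance = numeric(), stringsAsFactors = FALSE)
  if (!is.null(ser) && nrow(ser) > 0) {
    key <- paste(ser$chain_a, ser$seq_a)
    best <- ser[order(key, ser$distance), , drop = FALSE]
    best <- best[!duplicated(paste(best$chain_a, best$seq_a)), , drop = FALSE]
    serines <- data.frame(chain_id = best$chain_a, seq_id = best$seq_a,
                          his_chain = best$chain_b, his_seq = best$seq_b,
                          distance = best$distance, stringsAsFactors = FALSE)
    serines <- serines[order(serines$chain_id, serines$seq_id), , drop = FALSE]
    rownames(serines) <- NULL
  }

  n_per_chain <- table(factor(his_tab$chain_id, levels = c(chain_a, chain_b)))
  structure(
    list(chain_a = chain_a, chain_b = chain_b, clasp = clasp, flanks = flanks,
         histidines = his_tab, serines = serines,
         evidence = list(stacking = stacks, contacts = ser),
         complete = all(n_per_chain == 2), params = params),
    class = "wafer_motif"
  )
}

#' @export
print.wafer_motif <- function(x, ...) {
  if (is.null(x$clasp)) {
    cat("<wafer_motif> empty (no cross-chain His-His stacking)\n")
    return(invisible(x))
  }
  cat(sprintf("<wafer_motif> chains %s/%s\n", x$chain_a, x$chain_b))
  cat(sprintf("  clasp : His%d(%s) x His%d(%s)  d=%.2f A angle=%.1f [%s]\n",
              x$clasp$a$seq_id, x$chain_a, x$clasp$b$seq_id, x$chain_b,
              x$clasp$distance, x$clasp$angle, x$clasp$class))
  for (f in x$flanks) {
    cat(sprintf("  flank : His%d(%s) x His%d(%s)  d=%.2f A [%s%s]\n",
                f$pair$a$seq_id, x$chain_a, f$pair$b$seq_id, x$chain_b,
                f$pair$distance, f$pair$class,
                if (is.null(f$polar_evidence)) "" else "+polar"))
  }
  if (nrow(x$serines)) {
    cat(sprintf("  serines: %s\n", paste(
      sprintf("Ser%d(%s)->His%d(%s) %.2f A", x$serines$seq_id,
              x$serines$chain_id, x$serines$his_seq, x$serines$his_chain,
              x$serines$distance), collapse = "; ")))
  }
  invisible(x)
}

#' Does the motif connect the two active sites?
#'
#' Builds a contact graph whose nodes are the motif residues and the two
#' ligands, with edges for every stacking pair and every polar contact at
#' `params$polar_cutoff`, and asks for a path from the ligand owned by one
#' chain to the ligand owned by the other.
#'
#' @param model a [structure_model][read_structure].
#' @param motif a [wafer_motif][detect_wafer_motif]; must be non-empty.
#' @param ligands list of [ligand_instance][extract_ligands] objects, one
#'   per subunit.
#' @param params a [wafer_params()] list.
#' @return list with `connected` (logical) and `path` (character vector of
#'   node labels along one shortest path, empty when unconnected).
#' @export
motif_connects_active_sites <- function(model, motif, ligands,
                                        params = wafer_params()) {
  stopifnot(inherits(motif, "wafer_motif"))
  if (is.null(motif$clasp)) {
    wafer_stop("wafer_error_usage", "motif is empty; nothing to connect")
  }
  if (length(ligands) < 2) return(list(connected = FALSE, path = character()))

  res_tab <- rbind(motif$histidines,
                   motif$serines[, c("chain_id", "seq_id"), drop = FALSE])
  res_tab <- unique(res_tab)
  res_lab <- sprintf("%s:%d", res_tab$chain_id, res_tab$seq_id)
  res_atoms <- lapply(seq_len(nrow(res_tab)), function(i) {
    residue_atoms(model, res_tab$chain_id[i], res_tab$seq_id[i])
  })
  lig_lab <- vapply(ligands, function(l) {
    sprintf("%s[%s]", l$comp_id, l$parent_chain_id)
  }, "")

  edges <- character(0)
  add_edge <- function(u, v) edges <<- c(edges, u, v)

  # residue-residue: stacking evidence plus polar contacts
  n <- nrow(res_tab)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      cc <- polar_contacts(res_atoms[[i]], res_atoms[[j]], params$polar_cutoff)
      if (nrow(cc) > 0) add_edge(res_lab[i], res_lab[j])
    }
  }
  stack_edge <- function(s) {
    u <- sprintf("%s:%d", motif$chain_a, s$a$seq_id)
    v <- sprintf("%s:%d", motif$chain_b, s$b$seq_id)
    if (u %in% res_lab && v %in% res_lab) add_edge(u, v)
  }
  stack_edge(motif$clasp)
  for (f in motif$flanks) stack_edge(f$pair)

  # ligand-residue polar contacts
  for (k in seq_along(ligands)) {
    for (i in seq_len(n)) {
      cc <- polar_contacts(res_atoms[[i]], ligands[[k]]$atoms,
                           params$polar_cutoff)
      if (nrow(cc) > 0) add_edge(lig_lab[k], res_lab[i])
    }
  }

  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unique(c(res_lab, lig_lab)))
  if (length(edges) > 0) g <- g + igraph::edges(edges)

  from <- lig_lab[1]
  to <- lig_lab[2]
  sp <- suppressWarnings(igraph::shortest_paths(g, from = from, to = to,
                                                output = "vpath"))
  vp <- sp$vpath[[1]]
  if (length(vp) == 0) {
    list(connected = FALSE, path = character())
  } else {
    list(connected = TRUE, path = igraph::V(g)$name[as.integer(vp)])
  }
}
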