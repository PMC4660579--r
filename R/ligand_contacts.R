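# Protein-GSH contact classification by tripeptide moiety, and generic
# binding-pocket residue enumeration around a probe.

# standard chemical-component atom-name partition of glutathione:
# suffix 1 = gamma-glutamyl, suffix 2 = cysteinyl, suffix 3 = glycyl
GSH_MOIETY <- list(
  glutamyl = c("N1", "CA1", "C1", "O11", "O12", "CB1", "CG1", "CD1", "OE1"),
  cys_core = c("N2", "CA2", "C2", "O2", "CB2", "SG2"),
  glycyl   = c("N3", "CA3", "C3", "O31", "O32")
)

gsh_moiety_of <- function(atom_name) {
  m <- rep(NA_character_, length(atom_name))
  for (g in names(GSH_MOIETY)) m[atom_name %in% GSH_MOIETY[[g]]] <- g
  m
}

#' Classify protein-GSH contacts into the three moiety groups
#'
#' Finds polar (N/O/S, <= `params$polar_cutoff`) and nonpolar (C--C,
#' <= `params$nonpolar_cutoff`) contacts between the polymer chains and one
#' bound glutathione, and groups each contact by the GSH moiety of the
#' ligand atom: the gamma-glutamyl arm (suffix-1 atoms), the cysteinyl core
#' (suffix-2), or the glycyl arm (suffix-3). Every protein residue is
#' additionally tagged by domain: author numbers up to
#' `params$domain_boundary` belong to the N-terminal (thioredoxin-fold)
#' domain, larger ones to the all-helical C-terminal domain, whose GSH
#' contacts are reported separately as `cterm_interactors`.
#'
#' @param model a [structure_model][read_structure].
#' @param ligand a [ligand_instance][extract_ligands] with comp_id GSH (or
#'   GSH-like standard atom names).
#' @param params a [wafer_params()] list.
#' @return `gsh_contact_map`: list with `ligand` (address), `contacts`
#'   (data.frame with `moiety` and `domain` columns), `groups` (contacts
#'   split by moiety) and `cterm_interactors`.
#' @export
classify_gsh_contacts <- function(model, ligand, params = wafer_params()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(ligand, "ligand_instance"))
  unknown <- setdiff(ligand$atoms$atom_name, unlist(GSH_MOIETY))
  if (length(unknown) > 0) {
    wafer_stop("wafer_error_naming",
               "nonstandard GSH atom name(s): %s",
               paste(unknown, collapse = ", "))
  }
  a <- model$atoms
  protein <- best_altloc(a[!a$is_hetero & !is_water(a), , drop = FALSE])
  lig <- best_altloc(ligand$atoms)

  contacts <- rbind(
    polar_contacts(protein, lig, params$polar_cutoff),
    nonpolar_contacts(protein, lig, params$nonpolar_cutoff)
  )
  if (nrow(contacts) > 0) {
    contacts$moiety <- gsh_moiety_of(contacts$atom_b)
    contacts$domain <- ifelse(contacts$seq_a <= params$domain_boundary,
                              "N-terminal", "C-terminal")
    contacts <- contacts[order(contacts$moiety, contacts$distance), ,
                         drop = FALSE]
    rownames(contacts) <- NULL
  } else {
    contacts$moiety <- character(0)
    contacts$domain <- character(0)
  }
  groups <- split(contacts, factor(contacts$moiety, levels = names(GSH_MOIETY)))
  structure(
    list(
      ligand = list(comp_id = ligand$comp_id,
                    parent_chain_id = ligand$parent_chain_id,
                    seq_id = ligand$seq_id),
      contacts = contacts,
      groups = groups,
      cterm_interactors = contacts[contacts$domain == "C-terminal", ,
                                   drop = FALSE],
      params = params
    ),
    class = "gsh_contact_map"
  )
}

#' @export
print.gsh_contact_map <- function(x, ...) {
  cat(sprintf("<gsh_contact_map> %s (owner chain %s): %d contacts\n",
              x$ligand$comp_id, x$ligand$parent_chain_id, nrow(x$contacts)))
  for (g in names(x$groups)) {
    res <- unique(sprintf("%s%s:%d", x$groups[[g]]$res_a,
                          x$groups[[g]]$chain_a, x$groups[[g]]$seq_a))
    cat(sprintf("  %-8s: %s\n", g,
                if (length(res)) paste(res, collapse = ", ") else "-"))
  }
  invisible(x)
}

#' Residues lining a binding pocket around a probe
#'
#' Lists every polymer residue with at least one heavy atom within `cutoff`
#' of the probe, sorted by minimum distance. The probe may be any atom
#' selection: a single atom (e.g. the GSH thiol sulfur SG2, used to sound
#' the hydrophobic-substrate cavity when no second ligand is present), a
#' whole ligand, or an arbitrary coordinate matrix.
#'
#' @param model a [structure_model][read_structure].
#' @param probe a [ligand_instance][extract_ligands], an atom table, or an
#'   n x 3 coordinate matrix.
#' @param cutoff heavy-atom distance cutoff (A).
#' @return `pocket_listing` data.frame: residue addresses with
#'   `min_distance`, ascending.
#' @export
pocket_residues <- function(model, probe, cutoff) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0)
  pxyz <- if (inherits(probe, "ligand_instance")) {
    as.matrix(probe$atoms[, c("x", "y", "z")])
  } else if (is.data.frame(probe)) {
    as.matrix(probe[, c("x", "y", "z")])
  } else {
    m <- as.matrix(probe)
    if (ncol(m) != 3) wafer_stop("wafer_error_usage",
                                 "probe matrix must have 3 columns")
    m
  }
  a <- model$atoms
  protein <- best_altloc(a[!a$is_hetero & !is_water(a), , drop = FALSE])
  if (nrow(protein) == 0) {
    return(structure(data.frame(chain_id = character(), seq_id = integer(),
                                ins_code = character(), res_name = character(),
                                min_distance = numeric()),
                     class = c("pocket_listing", "data.frame")))
  }
  dm <- cross_dist(protein[, c("x", "y", "z")], pxyz)
  dmin <- apply(dm, 1, min)
  res <- residue_index(protein)
  key <- residue_key(protein)
  res$min_distance <- as.numeric(tapply(dmin, key, min)[
    paste(res$chain_id, res$seq_id, res$ins_code, sep = "|")])
  res <- res[res$min_distance <= cutoff, , drop = FALSE]
  res <- res[order(res$min_distance), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("pocket_listing", "data.frame"))
}
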