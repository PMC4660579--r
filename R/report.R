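# One-call analysis report: motif detection, GSH contact classification,
# the named active-site distances, and optional superposition/conservation
# sections, with the full parameter snapshot for provenance.

#' Configuration for [run_report()]
#'
#' @param structure path to the coordinate file to analyse (PDB or mmCIF).
#' @param chains length-2 character vector naming the dimer chains, or
#'   `NULL` to pick the polymer chain pair with the largest cross-chain
#'   contact count.
#' @param ligand chemical component id of the active-site ligand.
#' @param compare optional path to a homolog structure; adds a
#'   superposition section (align policy, all common heavy atoms).
#' @param alignment optional path to an aligned FASTA; with
#'   `alignment_row`, adds a conservation section mapped onto the first
#'   dimer chain.
#' @param alignment_row row id of `structure`'s sequence in the alignment.
#' @param positions author residue numbers to report conservation for
#'   (mapped through the alignment); default: motif plus GSH-binding
#'   positions found in the structure.
#' @param params a [wafer_params()] list.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(structure, chains = NULL, ligand = "GSH",
                            compare = NULL, alignment = NULL,
                            alignment_row = NULL, positions = NULL,
                            params = wafer_params()) {
  structure(
    list(structure = structure, chains = chains, ligand = ligand,
         compare = compare, alignment = alignment,
         alignment_row = alignment_row, positions = positions,
         params = params),
    class = "analysis_config"
  )
}

# pick the polymer chain pair with the largest cross-chain contact count
pick_dimer <- function(model, cutoff) {
  chains <- polymer_chain_ids(model)
  if (length(chains) < 2) {
    wafer_stop("wafer_error_usage",
               "need at least two polymer chains, found: %s",
               paste(chains, collapse = " "))
  }
  best <- NULL
  for (i in seq_along(chains)) {
    for (j in seq_along(chains)) {
      if (j <= i) next
      iface <- interface_residues(model, chains[i], chains[j], cutoff)
      n <- nrow(iface$residues_a) + nrow(iface$residues_b)
      if (is.null(best) || n > best$n) {
        best <- list(chains = c(chains[i], chains[j]), n = n)
      }
    }
  }
  best$chains
}

# the named active-site atom pair distances (same-subunit ligand), skipped
# silently when an atom is absent from the structure
named_distances <- function(model, ligands, params) {
  specs <- list(
    list(label = "Phe108_CE1-GSH_CB1", seq = 108, atom = "CE1", gsh = "CB1"),
    list(label = "His69_ND1-GSH_O12", seq = 69, atom = "ND1", gsh = "O12"),
    list(label = "Ser68_OG-GSH_O11", seq = 68, atom = "OG", gsh = "O11"),
    list(label = "Ser68_N-GSH_O12", seq = 68, atom = "N", gsh = "O12")
  )
  out <- NULL
  for (lig in ligands) {
    ch <- lig$parent_chain_id
    for (s in specs) {
      at <- tryCatch(select_atom(model, ch, s$seq, s$atom),
                     error = function(e) NULL)
      ga <- lig$atoms[lig$atoms$atom_name == s$gsh, , drop = FALSE]
      if (is.null(at) || nrow(ga) == 0) next
      out <- rbind(out, data.frame(
        chain = ch, label = s$label,
        distance = round(atom_distance(at, ga[1, ]), 3),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Run the full interface-motif analysis and assemble a report
#'
#' Reads the structure, identifies (or accepts) the dimer chain pair,
#' detects the wafer motif, extracts and classifies the ligand contacts per
#' subunit, evaluates whether the motif connects the two active sites,
#' computes the named active-site distances, and optionally adds
#' superposition (against `compare`) and conservation (from `alignment`)
#' sections. An absent motif is a valid result, not an error. The report is
#' deterministic given the config and inputs.
#'
#' @param config an [analysis_config()].
#' @return `analysis_report` list; see [write_report()] for serialization.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  params <- config$params
  model <- read_structure(config$structure)
  chains <- config$chains %||% pick_dimer(model, params$interface_cutoff)
  stopifnot(length(chains) == 2)

  motif <- detect_wafer_motif(model, chains[1], chains[2], params)
  ligands <- extract_ligands(model, config$ligand)
  ligands <- Filter(function(l) l$parent_chain_id %in% chains, ligands)

  contact_maps <- lapply(ligands, function(l) {
    classify_gsh_contacts(model, l, params)
  })
  connectivity <- if (!is.null(motif$clasp) && length(ligands) >= 2) {
    motif_connects_active_sites(model, motif, ligands[1:2], params)
  } else {
    list(connected = FALSE, path = character())
  }

  superpose <- NULL
  if (!is.null(config$compare)) {
    other <- read_structure(config$compare)
    fit <- structure_rmsd(model, other, policy = "align")
    superpose <- list(target = other$structure_id, rmsd = fit$rmsd,
                      n_pairs = fit$n_pairs)
  }

  conservation <- NULL
  if (!is.null(config$alignment) && !is.null(config$alignment_row)) {
    aln <- read_alignment(config$alignment)
    cmap <- map_columns_to_structure(aln, config$alignment_row, model,
                                     chains[1])
    pos <- config$positions %||%
      sort(unique(c(motif$histidines$seq_id, motif$serines$seq_id)))
    cols <- cmap$column[match(pos, cmap$seq_id)]
    keep <- !is.na(cols)
    if (any(keep)) {
      rep_tab <- conservation_report(aln, cols[keep])
      rep_tab$seq_id <- pos[keep]
      conservation <- rep_tab
    }
  }

  structure(
    list(
      structure_id = model$structure_id,
      chains = chains,
      counts = list(all = count_atoms(model, "all"),
                    protein = count_atoms(model, "protein"),
                    water = count_atoms(model, "water"),
                    hetero = count_atoms(model, "hetero")),
      motif = motif,
      ligands = ligands,
      contact_maps = contact_maps,
      connectivity = connectivity,
      distances = named_distances(model, ligands, params),
      superposition = superpose,
      conservation = conservation,
      config = list(structure = config$structure, ligand = config$ligand,
                    compare = config$compare, alignment = config$alignment),
      params = unclass(params),
      version = as.character(utils::packageVersion("wafermotif"))
    ),
    class = "analysis_report"
  )
}

# JSON-friendly view of the report (plain lists/vectors only)
report_as_list <- function(report) {
  motif <- report$motif
  motif_out <- if (is.null(motif$clasp)) {
    list(present = FALSE)
  } else {
    list(
      present = TRUE,
      clasp = list(
        a = sprintf("%s:%d", motif$chain_a, motif$clasp$a$seq_id),
        b = sprintf("%s:%d", motif$chain_b, motif$clasp$b$seq_id),
        distance = round(motif$clasp$distance, 3),
        angle = round(motif$clasp$angle, 2),
        class = motif$clasp$class),
      flanks = lapply(motif$flanks, function(f) list(
        a = sprintf("%s:%d", motif$chain_a, f$pair$a$seq_id),
        b = sprintf("%s:%d", motif$chain_b, f$pair$b$seq_id),
        distance = round(f$pair$distance, 3), class = f$pair$class)),
      histidines = sprintf("%s:%d", motif$histidines$chain_id,
                           motif$histidines$seq_id),
      serines = if (nrow(motif$serines)) sprintf(
        "%s:%d->%s:%d", motif$serines$chain_id, motif$serines$seq_id,
        motif$serines$his_chain, motif$serines$his_seq) else character(0)
    )
  }
  list(
    structure_id = report$structure_id,
    chains = report$chains,
    counts = report$counts,
    motif = motif_out,
    ligands = lapply(report$ligands, function(l) list(
      comp_id = l$comp_id, owner = l$parent_chain_id, seq_id = l$seq_id)),
    gsh_contacts = lapply(report$contact_maps, function(cm) list(
      owner = cm$ligand$parent_chain_id,
      n_contacts = nrow(cm$contacts),
      by_moiety = lapply(cm$groups, function(g) unique(
        sprintf("%s%s:%d", g$res_a, g$chain_a, g$seq_a))),
      cterm_interactors = unique(sprintf(
        "%s%s:%d", cm$cterm_interactors$res_a, cm$cterm_interactors$chain_a,
        cm$cterm_interactors$seq_a)))),
    connects_active_sites = report$connectivity$connected,
    connection_path = report$connectivity$path,
    distances = report$distances,
    superposition = report$superposition,
    conservation = report$conservation,
    config = report$config,
    params = report$params,
    version = report$version
  )
}

#' Serialize an analysis report
#'
#' JSON output is deterministic (no timestamps) so identical configurations
#' yield byte-identical files.
#'
#' @param report an `analysis_report` from [run_report()].
#' @param path output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "analysis_report"))
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print_report(report)), con)
  }
  invisible(path)
}

print_report <- function(report) {
  cat(sprintf("Structure %s, dimer %s/%s\n", report$structure_id,
              report$chains[1], report$chains[2]))
  cat(sprintf("Atoms: %d (protein %d, water %d, hetero %d)\n",
              report$counts$all, report$counts$protein,
              report$counts$water, report$counts$hetero))
  print(report$motif)
  if (!is.null(report$distances)) {
    cat("Named distances (A):\n")
    for (i in seq_len(nrow(report$distances))) {
      cat(sprintf("  [%s] %-22s %.1f\n", report$distances$chain[i],
                  report$distances$label[i], report$distances$distance[i]))
    }
  }
  cat(sprintf("Motif connects the two active sites: %s\n",
              report$connectivity$connected))
  if (length(report$connectivity$path)) {
    cat(sprintf("  path: %s\n",
                paste(report$connectivity$path, collapse = " - ")))
  }
  if (!is.null(report$superposition)) {
    cat(sprintf("Superposition vs %s: rmsd %.2f A over %d atom pairs\n",
                report$superposition$target, report$superposition$rmsd,
                report$superposition$n_pairs))
  }
  invisible(report)
}

#' @export
print.analysis_report <- function(x, ...) print_report(x)
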