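# Structure I/O and selection. Parsing/writing is delegated to bio3d; the
# rest of the package only ever sees the flat atom table defined here.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
WATER_NAMES <- c("HOH", "WAT")

#' Read a macromolecular structure into a uniform atom table
#'
#' Parses a PDB or mmCIF coordinate file (or literal text in either format)
#' into a `structure_model`: a flat table of non-hydrogen atoms preserving
#' author residue numbering, alternate locations, occupancies and waters.
#' Only the first model of a multi-model file is kept. Hydrogen (and
#' deuterium) records are dropped: crystal structures at typical resolution
#' carry no meaningful hydrogen positions and every distance criterion in
#' this package is heavy-atom.
#'
#' @param source path to a coordinate file, or a character string containing
#'   the file's text (detected by embedded newlines).
#' @param format one of `"auto"`, `"pdb"`, `"cif"`. With `"auto"` the format
#'   is taken from the file extension, falling back to content sniffing.
#' @return An object of class `structure_model` with elements
#'   `structure_id`, `source_format` and `atoms` (a data.frame with columns
#'   `record`, `atom_name`, `altloc`, `res_name`, `chain_id`, `seq_id`,
#'   `ins_code`, `x`, `y`, `z`, `occupancy`, `element`, `is_hetero`).
#' @seealso [write_structure()], [count_atoms()], [extract_ligands()],
#'   [select_atom()]
#' @export
#' @examples
#' pdb_txt <- paste(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
#'   "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
#'   "END", sep = "\n")
#' m <- read_structure(pdb_txt, format = "pdb")
#' count_atoms(m)
read_structure <- function(source, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  stopifnot(is.character(source), length(source) == 1)

  is_text <- grepl("\n", source, fixed = TRUE)
  path <- source
  if (is_text) {
    # extension-less for "auto" so the format comes from content sniffing
    path <- tempfile(fileext = switch(format, cif = ".cif", pdb = ".pdb", ""))
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(source, "\n", fixed = TRUE)[[1]], path)
  } else if (!file.exists(path)) {
    wafer_stop("wafer_error_io", "structure file not found: %s", path)
  }

  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else sniff_format(path)
  }

  parsed <- tryCatch(
    suppressWarnings(if (format == "cif") {
      bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE,
                      hex = TRUE)
    }),
    error = function(e) {
      wafer_stop("wafer_error_format",
                 "cannot parse '%s' as %s: %s", source_label(source, is_text),
                 format, conditionMessage(e))
    }
  )

  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) {
    wafer_stop("wafer_error_empty_model",
               "no coordinate records in %s", source_label(source, is_text))
  }

  element <- toupper(trimws(as.character(at$elesy)))
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- infer_element(at$elety[missing_el])

  atoms <- data.frame(
    record = as.character(at$type),
    atom_name = trimws(as.character(at$elety)),
    altloc = blank_na(at$alt),
    res_name = trimws(as.character(at$resid)),
    chain_id = blank_na(at$chain),
    seq_id = as.integer(at$resno),
    ins_code = blank_na(at$insert),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    element = element,
    stringsAsFactors = FALSE
  )
  atoms$is_hetero <- atoms$record == "HETATM"
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0) {
    wafer_stop("wafer_error_empty_model",
               "no heavy atoms in %s", source_label(source, is_text))
  }
  rownames(atoms) <- NULL
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    wafer_stop("wafer_error_format",
               "non-finite coordinates at atom record %d", which(bad)[1])
  }

  new_structure_model(
    structure_id = if (is_text) "text" else
      toupper(tools::file_path_sans_ext(basename(path))),
    source_format = format,
    atoms = atoms
  )
}

new_structure_model <- function(structure_id, source_format, atoms) {
  structure(
    list(structure_id = structure_id, source_format = source_format,
         atoms = atoms),
    class = "structure_model"
  )
}

sniff_format <- function(path) {
  head_lines <- readLines(path, n = 50, warn = FALSE)
  if (any(grepl("^(data_|loop_|_atom_site)", head_lines))) return("cif")
  if (any(grepl("^(ATOM|HETATM|HEADER|CRYST1|MODEL)", head_lines))) return("pdb")
  wafer_stop("wafer_error_format",
             "cannot determine coordinate format of '%s' (first line: %s)",
             path, if (length(head_lines)) head_lines[1] else "<empty>")
}

source_label <- function(source, is_text) {
  if (is_text) "<literal text>" else source
}

blank_na <- function(v) {
  v <- trimws(as.character(v))
  v[is.na(v)] <- ""
  v
}

# element symbol from a chemical-component atom name, e.g. "CE1" -> C,
# "ND1" -> N, "OG" -> O, "SG2" -> S, "FE" left as-is for two-letter metals
infer_element <- function(name) {
  name <- toupper(trimws(as.character(name)))
  stripped <- sub("^[0-9']+", "", name)
  two <- substr(stripped, 1, 2)
  el <- substr(stripped, 1, 1)
  metals <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "CU", "NI", "SE")
  el[two %in% metals & nchar(stripped) == 2] <- two[two %in% metals & nchar(stripped) == 2]
  el
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %s (%s)\n", x$structure_id, x$source_format))
  cat(sprintf("  %d heavy atoms | chains: %s\n", nrow(a),
              paste(sort(unique(a$chain_id)), collapse = " ")))
  cat(sprintf("  protein %d | water %d | hetero %d\n",
              count_atoms(x, "protein"), count_atoms(x, "water"),
              count_atoms(x, "hetero")))
  invisible(x)
}

is_water <- function(atoms) atoms$res_name %in% WATER_NAMES

#' Count heavy-atom records by category
#'
#' Counts follow the refinement-table convention: every atom record is
#' counted, including alternate-location duplicates. `protein` counts
#' non-hetero (polymer) records, `water` counts HOH/WAT records, `hetero`
#' the remaining heteroatoms, and the three categories always sum to `all`.
#'
#' @param model a [structure_model][read_structure].
#' @param category `"all"`, `"protein"`, `"water"` or `"hetero"`.
#' @return integer count.
#' @export
count_atoms <- function(model, category = c("all", "protein", "water", "hetero")) {
  stopifnot(inherits(model, "structure_model"))
  if (is.character(category) && length(category) == 1 &&
      !category %in% c("all", "protein", "water", "hetero")) {
    wafer_stop("wafer_error_usage", "unknown atom category '%s'", category)
  }
  category <- match.arg(category)
  a <- model$atoms
  w <- is_water(a)
  switch(category,
    all = nrow(a),
    protein = sum(!a$is_hetero & !w),
    water = sum(w),
    hetero = sum(a$is_hetero & !w)
  )
}

# split index for residues: one key per (chain, seq, insertion)
residue_key <- function(atoms) {
  paste(atoms$chain_id, atoms$seq_id, atoms$ins_code, sep = "|")
}

polymer_chain_ids <- function(model) {
  a <- model$atoms
  ids <- unique(a$chain_id[!a$is_hetero & !is_water(a) &
                             a$res_name %in% STANDARD_AA])
  sort(ids)
}

# atom table of one polymer chain (no waters/ligands)
chain_atoms <- function(model, chain_id, polymer_only = TRUE) {
  a <- model$atoms
  sel <- a$chain_id == chain_id
  if (polymer_only) sel <- sel & !a$is_hetero & !is_water(a)
  a[sel, , drop = FALSE]
}

# one-letter sequence of a polymer chain in author-numbering order
chain_sequence <- function(model, chain_id) {
  a <- chain_atoms(model, chain_id)
  if (nrow(a) == 0) {
    wafer_stop("wafer_error_lookup", "no polymer chain '%s' in %s",
               chain_id, model$structure_id)
  }
  ord <- order(a$seq_id, a$ins_code)
  a <- a[ord, , drop = FALSE]
  keys <- residue_key(a)
  first <- !duplicated(keys)
  res <- a[first, , drop = FALSE]
  one <- bio3d::aa321(res$res_name)
  one[is.na(one) | !res$res_name %in% STANDARD_AA] <- "X"
  list(sequence = paste(one, collapse = ""), seq_id = res$seq_id,
       ins_code = res$ins_code, res_name = res$res_name)
}

#' Extract bound ligand instances by component id
#'
#' Returns one `ligand_instance` per matching hetero residue. Each instance
#' is annotated with the polymer chain owning its active site, defined as
#' the chain with the smallest heavy-atom distance to the ligand; this
#' assignment depends only on geometry, never on how the deposition labelled
#' the ligand's chain.
#'
#' @param model a [structure_model][read_structure].
#' @param comp_id chemical component code, 1-3 characters (e.g. `"GSH"`).
#' @return list of `ligand_instance` objects (possibly empty), each with
#'   elements `comp_id`, `atoms`, `parent_chain_id`, `file_chain_id`,
#'   `seq_id`, `min_distance`.
#' @export
extract_ligands <- function(model, comp_id) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.character(comp_id) || length(comp_id) != 1 ||
      !nchar(comp_id) %in% 1:3) {
    wafer_stop("wafer_error_usage",
               "comp_id must be a 1-3 character component code")
  }
  a <- model$atoms
  lig <- a[a$is_hetero & a$res_name == toupper(comp_id), , drop = FALSE]
  if (nrow(lig) == 0) return(list())

  poly_ids <- polymer_chain_ids(model)
  poly <- lapply(poly_ids, function(ch) as.matrix(
    chain_atoms(model, ch)[, c("x", "y", "z")]))
  names(poly) <- poly_ids

  out <- lapply(split(seq_len(nrow(lig)), residue_key(lig)), function(idx) {
    res <- lig[idx, , drop = FALSE]
    xyz <- as.matrix(res[, c("x", "y", "z")])
    dmin <- vapply(poly, function(p) min(cross_dist(xyz, p)), numeric(1))
    owner <- if (length(dmin)) names(dmin)[which.min(dmin)] else NA_character_
    structure(
      list(comp_id = toupper(comp_id), atoms = res,
           parent_chain_id = owner,
           file_chain_id = res$chain_id[1], seq_id = res$seq_id[1],
           min_distance = if (length(dmin)) min(dmin) else NA_real_),
      class = "ligand_instance"
    )
  })
  names(out) <- NULL
  # stable order: by owner chain then residue number
  out[order(vapply(out, function(l) l$parent_chain_id, ""),
            vapply(out, function(l) l$seq_id, 1L))]
}

#' @export
print.ligand_instance <- function(x, ...) {
  cat(sprintf("<ligand_instance> %s %s:%d (%d atoms, owner chain %s, %.2f A)\n",
              x$comp_id, x$file_chain_id, x$seq_id, nrow(x$atoms),
              x$parent_chain_id, x$min_distance))
  invisible(x)
}

#' Select a single atom by address
#'
#' Resolves `chain:seq_id:atom_name` to exactly one atom row. When
#' alternate locations exist, the highest-occupancy conformer is returned,
#' ties broken by altloc letter order; pass `altloc` to select explicitly.
#'
#' @param model a [structure_model][read_structure].
#' @param chain_id,seq_id,atom_name atom address in author numbering.
#' @param ins_code insertion code, default blank.
#' @param altloc explicit alternate-location id, or `NULL` for the
#'   highest-occupancy policy.
#' @return one-row data.frame (same columns as `model$atoms`).
#' @export
select_atom <- function(model, chain_id, seq_id, atom_name, ins_code = "",
                        altloc = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  sel <- a$chain_id == chain_id & a$seq_id == seq_id &
    a$atom_name == atom_name & a$ins_code == ins_code
  if (!is.null(altloc)) sel <- sel & a$altloc == altloc
  hit <- a[sel, , drop = FALSE]
  if (nrow(hit) == 0) {
    wafer_stop("wafer_error_lookup", "no atom %s:%s%s:%s%s in %s",
               chain_id, seq_id, ins_code, atom_name,
               if (is.null(altloc)) "" else paste0(" altloc=", altloc),
               model$structure_id)
  }
  hit <- hit[order(-hit$occupancy, hit$altloc), , drop = FALSE]
  hit[1, , drop = FALSE]
}

# reduce an atom table to a single conformer: per (residue, atom name) keep
# the highest-occupancy record, ties broken by altloc letter
best_altloc <- function(atoms) {
  if (nrow(atoms) == 0) return(atoms)
  key <- paste(residue_key(atoms), atoms$atom_name, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

#' Write a structure model as a PDB file
#'
#' Formats the atom table back to PDB, preserving records, names, author
#' numbering, insertion codes, altlocs and occupancies (coordinates to the
#' format's 3 decimals).
#'
#' @param model a [structure_model][read_structure].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = a$record,
    resno = a$seq_id,
    resid = a$res_name,
    eleno = seq_len(nrow(a)),
    elety = a$atom_name,
    chain = ifelse(a$chain_id == "", " ", a$chain_id),
    insert = ifelse(a$ins_code == "", NA, a$ins_code),
    alt = ifelse(a$altloc == "", NA, a$altloc),
    o = a$occupancy,
    b = rep(0, nrow(a)),
    elesy = a$element,
    end = TRUE
  )
  invisible(path)
}
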