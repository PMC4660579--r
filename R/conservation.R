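# Alignment-column statistics: WebLogo-style information content with the
# small-sample correction, mapping of alignment columns onto author residue
# numbers of a structure, and per-position conservation reports.

new_alignment <- function(ids, m) {
  stopifnot(is.matrix(m), length(ids) == nrow(m), !anyDuplicated(ids))
  dimnames(m) <- NULL
  structure(list(ids = as.character(ids), seqs = m), class = "aa_alignment")
}

#' Read an aligned FASTA file
#'
#' All rows must have equal length over the 20 amino-acid letters plus the
#' gap characters `-` and `.` (gaps are normalized to `-`; `X` is accepted
#' as unknown). Alignment computation itself (Clustal and friends) is out
#' of scope; this consumes their product.
#'
#' @param source path to an aligned FASTA file, or literal FASTA text.
#' @return `aa_alignment`: list with `ids` and `seqs` (character matrix,
#'   rows = sequences, columns = alignment columns).
#' @export
read_alignment <- function(source) {
  stopifnot(is.character(source), length(source) == 1)
  path <- source
  if (grepl("\n", source, fixed = TRUE)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(source, "\n", fixed = TRUE)[[1]], path)
  } else if (!file.exists(path)) {
    wafer_stop("wafer_error_io", "alignment file not found: %s", path)
  }
  ss <- tryCatch(Biostrings::readBStringSet(path), error = function(e) {
    wafer_stop("wafer_error_format", "cannot read FASTA: %s",
               conditionMessage(e))
  })
  if (length(ss) == 0) {
    wafer_stop("wafer_error_format", "no sequences in %s", path)
  }
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) != 1) {
    wafer_stop("wafer_error_length",
               "ragged alignment: row lengths %s",
               paste(unique(lens), collapse = ", "))
  }
  rows <- toupper(as.character(ss))
  m <- do.call(rbind, strsplit(rows, ""))
  m[m == "."] <- "-"
  bad <- !(m %in% c(AA20, "-", "X"))
  if (any(bad)) {
    wafer_stop("wafer_error_alphabet",
               "non-amino-acid character(s): %s",
               paste(unique(m[bad]), collapse = " "))
  }
  ids <- sub("\\s.*$", "", names(ss))
  new_alignment(ids, m)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an `aa_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(c(paste0(">", aln$ids[i]),
                 paste(aln$seqs[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d sequences x %d columns\n",
              nrow(x$seqs), ncol(x$seqs)))
  invisible(x)
}

#' Per-column residue frequencies and information content
#'
#' Computes the WebLogo statistics for one alignment column: residue
#' frequencies over the non-gap letters, Shannon entropy
#' `H = -sum f_i log2 f_i`, and information content
#' `R = log2(20) - (H + e_n)` with the small-sample correction
#' `e_n = (19 / (2 n ln 2))`, clamped at zero. Letter heights are
#' `f_i * R`, ordered most to least frequent, so the stack height equals R.
#' Gap-only columns are flagged and carry `NA` information (missing, not
#' zero); columns more than half gaps are flagged `low_confidence`.
#'
#' @param aln an `aa_alignment` (see [read_alignment()]).
#' @param col column index (1-based).
#' @param correction apply the small-sample correction (default `TRUE`).
#' @return `column_profile`: list with `column`, `counts`, `n_ungapped`,
#'   `frequencies`, `entropy`, `information`, `heights`, `flag`.
#' @export
column_profile <- function(aln, col, correction = TRUE) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (col < 1 || col > ncol(aln$seqs)) {
    wafer_stop("wafer_error_usage", "column %d out of bounds (1..%d)",
               col, ncol(aln$seqs))
  }
  letters_ <- aln$seqs[, col]
  obs <- letters_[letters_ != "-"]
  n <- length(obs)
  gap_frac <- 1 - n / length(letters_)

  if (n == 0) {
    return(structure(
      list(column = col, counts = integer(0), n_ungapped = 0L,
           frequencies = numeric(0), entropy = NA_real_,
           information = NA_real_, heights = numeric(0), flag = "all_gap"),
      class = "column_profile"))
  }
  counts <- table(obs)
  freqs <- as.numeric(counts) / n
  names(freqs) <- names(counts)
  h <- -sum(freqs * log2(freqs))
  e_n <- if (correction) 19 / (2 * n * log(2)) else 0
  r <- max(0, log2(20) - (h + e_n))
  ord <- order(freqs, names(freqs), decreasing = c(TRUE, FALSE),
               method = "radix")
  heights <- freqs[ord] * r
  structure(
    list(column = col, counts = as.integer(counts)[ord],
         n_ungapped = as.integer(n), frequencies = freqs[ord],
         entropy = h, information = r, heights = heights,
         flag = if (gap_frac > 0.5) "low_confidence" else "ok"),
    class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  if (identical(x$flag, "all_gap")) {
    cat(sprintf("<column_profile> col %d: all gaps\n", x$column))
    return(invisible(x))
  }
  cat(sprintf("<column_profile> col %d: n=%d R=%.3f bits [%s]  %s\n",
              x$column, x$n_ungapped, x$information, x$flag,
              paste(sprintf("%s %.2f", names(x$frequencies), x$frequencies),
                    collapse = " ")))
  invisible(x)
}

#' Map alignment columns onto structure residue numbers
#'
#' Matches the ungapped sequence of one alignment row against the polymer
#' sequence of a chain (allowing truncation at either terminus) and returns
#' the bijection between alignment columns and author residue numbers; gap
#' columns map to nothing.
#'
#' @param aln an `aa_alignment`.
#' @param row_id id of the alignment row corresponding to the structure.
#' @param model a [structure_model][read_structure].
#' @param chain polymer chain id.
#' @param max_mismatch residue mismatches tolerated at the best offset
#'   (default 0).
#' @return data.frame: `column`, `row_pos` (ungapped position in the row),
#'   `seq_id`, `ins_code`, `res_name` (chain residue), `letter` (row).
#' @export
map_columns_to_structure <- function(aln, row_id, model, chain,
                                     max_mismatch = 0L) {
  stopifnot(inherits(aln, "aa_alignment"))
  ri <- match(row_id, aln$ids)
  if (is.na(ri)) {
    wafer_stop("wafer_error_lookup", "no alignment row '%s'", row_id)
  }
  row <- aln$seqs[ri, ]
  ungapped_cols <- which(row != "-")
  row_seq <- row[ungapped_cols]
  cs <- chain_sequence(model, chain)
  chain_seq <- strsplit(cs$sequence, "")[[1]]

  lr <- length(row_seq); lc <- length(chain_seq)
  # offsets: position of row start relative to chain start (can be negative
  # when the row overhangs an N-terminally truncated chain)
  offsets <- (-lr + 1):(lc - 1)
  best <- NULL
  for (off in offsets) {
    i <- seq_len(lr)
    j <- i + off
    ok <- j >= 1 & j <= lc
    if (!any(ok)) next
    mm <- sum(row_seq[ok] != chain_seq[j[ok]] &
                row_seq[ok] != "X" & chain_seq[j[ok]] != "X")
    overlap <- sum(ok)
    if (is.null(best) || mm < best$mm ||
        (mm == best$mm && overlap > best$overlap)) {
      best <- list(off = off, mm = mm, overlap = overlap)
    }
  }
  if (is.null(best) || best$mm > max_mismatch) {
    i <- seq_len(lr); j <- i + (best$off %||% 0)
    ok <- j >= 1 & j <= lc
    first_bad <- which(ok & row_seq != chain_seq[pmin(pmax(j, 1), lc)])[1]
    wafer_stop("wafer_error_mapping",
               "row '%s' does not match chain %s (%d mismatches at best offset; first at row position %s)",
               row_id, chain, best$mm %||% -1,
               if (is.na(first_bad)) "?" else first_bad)
  }
  i <- seq_len(lr)
  j <- i + best$off
  ok <- j >= 1 & j <= lc
  data.frame(
    column = ungapped_cols[ok], row_pos = i[ok], seq_id = cs$seq_id[j[ok]],
    ins_code = cs$ins_code[j[ok]], res_name = cs$res_name[j[ok]],
    letter = row_seq[ok], stringsAsFactors = FALSE
  )
}

#' Conservation report for positions of interest
#'
#' Per requested column: consensus residue, its frequency, and information
#' content; optionally restricted to a subset of rows (e.g. one GST class)
#' so that class-wise panels can be compared.
#'
#' @param aln an `aa_alignment`.
#' @param columns integer vector of column indices (1-based).
#' @param rows optional character vector of row ids to restrict to.
#' @param correction apply the small-sample correction.
#' @return data.frame: `column`, `consensus`, `frequency`, `information`,
#'   `n_ungapped`, `flag`.
#' @export
conservation_report <- function(aln, columns, rows = NULL, correction = TRUE) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!is.null(rows)) {
    keep <- match(rows, aln$ids)
    if (anyNA(keep)) {
      wafer_stop("wafer_error_lookup", "unknown row id(s): %s",
                 paste(rows[is.na(keep)], collapse = ", "))
    }
    aln <- new_alignment(aln$ids[keep],
                         aln$seqs[keep, , drop = FALSE])
  }
  do.call(rbind, lapply(columns, function(j) {
    p <- column_profile(aln, j, correction = correction)
    if (identical(p$flag, "all_gap")) {
      data.frame(column = j, consensus = NA_character_,
                 frequency = NA_real_, information = NA_real_,
                 n_ungapped = 0L, flag = "all_gap",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(column = j, consensus = names(p$frequencies)[1],
                 frequency = as.numeric(p$frequencies[1]),
                 information = p$information, n_ungapped = p$n_ungapped,
                 flag = p$flag, stringsAsFactors = FALSE)
    }
  }))
}
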