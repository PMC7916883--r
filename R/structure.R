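# Structure input/output and residue bookkeeping.
#
# Structures are held as an `md_structure`: a tibble of atoms in PDB
# conventions (author residue numbering, coordinates in Angstrom) plus a
# title. Parsing of the fixed-column records is delegated to bio3d; this
# layer adds validation, altloc resolution by occupancy, and chain
# selection.

.pdb_lines <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    return(readLines(pdb, warn = FALSE))
  }
  unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
}

.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) {
    abort("no ATOM records found in PDB input")
  }
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(sprintf("malformed coordinate field at line %d: record too short", i))
    }
    for (field in list(c(31, 38), c(39, 46), c(47, 54))) {
      val <- suppressWarnings(as.numeric(substr(ln, field[1], field[2])))
      if (is.na(val)) {
        abort(sprintf(
          "malformed coordinate field at line %d: '%s' is not numeric",
          i, trimws(substr(ln, field[1], field[2]))
        ))
      }
    }
  }
  invisible(lines)
}

# Highest-occupancy altloc wins; ties go to the alphabetically first
# altloc letter.
.resolve_altloc <- function(atoms) {
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) {
    return(atoms)
  }
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, atoms$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  keep <- !duplicated(key[ord])
  atoms[sort(ord[keep]), , drop = FALSE]
}

#' Read a protein structure from PDB text
#'
#' Parses fixed-column PDB `ATOM`/`HETATM` records into an `md_structure`.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties broken by the first altloc letter); author residue
#' numbering is preserved verbatim and no renumbering takes place.
#'
#' @param pdb Path to a PDB file, or PDB-format text (a single string or a
#'   character vector of lines).
#' @param chains Optional character vector of chain identifiers to keep. An
#'   error is raised if a requested chain is absent.
#' @return An `md_structure`: a list with `atoms` (a tibble with columns
#'   `eleno`, `elety`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`,
#'   `o`, `b`, `element`, `type`; coordinates in Angstrom) and `title`.
#' @export
#' @examples
#' s <- read_structure(c(
#'   "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
#' ))
#' s$atoms$x
read_structure <- function(pdb, chains = NULL) {
  lines <- .pdb_lines(pdb)
  .validate_pdb_lines(lines)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  p <- bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
  atoms <- as_tibble(p$atom)
  atoms <- atoms[, c(
    "eleno", "elety", "alt", "resid", "chain", "resno", "insert",
    "x", "y", "z", "o", "b", "elesy", "type"
  )]
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms <- .resolve_altloc(atoms)
  atoms$element <- .infer_element(atoms$elety, atoms$elesy)
  if (!is.null(chains)) {
    missing_ch <- setdiff(chains, unique(atoms$chain))
    if (length(missing_ch) > 0) {
      abort(sprintf(
        "requested chain(s) not present in structure: %s",
        paste(missing_ch, collapse = ", ")
      ))
    }
    atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  }
  title <- trimws(sub("^TITLE\\s{0,4}", "", grep("^TITLE", lines, value = TRUE)))
  structure(
    list(atoms = atoms, title = paste(title, collapse = " ")),
    class = "md_structure"
  )
}

#' @export
print.md_structure <- function(x, ...) {
  ca <- calpha_trace(x)
  cat(sprintf(
    "<md_structure> %d atoms, %d chains (%s), %d C-alpha residues\n",
    nrow(x$atoms), length(unique(x$atoms$chain)),
    paste(sort(unique(x$atoms$chain)), collapse = ","), nrow(ca)
  ))
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' Writes fixed-column PDB records; coordinates keep the 0.001 Angstrom
#' precision of the format, so a read/write round trip reproduces them
#' exactly.
#'
#' @param x An `md_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "md_structure"))
  a <- x$atoms
  bio3d::write.pdb(
    file = path,
    type = a$type,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resid, eleno = a$eleno, elety = a$elety,
    chain = ifelse(a$chain == " ", "", a$chain),
    insert = a$insert, o = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b), elesy = a$element
  )
  invisible(path)
}

#' Extract the C-alpha trace
#'
#' Returns one CA atom per standard amino-acid residue, in atom order.
#' `HETATM` records and non-standard residues never enter the trace.
#'
#' @param x An `md_structure`.
#' @param chains Optional chains to restrict to.
#' @return A tibble with columns `chain`, `resno`, `insert`, `resid`, `aa`
#'   (one-letter code), `x`, `y`, `z` and `atom_row` (row index into
#'   `x$atoms`).
#' @export
calpha_trace <- function(x, chains = NULL) {
  a <- x$atoms
  keep <- a$type == "ATOM" & a$elety == "CA" & a$resid %in% .standard_aa3
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  ca <- a[keep, , drop = FALSE]
  tibble(
    chain = ca$chain, resno = ca$resno, insert = ca$insert,
    resid = ca$resid, aa = unname(.aa3_to_1[ca$resid]),
    x = ca$x, y = ca$y, z = ca$z, atom_row = which(keep)
  )
}

#' One-letter sequence of a chain
#'
#' @param x An `md_structure`.
#' @param chain Chain identifier.
#' @return A single string over the standard one-letter alphabet, read off
#'   the C-alpha trace in residue order.
#' @export
structure_sequence <- function(x, chain) {
  ca <- calpha_trace(x, chains = chain)
  if (nrow(ca) == 0) abort(sprintf("chain '%s' has no C-alpha atoms", chain))
  paste(ca$aa, collapse = "")
}

#' Report numbering gaps in each chain
#'
#' Missing residues are not reconstructed; chains are reported as-is with
#' the gaps implied by their author numbering.
#'
#' @param x An `md_structure`.
#' @return A tibble with one row per gap: `chain`, `after_resno`,
#'   `before_resno`, `n_missing`.
#' @export
report_gaps <- function(x) {
  ca <- calpha_trace(x)
  out <- list()
  for (ch in unique(ca$chain)) {
    rn <- ca$resno[ca$chain == ch]
    d <- diff(rn)
    idx <- which(d > 1)
    if (length(idx) > 0) {
      out[[ch]] <- tibble(
        chain = ch, after_resno = rn[idx], before_resno = rn[idx + 1],
        n_missing = d[idx] - 1L
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      chain = character(), after_resno = integer(),
      before_resno = integer(), n_missing = integer()
    ))
  }
  bind_rows(out)
}

#' Prepare a dimer from a crystal structure
#'
#' Reads a structure, keeps the requested two chains (dropping any further
#' copies of the biological unit in the asymmetric unit), and reports
#' residues missing from the model. Incomplete models are accepted and the
#' gaps surfaced; no loop reconstruction is attempted.
#'
#' @param pdb Path or PDB text, as for [read_structure()].
#' @param chains The two chain identifiers forming the functional dimer.
#' @return An `md_structure` with a `gaps` attribute (the [report_gaps()]
#'   tibble).
#' @export
prepare_dimer <- function(pdb, chains = c("A", "B")) {
  if (length(chains) != 2) abort("a dimer preparation needs exactly two chains")
  s <- read_structure(pdb, chains = chains)
  gaps <- report_gaps(s)
  if (nrow(gaps) > 0) {
    inform(sprintf(
      "prepared dimer has %d numbering gap(s) (%d residues missing)",
      nrow(gaps), sum(gaps$n_missing)
    ))
  }
  attr(s, "gaps") <- gaps
  s
}

#' Export sequences to FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
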