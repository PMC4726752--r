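#' @importFrom rlang .data
#' @import tibble
NULL

ATOM_COLS <- c("frame", "record", "serial", "name", "alt", "res_name",
               "chain", "res_seq", "insertion", "x", "y", "z",
               "occupancy", "b_factor", "element")

#' Construct an ensemble tibble from atom records
#'
#' An ensemble is an ordered set of structure frames sharing one topology
#' (the same atoms in the same order), standing in for a molecular dynamics
#' trajectory. It is stored as a plain tibble of atom records with one row
#' per atom per frame and a `frame` column (0-based), so all dplyr verbs
#' apply; the class tag `"cp_ensemble"` marks it for methods.
#'
#' @param atoms A data frame with columns `frame`, `record`, `serial`,
#'   `name`, `alt`, `res_name`, `chain`, `res_seq`, `insertion`, `x`, `y`,
#'   `z`, `occupancy`, `b_factor`, `element`. Missing bookkeeping columns
#'   are filled with defaults; coordinates and identities are required.
#' @return A tibble of class `cp_ensemble`.
#' @export
as_ensemble <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  defaults <- list(frame = 0L, record = "ATOM", alt = NA_character_,
                   insertion = NA_character_, occupancy = 1, b_factor = 0,
                   serial = NA_integer_)
  for (col in names(defaults)) {
    if (!col %in% names(atoms)) atoms[[col]] <- defaults[[col]]
  }
  missing <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  atoms <- atoms[, ATOM_COLS]
  atoms$frame <- as.integer(atoms$frame)
  atoms$res_seq <- as.integer(atoms$res_seq)
  if (is.na(atoms$serial[1])) {
    atoms$serial <- stats::ave(seq_len(nrow(atoms)), atoms$frame,
                               FUN = seq_along)
  }
  validate_ensemble(atoms)
  class(atoms) <- c("cp_ensemble", class(tibble::tibble()))
  atoms
}

atom_identity <- function(atoms) {
  paste(atoms$chain, atoms$res_seq,
        ifelse(is.na(atoms$insertion), "", atoms$insertion),
        atoms$name, sep = "|")
}

validate_ensemble <- function(atoms) {
  if (nrow(atoms) == 0) stop("ensemble has no atoms", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table", call. = FALSE)
  }
  ids <- atom_identity(atoms)
  keys <- split(ids, atoms$frame)
  ref <- keys[[1]]
  if (anyDuplicated(ref)) {
    dup <- ref[duplicated(ref)][1]
    stop("duplicate atom identity within a frame: ", dup, call. = FALSE)
  }
  for (k in seq_along(keys)) {
    if (!identical(keys[[k]], ref)) {
      stop("topology error: frame ", names(keys)[k],
           " does not share the topology of frame ", names(keys)[1],
           " (same atoms in the same order are required)", call. = FALSE)
    }
  }
  invisible(atoms)
}

#' Number of frames in an ensemble
#' @param atoms An ensemble tibble.
#' @return Integer frame count.
#' @export
n_frames <- function(atoms) length(unique(atoms$frame))

#' Extract one frame of an ensemble
#' @param atoms An ensemble tibble.
#' @param frame 0-based frame index.
#' @return A single-frame ensemble tibble.
#' @export
get_frame <- function(atoms, frame) {
  out <- atoms[atoms$frame == frame, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("frame ", frame, " not present (frames: ",
         paste(range(atoms$frame), collapse = ".."), ")", call. = FALSE)
  }
  out
}

#' The shared topology key of an ensemble
#' @param atoms An ensemble tibble.
#' @return Character vector of `chain|res_seq|insertion|name` identities in
#'   file order, one entry per atom of a frame.
#' @export
topology_key <- function(atoms) {
  atom_identity(atoms[atoms$frame == atoms$frame[1], , drop = FALSE])
}

parse_pdb_num <- function(txt, lineno, what) {
  val <- suppressWarnings(as.numeric(txt))
  bad <- is.na(val) & trimws(txt) != ""
  empty <- trimws(txt) == ""
  val[empty] <- NA_real_
  if (any(bad)) {
    stop("parse error at line ", lineno[bad][1], ": malformed ", what,
         " field '", trimws(txt[bad][1]), "'", call. = FALSE)
  }
  val
}

guess_element <- function(name) {
  stripped <- gsub("[^A-Za-z]", "", name)
  toupper(substr(stripped, 1, 1))
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' Parses fixed-column PDB `ATOM`/`HETATM` records, honouring `MODEL` /
#' `ENDMDL` blocks: each model becomes one frame (a single-model file yields
#' a one-frame ensemble). `HETATM` records (cofactors, ligands) are
#' retained; hydrogens are retained in the table but excluded by heavy-atom
#' selections. Alternate locations are resolved to the highest-occupancy
#' conformer (tie: first in file). All models must share one topology.
#'
#' @param path Path to a PDB file.
#' @param dialect Only `"pdb"` is supported.
#' @return An ensemble tibble (see [as_ensemble()]).
#' @export
read_structure <- function(path, dialect = "pdb") {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  is_atom <- rec %in% c("ATOM", "HETATM")
  is_model <- rec == "MODEL"

  frame_of <- cumsum(is_model)
  if (any(is_model)) frame_of <- frame_of - 1L else frame_of <- frame_of
  lineno <- seq_along(lines)[is_atom]
  al <- lines[is_atom]
  if (length(al) == 0) stop("no ATOM/HETATM records in ", path, call. = FALSE)

  field <- function(from, to) substr(al, from, to)
  serial <- parse_pdb_num(field(7, 11), lineno, "serial")
  x <- parse_pdb_num(field(31, 38), lineno, "x")
  y <- parse_pdb_num(field(39, 46), lineno, "y")
  z <- parse_pdb_num(field(47, 54), lineno, "z")
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    i <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("parse error at line ", lineno[i], ": empty coordinate field",
         call. = FALSE)
  }
  occ <- parse_pdb_num(field(55, 60), lineno, "occupancy")
  occ[is.na(occ)] <- 1
  bf <- parse_pdb_num(field(61, 66), lineno, "b_factor")
  bf[is.na(bf)] <- 0
  res_seq <- parse_pdb_num(field(23, 26), lineno, "res_seq")
  if (anyNA(res_seq)) {
    stop("parse error at line ", lineno[which(is.na(res_seq))[1]],
         ": malformed residue number", call. = FALSE)
  }
  elem <- trimws(field(77, 78))
  name <- trimws(field(13, 16))
  elem[elem == ""] <- guess_element(name[elem == ""])
  alt <- substr(al, 17, 17)
  alt[alt %in% c(" ", "")] <- NA_character_
  ins <- substr(al, 27, 27)
  ins[ins %in% c(" ", "")] <- NA_character_

  atoms <- tibble::tibble(
    frame = frame_of[is_atom],
    record = rec[is_atom],
    serial = as.integer(serial),
    name = name,
    alt = alt,
    res_name = trimws(field(18, 20)),
    chain = substr(al, 22, 22),
    res_seq = as.integer(res_seq),
    insertion = ins,
    x = x, y = y, z = z,
    occupancy = occ,
    b_factor = bf,
    element = elem
  )
  atoms <- resolve_altloc(atoms)
  as_ensemble(atoms)
}

# keep highest-occupancy alternate conformer; tie -> first in file
resolve_altloc <- function(atoms) {
  if (all(is.na(atoms$alt))) return(atoms)
  key <- paste(atoms$frame, atom_identity(atoms), sep = "@")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  keep_first <- !duplicated(key[ord])
  kept <- sort(ord[keep_first])
  atoms[kept, , drop = FALSE]
}

fmt_atom_name <- function(name, element) {
  # one/two-letter element alignment per the fixed-column convention
  ifelse(nchar(name) >= 4, sprintf("%-4s", name),
         ifelse(nchar(element) == 2, sprintf("%-4s", name),
                sprintf(" %-3s", name)))
}

#' Write an ensemble to a (multi-model) PDB file
#'
#' Inverse of [read_structure()]: coordinates are written at the format's
#' 0.001 Angstrom precision and occupancy/B-factor at 0.01, so a round trip
#' reproduces coordinates to within 1e-3 Angstrom and all identifiers
#' exactly. Ensembles with more than one frame are written as
#' `MODEL`/`ENDMDL` blocks.
#'
#' @param atoms An ensemble tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(atoms, path) {
  validate_ensemble(atoms)
  frames <- sort(unique(atoms$frame))
  multi <- length(frames) > 1
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- atoms[atoms$frame == frames[k], , drop = FALSE]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    lines <- sprintf(
      "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      fr$record, fr$serial %% 100000L,
      fmt_atom_name(fr$name, fr$element),
      ifelse(is.na(fr$alt), " ", fr$alt),
      fr$res_name, fr$chain, fr$res_seq,
      ifelse(is.na(fr$insertion), " ", fr$insertion),
      fr$x, fr$y, fr$z, fr$occupancy, fr$b_factor,
      sprintf("%2s", fr$element))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
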