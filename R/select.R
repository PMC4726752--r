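MAIN_CHAIN_NAMES <- c("N", "CA", "C", "O")

#' Parse a selection expression
#'
#' Selections are whitespace-separated `key:value` clauses combined with
#' logical AND, plus bare class keywords:
#' `"chain:A resid:240-260 name:CA"`, `"heavy"`, `"mainchain"`, `"calpha"`,
#' `"sidechain"`, `"all"`. `resid` accepts single numbers, ranges `a-b`
#' and comma-separated lists; `chain`, `name` and `resname` accept
#' comma-separated alternatives. Evaluation is order-independent.
#'
#' @param expr Selection string (or an already-parsed selection).
#' @return An object of class `cp_selection`.
#' @export
parse_selection <- function(expr) {
  if (inherits(expr, "cp_selection")) return(expr)
  stopifnot(is.character(expr), length(expr) == 1)
  tokens <- strsplit(trimws(expr), "\\s+")[[1]]
  tokens <- tokens[tokens != ""]
  sel <- list(chain = NULL, resid = NULL, resname = NULL, name = NULL,
              class = character(), text = expr)
  for (tok in tokens) {
    if (!grepl(":", tok, fixed = TRUE)) {
      kw <- tolower(tok)
      if (!kw %in% c("all", "heavy", "mainchain", "calpha", "sidechain")) {
        stop("unknown selection keyword: '", tok, "'", call. = FALSE)
      }
      sel$class <- c(sel$class, kw)
      next
    }
    kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
    key <- tolower(kv[1])
    val <- kv[2]
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    if (key == "resid") {
      ids <- unlist(lapply(parts, function(p) {
        if (grepl("^-?[0-9]+--?[0-9]+$", p)) {
          ab <- as.integer(strsplit(sub("^(-?[0-9]+)-", "\\1 ", p), " ")[[1]])
          seq(ab[1], ab[2])
        } else as.integer(p)
      }))
      if (anyNA(ids)) stop("malformed resid clause: '", tok, "'", call. = FALSE)
      sel$resid <- c(sel$resid, ids)
    } else if (key %in% c("chain", "resname", "name")) {
      sel[[key]] <- c(sel[[key]], parts)
    } else {
      stop("unknown selection key: '", key, "'", call. = FALSE)
    }
  }
  structure(sel, class = "cp_selection")
}

selection_mask <- function(atoms, sel) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(sel$chain)) keep <- keep & atoms$chain %in% sel$chain
  if (!is.null(sel$resid)) keep <- keep & atoms$res_seq %in% sel$resid
  if (!is.null(sel$resname)) keep <- keep & atoms$res_name %in% sel$resname
  if (!is.null(sel$name)) keep <- keep & atoms$name %in% sel$name
  for (kw in sel$class) {
    keep <- keep & switch(kw,
      all = TRUE,
      heavy = toupper(atoms$element) != "H",
      mainchain = atoms$record == "ATOM" & atoms$name %in% MAIN_CHAIN_NAMES,
      calpha = atoms$record == "ATOM" & atoms$name == "CA",
      sidechain = atoms$record == "ATOM" &
        toupper(atoms$element) != "H" &
        !atoms$name %in% MAIN_CHAIN_NAMES)
  }
  keep
}

#' Select atoms from an ensemble or frame
#'
#' Applies a selection expression and returns the matching atoms in file
#' order. An empty result is valid but reported with a warning, so silent
#' typos in residue numbers do not go unnoticed.
#'
#' @param atoms An ensemble tibble (one or more frames).
#' @param expr Selection string or parsed selection (see
#'   [parse_selection()]).
#' @return The matching rows, order preserved.
#' @export
#' @examples
#' fr <- make_reference_site(matrix(c(0, 3, 3, 0), 2, 2), seed = 1)
#' select_atoms(fr, "heavy")
select_atoms <- function(atoms, expr) {
  sel <- parse_selection(expr)
  out <- atoms[selection_mask(atoms, sel), , drop = FALSE]
  if (nrow(out) == 0) {
    warning("selection '", sel$text, "' matched no atoms", call. = FALSE)
  }
  out
}

#' An atom specification
#'
#' Resolves to exactly one atom in a frame. Also accepted everywhere as a
#' compact string `"chain:res_seq:name"` (e.g. `"A:261:OG1"`), with an
#' optional insertion code appended to the residue number (`"A:100A:CA"`).
#'
#' @param chain Chain identifier.
#' @param res_seq Residue number.
#' @param name Atom name.
#' @param insertion Optional insertion code.
#' @return An object of class `cp_atom_spec`.
#' @export
atom_spec <- function(chain, res_seq, name, insertion = NA_character_) {
  structure(list(chain = as.character(chain), res_seq = as.integer(res_seq),
                 name = as.character(name),
                 insertion = as.character(insertion)),
            class = "cp_atom_spec")
}

#' @export
format.cp_atom_spec <- function(x, ...) {
  paste0(x$chain, ":", x$res_seq,
         ifelse(is.na(x$insertion), "", x$insertion), ":", x$name)
}

#' @export
print.cp_atom_spec <- function(x, ...) {
  cat("<atom spec ", format(x), ">\n", sep = "")
  invisible(x)
}

as_atom_spec <- function(spec) {
  if (inherits(spec, "cp_atom_spec")) return(spec)
  stopifnot(is.character(spec), length(spec) == 1)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    stop("atom spec must be 'chain:res_seq:name', got '", spec, "'",
         call. = FALSE)
  }
  res <- parts[2]
  ins <- NA_character_
  if (grepl("^[0-9]+[A-Za-z]$", res)) {
    ins <- substr(res, nchar(res), nchar(res))
    res <- substr(res, 1, nchar(res) - 1)
  }
  atom_spec(parts[1], as.integer(res), parts[3], ins)
}

# resolve a spec to exactly one row of a single-frame table
resolve_spec <- function(frame, spec) {
  spec <- as_atom_spec(spec)
  hit <- frame$chain == spec$chain & frame$res_seq == spec$res_seq &
    frame$name == spec$name &
    (is.na(spec$insertion) | (!is.na(frame$insertion) &
                                frame$insertion == spec$insertion))
  n <- sum(hit)
  if (n == 0) {
    stop("atom spec '", format(spec), "' matches no atom in the frame",
         call. = FALSE)
  }
  if (n > 1) {
    stop("atom spec '", format(spec), "' is ambiguous (", n, " matches)",
         call. = FALSE)
  }
  frame[hit, , drop = FALSE]
}
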