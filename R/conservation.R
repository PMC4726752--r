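MSA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                  "X", "-")

new_msa <- function(tbl) {
  widths <- nchar(tbl$seq)
  if (length(unique(widths)) != 1) {
    bad <- tbl$id[widths != widths[1]][1]
    stop("ragged alignment: record '", bad, "' has width ",
         widths[widths != widths[1]][1], ", expected ", widths[1],
         call. = FALSE)
  }
  chars <- unique(strsplit(paste(tbl$seq, collapse = ""), "")[[1]])
  bad <- setdiff(chars, MSA_ALPHABET)
  if (length(bad) > 0) {
    stop("characters outside the alignment alphabet: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  out <- tibble::as_tibble(tbl)
  attr(out, "L") <- widths[1]
  class(out) <- c("cp_msa", class(out))
  out
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' All records must share one width; lowercase residues are uppercased
#' with a message; `.` gap characters are normalised to `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @param format Only `"fasta"`.
#' @return An alignment tibble of class `cp_msa` (columns `id`, `seq`)
#'   with the alignment width in attribute `"L"`.
#' @export
read_msa <- function(path, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
    message("lowercase residues uppercased")
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  ids <- names(aa)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  new_msa(tibble::tibble(id = ids, seq = unname(seqs)))
}

#' Write an alignment to FASTA
#' @param msa A `cp_msa` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa <- function(msa, path) {
  writeLines(paste0(">", msa$id, "\n", msa$seq), path)
  invisible(path)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seq, ""))
}

#' Per-column conservation by normalized Shannon entropy
#'
#' For each column the amino-acid frequencies (gaps excluded) give a
#' Shannon entropy H, and the conservation score is `1 - H / log(20)`: 1
#' for a monomorphic column, 0 for a uniform one. This is a declared
#' simplified stand-in for tree-aware evolutionary-rate estimation (such
#' as ConSurf's Bayesian method): it ranks columns for "highly conserved"
#' flags but ignores phylogeny and substitution similarity. Columns with
#' more than 50% gaps are flagged unreliable; all-gap columns score `NA`.
#'
#' @param msa A `cp_msa` tibble.
#' @param method Only `"normalized-entropy"`.
#' @return A tibble with columns `column`, `score`, `gap_fraction`,
#'   `flagged`; method recorded in attribute `"method"`.
#' @export
column_conservation <- function(msa, method = "normalized-entropy") {
  method <- match.arg(method, "normalized-entropy")
  if (nrow(msa) == 0) stop("empty alignment", call. = FALSE)
  m <- msa_matrix(msa)
  L <- ncol(m)
  score <- numeric(L)
  gapf <- numeric(L)
  for (cidx in seq_len(L)) {
    col <- m[, cidx]
    gap <- col %in% c("-", "X")
    gapf[cidx] <- mean(col == "-")
    res <- col[col != "-" & col != "X"]
    if (length(res) == 0) {
      score[cidx] <- NA_real_
      next
    }
    p <- table(res) / length(res)
    H <- -sum(p * log(p))
    score[cidx] <- 1 - H / log(20)
  }
  out <- tibble::tibble(column = seq_len(L), score = score,
                        gap_fraction = gapf, flagged = gapf > 0.5)
  attr(out, "method") <- method
  class(out) <- c("cp_conservation", class(out))
  out
}

#' @export
autoplot.cp_conservation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$column, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue", width = 1) +
    ggplot2::labs(x = "alignment column",
                  y = "conservation (1 - H/log 20)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

default_substitution <- function(substitution, match, mismatch) {
  if (is.matrix(substitution)) return(substitution)
  if (identical(substitution, "simple")) {
    letters20 <- MSA_ALPHABET[1:21]  # 20 aa + X
    m <- matrix(mismatch, 21, 21, dimnames = list(letters20, letters20))
    diag(m) <- match
    return(m)
  }
  mat_env <- new.env()
  utils::data(list = substitution, package = "Biostrings", envir = mat_env)
  get(substitution, envir = mat_env)
}

#' Optimal global alignment of two sequences with affine gaps
#'
#' Needleman-Wunsch global alignment (via Biostrings) under an affine gap
#' model in which a gap of length L costs `gap_open + gap_extend * L`.
#' The result is returned as a residue map: the ordered correspondence of
#' 1-based ungapped positions produced by match/mismatch columns only.
#'
#' @param seq_a,seq_b Ungapped amino-acid sequences (character scalars).
#' @param substitution `"BLOSUM62"` (default), any Biostrings matrix name,
#'   `"simple"` for a match/mismatch matrix, or a numeric matrix.
#' @param gap_open,gap_extend Affine gap parameters (defaults 10 and 0.5).
#' @param match,mismatch Scores used when `substitution = "simple"`.
#' @return A tibble of class `cp_residue_map` with columns `pos_a`,
#'   `pos_b`, `res_a`, `res_b`; alignment score, aligned strings and the
#'   gap parameters are carried as attributes.
#' @export
#' @examples
#' m <- align_pair("ACDEFGH", "ACEFGH")
#' map_residue(m, 5)
align_pair <- function(seq_a, seq_b, substitution = "BLOSUM62",
                       gap_open = 10, gap_extend = 0.5,
                       match = 1, mismatch = -1) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  for (s in c(seq_a, seq_b)) {
    bad <- setdiff(unique(strsplit(s, "")[[1]]), setdiff(MSA_ALPHABET, "-"))
    if (length(bad) > 0) {
      stop("characters outside the amino-acid alphabet: ",
           paste(bad, collapse = " "), call. = FALSE)
    }
  }
  mat <- default_substitution(substitution, match, mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pos_a <- cumsum(a != "-")
  pos_b <- cumsum(b != "-")
  both <- a != "-" & b != "-"
  out <- tibble::tibble(pos_a = pos_a[both], pos_b = pos_b[both],
                        res_a = a[both], res_b = b[both])
  attr(out, "score") <- Biostrings::score(aln)
  attr(out, "aligned_a") <- paste(a, collapse = "")
  attr(out, "aligned_b") <- paste(b, collapse = "")
  attr(out, "params") <- list(substitution = if (is.matrix(substitution))
    "custom" else substitution, gap_open = gap_open,
    gap_extend = gap_extend)
  attr(out, "len_a") <- nchar(seq_a)
  attr(out, "len_b") <- nchar(seq_b)
  class(out) <- c("cp_residue_map", class(out))
  out
}

#' @export
glance.cp_residue_map <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(score = attr(x, "score"), n_pairs = nrow(x),
                 substitution = p$substitution, gap_open = p$gap_open,
                 gap_extend = p$gap_extend)
}

#' Map a residue position through a residue map
#'
#' Returns the aligned partner position of an ungapped position in
#' sequence A, or `NA` when it sits opposite a gap — the operation behind
#' transferring mutation sites between homologs (e.g. a human-enzyme
#' mutation onto the yeast numbering).
#'
#' @param map A `cp_residue_map` from [align_pair()].
#' @param pos_a 1-based ungapped position(s) in sequence A.
#' @return Integer vector: partner position(s) in sequence B, `NA` where
#'   unaligned.
#' @export
map_residue <- function(map, pos_a) {
  len_a <- attr(map, "len_a")
  if (any(pos_a < 1 | pos_a > len_a)) {
    stop("position out of range 1..", len_a, call. = FALSE)
  }
  map$pos_b[match(pos_a, map$pos_a)]
}

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Project a conservation profile onto a structure
#'
#' Writes each residue's conservation score into the B-factor column of
#' all its atoms, the conventional vehicle for colouring a structure by
#' conservation. Structure residues of the chosen chain are matched in
#' order, 1:1, to the ungapped positions of the target sequence in the
#' alignment; residues left over (or opposite all-gap columns) receive
#' the sentinel value and are reported in attribute `"unmapped"`.
#' Residue-identity mismatches between structure and sequence are
#' reported with a warning, not an error, so homology-model numbering
#' quirks remain visible.
#'
#' @param profile A conservation tibble from [column_conservation()].
#' @param msa The `cp_msa` the profile was computed from.
#' @param target_id Identifier of the structure's sequence in the
#'   alignment.
#' @param atoms A single-frame ensemble tibble.
#' @param chain Chain to annotate.
#' @param sentinel B-factor written to unmapped residues (default -1).
#' @return The frame with updated B-factors (class preserved); unmapped
#'   residue keys in attribute `"unmapped"`.
#' @export
project_profile <- function(profile, msa, target_id, atoms, chain,
                            sentinel = -1) {
  hit <- which(msa$id == target_id)
  if (length(hit) != 1) {
    stop("target id '", target_id, "' not present exactly once in the ",
         "alignment", call. = FALSE)
  }
  aligned <- strsplit(msa$seq[hit], "")[[1]]
  ungapped_cols <- which(aligned != "-")
  target_seq <- aligned[ungapped_cols]

  fr <- atoms[atoms$frame == atoms$frame[1], , drop = FALSE]
  on_chain <- fr$chain == chain & fr$record == "ATOM"
  res_key <- paste(fr$res_seq, ifelse(is.na(fr$insertion), "",
                                      fr$insertion))
  res_levels <- unique(res_key[on_chain])
  n_res <- length(res_levels)

  scores <- rep(sentinel, n_res)
  n_map <- min(n_res, length(target_seq))
  col_scores <- profile$score[ungapped_cols]
  scores[seq_len(n_map)] <- ifelse(is.na(col_scores[seq_len(n_map)]),
                                   sentinel, col_scores[seq_len(n_map)])
  # report residue-identity mismatches where the structure names residues
  res_names <- fr$res_name[on_chain][match(res_levels, res_key[on_chain])]
  olc <- unname(AA_3TO1[toupper(res_names[seq_len(n_map)])])
  mism <- which(!is.na(olc) & olc != target_seq[seq_len(n_map)])
  if (length(mism) > 0) {
    warning("residue identity mismatch at structure position(s) ",
            paste(utils::head(res_levels[mism], 5), collapse = ", "),
            " (structure vs alignment sequence)", call. = FALSE)
  }
  unmapped <- res_levels[scores == sentinel]

  out <- atoms
  key_all <- paste(atoms$res_seq, ifelse(is.na(atoms$insertion), "",
                                         atoms$insertion))
  sel <- atoms$chain == chain & atoms$record == "ATOM"
  idx <- match(key_all[sel], res_levels)
  out$b_factor[sel] <- scores[idx]
  attr(out, "unmapped") <- unmapped
  out
}
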