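coords_matrix <- function(frame) {
  cbind(frame$x, frame$y, frame$z)
}

#' Measure an interatomic distance in every frame
#'
#' Euclidean distance between two atoms, one value per frame. This is the
#' primitive behind active-site descriptor scoring and choke-point
#' monitoring of trajectory stand-ins.
#'
#' @param atoms An ensemble tibble.
#' @param a,b Atom specs (`"chain:res:name"` strings or [atom_spec()]).
#' @return A tibble with columns `frame` and `distance` (Angstrom).
#' @export
#' @examples
#' fr <- make_reference_site(matrix(c(0, 5, 5, 0), 2, 2), seed = 1)
#' measure_distance(fr, "S:1:CA", "S:2:CA")
measure_distance <- function(atoms, a, b) {
  frames <- sort(unique(atoms$frame))
  d <- vapply(frames, function(k) {
    fr <- atoms[atoms$frame == k, , drop = FALSE]
    pa <- resolve_spec(fr, a)
    pb <- resolve_spec(fr, b)
    sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2 + (pa$z - pb$z)^2)
  }, numeric(1))
  tibble::tibble(frame = frames, distance = d)
}

# closed-form least-squares rigid superposition (SVD construction);
# proper rotation enforced via the determinant sign correction
kabsch <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), ncol(mobile) == 3)
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd, fitted = fitted)
}

# pair atoms of two frames over a selection; `pairing` is either NULL
# (match by identical chain/res_seq/insertion/name) or a residue map whose
# pos_a indexes mobile-chain residue ordinals and pos_b reference ones
pair_atoms <- function(mobile, reference, expr = "heavy", pairing = NULL) {
  ma <- select_atoms(mobile, expr)
  ra <- select_atoms(reference, expr)
  if (is.null(pairing)) {
    ka <- atom_identity(ma)
    kb <- atom_identity(ra)
    common <- intersect(ka, kb)
    list(mobile = ma[match(common, ka), , drop = FALSE],
         reference = ra[match(common, kb), , drop = FALSE])
  } else {
    stopifnot(inherits(pairing, "cp_residue_map"))
    res_ord <- function(fr) {
      key <- paste(fr$chain, fr$res_seq,
                   ifelse(is.na(fr$insertion), "", fr$insertion))
      match(key, unique(key))
    }
    oa <- res_ord(ma)
    ob <- res_ord(ra)
    mi <- integer(0); ri <- integer(0)
    for (p in seq_len(nrow(pairing))) {
      ia <- which(oa == pairing$pos_a[p])
      ib <- which(ob == pairing$pos_b[p])
      nm <- intersect(ma$name[ia], ra$name[ib])
      mi <- c(mi, ia[match(nm, ma$name[ia])])
      ri <- c(ri, ib[match(nm, ra$name[ib])])
    }
    list(mobile = ma[mi, , drop = FALSE],
         reference = ra[ri, , drop = FALSE])
  }
}

#' Least-squares rigid superposition of two frames
#'
#' Optimal rotation/translation of `mobile` onto `reference` over a paired
#' atom set, computed with the closed-form SVD construction and a proper
#' rotation (determinant +1) enforced. Pairing is by identical atom
#' identity, or through a residue map for cross-homolog superpositions
#' (sequence-aligned residues, matched atom names).
#'
#' @param mobile,reference Single-frame ensemble tibbles.
#' @param expr Selection applied to both frames (default `"heavy"`).
#' @param pairing `NULL` for identity pairing, or a residue map from
#'   [align_pair()] whose `pos_a` refers to mobile residue ordinals and
#'   `pos_b` to reference ones.
#' @return An object of class `cp_superposition`: list with `rotation`
#'   (3x3), `translation` (length 3), `rmsd` (Angstrom) and `n_atoms`.
#' @export
superpose <- function(mobile, reference, expr = "heavy", pairing = NULL) {
  pr <- pair_atoms(mobile, reference, expr, pairing)
  n <- nrow(pr$mobile)
  if (n < 3) {
    stop("underdetermined superposition: ", n,
         " paired atoms (need at least 3)", call. = FALSE)
  }
  fit <- kabsch(coords_matrix(pr$mobile), coords_matrix(pr$reference))
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_atoms = n),
            class = "cp_superposition")
}

#' @export
print.cp_superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d paired atoms, rmsd %.4f A>\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.cp_superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n_atoms)
}

#' Apply a superposition to a frame
#' @param frame A single-frame ensemble tibble.
#' @param fit A `cp_superposition`.
#' @return The frame with transformed coordinates.
#' @export
apply_transform <- function(frame, fit) {
  xyz <- coords_matrix(frame) %*% t(fit$rotation)
  xyz <- sweep(xyz, 2, fit$translation, "+")
  frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
  frame
}

#' Per-frame RMSD of an ensemble against a reference frame
#'
#' Each frame is first superposed onto the reference over the selection,
#' then the root-mean-square deviation of the paired atoms is reported, as
#' in standard trajectory analysis.
#'
#' @param atoms An ensemble tibble.
#' @param reference A single-frame ensemble tibble sharing the selected
#'   topology.
#' @param expr Selection (default `"calpha"`).
#' @return A tibble with columns `frame` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(atoms, reference, expr = "calpha") {
  frames <- sort(unique(atoms$frame))
  r <- vapply(frames, function(k) {
    superpose(atoms[atoms$frame == k, , drop = FALSE], reference, expr)$rmsd
  }, numeric(1))
  tibble::tibble(frame = frames, rmsd = r)
}
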