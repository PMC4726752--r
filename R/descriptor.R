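#' Build a reference-based active-site geometric descriptor
#'
#' Captures a catalytically competent active-site geometry as the full set
#' of pairwise distances between a small set of site atoms measured in a
#' reference frame (for a flavoprotein monooxygenase: the hydrogen-bonding
#' partners of the bound aromatic substrate plus the reactive flavin C4X
#' atom). All k*(k-1)/2 unordered pairs are used, which fully determines the
#' site geometry up to chirality. The descriptor is immutable after
#' construction.
#'
#' @param reference A single-frame ensemble tibble (the reference holo
#'   structure).
#' @param site_atoms Character vector (or list of [atom_spec()]) of k >= 2
#'   atom specs, all resolvable in `reference`.
#' @param reference_id Provenance string recorded in the descriptor.
#' @return An object of class `cp_descriptor` with elements `site_atoms`,
#'   `pairs` (tibble: `atom_i`, `atom_j`, `ref_distance`) and
#'   `reference_id`.
#' @export
#' @examples
#' site <- make_reference_site(4.32 * (1 - diag(4)), seed = 1)
#' d <- build_descriptor(site, c("S:1:CA", "S:2:CA", "S:3:CA", "S:4:CA"))
#' tidy(d)
build_descriptor <- function(reference, site_atoms,
                             reference_id = "reference") {
  specs <- lapply(site_atoms, as_atom_spec)
  k <- length(specs)
  if (k < 2) stop("need at least 2 site atoms", call. = FALSE)
  labels <- vapply(specs, format, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate site atom spec: ", labels[duplicated(labels)][1],
         call. = FALSE)
  }
  fr <- reference[reference$frame == reference$frame[1], , drop = FALSE]
  pos <- t(vapply(specs, function(s) {
    a <- resolve_spec(fr, s)
    c(a$x, a$y, a$z)
  }, numeric(3)))
  idx <- utils::combn(k, 2)
  dists <- sqrt(rowSums((pos[idx[1, ], , drop = FALSE] -
                           pos[idx[2, ], , drop = FALSE])^2))
  if (any(dists <= 0)) {
    stop("coincident site atoms give a zero reference distance",
         call. = FALSE)
  }
  structure(list(
    site_atoms = labels,
    pairs = tibble::tibble(atom_i = labels[idx[1, ]],
                           atom_j = labels[idx[2, ]],
                           ref_distance = dists),
    reference_id = reference_id),
    class = "cp_descriptor")
}

#' @export
print.cp_descriptor <- function(x, ...) {
  cat("<active-site descriptor: ", length(x$site_atoms), " atoms, ",
      nrow(x$pairs), " pairs, reference '", x$reference_id, "'>\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.cp_descriptor <- function(x, ...) x$pairs

apply_mapping <- function(spec_label, mapping) {
  if (is.null(mapping)) return(spec_label)
  if (inherits(mapping, "cp_residue_map")) {
    sp <- as_atom_spec(spec_label)
    tgt <- map_residue(mapping, sp$res_seq)
    if (is.na(tgt)) {
      stop("site atom ", spec_label,
           " maps to a gap in the residue map", call. = FALSE)
    }
    return(format(atom_spec(sp$chain, tgt, sp$name, sp$insertion)))
  }
  if (!is.null(names(mapping))) {
    hit <- match(spec_label, names(mapping))
    if (!is.na(hit)) return(unname(mapping[hit]))
    return(spec_label)
  }
  stop("mapping must be NULL, a residue map, or a named character vector",
       call. = FALSE)
}

#' Score frames against an active-site descriptor
#'
#' For every frame, each descriptor pair contributes the deviation between
#' its distance in the frame and its reference distance; the frame score S
#' is the sum over pairs. A low S marks a frame whose active-site geometry
#' resembles the reference (catalytically plausible). By default deviations
#' enter as absolute values so that opposite-signed distortions cannot
#' cancel; `signed = TRUE` gives the raw signed sum for fidelity
#' experiments.
#'
#' @param descriptor A `cp_descriptor`.
#' @param atoms An ensemble tibble (any number of frames).
#' @param mapping `NULL` (identity), a residue map applied to site-atom
#'   residue numbers, or a named character vector of full atom-spec
#'   replacements (e.g. `c("A:212:OG" = "A:261:OG1")`) for scoring a
#'   homolog whose site atoms differ in numbering or atom name.
#' @param signed If `TRUE`, sum signed differences instead of absolute
#'   deviations.
#' @return A tibble of class `cp_scores` with columns `frame` and `S`
#'   (Angstrom), carrying the per-pair deviations as a long tibble in
#'   attribute `"deviations"`.
#' @export
score_frames <- function(descriptor, atoms, mapping = NULL, signed = FALSE) {
  stopifnot(inherits(descriptor, "cp_descriptor"))
  frames <- sort(unique(atoms$frame))
  if (length(frames) == 0) stop("empty ensemble", call. = FALSE)
  labels <- vapply(descriptor$site_atoms, apply_mapping, character(1),
                   mapping = mapping)
  mapped_pairs <- tibble::tibble(
    atom_i = vapply(descriptor$pairs$atom_i, apply_mapping, character(1),
                    mapping = mapping),
    atom_j = vapply(descriptor$pairs$atom_j, apply_mapping, character(1),
                    mapping = mapping),
    ref_distance = descriptor$pairs$ref_distance)

  dev_rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    fr <- atoms[atoms$frame == frames[fi], , drop = FALSE]
    pos <- t(vapply(labels, function(s) {
      a <- tryCatch(resolve_spec(fr, s), error = function(e) {
        stop("frame ", frames[fi], ": ", conditionMessage(e), call. = FALSE)
      })
      c(a$x, a$y, a$z)
    }, numeric(3)))
    rownames(pos) <- labels
    d <- sqrt(rowSums((pos[mapped_pairs$atom_i, , drop = FALSE] -
                         pos[mapped_pairs$atom_j, , drop = FALSE])^2))
    dev <- d - mapped_pairs$ref_distance
    if (!signed) dev <- abs(dev)
    dev_rows[[fi]] <- tibble::tibble(
      frame = frames[fi],
      pair = paste(mapped_pairs$atom_i, mapped_pairs$atom_j, sep = "--"),
      deviation = dev)
  }
  devs <- dplyr::bind_rows(dev_rows)
  out <- dplyr::summarise(dplyr::group_by(devs, .data$frame),
                          S = sum(.data$deviation), .groups = "drop")
  out <- tibble::as_tibble(out)
  attr(out, "deviations") <- devs
  attr(out, "signed") <- signed
  attr(out, "reference_id") <- descriptor$reference_id
  class(out) <- c("cp_scores", class(out))
  out
}

#' @rdname score_frames
#' @export
score_frame <- function(descriptor, atoms, mapping = NULL, signed = FALSE) {
  score_frames(descriptor, atoms, mapping = mapping, signed = signed)
}

#' Select catalytically plausible frames for docking
#'
#' Combines the two conformational pre-selection criteria: a frame is
#' eligible when its choke-point diameter reaches `min_diameter` (the
#' channel is open wide enough for the substrate), and eligible frames are
#' ranked by ascending descriptor score S (most reference-like active site
#' first). Ties are broken by lower frame index.
#'
#' @param scores A `cp_scores` tibble from [score_frames()].
#' @param diameters A tibble with columns `frame` and `diameter` (e.g. from
#'   [diameter_series()]), covering the same frames.
#' @param min_diameter Minimum choke-point diameter in Angstrom (default
#'   4.0, an aromatic ring clearance).
#' @param n Number of frames requested.
#' @return A tibble with columns `rank`, `frame`, `S`, `diameter`. Fewer
#'   than `n` rows (with a warning) if fewer frames are eligible.
#' @export
select_frames <- function(scores, diameters, min_diameter = 4, n = 1) {
  if (!setequal(scores$frame, diameters$frame)) {
    stop("scores and diameters cover different frame sets", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(scores)[, c("frame", "S")],
    tibble::as_tibble(diameters)[, c("frame", "diameter")],
    by = "frame")
  eligible <- joined[joined$diameter >= min_diameter, , drop = FALSE]
  eligible <- eligible[order(eligible$S, eligible$frame), , drop = FALSE]
  if (nrow(eligible) == 0) {
    warning("no frame reaches min_diameter = ", min_diameter,
            " A; empty selection", call. = FALSE)
  } else if (nrow(eligible) < n) {
    warning("only ", nrow(eligible), " of ", n,
            " requested frames are eligible", call. = FALSE)
  }
  out <- utils::head(eligible, n)
  tibble::tibble(rank = seq_len(nrow(out)), frame = out$frame,
                 S = out$S, diameter = out$diameter)
}

#' @export
autoplot.cp_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$S)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "frame", y = "descriptor score S (Å)",
                  title = "Active-site descriptor score per frame") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
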