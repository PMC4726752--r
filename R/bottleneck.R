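as_residue_id <- function(x) {
  if (inherits(x, "cp_residue_id")) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("residue id must be 'chain:res_seq', got '", x, "'", call. = FALSE)
  }
  structure(list(chain = parts[1], res_seq = as.integer(parts[2])),
            class = "cp_residue_id")
}

residue_atoms <- function(frame, rid, heavy = TRUE) {
  rid <- as_residue_id(rid)
  out <- frame[frame$chain == rid$chain & frame$res_seq == rid$res_seq, ,
               drop = FALSE]
  if (heavy) out <- out[toupper(out$element) != "H", , drop = FALSE]
  if (nrow(out) == 0) {
    stop("residue ", rid$chain, ":", rid$res_seq,
         " has no (heavy) atoms in the frame", call. = FALSE)
  }
  out
}

min_pair_surface_distance <- function(a, b) {
  ra <- vdw_radius(a$element)
  rb <- vdw_radius(b$element)
  pa <- coords_matrix(a)
  pb <- coords_matrix(b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * (pa %*% t(pb))
  d <- sqrt(pmax(d2, 0)) - outer(ra, rb, "+")
  min(d)
}

#' Choke-point diameter between a residue pair
#'
#' The free diameter of a channel at its bottleneck, parameterized by the
#' two residues flanking the choke point. In the default
#' `"closest-heavy-atom"` mode it is the minimum over heavy-atom pairs of
#' the surface-to-surface distance `dist(a, b) - vdw(a) - vdw(b)`; it can
#' be negative when surfaces interpenetrate. The `"centroid"` mode uses
#' side-chain centroid separation instead (no radius subtraction).
#'
#' @param frame A single-frame ensemble tibble.
#' @param res1,res2 Residue ids `"chain:res_seq"`.
#' @param mode `"closest-heavy-atom"` (default) or `"centroid"`.
#' @return Diameter in Angstrom (scalar).
#' @export
bottleneck_diameter <- function(frame, res1, res2,
                                mode = c("closest-heavy-atom", "centroid")) {
  mode <- match.arg(mode)
  a <- residue_atoms(frame, res1)
  b <- residue_atoms(frame, res2)
  if (mode == "closest-heavy-atom") {
    min_pair_surface_distance(a, b)
  } else {
    sc <- function(r) {
      side <- r[!r$name %in% MAIN_CHAIN_NAMES, , drop = FALSE]
      if (nrow(side) == 0) side <- r
      colMeans(coords_matrix(side))
    }
    sqrt(sum((sc(a) - sc(b))^2))
  }
}

#' Choke-point diameter tracked across an ensemble
#'
#' Applies [bottleneck_diameter()] to every frame, giving the time series
#' of channel diameter at a choke point — the quantity whose collapse
#' distinguishes blocked mutants from an open wild-type channel.
#'
#' @inheritParams bottleneck_diameter
#' @param atoms An ensemble tibble.
#' @return A tibble of class `cp_bottleneck_series` with columns `frame`
#'   and `diameter` (Angstrom); the residue pair and mode are carried as
#'   attributes.
#' @export
diameter_series <- function(atoms, res1, res2,
                            mode = c("closest-heavy-atom", "centroid")) {
  mode <- match.arg(mode)
  frames <- sort(unique(atoms$frame))
  if (length(frames) == 0) stop("empty ensemble", call. = FALSE)
  d <- vapply(frames, function(k) {
    tryCatch(
      bottleneck_diameter(atoms[atoms$frame == k, , drop = FALSE],
                          res1, res2, mode),
      error = function(e) stop("frame ", k, ": ", conditionMessage(e),
                               call. = FALSE))
  }, numeric(1))
  out <- tibble::tibble(frame = frames, diameter = d)
  attr(out, "pair") <- c(as.character(res1)[1], as.character(res2)[1])
  attr(out, "mode") <- mode
  class(out) <- c("cp_bottleneck_series", class(out))
  out
}

#' Classify a channel as open, closed or persistently blocked
#'
#' A frame is open when the choke-point diameter reaches the threshold;
#' `blocked_persistently` is set when no frame is ever open (the behaviour
#' of a channel-spanning salt bridge in a double mutant, as opposed to
#' single mutants fluctuating between open and closed states).
#'
#' @param series A tibble with columns `frame` and `diameter` (e.g. from
#'   [diameter_series()]).
#' @param threshold Open/closed diameter threshold in Angstrom (default
#'   4.0).
#' @return A tibble of class `cp_channel_state` with columns `frame`,
#'   `diameter`, `open`; use [glance()] for `open_fraction` and
#'   `blocked_persistently`.
#' @export
classify_channel <- function(series, threshold = 4) {
  if (nrow(series) == 0) stop("empty diameter series", call. = FALSE)
  out <- tibble::tibble(frame = series$frame, diameter = series$diameter,
                        open = series$diameter >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "pair") <- attr(series, "pair")
  class(out) <- c("cp_channel_state", class(out))
  out
}

#' @export
glance.cp_channel_state <- function(x, ...) {
  tibble::tibble(threshold = attr(x, "threshold"),
                 n_frames = nrow(x),
                 open_fraction = mean(x$open),
                 blocked_persistently = !any(x$open))
}

#' @export
autoplot.cp_channel_state <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$frame, y = .data$diameter)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$open), size = 0.9) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "frame", y = "choke-point diameter (Å)",
                  colour = sprintf("open (≥ %.1f Å)", thr)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cp_bottleneck_series <- function(object, ...) {
  pair <- attr(object, "pair")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$frame, y = .data$diameter)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "frame", y = "choke-point diameter (Å)",
                  title = paste("Bottleneck", paste(pair, collapse = " / "))) +
    ggplot2::theme_minimal()
}

BASIC_N_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                      HIS = c("ND1", "NE2"))
ACIDIC_O_ATOMS <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

side_chain_charged_atoms <- function(frame, rid, table, kind) {
  r <- residue_atoms(frame, rid)
  wanted <- table[[toupper(r$res_name[1])]]
  if (is.null(wanted)) {
    stop("residue ", format_rid(rid), " (", r$res_name[1],
         ") is not a ", kind, " residue", call. = FALSE)
  }
  out <- r[r$name %in% wanted, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("residue ", format_rid(rid), " lacks its ", kind,
         " side-chain atoms (", paste(wanted, collapse = "/"),
         "): truncated model?", call. = FALSE)
  }
  out
}

format_rid <- function(rid) {
  rid <- as_residue_id(rid)
  paste0(rid$chain, ":", rid$res_seq)
}

#' Salt-bridge detection between a basic and an acidic residue
#'
#' A salt bridge is called when the minimal distance between the basic
#' side-chain nitrogens (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2) and the
#' acidic side-chain oxygens (Glu OE1/OE2, Asp OD1/OD2) is at most
#' `cutoff`. Missing side-chain atoms are an error, distinguishing
#' truncated models from genuinely absent interactions.
#'
#' @param frame A single-frame ensemble tibble.
#' @param basic_res,acidic_res Residue ids `"chain:res_seq"`.
#' @param cutoff N-O distance cutoff in Angstrom (default 4.0).
#' @return A one-row tibble with `present` (logical) and `min_no_distance`
#'   (Angstrom).
#' @export
salt_bridge_present <- function(frame, basic_res, acidic_res, cutoff = 4) {
  n_atoms <- side_chain_charged_atoms(frame, basic_res, BASIC_N_ATOMS,
                                      "basic")
  o_atoms <- side_chain_charged_atoms(frame, acidic_res, ACIDIC_O_ATOMS,
                                      "acidic")
  pn <- coords_matrix(n_atoms)
  po <- coords_matrix(o_atoms)
  d2 <- outer(rowSums(pn^2), rowSums(po^2), "+") - 2 * (pn %*% t(po))
  dmin <- sqrt(max(min(d2), 0))
  tibble::tibble(present = dmin <= cutoff, min_no_distance = dmin)
}

#' Salt-bridge persistence across an ensemble
#'
#' Applies [salt_bridge_present()] per frame; the persistence is the
#' fraction of frames with the bridge formed. A persistence of 1 at a
#' blocked choke point reproduces the stable channel-spanning salt bridge
#' of a double mutant.
#'
#' @inheritParams salt_bridge_present
#' @param atoms An ensemble tibble.
#' @return A tibble of class `cp_salt_bridge_series` with columns `frame`,
#'   `min_no_distance`, `bridged`; [glance()] reports `persistence`.
#' @export
salt_bridge_series <- function(atoms, basic_res, acidic_res, cutoff = 4) {
  frames <- sort(unique(atoms$frame))
  rows <- lapply(frames, function(k) {
    r <- salt_bridge_present(atoms[atoms$frame == k, , drop = FALSE],
                             basic_res, acidic_res, cutoff)
    tibble::tibble(frame = k, min_no_distance = r$min_no_distance,
                   bridged = r$present)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("cp_salt_bridge_series", class(out))
  out
}

#' @export
glance.cp_salt_bridge_series <- function(x, ...) {
  tibble::tibble(cutoff = attr(x, "cutoff"), n_frames = nrow(x),
                 persistence = mean(x$bridged))
}
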