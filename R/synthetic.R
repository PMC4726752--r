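C_VDW <- 1.70  # Bondi carbon, used throughout the tube geometry

ring_atoms <- function(radius, z, n_ang, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n_ang) - 1) / n_ang
  cbind(radius * cos(th), radius * sin(th), rep(z, n_ang))
}

#' Generate a tube ensemble with a programmable constriction
#'
#' Builds a synthetic structure ensemble emulating an enzyme
#' substrate-access channel: carbon pseudo-atoms on a cylindrical lattice
#' form a tube with one capped end, a cofactor marker atom (`FAD:C4X`)
#' sits at the base, and a constriction ring mid-tube narrows the free
#' lumen to a per-frame radius. Two gate residues (an arginine at A:248
#' and a glutamate at A:382, echoing the channel-flanking pair of a
#' flavoprotein monooxygenase) sit diametrically across the constriction,
#' so the gate-pair choke diameter equals the free diameter of the
#' constriction.
#'
#' All radii in this generator are FREE (clearance) radii: ring atom
#' centers are placed at `radius + 1.70` A (the carbon van der Waals
#' radius), so a constriction of free radius r yields a detected tunnel
#' bottleneck radius of r and a gate-pair surface-to-surface diameter of
#' 2 r exactly (plus noise).
#'
#' @param n_frames Number of frames.
#' @param constriction_radius Free radius of the constriction in Angstrom:
#'   a single number, a numeric vector of length `n_frames`, or a function
#'   of the 0-based frame index.
#' @param base_radius Free radius of the unconstricted tube (default 5,
#'   roomy enough that the constriction always governs the bottleneck).
#' @param tube_length Tube length in Angstrom (default 20).
#' @param constriction_at Fractional position of the constriction along
#'   the tube (default 0.6, clear of the default start point).
#' @param atom_spacing Lattice spacing of shell atoms in Angstrom
#'   (default 1.2; must not exceed twice the carbon radius or the wall
#'   leaks).
#' @param noise_sd Gaussian noise (sd, Angstrom) added to the constriction
#'   radius per frame; applied to the ring radius, not per atom, so the
#'   analytic bottleneck stays known per frame (returned in attribute
#'   `"constriction_radius"`).
#' @param seed Mandatory integer seed; the generator is a pure function of
#'   its arguments.
#' @param blocked If `TRUE`, the gate side chains (Arg NH1, Glu OE1) are
#'   extended into the lumen with a fixed 3.0 A N-O separation in every
#'   frame, forming a channel-spanning salt bridge; otherwise they point
#'   outward into the wall.
#' @return An ensemble tibble; attributes `"constriction_radius"` (the
#'   realized per-frame free radius) and `"gate_pair"` (`c("A:248",
#'   "A:382")`).
#' @export
#' @examples
#' ens <- make_tunnel_ensemble(3, constriction_radius = 3, seed = 1)
#' diameter_series(ens, "A:248", "A:382")
make_tunnel_ensemble <- function(n_frames, constriction_radius,
                                 base_radius = 5, tube_length = 20,
                                 constriction_at = 0.6, atom_spacing = 1.2,
                                 noise_sd = 0, seed, blocked = FALSE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_frames >= 1, base_radius > 0, tube_length > 0,
            atom_spacing > 0)
  if (atom_spacing > 2 * C_VDW) {
    stop("infeasible geometry: atom_spacing > ", 2 * C_VDW,
         " A leaves gaps in the wall", call. = FALSE)
  }
  t_idx <- seq_len(n_frames) - 1
  r_nom <- if (is.function(constriction_radius)) {
    vapply(t_idx, constriction_radius, numeric(1))
  } else if (length(constriction_radius) == 1) {
    rep(constriction_radius, n_frames)
  } else {
    stopifnot(length(constriction_radius) == n_frames)
    constriction_radius
  }
  if (any(r_nom <= 0)) stop("constriction radii must be positive",
                            call. = FALSE)
  if (any(r_nom > base_radius)) {
    stop("constriction radius exceeds the base radius", call. = FALSE)
  }
  r_t <- withr::with_seed(seed, r_nom + stats::rnorm(n_frames, 0, noise_sd))
  r_t <- pmax(r_t, 0.1)

  Rw <- base_radius + C_VDW        # wall atom-center radius
  zc <- constriction_at * tube_length
  n_ang <- max(8L, ceiling(2 * pi * Rw / atom_spacing))

  # static scaffold: wall rings (constriction plane excluded), base cap
  zs <- seq(0, tube_length, by = atom_spacing)
  zs <- zs[abs(zs - zc) > atom_spacing / 2]
  wall <- do.call(rbind, lapply(zs, function(z) ring_atoms(Rw, z, n_ang)))
  cap_radii <- seq(0, Rw, by = atom_spacing)
  cap <- do.call(rbind, lapply(cap_radii, function(r) {
    if (r == 0) matrix(c(0, 0, 0), 1) else {
      ring_atoms(r, 0, max(4L, ceiling(2 * pi * r / atom_spacing)))
    }
  }))
  static_xyz <- rbind(wall, cap)
  n_static <- nrow(static_xyz)

  # per-frame washer: rings from the constriction radius out to the wall,
  # fixed count so topology is frame-invariant
  rcon_centers <- r_t + C_VDW
  n_wash <- max(2L, ceiling((Rw - min(rcon_centers)) / atom_spacing) + 1L)

  frames <- lapply(seq_len(n_frames), function(fi) {
    rc <- rcon_centers[fi]
    wash_radii <- seq(rc, Rw, length.out = n_wash)
    washer <- do.call(rbind, lapply(wash_radii, function(r) {
      ring_atoms(r, zc, n_ang, phase = pi / n_ang)
    }))
    # gate atoms: CA on the inner constriction circle at angles 0 and pi
    gate_ca <- rbind(c(rc, 0, zc), c(-rc, 0, zc))
    side_r <- if (blocked) 1.5 else rc + 1.3
    gate_side <- rbind(c(side_r, 0, zc), c(-side_r, 0, zc))
    marker <- matrix(c(0, 0, 0.5), 1)
    xyz <- rbind(static_xyz, washer, gate_ca, gate_side, marker)

    n_mobile <- n_wash * n_ang
    tibble::tibble(
      frame = fi - 1L,
      record = c(rep("HETATM", n_static + n_mobile),
                 "ATOM", "ATOM", "ATOM", "ATOM", "HETATM"),
      serial = seq_len(nrow(xyz)),
      name = c(rep("C1", n_static + n_mobile),
               "CA", "CA", "NH1", "OE1", "C4X"),
      alt = NA_character_,
      res_name = c(rep("TUB", n_static + n_mobile),
                   "ARG", "GLU", "ARG", "GLU", "FAD"),
      chain = c(rep("W", n_static + n_mobile),
                "A", "A", "A", "A", "X"),
      res_seq = c(seq_len(n_static + n_mobile),
                  248L, 382L, 248L, 382L, 1L),
      insertion = NA_character_,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, b_factor = 0,
      element = c(rep("C", n_static + n_mobile),
                  "C", "C", "N", "O", "C"))
  })
  out <- as_ensemble(dplyr::bind_rows(frames))
  attr(out, "constriction_radius") <- r_t
  attr(out, "gate_pair") <- c("A:248", "A:382")
  attr(out, "marker") <- "X:1:C4X"
  out
}

#' Blocked (salt-bridged) variant of the tube ensemble
#'
#' Same geometry as [make_tunnel_ensemble()] but the gate residues' side
#' chains (Arg NH1, Glu OE1) span the lumen with a fixed 3.0 A N-O
#' separation in every frame, emulating the stable channel-spanning salt
#' bridge of a double mutant: salt-bridge persistence is 1 and the channel
#' is persistently closed at the default 4 A threshold.
#'
#' @inheritParams make_tunnel_ensemble
#' @return An ensemble tibble (see [make_tunnel_ensemble()]).
#' @export
make_blocked_variant <- function(n_frames, constriction_radius = 3,
                                 base_radius = 5, tube_length = 20,
                                 constriction_at = 0.6, atom_spacing = 1.2,
                                 noise_sd = 0, seed) {
  make_tunnel_ensemble(n_frames, constriction_radius, base_radius,
                       tube_length, constriction_at, atom_spacing,
                       noise_sd, seed, blocked = TRUE)
}

#' Default tunnel-search start point for a synthetic tube
#'
#' A point on the tube axis in front of the cofactor marker, with enough
#' clearance for the default probe.
#'
#' @param ensemble An ensemble from [make_tunnel_ensemble()].
#' @param offset Distance above the marker along the tube axis (default
#'   6 A, clear of the marker and cap so the constriction governs the
#'   bottleneck).
#' @return Numeric length-3 point.
#' @export
tunnel_start <- function(ensemble, offset = 6) {
  fr <- get_frame(ensemble, min(ensemble$frame))
  m <- resolve_spec(fr, attr(ensemble, "marker") %||% "X:1:C4X")
  c(m$x, m$y, m$z + offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a reference active site realizing an exact distance matrix
#'
#' Embeds a target pairwise distance matrix in 3-space by classical
#' multidimensional scaling (exact for any realizable matrix; residual
#' checked against 1e-6 A) and decorates the frame with decoy atoms at
#' least 8 A away, standing in for a reference holo active site with known
#' geometry. [build_descriptor()] on the output reproduces the matrix.
#'
#' @param dist_matrix Symmetric k x k matrix of target distances
#'   (Angstrom), zero diagonal.
#' @param n_decoys Number of decoy atoms (default 10).
#' @param seed Integer seed for decoy placement.
#' @return A single-frame ensemble tibble: site atoms as chain `S`
#'   residues 1..k (atom `CA`), decoys as chain `D`.
#' @export
#' @examples
#' site <- make_reference_site(4.32 * (1 - diag(4)), seed = 1)
#' build_descriptor(site, sprintf("S:%d:CA", 1:4))
make_reference_site <- function(dist_matrix, n_decoys = 10, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  D <- as.matrix(dist_matrix)
  k <- nrow(D)
  stopifnot(k >= 2, ncol(D) == k)
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0) ||
      any(D[upper.tri(D)] <= 0)) {
    stop("distance matrix must be symmetric with zero diagonal and ",
         "positive off-diagonal entries", call. = FALSE)
  }
  X <- suppressWarnings(stats::cmdscale(stats::as.dist(D),
                                        k = min(3, k - 1)))
  if (ncol(X) < 3) X <- cbind(X, matrix(0, k, 3 - ncol(X)))
  resid <- max(abs(as.matrix(stats::dist(X)) - D))
  if (resid > 1e-6) {
    stop(sprintf(paste0("distance matrix is not embeddable in 3-space ",
                        "(embedding residual %.3g A)"), resid),
         call. = FALSE)
  }
  decoys <- withr::with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n_decoys), n_decoys, 3)
    u <- u / sqrt(rowSums(u^2))
    span <- max(abs(X)) + 8 + stats::runif(n_decoys, 2, 10)
    u * span
  })
  if (n_decoys > 0) {
    min_sep <- min(as.matrix(stats::dist(rbind(X, decoys)))[
      seq_len(k), k + seq_len(n_decoys), drop = FALSE])
    stopifnot(min_sep >= 8)
  }
  atoms <- tibble::tibble(
    frame = 0L,
    record = "ATOM",
    serial = seq_len(k + n_decoys),
    name = "CA",
    alt = NA_character_,
    res_name = c(rep("SIT", k), rep("DEC", n_decoys)),
    chain = c(rep("S", k), rep("D", n_decoys)),
    res_seq = c(seq_len(k), seq_len(n_decoys)),
    insertion = NA_character_,
    x = c(X[, 1], decoys[, 1]),
    y = c(X[, 2], decoys[, 2]),
    z = c(X[, 3], decoys[, 3]),
    occupancy = 1, b_factor = 0, element = "C")
  as_ensemble(atoms)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# probability of the consensus residue giving normalized-entropy
# conservation `target` when the remaining mass is spread over 19 residues
consensus_prob_for <- function(target) {
  score_of <- function(p) {
    q <- (1 - p) / 19
    H <- -(p * log(p) + if (q > 0) 19 * q * log(q) else 0)
    1 - H / log(20)
  }
  if (target >= 1) return(1)
  if (target <= 0) return(1 / 20)
  stats::uniroot(function(p) score_of(p) - target,
                 lower = 1 / 20 + 1e-9, upper = 1 - 1e-12,
                 tol = 1e-12)$root
}

#' Generate an alignment with controlled per-column conservation
#'
#' Each column is drawn i.i.d. from a categorical distribution over the 20
#' amino acids whose normalized-entropy conservation equals the requested
#' per-column target exactly in expectation (one consensus residue carries
#' probability p, the rest share the remainder uniformly; p is solved per
#' column). No gaps are generated.
#'
#' @param n_seqs Number of sequences.
#' @param profile Numeric vector in `[0, 1]`: target conservation per
#'   column.
#' @param seed Mandatory integer seed.
#' @return An alignment tibble (class `cp_msa`, columns `id`, `seq`) of
#'   width `length(profile)`.
#' @export
make_msa <- function(n_seqs, profile, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_seqs >= 1, all(profile >= 0 & profile <= 1))
  L <- length(profile)
  cols <- withr::with_seed(seed, {
    lapply(seq_len(L), function(cidx) {
      p <- consensus_prob_for(profile[cidx])
      consensus <- sample(AA20, 1)
      others <- setdiff(AA20, consensus)
      probs <- c(p, rep((1 - p) / 19, 19))
      sample(c(consensus, others), n_seqs, replace = TRUE, prob = probs)
    })
  })
  mat <- do.call(cbind, cols)
  seqs <- apply(mat, 1, paste, collapse = "")
  new_msa(tibble::tibble(id = sprintf("synthetic_%03d", seq_len(n_seqs)),
                         seq = seqs))
}
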