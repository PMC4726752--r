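#' Detect substrate-access tunnels by a grid widest-path search
#'
#' Builds a regular grid over the structure's bounding box, assigns every
#' node its clearance (distance to the nearest heavy-atom van der Waals
#' surface), removes nodes a probe sphere cannot occupy, and finds for each
#' bulk-solvent exit the path from the start point that maximizes the
#' minimum clearance along the way (widest path, computed via a maximum
#' spanning tree on the 6-connected grid graph). A box-boundary node
#' counts as a bulk-solvent exit when the sphere of radius `shell_radius`
#' centred `shell_depth` outward of it (along the direction away from the
#' protein centroid) contains no protein atoms — the shell criterion, with
#' the conventional 6 A / 6 A defaults. Exits closer than `shell_radius`
#' to each other are merged and the widest representative kept; tunnels
#' are returned sorted by bottleneck radius, widest first.
#'
#' @param frame A single-frame ensemble tibble.
#' @param start Numeric length-3 start point in Angstrom (typically just in
#'   front of the flavin isoalloxazine); must lie in free space with
#'   clearance of at least `probe_radius`.
#' @param probe_radius Probe sphere radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param shell_radius,shell_depth Bulk-solvent shell parameters in
#'   Angstrom (defaults 6 and 6).
#' @param grid_spacing Grid resolution in Angstrom (default 0.5); the
#'   bottleneck radius is accurate to about one spacing.
#' @return A tibble of class `cp_tunnels`, one row per tunnel, with
#'   `tunnel`, `bottleneck_radius`, `bottleneck_x/y/z`, `exit_x/y/z`,
#'   `n_points` and a `profile` list-column (tibbles with `step`, `x`,
#'   `y`, `z`, `radius` along the centerline from start to exit). Zero
#'   rows when no exit is reachable (fully enclosed start).
#' @export
detect_tunnels <- function(frame, start, probe_radius = 1.4,
                           shell_radius = 6, shell_depth = 6,
                           grid_spacing = 0.5) {
  heavy <- frame[toupper(frame$element) != "H", , drop = FALSE]
  if (nrow(heavy) == 0) stop("frame has no heavy atoms", call. = FALSE)
  A <- coords_matrix(heavy)
  rA <- vdw_radius(heavy$element)
  stopifnot(length(start) == 3, all(is.finite(start)))

  start_clear <- min(sqrt(colSums((t(A) - start)^2)) - rA)
  margin <- probe_radius + 2 * grid_spacing
  lo <- pmin(apply(A, 2, min), start) - margin
  hi <- pmax(apply(A, 2, max), start) + margin
  # align the grid so the start point is a grid node: narrow apertures on
  # the start's axis are then sampled at their true clearance
  lo <- start - grid_spacing * ceiling((start - lo) / grid_spacing)
  ax <- seq(lo[1], hi[1], by = grid_spacing)
  ay <- seq(lo[2], hi[2], by = grid_spacing)
  az <- seq(lo[3], hi[3], by = grid_spacing)
  nx <- length(ax); ny <- length(ay); nz <- length(az)
  N <- nx * ny * nz

  gx <- rep(ax, times = ny * nz)
  gy <- rep(rep(ay, each = nx), times = nz)
  gz <- rep(az, each = nx * ny)

  clear <- rep(Inf, N)
  for (i in seq_len(nrow(A))) {
    d <- sqrt((gx - A[i, 1])^2 + (gy - A[i, 2])^2 + (gz - A[i, 3])^2) - rA[i]
    clear <- pmin(clear, d)
  }

  if (start_clear < probe_radius) {
    ok <- which(clear >= probe_radius)
    if (length(ok) == 0) {
      stop("start point is buried and no grid node has clearance >= ",
           probe_radius, call. = FALSE)
    }
    d2 <- (gx[ok] - start[1])^2 + (gy[ok] - start[2])^2 +
      (gz[ok] - start[3])^2
    b <- ok[which.min(d2)]
    stop(sprintf(paste0("start point has clearance %.2f A < probe radius ",
                        "%.2f A; nearest valid point is (%.2f, %.2f, %.2f)"),
                 start_clear, probe_radius, gx[b], gy[b], gz[b]),
         call. = FALSE)
  }

  keep <- clear >= probe_radius
  if (!any(keep)) return(empty_tunnels())
  new_id <- integer(N)
  kept <- which(keep)
  new_id[kept] <- seq_along(kept)

  ix <- ((kept - 1L) %% nx) + 1L
  iy <- (((kept - 1L) %/% nx) %% ny) + 1L
  iz <- ((kept - 1L) %/% (nx * ny)) + 1L

  edge_pairs <- function(offset, open_dim) {
    a <- kept[open_dim]
    b <- a + offset
    sel <- keep[b]
    cbind(new_id[a[sel]], new_id[b[sel]])
  }
  E <- rbind(edge_pairs(1L, ix < nx),
             edge_pairs(nx, iy < ny),
             edge_pairs(nx * ny, iz < nz))
  kclear <- clear[kept]
  if (nrow(E) == 0) return(empty_tunnels())
  w <- pmin(kclear[E[, 1]], kclear[E[, 2]])
  g <- igraph::graph_from_edgelist(E, directed = FALSE)
  if (igraph::vcount(g) < length(kept)) {
    g <- igraph::add_vertices(g, length(kept) - igraph::vcount(g))
  }

  d2s <- (gx[kept] - start[1])^2 + (gy[kept] - start[2])^2 +
    (gz[kept] - start[3])^2
  start_v <- which.min(d2s)

  comp <- igraph::components(g)$membership
  boundary <- which(ix == 1L | ix == nx | iy == 1L | iy == ny |
                      iz == 1L | iz == nz)
  boundary <- boundary[comp[boundary] == comp[start_v]]
  if (length(boundary) == 0) return(empty_tunnels())

  centroid <- colMeans(A)
  B <- cbind(gx[kept[boundary]], gy[kept[boundary]], gz[kept[boundary]])
  U <- sweep(B, 2, centroid)
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  P <- B + shell_depth * U / nrm
  mind <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(A))) {
    d2 <- (P[, 1] - A[i, 1])^2 + (P[, 2] - A[i, 2])^2 +
      (P[, 3] - A[i, 3])^2
    mind <- pmin(mind, d2)
  }
  exits <- boundary[sqrt(mind) > shell_radius]
  if (length(exits) == 0) return(empty_tunnels())

  # widest paths from start: maximum spanning tree, then the unique tree
  # path; bottleneck[v] accumulated in BFS order from the start
  mst <- igraph::mst(g, weights = -w)
  bf <- igraph::bfs(mst, root = start_v, unreachable = FALSE,
                    father = TRUE, order = TRUE)
  father <- as.integer(bf$father)
  order_v <- as.integer(bf$order)
  order_v <- order_v[!is.na(order_v)]
  bottleneck <- rep(NA_real_, length(kept))
  bottleneck[start_v] <- kclear[start_v]
  for (v in order_v) {
    f <- father[v]
    if (!is.na(f)) bottleneck[v] <- min(bottleneck[f], kclear[v])
  }

  # merge exits whose mouths lie within shell_radius: cell binning at the
  # shell length scale, components over adjacent occupied cells
  Epos <- cbind(gx[kept[exits]], gy[kept[exits]], gz[kept[exits]])
  cellkey <- floor(sweep(Epos, 2, lo) / shell_radius)
  cells <- unique(cellkey)
  ckey <- function(m) paste(m[, 1], m[, 2], m[, 3])
  cell_of <- match(ckey(cellkey), ckey(cells))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cedges <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- match(ckey(sweep(cells, 2, -off[r, ])), ckey(cells))
    okc <- which(!is.na(nb) & nb > seq_len(nrow(cells)))
    if (length(okc)) cedges <- rbind(cedges, cbind(okc, nb[okc]))
  }
  if (is.null(cedges) || nrow(cedges) == 0) {
    cluster_of_cell <- seq_len(nrow(cells))
  } else {
    cg <- igraph::graph_from_edgelist(cedges, directed = FALSE)
    if (igraph::vcount(cg) < nrow(cells)) {
      cg <- igraph::add_vertices(cg, nrow(cells) - igraph::vcount(cg))
    }
    cluster_of_cell <- igraph::components(cg)$membership
  }
  cluster <- cluster_of_cell[cell_of]

  rows <- lapply(sort(unique(cluster)), function(cl) {
    members <- exits[cluster == cl]
    bn <- bottleneck[members]
    rep_v <- members[which.max(bn)]
    path <- rep_v
    while (!is.na(father[path[1]])) path <- c(father[path[1]], path)
    prof <- tibble::tibble(
      step = seq_along(path),
      x = gx[kept[path]], y = gy[kept[path]], z = gz[kept[path]],
      radius = kclear[path])
    imin <- which.min(prof$radius)
    tibble::tibble(
      bottleneck_radius = prof$radius[imin],
      bottleneck_x = prof$x[imin], bottleneck_y = prof$y[imin],
      bottleneck_z = prof$z[imin],
      exit_x = prof$x[nrow(prof)], exit_y = prof$y[nrow(prof)],
      exit_z = prof$z[nrow(prof)],
      n_points = nrow(prof),
      profile = list(prof))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$bottleneck_radius), , drop = FALSE]
  out <- tibble::tibble(tunnel = seq_len(nrow(out)), out)
  attr(out, "params") <- list(probe_radius = probe_radius,
                              shell_radius = shell_radius,
                              shell_depth = shell_depth,
                              grid_spacing = grid_spacing)
  class(out) <- c("cp_tunnels", class(out))
  out
}

empty_tunnels <- function() {
  out <- tibble::tibble(tunnel = integer(), bottleneck_radius = numeric(),
                        bottleneck_x = numeric(), bottleneck_y = numeric(),
                        bottleneck_z = numeric(), exit_x = numeric(),
                        exit_y = numeric(), exit_z = numeric(),
                        n_points = integer(), profile = list())
  class(out) <- c("cp_tunnels", class(out))
  out
}

#' Export tunnel centerlines as a PDB pseudo-atom trace
#'
#' Writes each tunnel centerline as a chain of pseudo-atoms (one residue
#' per tunnel, B-factor = local free radius) so detected tunnels can be
#' inspected in any molecular viewer.
#'
#' @param tunnels A `cp_tunnels` tibble.
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_tunnels_pdb <- function(tunnels, path) {
  if (nrow(tunnels) == 0) stop("no tunnels to write", call. = FALSE)
  rows <- lapply(seq_len(nrow(tunnels)), function(i) {
    p <- tunnels$profile[[i]]
    tibble::tibble(frame = 0L, record = "HETATM",
                   serial = NA_integer_, name = "C",
                   alt = NA_character_, res_name = "TUN",
                   chain = "T", res_seq = i * 100000L + p$step,
                   insertion = NA_character_,
                   x = p$x, y = p$y, z = p$z,
                   occupancy = 1, b_factor = p$radius, element = "C")
  })
  atoms <- dplyr::bind_rows(rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$res_seq <- match(atoms$res_seq, unique(atoms$res_seq))
  write_structure(as_ensemble(atoms), path)
}
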