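# fixtures are built in code; nothing is read from disk

AA_1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# a minimal synthetic polypeptide: N/CA/C/O per residue along x
toy_protein_frame <- function(seq_1letter, chain = "A", frame = 0L,
                              jitter = 0, seed = 1) {
  aa <- strsplit(seq_1letter, "")[[1]]
  n <- length(aa)
  offs <- matrix(c(0, 0, 0,   1.5, 0.4, 0,   2.4, -0.6, 0.3,
                   2.9, -1.6, 0.1), 4, 3, byrow = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    base <- c(3.8 * (i - 1), 0.5 * ((i %% 3) - 1), 0.3 * (i %% 2))
    xyz <- sweep(offs, 2, base, "+")
    tibble::tibble(frame = frame, record = "ATOM",
                   serial = NA_integer_,
                   name = c("N", "CA", "C", "O"), alt = NA_character_,
                   res_name = AA_1TO3[[aa[i]]], chain = chain,
                   res_seq = i, insertion = NA_character_,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, b_factor = 0,
                   element = c("N", "C", "C", "O"))
  })
  atoms <- dplyr::bind_rows(rows)
  if (jitter > 0) {
    atoms[, c("x", "y", "z")] <- withr::with_seed(seed,
      atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(atoms), 0, jitter), ncol = 3))
  }
  as_ensemble(atoms)
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
    matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d),
             2 * (b * d + a * cc),
             2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2,
             2 * (cc * d - a * b),
             2 * (b * d - a * cc), 2 * (cc * d + a * b),
             a^2 - b^2 - cc^2 + d^2), 3, 3, byrow = TRUE)
  })
}

rigid_move <- function(frame, seed = 1, shift = c(5, -3, 2)) {
  R <- random_rotation(seed)
  xyz <- cbind(frame$x, frame$y, frame$z) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
  frame
}

# independent brute-force descriptor score from raw coordinates
brute_force_score <- function(frame, site_specs, ref_dists, signed = FALSE) {
  pos <- t(vapply(site_specs, function(s) {
    hit <- chokepoint:::resolve_spec(frame, s)
    c(hit$x, hit$y, hit$z)
  }, numeric(3)))
  k <- nrow(pos)
  total <- 0
  p <- 1
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      dev <- d - ref_dists[p]
      total <- total + if (signed) dev else abs(dev)
      p <- p + 1
    }
  }
  total
}

# exhaustive affine-gap global alignment score by full enumeration of all
# monotone alignments (no dynamic-programming table, no memoisation)
enumerate_align_score <- function(a, b, submat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  gap_cost <- function(len, opening) {
    if (len == 0) return(0)
    gap_extend * len + if (opening) gap_open else 0
  }
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    if (i > n) return(-gap_cost(m - j + 1, prev != "GA"))
    if (j > m) return(-gap_cost(n - i + 1, prev != "GB"))
    best <- -Inf
    best <- max(best, submat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    best <- max(best,
                rec(i + 1, j, "GB") - gap_cost(1, prev != "GB"))
    best <- max(best,
                rec(i, j + 1, "GA") - gap_cost(1, prev != "GA"))
    best
  }
  rec(1, 1, "M")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
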