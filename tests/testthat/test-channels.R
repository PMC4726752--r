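two_carbons <- function(sep) {
  as_ensemble(tibble::tibble(
    name = "C1", element = "C", res_name = "XXX", chain = "A",
    res_seq = 1:2, x = c(0, sep), y = 0, z = 0))
}

test_that("bottleneck diameter is surface-to-surface between closest heavy atoms", {
  fr <- two_carbons(10)
  expect_equal(bottleneck_diameter(fr, "A:1", "A:2"), 10 - 2 * 1.70)
  moved <- rigid_move(fr, seed = 3)
  expect_equal(bottleneck_diameter(moved, "A:1", "A:2"), 6.60,
               tolerance = 1e-9)
  expect_error(bottleneck_diameter(fr, "A:1", "B:9"), "B:9")
})

test_that("multi-atom bottleneck equals the exhaustive heavy-pair minimum", {
  withr::with_seed(77, {
    for (trial in 1:50) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      elements <- c("C", "N", "O", "S")
      a <- tibble::tibble(
        name = paste0("X", seq_len(n1)), element = sample(elements, n1, TRUE),
        res_name = "AAA", chain = "A", res_seq = 1L,
        x = stats::rnorm(n1, 0, 2), y = stats::rnorm(n1, 0, 2),
        z = stats::rnorm(n1, 0, 2))
      b <- tibble::tibble(
        name = paste0("Y", seq_len(n2)), element = sample(elements, n2, TRUE),
        res_name = "BBB", chain = "A", res_seq = 2L,
        x = stats::rnorm(n2, 12, 2), y = stats::rnorm(n2, 0, 2),
        z = stats::rnorm(n2, 0, 2))
      fr <- as_ensemble(dplyr::bind_rows(a, b))
      got <- bottleneck_diameter(fr, "A:1", "A:2")
      want <- Inf
      for (i in seq_len(n1)) {
        for (j in seq_len(n2)) {
          d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                      (a$z[i] - b$z[j])^2) -
            vdw_radius(a$element[i]) - vdw_radius(b$element[j])
          want <- min(want, d)
        }
      }
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("diameter series tracks a linearly closing gate monotonically", {
  radii <- seq(4, 1, length.out = 10)
  ens <- make_tunnel_ensemble(10, constriction_radius = radii, seed = 2)
  ser <- diameter_series(ens, "A:248", "A:382")
  expect_equal(nrow(ser), 10)
  expect_true(all(diff(ser$diameter) < 0))
  expect_equal(ser$diameter, 2 * radii, tolerance = 1e-9)
  # constant ensemble -> constant series
  const <- make_tunnel_ensemble(3, constriction_radius = 2.5, seed = 4)
  expect_equal(diff(range(diameter_series(const, "A:248",
                                          "A:382")$diameter)), 0)
  expect_error(diameter_series(const[0, ], "A:248", "A:382"), "empty")
})

test_that("channel classification counts open frames against the threshold", {
  ser <- tibble::tibble(frame = 0:3, diameter = c(5, 3, 5, 3))
  st <- classify_channel(ser, threshold = 4)
  g <- glance(st)
  expect_equal(g$open_fraction, 0.5)
  expect_false(g$blocked_persistently)
  expect_true(glance(classify_channel(ser, threshold = Inf))
              $blocked_persistently)
  expect_equal(glance(classify_channel(ser, threshold = -Inf))$open_fraction,
               1.0)
  all_open <- classify_channel(tibble::tibble(frame = 0:1,
                                              diameter = c(9, 8)), 4)
  expect_equal(glance(all_open)$open_fraction, 1)
  all_shut <- classify_channel(tibble::tibble(frame = 0:1,
                                              diameter = c(1, 2)), 4)
  expect_true(glance(all_shut)$blocked_persistently)
})

test_that("salt bridges are called from side-chain N-O distances only", {
  fr <- as_ensemble(tibble::tibble(
    name = c("CA", "NH1", "CA", "OE1"),
    element = c("C", "N", "C", "O"),
    res_name = c("ARG", "ARG", "GLU", "GLU"),
    chain = "A", res_seq = c(1L, 1L, 2L, 2L),
    x = c(-2, 0, 5.5, 3.5), y = 0, z = 0))
  r <- salt_bridge_present(fr, "A:1", "A:2")
  expect_true(r$present)
  expect_equal(r$min_no_distance, 3.5, tolerance = 1e-12)
  far <- fr
  far$x[4] <- 5.0
  r2 <- salt_bridge_present(far, "A:1", "A:2", cutoff = 4)
  expect_false(r2$present)
  expect_equal(r2$min_no_distance, 5.0)
  # a glycine cannot be the basic partner
  gly <- fr
  gly$res_name[1:2] <- "GLY"
  expect_error(salt_bridge_present(gly, "A:1", "A:2"), "not a basic")
  # arginine lacking its guanidinium nitrogens is a truncation error
  trunc <- fr[-2, ]
  expect_error(salt_bridge_present(trunc, "A:1", "A:2"), "truncated")
})

test_that("salt-bridge persistence separates blocked from open ensembles", {
  blocked <- make_blocked_variant(5, seed = 11)
  wt <- make_tunnel_ensemble(5, constriction_radius = 3, seed = 11)
  expect_equal(glance(salt_bridge_series(blocked, "A:248", "A:382"))
               $persistence, 1.0)
  expect_equal(glance(salt_bridge_series(wt, "A:248", "A:382"))
               $persistence, 0.0)
  one <- salt_bridge_series(get_frame(blocked, 0), "A:248", "A:382")
  expect_true(glance(one)$persistence %in% c(0, 1))
})

test_that("tunnel detection recovers a tube and its constriction", {
  # plain tube, atoms placed directly at center radius 4.0
  r_center <- 4.0
  n_ang <- 24
  zs <- seq(0, 14, by = 1.2)
  rows <- lapply(zs, function(z) {
    th <- 2 * pi * seq_len(n_ang) / n_ang
    tibble::tibble(x = r_center * cos(th), y = r_center * sin(th), z = z)
  })
  cap <- tibble::tibble(x = c(0, 1.2, -1.2, 0, 0, 2.4, -2.4, 0, 0),
                        y = c(0, 0, 0, 1.2, -1.2, 0, 0, 2.4, -2.4), z = 0)
  xyz <- dplyr::bind_rows(c(rows, list(cap)))
  fr <- as_ensemble(tibble::tibble(
    name = "C1", element = "C", res_name = "TUB", chain = "W",
    res_seq = seq_len(nrow(xyz)), x = xyz$x, y = xyz$y, z = xyz$z))
  tun <- detect_tunnels(fr, start = c(0, 0, 7), probe_radius = 1.4,
                        grid_spacing = 0.5)
  expect_equal(nrow(tun), 1)
  expect_equal(tun$bottleneck_radius, r_center - 1.70, tolerance = 0.5)

  # constriction mid-tube governs the bottleneck and its position
  ens <- make_tunnel_ensemble(1, constriction_radius = 2.0, seed = 1)
  tun2 <- detect_tunnels(get_frame(ens, 0), tunnel_start(ens),
                         grid_spacing = 0.5)
  expect_equal(nrow(tun2), 1)
  expect_equal(tun2$bottleneck_radius, 2.0, tolerance = 0.5)
  expect_equal(tun2$bottleneck_z, 12, tolerance = 1.0)

  # profile invariants
  prof <- tun2$profile[[1]]
  expect_true(all(prof$radius >= 1.4))
  expect_equal(min(prof$radius), tun2$bottleneck_radius)
})

test_that("tunnel search errors and empty results are explicit", {
  ens <- make_tunnel_ensemble(1, constriction_radius = 3, seed = 1)
  fr <- get_frame(ens, 0)
  # start inside an atom: error suggests a valid point
  expect_error(detect_tunnels(fr, c(0, 0, 0.5), grid_spacing = 0.5),
               "nearest valid point")
  # aperture below the probe: no tunnel
  shut <- make_tunnel_ensemble(1, constriction_radius = 1.0, seed = 1)
  expect_equal(nrow(detect_tunnels(get_frame(shut, 0), tunnel_start(shut),
                                   grid_spacing = 0.5)), 0)
})

test_that("detected bottleneck converges to the analytic clearance with the grid", {
  ens <- make_tunnel_ensemble(1, constriction_radius = 2.5,
                              base_radius = 3.5, tube_length = 12,
                              constriction_at = 0.6, seed = 1)
  fr <- get_frame(ens, 0)
  st <- tunnel_start(ens, offset = 4.5)
  errs <- vapply(c(1.0, 0.5, 0.25), function(h) {
    tun <- detect_tunnels(fr, st, grid_spacing = h)
    abs(tun$bottleneck_radius[1] - 2.5)
  }, numeric(1))
  expect_true(all(errs <= c(1.0, 0.5, 0.25) + 1e-9))
})

test_that("shrinking the constriction never widens the detected bottleneck", {
  radii <- c(3.5, 2.5, 1.5)
  got <- vapply(radii, function(r) {
    ens <- make_tunnel_ensemble(1, constriction_radius = r, seed = 1)
    detect_tunnels(get_frame(ens, 0), tunnel_start(ens),
                   grid_spacing = 0.5)$bottleneck_radius[1]
  }, numeric(1))
  expect_true(all(diff(got) < 0))
})

test_that("tunnel geometry is invariant under rigid motion within grid error", {
  ens <- make_tunnel_ensemble(1, constriction_radius = 2.5, seed = 1)
  fr <- get_frame(ens, 0)
  st <- tunnel_start(ens)
  b1 <- detect_tunnels(fr, st, grid_spacing = 0.5)$bottleneck_radius[1]
  moved <- rigid_move(fr, seed = 13)
  R <- random_rotation(13)
  st2 <- as.vector(R %*% st) + c(5, -3, 2)
  b2 <- detect_tunnels(moved, st2, grid_spacing = 0.5)$bottleneck_radius[1]
  expect_lt(abs(b1 - b2), 0.5)
})
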