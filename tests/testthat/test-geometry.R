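rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
    2 * (q[2] * q[4] - q[1] * q[3]),
    2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] + q[1] * q[2]),
    2 * (q[2] * q[4] + q[1] * q[3]), 2 * (q[3] * q[4] - q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3)
}

test_that("helix detection accepts ideal helices and rejects strands", {
  h <- ideal_helix(12)
  segs <- detect_helices(h)
  expect_equal(nrow(segs), 1L)
  expect_equal(c(segs$start, segs$end), c(1L, 12L))

  # extended strand: 3.4 A rise fails the distance windows
  strand <- tibble::tibble(resno = 1:10, resname = "ALA", chain = "A",
                           plddt = NA_real_,
                           ca_x = 0, ca_y = (1:10 %% 2) * 1.0,
                           ca_z = (1:10) * 3.4)
  expect_equal(nrow(detect_helices(strand)), 0L)

  # two helices joined by a coil: two segments at the constructed angle
  cs <- composite_structure(list(
    list(n_res = 10),
    list(n_res = 10, rotation = rot_x(90), translation = c(12, 0, 12))),
    coil = 4)
  segs2 <- detect_helices(cs)
  expect_equal(nrow(segs2), 2L)
  expect_equal(interhelix_angle(segs2[1, ], segs2[2, ]), 90, tolerance = 1)

  # three-helix layout (the mKRAB-like topology) detects three segments
  cs3 <- composite_structure(list(
    list(n_res = 8),
    list(n_res = 14, rotation = rot_x(90), translation = c(10, 0, 12)),
    list(n_res = 8, rotation = rot_x(175), translation = c(20, 18, 6))),
    coil = 4)
  expect_equal(nrow(detect_helices(cs3)), 3L)

  expect_error(composite_structure(list(list(n_res = 10), list(n_res = 0))),
               class = "krabstrat_geom_error")
  expect_error(composite_structure(list(list(n_res = 10),
                                        list(n_res = 10))),
               class = "krabstrat_geom_error")  # overlapping placement
})

test_that("helix axis recovers generator parameters and transforms equivariantly", {
  for (n in c(6, 10, 20, 30)) {
    ax <- helix_axis(as.matrix(ideal_helix(n)[, c("ca_x", "ca_y", "ca_z")]))
    expect_lt(acos(abs(sum(ax$axis_dir * c(0, 0, 1)))) * 180 / pi, 1)
    expect_equal(ax$twist, 100, tolerance = 0.5)
    expect_equal(ax$rise, 1.5, tolerance = 0.02)
    expect_equal(ax$radius, 2.3, tolerance = 0.05)
  }

  # equivariance under a known rigid transform
  set.seed(7)
  ca <- as.matrix(ideal_helix(14)[, c("ca_x", "ca_y", "ca_z")])
  ax0 <- helix_axis(ca)
  for (k in 1:5) {
    R <- random_rotation()
    moved <- ca %*% t(R) + matrix(c(3, -2, 8), nrow(ca), 3, byrow = TRUE)
    ax1 <- helix_axis(moved)
    expect_equal(as.numeric(ax1$axis_dir), as.numeric(R %*% ax0$axis_dir),
                 tolerance = 1e-6)
    expect_equal(ax1$twist, ax0$twist, tolerance = 1e-6)
  }

  # robust to moderate coordinate noise
  set.seed(99)
  ok <- vapply(1:10, function(k) {
    noisy <- ca + matrix(stats::rnorm(length(ca), sd = 0.2), nrow(ca), 3)
    ax <- helix_axis(noisy)
    acos(abs(sum(ax$axis_dir * c(0, 0, 1)))) * 180 / pi < 3
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  expect_error(helix_axis(cbind(0, 0, 1:10)), class = "krabstrat_geom_error")
  expect_error(helix_axis(ca[1:3, ]), class = "krabstrat_geom_error")
})

test_that("Kabsch superposition is exact, chirality-safe and matches bio3d", {
  ca <- as.matrix(ideal_helix(15)[, c("ca_x", "ca_y", "ca_z")])
  self <- kabsch_superpose(ca, ca)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)

  set.seed(3)
  R <- random_rotation(); tr <- c(5, -1, 2)
  moved <- ca %*% t(R) + matrix(tr, nrow(ca), 3, byrow = TRUE)
  fit <- kabsch_superpose(ca, moved)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # mirrored input still yields a proper rotation
  mirrored <- ca %*% diag(c(-1, 1, 1))
  fitm <- kabsch_superpose(ca, mirrored)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0)

  expect_error(kabsch_superpose(ca[1:2, ], ca[1:2, ]),
               class = "krabstrat_geom_error")
  expect_error(kabsch_superpose(ca, ca[1:5, ]), class = "krabstrat_geom_error")

  # independent cross-check against the bio3d least-squares fit
  skip_if_not_installed("bio3d")
  noisy <- moved + matrix(stats::rnorm(length(ca), sd = 0.3), nrow(ca), 3)
  fit2 <- kabsch_superpose(ca, noisy)
  ref <- suppressWarnings(
    bio3d::fit.xyz(as.numeric(t(ca)), as.numeric(t(noisy))))
  rmsd_ref <- sqrt(mean(colSums((matrix(ref, nrow = 3) - t(ca))^2)))
  expect_equal(fit2$rmsd, rmsd_ref, tolerance = 1e-6)
})

test_that("a one-residue insertion rotates the register by the helix twist", {
  a <- ideal_helix(20)
  b <- ideal_helix(21)

  # identical structures: no rotation
  expect_equal(azimuthal_rotation(a, a, 3:9, 15), 0, tolerance = 1e-6)

  # insertion upstream of the probe: the probe advances one position, so
  # its side chain turns by the per-residue twist (100 degrees here)
  ang <- azimuthal_rotation(a, b, anchor_range = 3:9, probe_a = 15,
                            probe_b = 16)
  expect_equal(abs(ang), 100, tolerance = 2)

  # antisymmetry: swapping the structures negates the angle
  ang_rev <- azimuthal_rotation(b, a, anchor_range = 3:9, probe_a = 16,
                                probe_b = 15)
  expect_equal(ang_rev, -ang, tolerance = 1e-6)

  # rigid global transforms leave the measurement invariant
  set.seed(5)
  R <- random_rotation()
  b_moved <- krabstrat:::transform_coords(b, R, c(4, 4, -2))
  expect_equal(azimuthal_rotation(a, b_moved, 3:9, 15, 16), ang,
               tolerance = 1e-6)
})

test_that("PDB round trip preserves coordinates, pLDDT, and pseudo-CB works", {
  skip_if_not_installed("bio3d")
  h <- ideal_helix(10)
  h$plddt <- seq(50, 95, length.out = 10)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  r <- read_structure(f)
  expect_equal(nrow(r), 10L)
  expect_equal(as.matrix(r[, c("ca_x", "ca_y", "ca_z")]),
               as.matrix(h[, c("ca_x", "ca_y", "ca_z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(r$plddt, h$plddt, tolerance = 0.01)

  # glycine without CB is fine; the probe falls back to a pseudo-CB built
  # from the backbone
  g <- ideal_helix(10, with_cb = FALSE)
  g$resname <- "GLY"
  write_pdb(g, f)
  rg <- read_structure(f)
  expect_true(all(is.na(rg$cb_x)))
  cb <- krabstrat:::cb_vector(rg, 5)
  expect_equal(sqrt(sum(cb$vec^2)), 1.53, tolerance = 1e-6)

  # malformed ATOM lines report their line number
  lines <- readLines(f)
  lines[3] <- substr(lines[3], 1, 40)
  writeLines(lines, f)
  expect_error(read_structure(f), regexp = "line 3",
               class = "krabstrat_parse_error")
})
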