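#' Read residue coordinates from a PDB file
#'
#' Parses ATOM records (via bio3d) into one row per residue with CA
#' (required), CB, N and C positions and the B-factor column as `plddt`
#' (AlphaFold models store pLDDT there; it is reported, never used to
#' filter). The file is pre-validated line by line so malformed ATOM
#' records fail with their line number; when alternate locations are
#' present the first one is taken with a warning.
#'
#' @param path PDB file path.
#' @param chain Optional chain selector; default: first chain in the file.
#' @return A `residue_coords` tibble (see [ideal_helix()] for the columns).
#' @export
read_structure <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^ATOM  |^HETATM", lines)
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54)))))) {
      abort(sprintf("malformed ATOM record at line %d of '%s'", i, path),
            class = "krabstrat_parse_error")
    }
  }
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("bio3d is required to read PDB files")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- as_tibble(pdb$atom)
  if (is.null(chain)) chain <- at$chain[1]
  at <- filter(at, .data$chain == !!chain, .data$type == "ATOM")
  if (any(!is.na(at$alt) & at$alt != "A")) {
    warn("alternate locations present; taking the first altloc")
    at <- filter(at, is.na(.data$alt) | .data$alt == "A")
  }
  pick <- function(elety) {
    at %>%
      filter(.data$elety == !!elety) %>%
      distinct(.data$resno, .keep_all = TRUE) %>%
      select("resno", "x", "y", "z")
  }
  ca <- pick("CA")
  if (nrow(ca) == 0) {
    abort(sprintf("no CA atoms found in '%s' (chain %s)", path, chain),
          class = "krabstrat_parse_error")
  }
  base <- at %>%
    filter(.data$elety == "CA") %>%
    distinct(.data$resno, .keep_all = TRUE) %>%
    select("resno", resname = "resid", "chain", plddt = "b")
  missing_ca <- setdiff(unique(at$resno), ca$resno)
  if (length(missing_ca) > 0) {
    abort(sprintf("residue %d has no CA atom", missing_ca[1]),
          class = "krabstrat_parse_error")
  }
  add_atom <- function(df, tag) {
    co <- pick(tag)
    names(co)[2:4] <- paste0(tolower(tag), "_", c("x", "y", "z"))
    left_join(df, co, by = "resno")
  }
  out <- base %>%
    left_join(setNames(ca, c("resno", "ca_x", "ca_y", "ca_z")), by = "resno") %>%
    add_atom("CB") %>% add_atom("N") %>% add_atom("C") %>%
    arrange(.data$resno)
  if (any(is.na(out$cb_x) & out$resname != "GLY")) {
    warn("CB missing for non-glycine residue(s); pseudo-CB will be used where needed")
  }
  class(out) <- c("residue_coords", class(out))
  out
}

#' Write residue coordinates as a PDB file
#'
#' Emits standard ATOM records for the N, CA, C and CB atoms present; used
#' to materialize synthetic fixtures.
#'
#' @param coords A `residue_coords` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(coords, path) {
  lines <- character()
  serial <- 0L
  for (i in seq_len(nrow(coords))) {
    for (atom in c("N", "CA", "C", "CB")) {
      cols <- paste0(tolower(atom), "_", c("x", "y", "z"))
      xyz <- as.numeric(coords[i, cols])
      if (anyNA(xyz)) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        serial, paste0(" ", atom), coords$resname[i],
        coords$chain[i], coords$resno[i],
        xyz[1], xyz[2], xyz[3], 1.00,
        if (is.na(coords$plddt[i])) 0 else coords$plddt[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

ca_matrix <- function(coords, resno = NULL) {
  if (!is.null(resno)) coords <- coords[coords$resno %in% resno, ]
  as.matrix(coords[, c("ca_x", "ca_y", "ca_z")])
}

#' Detect alpha-helical segments from CA geometry
#'
#' Marks maximal runs where the CA(i)-CA(i+3) distance lies in 4.6--5.8 A
#' and the CA(i)-CA(i+4) distance in 5.6--6.8 A (P-SEA-style
#' distance criteria; no hydrogen bonds needed) and fits each run with
#' [helix_axis()]. Runs shorter than `min_length` residues are dropped.
#'
#' @param coords A `residue_coords` tibble.
#' @param min_length Minimum residues per segment. Default 5.
#' @param d13 Acceptance window for the i,i+3 distance.
#' @param d14 Acceptance window for the i,i+4 distance.
#' @return A `helix_segments` tibble: `start`, `end` (resno, inclusive),
#'   `n_res`, axis point/direction columns, `rise`, `twist`.
#' @export
detect_helices <- function(coords, min_length = 5, d13 = c(4.6, 5.8),
                           d14 = c(5.6, 6.8)) {
  ca <- ca_matrix(coords)
  n <- nrow(ca)
  helical <- rep(FALSE, n)
  if (n >= 5) {
    for (i in seq_len(n - 4)) {
      a13 <- sqrt(sum((ca[i, ] - ca[i + 3, ])^2))
      a14 <- sqrt(sum((ca[i, ] - ca[i + 4, ])^2))
      if (a13 >= d13[1] && a13 <= d13[2] && a14 >= d14[1] && a14 <= d14[2]) {
        helical[i:(i + 4)] <- TRUE
      }
    }
  }
  runs <- rle(helical)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1
  segs <- which(runs$values & runs$lengths >= min_length)
  out <- purrr::map_dfr(segs, function(k) {
    idx <- starts[k]:stops[k]
    ax <- helix_axis(ca[idx, , drop = FALSE])
    tibble(start = coords$resno[idx[1]], end = coords$resno[idx[length(idx)]],
           n_res = length(idx),
           point_x = ax$axis_point[1], point_y = ax$axis_point[2],
           point_z = ax$axis_point[3],
           dir_x = ax$axis_dir[1], dir_y = ax$axis_dir[2], dir_z = ax$axis_dir[3],
           rise = ax$rise, twist = ax$twist)
  })
  if (nrow(out) == 0) {
    out <- tibble(start = integer(), end = integer(), n_res = integer(),
                  point_x = numeric(), point_y = numeric(), point_z = numeric(),
                  dir_x = numeric(), dir_y = numeric(), dir_z = numeric(),
                  rise = numeric(), twist = numeric())
  }
  class(out) <- c("helix_segments", class(out))
  out
}

#' Fit an axis to a helical CA trace
#'
#' The axis direction comes from the second differences of the CA trace:
#' for an ideal helix they are exactly perpendicular to the axis, so
#' normalized cross products of consecutive second differences recover the
#' direction without bias at any length. The axis point and helix radius
#' come from an algebraic circle fit of the CAs projected onto the plane
#' normal to the axis; rise and twist from projections on and about the
#' axis. The direction is oriented N-terminus to C-terminus.
#'
#' @param ca Numeric matrix (n x 3) of CA coordinates, n >= 4.
#' @return List `axis_point`, `axis_dir` (unit), `rise` (A per residue),
#'   `twist` (degrees per residue), `radius`.
#' @export
helix_axis <- function(ca) {
  n <- nrow(ca)
  if (n < 4) abort("helix axis needs at least 4 CA atoms",
                   class = "krabstrat_geom_error")
  d <- diff(ca)            # (n-1) x 3 first differences
  c2 <- diff(d)            # (n-2) x 3 second differences, perpendicular to axis
  chain_dir <- ca[n, ] - ca[1, ]
  norms <- sqrt(rowSums(c2^2))
  c2n <- c2[norms > 1e-9, , drop = FALSE] / norms[norms > 1e-9]
  if (nrow(c2n) < 2) {
    abort("degenerate (collinear) CA trace", class = "krabstrat_geom_error")
  }
  # initial axis estimate: the direction most perpendicular to every second
  # difference (exact for noise-free helices), refined by minimizing the
  # algebraic circle residual of the CAs projected along the axis
  eig <- eigen(t(c2n) %*% c2n, symmetric = TRUE)
  dir <- eig$vectors[, 3]
  if (eig$values[3] > 0.5 * eig$values[2]) {
    abort("degenerate CA trace: no well-defined helix axis",
          class = "krabstrat_geom_error")
  }
  circle_residual <- function(ang) {
    d <- c(cos(ang[1]) * cos(ang[2]), cos(ang[1]) * sin(ang[2]), sin(ang[1]))
    u <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    f1 <- u - sum(u * d) * d; f1 <- f1 / sqrt(sum(f1^2))
    f2 <- c(d[2] * f1[3] - d[3] * f1[2], d[3] * f1[1] - d[1] * f1[3],
            d[1] * f1[2] - d[2] * f1[1])
    pp <- cbind(ca %*% f1, ca %*% f2)
    A <- cbind(2 * pp, 1)
    b <- rowSums(pp^2)
    sum((b - A %*% qr.solve(A, b))^2)
  }
  a0 <- c(asin(pmin(1, pmax(-1, dir[3]))), atan2(dir[2], dir[1]))
  a1 <- stats::optim(a0, circle_residual, method = "Nelder-Mead")$par
  dir <- c(cos(a1[1]) * cos(a1[2]), cos(a1[1]) * sin(a1[2]), sin(a1[1]))
  if (sum(dir * chain_dir) < 0) dir <- -dir

  # orthonormal basis of the normal plane
  u <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- u - sum(u * dir) * dir; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  p <- cbind(ca %*% e1, ca %*% e2)
  # Kasa algebraic circle fit: minimizes ||p - c||^2 - r^2 residuals linearly
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  center2 <- sol[1:2]
  radius <- sqrt(sol[3] + sum(center2^2))
  t_along <- as.numeric(ca %*% dir)
  axis_point <- center2[1] * e1 + center2[2] * e2 + mean(t_along) * dir

  rise <- (t_along[n] - t_along[1]) / (n - 1)
  ang <- atan2(p[, 2] - center2[2], p[, 1] - center2[1])
  dang <- diff(ang)
  dang <- (dang + pi) %% (2 * pi) - pi
  # signed per-residue twist, right-handed about the N-to-C axis direction
  twist <- mean(dang) * 180 / pi
  list(axis_point = axis_point, axis_dir = dir,
       rise = rise, twist = twist, radius = radius)
}

#' Angle between two helix axes
#'
#' @param seg1,seg2 Single rows of a `helix_segments` tibble (or lists with
#'   `dir_x/dir_y/dir_z` or `axis_dir`).
#' @return Angle in degrees (0 to 180) between the oriented axes.
#' @export
interhelix_angle <- function(seg1, seg2) {
  dir_of <- function(s) {
    if ("axis_dir" %in% names(s)) s[["axis_dir"]] else
      c(s[["dir_x"]], s[["dir_y"]], s[["dir_z"]])
  }
  d1 <- dir_of(seg1); d2 <- dir_of(seg2)
  d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
  acos(pmin(1, pmax(-1, sum(d1 * d2)))) * 180 / pi
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `moving` onto `fixed`
#' over the given residue range (SVD solution with the determinant
#' correction, so mirrored inputs still yield a proper rotation).
#'
#' @param fixed,moving `residue_coords` tibbles (or n x 3 CA matrices).
#' @param resno Residue numbers to superpose on (matrices: all rows).
#' @return List `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom over the fitted atoms). Apply as `x %*% t(R) + t`.
#' @export
kabsch_superpose <- function(fixed, moving, resno = NULL) {
  X <- if (is.matrix(fixed)) fixed else ca_matrix(fixed, resno)
  Y <- if (is.matrix(moving)) moving else ca_matrix(moving, resno)
  if (nrow(X) != nrow(Y)) {
    abort("superposition needs equal atom counts", class = "krabstrat_geom_error")
  }
  if (nrow(X) < 3) {
    abort("superposition needs at least 3 atoms", class = "krabstrat_geom_error")
  }
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(Y - matrix(cy, nrow(Y), 3, byrow = TRUE)) %*%
    (X - matrix(cx, nrow(X), 3, byrow = TRUE))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cx - as.numeric(R %*% cy)
  Yt <- Y %*% t(R) + matrix(tr, nrow(Y), 3, byrow = TRUE)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((Yt - X)^2))))
}

# standard tetrahedral pseudo-CB from N, CA, C (used when CB is absent,
# e.g. glycine probes)
pseudo_cb <- function(n, ca, cc) {
  v1 <- n - ca; v2 <- cc - ca
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  bis <- -(v1 + v2); bis <- bis / sqrt(sum(bis^2))
  perp <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
  perp <- perp / sqrt(sum(perp^2))
  ang <- 54.75 * pi / 180
  ca + 1.53 * (cos(ang) * bis + sin(ang) * perp)
}

cb_vector <- function(coords, resno) {
  row <- coords[coords$resno == resno, ]
  if (nrow(row) != 1) {
    abort(sprintf("probe residue %d not found", resno),
          class = "krabstrat_geom_error")
  }
  ca <- as.numeric(row[, c("ca_x", "ca_y", "ca_z")])
  cb <- as.numeric(row[, c("cb_x", "cb_y", "cb_z")])
  if (anyNA(cb)) {
    nn <- as.numeric(row[, c("n_x", "n_y", "n_z")])
    cc <- as.numeric(row[, c("c_x", "c_y", "c_z")])
    if (anyNA(nn) || anyNA(cc)) {
      abort(sprintf("residue %d has neither CB nor backbone for pseudo-CB", resno),
            class = "krabstrat_geom_error")
    }
    cb <- pseudo_cb(nn, ca, cc)
  }
  list(ca = ca, vec = cb - ca)
}

#' Azimuthal side-chain register rotation between two structures
#'
#' Superposes `struct_b` onto `struct_a` over the anchor residues, fits the
#' shared helix axis on the anchor CAs of `struct_a`, and returns the signed
#' angle (right-handed about the N-to-C axis direction, in (-180, 180])
#' between the two probe side-chain vectors (CA to CB, pseudo-CB if absent)
#' after projection onto the plane normal to the axis. Inserting one residue
#' upstream of the probe in an ideal helix rotates the probe side chain by
#' the per-residue twist (about 100 degrees) — the geometric fingerprint of
#' the one-residue aKRAB/mKRAB difference.
#'
#' @param struct_a,struct_b `residue_coords` tibbles.
#' @param anchor_range Residue numbers (in both structures) of the shared,
#'   superposable helix stretch.
#' @param probe_a Probe residue number in `struct_a`.
#' @param probe_b Probe residue number in `struct_b`; defaults to `probe_a`.
#' @return Signed rotation in degrees.
#' @export
azimuthal_rotation <- function(struct_a, struct_b, anchor_range, probe_a,
                               probe_b = probe_a) {
  fit <- kabsch_superpose(struct_a, struct_b, resno = anchor_range)
  b_t <- transform_coords(struct_b, fit$rotation, fit$translation)
  ax <- helix_axis(ca_matrix(struct_a, anchor_range))
  dir <- ax$axis_dir
  va <- cb_vector(struct_a, probe_a)$vec
  vb <- cb_vector(b_t, probe_b)$vec
  pa <- va - sum(va * dir) * dir
  pb <- vb - sum(vb * dir) * dir
  if (sqrt(sum(pa^2)) < 1e-9 || sqrt(sum(pb^2)) < 1e-9) {
    abort("probe side chain lies on the helix axis; azimuth undefined",
          class = "krabstrat_geom_error")
  }
  cross <- c(pa[2] * pb[3] - pa[3] * pb[2],
             pa[3] * pb[1] - pa[1] * pb[3],
             pa[1] * pb[2] - pa[2] * pb[1])
  ang <- atan2(sum(cross * dir), sum(pa * pb)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}
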