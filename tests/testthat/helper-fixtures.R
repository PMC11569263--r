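# in-code fixtures shared across test files

# bare frame holding only water oxygens at given coordinates (n x 3)
water_frame <- function(coords, time = 0) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  md_frame(data.frame(
    serial = seq_len(n), atom_name = "OW", element = "O",
    residue_name = "SOL", residue_number = seq_len(n), subunit_id = "W",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    vdw_radius = 1.52, stringsAsFactors = FALSE), time = time)
}

# frame of uniformly random waters in a cube of the given edge length
random_water_frame <- function(n, box = 40, time = 0) {
  water_frame(matrix(runif(3 * n, -box / 2, box / 2), ncol = 3),
              time = time)
}

# arbitrary-atom frame builder: rows of (name, element, resno, chain, x, y, z)
atoms_frame <- function(name, resno, chain, x, y, z, element = NULL,
                        resname = "ALA", vdw = 1.70, time = 0) {
  n <- length(x)
  if (is.null(element)) element <- substr(name, 1, 1)
  md_frame(data.frame(
    serial = seq_len(n), atom_name = rep_len(name, n),
    element = rep_len(element, n), residue_name = rep_len(resname, n),
    residue_number = rep_len(resno, n), subunit_id = rep_len(chain, n),
    x = x, y = y, z = z, vdw_radius = rep_len(vdw, n),
    stringsAsFactors = FALSE), time = time)
}

# apply a rigid rotation about z plus an xy translation to every atom
rotate_frame_z <- function(frame, angle_deg, shift_xy = c(0, 0)) {
  th <- angle_deg * pi / 180
  x <- frame$atoms$x; y <- frame$atoms$y
  frame$atoms$x <- cos(th) * x - sin(th) * y + shift_xy[1]
  frame$atoms$y <- sin(th) * x + cos(th) * y + shift_xy[2]
  frame
}

# apply an arbitrary rigid 3-D rotation (by unit axis + angle) + translation
rotate_frame_3d <- function(frame, axis, angle_deg, shift = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  m <- cbind(frame$atoms$x, frame$atoms$y, frame$atoms$z) %*% t(R)
  frame$atoms$x <- m[, 1] + shift[1]
  frame$atoms$y <- m[, 2] + shift[2]
  frame$atoms$z <- m[, 3] + shift[3]
  frame
}

# exhaustive per-water loop distance count (independent oracle)
brute_force_water_count <- function(frame, reference, cutoff) {
  w <- water_oxygens(frame)
  cnt <- 0L
  for (i in seq_len(nrow(w))) {
    d <- sqrt((w$x[i] - reference[1])^2 + (w$y[i] - reference[2])^2 +
              (w$z[i] - reference[3])^2)
    if (d <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# hexamer frame with six CA atoms of one residue on a ring (plus optional
# pore-defining TM1 stubs so pore_center resolves)
hexamer_ca_frame <- function(residue = 181, ring_radius = 20, z = 0,
                             with_pore_stubs = TRUE) {
  phis <- 2 * pi * (0:5) / 6
  nm <- rep("CA", 6); rn <- rep(residue, 6); ch <- LETTERS[1:6]
  x <- ring_radius * cos(phis); y <- ring_radius * sin(phis); zz <- rep(z, 6)
  if (with_pore_stubs) {
    nm <- c(nm, rep("CA", 6)); rn <- c(rn, rep(80L, 6))
    ch <- c(ch, LETTERS[1:6])
    x <- c(x, 2 * cos(phis)); y <- c(y, 2 * sin(phis)); zz <- c(zz, rep(0, 6))
  }
  atoms_frame(nm, rn, ch, x, y, zz, element = "C")
}
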