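make_angle_frame <- function(ca, cg) {
  atoms_frame(c("CA", "CA", "CA", "CA", "CG"),
              c(80, 81, 82, 181, 181),
              "A",
              x = c(1, -1, 0, ca[1], cg[1]),
              y = c(0, 0, 1, ca[2], cg[2]),
              z = c(0, 0, -1, ca[3], cg[3]),
              element = "C")
}

test_that("rotation angle is 0 toward the pore, 90 tangential, NA when degenerate", {
  # pore center = mean of CA 80-82 = (0, 1/3, -1/3); use symmetric stubs
  f0 <- atoms_frame(c("CA", "CA", "CA", "CA", "CA", "CG"),
                    c(80, 81, 82, 83, 181, 181), "A",
                    x = c(1, -1, 0, 0, 10, 8),
                    y = c(0, 0, 1, -1, 0, 0),
                    z = c(0, 0, 0, 0, 5, 6),
                    element = "C")
  expect_equal(rotation_angle(f0, 181, "A"), 0)
  f90 <- f0
  f90$atoms$x[6] <- 10; f90$atoms$y[6] <- 2
  expect_equal(rotation_angle(f90, 181, "A"), 90)
  f180 <- f0
  f180$atoms$x[6] <- 12
  expect_equal(rotation_angle(f180, 181, "A"), 180)
  fdeg <- f0
  fdeg$atoms$x[6] <- 10; fdeg$atoms$z[6] <- 7   # Cgamma right above Calpha
  expect_true(is.na(rotation_angle(fdeg, 181, "A")))
})

test_that("rotation angle is invariant under rigid z-rotation plus xy-translation", {
  set.seed(33)
  ch <- build_channel(channel_spec(n_frames = 1, n_replicas = 1, seed = 12))
  f <- ch$trajectories[[1]]$frames[[1]]
  for (i in 1:10) {
    fr <- rotate_frame_z(f, runif(1, 0, 360), runif(2, -20, 20))
    for (s in c("A", "D"))
      expect_equal(rotation_angle(fr, 181, s), rotation_angle(f, 181, s),
                   tolerance = 1e-9)
  }
})

test_that("moiety distance is the in-plane distance of the moiety center", {
  base <- atoms_frame(c("CA", "CA", "CA", "CA"), c(80, 81, 82, 83), "A",
                      x = c(1, -1, 0, 0), y = c(0, 0, 1, -1),
                      z = c(0, 0, 0, 0), element = "C")
  add_moiety <- function(f, xyz, names = "NZ") {
    extra <- atoms_frame(names, rep(181L, nrow(xyz)), "A",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         element = "N")$atoms
    extra$serial <- nrow(f$atoms) + seq_len(nrow(extra))
    md_frame(rbind(f$atoms, extra), time = 0)
  }
  f1 <- add_moiety(base, rbind(c(3, 4, 10)))
  expect_equal(moiety_distance(f1, "NZ", 181, "A"), 5.0)
  f2 <- add_moiety(base, rbind(c(3, 4, 0), c(5, 4, 2)), c("OE1", "OE2"))
  expect_equal(moiety_distance(f2, c("OE1", "OE2"), 181, "A"), sqrt(32))
  f3 <- add_moiety(base, rbind(c(0, 0, 7)))
  expect_equal(moiety_distance(f3, "NZ", 181, "A"), 0)
})

test_that("moiety atom sets resolve from residue type presets", {
  f <- atoms_frame(c("CA", "CA", "CA", "CA", "CA", "NZ"),
                   c(80, 81, 82, 83, 181, 181), "A",
                   x = c(1, -1, 0, 0, 9, 6), y = c(0, 0, 1, -1, 0, 8),
                   z = rep(0, 6), element = c(rep("C", 5), "N"),
                   resname = "LYS")
  expect_equal(moiety_distance(f, NULL, 181, "A"), 10)
})

test_that("triangle areas match the closed form", {
  f <- atoms_frame(c("CA", "CA", "CA"), c(143, 177, 253), "A",
                   x = c(0, 3, 0), y = c(0, 0, 4), z = c(0, 0, 0),
                   element = "C")
  expect_identical(triangle_area(f, c(143, 177, 253), "CA", "A"), 6.0)
  fc <- atoms_frame(c("CA", "CA", "CA"), c(143, 177, 253), "A",
                    x = c(0, 1, 2), y = c(0, 1, 2), z = c(0, 1, 2),
                    element = "C")
  expect_equal(triangle_area(fc), 0)
  ft <- atoms_frame(c("CA", "CA", "CA"), c(143, 177, 253), "A",
                    x = c(0, 1, 0), y = c(0, 0, 1), z = c(0, 0, 1),
                    element = "C")
  expect_equal(triangle_area(ft), sqrt(2) / 2)
})

test_that("triangle area is rigid-invariant and scales quadratically", {
  f <- atoms_frame(c("CA", "CA", "CA"), c(143, 177, 253), "A",
                   x = c(0.3, 3.1, -0.4), y = c(0.1, 0.5, 4.2),
                   z = c(-1, 2, 0.7), element = "C")
  a0 <- triangle_area(f)
  fr <- rotate_frame_3d(f, c(1, 2, 3), 77, c(5, -6, 7))
  expect_equal(triangle_area(fr), a0, tolerance = 1e-9)
  fs <- f
  fs$atoms$x <- 2 * f$atoms$x
  fs$atoms$y <- 2 * f$atoms$y
  fs$atoms$z <- 2 * f$atoms$z
  expect_equal(triangle_area(fs), 4 * a0, tolerance = 1e-9)
})

test_that("torsions follow the IUPAC sign convention", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 0, 1)), 90)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 0, -1)), -90)
  expect_true(is.na(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                   c(3, 1, 0))))
  # agreement with an established torsion implementation on random geometry
  set.seed(4)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 as.numeric(bio3d::torsion.xyz(as.vector(t(p)))),
                 tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD is zero on self and on rigid copies", {
  ch <- build_channel(channel_spec(n_frames = 1, n_replicas = 1, seed = 8))
  f <- ch$trajectories[[1]]$frames[[1]]
  expect_equal(kabsch_rmsd(f, f), 0, tolerance = 1e-12)
  fr <- rotate_frame_3d(f, c(0.2, -1, 0.5), 37, c(3, 4, 5))
  expect_lt(kabsch_rmsd(fr, f), 1e-8)
  expect_lt(kabsch_rmsd(fr, f, selection_spec("TM3_FIT")), 1e-8)
})

test_that("Kabsch RMSD is symmetric and fitted never exceeds unfitted", {
  set.seed(66)
  ch <- build_channel(channel_spec(n_frames = 1, n_replicas = 1, seed = 8))
  ref <- ch$trajectories[[1]]$frames[[1]]
  for (i in 1:20) {
    mob <- ref
    n <- nrow(mob$atoms)
    mob$atoms$x <- mob$atoms$x + rnorm(n, sd = 0.5)
    mob$atoms$y <- mob$atoms$y + rnorm(n, sd = 0.5)
    mob$atoms$z <- mob$atoms$z + rnorm(n, sd = 0.5)
    r1 <- kabsch_rmsd(mob, ref)
    r2 <- kabsch_rmsd(ref, mob)
    expect_lt(abs(r1 - r2), 1e-9)
    unfitted <- sqrt(mean(rowSums(
      (hydrogate:::sel_coords(mob, selection_spec("TM1")) -
       hydrogate:::sel_coords(ref, selection_spec("TM1")))^2)))
    expect_lte(r1, unfitted + 1e-12)
  }
})

test_that("Kabsch agrees with a direct numerical optimizer over rigid motions", {
  set.seed(5)
  ref <- matrix(rnorm(30, sd = 4), 10, 3)
  mob <- ref
  mob[4, ] <- mob[4, ] + c(1, 0, 0)
  mkframe <- function(m) atoms_frame("CA", 80:89, "A",
                                     x = m[, 1], y = m[, 2], z = m[, 3],
                                     element = "C")
  sel <- selection_spec(c(80, 89))
  got <- kabsch_rmsd(mkframe(mob), mkframe(ref), sel)
  # oracle: optimize Euler angles + translation numerically
  obj <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    moved <- mob %*% t(Rz %*% Ry %*% Rx)
    moved <- sweep(moved, 2, p[4:6], `+`)
    sqrt(mean(rowSums((moved - ref)^2)))
  }
  o <- optim(rep(0, 6), obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  o <- optim(o$par, obj, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(got, o$value, tolerance = 1e-6)
  expect_lte(got, o$value + 1e-9)
})

test_that("descriptor series are constant on constant trajectories and recover planted distributions", {
  ch <- build_channel(channel_spec(n_frames = 3, n_replicas = 1, seed = 19,
                                   orientation_kappa = 1e9))
  ds <- series_over_trajectory(ch$trajectories[[1]], "triangle_area",
                               residues = c(143, 177, 253))
  expect_lt(diff(range(ds$series[[1]]$values)), 1e-9)
  expect_equal(sum(ds$histogram$density), 1, tolerance = 1e-9)

  ch2 <- build_channel(channel_spec(n_frames = 90, n_replicas = 1,
                                    seed = 23,
                                    pore_water_density = 0,
                                    shell_water_density = 0))
  da <- series_over_trajectory(ch2$trajectories[[1]], "rotation_angle",
                               residue = 181)
  vals <- da$values
  expect_gte(length(vals), 500)
  expect_true(all(vals >= 0 & vals <= 180))
  cm <- hydrogate:::circular_mean_deg(vals)
  expect_lt(abs(cm - 60), 2)
})
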