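test_that("single-model PDB round-trips atoms and coordinates", {
  f <- atoms_frame(c("CA", "CB", "CG", "CA", "CB", "CG", "CA", "CB", "CG", "CA"),
                   c(80, 80, 80, 81, 81, 81, 82, 82, 82, 83),
                   "A",
                   x = seq(0.1, 1, by = 0.1) * 3,
                   y = seq(-1, 0.8, by = 0.2),
                   z = seq(5, 9.5, by = 0.5),
                   element = "C")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(f, path)
  tr <- read_structure(path)
  expect_length(tr, 1L)
  a <- tr$frames[[1]]$atoms
  expect_equal(nrow(a), 10L)
  expect_identical(a$atom_name, f$atoms$atom_name)
  expect_identical(a$residue_number, f$atoms$residue_number)
  expect_identical(a$subunit_id, f$atoms$subunit_id)
  expect_equal(a$x, f$atoms$x, tolerance = 1e-8)
})

test_that("multi-MODEL PDB yields one frame per model with stable ordering", {
  frames <- lapply(0:2, function(k) {
    f <- atoms_frame(rep(c("CA", "CB"), 3), rep(80:82, each = 2), "B",
                     x = 1:6 + k, y = rep(2, 6), z = rep(3, 6) + 0.5 * k,
                     element = "C", time = k)
    f
  })
  tr0 <- md_trajectory(frames)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tr0, path)
  tr <- read_structure(path)
  expect_length(tr, 3L)
  for (k in 1:3) {
    expect_identical(tr$frames[[k]]$atoms$atom_name,
                     tr$frames[[1]]$atoms$atom_name)
    expect_equal(tr$frames[[k]]$atoms$x, frames[[k]]$atoms$x,
                 tolerance = 1e-8)
  }
})

test_that("synthetic hexamer survives a PDB write/read cycle within format precision", {
  ch <- build_channel(channel_spec(n_frames = 2, n_replicas = 1, seed = 11))
  tr <- ch$trajectories[[1]]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tr, path)
  tr2 <- read_structure(path)
  expect_length(tr2, 2L)
  for (k in 1:2) {
    a <- tr$frames[[k]]$atoms; b <- tr2$frames[[k]]$atoms
    expect_identical(b$atom_name, a$atom_name)
    expect_identical(b$residue_number, a$residue_number)
    expect_lt(max(abs(b$x - a$x), abs(b$y - a$y), abs(b$z - a$z)), 1e-3)
  }
  # waters recognized after the round trip
  expect_equal(nrow(water_oxygens(tr2$frames[[1]])),
               nrow(water_oxygens(tr$frames[[1]])))
})

test_that("XYZ frames parse with element-derived radii", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "frame 0",
               "C 0.0 0.0 0.0", "O 1.5 0.0 0.0", "N 0.0 1.5 0.0",
               "3", "frame 1",
               "C 0.1 0.0 0.0", "O 1.6 0.0 0.0", "N 0.0 1.6 0.0"), path)
  tr <- read_structure(path)
  expect_length(tr, 2L)
  expect_equal(tr$frames[[1]]$atoms$vdw_radius, c(1.70, 1.52, 1.55))
  expect_equal(tr$frames[[2]]$atoms$x, c(0.1, 1.6, 0.0))
})

test_that("malformed and unknown-element records raise informative errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A  80       1.000   2.000   3.000",
               "ATOM      2  CA  ALA A  81       bad     2.000   3.000"),
             path)
  expect_error(read_structure(path), "line 2")
  path2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "x", "Xx 0 0 0"), path2)
  expect_error(read_structure(path2), "XX")
})

test_that("trajectory invariants are enforced", {
  f1 <- atoms_frame("CA", 80:82, "A", x = 1:3, y = 1:3, z = 1:3,
                    element = "C", time = 0)
  f2 <- atoms_frame("CA", 80:82, "A", x = 2:4, y = 1:3, z = 1:3,
                    element = "C", time = 1)
  f3 <- atoms_frame("CA", 80:83, "A", x = 1:4, y = 1:4, z = 1:4,
                    element = "C", time = 2)
  expect_s3_class(md_trajectory(list(f1, f2)), "md_trajectory")
  expect_error(md_trajectory(list(f1, f3)), "atom count")
  f2$time <- 0
  expect_error(md_trajectory(list(f1, f2)), "strictly increasing")
})

test_that("select_atoms matches residue range, names and subunits", {
  ch <- build_channel(channel_spec(n_frames = 1, n_replicas = 1, seed = 3))
  f <- ch$trajectories[[1]]$frames[[1]]
  # 31 TM1 residues x 6 subunits
  expect_equal(nrow(select_atoms(f, selection_spec("TM1"))), 186L)
  one <- select_atoms(f, selection_spec(181, "CG", "A"))
  expect_equal(nrow(one), 1L)
  expect_error(select_atoms(f, selection_spec(c(999, 999))),
               "empty selection")
})

test_that("select_atoms is idempotent, order-stable and additive over disjoint ranges", {
  ch <- build_channel(channel_spec(n_frames = 1, n_replicas = 1, seed = 3))
  f <- ch$trajectories[[1]]$frames[[1]]
  s1 <- select_atoms(f, selection_spec(c(80, 95)))
  s2 <- select_atoms(f, selection_spec(c(96, 110)))
  su <- select_atoms(f, selection_spec(c(80, 110)))
  both <- rbind(s1, s2)
  expect_setequal(both$serial, su$serial)
  # order stability: serial numbers ascending within each subunit block order
  expect_identical(su$serial, sort(su$serial))
})

test_that("series and profiles round-trip through CSV and JSON", {
  ss <- scalar_series(c(0, 1), LETTERS[1:6],
                      matrix(seq(0.5, 6.5, length.out = 12), 2, 6),
                      unit = "deg", metric = "rotation_angle")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_table(ss, csv)
  back <- read_table(csv)
  expect_equal(nrow(back), 2L)
  expect_equal(ncol(back), 7L)
  expect_equal(back[["A.deg"]], ss$values[, 1])
  js <- withr::local_tempfile(fileext = ".json")
  write_table(ss, js)
  backj <- read_table(js)
  expect_equal(backj$values$A, ss$values[, 1])

  ch <- build_channel(channel_spec(n_frames = 2, n_replicas = 2, seed = 5))
  ap <- axial_water_histogram(ch$trajectories, cylinder_radius = 10,
                              dz = 1, z_range = c(-15, 15))
  js2 <- withr::local_tempfile(fileext = ".json")
  write_table(ap, js2)
  backa <- read_table(js2)
  expect_length(backa$mean, length(backa$bin_edges_A) - 1L)
  expect_equal(backa$mean, ap$mean)
  expect_equal(backa$sd_of_mean, ap$sd_of_mean)
})
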