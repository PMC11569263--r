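# Best & Fisher (1979) rejection sampler; mu, kappa in radians
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(((runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(runif(1) - 0.5) * acos(max(-1, min(1, f))) + mu
    }
  }
  out
}

#' Specification of a synthetic pseudo-hexameric channel
#'
#' Ground-truth generator parameters for [build_channel]. The defaults
#' emulate the study conditions: a hexamer whose four concentric helix
#' rings carry the TM1-TM4 residue numbering, waters placed as a
#' homogeneous Poisson process at bulk-like density 0.0334 per cubic
#' Angstrom in the 10 Angstrom pore cylinder and at 0.00332 per cubic
#' Angstrom in the 6 Angstrom back-pore shells around residue 181 (about
#' 18 waters per channel summed over the six shells, the hydrated-state
#' figure), side-chain
#' orientations of residue 181 drawn from a von Mises distribution, three
#' replicas of 25 frames spanning 50 ns.
#'
#' @param n_subunits Number of subunits (default 6).
#' @param ring_radii Named radii (Angstrom) of the TM1/TM2/TM3/TM4 rings.
#' @param helix_z Axial extent of the helices, Angstrom.
#' @param vdw_radius Pseudo-atom van der Waals radius (carbon, 1.70).
#' @param pore_cylinder_radius,pore_water_density Pore water region:
#'   cylinder radius (Angstrom) and Poisson density (per cubic Angstrom).
#' @param shell_radius,shell_water_density Back-pore region: shell radius
#'   around the Calpha of `orientation_residue` and its Poisson density.
#' @param orientation_residue Residue whose Cgamma orientation is planted.
#' @param orientation_mu,orientation_kappa von Mises mean (degrees, 0 =
#'   toward the pore) and concentration of the planted orientations.
#' @param n_frames,n_replicas,dt Frames per replica, replica count, frame
#'   spacing (ns).
#' @param seed RNG seed; identical specs and seeds give identical output.
#' @return Object of class `"channel_spec"`.
#' @export
channel_spec <- function(n_subunits = 6,
                         ring_radii = c(TM1 = 8, TM2 = 14, TM3 = 20,
                                        TM4 = 26),
                         helix_z = c(-15, 15),
                         vdw_radius = 1.70,
                         pore_cylinder_radius = 10,
                         pore_water_density = 0.0334,
                         shell_radius = 6,
                         shell_water_density = 0.00332,
                         orientation_residue = 181,
                         orientation_mu = 60,
                         orientation_kappa = 8,
                         n_frames = 25, n_replicas = 3, dt = 2,
                         seed = 1) {
  stopifnot(n_subunits >= 1, all(ring_radii > vdw_radius),
            pore_water_density >= 0, shell_water_density >= 0,
            n_frames >= 1, n_replicas >= 1, dt > 0)
  structure(as.list(environment()), class = "channel_spec")
}

# residue ranges carried by the pseudo-helices (Orai1 numbering)
helix_residue_ranges <- function() {
  list(TM1 = tm_presets$TM1, TM2 = tm_presets$TM2,
       TM3 = tm_presets$TM3, TM4 = tm_presets$TM4)
}

atom_row <- function(serial, name, element, resname, resno, chain,
                     pos, vdw) {
  data.frame(serial = serial, atom_name = name, element = element,
             residue_name = resname, residue_number = resno,
             subunit_id = chain, x = pos[1], y = pos[2], z = pos[3],
             vdw_radius = vdw, stringsAsFactors = FALSE)
}

#' Build a synthetic pseudo-hexameric channel trajectory
#'
#' Each subunit contributes one Calpha column per helix ring at the ring's
#' radius and the subunit's azimuth, carrying the TM residue numbering, so
#' the pore-defining selection (Calpha 80-110) resolves and its geometric
#' center sits at the origin. The Cgamma of `orientation_residue` is
#' placed 1.5 Angstrom from its Calpha in the xy-plane, rotated by a von
#' Mises-distributed angle away from the pore direction (one draw per
#' frame, subunit and replica). Waters (residue SOL, atom OW) are
#' Poisson-placed per frame in the pore cylinder and the back-pore shells.
#'
#' @param spec A [channel_spec].
#' @return Object of class `"synthetic_channel"`: `trajectories` (list of
#'   [md_trajectory], one per replica), `spec`, and `truth` with
#'   `orientations_deg` (replica x frame x subunit array of planted signed
#'   angles) and per-frame planted water counts per region.
#' @export
build_channel <- function(spec = channel_spec()) {
  stopifnot(inherits(spec, "channel_spec"))
  set.seed(spec$seed)
  ns <- spec$n_subunits
  phis <- 2 * pi * (seq_len(ns) - 1) / ns
  chains <- LETTERS[seq_len(ns)]
  ranges <- helix_residue_ranges()
  # static protein template (coordinates of CG filled per frame)
  rows <- list()
  serial <- 0L
  for (s in seq_len(ns)) {
    dirs <- c(cos(phis[s]), sin(phis[s]))
    for (h in names(ranges)) {
      rr <- ranges[[h]]
      resnos <- rr[1]:rr[2]
      zz <- seq(spec$helix_z[1], spec$helix_z[2], length.out = length(resnos))
      for (i in seq_along(resnos)) {
        serial <- serial + 1L
        rows[[length(rows) + 1L]] <- atom_row(
          serial, "CA", "C", "ALA", resnos[i], chains[s],
          c(spec$ring_radii[[h]] * dirs, zz[i]), spec$vdw_radius)
      }
    }
  }
  protein <- do.call(rbind, rows)
  # Cgamma rows for the orientation residue, one per subunit
  ca181 <- protein[protein$residue_number == spec$orientation_residue &
                   protein$atom_name == "CA", ]
  cg_template <- ca181
  cg_template$atom_name <- "CG"
  cg_template$serial <- max(protein$serial) + seq_len(nrow(cg_template))
  mu <- spec$orientation_mu * pi / 180
  n_total_frames <- spec$n_replicas * spec$n_frames
  orientations <- array(
    rvonmises(n_total_frames * ns, mu, spec$orientation_kappa) * 180 / pi,
    dim = c(spec$n_replicas, spec$n_frames, ns))
  pore_counts <- matrix(0L, spec$n_replicas, spec$n_frames)
  shell_counts <- array(0L, dim = c(spec$n_replicas, spec$n_frames, ns))
  trajectories <- vector("list", spec$n_replicas)
  # trajectories need a constant atom count across frames: per-frame Poisson
  # water counts are padded up to the replica maximum with reservoir waters
  # parked far above the channel, outside every analysis region
  reservoir_z <- spec$helix_z[2] + 100
  for (r in seq_len(spec$n_replicas)) {
    frame_waters <- vector("list", spec$n_frames)
    for (k in seq_len(spec$n_frames)) {
      waters <- list()
      # pore cylinder (Poisson point process)
      vol <- pi * spec$pore_cylinder_radius^2 * diff(spec$helix_z)
      npw <- rpois(1, spec$pore_water_density * vol)
      pore_counts[r, k] <- npw
      if (npw > 0) {
        rad <- spec$pore_cylinder_radius * sqrt(runif(npw))
        ang <- runif(npw, 0, 2 * pi)
        waters[[1]] <- cbind(rad * cos(ang), rad * sin(ang),
                             runif(npw, spec$helix_z[1], spec$helix_z[2]))
      }
      # back-pore shells around each subunit's orientation residue
      for (s in seq_len(ns)) {
        vs <- 4 / 3 * pi * spec$shell_radius^3
        nsw <- rpois(1, spec$shell_water_density * vs)
        shell_counts[r, k, s] <- nsw
        if (nsw > 0) {
          u <- matrix(rnorm(3 * nsw), ncol = 3)
          u <- u / sqrt(rowSums(u^2))
          rr <- spec$shell_radius * runif(nsw)^(1 / 3)
          waters[[length(waters) + 1L]] <-
            u * rr + matrix(c(ca181$x[s], ca181$y[s], ca181$z[s]),
                            nsw, 3, byrow = TRUE)
        }
      }
      frame_waters[[k]] <- if (length(waters)) do.call(rbind, waters)
                           else matrix(0, 0, 3)
    }
    n_water <- max(vapply(frame_waters, nrow, 0L))
    frames <- vector("list", spec$n_frames)
    for (k in seq_len(spec$n_frames)) {
      wxyz <- frame_waters[[k]]
      pad <- n_water - nrow(wxyz)
      if (pad > 0) {
        rad <- 20 * sqrt(runif(pad))
        ang <- runif(pad, 0, 2 * pi)
        wxyz <- rbind(wxyz, cbind(rad * cos(ang), rad * sin(ang),
                                  reservoir_z + runif(pad, 0, 10)))
      }
      cg <- cg_template
      for (s in seq_len(ns)) {
        ca <- c(ca181$x[s], ca181$y[s], ca181$z[s])
        toward <- -c(cos(phis[s]), sin(phis[s]))   # unit vector to the axis
        th <- orientations[r, k, s] * pi / 180
        rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        d <- rot %*% toward
        cg$x[s] <- ca[1] + 1.5 * d[1]
        cg$y[s] <- ca[2] + 1.5 * d[2]
        cg$z[s] <- ca[3]
      }
      atoms <- rbind(protein, cg)
      if (n_water > 0) {
        wdf <- data.frame(
          serial = max(atoms$serial) + seq_len(n_water),
          atom_name = "OW", element = "O", residue_name = "SOL",
          residue_number = 1000L + seq_len(n_water),
          subunit_id = "W", x = wxyz[, 1], y = wxyz[, 2], z = wxyz[, 3],
          vdw_radius = 1.52, stringsAsFactors = FALSE)
        atoms <- rbind(atoms, wdf)
      }
      frames[[k]] <- md_frame(atoms, time = (k - 1) * spec$dt)
    }
    trajectories[[r]] <- md_trajectory(frames, r)
  }
  structure(list(trajectories = trajectories, spec = spec,
                 truth = list(orientations_deg = orientations,
                              pore_water_counts = pore_counts,
                              shell_water_counts = shell_counts)),
            class = "synthetic_channel")
}

#' @export
print.synthetic_channel <- function(x, ...) {
  cat(sprintf(
    "<synthetic_channel> %d replicas x %d frames, %d subunits, seed %d\n",
    x$spec$n_replicas, x$spec$n_frames, x$spec$n_subunits, x$spec$seed))
  invisible(x)
}

#' Single ring of pseudo-atoms in one slice plane
#'
#' Analytic test geometry for the pore-radius machinery: `n_atoms`
#' identical atoms equally spaced on a circle give a slice radius of
#' exactly `radius - vdw_radius` at the ring center.
#'
#' @param n_atoms Atoms on the ring.
#' @param radius Ring (cylindrical) radius, Angstrom.
#' @param center_xy In-plane ring center.
#' @param z Slice height.
#' @param residue_start First residue number (consecutive along the ring).
#' @param vdw_radius Atom radius, Angstrom.
#' @param subunit Chain label.
#' @return Data frame of atom records (combine with [md_frame]).
#' @export
ring_atoms <- function(n_atoms = 12, radius = 8.0, center_xy = c(0, 0),
                       z = 0, residue_start = 80, vdw_radius = 1.70,
                       subunit = "A") {
  ang <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
  data.frame(serial = seq_len(n_atoms), atom_name = "CA", element = "C",
             residue_name = "ALA",
             residue_number = residue_start + seq_len(n_atoms) - 1L,
             subunit_id = subunit,
             x = center_xy[1] + radius * cos(ang),
             y = center_xy[2] + radius * sin(ang),
             z = z, vdw_radius = vdw_radius, stringsAsFactors = FALSE)
}

#' Specification of synthetic microscopy images
#'
#' Parameters for [make_fret_images] and [make_nfat_population]. Cells are
#' disk footprints on a grid; intensities are counts on a 16-bit scale.
#'
#' @param shape Image dimensions (rows, cols).
#' @param background Planted background level, counts.
#' @param n_cells Number of cells.
#' @param cell_radius Footprint radius, pixels.
#' @param E_true Planted FRET efficiencies, recycled over cells (must be
#'   in `[0, 1)`).
#' @param a,b,G Planted calibration (see [fret_calibration]).
#' @param donor_level,acceptor_level Unquenched donor / acceptor
#'   intensities per cell pixel, counts.
#' @param nfat_ratios Planted nucleus/cytosol ratios, recycled over cells.
#' @param cytosol_level Cytosol intensity above background, counts.
#' @param noise `"none"` or `"poisson"` (shot noise on every channel).
#' @param seed RNG seed.
#' @return Object of class `"image_spec"`.
#' @export
image_spec <- function(shape = c(96, 96), background = 50, n_cells = 3,
                       cell_radius = 10,
                       E_true = c(0.1, 0.3, 0.5),
                       a = 0.1, b = 0.5, G = 2.75,
                       donor_level = 1000, acceptor_level = 1000,
                       nfat_ratios = c(0.5, 1.0, 1.5),
                       cytosol_level = 200,
                       noise = c("none", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  stopifnot(all(E_true >= 0), all(E_true < 1), background >= 0,
            all(nfat_ratios > 0), G > 0, a >= 0, b >= 0)
  structure(as.list(environment()), class = "image_spec")
}

# disk footprints on a grid; errors if the cells cannot be placed
cell_footprints <- function(shape, n_cells, cell_radius, pad = 3) {
  step <- 2 * cell_radius + 2 * pad
  per_row <- max(1L, floor((shape[2] - pad) / step))
  labels <- matrix(0L, shape[1], shape[2])
  centers <- matrix(0, n_cells, 2)
  for (i in seq_len(n_cells)) {
    r0 <- pad + cell_radius + step * ((i - 1) %/% per_row)
    c0 <- pad + cell_radius + step * ((i - 1) %% per_row)
    if (r0 + cell_radius > shape[1] || c0 + cell_radius > shape[2])
      stop("cells do not fit in the image; enlarge shape or shrink cells")
    centers[i, ] <- c(r0, c0)
    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    labels[(rows - r0)^2 + (cols - c0)^2 <= cell_radius^2] <- i
  }
  list(labels = labels, centers = centers)
}

#' Synthesize a three-cube FRET image triple with known ground truth
#'
#' Inverse model of the apparent-efficiency equation: inside cell `i` the
#' noise-free channel intensities are `I_CFP = donor_level * (1 - E_i)`
#' (donor quenching), `I_YFP = acceptor_level`, and `I_FRET = a I_YFP +
#' b I_CFP + G E_i / (1 - E_i) * I_CFP` (bleed-through plus sensitized
#' emission), so background subtraction, gating and [fret_eapp] recover
#' `E_i` exactly in the noise-free case.
#'
#' @param spec An [image_spec].
#' @return List of class `"fret_image_set"`: `images` (list `cfp`, `yfp`,
#'   `fret`, raw counts including background), `labels` (cell label
#'   raster), `cal` (the planted [fret_calibration]), `truth` (data frame
#'   `cell`, `E_true`), `spec`.
#' @export
make_fret_images <- function(spec = image_spec()) {
  stopifnot(inherits(spec, "image_spec"))
  set.seed(spec$seed)
  fp <- cell_footprints(spec$shape, spec$n_cells, spec$cell_radius)
  E <- rep_len(spec$E_true, spec$n_cells)
  C <- matrix(0, spec$shape[1], spec$shape[2]); Y <- C; F_ <- C
  for (i in seq_len(spec$n_cells)) {
    inside <- fp$labels == i
    Ci <- spec$donor_level * (1 - E[i])
    Yi <- spec$acceptor_level
    Fi <- spec$a * Yi + spec$b * Ci + spec$G * E[i] / (1 - E[i]) * Ci
    C[inside] <- Ci; Y[inside] <- Yi; F_[inside] <- Fi
  }
  C <- C + spec$background
  Y <- Y + spec$background
  F_ <- F_ + spec$background
  if (spec$noise == "poisson") {
    C[] <- rpois(length(C), C)
    Y[] <- rpois(length(Y), Y)
    F_[] <- rpois(length(F_), F_)
  }
  structure(list(images = list(cfp = C, yfp = Y, fret = F_),
                 labels = fp$labels,
                 cal = fret_calibration(spec$a, spec$b, spec$G),
                 truth = data.frame(cell = seq_len(spec$n_cells),
                                    E_true = E),
                 spec = spec),
            class = "fret_image_set")
}

#' Per-cell mean gated efficiency of an [eapp_map]
#'
#' @param map An `"eapp_map"` (see [fret_eapp_map]).
#' @param labels Integer cell label raster (0 = background).
#' @param use_median Report medians instead of means.
#' @return Data frame `cell`, `eapp`, `n_pixels`.
#' @export
eapp_cell_means <- function(map, labels, use_median = FALSE) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  use <- map$valid & !is.na(map$eapp) & map$eapp >= 0
  do.call(rbind, lapply(ids, function(id) {
    px <- use & labels == id
    data.frame(cell = id,
               eapp = if (any(px)) {
                 if (use_median) stats::median(map$eapp[px])
                 else mean(map$eapp[px])
               } else NA_real_,
               n_pixels = sum(px))
  }))
}

#' Synthesize an NFAT translocation population with known categories
#'
#' Each cell is a disk footprint whose outer region (cytosol) sits at
#' `cytosol_level` above background and whose inner disk (nucleus, half
#' the radius) sits at `ratio * cytosol_level`, so the background-
#' subtracted nucleus/cytosol mean ratio equals the planted ratio exactly
#' in the noise-free case.
#'
#' @param spec An [image_spec]; `nfat_ratios` is recycled over cells.
#' @return List of class `"nfat_image_set"`: `image`, `nucleus_labels`,
#'   `cytosol_labels`, `truth` (data frame `cell`, `ratio`, `category`),
#'   `spec`.
#' @export
make_nfat_population <- function(spec = image_spec()) {
  stopifnot(inherits(spec, "image_spec"))
  set.seed(spec$seed)
  fp <- cell_footprints(spec$shape, spec$n_cells, spec$cell_radius)
  ratios <- rep_len(spec$nfat_ratios, spec$n_cells)
  img <- matrix(spec$background, spec$shape[1], spec$shape[2])
  nuc <- matrix(0L, spec$shape[1], spec$shape[2])
  cyt <- matrix(0L, spec$shape[1], spec$shape[2])
  rows <- matrix(seq_len(spec$shape[1]), spec$shape[1], spec$shape[2])
  cols <- matrix(seq_len(spec$shape[2]), spec$shape[1], spec$shape[2],
                 byrow = TRUE)
  for (i in seq_len(spec$n_cells)) {
    d2 <- (rows - fp$centers[i, 1])^2 + (cols - fp$centers[i, 2])^2
    inner <- d2 <= (spec$cell_radius / 2)^2
    outer <- d2 <= spec$cell_radius^2 & !inner
    img[outer] <- spec$background + spec$cytosol_level
    img[inner] <- spec$background + ratios[i] * spec$cytosol_level
    nuc[inner] <- i
    cyt[outer] <- i
  }
  if (spec$noise == "poisson") img[] <- rpois(length(img), img)
  truth <- data.frame(cell = seq_len(spec$n_cells), ratio = ratios,
                      category = nfat_classify(ratios, rep(1, length(ratios))))
  structure(list(image = img, nucleus_labels = nuc, cytosol_labels = cyt,
                 truth = truth, spec = spec),
            class = "nfat_image_set")
}
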