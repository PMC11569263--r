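#' Geometric pore center of a frame
#'
#' The pore center is the arithmetic mean position of a pore-defining
#' selection, by default the Calpha atoms of residues 80-110 (TM1, the
#' pore-lining helix of the hexamer).
#'
#' @param frame A [md_frame].
#' @param pore_selection A [selection_spec]; default Calpha 80-110, all
#'   subunits.
#' @return Numeric length-3 `(x, y, z)` in Angstrom.
#' @export
pore_center <- function(frame, pore_selection = selection_spec("TM1")) {
  colMeans(sel_coords(frame, pore_selection))
}

z_slice_centers <- function(z_range, dz) {
  zk <- seq(z_range[1] + dz / 2, z_range[2], by = dz)
  zk[zk <= z_range[2] - dz / 2 + 1e-9]
}

# largest probe sphere radius centred at (cx, cy, z_k) given candidate atoms:
# min_i ( ||(c, z_k) - x_i|| - r_vdw,i )
probe_radius_at <- function(cxy, zk, ax, ay, az, ar) {
  min(sqrt((cxy[1] - ax)^2 + (cxy[2] - ay)^2 + (zk - az)^2) - ar)
}

# maximize probe radius over the slice plane with deterministic Nelder-Mead;
# the search runs over the displacement from the seed so the initial simplex
# has a fixed absolute size regardless of the seed's coordinates
optimize_slice_center <- function(seed_xy, zk, ax, ay, az, ar) {
  fn <- function(d) -probe_radius_at(seed_xy + d, zk, ax, ay, az, ar)
  o <- optim(c(0, 0), fn, method = "Nelder-Mead",
             control = list(reltol = 1e-10, maxit = 2000))
  # restart once from the optimum: guards against premature simplex collapse
  fn2 <- function(d) -probe_radius_at(seed_xy + o$par + d, zk, ax, ay, az, ar)
  o2 <- optim(c(0, 0), fn2, method = "Nelder-Mead",
              control = list(reltol = 1e-10, maxit = 2000))
  ctr <- unname(seed_xy + o$par + o2$par)
  list(center = ctr, radius = -o2$value)
}

#' HOLE-style slice-wise maximal-sphere pore radius profile
#'
#' For each slice along the pore (z) axis, the pore radius is the radius of
#' the largest sphere centred in that slice that touches no atom's van der
#' Waals surface: `max over in-plane centers c of min over atoms i of
#' (||(c, z_k) - x_i|| - r_vdw,i)`. With `optimize_center = FALSE` the
#' center is fixed at the pore-center xy; with `TRUE` it is found by a
#' deterministic local optimizer seeded from the previous slice (first slice
#' from the pore-center xy). Negative radii (sterically blocked slices) are
#' reported as-is; slices with no protein atoms nearby are `NA`.
#'
#' @param frame A [md_frame].
#' @param z_range Length-2 numeric, slice range in Angstrom relative to the
#'   pore center z.
#' @param dz Slice thickness, Angstrom.
#' @param protein_selection [selection_spec] of the atoms forming the pore
#'   wall, or `NULL` for every non-water atom.
#' @param optimize_center Logical, see above.
#' @param pore_selection Selection defining the pore center.
#' @param margin Axial slack: atoms with `|z_i - z_k| <= r_vdw + margin`
#'   are considered for a slice (Angstrom).
#' @return Object of class `"pore_profile"` with fields `z` (slice centers,
#'   relative to pore-center z), `radius`, `center_xy` (per-slice optimized
#'   centers) and `pore_center`.
#' @export
pore_radius_profile <- function(frame, z_range = c(-20, 20), dz = 1.0,
                                protein_selection = NULL,
                                optimize_center = FALSE,
                                pore_selection = selection_spec("TM1"),
                                margin = 3.0) {
  stopifnot(dz > 0, length(z_range) == 2L, z_range[1] < z_range[2])
  ctr <- pore_center(frame, pore_selection)
  a <- if (is.null(protein_selection)) {
    frame$atoms[!is_water_oxygen(frame$atoms), , drop = FALSE]
  } else select_atoms(frame, protein_selection)
  if (!nrow(a)) stop("no protein atoms for pore profile")
  zk <- z_slice_centers(z_range, dz)
  radius <- rep(NA_real_, length(zk))
  cx <- rep(NA_real_, length(zk)); cy <- cx
  seed <- ctr[1:2]
  for (k in seq_along(zk)) {
    zabs <- ctr[3] + zk[k]
    near <- abs(a$z - zabs) <= a$vdw_radius + margin
    if (!any(near)) next
    ax <- a$x[near]; ay <- a$y[near]; az <- a$z[near]; ar <- a$vdw_radius[near]
    if (optimize_center) {
      o <- optimize_slice_center(seed, zabs, ax, ay, az, ar)
      radius[k] <- o$radius
      cx[k] <- o$center[1]; cy[k] <- o$center[2]
      seed <- o$center
    } else {
      radius[k] <- probe_radius_at(ctr[1:2], zabs, ax, ay, az, ar)
      cx[k] <- ctr[1]; cy[k] <- ctr[2]
    }
  }
  structure(list(z = zk, radius = radius,
                 center_xy = cbind(x = cx, y = cy),
                 pore_center = ctr, dz = dz),
            class = "pore_profile")
}

#' Replica-aggregated pore radius profile
#'
#' Computes [pore_radius_profile] for every frame of every replica inside a
#' time window, time-averages within replicas and reports the cross-replica
#' mean and standard deviation of the mean (sample SD across replica means
#' divided by sqrt of the replica count).
#'
#' @param trajs A [md_trajectory] or list of replicas.
#' @param window Length-2 time window in ns, or `NULL` for all frames.
#' @param last_ns Alternative window: final `last_ns` ns of each replica.
#' @param ... Passed to [pore_radius_profile].
#' @inheritParams pore_radius_profile
#' @return A `"pore_profile"` with `per_replica` (replica x slice matrix),
#'   `mean` and `sd_of_mean`.
#' @export
profile_over_trajectory <- function(trajs, window = NULL, last_ns = NULL,
                                    z_range = c(-20, 20), dz = 1.0, ...) {
  reps <- as_replica_list(trajs)
  reps <- lapply(reps, trajectory_window, window = window, last_ns = last_ns)
  zk <- z_slice_centers(z_range, dz)
  per <- t(vapply(reps, function(tr) {
    prof <- vapply(tr$frames, function(f)
      pore_radius_profile(f, z_range = z_range, dz = dz, ...)$radius,
      numeric(length(zk)))
    rowMeans(matrix(prof, nrow = length(zk)), na.rm = TRUE)
  }, numeric(length(zk))))
  per <- matrix(per, nrow = length(reps))
  m <- colMeans(per, na.rm = TRUE)
  sdm <- apply(per, 2, function(v) stats::sd(v) / sqrt(sum(!is.na(v))))
  if (length(reps) == 1L) sdm <- rep(0, length(m))
  structure(list(z = zk, per_replica = per, mean = m, sd_of_mean = sdm,
                 radius = m, n_replicas = length(reps), dz = dz),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  ok <- is.finite(x$radius)
  cat(sprintf("<pore_profile> %d slices (dz = %g A), radius %.2f..%.2f A%s\n",
              length(x$z), x$dz,
              if (any(ok)) min(x$radius[ok]) else NA,
              if (any(ok)) max(x$radius[ok]) else NA,
              if (!is.null(x$n_replicas))
                sprintf(", mean over %d replicas", x$n_replicas) else ""))
  invisible(x)
}
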