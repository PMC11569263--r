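#' Count water oxygens within a cutoff of a reference point
#'
#' Waters are identified by [water_oxygens]; the boundary is inclusive
#' (distance `<= cutoff`), fixed for determinism.
#'
#' @param frame A [md_frame].
#' @param reference Length-3 point, Angstrom.
#' @param cutoff Distance cutoff, Angstrom (`> 0`).
#' @return Integer count (0 when the frame holds no waters).
#' @export
count_waters_within <- function(frame, reference, cutoff) {
  stopifnot(cutoff > 0, length(reference) == 3L)
  w <- water_oxygens(frame)
  if (!nrow(w)) return(0L)
  d2 <- (w$x - reference[1])^2 + (w$y - reference[2])^2 +
        (w$z - reference[3])^2
  sum(d2 <= cutoff^2)
}

#' Axial water histogram inside a pore-centred cylinder
#'
#' Per frame, water oxygens whose xy-distance from the vertical axis through
#' the pore center is `<= cylinder_radius` are binned by z (relative to the
#' pore-center z). Counts are time-averaged within each replica; the
#' cross-replica mean and SD of the mean are reported. The conducting-pore
#' analysis uses a 10 Angstrom cylinder, the back-pore analysis 30 Angstrom.
#'
#' @param trajs A [md_trajectory] or list of replicas.
#' @param cylinder_radius Cylinder radius, Angstrom (`> 0`).
#' @param dz Bin width along z, Angstrom (`> 0`).
#' @param z_range Histogram extent relative to pore-center z, Angstrom.
#' @param window,last_ns Time window (ns), see [trajectory_window].
#' @param pore_selection Selection defining the pore center.
#' @return Object of class `"axial_profile"`: `bin_edges`,
#'   `per_replica_counts` (replica x bin, time-averaged waters per bin),
#'   `mean`, `sd_of_mean`.
#' @export
axial_water_histogram <- function(trajs, cylinder_radius = 10, dz = 1.0,
                                  z_range = c(-30, 30), window = NULL,
                                  last_ns = NULL,
                                  pore_selection = selection_spec("TM1")) {
  stopifnot(cylinder_radius > 0, dz > 0)
  reps <- as_replica_list(trajs)
  reps <- lapply(reps, trajectory_window, window = window, last_ns = last_ns)
  edges <- seq(z_range[1], z_range[2], by = dz)
  nb <- length(edges) - 1L
  per <- t(vapply(reps, function(tr) {
    acc <- numeric(nb)
    for (f in tr$frames)
      acc <- acc + frame_axial_counts(f, cylinder_radius, edges,
                                      pore_selection)
    acc / length(tr$frames)
  }, numeric(nb)))
  per <- matrix(per, nrow = length(reps))
  m <- colMeans(per)
  sdm <- if (length(reps) > 1L)
    apply(per, 2, stats::sd) / sqrt(length(reps)) else rep(0, nb)
  structure(list(bin_edges = edges, per_replica_counts = per,
                 mean = m, sd_of_mean = sdm,
                 cylinder_radius = cylinder_radius, unit = "waters"),
            class = "axial_profile")
}

#' Count water oxygens inside a pore-centred cylinder segment
#'
#' Companion to [axial_water_histogram]: the histogram's bin sum equals this
#' count exactly (same cylinder, same z extent relative to the pore center).
#'
#' @inheritParams axial_water_histogram
#' @param frame A [md_frame].
#' @return Integer count.
#' @export
count_waters_in_cylinder <- function(frame, cylinder_radius = 10,
                                     z_range = c(-30, 30),
                                     pore_selection = selection_spec("TM1")) {
  ctr <- pore_center(frame, pore_selection)
  w <- water_oxygens(frame)
  if (!nrow(w)) return(0L)
  zrel <- w$z - ctr[3]
  sum((w$x - ctr[1])^2 + (w$y - ctr[2])^2 <= cylinder_radius^2 &
      zrel >= z_range[1] & zrel <= z_range[2])
}

frame_axial_counts <- function(frame, cylinder_radius, edges, pore_selection) {
  ctr <- pore_center(frame, pore_selection)
  w <- water_oxygens(frame)
  if (!nrow(w)) return(numeric(length(edges) - 1L))
  inside <- (w$x - ctr[1])^2 + (w$y - ctr[2])^2 <= cylinder_radius^2
  zrel <- w$z[inside] - ctr[3]
  zrel <- zrel[zrel >= edges[1] & zrel <= edges[length(edges)]]
  if (!length(zrel)) return(numeric(length(edges) - 1L))
  # right-closed bins, lowest edge included
  tabulate(pmax(1L, findInterval(zrel, edges, rightmost.closed = TRUE)),
           nbins = length(edges) - 1L)
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf(
    "<axial_profile> %d bins of %g A, cylinder %g A, %d replica(s), total %.1f waters\n",
    length(x$mean), diff(x$bin_edges[1:2]), x$cylinder_radius,
    nrow(x$per_replica_counts), sum(x$mean)))
  invisible(x)
}

#' Solvation-shell water-count distribution around a residue atom
#'
#' For every frame and subunit, counts the water oxygens within `cutoff` of
#' the named atom of `residue` (default: 6 Angstrom around the Calpha of
#' residue 181, the TM3/TM4-interface position). Counts are pooled over
#' frames, subunits and replicas into a normalized distribution; the
#' per-channel mean (sum over the six subunit shells, averaged over frames
#' and replicas) is the headline hydration number. A water lying in two
#' shells is counted in both.
#'
#' @param trajs A [md_trajectory] or list of replicas.
#' @param residue Residue number.
#' @param atom_name Atom name, default `"CA"`.
#' @param cutoff Shell radius, Angstrom.
#' @param window,last_ns Time window (ns); the study uses the final 50 ns.
#' @param subunits Subunit ids, or `"all"`.
#' @return Object of class `"shell_count_distribution"`: `counts` (one per
#'   frame-subunit sample), `frequency` (named, sums to 1),
#'   `per_channel_mean`, `per_subunit_mean`, and the per-replica series.
#' @export
shell_count_distribution <- function(trajs, residue = 181, atom_name = "CA",
                                     cutoff = 6, window = NULL,
                                     last_ns = NULL, subunits = "all") {
  reps <- as_replica_list(trajs)
  reps <- lapply(reps, trajectory_window, window = window, last_ns = last_ns)
  spec <- selection_spec(residue, atom_name, subunits)
  counts <- list(); channel_sums <- numeric(0)
  series <- list()
  for (tr in reps) {
    refs0 <- select_atoms(tr$frames[[1]], spec)
    mat <- matrix(NA_integer_, length(tr$frames), nrow(refs0),
                  dimnames = list(NULL, refs0$subunit_id))
    for (i in seq_along(tr$frames)) {
      refs <- select_atoms(tr$frames[[i]], spec)
      mat[i, ] <- vapply(seq_len(nrow(refs)), function(j)
        count_waters_within(tr$frames[[i]],
                            c(refs$x[j], refs$y[j], refs$z[j]), cutoff),
        0L)
    }
    counts[[length(counts) + 1L]] <- as.vector(mat)
    channel_sums <- c(channel_sums, rowSums(mat))
    series[[length(series) + 1L]] <- mat
  }
  pooled <- unlist(counts)
  freq <- table(pooled) / length(pooled)
  structure(list(counts = pooled,
                 frequency = setNames(as.numeric(freq), names(freq)),
                 per_channel_mean = mean(channel_sums),
                 per_subunit_mean = mean(pooled),
                 per_replica = series,
                 residue = residue, atom_name = atom_name, cutoff = cutoff),
            class = "shell_count_distribution")
}

#' @export
print.shell_count_distribution <- function(x, ...) {
  cat(sprintf(
    "<shell_count_distribution> %s of residue %d, cutoff %g A: %d samples,\n  mean %.2f waters/shell, %.2f waters/channel\n",
    x$atom_name, x$residue, x$cutoff, length(x$counts),
    x$per_subunit_mean, x$per_channel_mean))
  invisible(x)
}
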