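cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

atom_xyz <- function(frame, residue, atom_name, subunit) {
  a <- select_atoms(frame, selection_spec(residue, atom_name, subunit))
  if (nrow(a) != 1L)
    stop("selection for residue ", residue, " ", atom_name, " in subunit ",
         subunit, " resolves to ", nrow(a), " atoms")
  c(a$x, a$y, a$z)
}

#' Projected side-chain rotation angle
#'
#' Angle between two vectors projected into the membrane (xy) plane, both
#' anchored at the residue's Calpha: the side-chain vector Calpha->Cgamma
#' and the pore vector Calpha->pore-center. 0 degrees means the side chain
#' points at the pore, 180 degrees away from it.
#'
#' @param frame A [md_frame].
#' @param residue Residue number (default 181).
#' @param subunit Subunit id.
#' @param pore_selection Selection defining the pore center.
#' @return Angle in degrees in `[0, 180]`, or `NA` when either projected
#'   vector is degenerate (length below 1e-6 Angstrom).
#' @export
rotation_angle <- function(frame, residue = 181, subunit = "A",
                           pore_selection = selection_spec("TM1")) {
  ca <- atom_xyz(frame, residue, "CA", subunit)
  cg <- atom_xyz(frame, residue, "CG", subunit)
  ctr <- pore_center(frame, pore_selection)
  u <- (cg - ca)[1:2]
  v <- (ctr - ca)[1:2]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-6 || nv < 1e-6) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# default charge-carrying moiety atom sets by residue type
moiety_presets <- list(
  LYS = "NZ",
  ARG = c("CZ", "NH1", "NH2", "NE"),
  GLU = c("CD", "OE1", "OE2"),
  ASP = c("CG", "OD1", "OD2")
)

#' In-plane distance of a charged moiety from the pore center
#'
#' xy-plane distance between the geometric center of the named atoms of a
#' residue (e.g. the lysine ammonium nitrogen NZ, the glutamate carboxyl
#' CD/OE1/OE2, or the arginine guanidinium CZ/NH1/NH2/NE) and the pore
#' center.
#'
#' @param frame A [md_frame].
#' @param atom_names Moiety atom names; `NULL` looks the set up by the
#'   residue's name in the built-in presets (LYS, ARG, GLU, ASP).
#' @param residue Residue number.
#' @param subunit Subunit id.
#' @param pore_selection Selection defining the pore center.
#' @return Distance in Angstrom.
#' @export
moiety_distance <- function(frame, atom_names = NULL, residue = 181,
                            subunit = "A",
                            pore_selection = selection_spec("TM1")) {
  if (is.null(atom_names)) {
    rn <- unique(select_atoms(frame,
      selection_spec(residue, "CA", subunit))$residue_name)
    atom_names <- moiety_presets[[rn]]
    if (is.null(atom_names))
      stop("no moiety preset for residue type ", rn,
           "; pass atom_names explicitly")
  }
  at <- select_atoms(frame, selection_spec(residue, atom_names, subunit))
  ctr <- pore_center(frame, pore_selection)
  cen <- colMeans(cbind(at$x, at$y))
  sqrt(sum((cen - ctr[1:2])^2))
}

#' Triangle area spanned by three residue atoms
#'
#' Full 3-D area `0.5 * ||(B - A) x (C - A)||` of the triangle formed by
#' one atom from each of three residues; the default triple (143, 177, 253)
#' tracks the TM2/TM3/TM4 packing at the peripheral helix interface.
#'
#' @param frame A [md_frame].
#' @param residues Integer triple.
#' @param atom Atom name, default `"CA"`.
#' @param subunit Subunit id.
#' @return Area in square Angstrom.
#' @export
triangle_area <- function(frame, residues = c(143, 177, 253), atom = "CA",
                          subunit = "A") {
  stopifnot(length(residues) == 3L)
  p <- lapply(residues, function(r) atom_xyz(frame, r, atom, subunit))
  0.5 * sqrt(sum(cross3(p[[2]] - p[[1]], p[[3]] - p[[1]])^2))
}

#' Signed torsion (dihedral) angle of four points
#'
#' IUPAC convention: cis = 0, trans = 180, positive for a right-handed
#' (clockwise, viewed from the first toward the fourth atom) twist.
#'
#' @param p1,p2,p3,p4 Length-3 points.
#' @return Angle in degrees in `(-180, 180]`, `NA` on degenerate geometry.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) return(NA_real_)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# optimal rotation (no reflection) mapping mobile onto ref, both n x 3
kabsch_fit <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, center_mobile = cm, center_ref = cr)
}

kabsch_apply <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$center_mobile) %*% t(fit$rotation),
        2, fit$center_ref, `+`)
}

rmsd_coords <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD after optimal rigid-body superposition
#'
#' Fits the `fit_selection` atoms of `mobile` onto those of `reference` by
#' the optimal rotation + translation (Kabsch, SVD-based, reflections
#' excluded), then measures the RMSD over `measure_selection` after
#' applying that transform. The default measures over the fitted atoms,
#' e.g. per-TM Calpha RMSD against a reference structure.
#'
#' @param mobile,reference [md_frame] objects with matching selections
#'   (equal atom counts, identical ordering).
#' @param fit_selection [selection_spec] used for the superposition
#'   (default: Calpha of TM1).
#' @param measure_selection Selection the RMSD is computed over; default
#'   `fit_selection`.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(mobile, reference,
                        fit_selection = selection_spec("TM1"),
                        measure_selection = fit_selection) {
  fm <- sel_coords(mobile, fit_selection)
  fr <- sel_coords(reference, fit_selection)
  if (nrow(fm) != nrow(fr))
    stop("fit selection resolves to ", nrow(fm), " atoms in mobile but ",
         nrow(fr), " in reference")
  if (nrow(fm) < 3L) stop("need at least 3 atoms to superpose")
  fit <- kabsch_fit(fm, fr)
  mm <- sel_coords(mobile, measure_selection)
  mr <- sel_coords(reference, measure_selection)
  if (nrow(mm) != nrow(mr)) stop("measure selection count mismatch")
  rmsd_coords(kabsch_apply(mm, fit), mr)
}

#' Per-frame, per-subunit descriptor series over trajectories
#'
#' Evaluates one of the scalar conformational descriptors on every frame
#' and subunit of one or more replicas, returning the per-replica series
#' and a pooled normalized histogram of all values.
#'
#' @param trajs A [md_trajectory] or list of replicas.
#' @param metric `"rotation_angle"`, `"moiety_distance"` or
#'   `"triangle_area"`.
#' @param window,last_ns Time window in ns.
#' @param subunits Subunit ids, or `"all"` for every subunit carrying the
#'   required atoms.
#' @param bin_width Histogram bin width (degrees for angles: default 5;
#'   otherwise 1 unit).
#' @param ... Passed to the metric function (`residue`, `atom_names`,
#'   `residues`, ...).
#' @return List of class `"descriptor_series"`: `series` (one
#'   [scalar_series] per replica), `values` (pooled), `histogram`
#'   (`mids`, `density` summing to 1), `metric`, `unit`.
#' @export
series_over_trajectory <- function(trajs,
                                   metric = c("rotation_angle",
                                              "moiety_distance",
                                              "triangle_area"),
                                   window = NULL, last_ns = NULL,
                                   subunits = "all", bin_width = NULL, ...) {
  metric <- match.arg(metric)
  reps <- as_replica_list(trajs)
  reps <- lapply(reps, trajectory_window, window = window, last_ns = last_ns)
  unit <- switch(metric, rotation_angle = "deg",
                 moiety_distance = "A", triangle_area = "A^2")
  if (is.null(bin_width)) bin_width <- if (unit == "deg") 5 else 1
  fn <- switch(metric,
    rotation_angle = function(f, s, ...) rotation_angle(f, subunit = s, ...),
    moiety_distance = function(f, s, ...) moiety_distance(f, subunit = s, ...),
    triangle_area = function(f, s, ...) triangle_area(f, subunit = s, ...))
  if (identical(subunits, "all")) {
    args <- list(...)
    res <- if (!is.null(args[["residue"]])) args[["residue"]] else
           if (!is.null(args[["residues"]])) args[["residues"]][1] else 181
    subunits <- sort(unique(select_atoms(reps[[1]]$frames[[1]],
      selection_spec(res, "CA"))$subunit_id))
  }
  series <- lapply(reps, function(tr) {
    vals <- matrix(NA_real_, length(tr$frames), length(subunits),
                   dimnames = list(NULL, subunits))
    for (i in seq_along(tr$frames))
      for (j in seq_along(subunits))
        vals[i, j] <- fn(tr$frames[[i]], subunits[j], ...)
    scalar_series(frame_times(tr), subunits, vals, unit = unit,
                  metric = metric)
  })
  pooled <- unlist(lapply(series, function(s) as.vector(s$values)))
  pooled <- pooled[!is.na(pooled)]
  lo <- floor(min(pooled) / bin_width) * bin_width
  hi <- ceiling(max(pooled) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  h <- graphics::hist(pooled, breaks = seq(lo, hi, by = bin_width),
                      plot = FALSE)
  structure(list(series = series, values = pooled,
                 histogram = list(mids = h$mids,
                                  density = h$counts / length(pooled),
                                  bin_width = bin_width),
                 metric = metric, unit = unit),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat(sprintf("<descriptor_series> %s [%s]: %d replicas, %d pooled values, mean %.2f\n",
              x$metric, x$unit, length(x$series), length(x$values),
              mean(x$values)))
  invisible(x)
}

# circular mean of angles given in degrees
circular_mean_deg <- function(x) {
  a <- x * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
}
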