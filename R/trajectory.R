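# Bondi-type van der Waals radii (Angstrom), overridable in read_structure()
vdw_radii_default <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                       S = 1.80, P = 1.80)

water_resnames <- c("HOH", "SOL", "TIP3", "WAT")
water_o_names  <- c("O", "OW", "OH2")

#' Construct a single trajectory frame
#'
#' A frame holds an ordered atom table plus a time stamp. Atom order is the
#' identity used to match atoms across frames; it is never re-sorted.
#'
#' @param atoms Data frame with columns `serial`, `atom_name`, `element`,
#'   `residue_name`, `residue_number`, `subunit_id`, `x`, `y`, `z`,
#'   `vdw_radius` (Angstrom).
#' @param time Time stamp in ns (`>= 0`).
#' @param box Optional length-3 box vector, Angstrom.
#' @return Object of class `"md_frame"`.
#' @export
md_frame <- function(atoms, time = 0, box = NULL) {
  req <- c("serial", "atom_name", "element", "residue_name",
           "residue_number", "subunit_id", "x", "y", "z", "vdw_radius")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!is.na(atoms$vdw_radius) & atoms$vdw_radius <= 0))
    stop("vdw_radius must be > 0")
  stopifnot(is.numeric(time), time >= 0)
  atoms$serial <- as.integer(atoms$serial)
  atoms$residue_number <- as.integer(atoms$residue_number)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, time = as.numeric(time), box = box),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  nw <- sum(is_water_oxygen(x$atoms))
  cat(sprintf("<md_frame> %d atoms (%d water oxygens), t = %g ns\n",
              nrow(x$atoms), nw, x$time))
  invisible(x)
}

#' Construct a trajectory from frames
#'
#' All frames must share atom count and atom ordering (checked on names and
#' residue numbers); frame times must be strictly increasing.
#'
#' @param frames List of [md_frame] objects.
#' @param replica_id Integer replica label.
#' @return Object of class `"md_trajectory"`.
#' @export
md_trajectory <- function(frames, replica_id = 1L) {
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, TRUE, "md_frame")))
  n <- vapply(frames, function(f) nrow(f$atoms), 0L)
  if (length(unique(n)) != 1L)
    stop("frames differ in atom count")
  key <- function(f) paste(f$atoms$atom_name, f$atoms$residue_number,
                           f$atoms$subunit_id)
  k1 <- key(frames[[1]])
  for (f in frames[-1])
    if (!identical(key(f), k1)) stop("frames differ in atom ordering")
  tt <- vapply(frames, `[[`, 0, "time")
  if (any(diff(tt) <= 0)) stop("frame times must be strictly increasing")
  structure(list(frames = frames, replica_id = as.integer(replica_id)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  tt <- frame_times(x)
  cat(sprintf("<md_trajectory> replica %d: %d frames, %d atoms, t = %g..%g ns\n",
              x$replica_id, length(x$frames), nrow(x$frames[[1]]$atoms),
              min(tt), max(tt)))
  invisible(x)
}

#' @export
length.md_trajectory <- function(x) length(x$frames)

#' Frame times of a trajectory (ns)
#' @param traj A [md_trajectory].
#' @export
frame_times <- function(traj) vapply(traj$frames, `[[`, 0, "time")

#' Subset a trajectory to a time window
#'
#' @param traj A [md_trajectory].
#' @param window Length-2 numeric `c(from, to)` in ns (inclusive), or `NULL`
#'   for all frames.
#' @param last_ns Alternatively, keep the final `last_ns` ns of the
#'   trajectory (inclusive of the boundary).
#' @return A [md_trajectory] restricted to the window.
#' @export
trajectory_window <- function(traj, window = NULL, last_ns = NULL) {
  tt <- frame_times(traj)
  if (!is.null(last_ns)) window <- c(max(tt) - last_ns, max(tt))
  if (is.null(window)) return(traj)
  keep <- tt >= window[1] & tt <= window[2]
  if (!any(keep)) stop("empty time window [", window[1], ", ", window[2], "] ns")
  md_trajectory(traj$frames[keep], traj$replica_id)
}

# accept a single trajectory or a list of replicas; always return a list
as_replica_list <- function(trajs) {
  if (inherits(trajs, "md_trajectory")) return(list(trajs))
  stopifnot(length(trajs) >= 1L,
            all(vapply(trajs, inherits, TRUE, "md_trajectory")))
  trajs
}

is_water_oxygen <- function(atoms) {
  atoms$residue_name %in% water_resnames & atoms$atom_name %in% water_o_names
}

#' Water oxygen atoms of a frame
#'
#' Waters are recognized by residue name (HOH, SOL, TIP3, WAT) and oxygen
#' atom name (O, OW, OH2); hydrogens are never required.
#'
#' @param frame A [md_frame].
#' @return Data frame of water-oxygen atom records (possibly 0 rows).
#' @export
water_oxygens <- function(frame) {
  frame$atoms[is_water_oxygen(frame$atoms), , drop = FALSE]
}

# element symbol from a PDB atom name when the element column is absent;
# digits strip (e.g. "1HB" -> H), two-letter water names handled upstream
infer_element <- function(atom_name) {
  s <- sub("^[0-9]*", "", atom_name)
  toupper(substr(s, 1, 1))
}

assign_vdw <- function(element, vdw_table) {
  r <- unname(vdw_table[element])
  bad <- is.na(r)
  if (any(bad))
    stop("unknown element(s) with no vdW radius: ",
         paste(unique(element[bad]), collapse = ", "))
  r
}

#' Read a structure or trajectory from PDB or XYZ
#'
#' Multi-MODEL PDB files become multi-frame trajectories (fixed-column v3.3
#' dialect; the chain id column carries the subunit id). XYZ files carry
#' only element symbols and coordinates; atom names are set to the element,
#' residue numbers to the atom index and the subunit to `"A"`.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param vdw Named element-to-radius table (Angstrom) used to assign
#'   `vdw_radius`; defaults to a Bondi-type table (C 1.70, N 1.55, O 1.52,
#'   S 1.80, H 1.20, P 1.80).
#' @param dt,t0 Frame spacing and first-frame time in ns (coordinate files
#'   carry no time stamps).
#' @return A [md_trajectory].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           vdw = vdw_radii_default, dt = 1, t0 = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "pdb") read_pdb_trajectory(path, vdw, dt, t0)
  else read_xyz_trajectory(path, vdw, dt, t0)
}

read_pdb_trajectory <- function(path, vdw, dt, t0) {
  lines <- readLines(path, warn = FALSE)
  at <- grep("^(ATOM  |HETATM)", lines)
  if (!length(at)) stop("no ATOM/HETATM records in ", path)
  for (i in at) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54)))))
    if (!ok) stop("malformed PDB coordinate record at line ", i, ": ", ln)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  elem <- trimws(as.character(a$elesy))
  blank <- is.na(elem) | elem == ""
  elem[blank] <- infer_element(a$elety[blank])
  atoms0 <- data.frame(
    serial = a$eleno,
    atom_name = a$elety,
    element = elem,
    residue_name = a$resid,
    residue_number = a$resno,
    subunit_id = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    x = 0, y = 0, z = 0,
    vdw_radius = assign_vdw(elem, vdw),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(k) {
    m <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    f <- atoms0
    f$x <- m[, 1]; f$y <- m[, 2]; f$z <- m[, 3]
    md_frame(f, time = t0 + dt * (k - 1))
  })
  md_trajectory(frames)
}

read_xyz_trajectory <- function(path, vdw, dt, t0) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("malformed XYZ atom-count record at line ", i, ": ", lines[i])
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(parts, length, 0L) < 4L)
    if (length(bad))
      stop("malformed XYZ atom record at line ", i + 1L + bad[1])
    el <- toupper(vapply(parts, `[`, "", 1))
    co <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
    if (anyNA(co)) stop("non-numeric XYZ coordinates near line ", i)
    atoms <- data.frame(
      serial = seq_len(n), atom_name = el, element = el,
      residue_name = "UNK", residue_number = seq_len(n), subunit_id = "A",
      x = co[1, ], y = co[2, ], z = co[3, ],
      vdw_radius = assign_vdw(el, vdw), stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <-
      md_frame(atoms, time = t0 + dt * length(frames))
    i <- i + 2L + n
  }
  md_trajectory(frames)
}

#' Write a frame or trajectory to a PDB file
#'
#' Fixed-column v3.3 PDB; one MODEL block per frame; the chain id column
#' carries the subunit id. Coordinates are written at 1e-3 Angstrom
#' precision (the format's fixed width).
#'
#' @param x A [md_frame] or [md_trajectory].
#' @param path Output file.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "md_frame")) x <- md_trajectory(list(x))
  stopifnot(inherits(x, "md_trajectory"))
  a <- x$frames[[1]]$atoms
  xyz <- t(vapply(x$frames,
                  function(f) as.numeric(t(cbind(f$atoms$x, f$atoms$y, f$atoms$z))),
                  numeric(3L * nrow(a))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   eleno = a$serial, elety = a$atom_name,
                   resid = a$residue_name, resno = a$residue_number,
                   chain = substr(a$subunit_id, 1, 1),
                   elesy = a$element)
  invisible(path)
}
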