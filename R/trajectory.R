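# Trajectory analysis: readers for standard coordinate formats, atom
# selection, least-squares superposition, swing-angle series with two-state
# transition detection, 3D occupancy maps and visited volume, ligand
# center-of-mass displacement / orientation, and pairwise distances with
# contact-lifetime statistics.

new_trajectory <- function(times, xyz, atoms) {
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[3] == 3,
            dim(xyz)[1] == length(times), dim(xyz)[2] == nrow(atoms))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(times = times, xyz = xyz, atoms = atoms,
                 dt = if (length(times) > 1) times[2] - times[1] else NA_real_),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.4g..%.4g ns\n",
              dim(x$xyz)[1], dim(x$xyz)[2], min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' Read a trajectory from standard coordinate formats
#'
#' Supports multi-frame XYZ (plain text), PDB (single- or multi-model, read
#' through bio3d) and DCD binary frames with a PDB topology (bio3d). Atom
#' metadata (names, residue numbers/names) comes from the topology when one
#' is given, else from the coordinate file itself.
#'
#' @param coords_path Coordinate file (.xyz, .pdb or .dcd).
#' @param topology_path Optional PDB topology (required for DCD).
#' @param dt Frame interval in ns, used when the file carries no times
#'   (XYZ comment fields `t=<ns>` take precedence).
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(coords_path, topology_path = NULL, dt = 0.24) {
  ext <- tolower(tools::file_ext(coords_path))
  top <- if (!is.null(topology_path)) {
    p <- bio3d::read.pdb(topology_path)
    data.frame(elety = p$atom$elety, resid = p$atom$resid,
               resno = p$atom$resno, stringsAsFactors = FALSE)
  }
  if (ext == "xyz") {
    tr <- read_xyz_frames(coords_path, dt = dt)
    atoms <- top %||% data.frame(elety = tr$names, resid = "MOL", resno = 1L,
                                 stringsAsFactors = FALSE)
    if (nrow(atoms) != dim(tr$xyz)[2])
      stop("format error: topology has ", nrow(atoms), " atoms but frames have ",
           dim(tr$xyz)[2])
    new_trajectory(tr$times, tr$xyz, atoms)
  } else if (ext == "pdb") {
    p <- bio3d::read.pdb(coords_path, multi = TRUE)
    nat <- nrow(p$atom)
    nf <- nrow(p$xyz)
    xyz <- aperm(array(t(p$xyz), c(3, nat, nf)), c(3, 2, 1))
    atoms <- data.frame(elety = p$atom$elety, resid = p$atom$resid,
                        resno = p$atom$resno, stringsAsFactors = FALSE)
    new_trajectory(dt * (seq_len(nf) - 1), xyz, atoms)
  } else if (ext == "dcd") {
    if (is.null(top)) stop("a PDB topology is required to read DCD frames")
    m <- bio3d::read.dcd(coords_path, verbose = FALSE)
    nf <- nrow(m)
    if (ncol(m) != 3 * nrow(top))
      stop("format error: topology has ", nrow(top), " atoms but DCD frames have ",
           ncol(m) / 3)
    xyz <- aperm(array(t(m), c(3, nrow(top), nf)), c(3, 2, 1))
    new_trajectory(dt * (seq_len(nf) - 1), xyz, top)
  } else stop("unsupported trajectory format: .", ext)
}

# Multi-frame XYZ: per frame a line with the atom count, a comment line
# (optionally containing `t=<ns>`), then `name x y z` records.
read_xyz_frames <- function(path, dt = 0.24) {
  txt <- readLines(path, warn = FALSE)
  i <- 1L; frames <- list(); times <- numeric(0); nms <- NULL; nf <- 0L
  while (i <= length(txt)) {
    if (!nzchar(trimws(txt[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(txt[i])))
    if (is.na(nat)) stop("format error: expected an atom count at line ", i)
    if (i + 1L + nat > length(txt))
      stop("format error: truncated frame ", nf + 1L, " at line ", i)
    comment <- txt[i + 1L]
    nf <- nf + 1L
    tm <- regmatches(comment, regexec("t=([0-9eE+.-]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else
      (nf - 1L) * dt)
    rec <- strsplit(trimws(txt[(i + 2L):(i + 1L + nat)]), "\\s+")
    if (any(lengths(rec) < 4))
      stop("format error: malformed coordinate record in frame ", nf)
    if (is.null(nms)) nms <- vapply(rec, `[`, "", 1)
    frames[[nf]] <- matrix(as.numeric(unlist(lapply(rec, `[`, 2:4))),
                           ncol = 3, byrow = TRUE)
    i <- i + 2L + nat
  }
  nat <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 0L) != nat))
    stop("format error: atom count varies across frames")
  xyz <- array(0, c(nf, nat, 3))
  for (k in seq_len(nf)) xyz[k, , ] <- frames[[k]]
  list(times = times, xyz = xyz, names = nms)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nat <- dim(traj$xyz)[2]
  for (k in seq_len(n_frames(traj))) {
    writeLines(c(as.character(nat),
                 sprintf("frame %d t=%.6g", k, traj$times[k])), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$elety,
                       traj$xyz[k, , 1], traj$xyz[k, , 2], traj$xyz[k, , 3]),
               con)
  }
  invisible(path)
}

#' Select atom indices by name / residue
#'
#' @param traj An `md_trajectory`.
#' @param elety Atom name(s) (e.g. `"CA"`), or `NULL` for any.
#' @param resid Residue name(s), or `NULL`.
#' @param resno Residue number(s), or `NULL`.
#' @return Integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(traj, elety = NULL, resid = NULL, resno = NULL) {
  keep <- rep(TRUE, nrow(traj$atoms))
  if (!is.null(elety)) keep <- keep & traj$atoms$elety %in% elety
  if (!is.null(resid)) keep <- keep & traj$atoms$resid %in% resid
  if (!is.null(resno)) keep <- keep & traj$atoms$resno %in% resno
  which(keep)
}

# Optimal rotation (Kabsch, via 3x3 SVD): returns R minimizing ||P R - Q||
# for centered row-vector coordinate matrices P, Q (n x 3).
kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Superpose every frame onto the reference frame using the alignment atoms;
# returns the trajectory with all atoms transformed.
superpose_frames <- function(traj, ref_xyz, align_ix) {
  out <- traj$xyz
  refA <- ref_xyz[align_ix, , drop = FALSE]
  ref_ctr <- colMeans(refA)
  refC <- sweep(refA, 2, ref_ctr)
  for (k in seq_len(n_frames(traj))) {
    mob <- out[k, , ]
    mobA <- mob[align_ix, , drop = FALSE]
    ctr <- colMeans(mobA)
    R <- kabsch_rotation(sweep(mobA, 2, ctr), refC)
    out[k, , ] <- sweep(sweep(mob, 2, ctr) %*% R, 2, ref_ctr, `+`)
  }
  traj$xyz <- out
  traj
}

new_swing_series <- function(times, theta, reference = "reference") {
  stopifnot(length(times) == length(theta))
  if (any(theta < -1e-9 | theta > 180 + 1e-9))
    stop("swing angles must lie in [0, 180] degrees")
  structure(list(times = times, theta = theta, reference = reference,
                 states = NULL, transitions = NULL, rate = NULL),
            class = "swing_series")
}

#' Construct a swing-angle series from raw angles
#'
#' @param times Frame times (ns), strictly increasing.
#' @param theta Angles in degrees, within \[0, 180\].
#' @param reference Label of the reference structure.
#' @return A `swing_series`.
#' @export
swing_series <- function(times, theta, reference = "reference")
  new_swing_series(times, theta, reference)

#' @export
print.swing_series <- function(x, ...) {
  cat(sprintf("Swing-angle series: %d frames, theta = %.1f..%.1f deg\n",
              length(x$theta), min(x$theta), max(x$theta)))
  if (!is.null(x$rate))
    cat(sprintf("  %d transitions, rate %.3g +/- %.3g /us\n",
                nrow(x$transitions), x$rate, x$rate_se))
  invisible(x)
}

#' Side-chain swing angle against a reference structure
#'
#' After least-squares superposition of the alignment atoms of every frame
#' onto the reference (skipped when `align = NULL`, e.g. for trajectories
#' generated in the reference frame), the swing angle of a residue is the
#' angle between its side-chain vector (`vec_atoms[1]` to `vec_atoms[2]`,
#' by default C-alpha to the guanidinium carbon CZ) in the frame and the same
#' vector in the reference.
#'
#' @param traj An `md_trajectory`.
#' @param reference Reference structure: an `md_trajectory` (first frame used).
#' @param resno Residue number of the swinging residue.
#' @param vec_atoms Length-2 atom names defining the side-chain vector.
#' @param align Atom indices (in both trajectory and reference) used for the
#'   rigid superposition, or `NULL` for none.
#' @return A `swing_series`.
#' @export
swing_angle <- function(traj, reference, resno,
                        vec_atoms = c("CA", "CZ"), align = NULL) {
  ref_xyz <- reference$xyz[1, , ]
  pick <- function(tr, nm) {
    ix <- select_atoms(tr, elety = nm, resno = resno)
    if (length(ix) != 1)
      stop("selection error: atom ", nm, " of residue ", resno,
           " resolves to ", length(ix), " atoms")
    ix
  }
  ia <- pick(traj, vec_atoms[1]); ib <- pick(traj, vec_atoms[2])
  ra <- pick(reference, vec_atoms[1]); rb <- pick(reference, vec_atoms[2])
  if (!is.null(align)) traj <- superpose_frames(traj, ref_xyz, align)
  vref <- ref_xyz[rb, ] - ref_xyz[ra, ]
  v <- traj$xyz[, ib, , drop = FALSE] - traj$xyz[, ia, , drop = FALSE]
  v <- matrix(v, ncol = 3)
  cosang <- (v %*% vref) / (sqrt(rowSums(v^2)) * sqrt(sum(vref^2)))
  theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  new_swing_series(traj$times, as.numeric(theta))
}

#' Two-state assignment and transition-rate estimate
#'
#' Assigns internal/external states by two-threshold hysteresis: the state
#' switches to internal only when theta drops below `theta_internal` and to
#' external only when it rises above `theta_external`; frames in between keep
#' the previous state (label "intermediate" until the first committed state).
#' Dwells shorter than `min_dwell` are discarded as chatter. The transition
#' rate is the number of surviving transitions divided by the total time,
#' reported per microsecond with a Poisson standard error `sqrt(n)/T`.
#'
#' @param series A `swing_series`.
#' @param theta_internal Internal threshold (deg).
#' @param theta_external External threshold (deg); must exceed
#'   `theta_internal`.
#' @param min_dwell Minimum dwell time (ns).
#' @return The series with `states`, `transitions` (data frame: time,
#'   direction), `rate` and `rate_se` (per us) filled in.
#' @export
detect_transitions <- function(series, theta_internal = 60,
                               theta_external = 100, min_dwell = 5) {
  if (theta_internal >= theta_external)
    stop("parameter error: theta_internal must be below theta_external")
  th <- series$theta
  n <- length(th)
  cand <- ifelse(th < theta_internal, 1L, ifelse(th > theta_external, 2L, 0L))
  states <- integer(n)
  cur <- 0L
  for (k in seq_len(n)) {
    if (cand[k] != 0L) cur <- cand[k]
    states[k] <- cur
  }
  # run-length segments of committed states; drop dwells below min_dwell by
  # merging them into the preceding state
  seg <- rle(states)
  keep_states <- seg$values
  keep_len <- seg$lengths
  dtv <- diff(series$times)
  dt <- if (length(dtv)) stats::median(dtv) else NA_real_
  merged <- list(values = integer(0), lengths = integer(0))
  for (i in seq_along(keep_states)) {
    dur <- keep_len[i] * dt
    prev <- length(merged$values)
    if (keep_states[i] != 0L && prev > 0 && !is.na(dur) && dur < min_dwell &&
        merged$values[prev] != 0L) {
      merged$lengths[prev] <- merged$lengths[prev] + keep_len[i]
    } else if (prev > 0 && merged$values[prev] == keep_states[i]) {
      merged$lengths[prev] <- merged$lengths[prev] + keep_len[i]
    } else {
      merged$values <- c(merged$values, keep_states[i])
      merged$lengths <- c(merged$lengths, keep_len[i])
    }
  }
  # consolidate equal neighbours created by the dwell filter
  final <- rle(rep(merged$values, merged$lengths))
  ends <- cumsum(final$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  committed <- final$values != 0L
  tr_time <- numeric(0); tr_dir <- character(0)
  last_state <- 0L
  for (i in seq_along(final$values)) {
    st <- final$values[i]
    if (st == 0L) next
    if (last_state != 0L && st != last_state) {
      tr_time <- c(tr_time, series$times[starts[i]])
      tr_dir <- c(tr_dir, if (st == 1L) "to_internal" else "to_external")
    }
    last_state <- st
  }
  total_ns <- diff(range(series$times))
  n_tr <- length(tr_time)
  series$states <- c("intermediate", "internal", "external")[
    rep(final$values, final$lengths) + 1L]
  series$transitions <- data.frame(time = tr_time, direction = tr_dir,
                                   stringsAsFactors = FALSE)
  series$rate <- if (total_ns > 0) n_tr / total_ns * 1e3 else NA_real_ # per us
  series$rate_se <- if (total_ns > 0) sqrt(n_tr) / total_ns * 1e3 else NA_real_
  series$thresholds <- c(internal = theta_internal, external = theta_external,
                         min_dwell = min_dwell)
  series
}

#' 3D occupancy map of an atom selection
#'
#' Voxelizes space around the selection and records, per voxel, the fraction
#' of frames in which any selected atom (rasterized as a sphere of `radius`;
#' 0 treats atoms as points) covers the voxel center.
#'
#' @param traj An `md_trajectory` (already aligned to a common reference).
#' @param sel Atom indices.
#' @param voxel_size Voxel edge length (A).
#' @param radius Rasterization radius (A); default 1.9, a typical van der
#'   Waals radius for side-chain heavy atoms.
#' @param margin Extra margin around the selection's bounding box (A).
#' @return An `occupancy_grid`: `origin`, `voxel_size`, `dims`, and an array
#'   `occupancy` with values in \[0, 1\].
#' @export
occupancy_map <- function(traj, sel, voxel_size = 1.0, radius = 1.9,
                          margin = NULL) {
  if (voxel_size <= 0) stop("parameter error: voxel_size must be positive")
  if (!length(sel)) stop("selection error: empty atom selection")
  if (is.null(margin)) margin <- radius + voxel_size
  nf <- n_frames(traj)
  xs <- traj$xyz[, sel, 1, drop = FALSE]
  ys <- traj$xyz[, sel, 2, drop = FALSE]
  zs <- traj$xyz[, sel, 3, drop = FALSE]
  lo <- c(min(xs), min(ys), min(zs)) - margin
  hi <- c(max(xs), max(ys), max(zs)) + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size)))
  counts <- array(0L, dims)
  if (radius <= 0) {
    vx <- pmin(dims[1], pmax(1L, floor((xs - lo[1]) / voxel_size) + 1L))
    vy <- pmin(dims[2], pmax(1L, floor((ys - lo[2]) / voxel_size) + 1L))
    vz <- pmin(dims[3], pmax(1L, floor((zs - lo[3]) / voxel_size) + 1L))
    lin <- matrix(vx + (vy - 1L) * dims[1] + (vz - 1L) * dims[1] * dims[2],
                  nrow = nf)
    for (k in seq_len(nf)) {
      ids <- unique(lin[k, ])
      counts[ids] <- counts[ids] + 1L
    }
  } else {
    cx <- lo[1] + (seq_len(dims[1]) - 0.5) * voxel_size
    cy <- lo[2] + (seq_len(dims[2]) - 0.5) * voxel_size
    cz <- lo[3] + (seq_len(dims[3]) - 0.5) * voxel_size
    for (k in seq_len(nf)) {
      covered <- integer(0)
      for (j in seq_along(sel)) {
        p <- c(xs[k, j, 1], ys[k, j, 1], zs[k, j, 1])
        ix <- which(abs(cx - p[1]) <= radius)
        iy <- which(abs(cy - p[2]) <= radius)
        iz <- which(abs(cz - p[3]) <= radius)
        if (!length(ix) || !length(iy) || !length(iz)) next
        gx <- rep(cx[ix], length(iy) * length(iz))
        gy <- rep(rep(cy[iy], each = length(ix)), length(iz))
        gz <- rep(cz[iz], each = length(ix) * length(iy))
        ok <- (gx - p[1])^2 + (gy - p[2])^2 + (gz - p[3])^2 <= radius^2
        if (!any(ok)) next
        lin <- (rep(ix, length(iy) * length(iz)))[ok] +
          (rep(rep(iy, each = length(ix)), length(iz))[ok] - 1L) * dims[1] +
          (rep(iz, each = length(ix) * length(iy))[ok] - 1L) * dims[1] * dims[2]
        covered <- c(covered, lin)
      }
      ids <- unique(covered)
      counts[ids] <- counts[ids] + 1L
    }
  }
  structure(list(origin = lo, voxel_size = voxel_size, dims = dims,
                 occupancy = counts / nf, n_frames = nf),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("Occupancy grid: %d x %d x %d voxels of %.2f A (%d frames)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size, x$n_frames))
  invisible(x)
}

#' Visited volume above an occupancy threshold
#'
#' The total volume of space visited by the selection: the number of voxels
#' whose occupancy fraction reaches `threshold`, times the voxel volume.
#' `threshold = 0.01` corresponds to the conventional 1% occupancy isosurface.
#'
#' @param grid An `occupancy_grid`.
#' @param threshold Occupancy fraction in (0, 1].
#' @return Volume in A^3.
#' @export
visited_volume <- function(grid, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  sum(grid$occupancy >= threshold) * grid$voxel_size^3
}

#' Ligand center-of-mass displacement and orientation series
#'
#' After optional superposition of each frame onto the reference using the
#' alignment atoms (e.g. the protein backbone), reports per frame the
#' displacement of the selection's center of mass from its reference position
#' and the rotation angle of the optimal superposition of the (centered)
#' selection onto its reference pose.
#'
#' @param traj An `md_trajectory`.
#' @param sel Atom indices of the ligand.
#' @param reference Reference `md_trajectory` (first frame used).
#' @param align Alignment atom indices, or `NULL`.
#' @return Data frame with `time`, `displacement` (A) and `orientation` (deg).
#' @export
com_orientation <- function(traj, sel, reference, align = NULL) {
  if (length(sel) < 3)
    stop("selection error: need at least 3 atoms to define an orientation")
  ref_xyz <- reference$xyz[1, , ]
  if (!is.null(align)) traj <- superpose_frames(traj, ref_xyz, align)
  refL <- ref_xyz[sel, , drop = FALSE]
  ref_com <- colMeans(refL)
  refC <- sweep(refL, 2, ref_com)
  nf <- n_frames(traj)
  disp <- numeric(nf); ang <- numeric(nf)
  for (k in seq_len(nf)) {
    L <- traj$xyz[k, sel, ]
    com <- colMeans(L)
    disp[k] <- sqrt(sum((com - ref_com)^2))
    R <- kabsch_rotation(sweep(L, 2, com), refC)
    ang[k] <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  }
  data.frame(time = traj$times, displacement = disp, orientation = ang)
}

#' Pairwise distance series and contact statistics
#'
#' Per-frame distance between two uniquely resolved atoms, plus contact
#' episodes: maximal runs of frames with distance below `cutoff`, each with
#' its start, end and duration (frames in contact times the frame interval).
#'
#' @param traj An `md_trajectory`.
#' @param atom_a,atom_b Atom index, or a list of selection arguments passed to
#'   [select_atoms()] (e.g. `list(elety = "CZ", resno = 372)`).
#' @param cutoff Contact cutoff (A).
#' @return List with `series` (data frame time, distance) and `episodes`
#'   (data frame start, end, duration in ns).
#' @export
distance_series <- function(traj, atom_a, atom_b, cutoff = 3.5) {
  resolve <- function(a, nm) {
    if (is.numeric(a) && length(a) == 1) return(as.integer(a))
    ix <- do.call(select_atoms, c(list(traj = traj), a))
    if (length(ix) != 1)
      stop("ambiguous atom query for ", nm, ": resolves to ", length(ix),
           " atoms (indices ", paste(utils::head(ix, 5), collapse = ", "), ")")
    ix
  }
  ia <- resolve(atom_a, "atom_a"); ib <- resolve(atom_b, "atom_b")
  d <- sqrt(rowSums((traj$xyz[, ia, ] - traj$xyz[, ib, ])^2))
  dtv <- diff(traj$times)
  dt <- if (length(dtv)) stats::median(dtv) else 0
  below <- d < cutoff
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  ep <- which(r$values)
  episodes <- data.frame(
    start = traj$times[starts[ep]],
    end = traj$times[ends[ep]],
    duration = r$lengths[ep] * dt)
  list(series = data.frame(time = traj$times, distance = d),
       episodes = episodes)
}
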