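# Seeded synthetic-trajectory generators standing in for unreleased
# microsecond MD data: a minimal residue whose side chain switches between an
# internal and an external pose as a two-state continuous-time Markov
# (telegraph) process, a point ligand performing a reflected random walk in a
# box of known volume, and a two-atom fixture whose distance follows a
# prescribed contact schedule.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(expr)
}

# Rigid backbone of the minimal residue (A, CA at the origin); the side-chain
# vector CA->CZ swings in the xz-plane.
.residue_backbone <- rbind(
  N = c(-1.20, 0.80, -0.40),
  CA = c(0, 0, 0),
  C = c(1.30, 0.70, -0.30))
.sidechain_length <- 4.1

#' Generate a telegraph (two-state) side-chain trajectory
#'
#' A minimal residue (N, CA, C backbone plus a CZ side-chain tip) whose
#' side-chain vector alternates between an internal pose at `pose_internal`
#' degrees and an external pose at `pose_external` degrees from the reference
#' direction (+z). State dwell times are exponential with mean `1/rate`
#' (a symmetric continuous-time two-state Markov process), sampled every `dt`
#' ns, with Gaussian jitter of `jitter_sd` degrees on the swing angle.
#' The expected number of transitions over a duration T is `rate * T`.
#'
#' @param rate Switching rate per microsecond (per state).
#' @param duration Total time (ns).
#' @param dt Frame interval (ns); default 0.24 ns.
#' @param pose_internal,pose_external Pose angles (deg) of the two states.
#' @param jitter_sd Angular jitter standard deviation (deg).
#' @param start_state `"internal"` or `"external"`.
#' @param seed RNG seed (recorded in the ground truth).
#' @return List with `trajectory` (an `md_trajectory`), `reference` (a
#'   1-frame `md_trajectory` with the side chain at 0 deg) and `ground_truth`
#'   (true transition times, per-frame states, dwell times, rate, seed).
#' @export
generate_telegraph_trajectory <- function(rate = 1.7, duration = 10000,
                                          dt = 0.24,
                                          pose_internal = 30,
                                          pose_external = 130,
                                          jitter_sd = 8,
                                          start_state = "internal",
                                          seed = 1) {
  stopifnot(rate >= 0, duration > 0, dt > 0, jitter_sd >= 0)
  if (rate > 0 && dt > 1 / (10 * rate * 1e-3))
    warning("frame interval ", dt, " ns undersamples switching at ", rate,
            " /us")
  rate_ns <- rate * 1e-3
  with_seed(seed, {
    # exact event times of the continuous-time process
    ev <- numeric(0)
    t <- 0
    if (rate_ns > 0) repeat {
      t <- t + stats::rexp(1, rate_ns)
      if (t >= duration) break
      ev <- c(ev, t)
    }
    times <- seq(0, duration, by = dt)
    s0 <- match.arg(start_state, c("internal", "external"))
    # state index per frame: number of events before each frame time
    flips <- findInterval(times, ev)
    state <- (flips + (s0 == "external")) %% 2 # 0 internal, 1 external
    pose <- ifelse(state == 0, pose_internal, pose_external)
    theta <- pose + stats::rnorm(length(pose), 0, jitter_sd)
    theta <- pmin(179.5, pmax(0.5, theta))
    nf <- length(times)
    xyz <- array(0, c(nf, 4, 3))
    for (a in 1:3) xyz[, a, ] <- matrix(.residue_backbone[a, ], nf, 3,
                                        byrow = TRUE)
    rad <- theta * pi / 180
    xyz[, 4, 1] <- .sidechain_length * sin(rad)
    xyz[, 4, 3] <- .sidechain_length * cos(rad)
    atoms <- data.frame(elety = c("N", "CA", "C", "CZ"), resid = "ARG",
                        resno = 372L, stringsAsFactors = FALSE)
    traj <- new_trajectory(times, xyz, atoms)
    ref_xyz <- array(0, c(1, 4, 3))
    for (a in 1:3) ref_xyz[1, a, ] <- .residue_backbone[a, ]
    ref_xyz[1, 4, 3] <- .sidechain_length
    reference <- new_trajectory(0, ref_xyz, atoms)
    dwells <- diff(c(0, ev, duration))
    list(trajectory = traj, reference = reference,
         ground_truth = list(
           transition_times = ev,
           n_transitions = length(ev),
           dwell_times = dwells,
           state = c("internal", "external")[state + 1],
           rate = rate, duration = duration, dt = dt, seed = seed,
           pose_internal = pose_internal, pose_external = pose_external))
  })
}

#' Generate a confined random-walk ligand trajectory
#'
#' A point ligand performing a Gaussian random walk with reflecting
#' boundaries inside a rectangular box whose volume is known exactly; the
#' visited-volume estimator applied to a long walk must converge to the box
#' volume as the occupancy threshold approaches zero.
#'
#' @param box Box edge lengths (A), length-3.
#' @param step_sd Per-step displacement standard deviation per axis (A); must
#'   be below the smallest box edge.
#' @param n_steps Number of steps (frames = `n_steps + 1`).
#' @param dt Frame interval (ns).
#' @param origin Lower corner of the box (A).
#' @param seed RNG seed.
#' @return List with `trajectory` (single-atom `md_trajectory`) and
#'   `ground_truth` (box volume, box, seed).
#' @export
generate_random_walk_ligand <- function(box = c(10, 10, 10), step_sd = 1.0,
                                        n_steps = 150000, dt = 0.24,
                                        origin = c(0, 0, 0), seed = 1) {
  stopifnot(length(box) == 3, all(box > 0), n_steps >= 0)
  if (step_sd >= min(box))
    stop("parameter error: step_sd = ", step_sd,
         " must be smaller than the smallest box edge (", min(box), ")")
  with_seed(seed, {
    nf <- n_steps + 1L
    xyz <- array(0, c(nf, 1, 3))
    for (ax in 1:3) {
      raw <- cumsum(c(box[ax] / 2, stats::rnorm(n_steps, 0, step_sd)))
      p <- raw %% (2 * box[ax])
      xyz[, 1, ax] <- origin[ax] + ifelse(p <= box[ax], p, 2 * box[ax] - p)
    }
    atoms <- data.frame(elety = "LIG", resid = "LIG", resno = 1L,
                        stringsAsFactors = FALSE)
    traj <- new_trajectory(dt * (seq_len(nf) - 1), xyz, atoms)
    list(trajectory = traj,
         ground_truth = list(volume = prod(box), box = box, origin = origin,
                             step_sd = step_sd, seed = seed))
  })
}

#' Generate a two-atom contact fixture
#'
#' Two atoms whose distance is `below` during the scheduled contact episodes
#' and `above` otherwise; used to validate contact-lifetime extraction
#' exactly. Episodes are half-open intervals `[start, end)` in ns and must
#' not overlap.
#'
#' @param schedule Data frame with `start` and `end` columns (ns).
#' @param duration Total time (ns).
#' @param dt Frame interval (ns).
#' @param below,above Distances (A) in and out of contact.
#' @return An `md_trajectory` of two atoms.
#' @export
generate_contact_fixture <- function(schedule, duration, dt = 0.1,
                                     below = 3.0, above = 6.0) {
  stopifnot(below < above, duration > 0, dt > 0)
  if (nrow(schedule) > 0) {
    stopifnot(all(schedule$end > schedule$start))
    o <- order(schedule$start)
    s <- schedule[o, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("schedule error: contact episodes overlap")
  }
  times <- seq(0, duration, by = dt)
  in_contact <- rep(FALSE, length(times))
  for (i in seq_len(nrow(schedule)))
    in_contact <- in_contact |
      (times >= schedule$start[i] & times < schedule$end[i])
  d <- ifelse(in_contact, below, above)
  nf <- length(times)
  xyz <- array(0, c(nf, 2, 3))
  xyz[, 2, 1] <- d
  atoms <- data.frame(elety = c("CZ", "C1"), resid = c("ARG", "SHK"),
                      resno = c(372L, 500L), stringsAsFactors = FALSE)
  new_trajectory(times, xyz, atoms)
}

#' Write a generated trajectory with its ground-truth sidecar
#'
#' Writes the trajectory as multi-frame XYZ and the ground truth as a JSON
#' sidecar (`<path>.json`).
#'
#' @param gen Output of a generator (list with `trajectory`, `ground_truth`).
#' @param path Output XYZ path.
#' @return `path`, invisibly.
#' @export
write_generated <- function(gen, path) {
  write_xyz(gen$trajectory, path)
  jsonlite::write_json(gen$ground_truth, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
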