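## Ghost-chain evolution: beads travel on straight chords from start to
## destination.  Each step the unlocked bead furthest from its destination
## advances by delta, and the move is propagated outward along the chain
## by link-length restoration on each neighbor's own chord.  The chain may
## pass through itself (crossings are charged retroactively elsewhere);
## link lengths may transiently deviate from their rest values, which is
## the price of forbidding local rotations.

#' Ghost-transformation settings
#'
#' @param delta step size in link-length units; the default 0.02 (two
#'   percent of the link length) is small enough to capture all
#'   self-crossing events.
#' @param record_every frame stride for stored trajectory frames.
#'   Crossing detection should always run on stride-1 trajectories.
#' @return a `transform_spec` list.
#' @export
transform_spec <- function(delta = 0.02, record_every = 1L) {
  stopifnot(delta > 0, delta <= 0.1, record_every >= 1)
  structure(list(delta = delta, record_every = as.integer(record_every)),
            class = "transform_spec")
}

#' Evolve a chain between two conformations as a ghost chain
#'
#' Straight-line bead paths with furthest-bead-first stepping: per step,
#' (1) the unlocked bead with the largest remaining distance to its
#' destination (ties broken toward the lower index) advances by
#' `min(delta, remaining)` along its chord and is snapped and locked when
#' it arrives; (2) the move propagates outward in both directions, each
#' neighbor moving to the point on its own chord that restores its link
#' rest length to the just-updated bead (the forward line-sphere root
#' nearest the neighbor's current path parameter), or snapping the
#' neighbor to its destination when it is within `delta` of arriving;
#' (3) a bead with no continuous forward solution remains stationary for
#' the step - its link length deviates instead - and blocks propagation
#' past it; it resumes (possibly catching up by more than `delta`) once
#' a solution reappears or it becomes the furthest bead.  Locked beads
#' never move; if a link constraint cannot be met against a locked bead
#' the inner bead stalls instead.
#'
#' @param a,b `chain`s with equal bead counts and shared rest lengths.
#'   Align them (e.g. [align_mrsd()]) before evolving.
#' @param spec a [transform_spec()].
#' @return a `trajectory`: `frames` (stride `record_every`, always
#'   including first and last), `all_frames` (stride 1, used for crossing
#'   detection), `per_bead_path` (accumulated straight-path lengths),
#'   `locked_at` (step at which each bead locked), `n_steps`, `start`,
#'   `end`, `spec`.
#' @export
evolve_ghost <- function(a, b, spec = transform_spec()) {
  stopifnot_same_size(a, b)
  if (length(a$rest_lengths) != length(b$rest_lengths) ||
      any(abs(a$rest_lengths - b$rest_lengths) > 1e-9))
    stop("chains must share rest lengths")
  delta <- spec$delta
  n <- n_beads(a)
  start <- a$coords; dest <- b$coords
  chord <- dest - start
  chord_len <- sqrt(rowSums(chord * chord))
  u <- chord / ifelse(chord_len > 0, chord_len, 1)   # unit path directions
  s <- rep(0, n)                                     # path parameters
  locked <- chord_len <= 1e-12
  locked_at <- ifelse(locked, 0L, NA_integer_)
  pos <- start
  path_len <- rep(0, n)
  rest <- a$rest_lengths
  frames <- list(pos)
  guard <- ceiling(max(chord_len, delta) / delta) * n * 4 + 16
  step <- 0L
  while (!all(locked)) {
    step <- step + 1L
    if (step > guard)
      stop("ghost evolution failed to terminate within the step guard")
    remaining <- ifelse(locked, -Inf, chord_len - s)
    j <- which.max(remaining)                        # ties -> lowest index
    new_s <- s
    rem <- chord_len[j] - s[j]
    if (rem < delta) {
      new_s[j] <- chord_len[j]
    } else {
      new_s[j] <- s[j] + delta
    }
    pos_new <- pos
    pos_new[j, ] <- start[j, ] + u[j, ] * new_s[j]
    newly_locked <- logical(n)
    if (new_s[j] >= chord_len[j] - 1e-12) {
      pos_new[j, ] <- dest[j, ]                      # snap exactly
      newly_locked[j] <- TRUE
    }
    for (dir in c(-1L, 1L)) {
      k <- j + dir
      while (k >= 1L && k <= n) {
        if (locked[k]) break                         # hard anchors
        if (chord_len[k] - s[k] < delta) {           # snap rule: within one
          new_s[k] <- chord_len[k]                   # step of the destination
          pos_new[k, ] <- dest[k, ]
          newly_locked[k] <- TRUE
          k <- k + dir
          next
        }
        rl <- rest[min(k, k - dir)]                  # link between k and k-dir
        sol <- chord_sphere_param(start[k, ], u[k, ], chord_len[k], s[k],
                                  pos_new[k - dir, ], rl, delta)
        if (is.null(sol)) break                      # stall: no continuous move
        if (abs(sol - s[k]) > 1e-15) {
          new_s[k] <- sol
          pos_new[k, ] <- start[k, ] + u[k, ] * sol
        }
        k <- k + dir
      }
    }
    path_len <- path_len + abs(new_s - s)
    s <- new_s
    pos <- pos_new
    locked_at[newly_locked & is.na(locked_at)] <- step
    locked <- locked | newly_locked
    frames[[length(frames) + 1L]] <- pos
  }
  keep <- unique(c(seq(1L, length(frames), by = spec$record_every),
                   length(frames)))
  structure(list(frames = frames[keep], all_frames = frames,
                 per_bead_path = path_len, locked_at = locked_at,
                 n_steps = step, start = a, end = b, spec = spec),
            class = "trajectory")
}

## Root of |start + u t - center| = radius nearest to t0, restricted to
## forward motion: beads progress monotonically toward the destination,
## and when the constraint would demand backward motion (or no real
## solution exists) the bead stays put for the step, letting the link
## length deviate instead.  A bead resuming after a stationary period
## may catch up by more than one step size; the mover itself never
## exceeds delta.  Returns NULL when no admissible root exists.
chord_sphere_param <- function(start, u, chord_len, t0, center, radius,
                               delta) {
  w <- start - center
  bq <- sum(u * w)
  cq <- sum(w * w) - radius^2
  disc <- bq * bq - cq
  if (disc < 0) return(NULL)
  sq <- sqrt(disc)
  roots <- c(-bq - sq, -bq + sq)
  ok <- roots >= t0 - 1e-9
  if (!any(ok)) return(NULL)
  roots <- roots[ok]
  r <- roots[which.min(abs(roots - t0))]
  ## the path ends at the destination: a root beyond it means no
  ## continuous solution on the remaining path
  if (r > chord_len + 1e-9) return(NULL)
  min(r, chord_len)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d beads, %d steps, total path %.4g\n",
              n_beads(x$start), x$n_steps, sum(x$per_bead_path)))
  invisible(x)
}

#' Ghost distance of a trajectory
#'
#' The summed per-bead straight-path length; close to N x MRSD of the
#' endpoint pair (within N x delta) because paths are straight and
#' stationary periods add nothing.
#'
#' @param traj a `trajectory` from [evolve_ghost()].
#' @return list with `total` and `per_bead`.
#' @export
ghost_distance <- function(traj) {
  list(total = sum(traj$per_bead_path), per_bead = traj$per_bead_path)
}

#' Link-length statistics over a trajectory
#'
#' Diagnoses how strongly the straight-path approximation violates the
#' constant-link-length constraint.
#'
#' @param traj a `trajectory`.
#' @return list with `mean` and `sd` over all links and frames, and a
#'   `per_step` matrix (frames x links) of link lengths.
#' @export
link_length_profile <- function(traj) {
  m <- t(vapply(traj$all_frames, link_lengths_of,
                numeric(n_beads(traj$start) - 1L)))
  list(mean = mean(m), sd = stats::sd(as.vector(m)), per_step = m)
}
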