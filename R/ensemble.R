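## Unfolded-ensemble generation: a native-biased extension of the pivot
## algorithm.  Bond and dihedral angles at a randomly chosen residue are
## redrawn from Boltzmann distributions centred on the native values, the
## downstream chain is rigidly rotated, and moves creating steric overlap
## are rejected.

#' Ensemble generation settings
#'
#' Bundles the knobs of the native-biased pivot generator.  The potential
#' is the coarse-grained Go-model form: harmonic in the bond angle,
#' E_theta = k_theta (theta - theta0)^2, and a two-term cosine series in
#' the dihedral, E_phi = k_phi1 [1 - cos(phi - phi0)] +
#' k_phi3 [1 - cos 3(phi - phi0)].  The dihedral stiffnesses are much
#' smaller than the bond-angle stiffness, so dihedrals are sampled nearly
#' uniformly at the default temperature.  With all stiffnesses zero the
#' generator reduces to the unbiased self-avoiding pivot algorithm; with
#' infinite stiffness the chain is rigid and stays native.
#'
#' @param n_structures number of unfolded conformations to generate.
#' @param n_pivot successful (accepted) pivot moves per conformation;
#'   `NULL` means the default 3(N-2) for an N-bead chain, matching three
#'   pivot visits per interior residue on average.
#' @param k_theta bond-angle stiffness (energy/rad^2), default 20.
#' @param k_phi1,k_phi3 dihedral stiffnesses (energy), defaults 1 and 0.5.
#' @param temperature dimensionless kT, default 1.
#' @param steric_cutoff minimal allowed distance between non-neighbor
#'   beads (same units as the chain); `NULL` means it must be supplied by
#'   the caller (see [steric_cutoff()]).
#' @param seed integer seed; each structure uses an independent stream
#'   derived from (seed, structure index).
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_structures = 200L, n_pivot = NULL,
                          k_theta = 20, k_phi1 = 1, k_phi3 = 0.5,
                          temperature = 1, steric_cutoff = NULL,
                          seed = 1L) {
  stopifnot(k_theta >= 0, k_phi1 >= 0, k_phi3 >= 0, temperature > 0,
            is.null(n_pivot) || n_pivot >= 1)
  structure(list(n_structures = as.integer(n_structures),
                 n_pivot = if (!is.null(n_pivot)) as.integer(n_pivot),
                 k_theta = k_theta, k_phi1 = k_phi1, k_phi3 = k_phi3,
                 temperature = temperature, steric_cutoff = steric_cutoff,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

## deterministic per-structure seed below 2^31, decorrelating the streams
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(index) * 69621) %% 2147483647
  as.integer((x * 16807) %% 2147483629)
}

#' Native internal angles of a chain
#'
#' Bond angle at bead i is defined by beads (i-1, i, i+1) and lies in
#' (0, pi); the dihedral for quadruple (i-1, i, i+1, i+2) lies in
#' (-pi, pi].  Angles whose defining beads are collinear are returned as
#' `NA` and flagged.
#'
#' @param native a `chain`.
#' @return list with `theta` (length N-2, bead-indexed 2..N-1), `phi`
#'   (length N-3), and logical `defined_phi`.
#' @export
native_internal_angles <- function(native) {
  r <- native$coords
  n <- nrow(r)
  theta <- rep(NA_real_, max(n - 2L, 0L))
  for (i in seq_len(n - 2L) + 1L)
    theta[i - 1L] <- bond_angle(r[i - 1L, ], r[i, ], r[i + 1L, ])
  phi <- rep(NA_real_, max(n - 3L, 0L))
  for (i in seq_len(n - 3L) + 1L)
    phi[i - 1L] <- dihedral_angle(r[i - 1L, ], r[i, ], r[i + 1L, ],
                                  r[i + 2L, ])
  list(theta = theta, phi = phi, defined_phi = !is.na(phi))
}

bond_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv))))
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c12 <- cross3(b1, b2); c23 <- cross3(b2, b3)
  if (sum(c12 * c12) < 1e-20 || sum(c23 * c23) < 1e-20) return(NA_real_)
  x <- sum(c12 * c23)
  y <- sum(cross3(c12, c23) * b2) / sqrt(sum(b2 * b2))
  atan2(y, x)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## inverse-CDF sampling from an unnormalized density tabulated on a
## fixed grid; rejection-free and reproducible
grid_sample <- function(n, grid, dens, rng_u = stats::runif(n)) {
  cum <- cumsum(dens)
  if (cum[length(cum)] <= 0) stop("degenerate sampling density")
  cum <- cum / cum[length(cum)]
  idx <- findInterval(rng_u, cum) + 1L
  idx[idx > length(grid)] <- length(grid)
  ## linear interpolation within the grid cell
  lo <- c(0, cum)[idx]
  hi <- cum[idx]
  w <- ifelse(hi > lo, (rng_u - lo) / (hi - lo), 0.5)
  step <- grid[2L] - grid[1L]
  grid[idx] - step / 2 + w * step
}

angle_grid_n <- 4096L

#' Sample a bond angle from the harmonic Boltzmann density
#'
#' Density proportional to exp(-k_theta (theta - theta0)^2 / kT)
#' restricted to (0, pi), sampled by inverse CDF on a 4096-point grid.
#'
#' @param theta0 native bond angle in (0, pi).
#' @param k_theta stiffness (energy/rad^2); `Inf` returns `theta0`.
#' @param kT temperature.
#' @param n number of draws.
#' @return numeric vector of angles in (0, pi).
#' @export
sample_bond_angle <- function(theta0, k_theta, kT = 1, n = 1L) {
  stopifnot(theta0 > 0, theta0 < pi)
  if (!is.finite(k_theta) || k_theta / kT > 1e12)
    return(rep(theta0, n))
  step <- pi / angle_grid_n
  grid <- seq(step / 2, pi - step / 2, length.out = angle_grid_n)
  dens <- exp(-(k_theta * (grid - theta0)^2 -
                  min(k_theta * (grid - theta0)^2)) / kT)
  grid_sample(n, grid, dens)
}

#' Sample a dihedral from the periodic Boltzmann density
#'
#' Density proportional to exp(-(k_phi1 (1 - cos(phi - phi0)) +
#' k_phi3 (1 - cos 3(phi - phi0))) / kT) on (-pi, pi].
#'
#' @param phi0 native dihedral in (-pi, pi].
#' @param k_phi1,k_phi3 stiffnesses (energy); `Inf` returns `phi0`.
#' @param kT temperature.
#' @param n number of draws.
#' @return numeric vector of angles wrapped to (-pi, pi].
#' @export
sample_dihedral <- function(phi0, k_phi1, k_phi3, kT = 1, n = 1L) {
  if (!is.finite(k_phi1) || !is.finite(k_phi3) ||
      (k_phi1 + k_phi3) / kT > 1e12)
    return(rep(phi0, n))
  step <- 2 * pi / angle_grid_n
  grid <- seq(-pi + step / 2, pi - step / 2, length.out = angle_grid_n)
  e <- k_phi1 * (1 - cos(grid - phi0)) + k_phi3 * (1 - cos(3 * (grid - phi0)))
  dens <- exp(-(e - min(e)) / kT)
  wrap_angle(grid_sample(n, grid, dens))
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

rotate_about <- function(points, axis, angle, origin) {
  ## Rodrigues rotation of an m x 3 matrix about a unit axis through origin
  k <- axis / sqrt(sum(axis * axis))
  p <- sweep(points, 2L, origin)
  kx <- cbind(p[, 2L] * k[3L] - p[, 3L] * k[2L],
              p[, 3L] * k[1L] - p[, 1L] * k[3L],
              p[, 1L] * k[2L] - p[, 2L] * k[1L])
  kdp <- as.vector(p %*% k)
  rot <- p * cos(angle) - kx * sin(angle) +
    outer(kdp, k) * (1 - cos(angle))
  sweep(rot, 2L, -origin)
}

## deterministic unit vector perpendicular to v
perp_unit <- function(v) {
  a <- if (abs(v[1L]) < 0.9 * sqrt(sum(v * v))) c(1, 0, 0) else c(0, 1, 0)
  w <- cross3(v, a)
  w / sqrt(sum(w * w))
}

#' Apply one pivot move
#'
#' Rotates all beads downstream of interior bead `i` (1-based; `2 <= i <=
#' N-1`) so that the bond angle at `i` becomes `new_theta` and the
#' dihedral about bond i -> i+1 becomes `new_phi`.  For the last interior
#' bead (`i = N-1`) only the angle is changed.  Beads `1..i` do not move
#' and all link lengths are preserved (rigid rotations).
#'
#' @param x a `chain`.
#' @param i interior bead index (1-based).
#' @param new_theta target bond angle in (0, pi).
#' @param new_phi target dihedral in (-pi, pi] (ignored for `i = N-1`).
#' @return the pivoted `chain`.
#' @export
apply_pivot <- function(x, i, new_theta, new_phi = NULL) {
  r <- x$coords
  n <- nrow(r)
  if (i < 2L || i > n - 1L) stop("pivot index must be interior (2..N-1)")
  u <- r[i - 1L, ] - r[i, ]; v <- r[i + 1L, ] - r[i, ]
  axis <- cross3(u, v)
  if (sum(axis * axis) < 1e-20) axis <- perp_unit(u)   # collinear triple
  cur_theta <- bond_angle(r[i - 1L, ], r[i, ], r[i + 1L, ])
  down <- (i + 1L):n
  r[down, ] <- rotate_about(r[down, , drop = FALSE], axis,
                            new_theta - cur_theta, r[i, ])
  if (i <= n - 2L && !is.null(new_phi)) {
    cur_phi <- dihedral_angle(r[i - 1L, ], r[i, ], r[i + 1L, ], r[i + 2L, ])
    if (is.na(cur_phi)) cur_phi <- 0
    bond <- r[i + 1L, ] - r[i, ]
    tail <- (i + 2L):n
    r[tail, ] <- rotate_about(r[tail, , drop = FALSE], bond,
                              new_phi - cur_phi, r[i + 1L, ])
  }
  chain(r, x$rest_lengths, x$label)
}

## smallest distance between beads separated by >= 2 along the chain
min_nonneighbor_distance <- function(coords) {
  n <- nrow(coords)
  if (n < 3L) return(Inf)
  d <- as.matrix(stats::dist(coords))
  d[row(d) >= col(d) - 1L] <- Inf
  min(d)
}

self_avoiding <- function(coords, cutoff) {
  min_nonneighbor_distance(coords) >= cutoff
}

## after a pivot at bead i only pairs straddling the pivot can newly
## clash (each side moves rigidly), so checking upstream-vs-downstream
## distances suffices when the pre-move chain was self-avoiding
cross_pairs_clear <- function(coords, i, cutoff) {
  n <- nrow(coords)
  up <- coords[seq_len(i), , drop = FALSE]
  dn <- coords[(i + 1L):n, , drop = FALSE]
  d2 <- outer(rowSums(up^2), rowSums(dn^2), "+") - 2 * up %*% t(dn)
  ## mask the bonded pair (i, i+1)
  d2[i, 1L] <- Inf
  min(d2) >= cutoff^2 - 1e-12
}

#' Generate an unfolded ensemble by native-biased pivoting
#'
#' Each conformation restarts from the native chain and performs
#' `n_pivot` accepted pivot moves; a move is rejected (and a new random
#' residue drawn) whenever any non-neighbor bead pair comes closer than
#' the steric cutoff.  Reproducible: structure `k` uses an RNG stream
#' derived from `(spec$seed, k)`, so ensembles are order-independent.
#'
#' @param native a `chain` (>= 4 beads).
#' @param contacts a `contact_set` from [native_contact_set()] (used only
#'   for the per-conformation fraction of native contacts Q); may be
#'   `NULL`.
#' @param spec an [ensemble_spec()]; `spec$steric_cutoff` must be set (in
#'   the native chain's units).
#' @return an `unfolded_ensemble`: list of `chain`s, per-conformation
#'   `q_values`, the `spec`, and the `native` chain.
#' @export
generate_unfolded <- function(native, contacts, spec) {
  n <- n_beads(native)
  if (n < 4L) stop("native chain must have at least 4 beads")
  if (is.null(spec$steric_cutoff))
    stop("spec$steric_cutoff must be set (see steric_cutoff())")
  n_pivot <- if (is.null(spec$n_pivot)) 3L * (n - 2L) else spec$n_pivot
  ang <- native_internal_angles(native)
  confs <- vector("list", spec$n_structures)
  qv <- rep(NA_real_, spec$n_structures)
  for (k in seq_len(spec$n_structures)) {
    confs[[k]] <- pivot_walk(native, ang, n_pivot, spec, derive_seed(spec$seed, k))
    if (!is.null(contacts))
      qv[k] <- fraction_native_contacts(confs[[k]], native, contacts)
  }
  structure(list(conformations = confs, q_values = qv, spec = spec,
                 native = native),
            class = "unfolded_ensemble")
}

pivot_walk <- function(start, ang, n_pivot, spec, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cur <- start
  n <- n_beads(start)
  accepted <- 0L; attempts <- 0L
  while (accepted < n_pivot) {
    attempts <- attempts + 1L
    if (attempts >= 1e5L && accepted / attempts < 1e-3)
      stop(sprintf(paste0("pivot acceptance rate %.2g after %d attempts; ",
                          "steric cutoff too large for this chain?"),
                   accepted / attempts, attempts))
    i <- sample(2:(n - 1L), 1L)
    theta0 <- ang$theta[i - 1L]
    ## collinear native triples sit on the boundary of (0, pi)
    if (is.na(theta0) || theta0 >= pi - 1e-9) theta0 <- pi - 1e-6
    if (theta0 <= 1e-9) theta0 <- 1e-6
    nt <- sample_bond_angle(theta0, spec$k_theta, spec$temperature)
    np <- NULL
    if (i <= n - 2L) {
      phi0 <- ang$phi[i - 1L]
      if (is.na(phi0)) phi0 <- 0
      np <- sample_dihedral(phi0, spec$k_phi1, spec$k_phi3, spec$temperature)
    }
    cand <- apply_pivot(cur, i, nt, np)
    if (cross_pairs_clear(cand$coords, i, spec$steric_cutoff)) {
      cur <- cand
      accepted <- accepted + 1L
    }
  }
  cur
}

#' Fraction of native contacts formed in a conformation
#'
#' A native contact (i, j) counts as formed when the conformation's
#' bead-bead distance is at most 1.2 times the native distance (the usual
#' Go-model criterion for C-alpha-only chains).
#'
#' @param conf,native `chain`s with equal bead counts.
#' @param contacts a `contact_set` (residue index pairs).
#' @param tol_factor formation criterion multiplier, default 1.2.
#' @return Q in `[0, 1]` (`NA` if the contact set is empty).
#' @export
fraction_native_contacts <- function(conf, native, contacts,
                                     tol_factor = 1.2) {
  stopifnot_same_size(conf, native)
  p <- contacts$pairs
  if (is.null(p) || nrow(p) == 0L) return(NA_real_)
  dn <- sqrt(rowSums((native$coords[p[, 1L], , drop = FALSE] -
                        native$coords[p[, 2L], , drop = FALSE])^2))
  dc <- sqrt(rowSums((conf$coords[p[, 1L], , drop = FALSE] -
                        conf$coords[p[, 2L], , drop = FALSE])^2))
  mean(dc <= tol_factor * dn)
}
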