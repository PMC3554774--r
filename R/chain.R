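#' Construct a bead-and-link chain
#'
#' A `chain` is the fundamental geometry object of the package: an ordered
#' set of N bead positions in 3D connected by N-1 links, each link carrying
#' a rest (equilibrium) length.  Coordinates are in link-length units for
#' ideal chains, or in Angstrom when freshly read from a PDB file (see
#' [rescale_chain()]).
#'
#' @param coords numeric N x 3 matrix of bead positions (N >= 2, finite).
#' @param rest_lengths numeric vector of N-1 strictly positive per-link rest
#'   lengths.  Defaults to the current geometric link lengths.
#' @param label free-text identifier carried through transformations.
#' @return An object of class `chain`.
#' @export
chain <- function(coords, rest_lengths = NULL, label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 2L) stop("a chain needs at least 2 beads")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (is.null(rest_lengths)) rest_lengths <- link_lengths_of(coords)
  rest_lengths <- as.double(rest_lengths)
  if (length(rest_lengths) != n - 1L)
    stop("rest_lengths must have length N - 1")
  if (!all(is.finite(rest_lengths)) || any(rest_lengths <= 0))
    stop("rest_lengths must be strictly positive and finite")
  structure(list(coords = coords, rest_lengths = rest_lengths,
                 label = as.character(label)[1L]),
            class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("<chain> %s: %d beads, %d links, mean link length %.4g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              n_beads(x), n_beads(x) - 1L, mean(link_lengths(x))))
  invisible(x)
}

#' Number of beads in a chain
#' @param x a `chain`.
#' @return integer bead count.
#' @export
n_beads <- function(x) nrow(x$coords)

link_lengths_of <- function(coords) {
  d <- diff(coords)
  sqrt(rowSums(d * d))
}

#' Current geometric link lengths of a chain
#' @param x a `chain`.
#' @return numeric vector of N-1 Euclidean link lengths.
#' @export
link_lengths <- function(x) link_lengths_of(x$coords)

stopifnot_same_size <- function(a, b) {
  if (n_beads(a) != n_beads(b))
    stop(sprintf("chains have different bead counts (%d vs %d)",
                 n_beads(a), n_beads(b)))
}

per_bead_distances <- function(a, b) {
  d <- a$coords - b$coords
  sqrt(rowSums(d * d))
}

#' Mean root squared distance between two chains
#'
#' The MRSD is the mean over beads of the per-bead Euclidean distance.  It
#' equals the total straight-line distance travelled per bead when every
#' bead moves on a straight path, and is always less than or equal to the
#' RMSD.
#'
#' @param a,b `chain` objects with equal bead counts.
#' @return non-negative length (same units as the coordinates).
#' @seealso [rmsd()], [align_mrsd()]
#' @export
mrsd <- function(a, b) {
  stopifnot_same_size(a, b)
  mean(per_bead_distances(a, b))
}

#' Root mean squared distance between two chains (no fitting)
#'
#' Plain coordinate RMSD of two already-posed chains; use [align_rmsd()]
#' for the least-squares superposed value.
#'
#' @inheritParams mrsd
#' @return non-negative length.
#' @export
rmsd <- function(a, b) {
  stopifnot_same_size(a, b)
  sqrt(mean(per_bead_distances(a, b)^2))
}

## Kabsch: optimal proper rotation mapping x onto y (both centred), via SVD
## with reflection correction.
kabsch_rotation <- function(x, y, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(x))
  h <- crossprod(x * weights, y)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- diag(c(1, 1, d))
  sv$v %*% s %*% t(sv$u)
}

apply_rigid <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2L, -translation)
}

new_alignment <- function(mobile, rotation, translation, target,
                          degenerate = FALSE, converged = TRUE) {
  fitted <- chain(apply_rigid(mobile$coords, rotation, translation),
                  mobile$rest_lengths, mobile$label)
  structure(list(transform = list(rotation = rotation,
                                  translation = translation),
                 fitted = fitted,
                 mrsd = mrsd(fitted, target),
                 rmsd = rmsd(fitted, target),
                 degenerate = degenerate, converged = converged),
            class = "chain_alignment")
}

#' @export
print.chain_alignment <- function(x, ...) {
  cat(sprintf("<chain_alignment> rmsd = %.6g, mrsd = %.6g%s\n", x$rmsd,
              x$mrsd, if (x$degenerate) " (degenerate input)" else ""))
  invisible(x)
}

is_collinear <- function(coords, tol = 1e-9) {
  cc <- sweep(coords, 2L, colMeans(coords))
  s <- svd(cc, nu = 0L, nv = 0L)$d
  s[2L] <= tol * max(s[1L], 1)
}

#' Rigid-body superposition minimizing RMSD
#'
#' Least-squares (Kabsch) superposition of `mobile` onto `target` over
#' proper rigid motions; reflections are excluded.  Collinear inputs have
#' no unique rotation about their axis; the result is still optimal and is
#' flagged `degenerate`.
#'
#' @param mobile,target `chain` objects with equal bead counts (N >= 3 for
#'   a unique rotation).
#' @return a `chain_alignment`: the rigid transform (`rotation`,
#'   `translation`), the `fitted` mobile chain, and residual `rmsd` and
#'   `mrsd`.
#' @export
align_rmsd <- function(mobile, target) {
  stopifnot_same_size(mobile, target)
  mx <- colMeans(mobile$coords); my <- colMeans(target$coords)
  r <- kabsch_rotation(sweep(mobile$coords, 2L, mx),
                       sweep(target$coords, 2L, my))
  new_alignment(mobile, r, my - as.vector(r %*% mx), target,
                degenerate = is_collinear(mobile$coords))
}

#' Rigid-body superposition minimizing MRSD
#'
#' Minimizes the mean of per-bead Euclidean distances (a sum-of-norms
#' objective) over proper rigid motions by iteratively reweighted least
#' squares: each iterate solves a weighted Kabsch problem with weights
#' 1/max(d_i, eps) followed by a Weiszfeld translation update (the
#' geometric-median step for the translation component).  MRSD-optimal
#' poses are globally different from RMSD-optimal ones.
#'
#' @inheritParams align_rmsd
#' @param max_iter maximum IRLS iterations (convergence is linear,
#'   so well-separated poses may need a few hundred).
#' @param tol relative-change convergence tolerance on the objective.
#' @return a `chain_alignment` (see [align_rmsd()]); `converged` reports
#'   whether the iteration met `tol` (a warning is emitted otherwise and
#'   the best iterate returned).
#' @export
align_mrsd <- function(mobile, target, max_iter = 2000L, tol = 1e-10) {
  stopifnot_same_size(mobile, target)
  eps <- 1e-9
  fit <- align_rmsd(mobile, target)   # RMSD pose seeds the iteration
  best <- fit; obj <- fit$mrsd
  cur <- fit$fitted$coords
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((cur - target$coords)^2))
    w <- 1 / pmax(d, eps)
    ## weighted centroids, then weighted Kabsch about them
    mx <- colSums(cur * w) / sum(w)
    my <- colSums(target$coords * w) / sum(w)
    r <- kabsch_rotation(sweep(cur, 2L, mx), sweep(target$coords, 2L, my),
                         weights = w)
    cur <- sweep(sweep(cur, 2L, mx) %*% t(r), 2L, -my)
    new_obj <- mean(sqrt(rowSums((cur - target$coords)^2)))
    done <- abs(obj - new_obj) < tol * max(obj, 1e-6)
    obj <- new_obj
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    warning("align_mrsd did not converge; returning best iterate")
  ## recover the single net rigid transform mobile -> cur via Kabsch on the
  ## exact correspondence (residual ~ machine precision)
  mx <- colMeans(mobile$coords); my <- colMeans(cur)
  r <- kabsch_rotation(sweep(mobile$coords, 2L, mx), sweep(cur, 2L, my))
  res <- new_alignment(mobile, r, my - as.vector(r %*% mx), target,
                       degenerate = is_collinear(mobile$coords),
                       converged = converged)
  ## guard: never worse than the RMSD pose measured in MRSD
  if (res$mrsd > best$mrsd + 1e-12) best else res
}
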