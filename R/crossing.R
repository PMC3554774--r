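## Projection-crossing bookkeeping.  A chain of N beads and L = N-1 links
## is parametrized uniformly by t in [0, L]; link k occupies [k-1, k).
## The crossing matrix of a single conformation records, for every
## non-adjacent link pair whose 2D projections intersect, the chain
## parameters of the intersection on both links, signed by the over-under
## sense: the entry for (i, j) is negative iff link i passes under link j.
## A true self-crossing of a ghost trajectory is a discontinuous sign flip
## of an entry between consecutive frames.

plane_axes <- function(plane) {
  switch(plane,
         XY = list(inplane = c(1L, 2L), out = 3L),
         XZ = list(inplane = c(1L, 3L), out = 2L),
         YZ = list(inplane = c(2L, 3L), out = 1L),
         stop("plane must be one of 'XY', 'XZ', 'YZ'"))
}

#' Signed projection-crossing matrix of a conformation
#'
#' @param x a `chain` or an N x 3 coordinate matrix.
#' @param plane projection plane, one of `"XY"` (default), `"XZ"`, `"YZ"`.
#' @return a `crossing_matrix`: data frame with one row per crossed link
#'   pair `i < j` and columns `i`, `j`, `ti`, `tj` (chain parameters of
#'   the intersection, `ti` in `[i-1, i)`), and `sign_i` (the sign of the
#'   matrix entry `(i, j)`; the `(j, i)` entry carries `-sign_i`).
#' @export
projection_crossings <- function(x, plane = "XY") {
  coords <- if (inherits(x, "chain")) x$coords else as.matrix(x)
  if (is_collinear(coords, tol = 1e-12)) {
    ## a straight chain is simple: no crossings in any projection
    res <- data.frame(i = integer(), j = integer(), ti = numeric(),
                      tj = numeric(), sign_i = numeric())
  } else {
    res <- projection_crossings_coords(coords, plane)
    if (is.null(res)) {
      ## degenerate parallel overlap: deterministic tiny rotation about a
      ## generic axis for this conformation
      warning("degenerate projected segments; applying 1e-7 rotation")
      ax <- c(1, 2, 3) / sqrt(14)
      res <- projection_crossings_coords(
        rotate_about(coords, ax, 1e-7, colMeans(coords)), plane)
      if (is.null(res))
        res <- projection_crossings_coords(
          rotate_about(coords, ax, 1e-5, colMeans(coords)), plane)
      if (is.null(res)) {
        ## segments collinear in 3D: no transversal crossing exists;
        ## compute the matrix with those pairs excluded
        warning("3D-collinear segment pair; excluded from the projection")
        res <- projection_crossings_coords(coords, plane,
                                           ignore_degenerate = TRUE)
      }
    }
  }
  attr(res, "plane") <- plane
  class(res) <- c("crossing_matrix", class(res))
  res
}

projection_crossings_coords <- function(coords, plane,
                                        ignore_degenerate = FALSE) {
  ax <- plane_axes(plane)
  p <- coords[, ax$inplane, drop = FALSE]
  z <- coords[, ax$out]
  l <- nrow(coords) - 1L
  empty <- data.frame(i = integer(), j = integer(), ti = numeric(),
                      tj = numeric(), sign_i = numeric())
  if (l < 3L) return(empty)
  pr <- which(upper.tri(matrix(0, l, l)), arr.ind = TRUE)
  pr <- pr[pr[, 2L] - pr[, 1L] >= 2L, , drop = FALSE]   # non-adjacent only
  i <- pr[, 1L]; j <- pr[, 2L]
  a <- p[i, , drop = FALSE];  d1 <- p[i + 1L, , drop = FALSE] - a
  b <- p[j, , drop = FALSE];  d2 <- p[j + 1L, , drop = FALSE] - b
  w <- b - a
  denom <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
  numu <- w[, 1L] * d2[, 2L] - w[, 2L] * d2[, 1L]
  numv <- w[, 1L] * d1[, 2L] - w[, 2L] * d1[, 1L]
  tol <- 1e-12 * max(1, max(abs(p)))
  par <- abs(denom) <= tol
  if (!ignore_degenerate && any(par & abs(numu) <= tol)) {
    ## collinear projected segments: possible overlap, caller perturbs
    bb_overlap <- function(q) {
      lo1 <- pmin(a[q, ], a[q, ] + d1[q, ]); hi1 <- pmax(a[q, ], a[q, ] + d1[q, ])
      lo2 <- pmin(b[q, ], b[q, ] + d2[q, ]); hi2 <- pmax(b[q, ], b[q, ] + d2[q, ])
      all(lo1 <= hi2 + tol) && all(lo2 <= hi1 + tol)
    }
    deg <- which(par & abs(numu) <= tol)
    if (any(vapply(deg, bb_overlap, logical(1L)))) return(NULL)
  }
  u <- ifelse(par, NA_real_, numu / denom)
  v <- ifelse(par, NA_real_, numv / denom)
  hit <- !par & u >= 0 & u < 1 & v >= 0 & v < 1
  if (!any(hit)) return(empty)
  i <- i[hit]; j <- j[hit]; u <- u[hit]; v <- v[hit]
  zi <- z[i] + u * (z[i + 1L] - z[i])
  zj <- z[j] + v * (z[j + 1L] - z[j])
  data.frame(i = i, j = j, ti = (i - 1) + u, tj = (j - 1) + v,
             sign_i = ifelse(zi < zj, -1, 1))
}

#' Detect true self-crossing events along a ghost trajectory
#'
#' A crossing event is recorded for a link pair when its projection
#' crossing-matrix entry changes sign between consecutive frames without
#' passing through zero (the entry must be present, with opposite signs,
#' in both frames; an entry that appears or disappears reflects the
#' projected crossing being created or destroyed without a true
#' crossing).  The snapshot attached to each event is the frame *before*
#' the sign flip.  Any link pair crossing an even number of times has its
#' events cancelled pairwise with a warning (the pair's net topology is
#' unchanged; the paper expects each pair to cross at most once).
#'
#' @param traj a `trajectory` from [evolve_ghost()] (stride-1 frames are
#'   used).
#' @param plane projection plane.
#' @return a `crossing_record`: `events` (chronological list with `id`,
#'   `links`, `t` = c(ti, tj), `pre_sign` of entry (i, j) before the
#'   flip, `sense` = sign after the flip, `step`, `snapshot` coordinate
#'   matrix), the cumulative matrix `C` (data frame as in
#'   [projection_crossings()] plus `order`), the chain size, and `plane`.
#' @export
detect_true_crossings <- function(traj, plane = "XY") {
  frames <- traj$all_frames
  rest <- traj$start$rest_lengths
  mats <- lapply(frames, function(f) projection_crossings(f, plane))
  events <- list()
  for (k in seq_len(length(frames) - 1L)) {
    m0 <- mats[[k]]; m1 <- mats[[k + 1L]]
    if (nrow(m0) == 0L && nrow(m1) == 0L) next
    key0 <- paste(m0$i, m0$j); key1 <- paste(m1$i, m1$j)
    common <- intersect(key0, key1)
    i0 <- match(common, key0); i1 <- match(common, key1)
    flip <- which(m0$sign_i[i0] * m1$sign_i[i1] < 0)
    for (f in flip) {
      r0 <- m0[i0[f], ]
      geo <- event_geometry(frames[[k]], r0$i, r0$j)
      events[[length(events) + 1L]] <-
        list(links = c(r0$i, r0$j), t = geo$t, gap = geo$gap,
             pre_sign = r0$sign_i, sense = -r0$sign_i, step = k + 1L,
             snapshot = frames[[k]])
    }
    ## a projected crossing created or destroyed between the frames can
    ## hide a sign flip inside the step (it slides off a segment end):
    ## refine those pairs - and near-miss pairs whose intersection sits
    ## just outside a segment at both frames - on interpolated sub-frames
    near <- union(near_pairs(frames[[k]], plane),
                  near_pairs(frames[[k + 1L]], plane))
    cand <- setdiff(union(union(key0, key1), near), common)
    for (key in cand) {
      pq <- as.integer(strsplit(key, " ", fixed = TRUE)[[1L]])
      hit <- refine_flip(frames[[k]], frames[[k + 1L]], pq[1L], pq[2L],
                         plane)
      if (!is.null(hit)) {
        geo <- event_geometry(frames[[k]], pq[1L], pq[2L])
        events[[length(events) + 1L]] <-
          list(links = pq, t = geo$t, gap = geo$gap,
               pre_sign = hit$pre_sign, sense = -hit$pre_sign,
               step = k + 1L, snapshot = frames[[k]])
      }
    }
  }
  ## pairwise cancellation of repeated crossings of the same link pair
  if (length(events)) {
    keys <- vapply(events, function(e) paste(e$links, collapse = "-"), "")
    drop <- logical(length(events))
    for (key in unique(keys)) {
      idx <- which(keys == key)
      if (length(idx) > 1L) {
        ncancel <- 2L * (length(idx) %/% 2L)
        drop[idx[seq_len(ncancel)]] <- TRUE
        warning(sprintf(
          "link pair %s crossed %d times; cancelling %d events pairwise",
          key, length(idx), ncancel))
      }
    }
    events <- events[!drop]
  }
  for (k in seq_along(events)) events[[k]]$id <- k
  cmat <- if (length(events)) {
    data.frame(
      i = vapply(events, function(e) e$links[1L], 0),
      j = vapply(events, function(e) e$links[2L], 0),
      ti = vapply(events, function(e) e$t[1L], 0),
      tj = vapply(events, function(e) e$t[2L], 0),
      sign_i = vapply(events, function(e) e$pre_sign, 0),
      order = seq_along(events))
  } else {
    data.frame(i = integer(), j = integer(), ti = numeric(),
               tj = numeric(), sign_i = numeric(), order = integer())
  }
  structure(list(events = events, C = cmat,
                 n_beads = nrow(frames[[1L]]), rest_lengths = rest,
                 plane = plane),
            class = "crossing_record")
}

## keys of non-adjacent link pairs whose projected intersection lies
## within `margin` outside either segment (candidates for transient
## crossings hidden between frames)
near_pairs <- function(coords, plane, margin = 0.75) {
  ax <- plane_axes(plane)
  p <- coords[, ax$inplane, drop = FALSE]
  l <- nrow(coords) - 1L
  if (l < 3L) return(character())
  pr <- which(upper.tri(matrix(0, l, l)), arr.ind = TRUE)
  pr <- pr[pr[, 2L] - pr[, 1L] >= 2L, , drop = FALSE]
  i <- pr[, 1L]; j <- pr[, 2L]
  a <- p[i, , drop = FALSE];  d1 <- p[i + 1L, , drop = FALSE] - a
  b <- p[j, , drop = FALSE];  d2 <- p[j + 1L, , drop = FALSE] - b
  w <- b - a
  denom <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
  tol <- 1e-12 * max(1, max(abs(p)))
  u <- ifelse(abs(denom) <= tol, NA_real_,
              (w[, 1L] * d2[, 2L] - w[, 2L] * d2[, 1L]) / denom)
  v <- ifelse(abs(denom) <= tol, NA_real_,
              (w[, 1L] * d1[, 2L] - w[, 2L] * d1[, 1L]) / denom)
  hit <- !is.na(u) & u >= -margin & u < 1 + margin &
    v >= -margin & v < 1 + margin
  paste(i[hit], j[hit])
}

## entry of the crossing matrix for one specific link pair, or NULL
pair_entry <- function(coords, i, j, plane) {
  ax <- plane_axes(plane)
  p <- coords[, ax$inplane, drop = FALSE]
  z <- coords[, ax$out]
  a <- p[i, ]; d1 <- p[i + 1L, ] - a
  b <- p[j, ]; d2 <- p[j + 1L, ] - b
  w <- b - a
  denom <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(denom) <= 1e-14 * max(1, max(abs(p)))) return(NULL)
  u <- (w[1L] * d2[2L] - w[2L] * d2[1L]) / denom
  v <- (w[1L] * d1[2L] - w[2L] * d1[1L]) / denom
  if (u < 0 || u >= 1 || v < 0 || v >= 1) return(NULL)
  zi <- z[i] + u * (z[i + 1L] - z[i])
  zj <- z[j] + v * (z[j + 1L] - z[j])
  list(t = c((i - 1) + u, (j - 1) + v), sign_i = if (zi < zj) -1 else 1)
}

## parameters (s, t) of the closest approach of segments p1-p2, q1-q2
segment_closest_params <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-30 && e <= 1e-30) return(c(0, 0))
  if (a <= 1e-30) return(c(0, min(1, max(0, f / e))))
  c1 <- sum(d1 * r)
  if (e <= 1e-30) return(c(min(1, max(0, -c1 / a)), 0))
  b <- sum(d1 * d2)
  den <- a * e - b * b
  s <- if (den > 1e-30) min(1, max(0, (b * f - c1 * e) / den)) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- min(1, max(0, -c1 / a)) }
  else if (t > 1) { t <- 1; s <- min(1, max(0, (b - c1) / a)) }
  c(s, t)
}

## refine an event's encounter parameters to the 3D closest approach of
## its two links on the snapshot (where the passage actually happens,
## independent of the detection plane), and record the gap vector from
## the j-strand to the i-strand there
event_geometry <- function(snapshot, i, j) {
  st <- segment_closest_params(snapshot[i, ], snapshot[i + 1L, ],
                               snapshot[j, ], snapshot[j + 1L, ])
  pi_ <- snapshot[i, ] + st[1L] * (snapshot[i + 1L, ] - snapshot[i, ])
  pj_ <- snapshot[j, ] + st[2L] * (snapshot[j + 1L, ] - snapshot[j, ])
  list(t = c((i - 1) + st[1L], (j - 1) + st[2L]), gap = pi_ - pj_)
}

## minimum distance between 3D segments p1-p2 and q1-q2
segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-30 && e <= 1e-30) return(sqrt(sum(r * r)))
  if (a <= 1e-30) { s <- 0; t <- min(1, max(0, f / e)) }
  else {
    c1 <- sum(d1 * r)
    if (e <= 1e-30) { t <- 0; s <- min(1, max(0, -c1 / a)) }
    else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-30) min(1, max(0, (b * f - c1 * e) / den)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(1, max(0, -c1 / a)) }
      else if (t > 1) { t <- 1; s <- min(1, max(0, (b - c1) / a)) }
    }
  }
  v <- (p1 + s * d1) - (q1 + t * d2)
  sqrt(sum(v * v))
}

## scan linearly interpolated sub-frames for a sign flip of one pair;
## returns the pre-flip entry or NULL.  Pairs whose segments cannot
## touch between the frames (minimum distance exceeding what the bead
## motion allows) are dismissed outright.
refine_flip <- function(f0, f1, i, j, plane, grid = 64L) {
  idx <- c(i, i + 1L, j, j + 1L)
  dmove <- sqrt(max(rowSums((f1[idx, , drop = FALSE] -
                               f0[idx, , drop = FALSE])^2)))
  reach <- 2 * dmove + 1e-12
  if (segment_distance(f0[i, ], f0[i + 1L, ], f0[j, ], f0[j + 1L, ]) > reach &&
      segment_distance(f1[i, ], f1[i + 1L, ], f1[j, ], f1[j + 1L, ]) > reach)
    return(NULL)
  refine_flip_scan(f0, f1, i, j, plane, grid, depth = 3L)
}

## scan interpolated sub-frames for a sign flip between consecutive
## grid points; when the projected crossing exists but no flip resolves,
## re-scan its presence window at finer resolution (narrow post-flip
## windows near a segment end need it)
refine_flip_scan <- function(f0, f1, i, j, plane, grid, depth) {
  prev <- NULL
  pres <- integer()
  for (g in 0:grid) {
    fr <- f0 + (g / grid) * (f1 - f0)
    e <- pair_entry(fr, i, j, plane)
    if (!is.null(e)) {
      pres <- c(pres, g)
      if (!is.null(prev) && prev$sign_i * e$sign_i < 0)
        return(list(t = prev$t, pre_sign = prev$sign_i))
    }
    ## a gap in the projected crossing means any sign change across it
    ## went "through zero" and is not a true crossing
    prev <- e
  }
  if (!length(pres) || depth == 0L) return(NULL)
  lo <- max(0L, min(pres) - 1L) / grid
  hi <- min(grid, max(pres) + 1L) / grid
  if (hi - lo >= 1) return(NULL)        # no further resolution to gain
  g0 <- f0 + lo * (f1 - f0)
  g1 <- f0 + hi * (f1 - f0)
  refine_flip_scan(g0, g1, i, j, plane, grid, depth - 1L)
}

#' @export
print.crossing_record <- function(x, ...) {
  cat(sprintf("<crossing_record> %d true crossing event(s), plane %s\n",
              length(x$events), x$plane))
  if (length(x$events)) print(x$C)
  invisible(x)
}

encounter_table <- function(record, residual) {
  ev <- record$events[residual]
  if (!length(ev))
    return(list(event = integer(), param = numeric(), visit = integer(),
                sense = list()))
  ## sense of the strand at each encounter: the 3D gap vector from the
  ## other strand (negated on the second visit); fabricated records
  ## without a gap fall back to the scalar projection sign
  event <- integer(); param <- numeric(); visit <- integer()
  sense <- list()
  for (e in ev) {
    g <- if (!is.null(e$gap) && sqrt(sum(e$gap^2)) > 1e-12) e$gap
         else c(e$pre_sign, 0, 0)
    event <- c(event, e$id, e$id)
    param <- c(param, e$t)
    visit <- c(visit, 1L, 2L)
    sense <- c(sense, list(g), list(-g))
  }
  ord <- order(param)
  list(event = event[ord], param = param[ord], visit = visit[ord],
       sense = sense[ord])
}

#' Identify uncrossing substructures among residual events
#'
#' Enumerates, for the residual (not-yet-reversed) crossing events of a
#' record: the start/end legs of every event, loops (events whose two
#' encounters are consecutive among residual encounters along the chain),
#' and elbows (event pairs whose four encounters pair up into two
#' chain-adjacent same-sense pairs; the longer-arc pair segment is the
#' elbow, the other the obstruction).
#'
#' @param record a `crossing_record`.
#' @param residual integer vector of residual event ids (defaults to all).
#' @return list of substructures, each with `kind` (`start_leg`,
#'   `end_leg`, `loop`, `elbow`), `events`, and chain-parameter `span`
#'   (legs/loops) or `span` + `obstruction` intervals (elbows).
#' @export
find_substructures <- function(record,
                               residual = vapply(record$events,
                                                 `[[`, 0L, "id")) {
  out <- list()
  enc <- encounter_table(record, residual)
  if (!length(enc$param)) return(out)
  l_total <- record$n_beads - 1
  for (id in residual) {
    e <- record$events[[id]]
    out[[length(out) + 1L]] <- list(kind = "start_leg", events = id,
                                    span = c(0, e$t[1L]))
    out[[length(out) + 1L]] <- list(kind = "end_leg", events = id,
                                    span = c(e$t[2L], l_total))
    pos <- which(enc$event == id)
    if (diff(pos) == 1L)
      out[[length(out) + 1L]] <- list(kind = "loop", events = id,
                                      span = c(e$t[1L], e$t[2L]))
  }
  ## elbows: unordered residual event pairs
  if (length(residual) >= 2L) {
    for (a in seq_along(residual)[-length(residual)]) {
      for (b in seq((a + 1L), length(residual))) {
        ea <- residual[a]; eb <- residual[b]
        pos <- sort(which(enc$event %in% c(ea, eb)))
        ## the four encounters must pair up into two chain-adjacent
        ## cross-event pairs: (p1,p2) and (p3,p4)
        ok <- pos[2L] == pos[1L] + 1L && pos[4L] == pos[3L] + 1L &&
          enc$event[pos[1L]] != enc$event[pos[2L]] &&
          enc$event[pos[3L]] != enc$event[pos[4L]]
        ## same over-under sense: the strand passes on the same side of
        ## the obstruction at both crossings (gap vectors aligned)
        if (ok && sum(enc$sense[[pos[1L]]] * enc$sense[[pos[2L]]]) > 0) {
          iv <- list(range(enc$param[pos[1:2]]), range(enc$param[pos[3:4]]))
          long <- which.max(vapply(iv, diff, 0))
          out[[length(out) + 1L]] <-
            list(kind = "elbow", events = c(ea, eb),
                 span = iv[[long]], obstruction = iv[[3L - long]])
        }
      }
    }
  }
  out
}

## position of chain parameter t on a coordinate matrix
point_at_param <- function(coords, t) {
  l <- nrow(coords) - 1L
  k <- min(max(floor(t), 0), l - 1)          # link index - 1
  frac <- t - k
  coords[k + 1L, ] + frac * (coords[k + 2L, ] - coords[k + 1L, ])
}

## bead indices strictly inside a chain-parameter interval
beads_inside <- function(span, n) {
  k <- seq_len(n)
  k[(k - 1) > span[1L] & (k - 1) < span[2L]]
}

## bead indices of a leg: terminus up to (not including) the root param
beads_of_leg <- function(root_param, n, side) {
  k <- seq_len(n)
  if (side == "start") k[(k - 1) < root_param] else k[(k - 1) > root_param]
}
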