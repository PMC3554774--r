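## Shared fixtures and independent oracles, built in code at test time.

## Horn's closed-form quaternion superposition: an oracle independent of
## the package's SVD-based Kabsch implementation.
quaternion_rmsd_fit <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  s <- crossprod(xc, yc)
  k <- matrix(0, 4, 4)
  k[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  k[1, 2] <- k[2, 1] <- s[2, 3] - s[3, 2]
  k[1, 3] <- k[3, 1] <- s[3, 1] - s[1, 3]
  k[1, 4] <- k[4, 1] <- s[1, 2] - s[2, 1]
  k[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  k[2, 3] <- k[3, 2] <- s[1, 2] + s[2, 1]
  k[2, 4] <- k[4, 2] <- s[1, 3] + s[3, 1]
  k[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  k[3, 4] <- k[4, 3] <- s[2, 3] + s[3, 2]
  k[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sum(xc^2) + sum(yc^2) - 2 * lam
  sqrt(max(0, e2) / nrow(x))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_chain <- function(n, sd = 1) {
  chain(matrix(cumsum(rnorm(3 * n, sd = sd)), n, 3))
}

## synthetic crossing records with fabricated snapshots: exercise the
## uncrossing operator algebra and search without a trajectory
make_random_record <- function(n_events, n_beads, seed) {
  set.seed(seed)
  l <- n_beads - 1L
  pairs <- which(upper.tri(matrix(0, l, l)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 2, , drop = FALSE]
  sel <- pairs[sample(nrow(pairs), n_events), , drop = FALSE]
  events <- lapply(seq_len(n_events), function(k) {
    i <- sel[k, 1]; j <- sel[k, 2]
    list(links = c(i, j),
         t = c(i - 1 + runif(1, 0.05, 0.95), j - 1 + runif(1, 0.05, 0.95)),
         pre_sign = sample(c(-1, 1), 1), sense = NA_real_, step = k,
         snapshot = matrix(cumsum(rnorm(n_beads * 3, sd = 0.6)),
                           n_beads, 3),
         id = k)
  })
  structure(list(events = events, C = NULL, n_beads = n_beads,
                 rest_lengths = rep(1, l), plane = "XY"),
            class = "crossing_record")
}

## plain recursive enumeration of every move sequence - the oracle for
## the branch-and-bound search (no pruning, no dedup)
exhaustive_min_cost <- function(record) {
  ids <- vapply(record$events, `[[`, 0L, "id")
  rec_fun <- function(residual, acc) {
    if (!length(residual)) return(acc)
    best <- Inf
    for (m in applicable_moves(record, residual))
      best <- min(best, rec_fun(setdiff(residual, m$events), acc + m$cost))
    best
  }
  rec_fun(ids, 0)
}

## a crossing record built by hand: one event on an explicit snapshot
manual_record <- function(links, t, pre_sign, snapshot,
                          rest = rep(1, nrow(snapshot) - 1)) {
  ev <- list(list(links = links, t = t, pre_sign = pre_sign,
                  sense = -pre_sign, step = 2L, snapshot = snapshot,
                  id = 1L))
  structure(list(events = ev, C = NULL, n_beads = nrow(snapshot),
                 rest_lengths = rest, plane = "XY"),
            class = "crossing_record")
}

## three-residue synthetic PDB text with an altLoc pair on residue 2
altloc_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA AGLY A   2       4.800   0.000   0.000  0.60  0.00           C",
    "ATOM      4  CA BGLY A   2       4.900   0.500   0.000  0.40  0.00           C",
    "ATOM      5  CA  ALA A   3       8.600   0.000   0.000  1.00  0.00           C",
    "ATOM      6  O   HOH A   9      99.000  99.000  99.000  1.00  0.00           O",
    "END")
}

## scaled trefoil posing as a knotted C-alpha trace (3.8 A links)
knotted_native <- function(n = 34) {
  tre <- open_trefoil(n)
  chain(tre$coords * 3.8, label = "synthetic-trefoil")
}

## two independent crossing episodes in disjoint chain regions - the
## shape of a two-stage transformation whose stagewise repairs remain
## valid in the joint record
make_two_stage_record <- function(seed) {
  set.seed(seed)
  n_beads <- 14L
  mk_ev <- function(id, links_pool) {
    ij <- sort(sample(links_pool, 2))
    while (ij[2] - ij[1] < 2) ij <- sort(sample(links_pool, 2))
    list(links = ij,
         t = c(ij[1] - 1 + runif(1, .05, .95),
               ij[2] - 1 + runif(1, .05, .95)),
         pre_sign = sample(c(-1, 1), 1), sense = NA_real_, step = id,
         snapshot = matrix(cumsum(rnorm(n_beads * 3, sd = 0.6)),
                           n_beads, 3),
         id = id)
  }
  ev <- list(mk_ev(1L, 1:6), mk_ev(2L, 1:6),
             mk_ev(3L, 8:13), mk_ev(4L, 8:13))
  structure(list(events = ev, C = NULL, n_beads = n_beads,
                 rest_lengths = rep(1, n_beads - 1L), plane = "XY"),
            class = "crossing_record")
}
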