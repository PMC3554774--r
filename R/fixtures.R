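## Synthetic chains and tangles: everything the pipeline needs for
## testing and calibration without any structure downloads.

#' Random self-avoiding walk chain
#'
#' Continuum hard-sphere SAW with unit links: an unbiased (zero
#' stiffness) pivot walk started from a straight chain, accepting only
#' conformations whose non-neighbor bead pairs are at least one link
#' length apart.
#'
#' @param n_links number of links (N = n_links + 1 beads).
#' @param seed integer seed.
#' @param n_pivot accepted pivot moves (default 3(N-2)).
#' @return a `chain` with unit links.
#' @export
random_saw <- function(n_links, seed = 1L, n_pivot = NULL) {
  n <- n_links + 1L
  straight <- chain(cbind(0:(n - 1L), 0, 0), label = "saw")
  if (n < 4L) return(straight)
  if (is.null(n_pivot)) n_pivot <- 3L * (n - 2L)
  spec <- ensemble_spec(n_structures = 1L, n_pivot = n_pivot, k_theta = 0,
                        k_phi1 = 0, k_phi3 = 0, steric_cutoff = 1,
                        seed = seed)
  ang <- native_internal_angles(straight)
  pivot_walk(straight, ang, n_pivot, spec, derive_seed(seed, 1L))
}

## equal-chord resampling of a dense curve; chords equal to ~1e-12
equal_chord_resample <- function(dense, n_beads) {
  seg <- diff(dense)
  arc <- sum(sqrt(rowSums(seg * seg)))
  place <- function(cl) {
    pts <- matrix(NA_real_, n_beads, 3L)
    pts[1L, ] <- dense[1L, ]
    cur <- dense[1L, ]; idx <- 1L
    for (k in 2:(n_beads)) {
      ## first dense vertex at distance >= cl from cur
      while (idx < nrow(dense) &&
             sqrt(sum((dense[idx + 1L, ] - cur)^2)) < cl) idx <- idx + 1L
      if (idx >= nrow(dense)) return(list(ok = FALSE, short = TRUE))
      a <- dense[idx, ]; b <- dense[idx + 1L, ]
      lo <- 0; hi <- 1
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (sqrt(sum((a + mid * (b - a) - cur)^2)) < cl) lo <- mid
        else hi <- mid
      }
      cur <- a + hi * (b - a)
      pts[k, ] <- cur
      if (k < n_beads) {
        ## ensure forward progress for the next search
        if (sqrt(sum((dense[idx + 1L, ] - cur)^2)) < 1e-14) idx <- idx + 1L
      }
    }
    list(ok = TRUE, pts = pts,
         miss = sqrt(sum((cur - dense[nrow(dense), ])^2)))
  }
  lo <- arc / (n_beads * 4); hi <- arc / (n_beads - 1L) * 1.5
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    r <- place(mid)
    if (!r$ok) hi <- mid else lo <- mid
  }
  r <- place(lo)
  pts <- r$pts
  pts[n_beads, ] <- dense[nrow(dense), ]
  pts
}

#' Open trefoil chain
#'
#' An open polyline tracing the parametric trefoil curve, resampled to
#' equal unit links.  Straightening it as a ghost chain necessarily
#' produces at least one true crossing and a positive uncrossing
#' distance.
#'
#' @param n_beads number of beads (>= 20 recommended so the knot
#'   survives the discretization).
#' @return a `chain` with (near-machine) equal unit links.
#' @export
open_trefoil <- function(n_beads = 30L) {
  t <- seq(0.15, 2 * pi - 0.15, length.out = 20000L)
  dense <- cbind(sin(t) + 2 * sin(2 * t),
                 cos(t) - 2 * cos(2 * t),
                 -sin(3 * t))
  pts <- equal_chord_resample(dense, n_beads)
  cl <- sqrt(sum((pts[2L, ] - pts[1L, ])^2))
  chain(pts / cl, rest_lengths = rep(1, n_beads - 1L), label = "trefoil")
}

#' Conformation pair whose ghost transformation crosses itself twice
#'
#' A constructed 7-link chain pair: evolving A to B as a ghost chain
#' yields exactly two true crossing events, the link pair (5, 7) first
#' and (2, 4) second.
#'
#' @param validate re-run the detection pipeline and stop if the
#'   constructed pair does not reproduce the expected events.
#' @return list with chains `a` and `b`.
#' @export
two_crossing_fixture <- function(validate = FALSE) {
  a <- chain(two_crossing_coords$a, label = "fixture-A")
  b <- chain(two_crossing_coords$b, rest_lengths = a$rest_lengths,
             label = "fixture-B")
  if (validate) {
    traj <- evolve_ghost(a, b, transform_spec(delta = 0.02))
    rec <- detect_true_crossings(traj)
    links <- lapply(rec$events, function(e) as.integer(e$links))
    if (length(rec$events) != 2L ||
        !identical(links[[1L]], c(5L, 7L)) ||
        !identical(links[[2L]], c(2L, 4L)))
      stop("two_crossing_fixture failed validation")
  }
  list(a = a, b = b)
}

#' Ideal C-alpha helix trace
#'
#' Standard alpha-helix C-alpha geometry: radius 2.3 A, rise 1.5 A per
#' residue, 100 degrees per turn.
#'
#' @param n residues.
#' @return a `chain` in Angstrom, label `"synthetic-helix"`.
#' @export
synthetic_helix <- function(n = 24L) {
  i <- seq_len(n) - 1L
  ang <- i * 100 * pi / 180
  chain(cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i),
        label = "synthetic-helix")
}

#' Synthetic beta-hairpin C-alpha trace
#'
#' Two antiparallel extended strands (3.4 A rise, alternating 1.0 A
#' pleat) joined by a short turn, 4.8 A apart.
#'
#' @param n residues (>= 8).
#' @return a `chain` in Angstrom, label `"synthetic-hairpin"`.
#' @export
synthetic_hairpin <- function(n = 24L) {
  m <- (n - 2L) %/% 2L                       # residues per strand
  i <- seq_len(m) - 1L
  s1 <- cbind(3.4 * i, 1.0 * (i %% 2), 0)
  top <- max(3.4 * i)
  turn <- rbind(c(top + 2.4, 2.4, 1.2), c(top + 2.4, 2.4, 3.6))
  i2 <- seq_len(n - m - 2L) - 1L
  s2 <- cbind(top - 3.4 * i2, 1.0 * (i2 %% 2), 4.8)
  chain(rbind(s1, turn, s2), label = "synthetic-hairpin")
}

helix_segment <- function(n, origin = c(0, 0, 0), dir = 1, phase = 0) {
  i <- seq_len(n) - 1L
  ang <- phase + dir * i * 100 * pi / 180
  cbind(2.3 * cos(ang) + origin[1L], 2.3 * sin(ang) + origin[2L],
        origin[3L] + dir * 1.5 * i)
}

#' Synthetic three-helix bundle C-alpha trace
#'
#' Three antiparallel ideal helices joined by two-residue loops - a
#' minimal all-alpha fold with genuine tertiary structure, used to
#' exercise the pathway analyses without structure downloads.
#'
#' @param n_helix residues per helix (default 12; total 3 n_helix + 4).
#' @return a `chain` in Angstrom, label `"synthetic-bundle"`.
#' @export
synthetic_helix_bundle <- function(n_helix = 12L) {
  h1 <- helix_segment(n_helix)
  z1 <- h1[n_helix, 3L]
  l1 <- cbind(c(4.5, 8.0), c(1.5, 0.5), c(z1 + 2.2, z1 + 0.8))
  h2 <- helix_segment(n_helix, c(10, 3, z1), -1, phase = 2)
  z2 <- h2[n_helix, 3L]
  l2 <- cbind(c(8.0, 5.0), c(6.5, 8.0), c(z2 - 1.5, z2 - 0.5))
  h3 <- helix_segment(n_helix, c(4, 10, z2), 1, phase = 4)
  chain(rbind(h1, l1, h2, l2, h3), label = "synthetic-bundle")
}

#' Synthetic four-strand beta-meander C-alpha trace
#'
#' Four antiparallel extended strands (3.3 A rise, 1 A pleat, 4.8 A
#' strand spacing) joined by single-residue turns.
#'
#' @param n_strand residues per strand (default 7; total 4 n_strand + 3).
#' @return a `chain` in Angstrom, label `"synthetic-sheet"`.
#' @export
synthetic_beta_sheet <- function(n_strand = 7L) {
  i <- seq_len(n_strand) - 1L
  strand <- function(k, rev) {
    x <- if (rev) 3.3 * (n_strand - 1L) - 3.3 * i else 3.3 * i
    cbind(x, 1.0 * (i %% 2), 4.8 * k)
  }
  turn <- function(k, xend) cbind(xend, 3.3, 4.8 * k + 2.4)
  xhi <- 3.3 * (n_strand - 1L) + 2.8
  chain(rbind(strand(0, FALSE), turn(0, xhi), strand(1, TRUE),
              turn(1, -2.8), strand(2, FALSE), turn(2, xhi),
              strand(3, TRUE)),
        label = "synthetic-sheet")
}

#' Synthetic PDB text for a C-alpha chain
#'
#' Writes ATOM records for each bead as a CA atom plus an outward-facing
#' pseudo side-chain CB, giving the parsers and heavy-atom contact code
#' something realistic to chew on.  Purely synthetic; the file name
#' should carry a `synthetic` label.
#'
#' @param x a `chain` in Angstrom.
#' @param chain_id PDB chain identifier.
#' @param cb add CB pseudo-atoms (default TRUE).
#' @return character vector of PDB lines.
#' @export
synthetic_pdb_text <- function(x, chain_id = "A", cb = TRUE) {
  co <- x$coords
  n <- nrow(co)
  centre <- colMeans(co)
  lines <- character()
  serial <- 0L
  for (k in seq_len(n)) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, chain_id, k, co[k, 1L], co[k, 2L], co[k, 3L]))
    if (cb) {
      out <- co[k, ] - centre
      nrm <- sqrt(sum(out * out))
      out <- if (nrm > 1e-9) out / nrm else c(1, 0, 0)
      p <- co[k, ] + 1.5 * out
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CB  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, chain_id, k, p[1L], p[2L], p[3L]))
    }
  }
  c(lines, "END")
}
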