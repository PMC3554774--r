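test_that("internal angles match an independent vector-algebra oracle", {
  oracle_theta <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  oracle_phi <- function(p1, p2, p3, p4) {
    ## Gram-Schmidt construction, independent of the atan2 route
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n2 <- b2 / sqrt(sum(b2^2))
    ## half-planes: the first arm points from p2 back toward p1
    v <- -(b1 - sum(b1 * n2) * n2)
    w <- b3 - sum(b3 * n2) * n2
    ang <- acos(max(-1, min(1, sum(v * w) / sqrt(sum(v^2) * sum(w^2)))))
    ## sign from the handedness of (v, w, b2); the convention here is
    ## phi > 0 when (v x w) points along b2... compare both branches
    s <- sign(sum(cross_oracle(v, w) * n2))
    -s * ang
  }
  cross_oracle <- function(a, b)
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  set.seed(31)
  for (k in 1:100) {
    x <- random_chain(6)
    ang <- native_internal_angles(x)
    for (i in 2:5)
      expect_equal(ang$theta[i - 1],
                   oracle_theta(x$coords[i - 1, ], x$coords[i, ],
                                x$coords[i + 1, ]), tolerance = 1e-10)
    for (i in 2:4)
      expect_equal(abs(ang$phi[i - 1]),
                   abs(oracle_phi(x$coords[i - 1, ], x$coords[i, ],
                                  x$coords[i + 1, ], x$coords[i + 2, ])),
                   tolerance = 1e-10)
  }
  ## planar zigzag: theta = pi/2, trans dihedral |phi| = pi
  zig <- chain(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0),
                     c(2, 2, 0)))
  ang <- native_internal_angles(zig)
  expect_equal(ang$theta, rep(pi / 2, 3), tolerance = 1e-12)
  expect_equal(abs(ang$phi), rep(pi, 2), tolerance = 1e-12)
  ## straight chain: dihedrals undefined and flagged
  line <- chain(cbind(0:4, 0, 0))
  angl <- native_internal_angles(line)
  expect_true(all(is.na(angl$phi)))
  expect_false(any(angl$defined_phi))
})

test_that("bond-angle sampler matches quadrature and its limits", {
  expect_equal(sample_bond_angle(1.1, Inf, 1, n = 5), rep(1.1, 5))
  set.seed(37)
  s <- sample_bond_angle(1.8, 20, 1, n = 2e4)
  g <- seq(1e-5, pi - 1e-5, length.out = 20001)
  d <- exp(-20 * (g - 1.8)^2)
  m <- sum(g * d) / sum(d)
  v <- sum((g - m)^2 * d) / sum(d)
  expect_equal(mean(s), m, tolerance = 4 * sqrt(v / length(s)) / m)
  expect_equal(var(s), v, tolerance = 0.05)
  s0 <- sample_bond_angle(1.0, 0, 1, n = 2e4)   # uniform limit
  expect_equal(mean(s0), pi / 2, tolerance = 0.03)
  expect_gt(min(s0), 0); expect_lt(max(s0), pi)
})

test_that("dihedral sampler is periodic, centred, and uniform at zero k", {
  expect_equal(sample_dihedral(0.5, Inf, Inf, 1, n = 3), rep(0.5, 3))
  set.seed(41)
  s <- sample_dihedral(2.0, 1, 0.5, 1, n = 2e4)
  circ_mean <- atan2(mean(sin(s)), mean(cos(s)))
  expect_equal(circ_mean, 2.0, tolerance = 0.05)
  ## chi-squared against quadrature of the density
  g <- seq(-pi + 1e-6, pi - 1e-6, length.out = 2001)
  dens <- exp(-(1 * (1 - cos(g - 2)) + 0.5 * (1 - cos(3 * (g - 2)))))
  breaks <- seq(-pi, pi, length.out = 21)
  obs <- table(cut(s, breaks))
  pexp <- vapply(seq_len(20), function(b) {
    sel <- g >= breaks[b] & g < breaks[b + 1]
    sum(dens[sel])
  }, 0)
  pexp <- pexp / sum(pexp)
  pval <- suppressWarnings(chisq.test(as.vector(obs), p = pexp)$p.value)
  expect_gt(pval, 1e-4)
  s0 <- sample_dihedral(1.0, 0, 0, 1, n = 2e4)  # uniform limit
  expect_lt(abs(mean(s0 > 0) - 0.5), 0.02)
})

test_that("pivot moves hit the requested angles and preserve geometry", {
  set.seed(43)
  x <- random_saw(9, seed = 3)
  for (trial in 1:30) {
    i <- sample(2:9, 1)
    nt <- runif(1, 0.2, pi - 0.2)
    np <- if (i <= 8) runif(1, -pi, pi) else NULL
    y <- apply_pivot(x, i, nt, np)
    ang <- native_internal_angles(y)
    expect_equal(ang$theta[i - 1], nt, tolerance = 1e-9)
    if (i <= 7) expect_equal(ang$phi[i - 1], np, tolerance = 1e-9)
    expect_lt(max(abs(link_lengths(y) - link_lengths(x))), 1e-9)
    expect_equal(y$coords[1:i, ], x$coords[1:i, ])   # upstream untouched
  }
  ## identity pivot leaves the chain unchanged
  ang0 <- native_internal_angles(x)
  y0 <- apply_pivot(x, 5, ang0$theta[4], ang0$phi[4])
  expect_lt(max(abs(y0$coords - x$coords)), 1e-12)
  expect_error(apply_pivot(x, 1, 1), "interior")
})

test_that("ensemble generation honors its limits, sterics and seed", {
  hx <- synthetic_helix(16)
  st <- read_calpha_trace(synthetic_pdb_text(hx))
  ct <- native_contact_set(st)
  bl <- representative_link_length(st)
  native <- rescale_chain(st$calpha, bl)
  cut <- steric_cutoff(st, ct) / bl
  ## infinite stiffness: rigid, native retained
  rigid <- generate_unfolded(native, ct,
                             ensemble_spec(3, k_theta = Inf, k_phi1 = Inf,
                                           k_phi3 = Inf,
                                           steric_cutoff = cut, seed = 5))
  expect_lt(max(vapply(rigid$conformations,
                       function(c) rmsd(c, native), 0)), 1e-9)
  expect_equal(rigid$q_values, rep(1, 3))
  ## default stiffness: links conserved, sterics respected, reproducible
  ens <- generate_unfolded(native, ct,
                           ensemble_spec(4, steric_cutoff = cut, seed = 6))
  for (c in ens$conformations) {
    expect_lt(max(abs(link_lengths(c) - native$rest_lengths)), 1e-9)
    expect_gte(foldnx:::min_nonneighbor_distance(c$coords), cut - 1e-9)
  }
  ens2 <- generate_unfolded(native, ct,
                            ensemble_spec(4, steric_cutoff = cut, seed = 6))
  expect_identical(ens$conformations[[3]]$coords,
                   ens2$conformations[[3]]$coords)
})

test_that("unfolding deepens with the number of accepted pivots", {
  ## 58-residue three-helix bundle, 50 structures per ensemble: the
  ## ensemble-mean aligned RMSD to the native grows through the
  ## unfolding regime (N/8, N/4, N pivots) and then plateaus at the
  ## random-coil level (3N pivots) rather than shrinking back
  bun <- synthetic_helix_bundle(18L)
  st <- read_calpha_trace(synthetic_pdb_text(bun))
  ct <- native_contact_set(st)
  bl <- representative_link_length(st)
  native <- rescale_chain(st$calpha, bl)
  cut <- steric_cutoff(st, ct) / bl
  n <- n_beads(native)
  ms <- vapply(c(n %/% 8L, n %/% 4L, n, 3L * n), function(np) {
    e <- generate_unfolded(native, ct,
                           ensemble_spec(50, n_pivot = np,
                                         steric_cutoff = cut, seed = 7))
    mean(vapply(e$conformations,
                function(c) align_rmsd(c, native)$rmsd, 0))
  }, 0)
  expect_true(all(diff(ms[1:3]) > 0))
  expect_equal(ms[4], ms[3], tolerance = 0.05)
})

test_that("fraction of native contacts agrees with a brute-force scan", {
  hx <- synthetic_helix(14)
  st <- read_calpha_trace(synthetic_pdb_text(hx))
  ct <- native_contact_set(st)
  native <- rescale_chain(st$calpha, representative_link_length(st))
  expect_equal(fraction_native_contacts(native, native, ct), 1)
  ext <- chain(cbind(0:(n_beads(native) - 1), 0, 0), native$rest_lengths)
  expect_lt(fraction_native_contacts(ext, native, ct), 0.05)
  set.seed(47)
  conf <- chain(native$coords + matrix(rnorm(nrow(native$coords) * 3,
                                             sd = 0.5), ncol = 3),
                native$rest_lengths)
  q <- fraction_native_contacts(conf, native, ct)
  formed <- 0
  for (r in seq_len(nrow(ct$pairs))) {
    i <- ct$pairs[r, 1]; j <- ct$pairs[r, 2]
    dn <- sqrt(sum((native$coords[i, ] - native$coords[j, ])^2))
    dc <- sqrt(sum((conf$coords[i, ] - conf$coords[j, ])^2))
    if (dc <= 1.2 * dn) formed <- formed + 1
  }
  expect_equal(q, formed / nrow(ct$pairs))
})

test_that("random SAWs are self-avoiding with unit links", {
  for (k in 1:30) {
    w <- random_saw(9, seed = 500 + k)
    expect_equal(link_lengths(w), rep(1, 9), tolerance = 1e-9)
    expect_gte(foldnx:::min_nonneighbor_distance(w$coords), 1 - 1e-9)
  }
  expect_equal(n_beads(random_saw(1, seed = 1)), 2L)
})
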