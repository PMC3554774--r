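test_that("projection crossings carry the hand-computed parameters and signs", {
  ## 3-link chain: link 3 passes over link 1 at one third of link 1
  ch <- chain(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(1, -1, 1)))
  m <- projection_crossings(ch)
  expect_equal(nrow(m), 1L)
  expect_equal(m$i, 1); expect_equal(m$j, 3)
  expect_equal(m$ti, 2 / 3, tolerance = 1e-12)
  expect_equal(m$tj, 8 / 3, tolerance = 1e-12)
  expect_equal(m$sign_i, -1)            # link 1 under link 3
  ## planar chain in the projection plane without intersections
  flat <- chain(cbind(c(0, 1, 2, 3), c(0, 1, 0, 1), 0))
  expect_equal(nrow(projection_crossings(flat)), 0L)
  ## antisymmetry is encoded: the (j, i) entry is the sign flip of (i, j)
  expect_error(projection_crossings(ch, "AB"), "plane")
})

test_that("true crossings require a sign flip, not entry churn", {
  ## identical projection, flipped over-under sense: exactly one event
  ch1 <- chain(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(1, -1, 1)))
  ch2 <- chain(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(1, -1, -1)),
               ch1$rest_lengths)
  fake <- list(all_frames = list(ch1$coords, ch2$coords), start = ch1)
  rec <- detect_true_crossings(fake)
  expect_length(rec$events, 1L)
  expect_equal(rec$events[[1]]$links, c(1, 3))
  expect_equal(rec$events[[1]]$pre_sign, -1)
  expect_identical(rec$events[[1]]$snapshot, ch1$coords)  # pre-flip frame
  ## rigid translation: no events
  a <- random_saw(7, seed = 77)
  b <- chain(sweep(a$coords, 2, -c(1, 1, 0)), a$rest_lengths)
  expect_length(detect_true_crossings(evolve_ghost(a, b))$events, 0L)
})

test_that("a crossing undone by a later recrossing cancels pairwise", {
  ## flip and flip back across three frames: zero net events
  ch1 <- chain(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(1, -1, 1)))
  ch2 <- chain(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(1, -1, -1)),
               ch1$rest_lengths)
  fake <- list(all_frames = list(ch1$coords, ch2$coords, ch1$coords),
               start = ch1)
  expect_warning(rec <- detect_true_crossings(fake), "cancelling")
  expect_length(rec$events, 0L)
})

test_that("the constructed two-crossing pair reproduces its C and O matrices", {
  fx <- two_crossing_fixture(validate = TRUE)
  tr <- evolve_ghost(fx$a, fx$b)
  rec <- detect_true_crossings(tr)
  expect_length(rec$events, 2L)
  expect_equal(rec$C$i, c(5, 2))
  expect_equal(rec$C$j, c(7, 4))
  expect_equal(rec$C$order, c(1, 2))     # (5,7) crossed first
  ## doubling the frame rate leaves the event multiset unchanged
  tr2 <- evolve_ghost(fx$a, fx$b, transform_spec(0.01))
  rec2 <- detect_true_crossings(tr2)
  expect_equal(lapply(rec2$events, `[[`, "links"),
               lapply(rec$events, `[[`, "links"))
})

test_that("substructures: legs always, loops when consecutive, elbows same-sense", {
  ## single event with encounters at 1.2 and 2.7 on a 5-link chain
  snap <- matrix(cumsum(rnorm(18)), 6, 3)
  rec <- manual_record(c(2, 3), c(1.2, 2.7), -1, snap)
  subs <- find_substructures(rec)
  kinds <- vapply(subs, `[[`, "", "kind")
  expect_setequal(kinds, c("start_leg", "end_leg", "loop"))
  loop <- subs[[which(kinds == "loop")]]
  expect_equal(loop$span, c(1.2, 2.7))
  expect_equal(subs[[which(kinds == "start_leg")]]$span, c(0, 1.2))
  expect_equal(subs[[which(kinds == "end_leg")]]$span, c(2.7, 5))
  expect_length(find_substructures(rec, integer()), 0L)
})

test_that("interleaved same-sense pairs form elbows over the longer arc", {
  set.seed(61)
  snap <- matrix(cumsum(rnorm(36)), 12, 3)
  mk2 <- function(s1, s2) {
    ev <- list(list(links = c(2, 5), t = c(1.5, 4.5), pre_sign = s1,
                    sense = -s1, step = 1L, snapshot = snap, id = 1L),
               list(links = c(3, 6), t = c(2.5, 5.5), pre_sign = s2,
                    sense = -s2, step = 2L, snapshot = snap, id = 2L))
    structure(list(events = ev, C = NULL, n_beads = 12L,
                   rest_lengths = rep(1, 11), plane = "XY"),
              class = "crossing_record")
  }
  ## same sense: encounters pair as (1.5, 2.5) and (4.5, 5.5); the elbow
  ## is the longer-arc pair segment
  subs <- find_substructures(mk2(-1, -1))
  elb <- Filter(function(s) s$kind == "elbow", subs)
  expect_length(elb, 1L)
  expect_equal(sort(c(elb[[1]]$span, elb[[1]]$obstruction)),
               c(1.5, 2.5, 4.5, 5.5))
  expect_equal(diff(elb[[1]]$span), 1)
  ## opposite senses: no elbow
  expect_length(Filter(function(s) s$kind == "elbow",
                       find_substructures(mk2(-1, 1))), 0L)
  ## loops are judged on the residual set: with both events live the
  ## encounters interleave (1.5 < 2.5 < 4.5 < 5.5 is NOT consecutive for
  ## event 1), so event 1 has no loop until event 2 is reversed
  kinds_full <- vapply(find_substructures(mk2(-1, -1)), `[[`, "", "kind")
  expect_false("loop" %in% kinds_full)
  subs_resid <- find_substructures(mk2(-1, -1), residual = 1L)
  expect_true("loop" %in% vapply(subs_resid, `[[`, "", "kind"))
})

test_that("event sets and uncrossing distance agree across projection planes", {
  found <- 0L
  for (k in 1:12) {
    p <- random_saw(12, seed = 700 + k)
    q <- random_saw(12, seed = 800 + k)
    al <- align_mrsd(p, q)
    tr <- evolve_ghost(al$fitted, q)
    sets <- character(); ds <- numeric()
    for (pl in c("XY", "XZ", "YZ")) {
      rec <- suppressWarnings(detect_true_crossings(tr, pl))
      ev <- vapply(rec$events, function(e) paste(e$links, collapse = "-"),
                   "")
      sets <- c(sets, paste(sort(ev), collapse = ";"))
      ds <- c(ds, uncrossing_distance(rec))
    }
    expect_equal(sets[2], sets[1]); expect_equal(sets[3], sets[1])
    if (nzchar(sets[1])) {
      found <- found + 1L
      expect_equal(ds[2], ds[1], tolerance = 0.05)
      expect_equal(ds[3], ds[1], tolerance = 0.05)
    }
  }
  expect_gte(found, 1L)   # at least one fixture actually crossed
})
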