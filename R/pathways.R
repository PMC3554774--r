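## Transformation records, consensus pathway histograms, representative
## transformations, and the pathway-overlap order parameter chi.

#' Compute one minimal folding transformation
#'
#' Runs the whole machinery for one unfolded-to-native pair: MRSD
#' alignment, optional every-other-bead coarse-graining (with the native
#' as rest-length reference), ghost evolution, true-crossing detection,
#' and the minimal uncrossing search.
#'
#' @param unfolded,native `chain`s in link-length units.
#' @param spec a [transform_spec()].
#' @param coarse_grain coarse-grain both chains before evolving
#'   (default TRUE, removing crossings with loops/elbows under three
#'   original links).
#' @param plane projection plane for crossing detection.
#' @param id free-text identifier for the record.
#' @return a `transformation_record`: `id`, `mrsd`, `rmsd` (full
#'   resolution, aligned), `d_ghost`, `d_nx`, `n_events`, `moves` (each
#'   with `kind`, `events`, `span`, `cost`), `notation`.
#' @export
transformation_record <- function(unfolded, native,
                                  spec = transform_spec(),
                                  coarse_grain = TRUE, plane = "XY",
                                  id = unfolded$label) {
  al_r <- align_rmsd(unfolded, native)
  al <- align_mrsd(unfolded, native)
  mob <- al$fitted
  nat <- native
  if (coarse_grain) {
    mob <- coarse_grain_every_other(mob, reference = native)
    nat <- coarse_grain_every_other(native, reference = native)
  } else {
    mob <- chain(mob$coords, nat$rest_lengths, mob$label)
  }
  traj <- evolve_ghost(mob, nat, spec)
  record <- detect_true_crossings(traj, plane)
  un <- minimal_uncrossing(record)
  structure(list(id = id, mrsd = al$mrsd, rmsd = al_r$rmsd,
                 d_ghost = ghost_distance(traj)$total, d_nx = un$d_nx,
                 n_events = length(record$events),
                 moves = lapply(un$moves, function(m)
                   m[c("kind", "events", "span", "cost")]),
                 notation = un$notation),
            class = "transformation_record")
}

#' @export
print.transformation_record <- function(x, ...) {
  cat(sprintf(
    "<transformation_record> %s: mrsd %.3g, d_ghost %.4g, d_nx %.4g (%s)\n",
    x$id, x$mrsd, x$d_ghost, x$d_nx,
    if (nzchar(x$notation)) x$notation else "no uncrossing needed"))
  invisible(x)
}

#' Transformations for a whole unfolded ensemble
#'
#' @param ensemble an `unfolded_ensemble` (chains in link-length units).
#' @param ... passed to [transformation_record()].
#' @return list of `transformation_record`s.
#' @export
ensemble_transformations <- function(ensemble, ...) {
  lapply(seq_along(ensemble$conformations), function(k)
    transformation_record(ensemble$conformations[[k]], ensemble$native,
                          id = sprintf("%s#%03d", ensemble$native$label, k),
                          ...))
}

#' Ensemble-level order parameters from transformation records
#'
#' Ensemble means of MRSD, RMSD, D_nx and the derived identities
#' D_total = N * MRSD + D_nx and INX = D_nx / (N * MRSD).
#'
#' @param records list of `transformation_record`s.
#' @param n chain length in residues (full resolution).
#' @return one-row data frame (see [order_param_table()]).
#' @export
ensemble_order_params <- function(records, n) {
  tab <- data.frame(
    n = n,
    mrsd = mean(vapply(records, `[[`, 0, "mrsd")),
    rmsd = mean(vapply(records, `[[`, 0, "rmsd")),
    d_ghost = mean(vapply(records, `[[`, 0, "d_ghost")),
    d_nx = mean(vapply(records, `[[`, 0, "d_nx")))
  order_param_table(tab)
}

span_overlap <- function(a, b) max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))

#' Pathway overlap chi between two transformations
#'
#' Moves of the same type whose residue spans overlap in primary
#' sequence are matched (greedily by overlap size, each move matched at
#' most once; a move overlapping several partners goes to the one with
#' the larger overlap).  With d_a, d_b the full move-cost vectors and
#' the matched pairs P, chi = sum_P d_a d_b / (|d_a| |d_b|), in [0, 1].
#' Two empty records overlap perfectly (chi = 1); one empty record gives
#' chi = 0.
#'
#' @param a,b `transformation_record`s of the same protein.
#' @return chi in [0, 1].
#' @export
overlap_chi <- function(a, b) {
  ma <- a$moves; mb <- b$moves
  if (!length(ma) && !length(mb)) return(1)
  if (!length(ma) || !length(mb)) return(0)
  cand <- list()
  for (p in seq_along(ma)) for (q in seq_along(mb)) {
    if (ma[[p]]$kind != mb[[q]]$kind) next
    ov <- span_overlap(ma[[p]]$span, mb[[q]]$span)
    if (ov > 0) cand[[length(cand) + 1L]] <- c(p, q, ov)
  }
  if (!length(cand)) return(0)
  cand <- cand[order(-vapply(cand, `[[`, 0, 3L))]
  used_a <- logical(length(ma)); used_b <- logical(length(mb))
  num <- 0
  for (cc in cand) {
    p <- cc[1L]; q <- cc[2L]
    if (used_a[p] || used_b[q]) next
    used_a[p] <- TRUE; used_b[q] <- TRUE
    num <- num + ma[[p]]$cost * mb[[q]]$cost
  }
  da <- sqrt(sum(vapply(ma, `[[`, 0, "cost")^2))
  db <- sqrt(sum(vapply(mb, `[[`, 0, "cost")^2))
  if (da == 0 || db == 0) return(if (da == db) 1 else 0)
  min(1, num / (da * db))
}

#' Mean pairwise overlap of a set of transformations
#'
#' @param records list of `transformation_record`s.
#' @return list with the symmetric `chi` matrix (unit diagonal) and
#'   `mean_chi` over distinct pairs.
#' @export
overlap_matrix <- function(records) {
  k <- length(records)
  chi <- diag(1, k)
  if (k >= 2L)
    for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k))
      chi[a, b] <- chi[b, a] <- overlap_chi(records[[a]], records[[b]])
  list(chi = chi,
       mean_chi = if (k >= 2L) mean(chi[upper.tri(chi)]) else NA_real_)
}

## map a record onto the 8-slot consensus scheme
## slots: Ls, Le, R(first), E(first), R(middle), E(middle), R(last), E(last)
slot_names <- c("Ls", "Le", "R1", "E1", "R2", "E2", "R3", "E3")

record_slots <- function(record) {
  v <- stats::setNames(numeric(8L), slot_names)
  kinds <- vapply(record$moves, `[[`, "", "kind")
  costs <- vapply(record$moves, `[[`, 0, "cost")
  v["Ls"] <- sum(costs[kinds == "L_start"])
  v["Le"] <- sum(costs[kinds == "L_end"])
  for (ty in c("R", "E")) {
    slots <- paste0(ty, 1:3)
    cc <- costs[kinds == ty]            # in order of occurrence
    nn <- length(cc)
    if (nn == 1L) v[slots[c(1L, 3L)]] <- cc / 2
    else if (nn == 2L) v[slots[c(1L, 3L)]] <- cc
    else if (nn == 3L) v[slots] <- cc
    else if (nn >= 4L) {
      v[slots[1L]] <- cc[1L]
      v[slots[3L]] <- cc[nn]
      v[slots[2L]] <- sum(cc[2:(nn - 1L)])
    }
  }
  v
}

record_class <- function(record) {
  if (!length(record$moves)) return("misc_largest")
  kinds <- vapply(record$moves, `[[`, "", "kind")
  costs <- vapply(record$moves, `[[`, 0, "cost")
  ## ties: leg beats loop/elbow, start beats end
  pref <- match(kinds, c("L_start", "L_end", "R", "E"))
  top <- order(-costs, pref)[1L]
  switch(kinds[top], L_start = "Ls_largest", L_end = "Le_largest",
         "misc_largest")
}

#' Consensus minimal-pathway histograms
#'
#' Transformations are classed by their largest-cost move (start leg,
#' end leg, or miscellaneous loop/elbow) and each is mapped onto the
#' 8-slot general scheme Ls, Le, (R, E) x 3: a single loop splits half
#' into the first and half into the last R slot, two loops go first and
#' last, three in order, and four or more have the middle ones
#' aggregated into the middle slot (same recipe for elbows).  Slot-wise
#' means are reported per class.
#'
#' @param records list of `transformation_record`s.
#' @return a `consensus_histograms` list: per-class `slots` (mean
#'   distances), `fraction` of transformations, `n`; plus
#'   `representable` (share of records needing no middle-slot
#'   aggregation).
#' @export
consensus_histogram <- function(records) {
  cls <- vapply(records, record_class, "")
  slots <- t(vapply(records, record_slots, numeric(8L)))
  out <- lapply(c("Ls_largest", "Le_largest", "misc_largest"),
                function(cl) {
    sel <- cls == cl
    list(class = cl,
         slots = if (any(sel)) colMeans(slots[sel, , drop = FALSE])
                 else stats::setNames(numeric(8L), slot_names),
         fraction = mean(sel), n = sum(sel))
  })
  names(out) <- c("Ls_largest", "Le_largest", "misc_largest")
  nR <- vapply(records, function(r)
    sum(vapply(r$moves, `[[`, "", "kind") == "R"), 0)
  nE <- vapply(records, function(r)
    sum(vapply(r$moves, `[[`, "", "kind") == "E"), 0)
  structure(c(out, list(representable = mean(nR <= 3 & nE <= 3))),
            class = "consensus_histograms")
}

#' @export
print.consensus_histograms <- function(x, ...) {
  for (cl in c("Ls_largest", "Le_largest", "misc_largest"))
    cat(sprintf("%-12s %4.0f%% of transformations; slot means: %s\n", cl,
                100 * x[[cl]]$fraction,
                paste(sprintf("%s=%.3g", slot_names, x[[cl]]$slots),
                      collapse = " ")))
  cat(sprintf("representable without aggregation: %.0f%%\n",
              100 * x$representable))
  invisible(x)
}

#' Most representative transformation
#'
#' Maps every record onto the 8-slot scheme and returns the record whose
#' slot vector deviates least (Euclidean distance, normalized by the
#' class-mean norm) from its class mean, minimized over the three
#' classes; ties go to the lower record index.
#'
#' @param records list of `transformation_record`s.
#' @param histograms optional [consensus_histogram()] output (recomputed
#'   if missing).
#' @return list with `index`, `id`, `class`, `deviation`.
#' @export
representative_transformation <- function(records,
                                          histograms =
                                            consensus_histogram(records)) {
  slots <- t(vapply(records, record_slots, numeric(8L)))
  best <- list(index = NA_integer_, deviation = Inf, class = NA_character_)
  for (cl in c("Ls_largest", "Le_largest", "misc_largest")) {
    h <- histograms[[cl]]
    if (h$n == 0L) next
    norm <- sqrt(sum(h$slots^2))
    if (norm == 0) norm <- 1
    for (k in seq_along(records)) {
      dev <- sqrt(sum((slots[k, ] - h$slots)^2)) / norm
      if (dev < best$deviation - 1e-12) {
        best <- list(index = k, deviation = dev, class = cl)
      }
    }
  }
  best$id <- records[[best$index]]$id
  best
}
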