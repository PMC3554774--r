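## Canonical uncrossing moves and the minimal-cost move-sequence search.
## Costs are distances travelled by beads on the event snapshot (the
## conformation just before the crossing): a leg sends every bead between
## a terminus and the crossing point to the crossing and back; a loop is
## pinched onto its crossing point and reopened (the cheap realization of
## a Reidemeister type-I twist); an elbow segment visits its nearest
## points on the obstructing strand and returns.  All costs therefore
## scale linearly with the coordinates.

move_kinds <- c(L_start = 1L, L_end = 2L, R = 3L, E = 4L)

new_move <- function(kind, events, cost, span, snapshot_id, root = NA) {
  list(kind = kind, events = sort(events), cost = cost, span = span,
       snapshot_id = snapshot_id, root = root)
}

move_key <- function(m) sprintf("%d-%03d", move_kinds[[m$kind]],
                                if (is.na(m$root)) min(m$events) else m$root)

#' Operator-notation label of a move sequence
#' @param moves list of moves (e.g. from [minimal_uncrossing()]).
#' @return character such as `"Ls1 R3 E24"` (left-most applied first here;
#'   operators are written in application order).
#' @export
operator_notation <- function(moves) {
  lab <- vapply(moves, function(m) {
    switch(m$kind,
           L_start = sprintf("Ls%d", m$root),
           L_end = sprintf("Le%d", m$root),
           R = sprintf("R%d", m$events[1L]),
           E = sprintf("E%s", paste(m$events, collapse = "")))
  }, "")
  paste(lab, collapse = " ")
}

## 3D location of an event's crossing point on a snapshot: midpoint of the
## two encounter points (the strands coincide there up to one step size)
crossing_point <- function(ev, snapshot) {
  (point_at_param(snapshot, ev$t[1L]) + point_at_param(snapshot, ev$t[2L])) / 2
}

snapshot_of <- function(record, id) record$events[[id]]$snapshot

#' Cost a (possibly compound) leg move
#'
#' Reverses the root event and every residual event with an encounter
#' between the terminus and the root encounter.  Every bead from the
#' terminus up to (not including) the root crossing point travels to the
#' crossing and back: cost = 2 * sum_b |r_b - r_x|, evaluated on the
#' snapshot of the chronologically last constituent event.
#'
#' @param record a `crossing_record`.
#' @param root_id id of the root (deepest) event being undone.
#' @param side `"start"` or `"end"`.
#' @param residual residual event ids (defaults to all).
#' @return a move (kind `L_start`/`L_end`).
#' @export
leg_cost <- function(record, root_id, side = c("start", "end"),
                     residual = vapply(record$events, `[[`, 0L, "id")) {
  side <- match.arg(side)
  root <- record$events[[root_id]]
  root_param <- if (side == "start") root$t[1L] else root$t[2L]
  members <- root_id
  for (id in setdiff(residual, root_id)) {
    e <- record$events[[id]]
    on_leg <- if (side == "start") e$t[1L] < root_param
              else e$t[2L] > root_param
    if (on_leg) members <- c(members, id)
  }
  snap_id <- max(members)            # chronologically last constituent
  snap <- snapshot_of(record, snap_id)
  rx <- crossing_point(root, snap)
  beads <- beads_of_leg(root_param, record$n_beads, side)
  cost <- if (length(beads))
    2 * sum(sqrt(rowSums(sweep(snap[beads, , drop = FALSE], 2L, rx)^2)))
  else 0
  new_move(if (side == "start") "L_start" else "L_end", members, cost,
           span = if (side == "start") c(0, root_param)
                  else c(root_param, record$n_beads - 1),
           snapshot_id = snap_id, root = root_id)
}

#' Cost a loop (Reidemeister-I pinch) move
#'
#' The beads strictly inside the loop span are pinched onto the crossing
#' point and reopened: cost = 2 * sum over interior beads of the distance
#' to the crossing point, on the event snapshot.
#'
#' @param record a `crossing_record`.
#' @param event_id the loop's event id (its applicability - consecutive
#'   encounters among residual events - is checked by
#'   [applicable_moves()], not here).
#' @return a move of kind `R`.
#' @export
loop_cost <- function(record, event_id) {
  ev <- record$events[[event_id]]
  snap <- ev$snapshot
  rx <- crossing_point(ev, snap)
  beads <- beads_inside(c(ev$t[1L], ev$t[2L]), record$n_beads)
  cost <- if (length(beads))
    2 * sum(sqrt(rowSums(sweep(snap[beads, , drop = FALSE], 2L, rx)^2)))
  else 0
  new_move("R", event_id, cost, span = c(ev$t[1L], ev$t[2L]),
           snapshot_id = event_id)
}

## nearest point on a polyline (m x 3 vertex matrix) to point q
nearest_on_polyline <- function(verts, q) {
  best <- verts[1L, ]; bd <- sum((q - best)^2)
  if (nrow(verts) >= 2L) {
    for (s in seq_len(nrow(verts) - 1L)) {
      a <- verts[s, ]; b <- verts[s + 1L, ]
      ab <- b - a
      den <- sum(ab * ab)
      t <- if (den > 0) min(1, max(0, sum((q - a) * ab) / den)) else 0
      p <- a + t * ab
      d <- sum((q - p)^2)
      if (d < bd) { bd <- d; best <- p }
    }
  }
  best
}

#' Cost an elbow move
#'
#' Each bead of the elbow segment moves straight to its closest point on
#' the obstructing strand (the polyline between the two crossing
#' encounters on the other strand) and back: cost = 2 * sum_b
#' |r_b - q_b|, costed on the later event's snapshot.  Reverses both
#' events.
#'
#' @param record a `crossing_record`.
#' @param events the elbow's two event ids.
#' @param span,obstruction chain-parameter intervals from
#'   [find_substructures()].
#' @return a move of kind `E`.
#' @export
elbow_cost <- function(record, events, span, obstruction) {
  snap_id <- max(events)
  snap <- snapshot_of(record, snap_id)
  beads <- beads_inside(span, record$n_beads)
  ob_beads <- beads_inside(obstruction, record$n_beads)
  verts <- rbind(point_at_param(snap, obstruction[1L]),
                 if (length(ob_beads)) snap[ob_beads, , drop = FALSE],
                 point_at_param(snap, obstruction[2L]))
  cost <- 0
  for (b in beads)
    cost <- cost + 2 * sqrt(sum((snap[b, ] -
                                   nearest_on_polyline(verts, snap[b, ]))^2))
  new_move("E", events, cost, span = span, snapshot_id = snap_id)
}

#' Enumerate the currently applicable uncrossing moves
#'
#' Start and end leg moves are enumerated for every residual event as
#' root (each undoing all shallower residual events on its side); loop
#' moves for every residual event whose two encounters are consecutive
#' among residual encounters; elbow moves for every residual
#' consecutive same-sense event pair.  Moves are returned in the
#' canonical order `L_start < L_end < R < E`, then by root/event id.
#'
#' @param record a `crossing_record`.
#' @param residual residual event ids.
#' @return list of costed moves.
#' @export
applicable_moves <- function(record,
                             residual = vapply(record$events, `[[`, 0L,
                                               "id")) {
  if (!length(residual)) return(list())
  subs <- find_substructures(record, residual)
  moves <- list()
  for (id in residual) {
    moves[[length(moves) + 1L]] <- leg_cost(record, id, "start", residual)
    moves[[length(moves) + 1L]] <- leg_cost(record, id, "end", residual)
  }
  for (s in subs) {
    if (s$kind == "loop")
      moves[[length(moves) + 1L]] <- loop_cost(record, s$events)
    if (s$kind == "elbow")
      moves[[length(moves) + 1L]] <- elbow_cost(record, s$events, s$span,
                                                s$obstruction)
  }
  moves[order(vapply(moves, move_key, ""))]
}

#' Minimal uncrossing cost by depth-first branch-and-bound
#'
#' Searches the tree of ordered move sequences that reverse every
#' recorded crossing event exactly once, pruning any branch whose
#' accumulated cost reaches the incumbent.  The incumbent is initialized
#' with the cheaper of the two single compound leg moves that undo all
#' events at once (legs are always applicable, so the search space is
#' never empty).  Children are expanded in canonical order and commuting
#' sibling moves (disjoint event sets, both applicable with identical
#' cost before and after the swap) are expanded in canonical order only,
#' making the result deterministic.
#'
#' @param record a `crossing_record` from [detect_true_crossings()].
#' @return an `uncross_result`: `moves` (ordered list), `d_nx` (total
#'   cost, link-length units), and `notation`.
#' @export
minimal_uncrossing <- function(record) {
  all_ids <- vapply(record$events, `[[`, 0L, "id")
  if (!length(all_ids))
    return(structure(list(moves = list(), d_nx = 0, notation = ""),
                     class = "uncross_result"))
  ## greedy incumbent: compound legs from the deepest residual root until
  ## every event is reversed (usually a single move per side)
  greedy_legs <- function(side) {
    residual <- all_ids; seq <- list(); total <- 0
    while (length(residual)) {
      enc <- vapply(record$events[residual],
                    function(e) if (side == "start") e$t[1L] else -e$t[2L], 0)
      m <- leg_cost(record, residual[which.max(enc)], side, residual)
      residual <- setdiff(residual, m$events)
      seq <- c(seq, list(m)); total <- total + m$cost
    }
    list(cost = total, seq = seq)
  }
  g1 <- greedy_legs("start"); g2 <- greedy_legs("end")
  best <- if (g1$cost <= g2$cost) g1 else g2

  env <- new.env(parent = emptyenv())
  env$best_cost <- best$cost
  env$best_seq <- best$seq

  dfs <- function(residual, acc, seq, prev, parent_moves) {
    if (!length(residual)) {
      if (acc < env$best_cost) {
        env$best_cost <- acc
        env$best_seq <- seq
      }
      return(invisible())
    }
    moves <- applicable_moves(record, residual)
    parent_keys <- vapply(parent_moves, function(m)
      paste(m$kind, paste(m$events, collapse = ","), signif(m$cost, 12)), "")
    for (m in moves) {
      if (acc + m$cost >= env$best_cost) next
      if (!is.null(prev) && !length(intersect(m$events, prev$events))) {
        ## commuting-sibling dedup: m could have been taken before prev
        mk <- paste(m$kind, paste(m$events, collapse = ","),
                    signif(m$cost, 12))
        if (mk %in% parent_keys && move_key(m) < move_key(prev)) next
      }
      dfs(setdiff(residual, m$events), acc + m$cost, c(seq, list(m)), m,
          moves)
    }
  }
  dfs(all_ids, 0, list(), NULL, list())
  structure(list(moves = env$best_seq, d_nx = env$best_cost,
                 notation = operator_notation(env$best_seq)),
            class = "uncross_result")
}

#' @export
print.uncross_result <- function(x, ...) {
  cat(sprintf("<uncross_result> D_nx = %.6g via %d move(s): %s\n",
              x$d_nx, length(x$moves), x$notation))
  invisible(x)
}

#' Total non-crossing distance of a transformation
#'
#' Runs the global (history-aware) minimal uncrossing search over the
#' whole collection of crossing events of a trajectory, rather than
#' repairing events greedily in chronological order; when a
#' transformation decomposes into stages with separate crossing
#' episodes, the joint optimum never exceeds the sum of the stage
#' optima.
#'
#' @param record a `crossing_record`.
#' @return D_nx in link-length units.
#' @export
uncrossing_distance <- function(record) minimal_uncrossing(record)$d_nx
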