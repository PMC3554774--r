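## End-to-end convenience: PDB (or synthetic native) -> unfolded
## ensemble -> minimal transformations -> ensemble order parameters.

#' Full minimal-transformation pipeline for one protein
#'
#' Reads a native structure, builds the heavy-atom native contact set
#' and steric cutoff, rescales to link-length units, generates the
#' unfolded ensemble by native-biased pivoting, and computes one
#' minimal transformation per unfolded conformation.
#'
#' @param pdb_source PDB path or text (see [read_calpha_trace()]), or a
#'   `protein_structure`.
#' @param n_structures unfolded conformations to generate.
#' @param seed integer seed.
#' @param n_pivot accepted pivots per conformation (default 3(N-2)).
#' @param delta ghost step size (link lengths).
#' @param coarse_grain every-other-bead smoothing before evolving.
#' @param plane projection plane for crossing detection.
#' @param chain_id optional PDB chain identifier.
#' @return a `fold_result`: `structure`, `contacts`, `ensemble`
#'   (link-length units), `records` (transformation records),
#'   `params` (one-row data frame from [ensemble_order_params()]),
#'   `link_length` (Angstrom), `seed`.
#' @export
fold_pipeline <- function(pdb_source, n_structures = 20L, seed = 1L,
                          n_pivot = NULL, delta = 0.02,
                          coarse_grain = TRUE, plane = "XY",
                          chain_id = NULL) {
  struct <- if (inherits(pdb_source, "protein_structure")) pdb_source
            else read_calpha_trace(pdb_source, chain_id)
  contacts <- native_contact_set(struct)
  bl <- representative_link_length(struct)
  cutoff <- steric_cutoff(struct, contacts)
  native <- rescale_chain(struct$calpha, bl)
  spec <- ensemble_spec(n_structures = n_structures, n_pivot = n_pivot,
                        steric_cutoff = cutoff / bl, seed = seed)
  ens <- generate_unfolded(native, contacts, spec)
  records <- ensemble_transformations(ens, spec = transform_spec(delta),
                                      coarse_grain = coarse_grain,
                                      plane = plane)
  params <- ensemble_order_params(records, n_beads(native))
  params$lro <- lro(struct)
  params$rco <- rco(struct)
  params$aco <- aco(struct)
  structure(list(structure = struct, contacts = contacts, ensemble = ens,
                 records = records, params = params, link_length = bl,
                 seed = seed),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %s: %d transformations\n",
              x$structure$label, length(x$records)))
  print(signif(as.data.frame(x$params), 3))
  invisible(x)
}

#' Summary statistics of a set of transformation records
#'
#' The per-ensemble pathway numbers used to characterize minimal
#' folding pathways: the share of the total uncrossing distance carried
#' by leg moves (and by each leg separately), the fraction of
#' transformations requiring each leg, both legs, any leg, and the
#' fraction dominated (largest move) by a leg.
#'
#' @param records list of `transformation_record`s.
#' @return one-row data frame.
#' @export
pathway_statistics <- function(records) {
  kind_cost <- function(r, kinds) {
    if (!length(r$moves)) return(0)
    k <- vapply(r$moves, `[[`, "", "kind")
    sum(vapply(r$moves, `[[`, 0, "cost")[k %in% kinds])
  }
  tot <- vapply(records, `[[`, 0, "d_nx")
  ls <- vapply(records, kind_cost, 0, "L_start")
  le <- vapply(records, kind_cost, 0, "L_end")
  cls <- vapply(records, record_class, "")
  data.frame(
    n_transformations = length(records),
    mean_d_nx = mean(tot),
    leg_share = sum(ls + le) / max(sum(tot), .Machine$double.eps),
    ls_share = sum(ls) / max(sum(tot), .Machine$double.eps),
    le_share = sum(le) / max(sum(tot), .Machine$double.eps),
    frac_ls = mean(ls > 0),
    frac_le = mean(le > 0),
    frac_both_legs = mean(ls > 0 & le > 0),
    frac_any_leg = mean(ls > 0 | le > 0),
    frac_leg_dominated = mean(cls %in% c("Ls_largest", "Le_largest")),
    frac_no_uncrossing = mean(tot == 0))
}
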