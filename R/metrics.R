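## Native-structure order parameters and class statistics.

#' Long-range order (LRO)
#'
#' Number of long-range native contacts - C-alpha pairs within
#' `ca_cutoff` with sequence separation greater than `min_sep` - divided
#' by the number of residues.
#'
#' @param struct a `protein_structure`.
#' @param ca_cutoff C-alpha distance cutoff in Angstrom (default 8).
#' @param min_sep contacts require `j - i > min_sep` (default 12).
#' @return dimensionless LRO.
#' @export
lro <- function(struct, ca_cutoff = 8, min_sep = 12L) {
  co <- struct$calpha$coords
  n <- nrow(co)
  d <- as.matrix(stats::dist(co))
  sep <- abs(row(d) - col(d))
  sum(d[upper.tri(d)] <= ca_cutoff & sep[upper.tri(sep)] > min_sep) / n
}

heavy_contact_seps <- function(struct, heavy_cutoff, min_sep) {
  at <- struct$atoms
  xyz <- cbind(at$x, at$y, at$z)
  n <- nrow(xyz)
  seps <- integer()
  block <- 2048L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(rowSums(xyz[s:e, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[s:e, , drop = FALSE] %*% t(xyz)
    hit <- which(d2 <= heavy_cutoff^2 + 1e-9, arr.ind = TRUE)
    if (nrow(hit)) {
      a <- at$ri[s:e][hit[, 1L]]; b <- at$ri[hit[, 2L]]
      keep <- (b - a) >= min_sep           # each unordered pair once
      seps <- c(seps, (b - a)[keep])
    }
  }
  seps
}

#' Relative contact order (RCO)
#'
#' RCO = (1 / (L N)) * sum of sequence separations over the L contacts
#' between non-hydrogen atoms within `heavy_cutoff`.
#'
#' @param struct a `protein_structure`.
#' @param heavy_cutoff heavy-atom cutoff in Angstrom (default 6).
#' @param min_sep minimal residue separation counted as a contact
#'   (default 2, excluding covalent neighbors).
#' @return dimensionless RCO.
#' @export
rco <- function(struct, heavy_cutoff = 6, min_sep = 2L) {
  seps <- heavy_contact_seps(struct, heavy_cutoff, min_sep)
  if (!length(seps)) return(0)
  mean(seps) / nrow(struct$residues)
}

#' Absolute contact order (ACO)
#'
#' Mean sequence separation (in residues) of the heavy-atom contacts of
#' [rco()].
#'
#' @inheritParams rco
#' @return ACO in residues.
#' @export
aco <- function(struct, heavy_cutoff = 6, min_sep = 2L) {
  seps <- heavy_contact_seps(struct, heavy_cutoff, min_sep)
  if (!length(seps)) return(0)
  mean(seps)
}

#' Two-sided Welch t-test p-value
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; the workhorse for class discrimination.
#'
#' @param group_a,group_b numeric vectors (length >= 2 each).
#' @return p-value in (0, 1].
#' @export
welch_p <- function(group_a, group_b) {
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    return(if (mean(group_a) == mean(group_b)) 1 else 0)
  stats::t.test(group_a, group_b, var.equal = FALSE)$p.value
}

#' Derived-column identities of the per-protein metric table
#'
#' Adds D_total = N * MRSD + D_nx, D_nx / N, D_total / N, and
#' INX = D_nx / (N * MRSD) to a per-protein table.
#'
#' @param tab data frame with columns `n`, `mrsd`, `d_nx` (any others are
#'   carried through).
#' @return the augmented data frame.
#' @export
order_param_table <- function(tab) {
  stopifnot(all(c("n", "mrsd", "d_nx") %in% names(tab)))
  tab$d_total <- tab$n * tab$mrsd + tab$d_nx
  tab$d_nx_per_n <- tab$d_nx / tab$n
  tab$d_total_per_n <- tab$d_total / tab$n
  tab$inx <- tab$d_nx / (tab$n * tab$mrsd)
  tab
}

#' Packaged per-protein order-parameter table
#'
#' The 45-protein reference table (printed per-protein LRO, RCO, ACO,
#' MRSD, RMSD, D_nx, N, structural and kinetic class labels) shipped
#' with the package, with the derived columns of [order_param_table()].
#'
#' @return data frame with one row per protein.
#' @export
load_protein_table <- function() {
  f <- system.file("extdata", "protein_order_params.tsv",
                   package = "foldnx", mustWork = TRUE)
  tab <- utils::read.delim(f, stringsAsFactors = FALSE)
  order_param_table(tab)
}

#' Compare a metric between protein classes
#'
#' Per-class means and pairwise two-sided Welch p-values for each
#' requested metric; single-member classes are flagged (`NA` p-values).
#'
#' @param tab per-protein data frame (e.g. [load_protein_table()]).
#' @param class_col name of the class-label column.
#' @param metrics character vector of metric column names.
#' @param alpha significance threshold used for the `significant` flag.
#' @return a `class_comparison`: `means` (class x metric), `p_values`
#'   (named list of pairwise matrices), `significant`.
#' @export
class_compare <- function(tab, class_col, metrics, alpha = 0.05) {
  cls <- tab[[class_col]]
  keep <- !is.na(cls)
  tab <- tab[keep, , drop = FALSE]; cls <- cls[keep]
  levels <- unique(cls)
  means <- sapply(metrics, function(m)
    vapply(levels, function(l) mean(tab[[m]][cls == l]), 0))
  means <- matrix(means, nrow = length(levels),
                  dimnames = list(levels, metrics))
  pv <- lapply(metrics, function(m) {
    p <- matrix(NA_real_, length(levels), length(levels),
                dimnames = list(levels, levels))
    for (a in seq_along(levels)) for (b in seq_along(levels)) {
      if (a >= b) next
      ga <- tab[[m]][cls == levels[a]]; gb <- tab[[m]][cls == levels[b]]
      if (length(ga) >= 2L && length(gb) >= 2L)
        p[a, b] <- p[b, a] <- welch_p(ga, gb)
    }
    p
  })
  names(pv) <- metrics
  structure(list(means = means, p_values = pv,
                 significant = lapply(pv, function(p) p < alpha),
                 alpha = alpha, class_col = class_col),
            class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  cat(sprintf("<class_comparison> by %s\n", x$class_col))
  print(signif(x$means, 3))
  invisible(x)
}

#' Power-law fit on log-log axes
#'
#' Least-squares fit of log(value) on log(n): value ~ prefactor *
#' n^exponent.
#'
#' @param n,value positive numeric vectors.
#' @return a `scaling_fit`: `exponent`, `prefactor`, `residuals`, `fit`.
#' @export
scaling_fit <- function(n, value) {
  stopifnot(all(n > 0), all(value > 0))
  fit <- stats::lm(log(value) ~ log(n))
  structure(list(exponent = unname(stats::coef(fit)[2L]),
                 prefactor = exp(unname(stats::coef(fit)[1L])),
                 residuals = stats::residuals(fit), fit = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> value ~ %.4g * n^%.4g\n", x$prefactor,
              x$exponent))
  invisible(x)
}

#' Crossover size of two fitted power laws
#'
#' Solves prefactor_1 * n^p1 = prefactor_2 * n^p2.
#'
#' @param fit1,fit2 `scaling_fit` objects with different exponents.
#' @return crossover n (> 0).
#' @export
scaling_crossover <- function(fit1, fit2) {
  if (abs(fit1$exponent - fit2$exponent) < 1e-12)
    stop("equal exponents: no crossover")
  (fit1$prefactor / fit2$prefactor)^(1 / (fit2$exponent - fit1$exponent))
}
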