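## PDB input and coarse-graining.  Parsing of the PDB format itself is
## delegated to bio3d; this module owns the selection rules (first model,
## one chain, altLoc by occupancy, no HETATM/waters/hydrogens), the
## C-alpha trace extraction, contact sets, steric cutoffs, and the
## trajectory writers.

#' Read a protein structure and extract its C-alpha trace
#'
#' Reads PDB text or a PDB file (first model only), keeps ATOM records of
#' one chain (by default the first chain containing C-alpha atoms), drops
#' HETATM records, waters, and hydrogens, resolves alternate locations to
#' the highest occupancy (ties to altLoc `"A"`), and requires exactly one
#' C-alpha per residue in the span.
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB
#'   text lines (anything containing a newline or multiple elements is
#'   treated as text).
#' @param chain_id chain identifier; `NULL` picks the first protein
#'   chain.
#' @return a `protein_structure`: `atoms` (data frame of heavy atoms
#'   with 1-based residue index `ri`), `residues` (data frame), `calpha`
#'   (a [chain()] in Angstrom), `label`.
#' @export
read_calpha_trace <- function(pdb_source, chain_id = NULL) {
  file <- pdb_source
  label <- "pdb"
  if (length(pdb_source) > 1L || grepl("\n", pdb_source[1L], fixed = TRUE) ||
      !file.exists(pdb_source[1L])) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(unlist(strsplit(pdb_source, "\n", fixed = TRUE)), file)
  } else {
    label <- sub("\\.(pdb|ent)$", "", basename(pdb_source),
                 ignore.case = TRUE)
  }
  pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  ## hydrogens out (element symbol if present, else atom-name heuristic)
  elesy <- at$elesy
  noel <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[noel] <- substr(gsub("^[0-9]*", "", trimws(at$elety[noel])), 1L, 1L)
  at <- at[!(toupper(trimws(elesy)) %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop("no protein ATOM records found")
  if (is.null(chain_id)) {
    ca_chains <- unique(at$chain[at$elety == "CA"])
    if (!length(ca_chains)) stop("no C-alpha atoms found in any chain")
    chain_id <- ca_chains[1L]
  }
  at <- at[at$chain %in% chain_id, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("chain '%s' is empty", chain_id))
  ## altLoc resolution: per (residue, atom name) keep highest occupancy,
  ## ties to the alphabetically first altLoc (i.e. 'A')
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  rowid <- seq_len(nrow(at))
  ord <- order(key, -occ, alt)
  keep_rows <- sort(rowid[ord][!duplicated(key[ord])])  # file order kept
  at <- at[keep_rows, , drop = FALSE]
  rkey <- paste(at$resno, at$insert, sep = "|")
  at$ri <- match(rkey, unique(rkey))
  n <- max(at$ri)
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(seq_len(n), ca$ri)
  if (length(missing_ca)) {
    miss <- unique(rkey)[missing_ca]
    stop(sprintf("residue(s) without a C-alpha atom: %s",
                 paste(sub("\\|.*", "", miss), collapse = ", ")))
  }
  ca <- ca[order(ca$ri), , drop = FALSE]
  residues <- data.frame(ri = seq_len(n),
                         resno = ca$resno, insert = ca$insert,
                         resid = ca$resid, stringsAsFactors = FALSE)
  calpha <- chain(cbind(ca$x, ca$y, ca$z), label = label)
  structure(list(atoms = at, residues = residues, calpha = calpha,
                 chain_id = chain_id, label = label),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s chain %s: %d residues, %d heavy atoms\n",
              x$label, x$chain_id, nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' Representative C-alpha link length
#'
#' The first C-alpha to C-alpha distance from the N-terminus, used as the
#' equilibrium length for every link of the coarse-grained chain (the
#' distribution of such distances in the PDB is sharply peaked around
#' 3.76 Angstrom).
#'
#' @param struct a `protein_structure`.
#' @return length in Angstrom.
#' @export
representative_link_length <- function(struct) {
  link_lengths(struct$calpha)[1L]
}

#' Native contact set from heavy atoms
#'
#' Residue pair (i, j) is a native contact when any heavy-atom pair
#' across the two residues is within `heavy_cutoff`.  Covalent neighbors
#' are excluded (`j - i >= min_sep`).
#'
#' @param struct a `protein_structure`.
#' @param heavy_cutoff distance cutoff in Angstrom (default 4.9).
#' @param min_sep minimal sequence separation (default 2).
#' @return a `contact_set`: `pairs` (two-column matrix, i < j),
#'   `separations`, and the `definition` record.
#' @export
native_contact_set <- function(struct, heavy_cutoff = 4.9,
                               min_sep = 2L) {
  at <- struct$atoms
  if (all(at$elety == "CA"))
    warning("structure has no side-chain heavy atoms; contacts computed from C-alpha only")
  xyz <- cbind(at$x, at$y, at$z)
  hits <- atom_pair_residues(xyz, at$ri, heavy_cutoff, min_sep)
  pairs <- unique(hits)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  structure(list(pairs = pairs, separations = pairs[, 2L] - pairs[, 1L],
                 definition = list(heavy_cutoff = heavy_cutoff,
                                   min_sep = min_sep)),
            class = "contact_set")
}

## residue-index pairs (i < j, j - i >= min_sep) with any atom-atom
## distance <= cutoff; plain all-pairs scan in blocks
atom_pair_residues <- function(xyz, ri, cutoff, min_sep) {
  n <- nrow(xyz)
  out <- matrix(integer(), 0L, 2L)
  block <- 2048L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(rowSums(xyz[s:e, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[s:e, , drop = FALSE] %*% t(xyz)
    hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
    if (nrow(hit)) {
      a <- ri[s:e][hit[, 1L]]; b <- ri[hit[, 2L]]
      keep <- (b - a) >= min_sep
      out <- rbind(out, cbind(a[keep], b[keep]))
    }
  }
  unique(out)
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set> %d contacts (heavy cutoff %.2f A, |i-j| >= %d)\n",
              nrow(x$pairs), x$definition$heavy_cutoff, x$definition$min_sep))
  invisible(x)
}

#' Steric cutoff for the coarse-grained model
#'
#' The smaller of the minimum native-contact C-alpha distance and the
#' first link length; with an empty contact set the first link length is
#' used (with a warning).
#'
#' @param struct a `protein_structure`.
#' @param contacts a `contact_set` from [native_contact_set()].
#' @return length in Angstrom.
#' @export
steric_cutoff <- function(struct, contacts) {
  first_link <- representative_link_length(struct)
  if (is.null(contacts) || nrow(contacts$pairs) == 0L) {
    warning("empty contact set; using the first link length as steric cutoff")
    return(first_link)
  }
  co <- struct$calpha$coords
  d <- sqrt(rowSums((co[contacts$pairs[, 1L], , drop = FALSE] -
                       co[contacts$pairs[, 2L], , drop = FALSE])^2))
  min(min(d), first_link)
}

#' Coarse-grain a chain by keeping every other bead
#'
#' Keeps beads 1, 3, 5, ... (1-based); if the last bead is not kept it is
#' appended so both termini survive (legs are rooted at termini).  This
#' smoothing, in the spirit of the first steps of
#' Koniaris-Muthukumar-Taylor reduction, removes potential self-crossings
#' whose loop or elbow is smaller than three original links.  Rest
#' lengths are recomputed from the retained coordinates of `reference`
#' (the conformation designated native), so a native/unfolded pair
#' coarse-grained with the same reference stays consistent.
#'
#' @param x a `chain`.
#' @param reference a `chain` supplying rest lengths (default `x`).
#' @return the coarse-grained `chain` (unchanged, with a warning, for
#'   N < 4).
#' @export
coarse_grain_every_other <- function(x, reference = x) {
  n <- n_beads(x)
  if (n < 4L) {
    warning("chain too short to coarse-grain; returned unchanged")
    return(x)
  }
  keep <- unique(c(seq(1L, n, by = 2L), n))
  chain(x$coords[keep, , drop = FALSE],
        link_lengths_of(reference$coords[keep, , drop = FALSE]),
        x$label)
}

#' Rescale a chain to link-length units
#'
#' @param x a `chain` in Angstrom.
#' @param link_length representative link length in Angstrom (e.g. from
#'   [representative_link_length()]).
#' @return the rescaled `chain`.
#' @export
rescale_chain <- function(x, link_length) {
  chain(x$coords / link_length, x$rest_lengths / link_length, x$label)
}

#' Write a trajectory to multi-model PDB or XYZ
#'
#' PDB output (extension `.pdb`) writes one MODEL block per frame with
#' CA-only ATOM records in fixed-width columns; `.xyz` writes standard
#' XYZ frames.
#'
#' @param traj a `trajectory` (its `frames` are written) or a list of
#'   coordinate matrices.
#' @param file output path; format chosen by extension.
#' @export
write_trajectory <- function(traj, file) {
  frames <- if (inherits(traj, "trajectory")) traj$frames else traj
  ext <- tolower(sub(".*\\.", "", file))
  con <- file(file, "w")
  on.exit(close(con))
  if (ext == "pdb") {
    for (m in seq_along(frames)) {
      writeLines(sprintf("MODEL     %4d", m), con)
      f <- frames[[m]]
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        seq_len(nrow(f)), seq_len(nrow(f)), f[, 1L], f[, 2L], f[, 3L],
        1, 0), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else if (ext == "xyz") {
    for (f in frames) {
      writeLines(as.character(nrow(f)), con)
      writeLines("frame", con)
      writeLines(sprintf("CA %12.6f %12.6f %12.6f",
                         f[, 1L], f[, 2L], f[, 3L]), con)
    }
  } else stop("unsupported trajectory extension: ", ext)
  invisible(file)
}

#' Read a multi-model CA-only PDB trajectory
#'
#' @param file path written by [write_trajectory()] (or any multi-model
#'   CA-only PDB).
#' @return list of coordinate matrices, one per MODEL.
#' @export
read_trajectory_pdb <- function(file) {
  lines <- readLines(file)
  frames <- list()
  cur <- NULL
  for (ln in lines) {
    tag <- substr(ln, 1L, 6L)
    if (tag == "MODEL ") cur <- character()
    else if (startsWith(tag, "ATOM") && !is.null(cur)) cur <- c(cur, ln)
    else if (tag == "ENDMDL") {
      frames[[length(frames) + 1L]] <-
        cbind(as.numeric(substr(cur, 31L, 38L)),
              as.numeric(substr(cur, 39L, 46L)),
              as.numeric(substr(cur, 47L, 54L)))
      cur <- NULL
    }
  }
  if (!length(frames) && any(startsWith(lines, "ATOM"))) {
    at <- lines[startsWith(lines, "ATOM")]
    frames[[1L]] <- cbind(as.numeric(substr(at, 31L, 38L)),
                          as.numeric(substr(at, 39L, 46L)),
                          as.numeric(substr(at, 47L, 54L)))
  }
  frames
}

#' Read/write the plain-text chain format (one "x y z" triple per line)
#' @param file path.
#' @param label chain label.
#' @return a `chain`.
#' @export
read_chain_txt <- function(file, label = basename(file)) {
  m <- as.matrix(utils::read.table(file, col.names = c("x", "y", "z")))
  chain(m, label = label)
}

#' @rdname read_chain_txt
#' @param x a `chain` to write.
#' @export
write_chain_txt <- function(x, file) {
  utils::write.table(format(x$coords, digits = 12), file,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
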