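# Theoretical maximum accessible surface areas per residue (A^2), used to
# normalise SASA to relative SASA (Tien et al. 2013, theoretical set).
MAX_ASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLU = 223,
  GLN = 225, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174)

# Van der Waals radii (A) by element; unknown elements get the default.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.80

# Deterministic, approximately uniform points on the unit sphere
# (Fibonacci/golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

element_radius <- function(elements) {
  r <- VDW_RADII[elements]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' Atom-level solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over each atom using a deterministic golden-spiral
#' point lattice; a surface point is accessible if it lies outside every
#' neighbouring atom's expanded sphere.
#'
#' @param xyz Numeric matrix (n x 3) of atom coordinates in Angstrom.
#' @param elements Character vector of element symbols (length n).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere points per atom (default 960).
#' @return Numeric vector of per-atom SASA in A^2.
#' @export
shrake_rupley <- function(xyz, elements, probe = 1.4, n_points = 960L) {
  n <- nrow(xyz)
  stopifnot(length(elements) == n)
  radii <- element_radius(elements) + probe
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    surf <- sweep(pts * radii[i], 2L, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        free <- free & dj >= radii[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else frac <- 1
    sasa[i] <- frac * 4 * pi * radii[i]^2
  }
  sasa
}

#' Per-residue relative solvent accessibility of a chain
#'
#' Sums heavy-atom Shrake-Rupley SASA per residue and divides by the
#' residue type's theoretical maximum, capping at 1. A value of 0 is a
#' completely buried residue, 1 a completely exposed one. Hydrogens are
#' ignored. By default the whole structure (all chains) occludes, so burial
#' is measured in the complex.
#'
#' @param pdb A `bio3d` pdb object ([bio3d::read.pdb]).
#' @param chain Chain identifier to report residues for.
#' @param occluders `"all"` (default) or `"chain"` to ignore other chains.
#' @param probe,n_points Passed to [shrake_rupley()].
#' @return Data frame with `chain`, `resno`, `resid`, `sasa`, `rsasa`
#'   (`NA` for residue types without a reference maximum).
#' @export
compute_rsasa <- function(pdb, chain, occluders = c("all", "chain"),
                          probe = 1.4, n_points = 960L) {
  occluders <- match.arg(occluders)
  atoms <- pdb$atom
  atoms$element <- infer_element(atoms)
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (occluders == "chain") atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (!any(atoms$chain == chain)) stop("chain ", chain, " not in structure")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  sasa <- shrake_rupley(xyz, atoms$element, probe, n_points)
  sel <- atoms$chain == chain
  key <- paste(atoms$resno[sel], atoms$resid[sel])
  agg <- tapply(sasa[sel], key, sum)
  parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  out <- data.frame(chain = chain, resno = as.integer(parts[, 1]),
                    resid = parts[, 2], sasa = as.numeric(agg))
  out <- out[order(out$resno), , drop = FALSE]
  out$rsasa <- pmin(1, out$sasa / MAX_ASA[out$resid])
  rownames(out) <- NULL
  out
}

# Element symbol per atom: use the PDB element column when present, else the
# first letter of the atom name.
infer_element <- function(atoms) {
  el <- atoms$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(atoms))
  el <- toupper(trimws(el))
  miss <- is.na(el) | el == ""
  el[miss] <- substr(gsub("[0-9]", "", toupper(trimws(atoms$elety[miss]))),
                     1L, 1L)
  el
}

#' Interface contact residues between two chains
#'
#' A residue of `chain_a` is a contact if any of its heavy atoms lies within
#' `cutoff` (strict <) of any heavy atom of `chain_b` inside `region_b`.
#'
#' @param pdb A `bio3d` pdb object.
#' @param chain_a,chain_b Chain identifiers.
#' @param region_b Integer residue numbers on `chain_b` defining the partner
#'   region; default is the whole chain.
#' @param cutoff Distance cutoff in Angstrom (default 6).
#' @return Sorted integer residue numbers of `chain_a` in contact.
#' @export
contact_residues <- function(pdb, chain_a, chain_b, region_b = NULL,
                             cutoff = 6) {
  atoms <- pdb$atom
  atoms$element <- infer_element(atoms)
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  a <- atoms[atoms$chain == chain_a, , drop = FALSE]
  b <- atoms[atoms$chain == chain_b, , drop = FALSE]
  if (!is.null(region_b)) b <- b[b$resno %in% region_b, , drop = FALSE]
  if (!nrow(b)) {
    warning("empty partner region")
    return(integer(0))
  }
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  hit <- rowSums(d2 < cutoff^2) > 0
  sort(unique(a$resno[hit]))
}

#' Write per-position medians into the B-factor field of a PDB
#'
#' Each mapped residue's temperature factor is set to its per-position median
#' score; unmapped residues get the sentinel value, which is documented in a
#' REMARK header line.
#'
#' @param pdb A `bio3d` pdb object.
#' @param summaries Data frame from [per_position_median()].
#' @param path Output PDB path.
#' @param chain Chain to annotate (other chains get the sentinel).
#' @param offset Added to the model residue number to obtain the full-length
#'   position (e.g. 480 when the model starts at full-length residue 481 with
#'   `resno = 1`).
#' @param sentinel B-factor written for unmapped residues (default -9.99).
#' @return `path`, invisibly.
#' @export
map_scores_to_structure <- function(pdb, summaries, path, chain = "A",
                                    offset = 0L, sentinel = -9.99) {
  pos <- pdb$atom$resno + offset
  if (anyDuplicated(unique(pdb$atom[pdb$atom$chain == chain,
                                    c("resno", "chain")])$resno))
    stop("mapping collision: duplicate residue numbers in chain ", chain)
  b <- summaries$median_score[match(pos, summaries$position)]
  b[pdb$atom$chain != chain] <- NA
  b[!is.finite(b)] <- sentinel
  bio3d::write.pdb(pdb, file = path, b = b)
  txt <- readLines(path)
  writeLines(c(sprintf(
    "REMARK   3 B-FACTOR = PER-POSITION MEDIAN SCORE; UNMAPPED = %.2f",
    sentinel), txt), path)
  invisible(path)
}

#' Rank correlation of burial with per-position median scores
#'
#' Spearman correlation between residue rSASA and the per-position median
#' score on shared positions.
#'
#' @param features Data frame from [compute_rsasa()] with full-length
#'   `position` column (add `offset` to `resno` beforehand if needed).
#' @param summaries Data frame from [per_position_median()].
#' @param min_shared Minimum shared positions (default 10).
#' @return List with `rho`, `n`; `rho` is `NA` (with a message) for constant
#'   input.
#' @export
burial_correlation <- function(features, summaries, min_shared = 10L) {
  if (is.null(features$position)) features$position <- features$resno
  m <- merge(features[, c("position", "rsasa")],
             summaries[, c("position", "median_score")], by = "position")
  m <- m[is.finite(m$rsasa) & is.finite(m$median_score), , drop = FALSE]
  if (nrow(m) < min_shared)
    stop("need at least ", min_shared, " shared positions")
  if (stats::sd(m$rsasa) == 0 || stats::sd(m$median_score) == 0) {
    message("constant input: correlation undefined")
    return(list(rho = NA_real_, n = nrow(m)))
  }
  list(rho = stats::cor(m$rsasa, m$median_score, method = "spearman"),
       n = nrow(m))
}

#' Write a minimal PDB file from an atom table
#'
#' Utility for constructing small synthetic structures (test fixtures, toy
#' peptides) without external files.
#'
#' @param atoms Data frame with columns `resno`, `resid`, `elety`, `element`,
#'   `chain`, `x`, `y`, `z` and optionally `b`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  if (is.null(atoms$b)) atoms$b <- 0
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    formatC(substr(paste0(" ", atoms$elety), 1, 4), width = -4),
    atoms$resid, atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
    1, atoms$b, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
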