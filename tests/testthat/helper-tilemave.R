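# Small fixtures shared across tests; everything is generated in code.

# A two-tile miniature region (positions 487-506) cut from the default
# synthetic reference, nonsense programmed in the second tile.
mini_tiles <- function() {
  ref <- substr(synthetic_reference_protein(), 1, 20)
  make_tiles(data.frame(tile_id = 1:2,
                        start_pos = c(487L, 497L), end_pos = c(496L, 506L),
                        includes_nonsense = c(FALSE, TRUE)),
             ref, region_start = 487L)
}

# Write one FASTQ record set to a temp file pair and return the paths.
tmp_fastq_pair <- function(r1, r2, q1 = strrep("F", 151), q2 = q1) {
  if (length(q1) == 1L) q1 <- rep(q1, length(r1))
  if (length(q2) == 1L) q2 <- rep(q2, length(r2))
  ids <- sprintf("read%04d", seq_along(r1))
  p1 <- tempfile(fileext = "_R1.fastq"); p2 <- tempfile(fileext = "_R2.fastq")
  writeLines(if (length(r1)) paste0("@", ids, "\n", r1, "\n+\n", q1)
             else character(0), p1)
  writeLines(if (length(r2)) paste0("@", ids, "\n", r2, "\n+\n", q2)
             else character(0), p2)
  c(p1, p2)
}

# Read pair for a given variant amplicon (or the wild-type amplicon).
amplicon_pair <- function(tile, position = NULL, alt_aa = NULL) {
  ctx <- tile_amplicon(tile)
  amp <- if (is.null(position)) ctx$amplicon else
    tilemave:::mutant_amplicon(tile, ctx, position, alt_aa)
  list(r1 = substr(amp, 1, 151),
       r2 = as.character(Biostrings::reverseComplement(
         Biostrings::DNAString(substr(amp, nchar(amp) - 150, nchar(amp))))),
       amplicon = amp)
}

# Independent brute-force DerSimonian-Laird pooling, written directly from
# the estimator's definition (kept separate from the package implementation).
dl_oracle <- function(s, se) {
  w <- 1 / se^2
  mu_f <- sum(w * s) / sum(w)
  Q <- sum(w * (s - mu_f)^2)
  tau2 <- max(0, (Q - (length(s) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(score = sum(ws * s) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2)
}

# Brute-force AUC by concordant-pair counting (ties count 1/2).
auc_oracle <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Independent Shrake-Rupley evaluation using random (not lattice) sphere
# points; serves as a second implementation for cross-checking.
sasa_oracle <- function(xyz, elements, probe = 1.4, n_points = 2000L,
                        seed = 11L) {
  set.seed(seed)
  z <- runif(n_points, -1, 1)
  th <- runif(n_points, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  pts <- cbind(r * cos(th), r * sin(th), z)
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
             P = 1.80)[elements]
  radii[is.na(radii)] <- 1.80
  radii <- radii + probe
  vapply(seq_len(nrow(xyz)), function(i) {
    surf <- sweep(pts * radii[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in setdiff(seq_len(nrow(xyz)), i)) {
      d2 <- rowSums(sweep(surf, 2, xyz[j, ], `-`)^2)
      free <- free & d2 >= radii[j]^2
    }
    mean(free) * 4 * pi * radii[i]^2
  }, numeric(1))
}

# Three-residue toy peptide (backbone heavy atoms only, idealised geometry).
toy_peptide_atoms <- function() {
  data.frame(
    resno = rep(1:3, each = 4),
    resid = rep(c("GLY", "ALA", "SER"), each = 4),
    elety = rep(c("N", "CA", "C", "O"), 3),
    element = rep(c("N", "C", "C", "O"), 3),
    chain = "A",
    x = c(0.0, 1.4, 2.1, 1.6, 3.4, 4.2, 5.6, 6.2, 6.3, 7.7, 8.4, 8.0),
    y = c(0.0, 0.2, 1.4, 2.5, 1.4, 2.5, 2.3, 1.2, 3.4, 3.3, 4.5, 5.6),
    z = c(0.0, 0.8, 0.4, 0.2, 0.6, 1.2, 1.0, 0.8, 1.6, 1.8, 2.4, 2.2))
}
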