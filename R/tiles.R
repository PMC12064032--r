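#' @importFrom stats density median rnorm runif rbinom rgamma setNames complete.cases
#' @importFrom utils write.table read.table head
NULL

# Amino-acid alphabet in fixed alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# One fixed codon per amino acid (yeast-preferred where a choice exists) and a
# single alternative synonymous codon used for the per-position synonymous
# wild-type marker. M and W are encoded by a single codon and have no marker.
PRIMARY_CODON <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "TTG", M = "ATG", N = "AAT",
  P = "CCA", Q = "CAA", R = "AGA", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT")

SYNONYM_CODON <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTA", M = NA, N = "AAC",
  P = "CCT", Q = "CAG", R = "CGT", S = "TCC", T = "ACC", V = "GTC",
  W = NA, Y = "TAC")

STOP_CODON <- "TAA"

#' Synthetic reference protein segment
#'
#' A fixed, deterministically generated 270-residue amino-acid sequence used as
#' the default reference for the scored region (positions 487-756 in
#' full-length numbering). It is synthetic: the assayed protein's
#' yeast-codon-optimised coding sequence is not redistributed here, and none of
#' the pipeline's statistics depend on residue identities. Methionine and
#' tryptophan are absent because single-codon amino acids admit no synonymous
#' marker codon (substitutions to M/W remain in the library).
#'
#' @return A length-one character string of 270 one-letter residues.
#' @export
synthetic_reference_protein <- function() {
  paste0(
    "VPGCCYKHQARLTGSIVTPTQRRASCKCDKSYITKPSCCQDGFPDIVEPETYDV",
    "SNYYHSAAKHEVRGENSHLQDQPCGPCKNGHQFSDVTQQSVDSCAYAAVAPLQH",
    "AIHILTPDTQKQQLGVPIPCGHKRGTEHIIHKVHIIKTRCEQATYNAAEQNPIK",
    "YQHHLFCISYVASIFHKFARQKSCRAVYDHEAHHLYVLYARTSAFGCFRELLVE",
    "CFKHYLNRGTYICTYGHNSTFSGNLIGLGPSKEHNEPADQHFKKTGFDQNAKIL")
}

#' Encode a protein segment with the fixed codon table
#'
#' @param aa Character string of one-letter residues.
#' @return Coding DNA string, 3 nucleotides per residue.
#' @export
protein_to_dna <- function(aa) {
  res <- strsplit(aa, "")[[1]]
  bad <- setdiff(res, AA20)
  if (length(bad)) stop("unknown residues: ", paste(unique(bad), collapse = ","))
  paste(PRIMARY_CODON[res], collapse = "")
}

#' Translate a coding DNA string
#'
#' Codon-wise translation with the standard genetic code; stops are "*".
#'
#' @param dna Coding DNA string, length a multiple of 3.
#' @return Character vector of one-letter residues.
#' @export
translate_dna <- function(dna) {
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("coding length not a multiple of 3")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Build a tile configuration
#'
#' Tiles partition a contiguous protein region; each tile carries its own
#' wild-type coding sequence and amplicon context. The default layout is the
#' seven-tile split of positions 487-756 (40, 42, 28, 40, 40, 40, 40 residues),
#' with nonsense mutations programmed only in the final tile.
#'
#' @param boundaries Data frame with columns `tile_id`, `start_pos`, `end_pos`,
#'   `includes_nonsense`.
#' @param ref_protein Reference protein string covering the region.
#' @param region_start Full-length position of the first residue of
#'   `ref_protein`.
#' @return Data frame of class `tilemave_tiles` with one row per tile and an
#'   added `wt_dna` column.
#' @export
make_tiles <- function(boundaries, ref_protein, region_start) {
  stopifnot(all(c("tile_id", "start_pos", "end_pos", "includes_nonsense") %in%
                  names(boundaries)))
  b <- boundaries[order(boundaries$start_pos), , drop = FALSE]
  res <- strsplit(ref_protein, "")[[1]]
  b$wt_dna <- vapply(seq_len(nrow(b)), function(i) {
    idx <- (b$start_pos[i]:b$end_pos[i]) - region_start + 1L
    if (any(idx < 1L) || any(idx > length(res)))
      stop("tile ", b$tile_id[i], " extends beyond the reference")
    protein_to_dna(paste(res[idx], collapse = ""))
  }, character(1))
  rownames(b) <- NULL
  class(b) <- c("tilemave_tiles", "data.frame")
  validate_tiles(b, ref_protein, region_start)
  b
}

#' Default seven-tile layout for a 270-residue C-terminal domain
#'
#' Positions 487-526, 527-568, 569-596, 597-636, 637-676, 677-716 and 717-756;
#' only the last tile programs nonsense substitutions.
#'
#' @param ref_protein Reference protein for positions 487-756; defaults to
#'   [synthetic_reference_protein()].
#' @return A `tilemave_tiles` data frame with 7 rows.
#' @export
default_tiles <- function(ref_protein = synthetic_reference_protein()) {
  boundaries <- data.frame(
    tile_id = 1:7,
    start_pos = c(487L, 527L, 569L, 597L, 637L, 677L, 717L),
    end_pos   = c(526L, 568L, 596L, 636L, 676L, 716L, 756L),
    includes_nonsense = c(rep(FALSE, 6), TRUE))
  make_tiles(boundaries, ref_protein, region_start = 487L)
}

#' Validate a tile configuration
#'
#' Checks that tiles partition a contiguous region without gaps or overlaps and
#' that each tile's coding sequence translates to the reference segment.
#'
#' @inheritParams make_tiles
#' @param tiles A `tilemave_tiles` data frame.
#' @return `tiles`, invisibly; stops on violation.
#' @export
validate_tiles <- function(tiles, ref_protein = NULL, region_start = NULL) {
  b <- tiles[order(tiles$start_pos), , drop = FALSE]
  if (any(b$end_pos < b$start_pos)) stop("tile with end before start")
  if (nrow(b) > 1L) {
    gap <- b$start_pos[-1L] - b$end_pos[-nrow(b)]
    if (any(gap != 1L))
      stop("tiles must partition a contiguous region (gap or overlap at tile ",
           b$tile_id[which(gap != 1L)[1L] + 1L], ")")
  }
  nres <- b$end_pos - b$start_pos + 1L
  if (any(nchar(b$wt_dna) != 3L * nres)) stop("wt_dna length mismatch")
  if (!is.null(ref_protein)) {
    res <- strsplit(ref_protein, "")[[1]]
    for (i in seq_len(nrow(b))) {
      idx <- (b$start_pos[i]:b$end_pos[i]) - region_start + 1L
      if (!identical(translate_dna(b$wt_dna[i]), res[idx]))
        stop("tile ", b$tile_id[i], " coding sequence does not translate to ",
             "the reference segment")
    }
  }
  invisible(tiles)
}

#' Wild-type residue lookup for a tile set
#'
#' @param tiles A `tilemave_tiles` data frame.
#' @return Named character vector of wild-type residues, names = positions.
#' @export
tile_wt_residues <- function(tiles) {
  out <- unlist(lapply(seq_len(nrow(tiles)), function(i) {
    aa <- translate_dna(tiles$wt_dna[i])
    names(aa) <- tiles$start_pos[i]:tiles$end_pos[i]
    aa
  }))
  out[order(as.integer(names(out)))]
}

#' Enumerate the programmed variant library for a tile set
#'
#' For every position: 19 missense substitutions and one synonymous wild-type
#' marker; tiles flagged `includes_nonsense` additionally program one stop
#' (`Ter`) substitution per position. For the default seven-tile layout this
#' yields 19 x 270 + 40 = 5170 non-synonymous keys plus 270 `Syn` markers.
#'
#' @param tiles A `tilemave_tiles` data frame.
#' @return Data frame with columns `position`, `wt_aa`, `alt_aa` (one-letter
#'   residue, `"Ter"`, or `"Syn"`), `tile_id`, in deterministic
#'   position-then-substitution order.
#' @export
design_library <- function(tiles) {
  validate_tiles(tiles)
  rows <- lapply(seq_len(nrow(tiles)), function(i) {
    pos <- tiles$start_pos[i]:tiles$end_pos[i]
    wt <- translate_dna(tiles$wt_dna[i])
    n_alt <- 20L + tiles$includes_nonsense[i]  # 19 missense + [Ter] + Syn
    alts <- c(if (tiles$includes_nonsense[i])
      vapply(wt, function(a) c(setdiff(AA20, a), "Ter", "Syn"),
             character(21))
      else vapply(wt, function(a) c(setdiff(AA20, a), "Syn"),
                  character(20)))
    data.frame(position = rep(pos, each = n_alt),
               wt_aa = rep(wt, each = n_alt), alt_aa = as.vector(alts),
               tile_id = tiles$tile_id[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label variants in protein notation
#'
#' @param library Data frame with `position`, `wt_aa`, `alt_aa`.
#' @return Character vector like `"L550P"`, `"Q542Ter"`, `"A490Syn"`.
#' @export
variant_label <- function(library) {
  paste0(library$wt_aa, library$position, library$alt_aa)
}
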