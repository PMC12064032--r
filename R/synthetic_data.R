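# Amplicon geometry shared by the read simulator and the variant caller.
# Every tile is embedded in fixed primer/adapter flanks so that all amplicons
# have the same total length; with 151-nt mates this places the entire coding
# region inside the mutual overlap of the two reads.
AMPLICON_LEN <- 176L
READ_LEN <- 151L
FLANK5 <- "ACACGACGCTCTTCCGATCTGTACA"  # 25 nt
FLANK3_POOL <- paste0("AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                      "GTAGCTAGCCTGATCGATGCTAGCTAAGCTTGG",
                      "CATGACCTGAGGTCATCCAGTGGACTTCAGAAC",
                      "GCTTACGGATCCAAGCTTGAGCTCGAGATCTGA",
                      "TCGACCTCGAGGGG")  # 148 nt, covers a 1-residue tile

#' Amplicon context of a tile
#'
#' @param tile One row of a `tilemave_tiles` data frame.
#' @return List with `amplicon` (wild-type amplicon sequence), `coding_start`
#'   (1-based offset of the first coding base) and `offset` (shift between the
#'   two mates, i.e. amplicon length minus read length).
#' @export
tile_amplicon <- function(tile) {
  coding <- tile$wt_dna
  flank3_len <- AMPLICON_LEN - nchar(FLANK5) - nchar(coding)
  if (flank3_len < 0L)
    stop("tile ", tile$tile_id, " coding sequence too long for the amplicon")
  if (flank3_len > nchar(FLANK3_POOL))
    stop("tile ", tile$tile_id, " too short for the fixed amplicon length")
  list(amplicon = paste0(FLANK5, coding, substr(FLANK3_POOL, 1L, flank3_len)),
       coding_start = nchar(FLANK5) + 1L,
       offset = AMPLICON_LEN - READ_LEN)
}

#' Simulation parameters for the synthetic dual-assay screen
#'
#' Defaults emulate the study conditions of a tiled site-saturation screen read
#' out by growth selection: sequencing depth of 200 reads per variant and
#' condition, three replicates, selection strength `k = 2` mapping the true
#' score to a log growth advantage, and per-tile low-abundance modes drawn
#' uniformly in [-3.5, -1.5] to reproduce the tile-to-tile variation of the
#' destabilised peak. The abundance truth is a two-component mixture (wild-type
#' mode at 0, mixture weight `frac_low` of destabilised variants); the
#' interaction truth is a sharp unimodal core with sparse loss and gain tails.
#'
#' @param depth Expected reads per variant per condition.
#' @param n_replicates Number of selection replicates (>= 2).
#' @param k Selection strength multiplier.
#' @param replicate_noise_sd SD of the multiplicative replicate noise on the
#'   log growth advantage.
#' @param frac_low Mixture weight of the low-abundance component.
#' @param low_mode_range Range the per-tile low-abundance mode is drawn from.
#' @param low_sd,wt_sd SDs of the low-abundance and wild-type-like abundance
#'   components.
#' @param loss_mode,loss_sd Location/SD of the loss-of-interaction tail.
#' @param p_loss_given_low Probability that a destabilised variant also loses
#'   interaction.
#' @param p_loss_indep Probability of interaction loss for a stable variant.
#' @param gain_positions Positions whose hydrophobic/aromatic substitutions
#'   gain interaction.
#' @param gain_mean,gain_sd Location/SD of the gain-of-interaction tail.
#' @param ter_tolerated_from First position from which nonsense variants are
#'   tolerated (mildly increased abundance) rather than destabilising.
#' @param error_rate Per-base sequencing error probability.
#' @param seed Integer master seed.
#' @return List of class `tilemave_sim_params`.
#' @export
sim_params <- function(depth = 200, n_replicates = 3L, k = 2,
                       replicate_noise_sd = 0.1, frac_low = 0.4,
                       low_mode_range = c(-3.5, -1.5), low_sd = 0.15,
                       wt_sd = 0.2, loss_mode = -2, loss_sd = 0.3,
                       p_loss_given_low = 0.8, p_loss_indep = 0.02,
                       gain_positions = 601:604, gain_mean = 1, gain_sd = 0.2,
                       ter_tolerated_from = 745L, error_rate = 0.001,
                       seed = 1L) {
  stopifnot(depth > 0, n_replicates >= 2L, error_rate >= 0, error_rate <= 1,
            frac_low >= 0, frac_low <= 1, p_loss_given_low >= 0,
            p_loss_given_low <= 1, p_loss_indep >= 0, p_loss_indep <= 1,
            diff(low_mode_range) >= 0, low_mode_range[2] < 0)
  structure(as.list(environment()), class = "tilemave_sim_params")
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so all randomness flows from explicit seeds.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Per-stage seeds derived from the master seed with a fixed counter so that
# adding a stage never shifts another stage's random stream.
stage_seed <- function(seed, stage) {
  stages <- c(effects = 1L, counts = 2L, fastq = 3L, other = 9L)
  idx <- stages[[stage]]
  (as.integer(seed) * 101L + idx * 7919L) %% 2147483647L
}

#' Draw ground-truth variant effects
#'
#' Assigns every library member a true abundance effect, a true interaction
#' effect and a mixture class. Synonymous markers are exactly neutral. Nonsense
#' variants before `ter_tolerated_from` are forced into the low-abundance
#' class; later ones get mildly positive truths, mimicking tolerated C-terminal
#' truncation.
#'
#' @param library Data frame from [design_library()].
#' @param params [sim_params()] list.
#' @param seed Seed; defaults to the stage seed derived from `params$seed`.
#' @return `library` with added columns `true_abundance`, `true_interaction`,
#'   `mixture_class`, plus an attribute `low_modes` (named per-tile vector).
#' @export
draw_effects <- function(library, params = sim_params(),
                         seed = stage_seed(params$seed, "effects")) {
  stopifnot(nrow(library) > 0)
  with_seed(seed, {
    tiles_present <- sort(unique(library$tile_id))
    low_modes <- setNames(
      runif(length(tiles_present), params$low_mode_range[1],
            params$low_mode_range[2]),
      tiles_present)
    n <- nrow(library)
    ab <- numeric(n); int <- numeric(n)
    cls <- rep("WT-like", n)
    is_syn <- library$alt_aa == "Syn"
    is_ter <- library$alt_aa == "Ter"
    is_mis <- !is_syn & !is_ter
    mode_of <- low_modes[as.character(library$tile_id)]

    # abundance mixture
    low <- (is_mis & rbinom(n, 1L, params$frac_low) == 1L) |
      (is_ter & library$position < params$ter_tolerated_from)
    ab[low] <- rnorm(sum(low), mode_of[low], params$low_sd)
    wtlike <- !low & !is_syn
    ab[wtlike] <- rnorm(sum(wtlike), 0, params$wt_sd)
    ter_ok <- is_ter & library$position >= params$ter_tolerated_from
    ab[ter_ok] <- abs(rnorm(sum(ter_ok), 0.3, 0.05))
    cls[low] <- "low-abundance"

    # interaction: sharp core, loss tail coupled to destabilisation, sparse
    # independent loss, and a planted gain region
    int[!is_syn] <- rnorm(sum(!is_syn), 0, params$wt_sd)
    loss <- (low & rbinom(n, 1L, params$p_loss_given_low) == 1L) |
      (wtlike & is_mis & rbinom(n, 1L, params$p_loss_indep) == 1L)
    int[loss] <- rnorm(sum(loss), params$loss_mode, params$loss_sd)
    cls[loss & !low] <- "loss-of-interaction"
    hydrophobic <- c("F", "I", "L", "M", "V", "W", "Y")
    gain <- wtlike & is_mis & library$position %in% params$gain_positions &
      library$alt_aa %in% hydrophobic
    int[gain] <- rnorm(sum(gain), params$gain_mean, params$gain_sd)
    int[ter_ok] <- abs(rnorm(sum(ter_ok), 0.3, 0.05))
    cls[gain] <- "gain-of-interaction"

    ab[is_syn] <- 0; int[is_syn] <- 0; cls[is_syn] <- "WT-like"
    out <- library
    out$true_abundance <- ab
    out$true_interaction <- int
    out$mixture_class <- cls
    attr(out, "low_modes") <- low_modes
    out
  })
}

#' Simulate selection-driven count tables
#'
#' Models plate selection per tile and assay: control frequencies are Dirichlet
#' around uniform library representation; selection frequencies are
#' proportional to `f_ctrl * exp(k * truth * (1 + noise))` with independent
#' multiplicative replicate noise per variant and replicate; counts are
#' multinomial at a total depth of `depth` reads per variant.
#'
#' @param truths Data frame from [draw_effects()].
#' @param params [sim_params()] list.
#' @param assays Which assays to simulate (`"abundance"` uses
#'   `true_abundance`, `"interaction"` uses `true_interaction`).
#' @param seed Seed; defaults to the stage seed derived from `params$seed`.
#' @return Long data frame (class `tilemave_counts`) with columns `tile_id`,
#'   `position`, `wt_aa`, `alt_aa`, `assay`, `condition`
#'   (control/selection), `replicate`, `count`.
#' @export
simulate_counts <- function(truths, params = sim_params(),
                            assays = c("abundance", "interaction"),
                            seed = stage_seed(params$seed, "counts")) {
  with_seed(seed, {
    pieces <- list()
    for (assay in assays) {
      truth_col <- paste0("true_", assay)
      for (tid in sort(unique(truths$tile_id))) {
        sub <- truths[truths$tile_id == tid, , drop = FALSE]
        m <- nrow(sub)
        total <- round(params$depth * m)
        f_ctrl <- rgamma(m, shape = 50, rate = 1)
        f_ctrl <- f_ctrl / sum(f_ctrl)
        for (r in seq_len(params$n_replicates)) {
          noise <- rnorm(m, 0, params$replicate_noise_sd)
          w_sel <- f_ctrl * exp(params$k * sub[[truth_col]] * (1 + noise))
          c_ctrl <- as.vector(stats::rmultinom(1L, total, f_ctrl))
          c_sel <- as.vector(stats::rmultinom(1L, total, w_sel / sum(w_sel)))
          pieces[[length(pieces) + 1L]] <- data.frame(
            tile_id = tid, position = sub$position, wt_aa = sub$wt_aa,
            alt_aa = sub$alt_aa, assay = assay,
            condition = rep(c("control", "selection"), each = m),
            replicate = r, count = c(c_ctrl, c_sel))
        }
      }
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    class(out) <- c("tilemave_counts", "data.frame")
    out
  })
}

# Reverse complement of a character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Apply independent per-base substitution errors to reads (character vector).
apply_seq_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), error_rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(chars), n_err[i])
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(bases, b), 1L), "")
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

# Build the mutant amplicon for one variant key within a tile.
mutant_amplicon <- function(tile, ctx, position, alt_aa) {
  rel <- position - tile$start_pos  # 0-based codon index
  codon_start <- ctx$coding_start + 3L * rel
  wt_codon <- substr(ctx$amplicon, codon_start, codon_start + 2L)
  new_codon <- if (alt_aa == "Syn") {
    aa <- Biostrings::GENETIC_CODE[[wt_codon]]
    syn <- SYNONYM_CODON[[aa]]
    if (is.na(syn)) stop("no synonymous marker codon for ", aa)
    syn
  } else if (alt_aa == "Ter") STOP_CODON else PRIMARY_CODON[[alt_aa]]
  paste0(substr(ctx$amplicon, 1L, codon_start - 1L), new_codon,
         substr(ctx$amplicon, codon_start + 3L, nchar(ctx$amplicon)))
}

#' Emit paired-end FASTQ for a count table
#'
#' Each counted molecule yields one read pair: R1 is the first 151 nt of the
#' variant amplicon, R2 the reverse complement of its last 151 nt, so the
#' mates fully cover the tile from opposite ends. Per-base substitution errors
#' are applied independently to each mate at `params$error_rate`; qualities are
#' written as constant Phred 37 (offset 33).
#'
#' @param counts Count table (one assay), e.g. from [simulate_counts()].
#' @param tiles `tilemave_tiles` data frame.
#' @param params [sim_params()] list.
#' @param dir Output directory for the FASTQ files.
#' @param seed Seed; defaults to the stage seed derived from `params$seed`.
#' @return Data frame manifest with one row per (tile, condition, replicate)
#'   and columns `tile_id`, `condition`, `replicate`, `r1`, `r2`, `n_pairs`.
#' @export
emit_fastq <- function(counts, tiles, params = sim_params(), dir = tempdir(),
                       seed = stage_seed(params$seed, "fastq")) {
  if (length(unique(counts$assay)) > 1L)
    stop("emit_fastq expects counts for a single assay")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    manifest <- list()
    for (tid in sort(unique(counts$tile_id))) {
      tile <- tiles[tiles$tile_id == tid, , drop = FALSE]
      ctx <- tile_amplicon(tile)
      sub <- counts[counts$tile_id == tid, , drop = FALSE]
      keys <- unique(sub[, c("position", "alt_aa")])
      amp <- vapply(seq_len(nrow(keys)), function(i)
        mutant_amplicon(tile, ctx, keys$position[i], keys$alt_aa[i]), "")
      key_id <- paste(keys$position, keys$alt_aa)
      amp_of <- setNames(amp, key_id)
      for (cond in unique(sub$condition)) for (r in unique(sub$replicate)) {
        cell <- sub[sub$condition == cond & sub$replicate == r, , drop = FALSE]
        cell <- cell[cell$count > 0L, , drop = FALSE]
        amps <- rep(amp_of[paste(cell$position, cell$alt_aa)], cell$count)
        r1 <- substr(amps, 1L, READ_LEN)
        r2 <- revcomp(substr(amps, nchar(amps) - READ_LEN + 1L, nchar(amps)))
        r1 <- apply_seq_errors(r1, params$error_rate)
        r2 <- apply_seq_errors(r2, params$error_rate)
        stem <- file.path(dir, sprintf("tile%d_%s_rep%d", tid, cond, r))
        qual <- strrep("F", READ_LEN)
        ids <- sprintf("t%d:%s:r%d:%07d", tid, cond, r, seq_along(r1))
        write_fastq(paste0(stem, "_R1.fastq"), ids, r1, qual)
        write_fastq(paste0(stem, "_R2.fastq"), ids, r2, qual)
        manifest[[length(manifest) + 1L]] <- data.frame(
          tile_id = tid, condition = cond, replicate = r,
          r1 = paste0(stem, "_R1.fastq"), r2 = paste0(stem, "_R2.fastq"),
          n_pairs = length(r1))
      }
    }
    out <- do.call(rbind, manifest)
    rownames(out) <- NULL
    out
  })
}

# Minimal 4-line-record FASTQ writer (constant or per-read quality strings).
write_fastq <- function(path, ids, seqs, quals) {
  if (length(quals) == 1L) quals <- rep(quals, length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}

#' Write a ground-truth table as TSV
#'
#' @param truths Data frame from [draw_effects()].
#' @param path Output TSV path.
#' @export
write_truth_tsv <- function(truths, path) {
  utils::write.table(
    data.frame(variant = variant_label(truths),
               truths[, c("tile_id", "position", "wt_aa", "alt_aa",
                          "true_abundance", "true_interaction",
                          "mixture_class")]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tile configuration as YAML
#'
#' @param tiles `tilemave_tiles` data frame.
#' @param path Output YAML path.
#' @export
write_tiles_yaml <- function(tiles, path) {
  yaml::write_yaml(lapply(seq_len(nrow(tiles)), function(i)
    as.list(tiles[i, , drop = FALSE])), path)
  invisible(path)
}
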