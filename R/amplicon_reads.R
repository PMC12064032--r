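#' Read-pair filtering and overlap-merge policy
#'
#' Defaults reproduce the stated preprocessing: mates shorter than 151 nt are
#' dropped and survivors cropped to 151 nt; minimum and average base quality of
#' 1, no ambiguous bases; zero mismatches tolerated between the mates inside
#' their overlap ("unresolvable" pairs removed); only positions covered by both
#' mates are used for variant calling. "Maximum mismatches" refers to
#' disagreement between the two mates inside the overlap, not to differences
#' versus the wild-type sequence.
#'
#' @param min_len Minimum mate length before cropping.
#' @param crop_len Length mates are cropped to.
#' @param min_quality Minimum per-base Phred quality.
#' @param avg_quality Minimum mean Phred quality (inclusive boundary).
#' @param max_n Maximum number of ambiguous (N) bases per mate.
#' @param max_overlap_mismatches Maximum tolerated mate disagreements in the
#'   overlap; disagreements within tolerance are resolved by the
#'   higher-quality base.
#' @param overlap_only If `TRUE`, codons not fully covered by both mates are
#'   excluded from variant calling.
#' @param remove_unresolvable Drop pairs whose overlap disagreement exceeds
#'   `max_overlap_mismatches`.
#' @param keep_multi Retain reads with multiple amino-acid changes as distinct
#'   multi-variant keys (for QC) instead of rejecting them.
#' @param phred_offset ASCII offset of the quality encoding.
#' @return List of class `tilemave_merge_policy`.
#' @export
merge_policy <- function(min_len = 151L, crop_len = 151L, min_quality = 1L,
                         avg_quality = 1L, max_n = 0L,
                         max_overlap_mismatches = 0L, overlap_only = TRUE,
                         remove_unresolvable = TRUE, keep_multi = FALSE,
                         phred_offset = 33L) {
  stopifnot(min_len >= 0, crop_len >= 0, min_quality >= 0, avg_quality >= 0,
            max_n >= 0, max_overlap_mismatches >= 0)
  structure(as.list(environment()), class = "tilemave_merge_policy")
}

#' Read a pair of FASTQ files
#'
#' @param r1_path,r2_path Paths to the mate FASTQ files (gzip allowed).
#' @return Data frame with columns `id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual` (sequences and quality strings as characters).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  rd <- function(path) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    list(id = names(x), seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1_path); b <- rd(r2_path)
  if (length(a$seq) != length(b$seq))
    stop("mate files differ in record count")
  data.frame(id = a$id, r1_seq = unname(a$seq), r1_qual = unname(a$qual),
             r2_seq = unname(b$seq), r2_qual = unname(b$qual))
}

# Per-read (min, mean) Phred quality from a quality string vector.
qual_stats <- function(quals, phred_offset) {
  t(vapply(quals, function(q) {
    v <- utf8ToInt(q) - phred_offset
    c(min(v), mean(v))
  }, numeric(2), USE.NAMES = FALSE))
}

count_N <- function(seqs) nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))

#' Length/quality filtering and cropping of read pairs
#'
#' Mates shorter than `min_len` are dropped, survivors cropped to `crop_len`;
#' a pair is kept only if both mates meet the per-base and mean quality
#' thresholds (boundary inclusive) and the ambiguous-base limit.
#'
#' @param pairs Data frame from [read_fastq_pairs()].
#' @param policy [merge_policy()] list.
#' @return Filtered, cropped `pairs`; attribute `n_dropped` records the count.
#' @export
trim_and_filter <- function(pairs, policy = merge_policy()) {
  long_enough <- nchar(pairs$r1_seq) >= policy$min_len &
    nchar(pairs$r2_seq) >= policy$min_len
  p <- pairs[long_enough, , drop = FALSE]
  for (col in c("r1_seq", "r1_qual", "r2_seq", "r2_qual"))
    p[[col]] <- substr(p[[col]], 1L, policy$crop_len)
  ok <- rep(TRUE, nrow(p))
  for (m in c("r1", "r2")) {
    qs <- qual_stats(p[[paste0(m, "_qual")]], policy$phred_offset)
    ok <- ok & qs[, 1] >= policy$min_quality & qs[, 2] >= policy$avg_quality &
      count_N(p[[paste0(m, "_seq")]]) <= policy$max_n
  }
  out <- p[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nrow(pairs) - nrow(out)
  out
}

# Count character mismatches between two equal-length strings.
str_mismatches <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

#' Merge one read pair at a fixed amplicon offset
#'
#' The reverse mate is reverse-complemented and aligned at
#' `offset = amplicon length - read length`; the merged sequence has length
#' `read length + offset`. Overlap disagreements beyond the policy's tolerance
#' reject the pair as unresolvable; tolerated disagreements are resolved by
#' the higher-quality base.
#'
#' @param r1_seq,r1_qual,r2_seq,r2_qual One read pair (R2 in sequencing
#'   orientation).
#' @param offset Mate shift in nucleotides (>= 0, < read length).
#' @param policy [merge_policy()] list.
#' @param r2_rc Optional precomputed reverse complement of `r2_seq` (batch
#'   callers avoid repeated single-sequence conversions).
#' @return List with `status` (`"merged"` or `"unresolvable"`), `merged`
#'   (sequence or `NA`), `overlap_start`, `overlap_end` (merged coordinates
#'   covered by both mates), `n_mismatch`.
#' @export
merge_overlap <- function(r1_seq, r1_qual, r2_seq, r2_qual, offset,
                          policy = merge_policy(), r2_rc = NULL) {
  len <- nchar(r1_seq)
  if (offset >= len) stop("amplicon offset not smaller than read length")
  r2rc <- if (is.null(r2_rc)) revcomp(r2_seq) else r2_rc
  ov_len <- len - offset
  s1 <- substr(r1_seq, offset + 1L, len)
  s2 <- substr(r2rc, 1L, ov_len)
  v1 <- utf8ToInt(s1); v2 <- utf8ToInt(s2)
  mm <- which(v1 != v2)
  if (length(mm) > policy$max_overlap_mismatches && policy$remove_unresolvable)
    return(list(status = "unresolvable", merged = NA_character_,
                overlap_start = offset + 1L, overlap_end = len,
                n_mismatch = length(mm)))
  ov <- v1
  if (length(mm)) {
    q2r <- paste(rev(strsplit(r2_qual, "")[[1]]), collapse = "")
    q1 <- utf8ToInt(substr(r1_qual, offset + 1L, len))[mm]
    q2 <- utf8ToInt(substr(q2r, 1L, ov_len))[mm]
    ov[mm] <- ifelse(q2 > q1, v2[mm], v1[mm])
  }
  merged <- paste0(substr(r1_seq, 1L, offset), intToUtf8(ov),
                   substr(r2rc, ov_len + 1L, len))
  list(status = "merged", merged = merged,
       overlap_start = offset + 1L, overlap_end = len,
       n_mismatch = length(mm))
}

#' Call the variant encoded by a merged amplicon sequence
#'
#' The coding region is compared codon-by-codon to the tile's wild-type
#' sequence. No changed codons is a wild-type call; a single silent codon
#' change is a synonymous (`Syn`) call at that position; exactly one
#' amino-acid-changing codon yields that variant key (a stop codon gives
#' `Ter`); anything else is rejected (the libraries are single-substitution by
#' design) unless `policy$keep_multi` retains multi-keys for QC. With
#' `overlap_only`, codons not fully inside the mate overlap are excluded from
#' the comparison.
#'
#' @param merged Merged amplicon sequence.
#' @param tile One row of a `tilemave_tiles` data frame.
#' @param policy [merge_policy()] list.
#' @param overlap_start,overlap_end Merged coordinates covered by both mates.
#' @return List with `type` (`"wt"`, `"syn"`, `"variant"`, `"multi"`, or
#'   `"rejected"`), and for calls `position`, `wt_aa`, `alt_aa`; rejections
#'   carry a `reason`.
#' @export
call_variant <- function(merged, tile, policy = merge_policy(),
                         overlap_start = 1L, overlap_end = nchar(merged)) {
  ctx <- tile_amplicon(tile)
  n_codon <- nchar(tile$wt_dna) %/% 3L
  starts <- ctx$coding_start + 3L * (seq_len(n_codon) - 1L)
  if (max(starts) + 2L > nchar(merged))
    return(list(type = "rejected", reason = "incomplete_coding"))
  in_frame <- rep(TRUE, n_codon)
  if (policy$overlap_only)
    in_frame <- starts >= overlap_start & (starts + 2L) <= overlap_end
  obs <- substring(merged, starts, starts + 2L)
  wt <- substring(tile$wt_dna, 3L * (seq_len(n_codon) - 1L) + 1L,
                  3L * seq_len(n_codon))
  diff <- which(obs != wt & in_frame)
  if (any(!obs[diff] %in% names(Biostrings::GENETIC_CODE)))
    return(list(type = "rejected", reason = "ambiguous_base"))
  if (!length(diff)) return(list(type = "wt"))
  obs_aa <- unname(Biostrings::GENETIC_CODE[obs[diff]])
  wt_aa <- unname(Biostrings::GENETIC_CODE[wt[diff]])
  silent <- obs_aa == wt_aa
  pos <- tile$start_pos + diff - 1L
  if (all(silent)) {
    if (length(diff) == 1L)
      return(list(type = "syn", position = pos, wt_aa = wt_aa,
                  alt_aa = "Syn"))
    return(list(type = "rejected", reason = "multiple_synonymous"))
  }
  changed <- which(!silent)
  if (length(changed) == 1L && length(diff) == 1L) {
    alt <- if (obs_aa[changed] == "*") "Ter" else obs_aa[changed]
    return(list(type = "variant", position = pos[changed],
                wt_aa = wt_aa[changed], alt_aa = alt))
  }
  if (policy$keep_multi) {
    alt <- ifelse(obs_aa == "*", "Ter", obs_aa)
    return(list(type = "multi",
                key = paste(paste0(wt_aa, pos, alt), collapse = ",")))
  }
  list(type = "rejected", reason = "multiple_aa_changes")
}

# Vectorised merge + call over many read pairs of one tile; operates on unique
# (r1, r2) sequence pairs so error-free data is called once per variant.
call_pairs <- function(pairs, tile, policy) {
  ctx <- tile_amplicon(tile)
  key <- paste(pairs$r1_seq, pairs$r2_seq)
  ux <- !duplicated(key)
  uniq <- pairs[ux, , drop = FALSE]
  r2rc_all <- revcomp(uniq$r2_seq)
  calls <- lapply(seq_len(nrow(uniq)), function(i) {
    m <- merge_overlap(uniq$r1_seq[i], uniq$r1_qual[i], uniq$r2_seq[i],
                       uniq$r2_qual[i], ctx$offset, policy,
                       r2_rc = r2rc_all[i])
    if (m$status != "merged")
      return(list(type = "rejected", reason = "unresolvable_overlap"))
    call_variant(m$merged, tile, policy, m$overlap_start, m$overlap_end)
  })
  idx <- match(key, key[ux])
  list(calls = calls, idx = idx)
}

#' Count variants from paired FASTQ files
#'
#' Runs filtering, overlap merging and codon-level calling for each listed
#' file pair and tallies accepted calls per variant key. Every input pair ends
#' up in exactly one of: a variant/Syn key, the wild-type tally, or a rejection
#' reason (conservation is asserted internally).
#'
#' @param manifest Data frame with columns `tile_id`, `condition`,
#'   `replicate`, `r1`, `r2` (as produced by [emit_fastq()]).
#' @param tiles `tilemave_tiles` data frame.
#' @param policy [merge_policy()] list.
#' @return Count table (class `tilemave_counts`) with columns `tile_id`,
#'   `position`, `wt_aa`, `alt_aa` (`Syn`, `Ter`, residue, or `WT` for exact
#'   wild-type reads with `position = NA`), `condition`, `replicate`, `count`;
#'   attribute `qc` holds a per-file list of totals and rejection reasons.
#' @export
count_variants <- function(manifest, tiles, policy = merge_policy()) {
  need <- c("tile_id", "condition", "replicate", "r1", "r2")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  out <- list(); qc <- list()
  for (i in seq_len(nrow(manifest))) {
    tile <- tiles[tiles$tile_id == manifest$tile_id[i], , drop = FALSE]
    if (!nrow(tile)) stop("unknown tile_id ", manifest$tile_id[i])
    pairs <- read_fastq_pairs(manifest$r1[i], manifest$r2[i])
    n_in <- nrow(pairs)
    kept <- trim_and_filter(pairs, policy)
    n_filtered <- attr(kept, "n_dropped")
    if (nrow(kept)) {
      cp <- call_pairs(kept, tile, policy)
      types <- vapply(cp$calls, `[[`, "", "type")[cp$idx]
      keys <- vapply(cp$calls, function(cl) {
        switch(cl$type,
               wt = "NA WT NA",
               syn = ,
               variant = paste(cl$position, cl$alt_aa, cl$wt_aa),
               multi = paste(NA, cl$key, NA),
               paste(NA, "rej", cl$reason))
      }, "")[cp$idx]
      accept <- types %in% c("wt", "syn", "variant", "multi")
      tab <- table(keys[accept])
      parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
      out[[i]] <- data.frame(
        tile_id = tile$tile_id,
        position = suppressWarnings(as.integer(parts[, 1])),
        wt_aa = ifelse(parts[, 3] == "NA", NA, parts[, 3]),
        alt_aa = parts[, 2],
        condition = manifest$condition[i], replicate = manifest$replicate[i],
        count = as.integer(tab))
      rej <- table(sub("^NA rej ", "", keys[!accept]))
      n_rej <- sum(!accept)
    } else {
      rej <- table(character(0)); n_rej <- 0L
    }
    qc[[i]] <- list(tile_id = tile$tile_id,
                    condition = manifest$condition[i],
                    replicate = manifest$replicate[i],
                    n_pairs = n_in, n_filtered = n_filtered,
                    n_rejected = n_rej,
                    n_accepted = n_in - n_filtered - n_rej,
                    rejection_reasons = as.list(rej))
    stopifnot(qc[[i]]$n_accepted + n_filtered + n_rej == n_in)
  }
  counts <- do.call(rbind, out)
  if (is.null(counts))
    counts <- data.frame(tile_id = integer(), position = integer(),
                         wt_aa = character(), alt_aa = character(),
                         condition = character(), replicate = integer(),
                         count = integer())
  rownames(counts) <- NULL
  class(counts) <- c("tilemave_counts", "data.frame")
  attr(counts, "qc") <- qc
  counts
}

#' Write a count table as TSV
#'
#' @param counts `tilemave_counts` data frame.
#' @param path Output TSV path.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the QC report of a count run as JSON
#'
#' @param counts `tilemave_counts` with a `qc` attribute.
#' @param path Output JSON path.
#' @export
write_qc_json <- function(counts, path) {
  jsonlite::write_json(attr(counts, "qc"), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
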