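test_that("length, N and quality filters drop the right pairs", {
  good <- strrep("A", 151)
  short <- strrep("A", 150)
  withN <- paste0(strrep("A", 75), "N", strrep("A", 75))
  p <- merge_policy()

  pairs <- data.frame(id = "x", r1_seq = short, r1_qual = strrep("F", 150),
                      r2_seq = good, r2_qual = strrep("F", 151))
  expect_equal(nrow(trim_and_filter(pairs, p)), 0L)

  pairs <- data.frame(id = "x", r1_seq = withN, r1_qual = strrep("F", 151),
                      r2_seq = good, r2_qual = strrep("F", 151))
  expect_equal(nrow(trim_and_filter(pairs, p)), 0L)
  expect_equal(nrow(trim_and_filter(pairs, merge_policy(max_n = 1))), 1L)

  # a zero-quality base ('!' = Phred 0) fails min_quality = 1, boundary is
  # inclusive so Phred 1 ('"') passes
  q_bad <- paste0(strrep("F", 150), "!")
  q_edge <- paste0(strrep("F", 150), "\"")
  pairs <- data.frame(id = c("a", "b"), r1_seq = good,
                      r1_qual = c(q_bad, q_edge), r2_seq = good,
                      r2_qual = strrep("F", 151))
  expect_equal(nrow(trim_and_filter(pairs, p)), 1L)

  # construction count: 100 good + 50 short pairs -> 100 survivors
  f <- tmp_fastq_pair(c(rep(good, 100), rep(short, 50)),
                      c(rep(good, 100), rep(short, 50)),
                      q1 = c(rep(strrep("F", 151), 100),
                             rep(strrep("F", 150), 50)))
  got <- trim_and_filter(read_fastq_pairs(f[1], f[2]), p)
  expect_equal(nrow(got), 100L)
  expect_equal(attr(got, "n_dropped"), 50L)
  # reads longer than crop_len are cropped to it
  expect_true(all(nchar(got$r1_seq) == 151L))
})

test_that("overlap merging applies the mismatch policy at a fixed offset", {
  # identical mates over full overlap (offset 0): merged equals the mate
  s <- paste(sample(c("A", "C", "G", "T"), 151, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  q <- strrep("F", 151)
  m <- merge_overlap(s, q, rc, q, offset = 0)
  expect_identical(m$merged, s)
  expect_equal(m$n_mismatch, 0L)

  # one overlap mismatch with the default zero tolerance: rejected
  s2 <- s
  substr(s2, 80, 80) <- setdiff(c("A", "C", "G", "T"),
                                substr(s2, 80, 80))[1]
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s2)))
  m2 <- merge_overlap(s, q, rc2, q, offset = 0)
  expect_equal(m2$status, "unresolvable")
  expect_equal(m2$n_mismatch, 1L)

  # with tolerance 1 the disagreement resolves to the higher-quality base
  q_low <- paste0(strrep("F", 79), "#", strrep("F", 71))
  m3 <- merge_overlap(s, q_low, rc2, q, offset = 0,
                      policy = merge_policy(max_overlap_mismatches = 1))
  expect_equal(m3$status, "merged")
  expect_identical(substr(m3$merged, 80, 80), substr(s2, 80, 80))

  # constructed offset 20: merged length is 151 + 20
  amp <- paste(sample(c("A", "C", "G", "T"), 171, replace = TRUE),
               collapse = "")
  r1 <- substr(amp, 1, 151)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amp, 21, 171))))
  m4 <- merge_overlap(r1, q, r2, q, offset = 20)
  expect_equal(nchar(m4$merged), 171L)
  expect_identical(m4$merged, amp)
  expect_error(merge_overlap(r1, q, r2, q, offset = 151), "offset")
})

test_that("codon-level calling classifies wild-type, Syn, single and multi variants", {
  tiles <- mini_tiles()
  tile <- tiles[1, , drop = FALSE]
  ctx <- tile_amplicon(tile)
  p <- merge_policy()
  wt <- call_variant(ctx$amplicon, tile, p)
  expect_equal(wt$type, "wt")

  # single amino-acid-changing codon at position 490 -> that variant key
  mut <- tilemave:::mutant_amplicon(tile, ctx, 490L, "P")
  v <- call_variant(mut, tile, p)
  expect_equal(v[c("type", "position", "alt_aa")],
               list(type = "variant", position = 490L, alt_aa = "P"))
  expect_equal(v$wt_aa, substr(synthetic_reference_protein(), 4, 4))

  # synonymous marker codon -> Syn call at that position
  syn <- tilemave:::mutant_amplicon(tile, ctx, 492L, "Syn")
  expect_equal(call_variant(syn, tile, p)[c("type", "position")],
               list(type = "syn", position = 492L))

  # stop codon -> Ter
  ter <- tilemave:::mutant_amplicon(tile, ctx, 493L, "Ter")
  expect_equal(call_variant(ter, tile, p)$alt_aa, "Ter")

  # two nonsynonymous codon changes -> rejected by default, kept as a
  # multi-key for QC when requested
  mut2 <- tilemave:::mutant_amplicon(tile, ctx, 494L, "G")
  codon_start <- ctx$coding_start + 3 * (490 - tile$start_pos)
  substr(mut2, codon_start, codon_start + 2) <- "CCA"
  expect_equal(call_variant(mut2, tile, p)$type, "rejected")
  keep <- call_variant(mut2, tile, merge_policy(keep_multi = TRUE))
  expect_equal(keep$type, "multi")
  expect_match(keep$key, "490P")
  expect_match(keep$key, "494G")
})

test_that("strand handling is consistent: paired calling equals direct calling", {
  tiles <- mini_tiles()
  tile <- tiles[2, , drop = FALSE]
  pr <- amplicon_pair(tile, 500L, "K")
  m <- merge_overlap(pr$r1, strrep("F", 151), pr$r2, strrep("F", 151),
                     offset = nchar(pr$amplicon) - 151)
  via_pair <- call_variant(m$merged, tile, merge_policy(),
                           m$overlap_start, m$overlap_end)
  direct <- call_variant(pr$amplicon, tile, merge_policy())
  expect_equal(via_pair[c("type", "position", "wt_aa", "alt_aa")],
               direct[c("type", "position", "wt_aa", "alt_aa")])
})

test_that("count_variants tallies calls and conserves every input pair", {
  tiles <- mini_tiles()
  tile <- tiles[1, , drop = FALSE]
  pr <- amplicon_pair(tile, 491L, "R")
  f <- tmp_fastq_pair(rep(pr$r1, 1000), rep(pr$r2, 1000))
  man <- data.frame(tile_id = 1L, condition = "control", replicate = 1L,
                    r1 = f[1], r2 = f[2])
  ct <- count_variants(man, tiles)
  expect_equal(ct$count[ct$position == 491 & ct$alt_aa == "R"], 1000L)
  qc <- attr(ct, "qc")[[1]]
  expect_equal(qc$n_accepted, 1000L)

  # empty file
  fe <- tmp_fastq_pair(character(0), character(0))
  cte <- count_variants(data.frame(tile_id = 1L, condition = "control",
                                   replicate = 1L, r1 = fe[1], r2 = fe[2]),
                        tiles)
  expect_equal(nrow(cte), 0L)
  expect_equal(attr(cte, "qc")[[1]]$n_pairs, 0L)

  # conservation with a mix of good, mismatching and short pairs
  bad_r2 <- pr$r2
  substr(bad_r2, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                    substr(bad_r2, 60, 60))[1]
  fm <- tmp_fastq_pair(c(rep(pr$r1, 10), pr$r1, substr(pr$r1, 1, 100)),
                       c(rep(pr$r2, 10), bad_r2, substr(pr$r2, 1, 100)),
                       q1 = c(rep(strrep("F", 151), 11), strrep("F", 100)))
  ctm <- count_variants(data.frame(tile_id = 1L, condition = "control",
                                   replicate = 1L, r1 = fm[1], r2 = fm[2]),
                        tiles)
  qcm <- attr(ctm, "qc")[[1]]
  expect_equal(qcm$n_pairs, 12L)
  expect_equal(qcm$n_filtered, 1L)
  expect_equal(qcm$n_rejected, 1L)
  expect_equal(qcm$n_accepted, 10L)
  expect_equal(qcm$rejection_reasons$unresolvable_overlap, 1L)
})

test_that("error-free simulated reads round-trip to the simulated counts", {
  tiles <- mini_tiles()
  lib <- design_library(tiles)
  p <- sim_params(depth = 8, error_rate = 0, seed = 31, n_replicates = 2)
  tr <- draw_effects(lib, p)
  ct <- simulate_counts(tr, p, assays = "abundance")
  dir <- withr::local_tempdir()
  man <- emit_fastq(ct, tiles, p, dir)
  got <- count_variants(man, tiles)
  a <- ct[ct$count > 0, ]
  m <- merge(a, got, by = c("tile_id", "position", "alt_aa", "condition",
                            "replicate"))
  expect_equal(nrow(m), nrow(a))
  expect_equal(m$count.x, m$count.y)
  expect_equal(sum(got$count), sum(ct$count))
})
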