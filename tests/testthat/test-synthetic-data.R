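test_that("library design enumerates the programmed variants", {
  tiles <- default_tiles()
  lib <- design_library(tiles)
  expect_equal(sum(lib$alt_aa != "Syn"), 5170L)
  expect_equal(sum(lib$alt_aa == "Syn"), 270L)
  expect_equal(length(unique(lib$position)), 270L)
  expect_equal(sum(lib$alt_aa == "Ter"), 40L)
  expect_true(all(lib$position[lib$alt_aa == "Ter"] >= 717))

  # smallest case: one tile of one residue without nonsense
  one <- make_tiles(data.frame(tile_id = 1, start_pos = 487, end_pos = 487,
                               includes_nonsense = FALSE),
                    substr(synthetic_reference_protein(), 1, 1), 487L)
  lib1 <- design_library(one)
  expect_equal(sum(lib1$alt_aa != "Syn"), 19L)
  expect_equal(sum(lib1$alt_aa == "Syn"), 1L)

  # brute-force enumeration oracle for a two-residue nonsense tile
  two <- make_tiles(data.frame(tile_id = 1, start_pos = 487, end_pos = 488,
                               includes_nonsense = TRUE),
                    substr(synthetic_reference_protein(), 1, 2), 487L)
  lib2 <- design_library(two)
  wt <- strsplit(substr(synthetic_reference_protein(), 1, 2), "")[[1]]
  aa20 <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
  expected <- do.call(rbind, lapply(1:2, function(j)
    data.frame(position = 486L + j,
               alt_aa = c(setdiff(aa20, wt[j]), "Ter"))))
  got <- lib2[lib2$alt_aa != "Syn", c("position", "alt_aa")]
  expect_equal(nrow(got), 40L)
  expect_setequal(paste(got$position, got$alt_aa),
                  paste(expected$position, expected$alt_aa))
})

test_that("tile validation rejects gapped or overlapping layouts", {
  ref <- substr(synthetic_reference_protein(), 1, 30)
  expect_error(
    make_tiles(data.frame(tile_id = 1:2, start_pos = c(487, 499),
                          end_pos = c(496, 516), includes_nonsense = FALSE),
               ref, 487L),
    "contiguous")
  expect_error(
    make_tiles(data.frame(tile_id = 1:2, start_pos = c(487, 495),
                          end_pos = c(496, 516), includes_nonsense = FALSE),
               ref, 487L),
    "contiguous")
  tiles <- mini_tiles()
  expect_equal(translate_dna(tiles$wt_dna[1]),
               strsplit(substr(synthetic_reference_protein(), 1, 10), "")[[1]])
})

test_that("effect draws are seeded, neutral for Syn, and hit the mixture weight", {
  tiles <- default_tiles()
  lib <- design_library(tiles)
  p <- sim_params(seed = 5)
  t1 <- draw_effects(lib, p)
  t2 <- draw_effects(lib, p)
  expect_identical(t1, t2)
  expect_true(all(t1$true_abundance[t1$alt_aa == "Syn"] == 0))
  expect_true(all(t1$true_interaction[t1$alt_aa == "Syn"] == 0))

  # binomial check on the low-abundance fraction over ~10,000 missense draws
  big <- lib[rep(seq_len(nrow(lib)), 2), ]
  mis <- droplevels(big[!big$alt_aa %in% c("Syn", "Ter"), ])
  tr <- draw_effects(mis, sim_params(frac_low = 0.4, seed = 9))
  frac <- mean(tr$mixture_class == "low-abundance")
  expect_gt(nrow(tr), 10000)
  expect_lt(abs(frac - 0.4), 0.02)

  # early nonsense is forced low-abundant; late nonsense is tolerated
  ter <- draw_effects(lib, p)
  early <- ter$alt_aa == "Ter" & ter$position < 745
  late <- ter$alt_aa == "Ter" & ter$position >= 745
  expect_true(all(ter$mixture_class[early] == "low-abundance"))
  expect_true(all(ter$true_abundance[late] > 0))
})

test_that("truth distribution is bimodal at the planted per-tile modes", {
  tiles <- default_tiles()
  lib <- design_library(tiles)
  tr <- draw_effects(lib, sim_params(seed = 21))
  modes <- attr(tr, "low_modes")
  expect_gt(nrow(tr), 5000)
  for (tid in c(1, 4, 7)) {
    x <- tr$true_abundance[tr$tile_id == tid & tr$alt_aa != "Syn"]
    m <- detect_low_mode(x, guard = -0.25)
    expect_lt(abs(m - modes[[as.character(tid)]]), 0.1)
  }
})

test_that("count simulation conserves depth and follows the growth model", {
  tiles <- mini_tiles()
  lib <- design_library(tiles)
  p <- sim_params(depth = 100, seed = 2)
  tr <- draw_effects(lib, p)
  ct <- simulate_counts(tr, p, assays = "abundance")
  for (r in 1:3) for (cond in c("control", "selection")) {
    sub <- ct[ct$tile_id == 1 & ct$replicate == r & ct$condition == cond, ]
    expect_equal(sum(sub$count),
                 round(100 * sum(lib$tile_id == 1)))
  }

  # analytic expectation: scores 0 vs -1 at k = 2 change the count ratio by
  # e^{-2}; checked within 3 binomial standard errors at large depth
  two <- lib[lib$tile_id == 1 & lib$alt_aa == "Syn", ][1:2, ]
  truth <- two
  truth$true_abundance <- c(0, -1)
  truth$true_interaction <- 0
  truth$mixture_class <- "WT-like"
  pk <- sim_params(depth = 2e5, k = 2, replicate_noise_sd = 0, seed = 8,
                   n_replicates = 2)
  ctk <- simulate_counts(truth, pk, assays = "abundance")
  g <- function(cond, r, pos) ctk$count[ctk$condition == cond &
                                          ctk$replicate == r &
                                          ctk$position == pos]
  pos <- two$position
  ratio <- (g("selection", 1, pos[2]) / g("selection", 1, pos[1])) /
    (g("control", 1, pos[2]) / g("control", 1, pos[1]))
  se_log <- sqrt(sum(1 / c(g("selection", 1, pos[1]),
                           g("selection", 1, pos[2]),
                           g("control", 1, pos[1]),
                           g("control", 1, pos[2]))))
  expect_lt(abs(log(ratio) - (-2)), 3 * se_log)

  # k = 0: no systematic frequency change between conditions
  p0 <- sim_params(depth = 500, k = 0, replicate_noise_sd = 0, seed = 4)
  ct0 <- simulate_counts(draw_effects(lib, p0), p0, assays = "abundance")
  w <- ct0[ct0$tile_id == 1 & ct0$replicate == 1, ]
  f_ctrl <- w$count[w$condition == "control"] /
    sum(w$count[w$condition == "control"])
  f_sel <- w$count[w$condition == "selection"] /
    sum(w$count[w$condition == "selection"])
  expect_lt(abs(mean(f_sel - f_ctrl)), 1e-4)
  expect_gt(cor(f_ctrl, f_sel), 0.9)
})

test_that("emitted reads carry the variant codons and the error rate", {
  tiles <- mini_tiles()
  lib <- design_library(tiles)
  p <- sim_params(depth = 3, error_rate = 0, seed = 6, n_replicates = 2)
  tr <- draw_effects(lib, p)
  ct <- simulate_counts(tr, p, assays = "abundance")
  dir <- withr::local_tempdir()
  man <- emit_fastq(ct, tiles, p, dir)
  expect_equal(sum(man$n_pairs), sum(ct$count))

  # single wild-type-like molecule: both mates translate back to the tile
  pair <- amplicon_pair(tiles[1, , drop = FALSE])
  merged <- merge_overlap(pair$r1, strrep("F", 151), pair$r2,
                          strrep("F", 151),
                          offset = nchar(pair$amplicon) - 151)
  expect_identical(merged$merged, pair$amplicon)
  aa <- translate_dna(substr(merged$merged, 26, 25 + nchar(tiles$wt_dna[1])))
  expect_identical(aa, translate_dna(tiles$wt_dna[1]))

  # empirical per-base error rate over >= 10,000 read pairs
  pe <- sim_params(depth = 15, error_rate = 0.001, seed = 13,
                   n_replicates = 2)
  cte <- simulate_counts(tr, pe, assays = "abundance")
  dire <- withr::local_tempdir()
  mane <- emit_fastq(cte, tiles, pe, dire)
  f <- mane[mane$condition == "control" & mane$replicate == 1, ]
  pairs <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
    pr <- read_fastq_pairs(f$r1[i], f$r2[i])
    pr$tile_id <- f$tile_id[i]
    pr
  }))
  expect_gt(nrow(pairs), 5000)
  mism <- 0; bases <- 0
  for (tid in unique(pairs$tile_id)) {
    tile <- tiles[tiles$tile_id == tid, , drop = FALSE]
    ctx <- tile_amplicon(tile)
    sub <- pairs[pairs$tile_id == tid, ]
    # R2 reverse complement vs R1 in the overlap: each mate contributes
    # errors independently, so the pairwise mismatch rate is ~2 * error_rate
    r2rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(sub$r2_seq)))
    s1 <- substr(sub$r1_seq, ctx$offset + 1, 151)
    s2 <- substr(r2rc, 1, 151 - ctx$offset)
    mism <- mism + sum(vapply(seq_len(nrow(sub)), function(i)
      sum(utf8ToInt(s1[i]) != utf8ToInt(s2[i])), numeric(1)))
    bases <- bases + nrow(sub) * (151 - ctx$offset)
  }
  rate_per_mate <- mism / bases / 2
  expect_lt(abs(rate_per_mate - 0.001), 3 * sqrt(0.002 / bases) + 2e-4)
})

test_that("the whole generator is byte-deterministic in its seed", {
  tiles <- mini_tiles()
  lib <- design_library(tiles)
  p <- sim_params(depth = 5, seed = 17, n_replicates = 2)
  run <- function() {
    tr <- draw_effects(lib, p)
    ct <- simulate_counts(tr, p)
    d <- tempfile()
    man <- emit_fastq(ct[ct$assay == "abundance", ], tiles, p, d)
    list(tr = tr, ct = ct,
         fq = lapply(c(man$r1, man$r2), readLines))
  }
  a <- run(); b <- run()
  expect_identical(a$tr, b$tr)
  expect_identical(a$ct, b$ct)
  expect_identical(a$fq, b$fq)
})
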