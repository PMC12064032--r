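#' Scoring configuration
#'
#' @param epsilon Pseudocount added to every count (default 0.5, the
#'   convention of log-ratio MAVE scorers).
#' @param min_count Minimum control count (summed over replicates) for a
#'   variant to be scored.
#' @param reference_mode `"pooled_synonymous"` pools all synonymous markers
#'   plus exact wild-type reads per tile as the neutral reference;
#'   `"wt_only"` uses only the exact wild-type tally.
#' @return List of class `tilemave_scoring_config`.
#' @export
scoring_config <- function(epsilon = 0.5, min_count = 0L,
                           reference_mode = c("pooled_synonymous",
                                              "wt_only")) {
  stopifnot(epsilon > 0, min_count >= 0)
  reference_mode <- match.arg(reference_mode)
  structure(list(epsilon = epsilon, min_count = min_count,
                 reference_mode = reference_mode),
            class = "tilemave_scoring_config")
}

#' Pooled neutral-reference count for one tile/condition/replicate
#'
#' Sums the counts of all synonymous wild-type markers (and the exact
#' wild-type tally, if present) in the tile, which serves as the neutral
#' reference the variant log-ratios are normalised to.
#'
#' @param counts `tilemave_counts` data frame (single assay).
#' @param tile_id,condition,replicate Cell to pool.
#' @param reference_mode See [scoring_config()].
#' @return Pooled reference count (numeric scalar); errors if the tile has no
#'   synonymous coverage in that cell.
#' @export
pool_reference <- function(counts, tile_id, condition, replicate,
                           reference_mode = "pooled_synonymous") {
  sel <- counts$tile_id == tile_id & counts$condition == condition &
    counts$replicate == replicate
  ref_keys <- if (reference_mode == "wt_only") "WT" else c("Syn", "WT")
  sub <- counts[sel & counts$alt_aa %in% ref_keys, , drop = FALSE]
  total <- sum(sub$count)
  if (nrow(sub) == 0L || total <= 0)
    stop("no synonymous/wild-type reference coverage for tile ", tile_id,
         ", ", condition, ", replicate ", replicate)
  total
}

#' Per-replicate enrichment score and standard error
#'
#' `s_r = ln((c_sel + eps)/(c_ctrl + eps)) - ln((ref_sel + eps)/(ref_ctrl + eps))`
#' with Poisson-approximation standard error
#' `se_r = sqrt(1/(c_sel+eps) + 1/(c_ctrl+eps) + 1/(ref_sel+eps) + 1/(ref_ctrl+eps))`,
#' treating the control condition as the first and the selection condition as
#' the second time point. Vectorised over variants.
#'
#' @param c_ctrl,c_sel Variant counts in control and selection.
#' @param ref_ctrl,ref_sel Pooled reference counts.
#' @param epsilon Pseudocount.
#' @return List with numeric vectors `score` and `se`.
#' @export
replicate_score <- function(c_ctrl, c_sel, ref_ctrl, ref_sel,
                            epsilon = 0.5) {
  if (any(c(c_ctrl, c_sel, ref_ctrl, ref_sel) < 0))
    stop("counts must be non-negative")
  s <- log((c_sel + epsilon) / (c_ctrl + epsilon)) -
    log((ref_sel + epsilon) / (ref_ctrl + epsilon))
  se <- sqrt(1 / (c_sel + epsilon) + 1 / (c_ctrl + epsilon) +
               1 / (ref_sel + epsilon) + 1 / (ref_ctrl + epsilon))
  list(score = s, se = se)
}

#' Random-effects combination of replicate scores
#'
#' DerSimonian-Laird method-of-moments pooling: with fixed-effect weights
#' `w = 1/se^2`, heterogeneity `Q = sum(w (s - s_fixed)^2)` and
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`; the combined
#' score reweights by `1/(se^2 + tau2)`.
#'
#' @param s_r Per-replicate scores (finite).
#' @param se_r Per-replicate standard errors (> 0).
#' @return List with `score`, `se`, `tau2`, `n_used`.
#' @export
combine_replicates <- function(s_r, se_r) {
  keep <- is.finite(s_r) & is.finite(se_r) & se_r > 0
  s_r <- s_r[keep]; se_r <- se_r[keep]
  k <- length(s_r)
  if (k == 0L) return(list(score = NA_real_, se = NA_real_,
                           tau2 = NA_real_, n_used = 0L))
  if (k == 1L) {
    warning("single replicate: returning it unpooled")
    return(list(score = s_r, se = se_r, tau2 = 0, n_used = 1L))
  }
  w <- 1 / se_r^2
  s_fixed <- sum(w * s_r) / sum(w)
  Q <- sum(w * (s_r - s_fixed)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (se_r^2 + tau2)
  list(score = sum(w_star * s_r) / sum(w_star),
       se = sqrt(1 / sum(w_star)), tau2 = tau2, n_used = k)
}

# Row-wise DerSimonian-Laird over matrices (variants x replicates); NA cells
# are dropped per row. Same estimator as combine_replicates, vectorised.
combine_replicates_matrix <- function(s, se) {
  ok <- is.finite(s) & is.finite(se) & se > 0
  s[!ok] <- NA; se[!ok] <- NA
  k <- rowSums(ok)
  w <- 1 / se^2
  sw <- rowSums(w, na.rm = TRUE)
  s_fixed <- rowSums(w * s, na.rm = TRUE) / sw
  Q <- rowSums(w * (s - s_fixed)^2, na.rm = TRUE)
  denom <- sw - rowSums(w^2, na.rm = TRUE) / sw
  tau2 <- pmax(0, (Q - (k - 1)) / denom)
  tau2[k < 2L] <- 0
  w_star <- 1 / (se^2 + tau2)
  sws <- rowSums(w_star, na.rm = TRUE)
  score <- rowSums(w_star * s, na.rm = TRUE) / sws
  out_se <- sqrt(1 / sws)
  score[k == 0L] <- NA; out_se[k == 0L] <- NA; tau2[k == 0L] <- NA
  list(score = score, se = out_se, tau2 = tau2, n_used = k)
}

#' Score a count table
#'
#' Computes per-replicate enrichment scores normalised to the pooled
#' synonymous reference of each tile and combines replicates by
#' DerSimonian-Laird random effects. Synonymous markers are scored like any
#' other variant (their scores distribute around 0); exact wild-type tallies
#' enter only the reference pool. If `library` is given, programmed variants
#' absent from every replicate are emitted with `NA` scores so that missing
#' variants surface downstream.
#'
#' @param counts `tilemave_counts` data frame; an `assay` column is optional
#'   (a single unnamed assay is assumed otherwise).
#' @param config [scoring_config()] list.
#' @param library Optional design from [design_library()].
#' @return Data frame of class `tilemave_scores`: variant key columns,
#'   `assay`, `score`, `se`, `tau2`, `n_replicates_used` and per-replicate
#'   `score_rep<r>` / `se_rep<r>` columns.
#' @export
score_dataset <- function(counts, config = scoring_config(),
                          library = NULL) {
  if (is.null(counts$assay)) counts$assay <- "assay"
  pieces <- list()
  for (assay in unique(counts$assay)) {
    ca <- counts[counts$assay == assay, , drop = FALSE]
    for (tid in sort(unique(ca$tile_id))) {
      sub <- ca[ca$tile_id == tid, , drop = FALSE]
      reps <- sort(unique(sub$replicate))
      keys <- unique(sub[!sub$alt_aa %in% "WT",
                         c("position", "wt_aa", "alt_aa"), drop = FALSE])
      keys <- keys[order(keys$position, keys$alt_aa), , drop = FALSE]
      kid <- paste(keys$position, keys$alt_aa)
      s_mat <- matrix(NA_real_, nrow(keys), length(reps))
      se_mat <- matrix(NA_real_, nrow(keys), length(reps))
      ctrl_total <- numeric(nrow(keys))
      for (j in seq_along(reps)) {
        r <- reps[j]
        refs <- vapply(c("control", "selection"), function(cond)
          pool_reference(sub, tid, cond, r, config$reference_mode),
          numeric(1))
        cc <- sub[sub$condition == "control" & sub$replicate == r, ]
        cs <- sub[sub$condition == "selection" & sub$replicate == r, ]
        c_ctrl <- cc$count[match(kid, paste(cc$position, cc$alt_aa))]
        c_sel <- cs$count[match(kid, paste(cs$position, cs$alt_aa))]
        c_ctrl[is.na(c_ctrl)] <- 0; c_sel[is.na(c_sel)] <- 0
        ctrl_total <- ctrl_total + c_ctrl
        rs <- replicate_score(c_ctrl, c_sel, refs[["control"]],
                              refs[["selection"]], config$epsilon)
        s_mat[, j] <- rs$score; se_mat[, j] <- rs$se
      }
      comb <- combine_replicates_matrix(s_mat, se_mat)
      rec <- data.frame(tile_id = tid, position = keys$position,
                        wt_aa = keys$wt_aa, alt_aa = keys$alt_aa,
                        assay = assay, score = comb$score, se = comb$se,
                        tau2 = comb$tau2, n_replicates_used = comb$n_used)
      for (j in seq_along(reps)) {
        rec[[paste0("score_rep", reps[j])]] <- s_mat[, j]
        rec[[paste0("se_rep", reps[j])]] <- se_mat[, j]
      }
      low <- ctrl_total < config$min_count
      rec$score[low] <- NA; rec$se[low] <- NA
      pieces[[length(pieces) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, pieces)
  if (!is.null(library)) {
    lib <- library
    lib$assay <- NULL
    for (assay in unique(out$assay)) {
      have <- out[out$assay == assay, ]
      miss <- lib[!paste(lib$position, lib$alt_aa) %in%
                    paste(have$position, have$alt_aa), , drop = FALSE]
      if (nrow(miss)) {
        add <- data.frame(tile_id = miss$tile_id, position = miss$position,
                          wt_aa = miss$wt_aa, alt_aa = miss$alt_aa,
                          assay = assay, score = NA_real_, se = NA_real_,
                          tau2 = NA_real_, n_replicates_used = 0L)
        for (col in setdiff(names(out), names(add))) add[[col]] <- NA_real_
        out <- rbind(out, add[, names(out)])
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("tilemave_scores", "data.frame")
  out
}

#' Write a score table as TSV
#'
#' @param scores `tilemave_scores` data frame.
#' @param path Output TSV path.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores_tsv()]
#'
#' @param path TSV path.
#' @return `tilemave_scores` data frame.
#' @export
read_scores_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("tilemave_scores", "data.frame")
  out
}
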