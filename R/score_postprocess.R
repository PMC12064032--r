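# Fixed heatmap row order: hydrophobic/aliphatic, aromatic, polar, charged,
# special, then the nonsense row last.
HEATMAP_ROW_ORDER <- c("G", "A", "V", "L", "I", "M", "F", "W", "Y", "P",
                       "S", "T", "C", "N", "Q", "D", "E", "K", "R", "H",
                       "Ter")

#' Detect the low-abundance mode of one tile's score distribution
#'
#' Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth) over
#' the finite scores; the mode is the highest-density local maximum at scores
#' below `guard`. Deterministic for fixed input.
#'
#' @param scores Numeric scores of one tile (raw, unrescaled).
#' @param guard Scores above this threshold are never accepted as the low
#'   mode (default -0.25).
#' @param min_n Minimum number of finite scores required.
#' @return The mode location `m_t` (negative scalar); errors if the
#'   distribution has no density maximum below `guard` (unimodal tile).
#' @export
detect_low_mode <- function(scores, guard = -0.25, min_n = 50L) {
  x <- scores[is.finite(scores)]
  if (length(x) < min_n)
    stop("need at least ", min_n, " finite scores to detect a mode")
  d <- stats::density(x, bw = "nrd0")
  i <- seq_along(d$y)
  is_max <- d$y >= c(-Inf, d$y[-length(d$y)]) &
    d$y >= c(d$y[-1], -Inf)
  cand <- which(is_max & d$x < guard)
  if (!length(cand))
    stop("no density maximum below ", guard,
         ": tile score distribution is not bimodal")
  d$x[cand[which.max(d$y[cand])]]
}

#' Rescale one tile's scores by its low-abundance mode
#'
#' Divides scores and standard errors by `|m_t|`, mapping the low-abundance
#' peak to -1 and wild-type to 0. Values are not clamped: scores above 0
#' (increased abundance) or below -1 remain meaningful.
#'
#' @param scores,ses Numeric vectors.
#' @param m_t Low-mode location (< 0).
#' @return List with `scores`, `ses`, `m_t`.
#' @export
rescale_tile <- function(scores, ses, m_t) {
  if (!is.finite(m_t) || m_t >= 0) stop("low mode m_t must be negative")
  list(scores = scores / abs(m_t), ses = ses / abs(m_t), m_t = m_t)
}

#' Rescale bimodal scores per tile across a score table
#'
#' Applies [detect_low_mode()] and [rescale_tile()] tile by tile to the rows
#' of one assay, leaving other assays untouched (interaction scores are
#' unimodal and are not rescaled). Per-replicate score/SE columns are rescaled
#' consistently. Tiles without a detectable low mode fall back to the pooled
#' mode over all tiles if `fallback_global` is set, otherwise error.
#'
#' @param scores `tilemave_scores` data frame.
#' @param assay Assay whose scores are rescaled (default `"abundance"`).
#' @param guard,min_n Passed to [detect_low_mode()].
#' @param fallback_global Use the global low mode for unimodal tiles.
#' @return `scores` with rescaled values for `assay`; attribute
#'   `rescale_report` holds the per-tile `m_t` values.
#' @export
rescale_scores <- function(scores, assay = "abundance", guard = -0.25,
                           min_n = 50L, fallback_global = TRUE) {
  rows <- scores$assay == assay
  report <- list()
  score_cols <- c("score", grep("^score_rep", names(scores), value = TRUE))
  se_cols <- c("se", grep("^se_rep", names(scores), value = TRUE))
  global_mode <- if (fallback_global)
    tryCatch(detect_low_mode(scores$score[rows], guard, min_n),
             error = function(e) NA_real_) else NA_real_
  for (tid in sort(unique(scores$tile_id[rows]))) {
    sel <- rows & scores$tile_id == tid
    m_t <- tryCatch(detect_low_mode(scores$score[sel], guard, min_n),
                    error = function(e) {
                      if (fallback_global && is.finite(global_mode)) {
                        warning("tile ", tid, " not bimodal; using the ",
                                "global low mode")
                        global_mode
                      } else stop(e)
                    })
    for (col in score_cols) scores[[col]][sel] <- scores[[col]][sel] / abs(m_t)
    for (col in se_cols) scores[[col]][sel] <- scores[[col]][sel] / abs(m_t)
    report[[as.character(tid)]] <- m_t
  }
  attr(scores, "rescale_report") <- unlist(report)
  scores
}

#' Write the per-tile rescale report as JSON
#'
#' @param scores Output of [rescale_scores()].
#' @param path Output JSON path.
#' @export
write_rescale_json <- function(scores, path) {
  rep <- attr(scores, "rescale_report")
  jsonlite::write_json(as.list(rep), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-position median scores
#'
#' Median over available missense substitutions at each position (synonymous
#' markers always excluded; nonsense excluded by default).
#'
#' @param scores `tilemave_scores` data frame (one assay, or use `assay`).
#' @param assay Assay to summarise; `NULL` uses all rows.
#' @param include_ter Include nonsense (`Ter`) rows in the median.
#' @return Data frame with `position`, `median_score`, `n_variants`,
#'   `missing_fraction`; positions with no finite scores get `NA` medians.
#' @export
per_position_median <- function(scores, assay = NULL, include_ter = FALSE) {
  s <- if (is.null(assay)) scores else scores[scores$assay == assay, ]
  s <- s[s$alt_aa != "Syn", , drop = FALSE]
  if (!include_ter) s <- s[s$alt_aa != "Ter", , drop = FALSE]
  pos <- sort(unique(s$position))
  out <- do.call(rbind, lapply(pos, function(p) {
    v <- s$score[s$position == p]
    data.frame(position = p,
               median_score = if (any(is.finite(v)))
                 stats::median(v[is.finite(v)]) else NA_real_,
               n_variants = sum(is.finite(v)),
               missing_fraction = mean(!is.finite(v)))
  }))
  rownames(out) <- NULL
  out
}

#' Substitution-by-position heatmap matrix
#'
#' Builds the 21 x L matrix (20 amino-acid rows in a fixed physicochemical
#' order plus a terminal `Ter` row) of scores over a position range, with a
#' companion mask marking wild-type and missing cells.
#'
#' @param scores `tilemave_scores` data frame (single assay).
#' @param region Integer positions to include; default is the scored range.
#' @return List with `matrix` (scores; `NA` where not scored) and `mask`
#'   (character matrix: `"score"`, `"wt"`, or `"missing"`).
#' @export
heatmap_matrix <- function(scores,
                           region = seq(min(scores$position),
                                        max(scores$position))) {
  s <- scores[scores$alt_aa != "Syn" & scores$position %in% region, ]
  mat <- matrix(NA_real_, length(HEATMAP_ROW_ORDER), length(region),
                dimnames = list(HEATMAP_ROW_ORDER, region))
  mask <- matrix("missing", nrow(mat), ncol(mat), dimnames = dimnames(mat))
  ri <- match(s$alt_aa, HEATMAP_ROW_ORDER)
  ci <- match(s$position, region)
  ok <- !is.na(ri) & !is.na(ci)
  idx <- cbind(ri[ok], ci[ok])
  mat[idx] <- s$score[ok]
  mask[idx] <- ifelse(is.finite(s$score[ok]), "score", "missing")
  wt <- unique(s[, c("position", "wt_aa")])
  wt <- wt[!is.na(wt$wt_aa), , drop = FALSE]
  widx <- cbind(match(wt$wt_aa, HEATMAP_ROW_ORDER),
                match(wt$position, region))
  widx <- widx[stats::complete.cases(widx), , drop = FALSE]
  mask[widx] <- "wt"
  mat[widx] <- NA_real_
  list(matrix = mat, mask = mask)
}

#' Write a heatmap matrix and its mask as CSV files
#'
#' @param hm Output of [heatmap_matrix()].
#' @param matrix_path,mask_path Output CSV paths.
#' @export
write_heatmap_csv <- function(hm, matrix_path, mask_path) {
  utils::write.csv(hm$matrix, matrix_path)
  utils::write.csv(hm$mask, mask_path)
  invisible(matrix_path)
}
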