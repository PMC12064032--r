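CLINVAR_CLASSES <- c("benign", "likely benign", "likely pathogenic",
                     "pathogenic", "VUS", "none")

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Glu = "E",
  Gln = "Q", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "Ter")

#' Parse protein-level HGVS variant notation
#'
#' Accepts `"p.Leu550Pro"`, `"Leu550Pro"`, `"L550P"`, and `"...Ter"` stop
#' notation.
#'
#' @param x Character vector of variant labels.
#' @return Data frame with `position`, `wt_aa`, `alt_aa`; unparseable labels
#'   yield `NA` rows.
#' @export
parse_hgvs_p <- function(x) {
  x0 <- sub("^p\\.", "", x)
  m3 <- regmatches(x0, regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$", x0))
  m1 <- regmatches(x0, regexec("^([A-Z])(\\d+)(Ter|\\*|[A-Z])$", x0))
  out <- data.frame(position = rep(NA_integer_, length(x)),
                    wt_aa = NA_character_, alt_aa = NA_character_)
  for (i in seq_along(x)) {
    if (length(m3[[i]]) == 4L) {
      wt <- AA_THREE_TO_ONE[m3[[i]][2]]
      alt <- AA_THREE_TO_ONE[m3[[i]][4]]
      if (!is.na(wt) && !is.na(alt)) {
        out$position[i] <- as.integer(m3[[i]][3])
        out$wt_aa[i] <- unname(wt)
        out$alt_aa[i] <- unname(alt)
      }
    } else if (length(m1[[i]]) == 4L) {
      out$position[i] <- as.integer(m1[[i]][3])
      out$wt_aa[i] <- m1[[i]][2]
      out$alt_aa[i] <- sub("^\\*$", "Ter", m1[[i]][4])
    }
  }
  out
}

#' Read a stability/conservation prediction table
#'
#' Stability predictions supplied in Rosetta Energy Units are converted to
#' kcal/mol on read by dividing by 2.9 (exactly once).
#'
#' @param path TSV/CSV with columns `variant` (HGVS-p or one-letter) plus
#'   `ddG` and/or `ddE`.
#' @param ddg_units `"REU"` (divide by 2.9 on read) or `"kcal/mol"`.
#' @return Data frame with `position`, `wt_aa`, `alt_aa`, `ddG` (kcal/mol),
#'   `ddE`.
#' @export
read_predictions <- function(path, ddg_units = c("REU", "kcal/mol")) {
  ddg_units <- match.arg(ddg_units)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  out <- cbind(parse_hgvs_p(tab$variant), tab[setdiff(names(tab), "variant")])
  if (!is.null(out$ddG) && ddg_units == "REU") out$ddG <- out$ddG / 2.9
  out
}

#' Classify a score against the detrimental cutoff
#'
#' Scores strictly below the cutoff are detrimental; ties at the cutoff are
#' wild-type-like.
#'
#' @param score Numeric scores.
#' @param cutoff Detrimental cutoff (default -0.5).
#' @return Character vector in `{"detrimental", "wild-type-like",
#'   "unclassified"}` (the latter for missing scores).
#' @export
classify_detrimental <- function(score, cutoff = -0.5) {
  ifelse(!is.finite(score), "unclassified",
         ifelse(score < cutoff, "detrimental", "wild-type-like"))
}

#' ROC curve and AUC by the Mann-Whitney statistic
#'
#' AUC is the Mann-Whitney U statistic divided by `n_pos * n_neg`, counting
#' ties as 1/2. With `orientation = "lower"` the predictor is negated first,
#' so that "more negative implies positive class" yields AUC >= 0.5 for an
#' informative predictor.
#'
#' @param values Numeric predictor.
#' @param labels Logical or 0/1 vector; `TRUE`/1 is the positive class.
#' @param orientation `"higher"` (larger value = positive class) or
#'   `"lower"`.
#' @return List with `auc`, `n_pos`, `n_neg`, and `curve` (data frame of
#'   `fpr`, `tpr` points).
#' @export
roc_auc <- function(values, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    return(list(auc = NA_real_, n_pos = n_pos, n_neg = n_neg,
                curve = NULL))
  v <- if (orientation == "lower") -values else values
  r <- rank(v, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(v, decreasing = TRUE)
  tpr <- cumsum(labels[ord]) / n_pos
  fpr <- cumsum(!labels[ord]) / n_neg
  # keep one point per distinct threshold (the last index at each value)
  thr_last <- rev(!duplicated(rev(v[ord])))
  curve <- data.frame(fpr = c(0, fpr[thr_last]), tpr = c(0, tpr[thr_last]))
  list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve)
}

#' Benchmark predictors against clinical classifications
#'
#' Joins scores with annotations on (position, wt_aa, alt_aa); positives are
#' pathogenic and likely pathogenic variants, negatives benign and likely
#' benign; VUS and unannotated variants are excluded. AUCs are computed for
#' the abundance and interaction scores (lower = more pathogenic), and for
#' `ddG` (higher = more pathogenic) and `ddE` (lower = more pathogenic) when
#' present.
#'
#' @param scores `tilemave_scores` data frame with assays `"abundance"`
#'   and/or `"interaction"`.
#' @param annotations Data frame with `position`, `wt_aa`, `alt_aa`,
#'   `clinvar_class` (and optionally `gnomad_af`).
#' @param predictions Optional data frame from [read_predictions()].
#' @return List with per-predictor entries (`auc`, `n_pos`, `n_neg`,
#'   `curve`) and `n_test` (clinically classified variants in the test set).
#' @export
pathogenicity_benchmark <- function(scores, annotations,
                                    predictions = NULL) {
  ann <- annotations
  bad <- setdiff(unique(ann$clinvar_class), CLINVAR_CLASSES)
  if (length(bad)) stop("unknown clinical classes: ",
                        paste(bad, collapse = ", "))
  ann <- ann[ann$clinvar_class %in%
               c("benign", "likely benign", "likely pathogenic",
                 "pathogenic"), , drop = FALSE]
  ann$label <- ann$clinvar_class %in% c("pathogenic", "likely pathogenic")
  key <- function(d) paste(d$position, d$wt_aa, d$alt_aa)
  out <- list()
  n_test <- 0L
  for (assay in intersect(unique(scores$assay),
                          c("abundance", "interaction"))) {
    s <- scores[scores$assay == assay, ]
    m <- merge(s[, c("position", "wt_aa", "alt_aa", "score")], ann,
               by = c("position", "wt_aa", "alt_aa"))
    out[[assay]] <- roc_auc(m$score, m$label, orientation = "lower")
    n_test <- max(n_test, sum(is.finite(m$score)))
  }
  if (!is.null(predictions)) {
    p <- merge(predictions, ann, by = c("position", "wt_aa", "alt_aa"))
    if (!is.null(p$ddG))
      out$ddG <- roc_auc(p$ddG, p$label, orientation = "higher")
    if (!is.null(p$ddE))
      out$ddE <- roc_auc(p$ddE, p$label, orientation = "lower")
  }
  out$n_test <- n_test
  out
}

#' Mechanistic classification of a variant from its two scores
#'
#' Pointwise rule on the (abundance, interaction) pair: below both loss
#' thresholds is dual loss; below only one is the corresponding single loss;
#' interaction above the gain threshold with intact abundance is gain of
#' interaction; otherwise wild-type-like. Missing scores are unclassified.
#'
#' @param abundance,interaction Numeric score vectors.
#' @param thresholds Named list with `a` (abundance loss), `i` (interaction
#'   loss), `g` (interaction gain).
#' @return Character vector of categories.
#' @export
classify_mechanism <- function(abundance, interaction,
                               thresholds = list(a = -0.5, i = -0.5,
                                                 g = 0.3)) {
  ifelse(!is.finite(abundance) | !is.finite(interaction), "unclassified",
  ifelse(abundance < thresholds$a & interaction < thresholds$i, "dual-loss",
  ifelse(abundance < thresholds$a, "loss-of-abundance",
  ifelse(interaction < thresholds$i, "loss-of-interaction-only",
  ifelse(interaction > thresholds$g, "gain-of-interaction", "WT-like")))))
}

#' Pairwise replicate correlations
#'
#' Pearson correlations between per-replicate scores on shared non-missing
#' variants, reported per assay together with the minimum.
#'
#' @param scores `tilemave_scores` data frame with `score_rep<r>` columns.
#' @return Named list per assay: `cor_matrix` and `min_r`.
#' @export
replicate_qc <- function(scores) {
  rep_cols <- grep("^score_rep", names(scores), value = TRUE)
  if (length(rep_cols) < 2L) stop("need at least two replicates")
  out <- list()
  for (assay in unique(scores$assay)) {
    s <- scores[scores$assay == assay, rep_cols, drop = FALSE]
    cm <- matrix(NA_real_, length(rep_cols), length(rep_cols),
                 dimnames = list(rep_cols, rep_cols))
    for (i in seq_along(rep_cols)) for (j in seq_along(rep_cols)) {
      ok <- is.finite(s[[i]]) & is.finite(s[[j]])
      if (sum(ok) >= 2L) cm[i, j] <- stats::cor(s[[i]][ok], s[[j]][ok])
    }
    off <- cm[upper.tri(cm)]
    out[[assay]] <- list(cor_matrix = cm,
                         min_r = if (all(is.na(off))) NA_real_
                                 else min(off, na.rm = TRUE))
  }
  out
}
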