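#' Assemble a pipeline run configuration
#'
#' @param outdir Output directory; every stage writes its files here.
#' @param tiles `tilemave_tiles` data frame.
#' @param params [sim_params()] for the simulation stages.
#' @param policy [merge_policy()] for read processing.
#' @param scoring [scoring_config()].
#' @param thresholds Mechanism thresholds (`a`, `i`, `g`), see
#'   [classify_mechanism()].
#' @param seed Master seed; per-stage seeds are derived from it with a fixed
#'   counter so adding a stage never shifts another stage's random stream.
#' @param use_fastq If `TRUE` the pipeline emits paired FASTQ and re-counts
#'   variants from the reads; otherwise it scores the simulated counts
#'   directly.
#' @param annotations Optional clinical annotation data frame for the
#'   evaluation stage (synthetic labels derived from the ground truth are
#'   used otherwise).
#' @param structure_path Optional PDB file for the structure stage.
#' @param chain,offset Chain and residue-number offset for the structure
#'   stage.
#' @param log_level `"quiet"`, `"info"`, or `"debug"`.
#' @return List of class `tilemave_run_config`.
#' @export
run_config <- function(outdir, tiles = default_tiles(),
                       params = sim_params(), policy = merge_policy(),
                       scoring = scoring_config(),
                       thresholds = list(a = -0.5, i = -0.5, g = 0.3),
                       seed = params$seed, use_fastq = FALSE,
                       annotations = NULL, structure_path = NULL,
                       chain = "A", offset = 0L, log_level = "info") {
  params$seed <- seed
  structure(as.list(environment()), class = "tilemave_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `outdir`, `seed`, `use_fastq`, `log_level`,
#' `structure_path`, `chain`, `offset`, plus nested `params`, `policy`,
#' `scoring`, `thresholds`, and `tiles` (list of boundary records with
#' `tile_id`, `start_pos`, `end_pos`, `includes_nonsense`).
#'
#' @param path YAML file path.
#' @return `tilemave_run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  tiles <- if (is.null(y$tiles)) default_tiles() else {
    b <- do.call(rbind, lapply(y$tiles, as.data.frame))
    make_tiles(b, synthetic_reference_protein(), region_start = 487L)
  }
  args <- list(
    outdir = y$outdir %||% tempfile("tilemave_run"),
    tiles = tiles,
    params = do.call(sim_params, y$params %||% list()),
    policy = do.call(merge_policy, y$policy %||% list()),
    scoring = do.call(scoring_config, y$scoring %||% list()))
  for (k in c("thresholds", "seed", "use_fastq", "structure_path", "chain",
              "offset", "log_level"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a run configuration
#'
#' Checks every invariant (tile contiguity, positive depth, probability
#' bounds, requested-but-missing inputs) and returns a report rather than
#' stopping.
#'
#' @param config `tilemave_run_config` list.
#' @return Data frame with columns `check`, `ok`, `message`.
#' @export
validate_config <- function(config) {
  checks <- list()
  add <- function(check, ok, msg = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, ok = ok,
                                                 message = msg)
  }
  tile_err <- tryCatch({ validate_tiles(config$tiles); NULL },
                       error = conditionMessage)
  add("tiles", is.null(tile_err), tile_err %||% "")
  add("depth", config$params$depth > 0,
      if (config$params$depth <= 0) "depth must be positive" else "")
  add("replicates", config$params$n_replicates >= 2,
      if (config$params$n_replicates < 2) "need >= 2 replicates" else "")
  add("error_rate",
      config$params$error_rate >= 0 && config$params$error_rate <= 1,
      "")
  add("epsilon", config$scoring$epsilon > 0, "")
  add("structure",
      is.null(config$structure_path) || file.exists(config$structure_path),
      if (!is.null(config$structure_path) &&
          !file.exists(config$structure_path))
        paste("structure file not found:", config$structure_path) else "")
  do.call(rbind, checks)
}

pipeline_log <- function(config, level, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[config$log_level %||% "info"]] >= levels[[level]])
    message("[tilemave] ", ...)
}

# Write a table atomically: .partial until complete, then renamed.
write_stage_tsv <- function(tab, path) {
  tmp <- paste0(path, ".partial")
  utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  path
}

#' Run the full pipeline
#'
#' Executes simulate -> (reads -> counts) -> score -> rescale -> aggregate ->
#' [structure] -> evaluate, writing each stage's table under
#' `config$outdir` and a run manifest (seed, per-stage files with MD5 hashes
#' and record counts). Deterministic for a fixed seed and config.
#'
#' @param config `tilemave_run_config` list.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  rep <- validate_config(config)
  if (!all(rep$ok))
    stop("invalid configuration: ",
         paste(rep$message[!rep$ok], collapse = "; "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  record <- function(stage, files, n) {
    manifest$stages[[stage]] <<- list(
      files = files, md5 = unname(tools::md5sum(files)), n_records = n)
  }
  stage <- function(name, expr) {
    pipeline_log(config, "info", "stage: ", name)
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  truths <- stage("simulate", {
    lib <- design_library(config$tiles)
    tr <- draw_effects(lib, config$params)
    f <- file.path(config$outdir, "truth.tsv")
    write_truth_tsv(tr, f)
    record("simulate", f, nrow(tr))
    tr
  })

  counts <- stage("counts", {
    ct <- simulate_counts(truths, config$params)
    if (isTRUE(config$use_fastq)) {
      pieces <- lapply(unique(ct$assay), function(assay) {
        fq_dir <- file.path(config$outdir, paste0("fastq_", assay))
        man <- emit_fastq(ct[ct$assay == assay, ], config$tiles,
                          config$params, fq_dir,
                          seed = stage_seed(config$seed, "fastq") +
                            (assay == "interaction"))
        cc <- count_variants(man, config$tiles, config$policy)
        cc$assay <- assay
        cc
      })
      ct <- do.call(rbind, pieces)
      class(ct) <- c("tilemave_counts", "data.frame")
    }
    f <- file.path(config$outdir, "counts.tsv")
    write_stage_tsv(ct, f)
    record("counts", f, nrow(ct))
    ct
  })

  scores <- stage("score", {
    sc <- score_dataset(counts, config$scoring,
                        library = design_library(config$tiles))
    f <- file.path(config$outdir, "scores.tsv")
    write_stage_tsv(sc, f)
    record("score", f, nrow(sc))
    sc
  })

  rescaled <- stage("rescale", {
    rs <- rescale_scores(scores, assay = "abundance")
    f <- file.path(config$outdir, "scores_rescaled.tsv")
    write_stage_tsv(rs, f)
    fr <- file.path(config$outdir, "rescale_report.json")
    write_rescale_json(rs, fr)
    record("rescale", c(f, fr), nrow(rs))
    rs
  })

  summaries <- stage("aggregate", {
    out <- list()
    files <- character()
    for (assay in unique(rescaled$assay)) {
      out[[assay]] <- per_position_median(rescaled, assay = assay)
      f <- file.path(config$outdir,
                     paste0("position_medians_", assay, ".tsv"))
      write_stage_tsv(out[[assay]], f)
      hm <- heatmap_matrix(rescaled[rescaled$assay == assay, ])
      fm <- file.path(config$outdir, paste0("heatmap_", assay, ".csv"))
      fk <- file.path(config$outdir, paste0("heatmap_", assay, "_mask.csv"))
      write_heatmap_csv(hm, fm, fk)
      files <- c(files, f, fm, fk)
    }
    record("aggregate", files, sum(vapply(out, nrow, 0L)))
    out
  })

  if (!is.null(config$structure_path)) stage("structure", {
    pdb <- bio3d::read.pdb(config$structure_path)
    feats <- compute_rsasa(pdb, config$chain)
    feats$position <- feats$resno + config$offset
    f <- file.path(config$outdir, "residue_features.tsv")
    write_stage_tsv(feats, f)
    fp <- file.path(config$outdir, "scores_on_structure.pdb")
    map_scores_to_structure(pdb, summaries$abundance, fp,
                            chain = config$chain, offset = config$offset)
    record("structure", c(f, fp), nrow(feats))
  })

  stage("evaluate", {
    ann <- config$annotations
    if (is.null(ann)) {
      # synthetic labels straight from the simulated ground truth
      mis <- truths[!truths$alt_aa %in% c("Syn", "Ter"), ]
      ann <- data.frame(position = mis$position, wt_aa = mis$wt_aa,
                        alt_aa = mis$alt_aa,
                        clinvar_class = ifelse(
                          mis$mixture_class == "low-abundance",
                          "pathogenic", "benign"))
    }
    bench <- pathogenicity_benchmark(rescaled, ann)
    qc <- replicate_qc(rescaled)
    f <- file.path(config$outdir, "benchmark.json")
    jsonlite::write_json(
      list(auc = lapply(bench[setdiff(names(bench), "n_test")],
                        function(x) x[c("auc", "n_pos", "n_neg")]),
           n_test = bench$n_test,
           min_replicate_r = lapply(qc, `[[`, "min_r")),
      f, auto_unbox = TRUE, digits = NA)
    record("evaluate", f, bench$n_test)
  })

  mf <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  pipeline_log(config, "info", "done: ", config$outdir)
  invisible(manifest)
}
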