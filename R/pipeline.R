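## fill a user config with defaults; the resolved config is written beside
## the outputs so every run is self-describing
resolveConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- list(
    seed = 1L,
    simulate = NULL,                 # list(design = "cytokine"|"phospho")
    input = NULL,                    # list(panel_csv=, analyte_csv=)
    preprocess = list(batch_correct = TRUE, outlier_remove = TRUE,
                      confidence = 0.995, n_components = 2),
    plsda = list(n_lv = 2, contrast = "all", grid_step = 0.5,
                 duration = NULL),
    inference = list(permutations = 1000, loo_refits = 1000),
    stats = list(posthoc = "dunnett", reference = NULL, top_k = 4),
    network = NULL)                  # list(subsets = list(...), q = 0.1)
  mergeList <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        mergeList(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  mergeList(def, config)
}

#' Run the full panel-analysis pipeline
#'
#' Orchestrates one analysis arc end to end: obtain a panel (simulate a
#' canned design or read a CSV), preprocess (linear-range exclusion,
#' z-scoring, batch correction when multiple batches are present, iterative
#' outlier removal), fit and rotate the PLS-DA, compute the leave-one-out
#' loading envelope and the label-permutation p, run the univariate
#' follow-up statistics on the LV1 scores and top-loading analytes, and
#' (optionally) build correlation networks for configured subsets. All
#' artifacts are written to `outDir` together with a machine-readable
#' manifest (package version, seed, config hash, per-file content hashes),
#' so identical seeds yield byte-identical manifests.
#'
#' A single master seed (argument `seed`, falling back to `config$seed`)
#' derives the seeds of every stochastic stage (simulation, permutation,
#' Dunnett Monte Carlo).
#'
#' @param config configuration list, or path to a YAML/JSON config file.
#'   See the package vignette for the schema; every field has a default.
#' @param outDir output directory (created if needed).
#' @param seed optional master seed overriding `config$seed`.
#' @return (invisibly) a list with the in-memory stage results and
#'   `manifest`, the parsed manifest.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("plexsig_run_"),
                        seed = NULL) {
  cfg <- resolveConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name) files <<- c(files, name)

  ## ---- stage: input ----
  if (!is.null(cfg$input)) {
    message("stage input: reading ", cfg$input$panel_csv)
    panel <- readPanelCsv(cfg$input$panel_csv, cfg$input$analyte_csv)
  } else {
    designName <- if (is.null(cfg$simulate)) "cytokine"
      else cfg$simulate$design
    message("stage simulate: design '", designName, "', seed ", cfg$seed)
    fx <- emulateStudyDesigns(seed = cfg$seed)[[designName]]
    panel <- fx$panel
    writeGroundTruthJson(fx$truth, file.path(outDir, "ground_truth.json"))
    emit("ground_truth.json")
  }
  message(sprintf("  panel: %d samples x %d analytes", ncol(panel),
                  nrow(panel)))

  ## ---- stage: preprocess ----
  pp <- preprocessPanel(panel,
    batchCorrect = isTRUE(cfg$preprocess$batch_correct),
    outlierRemove = isTRUE(cfg$preprocess$outlier_remove),
    confidence = cfg$preprocess$confidence,
    nComponents = cfg$preprocess$n_components)
  message(sprintf("stage preprocess: excluded %d analyte(s), removed %d sample(s)",
                  nrow(pp$report@excludedAnalytes),
                  nrow(pp$report@removedSamples)))
  cleaned <- pp$panel
  writePanelCsv(cleaned, file.path(outDir, "cleaned_panel.csv"))
  writeCleaningReportJson(pp$report, file.path(outDir,
                                               "cleaning_report.json"))
  emit("cleaned_panel.csv"); emit("cleaning_report.json")

  ## ---- stage: plsda (optionally on one duration) ----
  target <- if (is.null(cfg$plsda$duration)) cleaned else
    zscorePanel(subsetPanel(cleaned, duration = cfg$plsda$duration))
  model <- rotateLvPlane(
    fitPlsda(target, nLv = cfg$plsda$n_lv),
    contrast = cfg$plsda$contrast, gridStep = cfg$plsda$grid_step)
  message(sprintf("stage plsda: rotated %.1f deg, LV1 separation %.3g",
                  model@rotationAngle * 180 / pi, model@separation[1]))
  writePlsdaJson(model, file.path(outDir, "plsda_model.json"))
  emit("plsda_model.json")

  ## ---- stage: inference ----
  env <- looLoadingStability(target, contrast = cfg$plsda$contrast,
                             nRefits = cfg$inference$loo_refits,
                             nLv = cfg$plsda$n_lv,
                             gridStep = cfg$plsda$grid_step)
  perm <- permutationTest(target, contrast = cfg$plsda$contrast,
                          B = cfg$inference$permutations,
                          seed = cfg$seed + 1L, nLv = cfg$plsda$n_lv,
                          gridStep = cfg$plsda$grid_step)
  message(sprintf("stage inference: %d LOO refits, permutation p = %.4g",
                  env@nRefits, perm@pValue))
  writeEnvelopeCsv(env, file.path(outDir, "loading_envelope.csv"))
  writePermutationJson(perm, file.path(outDir, "permutation.json"))
  emit("loading_envelope.csv"); emit("permutation.json")

  ## ---- stage: stats ----
  groups <- sampleGroups(target)
  scores <- model@scores[, 1]
  rows <- list()
  if (nlevels(groups) > 2L) {
    av <- oneWayAnova(scores, groups)
    rows[[1]] <- data.frame(analyte = "LV1_scores", comparison = "all",
                            estimate = NA_real_, statistic = av$F,
                            df = paste(av$dfBetween, av$dfWithin, sep = ","),
                            p = av$p, p_adj = NA_real_, method = "anova")
  } else {
    lv <- levels(groups)
    tt <- twoSampleT(scores[groups == lv[1]], scores[groups == lv[2]])
    rows[[1]] <- data.frame(analyte = "LV1_scores",
                            comparison = paste(lv[1], "-", lv[2]),
                            estimate = tt$estimate, statistic = tt$t,
                            df = as.character(tt$df), p = tt$p,
                            p_adj = NA_real_, method = "t")
  }
  topK <- topLoadings(model, k = min(cfg$stats$top_k,
                                     nrow(model@loadings)))
  m <- panelMatrix(target)
  for (an in topK$analyte) {
    v <- m[, an]
    if (nlevels(groups) > 2L) {
      av <- oneWayAnova(v, groups)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, comparison = "all", estimate = NA_real_,
        statistic = av$F,
        df = paste(av$dfBetween, av$dfWithin, sep = ","), p = av$p,
        p_adj = NA_real_, method = "anova")
      ph <- if (identical(cfg$stats$posthoc, "tukey")) tukeyHsd(v, groups)
        else dunnettTest(v, groups,
               reference = if (is.null(cfg$stats$reference))
                 levels(groups)[1] else cfg$stats$reference,
               seed = cfg$seed + 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, comparison = ph$comparison, estimate = ph$estimate,
        statistic = ph$t, df = as.character(ph$df), p = ph$p,
        p_adj = ph$p_adj, method = ph$method)
    } else {
      lv <- levels(groups)
      tt <- twoSampleT(v[groups == lv[1]], v[groups == lv[2]])
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, comparison = paste(lv[1], "-", lv[2]),
        estimate = tt$estimate, statistic = tt$t,
        df = as.character(tt$df), p = tt$p, p_adj = NA_real_,
        method = "t")
    }
  }
  statsDf <- do.call(rbind, rows)
  message(sprintf("stage stats: %d test rows on LV1 scores + top %d analytes",
                  nrow(statsDf), nrow(topK)))
  utils::write.csv(statsDf, file.path(outDir, "stats.csv"),
                   row.names = FALSE)
  emit("stats.csv")

  ## ---- stage: network (optional) ----
  nets <- list()
  if (!is.null(cfg$network)) {
    for (ss in cfg$network$subsets) {
      net <- correlationNetwork(cleaned, group = ss$group,
                                duration = ss$duration,
                                qThreshold = if (is.null(cfg$network$q))
                                  0.1 else cfg$network$q)
      tag <- paste0(c(ss$group, ss$duration), collapse = "_")
      tag <- gsub("[^A-Za-z0-9_]", "-", tag)
      fn <- sprintf("network_%s.tsv", tag)
      message(sprintf("stage network [%s]: %d/%d significant pairs", tag,
                      nrow(net@edges), net@nComparisons))
      writeNetworkTsv(net, file.path(outDir, fn))
      emit(fn)
      nets[[tag]] <- net
    }
  }

  ## ---- resolved config + manifest ----
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE)
  writeLines(cfgJson, file.path(outDir, "config.json"))
  emit("config.json")
  files <- sort(unique(files))
  manifest <- list(
    package = "plexsig",
    version = as.character(utils::packageVersion("plexsig")),
    seed = cfg$seed,
    config_hash = fnv1a(as.character(cfgJson)),
    files = lapply(files, function(f)
      list(name = f, hash = fileHash(file.path(outDir, f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("run complete: ", length(files), " artifact(s) in ", outDir)
  invisible(list(panel = panel, cleaned = cleaned, report = pp$report,
                 model = model, envelope = env, permutation = perm,
                 stats = statsDf, networks = nets, manifest = manifest,
                 outDir = outDir))
}
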