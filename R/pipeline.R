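#' Default pipeline configuration
#'
#' Returns the configuration list consumed by \code{\link{runPipeline}}.
#' Fields:
#' \describe{
#'   \item{input}{"synthetic" or "files". Synthetic mode generates a study
#'     from \code{design}; files mode reads a manifest CSV with columns
#'     file, subject, condition, segment.}
#'   \item{design}{for synthetic mode: arguments passed to
#'     \code{\link{StudyDesign}} (nSubjects, epochLength, sfreq, ...).}
#'   \item{manifest}{for files mode: path to the manifest CSV.}
#'   \item{preprocess}{list(bandpass = c(low, high) or NULL, lineFreq =
#'     50 or NULL, averageReference = TRUE/FALSE, detectBad = TRUE/FALSE).
#'     Synthetic data are generated clean, so all stages default off in
#'     synthetic mode.}
#'   \item{connectivity}{list(band, windowS, overlap, keep, weightFloor).}
#'   \item{plankMapping}{which plank segment feeds the "plank" task cell:
#'     "plank_end" (default), "plank_start" or "mean_of_both".}
#'   \item{seed}{global seed; every stochastic stage derives a stable
#'     sub-seed from it and the epoch identifiers.}
#'   \item{outDir}{output directory, or NULL to skip writing files.}
#' }
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged shallowly per top-level key).
#' @return the configuration list.
#' @export
defaultPipelineConfig <- function(...) {
  cfg <- list(
    input = "synthetic",
    design = list(nSubjects = 20, epochLength = 10, sfreq = 250),
    manifest = NULL,
    preprocess = list(bandpass = NULL, lineFreq = NULL,
                      averageReference = FALSE, detectBad = FALSE),
    connectivity = list(band = c(1, 40), windowS = 2, overlap = 0.5,
                        keep = 0.75, weightFloor = 1e-6),
    plankMapping = "plank_end",
    bonferroniAcrossScopes = FALSE,
    covariates = NULL,
    seed = 1,
    outDir = NULL
  )
  ov <- list(...)
  for (k in names(ov)) {
    # single-bracket assignment keeps keys whose value is NULL
    if (is.list(cfg[[k]]) && is.list(ov[[k]]) && length(ov[[k]])) {
      for (k2 in names(ov[[k]])) cfg[[k]][k2] <- list(ov[[k]][[k2]])
    } else cfg[k] <- list(ov[[k]])
  }
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' The file representation round-trips losslessly through
#' \code{writePipelineConfig} and \code{readPipelineConfig}.
#'
#' @param path YAML file path.
#' @return \code{readPipelineConfig}: the config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(defaultPipelineConfig, cfg)
}

#' @rdname readPipelineConfig
#' @param config a configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Per-epoch metric block: Pearson -> distance -> global + regional
# efficiency; wPLI -> threshold -> Louvain Q; wPLI -> centrality -> regional
# means. Returns a data.frame of metric rows.
.epochMetrics <- function(epoch, map, conn_cfg, seed,
                          metrics = c("efficiency", "modularity",
                                      "centrality")) {
  labs <- channelLabels(epoch)
  rows <- list()
  regions <- regionNames(map)
  base <- data.frame(subject = epoch@subjectId, condition = epoch@condition,
                     task = epoch@task, stringsAsFactors = FALSE)

  if ("efficiency" %in% metrics) {
    pc <- pearsonConnectivity(epoch)
    dm <- connectivityToDistance(pc, conn_cfg$weightFloor)
    rows$glob <- cbind(base, scope = "global", metric = "efficiency",
                       value = networkEfficiency(dm))
    for (r in regions)
      rows[[paste0("eff.", r)]] <-
        cbind(base, scope = r, metric = "efficiency",
              value = regionalValue(dm, r, map, "efficiency"))
  }

  if (any(c("modularity", "centrality") %in% metrics)) {
    wp <- wpliConnectivity(epoch, band = conn_cfg$band,
                           windowS = conn_cfg$windowS,
                           overlap = conn_cfg$overlap)
    if ("modularity" %in% metrics) {
      bin <- proportionalThreshold(wp, conn_cfg$keep)
      part <- louvainPartition(bin, seed = seed)
      rows$q <- cbind(base, scope = "global", metric = "modularity",
                      value = part@Q)
    }
    if ("centrality" %in% metrics) {
      cv <- eigenvectorCentrality(wp)
      for (r in regions)
        rows[[paste0("cen.", r)]] <-
          cbind(base, scope = r, metric = "centrality",
                value = regionalValue(cv, r, map, "centrality"))
    }
  }
  do.call(rbind, rows)
}

.loadManifestEpochs <- function(cfg) {
  mf <- utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("file", "subject", "condition", "segment") %in% names(mf)))
  base_dir <- dirname(cfg$manifest)
  lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$file[i]
    if (!file.exists(p)) p <- file.path(base_dir, mf$file[i])
    rec <- readRecording(p)
    pp <- cfg$preprocess
    if (!is.null(pp$bandpass))
      rec <- bandpassFilter(rec, pp$bandpass[1], pp$bandpass[2])
    if (!is.null(pp$lineFreq)) rec <- removeLineNoise(rec, pp$lineFreq)
    if (isTRUE(pp$averageReference)) rec <- averageReference(rec)
    if (isTRUE(pp$detectBad)) {
      rep_ <- detectBadChannels(rec)
      bad <- union(rep_@flatline, rep_@lowCorrelation)
      if (length(bad) && !is.null(rec@positions))
        rec <- interpolateChannels(rec, bad)
    }
    EEGEpoch(rec, mf$subject[i], mf$condition[i], mf$segment[i])
  })
}

# Collapse the plank segments of a metrics table into the "plank" task cell
# per the configured mapping; elevator rows pass through.
.collapsePlank <- function(metrics, epochs, mapping) {
  seg <- vapply(epochs, function(e) e@segment, "")
  if (mapping %in% c("plank_end", "plank_start")) {
    keep <- seg == "elevator" | seg == mapping
  } else if (mapping == "mean_of_both") {
    keep <- rep(TRUE, length(seg))
  } else stop("unknown plank mapping: ", mapping)
  keep
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the epochs, computes per-epoch connectivity and
#' graph metrics, averages replicate epochs within each
#' (subject, condition, task) cell, and runs the statistical layer: a KS
#' normality screen and a 2x2 fully-within repeated-measures ANOVA per
#' (scope, metric), Bonferroni post hocs for significant interactions, and
#' optional Spearman correlations against subject covariates. All outputs
#' are reproducible from \code{config$seed}: every epoch's stochastic
#' stages use a sub-seed derived by stable hashing of the (subject,
#' condition, task) identifiers, independent of iteration order.
#'
#' Per-epoch stage failures do not abort the batch: failing epochs are
#' collected in the returned \code{failures} data.frame.
#'
#' @param config a configuration list from
#'   \code{\link{defaultPipelineConfig}} or \code{\link{readPipelineConfig}}.
#' @param epochs optionally, a precomputed list of \code{EEGEpoch} (skips
#'   input generation; used for custom studies).
#' @return list(metrics, anova, posthoc, normality, correlations,
#'   failures, config). If \code{config$outDir} is set, CSV artifacts and
#'   a JSON run manifest are written there.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), epochs = NULL) {
  cfg <- config
  if (is.null(epochs)) {
    epochs <- if (cfg$input == "synthetic") {
      design <- do.call(StudyDesign, c(cfg$design, list(seed = cfg$seed)))
      generateStudy(design)
    } else {
      .loadManifestEpochs(cfg)
    }
  }
  labs <- channelLabels(epochs[[1]])
  map <- restrictRegionMap(defaultRegionMap(), labs)

  keep <- .collapsePlank(NULL, epochs, cfg$plankMapping)
  epochs <- epochs[keep]

  metric_rows <- vector("list", length(epochs))
  failures <- list()
  for (i in seq_along(epochs)) {
    e <- epochs[[i]]
    sub_seed <- deriveSeed(cfg$seed, "metrics", e@subjectId, e@condition,
                           e@task, e@segment)
    metric_rows[[i]] <- tryCatch(
      .epochMetrics(e, map, cfg$connectivity, sub_seed),
      error = function(err) {
        failures[[length(failures) + 1]] <<- data.frame(
          subject = e@subjectId, condition = e@condition, task = e@task,
          stage = "metrics", message = conditionMessage(err))
        NULL
      })
  }
  metrics <- do.call(rbind, metric_rows)
  if (is.null(metrics) || !nrow(metrics)) stop("no epoch produced metrics")
  # average replicate epochs within each cell (e.g. mean_of_both mapping,
  # or per-condition averaging of repeated segments)
  metrics <- stats::aggregate(
    value ~ subject + condition + task + scope + metric, metrics, mean)

  combos <- unique(metrics[, c("scope", "metric")])
  anova_rows <- list(); normality_rows <- list(); posthoc_rows <- list()
  for (i in seq_len(nrow(combos))) {
    sc <- combos$scope[i]; me <- combos$metric[i]
    sub <- metrics[metrics$scope == sc & metrics$metric == me, ]
    # subjects that lost an epoch to a stage failure have incomplete cells;
    # the within-subject ANOVA uses complete cases only
    cnt <- table(sub$subject)
    incomplete <- names(cnt)[cnt < 4]
    if (length(incomplete)) {
      failures[[length(failures) + 1]] <- data.frame(
        subject = paste(incomplete, collapse = ";"), condition = NA,
        task = NA, stage = paste0("anova:", sc, ":", me),
        message = "incomplete cells; subject excluded")
      sub <- sub[!sub$subject %in% incomplete, ]
    }
    if (length(unique(sub$subject)) < 2) next
    ks <- tryCatch(
      ksNormality(sub$value, nrep = 2000,
                  seed = deriveSeed(cfg$seed, "ks", sc, me)),
      error = function(e) list(statistic = NA_real_, p = NA_real_))
    normality_rows[[i]] <- data.frame(scope = sc, metric = me,
                                      ks_statistic = ks$statistic,
                                      ks_p = ks$p)
    an <- rmAnova2x2(sub)
    an$scope <- sc; an$metric <- me
    if (isTRUE(cfg$bonferroniAcrossScopes))
      an$p_adj_scopes <- pmin(1, an$p * nrow(combos))
    anova_rows[[i]] <- an

    int_p <- an$p[an$effect == "condition:task"]
    if (is.finite(int_p) && int_p < 0.05) {
      ph_tab <- data.frame(subject = sub$subject,
                           cell = paste(sub$condition, sub$task, sep = "."),
                           value = sub$value)
      cmp <- list(c("negative.elevator", "neutral.elevator"),
                  c("negative.plank", "neutral.plank"),
                  c("negative.plank", "negative.elevator"),
                  c("neutral.plank", "neutral.elevator"))
      ph <- bonferroniPairwise(ph_tab, cmp)
      ph$scope <- sc; ph$metric <- me
      posthoc_rows[[length(posthoc_rows) + 1]] <- ph
    }
  }
  anova <- do.call(rbind, anova_rows)
  normality <- do.call(rbind, normality_rows)
  posthoc <- if (length(posthoc_rows)) do.call(rbind, posthoc_rows) else
    data.frame()

  correlations <- data.frame()
  if (!is.null(cfg$covariates)) {
    cov <- utils::read.csv(cfg$covariates, stringsAsFactors = FALSE)
    stopifnot("subject" %in% names(cov))
    cov_cols <- setdiff(names(cov), "subject")
    cor_rows <- list()
    for (i in seq_len(nrow(combos))) {
      sc <- combos$scope[i]; me <- combos$metric[i]
      sub <- metrics[metrics$scope == sc & metrics$metric == me, ]
      per_subj <- stats::aggregate(value ~ subject, sub, mean)
      merged <- merge(per_subj, cov, by = "subject")
      for (cc in cov_cols) {
        r <- tryCatch(spearmanCorrelation(merged$value, merged[[cc]]),
                      error = function(e) list(rho = NA_real_, p = NA_real_))
        cor_rows[[length(cor_rows) + 1]] <-
          data.frame(scope = sc, metric = me, covariate = cc,
                     rho = r$rho, p = r$p)
      }
    }
    correlations <- do.call(rbind, cor_rows)
  }

  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame()

  result <- list(metrics = metrics, anova = anova, posthoc = posthoc,
                 normality = normality, correlations = correlations,
                 failures = failures, config = cfg)

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    writeMetricsTable(metrics, file.path(cfg$outDir, "metrics.csv"))
    .writeStableCSV(anova, file.path(cfg$outDir, "anova.csv"))
    .writeStableCSV(normality, file.path(cfg$outDir, "normality.csv"))
    if (nrow(posthoc))
      .writeStableCSV(posthoc, file.path(cfg$outDir, "posthoc.csv"))
    if (nrow(correlations))
      .writeStableCSV(correlations, file.path(cfg$outDir, "correlations.csv"))
    if (nrow(failures))
      .writeStableCSV(failures, file.path(cfg$outDir, "failures.csv"))
    manifest <- list(
      package = "eegraph",
      version = as.character(utils::packageVersion("eegraph")),
      seed = cfg$seed,
      parameters = cfg[setdiff(names(cfg), "outDir")],
      n_epochs = length(epochs),
      n_failures = nrow(failures))
    jsonlite::write_json(manifest, file.path(cfg$outDir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  result
}

.writeStableCSV <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
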