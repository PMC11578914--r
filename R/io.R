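## Delimited-text IO and the end-to-end pipeline.

#' Write an ordinal dataset as delimited text
#'
#' Tab-separated with header: item columns, group column(s), optional
#' cluster ID; missing cells are written empty.
#'
#' @param dataset an \linkS4class{OrdinalDataset}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeDataset <- function(dataset, path) {
  df <- as.data.frame(dataset@items)
  for (col in names(dataset@groups)) df[[col]] <- dataset@groups[[col]]
  if (!is.null(dataset@cluster)) df$cluster <- dataset@cluster
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a survey table into an ordinal dataset
#'
#' Delimited text with header; item categories must be integer-coded in
#' 1..nCategories. Out-of-range or non-integer categories are rejected with
#' the offending row and column; empty cells become missing.
#'
#' @param path input file.
#' @param items item column names (default: columns starting with
#'   \code{"item"}).
#' @param groupCols grouping column name(s) (default \code{"label"} if
#'   present, else all non-item, non-cluster columns).
#' @param clusterCol optional cluster ID column.
#' @param nCategories number of categories C (default: maximum observed).
#' @param sep field separator.
#' @return an \linkS4class{OrdinalDataset}.
#' @export
readSurveyTable <- function(path, items = NULL, groupCols = NULL,
                            clusterCol = NULL, nCategories = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  if (is.null(items)) items <- grep("^item", names(df), value = TRUE)
  if (!length(items)) stop("no item columns found")
  miss <- setdiff(items, names(df))
  if (length(miss)) stop("missing item column(s): ", paste(miss, collapse = ", "))
  if (is.null(clusterCol) && "cluster" %in% names(df)) clusterCol <- "cluster"
  if (is.null(groupCols)) {
    groupCols <- setdiff(names(df), c(items, clusterCol))
    if ("label" %in% groupCols) groupCols <- union("label", setdiff(groupCols, "label"))
  }
  if (!length(groupCols)) stop("no grouping column(s) found")
  y <- as.matrix(df[, items, drop = FALSE])
  storage.mode(y) <- "double"
  C <- if (is.null(nCategories)) max(y, na.rm = TRUE) else nCategories
  bad <- which(!is.na(y) & (y < 1 | y > C | y != round(y)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid category value %s at row %d, column '%s' (expected integer 1..%d)",
                 format(y[bad[1, , drop = FALSE]]), bad[1, 1], items[bad[1, 2]], C))
  storage.mode(y) <- "integer"
  groups <- df[, groupCols, drop = FALSE]
  if (!"label" %in% names(groups))
    groups$label <- do.call(paste, c(lapply(groups, as.character), sep = "."))
  cnt <- table(groups$label)
  if (any(cnt == 0)) stop("empty group in input")
  cl <- if (!is.null(clusterCol)) as.character(df[[clusterCol]]) else NULL
  new("OrdinalDataset", items = y, groups = groups, cluster = cl,
      nCategories = as.integer(C), seed = NA_integer_)
}

#' Pipeline configuration
#'
#' @param input path to a survey table, or a \linkS4class{PopulationSpec} /
#'   path to a YAML spec to simulate from.
#' @param grouping grouping column(s) forming the analysis groups.
#' @param reference reference group label for trend centering (default:
#'   first group).
#' @param residualPairs correlated-residual item pairs.
#' @param ladder a \code{\link{ladderConfig}}.
#' @param run named logical toggles: dimensionality, dfi, dmacs,
#'   freedVsFixed, icc.
#' @param dfiReps replications for the dynamic cutoffs.
#' @param paSets parallel-analysis reference sets.
#' @param seed integer seed (recorded in every output).
#' @param outDir output directory.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(input, grouping = "label", reference = NULL,
                           residualPairs = rbind(c(3L, 4L)),
                           ladder = ladderConfig(),
                           run = c(dimensionality = TRUE, dfi = FALSE,
                                   dmacs = TRUE, freedVsFixed = TRUE,
                                   icc = FALSE),
                           dfiReps = 100L, paSets = 200L, seed = 1L,
                           outDir = tempfile("ordinvar_run_")) {
  structure(list(input = input, grouping = grouping, reference = reference,
                 residualPairs = residualPairs, ladder = ladder, run = run,
                 dfiReps = dfiReps, paSets = paSets, seed = seed,
                 outDir = outDir),
            class = "PipelineConfig")
}

#' Run the full invariance/trend pipeline
#'
#' Executes dimensionality assessment, the invariance ladder, and (as
#' toggled) d_MACS, freed-versus-fixed trends, the ICC clustering check and
#' dynamic fit-index cutoffs; writes a report bundle (JSON manifest + TSV
#' tables) to the configured output directory. Identical configuration and
#' seed reproduce an identical bundle.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, the results list (also written to disk).
#' @export
runPipeline <- function(config) {
  dataset <- config$input
  if (is.character(dataset)) {
    dataset <- if (grepl("\\.ya?ml$", dataset))
      simulateOrdinal(readSpec(dataset), seed = config$seed)
    else readSurveyTable(dataset)
  } else if (is(dataset, "PopulationSpec")) {
    dataset <- simulateOrdinal(dataset, seed = config$seed)
  }
  stopifnot(is(dataset, "OrdinalDataset"))
  res <- list(seed = config$seed, grouping = config$grouping)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  run <- config$run
  on <- function(what) isTRUE(run[[what]])

  if (on("dimensionality"))
    res$dimensionality <- stage("dimensionality",
      parallelAnalysis(dataset, nSets = config$paSets, seed = config$seed))

  res$descriptives <- stage("descriptives",
    describeItems(dataset, grouping = config$grouping))

  res$ladder <- stage("invariance",
    runLadder(dataset, grouping = config$grouping,
              residualPairs = config$residualPairs, config = config$ladder))

  ## d_MACS needs latent means separated from item parameters, so it is
  ## computed from the (partial) scalar fit and skipped below that level
  if (on("dmacs") && grepl("scalar", res$ladder@level))
    res$dmacs <- stage("dmacs",
      dmacsTable(res$ladder@steps$intercepts, reference = config$reference))

  if (grepl("scalar", res$ladder@level)) {
    res$trend <- stage("trends",
      latentTrend(res$ladder, reference = config$reference))
    if (on("freedVsFixed")) {
      freed <- res$ladder@freed
      if (!length(unlist(freed))) freed <- list(intercepts = integer(0))
      if (length(unlist(freed)))
        res$freedVsFixed <- stage("freedVsFixed",
          freedVsFixed(dataset, noninvariantParams = freed,
                       grouping = config$grouping,
                       residualPairs = config$residualPairs,
                       reference = config$reference))
    }
  }

  if (on("icc") && !is.null(dataset@cluster))
    res$icc <- stage("icc", {
      vapply(seq_len(ncol(dataset@items)), function(j)
        iccOneway(dataset@items[, j], dataset@cluster), numeric(1))
    })

  if (on("dfi"))
    res$dfi <- stage("dfi", {
      f <- .groupFactor(dataset, config$grouping)
      pooled <- polyMoments(dataset@items[, , drop = FALSE])
      m1 <- cfaModel(list(pooled), "configural",
                     residualPairs = config$residualPairs)
      fit1 <- suppressWarnings(fitCfa(list(pooled), m1))
      dfiCutoffs(fit1, reps = config$dfiReps, seed = config$seed)
    })

  writeReport(res, config$outDir)
  invisible(res)
}

#' Write a pipeline report bundle
#'
#' JSON manifest (machine-readable, every decision reproducible from the
#' stored delta values) plus delimited tables: the invariance table
#' (model, chisq, df, CFI, RMSEA + CI, TLI, SRMR, delta indices, decision),
#' trend tables, d_MACS table, descriptives.
#'
#' @param results list produced by \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeReport <- function(results, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  manifest <- list(package = "ordinvar",
                   version = as.character(utils::packageVersion("ordinvar")),
                   seed = results$seed, grouping = results$grouping,
                   tables = character(0))
  putTable <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$tables <<- c(manifest$tables, paste0(name, ".tsv"))
  }
  if (!is.null(results$ladder)) {
    putTable(comparisonTable(results$ladder), "invariance")
    manifest$invariance <- list(
      level = achievedLevel(results$ladder),
      freed = results$ladder@freed,
      rules = results$ladder@config[c("deltaRmseaMax", "deltaCfiMin",
                                      "deltaCfiMinIntercepts")],
      comparisons = comparisonTable(results$ladder))
  }
  if (!is.null(results$dimensionality)) {
    putTable(screeTable(results$dimensionality), "scree")
    manifest$dimensionality <- list(
      retained = results$dimensionality@retained,
      ratio = results$dimensionality@ratio,
      unidimensional = results$dimensionality@unidimensional,
      nSets = results$dimensionality@nSets,
      corMethod = results$dimensionality@corMethod)
  }
  if (!is.null(results$descriptives)) putTable(results$descriptives, "descriptives")
  if (!is.null(results$dmacs)) putTable(results$dmacs, "dmacs")
  if (!is.null(results$trend)) {
    putTable(results$trend, "trend")
    manifest$trend <- list(reference = results$trend$reference[1],
                           variant = results$trend$variant[1],
                           ciMethod = "delta method, asymptotic parameter covariance")
  }
  if (!is.null(results$freedVsFixed)) {
    putTable(rbind(results$freedVsFixed$freed, results$freedVsFixed$fixed),
             "trend_freed_vs_fixed")
    manifest$freedVsFixed <- list(
      maxAbsDifference = results$freedVsFixed$maxAbsDifference)
  }
  if (!is.null(results$icc)) manifest$icc <- as.list(results$icc)
  if (!is.null(results$dfi)) {
    putTable(as.data.frame(results$dfi), "dfi_cutoffs")
    manifest$dfi <- list(reps = attr(results$dfi, "reps"),
                         misspecification = attr(results$dfi, "misspecification"))
  }
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(p)
}

#' Export group moments as a JSON audit report
#'
#' @param moments a \linkS4class{PolychoricMoments}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
momentsToJson <- function(moments, path) {
  x <- list(group = moments@group, n = moments@n, items = moments@items,
            thresholds = moments@thresholds,
            correlations = moments@rho,
            asymptoticVariances = diag(moments@acov),
            pairwiseN = moments@pairN)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
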