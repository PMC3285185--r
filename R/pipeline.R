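#' Run the multi-model neutrality-testing pipeline
#'
#' Orchestrates, for each requested model of population history: history
#' assembly from posterior tables, posterior predictive simulation,
#' dataset-level and locus-level goodness-of-fit tests, and (optionally)
#' the HKA branch.  Writes `report.tsv`, `report.json` and a
#' reproducibility manifest to the output directory.  A failure in one
#' model is logged and the remaining models still run.
#'
#' @param config a named list, or the path of a YAML file, with entries:
#'   \describe{
#'     \item{models}{character subset of `two_island`,
#'       `isolation_migration`, `bottleneck`, `hybridization`,
#'       `selection_subset`.}
#'     \item{empirical}{per-locus statistics: a data.frame or a TSV path
#'       in the [readTable1()] dialect.}
#'     \item{posteriors}{named list of [PosteriorTable-class] objects or
#'       TSV paths: `lamarc`, `im`, `rates`, `recomb`, optionally `fd`.}
#'     \item{loci}{data.frame (or TSV path) with columns `locus`,
#'       `length`, `ploidy`.}
#'     \item{nHistories, nPerDeme, alpha, fdrQ, seed, outDir}{run
#'       settings.}
#'     \item{selectionExclude}{loci excluded by the selection-subset
#'       model (required when that model is requested).}
#'     \item{hka}{optional list of HKA input data.frames or TSV paths
#'       (one per outgroup).}
#'   }
#' @return (invisibly) a list with per-model results and the report
#'   data.frame.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- .normalizeConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  results <- list()
  for (model in cfg$models) {
    res <- tryCatch(.runOneModel(model, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      message("model ", model, " failed: ", conditionMessage(res))
      report[[model]] <- data.frame(model = model, statistic = NA,
                                    measure = "error",
                                    empirical = NA_real_, p = NA_real_,
                                    significant = NA,
                                    error = conditionMessage(res),
                                    stringsAsFactors = FALSE)
      next
    }
    results[[model]] <- res
    for (stat in c("pi", "phiSt", "tajd"))
      utils::write.table(
        slot(res$predictive, stat),
        file.path(cfg$outDir, sprintf("predictive_%s_%s.tsv", model, stat)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    tab <- res$dataset@table
    tab$model <- model
    tab$error <- NA_character_
    report[[model]] <- tab
  }
  if (!is.null(cfg$hka)) {
    removals <- lapply(cfg$hka, function(x) iterativeRemoval(x,
                                                             cfg$alpha)$removed)
    results$hka <- list(removals = removals,
                        outliers = consensusOutliers(removals))
  }
  reportTab <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  utils::write.table(reportTab, file.path(cfg$outDir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    models = lapply(results[intersect(names(results), cfg$models)],
                    function(r) list(
                      dataset = r$dataset@table,
                      locus = r$locus@table[r$locus@table$significant, ,
                                            drop = FALSE])),
    hka = if (!is.null(results$hka)) results$hka else NULL)
  jsonlite::write_json(json, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest <- list(
    package = "coalfit",
    version = as.character(utils::packageVersion("coalfit")),
    seed = cfg$seed, nHistories = cfg$nHistories,
    models = cfg$models,
    inputFiles = cfg$inputFiles,
    inputHashes = if (length(cfg$inputFiles))
      as.list(tools::md5sum(unlist(cfg$inputFiles))) else list(),
    timeUnits = "4*N0 generations (ms conventions)")
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, report = reportTab, outDir = cfg$outDir))
}

.normalizeConfig <- function(config) {
  cfg <- config
  cfg$models <- match.arg(config$models,
                          c("two_island", "isolation_migration",
                            "bottleneck", "hybridization",
                            "selection_subset"),
                          several.ok = TRUE)
  cfg$inputFiles <- list()
  grab <- function(x, reader) {
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x)) stop("input file does not exist: ", x)
      cfg$inputFiles[[length(cfg$inputFiles) + 1L]] <<- x
      reader(x)
    } else x
  }
  cfg$empirical <- grab(config$empirical, readTable1)
  cfg$posteriors <- lapply(setNames(nm = names(config$posteriors)),
                           function(nm) grab(config$posteriors[[nm]],
                                             function(p)
                                               readPosterior(p, nm)))
  cfg$loci <- grab(config$loci, function(p)
    utils::read.delim(p, stringsAsFactors = FALSE))
  if (is.null(cfg$loci))
    cfg$loci <- data.frame(locus = cfg$empirical$locus,
                           length = cfg$empirical$length_bp,
                           ploidy = 1, stringsAsFactors = FALSE)
  if (!is.null(config$hka))
    cfg$hka <- lapply(config$hka, grab, reader = readHKAInput)
  if (is.null(cfg$nHistories)) cfg$nHistories <- 1000
  if (is.null(cfg$nPerDeme)) cfg$nPerDeme <- c(50, 50)
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (is.null(cfg$fdrQ)) cfg$fdrQ <- 0.05
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outDir)) cfg$outDir <- "coalfit_report"
  if ("selection_subset" %in% cfg$models &&
      is.null(config$selectionExclude))
    stop("selection_subset requires an explicit selectionExclude list")
  cfg
}

.runOneModel <- function(model, cfg) {
  isSubset <- model == "selection_subset"
  demSource <- if (model == "two_island") "lamarc" else "im"
  dem <- cfg$posteriors[[demSource]]
  if (is.null(dem)) stop("no ", demSource, " posterior table supplied")
  loci <- cfg$loci
  empirical <- cfg$empirical
  if (isSubset) {
    keep <- !(loci$locus %in% cfg$selectionExclude)
    loci <- loci[keep, , drop = FALSE]
    empirical <- empirical[!(empirical$locus %in% cfg$selectionExclude), ,
                           drop = FALSE]
  }
  histModel <- if (isSubset) "isolation_migration" else model
  hist <- assembleHistories(
    dem, cfg$posteriors$rates, cfg$posteriors$recomb, loci,
    n = cfg$nHistories, model = histModel,
    lamarcTheta = if (histModel == "bottleneck") cfg$posteriors$lamarc,
    fd = cfg$posteriors$fd, seed = deriveSeed(cfg$seed, match(model,
      c("two_island", "isolation_migration", "bottleneck",
        "hybridization", "selection_subset"))))
  pred <- posteriorPredictive(hist, nPerDeme = cfg$nPerDeme,
                              seed = hist@seed)
  list(histories = hist,
       predictive = pred,
       dataset = gofDataset(empirical, pred, alpha = cfg$alpha),
       locus = gofLocusFdr(empirical, pred, q = cfg$fdrQ))
}
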