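#' Read a run configuration file
#'
#' YAML configuration driving [runPipeline()]. Required fields:
#' `counts`, `annotation` (file paths), `design` with `initial`,
#' `control`, `treated` sample ids (`control`/`treated` may list
#' replicate finals). Optional: `filters` (`min_initial`, `min_sgrnas`,
#' `min_reference`), `classify` (`z_cut`, `essential_cut`, `top_n`),
#' `seed`, `output_dir`.
#'
#' @param path YAML file path.
#' @return a validated named list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("run config not found: ", path)
    cfg <- yaml::read_yaml(path)
    for (f in c("counts", "annotation", "design"))
        if (is.null(cfg[[f]])) stop("run config missing field '", f, "'")
    for (f in c("initial", "control", "treated"))
        if (is.null(cfg$design[[f]]))
            stop("run config design missing '", f, "'")
    defaults <- list(filters = list(min_initial = 100, min_sgrnas = 6,
                                    min_reference = 10),
                     classify = list(z_cut = 2, essential_cut = -0.5,
                                     top_n = 30),
                     seed = 1, output_dir = ".")
    cfg <- utils::modifyList(defaults, cfg)
    bad <- unlist(cfg$filters) < 0
    if (any(bad)) stop("filter thresholds must be non-negative")
    cfg
}

#' Run the screen-scoring pipeline from a configuration
#'
#' End-to-end orchestration: read counts and annotation, assemble the
#' [ScreenExperiment] with the configured sample roles, score with
#' [scoreScreen()], and write four artifacts into the output directory:
#' `scores.tsv` (per-gene table, selective z ascending),
#' `rank_plot.tsv`, `scatter.tsv` (scaled control vs treated per gene)
#' and `summary.json` (anchors, filter tallies, thresholds, seed, top
#' hit lists). Deterministic: identical config and inputs give
#' identical outputs.
#'
#' @param config path to a YAML run configuration, or the list from
#'   [readRunConfig()].
#' @param outputDir overrides the config's `output_dir`.
#' @return the [GeneScores] object, invisibly; file paths in
#'   `metadata`-style attribute `files`.
#' @export
runPipeline <- function(config, outputDir = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    outDir <- if (is.null(outputDir)) config$output_dir else outputDir
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    }
    counts <- stage("read_counts", readCountTable(config$counts))
    ann <- stage("read_annotation", readLibraryAnnotation(config$annotation))
    des <- config$design
    roles <- c(stats::setNames("initial", des$initial),
               stats::setNames(rep("final_control", length(des$control)),
                               des$control),
               stats::setNames(rep("final_treated", length(des$treated)),
                               des$treated))
    missing <- setdiff(names(roles),
                       setdiff(colnames(counts), c("sgRNA", "gene")))
    if (length(missing))
        stop("[design] sample id(s) not in count table: ",
             paste(missing, collapse = ", "))
    se <- stage("assemble", ScreenExperiment(counts, ann, roles))
    gs <- stage("score", scoreScreen(
        se, minInitial = config$filters$min_initial,
        minSgRNAs = config$filters$min_sgrnas,
        minReference = config$filters$min_reference,
        zCut = config$classify$z_cut,
        essentialCut = config$classify$essential_cut))

    files <- file.path(outDir, c("scores.tsv", "rank_plot.tsv",
                                 "scatter.tsv", "summary.json"))
    names(files) <- c("scores", "rankPlot", "scatter", "summary")
    writeScoreTable(gs, files["scores"])
    utils::write.table(rankPlotData(gs), files["rankPlot"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab <- as.data.frame(scoreTable(gs))
    utils::write.table(
        data.frame(gene = tab$gene, scaled_control = tab$scaledControl,
                   scaled_treated = tab$scaledTreated,
                   category = tab$category),
        files["scatter"], sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(
        package = as.character(utils::packageVersion("crisprSelect")),
        seed = config$seed,
        anchors = lapply(gs@anchors, as.list),
        tallies = gs@tallies,
        params = gs@params,
        nGenesScored = nrow(tab),
        categories = as.list(table(tab$category)),
        topHits = topHits(gs, config$classify$top_n))
    jsonlite::write_json(summary, files["summary"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    attr(gs, "files") <- files
    invisible(gs)
}

#' Write a simulated screen as plain-text fixture files
#'
#' Wraps [simulateScreen()] with a preset and writes `counts.tsv`,
#' `annotation.tsv`, `truth_genes.tsv` and `truth_sgrnas.tsv` plus a
#' ready-to-run `config.yaml` into a directory — reproducible fixtures
#' for tests and examples.
#'
#' @param seed integer seed.
#' @param size preset name passed to [simPreset()].
#' @param outDir output directory (created if needed).
#' @param ... preset overrides.
#' @return named character vector of the file paths, invisibly.
#' @export
makeFixture <- function(seed = 7, size = "small", outDir = tempfile(),
                        ...) {
    sim <- simulateScreen(simPreset(size, seed = seed, ...))
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    se <- screen(sim)
    cts <- data.frame(sgRNA = rownames(se),
                      gene = ifelse(is.na(rowData(se)$gene), "",
                                    rowData(se)$gene),
                      assay(se, "counts"), check.names = FALSE,
                      stringsAsFactors = FALSE)
    ann <- data.frame(sgrna = rownames(se),
                      gene = ifelse(is.na(rowData(se)$gene), "",
                                    rowData(se)$gene),
                      control_class = rowData(se)$controlClass,
                      core_essential = rowData(se)$coreEssential,
                      stringsAsFactors = FALSE)
    files <- file.path(outDir, c("counts.tsv", "annotation.tsv",
                                 "truth_genes.tsv", "truth_sgrnas.tsv",
                                 "config.yaml"))
    names(files) <- c("counts", "annotation", "truthGenes", "truthSgRNAs",
                      "config")
    utils::write.table(cts, files["counts"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ann, files["annotation"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(geneTruth(sim)), files["truthGenes"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(sgRNATruth(sim)),
                       files["truthSgRNAs"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(list(
        counts = unname(files["counts"]),
        annotation = unname(files["annotation"]),
        design = list(initial = "initial", control = "final_dmso",
                      treated = "final_drug"),
        seed = seed, output_dir = file.path(outDir, "results")),
        files["config"])
    invisible(files)
}
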