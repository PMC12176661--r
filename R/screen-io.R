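#' Read a MAGeCK-count-style sgRNA count table
#'
#' Parses a tab-separated count table whose first two columns are the
#' sgRNA id and the gene id, followed by one column of integer read
#' counts per sample (the output format of common sgRNA counting tools).
#' The gene column is retained so it can be cross-validated against the
#' library annotation when the [ScreenExperiment] is assembled.
#'
#' @param path path to a UTF-8 tab-separated file with a header row.
#' @return a `data.frame` with columns `sgRNA`, `gene` and one integer
#'   column per sample, one row per sgRNA.
#' @details Duplicate sgRNA ids, negative or non-integer counts, and
#'   tables without sample columns are hard errors naming the offending
#'   id or cell.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("sgRNA\tgene\tinitial\tfinal",
#'              "sgA_1\tGENE_A\t120\t80",
#'              "sgB_1\tGENE_B\t95\t110"), tsv)
#' readCountTable(tsv)
#' @export
readCountTable <- function(path) {
    if (!file.exists(path)) stop("count table not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             colClasses = c("character", "character"),
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 3L)
        stop("count table has no sample columns (need sgRNA, gene, samples)")
    colnames(tab)[1:2] <- c("sgRNA", "gene")
    dup <- tab$sgRNA[duplicated(tab$sgRNA)]
    if (length(dup))
        stop("duplicate sgRNA id(s): ", paste(unique(dup), collapse = ", "))
    for (j in seq(3L, ncol(tab))) {
        v <- tab[[j]]
        if (!is.numeric(v))
            v <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(v) | v < 0 | v != round(v))
        if (length(bad))
            stop(sprintf(
                "non-integer or negative count in column '%s', row %d (sgRNA %s)",
                colnames(tab)[j], bad[1L], tab$sgRNA[bad[1L]]))
        tab[[j]] <- as.integer(round(v))
    }
    tab
}

#' Read an sgRNA library annotation table
#'
#' Reads the tab-separated sgRNA-to-gene map with the two reference-set
#' flags the scoring pipeline needs: the control class of each sgRNA
#' (`targeting` / `non_targeting`, the latter defining the neutral
#' scaling anchor) and a per-gene core-essential flag (the
#' full-depletion anchor).
#'
#' @param path tab-separated file with header columns `sgrna`, `gene`,
#'   `control_class`, `core_essential` (logical or 0/1; empty gene for
#'   non-targeting sgRNAs).
#' @return a validated `data.frame` with those four columns; `gene` is
#'   `NA` for non-targeting sgRNAs.
#' @export
readLibraryAnnotation <- function(path) {
    if (!file.exists(path)) stop("annotation not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character",
                             check.names = FALSE)
    need <- c("sgrna", "gene", "control_class", "core_essential")
    if (!all(need %in% colnames(tab)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    tab <- tab[, need]
    tab$gene[tab$gene %in% c("", "NA", "-")] <- NA_character_
    tab$core_essential <- as.logical(
        ifelse(tab$core_essential %in% c("1", "TRUE", "true"), TRUE,
        ifelse(tab$core_essential %in% c("0", "FALSE", "false", ""), FALSE,
               NA)))
    validateAnnotation(tab)
    tab
}

validateAnnotation <- function(ann) {
    dup <- ann$sgrna[duplicated(ann$sgrna)]
    if (length(dup))
        stop("duplicate sgRNA id(s) in annotation: ",
             paste(unique(dup), collapse = ", "))
    bad <- setdiff(unique(ann$control_class), .CONTROL_CLASSES)
    if (length(bad))
        stop("unknown control_class token(s): ", paste(bad, collapse = ", "))
    nt <- ann$control_class == "non_targeting"
    if (any(!is.na(ann$gene[nt])))
        stop("non-targeting sgRNA(s) carry a gene id: ",
             paste(ann$sgrna[nt & !is.na(ann$gene)], collapse = ", "))
    if (any(is.na(ann$gene[!nt])))
        stop("targeting sgRNA(s) without a gene id: ",
             paste(ann$sgrna[!nt & is.na(ann$gene)], collapse = ", "))
    if (anyNA(ann$core_essential))
        stop("core_essential flag must be TRUE/FALSE (or 1/0)")
    if (any(ann$core_essential[nt]))
        stop("core_essential applies only to targeting sgRNAs")
    # per-gene consistency of the core-essential flag
    tg <- ann[!nt, ]
    flag <- tapply(tg$core_essential, tg$gene, function(x) length(unique(x)))
    if (any(flag > 1L))
        stop("inconsistent core_essential flag for gene(s): ",
             paste(names(flag)[flag > 1L], collapse = ", "))
    if (!any(tg$core_essential))
        warning("annotation has zero core-essential genes; ",
                "reference scaling will fail downstream")
    invisible(ann)
}

#' Assemble a ScreenExperiment from counts, annotation and sample roles
#'
#' Joins a parsed count table with the library annotation and the sample
#' role design into a validated [ScreenExperiment]. The count table's
#' own gene column is cross-checked against the annotation; any
#' disagreement is an error listing the sgRNAs. sgRNAs present in the
#' annotation but absent from the counts are added as zero-count rows
#' (with a warning tally) and will fall to the initial-count filter.
#'
#' @param counts `data.frame` from [readCountTable()], or an integer
#'   matrix with sgRNA rownames and sample colnames.
#' @param annotation `data.frame` from [readLibraryAnnotation()] (or of
#'   the same shape).
#' @param roles named character vector mapping every sample id to a role
#'   in `"initial"`, `"final_control"`, `"final_treated"`; exactly one
#'   sample must be `"initial"`.
#' @return a [ScreenExperiment].
#' @examples
#' sim <- simulateScreen(simPreset("small", seed = 1))
#' screen(sim)   # already assembled; the constructor is for file input
#' @export
ScreenExperiment <- function(counts, annotation, roles) {
    validateAnnotation(annotation)
    if (is.data.frame(counts)) {
        if (!all(c("sgRNA", "gene") %in% colnames(counts)))
            stop("count data.frame needs 'sgRNA' and 'gene' columns")
        m <- match(counts$sgRNA, annotation$sgrna)
        if (anyNA(m))
            stop("sgRNA(s) in counts missing from annotation: ",
                 paste(counts$sgRNA[is.na(m)], collapse = ", "))
        annGene <- annotation$gene[m]
        ctGene <- counts$gene
        ctGene[ctGene %in% c("", "NA", "-")] <- NA_character_
        mismatch <- which(!is.na(ctGene) & !is.na(annGene) &
                          ctGene != annGene)
        mismatch <- c(mismatch, which(xor(is.na(ctGene), is.na(annGene))))
        if (length(mismatch))
            stop("gene column disagrees with annotation for sgRNA(s): ",
                 paste(counts$sgRNA[sort(unique(mismatch))], collapse = ", "))
        mat <- as.matrix(counts[, setdiff(colnames(counts),
                                          c("sgRNA", "gene")), drop = FALSE])
        rownames(mat) <- counts$sgRNA
    } else {
        mat <- as.matrix(counts)
        if (is.null(rownames(mat)) || is.null(colnames(mat)))
            stop("count matrix needs sgRNA rownames and sample colnames")
        if (!all(rownames(mat) %in% annotation$sgrna))
            stop("sgRNA(s) in counts missing from annotation: ",
                 paste(setdiff(rownames(mat), annotation$sgrna),
                       collapse = ", "))
    }
    storage.mode(mat) <- "integer"
    missing <- setdiff(annotation$sgrna, rownames(mat))
    if (length(missing)) {
        warning(length(missing),
                " annotated sgRNA(s) absent from counts; added as zeros")
        zero <- matrix(0L, length(missing), ncol(mat),
                       dimnames = list(missing, colnames(mat)))
        mat <- rbind(mat, zero)
    }
    mat <- mat[annotation$sgrna, , drop = FALSE]
    if (is.null(names(roles)) || !setequal(names(roles), colnames(mat)))
        stop("roles must name every sample: ",
             paste(colnames(mat), collapse = ", "))
    rd <- S4Vectors::DataFrame(
        gene = annotation$gene,
        controlClass = annotation$control_class,
        coreEssential = annotation$core_essential,
        row.names = annotation$sgrna)
    cd <- S4Vectors::DataFrame(role = unname(roles[colnames(mat)]),
                               row.names = colnames(mat))
    se <- SummarizedExperiment(assays = list(counts = mat),
                               rowData = rd, colData = cd)
    new("ScreenExperiment", se)
}

#' Write and read a gene score table
#'
#' `writeScoreTable()` serializes the per-gene table of a [GeneScores]
#' object (or a bare score `DataFrame`/`data.frame`) as a tab-separated
#' file sorted by selective-essentiality z ascending, numeric values at
#' 10 significant digits. `readScoreTable()` reads such a file back.
#'
#' @param scores a [GeneScores] object or its score table.
#' @param path output (input) file path.
#' @return `writeScoreTable()` returns `path` invisibly;
#'   `readScoreTable()` a `data.frame`.
#' @export
writeScoreTable <- function(scores, path) {
    tab <- if (is(scores, "GeneScores")) scoreTable(scores) else scores
    tab <- as.data.frame(tab)
    tab <- tab[order(tab$selectiveZ, tab$gene), , drop = FALSE]
    out <- data.frame(
        gene = tab$gene,
        n_sgrnas = tab$nSgRNAs,
        raw_control = sprintf("%.10g", tab$rawControl),
        raw_treated = sprintf("%.10g", tab$rawTreated),
        scaled_control = sprintf("%.10g", tab$scaledControl),
        scaled_treated = sprintf("%.10g", tab$scaledTreated),
        selective_z = sprintf("%.10g", tab$selectiveZ),
        category = tab$category,
        stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}
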