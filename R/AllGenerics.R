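#' Accessors for screen result and simulation objects
#'
#' `scoreTable()` returns the per-gene score `DataFrame` of a
#' [GeneScores] object; `sgRNAScores()` the per-sgRNA log2 fold-changes;
#' `anchors()` the per-arm reference medians; `filterTallies()` the
#' filter counts. `geneTruth()`, `sgRNATruth()` and `simConfig()` expose
#' the planted truth and configuration of a [SimulatedScreen].
#'
#' @param x a [GeneScores] or [SimulatedScreen] object.
#' @return the requested component (see Description).
#' @name accessors
#' @aliases scoreTable anchors sgRNAScores filterTallies geneTruth
#'   sgRNATruth simConfig screen
NULL

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))
#' @rdname accessors
#' @export
setGeneric("sgRNAScores", function(x) standardGeneric("sgRNAScores"))
#' @rdname accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @rdname accessors
#' @export
setGeneric("filterTallies", function(x) standardGeneric("filterTallies"))
#' @rdname accessors
#' @export
setGeneric("geneTruth", function(x) standardGeneric("geneTruth"))
#' @rdname accessors
#' @export
setGeneric("sgRNATruth", function(x) standardGeneric("sgRNATruth"))
#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))
#' @rdname accessors
#' @export
setGeneric("screen", function(x) standardGeneric("screen"))

#' @rdname accessors
setMethod("scoreTable", "GeneScores", function(x) x@table)
#' @rdname accessors
setMethod("sgRNAScores", "GeneScores", function(x) x@sgRNAScores)
#' @rdname accessors
setMethod("anchors", "GeneScores", function(x) x@anchors)
#' @rdname accessors
setMethod("filterTallies", "GeneScores", function(x) x@tallies)
#' @rdname accessors
setMethod("geneTruth", "SimulatedScreen", function(x) x@geneTruth)
#' @rdname accessors
setMethod("sgRNATruth", "SimulatedScreen", function(x) x@sgRNATruth)
#' @rdname accessors
setMethod("simConfig", "SimulatedScreen", function(x) x@config)
#' @rdname accessors
setMethod("screen", "SimulatedScreen", function(x) x@screen)

setMethod("show", "ScreenExperiment", function(object) {
    rd <- rowData(object)
    cat("ScreenExperiment:", nrow(object), "sgRNAs x", ncol(object),
        "samples\n")
    cat("  targeting:", sum(rd$controlClass == "targeting"),
        "| non-targeting:", sum(rd$controlClass == "non_targeting"),
        "| core-essential genes:",
        length(unique(rd$gene[rd$coreEssential & !is.na(rd$gene)])), "\n")
    cat("  roles:", paste(sprintf("%s=%s", colnames(object),
                                  colData(object)$role), collapse = ", "),
        "\n")
})

setMethod("show", "GeneScores", function(object) {
    tab <- object@table
    cat("GeneScores:", nrow(tab), "genes,",
        nrow(object@sgRNAScores), "sgRNAs\n")
    if (nrow(tab)) {
        cat("  categories:",
            paste(sprintf("%s=%d", names(table(tab$category)),
                          as.integer(table(tab$category))), collapse = ", "),
            "\n")
    }
    a <- object@anchors
    for (arm in names(a))
        cat(sprintf("  anchors[%s]: non-targeting %.4f, core-essential %.4f\n",
                    arm, a[[arm]]["nontargeting"], a[[arm]]["coreEssential"]))
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes x", object@sgRNAsPerGene,
        "sgRNAs +", object@nNonTargeting, "non-targeting\n")
    cat(sprintf("  core-essential %d, selective %d (f=%.2f), sensitizing %d (f=%.2f)\n",
                object@nCoreEssential, object@nSelective,
                object@selectiveEffect, object@nSensitizing,
                object@sensitizingEffect))
    cat(sprintf("  g=%.1f doublings, depth %.0f reads/sgRNA, overdispersion %.2f, seed %d\n",
                object@generations, object@depth, object@overdispersion,
                object@seed))
})

setMethod("show", "SimulatedScreen", function(object) {
    cat("SimulatedScreen (seed", object@config@seed, ")\n")
    show(object@screen)
})
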