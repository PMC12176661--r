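#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- rowData colData assayNames
NULL

.SAMPLE_ROLES <- c("initial", "final_control", "final_treated")
.CONTROL_CLASSES <- c("targeting", "non_targeting")
.CATEGORIES <- c("selectively_lethal", "sensitizing_enriched",
                 "essential_both", "neutral")

#' Container for a pooled CRISPR screen
#'
#' `ScreenExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with the row and column metadata a two-arm knockout screen needs: a
#' `"counts"` assay of non-negative integer sgRNA read counts, per-sgRNA
#' library annotation (target gene, control class, core-essential reference
#' flag) in `rowData`, and a sample `role` column (`"initial"`,
#' `"final_control"` or `"final_treated"`) in `colData`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [ScreenExperiment()] for the validating constructor,
#'   [scoreScreen()] for the scoring pipeline.
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    cts <- assay(object, "counts")
    if (anyNA(cts) || any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be non-negative integers")
    rd <- rowData(object)
    need <- c("gene", "controlClass", "coreEssential")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "sgRNA ids (rownames) must be unique")
    if (!all(rd$controlClass %in% .CONTROL_CLASSES))
        msg <- c(msg, "controlClass must be 'targeting' or 'non_targeting'")
    nt <- rd$controlClass == "non_targeting"
    if (any(!is.na(rd$gene[nt])))
        msg <- c(msg, "non-targeting sgRNAs must not carry a gene id")
    if (any(is.na(rd$gene[!nt]) | rd$gene[!nt] == ""))
        msg <- c(msg, "targeting sgRNAs must carry exactly one gene id")
    if (any(rd$coreEssential[nt]))
        msg <- c(msg, "coreEssential applies only to targeting sgRNAs")
    if (!"role" %in% colnames(colData(object)))
        return("colData must contain a 'role' column")
    role <- colData(object)$role
    if (!all(role %in% .SAMPLE_ROLES))
        msg <- c(msg, paste("sample roles must be one of:",
                            paste(.SAMPLE_ROLES, collapse = ", ")))
    if (sum(role == "initial") != 1)
        msg <- c(msg, "exactly one sample must have role 'initial'")
    if (length(msg)) msg else TRUE
})

#' Scored gene table of a selective-essentiality screen
#'
#' Result container of [scoreScreen()]. Holds the per-gene score table
#' (raw and scaled gene fitness scores in both arms, the selective
#' essentiality z-score and a hit category), the per-sgRNA log2
#' fold-changes, the reference anchors (non-targeting and core-essential
#' medians per arm) and the filter tallies of the run.
#'
#' @slot table `DataFrame`, one row per scored gene.
#' @slot sgRNAScores `DataFrame`, one row per surviving sgRNA.
#' @slot anchors named list, per arm, of the non-targeting and
#'   core-essential median sgRNA log2 fold-changes (log2 units).
#' @slot tallies named list of filter counts (sgRNAs/genes removed).
#' @slot params named list of the thresholds the run used.
#' @seealso [scoreTable()], [anchors()], [sgRNAScores()],
#'   [writeScoreTable()].
#' @export
setClass("GeneScores",
    representation(table = "DataFrame", sgRNAScores = "DataFrame",
                   anchors = "list", tallies = "list", params = "list"))

setValidity("GeneScores", function(object) {
    tab <- object@table
    need <- c("gene", "nSgRNAs", "rawControl", "rawTreated",
              "scaledControl", "scaledTreated", "selectiveZ", "category")
    if (!all(need %in% colnames(tab)))
        return(paste("table must contain:", paste(need, collapse = ", ")))
    if (nrow(tab) && !all(tab$category %in% .CATEGORIES))
        return("unknown hit category")
    TRUE
})

#' Configuration of the synthetic screen generator
#'
#' Parameters of the generative model behind [simulateScreen()]: library
#' structure (metabolic-style gene set, non-targeting controls,
#' core-essential reference genes), planted per-arm fitness effects,
#' per-sgRNA efficacies, population doublings, sequencing depth and count
#' noise. The defaults describe the two-arm vehicle/drug design the
#' simulator emulates; [simPreset()] bundles the scenarios used throughout
#' the package.
#'
#' @slot nGenes number of targeted genes.
#' @slot sgRNAsPerGene guides per gene (default 8).
#' @slot nNonTargeting number of non-targeting control sgRNAs.
#' @slot nCoreEssential number of core-essential reference genes.
#' @slot nSelective number of planted selectively-lethal genes (depleted
#'   in the drug arm only).
#' @slot nSensitizing number of planted sensitizing genes (enriched in
#'   the drug arm).
#' @slot selectiveEffect drug-arm fitness effect of selective genes
#'   (dimensionless growth-rate modifier, negative = depletion).
#' @slot sensitizingEffect drug-arm fitness effect of sensitizing genes.
#' @slot essentialEffect both-arm fitness effect of core-essential genes.
#' @slot generations population doublings per arm.
#' @slot depth expected reads per sgRNA per sample.
#' @slot overdispersion count-noise parameter; 0 gives multinomial
#'   sampling, larger values gamma-overdispersed multinomial.
#' @slot initialSdLog log-sd of the log-normal initial sgRNA abundances.
#' @slot efficacyShape1,efficacyShape2 Beta parameters of per-sgRNA
#'   efficacy (mode near 1).
#' @slot seed integer RNG seed; a fixed seed gives identical output.
#' @export
setClass("SimConfig",
    representation(nGenes = "integer", sgRNAsPerGene = "integer",
                   nNonTargeting = "integer", nCoreEssential = "integer",
                   nSelective = "integer", nSensitizing = "integer",
                   selectiveEffect = "numeric", sensitizingEffect = "numeric",
                   essentialEffect = "numeric", generations = "numeric",
                   depth = "numeric", overdispersion = "numeric",
                   initialSdLog = "numeric",
                   efficacyShape1 = "numeric", efficacyShape2 = "numeric",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L || object@sgRNAsPerGene < 1L)
        msg <- c(msg, "nGenes and sgRNAsPerGene must be positive")
    if (object@nNonTargeting < 0L || object@nCoreEssential < 0L)
        msg <- c(msg, "library part sizes must be non-negative")
    if (object@nCoreEssential + object@nSelective + object@nSensitizing >
        object@nGenes)
        msg <- c(msg, "planted gene classes exceed nGenes")
    if (object@depth <= 0) msg <- c(msg, "depth must be positive")
    if (object@overdispersion < 0)
        msg <- c(msg, "overdispersion must be >= 0")
    if (object@generations < 0)
        msg <- c(msg, "generations must be >= 0")
    if (object@efficacyShape1 <= 0 || object@efficacyShape2 <= 0)
        msg <- c(msg, "efficacy Beta shapes must be positive")
    if (length(msg)) msg else TRUE
})

#' A simulated screen with its ground truth
#'
#' Return value of [simulateScreen()]: the simulated
#' [ScreenExperiment] plus the planted truth — per-gene arm fitness
#' effects and category, per-sgRNA efficacy and realized initial
#' abundance — and the generating [SimConfig].
#'
#' @slot screen the simulated `ScreenExperiment`.
#' @slot geneTruth `DataFrame`: gene, fControl, fTreated, coreEssential,
#'   category.
#' @slot sgRNATruth `DataFrame`: sgrna, gene, efficacy,
#'   initialAbundance.
#' @slot config the generating `SimConfig`.
#' @export
setClass("SimulatedScreen",
    representation(screen = "ScreenExperiment", geneTruth = "DataFrame",
                   sgRNATruth = "DataFrame", config = "SimConfig"))
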