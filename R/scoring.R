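#' Filter sgRNAs on initial-population representation
#'
#' Removes sgRNAs whose read count in the designated initial sample is
#' below `minInitial` (default 100), the standard guard against guides
#' too poorly represented at the start of the screen to measure
#' depletion. The removal tally is recorded in `metadata(se)$tallies`.
#'
#' @param se a [ScreenExperiment] with one `initial` sample.
#' @param minInitial minimum initial read count to retain a guide.
#' @return the filtered `ScreenExperiment`.
#' @export
filterSgRNAs <- function(se, minInitial = 100) {
    init <- initialSample(se)
    keep <- assay(se, "counts")[, init] >= minInitial
    out <- se[keep, ]
    md <- metadata(se)
    md$tallies$sgRNAsRemovedLowInitial <- sum(!keep)
    md$tallies$minInitial <- minInitial
    metadata(out) <- md
    out
}

#' Filter genes on surviving sgRNA support
#'
#' After the initial-count filter, removes all guides of genes left with
#' fewer than `minSgRNAs` distinct surviving guides (default 6), so that
#' gene scores rest on adequate sgRNA support. Non-targeting sgRNAs have
#' no gene and are never removed by this filter.
#'
#' @param se a [ScreenExperiment], typically after [filterSgRNAs()].
#' @param minSgRNAs minimum surviving guides per gene.
#' @return the filtered `ScreenExperiment`; the number of removed genes
#'   is added to `metadata(se)$tallies`.
#' @export
filterGenes <- function(se, minSgRNAs = 6) {
    rd <- rowData(se)
    targeting <- rd$controlClass == "targeting"
    support <- table(rd$gene[targeting])
    lowGenes <- names(support)[support < minSgRNAs]
    keep <- !targeting | !(rd$gene %in% lowGenes)
    out <- se[keep, ]
    md <- metadata(se)
    md$tallies$genesRemovedLowSupport <- length(lowGenes)
    md$tallies$sgRNAsRemovedLowSupport <- sum(!keep)
    md$tallies$minSgRNAs <- minSgRNAs
    metadata(out) <- md
    out
}

#' Pseudocount-normalized relative sgRNA abundances
#'
#' Adds an `"abundance"` assay: per sample, each sgRNA's count plus a
#' pseudocount of one, divided by the sample total of those
#' pseudocounted counts. Every column is a proper probability
#' distribution (sums to 1) and strictly positive, so downstream log2
#' fold-changes are always defined.
#'
#' @param se a [ScreenExperiment] (filters applied).
#' @return `se` with an added `"abundance"` assay.
#' @export
normalizeAbundance <- function(se) {
    cts <- assay(se, "counts")
    if (nrow(cts) == 0L) stop("no sgRNAs left to normalize")
    pc <- cts + 1
    assay(se, "abundance") <- sweep(pc, 2L, colSums(pc), "/")
    se
}

initialSample <- function(se) {
    init <- colnames(se)[colData(se)$role == "initial"]
    if (length(init) != 1L)
        stop("exactly one sample with role 'initial' is required")
    init
}

armSamples <- function(se, arm = c("control", "treated")) {
    arm <- match.arg(arm)
    role <- paste0("final_", arm)
    smp <- colnames(se)[colData(se)$role == role]
    if (!length(smp)) stop("no sample with role '", role, "'")
    smp
}

#' Per-sgRNA log2 fold-change between final and initial populations
#'
#' The sgRNA enrichment/depletion score: log2 of the ratio of
#' pseudocount-normalized abundances, final over initial. With several
#' final samples in an arm, per-sample log2 fold-changes against the
#' shared initial sample are averaged at the sgRNA level.
#'
#' @param se a [ScreenExperiment]; the `"abundance"` assay is computed
#'   if absent.
#' @param finalSamples character vector of final sample id(s).
#' @param initialSample initial sample id (defaults to the designated
#'   initial sample).
#' @return named numeric vector of log2 fold-changes (log2 units), one
#'   per sgRNA.
#' @export
sgRNALfc <- function(se, finalSamples, initialSample = NULL) {
    if (!"abundance" %in% assayNames(se)) se <- normalizeAbundance(se)
    if (is.null(initialSample)) initialSample <- initialSample(se)
    ab <- assay(se, "abundance")
    miss <- setdiff(c(finalSamples, initialSample), colnames(ab))
    if (length(miss)) stop("sample(s) not found: ",
                           paste(miss, collapse = ", "))
    lfc <- log2(ab[, finalSamples, drop = FALSE] / ab[, initialSample])
    rowMeans(lfc)
}

#' Gene scores as the mean log2 fold-change of a gene's guides
#'
#' @param lfc named per-sgRNA log2 fold-change vector (from
#'   [sgRNALfc()]).
#' @param se the [ScreenExperiment] the lfc was computed on (supplies
#'   the sgRNA-to-gene map).
#' @return `DataFrame` with `gene`, `nSgRNAs` and `score` (mean log2
#'   fold-change over the gene's surviving guides), sorted by gene id.
#' @export
geneScore <- function(lfc, se) {
    rd <- rowData(se)[names(lfc), , drop = FALSE]
    targeting <- rd$controlClass == "targeting"
    stopifnot(all(!is.na(rd$gene[targeting])))
    g <- rd$gene[targeting]
    v <- lfc[targeting]
    score <- tapply(v, g, mean)
    n <- as.integer(table(g)[names(score)])
    S4Vectors::DataFrame(gene = names(score), nSgRNAs = n,
                         score = as.numeric(score))
}

#' Reference anchors: medians of non-targeting and core-essential guides
#'
#' Computes, on the sgRNA-level log2 fold-changes of one arm, the median
#' over non-targeting sgRNAs (the neutral reference, scaled to 0) and
#' the median over sgRNAs targeting core-essential genes (the
#' full-depletion reference, scaled to -1). An even-length reference set
#' uses the midpoint of the two central values. The screen's internal
#' control requires the non-targeting median to exceed the
#' core-essential median; otherwise scaling is refused.
#'
#' @param lfc named per-sgRNA log2 fold-change vector.
#' @param se the [ScreenExperiment] supplying the reference flags.
#' @param minReference minimum surviving sgRNAs per reference class
#'   (default 10).
#' @return named numeric vector `c(nontargeting=, coreEssential=)` in
#'   log2 units.
#' @export
computeAnchors <- function(lfc, se, minReference = 10) {
    rd <- rowData(se)[names(lfc), , drop = FALSE]
    nt <- rd$controlClass == "non_targeting"
    ce <- rd$controlClass == "targeting" & rd$coreEssential
    if (sum(nt) < minReference)
        stop("too few surviving non-targeting sgRNAs (", sum(nt),
             " < ", minReference, ")")
    if (sum(ce) < minReference)
        stop("too few surviving core-essential sgRNAs (", sum(ce),
             " < ", minReference, ")")
    a <- c(nontargeting = stats::median(lfc[nt]),
           coreEssential = stats::median(lfc[ce]))
    if (a["nontargeting"] <= a["coreEssential"])
        stop("non-targeting median (", signif(a[1], 4),
             ") not above core-essential median (", signif(a[2], 4),
             "): screen failed its internal control")
    a
}

#' Scale scores to the non-targeting / core-essential reference frame
#'
#' Affine map sending the non-targeting anchor to 0 and the
#' core-essential anchor to -1:
#' `(x - median_nt) / (median_nt - median_ce)`. Applied to gene scores
#' for reporting and to sgRNA-level log2 fold-changes for the anchoring
#' diagnostics.
#'
#' @param x numeric scores in log2 units.
#' @param anchors anchors from [computeAnchors()].
#' @return dimensionless scaled scores (0 = neutral, -1 =
#'   core-essential depletion).
#' @export
scaleScores <- function(x, anchors) {
    span <- anchors[["nontargeting"]] - anchors[["coreEssential"]]
    if (!is.finite(span) || span <= 0)
        stop("invalid anchors: non-targeting median must exceed ",
             "core-essential median")
    (x - anchors[["nontargeting"]]) / span
}

#' Selective-essentiality z-score
#'
#' The z-scored difference of scaled gene scores, drug-treated minus
#' vehicle control, over all scored genes: strongly negative values mark
#' genes selectively required under treatment (synthetic-lethal
#' candidates), strongly positive values genes whose loss sensitizes to
#' the vehicle arm only (enriched under drug). The default uses the
#' plain sample mean and standard deviation; `robust = TRUE` substitutes
#' median and MAD.
#'
#' @param scaledTreated,scaledControl scaled gene scores on the same
#'   gene set (same order).
#' @param robust use median/MAD instead of mean/sd.
#' @return numeric z-scores; with the default scaling these have mean 0
#'   and sample standard deviation 1 over the scored genes.
#' @export
selectiveEssentiality <- function(scaledTreated, scaledControl,
                                  robust = FALSE) {
    if (length(scaledTreated) != length(scaledControl))
        stop("arms must be scored on the identical gene set")
    d <- scaledTreated - scaledControl
    ctr <- if (robust) stats::median(d) else mean(d)
    scl <- if (robust) stats::mad(d) else stats::sd(d)
    if (!is.finite(scl) || scl == 0)
        stop("zero spread in score differences: degenerate screen")
    (d - ctr) / scl
}

#' Categorize genes from scaled scores and selective z
#'
#' Rule order: a gene scaled at or below `essentialCut` in both arms is
#' `essential_both` (required regardless of treatment, so not a
#' selective hit whatever its z); otherwise `selectively_lethal` if
#' `selectiveZ <= -zCut`, `sensitizing_enriched` if
#' `selectiveZ >= zCut`, else `neutral`.
#'
#' @param tab `DataFrame`/`data.frame` with `scaledControl`,
#'   `scaledTreated`, `selectiveZ`.
#' @param zCut selective-z cut-off (default 2).
#' @param essentialCut scaled-score cut-off for essential-in-both
#'   (default -0.5).
#' @return `tab` with a `category` column added.
#' @export
classifyGenes <- function(tab, zCut = 2, essentialCut = -0.5) {
    cat <- rep("neutral", nrow(tab))
    cat[tab$selectiveZ >= zCut] <- "sensitizing_enriched"
    cat[tab$selectiveZ <= -zCut] <- "selectively_lethal"
    both <- tab$scaledControl <= essentialCut &
            tab$scaledTreated <= essentialCut
    cat[both] <- "essential_both"
    tab$category <- cat
    tab
}

#' Rank-plot table of selective essentiality
#'
#' Orders scored genes by selective z ascending (most selectively lethal
#' first), breaking ties lexicographically by gene id, and attaches
#' ranks `1..G` — the table behind a gene-enrichment rank plot of
#' differential sgRNA representation.
#'
#' @param scores a [GeneScores] object or its score table.
#' @return `data.frame` with `rank`, `gene`, `selectiveZ`, `category`.
#' @export
rankPlotData <- function(scores) {
    tab <- if (is(scores, "GeneScores")) scoreTable(scores) else scores
    tab <- as.data.frame(tab)
    ord <- order(tab$selectiveZ, tab$gene)
    data.frame(rank = seq_len(nrow(tab)), gene = tab$gene[ord],
               selectiveZ = tab$selectiveZ[ord],
               category = tab$category[ord], stringsAsFactors = FALSE)
}

#' Top selective hits in each tail
#'
#' @param scores a [GeneScores] object or its score table.
#' @param n list size per tail.
#' @return list with `depleted` (most negative selective z first) and
#'   `enriched` (most positive first) character vectors of gene ids.
#' @export
topHits <- function(scores, n = 30) {
    tab <- if (is(scores, "GeneScores")) scoreTable(scores) else scores
    tab <- as.data.frame(tab)
    ord <- order(tab$selectiveZ, tab$gene)
    list(depleted = utils::head(tab$gene[ord], n),
         enriched = utils::head(tab$gene[rev(ord)], n))
}

#' Score a two-arm screen end to end
#'
#' Runs the full selective-essentiality pipeline on a
#' [ScreenExperiment]: initial-count filter, gene-support filter,
#' pseudocount normalization, per-sgRNA log2 fold-change per arm
#' (replicate finals averaged at sgRNA level), gene scores as mean lfc,
#' reference anchoring on non-targeting (0) and core-essential (-1)
#' sgRNA medians, scaling, the z-scored treated-minus-control
#' difference, and hit categorization.
#'
#' @param se a [ScreenExperiment] with an initial sample and at least
#'   one `final_control` and one `final_treated` sample.
#' @inheritParams filterSgRNAs
#' @inheritParams filterGenes
#' @inheritParams computeAnchors
#' @inheritParams classifyGenes
#' @param robust use median/MAD for the selective z (see
#'   [selectiveEssentiality()]).
#' @return a [GeneScores] object.
#' @examples
#' sim <- simulateScreen(simPreset("small", seed = 1))
#' gs <- scoreScreen(screen(sim))
#' gs
#' head(as.data.frame(scoreTable(gs)))
#' @export
scoreScreen <- function(se, minInitial = 100, minSgRNAs = 6,
                        minReference = 10, zCut = 2, essentialCut = -0.5,
                        robust = FALSE) {
    stopifnot(is(se, "ScreenExperiment"))
    validObject(se)
    se <- filterSgRNAs(se, minInitial = minInitial)
    se <- filterGenes(se, minSgRNAs = minSgRNAs)
    se <- normalizeAbundance(se)

    lfcC <- sgRNALfc(se, armSamples(se, "control"))
    lfcT <- sgRNALfc(se, armSamples(se, "treated"))
    anch <- list(control = computeAnchors(lfcC, se, minReference),
                 treated = computeAnchors(lfcT, se, minReference))

    gsC <- geneScore(lfcC, se)
    gsT <- geneScore(lfcT, se)
    stopifnot(identical(gsC$gene, gsT$gene))

    tab <- S4Vectors::DataFrame(
        gene = gsC$gene, nSgRNAs = gsC$nSgRNAs,
        rawControl = gsC$score, rawTreated = gsT$score,
        scaledControl = scaleScores(gsC$score, anch$control),
        scaledTreated = scaleScores(gsT$score, anch$treated))
    tab$selectiveZ <- selectiveEssentiality(tab$scaledTreated,
                                            tab$scaledControl,
                                            robust = robust)
    tab <- classifyGenes(tab, zCut = zCut, essentialCut = essentialCut)

    rd <- rowData(se)
    sg <- S4Vectors::DataFrame(
        sgrna = rownames(se), gene = rd$gene,
        controlClass = rd$controlClass, coreEssential = rd$coreEssential,
        lfcControl = lfcC, lfcTreated = lfcT,
        scaledControl = scaleScores(lfcC, anch$control),
        scaledTreated = scaleScores(lfcT, anch$treated))

    new("GeneScores", table = tab, sgRNAScores = sg, anchors = anch,
        tallies = metadata(se)$tallies,
        params = list(minInitial = minInitial, minSgRNAs = minSgRNAs,
                      minReference = minReference, zCut = zCut,
                      essentialCut = essentialCut, robust = robust))
}
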