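suppressPackageStartupMessages(library(SummarizedExperiment))

# Build a small ScreenExperiment directly from a count matrix and an
# annotation data.frame; defaults give a 3-sample two-arm design.
toyScreen <- function(counts, annotation,
                      roles = c(initial = "initial",
                                final_dmso = "final_control",
                                final_drug = "final_treated")) {
    ScreenExperiment(counts, annotation, roles)
}

# Annotation for nGenes genes x perGene guides + nNT non-targeting,
# with the first nCE genes flagged core-essential.
toyAnnotation <- function(nGenes, perGene, nNT = 0, nCE = 0) {
    genes <- sprintf("G%02d", seq_len(nGenes))
    data.frame(
        sgrna = c(paste0(rep(genes, each = perGene), "_sg",
                         rep(seq_len(perGene), nGenes)),
                  if (nNT) sprintf("NT_%02d", seq_len(nNT))),
        gene = c(rep(genes, each = perGene),
                 rep(NA_character_, nNT)),
        control_class = rep(c("targeting", "non_targeting"),
                            c(nGenes * perGene, nNT)),
        core_essential = c(rep(genes %in% genes[seq_len(nCE)],
                               each = perGene), rep(FALSE, nNT)),
        stringsAsFactors = FALSE)
}

# Independent straight-line reimplementation of the scoring formulas,
# written directly from their definitions: initial-count filter, gene
# support filter, pseudocount abundance, log2 fold-change, mean gene
# score, reference medians, affine scaling, z-scored difference. Used
# as the oracle the pipeline is checked against.
oracleScore <- function(cts, ann, minInitial = 100, minSgRNAs = 6) {
    stopifnot(identical(rownames(cts), ann$sgrna))
    keep <- cts[, "initial"] >= minInitial
    cts <- cts[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
    tg <- ann$control_class == "targeting"
    supp <- table(ann$gene[tg])
    bad <- names(supp)[supp < minSgRNAs]
    keep2 <- !tg | !(ann$gene %in% bad)
    cts <- cts[keep2, , drop = FALSE]
    ann <- ann[keep2, , drop = FALSE]

    ab <- apply(cts + 1, 2, function(x) x / sum(x))
    lfc <- list(control = log2(ab[, "final_dmso"] / ab[, "initial"]),
                treated = log2(ab[, "final_drug"] / ab[, "initial"]))
    tg <- ann$control_class == "targeting"
    nt <- ann$control_class == "non_targeting"
    ce <- tg & ann$core_essential
    res <- list()
    for (arm in names(lfc)) {
        v <- lfc[[arm]]
        gscore <- tapply(v[tg], ann$gene[tg], mean)
        mNT <- median(v[nt]); mCE <- median(v[ce])
        res[[arm]] <- (gscore - mNT) / (mNT - mCE)
    }
    stopifnot(identical(names(res$control), names(res$treated)))
    d <- res$treated - res$control
    z <- (d - mean(d)) / sd(d)
    list(gene = names(d), scaledControl = as.numeric(res$control),
         scaledTreated = as.numeric(res$treated), z = as.numeric(z))
}
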