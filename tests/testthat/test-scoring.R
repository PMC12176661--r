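# Screen with hand-chosen initial counts: 10 targeting sgRNAs over 2
# genes plus 2 non-targeting; three guides sit below the default
# initial-count threshold.
filterFixture <- function() {
    ann <- toyAnnotation(2, 5, nNT = 2, nCE = 1)
    init <- c(99L, 100L, 150L, 200L, 250L,   # G01: one guide below 100
              98L, 97L, 300L, 400L, 500L,    # G02: two below
              50L, 120L)                     # non-targeting
    cts <- cbind(initial = init, final_dmso = rep(100L, 12),
                 final_drug = rep(100L, 12))
    rownames(cts) <- ann$sgrna
    toyScreen(cts, ann)
}

test_that("initial-count filter removes exactly the under-covered guides", {
    se <- filterFixture()
    f <- filterSgRNAs(se, minInitial = 100)
    expect_equal(nrow(f), 8L)
    expect_equal(metadata(f)$tallies$sgRNAsRemovedLowInitial, 4L)
    # boundary: 99 removed, 100 retained
    expect_false("G01_sg1" %in% rownames(f))
    expect_true("G01_sg2" %in% rownames(f))
    # non-targeting guides are subject to this filter too
    expect_false("NT_01" %in% rownames(f))
    # minInitial = 0 is the identity
    expect_identical(rownames(filterSgRNAs(se, 0)), rownames(se))
})

test_that("gene-support filter drops whole genes, never non-targeting", {
    se <- filterSgRNAs(filterFixture(), 100)
    # G01 has 4 surviving guides, G02 has 3, NT_02 survives
    f <- filterGenes(se, minSgRNAs = 4)
    expect_setequal(unique(na.omit(rowData(f)$gene)), "G01")
    expect_true("NT_02" %in% rownames(f))
    expect_equal(metadata(f)$tallies$genesRemovedLowSupport, 1L)
    # minSgRNAs = 1 is the identity on targeting guides
    expect_identical(rownames(filterGenes(se, 1)), rownames(se))
    # {6, 6, 4} surviving guides at the default threshold -> 12 rows
    ann <- toyAnnotation(3, 6)
    cts <- cbind(initial = c(rep(200L, 12), 200L, 200L, 200L, 200L,
                             10L, 10L),
                 final_dmso = 100L, final_drug = 100L)
    rownames(cts) <- ann$sgrna
    se2 <- filterGenes(filterSgRNAs(suppressWarnings(toyScreen(cts, ann)), 100), 6)
    expect_equal(nrow(se2), 12L)
    expect_setequal(unique(rowData(se2)$gene), c("G01", "G02"))
})

test_that("pseudocount abundances form proper per-sample distributions", {
    ann <- toyAnnotation(1, 3)
    cts <- cbind(initial = c(1L, 3L, 0L), final_dmso = c(0L, 0L, 2L),
                 final_drug = c(5L, 5L, 5L))
    rownames(cts) <- ann$sgrna
    se <- normalizeAbundance(suppressWarnings(toyScreen(cts, ann)))
    ab <- assay(se, "abundance")
    expect_equal(unname(ab[, "initial"]), c(2, 4, 1) / 7)
    expect_equal(unname(ab[, "final_dmso"]), c(1, 1, 3) / 5)
    # all counts equal -> uniform
    expect_equal(unname(ab[, "final_drug"]), rep(1 / 3, 3))
    expect_equal(unname(colSums(ab)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(ab > 0))
})

test_that("sgRNA log2 fold-changes follow abundance ratios", {
    ann <- toyAnnotation(1, 2)
    # pseudocounted fractions: initial {1/3, 2/3}, final {2/3, 1/3}
    cts <- cbind(initial = c(1L, 3L), final_dmso = c(3L, 1L),
                 final_drug = c(1L, 3L))
    rownames(cts) <- ann$sgrna
    se <- suppressWarnings(toyScreen(cts, ann))
    expect_equal(unname(sgRNALfc(se, "final_dmso")), c(1, -1))
    # identical sample -> 0 (and antisymmetry above)
    expect_equal(unname(sgRNALfc(se, "final_drug")), c(0, 0))
    expect_error(sgRNALfc(se, "nope"), "not found")
})

test_that("gene scores are plain means of surviving guide lfcs", {
    ann <- toyAnnotation(2, 6)
    cts <- cbind(initial = rep(100L, 12), final_dmso = rep(100L, 12),
                 final_drug = rep(100L, 12))
    rownames(cts) <- ann$sgrna
    se <- suppressWarnings(toyScreen(cts, ann))
    lfc <- setNames(c(-1, -2, -3, 0, 0, 0,
                      -1, -1, -1, -1, -1, 5), ann$sgrna)
    gs <- geneScore(lfc, se)
    expect_equal(gs$score[gs$gene == "G01"], -1)
    expect_equal(gs$score[gs$gene == "G02"], 0)  # outlier guide pulls to 0
    expect_equal(gs$nSgRNAs, c(6L, 6L))
})

test_that("reference anchors are class medians with guarded degeneracy", {
    ann <- toyAnnotation(1, 3, nNT = 3, nCE = 1)
    cts6 <- cbind(initial = rep(100L, 6), final_dmso = rep(100L, 6),
                  final_drug = rep(100L, 6))
    rownames(cts6) <- ann$sgrna
    se <- toyScreen(cts6, ann)
    lfc <- setNames(c(-2.0, -1.8, -1.6, 0.1, 0.2, 0.3), ann$sgrna)
    a <- computeAnchors(lfc, se, minReference = 3)
    expect_equal(unname(a), c(0.2, -1.8))
    # even-length reference set: midpoint of the two central values
    ann4 <- toyAnnotation(1, 4, nNT = 4, nCE = 1)
    cts8 <- cbind(initial = rep(100L, 8), final_dmso = rep(100L, 8),
                  final_drug = rep(100L, 8))
    rownames(cts8) <- ann4$sgrna
    se4 <- toyScreen(cts8, ann4)
    lfc4 <- setNames(c(-3, -2, -1, -0.5, 0.1, 0.2, 0.4, 0.8), ann4$sgrna)
    a4 <- computeAnchors(lfc4, se4, minReference = 4)
    expect_equal(unname(a4), c(0.3, -1.5))
    # too few reference guides names the class
    expect_error(computeAnchors(lfc, se, minReference = 4),
                 "non-targeting")
    # anchors equal (or inverted): screen failed its internal control
    flat <- setNames(rep(0.5, 6), ann$sgrna)
    expect_error(computeAnchors(flat, se, minReference = 3),
                 "internal control")
})

test_that("scaling maps the anchors to 0 and -1", {
    a <- c(nontargeting = 0.2, coreEssential = -1.8)
    expect_equal(scaleScores(0.2, a), 0)
    expect_equal(scaleScores(-1.8, a), -1)
    expect_equal(scaleScores(-0.8, a), -0.5)
    expect_error(scaleScores(0, c(nontargeting = -1, coreEssential = 0)),
                 "anchors")
})

test_that("selective z is an exact z-score of scaled differences", {
    z <- selectiveEssentiality(c(-2, 0, 2), c(0, 0, 0))
    expect_equal(z, c(-1, 0, 1))
    expect_error(selectiveEssentiality(c(1, 1, 1), c(1, 1, 1)),
                 "degenerate")
    set.seed(42)
    for (i in 1:5) {
        d <- rnorm(50)
        z <- selectiveEssentiality(d, numeric(50))
        expect_equal(mean(z), 0, tolerance = 1e-12)
        expect_equal(sd(z), 1, tolerance = 1e-12)
    }
    # robust variant centres on the median
    zr <- selectiveEssentiality(c(-10, 0, 0.1, -0.1, 0.2), numeric(5),
                                robust = TRUE)
    expect_equal(zr[2], 0)
})

test_that("hit categories follow the documented rule order", {
    tab <- data.frame(scaledControl = c(-1.2, 0.0, 0.1, 0.0),
                      scaledTreated = c(-1.1, -1.5, 0.4, 0.1),
                      selectiveZ = c(-4, -3, 3, 0.5))
    out <- classifyGenes(tab)
    # essential in both arms wins regardless of z
    expect_identical(out$category,
                     c("essential_both", "selectively_lethal",
                       "sensitizing_enriched", "neutral"))
})

test_that("rank tables are z-ordered with lexicographic tie-breaks", {
    tab <- data.frame(gene = c("B", "A", "C", "D"),
                      selectiveZ = c(0, 0, -1, 1),
                      category = "neutral")
    rp <- rankPlotData(tab)
    expect_equal(rp$rank, 1:4)
    expect_identical(rp$gene, c("C", "A", "B", "D"))
    expect_equal(nrow(rp), nrow(tab))
})

test_that("full pipeline matches the straight-line oracle", {
    sim <- simulateScreen(simPreset("small", seed = 11, nGenes = 50,
                                    sgRNAsPerGene = 6, nNonTargeting = 60,
                                    nCoreEssential = 10, nSelective = 8,
                                    depth = 400))
    se <- screen(sim)
    gs <- scoreScreen(se)
    ann <- as.data.frame(rowData(se))
    ann$sgrna <- rownames(se)
    ann$control_class <- ann$controlClass
    ann$core_essential <- ann$coreEssential
    orc <- oracleScore(assay(se, "counts"), ann)
    tab <- as.data.frame(scoreTable(gs))
    m <- match(orc$gene, tab$gene)
    expect_false(anyNA(m))
    expect_equal(tab$scaledControl[m], orc$scaledControl,
                 tolerance = 1e-10)
    expect_equal(tab$scaledTreated[m], orc$scaledTreated,
                 tolerance = 1e-10)
    expect_equal(tab$selectiveZ[m], orc$z, tolerance = 1e-10)
})

test_that("scores are invariant to sequencing depth rescaling", {
    sim <- simulateScreen(simPreset("small", seed = 3, depth = 1000))
    se <- screen(sim)
    lfc1 <- sgRNALfc(filterSgRNAs(se, 100), "final_drug")
    se2 <- se
    assay(se2, "counts")[, "final_drug"] <-
        assay(se2, "counts")[, "final_drug"] * 7L
    lfc2 <- sgRNALfc(filterSgRNAs(se2, 100), "final_drug")
    # discrepancy is pure pseudocount error, O(1/count) in the final count
    cts <- assay(filterSgRNAs(se, 100), "counts")[, "final_drug"]
    err <- abs(lfc1 - lfc2)
    expect_lt(max(err[cts >= 50]), 0.05)
    expect_lt(max(err[cts >= 500]), 0.005)
    # worst case (a zero-count guide) is bounded by the scale factor
    expect_lt(max(err), log2(7) + 1e-9)
})

test_that("reducing a gene's treated counts never raises its selective z", {
    sim <- simulateScreen(simPreset("small", seed = 5, depth = 500))
    se <- screen(sim)
    gene <- geneTruth(sim)$gene[geneTruth(sim)$category == "neutral"][1]
    rows <- which(!is.na(rowData(se)$gene) & rowData(se)$gene == gene)
    zAt <- function(shrink) {
        se2 <- se
        cts <- assay(se2, "counts")
        cts[rows, "final_drug"] <-
            as.integer(floor(cts[rows, "final_drug"] * shrink))
        assay(se2, "counts") <- cts
        tab <- as.data.frame(scoreTable(scoreScreen(se2)))
        tab$selectiveZ[tab$gene == gene]
    }
    zs <- vapply(c(1, 0.5, 0.2, 0.05), zAt, numeric(1))
    expect_true(all(diff(zs) < 1e-12))
})

test_that("scored gene z has mean 0 and sample sd 1 on simulated screens", {
    for (s in c(2, 9)) {
        gs <- scoreScreen(screen(simulateScreen(simPreset("small",
                                                          seed = s))))
        z <- scoreTable(gs)$selectiveZ
        expect_equal(mean(z), 0, tolerance = 1e-12)
        expect_equal(sd(z), 1, tolerance = 1e-12)
    }
})
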