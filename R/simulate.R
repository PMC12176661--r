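#' Construct a simulator configuration
#'
#' Builds a [SimConfig] for [simulateScreen()]. Defaults describe a
#' mid-sized two-arm (vehicle vs drug) knockout screen of a
#' metabolic-style library: 8 guides per gene, log-normally skewed
#' initial representation, Beta-distributed guide efficacies with mode
#' near 1, deterministic exponential growth with fitness entering the
#' doubling exponent, and multinomial sequencing noise.
#'
#' @param nGenes,sgRNAsPerGene,nNonTargeting library structure.
#' @param nCoreEssential core-essential reference genes (planted at
#'   `essentialEffect` in both arms).
#' @param nSelective,selectiveEffect selectively-lethal genes: fitness
#'   `selectiveEffect` in the drug arm, 0 in the vehicle arm.
#' @param nSensitizing,sensitizingEffect drug-arm enriched genes.
#' @param essentialEffect both-arm fitness of core-essential genes
#'   (-1 = no net doubling for a fully efficacious guide).
#' @param generations population doublings per arm.
#' @param depth expected reads per sgRNA per sample.
#' @param overdispersion 0 for multinomial counts; > 0 adds
#'   gamma-distributed abundance noise (variance `overdispersion` per
#'   unit mean) before multinomial draws.
#' @param initialSdLog log-sd of initial abundance skew.
#' @param efficacyShape1,efficacyShape2 Beta parameters of sgRNA
#'   efficacy in `[0, 1]`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a validated [SimConfig].
#' @export
SimConfig <- function(nGenes = 300, sgRNAsPerGene = 8, nNonTargeting = 200,
                      nCoreEssential = 40, nSelective = 20,
                      nSensitizing = 10, selectiveEffect = -0.4,
                      sensitizingEffect = 0.4, essentialEffect = -1,
                      generations = 8, depth = 500, overdispersion = 0,
                      initialSdLog = 0.5, efficacyShape1 = 10,
                      efficacyShape2 = 1.5, seed = 1) {
    new("SimConfig", nGenes = as.integer(nGenes),
        sgRNAsPerGene = as.integer(sgRNAsPerGene),
        nNonTargeting = as.integer(nNonTargeting),
        nCoreEssential = as.integer(nCoreEssential),
        nSelective = as.integer(nSelective),
        nSensitizing = as.integer(nSensitizing),
        selectiveEffect = selectiveEffect,
        sensitizingEffect = sensitizingEffect,
        essentialEffect = essentialEffect,
        generations = generations, depth = depth,
        overdispersion = overdispersion, initialSdLog = initialSdLog,
        efficacyShape1 = efficacyShape1, efficacyShape2 = efficacyShape2,
        seed = as.integer(seed))
}

#' Simulator presets
#'
#' Three bundled scenarios: `"small"` (24 genes x 6 guides + 30
#' non-targeting; fast fixtures and smoke tests), `"lowdose"` (300
#' genes x 8 guides, 14-day-style arm of ~8 doublings, moderate
#' selective effects) and `"highdose"` (longer 17-day-style arm of ~10
#' doublings with stronger selective effects).
#'
#' @param preset one of `"small"`, `"lowdose"`, `"highdose"`.
#' @param seed integer seed.
#' @param ... overrides passed to [SimConfig()].
#' @return a [SimConfig].
#' @export
simPreset <- function(preset = c("small", "lowdose", "highdose"),
                      seed = 1, ...) {
    preset <- match.arg(preset)
    base <- switch(preset,
        small = list(nGenes = 24, sgRNAsPerGene = 6, nNonTargeting = 30,
                     nCoreEssential = 4, nSelective = 4, nSensitizing = 2,
                     generations = 8, depth = 300),
        lowdose = list(nGenes = 300, sgRNAsPerGene = 8,
                       nNonTargeting = 200, nCoreEssential = 40,
                       nSelective = 20, nSensitizing = 10,
                       selectiveEffect = -0.4, generations = 8,
                       depth = 500),
        highdose = list(nGenes = 300, sgRNAsPerGene = 8,
                        nNonTargeting = 200, nCoreEssential = 40,
                        nSelective = 20, nSensitizing = 10,
                        selectiveEffect = -0.6, generations = 10,
                        depth = 500))
    args <- utils::modifyList(c(base, seed = seed), list(...))
    do.call(SimConfig, args)
}

simStructure <- function(config) {
    nG <- config@nGenes
    genes <- sprintf("GENE%04d", seq_len(nG))
    idx <- sample.int(nG)   # random placement of planted classes
    ce <- idx[seq_len(config@nCoreEssential)]
    rest <- idx[config@nCoreEssential + seq_len(nG - config@nCoreEssential)]
    sel <- rest[seq_len(config@nSelective)]
    sen <- rest[config@nSelective + seq_len(config@nSensitizing)]
    fC <- fT <- numeric(nG)
    fC[ce] <- fT[ce] <- config@essentialEffect
    fT[sel] <- config@selectiveEffect
    fT[sen] <- config@sensitizingEffect
    category <- rep("neutral", nG)
    category[ce] <- "essential_both"
    category[sel] <- "selectively_lethal"
    category[sen] <- "sensitizing_enriched"
    list(genes = genes, fControl = fC, fTreated = fT,
         coreEssential = seq_len(nG) %in% ce, category = category)
}

drawCounts <- function(p, total, overdispersion) {
    if (overdispersion > 0) {
        w <- stats::rgamma(length(p), shape = 1 / overdispersion,
                           rate = 1 / overdispersion)
        p <- p * w
        p <- p / sum(p)
    }
    as.integer(stats::rmultinom(1L, size = total, prob = p))
}

#' Simulate a two-arm pooled CRISPR screen with known ground truth
#'
#' Generates an initial population, a vehicle-control arm and a
#' drug-treated arm from one configuration. Initial sgRNA abundances are
#' log-normal; each arm grows deterministically for `generations`
#' doublings with per-sgRNA expected abundance proportional to
#' `p0 * 2^(g * (1 + e * f))`, where `e` is the guide's efficacy and `f`
#' the gene's arm fitness effect (0 for non-targeting guides); read
#' counts per sample are multinomial at the configured depth (optionally
#' gamma-overdispersed). Planted effects and realized efficacies are
#' returned as truth for parameter-recovery benchmarking.
#'
#' @param config a [SimConfig].
#' @return a [SimulatedScreen]; samples are `initial` (role
#'   `"initial"`), `final_dmso` (`"final_control"`) and `final_drug`
#'   (`"final_treated"`).
#' @examples
#' sim <- simulateScreen(simPreset("small", seed = 7))
#' sim
#' @export
simulateScreen <- function(config) {
    validObject(config)
    set.seed(config@seed)
    str <- simStructure(config)
    nT <- config@nGenes * config@sgRNAsPerGene
    sgGene <- rep(str$genes, each = config@sgRNAsPerGene)
    sgId <- paste0(sgGene, "_sg", rep(seq_len(config@sgRNAsPerGene),
                                      times = config@nGenes))
    ntId <- sprintf("NTC_%04d", seq_len(config@nNonTargeting))
    ids <- c(sgId, ntId)
    n <- length(ids)

    eff <- c(stats::rbeta(nT, config@efficacyShape1, config@efficacyShape2),
             rep(1, config@nNonTargeting))
    gi <- match(sgGene, str$genes)
    fC <- c(str$fControl[gi], rep(0, config@nNonTargeting))
    fT <- c(str$fTreated[gi], rep(0, config@nNonTargeting))

    p0 <- stats::rlnorm(n, meanlog = 0, sdlog = config@initialSdLog)
    p0 <- p0 / sum(p0)
    g <- config@generations
    grow <- function(f) {
        p <- p0 * 2^(g * (1 + eff * f))
        if (any(!is.finite(p))) stop("non-finite expected abundances")
        p / sum(p)
    }
    pC <- grow(fC)
    pT <- grow(fT)

    total <- as.integer(round(config@depth * n))
    cts <- cbind(initial = drawCounts(p0, total, config@overdispersion),
                 final_dmso = drawCounts(pC, total, config@overdispersion),
                 final_drug = drawCounts(pT, total, config@overdispersion))
    rownames(cts) <- ids

    ann <- data.frame(
        sgrna = ids,
        gene = c(sgGene, rep(NA_character_, config@nNonTargeting)),
        control_class = rep(c("targeting", "non_targeting"),
                            c(nT, config@nNonTargeting)),
        core_essential = c(str$coreEssential[gi],
                           rep(FALSE, config@nNonTargeting)),
        stringsAsFactors = FALSE)
    se <- ScreenExperiment(cts, ann,
                           roles = c(initial = "initial",
                                     final_dmso = "final_control",
                                     final_drug = "final_treated"))
    new("SimulatedScreen", screen = se,
        geneTruth = S4Vectors::DataFrame(
            gene = str$genes, fControl = str$fControl,
            fTreated = str$fTreated, coreEssential = str$coreEssential,
            category = str$category),
        sgRNATruth = S4Vectors::DataFrame(
            sgrna = ids, gene = ann$gene, efficacy = eff,
            fControl = fC, fTreated = fT, initialAbundance = p0),
        config = config)
}

#' Analytic expected log2 fold-change of each simulated sgRNA
#'
#' The sampling-free oracle for the simulator's deterministic growth
#' model: log2 of the renormalized expected abundance ratio, final over
#' initial, per sgRNA. Composition renormalization is included exactly,
#' so in a library where one guide depletes the remaining guides gain
#' the complementary log2 correction.
#'
#' @param sim a [SimulatedScreen].
#' @param arm `"control"` or `"treated"`.
#' @return named numeric vector of expected log2 fold-changes.
#' @export
expectedLfc <- function(sim, arm = c("control", "treated")) {
    arm <- match.arg(arm)
    tr <- sim@sgRNATruth
    f <- if (arm == "control") tr$fControl else tr$fTreated
    g <- sim@config@generations
    p <- tr$initialAbundance * 2^(g * (1 + tr$efficacy * f))
    p <- p / sum(p)
    stats::setNames(log2(p / tr$initialAbundance), tr$sgrna)
}

# Mann-Whitney AUROC with midrank tie handling
aurocScore <- function(scorePos, scoreNeg) {
    r <- rank(c(scorePos, scoreNeg))
    np <- length(scorePos); nn <- length(scoreNeg)
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Parameter-recovery metrics for a scored simulated screen
#'
#' Compares pipeline output against planted truth: AUROC of the
#' selective-essentiality z (more negative = higher score) for planted
#' selectively-lethal vs planted neutral genes; recall of planted
#' selective genes among the `topN` most negative z; and sign accuracy
#' (fraction with positive z) for planted sensitizing genes.
#'
#' @param scores a [GeneScores] from [scoreScreen()], or any
#'   `data.frame` with `gene` and `selectiveZ` columns.
#' @param truth the gene truth of the generating [SimulatedScreen] (the
#'   object itself is also accepted).
#' @param topN list size for recall; defaults to the number of planted
#'   selective genes.
#' @return list with `auroc`, `recall`, `signAccuracySensitizing`, and
#'   the class sizes used.
#' @export
recoveryMetrics <- function(scores, truth, topN = NULL) {
    if (is(truth, "SimulatedScreen")) truth <- geneTruth(truth)
    tab <- if (is(scores, "GeneScores")) as.data.frame(scoreTable(scores))
           else as.data.frame(scores)
    truth <- as.data.frame(truth)
    truth <- truth[truth$gene %in% tab$gene, , drop = FALSE]
    if (!all(tab$gene %in% truth$gene))
        stop("scored gene(s) missing from truth: ",
             paste(setdiff(tab$gene, truth$gene), collapse = ", "))
    planted <- truth$category[match(tab$gene, truth$gene)]
    sel <- planted == "selectively_lethal"
    neu <- planted == "neutral"
    sen <- planted == "sensitizing_enriched"
    if (!any(sel) || !any(neu))
        stop("truth must contain planted selective and neutral genes")
    if (is.null(topN)) topN <- sum(sel)
    auroc <- aurocScore(-tab$selectiveZ[sel], -tab$selectiveZ[neu])
    top <- tab$gene[order(tab$selectiveZ, tab$gene)][
        seq_len(min(topN, nrow(tab)))]
    recall <- sum(tab$gene[sel] %in% top) / sum(sel)
    signAcc <- if (any(sen)) mean(tab$selectiveZ[sen] > 0) else NA_real_
    list(auroc = auroc, recall = recall,
         signAccuracySensitizing = signAcc, topN = topN,
         nSelective = sum(sel), nNeutral = sum(neu),
         nSensitizing = sum(sen))
}
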