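#' Composite RNA in situ hybridization expression score
#'
#' The cumulative score of an RNA-ISH-stained tissue section whose
#' cells have been binned into expression levels 0-4: the sum of each
#' level times the percentage of cells at that level,
#' `0*A + 1*B + 2*C + 3*D + 4*E` with `A + B + C + D + E = 100`. Range
#' 0 (all cells unstained) to 400 (all cells at the highest level).
#' The per-cell level assignment (dot-counting under the microscope) is
#' upstream of this function.
#'
#' @param bins numeric vector of length 5: percentages of cells at
#'   levels 0, 1, 2, 3, 4, each in `[0, 100]` and summing to 100
#'   (tolerance 1e-9).
#' @return the composite score, in `[0, 400]`.
#' @examples
#' ishCompositeScore(c(0, 0, 0, 0, 100))      # 400
#' ishCompositeScore(c(10, 20, 30, 25, 15))   # 215
#' @export
ishCompositeScore <- function(bins) {
    bins <- as.numeric(bins)
    if (length(bins) != 5L)
        stop("bins must give percentages for the five levels 0-4")
    if (anyNA(bins) || any(bins < 0) || any(bins > 100))
        stop("bin percentages must lie in [0, 100]")
    if (abs(sum(bins) - 100) > 1e-9)
        stop("bin percentages must sum to 100 (got ", sum(bins), ")")
    sum(bins * 0:4)
}

#' Autophagic-flux index from a tandem GFP/RFP reporter
#'
#' For a GFP-LC3-RFP reporter read out per well, autophagic flux is the
#' RFP/GFP ratio (GFP is degraded with the autophagosome, RFP is not),
#' normalized so that the mean ratio of the vehicle (DMSO) wells is 1:
#' `index_w = (rfp_w / gfp_w) / mean_DMSO(rfp / gfp)`.
#'
#' @param wells `data.frame` with columns `gfp` (> 0), `rfp` (>= 0) and
#'   `condition`; rows are wells.
#' @param normalizer condition label of the vehicle wells (default
#'   `"DMSO"`).
#' @return `wells` with `ratio` and `index` columns added; the mean
#'   index over normalizer wells is exactly 1.
#' @export
autophagyIndex <- function(wells, normalizer = "DMSO") {
    stopifnot(is.data.frame(wells),
              all(c("gfp", "rfp", "condition") %in% colnames(wells)))
    if (any(!is.finite(wells$gfp)) || any(wells$gfp <= 0))
        stop("gfp signal must be positive in every well")
    if (any(!is.finite(wells$rfp)) || any(wells$rfp < 0))
        stop("rfp signal must be non-negative")
    isNorm <- wells$condition == normalizer
    if (!any(isNorm))
        stop("no wells with normalizer condition '", normalizer, "'")
    wells$ratio <- wells$rfp / wells$gfp
    wells$index <- wells$ratio / mean(wells$ratio[isNorm])
    wells
}

#' Bliss-independence synergy excess for a dose-combination matrix
#'
#' Given a grid of observed inhibition fractions for combinations of
#' two agents (rows: doses of drug A including 0; columns: doses of
#' drug B including 0), computes the Bliss expectation from the
#' single-agent responses, `E = yA + yB - yA*yB`, and the excess
#' `observed - expected` for every true combination cell. Positive
#' excess indicates synergy beyond independence. Inhibition values are
#' clamped into `[0, 1]` first (assay noise can push responses slightly
#' past baseline); clamping is reported via the returned `nClamped`.
#'
#' @param mat numeric matrix of inhibition fractions in `[0, 1]` (or
#'   percentages if `percent = TRUE`); `mat[1, ]` and `mat[, 1]` are
#'   the single-agent rows at partner dose 0, `mat[1, 1]` the untreated
#'   baseline. Dimnames, if numeric doses, must be strictly increasing
#'   from 0.
#' @param percent inputs are percentage inhibition (divided by 100
#'   before computing).
#' @param clampTol values outside `[0 - clampTol, 1 + clampTol]` are an
#'   error rather than clamped (default 0.25).
#' @return list with `excess` (matrix over combination cells, fraction
#'   units), `expected`, `meanExcess` and `peakExcess` (percentage
#'   points over combination cells), and `nClamped`.
#' @examples
#' m <- rbind(c(0, 0.5), c(0.2, 0.75))   # yA=0.2, yB=0.5, obs 0.75
#' blissExcess(m)$excess                 # +0.15
#' @export
blissExcess <- function(mat, percent = FALSE, clampTol = 0.25) {
    mat <- as.matrix(mat)
    if (nrow(mat) < 2L || ncol(mat) < 2L)
        stop("dose matrix needs at least one combination cell")
    if (percent) mat <- mat / 100
    for (dn in dimnames(mat)) {
        d <- suppressWarnings(as.numeric(dn))
        if (!is.null(dn) && !anyNA(d)) {
            if (d[1L] != 0) stop("dose axes must start at 0")
            if (is.unsorted(d, strictly = TRUE))
                stop("dose axes must be strictly increasing")
        }
    }
    out <- range(mat)
    if (out[1L] < -clampTol || out[2L] > 1 + clampTol)
        stop("inhibition outside [0, 1] beyond the clamping tolerance")
    nClamped <- sum(mat < 0 | mat > 1)
    mat <- pmin(pmax(mat, 0), 1)
    yA <- mat[, 1L]
    yB <- mat[1L, ]
    expected <- outer(yA, yB, function(a, b) a + b - a * b)
    excess <- (mat - expected)[-1L, -1L, drop = FALSE]
    list(excess = excess,
         expected = expected[-1L, -1L, drop = FALSE],
         meanExcess = 100 * mean(excess),
         peakExcess = 100 * max(excess),
         nClamped = nClamped)
}

.PIP_PEAKS <- c("PtdIns", "PtdIns3P", "PtdIns4P", "PtdIns5P",
                "PtdIns(3,5)P2", "PtdIns(4,5)P2")

#' Phosphoinositide peak percentages from radiolabelled HPLC counts
#'
#' Expresses the scintillation counts of the six detectable
#' glycero-inositol peaks (PtdIns, PtdIns3P, PtdIns4P, PtdIns5P,
#' PtdIns(3,5)P2, PtdIns(4,5)P2) as percentages of their sum, after
#' subtracting per-peak background counts (determined from adjacent
#' chromatogram regions). Negative net counts are clamped at zero
#' before normalization.
#'
#' @param raw numeric vector of six raw peak counts; names default to
#'   the six peaks in the order above.
#' @param background per-peak background counts (scalar or length 6;
#'   default 0).
#' @return named numeric vector of six percentages summing to 100.
#' @export
pipPercentages <- function(raw, background = 0) {
    raw <- as.numeric(raw)
    if (length(raw) != 6L)
        stop("exactly six peak counts are required")
    if (anyNA(raw) || any(raw < 0)) stop("raw counts must be >= 0")
    if (length(background) == 1L) background <- rep(background, 6L)
    if (length(background) != 6L || anyNA(background) ||
        any(background < 0))
        stop("background must be a non-negative scalar or length-6 vector")
    net <- pmax(raw - background, 0)
    tot <- sum(net)
    if (tot == 0) stop("all net peak counts are zero")
    stats::setNames(100 * net / tot, .PIP_PEAKS)
}
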