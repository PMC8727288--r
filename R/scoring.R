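#' Compute weighted and unweighted polygenic risk scores
#'
#' The weighted score is the plain weighted sum `sum_j w_j g_j` of
#' risk-allele dosages with per-SNP log-odds-ratio weights; the unweighted
#' score is the plain risk-allele count `sum_j g_j`. (The printed control
#' median near 7.5 over a 41-SNP panel with per-SNP log-ORs well below 1 is
#' only consistent with the sum, not a mean; a mean normalization is exposed
#' via `normalize` but off by default.) Missing dosages are, under the
#' default `mean_impute` policy, replaced by twice the reference control
#' frequency; under `complete_only` individuals with any missing panel
#' genotype receive no score and are flagged.
#'
#' @param genotypes \linkS4class{GenotypeExperiment}.
#' @param missingPolicy `"mean_impute"` (default) or `"complete_only"`.
#' @param imputeFreqs per-variant frequencies used by `mean_impute`; defaults
#'   to the panel's `freq_<refAncestry>` column.
#' @param refAncestry ancestry label naming the default impute frequencies.
#' @param normalize divide both scores by the number of panel SNPs?
#' @return `DataFrame` score set: `sample_id`, `prs_weighted`,
#'   `prs_unweighted`, `n_missing_snps`, `scored`.
#' @examples
#' pan <- S4Vectors::DataFrame(variant_id = c("a", "b"), chrom = "1",
#'     pos = c(1L, 2L), risk_allele = c("G", "C"), other_allele = c("A", "T"),
#'     weight = c(log(2), log(1.5)), freq_EUR = c(0.3, 0.3))
#' ge <- GenotypeExperiment(matrix(c(2, 1), 2, 1), pan,
#'                          data.frame(sample_id = "s1"))
#' computePRS(ge)   # weighted 2*ln2 + 1*ln1.5 = 1.7918, unweighted 3
#' @export
computePRS <- function(genotypes,
                       missingPolicy = c("mean_impute", "complete_only"),
                       imputeFreqs = NULL, refAncestry = "EUR",
                       normalize = FALSE) {
    missingPolicy <- match.arg(missingPolicy)
    d <- dosageMatrix(genotypes)
    w <- riskWeights(genotypes)
    nMiss <- colSums(is.na(d))
    scored <- rep(TRUE, ncol(d))
    if (missingPolicy == "mean_impute") {
        if (any(nMiss > 0)) {
            if (is.null(imputeFreqs))
                imputeFreqs <- ancestryFreqs(genotypes, refAncestry)
            fill <- 2 * imputeFreqs[rownames(d)]
            idx <- which(is.na(d), arr.ind = TRUE)
            d[idx] <- fill[idx[, 1]]
        }
    } else {
        scored <- nMiss == 0L
        ## all-missing (or any-missing) individuals carry NA scores
    }
    pw <- as.vector(w %*% ifelse(is.na(d), 0, d))
    pu <- unname(colSums(d, na.rm = TRUE))
    pw[!scored] <- NA_real_
    pu[!scored] <- NA_real_
    scored <- unname(scored)
    if (normalize && nrow(d) > 0) {
        pw <- pw / nrow(d)
        pu <- pu / nrow(d)
    }
    S4Vectors::DataFrame(sample_id = colnames(d), prs_weighted = pw,
                         prs_unweighted = pu,
                         n_missing_snps = as.integer(nMiss),
                         scored = scored)
}

#' Empirical quantile cutoffs from a reference control population
#'
#' Boundaries are the k/nBins empirical quantiles under the inverse-ECDF
#' convention (`quantile(p)` = smallest x with CDF(x) >= p, type 1 - no
#' interpolation), giving deterministic, half-open bins.
#'
#' @param controlScores reference score vector (NAs dropped).
#' @param nBins number of bins (5 for quintiles).
#' @param source provenance tag stored with the cutoffs.
#' @return \linkS4class{PrsCutoffs}.
#' @export
referenceCutoffs <- function(controlScores, nBins = 5L,
                             source = "internal_controls") {
    controlScores <- controlScores[!is.na(controlScores)]
    if (length(unique(controlScores)) < nBins)
        stop("need at least ", nBins, " distinct reference scores")
    b <- unname(quantile(controlScores, probs = seq_len(nBins - 1) / nBins,
                         type = 1))
    if (any(diff(b) <= 0))
        stop("reference distribution too discrete for distinct boundaries")
    new("PrsCutoffs", boundaries = b, range = range(controlScores),
        source = source, nReference = length(controlScores))
}

#' External European-ancestry quintile cutoffs
#'
#' The published quintile boundaries for the 41-SNP CLL score, derived from
#' 7983 external consortium controls, shipped as a plain-text fixture.
#'
#' @return \linkS4class{PrsCutoffs} with interior boundaries
#'   6.80, 7.32, 7.77, 8.28 over the observed range 4.32-11.31.
#' @export
eaReferenceCutoffs <- function() {
    f <- system.file("extdata", "ea_quintile_cutoffs.tsv", package = "cllprs",
                     mustWork = TRUE)
    df <- read.delim(f)
    new("PrsCutoffs", boundaries = df$boundary[df$kind == "interior"],
        range = range(df$boundary),
        source = "external_reference", nReference = 7983L)
}

#' Assign a quantile category
#'
#' Bins are left-closed, right-open (a score equal to a boundary belongs to
#' the upper bin); scores below the first boundary map to the first bin and
#' scores at or above the last boundary to the last, so the extreme bins are
#' open-ended.
#'
#' @param score numeric score(s); NaN is an error.
#' @param cutoffs \linkS4class{PrsCutoffs}.
#' @return factor of bin labels `Q1..Qn`.
#' @examples
#' assignQuantile(7.46, eaReferenceCutoffs())   # Q3
#' assignQuantile(6.80, eaReferenceCutoffs())   # Q2: boundary joins upper bin
#' @export
assignQuantile <- function(score, cutoffs) {
    if (any(is.nan(score))) stop("NaN score")
    nBins <- length(cutoffs@boundaries) + 1L
    idx <- findInterval(score, cutoffs@boundaries) + 1L
    factor(paste0("Q", idx), levels = paste0("Q", seq_len(nBins)))
}

#' Flag scores at or above a reference percentile
#'
#' The threshold is the reference percentile value under the same inverse-ECDF
#' convention as [referenceCutoffs()]; a score equal to the threshold is
#' flagged.
#'
#' @param score numeric score(s).
#' @param referenceScores reference distribution (NAs dropped).
#' @param percentile reference percentile in (0, 1), default 0.99.
#' @return logical vector.
#' @export
topPercentileFlag <- function(score, referenceScores, percentile = 0.99) {
    referenceScores <- referenceScores[!is.na(referenceScores)]
    if (!length(referenceScores)) stop("empty reference")
    if (percentile <= 0 || percentile >= 1) stop("percentile must be in (0,1)")
    thr <- quantile(referenceScores, percentile, type = 1, names = FALSE)
    score >= thr
}

#' Score a cohort and attach quantile and top-percentile categories
#'
#' Convenience wrapper: computes PRS, assigns quantiles against the given
#' cutoffs, and flags the reference 99th percentile.
#'
#' @param genotypes \linkS4class{GenotypeExperiment}.
#' @param cutoffs \linkS4class{PrsCutoffs}; when `NULL`, quintiles are
#'   derived from this cohort's own controls (requires a `phenotype` column).
#' @param referenceScores reference distribution for the top-percentile flag;
#'   defaults to this cohort's controls.
#' @param percentile top-percentile threshold, default 0.99.
#' @param ... passed to [computePRS()].
#' @return `DataFrame` score set with `quantile_category` and
#'   `top_percentile` columns; the cutoffs used are in `metadata()`.
#' @export
scoreCohort <- function(genotypes, cutoffs = NULL, referenceScores = NULL,
                        percentile = 0.99, ...) {
    ss <- computePRS(genotypes, ...)
    sd_ <- sampleData(genotypes)
    if (is.null(cutoffs) || is.null(referenceScores)) {
        if (!"phenotype" %in% colnames(sd_))
            stop("internal reference requires a phenotype column")
        ctrl <- ss$prs_weighted[sd_$phenotype == "control"]
        if (is.null(cutoffs))
            cutoffs <- referenceCutoffs(ctrl)
        if (is.null(referenceScores))
            referenceScores <- ctrl
    }
    ss$quantile_category <- assignQuantile(ss$prs_weighted, cutoffs)
    ss$top_percentile <- topPercentileFlag(ss$prs_weighted, referenceScores,
                                           percentile)
    S4Vectors::metadata(ss)$cutoffs <- cutoffs
    ss
}
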