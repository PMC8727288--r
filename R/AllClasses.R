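#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom stats quantile rbinom rnorm runif rmultinom pchisq pnorm qnorm
#'   median sd var complete.cases binomial glm.fit chisq.test fisher.test
#'   kruskal.test t.test optim optimHess setNames
#' @importFrom utils read.delim write.table packageVersion head
NULL

## Phenotype categories used throughout, in increasing clone-size order.
.CATEGORIES <- c("control", "LC-MBL", "HC-MBL", "CLL")

#' GenotypeExperiment: risk-allele dosages with SNP panel and sample metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"dosage"` assay of risk-allele counts (variants x samples, values
#' 0/1/2 or `NA` for missing). `rowData` carries the SNP weight panel
#' (`variant_id`, `chrom`, `pos`, `risk_allele`, `other_allele`, `weight`,
#' and one `freq_<ancestry>` column per reference population); `colData`
#' carries per-sample covariates (`sample_id`, `age`, `sex`, and optionally
#' `phenotype`, `cohort`, `ancestry`).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

.validGenotypeExperiment <- function(object) {
    msg <- NULL
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && !all(bad %in% c(0, 1, 2)))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("variant_id", "risk_allele", "other_allele", "weight")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste("rowData lacks column(s):",
                            paste(miss, collapse = ", ")))
    if (!length(miss) && nrow(rd)) {
        if (anyDuplicated(rd$variant_id))
            msg <- c(msg, "variant_ids must be unique")
        if (any(rd$risk_allele == rd$other_allele))
            msg <- c(msg, "risk_allele must differ from other_allele")
        if (any(!is.finite(rd$weight)))
            msg <- c(msg, "weights must be finite")
        fr <- grep("^freq_", colnames(rd), value = TRUE)
        for (fc in fr) {
            f <- rd[[fc]]
            if (any(f < 0 | f > 1, na.rm = TRUE))
                msg <- c(msg, paste(fc, "outside [0, 1]"))
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeExperiment", .validGenotypeExperiment)

#' Quantile cutoffs for PRS stratification
#'
#' Interior boundaries of left-closed right-open score bins; the first bin is
#' open below and the last open above, so every finite score is assignable.
#'
#' @slot boundaries strictly increasing interior boundaries (4 for quintiles).
#' @slot range observed reference range (informational; may be `NA`).
#' @slot source `"external_reference"` or `"internal_controls"`.
#' @slot nReference size of the reference control set the boundaries came from.
#' @export
setClass("PrsCutoffs", representation(
    boundaries = "numeric",
    range = "numeric",
    source = "character",
    nReference = "integer"
))

setValidity("PrsCutoffs", function(object) {
    b <- object@boundaries
    if (length(b) < 1L) return("at least one boundary required")
    if (any(!is.finite(b))) return("boundaries must be finite")
    if (is.unsorted(b, strictly = TRUE)) return("boundaries must be strictly increasing")
    if (!object@source %in% c("external_reference", "internal_controls"))
        return("source must be 'external_reference' or 'internal_controls'")
    TRUE
})

#' Quality-control report
#'
#' Removal decisions and supporting statistics from [qcFilter()].
#'
#' @slot removedVariants data.frame(variant_id, reason) with reason in
#'   monomorphic / call_rate / hwe / ambiguous_alleles.
#' @slot removedSamples data.frame(sample_id, reason) with reason in
#'   call_rate / sex_discordance / relative.
#' @slot hwePvalues named exact-test p-values for tested variants.
#' @slot variantCallRates,sampleCallRates named call-rate vectors.
#' @slot duplicateConcordance data.frame(sample_a, sample_b, n_joint,
#'   concordance) for declared duplicate pairs.
#' @export
setClass("QCReport", representation(
    removedVariants = "data.frame",
    removedSamples = "data.frame",
    hwePvalues = "numeric",
    variantCallRates = "numeric",
    sampleCallRates = "numeric",
    duplicateConcordance = "data.frame"
))

setValidity("QCReport", function(object) {
    p <- object@hwePvalues
    if (length(p) && any(p < 0 | p > 1, na.rm = TRUE))
        return("HWE p-values outside [0, 1]")
    cr <- c(object@variantCallRates, object@sampleCallRates)
    if (length(cr) && any(cr < 0 | cr > 1, na.rm = TRUE))
        return("call rates outside [0, 1]")
    TRUE
})

#' Fitted binary logistic model
#'
#' Maximum-likelihood logistic fit (IRLS) with Wald covariance from the
#' observed information at convergence.
#'
#' @slot coef named coefficient vector, log-odds scale.
#' @slot vcov Wald covariance matrix aligned with `coef`.
#' @slot logLik maximized log-likelihood.
#' @slot nIter IRLS iterations used.
#' @slot converged,separation fit diagnostics; when `separation` is `TRUE`
#'   the affected estimates are not interpretable as finite log-odds.
#' @slot nUsed rows used after listwise deletion.
#' @export
setClass("ModelFit", representation(
    coef = "numeric",
    vcov = "matrix",
    logLik = "numeric",
    nIter = "integer",
    converged = "logical",
    separation = "logical",
    nUsed = "integer"
))

setValidity("ModelFit", function(object) {
    if (length(object@coef) != nrow(object@vcov) ||
        nrow(object@vcov) != ncol(object@vcov))
        return("coef and vcov dimensions disagree")
    dv <- abs(object@vcov - t(object@vcov))
    mv <- suppressWarnings(max(abs(object@vcov), na.rm = TRUE))
    if (is.finite(mv) && any(dv > 1e-8 * (1 + mv), na.rm = TRUE))
        return("vcov must be symmetric")
    TRUE
})

#' Association results table
#'
#' Rows of contrasts (quintile indicators, continuous score terms, ...) with
#' counts, odds ratios, Wald confidence limits and p-values, mirroring the
#' case-control layout used for PRS reporting, plus the c-statistic of the
#' adjusted model.
#'
#' @slot table data.frame with columns contrast, n_cases, n_controls,
#'   or_, ci_low, ci_high, p.
#' @slot modelInfo list of model metadata (adjustment covariates, reference
#'   category, outcome label, medians).
#' @slot cStatistic length-3 numeric (estimate, CI low, CI high), possibly NA.
#' @export
setClass("AssociationTable", representation(
    table = "data.frame",
    modelInfo = "list",
    cStatistic = "numeric"
))

setValidity("AssociationTable", function(object) {
    tb <- object@table
    need <- c("contrast", "or_", "ci_low", "ci_high", "p")
    if (!all(need %in% colnames(tb)))
        return(paste("table lacks column(s):",
                     paste(setdiff(need, colnames(tb)), collapse = ", ")))
    ok <- is.finite(tb$or_) & is.finite(tb$ci_low) & is.finite(tb$ci_high)
    if (any(ok & (tb$ci_low > tb$or_ + 1e-8 | tb$or_ > tb$ci_high + 1e-8)))
        return("confidence limits must bracket the odds ratio")
    TRUE
})

#' Heterogeneity (trend) test result
#'
#' Likelihood-ratio comparison of a polytomous logit with category-specific
#' PRS slopes against one with a single shared slope; covariate effects stay
#' category-specific in both models.
#'
#' @slot lrt likelihood-ratio statistic, `2 * (logLik_free - logLik_shared)`.
#' @slot df number of case categories minus one.
#' @slot pHet chi-square tail probability.
#' @slot slopes data.frame(category, slope, se, ci_low, ci_high) from the
#'   unconstrained model.
#' @slot converged both nested fits converged.
#' @export
setClass("HeterogeneityResult", representation(
    lrt = "numeric",
    df = "integer",
    pHet = "numeric",
    slopes = "data.frame",
    converged = "logical"
))

setValidity("HeterogeneityResult", function(object) {
    if (object@lrt < -1e-6) return("LRT statistic must be non-negative")
    if (object@df < 0L) return("df must be >= 0")
    TRUE
})
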