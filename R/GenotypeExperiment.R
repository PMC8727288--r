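#' Construct a GenotypeExperiment
#'
#' @param dosage numeric matrix of risk-allele counts, variants in rows and
#'   samples in columns; values 0/1/2 or `NA`.
#' @param panel SNP panel `data.frame`/`DataFrame` with columns `variant_id`,
#'   `chrom`, `pos`, `risk_allele`, `other_allele`, `weight` (natural-log odds
#'   ratio per risk allele) and `freq_<ancestry>` columns.
#' @param samples per-sample `data.frame`/`DataFrame`; must contain
#'   `sample_id`, typically also `age`, `sex` (`"M"`/`"F"`), `phenotype`
#'   (control / LC-MBL / HC-MBL / CLL), `cohort`, `ancestry`.
#'
#' @return A \linkS4class{GenotypeExperiment}.
#' @examples
#' panel <- makePanel(5, seed = 1)
#' samples <- data.frame(sample_id = c("s1", "s2"), age = c(60, 70),
#'                       sex = c("M", "F"), ancestry = "EUR")
#' ge <- GenotypeExperiment(matrix(0, 5, 2), panel, samples)
#' @export
GenotypeExperiment <- function(dosage, panel, samples) {
    dosage <- as.matrix(dosage)
    panel <- S4Vectors::DataFrame(panel)
    samples <- S4Vectors::DataFrame(samples)
    if (nrow(panel) != nrow(dosage))
        stop("panel rows must match dosage rows")
    if (nrow(samples) != ncol(dosage))
        stop("sample rows must match dosage columns")
    rownames(dosage) <- panel$variant_id
    colnames(dosage) <- samples$sample_id
    rownames(panel) <- panel$variant_id
    rownames(samples) <- samples$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowData = panel, colData = samples)
    new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment risk-allele dosage matrix (variants x samples).
#' @param x a `GenotypeExperiment`.
#' @export
dosageMatrix <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeExperiment the SNP panel (rowData) as a `DataFrame`.
#' @export
snpPanel <- function(x) SummarizedExperiment::rowData(x)

#' @describeIn GenotypeExperiment per-sample metadata (colData) as a `DataFrame`.
#' @export
sampleData <- function(x) SummarizedExperiment::colData(x)

#' @describeIn GenotypeExperiment named vector of per-SNP log-OR weights.
#' @export
riskWeights <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    setNames(rd$weight, rd$variant_id)
}

#' Risk-allele frequencies for one or all reference ancestries
#'
#' @param x a `GenotypeExperiment` or panel `DataFrame`/`data.frame`.
#' @param ancestry label such as `"EUR"`; `NULL` returns the full
#'   variants x ancestries matrix.
#' @return named frequency vector, or matrix when `ancestry` is `NULL`.
#' @export
ancestryFreqs <- function(x, ancestry = NULL) {
    rd <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::rowData(x)
          else S4Vectors::DataFrame(x)
    fc <- grep("^freq_", colnames(rd), value = TRUE)
    if (!length(fc)) stop("no freq_<ancestry> columns present")
    m <- as.matrix(as.data.frame(rd[, fc, drop = FALSE]))
    colnames(m) <- sub("^freq_", "", fc)
    rownames(m) <- rd$variant_id
    if (is.null(ancestry)) return(m)
    if (!ancestry %in% colnames(m))
        stop("unknown ancestry label: ", ancestry)
    m[, ancestry]
}

setMethod("show", "GenotypeExperiment", function(object) {
    cat("GenotypeExperiment:", nrow(object), "variants x", ncol(object),
        "samples\n")
    d <- dosageMatrix(object)
    cat(sprintf("  missing dosages: %.2f%%\n", 100 * mean(is.na(d))))
    anc <- grep("^freq_", colnames(SummarizedExperiment::rowData(object)),
                value = TRUE)
    if (length(anc))
        cat("  reference ancestries:",
            paste(sub("^freq_", "", anc), collapse = ", "), "\n")
    if ("phenotype" %in% colnames(SummarizedExperiment::colData(object))) {
        tab <- table(SummarizedExperiment::colData(object)$phenotype)
        cat("  phenotypes:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    invisible(NULL)
})

setMethod("show", "PrsCutoffs", function(object) {
    cat("PrsCutoffs (", length(object@boundaries) + 1L, " bins, source: ",
        object@source, ", n = ", object@nReference, ")\n", sep = "")
    cat("  interior boundaries:",
        paste(format(object@boundaries), collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport\n")
    cat("  variants removed:", nrow(object@removedVariants))
    if (nrow(object@removedVariants))
        cat(" (", paste(names(table(object@removedVariants$reason)),
                        table(object@removedVariants$reason),
                        sep = ":", collapse = ", "), ")", sep = "")
    cat("\n  samples removed:", nrow(object@removedSamples), "\n")
    invisible(NULL)
})

setMethod("show", "ModelFit", function(object) {
    cat("ModelFit:", object@nUsed, "observations,",
        length(object@coef), "coefficients;",
        if (object@converged) "converged" else "NOT converged",
        if (object@separation) "(separation flagged)" else "", "\n")
    se <- sqrt(diag(object@vcov))
    print(data.frame(estimate = object@coef, se = se,
                     row.names = names(object@coef)))
    invisible(NULL)
})

setMethod("show", "AssociationTable", function(object) {
    cat("AssociationTable (outcome:",
        object@modelInfo$outcome %||% "?", ")\n")
    print(object@table, row.names = FALSE)
    if (all(is.finite(object@cStatistic)))
        cat(sprintf("  c-statistic %.3f (%.3f-%.3f)\n",
                    object@cStatistic[1], object@cStatistic[2],
                    object@cStatistic[3]))
    invisible(NULL)
})

setMethod("show", "HeterogeneityResult", function(object) {
    cat(sprintf("Heterogeneity LRT = %.3f on %d df, p = %.3g\n",
                object@lrt, object@df, object@pHet))
    print(object@slopes, row.names = FALSE)
    invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn AssociationTable the underlying data.frame of contrasts.
#' @param x an `AssociationTable`.
#' @export
associationTable <- function(x) x@table

#' @describeIn AssociationTable c-statistic (estimate, low, high) of the
#'   adjusted model.
#' @export
cStatisticOf <- function(x) x@cStatistic
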