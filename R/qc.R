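#' Concordance between duplicate genotype vectors
#'
#' Fraction of jointly called (both non-missing) positions at which the two
#' dosage vectors agree; genotyping duplicates are expected to exceed 99%.
#'
#' @param dosagesA,dosagesB equal-length dosage vectors.
#' @return list with `concordance` (NA when no position is jointly called),
#'   `nJoint`, and `defined`.
#' @export
duplicateConcordance <- function(dosagesA, dosagesB) {
    if (length(dosagesA) != length(dosagesB))
        stop("dosage vectors must have equal length")
    joint <- !is.na(dosagesA) & !is.na(dosagesB)
    n <- sum(joint)
    if (n == 0)
        return(list(concordance = NA_real_, nJoint = 0L, defined = FALSE))
    list(concordance = mean(dosagesA[joint] == dosagesB[joint]),
         nJoint = as.integer(n), defined = TRUE)
}

#' Variant- and sample-level genotype quality control
#'
#' Applies, in this fixed order: (1) samples with call rate below
#' `sampleCallMin` removed (plus any precomputed sex-discordance or
#' relatedness flags in the sample data), (2) monomorphic variants removed,
#' (3) variants with call rate below `snpCallMin` removed, (4) variants in
#' extreme Hardy-Weinberg disequilibrium (exact-test p below `hweAlpha`)
#' removed, computed on the retained samples. All thresholds are strict
#' (`< threshold` removes). Sample-level filtering precedes variant
#' statistics so that sample missingness cannot distort call rates or HWE.
#'
#' HWE is tested in controls only when a `phenotype` column is available
#' (`hweSamples = "controls"`, the default), otherwise in all retained
#' samples.
#'
#' @param genotypes \linkS4class{GenotypeExperiment}.
#' @param snpCallMin variant call-rate threshold (default 0.95).
#' @param sampleCallMin sample call-rate threshold (default 0.90).
#' @param hweAlpha HWE exact-test removal threshold (default 1e-5).
#' @param dropMonomorphic remove variants with a single observed dosage?
#' @param hweSamples `"controls"` or `"all"`.
#' @param hweTest `"exact"` (default) or `"chisq"`.
#' @param duplicatePairs optional data.frame(sample_a, sample_b) of declared
#'   duplicates; their concordance is recorded in the report.
#' @return list with `genotypes` (filtered) and `report`
#'   (\linkS4class{QCReport}).
#' @export
qcFilter <- function(genotypes, snpCallMin = 0.95, sampleCallMin = 0.90,
                     hweAlpha = 1e-5, dropMonomorphic = TRUE,
                     hweSamples = c("controls", "all"),
                     hweTest = c("exact", "chisq"),
                     duplicatePairs = NULL) {
    stopifnot(snpCallMin > 0, snpCallMin <= 1,
              sampleCallMin > 0, sampleCallMin <= 1)
    hweSamples <- match.arg(hweSamples)
    hweTest <- match.arg(hweTest)
    d <- dosageMatrix(genotypes)
    sd_ <- sampleData(genotypes)

    dup <- data.frame(sample_a = character(), sample_b = character(),
                      n_joint = integer(), concordance = numeric())
    if (!is.null(duplicatePairs)) for (i in seq_len(nrow(duplicatePairs))) {
        a <- duplicatePairs[i, 1]; b <- duplicatePairs[i, 2]
        cc <- duplicateConcordance(d[, a], d[, b])
        dup <- rbind(dup, data.frame(sample_a = a, sample_b = b,
                                     n_joint = cc$nJoint,
                                     concordance = cc$concordance))
    }

    ## (1) sample filters
    sampleCR <- colMeans(!is.na(d))
    remS <- data.frame(sample_id = character(), reason = character())
    lowS <- names(sampleCR)[sampleCR < sampleCallMin]
    if (length(lowS))
        remS <- rbind(remS, data.frame(sample_id = lowS, reason = "call_rate"))
    flagMap <- c(sex_discordant = "sex_discordance", is_relative = "relative")
    for (col in names(flagMap)) {
        if (col %in% colnames(sd_)) {
            ids <- setdiff(sd_$sample_id[which(sd_[[col]])], remS$sample_id)
            if (length(ids))
                remS <- rbind(remS, data.frame(sample_id = ids,
                                               reason = flagMap[[col]]))
        }
    }
    keepS <- setdiff(colnames(d), remS$sample_id)
    d2 <- d[, keepS, drop = FALSE]

    remV <- data.frame(variant_id = character(), reason = character())
    ## (2) monomorphic
    if (dropMonomorphic && nrow(d2)) {
        nUniq <- apply(d2, 1L, function(x) length(unique(x[!is.na(x)])))
        mono <- rownames(d2)[nUniq <= 1L]
        if (length(mono))
            remV <- rbind(remV, data.frame(variant_id = mono,
                                           reason = "monomorphic"))
    }
    ## (3) variant call rate
    variantCR <- rowMeans(!is.na(d2))
    lowV <- setdiff(names(variantCR)[variantCR < snpCallMin], remV$variant_id)
    if (length(lowV))
        remV <- rbind(remV, data.frame(variant_id = lowV, reason = "call_rate"))
    ## (4) HWE on retained samples (controls when available)
    hweCols <- keepS
    if (hweSamples == "controls" && "phenotype" %in% colnames(sd_)) {
        ctrl <- sd_$sample_id[sd_$phenotype == "control"]
        if (length(intersect(ctrl, keepS))) hweCols <- intersect(ctrl, keepS)
    }
    testFun <- if (hweTest == "exact") hweExactTest else hweChisqTest
    hweP <- rep(NA_real_, nrow(d2)); names(hweP) <- rownames(d2)
    for (v in setdiff(rownames(d2), remV$variant_id)) {
        gc <- .genoCounts(d2[v, hweCols])
        if (sum(gc) >= 1) hweP[v] <- testFun(gc[1], gc[2], gc[3])
    }
    hweBad <- names(hweP)[!is.na(hweP) & hweP < hweAlpha]
    if (length(hweBad))
        remV <- rbind(remV, data.frame(variant_id = hweBad, reason = "hwe"))

    keepV <- setdiff(rownames(d2), remV$variant_id)
    if (!length(keepV) || !length(keepS))
        warning("QC removed everything in one dimension")
    out <- genotypes[match(keepV, rownames(d)),
                     match(keepS, colnames(d))]
    report <- new("QCReport", removedVariants = remV, removedSamples = remS,
                  hwePvalues = hweP[!is.na(hweP)],
                  variantCallRates = rowMeans(!is.na(d)),
                  sampleCallRates = sampleCR,
                  duplicateConcordance = dup)
    list(genotypes = out, report = report)
}
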