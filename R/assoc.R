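#' Concordance statistic (AUC) with Hanley-McNeil confidence interval
#'
#' Probability that a random case outranks a random control on the model's
#' predicted risk, with half credit for ties (the Mann-Whitney form, computed
#' from midranks). The 95% CI uses the Hanley-McNeil standard error and is
#' truncated to [0, 1].
#'
#' @param predicted predicted probabilities (or any monotone risk score).
#' @param outcome binary 0/1 vector.
#' @return list(auc, ci_low, ci_high, se, defined); `defined = FALSE` with
#'   NA values when only one outcome class is present.
#' @export
cStatistic <- function(predicted, outcome) {
    if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
    ok <- !is.na(predicted) & !is.na(outcome)
    predicted <- predicted[ok]; outcome <- outcome[ok]
    n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
    if (n1 == 0 || n0 == 0)
        return(list(auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    se = NA_real_, defined = FALSE))
    r <- rank(predicted)          # midranks give ties half credit
    auc <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
    z <- 1.959964
    list(auc = auc, ci_low = max(0, auc - z * se),
         ci_high = min(1, auc + z * se), se = se, defined = TRUE)
}

#' Kruskal-Wallis rank test across score groups
#'
#' Tie-corrected H statistic with a chi-square reference on
#' (groups - 1) degrees of freedom (delegates to `stats::kruskal.test`).
#' Identical values across all groups give H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list(H, df, p).
#' @export
kruskalWallis <- function(groups) {
    stopifnot(length(groups) >= 2, all(lengths(groups) > 0))
    if (length(unique(unlist(groups))) == 1L)
        return(list(H = 0, df = length(groups) - 1L, p = 1))
    kt <- kruskal.test(groups)
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}

#' Crude 2x2 association
#'
#' Cross-product odds ratio `ad/bc` with Woolf (log-scale) confidence
#' limits, the two-sided chi-square p-value (no continuity correction) and
#' Fisher's exact p. Counts are (case exposed, control exposed,
#' case unexposed, control unexposed). With a zero margin the OR is
#' non-estimable unless `haldane = TRUE`, which adds 0.5 to every cell
#' (requested explicitly, never silently).
#'
#' @param a,b,c,d non-negative counts as described above.
#' @param haldane apply the Haldane-Anscombe 0.5 correction?
#' @return list(or, ci_low, ci_high, p_chisq, p_fisher, estimable).
#' @export
twoByTwo <- function(a, b, c, d, haldane = FALSE) {
    stopifnot(all(c(a, b, c, d) >= 0))
    m <- matrix(c(a, c, b, d), 2, 2)  # rows exposed/unexposed, cols case/ctrl
    pChi <- tryCatch(suppressWarnings(
        chisq.test(m, correct = FALSE)$p.value), error = function(e) NA_real_)
    pFish <- fisher.test(m)$p.value
    cells <- c(a, b, c, d)
    if (any(cells == 0) && !haldane)
        return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p_chisq = pChi, p_fisher = pFish, estimable = FALSE))
    if (haldane) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se <- sqrt(sum(1 / cells))
    z <- 1.959964
    list(or = or, ci_low = exp(log(or) - z * se),
         ci_high = exp(log(or) + z * se),
         p_chisq = pChi, p_fisher = pFish, estimable = TRUE)
}

## One table row from a fit term (or a flagged NA row).
.orRow <- function(contrast, fit, term, nCase, nCtrl, scale = 1) {
    o <- oddsRatioWald(fit, term, scale)
    data.frame(contrast = contrast, n_cases = nCase, n_controls = nCtrl,
               or_ = o$or, ci_low = o$ci_low, ci_high = o$ci_high, p = o$p)
}

#' Quintile-based PRS association with age/sex adjustment
#'
#' One logistic fit with indicator terms for every non-reference quantile
#' bin plus age and sex; the middle quintile is the reference (OR = 1 by
#' construction). Cell counts are reported per bin; an empty bin yields a
#' flagged (NA) row.
#'
#' @param categories factor of quantile bins (`Q1..Q5`).
#' @param outcome binary 0/1 case indicator.
#' @param covariates data.frame/DataFrame with `age` and `sex`.
#' @param reference reference bin, default `"Q3"`.
#' @return \linkS4class{AssociationTable} with the adjusted c-statistic.
#' @export
quintileAssociation <- function(categories, outcome, covariates,
                                reference = "Q3") {
    categories <- as.factor(categories)
    bins <- levels(categories)
    if (!reference %in% bins) stop("reference bin absent")
    nonref <- setdiff(bins, reference)
    ind <- vapply(nonref, function(q) as.numeric(categories == q),
                  numeric(length(categories)))
    X <- .covDesign(covariates, ind)
    fit <- fitLogistic(outcome, X)
    rows <- do.call(rbind, lapply(bins, function(q) {
        nCase <- sum(categories == q & outcome == 1, na.rm = TRUE)
        nCtrl <- sum(categories == q & outcome == 0, na.rm = TRUE)
        if (q == reference)
            return(data.frame(contrast = q, n_cases = nCase,
                              n_controls = nCtrl, or_ = 1, ci_low = 1,
                              ci_high = 1, p = NA_real_))
        if (nCase + nCtrl == 0)
            return(data.frame(contrast = q, n_cases = 0L, n_controls = 0L,
                              or_ = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, p = NA_real_))
        .orRow(q, fit, q, nCase, nCtrl)
    }))
    keep <- complete.cases(X) & !is.na(outcome)
    pred <- as.vector(X[keep, , drop = FALSE] %*% fit@coef)
    cs <- cStatistic(stats::plogis(pred), outcome[keep])
    new("AssociationTable", table = rows,
        modelInfo = list(adjustment = c("age", "sex"), reference = reference,
                         fit = fit),
        cStatistic = c(cs$auc, cs$ci_low, cs$ci_high))
}

#' Per-SNP log-additive association
#'
#' One age/sex-adjusted logistic fit per variant with dosage as a single
#' linear term (log-additive model). Significance is flagged at the nominal
#' p < 0.05 with no multiple-testing correction, matching an a-priori panel
#' of susceptibility SNPs. Monomorphic variants give non-estimable rows.
#'
#' @param genotypes \linkS4class{GenotypeExperiment}.
#' @param outcome binary 0/1 case indicator over samples.
#' @param covariates data.frame with `age` and `sex`; defaults to the
#'   object's own sample data.
#' @return data.frame: variant_id, or_, ci_low, ci_high, p, n_used,
#'   significant.
#' @export
perSnpAssociation <- function(genotypes, outcome, covariates = NULL) {
    if (is.null(covariates)) covariates <- sampleData(genotypes)
    d <- dosageMatrix(genotypes)
    out <- lapply(rownames(d), function(v) {
        g <- d[v, ]
        if (length(unique(g[!is.na(g)])) < 2L)
            return(data.frame(variant_id = v, or_ = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p = NA_real_, n_used = sum(!is.na(g)),
                              significant = NA))
        X <- .covDesign(covariates, cbind(dosage = g))
        fit <- fitLogistic(outcome, X)
        o <- oddsRatioWald(fit, "dosage")
        data.frame(variant_id = v, or_ = o$or, ci_low = o$ci_low,
                   ci_high = o$ci_high, p = o$p, n_used = fit@nUsed,
                   significant = isTRUE(o$p < 0.05))
    })
    do.call(rbind, out)
}

#' Continuous-PRS association adjusted for age and sex
#'
#' @param prs continuous score.
#' @param outcome binary 0/1.
#' @param covariates data.frame with `age`, `sex`.
#' @return list(or, ci_low, ci_high, p, fit, cstat) where `cstat` is the
#'   adjusted-model c-statistic from [cStatistic()].
#' @export
continuousAssociation <- function(prs, outcome, covariates) {
    X <- .covDesign(covariates, cbind(prs = prs))
    fit <- fitLogistic(outcome, X)
    o <- oddsRatioWald(fit, "prs")
    keep <- complete.cases(X) & !is.na(outcome)
    pred <- stats::plogis(as.vector(X[keep, , drop = FALSE] %*% fit@coef))
    cs <- cStatistic(pred, outcome[keep])
    c(o, list(fit = fit, cstat = cs))
}

#' Top-percentile versus middle-quintile contrast
#'
#' Age/sex-adjusted odds ratio comparing individuals at or above the
#' reference 99th percentile with the middle-quintile reference group,
#' restricted to those two groups.
#'
#' @param topFlag logical top-percentile indicator.
#' @param categories quantile bins.
#' @param outcome binary 0/1.
#' @param covariates data.frame with `age`, `sex`.
#' @param reference middle bin label.
#' @return list(or, ci_low, ci_high, p, n_top_cases, pct_top_cases).
#' @export
topPercentileAssociation <- function(topFlag, categories, outcome, covariates,
                                     reference = "Q3") {
    sel <- topFlag | categories == reference
    X <- .covDesign(as.data.frame(covariates)[sel, , drop = FALSE],
                    cbind(top = as.numeric(topFlag[sel])))
    fit <- fitLogistic(outcome[sel], X)
    o <- oddsRatioWald(fit, "top")
    nTop <- sum(topFlag & outcome == 1, na.rm = TRUE)
    c(o, list(n_top_cases = nTop,
              pct_top_cases = 100 * nTop / sum(outcome == 1, na.rm = TRUE)))
}

#' Environmental exposure screen
#'
#' For each exposure column: a crude two-sided chi-square test (binary
#' exposures) or Student's t test (continuous), then an age/sex-adjusted
#' logistic odds ratio, each on that exposure's complete cases (so
#' denominators differ with missingness and are reported). Exposures with a
#' single observed level are skipped with a reason.
#'
#' @param samples data.frame/DataFrame with `age`, `sex` and the exposures.
#' @param exposures character vector of column names.
#' @param outcome binary 0/1 over rows of `samples`.
#' @return data.frame: exposure, n_used, n_exposed_cases, n_exposed_controls,
#'   crude_p, or_adj, ci_low, ci_high, p_adj, note.
#' @export
exposureScreen <- function(samples, exposures, outcome) {
    sd_ <- as.data.frame(samples)
    out <- lapply(exposures, function(e) {
        x <- sd_[[e]]
        ok <- !is.na(x) & !is.na(outcome) & !is.na(sd_$age) & !is.na(sd_$sex)
        xi <- x[ok]; yi <- outcome[ok]
        row <- data.frame(exposure = e, n_used = sum(ok),
                          n_exposed_cases = NA_integer_,
                          n_exposed_controls = NA_integer_,
                          crude_p = NA_real_, or_adj = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_adj = NA_real_, note = "")
        if (length(unique(xi)) < 2L) {
            row$note <- "single_level"
            return(row)
        }
        binary <- all(xi %in% c(0, 1, TRUE, FALSE))
        row$crude_p <- if (binary)
            suppressWarnings(chisq.test(table(xi, yi), correct = FALSE)$p.value)
        else t.test(xi ~ yi)$p.value
        if (binary) {
            row$n_exposed_cases <- sum(xi == 1 & yi == 1)
            row$n_exposed_controls <- sum(xi == 1 & yi == 0)
        }
        X <- .covDesign(sd_[ok, , drop = FALSE], cbind(exposure = as.numeric(xi)))
        fit <- fitLogistic(yi, X)
        o <- oddsRatioWald(fit, "exposure")
        if (!o$estimable) row$note <- "separation"
        row$or_adj <- o$or; row$ci_low <- o$ci_low
        row$ci_high <- o$ci_high; row$p_adj <- o$p
        row
    })
    do.call(rbind, out)
}
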