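## Synthetic genotype-phenotype cohorts with the statistical structure the
## downstream analysis assumes: Hardy-Weinberg genotypes at independent SNPs
## with ancestry-specific risk-allele frequencies, a four-category outcome
## (control / LC-MBL / HC-MBL / CLL) from a multinomial logit with graded
## per-unit PRS effects, age and sex covariate effects, and optional QC
## artifacts (missingness, HWE distortion, duplicates, monomorphic sites).

## One global seed; deterministic per-operation substreams.
.childSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
    plo <- pnorm((lo - mean) / sd)
    phi <- pnorm((hi - mean) / sd)
    qnorm(runif(n, plo, phi)) * sd + mean
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Generate a synthetic SNP weight panel
#'
#' Draws per-variant log-odds-ratio weights uniformly from `weightRange` and
#' ancestry-specific risk-allele frequencies uniformly from `freqRanges`.
#' Defaults emulate a 41-SNP CLL susceptibility panel on the published score
#' scale: per-allele odds ratios between 1.10 and 1.40 and European-ancestry
#' risk-allele frequencies in (0.25, 0.60) put the control weighted-sum score
#' near mean 7.5 with standard deviation near 1, matching the printed
#' control median (7.46) and quintile boundaries (6.80-8.28) of the external
#' reference. The African-ancestry range is shifted about 0.07 lower,
#' matching the reported median European-African frequency difference (7.2%)
#' that drives cross-ancestry score attenuation.
#'
#' @param nSnps number of variants (>= 0).
#' @param weightRange length-2 range for uniform log-OR weights.
#' @param freqRanges named list, one `(lo, hi)` frequency range per ancestry.
#' @param seed integer seed; output is reproducible for a fixed seed.
#' @param allowPalindromic keep strand-ambiguous (A/T, C/G) allele pairs?
#'   Off by default so the default pipeline is not thinned by the
#'   conservative harmonization policy.
#' @return `DataFrame` panel usable as `rowData` of a
#'   \linkS4class{GenotypeExperiment}.
#' @export
makePanel <- function(nSnps,
                      weightRange = c(log(1.10), log(1.40)),
                      freqRanges = list(EUR = c(0.25, 0.60),
                                        AFR = c(0.18, 0.53),
                                        EAS = c(0.15, 0.55)),
                      seed = 1,
                      allowPalindromic = FALSE) {
    stopifnot(nSnps >= 0, length(weightRange) == 2)
    if (weightRange[1] > weightRange[2])
        stop("invalid weight range: lo > hi")
    for (a in names(freqRanges)) {
        r <- freqRanges[[a]]
        if (r[1] > r[2] || r[1] < 0 || r[2] > 1)
            stop("invalid frequency range for ancestry ", a)
    }
    if (nSnps == 0) {
        pan <- S4Vectors::DataFrame(variant_id = character(),
                                    chrom = character(), pos = integer(),
                                    risk_allele = character(),
                                    other_allele = character(),
                                    weight = numeric())
        for (a in names(freqRanges)) pan[[paste0("freq_", a)]] <- numeric()
        return(pan)
    }
    set.seed(.childSeed(seed, "makePanel"))
    chrom <- sort(sample(1:22, nSnps, replace = TRUE))
    pos <- integer(nSnps)
    for (cc in unique(chrom)) {
        idx <- which(chrom == cc)
        pos[idx] <- sort(sample.int(2.4e8, length(idx)))
    }
    risk <- other <- character(nSnps)
    for (i in seq_len(nSnps)) {
        repeat {
            al <- sample(.BASES, 2)
            if (allowPalindromic || .COMP[al[1]] != al[2]) break
        }
        risk[i] <- al[1]; other[i] <- al[2]
    }
    pan <- S4Vectors::DataFrame(
        variant_id = sprintf("snp%03d", seq_len(nSnps)),
        chrom = as.character(chrom), pos = pos,
        risk_allele = risk, other_allele = other,
        weight = runif(nSnps, weightRange[1], weightRange[2]))
    for (a in names(freqRanges))
        pan[[paste0("freq_", a)]] <- runif(nSnps, freqRanges[[a]][1],
                                           freqRanges[[a]][2])
    pan
}

#' Simulate Hardy-Weinberg genotypes for a sample table
#'
#' Dosage at variant j for an individual of ancestry a is
#' `Binomial(2, f_aj)`, independent across variants and individuals.
#'
#' @param panel SNP panel with `freq_<ancestry>` columns.
#' @param samples data.frame/DataFrame with `sample_id` and `ancestry`
#'   matching panel frequency columns.
#' @param seed integer seed.
#' @return \linkS4class{GenotypeExperiment} with complete dosages.
#' @export
simulateGenotypes <- function(panel, samples, seed = 1) {
    panel <- S4Vectors::DataFrame(panel)
    samples <- S4Vectors::DataFrame(samples)
    fm <- ancestryFreqs(panel)
    anc <- as.character(samples$ancestry)
    bad <- setdiff(unique(anc), colnames(fm))
    if (length(bad))
        stop("unknown ancestry label(s): ", paste(bad, collapse = ", "))
    set.seed(.childSeed(seed, "simulateGenotypes"))
    p <- fm[, anc, drop = FALSE]   # variants x samples success probs
    d <- matrix(rbinom(length(p), 2L, p), nrow = nrow(fm))
    GenotypeExperiment(d, panel, samples)
}

#' Simulation configuration with study-scale defaults
#'
#' Defaults encode the study conditions the generator emulates: the cohort
#' group sizes (2631 controls, 396 LC-MBL, 164 HC-MBL, 696 CLL for the
#' European-ancestry arm), graded continuous-PRS effects rising with clone
#' size (per-unit odds ratios 1.75, 2.14, 2.53 for LC-MBL, HC-MBL, CLL), an
#' age effect of 1.83-fold per decade and a 1.73-fold male effect, ages from
#' a truncated normal (mean 64, sd 10, range 30-100) and a 45% male source
#' population.
#'
#' @param nPerGroup named target case-control counts; names from
#'   control / LC-MBL / HC-MBL / CLL.
#' @param ancestryMix named ancestry proportions, summing to 1.
#' @param categoryPrsSlopes per-unit log-OR of the weighted PRS, one per case
#'   category.
#' @param categoryIntercepts multinomial-logit intercepts vs control; `NULL`
#'   calibrates them once, at population-mean PRS/age/sex, to
#'   `targetPrevalence`.
#' @param targetPrevalence category probabilities at mean covariates used for
#'   the intercept calibration.
#' @param ageEffect log-OR per year of age; `sexEffect` log-OR for male sex.
#' @param ageDist `(mean, sd, min, max)` of the truncated-normal age draw.
#' @param maleFraction source-population male proportion.
#' @param nSnps panel size when the cohort builds its own panel.
#' @param seed global integer seed; all substreams derive from it.
#' @return validated config list of class `cllprs_simconfig`.
#' @export
simulationConfig <- function(nPerGroup = c(control = 2631, `LC-MBL` = 396,
                                           `HC-MBL` = 164, CLL = 696),
                             ancestryMix = c(EUR = 1),
                             categoryPrsSlopes = c(`LC-MBL` = log(1.75),
                                                   `HC-MBL` = log(2.14),
                                                   CLL = log(2.53)),
                             categoryIntercepts = NULL,
                             targetPrevalence = c(`LC-MBL` = 0.05,
                                                  `HC-MBL` = 0.02,
                                                  CLL = 0.05),
                             ageEffect = log(1.83) / 10,
                             sexEffect = log(1.73),
                             ageDist = c(mean = 64, sd = 10, min = 30, max = 100),
                             maleFraction = 0.45,
                             nSnps = 41,
                             seed = 1) {
    if (abs(sum(ancestryMix) - 1) > 1e-8)
        stop("ancestry proportions must sum to 1")
    if (any(nPerGroup < 0)) stop("group sizes must be >= 0")
    if (ageDist[["sd"]] <= 0) stop("age sd must be > 0")
    if (any(!is.finite(categoryPrsSlopes))) stop("slopes must be finite")
    if (!"control" %in% names(nPerGroup))
        stop("config must include a control group")
    cases <- setdiff(names(nPerGroup), "control")
    if (!length(cases)) stop("config needs at least one case category")
    if (!all(cases %in% names(categoryPrsSlopes)))
        stop("every case category needs a PRS slope")
    structure(list(nPerGroup = nPerGroup, ancestryMix = ancestryMix,
                   categoryPrsSlopes = categoryPrsSlopes,
                   categoryIntercepts = categoryIntercepts,
                   targetPrevalence = targetPrevalence,
                   ageEffect = ageEffect, sexEffect = sexEffect,
                   ageDist = ageDist, maleFraction = maleFraction,
                   nSnps = nSnps, seed = seed),
              class = "cllprs_simconfig")
}

## Intercepts such that softmax at population-mean PRS/age/sex hits the
## target prevalences: eta_c = log(p_c / p_control) at the means.
.calibrateIntercepts <- function(config, panel) {
    cases <- setdiff(names(config$nPerGroup), "control")
    prev <- config$targetPrevalence[cases]
    if (any(is.na(prev))) stop("targetPrevalence missing for some category")
    mix <- config$ancestryMix
    fm <- ancestryFreqs(panel)
    fmix <- as.vector(fm[, names(mix), drop = FALSE] %*% mix)
    meanPrs <- sum(panel$weight * 2 * fmix)
    p0 <- 1 - sum(prev)
    log(prev / p0) -
        config$categoryPrsSlopes[cases] * meanPrs -
        config$ageEffect * config$ageDist[["mean"]] -
        config$sexEffect * config$maleFraction
}

.linearPredictors <- function(prs, age, male, config, intercepts) {
    cases <- names(intercepts)
    eta <- vapply(cases, function(cc)
        intercepts[[cc]] + config$categoryPrsSlopes[[cc]] * prs +
            config$ageEffect * age + config$sexEffect * male,
        numeric(length(prs)))
    if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1)
    colnames(eta) <- cases
    eta
}

#' Assign multinomial-logit phenotypes and sample exact group sizes
#'
#' Log-odds of case category c versus control are
#' `intercept_c + slope_c * PRS + ageEffect * age + sexEffect * male`.
#' Categories are drawn per individual, then exact group sizes are achieved
#' by case-control subsampling from the assigned pool; a pool too small for a
#' requested group is a simulation error (callers oversample, see
#' [simulateCohort()]).
#'
#' @param genotypes \linkS4class{GenotypeExperiment} pool with `age`, `sex`
#'   in its sample data.
#' @param config a [simulationConfig()].
#' @param intercepts optional named intercepts overriding the config.
#' @return subset `GenotypeExperiment` with a `phenotype` column.
#' @export
simulatePhenotypes <- function(genotypes, config, intercepts = NULL) {
    stopifnot(is(genotypes, "GenotypeExperiment"))
    if (is.null(intercepts))
        intercepts <- config$categoryIntercepts %||%
            .calibrateIntercepts(config, snpPanel(genotypes))
    sd_ <- sampleData(genotypes)
    prs <- as.vector(riskWeights(genotypes) %*%
                     ifelse(is.na(dosageMatrix(genotypes)), 0,
                            dosageMatrix(genotypes)))
    male <- as.integer(sd_$sex == "M")
    eta <- .linearPredictors(prs, sd_$age, male, config, intercepts)
    set.seed(.childSeed(config$seed, "simulatePhenotypes"))
    expEta <- cbind(control = 1, exp(eta))
    pr <- expEta / rowSums(expEta)
    cum <- pr
    for (k in seq_len(ncol(pr))[-1]) cum[, k] <- cum[, k - 1] + cum[, k]
    cat_ <- colnames(pr)[max.col(runif(nrow(pr)) < cum, ties.method = "first")]
    keep <- integer(0)
    for (g in names(config$nPerGroup)) {
        avail <- which(cat_ == g)
        want <- config$nPerGroup[[g]]
        if (length(avail) < want)
            stop("simulation error: category '", g, "' yielded ",
                 length(avail), " individuals, ", want,
                 " requested; probability mass too small for this pool")
        keep <- c(keep, if (want) sample(avail, want) else integer(0))
    }
    lev <- names(config$nPerGroup)
    lev <- c(intersect(.CATEGORIES, lev), setdiff(lev, .CATEGORIES))
    out <- genotypes[, sort(keep)]
    SummarizedExperiment::colData(out)$phenotype <-
        factor(cat_[sort(keep)], levels = lev)
    out
}

#' Simulate a complete case-control cohort
#'
#' Builds (or accepts) a SNP panel, draws covariates and Hardy-Weinberg
#' genotypes for a candidate pool, assigns phenotypes under the multinomial
#' logit, and subsamples to the exact group sizes in the config. The pool is
#' grown geometrically until every group is filled, up to a 100x oversampling
#' cap relative to the requested cohort size.
#'
#' @param config a [simulationConfig()].
#' @param panel optional pre-built panel; by default [makePanel()] with the
#'   config's `nSnps` and seed.
#' @return \linkS4class{GenotypeExperiment} with phenotype, age, sex,
#'   ancestry and cohort columns.
#' @export
simulateCohort <- function(config = simulationConfig(), panel = NULL) {
    if (is.null(panel)) panel <- makePanel(config$nSnps, seed = config$seed)
    intercepts <- config$categoryIntercepts %||%
        .calibrateIntercepts(config, panel)
    nTotal <- sum(config$nPerGroup)
    ## expected yield per candidate for the scarcest group drives pool size
    poolN <- max(4L * nTotal, 2000L)
    capN <- 100L * nTotal
    attempt <- 0L
    repeat {
        attempt <- attempt + 1L
        set.seed(.childSeed(config$seed, paste0("cohortCovariates", attempt)))
        anc <- sample(names(config$ancestryMix), poolN, replace = TRUE,
                      prob = config$ancestryMix)
        samples <- S4Vectors::DataFrame(
            sample_id = sprintf("ind%06d", seq_len(poolN)),
            age = .rtruncnorm(poolN, config$ageDist[["mean"]],
                              config$ageDist[["sd"]], config$ageDist[["min"]],
                              config$ageDist[["max"]]),
            sex = ifelse(runif(poolN) < config$maleFraction, "M", "F"),
            ancestry = anc,
            cohort = "synthetic")
        pool <- simulateGenotypes(panel, samples,
                                  seed = .childSeed(config$seed,
                                                    paste0("cohortGeno", attempt)))
        res <- tryCatch(simulatePhenotypes(pool, config, intercepts),
                        error = function(e) e)
        if (!inherits(res, "error")) return(res)
        if (poolN >= capN)
            stop("simulation error after 100x oversampling: ",
                 conditionMessage(res))
        poolN <- min(capN, poolN * 4L)
    }
}

#' Specification of QC artifacts to inject
#'
#' @param snpMissingRates named per-variant missingness rates.
#' @param sampleMissingRates named per-sample missingness rates.
#' @param hweViolationSnps data.frame(variant_id, f) where `f` is an
#'   inbreeding-like distortion: P(het) = 2p(1-p)(1-f), the homozygote excess
#'   (f > 0) or deficit (f < 0) reallocated to/from the homozygote classes.
#' @param duplicatePairs data.frame(source_id, dup_id, discordance): a copy of
#'   `source_id` appended under `dup_id`, each jointly called entry flipped to
#'   a different dosage with the given probability.
#' @param monomorphicSnps variant ids forced to constant dosage 0.
#' @return validated list of class `cllprs_artifacts`.
#' @export
artifactSpec <- function(snpMissingRates = numeric(),
                         sampleMissingRates = numeric(),
                         hweViolationSnps = data.frame(variant_id = character(),
                                                       f = numeric()),
                         duplicatePairs = data.frame(source_id = character(),
                                                     dup_id = character(),
                                                     discordance = numeric()),
                         monomorphicSnps = character()) {
    rates <- c(snpMissingRates, sampleMissingRates, duplicatePairs$discordance)
    if (length(rates) && any(rates < 0 | rates > 1))
        stop("all rates must lie in [0, 1]")
    structure(list(snpMissingRates = snpMissingRates,
                   sampleMissingRates = sampleMissingRates,
                   hweViolationSnps = hweViolationSnps,
                   duplicatePairs = duplicatePairs,
                   monomorphicSnps = monomorphicSnps),
              class = "cllprs_artifacts")
}

#' Inject QC artifacts into a genotype matrix
#'
#' Applies, in order: HWE-distorted regeneration of listed variants,
#' monomorphic flattening, per-variant then per-sample missingness, and
#' appended duplicate samples with the stated discordance. An empty spec
#' returns the input unchanged.
#'
#' @param genotypes \linkS4class{GenotypeExperiment}.
#' @param spec an [artifactSpec()].
#' @param seed integer seed.
#' @return modified `GenotypeExperiment` (duplicates appended as new columns).
#' @export
injectArtifacts <- function(genotypes, spec, seed = 1) {
    stopifnot(is(genotypes, "GenotypeExperiment"),
              inherits(spec, "cllprs_artifacts"))
    d <- dosageMatrix(genotypes)
    sd_ <- sampleData(genotypes)
    badV <- setdiff(c(names(spec$snpMissingRates),
                      spec$hweViolationSnps$variant_id,
                      spec$monomorphicSnps), rownames(d))
    badS <- setdiff(c(names(spec$sampleMissingRates),
                      spec$duplicatePairs$source_id), colnames(d))
    if (length(badV) || length(badS))
        stop("unknown id(s): ", paste(c(badV, badS), collapse = ", "))
    set.seed(.childSeed(seed, "injectArtifacts"))
    fm <- ancestryFreqs(snpPanel(genotypes))
    anc <- as.character(sd_$ancestry)
    for (i in seq_len(nrow(spec$hweViolationSnps))) {
        v <- spec$hweViolationSnps$variant_id[i]
        f <- spec$hweViolationSnps$f[i]
        p <- fm[v, anc]
        pHet <- pmax(0, 2 * p * (1 - p) * (1 - f))
        pHomR <- pmax(0, p^2 + p * (1 - p) * f)
        pHomO <- pmax(0, 1 - pHet - pHomR)
        u <- runif(ncol(d))
        d[v, ] <- ifelse(u < pHomO, 0L, ifelse(u < pHomO + pHet, 1L, 2L))
    }
    if (length(spec$monomorphicSnps))
        d[spec$monomorphicSnps, ] <- 0L
    for (v in names(spec$snpMissingRates))
        d[v, runif(ncol(d)) < spec$snpMissingRates[[v]]] <- NA
    for (s in names(spec$sampleMissingRates))
        d[runif(nrow(d)) < spec$sampleMissingRates[[s]], s] <- NA
    if (nrow(spec$duplicatePairs)) {
        for (i in seq_len(nrow(spec$duplicatePairs))) {
            src <- spec$duplicatePairs$source_id[i]
            dupId <- spec$duplicatePairs$dup_id[i]
            r <- spec$duplicatePairs$discordance[i]
            col <- d[, src]
            flip <- !is.na(col) & runif(length(col)) < r
            col[flip] <- vapply(col[flip], function(g)
                sample(setdiff(0:2, g), 1L), numeric(1))
            d <- cbind(d, setNames(data.frame(col), dupId)[[1]])
            colnames(d)[ncol(d)] <- dupId
            row <- sd_[src, , drop = FALSE]
            row$sample_id <- dupId
            sd_ <- rbind(sd_, row)
        }
    }
    GenotypeExperiment(d, snpPanel(genotypes), sd_)
}
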