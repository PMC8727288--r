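## Independent oracles, deliberately implemented by a different route than
## the package code they check.

## HWE exact test by full enumeration with log-factorial probabilities:
## P(nAB | n, nA) = n! / (nAA! nAB! nBB!) * 2^nAB * nA! nB! / (2n)!
hweEnumOracle <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    nA <- 2 * nAA + nAB
    nB <- 2 * nBB + nAB
    hets <- seq.int(min(nA, nB) %% 2, min(nA, nB), by = 2)
    lp <- vapply(hets, function(h) {
        aa <- (nA - h) / 2; bb <- (nB - h) / 2
        lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
            h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
    }, numeric(1))
    p <- exp(lp - max(lp)); p <- p / sum(p)
    pObs <- p[match(nAB, hets)]
    min(1, sum(p[p <= pObs * (1 + 1e-12)]))
}

## c-statistic by brute-force double loop over all case-control pairs.
aucPairOracle <- function(pred, y) {
    cases <- pred[y == 1]; ctrls <- pred[y == 0]
    tot <- 0
    for (a in cases) tot <- tot + sum(a > ctrls) + 0.5 * sum(a == ctrls)
    tot / (length(cases) * length(ctrls))
}

## 1-d grid search over the two-ancestry admixture likelihood.
admixGridOracle <- function(g, f2, step = 0.001) {
    qs <- seq(0, 1, by = step)
    f2 <- pmin(pmax(f2, 1e-6), 1 - 1e-6)
    ll <- vapply(qs, function(q) {
        p <- q * f2[, 1] + (1 - q) * f2[, 2]
        sum(g * log(p) + (2 - g) * log1p(-p), na.rm = TRUE)
    }, numeric(1))
    qs[which.max(ll)]
}

## Small complete cohort shared by several test files (cheap, built once).
smallCohort <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateCohort(simulationConfig(
                nPerGroup = c(control = 400, `LC-MBL` = 70, `HC-MBL` = 40,
                              CLL = 90), seed = 42))
        cache
    }
})

## Paired two-population attenuation simulation: the same 41-SNP panel with
## per-allele effects fixed; population 2 has every risk-allele frequency
## shifted 0.25 lower (floored at 0.02). Returns per-replicate top-quintile
## ORs and c-statistics for both populations.
attenuationPair <- function(seedBase, nRep = 2, nv = 41, n = 12000) {
    set.seed(seedBase)
    w <- runif(nv, log(1.1), log(1.4))
    f0 <- runif(nv, 0.30, 0.60)
    run <- function(freqs, seed) {
        set.seed(seed)
        g <- matrix(rbinom(nv * n, 2, freqs), nrow = nv)
        prs <- as.vector(w %*% g)
        y <- rbinom(n, 1, stats::plogis(prs - mean(prs) - 2))
        idx <- c(sample(which(y == 1), 1200), sample(which(y == 0), 3500))
        yy <- y[idx]; ps <- prs[idx]
        cov <- data.frame(age = rnorm(length(idx), 64, 10),
                          sex = sample(c("M", "F"), length(idx), TRUE))
        ca <- continuousAssociation(ps, yy, cov)
        cuts <- referenceCutoffs(ps[yy == 0])
        qa <- quintileAssociation(assignQuantile(ps, cuts), yy, cov)
        c(q5 = associationTable(qa)$or_[5], auc = ca$cstat$auc)
    }
    ea <- t(vapply(seq_len(nRep), function(r) run(f0, seedBase + 10 + r),
                   numeric(2)))
    aa <- t(vapply(seq_len(nRep), function(r)
        run(pmax(0.02, f0 - 0.25), seedBase + 20 + r), numeric(2)))
    list(ea = ea, aa = aa)
}

## Binary case-control draw from a logistic model on a given PRS, used by
## calibration/recovery tests: samples nCase cases and nCtrl controls.
drawCaseControl <- function(prs, age, male, slope, nCase, nCtrl,
                            ageEff = log(1.83) / 10, sexEff = log(1.73),
                            intercept = NULL) {
    if (is.null(intercept))
        intercept <- -(slope * mean(prs) + ageEff * mean(age) +
                       sexEff * mean(male)) - 2
    eta <- intercept + slope * prs + ageEff * age + sexEff * male
    y <- rbinom(length(prs), 1, stats::plogis(eta))
    ic <- sample(which(y == 1), nCase)
    i0 <- sample(which(y == 0), nCtrl)
    idx <- c(ic, i0)
    list(idx = idx, y = y[idx])
}
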