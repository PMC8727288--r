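test_that("logistic fit reproduces the closed-form 2x2 log-OR and Woolf SE", {
    a <- 50; b <- 597; c_ <- 103; d <- 553
    y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    x <- c(rep(1, a + b), rep(0, c_ + d))
    fit <- fitLogistic(y, cbind(`(Intercept)` = 1, x = x))
    expect_equal(fit@coef[["x"]], log((a * d) / (c_ * b)), tolerance = 1e-8)
    expect_equal(sqrt(fit@vcov["x", "x"]),
                 sqrt(1 / a + 1 / b + 1 / c_ + 1 / d), tolerance = 1e-8)
    expect_true(fit@converged)
    expect_false(fit@separation)

    ## degenerate one-class outcome is flagged
    f0 <- fitLogistic(rep(0, 20), cbind(1, rnorm(20)))
    expect_true(f0@separation)
    expect_false(oddsRatioWald(f0, "x1")$estimable)
})

test_that("Wald odds ratios rescale correctly and degenerate cleanly", {
    vc <- diag(c(0.01, 1e-4))
    dimnames(vc) <- list(c("(Intercept)", "age"), c("(Intercept)", "age"))
    fit <- new("ModelFit", coef = c(`(Intercept)` = 0, age = 0.0605),
               vcov = vc, logLik = 0, nIter = 1L,
               converged = TRUE, separation = FALSE, nUsed = 10L)
    o <- oddsRatioWald(fit, "age", scale = 10)
    expect_equal(o$or, exp(0.605), tolerance = 1e-12)
    expect_lt(o$ci_low, o$or); expect_gt(o$ci_high, o$or)

    fit0 <- new("ModelFit", coef = c(x = 0), vcov = matrix(0.04, 1, 1,
               dimnames = list("x", "x")), logLik = 0, nIter = 1L,
               converged = TRUE, separation = FALSE, nUsed = 10L)
    o0 <- oddsRatioWald(fit0, "x")
    expect_equal(o0$or, 1)
    expect_true(o0$ci_low < 1 && o0$ci_high > 1)
    expect_equal(o0$p, 1)

    fitSe0 <- new("ModelFit", coef = c(x = log(2)), vcov = matrix(0, 1, 1,
               dimnames = list("x", "x")), logLik = 0, nIter = 1L,
               converged = TRUE, separation = FALSE, nUsed = 10L)
    oSe0 <- oddsRatioWald(fitSe0, "x")
    expect_equal(c(oSe0$ci_low, oSe0$ci_high), c(2, 2))
})

test_that("Wald calibration: null slope exceeds 4 SE only rarely", {
    set.seed(111)
    hits <- vapply(1:60, function(i) {
        x <- rnorm(2000); y <- rbinom(2000, 1, 0.3)
        fit <- fitLogistic(y, cbind(1, x = x))
        abs(fit@coef[["x"]] / sqrt(fit@vcov["x", "x"])) > 4
    }, logical(1))
    expect_lt(mean(hits), 0.05)
})

test_that("multinomial logit with one case category equals the binary fit", {
    set.seed(112)
    n <- 800
    x <- rnorm(n); z <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, stats::plogis(-1 + 0.8 * x - 0.4 * z))
    X <- cbind(`(Intercept)` = 1, x = x, z = z)
    bin <- fitLogistic(y, X)
    mm <- fitMultinomial(factor(ifelse(y == 1, "case", "control"),
                                levels = c("control", "case")), X)
    expect_equal(unname(mm$coef[paste0("case:", colnames(X))]),
                 unname(bin@coef), tolerance = 1e-6)
    expect_equal(mm$logLik, bin@logLik, tolerance = 1e-8)
})

test_that("unconstrained multinomial matches an independent implementation", {
    skip_if_not_installed("nnet")
    set.seed(113)
    n <- 1200
    x <- rnorm(n)
    eta1 <- -1 + 0.5 * x; eta2 <- -1.5 + 1.0 * x
    den <- 1 + exp(eta1) + exp(eta2)
    u <- runif(n)
    y <- ifelse(u < exp(eta1) / den, "A", ifelse(u < (exp(eta1) + exp(eta2)) / den, "B", "control"))
    y <- factor(y, levels = c("control", "A", "B"))
    X <- cbind(`(Intercept)` = 1, x = x)
    mine <- fitMultinomial(y, X)
    ref <- nnet::multinom(y ~ x, trace = FALSE, reltol = 1e-12)
    rc <- coef(ref)
    expect_equal(unname(mine$coef[c("A:(Intercept)", "A:x")]),
                 unname(rc["A", ]), tolerance = 1e-4)
    expect_equal(unname(mine$coef[c("B:(Intercept)", "B:x")]),
                 unname(rc["B", ]), tolerance = 1e-4)
})

test_that("c-statistic equals the pairwise oracle and external reference", {
    expect_equal(cStatistic(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)

    set.seed(114)
    for (i in 1:5) {
        n <- 400
        pred <- round(runif(n), 2)       # rounding forces ties
        y <- rbinom(n, 1, 0.4)
        cs <- cStatistic(pred, y)
        expect_equal(cs$auc, aucPairOracle(pred, y), tolerance = 1e-12)
        if (requireNamespace("pROC", quietly = TRUE))
            expect_equal(cs$auc,
                         as.numeric(pROC::auc(pROC::roc(
                             y, pred, quiet = TRUE, direction = "<",
                             levels = c(0, 1)))),
                         tolerance = 1e-12)
    }

    ## null predictions give AUC near 0.5; single-class outcome undefined
    set.seed(115)
    y <- rbinom(5000, 1, 0.5)
    cs0 <- cStatistic(runif(5000), y)
    expect_lt(abs(cs0$auc - 0.5), 0.05)
    expect_false(cStatistic(runif(10), rep(1, 10))$defined)
})

test_that("Kruskal-Wallis matches the direct rank formula and Wilcoxon", {
    expect_equal(kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$H,
                 7.2, tolerance = 1e-12)
    expect_equal(kruskalWallis(list(c(1, 1, 1), c(1, 1)))$H, 0)

    set.seed(116)
    a <- rnorm(30); b <- rnorm(25, 0.5)
    kw <- kruskalWallis(list(a, b))
    wx <- stats::wilcox.test(a, b, correct = FALSE, exact = FALSE)
    expect_equal(kw$p, wx$p.value, tolerance = 1e-6)
})

test_that("2x2 machinery: cross-product OR, Woolf CI, zero-cell handling", {
    t2 <- twoByTwo(50, 597, 103, 553)
    expect_equal(t2$or, (50 * 553) / (597 * 103), tolerance = 1e-12)
    expect_equal(t2$or, 0.450, tolerance = 0.002)
    expect_lt(t2$ci_low, t2$or); expect_gt(t2$ci_high, t2$or)

    expect_equal(twoByTwo(10, 10, 10, 10)$or, 1)

    z <- twoByTwo(0, 10, 5, 10)
    expect_false(z$estimable)
    expect_true(is.finite(z$p_fisher))
    zh <- twoByTwo(0, 10, 5, 10, haldane = TRUE)
    expect_equal(zh$or, (0.5 * 10.5) / (10.5 * 5.5), tolerance = 1e-12)
})

test_that("quintile association keeps the middle-quintile reference at OR 1", {
    co <- smallCohort()
    ss <- scoreCohort(co)
    sd_ <- sampleData(co)
    y <- as.integer(sd_$phenotype != "control")
    at <- quintileAssociation(ss$quantile_category, y, sd_)
    tb <- associationTable(at)
    expect_equal(tb$contrast, paste0("Q", 1:5))
    expect_equal(tb$or_[tb$contrast == "Q3"], 1)
    expect_equal(sum(tb$n_cases), sum(y))
    expect_equal(sum(tb$n_controls), sum(y == 0))
    ## monotone risk was injected, so Q5 exceeds Q1
    expect_gt(tb$or_[5], tb$or_[1])
    ## degenerate constant outcome flags every contrast
    atBad <- quintileAssociation(ss$quantile_category, rep(0, length(y)), sd_)
    expect_true(all(is.na(associationTable(atBad)$or_[-3])))
})

test_that("per-SNP log-additive models recover effects and lose power at low MAF", {
    set.seed(117)
    n <- 5000
    mkSnp <- function(maf) rbinom(n, 2, maf)
    age <- rnorm(n, 64, 10); male <- rbinom(n, 1, 0.45)
    covs <- data.frame(age = age, sex = ifelse(male == 1, "M", "F"))
    seFor <- function(maf) {
        g <- mkSnp(maf)
        y <- rbinom(n, 1, stats::plogis(-1 + log(1.4) * g))
        pan <- S4Vectors::DataFrame(variant_id = "v1", chrom = "1", pos = 1L,
                                    risk_allele = "G", other_allele = "A",
                                    weight = log(1.4), freq_EUR = maf)
        ge <- GenotypeExperiment(matrix(g, nrow = 1), pan,
                                 cbind(data.frame(sample_id = as.character(1:n)),
                                       covs))
        tab <- perSnpAssociation(ge, y)
        c(est = log(tab$or_), se = (log(tab$ci_high) - log(tab$ci_low)) /
              (2 * 1.959964))
    }
    common <- seFor(0.3)
    rare <- seFor(0.05)
    expect_lt(abs(common[["est"]] - log(1.4)), 4 * common[["se"]])
    expect_gt(rare[["se"]], common[["se"]])

    ## monomorphic variant yields a non-estimable row
    pan <- S4Vectors::DataFrame(variant_id = "v1", chrom = "1", pos = 1L,
                                risk_allele = "G", other_allele = "A",
                                weight = 0.1, freq_EUR = 0)
    geM <- GenotypeExperiment(matrix(0, 1, 50), pan,
                              data.frame(sample_id = as.character(1:50),
                                         age = 60, sex = "F"))
    expect_true(is.na(perSnpAssociation(geM, rbinom(50, 1, 0.5))$or_))
})

test_that("heterogeneity test: degeneracy, null calibration, and graded power", {
    co <- smallCohort()
    ss <- scoreCohort(co)
    sd_ <- sampleData(co)

    ## collapsing to one case category: constrained == unconstrained, LRT ~ 0
    oneCase <- factor(ifelse(sd_$phenotype == "control", "control", "case"),
                      levels = c("control", "case"))
    h1 <- heterogeneityTest(oneCase, ss$prs_weighted, sd_)
    expect_lt(h1@lrt, 1e-4)
    expect_equal(h1@pHet, 1)

    ## null calibration: identical true slopes, rejection ~ 5% at alpha 0.05
    set.seed(118)
    nrep <- 400
    rej <- logical(nrep)
    for (i in seq_len(nrep)) {
        n <- 240
        prs <- rnorm(n, 7.5, 1)
        age <- rnorm(n, 64, 8); sex <- ifelse(runif(n) < 0.45, "M", "F")
        eta <- 0.6 * (prs - 7.5)
        den <- 1 + 2 * exp(eta)
        u <- runif(n)
        y <- ifelse(u < exp(eta) / den, "A",
                    ifelse(u < 2 * exp(eta) / den, "B", "control"))
        h <- heterogeneityTest(factor(y, levels = c("control", "A", "B")),
                               prs, data.frame(age = age, sex = sex))
        rej[i] <- h@pHet < 0.05
    }
    expect_gt(mean(rej), 0.02)
    expect_lt(mean(rej), 0.09)

    ## graded injected slopes: ordered estimates and clear rejection
    h3 <- heterogeneityTest(sd_$phenotype, ss$prs_weighted, sd_)
    expect_equal(h3@df, 2L)
    expect_true(h3@converged)
    expect_gte(h3@lrt, 0)
})

test_that("a confounded exposure loses significance after age/sex adjustment", {
    set.seed(120)
    n <- 2877
    age <- rnorm(n, 64, 10)
    sex <- ifelse(runif(n) < 0.45, "M", "F")
    y <- rbinom(n, 1, stats::plogis(-4 + 0.06 * age))
    expo <- rbinom(n, 1, stats::plogis(-4.5 + 0.065 * age))  # age-driven only
    nullExpo <- rbinom(n, 1, 0.3)
    smp <- data.frame(sample_id = as.character(1:n), age = age, sex = sex,
                      confounded = expo, null_exposure = nullExpo,
                      constant = 1)
    scr <- exposureScreen(smp, c("confounded", "null_exposure", "constant"), y)
    conf <- scr[scr$exposure == "confounded", ]
    expect_lt(conf$crude_p, 0.05)                # crude association present
    expect_true(conf$ci_low < 1 & conf$ci_high > 1)  # adjusted CI covers 1
    nul <- scr[scr$exposure == "null_exposure", ]
    expect_true(nul$ci_low < 1 & nul$ci_high > 1)
    expect_equal(scr$note[scr$exposure == "constant"], "single_level")
})

test_that("lower risk-allele frequencies attenuate quintile OR and c-statistic", {
    ## identical true per-allele effects; the same panel's frequencies are
    ## uniformly shifted down for the second population, shrinking the score
    ## variance -- the top-vs-middle quintile contrast and the model
    ## discrimination both attenuate (the per-unit OR does not, since the
    ## score is the true linear predictor in an LD-free simulation)
    res <- attenuationPair(seedBase = 121, nRep = 2)
    expect_lt(mean(res$aa[, "auc"]), mean(res$ea[, "auc"]))
    expect_lt(mean(res$aa[, "q5"]), mean(res$ea[, "q5"]))
})
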