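#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts: conditional on the observed
#' allele counts, the p-value sums the probabilities of every heterozygote
#' count whose conditional probability does not exceed that of the observed
#' count. Probabilities are built by the standard two-sided recurrence over
#' heterozygote counts, which is numerically stable for the sample sizes seen
#' in genotyping QC. Used as the variant filter at `P < 1e-5` in [qcFilter()].
#'
#' @param nHomRisk,nHet,nHomOther genotype counts (risk-allele homozygote,
#'   heterozygote, other homozygote).
#' @return two-sided exact p-value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)   # modal configuration: p = 1
#' hweExactTest(50, 0, 50)    # extreme heterozygote deficit
#' @export
hweExactTest <- function(nHomRisk, nHet, nHomOther) {
    if (any(c(nHomRisk, nHet, nHomOther) < 0))
        stop("genotype counts must be non-negative")
    n <- nHomRisk + nHet + nHomOther
    if (n < 1) stop("at least one genotyped individual required")
    ## rare allele count; parity of nHet is fixed by the allele count
    nA <- 2 * nHomRisk + nHet
    nB <- 2 * nHomOther + nHet
    nRare <- min(nA, nB)
    if (nRare == 0) return(1)
    hetVals <- seq.int(nRare %% 2, nRare, by = 2)
    probs <- numeric(length(hetVals))
    ## start at the mode-ish midpoint and fill both directions by recurrence:
    ## P(h+2)/P(h) = [ (nA-h)/2 * (nB-h)/2 * 4 ] / [ (h+2)(h+1) ]  (unnorm.)
    mid <- which.min(abs(hetVals - nRare * (max(nA, nB) / (2 * n))))
    probs[mid] <- 1
    if (mid < length(hetVals)) for (i in mid:(length(hetVals) - 1)) {
        h <- hetVals[i]
        probs[i + 1] <- probs[i] * ((nA - h) * (nB - h)) /
            ((h + 2) * (h + 1))
    }
    if (mid > 1) for (i in mid:2) {
        h <- hetVals[i]
        probs[i - 1] <- probs[i] * (h * (h - 1)) /
            ((nA - h + 2) * (nB - h + 2))
    }
    probs <- probs / sum(probs)
    pObs <- probs[match(nHet, hetVals)]
    if (is.na(pObs)) stop("heterozygote count inconsistent with allele counts")
    ## tolerance guards equal-probability configurations against roundoff
    min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

#' Asymptotic chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test against expected proportions
#' p^2, 2pq, q^2; offered as an alternative to the exact test for large,
#' common-allele variants.
#'
#' @inheritParams hweExactTest
#' @return p-value.
#' @export
hweChisqTest <- function(nHomRisk, nHet, nHomOther) {
    n <- nHomRisk + nHet + nHomOther
    if (n < 1) stop("at least one genotyped individual required")
    p <- (2 * nHomRisk + nHet) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(1)
    x2 <- sum((c(nHomRisk, nHet, nHomOther) - e)^2 / e)
    pchisq(x2, df = 1, lower.tail = FALSE)
}

## Genotype counts (hom-risk, het, hom-other) from a dosage vector.
.genoCounts <- function(d) {
    d <- d[!is.na(d)]
    c(sum(d == 2), sum(d == 1), sum(d == 0))
}
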