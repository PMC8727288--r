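#' Supervised admixture proportions for one individual
#'
#' Maximizes the binomial likelihood
#' `sum_j [ g_j log p_j + (2 - g_j) log(1 - p_j) ]` with
#' `p_j = sum_k q_k f_kj` over the K-simplex by EM, with the reference
#' allele-frequency matrix held fixed (the supervised analog of model-based
#' ancestry estimation against reference panels). The log-likelihood is
#' non-decreasing at every iteration; iteration stops when the increase
#' falls below `tol`. Missing dosages are skipped (likelihood over observed
#' sites only); frequencies are clamped to `[1e-6, 1 - 1e-6]`.
#'
#' @param dosages risk-allele dosage vector over variants (0/1/2 or NA).
#' @param refFreqs variants x K matrix of reference risk-allele frequencies,
#'   ancestry labels as column names.
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param maxIter iteration cap; exceeding it flags `converged = FALSE`.
#' @return list with `proportions` (named, sums to 1), `logLik`,
#'   `nIterations`, `converged`, `label` (from [classifyAncestry()] when AFR
#'   and EUR columns are present, else NA).
#' @export
estimateAdmixture <- function(dosages, refFreqs, tol = 1e-6, maxIter = 1000L) {
    refFreqs <- as.matrix(refFreqs)
    K <- ncol(refFreqs)
    if (K < 2) stop("need at least two reference ancestries")
    obs <- !is.na(dosages)
    if (!any(obs)) stop("no non-missing dosages")
    g <- dosages[obs]
    f <- pmin(pmax(refFreqs[obs, , drop = FALSE], 1e-6), 1 - 1e-6)
    q <- rep(1 / K, K)                      # uniform simplex start
    ll <- -Inf
    it <- 0L
    converged <- FALSE
    M <- length(g)
    repeat {
        it <- it + 1L
        p <- as.vector(f %*% q)
        llNew <- sum(g * log(p) + (2 - g) * log1p(-p))
        if (llNew - ll < tol && it > 1L) {
            ll <- llNew; converged <- TRUE; break
        }
        ll <- llNew
        if (it >= maxIter) break
        ## E-step responsibilities, M-step on expected allele-origin counts
        A <- f * rep(q, each = M)            # q_k f_kj
        B <- (1 - f) * rep(q, each = M)      # q_k (1 - f_kj)
        qNew <- colSums(g * A / p + (2 - g) * B / (1 - p)) / (2 * M)
        q <- qNew / sum(qNew)
    }
    q <- setNames(as.vector(q), colnames(refFreqs))
    lab <- if (all(c("AFR", "EUR") %in% names(q)))
        classifyAncestry(q) else NA_character_
    list(proportions = q, logLik = ll, nIterations = it,
         converged = converged, label = lab)
}

#' Admixture estimation for every sample of a GenotypeExperiment
#'
#' @param genotypes \linkS4class{GenotypeExperiment}.
#' @param refFreqs variants x K reference frequency matrix; by default the
#'   panel's own `freq_<ancestry>` columns.
#' @inheritParams estimateAdmixture
#' @return `DataFrame` with one row per sample: proportions, label,
#'   log-likelihood and convergence diagnostics.
#' @export
estimateAdmixtureAll <- function(genotypes, refFreqs = NULL,
                                 tol = 1e-6, maxIter = 5000L) {
    if (is.null(refFreqs)) refFreqs <- ancestryFreqs(genotypes)
    d <- dosageMatrix(genotypes)
    res <- lapply(seq_len(ncol(d)), function(i)
        estimateAdmixture(d[, i], refFreqs, tol, maxIter))
    props <- do.call(rbind, lapply(res, `[[`, "proportions"))
    out <- S4Vectors::DataFrame(sample_id = colnames(d), props,
                                label = vapply(res, `[[`, "", "label"),
                                log_likelihood = vapply(res, `[[`, 0, "logLik"),
                                n_iterations = vapply(res, function(r)
                                    as.integer(r$nIterations), 1L),
                                converged = vapply(res, `[[`, TRUE, "converged"))
    out
}

#' Classify ancestry from admixture proportions
#'
#' The African-American rule is checked first and is inclusive
#' (African proportion >= 50%); the European rule is exclusive
#' (European proportion > 80%); everything else is OTHER.
#'
#' @param proportions named simplex vector containing `AFR` and `EUR`.
#' @return `"AA"`, `"EA"`, or `"OTHER"`.
#' @examples
#' classifyAncestry(c(AFR = 0.5, EUR = 0.5))    # "AA"
#' classifyAncestry(c(AFR = 0.10, EUR = 0.80))  # "OTHER"
#' @export
classifyAncestry <- function(proportions) {
    if (!all(c("AFR", "EUR") %in% names(proportions)))
        stop("proportions must include AFR and EUR")
    if (proportions[["AFR"]] >= 0.50) return("AA")
    if (proportions[["EUR"]] > 0.80) return("EA")
    "OTHER"
}
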