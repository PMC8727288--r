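#' Binary logistic regression with Wald covariance
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (via `stats::glm.fit`), returning the coefficient vector, the Wald
#' covariance from the observed information at convergence, and diagnostics.
#' Complete or quasi-complete separation is detected from fitted
#' probabilities pinned at 0/1 together with diverging coefficients and
#' flagged rather than silently corrected; flagged terms should be reported
#' as non-estimable.
#'
#' @param outcome 0/1 vector (or logical/two-level factor).
#' @param design numeric model matrix including an intercept column.
#' @param tol IRLS convergence tolerance.
#' @param maxIter IRLS iteration cap.
#' @return \linkS4class{ModelFit}.
#' @export
fitLogistic <- function(outcome, design, tol = 1e-10, maxIter = 100L) {
    if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
    outcome <- as.numeric(outcome)
    if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
    design <- as.matrix(design)
    keep <- complete.cases(design) & !is.na(outcome)
    y <- outcome[keep]; X <- design[keep, , drop = FALSE]
    if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
    degenerate <- length(unique(y)) < 2L
    fit <- suppressWarnings(
        glm.fit(X, y, family = binomial(),
                control = list(epsilon = tol, maxit = maxIter)))
    beta <- fit$coefficients
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    ## aliased (collinear) columns get NA coefficients from the QR fit;
    ## invert the information on the estimable block only
    est <- !is.na(beta)
    vc <- matrix(NA_real_, ncol(X), ncol(X),
                 dimnames = list(colnames(X), colnames(X)))
    info <- crossprod(X[, est, drop = FALSE] * sqrt(w))
    vc[est, est] <- tryCatch(solve(info), error = function(e)
        matrix(NA_real_, sum(est), sum(est)))
    eps <- 1e-8
    separation <- degenerate ||
        ((any(mu < eps) || any(mu > 1 - eps)) &&
         any(abs(beta) > 10, na.rm = TRUE))
    ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    new("ModelFit", coef = beta, vcov = vc, logLik = ll,
        nIter = as.integer(fit$iter),
        converged = isTRUE(fit$converged) && !separation,
        separation = separation, nUsed = as.integer(sum(keep)))
}

#' Odds ratio with Wald confidence interval from a fitted model
#'
#' `OR = exp(scale * beta)`, CI `exp(scale * (beta +/- z * SE))` with
#' `z = 1.959964`, two-sided Wald p-value. `scale` rescales the contrast
#' (e.g. `scale = 10` turns a per-year age coefficient into a per-decade
#' odds ratio).
#'
#' @param fit \linkS4class{ModelFit}.
#' @param term coefficient name.
#' @param scale multiplier applied to the coefficient before exponentiation.
#' @return list(or, ci_low, ci_high, p, estimable).
#' @export
oddsRatioWald <- function(fit, term, scale = 1) {
    if (!term %in% names(fit@coef)) stop("no such term: ", term)
    b <- fit@coef[[term]]
    se <- sqrt(fit@vcov[term, term])
    if (fit@separation || !is.finite(b) || !is.finite(se))
        return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_, estimable = FALSE))
    z <- 1.959964
    p <- if (se == 0) as.numeric(b == 0)
         else 2 * pnorm(-abs(b / se))
    list(or = exp(scale * b),
         ci_low = exp(scale * (b - z * se)),
         ci_high = exp(scale * (b + z * se)),
         p = p, estimable = TRUE)
}

## Build an age+sex (plus extras) design matrix with intercept.
.covDesign <- function(samples, extra = NULL) {
    sd_ <- as.data.frame(samples)
    X <- cbind(`(Intercept)` = 1,
               age = sd_$age,
               male = as.integer(sd_$sex == "M"))
    if (!is.null(extra)) X <- cbind(X, extra)
    X
}
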