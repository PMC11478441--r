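#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Wraps the binomial IRLS fitter (\code{stats::glm.fit}, tolerance
#' 1e-10, at most 100 iterations) and augments the result with the
#' observed-information standard errors, the log-likelihood and a
#' quasi-complete-separation flag: when any coefficient diverges beyond
#' 20 on the log-odds scale, or a standard error beyond 100, the fit is
#' returned flagged non-converged rather than reported silently.
#'
#' @param y binary 0/1 response.
#' @param X design matrix (include an intercept column yourself or use
#'   \code{addIntercept = TRUE}); must be full column rank on the rows
#'   used.
#' @param weights optional prior case weights (e.g. aggregated tables).
#' @param addIntercept prepend a column of ones (default \code{TRUE}).
#' @return object of class \code{"GLMFit"}: list with
#'   \code{coefficients}, \code{se}, \code{loglik}, \code{converged},
#'   \code{separation}, \code{iterations}, \code{fitted}, \code{n},
#'   \code{df}.
#' @examples
#' y <- rep(c(1, 0), c(3, 7))
#' fitLogistic(y, NULL)$coefficients   # logit(0.3)
#' @export
fitLogistic <- function(y, X = NULL, weights = NULL, addIntercept = TRUE) {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
    n <- length(y)
    if (is.null(X)) X <- matrix(numeric(0), n, 0)
    X <- as.matrix(X)
    if (addIntercept)
        X <- cbind(`(Intercept)` = 1, X)
    if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (is.null(weights)) weights <- rep(1, n)
    cc <- stats::complete.cases(X) & !is.na(y)
    Xc <- X[cc, , drop = FALSE]; yc <- y[cc]; wc <- weights[cc]
    if (nrow(Xc) < ncol(Xc))
        stop("fewer complete-case rows than design columns")
    if (qr(Xc)$rank < ncol(Xc))
        stop("design matrix is rank deficient on complete cases")
    fit <- stats::glm.fit(Xc, yc, weights = wc,
                          family = stats::binomial(),
                          control = stats::glm.control(epsilon = 1e-10,
                                                       maxit = 100))
    beta <- fit$coefficients
    mu <- fit$fitted.values
    w <- wc * mu * (1 - mu)
    info <- crossprod(Xc * w, Xc)
    se <- suppressWarnings(sqrt(diag(solve(info))))
    ll <- sum(wc * (yc * log(pmax(mu, 1e-300)) +
                    (1 - yc) * log(pmax(1 - mu, 1e-300))))
    separation <- any(abs(beta) > 20) || any(!is.finite(se)) ||
        any(se > 100)
    structure(list(coefficients = beta, se = se, loglik = ll,
                   converged = fit$converged && !separation,
                   separation = separation,
                   iterations = fit$iter, fitted = mu,
                   n = nrow(Xc), df = ncol(Xc),
                   rows = which(cc)),
              class = "GLMFit")
}

#' @export
print.GLMFit <- function(x, ...) {
    cat("GLMFit: n =", x$n, ", loglik =", round(x$loglik, 3),
        if (!x$converged) "(NOT converged)" else "", "\n")
    print(round(cbind(beta = x$coefficients, se = x$se), 4))
    invisible(x)
}

#' Wald odds ratio with 95\% confidence interval
#'
#' OR = exp(beta), CI = exp(beta +/- 1.96 se), two-sided Wald p.
#'
#' @param fit a converged \code{\link{fitLogistic}} result.
#' @param term coefficient name.
#' @return list with \code{or}, \code{ciLow}, \code{ciHigh}, \code{p},
#'   \code{beta}, \code{se}.
#' @examples
#' y <- rep(c(1, 0, 1, 0), c(10, 90, 5, 95))
#' x <- rep(c(1, 1, 0, 0), c(10, 90, 5, 95))
#' waldOR(fitLogistic(y, cbind(exposed = x)), "exposed")$or
#' @export
waldOR <- function(fit, term) {
    if (!fit$converged)
        stop("fit did not converge (separation = ", fit$separation,
             ", iterations = ", fit$iterations, ")")
    if (!term %in% names(fit$coefficients))
        stop("unknown term '", term, "'")
    b <- fit$coefficients[[term]]
    s <- fit$se[[match(term, names(fit$coefficients))]]
    if (!is.finite(s)) stop("standard error not finite for '", term, "'")
    z <- b / s
    list(or = exp(b), ciLow = exp(b - 1.96 * s),
         ciHigh = exp(b + 1.96 * s),
         p = 2 * stats::pnorm(-abs(z)), beta = b, se = s)
}

#' Likelihood-ratio test of nested logistic models
#'
#' @param full,reduced converged \code{\link{fitLogistic}} results, the
#'   reduced model nested in the full one and fitted on the same rows.
#' @param df difference in number of parameters.
#' @return upper-tail chi-square p-value.
#' @export
lrt <- function(full, reduced, df) {
    if (!full$converged || !reduced$converged)
        stop("both fits must have converged")
    stat <- 2 * (full$loglik - reduced$loglik)
    if (stat < -1e-8)
        stop("nesting violation: full model has lower likelihood")
    stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
}

#' Named covariate presets
#'
#' \code{"set1"}: the screening-stage adjustment (age, sex, residence,
#' BMI, energy intake, education, income). \code{"set2"}: the
#' modelling-stage adjustment (age, sex, BMI, residence, exercise,
#' education, income, smoking, alcohol, energy intake).
#'
#' @param name \code{"set1"} or \code{"set2"}.
#' @return character vector of column names.
#' @export
covariateSet <- function(name = c("set1", "set2")) {
    switch(match.arg(name),
        set1 = c("age", "sex", "residence", "bmi", "energy",
                 "education", "income"),
        set2 = c("age", "sex", "bmi", "residence", "exercise",
                 "education", "income", "smoking", "alcohol", "energy"))
}

## Expand a covariate data frame into a numeric design matrix:
## factors/characters become treatment-coded indicator columns.
buildDesign <- function(data, covariates) {
    if (!length(covariates))
        return(matrix(numeric(0), nrow(data), 0))
    miss <- setdiff(covariates, colnames(data))
    if (length(miss))
        stop("covariates not found: ", paste(miss, collapse = ", "))
    df <- as.data.frame(data[, covariates, drop = FALSE])
    for (nm in colnames(df))
        if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    mm <- stats::model.matrix(
        ~ ., data = df,
        contrasts.arg = lapply(Filter(is.factor, df),
                               stats::contrasts, contrasts = TRUE))
    mm[, -1, drop = FALSE]   # drop intercept; fitLogistic adds its own
}

#' Covariate-adjusted logistic GWAS scan
#'
#' For each SNP, its additive minor-allele dosage (0/1/2) is added to
#' the covariate-only logistic model; the per-allele odds ratio, Wald
#' p-value and a pass flag at \code{alpha} are recorded. Rows with a
#' missing covariate are dropped globally (complete-case); rows missing
#' the SNP call are dropped for that SNP only. A SNP monomorphic on the
#' analysed rows, or whose fit is flagged for separation, is skipped
#' with a recorded reason.
#'
#' @param cohort a \linkS4class{CohortExperiment} with an
#'   \code{outcome} column.
#' @param covariates character vector of colData column names (see
#'   \code{\link{covariateSet}}); default none.
#' @param alpha screening threshold (default 5e-4).
#' @return \code{DataFrame}: \code{snp}, \code{beta}, \code{se},
#'   \code{or}, \code{ciLow}, \code{ciHigh}, \code{p}, \code{pass},
#'   \code{note}.
#' @examples
#' ce <- simulateCohort(defaultCohortConfig(), seed = 5,
#'                      design = "balanced", nCase = 150, nControl = 150)
#' gwasScan(ce, covariates = c("age", "sex"))
#' @export
gwasScan <- function(cohort, covariates = character(), alpha = 5e-4) {
    y <- cohortOutcome(cohort)
    if (is.null(y)) stop("cohort has no outcome column")
    g <- dosage(cohort)
    Z <- buildDesign(colData(cohort), covariates)
    cc <- stats::complete.cases(Z) & !is.na(y)
    yc <- y[cc]; Zc <- Z[cc, , drop = FALSE]; gc <- g[, cc, drop = FALSE]
    rows <- lapply(seq_len(nrow(gc)), function(i) {
        gi <- gc[i, ]
        use <- !is.na(gi)
        base <- data.frame(snp = rownames(gc)[i], beta = NA_real_,
                           se = NA_real_, or = NA_real_,
                           ciLow = NA_real_, ciHigh = NA_real_,
                           p = NA_real_, pass = FALSE, note = "")
        if (length(unique(gi[use])) < 2) {
            base$note <- "monomorphic"
            return(base)
        }
        fit <- tryCatch(
            fitLogistic(yc[use],
                        cbind(Zc[use, , drop = FALSE], snp = gi[use])),
            error = function(e) e)
        if (inherits(fit, "error")) {
            base$note <- conditionMessage(fit)
            return(base)
        }
        if (!fit$converged) {
            base$note <- if (fit$separation) "separation" else
                "not converged"
            return(base)
        }
        w <- waldOR(fit, "snp")
        base[c("beta", "se", "or", "ciLow", "ciHigh", "p")] <-
            list(w$beta, w$se, w$or, w$ciLow, w$ciHigh, w$p)
        base$pass <- w$p < alpha
        base
    })
    out <- DataFrame(do.call(rbind, rows))
    rownames(out) <- out$snp
    metadata(out) <- list(alpha = alpha, covariates = covariates,
                          n = sum(cc))
    out
}
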