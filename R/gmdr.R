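#' Score residuals for generalized MDR
#'
#' Per-sample score s_i = y_i - p_i where p_i is the fitted probability
#' of the null (covariate-only, or intercept-only) logistic model. With
#' an intercept present the scores sum to zero, so pooling cell scores
#' against a threshold of zero compares each multilocus cell against
#' the covariate-adjusted baseline risk.
#'
#' @param outcome binary 0/1 vector.
#' @param covariates optional numeric design (matrix/data.frame) of
#'   null-model covariates; factors are expanded.
#' @return numeric score vector (same length/order as \code{outcome}).
#' @examples
#' scoreResiduals(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
#' @export
scoreResiduals <- function(outcome, covariates = NULL) {
    X <- if (is.null(covariates)) NULL
         else buildDesign(as.data.frame(covariates),
                          colnames(as.data.frame(covariates)))
    fit <- fitLogistic(outcome, X)
    if (!fit$converged)
        stop("null model did not converge (possible separation)")
    s <- rep(NA_real_, length(outcome))
    s[fit$rows] <- as.numeric(outcome[fit$rows]) - fit$fitted
    s
}

## Integer cell id (1-based) for a combination of dosage rows: base-3
## code over the combination's genotypes. Samples with any missing
## genotype get NA.
cellIds <- function(g) {
    k <- nrow(g)
    id <- rep(1L, ncol(g))
    for (i in seq_len(k)) id <- id + as.integer(g[i, ]) * 3L^(i - 1L)
    id
}

#' Label multilocus genotype cells high/low risk
#'
#' Samples are partitioned by their exact multilocus genotype at the
#' combination's SNPs; a cell is labeled high-risk iff the sum of its
#' members' score residuals exceeds \code{threshold} (default 0, the
#' centred-score convention). Cells never observed are low-risk by
#' default. Samples with a missing genotype at any SNP of the
#' combination are excluded.
#'
#' @param g dosage matrix restricted to the combination (SNP x sample).
#' @param scores score residuals aligned with the samples.
#' @param threshold cell score-sum threshold (default 0).
#' @return \code{DataFrame}: \code{cell} (genotype key, e.g. "1|2"),
#'   \code{n}, \code{scoreSum}, \code{highRisk}.
#' @examples
#' g <- rbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1))
#' labelCells(g, c(0.6, -0.4, 0.7, 0.7))
#' @export
labelCells <- function(g, scores, threshold = 0) {
    g <- rbind(g)
    ok <- colSums(is.na(g)) == 0 & !is.na(scores)
    if (!any(ok))
        return(DataFrame(cell = character(), n = integer(),
                         scoreSum = numeric(), highRisk = logical()))
    gg <- g[, ok, drop = FALSE]
    key <- apply(gg, 2, paste, collapse = "|")
    sums <- rowsum(scores[ok], key)
    ns <- as.integer(table(key)[rownames(sums)])
    DataFrame(cell = rownames(sums), n = ns,
              scoreSum = as.numeric(sums),
              highRisk = as.numeric(sums) > threshold)
}

#' Balanced accuracy of a high/low-risk classification
#'
#' Samples in high-risk cells are predicted cases; balanced accuracy is
#' (sensitivity + specificity) / 2.
#'
#' @param predictedHigh logical per-sample prediction.
#' @param outcome binary 0/1.
#' @return balanced accuracy in [0, 1]; errors if the evaluated set
#'   lacks a case or a control.
#' @examples
#' balancedAccuracy(rep(c(TRUE, FALSE, FALSE, TRUE), c(8, 2, 6, 4)),
#'                  rep(c(1, 0), c(10, 10)))   # 0.7
#' @export
balancedAccuracy <- function(predictedHigh, outcome) {
    if (!any(outcome == 1) || !any(outcome == 0))
        stop("balanced accuracy undefined: single-class evaluation set")
    sens <- mean(predictedHigh[outcome == 1])
    spec <- mean(!predictedHigh[outcome == 0])
    (sens + spec) / 2
}

#' Stratified cross-validation fold plan
#'
#' Assigns each sample a fold in 1..nFolds, stratified by case status
#' so that fold sizes differ by at most one within each outcome class
#' (essential for rare outcomes, where unstratified folds can lose all
#' cases).
#'
#' @param outcome binary 0/1.
#' @param nFolds number of folds (default 10).
#' @param seed integer seed.
#' @return integer fold vector.
#' @export
makeCVPlan <- function(outcome, nFolds = 10, seed) {
    set.seed(as.integer(seed))
    fold <- integer(length(outcome))
    for (cls in unique(outcome)) {
        idx <- which(outcome == cls)
        fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    fold
}

#' Cross-validate one SNP combination
#'
#' For each fold: cells are labeled on the training nine-tenths, the
#' labels applied to the held-out tenth (test cells unseen in training
#' are low-risk), and trained/testing balanced accuracies (TRBA/TEBA)
#' computed. A fold whose training or test part lacks a class is
#' recorded with \code{NA}.
#'
#' @param g dosage matrix restricted to the combination.
#' @param scores score residuals (see \code{\link{scoreResiduals}}).
#' @param outcome binary 0/1.
#' @param plan fold assignment from \code{\link{makeCVPlan}}.
#' @param threshold cell-labeling threshold (default 0).
#' @return \code{data.frame} with one row per fold: \code{fold},
#'   \code{trba}, \code{teba}.
#' @export
crossValidate <- function(g, scores, outcome, plan, threshold = 0) {
    g <- rbind(g)
    ok <- colSums(is.na(g)) == 0 & !is.na(scores) & !is.na(outcome)
    g <- g[, ok, drop = FALSE]
    scores <- scores[ok]; outcome <- outcome[ok]; plan <- plan[ok]
    id <- cellIds(g)
    nFolds <- max(plan)
    res <- lapply(seq_len(nFolds), function(f) {
        tr <- plan != f
        if (length(unique(outcome[tr])) < 2 ||
            length(unique(outcome[!tr])) < 2)
            return(data.frame(fold = f, trba = NA_real_,
                              teba = NA_real_))
        sums <- rowsum(scores[tr], id[tr])
        highCells <- as.integer(rownames(sums))[sums[, 1] > threshold]
        predTr <- id[tr] %in% highCells
        predTe <- id[!tr] %in% highCells   # unseen cells -> low risk
        data.frame(fold = f,
                   trba = balancedAccuracy(predTr, outcome[tr]),
                   teba = balancedAccuracy(predTe, outcome[!tr]))
    })
    do.call(rbind, res)
}

#' Exact Wilcoxon signed-rank test of fold accuracies against 0.5
#'
#' Two-sided signed-rank test of the per-fold testing balanced
#' accuracies against the chance value 0.5, using the exact null
#' distribution (ties or zeros fall back to the usual approximation
#' with a warning suppressed but recorded).
#'
#' @param x numeric fold accuracies (typically 10 values).
#' @param nullValue chance accuracy (default 0.5).
#' @return p-value; exactly 1 (with a warning) when every fold equals
#'   the null value.
#' @examples
#' signedRankTest(0.5 + (1:10) / 100)   # 2 / 2^10
#' @export
signedRankTest <- function(x, nullValue = 0.5) {
    x <- x[!is.na(x)]
    if (!length(x)) stop("no fold accuracies supplied")
    d <- x - nullValue
    if (all(d == 0)) {
        warning("all folds exactly at the null value; p = 1")
        return(1)
    }
    if (sum(d != 0) < 6)
        warning("fewer than 6 non-tied folds; signed-rank p unstable")
    suppressWarnings(
        stats::wilcox.test(x, mu = nullValue, exact = TRUE,
                           correct = FALSE)$p.value)
}

## Deterministic tie-break helper: index of the maximum, preferring the
## lexicographically smallest SNP-id combination so results do not
## depend on enumeration order.
whichBest <- function(values, keys) {
    mx <- max(values, na.rm = TRUE)
    cand <- which(!is.na(values) & values >= mx - 1e-12)
    cand[order(keys[cand])][1]
}

#' Exhaustive GMDR model search
#'
#' Cross-validates every k-SNP combination of the candidate set for
#' each k in \code{kRange}. Within each fold the fold-best combination
#' is the one with the highest training balanced accuracy; per k, the
#' selected model is the modal fold-best combination and its CVC the
#' number of folds that chose it (ties broken by higher mean TEBA).
#' The overall best model minimises the exact signed-rank p of its fold
#' TEBAs against 0.5, ties broken by higher CVC then higher TEBA. All
#' tie-breaks resolve to the lexicographically smallest combination, so
#' the result is invariant to enumeration order.
#'
#' @param cohort \linkS4class{CohortExperiment} (or dosage matrix plus
#'   \code{outcome}).
#' @param candidates character SNP ids to search over.
#' @param kRange integer vector of combination sizes.
#' @param covariates optional covariate columns for the null-model
#'   score residuals.
#' @param nFolds folds (default 10).
#' @param seed seed for the fold plan.
#' @param threshold cell-labeling threshold (default 0).
#' @param budget maximum number of combinations (default 20000).
#' @param outcome optional explicit outcome (when \code{cohort} is a
#'   bare matrix).
#' @param plan optional explicit fold plan (overrides \code{seed}).
#' @return a \linkS4class{GMDRResult}.
#' @examples
#' ce <- simulateCohort(defaultCohortConfig(), seed = 11,
#'                      design = "balanced", nCase = 250, nControl = 250)
#' gmdrSearch(ce, rownames(ce)[1:4], kRange = 2, seed = 1)
#' @export
gmdrSearch <- function(cohort, candidates, kRange, covariates = NULL,
                       nFolds = 10, seed = 1, threshold = 0,
                       budget = 20000, outcome = NULL, plan = NULL) {
    if (is(cohort, "CohortExperiment")) {
        g <- dosage(cohort)
        outcome <- outcome %||% cohortOutcome(cohort)
        covData <- if (!is.null(covariates))
            as.data.frame(colData(cohort))[, covariates, drop = FALSE]
    } else {
        g <- as.matrix(cohort)
        covData <- covariates
    }
    if (is.null(outcome)) stop("outcome required")
    stopifnot(all(candidates %in% rownames(g)),
              all(kRange >= 1), all(kRange <= length(candidates)))
    nComb <- sum(choose(length(candidates), kRange))
    if (nComb > budget)
        stop("search budget exceeded: ", nComb, " combinations > ",
             budget, "; reduce kRange or raise budget")
    scores <- scoreResiduals(outcome, covData)
    plan <- plan %||% makeCVPlan(outcome, nFolds, seed)
    nFolds <- max(plan)

    perK <- list()
    for (k in sort(unique(kRange))) {
        combs <- utils::combn(sort(candidates), k, simplify = FALSE)
        keys <- vapply(combs, paste, "", collapse = "+")
        trba <- matrix(NA_real_, length(combs), nFolds)
        teba <- matrix(NA_real_, length(combs), nFolds)
        for (ci in seq_along(combs)) {
            cv <- crossValidate(g[combs[[ci]], , drop = FALSE], scores,
                                outcome, plan, threshold)
            trba[ci, ] <- cv$trba
            teba[ci, ] <- cv$teba
        }
        foldBest <- vapply(seq_len(nFolds), function(f) {
            if (all(is.na(trba[, f]))) NA_integer_
            else whichBest(trba[, f], keys)
        }, 1L)
        tab <- table(foldBest)
        topCount <- max(tab)
        cand <- as.integer(names(tab)[tab == topCount])
        bi <- if (length(cand) > 1) {  # tie: higher mean TEBA, lexicomin
            means <- vapply(cand, function(i)
                mean(teba[i, ], na.rm = TRUE), 1.0)
            cand[whichBest(means, keys[cand])]
        } else cand
        p <- signedRankTest(teba[bi, ])
        perK[[as.character(k)]] <- list(
            k = k, snps = combs[[bi]],
            trba = mean(trba[bi, ], na.rm = TRUE),
            teba = mean(teba[bi, ], na.rm = TRUE),
            cvc = as.integer(topCount), p = p,
            folds = data.frame(fold = seq_len(nFolds),
                               trba = trba[bi, ], teba = teba[bi, ],
                               foldBest = foldBest == bi))
    }
    models <- DataFrame(
        k = vapply(perK, function(m) as.integer(m$k), 1L),
        snps = vapply(perK, function(m) paste(m$snps, collapse = "+"), ""),
        trba = vapply(perK, `[[`, 1.0, "trba"),
        teba = vapply(perK, `[[`, 1.0, "teba"),
        cvc = vapply(perK, `[[`, 1L, "cvc"),
        p = vapply(perK, `[[`, 1.0, "p"))
    ## overall best: minimal signed-rank p, ties by CVC then TEBA then
    ## lexicographically smallest model
    ord <- order(models$p, -models$cvc, -models$teba, models$snps)
    best <- perK[[ord[1]]]
    new("GMDRResult", models = models, best = best,
        folds = DataFrame(best$folds),
        nEvaluated = nComb, nFolds = as.integer(nFolds))
}
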