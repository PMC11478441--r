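#' Define a lifestyle stratum
#'
#' A numeric exposure is split at a cutoff (low iff value < cutoff,
#' strict, matching conventions such as "low WBC" = count < 4e9/L and
#' "low coffee" = < 3 g/day); smoking status is mapped specially
#' (non-smokers vs former + current pooled).
#'
#' @param variable column name of the exposure.
#' @param cutoff numeric cutoff (ignored for \code{type = "smoking"}).
#' @param labels two labels, low then high.
#' @param type \code{"numeric"} or \code{"smoking"}.
#' @return classed list of class \code{"StratumDefinition"}.
#' @export
stratumDefinition <- function(variable, cutoff = NA_real_,
                              labels = c("low", "high"),
                              type = c("numeric", "smoking")) {
    type <- match.arg(type)
    if (type == "numeric" && !is.finite(cutoff))
        stop("numeric stratum requires a finite cutoff")
    structure(list(variable = variable, cutoff = cutoff,
                   labels = labels, type = type),
              class = "StratumDefinition")
}

#' Shipped stratum presets
#'
#' \code{wbc}: white blood cell count < 4 (1e9/L); \code{coffee}:
#' < 3 g/day; \code{energy}: < 100 (percent of estimated need);
#' \code{carbohydrate}: < 65 En\%; \code{protein}: < 13 En\%;
#' \code{fat}: < 20 En\%; \code{smoking}: non vs former + current.
#'
#' @param name preset name.
#' @return a \code{\link{stratumDefinition}}.
#' @export
stratumPreset <- function(name = c("wbc", "coffee", "energy",
                                   "carbohydrate", "protein", "fat",
                                   "smoking")) {
    switch(match.arg(name),
        wbc = stratumDefinition("wbc", 4),
        coffee = stratumDefinition("coffee", 3),
        energy = stratumDefinition("energy", 100),
        carbohydrate = stratumDefinition("carbohydrate", 65),
        protein = stratumDefinition("protein", 13),
        fat = stratumDefinition("fat", 20),
        smoking = stratumDefinition("smoking", type = "smoking",
                                    labels = c("non", "smoke+former")))
}

#' Dichotomize an exposure into low/high strata
#'
#' @param values numeric exposure values, or smoking categories
#'   (\code{"non"/"former"/"current"}) for a smoking definition.
#' @param definition a \code{\link{stratumDefinition}}.
#' @return factor with the definition's two labels; missing exposures
#'   stay \code{NA} and the count is attached as attribute
#'   \code{"nMissing"}.
#' @examples
#' dichotomize(c(3.9, 4.0), stratumPreset("wbc"))  # low, high
#' @export
dichotomize <- function(values, definition) {
    if (definition$type == "smoking") {
        v <- as.character(values)
        bad <- !is.na(v) & !v %in% c("non", "former", "current")
        if (any(bad))
            stop("unknown smoking status: ",
                 paste(unique(v[bad]), collapse = ", "))
        lab <- ifelse(v == "non", definition$labels[1],
                      definition$labels[2])
    } else {
        v <- as.numeric(values)
        lab <- ifelse(v < definition$cutoff, definition$labels[1],
                      definition$labels[2])
    }
    structure(factor(lab, levels = definition$labels),
              nMissing = sum(is.na(lab)))
}

#' Stratified adjusted odds ratios by PRS category
#'
#' Within each stratum level, a logistic model of the outcome on PRS
#' category indicators plus covariates is fitted; odds ratios are
#' reported against the low-PRS reference (within-stratum reference by
#' default; \code{reference = "pooled"} instead fits one model with
#' stratum main effects and PRS-by-stratum terms so all cells share the
#' pooled low-PRS baseline). Cells that are empty or whose fit is
#' flagged (separation/non-convergence) are marked inestimable rather
#' than fabricated. The gene-environment interaction p-value (see
#' \code{\link{interactionPvalue}}) is attached.
#'
#' @param outcome binary 0/1.
#' @param prsCat factor low/medium/high.
#' @param stratum two-level factor from \code{\link{dichotomize}}.
#' @param covariates optional data.frame of adjustment covariates.
#' @param reference \code{"within"} or \code{"pooled"}.
#' @return \code{DataFrame} with one row per stratum x PRS category:
#'   \code{stratum}, \code{prs}, \code{n}, \code{cases}, \code{or},
#'   \code{ciLow}, \code{ciHigh}, \code{p}, \code{note};
#'   \code{metadata()} carries \code{interactionP}.
#' @export
stratifiedOR <- function(outcome, prsCat, stratum, covariates = NULL,
                         reference = c("within", "pooled")) {
    reference <- match.arg(reference)
    prsCat <- factor(prsCat)
    stratum <- factor(stratum)
    lev <- levels(stratum)
    cats <- levels(prsCat)
    Z <- if (is.null(covariates)) NULL
         else buildDesign(as.data.frame(covariates),
                          colnames(as.data.frame(covariates)))
    rows <- list()
    for (s in lev) {
        inS <- !is.na(stratum) & stratum == s & !is.na(prsCat) &
            !is.na(outcome)
        ys <- outcome[inS]
        ps <- droplevels(prsCat[inS])
        fit <- NULL
        if (reference == "within" && nlevels(ps) > 1 &&
            cats[1] %in% levels(ps)) {
            D <- stats::model.matrix(~ p, data.frame(
                p = factor(ps, levels = cats)))[, -1, drop = FALSE]
            colnames(D) <- paste0("prs", cats[-1])
            Zi <- if (is.null(Z)) D else cbind(D, Z[inS, , drop = FALSE])
            fit <- tryCatch(fitLogistic(ys, Zi), error = function(e) NULL)
        }
        for (cat in cats) {
            inCell <- inS & prsCat == cat
            n <- sum(inCell)
            row <- data.frame(stratum = s, prs = cat, n = n,
                              cases = sum(outcome[inCell] == 1),
                              or = NA_real_, ciLow = NA_real_,
                              ciHigh = NA_real_, p = NA_real_,
                              note = "")
            if (n == 0) {
                row$note <- "empty cell"
            } else if (cat == cats[1]) {
                row$or <- 1; row$note <- "reference"
            } else if (is.null(fit) || !fit$converged ||
                       !paste0("prs", cat) %in% names(fit$coefficients)) {
                row$note <- "inestimable"
            } else {
                w <- tryCatch(waldOR(fit, paste0("prs", cat)),
                              error = function(e) NULL)
                if (is.null(w)) row$note <- "inestimable"
                else row[c("or", "ciLow", "ciHigh", "p")] <-
                    list(w$or, w$ciLow, w$ciHigh, w$p)
            }
            rows[[length(rows) + 1]] <- row
        }
    }
    if (reference == "pooled") {
        ## one joint model: stratum + PRS + PRS:stratum, pooled low-PRS
        ## baseline; cell ORs = exp(linear combination)
        ok <- !is.na(stratum) & !is.na(prsCat) & !is.na(outcome)
        df <- data.frame(p = factor(prsCat[ok], levels = cats),
                         s = factor(stratum[ok], levels = lev))
        D <- stats::model.matrix(~ p * s, df)[, -1, drop = FALSE]
        Zi <- if (is.null(Z)) D else cbind(D, Z[ok, , drop = FALSE])
        fit <- fitLogistic(outcome[ok], Zi)
        out <- do.call(rbind, rows)
        for (i in seq_len(nrow(out))) {
            cat <- out$prs[i]; s <- out$stratum[i]
            if (cat == cats[1]) next
            terms <- paste0("p", cat)
            if (s != lev[1])
                terms <- c(terms, paste0("p", cat, ":s", s))
            terms <- intersect(terms, names(fit$coefficients))
            b <- sum(fit$coefficients[terms])
            v <- tryCatch({
                cv <- solve(crossprod(
                    Zi * (fit$fitted * (1 - fit$fitted)), Zi))
                idx <- match(terms, colnames(Zi))
                sum(cv[idx, idx])
            }, error = function(e) NA_real_)
            out$or[i] <- exp(b)
            if (is.finite(v) && v > 0) {
                out$ciLow[i] <- exp(b - 1.96 * sqrt(v))
                out$ciHigh[i] <- exp(b + 1.96 * sqrt(v))
                out$p[i] <- 2 * stats::pnorm(-abs(b / sqrt(v)))
            }
        }
        rows <- split(out, seq_len(nrow(out)))
    }
    res <- DataFrame(do.call(rbind, rows))
    ip <- tryCatch(
        interactionPvalue(outcome, prsCat, stratum, covariates),
        error = function(e) NA_real_)
    metadata(res) <- list(interactionP = ip, reference = reference)
    res
}

#' Gene-environment interaction p-value
#'
#' Likelihood-ratio test comparing the logistic model with PRS-category
#' by stratum product terms against the main-effects model, on
#' (categories - 1) x (levels - 1) degrees of freedom.
#'
#' @inheritParams stratifiedOR
#' @return p-value in [0, 1].
#' @export
interactionPvalue <- function(outcome, prsCat, stratum,
                              covariates = NULL) {
    prsCat <- factor(prsCat)
    stratum <- factor(stratum)
    if (nlevels(droplevels(prsCat[!is.na(prsCat)])) < 2 ||
        nlevels(droplevels(stratum[!is.na(stratum)])) < 2)
        stop("degenerate factor: both PRS category and stratum must vary")
    ok <- !is.na(prsCat) & !is.na(stratum) & !is.na(outcome)
    Z <- if (is.null(covariates)) NULL
         else buildDesign(as.data.frame(covariates),
                          colnames(as.data.frame(covariates)))
    if (!is.null(Z)) {
        ok <- ok & stats::complete.cases(Z)
        Z <- Z[ok, , drop = FALSE]
    }
    df0 <- data.frame(p = droplevels(prsCat[ok]),
                      s = droplevels(stratum[ok]))
    Dmain <- stats::model.matrix(~ p + s, df0)[, -1, drop = FALSE]
    Dfull <- stats::model.matrix(~ p * s, df0)[, -1, drop = FALSE]
    Xr <- if (is.null(Z)) Dmain else cbind(Dmain, Z)
    Xf <- if (is.null(Z)) Dfull else cbind(Dfull, Z)
    dfInt <- ncol(Dfull) - ncol(Dmain)
    lrt(fitLogistic(outcome[ok], Xf), fitLogistic(outcome[ok], Xr),
        dfInt)
}

#' Cell-means incidence report
#'
#' Observed outcome incidence per PRS category x stratum cell, the
#' descriptive complement to the model-based interaction test.
#'
#' @inheritParams stratifiedOR
#' @return \code{DataFrame}: \code{stratum}, \code{prs}, \code{n},
#'   \code{cases}, \code{incidence}.
#' @export
cellIncidence <- function(outcome, prsCat, stratum) {
    ok <- !is.na(outcome) & !is.na(prsCat) & !is.na(stratum)
    tab <- expand.grid(prs = levels(factor(prsCat)),
                       stratum = levels(factor(stratum)),
                       stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(tab)), function(i) {
        inCell <- ok & prsCat == tab$prs[i] & stratum == tab$stratum[i]
        data.frame(stratum = tab$stratum[i], prs = tab$prs[i],
                   n = sum(inCell), cases = sum(outcome[inCell] == 1),
                   incidence = if (sum(inCell))
                       mean(outcome[inCell]) else NA_real_)
    })
    DataFrame(do.call(rbind, res))
}

#' Simplified dietary inflammatory index
#'
#' DII_i = sum_c score_c * intake_ic / 100: each dietary component's
#' daily intake is multiplied by its inflammatory score, the products
#' summed and divided by 100. Negative scores are anti-inflammatory.
#'
#' @param intakes numeric matrix or data.frame, samples x components,
#'   daily intakes in component-specific units.
#' @param scores named numeric inflammatory scores covering every
#'   column of \code{intakes}; a component without a score raises an
#'   error naming it.
#' @return numeric per-sample DII.
#' @examples
#' computeDII(cbind(a = 10, b = 50), c(a = 0.5, b = -0.2))  # -0.05
#' @export
computeDII <- function(intakes, scores) {
    m <- as.matrix(intakes)
    miss <- setdiff(colnames(m), names(scores))
    if (length(miss))
        stop("no inflammatory score for component(s): ",
             paste(miss, collapse = ", "))
    if (any(!is.finite(scores[colnames(m)])))
        stop("inflammatory scores must be finite")
    as.numeric(m %*% scores[colnames(m)]) / 100
}

#' Synthetic 38-component inflammatory score table
#'
#' Loads the score table shipped at
#' \code{inst/extdata/dii_scores_synthetic.tsv}: 38 food and nutrient
#' components (the common literature set minus garlic, ginger, saffron
#' and turmeric) with synthetic placeholder scores for testing and
#' demonstration. Real analyses must supply a published score table.
#'
#' @return named numeric vector of length 38.
#' @export
diiScoreTable <- function() {
    path <- system.file("extdata", "dii_scores_synthetic.tsv",
                        package = "gmdrPRS", mustWork = TRUE)
    tab <- utils::read.delim(path)
    stats::setNames(tab$score, tab$component)
}
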