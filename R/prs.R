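#' Assign risk alleles from the association scan
#'
#' For each model SNP the risk allele is the allele whose additive
#' dosage carries an odds ratio above 1: the coded minor allele when
#' OR > 1, otherwise the major allele. An OR exactly 1 is direction-
#' ambiguous and raises an error.
#'
#' @param gwas result of \code{\link{gwasScan}} (needs columns
#'   \code{snp}, \code{or}).
#' @param snps SNP ids of the chosen model.
#' @param snpInfo optional \code{DataFrame} with \code{minorAllele} /
#'   \code{majorAllele} columns (ids as rownames) used to attach allele
#'   labels.
#' @return \code{DataFrame}: \code{snp}, \code{riskAllele},
#'   \code{otherAllele}, \code{or}, \code{riskIsMinor}.
#' @examples
#' gw <- DataFrame(snp = c("a", "b"), or = c(1.59, 0.63),
#'                 row.names = c("a", "b"))
#' assignRiskAlleles(gw, c("a", "b"))
#' @export
assignRiskAlleles <- function(gwas, snps, snpInfo = NULL) {
    miss <- setdiff(snps, gwas$snp)
    if (length(miss))
        stop("no association OR for: ", paste(miss, collapse = ", "))
    or <- gwas$or[match(snps, gwas$snp)]
    if (any(is.na(or)))
        stop("OR unavailable (skipped SNP) for: ",
             paste(snps[is.na(or)], collapse = ", "))
    if (any(or == 1))
        stop("ambiguous risk direction (OR exactly 1) for: ",
             paste(snps[or == 1], collapse = ", "))
    riskIsMinor <- or > 1
    minor <- major <- rep(NA_character_, length(snps))
    if (!is.null(snpInfo)) {
        idx <- match(snps, rownames(snpInfo))
        if ("minorAllele" %in% colnames(snpInfo))
            minor <- snpInfo$minorAllele[idx]
        if ("majorAllele" %in% colnames(snpInfo))
            major <- snpInfo$majorAllele[idx]
    }
    DataFrame(snp = snps,
              riskAllele = ifelse(riskIsMinor, minor, major),
              otherAllele = ifelse(riskIsMinor, major, minor),
              or = or, riskIsMinor = riskIsMinor,
              row.names = snps)
}

#' Risk-allele-count polygenic risk score
#'
#' Per SNP the score is the number of risk alleles carried (0/1/2; the
#' coded dosage when the minor allele is the risk allele, 2 - dosage
#' otherwise); the PRS is the sum over the model SNPs, an integer in
#' [0, 2k]. By default a sample missing any model genotype is excluded
#' (score \code{NA}) and flagged; with
#' \code{missingPolicy = "meanImpute"} missing risk counts are replaced
#' by the SNP's mean observed risk count (score becomes non-integer).
#'
#' @param genotypes \linkS4class{CohortExperiment} or dosage matrix.
#' @param riskAlleles map from \code{\link{assignRiskAlleles}} (needs
#'   \code{snp} and \code{riskIsMinor}).
#' @param missingPolicy \code{"exclude"} (default) or
#'   \code{"meanImpute"}.
#' @return numeric vector of per-sample scores, with attribute
#'   \code{"flagged"} listing excluded sample names.
#' @examples
#' g <- rbind(a = c(2, 0, 1))  # risk allele = coded minor allele
#' m <- DataFrame(snp = "a", riskIsMinor = TRUE)
#' computePRS(g, m)
#' @export
computePRS <- function(genotypes, riskAlleles,
                       missingPolicy = c("exclude", "meanImpute")) {
    missingPolicy <- match.arg(missingPolicy)
    g <- if (is(genotypes, "CohortExperiment")) dosage(genotypes)
         else as.matrix(genotypes)
    miss <- setdiff(riskAlleles$snp, rownames(g))
    if (length(miss))
        stop("genotypes missing mapped SNPs: ",
             paste(miss, collapse = ", "))
    gm <- g[riskAlleles$snp, , drop = FALSE]
    flip <- !riskAlleles$riskIsMinor
    gm[flip, ] <- 2 - gm[flip, , drop = FALSE]
    if (missingPolicy == "meanImpute") {
        for (i in seq_len(nrow(gm))) {
            na <- is.na(gm[i, ])
            if (any(na)) gm[i, na] <- mean(gm[i, !na])
        }
        score <- colSums(gm)
        flagged <- character()
    } else {
        score <- colSums(gm)   # NA propagates for incomplete samples
        flagged <- colnames(gm)[is.na(score)] %||% character()
    }
    structure(as.numeric(score), names = colnames(gm),
              flagged = flagged)
}

#' Categorize polygenic risk scores
#'
#' Fixed mode: low = score <= cut1, medium = cut1 < score <= cut2,
#' high = score > cut2; the shipped default \code{c(6, 8)} reproduces
#' the low 0-6 / medium 7-8 / high >= 9 convention for an eight-SNP
#' score. Tertile mode: cut points are the empirical 1/3 and 2/3
#' quantiles (type 1, ties assigned to the lower category).
#'
#' @param scores numeric scores (\code{NA} allowed, stays \code{NA}).
#' @param cutPoints numeric \code{c(cut1, cut2)} or \code{"tertile"}.
#' @return factor with levels \code{low}, \code{medium}, \code{high}
#'   and attribute \code{"cutPoints"}.
#' @examples
#' categorizePRS(c(0, 7, 9))                 # low, medium, high
#' categorizePRS(0:16, cutPoints = "tertile")
#' @export
categorizePRS <- function(scores, cutPoints = c(6, 8)) {
    sc <- scores[!is.na(scores)]
    if (!length(sc)) stop("no scores to categorize")
    if (identical(cutPoints, "tertile")) {
        if (length(unique(sc)) < 2)
            stop("degenerate score distribution: ",
                 "all scores equal, tertiles undefined")
        cutPoints <- as.numeric(
            stats::quantile(sc, c(1, 2) / 3, type = 1))
        if (cutPoints[1] == cutPoints[2])  # keep the middle band non-empty
            cutPoints[1] <- max(sc[sc < cutPoints[2]], min(sc))
    }
    stopifnot(length(cutPoints) == 2, cutPoints[1] <= cutPoints[2])
    lab <- ifelse(scores <= cutPoints[1], "low",
           ifelse(scores <= cutPoints[2], "medium", "high"))
    structure(factor(lab, levels = c("low", "medium", "high")),
              cutPoints = cutPoints)
}

#' Build a PRSProfile from a cohort, a model and the association scan
#'
#' Convenience wrapper: assigns risk alleles, computes scores and
#' categories, and wraps them in a \linkS4class{PRSProfile}.
#'
#' @param cohort \linkS4class{CohortExperiment}.
#' @param snps model SNP ids.
#' @param gwas \code{\link{gwasScan}} result.
#' @param cutPoints passed to \code{\link{categorizePRS}}; the preset
#'   \code{"gc8"} pins the fixed cuts \code{c(6, 8)}.
#' @param missingPolicy passed to \code{\link{computePRS}}.
#' @return a \linkS4class{PRSProfile}.
#' @export
buildPRS <- function(cohort, snps, gwas, cutPoints = "tertile",
                     missingPolicy = "exclude") {
    if (identical(cutPoints, "gc8")) cutPoints <- c(6, 8)
    map <- assignRiskAlleles(gwas, snps, snpInfo(cohort))
    sc <- computePRS(cohort, map, missingPolicy)
    cat3 <- categorizePRS(sc, cutPoints)
    new("PRSProfile", score = as.numeric(sc), category = cat3,
        cutPoints = attr(cat3, "cutPoints"), snps = snps,
        riskAlleles = map, flagged = attr(sc, "flagged"))
}
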