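#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData rowData<- colData colData<-
NULL

#' CohortExperiment: genotypes, phenotypes and exposures for one cohort
#'
#' A thin extension of
#' \link[SummarizedExperiment]{SummarizedExperiment} holding a
#' case-control cohort: a single \code{"dosage"} assay of minor-allele
#' counts (SNP x sample, values 0/1/2 or \code{NA} for missing calls),
#' per-SNP metadata in \code{rowData} (alleles, simulated MAF, ...),
#' per-sample phenotype/covariate/exposure columns in \code{colData}
#' (including the binary \code{outcome}), and -- for simulated cohorts --
#' a truth record of the planted effects in \code{metadata()$truth}.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
    msg <- character()
    if (!("dosage" %in% names(assays(object))))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && (any(bad < 0) || any(bad > 2)))
            msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
    }
    if ("outcome" %in% colnames(colData(object))) {
        y <- colData(object)$outcome
        if (!all(y %in% c(0L, 1L, NA)))
            msg <- c(msg, "outcome must be binary 0/1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CohortExperiment
#'
#' @param dosage integer matrix of minor-allele counts, SNPs in rows and
#'   samples in columns; \code{NA} marks missing calls.
#' @param snpInfo \code{DataFrame}/\code{data.frame} of per-SNP metadata
#'   (one row per SNP). Optional.
#' @param sampleData \code{DataFrame}/\code{data.frame} of per-sample
#'   phenotype, covariate and exposure columns. Optional.
#' @param truth optional truth record (list) describing planted effects
#'   of a simulated cohort.
#' @return A \linkS4class{CohortExperiment}.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 1L), 2, 2,
#'             dimnames = list(c("snp1", "snp2"), c("s1", "s2")))
#' ce <- CohortExperiment(d, sampleData = data.frame(outcome = c(0L, 1L)))
#' dosage(ce)
#' @export
CohortExperiment <- function(dosage, snpInfo = NULL, sampleData = NULL,
                             truth = NULL) {
    dosage <- as.matrix(dosage)
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("snp", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("sample", seq_len(ncol(dosage)))
    if (is.null(snpInfo))
        snpInfo <- DataFrame(row.names = rownames(dosage))
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = colnames(dosage))
    se <- SummarizedExperiment(
        assays = SimpleList(dosage = dosage),
        rowData = snpInfo, colData = sampleData)
    obj <- new("CohortExperiment", se)
    if (!is.null(truth)) metadata(obj)$truth <- truth
    obj
}

#' @describeIn CohortExperiment the dosage matrix (SNP x sample).
#' @param object,x a \code{CohortExperiment}.
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @rdname CohortExperiment
#' @export
setMethod("dosage", "CohortExperiment",
          function(object) assay(object, "dosage"))

#' @describeIn CohortExperiment per-SNP metadata (rowData).
#' @export
setGeneric("snpInfo", function(object) standardGeneric("snpInfo"))

#' @rdname CohortExperiment
#' @export
setMethod("snpInfo", "CohortExperiment", function(object) rowData(object))

#' @describeIn CohortExperiment truth record of planted effects
#'   (\code{NULL} for non-simulated cohorts).
#' @export
setGeneric("truthRecord", function(object) standardGeneric("truthRecord"))

#' @rdname CohortExperiment
#' @export
setMethod("truthRecord", "CohortExperiment",
          function(object) metadata(object)$truth)

#' @describeIn CohortExperiment binary outcome vector.
#' @export
setGeneric("cohortOutcome", function(object) standardGeneric("cohortOutcome"))

#' @rdname CohortExperiment
#' @export
setMethod("cohortOutcome", "CohortExperiment",
          function(object) colData(object)$outcome)

setMethod("show", "CohortExperiment", function(object) {
    cat("CohortExperiment:", nrow(object), "SNPs x", ncol(object),
        "samples\n")
    y <- colData(object)$outcome
    if (!is.null(y))
        cat("  outcome: ", sum(y == 1, na.rm = TRUE), " cases / ",
            sum(y == 0, na.rm = TRUE), " controls\n", sep = "")
    tr <- metadata(object)$truth
    if (!is.null(tr))
        cat("  simulated cohort (seed ", tr$seed, "), planted pairs: ",
            if (length(tr$plantedPairs))
                paste(vapply(tr$plantedPairs, paste, "", collapse = "+"),
                      collapse = ", ") else "none", "\n", sep = "")
    invisible(NULL)
})

#' QCReport: per-SNP quality-control outcome
#'
#' Produced by \code{\link{applyQC}}. Holds the per-SNP statistics, the
#' thresholds used, the kept SNP ids and the failure reasons for removed
#' SNPs, plus a per-sample heterozygosity table (reported, not used for
#' exclusion).
#'
#' @slot snpStats \code{DataFrame} of per-SNP statistics and pass flags.
#' @slot thresholds list of thresholds used.
#' @slot kept character vector of retained SNP ids.
#' @slot removed \code{DataFrame} of removed SNPs with failure reasons.
#' @slot sampleHet \code{DataFrame} of per-sample heterozygosity.
#' @export
setClass("QCReport", representation(
    snpStats = "DataFrame", thresholds = "list",
    kept = "character", removed = "DataFrame", sampleHet = "DataFrame"))

#' @describeIn QCReport ids of SNPs passing all thresholds.
#' @param object a \code{QCReport}.
#' @export
setGeneric("keptSNPs", function(object) standardGeneric("keptSNPs"))

#' @rdname QCReport
#' @export
setMethod("keptSNPs", "QCReport", function(object) object@kept)

#' @describeIn QCReport per-SNP statistics table.
#' @export
setGeneric("snpStats", function(object) standardGeneric("snpStats"))

#' @rdname QCReport
#' @export
setMethod("snpStats", "QCReport", function(object) object@snpStats)

setMethod("show", "QCReport", function(object) {
    cat("QCReport:", nrow(object@snpStats), "SNPs in,",
        length(object@kept), "kept,", nrow(object@removed), "removed\n")
    if (nrow(object@removed)) {
        tab <- table(unlist(strsplit(object@removed$reasons, ";")))
        cat("  failures:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    invisible(NULL)
})

#' GMDRResult: model search output of the GMDR engine
#'
#' Produced by \code{\link{gmdrSearch}}. \code{models} holds the best
#' model per combination size k (trained balanced accuracy TRBA, testing
#' balanced accuracy TEBA, cross-validation consistency CVC and exact
#' signed-rank p of the fold TEBAs against 0.5); \code{best} the overall
#' best model; \code{folds} per-fold accuracies of the best model.
#'
#' @slot models \code{DataFrame}, one row per combination size.
#' @slot best list describing the overall best model.
#' @slot folds \code{DataFrame} of per-fold TRBA/TEBA for the best model.
#' @slot nEvaluated number of SNP combinations cross-validated.
#' @slot nFolds number of cross-validation folds.
#' @export
setClass("GMDRResult", representation(
    models = "DataFrame", best = "list", folds = "DataFrame",
    nEvaluated = "numeric", nFolds = "integer"))

#' @describeIn GMDRResult the overall best model (list with snps, trba,
#'   teba, cvc, p).
#' @param object a \code{GMDRResult}.
#' @export
setGeneric("bestModel", function(object) standardGeneric("bestModel"))

#' @rdname GMDRResult
#' @export
setMethod("bestModel", "GMDRResult", function(object) object@best)

#' @describeIn GMDRResult per-k model summary table.
#' @export
setGeneric("modelTable", function(object) standardGeneric("modelTable"))

#' @rdname GMDRResult
#' @export
setMethod("modelTable", "GMDRResult", function(object) object@models)

setMethod("show", "GMDRResult", function(object) {
    cat("GMDRResult:", object@nEvaluated, "combinations evaluated,",
        object@nFolds, "folds\n")
    b <- object@best
    cat("  best model: ", paste(b$snps, collapse = " + "), "\n",
        "  TRBA ", round(b$trba, 4), ", TEBA ", round(b$teba, 4),
        ", CVC ", b$cvc, "/", object@nFolds,
        ", signed-rank p ", signif(b$p, 4), "\n", sep = "")
    invisible(NULL)
})

#' PRSProfile: per-sample risk-allele-count polygenic risk score
#'
#' Produced by \code{\link{computePRS}} +
#' \code{\link{categorizePRS}} or the convenience wrapper
#' \code{\link{buildPRS}}. Scores are integer risk-allele counts in
#' [0, 2k] over the k model SNPs; categories are low/medium/high.
#'
#' @slot score numeric vector of per-sample scores (NA = not scorable).
#' @slot category factor with levels low/medium/high.
#' @slot cutPoints numeric length-2 upper bounds of low and medium.
#' @slot snps character ids of the scored SNPs.
#' @slot riskAlleles \code{DataFrame} risk-allele map used.
#' @slot flagged character ids of samples excluded for missing genotypes.
#' @export
setClass("PRSProfile", representation(
    score = "numeric", category = "factor", cutPoints = "numeric",
    snps = "character", riskAlleles = "DataFrame", flagged = "character"))

#' @describeIn PRSProfile numeric score vector.
#' @param object a \code{PRSProfile}.
#' @export
setGeneric("prsScore", function(object) standardGeneric("prsScore"))

#' @rdname PRSProfile
#' @export
setMethod("prsScore", "PRSProfile", function(object) object@score)

#' @describeIn PRSProfile low/medium/high category factor.
#' @export
setGeneric("prsCategory", function(object) standardGeneric("prsCategory"))

#' @rdname PRSProfile
#' @export
setMethod("prsCategory", "PRSProfile", function(object) object@category)

setMethod("show", "PRSProfile", function(object) {
    cat("PRSProfile:", length(object@score), "samples,",
        length(object@snps), "SNPs, cuts (",
        object@cutPoints[1], ",", object@cutPoints[2], ")\n")
    print(table(object@category))
    if (length(object@flagged))
        cat("  ", length(object@flagged),
            "samples flagged for missing genotypes\n")
    invisible(NULL)
})
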