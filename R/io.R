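#' Read a dosage TSV
#'
#' Expected layout: tab-separated, header of SNP ids, first column
#' \code{sample}, values 0/1/2 minor-allele counts or \code{NA}.
#'
#' @param path file path.
#' @return integer dosage matrix, SNPs in rows, samples in columns.
#' @export
readDosage <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE)
    if (colnames(tab)[1] != "sample")
        stop("dosage TSV must start with a 'sample' column")
    m <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(m) <- tab$sample
    bad <- m[!is.na(m)]
    if (any(bad != round(bad)) || any(bad < 0 | bad > 2))
        stop("dosage values must be 0, 1, 2 or NA")
    storage.mode(m) <- "integer"
    m
}

#' Write a dosage TSV
#'
#' Rows are samples, header names the SNPs; values are minor-allele
#' counts (0/1/2) with \code{NA} for missing calls.
#'
#' @param genotypes dosage matrix (SNP x sample) or
#'   \linkS4class{CohortExperiment}.
#' @param path output path.
#' @export
writeDosage <- function(genotypes, path) {
    g <- if (is(genotypes, "CohortExperiment")) dosage(genotypes)
         else as.matrix(genotypes)
    df <- data.frame(sample = colnames(g), t(g), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read biallelic genotypes from a VCF
#'
#' Parses GT fields ("0/0", "0/1", "1/1", "./.", phased variants
#' allowed) into ALT-allele counts, then re-orients each SNP to
#' minor-allele dosage (flipping when the ALT frequency exceeds 0.5).
#' Multi-allelic records are rejected with their positions reported.
#'
#' @param path VCF path.
#' @return list with \code{dosage} (minor-allele counts, SNP x sample)
#'   and \code{snpInfo} (\code{DataFrame}: chrom, pos, ref, alt,
#'   minorAllele, majorAllele, flipped).
#' @export
readGenotypesVCF <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fixm <- vcfR::getFIX(v)
    if (is.null(dim(fixm))) fixm <- t(fixm)   # single-record VCF
    fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi))
        stop("multi-allelic records not supported at: ",
             paste(paste0(fix$CHROM[multi], ":", fix$POS[multi]),
                   collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    count <- function(x) {
        x <- gsub("\\|", "/", x)
        ifelse(is.na(x) | x %in% c("./.", "."), NA_integer_,
               vapply(strsplit(x, "/"), function(a)
                   sum(as.integer(a)), 1L))
    }
    d <- apply(gt, 2, count)
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(gt))
    dimnames(d) <- dimnames(gt)
    rownames(d) <- fix$ID
    altFreq <- rowMeans(d, na.rm = TRUE) / 2
    flipped <- !is.na(altFreq) & altFreq > 0.5
    d[flipped, ] <- 2L - d[flipped, , drop = FALSE]
    storage.mode(d) <- "integer"
    info <- DataFrame(
        chrom = fix$CHROM, pos = as.integer(fix$POS),
        ref = fix$REF, alt = fix$ALT,
        minorAllele = ifelse(flipped, fix$REF, fix$ALT),
        majorAllele = ifelse(flipped, fix$ALT, fix$REF),
        flipped = flipped, row.names = rownames(d))
    list(dosage = d, snpInfo = info)
}

#' Write genotypes as a minimal biallelic VCF
#'
#' Emits a VCFv4.2 text file with GT-only genotype columns; dosages are
#' written against the ALT allele (the minor allele), positions are
#' 1-based.
#'
#' @param genotypes dosage matrix (SNP x sample) or
#'   \linkS4class{CohortExperiment}.
#' @param path output path.
#' @param snpInfo optional \code{DataFrame} with \code{chrom},
#'   \code{pos}, \code{minorAllele}, \code{majorAllele}; synthesized
#'   when absent.
#' @export
writeVCF <- function(genotypes, path, snpInfo = NULL) {
    g <- if (is(genotypes, "CohortExperiment")) dosage(genotypes)
         else as.matrix(genotypes)
    if (is.null(snpInfo) && is(genotypes, "CohortExperiment"))
        snpInfo <- snpInfo(genotypes)
    n <- nrow(g)
    chrom <- pos <- NULL
    if (!is.null(snpInfo) && "chrom" %in% colnames(snpInfo))
        chrom <- snpInfo$chrom
    if (!is.null(snpInfo) && "pos" %in% colnames(snpInfo))
        pos <- snpInfo$pos
    chrom <- chrom %||% rep("1", n)
    pos <- pos %||% seq_len(n) * 1000L
    minor <- if (!is.null(snpInfo) && "minorAllele" %in% colnames(snpInfo))
        snpInfo$minorAllele else rep("A", n)
    major <- if (!is.null(snpInfo) && "majorAllele" %in% colnames(snpInfo))
        snpInfo$majorAllele else rep("G", n)
    gtStr <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = n)
    gtStr[is.na(g)] <- "./."
    header <- c("##fileformat=VCFv4.2",
                "##source=gmdrPRS",
                paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                       "Description=\"Genotype\">"),
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(g)),
                      collapse = "\t"))
    body <- vapply(seq_len(n), function(i)
        paste(c(chrom[i], pos[i], rownames(g)[i], major[i], minor[i],
                ".", "PASS", ".", "GT", gtStr[i, ]), collapse = "\t"),
        "")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read and validate a pipeline configuration
#'
#' YAML with top-level keys (unknown keys rejected): \code{seed},
#' \code{simulate} (n, design, nCase, nControl, missingRate),
#' \code{qc} (maxMissing, minMAF, minHweP, maxHet), \code{gwas}
#' (alpha, covariates or covariateSet), \code{prune} (dprimeThreshold,
#' maxCandidates), \code{gmdr} (kRange, nFolds, threshold, budget),
#' \code{prs} (cutPoints), \code{strata} (preset names), \code{dii}
#' (scoreTable path or "synthetic").
#'
#' @param path YAML path.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    known <- c("seed", "simulate", "qc", "gwas", "prune", "gmdr",
               "prs", "strata", "dii", "genotypes", "phenotypes")
    unknown <- setdiff(names(cfg), known)
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    if (is.null(cfg$seed)) stop("config requires a 'seed'")
    cfg
}

#' Run the full analysis pipeline
#'
#' Stage order: cohort (simulated from the default template, scaled by
#' the config, or read from files) -> SNP quality control ->
#' covariate-adjusted GWAS screen -> D' LD pruning of the screen's top
#' SNPs -> exhaustive GMDR search -> risk-allele PRS with categories ->
#' stratified odds ratios with interaction p per configured stratum
#' (-> DII if configured). Each stage writes a TSV/JSON output and a
#' per-stage in/out count into the run manifest; rerunning the same
#' config and seed reproduces identical stage outputs.
#'
#' @param config list from \code{\link{readPipelineConfig}} (or
#'   assembled in code).
#' @param outDir output directory (created).
#' @return the run manifest (list), invisibly; written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "gmdrPRS",
                     version = as.character(
                         utils::packageVersion("gmdrPRS")),
                     seed = config$seed, stages = list(),
                     timestamp = format(Sys.time(), tz = "UTC"))
    outfile <- function(f) file.path(outDir, f)

    ## --- cohort ------------------------------------------------------
    if (!is.null(config$genotypes)) {
        gen <- if (grepl("\\.vcf$", config$genotypes))
            readGenotypesVCF(config$genotypes)
        else list(dosage = readDosage(config$genotypes), snpInfo = NULL)
        pheno <- utils::read.delim(config$phenotypes)
        if (!all(colnames(gen$dosage) %in% pheno$sample))
            stop("sample ids missing from phenotype table: ",
                 paste(setdiff(colnames(gen$dosage), pheno$sample),
                       collapse = ", "))
        pheno <- pheno[match(colnames(gen$dosage), pheno$sample), ]
        rownames(pheno) <- pheno$sample
        cohort <- CohortExperiment(gen$dosage, snpInfo = gen$snpInfo,
                                   sampleData = pheno[, -1, drop = FALSE])
    } else {
        sim <- config$simulate %||% list()
        tmpl <- defaultCohortConfig()
        if (!is.null(sim$n)) tmpl$n <- sim$n
        if (!is.null(sim$missingRate)) tmpl$missingRate <- sim$missingRate
        cohort <- simulateCohort(
            tmpl, seed = config$seed,
            design = sim$design %||% "population",
            nCase = sim$nCase %||% 2000, nControl = sim$nControl %||% 2000)
    }
    manifest$stages$cohort <- list(
        snps = nrow(cohort), samples = ncol(cohort),
        cases = sum(cohortOutcome(cohort) == 1))

    ## --- QC ----------------------------------------------------------
    th <- do.call(qcThresholds, config$qc %||% list())
    qc <- applyQC(cohort, th)
    utils::write.table(as.data.frame(snpStats(qc$report)),
                       outfile("qc_snp_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cohort <- qc$genotypes
    manifest$stages$qc <- list(kept = length(keptSNPs(qc$report)),
                               removed = nrow(qc$report@removed))
    if (nrow(cohort) == 0) stop("pipeline halted at qc: no SNPs left")

    ## --- GWAS screen -------------------------------------------------
    gwCfg <- config$gwas %||% list()
    covs <- gwCfg$covariates %||%
        (if (!is.null(gwCfg$covariateSet))
             covariateSet(gwCfg$covariateSet) else character())
    covs <- intersect(covs, colnames(colData(cohort)))
    gw <- gwasScan(cohort, covariates = covs,
                   alpha = gwCfg$alpha %||% 5e-4)
    utils::write.table(as.data.frame(gw), outfile("gwas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$gwas <- list(tested = nrow(gw),
                                 passed = sum(gw$pass, na.rm = TRUE))

    ## --- LD pruning of screen candidates -----------------------------
    prCfg <- config$prune %||% list()
    maxCand <- prCfg$maxCandidates %||% 10
    cand <- gw$snp[order(gw$p)]
    cand <- cand[!is.na(gw$p[match(cand, gw$snp)])][
        seq_len(min(maxCand, sum(!is.na(gw$p))))]
    dm <- dprimeMatrix(cohort, cand)
    kept <- ldPrune(dm, stats::setNames(gw$p, gw$snp),
                    threshold = prCfg$dprimeThreshold %||% 0.4)
    manifest$stages$prune <- list(candidates = length(cand),
                                  kept = length(kept))

    ## --- GMDR --------------------------------------------------------
    gmCfg <- config$gmdr %||% list()
    kRange <- gmCfg$kRange %||% seq(2, min(4, length(kept)))
    gm <- gmdrSearch(cohort, kept, kRange = kRange,
                     covariates = if (length(covs)) covs,
                     nFolds = gmCfg$nFolds %||% 10,
                     seed = config$seed,
                     threshold = gmCfg$threshold %||% 0,
                     budget = gmCfg$budget %||% 20000)
    utils::write.table(as.data.frame(modelTable(gm)),
                       outfile("gmdr_models.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    b <- bestModel(gm)
    jsonlite::write_json(
        list(snps = b$snps, trba = b$trba, teba = b$teba, cvc = b$cvc,
             signedRankP = b$p),
        outfile("gmdr_best.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$gmdr <- list(evaluated = gm@nEvaluated,
                                 best = paste(b$snps, collapse = "+"))

    ## --- PRS ---------------------------------------------------------
    prs <- buildPRS(cohort, b$snps, gw,
                    cutPoints = config$prs$cutPoints %||% "tertile")
    utils::write.table(
        data.frame(sample = colnames(cohort), score = prsScore(prs),
                   category = as.character(prsCategory(prs))),
        outfile("prs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$prs <- list(
        snps = length(b$snps),
        sizes = as.list(table(prsCategory(prs))))

    ## --- stratified interaction analysis -----------------------------
    strata <- config$strata %||% character()
    y <- cohortOutcome(cohort)
    for (s in strata) {
        def <- stratumPreset(s)
        if (!def$variable %in% colnames(colData(cohort))) next
        lab <- dichotomize(colData(cohort)[[def$variable]], def)
        tab <- stratifiedOR(y, prsCategory(prs), lab)
        df <- as.data.frame(tab)
        df$interactionP <- metadata(tab)$interactionP
        utils::write.table(df, outfile(paste0("strata_", s, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$stages[[paste0("strata_", s)]] <-
            list(interactionP = metadata(tab)$interactionP)
    }

    ## --- DII ---------------------------------------------------------
    if (!is.null(config$dii)) {
        scores <- if (identical(config$dii$scoreTable, "synthetic"))
            diiScoreTable()
        else {
            tab <- utils::read.delim(config$dii$scoreTable)
            stats::setNames(tab$score, tab$component)
        }
        cols <- grep("^dii_", colnames(colData(cohort)), value = TRUE)
        if (length(cols)) {
            intakes <- as.matrix(as.data.frame(
                colData(cohort)[, cols, drop = FALSE]))
            colnames(intakes) <- sub("^dii_", "", cols)
            dii <- computeDII(intakes,
                              scores[colnames(intakes)])
            utils::write.table(
                data.frame(sample = colnames(cohort), dii = dii),
                outfile("dii.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
            manifest$stages$dii <- list(n = length(dii))
        }
    }

    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
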