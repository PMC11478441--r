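#' Specify SNPs for simulation
#'
#' Builds the SNP specification table consumed by
#' \code{\link{simulateGenotypes}}. Each SNP has an id and a minor
#' allele frequency; a SNP may optionally be linked to an earlier SNP
#' through a target D' (normalised linkage disequilibrium), in which
#' case the pair is drawn jointly from the two-locus haplotype
#' distribution implied by the two MAFs and D'.
#'
#' @param id character SNP ids (unique).
#' @param maf minor allele frequencies in (0, 0.5].
#' @param ldPartner optional character: for each SNP, the id of the SNP
#'   it is linked to (\code{NA} = unlinked). A partner must appear
#'   earlier in the table and itself be unlinked.
#' @param ldDprime target D' in [0, 1] for linked SNPs (\code{NA}
#'   otherwise).
#' @param minorAllele,majorAllele optional allele labels (defaults
#'   "A"/"G").
#' @return \code{DataFrame} with one row per SNP.
#' @examples
#' snpSpec(c("rs1", "rs2"), c(0.3, 0.2), ldPartner = c(NA, "rs1"),
#'         ldDprime = c(NA, 0.9))
#' @export
snpSpec <- function(id, maf, ldPartner = NA_character_, ldDprime = NA_real_,
                    minorAllele = "A", majorAllele = "G") {
    n <- length(id)
    stopifnot(!anyDuplicated(id), length(maf) == n)
    if (any(maf <= 0 | maf > 0.5))
        stop("maf must be in (0, 0.5]")
    ldPartner <- rep_len(as.character(ldPartner), n)
    ldDprime <- rep_len(as.numeric(ldDprime), n)
    if (any(is.na(ldPartner) != is.na(ldDprime)))
        stop("ldDprime must be given exactly for SNPs with an ldPartner")
    if (any(!is.na(ldDprime) & (ldDprime < 0 | ldDprime > 1)))
        stop("ldDprime must lie in [0, 1]")
    for (i in which(!is.na(ldPartner))) {
        j <- match(ldPartner[i], id)
        if (is.na(j) || j >= i)
            stop("ldPartner must reference an earlier SNP id")
        if (!is.na(ldPartner[j]))
            stop("an LD partner must itself be unlinked")
    }
    DataFrame(id = as.character(id), maf = maf,
              ldPartner = ldPartner, ldDprime = ldDprime,
              minorAllele = rep_len(minorAllele, n),
              majorAllele = rep_len(majorAllele, n))
}

## Two-locus haplotype frequencies (minor/minor coding) for MAFs pA, pB
## and normalised D'. D = dprime * Dmax with Dmax for positive D.
haplotypeFreqs <- function(pA, pB, dprime) {
    dmax <- min(pA * (1 - pB), (1 - pA) * pB)
    if (dprime > 0 && dmax <= 0)
        stop("requested D' infeasible: a locus is monomorphic")
    D <- dprime * dmax
    h <- c(mm = pA * pB + D,          # minor-minor
           mM = pA * (1 - pB) - D,    # minor-Major
           Mm = (1 - pA) * pB - D,
           MM = (1 - pA) * (1 - pB) + D)
    if (any(h < -1e-12))
        stop("requested D' infeasible for given MAFs")
    pmax(h, 0)
}

#' Simulate Hardy-Weinberg genotypes, with optional pairwise LD
#'
#' Unlinked SNPs are drawn per sample as Binomial(2, MAF) minor-allele
#' counts (Hardy-Weinberg equilibrium by construction). A SNP with an
#' \code{ldPartner} is drawn jointly with its partner: each sample
#' receives two independent haplotypes from the two-locus haplotype
#' distribution implied by the two MAFs and the target D'. Missing calls
#' are injected completely at random at \code{missingRate} after
#' genotypes are drawn. Draws are made SNP by SNP in specification
#' order from a single stream seeded by \code{seed}, so identical
#' (spec, n, seed) reproduce identical matrices.
#'
#' @param specs a table from \code{\link{snpSpec}}.
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @param missingRate scalar or per-SNP missing-call rate in [0, 1)
#'   (default 0).
#' @return integer matrix, SNPs in rows, samples in columns.
#' @examples
#' g <- simulateGenotypes(snpSpec("rs1", 0.5), n = 1000, seed = 1)
#' table(g)
#' @export
simulateGenotypes <- function(specs, n, seed, missingRate = 0) {
    stopifnot(n >= 1, nrow(specs) >= 1)
    if (any(missingRate < 0 | missingRate >= 1))
        stop("missingRate must be in [0, 1)")
    missingRate <- rep_len(missingRate, nrow(specs))
    set.seed(as.integer(seed))
    g <- matrix(NA_integer_, nrow(specs), n,
                dimnames = list(specs$id,
                                sprintf("sample%04d", seq_len(n))))
    for (i in seq_len(nrow(specs))) {
        if (is.na(specs$ldPartner[i])) {
            if (is.na(g[i, 1]))   # not already drawn as someone's partner
                g[i, ] <- stats::rbinom(n, 2L, specs$maf[i])
        } else {
            j <- match(specs$ldPartner[i], specs$id)
            h <- haplotypeFreqs(specs$maf[j], specs$maf[i],
                                specs$ldDprime[i])
            hap1 <- sample.int(4L, n, replace = TRUE, prob = h)
            hap2 <- sample.int(4L, n, replace = TRUE, prob = h)
            ## haplotypes 1,2 carry the partner's minor allele; 1,3 carry
            ## this SNP's minor allele
            g[j, ] <- (hap1 <= 2L) + (hap2 <= 2L)
            g[i, ] <- (hap1 %% 2L == 1L) + (hap2 %% 2L == 1L)
        }
    }
    for (i in seq_len(nrow(specs)))
        if (missingRate[i] > 0)
            g[i, stats::runif(n) < missingRate[i]] <- NA_integer_
    storage.mode(g) <- "integer"
    g
}

#' Default exposure and covariate distributions
#'
#' The defaults emulate a Korean adult health-examinee cohort: age ~
#' N(53.5, 8), 35\% male, BMI ~ N(24, 2.9), white blood cell count ~
#' N(5.7, 1.55) 1e9/L, energy intake as percent of estimated need ~
#' N(98.7, 31.5), macronutrient energy fractions (carbohydrate ~
#' N(71.5, 7), protein ~ N(13.45, 2.6), fat ~ N(14, 5.4) En\%),
#' smoking status (non/former/current) with probabilities
#' (0.73, 0.16, 0.11), moderate alcohol 4.8\%, regular exercise 54\%,
#' three-level education (0.30, 0.43, 0.27) and income (0.30, 0.61,
#' 0.09), four residence regions, coffee intake (g/day) as a
#' zero-inflated gamma (15\% never-drinkers, gamma shape 2 scale 3).
#'
#' @return named list of distribution settings, overridable entry-wise
#'   via the \code{config} argument of \code{\link{simulateExposures}}.
#' @export
defaultExposureConfig <- function() {
    list(
        age = list(dist = "normal", mean = 53.5, sd = 8),
        sex = list(dist = "bernoulli", p = 0.35,
                   labels = c("female", "male")),
        bmi = list(dist = "normal", mean = 24, sd = 2.9),
        wbc = list(dist = "normal", mean = 5.7, sd = 1.55),
        energy = list(dist = "normal", mean = 98.7, sd = 31.5),
        carbohydrate = list(dist = "normal", mean = 71.5, sd = 7),
        protein = list(dist = "normal", mean = 13.45, sd = 2.6),
        fat = list(dist = "normal", mean = 14, sd = 5.4),
        smoking = list(dist = "categorical",
                       labels = c("non", "former", "current"),
                       p = c(0.73, 0.16, 0.11)),
        alcohol = list(dist = "bernoulli", p = 0.048,
                       labels = c("mild", "moderate")),
        exercise = list(dist = "bernoulli", p = 0.54,
                        labels = c("no", "yes")),
        education = list(dist = "categorical",
                         labels = c("lessHS", "HS", "college"),
                         p = c(0.30, 0.43, 0.27)),
        income = list(dist = "categorical",
                      labels = c("low", "medium", "high"),
                      p = c(0.30, 0.61, 0.09)),
        residence = list(dist = "categorical",
                         labels = c("r1", "r2", "r3", "r4"),
                         p = c(0.4, 0.3, 0.2, 0.1)),
        coffee = list(dist = "zigamma", p0 = 0.15, shape = 2, scale = 3)
    )
}

drawExposure <- function(cfg, n) {
    switch(cfg$dist,
        normal = stats::rnorm(n, cfg$mean, cfg$sd),
        lognormal = stats::rlnorm(n, cfg$meanlog, cfg$sdlog),
        bernoulli = factor(cfg$labels[1 + stats::rbinom(n, 1, cfg$p)],
                           levels = cfg$labels),
        categorical = factor(
            sample(cfg$labels, n, replace = TRUE, prob = cfg$p),
            levels = cfg$labels),
        zigamma = ifelse(stats::runif(n) < cfg$p0, 0,
                         stats::rgamma(n, shape = cfg$shape,
                                       scale = cfg$scale)),
        point = rep(cfg$value, n),
        stop("unknown distribution '", cfg$dist, "'"))
}

#' Simulate covariates, lifestyle exposures and dietary intakes
#'
#' @param n number of samples.
#' @param config list overriding entries of
#'   \code{\link{defaultExposureConfig}}; an entry named after an
#'   unknown distribution raises an error. Extra entries add columns.
#' @param seed integer seed.
#' @param diiComponents optional character vector of dietary component
#'   names; when given, per-component intakes are simulated as
#'   lognormal(log 10, 0.5) columns prefixed \code{"dii_"}.
#' @return \code{DataFrame}, one row per sample.
#' @examples
#' e <- simulateExposures(5, seed = 1)
#' e$wbc
#' @export
simulateExposures <- function(n, config = list(), seed,
                              diiComponents = NULL) {
    cfg <- defaultExposureConfig()
    for (nm in names(config)) cfg[[nm]] <- config[[nm]]
    set.seed(as.integer(seed))
    cols <- lapply(cfg, drawExposure, n = n)
    out <- DataFrame(cols)
    rownames(out) <- sprintf("sample%04d", seq_len(n))
    if (!is.null(diiComponents))
        for (comp in diiComponents)
            out[[paste0("dii_", comp)]] <- stats::rlnorm(n, log(10), 0.5)
    out
}

#' Specify a data-generating effect model
#'
#' Assembles the per-sample disease log-odds
#' \eqn{\eta_i = \alpha + \sum_s \beta_s g_{is} + \sum_{(a,b)} C_{ab}[g_{ia}, g_{ib}]
#' + \sum_c \gamma_c x_{ic} + \sum_t \delta_t S_{it} E_{it}}
#' where \eqn{g} are minor-allele dosages, \eqn{C} are 3x3 epistasis
#' cell log-odds offsets, \eqn{x} covariates, and each gene-environment
#' term multiplies a risk-allele-count score \eqn{S} (sum of dosages
#' over a SNP set) with an exposure value \eqn{E}. Outcomes are then
#' Bernoulli(plogis(eta)).
#'
#' @param intercept baseline log-odds (e.g. \code{qlogis(0.006)} for a
#'   0.6\% rare outcome).
#' @param additive named numeric, per-SNP log-OR per minor allele.
#' @param epistasis list of \code{list(snps = c(a, b), cells = M)} with
#'   \code{M} a 3x3 matrix of log-odds offsets indexed by (dosage a + 1,
#'   dosage b + 1).
#' @param covariates named numeric, log-OR per unit of a numeric
#'   exposure column (factors must be pre-coded).
#' @param gxe list of \code{list(snps =, exposure =, beta =)} terms.
#' @return classed list of class \code{"EffectModel"}.
#' @export
effectModel <- function(intercept = qlogis(0.006), additive = numeric(),
                        epistasis = list(), covariates = numeric(),
                        gxe = list()) {
    stopifnot(is.finite(intercept),
              all(is.finite(additive)), all(is.finite(covariates)))
    for (e in epistasis) {
        stopifnot(length(e$snps) == 2,
                  is.matrix(e$cells), all(dim(e$cells) == c(3, 3)),
                  all(is.finite(e$cells)))
    }
    structure(list(intercept = intercept, additive = additive,
                   epistasis = epistasis, covariates = covariates,
                   gxe = gxe),
              class = "EffectModel")
}

## A pure (checkerboard) epistasis cell matrix: offset applied where the
## two dosages have odd sum, yielding strong joint but weak marginal
## signal at intermediate MAFs.
#' Checkerboard epistasis cell offsets
#'
#' 3x3 log-odds offset matrix with \code{beta} on cells whose two
#' dosages sum to an odd number -- a near-pure epistatic pattern with
#' weak marginal effects.
#' @param beta log-odds offset (default \code{log(4)}, a four-fold
#'   odds contrast between neighbouring cells).
#' @return 3x3 numeric matrix.
#' @export
checkerboardCells <- function(beta = log(4)) {
    outer(0:2, 0:2, function(a, b) beta * ((a + b) %% 2))
}

linearPredictor <- function(genotypes, exposures, model) {
    n <- ncol(genotypes)
    eta <- rep(model$intercept, n)
    for (s in names(model$additive)) {
        if (!s %in% rownames(genotypes))
            stop("effect model references unknown SNP '", s, "'")
        eta <- eta + model$additive[[s]] * genotypes[s, ]
    }
    for (e in model$epistasis) {
        if (!all(e$snps %in% rownames(genotypes)))
            stop("epistasis term references unknown SNP")
        ga <- genotypes[e$snps[1], ]
        gb <- genotypes[e$snps[2], ]
        eta <- eta + e$cells[cbind(ga + 1L, gb + 1L)]
    }
    for (cv in names(model$covariates)) {
        if (!cv %in% colnames(exposures))
            stop("effect model references unknown exposure '", cv, "'")
        eta <- eta + model$covariates[[cv]] * as.numeric(exposures[[cv]])
    }
    for (t in model$gxe) {
        if (!all(t$snps %in% rownames(genotypes)) ||
            !t$exposure %in% colnames(exposures))
            stop("gxe term references unknown SNP or exposure")
        score <- colSums(genotypes[t$snps, , drop = FALSE])
        eta <- eta + t$beta * score * as.numeric(exposures[[t$exposure]])
    }
    if (any(!is.finite(eta)))
        stop("non-finite linear predictor; check effect model coefficients")
    eta
}

#' Simulate the binary outcome from an effect model
#'
#' @param genotypes SNP x sample dosage matrix (no missing calls at SNPs
#'   used by the model).
#' @param exposures per-sample exposure table (may be \code{NULL} when
#'   the model uses none).
#' @param model an \code{\link{effectModel}}.
#' @param seed integer seed.
#' @return list with \code{outcome} (integer 0/1) and \code{truth}
#'   (planted pairs, additive risk SNPs, the model, the seed).
#' @examples
#' g <- simulateGenotypes(snpSpec("rs1", 0.3), 200, seed = 1)
#' simulateOutcome(g, NULL, effectModel(qlogis(0.5)), seed = 2)$outcome[1:5]
#' @export
simulateOutcome <- function(genotypes, exposures, model, seed) {
    eta <- linearPredictor(genotypes, exposures, model)
    set.seed(as.integer(seed))
    y <- stats::rbinom(length(eta), 1L, stats::plogis(eta))
    truth <- list(
        plantedPairs = lapply(model$epistasis, function(e) e$snps),
        riskSNPs = names(model$additive)[model$additive > 0],
        model = model, seed = as.integer(seed))
    list(outcome = as.integer(y), truth = truth)
}

#' Default cohort template
#'
#' A one-tenth-scale emulation of a large urban-hospital case-control
#' cohort with a rare outcome: 4,830 samples, baseline prevalence 0.6\%,
#' ten unlinked SNPs at the reported minor allele frequencies of a
#' ten-variant gastric-cancer panel, a planted checkerboard epistasis on
#' the two strongest variants, and modest additive effects.
#'
#' @return list of arguments understood by \code{\link{simulateCohort}}.
#' @export
defaultCohortConfig <- function() {
    ids <- c("rs7521784", "rs12693006", "rs1045653", "rs9835646",
             "rs630760", "rs11946315", "rs1207808", "rs58499534",
             "rs10831776", "rs205881")
    mafs <- c(0.4178, 0.2374, 0.3389, 0.196, 0.1762, 0.2759, 0.2762,
              0.2156, 0.2622, 0.2407)
    list(
        n = 4830,
        snps = snpSpec(ids, mafs),
        model = effectModel(
            intercept = qlogis(0.006),
            additive = c(rs7521784 = log(1.38), rs1045653 = log(0.63)),
            epistasis = list(list(snps = c("rs12693006", "rs58499534"),
                                  cells = checkerboardCells(log(4))))),
        exposureConfig = list(),
        missingRate = 0)
}

#' Simulate a full case-control cohort
#'
#' Draws genotypes, exposures and the outcome from one configuration and
#' packs them into a \linkS4class{CohortExperiment} carrying a truth
#' record. With \code{design = "balanced"}, batches are simulated until
#' the requested numbers of cases and controls are reached
#' (retrospective case-control sampling from the same population model).
#'
#' @param config list as returned by \code{\link{defaultCohortConfig}}
#'   (entries: \code{n}, \code{snps}, \code{model},
#'   \code{exposureConfig}, \code{missingRate}, optional
#'   \code{diiComponents}).
#' @param seed integer seed; the genotype, exposure and outcome streams
#'   are derived from it deterministically.
#' @param design \code{"population"} (n samples as simulated) or
#'   \code{"balanced"}.
#' @param nCase,nControl target counts for \code{design = "balanced"}.
#' @return a \linkS4class{CohortExperiment}.
#' @examples
#' ce <- simulateCohort(defaultCohortConfig(), seed = 7)
#' ce
#' @export
simulateCohort <- function(config = defaultCohortConfig(), seed,
                           design = c("population", "balanced"),
                           nCase = 2000, nControl = 2000) {
    design <- match.arg(design)
    seed <- as.integer(seed)
    drawBatch <- function(n, s) {
        g <- simulateGenotypes(config$snps, n, seed = s,
                               missingRate = config$missingRate %||% 0)
        e <- simulateExposures(n, config$exposureConfig %||% list(),
                               seed = s + 1L,
                               diiComponents = config$diiComponents)
        ## outcome is generated before missingness matters: regenerate a
        ## complete matrix when calls are masked
        gFull <- if (any(is.na(g)))
            simulateGenotypes(config$snps, n, seed = s) else g
        o <- simulateOutcome(gFull, e, config$model, seed = s + 2L)
        list(g = g, e = e, y = o$outcome, truth = o$truth)
    }
    if (design == "population") {
        b <- drawBatch(config$n, seed)
        g <- b$g; e <- b$e; y <- b$y; truth <- b$truth
    } else {
        gs <- list(); es <- list(); ys <- integer(); truth <- NULL
        got <- c(case = 0L, control = 0L)
        s <- seed
        while (got["case"] < nCase || got["control"] < nControl) {
            b <- drawBatch(max(config$n, 2000L), s)
            truth <- truth %||% b$truth
            keep <- logical(length(b$y))
            needCase <- nCase - got["case"]
            needCtrl <- nControl - got["control"]
            keep[which(b$y == 1L)[seq_len(min(needCase, sum(b$y == 1L)))]] <- TRUE
            keep[which(b$y == 0L)[seq_len(min(needCtrl, sum(b$y == 0L)))]] <- TRUE
            gs[[length(gs) + 1L]] <- b$g[, keep, drop = FALSE]
            es[[length(es) + 1L]] <- b$e[keep, , drop = FALSE]
            ys <- c(ys, b$y[keep])
            got <- got + c(case = sum(b$y[keep] == 1L),
                           control = sum(b$y[keep] == 0L))
            s <- s + 101L
            if (s > seed + 101L * 500L)
                stop("balanced design unreachable: outcome too rare")
        }
        g <- do.call(cbind, gs)
        e <- do.call(rbind, es)
        y <- ys
        colnames(g) <- sprintf("sample%05d", seq_along(y))
        rownames(e) <- colnames(g)
    }
    e$outcome <- y
    if (sum(y == 1L) < 1L || sum(y == 0L) < 1L)
        stop("simulated cohort must contain at least one case and one control")
    truth$seed <- seed
    info <- config$snps
    rownames(info) <- info$id
    CohortExperiment(g, snpInfo = info, sampleData = e, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
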