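test_that("intercept-only fit returns the logit of the case fraction", {
    y <- rep(c(1, 0), c(30, 70))
    fit <- fitLogistic(y, NULL)
    expect_equal(unname(fit$coefficients), qlogis(0.3), tolerance = 1e-8)
    expect_lte(fit$loglik, 0)
})

test_that("logistic fits reproduce 2x2 cross-product odds ratios", {
    f <- fit2x2(10, 90, 5, 95)
    expect_equal(exp(f$coefficients[["exposed"]]), crossOR(10, 90, 5, 95),
                 tolerance = 1e-8)
    expect_equal(exp(f$coefficients[["exposed"]]), 2.111111,
                 tolerance = 1e-6)
    set.seed(23)
    for (rep in 1:40) {
        cells <- sample(c(1:6, 10, 25, 90), 4, replace = TRUE)
        f <- fit2x2(cells[1], cells[2], cells[3], cells[4])
        expect_equal(exp(f$coefficients[["exposed"]]),
                     crossOR(cells[1], cells[2], cells[3], cells[4]),
                     tolerance = 1e-8)
    }
})

test_that("Wald OR and CI follow the closed form", {
    fake <- structure(list(coefficients = c(b = 0), se = c(0.1),
                           converged = TRUE, separation = FALSE,
                           iterations = 1), class = "GLMFit")
    w <- waldOR(fake, "b")
    expect_equal(w$or, 1)
    expect_equal(c(w$ciLow, w$ciHigh), exp(c(-1, 1) * 1.96 * 0.1),
                 tolerance = 1e-10)

    tight <- structure(list(coefficients = c(b = log(2)), se = c(1e-9),
                            converged = TRUE, separation = FALSE,
                            iterations = 1), class = "GLMFit")
    wt <- waldOR(tight, "b")
    expect_equal(c(wt$ciLow, wt$or, wt$ciHigh), c(2, 2, 2),
                 tolerance = 1e-6)
})

test_that("Wald p agrees with the chi-square score test in magnitude", {
    f <- fit2x2(10, 90, 5, 95)
    w <- waldOR(f, "exposed")
    pScore <- prop.test(c(10, 5), c(100, 100), correct = FALSE)$p.value
    expect_lt(abs(log10(w$p) - log10(pScore)), 1)
})

test_that("parameter recovery: planted OR 3 recovered within 10%", {
    g <- simulateGenotypes(snpSpec("s1", 0.3), 20000, seed = 25)
    o <- simulateOutcome(g, NULL, effectModel(
        qlogis(0.15), additive = c(s1 = log(3))), seed = 26)
    fit <- fitLogistic(o$outcome, cbind(snp = g["s1", ]))
    expect_lt(abs(exp(fit$coefficients[["snp"]]) - 3) / 3, 0.1)
})

test_that("separation is flagged, not silently reported", {
    y <- rep(c(1, 0), each = 20)
    x <- y                      # perfect separation
    fit <- fitLogistic(y, cbind(x = x))
    expect_false(fit$converged)
    expect_true(fit$separation)
    expect_error(waldOR(fit, "x"), "converge")
})

test_that("rank-deficient or short designs are rejected", {
    y <- rbinom(10, 1, 0.5)
    X <- cbind(a = 1:10, b = 2 * (1:10))
    expect_error(fitLogistic(y, X), "rank")
    expect_error(fitLogistic(c(0, 1), cbind(a = 1:2, b = c(2, 1), c = c(1, 3))),
                 "fewer complete-case rows")
})

test_that("likelihood-ratio test behaves at the boundaries", {
    y <- rbinom(200, 1, 0.4)
    x <- rnorm(200)
    full <- fitLogistic(y, cbind(x = x))
    expect_equal(lrt(full, full, 0), 1)

    g <- simulateGenotypes(snpSpec("s1", 0.3), 10000, seed = 27)
    o <- simulateOutcome(g, NULL, effectModel(
        qlogis(0.2), additive = c(s1 = log(2))), seed = 28)
    f1 <- fitLogistic(o$outcome, cbind(snp = g["s1", ]))
    f0 <- fitLogistic(o$outcome, NULL)
    expect_lt(lrt(f1, f0, 1), 1e-6)
    expect_error(lrt(f0, f1, 1), "nesting")
})

test_that("Wald and LRT p-values agree within a factor of two", {
    g <- simulateGenotypes(snpSpec("s1", 0.3), 5000, seed = 29)
    o <- simulateOutcome(g, NULL, effectModel(
        qlogis(0.2), additive = c(s1 = log(1.2))), seed = 30)
    f1 <- fitLogistic(o$outcome, cbind(snp = g["s1", ]))
    f0 <- fitLogistic(o$outcome, NULL)
    pW <- waldOR(f1, "snp")$p
    pL <- lrt(f1, f0, 1)
    expect_lt(max(pW / pL, pL / pW), 2)
})

test_that("the GWAS scan flags planted signals and skips monomorphs", {
    cfg <- nullCohortConfig(nSnps = 6, n = 20000, prevalence = 0.1)
    cfg$model <- effectModel(qlogis(0.1), additive = c(s02 = log(1.6)))
    ce <- simulateCohort(cfg, seed = 33)
    gw <- gwasScan(ce, covariates = c("age", "sex"))
    expect_true(gw["s02", "pass"])
    expect_gt(gw["s02", "or"], 1.3)

    g <- dosage(ce)[1:3, 1:500]
    g[3, ] <- 0L
    ce2 <- CohortExperiment(g, sampleData = data.frame(
        outcome = cohortOutcome(ce)[1:500]))
    gw2 <- gwasScan(ce2)
    expect_equal(gw2$note[3], "monomorphic")
    expect_true(is.na(gw2$or[3]))
})

test_that("GWAS results are invariant to SNP and sample ordering", {
    cfg <- nullCohortConfig(nSnps = 5, n = 800)
    ce <- simulateCohort(cfg, seed = 35)
    gw <- gwasScan(ce, covariates = c("age", "bmi"))
    perm <- sample(ncol(ce))
    gwPerm <- gwasScan(ce[rev(rownames(ce)), perm],
                       covariates = c("age", "bmi"))
    for (s in rownames(ce)) {
        expect_equal(gw[s, "p"], gwPerm[s, "p"], tolerance = 1e-8)
        expect_equal(gw[s, "or"], gwPerm[s, "or"], tolerance = 1e-8)
    }
})

test_that("covariate adjustment attenuates confounded SNP effects", {
    set.seed(37)
    n <- 8000
    g <- rbinom(n, 2, 0.3)
    conf <- g + rnorm(n)             # covariate correlated with the SNP
    y <- rbinom(n, 1, plogis(-2 + 0.8 * conf))  # disease via covariate
    ce <- CohortExperiment(rbind(s1 = g), sampleData = data.frame(
        outcome = y, conf = conf))
    crude <- gwasScan(ce)
    adj <- gwasScan(ce, covariates = "conf")
    expect_lt(abs(adj["s1", "beta"]), abs(crude["s1", "beta"]))
})
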