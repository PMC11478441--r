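test_that("score residuals follow the intercept-only closed form", {
    y <- rep(c(1, 0), c(3, 7))
    s <- scoreResiduals(y)
    expect_equal(s, rep(c(0.7, -0.3), c(3, 7)), tolerance = 1e-8)
    expect_lt(abs(sum(s)), 1e-6)
})

test_that("covariate adjustment shrinks case scores where risk is predicted", {
    set.seed(43)
    n <- 2000
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 1.5 * x))
    s <- scoreResiduals(y, data.frame(x = x))
    expect_lt(abs(sum(s)), 1e-6)
    cases <- y == 1
    ## cases with high predicted risk contribute smaller scores
    expect_lt(cor(s[cases], x[cases]), 0)
})

test_that("cell labeling applies the score-sum rule", {
    g <- rbind(a = c(0, 0, 1, 1, 2), b = c(0, 0, 1, 1, 0))
    s <- c(0.6, -0.4, -0.2, -0.3, -0.1)
    cells <- labelCells(g, s)
    expect_true(cells$highRisk[cells$cell == "0|0"])      # sum 0.2
    expect_false(cells$highRisk[cells$cell == "1|1"])     # all negative
    expect_equal(sum(cells$n), 5L)
    empty <- labelCells(g[, 0, drop = FALSE], numeric())
    expect_equal(nrow(empty), 0L)
})

test_that("balanced accuracy matches its closed form and degenerate cases", {
    pred <- rep(c(TRUE, FALSE, FALSE, TRUE), c(8, 2, 6, 4))
    y <- rep(c(1, 0), c(10, 10))
    expect_equal(balancedAccuracy(pred, y), 0.7)
    expect_equal(balancedAccuracy(rep(TRUE, 20), y), 0.5)
    expect_equal(balancedAccuracy(rep(FALSE, 20), y), 0.5)
    expect_error(balancedAccuracy(pred[1:10], rep(1, 10)),
                 "single-class")
    expect_equal(balancedAccuracy(c(rep(TRUE, 10), rep(FALSE, 10)), y), 1)
})

test_that("fold plans are stratified with near-equal sizes", {
    y <- rep(c(1, 0), c(33, 467))
    plan <- makeCVPlan(y, 10, seed = 45)
    for (cls in 0:1) {
        sizes <- table(plan[y == cls])
        expect_lte(diff(range(sizes)), 1)
        expect_equal(length(sizes), 10L)
    }
})

test_that("for k=1 without covariates, labels equal the sign of the cell
          case-fraction excess", {
    set.seed(47)
    g <- rbind(s = rbinom(1200, 2, 0.4))
    y <- rbinom(1200, 1, plogis(-1 + 0.5 * g[1, ]))
    cells <- labelCells(g, scoreResiduals(y))
    for (i in seq_len(nrow(cells))) {
        members <- g[1, ] == as.integer(cells$cell[i])
        expect_equal(cells$highRisk[i],
                     mean(y[members]) > mean(y))
    }
})

test_that("cross-validation is deterministic and detects planted pairs", {
    ce <- simulateCohort(plantedPairConfig(n = 4000, prevalence = 0.2),
                         seed = 49)
    y <- cohortOutcome(ce)
    s <- scoreResiduals(y)
    plan <- makeCVPlan(y, 10, seed = 50)
    cv1 <- crossValidate(dosage(ce)[c("s03", "s07"), ], s, y, plan)
    cv2 <- crossValidate(dosage(ce)[c("s03", "s07"), ], s, y, plan)
    expect_identical(cv1, cv2)
    expect_gt(mean(cv1$teba), 0.55)
})

test_that("null-data testing accuracy centres on 0.5 and TRBA >= TEBA", {
    set.seed(51)
    tr <- te <- numeric(100)
    for (i in 1:100) {
        g <- simulateGenotypes(snpSpec(c("a", "b"), c(0.3, 0.3)), 500,
                               seed = 5100 + i)
        y <- rbinom(500, 1, 0.3)
        plan <- makeCVPlan(y, 10, seed = i)
        cv <- crossValidate(g, scoreResiduals(y), y, plan)
        tr[i] <- mean(cv$trba); te[i] <- mean(cv$teba)
    }
    expect_lt(abs(mean(te) - 0.5), 0.02)
    expect_gt(mean(tr), mean(te))   # training optimism
})

test_that("signed-rank p matches exact extreme and symmetric cases", {
    expect_equal(signedRankTest(0.5 + (1:10) / 100), 2 / 2^10,
                 tolerance = 1e-12)
    sym <- 0.5 + c(-5, -4, -2, -1, 1.5, 2.5, 3.5, 4.5) / 100
    expect_gt(signedRankTest(sym), 0.7)
    expect_warning(p1 <- signedRankTest(rep(0.5, 10)), "null value")
    expect_equal(p1, 1)
})

test_that("signed-rank p equals full sign enumeration on random inputs", {
    set.seed(53)
    for (rep in 1:50) {
        x <- 0.5 + sample(seq(-0.2, 0.2, by = 0.013), 10)
        x <- x[x != 0.5]
        if (anyDuplicated(abs(x - 0.5))) next
        expect_equal(signedRankTest(x), signedRankOracle(x),
                     tolerance = 1e-12)
    }
})

test_that("the exhaustive search counts combinations and respects budget", {
    cfg <- nullCohortConfig(nSnps = 10, n = 200, prevalence = 0.3)
    ce <- simulateCohort(cfg, seed = 55)
    gm <- gmdrSearch(ce, rownames(ce), kRange = 2:8, seed = 1)
    expect_equal(gm@nEvaluated, sum(choose(10, 2:8)))   # 837
    expect_equal(nrow(modelTable(gm)), 7L)
    expect_error(
        gmdrSearch(ce, rownames(ce), kRange = 2:8, seed = 1, budget = 10),
        "budget")
})

test_that("a planted pure-epistatic pair is selected with full consistency", {
    ce <- simulateCohort(plantedPairConfig(n = 22000), seed = 57,
                         design = "balanced",
                         nCase = 1000, nControl = 1000)
    gm <- gmdrSearch(ce, rownames(ce), kRange = 2, seed = 57)
    b <- bestModel(gm)
    expect_identical(sort(b$snps), c("s03", "s07"))
    expect_equal(b$cvc, 10L)
    expect_lt(b$p, 0.01)
    expect_gt(b$teba, 0.55)
})

test_that("search results are invariant to sample order and enumeration order", {
    ce <- simulateCohort(plantedPairConfig(n = 1500, prevalence = 0.3),
                         seed = 59)
    y <- cohortOutcome(ce)
    plan <- makeCVPlan(y, 10, seed = 60)
    gm1 <- gmdrSearch(ce, rownames(ce)[1:6], kRange = 2, plan = plan)
    set.seed(61)
    perm <- sample(ncol(ce))
    gm2 <- gmdrSearch(ce[, perm], rownames(ce)[c(4, 2, 6, 1, 5, 3)],
                      kRange = 2, plan = plan[perm])
    expect_identical(bestModel(gm1)$snps, bestModel(gm2)$snps)
    expect_identical(bestModel(gm1)$cvc, bestModel(gm2)$cvc)
    expect_equal(bestModel(gm1)$teba, bestModel(gm2)$teba,
                 tolerance = 1e-12)
})

test_that("samples missing a combination genotype are dropped per combination", {
    g <- rbind(a = c(0, 1, NA, 2, 1, 0), b = c(0, 1, 1, 2, NA, 0))
    y <- c(1, 0, 1, 0, 1, 0)
    s <- scoreResiduals(y)
    cells <- labelCells(g, s)
    expect_equal(sum(cells$n), 4L)   # two samples dropped
})
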