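test_that("HWE exact test handles worked and extreme tables", {
    expect_identical(hweExactTest(100, 0, 0), 1)
    expect_equal(hweExactTest(25, 50, 25), hweOracle(25, 50, 25))
    expect_lt(hweExactTest(0, 100, 0), 1e-10)
    expect_error(hweExactTest(0, 0, 0), "zero")
    expect_error(hweExactTest(-1, 2, 3), "non-negative")
})

test_that("HWE exact test equals brute-force enumeration for n <= 50", {
    got <- numeric(); want <- numeric()
    for (n in 1:50) for (nAa in 0:n) for (naa in 0:(n - nAa)) {
        nAA <- n - nAa - naa
        got <- c(got, hweExactTest(nAA, nAa, naa))
        want <- c(want, hweOracle(nAA, nAa, naa))
    }
    expect_equal(got, want, tolerance = 1e-10)
})

test_that("per-SNP statistics match hand counts", {
    g <- rbind(a = c(0, 0, 1, 1), b = c(NA, NA, NA, NA),
               c = c(2, 2, 2, 2))
    st <- computeSnpStats(g)
    expect_equal(st["a", "maf"], 0.25)
    expect_equal(st["a", "hetRate"], 0.5)
    expect_equal(st["a", "callRate"], 1.0)
    expect_true(st["b", "noCalls"])
    expect_equal(st["b", "callRate"], 0)
    expect_equal(st["c", "maf"], 0)        # folded after re-orientation
    expect_true(st["c", "flipped"])
})

test_that("QC keeps and removes SNPs by the stated thresholds", {
    set.seed(1)
    good <- rbinom(400, 2, 0.3)
    rare <- rbinom(400, 2, 0.005)          # MAF below 0.01
    hweBad <- rep(1L, 400)                 # all heterozygous
    patchy <- good; patchy[1:40] <- NA     # 10% missing
    g <- rbind(good = good, rare = rare, hweBad = hweBad,
               patchy = patchy)
    qc <- applyQC(g)
    expect_identical(keptSNPs(qc$report), "good")
    rem <- qc$report@removed
    expect_equal(rem$reasons[rem$id == "rare"], "maf")
    expect_equal(rem$reasons[rem$id == "hweBad"], "hwe")
    expect_equal(rem$reasons[rem$id == "patchy"], "missing")
    expect_equal(length(keptSNPs(qc$report)) + nrow(rem), nrow(g))

    ## common high-heterozygosity SNP in HWE is kept
    st <- computeSnpStats(rbind(x = good))
    expect_gt(st$hetRate, 0.30)
    expect_true("good" %in% keptSNPs(qc$report))
})

test_that("QC is idempotent", {
    cfg <- nullCohortConfig(nSnps = 8)
    cfg$missingRate <- 0.03
    ce <- simulateCohort(cfg, seed = 9)
    once <- applyQC(ce)
    twice <- applyQC(once$genotypes)
    expect_identical(dosage(once$genotypes), dosage(twice$genotypes))
})

test_that("empty QC result warns rather than errors", {
    g <- rbind(a = rep(1L, 100))   # extreme heterozygote excess
    expect_warning(qc <- applyQC(g), "no SNP passed")
    expect_length(keptSNPs(qc$report), 0)
})

test_that("D-prime estimation matches the known-phase closed form", {
    set.seed(101)
    for (rep in 1:5) {
        pA <- runif(1, 0.1, 0.5); pB <- runif(1, 0.1, 0.5)
        dp <- runif(1, 0, 0.95)
        dmax <- min(pA * (1 - pB), (1 - pA) * pB)
        h <- c(pA * pB + dp * dmax, pA * (1 - pB) - dp * dmax,
               (1 - pA) * pB - dp * dmax,
               (1 - pA) * (1 - pB) + dp * dmax)
        ph <- drawPhased(h, 20000)
        want <- dprimeFromHaps(ph$hapCounts)   # oracle sees the phase
        got <- estimateDprime(ph$g["a", ], ph$g["b", ])
        expect_lt(abs(got - want), 0.02)
    }
})

test_that("D-prime is 1 for duplicated SNPs, ~0 for independent ones", {
    g <- simulateGenotypes(snpSpec("a", 0.3), 2000, seed = 13)
    expect_equal(estimateDprime(g[1, ], g[1, ]), 1)
    g2 <- simulateGenotypes(snpSpec(c("x", "y"), c(0.3, 0.3)), 50000,
                            seed = 14)
    expect_lt(estimateDprime(g2["x", ], g2["y", ]), 0.05)
})

test_that("D-prime is symmetric, bounded, and rejects monomorphic input", {
    set.seed(15)
    for (rep in 1:10) {
        g <- simulateGenotypes(
            snpSpec(c("a", "b"), runif(2, 0.05, 0.5)), 300,
            seed = 150 + rep)
        d12 <- estimateDprime(g[1, ], g[2, ])
        d21 <- estimateDprime(g[2, ], g[1, ])
        expect_equal(d12, d21, tolerance = 1e-6)
        expect_gte(d12, 0); expect_lte(d12, 1)
    }
    expect_error(estimateDprime(rep(0, 100), rbinom(100, 2, 0.3)),
                 "monomorphic")
})

test_that("HWE rejection rate is at most 7% under the null at n=2000", {
    sp <- snpSpec(sprintf("s%03d", 1:400), rep(0.3, 400))
    g <- simulateGenotypes(sp, 2000, seed = 17)
    ps <- computeSnpStats(g)$hweP
    expect_lte(mean(ps <= 0.05), 0.07)
})

test_that("LD pruning keeps the stronger-associated SNP of a linked pair", {
    m <- matrix(c(1, 0.9, 0.9, 1), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    expect_identical(ldPrune(m, c(a = 1e-6, b = 1e-3)), "a")
    expect_identical(ldPrune(m, c(a = 1e-3, b = 1e-6)), "b")

    m0 <- diag(1, 3)
    dimnames(m0) <- list(letters[1:3], letters[1:3])
    expect_identical(ldPrune(m0, c(a = .1, b = .2, c = .3)),
                     c("a", "b", "c"))
    expect_error(ldPrune(m, c(a = 1e-6)), "missing gwasP")
})

test_that("pruned sets contain no pair at or above the threshold", {
    ## three LD clusters of linked SNPs plus singletons
    set.seed(19)
    specs <- snpSpec(
        sprintf("s%02d", 1:9), rep(0.3, 9),
        ldPartner = c(NA, "s01", "s01", NA, "s04", NA, NA, "s07", NA),
        ldDprime = c(NA, 0.9, 0.85, NA, 0.95, NA, NA, 0.9, NA))
    g <- simulateGenotypes(specs, 8000, seed = 19)
    dm <- dprimeMatrix(g)
    p <- setNames(runif(9, 1e-6, 1e-3), rownames(g))
    kept <- ldPrune(dm, p, threshold = 0.4)
    sub <- dm[kept, kept]
    diag(sub) <- 0
    expect_true(all(sub < 0.4))
    expect_gte(length(kept), 4)
})
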