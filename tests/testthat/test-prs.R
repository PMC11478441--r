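test_that("risk alleles follow the OR direction", {
    gw <- S4Vectors::DataFrame(snp = c("a", "b", "c"),
                               or = c(1.59, 0.63, 1.0),
                               row.names = c("a", "b", "c"))
    info <- S4Vectors::DataFrame(minorAllele = c("G", "T", "A"),
                                 majorAllele = c("T", "C", "C"),
                                 row.names = c("a", "b", "c"))
    map <- assignRiskAlleles(gw, c("a", "b"), info)
    expect_equal(map["a", "riskAllele"], "G")   # minor allele risk
    expect_true(map["a", "riskIsMinor"])
    expect_equal(map["b", "riskAllele"], "C")   # major allele risk
    expect_false(map["b", "riskIsMinor"])
    expect_error(assignRiskAlleles(gw, "c", info), "ambiguous")
    expect_error(assignRiskAlleles(gw, "nosuch", info), "no association")
})

test_that("risk-allele counting scores genotypes 0/1/2 and sums them", {
    ## one SNP, G = risk = minor allele: TT, GT, GG -> 0, 1, 2
    map <- S4Vectors::DataFrame(snp = "s", riskIsMinor = TRUE,
                                row.names = "s")
    g <- rbind(s = c(TT = 0L, GT = 1L, GG = 2L))
    expect_equal(as.numeric(computePRS(g, map)), c(0, 1, 2))
    ## major-allele risk flips the count
    mapM <- S4Vectors::DataFrame(snp = "s", riskIsMinor = FALSE,
                                 row.names = "s")
    expect_equal(as.numeric(computePRS(g, mapM)), c(2, 1, 0))
    ## eight heterozygous SNPs sum to 8
    g8 <- matrix(1L, 8, 3, dimnames = list(paste0("s", 1:8), NULL))
    map8 <- S4Vectors::DataFrame(snp = paste0("s", 1:8),
                                 riskIsMinor = rep(TRUE, 8),
                                 row.names = paste0("s", 1:8))
    expect_equal(as.numeric(computePRS(g8, map8)), c(8, 8, 8))
})

test_that("missing genotypes are excluded and flagged, or imputed on request", {
    g <- matrix(c(1L, NA, 2L, 0L), 2, 2,
                dimnames = list(c("s1", "s2"), c("A", "B")))
    map <- S4Vectors::DataFrame(snp = c("s1", "s2"),
                                riskIsMinor = c(TRUE, TRUE),
                                row.names = c("s1", "s2"))
    sc <- computePRS(g, map)
    expect_true(is.na(sc[["A"]]))
    expect_identical(attr(sc, "flagged"), "A")
    expect_equal(sc[["B"]], 2 + 0)
    scI <- computePRS(g, map, missingPolicy = "meanImpute")
    expect_false(anyNA(scI))
    expect_length(attr(scI, "flagged"), 0)
})

test_that("PRS is invariant to SNP order and allele-label swaps", {
    set.seed(63)
    g <- simulateGenotypes(snpSpec(paste0("s", 1:4), rep(0.3, 4)), 100,
                           seed = 63)
    map <- S4Vectors::DataFrame(snp = paste0("s", 1:4),
                                riskIsMinor = c(TRUE, FALSE, TRUE, TRUE),
                                row.names = paste0("s", 1:4))
    s1 <- computePRS(g, map)
    s2 <- computePRS(g[4:1, ], map[4:1, ])
    expect_equal(s1, s2)
    ## swap coding of s2 (dosage -> 2 - dosage) and flip its direction
    gSwap <- g; gSwap["s2", ] <- 2L - gSwap["s2", ]
    mapSwap <- map; mapSwap["s2", "riskIsMinor"] <- TRUE
    expect_equal(computePRS(gSwap, mapSwap), s1)
})

test_that("fixed cuts reproduce the 0-6 / 7-8 / >=9 categories", {
    cat3 <- categorizePRS(c(0, 6, 7, 8, 9, 16))
    expect_equal(as.character(cat3),
                 c("low", "low", "medium", "medium", "high", "high"))
    expect_true(is.na(categorizePRS(c(3, NA))[2]))
})

test_that("tertile cuts split near-uniform scores into near-equal thirds", {
    cat3 <- categorizePRS(0:16, cutPoints = "tertile")
    sizes <- table(cat3)
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sum(sizes), 17L)
    expect_error(categorizePRS(rep(5, 10), cutPoints = "tertile"),
                 "degenerate")
})

test_that("category counts always partition the scored samples", {
    set.seed(65)
    sc <- c(rpois(200, 8), NA, NA)
    cat3 <- categorizePRS(sc, cutPoints = "tertile")
    expect_equal(sum(table(cat3)), sum(!is.na(sc)))
})

test_that("cases carry higher PRS when all mapped alleles are risk alleles", {
    cfg <- nullCohortConfig(nSnps = 6, n = 6000, prevalence = 0.15)
    cfg$model <- effectModel(
        qlogis(0.1),
        additive = setNames(rep(log(1.4), 6), sprintf("s%02d", 1:6)))
    ce <- simulateCohort(cfg, seed = 67)
    map <- S4Vectors::DataFrame(snp = rownames(ce),
                                riskIsMinor = rep(TRUE, 6),
                                row.names = rownames(ce))
    sc <- computePRS(ce, map)
    y <- cohortOutcome(ce)
    expect_gt(mean(sc[y == 1]), mean(sc[y == 0]))
})

test_that("buildPRS wires the scan, scoring and categories together", {
    cfg <- nullCohortConfig(nSnps = 4, n = 3000, prevalence = 0.2)
    cfg$model <- effectModel(
        qlogis(0.15),
        additive = c(s01 = log(1.5), s02 = -log(1.5), s03 = log(1.3),
                     s04 = log(1.3)))
    ce <- simulateCohort(cfg, seed = 69)
    gw <- gwasScan(ce)
    prs <- buildPRS(ce, rownames(ce), gw, cutPoints = "gc8")
    expect_s4_class(prs, "PRSProfile")
    expect_equal(prs@cutPoints, c(6, 8))
    expect_true(all(prsScore(prs) >= 0 & prsScore(prs) <= 8))
    expect_equal(length(prsScore(prs)), ncol(ce))
})
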