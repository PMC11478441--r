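## Independent oracles used to check the package implementations.
## Each derives its answer along a different route than the code under
## test (full enumeration, closed forms on known phase, cross-products).

## Brute-force HWE exact test: enumerate every genotype table with the
## observed sample size and allele counts, compute each table's
## conditional probability from first principles (multinomial kernel
## n! 2^het / (nAA! nAa! naa!)), normalize, and sum the probabilities of
## tables no more probable than the observed one.
hweOracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    rare <- min(2 * nAA + nAa, 2 * naa + nAa)
    if (rare == 0) return(1)
    tables <- list()
    for (h in 0:rare) {
        if ((rare - h) %% 2 != 0) next
        r2 <- (rare - h) / 2
        c2 <- n - h - r2
        if (c2 < 0) next
        tables[[length(tables) + 1]] <- c(het = h, rhom = r2, chom = c2)
    }
    w <- vapply(tables, function(t) {
        ## n! 2^h / (h! r2! c2!) computed multiplicatively
        exp(lgamma(n + 1) - lgamma(t["het"] + 1) - lgamma(t["rhom"] + 1) -
            lgamma(t["chom"] + 1) + t["het"] * log(2))
    }, 1.0)
    p <- w / sum(w)
    hets <- vapply(tables, `[[`, 1.0, "het")
    obs <- p[hets == nAa]
    min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

## Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
## assignments of the ranked absolute deviations (valid for tie-free,
## zero-free inputs).
signedRankOracle <- function(x, mu = 0.5) {
    d <- x - mu
    stopifnot(all(d != 0), !anyDuplicated(abs(d)))
    r <- rank(abs(d))
    n <- length(d)
    tObs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    tAll <- as.numeric(signs %*% r)
    pLess <- mean(tAll <= tObs)
    pGreater <- mean(tAll >= tObs)
    min(1, 2 * min(pLess, pGreater))
}

## D' from known haplotype frequencies (closed form on true phase).
dprimeFromHaps <- function(h) {   # h = c(h11, h10, h01, h00)
    h <- h / sum(h)
    pA <- h[1] + h[2]; pB <- h[1] + h[3]
    D <- h[1] - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    abs(D) / dmax
}

## Draw a phased two-locus sample: returns genotype rows and the
## realized haplotype counts (the oracle knows the phase).
drawPhased <- function(h, n) {
    hap1 <- sample.int(4, n, replace = TRUE, prob = h)
    hap2 <- sample.int(4, n, replace = TRUE, prob = h)
    counts <- tabulate(c(hap1, hap2), 4)
    g1 <- (hap1 <= 2) + (hap2 <= 2)
    g2 <- (hap1 %% 2 == 1) + (hap2 %% 2 == 1)
    list(g = rbind(a = g1, b = g2), hapCounts = counts)
}

## 2x2 cross-product odds ratio.
crossOR <- function(a, b, c, d) (a * d) / (b * c)

## Fit a logistic 2x2 design from an aggregated table via fitLogistic
## with weights (exposed cases a, exposed controls b, unexposed cases c,
## unexposed controls d).
fit2x2 <- function(a, b, c, d) {
    y <- c(1, 0, 1, 0)
    x <- c(1, 1, 0, 0)
    fitLogistic(y, cbind(exposed = x), weights = c(a, b, c, d))
}

## Small null cohort builder used across tests.
nullCohortConfig <- function(nSnps = 5, maf = 0.3, n = 600,
                             prevalence = 0.3) {
    list(n = n,
         snps = snpSpec(sprintf("s%02d", seq_len(nSnps)),
                        rep(maf, nSnps)),
         model = effectModel(intercept = qlogis(prevalence)),
         exposureConfig = list(), missingRate = 0)
}

## Planted checkerboard-pair cohort config.
plantedPairConfig <- function(nSnps = 10, maf = 0.3, n = 5000,
                              prevalence = 0.1, beta = log(4),
                              pair = c("s03", "s07")) {
    cfg <- nullCohortConfig(nSnps, maf, n, prevalence)
    cfg$model <- effectModel(
        intercept = qlogis(prevalence),
        epistasis = list(list(snps = pair,
                              cells = checkerboardCells(beta))))
    cfg
}
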