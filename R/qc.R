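#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on one biallelic genotype table, using the
#' conditional distribution of the heterozygote count given the allele
#' counts (the Levene-Haldane distribution): all heterozygote counts
#' compatible with the observed allele margin are enumerated and the
#' probabilities of tables no more probable than the observed one are
#' summed.
#'
#' @param nAA,nAa,naa genotype counts (major homozygote, heterozygote,
#'   minor homozygote); non-negative, total >= 1.
#' @return exact two-sided p-value in (0, 1]. Monomorphic tables return
#'   exactly 1.
#' @examples
#' hweExactTest(25, 50, 25)
#' hweExactTest(0, 100, 0)   # extreme heterozygote excess
#' @export
hweExactTest <- function(nAA, nAa, naa) {
    counts <- c(nAA, nAa, naa)
    if (any(is.na(counts)) || any(counts < 0))
        stop("genotype counts must be non-negative")
    n <- sum(counts)
    if (n < 1)
        stop("undefined input: all genotype counts are zero")
    rare <- min(2 * nAA + nAa, 2 * naa + nAa)  # rare allele copies
    if (rare == 0)
        return(1)
    hs <- seq(rare %% 2, rare, by = 2)
    hs <- hs[n - (hs + (rare - hs) / 2) >= 0]
    ## log P(h) up to a constant: n! 2^h / (h! homR! homC!)
    logw <- hs * log(2) - lfactorial(hs) -
        lfactorial((rare - hs) / 2) -
        lfactorial(n - (hs + (rare - hs) / 2))
    w <- exp(logw - max(logw))
    p <- w / sum(w)
    obs <- p[match(nAa, hs)]
    min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Per-SNP summary statistics
#'
#' Computes, from non-missing calls per SNP: minor allele frequency
#' (folded to [0, 0.5] -- if the coded allele exceeds frequency 0.5 the
#' orientation is flagged), call rate, heterozygote fraction and the
#' exact Hardy-Weinberg p-value. SNPs with zero non-missing calls are
#' flagged and their statistics set to \code{NA}.
#'
#' @param genotypes SNP x sample dosage matrix (0/1/2/NA) or a
#'   \linkS4class{CohortExperiment}.
#' @return \code{DataFrame} with columns \code{id}, \code{maf},
#'   \code{callRate}, \code{hetRate}, \code{hweP}, \code{flipped},
#'   \code{noCalls}.
#' @examples
#' g <- rbind(s1 = c(0, 0, 1, 1))
#' computeSnpStats(g)
#' @export
computeSnpStats <- function(genotypes) {
    g <- if (is(genotypes, "CohortExperiment")) dosage(genotypes)
         else as.matrix(genotypes)
    stopifnot(ncol(g) >= 1)
    res <- lapply(seq_len(nrow(g)), function(i) {
        x <- g[i, ]
        x <- x[!is.na(x)]
        if (!length(x))
            return(data.frame(maf = NA_real_, callRate = 0,
                              hetRate = NA_real_, hweP = NA_real_,
                              flipped = NA, noCalls = TRUE))
        af <- mean(x) / 2            # frequency of the coded allele
        flipped <- af > 0.5
        n0 <- sum(x == 0); n1 <- sum(x == 1); n2 <- sum(x == 2)
        hwe <- if (flipped) hweExactTest(n2, n1, n0)
               else hweExactTest(n0, n1, n2)
        data.frame(maf = min(af, 1 - af),
                   callRate = length(x) / ncol(g),
                   hetRate = n1 / length(x), hweP = hwe,
                   flipped = flipped, noCalls = FALSE)
    })
    out <- DataFrame(do.call(rbind, res))
    out <- cbind(DataFrame(id = rownames(g) %||%
                               paste0("snp", seq_len(nrow(g)))), out)
    rownames(out) <- out$id
    out
}

#' Default SNP quality-control thresholds
#'
#' Call rate >= 96\% (missing rate < 4\%), MAF > 0.01, exact
#' Hardy-Weinberg p > 0.05, heterozygote fraction < 0.30.
#' @return named list.
#' @export
qcThresholds <- function(maxMissing = 0.04, minMAF = 0.01,
                         minHweP = 0.05, maxHet = 0.30) {
    th <- list(maxMissing = maxMissing, minMAF = minMAF,
               minHweP = minHweP, maxHet = maxHet)
    if (any(unlist(th) < 0 | unlist(th) > 1))
        stop("all thresholds must lie in [0, 1]")
    th
}

#' Apply SNP-level quality control
#'
#' A SNP is kept iff call rate >= 1 - maxMissing, MAF > minMAF and
#' exact HWE p > minHweP. Every failure reason is recorded; an empty
#' result set produces a warning, not an error.
#'
#' Heterozygosity is a per-sample criterion on these arrays (mean
#' heterozygous fraction across the chip below \code{maxHet}): a SNP
#' with MAF 0.3 has an expected heterozygote fraction of 0.42 under
#' Hardy-Weinberg, so thresholding SNPs at 0.30 would discard most
#' common variants. The report therefore carries a per-sample
#' heterozygosity table with a flag at \code{maxHet}; samples are not
#' excluded unless \code{excludeHetSamples = TRUE}.
#'
#' @param genotypes a \linkS4class{CohortExperiment} or dosage matrix.
#' @param thresholds from \code{\link{qcThresholds}}.
#' @param excludeHetSamples drop samples flagged for heterozygosity
#'   (default \code{FALSE}).
#' @return list with \code{genotypes} (the filtered object, same class
#'   as the input) and \code{report} (\linkS4class{QCReport}).
#' @examples
#' ce <- simulateCohort(defaultCohortConfig(), seed = 3)
#' qc <- applyQC(ce)
#' qc$report
#' @export
applyQC <- function(genotypes, thresholds = qcThresholds(),
                    excludeHetSamples = FALSE) {
    g <- if (is(genotypes, "CohortExperiment")) dosage(genotypes)
         else as.matrix(genotypes)
    st <- computeSnpStats(g)
    fail <- cbind(
        missing = st$noCalls | st$callRate < 1 - thresholds$maxMissing,
        maf = !st$noCalls & st$maf <= thresholds$minMAF,
        hwe = !st$noCalls & st$hweP <= thresholds$minHweP)
    pass <- rowSums(fail) == 0
    st$pass <- pass
    reasons <- apply(fail, 1, function(r)
        paste(colnames(fail)[r], collapse = ";"))
    removed <- DataFrame(id = st$id[!pass], reasons = reasons[!pass])
    if (!any(pass))
        warning("no SNP passed quality control")
    hets <- colMeans(g == 1, na.rm = TRUE)
    sampleHet <- DataFrame(sample = colnames(g) %||%
                               as.character(seq_len(ncol(g))),
                           hetRate = as.numeric(hets),
                           flagged = as.numeric(hets) >= thresholds$maxHet)
    report <- new("QCReport", snpStats = st, thresholds = thresholds,
                  kept = st$id[pass], removed = removed,
                  sampleHet = sampleHet)
    keepSample <- if (excludeHetSamples) !sampleHet$flagged
                  else rep(TRUE, ncol(g))
    filtered <- if (is(genotypes, "CohortExperiment"))
        genotypes[pass, keepSample] else g[pass, keepSample, drop = FALSE]
    list(genotypes = filtered, report = report)
}

#' Estimate D' between two SNPs from unphased genotypes
#'
#' Haplotype frequencies are estimated by EM over the nine two-locus
#' genotype classes (only the double heterozygote has ambiguous phase;
#' its cis/trans split is re-estimated each iteration until the largest
#' frequency change falls below \code{tol}). D' = |D| / Dmax where
#' D = p11 - pA pB on the estimated haplotype frequencies.
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) of equal length; pairs with a
#'   missing call at either SNP are dropped.
#' @param tol EM convergence tolerance (default 1e-8).
#' @return D' in [0, 1].
#' @examples
#' g <- simulateGenotypes(snpSpec(c("a", "b"), c(0.3, 0.2),
#'     ldPartner = c(NA, "a"), ldDprime = c(NA, 0.8)), 5000, seed = 1)
#' estimateDprime(g[1, ], g[2, ])
#' @export
estimateDprime <- function(g1, g2, tol = 1e-8) {
    ok <- !is.na(g1) & !is.na(g2)
    g1 <- g1[ok]; g2 <- g2[ok]
    if (length(g1) < 2)
        stop("too few complete genotype pairs")
    if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
        stop("LD undefined: a SNP is monomorphic among complete pairs")
    n <- length(g1)
    cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
    pA <- mean(g1) / 2; pB <- mean(g2) / 2
    ## haplotype freqs h = c(h11, h10, h01, h00); allele 1 = coded allele
    h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
    ## haplotype copies are phase-determined for every genotype class
    ## except the double heterozygote (1,1): a sample with dosages (i, j)
    ## carries min(i, j) copies of hap 11, i - min(i,j) of 10, etc.
    eFixed <- c(0, 0, 0, 0)
    for (i in 0:2) for (j in 0:2) {
        m <- cnt[i + 1, j + 1]
        if (m == 0 || (i == 1 && j == 1)) next
        c11 <- min(i, j); c10 <- i - c11; c01 <- j - c11
        c00 <- 2 - c11 - c10 - c01
        eFixed <- eFixed + m * c(c11, c10, c01, c00)
    }
    mdh <- cnt[2, 2]
    for (iter in 1:1000) {
        e <- eFixed
        if (mdh > 0) {
            pcis <- h[1] * h[4]   # 11/00 resolution of the double het
            ptr <- h[2] * h[3]    # 10/01 resolution
            w <- if (pcis + ptr > 0) pcis / (pcis + ptr) else 0.5
            e <- e + mdh * c(w, 1 - w, 1 - w, w)
        }
        hNew <- e / (2 * n)
        if (max(abs(hNew - h)) < tol) { h <- hNew; break }
        h <- hNew
    }
    pA <- h[1] + h[2]; pB <- h[1] + h[3]
    D <- h[1] - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    if (dmax <= 0)
        stop("LD undefined: a SNP is monomorphic")
    min(1, abs(D) / dmax)
}

#' Pairwise D' matrix
#'
#' @param genotypes dosage matrix or \linkS4class{CohortExperiment}.
#' @param ids optional subset of SNP ids.
#' @return symmetric matrix of D' values (diagonal 1).
#' @export
dprimeMatrix <- function(genotypes, ids = NULL) {
    g <- if (is(genotypes, "CohortExperiment")) dosage(genotypes)
         else as.matrix(genotypes)
    if (!is.null(ids)) g <- g[ids, , drop = FALSE]
    k <- nrow(g)
    m <- diag(1, k)
    dimnames(m) <- list(rownames(g), rownames(g))
    if (k < 2) return(m)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
        m[i, j] <- m[j, i] <- estimateDprime(g[i, ], g[j, ])
    m
}

#' Greedy D'-based LD pruning
#'
#' Among any SNP pair with D' at or above the threshold, the SNP with
#' the larger association p-value is removed (ties broken by genomic
#' order: the earlier SNP is kept). The returned set has all pairwise
#' D' below the threshold.
#'
#' @param dprime symmetric D' matrix with SNP ids as dimnames, in
#'   genomic order.
#' @param gwasP named numeric of association p-values covering every
#'   SNP in \code{dprime}.
#' @param threshold D' at/above which a pair counts as strongly linked
#'   (default 0.4).
#' @return character vector of kept SNP ids (genomic order preserved).
#' @examples
#' m <- matrix(c(1, .9, .9, 1), 2, dimnames = list(c("a","b"), c("a","b")))
#' ldPrune(m, c(a = 1e-6, b = 1e-3))
#' @export
ldPrune <- function(dprime, gwasP, threshold = 0.4) {
    ids <- rownames(dprime)
    if (is.null(ids)) stop("dprime must carry SNP ids as dimnames")
    if (!all(ids %in% names(gwasP)))
        stop("missing gwasP for: ",
             paste(setdiff(ids, names(gwasP)), collapse = ", "))
    keep <- ids
    repeat {
        m <- dprime[keep, keep, drop = FALSE]
        diag(m) <- 0
        if (all(m < threshold, na.rm = TRUE)) break
        idx <- which(m == max(m), arr.ind = TRUE)[1, ]
        a <- keep[idx[1]]; b <- keep[idx[2]]
        drop <- if (gwasP[a] > gwasP[b]) a
                else if (gwasP[b] > gwasP[a]) b
                else keep[max(match(c(a, b), ids))]  # tie: later pos out
        keep <- setdiff(keep, drop)
    }
    keep
}
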