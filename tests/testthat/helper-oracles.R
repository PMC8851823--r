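# Independent oracles and small fixture builders shared across tests.

# random dosage matrix with missingness, SNPs x samples
randomDosage <- function(nSnps, nSamples, missingRate = 0.02) {
    d <- matrix(sample(0:2, nSnps * nSamples, replace = TRUE), nrow = nSnps,
                dimnames = list(sprintf("s%04d", seq_len(nSnps)),
                                paste0("ind", seq_len(nSamples))))
    if (missingRate > 0)
        d[runif(length(d)) < missingRate] <- NA_integer_
    storage.mode(d) <- "integer"
    d
}

# brute-force per-pair opposing-homozygote count and comparable-SNP count
bruteRejections <- function(d) {
    ids <- colnames(d)
    out <- NULL
    for (i in seq_len(ncol(d) - 1L)) {
        for (j in (i + 1L):ncol(d)) {
            x <- d[, i]; y <- d[, j]
            ok <- !is.na(x) & !is.na(y)
            delta <- sum((x == 0 & y == 2) | (x == 2 & y == 0), na.rm = TRUE)
            out <- rbind(out, data.frame(sample_i = ids[i], sample_j = ids[j],
                                         delta = delta, n_eff = sum(ok)))
        }
    }
    out
}

# binomial log-pmf by plain arithmetic, independent of dbinom's saddle-point
logBinomOracle <- function(delta, n, tau) {
    lchoose(n, delta) + delta * log(tau) + (n - delta) * log1p(-tau)
}

# genotype -> observed-genotype transition matrix at per-genotype error e
errorTransition <- function(e, model) {
    if (model == "genotype_uniform") {
        t0 <- matrix(e / 2, 3, 3)
        diag(t0) <- 1 - e
        return(t0)
    }
    # allele_flip: g' = g - Bin(g, e/2) + Bin(2 - g, e/2)
    t0 <- matrix(0, 3, 3)
    for (g in 0:2) {
        for (x in 0:g) {
            for (y in 0:(2 - g)) {
                t0[g + 1, g - x + y + 1] <- t0[g + 1, g - x + y + 1] +
                    dbinom(x, g, e / 2) * dbinom(y, 2 - g, e / 2)
            }
        }
    }
    t0
}

# exhaustive enumeration: probability that a true parent-offspring pair at a
# HWE locus with frequency p appears opposing-homozygous at error rate e
enumOpposingProb <- function(p, e, model) {
    q <- 1 - p
    pParent <- c(q^2, 2 * p * q, p^2)              # dosage 0, 1, 2
    # offspring | parent: transmitted allele from parent, other from pool
    pOff <- rbind(c(q, p, 0),
                  c(q / 2, 1 / 2, p / 2),
                  c(0, q, p))
    tr <- errorTransition(e, model)
    prob <- 0
    for (gp in 0:2) {
        for (go in 0:2) {
            joint <- pParent[gp + 1] * pOff[gp + 1, go + 1]
            obs <- outer(tr[gp + 1, ], tr[go + 1, ])
            prob <- prob + joint * (obs[1, 3] + obs[3, 1])
        }
    }
    prob
}

# simulate one true parent-offspring genotype pair per locus at frequency p
simTrioLocus <- function(n, p) {
    gp <- rbinom(n, 2, p)
    fromParent <- as.integer(runif(n) < gp / 2)
    go <- fromParent + as.integer(runif(n) < p)
    list(parent = gp, offspring = go)
}

applyGenotypeUniformError <- function(g, e) {
    hit <- which(runif(length(g)) < e)
    g[hit] <- (g[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
    g
}
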