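#' Number of SNPs required to separate the two rejection rates
#'
#' How many SNPs are needed so that a pair's rejection rate distinguishes
#' the error component (`p0`, true first-degree pairs) from the rejection
#' component (`p1`) at power `power`, when every pair among `nIndividuals`
#' is tested and the global significance level is Bonferroni-adjusted by
#' the number of pairs?  Uses the normal approximation to the binomial for
#' a one-sample test of proportions:
#'
#' \deqn{n = \lceil (z_{1-\alpha'/2}\sqrt{p_0(1-p_0)} +
#'   z_{power}\sqrt{p_1(1-p_1)})^2 / (p_1-p_0)^2 \rceil}
#'
#' with \eqn{\alpha' = \alpha / {nIndividuals \choose 2}}.  The default is
#' two-sided in the adjusted level (`sided = "two"`); a one-sided variant is
#' available.  No continuity correction is applied.
#'
#' @param p0 null rate (the error-component rate), `0 < p0 < p1`.
#' @param p1 alternative rate (the rejection-component rate), `< 1`.
#' @param alphaGlobal global significance level in `(0, 1)`.
#' @param power target power in `(0.5, 1)`.
#' @param nIndividuals number of individuals screened (>= 2).
#' @param sided `"two"` or `"one"`.
#' @return a [PowerDesign-class].
#' @examples
#' requiredSnps(0.000735, 0.01, 0.01, 0.99, 300)  # 1611 SNPs
#' @export
requiredSnps <- function(p0, p1, alphaGlobal = 0.01, power = 0.99,
                         nIndividuals, sided = c("two", "one")) {
    sided <- match.arg(sided)
    if (!(p0 > 0 && p0 < p1 && p1 < 1))
        stop("need 0 < p0 < p1 < 1")
    stopifnot(alphaGlobal > 0, alphaGlobal < 1, power > 0.5, power < 1)
    nTests <- pairCount(nIndividuals)
    alphaAdj <- alphaGlobal / nTests
    z1 <- stats::qnorm(1 - if (sided == "two") alphaAdj / 2 else alphaAdj)
    z2 <- stats::qnorm(power)
    n <- ceiling((z1 * sqrt(p0 * (1 - p0)) + z2 * sqrt(p1 * (1 - p1)))^2 /
                 (p1 - p0)^2)
    new("PowerDesign", p0 = p0, p1 = p1, alphaGlobal = alphaGlobal,
        power = power, nIndividuals = nIndividuals, nTests = nTests,
        alphaAdjusted = alphaAdj, sided = sided, requiredSnps = n)
}

#' Power achieved at a fixed number of SNPs
#'
#' Normal-approximation power of the proportion test of `p0` against
#' `p1 > p0` at significance level `alphaAdjusted` with `nSnps` SNPs; the
#' inverse view of [requiredSnps()], so
#' `achievedPower(requiredSnps(...)@requiredSnps, ...) >= power`.
#'
#' @param nSnps number of SNPs compared.
#' @param p0,p1 null and alternative rates.
#' @param alphaAdjusted the (already multiple-testing-adjusted)
#'   significance level.
#' @param sided `"two"` or `"one"`.
#' @return the power, a probability.
#' @export
achievedPower <- function(nSnps, p0, p1, alphaAdjusted,
                          sided = c("two", "one")) {
    sided <- match.arg(sided)
    if (!(p0 > 0 && p0 < p1 && p1 < 1))
        stop("need 0 < p0 < p1 < 1")
    z1 <- stats::qnorm(1 - if (sided == "two") alphaAdjusted / 2
                           else alphaAdjusted)
    stats::pnorm((abs(p1 - p0) * sqrt(nSnps) - z1 * sqrt(p0 * (1 - p0))) /
                 sqrt(p1 * (1 - p1)))
}

setMethod("show", "PowerDesign", function(object) {
    cat("PowerDesign\n")
    cat(sprintf("  p0 = %.6g  p1 = %.6g  (%s-sided)\n", object@p0,
                object@p1, object@sided))
    cat(sprintf("  %d individuals -> %s pairwise tests; alpha %.3g -> %.3g\n",
                as.integer(object@nIndividuals),
                format(object@nTests, big.mark = ","), object@alphaGlobal,
                object@alphaAdjusted))
    cat(sprintf("  power %.2f  =>  required SNPs: %s\n", object@power,
                format(object@requiredSnps, big.mark = ",")))
    invisible(NULL)
})
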