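#' Exact upper tail of the binomial distribution
#'
#' Computes `P(X >= successes)` for `X ~ Binomial(trials, prob)` by exact
#' summation of the probability mass function (no normal approximation).
#' This is the significance measure used to classify candidate genes by their
#' connectivity to a seed list: a gene with `d` interactions of which `s` hit
#' seeds is scored by the chance of `s` or more seed hits under a background
#' seed probability.
#'
#' @param successes Non-negative integer count of observed successes.
#' @param trials Non-negative integer number of trials; `successes <= trials`.
#' @param prob Success probability in `[0, 1]`.
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' pBinomTail(3, 10, 0.1)
#' @export
pBinomTail <- function(successes, trials, prob) {
  .checkCount(successes, "successes")
  .checkCount(trials, "trials")
  if (successes > trials)
    stop("'successes' (", successes, ") exceeds 'trials' (", trials, ")")
  if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
      prob < 0 || prob > 1)
    stop("'prob' must be a single probability in [0, 1]")
  if (successes == 0L) return(1)
  stats::pbinom(successes - 1, size = trials, prob = prob, lower.tail = FALSE)
}

#' Exact upper tail of the hypergeometric distribution
#'
#' Computes `P(X >= overlap)` for the overlap of a drawn set with a marked
#' subpopulation: `draws` genes sampled without replacement from a universe of
#' `popSize` genes of which `successesInPop` are marked. Used for gene-set
#' overlap enrichment and motif enrichment.
#'
#' @param overlap Observed overlap count.
#' @param draws Size of the drawn set.
#' @param successesInPop Number of marked genes in the universe.
#' @param popSize Universe size.
#' @return Upper-tail probability.
#' @examples
#' pHyperTail(4, 4, 5, 10)
#' @export
pHyperTail <- function(overlap, draws, successesInPop, popSize) {
  .checkCount(overlap, "overlap")
  .checkCount(draws, "draws")
  .checkCount(successesInPop, "successesInPop")
  .checkCount(popSize, "popSize")
  if (draws > popSize || successesInPop > popSize)
    stop("'draws' and 'successesInPop' must not exceed 'popSize'")
  if (overlap > min(draws, successesInPop))
    stop("'overlap' (", overlap, ") exceeds min(draws, successesInPop)")
  if (overlap == 0L) return(1)
  stats::phyper(overlap - 1, m = successesInPop, n = popSize - successesInPop,
                k = draws, lower.tail = FALSE)
}

#' Exact upper tail of the Poisson distribution
#'
#' Computes `P(X >= observed)` for `X ~ Poisson(lambda)` by series summation.
#' Used to score ortholog-presence enrichment of a gene set against the
#' genome-wide presence rate.
#'
#' @param observed Non-negative integer count.
#' @param lambda Non-negative mean.
#' @return Upper-tail probability.
#' @examples
#' pPoisTail(3, 1.0)
#' @export
pPoisTail <- function(observed, lambda) {
  .checkCount(observed, "observed")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0)
    stop("'lambda' must be a single non-negative number")
  if (observed == 0L) return(1)
  stats::ppois(observed - 1, lambda = lambda, lower.tail = FALSE)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midrank tie handling. For small
#' samples the p-value is exact: without ties (combined n <= 20) it comes
#' from the closed-form null distribution of U, and with ties (combined
#' n <= 14) from full enumeration of all assignments of the pooled midranks
#' to the two groups. Larger samples use a normal approximation with tie
#' correction and continuity correction.
#' Directional pipeline claims (a seed set has "higher
#' average degree", a gene set has "higher expression") pass
#' `alternative = "greater"` explicitly; the default is two-sided.
#'
#' @param a,b Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger),
#'   or `"less"`.
#' @param exactLimit Combined sample size at or below which the exact
#'   distribution is used when there are no ties.
#' @param exactTieLimit Combined sample size at or below which tied samples
#'   are handled by full enumeration instead of the approximation.
#' @return An object of class `"htest"` with the U `statistic` (for sample
#'   `a`) and `p.value`.
#' @examples
#' mannWhitneyTest(c(3, 4), c(1, 2), alternative = "greater")
#' @export
mannWhitneyTest <- function(a, b,
                            alternative = c("two.sided", "greater", "less"),
                            exactLimit = 20L, exactTieLimit = 14L) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  nA <- length(a); nB <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- table(pooled)
  hasTies <- any(ties > 1L)

  if (!hasTies && (nA + nB) <= exactLimit) {
    # exact null distribution of U (no ties): P(U >= u) and P(U <= u)
    pGreater <- .pwilcoxGeq(U, nA, nB)
    pLess <- stats::pwilcox(U, m = nA, n = nB)
    p <- switch(alternative,
                greater = pGreater,
                less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
  } else if (hasTies && (nA + nB) <= exactTieLimit) {
    # exact by enumeration over all assignments of the pooled midranks
    offset <- nA * (nA + 1) / 2
    us <- utils::combn(nA + nB, nA,
                       FUN = function(idx) sum(r[idx]) - offset)
    pGreater <- mean(us >= U - 1e-9)
    pLess <- mean(us <= U + 1e-9)
    p <- switch(alternative,
                greater = pGreater,
                less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
  } else {
    mu <- nA * nB / 2
    n <- nA + nB
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- nA * nB / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    z <- U - mu
    corr <- switch(alternative,
                   two.sided = sign(z) * 0.5,
                   greater = 0.5,
                   less = -0.5)
    z <- if (sigma2 > 0) (z - corr) / sqrt(sigma2) else 0
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = min(1, 2 * stats::pnorm(abs(z),
                                                   lower.tail = FALSE)))
  }
  structure(list(statistic = c(U = U), p.value = p,
                 alternative = alternative,
                 method = "Mann-Whitney U test",
                 data.name = "a and b"),
            class = "htest")
}

# P(U >= u) under the exact no-ties null
.pwilcoxGeq <- function(u, m, n) {
  if (u <= 0) return(1)
  stats::pwilcox(u - 1, m = m, n = n, lower.tail = FALSE) +
    0  # pwilcox is defined on integers; U is integral when there are no ties
}

#' Benjamini-Hochberg q-values
#'
#' FDR-adjusted p-values in input order (step-up procedure), clipped to 1.
#'
#' @param p Non-empty numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @examples
#' bhQvalues(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhQvalues <- function(p) {
  if (length(p) == 0L) stop("'p' must be non-empty")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Combine p-values analytically (product method)
#'
#' Combines independent p-values via the closed form
#' `k * sum_{i=0}^{n-1} (-ln k)^i / i!` where `k` is the product of the
#' p-values: the probability of observing a p-value set as extreme or more
#' extreme (smaller product) than the given one. This equals the chi-square
#' survival value of Fisher's statistic `-2 ln k` with `2n` degrees of
#' freedom.
#'
#' @param p Numeric vector of p-values, each in `(0, 1]`.
#' @param zeroOk If `TRUE`, a zero p-value yields a combined value of 0
#'   instead of an error. Default `FALSE`: zeros usually signal upstream
#'   underflow and are rejected.
#' @return Combined probability.
#' @examples
#' combinePAnalytic(c(0.1, 0.1))
#' @export
combinePAnalytic <- function(p, zeroOk = FALSE) {
  .checkPVector(p, openUpper = FALSE)
  if (any(p == 0)) {
    if (zeroOk) return(0)
    stop("p-values of exactly 0 are not combinable (set zeroOk = TRUE to ",
         "return 0)")
  }
  n <- length(p)
  logk <- sum(log(p))
  # k * sum (-log k)^i / i!, accumulated in log space for stability
  terms <- logk + cumsum(c(0, log(-logk) - log(seq_len(n - 1))))
  min(1, sum(exp(terms)))
}

#' Combine p-values by the z-method (Stouffer)
#'
#' Unweighted Stouffer combination: `z = sum(qnorm(1 - p_i)) / sqrt(n)`,
#' returning the upper normal tail `1 - pnorm(z)`.
#'
#' @param p Numeric vector of p-values, each strictly inside `(0, 1)`.
#' @return Combined probability.
#' @examples
#' combinePZ(c(0.1, 0.1))
#' @export
combinePZ <- function(p) {
  .checkPVector(p, openUpper = TRUE)
  z <- sum(stats::qnorm(p, lower.tail = FALSE)) / sqrt(length(p))
  stats::pnorm(z, lower.tail = FALSE)
}

.checkPVector <- function(p, openUpper) {
  if (length(p) == 0L) stop("'p' must be non-empty")
  if (anyNA(p)) stop("p-values must not contain NA")
  if (any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  if (openUpper && any(p == 0 | p == 1))
    stop("the z-method requires p-values strictly inside (0, 1)")
  invisible(TRUE)
}

.checkCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x))
    stop("'", name, "' must be a single non-negative integer")
  invisible(TRUE)
}
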