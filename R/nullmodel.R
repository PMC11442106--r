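#' Gamete allele-dose distribution under polysomic inheritance
#'
#' With random bivalent pairing an autopolyploid gamete receives
#' \code{ploidy/2} of the parent's \code{ploidy} homologs, drawn without
#' replacement, so the gamete dose of an allele carried on \code{parentDose}
#' homologs is hypergeometric. For ploidy 6 and a simplex parent this is the
#' classical 1:1 carrier ratio. No double reduction is modelled.
#'
#' @param ploidy even integer >= 2.
#' @param parentDose allele copy number in the parent, 0..ploidy.
#' @return Named numeric vector: P(gamete dose = 0..min(parentDose, ploidy/2)).
#' @examples
#' gameteDosePmf(6, 1)  # 0: 1/2, 1: 1/2
#' gameteDosePmf(6, 2)  # 0: 0.2, 1: 0.6, 2: 0.2
#' @export
gameteDosePmf <- function(ploidy, parentDose) {
  if (ploidy %% 2 != 0) stop("ploidy must be even")
  stopifnot(parentDose >= 0, parentDose <= ploidy)
  k <- 0:min(parentDose, ploidy / 2)
  p <- stats::dhyper(k, m = parentDose, n = ploidy - parentDose, k = ploidy / 2)
  stats::setNames(p, k)
}

#' Progeny allele-dose distribution for a donor x nulliplex cross
#'
#' The nulliplex parent contributes dose 0, so the progeny dose equals the
#' donor gamete dose. The expected progeny allele frequency is
#' \code{plexity / (2 * ploidy)} (1/12, about 0.083, for a hexaploid simplex
#' cross).
#'
#' @param ploidy even integer.
#' @param plexity donor allele copy number (0..ploidy).
#' @return Named numeric vector over progeny dose.
#' @export
progenyDosePmf <- function(ploidy, plexity) {
  gameteDosePmf(ploidy, plexity)
}

## pmf of the sum of n i.i.d. doses, by n-fold convolution
.bulkDoseSumPmf <- function(n, ploidy, plexity) {
  pmf <- as.numeric(progenyDosePmf(ploidy, plexity))
  out <- 1
  for (i in seq_len(n)) {
    res <- numeric(length(out) + length(pmf) - 1L)
    for (k in seq_along(pmf))
      res[k:(k + length(out) - 1L)] <- res[k:(k + length(out) - 1L)] + pmf[k] * out
    out <- res
  }
  out  # over sum 0 .. n * maxdose
}

#' Simulate the no-QTL null distribution of the delta SNP-index
#'
#' Under the null each bulk member's allele dose is an independent draw from
#' the progeny dose distribution; the bulk allele frequency is the dose sum
#' over \code{ploidy * n} homologs, and the observed per-bulk SNP-index is a
#' binomial read draw at the bulk's depth. The delta SNP-index is high-bulk
#' index minus low-bulk index. Thresholds are empirical percentiles (2.5/97.5
#' for 95\%, 0.5/99.5 for 99\%, \code{stats::quantile} type 7).
#'
#' @param nLow,nHigh bulk sizes (individuals).
#' @param depthLow,depthHigh read depths for the two bulks.
#' @param ploidy,plexity segregation model.
#' @param replicates Monte-Carlo sample size (default 10000; below 1000 a
#'   warning is issued, thresholds are unstable).
#' @param seed integer seed; if non-NULL the RNG is seeded locally so results
#'   are reproducible.
#' @return A \code{\linkS4class{NullDistribution}}.
#' @export
simulateNull <- function(nLow, nHigh, depthLow, depthHigh,
                         ploidy = 6, plexity = 1,
                         replicates = 10000, seed = NULL) {
  stopifnot(nLow >= 1, nHigh >= 1, depthLow >= 1, depthHigh >= 1,
            replicates >= 1)
  if (replicates < 1000)
    warning("replicates < 1000: confidence thresholds will be unstable")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("seed must be a single integer")
    set.seed(as.integer(seed))
  }
  pmfLow <- .bulkDoseSumPmf(nLow, ploidy, plexity)
  pmfHigh <- .bulkDoseSumPmf(nHigh, ploidy, plexity)
  sLow <- sample.int(length(pmfLow), replicates, replace = TRUE,
                     prob = pmfLow) - 1L
  sHigh <- sample.int(length(pmfHigh), replicates, replace = TRUE,
                      prob = pmfHigh) - 1L
  iLow <- stats::rbinom(replicates, depthLow, sLow / (ploidy * nLow)) / depthLow
  iHigh <- stats::rbinom(replicates, depthHigh, sHigh / (ploidy * nHigh)) / depthHigh
  delta <- iHigh - iLow
  q <- stats::quantile(delta, c(0.025, 0.975, 0.005, 0.995), names = FALSE)
  th <- matrix(q, 2, 2, dimnames = list(c("lower", "upper"), c("95", "99")))
  new("NullDistribution",
      nLow = as.integer(nLow), nHigh = as.integer(nHigh),
      depthLow = as.integer(depthLow), depthHigh = as.integer(depthHigh),
      ploidy = as.integer(ploidy), plexity = as.integer(plexity),
      replicates = as.integer(replicates),
      deltaSamples = delta, absDeltaSorted = sort(abs(delta)),
      thresholds = th)
}

#' Exact distribution of an observed bulk SNP-index
#'
#' Brute-force oracle: enumerates every composition of \code{n} member doses
#' (each 0..plexity), weights it by the product of progeny dose
#' probabilities, and mixes the binomial read distribution at the implied bulk
#' allele frequency. Intended for small problems; a guard refuses more than
#' 1e7 enumerated combinations.
#'
#' @param n bulk size.
#' @param depth read depth.
#' @param ploidy,plexity segregation model.
#' @return \code{data.frame} with columns \code{index} (k/depth) and
#'   \code{prob}.
#' @export
exactBulkIndexPmf <- function(n, depth, ploidy = 6, plexity = 1) {
  nComb <- (plexity + 1)^n * (depth + 1)
  if (nComb > 1e7)
    stop("enumeration too large (", nComb, " combinations); use simulateNull()")
  pmf <- as.numeric(progenyDosePmf(ploidy, plexity))
  doses <- 0:plexity
  grid <- do.call(expand.grid, rep(list(doses), n))
  w <- apply(grid, 1L, function(d) prod(pmf[d + 1L]))
  s <- rowSums(grid)
  k <- 0:depth
  prob <- numeric(depth + 1L)
  for (i in seq_along(w)) {
    f <- s[i] / (ploidy * n)
    prob <- prob + w[i] * stats::dbinom(k, depth, f)
  }
  data.frame(index = k / depth, prob = prob)
}

#' Empirical two-sided P value and significance flags
#'
#' \code{p = (1 + #[ |delta_null| >= |delta| ]) / (replicates + 1)}, so p is
#' never zero. \code{sig95}/\code{sig99} flag observations strictly outside
#' the corresponding empirical threshold interval; \code{sig99} implies
#' \code{sig95} by threshold nesting.
#'
#' @param delta observed delta SNP-index value(s); vectorised.
#' @param nulldist a \code{\linkS4class{NullDistribution}} computed at the
#'   observation's depth pair.
#' @return \code{data.frame} with columns \code{p}, \code{sig95},
#'   \code{sig99}.
#' @export
empiricalPValue <- function(delta, nulldist) {
  stopifnot(is(nulldist, "NullDistribution"))
  sa <- nulldist@absDeltaSorted
  R <- nulldist@replicates
  nGE <- R - findInterval(abs(delta), sa, left.open = TRUE)
  th <- nulldist@thresholds
  data.frame(
    p = (1 + nGE) / (R + 1),
    sig95 = delta < th["lower", "95"] | delta > th["upper", "95"],
    sig99 = delta < th["lower", "99"] | delta > th["upper", "99"])
}

## Deterministic per-depth-pair seed stream derived from a global seed.
.keySeed <- function(seed, depthLow, depthHigh) {
  (as.double(seed) + 7919 * depthLow + 104729 * depthHigh) %% 2147483647
}

## Environment-backed cache of NullDistribution objects keyed by depth pair.
.nullCache <- function() new.env(parent = emptyenv())

.cachedNull <- function(cache, depthLow, depthHigh, nLow, nHigh,
                        ploidy, plexity, replicates, seed) {
  key <- paste0(depthLow, ":", depthHigh)
  nd <- cache[[key]]
  if (is.null(nd)) {
    nd <- simulateNull(nLow, nHigh, depthLow, depthHigh, ploidy, plexity,
                       replicates, seed = .keySeed(seed, depthLow, depthHigh))
    cache[[key]] <- nd
  }
  nd
}
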