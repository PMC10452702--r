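## Poisson statistics of cell encapsulation. When droplets are generated
## uniformly from a dilute cell suspension, the number of cells landing in
## one droplet is Poisson with mean lambda (cells per droplet, CPD):
##   rho_k = lambda^k e^{-lambda} / k!
## Dilution trades capture for specificity: the single-cell fraction rho_1
## peaks at 1/e (36.8%) at lambda = 1, where 26.4% of droplets already hold
## two or more cells.

#' Poisson probability of k cells in one droplet
#'
#' @param lambda mean cells per droplet (CPD), >= 0.
#' @param k nonnegative integer cell count (vectorized).
#' @return \eqn{\rho_k = \lambda^k e^{-\lambda}/k!}.
#' @examples
#' encapsulationPMF(1, 1)      # 1/e, the single-cell ceiling
#' 1 - sum(encapsulationPMF(1, 0:1))  # P(k >= 2) at lambda = 1
#' @export
encapsulationPMF <- function(lambda, k) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (any(k < 0) || any(k != floor(k))) stop("k must be a nonnegative integer")
  dpois(k, lambda)
}

#' Encapsulation rates under Poisson loading
#'
#' Empty, single-cell and multicell (>= 2) droplet fractions at a given
#' cells-per-droplet mean, plus the conditional single-cell rate
#' \eqn{\rho_1/(1-\rho_0)} (the fraction of occupied droplets that hold
#' exactly one cell). The conditional rate is undefined at \code{lambda = 0}
#' and returned as \code{NA} there.
#'
#' @param lambda mean cells per droplet (vectorized).
#' @return data.frame with columns \code{lambda}, \code{empty},
#'   \code{single}, \code{multiple}, \code{singleCellRate}.
#' @examples
#' encapsulationRates(0.26)   # the >20% single / <3% multicell regime
#' @export
encapsulationRates <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  empty <- dpois(0, lambda)
  single <- dpois(1, lambda)
  multiple <- 1 - empty - single
  scr <- ifelse(lambda > 0, single / (1 - empty), NA_real_)
  data.frame(lambda = lambda, empty = empty, single = single,
             multiple = pmax(multiple, 0), singleCellRate = scr)
}

#' Estimate cells per droplet from detection counts
#'
#' Inverts the Poisson zero term: with \eqn{N^d} detected droplets of which
#' \eqn{M^d} are positive (hold at least one cell),
#' \eqn{\hat\lambda = -\ln(1 - M^d/N^d)}.
#'
#' @param nDroplets detected droplet count \eqn{N^d} (> 0).
#' @param nPositive positive droplet count \eqn{M^d} (0 <= M <= N).
#' @return The CPD estimate; \code{Inf} with a warning when every droplet is
#'   positive.
#' @export
estimateCPD <- function(nDroplets, nPositive) {
  if (nDroplets <= 0) stop("nDroplets must be positive")
  if (nPositive < 0 || nPositive > nDroplets)
    stop("nPositive must lie in [0, nDroplets]")
  if (nPositive == nDroplets) {
    warning("all droplets positive: CPD estimate is infinite")
    return(Inf)
  }
  ## -log(1 - M/N), via log1p for accuracy at small positive fractions
  -log1p(-nPositive / nDroplets)
}

#' Cells per droplet from cell density and droplet size
#'
#' The expected cell load of a droplet is the cell concentration of the
#' dispersed phase times the droplet volume:
#' \eqn{\lambda = D_{cell} \cdot \frac{4}{3}\pi R^3}. Units are made
#' explicit so they verifiably cancel.
#'
#' @param cellDensity cell concentration of the dispersed phase.
#' @param dropletRadius droplet radius.
#' @param densityUnit \code{"cells_per_mL"} or \code{"cells_per_pL"}.
#' @param radiusUnit \code{"um"} or \code{"cm"}.
#' @return Dimensionless expected cells per droplet.
#' @examples
#' cpdFromDensity(1e6, 10, "cells_per_mL", "um")  # ~0.0042 for 20 um droplets
#' @export
cpdFromDensity <- function(cellDensity, dropletRadius,
                           densityUnit = c("cells_per_mL", "cells_per_pL"),
                           radiusUnit = c("um", "cm")) {
  densityUnit <- match.arg(densityUnit)
  radiusUnit <- match.arg(radiusUnit)
  if (any(cellDensity < 0) || any(dropletRadius < 0))
    stop("cellDensity and dropletRadius must be >= 0")
  rCm <- switch(radiusUnit, um = dropletRadius * 1e-4, cm = dropletRadius)
  volMl <- 4 / 3 * pi * rCm^3            # 1 mL = 1 cm^3
  densMl <- switch(densityUnit,
                   cells_per_mL = cellDensity,
                   cells_per_pL = cellDensity * 1e9)  # 1 mL = 1e9 pL
  densMl * volMl
}

#' Summarize per-droplet cell counts
#'
#' Aggregates a vector of per-droplet cell counts into an
#' [EncapsulationSummary-class]: detected and positive droplet numbers, the
#' count histogram, category rates, the conditional single-cell rate and
#' the CPD estimate from the positive fraction.
#'
#' @param counts integer vector of per-droplet cell counts.
#' @return An [EncapsulationSummary-class].
#' @examples
#' counts <- rpois(5000, 0.26)
#' summarizeEncapsulation(counts)
#' @export
summarizeEncapsulation <- function(counts) {
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative integers")
  n <- length(counts)
  m <- sum(counts >= 1L)
  kmax <- if (n) max(counts) else 0L
  hist <- as.integer(table(factor(counts, levels = 0:kmax)))
  names(hist) <- 0:kmax
  rates <- if (n) c(empty = mean(counts == 0L),
                    single = mean(counts == 1L),
                    multiple = mean(counts >= 2L))
  else c(empty = 0, single = 0, multiple = 0)
  scr <- if (m > 0) sum(counts == 1L) / m else NA_real_
  lam <- if (n == 0L) NA_real_
  else if (m == n) Inf
  else -log1p(-m / n)
  new("EncapsulationSummary",
      nDroplets = n, nPositive = m, countsByK = hist,
      rates = rates, singleCellRate = scr, lambdaHat = lam)
}
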