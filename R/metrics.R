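## Evaluation: analytic circle IoU, one-to-one detection matching,
## precision/recall/F1, cell localization against valid areas, counting
## mean relative error, and goodness of fit of observed encapsulation rates
## to the Poisson curves.

#' Intersection-over-union of two circles
#'
#' Analytic lens-area computation (no rasterization). Vectorized over both
#' circles; symmetric; returns values in [0, 1], 1 iff the circles are
#' identical, 0 when they are disjoint.
#'
#' @param cx1,cy1,r1 first circle center and radius.
#' @param cx2,cy2,r2 second circle center and radius.
#' @return IoU fraction(s).
#' @examples
#' circleIoU(0, 0, 10, 0, 0, 20)  # concentric, radii r and 2r -> 0.25
#' @export
circleIoU <- function(cx1, cy1, r1, cx2, cy2, r2) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("radii must be positive")
  d <- sqrt((cx1 - cx2)^2 + (cy1 - cy2)^2)
  a1 <- pi * r1^2
  a2 <- pi * r2^2
  inter <- ifelse(
    d >= r1 + r2, 0,
    ifelse(d <= abs(r1 - r2), pi * pmin(r1, r2)^2, {
      q1 <- pmin(pmax((d^2 + r1^2 - r2^2) / (2 * d * r1), -1), 1)
      q2 <- pmin(pmax((d^2 + r2^2 - r1^2) / (2 * d * r2), -1), 1)
      s <- pmax((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2), 0)
      r1^2 * acos(q1) + r2^2 * acos(q2) - 0.5 * sqrt(s)
    }))
  iou <- inter / (a1 + a2 - inter)
  pmin(pmax(iou, 0), 1)
}

#' Match predicted circles to ground-truth circles
#'
#' Greedy one-to-one matching in descending IoU order: the highest-IoU
#' (truth, prediction) pair is fixed first, both members removed, and so on;
#' pairs with IoU below the threshold \code{theta} are never matched. The
#' result is invariant to the ordering of the inputs up to IoU ties.
#'
#' @param truth data.frame of truth circles (\code{cx}, \code{cy}, \code{r}).
#' @param pred data.frame of predicted circles.
#' @param theta IoU threshold in (0, 1).
#' @return List with \code{pairs} (data.frame \code{truthIdx},
#'   \code{predIdx}, \code{iou}), \code{unmatchedTruth},
#'   \code{unmatchedPred}, and \code{theta}.
#' @export
matchCircles <- function(truth, pred, theta = 0.5) {
  stopifnot(theta > 0, theta < 1)
  nt <- nrow(truth); np <- nrow(pred)
  pairs <- data.frame(truthIdx = integer(0), predIdx = integer(0),
                      iou = numeric(0))
  if (nt > 0 && np > 0) {
    iou <- outer(seq_len(nt), seq_len(np), function(i, j)
      circleIoU(truth$cx[i], truth$cy[i], truth$r[i],
                pred$cx[j], pred$cy[j], pred$r[j]))
    repeat {
      best <- which.max(iou)
      if (length(best) == 0L || iou[best] < theta) break
      i <- ((best - 1) %% nt) + 1
      j <- ((best - 1) %/% nt) + 1
      pairs <- rbind(pairs, data.frame(truthIdx = i, predIdx = j,
                                       iou = iou[best]))
      iou[i, ] <- -1
      iou[, j] <- -1
    }
  }
  list(pairs = pairs,
       unmatchedTruth = setdiff(seq_len(nt), pairs$truthIdx),
       unmatchedPred = setdiff(seq_len(np), pairs$predIdx),
       theta = theta)
}

#' Precision, recall and F1 from match counts
#'
#' @param tp,fp,fn nonnegative counts of true positives, false positives
#'   and false negatives.
#' @return Named numeric vector \code{precision}, \code{recall}, \code{f1}
#'   (each 0 when its denominator vanishes).
#' @export
prf1 <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Score predicted cell locations against annotated centroids
#'
#' Each annotated centroid owns a circular valid area of radius
#' \code{radius} px. Predictions are matched to centroids greedily by
#' nearest distance, one-to-one; a matched prediction is a true positive
#' iff it falls inside the valid area of its centroid.
#'
#' @param truth two-column matrix of annotated cell centroids (x, y).
#' @param pred two-column matrix of predicted locations.
#' @param radius valid-area radius in px.
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall} and \code{radius}. Precision is \code{NA} when there are
#'   no predictions, recall \code{NA} when there are no centroids.
#' @export
localizationScore <- function(truth, pred, radius) {
  stopifnot(radius > 0)
  truth <- matrix(as.numeric(truth), ncol = 2)
  pred <- matrix(as.numeric(pred), ncol = 2)
  nt <- nrow(truth); np <- nrow(pred)
  tp <- 0L
  if (nt > 0 && np > 0) {
    d <- outer(seq_len(nt), seq_len(np), function(i, j)
      sqrt((truth[i, 1] - pred[j, 1])^2 + (truth[i, 2] - pred[j, 2])^2))
    repeat {
      best <- which.min(d)
      if (length(best) == 0L || d[best] > radius) break
      tp <- tp + 1L
      i <- ((best - 1) %% nt) + 1
      j <- ((best - 1) %/% nt) + 1
      d[i, ] <- Inf
      d[, j] <- Inf
    }
  }
  list(tp = tp, fp = np - tp, fn = nt - tp,
       precision = if (np > 0) tp / np else NA_real_,
       recall = if (nt > 0) tp / nt else NA_real_,
       radius = radius)
}

#' Mean relative error of per-droplet cell counts
#'
#' \eqn{\mathrm{MRE} = \mathrm{mean}(|pred - true| / true)} over droplets
#' with a positive true count; zero-count droplets cannot enter a relative
#' error and are excluded (their number is reported as an attribute).
#'
#' @param trueCounts,predCounts paired integer vectors.
#' @return The MRE, with attribute \code{nExcluded}.
#' @export
countingMRE <- function(trueCounts, predCounts) {
  stopifnot(length(trueCounts) == length(predCounts))
  ok <- trueCounts >= 1
  if (!any(ok)) stop("no droplets with positive true count")
  mre <- mean(abs(predCounts[ok] - trueCounts[ok]) / trueCounts[ok])
  attr(mre, "nExcluded") <- sum(!ok)
  mre
}

#' Goodness of fit of observed encapsulation rates to the Poisson curves
#'
#' Residual sum of squares of observed (lambda, rate) points against the
#' theoretical Poisson curve for the chosen rate. When a vector of raw
#' per-droplet counts is supplied, a chi-squared statistic of the count
#' histogram against \code{Poisson(lambda)} is computed as well (expected
#' bins below 5 are pooled into the tail).
#'
#' @param lambda vector of CPD values at which rates were observed.
#' @param observed observed rates, same length as \code{lambda}.
#' @param curve which rate the observations are of.
#' @param counts optional integer vector of per-droplet counts observed at
#'   a single \code{lambda} (used for the chi-squared test).
#' @param countsLambda the lambda the \code{counts} are tested against
#'   (defaults to \code{lambda[1]}).
#' @return List with \code{rss} and, when counts are given, \code{chisq}
#'   (statistic, df, p.value).
#' @export
poissonFitRSS <- function(lambda, observed,
                          curve = c("single", "multiple", "empty",
                                    "singleCellRate"),
                          counts = NULL, countsLambda = lambda[1]) {
  curve <- match.arg(curve)
  stopifnot(length(lambda) == length(observed))
  theo <- encapsulationRates(lambda)[[curve]]
  rss <- sum((observed - theo)^2)
  out <- list(rss = rss, curve = curve)
  if (!is.null(counts)) {
    n <- length(counts)
    kmax <- max(counts, 1L)
    p <- dpois(0:kmax, countsLambda)
    p <- c(p, 1 - sum(p))  # tail bin k > kmax
    obs <- c(as.integer(table(factor(counts, levels = 0:kmax))), 0L)
    e <- n * p
    ## pool sparse high-count bins into the last adequate bin
    while (length(e) > 2 && e[length(e)] < 5) {
      k <- length(e)
      e[k - 1] <- e[k - 1] + e[k]
      obs[k - 1] <- obs[k - 1] + obs[k]
      e <- e[-k]; obs <- obs[-k]
    }
    stat <- sum((obs - e)^2 / e)
    df <- length(e) - 1
    out$chisq <- list(statistic = stat, df = df,
                      p.value = pchisq(stat, df, lower.tail = FALSE))
  }
  out
}

#' Category-aware F1 of droplet recognition
#'
#' Matches predicted circles to truth circles one-to-one at IoU threshold
#' \code{theta} (ignoring category), then scores the three droplet
#' categories: a matched pair with agreeing category is a true positive for
#' it; a matched pair with disagreeing categories counts as a false
#' positive for the predicted category and a false negative for the true
#' one; unmatched truth circles are false negatives of their category and
#' unmatched predictions false positives of theirs.
#'
#' @param truth data.frame with \code{cx}, \code{cy}, \code{r},
#'   \code{category}.
#' @param pred data.frame with the same columns.
#' @param theta circle-IoU matching threshold.
#' @return List with \code{perCategory} (data.frame of tp/fp/fn/precision/
#'   recall/f1 for empty, single, multiple) and \code{meanF1}.
#' @export
categoryF1 <- function(truth, pred, theta = 0.7) {
  cats <- c("empty", "single", "multiple")
  m <- matchCircles(truth, pred, theta)
  tp <- fp <- fn <- setNames(integer(3), cats)
  for (i in seq_len(nrow(m$pairs))) {
    tc <- truth$category[m$pairs$truthIdx[i]]
    pc <- pred$category[m$pairs$predIdx[i]]
    if (tc == pc) tp[tc] <- tp[tc] + 1L
    else {
      if (pc %in% cats) fp[pc] <- fp[pc] + 1L
      fn[tc] <- fn[tc] + 1L
    }
  }
  for (i in m$unmatchedTruth) fn[truth$category[i]] <- fn[truth$category[i]] + 1L
  for (j in m$unmatchedPred) {
    pc <- pred$category[j]
    if (pc %in% cats) fp[pc] <- fp[pc] + 1L
  }
  per <- do.call(rbind, lapply(cats, function(k) {
    s <- prf1(tp[k], fp[k], fn[k])
    data.frame(category = k, tp = tp[k], fp = fp[k], fn = fn[k],
               precision = s["precision"], recall = s["recall"],
               f1 = s["f1"])
  }))
  rownames(per) <- NULL
  list(perCategory = per, meanF1 = mean(per$f1))
}
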