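## Stage 1: droplet proposal generation by adaptive-scale circular template
## matching (ASTM) on an Otsu foreground.
##
## The matching response of a binary disk template of diameter r at a pixel
## is the fraction of the template area lying on foreground; it equals a
## normalized correlation of the foreground with the disk kernel. Scales
## start above the largest expected droplet and shrink adaptively: whenever
## no pixel reaches the response threshold sigma, the next scale is
## r_next = Dmax * r_cur (capped below by a fixed contraction factor so the
## sequence always terminates). Accepted circles have their foreground
## erased so one droplet cannot fire again at a smaller scale; a final
## circle-IoU non-maximum suppression removes residual duplicates.

#' Binarize droplet foreground by Otsu thresholding
#'
#' Applies a global Otsu threshold with polarity chosen so that droplets
#' (dark in brightfield) become foreground, then fills interior holes so
#' droplets are solid disks. When the histogram carries no real foreground
#' (near-constant frame, e.g. pure oil background), an all-zero mask is
#' returned: the split is rejected if Otsu's between-class variance explains
#' less than \code{minSeparation} of the total variance, which a single
#' noise mode cannot exceed.
#'
#' @param image numeric matrix, intensities in [0, 255].
#' @param fillHoles fill enclosed background holes inside foreground.
#' @param minSeparation minimum fraction of total intensity variance that
#'   the Otsu split must explain for the mask to be considered non-empty.
#' @return Binary 0/1 matrix of the image size, with attribute
#'   \code{threshold} (NA when the frame was judged foreground-free).
#' @export
binarizeForeground <- function(image, fillHoles = TRUE, minSeparation = 0.75) {
  stopifnot(is.matrix(image), length(image) > 0)
  x <- image / 255
  if (max(x) - min(x) < 1e-8) {
    mask <- matrix(0L, nrow(image), ncol(image))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)

  below <- x <= thr
  p0 <- mean(below)
  eta <- 0
  if (p0 > 0 && p0 < 1) {
    mu0 <- mean(x[below]); mu1 <- mean(x[!below])
    eta <- p0 * (1 - p0) * (mu1 - mu0)^2 / stats::var(as.vector(x))
  }
  if (eta < minSeparation) {
    mask <- matrix(0L, nrow(image), ncol(image))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }

  fg <- below
  if (mean(fg) > 0.5) fg <- !fg  # droplets are the minority phase
  if (fillHoles) {
    filled <- EBImage::fillHull(EBImage::Image(fg * 1))
    fg <- EBImage::imageData(filled) > 0.5
  }
  mask <- matrix(as.integer(fg), nrow(image), ncol(image))
  attr(mask, "threshold") <- as.numeric(thr) * 255
  mask
}

## Binary disk kernel of diameter r (odd raster side >= r).
diskKernel <- function(r) {
  h <- floor(r / 2)
  off <- -h:h
  k <- outer(off^2, off^2, `+`) <= (r / 2)^2
  storage.mode(k) <- "double"
  k
}

#' Circular template matching response map
#'
#' For every pixel, the fraction of a binary disk template of diameter
#' \code{r} (centered there, zero-padded at borders) that lies on
#' foreground. Values are in [0, 1]; 1 means the disk fits entirely inside
#' the foreground.
#'
#' @param F binary foreground matrix (0/1).
#' @param r template diameter in px.
#' @return Numeric matrix of responses, same size as \code{F}.
#' @export
matchResponse <- function(F, r) {
  stopifnot(r >= 2)
  k <- diskKernel(r)
  resp <- EBImage::filter2(EBImage::Image(F * 1), k / sum(k), boundary = 0)
  resp <- matrix(EBImage::imageData(resp), nrow(F), ncol(F))
  pmin(pmax(resp, 0), 1)
}

## Local maxima of a response map at or above sigma. 8-neighborhood; on
## plateaus the first pixel in raster order (row, then column) wins.
## Returns a data.frame (row, col, score) sorted by decreasing score.
localMaxima <- function(resp, sigma) {
  H <- nrow(resp); W <- ncol(resp)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- resp
  sh <- function(di, dj) pad[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  ## earlier raster neighbors must be strictly smaller; later ones not larger
  ok <- resp >= sigma &
    resp >  sh(-1, -1) & resp >  sh(-1, 0) & resp >  sh(-1, 1) &
    resp >  sh(0, -1) &
    resp >= sh(0, 1) &
    resp >= sh(1, -1) & resp >= sh(1, 0) & resp >= sh(1, 1)
  idx <- which(ok)
  if (!length(idx))
    return(data.frame(row = integer(0), col = integer(0), score = numeric(0)))
  rows <- ((idx - 1) %% H) + 1
  cols <- ((idx - 1) %/% H) + 1
  out <- data.frame(row = rows, col = cols, score = resp[idx])
  out[order(-out$score, out$row, out$col), , drop = FALSE]
}

## Zero the foreground inside a circle.
eraseCircle <- function(F, cx, cy, r) {
  H <- nrow(F); W <- ncol(F)
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  sub <- F[rows, cols, drop = FALSE]
  sub[d2 <= r^2] <- 0L
  F[rows, cols] <- sub
  F
}

#' Greedy adaptive-scale droplet proposal search
#'
#' Iterates template scales downward from \code{rInit}. At each scale the
#' full response map is computed; local maxima reaching \code{sigma} are
#' accepted as droplet proposals (center = pixel, diameter = current scale),
#' mutually non-overlapping maxima being taken per pass and their foreground
#' erased before the same scale is re-searched. When the best response falls
#' below \code{sigma}, the scale shrinks to the equivalent diameter of the
#' best covered foreground area, \code{sqrt(Dmax) * r}, capped at
#' \code{minShrink * r} so progress is guaranteed, until \code{rMin} is
#' reached or the foreground is exhausted.
#'
#' @param F binary foreground matrix.
#' @param cfg an [AstmConfig-class].
#' @return data.frame of proposals: \code{cx}, \code{cy}, \code{r} (circle
#'   radius, px), \code{score}.
#' @seealso [nmsCircles()], [detectDroplets()]
#' @export
greedyPropose <- function(F, cfg) {
  validObject(cfg)
  if (cfg@rInit <= cfg@rMin)
    stop("rInit must exceed rMin")
  Fw <- F
  props <- list()
  r <- cfg@rInit
  passes <- 0L
  while (r >= cfg@rMin && any(Fw > 0)) {
    repeat {
      passes <- passes + 1L
      if (passes > 1000L) {
        warning("ASTM pass budget exhausted; returning proposals found so far")
        r <- 0
        break
      }
      resp <- matchResponse(Fw, r)
      dmax <- max(resp)
      if (dmax < cfg@sigma) break
      cand <- localMaxima(resp, cfg@sigma)
      accRow <- numeric(0); accCol <- numeric(0)
      for (i in seq_len(nrow(cand))) {
        if (length(accRow) == 0L ||
            all(sqrt((accRow - cand$row[i])^2 +
                     (accCol - cand$col[i])^2) >= r)) {
          accRow <- c(accRow, cand$row[i])
          accCol <- c(accCol, cand$col[i])
          props[[length(props) + 1L]] <-
            data.frame(cx = cand$col[i], cy = cand$row[i],
                       r = r / 2, score = cand$score[i])
        }
      }
      ## erase one shrink step beyond the accepted radius: the true droplet
      ## radius lies in [r/2, r/2/minShrink) on the quantized scale grid, and
      ## leftover slivers would fire again at much smaller scales
      for (i in seq_along(accRow))
        Fw <- eraseCircle(Fw, accCol[i], accRow[i], r / 2 / cfg@minShrink)
    }
    if (r == 0 || dmax <= 0) break
    ## adaptive shrink: the best response Dmax at scale r covers a foreground
    ## area of (pi r^2/4) Dmax, i.e. an equivalent disk of diameter
    ## r * sqrt(Dmax); jumping there (capped by minShrink for guaranteed
    ## progress) lands the next scale on the largest remaining droplet
    r <- min(sqrt(dmax), cfg@minShrink) * r
  }
  if (length(props)) do.call(rbind, props)
  else data.frame(cx = numeric(0), cy = numeric(0),
                  r = numeric(0), score = numeric(0))
}

#' Non-maximum suppression on circle proposals
#'
#' Proposals are ranked by decreasing score; any proposal whose circle IoU
#' with an already-kept proposal exceeds \code{nmsIou} is dropped. The
#' operation is idempotent and returns proposals in descending score order.
#'
#' @param proposals data.frame with \code{cx}, \code{cy}, \code{r},
#'   \code{score}.
#' @param nmsIou suppression threshold on circle IoU.
#' @return Filtered proposal data.frame.
#' @export
nmsCircles <- function(proposals, nmsIou = 0.3) {
  if (nrow(proposals) == 0L) return(proposals)
  ord <- order(-proposals$score, proposals$cy, proposals$cx)
  p <- proposals[ord, , drop = FALSE]
  keep <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    ki <- which(keep)
    if (length(ki) == 0L ||
        all(circleIoU(p$cx[i], p$cy[i], p$r[i],
                      p$cx[ki], p$cy[ki], p$r[ki]) <= nmsIou))
      keep[i] <- TRUE
  }
  out <- p[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect droplets in a grayscale frame
#'
#' Full stage-1 pipeline: Otsu foreground binarization, greedy
#' adaptive-scale template matching, and circle non-maximum suppression.
#'
#' @param image numeric matrix, intensities in [0, 255].
#' @param cfg an [AstmConfig-class].
#' @return data.frame of droplet proposals (\code{cx}, \code{cy}, \code{r},
#'   \code{score}).
#' @examples
#' scene <- renderScene(sceneConfig(nDroplets = 25, seed = 11))
#' props <- detectDroplets(sceneImage(scene), astmConfig())
#' nrow(props)
#' @export
detectDroplets <- function(image, cfg = astmConfig()) {
  F <- binarizeForeground(image)
  nmsCircles(greedyPropose(F, cfg), cfg@nmsIou)
}
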