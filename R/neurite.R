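## Image-level neurite-interaction metrics: Otsu binarization, medial-axis
## mean fiber width, axon-dendrite bundling fraction, and synapse density by
## pre/post puncta colocalization.

#' Binarize a grayscale image with Otsu's threshold
#'
#' The threshold maximizes the between-class variance over a 256-bin
#' histogram spanning the observed intensity range; pixels strictly above the
#' threshold are foreground. Ties break toward the smaller threshold.
#'
#' @param image numeric matrix of intensities (>= 2 distinct values).
#' @param pixelSize pixel size in nm for the returned mask.
#' @return A \linkS4class{MaskImage}. The chosen threshold is attached as
#'   attribute \code{"threshold"} of the returned object's mask.
#' @export
binarizeOtsu <- function(image, pixelSize = 133) {
  stopifnot(is.matrix(image), is.numeric(image))
  rng <- range(image)
  if (diff(rng) == 0)
    stop("constant image: Otsu threshold undefined", call. = FALSE)
  levels <- 256L
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- hist(image, breaks = breaks, plot = FALSE)$counts
  n <- sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(h) / n
  mu <- cumsum(h * mids) / n
  muT <- mu[levels]
  # between-class variance for thresholds at each bin's upper edge
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)            # which.max: first maximum = smaller threshold
  threshold <- breaks[k + 1L]
  mask <- image > threshold
  out <- MaskImage(mask, pixelSize)
  attr(out@mask, "threshold") <- threshold
  out
}

## ---- skeletonization --------------------------------------------------------

# Shift a logical/numeric matrix by (dr, dc), zero-filling.
.shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen topology-preserving thinning; returns a logical skeleton of the
# same shape. Rows increase downward; neighbours P2..P9 run clockwise from
# north.
.thinMask <- function(mask) {
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  offs <- list(P2 = c(-1, 0), P3 = c(-1, 1), P4 = c(0, 1), P5 = c(1, 1),
               P6 = c(1, 0), P7 = c(1, -1), P8 = c(0, -1), P9 = c(-1, -1))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- lapply(offs, function(o) .shiftMat(img, -o[1], -o[2]))
      B <- Reduce(`+`, nb)
      seqn <- nb[c("P2", "P3", "P4", "P5", "P6", "P7", "P8", "P9", "P2")]
      A <- matrix(0, nrow(img), ncol(img))
      for (i in 1:8) A <- A + (seqn[[i]] == 0) * (seqn[[i + 1]] == 1)
      if (pass == 1) {
        c1 <- nb$P2 * nb$P4 * nb$P6 == 0
        c2 <- nb$P4 * nb$P6 * nb$P8 == 0
      } else {
        c1 <- nb$P2 * nb$P4 * nb$P8 == 0
        c2 <- nb$P2 * nb$P6 * nb$P8 == 0
      }
      del <- img == 1 & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        img[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1
}

#' Medial-axis skeleton of a mask
#'
#' Topology-preserving (Zhang-Suen) thinning to a one-pixel-wide skeleton.
#'
#' @param mask a \linkS4class{MaskImage}.
#' @return A \linkS4class{MaskImage} holding the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is(mask, "MaskImage"))
  MaskImage(.thinMask(mask@mask), mask@pixelSize)
}

#' Mean fiber width of a binary mask
#'
#' The mask is thinned to its medial axis; the local width at each skeleton
#' pixel is \code{2*EDT - 1} pixels, where EDT is the Euclidean distance to
#' the nearest background pixel centre (the half-pixel correction makes the
#' estimate exact on odd-width ribbons). The mean width is the mean over
#' skeleton pixels, scaled to nm.
#'
#' @param mask a \linkS4class{MaskImage} with at least 3 foreground pixels.
#' @return A \linkS4class{BundleWidthResult}.
#' @examples
#' m <- matrix(FALSE, 21, 40); m[6:16, ] <- TRUE
#' meanWidth(meanFiberWidth(MaskImage(m, 133))) / 133   # ~11 px
#' @export
meanFiberWidth <- function(mask) {
  stopifnot(is(mask, "MaskImage"))
  m <- mask@mask
  if (sum(m) < 3L) stop("mask needs a foreground component of >= 3 pixels",
                        call. = FALSE)
  # pad so the image border counts as background for both operations
  pm <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pm[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  skel <- .thinMask(pm)
  edt <- EBImage::imageData(EBImage::distmap(matrix(as.numeric(pm), nrow(pm), ncol(pm))))
  wpx <- 2 * edt[skel] - 1
  new("BundleWidthResult",
      meanWidth = mean(wpx) * mask@pixelSize,
      widths = as.numeric(wpx) * mask@pixelSize,
      skeletonLength = sum(skel) * mask@pixelSize)
}

#' Fraction of dendrite length bundled with axons
#'
#' Skeletonizes the dendrite mask and reports the fraction of dendrite
#' skeleton pixels that fall inside the axon mask dilated by one pixel (the
#' one-pixel tolerance absorbs single-pixel registration error).
#'
#' @param axon,dendrite \linkS4class{MaskImage} objects on the same grid.
#' @return Numeric fraction in [0, 1].
#' @export
dendriteBundlingFraction <- function(axon, dendrite) {
  stopifnot(is(axon, "MaskImage"), is(dendrite, "MaskImage"))
  if (!all(dim(axon@mask) == dim(dendrite@mask)) ||
      abs(axon@pixelSize - dendrite@pixelSize) > 1e-9)
    stop("axon and dendrite masks must share grid and pixel size", call. = FALSE)
  if (!any(dendrite@mask)) stop("empty dendrite mask", call. = FALSE)
  skel <- .thinMask(dendrite@mask)
  if (!any(skel)) stop("dendrite skeleton is empty", call. = FALSE)
  dil <- EBImage::imageData(EBImage::dilate(
    matrix(as.numeric(axon@mask), nrow(axon@mask)),
    EBImage::makeBrush(3L, "box"))) > 0
  mean(dil[skel])
}

# Greedy one-to-one matching: repeatedly pair the globally closest unmatched
# (pre, post) pair with distance <= radius. Returns index pairs.
.greedyMatch <- function(pre, post, radius) {
  if (!nrow(pre) || !nrow(post)) return(matrix(integer(0), ncol = 2))
  D <- outer(seq_len(nrow(pre)), seq_len(nrow(post)),
             function(i, j) sqrt((pre[i, 1] - post[j, 1])^2 +
                                   (pre[i, 2] - post[j, 2])^2))
  pairs <- NULL
  repeat {
    k <- which.min(D)
    if (!length(k) || !is.finite(D[k]) || D[k] > radius) break
    ij <- arrayInd(k, dim(D))
    pairs <- rbind(pairs, ij)
    D[ij[1], ] <- Inf
    D[, ij[2]] <- Inf
  }
  if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs
}

#' Synapse density from pre/post puncta colocalization
#'
#' Pre- and post-synaptic puncta are matched one-to-one greedily: the
#' globally closest unmatched pair within the colocalization radius (default
#' 266 nm, two camera pixels at 133 nm) is paired repeatedly. The density is
#' the number of matched pairs divided by the dendrite foreground area in
#' square micrometres.
#'
#' @param pre,post \linkS4class{PunctaSet} objects (nm coordinates).
#' @param dendrite non-empty \linkS4class{MaskImage} giving the dendrite area.
#' @param radius colocalization radius in nm (default 266).
#' @return List with \code{nMatched}, \code{density} (per um^2),
#'   \code{areaUm2} and the matched index \code{pairs}.
#' @export
synapseDensity <- function(pre, post, dendrite, radius = 266) {
  stopifnot(is(pre, "PunctaSet"), is(post, "PunctaSet"), is(dendrite, "MaskImage"),
            radius > 0)
  if (!any(dendrite@mask)) stop("empty dendrite mask", call. = FALSE)
  pairs <- .greedyMatch(pre@coords, post@coords, radius)
  areaUm2 <- sum(dendrite@mask) * dendrite@pixelSize^2 / 1e6
  list(nMatched = nrow(pairs), density = nrow(pairs) / areaUm2,
       areaUm2 = areaUm2, pairs = pairs)
}
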