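## Synthetic neurite scenes: smooth random axon/dendrite paths dilated to
## their widths, optional axon-along-dendrite bundling, and paired pre/post
## synaptic puncta on dendrites with orphan puncta per channel.

# A smooth random path across the pixel grid: unit steps with slowly
# drifting direction, started on a random border, until the path leaves the
# image. Returns an m x 2 matrix of (row, col) pixel indices.
.randomPath <- function(shape) {
  nr <- shape[1]; nc <- shape[2]
  side <- sample.int(4L, 1L)
  pos <- switch(side,
                c(1, stats::runif(1, 1, nc)),
                c(nr, stats::runif(1, 1, nc)),
                c(stats::runif(1, 1, nr), 1),
                c(stats::runif(1, 1, nr), nc))
  # head inward
  th <- switch(side,
               stats::runif(1, pi / 4, 3 * pi / 4),
               stats::runif(1, -3 * pi / 4, -pi / 4),
               stats::runif(1, -pi / 4, pi / 4),
               stats::runif(1, 3 * pi / 4, 5 * pi / 4))
  pts <- matrix(0, nr + nc, 2L)
  k <- 0L
  repeat {
    if (pos[1] < 1 || pos[1] > nr || pos[2] < 1 || pos[2] > nc) break
    k <- k + 1L
    if (k > nrow(pts)) pts <- rbind(pts, matrix(0, nr + nc, 2L))
    pts[k, ] <- pos
    th <- th + stats::rnorm(1, 0, 0.06)
    pos <- pos + c(sin(th), cos(th))
  }
  pts[seq_len(k), , drop = FALSE]
}

# Rasterize a path and dilate it to the requested odd width in pixels.
.rasterizePath <- function(path, shape, widthPx) {
  m <- matrix(0, shape[1], shape[2])
  ij <- unique(round(path))
  ij <- ij[ij[, 1] >= 1 & ij[, 1] <= shape[1] &
             ij[, 2] >= 1 & ij[, 2] <= shape[2], , drop = FALSE]
  m[cbind(ij[, 1], ij[, 2])] <- 1
  if (widthPx > 1L)
    m <- EBImage::imageData(EBImage::dilate(m, EBImage::makeBrush(widthPx, "disc")))
  m > 0
}

.oddPx <- function(widthNm, pixelSize) {
  w <- max(1L, round(widthNm / pixelSize))
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(w)
}

#' Simulate a neurite scene: masks, bundling and synaptic puncta
#'
#' Axons and dendrites are smooth random paths dilated to their widths. With
#' probability \code{bundlingProbability} an axon is laid along a (randomly
#' chosen) dendrite path, emulating axon-dendrite fasciculation. Synapse
#' pairs are placed at random dendrite-path positions, the post punctum
#' offset from the pre punctum by a per-coordinate Normal(0,
#' \code{pairOffsetSd}); orphan puncta are added uniformly per channel.
#'
#' @param config a \linkS4class{NeuriteSceneConfig}.
#' @return List with \code{axonMask} and \code{dendriteMask}
#'   (\linkS4class{MaskImage}), \code{prePuncta} and \code{postPuncta}
#'   (\linkS4class{PunctaSet}), and \code{groundTruth} (realized widths in
#'   nm, per-dendrite bundled flags, the length-weighted bundled fraction,
#'   and the synapse pair count).
#' @examples
#' scene <- simulateNeuriteScene(neuriteSceneConfig(seed = 2L))
#' scene$dendriteMask
#' @export
simulateNeuriteScene <- function(config) {
  stopifnot(is(config, "NeuriteSceneConfig"))
  validObject(config)
  shape <- config@imageShape
  ps <- config@pixelSize
  axPx <- .oddPx(config@axonWidth, ps)
  dnPx <- .oddPx(config@dendriteWidth, ps)

  dendPaths <- .withSubstream(config@seed, "dendrites",
                              lapply(seq_len(config@nDendrites),
                                     function(i) .randomPath(shape)))
  dendMask <- Reduce(`|`, lapply(dendPaths, .rasterizePath, shape = shape,
                                 widthPx = dnPx),
                     matrix(FALSE, shape[1], shape[2]))

  bundled <- .withSubstream(config@seed, "bundling",
                            stats::runif(config@nAxons) < config@bundlingProbability)
  hostIdx <- .withSubstream(config@seed, "bundle-host",
                            sample.int(max(config@nDendrites, 1L),
                                       config@nAxons, replace = TRUE))
  axonPaths <- .withSubstream(config@seed, "axons",
                              lapply(seq_len(config@nAxons), function(i) {
                                if (bundled[i] && config@nDendrites > 0L)
                                  dendPaths[[hostIdx[i]]]
                                else .randomPath(shape)
                              }))
  axonMask <- Reduce(`|`, lapply(axonPaths, .rasterizePath, shape = shape,
                                 widthPx = axPx),
                     matrix(FALSE, shape[1], shape[2]))

  # ground-truth bundling: length-weighted fraction of dendrite path carrying
  # a bundled axon
  dendLen <- vapply(dendPaths, nrow, 1L)
  dendBundled <- vapply(seq_len(config@nDendrites), function(j)
    any(bundled & hostIdx == j), TRUE)
  truthFraction <- if (sum(dendLen)) sum(dendLen[dendBundled]) / sum(dendLen) else 0

  # puncta: pixel (row, col) -> nm (x = (col - 0.5) * ps, y = (row - 0.5) * ps)
  toNm <- function(rc) cbind(x = (rc[, 2] - 0.5) * ps, y = (rc[, 1] - 0.5) * ps)
  allDend <- do.call(rbind, dendPaths)
  pre <- matrix(numeric(0), ncol = 2)
  post <- matrix(numeric(0), ncol = 2)
  if (config@nSynapsePairs > 0L && nrow(allDend)) {
    sel <- .withSubstream(config@seed, "synapses", {
      idx <- sample.int(nrow(allDend), config@nSynapsePairs, replace = TRUE)
      offs <- matrix(stats::rnorm(2L * config@nSynapsePairs, 0,
                                  config@pairOffsetSd), ncol = 2)
      list(idx = idx, offs = offs)
    })
    prePts <- toNm(round(allDend[sel$idx, , drop = FALSE]))
    pre <- prePts
    post <- prePts + sel$offs
  }
  if (config@nOrphanPuncta > 0L) {
    orphans <- .withSubstream(config@seed, "orphans", {
      n <- config@nOrphanPuncta
      list(pre = cbind(stats::runif(n, 0, shape[2] * ps),
                       stats::runif(n, 0, shape[1] * ps)),
           post = cbind(stats::runif(n, 0, shape[2] * ps),
                        stats::runif(n, 0, shape[1] * ps)))
    })
    pre <- rbind(pre, orphans$pre)
    post <- rbind(post, orphans$post)
  }

  list(axonMask = MaskImage(axonMask, ps),
       dendriteMask = MaskImage(dendMask, ps),
       prePuncta = PunctaSet(pre, "pre"),
       postPuncta = PunctaSet(post, "post"),
       groundTruth = list(axonWidthNm = axPx * ps, dendriteWidthNm = dnPx * ps,
                          dendriteBundled = dendBundled,
                          bundledFraction = truthFraction,
                          nSynapsePairs = config@nSynapsePairs))
}
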