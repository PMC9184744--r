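## Synthetic co-IP spectral-count tables emulating the three-bait + IgG
## design: Poisson baseline counts for every protein in every sample, a fold
## enrichment for true interactors in bait samples, and a fraction of counts
## carried by peptides shared between randomly paired proteins.

#' Simulate co-IP spectral counts
#'
#' Counts are drawn Poisson with mean \code{baselineCount} for all proteins in
#' the IgG control samples; true interactors get mean
#' \code{baselineCount * baitEnrichment} in the bait samples. A
#' \code{sharedPeptideFraction} of each protein's drawn count is reassigned
#' to a peptide shared with a randomly paired partner protein (pairing fixed
#' per simulation); the rest stays unique. The table covers
#' \code{nBaits} baits plus one "IgG" control, times \code{nReplicates}.
#'
#' @param config a \linkS4class{CoIPSimConfig}.
#' @return List with \code{counts} (a \linkS4class{SpectralCounts}) and
#'   \code{groundTruth} (list with logical \code{interactor} named by
#'   protein id, bait sample names, and the shared-peptide pairing).
#' @examples
#' sim <- simulateSpectralCounts(coipSimConfig(nProteins = 10L, seed = 3L))
#' sim$counts
#' @export
simulateSpectralCounts <- function(config) {
  stopifnot(is(config, "CoIPSimConfig"))
  validObject(config)
  np <- config@nProteins
  ids <- sprintf("P%03d", seq_len(np))
  proteins <- data.frame(protein_id = ids, length = config@proteinLengths)
  interactor <- c(rep(TRUE, config@nTrueInteractors),
                  rep(FALSE, np - config@nTrueInteractors))
  names(interactor) <- ids
  samples <- c(sprintf("bait%d", seq_len(config@nBaits)), "IgG")

  # fixed random pairing of proteins for shared peptides
  pairing <- NULL
  if (config@sharedPeptideFraction > 0) {
    perm <- .withSubstream(config@seed, "pairing", sample.int(np))
    ia <- perm[seq_len(floor(np / 2))]
    ib <- perm[floor(np / 2) + seq_len(floor(np / 2))]
    pairing <- data.frame(a = ids[ia], b = ids[ib])
  }

  uq <- list(); sh <- list()
  for (s in samples) {
    isBait <- s != "IgG"
    for (r in seq_len(config@nReplicates)) {
      mu <- rep(config@baselineCount, np)
      if (isBait) mu[interactor] <- mu[interactor] * config@baitEnrichment
      total <- .withSubstream(config@seed, sprintf("counts:%s:%d", s, r),
                              stats::rpois(np, mu))
      shared <- round(total * config@sharedPeptideFraction)
      # a protein left unpaired (odd count) keeps all its counts unique
      if (!is.null(pairing))
        shared[!ids %in% c(pairing$a, pairing$b)] <- 0
      else shared[] <- 0
      unique_ <- total - shared
      uq[[length(uq) + 1L]] <- data.frame(protein_id = ids, sample = s,
                                          replicate = r, count = unique_)
      if (!is.null(pairing)) {
        sv <- stats::setNames(shared, ids)
        cnt <- sv[pairing$a] + sv[pairing$b]
        keep <- cnt > 0
        if (any(keep)) {
          sh[[length(sh) + 1L]] <- data.frame(
            peptide_id = sprintf("pep_%s_%s", pairing$a[keep], pairing$b[keep]),
            sample = s, replicate = r, count = as.numeric(cnt[keep]),
            sharers = paste(pairing$a[keep], pairing$b[keep], sep = ";"))
        }
      }
    }
  }
  sc <- SpectralCounts(proteins, do.call(rbind, uq),
                       if (length(sh)) do.call(rbind, sh) else NULL)
  list(counts = sc,
       groundTruth = list(interactor = interactor,
                          baits = samples[samples != "IgG"], pairing = pairing))
}
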