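## dNSAF scoring of co-IP spectral counts, bait-vs-IgG fold-change filtering,
## and multi-bait intersection / pooling of candidate lists.

# dSpC and dNSAF for one (sample, replicate): distributed spectral counts
#   dSpC_k = uSpC_k + sum over shared peptides p containing k of
#            sSpC_p * uSpC_k / sum_{j in sharers(p)} uSpC_j
# (equal split among sharers when all sharers have uSpC = 0), then
#   dNSAF_k = (dSpC_k / L_k) / sum_i (dSpC_i / L_i).
.dnsafOne <- function(sc, sample, replicate) {
  p <- sc@proteins
  u <- sc@uniqueCounts
  u <- u[u$sample == sample & u$replicate == replicate, , drop = FALSE]
  uSpC <- stats::setNames(rep(0, nrow(p)), p$protein_id)
  if (nrow(u)) {
    agg <- tapply(u$count, u$protein_id, sum)
    uSpC[names(agg)] <- agg
  }
  dSpC <- uSpC
  s <- sc@sharedCounts
  if (nrow(s)) {
    s <- s[s$sample == sample & s$replicate == replicate, , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      sharers <- strsplit(s$sharers[i], ";", fixed = TRUE)[[1]]
      usum <- sum(uSpC[sharers])
      if (usum > 0) {
        dSpC[sharers] <- dSpC[sharers] + s$count[i] * uSpC[sharers] / usum
      } else {
        dSpC[sharers] <- dSpC[sharers] + s$count[i] / length(sharers)
      }
    }
  }
  saf <- dSpC / p$length
  denom <- sum(saf)
  if (denom <= 0)
    stop(sprintf("all-zero spectral counts for sample '%s' replicate %d",
                 sample, replicate), call. = FALSE)
  data.frame(protein_id = p$protein_id, length = p$length,
             dSpC = as.numeric(dSpC), dNSAF = as.numeric(saf / denom))
}

#' Compute dNSAF scores for one sample
#'
#' Distributed normalized spectral abundance factors: shared-peptide counts
#' are distributed among sharing proteins in proportion to their unique
#' counts (equal split if all sharers have zero unique counts), the
#' distributed counts are length-normalized, and the result is scaled so the
#' per-sample dNSAF values sum to 1. With replicates, dNSAF is computed per
#' replicate and then combined.
#'
#' @param counts a \linkS4class{SpectralCounts}.
#' @param sample sample label (a bait name or "IgG").
#' @param combine "mean" (default: average dNSAF across replicates) or a
#'   single replicate id.
#' @return A \linkS4class{DNSAFTable}.
#' @examples
#' sc <- SpectralCounts(
#'   proteins = data.frame(protein_id = c("A", "B"), length = c(100, 200)),
#'   uniqueCounts = data.frame(protein_id = c("A", "B"), sample = "bait1",
#'                             replicate = 1L, count = c(4, 6)),
#'   sharedCounts = data.frame(peptide_id = "pep1", sample = "bait1",
#'                             replicate = 1L, count = 10, sharers = "A;B"))
#' computeDnsaf(sc, "bait1")
#' @export
computeDnsaf <- function(counts, sample, combine = "mean") {
  stopifnot(is(counts, "SpectralCounts"))
  validObject(counts)
  reps <- sort(unique(counts@uniqueCounts$replicate[
    counts@uniqueCounts$sample == sample]))
  if (!length(reps))
    stop(sprintf("sample '%s' absent from the spectral-count table", sample),
         call. = FALSE)
  if (!identical(combine, "mean")) {
    if (!combine %in% reps)
      stop(sprintf("replicate %s absent for sample '%s'", combine, sample),
           call. = FALSE)
    reps <- combine
  }
  per <- lapply(reps, function(r) .dnsafOne(counts, sample, r))
  tab <- per[[1]]
  if (length(per) > 1L) {
    tab$dSpC <- rowMeans(vapply(per, function(x) x$dSpC, numeric(nrow(tab))))
    tab$dNSAF <- rowMeans(vapply(per, function(x) x$dNSAF, numeric(nrow(tab))))
  }
  new("DNSAFTable", sample = as.character(sample), table = tab)
}

#' Filter candidates by dNSAF fold change against a control
#'
#' Keeps protein k iff \code{dNSAF_bait(k) / dNSAF_control(k) > threshold}
#' (strictly greater: a fold change of exactly 1 is removed). Proteins with
#' zero control dNSAF but positive bait dNSAF are kept with an infinite fold
#' change; proteins absent (zero) in the bait sample are dropped.
#'
#' @param bait,control \linkS4class{DNSAFTable} objects over a shared protein
#'   universe.
#' @param threshold fold-change threshold (default 1).
#' @return A \linkS4class{CandidateList} ordered by decreasing fold change,
#'   with the fold changes as scores.
#' @export
foldChangeFilter <- function(bait, control, threshold = 1) {
  stopifnot(is(bait, "DNSAFTable"), is(control, "DNSAFTable"))
  b <- stats::setNames(bait@table$dNSAF, bait@table$protein_id)
  ctl <- stats::setNames(control@table$dNSAF, control@table$protein_id)
  ids <- names(b)[b > 0]
  fc <- vapply(ids, function(k) {
    c0 <- if (k %in% names(ctl)) ctl[[k]] else 0
    if (c0 == 0) Inf else b[[k]] / c0
  }, 0)
  keep <- fc > threshold
  ord <- order(-fc[keep], ids[keep])
  CandidateList(ids[keep][ord], scores = fc[keep][ord],
                provenance = list(bait = bait@sample, control = control@sample,
                                  threshold = threshold))
}

#' Intersect candidate lists across baits
#'
#' Set intersection of two or more candidate lists (the "common to all baits"
#' criterion), plus exclusive Venn region counts for all 2^n - 1 non-empty
#' bait combinations.
#'
#' @param lists list of >= 2 \linkS4class{CandidateList}; names are used as
#'   region labels (defaulting to the recorded bait names).
#' @return List with \code{candidates} (\linkS4class{CandidateList}, ordered
#'   as in the first list) and \code{venn} (named integer vector of exclusive
#'   region counts, labels joined with "&").
#' @export
intersectCandidates <- function(lists) {
  if (length(lists) < 2L) stop("need >= 2 candidate lists", call. = FALSE)
  sets <- lapply(lists, candidateIds)
  labels <- names(lists)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(seq_along(lists), function(i) {
      bl <- lists[[i]]@provenance$bait
      if (is.null(bl)) sprintf("list%d", i) else bl
    }, "")
  common <- Reduce(intersect, sets)
  common <- sets[[1]][sets[[1]] %in% common]
  n <- length(sets)
  allIds <- unique(unlist(sets))
  member <- vapply(sets, function(s) allIds %in% s, logical(length(allIds)))
  if (length(allIds) == 1L) member <- matrix(member, nrow = 1L)
  venn <- integer(0)
  for (m in seq_len(2^n - 1L)) {
    inset <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1L)))
    region <- sum(apply(member, 1, function(row) all(row == inset)))
    venn[paste(labels[inset], collapse = "&")] <- region
  }
  list(candidates = CandidateList(common,
                                  provenance = list(operation = "intersection",
                                                    sources = labels)),
       venn = venn)
}

#' Pool candidate lists restricted to an annotation
#'
#' Union of the input lists restricted to annotation-true proteins (e.g. the
#' pooled transmembrane-protein list across baits), deduplicated in order of
#' first appearance.
#'
#' @param lists list of \linkS4class{CandidateList}.
#' @param annotation named logical vector (protein id -> TRUE/FALSE). Pooled
#'   ids missing from the annotation are treated as FALSE with a warning.
#' @return A \linkS4class{CandidateList} with provenance recording sources.
#' @export
poolCandidates <- function(lists, annotation) {
  ids <- unlist(lapply(lists, candidateIds), use.names = FALSE)
  ids <- ids[!duplicated(ids)]
  miss <- setdiff(ids, names(annotation))
  if (length(miss)) {
    warning(sprintf("%d pooled id(s) missing from the annotation; treated as FALSE",
                    length(miss)))
    annotation[miss] <- FALSE
  }
  CandidateList(ids[annotation[ids]],
                provenance = list(operation = "pool",
                                  sources = vapply(lists, function(x) {
                                    b <- x@provenance$bait
                                    if (is.null(b)) "" else b
                                  }, "")))
}
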