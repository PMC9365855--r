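# Distance-binned, hemisphere-aware group-consensus structural connectome.
# Edges observed in any subject are binned by Euclidean length, separately
# for intra- and inter-hemispheric edges; within each bin the most
# frequently occurring edges are retained, as many as the average subject
# has in that bin. This preserves the cohort's density and edge-length
# distribution, which fraction-of-subjects thresholding does not.

# internal: pooled edge table across a subject stack
edge_table <- function(stack, parc) {
  n <- parc$n_regions
  ut <- which(upper.tri(matrix(0, n, n)))
  counts <- numeric(length(ut))
  wsum <- numeric(length(ut))
  for (s in stack) {
    wv <- s$weights[ut]
    present <- wv > 0
    counts <- counts + present
    wsum <- wsum + wv
  }
  idx <- arrayInd(ut, c(n, n))
  d <- centroid_distances(parc)
  data.frame(i = idx[, 1], j = idx[, 2],
             count = counts,
             mean_weight = ifelse(counts > 0, wsum / pmax(counts, 1), 0),
             length = d[ut],
             inter = parc$hemisphere[idx[, 1]] != parc$hemisphere[idx[, 2]])
}

#' Distance-binned group-consensus structural network
#'
#' Builds the binary consensus connectome from a stack of subject
#' structural networks. Existing edges (present in at least one subject)
#' are binned by Euclidean length, separately for intra- and
#' inter-hemispheric classes so interhemispheric edges are not
#' under-represented. Within each bin, the k most frequently occurring
#' edges are retained, where k is the rounded mean number of edges a
#' subject has in that bin; frequency ties are broken by higher mean
#' weight, then by shorter length (deterministic). The number of bins
#' defaults to the rounded square root of the mean per-subject edge count.
#'
#' @param stack list of structural `network` objects (>= 2 subjects).
#' @param parc the aligned `parcellation`.
#' @param n_bins number of length bins per hemisphere class, or "auto".
#' @return A binary structural `network` with attribute `bin_audit`, a
#'   per-bin data frame of target and retained edge counts.
#' @export
group_consensus <- function(stack, parc, n_bins = "auto") {
  stopifnot(length(stack) >= 2)
  for (s in stack) stopifnot(inherits(s, "network"),
                             s$n_regions == parc$n_regions)
  n_subj <- length(stack)
  et <- edge_table(stack, parc)
  et <- et[et$count > 0, , drop = FALSE]
  mean_edges <- sum(et$count) / n_subj
  if (identical(n_bins, "auto")) n_bins <- max(1L, round(sqrt(mean_edges)))
  n_bins <- as.integer(n_bins)

  n <- parc$n_regions
  out <- matrix(0, n, n)
  audit <- list()
  for (inter in c(FALSE, TRUE)) {
    cls <- et[et$inter == inter, , drop = FALSE]
    if (nrow(cls) == 0) {
      warning(sprintf("no %s-hemispheric edges in any subject; class skipped",
                      if (inter) "inter" else "intra"))
      next
    }
    breaks <- seq(min(cls$length), max(cls$length), length.out = n_bins + 1)
    bin <- findInterval(cls$length, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    for (b in sort(unique(bin))) {
      sel <- cls[bin == b, , drop = FALSE]
      k <- round(sum(sel$count) / n_subj)
      if (k == 0) {
        audit[[length(audit) + 1]] <-
          data.frame(inter = inter, bin = b, target = 0, retained = 0)
        next
      }
      ord <- order(-sel$count, -sel$mean_weight, sel$length)
      keep <- sel[ord[seq_len(min(k, nrow(sel)))], , drop = FALSE]
      out[cbind(keep$i, keep$j)] <- 1
      audit[[length(audit) + 1]] <-
        data.frame(inter = inter, bin = b, target = k, retained = nrow(keep))
    }
  }
  out <- out + t(out)
  net <- network(out, parc, kind = "structural")
  attr(net, "bin_audit") <- do.call(rbind, audit)
  net
}

#' Weighted consensus network
#'
#' Assigns weights to the edges of a binary consensus mask: for each
#' retained edge, the mean over subjects with a nonzero weight of the log
#' weight, then min-max scaled over retained edges so weights lie in
#' (0, 1] (the strongest edge gets exactly 1).
#'
#' @param stack list of structural `network` objects.
#' @param mask binary consensus `network` (e.g. from [group_consensus()]).
#' @param parc the aligned `parcellation`.
#' @return A weighted structural `network` supported on the mask.
#' @export
weight_consensus <- function(stack, mask, parc) {
  stopifnot(inherits(mask, "network"), length(stack) >= 1)
  n <- parc$n_regions
  ut <- which(upper.tri(matrix(0, n, n)) & mask$weights > 0)
  if (length(ut) == 0) stop("empty consensus mask")
  logmean <- vapply(ut, function(e) {
    w <- vapply(stack, function(s) s$weights[e], numeric(1))
    w <- w[w > 0]
    if (length(w) == 0) return(NA_real_)
    mean(log(w))
  }, numeric(1))
  if (anyNA(logmean)) {
    bad <- arrayInd(ut[is.na(logmean)], c(n, n))
    stop(sprintf("mask edge(s) absent in every subject, e.g. (%d, %d)",
                 bad[1, 1], bad[1, 2]))
  }
  rng <- range(logmean)
  scaled <- if (rng[2] > rng[1]) {
    # map to (0, 1]: strictly positive so retained edges stay present
    eps <- 1 / (1 + length(logmean))
    pmin(1, eps + (1 - eps) * (logmean - rng[1]) / (rng[2] - rng[1]))
  } else rep(1, length(logmean))
  out <- matrix(0, n, n)
  out[ut] <- scaled
  out <- out + t(out)
  network(out, parc, kind = "structural")
}
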