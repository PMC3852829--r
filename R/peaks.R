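#' Filter peaks by q-value
#'
#' Keeps peaks with `q_value` strictly below `q_max`, the criterion used
#' for consensus-site selection (e.g. `q < 1e-10`). Order is preserved and
#' the operation is idempotent.
#'
#' @param peaks a [PeakSet].
#' @param q_max strict upper bound on the raw q-value, in (0, 1].
#' @return The filtered [PeakSet] (possibly empty).
#' @export
filter_by_q <- function(peaks, q_max) {
  if (!(q_max > 0 && q_max <= 1)) stop_domain("q_max must be in (0, 1]")
  out <- peaks[peaks$q_value < q_max, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("tf_name", "replicate")] <-
    attributes(peaks)[c("tf_name", "replicate")]
  class(out) <- class(peaks)
  out
}

# Chained-overlap clustering of intervals on one chromosome: after sorting
# by start, a peak joins the current cluster when it shares >= min_overlap
# bases with the cluster's running span. Returns cluster ids in input order.
chain_clusters <- function(start, end, min_overlap = 1L) {
  o <- order(start, end)
  cl <- integer(length(start))
  cur <- 0L; cur_end <- -Inf
  for (i in o) {
    if (min(cur_end, end[i]) - start[i] >= min_overlap) {
      cur_end <- max(cur_end, end[i])
    } else {
      cur <- cur + 1L
      cur_end <- end[i]
    }
    cl[i] <- cur
  }
  cl
}

#' Consensus peaks between two peak sets
#'
#' Groups the peaks of both sets into clusters connected by chained
#' overlap of at least `min_overlap` bases on the same chromosome. Every
#' cluster containing peaks from both sides yields one consensus peak: the
#' intersection of the two sides' spans within the cluster. The consensus
#' q-value is the maximum over all member peaks (the least significant
#' member); summits are dropped. Output is sorted by (chrom, start) and is
#' symmetric in its two arguments.
#'
#' @param a,b [PeakSet]s, typically the same factor in two cell lines.
#' @param min_overlap minimum shared bases for two intervals to count as
#'   overlapping (default 1, the weakest standard criterion).
#' @return A [PeakSet] of consensus sites; its `tf_name` is taken from `a`
#'   and its `replicate` is `"consensus"`.
#' @export
overlap_consensus <- function(a, b, min_overlap = 1L) {
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop_domain("min_overlap must be >= 1")
  all_chrom <- c(a$chrom, b$chrom)
  all_start <- c(a$start, b$start)
  all_end <- c(a$end, b$end)
  all_q <- c(a$q_value, b$q_value)
  side <- rep(c("a", "b"), c(nrow(a), nrow(b)))

  out <- list()
  for (ch in sort(unique(all_chrom))) {
    i <- which(all_chrom == ch)
    cl <- chain_clusters(all_start[i], all_end[i], min_overlap)
    for (k in unique(cl)) {
      j <- i[cl == k]
      ja <- j[side[j] == "a"]; jb <- j[side[j] == "b"]
      if (!length(ja) || !length(jb)) next
      s <- max(min(all_start[ja]), min(all_start[jb]))
      e <- min(max(all_end[ja]), max(all_end[jb]))
      if (e - s < min_overlap) next
      out[[length(out) + 1L]] <- list(chrom = ch, start = s, end = e,
                                      q = max(all_q[j]))
    }
  }
  if (!length(out)) {
    return(PeakSet(character(), integer(), integer(),
                   tf_name = attr(a, "tf_name"), replicate = "consensus"))
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  PeakSet(df$chrom, df$start, df$end, q_value = df$q,
          tf_name = attr(a, "tf_name"), replicate = "consensus")
}
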