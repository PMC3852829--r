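#' Distance-decay weight of one binding site
#'
#' The contribution of a binding site at distance `delta_bp` from a TSS is
#' `exp(-(0.5 + 4 * delta))` where `delta` is the distance normalised to
#' the regulatory distance cutoff `D` (so `delta` runs over \[0, 1\] and
#' the weight decays from `exp(-0.5) ~ 0.607` at the TSS to
#' `exp(-4.5) ~ 0.011` at the cutoff). Normalising by `D` is the
#' established regulatory-potential convention; an unnormalised base-pair
#' distance in the exponent would extinguish every weight within a few bp.
#' Set `norm_bp` to use a fixed normalisation instead of `D`.
#'
#' @param delta_bp non-negative distance(s) in bp, at most `D`.
#' @param D regulatory distance cutoff in bp.
#' @param norm_bp optional fixed normalisation length in bp; default uses
#'   `D` itself.
#' @return Numeric weight(s) in `[exp(-4.5), exp(-0.5)]`.
#' @export
site_weight <- function(delta_bp, D, norm_bp = NULL) {
  if (D < 1) stop_domain("D must be a positive integer")
  if (any(delta_bp < 0)) stop_domain("delta_bp must be non-negative")
  if (any(delta_bp > D)) stop_domain("delta_bp exceeds the cutoff D")
  s <- if (is.null(norm_bp)) D else as.numeric(norm_bp)
  exp(-(0.5 + 4 * delta_bp / s))
}

# Anchor point of each peak: the summit when the caller reported one,
# otherwise the floor of the interval midpoint.
peak_anchor <- function(peaks) {
  mid <- floor((peaks$start + peaks$end) / 2)
  ifelse(is.na(peaks$summit), mid, peaks$summit)
}

#' Regulatory potential of every gene for one peak set
#'
#' For each gene, sums the distance-decay weights of all peaks whose
#' anchor point (summit if present, else interval midpoint) lies within
#' `D` bp of the gene's TSS on the same chromosome (boundary inclusive,
#' `|anchor - tss| <= D`). Genes with no peak in range score 0.
#'
#' @param peaks a [PeakSet].
#' @param ann a [GenomeAnnotation].
#' @param D regulatory distance cutoff in bp (positive integer).
#' @param norm_bp passed to [site_weight].
#' @return An `RPTable`: a `data.frame` with one row per annotation gene
#'   and columns `gene_id`, `k` (number of contributing peaks), `S_g`,
#'   plus attributes `tf_name`, `replicate`, `cutoff_D`.
#' @export
regulatory_potential <- function(peaks, ann, D, norm_bp = NULL) {
  if (D < 1) stop_domain("D must be a positive integer")
  ng <- nrow(ann)
  k <- integer(ng)
  sg <- numeric(ng)
  if (nrow(peaks) > 0) {
    anchor <- peak_anchor(peaks)
    for (ch in unique(ann$chrom)) {
      gi <- which(ann$chrom == ch)
      pi <- which(peaks$chrom == ch)
      if (!length(pi)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(anchor[pi], width = 1L),
        IRanges::IRanges(ann$tss[gi] - D, ann$tss[gi] + D))
      if (!length(hits)) next
      g <- gi[S4Vectors::subjectHits(hits)]
      p <- pi[S4Vectors::queryHits(hits)]
      w <- site_weight(abs(anchor[p] - ann$tss[g]), D, norm_bp)
      agg <- rowsum(cbind(w, 1), group = g)
      idx <- as.integer(rownames(agg))
      sg[idx] <- agg[, 1]
      k[idx] <- as.integer(agg[, 2])
    }
  }
  rp <- data.frame(gene_id = ann$gene_id, k = k, S_g = sg,
                   stringsAsFactors = FALSE)
  attr(rp, "tf_name") <- attr(peaks, "tf_name")
  attr(rp, "replicate") <- attr(peaks, "replicate")
  attr(rp, "cutoff_D") <- as.integer(D)
  class(rp) <- c("RPTable", "data.frame")
  rp
}

#' Top regulated genes by regulatory potential
#'
#' Orders genes by decreasing `S_g` (ties broken lexicographically by gene
#' id) and takes the first `N` whose score strictly exceeds `min_score`.
#' Fewer than `N` genes may be returned.
#'
#' @param rp an `RPTable` from [regulatory_potential].
#' @param N target set size (e.g. 100, 200, 500, 800).
#' @param min_score strict lower bound on `S_g` (default 0, which also
#'   drops genes without any peak in range).
#' @return A `RegulatedGeneSet`: a list with `genes` (ordered ids),
#'   `scores`, and the provenance fields `tf_name`, `replicate`,
#'   `cutoff_D`, `N`, `min_score`.
#' @export
top_genes <- function(rp, N, min_score = 0) {
  if (N < 1) stop_domain("N must be a positive integer")
  keep <- rp[rp$S_g > min_score, , drop = FALSE]
  ord <- order(-keep$S_g, keep$gene_id, method = "radix")
  keep <- keep[utils::head(ord, N), , drop = FALSE]
  structure(list(tf_name = attr(rp, "tf_name"),
                 replicate = attr(rp, "replicate"),
                 cutoff_D = attr(rp, "cutoff_D"),
                 N = as.integer(N),
                 genes = keep$gene_id,
                 scores = keep$S_g,
                 min_score = min_score),
            class = "RegulatedGeneSet")
}

#' @export
print.RegulatedGeneSet <- function(x, ...) {
  cat(sprintf("RegulatedGeneSet: %s/%s D=%d N=%d -> %d genes (min S_g kept: %s)\n",
              x$tf_name, x$replicate, x$cutoff_D, x$N, length(x$genes),
              if (length(x$scores)) format(min(x$scores), digits = 4) else "NA"))
  invisible(x)
}
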