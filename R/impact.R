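#' Hypergeometric upper-tail probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, M, n)`: drawing `n` genes
#' without replacement from a universe of `N` of which `M` are marked,
#' the probability of at least `x` marked draws. Summed from the upper
#' side in log-space, so no `1 - sum` cancellation occurs for small tails.
#'
#' @param N universe size.
#' @param M number of marked genes, `0 <= M <= N`.
#' @param n draw size, `0 <= n <= N`.
#' @param x threshold count, `0 <= x <= min(M, n) + 1`.
#' @return The tail probability in \[0, 1\].
#' @export
hypergeom_tail <- function(N, M, n, x) {
  if (M < 0 || M > N || n < 0 || n > N)
    stop_domain("need 0 <= M <= N and 0 <= n <= N (got N=%d M=%d n=%d)", N, M, n)
  if (x < 0 || x > min(M, n) + 1)
    stop_domain("need 0 <= x <= min(M, n) + 1 (got x=%d)", x)
  if (x <= max(0, n + M - N)) return(1)
  hi <- min(M, n)
  if (x > hi) return(0)
  i <- x:hi
  lg <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  mx <- max(lg)
  min(1, exp(mx) * sum(exp(lg - mx)))
}

#' Impact of a regulated gene set on a differential-expression set
#'
#' The impact score is `R = n_e / n_t`: the fraction of a factor's
#' regulated genes (`n_t` of them) that are also differentially expressed
#' in the given direction (`n_e` overlapping genes). Its significance is
#' the hypergeometric tail `P(X >= n_e)` with the regulated genes as the
#' marked set and the DE set as the draw.
#'
#' @param regulated character vector of regulated gene ids.
#' @param de_set character vector of DE gene ids (one direction).
#' @param universe character vector of all eligible genes; both sets must
#'   be subsets of it.
#' @return A list with `R`, `p` and `n_e`. An empty regulated set returns
#'   `R = 0, p = 1` with a warning.
#' @export
impact_score <- function(regulated, de_set, universe) {
  regulated <- unique(regulated); de_set <- unique(de_set)
  universe <- unique(universe)
  bad <- setdiff(c(regulated, de_set), universe)
  if (length(bad))
    stop_validation("genes outside the universe: %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  if (!length(regulated)) {
    warning("empty regulated set; returning R = 0, p = 1")
    return(list(R = 0, p = 1, n_e = 0L))
  }
  n_e <- length(intersect(regulated, de_set))
  list(R = n_e / length(regulated),
       p = hypergeom_tail(length(universe), length(regulated),
                          length(de_set), n_e),
       n_e = n_e)
}

# Union of two replicate peak sets of the same factor.
merge_peaksets <- function(ps_list) {
  df <- do.call(rbind, lapply(ps_list, as.data.frame))
  PeakSet(df$chrom, df$start, df$end, summit = df$summit, score = df$score,
          q_value = df$q_value, tf_name = attr(ps_list[[1]], "tf_name"),
          replicate = "merged")
}

#' Scan TF impact over a grid of distances and set sizes
#'
#' For every peak set (factor x replicate), distance cutoff `D` and set
#' size `N`: computes regulatory potentials, takes the top-`N` regulated
#' genes, and scores their overlap with the up- and down-regulated sets.
#' Replicates are scored independently by default so reproducibility
#' across replicates is visible in the output.
#'
#' @param tf_peaksets list of [PeakSet]s.
#' @param ann a [GenomeAnnotation].
#' @param up,down disjoint character vectors of DE gene ids.
#' @param Ns regulated-set sizes (default `c(100, 200, 500, 800)`).
#' @param Ds distance cutoffs in bp (default
#'   `c(1000, 3000, 5000, 10000)`).
#' @param p_threshold per-cell significance flag threshold (default
#'   0.001); no correction is applied across the grid (set
#'   `bh_across_grid = TRUE` to flag on BH-adjusted grid p-values
#'   instead).
#' @param tested_genes optional character vector of genes actually tested
#'   for differential expression; the hypergeometric universe is the
#'   annotation intersected with these (default: all annotation genes).
#' @param min_score strict `S_g` floor passed to [top_genes].
#' @param merge_replicates `"none"` (default) or `"union"` to pool each
#'   factor's replicates into one merged peak set first.
#' @param bh_across_grid flag significance on BH-adjusted p-values across
#'   all grid cells (off by default).
#' @return An `ImpactResult` `data.frame` with one row per
#'   (tf_name, replicate, cutoff_D, set_size_N) and columns `n_t`,
#'   `n_e_up`, `n_e_down`, `R_up`, `R_down`, `p_up`, `p_down`,
#'   `significant_up`, `significant_down`.
#' @export
scan_impact <- function(tf_peaksets, ann, up, down,
                        Ns = c(100L, 200L, 500L, 800L),
                        Ds = c(1000L, 3000L, 5000L, 10000L),
                        p_threshold = 0.001, tested_genes = NULL,
                        min_score = 0, merge_replicates = c("none", "union"),
                        bh_across_grid = FALSE) {
  merge_replicates <- match.arg(merge_replicates)
  if (length(intersect(up, down)))
    stop_validation("up and down sets must be disjoint")
  universe <- ann$gene_id
  if (!is.null(tested_genes)) universe <- intersect(universe, tested_genes)
  bad <- setdiff(c(up, down), universe)
  if (length(bad))
    stop_validation("DE genes outside the universe: %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  if (merge_replicates == "union") {
    tfs <- vapply(tf_peaksets, attr, "", "tf_name")
    tf_peaksets <- lapply(split(tf_peaksets, tfs), merge_peaksets)
  }
  rows <- vector("list", length(tf_peaksets) * length(Ds) * length(Ns))
  ri <- 0L
  for (ps in tf_peaksets) {
    for (D in Ds) {
      rp <- regulatory_potential(ps, ann, D)
      for (N in Ns) {
        tg <- top_genes(rp, N, min_score)
        reg <- intersect(tg$genes, universe)
        iu <- if (length(reg)) impact_score(reg, up, universe) else
          list(R = 0, p = 1, n_e = 0L)
        id <- if (length(reg)) impact_score(reg, down, universe) else
          list(R = 0, p = 1, n_e = 0L)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          tf_name = attr(ps, "tf_name"), replicate = attr(ps, "replicate"),
          cutoff_D = as.integer(D), set_size_N = as.integer(N),
          n_t = length(reg), n_e_up = iu$n_e, n_e_down = id$n_e,
          R_up = iu$R, R_down = id$R, p_up = iu$p, p_down = id$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows[seq_len(ri)])
  if (bh_across_grid) {
    res$significant_up <- bh_adjust(res$p_up) < p_threshold
    res$significant_down <- bh_adjust(res$p_down) < p_threshold
  } else {
    res$significant_up <- res$p_up < p_threshold
    res$significant_down <- res$p_down < p_threshold
  }
  class(res) <- c("ImpactResult", "data.frame")
  res
}

#' Rank factors within each grid cell
#'
#' Orders the factors in every (cutoff_D, set_size_N) cell by descending
#' `R_down`, then ascending `p_down`, then factor name — the ordering used
#' to call the top factor.
#'
#' @param results an `ImpactResult` from [scan_impact].
#' @return The same table with a `rank` column, sorted within cells.
#' @export
rank_impact <- function(results) {
  o <- order(results$cutoff_D, results$set_size_N, -results$R_down,
             results$p_down, results$tf_name, method = "radix")
  res <- results[o, , drop = FALSE]
  cell <- paste(res$cutoff_D, res$set_size_N, res$replicate)
  res$rank <- stats::ave(seq_len(nrow(res)), cell, FUN = seq_along)
  rownames(res) <- NULL
  res
}

#' Top factor by mean down-impact on the N = 200 set
#'
#' Averages `R_down` across replicates at `set_size_N = 200` (or the
#' closest available N) and the given distance cutoffs, and returns the
#' factor with the highest mean, ties broken by smaller mean `p_down`
#' then name.
#'
#' @param results an `ImpactResult`.
#' @param N set size to use (default 200).
#' @return A one-row `data.frame` with `tf_name`, `mean_R_down`,
#'   `mean_p_down`.
#' @export
top_tf <- function(results, N = 200L) {
  if (!N %in% results$set_size_N)
    N <- results$set_size_N[which.min(abs(results$set_size_N - N))]
  sub <- results[results$set_size_N == N, , drop = FALSE]
  agg <- stats::aggregate(cbind(R_down, p_down) ~ tf_name, data = sub, FUN = mean)
  agg <- agg[order(-agg$R_down, agg$p_down, agg$tf_name), , drop = FALSE]
  data.frame(tf_name = agg$tf_name[1], mean_R_down = agg$R_down[1],
             mean_p_down = agg$p_down[1], set_size_N = as.integer(N),
             stringsAsFactors = FALSE)
}
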