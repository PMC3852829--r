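#' Drop genes with low variability across samples
#'
#' Removes genes whose across-sample standard deviation (n - 1
#' denominator) is below `min_sd`, mirroring the usual pre-filter before
#' two-group testing on log-scale intensities.
#'
#' @param m an [ExpressionMatrix].
#' @param min_sd minimum standard deviation to keep a gene (log2 units).
#' @return The filtered [ExpressionMatrix]; gene order preserved.
#' @export
filter_low_variability <- function(m, min_sd = 0.1) {
  if (min_sd < 0) stop_domain("min_sd must be non-negative")
  x <- m$values
  mu <- rowMeans(x)
  sds <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  keep <- sds >= min_sd
  if (!any(keep))
    stop_validation("low-variability filter removed every gene (min_sd = %g)", min_sd)
  ExpressionMatrix(x[keep, , drop = FALSE], m$groups)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: with `m` p-values sorted ascending,
#' `adj_(i) = min_(j >= i) m * p_(j) / j`, capped at 1, returned in the
#' original input order.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!(p > 0 & p <= 1)) || anyNA(p))
    stop_domain("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  adj[order(o)]
}

#' Two-group differential expression (Welch t-test)
#'
#' Per-gene two-sided Welch unequal-variance t-test of treatment against
#' control with `log2_fc = mean(treatment) - mean(control)`, followed by
#' Benjamini-Hochberg adjustment across all tested genes. This is a
#' transparent stand-in for a moderated-statistic engine such as limma;
#' externally computed up/down lists can be injected downstream instead
#' (see [scan_impact]). Genes with zero variance in both groups and equal
#' means get p = 1 by convention; zero variance with unequal means gets
#' the smallest representable p.
#'
#' @param m an [ExpressionMatrix]; both groups need >= 2 samples.
#' @param alpha significance level used only to label the `direction`
#'   column (default 0.01).
#' @return A `DEResult` `data.frame` with columns `gene_id`, `log2_fc`,
#'   `p_value`, `adj_p`, `direction` (`up`/`down`/`ns`).
#' @export
differential_expression <- function(m, alpha = 0.01) {
  x <- m$values
  ctl <- x[, m$groups == "control", drop = FALSE]
  trt <- x[, m$groups == "treatment", drop = FALSE]
  n1 <- ncol(ctl); n2 <- ncol(trt)
  if (n1 < 2 || n2 < 2) stop_validation("both groups need at least 2 samples")
  m1 <- rowMeans(ctl); m2 <- rowMeans(trt)
  v1 <- rowSums((ctl - m1)^2) / (n1 - 1)
  v2 <- rowSums((trt - m2)^2) / (n2 - 1)
  fc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tt <- fc / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0 & fc == 0] <- 1
  p[se2 == 0 & fc != 0] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)  # keep within (0, 1] for BH
  adj <- bh_adjust(p)
  direction <- rep("ns", length(p))
  direction[adj < alpha & fc > 0] <- "up"
  direction[adj < alpha & fc < 0] <- "down"
  res <- data.frame(gene_id = rownames(x), log2_fc = fc, p_value = p,
                    adj_p = adj, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Up- and down-regulated gene sets
#'
#' @param results a `DEResult` from [differential_expression].
#' @param alpha strict threshold on the adjusted p-value (default 0.01).
#' @return A list with character vectors `up` (`adj_p < alpha`,
#'   `log2_fc > 0`) and `down` (`adj_p < alpha`, `log2_fc < 0`); always
#'   disjoint.
#' @export
de_gene_sets <- function(results, alpha = 0.01) {
  if (!(alpha > 0 && alpha < 1)) stop_domain("alpha must be in (0, 1)")
  sig <- results$adj_p < alpha
  list(up = results$gene_id[sig & results$log2_fc > 0],
       down = results$gene_id[sig & results$log2_fc < 0])
}
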