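#' Stage 1: categories enriched among regulated genes
#'
#' Hypergeometric enrichment of each functional category among a factor's
#' regulated genes, BH-adjusted across all tested categories. This is a
#' gene-based stand-in for region-based tools: the category membership in
#' the universe is the marked set and the regulated genes are the draw.
#'
#' @param regulated character vector of regulated gene ids.
#' @param categories a [FunctionalCategorySet].
#' @param universe character vector of all eligible gene ids
#'   (`regulated` must be a subset).
#' @return A `data.frame` with one row per testable category:
#'   `category_id`, `name`, `cat_size` (members in the universe),
#'   `overlap` (members regulated), `p_reg`, `adj_p_reg`. Categories with
#'   no gene in the universe are skipped with a warning.
#' @export
enrich_regulated <- function(regulated, categories, universe) {
  universe <- unique(universe)
  regulated <- unique(regulated)
  bad <- setdiff(regulated, universe)
  if (length(bad))
    stop_validation("regulated genes outside the universe: %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  in_univ <- lapply(categories, function(cc) intersect(cc$genes, universe))
  empty <- vapply(in_univ, length, 1L) == 0L
  if (any(empty)) {
    warning(sprintf("skipping %d categor%s with no genes in the universe",
                    sum(empty), if (sum(empty) == 1) "y" else "ies"))
    categories <- categories[!empty]
    in_univ <- in_univ[!empty]
  }
  if (!length(categories))
    return(data.frame(category_id = character(), name = character(),
                      cat_size = integer(), overlap = integer(),
                      p_reg = numeric(), adj_p_reg = numeric()))
  N <- length(universe); n <- length(regulated)
  cat_size <- vapply(in_univ, length, 1L)
  overlap <- vapply(in_univ, function(g) length(intersect(g, regulated)), 1L)
  p <- mapply(function(M, x) hypergeom_tail(N, M, n, x), cat_size, overlap)
  data.frame(category_id = vapply(categories, `[[`, "", "category_id"),
             name = vapply(categories, `[[`, "", "name"),
             cat_size = unname(cat_size), overlap = unname(overlap),
             p_reg = unname(p), adj_p_reg = bh_adjust(unname(p)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stage 2: cross-enrichment of DE genes within regulated categories
#'
#' For every category surviving stage 1 (`adj_p_reg < alpha`), tests
#' whether the up- or down-regulated DE genes are over-represented among
#' the category's *regulated* members: the marked set is
#' `M_cat = |regulated ∩ category|` and the success count is
#' `x_dir = |regulated ∩ category ∩ dir|`, drawn `|dir|` times from the
#' universe. BH adjustment per direction runs over the stage-1 survivors
#' only. A category is flagged transition-related in a direction when both
#' its stage-1 and that direction's stage-2 adjusted p fall below `alpha`.
#'
#' @param stage1 output of [enrich_regulated].
#' @param regulated,up,down character gene-id vectors.
#' @param categories the [FunctionalCategorySet] used in stage 1.
#' @param universe character vector of all eligible gene ids.
#' @param alpha threshold for both stages (default 0.05).
#' @return An `EnrichmentResult` `data.frame` with one row per stage-1
#'   category: `category_id`, `name`, `M_cat`, `x_up`, `x_down`, `p_reg`,
#'   `adj_p_reg`, `p_up`, `p_down`, `adj_p_up`, `adj_p_down`,
#'   `emt_related_up`, `emt_related_down` (stage-2 fields `NA` for
#'   non-survivors).
#' @export
cross_enrichment <- function(stage1, regulated, up, down, categories,
                             universe, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop_domain("alpha must be in (0, 1)")
  universe <- unique(universe); regulated <- unique(regulated)
  up <- unique(up); down <- unique(down)
  N <- length(universe)
  res <- stage1[, c("category_id", "name", "p_reg", "adj_p_reg")]
  genes_by_id <- stats::setNames(lapply(categories, `[[`, "genes"),
                                 vapply(categories, `[[`, "", "category_id"))
  reg_in_cat <- lapply(genes_by_id[res$category_id],
                       function(g) intersect(g, regulated))
  res$M_cat <- vapply(reg_in_cat, length, 1L)
  res$x_up <- vapply(reg_in_cat, function(g) length(intersect(g, up)), 1L)
  res$x_down <- vapply(reg_in_cat, function(g) length(intersect(g, down)), 1L)
  surv <- res$adj_p_reg < alpha
  res$p_up <- res$p_down <- res$adj_p_up <- res$adj_p_down <- NA_real_
  if (any(surv)) {
    res$p_up[surv] <- mapply(function(M, x) hypergeom_tail(N, M, length(up), x),
                             res$M_cat[surv], res$x_up[surv])
    res$p_down[surv] <- mapply(function(M, x) hypergeom_tail(N, M, length(down), x),
                               res$M_cat[surv], res$x_down[surv])
    res$adj_p_up[surv] <- bh_adjust(res$p_up[surv])
    res$adj_p_down[surv] <- bh_adjust(res$p_down[surv])
  }
  res$emt_related_up <- surv & !is.na(res$adj_p_up) & res$adj_p_up < alpha
  res$emt_related_down <- surv & !is.na(res$adj_p_down) & res$adj_p_down < alpha
  res <- res[, c("category_id", "name", "M_cat", "x_up", "x_down",
                 "p_reg", "adj_p_reg", "p_up", "p_down", "adj_p_up",
                 "adj_p_down", "emt_related_up", "emt_related_down")]
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}
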