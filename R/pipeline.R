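#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline]. Inputs
#' come either from a simulation (`simulate = TRUE`, with `sim` a
#' [simulation_config]) or from files: `annotation` (TSV), a peak
#' `manifest` (TSV with columns `tf_name`, `replicate`, `path`,
#' `dialect`), and either `matrix` + `groups` or precomputed `up_list` /
#' `down_list` files; `gmt` supplies the functional categories.
#'
#' @param outdir output directory.
#' @param simulate generate inputs with the synthetic module first.
#' @param sim a [simulation_config] (when `simulate`).
#' @param annotation,manifest,matrix,groups,up_list,down_list,gmt input
#'   file paths (when not simulating; `gmt` optional either way).
#' @param Ns,Ds impact-scan grid.
#' @param alpha_de,alpha_enrich,p_threshold significance thresholds.
#' @param min_sd low-variability filter threshold (log2 units).
#' @param min_score strict regulatory-potential floor for top-gene sets.
#' @param qmax optional strict q-value filter applied to every peak set.
#' @param seed RNG seed (also used as the simulation seed).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(outdir, simulate = FALSE, sim = NULL,
                            annotation = NULL, manifest = NULL,
                            matrix = NULL, groups = NULL, up_list = NULL,
                            down_list = NULL, gmt = NULL,
                            Ns = c(100L, 200L, 500L, 800L),
                            Ds = c(1000L, 3000L, 5000L, 10000L),
                            alpha_de = 0.01, alpha_enrich = 0.05,
                            p_threshold = 0.001, min_sd = 0.1,
                            min_score = 0, qmax = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (simulate) {
    if (is.null(cfg$sim)) cfg$sim <- simulation_config(seed = seed)
  } else {
    for (f in c("annotation", "manifest")) {
      if (is.null(cfg[[f]])) stop_config("config needs '%s' unless simulating", f)
      if (!file.exists(cfg[[f]])) stop_config("%s file not found: %s", f, cfg[[f]])
    }
    have_matrix <- !is.null(cfg$matrix)
    have_lists <- !is.null(cfg$up_list) && !is.null(cfg$down_list)
    if (!have_matrix && !have_lists)
      stop_config("config needs either 'matrix'+'groups' or 'up_list'+'down_list'")
    for (f in c("matrix", "groups", "up_list", "down_list", "gmt"))
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        stop_config("%s file not found: %s", f, cfg[[f]])
  }
  structure(cfg, class = "PipelineConfig")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file whose keys match [pipeline_config] arguments
#'   (`sim` may be an object of [simulation_config] arguments).
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- do.call(simulation_config, as.list(raw$sim))
  do.call(pipeline_config, raw)
}

read_manifest_peaksets <- function(manifest_path, qmax = NULL) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("tf_name", "replicate", "path", "dialect")
  if (!all(need %in% names(man)))
    stop_parse("manifest must have columns %s", paste(need, collapse = ", "))
  ps <- Map(read_peaks, man$path, man$dialect, man$tf_name, man$replicate)
  names(ps) <- paste(man$tf_name, man$replicate, sep = ".")
  if (!is.null(qmax)) ps <- lapply(ps, filter_by_q, q_max = qmax)
  ps
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[tfimpact:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the whole pipeline
#'
#' Orchestrates (optional) simulation, differential expression, the
#' impact scan, and the two-stage functional enrichment of the top
#' factor's regulated genes; writes per-stage TSVs and a machine-readable
#' `report.json` into `config$outdir`.
#'
#' The report's "top factor" is the factor with the highest `R_down` on
#' the N = 200 set averaged over replicates (ties by `p_down`, then
#' name). Its regulated set for enrichment is the top 200 genes of the
#' replicate-union regulatory potential at the largest scanned distance.
#'
#' @param config a `PipelineConfig` (or path to a JSON one).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs ---------------------------------------------------------
  if (isTRUE(config$simulate)) {
    log_stage("simulate", "seed %d, %d genes, %d TFs",
              config$sim$seed, config$sim$n_genes, config$sim$n_tfs)
    sim <- simulate_dataset(config$sim, file.path(config$outdir, "sim"))
    ann <- sim$annotation
    peaksets <- sim$peaks
    expr <- sim$expression
    cats <- sim$categories
    up_list <- down_list <- NULL
  } else {
    ann <- read_gene_annotation(config$annotation, "tsv")
    peaksets <- read_manifest_peaksets(config$manifest, config$qmax)
    expr <- if (!is.null(config$matrix))
      read_expression_matrix(config$matrix, config$groups) else NULL
    cats <- if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL
    up_list <- if (!is.null(config$up_list)) read_gene_list(config$up_list)
    down_list <- if (!is.null(config$down_list)) read_gene_list(config$down_list)
  }
  log_stage("inputs", "%d genes, %d peak sets", nrow(ann), length(peaksets))

  # --- differential expression ---------------------------------------
  if (!is.null(up_list)) {
    up <- up_list; down <- setdiff(down_list, up_list)
    tested <- NULL
    log_stage("de", "using injected lists: %d up, %d down", length(up), length(down))
  } else {
    kept <- filter_low_variability(expr, config$min_sd)
    de <- differential_expression(kept, config$alpha_de)
    write_table(de, file.path(config$outdir, "de.tsv"))
    sets <- de_gene_sets(de, config$alpha_de)
    up <- sets$up; down <- sets$down
    tested <- de$gene_id
    log_stage("de", "%d genes tested (of %d), %d up, %d down at adj p < %g",
              nrow(de), nrow(expr$values), length(up), length(down),
              config$alpha_de)
  }

  # --- impact scan ----------------------------------------------------
  impact <- scan_impact(peaksets, ann, up, down, Ns = config$Ns,
                        Ds = config$Ds, p_threshold = config$p_threshold,
                        tested_genes = tested, min_score = config$min_score)
  ranked <- rank_impact(impact)
  write_table(ranked, file.path(config$outdir, "impact.tsv"),
              sort_by = c("cutoff_D", "set_size_N", "rank", "replicate"))
  log_stage("scan", "%d grid cells over %d TFs", nrow(impact),
            length(unique(impact$tf_name)))
  best <- top_tf(impact, 200L)

  # --- enrichment of the top factor's regulated genes -----------------
  enrich <- NULL
  if (!is.null(cats)) {
    universe <- if (is.null(tested)) ann$gene_id else intersect(ann$gene_id, tested)
    sel <- peaksets[vapply(peaksets, attr, "", "tf_name") == best$tf_name]
    rp <- regulatory_potential(merge_peaksets(sel), ann, max(config$Ds))
    regulated <- intersect(top_genes(rp, 200L, config$min_score)$genes, universe)
    stage1 <- enrich_regulated(regulated, cats, universe)
    enrich <- cross_enrichment(stage1, regulated, intersect(up, universe),
                               intersect(down, universe), cats, universe,
                               config$alpha_enrich)
    write_table(enrich, file.path(config$outdir, "enrich.tsv"))
    log_stage("enrich", "%d categories, %d flagged down-related",
              nrow(enrich), sum(enrich$emt_related_down))
  }

  # --- report ---------------------------------------------------------
  cells <- ranked[ranked$rank == 1,
                  c("cutoff_D", "set_size_N", "replicate", "tf_name",
                    "R_down", "p_down")]
  report <- list(
    parameters = list(Ns = config$Ns, Ds = config$Ds,
                      alpha_de = config$alpha_de,
                      alpha_enrich = config$alpha_enrich,
                      p_threshold = config$p_threshold,
                      min_sd = config$min_sd, min_score = config$min_score,
                      seed = config$seed,
                      grid_cells = nrow(impact)),
    n_up = length(up), n_down = length(down),
    top_per_cell = cells,
    top_tf = as.list(best),
    emt_related_down = if (!is.null(enrich))
      enrich$category_id[enrich$emt_related_down] else character(),
    emt_related_up = if (!is.null(enrich))
      enrich$category_id[enrich$emt_related_up] else character())
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
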