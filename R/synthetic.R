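# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Parameters of the synthetic regulatory-genomics world: one chromosome
#' of `chrom_length` bp carrying `n_genes` well-spaced genes; `n_tfs`
#' factors with two ChIP replicates each, one of which (`planted_tf`)
#' binds next to `n_target_genes` target genes with anchors scattered
#' `Normal(tss, proximity_sd)`; a two-group log2 expression matrix
#' (`n_control` vs `n_treatment` samples) in which a `frac_targets_down`
#' share of the targets is knocked down by `effect_size` log2 units in
#' treatment and an equally sized disjoint set of non-target genes goes
#' up; and `n_categories` GMT gene sets, one of which is loaded with
#' planted targets. The seed fully determines every output.
#'
#' The defaults emulate a mid-sized ChIP + microarray study: 6 vs 9
#' samples as in a multi-timepoint induction design collapsed to
#' early/late groups, a 1.5 log2-unit knockdown against 0.5 log2 units of
#' noise, and ~2000 background peaks per factor on a 100 Mb chromosome.
#'
#' @param seed integer RNG seed.
#' @param n_genes,chrom_length,min_spacing gene count, chromosome length
#'   and minimum TSS spacing (bp).
#' @param n_tfs,planted_tf,n_target_genes factor count, which factor
#'   carries signal, and how many genes it targets.
#' @param proximity_sd bp scatter of planted peak anchors around target
#'   TSSs.
#' @param background_peaks_per_tf uniform background peaks per replicate.
#' @param peak_width width of simulated peaks (bp).
#' @param q_value_range log-uniform range for decorative peak q-values.
#' @param planted_q when `TRUE`, planted peaks get q = 1e-12 so they
#'   survive a strict `q < 1e-10` consensus filter.
#' @param n_control,n_treatment group sizes.
#' @param baseline_mean,baseline_sd per-gene baseline distribution (log2).
#' @param effect_size planted group effect (log2 units).
#' @param frac_targets_down share of targets planted down (the rest of the
#'   DE signal is an equal number of planted-up non-targets).
#' @param noise_sd residual noise sd (log2 units).
#' @param n_categories,planted_category_overlap GMT category count and the
#'   share of planted targets placed into the planted category.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 1000L, chrom_length = 1e8,
                              min_spacing = 25000L, n_tfs = 8L,
                              planted_tf = "TF1", n_target_genes = 200L,
                              proximity_sd = 300, background_peaks_per_tf = 2000L,
                              peak_width = 200L, q_value_range = c(1e-30, 0.5),
                              planted_q = FALSE, n_control = 6L,
                              n_treatment = 9L, baseline_mean = 8,
                              baseline_sd = 1.5, effect_size = 1.5,
                              frac_targets_down = 0.7, noise_sd = 0.5,
                              n_categories = 50L,
                              planted_category_overlap = 0.8) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_genes, cfg$n_tfs, cfg$n_target_genes, cfg$n_control,
              cfg$n_treatment, cfg$n_categories, cfg$peak_width)
  if (any(counts < 1)) stop_config("all counts must be positive")
  if (cfg$background_peaks_per_tf < 0)
    stop_config("background_peaks_per_tf must be non-negative")
  if (cfg$frac_targets_down < 0 || cfg$frac_targets_down > 1 ||
      cfg$planted_category_overlap < 0 || cfg$planted_category_overlap > 1)
    stop_config("fractions must lie in [0, 1]")
  if (cfg$n_target_genes > cfg$n_genes)
    stop_config("n_target_genes cannot exceed n_genes")
  if (!(cfg$q_value_range[1] > 0 && cfg$q_value_range[2] <= 1 &&
        cfg$q_value_range[1] <= cfg$q_value_range[2]))
    stop_config("q_value_range must be an increasing pair in (0, 1]")
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a gene annotation
#'
#' Places `n_genes` TSSs uniformly at random on one chromosome with at
#' least `min_spacing` bp between consecutive TSSs, random strands.
#'
#' @param cfg a [simulation_config].
#' @return A [GenomeAnnotation] on chromosome `"chr1"`.
#' @export
simulate_annotation <- function(cfg) {
  n <- cfg$n_genes; s <- cfg$min_spacing
  free <- cfg$chrom_length - (n - 1) * s
  if (free < n)
    stop_config("cannot place %d genes %d bp apart on %g bp", n, s, cfg$chrom_length)
  with_seed(cfg$seed + 101L, {
    tss <- sort(sample.int(free, n) - 1L) + (seq_len(n) - 1L) * s
    strand <- sample(c("+", "-"), n, replace = TRUE)
    GenomeAnnotation(sprintf("g%04d", seq_len(n)), "chr1", strand, tss,
                     chrom_sizes = c(chr1 = cfg$chrom_length))
  })
}

#' Planted truth of a simulation
#'
#' Deterministically derives (from the seed alone) which genes are the
#' planted factor's targets, which of those are planted down, and which
#' disjoint non-target genes are planted up.
#'
#' @param cfg a [simulation_config].
#' @param ann the matching [simulate_annotation] output.
#' @return A list with `planted_tf`, `targets`, `planted_down`,
#'   `planted_up`.
#' @export
simulation_truth <- function(cfg, ann) {
  with_seed(cfg$seed + 202L, {
    targets <- sort(sample(ann$gene_id, cfg$n_target_genes))
    n_down <- round(cfg$frac_targets_down * cfg$n_target_genes)
    planted_down <- sort(sample(targets, n_down))
    planted_up <- sort(sample(setdiff(ann$gene_id, targets), n_down))
    list(planted_tf = cfg$planted_tf, targets = targets,
         planted_down = planted_down, planted_up = planted_up)
  })
}

#' Simulate peak sets (two replicates per factor)
#'
#' The planted factor gets one peak per target gene per replicate, with
#' the anchor drawn `Normal(tss, proximity_sd)` (independently redrawn in
#' replicate 2) and the summit at the anchor, plus uniform background
#' peaks; all other factors get background only. Q-values are log-uniform
#' in `q_value_range` (and 1e-12 for planted peaks when `planted_q`).
#'
#' @param cfg a [simulation_config].
#' @param ann the matching annotation.
#' @return A list of `2 * n_tfs` [PeakSet]s named `"TFi.rep"`.
#' @export
simulate_peaks <- function(cfg, ann) {
  truth <- simulation_truth(cfg, ann)
  L <- cfg$chrom_length; w <- cfg$peak_width
  tss_of <- stats::setNames(ann$tss, ann$gene_id)
  out <- list()
  for (ti in seq_len(cfg$n_tfs)) {
    tf <- sprintf("TF%d", ti)
    for (rep_i in 1:2) {
      out[[paste0(tf, ".rep", rep_i)]] <- with_seed(
        cfg$seed + 1000L + 17L * ti + rep_i, {
          anchors <- sample.int(L, cfg$background_peaks_per_tf) - 1L
          planted <- logical(length(anchors))
          if (tf == cfg$planted_tf) {
            pa <- round(stats::rnorm(length(truth$targets),
                                     tss_of[truth$targets], cfg$proximity_sd))
            pa <- pmin(pmax(pa, 0), L - 1)
            anchors <- c(anchors, pa)
            planted <- c(planted, rep(TRUE, length(pa)))
          }
          start <- pmax(0, anchors - w %/% 2)
          end <- pmin(L, start + w)
          start <- pmin(start, end - 1)
          q <- 10^stats::runif(length(anchors), log10(cfg$q_value_range[1]),
                               log10(cfg$q_value_range[2]))
          if (cfg$planted_q) q[planted] <- 1e-12
          o <- order(start, end)
          PeakSet("chr1", start[o], end[o], summit = anchors[o],
                  score = round(stats::runif(length(anchors), 0, 1000))[o],
                  q_value = q[o], tf_name = tf,
                  replicate = paste0("rep", rep_i))
        })
    }
  }
  out
}

#' Simulate a two-group expression matrix
#'
#' `value = baseline_g + effect_g * is_treatment + Normal(0, noise_sd)`,
#' with `baseline_g ~ Normal(baseline_mean, baseline_sd)` and `effect_g`
#' equal to `-effect_size` for planted-down targets, `+effect_size` for
#' planted-up genes and 0 otherwise.
#'
#' @param cfg a [simulation_config].
#' @param ann the matching annotation.
#' @return An [ExpressionMatrix] with samples `C1..` and `T1..`.
#' @export
simulate_expression <- function(cfg, ann) {
  truth <- simulation_truth(cfg, ann)
  n <- nrow(ann)
  samples <- c(paste0("C", seq_len(cfg$n_control)),
               paste0("T", seq_len(cfg$n_treatment)))
  groups <- stats::setNames(rep(c("control", "treatment"),
                                c(cfg$n_control, cfg$n_treatment)), samples)
  with_seed(cfg$seed + 303L, {
    baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    eff <- numeric(n)
    eff[ann$gene_id %in% truth$planted_down] <- -cfg$effect_size
    eff[ann$gene_id %in% truth$planted_up] <- cfg$effect_size
    m <- baseline +
      outer(eff, as.numeric(groups == "treatment")) +
      matrix(stats::rnorm(n * length(samples), 0, cfg$noise_sd), n)
    dimnames(m) <- list(ann$gene_id, samples)
    ExpressionMatrix(m, groups)
  })
}

#' Simulate functional categories
#'
#' One planted category holds a `planted_category_overlap` share of the
#' planted factor's targets plus ~25% random non-target fill; the
#' remaining categories are uniform draws with sizes in 10-200.
#'
#' @param cfg a [simulation_config].
#' @param ann the matching annotation.
#' @return A [FunctionalCategorySet]; the planted category id is
#'   `"cat_planted"`.
#' @export
simulate_categories <- function(cfg, ann) {
  truth <- simulation_truth(cfg, ann)
  with_seed(cfg$seed + 404L, {
    n_in <- round(cfg$planted_category_overlap * length(truth$targets))
    members <- if (n_in > 0) sample(truth$targets, n_in) else character()
    fill <- sample(setdiff(ann$gene_id, truth$targets),
                   max(1L, round(0.25 * max(n_in, 10L))))
    ids <- c("cat_planted", sprintf("cat%03d", seq_len(cfg$n_categories - 1L)))
    nms <- c("planted target category",
             sprintf("random category %d", seq_len(cfg$n_categories - 1L)))
    genes <- c(list(c(members, fill)),
               lapply(seq_len(cfg$n_categories - 1L), function(i)
                 sample(ann$gene_id, sample(10:200, 1))))
    FunctionalCategorySet(ids, nms, genes)
  })
}

#' Write a complete simulated dataset to disk
#'
#' Emits `genes.tsv`, one narrowPeak per factor/replicate, `expr.tsv`,
#' `groups.tsv`, `categories.gmt`, a peak manifest `manifest.tsv` and
#' `truth.json` (the planted assignments, for test harnesses).
#'
#' @param cfg a [simulation_config].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_dataset <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(cfg)
  truth <- simulation_truth(cfg, ann)
  peaks <- simulate_peaks(cfg, ann)
  expr <- simulate_expression(cfg, ann)
  cats <- simulate_categories(cfg, ann)
  p <- function(f) file.path(outdir, f)
  utils::write.table(as.data.frame(ann)[c("gene_id", "chrom", "strand", "tss")],
                     p("genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(tf_name = character(), replicate = character(),
                         path = character(), dialect = character())
  for (nm in names(peaks)) {
    f <- p(paste0(nm, ".narrowPeak"))
    write_narrowpeak(peaks[[nm]], f)
    manifest <- rbind(manifest, data.frame(
      tf_name = attr(peaks[[nm]], "tf_name"),
      replicate = attr(peaks[[nm]], "replicate"),
      path = f, dialect = "narrowPeak"))
  }
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression_matrix(expr, p("expr.tsv"), p("groups.tsv"))
  write_gmt(cats, p("categories.gmt"))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(annotation = ann, truth = truth, peaks = peaks,
                 expression = expr, categories = cats, outdir = outdir,
                 manifest = p("manifest.tsv")))
}
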