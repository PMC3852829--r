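small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 300, n_tfs = 3, n_target_genes = 60,
         background_peaks_per_tf = 500, n_categories = 10),
    list(...))
  do.call(simulation_config, args)
}

test_that("config validation rejects impossible worlds", {
  expect_error(simulation_config(n_genes = 0), class = "tfimpact_config_error")
  expect_error(simulation_config(frac_targets_down = 1.2),
               class = "tfimpact_config_error")
  expect_error(simulation_config(n_target_genes = 50, n_genes = 10),
               class = "tfimpact_config_error")
  expect_error(simulation_config(q_value_range = c(0, 1)),
               class = "tfimpact_config_error")
  expect_error(simulate_annotation(simulation_config(n_genes = 5000,
                                                     chrom_length = 1e6)),
               class = "tfimpact_config_error")
})

test_that("simulated annotation is spaced, stranded and seed-determined", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 300L)
  expect_false(anyDuplicated(ann$gene_id) > 0)
  expect_true(all(diff(sort(ann$tss)) >= cfg$min_spacing))
  expect_true(all(ann$tss >= 0 & ann$tss < cfg$chrom_length))
  expect_identical(simulate_annotation(cfg), ann)           # same seed
  ann2 <- simulate_annotation(small_cfg(seed = 2))
  expect_false(identical(ann2$tss, ann$tss))                # different seed
})

test_that("planted peaks sit near target TSSs, others are background", {
  cfg <- small_cfg(proximity_sd = 200)
  ann <- simulate_annotation(cfg)
  truth <- simulation_truth(cfg, ann)
  peaks <- simulate_peaks(cfg, ann)
  expect_length(peaks, 2L * cfg$n_tfs)
  rp <- regulatory_potential(peaks[["TF1.rep1"]], ann, 1000L)
  expect_true(all(rp$k[rp$gene_id %in% truth$targets] >= 1L))
  # replicate 2 redraws anchors but keeps the same targets
  p1 <- peaks[["TF1.rep1"]]; p2 <- peaks[["TF1.rep2"]]
  expect_false(identical(p1$summit, p2$summit))
  rp2 <- regulatory_potential(p2, ann, 1000L)
  expect_true(all(rp2$k[rp2$gene_id %in% truth$targets] >= 1L))
  # q-values live in the configured range
  for (ps in peaks)
    expect_true(all(ps$q_value >= cfg$q_value_range[1] &
                    ps$q_value <= cfg$q_value_range[2]))
})

test_that("background-only factors have near-TSS peak counts at chance level", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  D <- 1000L
  rp <- regulatory_potential(simulate_peaks(cfg, ann)[["TF2.rep1"]], ann, D)
  lambda <- cfg$background_peaks_per_tf * (2 * D + 1) * nrow(ann) /
    cfg$chrom_length
  expect_lt(abs(sum(rp$k) - lambda), 3 * sqrt(lambda) + 1)
})

test_that("empty background leaves planted peaks only", {
  cfg <- small_cfg(background_peaks_per_tf = 0)
  ann <- simulate_annotation(cfg)
  peaks <- simulate_peaks(cfg, ann)
  expect_equal(nrow(peaks[["TF1.rep1"]]), cfg$n_target_genes)
  expect_equal(nrow(peaks[["TF2.rep1"]]), 0L)
})

test_that("planted_q makes planted peaks pass the strict consensus filter", {
  cfg <- small_cfg(planted_q = TRUE, q_value_range = c(1e-9, 0.5),
                   background_peaks_per_tf = 50)
  ann <- simulate_annotation(cfg)
  ps <- simulate_peaks(cfg, ann)[["TF1.rep1"]]
  kept <- filter_by_q(ps, 1e-10)
  expect_equal(nrow(kept), cfg$n_target_genes)
})

test_that("expression matrix encodes the planted effects", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  truth <- simulation_truth(cfg, ann)
  expect_length(truth$planted_down, round(0.7 * 60))
  expect_length(intersect(truth$planted_up, truth$targets), 0)

  m <- simulate_expression(cfg, ann)
  expect_equal(dim(m$values), c(300L, 15L))
  expect_equal(as.integer(table(m$groups)[c("control", "treatment")]), c(6L, 9L))
  # noise -> 0 limit recovers the planted effect exactly
  m0 <- simulate_expression(small_cfg(noise_sd = 1e-9), ann)
  fc <- rowMeans(m0$values[, m0$groups == "treatment"]) -
    rowMeans(m0$values[, m0$groups == "control"])
  expect_equal(unname(fc[truth$planted_down]), rep(-1.5, length(truth$planted_down)),
               tolerance = 1e-6)
  expect_equal(unname(fc[truth$planted_up]), rep(1.5, length(truth$planted_up)),
               tolerance = 1e-6)
  expect_equal(unname(fc[setdiff(ann$gene_id, c(truth$planted_down,
                                                truth$planted_up))]),
               rep(0, 300 - 2 * length(truth$planted_down)), tolerance = 1e-6)
})

test_that("categories include a loaded planted category with sane sizes", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  truth <- simulation_truth(cfg, ann)
  cats <- simulate_categories(cfg, ann)
  expect_length(cats, cfg$n_categories)
  planted <- cats[["cat_planted"]]
  expect_equal(sum(planted$genes %in% truth$targets),
               round(cfg$planted_category_overlap * cfg$n_target_genes))
  sizes <- vapply(cats, function(cc) length(cc$genes), 1L)
  expect_true(all(sizes >= 10 & sizes <= 200))
  # zero overlap turns the planted category into a null
  cats0 <- simulate_categories(small_cfg(planted_category_overlap = 0), ann)
  expect_equal(sum(cats0[["cat_planted"]]$genes %in% truth$targets), 0)
})

test_that("simulate_dataset writes a byte-stable, re-readable bundle", {
  cfg <- small_cfg(background_peaks_per_tf = 100)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("genes.tsv", "expr.tsv", "groups.tsv", "categories.gmt",
              "TF1.rep1.narrowPeak", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  ann <- read_gene_annotation(file.path(d1, "genes.tsv"), "tsv")
  expect_equal(ann$tss, sim$annotation$tss)
  ps <- read_peaks(file.path(d1, "TF1.rep1.narrowPeak"), "narrowPeak")
  expect_equal(nrow(ps), nrow(sim$peaks[["TF1.rep1"]]))
  m <- read_expression_matrix(file.path(d1, "expr.tsv"),
                              file.path(d1, "groups.tsv"))
  expect_equal(m$values, sim$expression$values, tolerance = 1e-12)
})
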