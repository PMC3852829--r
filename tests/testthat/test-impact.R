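test_that("hypergeom_tail matches enumeration and handles edge cases", {
  expect_equal(hypergeom_tail(10, 5, 4, 0), 1)
  expect_equal(hypergeom_tail(10, 5, 4, 3), 55 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 5, 4, 5), 0)  # x = min(M, n) + 1
  # certain event when x below the support minimum (n + M - N)
  expect_equal(hypergeom_tail(10, 8, 7, 5), 1)
  expect_error(hypergeom_tail(10, 11, 4, 0), class = "tfimpact_domain_error")
  expect_error(hypergeom_tail(10, 5, 4, 6), class = "tfimpact_domain_error")
  expect_error(hypergeom_tail(10, 5, 4, -1), class = "tfimpact_domain_error")
})

test_that("hypergeom_tail agrees with the oracle over a small sweep", {
  for (N in c(1, 4, 8)) for (M in 0:N) for (n in 0:N)
    for (x in 0:(min(M, n) + 1)) {
      expect_equal(hypergeom_tail(N, M, n, x), hyper_oracle(N, M, n, x),
                   tolerance = 1e-12,
                   info = sprintf("N=%d M=%d n=%d x=%d", N, M, n, x))
    }
  # second independent route at a size where enumeration is uncomfortable
  expect_equal(hypergeom_tail(20000, 200, 2000, 40),
               stats::phyper(39, 200, 19800, 2000, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("hypergeom_tail is non-increasing in x", {
  for (x in 0:6) {
    expect_gte(hypergeom_tail(30, 12, 9, x), hypergeom_tail(30, 12, 9, x + 1))
  }
})

test_that("impact_score computes R and its hypergeometric p", {
  universe <- sprintf("g%02d", 1:10)
  reg <- universe[1:5]; de <- universe[c(1, 2, 3, 8)]
  sc <- impact_score(reg, de, universe)
  expect_equal(sc$R, 0.6)
  expect_equal(sc$n_e, 3L)
  expect_equal(sc$p, 55 / 210, tolerance = 1e-12)

  expect_equal(impact_score(reg, universe[c(1, 8, 9)], universe)$R, 0.2)
  disjoint <- impact_score(universe[1:2], universe[5:6], universe)
  expect_equal(disjoint$R, 0)
  expect_equal(disjoint$p, 1)
  expect_equal(impact_score(universe[1:3], universe[1:5], universe)$R, 1)
  expect_warning(res <- impact_score(character(), de, universe), "empty")
  expect_equal(res$p, 1)
  expect_error(impact_score(c(reg, "nope"), de, universe),
               "nope", class = "tfimpact_validation_error")
})

test_that("growing the universe with irrelevant genes shrinks p, not R", {
  u1 <- sprintf("g%02d", 1:20)
  u2 <- c(u1, sprintf("x%02d", 1:30))
  reg <- u1[1:6]; de <- u1[c(1:4, 15)]
  s1 <- impact_score(reg, de, u1)
  s2 <- impact_score(reg, de, u2)
  expect_equal(s1$R, s2$R)
  expect_lt(s2$p, s1$p)
})

test_that("scan_impact is deterministic, validates inputs, zeroes empties", {
  ann <- toy_ann(seq(10000L, 100000L, by = 10000L))
  g <- ann$gene_id
  tfA <- toy_peaks(c(9950L, 19950L, 29950L), c(10050L, 20050L, 30050L),
                   summit = c(10000L, 20000L, 30000L), tf = "A", rep = "rep1")
  tfA2 <- toy_peaks(tfA$start, tfA$end, summit = tfA$summit,
                    tf = "A", rep = "rep2")
  empty <- toy_peaks(integer(), integer(), tf = "B", rep = "rep1")
  res <- scan_impact(list(tfA, tfA2, empty), ann, up = g[1],
                     down = c(g[2], g[3]), Ns = c(2L, 3L), Ds = c(1000L, 5000L))
  # identical replicate peak files give identical numbers
  a1 <- res[res$replicate == "rep1" & res$tf_name == "A",
            c("n_t", "R_up", "R_down", "p_up", "p_down")]
  a2 <- res[res$replicate == "rep2" & res$tf_name == "A",
            c("n_t", "R_up", "R_down", "p_up", "p_down")]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
  # a TF without peaks scores zero everywhere, never significant
  b <- res[res$tf_name == "B", ]
  expect_true(all(b$R_up == 0 & b$R_down == 0 & b$p_up == 1 & b$p_down == 1))
  expect_false(any(b$significant_up | b$significant_down))
  # full determinism
  res2 <- scan_impact(list(tfA, tfA2, empty), ann, up = g[1],
                      down = c(g[2], g[3]), Ns = c(2L, 3L), Ds = c(1000L, 5000L))
  expect_identical(res, res2)

  expect_error(scan_impact(list(tfA), ann, up = g[1], down = g[1]),
               class = "tfimpact_validation_error")
  expect_error(scan_impact(list(tfA), ann, up = "missing", down = g[2]),
               "missing", class = "tfimpact_validation_error")
})

test_that("scan_impact arithmetic on a hand-checkable cell", {
  ann <- toy_ann(c(1000L, 5000L, 9000L, 13000L, 17000L))
  g <- ann$gene_id
  ps <- toy_peaks(c(900L, 4900L), c(1100L, 5100L),
                  summit = c(1000L, 5000L), tf = "T", rep = "r")
  res <- scan_impact(list(ps), ann, up = character(), down = g[1:2],
                     Ns = 2L, Ds = 1000L)
  expect_equal(res$n_t, 2L)
  expect_equal(res$R_down, 1)          # both regulated genes are down
  expect_equal(res$p_down, hyper_oracle(5, 2, 2, 2), tolerance = 1e-12)
  expect_equal(res$R_up, 0)
})

test_that("replicate merging pools peaks before scoring", {
  ann <- toy_ann(c(1000L, 50000L))
  r1 <- toy_peaks(900L, 1100L, summit = 1000L, tf = "T", rep = "rep1")
  r2 <- toy_peaks(49900L, 50100L, summit = 50000L, tf = "T", rep = "rep2")
  res <- scan_impact(list(r1, r2), ann, up = character(), down = "g001",
                     Ns = 5L, Ds = 1000L, merge_replicates = "union")
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_t, 2L)  # both genes hit after pooling
})

test_that("rank_impact and top_tf order factors as documented", {
  res <- data.frame(
    tf_name = c("A", "B", "C", "A", "B", "C"),
    replicate = "rep1",
    cutoff_D = 1000L, set_size_N = rep(c(200L, 500L), each = 3),
    n_t = 10L, n_e_up = 0L, n_e_down = 0L,
    R_up = 0, R_down = c(0.5, 0.9, 0.5, 0.2, 0.2, 0.8),
    p_up = 1, p_down = c(0.01, 0.001, 0.002, 0.5, 0.4, 0.001),
    significant_up = FALSE, significant_down = FALSE)
  rk <- rank_impact(res)
  expect_equal(rk$tf_name[rk$set_size_N == 200L][1:3], c("B", "C", "A"))
  expect_equal(top_tf(res, 200L)$tf_name, "B")
  expect_equal(top_tf(res, 500L)$tf_name, "C")
})
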