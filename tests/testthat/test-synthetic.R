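test_that("noise-free generation reproduces planted amplitudes exactly", {
  cfg <- tiny_config(rng_seed = 51,
                     events = list(list(chromosome = 1L, genes = 5:10,
                                        direction = "amp", effect = 1.2,
                                        frequency = 1.0, cohorts = NULL)),
                     expr_noise_sd = 0, cna_noise_sd = 0)
  sim <- simulate_cohorts(cfg)
  cna <- segments_to_gene_cna(sim$segments, sim$annotation,
                              samples = sim$manifest$A$tumor)
  ev_genes <- sim$truth$events[[1]]$gene_ids
  expect_true(all(cna[ev_genes, ] == 1.2))
  expect_true(all(cna[setdiff(rownames(cna), ev_genes), ] == 0))
  # realized frequency matches the truth indicators
  expect_equal(sim$truth$events[[1]]$realized_freq[["A"]], 1)
  # normal samples never carry the event
  cna_n <- segments_to_gene_cna(sim$segments, sim$annotation,
                                samples = sim$manifest$A$normal)
  expect_true(all(cna_n == 0))
})

test_that("realized event frequencies are binomially consistent", {
  cfg <- tiny_config(rng_seed = 53,
                     events = list(list(chromosome = 2L, genes = 10:15,
                                        direction = "del", effect = 1,
                                        frequency = 0.10, cohorts = NULL)))
  sim <- simulate_cohorts(cfg)
  for (co in names(cfg$cohort_sizes)) {
    n <- cfg$cohort_sizes[[co]]
    f <- sim$truth$events[[1]]$realized_freq[[co]]
    expect_lt(abs(f - 0.10), 3 * sqrt(0.1 * 0.9 / n))
    expect_equal(f, mean(sim$truth$events[[1]]$indicators[[co]]))
  }
})

test_that("generation is deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- tiny_config(rng_seed = 55,
                     events = list(list(chromosome = 1L, genes = 3:8,
                                        direction = "amp", effect = 1.5,
                                        frequency = 0.2, cohorts = NULL)))
  f1 <- simulate_cohorts(cfg, dir = d1)$files
  f2 <- simulate_cohorts(cfg, dir = d2)$files
  for (nm in c("segments", "annotation", "manifest")) {
    expect_identical(unname(tools::md5sum(f1[[nm]])), unname(tools::md5sum(f2[[nm]])))
  }
  for (co in names(f1$expression)) {
    expect_identical(unname(tools::md5sum(f1$expression[[co]])),
                     unname(tools::md5sum(f2$expression[[co]])))
  }
  # a different seed changes the data
  f3 <- simulate_cohorts(tiny_config(rng_seed = 56), dir = withr::local_tempdir())$files
  expect_false(identical(unname(tools::md5sum(f3$segments)),
                         unname(tools::md5sum(f1$segments))))
})

test_that("generated gene order matches the annotation and expression is coupled to dosage", {
  cfg <- tiny_config(rng_seed = 57,
                     events = list(list(chromosome = 1L, genes = 10:15,
                                        direction = "amp", effect = 1.5,
                                        frequency = 0.3, cohorts = NULL)))
  sim <- simulate_cohorts(cfg)
  expect_identical(rownames(sim$expression$A), sim$annotation$gene_id)
  co <- as_cohort_set(sim)
  expect_identical(rownames(co$cohorts$A$expression), co$annotation$gene_id)
  # dosage coupling: event carriers express the member genes higher
  g <- sim$truth$events[[1]]$gene_ids[1]
  carriers <- sim$truth$events[[1]]$indicators$A
  expr <- log2(1 + sim$expression$A[g, names(carriers)])
  expect_gt(mean(expr[carriers]) - mean(expr[!carriers]), 1)
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(tiny_config(events = list(
    list(chromosome = 1L, genes = 5:10, direction = "amp", effect = 1, frequency = 0.5),
    list(chromosome = 1L, genes = 8:12, direction = "del", effect = 1, frequency = 0.5))),
    "overlapping")
  expect_error(tiny_config(events = list(
    list(chromosome = 1L, genes = 35:45, direction = "amp", effect = 1, frequency = 0.5))),
    "outside")
  expect_error(tiny_config(events = list(
    list(chromosome = 1L, genes = 1:5, direction = "gain", effect = 1, frequency = 0.5))),
    "direction")
  expect_error(tiny_config(expr_noise_sd = -1), "sds")
})

test_that("recovery scoring handles hits, misses and empty call sets", {
  truth <- list(events = list(list(chromosome = "chr1", direction = "amp",
                                   gene_ids = c("g1", "g2", "g3"))))
  sig <- structure(list(name = "g2",
                        weights = c(g1 = 0.9, g2 = 0.95, g3 = 0.8, g4 = 0.1),
                        range = list(chromosome = "chr1")),
                   class = "cocna_signature")
  calls_hit <- data.frame(is_driver = TRUE, is_pan_amp = TRUE, is_pan_del = FALSE)
  r <- score_recovery(truth, list(calls = calls_hit, signatures = list(sig)))
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$jaccard, 1)
  # wrong direction: no credit
  calls_del <- data.frame(is_driver = TRUE, is_pan_amp = FALSE, is_pan_del = TRUE)
  r2 <- score_recovery(truth, list(calls = calls_del, signatures = list(sig)))
  expect_equal(r2$recall, 0)
  expect_equal(r2$precision, 0)
  # no calls at all: recall 0, precision undefined
  calls_none <- data.frame(is_driver = logical(0), is_pan_amp = logical(0),
                           is_pan_del = logical(0))
  r3 <- score_recovery(truth, list(calls = calls_none, signatures = list()))
  expect_equal(r3$recall, 0)
  expect_true(is.na(r3$precision))
})
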