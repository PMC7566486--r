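test_that("sliding windows match a brute-force builder and never cross chromosomes", {
  set.seed(2)
  ann <- data.frame(
    gene_id = sprintf("g%03d", 1:90),
    chromosome = sample(paste0("chr", 1:4), 90, replace = TRUE),
    start = sample.int(5e6, 90))
  ann$end <- ann$start + 1000
  ann <- sort_annotation(ann)
  for (S in c(10, 20, 50)) {
    for (pos in sample(nrow(ann), 30)) {
      win <- cocna:::.gene_window(ann, pos, S)
      expect_identical(win, oracle_window(ann, pos, S / 2))
      expect_length(unique(ann$chromosome[win]), 1L)
    }
  }
})

test_that("attractor config validates its invariants", {
  expect_error(attractor_config(window_size = 9), "even integer")
  expect_error(attractor_config(window_size = 13), "even integer")
  expect_error(attractor_config(alpha = 0), "alpha")
  expect_error(attractor_config(strength_threshold = 1.2), "strength_threshold")
})

test_that("a planted co-expressed block is an attractor with strength >= 0.5", {
  co <- block_cohorts(seed = 101)
  sig <- iterate_attractor("g025", co$annotation$gene_id, co)
  expect_true(sig$converged)
  expect_gte(sig$strength, 0.5)
  block_ids <- sprintf("g%03d", 21:30)
  # the members above the range threshold are exactly the planted block
  expect_setequal(names(sig$weights)[sig$weights > 0.5], block_ids)
  expect_lt(max(sig$weights[setdiff(names(sig$weights), block_ids)]), 0.3)
  expect_identical(sig$range$first_gene, "g021")
  expect_identical(sig$range$last_gene, "g030")
})

test_that("every block-member seed converges to the identical attractor", {
  co <- block_cohorts(seed = 102)
  sigs <- lapply(sprintf("g%03d", 21:30), iterate_attractor,
                 window_genes = co$annotation$gene_id, cohorts = co)
  ref <- sigs[[1]]
  for (s in sigs[-1]) {
    expect_identical(s$name, ref$name)
    expect_lt(max(abs(s$weights - ref$weights)), 1e-6)
  }
  # determinism: rerunning the same seed gives bit-identical weights
  again <- iterate_attractor("g025", co$annotation$gene_id, co)
  ref2 <- iterate_attractor("g025", co$annotation$gene_id, co)
  expect_identical(again$weights, ref2$weights)
})

test_that("noise windows do not produce strong attractors", {
  co <- block_cohorts(block = integer(0), seed = 103)
  strengths <- vapply(sprintf("g%03d", seq(1, 51, by = 2)), function(g) {
    iterate_attractor(g, co$annotation$gene_id, co)$strength
  }, numeric(1))
  expect_gte(mean(strengths < 0.5), 0.95)
})

test_that("constant expression yields a degenerate zero-strength signature", {
  co <- block_cohorts(n_genes = 12, block = integer(0), n = c(20, 20), seed = 104)
  for (i in seq_along(co$cohorts)) {
    co$cohorts[[i]]$expression[] <- 1
  }
  sig <- iterate_attractor("g005", co$annotation$gene_id, co)
  expect_true(sig$degenerate)
  expect_identical(sig$strength, 0)
})

test_that("first pass recovers the planted block and only it", {
  co <- block_cohorts(seed = 105)
  found <- first_pass(co, attractor_config(window_size = 50))
  expect_gt(length(found), 0)
  block_ids <- sprintf("g%03d", 21:30)
  for (s in found) {
    expect_true(s$range$first_gene %in% block_ids)
    expect_true(s$range$last_gene %in% block_ids)
  }
  # pure noise: nothing survives the strength filter
  co0 <- block_cohorts(block = integer(0), seed = 106)
  expect_length(first_pass(co0, attractor_config(window_size = 50)), 0)
})

test_that("the strength filter needs five strong genes: 5-gene block passes, 4 fails", {
  co5 <- block_cohorts(block = 21:25, r = 0.95, seed = 107)
  found5 <- first_pass(co5, attractor_config(window_size = 50))
  expect_gt(length(found5), 0)
  co4 <- block_cohorts(block = 21:24, r = 0.95, seed = 108)
  expect_length(first_pass(co4, attractor_config(window_size = 50)), 0)
})

test_that("range merging is the transitive closure of overlap", {
  ann <- data.frame(gene_id = sprintf("g%02d", 1:40),
                    chromosome = rep(c("chr1", "chr2"), each = 20),
                    start = rep(1:20 * 100, 2), end = rep(1:20 * 100 + 50, 2))
  ann <- sort_annotation(ann)
  stub <- function(name, chr, lo, hi) {
    structure(list(name = name, weights = setNames(1, name),
                   range = list(chromosome = chr, start_idx = lo, end_idx = hi)),
              class = "cocna_signature")
  }
  # overlapping pair merges
  cl <- merge_ranges(list(stub("a", "chr1", 1, 10), stub("b", "chr1", 8, 15)), ann)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$start_idx, 1)
  expect_identical(cl[[1]]$end_idx, 15)
  # disjoint stays apart
  cl2 <- merge_ranges(list(stub("a", "chr1", 1, 5), stub("b", "chr1", 7, 12)), ann)
  expect_length(cl2, 2)
  # chain a~b, b~c with a,c disjoint merges transitively
  cl3 <- merge_ranges(list(stub("a", "chr1", 1, 6), stub("c", "chr1", 9, 14),
                           stub("b", "chr1", 5, 10)), ann)
  expect_length(cl3, 1)
  expect_identical(cl3[[1]]$gene_ids, ann$gene_id[1:14])
  # same intervals on different chromosomes never merge
  cl4 <- merge_ranges(list(stub("a", "chr1", 1, 10), stub("b", "chr2", 21, 30)), ann)
  expect_length(cl4, 2)
})

test_that("second pass picks the strongest attractor per cluster", {
  # two independent blocks in one window: r=0.95 block beats r=0.75 block
  set.seed(109)
  n_genes <- 40
  n <- c(70, 60)
  ann <- data.frame(gene_id = sprintf("g%03d", 1:n_genes), chromosome = "chr1",
                    start = (1:n_genes - 1) * 100000 + 1,
                    end = (1:n_genes - 1) * 100000 + 50000)
  strong <- 5:12
  weak <- 25:32
  expr <- lapply(seq_along(n), function(ci) {
    m <- matrix(rnorm(n_genes * n[ci]), n_genes)
    for (spec in list(list(g = strong, r = 0.95), list(g = weak, r = 0.75))) {
      z <- rnorm(n[ci])
      m[spec$g, ] <- sqrt(spec$r) * matrix(z, length(spec$g), n[ci], byrow = TRUE) +
        sqrt(1 - spec$r) * matrix(rnorm(length(spec$g) * n[ci]), length(spec$g))
    }
    raw <- pmax(2^(m + 5) - 1, 0)
    dimnames(raw) <- list(ann$gene_id, sprintf("C%d_%03d", ci, seq_len(n[ci])))
    raw
  })
  names(expr) <- c("A", "B")
  co <- cohort_set(expr, flat_segments(unlist(lapply(expr, colnames))), ann)
  cluster <- list(list(chromosome = "chr1", start_idx = 1, end_idx = n_genes,
                       gene_ids = ann$gene_id))
  reps <- second_pass(cluster, co, attractor_config(window_size = 50))
  expect_length(reps, 1)
  members <- names(reps[[1]]$weights)[reps[[1]]$weights > 0.5]
  expect_true(all(members %in% sprintf("g%03d", strong)))

  # idempotence on a clean single-block fixture: the representative
  # reproduces the first-pass attractor
  co1 <- block_cohorts(seed = 110)
  fp <- first_pass(co1, attractor_config(window_size = 50))
  cl <- merge_ranges(fp, co1$annotation)
  rep1 <- second_pass(cl, co1, attractor_config(window_size = 50))
  expect_length(rep1, 1)
  expect_identical(rep1[[1]]$name, fp[[1]]$name)
  # the representative is computed inside the (narrower) cluster range, so
  # weights agree closely but not bit-exactly with the windowed first pass
  expect_setequal(names(rep1[[1]]$weights)[rep1[[1]]$weights > 0.5],
                  names(fp[[1]]$weights)[fp[[1]]$weights > 0.5])
  common <- intersect(names(rep1[[1]]$weights), names(fp[[1]]$weights))
  expect_lt(max(abs(rep1[[1]]$weights[common] - fp[[1]]$weights[common])), 0.05)
})

test_that("final filters drop unexpressed top genes (strictly above half) and sex chromosomes", {
  co <- block_cohorts(n_genes = 12, block = 3:8, n = c(20, 20), seed = 111)
  sig <- iterate_attractor("g005", co$annotation$gene_id, co)
  # autosomal, expressed: retained
  expect_length(final_filters(list(sig), co), 1)
  # top gene zero in exactly half the samples: retained (strict 'more than')
  co_half <- co
  top1 <- names(sort(sig$weights, decreasing = TRUE))[1]
  co_half$cohorts[[1]]$raw[top1, ] <- 0  # 20 of 40 pooled samples
  expect_length(final_filters(list(sig), co_half), 1)
  # one more zero sample tips it over the boundary
  co_over <- co_half
  co_over$cohorts[[2]]$raw[top1, 1] <- 0  # 21 of 40
  expect_length(final_filters(list(sig), co_over), 0)
  # chromosome X ranges are removed
  sigX <- sig
  sigX$range$chromosome <- "chrX"
  expect_length(final_filters(list(sigX), co), 0)
})
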