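test_that("signature levels average the top-k gene rows", {
  co <- block_cohorts(n_genes = 12, block = integer(0), n = c(10, 10), seed = 21)
  sig <- structure(list(name = "g001",
                        weights = setNames(seq(1, 0.1, length.out = 12),
                                           co$annotation$gene_id)),
                   class = "cocna_signature")
  # top_k = 1: level equals the name gene's row
  lv1 <- signature_levels(sig, co, top_k = 1)
  expect_equal(lv1$expr[[1]], co$cohorts[[1]]$expression["g001", ])
  # equal rows -> the level is that common row
  co2 <- co
  v <- rnorm(10)
  for (g in co$annotation$gene_id[1:5]) co2$cohorts[[1]]$expression[g, ] <- v
  expect_equal(unname(signature_levels(sig, co2, top_k = 5)$expr[[1]]), v)
  # two genes with rows [1,3] and [3,1] -> level [2,2]
  co3 <- co
  co3$cohorts[[1]]$cna["g001", ] <- rep(c(1, 3), 5)
  co3$cohorts[[1]]$cna["g002", ] <- rep(c(3, 1), 5)
  expect_equal(unname(signature_levels(sig, co3, top_k = 2)$cna[[1]]), rep(2, 10))
  # missing gene in the CNA matrix errors with the gene named
  co4 <- co
  rownames(co4$cohorts[[1]]$cna)[1] <- "zzz"
  expect_error(signature_levels(sig, co4, top_k = 1), "g001")
})

test_that("perfect expression/CNA coupling attains the minimum permutation P", {
  set.seed(31)
  lv <- list(expr = lapply(1:3, function(i) rnorm(40)), cna = NULL)
  lv$cna <- lv$expr
  res <- permutation_test(lv, rep(1 / 3, 3), call_config(n_permutations = 200, rng_seed = 5))
  expect_identical(res$assoc, 1)
  expect_equal(res$p_raw, 1 / 201)
})

test_that("permutation P values are reproducible for a fixed seed and sane otherwise", {
  set.seed(33)
  e <- rnorm(60)
  lv <- list(expr = list(e), cna = list(e + rnorm(60, 0, 0.8)))
  cfg <- call_config(n_permutations = 300, rng_seed = 42)
  r1 <- permutation_test(lv, 1, cfg)
  r2 <- permutation_test(lv, 1, cfg)
  expect_identical(r1$p_raw, r2$p_raw)
  expect_identical(r1$assoc, r2$assoc)
  # the caller's RNG stream is not disturbed
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(permutation_test(lv, 1, cfg)); after <- rnorm(1)
  expect_identical(before, after)
  # an uncoupled pair is clearly non-significant
  lv0 <- list(expr = list(rnorm(60)), cna = list(rnorm(60)))
  expect_gt(permutation_test(lv0, 1, cfg)$p_raw, 0.05)
  expect_error(call_config(n_permutations = 50), ">= 100")
})

test_that("thresholds from symmetric normal noise are symmetric and centered", {
  set.seed(35)
  co <- block_cohorts(n_genes = 30, block = integer(0), n = c(20, 20), seed = 36)
  for (i in 1:2) {
    co$cohorts[[i]]$normal_cna <- matrix(rnorm(30 * 50, mean = 0.3, sd = 0.25), 30,
                                         dimnames = list(co$annotation$gene_id, NULL))
  }
  th <- derive_thresholds(co, call_config())
  # per-sample centering removes the common offset; tails are symmetric
  expect_gt(th$t_amp, 0)
  expect_lt(th$t_del, 0)
  expect_lt(abs(th$t_amp + th$t_del), 0.05)
  # one constant normal sample centers to all-zero: degenerate, flagged
  co1 <- co
  co1$cohorts[[1]]$normal_cna <- matrix(0.7, 30, 1)
  co1$cohorts[[2]]$normal_cna <- NULL
  expect_warning(expect_warning(th1 <- derive_thresholds(co1, call_config()),
                                "without normal"), "degenerate")
  expect_identical(th1$t_amp, 0)
  expect_identical(th1$t_del, 0)
  # no normals anywhere: error directing to configuration
  co2 <- co
  for (i in 1:2) co2$cohorts[[i]]$normal_cna <- NULL
  expect_error(derive_thresholds(co2, call_config()), "configuration")
})

test_that("frequency classification uses strict inequalities everywhere", {
  th <- list(t_amp = 0.45, t_del = -0.62)
  cfg <- call_config()
  # 4 of 100 samples above t_amp -> 4% > 3% -> amplified in that cohort
  lv <- c(rep(0.5, 4), rep(0, 96))
  fr <- classify_frequencies(list(lv), th, cfg)
  expect_identical(fr$n_types_amp, 1L)
  # exactly 3% is NOT amplified
  lv3 <- c(rep(0.5, 3), rep(0, 97))
  expect_identical(classify_frequencies(list(lv3), th, cfg)$n_types_amp, 0L)
  # a level exactly at the threshold does not count as altered
  expect_identical(classify_frequencies(list(rep(0.45, 10)), th, cfg)$amp_freq, 0)
  # amplified in exactly 6 types -> not pan-cancer; 7 -> pan-cancer
  six <- replicate(6, lv, simplify = FALSE)
  seven <- replicate(7, lv, simplify = FALSE)
  expect_false(classify_frequencies(six, th, cfg)$is_pan_amp)
  expect_true(classify_frequencies(seven, th, cfg)$is_pan_amp)
  # raising t_amp never increases any amplification frequency
  set.seed(37)
  levs <- replicate(5, rnorm(50, 0, 0.5), simplify = FALSE)
  f1 <- classify_frequencies(levs, list(t_amp = 0.3, t_del = -0.3), cfg)$amp_freq
  f2 <- classify_frequencies(levs, list(t_amp = 0.5, t_del = -0.3), cfg)$amp_freq
  expect_true(all(f2 <= f1))
})

test_that("co-alteration counts strictly-closer-than-0.1 CNA pairs among altered samples", {
  th <- list(t_amp = 0.45, t_del = -0.62)
  cfg <- call_config()
  w <- 1
  mk <- function(cna) list(expr = list(rnorm(length(cna))), cna = list(cna))
  # identical amplified levels -> co-altered everywhere
  a <- mk(rep(1, 20))
  b <- a
  b$expr <- list(rnorm(20))
  expect_identical(co_alteration(a, b, "amp", th, w, cfg)$co_freq, 1)
  # exact difference of 0.1 is NOT co-altered
  b2 <- mk(rep(1.1, 20))
  expect_identical(co_alteration(a, b2, "amp", th, w, cfg)$co_freq, 0)
  # nothing altered -> frequency undefined
  a0 <- mk(rep(0, 20))
  expect_true(is.na(co_alteration(a0, a0, "amp", th, w, cfg)$co_freq))
  # 80/20 mixture: both amplified together in 16, one alone in 4
  cna_a <- c(rep(1, 20))
  cna_b <- c(rep(1.02, 16), rep(0, 4))
  expect_equal(co_alteration(mk(cna_a), mk(cna_b), "amp", th, w, cfg)$co_freq, 0.8)
})

test_that("driver designation enforces the dual condition with Bonferroni", {
  cfg <- call_config()
  calls <- data.frame(p_raw = c(0.002, 0.002, 0.04),
                      is_pan_amp = c(TRUE, FALSE, TRUE),
                      is_pan_del = c(FALSE, FALSE, FALSE))
  out <- designate_drivers(calls, cfg)
  expect_equal(out$p_bonferroni, pmin(1, calls$p_raw * 3))
  # row 1: both conditions -> driver; row 2: frequency fails; row 3:
  # adjusted association fails (0.04 * 3 = 0.12)
  expect_identical(out$is_driver, c(TRUE, FALSE, FALSE))
  expect_identical(out$direction, c("amp", "", "amp"))
})
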