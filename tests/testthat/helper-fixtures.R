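# Shared fixtures and independent oracles. Everything is built in code at
# test time; no data files.

# Brute-force lower weighted median: scan every candidate value and return the
# smallest one whose cumulative weight of {values <= v} reaches half.
oracle_weighted_median <- function(values, weights) {
  tot <- sum(weights)
  for (v in sort(values)) {
    if (sum(weights[values <= v]) / tot >= 0.5 - 1e-12) return(v)
  }
  stop("unreachable")
}

# Closed-form mutual information of a bivariate Gaussian, in nats.
gaussian_mi <- function(rho) -0.5 * log(1 - rho^2)

# Brute-force sliding-window builder over an annotation data.frame: positions
# within `half` ranks of the gene on its own chromosome.
oracle_window <- function(annotation, pos, half) {
  chr <- annotation$chromosome[pos]
  cand <- which(annotation$chromosome == chr)
  k <- which(cand == pos)
  cand[abs(seq_along(cand) - k) <= half]
}

# Flat (all-diploid) segments covering one chromosome for a set of samples.
flat_segments <- function(samples, chrom = "chr1", len = 2e7, value = 0) {
  data.frame(sample = samples, chromosome = chrom, start = 1, end = len,
             seg_mean = value, stringsAsFactors = FALSE)
}

# A multi-cohort fixture with one window-sized chromosome containing a planted
# co-expressed block sharing a latent factor at pairwise correlation ~ r.
# CNA is flat so only the expression structure matters.
block_cohorts <- function(n_genes = 51, block = 21:30, n = c(70, 60, 80),
                          r = 0.9, seed = 1) {
  set.seed(seed)
  ann <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)), chromosome = "chr1",
                    start = (seq_len(n_genes) - 1) * 100000 + 1,
                    end = (seq_len(n_genes) - 1) * 100000 + 50000)
  lam <- sqrt(r)
  noise <- sqrt(1 - r)
  expr <- lapply(seq_along(n), function(ci) {
    m <- matrix(rnorm(n_genes * n[ci]), n_genes)
    if (length(block)) {
      z <- rnorm(n[ci])
      m[block, ] <- lam * matrix(z, length(block), n[ci], byrow = TRUE) +
        noise * matrix(rnorm(length(block) * n[ci]), length(block))
    }
    raw <- pmax(2^(m + 5) - 1, 0)
    dimnames(raw) <- list(ann$gene_id, sprintf("C%d_T%03d", ci, seq_len(n[ci])))
    raw
  })
  names(expr) <- paste0("C", seq_along(n))
  seg <- flat_segments(unlist(lapply(expr, colnames)))
  cohort_set(expr, seg, ann)
}

# A tiny synthetic config for fast pipeline-level tests.
tiny_config <- function(rng_seed = 1L, events = list(), confounders = list(),
                        n_normal_per_cohort = 6L, ...) {
  synthetic_config(n_chromosomes = 2L, genes_per_chromosome = 40L,
                   cohort_sizes = setNames(c(60L, 50L, 50L), c("A", "B", "C")),
                   n_normal_per_cohort = n_normal_per_cohort,
                   events = events, confounders = confounders,
                   rng_seed = rng_seed, ...)
}
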