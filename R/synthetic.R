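#' Synthetic multi-cohort configuration
#'
#' Describes a synthetic genome and patient cohorts with planted recurrent
#' copy-number events, so that every pipeline stage can be exercised against
#' known ground truth. Genes are placed at regular midpoints (100 kb apart,
#' 50 kb long) per chromosome. Each tumor sample receives random baseline
#' copy-number segments (log2-ratio noise around diploid); each planted event
#' fires independently per sample with its per-cohort frequency and replaces
#' its region with a single segment at the event's signed effect size (plus
#' segment noise). Expression on the log2 scale is a per-gene baseline plus
#' `dosage_slope` times the gene's copy-number dose, plus optional latent
#' confounder factors, plus Gaussian noise; it is exported on the raw scale
#' via `2^x - 1` (clipped at 0) so the pipeline's `log2(1 + X)` transform is
#' exercised. Normal samples carry baseline segments only (event frequency 0).
#'
#' @param n_chromosomes,genes_per_chromosome Genome shape.
#' @param cohort_sizes Named integer vector of tumor sample counts.
#' @param n_normal_per_cohort Matched normal samples per cohort.
#' @param events List of planted events: each
#'   `list(chromosome=, genes=from:to (index within chromosome), direction=
#'   "amp"|"del", effect=, frequency=, cohorts= names or NULL for all)`.
#' @param confounders List of planted co-expression blocks without a CNA
#'   footprint: each `list(chromosome=, genes=, strength=)` for a
#'   co-localized block, or `list(gene_ids=, strength=)` for a scattered
#'   (immune-like) set given as global gene indices.
#' @param dosage_slope Expression (log2) units per copy-number log2-ratio
#'   unit. Default 1.
#' @param expr_noise_sd Per-gene, per-sample expression noise sd. Default 0.25.
#' @param cna_noise_sd Sd of baseline segment means (and of the noise on event
#'   segments). Default 0.25, a typical scale for array-derived segment noise.
#' @param segments_per_chromosome Mean number of baseline segments per
#'   chromosome per sample. Default 4.
#' @param rng_seed Seed making the generated data reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 4L, genes_per_chromosome = 75L,
                             cohort_sizes = setNames(c(140L, 130L, 120L, 120L,
                                                       110L, 110L, 100L, 100L),
                                                     paste0("C", 1:8)),
                             n_normal_per_cohort = 10L,
                             events = list(),
                             confounders = list(),
                             dosage_slope = 1,
                             expr_noise_sd = 0.25,
                             cna_noise_sd = 0.25,
                             segments_per_chromosome = 4,
                             rng_seed = 1L) {
  if (is.null(names(cohort_sizes))) names(cohort_sizes) <- paste0("C", seq_along(cohort_sizes))
  cfg <- structure(list(n_chromosomes = as.integer(n_chromosomes),
                        genes_per_chromosome = as.integer(genes_per_chromosome),
                        cohort_sizes = cohort_sizes,
                        n_normal_per_cohort = as.integer(n_normal_per_cohort),
                        events = events, confounders = confounders,
                        dosage_slope = dosage_slope,
                        expr_noise_sd = expr_noise_sd, cna_noise_sd = cna_noise_sd,
                        segments_per_chromosome = segments_per_chromosome,
                        rng_seed = as.integer(rng_seed)),
                   class = "synthetic_config")
  .validate_synthetic(cfg)
  cfg
}

.validate_synthetic <- function(cfg) {
  if (cfg$expr_noise_sd < 0 || cfg$cna_noise_sd < 0) stop("noise sds must be >= 0")
  by_chr <- list()
  for (ev in cfg$events) {
    g <- range(ev$genes)
    if (g[1] < 1 || g[2] > cfg$genes_per_chromosome) stop("event gene range outside chromosome")
    if (ev$chromosome < 1 || ev$chromosome > cfg$n_chromosomes) stop("event chromosome out of range")
    if (!(ev$direction %in% c("amp", "del"))) stop("event direction must be 'amp' or 'del'")
    if (ev$frequency < 0 || ev$frequency > 1) stop("event frequency must be in [0, 1]")
    key <- as.character(ev$chromosome)
    for (prev in by_chr[[key]]) {
      if (g[1] <= prev[2] && prev[1] <= g[2]) stop("overlapping planted events on one chromosome")
    }
    by_chr[[key]] <- c(by_chr[[key]], list(g))
  }
  invisible(cfg)
}

#' Named synthetic profiles
#'
#' Three ready-made study conditions: `"realistic"` — 8 cohorts (100-140
#' tumors each, 10 normals), 3 planted amplicons and 1 planted deletion of
#' 12 genes each at 10% per-sample event frequency in all cohorts
#' (|log2-ratio| effect 1.5), plus one co-localized copy-number-neutral
#' confounder block, at default noise; `"clean"` — the same layout without
#' confounder and with low noise and 25% event frequency; `"null"` — the
#' same genome and cohorts with no planted structure at all.
#'
#' @param name One of `"realistic"`, `"clean"`, `"null"`.
#' @param rng_seed Seed stored in the returned config.
#' @return A [synthetic_config()].
#' @export
synthetic_profile <- function(name = c("realistic", "clean", "null"), rng_seed = 1L) {
  name <- match.arg(name)
  events <- list(
    list(chromosome = 1L, genes = 20:31, direction = "amp", effect = 1.5,
         frequency = 0.10, cohorts = NULL),
    list(chromosome = 2L, genes = 40:51, direction = "amp", effect = 1.5,
         frequency = 0.10, cohorts = NULL),
    list(chromosome = 3L, genes = 10:21, direction = "amp", effect = 1.5,
         frequency = 0.10, cohorts = NULL),
    list(chromosome = 4L, genes = 50:61, direction = "del", effect = 1.5,
         frequency = 0.10, cohorts = NULL))
  confounders <- list(list(chromosome = 2L, genes = 5:16, strength = 1.0))
  switch(name,
    realistic = synthetic_config(events = events, confounders = confounders,
                                 rng_seed = rng_seed),
    clean = {
      ev <- lapply(events, function(e) { e$frequency <- 0.25; e })
      synthetic_config(events = ev, confounders = list(),
                       expr_noise_sd = 0.1, cna_noise_sd = 0.1, rng_seed = rng_seed)
    },
    null = synthetic_config(events = list(), confounders = list(), rng_seed = rng_seed))
}

#' Generate a synthetic multi-cohort data set
#'
#' Draws the genome, cohorts, segments and expression described by a
#' [synthetic_config()]. With `dir` set, also writes the pipeline's input
#' files: one expression TSV per cohort, a pooled SEG-like segment TSV, an
#' annotation TSV, and a YAML cohort manifest — byte-identical across runs
#' with the same seed.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Optional output directory for the TSV/YAML files.
#' @return An object of class `cocna_sim`: `annotation`, `expression` (named
#'   list of raw matrices covering tumor and normal columns), `segments`,
#'   `manifest`, `truth` (per-event member genes, per-sample indicators and
#'   realized per-cohort frequencies; per-confounder member genes), `config`,
#'   and `files` (paths, when written).
#' @export
simulate_cohorts <- function(cfg = synthetic_profile("realistic"), dir = NULL) {
  sim <- withr_seed(cfg$rng_seed, .simulate_impl(cfg))
  if (!is.null(dir)) sim$files <- .write_sim(sim, dir)
  sim
}

.simulate_impl <- function(cfg) {
  gpc <- cfg$genes_per_chromosome
  nchr <- cfg$n_chromosomes
  gene_len <- 50000L
  spacing <- 100000L
  chrom_len <- gpc * spacing
  annotation <- data.frame(
    gene_id = sprintf("G%02d_%03d", rep(seq_len(nchr), each = gpc),
                      rep(seq_len(gpc), nchr)),
    chromosome = paste0("chr", rep(seq_len(nchr), each = gpc)),
    start = rep((seq_len(gpc) - 1L) * spacing + 1L, nchr),
    end = rep((seq_len(gpc) - 1L) * spacing + gene_len, nchr),
    stringsAsFactors = FALSE)
  annotation <- sort_annotation(annotation)
  G <- nrow(annotation)
  baseline <- runif(G, 2.5, 7.5)

  cohorts <- names(cfg$cohort_sizes)
  manifest <- list()
  seg_rows <- list()
  truth_ind <- lapply(cfg$events, function(e) list())
  expression <- list()

  # global index of an event's genes
  ev_global <- lapply(cfg$events, function(ev) {
    which(annotation$chromosome == paste0("chr", ev$chromosome) &
          as.integer(sub(".*_", "", annotation$gene_id)) %in% ev$genes)
  })
  conf_global <- lapply(cfg$confounders, function(cf) {
    if (!is.null(cf$gene_ids)) return(cf$gene_ids)
    which(annotation$chromosome == paste0("chr", cf$chromosome) &
          as.integer(sub(".*_", "", annotation$gene_id)) %in% cf$genes)
  })

  for (co in cohorts) {
    n_t <- cfg$cohort_sizes[[co]]
    n_n <- cfg$n_normal_per_cohort
    tum <- sprintf("%s_T%03d", co, seq_len(n_t))
    nrm <- if (n_n > 0) sprintf("%s_N%03d", co, seq_len(n_n)) else character(0)
    manifest[[co]] <- list(tumor = tum, normal = nrm)

    fires <- matrix(FALSE, length(cfg$events), n_t)
    for (ei in seq_along(cfg$events)) {
      ev <- cfg$events[[ei]]
      affected <- is.null(ev$cohorts) || co %in% ev$cohorts
      if (affected && ev$frequency > 0) {
        fires[ei, ] <- runif(n_t) < ev$frequency
      }
      truth_ind[[ei]][[co]] <- setNames(fires[ei, ], tum)
    }

    segs <- .sample_segments(c(tum, nrm), nchr, chrom_len, cfg, fires, annotation,
                             is_tumor = c(rep(TRUE, n_t), rep(FALSE, length(nrm))))
    seg_rows[[co]] <- segs

    cna <- segments_to_gene_cna(segs, annotation, samples = c(tum, nrm))
    x <- baseline + cfg$dosage_slope * cna +
      matrix(rnorm(G * ncol(cna), 0, cfg$expr_noise_sd), G)
    for (fi in seq_along(cfg$confounders)) {
      z <- rnorm(ncol(cna))
      gi <- conf_global[[fi]]
      x[gi, ] <- x[gi, ] + cfg$confounders[[fi]]$strength * matrix(z, length(gi), ncol(cna),
                                                                   byrow = TRUE)
    }
    raw <- pmax(2^x - 1, 0)
    dimnames(raw) <- list(annotation$gene_id, c(tum, nrm))
    expression[[co]] <- raw
  }

  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  truth <- list(
    events = lapply(seq_along(cfg$events), function(ei) {
      ev <- cfg$events[[ei]]
      ind <- truth_ind[[ei]]
      list(chromosome = paste0("chr", ev$chromosome),
           direction = ev$direction,
           effect = ev$effect,
           gene_ids = annotation$gene_id[ev_global[[ei]]],
           indicators = ind,
           realized_freq = vapply(ind, mean, numeric(1)))
    }),
    confounders = lapply(seq_along(cfg$confounders), function(fi) {
      list(gene_ids = annotation$gene_id[conf_global[[fi]]])
    }))
  structure(list(annotation = annotation, expression = expression,
                 segments = segments, manifest = manifest, truth = truth,
                 config = cfg, files = NULL),
            class = "cocna_sim")
}

# Segments for one cohort's samples. Baseline: Poisson-many random breakpoints
# per chromosome, segment means ~ N(0, cna_noise_sd). A firing event carves
# its region out of the baseline and inserts one segment at the signed effect
# (plus segment noise). Plain vector accumulation keeps this fast.
.sample_segments <- function(samples, nchr, chrom_len, cfg, fires, annotation, is_tumor) {
  ev_by_chr <- split(seq_along(cfg$events),
                     vapply(cfg$events, function(e) e$chromosome, numeric(1)))
  spacing <- 100000L
  gene_len <- 50000L
  acc_sample <- list(); acc_chr <- list()
  acc_start <- list(); acc_end <- list(); acc_mean <- list()
  j <- 0L
  for (si in seq_along(samples)) {
    for (chr in seq_len(nchr)) {
      nb <- rpois(1L, cfg$segments_per_chromosome - 1)
      bp <- sort(unique(1L + floor(runif(nb) * (chrom_len - 2L))))
      st <- c(1L, bp)
      en <- c(bp - 1L, chrom_len)
      mn <- rnorm(length(st), 0, cfg$cna_noise_sd)
      for (ei in ev_by_chr[[as.character(chr)]]) {
        if (!is_tumor[si] || !fires[ei, si]) next
        ev <- cfg$events[[ei]]
        g <- range(ev$genes)
        from <- (g[1] - 1L) * spacing + 1L
        to <- (g[2] - 1L) * spacing + gene_len
        eff <- if (ev$direction == "amp") ev$effect else -ev$effect
        value <- eff + rnorm(1L, 0, cfg$cna_noise_sd)
        # clip neighbours, insert one event segment
        keepL <- st < from
        keepR <- en > to
        stL <- st[keepL]; enL <- pmin(en[keepL], from - 1L); mnL <- mn[keepL]
        okL <- stL <= enL
        stR <- pmax(st[keepR], to + 1L); enR <- en[keepR]; mnR <- mn[keepR]
        okR <- stR <= enR
        st <- c(stL[okL], from, stR[okR])
        en <- c(enL[okL], to, enR[okR])
        mn <- c(mnL[okL], value, mnR[okR])
        o <- order(st)
        st <- st[o]; en <- en[o]; mn <- mn[o]
      }
      j <- j + 1L
      acc_sample[[j]] <- rep(samples[si], length(st))
      acc_chr[[j]] <- rep(paste0("chr", chr), length(st))
      acc_start[[j]] <- st; acc_end[[j]] <- en; acc_mean[[j]] <- mn
    }
  }
  data.frame(sample = unlist(acc_sample, use.names = FALSE),
             chromosome = unlist(acc_chr, use.names = FALSE),
             start = unlist(acc_start, use.names = FALSE),
             end = unlist(acc_end, use.names = FALSE),
             seg_mean = unlist(acc_mean, use.names = FALSE),
             stringsAsFactors = FALSE)
}

.write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (co in names(sim$expression)) {
    p <- file.path(dir, paste0("expression_", co, ".tsv"))
    df <- data.frame(gene_id = rownames(sim$expression[[co]]),
                     sim$expression[[co]], check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files$expression[[co]] <- p
  }
  files$segments <- file.path(dir, "segments.tsv")
  seg <- sim$segments
  names(seg) <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  utils::write.table(seg, files$segments, sep = "\t", quote = FALSE, row.names = FALSE)
  files$annotation <- file.path(dir, "annotation.tsv")
  utils::write.table(sim$annotation[, c("gene_id", "chromosome", "start", "end")],
                     files$annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  files$manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(sim$manifest, files$manifest)
  files
}

#' Build a [cohort_set()] directly from a simulation
#'
#' Convenience wrapper equivalent to writing the simulated files and reading
#' them back through the I/O layer.
#'
#' @param sim A `cocna_sim` from [simulate_cohorts()].
#' @return A `cocna_cohorts` object.
#' @export
as_cohort_set <- function(sim) {
  cohort_set(sim$expression, sim$segments, sim$annotation, sim$manifest)
}

#' Score recovery of planted events
#'
#' A planted event is recovered when some driver call's chromosomal range
#' overlaps the event's gene range in the matching direction. Precision is
#' the fraction of driver calls that overlap some event correctly (NA when
#' there are no driver calls), recall the fraction of events recovered, and
#' each event additionally gets the Jaccard index between the best-matching
#' call's member genes (weight above the range threshold) and the planted
#' member genes.
#'
#' @param truth The `truth` element of a `cocna_sim`.
#' @param fit A `cocna` fit (or a list with `calls` and `signatures`).
#' @return List with `precision`, `recall`, `jaccard` (per event), and the
#'   per-event/per-call match tables.
#' @export
score_recovery <- function(truth, fit) {
  calls <- fit$calls
  sigs <- fit$signatures
  events <- truth$events
  if (!length(events)) {
    return(list(precision = NA_real_, recall = NA_real_, jaccard = numeric(0)))
  }
  drv <- which(calls$is_driver)
  ev_hit <- logical(length(events))
  jac <- rep(NA_real_, length(events))
  call_hit <- logical(length(drv))
  for (ei in seq_along(events)) {
    ev <- events[[ei]]
    for (k in seq_along(drv)) {
      i <- drv[k]
      sig <- sigs[[i]]
      dir_ok <- (ev$direction == "amp" && calls$is_pan_amp[i]) ||
                (ev$direction == "del" && calls$is_pan_del[i])
      if (!dir_ok || sig$range$chromosome != ev$chromosome) next
      members <- names(sig$weights)[sig$weights > 0.5]
      if (!any(members %in% ev$gene_ids)) next
      ev_hit[ei] <- TRUE
      call_hit[k] <- TRUE
      j <- length(intersect(members, ev$gene_ids)) / length(union(members, ev$gene_ids))
      if (is.na(jac[ei]) || j > jac[ei]) jac[ei] <- j
    }
  }
  list(precision = if (!length(drv)) NA_real_ else mean(call_hit),
       recall = mean(ev_hit),
       jaccard = jac,
       events_recovered = ev_hit)
}
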