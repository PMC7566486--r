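#' Write fit outputs as plain-text files
#'
#' Emits, under `dir`: `signatures.tsv` (one row per signature gene with
#' weight and top-five flag), `signature_ranges.bed` (0-based half-open BED of
#' signature ranges), `signatures_summary.tsv`, `calls.tsv`,
#' `co_alterations.tsv`, and `run_manifest.json` (configuration snapshot,
#' funnel counts, thresholds, and md5 checksums of every written file).
#'
#' @param fit A `cocna` fit.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cocna <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- fit$cohorts$annotation
  paths <- c(signatures = file.path(dir, "signatures.tsv"),
             bed = file.path(dir, "signature_ranges.bed"),
             summary = file.path(dir, "signatures_summary.tsv"),
             calls = file.path(dir, "calls.tsv"),
             co = file.path(dir, "co_alterations.tsv"),
             manifest = file.path(dir, "run_manifest.json"))

  gene_rows <- lapply(fit$signatures, function(sig) {
    g <- names(sig$weights)
    i <- match(g, ann$gene_id)
    top5 <- names(sort(sig$weights, decreasing = TRUE))[seq_len(min(5L, length(sig$weights)))]
    data.frame(signature = sig$name, gene_id = g,
               chromosome = ann$chromosome[i], start = ann$start[i], end = ann$end[i],
               weight = unname(sig$weights), is_top5 = g %in% top5,
               stringsAsFactors = FALSE)
  })
  gene_df <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(signature = character(0), gene_id = character(0), chromosome = character(0),
               start = integer(0), end = integer(0), weight = numeric(0), is_top5 = logical(0))
  utils::write.table(gene_df, paths[["signatures"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  bed <- lapply(fit$signatures, function(sig) {
    sprintf("%s\t%d\t%d\t%s\t%d", sig$range$chromosome, sig$range$start_bp - 1L,
            sig$range$end_bp, sig$name, round(1000 * sig$strength))
  })
  writeLines(unlist(bed), paths[["bed"]])

  sum_df <- do.call(rbind, lapply(fit$signatures, function(sig) {
    data.frame(name = sig$name, chromosome = sig$range$chromosome,
               start_bp = sig$range$start_bp, end_bp = sig$range$end_bp,
               strength = sig$strength, n_members = sig$range$n_members,
               converged = sig$converged, stringsAsFactors = FALSE)
  }))
  if (is.null(sum_df)) sum_df <- data.frame(name = character(0))
  utils::write.table(sum_df, paths[["summary"]], sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(fit$calls, paths[["calls"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$co_alterations, paths[["co"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cocna")),
    config = list(attractor = unclass(fit$config$attractor),
                  association = unclass(fit$config$association),
                  calls = unclass(fit$config$calls)),
    thresholds = fit$thresholds[c("t_amp", "t_del")],
    funnel = as.list(fit$funnel),
    checksums = as.list(tools::md5sum(unname(paths[names(paths) != "manifest"]))))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Run the end-to-end pipeline from a configuration file
#'
#' Orchestrates preprocess, discovery, calling and reporting in one call,
#' from a YAML configuration. The configuration either names input files —
#' `expression` (cohort -> TSV path), `segments`, `annotation`, `manifest` —
#' or a synthetic `profile` (`"clean"`, `"realistic"`, `"null"`) to generate.
#' Optional keys override defaults of [attractor_config()], [assoc_config()]
#' and [call_config()] (e.g. `window_size`, `n_permutations`), `rng_seed`
#' seeds all randomness, and `thresholds: {t_amp: ..., t_del: ...}` bypasses
#' normal-sample derivation.
#'
#' Outputs are written via [write_cocna()]; re-running with an identical
#' configuration and seed reproduces identical files.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (default: `output` key, or tempdir).
#' @param verbose Narrate progress.
#' @return The `cocna` fit, invisibly, with `out_files` attached.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(out_dir)) out_dir <- cfg$output %||% tempfile("cocna_run_")
  seed <- as.integer(cfg$rng_seed %||% 1L)

  take <- function(f, keys) do.call(f, cfg[intersect(keys, names(cfg))])
  acfg <- take(attractor_config,
               c("window_size", "alpha", "epsilon", "strength_threshold",
                 "range_weight_threshold", "max_iterations"))
  mcfg <- take(assoc_config, c("n_bins", "spline_order"))
  ccfg <- take(call_config, c("n_permutations", "percentile", "t_freq",
                              "min_types", "co_cna_diff", "top_k"))
  if (!is.null(cfg$alpha_level)) ccfg$alpha <- cfg$alpha_level
  ccfg$rng_seed <- seed

  sim <- NULL
  if (!is.null(cfg$profile)) {
    sim <- simulate_cohorts(synthetic_profile(cfg$profile, rng_seed = seed))
    cohorts <- as_cohort_set(sim)
  } else {
    for (key in c("expression", "segments", "annotation", "manifest")) {
      if (is.null(cfg[[key]])) stop("config must name input files or a synthetic profile; missing: ", key)
    }
    paths <- c(unlist(cfg$expression), cfg$segments, cfg$annotation, cfg$manifest)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("input file(s) not found: ", paste(missing, collapse = ", "))
    expr <- lapply(cfg$expression, read_expression)
    cohorts <- cohort_set(expr, read_segments(cfg$segments),
                          read_annotation(cfg$annotation), read_manifest(cfg$manifest))
  }

  thresholds <- NULL
  if (!is.null(cfg$thresholds)) {
    thresholds <- list(t_amp = cfg$thresholds$t_amp, t_del = cfg$thresholds$t_del)
  }
  fit <- cocna(cohorts, attractor = acfg, association = mcfg, calls = ccfg,
               thresholds = thresholds, verbose = verbose)
  paths <- write_cocna(fit, out_dir)
  if (!is.null(sim)) {
    rec <- score_recovery(sim$truth, fit)
    if (verbose) message(sprintf("recovery vs planted truth: precision %.2f, recall %.2f",
                                 rec$precision, rec$recall))
    attr(fit, "recovery") <- rec
  }
  attr(fit, "out_files") <- paths
  if (verbose) message("outputs written to ", out_dir)
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
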