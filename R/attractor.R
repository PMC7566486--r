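#' Attractor discovery configuration
#'
#' Tuning parameters for the genomically co-localized attractor metagene
#' algorithm.
#'
#' @param window_size Number of flanking genes considered around each seed
#'   (`window_size / 2` on each side, truncated at chromosome ends), so a full
#'   window holds `window_size + 1` genes. Default 150.
#' @param alpha Exponent applied to (positive) gene weights when mixing
#'   expression rows into the metagene; larger values sharpen the signature.
#'   Default 2.
#' @param epsilon Convergence tolerance on the max absolute change of the
#'   weight vector between iterations. Default 1e-7.
#' @param strength_threshold Minimum strength (fifth-highest gene weight) for
#'   a converged attractor to survive, guaranteeing at least five strongly
#'   co-expressed genes. Default 0.5.
#' @param range_weight_threshold Weight above which a gene counts as a member
#'   when delimiting the signature's chromosomal range. Default 0.5.
#' @param max_iterations Iteration cap; runs hitting it are flagged
#'   non-converged. Default 100.
#' @return An object of class `attractor_config`.
#' @export
attractor_config <- function(window_size = 150L, alpha = 2, epsilon = 1e-7,
                             strength_threshold = 0.5, range_weight_threshold = 0.5,
                             max_iterations = 100L) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 10L || window_size %% 2L != 0L) {
    stop("window_size must be an even integer >= 10")
  }
  if (alpha <= 0) stop("alpha must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (strength_threshold <= 0 || strength_threshold >= 1) stop("strength_threshold must be in (0,1)")
  if (range_weight_threshold <= 0 || range_weight_threshold >= 1) {
    stop("range_weight_threshold must be in (0,1)")
  }
  structure(list(window_size = window_size, alpha = alpha, epsilon = epsilon,
                 strength_threshold = strength_threshold,
                 range_weight_threshold = range_weight_threshold,
                 max_iterations = as.integer(max_iterations)),
            class = "attractor_config")
}

# Precompute per-cohort basis stacks for all genes; cohorts with fewer than 8
# samples are excluded (with renormalized weights), mirroring
# pan_cancer_association().
.build_ctx <- function(cohorts, assoc_cfg) {
  ns <- vapply(cohorts$cohorts, function(co) ncol(co$expression), integer(1))
  keep <- ns >= 8L
  if (!any(keep)) stop("every cohort has fewer than 8 samples")
  if (!all(keep)) {
    warning(sprintf("excluding %d cohort(s) with fewer than 8 samples from association",
                    sum(!keep)))
  }
  idx <- which(keep)
  blocks <- lapply(idx, function(i) .mi_block(cohorts$cohorts[[i]]$expression, assoc_cfg))
  list(blocks = blocks,
       E = lapply(idx, function(i) cohorts$cohorts[[i]]$expression),
       weights = cohorts$weights[idx] / sum(cohorts$weights[idx]),
       cfg = assoc_cfg)
}

# Pan-cancer association of a per-cohort metagene list against genes `idx`.
.pan_assoc_vs_genes <- function(metas, ctx, idx) {
  W <- vapply(seq_along(ctx$blocks), function(c) {
    .assoc_vs_block(metas[[c]], ctx$blocks[[c]], idx, ctx$cfg)
  }, numeric(length(idx)))
  W <- matrix(W, nrow = length(idx))
  .row_weighted_median(W, ctx$weights)
}

# Sliding window around ordered position `pos` (global annotation row index):
# up to S/2 genes each side, truncated at the chromosome boundary.
.gene_window <- function(annotation, pos, window_size) {
  chr <- annotation$chromosome[pos]
  on_chr <- which(annotation$chromosome == chr)
  k <- match(pos, on_chr)
  half <- window_size %/% 2L
  on_chr[max(1L, k - half):min(length(on_chr), k + half)]
}

# Core iteration over global gene indices. Returns a cocna_signature or a
# degenerate stub (strength 0) when no gene is positively associated.
.attractor_core <- function(seed_pos, win_pos, ctx, annotation, cfg) {
  metas <- lapply(ctx$E, function(E) E[seed_pos, ])
  w <- .pan_assoc_vs_genes(metas, ctx, win_pos)
  converged <- FALSE
  iters <- 0L
  repeat {
    iters <- iters + 1L
    f <- pmax(w, 0)^cfg$alpha
    tot <- sum(f)
    if (tot <= 0) {
      return(.degenerate_signature(seed_pos, win_pos, annotation))
    }
    fw <- f / tot
    metas <- lapply(ctx$E, function(E) as.vector(fw %*% E[win_pos, , drop = FALSE]))
    w_new <- .pan_assoc_vs_genes(metas, ctx, win_pos)
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < cfg$epsilon) {
      converged <- TRUE
      break
    }
    if (iters >= cfg$max_iterations) break
  }
  .make_signature(seed_pos, win_pos, w, metas, converged, iters, annotation, cfg)
}

.degenerate_signature <- function(seed_pos, win_pos, annotation) {
  structure(list(name = annotation$gene_id[seed_pos],
                 seed = annotation$gene_id[seed_pos],
                 window_genes = annotation$gene_id[win_pos],
                 weights = setNames(rep(0, length(win_pos)), annotation$gene_id[win_pos]),
                 strength = 0, converged = TRUE, n_iter = 0L,
                 degenerate = TRUE, range = NULL, metagene = NULL,
                 window_idx = win_pos),
            class = "cocna_signature")
}

.make_signature <- function(seed_pos, win_pos, w, metas, converged, iters, annotation, cfg) {
  names(w) <- annotation$gene_id[win_pos]
  top <- win_pos[which.max(w)]
  strength <- sort(w, decreasing = TRUE)[min(5L, length(w))]
  memb <- win_pos[w > cfg$range_weight_threshold]
  if (!length(memb)) memb <- top
  rng <- list(chromosome = annotation$chromosome[top],
              start_idx = min(memb), end_idx = max(memb),
              first_gene = annotation$gene_id[min(memb)],
              last_gene = annotation$gene_id[max(memb)],
              start_bp = min(annotation$start[memb]),
              end_bp = max(annotation$end[memb]),
              n_members = length(memb))
  structure(list(name = annotation$gene_id[top],
                 seed = annotation$gene_id[seed_pos],
                 window_genes = annotation$gene_id[win_pos],
                 weights = w,
                 strength = strength,
                 converged = converged,
                 n_iter = iters,
                 degenerate = FALSE,
                 range = rng,
                 metagene = metas,
                 window_idx = win_pos),
            class = "cocna_signature")
}

#' @export
print.cocna_signature <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("Degenerate attractor (seed %s): no positively associated gene\n", x$seed))
    return(invisible(x))
  }
  top <- sort(x$weights, decreasing = TRUE)[seq_len(min(5L, length(x$weights)))]
  cat(sprintf("Attractor signature %s  (strength %.3f, %s:%d-%d, %d member genes%s)\n",
              x$name, x$strength, x$range$chromosome, x$range$start_bp, x$range$end_bp,
              x$range$n_members, if (x$converged) "" else ", NOT converged"))
  cat("  top genes:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Run the attractor iteration from one seed
#'
#' Starting from the seed gene's expression as the metagene, alternately
#' (a) scores every window gene by its pan-cancer association with the
#' metagene and (b) rebuilds the per-cohort metagene as the weighted average
#' of window-gene expression with mixing coefficients
#' `max(weight, 0)^alpha / sum(...)`, until the weight vector changes by less
#' than `epsilon` (sup norm) or `max_iterations` is hit (flagged
#' non-converged). Negative associations get zero mixing weight: dosage-driven
#' signatures are positively co-expressed.
#'
#' @param seed_gene Gene id of the seed (must lie in `window_genes`).
#' @param window_genes Gene ids forming the window (annotation order).
#' @param cohorts A [cohort_set()].
#' @param cfg An [attractor_config()].
#' @param assoc_cfg An [assoc_config()].
#' @return A `cocna_signature`: weights, name (highest-weight gene), strength
#'   (fifth-highest weight), chromosomal range (genes with weight above
#'   `range_weight_threshold`), per-cohort metagene vectors and convergence
#'   flags. If no window gene is positively associated the result is a
#'   degenerate signature with strength 0.
#' @export
iterate_attractor <- function(seed_gene, window_genes, cohorts,
                              cfg = attractor_config(), assoc_cfg = assoc_config()) {
  ann <- cohorts$annotation
  win_pos <- match(window_genes, ann$gene_id)
  if (anyNA(win_pos)) stop("window contains genes absent from the annotation")
  seed_pos <- match(seed_gene, ann$gene_id)
  if (is.na(seed_pos) || !(seed_pos %in% win_pos)) stop("seed_gene must be in window_genes")
  ctx <- .build_ctx_subset(cohorts, assoc_cfg, win_pos)
  # ctx holds only the window genes; remap indices
  sub <- match(win_pos, win_pos)
  sig <- .attractor_core(match(seed_pos, win_pos), sub, ctx,
                         ann[win_pos, , drop = FALSE], cfg)
  sig$window_idx <- win_pos
  if (!is.null(sig$range)) {
    sig$range$start_idx <- win_pos[sig$range$start_idx]
    sig$range$end_idx <- win_pos[sig$range$end_idx]
  }
  sig
}

# Context restricted to a subset of genes (cheap for one-off windows).
.build_ctx_subset <- function(cohorts, assoc_cfg, gene_idx) {
  sub <- cohorts
  sub$cohorts <- lapply(cohorts$cohorts, function(co) {
    co$expression <- co$expression[gene_idx, , drop = FALSE]
    co
  })
  .build_ctx(sub, assoc_cfg)
}

#' First discovery pass: every gene seeds its window
#'
#' Runs the attractor iteration once per annotated gene, each within its own
#' sliding window (windows never cross chromosome boundaries), and keeps the
#' converged attractors whose strength reaches `strength_threshold` — i.e.
#' those with at least five strongly co-expressed genes.
#'
#' @inheritParams iterate_attractor
#' @param ctx Optional precomputed association context (internal reuse).
#' @return List of surviving `cocna_signature` objects, one per seed that
#'   produced one.
#' @export
first_pass <- function(cohorts, cfg = attractor_config(), assoc_cfg = assoc_config(),
                       ctx = NULL) {
  ann <- cohorts$annotation
  if (is.null(ctx)) ctx <- .build_ctx(cohorts, assoc_cfg)
  out <- vector("list", nrow(ann))
  n_nonconv <- 0L
  for (pos in seq_len(nrow(ann))) {
    win <- .gene_window(ann, pos, cfg$window_size)
    sig <- .attractor_core(pos, win, ctx, ann, cfg)
    if (!sig$converged) n_nonconv <- n_nonconv + 1L
    if (!sig$degenerate && sig$strength >= cfg$strength_threshold) out[[pos]] <- sig
  }
  if (n_nonconv > 0L) {
    warning(sprintf("%d of %d seeded runs did not converge within max_iterations",
                    n_nonconv, nrow(ann)))
  }
  Filter(Negate(is.null), out)
}

#' Merge overlapping signature ranges into clusters
#'
#' Takes the chromosomal ranges of surviving attractors and merges every
#' transitively overlapping group on the same chromosome into one cluster
#' whose range is the union (first to last member gene).
#'
#' @param signatures List of `cocna_signature` objects.
#' @param annotation Sorted annotation (defines the gene index).
#' @return List of clusters, each `list(chromosome, start_idx, end_idx,
#'   gene_ids, members)` where `members` are the contributing signature names.
#' @export
merge_ranges <- function(signatures, annotation) {
  if (!length(signatures)) return(list())
  df <- data.frame(chr = vapply(signatures, function(s) s$range$chromosome, character(1)),
                   lo = vapply(signatures, function(s) s$range$start_idx, numeric(1)),
                   hi = vapply(signatures, function(s) s$range$end_idx, numeric(1)),
                   nm = vapply(signatures, function(s) s$name, character(1)),
                   stringsAsFactors = FALSE)
  ord <- order(.chrom_rank(df$chr), df$lo, df$hi)
  df <- df[ord, , drop = FALSE]
  clusters <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    if (!is.null(cur) && df$chr[i] == cur$chromosome && df$lo[i] <= cur$end_idx) {
      cur$end_idx <- max(cur$end_idx, df$hi[i])
      cur$members <- c(cur$members, df$nm[i])
    } else {
      if (!is.null(cur)) clusters[[length(clusters) + 1L]] <- cur
      cur <- list(chromosome = df$chr[i], start_idx = df$lo[i], end_idx = df$hi[i],
                  members = df$nm[i])
    }
  }
  clusters[[length(clusters) + 1L]] <- cur
  lapply(clusters, function(cl) {
    cl$gene_ids <- annotation$gene_id[cl$start_idx:cl$end_idx]
    cl
  })
}

# TRUE when two signatures are the same attractor: same name gene and sup-norm
# weight distance < 1e-4 over their common genes.
.same_signature <- function(a, b, tol = 1e-4) {
  if (a$name != b$name) return(FALSE)
  common <- intersect(names(a$weights), names(b$weights))
  if (!length(common)) return(FALSE)
  max(abs(a$weights[common] - b$weights[common])) < tol
}

#' Second pass: one representative attractor per cluster
#'
#' Re-runs the attractor iteration inside each merged cluster, seeding from
#' every gene in the cluster's range and considering only those genes.
#' Distinct converged attractors are deduplicated (same name gene, sup-norm
#' weight distance < 1e-4) and the highest-strength one represents the
#' cluster; ties go to the leftmost seed. A cluster whose every re-seeded run
#' is degenerate is dropped with a warning.
#'
#' @param clusters Output of [merge_ranges()].
#' @inheritParams first_pass
#' @return List of representative `cocna_signature` objects, one per
#'   surviving cluster.
#' @export
second_pass <- function(clusters, cohorts, cfg = attractor_config(),
                        assoc_cfg = assoc_config(), ctx = NULL) {
  ann <- cohorts$annotation
  if (is.null(ctx)) ctx <- .build_ctx(cohorts, assoc_cfg)
  out <- list()
  for (cl in clusters) {
    win <- cl$start_idx:cl$end_idx
    best <- NULL
    for (pos in win) {
      sig <- .attractor_core(pos, win, ctx, ann, cfg)
      if (sig$degenerate || !sig$converged) next
      if (is.null(best) || sig$strength > best$strength) best <- sig
      # ties keep the earlier (leftmost) seed: strict > above
    }
    if (is.null(best)) {
      warning(sprintf("cluster %s:%d-%d yielded no usable attractor; dropped",
                      cl$chromosome, cl$start_idx, cl$end_idx))
      next
    }
    dup <- any(vapply(out, .same_signature, logical(1), b = best))
    if (!dup) out[[length(out) + 1L]] <- best
  }
  out
}

#' Final signature filters
#'
#' Removes signatures whose top five genes are unreliably measured — any of
#' them having raw expression 0 in more than half of the pooled tumor
#' samples — and removes gender-driven signatures whose range lies on
#' chromosome X or Y.
#'
#' @param signatures List of `cocna_signature` objects.
#' @param cohorts A [cohort_set()] (supplies the raw expression matrices).
#' @return The retained signatures.
#' @export
final_filters <- function(signatures, cohorts) {
  if (!length(signatures)) return(signatures)
  n_tot <- sum(vapply(cohorts$cohorts, function(co) ncol(co$raw), integer(1)))
  zero_counts <- Reduce(`+`, lapply(cohorts$cohorts, function(co) rowSums(co$raw == 0)))
  zero_frac <- zero_counts / n_tot
  keep <- vapply(signatures, function(sig) {
    if (.is_sex_chrom(sig$range$chromosome)) return(FALSE)
    top5 <- names(sort(sig$weights, decreasing = TRUE))[seq_len(min(5L, length(sig$weights)))]
    all(zero_frac[top5] <= 0.5)
  }, logical(1))
  signatures[keep]
}

#' Discover genomically co-localized signatures
#'
#' The full discovery stage: first pass over every seed gene, range merging,
#' second pass picking one representative per cluster, then the final
#' expression-support and sex-chromosome filters.
#'
#' @inheritParams first_pass
#' @param verbose Narrate the discovery funnel via [message()].
#' @return List with `signatures` (the final list) and `funnel` (named counts
#'   for each stage).
#' @export
discover_signatures <- function(cohorts, cfg = attractor_config(),
                                assoc_cfg = assoc_config(), verbose = TRUE) {
  ctx <- .build_ctx(cohorts, assoc_cfg)
  fp <- first_pass(cohorts, cfg, assoc_cfg, ctx = ctx)
  if (verbose) message(sprintf("first pass: %d attractors with strength >= %.2f",
                               length(fp), cfg$strength_threshold))
  cl <- merge_ranges(fp, cohorts$annotation)
  if (verbose) message(sprintf("merged into %d chromosomal range clusters", length(cl)))
  sp <- second_pass(cl, cohorts, cfg, assoc_cfg, ctx = ctx)
  fin <- final_filters(sp, cohorts)
  if (verbose) message(sprintf("second pass: %d representatives; %d after final filters",
                               length(sp), length(fin)))
  list(signatures = fin,
       funnel = c(first_pass = length(fp), clusters = length(cl),
                  second_pass = length(sp), final = length(fin)))
}
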