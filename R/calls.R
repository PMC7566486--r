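#' Driver-calling configuration
#'
#' @param n_permutations Number of within-cohort permutations for the
#'   expression/CNA association null. Default 10000.
#' @param alpha Significance level on the Bonferroni-adjusted permutation P.
#'   Default 0.05.
#' @param percentile Tail percentile (percent) of centered normal-sample CNA
#'   used to derive the amplification/deletion thresholds. Default 10.
#' @param t_freq Per-cohort alteration frequency a signature must strictly
#'   exceed to count as amplified/deleted in that cancer type. Default 0.03.
#' @param min_types A signature is on a pan-cancer amplicon (deleted region)
#'   when it is amplified (deleted) in strictly more than this many cancer
#'   types. Default 6.
#' @param co_cna_diff Two adjacent signatures are co-altered in a sample when
#'   their CNA levels differ by strictly less than this. Default 0.1.
#' @param top_k Number of top-weight genes averaged into a signature's
#'   expression/CNA level. Default 5.
#' @param rng_seed Seed for the permutation RNG.
#' @return An object of class `call_config`.
#' @export
call_config <- function(n_permutations = 10000L, alpha = 0.05, percentile = 10,
                        t_freq = 0.03, min_types = 6L, co_cna_diff = 0.1,
                        top_k = 5L, rng_seed = 1L) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 100L) stop("n_permutations must be >= 100")
  if (t_freq <= 0 || t_freq >= 1) stop("t_freq must be in (0, 1)")
  if (percentile <= 0 || percentile >= 50) stop("percentile must be in (0, 50)")
  structure(list(n_permutations = n_permutations, alpha = alpha, percentile = percentile,
                 t_freq = t_freq, min_types = as.integer(min_types),
                 co_cna_diff = co_cna_diff, top_k = as.integer(top_k),
                 rng_seed = as.integer(rng_seed)),
            class = "call_config")
}

#' Per-cohort expression and CNA levels of a signature
#'
#' The signature's level in a sample is the unweighted mean of its `top_k`
#' highest-weight genes — applied to the normalized expression matrix for the
#' expression level and to the gene-level CNA matrix for the CNA level.
#'
#' @param sig A `cocna_signature`.
#' @param cohorts A [cohort_set()].
#' @param top_k Number of top genes averaged (default 5).
#' @return List with per-cohort lists `expr` and `cna` of sample-indexed
#'   vectors, plus `top_genes`.
#' @export
signature_levels <- function(sig, cohorts, top_k = 5L) {
  top <- names(sort(sig$weights, decreasing = TRUE))[seq_len(min(top_k, length(sig$weights)))]
  expr <- lapply(cohorts$cohorts, function(co) {
    colMeans(co$expression[top, , drop = FALSE])
  })
  cna <- lapply(cohorts$cohorts, function(co) {
    miss <- setdiff(top, rownames(co$cna))
    if (length(miss)) stop(sprintf("gene %s missing from the CNA matrix of cohort %s",
                                   miss[1L], co$name))
    colMeans(co$cna[top, , drop = FALSE])
  })
  list(expr = expr, cna = cna, top_genes = top)
}

#' Permutation test of the expression/CNA association
#'
#' The observed statistic is the pan-cancer (weighted-median) normalized-MI
#' association between a signature's expression and CNA levels. The null is
#' built by permuting the sample order of the CNA level within each cohort
#' `n_permutations` times (expression fixed, both marginals preserved),
#' sorting each cohort's null associations, and taking the weighted median
#' across cohorts rank by rank to obtain a pan-cancer null distribution. The
#' P value uses the add-one estimator `(1 + #{null > observed}) /
#' (n_permutations + 1)`, which cannot return 0 from finite permutations.
#'
#' Cohorts with fewer than 8 samples are excluded with a warning (weights
#' renormalized), mirroring [pan_cancer_association()].
#'
#' @param levels Output of [signature_levels()] (or any list with per-cohort
#'   `expr` and `cna` vectors).
#' @param weights Per-cohort weights.
#' @param cfg A [call_config()]; `n_permutations` and `rng_seed` are used.
#'   The RNG seed is applied via a local seed so the call is reproducible
#'   without disturbing the caller's RNG stream.
#' @param assoc_cfg An [assoc_config()].
#' @return List with `assoc` (observed) and `p_raw`.
#' @export
permutation_test <- function(levels, weights, cfg = call_config(),
                             assoc_cfg = assoc_config()) {
  np <- cfg$n_permutations
  ns <- vapply(levels$expr, length, integer(1))
  keep <- ns >= 8L
  if (!any(keep)) stop("every cohort has fewer than 8 samples")
  if (!all(keep)) {
    warning(sprintf("excluding %d cohort(s) with fewer than 8 samples", sum(!keep)))
  }
  expr <- levels$expr[keep]
  cna <- levels$cna[keep]
  w <- weights[keep] / sum(weights[keep])

  obs <- weighted_median(
    mapply(function(e, c) normalized_association(e, c, assoc_cfg), expr, cna),
    w)

  null_mat <- withr_seed(cfg$rng_seed, {
    vapply(seq_along(expr), function(ci) {
      sort(.permuted_assocs(expr[[ci]], cna[[ci]], np, assoc_cfg))
    }, numeric(np))
  })
  null_mat <- matrix(null_mat, nrow = np)
  pan_null <- .row_weighted_median(null_mat, w)
  list(assoc = obs, p_raw = (sum(pan_null > obs) + 1) / (np + 1))
}

# Evaluate set.seed()d code without disturbing the caller's RNG state.
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Normalized associations of e against np row-permutations of c, vectorised:
# one basis matrix per vector, one big crossprod per chunk of permutations.
.permuted_assocs <- function(e, c_vec, np, assoc_cfg) {
  n <- length(e)
  be <- .mi_basis(e, assoc_cfg)
  bc <- .mi_basis(c_vec, assoc_cfg)
  if (is.null(be) || is.null(bc)) return(rep(0, np))
  m <- assoc_cfg$n_bins
  he <- .entropy_raw(colSums(be) / n)
  hc <- .entropy_raw(colSums(bc) / n)
  self_e <- 2 * he - .entropy_raw(crossprod(be, be) / n)
  self_c <- 2 * hc - .entropy_raw(crossprod(bc, bc) / n)
  den <- max(self_e, self_c)
  if (den <= 0) return(rep(0, np))
  ec <- e - mean(e)
  cc <- c_vec - mean(c_vec)
  out <- numeric(np)
  chunk <- 1000L
  done <- 0L
  while (done < np) {
    nb <- min(chunk, np - done)
    perms <- replicate(nb, sample.int(n))                   # n x nb
    big <- bc[as.vector(perms), , drop = FALSE]             # (n*nb) x m
    # rearrange to n x (m*nb): permutation p occupies columns ((p-1)m+1):(pm)
    dim(big) <- c(n, nb * m)
    big <- big[, as.vector(t(matrix(seq_len(nb * m), nb, m))), drop = FALSE]
    hj <- .block_joint_entropy(be, big, n, m)
    mi <- he + hc - hj
    val <- mi / den
    r <- as.vector(crossprod(ec, matrix(cc[perms], n, nb)))
    val <- ifelse(r < 0, -val, val)
    out[done + seq_len(nb)] <- pmax(-1, pmin(1, val))
    done <- done + nb
  }
  out
}

#' Derive amplification/deletion thresholds from normal samples
#'
#' Each normal sample's gene-level CNA vector is centered by its own mean;
#' per cohort, all centered values are pooled and the amplification threshold
#' is the mean of the values at or above the `100 - percentile` quantile (the
#' deletion threshold symmetrically from the lower tail). The per-cohort
#' thresholds are aggregated with the weighted median. Cohorts without normal
#' samples are excluded with a warning; if no cohort has normals the
#' thresholds must be supplied via configuration instead and this function
#' errors.
#'
#' @param cohorts A [cohort_set()] with `normal_cna` matrices.
#' @param cfg A [call_config()] (uses `percentile`).
#' @return List with `t_amp` (> 0), `t_del` (< 0), and the per-cohort values.
#' @export
derive_thresholds <- function(cohorts, cfg = call_config()) {
  has <- vapply(cohorts$cohorts, function(co) !is.null(co$normal_cna) && ncol(co$normal_cna) > 0,
                logical(1))
  if (!any(has)) stop("no cohort has normal samples; supply thresholds via configuration")
  if (!all(has)) {
    warning(sprintf("%d cohort(s) without normal samples excluded from threshold derivation",
                    sum(!has)))
  }
  q <- cfg$percentile / 100
  per <- lapply(cohorts$cohorts[has], function(co) {
    centered <- sweep(co$normal_cna, 2L, colMeans(co$normal_cna))
    v <- as.vector(centered)
    hi <- stats::quantile(v, 1 - q, names = FALSE)
    lo <- stats::quantile(v, q, names = FALSE)
    c(amp = mean(v[v >= hi]), del = mean(v[v <= lo]))
  })
  amps <- vapply(per, `[[`, numeric(1), "amp")
  dels <- vapply(per, `[[`, numeric(1), "del")
  w <- cohorts$weights[has] / sum(cohorts$weights[has])
  t_amp <- weighted_median(amps, w)
  t_del <- weighted_median(dels, w)
  if (t_amp == 0 && t_del == 0) warning("degenerate thresholds: t_amp = t_del = 0")
  list(t_amp = t_amp, t_del = t_del, per_cohort_amp = amps, per_cohort_del = dels)
}

#' Classify per-cohort and pan-cancer alteration frequencies
#'
#' A signature's amplification frequency in a cohort is the fraction of tumor
#' samples whose CNA level strictly exceeds `t_amp` (deletion: strictly below
#' `t_del`). It counts as amplified in that cancer type when the frequency
#' strictly exceeds `t_freq`, and sits on a pan-cancer amplicon when
#' amplified in strictly more than `min_types` cancer types (deletions
#' symmetric).
#'
#' @param cna_levels Per-cohort list of CNA level vectors.
#' @param thresholds List with `t_amp` and `t_del`.
#' @param cfg A [call_config()].
#' @return List with per-cohort `amp_freq`/`del_freq`, counts
#'   `n_types_amp`/`n_types_del`, and flags `is_pan_amp`/`is_pan_del`.
#' @export
classify_frequencies <- function(cna_levels, thresholds, cfg = call_config()) {
  amp_freq <- vapply(cna_levels, function(v) mean(v > thresholds$t_amp), numeric(1))
  del_freq <- vapply(cna_levels, function(v) mean(v < thresholds$t_del), numeric(1))
  n_amp <- sum(amp_freq > cfg$t_freq)
  n_del <- sum(del_freq > cfg$t_freq)
  list(amp_freq = amp_freq, del_freq = del_freq,
       n_types_amp = n_amp, n_types_del = n_del,
       is_pan_amp = n_amp > cfg$min_types,
       is_pan_del = n_del > cfg$min_types)
}

#' Co-amplification / co-deletion of two adjacent signatures
#'
#' Over the pooled tumor samples in which at least one of the two signatures
#' is altered (CNA level beyond the direction's threshold), a sample is
#' co-altered when the two CNA levels differ by strictly less than
#' `co_cna_diff`. Also reports the pan-cancer association between the two
#' signatures' expression levels.
#'
#' @param levels_a,levels_b [signature_levels()] outputs for the two
#'   signatures (same cohorts).
#' @param direction `"amp"` or `"del"`.
#' @param thresholds List with `t_amp`, `t_del`.
#' @param weights Per-cohort weights.
#' @param cfg A [call_config()].
#' @param assoc_cfg An [assoc_config()].
#' @return List with `co_freq` (NA when no sample is altered in either) and
#'   `expr_assoc`.
#' @export
co_alteration <- function(levels_a, levels_b, direction = c("amp", "del"),
                          thresholds, weights, cfg = call_config(),
                          assoc_cfg = assoc_config()) {
  direction <- match.arg(direction)
  altered <- function(v) if (direction == "amp") v > thresholds$t_amp else v < thresholds$t_del
  n_either <- 0L
  n_co <- 0L
  for (ci in seq_along(levels_a$cna)) {
    va <- levels_a$cna[[ci]]
    vb <- levels_b$cna[[ci]]
    either <- altered(va) | altered(vb)
    n_either <- n_either + sum(either)
    n_co <- n_co + sum(either & (abs(va - vb) < cfg$co_cna_diff))
  }
  pairs <- mapply(function(a, b) list(a = a, b = b),
                  levels_a$expr, levels_b$expr, SIMPLIFY = FALSE)
  expr_assoc <- suppressWarnings(pan_cancer_association(pairs, weights, assoc_cfg))
  list(co_freq = if (n_either == 0L) NA_real_ else n_co / n_either,
       expr_assoc = expr_assoc,
       n_altered = n_either)
}

#' Designate driver signatures
#'
#' Applies the dual condition: a signature is a driver when its
#' Bonferroni-adjusted permutation P (multiplier = number of tested
#' signatures) is below `alpha` AND it sits on a pan-cancer amplicon or
#' deleted region.
#'
#' @param calls Data.frame with columns `p_raw`, `is_pan_amp`, `is_pan_del`
#'   (one row per tested signature).
#' @param cfg A [call_config()].
#' @return The data.frame with added `p_bonferroni`, `is_driver`, and
#'   `direction` (`"amp"`, `"del"`, `"amp+del"`, or `""`).
#' @export
designate_drivers <- function(calls, cfg = call_config()) {
  m <- nrow(calls)
  calls$p_bonferroni <- pmin(1, calls$p_raw * m)
  calls$is_driver <- calls$p_bonferroni < cfg$alpha & (calls$is_pan_amp | calls$is_pan_del)
  calls$direction <- ifelse(calls$is_pan_amp & calls$is_pan_del, "amp+del",
                     ifelse(calls$is_pan_amp, "amp",
                     ifelse(calls$is_pan_del, "del", "")))
  calls
}

#' Run the full driver-calling stage on discovered signatures
#'
#' Computes signature levels, the permutation association test, thresholds
#' (from normal samples unless supplied), frequency classification, driver
#' designation, and co-alteration of genomically adjacent co-directional
#' driver pairs.
#'
#' @param signatures List of `cocna_signature` objects.
#' @param cohorts A [cohort_set()].
#' @param cfg A [call_config()].
#' @param assoc_cfg An [assoc_config()].
#' @param thresholds Optional `list(t_amp=, t_del=)` overriding normal-sample
#'   derivation (for cohorts without normals).
#' @param verbose Narrate the calling funnel.
#' @return List with `calls` (data.frame), `thresholds`, `levels`,
#'   `co_alterations` (data.frame), and `funnel` counts.
#' @export
call_drivers <- function(signatures, cohorts, cfg = call_config(),
                         assoc_cfg = assoc_config(), thresholds = NULL,
                         verbose = TRUE) {
  if (is.null(thresholds)) {
    thresholds <- derive_thresholds(cohorts, cfg)
  } else {
    if (verbose) message(sprintf("using configured thresholds t_amp=%.3f t_del=%.3f",
                                 thresholds$t_amp, thresholds$t_del))
  }
  if (!length(signatures)) {
    return(list(calls = data.frame(), thresholds = thresholds, levels = list(),
                co_alterations = data.frame(),
                funnel = c(tested = 0L, assoc_pass = 0L, freq_pass = 0L, drivers = 0L)))
  }
  levels <- lapply(signatures, signature_levels, cohorts = cohorts, top_k = cfg$top_k)
  rows <- vector("list", length(signatures))
  for (i in seq_along(signatures)) {
    sig <- signatures[[i]]
    # one RNG stream per signature, offset from the configured seed
    sub_cfg <- cfg
    sub_cfg$rng_seed <- (cfg$rng_seed + i * 1009L) %% .Machine$integer.max
    pt <- permutation_test(levels[[i]], cohorts$weights, sub_cfg, assoc_cfg)
    fr <- classify_frequencies(levels[[i]]$cna, thresholds, cfg)
    rows[[i]] <- data.frame(name = sig$name,
                            chromosome = sig$range$chromosome,
                            start_bp = sig$range$start_bp,
                            end_bp = sig$range$end_bp,
                            strength = sig$strength,
                            n_members = sig$range$n_members,
                            assoc = pt$assoc, p_raw = pt$p_raw,
                            n_types_amp = fr$n_types_amp, n_types_del = fr$n_types_del,
                            is_pan_amp = fr$is_pan_amp, is_pan_del = fr$is_pan_del,
                            max_amp_freq = max(fr$amp_freq), max_del_freq = max(fr$del_freq),
                            stringsAsFactors = FALSE)
  }
  calls <- designate_drivers(do.call(rbind, rows), cfg)
  funnel <- c(tested = nrow(calls),
              assoc_pass = sum(calls$p_bonferroni < cfg$alpha),
              freq_pass = sum(calls$is_pan_amp | calls$is_pan_del),
              drivers = sum(calls$is_driver))
  if (verbose) {
    message(sprintf(
      "%d signatures tested; %d pass association (adjusted P < %.2g); %d pass frequency; %d drivers (%d amplified, %d deleted)",
      funnel["tested"], funnel["assoc_pass"], cfg$alpha, funnel["freq_pass"], funnel["drivers"],
      sum(calls$is_driver & calls$is_pan_amp), sum(calls$is_driver & calls$is_pan_del)))
  }
  co <- .adjacent_co_alterations(signatures, levels, calls, cohorts, thresholds, cfg, assoc_cfg)
  list(calls = calls, thresholds = thresholds, levels = levels,
       co_alterations = co, funnel = funnel)
}

# Co-alteration for consecutive driver signatures on the same chromosome
# called in the same direction.
.adjacent_co_alterations <- function(signatures, levels, calls, cohorts,
                                     thresholds, cfg, assoc_cfg) {
  out <- list()
  drv <- which(calls$is_driver)
  if (length(drv) < 2L) {
    return(data.frame(sig_a = character(0), sig_b = character(0),
                      direction = character(0), co_freq = numeric(0),
                      expr_assoc = numeric(0)))
  }
  starts <- vapply(signatures, function(s) s$range$start_idx, numeric(1))
  ord <- drv[order(.chrom_rank(calls$chromosome[drv]), starts[drv])]
  for (j in seq_len(length(ord) - 1L)) {
    a <- ord[j]; b <- ord[j + 1L]
    if (calls$chromosome[a] != calls$chromosome[b]) next
    dir_a <- if (calls$is_pan_amp[a]) "amp" else "del"
    dir_b <- if (calls$is_pan_amp[b]) "amp" else "del"
    if (dir_a != dir_b) next
    ca <- co_alteration(levels[[a]], levels[[b]], dir_a, thresholds,
                        cohorts$weights, cfg, assoc_cfg)
    out[[length(out) + 1L]] <- data.frame(sig_a = calls$name[a], sig_b = calls$name[b],
                                          direction = dir_a, co_freq = ca$co_freq,
                                          expr_assoc = ca$expr_assoc,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(sig_a = character(0), sig_b = character(0),
                      direction = character(0), co_freq = numeric(0),
                      expr_assoc = numeric(0)))
  }
  do.call(rbind, out)
}
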