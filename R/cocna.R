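#' Fit the co-localized signature / driver-CNA model
#'
#' The full estimator: discovers genomically co-localized attractor metagene
#' signatures in the multi-cohort expression data, then designates each as a
#' driver amplification or deletion when it passes both the permutation test
#' on its pan-cancer expression/CNA association and the cross-cohort
#' alteration-frequency rule.
#'
#' @param cohorts A [cohort_set()] (or a `cocna_sim`, converted via
#'   [as_cohort_set()]).
#' @param attractor An [attractor_config()].
#' @param association An [assoc_config()].
#' @param calls A [call_config()].
#' @param thresholds Optional `list(t_amp=, t_del=)` overriding the
#'   normal-sample derivation.
#' @param verbose Narrate the funnel (signatures found, association-passing,
#'   frequency-passing, drivers).
#' @return An object of class `cocna` with elements `signatures`, `calls`
#'   (data.frame), `thresholds`, `co_alterations`, `funnel`, `levels`, the
#'   configurations, and the input `cohorts`.
#' @seealso [summary.cocna()], [coef.cocna()], [plot.cocna()],
#'   [score_recovery()], [write_cocna()]
#' @examples
#' \donttest{
#' sim <- simulate_cohorts(synthetic_profile("clean", rng_seed = 7))
#' fit <- cocna(as_cohort_set(sim),
#'              attractor = attractor_config(window_size = 50),
#'              calls = call_config(n_permutations = 500, rng_seed = 7))
#' print(fit)
#' score_recovery(sim$truth, fit)
#' }
#' @export
cocna <- function(cohorts, attractor = attractor_config(),
                  association = assoc_config(), calls = call_config(),
                  thresholds = NULL, verbose = TRUE) {
  if (inherits(cohorts, "cocna_sim")) cohorts <- as_cohort_set(cohorts)
  if (!inherits(cohorts, "cocna_cohorts")) stop("cohorts must be a cohort_set()")
  disc <- discover_signatures(cohorts, attractor, association, verbose = verbose)
  called <- call_drivers(disc$signatures, cohorts, calls, association,
                         thresholds = thresholds, verbose = verbose)
  structure(list(signatures = disc$signatures,
                 calls = called$calls,
                 thresholds = called$thresholds,
                 co_alterations = called$co_alterations,
                 levels = called$levels,
                 funnel = c(disc$funnel, called$funnel),
                 config = list(attractor = attractor, association = association,
                               calls = calls),
                 cohorts = cohorts),
            class = "cocna")
}

#' @export
print.cocna <- function(x, ...) {
  f <- x$funnel
  cat("Genomically co-localized signature / driver-CNA fit\n")
  cat(sprintf("  cohorts: %d (%d tumor samples, %d genes)\n",
              length(x$cohorts$cohorts),
              sum(vapply(x$cohorts$cohorts, function(co) ncol(co$expression), integer(1))),
              nrow(x$cohorts$annotation)))
  cat(sprintf("  discovery funnel: %d seeded attractors -> %d clusters -> %d signatures\n",
              f[["first_pass"]], f[["clusters"]], f[["final"]]))
  cat(sprintf("  thresholds: t_amp = %.3f, t_del = %.3f\n",
              x$thresholds$t_amp, x$thresholds$t_del))
  if (nrow(x$calls)) {
    cat(sprintf("  calls: %d tested, %d association-passing, %d frequency-passing, %d drivers (%d amp, %d del)\n",
                f[["tested"]], f[["assoc_pass"]], f[["freq_pass"]], f[["drivers"]],
                sum(x$calls$is_driver & x$calls$is_pan_amp),
                sum(x$calls$is_driver & x$calls$is_pan_del)))
  } else {
    cat("  calls: no signatures survived discovery\n")
  }
  invisible(x)
}

#' Summarise a fit as a calls table
#'
#' @param object A `cocna` fit.
#' @param ... Unused.
#' @return The calls data.frame (one row per tested signature), ordered by
#'   genome position, with class `summary.cocna` for printing.
#' @export
summary.cocna <- function(object, ...) {
  df <- object$calls
  if (nrow(df)) {
    df <- df[order(.chrom_rank(df$chromosome), df$start_bp), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("summary.cocna", "data.frame")
  df
}

#' @export
print.summary.cocna <- function(x, ...) {
  df <- as.data.frame(x)
  if (!nrow(df)) {
    cat("No signatures.\n")
    return(invisible(x))
  }
  show <- data.frame(signature = df$name,
                     range = sprintf("%s:%d-%d", df$chromosome, df$start_bp, df$end_bp),
                     strength = round(df$strength, 3),
                     assoc = round(df$assoc, 3),
                     p_adj = signif(df$p_bonferroni, 3),
                     types_amp = df$n_types_amp,
                     types_del = df$n_types_del,
                     driver = ifelse(df$is_driver, df$direction, ""))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Gene weights of the fitted signatures
#'
#' @param object A `cocna` fit.
#' @param ... Unused.
#' @return Named list (signature name -> named weight vector over its window
#'   genes).
#' @export
coef.cocna <- function(object, ...) {
  out <- lapply(object$signatures, function(s) s$weights)
  names(out) <- vapply(object$signatures, function(s) s$name, character(1))
  out
}

#' Bar plot of one signature's gene weights
#'
#' Draws the per-gene association weights of a signature along its genomic
#' window — the standard way these signatures are displayed — marking the
#' membership threshold that delimits the chromosomal range.
#'
#' @param x A `cocna` fit.
#' @param signature Index or name of the signature to draw.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted weights.
#' @export
plot.cocna <- function(x, signature = 1L, ...) {
  if (!length(x$signatures)) stop("no signatures to plot")
  if (is.character(signature)) {
    signature <- match(signature, vapply(x$signatures, function(s) s$name, character(1)))
    if (is.na(signature)) stop("no signature of that name")
  }
  sig <- x$signatures[[signature]]
  w <- sig$weights
  cols <- ifelse(w > x$config$attractor$range_weight_threshold, "firebrick", "grey70")
  graphics::barplot(w, names.arg = names(w), las = 2, col = cols, border = NA,
                    cex.names = 0.5, ylab = "association weight",
                    main = sprintf("signature %s (%s)", sig$name, sig$range$chromosome),
                    ...)
  graphics::abline(h = x$config$attractor$range_weight_threshold, lty = 2)
  invisible(w)
}
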