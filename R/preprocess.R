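#' Read a gene annotation table
#'
#' Tab-separated file with columns `gene_id`, `chromosome`, `start`, `end`
#' (1-based inclusive coordinates). Returns the table sorted genome-wide by
#' (chromosome, midpoint), with ties broken by gene id, and a `midpoint`
#' column `floor((start + end) / 2)`. Chromosomes are ordered numerically
#' where possible (chr1, chr2, ..., chr10, ..., chrX, chrY).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns gene_id, chromosome, start, end, midpoint.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  sort_annotation(df[, c(need, intersect("band", names(df)))])
}

# Numeric-aware chromosome ordering.
.chrom_rank <- function(chrom) {
  base <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(base))
  num[base %in% c("X", "x")] <- 1e3
  num[base %in% c("Y", "y")] <- 1e3 + 1
  num[base %in% c("M", "MT", "m", "mt")] <- 1e3 + 2
  bad <- is.na(num)
  if (any(bad)) num[bad] <- 2e3 + as.integer(factor(base[bad], levels = sort(unique(base[bad]))))
  num
}

.is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom, ignore.case = TRUE) %in% c("X", "Y", "x", "y")
}

#' Sort an annotation data.frame in genome order
#'
#' Orders genes by (chromosome, midpoint, gene_id) — the total ordering used
#' to build sliding windows — adding the `midpoint` column if absent.
#'
#' @param annotation data.frame with gene_id, chromosome, start, end.
#' @return The sorted annotation with a midpoint column.
#' @export
sort_annotation <- function(annotation) {
  if (any(annotation$start > annotation$end)) stop("annotation has start > end")
  if (anyDuplicated(annotation$gene_id)) stop("duplicated gene_id in annotation")
  annotation$midpoint <- floor((annotation$start + annotation$end) / 2)
  ord <- order(.chrom_rank(annotation$chromosome), annotation$midpoint, annotation$gene_id)
  out <- annotation[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an expression matrix
#'
#' Tab-separated file whose first column holds gene ids and whose header row
#' holds sample ids; values are nonnegative abundances (FPKM-like).
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, genes in rows (named), samples in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Read a copy-number segment table
#'
#' SEG-like tab-separated file with columns `Sample`, `Chromosome`, `Start`,
#' `End`, `Segment_Mean` (case-insensitive; `sample_id`/`seg_mean` variants
#' accepted). Coordinates are 1-based inclusive; segment means are log2
#' ratios (0 = diploid).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns sample, chromosome, start, end, seg_mean.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  nm[nm %in% c("sample_id")] <- "sample"
  nm[nm %in% c("segment_mean", "seg.mean")] <- "seg_mean"
  names(df) <- nm
  need <- c("sample", "chromosome", "start", "end", "seg_mean")
  if (!all(need %in% nm)) {
    stop("segment table must have columns Sample, Chromosome, Start, End, Segment_Mean")
  }
  df[, need]
}

#' Read a cohort manifest
#'
#' YAML or JSON file mapping cohort name to `tumor` and `normal` sample-id
#' lists.
#'
#' @param path Path to the YAML/JSON file.
#' @return A named list; each element has character vectors `tumor`, `normal`.
#' @export
read_manifest <- function(path) {
  man <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(man, function(x) {
    list(tumor = as.character(unlist(x$tumor)),
         normal = as.character(unlist(x$normal)))
  })
}

#' Normalize an expression matrix
#'
#' Applies `log2(1 + X)` to a nonnegative raw matrix and quantile-normalizes
#' the sample columns (limma's `normalizeQuantiles`, which averages tied
#' ranks), so that every sample shares the per-rank mean distribution.
#'
#' @param raw Nonnegative numeric matrix, genes in rows, >= 2 sample columns.
#' @return Matrix of quantile-normalized log2(1 + X) values, same dimnames.
#' @export
normalize_expression <- function(raw) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  if (any(!is.finite(raw))) stop("expression matrix must be finite")
  if (any(raw < 0)) stop("expression matrix must be nonnegative")
  if (ncol(raw) < 2L) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(log2(1 + raw), ties = TRUE)
  dimnames(out) <- dimnames(raw)
  out
}

#' Drop genes that are all-zero in any cohort
#'
#' A gene is removed when its raw value is 0 in every sample of at least one
#' cohort; removal applies to all cohorts so that the shared gene index stays
#' aligned.
#'
#' @param raw_list Named list of raw (pre-transform) expression matrices
#'   sharing the same gene rows in the same order.
#' @return A list with `cohorts` (the trimmed matrices) and `removed`
#'   (character vector of dropped gene ids).
#' @export
filter_zero_genes <- function(raw_list) {
  if (!length(raw_list)) stop("no cohorts supplied")
  genes <- rownames(raw_list[[1L]])
  for (m in raw_list) {
    if (!identical(rownames(m), genes)) stop("cohorts must share the same gene rows")
  }
  dead <- Reduce(`|`, lapply(raw_list, function(m) rowSums(m != 0) == 0L))
  list(cohorts = lapply(raw_list, function(m) m[!dead, , drop = FALSE]),
       removed = genes[dead])
}

#' Map copy-number segments to gene-level values
#'
#' Projects per-sample segment log2 ratios onto genes. A gene overlapping one
#' or more segments gets the overlap-length-weighted mean of their values
#' (containment reduces to the segment's value, and the result is continuous
#' in breakpoint position); a gene falling in a gap between two segments gets
#' the mean of the two flanking values; a gene beyond the first/last segment
#' of its chromosome gets the nearest segment's value. Samples with no
#' segments on a gene's chromosome get 0 (diploid) there, with a warning.
#'
#' Input coordinates are 1-based inclusive; overlap arithmetic treats
#' intervals as half-open `[start, end + 1)`.
#'
#' @param segments Segment data.frame as from [read_segments()].
#' @param annotation Sorted annotation as from [read_annotation()].
#' @param samples Optional character vector fixing the columns (defaults to
#'   the samples present in `segments`).
#' @return A genes x samples numeric matrix in annotation order.
#' @export
segments_to_gene_cna <- function(segments, annotation, samples = NULL) {
  if (is.null(samples)) samples <- unique(segments$sample)
  genes <- annotation$gene_id
  out <- matrix(0, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (any(segments$start > segments$end)) stop("segment with start > end")
  chroms <- unique(annotation$chromosome)
  ann_by_chr <- split(seq_len(nrow(annotation)), annotation$chromosome)
  seg_split <- split(segments, segments$sample)
  missing_chrom <- 0L
  for (s in samples) {
    seg_s <- seg_split[[s]]
    for (chr in chroms) {
      gi <- ann_by_chr[[chr]]
      seg <- seg_s[seg_s$chromosome == chr, , drop = FALSE]
      if (is.null(seg_s) || nrow(seg) == 0L) {
        missing_chrom <- missing_chrom + 1L
        next  # stays 0 (diploid)
      }
      seg <- seg[order(seg$start), , drop = FALSE]
      if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)])) {
        stop(sprintf("overlapping segments for sample %s on %s", s, chr))
      }
      out[gi, s] <- .genes_from_segments(annotation$start[gi], annotation$end[gi],
                                         seg$start, seg$end, seg$seg_mean)
    }
  }
  if (missing_chrom > 0L) {
    warning(sprintf(
      "%d sample/chromosome combination(s) had no segments; gene CNA set to 0 (diploid)",
      missing_chrom))
  }
  out
}

# Vectorised gene-level values for one sample/chromosome. All coordinates
# 1-based inclusive; overlaps computed on [start, end + 1).
.genes_from_segments <- function(g_start, g_end, s_start, s_end, s_mean) {
  k <- length(s_start)
  # overlap length of every gene with every segment
  ov <- pmax(outer(g_end + 1, s_end + 1, FUN = pmin) -
             outer(g_start, s_start, FUN = pmax), 0)
  tot <- rowSums(ov)
  val <- as.vector(ov %*% s_mean)
  hit <- tot > 0
  val[hit] <- val[hit] / tot[hit]
  # containment in a single segment: take that value exactly
  single <- hit & rowSums(ov > 0) == 1L
  if (any(single)) val[single] <- s_mean[max.col(ov, ties.method = "first")[single]]
  if (any(!hit)) {
    # gap / chromosome-end genes: index of last segment ending before the gene
    left <- findInterval(g_start[!hit] - 1L, s_end)
    gapval <- ifelse(left == 0L, s_mean[1L],
              ifelse(left == k, s_mean[k],
                     (s_mean[pmax(left, 1L)] + s_mean[pmin(left + 1L, k)]) / 2))
    val[!hit] <- gapval
  }
  val
}

#' Assemble a multi-cohort data set
#'
#' Builds the container the discovery and calling stages operate on: per
#' cohort, a quantile-normalized `log2(1 + X)` tumor expression matrix, a
#' gene-level tumor CNA matrix, and (when normal samples are listed) a
#' gene-level normal CNA matrix — all sharing one gene index in genome order —
#' plus per-cohort weights proportional to tumor sample counts. Genes that are
#' all-zero in any cohort's tumor samples are removed first.
#'
#' @param expression Named list (cohort -> raw genes x samples matrix). Columns
#'   must cover the manifest's tumor ids (and normal ids may be present but
#'   are not used).
#' @param segments Segment data.frame covering tumor (and any normal) samples.
#' @param annotation Annotation data.frame (sorted internally).
#' @param manifest Named list (cohort -> list(tumor=, normal=)); defaults to
#'   treating every expression column as a tumor sample with no normals.
#' @return An object of class `cocna_cohorts`.
#' @export
cohort_set <- function(expression, segments, annotation, manifest = NULL) {
  if (!length(expression)) stop("no cohorts supplied")
  if (is.null(names(expression))) stop("expression list must be named by cohort")
  annotation <- sort_annotation(annotation)
  if (is.null(manifest)) {
    manifest <- lapply(expression, function(m) list(tumor = colnames(m), normal = character(0)))
  }
  if (!all(names(expression) %in% names(manifest))) stop("manifest missing cohorts")

  genes <- annotation$gene_id
  raw <- lapply(names(expression), function(nm) {
    m <- expression[[nm]]
    miss <- setdiff(genes, rownames(m))
    if (length(miss)) stop(sprintf("cohort %s lacks %d annotated genes", nm, length(miss)))
    tum <- manifest[[nm]]$tumor
    bad <- setdiff(tum, colnames(m))
    if (length(bad)) stop(sprintf("cohort %s lacks tumor samples: %s", nm,
                                  paste(utils::head(bad, 3), collapse = ", ")))
    m[genes, tum, drop = FALSE]
  })
  names(raw) <- names(expression)

  fz <- filter_zero_genes(raw)
  raw <- fz$cohorts
  annotation <- annotation[!(annotation$gene_id %in% fz$removed), , drop = FALSE]
  rownames(annotation) <- NULL

  cohorts <- lapply(names(raw), function(nm) {
    tum <- manifest[[nm]]$tumor
    nrm <- manifest[[nm]]$normal
    cna <- segments_to_gene_cna(segments[segments$sample %in% tum, , drop = FALSE],
                                annotation, samples = tum)
    normal_cna <- NULL
    if (length(nrm)) {
      normal_cna <- segments_to_gene_cna(segments[segments$sample %in% nrm, , drop = FALSE],
                                         annotation, samples = nrm)
    }
    list(name = nm,
         raw = raw[[nm]],
         expression = normalize_expression(raw[[nm]]),
         cna = cna,
         normal_cna = normal_cna)
  })
  names(cohorts) <- names(raw)

  n_tumor <- vapply(cohorts, function(co) ncol(co$expression), integer(1))
  structure(list(annotation = annotation,
                 cohorts = cohorts,
                 weights = n_tumor / sum(n_tumor),
                 removed_genes = fz$removed),
            class = "cocna_cohorts")
}

#' @export
print.cocna_cohorts <- function(x, ...) {
  n <- vapply(x$cohorts, function(co) ncol(co$expression), integer(1))
  nn <- vapply(x$cohorts, function(co) if (is.null(co$normal_cna)) 0L else ncol(co$normal_cna),
               integer(1))
  cat(sprintf("Multi-cohort data set: %d genes, %d cohorts, %d tumor / %d normal samples\n",
              nrow(x$annotation), length(x$cohorts), sum(n), sum(nn)))
  for (i in seq_along(x$cohorts)) {
    cat(sprintf("  %-8s %4d tumor %4d normal  weight %.3f\n",
                names(x$cohorts)[i], n[i], nn[i], x$weights[i]))
  }
  if (length(x$removed_genes)) {
    cat(sprintf("  (%d all-zero genes removed)\n", length(x$removed_genes)))
  }
  invisible(x)
}
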