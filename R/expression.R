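#' Expression set for a two-group isoform experiment
#'
#' A light-weight container (in the spirit of edgeR's `DGEList`) holding a
#' unit-by-sample matrix of non-negative values, the sample-to-condition
#' design, and the normalization state. "Units" are transcripts on input and
#' genes or unique-CDS groups after [aggregate_expression()].
#'
#' @param values numeric matrix, units in rows (rownames required), samples in
#'   columns (colnames required), non-negative.
#' @param design data.frame with columns `sample` and `condition`; every
#'   matrix column must appear exactly once.
#' @param normalized logical; `TRUE` when `values` are CPM on effective
#'   library sizes.
#' @param norm_factors,lib_size optional per-sample TMM factors and library
#'   sizes (filled by [normalize_expression()]).
#' @return An object of class `iso_exprs`.
#' @export
iso_exprs <- function(values, design, normalized = FALSE,
                      norm_factors = NULL, lib_size = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row and column names")
  if (any(values < 0)) stop("negative expression values are not allowed")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition") %in% names(design)))
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  if (anyNA(design$sample))
    stop("every sample in the matrix must appear in the design")
  if (is.null(lib_size)) lib_size <- colSums(values)
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(values))
  names(lib_size) <- names(norm_factors) <- colnames(values)
  structure(list(values = values, design = design, normalized = normalized,
                 norm_factors = norm_factors, lib_size = lib_size,
                 effective_lib_size = lib_size * norm_factors),
            class = "iso_exprs")
}

#' @export
print.iso_exprs <- function(x, ...) {
  cat("iso_exprs:", nrow(x$values), "units x", ncol(x$values), "samples;",
      if (x$normalized) "normalized (CPM)" else "raw counts", "\n")
  cat("conditions:", paste(sprintf("%s (n=%d)", names(table(x$design$condition)),
                                   table(x$design$condition)), collapse = ", "), "\n")
  invisible(x)
}

conditions_of <- function(x) unique(x$design$condition)

cond_samples <- function(x, cond) x$design$sample[x$design$condition == cond]

# per-condition means of the value matrix (units x conditions)
condition_means <- function(x) {
  conds <- conditions_of(x)
  out <- sapply(conds, function(cc)
    rowMeans(x$values[, cond_samples(x, cc), drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(conds),
                                       dimnames = list(rownames(x$values), conds))
  out
}

#' Read an expression matrix and design from TSV files
#'
#' The matrix file has a header of sample names and transcript ids in the
#' first column; the design file has columns `sample` and `condition`.
#'
#' @param counts_path,design_path input files.
#' @return a raw [iso_exprs()].
#' @export
read_expression <- function(counts_path, design_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  iso_exprs(mat, design)
}

# weighted trimmed mean of M-values factor of sample obs against ref
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.30, abs_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) 1 else 2^f
}

#' TMM + sequencing-depth normalization
#'
#' Computes per-sample scaling factors by the weighted trimmed mean of
#' M-values (30% trim on log-ratios, 5% on absolute intensities; reference =
#' the sample whose 75th expression percentile is closest to the mean across
#' samples), rescales factors to geometric mean 1, and converts counts to CPM
#' of the effective library size (library size x factor).
#'
#' @param x a raw [iso_exprs()]. Pre-normalized input is passed through with
#'   unit factors and a notice.
#' @return a normalized [iso_exprs()].
#' @export
normalize_expression <- function(x) {
  stopifnot(inherits(x, "iso_exprs"))
  if (x$normalized) {
    message("input already normalized; keeping unit factors")
    return(x)
  }
  counts <- x$values
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero))
    stop("normalization error: sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  if (ncol(counts) == 1L) {
    f <- stats::setNames(1, colnames(counts))
  } else {
    f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(f75 - mean(f75)))
    f <- vapply(seq_len(ncol(counts)), function(j)
      tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref]), 0)
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(counts)
  }
  eff <- lib * f
  cpm <- sweep(counts, 2, eff, "/") * 1e6
  out <- iso_exprs(cpm, x$design, normalized = TRUE,
                   norm_factors = f, lib_size = lib)
  out$effective_lib_size <- eff
  out
}

#' Drop units with low expression in both conditions
#'
#' Removes units whose mean CPM is below `min_cpm` in every condition. When a
#' transcript-to-gene map is supplied, genes losing all their transcripts are
#' reported in the `dropped_genes` attribute.
#'
#' @param x a normalized [iso_exprs()].
#' @param min_cpm CPM threshold (default 1).
#' @param gene_map optional named vector transcript -> gene (see [tx2gene()]).
#' @return filtered [iso_exprs()].
#' @export
filter_low_expression <- function(x, min_cpm = 1, gene_map = NULL) {
  stopifnot(inherits(x, "iso_exprs"))
  if (!x$normalized) stop("filter_low_expression requires normalized input")
  cm <- condition_means(x)
  keep <- apply(cm >= min_cpm, 1, any)
  out <- subset_units(x, rownames(x$values)[keep])
  if (!is.null(gene_map)) {
    before <- unique(gene_map[rownames(x$values)])
    after <- unique(gene_map[rownames(out$values)])
    attr(out, "dropped_genes") <- setdiff(before, after)
  }
  out
}

subset_units <- function(x, units) {
  out <- x
  out$values <- x$values[units, , drop = FALSE]
  out
}

#' Aggregate transcript expression to gene or unique-CDS level
#'
#' Gene level sums the member transcripts of each gene, so gene-level column
#' sums equal transcript-level column sums. CDS level groups coding
#' transcripts sharing identical genomic CDS intervals (the same ORF) into one
#' unit and drops non-coding transcripts.
#'
#' @param x an [iso_exprs()] whose rows are transcripts.
#' @param ann the matching [iso_annotation()].
#' @param level `"gene"` or `"cds"`.
#' @return an [iso_exprs()] at the requested level. For `level = "cds"` the
#'   attributes `unit_gene` (unit -> gene) and `unit_members` (unit -> member
#'   transcripts) describe the grouping; for `"gene"` rownames are gene ids.
#' @export
aggregate_expression <- function(x, ann, level = c("gene", "cds")) {
  level <- match.arg(level)
  stopifnot(inherits(x, "iso_exprs"), inherits(ann, "iso_annotation"))
  txs <- rownames(x$values)
  missing <- setdiff(txs, ann$transcripts$transcript_id)
  if (length(missing))
    stop("aggregation error: transcripts absent from annotation: ",
         paste(utils::head(missing, 3), collapse = ", "))
  if (level == "gene") {
    g <- tx2gene(ann)[txs]
    vals <- rowsum(x$values, group = g, reorder = TRUE)
    out <- iso_exprs(vals, x$design, normalized = x$normalized,
                     norm_factors = x$norm_factors, lib_size = x$lib_size)
    out$effective_lib_size <- x$effective_lib_size
    return(out)
  }
  coding <- ann$transcripts$transcript_id[ann$transcripts$is_coding]
  txs <- intersect(txs, coding)
  if (!length(txs)) stop("aggregation error: no coding transcripts in matrix")
  keys <- vapply(txs, function(tt) cds_genomic_key(ann, tt), "")
  uk <- sort(unique(keys))
  unit_ids <- stats::setNames(sprintf("CDS_%04d", seq_along(uk)), uk)
  g <- unit_ids[keys]
  vals <- rowsum(x$values[txs, , drop = FALSE], group = g, reorder = TRUE)
  out <- iso_exprs(vals, x$design, normalized = x$normalized,
                   norm_factors = x$norm_factors, lib_size = x$lib_size)
  out$effective_lib_size <- x$effective_lib_size
  gmap <- tx2gene(ann)
  attr(out, "unit_gene") <- stats::setNames(
    vapply(rownames(vals), function(u) unname(gmap[txs[g == u][1L]]), ""),
    rownames(vals))
  attr(out, "unit_members") <- lapply(
    stats::setNames(rownames(vals), rownames(vals)), function(u) txs[g == u])
  out
}

#' Per-condition isoform usage
#'
#' Usage of isoform i in gene g and condition c is the mean normalized
#' expression of the isoform over the replicates of c divided by the mean
#' normalized gene expression (sum over member isoforms). Gene x condition
#' cells with zero gene expression are flagged not evaluable.
#'
#' @param x a normalized [iso_exprs()] at transcript (or CDS-unit) level.
#' @param gene_map named vector unit -> gene.
#' @return a `usage_table` data.frame with columns `gene_id`, `unit_id`, one
#'   usage column per condition, and logical `evaluable_<condition>` columns.
#' @export
compute_usage <- function(x, gene_map) {
  stopifnot(inherits(x, "iso_exprs"))
  if (!x$normalized) stop("compute_usage requires normalized input")
  cm <- condition_means(x)
  conds <- colnames(cm)
  g <- unname(gene_map[rownames(cm)])
  if (anyNA(g)) stop("units missing from gene map")
  gm <- rowsum(cm, group = g)[g, , drop = FALSE]
  usage <- cm / gm
  out <- data.frame(gene_id = g, unit_id = rownames(cm), stringsAsFactors = FALSE)
  for (cc in conds) {
    out[[paste0("usage_", cc)]] <- ifelse(gm[, cc] > 0, usage[, cc], NA_real_)
    out[[paste0("evaluable_", cc)]] <- gm[, cc] > 0
  }
  rownames(out) <- NULL
  attr(out, "conditions") <- conds
  class(out) <- c("usage_table", "data.frame")
  out
}

#' Remove minor isoforms before differential testing
#'
#' Two pre-filters guard the interaction tests against spurious hits driven by
#' consistently minor isoforms. `proportion` removes isoforms whose usage is
#' below `threshold` (default 0.10) in all conditions; `foldchange` removes
#' isoforms whose per-condition major-to-minor expression ratio is at least
#' `threshold` (default 2) in all conditions. The major isoform of each
#' condition is never removed.
#'
#' @param x a normalized [iso_exprs()].
#' @param gene_map named vector unit -> gene.
#' @param mode `"proportion"` or `"foldchange"`.
#' @param threshold filter threshold; defaults to 0.10 / 2 by mode.
#' @return filtered [iso_exprs()].
#' @export
filter_minor_isoforms <- function(x, gene_map,
                                  mode = c("proportion", "foldchange"),
                                  threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "proportion") 0.10 else 2
  if (mode == "proportion" && (threshold <= 0 || threshold >= 1))
    stop("contract error: proportion threshold must lie in (0,1)")
  stopifnot(inherits(x, "iso_exprs"))
  if (!x$normalized) stop("filter_minor_isoforms requires normalized input")
  cm <- condition_means(x)
  conds <- colnames(cm)
  g <- unname(gene_map[rownames(cm)])
  keep <- rep(TRUE, nrow(cm))
  for (gid in unique(g)) {
    idx <- which(g == gid)
    if (length(idx) < 2L) next
    sub <- cm[idx, , drop = FALSE]
    is_major <- matrix(FALSE, nrow(sub), length(conds))
    for (j in seq_along(conds)) {
      mx <- max(sub[, j])
      is_major[, j] <- sub[, j] == mx
    }
    major_any <- apply(is_major, 1, any)
    if (mode == "proportion") {
      tot <- colSums(sub)
      usage <- sweep(sub, 2, pmax(tot, .Machine$double.eps), "/")
      minor <- apply(usage < threshold, 1, all)
    } else {
      majors <- apply(sub, 2, max)
      ratio <- sweep(1 / pmax(sub, .Machine$double.eps), 2, majors, "*")
      minor <- apply(ratio >= threshold, 1, all)
    }
    keep[idx[minor & !major_any]] <- FALSE
  }
  subset_units(x, rownames(cm)[keep])
}
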