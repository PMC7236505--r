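# Differential analyses built on the shared NB interaction engine:
# gene-level DGE, transcript/CDS-level DIU with usage metrics.

#' Total isoform usage change (%)
#'
#' Half the L1 distance between a gene's isoform usage vectors in two
#' conditions, times 100: the percentage of gene expression redistributed
#' among isoforms between conditions. Symmetric in the conditions and
#' invariant to rescaling either condition's expression.
#'
#' @param e1,e2 per-isoform expression (condition means), same order.
#' @return percentage in `[0, 100]`; `NA` when a condition has zero total.
#' @export
total_usage_change <- function(e1, e2) {
  stopifnot(length(e1) == length(e2))
  s1 <- sum(e1); s2 <- sum(e2)
  if (s1 <= 0 || s2 <= 0) return(NA_real_)
  100 * 0.5 * sum(abs(e1 / s1 - e2 / s2))
}

#' Major isoforms per condition and switching status
#'
#' The major isoform of a gene in a condition is the unit with the highest
#' usage; ties break to the lexicographically smallest unit id (flagged). A
#' major-isoform switching event occurs when the major isoform differs
#' between the two conditions.
#'
#' @param usage a `usage_table` from [compute_usage()].
#' @param gene_id gene to evaluate.
#' @return list with `majors` (named by condition), `switching`, `tie`,
#'   `evaluable`.
#' @export
majors_and_switching <- function(usage, gene_id) {
  conds <- attr(usage, "conditions")
  sub <- usage[usage$gene_id == gene_id, , drop = FALSE]
  if (!nrow(sub)) stop("unknown gene ", gene_id)
  majors <- stats::setNames(rep(NA_character_, length(conds)), conds)
  tie <- FALSE
  evaluable <- stats::setNames(rep(FALSE, length(conds)), conds)
  for (cc in conds) {
    if (!all(sub[[paste0("evaluable_", cc)]])) next
    u <- sub[[paste0("usage_", cc)]]
    mx <- max(u)
    cand <- sort(sub$unit_id[u == mx])
    if (length(cand) > 1L) tie <- TRUE
    majors[cc] <- cand[1L]
    evaluable[cc] <- TRUE
  }
  switching <- if (all(evaluable)) majors[1L] != majors[2L] else NA
  list(majors = majors, switching = unname(switching), tie = tie,
       evaluable = evaluable)
}

#' Differential gene expression by NB likelihood ratio
#'
#' Per-gene two-group negative-binomial LRT (chi-square reference) of the
#' condition effect on raw gene-level counts with TMM effective library sizes
#' as offsets, BH correction across genes. The dispersion is a common
#' method-of-moments estimate pooled across all genes and conditions (a
#' single gene offers far too few residual degrees of freedom), floored at
#' 0.01. A gene is flagged DE when `FDR < alpha` and the fold change of
#' normalized condition means (pseudo-count 1) exceeds `fc_threshold`.
#'
#' @param x raw gene-level [iso_exprs()] (see [aggregate_expression()]).
#' @param fc_threshold fold-change cutoff on normalized condition means
#'   (default 1.5).
#' @param alpha FDR cutoff (default 0.05).
#' @return data.frame with per-gene statistic, p, FDR, fold change and DE flag.
#' @export
run_dge <- function(x, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(inherits(x, "iso_exprs"))
  if (x$normalized) stop("run_dge requires raw counts")
  if (length(conditions_of(x)) != 2L || any(table(x$design$condition) < 2L))
    stop("contract error: two conditions with >=2 replicates each are required")
  norm <- normalize_expression(x)
  cm <- condition_means(norm)
  cond <- x$design$condition
  offs <- norm$effective_lib_size
  genes <- rownames(x$values)
  phi <- estimate_dispersion(round(x$values), cond, offs)
  res <- lapply(genes, function(g) {
    y <- round(x$values[g, ])
    if (sum(y) == 0)
      return(data.frame(gene_id = g, statistic = NA_real_, df = NA_integer_,
                        p = NA_real_, stringsAsFactors = FALSE))
    Xf <- stats::model.matrix(~ factor(cond))
    Xr <- matrix(1, length(y), 1)
    off <- log(offs)
    dev_f <- nb_deviance(y, Xf, off, 1 / phi)
    dev_r <- nb_deviance(y, Xr, off, 1 / phi)
    stat <- max(0, dev_r - dev_f)
    data.frame(gene_id = g, statistic = stat, df = 1L,
               p = stats::pchisq(stat, 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  m1 <- cm[out$gene_id, 1L] + 1
  m2 <- cm[out$gene_id, 2L] + 1
  out$fc <- pmax(m1, m2) / pmin(m1, m2)
  out$log2fc <- log2(m2 / m1)
  out$de <- !is.na(out$fdr) & out$fdr < alpha & out$fc > fc_threshold
  rownames(out) <- NULL
  out
}

#' Differential isoform / CDS usage
#'
#' For every multi-unit gene, tests the unit-by-condition interaction with
#' [fit_interaction_test()] on raw counts (after the optional minor-isoform
#' pre-filter), corrects across genes by BH, and attaches the usage metrics:
#' total usage change of normalized condition means, per-condition major
#' units and the switching flag.
#'
#' @param x raw transcript-level [iso_exprs()].
#' @param ann matching [iso_annotation()].
#' @param level `"transcript"` or `"cds"`.
#' @param prefilter `NULL`, or a list `list(mode =, threshold =)` forwarded to
#'   [filter_minor_isoforms()].
#' @param alpha FDR cutoff for the DIU flag.
#' @return data.frame, one row per tested gene.
#' @export
run_diu <- function(x, ann, level = c("transcript", "cds"),
                    prefilter = NULL, alpha = 0.05) {
  level <- match.arg(level)
  stopifnot(inherits(x, "iso_exprs"))
  if (x$normalized) stop("run_diu requires raw counts")
  if (level == "cds") {
    x <- aggregate_expression(x, ann, "cds")
    gene_map <- attr(x, "unit_gene")
  } else {
    gene_map <- tx2gene(ann)[rownames(x$values)]
    if (anyNA(gene_map)) stop("transcripts absent from annotation")
  }
  norm <- normalize_expression(x)
  if (!is.null(prefilter)) {
    mode <- prefilter$mode %||% "proportion"
    kept <- filter_minor_isoforms(norm, gene_map, mode = mode,
                                  threshold = prefilter$threshold)
    units <- rownames(kept$values)
  } else units <- rownames(x$values)
  cond <- x$design$condition
  conds <- conditions_of(x)
  offs <- norm$effective_lib_size
  usage <- compute_usage(subset_units(norm, units), gene_map[units])
  cm <- condition_means(subset_units(norm, units))
  genes <- unique(gene_map[units])
  rows <- lapply(genes, function(g) {
    gu <- units[gene_map[units] == g]
    if (length(gu) < 2L) return(NULL)
    ft <- fit_interaction_test(x$values[gu, , drop = FALSE], cond, offs)
    ms <- majors_and_switching(usage, g)
    tc <- total_usage_change(cm[gu, conds[1L]], cm[gu, conds[2L]])
    df <- data.frame(gene_id = g, level = level, k_units = ft$k_units,
                     statistic = ft$statistic, df = ft$df, p = ft$p,
                     status = ft$status, total_change = tc,
                     switching = ms$switching, major_tie = ms$tie,
                     stringsAsFactors = FALSE)
    df[[paste0("major_", conds[1L])]] <- unname(ms$majors[conds[1L]])
    df[[paste0("major_", conds[2L])]] <- unname(ms$majors[conds[2L]])
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$fdr <- bh_adjust(out$p)
  out$diu <- !is.na(out$fdr) & out$fdr < alpha
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
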