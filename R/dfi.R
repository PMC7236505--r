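# Differential Feature Inclusion: inclusion rates, interaction tests on
# include/exclude count aggregates, category-level statistics and co-DFI.

#' Feature inclusion rate
#'
#' `FI = EInc / (EInc + EExc)`: the expression share of the isoforms that
#' include a feature among the gene's total expression.
#'
#' @param e_inc aggregated expression of feature-including isoforms.
#' @param e_exc aggregated expression of feature-excluding isoforms.
#' @return inclusion rate in `[0, 1]`; `NA` when the gene is unexpressed.
#' @export
feature_inclusion_rate <- function(e_inc, e_exc) {
  tot <- e_inc + e_exc
  ifelse(tot > 0, e_inc / tot, NA_real_)
}

# include/exclude split of a gene's isoforms for one feature id.
# Presence-varying: carriers of >=1 annotation of the id are "include".
# Positional-only variation: the positional class of the reference isoform
# (most expressed overall) defines "include"; shifted copies are "exclude".
# Returns NULL when the feature is not varying (nothing to test).
feature_membership <- function(ann, gene_id, category, feature_id, txs,
                               overall_expr, tol_bp = 9L) {
  proj <- lapply(txs, function(tt)
    feature_projections(ann, tt, category, feature_id))
  names(proj) <- txs
  carrier <- lengths(proj) > 0L
  if (any(carrier) && !all(carrier))
    return(list(include = txs[carrier], exclude = txs[!carrier],
                split = "presence"))
  if (!any(carrier)) return(NULL)
  layers <- vapply(proj[[1L]], `[[`, "", "layer")
  if (all(layers == "none")) return(NULL)          # presence-only, all carry it
  ref <- txs[which.max(overall_expr[txs])]
  eq_ref <- vapply(txs, function(tt)
    covered_positionally(proj[[ref]], proj[[tt]], tol_bp) &&
      covered_positionally(proj[[tt]], proj[[ref]], tol_bp), TRUE)
  if (all(eq_ref)) return(NULL)                    # not varying
  list(include = txs[eq_ref], exclude = txs[!eq_ref], split = "positional")
}

#' Differential feature inclusion analysis
#'
#' For every multi-isoform gene and every varying feature id (presence or
#' positional variation across the gene's isoforms), raw counts are collapsed
#' into feature-including and feature-excluding aggregates and the 2-unit
#' condition interaction is tested with [fit_interaction_test()]. P-values
#' are BH-corrected separately within each annotation category. Each record
#' carries the per-condition inclusion rates FI (from normalized condition
#' means), the inclusion change `delta_fi = 100 * |FI_A - FI_B|`, the favored
#' condition (largest FI; ties yield `"none"`), and the feature-switching
#' flag (FI crosses 0.5 between conditions).
#'
#' @param x raw transcript-level [iso_exprs()].
#' @param ann matching [iso_annotation()].
#' @param categories categories to test (default: all functional categories).
#' @param alpha per-category FDR cutoff for the DFI flag.
#' @param tol_bp positional tolerance for the varying/membership split.
#' @return data.frame, one row per tested gene x feature id.
#' @export
run_dfi <- function(x, ann, categories = NULL, alpha = 0.05, tol_bp = 9L) {
  stopifnot(inherits(x, "iso_exprs"), inherits(ann, "iso_annotation"))
  if (x$normalized) stop("run_dfi requires raw counts")
  if (is.null(categories)) categories <- sort(unique(ann$features$category))
  norm <- normalize_expression(x)
  cm <- condition_means(norm)
  conds <- colnames(cm)
  overall <- rowSums(norm$values)
  cond <- x$design$condition
  offs <- norm$effective_lib_size
  gmap <- tx2gene(ann)
  genes <- multi_isoform_genes(ann)
  rows <- list()
  for (g in genes) {
    txs <- intersect(names(gmap)[gmap == g], rownames(x$values))
    if (length(txs) < 2L) next
    fsub <- ann$features[ann$features$transcript_id %in% txs &
                           ann$features$category %in% categories, , drop = FALSE]
    if (!nrow(fsub)) next
    for (cat in unique(fsub$category)) {
      for (id in unique(fsub$feature_id[fsub$category == cat])) {
        mem <- feature_membership(ann, g, cat, id, txs, overall, tol_bp)
        if (is.null(mem)) next
        e_inc <- colSums(cm[mem$include, conds, drop = FALSE])
        e_exc <- colSums(cm[mem$exclude, conds, drop = FALSE])
        fi <- feature_inclusion_rate(e_inc, e_exc)
        evaluable <- all((e_inc + e_exc) > 0)
        agg <- rbind(inc = colSums(x$values[mem$include, , drop = FALSE]),
                     exc = colSums(x$values[mem$exclude, , drop = FALSE]))
        ft <- if (evaluable) fit_interaction_test(agg, cond, offs) else
          list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
               status = "not_testable")
        delta <- 100 * abs(fi[1L] - fi[2L])
        favored <- if (anyNA(fi) || fi[1L] == fi[2L]) "none" else
          conds[which.max(fi)]
        switching <- !anyNA(fi) && (fi[1L] - 0.5) * (fi[2L] - 0.5) < 0
        rec <- data.frame(gene_id = g, category = cat, feature_id = id,
                          split = mem$split, statistic = ft$statistic,
                          df = ft$df, p = ft$p, status = ft$status,
                          delta_fi = unname(delta), favored = favored,
                          feature_switching = switching,
                          stringsAsFactors = FALSE)
        rec[[paste0("fi_", conds[1L])]] <- unname(fi[1L])
        rec[[paste0("fi_", conds[2L])]] <- unname(fi[2L])
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$fdr <- NA_real_
  for (cat in unique(out$category)) {
    sel <- out$category == cat
    out$fdr[sel] <- bh_adjust(out$p[sel])
  }
  out$dfi <- !is.na(out$fdr) & out$fdr < alpha
  rownames(out) <- NULL
  attr(out, "conditions") <- conds
  out
}

#' Category-level DFI statistics: relative enrichment and condition bias
#'
#' Enrichment: per category, a two-sided Fisher exact test of (DFI features
#' in the category vs not) against (tested features in the category vs not),
#' BH across categories. Bias: per category, a two-sided exact binomial test
#' with p = 0.5 on the counts of DFI features favored in each condition
#' (ties excluded), BH across categories.
#'
#' @param dfi a result table from [run_dfi()].
#' @return list of data.frames `enrichment` and `bias`.
#' @export
dfi_category_stats <- function(dfi) {
  stopifnot(is.data.frame(dfi))
  conds <- attr(dfi, "conditions")
  tested <- dfi[dfi$status == "tested", , drop = FALSE]
  cats <- sort(unique(tested$category))
  n_dfi <- sum(tested$dfi)
  enr <- lapply(cats, function(cat) {
    a <- sum(tested$dfi & tested$category == cat)
    b <- n_dfi - a
    c2 <- sum(!tested$dfi & tested$category == cat)
    d <- sum(!tested$dfi) - c2
    ft <- stats::fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE))
    data.frame(category = cat, n_dfi = a, n_tested = a + c2,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  enr <- do.call(rbind, enr)
  enr$fdr <- bh_adjust(enr$p)
  bias <- lapply(cats, function(cat) {
    sub <- tested[tested$dfi & tested$category == cat &
                    tested$favored != "none", , drop = FALSE]
    if (!nrow(sub)) {
      message("category ", cat, " has no DFI features with a favored condition; skipped in bias test")
      return(NULL)
    }
    x1 <- sum(sub$favored == conds[1L]); n <- nrow(sub)
    bt <- stats::binom.test(x1, n, p = 0.5)
    out <- data.frame(category = cat, n_dfi_favored = n, p = bt$p.value,
                      stringsAsFactors = FALSE)
    out[[paste0("n_", conds[1L])]] <- x1
    out[[paste0("n_", conds[2L])]] <- n - x1
    out
  })
  bias <- do.call(rbind, bias)
  if (!is.null(bias)) bias$fdr <- bh_adjust(bias$p)
  list(enrichment = enr, bias = bias)
}

#' Co-differential feature inclusion
#'
#' For every unordered pair of feature ids that are both DFI (with a defined
#' favored condition) in at least `min_genes` common genes, counts the genes
#' where the two features are favored in the same condition (co-inclusion)
#' and in different conditions (mutual exclusion).
#'
#' @param dfi a result table from [run_dfi()].
#' @param min_genes minimum number of shared DFI genes per pair (default 5).
#' @return data.frame sorted by shared-gene count, one row per feature pair.
#' @export
run_co_dfi <- function(dfi, min_genes = 5L) {
  sub <- dfi[dfi$dfi & dfi$favored != "none", , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  key <- paste(sub$gene_id, sub$feature_id)
  sub <- sub[!duplicated(key), , drop = FALSE]
  rows <- list()
  ids <- sort(unique(sub$feature_id))
  by_id <- split(sub, sub$feature_id)
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1L):length(ids)) {
    a <- by_id[[ids[i]]]; b <- by_id[[ids[j]]]
    shared <- intersect(a$gene_id, b$gene_id)
    if (length(shared) < min_genes) next
    fa <- a$favored[match(shared, a$gene_id)]
    fb <- b$favored[match(shared, b$gene_id)]
    co <- sum(fa == fb)
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id_1 = ids[i], feature_id_2 = ids[j],
      n_genes_both_dfi = length(shared), n_co_inclusion = co,
      n_mutual_exclusion = length(shared) - co, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out[order(-out$n_genes_both_dfi, out$feature_id_1), , drop = FALSE]
}
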