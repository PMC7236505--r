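# PolyA-site library construction, differential polyadenylation (DPAU) and
# usage-weighted UTR lengthening analysis.

#' Distal polyA site usage
#'
#' `DPAU = EdPA / (EdPA + EpPA)`: the expression share of the isoforms using
#' the distal polyA site among distal + proximal expression.
#'
#' @param e_distal,e_proximal aggregated expression of distal / proximal
#'   isoforms.
#' @return usage in `[0, 1]`; `NA` when both are zero.
#' @export
dpau_rate <- function(e_distal, e_proximal) {
  tot <- e_distal + e_proximal
  ifelse(tot > 0, e_distal / tot, NA_real_)
}

#' Usage-weighted UTR length
#'
#' `UTRw = sum_i U_i * UTR_i`, the isoform-usage-weighted UTR length of a
#' gene in one condition; a convex combination of the isoform UTR lengths.
#'
#' @param usage per-isoform usages (renormalized to sum 1 over the isoforms
#'   considered).
#' @param utr_len matching UTR lengths in nt.
#' @return weighted length in nt.
#' @export
utr_weighted_length <- function(usage, utr_len) {
  stopifnot(length(usage) == length(utr_len))
  sum(usage * utr_len)
}

#' Build the per-gene polyA site library
#'
#' PolyA sites are the 3'-most genomic positions of coding, non-NMD
#' transcripts. Per gene, sites within a `merge_window` (default 75 bp,
#' single linkage) are merged into clusters; clusters holding less than
#' `min_frac` (default 10%) of total gene expression in every condition are
#' dropped together with their transcripts. Among surviving clusters the one
#' nearest the gene 5' end in transcript orientation is labeled proximal, the
#' farthest distal, and intermediate clusters are assigned to the nearest
#' labeled cluster. A gene is eligible for DPA when both labels exist and the
#' representative positions are at least `min_pair_dist` (default 60 bp)
#' apart. The cluster representative is the polyA position of its most
#' expressed member (ties: the 3'-most).
#'
#' @param ann an [iso_annotation()].
#' @param x a normalized [iso_exprs()] at transcript level.
#' @param merge_window single-linkage merge window in bp.
#' @param min_frac minimum expression share of a surviving cluster.
#' @param min_pair_dist minimum distal-proximal distance in bp.
#' @return object of class `polya_library` with data.frames `clusters`,
#'   `members` and `genes`.
#' @export
build_polya_library <- function(ann, x, merge_window = 75L, min_frac = 0.10,
                                min_pair_dist = 60L) {
  stopifnot(inherits(ann, "iso_annotation"), inherits(x, "iso_exprs"))
  if (!x$normalized) stop("build_polya_library requires normalized expression")
  cm <- condition_means(x)
  conds <- colnames(cm)
  tx <- ann$transcripts
  keep <- tx$is_coding & !tx$is_nmd & tx$transcript_id %in% rownames(cm)
  tx <- tx[keep, , drop = FALSE]
  clusters <- members <- genes <- list()
  for (g in unique(tx$gene_id)) {
    sub <- tx[tx$gene_id == g, , drop = FALSE]
    o <- order(sub$polya_pos)
    pos <- sub$polya_pos[o]; tid <- sub$transcript_id[o]
    cl <- cumsum(c(1L, diff(pos) > merge_window))   # single linkage in 1D
    total <- colSums(cm[tid, conds, drop = FALSE])
    if (all(total == 0)) next
    cdf <- data.frame(cluster = unique(cl))
    expr <- rowsum(cm[tid, conds, drop = FALSE], group = cl)
    share <- sweep(expr, 2, pmax(total, .Machine$double.eps), "/")
    surviving <- unique(cl)[apply(share >= min_frac, 1, any)]
    if (!length(surviving)) next
    tot_samp <- rowSums(x$values[tid, , drop = FALSE])
    rep_pos <- vapply(unique(cl), function(k) {
      idx <- which(cl == k)
      best <- idx[tot_samp[idx] == max(tot_samp[idx])]
      p <- pos[best]
      # tie-break: 3'-most in transcript orientation
      if (sub$strand[1L] == "+") max(p) else min(p)
    }, 0)
    names(rep_pos) <- unique(cl)
    # proximal = nearest the gene 5' end in transcript orientation
    sv_rep <- rep_pos[as.character(surviving)]
    prox <- surviving[if (sub$strand[1L] == "+") which.min(sv_rep) else which.max(sv_rep)]
    dist <- surviving[if (sub$strand[1L] == "+") which.max(sv_rep) else which.min(sv_rep)]
    label <- stats::setNames(rep(NA_character_, length(unique(cl))),
                             unique(cl))
    label[as.character(prox)] <- "proximal"
    label[as.character(dist)] <- "distal"
    for (k in setdiff(surviving, c(prox, dist))) {
      dp <- abs(rep_pos[as.character(k)] - rep_pos[as.character(prox)])
      dd <- abs(rep_pos[as.character(k)] - rep_pos[as.character(dist)])
      label[as.character(k)] <- if (dp <= dd) "proximal" else "distal"
    }
    eligible <- prox != dist &&
      abs(rep_pos[as.character(dist)] - rep_pos[as.character(prox)]) >= min_pair_dist
    kc <- unique(cl)[unique(cl) %in% surviving]
    clusters[[g]] <- data.frame(
      gene_id = g, cluster_id = paste0(g, ".", kc),
      rep_pos = unname(rep_pos[as.character(kc)]),
      span_start = vapply(kc, function(k) min(pos[cl == k]), 0),
      span_end = vapply(kc, function(k) max(pos[cl == k]), 0),
      label = unname(label[as.character(kc)]),
      n_members = vapply(kc, function(k) sum(cl == k), 0L),
      stringsAsFactors = FALSE)
    msel <- cl %in% surviving
    members[[g]] <- data.frame(
      gene_id = g, transcript_id = tid[msel],
      cluster_id = paste0(g, ".", cl[msel]),
      label = unname(label[as.character(cl[msel])]), stringsAsFactors = FALSE)
    genes[[g]] <- data.frame(
      gene_id = g, n_clusters = length(surviving),
      proximal_pos = unname(rep_pos[as.character(prox)]),
      distal_pos = unname(rep_pos[as.character(dist)]),
      pair_dist = abs(rep_pos[as.character(dist)] - rep_pos[as.character(prox)]),
      eligible = unname(eligible), stringsAsFactors = FALSE)
  }
  structure(list(clusters = do.call(rbind, clusters),
                 members = do.call(rbind, members),
                 genes = do.call(rbind, genes),
                 params = list(merge_window = merge_window, min_frac = min_frac,
                               min_pair_dist = min_pair_dist)),
            class = "polya_library")
}

#' @export
print.polya_library <- function(x, ...) {
  cat("polya_library:", if (is.null(x$genes)) 0 else nrow(x$genes), "genes,",
      if (is.null(x$clusters)) 0 else nrow(x$clusters), "clusters,",
      if (is.null(x$genes)) 0 else sum(x$genes$eligible), "eligible for DPA\n")
  invisible(x)
}

#' Export polyA clusters as BED
#'
#' Writes surviving clusters as 6-column BED (0-based half-open spans,
#' `gene|label` in the name field).
#'
#' @param lib a [build_polya_library()] result.
#' @param ann the matching [iso_annotation()] (for chromosome and strand).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polya_bed <- function(lib, ann, path) {
  cl <- lib$clusters
  g2 <- ann$transcripts[!duplicated(ann$transcripts$gene_id), ]
  i <- match(cl$gene_id, g2$gene_id)
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                   g2$chrom[i], as.integer(cl$span_start) - 1L,
                   as.integer(cl$span_end), cl$gene_id, cl$label, g2$strand[i])
  writeLines(lines, path)
  invisible(path)
}

#' Differential polyadenylation analysis
#'
#' For every DPA-eligible gene in the library, raw counts are collapsed into
#' distal and proximal aggregates and the 2-unit condition interaction is
#' tested with [fit_interaction_test()], BH-corrected across genes. Records
#' carry per-condition DPAU (from normalized condition means),
#' `delta_dpau = 100 * |DPAU_A - DPAU_B|`, the polyA switching flag (DPAU
#' crosses 0.5) and the favored condition (largest DPAU; ties `"none"`).
#'
#' @param lib a [build_polya_library()] result.
#' @param x raw transcript-level [iso_exprs()].
#' @param alpha FDR cutoff for the DPA flag.
#' @return data.frame, one row per eligible gene.
#' @export
run_dpa <- function(lib, x, alpha = 0.05) {
  stopifnot(inherits(lib, "polya_library"), inherits(x, "iso_exprs"))
  if (x$normalized) stop("run_dpa requires raw counts")
  norm <- normalize_expression(x)
  cm <- condition_means(norm)
  conds <- colnames(cm)
  cond <- x$design$condition
  offs <- norm$effective_lib_size
  el <- lib$genes$gene_id[lib$genes$eligible]
  rows <- lapply(el, function(g) {
    mem <- lib$members[lib$members$gene_id == g, , drop = FALSE]
    dtx <- mem$transcript_id[mem$label == "distal"]
    ptx <- mem$transcript_id[mem$label == "proximal"]
    e_d <- colSums(cm[dtx, conds, drop = FALSE])
    e_p <- colSums(cm[ptx, conds, drop = FALSE])
    dpau <- dpau_rate(e_d, e_p)
    agg <- rbind(dPA = colSums(x$values[dtx, , drop = FALSE]),
                 pPA = colSums(x$values[ptx, , drop = FALSE]))
    ft <- fit_interaction_test(agg, cond, offs)
    favored <- if (anyNA(dpau) || dpau[1L] == dpau[2L]) "none" else
      conds[which.max(dpau)]
    rec <- data.frame(gene_id = g, statistic = ft$statistic, df = ft$df,
                      p = ft$p, status = ft$status,
                      delta_dpau = 100 * abs(dpau[1L] - dpau[2L]),
                      polya_switching = !anyNA(dpau) &&
                        (dpau[1L] - 0.5) * (dpau[2L] - 0.5) < 0,
                      favored = favored, stringsAsFactors = FALSE)
    rec[[paste0("dpau_", conds[1L])]] <- unname(dpau[1L])
    rec[[paste0("dpau_", conds[2L])]] <- unname(dpau[2L])
    rec
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$fdr <- bh_adjust(out$p)
  out$dpa <- !is.na(out$fdr) & out$fdr < alpha
  rownames(out) <- NULL
  out
}

#' UTR lengthening / shortening analysis
#'
#' Computes the usage-weighted UTR length `UTRw = sum_i U_i * UTR_i` per gene
#' and condition over coding isoforms (usages renormalized to the coding
#' isoforms), and tests the per-gene differences `UTRw_B - UTRw_A` for a
#' global shift with a Wilcoxon signed-rank test (values are paired per
#' gene). An unpaired rank-sum variant is available with `paired = FALSE`.
#'
#' @param ann an [iso_annotation()].
#' @param usage a `usage_table` from [compute_usage()] on normalized
#'   transcript expression.
#' @param end `"utr3"` or `"utr5"`.
#' @param paired use the paired signed-rank test (default) or the unpaired
#'   rank-sum test.
#' @return list with `genes` (per-gene UTRw by condition and delta) and
#'   `test` (global statistic, p, method).
#' @export
run_utrl <- function(ann, usage, end = c("utr3", "utr5"), paired = TRUE) {
  end <- match.arg(end)
  conds <- attr(usage, "conditions")
  tx <- ann$transcripts
  lens <- stats::setNames(if (end == "utr3") tx$utr3_len else tx$utr5_len,
                          tx$transcript_id)
  coding <- tx$transcript_id[tx$is_coding]
  rows <- list()
  for (g in unique(usage$gene_id)) {
    sub <- usage[usage$gene_id == g & usage$unit_id %in% coding, , drop = FALSE]
    if (!nrow(sub)) next
    w <- stats::setNames(rep(NA_real_, length(conds)), conds)
    for (cc in conds) {
      u <- sub[[paste0("usage_", cc)]]
      if (anyNA(u) || sum(u) <= 0) next
      w[cc] <- utr_weighted_length(u / sum(u), lens[sub$unit_id])
    }
    rec <- data.frame(gene_id = g, stringsAsFactors = FALSE)
    rec[[paste0("utrw_", conds[1L])]] <- unname(w[1L])
    rec[[paste0("utrw_", conds[2L])]] <- unname(w[2L])
    rec$delta_utrw <- unname(w[2L] - w[1L])
    rows[[g]] <- rec
  }
  genes <- do.call(rbind, rows)
  test <- list(statistic = NA_real_, p = NA_real_,
               method = if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum")
  if (!is.null(genes)) {
    d <- genes$delta_utrw[!is.na(genes$delta_utrw)]
    if (length(d)) {
      if (all(d == 0)) {
        test$statistic <- 0; test$p <- 1
      } else if (paired) {
        wt <- suppressWarnings(stats::wilcox.test(d, mu = 0))
        test$statistic <- unname(wt$statistic); test$p <- wt$p.value
      } else {
        a <- genes[[paste0("utrw_", conds[1L])]]
        b <- genes[[paste0("utrw_", conds[2L])]]
        wt <- suppressWarnings(stats::wilcox.test(b, a))
        test$statistic <- unname(wt$statistic); test$p <- wt$p.value
      }
    }
  }
  list(genes = genes, test = test)
}
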