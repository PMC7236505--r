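# Functional Diversity Analysis: qualitative classification of genes and
# feature IDs as varying across isoforms, by presence or genomic position,
# plus the structural variants (APA, UTR lengths, CDS).

# projected annotations of one category (optionally one feature id) on a
# transcript: list of (feature_id, layer, intervals matrix or NULL)
feature_projections <- function(ann, transcript_id, category, feature_id = NULL) {
  f <- ann$features
  sel <- f$transcript_id == transcript_id & f$category == category
  if (!is.null(feature_id)) sel <- sel & f$feature_id == feature_id
  f <- f[sel, , drop = FALSE]
  lapply(seq_len(nrow(f)), function(i) {
    row <- f[i, ]
    iv <- if (row$layer == "none") NULL else
      project_feature_to_genomic(ann, transcript_id, row$start, row$end, row$layer)
    list(feature_id = row$feature_id, layer = row$layer, intervals = iv)
  })
}

# both endpoints of every interval within tol, interval-wise after sorting
positionally_equivalent <- function(iv1, iv2, tol_bp) {
  if (is.null(iv1) || is.null(iv2)) return(FALSE)
  if (nrow(iv1) != nrow(iv2)) return(FALSE)
  iv1 <- iv1[order(iv1[, 1L]), , drop = FALSE]
  iv2 <- iv2[order(iv2[, 1L]), , drop = FALSE]
  all(abs(iv1 - iv2) <= tol_bp)
}

# every annotation in a has an equivalent same-ID counterpart in b
covered_positionally <- function(a, b, tol_bp) {
  for (fa in a) {
    hit <- FALSE
    for (fb in b) {
      if (fb$feature_id == fa$feature_id &&
          positionally_equivalent(fa$intervals, fb$intervals, tol_bp)) {
        hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Presence / positional varying status of a functional category in a gene
#'
#' A gene varies for a category when at least one isoform pair differs in it.
#' In `presence` mode the pair must differ in carrying any annotation of the
#' category (or of one `feature_id` with `by = "feature_id"`). In
#' `positional` mode annotations are projected to genomic coordinates and the
#' pair varies when some annotation on one isoform has no counterpart of the
#' same feature id on the other with both endpoints within `tol_bp`
#' (disagreement must exceed 9 bp, i.e. 3 codons, by default). Presence-only
#' (layer `none`) categories are not positionally evaluable.
#'
#' @param ann an [iso_annotation()].
#' @param gene_id a multi-isoform gene.
#' @param category annotation category.
#' @param mode `"presence"` or `"positional"`.
#' @param tol_bp positional tolerance in bp (default 9).
#' @param by `"category"` for one call per category, `"feature_id"` for one
#'   call per feature id annotated on the gene.
#' @return data.frame with `gene_id`, `category`, `feature_id`, `mode`,
#'   `status` (`varying-evaluated`, `not_annotated`, `not_evaluable`),
#'   `varying`, and the witness isoform pair.
#' @export
varying_status <- function(ann, gene_id, category,
                           mode = c("presence", "positional"),
                           tol_bp = 9L, by = c("category", "feature_id")) {
  mode <- match.arg(mode); by <- match.arg(by)
  txs <- ann$transcripts$transcript_id[ann$transcripts$gene_id == gene_id]
  if (length(txs) < 2L)
    stop("contract error: varying status requires a multi-isoform gene")
  fsub <- ann$features[ann$features$transcript_id %in% txs &
                         ann$features$category == category, , drop = FALSE]
  mk <- function(feature_id, status, varying = NA, w1 = NA_character_,
                 w2 = NA_character_) {
    data.frame(gene_id = gene_id, category = category, feature_id = feature_id,
               mode = mode, status = status, varying = varying,
               witness_1 = w1, witness_2 = w2, stringsAsFactors = FALSE)
  }
  if (!nrow(fsub)) return(mk(NA_character_, "not_annotated"))
  ids <- if (by == "feature_id") sort(unique(fsub$feature_id)) else NA_character_
  out <- lapply(ids, function(id) {
    fid <- if (is.na(id)) NULL else id
    proj <- lapply(txs, function(tt) feature_projections(ann, tt, category, fid))
    names(proj) <- txs
    if (mode == "presence") {
      carrier <- lengths(proj) > 0L
      if (any(carrier) && !all(carrier))
        return(mk(id, "varying-evaluated", TRUE,
                  txs[which(carrier)[1L]], txs[which(!carrier)[1L]]))
      return(mk(id, "varying-evaluated", FALSE))
    }
    layers <- unique(fsub$layer[if (is.null(fid)) TRUE else fsub$feature_id == fid])
    if (all(layers == "none")) return(mk(id, "not_evaluable"))
    for (i in seq_along(txs)[-length(txs)]) for (j in (i + 1L):length(txs)) {
      a <- proj[[i]]; b <- proj[[j]]
      if (!covered_positionally(a, b, tol_bp) ||
          !covered_positionally(b, a, tol_bp))
        return(mk(id, "varying-evaluated", TRUE, txs[i], txs[j]))
    }
    mk(id, "varying-evaluated", FALSE)
  })
  do.call(rbind, out)
}

#' Structural variation of a gene: APA, UTR lengths, CDS
#'
#' `apa`: varying when some isoform pair's polyA positions (the 3'-most
#' genomic base of each isoform) differ by at least `apa_min_bp` (default
#' 100), absolute genomic distance. `utr3` / `utr5`: varying when some pair
#' of coding isoforms' UTR lengths differ by more than `utr_min_bp` (default
#' 75). `cds`: varying when some pair of coding isoforms differs in genomic
#' CDS intervals or CDS length. Non-coding isoforms are excluded from the
#' UTR/CDS kinds; fewer than two coding isoforms yields `not_evaluable`.
#'
#' @param ann an [iso_annotation()].
#' @param gene_id a multi-isoform gene.
#' @param kind one of `"apa"`, `"utr3"`, `"utr5"`, `"cds"`.
#' @param apa_min_bp,utr_min_bp thresholds in bp.
#' @return one-row data.frame as in [varying_status()].
#' @export
structural_varying <- function(ann, gene_id,
                               kind = c("apa", "utr3", "utr5", "cds"),
                               apa_min_bp = 100L, utr_min_bp = 75L) {
  kind <- match.arg(kind)
  tx <- ann$transcripts[ann$transcripts$gene_id == gene_id, , drop = FALSE]
  if (nrow(tx) < 2L)
    stop("contract error: structural varying requires a multi-isoform gene")
  mk <- function(status, varying = NA, w1 = NA_character_, w2 = NA_character_)
    data.frame(gene_id = gene_id, category = toupper(kind), feature_id = NA_character_,
               mode = "positional", status = status, varying = varying,
               witness_1 = w1, witness_2 = w2, stringsAsFactors = FALSE)
  if (kind == "apa") {
    pos <- tx$polya_pos
    for (i in seq_len(nrow(tx) - 1L)) for (j in (i + 1L):nrow(tx))
      if (abs(pos[i] - pos[j]) >= apa_min_bp)
        return(mk("varying-evaluated", TRUE, tx$transcript_id[i], tx$transcript_id[j]))
    return(mk("varying-evaluated", FALSE))
  }
  ctx <- tx[tx$is_coding, , drop = FALSE]
  if (nrow(ctx) < 2L) return(mk("not_evaluable"))
  if (kind %in% c("utr3", "utr5")) {
    len <- if (kind == "utr3") ctx$utr3_len else ctx$utr5_len
    for (i in seq_len(nrow(ctx) - 1L)) for (j in (i + 1L):nrow(ctx))
      if (abs(len[i] - len[j]) > utr_min_bp)
        return(mk("varying-evaluated", TRUE, ctx$transcript_id[i], ctx$transcript_id[j]))
    return(mk("varying-evaluated", FALSE))
  }
  keys <- vapply(ctx$transcript_id, function(tt) cds_genomic_key(ann, tt), "")
  for (i in seq_len(nrow(ctx) - 1L)) for (j in (i + 1L):nrow(ctx))
    if (keys[i] != keys[j] || ctx$cds_len[i] != ctx$cds_len[j])
      return(mk("varying-evaluated", TRUE, ctx$transcript_id[i], ctx$transcript_id[j]))
  mk("varying-evaluated", FALSE)
}

#' Category-level functional diversity summary
#'
#' For every annotation category (and, optionally, the structural kinds APA,
#' UTR3, UTR5, CDS) counts the multi-isoform genes annotated for it, those
#' varying, and the varying rate. Categories annotated on no multi-isoform
#' gene are excluded with a notice.
#'
#' @param ann an [iso_annotation()].
#' @param mode `"presence"` or `"positional"` for functional categories.
#' @param categories categories to evaluate (default: all in the annotation).
#' @param tol_bp,apa_min_bp,utr_min_bp thresholds, see [varying_status()] and
#'   [structural_varying()].
#' @param structural include the structural kinds (default TRUE).
#' @return data.frame with `category`, `mode`, `n_annotated`, `n_varying`,
#'   `rate`.
#' @export
fda_summary <- function(ann, mode = c("presence", "positional"),
                        categories = NULL, tol_bp = 9L, structural = TRUE,
                        apa_min_bp = 100L, utr_min_bp = 75L) {
  mode <- match.arg(mode)
  if (is.null(categories)) categories <- sort(unique(ann$features$category))
  genes <- multi_isoform_genes(ann)
  rows <- list()
  for (cat in categories) {
    calls <- lapply(genes, function(g)
      varying_status(ann, g, cat, mode = mode, tol_bp = tol_bp))
    calls <- do.call(rbind, calls)
    ev <- calls[calls$status == "varying-evaluated", , drop = FALSE]
    if (!nrow(ev)) {
      message("category ", cat, " not annotated/evaluable on any multi-isoform gene; skipped")
      next
    }
    rows[[cat]] <- data.frame(category = cat, mode = mode,
                              n_annotated = nrow(ev), n_varying = sum(ev$varying),
                              rate = mean(ev$varying), stringsAsFactors = FALSE)
  }
  if (structural) for (kind in c("apa", "utr3", "utr5", "cds")) {
    calls <- do.call(rbind, lapply(genes, function(g)
      structural_varying(ann, g, kind, apa_min_bp, utr_min_bp)))
    ev <- calls[calls$status == "varying-evaluated", , drop = FALSE]
    if (!nrow(ev)) next
    rows[[toupper(kind)]] <- data.frame(
      category = toupper(kind), mode = "positional", n_annotated = nrow(ev),
      n_varying = sum(ev$varying), rate = mean(ev$varying),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature-ID-level diversity with Fisher enrichment
#'
#' Calls varying status per feature id of one category across multi-isoform
#' genes, then tests each id's enrichment in varying status against all other
#' ids of the category with a two-sided Fisher exact test on the 2x2 table of
#' (varying, non-varying) gene counts, BH-corrected across ids.
#'
#' @inheritParams fda_summary
#' @param category one annotation category.
#' @return data.frame with per-id annotated/varying counts, `p` and `fdr`.
#' @export
fda_by_id <- function(ann, category, mode = c("presence", "positional"),
                      tol_bp = 9L) {
  mode <- match.arg(mode)
  genes <- multi_isoform_genes(ann)
  calls <- do.call(rbind, lapply(genes, function(g)
    varying_status(ann, g, category, mode = mode, tol_bp = tol_bp,
                   by = "feature_id")))
  calls <- calls[calls$status == "varying-evaluated", , drop = FALSE]
  if (!nrow(calls)) stop("category ", category, " has no evaluable feature ids")
  agg <- stats::aggregate(varying ~ feature_id, data = calls,
                          FUN = function(v) c(n = length(v), v = sum(v)))
  n_ann <- agg$varying[, "n"]; n_var <- agg$varying[, "v"]
  tot_ann <- sum(n_ann); tot_var <- sum(n_var)
  p <- vapply(seq_along(n_ann), function(i) {
    tab <- matrix(c(n_var[i], n_ann[i] - n_var[i],
                    tot_var - n_var[i],
                    (tot_ann - tot_var) - (n_ann[i] - n_var[i])), 2, byrow = TRUE)
    stats::fisher.test(tab)$p.value
  }, 0)
  data.frame(category = category, feature_id = agg$feature_id,
             n_genes_annotated = n_ann, n_genes_varying = n_var,
             rate = n_var / n_ann, p = p, fdr = bh_adjust(p),
             stringsAsFactors = FALSE)
}
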