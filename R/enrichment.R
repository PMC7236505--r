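# Fisher-based functional enrichment of a gene list against a background.

#' Fisher exact enrichment of a gene list
#'
#' For every term annotated on at least one test-set gene, builds the 2x2
#' table of term membership against test-set membership within the
#' background, runs a two-sided Fisher exact test, and corrects across terms
#' by BH. Terms can come from any annotation category: a gene carries a term
#' when any of its isoforms is annotated with the corresponding feature id.
#'
#' @param test_genes character vector of genes of interest (must be a subset
#'   of the background).
#' @param background_genes character vector defining the universe.
#' @param annotation either an [iso_annotation()] (with `category` selecting
#'   the feature category to use) or a data.frame with columns `gene_id` and
#'   `term_id`.
#' @param category annotation category when `annotation` is an
#'   [iso_annotation()]; `NULL` uses all categories.
#' @return data.frame with per-term counts, odds ratio, `p` and `fdr`.
#' @export
fisher_enrichment <- function(test_genes, background_genes, annotation,
                              category = NULL) {
  test_genes <- unique(test_genes)
  background_genes <- unique(background_genes)
  if (!length(test_genes)) stop("contract error: empty test gene list")
  if (!all(test_genes %in% background_genes))
    stop("contract error: test genes must be a subset of the background")
  if (inherits(annotation, "iso_annotation")) {
    f <- annotation$features
    if (!is.null(category)) f <- f[f$category %in% category, , drop = FALSE]
    g <- tx2gene(annotation)[f$transcript_id]
    terms <- data.frame(gene_id = unname(g), term_id = f$feature_id,
                        category = f$category, stringsAsFactors = FALSE)
  } else {
    terms <- as.data.frame(annotation, stringsAsFactors = FALSE)
    if (is.null(terms$category)) terms$category <- "term"
    stopifnot(all(c("gene_id", "term_id") %in% names(terms)))
  }
  terms <- terms[terms$gene_id %in% background_genes, , drop = FALSE]
  terms <- terms[!duplicated(paste(terms$gene_id, terms$term_id)), , drop = FALSE]
  n_bg <- length(background_genes)
  n_test <- length(test_genes)
  rows <- lapply(split(terms, terms$term_id), function(sub) {
    with_term <- unique(sub$gene_id)
    a <- sum(test_genes %in% with_term)
    if (a == 0L) return(NULL)
    b <- n_test - a
    c2 <- length(with_term) - a
    d <- (n_bg - n_test) - c2
    ft <- stats::fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE))
    data.frame(term_id = sub$term_id[1L], category = sub$category[1L],
               n_test_with = a, n_test_without = b,
               n_bg_with = c2, n_bg_without = d,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
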