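# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# write annotation dialect lines to a temp file, return the path
write_ann_lines <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

struct_line <- function(tx, cat, s, e, strand = "+", attrs = ".", src = "sim") {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", tx, src, cat, s, e, strand, attrs)
}

feat_line <- function(tx, cat, s, e, id, layer = "transcript", desc = "", src = "db") {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t.\t.\tID=%s;Desc=%s;Layer=%s",
          tx, src, cat, s, e, id, desc, layer)
}

# single-exon coding transcript: exon [g1,g2], CDS [c1,c2] genomic
coding_tx_lines <- function(tx, gene, g1, g2, c1 = NULL, c2 = NULL,
                            strand = "+", chrom = "chr1", extra_exons = NULL) {
  at <- sprintf("Chr=%s;Strand=%s;Gene=%s", chrom, strand, gene)
  ex <- rbind(c(g1, g2), extra_exons)
  span <- c(min(ex), max(ex))
  if (strand == "-") ex <- ex[order(-ex[, 1L]), , drop = FALSE]
  out <- struct_line(tx, "genomic", span[1], span[2], strand, at)
  out <- c(out, apply(ex, 1, function(r)
    struct_line(tx, "exon", r[1], r[2], strand)))
  if (!is.null(c1)) out <- c(out, struct_line(tx, "CDS", c1, c2, strand))
  last <- ex[nrow(ex), ]
  pa <- if (strand == "+") last[2] else last[1]
  c(out, struct_line(tx, "polyA", pa, pa, strand))
}

# iso_exprs with deterministic values and a standard 2x3 design
make_exprs <- function(values, n_reps = 3L, conditions = c("A", "B")) {
  samples <- paste0(rep(conditions, each = n_reps), "_", seq_len(n_reps))
  if (is.null(colnames(values))) colnames(values) <- samples
  iso_exprs(values, data.frame(sample = colnames(values),
                               condition = rep(conditions, each = n_reps)))
}

# exact two-sided Fisher p by enumeration of the hypergeometric support
# (minimum-likelihood convention), built from choose() only
fisher_oracle_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  pobs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# exact two-sided binomial p at p0 = 0.5 by enumeration
binom_oracle_p <- function(x, n) {
  probs <- choose(n, 0:n) * 0.5^n
  pobs <- probs[x + 1L]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# literal BH step-up: adjusted p_(i) = min_{j >= i} min(1, n * p_(j) / j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  a <- n * p[o] / seq_len(n)
  if (n > 1) for (i in (n - 1):1) a[i] <- min(a[i], a[i + 1])
  out <- numeric(n)
  out[o] <- pmin(1, a)
  out
}

# random single-transcript annotation for projection property tests
random_tx_annotation <- function(n_exons, strand) {
  widths <- sample(20:120, n_exons, replace = TRUE)
  gaps <- sample(50:500, n_exons, replace = TRUE)
  gstart <- cumsum(c(sample(1:1000, 1), head(widths + gaps, -1)))
  ex_plus <- cbind(gstart, gstart + widths - 1L)
  ex <- if (strand == "+") ex_plus else ex_plus[order(-ex_plus[, 1L]), , drop = FALSE]
  exdf <- data.frame(transcript_id = "T1", rank = seq_len(n_exons),
                     gstart = as.integer(ex[, 1L]), gend = as.integer(ex[, 2L]))
  tlen <- sum(widths)
  tx <- data.frame(transcript_id = "T1", gene_id = "G1", chrom = "chr1",
                   strand = strand, source = "sim", length = tlen,
                   is_coding = FALSE, is_nmd = FALSE, utr5_len = 0L,
                   cds_len = 0L, utr3_len = 0L, cds_gstart = NA_integer_,
                   cds_gend = NA_integer_,
                   polya_pos = if (strand == "+") exdf$gend[n_exons] else exdf$gstart[n_exons],
                   stringsAsFactors = FALSE)
  iso_annotation(tx, exdf, isofit:::empty_features_df())
}

# brute-force transcript->genome lookup table by walking exons base by base
per_base_map <- function(exdf, strand) {
  g <- integer(0)
  for (i in seq_len(nrow(exdf))) {
    r <- exdf$gstart[i]:exdf$gend[i]
    if (strand == "-") r <- rev(r)
    g <- c(g, r)
  }
  g
}
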