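# Two-isoform fixture on a shared 1-1000 exon so transcript coordinates equal
# genomic coordinates; features can then be placed at exact genomic positions.
two_tx_ann <- function(f1_start, f1_end, f2_start, f2_end, id1 = "F1",
                       id2 = "F1", tx2_has = TRUE) {
  lines <- c(coding_tx_lines("T1", "G1", 1L, 1000L, 101L, 400L),
             coding_tx_lines("T2", "G1", 1L, 1000L, 101L, 400L),
             feat_line("T1", "PFAM", f1_start, f1_end, id1))
  if (tx2_has)
    lines <- c(lines, feat_line("T2", "PFAM", f2_start, f2_end, id2))
  parse_annotation(write_ann_lines(lines))
}

test_that("presence and positional varying follow the pairwise rules", {
  # identical annotation sets -> not varying in either mode
  same <- two_tx_ann(200L, 260L, 200L, 260L)
  expect_false(varying_status(same, "G1", "PFAM", "presence")$varying)
  expect_false(varying_status(same, "G1", "PFAM", "positional")$varying)
  # feature on isoform 1 only -> presence varying (and hence positional too)
  only1 <- two_tx_ann(200L, 260L, 0L, 0L, tx2_has = FALSE)
  expect_true(varying_status(only1, "G1", "PFAM", "presence")$varying)
  expect_true(varying_status(only1, "G1", "PFAM", "positional")$varying)
  # end shifted by 12 bp -> positional varying at tol 9; 6 bp -> not
  shift12 <- two_tx_ann(200L, 260L, 200L, 272L)
  shift6 <- two_tx_ann(200L, 260L, 200L, 266L)
  expect_true(varying_status(shift12, "G1", "PFAM", "positional")$varying)
  expect_false(varying_status(shift6, "G1", "PFAM", "positional")$varying)
  expect_false(varying_status(shift12, "G1", "PFAM", "presence")$varying)
  # raising the tolerance is monotone: varying never appears
  expect_false(varying_status(shift12, "G1", "PFAM", "positional",
                              tol_bp = 12L)$varying)
  # witness pair is reported exactly when varying
  v <- varying_status(shift12, "G1", "PFAM", "positional")
  expect_setequal(c(v$witness_1, v$witness_2), c("T1", "T2"))
  expect_true(all(is.na(varying_status(same, "G1", "PFAM",
                                       "positional")[, c("witness_1", "witness_2")])))
})

test_that("status handling distinguishes absent and non-evaluable", {
  only1 <- two_tx_ann(200L, 260L, 0L, 0L, tx2_has = FALSE)
  expect_equal(varying_status(only1, "G1", "MIRNA", "presence")$status,
               "not_annotated")
  # presence-only labels cannot be positionally evaluated
  lines <- c(coding_tx_lines("T1", "G1", 1L, 1000L, 101L, 400L),
             coding_tx_lines("T2", "G1", 1L, 1000L, 101L, 400L),
             feat_line("T1", "NMD", 1L, 1L, "NMD", layer = "none"))
  ann <- parse_annotation(write_ann_lines(lines))
  expect_equal(varying_status(ann, "G1", "NMD", "positional")$status,
               "not_evaluable")
  expect_true(varying_status(ann, "G1", "NMD", "presence")$varying)
  single <- parse_annotation(write_ann_lines(
    coding_tx_lines("TS", "GS", 1L, 300L, 10L, 100L)))
  expect_error(varying_status(single, "GS", "PFAM", "presence"),
               "contract error")
})

test_that("varying calls are symmetric and duplicate-isoform invariant", {
  sim <- simulate_dataset(simulation_spec(n_genes = 15, seed = 4,
                                          motif_frac = 1))
  ann <- sim$annotation
  for (g in multi_isoform_genes(ann)) {
    v0 <- varying_status(ann, g, "DOMAIN", "presence")$varying
    # duplicate the first isoform (new id, same structure and features)
    ann2 <- ann
    t1 <- ann$transcripts$transcript_id[ann$transcripts$gene_id == g][1]
    dup <- function(df) {
      d <- df[df$transcript_id == t1, , drop = FALSE]
      if (!nrow(d)) return(df)
      d$transcript_id <- paste0(t1, "_dup")
      rbind(df, d)
    }
    ann2$transcripts <- dup(ann2$transcripts)
    ann2$exons <- dup(ann2$exons)
    ann2$features <- dup(ann2$features)
    expect_equal(varying_status(ann2, g, "DOMAIN", "presence")$varying, v0)
  }
})

test_that("presence variation implies positional variation", {
  sim <- simulate_dataset(simulation_spec(n_genes = 40, seed = 12,
                                          motif_frac = 1))
  for (g in multi_isoform_genes(sim$annotation)) {
    for (cat in c("DOMAIN", "MOTIF")) {
      pres <- varying_status(sim$annotation, g, cat, "presence")
      pos <- varying_status(sim$annotation, g, cat, "positional")
      if (pres$status == "varying-evaluated" && isTRUE(pres$varying))
        expect_true(pos$varying)
    }
  }
})

test_that("structural variation thresholds match the defaults", {
  # polyA ends 1000 vs 1120: 120 >= 100 -> APA varying
  lines <- c(coding_tx_lines("T1", "G1", 1L, 1000L, 101L, 400L),
             coding_tx_lines("T2", "G1", 1L, 1120L, 101L, 400L))
  ann <- parse_annotation(write_ann_lines(lines))
  expect_true(structural_varying(ann, "G1", "apa")$varying)
  expect_false(structural_varying(ann, "G1", "apa", apa_min_bp = 121L)$varying)
  # 3'UTR lengths 600 vs 650 differ by 50 <= 75 -> not varying
  expect_equal(ann$transcripts$utr3_len, c(600L, 720L))
  lines2 <- c(coding_tx_lines("T1", "G1", 1L, 1000L, 101L, 400L),
              coding_tx_lines("T2", "G1", 1L, 1050L, 101L, 400L))
  ann2 <- parse_annotation(write_ann_lines(lines2))
  expect_equal(ann2$transcripts$utr3_len, c(600L, 650L))
  expect_false(structural_varying(ann2, "G1", "utr3")$varying)
  expect_true(structural_varying(ann2, "G1", "utr3", utr_min_bp = 49L)$varying)
  # identical CDS spans with different 3' UTRs are not CDS varying
  expect_false(structural_varying(ann, "G1", "cds")$varying)
  lines3 <- c(coding_tx_lines("T1", "G1", 1L, 1000L, 101L, 400L),
              coding_tx_lines("T2", "G1", 1L, 1000L, 101L, 460L))
  expect_true(structural_varying(parse_annotation(write_ann_lines(lines3)),
                                 "G1", "cds")$varying)
  # UTR/CDS kinds need two coding isoforms
  lines4 <- c(coding_tx_lines("T1", "G1", 1L, 1000L, 101L, 400L),
              coding_tx_lines("T2", "G1", 1L, 1000L))
  nc <- parse_annotation(write_ann_lines(lines4))
  expect_equal(structural_varying(nc, "G1", "utr3")$status, "not_evaluable")
  expect_equal(structural_varying(nc, "G1", "cds")$status, "not_evaluable")
  expect_equal(structural_varying(nc, "G1", "apa")$status, "varying-evaluated")
})

test_that("category summaries aggregate hand-countable fixtures", {
  # 3 genes: G1 domain varying (on one isoform), G2 domain on both isoforms
  # (not varying), G3 not annotated for DOMAIN
  lines <- c(coding_tx_lines("A1", "G1", 1L, 1000L, 101L, 400L),
             coding_tx_lines("A2", "G1", 1L, 1120L, 101L, 400L),
             feat_line("A1", "DOMAIN", 150L, 210L, "D1"),
             coding_tx_lines("B1", "G2", 2001L, 3000L, 2101L, 2400L),
             coding_tx_lines("B2", "G2", 2001L, 3120L, 2101L, 2400L),
             feat_line("B1", "DOMAIN", 150L, 210L, "D1"),
             feat_line("B2", "DOMAIN", 150L, 210L, "D1"),
             coding_tx_lines("C1", "G3", 4001L, 5000L, 4101L, 4400L),
             coding_tx_lines("C2", "G3", 4001L, 5120L, 4101L, 4400L))
  ann <- parse_annotation(write_ann_lines(lines))
  s <- fda_summary(ann, "presence")
  dom <- s[s$category == "DOMAIN", ]
  expect_equal(dom$n_annotated, 2L)   # G3 is not annotated
  expect_equal(dom$n_varying, 1L)
  expect_equal(dom$rate, 0.5)
  apa <- s[s$category == "APA", ]
  expect_equal(apa$n_annotated, 3L)
  expect_equal(apa$n_varying, 3L)     # all ends differ by 120 bp
  # a category absent from all multi-isoform genes is skipped with a message
  expect_message(fda_summary(ann, "presence", categories = "GHOST",
                             structural = FALSE), "GHOST")
})

test_that("feature-ID diversity tests enrichment against the category rest", {
  # 30 genes; D1 annotated on 10 genes and varying in 8 of them; D2 on the
  # other 20, varying in 4: Fisher on (8,2 | 4,16)
  lines <- character(); g0 <- 0L
  for (i in 1:30) {
    g <- sprintf("G%02d", i); t1 <- paste0("T", i, "a"); t2 <- paste0("T", i, "b")
    base <- 1L + g0; g0 <- g0 + 5000L
    lines <- c(lines,
               coding_tx_lines(t1, g, base, base + 999L, base + 100L, base + 399L),
               coding_tx_lines(t2, g, base, base + 1119L, base + 100L, base + 399L))
    id <- if (i <= 10) "D1" else "D2"
    varying <- if (i <= 10) i <= 8 else i <= 14
    lines <- c(lines, feat_line(t1, "DOMAIN", 150L, 210L, id))
    if (!varying) lines <- c(lines, feat_line(t2, "DOMAIN", 150L, 210L, id))
  }
  ann <- parse_annotation(write_ann_lines(lines))
  res <- fda_by_id(ann, "DOMAIN", "presence")
  expect_equal(res$n_genes_annotated, c(10L, 20L))
  expect_equal(res$n_genes_varying, c(8L, 4L))
  d1 <- res[res$feature_id == "D1", ]
  expect_equal(d1$p, fisher_oracle_p(8, 2, 4, 16), tolerance = 1e-12)
  expect_equal(res$fdr, bh_adjust(res$p))
})
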