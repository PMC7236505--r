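# three single-exon coding isoforms with polyA ends 1000 / 1050 / 2000 and
# controllable expression shares
polya_fixture <- function(shares_a = c(0.4, 0.2, 0.4), shares_b = shares_a,
                          depth = 1000) {
  lines <- c(coding_tx_lines("Q1", "G1", 1L, 1000L, 101L, 400L),
             coding_tx_lines("Q2", "G1", 51L, 1050L, 151L, 450L),
             coding_tx_lines("Q3", "G1", 1L, 2000L, 101L, 400L))
  ann <- parse_annotation(write_ann_lines(lines))
  cnt <- cbind(matrix(rep(shares_a * depth, 3), 3),
               matrix(rep(shares_b * depth, 3), 3))
  dimnames(cnt) <- list(c("Q1", "Q2", "Q3"),
                        paste0(rep(c("A", "B"), each = 3), "_", 1:3))
  list(ann = ann, x = make_exprs(cnt))
}

test_that("polyA ends at 1000/1050/2000 cluster into an eligible pair", {
  fx <- polya_fixture()
  lib <- build_polya_library(fx$ann, normalize_expression(fx$x))
  expect_equal(nrow(lib$clusters), 2L)
  expect_equal(sort(lib$clusters$n_members), c(1L, 2L))
  # proximal = {1000, 1050} cluster (represented by the most expressed, Q1),
  # distal = {2000}
  expect_equal(lib$clusters$label[lib$clusters$rep_pos == 1000], "proximal")
  expect_equal(lib$clusters$label[lib$clusters$rep_pos == 2000], "distal")
  expect_true(lib$genes$eligible)
  expect_equal(lib$genes$pair_dist, 1000)
  # both members of the merged cluster carry the proximal label
  mem <- lib$members
  expect_setequal(mem$transcript_id[mem$label == "proximal"], c("Q1", "Q2"))
})

test_that("minor sites are dropped at the 10% floor and thresholds are monotone", {
  # Q2 carries 5% in both conditions -> its cluster member is dropped only
  # if the whole cluster is minor; give Q1+Q2 a separate minor cluster
  fx <- polya_fixture(shares_a = c(0.05, 0.04, 0.91))
  lib <- build_polya_library(fx$ann, normalize_expression(fx$x))
  # merged cluster {1000,1050} holds 9% < 10% -> dropped; lone distal remains
  expect_equal(nrow(lib$clusters), 1L)
  expect_false(lib$genes$eligible)
  # at a 5% floor the pair survives
  lib5 <- build_polya_library(fx$ann, normalize_expression(fx$x),
                              min_frac = 0.05)
  expect_equal(nrow(lib5$clusters), 2L)
  expect_true(lib5$genes$eligible)
  # raising min_frac never keeps more clusters
  for (mf in c(0.01, 0.05, 0.10, 0.25)) {
    l1 <- build_polya_library(fx$ann, normalize_expression(fx$x), min_frac = mf)
    l2 <- build_polya_library(fx$ann, normalize_expression(fx$x),
                              min_frac = mf + 0.05)
    n1 <- if (is.null(l1$clusters)) 0L else nrow(l1$clusters)
    n2 <- if (is.null(l2$clusters)) 0L else nrow(l2$clusters)
    expect_lte(n2, n1)
  }
  # lowering merge_window never merges more
  fx2 <- polya_fixture()
  for (w in c(10, 40, 75, 200)) {
    lw <- build_polya_library(fx2$ann, normalize_expression(fx2$x),
                              merge_window = w)
    ls <- build_polya_library(fx2$ann, normalize_expression(fx2$x),
                              merge_window = w / 2)
    expect_gte(nrow(ls$clusters), nrow(lw$clusters))
  }
})

test_that("clustering is idempotent and respects the pair distance", {
  fx <- polya_fixture()
  norm <- normalize_expression(fx$x)
  lib <- build_polya_library(fx$ann, norm)
  # re-clustering the representatives reproduces the clusters (they are
  # pairwise farther apart than the merge window)
  reps <- lib$clusters$rep_pos
  expect_true(all(diff(sort(reps)) > lib$params$merge_window))
  # a pair closer than min_pair_dist is not eligible
  lib2 <- build_polya_library(fx$ann, norm, min_pair_dist = 1001L)
  expect_false(lib2$genes$eligible)
  # single-polyA gene: one cluster, not eligible
  lines <- c(coding_tx_lines("R1", "G9", 1L, 900L, 101L, 400L),
             coding_tx_lines("R2", "G9", 1L, 900L, 101L, 460L))
  ann1 <- parse_annotation(write_ann_lines(lines))
  cnt <- matrix(500, 2, 6, dimnames = list(c("R1", "R2"),
                                           colnames(fx$x$values)))
  l1 <- build_polya_library(ann1, normalize_expression(make_exprs(cnt)))
  expect_equal(nrow(l1$clusters), 1L)
  expect_false(l1$genes$eligible)
})

test_that("NMD and non-coding isoforms are excluded from the library", {
  # T2 is coding but NMD (stop far upstream of the last junction)
  lines <- c(coding_tx_lines("N1", "G1", 1L, 1000L, 101L, 400L),
             coding_tx_lines("N2", "G1", 1L, 500L, 10L, 100L,
                             extra_exons = rbind(c(1201L, 2000L))),
             coding_tx_lines("N3", "G1", 1L, 3000L))   # non-coding
  ann <- parse_annotation(write_ann_lines(lines))
  expect_true(ann$transcripts$is_nmd[2])
  cnt <- matrix(300, 3, 6, dimnames = list(c("N1", "N2", "N3"),
                                           paste0(rep(c("A", "B"), each = 3), "_", 1:3)))
  lib <- build_polya_library(ann, normalize_expression(make_exprs(cnt)))
  expect_equal(lib$members$transcript_id, "N1")
})

test_that("DPAU follows the formula and detects planted flips", {
  expect_equal(dpau_rate(30, 10), 0.75)
  expect_equal(dpau_rate(0, 10), 0)
  expect_true(is.na(dpau_rate(0, 0)))
  # planted distal -> proximal flip at depth 2000
  fx <- polya_fixture(shares_a = c(0.85, 0, 0.15), shares_b = c(0.15, 0, 0.85),
                      depth = 2000)
  set.seed(1)
  x <- fx$x
  x$values <- matrix(rnbinom(length(x$values), mu = as.vector(x$values),
                             size = 20), nrow(x$values),
                     dimnames = dimnames(x$values))
  lib <- build_polya_library(fx$ann, normalize_expression(x))
  res <- run_dpa(lib, x)
  expect_equal(nrow(res), 1L)
  expect_lt(res$fdr, 1e-4)
  expect_true(res$polya_switching)
  expect_lt(abs(res$dpau_A - 0.15), 0.08)
  expect_lt(abs(res$dpau_B - 0.85), 0.08)
  expect_equal(res$favored, "B")
  expect_lt(abs(res$delta_dpau - 70), 10)
  # all-distal expression: DPAU 1 in both conditions, no test signal
  fx1 <- polya_fixture(shares_a = c(0.0, 0.0, 1.0))
  libx <- build_polya_library(fx1$ann, normalize_expression(fx1$x))
  expect_false(libx$genes$eligible)   # proximal cluster below the floor
})

test_that("delta-DPAU equals total usage change for 2-cluster 2-isoform genes", {
  set.seed(9)
  for (i in 1:200) {
    e <- matrix(runif(4, 1, 100), 2)   # rows: distal, proximal; cols: A, B
    d <- 100 * abs(dpau_rate(e[1, 1], e[2, 1]) - dpau_rate(e[1, 2], e[2, 2]))
    expect_equal(d, total_usage_change(e[, 1], e[, 2]), tolerance = 1e-9)
  }
})

test_that("UTRw is the usage-weighted UTR length with convex bounds", {
  expect_equal(utr_weighted_length(c(0.25, 0.75), c(100, 500)), 400)
  expect_equal(utr_weighted_length(1, 300), 300)
  set.seed(4)
  for (i in 1:100) {
    u <- rgamma(4, 1); u <- u / sum(u)
    len <- sample(50:800, 4)
    w <- utr_weighted_length(u, len)
    expect_gte(w, min(len)); expect_lte(w, max(len))
  }
})

test_that("UTR lengthening analysis weights usage and tests the global shift", {
  fx <- polya_fixture(shares_a = c(0.25, 0, 0.75))
  norm <- normalize_expression(fx$x)
  usage <- compute_usage(norm, tx2gene(fx$ann))
  res <- run_utrl(fx$ann, usage, end = "utr3")
  # identical usage in both conditions: delta 0, global p = 1
  expect_equal(res$genes$delta_utrw, 0, tolerance = 1e-9)
  expect_equal(res$test$p, 1)
  # utr3 lengths: Q1 600, Q2 600, Q3 1600; usage (.25, 0, .75) -> 1350
  expect_equal(res$genes$utrw_A, 0.25 * 600 + 0.75 * 1600, tolerance = 1)
  # single isoform gene: UTRw equals its UTR length in both conditions
  lines <- c(coding_tx_lines("S1", "GS", 1L, 1000L, 101L, 700L))
  ann1 <- parse_annotation(write_ann_lines(lines))
  cnt <- matrix(100, 1, 6, dimnames = list("S1", colnames(fx$x$values)))
  u1 <- compute_usage(normalize_expression(make_exprs(cnt)), tx2gene(ann1))
  r1 <- run_utrl(ann1, u1)
  expect_equal(r1$genes$utrw_A, 300)
  expect_equal(r1$genes$utrw_B, 300)
  # a planted usage shift toward the long isoform lengthens UTRw in B
  fx2 <- polya_fixture(shares_a = c(0.8, 0, 0.2), shares_b = c(0.2, 0, 0.8))
  u2 <- compute_usage(normalize_expression(fx2$x), tx2gene(fx2$ann))
  r2 <- run_utrl(fx2$ann, u2)
  expect_gt(r2$genes$delta_utrw, 500)
})
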