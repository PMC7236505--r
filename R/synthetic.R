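# Synthetic two-group isoform datasets with planted usage effects.
#
# Every generated gene is a self-consistent transcript family: isoforms share
# a 5' exon and differ in their 3' exon, so isoform families expose distinct
# polyA sites (>= 600 bp apart), 3' UTR length differences and a protein
# domain tracking one isoform. Counts are negative binomial around
# gene_mean x usage x library factor, with the usage vector flipped between
# conditions for planted genes. This makes the algebraic identities of the
# analysis modules (delta-FI = delta-DPAU = total usage change for 2-isoform
# genes) hold in expectation by construction.

#' Specification of a synthetic dataset
#'
#' @param n_genes number of genes.
#' @param seed RNG seed (mandatory; the dataset is a pure function of the
#'   spec).
#' @param conditions two condition labels.
#' @param reps_per_condition replicates per condition (default 3).
#' @param isoform_dist named probability vector over isoform counts per gene.
#' @param mean_range range of gene-level expected counts, sampled
#'   log-uniformly (default 50-500).
#' @param dispersion_range range of per-gene NB dispersions (default
#'   0.05-0.3).
#' @param frac_planted fraction of genes with a planted usage flip; planted
#'   genes are forced to two isoforms and are simultaneously DIU, DFI (the
#'   domain tracks isoform 1) and DPA (the isoforms use distinct polyA
#'   clusters) positives.
#' @param usage_flip usage of isoform 1 in condition 1 and condition 2 for
#'   planted genes (default `c(0.8, 0.2)`).
#' @param motif_frac fraction of genes additionally carrying a non-varying
#'   motif shared by all isoforms (default 0.5).
#' @param lib_factor_range per-sample library depth factor range.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000L, seed,
                            conditions = c("A", "B"),
                            reps_per_condition = 3L,
                            isoform_dist = c(`1` = 0.25, `2` = 0.40,
                                             `3` = 0.25, `4` = 0.10),
                            mean_range = c(50, 500),
                            dispersion_range = c(0.05, 0.3),
                            frac_planted = 0,
                            usage_flip = c(0.8, 0.2),
                            motif_frac = 0.5,
                            lib_factor_range = c(0.8, 1.2)) {
  if (missing(seed)) stop("spec error: a seed is mandatory")
  stopifnot(length(conditions) == 2L, reps_per_condition >= 2L,
            abs(sum(isoform_dist) - 1) < 1e-8, all(dispersion_range > 0),
            frac_planted >= 0, frac_planted <= 1,
            all(usage_flip > 0), all(usage_flip < 1))
  if (frac_planted > 0 && all(as.integer(names(isoform_dist))[isoform_dist > 0] < 2L))
    stop("spec error: planted usage effects need genes with >=2 isoforms")
  structure(list(n_genes = as.integer(n_genes), seed = as.integer(seed),
                 conditions = conditions,
                 reps_per_condition = as.integer(reps_per_condition),
                 isoform_dist = isoform_dist, mean_range = mean_range,
                 dispersion_range = dispersion_range,
                 frac_planted = frac_planted, usage_flip = usage_flip,
                 motif_frac = motif_frac, lib_factor_range = lib_factor_range),
            class = "simulation_spec")
}

# structural plan of one gene; local plus-strand layout reflected for minus
make_gene_structure <- function(gene_id, gi, chrom, strand, g0, n_iso) {
  exon1_w <- 400L
  tx_rows <- exon_rows <- vector("list", n_iso)
  width_total <- exon1_w + (600L + (n_iso - 1L) * 600L) +
    (300L + (n_iso - 1L) * 200L)
  for (i in seq_len(n_iso)) {
    gap <- 600L + (i - 1L) * 600L
    l2 <- 300L + (i - 1L) * 200L
    ex_local <- rbind(c(1L, exon1_w),
                      c(exon1_w + gap + 1L, exon1_w + gap + l2))
    tlen <- exon1_w + l2
    utr3 <- 100L + (i - 1L) * 150L
    utr5 <- 100L + ((tlen - utr3 - 100L) %% 3L)
    cds_len <- tlen - utr5 - utr3
    if (strand == "+") {
      ex <- cbind(g0 + ex_local[, 1L] - 1L, g0 + ex_local[, 2L] - 1L)
    } else {
      ex <- cbind(g0 + width_total - ex_local[, 2L],
                  g0 + width_total - ex_local[, 1L])
    }
    tid <- sprintf("TX%05d.%d", gi, i)
    exdf <- data.frame(transcript_id = tid, rank = seq_len(nrow(ex)),
                       gstart = as.integer(ex[, 1L]),
                       gend = as.integer(ex[, 2L]))
    cds_g1 <- tx_to_genomic(exdf, strand, utr5 + 1L)
    cds_g2 <- tx_to_genomic(exdf, strand, tlen - utr3)
    pa <- if (strand == "+") exdf$gend[nrow(exdf)] else exdf$gstart[nrow(exdf)]
    tx_rows[[i]] <- data.frame(
      transcript_id = tid, gene_id = gene_id, chrom = chrom, strand = strand,
      source = "sim", length = tlen, is_coding = TRUE,
      is_nmd = nmd_from_lengths(tlen, utr5, cds_len,
                                exdf$gend - exdf$gstart + 1L, 50L),
      utr5_len = utr5, cds_len = cds_len, utr3_len = utr3,
      cds_gstart = cds_g1, cds_gend = cds_g2, polya_pos = pa,
      stringsAsFactors = FALSE)
    exon_rows[[i]] <- exdf
  }
  list(transcripts = do.call(rbind, tx_rows), exons = do.call(rbind, exon_rows))
}

#' Simulate an annotated two-group isoform dataset
#'
#' Generates transcript structures satisfying the annotation invariants, a
#' negative-binomial count matrix, the experimental design and a ground-truth
#' table; optionally writes all four to `dir` (annotation dialect, counts
#' TSV, design TSV, truth TSV). Fully reproducible from `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @param dir optional output directory.
#' @return list with `annotation` ([iso_annotation()]), `counts` (matrix),
#'   `design` (data.frame), `truth` (data.frame) and `spec`.
#' @export
simulate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  n_planted <- round(spec$frac_planted * ng)
  planted <- rep(FALSE, ng)
  if (n_planted > 0) planted[sample.int(ng, n_planted)] <- TRUE
  k_opts <- as.integer(names(spec$isoform_dist))
  n_iso <- sample(k_opts, ng, replace = TRUE, prob = spec$isoform_dist)
  n_iso[planted] <- 2L
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  chrom <- paste0("chr", sample(1:5, ng, replace = TRUE))
  gene_mean <- exp(stats::runif(ng, log(spec$mean_range[1L]),
                                log(spec$mean_range[2L])))
  phi <- stats::runif(ng, spec$dispersion_range[1L], spec$dispersion_range[2L])
  has_motif <- stats::runif(ng) < spec$motif_frac

  n_s <- 2L * spec$reps_per_condition
  samples <- paste0(rep(spec$conditions, each = spec$reps_per_condition),
                    "_", seq_len(spec$reps_per_condition))
  cond <- rep(spec$conditions, each = spec$reps_per_condition)
  libfac <- stats::runif(n_s, spec$lib_factor_range[1L], spec$lib_factor_range[2L])

  tx_list <- ex_list <- feat_list <- vector("list", ng)
  counts_list <- vector("list", ng)
  truth <- vector("list", ng)
  for (g in seq_len(ng)) {
    gene_id <- sprintf("G%05d", g)
    st <- make_gene_structure(gene_id, g, chrom[g], strand[g],
                              1L + (g - 1L) * 50000L, n_iso[g])
    tx_list[[g]] <- st$transcripts
    ex_list[[g]] <- st$exons
    tids <- st$transcripts$transcript_id
    k <- n_iso[g]
    feats <- NULL
    if (k >= 2L) {
      feats <- data.frame(transcript_id = tids[1L], source = "PFAM",
                          category = "DOMAIN",
                          feature_id = sprintf("PF%05d", g),
                          layer = "protein", start = 5L, end = 10L,
                          description = "synthetic domain",
                          stringsAsFactors = FALSE)
    }
    if (has_motif[g]) {
      feats <- rbind(feats, data.frame(
        transcript_id = tids, source = "RBPDB", category = "MOTIF",
        feature_id = sprintf("MT%05d", g), layer = "transcript",
        start = 10L, end = 30L, description = "shared motif",
        stringsAsFactors = FALSE))
    }
    feat_list[[g]] <- feats
    if (planted[g]) {
      u1 <- c(spec$usage_flip[1L], 1 - spec$usage_flip[1L])
      u2 <- c(spec$usage_flip[2L], 1 - spec$usage_flip[2L])
    } else {
      u1 <- u2 <- {
        w <- stats::rgamma(k, shape = 2)
        w / sum(w)
      }
    }
    usage <- cbind(u1, u2)[, match(cond, spec$conditions), drop = FALSE]
    mu <- gene_mean[g] * usage * rep(libfac, each = k)
    cnt <- matrix(stats::rnbinom(k * n_s, mu = mu, size = 1 / phi[g]),
                  nrow = k, dimnames = list(tids, samples))
    counts_list[[g]] <- cnt
    truth[[g]] <- data.frame(
      gene_id = gene_id, n_isoforms = k, planted = planted[g],
      is_diu = planted[g], is_dfi = planted[g], is_dpa = planted[g],
      planted_delta = if (planted[g])
        100 * abs(spec$usage_flip[1L] - spec$usage_flip[2L]) else 0,
      feature_id = if (k >= 2L) sprintf("PF%05d", g) else NA_character_,
      gene_mean = gene_mean[g], dispersion = phi[g],
      stringsAsFactors = FALSE)
  }
  ann <- iso_annotation(do.call(rbind, tx_list), do.call(rbind, ex_list),
                        do.call(rbind, feat_list))
  counts <- do.call(rbind, counts_list)
  design <- data.frame(sample = samples, condition = cond,
                       stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth)
  out <- list(annotation = ann, counts = counts, design = design,
              truth = truth, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_annotation(ann, file.path(dir, "annotation.gff3"))
    utils::write.table(data.frame(transcript_id = rownames(counts), counts,
                                  check.names = FALSE),
                       file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
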