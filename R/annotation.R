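#' @keywords internal
"_PACKAGE"

STRUCTURAL_CATEGORIES <- c("genomic", "exon", "CDS", "polyA")

#' Isoform-resolved annotation container
#'
#' An `iso_annotation` bundles the structural models of a set of transcripts
#' (exons, CDS span, UTR lengths, polyA position, coding/NMD status) with a
#' flat table of positional functional features attached to them. It is
#' produced by [parse_annotation()] or [simulate_dataset()] and consumed by
#' all analysis modules.
#'
#' @param transcripts data.frame of per-transcript structural fields.
#' @param exons data.frame with columns `transcript_id`, `rank`, `gstart`,
#'   `gend`; rows ordered 5'->3' in transcript orientation (descending genomic
#'   coordinates on the minus strand).
#' @param features data.frame of functional features with columns
#'   `transcript_id`, `source`, `category`, `feature_id`, `layer`, `start`,
#'   `end`, `description`. Coordinates live in the layer's space: nucleotides
#'   of the mature transcript for `layer == "transcript"`, codons for
#'   `layer == "protein"`; `layer == "none"` marks presence-only labels.
#' @param warnings character vector of parse/validation warnings.
#' @return An object of class `iso_annotation`.
#' @export
iso_annotation <- function(transcripts, exons, features, warnings = character()) {
  structure(list(transcripts = transcripts, exons = exons,
                 features = features, warnings = warnings),
            class = "iso_annotation")
}

#' @export
print.iso_annotation <- function(x, ...) {
  cat("iso_annotation:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes,",
      nrow(x$features), "feature records\n")
  if (nrow(x$features))
    cat("categories:", paste(sort(unique(x$features$category)), collapse = ", "), "\n")
  if (length(x$warnings)) cat(length(x$warnings), "warnings\n")
  invisible(x)
}

empty_transcripts_df <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             chrom = character(), strand = character(), source = character(),
             length = integer(), is_coding = logical(), is_nmd = logical(),
             utr5_len = integer(), cds_len = integer(), utr3_len = integer(),
             cds_gstart = integer(), cds_gend = integer(),
             polya_pos = integer(), stringsAsFactors = FALSE)
}

empty_features_df <- function() {
  data.frame(transcript_id = character(), source = character(),
             category = character(), feature_id = character(),
             layer = character(), start = integer(), end = integer(),
             description = character(), stringsAsFactors = FALSE)
}

parse_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) >= 2) paste(p[-1], collapse = "=") else "", "")
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' Parse an isoform functional annotation file
#'
#' Reads the 9-column, tab-separated gff3-like dialect used throughout the
#' package. Column 1 is the transcript id, column 2 the source database,
#' column 3 the feature category, columns 4-5 start/end coordinates in the
#' record's own space, column 7 the strand (structural rows), and column 9 a
#' `key=value;...` attribute string. Structural rows use the reserved
#' categories `genomic` (transcript span; attributes `Chr`, `Strand`, `Gene`),
#' `exon`, `CDS` and `polyA`, all with genomic coordinates; exon rows appear
#' in transcript 5'->3' order. Every other row is a functional feature with
#' attributes `ID=...;Desc=...;Layer=transcript|protein|none` and coordinates
#' in the layer's space (codons for the protein layer).
#'
#' Coding status is inferred from the presence of a CDS row; NMD status is
#' computed with the 50-nt rule (see [predict_nmd()]). Features referencing
#' unknown transcripts are dropped with a collected warning; unknown feature
#' categories are preserved verbatim.
#'
#' @param path path to the annotation file.
#' @param nmd_threshold_nt premature-stop distance (nt) for the NMD call.
#' @return An [iso_annotation()] object; `$warnings` holds non-fatal issues.
#' @export
parse_annotation <- function(path, nmd_threshold_nt = 50L) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(iso_annotation(empty_transcripts_df(),
                          data.frame(transcript_id = character(), rank = integer(),
                                     gstart = integer(), gend = integer()),
                          empty_features_df()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("parse error: expected 9 tab-separated columns at line ",
         which(nf != 9L)[1L], " (found ", nf[nf != 9L][1L], ")")
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  tx_col <- m[, 1L]; src <- m[, 2L]; cat_col <- m[, 3L]
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end))
    stop("parse error: non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1L])
  warnings <- character()

  is_struct <- cat_col %in% STRUCTURAL_CATEGORIES
  gi <- which(cat_col == "genomic")
  tx_ids <- tx_col[gi]
  if (anyDuplicated(tx_ids))
    stop("parse error: duplicated genomic record for transcript ",
         tx_ids[duplicated(tx_ids)][1L])

  exons_list <- vector("list", length(tx_ids))
  tx_rows <- vector("list", length(tx_ids))
  for (j in seq_along(gi)) {
    tid <- tx_ids[j]
    attrs <- parse_attrs(m[gi[j], 9L])
    strand <- if (!is.na(attrs["Strand"])) unname(attrs["Strand"]) else m[gi[j], 7L]
    if (!strand %in% c("+", "-"))
      stop("model error: transcript ", tid, " has invalid strand '", strand, "'")
    sel <- which(tx_col == tid & cat_col == "exon")
    if (!length(sel)) stop("model error: transcript ", tid, " has no exon records")
    ex <- data.frame(transcript_id = tid, rank = seq_along(sel),
                     gstart = start[sel], gend = end[sel])
    if (any(ex$gend < ex$gstart))
      stop("model error: exon with end < start in transcript ", tid)
    es <- ex[order(ex$gstart), ]
    if (nrow(es) > 1L && any(es$gstart[-1L] <= es$gend[-nrow(es)]))
      stop("model error: overlapping exons in transcript ", tid)
    # enforce transcript orientation of exon listing
    if (strand == "+") ex <- ex[order(ex$gstart), ] else ex <- ex[order(-ex$gstart), ]
    ex$rank <- seq_len(nrow(ex))
    exons_list[[j]] <- ex
    tlen <- sum(ex$gend - ex$gstart + 1L)

    ci <- which(tx_col == tid & cat_col == "CDS")
    is_coding <- length(ci) > 0L
    utr5 <- cds_len <- utr3 <- 0L
    cds_gstart <- cds_gend <- NA_integer_
    if (is_coding) {
      lo <- min(start[ci], end[ci]); hi <- max(start[ci], end[ci])
      first_base <- if (strand == "+") lo else hi   # start codon, first base
      last_base <- if (strand == "+") hi else lo    # stop codon, last base
      t1 <- genomic_to_tx(ex, strand, first_base)
      t2 <- genomic_to_tx(ex, strand, last_base)
      if (is.na(t1) || is.na(t2) || t2 < t1)
        stop("model error: CDS outside exons for transcript ", tid)
      utr5 <- t1 - 1L; cds_len <- t2 - t1 + 1L; utr3 <- tlen - utr5 - cds_len
      cds_gstart <- first_base; cds_gend <- last_base
    }
    pa_exon <- if (strand == "+") ex$gend[nrow(ex)] else ex$gstart[nrow(ex)]
    pi <- which(tx_col == tid & cat_col == "polyA")
    if (length(pi) && start[pi[1L]] != pa_exon)
      warnings <- c(warnings, paste0("polyA record for ", tid,
                                     " disagrees with last exon boundary; using exon-derived position"))
    nmd <- is_coding && nrow(ex) > 1L &&
      nmd_from_lengths(tlen, utr5, cds_len, ex$gend - ex$gstart + 1L, nmd_threshold_nt)
    tx_rows[[j]] <- data.frame(
      transcript_id = tid, gene_id = unname(attrs["Gene"]),
      chrom = unname(attrs["Chr"]), strand = strand, source = src[gi[j]],
      length = tlen, is_coding = is_coding, is_nmd = nmd,
      utr5_len = utr5, cds_len = cds_len, utr3_len = utr3,
      cds_gstart = cds_gstart, cds_gend = cds_gend, polya_pos = pa_exon,
      stringsAsFactors = FALSE)
  }
  transcripts <- do.call(rbind, tx_rows)
  if (is.null(transcripts)) transcripts <- empty_transcripts_df()
  exons <- do.call(rbind, exons_list)
  if (anyNA(transcripts$gene_id))
    stop("model error: transcript ",
         transcripts$transcript_id[is.na(transcripts$gene_id)][1L],
         " lacks a Gene attribute")

  fi <- which(!is_struct)
  if (length(fi)) {
    known <- tx_col[fi] %in% transcripts$transcript_id
    if (any(!known))
      warnings <- c(warnings, paste0("feature at line ", which(!is_struct)[!known],
                                     " references unknown transcript ",
                                     tx_col[fi][!known], "; dropped"))
    fi <- fi[known]
  }
  if (length(fi)) {
    al <- lapply(m[fi, 9L], parse_attrs)
    features <- data.frame(
      transcript_id = tx_col[fi], source = src[fi], category = cat_col[fi],
      feature_id = vapply(al, function(a) if (is.na(a["ID"])) "" else unname(a["ID"]), ""),
      layer = vapply(al, function(a) if (is.na(a["Layer"])) "transcript" else unname(a["Layer"]), ""),
      start = start[fi], end = end[fi],
      description = vapply(al, function(a) if (is.na(a["Desc"])) "" else unname(a["Desc"]), ""),
      stringsAsFactors = FALSE)
    bad <- !features$layer %in% c("transcript", "protein", "none")
    if (any(bad)) stop("parse error: invalid Layer '", features$layer[bad][1L], "'")
    if (any(features$layer != "none" & features$end < features$start))
      stop("model error: feature with end < start on transcript ",
           features$transcript_id[features$end < features$start][1L])
    features
  } else features <- empty_features_df()
  iso_annotation(transcripts, exons, features, warnings)
}

#' Write an annotation object back to the file dialect
#'
#' Inverse of [parse_annotation()]: emits genomic/exon/CDS/polyA structural
#' rows per transcript followed by its feature rows, so that
#' `parse_annotation(write_annotation(x))` reproduces `x` record-for-record.
#'
#' @param ann an [iso_annotation()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "iso_annotation"))
  con <- file(path, "w"); on.exit(close(con))
  tx <- ann$transcripts
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    ex <- ann$exons[ann$exons$transcript_id == t$transcript_id, , drop = FALSE]
    ex <- ex[order(ex$rank), , drop = FALSE]
    span <- c(min(ex$gstart), max(ex$gend))
    rows <- sprintf("%s\t%s\tgenomic\t%d\t%d\t.\t%s\t.\tChr=%s;Strand=%s;Gene=%s",
                    t$transcript_id, t$source, span[1], span[2], t$strand,
                    t$chrom, t$strand, t$gene_id)
    rows <- c(rows, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t.",
                            t$transcript_id, t$source, ex$gstart, ex$gend, t$strand))
    if (t$is_coding)
      rows <- c(rows, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t.\t.",
                              t$transcript_id, t$source,
                              min(t$cds_gstart, t$cds_gend),
                              max(t$cds_gstart, t$cds_gend), t$strand))
    rows <- c(rows, sprintf("%s\t%s\tpolyA\t%d\t%d\t.\t%s\t.\t.",
                            t$transcript_id, t$source, t$polya_pos, t$polya_pos, t$strand))
    f <- ann$features[ann$features$transcript_id == t$transcript_id, , drop = FALSE]
    if (nrow(f)) {
      f <- f[order(f$category, f$feature_id, f$start), , drop = FALSE]
      rows <- c(rows, sprintf("%s\t%s\t%s\t%d\t%d\t.\t.\t.\tID=%s;Desc=%s;Layer=%s",
                              f$transcript_id, f$source, f$category,
                              f$start, f$end, f$feature_id, f$description, f$layer))
    }
    writeLines(rows, con)
  }
  invisible(path)
}

# transcript coordinate of genomic position g; NA if not exonic.
# ex: exon df in transcript orientation.
genomic_to_tx <- function(ex, strand, g) {
  w <- ex$gend - ex$gstart + 1L
  offs <- c(0L, cumsum(w))
  for (i in seq_len(nrow(ex))) {
    if (g >= ex$gstart[i] && g <= ex$gend[i]) {
      d <- if (strand == "+") g - ex$gstart[i] else ex$gend[i] - g
      return(offs[i] + d + 1L)
    }
  }
  NA_integer_
}

# genomic position of transcript coordinate t (scalar)
tx_to_genomic <- function(ex, strand, t) {
  w <- ex$gend - ex$gstart + 1L
  offs <- cumsum(w)
  i <- which(t <= offs)[1L]
  if (is.na(i) || t < 1L) return(NA_integer_)
  d <- t - c(0L, offs)[i] - 1L
  if (strand == "+") ex$gstart[i] + d else ex$gend[i] - d
}

exons_of <- function(ann, transcript_id) {
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(ex)) stop("unknown transcript ", transcript_id)
  ex[order(ex$rank), , drop = FALSE]
}

#' Project a feature from layer coordinates to genomic intervals
#'
#' Converts a feature's coordinates to nucleotide positions on the mature
#' transcript (codon c of the protein layer covers transcript nucleotides
#' `utr5_len + 3c - 2 .. utr5_len + 3c`), then splits the transcript interval
#' across exon boundaries. Intervals are returned 5'->3' in transcript order,
#' each with `gstart <= gend`.
#'
#' @param ann an [iso_annotation()].
#' @param transcript_id transcript carrying the feature.
#' @param start,end 1-based inclusive coordinates in the layer's space.
#' @param layer `"transcript"` or `"protein"`.
#' @return integer matrix with columns `gstart`, `gend`, one row per interval.
#' @export
project_feature_to_genomic <- function(ann, transcript_id, start, end,
                                       layer = c("transcript", "protein")) {
  layer <- match.arg(layer)
  tx <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, ]
  if (!nrow(tx)) stop("unknown transcript ", transcript_id)
  if (start > end || start < 1L) stop("coordinate error: invalid feature interval")
  if (layer == "protein") {
    if (!tx$is_coding)
      stop("contract error: protein-layer feature on non-coding transcript ",
           transcript_id)
    s <- tx$utr5_len + 3L * start - 2L
    e <- tx$utr5_len + 3L * end
  } else {
    s <- as.integer(start); e <- as.integer(end)
  }
  if (e > tx$length)
    stop("coordinate error: feature extends past end of transcript ", transcript_id)
  ex <- exons_of(ann, transcript_id)
  w <- ex$gend - ex$gstart + 1L
  offs <- cumsum(w)
  lo <- c(1L, offs[-length(offs)] + 1L)
  out <- NULL
  for (i in seq_len(nrow(ex))) {
    a <- max(s, lo[i]); b <- min(e, offs[i])
    if (a > b) next
    g1 <- tx_to_genomic(ex, tx$strand, a)
    g2 <- tx_to_genomic(ex, tx$strand, b)
    out <- rbind(out, c(min(g1, g2), max(g1, g2)))
  }
  colnames(out) <- c("gstart", "gend")
  out
}

nmd_from_lengths <- function(tlen, utr5, cds_len, exon_widths, threshold_nt) {
  if (length(exon_widths) < 2L) return(FALSE)
  stop_pos <- utr5 + cds_len
  last_junction <- tlen - exon_widths[length(exon_widths)]
  (last_junction - stop_pos) > threshold_nt
}

#' Predict NMD status with the 50-nt rule
#'
#' A coding transcript is flagged as a likely nonsense-mediated decay target
#' when the last base of its stop codon lies strictly more than
#' `threshold_nt` nucleotides (transcript coordinates) upstream of the last
#' exon-exon junction - the classical 50-nt premature-termination-codon rule.
#' Single-exon transcripts are never flagged.
#'
#' @param ann an [iso_annotation()].
#' @param transcript_id a coding transcript.
#' @param threshold_nt rule threshold in nucleotides (default 50).
#' @return logical.
#' @export
predict_nmd <- function(ann, transcript_id, threshold_nt = 50L) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, ]
  if (!nrow(tx)) stop("unknown transcript ", transcript_id)
  if (!tx$is_coding)
    stop("contract error: NMD prediction requires a coding transcript")
  ex <- exons_of(ann, transcript_id)
  nmd_from_lengths(tx$length, tx$utr5_len, tx$cds_len,
                   ex$gend - ex$gstart + 1L, threshold_nt)
}

# genomic CDS interval key (chrom:strand:sorted interval list); NA for non-coding
cds_genomic_key <- function(ann, transcript_id) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, ]
  if (!tx$is_coding) return(NA_character_)
  iv <- project_feature_to_genomic(ann, transcript_id,
                                   tx$utr5_len + 1L, tx$utr5_len + tx$cds_len,
                                   layer = "transcript")
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  paste0(tx$chrom, ":", tx$strand, ":",
         paste(iv[, 1L], iv[, 2L], sep = "-", collapse = ","))
}

#' Map transcripts to genes
#'
#' @param ann an [iso_annotation()].
#' @return named character vector, transcript id -> gene id.
#' @export
tx2gene <- function(ann) {
  stats::setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
}

#' Gene ids with at least `min_isoforms` annotated isoforms
#' @param ann an [iso_annotation()].
#' @param min_isoforms minimum isoform count (default 2).
#' @return character vector of gene ids.
#' @export
multi_isoform_genes <- function(ann, min_isoforms = 2L) {
  tab <- table(ann$transcripts$gene_id)
  names(tab)[tab >= min_isoforms]
}
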