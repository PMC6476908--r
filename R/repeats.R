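#' Repeat-element composition of a mapped read set
#'
#' A read counts toward a repeat class if it overlaps any interval of that
#' class by >= 1 bp; a read overlapping several classes counts once per
#' class but only once in the `any_RE` total, so the per-class counts may
#' exceed the total by the multi-class allowance. Proportions are of the
#' sample's declared `total_mapped`. The length-and-depth normalized
#' abundance is `count * 1e9 / (class_span_bp * total_mapped)` with the
#' class span the reduced (non-redundant) genomic length of its intervals.
#'
#' @param rs a `read_set`.
#' @param track repeat `GRanges` from [read_repeat_table()].
#' @return data.frame with one row per class plus an `any_RE` row:
#'   `re_class`, `read_count`, `proportion`, `normalized_abundance`,
#'   `span_bp`.
#' @export
re_read_fraction <- function(rs, track) {
  reads <- rs$reads
  total <- rs$total_mapped
  classes <- re_classes()
  rows <- lapply(classes, function(cl) {
    sub <- track[track$re_class == cl]
    span <- sum(width(reduce(sub, ignore.strand = TRUE)))
    cnt <- if (length(sub)) sum(overlapsAny(reads, sub, ignore.strand = TRUE))
           else 0L
    data.frame(re_class = cl, read_count = cnt,
               proportion = if (total > 0) cnt / total else 0,
               normalized_abundance = if (span > 0 && total > 0)
                 cnt * 1e9 / (span * total) else 0,
               span_bp = span)
  })
  any_cnt <- if (length(track)) sum(overlapsAny(reads, track,
                                                ignore.strand = TRUE)) else 0L
  any_span <- sum(width(reduce(track, ignore.strand = TRUE)))
  rows[[length(rows) + 1L]] <-
    data.frame(re_class = "any_RE", read_count = any_cnt,
               proportion = if (total > 0) any_cnt / total else 0,
               normalized_abundance = if (any_span > 0 && total > 0)
                 any_cnt * 1e9 / (any_span * total) else 0,
               span_bp = any_span)
  do.call(rbind, rows)
}

#' Detected lncRNAs in an abundance matrix
#'
#' Features carrying the lncRNA biotype in the annotation and showing
#' abundance above zero in at least one sample.
#'
#' @param mat features x samples abundance matrix with gene ids as
#'   rownames.
#' @param annotation a `genome_annotation` with a `biotype` column on genes.
#' @return data.frame with `gene_id`, `max_abundance`, `n_samples_detected`;
#'   empty (with a warning) when the annotation carries no lncRNA biotype.
#' @export
lncrna_profile <- function(mat, annotation) {
  bt <- annotation$genes$biotype
  lnc <- annotation$genes$gene_id[!is.na(bt) & bt %in% c("lncRNA", "lincRNA")]
  if (!length(lnc)) {
    warning("annotation carries no lncRNA biotype")
    return(data.frame(gene_id = character(0), max_abundance = numeric(0),
                      n_samples_detected = integer(0)))
  }
  sub <- mat[rownames(mat) %in% lnc, , drop = FALSE]
  det <- rowSums(sub > 0) > 0
  sub <- sub[det, , drop = FALSE]
  data.frame(gene_id = rownames(sub),
             max_abundance = if (nrow(sub)) apply(sub, 1, max) else numeric(0),
             n_samples_detected = as.integer(rowSums(sub > 0)),
             row.names = NULL)
}

#' Candidate cis targets of lncRNAs
#'
#' Protein-coding genes whose span lies strictly closer than `window` bp
#' (end-to-start gap, unstranded; 0 when overlapping) to a lncRNA gene
#' span. The distance is symmetric in the pair.
#'
#' @param lnc_ids character vector of lncRNA gene ids.
#' @param annotation a `genome_annotation`.
#' @param window bp, default 20,000 (strict `<`).
#' @return data.frame with `lncrna_id`, `coding_id`, `distance`.
#' @export
cis_targets <- function(lnc_ids, annotation, window = 20000L) {
  genes <- annotation$genes
  lnc <- genes[genes$gene_id %in% lnc_ids]
  coding <- genes[!is.na(genes$biotype) & genes$biotype == "protein_coding"]
  if (!length(lnc) || !length(coding))
    return(data.frame(lncrna_id = character(0), coding_id = character(0),
                      distance = numeric(0)))
  hits <- findOverlaps(lnc, coding, maxgap = window - 1L,
                       ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(lncrna_id = character(0), coding_id = character(0),
                      distance = numeric(0)))
  d <- distance(lnc[queryHits(hits)], coding[subjectHits(hits)],
                ignore.strand = TRUE)
  keep <- d < window
  data.frame(lncrna_id = lnc$gene_id[queryHits(hits)][keep],
             coding_id = coding$gene_id[subjectHits(hits)][keep],
             distance = d[keep], row.names = NULL)
}
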