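#' Transcript integrity number from a coverage vector
#'
#' With per-base depths `c_i` over the `L` exonic bases of a transcript and
#' `p_i = c_i / sum(c)` over covered bases, the score is
#' `TIN = 100 * exp(H) / L` where `H = -sum(p_i log p_i)` is the Shannon
#' entropy of the coverage profile. `exp(H)` is the effective number of
#' covered bases, so uniform coverage over a fraction `f` of the bases gives
#' exactly `100 * f`, a fully and uniformly covered transcript scores 100,
#' and an uncovered one scores 0. The score is invariant to scaling the
#' coverage by any positive constant. Every base is used (no position
#' subsampling), so the computation is deterministic.
#'
#' @param coverage non-negative numeric vector of per-base read depth over
#'   the transcript's exonic bases.
#' @return TIN in `[0, 100]`.
#' @export
compute_tin <- function(coverage) {
  stopifnot(length(coverage) >= 1L, all(coverage >= 0))
  total <- sum(coverage)
  if (total == 0) return(0)
  p <- coverage[coverage > 0] / total
  h <- -sum(p * log(p))
  100 * exp(h) / length(coverage)
}

#' Fragmentation class of a TIN score
#'
#' `fragmented` iff TIN <= 25, `intact` iff TIN > 75, else `intermediate`.
#'
#' @param tin numeric TIN value(s) in `[0, 100]`.
#' @return factor with levels fragmented/intermediate/intact.
#' @export
classify_fragmentation <- function(tin) {
  stopifnot(all(tin >= 0 & tin <= 100))
  cls <- ifelse(tin <= 25, "fragmented", ifelse(tin > 75, "intact",
                                                "intermediate"))
  factor(cls, levels = c("fragmented", "intermediate", "intact"))
}

#' Per-transcript, per-sample TIN and FPKM from read alignments
#'
#' For each transcript, per-base coverage over the union of its exons is
#' assembled from the sample's reads and scored with [compute_tin()];
#' abundance is FPKM over the exonic length with the sample's declared
#' `total_mapped` as depth denominator. Transcripts with zero coverage are
#' kept with TIN 0 (downstream analyses may filter on `fpkm > 0 & tin > 0`).
#'
#' @param read_sets list of `read_set` objects.
#' @param annotation a `genome_annotation`.
#' @return data.frame with `transcript_id`, `gene_id`, `sample_id`, `tin`,
#'   `fpkm`, `exonic_length`.
#' @export
transcript_tin <- function(read_sets, annotation) {
  if (inherits(read_sets, "read_set")) read_sets <- list(read_sets)
  ex_by_tx <- split(annotation$exons, annotation$exons$transcript_id)
  tx_ids <- annotation$transcripts$transcript_id
  gene_ids <- setNames(annotation$transcripts$gene_id, tx_ids)
  rows <- vector("list", length(read_sets))
  for (si in seq_along(read_sets)) {
    rs <- read_sets[[si]]
    cov <- coverage(rs$reads)
    tin <- numeric(length(tx_ids)); fpkm <- numeric(length(tx_ids))
    elen <- numeric(length(tx_ids))
    for (ti in seq_along(tx_ids)) {
      ex <- ex_by_tx[[tx_ids[ti]]]
      chr <- as.character(seqnames(ex))[1]
      elen[ti] <- sum(width(ex))
      if (chr %in% names(cov)) {
        rle <- cov[[chr]]
        v <- unlist(lapply(seq_along(ex), function(i) {
          s <- start(ex[i]); e <- end(ex[i])
          if (s > length(rle)) return(numeric(e - s + 1L))
          e2 <- min(e, length(rle))
          c(as.numeric(window(rle, s, e2)), numeric(e - e2))
        }), use.names = FALSE)
      } else {
        v <- numeric(elen[ti])
      }
      tin[ti] <- compute_tin(v)
      nreads <- countOverlaps(reduce(ex), rs$reads, ignore.strand = TRUE)
      fpkm[ti] <- sum(nreads) * 1e9 / (elen[ti] * rs$total_mapped)
    }
    rows[[si]] <- data.frame(transcript_id = tx_ids,
                             gene_id = unname(gene_ids[tx_ids]),
                             sample_id = rs$sample_id, tin = tin,
                             fpkm = fpkm, exonic_length = elen,
                             row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Pivot [transcript_tin()] output into a transcripts x samples matrix
#'
#' @param tin_df data.frame from [transcript_tin()].
#' @param value column to pivot (`"tin"` or `"fpkm"`).
#' @return numeric matrix, transcripts in rows.
#' @export
tin_matrix <- function(tin_df, value = "tin") {
  tx <- unique(tin_df$transcript_id)
  sm <- unique(tin_df$sample_id)
  m <- matrix(NA_real_, length(tx), length(sm), dimnames = list(tx, sm))
  m[cbind(match(tin_df$transcript_id, tx), match(tin_df$sample_id, sm))] <-
    tin_df[[value]]
  m
}

#' TIN correlation summaries
#'
#' Pairwise Pearson correlations of TIN profiles between samples (over
#' transcripts defined in both members of a pair), plus per-sample Pearson
#' correlations of TIN against transcript length and abundance. Pairs or
#' covariates with zero variance give `NA` and are reported as such.
#'
#' @param tin_mat transcripts x samples TIN matrix (see [tin_matrix()]).
#' @param length numeric transcript length per row (CDS length where
#'   annotated, exonic length otherwise).
#' @param abundance transcripts x samples abundance matrix (or a vector).
#' @return list with `sample_cor` (samples x samples matrix),
#'   `length_cor` and `abundance_cor` (named per sample).
#' @export
tin_correlations <- function(tin_mat, length = NULL, abundance = NULL) {
  if (nrow(tin_mat) < 3L) stop("need >= 3 transcripts")
  safe_cor <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  ns <- ncol(tin_mat)
  sc <- matrix(NA_real_, ns, ns, dimnames = list(colnames(tin_mat),
                                                 colnames(tin_mat)))
  for (i in seq_len(ns)) for (j in seq_len(ns))
    sc[i, j] <- if (i == j) 1 else safe_cor(tin_mat[, i], tin_mat[, j])
  lc <- ac <- setNames(rep(NA_real_, ns), colnames(tin_mat))
  if (!is.null(length))
    lc[] <- vapply(seq_len(ns), function(j) safe_cor(tin_mat[, j], length), 0)
  if (!is.null(abundance)) {
    if (is.matrix(abundance)) {
      ac[] <- vapply(seq_len(ns), function(j)
        safe_cor(tin_mat[, j], abundance[, j]), 0)
    } else {
      ac[] <- vapply(seq_len(ns), function(j)
        safe_cor(tin_mat[, j], abundance), 0)
    }
  }
  list(sample_cor = sc, length_cor = lc, abundance_cor = ac)
}
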