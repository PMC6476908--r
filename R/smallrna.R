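#' Counts-per-million normalization of small-RNA counts
#'
#' `CPM = count * 1e6 / depth` per sample.
#'
#' @param counts features x samples raw count matrix.
#' @param depth per-sample sequencing depth (positive, length `ncol`).
#' @return CPM matrix of the same shape.
#' @export
normalize_cpm <- function(counts, depth) {
  stopifnot(is.matrix(counts), length(depth) == ncol(counts))
  if (any(depth <= 0)) stop("depth must be > 0")
  sweep(counts * 1e6, 2L, depth, "/")
}

#' Keep features detected in every sample
#'
#' Detection = raw count > 0; used e.g. for the ubiquitously detected miRNA
#' filter.
#'
#' @param counts features x samples raw count matrix.
#' @return the rows of `counts` with a nonzero count in every sample.
#' @export
filter_ubiquitous <- function(counts) {
  counts[rowSums(counts > 0) == ncol(counts), , drop = FALSE]
}

#' Call de novo piRNA clusters in one sample
#'
#' Reads are filtered to the piRNA length range (26-33 nt inclusive by
#' default; read length = interval width), merged into intervals in which
#' consecutive reads are separated by at most `max_gap` bp, and a merged
#' interval is emitted iff its span reaches `min_cluster_length` and it
#' contains at least `min_reads` reads.
#'
#' @param rs a `read_set` of length-annotated small-RNA reads.
#' @param len_min,len_max read length bounds, nt (defaults 26 and 33).
#' @param min_cluster_length minimum cluster span, bp (default 5,000).
#' @param max_gap maximum inter-read gap merged, bp (default 1,000).
#' @param min_reads minimum supporting reads per cluster (default 10).
#' @return `GRanges` of clusters with metadata column `read_count`.
#' @export
call_pirna_clusters <- function(rs, len_min = 26L, len_max = 33L,
                                min_cluster_length = 5000L,
                                max_gap = 1000L, min_reads = 10L) {
  reads <- rs$reads
  reads <- reads[width(reads) >= len_min & width(reads) <= len_max]
  if (!length(reads))
    return(GRanges(read_count = integer(0)))
  merged <- reduce(granges(reads), min.gapwidth = max_gap + 1L,
                   ignore.strand = TRUE)
  cnt <- countOverlaps(merged, reads, ignore.strand = TRUE)
  keep <- width(merged) >= min_cluster_length & cnt >= min_reads
  out <- merged[keep]
  ord <- order(as.character(seqnames(out)), start(out))
  out <- out[ord]
  mcols(out)$read_count <- as.integer(cnt[keep][ord])
  out
}

#' Consensus piRNA clusters reproducible across samples
#'
#' Per-sample clusters that overlap by >= 1 bp are grouped transitively; a
#' consensus cluster (the union span of its group) is emitted iff the group
#' contains clusters from at least `min_samples` distinct samples. The
#' result is invariant to the order of the per-sample lists and every
#' member cluster lies inside its consensus span.
#'
#' @param cluster_list named list of per-sample cluster `GRanges` (from
#'   [call_pirna_clusters()]).
#' @param min_samples minimum number of supporting samples (default 3).
#' @return `GRanges` of consensus clusters with metadata column
#'   `n_samples_supporting`.
#' @export
reproducible_clusters <- function(cluster_list, min_samples = 3L) {
  if (is.null(names(cluster_list)))
    names(cluster_list) <- sprintf("sample_%d", seq_along(cluster_list))
  pooled <- do.call(c, c(lapply(cluster_list, granges), use.names = FALSE))
  if (!length(pooled))
    return(GRanges(n_samples_supporting = integer(0)))
  sample_of <- rep(names(cluster_list), lengths(cluster_list))
  # min.gapwidth = 0: merge only truly overlapping (>= 1 bp) clusters,
  # transitively; book-ended clusters are not merged
  groups <- reduce(pooled, min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- findOverlaps(groups, pooled, ignore.strand = TRUE)
  supp <- vapply(split(sample_of[subjectHits(hits)], queryHits(hits)),
                 function(s) length(unique(s)), 0L)
  n_support <- integer(length(groups))
  n_support[as.integer(names(supp))] <- supp
  out <- groups[n_support >= min_samples]
  supp_out <- n_support[n_support >= min_samples]
  ord <- order(as.character(seqnames(out)), start(out))
  out <- out[ord]
  mcols(out)$n_samples_supporting <- supp_out[ord]
  out
}

#' Repeat-element overlap of piRNA clusters
#'
#' A cluster is flagged as RE-overlapping if any repeat interval intersects
#' it by >= 1 bp. The distribution of overlapping clusters across repeat
#' classes is reported (a cluster touching several classes contributes to
#' each).
#'
#' @param clusters `GRanges` of clusters.
#' @param track repeat `GRanges` from [read_repeat_table()].
#' @return list with `overlaps` (logical per cluster), `fraction`
#'   (proportion of clusters overlapping any RE), `classes`
#'   (`CharacterList` of overlapping classes per cluster) and
#'   `class_counts` (named integer over [re_classes()]).
#' @export
cluster_re_overlap <- function(clusters, track) {
  n <- length(clusters)
  if (!length(track)) {
    return(list(overlaps = rep(FALSE, n), fraction = 0,
                classes = IRanges::CharacterList(rep(list(character(0)), n)),
                class_counts = setNames(integer(length(re_classes())),
                                        re_classes())))
  }
  hits <- findOverlaps(clusters, track, ignore.strand = TRUE)
  ov <- rep(FALSE, n)
  ov[unique(queryHits(hits))] <- TRUE
  cls <- rep(list(character(0)), n)
  if (length(hits)) {
    by_c <- split(as.character(track$re_class)[subjectHits(hits)],
                  queryHits(hits))
    cls[as.integer(names(by_c))] <- lapply(by_c, unique)
  }
  counts <- table(factor(unlist(cls), levels = re_classes()))
  list(overlaps = ov, fraction = if (n > 0) mean(ov) else NA_real_,
       classes = IRanges::CharacterList(cls),
       class_counts = setNames(as.integer(counts), re_classes()))
}
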