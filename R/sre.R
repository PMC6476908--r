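#' Call sperm RNA elements from pooled read coverage
#'
#' Reads from all samples are pooled and merged into maximal intervals in
#' which consecutive reads are separated by at most `max_gap` uncovered
#' bases; an interval is emitted as an SRE iff its peak per-base pooled
#' coverage reaches `min_support`. With `max_gap = 0` the emitted intervals
#' are exactly the contiguously covered islands of the pooled coverage
#' profile. Output is sorted by (chrom, start) and intervals are disjoint.
#'
#' @param read_sets list of `read_set` objects (or a single one).
#' @param min_support minimum peak pooled coverage (reads), default 3.
#' @param max_gap maximum uncovered gap bridged when merging, bp, default 0.
#' @return `GRanges` of SREs with metadata columns `sre_id` and
#'   `peak_coverage`.
#' @export
call_sres <- function(read_sets, min_support = 3L, max_gap = 0L) {
  if (inherits(read_sets, "read_set")) read_sets <- list(read_sets)
  stopifnot(min_support >= 1L, max_gap >= 0L)
  pooled <- do.call(c, c(lapply(read_sets, function(r) granges(r$reads)),
                         use.names = FALSE))
  if (length(pooled) == 0L)
    return(GRanges(sre_id = character(0), peak_coverage = integer(0)))
  strand(pooled) <- "*"
  merged <- reduce(pooled, min.gapwidth = max_gap + 1L, ignore.strand = TRUE)
  cov <- coverage(pooled)
  peak <- vapply(seq_along(merged), function(i) {
    v <- cov[[as.character(seqnames(merged[i]))]]
    max(S4Vectors::runValue(window(v, start(merged[i]),
                                   min(end(merged[i]), length(v)))))
  }, 0)
  keep <- peak >= min_support
  out <- merged[keep]
  out <- sort(GenomeInfoDb::sortSeqlevels(out))   # canonical (chrom, start)
  mcols(out)$sre_id <- sprintf("SRE%05d", seq_along(out))
  mcols(out)$peak_coverage <- as.integer(peak[keep])
  out
}

#' Quantify SREs per sample in RPKM
#'
#' A read counts toward an SRE if it overlaps it by at least 1 bp (and at
#' most once per SRE). RPKM for sample s is
#' `count * 1e9 / (sre_length_bp * total_mapped_s)`, with the sample's
#' declared `total_mapped` as the depth denominator. Mean and sample
#' (n-1) SD are computed across samples.
#'
#' @param sres `GRanges` of SREs from [call_sres()].
#' @param read_sets list of `read_set` objects.
#' @return list with `rpkm` and `counts` matrices (SRE x sample),
#'   `mean_abundance`, `abundance_sd`, and the SRE `GRanges`.
#' @export
quantify_sres <- function(sres, read_sets) {
  if (inherits(read_sets, "read_set")) read_sets <- list(read_sets)
  totals <- vapply(read_sets, function(r) r$total_mapped, 0)
  if (any(totals == 0))
    stop("undefined denominator: total_mapped is 0 for sample(s) ",
         paste(vapply(read_sets[totals == 0], function(r) r$sample_id, ""),
               collapse = ", "))
  ids <- vapply(read_sets, function(r) r$sample_id, "")
  counts <- vapply(read_sets, function(r)
    countOverlaps(sres, r$reads, ignore.strand = TRUE), numeric(length(sres)))
  counts <- matrix(counts, nrow = length(sres),
                   dimnames = list(sres$sre_id, ids))
  rpkm <- sweep(counts * 1e9 / width(sres), 2L, totals, "/")
  list(rpkm = rpkm, counts = counts,
       mean_abundance = rowMeans(rpkm),
       abundance_sd = apply(rpkm, 1L, sd),
       sres = sres)
}

#' Partition SREs into abundance deciles
#'
#' SREs are ranked by mean abundance in decreasing order (ties broken by
#' chromosome then start, so the labelling is deterministic); decile
#' `d = ceiling(10 * rank / n)`, decile 1 being the most abundant. The share
#' of total read mass carried by each decile is reported alongside.
#'
#' @param quant result of [quantify_sres()].
#' @return list with `decile` (named integer per SRE), `share` (per-decile
#'   percentage of total read counts) and `cumulative_share` (percent,
#'   reaching 100 at decile 10).
#' @export
partition_deciles <- function(quant) {
  n <- length(quant$mean_abundance)
  if (n < 10L) stop("decile undefined: fewer than 10 SREs")
  sres <- quant$sres
  ord <- order(-quant$mean_abundance, as.character(seqnames(sres)),
               start(sres))
  decile <- integer(n)
  decile[ord] <- as.integer(ceiling(10 * seq_len(n) / n))
  names(decile) <- names(quant$mean_abundance)
  mass <- rowSums(quant$counts)
  total <- sum(mass)
  share <- vapply(1:10, function(d) sum(mass[decile == d]), 0)
  share <- if (total > 0) 100 * share / total else rep(0, 10)
  list(decile = decile, share = setNames(share, 1:10),
       cumulative_share = setNames(cumsum(share), 1:10))
}

#' Classify SREs against a genome annotation
#'
#' Classes, in order of precedence: `EXON` if the SRE overlaps any annotated
#' exon by >= 1 bp; `NOVEL_INTRONIC` if it overlaps a gene body but no exon;
#' `UPDOWN10K` if it lies within `window` bp of a gene span; else `ORPHAN`.
#' All genes satisfying the winning rule are linked, so an SRE may carry
#' several gene ids (e.g. overlapping mitochondrial genes). Overlaps are
#' unstranded unless `stranded = TRUE`.
#'
#' @param sres `GRanges` of SREs.
#' @param annotation a `genome_annotation`.
#' @param window up/downstream window, bp (default 10,000).
#' @param stranded honour strand in overlap tests.
#' @return the input `GRanges` with added metadata columns `sre_class`
#'   (factor EXON/NOVEL_INTRONIC/UPDOWN10K/ORPHAN), `linked_genes`
#'   (`CharacterList`) and `distance_to_nearest_gene`.
#' @export
classify_sres <- function(sres, annotation, window = 10000L,
                          stranded = FALSE) {
  igs <- !stranded
  genes <- annotation$genes
  exons <- annotation$exons
  n <- length(sres)
  cls <- rep("ORPHAN", n)
  linked <- vector("list", n)

  hit_ex <- findOverlaps(sres, exons, ignore.strand = igs)
  has_ex <- unique(queryHits(hit_ex))
  cls[has_ex] <- "EXON"
  ex_genes <- split(exons$gene_id[subjectHits(hit_ex)], queryHits(hit_ex))
  linked[as.integer(names(ex_genes))] <- lapply(ex_genes, unique)

  hit_g <- findOverlaps(sres, genes, ignore.strand = igs)
  in_gene <- setdiff(unique(queryHits(hit_g)), has_ex)
  cls[in_gene] <- "NOVEL_INTRONIC"
  g_genes <- split(genes$gene_id[subjectHits(hit_g)], queryHits(hit_g))
  linked[in_gene] <- lapply(g_genes[as.character(in_gene)], unique)

  near <- findOverlaps(sres, genes, maxgap = window, ignore.strand = igs)
  cand <- setdiff(unique(queryHits(near)), c(has_ex, in_gene))
  cls[cand] <- "UPDOWN10K"
  n_genes <- split(genes$gene_id[subjectHits(near)], queryHits(near))
  linked[cand] <- lapply(n_genes[as.character(cand)], unique)

  dist <- rep(NA_real_, n)
  if (length(genes)) {
    dn <- distanceToNearest(sres, genes, ignore.strand = igs)
    dist[queryHits(dn)] <- mcols(dn)$distance
  } else {
    dist <- rep(Inf, n)
  }
  linked[vapply(linked, is.null, TRUE)] <- list(character(0))

  mcols(sres)$sre_class <- factor(cls, levels = c("EXON", "NOVEL_INTRONIC",
                                                  "UPDOWN10K", "ORPHAN"))
  mcols(sres)$linked_genes <- IRanges::CharacterList(linked)
  mcols(sres)$distance_to_nearest_gene <- dist
  sres
}

#' Nearest-gene proximity of orphan SREs
#'
#' For the orphan class (> `window` bp from any gene at classification
#' time), reports the unstranded distance to the nearest gene span and the
#' fraction lying within `threshold` bp of one (inclusive).
#'
#' @param sres classified `GRanges` from [classify_sres()].
#' @param annotation a `genome_annotation`.
#' @param threshold bp, default 30,000.
#' @return list with `distance` (named numeric per orphan; `Inf` when the
#'   annotation has no genes) and `fraction_within` (`NA` when there are no
#'   orphans).
#' @export
orphan_proximity <- function(sres, annotation, threshold = 30000L) {
  orp <- sres[sres$sre_class == "ORPHAN"]
  if (length(orp) == 0L)
    return(list(distance = setNames(numeric(0), character(0)),
                fraction_within = NA_real_))
  genes <- annotation$genes
  d <- rep(Inf, length(orp))
  if (length(genes)) {
    dn <- distanceToNearest(orp, genes, ignore.strand = TRUE)
    d[queryHits(dn)] <- mcols(dn)$distance
  }
  names(d) <- orp$sre_id
  frac <- if (all(is.infinite(d))) 0 else mean(d <= threshold)
  list(distance = d, fraction_within = frac)
}

#' Genes in or near the top-decile SREs
#'
#' The abundant gene set: the union of linked gene ids over top-decile SREs
#' of any class other than ORPHAN (orphans, by definition, link no gene).
#'
#' @param sres classified `GRanges` from [classify_sres()].
#' @param decile decile labels from [partition_deciles()] (aligned with
#'   `sres$sre_id`).
#' @return character vector of gene ids.
#' @export
abundant_gene_set <- function(sres, decile) {
  top <- sres[decile[sres$sre_id] == 1L & sres$sre_class != "ORPHAN"]
  sort(unique(unlist(top$linked_genes)))
}

#' Export an SRE table
#'
#' Writes one row per SRE with linked gene ids, coordinates, class, mean
#' abundance and abundance SD.
#'
#' @param sres classified `GRanges`.
#' @param quant result of [quantify_sres()].
#' @param path output TSV path (optional).
#' @return the table, invisibly written to `path` when given.
#' @export
sre_table <- function(sres, quant, path = NULL) {
  df <- data.frame(sre_id = sres$sre_id,
                   gene_id = vapply(as.list(sres$linked_genes),
                                    paste, "", collapse = ","),
                   chrom = as.character(seqnames(sres)),
                   start = start(sres), end = end(sres),
                   sre_class = as.character(sres$sre_class),
                   mean_abundance = quant$mean_abundance[sres$sre_id],
                   abundance_sd = quant$abundance_sd[sres$sre_id],
                   row.names = NULL)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
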