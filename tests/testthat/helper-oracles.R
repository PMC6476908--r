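# Independent brute-force oracles and tiny fixture builders. The oracles
# deliberately share no code with the package: everything is per-base /
# per-read enumeration on plain vectors.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# --- per-base coverage segmentation oracle ---------------------------------
# Returns a data.frame(chrom, start, end) of maximal intervals of covered
# bases in which consecutive covered runs are separated by <= max_gap
# uncovered bases and whose peak coverage reaches min_support.
oracle_segment <- function(gr, min_support, max_gap) {
  rows <- list()
  for (chr in sort(unique(as.character(seqnames(gr))))) {
    sub <- gr[as.character(seqnames(gr)) == chr]
    L <- max(end(sub))
    cov <- integer(L)
    for (i in seq_along(sub)) {
      idx <- start(sub)[i]:end(sub)[i]
      cov[idx] <- cov[idx] + 1L
    }
    pos <- which(cov > 0)
    if (!length(pos)) next
    brk <- which(diff(pos) > max_gap + 1L)
    starts <- pos[c(1L, brk + 1L)]
    ends <- pos[c(brk, length(pos))]
    for (k in seq_along(starts)) {
      if (max(cov[starts[k]:ends[k]]) >= min_support)
        rows[[length(rows) + 1L]] <- data.frame(chrom = chr,
                                                start = starts[k],
                                                end = ends[k])
    }
  }
  if (!length(rows)) return(data.frame(chrom = character(0),
                                       start = integer(0), end = integer(0)))
  do.call(rbind, rows)
}

granges_as_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr))
}

# --- piRNA cluster oracle ---------------------------------------------------
# Length-filter, segment by union with gap merging, then threshold on span
# and per-segment overlapping read count.
oracle_pirna <- function(gr, len_min, len_max, min_len, max_gap, min_reads) {
  keep <- width(gr) >= len_min & width(gr) <= len_max
  sub <- gr[keep]
  if (!length(sub)) return(data.frame(chrom = character(0),
                                      start = integer(0), end = integer(0)))
  segs <- oracle_segment(sub, min_support = 1L, max_gap = max_gap)
  if (!nrow(segs)) return(segs)
  cnt <- vapply(seq_len(nrow(segs)), function(i) {
    same <- as.character(seqnames(sub)) == segs$chrom[i]
    sum(same & start(sub) <= segs$end[i] & end(sub) >= segs$start[i])
  }, 0L)
  segs[(segs$end - segs$start + 1L) >= min_len & cnt >= min_reads, ,
       drop = FALSE]
}

# --- per-read interval overlap oracle --------------------------------------
oracle_read_overlap <- function(reads, track) {
  vapply(seq_along(reads), function(i) {
    same <- as.character(seqnames(track)) == as.character(seqnames(reads[i]))
    any(same & start(track) <= end(reads[i]) & end(track) >= start(reads[i]))
  }, logical(1))
}

# --- Benjamini-Hochberg step-up oracle -------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# --- exact hypergeometric upper tail by enumeration ------------------------
oracle_hyper_upper <- function(overlap, set_size, universe, query) {
  j <- overlap:min(set_size, query)
  sum(choose(set_size, j) * choose(universe - set_size, query - j)) /
    choose(universe, query)
}

# --- fixtures ---------------------------------------------------------------
# One-transcript-per-gene annotation from plain coordinate tables.
tiny_annotation <- function(genes, exons = NULL) {
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  g <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
               gene_id = genes$gene_id, biotype = genes$biotype)
  t <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
               transcript_id = paste0("tx_", genes$gene_id),
               gene_id = genes$gene_id)
  if (is.null(exons)) {
    exons <- data.frame(chrom = genes$chrom, start = genes$start,
                        end = genes$end, gene_id = genes$gene_id)
  }
  e <- GRanges(exons$chrom, IRanges(exons$start, exons$end),
               transcript_id = paste0("tx_", exons$gene_id),
               gene_id = exons$gene_id)
  spermkit:::new_genome_annotation(sort(g), sort(t), sort(e))
}

stack_reads <- function(chrom, start, end, n, sample_id = "s1",
                        total = NULL) {
  gr <- GRanges(rep(chrom, n), IRanges(rep(start, n), rep(end, n)))
  read_set(gr, sample_id, if (is.null(total)) n else total)
}

random_reads <- function(n, max_pos = 95000, chroms = c("c1", "c2"),
                         wmin = 20, wmax = 100) {
  GRanges(sample(chroms, n, replace = TRUE),
          IRanges(sample.int(max_pos, n, replace = TRUE),
                  width = sample(wmin:wmax, n, replace = TRUE)))
}

repeat_track <- function(chrom, start, end, cls) {
  GRanges(chrom, IRanges(start, end),
          re_class = factor(cls, levels = re_classes()),
          re_name = paste0(cls, "_", seq_along(chrom)))
}
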