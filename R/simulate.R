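#' Simulation configuration for the synthetic sperm transcriptome
#'
#' Bundles every knob of the synthetic-data generators. The defaults are
#' calibrated so that the simulated cohort reproduces the qualitative
#' structure of a real sperm RNA-seq study: a heavy-tailed per-gene
#' abundance distribution in which the top decile of called elements
#' carries about two thirds of the read mass (`abundance_sdlog = 1.9`,
#' calibrated at the pipeline level, where reads split over several
#' elements per gene and the support filter trims the low tail),
#' per-transcript
#' covered fractions `f ~ Beta(1, 3)` so that most transcripts are highly
#' fragmented (TIN below 25) and only a small minority are near intact, a
#' two-season (summer/winter) two-batch design with 5 samples per season,
#' and small-RNA reads with a 22 nt miRNA mode and 26-33 nt piRNA reads
#' concentrated in planted clusters.
#'
#' @param seed integer seed; the same seed yields byte-identical output from
#'   every generator. Each generator derives its own fixed substream offset.
#' @param n_chroms,chrom_length genome shape (bp).
#' @param n_genes,exons_per_gene,mean_exon_length,mean_intron_length gene
#'   model shape (bp).
#' @param lncrna_fraction fraction of genes flagged with the lncRNA biotype.
#' @param repeat_fraction named numeric: genome fraction covered per repeat
#'   class (names drawn from [re_classes()]).
#' @param abundance_meanlog,abundance_sdlog log-normal per-gene abundance
#'   (expected reads per transcript per sample) on the natural-log scale.
#' @param frag_shape1,frag_shape2 Beta parameters of the per-transcript
#'   covered fraction `f`.
#' @param read_length simulated read length, nt.
#' @param n_samples_per_group samples per season (two seasons).
#' @param n_orphan_clusters,orphan_read_count intergenic read clusters
#'   planted per genome and their per-sample read count.
#' @param n_features,base_meanlog,base_sdlog,dispersion,batch_effect,
#'   planted_log2fc count-matrix generator: number of features, log-normal
#'   base mean, per-feature NB dispersion (alpha), multiplicative batch
#'   effect on the NB mean, and a named numeric of planted season effects
#'   (feature id -> log2 fold change, summer relative to winter).
#' @param smallrna list of small-RNA parameters: `mirna_length` (22),
#'   `pirna_len_min`/`pirna_len_max` (26/33), `n_clusters`,
#'   `cluster_length`, `cluster_reads` (expected 26-33 nt reads per cluster
#'   per sample), `n_mirna_loci`, `mirna_reads`, `background_reads`, and
#'   optionally `cluster_coords` (a `GRanges` of planted cluster positions
#'   overriding random placement).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L, chrom_length = 2e6,
                       n_genes = 120L, exons_per_gene = 3L,
                       mean_exon_length = 500L, mean_intron_length = 800L,
                       lncrna_fraction = 0.1,
                       repeat_fraction = c(SINE = 0.08, LINE1 = 0.12,
                                           simple_repeat = 0.02),
                       abundance_meanlog = log(30), abundance_sdlog = 1.9,
                       frag_shape1 = 1, frag_shape2 = 3,
                       read_length = 75L,
                       n_samples_per_group = 5L,
                       n_orphan_clusters = 2L, orphan_read_count = 40L,
                       n_features = 2000L,
                       base_meanlog = log(100), base_sdlog = 1,
                       dispersion = 0.2, batch_effect = 1.3,
                       planted_log2fc = numeric(0),
                       smallrna = list()) {
  sr <- utils::modifyList(list(
    mirna_length = 22L, pirna_len_min = 26L, pirna_len_max = 33L,
    n_clusters = 2L, cluster_length = 8000L, cluster_reads = 600L,
    n_mirna_loci = 20L, mirna_reads = 50L, background_reads = 300L,
    cluster_coords = NULL), smallrna)
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              mean_exon_length = as.integer(mean_exon_length),
              mean_intron_length = as.integer(mean_intron_length),
              lncrna_fraction = lncrna_fraction,
              repeat_fraction = repeat_fraction,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              frag_shape1 = frag_shape1, frag_shape2 = frag_shape2,
              read_length = as.integer(read_length),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_orphan_clusters = as.integer(n_orphan_clusters),
              orphan_read_count = as.integer(orphan_read_count),
              n_features = as.integer(n_features),
              base_meanlog = base_meanlog, base_sdlog = base_sdlog,
              dispersion = dispersion, batch_effect = batch_effect,
              planted_log2fc = planted_log2fc, smallrna = sr)
  if (any(cfg$dispersion <= 0)) stop("dispersion must be > 0")
  if (cfg$frag_shape1 <= 0 || cfg$frag_shape2 <= 0)
    stop("fragmentation Beta shapes must be > 0")
  if (cfg$lncrna_fraction < 0 || cfg$lncrna_fraction > 1)
    stop("lncrna_fraction must be in [0, 1]")
  if (any(cfg$repeat_fraction < 0)) stop("repeat fractions must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Two-season, two-batch sample design for a configuration
#'
#' Seasons are blocks of `n_samples_per_group`; batches alternate within the
#' cohort so that batch is never confounded with season.
#'
#' @param config a [sim_config()].
#' @return data.frame with `sample_id`, `season`, `batch`.
#' @export
sim_design <- function(config) {
  g <- config$n_samples_per_group
  if (g < 2L) stop("design error: fewer than 2 samples per season")
  n <- 2L * g
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             season = rep(c("summer", "winter"), each = g),
             batch = rep_len(c("b1", "b2"), n),
             stringsAsFactors = FALSE)
}

.sim_chroms <- function(config) {
  setNames(rep(config$chrom_length, config$n_chroms),
           paste0("chr", seq_len(config$n_chroms)))
}

#' Generate a synthetic genome annotation and repeat track
#'
#' Places non-overlapping multi-exon genes with randomized intergenic gaps,
#' flags a configurable fraction of genes with the lncRNA biotype, and
#' scatters repeat intervals to a configurable genome fraction per class.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (a `genome_annotation`) and `repeats`
#'   (a `GRanges` repeat track as from [read_repeat_table()]).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  chroms <- .sim_chroms(config)
  footprint <- config$exons_per_gene * config$mean_exon_length +
    (config$exons_per_gene - 1L) * config$mean_intron_length
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  if (per_chrom * (footprint * 1.5 + 22000) > config$chrom_length)
    stop("sizing error: genome too small for the requested gene number")

  gene_rows <- list(); tx_rows <- list(); exon_rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    pos <- 1L
    n_here <- min(per_chrom, config$n_genes - gi)
    for (k in seq_len(n_here)) {
      gi <- gi + 1L
      gap <- round(runif(1, 22000, 45000))
      exw <- pmax(50L, round(runif(config$exons_per_gene, 0.6, 1.4) *
                               config$mean_exon_length))
      inw <- if (config$exons_per_gene > 1L)
        pmax(50L, round(runif(config$exons_per_gene - 1L, 0.6, 1.4) *
                          config$mean_intron_length)) else integer(0)
      gstart <- pos + gap
      estarts <- gstart + cumsum(c(0L, head(exw, -1) + inw))
      eends <- estarts + exw - 1L
      gend <- eends[length(eends)]
      if (gend > chroms[ci])
        stop("sizing error: genome too small for the requested gene number")
      gid <- sprintf("G%04d", gi); tid <- sprintf("T%04d", gi)
      gene_rows[[gi]] <- data.frame(chrom = names(chroms)[ci],
                                    start = gstart, end = gend, gene_id = gid)
      tx_rows[[gi]] <- data.frame(chrom = names(chroms)[ci],
                                  start = gstart, end = gend,
                                  transcript_id = tid, gene_id = gid)
      exon_rows[[gi]] <- data.frame(chrom = names(chroms)[ci],
                                    start = estarts, end = eends,
                                    transcript_id = tid, gene_id = gid)
      pos <- gend
    }
  }
  gdf <- do.call(rbind, gene_rows)
  n_lnc <- round(config$lncrna_fraction * config$n_genes)
  biotype <- rep("protein_coding", config$n_genes)
  biotype[sample.int(config$n_genes, n_lnc)] <- "lncRNA"
  genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                   gene_id = gdf$gene_id, biotype = biotype,
                   seqlengths = chroms)
  tdf <- do.call(rbind, tx_rows)
  txs <- GRanges(tdf$chrom, IRanges(tdf$start, tdf$end),
                 transcript_id = tdf$transcript_id, gene_id = tdf$gene_id,
                 seqlengths = chroms)
  edf <- do.call(rbind, exon_rows)
  exons <- GRanges(edf$chrom, IRanges(edf$start, edf$end),
                   transcript_id = edf$transcript_id, gene_id = edf$gene_id,
                   seqlengths = chroms)

  rep_rows <- list()
  for (cl in names(config$repeat_fraction)) {
    target <- config$repeat_fraction[[cl]] * sum(chroms)
    got <- 0
    while (got < target) {
      w <- sample(150:1200, 1L)
      ci <- sample.int(length(chroms), 1L)
      s <- sample.int(chroms[ci] - w, 1L)
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(chrom = names(chroms)[ci], start = s, end = s + w - 1L,
                   cls = cl)
      got <- got + w
    }
  }
  if (length(rep_rows)) {
    rdf <- do.call(rbind, rep_rows)
    repeats <- GRanges(rdf$chrom, IRanges(rdf$start, rdf$end),
                       re_class = factor(rdf$cls, levels = re_classes()),
                       re_name = paste0(rdf$cls, "_", seq_len(nrow(rdf))),
                       seqlengths = chroms)
  } else {
    repeats <- GRanges(re_class = factor(character(0), levels = re_classes()),
                       re_name = character(0), seqlengths = chroms)
  }
  list(annotation = new_genome_annotation(sort(genes), sort(txs), sort(exons)),
       repeats = sort(repeats))
}

# Map 0-based half-open blocks on the concatenated exonic coordinate of one
# transcript back to genomic intervals (possibly split at exon junctions).
.exonic_to_genomic <- function(blocks, exon_start, exon_width) {
  off <- cumsum(c(0L, exon_width))
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(exon_width)) {
    a <- pmax(blocks[, 1L], off[i]); b <- pmin(blocks[, 2L], off[i + 1L])
    keep <- b > a
    if (any(keep)) {
      gs <- exon_start[i] + (a[keep] - off[i])
      out_s <- c(out_s, gs); out_e <- c(out_e, gs + (b[keep] - a[keep]) - 1L)
    }
  }
  cbind(start = out_s, end = out_e)
}

#' Simulate fragmented per-sample read sets over an annotation
#'
#' For each transcript a covered window equal to fraction `f` of its exonic
#' span is chosen (`f ~ Beta(frag_shape1, frag_shape2)`, shared across
#' samples; the window position is re-drawn per sample). Reads are placed
#' uniformly over the window with wrap-around at the window edge, so
#' coverage within the window is flat by construction and the transcript
#' integrity score has the closed form `100 * f`. Per-transcript read counts
#' are Poisson with the gene's abundance as mean. Orphan read clusters are
#' planted in intergenic space more than 10 kb from any gene.
#'
#' @param annotation a `genome_annotation` (typically from
#'   [generate_annotation()]).
#' @param config a [sim_config()].
#' @param abundance optional named numeric overriding the drawn per-gene
#'   abundance (expected reads per transcript per sample).
#' @return list with `read_sets` (named list of `read_set`, one per sample)
#'   and `truth` (per-gene abundance, per-transcript covered fraction,
#'   orphan cluster coordinates, design).
#' @export
simulate_reads <- function(annotation, config, abundance = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 201L)
  design <- sim_design(config)
  genes <- annotation$genes; txs <- annotation$transcripts
  rl <- config$read_length
  if (is.null(abundance)) {
    abundance <- setNames(rlnorm(length(genes), config$abundance_meanlog,
                                 config$abundance_sdlog), genes$gene_id)
  } else {
    miss <- setdiff(genes$gene_id, names(abundance))
    if (length(miss)) abundance[miss] <- 0
    abundance <- abundance[genes$gene_id]
  }

  ex_by_tx <- split(annotation$exons, annotation$exons$transcript_id)
  tx_ids <- txs$transcript_id
  exonic_len <- setNames(vapply(ex_by_tx, function(e) sum(width(e)), 0)[tx_ids],
                         tx_ids)
  f_draw <- rbeta(length(tx_ids), config$frag_shape1, config$frag_shape2)
  W <- pmax(1L, round(f_draw * exonic_len))
  covered_fraction <- setNames(W / exonic_len, tx_ids)

  # intergenic anchors for orphan clusters: > 10 kb from any gene span
  orphans <- GRanges(seqlengths = .sim_chroms(config))
  if (config$n_orphan_clusters > 0L) {
    gaps <- gaps(reduce(genes, ignore.strand = TRUE))
    gaps <- gaps[strand(gaps) == "*" & width(gaps) > 24000 + 300]
    gaps <- head(gaps, config$n_orphan_clusters)
    if (length(gaps)) {
      os <- start(gaps) + 12000L
      orphans <- GRanges(seqnames(gaps), IRanges(os, os + 299L),
                         seqlengths = seqlengths(genes))
    }
  }

  chroms <- .sim_chroms(config)
  read_sets <- list()
  for (s in seq_len(nrow(design))) {
    rs_list <- vector("list", length(tx_ids) + 1L)
    for (t in seq_along(tx_ids)) {
      mu <- abundance[[txs$gene_id[t]]]
      n <- if (mu > 0) rpois(1L, mu) else 0L
      if (n == 0L) next
      ex <- ex_by_tx[[tx_ids[t]]]
      L <- exonic_len[[t]]; Wt <- W[t]
      w0 <- if (L > Wt) sample.int(L - Wt + 1L, 1L) - 1L else 0L
      rl_eff <- min(rl, Wt)
      starts <- sample.int(Wt, n, replace = TRUE) - 1L
      ov <- pmax(0L, starts + rl_eff - Wt)              # wrapped tail length
      b1 <- cbind(w0 + starts, w0 + starts + (rl_eff - ov))
      blocks <- rbind(b1, cbind(rep(w0, sum(ov > 0)), w0 + ov[ov > 0]))
      gb <- .exonic_to_genomic(blocks, start(ex), width(ex))
      rs_list[[t]] <- GRanges(as.character(seqnames(ex))[1],
                              IRanges(gb[, "start"], gb[, "end"]),
                              seqlengths = chroms)
    }
    if (length(orphans)) {
      og <- lapply(seq_along(orphans), function(i) {
        o <- orphans[i]
        st <- start(o) + sample.int(width(o) - rl, config$orphan_read_count,
                                    replace = TRUE) - 1L
        GRanges(seqnames(o), IRanges(st, st + rl - 1L),
                seqlengths = chroms)
      })
      rs_list[[length(tx_ids) + 1L]] <- do.call(c, og)
    }
    rs_list <- rs_list[!vapply(rs_list, is.null, TRUE)]
    gr <- if (length(rs_list)) sort(do.call(c, rs_list))
          else GRanges(seqlengths = chroms)
    read_sets[[design$sample_id[s]]] <- read_set(gr, design$sample_id[s])
  }
  list(read_sets = read_sets,
       truth = list(abundance = abundance,
                    covered_fraction = covered_fraction,
                    exonic_length = exonic_len,
                    orphan_clusters = orphans, design = design))
}

#' Simulate a seasonal negative-binomial count matrix
#'
#' Counts are NB with a log-normal base mean per feature, a multiplicative
#' batch effect, and planted summer-vs-winter log2 fold changes on selected
#' features; the truth (labels and effects) is returned alongside.
#'
#' @param config a [sim_config()]; `planted_log2fc` is a named numeric of
#'   feature id (`"feat_0001"` style) or index -> log2 fold change.
#' @return list with `counts` (features x samples integer matrix), `design`
#'   and `truth` (per-feature `log2fc` and logical `is_de`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- sim_design(config)
  set.seed(config$seed + 301L)
  m <- config$n_features
  feat <- sprintf("feat_%04d", seq_len(m))
  lfc <- setNames(rep(0, m), feat)
  pl <- config$planted_log2fc
  if (length(pl)) {
    idx <- if (is.null(names(pl))) as.integer(seq_along(pl)) else match(names(pl), feat)
    if (anyNA(idx) || any(idx < 1L | idx > m))
      stop("planted effect references a feature outside the matrix")
    lfc[idx] <- as.numeric(pl)
  }
  base_mu <- rlnorm(m, config$base_meanlog, config$base_sdlog)
  summer <- design$season == "summer"
  b2 <- design$batch == "b2"
  mu <- outer(base_mu, rep(1, nrow(design))) *
    2^(lfc %o% as.numeric(summer)) *
    config$batch_effect^(rep(1, m) %o% as.numeric(b2))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   nrow = m, dimnames = list(feat, design$sample_id))
  list(counts = counts, design = design,
       truth = list(log2fc = lfc, is_de = lfc != 0))
}

#' Simulate length-annotated small-RNA read sets
#'
#' Plants dense 26-33 nt read clusters and 22 nt miRNA loci on the genome of
#' `annotation`, with sparse background reads of mixed length elsewhere.
#'
#' @param annotation a `genome_annotation` carrying chromosome lengths.
#' @param config a [sim_config()] (see its `smallrna` parameter).
#' @return list with `read_sets` (named list of `read_set`; read length =
#'   interval width) and `truth` (`clusters` and `mirna_loci` as `GRanges`).
#' @export
simulate_small_rna <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  sr <- config$smallrna
  chroms <- .sim_chroms(config)
  set.seed(config$seed + 401L)
  design <- sim_design(config)

  if (!is.null(sr$cluster_coords)) {
    clusters <- sr$cluster_coords
    lens <- chroms[as.character(seqnames(clusters))]
    if (anyNA(lens) || any(end(clusters) > lens) || any(start(clusters) < 1L))
      stop("sizing error: planted cluster outside the genome")
  } else if (sr$n_clusters > 0L) {
    if (sr$cluster_length > min(chroms))
      stop("sizing error: planted cluster outside the genome")
    ci <- sample.int(length(chroms), sr$n_clusters, replace = TRUE)
    st <- vapply(ci, function(i)
      sample.int(chroms[i] - sr$cluster_length, 1L), 0L)
    clusters <- GRanges(names(chroms)[ci],
                        IRanges(st, width = sr$cluster_length),
                        seqlengths = chroms)
  } else {
    clusters <- GRanges(seqlengths = chroms)
  }
  mi <- sample.int(length(chroms), sr$n_mirna_loci, replace = TRUE)
  ms <- vapply(mi, function(i) sample.int(chroms[i] - sr$mirna_length, 1L), 0L)
  mirna_loci <- GRanges(names(chroms)[mi], IRanges(ms, width = sr$mirna_length),
                        seqlengths = chroms)

  read_sets <- list()
  for (s in seq_len(nrow(design))) {
    parts <- list()
    for (k in seq_along(clusters)) {
      n <- rpois(1L, sr$cluster_reads)
      if (n == 0L) next
      len <- sample(sr$pirna_len_min:sr$pirna_len_max, n, replace = TRUE)
      st <- start(clusters[k]) +
        sample.int(width(clusters[k]) - sr$pirna_len_max, n, replace = TRUE) - 1L
      parts[[length(parts) + 1L]] <-
        GRanges(seqnames(clusters[k]), IRanges(st, width = len),
                seqlengths = chroms)
    }
    for (k in seq_along(mirna_loci)) {
      n <- rpois(1L, sr$mirna_reads)
      if (n == 0L) next
      parts[[length(parts) + 1L]] <-
        GRanges(seqnames(mirna_loci[k]),
                IRanges(rep(start(mirna_loci[k]), n),
                        width = sr$mirna_length),
                seqlengths = chroms)
    }
    if (sr$background_reads > 0L) {
      len <- sample(18:40, sr$background_reads, replace = TRUE)
      ci <- sample.int(length(chroms), sr$background_reads, replace = TRUE)
      st <- vapply(ci, function(i) sample.int(chroms[i] - 40L, 1L), 0L)
      parts[[length(parts) + 1L]] <-
        GRanges(names(chroms)[ci], IRanges(st, width = len),
                seqlengths = chroms)
    }
    gr <- if (length(parts)) sort(do.call(c, parts))
          else GRanges(seqlengths = chroms)
    read_sets[[design$sample_id[s]]] <- read_set(gr, design$sample_id[s])
  }
  list(read_sets = read_sets,
       truth = list(clusters = clusters, mirna_loci = mirna_loci,
                    design = design))
}
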