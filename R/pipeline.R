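#' End-to-end synthetic cohort analysis
#'
#' Runs the whole pipeline from one configuration with a fixed seed:
#' synthetic annotation and repeat track, fragmented read simulation, SRE
#' calling/quantification/classification, decile partition, per-transcript
#' TIN, repeat composition, small-RNA simulation with per-sample piRNA
#' cluster calling and cross-sample consensus, seasonal count simulation
#' and NB differential testing. The same seed yields identical results.
#'
#' @param config a [sim_config()].
#' @param min_support,max_gap SRE caller parameters (see [call_sres()]).
#' @return list with components `annotation`, `repeats`, `truth`
#'   (read/small-RNA/count ground truths), `sres` (classified `GRanges`),
#'   `quant`, `deciles`, `orphan`, `abundant_genes`, `tin`, `re_summary`
#'   (per sample), `pirna` (per-sample and consensus clusters), `de`.
#' @export
run_sperm_pipeline <- function(config, min_support = 3L, max_gap = 0L) {
  gen <- generate_annotation(config)
  sim <- simulate_reads(gen$annotation, config)
  sres <- call_sres(sim$read_sets, min_support = min_support,
                    max_gap = max_gap)
  quant <- quantify_sres(sres, sim$read_sets)
  deciles <- partition_deciles(quant)
  sres <- classify_sres(sres, gen$annotation)
  orphan <- orphan_proximity(sres, gen$annotation)
  abundant <- abundant_gene_set(sres, deciles$decile)
  tin <- transcript_tin(sim$read_sets, gen$annotation)
  re_summary <- lapply(sim$read_sets, re_read_fraction, track = gen$repeats)

  smal <- simulate_small_rna(gen$annotation, config)
  per_sample <- lapply(smal$read_sets, call_pirna_clusters)
  consensus <- reproducible_clusters(per_sample, min_samples = 3L)
  re_ov <- cluster_re_overlap(consensus, gen$repeats)

  cts <- simulate_counts(config)
  de <- run_seasonal_de(cts$counts, cts$design)

  list(annotation = gen$annotation, repeats = gen$repeats,
       truth = list(reads = sim$truth, smallrna = smal$truth,
                    counts = cts$truth),
       sres = sres, quant = quant, deciles = deciles, orphan = orphan,
       abundant_genes = abundant, tin = tin, re_summary = re_summary,
       pirna = list(per_sample = per_sample, consensus = consensus,
                    re_overlap = re_ov),
       de = de)
}
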