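#' Coefficient-of-variation stability classes
#'
#' CV = sample (n-1) standard deviation / mean across samples, computed on
#' normalized abundances. Classes: `stable` (CV < 0.25), `moderate`
#' (0.25 <= CV <= 0.75, reading the boundaries inclusively) and `unstable`
#' (CV > 0.75). Features with mean 0 have no defined CV; they are flagged
#' `NA` and excluded from classification.
#'
#' @param mat features x samples numeric matrix (>= 2 columns).
#' @return data.frame with `feature_id`, `mean`, `sd`, `cv`,
#'   `stability_class` (factor stable/moderate/unstable, `NA` when
#'   undefined).
#' @export
compute_cv <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  data.frame(feature_id = rownames(mat), mean = mu, sd = s, cv = cv,
             stability_class = stability_class(cv), row.names = NULL)
}

#' Stability class of a CV value
#'
#' Boundary values 0.25 and 0.75 belong to `moderate` ("between 0.25 and
#' 0.75" read inclusively); `NA` stays `NA`.
#'
#' @param cv numeric CV value(s), >= 0.
#' @return factor with levels stable/moderate/unstable.
#' @export
stability_class <- function(cv) {
  cls <- rep(NA_character_, length(cv))
  cls[!is.na(cv) & cv < 0.25] <- "stable"
  cls[!is.na(cv) & cv >= 0.25 & cv <= 0.75] <- "moderate"
  cls[!is.na(cv) & cv > 0.75] <- "unstable"
  factor(cls, levels = c("stable", "moderate", "unstable"))
}

#' Gene-level stability assignment
#'
#' A gene receives a stability class iff every one of its SREs falls in that
#' same class; genes whose SREs disagree (or include an unclassifiable SRE)
#' are `unassigned`. Genes with no SREs are absent from the output.
#'
#' @param stability data.frame from [compute_cv()] over SREs.
#' @param links data.frame with `sre_id` and `gene_id` (one row per
#'   SRE-gene link, e.g. unnested from `classify_sres()` output).
#' @return data.frame with `gene_id` and `stability_class` (character, one
#'   of stable/moderate/unstable/unassigned).
#' @export
gene_stability <- function(stability, links) {
  cls <- as.character(stability$stability_class)
  names(cls) <- stability$feature_id
  by_gene <- split(cls[links$sre_id], links$gene_id)
  assigned <- vapply(by_gene, function(v) {
    if (anyNA(v) || length(unique(v)) != 1L) "unassigned" else v[[1]]
  }, "")
  data.frame(gene_id = names(assigned), stability_class = unname(assigned),
             row.names = NULL)
}

#' Tissue-enrichment partition of features
#'
#' A feature is assigned to fraction X iff its abundance in X exceeds `high`
#' FPKM and its abundance in both other fractions is below `low` FPKM; the
#' same rule applies symmetrically to testes, sperm and seminal fluid.
#' Anything else is `unassigned`, so each feature gets exactly one label.
#'
#' @param fpkm_testes,fpkm_sperm,fpkm_seminal_fluid FPKM per feature
#'   (equal-length non-negative vectors, optionally named).
#' @param high,low thresholds in FPKM (defaults 40 and 10).
#' @return data.frame with `feature_id`, the three FPKM columns and
#'   `fraction` (factor testes_enriched/sperm_enriched/
#'   seminal_fluid_enriched/unassigned).
#' @export
partition_enrichment <- function(fpkm_testes, fpkm_sperm, fpkm_seminal_fluid,
                                 high = 40, low = 10) {
  if (any(c(fpkm_testes, fpkm_sperm, fpkm_seminal_fluid) < 0))
    stop("input error: negative FPKM")
  n <- length(fpkm_testes)
  stopifnot(length(fpkm_sperm) == n, length(fpkm_seminal_fluid) == n)
  fraction <- rep("unassigned", n)
  fraction[fpkm_testes > high & fpkm_sperm < low & fpkm_seminal_fluid < low] <-
    "testes_enriched"
  fraction[fpkm_sperm > high & fpkm_testes < low & fpkm_seminal_fluid < low] <-
    "sperm_enriched"
  fraction[fpkm_seminal_fluid > high & fpkm_testes < low & fpkm_sperm < low] <-
    "seminal_fluid_enriched"
  ids <- names(fpkm_testes)
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_len(n))
  data.frame(feature_id = ids, fpkm_testes = fpkm_testes,
             fpkm_sperm = fpkm_sperm, fpkm_seminal_fluid = fpkm_seminal_fluid,
             fraction = factor(fraction,
                               levels = c("testes_enriched", "sperm_enriched",
                                          "seminal_fluid_enriched",
                                          "unassigned")),
             row.names = NULL)
}

#' Compare abundance variability between enrichment fractions
#'
#' One-way ANOVA of CV on fraction followed by all-pairs Tukey HSD
#' (studentized-range) comparisons. Groups with fewer than 2 members are
#' excluded with a warning.
#'
#' @param cv numeric CV per feature.
#' @param group factor/character group label per feature.
#' @return list with `anova_p`, `group_means`, and `tukey` (data.frame
#'   `comparison`, `diff`, `p_adj`).
#' @export
compare_fraction_variability <- function(cv, group) {
  keep <- !is.na(cv) & !is.na(group)
  cv <- cv[keep]; group <- factor(as.character(group[keep]))
  sizes <- table(group)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    cv <- cv[keep]; group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2L) stop("need >= 2 groups with >= 2 members")
  fit <- aov(cv ~ group)
  tuk <- TukeyHSD(fit)$group
  list(anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
       group_means = tapply(cv, group, mean),
       tukey = data.frame(comparison = rownames(tuk),
                          diff = tuk[, "diff"], p_adj = tuk[, "p adj"],
                          row.names = NULL))
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and each set of a collection within a stated universe, with Bonferroni
#' correction over the number of sets tested. Sets are intersected with the
#' universe before testing.
#'
#' @param query character vector of gene ids (must be a subset of
#'   `universe`).
#' @param collection named list of character vectors (e.g. from
#'   [read_gene_sets()]).
#' @param universe character vector of all testable gene ids.
#' @return data.frame with `set_id`, `overlap`, `set_size`, `universe_size`,
#'   `query_size`, `p`, `p_bonferroni`.
#' @export
overrepresentation_test <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  m <- length(collection)
  res <- lapply(names(collection), function(id) {
    set <- intersect(unique(collection[[id]]), universe)
    ov <- length(intersect(set, query))
    p <- phyper(ov - 1L, length(set), length(universe) - length(set),
                length(query), lower.tail = FALSE)
    data.frame(set_id = id, overlap = ov, set_size = length(set),
               universe_size = length(universe), query_size = length(query),
               p = p)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * m)
  out
}

#' Filter de novo assembled contigs
#'
#' Retains contigs with identity strictly above `min_identity` percent,
#' abundance strictly above `min_fpkm` FPKM, and detection in at least
#' `min_samples` samples.
#'
#' @param contigs data.frame with columns `identity` (percent), `fpkm`, and
#'   `n_samples_detected`.
#' @param min_identity,min_fpkm,min_samples thresholds (defaults 85, 50, 5).
#' @return the retained rows of `contigs`.
#' @export
filter_denovo_contigs <- function(contigs, min_identity = 85, min_fpkm = 50,
                                  min_samples = 5L) {
  need <- c("identity", "fpkm", "n_samples_detected")
  miss <- setdiff(need, names(contigs))
  if (length(miss))
    stop("input error: missing column(s) ", paste(miss, collapse = ", "))
  contigs[contigs$identity > min_identity & contigs$fpkm > min_fpkm &
            contigs$n_samples_detected >= min_samples, , drop = FALSE]
}
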