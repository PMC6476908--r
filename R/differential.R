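#' Median-of-ratios size factors
#'
#' The pseudo-reference is the per-feature geometric mean across samples
#' (features with any zero count are excluded from it); each sample's
#' factor is the median over features of its count-to-reference ratio, and
#' factors are rescaled to geometric mean 1. When no feature is nonzero in
#' every sample the function falls back, with a warning, to total-count
#' scaling.
#'
#' @param counts features x samples raw count matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  if (ncol(counts) == 1L) return(setNames(1, colnames(counts)))
  if (any(colSums(counts) == 0)) stop("a sample has no nonzero count")
  logref <- rowMeans(log(counts))
  ok <- is.finite(logref)
  if (!any(ok)) {
    warning("no feature nonzero in all samples; using total-count scaling")
    sf <- colSums(counts)
  } else {
    logratio <- sweep(log(counts[ok, , drop = FALSE]), 1L, logref[ok])
    sf <- exp(apply(logratio, 2L, median))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Moment-based per-feature NB dispersion with trend shrinkage
#'
#' On size-factor normalized counts, the raw method-of-moments estimate per
#' feature is `alpha = max(alpha_min, (s^2 - mu) / (mu^2 - s^2 / n))`, the
#' small-sample bias-corrected form of `(s^2 - mu) / mu^2` (the corrected
#' denominator keeps the estimator close to unbiased at n = 5 per group;
#' it is floored at a tenth of `mu^2` so a wild variance cannot flip its
#' sign). When a group label is supplied (the season of the design), the
#' moments are taken within groups and pooled with weights `n_g - 1`, so a
#' genuine between-group effect does not inflate the dispersion of the
#' features carrying it. Raw estimates are then shrunk 50% toward the
#' median raw estimate of the feature's abundance decile, stabilizing the
#' tail behaviour at small sample sizes. All-zero features get `NA`
#' (excluded from testing).
#'
#' @param counts features x samples raw count matrix (>= 3 samples).
#' @param sf size factors from [size_factors()].
#' @param alpha_min dispersion floor (default 1e-4).
#' @param group optional per-sample group label (e.g. season) for pooled
#'   within-group moments.
#' @return named numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, sf, alpha_min = 1e-4, group = NULL) {
  stopifnot(ncol(counts) >= 3L)
  norm <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(norm)
  mom <- function(m, v, n)
    ifelse(m > 0, (v - m) / pmax(m^2 - v / n, 0.1 * m^2), 0)
  if (is.null(group)) {
    raw_of <- mom(mu, apply(norm, 1L, var), ncol(norm))
  } else {
    group <- as.character(group)
    raw_num <- raw_den <- numeric(nrow(counts))
    for (g in unique(group)) {
      sub <- norm[, group == g, drop = FALSE]
      if (ncol(sub) < 2L) next
      a_g <- mom(rowMeans(sub), apply(sub, 1L, var), ncol(sub))
      w <- ncol(sub) - 1L
      raw_num <- raw_num + w * a_g
      raw_den <- raw_den + w
    }
    raw_of <- raw_num / raw_den
  }
  raw <- ifelse(mu > 0, pmax(alpha_min, raw_of), NA_real_)
  ok <- !is.na(raw)
  alpha <- raw
  if (sum(ok) >= 10L) {
    dec <- as.integer(cut(rank(mu[ok], ties.method = "first"),
                          breaks = 10L, labels = FALSE))
    trend <- tapply(raw[ok], dec, median)
    alpha[ok] <- pmax(alpha_min, 0.5 * raw[ok] + 0.5 * trend[dec])
  }
  setNames(alpha, rownames(counts))
}

# One NB GLM fit at fixed dispersion; returns season coefficient (natural
# log), its SE, and a convergence flag.
.nb_fit_one <- function(y, X, off, theta) {
  fam <- MASS::negative.binomial(theta = theta)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = fam, offset = off,
                             control = list(maxit = 50L, epsilon = 1e-6))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$rank < ncol(X))
    return(c(beta = NA_real_, se = NA_real_, converged = 0))
  p <- fit$rank
  Rmat <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  covun <- chol2inv(Rmat)
  se <- numeric(ncol(X))
  se[fit$qr$pivot[seq_len(p)]] <- sqrt(diag(covun))
  j <- ncol(X)                      # season indicator is the last column
  c(beta = unname(fit$coefficients[j]), se = se[j], converged = 1)
}

#' Negative-binomial Wald test for a two-season design
#'
#' Per feature, a log-linear model of the NB mean with intercept, batch
#' indicator(s) and a season indicator is fitted by iteratively reweighted
#' least squares at the feature's fixed dispersion, with log size factors
#' as offset. The season coefficient is reported as log2 fold change
#' (summer relative to winter) and its Wald p-value is taken against the
#' standard normal. Features that fail to converge are flagged and given
#' p = 1; features with undefined dispersion are excluded (NA row).
#'
#' @param counts features x samples raw count matrix.
#' @param sf size factors from [size_factors()].
#' @param dispersions per-feature dispersions from [estimate_dispersion()].
#' @param design data.frame with `sample_id`, `season`
#'   (`"summer"`/`"winter"`) and `batch`, rows aligned with `colnames`.
#' @return data.frame with `feature_id`, `log2fc`, `p`, `converged`.
#' @export
nb_wald_test <- function(counts, sf, dispersions, design) {
  stopifnot(nrow(design) == ncol(counts))
  season <- factor(design$season, levels = c("winter", "summer"))
  if (any(table(season) < 2L))
    stop("design error: fewer than 2 samples in a season")
  batch <- factor(design$batch)
  if (nlevels(batch) > 1L) {
    tab <- table(batch, season)
    if (all(rowSums(tab > 0) < 2L))
      stop("design error: batch perfectly confounded with season")
    X <- model.matrix(~ batch + season)
  } else {
    X <- model.matrix(~ season)
  }
  off <- log(sf)
  m <- nrow(counts)
  log2fc <- p <- rep(NA_real_, m)
  converged <- rep(FALSE, m)
  for (i in seq_len(m)) {
    a <- dispersions[i]
    if (is.na(a)) next
    r <- .nb_fit_one(counts[i, ], X, off, theta = 1 / a)
    if (r[["converged"]] == 1) {
      converged[i] <- TRUE
      log2fc[i] <- r[["beta"]] / log(2)
      z <- r[["beta"]] / r[["se"]]
      p[i] <- 2 * pnorm(-abs(z))
    } else {
      log2fc[i] <- 0
      p[i] <- 1
    }
  }
  data.frame(feature_id = rownames(counts), log2fc = log2fc, p = p,
             converged = converged, row.names = NULL)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (`q_(i) = min_{j >= i} m p_(j) / j`, capped at 1,
#' mapped back to input order), computed with `stats::p.adjust`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  pp <- p[!is.na(p)]
  if (any(pp < 0 | pp > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Significance filter on differential results
#'
#' Keeps features with `q < fdr` and absolute fold change `2^|log2fc| > fc`
#' (both strict), split by direction of the summer-vs-winter effect.
#'
#' @param results data.frame with `feature_id`, `log2fc`, `p`, `q`.
#' @param fdr q-value bound (default 0.05).
#' @param fc fold-change bound on the absolute fold change (default 1.5).
#' @return the input with a logical `significant` column and a `direction`
#'   column (`"up_summer"`/`"down_summer"`/`NA`).
#' @export
filter_de <- function(results, fdr = 0.05, fc = 1.5) {
  sig <- !is.na(results$q) & results$q < fdr &
    2^abs(results$log2fc) > fc
  results$significant <- sig
  results$direction <- ifelse(!sig, NA_character_,
                              ifelse(results$log2fc > 0, "up_summer",
                                     "down_summer"))
  results
}

#' Seasonal differential-abundance pipeline
#'
#' Size factors, dispersion estimation, per-feature NB Wald test with batch
#' adjustment, BH-FDR and the fold-change/FDR significance filter, in one
#' call.
#'
#' @inheritParams nb_wald_test
#' @inheritParams filter_de
#' @param alpha_min dispersion floor passed to [estimate_dispersion()].
#' @return data.frame with `feature_id`, `log2fc`, `p`, `q`, `converged`,
#'   `significant`, `direction`.
#' @export
run_seasonal_de <- function(counts, design, fdr = 0.05, fc = 1.5,
                            alpha_min = 1e-4) {
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, alpha_min = alpha_min,
                              group = design$season)
  res <- nb_wald_test(counts, sf, disp, design)
  res$q <- bh_adjust(res$p)
  filter_de(res, fdr = fdr, fc = fc)
}
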