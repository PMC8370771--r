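# Counts come in as a long tibble (cluster, sample, condition, count);
# internally we work on a clusters x samples matrix with per-sample totals
# as offsets.
counts_to_matrix <- function(counts) {
  assert_columns(counts, c("cluster", "sample", "condition", "count"), "count table")
  if (any(counts$count < 0)) stop("counts must be non-negative")
  cl <- factor(counts$cluster, levels = unique(counts$cluster))
  sm <- factor(counts$sample, levels = unique(counts$sample))
  Y <- matrix(0, nlevels(cl), nlevels(sm),
              dimnames = list(levels(cl), levels(sm)))
  Y[cbind(as.integer(cl), as.integer(sm))] <- counts$count
  cond <- counts$condition[!duplicated(sm)]
  names(cond) <- counts$sample[!duplicated(sm)]
  list(Y = Y, totals = colSums(Y), condition = factor(cond[colnames(Y)]))
}

# Vectorised Fisher scoring for per-cluster NB log-means with log-total
# offsets at fixed dispersion phi; equivalent to IRLS on the log link with
# one mean parameter per cluster (x group). Returns per-cluster log-lik and
# the fitted log-rates.
nb_fit_groups <- function(Y, totals, phi, groups = NULL, adjust = FALSE) {
  groups <- groups %||% factor(rep("all", ncol(Y)))
  eta <- matrix(NA_real_, nrow(Y), nlevels(groups),
                dimnames = list(rownames(Y), levels(groups)))
  ll <- matrix(0, nrow(Y), nlevels(groups))
  for (g in seq_len(nlevels(groups))) {
    sel <- groups == levels(groups)[g]
    Yg <- Y[, sel, drop = FALSE]
    tg <- totals[sel]
    e <- log((rowSums(Yg) + 0.5) / sum(tg))
    for (it in 1:50) {
      mu <- exp(e) %o% tg
      w <- 1 + phi * mu
      score <- rowSums((Yg - mu) / w)
      info <- rowSums(mu / w)
      step <- score / pmax(info, 1e-12)
      step <- pmin(pmax(step, -4), 4)
      e <- e + step
      if (max(abs(step)) < 1e-10) break
    }
    mu <- exp(e) %o% tg
    ll[, g] <- nb_loglik_rows(Yg, mu, phi)
    if (adjust) {
      # Cox-Reid adjustment: -1/2 log of the Fisher information of each
      # profiled mean parameter, correcting the downward bias of plain
      # profile-ML dispersion estimates
      info <- rowSums(mu / (1 + phi * mu))
      ll[, g] <- ll[, g] - 0.5 * log(pmax(info, 1e-12))
    }
    eta[, g] <- e
  }
  list(loglik = rowSums(ll), eta = eta)
}

# per-cluster NB (or Poisson-limit) log-likelihood
nb_loglik_rows <- function(Y, mu, phi) {
  if (phi < 1e-8) {
    return(rowSums(Y * log(pmax(mu, 1e-300)) - mu - lgamma(Y + 1)))
  }
  size <- 1 / phi
  rowSums(lgamma(Y + size) - lgamma(size) - lgamma(Y + 1) +
            Y * log(pmax(phi * mu, 1e-300)) - (Y + size) * log1p(phi * mu))
}

#' Estimate a common negative binomial dispersion
#'
#' Profiles the cluster-by-condition means out of the NB likelihood
#' (variance mu + phi mu^2, log-total offsets) and maximises the summed
#' Cox-Reid adjusted profile log-likelihood over a single dispersion shared
#' by all clusters, by bounded search on 0..10 with tolerance 1e-6. The
#' Cox-Reid term corrects the downward bias that plain profile ML incurs
#' from estimating one mean per cluster and condition.
#'
#' @param counts long count tibble (cluster, sample, condition, count).
#' @return the dispersion estimate phi (>= 0).
#' @export
estimate_common_dispersion <- function(counts) {
  cm <- counts_to_matrix(counts)
  if (all(cm$Y == 0)) stop("all counts are zero; dispersion is undefined")
  if (min(table(cm$condition)) < 2)
    stop("need at least 2 samples per condition")
  obj <- function(phi) -sum(nb_fit_groups(cm$Y, cm$totals, phi, cm$condition,
                                          adjust = TRUE)$loglik)
  opt <- optimize(obj, interval = c(0, 10), tol = 1e-6)
  # the optimum can sit at the Poisson boundary
  if (obj(0) <= opt$objective) 0 else opt$minimum
}

#' Differential cluster abundance by negative binomial regression
#'
#' Per cluster, fits the NB generalised linear model
#' `log mu = log(total) + b0 + b1 * condition` at a fixed common dispersion
#' (estimated from the data unless supplied) by Fisher scoring, and tests
#' `b1 = 0` with a likelihood-ratio chi-square on 1 degree of freedom.
#' Log fold changes are reported in log2 units; p-values are adjusted with
#' Benjamini-Hochberg FDR across clusters. Clusters with all-zero counts
#' are flagged and assigned p = 1, logFC = 0.
#'
#' @param counts long count tibble with exactly two conditions.
#' @param dispersion common NB dispersion; default: estimated by
#'   [estimate_common_dispersion()].
#' @return an `image3c_diff` tibble: cluster, logFC, p_value, fdr,
#'   mean_abundance, flagged. Attributes store the dispersion and the
#'   condition contrast (second level relative to the first).
#' @export
nb_test <- function(counts, dispersion = NULL) {
  cm <- counts_to_matrix(counts)
  if (nlevels(cm$condition) != 2)
    stop("nb_test compares exactly two conditions; got ",
         nlevels(cm$condition), " (use pairwise contrasts)")
  phi <- dispersion %||% estimate_common_dispersion(counts)
  nonzero <- rowSums(cm$Y) > 0
  fit1 <- nb_fit_groups(cm$Y, cm$totals, phi, cm$condition)
  fit0 <- nb_fit_groups(cm$Y, cm$totals, phi)
  lrt <- pmax(2 * (fit1$loglik - fit0$loglik), 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  logfc <- (fit1$eta[, 2] - fit1$eta[, 1]) / log(2)
  p[!nonzero] <- 1
  logfc[!nonzero] <- 0
  out <- tibble(cluster = rownames(cm$Y), logFC = unname(logfc),
                p_value = unname(p), fdr = unname(bh_fdr(p)),
                mean_abundance = unname(rowMeans(sweep(cm$Y, 2, cm$totals, "/"))),
                flagged = unname(!nonzero))
  structure(out, class = c("image3c_diff", class(out)),
            dispersion = phi,
            contrast = paste(levels(cm$condition)[2], "vs",
                             levels(cm$condition)[1]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement, as
#' used across all of the pipeline's per-cluster tests.
#'
#' @param p p-values between 0 and 1.
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' One-way ANOVA on per-cluster relative abundances
#'
#' For each cluster, a classical one-way ANOVA of per-sample relative
#' abundance against group, with BH-FDR adjustment across clusters. Used
#' for multi-group comparisons (e.g. female vs male composition).
#'
#' @param abundances long tibble: cluster, sample, group, abundance.
#' @return tibble: cluster, F, p_value, fdr, flagged (degenerate clusters
#'   with zero variance everywhere get NA statistics).
#' @export
anova_bh <- function(abundances) {
  assert_columns(abundances, c("cluster", "group", "abundance"), "abundance table")
  if (length(unique(abundances$group)) < 2) stop("need at least 2 groups")
  if (min(table(abundances$group, abundances$cluster)) < 2)
    stop("need at least 2 replicates per group")
  res <- lapply(split(abundances, abundances$cluster), function(df) {
    if (var(df$abundance) == 0)
      return(tibble(cluster = df$cluster[1], statistic = NA_real_,
                    p_value = NA_real_, flagged = TRUE))
    a <- summary(aov(abundance ~ factor(group), data = df))[[1]]
    tibble(cluster = df$cluster[1], statistic = a$`F value`[1],
           p_value = a$`Pr(>F)`[1], flagged = FALSE)
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- NA_real_
  ok <- !out$flagged
  out$fdr[ok] <- bh_fdr(out$p_value[ok])
  out
}

#' Export a volcano-plot table
#'
#' @param diff an `image3c_diff` result.
#' @param path optional CSV path.
#' @param cap maximum of `-log10(fdr)` (guards against fdr = 0).
#' @param alpha FDR cut used for the colour key.
#' @return tibble: cluster, logFC, neg_log10_fdr, colour key
#'   (up / down / ns).
#' @export
volcano_export <- function(diff, path = NULL, cap = 10, alpha = 0.05) {
  out <- tibble(cluster = diff$cluster, logFC = diff$logFC,
                neg_log10_fdr = pmin(-log10(pmax(diff$fdr, 10^(-cap))), cap),
                key = dplyr::case_when(
                  diff$fdr <= alpha & diff$logFC > 0 ~ "up",
                  diff$fdr <= alpha & diff$logFC < 0 ~ "down",
                  .default = "ns"))
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' @method tidy image3c_diff
#' @export
tidy.image3c_diff <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance image3c_diff
#' @export
glance.image3c_diff <- function(x, ...) {
  tibble(n_clusters = nrow(x), dispersion = attr(x, "dispersion"),
         contrast = attr(x, "contrast"),
         n_significant_05 = sum(x$fdr <= 0.05, na.rm = TRUE),
         n_significant_01 = sum(x$fdr <= 0.01, na.rm = TRUE))
}

#' Volcano plot of a differential abundance result
#' @param object an `image3c_diff` result.
#' @param alpha FDR threshold for highlighting.
#' @param ... unused.
#' @method autoplot image3c_diff
#' @export
autoplot.image3c_diff <- function(object, alpha = 0.05, ...) {
  df <- volcano_export(object, alpha = alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC, y = .data$neg_log10_fdr,
                                   colour = .data$key)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 3) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  colour = NULL, subtitle = attr(object, "contrast")) +
    ggplot2::theme_minimal()
}
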