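#' Trim redundant features by Spearman correlation
#'
#' Computes Spearman correlations between all feature pairs on the events of
#' one representative sample and greedily walks the pairs in panel order:
#' whenever both members of a pair are still kept and their absolute
#' correlation reaches the threshold, the later-listed feature is dropped
#' (the earlier one is kept, a deterministic and documented rule). Constant
#' features have undefined correlation; they are kept and flagged.
#'
#' @param table event feature tibble.
#' @param features feature columns to consider; default: all numeric columns
#'   that are not identifiers or flags.
#' @param threshold correlation at or above which a pair is redundant.
#' @param reference_sample sample whose events are used; default: the sample
#'   with the most events.
#' @return an `image3c_trim` list: `table` (trimmed), `kept`, `dropped`,
#'   `report` (one row per trimmed pair with its rho), `correlation` matrix,
#'   `constant` (flagged features).
#' @export
spearman_trim <- function(table, features = NULL, threshold = 0.85,
                          reference_sample = NULL) {
  features <- features %||% feature_columns(table)
  if (length(features) < 2) stop("need at least two features to trim")
  assert_columns(table, c("sample_id", features))
  reference_sample <- reference_sample %||%
    names(sort(table(table$sample_id), decreasing = TRUE))[1]
  ref <- table[table$sample_id == reference_sample, features, drop = FALSE]
  if (!nrow(ref)) stop("reference sample ", reference_sample, " has no events")
  constant <- features[vapply(ref, function(x) stats::var(x, na.rm = TRUE) == 0 ||
                                !is.finite(stats::var(x, na.rm = TRUE)), logical(1))]
  if (length(constant))
    warning("constant feature(s) with undefined correlation kept: ",
            paste(constant, collapse = ", "))
  rho <- suppressWarnings(cor(as.matrix(ref), method = "spearman",
                              use = "pairwise.complete.obs"))
  kept <- setNames(rep(TRUE, length(features)), features)
  pairs <- list()
  for (i in seq_len(length(features) - 1)) {
    if (!kept[i]) next
    for (j in seq(i + 1, length(features))) {
      if (!kept[j]) next
      r <- rho[i, j]
      if (!is.na(r) && abs(r) >= threshold) {
        kept[j] <- FALSE
        pairs[[length(pairs) + 1L]] <- tibble(
          feature_kept = features[i], feature_dropped = features[j], rho = r)
      }
    }
  }
  keep_cols <- c(setdiff(names(table), features), features[kept])
  structure(list(table = table[, keep_cols, drop = FALSE],
                 kept = features[kept], dropped = features[!kept],
                 report = if (length(pairs)) dplyr::bind_rows(pairs) else
                   tibble(feature_kept = character(), feature_dropped = character(),
                          rho = numeric()),
                 correlation = rho, constant = constant,
                 reference_sample = reference_sample, threshold = threshold),
            class = "image3c_trim")
}

# numeric feature columns, excluding identifiers/flags/cluster bookkeeping
feature_columns <- function(table) {
  drop <- c("event_id", "sample_id", "condition", "segmented", "cluster_id",
            grep("^gate_", names(table), value = TRUE))
  names(table)[vapply(table, is.numeric, logical(1)) & !names(table) %in% drop]
}

#' Flag replicate samples that do not correlate with the rest
#'
#' Summarises each sample by its vector of per-feature means, correlates it
#' (Spearman) against the element-wise median vector of all other samples,
#' and drops samples below the threshold. The full sample-by-sample
#' correlation matrix is returned for QC plots.
#'
#' @param table event feature tibble (post-trim).
#' @param features feature columns; default as in [spearman_trim()].
#' @param threshold minimum correlation with the leave-one-out reference.
#' @return list: `kept`, `dropped`, `rho` (per sample), `matrix`
#'   (sample correlations), `table` (events of kept samples).
#' @export
replicate_outlier_check <- function(table, features = NULL, threshold = 0.85) {
  features <- features %||% feature_columns(table)
  samples <- unique(table$sample_id)
  if (length(samples) < 3) {
    warning("fewer than 3 samples; replicate QC skipped")
    return(list(kept = samples, dropped = character(), rho = NULL,
                matrix = NULL, table = table))
  }
  M <- t(vapply(samples, function(s)
    colMeans(table[table$sample_id == s, features, drop = FALSE], na.rm = TRUE),
    numeric(length(features))))
  rownames(M) <- samples
  rho <- vapply(seq_along(samples), function(i) {
    ref <- apply(M[-i, , drop = FALSE], 2, median)
    suppressWarnings(cor(M[i, ], ref, method = "spearman",
                         use = "pairwise.complete.obs"))
  }, numeric(1))
  names(rho) <- samples
  keep <- !is.na(rho) & rho >= threshold
  full <- suppressWarnings(cor(t(M), method = "spearman"))
  list(kept = samples[keep], dropped = samples[!keep], rho = rho, matrix = full,
       table = table[table$sample_id %in% samples[keep], , drop = FALSE])
}

# ---------------------------------------------------------------------------
# logicle transform (biexponential inverse, root-finding implementation)

#' Estimate logicle parameters for one feature
#'
#' Auto-estimation mirrors the common practice for fluorescence features:
#' the top of scale T is the observed maximum, M = 4.5 decades, the
#' linearization width W is derived from the 5th percentile of the negative
#' values (W = 0.5 when there are none), and A = 0 extra negative decades.
#'
#' @param x numeric values of the feature.
#' @param m decades, t top of scale, w linearization width, a negative
#'   decades; any supplied value overrides the estimate.
#' @return a `logicle_params` list including the biexponential coefficients.
#' @export
logicle_params <- function(x, m = 4.5, t = NULL, w = NULL, a = 0) {
  t <- t %||% max(x, na.rm = TRUE)
  if (!is.finite(t) || t <= 0)
    stop("all values are non-positive; logicle needs a positive top of ",
         "scale (consider offsetting the feature)")
  if (is.null(w)) {
    neg <- x[x < 0 & is.finite(x)]
    w <- if (length(neg)) {
      r <- quantile(neg, 0.05, names = FALSE)
      max(0, (m - log10(t / abs(r))) / 2)
    } else 0.5
  }
  stopifnot(m > 0, w >= 0, a >= 0)
  # biexponential coefficients (standard parameterisation on y in [0, 1])
  wn <- w / (m + a)
  x2 <- a / (m + a); x1 <- x2 + wn; x0 <- x2 + 2 * wn
  b <- (m + a) * log(10)
  d <- if (wn <= 0) b else
    uniroot(function(d) 2 * (log(d) - log(b)) + wn * (d + b),
            lower = 1e-12, upper = b, tol = 1e-14)$root
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a / exp(d * x1)
  a_c <- t / ((exp(b) - mf_a) - c_a / exp(d))
  structure(list(t = t, m = m, w = w, a = a,
                 coef = list(a = a_c, b = b, c = c_a * a_c, d = d,
                             f = -mf_a * a_c, x1 = x1)),
            class = "logicle_params")
}

logicle_biexp <- function(y, params) {
  k <- params$coef
  k$a * exp(k$b * y) - k$c * exp(-k$d * y) + k$f
}

#' Logicle transform (and its inverse)
#'
#' Maps intensities onto the biexponential scale that is linear around zero
#' and logarithmic at high intensity. The forward transform inverts the
#' biexponential by bracketed bisection to a relative tolerance of 1e-10,
#' so `logicle_inverse(logicle(x, p), p)` round-trips to numerical
#' precision. Output is on 0..1 for x in 0..T; values above T map
#' above 1 and strongly negative values below 0.
#'
#' @param x intensities (forward) or scale positions (inverse).
#' @param params a [logicle_params()] object; for `logicle()` it may be
#'   omitted to auto-estimate from `x`.
#' @return transformed values; the params used are attached as an attribute
#'   by `logicle()` when auto-estimated.
#' @export
logicle <- function(x, params = NULL) {
  auto <- is.null(params)
  params <- params %||% logicle_params(x)
  lo <- rep(params$coef$x1 - 2, length(x))
  hi <- rep(2, length(x))
  while (any(logicle_biexp(lo, params) > x, na.rm = TRUE)) lo <- lo - 2
  while (any(logicle_biexp(hi, params) < x, na.rm = TRUE)) hi <- hi + 2
  for (i in 1:60) {   # bisection: 60 halvings beat the 1e-10 tolerance
    mid <- (lo + hi) / 2
    below <- logicle_biexp(mid, params) < x
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  y <- (lo + hi) / 2
  y[is.na(x)] <- NA_real_
  if (auto) attr(y, "params") <- params
  y
}

#' @rdname logicle
#' @export
logicle_inverse <- function(x, params) logicle_biexp(x, params)

#' Logicle-transform chosen feature columns of a table
#'
#' @param table event feature tibble.
#' @param features fluorescence-intensity feature columns to transform.
#' @return the table with transformed columns; attribute `transform_spec`
#'   records the per-feature parameters (serialisable with
#'   [write_transform_spec()]).
#' @export
logicle_transform_features <- function(table, features) {
  assert_columns(table, features)
  spec <- list()
  for (f in features) {
    p <- logicle_params(table[[f]])
    table[[f]] <- as.numeric(logicle(table[[f]], p))
    spec[[f]] <- p
  }
  attr(table, "transform_spec") <- spec
  table
}

#' Serialise / restore a transform specification
#'
#' @param table a table carrying a `transform_spec` attribute.
#' @param path JSON file path.
#' @export
write_transform_spec <- function(table, path) {
  spec <- attr(table, "transform_spec")
  if (is.null(spec)) stop("table has no transform_spec attribute")
  jsonlite::write_json(lapply(spec, function(p) p[c("t", "m", "w", "a")]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_spec
#' @export
read_transform_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) logicle_params(1, m = p$m, t = p$t, w = p$w, a = p$a))
}

# ---------------------------------------------------------------------------
# DNA landmark normalization

# landmarks of one sample: locations of the top-prominence KDE modes, sorted
dna_landmarks <- function(x, n_landmarks = 2) {
  d <- density(x, bw = "nrd0", n = 512)
  pk <- find_peaks(d$x, d$y)
  pk <- pk[pk$prominence > 0.01 * max(d$y), , drop = FALSE]
  sort(head(pk$x, n_landmarks))
}

# monotone piecewise-linear warp through (from_i -> to_i), slope-1 tails
landmark_warp <- function(x, from, to) {
  if (!length(from)) return(x)
  if (length(from) == 1) return(x + (to - from))
  out <- x
  out[x <= from[1]] <- x[x <= from[1]] + (to[1] - from[1])
  k <- length(from)
  out[x >= from[k]] <- x[x >= from[k]] + (to[k] - from[k])
  mid <- x > from[1] & x < from[k]
  if (any(mid)) out[mid] <- stats::approx(from, to, xout = x[mid])$y
  out
}

#' Align 2N/4N DNA peaks across samples
#'
#' Estimates up to `n_landmarks` high-prominence modes of each sample's
#' (already logicle-transformed) DNA intensity by Gaussian KDE with
#' Silverman's bandwidth, takes the per-landmark median across samples as
#' the base position, and warps each sample with a monotone piecewise-linear
#' map (identity slope outside the landmark range). This removes per-sample
#' intensity drift while preserving event order within each sample.
#'
#' @param table event feature tibble.
#' @param feature DNA intensity column name.
#' @param n_landmarks landmarks to align (2 for 2N and 4N).
#' @return the table with the warped column; attribute `dna_landmarks` is a
#'   tibble of per-sample landmark positions before/after, with samples
#'   flagged when fewer landmarks than requested were found.
#' @export
normalize_dna_peaks <- function(table, feature = "DNA_intensity", n_landmarks = 2) {
  assert_columns(table, c("sample_id", feature))
  samples <- unique(table$sample_id)
  lms <- lapply(samples, function(s)
    dna_landmarks(table[[feature]][table$sample_id == s], n_landmarks))
  names(lms) <- samples
  n_found <- lengths(lms)
  full <- n_found == max(n_found)
  base <- apply(do.call(rbind, lms[full]), 2, median)
  rows <- list()
  for (s in samples) {
    lm <- lms[[s]]
    if (!length(lm)) {
      warning("no DNA peaks found for sample ", s, "; left unwarped")
      rows[[s]] <- tibble(sample_id = s, landmark = NA_integer_,
                          before = NA_real_, after = NA_real_, flagged = TRUE)
      next
    }
    tgt <- if (length(lm) == length(base)) base else {
      if (length(lm) < n_landmarks)
        warning("sample ", s, " has ", length(lm), " of ", n_landmarks,
                " DNA peaks; aligning the peaks found")
      base[vapply(lm, function(v) which.min(abs(base - v)), integer(1))]
    }
    sel <- table$sample_id == s
    table[[feature]][sel] <- landmark_warp(table[[feature]][sel], lm, tgt)
    rows[[s]] <- tibble(sample_id = s, landmark = seq_along(lm),
                        before = lm, after = tgt, flagged = length(lm) < n_landmarks)
  }
  attr(table, "dna_landmarks") <- dplyr::bind_rows(rows)
  table
}

#' Scale features to unit standard deviation
#'
#' Divides each feature by its pooled (all-events) standard deviation so
#' that every feature contributes comparably to Euclidean distances in
#' clustering. Means are not shifted. Idempotent on unit-SD input.
#'
#' @param table event feature tibble (post-trim).
#' @param features feature columns; default as in [spearman_trim()].
#' @return the scaled table; attribute `scale_sd` holds the divisors.
#' @export
scale_features <- function(table, features = NULL) {
  features <- features %||% feature_columns(table)
  sds <- vapply(table[features], sd, numeric(1))
  bad <- features[!is.finite(sds) | sds == 0]
  if (length(bad))
    stop("cannot scale zero-variance feature(s): ", paste(bad, collapse = ", "))
  for (f in features) table[[f]] <- table[[f]] / sds[[f]]
  attr(table, "scale_sd") <- sds
  table
}
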