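#' Describe one synthetic cell population
#'
#' A population is the generator's unit of biological structure: a morphology
#' (size, nuclear/cell area ratio, internal granularity) plus per-channel
#' fluorescence intensities and a 2N/4N DNA-content mixture. Populations are
#' combined into samples by [sample_spec()].
#'
#' @param name population label, carried into ground-truth tables.
#' @param frequency fraction of events drawn from this population; the
#'   frequencies of a sample's populations must sum to 1.
#' @param cell_diameter,cell_diameter_sd mean and SD of cell diameter, pixels.
#' @param nc_ratio,nc_ratio_sd mean and SD of the nuclear/cell area ratio,
#'   in (0, 1).
#' @param granularity non-negative scalar controlling both the side-scatter
#'   intensity and the amplitude of the multiplicative log-normal speckle
#'   texture inside the cell.
#' @param channel_means named list of extra fluorescence channels; each entry
#'   is `c(meanlog, sdlog)` of the per-pixel intensity on that channel.
#' @param dna_4n_fraction fraction of events with replicated (4N) DNA content.
#' @return a `population_spec` object.
#' @examples
#' population_spec("blast", 1, cell_diameter = 8, nc_ratio = 0.8)
#' @export
population_spec <- function(name, frequency, cell_diameter, cell_diameter_sd = cell_diameter * 0.08,
                            nc_ratio = 0.5, nc_ratio_sd = 0.04, granularity = 0.5,
                            channel_means = list(), dna_4n_fraction = 0.15) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is_number(frequency) || frequency < 0 || frequency > 1)
    stop("frequency must be in [0, 1]")
  if (!is_number(cell_diameter) || cell_diameter <= 0)
    stop("cell_diameter mean must be > 0")
  if (!is_number(nc_ratio) || nc_ratio <= 0 || nc_ratio >= 1)
    stop("nc_ratio mean must be in (0, 1)")
  if (!is_number(granularity) || granularity < 0)
    stop("granularity must be >= 0")
  if (!is_number(dna_4n_fraction) || dna_4n_fraction < 0 || dna_4n_fraction > 1)
    stop("dna_4n_fraction must be in [0, 1]")
  structure(list(name = name, frequency = frequency,
                 cell_diameter = cell_diameter, cell_diameter_sd = cell_diameter_sd,
                 nc_ratio = nc_ratio, nc_ratio_sd = nc_ratio_sd,
                 granularity = granularity, channel_means = channel_means,
                 dna_4n_fraction = dna_4n_fraction),
            class = "population_spec")
}

#' Describe one synthetic sample
#'
#' Bundles populations with per-sample nuisance structure: a multiplicative
#' per-channel intensity drift, doublet and debris contamination rates, and a
#' seed making the sample a pure function of its spec.
#'
#' @param sample_id,condition labels carried through the pipeline.
#' @param n_events number of events to draw.
#' @param populations list of [population_spec()] objects; frequencies must
#'   sum to 1 (within 1e-9).
#' @param intensity_drift named numeric vector of per-channel multiplicative
#'   factors (> 0); unnamed channels default to 1.
#' @param doublet_rate,debris_rate contamination fractions; their sum must be
#'   below 1.
#' @param seed integer; same seed + same spec gives bit-identical output.
#' @return a `sample_spec` object.
#' @export
sample_spec <- function(sample_id, condition = "control", n_events = 1000L,
                        populations = list(), intensity_drift = numeric(),
                        doublet_rate = 0, debris_rate = 0, seed = 1L) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  stopifnot(length(populations) >= 1L, n_events >= 1L)
  freq <- vapply(populations, `[[`, numeric(1), "frequency")
  if (abs(sum(freq) - 1) > 1e-9)
    stop("population frequencies must sum to 1 (got ", sum(freq), ")")
  if (doublet_rate + debris_rate >= 1)
    stop("doublet_rate + debris_rate must be < 1")
  if (length(intensity_drift) && (is.null(names(intensity_drift)) || any(intensity_drift <= 0)))
    stop("intensity_drift must be a named vector of positive factors")
  structure(list(sample_id = sample_id, condition = condition,
                 n_events = as.integer(n_events), populations = populations,
                 intensity_drift = intensity_drift,
                 doublet_rate = doublet_rate, debris_rate = debris_rate,
                 seed = as.integer(seed)),
            class = "sample_spec")
}

#' Fluorescence spillover matrix
#'
#' Rows are true (emitting) channels, columns detected channels; the diagonal
#' is 1 and off-diagonal entries give the fraction of a channel's signal
#' detected in another. Detected images are `true %*% spill`; compensation
#' applies the inverse.
#'
#' @param spill square numeric matrix with identical row/column channel names.
#' @return a validated `spillover_matrix`.
#' @export
spillover_matrix <- function(spill) {
  spill <- as.matrix(spill)
  if (nrow(spill) != ncol(spill)) stop("spillover matrix must be square")
  if (is.null(rownames(spill))) rownames(spill) <- colnames(spill)
  if (is.null(rownames(spill)) || is.null(colnames(spill)))
    stop("spillover matrix needs channel names")
  if (any(abs(diag(spill) - 1) > 1e-12)) stop("spillover diagonal must be 1")
  off <- spill[row(spill) != col(spill)]
  if (any(off < 0 | off >= 1)) stop("off-diagonal spillover must be in [0, 1)")
  if (abs(det(spill)) < 1e-12) stop("spillover matrix is singular")
  structure(spill, class = c("spillover_matrix", "matrix"))
}

# ---------------------------------------------------------------------------
# rendering

# Ellipse raster on the frame grid; returns a logical matrix. `wobble`
# (low-order radial harmonics) emulates membrane undulation: real cell
# outlines are not analytic ellipses, and perfectly crisp ellipses alias
# shape features into a comb of discrete values.
render_ellipse <- function(frame, cx, cy, a, b, theta, wobble = NULL) {
  xs <- seq_len(frame) - 0.5
  dx <- outer(xs - cx, rep(1, frame))
  dy <- outer(rep(1, frame), xs - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  lim <- 1
  if (!is.null(wobble)) {
    phi <- atan2(v, u)
    for (j in seq_along(wobble$amp))
      lim <- lim + wobble$amp[j] * cos((j + 1) * phi + wobble$phase[j])
  }
  rho <= lim
}

new_wobble <- function(n_harmonics = 4, sd = 0.02) {
  list(amp = rnorm(n_harmonics, 0, sd), phase = runif(n_harmonics, 0, 2 * pi))
}

# Geometry draw for a single cell of a population; list of ellipse params.
draw_cell_geometry <- function(pop, frame) {
  d <- max(3, rnorm(1, pop$cell_diameter, pop$cell_diameter_sd))
  if (frame < d + 4)
    stop(sprintf("cell of diameter %.1f px does not fit in a %d px frame (4 px margin required)",
                 d, frame), call. = FALSE)
  # half-normal eccentricity: most singlets are nearly round, with a
  # smooth unimodal tail (aspect ratio ~ 1/elongation)
  elong <- 1 + abs(rnorm(1, 0, 0.05))
  a <- d / 2 * sqrt(elong)
  b <- d / 2 / sqrt(elong)
  theta <- runif(1, 0, pi)
  cx <- frame / 2 + runif(1, -2, 2)
  cy <- frame / 2 + runif(1, -2, 2)
  nc <- min(0.99, max(0.05, rnorm(1, pop$nc_ratio, pop$nc_ratio_sd)))
  # nucleus concentric up to a small offset that keeps it inside the cell
  off_max <- max(0, (1 - sqrt(nc)) * b * 0.5)
  phi <- runif(1, 0, 2 * pi)
  off <- runif(1, 0, off_max)
  # the nucleus shares the cell's boundary harmonics: both outlines are
  # shaped by the same membrane, and a scaled copy keeps the realised
  # nuclear/cell area ratio at its nominal value
  list(d = d, a = a, b = b, theta = theta, cx = cx, cy = cy, nc = nc,
       ncx = cx + off * cos(phi), ncy = cy + off * sin(phi),
       wobble = new_wobble())
}

# Paint one cell's channels onto existing canvases (sums emission channels,
# darkens brightfield). Used for singlets and for each member of a doublet.
paint_cell <- function(canvas, geom, pop, ploidy, channels, bf_bg) {
  frame <- nrow(canvas$BF)
  cell <- render_ellipse(frame, geom$cx, geom$cy, geom$a, geom$b, geom$theta,
                         geom$wobble)
  nuc <- render_ellipse(frame, geom$ncx, geom$ncy,
                        geom$a * sqrt(geom$nc), geom$b * sqrt(geom$nc),
                        geom$theta, geom$wobble) & cell
  npx <- sum(cell)
  sigma <- min(1.2, 0.25 + 0.3 * pop$granularity)
  # brightfield: darker elliptical body with mild speckle
  bf_cell <- bf_bg * 0.55 * exp(rnorm(npx, 0, 0.04 + 0.03 * pop$granularity))
  canvas$BF[cell] <- pmin(canvas$BF[cell], bf_cell)
  # side scatter: intensity and speckle amplitude both follow granularity
  if ("SSC" %in% channels && pop$granularity > 0) {
    ssc <- 60 * pop$granularity * exp(rnorm(npx, 0, sigma) - sigma^2 / 2)
    canvas$SSC[cell] <- canvas$SSC[cell] + ssc
  }
  # nuclear dye: fixed total intensity per genome copy number
  if ("DNA" %in% channels && sum(nuc) > 0) {
    total <- 5e4 * ploidy / 2
    tex <- exp(rnorm(sum(nuc), 0, 0.15))
    canvas$DNA[nuc] <- canvas$DNA[nuc] + total * tex / sum(tex)
  }
  for (ch in names(pop$channel_means)) {
    if (!ch %in% channels) next
    pr <- pop$channel_means[[ch]]
    level <- exp(rnorm(1, pr[1], if (length(pr) > 1) pr[2] else 0))
    canvas[[ch]][cell] <- canvas[[ch]][cell] + level * exp(rnorm(npx, 0, 0.1))
  }
  list(canvas = canvas, cell = cell, nucleus = nuc)
}

new_canvas <- function(frame, channels, bf_bg) {
  canvas <- lapply(channels, function(ch) matrix(0, frame, frame))
  names(canvas) <- channels
  canvas$BF <- matrix(rnorm(frame * frame, bf_bg, bf_bg * 0.01), frame, frame)
  canvas
}

#' Render one synthetic cell image stack
#'
#' Produces a multi-channel image of a single cell: a brightfield-like channel
#' (dark elliptical body on a bright background), a side-scatter channel whose
#' intensity tracks the population's granularity, a nuclear channel whose total
#' intensity reflects 2N or 4N DNA content, and any extra fluorescence
#' channels declared in the population spec. Ground-truth cell and nuclear
#' masks are attached.
#'
#' @param pop a [population_spec()].
#' @param seed integer; identical seeds give pixel-identical stacks.
#' @param frame frame side length in pixels; must exceed the cell diameter
#'   by at least 4 px.
#' @param channels channel names to render; `"BF"` is always present.
#' @param quantize round intensities to 16-bit unsigned integers, mirroring
#'   instrument TIFF exports.
#' @return an `image3c_event`: named channel matrices, masks, and a `truth`
#'   list (population, ploidy, doublet/debris flags).
#' @export
render_cell_image <- function(pop, seed, frame = 64L,
                              channels = c("BF", "SSC", "DNA"),
                              quantize = FALSE) {
  channels <- union("BF", channels)
  with_local_seed(seed, {
    bf_bg <- 3000
    geom <- draw_cell_geometry(pop, frame)
    ploidy <- if (runif(1) < pop$dna_4n_fraction) 4L else 2L
    res <- paint_cell(new_canvas(frame, channels, bf_bg), geom, pop, ploidy,
                      channels, bf_bg)
    ev <- new_event(res$canvas, masks = list(cell = res$cell, nucleus = res$nucleus),
                    truth = list(population = pop$name, ploidy = ploidy,
                                 diameter = geom$d, nc_ratio = geom$nc,
                                 is_doublet = FALSE, is_debris = FALSE))
    if (quantize) ev$channels <- lapply(ev$channels, function(m) round(pmin(pmax(m, 0), 65535)))
    ev
  })
}

new_event <- function(channels, masks = NULL, truth = NULL,
                      event_id = NA_character_, sample_id = NA_character_) {
  structure(list(event_id = event_id, sample_id = sample_id,
                 channels = channels, masks = masks, truth = truth,
                 flags = list()),
            class = "image3c_event")
}

render_doublet <- function(pops, seed, frame, channels) {
  channels <- union("BF", channels)
  with_local_seed(seed, {
    bf_bg <- 3000
    g1 <- draw_cell_geometry(pops[[1]], frame)
    g2 <- draw_cell_geometry(pops[[2]], frame)
    # second cell offset along a random axis for 30-60% mask overlap
    r <- (g1$d + g2$d) / 4
    dist <- 2 * r * runif(1, 0.35, 0.6)
    ang <- runif(1, 0, 2 * pi)
    shift_x <- dist * cos(ang) / 2; shift_y <- dist * sin(ang) / 2
    g1$cx <- g1$cx - shift_x; g1$cy <- g1$cy - shift_y
    g1$ncx <- g1$ncx - shift_x; g1$ncy <- g1$ncy - shift_y
    g2$cx <- g2$cx + shift_x; g2$cy <- g2$cy + shift_y
    g2$ncx <- g2$ncx + shift_x; g2$ncy <- g2$ncy + shift_y
    p1 <- if (runif(1) < pops[[1]]$dna_4n_fraction) 4L else 2L
    p2 <- if (runif(1) < pops[[2]]$dna_4n_fraction) 4L else 2L
    res <- paint_cell(new_canvas(frame, channels, bf_bg), g1, pops[[1]], p1, channels, bf_bg)
    res2 <- paint_cell(res$canvas, g2, pops[[2]], p2, channels, bf_bg)
    new_event(res2$canvas,
              masks = list(cell = res$cell | res2$cell, nucleus = res$nucleus | res2$nucleus),
              truth = list(population = pops[[1]]$name, ploidy = p1 + p2,
                           diameter = max(g1$d, g2$d), nc_ratio = NA_real_,
                           is_doublet = TRUE, is_debris = FALSE))
  })
}

render_debris <- function(seed, frame, channels) {
  channels <- union("BF", channels)
  with_local_seed(seed, {
    bf_bg <- 3000
    canvas <- new_canvas(frame, channels, bf_bg)
    d <- runif(1, 2, 5)
    frag <- render_ellipse(frame, frame / 2 + runif(1, -4, 4),
                           frame / 2 + runif(1, -4, 4),
                           d / 2 * 1.3, d / 2 / 1.3, runif(1, 0, pi))
    canvas$BF[frag] <- canvas$BF[frag] * 0.85
    if ("SSC" %in% channels) canvas$SSC[frag] <- runif(sum(frag), 0, 10)
    new_event(canvas, masks = list(cell = frag, nucleus = frag & FALSE),
              truth = list(population = "debris", ploidy = 0L, diameter = d,
                           nc_ratio = NA_real_, is_doublet = FALSE, is_debris = TRUE))
  })
}

#' Simulate one sample of cell images with ground truth
#'
#' Draws events from the spec's populations at their stated frequencies,
#' renders doublets (two overlapping cells) and debris (sub-threshold
#' fragments with no nuclear signal) at the spec's contamination rates,
#' applies per-channel multiplicative intensity drift, and optionally mixes
#' channels through a spillover matrix.
#'
#' @param spec a [sample_spec()].
#' @param spillover optional [spillover_matrix()]; its channels must exist.
#' @param frame frame side in pixels.
#' @param channels channels to render.
#' @param quantize round to 16-bit integers after drift/spillover.
#' @return list with `events` (list of `image3c_event`) and `truth`
#'   (tibble: event_id, sample_id, population, ploidy, flags).
#' @export
simulate_sample <- function(spec, spillover = NULL, frame = 64L,
                            channels = c("BF", "SSC", "DNA"), quantize = FALSE) {
  stopifnot(inherits(spec, "sample_spec"))
  channels <- union("BF", channels)
  extra <- unique(unlist(lapply(spec$populations, function(p) names(p$channel_means))))
  channels <- union(channels, extra)
  n <- spec$n_events
  with_local_seed(spec$seed, {
    kind <- sample(c("doublet", "debris", "singlet"), n, replace = TRUE,
                   prob = c(spec$doublet_rate, spec$debris_rate,
                            1 - spec$doublet_rate - spec$debris_rate))
    freq <- vapply(spec$populations, `[[`, numeric(1), "frequency")
    pop_idx <- sample.int(length(freq), n, replace = TRUE, prob = freq)
    seeds <- sample.int(2147483646L, n, replace = TRUE)
    events <- vector("list", n)
    for (i in seq_len(n)) {
      ev <- switch(kind[i],
        singlet = render_cell_image(spec$populations[[pop_idx[i]]], seeds[i],
                                    frame, channels),
        doublet = render_doublet(spec$populations[c(pop_idx[i], pop_idx[i])],
                                 seeds[i], frame, channels),
        debris  = render_debris(seeds[i], frame, channels))
      ev$event_id <- sprintf("%s_ev%05d", spec$sample_id, i)
      ev$sample_id <- spec$sample_id
      for (ch in names(spec$intensity_drift))
        if (ch %in% names(ev$channels))
          ev$channels[[ch]] <- ev$channels[[ch]] * spec$intensity_drift[[ch]]
      if (!is.null(spillover)) ev <- apply_spillover(ev, spillover)
      if (quantize) ev$channels <- lapply(ev$channels, function(m) round(pmin(pmax(m, 0), 65535)))
      events[[i]] <- ev
    }
    truth <- dplyr::bind_rows(lapply(events, function(e)
      tibble(event_id = e$event_id, sample_id = e$sample_id,
             condition = spec$condition,
             population = e$truth$population, ploidy = e$truth$ploidy,
             diameter = e$truth$diameter, nc_ratio = e$truth$nc_ratio,
             is_doublet = e$truth$is_doublet, is_debris = e$truth$is_debris)))
    list(events = events, truth = truth)
  })
}

# forward-mix channels through the spillover matrix (detected = true %*% S)
apply_spillover <- function(event, spill) {
  chs <- rownames(spill)
  miss <- setdiff(chs, names(event$channels))
  if (length(miss)) stop("spillover references missing channel(s): ",
                         paste(miss, collapse = ", "))
  P <- vapply(chs, function(ch) as.vector(event$channels[[ch]]),
              numeric(length(event$channels[[chs[1]]])))
  D <- P %*% unclass(spill)
  dims <- dim(event$channels[[chs[1]]])
  for (j in seq_along(chs)) event$channels[[chs[j]]] <- matrix(D[, j], dims[1], dims[2])
  event
}

#' Simulate a clusters-by-samples count matrix
#'
#' Generates per-cluster event counts for a two-condition experiment with
#' negative binomial noise around condition-specific expected proportions,
#' expected per-sample totals held fixed (10,000 events by default, the
#' per-sample recording depth the pipeline assumes). With `dispersion = 0`
#' sampling reduces to Poisson.
#'
#' @param n_clusters number of clusters.
#' @param n_per_condition samples per condition (length-2 vector or scalar).
#' @param baseline proportions per cluster (summing to 1); default uniform.
#' @param effect_log2 per-cluster log2 fold change applied to the second
#'   condition; default all zero.
#' @param dispersion NB dispersion phi (variance mu + phi mu^2), >= 0.
#' @param total expected events per sample.
#' @param conditions condition labels.
#' @param seed integer seed.
#' @return long tibble: cluster, sample, condition, count.
#' @export
simulate_count_matrix <- function(n_clusters, n_per_condition = 6L,
                                  baseline = NULL, effect_log2 = NULL,
                                  dispersion = 0.1, total = 10000L,
                                  conditions = c("A", "B"), seed = 1L) {
  if (length(n_per_condition) == 1L) n_per_condition <- rep(n_per_condition, 2L)
  baseline <- baseline %||% rep(1 / n_clusters, n_clusters)
  effect_log2 <- effect_log2 %||% rep(0, n_clusters)
  stopifnot(length(baseline) == n_clusters, length(effect_log2) == n_clusters,
            dispersion >= 0)
  if (abs(sum(baseline) - 1) > 1e-9) stop("baseline proportions must sum to 1")
  with_local_seed(seed, {
    out <- list()
    for (ci in 1:2) {
      p <- baseline * 2^(effect_log2 * (ci == 2))
      p <- p / sum(p)
      mu <- p * total
      for (s in seq_len(n_per_condition[ci])) {
        counts <- if (dispersion == 0) rpois(n_clusters, mu)
                  else rnbinom(n_clusters, mu = mu, size = 1 / dispersion)
        out[[length(out) + 1L]] <- tibble(
          cluster = sprintf("c%02d", seq_len(n_clusters)),
          sample = sprintf("%s%d", conditions[ci], s),
          condition = conditions[ci],
          count = as.integer(counts))
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Four well-separated demonstration populations
#'
#' A compact panel emulating common blood-cell morphologies: small
#' blast-like cells with a high nuclear/cytoplasmic ratio, large granular
#' and large agranular cells, and an intermediate population with a bright
#' extra fluorescence channel. Used throughout the tests and examples as the
#' ground-truth fixture for cluster recovery.
#'
#' By default the populations are non-cycling (`dna_4n = 0`): cycling cells
#' at 4N form a genuinely distinct density mode, which would make a
#' four-cluster ground truth ambiguous. Set `dna_4n` above zero when the
#' 2N/4N bimodality itself is under study (e.g. landmark normalization).
#'
#' @param dna_4n fraction of 4N events in every population.
#' @return list of four [population_spec()] objects.
#' @export
demo_populations <- function(dna_4n = 0) {
  list(
    population_spec("blast", 0.35, cell_diameter = 12, cell_diameter_sd = 0.8,
                    nc_ratio = 0.80, granularity = 0.2, dna_4n_fraction = dna_4n,
                    channel_means = list(FL1 = c(log(30), 0.25))),
    population_spec("large_granular", 0.30, cell_diameter = 22, cell_diameter_sd = 1.4,
                    nc_ratio = 0.35, granularity = 3, dna_4n_fraction = dna_4n,
                    channel_means = list(FL1 = c(log(60), 0.25))),
    population_spec("large_agranular", 0.20, cell_diameter = 22, cell_diameter_sd = 1.4,
                    nc_ratio = 0.35, granularity = 0.3, dna_4n_fraction = dna_4n,
                    channel_means = list(FL1 = c(log(30), 0.25))),
    population_spec("intermediate", 0.15, cell_diameter = 16, cell_diameter_sd = 1.0,
                    nc_ratio = 0.55, granularity = 1.2, dna_4n_fraction = dna_4n,
                    channel_means = list(FL1 = c(log(600), 0.25))))
}

#' Simulate a small multi-sample experiment from the demonstration panel
#'
#' @param n_samples number of samples (all drawn from the same populations).
#' @param n_events events per sample.
#' @param seed global seed; per-sample seeds are derived from it.
#' @param ... passed to [simulate_sample()].
#' @return list with concatenated `events` and `truth`.
#' @export
demo_experiment <- function(n_samples = 4L, n_events = 500L, seed = 1L, ...) {
  pops <- demo_populations()
  out <- lapply(seq_len(n_samples), function(s) {
    spec <- sample_spec(sprintf("s%02d", s), condition = "control",
                        n_events = n_events, populations = pops,
                        seed = stage_seed(seed, sprintf("sample%02d", s)))
    simulate_sample(spec, ...)
  })
  list(events = do.call(c, lapply(out, `[[`, "events")),
       truth = dplyr::bind_rows(lapply(out, `[[`, "truth")))
}

#' Simulate samples and reduce them straight to a feature table
#'
#' Renders each sample, segments, background-corrects and featurises its
#' events one sample at a time, keeping only the feature rows (the image
#' stacks of a large experiment would otherwise not fit in memory at once).
#'
#' @param specs list of [sample_spec()] objects.
#' @param spillover optional [spillover_matrix()] applied at render time and
#'   compensated before feature extraction.
#' @param frame,channels,quantize passed to [simulate_sample()].
#' @return list with `table` (ungated feature tibble) and `truth`.
#' @export
simulate_feature_table <- function(specs, spillover = NULL, frame = 64L,
                                   channels = c("BF", "SSC", "DNA"),
                                   quantize = FALSE) {
  if (inherits(specs, "sample_spec")) specs <- list(specs)
  tables <- list(); truths <- list()
  for (spec in specs) {
    sim <- simulate_sample(spec, spillover = spillover, frame = frame,
                           channels = channels, quantize = quantize)
    panel <- NULL
    rows <- vector("list", length(sim$events))
    for (i in seq_along(sim$events)) {
      ev <- sim$events[[i]]
      sim$events[i] <- list(NULL)
      if (!is.null(spillover)) ev <- compensate(ev, spillover)
      ev <- segment_masks(ev)
      if (isTRUE(ev$flags$unsegmentable)) {
        rows[[i]] <- tibble(event_id = ev$event_id, sample_id = ev$sample_id,
                            segmented = FALSE)
        next
      }
      ev <- subtract_background(ev)
      panel <- panel %||% default_feature_panel(names(ev$channels))
      row <- compute_features_one(ev, panel)
      rows[[i]] <- dplyr::bind_cols(row[, 1:2], tibble(segmented = TRUE),
                                    row[, -(1:2)])
    }
    tables[[spec$sample_id]] <- dplyr::bind_rows(rows)
    truths[[spec$sample_id]] <- sim$truth
    rm(sim); gc(FALSE)
  }
  list(table = dplyr::bind_rows(tables), truth = dplyr::bind_rows(truths))
}

# ---------------------------------------------------------------------------
# disk IO

#' Write events as multi-page TIFFs plus a manifest
#'
#' One 16-bit multi-page TIFF per event (one page per channel, in manifest
#' channel order) and a manifest CSV with event/sample IDs, relative file
#' paths, the channel list and any ground-truth columns.
#'
#' @param events list of `image3c_event`.
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth tibble joined into the manifest.
#' @return invisibly, the manifest tibble (also written to `manifest.csv`).
#' @export
write_event_images <- function(events, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(events, function(ev) {
    file <- file.path("images", paste0(ev$event_id, ".tif"))
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    pages <- lapply(ev$channels, function(m) pmin(pmax(m / 65535, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, file), bits.per.sample = 16L)
    tibble(event_id = ev$event_id, sample_id = ev$sample_id, file = file,
           channels = paste(names(ev$channels), collapse = ";"))
  })
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(truth)) manifest <- dplyr::left_join(manifest, truth,
                                                    by = c("event_id", "sample_id"))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read events back from a manifest of multi-page TIFFs
#'
#' @param manifest path to a manifest CSV (or the directory holding one).
#' @return list with `events` (channels only; masks are recomputed by
#'   [segment_masks()]) and the `manifest` tibble.
#' @export
read_event_images <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  base <- dirname(manifest)
  events <- lapply(seq_len(nrow(man)), function(i) {
    pages <- tiff::readTIFF(file.path(base, man$file[i]), all = TRUE)
    chs <- strsplit(man$channels[i], ";", fixed = TRUE)[[1]]
    channels <- lapply(pages, function(p) p * 65535)
    names(channels) <- chs
    new_event(channels, event_id = man$event_id[i], sample_id = man$sample_id[i])
  })
  list(events = events, manifest = man)
}
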