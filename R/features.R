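#' Compensate fluorescence spillover on an event
#'
#' Applies the inverse of the spillover matrix to every pixel's detected
#' channel vector, then clamps negatives at zero. With an identity matrix the
#' event is returned unchanged (up to the clamp).
#'
#' @param event an `image3c_event`.
#' @param spill a [spillover_matrix()]; rows = true channels,
#'   columns = detected channels.
#' @return the event with unmixed channels.
#' @export
compensate <- function(event, spill) {
  S <- unclass(spill)
  inv <- tryCatch(solve(S), error = function(e)
    stop("spillover matrix is singular and cannot be inverted", call. = FALSE))
  chs <- rownames(S)
  miss <- setdiff(chs, names(event$channels))
  if (length(miss)) stop("event lacks channel(s) named in the spillover matrix: ",
                         paste(miss, collapse = ", "))
  D <- vapply(chs, function(ch) as.vector(event$channels[[ch]]),
              numeric(length(event$channels[[chs[1]]])))
  Tm <- D %*% inv
  dims <- dim(event$channels[[chs[1]]])
  for (j in seq_along(chs))
    event$channels[[chs[j]]] <- matrix(pmax(Tm[, j], 0), dims[1], dims[2])
  event
}

#' Subtract per-channel background
#'
#' Estimates the background as the median intensity outside the cell mask
#' (or outside an Otsu foreground estimate when masks have not been computed
#' yet) and removes it. Emission channels are shifted down and clamped at
#' zero; channels whose object is darker than the background (brightfield)
#' are inverted into background-relative absorbance so that morphology is
#' preserved rather than clipped away.
#'
#' @param event an `image3c_event`.
#' @return the event with background-corrected channels.
#' @export
subtract_background <- function(event) {
  for (ch in names(event$channels)) {
    x <- event$channels[[ch]]
    bg_mask <- if (!is.null(event$masks$cell)) !event$masks$cell
               else {
                 dev <- abs(x - median(x))
                 dev <= otsu_threshold(dev)
               }
    if (!any(bg_mask)) {
      warning("no background pixels on channel ", ch,
              "; falling back to the global 5th percentile")
      b <- quantile(x, 0.05, names = FALSE)
    } else b <- median(x[bg_mask])
    fg_mask <- !bg_mask
    dark_object <- any(fg_mask) && median(x[fg_mask]) < b
    event$channels[[ch]] <- if (dark_object) pmax(b - x, 0) else pmax(x - b, 0)
  }
  event
}

#' Segment cell and nucleus masks
#'
#' Cell mask: Otsu threshold on the brightfield gradient-magnitude image,
#' morphologically closed (radius-3 disc) and hole-filled, keeping the
#' largest connected component. Nucleus mask: Otsu on the nuclear channel
#' restricted to the cell, forced to lie inside it. Events without
#' foreground are flagged `unsegmentable` and later fail gating.
#'
#' @param event an `image3c_event` with BF (and ideally DNA) channels.
#' @return the event with `masks$cell` and `masks$nucleus` set.
#' @export
segment_masks <- function(event) {
  if (is.null(event$channels$BF)) stop("segmentation needs a BF channel")
  g <- gradient_magnitude(event$channels$BF)
  thr <- otsu_threshold(g)
  bw <- g > thr
  if (!any(bw)) return(flag_unsegmentable(event))
  closed <- EBImage::closing(bw, EBImage::makeBrush(7L, "disc"))
  filled <- EBImage::fillHull(EBImage::Image(closed * 1)) > 0
  # the gradient ring sits one pixel outside the object; erode it back
  filled <- EBImage::erode(filled, EBImage::makeBrush(3L, "disc"))
  lab <- EBImage::bwlabel(filled)
  if (max(lab) == 0) return(flag_unsegmentable(event))
  sizes <- tabulate(lab[lab > 0])
  cell <- matrix(lab == which.max(sizes), nrow(lab), ncol(lab))
  # reject degenerate masks: specks, or noise blobs engulfing the frame
  if (sum(cell) < 5 || sum(cell) > 0.5 * length(cell))
    return(flag_unsegmentable(event))
  nucleus <- NULL
  if (!is.null(event$channels$DNA)) {
    dna <- event$channels$DNA
    inside <- dna[cell]
    nucleus <- if (diff(range(inside)) > 0) {
      nt <- otsu_threshold(inside)
      # Otsu assumes nucleus and cytoplasm both occupy the cell; when the
      # nucleus fills it, the split lands inside the nuclear texture. In
      # that case fall back to a near-zero cytoplasm floor.
      m0 <- mean(inside[inside <= nt]); m1 <- mean(inside[inside > nt])
      if (!is.finite(m0) || !is.finite(m1) || m0 > 0.3 * m1)
        nt <- 0.15 * quantile(inside, 0.9, names = FALSE)
      (dna > nt) & cell
    } else cell & FALSE
  }
  event$masks <- list(cell = cell, nucleus = nucleus)
  event$flags$unsegmentable <- FALSE
  event
}

flag_unsegmentable <- function(event) {
  event$flags$unsegmentable <- TRUE
  event$masks <- list(cell = NULL, nucleus = NULL)
  event
}

gradient_magnitude <- function(x) {
  gx <- x * 0; gy <- x * 0
  n <- nrow(x); m <- ncol(x)
  gx[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / 2
  gy[, 2:(m - 1)] <- (x[, 3:m] - x[, 1:(m - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

# ---------------------------------------------------------------------------
# feature panel

#' The default open feature panel
#'
#' Declares the per-event features computed by [compute_features()]:
#' geometry on the cell and nucleus masks (area, perimeter,
#' equivalent-circle diameter, major/minor axis, aspect ratio = minor/major,
#' circularity = 4*pi*A/P^2, shape ratio = diameter/major), the
#' nuclear/cell area ratio, per-channel intensity statistics (integrated,
#' mean, max pixel, RMS contrast), a brightfield gradient-RMS focus proxy,
#' and a three-point granularity spectrum on BF and SSC. Names are stable
#' API.
#'
#' @param channels channel names available on the events.
#' @return tibble with columns name, channel, mask, kind, scale.
#' @export
default_feature_panel <- function(channels = c("BF", "SSC", "DNA")) {
  geom <- c("area", "perimeter", "diameter", "major_axis", "minor_axis",
            "aspect_ratio", "circularity", "shape_ratio")
  rows <- list(
    tibble(name = paste0("cell_", geom), channel = NA_character_,
           mask = "cell", kind = "geometry"),
    tibble(name = paste0("nuc_", geom), channel = NA_character_,
           mask = "nucleus", kind = "geometry"),
    tibble(name = "nc_ratio", channel = NA_character_, mask = "nucleus",
           kind = "geometry"))
  for (ch in channels) {
    rows[[length(rows) + 1L]] <- tibble(
      name = paste0(ch, c("_intensity", "_mean_intensity", "_max_pixel", "_contrast")),
      channel = ch, mask = "cell", kind = "intensity")
  }
  if ("BF" %in% channels)
    rows[[length(rows) + 1L]] <- tibble(name = "BF_gradient_rms", channel = "BF",
                                        mask = "cell", kind = "intensity")
  for (ch in intersect(c("BF", "SSC"), channels))
    rows[[length(rows) + 1L]] <- tibble(name = paste0(ch, "_granularity_", 1:3),
                                        channel = ch, mask = "cell", kind = "texture")
  panel <- dplyr::bind_rows(rows)
  stopifnot(!anyDuplicated(panel$name))
  panel
}

# geometry descriptors of a boolean mask (pixel units; area = pixel count)
geometry_features <- function(mask) {
  area <- sum(mask)
  if (area == 0)
    return(c(area = 0, perimeter = 0, diameter = 0, major_axis = 0,
             minor_axis = 0, aspect_ratio = NA_real_, circularity = NA_real_,
             shape_ratio = NA_real_))
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  cv <- crossprod(cc) / area
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  major <- 4 * sqrt(max(ev[1], 0))
  minor <- 4 * sqrt(max(ev[2], 0))
  n <- nrow(mask); m <- ncol(mask)
  # Crofton two-direction perimeter: pi/4 times boundary crossings
  n_v <- sum(mask[-1, ] != mask[-n, ]) + sum(mask[1, ]) + sum(mask[n, ])
  n_h <- sum(mask[, -1] != mask[, -m]) + sum(mask[, 1]) + sum(mask[, m])
  per <- pi / 4 * (n_v + n_h)
  diam <- 2 * sqrt(area / pi)
  c(area = area, perimeter = per, diameter = diam, major_axis = major,
    minor_axis = minor,
    aspect_ratio = if (major > 0) minor / major else NA_real_,
    circularity = if (per > 0) 4 * pi * area / per^2 else NA_real_,
    shape_ratio = if (major > 0) diam / major else NA_real_)
}

granularity_spectrum <- function(x, mask, radii = 1:3) {
  total <- sum(x[mask])
  out <- setNames(numeric(length(radii)), radii)
  if (total <= 0) return(out)
  for (i in seq_along(radii)) {
    s <- radii[i]
    # square structuring element: openings are nested across sizes, so the
    # spectrum is monotone by construction
    op <- EBImage::opening(x, EBImage::makeBrush(2L * s + 1L, "box"))
    out[i] <- min(1, max(0, 1 - sum(op[mask]) / total))
  }
  out
}

compute_features_one <- function(event, panel) {
  if (isTRUE(event$flags$unsegmentable) || is.null(event$masks$cell))
    stop("event ", event$event_id, " has no masks; run segment_masks() first ",
         "(unsegmentable events must be dropped or flagged)")
  cell <- event$masks$cell
  nuc <- event$masks$nucleus
  vals <- list()
  gc_cell <- geometry_features(cell)
  vals[paste0("cell_", names(gc_cell))] <- gc_cell
  gn <- geometry_features(if (is.null(nuc)) cell & FALSE else nuc)
  vals[paste0("nuc_", names(gn))] <- gn
  vals[["nc_ratio"]] <- if (gc_cell[["area"]] > 0) gn[["area"]] / gc_cell[["area"]] else NA_real_
  for (ch in unique(stats::na.omit(panel$channel))) {
    x <- event$channels[[ch]]
    if (is.null(x)) stop("event ", event$event_id, " lacks channel ", ch)
    inm <- x[cell]
    vals[[paste0(ch, "_intensity")]] <- sum(inm)
    vals[[paste0(ch, "_mean_intensity")]] <- mean(inm)
    vals[[paste0(ch, "_max_pixel")]] <- max(inm)
    vals[[paste0(ch, "_contrast")]] <- sd(inm)
    if (ch == "BF") {
      g <- gradient_magnitude(x)
      vals[["BF_gradient_rms"]] <- sqrt(mean(g[cell]^2))
    }
    if (ch %in% c("BF", "SSC") && any(panel$name == paste0(ch, "_granularity_1"))) {
      gr <- granularity_spectrum(x, cell)
      vals[paste0(ch, "_granularity_", names(gr))] <- gr
    }
  }
  out <- tibble(event_id = event$event_id, sample_id = event$sample_id)
  keep <- intersect(panel$name, names(vals))
  dplyr::bind_cols(out, tibble::as_tibble(vals[keep]))
}

#' Compute the per-event feature table
#'
#' Runs the declared feature panel over a list of segmented events and
#' returns one row per event. Unsegmentable events yield a row of NA feature
#' values with `segmented = FALSE` so that gating can drop them explicitly.
#'
#' @param events one `image3c_event` or a list of them (masks present).
#' @param panel a feature panel, by default [default_feature_panel()] for
#'   the channels of the first event.
#' @return tibble: event_id, sample_id, segmented, then one column per
#'   feature in panel order.
#' @export
compute_features <- function(events, panel = NULL) {
  if (inherits(events, "image3c_event")) events <- list(events)
  panel <- panel %||% default_feature_panel(names(events[[1]]$channels))
  rows <- lapply(events, function(ev) {
    if (isTRUE(ev$flags$unsegmentable)) {
      na_row <- tibble::as_tibble(setNames(as.list(rep(NA_real_, nrow(panel))), panel$name))
      return(dplyr::bind_cols(tibble(event_id = ev$event_id, sample_id = ev$sample_id,
                                     segmented = FALSE), na_row))
    }
    row <- compute_features_one(ev, panel)
    dplyr::bind_cols(row[, 1:2], tibble(segmented = TRUE), row[, -(1:2)])
  })
  dplyr::bind_rows(rows)
}

# ---------------------------------------------------------------------------
# gating

#' Gate configuration
#'
#' @param focused `TRUE` for an automatic per-sample Otsu split of the BF
#'   gradient-RMS distribution, `FALSE` to disable, or a numeric threshold.
#' @param nucleated `TRUE` for the automatic DNA-intensity valley threshold
#'   (KDE valley between the debris band and the 2N mode, falling back to
#'   mean + 3 SD of the debris band), `FALSE`, or a numeric threshold.
#' @param singlet `TRUE` for the default area vs aspect-ratio box
#'   (aspect ratio >= 0.8, area <= 1.75 x the median nucleated area),
#'   `FALSE`, or a polygon data frame with columns `area`, `aspect_ratio`.
#' @param extra named list of additional manual gates, each
#'   `list(features = c(fx, fy), polygon = <data frame>)`; events inside the
#'   polygon are kept.
#' @return a `gate_config` list.
#' @export
gate_config <- function(focused = TRUE, nucleated = TRUE, singlet = TRUE,
                        extra = list()) {
  structure(list(focused = focused, nucleated = nucleated, singlet = singlet,
                 extra = extra), class = "gate_config")
}

# KDE valley between the two lowest-intensity modes. Returns NULL when the
# distribution is unimodal, or when the lowest mode is not a genuine
# low-signal band (debris or unfocused events sit far below the main
# population; the 2N mode of a healthy sample does not).
low_mode_valley <- function(x, low_ratio = 0.4) {
  d <- density(x, n = 512)
  pk <- find_peaks(d$x, d$y)
  pk <- pk[pk$prominence > 0.02 * max(d$y), , drop = FALSE]
  if (nrow(pk) < 2) return(NULL)
  locs <- sort(pk$x)
  if (locs[1] > low_ratio * max(locs)) return(NULL)
  seg <- d$x > locs[1] & d$x < locs[2]
  d$x[seg][which.min(d$y[seg])]
}

#' Gate an event table down to focused, nucleated singlets
#'
#' Applies, in order: a focus gate on the brightfield gradient RMS, a
#' nucleated gate on integrated DNA intensity, a singlet gate in the
#' area vs aspect-ratio plane, and any extra feature-space polygon gates
#' (e.g. manual erythrocyte out-gating). Thresholds default to the automatic
#' rules in [gate_config()]; every gate records a pass/fail flag.
#'
#' @param table feature tibble from [compute_features()].
#' @param gates a [gate_config()].
#' @param keep_all return all rows with flag columns instead of only the
#'   retained events.
#' @return the gated tibble; attribute `gate_report` holds per-gate counts
#'   and the thresholds used.
#' @export
gate_events <- function(table, gates = gate_config(), keep_all = FALSE) {
  tbl <- table
  pass <- !is.na(tbl$event_id)
  if ("segmented" %in% names(tbl)) pass <- pass & tbl$segmented
  report <- list()
  flag <- function(ok) ifelse(pass, ok, NA)

  if (!isFALSE(gates$focused)) {
    assert_columns(tbl, "BF_gradient_rms", "gating")
    thr <- if (is.numeric(gates$focused)) rep(gates$focused, nrow(tbl)) else {
      # per-sample Otsu split, engaged only when a distinct low-focus mode
      # exists (an all-focused sample is left intact)
      th <- tapply(tbl$BF_gradient_rms[pass], tbl$sample_id[pass], function(v)
        if (is.null(low_mode_valley(v))) -Inf else otsu_threshold(v))
      as.numeric(th[tbl$sample_id])
    }
    ok <- tbl$BF_gradient_rms >= thr
    tbl$gate_focused <- flag(ok)
    report$focused <- list(removed = sum(pass & !ok, na.rm = TRUE),
                           threshold = unique(round(thr, 4)))
    pass <- pass & !is.na(ok) & ok
  }
  if (!isFALSE(gates$nucleated)) {
    assert_columns(tbl, "DNA_intensity", "gating")
    if (is.numeric(gates$nucleated)) thr <- gates$nucleated
    else {
      x <- tbl$DNA_intensity[pass]
      thr <- low_mode_valley(x)
      if (is.null(thr)) {
        # no separable debris band; if a near-zero band exists anyway, cut
        # at mean + 3 SD of it, otherwise keep everything
        band <- x[x <= 0.05 * max(x)]
        if (length(band) >= 5) {
          thr <- mean(band) + 3 * sd(band)
          warning("DNA intensity has no clear valley; nucleated gate fell ",
                  "back to mean + 3 SD of the near-zero band")
        } else thr <- -Inf
      }
    }
    ok <- tbl$DNA_intensity >= thr
    tbl$gate_nucleated <- flag(ok)
    report$nucleated <- list(removed = sum(pass & !ok, na.rm = TRUE),
                             threshold = thr)
    pass <- pass & !is.na(ok) & ok
  }
  if (!isFALSE(gates$singlet)) {
    assert_columns(tbl, c("cell_area", "cell_aspect_ratio"), "gating")
    poly <- gates$singlet
    if (isTRUE(poly)) {
      # aspect ratio does the work: doublets elongate well below the 0.8
      # of near-round singlets; the area cap only removes gross aggregates
      amax <- 1.5 * quantile(tbl$cell_area[pass], 0.995, na.rm = TRUE, names = FALSE)
      poly <- data.frame(area = c(0, amax, amax, 0),
                         aspect_ratio = c(0.8, 0.8, 1.01, 1.01))
    }
    ok <- points_in_polygon(tbl$cell_area, tbl$cell_aspect_ratio,
                            poly[, c("area", "aspect_ratio")])
    tbl$gate_singlet <- flag(ok)
    report$singlet <- list(removed = sum(pass & !ok, na.rm = TRUE),
                           polygon = poly)
    pass <- pass & !is.na(ok) & ok
  }
  for (gname in names(gates$extra)) {
    g <- gates$extra[[gname]]
    assert_columns(tbl, g$features, paste0("gate '", gname, "'"))
    ok <- points_in_polygon(tbl[[g$features[1]]], tbl[[g$features[2]]], g$polygon)
    tbl[[paste0("gate_", gname)]] <- flag(ok)
    report[[gname]] <- list(removed = sum(pass & !ok, na.rm = TRUE))
    pass <- pass & !is.na(ok) & ok
  }
  # retained events must have a complete feature row (no NaN after gating)
  feats <- feature_columns(tbl)
  complete <- !apply(is.na(tbl[, feats, drop = FALSE]), 1, any)
  tbl$gate_complete <- flag(complete)
  report$complete <- list(removed = sum(pass & !complete, na.rm = TRUE))
  pass <- pass & complete
  out <- if (keep_all) tbl else tbl[pass, , drop = FALSE]
  attr(out, "gate_report") <- report
  out
}
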