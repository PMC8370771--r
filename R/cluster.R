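as_point_matrix <- function(points) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("points contain missing values")
  X
}

# kNN with duplicate-distance flooring; shared by density and clustering
knn_with_floor <- function(X, kmax) {
  nn <- knn_brute_cpp(X, kmax)
  rk_all <- nn$dist
  if (any(rk_all == 0)) {
    scale <- mean(rk_all[rk_all > 0])
    if (!is.finite(scale) || scale == 0) scale <- 1
    warning("duplicate points: k-th neighbour distances of 0 floored at ",
            "machine epsilon times the mean neighbour distance")
    nn$dist[nn$dist == 0] <- .Machine$double.eps * scale
  }
  nn
}

#' k-nearest-neighbour density estimate
#'
#' The standard kNN density estimator under Euclidean distance:
#' `density(i) = k / (n * V_d * r_k(i)^d)` with `r_k(i)` the distance to
#' the k-th nearest neighbour and `V_d` the d-dimensional unit-ball volume.
#' Exact duplicates (`r_k = 0`) are floored at machine epsilon times the
#' mean neighbour distance, with a warning.
#'
#' @param points numeric matrix or data frame of scaled features.
#' @param k number of neighbours (1 <= k < n).
#' @return numeric density per point. In high dimension the absolute values
#'   can under- or overflow; their ordering (all that mode seeking needs)
#'   is still carried by `r_k`.
#' @export
knn_density <- function(points, k) {
  X <- as_point_matrix(points)
  n <- nrow(X); d <- ncol(X)
  if (k < 1 || k >= n) stop("need 1 <= k < n")
  nn <- knn_with_floor(X, k)
  rk <- nn$dist[, k]
  vd <- pi^(d / 2) / gamma(d / 2 + 1)
  k / (n * vd * rk^d)
}

#' X-Shift-style density-ascent clustering
#'
#' Each point holds a directed pointer to the highest-density point among
#' its k nearest neighbours (itself included); points that point to
#' themselves are modes, and every point's cluster is the mode reached by
#' following pointers. Density ties are broken by point index, which makes
#' the pointer graph acyclic and the result deterministic. Cluster ids are
#' relabelled by decreasing cluster size.
#'
#' After the ascent, spurious modes (kNN density estimates fluctuate, so a
#' large cluster fragments when k is much smaller than its population) are
#' consolidated: each mode merges into its nearest denser mode unless the
#' density along the straight segment between them dips below both endpoint
#' densities — a deterministic, threshold-free valley test.
#'
#' @param points numeric matrix or data frame of scaled features.
#' @param k neighbourhood size; larger k merges modes and yields fewer
#'   clusters.
#' @param merge_modes apply the density-valley mode consolidation.
#' @return integer cluster ids (1 = largest); attributes `modes` (row
#'   indices of the density modes) and `pointer` (the ascent pointers).
#' @export
xshift_cluster <- function(points, k, merge_modes = TRUE) {
  X <- as_point_matrix(points)
  n <- nrow(X)
  if (k < 1 || k >= n) stop("need 1 <= k < n")
  nn <- knn_with_floor(X, k)
  assign_clusters(X, nn, k, merge_modes)
}

assign_clusters <- function(X, nn, k, merge_modes = TRUE) {
  rk <- nn$dist[, k]
  res <- xshift_assign_cpp(nn$idx[, seq_len(k), drop = FALSE], rk, k)
  root <- res$root
  if (merge_modes && k < nrow(X))
    root <- valley_merge_cpp(X, root, rk, k, 10L)
  sizes <- table(root)
  ord <- order(-as.numeric(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  ids <- as.integer(relabel[as.character(root)])
  attr(ids, "modes") <- sort(unique(root))
  attr(ids, "pointer") <- res$pointer
  ids
}

#' Choose k by the elbow of the cluster-count curve
#'
#' Clusters over a grid of k values and picks the elbow of the
#' (k, number-of-clusters) curve: the point with maximum distance from the
#' straight line joining the curve's endpoints in log-log space (a
#' kneedle-style rule). The curve is returned so that over- or
#' under-clustering can be confirmed visually.
#'
#' @param points numeric matrix or data frame of scaled features.
#' @param k_grid increasing grid of k values, length >= 4.
#' @return an `image3c_elbow` list: `k` (chosen), `curve`
#'   (tibble k, n_clusters, distance), and the reused neighbour index so a
#'   final clustering at `k` is free.
#' @export
elbow_select_k <- function(points, k_grid = seq(5L, 150L, by = 5L)) {
  X <- as_point_matrix(points)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) < 4) stop("k_grid must have at least 4 values")
  if (max(k_grid) >= nrow(X)) stop("largest k must be < number of points")
  nn <- knn_with_floor(X, max(k_grid))
  ncl <- vapply(k_grid, function(k) max(assign_clusters(X, nn, k)), integer(1))
  kp <- kneedle_point(log(k_grid), log(ncl))
  if (is.null(kp)) {
    warning("cluster-count curve has no elbow; returning the smallest k ",
            "with a stable count")
    k_star <- k_grid[min(which(ncl == ncl[length(ncl)]))]
    dist <- rep(0, length(k_grid))
  } else {
    k_star <- k_grid[kp$index]
    dist <- kp$distance
  }
  structure(list(k = k_star,
                 curve = tibble(k = k_grid, n_clusters = ncl, distance = dist),
                 nn = nn),
            class = "image3c_elbow")
}

# index of the point with maximum distance from the chord joining the
# curve's endpoints; NULL when the curve is degenerate (no bend)
kneedle_point <- function(x, y) {
  seg <- c(tail(x, 1) - x[1], tail(y, 1) - y[1])
  len <- sqrt(sum(seg^2))
  dist <- if (len == 0) rep(0, length(x)) else
    abs(seg[2] * (x - x[1]) - seg[1] * (y - y[1])) / len
  if (all(dist < 1e-12)) return(NULL)
  list(index = which.max(dist), distance = dist)
}

#' @method autoplot image3c_elbow
#' @export
autoplot.image3c_elbow <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$n_clusters)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "k (nearest neighbours)", y = "number of clusters",
                  title = paste0("elbow at k = ", object$k)) +
    ggplot2::theme_minimal()
}

#' Force-directed layout of the kNN graph
#'
#' Subsamples up to `cap` events per cluster, builds the symmetric kNN
#' graph (union of directed edges, weight 1/(1+distance)) and lays it out
#' with the Fruchterman-Reingold algorithm under a fixed seed. Disconnected
#' graphs are laid out component by component, side by side.
#'
#' @param points scaled feature matrix.
#' @param clusters integer cluster ids per row of `points`.
#' @param cap maximum events per cluster in the layout (`Inf` for all).
#' @param knn_k neighbours per event in the graph.
#' @param seed layout seed; identical seeds give identical coordinates.
#' @return an `image3c_fdl` list: `coords` (tibble row, cluster, x, y),
#'   `edges` (tibble from, to, weight; indices into the original rows) and
#'   the igraph object.
#' @export
build_fdl <- function(points, clusters, cap = 200L, knn_k = 10L, seed = 1L) {
  X <- as_point_matrix(points)
  stopifnot(length(clusters) == nrow(X))
  keep <- with_local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(X)), clusters), function(ix)
      if (length(ix) > cap) sort(sample(ix, cap)) else ix), use.names = FALSE)
  })
  keep <- sort(keep)
  Xs <- X[keep, , drop = FALSE]
  kk <- min(knn_k, nrow(Xs) - 1L)
  nn <- knn_brute_cpp(Xs, kk)
  edges <- tibble(from = rep(seq_len(nrow(Xs)), kk),
                  to = as.vector(nn$idx),
                  weight = 1 / (1 + as.vector(nn$dist)))
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = seq_len(nrow(Xs))))
  coords <- with_local_seed(seed, {
    if (igraph::is_connected(g)) {
      igraph::layout_with_fr(g, niter = 500, weights = igraph::E(g)$weight)
    } else {
      warning("kNN graph is disconnected; components laid out side by side")
      igraph::layout_components(g, layout = igraph::layout_with_fr)
    }
  })
  structure(list(
    coords = tibble(row = keep, cluster = clusters[keep],
                    x = coords[, 1], y = coords[, 2]),
    edges = tibble(from = keep[edges$from], to = keep[edges$to],
                   weight = edges$weight),
    graph = g), class = "image3c_fdl")
}

#' Write a force-directed layout's graph as graphML
#'
#' @param fdl an `image3c_fdl` from [build_fdl()].
#' @param path output file.
#' @export
write_graphml <- function(fdl, path) {
  g <- fdl$graph
  igraph::V(g)$x <- fdl$coords$x
  igraph::V(g)$y <- fdl$coords$y
  igraph::V(g)$cluster <- fdl$coords$cluster
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Per-cluster feature means and count matrix
#'
#' @param table clustered event tibble (must carry `cluster_id` and
#'   `sample_id`).
#' @param features feature columns to average; default as in
#'   [spearman_trim()].
#' @return list: `feature_means` (tibble, one row per cluster),
#'   `counts` (long tibble cluster, sample, count with explicit zeros) and
#'   `abundances` (per-sample relative abundances).
#' @export
summarize_clusters <- function(table, features = NULL) {
  assert_columns(table, c("cluster_id", "sample_id"))
  features <- features %||% feature_columns(table)
  means <- table |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(features), mean),
                     .groups = "drop")
  counts <- table |>
    dplyr::count(.data$cluster_id, .data$sample_id, name = "count") |>
    tidyr::complete(.data$cluster_id, .data$sample_id,
                    fill = list(count = 0L))
  abund <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(abundance = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  list(feature_means = means, counts = counts, abundances = abund)
}

#' Cluster an event table end to end
#'
#' Runs elbow-based selection of k (unless `k` is given), the final
#' density-ascent clustering, per-cluster summaries and (optionally) the
#' force-directed layout, and returns everything as one result object.
#'
#' @param table preprocessed event tibble (features scaled to unit SD).
#' @param features feature columns used as clustering space; default as in
#'   [spearman_trim()].
#' @param k fixed neighbourhood size; default: chosen by
#'   [elbow_select_k()] over `k_grid`.
#' @param k_grid grid for the elbow search.
#' @param fdl compute the force-directed layout.
#' @param fdl_cap,fdl_knn_k,seed layout parameters, see [build_fdl()].
#' @return an `image3c_clusters` object; see [tidy.image3c_clusters()],
#'   [glance.image3c_clusters()] and [autoplot.image3c_clusters()].
#' @export
cluster_events <- function(table, features = NULL, k = NULL,
                           k_grid = seq(5L, 150L, by = 5L), fdl = TRUE,
                           fdl_cap = 200L, fdl_knn_k = 10L, seed = 1L) {
  features <- features %||% feature_columns(table)
  X <- as_point_matrix(table[, features, drop = FALSE])
  elbow <- NULL
  if (is.null(k)) {
    elbow <- elbow_select_k(X, k_grid)
    k <- elbow$k
    ids <- assign_clusters(X, elbow$nn, k)
    elbow$nn <- NULL   # drop the big neighbour matrices from the result
  } else {
    ids <- xshift_cluster(X, k)
  }
  table$cluster_id <- as.integer(ids)
  summ <- summarize_clusters(table, features)
  layout <- if (isTRUE(fdl))
    build_fdl(X, table$cluster_id, cap = fdl_cap, knn_k = fdl_knn_k, seed = seed)
  structure(list(table = table, features = features, k_used = k,
                 elbow = elbow, feature_means = summ$feature_means,
                 counts = summ$counts, abundances = summ$abundances,
                 fdl = layout),
            class = "image3c_clusters")
}

#' @export
print.image3c_clusters <- function(x, ...) {
  cat("<image3c_clusters> ", nrow(x$table), " events, ",
      max(x$table$cluster_id), " clusters (k = ", x$k_used, ")\n", sep = "")
  invisible(x)
}

#' Tidy a clustering result into its per-event assignment table
#' @param x an `image3c_clusters` object.
#' @param ... unused.
#' @method tidy image3c_clusters
#' @export
tidy.image3c_clusters <- function(x, ...) {
  out <- x$table[, c("event_id", "sample_id", "cluster_id")]
  if (!is.null(x$fdl)) {
    xy <- tibble(row = x$fdl$coords$row, fdl_x = x$fdl$coords$x,
                 fdl_y = x$fdl$coords$y)
    out$row <- seq_len(nrow(out))
    out <- dplyr::left_join(out, xy, by = "row")
    out$row <- NULL
  }
  out
}

#' One-row summary of a clustering result
#' @param x an `image3c_clusters` object.
#' @param ... unused.
#' @method glance image3c_clusters
#' @export
glance.image3c_clusters <- function(x, ...) {
  tibble(n_events = nrow(x$table), n_clusters = max(x$table$cluster_id),
         k_used = x$k_used, n_samples = length(unique(x$table$sample_id)))
}

#' Plot the force-directed layout coloured by cluster
#' @param object an `image3c_clusters` object with a layout.
#' @param ... unused.
#' @method autoplot image3c_clusters
#' @export
autoplot.image3c_clusters <- function(object, ...) {
  if (is.null(object$fdl)) stop("result has no force-directed layout")
  ggplot2::ggplot(object$fdl$coords,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "cluster", x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::guides(colour = ggplot2::guide_legend(
      override.aes = list(size = 3)))
}
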