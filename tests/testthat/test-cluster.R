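test_that("kNN density matches its closed form in one dimension", {
  # two points at distance 1: density = k / (n * V_1 * r^1) with V_1 = 2
  X <- matrix(c(0, 1), ncol = 1)
  expect_equal(knn_density(X, 1), c(0.25, 0.25))

  # interior of a uniform grid is flat; the boundary is less dense
  X <- matrix(seq(0, 1, length.out = 101), ncol = 1)
  d <- knn_density(X, 4)
  interior <- d[20:80]
  expect_lt(diff(range(interior)) / mean(interior), 1e-9)
  expect_lt(d[1], mean(interior))
})

test_that("kNN density rank-agrees with the brute-force oracle", {
  withr::with_seed(31, {
    X <- matrix(rnorm(200 * 3), 200)
    d_fast <- knn_density(X, 10)
    d_slow <- oracle_knn_density(X, 10)
    expect_equal(cor(d_fast, d_slow, method = "spearman"), 1)
    expect_equal(d_fast, d_slow, tolerance = 1e-9)
  })
})

test_that("duplicate points are floored with a warning", {
  X <- matrix(c(0, 0, 0, 0, 5, 5), ncol = 2, byrow = TRUE)
  expect_warning(d <- knn_density(X, 1), "duplicate")
  expect_true(all(is.finite(d)))
})

test_that("density ascent separates well-separated blobs", {
  withr::with_seed(41, {
    X <- rbind(matrix(rnorm(500 * 2), ncol = 2),
               matrix(rnorm(500 * 2, mean = 10), ncol = 2))
    truth <- rep(1:2, each = 500)
    ids <- xshift_cluster(X, 30)
    expect_equal(max(ids), 2)
    expect_gte(mclust::adjustedRandIndex(ids, truth), 0.99)
  })
})

test_that("a unimodal blob collapses to one cluster at k = n - 1", {
  withr::with_seed(42, {
    X <- matrix(rnorm(150 * 2), ncol = 2)
    ids <- xshift_cluster(X, 149)
    expect_equal(max(ids), 1)
  })
})

test_that("ascent pointers are acyclic and end at modes", {
  for (s in 1:100) {
    X <- withr::with_seed(s, matrix(rnorm(80 * 2), ncol = 2))
    ids <- xshift_cluster(X, 8, merge_modes = FALSE)
    ptr <- attr(ids, "pointer")
    modes <- attr(ids, "modes")
    for (i in seq_len(nrow(X))) {
      seen <- integer()
      j <- i
      while (ptr[j] != j) {
        expect_false(j %in% seen)   # a revisit would mean a cycle
        seen <- c(seen, j)
        j <- ptr[j]
        expect_lte(length(seen), nrow(X))
      }
      expect_true(j %in% modes)
    }
  }
})

test_that("cluster labels are invariant to event order", {
  withr::with_seed(43, {
    X <- rbind(matrix(rnorm(200 * 2), ncol = 2),
               matrix(rnorm(200 * 2, 8), ncol = 2))
    ids <- xshift_cluster(X, 20)
    perm <- sample(nrow(X))
    ids_p <- xshift_cluster(X[perm, ], 20)
    expect_equal(mclust::adjustedRandIndex(ids[perm], ids_p), 1)
  })
})

test_that("cluster count decreases with k on average", {
  withr::with_seed(44, {
    X <- matrix(rnorm(600 * 3), ncol = 3)
    el <- elbow_select_k(X, k_grid = seq(5, 60, 5))
    expect_lt(cor(el$curve$k, el$curve$n_clusters, method = "spearman"), 0)
  })
})

test_that("the kneedle rule finds the joint of two line segments", {
  x <- 1:11
  y <- c(seq(10, 2, length.out = 5), seq(2, 1.4, length.out = 7)[-1])
  kp <- image3c:::kneedle_point(x, y)
  expect_equal(kp$index, 5)
  expect_null(image3c:::kneedle_point(1:5, rep(2, 5)))
})

test_that("the elbow recovers four well-separated blobs, one for a blob", {
  withr::with_seed(45, {
    ctr <- rbind(c(0, 0), c(12, 0), c(0, 12), c(12, 12))
    X <- do.call(rbind, lapply(1:4, function(i)
      sweep(matrix(rnorm(250 * 2), ncol = 2), 2, ctr[i, ], "+")))
    el <- elbow_select_k(X, k_grid = seq(5, 100, 5))
    expect_equal(el$curve$n_clusters[el$curve$k == el$k], 4L)
  })
  ones <- 0
  for (s in 1:20) {
    X <- withr::with_seed(300 + s, matrix(rnorm(300 * 2), ncol = 2))
    el <- suppressWarnings(elbow_select_k(X, k_grid = seq(5, 100, 5)))
    n_at_k <- el$curve$n_clusters[el$curve$k == el$k]
    if (n_at_k == 1) ones <- ones + 1
  }
  expect_gte(ones, 18)
})

test_that("the force-directed layout is deterministic and complete", {
  withr::with_seed(46, {
    X <- rbind(matrix(rnorm(60 * 2), ncol = 2),
               matrix(rnorm(40 * 2, 7), ncol = 2))
    ids <- xshift_cluster(X, 10)
    a <- build_fdl(X, ids, cap = Inf, seed = 5)
    b <- build_fdl(X, ids, cap = Inf, seed = 5)
    expect_equal(a$coords, b$coords)
    expect_equal(nrow(a$coords), 100)     # cap = all: every event laid out
    expect_true(all(is.finite(a$coords$x)))
  })
})

test_that("disconnected graphs are laid out component-wise without overlap", {
  withr::with_seed(47, {
    X <- rbind(matrix(rnorm(50 * 2, sd = 0.3), ncol = 2),
               matrix(rnorm(50 * 2, mean = 100, sd = 0.3), ncol = 2))
    ids <- rep(1:2, each = 50)
    expect_warning(fdl <- build_fdl(X, ids, cap = Inf, knn_k = 5, seed = 2),
                   "disconnected")
    h1 <- fdl$coords[fdl$coords$cluster == 1, c("x", "y")]
    h2 <- fdl$coords[fdl$coords$cluster == 2, c("x", "y")]
    # convex hulls of the two components must not intersect
    hull <- as.matrix(h1[chull(h1$x, h1$y), ])
    inside <- image3c:::points_in_polygon(h2$x, h2$y, as.data.frame(hull))
    expect_false(any(inside))
  })
})

test_that("graphML export writes a readable graph with coordinates", {
  withr::with_seed(48, {
    X <- matrix(rnorm(80 * 2), ncol = 2)
    ids <- xshift_cluster(X, 10)
    fdl <- build_fdl(X, ids, cap = Inf, seed = 1)
    f <- withr::local_tempfile(fileext = ".graphml")
    write_graphml(fdl, f)
    g <- igraph::read_graph(f, format = "graphml")
    expect_equal(igraph::vcount(g), 80)
    expect_true("x" %in% igraph::vertex_attr_names(g))
  })
})

test_that("cluster summaries match a hand-computed toy table", {
  toy <- tibble::tibble(
    event_id = as.character(1:6),
    sample_id = c("a", "a", "b", "b", "a", "b"),
    cluster_id = c(1L, 1L, 1L, 2L, 2L, 2L),
    f1 = c(1, 2, 3, 4, 5, 6), f2 = c(10, 20, 30, 40, 50, 60))
  s <- summarize_clusters(toy, features = c("f1", "f2"))
  expect_equal(s$feature_means$f1, c(2, 5))      # (1+2+3)/3, (4+5+6)/3
  expect_equal(s$feature_means$f2, c(20, 50))
  cnt <- s$counts
  expect_equal(sum(cnt$count), 6)
  expect_equal(cnt$count[cnt$cluster_id == 1 & cnt$sample_id == "a"], 2L)
  expect_equal(cnt$count[cnt$cluster_id == 2 & cnt$sample_id == "a"], 1L)
  ab <- s$abundances
  expect_equal(ab$abundance[ab$cluster_id == 1 & ab$sample_id == "b"], 1 / 3)

  one <- toy
  one$cluster_id <- 1L
  s1 <- summarize_clusters(one, features = c("f1", "f2"))
  expect_equal(s1$feature_means$f1, mean(toy$f1))
})

test_that("cluster_events returns a coherent tidy result", {
  withr::with_seed(49, {
    tbl <- tibble::tibble(
      event_id = as.character(1:300),
      sample_id = rep(c("a", "b", "c"), 100),
      f1 = c(rnorm(150), rnorm(150, 9)),
      f2 = c(rnorm(150), rnorm(150, 9)))
    res <- cluster_events(tbl, k_grid = seq(5, 50, 5), seed = 1, fdl_cap = 50)
    expect_s3_class(res, "image3c_clusters")
    expect_equal(glance(res)$n_clusters, 2L)
    td <- tidy(res)
    expect_equal(nrow(td), 300)
    expect_equal(sum(res$counts$count), 300)
    expect_equal(sum(!is.na(td$fdl_x)), nrow(res$fdl$coords))
    expect_s3_class(autoplot(res), "ggplot")
    expect_s3_class(autoplot(res$elbow), "ggplot")
  })
})
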