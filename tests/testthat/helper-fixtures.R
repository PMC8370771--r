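# Shared fixtures, built in code. The heavier ones are cached per test run.

local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = local_cache)) assign(key, expr, envir = local_cache)
  get(key, envir = local_cache)
}

# one mid-sized segmented-and-corrected event of a given population
fixture_event <- function(pop = demo_populations()[[4]], seed = 101) {
  ev <- render_cell_image(pop, seed = seed)
  subtract_background(segment_masks(ev))
}

# small multi-sample feature table with truth, cached (used by several files)
fixture_small_experiment <- function() {
  cached("small_experiment", {
    pops <- demo_populations()
    specs <- lapply(1:4, function(s)
      sample_spec(sprintf("s%02d", s), n_events = 150, populations = pops,
                  seed = 400 + s))
    simulate_feature_table(specs)
  })
}

# synthetic (non-image) feature table: cheap stand-in for table-level ops
fixture_feature_table <- function(n = 300, n_samples = 4, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_samples), function(s) {
      tibble::tibble(
        event_id = sprintf("s%d_e%d", s, seq_len(n)),
        sample_id = sprintf("s%02d", s),
        f_size = rnorm(n, 10), f_shape = runif(n), f_bright = rexp(n),
        f_texture = rnorm(n, 5, 2))
    }))
  })
}

# brute-force kNN density oracle: full distance matrix, no shared code path
oracle_knn_density <- function(X, k) {
  D <- as.matrix(dist(X))
  n <- nrow(X); d <- ncol(X)
  rk <- apply(D, 1, function(r) sort(r[-which.min(r)])[k])
  # which.min removes one zero (self); duplicates keep their zero distances
  rk <- pmax(rk, .Machine$double.eps)
  vd <- pi^(d / 2) / gamma(d / 2 + 1)
  unname(k / (n * vd * rk^d))
}

# exhaustive trimming oracle: rescan all pairs until stable
oracle_trim <- function(rho, threshold) {
  p <- nrow(rho)
  kept <- rep(TRUE, p)
  repeat {
    changed <- FALSE
    for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
      if (kept[i] && kept[j] && !is.na(rho[i, j]) && abs(rho[i, j]) >= threshold) {
        kept[j] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  kept
}

# two-condition count table where condition B counts are an exact multiple
fixture_ratio_counts <- function(ratio = 2, n_clusters = 4, base = 1000,
                                 total = 50000) {
  rows <- list()
  for (cond in c("A", "B")) for (s in 1:2) {
    cnt <- rep(base, n_clusters) * if (cond == "B") ratio else 1
    filler <- total - sum(cnt)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cluster = c(sprintf("c%d", seq_len(n_clusters)), "rest"),
      sample = paste0(cond, s), condition = cond,
      count = as.integer(c(cnt, filler)))
  }
  dplyr::bind_rows(rows)
}
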