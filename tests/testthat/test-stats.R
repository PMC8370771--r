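test_that("Poisson counts yield a near-zero common dispersion", {
  cm <- simulate_count_matrix(20, n_per_condition = 6, dispersion = 0, seed = 1)
  expect_lte(estimate_common_dispersion(cm), 0.01)
})

test_that("the common dispersion is recovered from NB simulations", {
  phis <- vapply(1:200, function(i) {
    cm <- simulate_count_matrix(20, n_per_condition = 6, dispersion = 0.3,
                                seed = 5000 + i)
    estimate_common_dispersion(cm)
  }, numeric(1))
  expect_gte(median(phis), 0.2)
  expect_lte(median(phis), 0.4)
})

test_that("degenerate count tables are handled gracefully", {
  cm <- simulate_count_matrix(5, n_per_condition = 2, dispersion = 0.1, seed = 3)
  cm$count <- rep(cm$count[1:5], 4)         # two identical samples per arm
  phi <- estimate_common_dispersion(cm)
  expect_true(is.finite(phi) && phi >= 0)
  cm$count <- 0L
  expect_error(estimate_common_dispersion(cm), "zero")
})

test_that("an exact two-fold change estimates logFC 1", {
  counts <- fixture_ratio_counts(ratio = 2)
  d <- nb_test(counts, dispersion = 1e-8)
  measured <- d$logFC[d$cluster != "rest"]
  expect_true(all(abs(measured - 1) < 0.05))
})

test_that("the likelihood-ratio statistic matches a grid-search oracle", {
  counts <- tibble::tibble(
    cluster = "c1",
    sample = c("A1", "A2", "B1", "B2"),
    condition = c("A", "A", "B", "B"),
    count = c(37L, 45L, 81L, 70L))
  totals <- c(1000, 1100, 950, 1050)
  full <- dplyr::bind_rows(counts, tibble::tibble(
    cluster = "rest", sample = counts$sample, condition = counts$condition,
    count = as.integer(totals - counts$count)))
  phi <- 0.05
  d <- nb_test(full, dispersion = phi)

  nb_ll <- function(y, mu) sum(lgamma(y + 1 / phi) - lgamma(1 / phi) -
                                 lgamma(y + 1) + y * log(phi * mu) -
                                 (y + 1 / phi) * log1p(phi * mu))
  grid <- exp(seq(log(1e-4), log(0.5), length.out = 4000))
  ll_null <- max(vapply(grid, function(l) nb_ll(counts$count, l * totals),
                        numeric(1)))
  ll_alt <- max(vapply(grid, function(l) nb_ll(counts$count[1:2], l * totals[1:2]),
                       numeric(1))) +
            max(vapply(grid, function(l) nb_ll(counts$count[3:4], l * totals[3:4]),
                       numeric(1)))
  lrt_oracle <- 2 * (ll_alt - ll_null)
  lrt_mine <- qchisq(d$p_value[d$cluster == "c1"], 1, lower.tail = FALSE)
  expect_lt(abs(lrt_mine - lrt_oracle), 1e-4)
})

test_that("the NB fit agrees with glm + negative.binomial at fixed phi", {
  phi <- 0.2
  cm <- simulate_count_matrix(5, n_per_condition = 4,
                              effect_log2 = c(1.5, 0, 0, 0, 0),
                              dispersion = phi, seed = 9)
  d <- nb_test(cm, dispersion = phi)
  tot <- tapply(cm$count, cm$sample, sum)
  for (cl in unique(cm$cluster)) {
    sub <- as.data.frame(cm[cm$cluster == cl, ])
    sub$off <- log(tot[sub$sample])
    f1 <- suppressWarnings(stats::glm(count ~ condition + offset(off),
                                      family = MASS::negative.binomial(1 / phi),
                                      data = sub))
    expect_lt(abs(d$logFC[d$cluster == cl] -
                    unname(stats::coef(f1)[2]) / log(2)), 1e-3)
  }
})

test_that("swapping condition labels negates logFC and keeps p-values", {
  cm <- simulate_count_matrix(12, n_per_condition = 5,
                              effect_log2 = c(rep(0, 10), 1, -1),
                              dispersion = 0.1, seed = 13)
  d1 <- nb_test(cm, dispersion = 0.1)
  cm2 <- cm
  cm2$condition <- ifelse(cm$condition == "A", "Z", "A")  # reverses the order
  d2 <- nb_test(cm2, dispersion = 0.1)
  expect_equal(d1$logFC, -d2$logFC, tolerance = 1e-9)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-9)
})

test_that("doubling counts and totals leaves logFC unchanged", {
  cm <- simulate_count_matrix(8, n_per_condition = 4,
                              effect_log2 = c(1, rep(0, 7)),
                              dispersion = 0.05, seed = 17)
  d1 <- nb_test(cm, dispersion = 1e-9)
  cm2 <- cm
  cm2$count <- cm$count * 2L
  d2 <- nb_test(cm2, dispersion = 1e-9)
  expect_equal(d1$logFC, d2$logFC, tolerance = 1e-6)
  # at finite dispersion the NB weights break exact scale equivariance,
  # but only marginally
  d3 <- nb_test(cm, dispersion = 0.05)
  d4 <- nb_test(cm2, dispersion = 0.05)
  expect_equal(d3$logFC, d4$logFC, tolerance = 1e-3)
})

test_that("all-zero clusters are flagged with p = 1", {
  cm <- simulate_count_matrix(4, n_per_condition = 3, dispersion = 0.1, seed = 19)
  cm$count[cm$cluster == "c02"] <- 0L
  d <- nb_test(cm, dispersion = 0.1)
  expect_true(d$flagged[d$cluster == "c02"])
  expect_equal(d$p_value[d$cluster == "c02"], 1)
  expect_equal(d$logFC[d$cluster == "c02"], 0)
})

test_that("BH adjustment matches hand computation and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1|between")
})

test_that("one-way ANOVA behaves classically", {
  # literally identical groups: no between-group variance at all
  ab <- tibble::tibble(cluster = "c1", sample = paste0("s", 1:6),
                       group = rep(c("f", "m"), each = 3),
                       abundance = rep(c(0.1, 0.12, 0.11), 2))
  res <- anova_bh(ab)
  expect_lt(res$statistic, 1e-20)
  expect_gt(res$p_value, 0.999)

  # two groups: F equals the square of the pooled-variance t statistic
  withr::with_seed(23, {
    ab2 <- tibble::tibble(cluster = "c1", sample = paste0("s", 1:10),
                          group = rep(c("f", "m"), each = 5),
                          abundance = c(rnorm(5, 0.2, 0.02), rnorm(5, 0.25, 0.02)))
    res2 <- anova_bh(ab2)
    tt <- t.test(abundance ~ group, data = ab2, var.equal = TRUE)
    expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res2$p_value, tt$p.value, tolerance = 1e-9)
  })
})

test_that("ANOVA power tracks the noncentral-F prediction", {
  n <- 6; delta <- 0.03; sdv <- 0.02
  ncp <- n * delta^2 / 2 / sdv^2   # two groups at +/- delta/2
  predicted <- 1 - pf(qf(0.95, 1, 2 * n - 2), 1, 2 * n - 2, ncp)
  hits <- vapply(1:400, function(i) {
    withr::with_seed(3000 + i, {
      ab <- tibble::tibble(cluster = "c1", sample = paste0("s", 1:(2 * n)),
                           group = rep(c("f", "m"), each = n),
                           abundance = c(rnorm(n, 0.2, sdv),
                                         rnorm(n, 0.2 + delta, sdv)))
      anova_bh(ab)$p_value <= 0.05
    })
  }, logical(1))
  expect_lt(abs(mean(hits) - predicted), 0.07)
})

test_that("volcano export is faithful, capped, and round-trips", {
  cm <- simulate_count_matrix(3, n_per_condition = 3, dispersion = 0.1, seed = 29)
  d <- nb_test(cm, dispersion = 0.1)
  v <- volcano_export(d)
  expect_equal(v$logFC, d$logFC)
  expect_equal(v$neg_log10_fdr, pmin(-log10(d$fdr), 10))
  d0 <- d
  d0$fdr[1] <- 0
  expect_equal(volcano_export(d0, cap = 8)$neg_log10_fdr[1], 8)
  f <- withr::local_tempfile(fileext = ".csv")
  volcano_export(d, path = f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$logFC, v$logFC, tolerance = 1e-12)
  expect_s3_class(autoplot(d), "ggplot")
  expect_gte(min(tidy(d)$fdr - tidy(d)$p_value), 0)
  expect_equal(glance(d)$dispersion, 0.1)
})
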