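test_that("rendering is a pure function of population and seed", {
  pop <- demo_populations()[[2]]
  a <- render_cell_image(pop, seed = 5)
  b <- render_cell_image(pop, seed = 5)
  expect_identical(a$channels, b$channels)
  expect_identical(a$masks, b$masks)
  c <- render_cell_image(pop, seed = 6)
  expect_false(identical(a$channels$BF, c$channels$BF))
})

test_that("zero granularity gives a silent side-scatter channel", {
  pop <- population_spec("quiet", 1, cell_diameter = 14, granularity = 0)
  ev <- render_cell_image(pop, seed = 2)
  expect_identical(sum(ev$channels$SSC[ev$masks$cell]), 0)
})

test_that("near-unit nuclear/cell ratio fills the cell with nucleus", {
  pop <- population_spec("full", 1, cell_diameter = 16, nc_ratio = 0.99,
                         nc_ratio_sd = 0)
  ev <- render_cell_image(pop, seed = 3)
  expect_gte(sum(ev$masks$nucleus) / sum(ev$masks$cell), 0.95)
})

test_that("cells that do not fit the frame are rejected", {
  pop <- population_spec("huge", 1, cell_diameter = 80, cell_diameter_sd = 0)
  expect_error(render_cell_image(pop, seed = 1, frame = 64), "does not fit")
})

test_that("population frequencies are respected within binomial bounds", {
  pops <- list(population_spec("a", 0.7, cell_diameter = 12),
               population_spec("b", 0.3, cell_diameter = 18))
  spec <- sample_spec("s1", n_events = 4000, populations = pops, seed = 21)
  sim <- simulate_sample(spec)
  n_a <- sum(sim$truth$population == "a")
  ci <- qbinom(c(0.005, 0.995), 4000, 0.7)
  expect_gte(n_a, ci[1])
  expect_lte(n_a, ci[2])
})

test_that("intensity drift scales the nuclear signal multiplicatively", {
  pops <- demo_populations()
  base <- sample_spec("s1", n_events = 60, populations = pops, seed = 31)
  drift <- sample_spec("s1", n_events = 60, populations = pops, seed = 31,
                       intensity_drift = c(DNA = 2))
  s0 <- simulate_sample(base)
  s2 <- simulate_sample(drift)
  tot <- function(sim) vapply(sim$events, function(e)
    sum(e$channels$DNA), numeric(1))
  ratio <- median(tot(s2)) / median(tot(s0))
  expect_gte(ratio, 1.9)
  expect_lte(ratio, 2.1)
})

test_that("identity spillover leaves stacks bit-identical", {
  pops <- demo_populations()
  spec <- sample_spec("s1", n_events = 10, populations = pops, seed = 41)
  eye <- spillover_matrix(diag(3) |>
                            `dimnames<-`(list(c("SSC", "DNA", "FL1"),
                                              c("SSC", "DNA", "FL1"))))
  plain <- simulate_sample(spec)
  mixed <- simulate_sample(spec, spillover = eye)
  expect_identical(plain$events[[4]]$channels, mixed$events[[4]]$channels)
})

test_that("spillover then compensation round-trips the true stack", {
  S <- spillover_matrix(matrix(c(1, 0.15, 0.05,
                                 0.08, 1, 0.1,
                                 0.02, 0.12, 1), 3, byrow = TRUE,
                               dimnames = list(c("SSC", "DNA", "FL1"),
                                               c("SSC", "DNA", "FL1"))))
  pops <- demo_populations()
  spec <- sample_spec("s1", n_events = 8, populations = pops, seed = 51)
  plain <- simulate_sample(spec)
  mixed <- simulate_sample(spec, spillover = S)
  for (i in seq_along(plain$events)) {
    rec <- compensate(mixed$events[[i]], S)
    for (ch in c("SSC", "DNA", "FL1")) {
      scale <- max(plain$events[[i]]$channels[[ch]], 1)
      expect_lt(max(abs(rec$channels[[ch]] - plain$events[[i]]$channels[[ch]])) / scale,
                1e-6)
    }
  }
})

test_that("doublets and debris carry ground-truth flags and structure", {
  pops <- demo_populations()
  spec <- sample_spec("s1", n_events = 300, populations = pops, seed = 61,
                      doublet_rate = 0.15, debris_rate = 0.1)
  sim <- simulate_sample(spec)
  expect_gt(sum(sim$truth$is_doublet), 15)
  expect_gt(sum(sim$truth$is_debris), 10)
  deb <- sim$events[[which(sim$truth$is_debris)[1]]]
  expect_identical(sum(deb$channels$DNA), 0)        # no nuclear signal
  dbl <- sim$events[[which(sim$truth$is_doublet)[1]]]
  med_single <- median(vapply(sim$events[!sim$truth$is_doublet & !sim$truth$is_debris],
                              function(e) sum(e$masks$cell), numeric(1)))
  expect_gt(sum(dbl$masks$cell), med_single)        # merged mask is larger
})

test_that("sample specs validate their invariants", {
  pops <- demo_populations()
  bad <- pops
  bad[[1]]$frequency <- 0.5
  expect_error(sample_spec("s", populations = bad), "sum to 1")
  expect_error(sample_spec("s", populations = pops, doublet_rate = 0.6,
                           debris_rate = 0.5), "< 1")
  expect_error(population_spec("p", 1, cell_diameter = -2), "> 0")
  expect_error(population_spec("p", 1, cell_diameter = 10, nc_ratio = 1.2),
               "in \\(0, 1\\)")
})

test_that("count simulation reduces to Poisson at zero dispersion", {
  cm <- simulate_count_matrix(5, n_per_condition = 100, dispersion = 0,
                              seed = 71)
  per_cluster <- split(cm$count, cm$cluster)
  ratio <- vapply(per_cluster, function(x) var(x) / mean(x), numeric(1))
  expect_true(all(ratio > 0.6 & ratio < 1.5))
  over <- simulate_count_matrix(5, n_per_condition = 100, dispersion = 0.3,
                                seed = 71)
  ratio2 <- vapply(split(over$count, over$cluster),
                   function(x) var(x) / mean(x), numeric(1))
  expect_true(all(ratio2 > 5))  # mu ~ 2000, so phi mu^2 dominates
})

test_that("count simulation keeps expected totals at the recording depth", {
  cm <- simulate_count_matrix(8, n_per_condition = 6, dispersion = 0.05,
                              total = 10000, seed = 81)
  tot <- tapply(cm$count, cm$sample, sum)
  expect_true(all(abs(tot - 10000) / 10000 < 0.15))
})

test_that("image export and import round-trip through 16-bit TIFF", {
  pops <- demo_populations()
  spec <- sample_spec("s1", n_events = 4, populations = pops, seed = 91)
  sim <- simulate_sample(spec)
  dir <- withr::local_tempdir()
  man <- write_event_images(sim$events, dir, sim$truth)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_event_images(dir)
  expect_equal(length(back$events), 4)
  expect_equal(names(back$events[[1]]$channels),
               names(sim$events[[1]]$channels))
  # 16-bit quantization: relative error bounded by one part in 2^16
  orig <- sim$events[[1]]$channels$DNA
  got <- back$events[[1]]$channels$DNA
  expect_lt(max(abs(got - orig)), 65535 / 2^16 + 1e-9)
  expect_true(all(c("population", "is_doublet") %in% names(back$manifest)))
})
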