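test_that("compensation inverts spillover exactly", {
  ev <- fixture_event()
  eye <- spillover_matrix(diag(2) |>
                            `dimnames<-`(list(c("SSC", "DNA"), c("SSC", "DNA"))))
  out <- compensate(ev, eye)
  expect_equal(out$channels$DNA, ev$channels$DNA, tolerance = 1e-12)

  # pure channel-1 signal leaking 20% into channel 2 comes back clean
  S <- spillover_matrix(matrix(c(1, 0.2, 0, 1), 2, byrow = TRUE,
                               dimnames = list(c("SSC", "DNA"), c("SSC", "DNA"))))
  ev2 <- ev
  ev2$channels$DNA <- ev$channels$SSC * 0.2   # what the detector would see
  rec <- compensate(ev2, S)
  expect_lt(max(abs(rec$channels$DNA)), 1e-9)

  # random 3x3 spillover agrees with an independent per-pixel solve
  set.seed(7)
  S3 <- diag(3); S3[row(S3) != col(S3)] <- runif(6, 0, 0.2)
  dimnames(S3) <- list(c("SSC", "DNA", "FL1"), c("SSC", "DNA", "FL1"))
  S3 <- spillover_matrix(S3)
  ev3 <- fixture_event(demo_populations()[[2]], seed = 5)
  ev3$channels$FL1 <- matrix(rexp(64 * 64, 1 / 50), 64)
  mixed <- ev3
  P <- sapply(c("SSC", "DNA", "FL1"), function(ch) as.vector(ev3$channels[[ch]]))
  D <- P %*% unclass(S3)
  for (j in 1:3) mixed$channels[[colnames(S3)[j]]] <- matrix(D[, j], 64)
  rec3 <- compensate(mixed, S3)
  for (px in sample(4096, 50)) {
    truth <- solve(t(unclass(S3)), D[px, ])
    got <- sapply(c("SSC", "DNA", "FL1"), function(ch) rec3$channels[[ch]][px])
    expect_lt(max(abs(got - pmax(truth, 0))), 1e-9)
  }
  expect_error(compensate(ev, spillover_matrix(
    matrix(c(1, 0.999999, 0.999999, 1), 2,
           dimnames = list(c("SSC", "DNA"), c("SSC", "DNA"))))), NA)
})

test_that("singular spillover matrices are rejected", {
  M <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(spillover_matrix(M), "singular|\\[0, 1\\)")
})

test_that("background subtraction zeroes flat frames and recovers signal", {
  ev <- fixture_event()
  flat <- ev
  flat$channels <- lapply(ev$channels, function(m) m * 0 + 57)
  out <- subtract_background(flat)
  for (ch in names(out$channels)) expect_equal(max(abs(out$channels[[ch]])), 0)

  # known additive background on an emission channel comes off within 1%
  ev2 <- fixture_event(seed = 55)
  truth <- sum(ev2$channels$DNA[ev2$masks$cell])
  ev2$channels$DNA <- ev2$channels$DNA + 40
  out2 <- subtract_background(ev2)
  got <- sum(out2$channels$DNA[out2$masks$cell])
  expect_lt(abs(got - truth) / truth, 0.01)
  # background itself is flattened to ~0
  expect_lt(median(out2$channels$DNA[!out2$masks$cell]), 1e-9)
})

test_that("segmentation recovers the rendered cell and flags blanks", {
  pop <- demo_populations()[[4]]
  ev <- render_cell_image(pop, seed = 9)
  seg <- segment_masks(ev)
  iou <- sum(seg$masks$cell & ev$masks$cell) / sum(seg$masks$cell | ev$masks$cell)
  expect_gte(iou, 0.8)
  expect_true(all(seg$masks$nucleus <= seg$masks$cell))

  blank <- ev
  blank$channels$BF <- matrix(3000, 64, 64)
  expect_true(segment_masks(blank)$flags$unsegmentable)
})

test_that("doublets segment to one merged, elongated object", {
  pops <- demo_populations()
  elongated <- 0
  for (s in 1:10) {
    dbl <- image3c:::render_doublet(pops[c(2, 2)], seed = 100 + s, frame = 64,
                                    channels = c("BF", "SSC", "DNA"))
    seg <- segment_masks(dbl)
    row <- compute_features(seg)
    if (row$cell_aspect_ratio < 0.8) elongated <- elongated + 1
  }
  expect_gte(elongated, 8)
})

test_that("an ideal disc has unit circularity and aspect ratio", {
  xs <- seq_len(64) - 0.5
  disc <- outer((xs - 32)^2, (xs - 32)^2, "+") <= 10^2
  g <- image3c:::geometry_features(disc)
  expect_lt(abs(g[["circularity"]] - 1), 0.05)
  expect_lt(abs(g[["aspect_ratio"]] - 1), 0.02)
  expect_equal(g[["area"]], sum(disc))
  expect_lt(abs(g[["diameter"]] - 20), 0.5)
})

test_that("granularity responds to the generator's texture level", {
  lo <- demo_populations()[[3]]; hi <- demo_populations()[[2]]
  lo$granularity <- 0
  hi$granularity <- 3
  wins <- 0
  for (s in 1:100) {
    e_lo <- fixture_event(lo, seed = 1000 + s)
    e_hi <- fixture_event(hi, seed = 1000 + s)
    g_lo <- image3c:::granularity_spectrum(e_lo$channels$SSC, e_lo$masks$cell)[["2"]]
    g_hi <- image3c:::granularity_spectrum(e_hi$channels$SSC, e_hi$masks$cell)[["2"]]
    if (g_hi > g_lo) wins <- wins + 1
  }
  expect_equal(wins, 100)
})

test_that("the granularity spectrum is monotone in the opening radius", {
  for (s in 1:20) {
    ev <- fixture_event(demo_populations()[[2]], seed = 2000 + s)
    for (ch in c("BF", "SSC")) {
      g <- image3c:::granularity_spectrum(ev$channels[[ch]], ev$masks$cell)
      expect_true(all(diff(g) >= -1e-12))
    }
  }
})

test_that("features are invariant under translation", {
  ev <- fixture_event(seed = 77)
  shift <- function(m, by) {
    out <- m * 0
    out[(1 + by):nrow(m), (1 + by):ncol(m)] <- m[1:(nrow(m) - by), 1:(ncol(m) - by)]
    out
  }
  ev2 <- ev
  ev2$channels <- lapply(ev$channels, shift, by = 5)
  ev2$masks <- lapply(ev$masks, function(m) shift(m, 5) > 0)
  f1 <- compute_features(ev)
  f2 <- compute_features(ev2)
  feats <- setdiff(names(f1), c("event_id", "sample_id", "segmented"))
  for (f in feats) {
    denom <- max(abs(f1[[f]]), 1e-9)
    expect_lt(abs(f1[[f]] - f2[[f]]) / denom, 1e-6)
  }
})

test_that("feature extraction demands masks and names the event", {
  ev <- render_cell_image(demo_populations()[[1]], seed = 1)
  ev$masks <- NULL
  ev$event_id <- "ev42"
  expect_error(compute_features(ev), "ev42")
})

test_that("gating removes debris and doublets but spares clean events", {
  pops <- demo_populations()
  specs <- lapply(1:2, function(s)
    sample_spec(sprintf("s%02d", s), n_events = 400, populations = pops,
                doublet_rate = 0.1, debris_rate = 0.08, seed = 700 + s))
  sim <- simulate_feature_table(specs)
  gated <- gate_events(sim$table, keep_all = TRUE)
  merged <- dplyr::left_join(gated, sim$truth, by = c("event_id", "sample_id"))

  debris <- merged[merged$is_debris, ]
  expect_true(all(!debris$gate_nucleated | is.na(debris$gate_nucleated)))

  dbl <- merged[merged$is_doublet & merged$segmented, ]
  caught <- is.na(dbl$gate_singlet) | !dbl$gate_singlet
  expect_gte(mean(caught), 0.8)

  clean <- merged[!merged$is_doublet & !merged$is_debris & merged$segmented, ]
  retained <- clean$gate_focused & clean$gate_nucleated & clean$gate_singlet
  expect_gte(mean(retained, na.rm = TRUE), 0.9)
})

test_that("disabled gates return the table row for row", {
  sim <- fixture_small_experiment()
  out <- gate_events(sim$table, gate_config(focused = FALSE, nucleated = FALSE,
                                            singlet = FALSE))
  expect_equal(nrow(out), nrow(sim$table))
  expect_equal(out$event_id, sim$table$event_id)
})

test_that("identity compensation and zero-background subtraction commute with features", {
  ev <- fixture_event(seed = 91)
  # a genuine zero-background input: clear the residual half-rectified
  # noise outside the cell so the background median is exactly zero
  for (ch in names(ev$channels)) ev$channels[[ch]][!ev$masks$cell] <- 0
  eye <- spillover_matrix(diag(3) |>
                            `dimnames<-`(list(c("BF", "SSC", "DNA"),
                                              c("BF", "SSC", "DNA"))))
  ev2 <- subtract_background(compensate(ev, eye))
  f1 <- compute_features(ev)
  f2 <- compute_features(ev2)
  expect_equal(as.data.frame(f1), as.data.frame(f2), tolerance = 1e-12)
})
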