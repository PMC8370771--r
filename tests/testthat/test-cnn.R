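test_that("crop/pad follows the centre rule exactly", {
  m32 <- matrix(rnorm(32 * 32), 32)
  expect_identical(crop_pad_32(m32), m32)

  m <- matrix(seq_len(40 * 25), nrow = 40, ncol = 25)
  out <- crop_pad_32(m)
  expect_equal(dim(out), c(32, 32))
  expect_equal(out[, 1:3], matrix(0, 32, 3))        # 3 leading zero columns
  expect_equal(out[, 29:32], matrix(0, 32, 4))      # 4 trailing zero columns
  expect_equal(out[, 4:28], m[5:36, ])              # rows lose (4, 4)

  tiny <- crop_pad_32(matrix(7, 1, 1))
  expect_equal(tiny[16, 16], 7)                     # 0-based (15, 15)
  expect_equal(sum(tiny != 0), 1)

  st <- array(rnorm(40 * 25 * 3), c(40, 25, 3))
  out3 <- crop_pad_32(st)
  expect_equal(dim(out3), c(32, 32, 3))
  expect_equal(out3[, 4:28, 2], st[5:36, , 2])
})

test_that("the built network has the prescribed architecture constants", {
  model <- build_network(7, classifier_config(seed = 1))
  shp <- network_shape(model)
  expect_equal(shp$flatten_length, 1392L)
  expect_equal(shp$final_feature_maps, 87L)
  expect_equal(shp$final_spatial, 4L)
  expect_equal(dim(model$weights$fc_w), c(1392L, 7L))

  # forward pass on a zero image: finite logits, softmax sums to one
  x <- array(0, c(32, 32, 3, 2))
  probs <- image3c:::network_probs(model, x)
  expect_true(all(is.finite(probs)))
  expect_equal(colSums(probs), c(1, 1), tolerance = 1e-6)
})

test_that("configs violating the fixed architecture are rejected", {
  expect_error(classifier_config(transitions = c(22, 44, 80)), "87")
  expect_error(classifier_config(splits = c(0.8, 0.1, 0.2)), "sum to 1")
  expect_error(build_network(1), "2 classes")
})

test_that("stratified splits partition the data reproducibly", {
  labels <- rep(c("a", "b", "c", "d"), times = c(400, 300, 200, 100))
  sp <- split_dataset(labels, c(0.8, 0.1, 0.1), seed = 5)
  expect_equal(length(sp$train), 800)
  expect_equal(length(sp$test), 100)
  expect_equal(length(sp$validate), 100)
  all_idx <- c(sp$train, sp$test, sp$validate)
  expect_setequal(all_idx, seq_along(labels))
  expect_equal(anyDuplicated(all_idx), 0L)
  for (cl in unique(labels)) {
    n_cl <- sum(labels == cl)
    expect_lte(abs(sum(labels[sp$train] == cl) - 0.8 * n_cl), 1)
  }
  sp2 <- split_dataset(labels, c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(sp, sp2)
  expect_error(split_dataset(c("a", "a", "a", "b", "b")), "b")
})

test_that("analytic gradients match finite differences of an independent forward pass", {
  model <- build_network(3, classifier_config(seed = 2))
  w <- model$weights
  wl <- image3c:::model_weight_lists(model)
  withr::with_seed(3, {
    x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    y <- c(0L, 2L)
  })
  # the two forward implementations agree
  res <- image3c:::cnn_pass_cpp(wl$W, wl$b, wl$fw, wl$fb, x, y, 0.1, 1e-4, TRUE)
  expect_equal(oracle_cnn_loss(w, x, y, 0.1, 1e-4), res$loss, tolerance = 1e-5)

  eps <- 1e-5
  for (li in c(1, 4, 7, 12)) {
    for (i in c(3, 11)) {
      wp <- w; wp$conv_w[[li]][i] <- wp$conv_w[[li]][i] + eps
      wm <- w; wm$conv_w[[li]][i] <- wm$conv_w[[li]][i] - eps
      num <- (oracle_cnn_loss(wp, x, y, 0.1, 1e-4) -
                oracle_cnn_loss(wm, x, y, 0.1, 1e-4)) / (2 * eps)
      expect_equal(res$gW[[li]][i], num, tolerance = 1e-3)
    }
  }
  fp <- w; fp$fc_w[10] <- fp$fc_w[10] + eps
  fm <- w; fm$fc_w[10] <- fm$fc_w[10] - eps
  num <- (oracle_cnn_loss(fp, x, y, 0.1, 1e-4) -
            oracle_cnn_loss(fm, x, y, 0.1, 1e-4)) / (2 * eps)
  expect_equal(res$gWfc[10], num, tolerance = 1e-3)
})

test_that("a brief training run learns separable toy classes", {
  withr::with_seed(7, {
    n <- 120
    x <- array(rnorm(32 * 32 * 3 * n, sd = 0.1), c(32, 32, 3, n))
    y <- rep(c("lo", "hi"), each = n / 2)
    x[10:22, 10:22, 1, y == "hi"] <- x[10:22, 10:22, 1, y == "hi"] + 3
  })
  model <- build_network(2, classifier_config(seed = 7))
  model <- train_classifier(model, x, y, iterations = 100, batch_size = 16)
  expect_equal(nrow(model$log), 1L)         # one log row per 100 iterations
  ev <- evaluate_classifier(model, x, y)
  expect_gte(ev$accuracy, 0.95)
  expect_s3_class(autoplot(model), "ggplot")
  expect_true(glance(model)$trained)
})

test_that("overwhelming L2 regularisation drives accuracy to chance", {
  withr::with_seed(8, {
    n <- 80
    x <- array(rnorm(32 * 32 * 3 * n, sd = 0.1), c(32, 32, 3, n))
    y <- rep(c("a", "b"), each = n / 2)
    x[5:15, 5:15, 2, y == "b"] <- x[5:15, 5:15, 2, y == "b"] + 3
  })
  cfg <- classifier_config(seed = 8, l2 = 10)
  model <- build_network(2, cfg)
  norm0 <- sum(vapply(model$weights$conv_w, function(w) sum(w^2), numeric(1)))
  model <- train_classifier(model, x, y, iterations = 100, batch_size = 16)
  norm1 <- sum(vapply(model$weights$conv_w, function(w) sum(w^2), numeric(1)))
  expect_lt(norm1, 0.7 * norm0)             # weights shrink towards zero
  ev <- evaluate_classifier(model, x, y)
  expect_lte(ev$accuracy, 0.75)             # chance is 0.5
})

test_that("classification reports calibrated-looking probability vectors", {
  withr::with_seed(9, {
    n <- 60
    x <- array(rnorm(32 * 32 * 3 * n, sd = 0.1), c(32, 32, 3, n))
    y <- rep(c("a", "b"), each = n / 2)
    x[8:20, 8:20, 3, y == "b"] <- x[8:20, 8:20, 3, y == "b"] + 3
  })
  model <- build_network(2, classifier_config(seed = 9))
  model <- train_classifier(model, x, y, iterations = 200, batch_size = 16)
  out <- classify(model, x)
  pm <- as.matrix(out[, model$classes])
  expect_equal(unname(rowSums(pm)), rep(1, n), tolerance = 1e-6)
  expect_gte(mean(out$predicted_class == y), 0.9)
  one <- classify(model, x[, , , 1, drop = FALSE])
  expect_equal(nrow(one), 1)
  expect_equal(ncol(as.matrix(one[, model$classes])), 2)
})

test_that("evaluation metrics match hand computation on a toy confusion", {
  conf <- matrix(c(5, 0, 0,
                   1, 4, 0,
                   0, 0, 5), 3, byrow = TRUE,
                 dimnames = list(truth = c("x", "y", "z"),
                                 predicted = c("x", "y", "z")))
  cm <- image3c:::confusion_metrics(conf)
  expect_equal(unname(cm$metrics$precision), c(5 / 6, 1, 1), tolerance = 1e-12)
  expect_equal(unname(cm$metrics$recall), c(1, 0.8, 1), tolerance = 1e-12)
  f1y <- 2 * 1 * 0.8 / 1.8
  expect_equal(cm$weighted_f1,
               (5 * (2 * (5 / 6) / (1 + 5 / 6)) + 5 * f1y + 5 * 1) / 15,
               tolerance = 1e-12)

  # perfect prediction: everything is 1
  perfect <- diag(4L)
  pm <- image3c:::confusion_metrics(perfect)
  expect_true(all(pm$metrics$precision == 1, pm$metrics$recall == 1,
                  pm$metrics$f1 == 1))
  expect_equal(pm$weighted_f1, 1)

  # a uniform-random predictor sits near 1/C accuracy
  withr::with_seed(10, {
    truth <- sample(4, 1000, replace = TRUE)
    pred <- sample(4, 1000, replace = TRUE)
    acc <- mean(truth == pred)
    expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
  })
})

test_that("cluster merging collapses the stated pairs to seven classes", {
  map <- c(Pc1 = "Pc1_CT", Pc9 = "Pc1_CT", Pc5 = "Pc5_CT", Pc8 = "Pc5_CT",
           Pc2 = "Pc2_CT", Pc3 = "Pc3_CT", Pc4 = "Pc4_CT", Pc6 = "Pc6_CT",
           Pc7 = "Pc7_CT")
  merged <- merge_classes(paste0("Pc", 1:9), map)
  expect_equal(nlevels(merged), 7L)
  expect_equal(as.character(merged[c(1, 9)]), c("Pc1_CT", "Pc1_CT"))
  expect_equal(as.character(merged[c(5, 8)]), c("Pc5_CT", "Pc5_CT"))

  ident <- merge_classes(paste0("Pc", 1:9))
  expect_equal(nlevels(ident), 9L)
  expect_equal(length(merge_classes(character())), 0L)
  expect_error(merge_classes(c("Pc1", "Pc10"), map), "Pc10")
})
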