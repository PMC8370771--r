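#' Crop or pad an image (stack) to 32 x 32
#'
#' Dimensions above 32 are centre-cropped; dimensions below 32 are
#' symmetrically zero-padded with the extra pixel on the trailing side when
#' the difference is odd. Channels are handled identically.
#'
#' @param x a matrix, an (h, w, c) array, or an (h, w, c, n) array.
#' @return the same structure with spatial size 32 x 32.
#' @export
crop_pad_32 <- function(x) {
  if (is.matrix(x)) return(crop_pad_plane(x))
  d <- dim(x)
  if (length(d) == 3) {
    out <- array(0, c(32, 32, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- crop_pad_plane(x[, , c])
    return(out)
  }
  if (length(d) == 4) {
    out <- array(0, c(32, 32, d[3], d[4]))
    for (n in seq_len(d[4])) for (c in seq_len(d[3]))
      out[, , c, n] <- crop_pad_plane(x[, , c, n])
    return(out)
  }
  stop("expected a matrix or a 3-/4-dimensional array")
}

crop_pad_plane <- function(m) {
  fit <- function(v) {  # returns (src range, dst range) for one axis
    n <- length(v)
    if (n >= 32) {
      s <- floor((n - 32) / 2) + 1L
      list(src = s:(s + 31L), dst = 1:32)
    } else {
      lead <- floor((32 - n) / 2)
      list(src = 1:n, dst = (lead + 1L):(lead + n))
    }
  }
  fr <- fit(seq_len(nrow(m))); fc <- fit(seq_len(ncol(m)))
  out <- matrix(0, 32, 32)
  out[fr$dst, fc$dst] <- m[fr$src, fc$src]
  out
}

#' Classifier configuration
#'
#' Architecture and training hyper-parameters of the image classifier:
#' three dense blocks take the 32 x 32 x 3 input down to 4 x 4 x 87
#' feature maps (the final width of 87 is fixed; intermediate transition
#' widths and the dense growth rate are configurable), which flatten to a
#' 1392-vector fully connected to the class logits. Training uses softmax
#' cross-entropy with L2 regularisation and Adam, the learning rate
#' decaying by `1 - lr_decay` every `decay_interval` iterations.
#'
#' @param growth channels added by each in-block convolution.
#' @param transitions output channels of the three strided transition
#'   convolutions; the last entry must be 87.
#' @param leaky_slope negative-side slope of the leaky ReLU.
#' @param l2 L2 weight-penalty coefficient.
#' @param learning_rate initial Adam learning rate (a constant 0.0006 is a
#'   supported alternative: set `lr_decay = 1`).
#' @param lr_decay multiplicative decay applied every `decay_interval`
#'   iterations.
#' @param decay_interval iterations per decay step (also the logging
#'   interval).
#' @param iterations,batch_size training length and batch size.
#' @param splits train/test/validate fractions (must sum to 1).
#' @param seed initialisation and batch-sampling seed.
#' @export
classifier_config <- function(growth = 8L, transitions = c(22L, 44L, 87L),
                              leaky_slope = 0.1, l2 = 1e-4,
                              learning_rate = 0.001, lr_decay = 0.99,
                              decay_interval = 100L, iterations = 25000L,
                              batch_size = 256L,
                              splits = c(train = 0.8, test = 0.1, validate = 0.1),
                              seed = 1L) {
  if (length(transitions) != 3 || transitions[3] != 87L)
    stop("the final transition must produce 87 feature maps")
  if (abs(sum(splits) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(growth = as.integer(growth), transitions = as.integer(transitions),
                 leaky_slope = leaky_slope, l2 = l2,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 decay_interval = as.integer(decay_interval),
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), splits = splits,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Build the untrained dense-block network
#'
#' Three dense blocks (three 3 x 3 same-padding convolutions each, every
#' layer receiving the concatenation of the block input and all previous
#' layer outputs, each followed by a leaky ReLU) each end in a 3 x 3
#' stride-2 transition convolution halving the spatial size:
#' 32 -> 16 -> 8 -> 4. The final 4 x 4 x 87 maps flatten to a vector of
#' length 1392, fully connected to the class logits. Weights use He
#' initialisation under the config seed.
#'
#' @param n_classes number of output classes (>= 2).
#' @param config a [classifier_config()].
#' @return an `image3c_classifier` (untrained).
#' @export
build_network <- function(n_classes, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  if (n_classes < 2) stop("need at least 2 classes")
  g <- config$growth; tr <- config$transitions
  c0 <- c(3L, tr[1], tr[2])
  conv_w <- list(); conv_b <- list()
  with_local_seed(config$seed, {
    for (b in 1:3) {
      for (l in 0:2) {
        cin <- c0[b] + l * g
        conv_w[[length(conv_w) + 1L]] <-
          array(rnorm(9 * cin * g, 0, sqrt(2 / (9 * cin))), c(3, 3, cin, g))
        conv_b[[length(conv_b) + 1L]] <- numeric(g)
      }
      cin <- c0[b] + 3L * g
      conv_w[[length(conv_w) + 1L]] <-
        array(rnorm(9 * cin * tr[b], 0, sqrt(2 / (9 * cin))), c(3, 3, cin, tr[b]))
      conv_b[[length(conv_b) + 1L]] <- numeric(tr[b])
    }
    flat <- 4L * 4L * tr[3]
    stopifnot(flat == 1392L)
    fc_w <- matrix(rnorm(flat * n_classes, 0, sqrt(1 / flat)), flat, n_classes)
    fc_b <- numeric(n_classes)
    structure(list(weights = list(conv_w = conv_w, conv_b = conv_b,
                                  fc_w = fc_w, fc_b = fc_b),
                   config = config, n_classes = as.integer(n_classes),
                   classes = NULL, preprocess = NULL,
                   log = NULL, trained = FALSE),
              class = "image3c_classifier")
  })
}

#' Architecture constants of a built network
#'
#' @param model an `image3c_classifier`.
#' @return list: flatten length, final feature maps, final spatial width.
#' @export
network_shape <- function(model) {
  tr <- model$config$transitions
  list(flatten_length = nrow(model$weights$fc_w),
       final_feature_maps = tr[3],
       final_spatial = as.integer(32 / 2^3))
}

#' Stratified train / test / validate split
#'
#' @param labels class label per event.
#' @param fractions three fractions summing to 1.
#' @param seed split seed.
#' @return list of integer index vectors `train`, `test`, `validate`;
#'   disjoint, covering all events, stratified by class.
#' @export
split_dataset <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small))
    stop("class(es) with fewer than 3 events cannot be split: ",
         paste(small, collapse = ", "))
  with_local_seed(seed, {
    parts <- list(train = integer(), test = integer(), validate = integer())
    for (cl in names(tab)) {
      ix <- sample(which(labels == cl))
      n <- length(ix)
      n1 <- round(fractions[1] * n)
      n2 <- round((fractions[1] + fractions[2]) * n) - n1
      parts$train <- c(parts$train, ix[seq_len(n1)])
      parts$test <- c(parts$test, ix[n1 + seq_len(n2)])
      parts$validate <- c(parts$validate, ix[seq(n1 + n2 + 1, n)])
    }
    lapply(parts, sort)
  })
}

# events (list or array) -> (32, 32, 3, N) double array in channel order
as_image_array <- function(images, channel_order = c("BF", "SSC", "DNA")) {
  if (is.array(images) && length(dim(images)) == 4) {
    if (!all(dim(images)[1:2] == 32)) images <- crop_pad_32(images)
    return(images)
  }
  if (!is.list(images)) stop("expected a list of events or a 4-d array")
  n <- length(images)
  out <- array(0, c(32, 32, 3, n))
  for (i in seq_len(n)) {
    ev <- images[[i]]
    chs <- if (inherits(ev, "image3c_event")) ev$channels else ev
    miss <- setdiff(channel_order, names(chs))
    if (length(miss)) stop("event ", i, " lacks channel(s): ",
                           paste(miss, collapse = ", "))
    for (c in seq_along(channel_order))
      out[, , c, i] <- crop_pad_plane(chs[[channel_order[c]]])
  }
  out
}

model_weight_lists <- function(model) {
  w <- model$weights
  list(W = w$conv_w, b = w$conv_b, fw = as.numeric(w$fc_w), fb = w$fc_b)
}

# forward pass in chunks; returns K x N probability matrix
network_probs <- function(model, x, chunk = 512L) {
  wl <- model_weight_lists(model)
  n <- dim(x)[4]
  probs <- matrix(0, model$n_classes, n)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    res <- cnn_pass_cpp(wl$W, wl$b, wl$fw, wl$fb,
                        x[, , , i0:i1, drop = FALSE], integer(),
                        model$config$leaky_slope, model$config$l2, FALSE)
    probs[, i0:i1] <- res$probs
  }
  probs
}

apply_preprocess <- function(model, x) {
  sc <- model$preprocess$channel_scale
  if (is.null(sc)) return(x)
  for (c in seq_along(sc)) x[, , c, ] <- x[, , c, ] / sc[c]
  x
}

#' Train the classifier on de novo cluster labels
#'
#' Mini-batch Adam on softmax cross-entropy with L2 regularisation. Batches
#' are sampled with replacement; the learning rate decays by the configured
#' factor every `decay_interval` iterations; training and test loss and
#' accuracy are recorded every 100 iterations. Inputs are scaled per
#' channel by the 99.5th percentile of the training set (stored with the
#' model for inference). If the test loss ends more than 20% above its
#' minimum while the training loss kept falling, an overfitting warning is
#' raised.
#'
#' @param model an `image3c_classifier` from [build_network()].
#' @param images training images: list of events (BF, SSC, DNA channels) or
#'   a (32, 32, 3, n) array.
#' @param labels class label per training image.
#' @param test_images,test_labels held-out monitoring set (optional but
#'   recommended).
#' @param iterations,batch_size override the config values.
#' @param verbose print the log lines as they are recorded.
#' @return the trained model, with `$log` holding one row per 100
#'   iterations.
#' @export
train_classifier <- function(model, images, labels, test_images = NULL,
                             test_labels = NULL, iterations = NULL,
                             batch_size = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "image3c_classifier"))
  cfg <- model$config
  iterations <- as.integer(iterations %||% cfg$iterations)
  batch_size <- as.integer(batch_size %||% cfg$batch_size)
  classes <- model$classes %||% sort(unique(as.character(labels)))
  if (length(classes) != model$n_classes)
    stop("network was built for ", model$n_classes, " classes but labels have ",
         length(classes))
  y <- match(as.character(labels), classes) - 1L
  if (anyNA(y)) stop("labels outside the model's class set")
  x <- as_image_array(images)
  # per-channel scaling from the training set
  sc <- vapply(1:3, function(c) {
    q <- quantile(x[, , c, ], 0.995, names = FALSE)
    if (q <= 0) 1 else q
  }, numeric(1))
  model$preprocess <- list(channel_order = c("BF", "SSC", "DNA"),
                           channel_scale = sc)
  model$classes <- classes
  x <- apply_preprocess(model, x)
  xt <- NULL; yt <- NULL
  if (!is.null(test_images)) {
    xt <- apply_preprocess(model, as_image_array(test_images))
    yt <- match(as.character(test_labels), classes) - 1L
    if (anyNA(yt)) stop("test labels outside the model's class set")
    if (length(setdiff(seq_along(classes) - 1L, unique(y))))
      stop("every class must appear in the training set")
  }
  wl <- model_weight_lists(model)
  adam <- list(mW = lapply(wl$W, function(w) w * 0),
               vW = lapply(wl$W, function(w) w * 0),
               mb = lapply(wl$b, function(b) b * 0),
               vb = lapply(wl$b, function(b) b * 0),
               mfw = wl$fw * 0, vfw = wl$fw * 0,
               mfb = wl$fb * 0, vfb = wl$fb * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  log_rows <- vector("list", iterations %/% 100L)
  n_tr <- dim(x)[4]
  with_local_seed(cfg$seed, {
    for (it in seq_len(iterations)) {
      lr <- cfg$learning_rate * cfg$lr_decay^((it - 1) %/% cfg$decay_interval)
      idx <- sample.int(n_tr, batch_size, replace = TRUE)
      res <- cnn_pass_cpp(wl$W, wl$b, wl$fw, wl$fb,
                          x[, , , idx, drop = FALSE], y[idx],
                          cfg$leaky_slope, cfg$l2, TRUE)
      if (!is.finite(res$loss))
        stop(sprintf("training diverged (non-finite loss) at iteration %d, lr %.2e",
                     it, lr))
      corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
      for (j in seq_along(wl$W)) {
        adam$mW[[j]] <- b1 * adam$mW[[j]] + (1 - b1) * res$gW[[j]]
        adam$vW[[j]] <- b2 * adam$vW[[j]] + (1 - b2) * res$gW[[j]]^2
        wl$W[[j]] <- wl$W[[j]] - lr * (adam$mW[[j]] / corr1) /
          (sqrt(adam$vW[[j]] / corr2) + eps)
        adam$mb[[j]] <- b1 * adam$mb[[j]] + (1 - b1) * res$gb[[j]]
        adam$vb[[j]] <- b2 * adam$vb[[j]] + (1 - b2) * res$gb[[j]]^2
        wl$b[[j]] <- wl$b[[j]] - lr * (adam$mb[[j]] / corr1) /
          (sqrt(adam$vb[[j]] / corr2) + eps)
      }
      adam$mfw <- b1 * adam$mfw + (1 - b1) * res$gWfc
      adam$vfw <- b2 * adam$vfw + (1 - b2) * res$gWfc^2
      wl$fw <- wl$fw - lr * (adam$mfw / corr1) / (sqrt(adam$vfw / corr2) + eps)
      adam$mfb <- b1 * adam$mfb + (1 - b1) * res$gbfc
      adam$vfb <- b2 * adam$vfb + (1 - b2) * res$gbfc^2
      wl$fb <- wl$fb - lr * (adam$mfb / corr1) / (sqrt(adam$vfb / corr2) + eps)

      if (it %% 100L == 0L) {
        row <- tibble(iteration = it, lr = lr,
                      train_loss = res$loss, train_acc = res$acc,
                      test_loss = NA_real_, test_acc = NA_real_)
        if (!is.null(xt)) {
          m2 <- model; m2$weights <- list(conv_w = wl$W, conv_b = wl$b,
                                          fc_w = matrix(wl$fw, nrow(model$weights$fc_w)),
                                          fc_b = wl$fb)
          pt <- network_probs(m2, xt)
          row$test_loss <- -mean(log(pmax(pt[cbind(yt + 1L, seq_along(yt))], 1e-300)))
          row$test_acc <- mean(max.col(t(pt)) - 1L == yt)
        }
        log_rows[[it %/% 100L]] <- row
        if (verbose)
          message(sprintf("iter %6d  loss %.4f  acc %.3f  test_acc %s", it,
                          res$loss, res$acc,
                          ifelse(is.na(row$test_acc), "-", sprintf("%.3f", row$test_acc))))
      }
    }
  })
  model$weights <- list(conv_w = wl$W, conv_b = wl$b,
                        fc_w = matrix(wl$fw, nrow(model$weights$fc_w)),
                        fc_b = wl$fb)
  model$log <- dplyr::bind_rows(log_rows)
  model$trained <- TRUE
  if (!is.null(xt) && nrow(model$log) >= 3) {
    tl <- model$log$test_loss
    imin <- which.min(tl)
    last <- nrow(model$log)
    if (tl[last] > 1.2 * tl[imin] &&
        model$log$train_loss[last] < model$log$train_loss[imin])
      warning("test loss diverged from training loss (possible memorisation); ",
              "inspect the training log")
  }
  model
}

#' Evaluate the classifier on a validation set
#'
#' @param model trained `image3c_classifier`.
#' @param images,labels validation images and their original cluster ids.
#' @return an `image3c_eval` list: per-class precision/recall/f1 (NA for
#'   classes absent from the validation set), support-weighted f1,
#'   accuracy, the confusion matrix (rows = truth), and per-event
#'   true-match probabilities (softmax probability of the original class).
#' @export
evaluate_classifier <- function(model, images, labels) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  x <- apply_preprocess(model, as_image_array(images))
  y <- match(as.character(labels), model$classes)
  if (anyNA(y)) stop("labels outside the model's class set")
  probs <- network_probs(model, x)
  pred <- max.col(t(probs))
  K <- model$n_classes
  conf <- matrix(0L, K, K, dimnames = list(truth = model$classes,
                                           predicted = model$classes))
  for (i in seq_along(y)) conf[y[i], pred[i]] <- conf[y[i], pred[i]] + 1L
  cm <- confusion_metrics(conf)
  structure(list(metrics = cm$metrics,
                 weighted_f1 = cm$weighted_f1,
                 accuracy = mean(pred == y),
                 confusion = conf,
                 true_match = probs[cbind(y, seq_along(y))]),
            class = "image3c_eval")
}

# per-class precision/recall/f1 and support-weighted f1 from a confusion
# matrix with truth in rows; classes absent from the truth get NA
confusion_metrics <- function(conf) {
  support <- rowSums(conf)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), NA_real_)
  rec <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), NA_real_)
  present <- support > 0
  metrics <- tibble(class = rownames(conf) %||% as.character(seq_len(nrow(conf))),
                    support = as.integer(support),
                    precision = ifelse(present, prec, NA_real_),
                    recall = rec, f1 = ifelse(present, f1, NA_real_))
  list(metrics = metrics,
       weighted_f1 = sum(f1[present] * support[present]) / sum(support[present]))
}

#' @export
print.image3c_eval <- function(x, ...) {
  cat("<image3c_eval> accuracy", round(x$accuracy, 3),
      " weighted f1", round(x$weighted_f1, 3), "\n")
  print(x$metrics)
  invisible(x)
}

#' Classify new images and report prediction reliability
#'
#' Runs a forward pass on new image stacks and returns the per-event
#' softmax probability vector (summing to 1), the argmax class, and the
#' maximum probability. A reliability report gives the fraction of events
#' whose maximum probability exceeds 0.5; predictions should be treated
#' with caution when that fraction is low.
#'
#' @param model trained `image3c_classifier`.
#' @param images list of events or a (32, 32, 3, n) array, channels in the
#'   model's training order.
#' @param reliability_threshold flag the run when the fraction of events
#'   with max probability > 0.5 falls below this.
#' @param path optional CSV path for the probability vectors.
#' @return tibble with one probability column per class plus
#'   `predicted_class` and `max_prob`; attribute `reliability` holds the
#'   report.
#' @export
classify <- function(model, images, reliability_threshold = 0.5, path = NULL) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  x <- apply_preprocess(model, as_image_array(images,
                                              model$preprocess$channel_order))
  probs <- network_probs(model, x)
  out <- tibble::as_tibble(setNames(as.data.frame(t(probs)), model$classes))
  out$predicted_class <- model$classes[max.col(t(probs))]
  out$max_prob <- apply(probs, 2, max)
  frac <- mean(out$max_prob > 0.5)
  attr(out, "reliability") <- list(
    fraction_confident = frac,
    flagged = frac < reliability_threshold)
  if (isTRUE(attr(out, "reliability")$flagged))
    warning(sprintf("only %.0f%% of events have a confident (max > 0.5) ",
                    100 * frac), "prediction; inspect images before trusting ",
            "the class assignments")
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Merge de novo clusters into training classes
#'
#' Clusters with strongly overlapping morphology can be merged before
#' training (e.g. 9 de novo clusters with two merges give 7 classes).
#'
#' @param ids cluster ids (character or factor).
#' @param map named character vector `old id -> class id`; ids absent from
#'   the map raise an error; `NULL` keeps every cluster as its own class.
#' @return factor of training class ids.
#' @export
merge_classes <- function(ids, map = NULL) {
  ids <- as.character(ids)
  if (is.null(map)) return(factor(ids))
  missing <- setdiff(unique(ids), names(map))
  if (length(missing))
    stop("cluster id(s) not covered by the merge map: ",
         paste(missing, collapse = ", "))
  factor(unname(map[ids]))
}

#' Training-curve plot for a trained classifier
#' @param object a trained `image3c_classifier`.
#' @param ... unused.
#' @method autoplot image3c_classifier
#' @export
autoplot.image3c_classifier <- function(object, ...) {
  if (is.null(object$log)) stop("model has no training log")
  long <- tidyr::pivot_longer(object$log,
                              c("train_loss", "test_loss", "train_acc", "test_acc"),
                              names_to = c("set", "metric"), names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "iteration", y = NULL, colour = NULL)
}

#' @method glance image3c_classifier
#' @export
glance.image3c_classifier <- function(x, ...) {
  lg <- x$log
  tibble(trained = isTRUE(x$trained),
         n_classes = x$n_classes,
         iterations = if (is.null(lg)) 0L else max(lg$iteration),
         final_train_acc = if (is.null(lg)) NA_real_ else tail(lg$train_acc, 1),
         final_test_acc = if (is.null(lg)) NA_real_ else tail(lg$test_acc, 1))
}

#' @export
print.image3c_classifier <- function(x, ...) {
  shp <- network_shape(x)
  cat("<image3c_classifier> ", x$n_classes, " classes, flatten ",
      shp$flatten_length, ", ", if (isTRUE(x$trained)) "trained" else "untrained",
      "\n", sep = "")
  invisible(x)
}
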