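# minimal one-feature network + discretization for parameter fitting
toy_disc <- function(bins, labels, b_low = 10, b_high = 20) {
  p <- ncol(bins)
  structure(list(bins = bins,
                 per_feature_mi = stats::setNames(rep(0.5, p),
                                                  colnames(bins)),
                 b_low = stats::setNames(rep(b_low, p), colnames(bins)),
                 b_high = stats::setNames(rep(b_high, p), colnames(bins)),
                 degenerate = stats::setNames(rep("none", p),
                                              colnames(bins)),
                 class_labels = labels,
                 class_levels = unique(labels)),
            class = "disc_table")
}

toy_net <- function(features) {
  bn_net(data.frame(from = "class", to = features, level = "first-level"))
}

test_that("CPTs on a six-case worked example match hand counts", {
  bins <- cbind(`100` = c(0L, 0L, 1L, 2L, 2L, 2L))
  labels <- c("n", "n", "n", "d", "d", "d")
  params <- fit_parameters(toy_net("100"), toy_disc(bins, labels),
                           pseudocount = 1)
  expect_equal(unname(params$prior), c(0.5, 0.5))
  # class n: counts (2,1,0) + 1 -> (3,2,1)/6; class d: (0,0,3)+1 -> (1,1,4)/6
  expect_equal(unname(params$cpts[["100"]][, "n"]), c(3, 2, 1) / 6)
  expect_equal(unname(params$cpts[["100"]][, "d"]), c(1, 1, 4) / 6)
  # unobserved bin smoothing: 1 / (n_class + 3)
  expect_equal(params$cpts[["100"]]["low", "d"], 1 / (3 + 3))
  expect_true(all(abs(colSums(params$cpts[["100"]]) - 1) < 1e-12))
  expect_true(all(params$cpts[["100"]] > 0))
})

test_that("parameter fitting rejects degenerate inputs", {
  bins <- cbind(`100` = c(0L, 2L))
  expect_error(fit_parameters(toy_net("200"), toy_disc(bins, c("a", "b"))),
               "absent from the discretized table")
  empty <- bn_net(data.frame(from = character(0), to = character(0),
                             level = character(0)))
  expect_error(fit_parameters(empty, toy_disc(bins, c("a", "b"))),
               "no first-level")
})

test_that("uninformative tables give the prior as posterior", {
  bins <- cbind(`100` = rep(c(0L, 1L, 2L), each = 4))
  labels <- rep(c("n", "d"), 6)
  params <- fit_parameters(toy_net("100"), toy_disc(bins, labels))
  post <- posterior(params, cbind(`100` = c(0L, 1L, 2L)))
  for (i in 1:3) expect_equal(unname(post[i, ]), unname(params$prior),
                              tolerance = 1e-12)
})

test_that("a single strong feature yields the textbook posterior", {
  params <- fit_parameters(
    toy_net("100"),
    toy_disc(cbind(`100` = c(0L, 2L, 0L, 2L)), c("n", "d", "n", "d")))
  # overwrite CPTs with exact values: P(high | d) = 0.9, P(high | n) = 0.1
  params$cpts[["100"]] <- cbind(n = c(0.8, 0.1, 0.1), d = c(0.05, 0.05, 0.9))
  params$prior <- c(n = 0.5, d = 0.5)
  post <- posterior(params, cbind(`100` = 2L))
  expect_equal(unname(post[1, "d"]), 0.9, tolerance = 1e-12)
})

test_that("posterior equals brute-force joint-table enumeration (7 features)", {
  set.seed(13)
  feats <- as.character(1:7 * 100)
  levels <- c("n", "d")
  cpts <- lapply(feats, function(f) {
    m <- matrix(runif(6, 0.05, 1), 3, 2, dimnames = list(NULL, levels))
    sweep(m, 2, colSums(m), "/")
  })
  names(cpts) <- feats
  prior <- c(n = 0.35, d = 0.65)
  params <- structure(list(class_levels = levels, prior = prior, cpts = cpts,
                           b_low = stats::setNames(rep(0, 7), feats),
                           b_high = stats::setNames(rep(1, 7), feats),
                           features = feats, positive_class = "d",
                           decision_threshold = 0.5, pseudocount = 1),
                      class = "bn_classifier")
  patterns <- as.matrix(expand.grid(rep(list(0:2), 7)))
  colnames(patterns) <- feats
  idx <- sample(nrow(patterns), 60)
  post <- posterior(params, patterns[idx, , drop = FALSE])
  for (r in seq_along(idx)) {
    pat <- patterns[idx[r], ]
    joint <- vapply(levels, function(l) {
      prior[[l]] * prod(vapply(feats, function(f) cpts[[f]][pat[[f]] + 1, l],
                               0))
    }, 0)
    expect_equal(unname(post[r, ]), unname(joint / sum(joint)),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(rowSums(post) - 1) < 1e-12))
})

test_that("log-space accumulation survives thousands of features", {
  nfeat <- 5000
  feats <- as.character(seq_len(nfeat))
  cpt <- cbind(n = c(0.6, 0.3, 0.1), d = c(0.1, 0.3, 0.6))
  params <- structure(list(class_levels = c("n", "d"),
                           prior = c(n = 0.5, d = 0.5),
                           cpts = stats::setNames(rep(list(cpt), nfeat),
                                                  feats),
                           b_low = stats::setNames(rep(0, nfeat), feats),
                           b_high = stats::setNames(rep(1, nfeat), feats),
                           features = feats, positive_class = "d",
                           decision_threshold = 0.5, pseudocount = 1),
                      class = "bn_classifier")
  bins <- matrix(0L, 1, nfeat, dimnames = list(NULL, feats))
  post <- posterior(params, bins)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_gt(post[1, "n"], 1 - 1e-9) # all-low overwhelmingly "n"
})

test_that("adding an uninformative feature leaves posteriors unchanged", {
  set.seed(29)
  labels <- sample(c("n", "d"), 60, replace = TRUE)
  bins <- cbind(`100` = sample(0:2, 60, replace = TRUE),
                `200` = sample(0:2, 60, replace = TRUE))
  params1 <- fit_parameters(toy_net("100"), toy_disc(bins, labels))
  params2 <- fit_parameters(toy_net(c("100", "200")),
                            toy_disc(bins, labels))
  flat <- cbind(n = rep(1 / 3, 3), d = rep(1 / 3, 3))
  params2$cpts[["200"]] <- flat
  cases <- cbind(`100` = c(0L, 1L, 2L), `200` = c(2L, 0L, 1L))
  p1 <- posterior(params1, cases[, "100", drop = FALSE])
  p2 <- posterior(params2, cases)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("a posterior exactly at the threshold is a negative call", {
  bins <- cbind(`100` = rep(c(0L, 2L), 10))
  labels <- rep(c("n", "d"), each = 10)
  params <- fit_parameters(toy_net("100"), toy_disc(bins, labels))
  params$cpts[["100"]] <- cbind(n = rep(1 / 3, 3), d = rep(1 / 3, 3))
  x <- matrix(c(5, 15, 25), 3, 1, dimnames = list(NULL, "100"))
  res <- classify(params, x)
  expect_true(all(abs(res$posterior[, "d"] - 0.5) < 1e-12))
  expect_true(all(res$calls == "n"))
})

test_that("ROC of a separable posterior passes through (0, 1) and is monotone", {
  scores <- c(0.9, 0.8, 0.85, 0.2, 0.1, 0.15)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- roc_points(scores, truth)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(roc$tpr[1], 0)
  expect_equal(utils::tail(roc$fpr, 1), 1)
})

test_that("classify reports error rate and ROC against provided labels", {
  tbl <- make_two_feature_table(n_per_class = 150, sep = 2.5, seed = 33)
  disc <- discretize_table(tbl)
  params <- fit_parameters(toy_net("3000"), disc)
  res <- classify(params, tbl)
  expect_lt(res$error_rate, 0.2)
  expect_s3_class(res$roc, "data.frame")
  expect_true(all(diff(res$roc$tpr) >= -1e-12))
  bad <- tbl$abundances[, "5000", drop = FALSE]
  expect_error(classify(params, bad), "missing classifier feature")
})

test_that("a frozen classifier round-trips through JSON", {
  tbl <- make_two_feature_table(seed = 44)
  disc <- discretize_table(tbl)
  params <- fit_parameters(toy_net(c("3000", "5000")), disc)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(params, path)
  back <- read_classifier(path)
  expect_equal(back$prior, params$prior)
  expect_equal(back$cpts, params$cpts)
  expect_equal(back$b_low, params$b_low)
  expect_equal(back$b_high, params$b_high)
  r1 <- classify(params, tbl)
  r2 <- classify(back, tbl)
  expect_identical(r1$calls, r2$calls)
  expect_equal(r1$posterior, r2$posterior)
})
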