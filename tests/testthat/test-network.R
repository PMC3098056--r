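# helper: discretized table + threshold from raw feature columns
disc_and_thr <- function(x, labels, n_perm = 30, seed = 1) {
  tbl <- sample_table(x, labels)
  disc <- discretize_table(tbl)
  thr <- permutation_baseline(tbl, n_perm = n_perm, seed = seed, disc = disc)
  list(tbl = tbl, disc = disc, thr = thr)
}

test_that("bn_net enforces acyclicity and the class root", {
  expect_error(bn_net(data.frame(from = "95", to = "class",
                                 level = "child")), "parents")
  expect_error(bn_net(data.frame(from = c("1", "2"), to = c("2", "1"),
                                 level = "child")), "cycle")
  expect_error(bn_net(data.frame(from = "class", to = "95",
                                 level = "child")), "first-level")
  net <- bn_net(data.frame(from = c("class", "95"), to = c("95", "39"),
                           level = c("first-level", "child")))
  expect_identical(first_level_features(net), "95")
})

test_that("first-level selection uses a strict threshold", {
  tbl <- make_two_feature_table(seed = 2)
  disc <- discretize_table(tbl)
  # threshold exactly at the diagnostic feature's MI: excluded
  thr_eq <- threshold_spec(disc$per_feature_mi[["3000"]], multiplier = 1)
  expect_false("3000" %in%
                 suppressWarnings(select_first_level(disc, thr_eq)))
  # just below: included
  thr_lo <- threshold_spec(disc$per_feature_mi[["3000"]] - 1e-9,
                           multiplier = 1)
  expect_true("3000" %in% suppressWarnings(select_first_level(disc, thr_lo)))
  # above every feature: empty with a warning
  thr_hi <- threshold_spec(2, multiplier = 1)
  expect_warning(sel <- select_first_level(disc, thr_hi), "no feature")
  expect_length(sel, 0)
})

test_that("a child carrying a bounded fraction of its parent gets linked", {
  set.seed(55)
  n <- 400
  labels <- rep(c("normal", "disease"), each = n / 2)
  parent <- rnorm(n, 60, 12) + ifelse(labels == "disease", 12, -12)
  child <- runif(n, 0.5, 1) * parent + rnorm(n, 0, 0.3 * 12)
  indep <- rnorm(n, 45, 9)
  d <- disc_and_thr(cbind(`100` = parent, `200` = child, `300` = indep),
                    labels)
  fl <- suppressWarnings(select_first_level(d$disc, d$thr))
  expect_true("100" %in% fl)
  links <- link_features(d$disc, fl, d$thr)
  key <- paste(pmin(links$feature1, links$feature2),
               pmax(links$feature1, links$feature2))
  expect_true("100 200" %in% key)       # parent-child dependence found
  expect_false(any(grepl("300", key)))  # independent feature not linked
  expect_false(any(links$feature1 == links$feature2)) # self pairs skipped
})

test_that("feature-feature links are compared on the attainable-MI scale", {
  # construct bins directly: feature g is a 2-level copy of f's extremes,
  # so MI(f, g) is capped at 1 bit; the documented rule divides by
  # log2(min alphabet) = 1 for the pair and log2(#classes) = 1 for the
  # class threshold
  bins <- cbind(`10` = rep(c(0L, 1L, 2L), 20),
                `20` = rep(c(0L, 0L, 2L), 20))
  labels <- rep(c("a", "b"), 30)
  disc <- structure(list(bins = bins,
                         per_feature_mi = c(`10` = 0.5, `20` = 0.4),
                         b_low = c(1, 1), b_high = c(2, 2),
                         degenerate = c("none", "none"),
                         class_labels = labels,
                         class_levels = c("a", "b")),
                    class = "disc_table")
  mi_pair <- mutual_information(bins[, 1], bins[, 2])
  scaled <- mi_pair / log2(2)   # alphabet of feature "20" is {0, 2}
  thr_below <- threshold_spec(scaled - 1e-6, multiplier = 1)
  thr_above <- threshold_spec(scaled + 1e-6, multiplier = 1)
  expect_equal(nrow(link_features(disc, "10", thr_below)), 1)
  expect_equal(nrow(link_features(disc, "10", thr_above)), 0)
})

test_that("a serial chain is pruned: class arc removed, parent arc added", {
  set.seed(9)
  n <- 1000
  labels <- rep(c("normal", "disease"), each = n / 2)
  v1 <- rnorm(n, 50, 10) + ifelse(labels == "disease", 10, -10)
  v2 <- v1 + rnorm(n, 0, 0.4 * 10)
  d <- disc_and_thr(cbind(`1000` = v1, `2000` = v2), labels)
  fl <- select_first_level(d$disc, d$thr)
  expect_setequal(fl, c("1000", "2000"))
  op <- orient_and_prune(d$disc, fl, link_features(d$disc, fl, d$thr))
  a <- op$net$arcs
  expect_true(any(a$from == "class" & a$to == "1000"))
  expect_false(any(a$from == "class" & a$to == "2000"))
  expect_true(any(a$from == "1000" & a$to == "2000" & a$level == "child"))
  dec <- op$decisions
  dem <- dec[dec$rule == "serial-chain-demotion", ]
  expect_equal(nrow(dem), 1)
  expect_gt(dem$drop_fraction, 0.75)
  expect_equal(dem$drop_fraction, 1 - dem$mi_after / dem$mi_before,
               tolerance = 1e-12)
})

test_that("independent causes both stay first-level with no feature arc", {
  set.seed(19)
  n <- 400
  labels <- rep(c("normal", "disease"), each = n / 2)
  v1 <- rnorm(n, 50, 10) + ifelse(labels == "disease", 10, -10)
  v2 <- rnorm(n, 30, 5) + ifelse(labels == "disease", -5, 5)
  d <- disc_and_thr(cbind(`1000` = v1, `2000` = v2), labels)
  fl <- select_first_level(d$disc, d$thr)
  op <- orient_and_prune(d$disc, fl, link_features(d$disc, fl, d$thr))
  expect_setequal(first_level_features(op$net), c("1000", "2000"))
})

test_that("demotion requires the drop to strictly exceed the threshold", {
  set.seed(9)
  n <- 1000
  labels <- rep(c("normal", "disease"), each = n / 2)
  v1 <- rnorm(n, 50, 10) + ifelse(labels == "disease", 10, -10)
  v2 <- v1 + rnorm(n, 0, 0.4 * 10)
  d <- disc_and_thr(cbind(`1000` = v1, `2000` = v2), labels)
  fl <- select_first_level(d$disc, d$thr)
  links <- link_features(d$disc, fl, d$thr)
  op <- orient_and_prune(d$disc, fl, links)
  drop <- op$decisions$drop_fraction[
    op$decisions$rule == "serial-chain-demotion"]
  # re-run with the threshold exactly at the observed drop: no demotion
  op_eq <- orient_and_prune(d$disc, fl, links, drop_threshold = drop)
  expect_equal(nrow(op_eq$decisions[
    op_eq$decisions$rule == "serial-chain-demotion", ]), 0)
  op_lt <- orient_and_prune(d$disc, fl, links,
                            drop_threshold = drop - 1e-9)
  expect_equal(nrow(op_lt$decisions[
    op_lt$decisions$rule == "serial-chain-demotion", ]), 1)
  expect_error(orient_and_prune(d$disc, fl, links, drop_threshold = 1),
               "0, 1")
})

test_that("constructed networks are DAGs with demoted features kept reachable", {
  set.seed(71)
  for (i in 1:10) {
    n <- 200
    labels <- rep(c("a", "b"), each = n / 2)
    base <- rnorm(n, 50, 10) + ifelse(labels == "b", 10, -10)
    x <- cbind(base,
               runif(n, 0.4, 1) * base + rnorm(n, 0, 4),
               runif(n, 0.4, 1) * base + rnorm(n, 0, 4),
               rnorm(n, 40, 8))
    colnames(x) <- as.character(c(100, 200, 300, 400))
    d <- disc_and_thr(x, labels, seed = i)
    fl <- suppressWarnings(select_first_level(d$disc, d$thr))
    if (length(fl) == 0) next
    op <- orient_and_prune(d$disc, fl, link_features(d$disc, fl, d$thr))
    g <- igraph::graph_from_data_frame(op$net$arcs)
    expect_true(igraph::is_dag(g))
    # class is the sole root
    indeg <- igraph::degree(g, mode = "in")
    expect_identical(names(indeg)[indeg == 0], "class")
    # every feature node reachable from class
    dist <- igraph::distances(g, v = "class", mode = "out")
    expect_true(all(is.finite(dist)))
  }
})

fake_report <- function(arc_counts, n_networks, errors = c(0.1, 0.2)) {
  structure(list(arc_counts = arc_counts, n_networks = n_networks,
                 repeat_error_rates = errors, threshold = NULL,
                 settings = bn_settings(), plan = cv_plan(n_repeats = 2),
                 fold_details = NULL),
            class = "stability_report")
}

test_that("consensus keeps arcs above the frequency threshold", {
  ac <- data.frame(from = c("class", "class"), to = c("95", "87"),
                   level = "first-level", count = c(501L, 500L))
  net <- build_consensus(fake_report(ac, 1000L), freq_threshold = 0.5)
  expect_identical(first_level_features(net), "95")  # 500/1000 is not > 0.5
  expect_equal(net$arcs$frequency, 0.501)
})

test_that("conflicting arc directions resolve to the majority", {
  ac <- data.frame(from = c("class", "class", "95", "96"),
                   to = c("95", "96", "96", "95"),
                   level = c("first-level", "first-level", "child", "child"),
                   count = c(900L, 900L, 600L, 400L))
  net <- build_consensus(fake_report(ac, 1000L))
  fa <- net$arcs[net$arcs$level == "child", ]
  expect_identical(fa$from, "95")
  expect_identical(fa$to, "96")
  expect_equal(fa$frequency, 1)  # pair occurred in every network
})

test_that("consensus drops feature arcs whose source is unreachable", {
  ac <- data.frame(from = c("class", "77", "88"),
                   to = c("95", "88", "99"),
                   level = c("first-level", "child", "child"),
                   count = c(800L, 700L, 700L))
  net <- build_consensus(fake_report(ac, 1000L))
  # 77 has no class arc and no parent: its arc (and the downstream one)
  # cannot attach to the class-rooted DAG
  expect_identical(net$arcs$to, "95")
})
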