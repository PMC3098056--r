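# Class-rooted Bayesian network construction.
#
# The class node is fixed as the root. Features whose maximized MI with the
# class exceeds the significance threshold become "first-level" candidates;
# feature-feature links above the (scale-adjusted) threshold are then
# organized by conditional-MI tests: a large drop of MI(C; V2 | V1) relative
# to MI(C; V2) indicates a serial chain C -> V1 -> V2, so the class arc to
# V2 is removed and V2 becomes a child of V1.

CLASS_NODE <- "class"

#' Construct a class-rooted Bayesian network
#'
#' @param arcs data.frame with columns `from`, `to`, `level`
#'   (`"first-level"` for class->feature arcs, `"child"` for
#'   feature->feature arcs) and optionally `frequency`.
#' @param class_node name of the class node (default `"class"`).
#' @return object of class `bn_net` with fields `nodes`, `arcs`,
#'   `class_node`. Construction fails if the graph is cyclic, the class
#'   node has a parent, or a `"first-level"` tag sits on a feature arc.
#' @export
bn_net <- function(arcs, class_node = CLASS_NODE) {
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  needed <- c("from", "to", "level")
  if (!all(needed %in% names(arcs))) {
    stop("`arcs` must have columns from, to, level")
  }
  arcs$from <- as.character(arcs$from)
  arcs$to <- as.character(arcs$to)
  arcs$level <- as.character(arcs$level)
  if (any(arcs$to == class_node)) stop("class node cannot have parents")
  if (any(arcs$from == arcs$to)) stop("self-loop arc")
  bad <- arcs$from == class_node & arcs$level != "first-level"
  if (any(bad)) stop("class arcs must carry level 'first-level'")
  bad <- arcs$from != class_node & arcs$level == "first-level"
  if (any(bad)) stop("feature-feature arcs cannot carry level 'first-level'")
  if (anyDuplicated(arcs[c("from", "to")])) stop("duplicate arc")
  feat_arcs <- arcs[arcs$from != class_node, , drop = FALSE]
  if (nrow(feat_arcs) > 0L && has_cycle(feat_arcs)) {
    stop("arcs contain a directed cycle")
  }
  nodes <- unique(c(class_node, arcs$from, arcs$to))
  structure(list(nodes = nodes, arcs = arcs, class_node = class_node),
            class = "bn_net")
}

#' First-level features of a network
#'
#' @param net a [bn_net()].
#' @return character vector of features with a class arc (the Markov
#'   blanket used by the classifier).
#' @export
first_level_features <- function(net) {
  stopifnot(inherits(net, "bn_net"))
  net$arcs$to[net$arcs$from == net$class_node]
}

#' @export
print.bn_net <- function(x, ...) {
  fl <- first_level_features(x)
  nf <- sum(x$arcs$from != x$class_node)
  cat("Class-rooted Bayesian network: ", length(x$nodes) - 1L,
      " feature nodes\n", sep = "")
  cat("  first-level (class arcs): ", length(fl),
      if (length(fl) > 0) paste0(" [", paste(fl, collapse = ", "), "]"),
      "\n", sep = "")
  cat("  feature-feature arcs: ", nf, "\n", sep = "")
  invisible(x)
}

# TRUE if a directed path source -> ... -> target exists in the arc set
path_exists <- function(arcs, source, target) {
  if (source == target) return(TRUE)
  frontier <- source
  seen <- character(0)
  while (length(frontier) > 0L) {
    nxt <- unique(arcs$to[arcs$from %in% frontier])
    if (target %in% nxt) return(TRUE)
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    frontier <- nxt
  }
  FALSE
}

has_cycle <- function(arcs) {
  for (i in seq_len(nrow(arcs))) {
    if (path_exists(arcs, arcs$to[i], arcs$from[i])) return(TRUE)
  }
  FALSE
}

#' Select first-level features by the MI significance threshold
#'
#' @param disc a [discretize_table()] result with `per_feature_mi`
#'   populated.
#' @param thr a [threshold_spec()].
#' @return character vector of features with
#'   `per_feature_mi > effective_threshold` (strict inequality; a feature
#'   exactly at the threshold is excluded). Empty results are allowed and
#'   raise a warning.
#' @export
select_first_level <- function(disc, thr) {
  stopifnot(inherits(disc, "disc_table"), inherits(thr, "threshold_spec"))
  sel <- names(disc$per_feature_mi)[disc$per_feature_mi > thr$effective_threshold]
  if (length(sel) == 0L) {
    warning("no feature exceeds the MI significance threshold (",
            sprintf("%.5f", thr$effective_threshold), " bits)")
  }
  sel
}

# observed alphabet size of each binned feature column
bin_alphabets <- function(bins) {
  apply(bins, 2L, function(b) length(unique(b)))
}

#' Link first-level features to other features by mutual information
#'
#' Every (first-level, other feature) pair is tested on the already
#' discretized values. Because the maximum attainable MI differs between a
#' class/feature pair (bounded by `log2(#classes)`) and a feature/feature
#' pair (bounded by `log2` of the smaller alphabet, 3 bins in general), the
#' comparison is made on the scale of the attainable maximum: a pair is
#' linked when `mi / log2(min alphabet)` exceeds
#' `effective_threshold / log2(#classes)`.
#'
#' @param disc a [discretize_table()] result.
#' @param first_level character vector from [select_first_level()].
#' @param thr a [threshold_spec()].
#' @return data.frame of candidate (undirected) links with columns
#'   `feature1` (first-level), `feature2`, `mi`, `scaled_mi`,
#'   `both_first_level`. First-level pairs appear once.
#' @export
link_features <- function(disc, first_level, thr) {
  stopifnot(inherits(disc, "disc_table"))
  if (length(first_level) == 0L) stop("`first_level` is empty")
  bins <- disc$bins
  feats <- colnames(bins)
  alpha <- bin_alphabets(bins)
  nclass <- length(disc$class_levels)
  rel_thr <- thr$effective_threshold / log2(nclass)
  out <- list()
  done <- character(0)
  for (f in first_level) {
    bf <- bins[, f]
    for (g in feats) {
      if (g == f) next
      key <- paste(sort(c(f, g)), collapse = "|")
      if (g %in% first_level && key %in% done) next
      done <- c(done, key)
      amin <- min(alpha[[f]], alpha[[g]])
      if (amin < 2L) next
      mi <- fast_mi(bf, bins[, g], 3L, 3L)
      smi <- mi / log2(amin)
      if (smi > rel_thr) {
        out[[length(out) + 1L]] <- data.frame(
          feature1 = f, feature2 = g, mi = mi, scaled_mi = smi,
          both_first_level = g %in% first_level,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(feature1 = character(0), feature2 = character(0),
                      mi = numeric(0), scaled_mi = numeric(0),
                      both_first_level = logical(0)))
  }
  do.call(rbind, out)
}

arc_decision <- function(source, target, rule, mi_before = NA_real_,
                         mi_after = NA_real_, drop_fraction = NA_real_) {
  data.frame(source = source, target = target, rule = rule,
             mi_before = mi_before, mi_after = mi_after,
             drop_fraction = drop_fraction, stringsAsFactors = FALSE)
}

#' Orient links and prune serial chains by conditional mutual information
#'
#' For each linked pair of first-level features (V1, V2) the conditional
#' mutual informations MI(C; V2 | V1) and MI(C; V1 | V2) are computed. A
#' fractional drop `1 - MI(C; V2 | V1) / MI(C; V2)` strictly greater than
#' `drop_threshold` identifies the serial chain C -> V1 -> V2: the class
#' arc to V2 is removed and V2 becomes a child of V1. If neither direction
#' drops, both features stay first-level and the arc between them is
#' directed away from the feature retaining the greater conditional MI with
#' the class. Links from a first-level feature to a non-first-level feature
#' are directed immediately (class-causality assumption); by default a
#' non-first-level feature is attached only to its single strongest
#' first-level parent.
#'
#' Pairs are processed in descending order of the stronger member's MI with
#' the class; any orientation that would create a directed cycle is skipped
#' and logged, so the result is always a DAG with the class as sole root.
#'
#' @param disc a [discretize_table()] result.
#' @param first_level features from [select_first_level()].
#' @param links candidate links from [link_features()].
#' @param drop_threshold fractional conditional-MI drop (in (0,1), default
#'   0.75) required to demote a feature; the drop must strictly exceed the
#'   threshold.
#' @param multi_parent allow a child feature to keep arcs from several
#'   parents (default `FALSE`).
#' @return list with `net` (a [bn_net()]) and `decisions` (an arc-decision
#'   log data.frame with columns `source`, `target`, `rule`, `mi_before`,
#'   `mi_after`, `drop_fraction`).
#' @export
orient_and_prune <- function(disc, first_level, links, drop_threshold = 0.75,
                             multi_parent = FALSE) {
  stopifnot(inherits(disc, "disc_table"))
  if (drop_threshold <= 0 || drop_threshold >= 1) {
    stop("`drop_threshold` must be in (0, 1)")
  }
  bins <- disc$bins
  labels <- disc$class_labels
  mi_class <- disc$per_feature_mi
  decisions <- list()
  feat_arcs <- data.frame(from = character(0), to = character(0),
                          level = character(0), stringsAsFactors = FALSE)
  demoted <- character(0)

  add_arc <- function(from, to) {
    feat_arcs[nrow(feat_arcs) + 1L, ] <<- list(from, to, "child")
  }
  log_dec <- function(d) decisions[[length(decisions) + 1L]] <<- d

  for (f in first_level) {
    log_dec(arc_decision(CLASS_NODE, f, "class-link",
                         mi_before = mi_class[[f]]))
  }

  # ---- first-level pairs: serial-chain demotion / CMI direction ----
  ff <- links[links$both_first_level, , drop = FALSE]
  if (nrow(ff) > 0L) {
    strength <- pmax(mi_class[ff$feature1], mi_class[ff$feature2])
    ff <- ff[order(-strength, ff$feature1, ff$feature2), , drop = FALSE]
    for (i in seq_len(nrow(ff))) {
      a <- ff$feature1[i]
      b <- ff$feature2[i]
      # a = stronger member (by MI with class)
      if (mi_class[[b]] > mi_class[[a]]) { tmp <- a; a <- b; b <- tmp }
      if (a %in% demoted || b %in% demoted) {
        if (multi_parent && xor(a %in% demoted, b %in% demoted)) {
          src <- if (a %in% demoted) b else a
          dst <- if (a %in% demoted) a else b
          if (!path_exists(feat_arcs, dst, src)) add_arc(src, dst)
        } else {
          log_dec(arc_decision(a, b, "demoted-skip"))
        }
        next
      }
      cmi_b_given_a <- conditional_mutual_information(labels, bins[, b], bins[, a])
      cmi_a_given_b <- conditional_mutual_information(labels, bins[, a], bins[, b])
      drop_b <- if (mi_class[[b]] > 0) 1 - cmi_b_given_a / mi_class[[b]] else 0
      drop_a <- if (mi_class[[a]] > 0) 1 - cmi_a_given_b / mi_class[[a]] else 0
      # when both directions drop past the threshold, the parent is the
      # feature retaining the greater conditional MI with the class
      if (drop_b > drop_threshold &&
          (drop_a <= drop_threshold || cmi_a_given_b >= cmi_b_given_a)) {
        if (path_exists(feat_arcs, b, a)) {
          log_dec(arc_decision(a, b, "cycle-skip"))
        } else {
          demoted <- c(demoted, b)
          add_arc(a, b)
          log_dec(arc_decision(a, b, "serial-chain-demotion",
                               mi_before = mi_class[[b]],
                               mi_after = cmi_b_given_a,
                               drop_fraction = drop_b))
        }
      } else if (drop_a > drop_threshold) {
        if (path_exists(feat_arcs, a, b)) {
          log_dec(arc_decision(b, a, "cycle-skip"))
        } else {
          demoted <- c(demoted, a)
          add_arc(b, a)
          log_dec(arc_decision(b, a, "serial-chain-demotion",
                               mi_before = mi_class[[a]],
                               mi_after = cmi_a_given_b,
                               drop_fraction = drop_a))
        }
      } else {
        # both stay first level; direct away from the feature with the
        # greater retained conditional MI with the class
        src <- if (cmi_a_given_b >= cmi_b_given_a) a else b
        dst <- if (identical(src, a)) b else a
        if (path_exists(feat_arcs, dst, src)) {
          log_dec(arc_decision(src, dst, "cycle-skip"))
        } else {
          add_arc(src, dst)
          log_dec(arc_decision(src, dst, "cmi-direction",
                               mi_before = if (identical(src, a)) cmi_a_given_b else cmi_b_given_a,
                               mi_after = if (identical(src, a)) cmi_b_given_a else cmi_a_given_b))
        }
      }
    }
  }

  # ---- first-level -> other-feature attachments ----
  fo <- links[!links$both_first_level, , drop = FALSE]
  if (nrow(fo) > 0L) {
    for (o in unique(fo$feature2)) {
      cand <- fo[fo$feature2 == o, , drop = FALSE]
      cand <- cand[order(-cand$mi, cand$feature1), , drop = FALSE]
      keep <- if (multi_parent) seq_len(nrow(cand)) else 1L
      for (i in seq_len(nrow(cand))) {
        parent <- cand$feature1[i]
        if (i %in% keep) {
          if (path_exists(feat_arcs, o, parent)) {
            log_dec(arc_decision(parent, o, "cycle-skip"))
          } else {
            add_arc(parent, o)
            log_dec(arc_decision(parent, o, "child-link",
                                 mi_before = cand$mi[i]))
          }
        } else {
          log_dec(arc_decision(parent, o, "multi-parent-skip",
                               mi_before = cand$mi[i]))
        }
      }
    }
  }

  keep_fl <- setdiff(first_level, demoted)
  arcs <- rbind(
    if (length(keep_fl) > 0L) {
      data.frame(from = CLASS_NODE, to = keep_fl, level = "first-level",
                 stringsAsFactors = FALSE)
    },
    feat_arcs)
  if (is.null(arcs)) {
    arcs <- data.frame(from = character(0), to = character(0),
                       level = character(0))
  }
  net <- bn_net(arcs)
  decisions <- if (length(decisions) > 0L) do.call(rbind, decisions) else
    arc_decision(character(0), character(0), character(0))[0L, ]
  list(net = net, decisions = decisions)
}

#' Build the full network for one training table
#'
#' Convenience wrapper chaining [discretize_table()],
#' [select_first_level()], [link_features()] and [orient_and_prune()]
#' with a precomputed threshold.
#'
#' @param tbl a [sample_table()] (training cases only).
#' @param thr a [threshold_spec()]; computed by [permutation_baseline()] if
#'   missing.
#' @param settings a [bn_settings()] list.
#' @return list with `net`, `decisions`, `disc` (the discretization used)
#'   and `thr`.
#' @export
build_network <- function(tbl, thr = NULL, settings = bn_settings()) {
  if (is.null(thr)) {
    thr <- permutation_baseline(tbl, n_perm = settings$n_perm,
                                multiplier = settings$multiplier,
                                seed = settings$seed,
                                exhaustive_cap = settings$exhaustive_cap,
                                n_candidates = settings$n_candidates)
  }
  disc <- discretize_table(tbl, exhaustive_cap = settings$exhaustive_cap,
                           n_candidates = settings$n_candidates)
  fl <- suppressWarnings(select_first_level(disc, thr))
  if (length(fl) == 0L) {
    return(list(net = bn_net(data.frame(from = character(0),
                                        to = character(0),
                                        level = character(0))),
                decisions = NULL, disc = disc, thr = thr))
  }
  links <- link_features(disc, fl, thr)
  op <- orient_and_prune(disc, fl, links,
                         drop_threshold = settings$drop_threshold,
                         multi_parent = settings$multi_parent)
  list(net = op$net, decisions = op$decisions, disc = disc, thr = thr)
}

#' Consensus ("average") network from cross-validation arc tallies
#'
#' Keeps arcs appearing in more than `freq_threshold` of the recorded
#' networks. Feature-arc occurrence is counted over both directions of a
#' pair; the direction kept is the majority direction among occurrences.
#' Feature arcs are added in descending frequency order; an arc whose
#' source is not reachable from the class, or that would create a cycle,
#' is skipped so the consensus is always a class-rooted DAG.
#'
#' @param report a [run_cv()] stability report.
#' @param freq_threshold fraction of networks (default 0.5) an arc must
#'   strictly exceed.
#' @return a [bn_net()] whose arcs carry a `frequency` column.
#' @export
build_consensus <- function(report, freq_threshold = 0.5) {
  stopifnot(inherits(report, "stability_report"))
  ac <- report$arc_counts
  if (nrow(ac) == 0L) stop("empty stability report")
  N <- report$n_networks
  cl <- ac[ac$from == CLASS_NODE, , drop = FALSE]
  cl <- cl[cl$count > freq_threshold * N, , drop = FALSE]
  arcs <- data.frame(from = character(0), to = character(0),
                     level = character(0), frequency = numeric(0),
                     stringsAsFactors = FALSE)
  if (nrow(cl) > 0L) {
    arcs <- data.frame(from = cl$from, to = cl$to, level = "first-level",
                       frequency = cl$count / N, stringsAsFactors = FALSE)
  }
  fa <- ac[ac$from != CLASS_NODE, , drop = FALSE]
  if (nrow(fa) > 0L) {
    key <- apply(cbind(fa$from, fa$to), 1L,
                 function(r) paste(sort(r), collapse = "|"))
    agg <- split(fa, key)
    pair_tot <- vapply(agg, function(d) sum(d$count), 0)
    keep <- names(agg)[pair_tot > freq_threshold * N]
    keep <- keep[order(-pair_tot[keep], keep)]
    for (k in keep) {
      d <- agg[[k]]
      d <- d[order(-d$count, d$from), , drop = FALSE]
      from <- d$from[1L]
      to <- d$to[1L]
      nodes <- unique(c(CLASS_NODE, arcs$from, arcs$to))
      if (!(from %in% nodes)) next # source not reachable from class
      feat <- arcs[arcs$from != CLASS_NODE, , drop = FALSE]
      if (path_exists(feat, to, from)) next
      arcs[nrow(arcs) + 1L, ] <- list(from, to, "child", sum(d$count) / N)
    }
  }
  if (nrow(arcs) == 0L) stop("no arc exceeds the consensus frequency threshold")
  bn_net(arcs)
}

#' Export a network to disk
#'
#' @param net a [bn_net()].
#' @param path output file path.
#' @param format `"edge-csv"` (3/4-column `source,target,level[,frequency]`
#'   CSV that round-trips through [import_network_csv()]), `"dot"`, or
#'   `"graphml"`.
#' @export
export_network <- function(net, path, format = c("edge-csv", "dot", "graphml")) {
  stopifnot(inherits(net, "bn_net"))
  format <- match.arg(format)
  if (nrow(net$arcs) == 0L) stop("refusing to export a network with no arcs")
  if (format == "edge-csv") {
    out <- net$arcs
    names(out)[1:2] <- c("source", "target")
    utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(net$arcs, directed = TRUE)
  igraph::write_graph(g, path, format = if (format == "dot") "dot" else "graphml")
  invisible(path)
}

#' Re-import a network from an edge CSV
#'
#' @param path file written by [export_network()] with format
#'   `"edge-csv"`. Acyclicity and root constraints are re-validated on
#'   import.
#' @return a [bn_net()].
#' @export
import_network_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("from", "to")
  bn_net(df)
}
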