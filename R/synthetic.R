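# Synthetic TOF-MS peak tables with known ground-truth structure.
#
# The generator emulates the structure of processed MALDI-TOF peak tables:
# a handful of primary diagnostic peaks whose class-conditional Gaussian
# means sit 1-2 SD apart, correlated "child" peaks that carry random but
# bounded fractions of a parent peak (protein modifications, doubly charged
# ions), a convolution pair where part of one peak's signal leaks into a
# neighboring peak, a pair of fragment peaks driven by an unobserved parent
# molecule, and class-independent noise peaks drawn from a single
# distribution. Intensities are truncated at zero after all mixing.

#' Specification for a synthetic peak table
#'
#' Defaults are scaled to a typical discovery study: 96 features, 200
#' cases per class, 5 primary markers with class-mean separations spread
#' over 1-2 SD, 7 child features (modifications plus one doubly charged
#' ion at half the parent m/z), one convolution pair and one
#' hidden-parent fragment pair.
#'
#' @param n_cases_per_class cases per class (default 200).
#' @param n_features number of peak features (default 96).
#' @param primaries data.frame with `feature` (index) and `effect` (class
#'   mean separation in SD units, in `[1, 2]`) and `sign` (+1: higher in
#'   disease).
#' @param children data.frame with `parent`, `child` (indices), `lo`,
#'   `hi` (per-case transfer-fraction bounds) and `kind`
#'   (`"modification"` or `"doubly-charged"`; a doubly charged child is
#'   assigned m/z = parent m/z / 2).
#' @param convolution data.frame with `donor`, `acceptor` (indices) and
#'   `fraction` of the donor's signal moved to the acceptor per case.
#' @param hidden_pair list with `features` (two indices), `effect` (SD
#'   separation of the unobserved parent), `lo1`, `hi1`, `lo2`, `hi2`
#'   (transfer bounds for the two fragments; the first fragment is coupled
#'   more tightly so it systematically carries more class information) and
#'   `noise_frac` (fragment noise SD as a fraction of the latent SD;
#'   smaller than `child_noise_frac` because fragments of one molecule
#'   track it closely).
#' @param child_noise_frac SD of a child's independent Gaussian noise as a
#'   fraction of its parent's SD (default 0.3).
#' @param mean_range,cv_range ranges for the per-feature baseline mean and
#'   coefficient of variation (defaults 20-100 intensity units and
#'   0.15-0.35).
#' @param class_names the two class labels.
#' @param seed integer seed; generation is bit-identical given the seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    n_cases_per_class = 200L,
    n_features = 96L,
    primaries = data.frame(feature = c(10L, 25L, 40L, 60L, 80L),
                           effect = c(2.0, 1.75, 1.5, 1.25, 1.0),
                           sign = c(1, -1, 1, -1, 1)),
    children = data.frame(parent = c(10L, 10L, 25L, 40L, 60L, 80L, 10L),
                          child = c(11L, 12L, 26L, 41L, 61L, 81L, 3L),
                          lo = 0.5, hi = 1.0,
                          kind = c(rep("modification", 6), "doubly-charged")),
    convolution = data.frame(donor = 25L, acceptor = 24L, fraction = 0.3),
    hidden_pair = list(features = c(50L, 51L), effect = 2.0,
                       lo1 = 0.75, hi1 = 0.95, lo2 = 0.35, hi2 = 0.65,
                       noise_frac = 0.15),
    child_noise_frac = 0.3,
    mean_range = c(20, 100),
    cv_range = c(0.15, 0.35),
    class_names = c("normal", "disease"),
    seed = 1L) {
  spec <- structure(list(n_cases_per_class = as.integer(n_cases_per_class),
                         n_features = as.integer(n_features),
                         primaries = primaries, children = children,
                         convolution = convolution, hidden_pair = hidden_pair,
                         child_noise_frac = child_noise_frac,
                         mean_range = mean_range, cv_range = cv_range,
                         class_names = class_names, seed = as.integer(seed)),
                    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  p <- spec$n_features
  prim <- spec$primaries$feature
  kids <- spec$children$child
  hid <- spec$hidden_pair$features
  acc <- spec$convolution$acceptor
  all_idx <- c(prim, kids, hid, acc, spec$children$parent,
               spec$convolution$donor)
  if (length(all_idx) > 0 && (any(all_idx < 1L) || any(all_idx > p))) {
    stop("feature indices must lie in [1, n_features]")
  }
  roles <- c(prim, kids, hid, acc)
  if (anyDuplicated(roles)) {
    stop("primary, child, hidden and acceptor feature indices must be disjoint")
  }
  if (nrow(spec$children) > 0 &&
      !all(spec$children$parent %in% prim)) {
    stop("every child's parent must be a primary feature")
  }
  if (nrow(spec$convolution) > 0 &&
      !all(spec$convolution$donor %in% prim)) {
    stop("every convolution donor must be a primary feature")
  }
  if (nrow(spec$primaries) > 0 &&
      (any(spec$primaries$effect < 0) )) {
    stop("primary effect sizes must be non-negative")
  }
  if (length(spec$class_names) != 2L) stop("exactly two class names required")
  invisible(spec)
}

# m/z grid: evenly spaced over 2-13 kDa, with doubly charged children moved
# to half their parent's m/z.
synthetic_mz <- function(spec) {
  mz <- round(seq(2000, 13000, length.out = spec$n_features), 1)
  dc <- spec$children[spec$children$kind == "doubly-charged", , drop = FALSE]
  if (nrow(dc) > 0L) {
    mz[dc$child] <- round(mz[dc$parent] / 2, 1)
  }
  if (anyDuplicated(mz)) stop("m/z grid collision; adjust spec indices")
  mz
}

#' Generate a synthetic peak table with known structure
#'
#' @param spec a [synthetic_spec()].
#' @param n_cases_per_class optional override of the spec's case count
#'   (used by [make_lockbox()]).
#' @param seed optional override of the spec's seed.
#' @return list with `table` (a [sample_table()]) and `truth`, the ground
#'   truth: `primaries`, `class_arcs`, `child_arcs` (parent -> child,
#'   including the convolution acceptor as a child of its donor),
#'   `hidden_pair` and `noise_features` (designated class-independent
#'   features), all as m/z node names.
#' @export
generate_peak_table <- function(spec, n_cases_per_class = NULL, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  npc <- if (is.null(n_cases_per_class)) spec$n_cases_per_class else
    as.integer(n_cases_per_class)
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  p <- spec$n_features
  n <- 2L * npc
  labels <- rep(spec$class_names, each = npc)
  is_disease <- labels == spec$class_names[2L]
  mz <- synthetic_mz(spec)

  # Per-feature baseline distribution parameters are part of the generative
  # model's identity: they are always drawn from the spec's own seed, so
  # independent case draws (e.g. training vs lockbox) share one model.
  pars <- with_local_seed(spec$seed, {
    mu <- stats::runif(p, spec$mean_range[1L], spec$mean_range[2L])
    list(mu = mu, sdv = mu * stats::runif(p, spec$cv_range[1L],
                                          spec$cv_range[2L]))
  })
  mu <- pars$mu
  sdv <- pars$sdv

  # case-level draws use an offset stream so they never overlap the
  # parameter draws
  x <- with_local_seed(seed + 1000003L, {
    x <- matrix(0, n, p)
    for (j in seq_len(p)) {
      x[, j] <- stats::rnorm(n, mu[j], sdv[j])
    }
    # primaries: shift the class-conditional means effect*SD apart
    for (i in seq_len(nrow(spec$primaries))) {
      j <- spec$primaries$feature[i]
      delta <- spec$primaries$sign[i] * spec$primaries$effect[i] * sdv[j]
      x[, j] <- x[, j] + ifelse(is_disease, delta / 2, -delta / 2)
    }
    # children: random, bounded fraction of the parent plus own noise
    for (i in seq_len(nrow(spec$children))) {
      pa <- spec$children$parent[i]
      ch <- spec$children$child[i]
      u <- stats::runif(n, spec$children$lo[i], spec$children$hi[i])
      x[, ch] <- u * x[, pa] +
        stats::rnorm(n, 0, spec$child_noise_frac * sdv[pa])
    }
    # hidden-parent fragments: two observed children of an unobserved
    # class-dependent molecule
    hp <- spec$hidden_pair
    if (length(hp$features) == 2L) {
      lat_mu <- mean(spec$mean_range)
      lat_sd <- lat_mu * mean(spec$cv_range)
      lat <- stats::rnorm(n, lat_mu, lat_sd) +
        ifelse(is_disease, hp$effect * lat_sd / 2, -hp$effect * lat_sd / 2)
      nf <- if (is.null(hp$noise_frac)) spec$child_noise_frac else hp$noise_frac
      u1 <- stats::runif(n, hp$lo1, hp$hi1)
      u2 <- stats::runif(n, hp$lo2, hp$hi2)
      x[, hp$features[1L]] <- u1 * lat + stats::rnorm(n, 0, nf * lat_sd)
      x[, hp$features[2L]] <- u2 * lat + stats::rnorm(n, 0, nf * lat_sd)
    }
    # convolution: move a fixed fraction of the donor into the acceptor
    for (i in seq_len(nrow(spec$convolution))) {
      dn <- spec$convolution$donor[i]
      ac <- spec$convolution$acceptor[i]
      fr <- spec$convolution$fraction[i]
      moved <- fr * x[, dn]
      x[, dn] <- x[, dn] - moved
      x[, ac] <- x[, ac] + moved
    }
    pmax(x, 0) # intensities are non-negative
  })

  colnames(x) <- format_mz(mz)
  tbl <- sample_table(x, labels, feature_ids = mz)
  nm <- colnames(x)
  prim_nm <- nm[spec$primaries$feature]
  child_arcs <- data.frame(
    parent = c(nm[spec$children$parent], nm[spec$convolution$donor]),
    child = c(nm[spec$children$child], nm[spec$convolution$acceptor]),
    kind = c(spec$children$kind, rep("convolution", nrow(spec$convolution))),
    stringsAsFactors = FALSE)
  special <- c(spec$primaries$feature, spec$children$child,
               spec$hidden_pair$features, spec$convolution$acceptor)
  truth <- list(primaries = prim_nm,
                class_arcs = data.frame(from = rep(CLASS_NODE,
                                                   length(prim_nm)),
                                        to = prim_nm,
                                        stringsAsFactors = FALSE),
                child_arcs = child_arcs,
                hidden_pair = nm[spec$hidden_pair$features],
                noise_features = nm[setdiff(seq_len(p), special)])
  list(table = tbl, truth = truth)
}

#' Split the generative model into training and lockbox tables
#'
#' Either draws two independent tables from the same generative parameters
#' (default) or partitions a single draw; class balance is preserved
#' within one case in both modes.
#'
#' @param spec a [synthetic_spec()].
#' @param fraction lockbox fraction in (0, 1) (default 1/3).
#' @param seed seed for the draw(s); the lockbox of an independent draw
#'   uses `seed + 1`.
#' @param mode `"independent"` (two draws) or `"partition"` (split one
#'   draw).
#' @return list with `training` and `lockbox` [sample_table()]s and
#'   `truth`.
#' @export
make_lockbox <- function(spec, fraction = 1 / 3, seed = spec$seed,
                         mode = c("independent", "partition")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  npc <- spec$n_cases_per_class
  n_lock <- as.integer(round(fraction * npc))
  n_train <- npc - n_lock
  if (n_lock < 1L || n_train < 1L) stop("degenerate lockbox fraction")
  if (mode == "independent") {
    tr <- generate_peak_table(spec, n_cases_per_class = n_train, seed = seed)
    lb <- generate_peak_table(spec, n_cases_per_class = n_lock,
                              seed = seed + 1L)
    return(list(training = tr$table, lockbox = lb$table, truth = tr$truth))
  }
  full <- generate_peak_table(spec, seed = seed)
  labels <- full$table$class_labels
  lock_idx <- unlist(lapply(spec$class_names, function(cl) {
    idx <- which(labels == cl)
    idx[seq_len(n_lock)]
  }))
  train_idx <- setdiff(seq_along(labels), lock_idx)
  list(training = subset_cases(full$table, train_idx),
       lockbox = subset_cases(full$table, lock_idx),
       truth = full$truth)
}
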