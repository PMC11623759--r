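# Stage 1 of MiCA: repeated-holdout signed-iterative Random Forest (rh-SiRF).
#
# Each repeat draws a train/test holdout; on bootstrap resamples of the
# training part an iteratively feature-reweighted regression forest is grown,
# its decision paths are turned into signed itemsets, and random intersection
# trees (RIT) surface itemsets recurring across paths. Candidates are ranked
# by stability: the fraction of holdout repeats in which they reappear.
#
# Signed items are coded as integers: feature v on the low side of a split
# threshold is 2v-1, on the high side 2v.

item_code <- function(feature, high) 2L * feature - 1L + as.integer(high)
item_feature <- function(code) (code + 1L) %/% 2L
item_sign <- function(code) ifelse(code %% 2L == 0L, "high", "low")

#' Discovery-stage configuration
#'
#' @param n_repeats Number of repeated train/test holdouts (default 1000).
#' @param n_bootstraps Bootstrap resamples of each training partition
#'   (default 250).
#' @param train_fraction Fraction of samples in the training partition
#'   (default 0.60; the remaining 40% form the holdout used to screen each
#'   repeat's out-of-sample fit).
#' @param n_irf_iterations Feature-reweighting iterations of the iterative
#'   random forest (default 3).
#' @param n_trees Trees per forest (default 100).
#' @param max_depth,min_node_size Tree size controls (defaults 5 and 5).
#' @param rit_depth,rit_children,rit_trees Random-intersection-tree shape
#'   (defaults: depth 5, 2 children, 50 trees).
#' @param min_stability Minimum holdout-stability for a candidate to enter
#'   the final clique network (default 0.5).
#' @param seed Master seed; the whole discovery run is deterministic given it.
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(n_repeats = 1000L, n_bootstraps = 250L,
                             train_fraction = 0.60, n_irf_iterations = 3L,
                             n_trees = 100L, max_depth = 5L,
                             min_node_size = 5L, rit_depth = 5L,
                             rit_children = 2L, rit_trees = 50L,
                             min_stability = 0.5, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("`train_fraction` must be in (0, 1)")
  for (nm in c("n_repeats", "n_bootstraps", "n_irf_iterations", "n_trees",
               "max_depth", "min_node_size", "rit_depth", "rit_children",
               "rit_trees"))
    check_count(get(nm), nm)
  check_probability(min_stability, "min_stability")
  structure(list(n_repeats = as.integer(n_repeats),
                 n_bootstraps = as.integer(n_bootstraps),
                 train_fraction = train_fraction,
                 n_irf_iterations = as.integer(n_irf_iterations),
                 n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size),
                 rit_depth = as.integer(rit_depth),
                 rit_children = as.integer(rit_children),
                 rit_trees = as.integer(rit_trees),
                 min_stability = min_stability, seed = as.integer(seed)),
            class = "discovery_config")
}

#' @rdname discovery_config
#' @details `fast_discovery_config()` is a scaled-down preset (50 repeats x
#'   20 bootstraps, 60-tree forests, 60 RIT trees) for interactive use and
#'   simulation studies.
#' @export
fast_discovery_config <- function(seed = 1L, ...) {
  args <- list(n_repeats = 50L, n_bootstraps = 20L, n_trees = 60L,
               n_irf_iterations = 3L, rit_trees = 60L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(discovery_config, args)
}

#' Grow a feature-weighted regression forest
#'
#' Wraps [ranger::ranger()] so that each node's candidate split variables are
#' sampled with probability proportional to `feature_weights` — the
#' reweighting mechanism of the iterative random forest. Impurity importances
#' are recorded for the next iteration.
#'
#' @param X Numeric predictor matrix (samples x features).
#' @param y Numeric outcome.
#' @param feature_weights Non-negative weights, one per feature, not all
#'   zero; normalised internally.
#' @param n_trees,max_depth,min_node_size Forest controls.
#' @param seed Integer seed (single-threaded, deterministic).
#' @return A `ranger` forest object.
#' @export
grow_weighted_forest <- function(X, y, feature_weights,
                                 n_trees = 100L, max_depth = 5L,
                                 min_node_size = 5L, seed = 1L) {
  X <- as_predictor_matrix(X)
  if (length(feature_weights) != ncol(X))
    stopf("need one weight per feature (%d != %d)", length(feature_weights),
          ncol(X))
  if (any(feature_weights < 0)) stopf("feature weights must be non-negative")
  s <- sum(feature_weights)
  if (s <= 0) stopf("feature weights must not all be zero")
  w <- feature_weights / s
  # candidate draws cannot exceed the number of selectable features
  mtry <- max(1L, min(floor(sqrt(ncol(X))), sum(w > 0)))
  withCallingHandlers(
    ranger::ranger(x = X, y = y, num.trees = n_trees, max.depth = max_depth,
                   min.node.size = min_node_size, split.select.weights = w,
                   mtry = mtry, importance = "impurity", seed = seed,
                   num.threads = 1L, verbose = FALSE),
    warning = function(cond) {
      if (grepl("Split select weights", conditionMessage(cond)))
        invokeRestart("muffleWarning")
    })
}

as_predictor_matrix <- function(X) {
  if (inherits(X, "feature_table")) X <- X$values
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' Iterated feature reweighting
#'
#' The iterative-random-forest loop: starting from uniform weights, each
#' iteration grows a weighted forest and sets the next weights proportional
#' to its (non-negative) impurity-decrease importances. Returns the weights
#' after the last iteration, i.e. the normalised importances of the final
#' forest; with `n_iterations = 1` these are plain uniform-weight forest
#' importances.
#'
#' @inheritParams grow_weighted_forest
#' @param n_iterations Number of reweighting iterations (>= 1).
#' @return Normalised feature-weight vector (sums to 1).
#' @export
iterate_importance <- function(X, y, n_iterations = 3L, n_trees = 100L,
                               max_depth = 5L, min_node_size = 5L,
                               seed = 1L) {
  X <- as_predictor_matrix(X)
  n_iterations <- check_count(n_iterations, "n_iterations")
  seeds <- child_seeds(seed, n_iterations)
  w <- rep(1 / ncol(X), ncol(X))
  for (k in seq_len(n_iterations)) {
    f <- grow_weighted_forest(X, y, w, n_trees = n_trees,
                              max_depth = max_depth,
                              min_node_size = min_node_size, seed = seeds[k])
    imp <- pmax(ranger::importance(f), 0)
    w <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / ncol(X), ncol(X))
  }
  w
}

#' Signed decision-path itemsets of a forest
#'
#' Walks every root-to-leaf path of every tree and records the set of
#' (feature, side) pairs encountered: a split sends samples with values at or
#' below the threshold to the "low" side and the rest to the "high" side.
#' Repeated use of the same (feature, side) along a path is deduplicated.
#' Each leaf's itemset is weighted by the number of rows of `X` reaching that
#' leaf; empty paths (unsplit trees) and unreached leaves are dropped.
#'
#' @param forest A trained [ranger::ranger()] regression forest.
#' @param X The matrix whose rows weight the leaves (normally the training
#'   data).
#' @return A `signed_itemsets` object: list with `sets` (integer signed-item
#'   codes per leaf), `weights`, and `feature_names`.
#' @export
signed_itemsets <- function(forest, X) {
  X <- as_predictor_matrix(X)
  fr <- forest$forest
  term <- predict(forest, X, type = "terminalNodes",
                  num.threads = 1L)$predictions
  sets <- vector("list", 0L)
  weights <- numeric(0L)
  for (t in seq_len(fr$num.trees)) {
    left <- fr$child.nodeIDs[[t]][[1L]]
    right <- fr$child.nodeIDs[[t]][[2L]]
    var0 <- fr$split.varIDs[[t]]
    nn <- length(left)
    if (nn <= 1L) next  # unsplit tree: empty path
    terminal <- left == 0L & right == 0L
    parent <- integer(nn)
    side <- integer(nn)
    internal <- which(!terminal)
    parent[left[internal] + 1L] <- internal
    side[left[internal] + 1L] <- 0L   # low side
    parent[right[internal] + 1L] <- internal
    side[right[internal] + 1L] <- 1L  # high side
    counts <- tabulate(term[, t] + 1L, nbins = nn)
    for (leaf in which(terminal)) {
      if (counts[leaf] == 0L) next
      node <- leaf
      items <- integer(0L)
      while (node != 1L) {
        par <- parent[node]
        items <- c(items, item_code(var0[par] + 1L, side[node]))
        node <- par
      }
      sets[[length(sets) + 1L]] <- sort.int(unique(items))
      weights[length(weights) + 1L] <- counts[leaf]
    }
  }
  structure(list(sets = sets, weights = weights,
                 feature_names = colnames(X)),
            class = "signed_itemsets")
}

# Holdout synergy screen: the candidate's presence-count indicator must
# correlate positively with the held-out outcome and no weaker than each of
# its single members' presence indicators.
holdout_synergy <- function(items, Xte, yte) {
  taxa <- sub(":(high|low)$", "", items)
  taxa <- unique(taxa[taxa %in% colnames(Xte)])
  if (length(taxa) < 2L) return(FALSE)
  pres <- Xte[, taxa, drop = FALSE] > 0
  ind <- rowSums(pres)
  if (var(ind) == 0 || var(yte) == 0) return(FALSE)
  r_all <- cor(ind, yte)
  if (!is.finite(r_all) || r_all <= 0) return(FALSE)
  r_members <- apply(pres, 2L, function(v)
    if (var(v) == 0) -Inf else cor(as.numeric(v), yte))
  all(r_all >= r_members)
}

# Restrict decision-path itemsets to their high-side items and weight every
# surviving path equally. Paths with fewer than two high items cannot yield a
# clique and are dropped.
orient_itemsets <- function(its) {
  sets <- lapply(its$sets, function(s) s[s %% 2L == 0L])
  ok <- lengths(sets) >= 2L
  structure(list(sets = sets[ok], weights = rep(1, sum(ok)),
                 feature_names = its$feature_names),
            class = "signed_itemsets")
}

#' Random intersection trees over itemsets
#'
#' Each RIT samples a root itemset (with probability proportional to its
#' weight) and recursively intersects it with further sampled itemsets, with
#' `rit_children` branches per node, down to `rit_depth`; a child never
#' re-draws the itemset sampled at its parent node, so each intersection
#' involves genuinely distinct draws. Every node set produced by at least one
#' intersection and containing at least two items is collected; each returned
#' set's prevalence is its exact weighted containment fraction over all
#' itemsets.
#'
#' @param itemsets A `signed_itemsets` object, or a plain list of atomic
#'   vectors (arbitrary item types, equal weights).
#' @param rit_depth,rit_children,rit_trees Tree shape (see
#'   [discovery_config()]).
#' @param seed Integer seed.
#' @return A data.frame sorted by decreasing prevalence with columns `key`
#'   (canonical item string), `items` (list column), `size`, `prevalence`.
#' @export
random_intersection_trees <- function(itemsets, rit_depth = 5L,
                                      rit_children = 2L, rit_trees = 50L,
                                      seed = 1L) {
  if (inherits(itemsets, "signed_itemsets")) {
    sets <- itemsets$sets
    weights <- itemsets$weights
    decode <- function(codes) {
      paste0(itemsets$feature_names[item_feature(codes)], ":",
             item_sign(codes))
    }
  } else {
    if (!is.list(itemsets)) stopf("`itemsets` must be a list")
    universe <- sort(unique(unlist(itemsets)))
    sets <- lapply(itemsets, function(s) sort.int(match(unique(s), universe)))
    weights <- rep(1, length(sets))
    decode <- function(codes) universe[codes]
  }
  if (length(sets) == 0L) stopf("`itemsets` is empty")
  n_items <- max(1L, unlist(sets, use.names = FALSE), na.rm = TRUE)
  M <- matrix(FALSE, n_items, length(sets))
  M[cbind(unlist(sets, use.names = FALSE),
          rep.int(seq_along(sets), lengths(sets)))] <- TRUE
  prob <- weights / sum(weights)

  found <- new.env(hash = TRUE, parent = emptyenv())
  with_seed(seed, {
    take <- function(exclude) {
      p <- prob
      p[exclude] <- 0
      if (sum(p) <= 0) return(NA_integer_)
      sample.int(length(sets), 1L, prob = p)
    }
    visit <- function(set, depth, parent_idx) {
      if (depth > 0L && length(set) >= 2L)
        assign(paste(set, collapse = ","), set, envir = found)
      if (depth < rit_depth && length(set) > 0L) {
        for (j in seq_len(rit_children)) {
          other <- take(parent_idx)
          if (is.na(other)) next
          visit(set[M[set, other]], depth + 1L, other)
        }
      }
    }
    for (tr in seq_len(rit_trees)) {
      root <- take(integer(0))
      visit(sets[[root]], 0L, root)
    }
  })

  cand <- as.list(found)
  if (length(cand) == 0L) {
    out <- data.frame(key = character(0), size = integer(0),
                      prevalence = numeric(0))
    out$items <- list()
    return(out)
  }
  prevalence <- vapply(cand, function(s) {
    sum(weights[colSums(M[s, , drop = FALSE]) == length(s)]) / sum(weights)
  }, numeric(1))
  items <- lapply(cand, decode)
  out <- data.frame(key = vapply(items, paste, "", collapse = ","),
                    size = lengths(cand), prevalence = prevalence,
                    row.names = NULL)
  out$items <- unname(items)
  out[order(-out$prevalence, out$key), ]
}

#' Repeated-holdout clique discovery (rh-SiRF)
#'
#' Runs the full stage-1 discovery on one stratum's data: for every repeat a
#' 60/40 train/test partition is drawn; an iteratively reweighted forest fit
#' on the training part is screened on the holdout, and repeats with
#' non-positive out-of-sample R^2 contribute no candidates (a pure-noise
#' guard). For contributing repeats, every bootstrap resample of the training
#' partition runs the reweighting loop, grows the forest, extracts signed
#' decision-path itemsets, and applies random intersection trees; the
#' candidate sets recovered in at least one bootstrap count towards that
#' repeat. A candidate's stability is the fraction of all repeats in which it
#' was recovered.
#'
#' The search is oriented towards cliques predictive of a *higher* outcome:
#' before the intersection stage each decision path is reduced to its
#' high-side items (taxa whose elevated abundance the path conditions on),
#' and every surviving path counts once. Co-absence patterns, which dominate
#' zero-inflated tables, are thereby excluded from the candidate space.
#'
#' Each repeat's 40% holdout also validates the candidates themselves: a
#' candidate counts towards the repeat only if its presence-count indicator
#' correlates positively with the held-out outcome *and* at least as strongly
#' as every one of its single members — i.e. the combination must out-predict
#' its parts out of sample, the defining property of a synergistic clique.
#' This screens out sets that merely hitch a strong single taxon to noise.
#'
#' Predictors enter raw (relative abundances, no covariate adjustment) —
#' adjustment happens in the inference stage.
#'
#' @param X A [feature_table()] or numeric matrix of predictors for a single
#'   stratum.
#' @param y Numeric outcome (RCI).
#' @param config A [discovery_config()].
#' @return A data.frame of `clique_candidates`, sorted by decreasing
#'   stability: `key`, `size`, `stability`, `mean_prevalence`, plus list
#'   columns `taxa` and `signs`. Attribute `n_repeats_used` counts repeats
#'   that passed the holdout screen.
#' @export
repeated_holdout_discovery <- function(X, y, config = discovery_config()) {
  X <- as_predictor_matrix(X)
  stopifnot(inherits(config, "discovery_config"))
  n <- nrow(X)
  if (length(y) != n) stopf("`y` must have one value per row of X")
  n_train <- round(config$train_fraction * n)
  if (n_train < 20L)
    stopf("training partition too small (%d < 20 samples)", n_train)
  seeds <- child_seeds(config$seed, config$n_repeats)

  counts <- new.env(hash = TRUE, parent = emptyenv())
  prevs <- new.env(hash = TRUE, parent = emptyenv())
  n_used <- 0L
  for (r in seq_len(config$n_repeats)) {
    rep_found <- with_seed(seeds[r], {
      idx <- sample.int(n, n_train)
      Xtr <- X[idx, , drop = FALSE]
      ytr <- y[idx]
      Xte <- X[-idx, , drop = FALSE]
      yte <- y[-idx]
      w <- iterate_importance(Xtr, ytr, config$n_irf_iterations,
                              n_trees = config$n_trees,
                              max_depth = config$max_depth,
                              min_node_size = config$min_node_size,
                              seed = sample.int(.Machine$integer.max, 1L))
      f <- grow_weighted_forest(Xtr, ytr, w, n_trees = config$n_trees,
                                max_depth = config$max_depth,
                                min_node_size = config$min_node_size,
                                seed = sample.int(.Machine$integer.max, 1L))
      pred <- predict(f, Xte, num.threads = 1L)$predictions
      r2 <- 1 - sum((yte - pred)^2) / sum((yte - mean(ytr))^2)
      if (!is.finite(r2) || r2 <= 0) NULL else {
        rep_env <- new.env(hash = TRUE, parent = emptyenv())
        for (b in seq_len(config$n_bootstraps)) {
          bidx <- sample.int(n_train, n_train, replace = TRUE)
          Xb <- Xtr[bidx, , drop = FALSE]
          yb <- ytr[bidx]
          wb <- iterate_importance(Xb, yb, config$n_irf_iterations,
                                   n_trees = config$n_trees,
                                   max_depth = config$max_depth,
                                   min_node_size = config$min_node_size,
                                   seed = sample.int(.Machine$integer.max, 1L))
          fb <- grow_weighted_forest(Xb, yb, wb, n_trees = config$n_trees,
                                     max_depth = config$max_depth,
                                     min_node_size = config$min_node_size,
                                     seed = sample.int(.Machine$integer.max, 1L))
          its <- orient_itemsets(signed_itemsets(fb, Xb))
          if (length(its$sets) == 0L) next
          cand <- random_intersection_trees(
            its, rit_depth = config$rit_depth,
            rit_children = config$rit_children, rit_trees = config$rit_trees,
            seed = sample.int(.Machine$integer.max, 1L))
          for (i in seq_len(nrow(cand))) {
            cur <- get0(cand$key[i], envir = rep_env)
            if (is.null(cur) &&
                holdout_synergy(cand$items[[i]], Xte, yte))
              assign(cand$key[i],
                     list(items = cand$items[[i]], prev = cand$prevalence[i]),
                     envir = rep_env)
          }
        }
        as.list(rep_env)
      }
    })
    if (is.null(rep_found)) next
    n_used <- n_used + 1L
    for (key in names(rep_found)) {
      assign(key, get0(key, envir = counts, ifnotfound = 0L) + 1L,
             envir = counts)
      assign(key, c(get0(key, envir = prevs), rep_found[[key]]$prev),
             envir = prevs)
      attr_key <- paste0(".items.", key)
      if (is.null(get0(attr_key, envir = prevs)))
        assign(attr_key, rep_found[[key]]$items, envir = prevs)
    }
  }

  keys <- ls(counts)
  items <- lapply(keys, function(k) get(paste0(".items.", k), envir = prevs))
  out <- data.frame(
    key = keys,
    size = lengths(items),
    stability = vapply(keys, function(k) get(k, envir = counts),
                       numeric(1)) / config$n_repeats,
    mean_prevalence = vapply(keys, function(k) mean(get(k, envir = prevs)),
                             numeric(1)),
    row.names = NULL)
  out$taxa <- lapply(items, function(it) sub(":(high|low)$", "", it))
  out$signs <- lapply(items, function(it) sub("^.*:", "", it))
  out <- out[order(-out$stability, -out$size, out$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_repeats_used") <- n_used
  class(out) <- c("clique_candidates", "data.frame")
  out
}

#' Assemble final cliques from ranked candidates
#'
#' Retains every candidate whose stability is at least `min_stability`
#' (processed by decreasing stability, then larger size, then lexicographic
#' key) and merges retained candidates that share at least one taxon into a
#' single connected component — the closed-loop network reported as one
#' clique.
#'
#' @param candidates Output of [repeated_holdout_discovery()].
#' @param min_stability Stability threshold (default 0.5). Raising it can
#'   only shrink the result.
#' @return A list of cliques, each a list with `taxa` (sorted union),
#'   `stability` (max over merged candidates), and `members` (the merged
#'   candidate rows). Empty, with a warning, if nothing passes the threshold.
#' @export
select_cliques <- function(candidates, min_stability = 0.5) {
  check_probability(min_stability, "min_stability")
  keep <- candidates[candidates$stability >= min_stability, , drop = FALSE]
  keep <- keep[order(-keep$stability, -keep$size, keep$key), , drop = FALSE]
  if (nrow(keep) == 0L) {
    warnf("no candidate reached stability %.2f; returning no cliques",
          min_stability)
    return(list())
  }
  comp <- seq_len(nrow(keep))  # union-find over taxon overlap
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  for (i in seq_len(nrow(keep))) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(keep$taxa[[i]], keep$taxa[[j]])) > 0L)
        comp[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(nrow(keep)), find, integer(1))
  lapply(unique(roots), function(rt) {
    rows <- keep[roots == rt, , drop = FALSE]
    list(taxa = sort(unique(unlist(rows$taxa))),
         stability = max(rows$stability), members = rows)
  })
}
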