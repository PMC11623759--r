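# Independent path-enumeration oracle built on ranger::treeInfo(): walks each
# tree's table recursively and drops each row of X down the splits.
oracle_itemsets <- function(forest, X) {
  sets <- list()
  weights <- numeric(0)
  for (t in seq_len(forest$num.trees)) {
    info <- ranger::treeInfo(forest, t)
    if (nrow(info) <= 1) next
    paths <- list()
    walk <- function(node, items) {
      row <- info[info$nodeID == node, ]
      if (row$terminal) {
        paths[[as.character(node)]] <<- sort(unique(items))
        return(invisible())
      }
      v <- row$splitvarID + 1
      walk(row$leftChild, c(items, 2L * v - 1L))   # low side
      walk(row$rightChild, c(items, 2L * v))       # high side
    }
    walk(0, integer(0))
    # drop rows of X down the tree to count leaf occupancy
    leaf_of <- function(x) {
      node <- 0
      repeat {
        row <- info[info$nodeID == node, ]
        if (row$terminal) return(node)
        node <- if (x[row$splitvarID + 1] <= row$splitval) row$leftChild else
          row$rightChild
      }
    }
    counts <- table(apply(X, 1, leaf_of))
    for (leaf in names(counts)) {
      sets[[length(sets) + 1L]] <- paths[[leaf]]
      weights[length(weights) + 1L] <- as.numeric(counts[[leaf]])
    }
  }
  list(sets = sets, weights = weights)
}

canon <- function(sets, weights) {
  keys <- vapply(sets, paste, "", collapse = "|")
  tapply(weights, keys, sum)
}

test_that("signed itemsets equal independent tree traversal", {
  withr::with_seed(5, {
    X <- matrix(rnorm(80 * 6), 80, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- X[, 1] * (X[, 2] > 0) + rnorm(80, 0, 0.5)
  })
  f <- grow_weighted_forest(X, y, rep(1, 6), n_trees = 12, max_depth = 3,
                            seed = 30)
  got <- signed_itemsets(f, X)
  want <- oracle_itemsets(f, X)
  expect_equal(sort(names(canon(got$sets, got$weights))),
               sort(names(canon(want$sets, want$weights))))
  expect_equal(canon(got$sets, got$weights)[names(canon(want$sets, want$weights))],
               canon(want$sets, want$weights))
})

test_that("a unit weight forces every split onto one feature", {
  withr::with_seed(6, {
    X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- rnorm(60)
  })
  f <- grow_weighted_forest(X, y, c(0, 0, 1, 0), n_trees = 10, seed = 3)
  for (t in seq_len(10)) {
    info <- ranger::treeInfo(f, t)
    expect_true(all(info$splitvarName[!info$terminal] == "f3"))
  }
  expect_error(grow_weighted_forest(X, y, c(0, 0, 0, 0)), "zero")
  expect_error(grow_weighted_forest(X, y, c(1, 1)), "one weight per feature")
})

test_that("a noiseless step function dominates the importances", {
  withr::with_seed(7, {
    X <- matrix(runif(200 * 8), 200, 8)
    y <- as.numeric(X[, 5] > 0.5)
  })
  f <- grow_weighted_forest(X, y, rep(1 / 8, 8), n_trees = 50, seed = 4)
  imp <- ranger::importance(f)
  expect_equal(unname(which.max(imp)), 5L)
})

test_that("one reweighting iteration returns uniform-forest importances", {
  withr::with_seed(8, {
    X <- matrix(rnorm(100 * 5), 100, 5)
    y <- X[, 2] + rnorm(100)
  })
  w <- iterate_importance(X, y, n_iterations = 1, n_trees = 30, seed = 40)
  seed1 <- withr::with_seed(40, sample.int(.Machine$integer.max - 1L, 1L))
  f <- grow_weighted_forest(X, y, rep(1 / 5, 5), n_trees = 30, seed = seed1)
  imp <- pmax(ranger::importance(f), 0)
  expect_equal(unname(w), unname(imp / sum(imp)))
  expect_equal(sum(w), 1)
})

test_that("reweighting stays near-uniform on pure noise", {
  withr::with_seed(9, {
    acc <- rep(0, 10)
    for (s in 1:20) {
      X <- matrix(rnorm(500 * 10), 500, 10)
      y <- rnorm(500)
      acc <- acc + iterate_importance(X, y, 2, n_trees = 30,
                                      seed = 1000 + s)
    }
    acc <- acc / 20
    expect_lt(max(acc) / min(acc), 5)
  })
})

test_that("reweighting concentrates on an interacting pair", {
  withr::with_seed(10, {
    X <- matrix(rnorm(500 * 52), 500, 52)
    y <- as.numeric(X[, 1] > 0 & X[, 2] > 0) + rnorm(500, 0, 0.3)
  })
  w <- iterate_importance(X, y, 3, n_trees = 60, seed = 77)
  expect_gt(w[1] + w[2], 0.5)
})

test_that("RIT prevalence equals brute-force containment counting", {
  its <- list(c(1, 2), c(1, 2), c(1, 3))
  out <- random_intersection_trees(its, rit_trees = 300, seed = 1)
  expect_equal(out$prevalence[out$key == "1,2"], 2 / 3)
  if ("1,3" %in% out$key)
    expect_equal(out$prevalence[out$key == "1,3"], 1 / 3)

  # identical itemsets: only subsets of S, S itself at prevalence 1
  same <- replicate(5, c(2, 4, 6), simplify = FALSE)
  out2 <- random_intersection_trees(same, rit_trees = 50, seed = 2)
  expect_true(all(vapply(out2$items, function(s) all(s %in% c(2, 4, 6)),
                         logical(1))))
  expect_equal(out2$prevalence[out2$key == "2,4,6"], 1)

  # disjoint itemsets: no candidate of size >= 2 survives an intersection
  disj <- list(c(1, 2), c(3, 4), c(5, 6))
  out3 <- random_intersection_trees(disj, rit_trees = 100, seed = 3)
  expect_equal(nrow(out3), 0)

  # random instances against a brute-force counter
  withr::with_seed(12, {
    for (i in 1:5) {
      sets <- replicate(12, sort(sample(1:6, sample(2:4, 1))),
                        simplify = FALSE)
      out4 <- random_intersection_trees(sets, rit_trees = 200, seed = i)
      for (j in seq_len(nrow(out4))) {
        s <- out4$items[[j]]
        brute <- mean(vapply(sets, function(it) all(s %in% it), logical(1)))
        expect_equal(out4$prevalence[j], brute)
      }
    }
  })
})

test_that("repeated-holdout discovery is deterministic and guards small data", {
  fx <- withr::with_seed(1, {
    X <- matrix(rgamma(60 * 8, 0.5) * rbinom(60 * 8, 1, 0.5), 60, 8)
    list(X = X, y = rnorm(60))
  })
  cfg <- discovery_config(n_repeats = 3, n_bootstraps = 2, n_trees = 15,
                          n_irf_iterations = 1, rit_trees = 10, seed = 99)
  a <- repeated_holdout_discovery(fx$X, fx$y, cfg)
  b <- repeated_holdout_discovery(fx$X, fx$y, cfg)
  expect_identical(a, b)
  expect_error(
    repeated_holdout_discovery(fx$X[1:20, ], fx$y[1:20], cfg),
    "too small")
})

test_that("clique selection merges overlapping candidates above threshold", {
  cand <- data.frame(key = c("A,B", "B,C", "D,E"), size = 2,
                     stability = c(0.9, 0.8, 0.7))
  cand$taxa <- list(c("A", "B"), c("B", "C"), c("D", "E"))
  cand$signs <- list(c("high", "high"), c("high", "high"), c("high", "high"))
  cliques <- select_cliques(cand, 0.6)
  expect_length(cliques, 2)
  expect_equal(cliques[[1]]$taxa, c("A", "B", "C"))
  expect_equal(cliques[[2]]$taxa, c("D", "E"))
  expect_equal(cliques[[1]]$stability, 0.9)

  single <- select_cliques(cand[3, ], 0.6)
  expect_length(single, 1)
  expect_equal(single[[1]]$taxa, c("D", "E"))

  expect_warning(none <- select_cliques(cand, 0.95), "no candidate")
  expect_length(none, 0)

  # monotonicity: a higher threshold never adds a clique
  for (th in c(0.65, 0.75, 0.85)) {
    lo <- suppressWarnings(select_cliques(cand, th))
    hi <- suppressWarnings(select_cliques(cand, th + 0.1))
    expect_lte(length(hi), length(lo))
  }
})
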