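p04_centers <- function() {
  ctr <- rbind(C0 = c(1, 1, 1), C1 = c(1, 0, 0), C3 = c(0.4, 0, 0),
               C2 = c(0, 1, 1), C4 = c(0, 0, 1))
  colnames(ctr) <- c("peritoneal", "liver1", "liver2")
  ctr
}

test_that("the founder clone is the unique fully clonal cluster", {
  ctr <- p04_centers()
  expect_equal(infer_root(ctr), "C0")
  single <- matrix(1, 1, 1, dimnames = list("K1", "S1"))
  expect_equal(infer_root(single), "K1")
  two_clonal <- rbind(A = c(1, 1), B = c(0.95, 0.99))
  colnames(two_clonal) <- c("S1", "S2")
  expect_error(infer_root(two_clonal), "single-origin")
  none <- rbind(A = c(1, 0.2), B = c(0.2, 1))
  colnames(none) <- c("S1", "S2")
  expect_error(infer_root(none), "no cluster")
})

test_that("greedy reconstruction recovers the branched P04-like topology", {
  tree <- build_tree(p04_centers())
  expect_equal(tree$root, "C0")
  expect_equal(tree$parent[["C1"]], "C0")
  expect_equal(tree$parent[["C3"]], "C1")
  expect_equal(tree$parent[["C2"]], "C0")
  expect_equal(tree$parent[["C4"]], "C2")
  expect_length(tree$unplaced, 0)
  ## brute-force enumeration confirms this is the unique sum-rule tree
  valid <- enumerate_trees(p04_centers(), tol = 0.02)
  expect_length(valid, 1)
  expect_equal(valid[[1]][names(tree$parent)], tree$parent)
})

test_that("a single cluster yields a root-only tree", {
  single <- matrix(1, 1, 1, dimnames = list("C0", "S1"))
  tree <- build_tree(single)
  expect_equal(tree$root, "C0")
  expect_length(tree$parent, 0)
  expect_equal(to_newick(tree), "C0;")
})

test_that("greedy equals the brute-force-unique tree on random noiseless scenarios", {
  n_unique <- 0; n_match <- 0
  for (seed in 1:50) {
    rc <- random_clone_centers(n_clones = 6, n_samples = 3, seed = seed)
    valid <- enumerate_trees(rc$ccf, tol = 0.02)
    if (length(valid) != 1) next
    n_unique <- n_unique + 1
    tree <- suppressWarnings(build_tree(rc$ccf, tol = 0.02))
    if (identical(sort(names(tree$parent)), sort(names(valid[[1]]))) &&
        all(valid[[1]][names(tree$parent)] == tree$parent))
      n_match <- n_match + 1
  }
  expect_gte(n_unique, 10)      # enough informative draws
  expect_equal(n_match, n_unique)
})

test_that("noisy p04 simulations recover the true topology in >= 90% of seeds", {
  sc <- build_scenario("p04_like")
  truth <- build_tree(p04_centers())
  true_ctr <- p04_centers()
  hits <- 0; n_seeds <- 50
  for (seed in seq_len(n_seeds)) {
    sc$seed <- 1000L + seed
    sim <- simulate_all_calls(sc)
    cm <- ccf_matrix(sim$calls, sim$purities)
    cl <- tryCatch(deconvolute(cm), error = function(e) NULL)
    if (is.null(cl) || nrow(cl$clusters) != 5) next
    tree <- tryCatch(suppressWarnings(build_tree(cl)),
                     error = function(e) NULL)
    if (is.null(tree)) next
    ## match inferred clusters to true clones by nearest center
    map <- apply(cl$centers, 1, function(v)
      rownames(true_ctr)[which.min(colSums((t(true_ctr) - v)^2))])
    if (anyDuplicated(map)) next
    relabeled <- stats::setNames(map[tree$parent], map[names(tree$parent)])
    if (identical(sort(names(relabeled)), sort(names(truth$parent))) &&
        all(truth$parent[names(relabeled)] == relabeled))
      hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("unplaceable clusters attach to the root with a warning", {
  ctr <- rbind(C0 = c(1, 1), C1 = c(0.9, 0), C2 = c(0.5, 0.9))
  colnames(ctr) <- c("S1", "S2")
  ## C1+C2 violate the sum rule under C0 in S1; C2 under C1 violates S2
  expect_warning(tree <- build_tree(ctr, tol = 0.05), "no feasible parent")
  expect_true(length(tree$unplaced) >= 1)
  expect_true(all(tree$parent[tree$unplaced] == "C0"))
})

test_that("composition subtracts children and omits absent clones", {
  tree <- build_tree(p04_centers())
  perit <- composition(tree, "peritoneal")
  expect_equal(perit[["C1"]], 0.6)
  expect_equal(perit[["C3"]], 0.4)
  expect_equal(perit[["C0"]], 0)        # fully explained by its children
  expect_false("C2" %in% names(perit))  # absent from this biopsy
  liver1 <- composition(tree, "liver1")
  expect_equal(liver1[["C2"]], 1)
  expect_false("C4" %in% names(liver1))
  liver2 <- composition(tree, "liver2")
  expect_equal(liver2[["C4"]], 1)
  expect_equal(liver2[["C2"]], 0)
})

test_that("biopsy distance is the mean absolute CCF difference and a metric", {
  mat <- cbind(A = c(1, 1, 0, 0.4), B = c(1, 0, 1, 0.4),
               C = c(1, 0.5, 0.5, 0.4))
  rownames(mat) <- paste0("m", 1:4)
  expect_equal(biopsy_distance(mat, "A", "A"), 0)
  expect_equal(biopsy_distance(mat, "A", "B"), mean(c(0, 1, 1, 0)))
  expect_equal(biopsy_distance(mat, "A", "B"), biopsy_distance(mat, "B", "A"))
  ## normal baseline: fully clonal sample at distance 1
  clonal <- cbind(S = rep(1, 5))
  rownames(clonal) <- paste0("m", 1:5)
  expect_equal(biopsy_distance(clonal, "normal", "S"), 1)
  ## triangle inequality over all triples incl. normal
  d <- distance_matrix(mat)
  ids <- rownames(d)
  for (i in ids) for (j in ids) for (k in ids)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("p04 distances rank liver rebiopsy closer than the peritoneum", {
  sc <- build_scenario("p04_like")
  sim <- simulate_all_calls(sc)
  cm <- ccf_matrix(sim$calls, sim$purities)
  expect_lt(biopsy_distance(cm, "liver1", "liver2"),
            biopsy_distance(cm, "liver1", "peritoneal"))
})

test_that("Newick export round-trips through an independent parser", {
  skip_if_not_installed("ape")
  ctr <- p04_centers()
  w <- stats::setNames(rep(150, 5), rownames(ctr))
  tree <- build_tree(ctr)
  tree$weights <- w
  nwk <- to_newick(tree)
  expect_equal(gsub(":[0-9]+", "", nwk), "((C3)C1,(C4)C2)C0;")
  ph <- ape::read.tree(text = nwk)
  ## same tip set and same parent-child relations after re-parsing
  expect_setequal(ph$tip.label, c("C3", "C4"))
  expect_setequal(ph$node.label, c("C0", "C1", "C2"))
  labs <- c(ph$tip.label, ph$node.label)
  edges <- apply(ph$edge, 1, function(e)
    paste(labs[e[1]], labs[e[2]], sep = "->"))
  expect_setequal(edges, c("C0->C1", "C1->C3", "C0->C2", "C2->C4"))
  expect_true(all(ph$edge.length == 150))
})

test_that("emitted trees always satisfy containment and the sum rule", {
  for (seed in c(2, 5, 8)) {
    rc <- random_clone_centers(seed = seed)
    tree <- suppressWarnings(build_tree(rc$ccf, tol = 0.02))
    expect_silent(validate_tree(tree))
  }
})
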