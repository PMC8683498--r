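## Simulated 1-D CCF instances on the read-count scale: components at given
## CCF centers, binomial noise at the given depth, diploid, purity 0.7.
sim_1d_instance <- function(centers, n_per, depth = 150, purity = 0.7,
                            seed = 1) {
  set.seed(seed)
  ccf_true <- rep(centers, n_per)
  ev <- expected_vaf(ccf_true, purity, 2, 1)
  alt <- stats::rbinom(length(ev), depth, ev)
  rec <- compute_ccf(alt, depth, purity = purity, cn_total = 2, m = 1)
  mat <- matrix(rec$ccf, ncol = 1,
                dimnames = list(sprintf("m%04d", seq_along(ev)), "S1"))
  raw <- matrix(rec$raw_ccf, ncol = 1, dimnames = dimnames(mat))
  vars <- matrix(rec$variance, ncol = 1, dimnames = dimnames(mat))
  list(x = structure(list(ccf = mat, raw = raw, variance = vars,
                          info = NULL), class = "ccf_matrix"),
       alt = alt, depth = rep(depth, length(ev)),
       vaf_scale = expected_vaf(1, purity, 2, 1))
}

test_that("a single clonal population yields one cluster at center 1", {
  mat <- matrix(1, 50, 1, dimnames = list(sprintf("m%02d", 1:50), "S1"))
  cl <- deconvolute(mat)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(unname(cl$centers[1, 1]), 1)
  expect_equal(cl$clusters$weight, 50)
  expect_equal(cl$clusters$classification, "clonal_all")
})

test_that("deconvolution matches the EM binomial-mixture oracle on 1-D mixtures", {
  cases <- list(
    list(centers = c(1.0, 0.4), n = c(150, 150), seed = 7),
    list(centers = c(1.0, 0.6, 0.25), n = c(150, 100, 80), seed = 13),
    list(centers = 0.8, n = 200, seed = 5)
  )
  for (cs in cases) {
    inst <- sim_1d_instance(cs$centers, cs$n, seed = cs$seed)
    cl <- deconvolute(inst$x)
    ## independent oracle: EM binomial mixture with BIC model selection,
    ## centers mapped from VAF to CCF scale
    oracle_ccf <- em_oracle_centers(inst$alt, inst$depth) / inst$vaf_scale
    expect_equal(nrow(cl$clusters), length(oracle_ccf),
                 info = paste("case centers:",
                              paste(cs$centers, collapse = "/")))
    got <- sort(pmin(cl$centers[, 1], 1))
    expect_true(all(abs(got - sort(pmin(oracle_ccf, 1))) < 0.05))
    ## and both recover the generating truth
    expect_true(all(abs(got - sort(cs$centers)) < 0.05))
  }
})

test_that("clusters partition the mutations and weights sum to the count", {
  inst <- sim_1d_instance(c(1.0, 0.4), c(150, 150), seed = 3)
  cl <- deconvolute(inst$x)
  expect_equal(sum(cl$clusters$weight), 300)
  expect_equal(sort(names(cl$assignment)), sort(rownames(inst$x$ccf)))
  expect_true(all(cl$assignment %in% cl$clusters$cluster_id))
})

test_that("cluster assignment is invariant to mutation input order", {
  inst <- sim_1d_instance(c(1.0, 0.5), c(100, 80), seed = 21)
  cl1 <- deconvolute(inst$x)
  perm <- sample(nrow(inst$x$ccf))
  x2 <- structure(list(ccf = inst$x$ccf[perm, , drop = FALSE],
                       raw = inst$x$raw[perm, , drop = FALSE],
                       variance = inst$x$variance[perm, , drop = FALSE],
                       info = NULL), class = "ccf_matrix")
  cl2 <- deconvolute(x2)
  expect_equal(cl1$centers, cl2$centers)
  expect_equal(cl1$assignment[sort(names(cl1$assignment))],
               cl2$assignment[sort(names(cl2$assignment))])
})

test_that("undersized clusters dissolve and input floor is enforced", {
  expect_error(deconvolute(matrix(1, 3, 1), min_cluster_size = 5),
               "min_cluster_size")
  ## 3 stray points cannot form their own cluster
  mat <- matrix(c(rep(1, 40), 0.52, 0.5, 0.48), ncol = 1,
                dimnames = list(sprintf("m%02d", 1:43), "S1"))
  cl <- deconvolute(mat, min_cluster_size = 5)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(sum(cl$clusters$weight), 43)
})

test_that("cluster classification follows the decision table", {
  expect_equal(classify_cluster(c(a = 1, b = 1, c = 1)), "clonal_all")
  expect_equal(classify_cluster(c(a = 0.9, b = 0.87)), "clonal_all")
  expect_equal(classify_cluster(c(a = 0.95, b = 0.02)), "private:a")
  expect_equal(classify_cluster(c(peritoneal = 0.4, liver1 = 0, liver2 = 0)),
               "private:peritoneal (subclonal)")
  expect_equal(classify_cluster(c(a = 0.5, b = 0.5)), "shared_subclonal")
  expect_equal(classify_cluster(c(a = 0.9, b = 0.5)), "shared_subclonal")
  expect_equal(classify_cluster(c(a = 0.02, b = 0.01)), "absent")
  ## missing centers treated as absent
  expect_equal(classify_cluster(c(a = 0.95, b = NA)), "private:a")
  ## threshold grid: boundary at clonal_threshold is inclusive
  expect_equal(classify_cluster(c(a = 0.85, b = 0.85)), "clonal_all")
  expect_equal(classify_cluster(c(a = 0.85, b = 0.10)), "private:a")
})

test_that("pairwise clustering recovers shared and private clusters", {
  set.seed(17)
  truth <- rbind(
    matrix(rep(c(1, 1), each = 200), ncol = 2),
    matrix(rep(c(1, 0), each = 150), ncol = 2),
    matrix(rep(c(0, 1), each = 180), ncol = 2))
  depth <- 150; purity <- 0.7
  ev <- expected_vaf(truth, purity, 2, 1)
  alt <- matrix(stats::rbinom(length(ev), depth, ev), ncol = 2)
  scale <- (purity * 2 + (1 - purity) * 2) / purity
  raw <- alt / depth * scale
  mat <- pmin(raw, 1)
  vars <- (scale^2) * (alt / depth) * (1 - alt / depth) / depth
  dimnames(mat) <- dimnames(raw) <- dimnames(vars) <-
    list(sprintf("m%03d", seq_len(nrow(mat))), c("a", "b"))
  x <- structure(list(ccf = mat, raw = raw, variance = vars,
                      info = data.frame(key = rownames(mat),
                                        gene = NA_character_)),
                 class = "ccf_matrix")
  pw <- pairwise_clusters(x, "a", "b")
  cls <- sort(pw$clusters$clusters$classification)
  expect_equal(cls, sort(c("clonal_all", "private:a", "private:b")))
  expect_equal(pw$clusters$clusters$weight[order(
    pw$clusters$clusters$classification)],
    c(200, 150, 180)[order(c("clonal_all", "private:a", "private:b"))])
  expect_equal(nrow(pw$scatter), 530)
})

test_that("a duplicated sample clusters on the diagonal", {
  inst <- sim_1d_instance(c(1.0, 0.4), c(100, 100), seed = 9)
  dup <- structure(list(
    ccf = cbind(A = inst$x$ccf[, 1], B = inst$x$ccf[, 1]),
    raw = cbind(A = inst$x$raw[, 1], B = inst$x$raw[, 1]),
    variance = cbind(A = inst$x$variance[, 1], B = inst$x$variance[, 1]),
    info = data.frame(key = rownames(inst$x$ccf), gene = NA)),
    class = "ccf_matrix")
  pw <- pairwise_clusters(dup, "A", "B")
  expect_true(all(abs(pw$clusters$centers[, "A"] -
                      pw$clusters$centers[, "B"]) < 1e-9))
})

test_that("p04_like peritoneal sample shows clusters near 1.0 and 0.4", {
  sc <- build_scenario("p04_like")
  sim <- simulate_all_calls(sc)
  cm <- ccf_matrix(sim$calls, sim$purities)
  sub <- structure(list(ccf = cm$ccf[, "peritoneal", drop = FALSE],
                        raw = cm$raw[, "peritoneal", drop = FALSE],
                        variance = cm$variance[, "peritoneal", drop = FALSE],
                        info = cm$info), class = "ccf_matrix")
  cl <- deconvolute(sub)
  ctr <- sort(cl$centers[, 1], decreasing = TRUE)
  ## C0+C1 mutations merge near 1, C3 near 0.4, absent clones near 0
  expect_true(any(abs(ctr - 1) < 0.05))
  expect_true(any(abs(ctr - 0.4) < 0.05))
})

test_that("p04_like pairwise peritoneal/liver1 separates the marker lineages", {
  sc <- build_scenario("p04_like")
  sim <- simulate_all_calls(sc)
  cm <- ccf_matrix(sim$calls, sim$purities)
  pw <- pairwise_clusters(cm, "peritoneal", "liver1")
  sca <- pw$scatter
  t790m <- sca[sca$gene == "EGFR_T790M" & !is.na(sca$gene), ]
  v600e <- sca[sca$gene == "BRAF_V600E" & !is.na(sca$gene), ]
  del19 <- sca[sca$gene == "EGFR_del19" & !is.na(sca$gene), ]
  expect_match(t790m$classification, "^private:peritoneal")
  expect_match(v600e$classification, "^private:liver1")
  expect_equal(del19$classification, "clonal_all")
})
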