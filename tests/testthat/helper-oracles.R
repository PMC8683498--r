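## Independent oracles used across the suite.

## EM fit of a k-component binomial mixture to (alt, depth) read counts.
em_binom_mixture <- function(alt, depth, k, max_iter = 500) {
  vaf <- alt / depth
  p <- stats::quantile(vaf, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  p <- pmin(pmax(p, 1e-3), 1 - 1e-3)
  if (k > 1) p <- p + seq(0, 1e-6, length.out = k)  # break exact ties
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logmat <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dbinom(alt, depth, p[j], log = TRUE),
      numeric(length(alt)))
    m <- apply(logmat, 1, max)
    lse <- m + log(rowSums(exp(logmat - m)))
    ll <- sum(lse)
    r <- exp(logmat - lse)
    w <- colMeans(r)
    p <- colSums(r * alt) / colSums(r * depth)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    if (ll - ll_old < 1e-9) break
    ll_old <- ll
  }
  list(p = p, w = w, loglik = ll,
       bic = -2 * ll + (2 * k - 1) * log(length(alt)))
}

## BIC-selected component VAF centers (components below min_weight dropped).
em_oracle_centers <- function(alt, depth, kmax = 5, min_weight = 0.02) {
  fits <- lapply(seq_len(kmax), function(k) em_binom_mixture(alt, depth, k))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
  sort(best$p[best$w >= min_weight])
}

## Exhaustive enumeration of all rooted trees over cluster centers that
## satisfy containment and the sum rule within tol. Returns a list of parent
## maps (named character vectors).
enumerate_trees <- function(centers, tol = 0.02,
                            clonal_threshold = 0.85) {
  ids <- rownames(centers)
  root <- ids[apply(centers >= clonal_threshold, 1, all)]
  if (length(root) != 1) return(list())
  nonroot <- setdiff(ids, root)
  if (!length(nonroot)) {
    out <- list(stats::setNames(character(0), character(0)))
    return(out)
  }
  choice_sets <- lapply(nonroot, function(i) setdiff(ids, i))
  grid <- do.call(expand.grid,
                  c(choice_sets, list(stringsAsFactors = FALSE)))
  valid <- list()
  for (g in seq_len(nrow(grid))) {
    parent <- stats::setNames(as.character(grid[g, ]), nonroot)
    ## reachability / acyclicity
    ok <- TRUE
    for (id in nonroot) {
      v <- id; seen <- character(0)
      repeat {
        if (v == root) break
        if (v %in% seen || !v %in% names(parent)) { ok <- FALSE; break }
        seen <- c(seen, v)
        v <- parent[[v]]
      }
      if (!ok) break
    }
    if (!ok) next
    ## containment
    for (id in nonroot) {
      if (any(centers[id, ] > centers[parent[[id]], ] + tol)) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    ## sum rule
    for (id in ids) {
      kids <- names(parent)[parent == id]
      if (!length(kids)) next
      if (any(colSums(centers[kids, , drop = FALSE]) > centers[id, ] + tol)) {
        ok <- FALSE; break
      }
    }
    if (ok) valid[[length(valid) + 1]] <- parent
  }
  valid
}

## Random noiseless clone scenario: a random tree over n_clones whose CCFs
## obey the sum rule strictly. Children nearly exhaust their parent's CCF in
## the samples where they are present, which keeps the tree identifiable;
## clones that end up absent everywhere are dropped.
random_clone_centers <- function(n_clones = 6, n_samples = 3, seed = 1) {
  set.seed(seed)
  ids <- paste0("C", seq_len(n_clones) - 1)
  parent <- stats::setNames(rep(NA_character_, n_clones), ids)
  for (i in seq_len(n_clones - 1) + 1)
    parent[ids[i]] <- ids[sample.int(i - 1, 1)]
  ccf <- matrix(0, n_clones, n_samples,
                dimnames = list(ids, paste0("S", seq_len(n_samples))))
  ccf[1, ] <- 1
  for (p_i in seq_len(n_clones)) {
    kids <- which(parent == ids[p_i])
    if (!length(kids)) next
    for (s in seq_len(n_samples)) {
      avail <- ccf[p_i, s]
      if (avail < 0.25) next
      props <- stats::runif(length(kids))
      vals <- round(0.92 * avail * props / sum(props), 2)
      vals <- pmin(vals, 0.8)  # only the root may be fully clonal
      vals[vals < 0.2] <- 0
      ccf[kids, s] <- vals
    }
  }
  present <- rowSums(ccf) > 0
  ccf <- ccf[present, , drop = FALSE]
  parent <- parent[present & !is.na(parent)]
  parent <- parent[parent %in% rownames(ccf)]
  list(ccf = ccf, parent = parent, root = ids[1])
}

## Simulated multi-sample call set + purity vector for a scenario.
simulate_all_calls <- function(sc) {
  calls <- do.call(rbind, lapply(sc$samples$sample_id,
                                 function(s) simulate_biopsy(sc, s)))
  list(calls = calls,
       purities = stats::setNames(sc$samples$purity, sc$samples$sample_id))
}
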