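## Clone-tree reconstruction from cluster CCFs: root inference, greedy
## attachment under containment + sum rule, per-biopsy composition,
## inter-lesion distances and Newick export.

cluster_centers <- function(clusters) {
  if (inherits(clusters, "ccf_clusters")) return(clusters$centers)
  stopifnot(is.matrix(clusters))
  clusters
}

cluster_weights <- function(clusters) {
  if (inherits(clusters, "ccf_clusters"))
    return(stats::setNames(clusters$clusters$weight,
                           clusters$clusters$cluster_id))
  stats::setNames(rep(NA_real_, nrow(clusters)), rownames(clusters))
}

#' Infer the founder clone (most common ancestor) among clusters
#'
#' The founder clone is the unique cluster that is clonal in every sample
#' (center at or above \code{clonal_threshold}); zero or multiple such
#' clusters signal unresolvable ancestry and raise an error.
#'
#' @param clusters A \code{ccf_clusters} object or a cluster x sample matrix
#'   of centers with cluster ids as row names.
#' @param clonal_threshold Clonality threshold (default 0.85).
#' @return The id of the founder cluster.
#' @export
infer_root <- function(clusters, clonal_threshold = 0.85) {
  ctr <- cluster_centers(clusters)
  clonal <- rownames(ctr)[apply(ctr >= clonal_threshold, 1, all)]
  if (length(clonal) == 0)
    stop("no cluster is clonal in all samples: ancestry unresolvable")
  if (length(clonal) > 1)
    stop("multiple fully clonal clusters (", paste(clonal, collapse = ", "),
         "): single-origin assumption violated")
  clonal
}

#' Reconstruct a rooted clone tree from cluster CCF centers
#'
#' Greedy attachment in descending total-CCF order: each cluster attaches to
#' the deepest existing node that satisfies containment (the child's center
#' does not exceed the candidate parent's by more than \code{tol} in any
#' sample) and keeps the sum rule (children's centers sum to at most the
#' parent's plus \code{tol} per sample) after attachment. Ties are broken by
#' cluster id. When the greedy pass leaves clusters without a feasible parent
#' (its depth preference can occupy room that a later cluster needs), an
#' exhaustive depth-first search over parent assignments is run, so a fully
#' feasible tree is recovered whenever one exists; only when no feasible tree
#' exists at all are the offending clusters attached to the root and flagged
#' rather than aborting the reconstruction.
#'
#' @param clusters A \code{ccf_clusters} object or centers matrix.
#' @param tol Absolute tolerance for containment and the sum rule
#'   (default 0.10, sized to absorb binomial CCF noise at ~150x depth).
#' @param clonal_threshold Passed to \code{\link{infer_root}}.
#' @return A \code{clone_tree}: list with \code{root}, \code{parent} (named
#'   character vector child -> parent), \code{centers}, \code{weights}
#'   (cluster-private mutation counts, used as branch lengths) and
#'   \code{unplaced} (ids force-attached to the root).
#' @examples
#' ctr <- rbind(C0 = c(1, 1, 1), C1 = c(1, 0, 0), C3 = c(0.4, 0, 0),
#'              C2 = c(0, 1, 1), C4 = c(0, 0, 1))
#' colnames(ctr) <- c("peritoneal", "liver1", "liver2")
#' build_tree(ctr)$parent
#' @export
build_tree <- function(clusters, tol = 0.10, clonal_threshold = 0.85) {
  ctr <- cluster_centers(clusters)
  w <- cluster_weights(clusters)
  root <- infer_root(ctr, clonal_threshold)
  ids <- rownames(ctr)
  rest <- setdiff(ids, root)
  rest <- rest[order(-rowSums(ctr[rest, , drop = FALSE]), rest)]
  parent <- stats::setNames(character(0), character(0))
  placed <- root
  unplaced <- character(0)
  depth <- function(v) {
    d <- 0
    while (v != root) { v <- parent[[v]]; d <- d + 1 }
    d
  }
  for (id in rest) {
    feasible <- placed[vapply(placed, function(p) {
      if (any(ctr[id, ] > ctr[p, ] + tol)) return(FALSE)
      kids <- c(names(parent)[parent == p], id)
      all(colSums(ctr[kids, , drop = FALSE]) <= ctr[p, ] + tol)
    }, TRUE)]
    if (!length(feasible)) {
      unplaced <- c(unplaced, id)
      parent[id] <- root
    } else {
      ds <- vapply(feasible, depth, 0)
      cand <- feasible[ds == max(ds)]
      parent[id] <- sort(cand)[1]
    }
    placed <- c(placed, id)
  }
  if (length(unplaced) && length(rest) <= 12) {
    full <- tree_search(ctr, root, rest, tol)
    if (!is.null(full)) {
      parent <- full
      unplaced <- character(0)
    }
  }
  if (length(unplaced))
    warning("no feasible parent for cluster(s) ",
            paste(unplaced, collapse = ", "), "; attached to root")
  tree <- structure(list(root = root, parent = parent, centers = ctr,
                         weights = w, unplaced = unplaced,
                         tol = tol),
                    class = "clone_tree")
  validate_tree(tree)
  tree
}

## Depth-first search for a fully feasible parent assignment; clusters are
## assigned in the given (descending total-CCF) order, candidate parents in
## sorted-id order, so the result is deterministic. Returns NULL when no
## feasible tree exists.
tree_search <- function(ctr, root, order_ids, tol) {
  assign_next <- function(parent, placed, remaining) {
    if (!length(remaining)) return(parent)
    id <- remaining[1]
    for (p in sort(placed)) {
      if (any(ctr[id, ] > ctr[p, ] + tol)) next
      kids <- c(names(parent)[parent == p], id)
      if (any(colSums(ctr[kids, , drop = FALSE]) > ctr[p, ] + tol)) next
      res <- assign_next(c(parent, stats::setNames(p, id)),
                         c(placed, id), remaining[-1])
      if (!is.null(res)) return(res)
    }
    NULL
  }
  assign_next(stats::setNames(character(0), character(0)), root, order_ids)
}

#' Validate containment and sum rule on a clone tree
#'
#' @param tree A \code{clone_tree}.
#' @param tol Tolerance; defaults to the tree's own.
#' @return The tree, invisibly; errors on violation.
#' @export
validate_tree <- function(tree, tol = tree$tol %||% 0.10) {
  ctr <- tree$centers
  ## clusters force-attached to the root are already flagged; they are
  ## exempt from the feasibility checks they are known to violate
  placed <- setdiff(names(tree$parent), tree$unplaced)
  for (child in placed) {
    p <- tree$parent[[child]]
    if (any(ctr[child, ] > ctr[p, ] + tol + 1e-9))
      stop("containment violated for ", child, " under ", p)
  }
  for (id in rownames(ctr)) {
    kids <- intersect(names(tree$parent)[tree$parent == id], placed)
    if (!length(kids)) next
    if (any(colSums(ctr[kids, , drop = FALSE]) > ctr[id, ] + tol + 1e-9))
      stop("sum rule violated at node ", id)
  }
  ## acyclicity / single root: every node must reach the root
  for (id in setdiff(rownames(ctr), tree$root)) {
    seen <- character(0); v <- id
    while (v != tree$root) {
      if (v %in% seen || !v %in% names(tree$parent)) stop("cycle or orphan at ", id)
      seen <- c(seen, v); v <- tree$parent[[v]]
    }
  }
  invisible(tree)
}

#' Per-biopsy cellular composition of a clone tree
#'
#' The cellular fraction of clone \eqn{v} in a sample is its CCF minus the
#' summed CCFs of its children (floored at zero); clones whose CCF in the
#' sample is below \code{absent_threshold} are omitted.
#'
#' @param tree A \code{clone_tree}.
#' @param sample_id Sample (column of the center matrix).
#' @param absent_threshold Clones below this CCF are omitted (default 0.10).
#' @return Named numeric vector of cellular fractions.
#' @examples
#' ctr <- rbind(C0 = c(1, 1, 1), C1 = c(1, 0, 0), C3 = c(0.4, 0, 0),
#'              C2 = c(0, 1, 1), C4 = c(0, 0, 1))
#' colnames(ctr) <- c("peritoneal", "liver1", "liver2")
#' composition(build_tree(ctr), "peritoneal")  # C1 0.6, C3 0.4
#' @export
composition <- function(tree, sample_id, absent_threshold = 0.10) {
  ctr <- tree$centers
  if (!sample_id %in% colnames(ctr)) stop("unknown sample: ", sample_id)
  out <- numeric(0)
  for (id in rownames(ctr)) {
    cc <- ctr[id, sample_id]
    if (cc < absent_threshold) next
    kids <- names(tree$parent)[tree$parent == id]
    kidsum <- if (length(kids)) sum(ctr[kids, sample_id]) else 0
    out[id] <- max(cc - kidsum, 0)
  }
  out
}

#' Mean absolute CCF distance between two biopsies
#'
#' Evolutionary genetic distance between two samples over a shared mutation
#' universe: the L1 norm of per-mutation CCF differences divided by the number
#' of mutations compared (mean absolute CCF difference). This is a metric on
#' CCF columns; the all-zero pseudo-sample \code{"normal"} serves as the
#' germline baseline.
#'
#' @param x A \code{ccf_matrix} or plain mutation x sample matrix.
#' @param sample_a,sample_b Sample ids, or \code{"normal"} for the all-zero
#'   baseline.
#' @return Nonnegative distance in CCF units.
#' @export
biopsy_distance <- function(x, sample_a, sample_b) {
  mat <- if (inherits(x, "ccf_matrix")) x$ccf else as.matrix(x)
  col <- function(s) {
    if (s == "normal") return(rep(0, nrow(mat)))
    if (!s %in% colnames(mat)) stop("unknown sample: ", s)
    mat[, s]
  }
  a <- col(sample_a); b <- col(sample_b)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("empty shared mutation universe")
  mean(abs(a[ok] - b[ok]))
}

#' All pairwise biopsy distances, including the germline baseline
#'
#' @param x A \code{ccf_matrix} or matrix.
#' @param include_normal Add the all-zero \code{"normal"} pseudo-sample
#'   (default TRUE).
#' @return Symmetric distance matrix.
#' @export
distance_matrix <- function(x, include_normal = TRUE) {
  mat <- if (inherits(x, "ccf_matrix")) x$ccf else as.matrix(x)
  ids <- colnames(mat)
  if (include_normal) ids <- c("normal", ids)
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a < b) d[a, b] <- d[b, a] <- biopsy_distance(x, ids[a], ids[b])
  }
  d
}

#' Export a clone tree as a Newick string
#'
#' Cluster ids label the nodes; branch lengths are the number of
#' cluster-private mutations (cluster weights) when available. Siblings are
#' emitted in canonical (sorted id) order.
#'
#' @param tree A \code{clone_tree}.
#' @return Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree) {
  w <- tree$weights
  emit <- function(id) {
    kids <- sort(names(tree$parent)[tree$parent == id])
    lab <- id
    if (id != tree$root && !is.na(w[id])) lab <- paste0(id, ":", w[id])
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, emit, ""), collapse = ","), ")", lab)
  }
  paste0(emit(tree$root), ";")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clone tree rooted at", x$root, "\n")
  for (child in names(x$parent))
    cat(" ", x$parent[[child]], "->", child, "\n")
  if (length(x$unplaced))
    cat("  [unplaced, forced to root:", paste(x$unplaced, collapse = ", "),
        "]\n")
  invisible(x)
}
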