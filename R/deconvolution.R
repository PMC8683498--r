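## Nonparametric subclone deconvolution: weighted kernel-density mode seeking
## over per-sample CCF coordinates, with cluster merging and size filtering.

#' Deconvolute CCF distributions into mutation clusters
#'
#' Identifies genetically distinct subpopulations as modes of the joint CCF
#' distribution. Per sample, a weighted Gaussian kernel density estimate is
#' computed over the non-missing CCFs (weights default to inverse variance;
#' bandwidth = median binomial SD of the CCFs, floored at
#' \code{bandwidth_floor}). Each mutation is snapped to its nearest density
#' mode in every coordinate; the distinct snapped vectors seed clusters, and
#' mutations are assigned to the nearest seed (hard Gaussian responsibility
#' under a shared isotropic bandwidth). Clusters whose centers differ by less
#' than \code{merge_tol} in every sample are merged; clusters below
#' \code{min_cluster_size} are dissolved into their nearest neighbor. Cluster
#' centers are the mean unclamped CCFs of their members (clamped to
#' \code{[0, 1]} for reporting), which avoids the downward bias that clamping
#' individual clonal CCFs at 1 would otherwise induce. Output is sorted by
#' descending member count; the procedure is invariant to input row order.
#'
#' @param x A \code{ccf_matrix} (preferred; supplies raw CCFs and variances)
#'   or a plain numeric mutation x sample matrix.
#' @param weights Optional per-mutation weights; defaults to inverse mean
#'   variance when available, else 1.
#' @param min_cluster_size Minimum mutations per reported cluster (default 5).
#' @param merge_tol Centers closer than this in every sample are merged
#'   (default 0.10).
#' @param bandwidth_floor Lower bound on the KDE bandwidth (default 0.05).
#' @param clonal_threshold,absent_threshold Passed to
#'   \code{\link{classify_cluster}}.
#' @return A \code{ccf_clusters} object: list with \code{clusters} (data frame:
#'   \code{cluster_id}, \code{weight}, \code{classification}, one
#'   \code{center.<sample>} column per sample), \code{centers} (cluster x
#'   sample matrix), \code{assignment} (cluster id per mutation, named by
#'   mutation key) and \code{samples}.
#' @examples
#' sc <- build_scenario("p04_like")
#' calls <- do.call(rbind, lapply(sc$samples$sample_id,
#'                                function(s) simulate_biopsy(sc, s)))
#' cm <- ccf_matrix(calls, setNames(sc$samples$purity, sc$samples$sample_id))
#' deconvolute(cm)
#' @export
deconvolute <- function(x, weights = NULL, min_cluster_size = 5,
                        merge_tol = 0.10, bandwidth_floor = 0.05,
                        clonal_threshold = 0.85, absent_threshold = 0.10) {
  if (inherits(x, "ccf_matrix")) {
    mat <- x$ccf; raw <- x$raw; vars <- x$variance
  } else {
    mat <- as.matrix(x); raw <- mat; vars <- NULL
  }
  if (is.null(rownames(mat)))
    rownames(mat) <- rownames(raw) <- paste0("m", seq_len(nrow(mat)))
  usable <- rowSums(!is.na(mat)) > 0
  mat <- mat[usable, , drop = FALSE]
  raw <- raw[usable, , drop = FALSE]
  if (!is.null(vars)) vars <- vars[usable, , drop = FALSE]
  n <- nrow(mat)
  if (n == 0) stop("all CCFs missing")
  if (n < min_cluster_size)
    stop("fewer mutations (", n, ") than min_cluster_size (",
         min_cluster_size, ")")
  if (is.null(weights)) {
    weights <- if (!is.null(vars)) {
      v <- rowMeans(vars, na.rm = TRUE)
      1 / pmax(v, 1e-4)
    } else rep(1, n)
  }
  weights <- weights / sum(weights)

  ## per-coordinate weighted KDE modes, then snap each value to nearest mode
  snapped <- mat
  for (j in seq_len(ncol(mat))) {
    ok <- !is.na(mat[, j])
    vals <- mat[ok, j]
    bw <- bandwidth_floor
    if (!is.null(vars)) {
      sds <- sqrt(vars[ok, j])
      bw <- max(stats::median(sds, na.rm = TRUE), bandwidth_floor)
    }
    modes <- kde_modes(vals, weights[ok] / sum(weights[ok]), bw)
    snapped[ok, j] <- modes[
      apply(abs(outer(vals, modes, "-")), 1, which.min)]
  }

  ## seeds = distinct snapped vectors; initial hard assignment by seed key
  key <- apply(round(snapped, 6), 1, paste, collapse = "|")
  groups <- split(seq_len(n), key)
  centers <- t(vapply(groups, function(ix)
    colMeans(raw[ix, , drop = FALSE], na.rm = TRUE), numeric(ncol(mat))))
  centers <- matrix(pmin(pmax(centers, 0), 1), nrow = length(groups),
                    dimnames = list(NULL, colnames(mat)))
  members <- groups

  ## merge clusters whose centers agree within merge_tol in every sample
  repeat {
    k <- length(members)
    if (k < 2) break
    dmax <- matrix(Inf, k, k)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      d <- abs(centers[a, ] - centers[b, ])
      dmax[a, b] <- if (all(is.na(d))) Inf else max(d, na.rm = TRUE)
    }
    best <- which(dmax == min(dmax), arr.ind = TRUE)[1, , drop = TRUE]
    if (dmax[best[1], best[2]] >= merge_tol) break
    a <- best[1]; b <- best[2]
    members[[a]] <- sort(c(members[[a]], members[[b]]))
    members[[b]] <- NULL
    centers <- recompute_centers(members, raw)
  }

  ## dissolve undersized clusters into nearest surviving neighbor
  repeat {
    sizes <- lengths(members)
    if (length(members) < 2 || all(sizes >= min_cluster_size)) break
    small <- which.min(ifelse(sizes < min_cluster_size, sizes, Inf))
    d <- apply(centers, 1, function(cn)
      sqrt(mean((cn - centers[small, ])^2, na.rm = TRUE)))
    d[small] <- Inf
    tgt <- which.min(d)
    members[[tgt]] <- sort(c(members[[tgt]], members[[small]]))
    members[[small]] <- NULL
    centers <- recompute_centers(members, raw)
  }

  ord <- order(-lengths(members),
               vapply(members, function(ix) min(rownames(mat)[ix]), ""))
  members <- members[ord]
  centers <- centers[ord, , drop = FALSE]
  ids <- paste0("K", seq_along(members))
  rownames(centers) <- ids
  assignment <- character(n)
  for (i in seq_along(members)) assignment[members[[i]]] <- ids[i]
  names(assignment) <- rownames(mat)
  classification <- vapply(seq_along(members), function(i)
    classify_cluster(centers[i, ], clonal_threshold, absent_threshold), "")
  clusters <- data.frame(cluster_id = ids, weight = lengths(members),
                         classification = classification,
                         stringsAsFactors = FALSE)
  for (s in colnames(centers)) clusters[[paste0("center.", s)]] <- centers[, s]
  structure(list(clusters = clusters, centers = centers,
                 assignment = assignment, samples = colnames(mat)),
            class = "ccf_clusters")
}

recompute_centers <- function(members, raw) {
  ctr <- t(vapply(members, function(ix)
    colMeans(raw[ix, , drop = FALSE], na.rm = TRUE), numeric(ncol(raw))))
  matrix(pmin(pmax(ctr, 0), 1), nrow = length(members),
         dimnames = list(NULL, colnames(raw)))
}

## Local maxima of a weighted Gaussian KDE on a fixed grid.
kde_modes <- function(vals, w, bw) {
  if (length(unique(vals)) == 1) return(vals[1])
  d <- stats::density(vals, weights = w, bw = bw, from = -0.25, to = 1.25,
                      n = 512)
  y <- d$y
  k <- length(y)
  is_max <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
              FALSE)
  ## ignore modes carrying negligible density relative to the main mode
  is_max <- is_max & y > max(y) * 1e-3
  if (!any(is_max)) return(d$x[which.max(y)])
  d$x[is_max]
}

#' Classify a cluster as clonal, shared-subclonal, private or absent
#'
#' A cluster is \code{clonal_all} when its center reaches
#' \code{clonal_threshold} in every sample; \code{private:<sample>} when it
#' exceeds \code{absent_threshold} in exactly one sample (a trailing
#' \code{" (subclonal)"} flag marks private clusters below the clonal
#' threshold in their own sample); \code{absent} when it is below
#' \code{absent_threshold} everywhere; otherwise \code{shared_subclonal}.
#' Missing centers are treated as absent.
#'
#' @param centers Named numeric vector of per-sample cluster centers.
#' @param clonal_threshold CCF at or above which a cluster counts as clonal in
#'   a sample (default 0.85).
#' @param absent_threshold CCF at or below which a cluster counts as absent
#'   from a sample (default 0.10).
#' @return Classification string.
#' @examples
#' classify_cluster(c(a = 1, b = 1, c = 1))      # clonal_all
#' classify_cluster(c(a = 0.95, b = 0.02))       # private:a
#' classify_cluster(c(a = 0.4, b = 0, c = 0))    # private:a (subclonal)
#' @export
classify_cluster <- function(centers, clonal_threshold = 0.85,
                             absent_threshold = 0.10) {
  cn <- centers
  cn[is.na(cn)] <- 0
  if (all(cn >= clonal_threshold)) return("clonal_all")
  present <- cn > absent_threshold
  if (sum(present) == 0) return("absent")
  if (sum(present) == 1) {
    s <- names(cn)[present]
    if (is.null(s)) s <- as.character(which(present))
    flag <- if (cn[present] < clonal_threshold) " (subclonal)" else ""
    return(paste0("private:", s, flag))
  }
  "shared_subclonal"
}

#' Pairwise deconvolution of two samples with a per-mutation scatter table
#'
#' Restricts the CCF matrix to two samples, deconvolutes the two-column
#' submatrix and emits a per-mutation table suitable for the classic pairwise
#' CCF scatter plot of shared versus private mutation clusters.
#'
#' @param x A \code{ccf_matrix}.
#' @param sample_a,sample_b Sample ids.
#' @param ... Passed to \code{\link{deconvolute}}.
#' @return A list: \code{clusters} (the \code{ccf_clusters} object for the
#'   pair) and \code{scatter} (data frame: mutation key, gene, \code{ccf_a},
#'   \code{ccf_b}, \code{cluster}, \code{classification}).
#' @export
pairwise_clusters <- function(x, sample_a, sample_b, ...) {
  stopifnot(inherits(x, "ccf_matrix"))
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(x$ccf)) stop("sample not in matrix: ", s)
  sub <- structure(list(
    ccf = x$ccf[, c(sample_a, sample_b), drop = FALSE],
    raw = x$raw[, c(sample_a, sample_b), drop = FALSE],
    variance = x$variance[, c(sample_a, sample_b), drop = FALSE],
    info = x$info), class = "ccf_matrix")
  cl <- deconvolute(sub, ...)
  keys <- names(cl$assignment)
  cls <- cl$clusters$classification[match(cl$assignment,
                                          cl$clusters$cluster_id)]
  scatter <- data.frame(
    key = keys,
    gene = x$info$gene[match(keys, x$info$key)],
    ccf_a = x$ccf[keys, sample_a],
    ccf_b = x$ccf[keys, sample_b],
    cluster = unname(cl$assignment),
    classification = cls,
    stringsAsFactors = FALSE
  )
  list(clusters = cl, scatter = scatter)
}

#' @export
print.ccf_clusters <- function(x, ...) {
  cat("CCF clusters over samples:", paste(x$samples, collapse = ", "), "\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}
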