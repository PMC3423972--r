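#' Agglomerative hierarchical clustering of compound profiles
#'
#' Greedy agglomeration: repeatedly merges the pair of active clusters at
#' minimum inter-cluster dissimilarity, recording that dissimilarity as the
#' merge height. Inter-cluster dissimilarity is the minimum cross-pair
#' distance for `single`, the maximum for `complete`, the unweighted
#' arithmetic mean over all cross pairs for `average` (UPGMA), and for
#' `centroid` the trial's measure evaluated between the coordinate-wise mean
#' profiles of the two clusters (mean over present entries per gene), which
#' supports centroid linkage under correlation measures the way Cluster 3.0
#' does rather than the Euclidean-only Lance-Williams update.
#'
#' When two candidate pairs tie at the minimum distance, the pair whose
#' (smaller, larger) tuple of minimal original row indices is lexicographically
#' least is merged, making results deterministic across platforms. Heights are
#' non-decreasing for single/complete/average; centroid linkage may produce
#' inversions, which are reported via a message but not rejected.
#'
#' @param d A `chemo_dist` from [pairwise_distance()].
#' @param linkage One of [chemo_linkages()].
#' @param profiles The [chemgen_matrix()] the distances came from; required
#'   for centroid linkage, ignored otherwise.
#' @param scale_by_shared Passed to the centroid distance kernel; must match
#'   the setting used for `d`.
#' @return An object of class `chemo_dendrogram`: list with `leaf_ids`,
#'   `merge` (an (n-1) x 2 integer matrix in `stats::hclust` convention:
#'   negative entries index leaves, positive entries earlier merges),
#'   `height`, `linkage`, and `measure`.
#' @export
cluster_profiles <- function(d, linkage, profiles = NULL,
                             scale_by_shared = FALSE) {
  stopifnot(inherits(d, "chemo_dist"))
  linkage <- match.arg(linkage, chemo_linkages())
  D <- d$d
  n <- nrow(D)
  if (n < 2) stop("need at least two compounds to cluster", call. = FALSE)
  off <- D
  diag(off) <- 0
  if (anyNA(off)) {
    stop(errorCondition(
      paste0("distance matrix under '", d$measure,
             "' has undefined entries; trial is degenerate"),
      class = c("chemo_degenerate_error", "error", "condition")))
  }
  cent <- NULL
  if (linkage == "centroid") {
    if (is.null(profiles)) {
      stop("centroid linkage requires 'profiles'", call. = FALSE)
    }
    stopifnot(inherits(profiles, "chemgen_matrix"))
    v <- profiles$values[d$ids, , drop = FALSE]
    cent <- v
  }
  members <- as.list(seq_len(n))
  node <- -seq_len(n)      # signed node reference per active cluster
  rep_ <- seq_len(n)       # minimal original row index per active cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  inversions <- 0L
  for (k in seq_len(n - 1L)) {
    na_ <- nrow(D)
    Du <- D
    Du[lower.tri(Du, diag = TRUE)] <- Inf
    mind <- min(Du)
    cand <- which(Du == mind, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      key1 <- pmin(rep_[cand[, 1]], rep_[cand[, 2]])
      key2 <- pmax(rep_[cand[, 1]], rep_[cand[, 2]])
      cand <- cand[order(key1, key2)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    height[k] <- mind
    if (k > 1L && mind < height[k - 1L]) inversions <- inversions + 1L
    merge[k, ] <- if (rep_[i] <= rep_[j]) c(node[i], node[j]) else c(node[j], node[i])
    newmem <- c(members[[i]], members[[j]])
    if (linkage == "single") {
      newd <- pmin(D[i, ], D[j, ])
    } else if (linkage == "complete") {
      newd <- pmax(D[i, ], D[j, ])
    } else if (linkage == "average") {
      ni <- length(members[[i]]); nj <- length(members[[j]])
      newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    } else {
      newc <- .centroid_profile(v, newmem)
      newd <- vapply(seq_len(na_), function(cc) {
        if (cc == i || cc == j) return(0)
        dd <- .pair_dist(newc, cent[cc, ], d$measure, scale_by_shared)
        if (is.na(dd) && .is_corr_measure(d$measure)) {
          dd <- .max_corr_dist(d$measure)
        }
        dd
      }, numeric(1))
      if (anyNA(newd)) {
        stop(errorCondition(
          "centroid distance undefined (no shared genes); trial is degenerate",
          class = c("chemo_degenerate_error", "error", "condition")))
      }
    }
    keep <- setdiff(seq_len(na_), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    members <- c(members[keep], list(newmem))
    node <- c(node[keep], k)
    rep_ <- c(rep_[keep], min(rep_[i], rep_[j]))
    if (linkage == "centroid") {
      cent <- rbind(cent[keep, , drop = FALSE], newc)
    }
  }
  if (inversions > 0L) {
    message(sprintf("%s linkage produced %d height inversion(s)",
                    linkage, inversions))
  }
  structure(list(leaf_ids = d$ids, merge = merge, height = height,
                 linkage = linkage, measure = d$measure),
            class = "chemo_dendrogram")
}

# per-gene mean over present entries across the member compounds
.centroid_profile <- function(v, idx) {
  cm <- colMeans(v[idx, , drop = FALSE], na.rm = TRUE)
  cm[is.nan(cm)] <- NA_real_
  cm
}

#' @export
print.chemo_dendrogram <- function(x, ...) {
  cat(sprintf("chemo_dendrogram: %d leaves, %s linkage on %s distances\n",
              length(x$leaf_ids), x$linkage, x$measure))
  invisible(x)
}

# leaf index sets of every merge node, in merge order
.merge_members <- function(t) {
  n <- length(t$leaf_ids)
  memb <- vector("list", n - 1L)
  part <- function(x) if (x < 0) -x else memb[[x]]
  for (k in seq_len(n - 1L)) {
    memb[[k]] <- c(part(t$merge[k, 1]), part(t$merge[k, 2]))
  }
  memb
}

#' Cut a dendrogram into k groups
#'
#' Undoes the last `k - 1` merges and returns the `k` resulting leaf sets
#' (height ties resolved by merge order: later merges are undone first).
#' Groups are ordered by their smallest original row index.
#'
#' @param t A `chemo_dendrogram`.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return List of `k` character vectors of leaf identifiers.
#' @export
cut_dendrogram <- function(t, k) {
  stopifnot(inherits(t, "chemo_dendrogram"))
  n <- length(t$leaf_ids)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n) {
    stop("'k' must be between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  }
  k <- as.integer(k)
  napply <- n - k
  memb <- .merge_members(t)
  consumed_leaf <- rep(FALSE, n)
  consumed_node <- rep(FALSE, n - 1L)
  for (m in seq_len(napply)) {
    for (child in t$merge[m, ]) {
      if (child < 0) consumed_leaf[-child] <- TRUE else consumed_node[child] <- TRUE
    }
  }
  groups <- c(
    lapply(which(!consumed_leaf), identity),
    memb[seq_len(napply)][!consumed_node[seq_len(napply)]]
  )
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  lapply(groups, function(g) t$leaf_ids[sort(g)])
}

#' Cophenetic distances of a dendrogram
#'
#' Entry (i, j) is the height of the merge that first joins leaves i and j.
#' Mainly an oracle surface for testing (e.g., the single-linkage cophenetic
#' distance is the subdominant ultrametric, bounded above by the input
#' distance for every pair).
#'
#' @param x A `chemo_dendrogram`.
#' @param ... Unused.
#' @return A `chemo_dist` with `measure = "cophenetic"`.
#' @exportS3Method stats::cophenetic
cophenetic.chemo_dendrogram <- function(x, ...) {
  n <- length(x$leaf_ids)
  h <- matrix(0, n, n, dimnames = list(x$leaf_ids, x$leaf_ids))
  memb <- vector("list", n - 1L)
  part <- function(z) if (z < 0) -z else memb[[z]]
  for (k in seq_len(n - 1L)) {
    a <- part(x$merge[k, 1]); b <- part(x$merge[k, 2])
    h[a, b] <- x$height[k]
    h[b, a] <- x$height[k]
    memb[[k]] <- c(a, b)
  }
  structure(list(ids = x$leaf_ids, d = h, measure = "cophenetic"),
            class = "chemo_dist")
}

#' Convert to a stats::hclust object
#'
#' Enables plotting and interoperability with base R tree utilities. Centroid
#' trees with height inversions convert, but base plotting may render them
#' oddly.
#'
#' @param x A `chemo_dendrogram`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @exportS3Method stats::as.hclust
as.hclust.chemo_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = .dend_leaf_order(x), labels = x$leaf_ids,
                 method = x$linkage, dist.method = x$measure,
                 call = match.call()),
            class = "hclust")
}
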