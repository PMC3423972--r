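#' Enumerate clustering trials
#'
#' Cartesian product of similarity measures and linkages, measures-major
#' (linkage varies fastest), minus an optional exclusion list. With the full
#' default sets this yields 28 trials; any chosen subset (e.g. the 19 trials
#' of the original screen analysis, whose identity was not recorded) can be
#' reproduced via `exclude`.
#'
#' @param measures Character vector of measure names ([chemo_measures()]).
#' @param linkages Character vector of linkage names ([chemo_linkages()]).
#' @param exclude Trials to drop: a data frame with `measure` and `linkage`
#'   columns, or a character vector of `"measure:linkage"` strings.
#' @return Data frame with columns `measure` and `linkage`.
#' @export
enumerate_trials <- function(measures = chemo_measures(),
                             linkages = chemo_linkages(),
                             exclude = NULL) {
  if (length(measures) < 1 || length(linkages) < 1) {
    stop("'measures' and 'linkages' must be non-empty", call. = FALSE)
  }
  bad_m <- setdiff(measures, chemo_measures())
  if (length(bad_m)) stop("unknown measure: ", paste(bad_m, collapse = ", "),
                          call. = FALSE)
  bad_l <- setdiff(linkages, chemo_linkages())
  if (length(bad_l)) stop("unknown linkage: ", paste(bad_l, collapse = ", "),
                          call. = FALSE)
  if (anyDuplicated(measures) || anyDuplicated(linkages)) {
    stop("'measures' and 'linkages' must not contain duplicates", call. = FALSE)
  }
  trials <- data.frame(
    measure = rep(measures, each = length(linkages)),
    linkage = rep(linkages, times = length(measures)),
    stringsAsFactors = FALSE)
  if (!is.null(exclude)) {
    if (is.character(exclude)) {
      parts <- strsplit(exclude, ":", fixed = TRUE)
      if (any(lengths(parts) != 2)) {
        stop("character 'exclude' entries must look like 'measure:linkage'",
             call. = FALSE)
      }
      exclude <- data.frame(measure = vapply(parts, `[`, "", 1),
                            linkage = vapply(parts, `[`, "", 2),
                            stringsAsFactors = FALSE)
    }
    stopifnot(is.data.frame(exclude),
              all(c("measure", "linkage") %in% names(exclude)))
    bad <- setdiff(exclude$measure, chemo_measures())
    if (length(bad)) stop("unknown measure in 'exclude': ",
                          paste(bad, collapse = ", "), call. = FALSE)
    bad <- setdiff(exclude$linkage, chemo_linkages())
    if (length(bad)) stop("unknown linkage in 'exclude': ",
                          paste(bad, collapse = ", "), call. = FALSE)
    key <- paste(trials$measure, trials$linkage, sep = ":")
    drop <- key %in% paste(exclude$measure, exclude$linkage, sep = ":")
    trials <- trials[!drop, , drop = FALSE]
    rownames(trials) <- NULL
  }
  trials
}

#' Subcluster extraction policies
#'
#' `min_size(m)` selects, for a given leaf, the smallest ancestor cluster with
#' at least `m` leaves (walking up the merge tree from the leaf); `cut_k(k)`
#' cuts the tree into `k` groups and selects the group containing the leaf.
#'
#' @param m,k Positive integer policy parameter.
#' @return A `subcluster_policy` object.
#' @export
min_size <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 1)
  structure(list(type = "min_size", m = as.integer(m)),
            class = "subcluster_policy")
}

#' @rdname min_size
#' @export
cut_k <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  structure(list(type = "cut_k", k = as.integer(k)),
            class = "subcluster_policy")
}

#' @export
print.subcluster_policy <- function(x, ...) {
  cat(sprintf("subcluster policy: %s(%d)\n", x$type,
              if (x$type == "min_size") x$m else x$k))
  invisible(x)
}

#' Extract the signature compound's subcluster from one tree
#'
#' Realizes "the compounds grouped with the signature" for a single clustering
#' trial under a [min_size()] or [cut_k()] policy.
#'
#' @param t A `chemo_dendrogram`.
#' @param signature_id Leaf identifier of the signature compound.
#' @param policy A `subcluster_policy`.
#' @return Character vector of leaf identifiers, including the signature.
#' @export
signature_subcluster <- function(t, signature_id, policy) {
  stopifnot(inherits(t, "chemo_dendrogram"),
            inherits(policy, "subcluster_policy"))
  pos <- match(signature_id, t$leaf_ids)
  if (is.na(pos)) {
    stop("signature compound '", signature_id, "' is not among the leaves",
         call. = FALSE)
  }
  if (policy$type == "cut_k") {
    groups <- cut_dendrogram(t, policy$k)
    hit <- vapply(groups, function(g) signature_id %in% g, logical(1))
    return(groups[[which(hit)]])
  }
  if (policy$m <= 1L) return(t$leaf_ids[pos])
  memb <- .merge_members(t)
  cur <- -pos
  for (k in seq_along(memb)) {
    if (cur %in% t$merge[k, ]) {
      cur <- k
      if (length(memb[[k]]) >= policy$m) {
        return(t$leaf_ids[sort(memb[[k]])])
      }
    }
  }
  t$leaf_ids  # root: m exceeds the leaf count
}

#' Consensus co-clustering ranking against a signature compound
#'
#' The prioritization engine: for each (measure, linkage) trial it computes
#' pairwise distances, builds the tree, extracts the signature compound's
#' subcluster, and finally ranks every compound by the fraction of completed
#' trials in which it co-clustered with the signature. Compounds that land in
#' the signature's neighborhood regardless of the choice of measure and
#' linkage are the robust mechanism-sharing candidates.
#'
#' A trial whose distance matrix is degenerate (undefined Euclidean/city-block
#' pairs with no shared genes) is skipped with a warning and excluded from the
#' frequency denominator: a failed trial carries no evidence.
#'
#' @param m A [chemgen_matrix()].
#' @param signature_id Compound identifier of the signature (reference)
#'   compound.
#' @param trials Data frame of trials from [enumerate_trials()].
#' @param policy A `subcluster_policy`; default `min_size(max(2, ceil(0.05 n)))`.
#' @param scale_by_shared Passed to [pairwise_distance()].
#' @return An object of class `consensus_ranking`: list with `signature_id`,
#'   `trials_run` (completed trials), `frequency` (named vector sorted by
#'   descending frequency, ties by compound id), `per_trial_members`, `policy`
#'   and `skipped`.
#' @export
consensus_rank <- function(m, signature_id, trials = enumerate_trials(),
                           policy = NULL, scale_by_shared = FALSE) {
  stopifnot(inherits(m, "chemgen_matrix"))
  ids <- rownames(m$values)
  if (!signature_id %in% ids) {
    stop("signature compound '", signature_id, "' is not in the matrix",
         call. = FALSE)
  }
  if (!is.data.frame(trials) || nrow(trials) < 1) {
    stop("at least one trial is required", call. = FALSE)
  }
  if (is.null(policy)) {
    policy <- min_size(max(2L, ceiling(0.05 * length(ids))))
  }
  counts <- stats::setNames(numeric(length(ids)), ids)
  dist_cache <- list()
  per_trial <- list()
  skipped <- character(0)
  for (ti in seq_len(nrow(trials))) {
    me <- trials$measure[ti]
    li <- trials$linkage[ti]
    key <- paste(me, li, sep = ":")
    dm <- dist_cache[[me]]
    if (is.null(dm)) {
      dm <- pairwise_distance(m, me, scale_by_shared)
      dist_cache[[me]] <- dm
    }
    sub <- tryCatch({
      dend <- cluster_profiles(dm, li,
                               profiles = if (li == "centroid") m else NULL,
                               scale_by_shared = scale_by_shared)
      signature_subcluster(dend, signature_id, policy)
    }, chemo_degenerate_error = function(e) {
      warning(sprintf("trial %s skipped: %s", key, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(sub)) {
      skipped <- c(skipped, key)
      next
    }
    counts[sub] <- counts[sub] + 1
    per_trial[[key]] <- sub
  }
  done <- nrow(trials) - length(skipped)
  if (done == 0) stop("all trials were degenerate; no ranking possible",
                      call. = FALSE)
  freq <- counts / done
  freq <- freq[order(-freq, names(freq))]
  structure(list(signature_id = signature_id, trials_run = done,
                 frequency = freq, per_trial_members = per_trial,
                 policy = policy, skipped = skipped),
            class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, n = 10, ...) {
  cat(sprintf("consensus_ranking: signature '%s', %d trial(s) completed",
              x$signature_id, x$trials_run))
  if (length(x$skipped)) cat(sprintf(" (%d skipped)", length(x$skipped)))
  cat("\ntop compounds by co-clustering frequency:\n")
  print(utils::head(x$frequency, n))
  invisible(x)
}

#' Ranking table of a consensus run
#'
#' @param x A `consensus_ranking`.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return Data frame with columns `rank`, `compound_id`, `frequency`,
#'   `n_trials`.
#' @export
as.data.frame.consensus_ranking <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(rank = seq_along(x$frequency),
             compound_id = names(x$frequency),
             frequency = unname(x$frequency),
             n_trials = x$trials_run,
             stringsAsFactors = FALSE)
}
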