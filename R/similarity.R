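#' Supported similarity measures and linkages
#'
#' The seven profile dissimilarity measures and four agglomerative linkages
#' over which clustering trials are enumerated.
#'
#' @return Character vector of measure (resp. linkage) names.
#' @export
chemo_measures <- function() {
  c("centered_corr", "uncentered_corr", "abs_centered_corr",
    "abs_uncentered_corr", "spearman", "euclidean", "cityblock")
}

#' @rdname chemo_measures
#' @export
chemo_linkages <- function() {
  c("single", "complete", "average", "centroid")
}

.is_corr_measure <- function(measure) {
  measure %in% c("centered_corr", "uncentered_corr", "abs_centered_corr",
                 "abs_uncentered_corr", "spearman")
}

# maximum of a correlation-family distance: the "no evidence of similarity"
# value substituted when the coefficient is undefined
.max_corr_dist <- function(measure) {
  if (startsWith(measure, "abs_")) 1 else 2
}

# Euclidean / city-block over co-present entries. Sums are NOT rescaled by the
# shared-gene count unless scale_by_shared; zero shared genes -> NA.
.minkowski_pair <- function(x, y, measure, scale_by_shared = FALSE) {
  ok <- !is.na(x) & !is.na(y)
  ns <- sum(ok)
  if (ns < 1L) return(NA_real_)
  dxy <- x[ok] - y[ok]
  s <- if (measure == "euclidean") sum(dxy * dxy) else sum(abs(dxy))
  if (scale_by_shared) s <- s / ns
  if (measure == "euclidean") sqrt(s) else s
}

# Scalar dissimilarity kernel between two profiles under any measure.
# Correlation family: undefined coefficients (constant profile, < 2 co-present
# genes, zero norm) return NA; callers substitute the measure maximum.
.pair_dist <- function(x, y, measure, scale_by_shared = FALSE) {
  if (!.is_corr_measure(measure)) {
    return(.minkowski_pair(x, y, measure, scale_by_shared))
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  r <- switch(measure,
    centered_corr = ,
    abs_centered_corr = suppressWarnings(stats::cor(x, y)),
    spearman = suppressWarnings(stats::cor(x, y, method = "spearman")),
    uncentered_corr = ,
    abs_uncentered_corr = {
      den <- sqrt(sum(x * x) * sum(y * y))
      if (den == 0) NA_real_ else sum(x * y) / den
    })
  if (is.na(r)) return(NA_real_)
  d <- if (startsWith(measure, "abs_")) 1 - abs(r) else 1 - r
  max(d, 0)  # clip rounding when |r| marginally exceeds 1
}

#' Pairwise compound-compound dissimilarity matrix
#'
#' Computes all compound pair dissimilarities under one named measure, using
#' only genes present in both profiles (pairwise-complete deletion). The
#' correlation-family distances are `1 - r` (or `1 - |r|` for the absolute
#' variants) with `r` the Pearson, uncentered (cosine-like, no mean
#' subtraction) or Spearman mid-rank coefficient over the co-present entries.
#' Euclidean and city-block sums run over co-present entries and, by default,
#' are not rescaled by the shared-gene count; set `scale_by_shared = TRUE` to
#' divide the sums by that count for length-invariance across missingness
#' patterns.
#'
#' An undefined correlation (constant profile, fewer than two shared genes,
#' zero norm) is conservatively replaced by the measure's maximum distance (2,
#' or 1 for absolute variants) with a warning. Euclidean/city-block pairs with
#' no shared genes are left `NA` (the trial is then degenerate and skipped by
#' [consensus_rank()]).
#'
#' @param m A [chemgen_matrix()] with at least two compounds.
#' @param measure One of [chemo_measures()].
#' @param scale_by_shared Divide Euclidean/city-block sums by the co-present
#'   gene count (default `FALSE`).
#' @return An object of class `chemo_dist`: list with `ids`, symmetric matrix
#'   `d` with zero diagonal, and `measure`.
#' @export
pairwise_distance <- function(m, measure, scale_by_shared = FALSE) {
  stopifnot(inherits(m, "chemgen_matrix"))
  measure <- match.arg(measure, chemo_measures())
  v <- m$values
  n <- nrow(v)
  if (n < 2) stop("need at least two compounds", call. = FALSE)
  ids <- rownames(v)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  n_undef <- 0L
  for (i in seq_len(n - 1L)) {
    xi <- v[i, ]
    for (j in (i + 1L):n) {
      dij <- .pair_dist(xi, v[j, ], measure, scale_by_shared)
      if (is.na(dij) && .is_corr_measure(measure)) {
        n_undef <- n_undef + 1L
        dij <- .max_corr_dist(measure)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (n_undef > 0L) {
    warning(sprintf(paste0("%d compound pair(s) had an undefined %s ",
                           "coefficient; distance set to the measure maximum"),
                    n_undef, measure), call. = FALSE)
  }
  if (!.is_corr_measure(measure) && anyNA(d)) {
    warning("some compound pairs share no genes; their ", measure,
            " distance is undefined (NA)", call. = FALSE)
  }
  structure(list(ids = ids, d = d, measure = measure), class = "chemo_dist")
}

#' @export
print.chemo_dist <- function(x, ...) {
  cat(sprintf("chemo_dist: %d compounds, measure = %s\n",
              length(x$ids), x$measure))
  invisible(x)
}
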