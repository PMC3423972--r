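# Independent naive oracles: direct-formula dissimilarities, an O(n^3)
# re-scan agglomeration that recomputes every inter-cluster distance from
# scratch at every step, and a choose()-based exact-test enumeration. These
# deliberately avoid the package's code paths (stats::cor, stats::dhyper,
# incremental distance updates).

oracle_midrank <- function(v) {
  vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
}

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) NA_real_ else num / den
}

oracle_pair_dist <- function(x, y, measure) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  nn <- length(x)
  if (measure %in% c("euclidean", "cityblock")) {
    if (nn < 1) return(NA_real_)
    s <- 0
    for (g in seq_len(nn)) {
      s <- s + if (measure == "euclidean") (x[g] - y[g])^2 else abs(x[g] - y[g])
    }
    return(if (measure == "euclidean") sqrt(s) else s)
  }
  if (nn < 2) return(NA_real_)
  r <- switch(measure,
    centered_corr = ,
    abs_centered_corr = oracle_pearson(x, y),
    spearman = oracle_pearson(oracle_midrank(x), oracle_midrank(y)),
    uncentered_corr = ,
    abs_uncentered_corr = {
      den <- sqrt(sum(x^2) * sum(y^2))
      if (den == 0) NA_real_ else sum(x * y) / den
    })
  if (is.na(r)) return(NA_real_)
  if (startsWith(measure, "abs_")) 1 - abs(r) else max(1 - r, 0)
}

oracle_distance_matrix <- function(v, measure) {
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  maxd <- if (startsWith(measure, "abs_")) 1 else 2
  corr_family <- !measure %in% c("euclidean", "cityblock")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- oracle_pair_dist(v[i, ], v[j, ], measure)
      if (is.na(dd) && corr_family) dd <- maxd
      d[i, j] <- d[j, i] <- dd
    }
  }
  d
}

oracle_colmeans_present <- function(v, idx) {
  out <- numeric(ncol(v))
  for (g in seq_len(ncol(v))) {
    col <- v[idx, g]
    col <- col[!is.na(col)]
    out[g] <- if (length(col)) sum(col) / length(col) else NA_real_
  }
  out
}

# naive re-scan agglomeration; returns merge heights and the cophenetic
# matrix (which pins down the topology as well)
oracle_cluster <- function(D, linkage, v = NULL, measure = NULL) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  maxd <- if (!is.null(measure) && startsWith(measure, "abs_")) 1 else 2
  corr_family <- !is.null(measure) &&
    !measure %in% c("euclidean", "cityblock")
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        A <- clusters[[i]]; B <- clusters[[j]]
        dd <- switch(linkage,
          single = min(D[A, B]),
          complete = max(D[A, B]),
          average = mean(D[A, B]),
          centroid = {
            cd <- oracle_pair_dist(oracle_colmeans_present(v, A),
                                   oracle_colmeans_present(v, B), measure)
            if (is.na(cd) && corr_family) cd <- maxd
            cd
          })
        key <- c(dd, min(min(A), min(B)), max(min(A), min(B)))
        if (is.null(best) || dd < best$key[1] - 1e-15 ||
            (abs(dd - best$key[1]) <= 1e-15 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    A <- clusters[[best$i]]; B <- clusters[[best$j]]
    heights <- c(heights, best$key[1])
    coph[A, B] <- best$key[1]
    coph[B, A] <- best$key[1]
    clusters <- c(clusters[-c(best$i, best$j)], list(c(A, B)))
  }
  list(heights = heights, coph = coph)
}

# exhaustive margin-consistent enumeration of the two-sided exact test
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  probs <- c()
  p_obs <- NA
  for (a2 in 0:min(r1, c1)) {
    b2 <- r1 - a2; c2 <- c1 - a2; d2 <- n - r1 - c2
    if (b2 < 0 || c2 < 0 || d2 < 0) next
    pr <- choose(r1, a2) * choose(n - r1, c2) / choose(n, c1)
    probs <- c(probs, pr)
    if (a2 == a) p_obs <- pr
  }
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}
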