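# programmatic fixtures: random profile matrices built in code at test time

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(.local_envir = env)
}

random_chemgen <- function(n = 10, g = 30, missing_rate = 0, seed = 1,
                           transform = "neglog10") {
  set.seed(seed)
  v <- matrix(runif(n * g), n, g,
              dimnames = list(sprintf("c%02d", seq_len(n)),
                              sprintf("g%02d", seq_len(g))))
  if (missing_rate > 0) {
    v[matrix(runif(n * g) < missing_rate, n, g)] <- NA_real_
  }
  # transform "neglog10" tag skips the [0,1] range check; values here are
  # uniform so either tag is valid
  chemgen_matrix(v, transform)
}

# wrap a plain numeric matrix (rows = compounds) as a chemgen_matrix
as_chemgen <- function(v, ids = NULL, transform = "neglog10") {
  if (is.null(dim(v))) v <- matrix(v, ncol = 1)
  if (is.null(rownames(v))) {
    rownames(v) <- if (is.null(ids)) sprintf("c%02d", seq_len(nrow(v))) else ids
  }
  if (is.null(colnames(v))) colnames(v) <- sprintf("g%02d", seq_len(ncol(v)))
  chemgen_matrix(v, transform)
}
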