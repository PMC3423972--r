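test_that("trial enumeration is the measures-major Cartesian product", {
  trials <- enumerate_trials()
  expect_equal(nrow(trials), 28)
  expect_equal(trials$measure[1:4], rep(chemo_measures()[1], 4))
  expect_equal(trials$linkage[1:4], chemo_linkages())
  expect_equal(anyDuplicated(paste(trials$measure, trials$linkage)), 0L)

  one <- enumerate_trials("spearman", "average")
  expect_equal(nrow(one), 1)

  # dropping 9 combinations leaves the 19-trial configuration
  excl <- trials[c(2, 5, 8, 11, 14, 17, 20, 23, 26), ]
  nineteen <- enumerate_trials(exclude = excl)
  expect_equal(nrow(nineteen), 19)
  excl_str <- paste(excl$measure, excl$linkage, sep = ":")
  expect_equal(enumerate_trials(exclude = excl_str), nineteen)

  expect_error(enumerate_trials(measures = c("euclidean", "bogus")),
               "unknown measure")
  expect_error(enumerate_trials(linkages = "ward"), "unknown linkage")
  expect_error(enumerate_trials(exclude = "euclidean-single"),
               "measure:linkage")
})

test_that("signature subcluster extraction follows the policy", {
  m <- as_chemgen(matrix(c(0, 1, 10), 3, 1,
                         dimnames = list(c("a", "b", "c"), "g1")))
  t <- cluster_profiles(pairwise_distance(m, "euclidean"), "single")
  expect_equal(signature_subcluster(t, "a", cut_k(2)), c("a", "b"))
  expect_equal(signature_subcluster(t, "c", cut_k(2)), "c")
  expect_equal(signature_subcluster(t, "a", min_size(1)), "a")
  expect_equal(signature_subcluster(t, "a", min_size(2)), c("a", "b"))
  expect_equal(signature_subcluster(t, "a", min_size(3)), c("a", "b", "c"))
  # m beyond the leaf count returns the root
  expect_equal(signature_subcluster(t, "b", min_size(10)), c("a", "b", "c"))
  expect_error(signature_subcluster(t, "zz", min_size(2)), "not among")
})

test_that("a profile duplicating the signature always co-clusters with it", {
  set.seed(31)
  sig <- runif(30)
  v <- rbind(signature = sig, twin = sig,
             matrix(runif(6 * 30), 6, 30,
                    dimnames = list(paste0("other", 1:6), NULL)))
  m <- as_chemgen(v)
  r <- consensus_rank(m, "signature", enumerate_trials(), min_size(2))
  expect_equal(r$trials_run, 28)
  expect_equal(unname(r$frequency["twin"]), 1)
  expect_equal(unname(r$frequency["signature"]), 1)
  expect_equal(names(r$frequency)[1:2], c("signature", "twin"))
})

test_that("min_size(1) under a single trial gives zero frequency elsewhere", {
  m <- random_chemgen(n = 8, g = 20, missing_rate = 0.05, seed = 14)
  r <- consensus_rank(m, rownames(m$values)[3],
                      enumerate_trials("euclidean", "complete"), min_size(1))
  expect_equal(r$trials_run, 1)
  expect_equal(unname(r$frequency[r$signature_id]), 1)
  expect_true(all(r$frequency[setdiff(names(r$frequency),
                                      r$signature_id)] == 0))
})

test_that("frequencies live in [0,1] and adding a trial moves them <= 1/(t+1)", {
  m <- random_chemgen(n = 10, g = 25, missing_rate = 0.1, seed = 15)
  sig <- rownames(m$values)[1]
  trials <- enumerate_trials(c("centered_corr", "spearman", "euclidean"),
                             c("single", "average"))
  r6 <- consensus_rank(m, sig, trials, min_size(3))
  expect_true(all(r6$frequency >= 0 & r6$frequency <= 1))
  extra <- rbind(trials, data.frame(measure = "cityblock",
                                    linkage = "complete"))
  r7 <- consensus_rank(m, sig, extra, min_size(3))
  ids <- names(r6$frequency)
  shift <- abs(r7$frequency[ids] - r6$frequency[ids])
  expect_true(all(shift <= 1 / (r6$trials_run + 1) + 1e-12))
})

test_that("relabeling compounds permutes the ranking equivariantly", {
  s <- simulate_chemgen(sim_params(n_compounds = 12, n_genes = 60,
                                   module_compounds = 3, module_genes = 15,
                                   effect_alpha = 0.1, missing_rate = 0.05,
                                   seed = 8))
  m <- s$matrix
  trials <- enumerate_trials(c("uncentered_corr", "euclidean"),
                             c("complete", "average"))
  r1 <- consensus_rank(m, s$truth$signature_id, trials, min_size(4))
  # relabel: prefix every id and shuffle row order
  set.seed(1)
  perm <- sample(nrow(m$values))
  v2 <- m$values[perm, ]
  rownames(v2) <- paste0("X_", rownames(v2))
  m2 <- chemgen_matrix(v2, m$transform)
  r2 <- consensus_rank(m2, paste0("X_", s$truth$signature_id), trials,
                       min_size(4))
  expect_equal(unname(r2$frequency[paste0("X_", names(r1$frequency))]),
               unname(r1$frequency))
})

test_that("a strongly planted module dominates the consensus ranking", {
  # half the genes carry near-zero module p-values: the planted compounds are
  # unambiguous nearest neighbours of the signature under every measure
  for (seed in c(2, 6)) {
    s <- simulate_chemgen(sim_params(module_genes = 50, effect_alpha = 0.005,
                                     seed = seed))
    r <- suppressMessages(
      consensus_rank(s$matrix, s$truth$signature_id, enumerate_trials(),
                     min_size(8)))
    top3 <- names(r$frequency)[2:4]  # after the signature itself
    expect_setequal(top3, setdiff(s$truth$module_compound_ids,
                                  s$truth$signature_id))
  }
})

test_that("degenerate trials are skipped and excluded from the denominator", {
  # compounds a and b share no genes: euclidean/cityblock are degenerate,
  # correlation measures fall back to the maximum and still complete
  v <- rbind(a = c(0.2, 0.1, 0.3, NA, NA, NA),
             b = c(NA, NA, NA, 0.5, 0.6, 0.1),
             c = c(0.3, 0.4, 0.5, 0.6, 0.2, 0.8),
             d = c(0.1, 0.9, 0.2, 0.3, 0.7, 0.4))
  m <- as_chemgen(v)
  trials <- enumerate_trials(c("euclidean", "centered_corr"), "single")
  w <- capture_warnings(r <- consensus_rank(m, "a", trials, min_size(2)))
  expect_true(any(grepl("skipped", w)))
  expect_equal(r$trials_run, 1)
  expect_equal(r$skipped, "euclidean:single")
  expect_true(all(r$frequency %in% c(0, 1)))

  # all trials degenerate -> error
  expect_error(
    suppressWarnings(consensus_rank(m, "a",
                                    enumerate_trials("euclidean", "single"),
                                    min_size(2))),
    "all trials")
})
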