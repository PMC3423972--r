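#' Parameters for the synthetic chemogenomic screen generator
#'
#' The generator emulates a compound x gene-deletion fitness-defect p-value
#' matrix: background entries are Uniform(0, 1) (null interactions) and a
#' planted block of "module" compounds sharing significant interactions over a
#' "module" gene set is drawn Beta(`effect_alpha`, 1) — a one-parameter family
#' spanning the null (`effect_alpha = 1` is Uniform) to strong signal
#' (`effect_alpha` near 0 piles mass near p = 0; the planted-block mean is
#' `effect_alpha / (effect_alpha + 1)`). Cells are then masked missing
#' completely at random at `missing_rate`, the simplest model of sporadic
#' assay dropouts. The defaults are the study conditions used throughout the
#' package's validation: a 20 x 100 screen with a 4-compound, 20-gene planted
#' module at `effect_alpha = 0.05`.
#'
#' @param n_compounds,n_genes Matrix dimensions.
#' @param module_compounds Number of planted module compounds (includes the
#'   signature compound); at most `n_compounds`.
#' @param module_genes Number of planted module genes; at most `n_genes`.
#' @param effect_alpha Positive Beta shape for planted p-values.
#' @param missing_rate Fraction in \[0, 1) of cells masked missing.
#' @param seed Integer seed; identical parameters give bit-identical output.
#' @param compound_prefix,gene_prefix Identifier prefixes.
#' @return A `sim_params` object.
#' @export
sim_params <- function(n_compounds = 20, n_genes = 100,
                       module_compounds = 4, module_genes = 20,
                       effect_alpha = 0.05, missing_rate = 0.05,
                       seed = 1L, compound_prefix = "cmpd",
                       gene_prefix = "gene") {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < 1 || x != round(x)) {
      stop("'", nm, "' must be a positive integer", call. = FALSE)
    }
  }
  chk_count(n_compounds, "n_compounds"); chk_count(n_genes, "n_genes")
  chk_count(module_compounds, "module_compounds")
  chk_count(module_genes, "module_genes")
  if (module_compounds > n_compounds) {
    stop("'module_compounds' must not exceed 'n_compounds'", call. = FALSE)
  }
  if (module_genes > n_genes) {
    stop("'module_genes' must not exceed 'n_genes'", call. = FALSE)
  }
  if (!is.numeric(effect_alpha) || length(effect_alpha) != 1 ||
      effect_alpha <= 0) {
    stop("'effect_alpha' must be a positive real", call. = FALSE)
  }
  if (!is.numeric(missing_rate) || length(missing_rate) != 1 ||
      missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    stop("'seed' must be an integer", call. = FALSE)
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_genes = as.integer(n_genes),
                 module_compounds = as.integer(module_compounds),
                 module_genes = as.integer(module_genes),
                 effect_alpha = effect_alpha,
                 missing_rate = missing_rate,
                 seed = as.integer(seed),
                 compound_prefix = compound_prefix,
                 gene_prefix = gene_prefix),
            class = "sim_params")
}

#' Generate a synthetic chemogenomic screen with planted ground truth
#'
#' Draws the matrix described in [sim_params()] and returns it together with
#' the planted truth (module compound and gene identifiers, and the signature
#' compound, which by convention is the first planted compound). The planted
#' module occupies the first `module_compounds` rows and first `module_genes`
#' columns; downstream stages never see row position, and ranking equivariance
#' under relabeling is part of the test suite.
#'
#' The session RNG state is saved and restored, so generation does not perturb
#' ambient randomness.
#'
#' @param params A [sim_params()] object.
#' @return List with elements `matrix` (a [chemgen_matrix()]) and `truth`
#'   (list `module_compound_ids`, `module_gene_ids`, `signature_id`).
#' @export
simulate_chemgen <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(params$seed)
  n <- params$n_compounds
  g <- params$n_genes
  mc <- params$module_compounds
  mg <- params$module_genes
  vals <- matrix(stats::runif(n * g), n, g)
  vals[seq_len(mc), seq_len(mg)] <-
    stats::rbeta(mc * mg, params$effect_alpha, 1)
  if (params$missing_rate > 0) {
    miss <- matrix(stats::runif(n * g) < params$missing_rate, n, g)
    vals[miss] <- NA_real_
  }
  cids <- sprintf("%s_%03d", params$compound_prefix, seq_len(n))
  gids <- sprintf("%s_%04d", params$gene_prefix, seq_len(g))
  dimnames(vals) <- list(cids, gids)
  list(matrix = chemgen_matrix(vals, "raw_p"),
       truth = list(module_compound_ids = cids[seq_len(mc)],
                    module_gene_ids = gids[seq_len(mg)],
                    signature_id = cids[1]))
}
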