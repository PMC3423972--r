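#' Compound-by-gene chemogenomic profile matrix
#'
#' Container for a compound x gene matrix of chemogenomic interaction scores.
#' In the paper-faithful mode (`transform = "raw_p"`) entries are fitness-defect
#' p-values in \[0, 1\], one row per compound treatment and one column per gene
#' deletion strain; similar rows suggest a shared mechanism of action. Missing
#' measurements are encoded as `NA` and carried through every downstream stage
#' by pairwise-complete deletion.
#'
#' @param values Numeric matrix with unique row names (compound identifiers)
#'   and unique column names (gene identifiers). `NA` marks a missing cell.
#' @param transform Either `"raw_p"` (entries are p-values, checked to lie in
#'   \[0, 1\]) or `"neglog10"` (entries are capped -log10 p scores).
#'
#' @return An object of class `chemgen_matrix`: a list with elements `values`
#'   (the numeric matrix) and `transform`.
#' @seealso [read_chemgen_tsv()], [transform_profiles()], [pairwise_distance()]
#' @export
chemgen_matrix <- function(values, transform = c("raw_p", "neglog10")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  compound_ids <- rownames(values)
  gene_ids <- colnames(values)
  if (is.null(compound_ids) || is.null(gene_ids)) {
    stop("'values' must carry row names (compounds) and column names (genes)",
         call. = FALSE)
  }
  if (anyDuplicated(compound_ids)) {
    stop("duplicate compound identifiers: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  present <- !is.na(values)
  if (any(!is.finite(values[present]))) {
    stop("non-finite values present in matrix", call. = FALSE)
  }
  if (transform == "raw_p" &&
      any(values[present] < 0 | values[present] > 1)) {
    stop("raw p-values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(values = values, transform = transform),
            class = "chemgen_matrix")
}

#' @export
print.chemgen_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("chemgen_matrix: %d compounds x %d genes (%s), %.1f%% missing\n",
              nrow(v), ncol(v), x$transform, 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.chemgen_matrix <- function(x) dim(x$values)

# number of fields a tab-separated line carries (strsplit drops a trailing
# empty field, so count tabs instead)
.tsv_nfields <- function(line) {
  nchar(line) - nchar(gsub("\t", "", line, fixed = TRUE)) + 1L
}

#' Read a chemogenomic profile matrix from tab-separated text
#'
#' Expects a header row whose first cell is an arbitrary corner label followed
#' by gene identifiers, then one row per compound with the compound identifier
#' in the first column. Empty cells and the token `NA` are read as missing.
#' Malformed input (ragged rows, duplicated identifiers, non-numeric cells)
#' raises an error naming the offending line.
#'
#' @param path Path to a TSV file.
#' @param transform Transform tag to attach; `"raw_p"` (default) validates the
#'   \[0, 1\] range.
#' @return A [chemgen_matrix()].
#' @export
read_chemgen_tsv <- function(path, transform = "raw_p") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) {
    stop("file must contain a header and at least one data row", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2) {
    stop("line 1: header must contain at least one gene column", call. = FALSE)
  }
  gene_ids <- header[-1]
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("line 1: duplicate gene identifier '%s'",
                 gene_ids[duplicated(gene_ids)][1]), call. = FALSE)
  }
  nfld <- length(header)
  n <- length(lines) - 1L
  vals <- matrix(NA_real_, n, nfld - 1L)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    nf <- .tsv_nfields(lines[i + 1L])
    if (nf > length(f)) f <- c(f, rep("", nf - length(f)))
    if (length(f) != nfld) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, nfld, length(f)), call. = FALSE)
    }
    ids[i] <- f[1]
    cells <- f[-1]
    miss <- cells == "" | cells == "NA"
    x <- suppressWarnings(as.numeric(cells))
    bad <- which(!miss & is.na(x))
    if (length(bad)) {
      stop(sprintf("line %d: non-numeric value '%s' in column %d",
                   i + 1L, cells[bad[1]], bad[1] + 1L), call. = FALSE)
    }
    x[miss] <- NA_real_
    vals[i, ] <- x
  }
  if (anyDuplicated(ids)) {
    first_dup <- which(duplicated(ids))[1]
    stop(sprintf("line %d: duplicate compound identifier '%s'",
                 first_dup + 1L, ids[first_dup]), call. = FALSE)
  }
  dimnames(vals) <- list(ids, gene_ids)
  chemgen_matrix(vals, transform)
}

#' Write a chemogenomic profile matrix as tab-separated text
#'
#' Inverse of [read_chemgen_tsv()]: values are printed with 12 significant
#' digits (the round-trip resolution), missing cells as `NA`, LF line endings.
#'
#' @param m A [chemgen_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chemgen_tsv <- function(m, path) {
  stopifnot(inherits(m, "chemgen_matrix"))
  v <- m$values
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))
  lines <- c(
    paste(c("compound", colnames(v)), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t")
    }, character(1))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Transform profile values
#'
#' `raw_p` returns the input unchanged. `neglog10` maps each present p-value to
#' `min(-log10(max(p, 10^-cap)), cap)`, so p = 0 maps to `cap`. Clustering raw
#' p-values weights non-significant noise heavily; the transform is offered as
#' an explicit alternative, never applied silently, and refuses to run twice.
#'
#' @param m A [chemgen_matrix()].
#' @param mode `"raw_p"` or `"neglog10"`.
#' @param cap Positive cap (default 10) on the -log10 scale.
#' @return A [chemgen_matrix()] with updated values and transform tag.
#' @export
transform_profiles <- function(m, mode = c("raw_p", "neglog10"), cap = 10) {
  stopifnot(inherits(m, "chemgen_matrix"))
  mode <- match.arg(mode)
  if (mode == "raw_p") return(m)
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0) {
    stop("'cap' must be a positive number", call. = FALSE)
  }
  if (m$transform != "raw_p") {
    stop("profiles are already transformed ('", m$transform,
         "'); refusing to apply neglog10 twice", call. = FALSE)
  }
  v <- m$values
  present <- !is.na(v)
  v[present] <- pmin(-log10(pmax(v[present], 10^(-cap))), cap)
  out <- m
  out$values <- v
  out$transform <- "neglog10"
  out
}

# leaf order of a dendrogram: left-to-right recursion over the merge records
.dend_leaf_order <- function(dend) {
  n <- length(dend$leaf_ids)
  orders <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    kids <- dend$merge[k, ]
    part <- function(x) if (x < 0) -x else orders[[x]]
    orders[[k]] <- c(part(kids[1]), part(kids[2]))
  }
  orders[[n - 1L]]
}

#' Write Cluster 3.0 compatible .cdt and .gtr files
#'
#' Emits the tree and data files read by Java TreeView: `<basename>.cdt` holds
#' the matrix with rows in dendrogram leaf order and a `GID` column keyed
#' `GENE{i}X` by original row index (0-based, Cluster 3.0 convention);
#' `<basename>.gtr` holds one line per merge (`NODE{k}X`, child, child, score)
#' where the score is the similarity `1 - height / max(height)`, so it is
#' non-increasing down the file whenever merge heights are monotone. Children
#' reference leaves as `GENE{i}X` and earlier merges as `NODE{j}X`. Only the
#' compound (row) tree is written; no column tree is emitted.
#'
#' @param m A [chemgen_matrix()] whose rows are the tree leaves.
#' @param dend A dendrogram from [cluster_profiles()] over the same compounds.
#' @param basename Output path prefix (`.cdt`/`.gtr` appended).
#' @return Invisibly, a named character vector with the two paths.
#' @export
write_cdt_gtr <- function(m, dend, basename) {
  stopifnot(inherits(m, "chemgen_matrix"), inherits(dend, "chemo_dendrogram"))
  ids <- rownames(m$values)
  if (!setequal(ids, dend$leaf_ids) || length(ids) != length(dend$leaf_ids)) {
    stop("dendrogram leaves do not match matrix rows", call. = FALSE)
  }
  gid <- stats::setNames(paste0("GENE", seq_along(ids) - 1L, "X"), ids)
  ord_ids <- dend$leaf_ids[.dend_leaf_order(dend)]
  v <- m$values
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.12g", x))
  cdt <- c(
    paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(v)), collapse = "\t"),
    vapply(ord_ids, function(id) {
      paste(c(gid[[id]], id, id, "1", fmt(v[id, ])), collapse = "\t")
    }, character(1))
  )
  hmax <- max(dend$height)
  score <- if (hmax > 0) 1 - dend$height / hmax else rep(1, length(dend$height))
  ref <- function(x) if (x < 0) gid[[dend$leaf_ids[-x]]] else paste0("NODE", x, "X")
  gtr <- vapply(seq_along(dend$height), function(k) {
    paste(c(paste0("NODE", k, "X"),
            ref(dend$merge[k, 1]), ref(dend$merge[k, 2]),
            sprintf("%.6f", score[k])), collapse = "\t")
  }, character(1))
  paths <- c(cdt = paste0(basename, ".cdt"), gtr = paste0(basename, ".gtr"))
  for (nm in names(paths)) {
    con <- file(paths[[nm]], open = "wb")
    writeLines(if (nm == "cdt") cdt else gtr, con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  invisible(paths)
}
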