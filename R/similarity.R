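#' Labeled symmetric similarity matrix
#'
#' A square similarity matrix over a set of entities (miRNAs or diseases)
#' with entries in `[0, 1]`, a unit diagonal, and a per-entry provenance
#' flag recording whether the value came from a curated/semantic source or
#' from the Gaussian interaction-profile kernel fallback.
#'
#' Symmetry is enforced by averaging `(S + t(S)) / 2`, entries are clamped to
#' `[0, 1]`, and the diagonal is set to exactly 1; curated tables are often
#' asymmetric at the last printed digit, which this normalisation absorbs.
#'
#' @param values square numeric matrix.
#' @param ids character ids (defaults to rownames).
#' @param source either a single string (`"curated"` or `"gaussian"`) applied
#'   to every entry, or a character matrix of per-entry flags.
#' @return object of class `similarity_matrix` with attribute `source_mask`.
#' @export
similarity_matrix <- function(values, ids = rownames(values),
                              source = "gaussian") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_data("similarity matrix must be square")
  if (is.null(ids)) ids <- paste0("id-", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_data("duplicate ids in similarity matrix")
  if (length(ids) != nrow(values)) stop_data("id length mismatch")
  if (max(abs(values - t(values))) > 1e-6)
    stop_data("similarity matrix is not symmetric")
  values <- (values + t(values)) / 2
  values <- pmin(pmax(values, 0), 1)
  diag(values) <- 1
  dimnames(values) <- list(ids, ids)
  if (is.character(source) && length(source) == 1L) {
    source <- matrix(source, nrow(values), ncol(values))
  }
  if (!all(source %in% c("curated", "gaussian")))
    stop_data("source flags must be 'curated' or 'gaussian'")
  dimnames(source) <- dimnames(values)
  structure(values, source_mask = source,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  src <- attr(x, "source_mask")
  cat(sprintf("similarity_matrix: %d x %d (%.1f%% curated entries)\n",
              nrow(x), ncol(x), 100 * mean(src == "curated")))
  invisible(x)
}

#' Gaussian interaction-profile kernel bandwidth
#'
#' The bandwidth is the mean squared norm of the association profiles along
#' the chosen axis: `theta = (1/m) * sum_i ||Y[i, ]||^2` for miRNAs, and the
#' column analogue for diseases.  An all-zero matrix has bandwidth 0, which
#' leaves the kernel undefined, and is rejected.
#'
#' @param Y an [association_matrix()] (any binary matrix works).
#' @param axis `"mirna"` (rows) or `"disease"` (columns).
#' @return positive scalar bandwidth.
#' @export
gaussian_bandwidth <- function(Y, axis = c("mirna", "disease")) {
  axis <- match.arg(axis)
  sq <- if (axis == "mirna") rowSums(Y^2) else colSums(Y^2)
  theta <- mean(sq)
  if (theta <= 0)
    stop_data("degenerate-profile: association matrix has no nonzero entries along axis '%s'", axis)
  theta
}

#' Gaussian interaction-profile kernel similarity
#'
#' `S[i, j] = exp(-||profile_i - profile_j||^2 / theta)` where profiles are
#' rows (miRNA axis) or columns (disease axis) of the association matrix and
#' `theta` is [gaussian_bandwidth()].  Entities with all-zero profiles are
#' allowed (their pairwise distances are still defined) as long as the global
#' bandwidth is positive.
#'
#' @inheritParams gaussian_bandwidth
#' @return a [similarity_matrix()] flagged `"gaussian"` throughout.
#' @export
gaussian_profile_similarity <- function(Y, axis = c("mirna", "disease")) {
  axis <- match.arg(axis)
  theta <- gaussian_bandwidth(Y, axis)
  P <- if (axis == "mirna") unclass(Y) else t(unclass(Y))
  sq <- rowSums(P^2)
  # ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b, floored at 0 against rounding
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0
  S <- exp(-d2 / theta)
  similarity_matrix(S, ids = rownames(P), source = "gaussian")
}

#' Fuse curated and Gaussian miRNA similarities
#'
#' A pair `(i, j)` "has functional similarity" when both members appear in
#' the curated table; those entries come from `MS`, all others from the
#' Gaussian kernel matrix `GMS`.  Coverage is per-miRNA, matching how
#' curated functional-similarity resources ship data.
#'
#' @param MS curated similarity: square labeled matrix over a subset of the
#'   miRNAs, or `NULL` for no curated data.
#' @param GMS Gaussian kernel [similarity_matrix()] over all miRNAs.
#' @return fused [similarity_matrix()]; `source_mask` records the branch.
#' @export
fuse_mirna_similarity <- function(MS, GMS) {
  fuse_with_fallback(MS, GMS, label = "miRNA")
}

fuse_with_fallback <- function(curated, fallback, label) {
  ids <- rownames(fallback)
  S <- unclass(fallback)
  src <- matrix("gaussian", length(ids), length(ids))
  if (!is.null(curated) && nrow(curated) > 0L) {
    cov_ids <- rownames(curated)
    unknown <- setdiff(cov_ids, ids)
    if (length(unknown))
      stop_data("curated %s similarity has unknown ids: %s", label,
                paste(unknown, collapse = ","))
    idx <- match(cov_ids, ids)
    S[idx, idx] <- as.matrix(curated)
    src[idx, idx] <- "curated"
  }
  similarity_matrix(S, ids = ids, source = src)
}

#' Fuse disease semantic and Gaussian similarities
#'
#' For pairs whose two members both have a hierarchy position (`covered`),
#' the similarity is the average of the two semantic models,
#' `(DS1 + DS2) / 2`; all other pairs fall back to the Gaussian kernel.
#'
#' @param DS1,DS2 semantic similarity matrices (hierarchy-decay and
#'   information-content models), labeled over the covered diseases.
#' @param GDS Gaussian kernel [similarity_matrix()] over all diseases.
#' @param covered character vector of covered disease ids; defaults to the
#'   ids of `DS1`.
#' @return fused [similarity_matrix()].
#' @export
fuse_disease_similarity <- function(DS1, DS2, GDS, covered = rownames(DS1)) {
  if (is.null(DS1) || is.null(DS2) || length(covered) == 0L)
    return(fuse_with_fallback(NULL, GDS, "disease"))
  if (!identical(dim(DS1), dim(DS2)) ||
      !identical(rownames(DS1), rownames(DS2)))
    stop_data("DS1 and DS2 must be labeled identically")
  keep <- match(covered, rownames(DS1))
  if (anyNA(keep)) stop_data("'covered' ids missing from semantic matrices")
  DS <- (as.matrix(DS1)[keep, keep, drop = FALSE] +
         as.matrix(DS2)[keep, keep, drop = FALSE]) / 2
  rownames(DS) <- colnames(DS) <- covered
  fuse_with_fallback(DS, GDS, "disease")
}

#' Read a labeled square similarity TSV
#'
#' First column holds row labels; header holds column labels.
#'
#' @param path TSV path.
#' @param source provenance flag for the whole table.
#' @return a [similarity_matrix()].
#' @export
read_similarity_tsv <- function(path, source = "curated") {
  if (!file.exists(path)) stop_data("input file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!identical(rownames(m), colnames(m)))
    stop_data("%s: row and column labels differ", path)
  similarity_matrix(m, source = source)
}

#' Write a labeled square similarity TSV
#'
#' @param S matrix with dimnames.
#' @param path output path.
#' @export
write_similarity_tsv <- function(S, path) {
  df <- data.frame(id = rownames(S), as.data.frame(unclass(S)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
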