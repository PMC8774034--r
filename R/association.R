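#' Binary miRNA-disease association matrix
#'
#' Wraps a binary `m x n` matrix `Y` whose rows are miRNAs and whose columns
#' are diseases; `Y[i, j] = 1` records a curated association.  Row and column
#' names carry the identifiers; prediction targets are the zero entries.
#'
#' @param values numeric matrix of 0/1 entries.
#' @param mirna_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param disease_ids character vector of unique column identifiers; defaults
#'   to `colnames(values)`.
#' @return an object of class `association_matrix`: the matrix with id
#'   dimnames.
#' @export
association_matrix <- function(values, mirna_ids = rownames(values),
                               disease_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop_data("association matrix must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_data("association matrix needs at least one row and one column")
  if (!all(values %in% c(0, 1)))
    stop_data("association matrix entries must be exactly 0 or 1")
  if (is.null(mirna_ids)) mirna_ids <- paste0("miRNA-", seq_len(nrow(values)))
  if (is.null(disease_ids)) disease_ids <- paste0("disease-", seq_len(ncol(values)))
  mirna_ids <- as.character(mirna_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(mirna_ids)) stop_data("duplicate miRNA ids")
  if (anyDuplicated(disease_ids)) stop_data("duplicate disease ids")
  if (length(mirna_ids) != nrow(values) || length(disease_ids) != ncol(values))
    stop_data("id lengths do not match matrix dimensions")
  dimnames(values) <- list(mirna_ids, disease_ids)
  structure(values, class = c("association_matrix", "matrix", "array"))
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d miRNAs x %d diseases, %d known associations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

mirna_ids <- function(Y) rownames(Y)
disease_ids <- function(Y) colnames(Y)

#' Read an association edge list
#'
#' Reads a two-column TSV (header `mirna_id`, `disease_id`) of known
#' associations and builds the binary matrix.  Duplicate edges collapse to a
#' single 1.  Row/column order follows first appearance unless explicit id
#' vectors are supplied (useful to retain entities with no associations).
#'
#' @param path TSV file path.
#' @param mirna_ids,disease_ids optional full id universes.
#' @return an [association_matrix()].
#' @export
read_association_tsv <- function(path, mirna_ids = NULL, disease_ids = NULL) {
  df <- read_tsv_checked(path, c("mirna_id", "disease_id"))
  if (is.null(mirna_ids)) mirna_ids <- unique(df$mirna_id)
  if (is.null(disease_ids)) disease_ids <- unique(df$disease_id)
  unknown_m <- setdiff(df$mirna_id, mirna_ids)
  unknown_d <- setdiff(df$disease_id, disease_ids)
  if (length(unknown_m) || length(unknown_d))
    stop_data(sprintf("edge list contains ids outside the supplied universe: %s",
                      paste(c(unknown_m, unknown_d), collapse = ",")))
  Y <- matrix(0, length(mirna_ids), length(disease_ids),
              dimnames = list(mirna_ids, disease_ids))
  Y[cbind(match(df$mirna_id, mirna_ids), match(df$disease_id, disease_ids))] <- 1
  association_matrix(Y)
}

#' Write an association edge list
#'
#' @param Y an [association_matrix()].
#' @param path output TSV path.
#' @export
write_association_tsv <- function(Y, path) {
  idx <- which(Y == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(mirna_id = rownames(Y)[idx[, 1]],
                   disease_id = colnames(Y)[idx[, 2]],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- shared error helpers ------------------------------------------------
# Errors carry condition classes so the CLI can map them to exit codes:
# mdgae_data_error -> 3, mdgae_divergence -> 4, mdgae_usage_error -> 2.

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("mdgae_data_error", "error")))
}

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("mdgae_usage_error", "error")))
}

stop_divergence <- function(msg, epoch, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      epoch = epoch,
                      class = c("mdgae_divergence", "error")))
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_data("input file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop_data("%s: missing required column(s): %s", path,
              paste(missing, collapse = ","))
  df
}
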