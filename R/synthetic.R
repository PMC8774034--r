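#' Specification for a planted synthetic dataset
#'
#' Describes a world the generator samples: a rank-`latent_rank` ground
#' truth over `m` miRNAs and `n` diseases, binarized to a target positive
#' density, with a fraction of symmetric label flips as curation noise, and
#' a curated-similarity table covering part of the miRNAs.  Defaults mirror
#' the scale and sparsity of curated human benchmarks (about 2.7% known
#' associations) at a desk-testable size.
#'
#' @param m,n numbers of miRNAs and diseases (defaults 200, 150).
#' @param latent_rank rank of the planted factor model, default 3.
#' @param density target positive density in (0, 1), default 0.027.
#' @param noise fraction of label flips in `[0, 1)`, applied symmetrically
#'   (equal expected counts 1->0 and 0->1); default 0.05.
#' @param curated_coverage fraction of miRNAs with curated similarity,
#'   default 0.9.
#' @param dag_coverage fraction of diseases mapped into the generated
#'   hierarchy, default 0 (no DAG emitted).
#' @param seed integer seed.
#' @return validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 200L, n = 150L, latent_rank = 3L,
                           density = 0.027, noise = 0.05,
                           curated_coverage = 0.9, dag_coverage = 0,
                           seed = 1L) {
  stopifnot(m >= 2, n >= 2, latent_rank >= 1,
            latent_rank <= min(m, n),
            density > 0, density < 1,
            noise >= 0, noise < 1,
            curated_coverage >= 0, curated_coverage <= 1,
            dag_coverage >= 0, dag_coverage <= 1)
  if (density * m * n < 5)
    stop_data("infeasible density: fewer than 5 expected positives")
  structure(list(m = as.integer(m), n = as.integer(n),
                 latent_rank = as.integer(latent_rank),
                 density = density, noise = noise,
                 curated_coverage = curated_coverage,
                 dag_coverage = dag_coverage, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample a planted synthetic dataset
#'
#' Draws latent factors `U` (`m x r`) and `V` (`n x r`) from a standard
#' normal, standardizes `U %*% t(V)` and squashes it through a logistic to
#' ground-truth probabilities, thresholds the probabilities so that exactly
#' `round(density * m * n)` entries are positive, then flips
#' `round(noise * n_pos)` positives and equally many zeros.  The curated
#' miRNA similarity is the cosine similarity of `U` rows mapped to `[0, 1]`
#' via `(x + 1) / 2`, restricted to a random covered subset.  Optionally a
#' random acyclic hierarchy (a random forest plus extra child->ancestor
#' edges) is emitted over a subset of diseases.  Fully reproducible from
#' the seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_dataset`: `Y`
#'   ([association_matrix()]), `truth` (ground-truth probability matrix),
#'   `mirna_sim` (curated block or `NULL`), `dag` ([disease_dag()] or
#'   `NULL`), `spec`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  m <- spec$m; n <- spec$n; r <- spec$latent_rank
  mir_ids <- sprintf("miR-%03d", seq_len(m))
  dis_ids <- sprintf("disease-%03d", seq_len(n))

  U <- matrix(stats::rnorm(m * r), m, r)
  V <- matrix(stats::rnorm(n * r), n, r)
  raw <- tcrossprod(U, V)
  z <- (raw - mean(raw)) / stats::sd(raw)
  truth <- stats::plogis(2 * z)   # slope 2: clear but not degenerate signal
  dimnames(truth) <- list(mir_ids, dis_ids)

  n_pos <- max(5L, round(spec$density * m * n))
  cutoff <- sort(truth, decreasing = TRUE)[n_pos]
  Y <- matrix(0, m, n, dimnames = dimnames(truth))
  Y[truth >= cutoff] <- 1           # continuous draws: ties have measure 0

  n_flip <- round(spec$noise * sum(Y))
  if (n_flip > 0) {
    ones <- which(Y == 1)
    zeros <- which(Y == 0)
    Y[sample(ones, n_flip)] <- 0
    Y[sample(zeros, n_flip)] <- 1
  }

  mirna_sim <- NULL
  n_cov <- round(spec$curated_coverage * m)
  if (n_cov >= 2) {
    covered <- sort(sample.int(m, n_cov))
    Uc <- U[covered, , drop = FALSE]
    norms <- sqrt(rowSums(Uc^2))
    cosi <- tcrossprod(Uc / norms)
    cosi[cosi > 1] <- 1; cosi[cosi < -1] <- -1
    MS <- (cosi + 1) / 2
    diag(MS) <- 1
    dimnames(MS) <- list(mir_ids[covered], mir_ids[covered])
    mirna_sim <- MS
  }

  dag <- NULL
  n_dag <- round(spec$dag_coverage * n)
  if (n_dag >= 2) {
    dag <- random_disease_dag(dis_ids[sort(sample.int(n, n_dag))])
  }

  structure(list(Y = association_matrix(Y), truth = truth,
                 mirna_sim = mirna_sim, dag = dag, spec = spec),
            class = "synthetic_dataset")
}

# Random acyclic hierarchy over the given diseases: nodes are ordered;
# each non-root attaches to one random earlier node (forest) and with
# probability 0.3 gains one extra edge to another earlier node, so all
# edges point child -> earlier node and the graph stays acyclic.
random_disease_dag <- function(dis_ids) {
  k <- length(dis_ids)
  nodes <- paste0("term-", seq_len(k))
  edges <- list()
  for (i in 2:k) {
    p <- sample.int(i - 1L, 1L)
    edges[[length(edges) + 1L]] <- c(nodes[i], nodes[p])
    if (i > 2 && stats::runif(1) < 0.3) {
      q <- sample(setdiff(seq_len(i - 1L), p), 1L)
      edges[[length(edges) + 1L]] <- c(nodes[i], nodes[q])
    }
  }
  edge_df <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  names(edge_df) <- c("child", "parent")
  disease_dag(edge_df, stats::setNames(sample(nodes), dis_ids))
}

#' Write a synthetic dataset to disk
#'
#' Emits the association edge list, the curated miRNA-similarity TSV (when
#' present), and the hierarchy TSV pair (when present), in the same
#' dialects the readers and the CLI consume.
#'
#' @param spec a [synthetic_spec()] (or an already sampled
#'   `synthetic_dataset`).
#' @param dir output directory, created if needed.
#' @return named character vector of the paths written.
#' @export
planted_benchmark <- function(spec, dir) {
  ds <- if (inherits(spec, "synthetic_dataset")) spec else simulate_dataset(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(associations = file.path(dir, "associations.tsv"))
  write_association_tsv(ds$Y, paths[["associations"]])
  if (!is.null(ds$mirna_sim)) {
    paths[["mirna_sim"]] <- file.path(dir, "mirna_similarity.tsv")
    write_similarity_tsv(ds$mirna_sim, paths[["mirna_sim"]])
  }
  if (!is.null(ds$dag)) {
    paths[["dag_edges"]] <- file.path(dir, "dag_edges.tsv")
    paths[["dag_roots"]] <- file.path(dir, "dag_roots.tsv")
    write_dag_tsv(ds$dag, paths[["dag_edges"]], paths[["dag_roots"]])
  }
  paths
}
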