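#' MeSH-style disease hierarchy
#'
#' A directed acyclic graph over disease terms, edges pointing child ->
#' parent.  Each disease id maps to its node via `disease_roots`; the
#' ancestor closure `N(i)` of that node (the node itself plus all ancestors)
#' drives both semantic-similarity models.  `membership_counts[t]` is the
#' number of diseases whose closure contains term `t` (a disease's own
#' closure contains its root, so every reachable term has count >= 1).
#'
#' @param parent_edges data.frame with columns `child`, `parent` (one row per
#'   edge), or `NULL`/empty for a forest of isolated roots.
#' @param disease_roots named character vector: names are disease ids,
#'   values the corresponding DAG node.
#' @param nodes optional extra node universe; defaults to everything seen in
#'   edges and roots.
#' @return object of class `disease_dag` with precomputed ancestor closures
#'   and membership counts.
#' @export
disease_dag <- function(parent_edges, disease_roots, nodes = NULL) {
  if (is.null(parent_edges) || nrow(as.data.frame(parent_edges)) == 0L) {
    parent_edges <- data.frame(child = character(), parent = character(),
                               stringsAsFactors = FALSE)
  } else {
    parent_edges <- data.frame(child = as.character(parent_edges[[1]]),
                               parent = as.character(parent_edges[[2]]),
                               stringsAsFactors = FALSE)
    parent_edges <- unique(parent_edges)
  }
  disease_roots <- vapply(disease_roots, as.character, character(1))
  if (is.null(names(disease_roots)) || anyDuplicated(names(disease_roots)))
    stop_data("disease_roots must be uniquely named by disease id")
  nodes <- unique(c(nodes, parent_edges$child, parent_edges$parent,
                    unname(disease_roots)))
  missing_roots <- setdiff(unname(disease_roots), nodes)
  if (length(missing_roots))
    stop_data("disease roots missing from DAG nodes: %s",
              paste(missing_roots, collapse = ","))

  parents_of <- split(parent_edges$parent, factor(parent_edges$child, levels = nodes))
  children_of <- split(parent_edges$child, factor(parent_edges$parent, levels = nodes))

  closures <- dag_ancestor_closures(nodes, parents_of)

  counts <- integer(length(nodes))
  names(counts) <- nodes
  for (d in names(disease_roots)) {
    nc <- closures[[disease_roots[[d]]]]
    counts[nc] <- counts[nc] + 1L
  }

  structure(list(nodes = nodes,
                 parent_edges = parent_edges,
                 parents_of = parents_of,
                 children_of = children_of,
                 closures = closures,
                 disease_roots = disease_roots,
                 membership_counts = counts,
                 total_diseases = length(disease_roots)),
            class = "disease_dag")
}

# Ancestor closure of every node by memoised DFS; detects cycles.
dag_ancestor_closures <- function(nodes, parents_of) {
  closures <- vector("list", length(nodes))
  names(closures) <- nodes
  state <- integer(length(nodes))   # 0 unseen, 1 in progress, 2 done
  names(state) <- nodes
  visit <- function(v) {
    if (state[[v]] == 2L) return(closures[[v]])
    if (state[[v]] == 1L) stop_data("cycle detected in disease hierarchy at node '%s'", v)
    state[[v]] <<- 1L
    anc <- v
    for (p in parents_of[[v]]) anc <- union(anc, visit(p))
    closures[[v]] <<- anc
    state[[v]] <<- 2L
    anc
  }
  for (v in nodes) visit(v)
  closures
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag: %d nodes, %d edges, %d diseases mapped\n",
              length(x$nodes), nrow(x$parent_edges), x$total_diseases))
  invisible(x)
}

dag_node_of <- function(dag, disease) {
  if (!disease %in% names(dag$disease_roots))
    stop_data("disease '%s' is not mapped into the hierarchy", disease)
  dag$disease_roots[[disease]]
}

#' Hierarchy-decay semantic contribution
#'
#' For a query disease `i`, each term `t` in the ancestor closure `N(i)`
#' contributes `SC1(i, i) = 1` at the disease itself and, one level up,
#' `SC1(i, j) = max { delta * SC1(i, t) : t child of j, t in N(i) }`:
#' contributions decay by `delta` per hierarchy level along the best
#' descending path.
#'
#' @param dag a [disease_dag()].
#' @param disease disease id (must be mapped via `disease_roots`).
#' @param delta per-level decay in (0, 1); default 0.5.
#' @return named numeric vector over `N(i)`.
#' @export
semantic_contribution_wang <- function(dag, disease, delta = 0.5) {
  if (delta <= 0 || delta >= 1) stop_data("delta must lie in (0, 1)")
  root <- dag_node_of(dag, disease)
  closure <- dag$closures[[root]]
  sc <- numeric(length(closure))
  names(sc) <- closure
  # topological order within the closure: a node is ready once all its
  # in-closure children are done (children feed parents)
  done <- setNames(rep(FALSE, length(closure)), closure)
  sc[root] <- 1
  done[root] <- TRUE
  pending <- setdiff(closure, root)
  while (length(pending)) {
    progressed <- FALSE
    for (j in pending) {
      kids <- intersect(dag$children_of[[j]], closure)
      if (all(done[kids])) {
        sc[j] <- max(delta * sc[kids])
        done[j] <- TRUE
        pending <- setdiff(pending, j)
        progressed <- TRUE
      }
    }
    if (!progressed) stop_data("hierarchy closure is not acyclic")
  }
  sc
}

#' Information-content semantic contribution
#'
#' A term's contribution is `-log(n_t / N)` where `n_t` is the number of
#' disease hierarchies containing the term and `N` the total number of
#' diseases (natural log).  Rare terms contribute more; a term present in
#' every hierarchy contributes 0.
#'
#' @param dag a [disease_dag()].
#' @param node DAG node (term) id.
#' @return nonnegative scalar.
#' @export
semantic_contribution_xuan <- function(dag, node) {
  if (!node %in% dag$nodes)
    stop_data("node '%s' is not in the hierarchy", node)
  count <- dag$membership_counts[[node]]
  if (count < 1L)
    stop_data("node '%s' appears in no disease hierarchy", node)
  -log(count / dag$total_diseases)
}

#' Pairwise disease semantic similarity
#'
#' `sim(i, j) = sum_{t in N(i) ∩ N(j)} (SC(i,t) + SC(j,t)) /
#' (sum_{t in N(i)} SC(i,t) + sum_{t in N(j)} SC(j,t))` under either
#' contribution model.  Lies in `[0, 1]`, is symmetric, and equals 1 at
#' `i = j`.
#'
#' @param dag a [disease_dag()].
#' @param i,j disease ids.
#' @param model `"wang"` (hierarchy decay) or `"xuan"` (information content).
#' @param delta decay for the wang model.
#' @return scalar similarity.
#' @export
semantic_similarity <- function(dag, i, j, model = c("wang", "xuan"),
                                delta = 0.5) {
  model <- match.arg(model)
  # identical hierarchy positions are maximally similar even when every
  # shared term has zero information content (degenerate denominators)
  if (identical(dag_node_of(dag, i), dag_node_of(dag, j))) return(1)
  sc_i <- disease_contributions(dag, i, model, delta)
  sc_j <- disease_contributions(dag, j, model, delta)
  shared <- intersect(names(sc_i), names(sc_j))
  denom <- sum(sc_i) + sum(sc_j)
  if (denom <= 0) return(0)
  sum(sc_i[shared] + sc_j[shared]) / denom
}

disease_contributions <- function(dag, disease, model, delta) {
  if (model == "wang") {
    semantic_contribution_wang(dag, disease, delta)
  } else {
    closure <- dag$closures[[dag_node_of(dag, disease)]]
    vapply(closure, function(t) semantic_contribution_xuan(dag, t), numeric(1))
  }
}

#' Semantic similarity matrix over the mapped diseases
#'
#' @param dag a [disease_dag()].
#' @param model contribution model.
#' @param delta decay for the wang model.
#' @param diseases subset of mapped disease ids (default all).
#' @return labeled symmetric matrix (plain matrix; feed to
#'   [fuse_disease_similarity()]).
#' @export
semantic_similarity_matrix <- function(dag, model = c("wang", "xuan"),
                                       delta = 0.5,
                                       diseases = names(dag$disease_roots)) {
  model <- match.arg(model)
  contribs <- lapply(diseases, function(d) disease_contributions(dag, d, model, delta))
  names(contribs) <- diseases
  totals <- vapply(contribs, sum, numeric(1))
  k <- length(diseases)
  S <- diag(1, k)
  if (k > 1) {
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        shared <- intersect(names(contribs[[a]]), names(contribs[[b]]))
        denom <- totals[[a]] + totals[[b]]
        val <- if (identical(dag$disease_roots[[diseases[a]]],
                             dag$disease_roots[[diseases[b]]])) 1
        else if (denom <= 0) 0
        else sum(contribs[[a]][shared] + contribs[[b]][shared]) / denom
        S[a, b] <- S[b, a] <- val
      }
    }
  }
  dimnames(S) <- list(diseases, diseases)
  S
}

#' Read hierarchy TSVs
#'
#' `edges_path`: two-column TSV (`child`, `parent`).  `roots_path`:
#' two-column TSV (`disease_id`, `dag_node`).  Membership counts are
#' computed internally.
#'
#' @param edges_path,roots_path file paths.
#' @return a [disease_dag()].
#' @export
read_dag_tsv <- function(edges_path, roots_path) {
  edges <- read_tsv_checked(edges_path, c("child", "parent"))
  roots <- read_tsv_checked(roots_path, c("disease_id", "dag_node"))
  disease_dag(edges, stats::setNames(roots$dag_node, roots$disease_id))
}

#' Write hierarchy TSVs
#'
#' @param dag a [disease_dag()].
#' @param edges_path,roots_path output paths.
#' @export
write_dag_tsv <- function(dag, edges_path, roots_path) {
  utils::write.table(dag$parent_edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  roots <- data.frame(disease_id = names(dag$disease_roots),
                      dag_node = unname(dag$disease_roots),
                      stringsAsFactors = FALSE)
  utils::write.table(roots, roots_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges_path, roots_path))
}
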