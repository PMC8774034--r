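# Shared fixtures and independent oracles.  Oracles are deliberately written
# as naive loops / enumerations so they share no code path with the package.

toy_Y <- function() association_matrix(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                                       c("m1", "m2"), c("d1", "d2"))

random_Y <- function(m, n, p = 0.3) {
  repeat {
    Y <- matrix(rbinom(m * n, 1, p), m, n)
    # need a nonzero matrix and both classes for most uses
    if (sum(Y) >= 1 && sum(Y) < m * n) break
  }
  association_matrix(Y)
}

random_similarity <- function(k) {
  B <- matrix(runif(k * k), k, k)
  S <- (B + t(B)) / 2
  diag(S) <- 1
  similarity_matrix(S, ids = paste0("e", seq_len(k)))
}

# --- naive matrix helpers ------------------------------------------------

mat_mult_loop <- function(A, B) {
  C <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (k in seq_len(ncol(A)))
        C[i, j] <- C[i, j] + A[i, k] * B[k, j]
  C
}

# straight-line oracle for the composed forward pass (no dropout)
forward_oracle <- function(Y, Am, Ad, st, hp) {
  enc <- function(A, X, W0, W1) {
    inner <- mat_mult_loop(mat_mult_loop(A, X), W0)
    inner[inner < 0] <- 0
    tanh(mat_mult_loop(mat_mult_loop(A, inner), W1))
  }
  dec <- function(A, Z, W2, W3) {
    inner <- mat_mult_loop(mat_mult_loop(A, Z), W2)
    inner[inner < 0] <- 0
    1 / (1 + exp(-mat_mult_loop(mat_mult_loop(A, inner), W3)))
  }
  Zm <- enc(Am, Y, st$mirna$W0, st$mirna$W1)
  Zd <- enc(Ad, t(Y), st$disease$W0, st$disease$W1)
  Fm <- dec(Am, Zm, st$mirna$W2, st$mirna$W3)
  Fd <- dec(Ad, Zd, st$disease$W2, st$disease$W3)
  Fc <- hp$alpha * Fm + (1 - hp$alpha) * t(Fd)
  s <- if (hp$attention_scale == "dim") hp$hidden_dim else sqrt(hp$hidden_dim)
  logits <- mat_mult_loop(Zm, t(Zd)) / s
  P <- matrix(0, nrow(logits), ncol(logits))
  for (i in seq_len(nrow(logits))) {
    e <- exp(logits[i, ])
    P[i, ] <- e / sum(e)
  }
  list(Zm = Zm, Zd = Zd, Fm = Fm, Fd = Fd, F = Fc, P = P, T = P * Fc)
}

# exhaustive pairwise AUROC oracle: P(score+ > score-) + 0.5 P(tie)
auroc_oracle <- function(labels, scores) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (a in ps) for (b in ns)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(ps) * length(ns))
}

# hierarchy-decay contribution oracle: max over all descending paths from
# ancestor j down to i of delta^length, by exhaustive path enumeration
wang_oracle <- function(dag, disease, delta = 0.5) {
  root <- dag$disease_roots[[disease]]
  closure <- dag$closures[[root]]
  best <- setNames(rep(-Inf, length(closure)), closure)
  # enumerate all upward paths from the root
  walk <- function(node, depth) {
    best[node] <<- max(best[node], delta^depth)
    for (p in dag$parents_of[[node]]) walk(p, depth + 1)
  }
  walk(root, 0)
  best[closure]
}

# random small DAG over <= max_nodes nodes, child -> earlier node
random_dag <- function(max_nodes = 12L, n_diseases = 4L) {
  k <- sample(max(3L, n_diseases):max_nodes, 1)
  nodes <- paste0("t", seq_len(k))
  edges <- NULL
  for (i in 2:k) {
    n_par <- sample(1:min(2, i - 1), 1)
    for (p in sample(seq_len(i - 1), n_par))
      edges <- rbind(edges, data.frame(child = nodes[i], parent = nodes[p]))
  }
  dis <- paste0("D", seq_len(n_diseases))
  disease_dag(edges, setNames(sample(nodes, n_diseases, replace = FALSE), dis),
              nodes = nodes)
}

# small trained fixture shared across tests (computed once per test run)
small_fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(synthetic_spec(m = 40, n = 30, density = 0.08,
                                            seed = 5))
      hp <- hyperparams(hidden_dim = 8, inter_dim = 16, max_epochs = 40,
                        seed = 5)
      Sm <- fuse_mirna_similarity(ds$mirna_sim,
                                  gaussian_profile_similarity(ds$Y, "mirna"))
      Sd <- fuse_disease_similarity(NULL, NULL,
                                    gaussian_profile_similarity(ds$Y, "disease"))
      fit <- train_gae(ds$Y, normalize_adjacency(Sm), normalize_adjacency(Sd), hp)
      cache <<- list(ds = ds, hp = hp, fit = fit)
    }
    cache
  }
})
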