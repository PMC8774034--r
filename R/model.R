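#' Model hyperparameters
#'
#' Collects every tunable of the collaborative graph-autoencoder model.
#'
#' @param alpha balance between miRNA-space and disease-space scores in
#'   `F = alpha * Fm + (1 - alpha) * t(Fd)`; in (0, 1), default 0.5.
#' @param beta weight of the reconstruction (label-propagation) loss;
#'   default 1.
#' @param lam L2 penalty on all weights, added explicitly to the loss;
#'   default 1e-7.
#' @param hidden_dim embedding dimension `d` of the encoder output;
#'   default 64.
#' @param inter_dim width of the intermediate (first) layer of encoder and
#'   decoder; default 256.
#' @param dropout dropout rate applied to the input of each of the four
#'   layers during training only; default 0.5.
#' @param learning_rate Adam learning rate; default 0.01.
#' @param max_epochs training epoch cap; default 200.
#' @param tol relative loss-change convergence tolerance; default 1e-4.
#' @param seed integer seed controlling weight initialization and dropout.
#' @param attention_scale `"dim"` divides attention logits by `d` (as the
#'   model defines them), `"sqrt_dim"` by `sqrt(d)` (the transformer
#'   convention); the choice only rescales logits.
#' @param loss_mode `"full"` (attention + reconstruction), or the ablations
#'   `"attention_only"` / `"reconstruction_only"`; the L2 term is always
#'   kept.
#' @param delta hierarchy-decay factor for disease semantic similarity.
#' @return validated list of class `mdgae_hyperparams`.
#' @export
hyperparams <- function(alpha = 0.5, beta = 1, lam = 1e-7,
                        hidden_dim = 64L, inter_dim = 256L,
                        dropout = 0.5, learning_rate = 0.01,
                        max_epochs = 200L, tol = 1e-4, seed = 1L,
                        attention_scale = c("dim", "sqrt_dim"),
                        loss_mode = c("full", "attention_only",
                                      "reconstruction_only"),
                        delta = 0.5) {
  attention_scale <- match.arg(attention_scale)
  loss_mode <- match.arg(loss_mode)
  stopifnot(alpha > 0, alpha < 1, beta >= 0, lam >= 0,
            hidden_dim >= 1, inter_dim >= 1,
            dropout >= 0, dropout < 1,
            learning_rate > 0, max_epochs >= 1, tol >= 0,
            delta > 0, delta < 1)
  structure(list(alpha = alpha, beta = beta, lam = lam,
                 hidden_dim = as.integer(hidden_dim),
                 inter_dim = as.integer(inter_dim),
                 dropout = dropout, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), tol = tol,
                 seed = as.integer(seed),
                 attention_scale = attention_scale,
                 loss_mode = loss_mode, delta = delta),
            class = "mdgae_hyperparams")
}

as_adjacency <- function(A) {
  if (inherits(A, "normalized_graph")) A$adjacency else as.matrix(A)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable row-wise softmax
row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Graph-convolutional encoder
#'
#' `Enc(A, X) = tanh(A %*% relu(A %*% X %*% W0) %*% W1)`: two graph
#' convolutions over the normalized similarity graph `A`, producing one
#' embedding row per node with entries in (-1, 1).
#'
#' @param A a [normalize_adjacency()] result or square matrix.
#' @param X input features, one row per node.
#' @param W0,W1 weight matrices (`ncol(X) x inter`, `inter x d`).
#' @return `nrow(X) x ncol(W1)` embedding matrix.
#' @export
gae_encode <- function(A, X, W0, W1) {
  A <- as_adjacency(A)
  check_shapes(A, X, W0, W1)
  tanh(A %*% relu(A %*% X %*% W0) %*% W1)
}

#' Graph-convolutional decoder
#'
#' `Dec(A, Z) = sigmoid(A %*% relu(A %*% Z %*% W2) %*% W3)`: reconstructs a
#' score matrix from embeddings, entries strictly in (0, 1).
#'
#' @param A adjacency as in [gae_encode()].
#' @param Z embeddings, one row per node.
#' @param W2,W3 weight matrices (`ncol(Z) x inter`, `inter x out`).
#' @return `nrow(Z) x ncol(W3)` score matrix.
#' @export
gae_decode <- function(A, Z, W2, W3) {
  A <- as_adjacency(A)
  check_shapes(A, Z, W2, W3)
  sigmoid(A %*% relu(A %*% Z %*% W2) %*% W3)
}

check_shapes <- function(A, X, Wa, Wb) {
  if (nrow(A) != ncol(A) || nrow(A) != nrow(X))
    stop_data("adjacency must be square and match the feature rows")
  if (ncol(X) != nrow(Wa) || ncol(Wa) != nrow(Wb))
    stop_data("weight shapes inconsistent with inputs")
  invisible(TRUE)
}

#' Convex combination of the two score matrices
#'
#' `F = alpha * Fm + (1 - alpha) * t(Fd)`; `Fm` scores from the miRNA-side
#' autoencoder (`m x n`) and `Fd` from the disease side (`n x m`).
#'
#' @param Fm,Fd score matrices.
#' @param alpha balance in (0, 1).
#' @return `m x n` combined score matrix.
#' @export
combine_scores <- function(Fm, Fd, alpha = 0.5) {
  if (!identical(dim(Fm), rev(dim(Fd))))
    stop_data("Fd transposed must match Fm's shape")
  if (alpha <= 0 || alpha >= 1) stop_data("alpha must lie in (0, 1)")
  alpha * Fm + (1 - alpha) * t(Fd)
}

#' Self-attention score matrix
#'
#' Treats the miRNA embeddings as queries and the disease embeddings as
#' keys: `T = softmax(Zm %*% t(Zd) / s) * F` with a row-wise softmax (each
#' miRNA's attention distribution over diseases) and elementwise product
#' with the combined score matrix playing the role of the value.  The scale
#' `s` is the embedding dimension `d` (default) or `sqrt(d)`.
#'
#' @param Zm,Zd embeddings (`m x d`, `n x d`).
#' @param F combined score matrix (`m x n`).
#' @param scale `"dim"` or `"sqrt_dim"`.
#' @return `m x n` attention score matrix with attribute `"softmax"` (the
#'   row-stochastic factor).
#' @export
attention_score <- function(Zm, Zd, F, scale = c("dim", "sqrt_dim")) {
  scale <- match.arg(scale)
  if (ncol(Zm) != ncol(Zd))
    stop_data("embedding dimensions differ between the two sides")
  if (nrow(Zm) != nrow(F) || nrow(Zd) != ncol(F))
    stop_data("score matrix shape does not match the embeddings")
  d <- ncol(Zm)
  s <- if (scale == "dim") d else sqrt(d)
  P <- row_softmax(tcrossprod(Zm, Zd) / s)
  structure(P * F, softmax = P)
}

#' Training objective
#'
#' Full mode: `0.5 * ||Y - T||_F^2 + beta * Lr + lam * sum ||W||_F^2` with
#' reconstruction loss `Lr = alpha * ||Y - Fm||_F^2 +
#' (1 - alpha) * ||Y - t(Fd)||_F^2`.  The ablations drop one data term;
#' the L2 term always remains.  All Frobenius terms are raw sums of squares
#' (no averaging over entries).
#'
#' @param Y binary association matrix.
#' @param T attention score matrix.
#' @param Fm,Fd per-side score matrices.
#' @param hp [hyperparams()].
#' @param weights optional list (arbitrarily nested) of weight matrices for
#'   the L2 term.
#' @return nonnegative scalar.
#' @export
total_loss <- function(Y, T, Fm, Fd, hp, weights = NULL) {
  if (!identical(dim(Y), dim(T)) || !identical(dim(Y), dim(Fm)) ||
      !identical(dim(Y), rev(dim(Fd))))
    stop_data("loss inputs have inconsistent shapes")
  att <- 0.5 * sum((Y - T)^2)
  rec <- hp$alpha * sum((Y - Fm)^2) + (1 - hp$alpha) * sum((Y - t(Fd))^2)
  l2 <- if (is.null(weights)) 0 else
    sum(unlist(weights, use.names = FALSE)^2)
  switch(hp$loss_mode,
         full = att + hp$beta * rec + hp$lam * l2,
         attention_only = att + hp$lam * l2,
         reconstruction_only = hp$beta * rec + hp$lam * l2)
}

# --- weight initialization ----------------------------------------------

glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

#' Initialize the trainable state
#'
#' Glorot-uniform weights for both autoencoders, drawn from the current RNG
#' stream.  The two autoencoders share no weights; they are coupled only
#' through the joint loss.
#'
#' @param m,n numbers of miRNAs and diseases.
#' @param hp [hyperparams()].
#' @return list of class `mdgae_state` with elements `mirna` and `disease`,
#'   each holding `W0, W1, W2, W3`.
#' @export
init_model_state <- function(m, n, hp) {
  side <- function(nin) list(W0 = glorot(nin, hp$inter_dim),
                             W1 = glorot(hp$inter_dim, hp$hidden_dim),
                             W2 = glorot(hp$hidden_dim, hp$inter_dim),
                             W3 = glorot(hp$inter_dim, nin))
  structure(list(mirna = side(n), disease = side(m), m = m, n = n),
            class = "mdgae_state")
}

# --- forward / backward --------------------------------------------------

# One autoencoder side.  X is the side's input (Y or t(Y)); masks are
# inverted-dropout multipliers (mask / (1 - p)) or NULL when inactive.
forward_side <- function(A, X, W, masks = NULL) {
  dmul <- function(M, k) if (is.null(masks)) M else M * masks[[k]]
  X0 <- dmul(X, 1L)
  AX0 <- A %*% X0
  U0 <- AX0 %*% W$W0
  H <- relu(U0)
  Hd <- dmul(H, 2L)
  AH <- A %*% Hd
  U1 <- AH %*% W$W1
  Z <- tanh(U1)
  Zd <- dmul(Z, 3L)
  AZ <- A %*% Zd
  U2 <- AZ %*% W$W2
  G <- relu(U2)
  Gd <- dmul(G, 4L)
  AG <- A %*% Gd
  Fs <- sigmoid(AG %*% W$W3)
  list(AX0 = AX0, U0 = U0, AH = AH, Z = Z, AZ = AZ, U2 = U2, AG = AG,
       Fs = Fs, masks = masks)
}

draw_masks <- function(A_nrow, dims, p) {
  lapply(dims, function(dd) {
    matrix((stats::runif(A_nrow * dd) >= p) / (1 - p), A_nrow, dd)
  })
}

# Full forward pass; training = TRUE activates dropout (consumes RNG).
forward_full <- function(Y, Am, Ad, state, hp, training = FALSE) {
  m <- nrow(Y); n <- ncol(Y)
  p <- if (training) hp$dropout else 0
  masks_m <- masks_d <- NULL
  if (p > 0) {
    masks_m <- draw_masks(m, c(n, hp$inter_dim, hp$hidden_dim, hp$inter_dim), p)
    masks_d <- draw_masks(n, c(m, hp$inter_dim, hp$hidden_dim, hp$inter_dim), p)
  }
  fm <- forward_side(Am, Y, state$mirna, masks_m)
  fd <- forward_side(Ad, t(Y), state$disease, masks_d)
  Fc <- hp$alpha * fm$Fs + (1 - hp$alpha) * t(fd$Fs)
  s <- if (hp$attention_scale == "dim") hp$hidden_dim else sqrt(hp$hidden_dim)
  P <- row_softmax(tcrossprod(fm$Z, fd$Z) / s)
  list(m_side = fm, d_side = fd, F = Fc, P = P, T = P * Fc, s = s)
}

forward_loss <- function(Y, fwd, state, hp) {
  total_loss(Y, fwd$T, fwd$m_side$Fs, fwd$d_side$Fs, hp,
             weights = list(state$mirna, state$disease))
}

# Backprop through one side given dF (grad w.r.t. the side's score matrix)
# and dZ_extra (grad reaching the undropped embedding from the attention
# term).  A is symmetric, so t(A) %*% M == A %*% M throughout.
backward_side <- function(A, X, W, cache, dF, dZ_extra) {
  dmul <- function(M, k) if (is.null(cache$masks)) M else M * cache$masks[[k]]
  dU3 <- dF * cache$Fs * (1 - cache$Fs)
  gW3 <- crossprod(cache$AG, dU3)
  dG <- dmul(A %*% (dU3 %*% t(W$W3)), 4L)
  dU2 <- dG * (cache$U2 > 0)
  gW2 <- crossprod(cache$AZ, dU2)
  dZ <- dmul(A %*% (dU2 %*% t(W$W2)), 3L) + dZ_extra
  dU1 <- dZ * (1 - cache$Z^2)
  gW1 <- crossprod(cache$AH, dU1)
  dH <- dmul(A %*% (dU1 %*% t(W$W1)), 2L)
  dU0 <- dH * (cache$U0 > 0)
  gW0 <- crossprod(cache$AX0, dU0)
  list(W0 = gW0, W1 = gW1, W2 = gW2, W3 = gW3)
}

backward_full <- function(Y, Am, Ad, state, hp, fwd) {
  att_on <- hp$loss_mode %in% c("full", "attention_only")
  rec_on <- hp$loss_mode %in% c("full", "reconstruction_only")
  m <- nrow(Y); n <- ncol(Y)
  zero_mn <- matrix(0, m, n)
  Fm <- fwd$m_side$Fs; FdT <- t(fwd$d_side$Fs)
  dFm <- zero_mn; dFdT <- zero_mn
  dZm_extra <- matrix(0, m, hp$hidden_dim)
  dZd_extra <- matrix(0, n, hp$hidden_dim)
  if (att_on) {
    dT <- fwd$T - Y
    dFc <- dT * fwd$P
    dP <- dT * fwd$F
    # softmax backward, row-wise: dS = P * (dP - rowSums(dP * P))
    dS <- fwd$P * (dP - rowSums(dP * fwd$P))
    dZm_extra <- (dS %*% fwd$d_side$Z) / fwd$s
    dZd_extra <- (crossprod(dS, fwd$m_side$Z)) / fwd$s
    dFm <- dFm + hp$alpha * dFc
    dFdT <- dFdT + (1 - hp$alpha) * dFc
  }
  if (rec_on) {
    dFm <- dFm + 2 * hp$beta * hp$alpha * (Fm - Y)
    dFdT <- dFdT + 2 * hp$beta * (1 - hp$alpha) * (FdT - Y)
  }
  gm <- backward_side(Am, Y, state$mirna, fwd$m_side, dFm, dZm_extra)
  gd <- backward_side(Ad, t(Y), state$disease, fwd$d_side, t(dFdT), dZd_extra)
  for (k in names(gm)) {
    gm[[k]] <- gm[[k]] + 2 * hp$lam * state$mirna[[k]]
    gd[[k]] <- gd[[k]] + 2 * hp$lam * state$disease[[k]]
  }
  list(mirna = gm, disease = gd)
}

#' Loss and analytic gradients at a given state
#'
#' Deterministic (dropout disabled) objective value and its gradient with
#' respect to every weight block; primarily for gradient verification.
#'
#' @param Y association matrix.
#' @param Am,Ad normalized graphs from [normalize_adjacency()].
#' @param state an `mdgae_state`.
#' @param hp [hyperparams()].
#' @return list with `loss` and `grads` (mirroring the state layout).
#' @export
loss_and_gradients <- function(Y, Am, Ad, state, hp) {
  Am <- as_adjacency(Am); Ad <- as_adjacency(Ad)
  Y <- unclass(Y)
  fwd <- forward_full(Y, Am, Ad, state, hp, training = FALSE)
  list(loss = forward_loss(Y, fwd, state, hp),
       grads = backward_full(Y, Am, Ad, state, hp, fwd))
}

# --- Adam ----------------------------------------------------------------

adam_init <- function(state) {
  zeros <- function(W) lapply(W, function(w) array(0, dim(w)))
  list(m = list(mirna = zeros(state$mirna[1:4]), disease = zeros(state$disease[1:4])),
       v = list(mirna = zeros(state$mirna[1:4]), disease = zeros(state$disease[1:4])),
       t = 0L)
}

adam_step <- function(state, grads, opt, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (side in c("mirna", "disease")) {
    for (k in names(grads[[side]])) {
      g <- grads[[side]][[k]]
      opt$m[[side]][[k]] <- b1 * opt$m[[side]][[k]] + (1 - b1) * g
      opt$v[[side]][[k]] <- b2 * opt$v[[side]][[k]] + (1 - b2) * g^2
      mhat <- opt$m[[side]][[k]] / c1
      vhat <- opt$v[[side]][[k]] / c2
      state[[side]][[k]] <- state[[side]][[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(state = state, opt = opt)
}

# --- training loop -------------------------------------------------------

#' Train the collaborative graph autoencoders
#'
#' Runs full-batch Adam on the joint objective until the epoch cap or until
#' the relative loss change drops below `hp$tol`.  All randomness (weight
#' initialization, dropout) derives from `hp$seed`, so identical inputs and
#' seed give identical output.  The returned scores come from a final
#' dropout-free forward pass.
#'
#' @param Y an [association_matrix()] (or plain binary matrix).
#' @param Am,Ad normalized similarity graphs ([normalize_adjacency()]),
#'   `m x m` and `n x n`.
#' @param hp [hyperparams()].
#' @return list of class `mdgae_fit`: `scores` (list with `Zm`, `Zd`, `Fm`,
#'   `Fd`, `F`, `T`, `attention`), `state`, `loss_trace`, `epochs`, `hp`.
#' @export
train_gae <- function(Y, Am, Ad, hp = hyperparams()) {
  Amat <- as_adjacency(Am); Admat <- as_adjacency(Ad)
  Ymat <- unclass(as.matrix(Y))
  m <- nrow(Ymat); n <- ncol(Ymat)
  if (nrow(Amat) != m) stop_data("miRNA graph size does not match Y rows")
  if (nrow(Admat) != n) stop_data("disease graph size does not match Y columns")

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(hp$seed)

  state <- init_model_state(m, n, hp)
  opt <- adam_init(state)
  loss_trace <- numeric(0)
  prev_loss <- Inf
  for (epoch in seq_len(hp$max_epochs)) {
    fwd <- forward_full(Ymat, Amat, Admat, state, hp, training = hp$dropout > 0)
    loss <- forward_loss(Ymat, fwd, state, hp)
    if (!is.finite(loss))
      stop_divergence("training diverged (non-finite loss) at epoch %d", epoch, epoch)
    loss_trace[epoch] <- loss
    if (epoch > 1L &&
        abs(prev_loss - loss) / max(abs(prev_loss), 1e-12) < hp$tol) break
    prev_loss <- loss
    grads <- backward_full(Ymat, Amat, Admat, state, hp, fwd)
    upd <- adam_step(state, grads, opt, hp$learning_rate)
    state <- upd$state
    opt <- upd$opt
  }

  fin <- forward_full(Ymat, Amat, Admat, state, hp, training = FALSE)
  scores <- list(Zm = fin$m_side$Z, Zd = fin$d_side$Z,
                 Fm = fin$m_side$Fs, Fd = fin$d_side$Fs,
                 F = fin$F, T = fin$T, attention = fin$P)
  dimnames(scores$F) <- dimnames(scores$T) <- dimnames(scores$Fm) <- dimnames(Ymat)
  structure(list(scores = scores, state = state, loss_trace = loss_trace,
                 epochs = length(loss_trace), hp = hp),
            class = "mdgae_fit")
}

#' @export
print.mdgae_fit <- function(x, ...) {
  cat(sprintf("mdgae_fit: %d epochs, final loss %.6g (mode %s)\n",
              x$epochs, x$loss_trace[x$epochs], x$hp$loss_mode))
  invisible(x)
}

# --- checkpointing -------------------------------------------------------

CHECKPOINT_FORMAT <- "mdgae-checkpoint-1"

#' Save a trained model to JSON
#'
#' Portable text checkpoint: format-version string, hyperparameters, and
#' all eight weight matrices at full double precision.
#'
#' @param fit an `mdgae_fit` (or a bare `mdgae_state` plus `hp`).
#' @param path output path.
#' @param hp hyperparameters when `fit` is a bare state.
#' @export
save_checkpoint <- function(fit, path, hp = NULL) {
  if (inherits(fit, "mdgae_fit")) {
    state <- fit$state; hp <- fit$hp
  } else {
    state <- fit
    if (is.null(hp)) stop_usage("hp required when saving a bare state")
  }
  payload <- list(format_version = CHECKPOINT_FORMAT,
                  m = state$m, n = state$n,
                  hyperparams = unclass(hp),
                  weights = list(mirna = lapply(state$mirna[1:4], unclass),
                                 disease = lapply(state$disease[1:4], unclass)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path JSON checkpoint from [save_checkpoint()].
#' @return list with `state` (`mdgae_state`) and `hp` ([hyperparams()]).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_data("checkpoint not found: %s", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format_version, CHECKPOINT_FORMAT))
    stop_data("unsupported checkpoint format: %s", payload$format_version)
  hp <- do.call(hyperparams, payload$hyperparams)
  to_mats <- function(side) lapply(side, function(w) as.matrix(w))
  state <- structure(list(mirna = to_mats(payload$weights$mirna),
                          disease = to_mats(payload$weights$disease),
                          m = payload$m, n = payload$n),
                     class = "mdgae_state")
  list(state = state, hp = hp)
}
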