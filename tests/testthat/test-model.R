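test_that("encoder and decoder reproduce hand-derived values", {
  I2 <- diag(2)
  # encoder: A=I, X=I, W0=I, W1=I -> tanh(relu(I)) = tanh(1) on the diagonal
  expect_equal(gae_encode(I2, I2, I2, I2), tanh(1) * I2, tolerance = 1e-12)
  # zero last layer -> all zeros / all 0.5
  W1z <- matrix(0, 2, 3)
  expect_equal(gae_encode(I2, I2, I2, W1z), matrix(0, 2, 3))
  expect_equal(gae_decode(I2, I2, I2, W1z), matrix(0.5, 2, 3))
  # 1x1 decoder: sigmoid(2)
  expect_equal(gae_decode(matrix(1), matrix(1), matrix(1), matrix(2)),
               matrix(1 / (1 + exp(-2))), tolerance = 1e-12)
  expect_error(gae_encode(I2, diag(3), I2, I2), class = "mdgae_data_error")
})

test_that("score combination and attention match their definitions", {
  set.seed(71)
  Fm <- matrix(runif(6), 2, 3)
  Fd <- t(Fm)
  expect_equal(combine_scores(Fm, Fd, 0.3), Fm)
  expect_equal(combine_scores(matrix(0.2, 1, 1), matrix(0.6, 1, 1), 0.5),
               matrix(0.4, 1, 1))
  expect_error(combine_scores(Fm, Fm, 0.5), class = "mdgae_data_error")

  # zero embeddings -> uniform softmax -> T = F / n
  Fc <- matrix(runif(8), 2, 4)
  T0 <- attention_score(matrix(0, 2, 3), matrix(0, 4, 3), Fc)
  expect_equal(unclass(T0), Fc / 4, ignore_attr = TRUE)
  # 1x1: softmax of a scalar is 1 -> T = F
  T1 <- attention_score(matrix(2, 1, 2), matrix(-1, 1, 2), matrix(0.7, 1, 1))
  expect_equal(as.numeric(T1), 0.7)
  # rows of the softmax factor always sum to 1, and 0 <= T <= F
  Zm <- matrix(rnorm(8), 2, 4); Zd <- matrix(rnorm(12), 3, 4)
  Fc2 <- matrix(runif(6), 2, 3)
  for (sc in c("dim", "sqrt_dim")) {
    Tt <- attention_score(Zm, Zd, Fc2, sc)
    P <- attr(Tt, "softmax")
    expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
    expect_true(all(Tt >= 0 & unclass(Tt) <= Fc2))
  }
})

test_that("the loss equals its printed form in all three modes", {
  Y <- matrix(c(1, 0, 0, 1), 2, 2)
  hp <- hyperparams(alpha = 0.5, beta = 1, lam = 0)
  expect_equal(total_loss(Y, Y, Y, t(Y), hp), 0)
  # 1x1 hand case: 0.5*(1-0.5)^2 = 0.125 with exact reconstruction
  Y1 <- matrix(1)
  expect_equal(total_loss(Y1, matrix(0.5), matrix(1), matrix(1), hp), 0.125)
  # random case vs direct arithmetic, all modes, with an L2 term
  set.seed(81)
  T <- matrix(runif(4), 2, 2); Fm <- matrix(runif(4), 2, 2)
  Fd <- matrix(runif(4), 2, 2)
  W <- list(list(A = matrix(rnorm(4), 2, 2)), list(B = matrix(rnorm(2), 1, 2)))
  att <- 0.5 * sum((Y - T)^2)
  rec <- 0.3 * sum((Y - Fm)^2) + 0.7 * sum((Y - t(Fd))^2)
  l2 <- 1e-3 * sum(unlist(W)^2)
  hp2 <- hyperparams(alpha = 0.3, beta = 2, lam = 1e-3)
  expect_equal(total_loss(Y, T, Fm, Fd, hp2, W), att + 2 * rec + l2,
               tolerance = 1e-12)
  hp_a <- hyperparams(alpha = 0.3, beta = 2, lam = 1e-3,
                      loss_mode = "attention_only")
  expect_equal(total_loss(Y, T, Fm, Fd, hp_a, W), att + l2, tolerance = 1e-12)
  hp_r <- hyperparams(alpha = 0.3, beta = 2, lam = 1e-3,
                      loss_mode = "reconstruction_only")
  expect_equal(total_loss(Y, T, Fm, Fd, hp_r, W), 2 * rec + l2,
               tolerance = 1e-12)
})

test_that("the composed forward pass matches the loop oracle", {
  set.seed(91)
  for (rep in 1:10) {
    m <- sample(2:8, 1); n <- sample(2:8, 1); d <- sample(2:4, 1)
    Y <- unclass(random_Y(m, n))
    Am <- normalize_adjacency(gaussian_profile_similarity(
      association_matrix(Y), "mirna"))$adjacency
    Ad <- normalize_adjacency(gaussian_profile_similarity(
      association_matrix(Y), "disease"))$adjacency
    hp <- hyperparams(hidden_dim = d, inter_dim = 5, dropout = 0)
    st <- init_model_state(m, n, hp)
    fwd <- mdgae:::forward_full(Y, Am, Ad, st, hp, training = FALSE)
    orc <- forward_oracle(Y, Am, Ad, st, hp)
    expect_equal(fwd$m_side$Z, orc$Zm, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(fwd$d_side$Z, orc$Zd, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(fwd$F, orc$F, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(fwd$T, orc$T, tolerance = 1e-6, ignore_attr = TRUE)
    # embeddings bound the rank of the attention logits
    expect_lte(qr(fwd$m_side$Z %*% t(fwd$d_side$Z))$rank, d)
    expect_true(all(fwd$F > 0 & fwd$F < 1))
  }
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(101)
  m <- 4; n <- 3
  Y <- unclass(random_Y(m, n))
  Am <- normalize_adjacency(gaussian_profile_similarity(
    association_matrix(Y), "mirna"))
  Ad <- normalize_adjacency(gaussian_profile_similarity(
    association_matrix(Y), "disease"))
  for (mode in c("full", "attention_only", "reconstruction_only")) {
    hp <- hyperparams(hidden_dim = 3, inter_dim = 5, dropout = 0, lam = 1e-3,
                      loss_mode = mode)
    st <- init_model_state(m, n, hp)
    lg <- loss_and_gradients(Y, Am, Ad, st, hp)
    eps <- 1e-5
    for (side in c("mirna", "disease")) {
      for (k in c("W0", "W1", "W2", "W3")) {
        idx <- sample(length(st[[side]][[k]]), 4)
        for (ii in idx) {
          stp <- st; stp[[side]][[k]][ii] <- st[[side]][[k]][ii] + eps
          stm <- st; stm[[side]][[k]][ii] <- st[[side]][[k]][ii] - eps
          gnum <- (loss_and_gradients(Y, Am, Ad, stp, hp)$loss -
                   loss_and_gradients(Y, Am, Ad, stm, hp)$loss) / (2 * eps)
          gana <- lg$grads[[side]][[k]][ii]
          expect_lt(abs(gnum - gana) / max(1e-6, abs(gnum), abs(gana)), 1e-4)
        }
      }
    }
  }
})

test_that("training is seed-deterministic and reduces the loss", {
  fx <- small_fit_fixture()
  fit <- fx$fit
  expect_lt(fit$loss_trace[fit$epochs], fit$loss_trace[1])
  Sm <- fuse_mirna_similarity(fx$ds$mirna_sim,
                              gaussian_profile_similarity(fx$ds$Y, "mirna"))
  Sd <- fuse_disease_similarity(NULL, NULL,
                                gaussian_profile_similarity(fx$ds$Y, "disease"))
  fit2 <- train_gae(fx$ds$Y, normalize_adjacency(Sm), normalize_adjacency(Sd),
                    fx$hp)
  expect_identical(fit2$scores$F, fit$scores$F)  # bitwise
  expect_identical(fit2$loss_trace, fit$loss_trace)
  # score bundle invariants
  sc <- fit$scores
  expect_equal(sc$F, fx$hp$alpha * sc$Fm + (1 - fx$hp$alpha) * t(sc$Fd),
               ignore_attr = TRUE)
  expect_equal(rowSums(sc$attention), rep(1, nrow(sc$F)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(sc$T >= 0 & sc$T <= sc$F))
  expect_true(all(sc$F > 0 & sc$F < 1))
})

test_that("exploding optimization aborts with a divergence diagnostic", {
  Y <- unclass(random_Y(4, 3))
  Am <- normalize_adjacency(gaussian_profile_similarity(
    association_matrix(Y), "mirna"))
  Ad <- normalize_adjacency(gaussian_profile_similarity(
    association_matrix(Y), "disease"))
  hp <- hyperparams(hidden_dim = 2, inter_dim = 4, learning_rate = 1e200,
                    max_epochs = 10, seed = 2)
  err <- tryCatch(train_gae(Y, Am, Ad, hp), mdgae_divergence = function(e) e)
  expect_s3_class(err, "mdgae_divergence")
  expect_true(is.numeric(err$epoch) && err$epoch >= 1)
})

test_that("checkpoints round-trip the full state", {
  fx <- small_fit_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fx$fit, path)
  back <- load_checkpoint(path)
  for (side in c("mirna", "disease")) for (k in c("W0", "W1", "W2", "W3"))
    expect_equal(back$state[[side]][[k]], fx$fit$state[[side]][[k]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$hp$alpha, fx$hp$alpha)
  expect_equal(back$hp$loss_mode, fx$hp$loss_mode)
  # scoring with the restored state reproduces the fit's scores
  ds <- fx$ds
  Sm <- fuse_mirna_similarity(ds$mirna_sim,
                              gaussian_profile_similarity(ds$Y, "mirna"))
  Sd <- fuse_disease_similarity(NULL, NULL,
                                gaussian_profile_similarity(ds$Y, "disease"))
  fwd <- mdgae:::forward_full(unclass(ds$Y),
                              normalize_adjacency(Sm)$adjacency,
                              normalize_adjacency(Sd)$adjacency,
                              back$state, back$hp, training = FALSE)
  expect_equal(fwd$F, fx$fit$scores$F, tolerance = 1e-10, ignore_attr = TRUE)
})
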