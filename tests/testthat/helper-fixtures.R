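# Small hand-built and generated fixtures shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_dataset <- function() {
  association_dataset(data.frame(
    snorna_id = c("s1", "s2", "s3", "s1"),
    disease_id = c("d1", "d1", "d2", "d2")
  ))
}

random_dataset <- function(n_s, n_d, density = 0.2, seed = 1) {
  set.seed(seed)
  A <- matrix(rbinom(n_s * n_d, 1, density), n_s)
  if (sum(A) == 0) A[1, 1] <- 1L
  pairs <- which(A == 1L, arr.ind = TRUE)
  association_dataset(data.frame(
    snorna_id = sprintf("s%d", pairs[, 1]),
    disease_id = sprintf("d%d", pairs[, 2])
  ))
}

# Random symmetric 0/1 adjacency without self-loops.
random_adjacency <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  Y <- matrix(0, n, n)
  Y[upper.tri(Y)] <- rbinom(n * (n - 1) / 2, 1, p)
  Y + t(Y)
}

# Zero-filled gated layer parameter set (state width H).
zero_gru_params <- function(H) {
  p <- list(Theta = matrix(0, H, H))
  for (nm in c("W_ab", "W_b", "W_az", "W_z", "W_ah", "W_h")) {
    p[[nm]] <- matrix(0, H, H)
  }
  for (nm in c("b_ab", "b_b", "b_az", "b_z", "b_ah", "b_h")) {
    p[[nm]] <- numeric(H)
  }
  p
}

random_gru_params <- function(H, seed = 1, scale = 0.5) {
  set.seed(seed)
  p <- list(Theta = matrix(rnorm(H * H, sd = scale), H))
  for (nm in c("W_ab", "W_b", "W_az", "W_z", "W_ah", "W_h")) {
    p[[nm]] <- matrix(rnorm(H * H, sd = scale), H)
  }
  for (nm in c("b_ab", "b_b", "b_az", "b_z", "b_ah", "b_h")) {
    p[[nm]] <- rnorm(H, sd = scale)
  }
  p
}

# Brute-force AUC: fraction of concordant positive-negative pairs, ties 1/2.
brute_force_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Held-out recovery experiment used by the model tests and acceptance suite:
# hold out 10% of positives (one CV-fold's worth), train, and score the
# held-out positives against an equal balanced negative draw.
recovery_auc <- function(seed, variant = "full", epochs = 300) {
  gen <- generate_planted_bipartite(synthetic_config(seed = seed))
  ds <- gen$dataset
  pos <- which(ds$A == 1L, arr.ind = TRUE)
  set.seed(seed + 500)
  held <- pos[sample(nrow(pos), round(0.1 * nrow(pos))), , drop = FALSE]
  split <- train_split(ds, held)
  eval_neg <- sample_negatives(ds, nrow(held), seed = seed + 900)
  cfg <- model_config(epochs = epochs, seed = seed, variant = variant)
  model <- cgsda_train(ds, split,
                       list(snorna = gen$snorna_features,
                            disease = gen$disease_features),
                       cfg, neg_exclude = eval_neg)
  S <- model$sd_scores
  compute_metrics(c(S[held], S[eval_neg]),
                  c(rep(1, nrow(held)), rep(0, nrow(eval_neg))))$auc
}
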