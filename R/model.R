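#' Model configuration
#'
#' Collects every tunable of the dual-branch model with the tuned defaults:
#' two spectral layers of polynomial orders 3 and 5, three gated layers with
#' one propagation step each, shared hidden width 64, learning rate 5e-4,
#' weight decay 1e-4, dropout 0.01 and 600 training epochs.
#'
#' @param cheb_layers Number of spectral layers.
#' @param cheb_orders Integer vector of per-layer Chebyshev orders
#'   (length `cheb_layers`).
#' @param cheb_halve_k0 Halve the k=0 interpolation term?
#' @param gated_layers Number of gated layers.
#' @param gated_seq_len Propagation steps within each gated layer.
#' @param gated_self_message Degree-scaled self-message aggregation variant?
#' @param hidden_dim Shared hidden/output width of encoders and branches.
#' @param learning_rate,weight_decay Adam step size and L2 weight decay.
#' @param dropout Dropout rate in `[0, 1)` on encoder outputs and layer
#'   inputs (training only).
#' @param epochs Training epochs.
#' @param variant One of `"full"`, `"no-cheb"`, `"no-gated"`, `"no-residual"`
#'   (the ablation variants).
#' @param residual Residual feature injection on? Forced off by the
#'   `"no-residual"` variant.
#' @param seed Integer seed controlling initialization, dropout and negative
#'   resampling.
#' @return A list of class `cgsda_config`.
#' @export
model_config <- function(cheb_layers = 2, cheb_orders = c(3, 5),
                         cheb_halve_k0 = FALSE, gated_layers = 3,
                         gated_seq_len = 1, gated_self_message = FALSE,
                         hidden_dim = 64, learning_rate = 5e-4,
                         weight_decay = 1e-4, dropout = 0.01, epochs = 600,
                         variant = c("full", "no-cheb", "no-gated",
                                     "no-residual"),
                         residual = TRUE, seed = 1) {
  variant <- match.arg(variant)
  if (length(cheb_orders) != cheb_layers) {
    stop("`cheb_orders` must have one order per spectral layer")
  }
  stopifnot(gated_layers >= 1, gated_seq_len >= 1, hidden_dim >= 1,
            dropout >= 0, dropout < 1, epochs >= 1)
  if (variant == "no-residual") residual <- FALSE
  structure(list(
    cheb_layers = as.integer(cheb_layers),
    cheb_orders = as.integer(cheb_orders),
    cheb_halve_k0 = cheb_halve_k0,
    gated_layers = as.integer(gated_layers),
    gated_seq_len = as.integer(gated_seq_len),
    gated_self_message = gated_self_message,
    hidden_dim = as.integer(hidden_dim),
    learning_rate = learning_rate,
    weight_decay = weight_decay,
    dropout = dropout,
    epochs = as.integer(epochs),
    variant = variant,
    residual = residual,
    seed = as.integer(seed)
  ), class = "cgsda_config")
}

.use_cheb <- function(config) config$variant != "no-cheb"
.use_gated <- function(config) config$variant != "no-gated"

.glorot <- function(n_in, n_out) {
  a <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -a, a), n_in, n_out)
}

# Initialize every learnable tensor.  gamma starts at all-ones (near-identity
# spectral filter); GRU/encoder weights are Glorot-uniform, biases zero.
.init_params <- function(d_s, d_d, config) {
  H <- config$hidden_dim
  params <- list(enc = list(W_s = .glorot(d_s, H), b_s = numeric(H),
                            W_d = .glorot(d_d, H), b_d = numeric(H)))
  if (.use_cheb(config)) {
    widths <- H
    for (m in seq_len(config$cheb_layers)) {
      widths <- c(widths, if (config$residual) widths[m] + H else widths[m])
    }
    params$cheb <- list(
      gamma = lapply(config$cheb_orders, function(K) rep(1, K + 1)),
      proj_W = .glorot(widths[config$cheb_layers + 1], H),
      proj_b = numeric(H)
    )
  }
  if (.use_gated(config)) {
    layers <- vector("list", config$gated_layers)
    for (m in seq_len(config$gated_layers)) {
      in_w <- if (config$residual) 2 * H else H
      lp <- list(P = if (in_w > H) .glorot(in_w, H) else NULL,
                 Theta = .glorot(H, H))
      for (nm in .gated_layer_params) lp[[nm]] <- .glorot(H, H)
      for (nm in .gated_layer_biases) lp[[nm]] <- numeric(H)
      layers[[m]] <- lp
    }
    params$gated <- list(layers = layers, proj_W = .glorot(H, H),
                         proj_b = numeric(H))
  }
  params
}

#' Encode raw node features into the shared hidden space
#'
#' One single-layer affine transform per side followed by a rectifier, with
#' the resulting rows stacked snoRNAs-first to align with the block
#' adjacency. Dropout (inverted, seeded by the caller's RNG state) is applied
#' only when `training = TRUE`.
#'
#' @param F_s0,F_d0 Raw snoRNA and disease feature matrices.
#' @param weights List with `W_s`, `b_s`, `W_d`, `b_d`.
#' @param dropout Dropout rate.
#' @param training Apply dropout?
#' @return The stacked encoded matrix (`N_S + N_D` rows, hidden width).
#' @export
encode_initial_features <- function(F_s0, F_d0, weights, dropout = 0,
                                    training = FALSE) {
  fwd <- .encode_forward(as.matrix(F_s0), as.matrix(F_d0), weights,
                         dropout, training)
  fwd$F0
}

.encode_forward <- function(F_s0, F_d0, weights, dropout, training) {
  if (ncol(F_s0) != nrow(weights$W_s) || ncol(F_d0) != nrow(weights$W_d)) {
    stop("feature width does not match the stored encoder weights")
  }
  add_b <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)
  A_s <- add_b(F_s0 %*% weights$W_s, weights$b_s)
  A_d <- add_b(F_d0 %*% weights$W_d, weights$b_d)
  F_mlp <- rbind(pmax(A_s, 0), pmax(A_d, 0))
  mask <- NULL
  F0 <- F_mlp
  if (training && dropout > 0) {
    mask <- matrix(stats::rbinom(length(F_mlp), 1, 1 - dropout), nrow(F_mlp))
    F0 <- F_mlp * mask / (1 - dropout)
  }
  list(F0 = F0, A_s = A_s, A_d = A_d, mask = mask)
}

.encode_backward <- function(dF0, F_s0, F_d0, weights, enc_cache, dropout) {
  if (!is.null(enc_cache$mask)) dF0 <- dF0 * enc_cache$mask / (1 - dropout)
  n_s <- nrow(F_s0)
  dA_s <- dF0[seq_len(n_s), , drop = FALSE] * (enc_cache$A_s > 0)
  dA_d <- dF0[-seq_len(n_s), , drop = FALSE] * (enc_cache$A_d > 0)
  list(W_s = crossprod(F_s0, dA_s), b_s = colSums(dA_s),
       W_d = crossprod(F_d0, dA_d), b_d = colSums(dA_d))
}

# Full forward pass with caches (internal).  Returns the fused embedding.
.model_forward <- function(L_hat, Y, F_s0, F_d0, params, config,
                           training = FALSE) {
  enc <- .encode_forward(F_s0, F_d0, params$enc, config$dropout, training)
  F0 <- enc$F0
  out <- NULL
  cheb <- gated <- NULL
  if (.use_cheb(config)) {
    ccfg <- list(halve_k0 = config$cheb_halve_k0, residual = config$residual,
                 dropout = config$dropout)
    cheb <- .cheb_branch_forward(L_hat, F0, params$cheb, ccfg, training)
    out <- cheb$out
  }
  if (.use_gated(config)) {
    gcfg <- list(seq_len = config$gated_seq_len, residual = config$residual,
                 dropout = config$dropout,
                 self_message = config$gated_self_message)
    gated <- .gated_branch_forward(Y, F0, params$gated, gcfg, training)
    out <- if (is.null(out)) gated$out else cbind(out, gated$out)
  }
  list(F_final = out, enc = enc, cheb = cheb, gated = gated, F0 = F0)
}

.model_backward <- function(dF_final, L_hat, Y, F_s0, F_d0, params, config,
                            fwd) {
  H <- config$hidden_dim
  grads <- list()
  dF0 <- matrix(0, nrow(fwd$F0), ncol(fwd$F0))
  col <- 0
  if (.use_cheb(config)) {
    ccfg <- list(halve_k0 = config$cheb_halve_k0, residual = config$residual,
                 dropout = config$dropout)
    bk <- .cheb_branch_backward(dF_final[, col + seq_len(H), drop = FALSE],
                                L_hat, fwd$F0, params$cheb, ccfg,
                                fwd$cheb$cache)
    grads$cheb <- bk$grads
    dF0 <- dF0 + bk$dF0
    col <- col + H
  }
  if (.use_gated(config)) {
    gcfg <- list(seq_len = config$gated_seq_len, residual = config$residual,
                 dropout = config$dropout,
                 self_message = config$gated_self_message)
    bk <- .gated_branch_backward(dF_final[, col + seq_len(H), drop = FALSE],
                                 Y, fwd$F0, params$gated, gcfg,
                                 fwd$gated$cache)
    grads$gated <- bk$grads
    dF0 <- dF0 + bk$dF0
  }
  grads$enc <- .encode_backward(dF0, F_s0, F_d0, params$enc, fwd$enc,
                                config$dropout)
  grads
}

#' Run the fused forward pass
#'
#' Orchestrates the ablation variants: the full model concatenates the
#' spectral and gated branch outputs (width `2 * hidden_dim`); `"no-cheb"`
#' and `"no-gated"` keep a single branch; `"no-residual"` runs both branches
#' without residual injection.
#'
#' @param graph A `hetero_graph`.
#' @param encoded The stacked encoded features from
#'   [encode_initial_features()].
#' @param params Parameter list as built internally by [cgsda_train()]
#'   (components `cheb`, `gated`).
#' @param config A [model_config()].
#' @return The fused embedding matrix `F_final`.
#' @export
cgsda_forward <- function(graph, encoded, params, config) {
  L_hat <- unclass(scaled_laplacian(graph))
  out <- NULL
  if (.use_cheb(config)) {
    ccfg <- list(halve_k0 = config$cheb_halve_k0, residual = config$residual,
                 dropout = 0)
    out <- .cheb_branch_forward(L_hat, as.matrix(encoded), params$cheb,
                                ccfg)$out
  }
  if (.use_gated(config)) {
    gcfg <- list(seq_len = config$gated_seq_len, residual = config$residual,
                 dropout = 0, self_message = config$gated_self_message)
    g <- .gated_branch_forward(graph$Y, as.matrix(encoded), params$gated,
                               gcfg)$out
    out <- if (is.null(out)) g else cbind(out, g)
  }
  out
}

#' Sigmoid inner-product decoder
#'
#' Scores every node pair as `sigmoid(f_i . f_j)`; the snoRNA x disease block
#' of interest is rows `1..n_s` by columns `n_s+1..n_s+n_d`. The full score
#' matrix is symmetric with entries strictly in (0, 1).
#'
#' @param F_final Fused embedding matrix.
#' @param n_s Number of snoRNA rows; when given, the snoRNA x disease block
#'   is attached as attribute `"sd_block"`.
#' @return The full score matrix.
#' @export
decode_scores <- function(F_final, n_s = NULL) {
  F_final <- as.matrix(F_final)
  Y_hat <- .logistic(tcrossprod(F_final))
  # keep the open-interval contract under floating-point saturation
  Y_hat <- pmin(pmax(Y_hat, 1e-12), 1 - 1e-12)
  if (!is.null(n_s)) {
    attr(Y_hat, "sd_block") <-
      Y_hat[seq_len(n_s), (n_s + 1):ncol(Y_hat), drop = FALSE]
  }
  Y_hat
}

#' Binary cross-entropy over selected scores
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` with probabilities clamped at
#' 1e-12 for numerical safety.
#'
#' @param scores Predicted probabilities in (0, 1).
#' @param labels 0/1 labels, same length.
#' @return Scalar loss.
#' @export
bce_loss <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# Adam update over an arbitrarily nested list of numeric arrays.
.adam_step <- function(state, params, grads, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p
      out_m <- if (is.null(m)) p else m
      out_v <- if (is.null(v)) p else v
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (i in keys) {
        if (is.null(p[[i]])) next
        r <- walk(p[[i]], g[[i]],
                  if (is.null(m)) NULL else m[[i]],
                  if (is.null(v)) NULL else v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      if (is.null(m)) { m <- p * 0; v <- p * 0 }
      g <- g + wd * p
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      m_hat <- m / (1 - beta1^t)
      v_hat <- v / (1 - beta2^t)
      list(p = p - lr * m_hat / (sqrt(v_hat) + eps), m = m, v = v)
    }
  }
  walk(params, grads, state$m, state$v)
}

# Uniform sample of n index pairs (rows of the flattened sd block) from the
# allowed pool, without replacement.
.sample_pairs <- function(pool, n) {
  if (length(pool) < n) stop("negative-sample pool exhausted")
  pool[sample.int(length(pool), n)]
}

#' Train the dual-branch association model
#'
#' Gradient-based training of every learnable tensor (encoders, spectral
#' filter values, GRU parameters, projections) by adaptive moment estimation
#' with L2 weight decay. Each epoch computes the binary cross-entropy on all
#' training positives plus an equal-size, freshly resampled set of negatives
#' drawn uniformly from pairs that are neither training nor held-out
#' positives (and outside `neg_exclude`). All randomness (initialization,
#' dropout, resampling) is driven by `config$seed`, so identical seeds give
#' identical fits.
#'
#' @param dataset An [association_dataset()].
#' @param split A [train_split()]; its zeroed positives are the held-out set.
#' @param features List with `snorna` and `disease` raw feature matrices
#'   (rows aligned to the dataset id order).
#' @param config A [model_config()].
#' @param neg_exclude Optional two-column index matrix of additional pairs
#'   (e.g. evaluation negatives) to keep out of the training negative pool.
#' @return A fitted model of class `cgsda_model` carrying the parameters,
#'   config, id orderings, loss trajectory and final embeddings.
#' @export
cgsda_train <- function(dataset, split = train_split(dataset), features,
                        config = model_config(), neg_exclude = NULL) {
  A_train <- split$A_train
  n_s <- nrow(A_train)
  n_d <- ncol(A_train)
  pos <- which(A_train == 1L)
  if (length(pos) == 0) stop("no training positives")
  F_s0 <- as.matrix(features$snorna)
  F_d0 <- as.matrix(features$disease)
  stopifnot(nrow(F_s0) == n_s, nrow(F_d0) == n_d)

  graph <- build_block_adjacency(dataset, split)
  Y <- graph$Y
  L_hat <- unclass(scaled_laplacian(Y))

  # negative pool: zero entries of A (so neither train nor held-out positives)
  pool <- which(dataset$A == 0L)
  if (!is.null(neg_exclude) && NROW(neg_exclude) > 0) {
    ex <- as.matrix(neg_exclude)[, 1:2, drop = FALSE]
    pool <- setdiff(pool, (ex[, 2] - 1L) * n_s + ex[, 1])
  }

  set.seed(config$seed)
  params <- .init_params(ncol(F_s0), ncol(F_d0), config)
  adam <- list(m = NULL, v = NULL)
  losses <- numeric(config$epochs)

  pos_i <- ((pos - 1L) %% n_s) + 1L
  pos_j <- ((pos - 1L) %/% n_s) + 1L

  for (epoch in seq_len(config$epochs)) {
    neg <- .sample_pairs(pool, length(pos))
    neg_i <- ((neg - 1L) %% n_s) + 1L
    neg_j <- ((neg - 1L) %/% n_s) + 1L
    ig <- c(pos_i, neg_i)
    jg <- n_s + c(pos_j, neg_j)
    y <- c(rep(1, length(pos)), rep(0, length(neg)))

    fwd <- .model_forward(L_hat, Y, F_s0, F_d0, params, config,
                          training = TRUE)
    Ff <- fwd$F_final
    z <- rowSums(Ff[ig, , drop = FALSE] * Ff[jg, , drop = FALSE])
    p <- .logistic(z)
    losses[epoch] <- bce_loss(p, y)

    dz <- (p - y) / length(y)
    dF <- matrix(0, nrow(Ff), ncol(Ff))
    acc_i <- rowsum(dz * Ff[jg, , drop = FALSE], group = ig)
    dF[as.integer(rownames(acc_i)), ] <-
      dF[as.integer(rownames(acc_i)), , drop = FALSE] + acc_i
    acc_j <- rowsum(dz * Ff[ig, , drop = FALSE], group = jg)
    dF[as.integer(rownames(acc_j)), ] <-
      dF[as.integer(rownames(acc_j)), , drop = FALSE] + acc_j

    grads <- .model_backward(dF, L_hat, Y, F_s0, F_d0, params, config, fwd)
    upd <- .adam_step(adam, params, grads, config$learning_rate,
                      config$weight_decay, epoch)
    params <- upd$p
    adam$m <- upd$m
    adam$v <- upd$v
  }

  F_final <- cgsda_forward(graph, encode_initial_features(F_s0, F_d0,
                                                          params$enc),
                           params, config)
  sd_scores <- attr(decode_scores(F_final, n_s), "sd_block")
  dimnames(sd_scores) <- list(dataset$snorna_ids, dataset$disease_ids)
  structure(list(
    params = params, config = config,
    snorna_ids = dataset$snorna_ids, disease_ids = dataset$disease_ids,
    n_s = n_s, n_d = n_d,
    losses = losses, F_final = F_final,
    sd_scores = sd_scores,
    split = split
  ), class = "cgsda_model")
}

#' @export
print.cgsda_model <- function(x, ...) {
  cat("<cgsda_model> variant '", x$config$variant, "': ", x$n_s,
      " snoRNAs x ", x$n_d, " diseases; ", x$config$epochs,
      " epochs, final loss ", format(utils::tail(x$losses, 1), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Predict association scores for snoRNA-disease pairs
#'
#' Scores are read from the decoded snoRNA x disease block of the fitted
#' model; the output preserves the order of `pairs`.
#'
#' @param object A fitted `cgsda_model`.
#' @param pairs Data frame (or two-column matrix) of snoRNA and disease
#'   identifiers; `NULL` scores every pair.
#' @param ... Unused.
#' @return A tibble with `snorna_id`, `disease_id`, `score`.
#' @export
predict.cgsda_model <- function(object, pairs = NULL, ...) {
  S <- object$sd_scores
  if (is.null(pairs)) {
    pairs <- expand.grid(snorna_id = object$snorna_ids,
                         disease_id = object$disease_ids,
                         stringsAsFactors = FALSE)
  }
  pairs <- as.data.frame(pairs)
  si <- match(as.character(pairs[[1]]), object$snorna_ids)
  di <- match(as.character(pairs[[2]]), object$disease_ids)
  if (anyNA(si)) stop("unknown snoRNA id: ",
                      paste(unique(pairs[[1]][is.na(si)]), collapse = ", "))
  if (anyNA(di)) stop("unknown disease id: ",
                      paste(unique(pairs[[2]][is.na(di)]), collapse = ", "))
  tibble::tibble(snorna_id = as.character(pairs[[1]]),
                 disease_id = as.character(pairs[[2]]),
                 score = S[cbind(si, di)])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-pair scores of a fitted model
#'
#' @param x A `cgsda_model`.
#' @param ... Unused.
#' @return One row per snoRNA-disease pair with the predicted score.
#' @export
tidy.cgsda_model <- function(x, ...) {
  predict(x)
}

#' One-row fit summary of a fitted model
#'
#' @param x A `cgsda_model`.
#' @param ... Unused.
#' @return A tibble with the variant, dimensions, epochs and initial/final
#'   training loss.
#' @export
glance.cgsda_model <- function(x, ...) {
  tibble::tibble(variant = x$config$variant, n_snorna = x$n_s,
                 n_disease = x$n_d, hidden_dim = x$config$hidden_dim,
                 epochs = x$config$epochs,
                 initial_loss = x$losses[1],
                 final_loss = utils::tail(x$losses, 1))
}
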