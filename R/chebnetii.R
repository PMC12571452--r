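#' Chebyshev interpolation nodes
#'
#' The order-`K` filter is parameterized by its values at the `K + 1`
#' Chebyshev nodes `x_j = cos((j + 0.5) * pi / (K + 1))`, `j = 0..K`, which
#' suppresses the Runge phenomenon of free polynomial coefficients.
#'
#' @param K Polynomial order (>= 0).
#' @return Numeric vector of `K + 1` strictly decreasing values in (-1, 1).
#' @export
chebyshev_nodes <- function(K) {
  if (K < 0) stop("K must be >= 0")
  j <- 0:K
  cos((j + 0.5) * pi / (K + 1))
}

#' Chebyshev polynomial of the first kind
#'
#' Evaluates `T_k(x)` by the three-term recurrence `T_0 = 1`, `T_1 = x`,
#' `T_k = 2 x T_{k-1} - T_{k-2}`; equal to `cos(k * acos(x))` on `[-1, 1]`.
#'
#' @param k Degree (>= 0).
#' @param x Scalar or vector with `|x| <= 1`.
#' @return `T_k(x)`, vectorized over `x`.
#' @export
cheb_polynomial_value <- function(k, x) {
  if (any(abs(x) > 1 + 1e-12)) stop("|x| must be <= 1")
  if (k == 0) return(rep(1, length(x)) * x^0)
  t_prev <- rep(1, length(x))
  t_cur <- x
  if (k == 1) return(t_cur)
  for (i in 2:k) {
    t_next <- 2 * x * t_cur - t_prev
    t_prev <- t_cur
    t_cur <- t_next
  }
  t_cur
}

#' Chebyshev interpolation filter weights
#'
#' Converts the learnable node values `gamma_j` into polynomial-basis weights
#' `w_k = (2 / (K + 1)) * sum_j gamma_j T_k(x_j)`. With `halve_k0 = TRUE` the
#' `k = 0` term is halved (the original-ChebNetII convention); the default
#' keeps the plain summation.
#'
#' @param gamma Numeric vector of `K + 1` filter values at the Chebyshev
#'   nodes.
#' @param halve_k0 Halve the `k = 0` weight?
#' @return Numeric vector `w_0..w_K`.
#' @export
interpolation_weights <- function(gamma, halve_k0 = FALSE) {
  K <- length(gamma) - 1L
  x <- chebyshev_nodes(K)
  w <- vapply(0:K, function(k) {
    (2 / (K + 1)) * sum(gamma * cheb_polynomial_value(k, x))
  }, numeric(1))
  if (halve_k0) w[1] <- w[1] / 2
  w
}

# Jacobian d w_k / d gamma_j as a (K+1) x (K+1) matrix; linear map, so the
# backward pass is a single matrix product.
.interp_weight_jacobian <- function(K, halve_k0 = FALSE) {
  x <- chebyshev_nodes(K)
  J <- t(vapply(0:K, function(k) {
    (2 / (K + 1)) * cheb_polynomial_value(k, x)
  }, numeric(K + 1)))
  if (halve_k0) J[1, ] <- J[1, ] / 2
  J
}

#' Scaled Laplacian of the block adjacency
#'
#' With the largest eigenvalue fixed at 2 (standard spectral-GNN practice),
#' the rescaled operator is `L_hat = L - I = -D^(-1/2) Y D^(-1/2)`, whose
#' spectrum lies in `[-1, 1]`. Isolated nodes get zero rows/columns.
#'
#' @param Y Symmetric nonnegative adjacency matrix (or a `hetero_graph`).
#' @return A symmetric matrix of class `spectral_operator`.
#' @export
scaled_laplacian <- function(Y) {
  if (inherits(Y, "hetero_graph")) Y <- Y$Y
  if (!isSymmetric(unname(Y))) stop("Y must be symmetric")
  deg <- rowSums(Y)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L_hat <- -(inv_sqrt * Y) * rep(inv_sqrt, each = nrow(Y))
  # row scaling by inv_sqrt, column scaling via the rep() trick
  L_hat <- (L_hat + t(L_hat)) / 2  # kill asymmetric rounding noise
  class(L_hat) <- c("spectral_operator", class(L_hat))
  L_hat
}

# Sum_k w_k T_k(L_hat) %*% F by the matrix recurrence; shared by the forward
# pass, the backward pass (the operator is symmetric) and the Z-cache builder.
.cheb_apply <- function(L_hat, F0, w, keep_terms = FALSE) {
  K <- length(w) - 1L
  Z_prev <- F0
  out <- w[1] * Z_prev
  terms <- if (keep_terms) list(Z_prev) else NULL
  if (K >= 1) {
    Z_cur <- L_hat %*% F0
    out <- out + w[2] * Z_cur
    if (keep_terms) terms[[2]] <- Z_cur
    if (K >= 2) {
      for (k in 2:K) {
        Z_next <- 2 * (L_hat %*% Z_cur) - Z_prev
        out <- out + w[k + 1] * Z_next
        Z_prev <- Z_cur
        Z_cur <- Z_next
        if (keep_terms) terms[[k + 1]] <- Z_next
      }
    }
  }
  if (keep_terms) list(out = out, terms = terms) else out
}

#' One ChebNetII spectral propagation
#'
#' Applies the interpolated polynomial filter `sum_k w_k T_k(L_hat)` to the
#' feature matrix `F` via the stable matrix recurrence `Z_0 = F`,
#' `Z_1 = L_hat F`, `Z_k = 2 L_hat Z_{k-1} - Z_{k-2}`. Width is preserved.
#' With all `gamma = 1` and no k0-halving the filter collapses to `2 I`
#' (the node sums of `T_k` vanish for `k >= 1`), giving a near-identity warm
#' start under the all-ones initialization.
#'
#' @param L_hat A [scaled_laplacian()] operator.
#' @param F Numeric feature matrix, one row per node.
#' @param gamma Filter values at the Chebyshev nodes (length `K + 1`).
#' @param halve_k0 Passed to [interpolation_weights()].
#' @return Filtered feature matrix, same shape as `F`.
#' @export
chebnetii_propagate <- function(L_hat, F, gamma, halve_k0 = FALSE) {
  F <- as.matrix(F)
  if (nrow(F) != nrow(L_hat)) stop("F row count must equal node count")
  w <- interpolation_weights(gamma, halve_k0)
  unclass(.cheb_apply(unclass(L_hat), F, w))
}

# ---- branch forward/backward (internal, used by the training engine) -------

# params: list(gamma = list(per layer), proj_W, proj_b)
# cfg: list(orders, halve_k0, residual, dropout)
# masks: list(per-layer dropout masks or NULL)
.cheb_branch_forward <- function(L_hat, F0, params, cfg, training = FALSE,
                                 masks = NULL) {
  M <- length(params$gamma)
  cache <- list(inputs = vector("list", M), terms = vector("list", M),
                masks = vector("list", M), widths = integer(M))
  prev <- F0
  for (m in seq_len(M)) {
    inp <- if (cfg$residual) cbind(prev, F0) else prev
    if (training && cfg$dropout > 0) {
      mask <- if (is.null(masks)) {
        matrix(stats::rbinom(length(inp), 1, 1 - cfg$dropout), nrow(inp))
      } else masks[[m]]
      inp_d <- inp * mask / (1 - cfg$dropout)
      cache$masks[[m]] <- mask
    } else {
      inp_d <- inp
    }
    w <- interpolation_weights(params$gamma[[m]], cfg$halve_k0)
    res <- .cheb_apply(L_hat, inp_d, w, keep_terms = TRUE)
    cache$inputs[[m]] <- inp_d
    cache$terms[[m]] <- res$terms
    cache$widths[m] <- ncol(prev)
    prev <- res$out
  }
  out <- prev %*% params$proj_W +
    matrix(params$proj_b, nrow(prev), length(params$proj_b), byrow = TRUE)
  cache$last <- prev
  list(out = out, cache = cache)
}

.cheb_branch_backward <- function(d_out, L_hat, F0, params, cfg, cache) {
  M <- length(params$gamma)
  grads <- list(gamma = vector("list", M),
                proj_W = crossprod(cache$last, d_out),
                proj_b = colSums(d_out))
  d_prev <- d_out %*% t(params$proj_W)
  dF0 <- matrix(0, nrow(F0), ncol(F0))
  for (m in rev(seq_len(M))) {
    w <- interpolation_weights(params$gamma[[m]], cfg$halve_k0)
    K <- length(w) - 1L
    dw <- vapply(0:K, function(k) {
      sum(d_prev * cache$terms[[m]][[k + 1]])
    }, numeric(1))
    grads$gamma[[m]] <- as.numeric(crossprod(
      .interp_weight_jacobian(K, cfg$halve_k0), dw))
    d_in <- .cheb_apply(L_hat, d_prev, w)  # operator polynomial is symmetric
    if (!is.null(cache$masks[[m]])) {
      d_in <- d_in * cache$masks[[m]] / (1 - cfg$dropout)
    }
    if (cfg$residual) {
      wp <- cache$widths[m]
      dF0 <- dF0 + d_in[, (wp + 1):ncol(d_in), drop = FALSE]
      d_prev <- d_in[, seq_len(wp), drop = FALSE]
    } else {
      d_prev <- d_in
    }
  }
  dF0 <- dF0 + d_prev  # layer-1 "previous output" is F0 itself
  list(grads = grads, dF0 = dF0)
}

#' Run the full ChebNetII branch
#'
#' Stacks `length(gamma)` spectral layers. Layer `m`'s input is the previous
#' layer's output, concatenated with the encoded initial features `F_mlp` when
#' the residual mechanism is on (layer 1 concatenates `F_mlp` with itself), so
#' with hidden width 64 the layer input widths run 128 then 192. A terminal
#' single linear layer projects back to the shared hidden width. Dropout is
#' applied to layer inputs only when `training = TRUE`.
#'
#' @param graph A [build_block_adjacency()] graph (or a bare symmetric `Y`).
#' @param F_mlp Encoded features, one row per node (snoRNAs first).
#' @param params List with `gamma` (list of per-layer node-value vectors),
#'   `proj_W`, `proj_b`.
#' @param residual Residual concatenation on? (default `TRUE`)
#' @param halve_k0 Halve the k=0 interpolation term? (default `FALSE`)
#' @param dropout Dropout rate on layer inputs (training only).
#' @param training Apply dropout?
#' @return The branch output matrix (`nrow(F_mlp)` x `ncol(proj_W)`).
#' @export
chebnetii_stack <- function(graph, F_mlp, params, residual = TRUE,
                            halve_k0 = FALSE, dropout = 0, training = FALSE) {
  L_hat <- scaled_laplacian(graph)
  cfg <- list(orders = lengths(params$gamma) - 1L, halve_k0 = halve_k0,
              residual = residual, dropout = dropout)
  .cheb_branch_forward(unclass(L_hat), as.matrix(F_mlp), params, cfg,
                       training = training)$out
}
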