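#' Prepare the initial GRU state of a gated layer
#'
#' Inputs narrower than the state width `H` are right-padded with zeros;
#' inputs wider than `H` (which arise when the residual concatenation widens
#' the layer input) go through the layer's learnable linear projector.
#'
#' @param F Layer input features (rows = nodes).
#' @param H State width.
#' @param projector Optional `ncol(F)` x `H` matrix, required when
#'   `ncol(F) > H`.
#' @return Node-state matrix of width `H`.
#' @export
prepare_initial_state <- function(F, H, projector = NULL) {
  F <- as.matrix(F)
  w <- ncol(F)
  if (w == H) return(F)
  if (w < H) return(cbind(F, matrix(0, nrow(F), H - w)))
  if (is.null(projector)) {
    stop("input wider than the state width needs a projector")
  }
  F %*% projector
}

#' Aggregate neighbor messages
#'
#' Computes `alpha_v = sum_{u in N(v)} e_{u,v} * Theta h_u` over the
#' undirected graph (all edge weights 1). Setting `literal_self = TRUE`
#' reproduces the degree-scaled self-message variant in which the target's own
#' state is summed over its neighborhood instead of the neighbors' states.
#'
#' @param graph A `hetero_graph` (or bare symmetric adjacency matrix).
#' @param states Node-state matrix (rows = nodes, width `H`).
#' @param Theta `H` x `H` message transform.
#' @param literal_self Use the target node's own state in the sum?
#' @return Matrix of aggregated messages, same shape as `states`.
#' @export
aggregate_messages <- function(graph, states, Theta, literal_self = FALSE) {
  Y <- if (inherits(graph, "hetero_graph")) graph$Y else graph
  states <- as.matrix(states)
  if (ncol(states) != nrow(Theta)) stop("state width must match Theta")
  msg <- states %*% Theta
  if (literal_self) rowSums(Y) * msg else Y %*% msg
}

#' One GRU state update
#'
#' Applies the gate equations exactly as written: reset gate
#' `beta = sigmoid(alpha W_ab + b_ab + h W_b + b_b)`, update gate
#' `zeta = sigmoid(alpha W_az + b_az + h W_z + b_z)`, candidate
#' `eta = tanh(alpha W_ah + b_ah + beta * (h W_h + b_h))`, and
#' `h' = (1 - zeta) * eta + zeta * h`. With all parameters zero this halves
#' the state (`beta = zeta = 1/2`, `eta = 0`).
#'
#' @param alpha Aggregated messages (rows = nodes, width `H`).
#' @param h Current states, same shape.
#' @param params List with `W_ab, W_b, W_az, W_z, W_ah, W_h` (`H` x `H`) and
#'   biases `b_ab, b_b, b_az, b_z, b_ah, b_h` (length `H`).
#' @param cache Return intermediate gate values too?
#' @return Updated state matrix, or (with `cache = TRUE`) a list with `h_new`
#'   and the gate intermediates.
#' @export
gru_update <- function(alpha, h, params, cache = FALSE) {
  add_b <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)
  beta <- .logistic(add_b(alpha %*% params$W_ab, params$b_ab) +
                      add_b(h %*% params$W_b, params$b_b))
  zeta <- .logistic(add_b(alpha %*% params$W_az, params$b_az) +
                      add_b(h %*% params$W_z, params$b_z))
  u <- add_b(h %*% params$W_h, params$b_h)
  eta <- tanh(add_b(alpha %*% params$W_ah, params$b_ah) + beta * u)
  h_new <- (1 - zeta) * eta + zeta * h
  if (cache) list(h_new = h_new, beta = beta, zeta = zeta, eta = eta, u = u)
  else h_new
}

# ---- branch forward/backward (internal) ------------------------------------

# layer params: list(P (projector or NULL), Theta, W_ab.., b_ab..)
# cfg: list(seq_len, residual, dropout, self_message)
.gated_layer_params <- c("W_ab", "W_b", "W_az", "W_z", "W_ah", "W_h")
.gated_layer_biases <- c("b_ab", "b_b", "b_az", "b_z", "b_ah", "b_h")

.gated_branch_forward <- function(Y, F0, params, cfg, training = FALSE,
                                  masks = NULL) {
  M <- length(params$layers)
  cache <- list(layers = vector("list", M))
  prev <- F0
  for (m in seq_len(M)) {
    lp <- params$layers[[m]]
    inp <- if (cfg$residual) cbind(prev, F0) else prev
    lcache <- list(width_prev = ncol(prev), mask = NULL)
    if (training && cfg$dropout > 0) {
      mask <- if (is.null(masks)) {
        matrix(stats::rbinom(length(inp), 1, 1 - cfg$dropout), nrow(inp))
      } else masks[[m]]
      inp_d <- inp * mask / (1 - cfg$dropout)
      lcache$mask <- mask
    } else {
      inp_d <- inp
    }
    lcache$inp_d <- inp_d
    h <- prepare_initial_state(inp_d, ncol(lp$Theta), lp$P)
    steps <- vector("list", cfg$seq_len)
    for (t in seq_len(cfg$seq_len)) {
      msg <- h %*% lp$Theta
      alpha <- if (cfg$self_message) rowSums(Y) * msg else Y %*% msg
      st <- gru_update(alpha, h, lp, cache = TRUE)
      steps[[t]] <- list(h_in = h, alpha = alpha, beta = st$beta,
                         zeta = st$zeta, eta = st$eta, u = st$u)
      h <- st$h_new
    }
    lcache$steps <- steps
    cache$layers[[m]] <- lcache
    prev <- h
  }
  out <- prev %*% params$proj_W +
    matrix(params$proj_b, nrow(prev), length(params$proj_b), byrow = TRUE)
  cache$last <- prev
  list(out = out, cache = cache)
}

.gated_branch_backward <- function(d_out, Y, F0, params, cfg, cache) {
  M <- length(params$layers)
  grads <- list(layers = vector("list", M),
                proj_W = crossprod(cache$last, d_out),
                proj_b = colSums(d_out))
  dh <- d_out %*% t(params$proj_W)
  dF0 <- matrix(0, nrow(F0), ncol(F0))
  deg <- rowSums(Y)
  for (m in rev(seq_len(M))) {
    lp <- params$layers[[m]]
    lc <- cache$layers[[m]]
    g <- list()
    for (nm in .gated_layer_params) g[[nm]] <- matrix(0, nrow(lp[[nm]]),
                                                     ncol(lp[[nm]]))
    for (nm in .gated_layer_biases) g[[nm]] <- numeric(length(lp[[nm]]))
    g$Theta <- matrix(0, nrow(lp$Theta), ncol(lp$Theta))
    for (t in rev(seq_len(cfg$seq_len))) {
      st <- lc$steps[[t]]
      dzeta <- dh * (st$h_in - st$eta)
      deta <- dh * (1 - st$zeta)
      dh_in <- dh * st$zeta
      dsh <- deta * (1 - st$eta^2)
      g$W_ah <- g$W_ah + crossprod(st$alpha, dsh)
      g$b_ah <- g$b_ah + colSums(dsh)
      dalpha <- dsh %*% t(lp$W_ah)
      dbeta <- dsh * st$u
      du <- dsh * st$beta
      g$W_h <- g$W_h + crossprod(st$h_in, du)
      g$b_h <- g$b_h + colSums(du)
      dh_in <- dh_in + du %*% t(lp$W_h)
      dsb <- dbeta * st$beta * (1 - st$beta)
      g$W_ab <- g$W_ab + crossprod(st$alpha, dsb)
      g$b_ab <- g$b_ab + colSums(dsb)
      g$b_b <- g$b_b + colSums(dsb)
      dalpha <- dalpha + dsb %*% t(lp$W_ab)
      g$W_b <- g$W_b + crossprod(st$h_in, dsb)
      dh_in <- dh_in + dsb %*% t(lp$W_b)
      dsz <- dzeta * st$zeta * (1 - st$zeta)
      g$W_az <- g$W_az + crossprod(st$alpha, dsz)
      g$b_az <- g$b_az + colSums(dsz)
      g$b_z <- g$b_z + colSums(dsz)
      dalpha <- dalpha + dsz %*% t(lp$W_az)
      g$W_z <- g$W_z + crossprod(st$h_in, dsz)
      dh_in <- dh_in + dsz %*% t(lp$W_z)
      dmsg <- if (cfg$self_message) deg * dalpha else Y %*% dalpha
      g$Theta <- g$Theta + crossprod(st$h_in, dmsg)
      dh_in <- dh_in + dmsg %*% t(lp$Theta)
      dh <- dh_in
    }
    # initial-state preparation
    inp_d <- lc$inp_d
    if (!is.null(lp$P)) {
      g$P <- crossprod(inp_d, dh)
      d_in <- dh %*% t(lp$P)
    } else {
      d_in <- dh[, seq_len(ncol(inp_d)), drop = FALSE]
    }
    if (!is.null(lc$mask)) d_in <- d_in * lc$mask / (1 - cfg$dropout)
    if (cfg$residual) {
      wp <- lc$width_prev
      dF0 <- dF0 + d_in[, (wp + 1):ncol(d_in), drop = FALSE]
      dh <- d_in[, seq_len(wp), drop = FALSE]
    } else {
      dh <- d_in
    }
    grads$layers[[m]] <- g
  }
  dF0 <- dF0 + dh
  list(grads = grads, dF0 = dF0)
}

#' Run the full gated graph sequence branch
#'
#' Stacks `length(params$layers)` gated layers. Each layer concatenates the
#' previous output with the encoded features `F_mlp` (residual), prepares the
#' initial GRU state by zero-padding or learned projection, and runs
#' `seq_len` aggregate-then-GRU propagation steps sharing that layer's
#' parameters. A terminal single linear layer projects to the shared hidden
#' width.
#'
#' @param graph A `hetero_graph` (or bare symmetric adjacency).
#' @param F_mlp Encoded features, one row per node (snoRNAs first).
#' @param params List with `layers` (each holding `P`, `Theta`, GRU weights
#'   and biases) plus `proj_W`, `proj_b`.
#' @param seq_len Propagation steps per layer (default 1).
#' @param residual Residual concatenation on?
#' @param self_message Use the degree-scaled self-message aggregation variant?
#' @param dropout Dropout rate on layer inputs (training only).
#' @param training Apply dropout?
#' @return The branch output matrix.
#' @export
gatedgcn_stack <- function(graph, F_mlp, params, seq_len = 1, residual = TRUE,
                           self_message = FALSE, dropout = 0,
                           training = FALSE) {
  Y <- if (inherits(graph, "hetero_graph")) graph$Y else graph
  cfg <- list(seq_len = seq_len, residual = residual, dropout = dropout,
              self_message = self_message)
  .gated_branch_forward(Y, as.matrix(F_mlp), params, cfg,
                        training = training)$out
}
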