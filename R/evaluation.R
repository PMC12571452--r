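#' Partition the positive pairs into cross-validation folds
#'
#' Uniform seeded partition of all 1-entries of `A` into `k` folds whose
#' sizes differ by at most one (911 positives at `k = 10` give nine folds of
#' 91 and one of 92).
#'
#' @param dataset An [association_dataset()].
#' @param k Number of folds (>= 2, <= number of positives).
#' @param seed Integer seed.
#' @return A list of class `fold_plan`: `folds` (list of two-column index
#'   matrices, columns `snorna`/`disease`), `k`, `seed`.
#' @export
make_folds <- function(dataset, k = 10, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  pos <- which(dataset$A == 1L, arr.ind = TRUE)
  n <- nrow(pos)
  if (k > n) stop("k exceeds the number of positives")
  set.seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- vector("list", k)
  at <- 0L
  for (f in seq_len(k)) {
    take <- idx[(at + 1):(at + sizes[f])]
    m <- pos[take, , drop = FALSE]
    colnames(m) <- c("snorna", "disease")
    folds[[f]] <- m
    at <- at + sizes[f]
  }
  structure(list(folds = folds, k = k, seed = seed), class = "fold_plan")
}

#' Sample negative (unknown) pairs
#'
#' Draws `n` distinct pairs uniformly from the 0-entries of `A`, excluding
#' any pairs in `exclude`.
#'
#' @param dataset An [association_dataset()].
#' @param n Number of pairs to draw.
#' @param exclude Optional two-column index matrix of pairs to keep out of
#'   the pool.
#' @param seed Optional integer seed.
#' @return Two-column integer matrix (columns `snorna`, `disease`).
#' @export
sample_negatives <- function(dataset, n, exclude = NULL, seed = NULL) {
  n_s <- nrow(dataset$A)
  pool <- which(dataset$A == 0L)
  if (!is.null(exclude) && NROW(exclude) > 0) {
    ex <- as.matrix(exclude)[, 1:2, drop = FALSE]
    pool <- setdiff(pool, (ex[, 2] - 1L) * n_s + ex[, 1])
  }
  if (length(pool) < n) stop("negative pool exhausted (",
                             length(pool), " < ", n, ")")
  if (!is.null(seed)) set.seed(seed)
  take <- pool[sample.int(length(pool), n)]
  out <- cbind(snorna = ((take - 1L) %% n_s) + 1L,
               disease = ((take - 1L) %/% n_s) + 1L)
  out
}

.auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # average ranks handle ties as 1/2 concordance
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.aupr_step <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  n1 <- sum(y)
  # evaluate only at the last index of each tie block
  keep <- c(s[-length(s)] != s[-1], TRUE)
  prec <- (tp / seq_along(y))[keep]
  rec <- (tp / n1)[keep]
  sum(diff(c(0, rec)) * prec)
}

#' The seven evaluation metrics for one score set
#'
#' AUC by the rank statistic (ties count one half), AUPR by step summation of
#' the precision-recall curve, and the five confusion-matrix metrics
#' (accuracy, recall, specificity, precision, F1) at the given score
#' threshold.
#'
#' @param scores Predicted scores.
#' @param labels 0/1 labels; both classes must be present.
#' @param threshold Classification threshold (default 0.5; scores at or above
#'   it are called positive).
#' @return A one-row tibble with columns `auc`, `aupr`, `f1`, `acc`, `rec`,
#'   `spe`, `pre`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("AUC/AUPR are undefined with a single class")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  rec <- tp / (tp + fn)
  spe <- tn / (tn + fp)
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  tibble::tibble(
    auc = .auc_rank(scores, labels),
    aupr = .aupr_step(scores, labels),
    f1 = f1,
    acc = (tp + tn) / length(labels),
    rec = rec,
    spe = spe,
    pre = pre
  )
}

# Train on one fold and score its balanced evaluation set (internal).
.fit_fold <- function(dataset, features, config, fold, fold_seed) {
  split <- train_split(dataset, fold)
  eval_neg <- sample_negatives(dataset, nrow(fold), seed = fold_seed)
  cfg <- config
  cfg$seed <- fold_seed
  model <- cgsda_train(dataset, split, features, cfg, neg_exclude = eval_neg)
  S <- model$sd_scores
  scores <- c(S[fold], S[eval_neg])
  labels <- c(rep(1L, nrow(fold)), rep(0L, nrow(eval_neg)))
  list(scores = scores, labels = labels, model = model)
}

#' k-fold cross-validation of the association model
#'
#' For each fold the model is retrained on the remaining positives (with
#' per-epoch balanced negative resampling); the held-out positives plus an
#' equal number of freshly sampled negatives - disjoint from all known
#' positives and excluded from that fold's training negatives - form the
#' balanced evaluation set. The report has one row per fold plus `mean` and
#' `sd` rows, in the metric order AUC, AUPR, F1, Acc, Rec, Spe, Pre.
#'
#' @param dataset An [association_dataset()].
#' @param features List with `snorna` and `disease` raw feature matrices.
#' @param config A [model_config()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed driving the fold plan, per-fold training and
#'   negative sampling.
#' @return A tibble of class `cgsda_cv` with `k + 2` rows.
#' @export
cross_validate <- function(dataset, features, config = model_config(),
                           k = 10, seed = 1) {
  plan <- make_folds(dataset, k, seed)
  rows <- purrr::map(seq_len(k), function(f) {
    fit <- .fit_fold(dataset, features, config, plan$folds[[f]],
                     fold_seed = as.integer((as.numeric(seed) * 100 + f) %%
                                              2147483647))
    dplyr::bind_cols(tibble::tibble(fold = as.character(f)),
                     compute_metrics(fit$scores, fit$labels))
  })
  per_fold <- dplyr::bind_rows(rows)
  num <- dplyr::select(per_fold, -"fold")
  summary <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(fold = "mean"),
                     dplyr::summarise(num, dplyr::across(
                       dplyr::everything(), mean))),
    dplyr::bind_cols(tibble::tibble(fold = "sd"),
                     dplyr::summarise(num, dplyr::across(
                       dplyr::everything(), stats::sd)))
  )
  out <- dplyr::bind_rows(per_fold, summary)
  class(out) <- c("cgsda_cv", class(out))
  out
}

#' Cross-validated ablation comparison
#'
#' Runs [cross_validate()] for each requested model variant on the same data
#' and seed and returns the mean metrics per variant (one row each), mirroring
#' an ablation table.
#'
#' @param dataset,features,config,k,seed As in [cross_validate()].
#' @param variants Character vector of variants to compare.
#' @return A tibble with one row per variant.
#' @export
run_ablation <- function(dataset, features, config = model_config(), k = 10,
                         seed = 1,
                         variants = c("full", "no-cheb", "no-gated",
                                      "no-residual")) {
  purrr::map_dfr(variants, function(v) {
    cfg <- config
    cfg$variant <- v
    if (v == "no-residual") cfg$residual <- FALSE
    rep <- cross_validate(dataset, features, cfg, k = k, seed = seed)
    dplyr::bind_cols(tibble::tibble(variant = v),
                     dplyr::select(rep[rep$fold == "mean", ], -"fold"))
  })
}

#' Rank candidate snoRNAs for a target disease
#'
#' Two case-study protocols: `"novel-disease"` retrains with every edge of
#' the target disease removed (the disease is treated as unseen) and ranks
#' all snoRNAs for it; `"novel-association"` trains on all known positives
#' and ranks only the unknown pairs of the target. Ranking is by descending
#' score, ties broken by snoRNA id for determinism.
#'
#' @param dataset An [association_dataset()].
#' @param features List with `snorna` and `disease` raw feature matrices.
#' @param config A [model_config()].
#' @param target Disease identifier.
#' @param mode `"novel-disease"` or `"novel-association"`.
#' @param top_n Number of candidates to return (default 15).
#' @return A tibble with `rank`, `snorna_id`, `disease_id`, `score`.
#' @export
rank_candidates <- function(dataset, features, config = model_config(),
                            target, mode = c("novel-disease",
                                             "novel-association"),
                            top_n = 15) {
  mode <- match.arg(mode)
  j <- match(target, dataset$disease_ids)
  if (is.na(j)) stop("unknown disease id: ", target)
  if (mode == "novel-disease") {
    held <- which(dataset$A[, j] == 1L)
    fold <- cbind(snorna = held, disease = rep(j, length(held)))
    split <- train_split(dataset, fold)
    model <- cgsda_train(dataset, split, features, config)
    cand <- seq_len(model$n_s)
  } else {
    model <- cgsda_train(dataset, train_split(dataset), features, config)
    cand <- which(dataset$A[, j] == 0L)
  }
  scores <- model$sd_scores[cand, j]
  ids <- dataset$snorna_ids[cand]
  ord <- order(-scores, ids)
  keep <- utils::head(ord, top_n)
  tibble::tibble(rank = seq_along(keep),
                 snorna_id = ids[keep],
                 disease_id = target,
                 score = scores[keep])
}
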