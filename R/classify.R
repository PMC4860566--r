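# Imbalanced voxel classification: random under-sampling of the majority
# class, classic discrete AdaBoost over decision stumps on the 10 PCA scores,
# and a leave-one-out cross-validation driver that fits the PCA inside each
# training fold.

as_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) return(ifelse(y == "disrupted", 1, -1))
  if (all(y %in% c(-1, 1))) return(as.numeric(y))
  stop("labels must be logical, 'disrupted'/'non-disrupted', or +/-1")
}

#' Balance a training set by under-sampling the majority class
#'
#' Keeps every minority sample and draws an equal number of majority samples
#' uniformly without replacement, deterministically for a given seed.
#'
#' @param X feature matrix (rows = samples).
#' @param y labels: logical (TRUE = disrupted), "disrupted"/"non-disrupted",
#'   or +/-1.
#' @param seed integer seed for the draw.
#' @return List with balanced `X`, `y` (+/-1) and the selected row `idx`.
#' @export
undersample <- function(X, y, seed = 1L) {
  y <- as_pm1(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  pos <- which(y == 1); neg <- which(y == -1)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present to balance")
  if (length(pos) <= length(neg)) { mino <- pos; majo <- neg }
  else { mino <- neg; majo <- pos }
  keep_majo <- if (length(majo) == length(mino)) majo
               else with_seed(seed, sample(majo, length(mino)))
  idx <- sort(c(mino, keep_majo))
  list(X = X[idx, , drop = FALSE], y = y[idx], idx = idx)
}

# Best decision stump under sample weights: O(n log n) sweep per feature.
best_stump <- function(X, y, w) {
  n <- nrow(X)
  best <- list(err = Inf)
  tot_pos <- sum(w[y == 1])
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xs <- X[o, j]; ys <- y[o]; ws <- w[o]
    # err_plus[i]: error of "predict +1 strictly above threshold after i"
    cum_pos <- cumsum(ws * (ys == 1))
    cum_neg <- cumsum(ws * (ys == -1))
    tot_neg <- cum_neg[n]
    i <- 0:n
    err_plus <- c(0, cum_pos) + (tot_neg - c(0, cum_neg))
    valid <- c(TRUE, xs[-n] != xs[-1], TRUE)     # cut only between distinct values
    err_plus[!valid] <- Inf
    err_minus <- ifelse(is.finite(err_plus), (tot_pos + tot_neg) - err_plus, Inf)
    bp <- which.min(err_plus); bm <- which.min(err_minus)
    for (cand in list(c(err_plus[bp], bp, 1), c(err_minus[bm], bm, -1))) {
      if (cand[1] < best$err) {
        cut <- cand[2] - 1
        thr <- if (cut == 0) xs[1] - 1
               else if (cut == n) xs[n] + 1
               else (xs[cut] + xs[cut + 1]) / 2
        best <- list(err = cand[1], feature = j, threshold = thr,
                     polarity = cand[3])
      }
    }
  }
  best
}

stump_predict <- function(feature, threshold, polarity, X) {
  ifelse(polarity * (X[, feature] - threshold) > 0, 1, -1)
}

#' Train a discrete AdaBoost stump ensemble
#'
#' Classic discrete AdaBoost: uniform initial weights; each round picks the
#' decision stump (feature, mid-point threshold, polarity) minimising the
#' weighted error; `alpha = 0.5 log((1 - eps) / eps)` with `eps` clamped to
#' `[1e-10, 1 - 1e-10]`; multiplicative weight update and renormalisation.
#' Boosting stops early when no stump beats chance (`eps >= 0.5`) or the
#' training set is separated (`eps <= 1e-10`).
#'
#' @param X numeric feature matrix (typically n x 10 PCA scores).
#' @param y labels as in [undersample()] (balanced input recommended).
#' @param n_rounds maximum boosting rounds T (default 100).
#' @return An object of class `ez_adaboost`: `stumps` (data frame), `alphas`,
#'   `errors` (weighted error trace) and `n_features`.
#' @export
train_adaboost <- function(X, y, n_rounds = 100L) {
  X <- as.matrix(X)
  y <- as_pm1(y)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  alphas <- errors <- wsums <- numeric(n_rounds)
  t <- 0L
  for (round in seq_len(n_rounds)) {
    st <- best_stump(X, y, w)
    eps <- st$err / sum(w)
    if (eps >= 0.5) break
    t <- t + 1L
    eps_c <- min(max(eps, 1e-10), 1 - 1e-10)
    a <- 0.5 * log((1 - eps_c) / eps_c)
    stumps[[t]] <- st[c("feature", "threshold", "polarity")]
    alphas[t] <- a
    errors[t] <- eps
    if (eps <= 1e-10) break
    h <- stump_predict(st$feature, st$threshold, st$polarity, X)
    w <- w * exp(-a * y * h)
    w <- w / sum(w)
    wsums[t] <- sum(w)
  }
  if (t == 0L) stop("no stump beat chance on the training data")
  structure(list(
    stumps = do.call(rbind, lapply(stumps[seq_len(t)], as.data.frame)),
    alphas = alphas[seq_len(t)],
    errors = errors[seq_len(t)],
    weight_sums = wsums[seq_len(t)],
    n_rounds = t, n_features = ncol(X)),
    class = "ez_adaboost")
}

#' @export
print.ez_adaboost <- function(x, ...) {
  cat(sprintf("<ez_adaboost> %d stumps over %d features; final weighted error %.4g\n",
              x$n_rounds, x$n_features, tail(x$errors, 1)))
  invisible(x)
}

#' Predict with an AdaBoost model
#'
#' The label is the sign of the weighted stump vote; a zero margin maps to the
#' negative (non-disrupted) class.
#'
#' @param object an `ez_adaboost`.
#' @param newdata matrix with the training feature count.
#' @param type "class" for logical labels (TRUE = disrupted) or "margin" for
#'   the real-valued vote sum.
#' @param ... unused.
#' @return Logical labels or numeric margins.
#' @export
predict.ez_adaboost <- function(object, newdata, type = c("class", "margin"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("model expects %d features, got %d",
                 object$n_features, ncol(newdata)))
  margin <- rep(0, nrow(newdata))
  for (t in seq_len(object$n_rounds)) {
    s <- object$stumps[t, ]
    margin <- margin + object$alphas[t] *
      stump_predict(s$feature, s$threshold, s$polarity, newdata)
  }
  if (type == "margin") margin else margin > 0
}

#' Leave-one-out cross-validated voxel classification
#'
#' For each held-out eye, the PCA is fitted on the training eyes' pooled
#' feature matrix only, the pooled training scores are balanced by
#' under-sampling, an AdaBoost model is trained, and every VOI voxel of the
#' held-out eye is classified. Deterministic given `seed`.
#'
#' @param eyes list of per-eye lists, each with `id`, `X` (n x 57 features for
#'   that eye's VOI voxels) and `y` (labels as in [undersample()]).
#' @param n_rounds boosting rounds per fold.
#' @param seed master integer seed (per-fold under-sampling seeds derive from it).
#' @param n_components PCA scores retained (default 10).
#' @return List of per-eye results: `id`, `pred` (logical), `margin`, counts
#'   `tp`, `fp`, `tn`, `fn`, metrics `sen`, `spe`, `bar` (percent, NA where
#'   undefined), and the fold `model`.
#' @export
loo_cv <- function(eyes, n_rounds = 100L, seed = 1L, n_components = 10L) {
  stopifnot(length(eyes) >= 2L)
  fold_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(eyes)))
  lapply(seq_along(eyes), function(i) {
    tr <- eyes[-i]
    Xtr <- do.call(rbind, lapply(tr, `[[`, "X"))
    ytr <- as_pm1(unlist(lapply(tr, function(e) as_pm1(e$y))))
    if (!any(ytr == 1))
      stop(sprintf("fold holding out eye '%s' has no disrupted training samples",
                   eyes[[i]]$id))
    pca <- fit_pca(Xtr, n_components = n_components)
    Str <- apply_pca(pca, Xtr)
    bal <- undersample(Str, ytr, seed = fold_seeds[i])
    model <- train_adaboost(bal$X, bal$y, n_rounds = n_rounds)
    Ste <- apply_pca(pca, eyes[[i]]$X)
    margin <- predict(model, Ste, type = "margin")
    pred <- margin > 0
    yte <- as_pm1(eyes[[i]]$y) == 1
    tp <- sum(pred & yte); fp <- sum(pred & !yte)
    tn <- sum(!pred & !yte); fn <- sum(!pred & yte)
    met <- sen_spe_bar(tp, fp, tn, fn)
    list(id = eyes[[i]]$id, pred = pred, margin = margin,
         tp = tp, fp = fp, tn = tn, fn = fn,
         sen = met[["sen"]], spe = met[["spe"]], bar = met[["bar"]],
         pca = pca, model = model)
  })
}
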