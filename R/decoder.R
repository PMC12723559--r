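#' Train an ensemble of aging-mechanism classifiers on EEG features
#'
#' Trains `n_models` multilayer perceptrons (4 inputs, two hidden layers of
#' 20 ReLU units, softmax output over the five conditions) on independent
#' random 60/10/30 train/validation/test splits. Optimization is Nadam
#' (Adam with Nesterov momentum) at learning rate 0.001 with categorical
#' cross-entropy, up to 100 epochs with early stopping after 10 epochs
#' without validation improvement; weights start from a zero-centered
#' normal. Features are standardized by training-split statistics; a
#' missing peak center frequency is imputed with the training-split median.
#'
#' @param features Numeric matrix or data frame, one row per circuit
#'   (columns e.g. offset, exponent, peak_cf, aperiodic_auc; `NA` allowed).
#' @param labels Condition label per row.
#' @param n_models Number of ensemble members / random splits.
#' @param split Train/validation/test fractions (sums to 1).
#' @param lr Learning rate.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, epochs.
#' @param hidden Hidden layer sizes.
#' @param classes Required label set; defaults to the labels present.
#' @param seed Integer seed; model m uses `seed + m`.
#'
#' @return Object of class `decoder_ensemble`: fitted members with their
#'   standardization and split metadata, overall `accuracy` per model
#'   (percent), and `per_class` accuracy matrix.
#' @export
train_decoder <- function(features, labels, n_models = 50,
                          split = c(0.6, 0.1, 0.3), lr = 0.001,
                          max_epochs = 100, patience = 10,
                          hidden = c(20, 20), classes = NULL, seed = 1) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels), abs(sum(split) - 1) < 1e-9)
  if (is.null(classes)) classes <- sort(unique(labels))
  missing_cls <- setdiff(classes, unique(labels))
  if (length(missing_cls))
    stop("missing label class: ", paste(missing_cls, collapse = ", "))
  y <- match(labels, classes)
  if (any(table(factor(labels, classes)) < 2))
    stop("need at least 2 samples per class")

  models <- vector("list", n_models)
  acc <- numeric(n_models)
  per_class <- matrix(NA_real_, n_models, length(classes),
                      dimnames = list(NULL, classes))
  for (m in seq_len(n_models)) {
    sd_m <- seed + m
    idx <- with_seed(sd_m, {
      # stratified split so every class appears in the training set
      tr <- c(); va <- c(); te <- c()
      for (k in seq_along(classes)) {
        ik <- sample(which(y == k))
        n_k <- length(ik)
        n_tr <- max(1, round(split[1] * n_k))
        n_va <- round(split[2] * n_k)
        tr <- c(tr, ik[seq_len(n_tr)])
        va <- c(va, ik[n_tr + seq_len(min(n_va, n_k - n_tr))])
        te <- c(te, setdiff(ik, c(ik[seq_len(n_tr + n_va)])))
      }
      list(tr = tr, va = va, te = te)
    })
    prep <- decoder_prep(X[idx$tr, , drop = FALSE])
    Xtr <- decoder_apply(prep, X[idx$tr, , drop = FALSE])
    Xva <- if (length(idx$va)) decoder_apply(prep, X[idx$va, , drop = FALSE])
           else Xtr
    yva <- if (length(idx$va)) y[idx$va] else y[idx$tr]
    fit <- mlp_fit(Xtr, y[idx$tr], n_classes = length(classes),
                   hidden = hidden, lr = lr, epochs = max_epochs,
                   patience = patience, X_val = Xva, y_val = yva,
                   seed = sd_m)
    models[[m]] <- list(fit = fit, prep = prep, split = idx)
    if (length(idx$te)) {
      Xte <- decoder_apply(prep, X[idx$te, , drop = FALSE])
      pred <- mlp_predict_class(fit, Xte)
      acc[m] <- 100 * mean(pred == y[idx$te])
      for (k in seq_along(classes)) {
        sel <- y[idx$te] == k
        if (any(sel)) per_class[m, k] <- 100 * mean(pred[sel] == k)
      }
    }
  }
  structure(list(models = models, classes = classes,
                 feature_names = colnames(X), accuracy = acc,
                 per_class = per_class, X = X, y = y, seed = seed),
            class = "decoder_ensemble")
}

# imputation (column median) + z-scoring parameters from a training block
decoder_prep <- function(Xtr) {
  med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  Xi <- Xtr
  for (j in seq_len(ncol(Xi))) Xi[is.na(Xi[, j]), j] <- med[j]
  ctr <- colMeans(Xi)
  scl <- apply(Xi, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(impute = med, center = ctr, scale = scl)
}

decoder_apply <- function(prep, X) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- prep$impute[j]
  sweep(sweep(X, 2, prep$center), 2, prep$scale, "/")
}

#' @export
print.decoder_ensemble <- function(x, ...) {
  cat(sprintf("Mechanism decoder ensemble: %d models, %d classes\n",
              length(x$models), length(x$classes)))
  cat(sprintf("  test accuracy: mean %.1f%%, range %.1f-%.1f%%\n",
              mean(x$accuracy), min(x$accuracy), max(x$accuracy)))
  invisible(x)
}

#' Class probabilities for a feature vector
#'
#' Averages the softmax outputs of the ensemble members (each member
#' imputes and standardizes the input with its own training statistics).
#'
#' @param model A `decoder_ensemble` (or a single member of one).
#' @param feature Numeric vector (one sample) or matrix (rows = samples)
#'   of raw, unstandardized features.
#' @return Matrix of class probabilities, rows summing to 1.
#' @export
classify <- function(model, feature) {
  if (is.null(dim(feature))) feature <- matrix(feature, nrow = 1)
  feature <- as.matrix(feature)
  storage.mode(feature) <- "double"
  members <- if (inherits(model, "decoder_ensemble")) model$models
             else list(model)
  classes <- if (inherits(model, "decoder_ensemble")) model$classes else NULL
  if (ncol(feature) != ncol(members[[1]]$fit$par$W[[1]]) &&
      nrow(members[[1]]$fit$par$W[[1]]) != ncol(feature))
    stop("feature vector has wrong length")
  P <- 0
  for (mm in members) {
    Xs <- decoder_apply(mm$prep, feature)
    P <- P + mlp_probs(mm$fit, Xs)
  }
  P <- P / length(members)
  colnames(P) <- classes
  P
}

#' Exact Shapley values for a prediction function of few features
#'
#' Enumerates all 2^d coalitions; the value of a coalition is the mean
#' prediction with the remaining features replaced by background rows.
#' Intended as the reference for the sampling approximation when the
#' feature count is small.
#'
#' @param f Prediction function taking a numeric matrix and returning one
#'   number per row.
#' @param x Numeric vector, the sample to explain.
#' @param background Matrix of background rows.
#' @return Numeric vector of per-feature Shapley values; they sum to
#'   `f(x) - mean(f(background))`.
#' @export
shapley_exact <- function(f, x, background) {
  d <- length(x)
  nb <- nrow(background)
  v <- numeric(2^d) # coalition values, bitmask-indexed
  for (mask in 0:(2^d - 1)) {
    Xb <- background
    for (j in seq_len(d)) if (bitwAnd(mask, bitwShiftL(1L, j - 1L)))
      Xb[, j] <- x[j]
    v[mask + 1] <- mean(f(Xb))
  }
  phi <- numeric(d)
  fact <- factorial(0:d)
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^d - 1)) {
      if (bitwAnd(mask, bit)) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1))) > 0)
      w <- fact[s + 1] * fact[d - s] / fact[d + 1]
      phi[j] <- phi[j] + w * (v[mask + bit + 1] - v[mask + 1])
    }
  }
  phi
}

#' Sampling (permutation) approximation of Shapley values
#'
#' Monte-Carlo estimator: random feature orderings, with the marginal
#' contribution of each feature averaged over orderings and background
#' rows.
#'
#' @inheritParams shapley_exact
#' @param n_perm Number of sampled orderings.
#' @param seed Integer seed.
#' @return Numeric vector of per-feature Shapley estimates.
#' @export
shapley_sampling <- function(f, x, background, n_perm = 200, seed = 1) {
  d <- length(x)
  with_seed(seed, {
    phi <- numeric(d)
    for (p in seq_len(n_perm)) {
      ord <- sample.int(d)
      Xb <- background
      prev <- mean(f(Xb))
      for (j in ord) {
        Xb[, j] <- x[j]
        cur <- mean(f(Xb))
        phi[j] <- phi[j] + (cur - prev)
        prev <- cur
      }
    }
    phi / n_perm
  })
}

#' Per-feature importance of the decoder via Shapley attribution
#'
#' Mean absolute Shapley value of each input feature for the predicted
#' class probability, averaged over a set of explained samples, using a
#' fixed background set drawn from the training data. With four features
#' the attribution is computed exactly (all 16 coalitions).
#'
#' @param ensemble A `decoder_ensemble`.
#' @param features Samples to explain (default: the ensemble's stored
#'   feature matrix).
#' @param n_background Background set size.
#' @param n_explain Maximum number of samples to explain.
#' @param exact Use exact enumeration (default for <= 8 features) or the
#'   sampling estimator.
#' @param seed Integer seed.
#' @return Named numeric vector of mean absolute Shapley values.
#' @export
attribute_features <- function(ensemble, features = NULL,
                               n_background = 50, n_explain = 30,
                               exact = NULL, seed = 1) {
  stopifnot(inherits(ensemble, "decoder_ensemble"))
  X <- if (is.null(features)) ensemble$X else as.matrix(features)
  if (nrow(X) == 0) stop("no samples to explain")
  d <- ncol(X)
  if (is.null(exact)) exact <- d <= 8
  with_seed(seed, {
    bg_idx <- sample.int(nrow(X), min(n_background, nrow(X)))
    ex_idx <- sample.int(nrow(X), min(n_explain, nrow(X)))
    background <- X[bg_idx, , drop = FALSE]
    # impute background NAs with the first member's statistics
    background <- decoder_apply(ensemble$models[[1]]$prep, background)
    background <- sweep(sweep(background, 2, ensemble$models[[1]]$prep$scale,
                              "*"), 2, ensemble$models[[1]]$prep$center, "+")
    total <- numeric(d)
    for (i in ex_idx) {
      x <- X[i, ]
      x[is.na(x)] <- ensemble$models[[1]]$prep$impute[is.na(x)]
      k_hat <- which.max(classify(ensemble, x))
      f <- function(M) classify(ensemble, M)[, k_hat]
      phi <- if (exact) shapley_exact(f, x, background)
             else shapley_sampling(f, x, background, seed = seed + i)
      total <- total + abs(phi)
    }
    out <- total / length(ex_idx)
    names(out) <- ensemble$feature_names
    out
  })
}
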