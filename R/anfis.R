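# Overall cognitive-impairment scoring: k-means labeling of feature
# vectors (k = 3), a Takagi-Sugeno ANFIS with Gaussian premises and linear
# consequents, hybrid training (global least squares on consequents + one
# full-batch gradient step on premises per epoch), and error statistics.

# ---- k-means labeling ------------------------------------------------------

# Squared Euclidean distance of every row of xs to each center row.
row_dist2 <- function(xs, centers) {
  d <- matrix(0, nrow(xs), nrow(centers))
  for (r in seq_len(nrow(centers))) {
    d[, r] <- rowSums(sweep(xs, 2, centers[r, ], "-")^2)
  }
  d
}

# k-means++ seeding: first center uniform, later centers sampled with
# probability proportional to squared distance from the nearest chosen one.
kmeanspp_centers <- function(xs, k) {
  n <- nrow(xs)
  idx <- sample.int(n, 1L)
  centers <- xs[idx, , drop = FALSE]
  for (j in seq_len(k - 1L)) {
    d2 <- apply(row_dist2(xs, centers), 1, min)
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    centers <- rbind(centers, xs[idx, , drop = FALSE])
  }
  centers
}

#' Cluster and label a feature table
#'
#' Z-standardizes the 13 features, clusters participants with k-means
#' (Lloyd's algorithm, k-means++ seeding, 10 restarts keeping the best
#' inertia), and assigns impairment labels 0 / 0.5 / 1 to the clusters
#' ordered by ascending mean standardized completion time plus error rate
#' (FH2 + FH3): slower search with more errors means higher impairment.
#'
#' @param features Data frame or matrix of feature vectors; a
#'   `participant_id` column is carried through if present. Columns `FH2`
#'   and `FH3` drive the label ordering (falling back to the overall
#'   feature mean if absent).
#' @param k Number of clusters (default 3).
#' @param seed Integer seed; identical seeds give identical labels.
#' @param n_restarts k-means restarts.
#' @return Object of class `etmt_dataset`: raw matrix `x`, standardized
#'   `xs`, per-feature `center`/`scale`, cluster assignment, numeric
#'   labels `y`, and per-cluster label values `cluster_labels`.
#' @export
kmeans_label <- function(features, k = 3L, seed = 1L, n_restarts = 10L) {
  ids <- NULL
  if (is.data.frame(features)) {
    if ("participant_id" %in% names(features)) {
      ids <- features$participant_id
      features <- features[, setdiff(names(features), "participant_id"),
                           drop = FALSE]
    }
    features <- as.matrix(features)
  }
  storage.mode(features) <- "double"
  if (nrow(unique(features)) < k) {
    stop_param("need at least ", k, " distinct feature vectors")
  }
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(features, 2, center, "-"), 2, scale, "/")
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      # a bad restart (empty cluster) is discarded by inertia comparison
      km <- tryCatch(
        suppressWarnings(
          stats::kmeans(xs, centers = kmeanspp_centers(xs, k),
                        iter.max = 100L, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
    }
    best
  })
  if (is.null(fit)) stop_param("k-means failed on degenerate data")
  sev_cols <- intersect(c("FH2", "FH3"), colnames(xs))
  severity <- vapply(seq_len(k), function(cl) {
    rows <- fit$cluster == cl
    if (length(sev_cols)) mean(xs[rows, sev_cols, drop = FALSE])
    else mean(xs[rows, , drop = FALSE])
  }, numeric(1))
  label_values <- if (k == 1) 0 else seq(0, 1, length.out = k)
  cluster_labels <- label_values[rank(severity, ties.method = "first")]
  structure(list(participant_id = ids, x = features, xs = xs,
                 center = center, scale = scale,
                 cluster = fit$cluster,
                 cluster_labels = cluster_labels,
                 y = cluster_labels[fit$cluster],
                 seed = seed),
            class = "etmt_dataset")
}

#' Build a labeled dataset from externally supplied targets
#'
#' Standardizes a feature matrix and attaches continuous or discrete
#' targets, for training an ANFIS on data labeled outside [kmeans_label()]
#' (e.g. simulation benchmarks).
#'
#' @param x Feature matrix.
#' @param y Numeric targets, one per row.
#' @param cluster Optional cluster assignment used for rule initialization;
#'   defaults to a single cluster.
#' @return An `etmt_dataset`.
#' @export
labeled_dataset <- function(x, y, cluster = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(length(y) == nrow(x))
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  cluster <- cluster %||% rep(1L, nrow(x))
  cluster_labels <- vapply(sort(unique(cluster)),
                           function(cl) mean(y[cluster == cl]), numeric(1))
  structure(list(participant_id = NULL, x = x, xs = xs, center = center,
                 scale = scale, cluster = as.integer(cluster),
                 cluster_labels = cluster_labels, y = as.numeric(y),
                 seed = NA_integer_),
            class = "etmt_dataset")
}

# ---- ANFIS model -----------------------------------------------------------

#' Initialize a Takagi-Sugeno ANFIS from a labeled dataset
#'
#' One rule per cluster (scatter partition): each rule's Gaussian premise
#' centers are the cluster means (in standardized space) and its widths the
#' cluster standard deviations, floored at `sigma_floor`; consequents start
#' as zero weights with the cluster's label value as intercept.
#'
#' @param dataset An `etmt_dataset` from [kmeans_label()] or
#'   [labeled_dataset()].
#' @param sigma_floor Minimum premise width.
#' @return Object of class `etmt_anfis`.
#' @export
anfis_init <- function(dataset, sigma_floor = 0.1) {
  stopifnot(inherits(dataset, "etmt_dataset"))
  clusters <- sort(unique(dataset$cluster))
  if (!length(clusters)) stop_param("dataset has no clusters")
  p <- ncol(dataset$xs)
  k <- length(clusters)
  centers <- matrix(0, k, p)
  sigmas <- matrix(sigma_floor, k, p)
  coef <- matrix(0, k, p + 1L)
  for (j in seq_len(k)) {
    rows <- dataset$cluster == clusters[j]
    if (!any(rows)) stop_param("empty cluster ", clusters[j])
    sub <- dataset$xs[rows, , drop = FALSE]
    centers[j, ] <- colMeans(sub)
    sds <- apply(sub, 2, stats::sd)
    sds[!is.finite(sds)] <- 0
    sigmas[j, ] <- pmax(sds, sigma_floor)
    coef[j, p + 1L] <- dataset$cluster_labels[j]
  }
  structure(list(n_inputs = p, n_rules = k, centers = centers,
                 sigmas = sigmas, coef = coef,
                 center_x = dataset$center, scale_x = dataset$scale,
                 feature_names = colnames(dataset$xs),
                 trained = FALSE, meta = list()),
            class = "etmt_anfis")
}

#' @export
print.etmt_anfis <- function(x, ...) {
  cat(sprintf("<etmt_anfis> %d inputs, %d rules (%strained)\n",
              x$n_inputs, x$n_rules, if (x$trained) "" else "un"))
  invisible(x)
}

# Rule firing strengths (n x k) for standardized inputs.
anfis_strengths <- function(model, xs) {
  n <- nrow(xs)
  w <- matrix(0, n, model$n_rules)
  for (r in seq_len(model$n_rules)) {
    z <- sweep(xs, 2, model$centers[r, ], "-")
    z <- sweep(z, 2, model$sigmas[r, ], "/")
    w[, r] <- exp(-0.5 * rowSums(z^2))
  }
  w
}

# Normalized strengths with the underflow fallback: when every rule's
# strength underflows to zero, the nearest-center rule takes weight 1.
anfis_norm_strengths <- function(model, xs) {
  w <- anfis_strengths(model, xs)
  tot <- rowSums(w)
  dead <- tot <= 0
  if (any(dead)) {
    nearest <- max.col(-row_dist2(xs[dead, , drop = FALSE], model$centers))
    for (i in seq_along(nearest)) {
      w[which(dead)[i], ] <- 0
      w[which(dead)[i], nearest[i]] <- 1
    }
    tot[dead] <- 1
  }
  w / tot
}

#' ANFIS forward pass
#'
#' Computes the Takagi-Sugeno output sum of normalized firing strengths
#' times rule-wise linear consequents for inputs already standardized with
#' the model's stored parameters.
#'
#' @param model An `etmt_anfis`.
#' @param x Standardized input: a vector of length `n_inputs` or a matrix
#'   with that many columns.
#' @return Numeric prediction(s).
#' @export
anfis_forward <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != model$n_inputs) {
      stop_param("input has length ", length(x), ", expected ",
                 model$n_inputs)
    }
    x <- matrix(x, 1L)
  }
  if (ncol(x) != model$n_inputs) {
    stop_param("input has ", ncol(x), " columns, expected ", model$n_inputs)
  }
  wn <- anfis_norm_strengths(model, x)
  f <- cbind(x, 1) %*% t(model$coef) # n x k rule outputs
  rowSums(wn * f)
}

#' Predict from raw (unstandardized) inputs
#'
#' @param model An `etmt_anfis`.
#' @param x Raw feature vector or matrix.
#' @return Numeric prediction(s).
#' @export
anfis_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  xs <- sweep(sweep(x, 2, model$center_x, "-"), 2, model$scale_x, "/")
  anfis_forward(model, xs)
}

#' Error statistics of predictions
#'
#' Errors are `actual - predicted`; reports the root-mean-square error, the
#' error mean, and the sample (n-1 denominator) standard deviation of the
#' errors.
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @return List `rmse`, `error_mean`, `error_std`, `n`.
#' @export
error_stats <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop_param("predicted and actual differ in length")
  }
  if (!length(predicted)) stop_param("need at least one prediction")
  e <- actual - predicted
  list(rmse = sqrt(mean(e^2)), error_mean = mean(e),
       error_std = if (length(e) > 1) stats::sd(e) else NA_real_,
       n = length(e))
}

# Stratified (by label when discrete) train/test split.
anfis_split <- function(y, train_frac, seed) {
  n <- length(y)
  levels <- unique(y)
  with_seed(seed, {
    if (length(levels) <= 5) {
      train <- integer(0)
      for (lv in levels) {
        idx <- which(y == lv)
        n_tr <- max(1L, round(length(idx) * train_frac))
        train <- c(train, sample(idx, min(n_tr, length(idx))))
      }
    } else {
      train <- sample.int(n, max(1L, round(n * train_frac)))
    }
    sort(train)
  })
}

#' Train an ANFIS with hybrid learning
#'
#' Splits the dataset into train and test partitions (label-stratified when
#' the targets are discrete), then runs `epochs` iterations of hybrid
#' learning: with premises fixed, all consequent coefficients are solved
#' globally by ridge-regularized least squares on the strength-weighted
#' design matrix; then one full-batch gradient step updates the premise
#' centers and widths against squared error.
#'
#' @param model An initialized `etmt_anfis`.
#' @param dataset The `etmt_dataset` to train on.
#' @param epochs Training epochs (0 returns the model unchanged, with
#'   statistics of the untrained model).
#' @param train_frac Fraction of samples in the training partition.
#' @param seed Split seed.
#' @param learn_rate Premise gradient step size.
#' @param ridge Least-squares regularization.
#' @return List with the trained `model`, `train_stats` and `test_stats`
#'   ([error_stats()]), the `split` indices, and the per-epoch training
#'   RMSE `history`.
#' @export
anfis_train <- function(model, dataset, epochs = 30L, train_frac = 0.75,
                        seed = 1L, learn_rate = 0.01, ridge = 1e-8) {
  stopifnot(inherits(model, "etmt_anfis"), inherits(dataset, "etmt_dataset"))
  if (train_frac <= 0 || train_frac >= 1) {
    stop_param("train_frac must be in (0, 1)")
  }
  n <- nrow(dataset$xs)
  if (n < 8) stop_param("dataset too small to split (need >= 8 samples)")
  train <- anfis_split(dataset$y, train_frac, seed)
  test <- setdiff(seq_len(n), train)
  if (!length(train) || !length(test)) stop_param("degenerate split")
  discrete <- length(unique(dataset$y)) <= 5
  if (discrete &&
      (length(unique(dataset$y[train])) < 2 ||
         length(unique(dataset$y[test])) < 2)) {
    stop_param("degenerate split: a partition is single-label")
  }
  xtr <- dataset$xs[train, , drop = FALSE]
  ytr <- dataset$y[train]
  p <- model$n_inputs
  k <- model$n_rules
  history <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    # (i) global least squares on consequents, premises fixed
    wn <- anfis_norm_strengths(model, xtr)
    design <- do.call(cbind, lapply(seq_len(k), function(r) {
      cbind(wn[, r] * xtr, wn[, r])
    }))
    gram <- crossprod(design) + ridge * diag(ncol(design))
    theta <- solve(gram, crossprod(design, ytr))
    model$coef <- matrix(theta, k, p + 1L, byrow = TRUE)
    # (ii) one full-batch gradient step on premise centers and widths
    w <- anfis_strengths(model, xtr)
    tot <- rowSums(w)
    live <- tot > 0
    if (any(live)) {
      xl <- xtr[live, , drop = FALSE]
      wl <- w[live, , drop = FALSE]
      totl <- tot[live]
      f <- cbind(xl, 1) %*% t(model$coef)
      pred <- rowSums((wl / totl) * f)
      err <- pred - ytr[live]
      m <- length(err)
      grad_c <- matrix(0, k, p)
      grad_s <- matrix(0, k, p)
      for (r in seq_len(k)) {
        # dE/dw_r = (2/m) err * (f_r - pred) / tot
        common <- (2 / m) * err * (f[, r] - pred) / totl * wl[, r]
        zc <- sweep(xl, 2, model$centers[r, ], "-")
        grad_c[r, ] <- colSums(common * sweep(zc, 2,
                                              model$sigmas[r, ]^2, "/"))
        grad_s[r, ] <- colSums(common * sweep(zc^2, 2,
                                              model$sigmas[r, ]^3, "/"))
      }
      model$centers <- model$centers - learn_rate * grad_c
      model$sigmas <- pmax(model$sigmas - learn_rate * grad_s, 1e-3)
    }
    history[epoch] <- sqrt(mean((anfis_forward(model, xtr) - ytr)^2))
  }
  model$trained <- epochs > 0
  model$meta <- list(epochs = epochs, train_frac = train_frac, seed = seed,
                     learn_rate = learn_rate, ridge = ridge,
                     n_train = length(train), n_test = length(test))
  list(model = model,
       train_stats = error_stats(anfis_forward(model, xtr), ytr),
       test_stats = error_stats(
         anfis_forward(model, dataset$xs[test, , drop = FALSE]),
         dataset$y[test]),
       split = list(train = train, test = test),
       history = history)
}

#' Score one participant with a trained ANFIS
#'
#' Standardizes the 13-entry feature vector with the model's stored
#' parameters, runs the forward pass, clips the cognitive-impairment score
#' to \[0, 1\] and bands it (thirds of the unit interval).
#'
#' @param model A trained `etmt_anfis`.
#' @param features Numeric vector of the 13 features (named or in FL1..FH4
#'   order).
#' @return List `score` (in \[0, 1\]), `band`, and the unclipped `raw`.
#' @export
score_participant <- function(model, features) {
  if (!isTRUE(model$trained)) stop_param("model is not trained")
  if (!is.null(names(features)) && !is.null(model$feature_names)) {
    features <- features[model$feature_names]
  }
  raw <- anfis_predict(model, as.numeric(features))
  score <- min(max(raw, 0), 1)
  list(score = score, band = score_band(score), raw = raw)
}

#' Write or read an ANFIS model as JSON
#'
#' Full-precision serialization of the standardization parameters, premise
#' Gaussians, consequent coefficients and metadata; a write/read round trip
#' reproduces the model exactly.
#'
#' @param model An `etmt_anfis`.
#' @param path File path.
#' @return `read_anfis_model` returns the model; the writer returns `path`
#'   invisibly.
#' @export
write_anfis_model <- function(model, path) {
  payload <- list(n_inputs = model$n_inputs, n_rules = model$n_rules,
                  centers = model$centers, sigmas = model$sigmas,
                  coef = model$coef, center_x = as.list(model$center_x),
                  scale_x = as.list(model$scale_x),
                  feature_names = model$feature_names,
                  trained = model$trained, meta = model$meta)
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              matrix = "rowmajor", pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_anfis_model
#' @export
read_anfis_model <- function(path) {
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  structure(list(n_inputs = p$n_inputs, n_rules = p$n_rules,
                 centers = as.matrix(p$centers),
                 sigmas = as.matrix(p$sigmas),
                 coef = as.matrix(p$coef),
                 center_x = unlist(p$center_x),
                 scale_x = unlist(p$scale_x),
                 feature_names = p$feature_names,
                 trained = isTRUE(p$trained),
                 meta = as.list(p$meta)),
            class = "etmt_anfis")
}
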