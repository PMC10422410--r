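# Shared fixtures and independent oracles for the test suite. Every
# oracle is implemented independently of the package's own algorithms.

# ---- fixture builders ------------------------------------------------------

# Gaze samples at a fixed 60 Hz grid.
make_samples <- function(x, y, rate_hz = 60, t0 = 0, valid = TRUE) {
  n <- length(x)
  data.frame(timestamp_ms = t0 + (seq_len(n) - 1) * 1000 / rate_hz,
             x_px = x, y_px = y, pupil_mm = 3.5,
             valid = rep_len(valid, n))
}

make_fix <- function(onset, duration, cx, cy) {
  data.frame(onset_ms = onset, duration_ms = duration, cx_px = cx,
             cy_px = cy)
}

# Fixation table visiting the given AOI labels of a layout in order.
fixations_visiting <- function(layout, labels, duration = 200, gap = 100) {
  idx <- match(labels, layout$aois$label)
  onset <- (seq_along(labels) - 1) * (duration + gap)
  make_fix(onset, duration, layout$aois$cx[idx], layout$aois$cy[idx])
}

# ---- Levenshtein oracle: plain recursion with memoization ------------------

lev_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1,
               rec(i - 1, j - 1) + (a[i] != b[j]))
    memo[[key]] <- val
    val
  }
  as.integer(rec(length(a), length(b)))
}

# ---- inattentional-blindness oracle ----------------------------------------

# Same skip-after-match scan, but the earlier-occurrence search is an
# exhaustive scan over every length with no early termination, coded
# separately from the package.
ib_oracle <- function(sp, min_len = 2) {
  sp <- unname(as.character(sp))
  n <- length(sp)
  count <- 0
  i <- 1
  while (i <= n) {
    best <- 0
    for (len in seq_len(n - i + 1)) {
      if (len < min_len) next
      pat <- sp[i:(i + len - 1)]
      found <- FALSE
      for (j in seq_len(max(0, i - len))) {
        if (identical(sp[j:(j + len - 1)], pat)) {
          found <- TRUE
          break
        }
      }
      if (found && len > best) best <- len
    }
    if (best > 0) {
      count <- count + 1
      i <- i + best
    } else {
      i <- i + 1
    }
  }
  as.integer(count)
}

# ---- centroid oracle -------------------------------------------------------

# Centroid of an aggregated Mamdani shape by fine-grid numeric integration
# evaluated directly from set definitions.
centroid_oracle <- function(fis, x1, x2, step = 1e-4) {
  tm <- function(bp, x) {
    a <- bp[[1]]; b <- bp[[2]]; cc <- bp[[3]]; d <- bp[[4]]
    ifelse(x >= b & x <= cc, 1,
           ifelse(x > a & x < b, (x - a) / (b - a),
                  ifelse(x > cc & x < d, (d - x) / (d - cc), 0)))
  }
  grid <- seq(fis$output$universe[1], fis$output$universe[2], by = step)
  agg <- numeric(length(grid))
  for (r in seq_len(nrow(fis$rules))) {
    w <- min(tm(fis$input1$sets[[fis$rules$in1[r]]], x1),
             tm(fis$input2$sets[[fis$rules$in2[r]]], x2))
    agg <- pmax(agg, pmin(w, tm(fis$output$sets[[fis$rules$out[r]]], grid)))
  }
  if (sum(agg) == 0) return(mean(fis$output$universe))
  sum(grid * agg) / sum(agg)
}

# ---- closed-form Takagi-Sugeno forward oracle ------------------------------

ts_forward_oracle <- function(centers, sigmas, coef, x) {
  k <- nrow(centers)
  p <- ncol(centers)
  w <- vapply(seq_len(k), function(r) {
    prod(exp(-(x - centers[r, ])^2 / (2 * sigmas[r, ]^2)))
  }, numeric(1))
  f <- vapply(seq_len(k), function(r) {
    sum(coef[r, seq_len(p)] * x) + coef[r, p + 1]
  }, numeric(1))
  sum(w / sum(w) * f)
}

random_anfis <- function(p = 13, k = 3) {
  structure(list(n_inputs = p, n_rules = k,
                 centers = matrix(stats::rnorm(k * p), k),
                 sigmas = matrix(stats::runif(k * p, 0.3, 2), k),
                 coef = matrix(stats::rnorm(k * (p + 1)), k),
                 center_x = rep(0, p), scale_x = rep(1, p),
                 feature_names = NULL, trained = TRUE, meta = list()),
            class = "etmt_anfis")
}

# ---- Takagi-Sugeno recovery benchmark --------------------------------------

# Known 2-input, 2-rule generator: rule centers (-1,-1) and (1,1), widths
# 0.6, consequents f1 = 0.5 + x1 - 0.5 x2 and f2 = -0.3 + 0.2 x1 + 0.8 x2;
# inputs drawn as Gaussian blobs (sd 0.6) around the rule centers, additive
# observation noise sd 0.01. Returns inputs, targets and the generating
# rule of each sample.
ts2_benchmark <- function(n = 200, seed = 1, noise_sd = 0.01) {
  set.seed(seed)
  cl <- rep(1:2, length.out = n)
  centers <- rbind(c(-1, -1), c(1, 1))
  x <- centers[cl, ] + matrix(stats::rnorm(2 * n, 0, 0.6), n)
  w1 <- exp(-rowSums(sweep(x, 2, centers[1, ])^2) / (2 * 0.6^2))
  w2 <- exp(-rowSums(sweep(x, 2, centers[2, ])^2) / (2 * 0.6^2))
  f1 <- 0.5 + 1.0 * x[, 1] - 0.5 * x[, 2]
  f2 <- -0.3 + 0.2 * x[, 1] + 0.8 * x[, 2]
  y <- (w1 * f1 + w2 * f2) / (w1 + w2) + stats::rnorm(n, 0, noise_sd)
  list(x = x, y = y, cl = cl)
}

# ---- adjusted Rand index ---------------------------------------------------

ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  expect <- si * sj / comb2(sum(tab))
  (sij - expect) / ((si + sj) / 2 - expect)
}

# Shared small layout set (deterministic), reused across files.
test_layouts <- function(seed = 42) make_layout_set(seed = seed)
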