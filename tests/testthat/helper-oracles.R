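# Independent reference implementations used as oracles: an exhaustive-search
# CART (plain R, quadratic per node), a direct cascade-convolution mDWT, and
# a brute-force divergence-gain scan.  These deliberately share no code with
# the package internals.

# --- exhaustive CART oracle -------------------------------------------------

oracle_cart <- function(X, y, classes) {
  X <- as.matrix(X)
  K <- length(classes)
  yi <- match(y, classes)
  grow <- function(rows) {
    cnt <- tabulate(yi[rows], K)
    n <- length(rows)
    if (sum(cnt > 0) <= 1 || n < 2) {
      return(list(leaf = TRUE, counts = cnt))
    }
    parent_sq <- sum(cnt^2) / n
    best <- NULL
    for (f in seq_len(ncol(X))) {
      xo <- sort(X[rows, f])
      for (i in seq_len(n - 1)) {
        if (xo[i] == xo[i + 1]) next
        thr <- xo[i] + 0.5 * (xo[i + 1] - xo[i])
        if (thr <= xo[i]) thr <- xo[i]
        left <- X[rows, f] <= thr
        cl <- tabulate(yi[rows][left], K)
        score <- sum(cl^2) / sum(left) + sum((cnt - cl)^2) / (n - sum(left))
        if (is.null(best) || score > best$score + 1e-12) {
          best <- list(f = f, thr = thr, score = score)
        }
      }
    }
    if (is.null(best) || best$score <= parent_sq + 1e-9) {
      return(list(leaf = TRUE, counts = cnt))
    }
    left <- rows[X[rows, best$f] <= best$thr]
    right <- setdiff(rows, left)
    list(leaf = FALSE, f = best$f, thr = best$thr, counts = cnt,
         left = grow(left), right = grow(right))
  }
  structure(list(root = grow(seq_len(nrow(X))), classes = classes),
            class = "oracle_cart")
}

oracle_cart_predict <- function(model, X) {
  X <- as.matrix(X)
  one <- function(node, x) {
    while (!node$leaf) {
      node <- if (x[node$f] <= node$thr) node$left else node$right
    }
    model$classes[which.max(node$counts)]
  }
  vapply(seq_len(nrow(X)), function(i) one(model$root, X[i, ]),
         model$classes[1])
}

# Random dataset with integer-grid features (duplicates force impure leaves).
random_cart_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(20:200, 1)
  d <- sample(1:5, 1)
  K <- sample(2:4, 1)
  X <- matrix(sample(0:6, n * d, replace = TRUE), n, d)
  y <- sample(0:(K - 1), n, replace = TRUE)
  # add label-feature association so trees are non-trivial
  y[X[, 1] >= 4] <- (y[X[, 1] >= 4] + 1) %% K
  list(X = X, y = y, classes = 0:(K - 1))
}

# --- direct cascade mDWT oracle --------------------------------------------

oracle_mdwt_channel <- function(x, lo, hi, levels) {
  out <- numeric(levels + 1)
  cur <- x
  L <- length(lo)
  for (lev in seq_len(levels)) {
    m <- length(cur)
    na <- ceiling(m / 2)
    a <- numeric(na)
    dsum <- 0
    for (k in 0:(na - 1)) {
      idx <- ((2 * k + 0:(L - 1)) %% m) + 1
      a[k + 1] <- sum(lo * cur[idx])
      dsum <- dsum + abs(sum(hi * cur[idx]))
    }
    out[lev] <- dsum
    cur <- a
  }
  out[levels + 1] <- sum(abs(cur))
  out
}

# --- brute-force DG oracle --------------------------------------------------

oracle_jsd2 <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) sum(ifelse(a > 0, a * log2(a / m), 0))
  min(max(0.5 * term(p) + 0.5 * term(q), 0), 1)
}

oracle_dg_scan <- function(values, labels, K, QL, QR) {
  o <- order(values)
  v <- values[o]
  l <- labels[o]
  n <- length(v)
  cand <- c()
  dg <- c()
  ig <- c()
  tot <- tabulate(l + 1, K)
  parent_imp <- 1 - sum((tot / n)^2)
  for (i in seq_len(n - 1)) {
    if (v[i] == v[i + 1]) next
    thr <- v[i] + 0.5 * (v[i + 1] - v[i])
    if (thr <= v[i]) thr <- v[i]
    left <- l[v <= thr]
    nl <- length(left)
    cl <- tabulate(left + 1, K)
    cr <- tot - cl
    impl <- 1 - sum((cl / nl)^2)
    impr <- 1 - sum((cr / (n - nl))^2)
    cand <- c(cand, thr)
    ig <- c(ig, parent_imp - nl / n * impl - (n - nl) / n * impr)
    dg <- c(dg, 1 - nl / n * oracle_jsd2(QL, cl / nl) -
              (n - nl) / n * oracle_jsd2(QR, cr / (n - nl)))
  }
  list(cand = cand, ig = ig, dg = dg)
}

# --- small fast generator configs ------------------------------------------

tiny_config <- function(..., seed = 1) {
  args <- list(n_subjects = 2, n_sessions = 1, n_gestures = 3,
               n_repetitions = 6, n_channels = 8, fs = 1000,
               movement_s = 1, rest_s = 0.5, ramp_s = 0.2, seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(generator_config, args)
}

# forest training error on its own training data
forest_error <- function(forest, X, y) {
  mean(predict(forest, X) != y)
}

# subset a feature object to windows of the given repetitions
features_at_rep <- function(f, reps) {
  emgadapt:::features_subset(f, which(f$repetition %in% reps))
}
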