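# Independent oracles, coded directly from the defining formulas and kept
# free of the package's internal computation paths.

# Power mean by the defining formula; limits handled by their closed forms.
oracle_power_mean <- function(x, p) {
  if (p == -Inf) {
    return(min(x))
  }
  if (p == Inf) {
    return(max(x))
  }
  if (p <= 0 && any(x == 0)) {
    return(0)
  }
  if (p == 0) {
    return(prod(x^(1 / length(x))))
  }
  (sum(x^p) / length(x))^(1 / p)
}

# Direct per-object evaluation of the generalized silhouette: loops over
# objects and clusters, no vectorized shortcuts shared with the package.
oracle_silhouette <- function(D, labels, p) {
  n <- nrow(D)
  lev <- sort(unique(labels))
  out <- data.frame(a = numeric(n), b = numeric(n), s = numeric(n))
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    cs <- vapply(
      lev[lev != labels[i]],
      function(C) oracle_power_mean(D[i, which(labels == C)], p),
      numeric(1)
    )
    b <- min(cs)
    if (length(own) == 0L) {
      out$a[i] <- 0
      out$b[i] <- b
      out$s[i] <- 0
    } else {
      a <- oracle_power_mean(D[i, own], p)
      out$a[i] <- a
      out$b[i] <- b
      out$s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
  }
  out
}

# Random symmetric dissimilarity matrix with zero diagonal.
random_diss <- function(n) {
  M <- matrix(stats::runif(n * n, 0.05, 2), n, n)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  D
}

# Random Gaussian-blob dataset with k labelled groups (labels need not match
# the geometry; they just induce a valid partition with every label present).
random_labelled_points <- function(n, k) {
  centers <- matrix(stats::runif(2 * k, 0, 8), k, 2)
  lab <- sample(rep(seq_len(k), length.out = n))
  coords <- centers[lab, ] + matrix(stats::rnorm(2 * n, 0, 0.8), n, 2)
  list(coords = coords, labels = lab)
}

# All partitions of n objects into exactly two nonempty clusters, as a matrix
# of 0/1 label rows (object 1 fixed to cluster 0 to skip label swaps).
all_bipartitions <- function(n) {
  m <- 2^(n - 1) - 1
  t(vapply(
    seq_len(m),
    function(code) c(0L, as.integer(intToBits(code)[seq_len(n - 1)])),
    integer(n)
  ))
}

# Minimum-spanning-tree edge weights by brute-force Prim's algorithm.
oracle_mst_weights <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  w <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    sub <- D[in_tree, !in_tree, drop = FALSE]
    w[step] <- min(sub)
    j <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
    in_tree[j] <- TRUE
  }
  sort(w)
}
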