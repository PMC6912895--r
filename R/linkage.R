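#' Agglomerative hierarchical clustering via Lance-Williams updates
#'
#' Builds the full merge tree for a dissimilarity matrix with one of four
#' linkage rules: `"single"`, `"average"` (group average, UPGMA),
#' `"complete"`, or `"flexible_beta"` (the classic Lance-Williams flexible
#' rule with \eqn{\alpha_i = \alpha_j = (1-\beta)/2}, \eqn{\gamma = 0};
#' cluster sizes do not enter the weights). The stored-matrix algorithm merges
#' the pair with the smallest current dissimilarity at every step and updates
#' the matrix with the Lance-Williams recurrence; ties are broken
#' deterministically by the smallest pair of cluster slot indices.
#'
#' Merge heights are monotone nondecreasing for single, average and complete
#' linkage. For the flexible rule, `beta = -0.25` sits exactly on the boundary
#' \eqn{\alpha_i + \alpha_j + \beta = 1} of the classical monotonicity
#' condition; heights are retained as computed and only the nesting of cuts is
#' guaranteed.
#'
#' @param x Coordinates (data frame or matrix; Euclidean distances are
#'   computed), a [stats::dist] object, or a full square symmetric
#'   dissimilarity matrix with zero diagonal.
#' @param method Linkage rule, one of `"single"`, `"average"`, `"complete"`,
#'   `"flexible_beta"`.
#' @param beta Flexible-rule parameter in `(-1, 1)`; used only by
#'   `"flexible_beta"`. The conventional space-conserving default is `-0.25`.
#'
#' @return A `merge_tree` object: a list with `merge` (an `(n-1) x 2` matrix
#'   in the standard linkage layout, negative entries = leaves, positive =
#'   earlier merges), `height`, `n`, `method` and `beta`. Convert with
#'   [as.hclust()] for dendrogram tooling, cut with [cut_tree()], or export
#'   with [tidy()].
#'
#' @examples
#' pts <- data.frame(x = c(0, 1, 5), y = 0)
#' tr <- agglomerate(pts, "single")
#' tidy(tr)
#' cut_tree(tr, 2)
#' @export
agglomerate <- function(x,
                        method = c("single", "average", "complete", "flexible_beta"),
                        beta = -0.25) {
  method <- match.arg(method)
  if (method == "flexible_beta" && (beta <= -1 || beta >= 1)) {
    stop("`beta` must lie in (-1, 1).", call. = FALSE)
  }
  D <- as_diss_matrix(x)
  if (nrow(D) < 2L) stop("need at least two objects.", call. = FALSE)
  res <- .lw_agglomerate(D, method, beta)
  structure(
    list(
      merge = res$merge, height = as.numeric(res$height),
      n = nrow(D), method = method,
      beta = if (method == "flexible_beta") beta else NA_real_
    ),
    class = "merge_tree"
  )
}

# A square numeric matrix with a zero diagonal or exact symmetry is taken to
# be a dissimilarity matrix (and then fully validated); anything else is
# treated as a coordinate table.
looks_like_diss <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x) &&
    (all(diag(x) == 0) ||
      isTRUE(all.equal(unname(x), unname(t(x)), tolerance = 1e-12)))
}

# Coerce any accepted geometry input to a validated full dissimilarity matrix.
as_diss_matrix <- function(x) {
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else if (looks_like_diss(x)) {
    D <- x
  } else {
    m <- as.matrix(as.data.frame(x))
    if (!is.numeric(m)) stop("coordinates must be numeric.", call. = FALSE)
    D <- as.matrix(stats::dist(m))
  }
  validate_dissimilarity(unname(D))
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last `k - 1` merges of the tree and labels the resulting groups
#' `1..k` in order of first member appearance (the same labelling convention
#' as [stats::cutree()]).
#'
#' @param tree A `merge_tree` from [agglomerate()].
#' @param k Number of clusters, between 1 and the number of objects.
#' @return An integer vector of cluster labels, one per object.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "merge_tree"))
  n <- tree$n
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n) {
    stop("`k` must be a single integer in [1, ", n, "].", call. = FALSE)
  }
  comp <- seq_len(n) # component id per leaf
  members <- vector("list", n - 1L)
  n_steps <- n - k
  for (s in seq_len(n_steps)) {
    left <- tree$merge[s, 1]
    right <- tree$merge[s, 2]
    lm <- if (left < 0) -left else members[[left]]
    rm_ <- if (right < 0) -right else members[[right]]
    members[[s]] <- c(lm, rm_)
    comp[members[[s]]] <- n + s
  }
  match(comp, unique(comp))
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf(
    "# Agglomerative merge tree: n = %d, method = %s%s\n",
    x$n, x$method,
    if (!is.na(x$beta)) sprintf(" (beta = %g)", x$beta) else ""
  ))
  cat(sprintf(
    "# heights: %.4g .. %.4g over %d merges\n",
    min(x$height), max(x$height), x$n - 1L
  ))
  invisible(x)
}

#' Merge table of a tree in tidy form
#'
#' One row per merge with the standard linkage-matrix encoding: negative
#' entries are leaves, positive entries earlier merge steps.
#'
#' @param x A `merge_tree`.
#' @param ... Ignored.
#' @return A tibble with columns `step`, `left`, `right`, `height`.
#' @export
tidy.merge_tree <- function(x, ...) {
  tibble::tibble(
    step = seq_len(x$n - 1L),
    left = x$merge[, 1],
    right = x$merge[, 2],
    height = x$height
  )
}

#' @export
as.hclust.merge_tree <- function(x, ...) {
  structure(
    list(
      merge = x$merge,
      height = x$height,
      order = tree_leaf_order(x$merge),
      labels = NULL,
      method = x$method,
      call = match.call(),
      dist.method = NULL
    ),
    class = "hclust"
  )
}

# Depth-first leaf ordering so the tree plots without crossing branches.
tree_leaf_order <- function(merge) {
  stack <- nrow(merge)
  out <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd < 0) {
      out <- c(out, -nd)
    } else {
      stack <- c(stack, merge[nd, 2], merge[nd, 1])
    }
  }
  out
}
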