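#' Seeded two-dimensional benchmark point patterns
#'
#' Generates the two-cluster benchmark archetypes used throughout the
#' package's evaluation, each a 2-D point set of 100 objects (1,000 for
#' `"random_big"`) with a priori cluster labels. The archetypes isolate
#' different combinations of separation, compactness and connectedness:
#'
#' * `"random_split"` — uniform square with no cluster structure, labelled by
#'   a vertical bisector (low separation, low compactness).
#' * `"transitional"` — two Gaussian blobs with a sparse bridge of points
#'   between them, bridge points labelled by the nearest blob centre
#'   (moderate separation and compactness).
#' * `"distinct"` — two widely separated compact Gaussian blobs (high
#'   separation, high compactness).
#' * `"offset_pairs_same"` — two strongly overlapping blobs in which every
#'   point is duplicated with a tiny offset and the duplicate carries the
#'   *same* label (low separation, high compactness, high local
#'   connectedness).
#' * `"offset_pairs_diff"` — identical coordinates for the same seed, but the
#'   duplicate carries the *other* label (low local connectedness); the pair
#'   of patterns isolates the connectedness criterion exactly.
#' * `"parallel"` — two long thin horizontal strips separated by more than
#'   their widths (high separation, low compactness).
#' * `"unequal"` — well-separated blobs of 20 and 80 points, the small one
#'   tighter (high separation, high compactness, unequal size).
#' * `"concentric"` — a tight central blob inside a surrounding annulus whose
#'   nearest-neighbour spacing along the ring is smaller than the ring-core
#'   gap (high separation, very different compactness).
#' * `"random_big"` — a 1,000-point uniform pattern, labelled by a vertical
#'   bisector; used for comparing clustering methods in the absence of true
#'   structure.
#'
#' All randomness flows from the explicit `seed` via an isolated RNG scope;
#' the caller's random-number state is untouched and the same call always
#' returns bit-identical coordinates.
#'
#' @param pattern Archetype name (see above).
#' @param seed Integer seed; required, no hidden global state.
#' @param n Number of points; defaults to 100 (1,000 for `"random_big"`).
#'   Archetype shapes scale their per-cluster counts proportionally.
#' @param offset Duplicate-pair offset magnitude for the `offset_pairs_*`
#'   patterns, as a fraction of the blob standard deviation. Default 0.01.
#'
#' @return A tibble of class `point_pattern` with columns `x`, `y`, `cluster`
#'   (integer labels) and attributes `pattern` and `seed`.
#' @examples
#' generate_pattern("concentric", seed = 1)
#' @export
generate_pattern <- function(pattern, seed, n = NULL, offset = 0.01) {
  pattern <- match.arg(pattern, pattern_ids())
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (is.null(n)) n <- if (pattern == "random_big") 1000L else 100L
  n <- as.integer(n)
  if (n < 4L) stop("`n` must be at least 4.", call. = FALSE)
  df <- withr::with_seed(seed, pattern_build(pattern, n, offset))
  structure(
    tibble::as_tibble(df),
    class = c("point_pattern", class(tibble::tibble())),
    pattern = pattern, seed = seed
  )
}

#' @rdname generate_pattern
#' @export
pattern_ids <- function() {
  c(
    "random_split", "transitional", "distinct", "offset_pairs_same",
    "offset_pairs_diff", "parallel", "unequal", "concentric", "random_big"
  )
}

pattern_build <- function(pattern, n, offset) {
  half <- n %/% 2L
  switch(pattern,
    random_split = ,
    random_big = {
      x <- stats::runif(n)
      y <- stats::runif(n)
      data.frame(x = x, y = y, cluster = ifelse(x < 0.5, 1L, 2L))
    },
    transitional = {
      n_bridge <- max(2L, round(0.08 * n))
      n_blob <- n - n_bridge
      n1 <- n_blob %/% 2L
      n2 <- n_blob - n1
      cx <- c(0, 4)
      x <- c(
        stats::rnorm(n1, cx[1], 0.5), stats::rnorm(n2, cx[2], 0.5),
        stats::runif(n_bridge, 0.9, 3.1)
      )
      y <- c(
        stats::rnorm(n_blob, 0, 0.5),
        stats::rnorm(n_bridge, 0, 0.15)
      )
      data.frame(x = x, y = y, cluster = ifelse(abs(x - cx[1]) < abs(x - cx[2]), 1L, 2L))
    },
    distinct = {
      data.frame(
        x = c(stats::rnorm(half, 0, 0.3), stats::rnorm(n - half, 6, 0.3)),
        y = c(stats::rnorm(half, 0, 0.3), stats::rnorm(n - half, 6, 0.3)),
        cluster = rep(1:2, c(half, n - half))
      )
    },
    offset_pairs_same = offset_pairs(n, offset, flip = FALSE),
    offset_pairs_diff = offset_pairs(n, offset, flip = TRUE),
    parallel = {
      data.frame(
        x = stats::runif(n, 0, 10),
        y = c(stats::runif(half, 0, 0.5), stats::runif(n - half, 2, 2.5)),
        cluster = rep(1:2, c(half, n - half))
      )
    },
    unequal = {
      n1 <- max(2L, round(0.2 * n))
      n2 <- n - n1
      data.frame(
        x = c(stats::rnorm(n1, 0, 0.25), stats::rnorm(n2, 5, 1)),
        y = c(stats::rnorm(n1, 0, 0.25), stats::rnorm(n2, 0, 1)),
        cluster = rep(1:2, c(n1, n2))
      )
    },
    concentric = {
      n_ring <- n - half
      theta <- 2 * pi * (seq_len(n_ring) - 1) / n_ring +
        stats::runif(n_ring, -0.2, 0.2) * 2 * pi / n_ring
      r <- stats::rnorm(n_ring, 1, 0.02)
      data.frame(
        x = c(stats::rnorm(half, 0, 0.1), r * cos(theta)),
        y = c(stats::rnorm(half, 0, 0.1), r * sin(theta)),
        cluster = rep(1:2, c(half, n_ring))
      )
    }
  )
}

# Shared geometry for the two offset-pair archetypes: base points from two
# strongly overlapping unit-sd blobs, each duplicated at a small random
# offset. Coordinates depend only on (n, offset) and the RNG state, so the
# "same" and "diff" variants coincide point-for-point at equal seeds.
offset_pairs <- function(n, offset, flip) {
  n_base <- n %/% 2L
  n1 <- n_base %/% 2L
  base <- data.frame(
    x = c(stats::rnorm(n1, 0, 1), stats::rnorm(n_base - n1, 1.5, 1)),
    y = stats::rnorm(n_base, 0, 1),
    cluster = rep(1:2, c(n1, n_base - n1))
  )
  ang <- stats::runif(n_base, 0, 2 * pi)
  dup <- data.frame(
    x = base$x + offset * cos(ang),
    y = base$y + offset * sin(ang),
    cluster = if (flip) 3L - base$cluster else base$cluster
  )
  out <- rbind(base, dup)
  out$cluster <- as.integer(out$cluster)
  out
}

#' Standardized two-variable Iris fixture
#'
#' The canonical 150-flower Fisher/Anderson Iris measurements restricted to
#' sepal length and petal length, each standardized to mean 0 and standard
#' deviation 1 (n - 1 denominator), with the three species (50 flowers each)
#' as the a priori partition. This is the worked real-data example for the
#' generalized silhouette: *I. setosa* is distinctly separated while
#' *I. versicolor* and *I. virginica* grade into each other.
#'
#' @return A tibble of class `point_pattern` with columns `sepal_length`,
#'   `petal_length` (standardized) and `cluster` (the species factor).
#' @examples
#' iris_fixture()
#' @export
iris_fixture <- function() {
  z <- scale(as.matrix(datasets::iris[, c("Sepal.Length", "Petal.Length")]))
  out <- tibble::tibble(
    sepal_length = as.numeric(z[, 1]),
    petal_length = as.numeric(z[, 2]),
    cluster = datasets::iris$Species
  )
  structure(
    out,
    class = c("point_pattern", class(tibble::tibble())),
    pattern = "iris", seed = NA_integer_
  )
}
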