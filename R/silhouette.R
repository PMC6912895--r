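#' Generalized silhouette widths
#'
#' Computes per-object silhouette widths in which the within- and
#' between-cluster average distances are generalized means of exponent `p`
#' ([power_mean()]). For a focal object `i` in cluster `A`,
#' `a(i)` is the generalized mean of the distances from `i` to the other
#' members of `A`, `c(i, C)` the generalized mean of the distances from `i` to
#' all members of another cluster `C`, `b(i) = min` over `C != A` of `c(i, C)`,
#' and
#' \deqn{s(i) = \frac{b(i) - a(i)}{\max(a(i), b(i))}.}
#' The classic silhouette of Rousseeuw is the special case `p = 1`; `p = -Inf`
#' scores connectedness (nearest-neighbor logic, tolerant of elongated or
#' irregular clusters), `p = +Inf` the strictest compactness.
#'
#' Conventions: an object alone in its cluster receives `s = 0` (its `a` is
#' recorded as 0); an object with `a = b = 0` (duplicates in two clusters)
#' receives `s = 0`; when several clusters tie for `b(i)`, the neighbor with
#' the smallest cluster label under the canonical (sorted) ordering is
#' reported. `s(i)` always lies in `[-1, 1]` and is invariant to rescaling all
#' distances by a positive constant.
#'
#' @param x The geometry: a data frame or matrix of numeric coordinates
#'   (Euclidean distances are computed), a [stats::dist] object, or a full
#'   square symmetric dissimilarity matrix with zero diagonal.
#' @param labels Cluster assignment: a vector with one label per object, or,
#'   when `x` is a data frame, the (possibly unquoted) name of one of its
#'   columns. At least two distinct clusters are required. When a column of
#'   `x` is named, the remaining columns are used as coordinates.
#' @param p Power-mean exponent (extended real; `"-inf"`/`"inf"` tokens
#'   accepted). Default 1, the classic silhouette.
#'
#' @return A tibble of class `gen_silhouette` with one row per object and
#'   columns `object` (identifier), `cluster`, `neighbor` (the cluster
#'   attaining `b`), `a`, `b`, `s`, and `p`. The exponent, object count and
#'   cluster count are also carried as attributes `p`, `n` and `k`.
#'
#' @seealso [silhouette_summary()] for MSW/MR, [silhouette_profile()] for a
#'   sweep over a grid of exponents, [autoplot.gen_silhouette()] for plotting.
#' @examples
#' pts <- data.frame(x = c(0, 1, 10, 11), y = 0, grp = c(1, 1, 2, 2))
#' gen_silhouette(pts, grp, p = 1)
#' gen_silhouette(pts, grp, p = -Inf)
#' @export
gen_silhouette <- function(x, labels, p = 1) {
  p <- parse_p(p)
  geom <- resolve_geometry(x, rlang::enquo(labels))
  core <- sil_core(geom$D, geom$labels, p)
  new_gen_silhouette(core, geom$ids, p)
}

new_gen_silhouette <- function(core, ids, p) {
  out <- tibble::tibble(
    object = ids,
    cluster = core$own,
    neighbor = core$neighbor,
    a = core$a,
    b = core$b,
    s = core$s,
    p = p
  )
  structure(out,
    class = c("gen_silhouette", class(out)),
    p = p, n = nrow(out), k = core$k
  )
}

# Turn the user-facing geometry argument into a full dissimilarity matrix plus
# a label vector. `labels_quo` may reference a column of a data-frame `x`.
resolve_geometry <- function(x, labels_quo) {
  labels <- NULL
  ids <- NULL
  if (inherits(x, "dist") || looks_like_diss(x)) {
    D <- as_diss_matrix(x)
  } else {
    df <- as.data.frame(x)
    lab_try <- try(rlang::eval_tidy(labels_quo, data = df), silent = TRUE)
    if (!inherits(lab_try, "try-error") && !is.null(lab_try)) {
      nm <- intersect(rlang::as_label(labels_quo), names(df))
      if (length(nm) == 1L) df <- df[setdiff(names(df), nm)]
      labels <- lab_try
    }
    if (!all(vapply(df, is.numeric, logical(1)))) {
      stop("coordinate columns must all be numeric.", call. = FALSE)
    }
    ids <- rownames(x)
    D <- validate_dissimilarity(as.matrix(stats::dist(as.matrix(df))))
  }
  if (is.null(labels)) {
    labels <- rlang::eval_tidy(labels_quo)
  }
  if (length(labels) != nrow(D)) {
    stop("`labels` must provide one cluster label per object (",
      nrow(D), " expected, ", length(labels), " given).",
      call. = FALSE
    )
  }
  if (anyNA(labels)) stop("`labels` must not contain NA.", call. = FALSE)
  if (is.null(ids)) ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(D)))
  list(D = unname(D), labels = labels, ids = ids)
}

validate_dissimilarity <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("dissimilarities must form a square matrix.", call. = FALSE)
  }
  if (any(!is.finite(D)) || any(D < 0)) {
    stop("dissimilarities must be finite and nonnegative.", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(D))) {
    stop("dissimilarity matrix must be symmetric.", call. = FALSE)
  }
  if (any(diag(D) != 0)) {
    stop("dissimilarity matrix must have a zero diagonal.", call. = FALSE)
  }
  invisible(D)
}

# The engine. D: full symmetric matrix (unnamed); labels: length-n vector;
# p: parsed exponent. Returns plain vectors; no tibble overhead so that the
# experiment drivers can call it in tight loops.
sil_core <- function(D, labels, p) {
  n <- nrow(D)
  lev <- sort(unique(labels))
  k <- length(lev)
  if (k < 2L) {
    stop("silhouette widths need at least two clusters.", call. = FALSE)
  }
  a <- rep(NA_real_, n)
  Cmat <- matrix(NA_real_, n, k)
  sizes <- integer(k)
  for (j in seq_len(k)) {
    mem <- which(labels == lev[j])
    sizes[j] <- length(mem)
    M <- D[, mem, drop = FALSE]
    M[cbind(mem, seq_along(mem))] <- NA # exclude each member's self-distance
    if (length(mem) > 1L) {
      cj <- pm_rows(M, p)
      a[mem] <- cj[mem]
      cj[mem] <- NA # own cluster is not a neighbor candidate
      Cmat[, j] <- cj
    } else {
      M2 <- M
      M2[mem, ] <- NA
      cj <- rep(NA_real_, n)
      nonmem <- setdiff(seq_len(n), mem)
      cj[nonmem] <- pm_rows(M[nonmem, , drop = FALSE], p)
      Cmat[, j] <- cj
    }
  }
  Cinf <- Cmat
  Cinf[is.na(Cinf)] <- Inf
  nb <- max.col(-Cinf, ties.method = "first")
  b <- Cinf[cbind(seq_len(n), nb)]
  singleton <- sizes[match(labels, lev)] == 1L
  s <- numeric(n)
  reg <- !singleton
  denom <- pmax(a[reg], b[reg])
  s[reg] <- ifelse(denom == 0, 0, (b[reg] - a[reg]) / denom)
  a[singleton] <- 0 # undefined within-cluster mean recorded as 0
  s[singleton] <- 0
  list(
    a = a, b = b, s = s,
    neighbor = lev[nb], own = labels, k = k, levels = lev, sizes = sizes
  )
}

#' Summarize a silhouette table: mean silhouette width and misclassification
#' rate
#'
#' The mean silhouette width (MSW) is the arithmetic mean of `s(i)` over the
#' sample — always arithmetic, whatever exponent built the table; the power
#' mean enters only the within/between distances `a(i)` and `b(i)`. The
#' misclassification rate (MR) is the proportion of objects with strictly
#' negative `s(i)`; objects at exactly zero, including singleton-cluster
#' objects, are not counted as misclassified but remain in both denominators.
#'
#' @param tab A `gen_silhouette` table from [gen_silhouette()].
#' @return A one-row tibble with columns `p`, `n`, `k`, `msw`, `mr` and
#'   `n_neg` (the number of negative-silhouette objects).
#' @examples
#' pts <- data.frame(x = c(0, 1, 10, 11), y = 0, grp = c(1, 1, 2, 2))
#' silhouette_summary(gen_silhouette(pts, grp))
#' @export
silhouette_summary <- function(tab) {
  stopifnot(inherits(tab, "gen_silhouette"), nrow(tab) > 0)
  tibble::tibble(
    p = attr(tab, "p"),
    n = nrow(tab),
    k = attr(tab, "k"),
    msw = mean(tab$s),
    mr = mean(tab$s < 0),
    n_neg = sum(tab$s < 0)
  )
}

#' Per-cluster mean silhouette widths
#'
#' @param tab A `gen_silhouette` table.
#' @return A tibble with one row per cluster: `cluster`, `n` (size), `msw`.
#'   The sample MSW equals the size-weighted mean of these per-cluster values.
#' @export
cluster_msw <- function(tab) {
  stopifnot(inherits(tab, "gen_silhouette"))
  tibble::as_tibble(tab) |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(n = dplyr::n(), msw = mean(s), .groups = "drop")
}

#' Silhouette profile over a grid of exponents
#'
#' Recomputes the generalized silhouette for one fixed geometry and partition
#' at each exponent of `p_grid`, in grid order — the silhouette analogue of a
#' diversity profile. Raw MSW values at different `p` are not directly
#' comparable (lower exponents vary over a broader range); read the profile as
#' a family of indices ordered by sensitivity to compactness.
#'
#' @inheritParams gen_silhouette
#' @param p_grid Numeric vector of exponents; defaults to [default_p_grid()].
#' @return A tibble with one row per exponent: `p`, `n`, `k`, `msw`, `mr`,
#'   `n_neg`.
#' @examples
#' pts <- data.frame(x = c(0, 1, 2, 10, 11, 12), y = 0)
#' silhouette_profile(pts, rep(1:2, each = 3), p_grid = c(-Inf, 0, 1, Inf))
#' @export
silhouette_profile <- function(x, labels, p_grid = default_p_grid()) {
  if (length(p_grid) < 1L) stop("`p_grid` must be nonempty.", call. = FALSE)
  p_grid <- vapply(p_grid, parse_p, numeric(1))
  geom <- resolve_geometry(x, rlang::enquo(labels))
  purrr::map_dfr(p_grid, function(p) {
    core <- sil_core(geom$D, geom$labels, p)
    tibble::tibble(
      p = p, n = length(core$s), k = core$k,
      msw = mean(core$s), mr = mean(core$s < 0), n_neg = sum(core$s < 0)
    )
  })
}

#' @export
print.gen_silhouette <- function(x, ...) {
  cat(sprintf(
    "# Generalized silhouette: n = %d, k = %d, p = %s, MSW = %.4f, MR = %.4f\n",
    attr(x, "n"), attr(x, "k"), format_p(attr(x, "p")),
    mean(x$s), mean(x$s < 0)
  ))
  NextMethod()
}

#' Tidy and glance methods for silhouette tables
#'
#' `tidy()` returns the per-object table as a plain tibble; `glance()` returns
#' the one-row MSW/MR summary of [silhouette_summary()].
#'
#' @param x,... A `gen_silhouette` object; further arguments ignored.
#' @return A tibble.
#' @export
tidy.gen_silhouette <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.gen_silhouette
#' @export
glance.gen_silhouette <- function(x, ...) {
  silhouette_summary(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
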