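line4 <- data.frame(x = c(0, 1, 10, 11), y = 0)

test_that("four collinear points reproduce hand-computed widths", {
  tab <- gen_silhouette(line4, c(1, 1, 2, 2), p = 1)
  expect_s3_class(tab, "gen_silhouette")
  expect_equal(tab$a[1], 1)
  expect_equal(tab$b[1], 10.5)
  expect_equal(tab$s[1], (10.5 - 1) / 10.5, tolerance = 1e-12)

  tmin <- gen_silhouette(line4, c(1, 1, 2, 2), p = -Inf)
  expect_equal(tmin$b[1], 10)
  expect_equal(tmin$s[1], 9 / 10)

  tmax <- gen_silhouette(line4, c(1, 1, 2, 2), p = "inf")
  expect_equal(tmax$b[1], 11)
  expect_equal(tmax$s[1], 10 / 11)
})

test_that("geometry can be given as coordinates, dist, or full matrix", {
  labs <- c(1, 1, 2, 2)
  D <- stats::dist(line4)
  t1 <- gen_silhouette(line4, labs)
  t2 <- gen_silhouette(D, labs)
  t3 <- gen_silhouette(as.matrix(D), labs)
  expect_equal(t1$s, t2$s)
  expect_equal(t2$s, t3$s)
  # a labelled column of the data frame works too
  t4 <- gen_silhouette(cbind(line4, grp = labs), grp)
  expect_equal(t4$s, t1$s)
})

test_that("singleton clusters take s = 0 and stay out of MR", {
  D <- random_diss(6)
  tab <- gen_silhouette(D, c(1, 1, 1, 2, 2, 3), p = 2)
  expect_equal(tab$s[6], 0)
  expect_equal(tab$a[6], 0)
  sm <- silhouette_summary(tab)
  expect_equal(sm$mr, mean(tab$s < 0))
})

test_that("duplicate objects across clusters give s = 0, not NaN", {
  pts <- data.frame(x = c(0, 0, 0, 5), y = 0)
  tab <- gen_silhouette(pts, c(1, 1, 2, 2), p = -Inf)
  expect_false(any(is.nan(tab$s)))
  expect_equal(tab$a[1], 0)
  expect_equal(tab$b[1], 0)
  expect_equal(tab$s[1], 0) # a = b = 0: zero-distance members in both clusters
})

test_that("neighbor ties resolve to the smallest cluster label", {
  # object 1 equidistant from clusters 2 and 3
  pts <- data.frame(x = c(0, 0, 0, 5, 5, -5, -5), y = 0)
  tab <- gen_silhouette(pts, c(1, 1, 1, 2, 2, 3, 3), p = 1)
  expect_equal(tab$neighbor[1], 2)
})

test_that("summaries do plain arithmetic on s", {
  tab <- gen_silhouette(random_diss(4), c(1, 1, 2, 2), p = 1)
  tab$s <- c(0.5, -0.2, 0.9, -0.1)
  sm <- silhouette_summary(tab)
  expect_equal(sm$msw, 0.275)
  expect_equal(sm$mr, 0.5)
  expect_equal(sm$n_neg, 2L)
})

test_that("sample MSW is the size-weighted mean of cluster MSW", {
  withr::with_seed(21, {
    d <- random_labelled_points(40, 3)
    tab <- gen_silhouette(as.data.frame(d$coords), d$labels, p = 0)
    cm <- cluster_msw(tab)
    expect_equal(sum(cm$n * cm$msw) / sum(cm$n), mean(tab$s))
  })
})

test_that("constant dissimilarities give s = 0 at every exponent", {
  D <- matrix(3, 8, 8)
  diag(D) <- 0
  prof <- silhouette_profile(D, rep(1:2, each = 4))
  expect_equal(prof$msw, rep(0, nrow(prof)))
  expect_equal(prof$mr, rep(0, nrow(prof)))
})

test_that("s stays in [-1, 1], positive exactly when b exceeds a", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      d <- random_labelled_points(30, sample(2:5, 1))
      p <- sample(c(-Inf, -2, 0, 1, 3, Inf), 1)
      tab <- gen_silhouette(as.data.frame(d$coords), d$labels, p = p)
      expect_true(all(tab$s >= -1 & tab$s <= 1))
      reg <- tab$a > 0 | tab$b > 0
      expect_identical(tab$s[reg] > 0, tab$b[reg] > tab$a[reg])
    }
  })
})

test_that("a and b are nondecreasing in p object-by-object", {
  p_grid <- c(-Inf, -3, -1, 0, 1, 2, Inf)
  withr::with_seed(41, {
    d <- random_labelled_points(35, 3)
    tabs <- lapply(p_grid, function(p) {
      gen_silhouette(as.data.frame(d$coords), d$labels, p = p)
    })
    for (j in seq_len(length(p_grid) - 1)) {
      expect_true(all(tabs[[j + 1]]$a - tabs[[j]]$a > -1e-10))
      expect_true(all(tabs[[j + 1]]$b - tabs[[j]]$b > -1e-10))
    }
  })
})

test_that("relabelling clusters and permuting objects act equivariantly", {
  withr::with_seed(51, {
    d <- random_labelled_points(25, 3)
    df <- as.data.frame(d$coords)
    tab <- gen_silhouette(df, d$labels, p = -1)
    # bijective relabelling: 1->c, 2->a, 3->b
    map <- c("c", "a", "b")
    tab2 <- gen_silhouette(df, map[d$labels], p = -1)
    expect_equal(tab2$s, tab$s, tolerance = 1e-12)
    expect_identical(tab2$cluster, map[d$labels])
    expect_identical(tab2$neighbor, map[tab$neighbor])
    # object permutation
    perm <- sample(25)
    tab3 <- gen_silhouette(df[perm, ], d$labels[perm], p = -1)
    expect_equal(tab3$s, tab$s[perm], tolerance = 1e-12)
  })
})

test_that("silhouettes are invariant to rescaling all distances", {
  withr::with_seed(61, {
    D <- random_diss(20)
    labs <- sample(rep(1:3, length.out = 20))
    for (p in c(-Inf, -2, 0, 1.5, Inf)) {
      t1 <- gen_silhouette(D, labs, p = p)
      t2 <- gen_silhouette(D * 137.5, labs, p = p)
      expect_equal(t1$s, t2$s, tolerance = 1e-12)
    }
  })
})

test_that("profiles preserve grid order and propagate the exponent", {
  grid <- c(2, -Inf, 0)
  prof <- silhouette_profile(line4, c(1, 1, 2, 2), p_grid = grid)
  expect_equal(prof$p, grid)
  expect_equal(prof$n, rep(4L, 3))
})

test_that("malformed inputs error clearly", {
  expect_error(gen_silhouette(line4, c(1, 1, 2)), "one cluster label per object")
  expect_error(gen_silhouette(line4, c(1, 1, 1, 1)), "at least two clusters")
  expect_error(gen_silhouette(line4, c(1, 1, NA, 2)), "NA")
  D <- random_diss(4)
  D[1, 2] <- D[1, 2] + 1
  expect_error(gen_silhouette(D, c(1, 1, 2, 2)), "symmetric")
  D <- random_diss(4)
  diag(D)[2] <- 0.3
  expect_error(gen_silhouette(D, c(1, 1, 2, 2)), "diagonal")
  expect_error(silhouette_profile(line4, c(1, 1, 2, 2), p_grid = numeric(0)), "nonempty")
})

test_that("tidy and glance return the table and the summary", {
  tab <- gen_silhouette(line4, c(1, 1, 2, 2))
  expect_identical(tidy(tab), tibble::as_tibble(tab))
  expect_identical(glance(tab), silhouette_summary(tab))
})
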