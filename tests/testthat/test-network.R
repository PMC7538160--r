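test_that("reciprocity correlation follows Pearson on the nonzero support", {
  x <- c(1, 2, 3, 4)
  expect_equal(io_reciprocity(x, x), 1)
  expect_equal(io_reciprocity(x, 2 * x), 1)
  expect_equal(io_reciprocity(x, 10 - 2 * x), -1)
  # both-zero regions are dropped before correlating
  xi <- c(0, 1, 2, 3, 4); yi <- c(0, 2, 4, 6, 8)
  expect_equal(io_reciprocity(xi, yi), 1)
  expect_equal(io_reciprocity(xi, yi), cor(xi[-1], yi[-1]))
  expect_error(io_reciprocity(c(0, 0, 0), c(0, 0, 0)), "fewer than 3")
  expect_error(io_reciprocity(1:3, 1:4), "same region order")
})

test_that("fold differences classify dominance and omit silent regions", {
  fd <- fold_difference(c(a = 2, b = 1, c = 0, d = 0),
                        c(a = 1, b = 1, c = 2, d = 0), floor = 0)
  expect_equal(nrow(fd), 3L)          # d omitted: both sides zero
  expect_equal(fd$ratio[fd$region == "a"], 2)
  expect_equal(fd$dominance[fd$region == "a"], "input-dominated")
  expect_equal(fd$dominance[fd$region == "b"], "balanced")
  expect_equal(fd$dominance[fd$region == "c"], "output-dominated")
  # the pseudo-floor keeps one-sided zeros finite
  fd2 <- fold_difference(c(r = 1), c(r = 0), floor = 0.01)
  expect_true(is.finite(fd2$ratio))
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(21)
  v <- matrix(runif(5 * 17), 5, 17,
              dimnames = list(paste0("m", 1:5), NULL))
  cm <- correlation_matrix(v)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 5))
  # duplicates correlate at 1; orthogonal centered vectors at 0
  dup <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(correlation_matrix(dup)[1, 2], 1)
  orth <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(correlation_matrix(orth)[1, 2], 0)
  expect_error(correlation_matrix(rbind(a = c(1, 1, 1), b = 1:3)), "a")
})

test_that("pearson correlation is invariant under affine maps of the vectors", {
  set.seed(22)
  v <- matrix(runif(6 * 17), 6, 17)
  cm <- correlation_matrix(v)
  # one common affine map applied to every vector
  cm2 <- correlation_matrix(2.5 * v + 7)
  expect_equal(cm2, cm, tolerance = 1e-12)
  # per-vector affine maps (positive gain) also leave Pearson r unchanged
  gains <- runif(6, 0.2, 5); offs <- runif(6, -10, 10)
  cm3 <- correlation_matrix(sweep(sweep(v, 1, gains, `*`), 1, offs, `+`))
  expect_equal(cm3, cm, tolerance = 1e-12)
})

test_that("complete linkage matches hand calculation and the exhaustive oracle", {
  # 3 leaves, distances {d12 = 0.1, d13 = d23 = 0.9}
  r <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.1,
                0.1, 0.1, 1), 3, 3)
  cl <- cluster_complete_linkage(r)
  expect_equal(cl$merge[1, ], c(-1L, -2L))   # the 0.1 pair merges first
  expect_equal(cl$height, c(0.1, 0.9))
  # duplicate vectors merge at height zero
  rd <- matrix(1, 2, 2)
  expect_equal(cluster_complete_linkage(rd)$height, 0)
  expect_error(cluster_complete_linkage(matrix(c(1, .2, .5, 1), 2, 2)),
               "symmetric")
  # random matrices up to 6 leaves against the exhaustive-merge oracle
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    v <- matrix(rnorm(n * 8), n, 8)
    cm <- correlation_matrix(v)
    cl <- cluster_complete_linkage(cm)
    orc <- oracle_complete_linkage(1 - cm)
    expect_equal(cl$height, orc$heights, tolerance = 1e-12)
    for (k in seq_len(n - 1)) {
      mine <- stats::cutree(cl$hclust, h = cl$height[k] + 1e-9)
      want <- orc$partitions[[k]]
      got <- lapply(split(seq_len(n), mine), sort)
      expect_setequal(lapply(got, paste, collapse = ","),
                      lapply(want, paste, collapse = ","))
    }
  }
})

test_that("clustering is equivariant under permutation of the inputs", {
  set.seed(24)
  v <- matrix(rnorm(7 * 10), 7, 10,
              dimnames = list(paste0("m", 1:7), NULL))
  cm <- correlation_matrix(v)
  cl <- cluster_complete_linkage(cm)
  perm <- sample(7)
  cl2 <- cluster_complete_linkage(cm[perm, perm])
  expect_equal(sort(cl$height), sort(cl2$height), tolerance = 1e-12)
  # same partition at every cut, modulo labels
  for (k in 2:6) {
    a <- cut_clusters(cl, k)
    b <- cut_clusters(cl2, k)[match(names(a), names(cut_clusters(cl2, k)))]
    expect_equal(adjusted_rand(a, b), 1)
  }
})

test_that("the default cohort clusters aIC apart from the mIC/pIC pool", {
  atl <- make_synthetic_atlas()
  gen <- generate_count_dataset(cohort_config(seed = 19L), atl)
  ct <- apply_background_threshold(normalize_counts(gen$counts))
  maj <- aggregate_to_major(ct, atl$hierarchy)
  inp <- maj[startsWith(maj$condition, "RV"), ]
  vecs <- region_vectors(inp)
  expect_equal(nrow(vecs), 18L)
  cl <- cluster_complete_linkage(correlation_matrix(vecs))
  cut2 <- cut_clusters(cl, 2)
  truth <- ifelse(startsWith(names(cut2), "aIC"), 1, 2)
  expect_equal(adjusted_rand(cut2, truth), 1)
})

test_that("starter centers rank rostral to caudal with dense ties", {
  expect_equal(unname(starter_center_ranks(1.9)), 1L)
  expect_equal(unname(starter_center_ranks(c(1.9, 0.7, -0.5))),
               c(1L, 2L, 3L))
  expect_equal(unname(starter_center_ranks(c(-0.5, 1.9, 0.7))),
               c(3L, 1L, 2L))
  expect_equal(unname(starter_center_ranks(c(0.7, 0.7, -0.5))),
               c(1L, 1L, 2L))
})
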