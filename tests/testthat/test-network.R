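test_that("chain adjacency has the chain topology", {
  # single section: no neighbors possible
  n1 <- build_adjacency(1)
  expect_equal(sum(n1$adjacency), 0)
  expect_equal(n1$neighbor_counts, 0L)

  n3 <- build_adjacency(3)
  A <- n3$adjacency
  expect_equal(A[1, 2], 1L)
  expect_equal(A[2, 3], 1L)
  expect_equal(A[1, 3], 0L)
  expect_equal(A, t(A))

  # the full freeway segmentation: 154 chained sections
  n154 <- build_adjacency(154)
  expect_equal(n154$M, 154L)
  expect_equal(sum(n154$adjacency) / 2, 153)
  expect_equal(max(n154$neighbor_counts), 2L)
  expect_equal(diag(n154$adjacency), setNames(rep(0L, 154),
                                              n154$section_ids))
})

test_that("edge-list input is validated", {
  net <- build_adjacency(cbind(c("a", "b"), c("b", "c")))
  expect_equal(net$M, 3L)
  expect_equal(net$adjacency["a", "b"], 1L)
  expect_equal(net$adjacency["a", "c"], 0L)

  expect_error(build_adjacency(cbind("a", "a")), "self-edge")
  expect_error(build_adjacency(cbind("a", "b"), labels = c("a", "a", "b")),
               "duplicate")
  expect_error(build_adjacency(cbind("a", "z"), labels = c("a", "b")),
               "unknown section label")
  asym <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 0), 3, 3)
  expect_error(build_adjacency(asym), "symmetric")
  diag_bad <- diag(3)
  expect_error(build_adjacency(diag_bad), "diagonal")
})

test_that("adjacency files round-trip through the plain-text formats", {
  f <- tempfile()
  writeLines("chain: 5", f)
  expect_equal(read_adjacency(f)$M, 5L)
  writeLines(c("# comment", "s1 s2", "s2 s3"), f)
  net <- read_adjacency(f)
  expect_equal(net$M, 3L)
  expect_equal(sum(net$adjacency) / 2, 2)
  writeLines("s1 s2 s3", f)
  expect_error(read_adjacency(f), "exactly two")
})

test_that("Leroux conditional matches its closed limits", {
  net <- build_adjacency(3)
  phi <- c(0.4, 0, -1.1)
  # independence limit
  c0 <- leroux_conditional(2, phi, rho = 0, delta = 0.7, net)
  expect_equal(c0$mean, 0)
  expect_equal(c0$variance, 0.49)
  # intrinsic-CAR limit: neighbor average, variance delta^2 / d
  c1 <- leroux_conditional(2, phi, rho = 1, delta = 0.7, net)
  expect_equal(c1$mean, (0.4 - 1.1) / 2)
  expect_equal(c1$variance, 0.49 / 2)
  expect_error(leroux_conditional(2, phi, rho = 1.2, delta = 1, net), "rho")
  expect_error(leroux_conditional(2, phi, rho = 0.5, delta = -1, net),
               "delta")
})

test_that("conditional law agrees with partitioned-Gaussian conditioning", {
  # the printed posterior means of the spatial fit as a spot check
  net <- build_adjacency(3)
  phi <- c(0.8, 0.2, -0.5)
  got <- leroux_conditional(2, phi, rho = 0.62, delta = 0.74, net)
  Q <- leroux_precision(0.62, 0.74, net)
  want <- conditional_from_precision(Q, 2, phi)
  expect_equal(got$mean, want$mean, tolerance = 1e-12)
  expect_equal(got$variance, want$variance, tolerance = 1e-12)

  # property: all chain sizes M <= 6, random configurations
  set.seed(42)
  for (rep in 1:25) {
    M <- sample(2:6, 1)
    net <- build_adjacency(M)
    rho <- runif(1, 0, 0.99)
    delta <- runif(1, 0.05, 3)
    phi <- rnorm(M)
    Q <- leroux_precision(rho, delta, net)
    for (m in seq_len(M)) {
      got <- leroux_conditional(m, phi, rho, delta, net)
      want <- conditional_from_precision(Q, m, phi)
      expect_equal(got$mean, want$mean, tolerance = 1e-10)
      expect_equal(got$variance, want$variance, tolerance = 1e-10)
    }
  }
})

test_that("conditional variance is non-increasing in neighbor count", {
  net <- build_adjacency(6)
  phi <- rep(0, 6)
  for (rho in c(0.2, 0.6, 0.95)) {
    v <- vapply(1:6, function(m)
      leroux_conditional(m, phi, rho, 1, net)$variance, 0)
    # interior sections have 2 neighbors, ends have 1
    expect_true(all(v[2:5] <= v[c(1, 6)]))
  }
})

test_that("joint log-density matches dense multivariate-normal evaluation", {
  net <- build_adjacency(4)
  set.seed(7)
  phi <- rnorm(4)
  got <- leroux_logdensity(phi, rho = 0.5, delta = 1, net)
  want <- dense_mvn_logdensity(phi, leroux_precision(0.5, 1, net))
  expect_equal(got, want, tolerance = 1e-12)

  # independence limit: sum of univariate normal log-densities
  expect_equal(leroux_logdensity(phi, 0, 0.6, net),
               sum(dnorm(phi, 0, 0.6, log = TRUE)), tolerance = 1e-12)

  # zero vector: quadratic form vanishes
  Q <- leroux_precision(0.3, 0.9, net)
  expect_equal(leroux_logdensity(rep(0, 4), 0.3, 0.9, net),
               -2 * log(2 * pi) + 0.5 * determinant(Q)$modulus[1],
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(leroux_logdensity(phi, 1, 1, net), "improper")
})

test_that("Leroux precision is symmetric positive definite for rho < 1", {
  set.seed(11)
  for (rep in 1:20) {
    M <- sample(2:6, 1)
    Q <- leroux_precision(runif(1, 0, 0.999), runif(1, 0.05, 5),
                          build_adjacency(M))
    expect_equal(Q, t(Q))
    expect_gt(min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("homogeneity segmentation recovers planted change points", {
  g <- data.frame(start_km = 0:9, end_km = 1:10,
                  curvature = rep(2, 10), grade = rep(1, 10))
  expect_equal(nrow(segment_by_homogeneity(g)), 1L)

  g$grade[6:10] <- 3
  s <- segment_by_homogeneity(g)
  expect_equal(nrow(s), 2L)
  expect_equal(s$end_km[1], 5)
  expect_equal(s$start_km[2], 5)

  # synthetic roadway with 153 planted breakpoints -> 154 sections
  set.seed(3)
  n_int <- 600
  cuts <- sort(sample(2:n_int, 153))
  sec <- findInterval(seq_len(n_int), cuts) # 0..153
  curv <- round(runif(154, 0, 4.35), 2)
  grad <- round(runif(154, 0, 2.91), 2)
  # force every boundary to be a genuine change in at least one attribute
  for (k in 2:154) if (curv[k] == curv[k - 1] && grad[k] == grad[k - 1])
    curv[k] <- curv[k] + 0.01
  km <- seq(0, 60, length.out = n_int + 1)
  g154 <- data.frame(start_km = km[-length(km)], end_km = km[-1],
                     curvature = curv[sec + 1], grade = grad[sec + 1])
  s154 <- segment_by_homogeneity(g154)
  expect_equal(nrow(s154), 154L)
  expect_equal(s154$start_km[1], 0)
  expect_equal(s154$end_km[154], 60)

  bad <- g[c(2, 1, 3:10), ]
  expect_error(segment_by_homogeneity(bad), "ordered")
})

test_that("crashes map to sections by half-open intervals", {
  s <- data.frame(section_id = c("a", "b"), start_km = c(0, 5),
                  end_km = c(5, 10))
  expect_equal(assign_sections(c(0, 4.99, 5, 10), s),
               c("a", "a", "b", "b"))
  expect_error(assign_sections(11, s), "outside")
})
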