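test_that("queen contiguity on small grids matches hand enumeration", {
  # single polygon: no neighbours
  g1 <- suppressMessages(queen_contiguity(make_lattice(1, 1, 1)))
  expect_equal(g1$nb, list(integer(0)))
  # 2x2: every cell touches the other three (diagonal counts)
  g2 <- queen_contiguity(make_lattice(2, 2, 1))
  expect_equal(unname(g2$m), rep(3L, 4))
  # 3x3: centre has 8, corners 3, edges 5
  g3 <- queen_contiguity(make_lattice(3, 3, 1))
  expect_equal(unname(g3$m[5]), 8L)
  expect_equal(unname(g3$m[c(1, 3, 7, 9)]), rep(3L, 4))
  expect_equal(unname(g3$m[c(2, 4, 6, 8)]), rep(5L, 4))
  # symmetry holds everywhere
  for (i in seq_along(g3$ids)) {
    for (k in g3$nb[[i]]) expect_true(i %in% g3$nb[[k]])
  }
})

test_that("neighbour-list text round trip reproduces the graph", {
  g <- queen_contiguity(make_lattice(3, 3, 1))
  path <- tempfile(fileext = ".txt")
  write_adjacency(g, path)
  g2 <- read_adjacency(path)
  expect_equal(g$nb, g2$nb)
  expect_equal(g$ids, g2$ids)
})

test_that("asymmetric or malformed neighbour lists are rejected", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("a1: a2", "a2:"), path)
  expect_error(read_adjacency(path), class = "spzip_invalid_argument")
  expect_error(adjacency_graph(c("a1", "a2"), list(1L, 1L)),
               class = "spzip_invalid_argument")  # self-loop
})

test_that("ICAR quadratic form matches hand arithmetic and is shift invariant", {
  path3 <- adjacency_graph(c("a1", "a2", "a3"), list(2L, c(1L, 3L), 2L))
  expect_equal(icar_quadform(c(0, 1, 3), path3), 5)
  expect_equal(icar_quadform(rep(4.2, 3), path3), 0)
  v <- c(-1, 0.5, 2)
  expect_equal(icar_quadform(v, path3), icar_quadform(v + 17.3, path3))
  expect_error(icar_quadform(1:2, path3), class = "spzip_invalid_argument")
})

test_that("quadratic form equals the dense Laplacian form on random graphs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
    A <- A + t(A)
    nb <- lapply(seq_len(n), function(i) which(A[i, ] == 1))
    g <- suppressMessages(adjacency_graph(paste0("a", 1:n), nb))
    L <- diag(rowSums(A)) - A
    v <- rnorm(n)
    expect_equal(icar_quadform(v, g),
                 as.numeric(t(v) %*% L %*% v), tolerance = 1e-12)
  }
})

test_that("ICAR full conditional is the neighbour mean with variance 1/(tau m)", {
  g <- adjacency_graph(paste0("a", 1:4),
                       list(c(2L, 3L), c(1L, 3L, 4L), c(1L, 2L), 2L))
  fc <- icar_full_conditional(2, c(1, 0, 3, 5), tau = 2, g)
  expect_equal(fc$mean, 3)          # mean of 1, 3, 5
  expect_equal(fc$variance, 1 / 6)  # 1/(2 * 3)
  # all neighbours equal c -> conditional mean c
  fc2 <- icar_full_conditional(4, c(7, 2, 7, 0), tau = 1, g)
  expect_equal(fc2$mean, 2)
  # islands have no conditional
  gi <- suppressMessages(adjacency_graph(c("a1", "a2"), list(integer(0), integer(0))))
  expect_error(icar_full_conditional(1, c(0, 0), 1, gi),
               class = "spzip_undefined_conditional")
})

test_that("full conditional density is consistent with the joint kernel", {
  g <- adjacency_graph(paste0("a", 1:4),
                       list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L)))
  tau <- 1.7
  s <- c(0.3, -0.8, 1.2, 0.1)
  log_kernel <- function(v) -tau / 2 * icar_quadform(v, g)
  for (i in 1:4) {
    fc <- icar_full_conditional(i, s, tau, g)
    for (x in c(-1, 0, 0.5, 2)) {
      sx <- s; sx[i] <- x
      s0 <- s; s0[i] <- 0
      lhs <- log_kernel(sx) - log_kernel(s0)
      rhs <- (-(x - fc$mean)^2 + (0 - fc$mean)^2) / (2 * fc$variance)
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  }
})

test_that("Gibbs sampling the ICAR matches dense-precision pairwise variances", {
  # 5-node path graph: Gibbs from the full conditionals (recentred each
  # sweep) should reproduce Var(s_i - s_k) from the pseudo-inverse of tau*L
  g <- adjacency_graph(paste0("a", 1:5),
                       list(2L, c(1L, 3L), c(2L, 4L), c(3L, 5L), 4L))
  tau <- 1
  L <- diag(g$m)
  for (e in seq_len(nrow(g$edges))) {
    L[g$edges[e, 1], g$edges[e, 2]] <- -1
    L[g$edges[e, 2], g$edges[e, 1]] <- -1
  }
  Sigma <- pseudo_inverse(tau * L)
  set.seed(7)
  s <- rep(0, 5)
  n_sweep <- 20000
  draws <- matrix(0, n_sweep, 5)
  for (it in seq_len(n_sweep)) {
    for (i in 1:5) {
      fc <- icar_full_conditional(i, s, tau, g)
      s[i] <- rnorm(1, fc$mean, sqrt(fc$variance))
    }
    s <- s - mean(s)
    draws[it, ] <- s
  }
  draws <- draws[-(1:1000), ]
  for (pair in list(c(1, 2), c(1, 5), c(2, 4))) {
    emp <- var(draws[, pair[1]] - draws[, pair[2]])
    theo <- Sigma[pair[1], pair[1]] + Sigma[pair[2], pair[2]] -
      2 * Sigma[pair[1], pair[2]]
    expect_equal(emp, theo, tolerance = 0.15)
  }
})

test_that("sample_icar draws are sum-to-zero and spatially smooth", {
  g <- queen_contiguity(make_lattice(4, 5, 1))
  set.seed(3)
  x <- sample_icar(g, tau = 0.5)
  expect_equal(mean(x), 0, tolerance = 1e-10)
  # neighbouring values are positively correlated relative to random pairs
  d_nb <- mean((x[g$edges[, 1]] - x[g$edges[, 2]])^2)
  all_pairs <- combn(length(x), 2)
  d_all <- mean((x[all_pairs[1, ]] - x[all_pairs[2, ]])^2)
  expect_lt(d_nb, d_all)
})
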