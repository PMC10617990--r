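test_that("partial correlations match the brute-force residual oracle", {
  tr <- generate_tree(30, 100, seed = 1)
  m <- 5L
  R <- stats::cov2cor(stats::rWishart(1, 10, diag(m))[, , 1])
  set.seed(2)
  X <- simulate_traits(tr, "BM", R = R / 100, root_state = 0, seed = 3)
  ec <- evolutionary_covariance(tr, X)
  # oracle: correlate GLS-whitened residuals after regressing each member
  # of a pair on all remaining traits
  C <- ape::vcv(tr)
  chC <- chol(C)
  Xw <- backsolve(chC, X[rownames(C), ], transpose = TRUE)
  onew <- backsolve(chC, rep(1, nrow(X)), transpose = TRUE)
  mu <- as.vector(crossprod(onew, Xw)) / sum(onew^2)
  Z <- Xw - outer(onew, mu)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    others <- setdiff(seq_len(m), c(i, j))
    ri <- stats::lm.fit(Z[, others, drop = FALSE], Z[, i])$residuals
    rj <- stats::lm.fit(Z[, others, drop = FALSE], Z[, j])$residuals
    # uncentred (cosine) correlation: the scatter is already about the
    # GLS mean
    expect_equal(ec$pcorr[i, j],
                 sum(ri * rj) / sqrt(sum(ri^2) * sum(rj^2)),
                 tolerance = 1e-10)
  }
  # a hand-inverted 3x3 precision check
  Rh <- ec$R_hat[1:3, 1:3]
  Om <- solve(Rh)
  expect_equal(ec3 <- evolutionary_covariance(tr, X[, 1:3])$pcorr[1, 2],
               -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2]), tolerance = 1e-12)
})

test_that("shared-cause construction flips the sign of the partial", {
  # a = 0.5x + 0.2y + 0.1z, b = 0.5x - 0.2y + 0.1z, c = x: marginally a
  # and b correlate positively; conditioning on c exposes the negative
  # contribution of y
  tr <- star_tree(400)
  set.seed(4)
  x <- rnorm(400); y <- rnorm(400); z <- rnorm(400)
  X <- cbind(a = 0.5 * x + 0.2 * y + 0.1 * z,
             b = 0.5 * x - 0.2 * y + 0.1 * z,
             c = x)
  rownames(X) <- tr$tip.label
  ec <- evolutionary_covariance(tr, X)
  expect_gt(ec$corr["a", "b"], 0)
  expect_lt(ec$pcorr["a", "b"], 0)
})

test_that("null partial correlations stay near zero and the test is
           calibrated", {
  tr <- generate_tree(56, 180, seed = 5)
  # diagonal-R simulation: mean |off-diagonal pcorr| stays small
  pc <- vapply(1:200, function(b) {
    X <- simulate_traits(tr, "BM", R = diag(3) / 180, root_state = 0,
                         seed = 400 + b)
    ec <- evolutionary_covariance(tr, X)
    mean(abs(ec$pcorr[upper.tri(ec$pcorr)]))
  }, numeric(1))
  # the sampling floor of |pcorr| at n = 56 is sqrt(2/pi)/sqrt(n - m):
  # about 0.11; the mean must sit at that floor with no systematic sign
  expect_lt(mean(pc), 0.12)
  # edge-exclusion null rejection ~ alpha at 1000 reps
  pw <- partial_correlation_power(tr, levels = 0, m = 4, n_reps = 1000,
                                  nuisance = 0, seed = 6)
  expect_lt(abs(pw$power - 0.05), 0.02)
})

test_that("phylogenetic PCA has orthonormal loadings and valid fractions", {
  tr <- generate_tree(25, 120, seed = 7)
  R <- stats::cov2cor(stats::rWishart(1, 8, diag(4))[, , 1])
  X <- simulate_traits(tr, "BM", R = R / 120, root_state = 0, seed = 8)
  p <- phylo_pca(tr, X)
  expect_lt(max(abs(crossprod(p$loadings) - diag(4))), 1e-8)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(p$variance_fraction >= 0))

  # star tree with equal branch lengths: ordinary PCA of centred data
  st <- star_tree(40)
  set.seed(9)
  Xs <- matrix(rnorm(40 * 3), 40, 3,
               dimnames = list(st$tip.label, c("a", "b", "c")))
  ps <- phylo_pca(st, Xs)
  ord <- stats::prcomp(Xs, center = TRUE, scale. = FALSE)
  for (j in 1:3)
    expect_equal(abs(ps$loadings[, j]), abs(ord$rotation[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA recovers a dominant axis of variation", {
  tr <- generate_tree(40, 100, seed = 10)
  v <- c(2, 1, 1) / sqrt(6)
  R <- 50 * tcrossprod(v) + diag(3)      # 50:1 dominant eigenvalue
  ang <- vapply(1:100, function(b) {
    X <- simulate_traits(tr, "BM", R = R / 100, root_state = 0,
                         seed = 500 + b)
    l1 <- phylo_pca(tr, X)$loadings[, 1]
    acos(min(1, abs(sum(l1 * v)))) * 180 / pi
  }, numeric(1))
  expect_lt(stats::median(ang), 5)
})

test_that("multivariate allometric slopes are PC1 loading ratios", {
  l1 <- c(len = 0.1519, area = 0.1563, width = 0.1138)
  expect_equal(round(allometry_multivariate(l1, "width", "len"), 3),
               0.749)
  expect_equal(allometry_multivariate(l1, "len", "len"), 1)
  expect_error(allometry_multivariate(l1, "len", "nope"), "not found")
  expect_error(allometry_multivariate(c(a = 1, b = 0), "a", "b"), "zero")

  # exact power law b = 0.5 * a with BM noise on the shared axis only
  tr <- generate_tree(56, 100, seed = 11)
  sl <- vapply(1:100, function(b) {
    a <- simulate_traits(tr, "BM", R = matrix(1 / 100), root_state = 0,
                         seed = 600 + b)
    X <- cbind(a = a[, 1], b = 0.5 * a[, 1])
    X <- X + matrix(rnorm(length(X), 0, 1e-3), nrow(X))
    p <- phylo_pca(tr, X)
    allometry_multivariate(p, "b", "a")
  }, numeric(1))
  expect_equal(mean(sl), 0.5, tolerance = 0.05)
})

test_that("bivariate allometry: collinear data and OR/LR attenuation", {
  tr <- generate_tree(30, 100, seed = 12)
  a <- simulate_traits(tr, "BM", R = matrix(1 / 100), root_state = 0,
                       seed = 13)
  X <- cbind(x = a[, 1], y = 0.5 * a[, 1] + 1)
  fit <- allometry_bivariate(tr, X, "x", "y", n_boot = 50, seed = 1)
  expect_equal(fit$slope_lr, 0.5, tolerance = 1e-9)
  expect_equal(fit$slope_or, 0.5, tolerance = 1e-9)
  expect_equal(fit$intercept_lr, 1, tolerance = 1e-8)

  # symmetric noise on both axes: OR stays near 1, LR attenuates
  st <- star_tree(200)
  res <- vapply(1:100, function(b) {
    set.seed(700 + b)
    u <- rnorm(200, 0, 1)
    X2 <- cbind(x = u + rnorm(200, 0, 0.6), y = u + rnorm(200, 0, 0.6))
    rownames(X2) <- st$tip.label
    f <- allometry_bivariate(st, X2, "x", "y", n_boot = 2, seed = 1)
    c(f$slope_lr, f$slope_or)
  }, numeric(2))
  expect_equal(mean(res[2, ]), 1, tolerance = 0.05)
  expect_lt(mean(res[1, ]), 0.9)
  expect_error(allometry_bivariate(tr, X, "nope", "y"), "not found")
})

test_that("ancestral estimates honour closed forms and equivariance", {
  # constant tips: every internal estimate equals the constant
  tr <- generate_tree(12, 90, seed = 14)
  v <- stats::setNames(rep(3.5, 12), tr$tip.label)
  anc <- ancestral_states(tr, v)
  expect_equal(anc$estimate, rep(3.5, nrow(anc)), tolerance = 1e-9)

  # 2-tip cherry: root is the inverse-branch-length weighted mean
  ch <- ape::read.tree(text = "(A:2,B:0.5);")
  va <- c(A = 1, B = 3)
  root <- ancestral_states(ch, va)$estimate[1]
  expect_equal(root, (1 / 2 + 3 / 0.5) / (1 / 2 + 1 / 0.5),
               tolerance = 1e-12)

  # translation equivariance under BM
  set.seed(15)
  v2 <- stats::setNames(rnorm(12), tr$tip.label)
  a1 <- ancestral_states(tr, v2)
  a2 <- ancestral_states(tr, v2 + 7)
  expect_equal(a2$estimate, a1$estimate + 7, tolerance = 1e-9)
  expect_equal(a2$variance, a1$variance, tolerance = 1e-9)
})

test_that("ancestral 95% intervals cover simulated internal states", {
  tr <- generate_tree(60, 100, seed = 16)
  n <- 60L; nn <- tr$Nnode
  dep <- ape::node.depth.edgelength(tr)
  D <- ape::dist.nodes(tr)
  S <- (outer(dep, dep, "+") - D) / 2     # BM covariance over all nodes
  L <- t(chol(S[-(n + 1L), -(n + 1L)] +
                diag(1e-10, n + nn - 1L)))  # root is deterministic (0)
  covered <- 0L; total <- 0L
  set.seed(17)
  for (b in 1:18) {
    z <- as.vector(L %*% rnorm(n + nn - 1L))
    allv <- append(z, 0, after = n)        # insert root value 0
    tips <- stats::setNames(allv[1:n], tr$tip.label)
    anc <- ancestral_states(tr, tips)
    truev <- allv[(n + 1L):(n + nn)]
    half <- 1.96 * sqrt(anc$variance)
    covered <- covered + sum(abs(anc$estimate - truev) <= half)
    total <- total + nn
  }
  expect_gt(total, 1000L)
  expect_equal(covered / total, 0.95, tolerance = 0.025)
})

test_that("edge-exclusion power increases with partial correlation", {
  tr <- generate_tree(56, 180, seed = 18)
  pw <- partial_correlation_power(tr, levels = c(0.2, 0.5, 0.8), m = 4,
                                  n_reps = 400, seed = 19)
  expect_true(all(diff(pw$power) >= 0))
  expect_gt(pw$power[3], 0.9)
  expect_error(partial_correlation_power(tr, levels = 0.99, m = 6,
                                         nuisance = 0.4, seed = 1),
               "non-PD")
})

test_that("allometry slopes are invariant to unit changes of both axes", {
  tr <- generate_tree(30, 100, seed = 20)
  R <- matrix(c(1, .6, .6, 1.2), 2) / 100
  X <- simulate_traits(tr, "BM", R = R, root_state = 0, seed = 21)
  colnames(X) <- c("x", "y")
  f1 <- allometry_bivariate(tr, X, "x", "y", n_boot = 10, seed = 1)
  # mm -> um on a log10 scale shifts both variables by 3
  f2 <- allometry_bivariate(tr, X + 3, "x", "y", n_boot = 10, seed = 1)
  expect_equal(f2$slope_lr, f1$slope_lr, tolerance = 1e-9)
  expect_equal(f2$slope_or, f1$slope_or, tolerance = 1e-9)
  p1 <- phylo_pca(tr, X); p2 <- phylo_pca(tr, X + 3)
  expect_equal(allometry_multivariate(p2, "x", "y"),
               allometry_multivariate(p1, "x", "y"), tolerance = 1e-9)
})
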