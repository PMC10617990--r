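test_that("model specifications are validated", {
  R <- matrix(c(1, .5, .5, 2), 2)
  expect_s3_class(evo_spec("BM", R), "evo_spec")
  expect_error(evo_spec("BM", matrix(c(1, 2, 3, 4), 2)), "symmetric")
  expect_error(evo_spec("BM", matrix(c(1, 2, 2, 1), 2)), "positive definite")
  expect_error(evo_spec("OU", R), "alpha")
  expect_error(evo_spec("OU", R, alpha = -1), ">= 0")
  expect_error(evo_spec("OU", R, alpha = 0), "> 0")
  expect_s3_class(evo_spec("OU", R, alpha = 0, ou_root = "fixed"),
                  "evo_spec")
  expect_error(evo_spec("EB", R), "r")
  expect_error(evo_spec("EB", R, r = 0.5), "<= 0")
})

test_that("model covariance matches small-tree closed forms", {
  # 2-tip cherry, branch length 1: BM tips are independent
  ch <- ape::read.tree(text = "(A:1,B:1);")
  mc <- model_covariance(ch, evo_spec("BM", matrix(1)))
  expect_equal(mc$cov, diag(2), ignore_attr = TRUE)
  # fixed-root OU converges entrywise to BM as alpha -> 0 (unit-depth
  # tree; the leading deviation is O(alpha * depth^2))
  tr <- generate_tree(8, 1, seed = 1)
  R <- matrix(c(1, .5, .5, 2), 2)
  bm <- model_covariance(tr, evo_spec("BM", R))
  ou <- model_covariance(tr, evo_spec("OU", R, alpha = 1e-8, theta = 0,
                                      ou_root = "fixed"))
  expect_lt(max(abs(ou$cov - bm$cov)), 1e-6)
  X <- simulate_traits(tr, "BM", R = R, root_state = 0, seed = 2)
  expect_equal(evo_loglik(tr, X, evo_spec("OU", R, alpha = 1e-8,
                                          theta = 0, ou_root = "fixed")),
               evo_loglik(tr, X, evo_spec("BM", R, root_state = 0)),
               tolerance = 1e-6)
  # OU rejects non-ultrametric trees
  nu <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  expect_error(model_covariance(nu, evo_spec("OU", matrix(1), alpha = 1)),
               "ultrametric")
})

test_that("analytic covariance matches Monte-Carlo for each model", {
  tr <- generate_tree(4, 50, seed = 2)
  R <- matrix(c(0.02, 0.008, 0.008, 0.03), 2)
  nrep <- 10000L
  specs <- list(
    evo_spec("BM", R, root_state = 0),
    evo_spec("OU", R, alpha = c(0.05, 0.08), theta = c(1, -1)),
    evo_spec("EB", R, r = -0.03, root_state = 0))
  args <- list(list(model = "BM", root_state = 0),
               list(model = "OU", alpha = c(0.05, 0.08), theta = c(1, -1)),
               list(model = "EB", r = -0.03, root_state = 0))
  for (i in seq_along(specs)) {
    mc <- model_covariance(tr, specs[[i]])
    arr <- do.call(simulate_traits,
                   c(list(tr), args[[i]], list(R = R, seed = 10 + i,
                                               nreps = nrep)))
    Y <- t(apply(arr, 3L, as.vector))
    emp <- stats::cov(Y)
    se <- sqrt((outer(diag(mc$cov), diag(mc$cov)) + mc$cov^2) / nrep)
    expect_true(all(abs(emp - mc$cov) <= 3.5 * se))
    expect_true(all(abs(colMeans(Y) - mc$mean) <= 3.5 * sqrt(diag(mc$cov) /
                                                               nrep)))
  }
})

test_that("log-likelihood matches closed forms and reductions", {
  # star tree, unit branches, standard normal data
  tr <- star_tree(5)
  X <- matrix(0, 5, 2, dimnames = list(tr$tip.label, c("a", "b")))
  ll <- evo_loglik(tr, X, evo_spec("BM", diag(2), root_state = 0))
  expect_equal(ll, -(5 * 2 / 2) * log(2 * pi), tolerance = 1e-10)

  # EB with r = 0 equals BM on identical data
  tr2 <- generate_tree(7, 80, seed = 3)
  R <- matrix(c(1, .4, .4, 1.5), 2)
  X2 <- simulate_traits(tr2, "BM", R = R, root_state = 1, seed = 4)
  llb <- evo_loglik(tr2, X2, evo_spec("BM", R, root_state = 1))
  lle <- evo_loglik(tr2, X2, evo_spec("EB", R, r = 0, root_state = 1))
  expect_equal(lle, llb, tolerance = 1e-10)

  # 2-tip tree: direct bivariate normal density per trait
  ch <- ape::read.tree(text = "(A:2,B:2);")
  x <- c(A = 0.3, B = -0.4)
  ll2 <- evo_loglik(ch, matrix(x, 2, 1, dimnames = list(names(x), "t")),
                    evo_spec("BM", matrix(0.5), root_state = 0))
  direct <- sum(stats::dnorm(x, 0, sqrt(0.5 * 2), log = TRUE))
  expect_equal(ll2, direct, tolerance = 1e-12)

  # invariant under permutation of tip order
  perm <- c(3, 1, 2, 5, 4, 6, 7)
  X2p <- X2[perm, , drop = FALSE]
  expect_equal(evo_loglik(tr2, X2p, evo_spec("BM", R, root_state = 1)),
               llb, tolerance = 1e-10)
})

test_that("OU analytic gradient agrees with finite differences", {
  tr <- generate_tree(12, 120, seed = 5)
  R <- matrix(c(1, .3, .3, .8), 2)
  X <- simulate_traits(tr, "OU", R = R, alpha = c(.02, .05), theta = 0,
                       seed = 6)
  tij <- ape::vcv(tr); depth <- max(diag(tij))
  par <- foliametry:::ou_par_pack(c(.03, .04), R)
  for (root in c("stationary", "fixed")) {
    g <- foliametry:::ou_profile_eval(par, X, tij, depth, root,
                                      want_grad = TRUE)$grad
    fd <- vapply(seq_along(par), function(j) {
      h <- 1e-6
      p1 <- par; p1[j] <- p1[j] + h
      p2 <- par; p2[j] <- p2[j] - h
      (foliametry:::ou_profile_eval(p1, X, tij, depth, root)$loglik -
         foliametry:::ou_profile_eval(p2, X, tij, depth, root)$loglik) /
        (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("fitted likelihood dominates the generating parameters", {
  tr <- generate_tree(40, 180, seed = 7)
  R <- matrix(c(1, .5, .5, 2), 2)
  X <- simulate_traits(tr, "BM", R = R, root_state = 0, seed = 8)
  for (mdl in c("BM", "OU", "EB")) {
    fit <- fit_evo(tr, X, mdl, restarts = 3, seed = 1)
    expect_gte(fit$loglik + 1e-6,
               evo_loglik(tr, X, evo_spec("BM", R, root_state = 0)))
  }
})

test_that("BM rate-matrix recovery and its improvement with tree size", {
  R <- matrix(c(1, .5, .5, 2), 2)
  err_at <- function(n_tips, reps) {
    tr <- generate_tree(n_tips, 180, seed = 11)
    Rsc <- R / 180          # unit-depth scaling keeps entries O(1)
    vapply(seq_len(reps), function(b) {
      X <- simulate_traits(tr, "BM", R = Rsc, root_state = 0,
                           seed = 100 + b)
      fit <- fit_evo(tr, X, "BM")
      max(abs(fit$R - Rsc) / max(abs(Rsc)))
    }, numeric(1))
  }
  e56 <- err_at(56, 100)
  expect_lt(stats::median(e56), 0.25)
  e32 <- err_at(32, 50)
  e128 <- err_at(128, 50)
  expect_lt(stats::median(e128), stats::median(e32))
})

test_that("OU halflife is recovered within a factor of two", {
  tr <- generate_tree(56, 180, seed = 13)
  hl_true <- 180 / 8
  al <- log(2) / hl_true
  R <- matrix(c(1, .3, .3, 1), 2) * 2 * al   # stationary variance ~ 1
  # fraction of per-trait halflife estimates within a factor of two
  ok <- vapply(1:100, function(b) {
    X <- simulate_traits(tr, "OU", R = R, alpha = al, theta = 0,
                         seed = 200 + b)
    fit <- fit_evo(tr, X, "OU", restarts = 2, seed = b)
    mean(fit$halflife > hl_true / 2 & fit$halflife < hl_true * 2)
  }, numeric(1))
  expect_gte(mean(ok), 0.8)
})

test_that("AIC and AICc follow their definitions and ranking", {
  expect_equal(aicc(0, 2, 56), 4 + 12 / 53)
  # AICc approaches AIC as n grows
  expect_lt(aicc(0, 5, 1e6) - 10, 1e-4)
  expect_true(is.infinite(aicc(0, 5, 6)))

  mk <- function(model, aiccv) structure(
    list(model = model, p = 2L, loglik = 0, AIC = aiccv, AICc = aiccv,
         n_obs = 504L),
    class = "evo_fit")
  tab <- aicc_rank(list(mk("BM", -227.73), mk("OU", -360.64),
                        mk("EB", -254.03)))
  expect_identical(tab$model, c("OU", "EB", "BM"))
  # exact ties break alphabetically, stably
  tab2 <- aicc_rank(list(mk("OU", -5), mk("BM", -5)))
  expect_identical(tab2$model, c("BM", "OU"))
  bad <- mk("BM", 0); bad$n_obs <- 10L
  expect_error(aicc_rank(list(mk("OU", 1), bad)), "n_obs")
})

test_that("halflife transforms attraction rates", {
  expect_equal(halflife(log(2))$halflife, 1)
  expect_equal(halflife(0.0347)$mean, 19.98, tolerance = 1e-3)
  expect_error(halflife(0), "> 0")
})

test_that("OU wins AICc on strongly attracted data", {
  tr <- generate_tree(40, 180, seed = 17)
  al <- log(2) / (180 / 16)
  R <- diag(2) * 2 * al
  wins <- vapply(1:20, function(b) {
    X <- simulate_traits(tr, "OU", R = R, alpha = al, theta = 0,
                         seed = 300 + b)
    ou <- fit_evo(tr, X, "OU", restarts = 2, seed = b)
    bm <- fit_evo(tr, X, "BM")
    ou$AICc < bm$AICc
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("single-replicate power run is reproducible", {
  p1 <- model_selection_power(n_tips = 12, m = 3, n_reps = 1, seed = 5)
  p2 <- model_selection_power(n_tips = 12, m = 3, n_reps = 1, seed = 5)
  expect_identical(p1$n_bm, p2$n_bm)
  expect_equal(p1$fraction_bm, p1$n_bm / (p1$n_reps - p1$failures))
})
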