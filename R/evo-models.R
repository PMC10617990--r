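# Multivariate Gaussian trait-evolution models on a phylogeny.
#
# Three models of continuous-trait evolution along branches:
#   BM  dX = sigma dB                    (drift / fluctuating selection)
#   OU  dX = alpha (theta - X) dt + sigma dB   (stabilising selection)
#   EB  dX = sigma e^{r t / 2} dB, r <= 0      (early burst / ACDC)
# Each implies a multivariate normal distribution of the stacked tip values
# (traits in blocks, species within block), fitted by maximum likelihood and
# ranked by AICc.  The rate matrix R = sigma sigma^T couples traits; the OU
# attraction is diagonal (one alpha per trait), with either a stationary
# root (the default) or a root clamped at the optimum.

#' Construct a trait-evolution model specification
#'
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param R m-by-m symmetric positive-definite rate matrix.
#' @param alpha per-trait OU attraction rates (> 0 for the stationary root
#'   form, >= 0 for the fixed root form); recycled to m.
#' @param theta per-trait OU optima; recycled to m.
#' @param r EB exponential rate (<= 0).
#' @param root_state per-trait root mean (BM/EB); recycled to m.
#' @param ou_root `"stationary"` or `"fixed"` (root clamped at `theta`).
#' @return a validated list of class `evo_spec`.
#' @export
evo_spec <- function(model = c("BM", "OU", "EB"), R, alpha = NULL,
                     theta = NULL, r = NULL, root_state = 0,
                     ou_root = c("stationary", "fixed")) {
  model <- match.arg(model)
  ou_root <- match.arg(ou_root)
  R <- as.matrix(R)
  m <- nrow(R)
  if (ncol(R) != m || max(abs(R - t(R))) > 1e-8 * max(abs(R), 1))
    stop("R must be a symmetric matrix")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("R must be positive definite")
  spec <- list(model = model, R = R, root_state = rep_len(root_state, m),
               ou_root = ou_root)
  if (model == "OU") {
    if (is.null(alpha)) stop("OU requires alpha")
    alpha <- rep_len(alpha, m)
    if (any(alpha < 0)) stop("alpha must be >= 0")
    if (ou_root == "stationary" && any(alpha == 0))
      stop("stationary-root OU requires alpha > 0")
    spec$alpha <- alpha
    spec$theta <- rep_len(if (is.null(theta)) 0 else theta, m)
  } else if (model == "EB") {
    if (is.null(r)) stop("EB requires r")
    if (length(r) != 1L || r > 0) stop("EB rate r must be a scalar <= 0")
    spec$r <- r
  }
  structure(spec, class = "evo_spec")
}

# EB branch-length transform applied to shared path lengths, r -> 0 limit
eb_transform <- function(tij, r) {
  if (abs(r) < 1e-12) tij else expm1(r * tij) / r
}

#' Tip mean and covariance implied by a trait-evolution model
#'
#' For BM the covariance between trait k of tip i and trait l of tip j is
#' `R[k,l] * t_ij`, with `t_ij` the shared root-to-MRCA path length; EB is
#' BM on exponentially transformed path lengths `(e^{r t} - 1)/r`.  For the
#' diagonal-alpha OU with a stationary root the covariance is
#' `R[k,l]/(a_k + a_l) * exp(-(a_k + a_l)(T - t_ij))` on an ultrametric tree
#' of depth `T`; the fixed-root form multiplies by
#' `(1 - exp(-(a_k + a_l) t_ij))` and reduces exactly to BM as alpha -> 0.
#'
#' @param tree a `phylo` tree.
#' @param spec an [evo_spec()].
#' @return list with `mean` (length n*m, traits in blocks) and `cov`
#'   (nm-by-nm), plus `tij` and `depth`.
#' @export
model_covariance <- function(tree, spec) {
  stopifnot(inherits(spec, "evo_spec"))
  tij <- ape::vcv(tree)
  n <- nrow(tij); m <- nrow(spec$R)
  depth <- max(diag(tij))
  if (spec$model == "BM") {
    cov <- kronecker(spec$R, tij)
    mu <- rep(spec$root_state, each = n)
  } else if (spec$model == "EB") {
    cov <- kronecker(spec$R, eb_transform(tij, spec$r))
    mu <- rep(spec$root_state, each = n)
  } else {
    if (!is_ultrametric(tree))
      stop("OU (stationary-root form) requires an ultrametric tree")
    cov <- ou_cov(tij, depth, spec$R, spec$alpha, spec$ou_root)
    mu <- rep(spec$theta, each = n)
  }
  list(mean = mu, cov = cov, tij = tij, depth = depth)
}

# nm x nm OU tip covariance, diagonal alpha
ou_cov <- function(tij, depth, R, alpha, ou_root) {
  n <- nrow(tij); m <- nrow(R)
  d <- depth - tij
  cov <- matrix(0, n * m, n * m)
  for (k in seq_len(m)) for (l in k:m) {
    a <- alpha[k] + alpha[l]
    blk <- if (ou_root == "stationary") {
      R[k, l] * exp(-a * d) / a
    } else if (a < 1e-14) {
      R[k, l] * tij
    } else {
      R[k, l] * exp(-a * d) * (-expm1(-a * tij)) / a
    }
    ik <- (k - 1L) * n + seq_len(n); il <- (l - 1L) * n + seq_len(n)
    cov[ik, il] <- blk
    if (l > k) cov[il, ik] <- blk
  }
  cov
}

#' Model log-likelihood of a trait table
#'
#' Multivariate normal log-density of the stacked species-by-trait values
#' under the mean and covariance implied by `spec` on `tree`.
#'
#' @param tree a `phylo` tree.
#' @param traits complete species-by-trait matrix (rownames = tip labels).
#' @param spec an [evo_spec()].
#' @return scalar log-likelihood.
#' @export
evo_loglik <- function(tree, traits, spec) {
  traits <- as.matrix(traits)
  mt <- match_tree_traits(tree, traits)
  y <- as.vector(mt$traits)
  mc <- model_covariance(mt$tree, spec)
  ch <- tryCatch(chol(mc$cov), error = function(e)
    chol(mc$cov + diag(1e-10 * mean(diag(mc$cov)), nrow(mc$cov))))
  z <- backsolve(ch, y - mc$mean, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# ---- closed-form profiled fits (matrix-normal structure) ----------------

# Given a species covariance V (n x n), the BM/EB maximum likelihood has a
# closed form: GLS root per trait and R_hat = crossprod of whitened
# residuals / n.  Returns loglik, root, R_hat.
mn_profile_fit <- function(V, X) {
  n <- nrow(X); m <- ncol(X)
  chV <- chol(V)
  Xw <- backsolve(chV, X, transpose = TRUE)
  onew <- backsolve(chV, rep(1, n), transpose = TRUE)
  denom <- sum(onew^2)
  root <- as.vector(crossprod(onew, Xw)) / denom
  resw <- Xw - outer(onew, root)
  Rhat <- crossprod(resw) / n
  ldV <- 2 * sum(log(diag(chV)))
  ldR <- as.numeric(determinant(Rhat, logarithm = TRUE)$modulus)
  ll <- -0.5 * (n * m * log(2 * pi) + m * ldV + n * ldR + n * m)
  list(loglik = ll, root = root, Rhat = Rhat)
}

# ---- OU likelihood + analytic gradient ----------------------------------

# Parameter vector for diagonal-alpha OU: c(log alpha (m), log diag L (m),
# strict lower triangle of L (m(m-1)/2)) with R = L L'.  theta profiled out
# by GLS.
ou_par_pack <- function(alpha, R) {
  L <- t(chol(R))
  m <- length(alpha)
  c(log(alpha), log(diag(L)), L[lower.tri(L)])
}

ou_par_unpack <- function(par, m) {
  alpha <- exp(par[seq_len(m)])
  L <- diag(exp(par[m + seq_len(m)]), m)
  L[lower.tri(L)] <- par[(2 * m + 1):length(par)]
  list(alpha = alpha, L = L, R = tcrossprod(L))
}

# Profiled (theta out) OU log-likelihood and gradient.  X is n x m, tij the
# shared-path matrix, depth the tree depth.
ou_profile_eval <- function(par, X, tij, depth, ou_root, want_grad = FALSE) {
  n <- nrow(X); m <- ncol(X)
  pp <- ou_par_unpack(par, m)
  C <- ou_cov(tij, depth, pp$R, pp$alpha, ou_root)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch))
    return(list(loglik = -1e10, grad = rep(0, length(par))))
  y <- as.vector(X)
  # GLS optimum per trait (design I_m (x) 1_n)
  Yw <- backsolve(ch, matrix(y, ncol = 1L), transpose = TRUE)
  Dw <- backsolve(ch, kronecker(diag(m), rep(1, n)), transpose = TRUE)
  A <- crossprod(Dw)
  theta <- tryCatch(solve(A, crossprod(Dw, Yw)), error = function(e) NULL)
  if (is.null(theta))
    return(list(loglik = -1e10, grad = rep(0, length(par))))
  rw <- as.vector(Yw - Dw %*% theta)
  quad <- sum(rw^2)
  ll <- -0.5 * (n * m * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
  if (!want_grad)
    return(list(loglik = ll, theta = as.vector(theta)))
  # dl/dC = -0.5 C^-1 + 0.5 u u',  u = C^-1 (y - D theta)
  u <- backsolve(ch, rw)
  P <- chol2inv(ch)
  G <- -0.5 * P + 0.5 * tcrossprod(u)
  d <- depth - tij
  idx <- function(k) (k - 1L) * n + seq_len(n)
  H <- matrix(0, m, m)           # H_kl = sum(G_blk(k,l) * S_kl)
  galpha <- numeric(m)
  for (k in seq_len(m)) for (l in k:m) {
    a <- pp$alpha[k] + pp$alpha[l]
    E <- exp(-a * d)
    if (ou_root == "stationary") {
      S <- E / a
      dSda <- -S * (d + 1 / a)
    } else {
      q <- -expm1(-a * tij)
      S <- E * q / a
      dSda <- E * (-d * q / a - q / a^2 + tij * (1 - q) / a)
    }
    Gkl <- G[idx(k), idx(l)]
    H[k, l] <- H[l, k] <- sum(Gkl * S)
    gblk <- pp$R[k, l] * sum(Gkl * dSda)
    galpha[k] <- galpha[k] + 2 * gblk
    if (l != k) galpha[l] <- galpha[l] + 2 * gblk
  }
  gL <- 2 * (H %*% pp$L)
  grad <- c(galpha * pp$alpha,                      # chain to log alpha
            diag(gL) * diag(pp$L),                  # chain to log diag L
            gL[lower.tri(gL)])
  list(loglik = ll, grad = grad, theta = as.vector(theta))
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' BM and EB exploit the matrix-normal structure of their likelihood: the
#' rate matrix and root state have closed-form maxima given the (for EB,
#' transformed) tree, so EB needs only a one-dimensional search over `r`.
#' The diagonal-alpha OU is fitted by bounded quasi-Newton (L-BFGS-B) with
#' analytic gradients over `log alpha` and the log-Cholesky factor of `R`,
#' with the optima profiled out by GLS, from `restarts` seeded starting
#' points.
#'
#' @param tree a `phylo` tree (>= 3 tips).
#' @param traits complete species-by-trait matrix, rownames = tip labels.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param restarts number of optimisation starts (OU only).
#' @param seed seed for restart jitter (OU only).
#' @param ou_root `"stationary"` or `"fixed"` root form for OU.
#' @param aicc_n AICc sample-size convention: `"cells"` (species x traits,
#'   the default) or `"species"`.
#' @param control passed to [stats::optim()] for OU.
#' @return an object of class `evo_fit`.
#' @export
fit_evo <- function(tree, traits, model = c("BM", "OU", "EB"),
                    restarts = 10L, seed = 1L,
                    ou_root = c("stationary", "fixed"),
                    aicc_n = c("cells", "species"), control = list()) {
  model <- match.arg(model)
  ou_root <- match.arg(ou_root)
  aicc_n <- match.arg(aicc_n)
  traits <- as.matrix(traits)
  mt <- match_tree_traits(tree, traits)
  X <- complete_trait_cases(mt$traits, action = "error")
  tree <- mt$tree
  n <- nrow(X); m <- ncol(X)
  if (n < 3L) stop("need at least 3 tips")
  tij <- ape::vcv(tree)
  depth <- max(diag(tij))
  fit <- list(model = model, n_species = n, m = m,
              trait_names = colnames(X), ou_root = ou_root)

  if (model == "BM") {
    pf <- mn_profile_fit(tij, X)
    fit$R <- pf$Rhat; fit$root_state <- pf$root; fit$loglik <- pf$loglik
    fit$p <- m + m * (m + 1) / 2
    fit$convergence <- list(code = 0L, restarts = 0L)
  } else if (model == "EB") {
    prof <- function(r) mn_profile_fit(eb_transform(tij, r), X)$loglik
    lo <- -30 / depth
    op <- stats::optimize(prof, lower = lo, upper = 0, maximum = TRUE,
                          tol = 1e-10)
    # the boundary r = 0 (exact BM) can beat the interior optimum
    if (prof(0) >= op$objective) op <- list(maximum = 0, objective = prof(0))
    pf <- mn_profile_fit(eb_transform(tij, op$maximum), X)
    fit$r <- op$maximum
    fit$R <- pf$Rhat; fit$root_state <- pf$root; fit$loglik <- pf$loglik
    fit$p <- m + m * (m + 1) / 2 + 1
    fit$convergence <- list(code = 0L, restarts = 0L)
  } else {
    ctl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)
    ctl$fnscale <- -1
    # stationary-matched start: alpha from a mid-depth halflife, R from the
    # sample covariance scaled back through R = (a_k + a_l) * S_kl
    a0 <- rep(log(2) / (depth / 2), m)
    S0 <- stats::cov(X)
    S0 <- S0 + diag(1e-8 * mean(diag(S0)) + 1e-12, m)
    R0 <- S0 * outer(a0, a0, "+")
    par0 <- ou_par_pack(a0, R0)
    lb <- c(rep(log(1e-8), m), rep(-30, m), rep(-1e3, m * (m - 1) / 2))
    ub <- c(rep(log(1e3), m), rep(30, m), rep(1e3, m * (m - 1) / 2))
    starts <- list(par0)
    if (restarts > 1L) {
      jit <- with_seed(seed, lapply(seq_len(restarts - 1L), function(i)
        par0 + stats::rnorm(length(par0), 0, 0.5)))
      starts <- c(starts, jit)
    }
    # optim calls fn and gr at the same point; cache the shared evaluation
    cache <- new.env(parent = emptyenv())
    evalf <- function(p, grad) {
      if (!is.null(cache$par) && identical(cache$par, p) &&
          (!grad || !is.null(cache$res$grad)))
        return(cache$res)
      res <- ou_profile_eval(p, X, tij, depth, ou_root, want_grad = grad)
      cache$par <- p; cache$res <- res
      res
    }
    best <- NULL; best_i <- NA_integer_; codes <- integer(0)
    for (i in seq_along(starts)) {
      op <- tryCatch(
        stats::optim(starts[[i]],
                     fn = function(p) evalf(p, FALSE)$loglik,
                     gr = function(p) evalf(p, TRUE)$grad,
                     method = "L-BFGS-B", lower = lb, upper = ub,
                     control = ctl),
        error = function(e) NULL)
      if (is.null(op)) { codes <- c(codes, -1L); next }
      codes <- c(codes, op$convergence)
      if (is.null(best) || op$value > best$value) { best <- op; best_i <- i }
    }
    if (is.null(best)) stop("OU optimisation failed on all restarts")
    pp <- ou_par_unpack(best$par, m)
    ev <- ou_profile_eval(best$par, X, tij, depth, ou_root)
    fit$R <- pp$R; fit$alpha <- pp$alpha; fit$theta <- ev$theta
    fit$loglik <- ev$loglik
    fit$p <- 2 * m + m * (m + 1) / 2
    fit$halflife <- log(2) / pp$alpha
    fit$convergence <- list(code = best$convergence,
                            restarts = length(starts),
                            best_restart = best_i, codes = codes)
  }
  dimnames(fit$R) <- list(fit$trait_names, fit$trait_names)
  fit$n_obs <- if (aicc_n == "cells") n * m else n
  fit$aicc_n <- aicc_n
  fit$AIC <- -2 * fit$loglik + 2 * fit$p
  fit$AICc <- aicc(fit$loglik, fit$p, fit$n_obs)
  fit$tree <- tree
  fit$traits <- X
  class(fit) <- "evo_fit"
  fit
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + (2 p^2 + 2 p) / (n - p - 1)`; infinite when `n <= p + 1`.
#'
#' @param loglik log-likelihood.
#' @param p free-parameter count.
#' @param n_obs sample size.
#' @return AICc value.
#' @export
aicc <- function(loglik, p, n_obs) {
  a <- -2 * loglik + 2 * p
  if (n_obs <= p + 1) return(Inf)
  a + (2 * p^2 + 2 * p) / (n_obs - p - 1)
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d species, %d trait(s)\n", x$model, x$n_species, x$m))
  cat(sprintf("  logLik %.4f  p %d  AIC %.4f  AICc %.4f (n_obs %d)\n",
              x$loglik, x$p, x$AIC, x$AICc, x$n_obs))
  if (x$model == "OU")
    cat(sprintf("  alpha: %s  (mean halflife %.3g My, %s root)\n",
                paste(signif(x$alpha, 3), collapse = ", "),
                mean(x$halflife), x$ou_root))
  if (x$model == "EB") cat(sprintf("  r: %.5g\n", x$r))
  invisible(x)
}

#' @export
summary.evo_fit <- function(object, ...) {
  out <- list(model = object$model, R = object$R, loglik = object$loglik,
              p = object$p, AIC = object$AIC, AICc = object$AICc,
              alpha = object$alpha, theta = object$theta, r = object$r,
              root_state = object$root_state, halflife = object$halflife,
              convergence = object$convergence)
  class(out) <- "summary.evo_fit"
  out
}

#' @export
print.summary.evo_fit <- function(x, ...) {
  cat(sprintf("%s model fit\n", x$model))
  cat(sprintf("logLik %.4f, p = %d, AIC %.4f, AICc %.4f\n",
              x$loglik, x$p, x$AIC, x$AICc))
  cat("Rate matrix R:\n"); print(signif(x$R, 4))
  if (!is.null(x$alpha)) {
    cat("alpha:\n"); print(signif(x$alpha, 4))
    cat("theta:\n"); print(signif(x$theta, 4))
    cat("halflife (My):\n"); print(signif(x$halflife, 4))
  }
  if (!is.null(x$r)) cat(sprintf("EB rate r: %.5g\n", x$r))
  invisible(x)
}

#' @export
logLik.evo_fit <- function(object, ...) {
  structure(object$loglik, df = object$p, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.evo_fit <- function(object, ...) {
  out <- c(as.vector(object$R[upper.tri(object$R, diag = TRUE)]))
  names(out) <- paste0("R.", which(upper.tri(object$R, diag = TRUE)))
  if (object$model == "OU")
    out <- c(out, stats::setNames(object$alpha,
                                  paste0("alpha.", seq_len(object$m))),
             stats::setNames(object$theta,
                             paste0("theta.", seq_len(object$m))))
  if (object$model == "EB") out <- c(out, r = object$r)
  if (!is.null(object$root_state))
    out <- c(out, stats::setNames(object$root_state,
                                  paste0("root.", seq_len(object$m))))
  out
}

#' Simulate trait matrices from a fitted model
#'
#' @param object an `evo_fit`.
#' @param nsim number of replicate matrices.
#' @param seed mandatory integer seed.
#' @param ... unused.
#' @return as [simulate_traits()].
#' @export
simulate.evo_fit <- function(object, nsim = 1L, seed, ...) {
  simulate_traits(object$tree, model = object$model, R = object$R,
                  alpha = object$alpha, theta = object$theta, r = object$r,
                  root_state = object$root_state, ou_root = object$ou_root,
                  seed = seed, nreps = nsim)
}

#' OU phylogenetic halflife
#'
#' `log(2)/alpha` per trait: the time for an OU trait to cover half the
#' distance to its optimum, in the tree's time units.
#'
#' @param alpha per-trait attraction rates (> 0), or an OU `evo_fit`.
#' @return named list with per-trait halflives and their mean.
#' @export
halflife <- function(alpha) {
  if (inherits(alpha, "evo_fit")) {
    if (alpha$model != "OU") stop("halflife is defined for OU fits only")
    alpha <- alpha$alpha
  }
  if (any(alpha <= 0)) stop("no stationary halflife: alpha must be > 0")
  hl <- log(2) / alpha
  list(halflife = hl, mean = mean(hl))
}

#' Rank fitted models by AICc
#'
#' @param fits list of `evo_fit` objects on identical data.
#' @return data frame sorted ascending by AICc (best first); exact ties are
#'   broken alphabetically by model name.
#' @export
aicc_rank <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "evo_fit")))
  n_obs <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n_obs)) != 1L)
    stop("fits were computed with inconsistent n_obs")
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    p = vapply(fits, `[[`, 0, "p"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    AICc = vapply(fits, `[[`, 0, "AICc"))
  tab <- tab[order(tab$AICc, tab$model), , drop = FALSE]
  tab$delta_AICc <- tab$AICc - tab$AICc[1L]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("rank", "model", "p", "loglik", "AIC", "AICc", "delta_AICc")]
}

#' BM-vs-OU model-selection power simulation
#'
#' Per replicate: draw a random correlated rate matrix, simulate BM tip
#' traits on the tree, fit multivariate BM and diagonal-alpha OU by maximum
#' likelihood, and record which model AICc selects.  Reports the fraction
#' of replicates selecting BM with its binomial standard error.
#'
#' @param tree a `phylo` tree, or `NULL` to generate a pure-birth tree.
#' @param n_tips,depth tree size used when `tree` is `NULL`.
#' @param m number of traits.
#' @param n_reps number of replicates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param restarts OU optimisation restarts per replicate.
#' @param rate_df Wishart degrees of freedom for the random trait
#'   correlation matrix.
#' @param aicc_n AICc sample-size convention (see [fit_evo()]).
#' @return list with `fraction_bm`, `se`, `n_reps`, `n_bm`, `failures`.
#' @export
model_selection_power <- function(tree = NULL, n_tips = 56L, depth = 180,
                                  m = 9L, n_reps = 200L, seed = 1L,
                                  restarts = 1L, rate_df = 2L * m,
                                  aicc_n = "cells") {
  stopifnot(n_reps >= 1L)
  if (is.null(tree)) tree <- generate_tree(n_tips, depth, seed = seed)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L * n_reps))
  n_bm <- 0L; failures <- 0L
  for (i in seq_len(n_reps)) {
    R <- with_seed(seeds[i], {
      W <- stats::rWishart(1L, df = rate_df, Sigma = diag(m))[, , 1L]
      stats::cov2cor(W)
    })
    X <- simulate_traits(tree, "BM", R = R, root_state = 0,
                         seed = seeds[n_reps + i])
    res <- tryCatch({
      bm <- fit_evo(tree, X, "BM", aicc_n = aicc_n)
      ou <- fit_evo(tree, X, "OU", restarts = restarts, seed = seeds[i],
                    aicc_n = aicc_n,
                    control = list(factr = 1e9, maxit = 300L))
      bm$AICc < ou$AICc
    }, error = function(e) NA)
    if (is.na(res)) failures <- failures + 1L
    else if (res) n_bm <- n_bm + 1L
  }
  used <- n_reps - failures
  frac <- n_bm / used
  list(fraction_bm = frac, se = sqrt(frac * (1 - frac) / used),
       n_reps = n_reps, n_bm = n_bm, failures = failures)
}
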