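# Phylogenetically conditioned descriptive statistics: GLS evolutionary
# covariance, partial correlations with edge-exclusion tests, phylogenetic
# PCA, bivariate and multivariate allometry, ancestral state estimation,
# and the partial-correlation power simulation.  All operations condition
# on the species correlation structure implied by a fitted evolutionary
# model (BM when no fit is supplied).

# n x n species correlation structure implied by a fitted model (or BM).
# For a diagonal-alpha OU fit the traits share a single structure built
# from the mean attraction rate.
species_structure <- function(tree, fit = NULL) {
  tij <- ape::vcv(tree)
  if (is.null(fit)) return(tij)
  stopifnot(inherits(fit, "evo_fit"))
  if (fit$model == "BM") tij
  else if (fit$model == "EB") eb_transform(tij, fit$r)
  else {
    a <- 2 * mean(fit$alpha)
    depth <- max(diag(tij))
    S <- exp(-a * (depth - tij))
    if (fit$ou_root == "fixed") S <- S * (-expm1(-a * tij))
    S
  }
}

#' Evolutionary covariance, correlations and partial correlations
#'
#' GLS estimate of the trait covariance conditional on the phylogeny:
#' `gls_mean = (1'C^-1 1)^-1 1'C^-1 X` and
#' `R_hat = (X - 1 mu)' C^-1 (X - 1 mu) / (n - 1)` with `C` the species
#' structure of the selected model.  Partial correlations come from the
#' precision matrix `O = R_hat^-1` as `-O_ij / sqrt(O_ii O_jj)`; each pair
#' is tested by the edge-exclusion deviance `-n log(1 - pcorr^2)` against
#' chi-squared with 1 degree of freedom (n = number of species).  A
#' Holm-adjusted column is reported alongside the raw p-values.
#'
#' @param tree a `phylo` tree.
#' @param traits complete species-by-trait matrix.
#' @param fit optional `evo_fit` providing the species structure (BM used
#'   when absent).
#' @return object of class `evo_covariance` with fields `gls_mean`,
#'   `R_hat`, `corr`, `pcorr`, `pvalues`, `pvalues_holm`, `n_species`.
#' @export
evolutionary_covariance <- function(tree, traits, fit = NULL) {
  traits <- as.matrix(traits)
  mt <- match_tree_traits(tree, traits)
  X <- complete_trait_cases(mt$traits)
  if (nrow(X) < nrow(mt$traits))
    mt <- match_tree_traits(ape::keep.tip(mt$tree, rownames(X)), X)
  X <- mt$traits
  n <- nrow(X); m <- ncol(X)
  C <- species_structure(mt$tree, fit)
  chC <- chol(C)
  Xw <- backsolve(chC, X, transpose = TRUE)
  onew <- backsolve(chC, rep(1, n), transpose = TRUE)
  mu <- as.vector(crossprod(onew, Xw)) / sum(onew^2)
  resw <- Xw - outer(onew, mu)
  R_hat <- crossprod(resw) / (n - 1)
  dimnames(R_hat) <- list(colnames(X), colnames(X))
  corr <- stats::cov2cor(R_hat)
  Om <- tryCatch(solve(R_hat), error = function(e)
    stop("singular evolutionary covariance"))
  s <- 1 / sqrt(diag(Om))
  pcorr <- -Om * outer(s, s)
  diag(pcorr) <- 1
  dev <- -n * log(pmax(1 - pcorr^2, .Machine$double.eps))
  pv <- stats::pchisq(dev, df = 1, lower.tail = FALSE)
  diag(pv) <- NA_real_
  ut <- upper.tri(pv)
  holm <- pv
  holm[ut] <- stats::p.adjust(pv[ut], method = "holm")
  holm[lower.tri(holm)] <- t(holm)[lower.tri(holm)]
  structure(list(gls_mean = stats::setNames(mu, colnames(X)), R_hat = R_hat,
                 corr = corr, pcorr = pcorr, pvalues = pv,
                 pvalues_holm = holm, n_species = n,
                 model = if (is.null(fit)) "BM" else fit$model),
            class = "evo_covariance")
}

#' @export
print.evo_covariance <- function(x, ...) {
  cat(sprintf("evolutionary covariance (%s structure, %d species)\n",
              x$model, x$n_species))
  cat("partial correlations:\n")
  print(signif(x$pcorr, 3))
  invisible(x)
}

#' Phylogenetic principal component analysis
#'
#' Eigen-decomposition of the GLS evolutionary covariance; scores are the
#' (ordinarily centred) deviations from the GLS mean projected on the
#' eigenvectors.  Component signs are fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @inheritParams evolutionary_covariance
#' @return object of class `phylo_pca` with `loadings` (columns = PCs),
#'   `scores`, `variance_fraction`, `gls_mean`.
#' @export
phylo_pca <- function(tree, traits, fit = NULL) {
  ec <- evolutionary_covariance(tree, traits, fit)
  eg <- eigen(ec$R_hat, symmetric = TRUE)
  V <- eg$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  traits <- as.matrix(traits)
  mt <- match_tree_traits(tree, traits)
  X <- complete_trait_cases(mt$traits)
  scores <- sweep(X, 2L, ec$gls_mean) %*% V
  colnames(V) <- colnames(scores) <- paste0("PC", seq_len(ncol(V)))
  rownames(V) <- colnames(X)
  vf <- pmax(eg$values, 0)
  structure(list(loadings = V, scores = scores,
                 variance_fraction = vf / sum(vf),
                 eigenvalues = eg$values, gls_mean = ec$gls_mean,
                 covariance = ec),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  cat("phylogenetic PCA\n")
  vf <- x$variance_fraction
  cat("variance fractions:", paste(sprintf("%.1f%%", 100 * vf[seq_len(min(4,
      length(vf)))]), collapse = ", "),
      if (length(vf) > 4) "..." else "", "\n")
  cat("PC1 loadings:\n"); print(signif(x$loadings[, 1L], 4))
  invisible(x)
}

#' Multivariate allometric slope from PC1 loadings
#'
#' The allometric scaling of trait `a` against trait `b` read from a
#' phylogeny-controlled PCA of log measurements: the ratio of their PC1
#' loadings.
#'
#' @param pca a [phylo_pca()] result, or a bare named vector of PC1
#'   loadings.
#' @param trait_a,trait_b trait names (numerator, denominator).
#' @return the slope `loading(trait_a) / loading(trait_b)`.
#' @export
allometry_multivariate <- function(pca, trait_a, trait_b) {
  l1 <- if (inherits(pca, "phylo_pca")) pca$loadings[, 1L] else pca
  if (!all(c(trait_a, trait_b) %in% names(l1)))
    stop("trait not found in PC1 loadings")
  if (abs(l1[[trait_b]]) < .Machine$double.eps)
    stop("zero denominator loading for ", trait_b)
  unname(l1[[trait_a]] / l1[[trait_b]])
}

#' Bivariate allometry under the phylogenetic model
#'
#' Linear-regression (GLS) and orthogonal (major-axis) slopes of trait `y`
#' on trait `x`, both conditioned on the phylogeny.  The GLS slope carries
#' an analytic confidence interval; the orthogonal slope (from the leading
#' eigenvector of the 2x2 evolutionary covariance) a seeded parametric
#' bootstrap interval.
#'
#' @inheritParams evolutionary_covariance
#' @param x,y trait names.
#' @param n_boot parametric bootstrap draws for the orthogonal slope CI.
#' @param seed seed for the bootstrap.
#' @param level confidence level.
#' @return object of class `allometry_fit` with `slope_lr`, `slope_or`,
#'   intercepts and confidence intervals.
#' @export
allometry_bivariate <- function(tree, traits, x, y, fit = NULL,
                                n_boot = 1000L, seed = 1L, level = 0.95) {
  traits <- as.matrix(traits)
  if (!all(c(x, y) %in% colnames(traits))) stop("trait not found")
  mt <- match_tree_traits(tree, traits[, c(x, y), drop = FALSE])
  X <- complete_trait_cases(mt$traits)
  n <- nrow(X)
  if (stats::var(X[, 1L]) == 0) stop("zero variance in ", x)
  C <- species_structure(mt$tree, fit)
  chC <- chol(C)
  Dw <- backsolve(chC, cbind(1, X[, 1L]), transpose = TRUE)
  yw <- backsolve(chC, X[, 2L], transpose = TRUE)
  A <- crossprod(Dw)
  beta <- solve(A, crossprod(Dw, yw))
  res <- yw - Dw %*% beta
  sigma2 <- sum(res^2) / (n - 2)
  se <- sqrt(sigma2 * diag(solve(A)))
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  # GLS trait moments (no precision inversion: exact collinearity allowed)
  Xw <- backsolve(chC, X, transpose = TRUE)
  onew2 <- backsolve(chC, rep(1, n), transpose = TRUE)
  mu <- as.vector(crossprod(onew2, Xw)) / sum(onew2^2)
  R_hat <- crossprod(Xw - outer(onew2, mu)) / (n - 1)
  or_slope <- function(S) {
    v <- eigen(S, symmetric = TRUE)$vectors[, 1L]
    v[2L] / v[1L]
  }
  slope_or <- or_slope(R_hat)
  # parametric bootstrap: matrix-normal draws with the estimated trait
  # covariance across the same species structure
  chR <- chol(R_hat + diag(1e-12 * max(diag(R_hat)), 2L))
  onew <- backsolve(chC, rep(1, n), transpose = TRUE)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      Z <- matrix(stats::rnorm(n * 2L), n, 2L)
      Xbw <- Z %*% chR             # whitened centred draw across species
      mub <- as.vector(crossprod(onew, Xbw)) / sum(onew^2)
      ecb <- crossprod(Xbw - outer(onew, mub)) / (n - 1)
      or_slope(ecb)
    }, numeric(1L))
  })
  ci_or <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                           names = FALSE)
  structure(list(x = x, y = y, n = n,
                 slope_lr = beta[2L], intercept_lr = beta[1L],
                 ci_lr = c(beta[2L] - tq * se[2L], beta[2L] + tq * se[2L]),
                 slope_or = slope_or,
                 intercept_or = unname(mu[2L] - slope_or * mu[1L]),
                 ci_or = ci_or, level = level),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("allometry %s ~ %s (n = %d)\n", x$y, x$x, x$n))
  cat(sprintf("  LR slope %.4f  [%.4f, %.4f]\n", x$slope_lr,
              x$ci_lr[1L], x$ci_lr[2L]))
  cat(sprintf("  OR slope %.4f  [%.4f, %.4f]\n", x$slope_or,
              x$ci_or[1L], x$ci_or[2L]))
  invisible(x)
}

#' Ancestral state estimation by conditional Gaussian
#'
#' Internal-node values of a scalar character (typically a PC score) under
#' the fitted model: tips and internal nodes are jointly Gaussian with the
#' model's node covariance structure; ancestral estimates are the
#' conditional means of the internal nodes given the tips, with conditional
#' variances scaled by the GLS variance estimate.
#'
#' @param tree a `phylo` tree.
#' @param values named per-tip numeric vector.
#' @param fit optional `evo_fit` (BM structure when absent).
#' @return data frame with `node` (ape node ids, internal nodes), the root
#'   first, `estimate` and `variance`.
#' @export
ancestral_states <- function(tree, values, fit = NULL) {
  n <- ape::Ntip(tree)
  if (is.null(names(values))) {
    if (length(values) != n) stop("values must be named by tip label")
    names(values) <- tree$tip.label
  }
  if (!all(tree$tip.label %in% names(values)))
    stop("missing values for tips: ",
         paste(setdiff(tree$tip.label, names(values)), collapse = ", "))
  v <- values[tree$tip.label]
  nn <- tree$Nnode
  all_ids <- seq_len(n + nn)
  dep <- ape::node.depth.edgelength(tree)
  D <- ape::dist.nodes(tree)
  shared <- (outer(dep, dep, "+") - D) / 2   # root-to-MRCA path lengths
  S <- if (is.null(fit) || fit$model == "BM") shared
  else if (fit$model == "EB") eb_transform(shared, fit$r)
  else {
    a <- 2 * mean(fit$alpha)
    depth <- max(dep[seq_len(n)])
    Sx <- exp(-a * D / 2) # stationary OU: exponential in tree distance
    if (fit$ou_root == "fixed")
      Sx <- exp(-a * (outer(dep, dep, "+") / 2 - shared)) *
        (-expm1(-a * shared)) / pmax(a, 1e-14)
    Sx
  }
  tips <- seq_len(n)
  ints <- (n + 1L):(n + nn)
  Stt <- S[tips, tips]
  # GLS mean and variance scale from the tips
  chS <- chol(Stt + diag(1e-12 * max(diag(Stt)), n))
  vw <- backsolve(chS, v, transpose = TRUE)
  onew <- backsolve(chS, rep(1, n), transpose = TRUE)
  mu <- sum(onew * vw) / sum(onew^2)
  sig2 <- sum((vw - mu * onew)^2) / (n - 1)
  K <- S[ints, tips, drop = FALSE]
  W <- K %*% chol2inv(chS)        # W = K Stt^-1
  est <- as.vector(mu + W %*% (v - mu))
  # conditional variance plus the universal-kriging term for the
  # estimated GLS mean
  varc <- sig2 * pmax(diag(S[ints, ints, drop = FALSE]) -
                        rowSums(W * K) +
                        (1 - rowSums(W))^2 / sum(onew^2), 0)
  data.frame(node = ints, estimate = est, variance = varc)
}

#' Power of the edge-exclusion test for partial correlations
#'
#' For each requested partial-correlation level, builds a trait covariance
#' whose (1,2) partial correlation equals the level (off-target partial
#' correlations set to a small nuisance value), simulates traits under the
#' model's species structure, applies the edge-exclusion test to the
#' target pair, and reports the rejection fraction.
#'
#' @param tree a `phylo` tree.
#' @param levels target partial correlations in (-1, 1).
#' @param m number of traits (>= 3).
#' @param n_reps replicates per level.
#' @param alpha_level test size.
#' @param nuisance off-target partial correlation magnitude.
#' @param fit optional `evo_fit` fixing the species structure.
#' @param seed master seed.
#' @return data frame with `level`, `power`, `se`.
#' @export
partial_correlation_power <- function(tree, levels, m = 4L, n_reps = 1000L,
                                      alpha_level = 0.05, nuisance = 0.05,
                                      fit = NULL, seed = 1L) {
  stopifnot(all(abs(levels) < 1), m >= 3L)
  C <- species_structure(tree, fit)
  n <- nrow(C)
  chC <- chol(C)
  out <- data.frame(level = levels, power = NA_real_, se = NA_real_)
  for (iL in seq_along(levels)) {
    Om <- matrix(-nuisance, m, m)
    Om[1L, 2L] <- Om[2L, 1L] <- -levels[iL]
    diag(Om) <- 1
    ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop("infeasible (non-PD) partial correlation structure at level ",
           levels[iL])
    R <- stats::cov2cor(solve(Om))
    chR <- chol(R)
    rej <- with_seed(seed + iL, {
      vapply(seq_len(n_reps), function(b) {
        Z <- matrix(stats::rnorm(n * m), n, m)
        X <- t(chC) %*% Z %*% chR
        Xw <- backsolve(chC, X, transpose = TRUE)
        onew <- backsolve(chC, rep(1, n), transpose = TRUE)
        mu <- as.vector(crossprod(onew, Xw)) / sum(onew^2)
        Rh <- crossprod(Xw - outer(onew, mu)) / (n - 1)
        O <- solve(Rh)
        pc <- -O[1L, 2L] / sqrt(O[1L, 1L] * O[2L, 2L])
        dev <- -n * log(max(1 - pc^2, .Machine$double.eps))
        stats::pchisq(dev, 1, lower.tail = FALSE) < alpha_level
      }, logical(1L))
    })
    p <- mean(rej)
    out$power[iL] <- p
    out$se[iL] <- sqrt(p * (1 - p) / n_reps)
  }
  out
}
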