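# Seeded generators for ultrametric trees and multivariate trait matrices
# drawn from the exact tip distribution implied by a BM/OU/EB model.

#' Generate a pure-birth ultrametric tree
#'
#' A Yule tree with `n_tips` tips, rescaled to total root-to-tip depth
#' `depth` (millions of years).  Tip labels are `sp01`, `sp02`, ...
#'
#' @param n_tips number of tips (>= 2).
#' @param depth root-to-tip depth in My.
#' @param seed mandatory integer seed.
#' @return an ultrametric `phylo` tree.
#' @export
generate_tree <- function(n_tips, depth = 180, seed) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  stopifnot(depth > 0)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$edge.length <- tree$edge.length * (depth / tree_depth(tree))
  tree$tip.label <- sprintf("sp%0*d", nchar(as.character(n_tips)),
                            seq_len(n_tips))
  tree
}

#' Simulate correlated traits on a tree under BM, OU or EB
#'
#' Tip values are drawn from the exact multivariate normal distribution
#' implied by the model (mean and covariance from [model_covariance()]),
#' via a Cholesky factorisation — not by Euler stepping along branches.
#'
#' @param tree a `phylo` tree (ultrametric required for the stationary-root
#'   OU form).
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param R m-by-m symmetric positive-definite trait rate matrix.
#' @param alpha per-trait OU attraction rates (>= 0), recycled to m.
#' @param theta per-trait OU optima, recycled to m.
#' @param r EB exponential rate (<= 0).
#' @param root_state per-trait root mean for BM/EB, recycled to m.
#' @param ou_root `"stationary"` (root drawn from the stationary
#'   distribution) or `"fixed"` (root clamped at `theta`).
#' @param seed mandatory integer seed.
#' @param nreps number of independent replicate matrices.
#' @return a species-by-trait matrix (rownames = tip labels), or an
#'   `n x m x nreps` array when `nreps > 1`.
#' @export
simulate_traits <- function(tree, model = c("BM", "OU", "EB"), R,
                            alpha = NULL, theta = NULL, r = NULL,
                            root_state = 0,
                            ou_root = c("stationary", "fixed"),
                            seed, nreps = 1L) {
  model <- match.arg(model)
  ou_root <- match.arg(ou_root)
  spec <- evo_spec(model, R = R, alpha = alpha, theta = theta, r = r,
                   root_state = root_state, ou_root = ou_root)
  mc <- model_covariance(tree, spec)
  n <- ape::Ntip(tree); m <- nrow(spec$R)
  L <- t(chol(mc$cov + diag(1e-12 * mean(diag(mc$cov)), nrow(mc$cov))))
  z <- with_seed(seed, matrix(stats::rnorm(n * m * nreps), n * m, nreps))
  draws <- mc$mean + L %*% z
  tn <- colnames(spec$R) %||% paste0("trait", seq_len(m))
  if (nreps == 1L) {
    out <- matrix(draws[, 1L], n, m, dimnames = list(tree$tip.label, tn))
    out
  } else {
    arr <- array(draws, dim = c(n, m, nreps),
                 dimnames = list(tree$tip.label, tn, NULL))
    arr
  }
}
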