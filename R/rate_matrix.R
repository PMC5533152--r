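#' Log-likelihood of multivariate Brownian motion on a tree
#'
#' Matrix-normal log density of an n x p tip trait matrix under Brownian
#' motion with root state `a` and evolutionary rate matrix `R`:
#' \deqn{\log L = -\tfrac12\{ np\log 2\pi + p\log|C| + n\log|R| +
#'   \mathrm{tr}[R^{-1}(X-1a^\top)^\top C^{-1}(X-1a^\top)]\}}
#' where C is the phylogenetic VCV of the tree. Under BM the variance
#' accumulated by a trait over a time interval is the interval length times
#' the rate sigma^2, which is exactly what C (time) and R (rate) encode.
#'
#' All linear algebra runs through Cholesky factors; C^-1 is never formed.
#'
#' @param tree Rooted `phylo` with branch lengths; ignored if `C` is given.
#' @param X Numeric matrix (n tips x p traits) with species rownames, or a
#'   named vector for p = 1.
#' @param a Root state vector, length p.
#' @param R p x p symmetric positive-definite rate matrix (a scalar for p = 1).
#' @param C Optional precomputed phylogenetic VCV (tips in rownames).
#' @return The log-likelihood (a scalar).
#' @export
bm_loglik <- function(tree = NULL, X, a, R, C = NULL) {
  if (is.null(C)) C <- phylo_vcv(tree)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(names(X), NULL))
  R <- as.matrix(R)
  X <- align_to_tips(X, fake_tree_for(rownames(C)), "trait matrix")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(a) == p, nrow(R) == p, ncol(R) == p)
  if (max(abs(R - t(R))) > 1e-12 * max(1, max(abs(R))))
    stop("R must be symmetric")
  LR <- tryCatch(chol(R), error = function(e) stop("R is not positive definite"))
  LC <- chol(C)
  logdetC <- 2 * sum(log(diag(LC)))
  logdetR <- 2 * sum(log(diag(LR)))
  E <- X - tcrossprod(rep(1, n), a)          # n x p residuals about the root
  W <- backsolve(LC, E, transpose = TRUE)    # C^{-1/2} E
  Q <- crossprod(W)                          # E' C^-1 E
  tr_term <- sum(diag(backsolve(LR, backsolve(LR, Q, transpose = TRUE))))
  -0.5 * (n * p * log(2 * pi) + p * logdetC + n * logdetR + tr_term)
}

# minimal stand-in so align_to_tips can be reused with a plain label set
fake_tree_for <- function(labels) list(tip.label = labels)

#' Closed-form ML fit of the evolutionary rate matrix
#'
#' Maximum-likelihood estimation of the root state vector and the p x p
#' evolutionary rate matrix of multivariate Brownian motion on a single tree,
#' in closed form:
#' \deqn{\hat a = (1^\top C^{-1}1)^{-1}1^\top C^{-1}X, \quad
#'       \hat R = (X-1\hat a^\top)^\top C^{-1}(X-1\hat a^\top)/n.}
#' The diagonal of R holds the trait rates (sigma^2 per unit time); the
#' off-diagonal the evolutionary covariance, from which the evolutionary
#' Pearson correlation r is derived. ML (1/n) scaling is used, matching the
#' likelihood above; AICc uses k = p + p(p+1)/2 parameters (k = 5 for p = 2)
#' and the number of tips as sample size.
#'
#' @param tree Rooted `phylo` with branch lengths; ignored if `C` is given.
#' @param X n x p trait matrix with species rownames (p = 2 is the supported
#'   surface; internals are written for general p).
#' @param C Optional precomputed phylogenetic VCV.
#' @return An object of class `rate_matrix_fit`: list with elements `R`, `a`,
#'   `logLik`, `k`, `AICc`, `r` (for p = 2), `n`, `p`.
#' @examples
#' tr <- simulate_tree(20, seed = 1)
#' X <- simulate_bm_traits(tr, a = c(0, 0), R = matrix(c(1, .5, .5, 1), 2), seed = 2)
#' fit_rate_matrix(tr, X)$r
#' @export
fit_rate_matrix <- function(tree = NULL, X, C = NULL) {
  if (is.null(C)) C <- phylo_vcv(tree)
  if (is.null(dim(X))) stop("X must be a matrix with one column per trait")
  X <- align_to_tips(as.matrix(X), fake_tree_for(rownames(C)), "trait matrix")
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 tips")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("trait column(s) ", paste(which(sds == 0), collapse = ", "),
         " are constant; the evolutionary correlation is undefined")
  LC <- chol(C)
  one <- rep(1, n)
  W1 <- backsolve(LC, one, transpose = TRUE)
  WX <- backsolve(LC, X, transpose = TRUE)
  a_hat <- drop(crossprod(W1, WX)) / sum(W1^2)
  E <- X - tcrossprod(one, a_hat)
  WE <- backsolve(LC, E, transpose = TRUE)
  R_hat <- crossprod(WE) / n
  dimnames(R_hat) <- list(colnames(X), colnames(X))
  ll <- tryCatch(
    bm_loglik(X = X, a = a_hat, R = R_hat, C = C),
    error = function(e) {
      # degenerate fit (e.g. collinear traits): evaluate with a tiny ridge so
      # the derived correlation is still reported
      warning("estimated rate matrix is singular; ",
              "log-likelihood evaluated with a 1e-10 ridge")
      eps <- 1e-10 * max(diag(R_hat))
      bm_loglik(X = X, a = a_hat, R = R_hat + diag(eps, p), C = C)
    })
  k <- p + p * (p + 1) / 2
  if (n <= k + 1)
    stop("AICc undefined for n = ", n, " tips with k = ", k,
         " parameters; use a larger tree")
  aicc <- 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
  r <- if (p == 2) correlation_from_R(R_hat) else NA_real_
  structure(
    list(R = R_hat, a = a_hat, logLik = ll, k = k, AICc = aicc, r = r,
         n = n, p = p),
    class = "rate_matrix_fit"
  )
}

#' Evolutionary correlation from a rate matrix
#'
#' @param R 2 x 2 (or p x p) rate matrix with strictly positive diagonal.
#' @param i,j Trait indices (defaults 1, 2).
#' @return Pearson evolutionary correlation `R[i,j]/sqrt(R[i,i]*R[j,j])`.
#' @examples
#' correlation_from_R(matrix(c(4, 2, 2, 4), 2)) # 0.5
#' @export
correlation_from_R <- function(R, i = 1, j = 2) {
  R <- as.matrix(R)
  if (R[i, i] <= 0 || R[j, j] <= 0)
    stop("zero (or negative) evolutionary variance; correlation undefined")
  R[i, j] / sqrt(R[i, i] * R[j, j])
}

#' @export
print.rate_matrix_fit <- function(x, ...) {
  cat("Brownian-motion rate matrix fit (", x$n, " tips, ", x$p, " traits)\n", sep = "")
  cat("  r =", format(x$r, digits = 4),
      " logLik =", format(x$logLik, digits = 6),
      " AICc =", format(x$AICc, digits = 6), "\n")
  invisible(x)
}

#' Fisher-z confidence interval for the evolutionary correlation
#'
#' Sampling interval for the per-tree estimate r-hat: atanh(r) +/- z * se with
#' se = 1/sqrt(n - 3). After GLS whitening the ML cross-products follow a
#' Wishart(n - 1) law regardless of tree shape, so the classical Fisher
#' approximation applies with the number of tips as n.
#'
#' @param object A `rate_matrix_fit`.
#' @param parm Ignored (only `r` has an interval).
#' @param level Confidence level, default 0.95.
#' @param ... Ignored.
#' @return Length-2 named vector (lower, upper).
#' @export
confint.rate_matrix_fit <- function(object, parm = "r", level = 0.95, ...) {
  z <- fisher_z(object$r)
  se <- 1 / sqrt(object$n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- fisher_inv(c(z - q * se, z + q * se))
  names(out) <- c("lower", "upper")
  out
}
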