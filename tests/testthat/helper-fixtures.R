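# Small fixtures shared across test files. Everything is built in code.

toy_tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n, len = 1, labels = sprintf("t%02d", seq_len(n))) {
  tr <- ape::stree(n, type = "star")
  tr$tip.label <- labels
  tr$edge.length <- rep(len, n)
  tr
}

# Independent brute-force GLS oracle: textbook normal equations with an
# explicit inverse, no Cholesky, no shared code with pgls_fit().
gls_oracle <- function(C, x, y) {
  Ci <- solve(C)
  D <- cbind(1, x)
  beta <- solve(t(D) %*% Ci %*% D) %*% t(D) %*% Ci %*% y
  e <- y - D %*% beta
  list(beta = drop(beta), resid = drop(e),
       sigma2 = drop(t(e) %*% Ci %*% e) / length(y))
}

# Independent multivariate-normal log-density oracle on vec(X) with the full
# Kronecker covariance R (x) C; O((np)^3), used only on tiny trees.
mvn_kron_loglik <- function(C, X, a, R) {
  n <- nrow(X); p <- ncol(X)
  Sigma <- kronecker(R, C)
  mu <- as.vector(rep(1, n) %o% a)   # vec(1 a')
  v <- as.vector(X) - mu
  -0.5 * (n * p * log(2 * pi) +
            as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
            drop(t(v) %*% solve(Sigma) %*% v))
}

random_pd_2x2 <- function() {
  A <- matrix(stats::rnorm(4), 2)
  crossprod(A) + diag(0.5, 2)
}
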