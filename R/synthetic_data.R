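#' Simulate an ultrametric Yule tree
#'
#' Pure-birth trees with branch lengths in time units (Ma). Tree-shape realism
#' beyond Yule is irrelevant to correctness testing here because every
#' downstream analysis conditions on the tree.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Speciation rate per lineage per Ma.
#' @param seed Optional integer seed.
#' @param tip_prefix Tip label prefix; labels are `<prefix><zero-padded i>`.
#' @return An ultrametric `phylo` with `$root.time` equal to the tree height.
#' @export
simulate_tree <- function(n_tips, birth = 1, seed = NULL, tip_prefix = "sp") {
  stopifnot(n_tips >= 2, birth > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  wid <- nchar(as.character(n_tips))
  tree$tip.label <- sprintf("%s%0*d", tip_prefix, wid, seq_len(n_tips))
  tree$root.time <- max(ape::node.depth.edgelength(tree))
  tree
}

#' Simulate correlated Brownian-motion traits on a tree
#'
#' Forward simulation: the root starts at `a`; along every branch each trait
#' vector gains an independent multivariate normal increment with covariance
#' (branch length x R). Simulation is branchwise in preorder — identical in
#' distribution to factorizing the full Kronecker covariance, at linear cost.
#'
#' @param tree `phylo` with branch lengths.
#' @param a Root state vector (length p).
#' @param R p x p symmetric positive-definite rate matrix (scalar for p = 1).
#' @param seed Optional integer seed.
#' @return n x p matrix of tip values, rows in canonical (lexicographic) tip
#'   order.
#' @export
simulate_bm_traits <- function(tree, a, R, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- as.matrix(R)
  p <- nrow(R)
  stopifnot(length(a) == p, !is.null(tree$edge.length))
  L <- tryCatch(t(chol(R)),
                error = function(e) stop("R_true must be positive definite"))
  n <- ape::Ntip(tree)
  states <- matrix(NA_real_, n + tree$Nnode, p)
  states[n + 1L, ] <- a
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    states[ch, ] <- states[par, ] +
      sqrt(tr$edge.length[i]) * drop(L %*% stats::rnorm(p))
  }
  X <- states[seq_len(n), , drop = FALSE]
  rownames(X) <- tree$tip.label
  colnames(X) <- paste0("trait", seq_len(p))
  X[order(rownames(X)), , drop = FALSE]
}

#' Overlay an allometric size component on residual traits
#'
#' Simulates a log10 size variable by univariate Brownian motion and builds
#' observed traits as `alpha_j + beta_j * size + residual_j`. This creates
#' exactly the structure that phylogenetic size-correction removes, so
#' [size_correct()] can be tested for recovery of the residuals.
#'
#' @param tree `phylo` with branch lengths.
#' @param resid n x 2 residual trait matrix (canonical tip order), e.g. from
#'   [simulate_bm_traits()].
#' @param alpha,beta Length-2 allometric intercepts and slopes (keel, ilium).
#' @param size_rate BM rate of the log10 size variable (per Ma).
#' @param size_root Root value of the log10 size variable.
#' @param seed Optional integer seed.
#' @return Data frame `species, log10_keel, log10_ilium, log10_size` with
#'   species rownames in canonical order.
#' @export
add_allometry <- function(tree, resid, alpha = c(0, 0), beta = c(1, 1),
                          size_rate = 0.004, size_root = 2, seed = NULL) {
  resid <- align_to_tips(resid, tree, "residual traits")
  size <- drop(simulate_bm_traits(tree, a = size_root,
                                  R = matrix(size_rate), seed = seed))
  size <- size[rownames(resid)]
  out <- data.frame(
    species = rownames(resid),
    log10_keel = alpha[1] + beta[1] * size + resid[, 1],
    log10_ilium = alpha[2] + beta[2] * size + resid[, 2],
    log10_size = size
  )
  rownames(out) <- out$species
  out
}

#' Perturb a tree sample by branch-length jitter
#'
#' Emulates a sample of alternative time-calibrations of one underlying tree:
#' each replicate multiplies every branch length by an independent lognormal
#' factor (median 1). Topology variation across the sample is deliberately
#' not emulated.
#'
#' @param tree The reference `phylo`.
#' @param n Number of replicate trees.
#' @param sdlog Lognormal sigma of the per-branch factor.
#' @param seed Optional integer seed.
#' @return A [tree_sample] of `n` trees.
#' @export
jitter_tree_sample <- function(tree, n, sdlog = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trees <- replicate(n, {
    tr <- tree
    tr$edge.length <- tr$edge.length *
      stats::rlnorm(length(tr$edge.length), 0, sdlog)
    tr$root.time <- NULL
    tr
  }, simplify = FALSE)
  as_tree_sample(trees)
}

#' Make a fossil (non-ultrametric) tree from a Yule tree
#'
#' Truncates each terminal branch by a Uniform(0, trim_frac x length) amount —
#' i.e. samples each fossil somewhere along its terminal lineage — and places
#' the root at `root_age` Ma before present, so all tips get positive
#' geological ages.
#'
#' @param n_tips,birth,seed As in [simulate_tree()].
#' @param root_age Age of the root in Ma before present.
#' @param trim_frac Maximum fraction of each terminal branch removed.
#' @return A non-ultrametric `phylo` with `$root.time = root_age`.
#' @export
simulate_fossil_tree <- function(n_tips, birth = 0.25, root_age = 131,
                                 trim_frac = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_tree(n_tips, birth)
  term <- tree$edge[, 2] <= ape::Ntip(tree)
  tree$edge.length[term] <- tree$edge.length[term] *
    (1 - trim_frac * stats::runif(sum(term)))
  tree$root.time <- root_age
  tree
}

#' Emit stratigraphic age ranges around a dated tree's true tip ages
#'
#' Strips branch lengths to a cladogram and, for each tip of true age t,
#' emits the range (t - u, t + u') with u, u' ~ Uniform(0, half_width),
#' truncated at 0. Every range contains its generating age by construction;
#' the truth is returned for recovery tests.
#'
#' @param tree Dated `phylo` (with `$root.time`).
#' @param half_width Maximum one-sided age uncertainty (Ma).
#' @param seed Optional integer seed.
#' @return List: `topology` (branch-length-free `phylo`), `ranges` (data frame
#'   `tip, max_date, min_date`), `true_ages` (named vector).
#' @export
simulate_fossil_ranges <- function(tree, half_width = 3, seed = NULL) {
  stopifnot(half_width >= 0)
  if (!is.null(seed)) set.seed(seed)
  truth <- tip_ages(tree)
  u_lo <- stats::runif(length(truth), 0, half_width)
  u_hi <- stats::runif(length(truth), 0, half_width)
  ranges <- data.frame(tip = names(truth),
                       max_date = truth + u_hi,
                       min_date = pmax(0, truth - u_lo))
  topology <- tree
  topology$edge.length <- NULL
  topology$root.time <- NULL
  list(topology = topology, ranges = ranges, true_ages = truth)
}

#' Synthetic analogue of the extant-bird study
#'
#' One call builds every input of the extant analysis at its study scale:
#' 137 species on an ultrametric tree (Yule, birth 0.065/Ma, height ~75 Ma),
#' a sample of `n_trees` alternative calibrations (branch-length jitter),
#' residual keel/ilium traits evolved under correlated BM with evolutionary
#' correlation `r_true` = 0.77, and an allometric body-mass overlay
#' (slope 1/3, log10 mass by BM). All defaults are the emulated study's
#' conditions; see the methods vignette for the rate choices.
#'
#' @param seed Master integer seed (drives tree, traits, size, jitter).
#' @param n_tips,n_trees Species and tree-sample sizes.
#' @param r_true Generating evolutionary correlation of the residuals.
#' @param resid_rate Residual BM rate (log10 units^2 per Ma) of both traits.
#' @param birth Yule speciation rate.
#' @return List: `trees` ([tree_sample]), `tree_true`, `traits` (data frame),
#'   `resid_true` (generating residual matrix), `r_true`.
#' @export
synthetic_extant_study <- function(seed = 1, n_tips = 137, n_trees = 1000,
                                   r_true = 0.77, resid_rate = 0.002,
                                   birth = 0.065) {
  R_true <- resid_rate * matrix(c(1, r_true, r_true, 1), 2)
  tree <- simulate_tree(n_tips, birth = birth, seed = seed)
  resid <- simulate_bm_traits(tree, a = c(0, 0), R = R_true,
                              seed = seed + 1L)
  traits <- add_allometry(tree, resid, alpha = c(0.87, 0.90),
                          beta = c(1 / 3, 1 / 3), size_rate = 0.004,
                          size_root = 2, seed = seed + 2L)
  trees <- jitter_tree_sample(tree, n_trees, sdlog = 0.1, seed = seed + 3L)
  list(trees = trees, tree_true = tree, traits = traits,
       resid_true = resid, r_true = r_true)
}

#' Synthetic analogue of the Mesozoic-bird study
#'
#' Builds the fossil analysis inputs at study scale: `n_tips` (default 10)
#' Early Cretaceous taxa on a non-ultrametric tree rooted ~131 Ma, keel/ilium
#' traits with correlation `r_true` = 0.90, femur length as the size overlay
#' (slope 1, length-on-length isometry), and stratigraphic ranges of
#' half-width 3 Ma around the true tip ages.
#'
#' @param seed Master integer seed.
#' @param n_tips Number of fossil taxa.
#' @param r_true Generating evolutionary correlation of the residuals.
#' @param resid_rate Residual BM rate (log10 units^2 per Ma).
#' @param half_width Stratigraphic age uncertainty half-width (Ma).
#' @return List: `tree_true`, `topology`, `ranges`, `traits`, `resid_true`,
#'   `true_ages`, `r_true`.
#' @export
synthetic_fossil_study <- function(seed = 1, n_tips = 10, r_true = 0.90,
                                   resid_rate = 0.005, half_width = 3) {
  R_true <- resid_rate * matrix(c(1, r_true, r_true, 1), 2)
  tree <- simulate_fossil_tree(n_tips, birth = 0.25, root_age = 131,
                               trim_frac = 0.8, seed = seed)
  resid <- simulate_bm_traits(tree, a = c(0, 0), R = R_true, seed = seed + 1L)
  traits <- add_allometry(tree, resid, alpha = c(-0.15, 0.05), beta = c(1, 1),
                          size_rate = 0.003, size_root = 1.6, seed = seed + 2L)
  fr <- simulate_fossil_ranges(tree, half_width = half_width, seed = seed + 3L)
  list(tree_true = tree, topology = fr$topology, ranges = fr$ranges,
       traits = traits, resid_true = resid, true_ages = fr$true_ages,
       r_true = r_true)
}
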