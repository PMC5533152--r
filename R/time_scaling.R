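#' Draw stochastic tip ages from stratigraphic ranges
#'
#' Each tip's age (time before present, Ma) is drawn independently from
#' Uniform(min_date, max_date), the standard treatment of stratigraphic age
#' uncertainty for fossil tips.
#'
#' @param ranges Data frame with columns `tip`, `max_date`, `min_date`
#'   (Ma before present, `max_date >= min_date >= 0`).
#' @param seed Optional integer seed for reproducibility.
#' @return Named numeric vector of ages (one per tip).
#' @export
draw_tip_ages <- function(ranges, seed = NULL) {
  validate_ranges(ranges)
  if (!is.null(seed)) set.seed(seed)
  ages <- stats::runif(nrow(ranges), min = ranges$min_date, max = ranges$max_date)
  stats::setNames(ages, ranges$tip)
}

validate_ranges <- function(ranges) {
  stopifnot(all(c("tip", "max_date", "min_date") %in% names(ranges)))
  if (anyDuplicated(ranges$tip))
    stop("duplicated tips in age-range table: ",
         paste(unique(ranges$tip[duplicated(ranges$tip)]), collapse = ", "))
  bad <- which(ranges$min_date > ranges$max_date)
  if (length(bad))
    stop("min_date > max_date for tip(s): ",
         paste(ranges$tip[bad], collapse = ", "))
  if (any(ranges$min_date < 0)) stop("negative stratigraphic dates")
  invisible(TRUE)
}

#' Node ages of a dated tree
#'
#' Ages are time before present; the tree must carry `$root.time` (set by the
#' time-scaling functions). Returned for tips then internal nodes, in ape's
#' node numbering.
#'
#' @param tree A `phylo` with branch lengths and `$root.time`.
#' @return Numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (is.null(tree$root.time))
    stop("tree has no $root.time; use basic_timescale()/equal_timescale() output")
  depths <- ape::node.depth.edgelength(tree)
  tree$root.time - depths
}

#' Tip ages of a dated tree
#' @param tree A `phylo` with `$root.time`.
#' @return Named numeric vector of tip ages (Ma before present).
#' @export
tip_ages <- function(tree) {
  ages <- node_ages(tree)[seq_len(ape::Ntip(tree))]
  stats::setNames(ages, tree$tip.label)
}

#' "Basic" a-posteriori time-scaling of a cladogram
#'
#' Dates every internal node at the oldest (maximum) age among its descendant
#' tips; branch lengths are parent age minus child age. This necessarily
#' produces zero-length branches wherever a node's age ties its oldest child,
#' which [equal_timescale()] subsequently removes.
#'
#' @param topology Rooted `phylo`; branch lengths, if any, are ignored.
#' @param ages Named numeric vector of tip ages (Ma before present), one per tip.
#' @return A `phylo` with branch lengths in Ma and `$root.time` set; some
#'   branch lengths may be exactly 0.
#' @export
basic_timescale <- function(topology, ages) {
  stopifnot(inherits(topology, "phylo"))
  # hard polytomies (incl. star topologies) are fine; only the
  # unrooted-binary node count is rejected
  if (!ape::is.rooted(topology) &&
      topology$Nnode == ape::Ntip(topology) - 2)
    stop("topology must be rooted")
  ages <- align_to_tips(ages, topology, "tip ages")[topology$tip.label]
  n <- ape::Ntip(topology)
  nn <- topology$Nnode
  node_age <- c(ages, rep(-Inf, nn))
  edge <- topology$edge
  # postorder: children before parents, so the max-descendant rule is one pass
  po <- ape::reorder.phylo(topology, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    par <- po[i, 1]; ch <- po[i, 2]
    node_age[par] <- max(node_age[par], node_age[ch])
  }
  out <- topology
  out$edge.length <- unname(node_age[edge[, 1]] - node_age[edge[, 2]])
  out$root.time <- unname(node_age[n + 1L])
  out
}

#' "Equal" zero-branch redistribution
#'
#' Removes the zero-length branches left by [basic_timescale()]: the root is
#' first pushed back by `root_extension`, then, proceeding from the root
#' toward the tips, every zero-length branch is eliminated by sliding its
#' child node earlier in time. The time is taken from the nearest ancestral
#' branch of positive length (the donor) and shared equally among the donor
#' and the contiguous chain of zero-length branches below it, so every branch
#' involved ends with the same positive length. Tip ages are never altered.
#'
#' When several zero-length chains hang off one donor, chains are resolved in
#' canonical order (toward the lexicographically smallest tip first), each
#' redistribution updating node ages before the next chain is handled.
#'
#' @param tree Output of [basic_timescale()] (branch lengths + `$root.time`).
#' @param root_extension Positive time (Ma) added basally before
#'   redistribution; default 1.
#' @return A `phylo` with all branch lengths strictly positive, identical tip
#'   ages, and updated `$root.time`.
#' @export
equal_timescale <- function(tree, root_extension = 1) {
  stopifnot(inherits(tree, "phylo"), root_extension > 0)
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  root <- n + 1L
  ages[root] <- ages[root] + root_extension
  edge <- ape::reorder.phylo(tree, "cladewise")$edge  # parents before children
  parent_of <- integer(n + tree$Nnode)
  parent_of[edge[, 2]] <- edge[, 1]
  children_of <- split(edge[, 2], factor(edge[, 1], levels = seq_len(n + tree$Nnode)))
  min_tip <- smallest_descendant_label(tree)
  tol <- 1e-12 * max(1, ages[root])

  repeat {
    zero_idx <- which(ages[edge[, 1]] - ages[edge[, 2]] <= tol)
    if (!length(zero_idx)) break
    ch <- edge[zero_idx[1], 2]            # first zero branch in preorder
    par <- edge[zero_idx[1], 1]
    # donor: nearest ancestral branch with positive length
    donor_ch <- par
    up_chain <- integer(0)                # zero-edge children between donor and ch
    while (donor_ch != root &&
           ages[parent_of[donor_ch]] - ages[donor_ch] <= tol) {
      up_chain <- c(donor_ch, up_chain)
      donor_ch <- parent_of[donor_ch]
    }
    if (donor_ch == root)
      stop("zero-length chain reaches the extended root; ",
           "increase root_extension (currently ", root_extension, ")")
    donor_par <- parent_of[donor_ch]
    # extend the chain tipward through zero branches, canonical order first
    down_chain <- ch
    repeat {
      kids <- children_of[[down_chain[length(down_chain)]]]
      zk <- kids[ages[down_chain[length(down_chain)]] - ages[kids] <= tol]
      if (!length(zk)) break
      down_chain <- c(down_chain, zk[which.min(min_tip[zk])])
    }
    path <- c(up_chain, down_chain)       # donor_ch's descendants down the chain
    path_nodes <- c(donor_ch, path)       # nodes whose ages move (last stays)
    L <- ages[donor_par] - ages[donor_ch]
    share <- L / length(path_nodes)       # donor + m chain branches, equal split
    keep <- path_nodes[length(path_nodes)]
    for (i in seq_along(path_nodes)[-length(path_nodes)])
      ages[path_nodes[i]] <- ages[donor_par] - i * share
    stopifnot(abs(ages[keep] - (ages[donor_par] - length(path_nodes) * share)) <= tol)
  }

  out <- tree
  out$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  out$root.time <- ages[root]
  out
}

# per node, the lexicographically smallest tip label in its subtree
# (used as the deterministic tie-break when chains fork)
smallest_descendant_label <- function(tree) {
  n <- ape::Ntip(tree)
  lab_rank <- rank(tree$tip.label, ties.method = "first")
  mt <- c(lab_rank, rep(Inf, tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    mt[po[i, 1]] <- min(mt[po[i, 1]], mt[po[i, 2]])
  mt
}

#' Stochastic calibration sample of time-scaled trees
#'
#' Repeats draw tip ages -> basic -> equal `n_draws` times, yielding the tree
#' sample over which the rate-matrix fit is iterated to propagate dating
#' uncertainty. Per-draw seeds are derived deterministically from the master
#' seed by draw index, so the sample is reproducible and order-independent.
#'
#' @param topology Rooted cladogram (`phylo`); branch lengths ignored.
#' @param ranges Age-range table (see [draw_tip_ages()]).
#' @param n_draws Number of calibrated trees (the reference analysis used 1,000).
#' @param root_extension Basal extension passed to [equal_timescale()].
#' @param seed Master integer seed.
#' @return A [tree_sample] of `n_draws` strictly-positive-branch trees.
#' @export
generate_calibration_sample <- function(topology, ranges, n_draws = 1000,
                                        root_extension = 1, seed = 1) {
  stopifnot(n_draws >= 1)
  validate_ranges(ranges)
  trees <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    draw_seed <- (seed + 104729 * i) %% 2147483647L
    trees[[i]] <- tryCatch({
      ages <- draw_tip_ages(ranges, seed = draw_seed)
      equal_timescale(basic_timescale(topology, ages), root_extension)
    }, error = function(e)
      stop("calibration draw ", i, ": ", conditionMessage(e), call. = FALSE))
  }
  as_tree_sample(trees)
}
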