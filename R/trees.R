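#' Parse one or more trees from Newick or NEXUS text
#'
#' Reads a single tree, a multi-tree Newick string/file (one tree per
#' semicolon-terminated statement), or a NEXUS `TREES` block, and returns a
#' validated [tree_sample]. All member trees must share an identical tip set;
#' tip labels are whitespace-normalized (trimmed, internal runs of whitespace
#' collapsed to `_`).
#'
#' @param text Newick/NEXUS text, or `NULL` if `file` is given.
#' @param file Path to a Newick or NEXUS file.
#' @return A `tree_sample`: a list of rooted `phylo` objects with identical
#'   tip sets, class `c("tree_sample", "multiPhylo")`.
#' @examples
#' ts <- parse_trees("((A:1,B:1):1,C:2); ((A:2,B:2):0.5,C:2.5);")
#' length(ts)
#' @export
parse_trees <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  is_nexus <- grepl("^\\s*#NEXUS", text, ignore.case = TRUE)
  trees <- tryCatch(
    {
      if (is_nexus) {
        tf <- tempfile(fileext = ".nex")
        on.exit(unlink(tf), add = TRUE)
        writeLines(text, tf)
        ape::read.nexus(tf)
      } else {
        check_newick_balance(text)
        ape::read.tree(text = text)
      }
    },
    error = function(e) stop("tree parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(trees)) stop("tree parse error: no tree could be read from input")
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, normalize_tip_labels)
  as_tree_sample(trees)
}

# Cheap structural pre-check so malformed Newick fails with a position,
# rather than with ape's opaque subscript errors.
check_newick_balance <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced parentheses: unmatched ')' at character ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth, " '(' left open at end of input",
         call. = FALSE)
  invisible(TRUE)
}

normalize_tip_labels <- function(tree) {
  lab <- trimws(tree$tip.label)
  lab <- gsub("^['\"]|['\"]$", "", lab)   # shed Newick label quoting
  lab <- trimws(lab)
  lab <- gsub("\\s+", "_", lab)
  tree$tip.label <- lab
  tree
}

#' Assemble a validated tree sample
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @return A `tree_sample` object.
#' @export
as_tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo")) stop("element ", i, " is not a phylo object")
    if (anyDuplicated(tr$tip.label))
      stop("tree ", i, ": duplicated tip labels: ",
           paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
      stop("tree ", i, ": negative branch lengths")
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)[-1]) {
    lab <- sort(trees[[i]]$tip.label)
    if (!identical(ref, lab)) {
      missing_here <- setdiff(ref, lab)
      extra_here <- setdiff(lab, ref)
      stop("tree ", i, " tip set differs from tree 1.\n",
           if (length(missing_here)) paste0("  absent in tree ", i, ": ",
                                            paste(missing_here, collapse = ", "), "\n") else "",
           if (length(extra_here)) paste0("  extra in tree ", i, ": ",
                                          paste(extra_here, collapse = ", ")) else "")
    }
  }
  structure(trees, class = c("tree_sample", "multiPhylo"))
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("tree_sample:", length(x), "tree(s),", length(x[[1]]$tip.label), "tips\n")
  invisible(x)
}

#' Write a tree sample as multi-line Newick
#'
#' @param trees A `tree_sample`, `multiPhylo`, or single `phylo`.
#' @param file Output path; `""` returns the Newick strings invisibly.
#' @return Character vector of Newick strings, invisibly.
#' @export
write_trees <- function(trees, file = "") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- vapply(trees, function(tr) ape::write.tree(tr), character(1))
  if (nzchar(file)) writeLines(out, file)
  invisible(out)
}

#' Phylogenetic variance-covariance matrix
#'
#' The among-tip covariance structure induced by Brownian motion on a rooted
#' tree with branch lengths in time units: entry (i, j) is the shared
#' root-to-MRCA path length of tips i and j; the diagonal holds root-to-tip
#' depths. Rows and columns follow the canonical (lexicographic) tip order so
#' that matrices from different trees over the same tip set are conformable.
#'
#' Zero-length branches are tolerated; if they make two tips covariance-
#' identical (C singular), a ridge of `1e-8 * max(diag(C))` is added with a
#' warning.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Symmetric positive-(semi)definite matrix with tip-label dimnames in
#'   lexicographic order.
#' @examples
#' phylo_vcv(parse_trees("((A:1,B:1):1,C:2);")[[1]])
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; the Brownian covariance is undefined")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  # polytomies are accepted as hard (the BM likelihood is well defined on
  # them), so a basal polytomy alone is not evidence of unrootedness; only
  # the unrooted-binary node count is rejected
  if (!ape::is.rooted(tree) && tree$Nnode == ape::Ntip(tree) - 2)
    stop("tree is unrooted; root it before computing the phylogenetic VCV")
  C <- ape::vcv.phylo(tree)
  ord <- order(rownames(C))
  C <- C[ord, ord, drop = FALSE]
  # coincident tips (identical rows) make C singular, sometimes only up to
  # floating-point noise, so a reciprocal-condition check backs up Cholesky
  ok <- tryCatch({ chol(C); rcond(C) > 1e-12 }, error = function(e) FALSE)
  if (!ok) {
    warning("phylogenetic VCV is singular (coincident tips); ",
            "adding ridge 1e-8 * max(diag)")
    C <- C + diag(1e-8 * max(diag(C)), nrow(C))
  }
  C
}

# Align rows of a matrix/data.frame (or a named vector) to the canonical
# lexicographic tip order of `tree`, erroring on mismatch.
align_to_tips <- function(x, tree, what = "data") {
  tips <- sort(tree$tip.label)
  nm <- if (is.null(dim(x))) names(x) else rownames(x)
  if (is.null(nm)) stop(what, " must carry species names (rownames or names)")
  missing_sp <- setdiff(tips, nm)
  if (length(missing_sp))
    stop(what, " lacks rows for tips: ", paste(missing_sp, collapse = ", "))
  if (is.null(dim(x))) x[tips] else x[tips, , drop = FALSE]
}
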