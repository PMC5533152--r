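#' Collapse per-specimen measurements to per-species log10 values
#'
#' Arithmetic means are taken per species on the measurement scale (mm), and
#' only then log10-transformed, so multi-specimen species are represented by
#' the mean individual, not the geometric mean.
#'
#' @param specimens Data frame with a `species` column and one or more numeric
#'   measurement columns in mm.
#' @param measure_cols Names of the measurement columns; default: every
#'   numeric column.
#' @return Data frame with one row per species: `species`, `n_specimens`, and
#'   one `log10_<col>` column per measurement.
#' @examples
#' average_specimens(data.frame(species = c("a", "a"), keel = c(40, 60)))
#' @export
average_specimens <- function(specimens, measure_cols = NULL) {
  stopifnot("species" %in% names(specimens))
  if (is.null(measure_cols))
    measure_cols <- names(specimens)[vapply(specimens, is.numeric, logical(1))]
  for (cl in measure_cols) {
    bad <- which(!is.finite(specimens[[cl]]) | specimens[[cl]] <= 0)
    if (length(bad))
      stop("nonpositive or missing ", cl, " for specimen row(s) ",
           paste(bad, collapse = ", "))
  }
  sp <- factor(specimens$species, levels = unique(specimens$species))
  out <- data.frame(species = levels(sp),
                    n_specimens = as.integer(table(sp)))
  for (cl in measure_cols)
    out[[paste0("log10_", cl)]] <-
      log10(tapply(specimens[[cl]], sp, mean)[out$species])
  rownames(out) <- out$species
  out
}

#' Phylogenetic generalized least squares regression
#'
#' GLS fit of `y` on `x` (with intercept) under the Brownian-motion covariance
#' C of the tree: beta-hat = (D' C^-1 D)^-1 D' C^-1 y with design D = [1, x].
#' The residuals are the phylogenetically size-corrected trait when `x` is a
#' size variable. sigma^2 uses ML (1/n) scaling.
#'
#' @param tree Rooted `phylo`; ignored if `C` supplied.
#' @param x,y Named numeric vectors aligned to the tree tips.
#' @param C Optional precomputed phylogenetic VCV.
#' @return List of class `pgls_fit`: `coefficients` (intercept, slope),
#'   `residuals` (named, canonical tip order), `sigma2`, `logLik`, `n`.
#' @export
pgls_fit <- function(tree = NULL, x, y, C = NULL) {
  if (is.null(C)) C <- phylo_vcv(tree)
  tips <- rownames(C)
  x <- align_to_tips(x, fake_tree_for(tips), "x")
  y <- align_to_tips(y, fake_tree_for(tips), "y")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n <- length(y)
  D <- cbind(intercept = 1, slope = x)
  LC <- chol(C)
  WD <- backsolve(LC, D, transpose = TRUE)
  Wy <- backsolve(LC, y, transpose = TRUE)
  XtX <- crossprod(WD)
  if (rcond(XtX) < 1e-12)
    stop("size variable has no variance (singular GLS design)")
  beta <- drop(solve(XtX, crossprod(WD, Wy)))
  e <- drop(y - D %*% beta)
  We <- backsolve(LC, e, transpose = TRUE)
  sigma2 <- sum(We^2) / n
  logdetC <- 2 * sum(log(diag(LC)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetC + n)
  names(e) <- tips
  structure(list(coefficients = beta, residuals = e, sigma2 = sigma2,
                 logLik = ll, n = n),
            class = "pgls_fit")
}

#' Phylogenetic size-correction of a trait table
#'
#' Regresses each focal log10 trait on the log10 size variable by independent
#' phylogenetic GLS fits on the same tree and returns the residuals — the
#' size-corrected traits used downstream by the rate-matrix fit.
#'
#' @param tree Rooted `phylo`; ignored if `C` supplied.
#' @param traits Data frame with species rownames (or a `species` column),
#'   containing `trait_cols` and `size_col`.
#' @param trait_cols Columns to correct (default `log10_keel`, `log10_ilium`).
#' @param size_col Size regressor column (default `log10_size`): log10 body
#'   mass for extant datasets, log10 femur length for fossil datasets.
#' @param C Optional precomputed phylogenetic VCV.
#' @return n x length(trait_cols) matrix of residuals, rows in canonical tip
#'   order, columns named `<trait>_resid`.
#' @export
size_correct <- function(tree = NULL, traits,
                         trait_cols = c("log10_keel", "log10_ilium"),
                         size_col = "log10_size", C = NULL) {
  if (is.null(C)) C <- phylo_vcv(tree)
  if ("species" %in% names(traits) && is.null(rownames(traits)))
    rownames(traits) <- traits$species
  if (!is.null(traits[["species"]])) rownames(traits) <- traits$species
  missing_cols <- setdiff(c(trait_cols, size_col), names(traits))
  if (length(missing_cols))
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "))
  traits <- align_to_tips(traits, fake_tree_for(rownames(C)), "trait table")
  x <- stats::setNames(traits[[size_col]], rownames(traits))
  out <- sapply(trait_cols, function(cl) {
    y <- stats::setNames(traits[[cl]], rownames(traits))
    pgls_fit(x = x, y = y, C = C)$residuals
  })
  colnames(out) <- paste0(sub("^log10_", "", trait_cols), "_resid")
  out
}
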