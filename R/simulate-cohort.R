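# Synthetic cohort tables: per-subject Gaussian features with stated group
# means/SDs and optional target Pearson correlations between feature pairs
# (Gaussian copula), mirroring the structure of a grouped measurement table
# with marker-behaviour correlation links.

#' Specify a synthetic cohort
#'
#' @param groups List of groups, each a list with `label`, `n`, and named
#'   numeric vectors `means` and `sds` (one entry per feature; all groups
#'   must use the same feature set).
#' @param correlations Optional list of links, each `list(a, b, r)` giving
#'   two feature names and a target Pearson correlation (attained in
#'   expectation; exactly at `|r| = 1`).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, correlations = list(), seed = 0) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  feats <- names(groups[[1]]$means)
  for (g in groups) {
    if (is.null(g$label) || !nzchar(g$label))
      stop("cohort_spec: every group needs a non-empty label", call. = FALSE)
    if (is.null(g$n) || g$n < 2)
      stop("cohort_spec: every group needs n >= 2", call. = FALSE)
    if (!identical(sort(names(g$means)), sort(feats)) ||
        !identical(sort(names(g$sds)), sort(feats)))
      stop("cohort_spec: groups must share one feature set with means and sds",
           call. = FALSE)
    if (any(g$sds < 0))
      stop("cohort_spec: sds must be >= 0", call. = FALSE)
  }
  for (l in correlations) {
    if (!all(c(l$a, l$b) %in% feats))
      stop("cohort_spec: correlation link names unknown feature", call. = FALSE)
    if (abs(l$r) > 1)
      stop("cohort_spec: |r| must be <= 1", call. = FALSE)
  }
  structure(list(groups = groups, correlations = correlations, seed = seed),
            class = "cohort_spec")
}

# Correlation matrix implied by the links; identity elsewhere.
cohort_cor_matrix <- function(feats, links) {
  R <- diag(length(feats))
  dimnames(R) <- list(feats, feats)
  for (l in links) {
    R[l$a, l$b] <- l$r
    R[l$b, l$a] <- l$r
  }
  R
}

#' Draw a per-subject measurement table from a cohort specification
#'
#' Features are Gaussian at the group's stated means/SDs; correlated pairs
#' are generated through a Gaussian copula whose correlation matrix carries
#' the target r values. Reproducible under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with columns `subject`, `group`, and one column per
#'   feature.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  feats <- names(spec$groups[[1]]$means)
  R <- cohort_cor_matrix(feats, spec$correlations)
  eig <- eigen(R, symmetric = TRUE)
  if (any(eig$values < -1e-8))
    stop("simulate_cohort: correlation matrix is not positive semi-definite",
         call. = FALSE)
  L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), nrow = length(feats))
  set.seed(spec$seed)
  rows <- lapply(spec$groups, function(g) {
    Z <- matrix(rnorm(g$n * length(feats)), g$n) %*% t(L)
    X <- sweep(Z, 2, g$sds[feats], `*`)
    X <- sweep(X, 2, g$means[feats], `+`)
    colnames(X) <- feats
    data.frame(subject = sprintf("%s_%02d", g$label, seq_len(g$n)),
               group = g$label, X, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
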