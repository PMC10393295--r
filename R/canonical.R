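# Cohort-level canonical pattern: PCA over flattened per-animal CSD patterns
# (PC 1 = canonical pattern) and the plain-average alternative.

#' Stack per-animal patterns into a cohort matrix
#'
#' Each pattern is flattened in depth-major order (depth index varies
#' fastest, i.e. R column-major order of the depth x time matrix) into one
#' row, yielding an N x (M*K) matrix.
#'
#' @param patterns named list of [grid_pattern()]s on a common grid.
#' @return Numeric matrix with one row per pattern, the grid axes attached as
#'   attributes `depth_axis` and `time_axis`, and row names from the list.
#' @export
stack_cohort <- function(patterns) {
  if (length(patterns) < 1) invalid_argument("no patterns to stack")
  ref <- patterns[[1]]
  for (i in seq_along(patterns))
    if (!same_grid(ref, patterns[[i]]))
      invalid_argument(sprintf("pattern %s is not on the common grid",
                               names(patterns)[i] %||% as.character(i)))
  mat <- do.call(rbind, lapply(patterns, function(p) as.vector(p$values)))
  rownames(mat) <- names(patterns)
  attr(mat, "depth_axis") <- ref$depth_axis
  attr(mat, "time_axis") <- ref$time_axis
  mat
}

#' Reshape a flattened pattern vector back to a grid
#'
#' Inverse of the flattening used by [stack_cohort()].
#'
#' @param v numeric vector of length M*K (depth-major).
#' @param depth_axis,time_axis grid axes.
#' @return A [csd_pattern()].
#' @export
unflatten_pattern <- function(v, depth_axis, time_axis) {
  csd_pattern(matrix(v, length(depth_axis), length(time_axis)),
              depth_axis, time_axis)
}

#' Extract the cohort's canonical CSD pattern by PCA
#'
#' Performs feature-wise mean-centred PCA on the stacked cohort matrix. The
#' first principal component, reshaped to the grid, is the canonical
#' pattern; its sign is fixed so that its correlation with the cohort mean
#' pattern is nonnegative.
#'
#' @param mat cohort matrix from [stack_cohort()] (N >= 2 rows).
#' @param depth_axis,time_axis grid axes; taken from `mat` attributes when
#'   omitted.
#' @return A `canonical_pattern`: list with `pc1` ([csd_pattern()], unit norm
#'   as a flattened vector), `explained_variance_ratio`, per-animal
#'   `loadings` (PC1 scores), and `cohort_mean` ([csd_pattern()]).
#' @export
pca_canonical <- function(mat, depth_axis = NULL, time_axis = NULL) {
  depth_axis <- depth_axis %||% attr(mat, "depth_axis")
  time_axis <- time_axis %||% attr(mat, "time_axis")
  if (is.null(depth_axis) || is.null(time_axis))
    invalid_argument("grid axes must be supplied or attached to the matrix")
  if (nrow(mat) < 2) invalid_argument("PCA needs at least 2 animals")
  centred <- scale(mat, center = TRUE, scale = FALSE)
  if (max(abs(centred)) == 0)
    stop_lamcsd("cohort has zero variance after centring",
                "lamcsd_degenerate_cohort")
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  v1 <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  mu <- colMeans(mat)
  s <- suppressWarnings(cor(v1, mu))
  if (is.finite(s) && s < 0) {
    v1 <- -v1
    scores <- -scores
  }
  structure(list(
    pc1 = unflatten_pattern(v1, depth_axis, time_axis),
    explained_variance_ratio = evr,
    loadings = scores,
    cohort_mean = unflatten_pattern(mu, depth_axis, time_axis)),
    class = "canonical_pattern")
}

#' @export
print.canonical_pattern <- function(x, ...) {
  cat(sprintf("<canonical_pattern> PC1 explains %.1f%% of cohort variance (n = %d)\n",
              100 * x$explained_variance_ratio[1], length(x$loadings)))
  invisible(x)
}

#' Plain cohort-average pattern
#'
#' @param mat cohort matrix from [stack_cohort()] (N >= 1 rows).
#' @param depth_axis,time_axis grid axes; taken from `mat` attributes when
#'   omitted.
#' @return A [csd_pattern()] of the element-wise mean.
#' @export
mean_pattern <- function(mat, depth_axis = NULL, time_axis = NULL) {
  depth_axis <- depth_axis %||% attr(mat, "depth_axis")
  time_axis <- time_axis %||% attr(mat, "time_axis")
  if (is.null(dim(mat)) || nrow(mat) < 1)
    invalid_argument("empty cohort matrix")
  unflatten_pattern(colMeans(mat), depth_axis, time_axis)
}
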