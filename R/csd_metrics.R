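# CSD pattern metrics: sink/source mass normalization, the exact 2-D
# Wasserstein (earth mover's) distance between patterns, cohort pairwise
# machinery, and inter-trial vs inter-animal variability comparison.

#' Split a CSD pattern into normalized sink and source masses
#'
#' Sinks (negative values, sign-flipped) and sources (positive values) are
#' normalized separately so that each sums to 1 -- equivalently the signed
#' pattern's sinks sum to -1 and its sources to +1. Distances computed on
#' these masses are therefore insensitive to overall amplitude.
#'
#' @param pattern a [csd_pattern()] or [grid_pattern()] containing at least
#'   one strictly negative and one strictly positive value.
#' @return A `normalized_mass_pair`: list with matrices `sink_mass`,
#'   `source_mass` (each summing to 1) and the grid axes.
#' @export
split_normalize <- function(pattern) {
  stopifnot(inherits(pattern, "grid_pattern"))
  x <- pattern$values
  sink <- pmax(-x, 0)
  src <- pmax(x, 0)
  if (sum(sink) <= 0 || sum(src) <= 0)
    degenerate_pattern(
      "pattern is single-signed; sink/source normalization (and WD) undefined")
  structure(list(sink_mass = sink / sum(sink),
                 source_mass = src / sum(src),
                 depth_axis = pattern$depth_axis,
                 time_axis = pattern$time_axis),
            class = "normalized_mass_pair")
}

# drop mass below `threshold` and renormalize the remainder back to the
# original total (amplitude-preserving)
threshold_mass <- function(m, threshold = 1e-12) {
  out <- m
  out[out <= threshold] <- 0
  s <- sum(out)
  if (s == 0) return(m)
  out * (sum(m) / s)
}

#' Exact first Wasserstein distance between two grid mass distributions
#'
#' Computes the earth mover's distance under the Euclidean ground metric in
#' grid-index coordinates (one grid step costs 1 along either axis by
#' default; the anisotropy of space vs time cost can be changed with the
#' weights). The transportation problem is solved exactly with a network
#' simplex, after thresholding mass below `threshold` and renormalizing the
#' remainder to the original total.
#'
#' @param a,b nonnegative matrices on the same grid, each summing to the same
#'   total (within 1e-6).
#' @param depth_weight,time_weight cost of one grid step along depth / time.
#' @param threshold mass below this value is dropped before the solve.
#' @return The transport cost (nonnegative scalar).
#' @export
wasserstein_2d <- function(a, b, depth_weight = 1, time_weight = 1,
                           threshold = 1e-12) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    invalid_argument("mass distributions must share a common grid")
  if (any(a < 0) || any(b < 0))
    invalid_argument("mass distributions must be nonnegative")
  if (abs(sum(a) - sum(b)) > 1e-6 * max(sum(a), sum(b)))
    invalid_argument("total masses differ beyond tolerance 1e-6")
  # threshold + amplitude-preserving renormalization per side
  athr <- threshold_mass(a, threshold)
  bthr <- threshold_mass(b, threshold) * (sum(a) / sum(b))
  # the ground cost is a metric, so W1 depends only on the signed residual
  # a - b (shared mass stays in place); transporting (a-b)+ to (b-a)+ is
  # exact and much smaller
  r <- athr - bthr
  pos <- which(r > 0)
  neg <- which(r < 0)
  if (length(pos) == 0 || length(neg) == 0) return(0)
  if (sum(r[pos]) <= 1e-15 * sum(a)) return(0)
  rcp <- arrayInd(pos, dim(a))
  rcn <- arrayInd(neg, dim(a))
  .emd_cost_coords(r[pos], -r[neg],
                   cbind(rcp[, 1] * depth_weight, rcp[, 2] * time_weight),
                   cbind(rcn[, 1] * depth_weight, rcn[, 2] * time_weight))
}

#' Exact transport cost under an explicit cost matrix
#'
#' Lower-level entry point: minimal cost of transporting mass `a` (length m)
#' to mass `b` (length n) under an m x n cost matrix, solved exactly.
#'
#' @param a,b nonnegative mass vectors with equal totals (within 1e-6).
#' @param cost m x n cost matrix.
#' @return The optimal transport cost.
#' @export
transport_cost <- function(a, b, cost) {
  .emd_cost_matrix(as.numeric(a), as.numeric(b), as.matrix(cost))
}

#' Total Wasserstein distance between two CSD patterns
#'
#' The distance between the sink masses and the distance between the source
#' masses are computed separately and summed. Both patterns are
#' sink/source-normalized first, so the result reflects differences in
#' pattern, not amplitude.
#'
#' @param p1,p2 [csd_pattern()]s on a common grid.
#' @inheritParams wasserstein_2d
#' @return A `wd_result`: list with `wd_sinks`, `wd_sources` and
#'   `wd_total = wd_sinks + wd_sources`.
#' @export
wd_csd <- function(p1, p2, depth_weight = 1, time_weight = 1,
                   threshold = 1e-12) {
  if (!same_grid(p1, p2))
    invalid_argument("patterns must lie on a common grid")
  m1 <- split_normalize(p1)
  m2 <- split_normalize(p2)
  ws <- wasserstein_2d(m1$sink_mass, m2$sink_mass, depth_weight, time_weight,
                       threshold)
  wo <- wasserstein_2d(m1$source_mass, m2$source_mass, depth_weight,
                       time_weight, threshold)
  structure(list(wd_sinks = ws, wd_sources = wo, wd_total = ws + wo),
            class = "wd_result")
}

#' @export
print.wd_result <- function(x, ...) {
  cat(sprintf("WD total %.4f (sinks %.4f + sources %.4f)\n",
              x$wd_total, x$wd_sinks, x$wd_sources))
  invisible(x)
}

#' Pairwise Wasserstein distances across a cohort
#'
#' @param patterns named list of [csd_pattern()]s on a common grid.
#'   Degenerate (single-signed) patterns are excluded with a warning.
#' @inheritParams wasserstein_2d
#' @return List with the symmetric `matrix` (zero diagonal, animal ids as
#'   dimnames), the `condensed` data.frame of the n(n-1)/2 unique pairs, and
#'   `excluded` ids.
#' @export
pairwise_wd <- function(patterns, depth_weight = 1, time_weight = 1,
                        threshold = 1e-12) {
  if (length(patterns) < 2)
    invalid_argument("pairwise_wd needs at least 2 patterns")
  ids <- names(patterns) %||% sprintf("pattern_%03d", seq_along(patterns))
  masses <- vector("list", length(patterns))
  ok <- logical(length(patterns))
  for (i in seq_along(patterns)) {
    masses[i] <- list(tryCatch(split_normalize(patterns[[i]]),
                               lamcsd_degenerate_pattern = function(e) NULL))
    ok[i] <- !is.null(masses[[i]])
  }
  if (any(!ok))
    warning(sprintf("excluding degenerate pattern(s): %s",
                    paste(ids[!ok], collapse = ", ")))
  keep <- which(ok)
  n <- length(keep)
  if (n < 2) invalid_argument("fewer than 2 non-degenerate patterns")
  mat <- matrix(0, n, n, dimnames = list(ids[keep], ids[keep]))
  rows <- list()
  for (i in seq_len(n - 1)) {
    mi <- masses[[keep[i]]]
    for (j in (i + 1):n) {
      mj <- masses[[keep[j]]]
      w <- wasserstein_2d(mi$sink_mass, mj$sink_mass, depth_weight,
                          time_weight, threshold) +
        wasserstein_2d(mi$source_mass, mj$source_mass, depth_weight,
                       time_weight, threshold)
      mat[i, j] <- mat[j, i] <- w
      rows[[length(rows) + 1L]] <- data.frame(id1 = ids[keep[i]],
                                              id2 = ids[keep[j]], wd = w)
    }
  }
  list(matrix = mat, condensed = do.call(rbind, rows), excluded = ids[!ok])
}

#' Normalize Wasserstein distances to a reference maximum
#'
#' @param values numeric WD values.
#' @param reference numeric reference set (e.g. all pairwise WDs between
#'   trial-averaged animal patterns); values are divided by its maximum.
#' @return Dimensionless normalized values.
#' @export
normalize_wd <- function(values, reference) {
  if (length(reference) == 0 || max(reference) <= 0)
    invalid_argument("reference set must be non-empty with a positive maximum")
  values / max(reference)
}

#' Compare inter-trial to inter-animal CSD variability
#'
#' For each animal, compares the distribution of its inter-trial pairwise
#' WDs to the distribution of inter-animal pairwise WDs with a two-sample
#' Kolmogorov-Smirnov test (asymptotic p), and flags animals whose
#' inter-trial distribution is stochastically larger than the inter-animal
#' distribution (one-sided KS at `alpha`). Also reports the pooled KS
#' statistic over all trials' WDs.
#'
#' @param trial_wds_per_animal named list of numeric vectors (each >= 2).
#' @param animal_wds numeric vector of inter-animal WDs (>= 2 values).
#' @param alpha significance level for the flag (default 0.001).
#' @return List with `per_animal` (data.frame: animal, statistic, p,
#'   flagged) and `pooled` (statistic, p).
#' @export
trial_vs_animal_variability <- function(trial_wds_per_animal, animal_wds,
                                        alpha = 0.001) {
  if (length(animal_wds) < 2)
    invalid_argument("need at least 2 inter-animal WDs")
  if (any(vapply(trial_wds_per_animal, length, 1L) < 2))
    invalid_argument("each animal needs at least 2 inter-trial WDs")
  ids <- names(trial_wds_per_animal) %||%
    sprintf("animal_%03d", seq_along(trial_wds_per_animal))
  per <- do.call(rbind, lapply(seq_along(trial_wds_per_animal), function(i) {
    x <- trial_wds_per_animal[[i]]
    two <- suppressWarnings(ks.test(x, animal_wds, exact = FALSE))
    # alternative = "less": CDF of x below that of y, i.e. x stochastically larger
    one <- suppressWarnings(ks.test(x, animal_wds, alternative = "less",
                                    exact = FALSE))
    data.frame(animal = ids[i], statistic = unname(two$statistic),
               p = two$p.value, flagged = one$p.value < alpha)
  }))
  pooled_x <- unlist(trial_wds_per_animal, use.names = FALSE)
  pooled <- suppressWarnings(ks.test(pooled_x, animal_wds, exact = FALSE))
  list(per_animal = per,
       pooled = list(statistic = unname(pooled$statistic),
                     p = pooled$p.value))
}
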