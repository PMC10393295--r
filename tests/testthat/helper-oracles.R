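# Independent oracles used by the tests. The transport oracle is a
# successive-shortest-paths min-cost-flow solver with Bellman-Ford path
# search -- deliberately a different algorithm from the package's network
# simplex. Augmenting along a shortest residual path at every step yields
# the exact optimum of the transportation LP.

lp_transport_oracle <- function(a, b, cost) {
  m <- length(a); n <- length(b)
  b <- b * (sum(a) / sum(b))
  f <- matrix(0, m, n)                # flow
  surplus <- a
  deficit <- b
  for (iter in seq_len(10 * (m + n) + 10)) {
    if (max(surplus) <= 1e-13 * sum(a)) break
    # Bellman-Ford from all surplus sources over the residual graph:
    # forward arcs i->j (cost c_ij), backward arcs j->i (-c_ij, if f_ij>0)
    ds <- ifelse(surplus > 1e-13 * sum(a), 0, Inf)   # source distances
    dd <- rep(Inf, n)                                # demand distances
    pred_d <- integer(n)              # source feeding demand j on the path
    pred_s <- integer(m)              # demand feeding source i (backward)
    for (pass in seq_len(m + n + 1)) {
      changed <- FALSE
      for (i in seq_len(m)) if (is.finite(ds[i])) {
        nd <- ds[i] + cost[i, ]
        upd <- nd < dd - 1e-15
        if (any(upd)) { dd[upd] <- nd[upd]; pred_d[upd] <- i; changed <- TRUE }
      }
      for (j in seq_len(n)) if (is.finite(dd[j])) {
        back <- which(f[, j] > 1e-15)
        for (i in back) {
          nd <- dd[j] - cost[i, j]
          if (nd < ds[i] - 1e-15) {
            ds[i] <- nd; pred_s[i] <- j; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    # augment to the closest deficit demand
    open <- which(deficit > 1e-13 * sum(a))
    t <- open[which.min(dd[open])]
    if (!is.finite(dd[t])) stop("oracle: no augmenting path")
    # walk the path backwards, collecting arcs and the bottleneck
    arcs <- list(); j <- t
    repeat {
      i <- pred_d[j]
      arcs[[length(arcs) + 1]] <- c(i, j, +1)
      # pred_s == 0 with finite distance means i kept its initial zero
      # label, i.e. it is a surplus source: the path starts here
      if (pred_s[i] == 0) break
      jb <- pred_s[i]
      arcs[[length(arcs) + 1]] <- c(i, jb, -1)
      j <- jb
    }
    src <- arcs[[length(arcs)]][1]
    amt <- min(surplus[src], deficit[t])
    for (arc in arcs) if (arc[3] < 0) amt <- min(amt, f[arc[1], arc[2]])
    for (arc in arcs) f[arc[1], arc[2]] <- f[arc[1], arc[2]] + arc[3] * amt
    surplus[src] <- surplus[src] - amt
    deficit[t] <- deficit[t] - amt
  }
  if (max(surplus) > 1e-9 * sum(a)) stop("oracle: did not converge")
  sum(f * cost)
}

# random mass vector with strictly positive entries
rand_mass <- function(k) {
  x <- runif(k, 0.05, 1)
  x / sum(x)
}

# small csd pattern on standard axes
make_pattern <- function(values, depth_axis = NULL, time_axis = NULL) {
  values <- as.matrix(values)
  depth_axis <- depth_axis %||% seq(0, by = 40, length.out = nrow(values))
  time_axis <- time_axis %||% seq(0, by = 1, length.out = ncol(values))
  csd_pattern(values, depth_axis, time_axis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# grid-index Euclidean cost matrix between all cells of an r x c grid and
# itself, matching the ground metric of wasserstein_2d
grid_cost <- function(r, c) {
  idx <- expand.grid(row = seq_len(r), col = seq_len(c))
  as.matrix(dist(idx[, c("row", "col")]))
}

# total WD oracle between two signed patterns via the LP on full grids
wd_oracle <- function(p1, p2) {
  s1 <- pmax(-p1, 0); s2 <- pmax(-p2, 0)
  o1 <- pmax(p1, 0); o2 <- pmax(p2, 0)
  cst <- grid_cost(nrow(p1), ncol(p1))
  lp_transport_oracle(as.vector(s1 / sum(s1)), as.vector(s2 / sum(s2)), cst) +
    lp_transport_oracle(as.vector(o1 / sum(o1)), as.vector(o2 / sum(o2)), cst)
}
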