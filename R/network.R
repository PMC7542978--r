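#' Signed weighted joint network
#'
#' A symmetric signed weight matrix over the 12 key channels (ten
#' finger/thumb bends, palm arch, thumb cross): 12 nodes, 66 unique
#' edges, zero diagonal, weights in \[-1, 1\]. Negative weights
#' (anticorrelated joints) are retained.
#'
#' @param weights symmetric numeric matrix with zero diagonal and
#'   entries in \[-1, 1\]; dimnames carry the node labels.
#' @param n_runs number of runs averaged into the weights.
#' @return an object of class `joint_network`.
#' @export
joint_network <- function(weights, n_runs = NA_integer_) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == ncol(weights))
  if (max(abs(weights - t(weights))) > 1e-10) stopf("weights must be symmetric")
  if (any(diag(weights) != 0)) stopf("diagonal must be zero")
  if (max(abs(weights)) > 1 + 1e-10) stopf("|weights| must be <= 1")
  if (is.null(rownames(weights)))
    dimnames(weights) <- list(paste0("n", seq_len(nrow(weights))),
                              paste0("n", seq_len(nrow(weights))))
  structure(list(nodes = rownames(weights), weights = (weights + t(weights)) / 2,
                 n_runs = n_runs),
            class = "joint_network")
}

#' @export
print.joint_network <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<joint_network> %d nodes, %d edges (%d pos / %d neg), mean from %s run(s)\n",
              length(x$nodes), sum(w != 0), sum(w > 0), sum(w < 0),
              ifelse(is.na(x$n_runs), "?", x$n_runs)))
  invisible(x)
}

#' Pearson correlation matrix of one run's network channels
#'
#' @param run a [sensor_run()] restricted to the 12 network channels
#'   (`default_layout()$graph12`).
#' @return 12 x 12 correlation matrix with the diagonal set to 0 for
#'   graph use.
#' @export
run_correlation <- function(run) {
  stopifnot(inherits(run, "sensor_run"))
  vars <- apply(run$data, 2, var)
  if (any(vars == 0))
    stopf("zero-variance channel(s): %s",
          paste(colnames(run$data)[vars == 0], collapse = ", "))
  C <- cor(run$data)
  diag(C) <- 0
  C
}

#' Mean correlation network over runs
#'
#' Elementwise mean of the per-run correlation matrices, typically
#' restricted to runs whose dominant component was correctly assigned.
#' Negative weights are retained.
#'
#' @param mats list of matrices from [run_correlation()].
#' @return a [joint_network()].
#' @export
mean_network <- function(mats) {
  stopifnot(length(mats) >= 1)
  joint_network(Reduce(`+`, mats) / length(mats), n_runs = length(mats))
}

#' Threshold a network's edges
#'
#' Keeps edges with weight at least `tau` (positive mode) or at most
#' `-tau` (negative mode); everything else is zeroed. Nodes are
#' retained even if isolated. The study thresholds in 0.05 steps for
#' display; metrics are computed unthresholded.
#'
#' @param net a [joint_network()].
#' @param tau non-negative threshold.
#' @param sign `"positive"` or `"negative"`.
#' @return a thresholded [joint_network()].
#' @export
threshold_network <- function(net, tau, sign = c("positive", "negative")) {
  stopifnot(inherits(net, "joint_network"), tau >= 0)
  sign <- match.arg(sign)
  w <- net$weights
  w[if (sign == "positive") w < tau else w > -tau] <- 0
  joint_network(w, n_runs = net$n_runs)
}

# All-pairs shortest path lengths by Floyd-Warshall on a length matrix
# (Inf where no edge, 0 diagonal). n is small (12), so this is cheap.
floyd_warshall <- function(len) {
  n <- nrow(len)
  D <- len
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

net_distances <- function(net) {
  aw <- abs(net$weights)
  len <- ifelse(aw > 0, 1 / aw, Inf)
  diag(len) <- 0
  floyd_warshall(len)
}

#' Global efficiency of a weighted network
#'
#' Mean over node pairs of the inverse shortest-path length, with edge
#' length 1/|weight| (connectivity follows weight magnitude; negative
#' correlations still carry signal). Disconnected pairs contribute 0.
#'
#' @param net a [joint_network()].
#' @return efficiency in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "joint_network"))
  n <- length(net$nodes)
  if (n < 2) stopf("need >= 2 nodes")
  D <- net_distances(net)
  d <- D[upper.tri(D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

# Onnela weighted clustering coefficient on |weights| scaled by max.
weighted_clustering <- function(W) {
  aw <- abs(W)
  mx <- max(aw)
  if (mx == 0) return(0)
  cube <- (aw / mx)^(1 / 3)
  num <- diag(cube %*% cube %*% cube)
  k <- rowSums(aw > 0)
  ok <- k > 1
  if (!any(ok)) return(0)
  mean(num[ok] / (k[ok] * (k[ok] - 1)))
}

# Characteristic path length; errors when disconnected.
char_path_length <- function(net) {
  D <- net_distances(net)
  d <- D[upper.tri(D)]
  if (any(!is.finite(d))) stopf("disconnected network: path length undefined")
  mean(d)
}

#' Weight-multiset null ensemble
#'
#' Random networks preserving the observed multiset of edge weights:
#' each null graph reassigns the weights to edges via `iterations`
#' random pairwise swaps. Serves as the comparison basis for the
#' observed metrics (two-sided rank-sum test).
#'
#' @param net a [joint_network()].
#' @param n_graphs ensemble size (study default 100).
#' @param iterations pairwise swaps per graph (study default 1000).
#' @param seed integer seed; identical seed gives identical ensemble.
#' @return an object of class `null_ensemble`: list of
#'   [joint_network()]s plus the generation parameters.
#' @export
null_ensemble <- function(net, n_graphs = 100, iterations = 1000, seed = 1L) {
  stopifnot(inherits(net, "joint_network"))
  n <- length(net$nodes)
  ut <- upper.tri(net$weights)
  w0 <- net$weights[ut]
  m <- length(w0)
  graphs <- with_seed(seed, lapply(seq_len(n_graphs), function(g) {
    w <- w0
    ij <- matrix(sample.int(m, 2 * iterations, replace = TRUE), ncol = 2)
    for (it in seq_len(iterations)) {
      a <- ij[it, 1]; b <- ij[it, 2]
      tmp <- w[a]; w[a] <- w[b]; w[b] <- tmp
    }
    W <- matrix(0, n, n, dimnames = dimnames(net$weights))
    W[ut] <- w
    joint_network(W + t(W))
  }))
  structure(list(graphs = graphs, n_graphs = n_graphs,
                 iterations = iterations, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d weight-shuffled graphs (%d swaps each, seed %d)\n",
              x$n_graphs, x$iterations, x$seed))
  invisible(x)
}

#' Compare an observed network metric against its null ensemble
#'
#' @param net a [joint_network()].
#' @param ensemble a [null_ensemble()] of the same network.
#' @param metric function mapping a network to a number (default
#'   [global_efficiency()]).
#' @return list with `observed`, `null_values`, and the two-sided
#'   rank-sum `p`.
#' @export
null_compare <- function(net, ensemble, metric = global_efficiency) {
  obs <- metric(net)
  vals <- vapply(ensemble$graphs, metric, 0)
  p <- suppressWarnings(wilcox.test(obs, vals, exact = FALSE)$p.value)
  list(observed = obs, null_values = vals, p = p)
}

#' Small-world metrics of a weighted network
#'
#' Small-world index `sigma = (C/C_null)/(L/L_null)` with the Onnela
#' weighted clustering coefficient C and characteristic path length L
#' (lengths 1/|weight|), null references from the ensemble means; and
#' small-world propensity `phi = 1 - sqrt((dC^2 + dL^2)/2)` where dC
#' and dL measure the deviation of C and L from lattice and random
#' references built from the same weight multiset (both clamped to
#' \[0, 1\]). Both conventions are computed on weight magnitudes.
#'
#' @param net a connected [joint_network()].
#' @param null a [null_ensemble()] for the random references.
#' @return list with `swp` (phi), `swi` (sigma), and the underlying
#'   `C`, `L`, `C_rand`, `L_rand`, `C_latt`, `L_latt`.
#' @export
small_world <- function(net, null) {
  stopifnot(inherits(net, "joint_network"), inherits(null, "null_ensemble"))
  C <- weighted_clustering(net$weights)
  L <- char_path_length(net)
  C_rand <- mean(vapply(null$graphs, function(g) weighted_clustering(g$weights), 0))
  L_rand <- mean(vapply(null$graphs, function(g) {
    D <- net_distances(g)
    d <- D[upper.tri(D)]
    mean(d[is.finite(d)])
  }, 0))
  latt <- lattice_reference(net)
  C_latt <- weighted_clustering(latt$weights)
  L_latt <- {
    D <- net_distances(latt)
    d <- D[upper.tri(D)]
    mean(d[is.finite(d)])
  }
  swi <- (C / C_rand) / (L / L_rand)
  dC <- (C_latt - C) / (C_latt - C_rand)
  dL <- (L - L_rand) / (L_latt - L_rand)
  dC <- min(max(dC, 0), 1)
  dL <- min(max(dL, 0), 1)
  if (!is.finite(dC)) dC <- 0
  if (!is.finite(dL)) dL <- 0
  swp <- 1 - sqrt((dC^2 + dL^2) / 2)
  list(swp = swp, swi = swi, C = C, L = L, C_rand = C_rand, L_rand = L_rand,
       C_latt = C_latt, L_latt = L_latt)
}

# Ring-lattice reference: the observed weight magnitudes, strongest
# assigned to the shortest ring distances.
lattice_reference <- function(net) {
  n <- length(net$nodes)
  ut <- which(upper.tri(net$weights), arr.ind = TRUE)
  ring_dist <- pmin(abs(ut[, 1] - ut[, 2]), n - abs(ut[, 1] - ut[, 2]))
  w <- sort(abs(net$weights[upper.tri(net$weights)]), decreasing = TRUE)
  ord <- order(ring_dist, ut[, 1], ut[, 2])
  W <- matrix(0, n, n, dimnames = dimnames(net$weights))
  idx <- which(upper.tri(W))
  W[idx[ord]] <- w
  joint_network(W + t(W))
}

# ---- signed Louvain ----------------------------------------------------

# Signed modularity with asymmetric treatment of negative weights
# (positive connections dominate): Q = Q+ /v+ - Q- /(v+ + v-).
signed_modularity <- function(Wp, Wn, comm, gamma = 1) {
  same <- outer(comm, comm, `==`)
  vp <- sum(Wp)
  vn <- sum(Wn)
  qp <- if (vp > 0) {
    sp <- rowSums(Wp)
    sum((Wp - gamma * outer(sp, sp) / vp) * same) / vp
  } else 0
  qn <- if (vn > 0) {
    sn <- rowSums(Wn)
    sum((Wn - gamma * outer(sn, sn) / vn) * same) / (vp + vn)
  } else 0
  qp - qn
}

# One local-moving pass to a fixed point, random node order.
louvain_once <- function(Wp, Wn, gamma) {
  n <- nrow(Wp)
  comm <- seq_len(n)
  q <- signed_modularity(Wp, Wn, comm, gamma)
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      cands <- unique(c(comm[-i], comm[i]))
      best_q <- q
      best_c <- comm[i]
      for (cc in cands) {
        if (cc == comm[i]) next
        trial <- comm
        trial[i] <- cc
        tq <- signed_modularity(Wp, Wn, trial, gamma)
        if (tq > best_q + 1e-12) {
          best_q <- tq
          best_c <- cc
        }
      }
      if (best_c != comm[i]) {
        comm[i] <- best_c
        q <- best_q
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(comm = comm, q = q)
}

canonical_labels <- function(comm) {
  match(comm, unique(comm))
}

#' Louvain community detection on a signed network
#'
#' Maximizes signed modularity (resolution `gamma`) with asymmetric
#' treatment of negative weights - positive within-module weight is
#' rewarded on the positive scale, negative within-module weight
#' penalized on the combined scale - by local moving from singleton
#' communities, with a seeded consensus over `restarts` random node
#' orders (the most frequent partition wins; ties go to the higher
#' modularity).
#'
#' @param net a [joint_network()] (signed weights allowed).
#' @param gamma resolution parameter (study value 1).
#' @param seed integer seed.
#' @param restarts number of restarts entering the consensus.
#' @return list with `modules` (named integer vector, labels 1..m in
#'   first-appearance order), `q` (signed modularity), `n_restarts`.
#' @export
louvain_modules <- function(net, gamma = 1, seed = 1L, restarts = 100) {
  stopifnot(inherits(net, "joint_network"))
  W <- net$weights
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  if (all(W == 0)) {
    modules <- seq_len(nrow(W))
    names(modules) <- net$nodes
    return(list(modules = modules, q = 0, n_restarts = 0))
  }
  runs <- with_seed(seed, lapply(seq_len(restarts), function(r)
    louvain_once(Wp, Wn, gamma)))
  keys <- vapply(runs, function(r) paste(canonical_labels(r$comm), collapse = "."), "")
  tab <- table(keys)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {  # tie: highest modularity, then lexicographic key
    qs <- vapply(top, function(k) max(vapply(runs[keys == k], `[[`, 0, "q")), 0)
    top <- sort(top[qs == max(qs)])[1]
  }
  pick <- runs[[which(keys == top)[1]]]
  modules <- canonical_labels(pick$comm)
  names(modules) <- net$nodes
  list(modules = modules, q = pick$q, n_restarts = restarts)
}
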