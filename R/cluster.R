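# Center each row and scale to unit norm, so the inner product of two
# standardized rows is their Pearson correlation.
row_standardize <- function(m) {
  m <- m - rowMeans(m)
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stopf("constant item cannot be compared by correlation")
  m / n
}

# One Lloyd run of k-means under correlation distance. Returns NULL if a
# cluster empties (caller re-initializes the replicate).
kmeans_cor_once <- function(XS, k, max_iter = 100) {
  cent <- XS[sample.int(nrow(XS), k), , drop = FALSE]
  assign_old <- rep(0L, nrow(XS))
  for (it in seq_len(max_iter)) {
    D <- 1 - tcrossprod(XS, cent)
    assign <- max.col(-D, ties.method = "first")
    if (length(unique(assign)) < k) return(NULL)
    if (all(assign == assign_old)) break
    assign_old <- assign
    for (j in seq_len(k)) {
      v <- colMeans(XS[assign == j, , drop = FALSE])
      v <- v - mean(v)
      cent[j, ] <- v / sqrt(sum(v^2))
    }
  }
  list(assign = assign, centroids = cent,
       tot = sum(D[cbind(seq_len(nrow(XS)), assign)]))
}

#' k-means taxonomy of aligned expression patterns
#'
#' Clusters the aligned EC vectors of all (run, component) items with
#' k-means under correlation distance (1 - Pearson r, compared after
#' row standardization), best of `replicates` seeded restarts. Each
#' cluster is then labeled with a component rank by maximum-agreement
#' bijective matching, and every item is flagged correct if its
#' component rank equals its cluster's label.
#'
#' @param items result of [aligned_items()], or a list with `ecs`
#'   (items x channels matrix) and `component` (integer rank per item).
#' @param k number of clusters (fixed to 3 in the study design).
#' @param seed integer seed for the restarts.
#' @param replicates number of random restarts (k-means is
#'   initialization-dependent).
#' @return an object of class `cluster_taxonomy`: `assignment` (cluster
#'   id per item), `centroids` (k x channels, standardized), `distance`
#'   (1 - r to own centroid), `label_map` (cluster id -> component
#'   rank), `correct` (logical per item), plus the item tags.
#' @export
cluster_components <- function(items, k = 3, seed = 1L, replicates = 50) {
  X <- items$ecs
  comp <- items$component
  stopifnot(nrow(X) == length(comp))
  if (nrow(X) < k) stopf("need at least k = %d items, got %d", k, nrow(X))
  XS <- row_standardize(X)
  if (nrow(unique(round(XS, 12))) < k) {
    warnf("fewer than k distinct patterns: degenerate taxonomy")
    return(structure(list(k = k, assignment = rep(1L, nrow(X)),
                          centroids = XS[1, , drop = FALSE],
                          distance = rep(0, nrow(X)),
                          label_map = NULL, correct = rep(NA, nrow(X)),
                          component = comp, degenerate = TRUE,
                          subject_id = items$subject_id,
                          run_index = items$run_index),
                     class = "cluster_taxonomy"))
  }
  best <- NULL
  with_seed(seed, {
    tries <- 0
    reps <- 0
    while (reps < replicates && tries < 20 * replicates) {
      tries <- tries + 1
      fit <- kmeans_cor_once(XS, k)
      if (is.null(fit)) next  # empty cluster: re-initialize this replicate
      reps <- reps + 1
      if (is.null(best) || fit$tot < best$tot) best <- fit
    }
  })
  if (is.null(best)) stopf("k-means failed to produce %d non-empty clusters", k)
  # label clusters by maximum-agreement bijective matching to ranks 1..k
  A <- matrix(0L, k, k)
  for (i in seq_along(comp))
    if (comp[i] <= k) A[best$assign[i], comp[i]] <- A[best$assign[i], comp[i]] + 1L
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p) sum(A[cbind(seq_len(k), p)]), 0L)
  label_map <- perms[[which.max(scores)]]
  D <- 1 - tcrossprod(XS, best$centroids)
  structure(list(k = k, assignment = best$assign, centroids = best$centroids,
                 distance = D[cbind(seq_len(nrow(X)), best$assign)],
                 label_map = label_map,
                 correct = label_map[best$assign] == comp,
                 component = comp, degenerate = FALSE,
                 subject_id = items$subject_id, run_index = items$run_index),
            class = "cluster_taxonomy")
}

#' @export
print.cluster_taxonomy <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<cluster_taxonomy> degenerate (identical patterns)\n")
  } else {
    cat(sprintf("<cluster_taxonomy> k = %d, %d items, %.1f%% correctly assigned\n",
                x$k, length(x$assignment), 100 * mean(x$correct)))
  }
  invisible(x)
}

#' Cross-tabulation of component ranks against cluster labels
#'
#' @param t a [cluster_components()] taxonomy.
#' @return a k x k contingency matrix, rows = component rank, columns =
#'   cluster label (as component rank); row sums equal the number of
#'   items per rank.
#' @export
misassignment_table <- function(t) {
  stopifnot(inherits(t, "cluster_taxonomy"), !isTRUE(t$degenerate))
  tab <- table(factor(t$component, levels = seq_len(t$k)),
               factor(t$label_map[t$assignment], levels = seq_len(t$k)))
  names(dimnames(tab)) <- c("component", "cluster_label")
  tab
}

#' Kruskal-Wallis salience analysis of sensor expression patterns
#'
#' For the correctly assigned items of one cluster, tests whether the 19
#' per-sensor EC distributions differ: omnibus Kruskal-Wallis on the
#' pooled ranks, then post-hoc pairwise rank comparisons (Dunn-type z
#' statistics with tie correction) with Bonferroni control.
#'
#' @param ecs items x sensors matrix of correctly assigned ECs.
#' @param alpha familywise significance level.
#' @param bonferroni_factor multiplier for the pairwise p-values;
#'   defaults to the number of pairs, `choose(ncol(ecs), 2)`.
#' @return an object of class `salience_result`: `H`, `p` (omnibus),
#'   `mean_ranks`, `pairs` (all pairwise comparisons with raw and
#'   corrected p), and `significant` (pairs with corrected p < alpha).
#' @export
sensor_salience <- function(ecs, alpha = 0.05,
                            bonferroni_factor = choose(ncol(ecs), 2)) {
  ecs <- as.matrix(ecs)
  if (nrow(ecs) < 2) stopf("salience statistic undefined for < 2 items")
  s <- ncol(ecs)
  sensors <- colnames(ecs) %||% paste0("S", seq_len(s))
  values <- as.vector(ecs)
  groups <- factor(rep(sensors, each = nrow(ecs)), levels = sensors)
  kw <- kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  n_per <- tabulate(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pooled <- N * (N + 1) / 12 - tie_term
  pairs <- combn(s, 2)
  z <- abs(mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]]) /
    sqrt(pooled * (1 / n_per[pairs[1, ]] + 1 / n_per[pairs[2, ]]))
  p_raw <- 2 * pnorm(-z)
  p_adj <- pmin(1, p_raw * bonferroni_factor)
  tab <- data.frame(sensor_a = sensors[pairs[1, ]],
                    sensor_b = sensors[pairs[2, ]],
                    z = as.numeric(z), p = as.numeric(p_raw),
                    p_bonferroni = as.numeric(p_adj))
  structure(list(H = unname(kw$statistic), p = kw$p.value,
                 mean_ranks = mean_ranks, n_items = nrow(ecs),
                 alpha = alpha, bonferroni_factor = bonferroni_factor,
                 pairs = tab,
                 significant = tab[tab$p_bonferroni < alpha, , drop = FALSE]),
            class = "salience_result")
}

#' @export
print.salience_result <- function(x, ...) {
  cat(sprintf("<salience_result> H = %.2f, p = %.3g; %d/%d sensor pairs significant at %.2f\n",
              x$H, x$p, nrow(x$significant), nrow(x$pairs), x$alpha))
  invisible(x)
}
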