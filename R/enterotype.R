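#' Jensen-Shannon distance matrix
#'
#' Converts each row of an abundance matrix to proportions, replaces zeros by
#' `pseudo` and renormalizes, then computes the Jensen-Shannon *distance*
#' `d(p, q) = sqrt(KL(p||m)/2 + KL(q||m)/2)` with `m = (p + q)/2`.  With the
#' natural logarithm the distance is bounded by `sqrt(log 2)`; it satisfies
#' the metric axioms, so it can feed medoid clustering directly.
#'
#' @param ab An `abundance_matrix`, or a numeric matrix of nonnegative
#'   abundances (rows = samples).
#' @param pseudo Zero-replacement value applied on the proportion scale.
#' @param log_base `"e"` (default) or `"2"`.
#' @return Object of class `jsd_dist`: list with `d` (symmetric matrix),
#'   `pseudo`, `log_base`.
#' @export
jsd_distance <- function(ab, pseudo = 1e-10, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  m <- if (inherits(ab, "abundance_matrix")) ab$percent else as.matrix(ab)
  if (any(is.na(m))) stop_es("abundance matrix contains missing values")
  if (any(m < 0)) stop_es("domain error: negative abundances")
  p <- sweep(m, 1, rowSums(m), "/")
  p[p == 0] <- pseudo
  p <- sweep(p, 1, rowSums(p), "/")
  lg <- if (log_base == "e") log else log2
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    pi <- p[i, ]
    for (j in (i + 1):n) {
      pj <- p[j, ]
      mid <- (pi + pj) / 2
      jsd <- 0.5 * sum(pi * lg(pi / mid)) + 0.5 * sum(pj * lg(pj / mid))
      d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
    }
  }
  structure(list(d = d, pseudo = pseudo, log_base = log_base),
            class = "jsd_dist")
}

as_dist_matrix <- function(d) {
  if (inherits(d, "jsd_dist")) d$d else as.matrix(d)
}

#' Partition-around-medoids clustering on a distance matrix
#'
#' Minimizes the total distance of samples to their cluster medoids.  For
#' tiny inputs (at most `exact_limit` candidate medoid sets) the optimum is
#' found by exact enumeration; otherwise the classical deterministic
#' BUILD + SWAP search (`cluster::pam`) is used, whose result is a local
#' optimum under single-medoid swaps.  Either way the procedure is
#' deterministic for a given input; `seed` is accepted for call-site
#' symmetry with the simulator but does not alter the result.
#'
#' @param d A `jsd_dist` or symmetric distance matrix.
#' @param k Number of clusters, `2 <= k < n`.
#' @param seed Unused (deterministic algorithm).
#' @param exact_limit Enumerate all medoid sets exactly when
#'   `choose(n, k)` does not exceed this bound.
#' @return Object of class `partition`: list with `labels` (named integer
#'   vector), `medoids` (cluster id -> sample id), `k`.
#' @export
pam_partition <- function(d, k, seed = NULL, exact_limit = 500) {
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  if (k < 2 || k >= n) stop_es("invalid k: need 2 <= k < n")
  if (choose(n, k) <= exact_limit) {
    best <- NULL; best_cost <- Inf
    for (med in utils::combn(n, k, simplify = FALSE)) {
      cost <- sum(do.call(pmin, lapply(med, function(m) dm[, m])))
      if (cost < best_cost - 1e-15) { best_cost <- cost; best <- med }
    }
    assign_to <- apply(dm[, best, drop = FALSE], 1, which.min)
    assign_to[best] <- seq_len(k)  # pin medoids to their own cluster on ties
    labels <- stats::setNames(as.integer(assign_to), rownames(dm))
    medoids <- stats::setNames(rownames(dm)[best], seq_len(k))
  } else {
    fit <- cluster::pam(stats::as.dist(dm), k = k, diss = TRUE)
    labels <- stats::setNames(as.integer(fit$clustering), rownames(dm))
    medoids <- stats::setNames(fit$medoids, seq_len(k))
  }
  structure(list(labels = labels, medoids = medoids, k = k),
            class = "partition")
}

#' Total distance of samples to their medoids
#' @param d Distance matrix or `jsd_dist`.
#' @param part A `partition`.
#' @return Numeric scalar (the PAM objective).
#' @export
pam_objective <- function(d, part) {
  dm <- as_dist_matrix(d)
  sum(dm[cbind(names(part$labels), part$medoids[as.character(part$labels)])])
}

#' Calinski-Harabasz scan over cluster numbers
#'
#' For each k, PAM is run and a medoid-based CH index is computed:
#' `B = sum_c n_c d(m_c, m*)^2` (m* the global medoid),
#' `W = sum_i d(i, m_c(i))^2`, `CH = (B/(k-1)) / (W/(n-k))`.
#' The k maximizing CH is reported as `optimal_k`.
#'
#' @param d A `jsd_dist` or distance matrix.
#' @param k_range Integer vector of cluster numbers within `[2, n-1]`.
#' @return Object of class `cluster_scan`: list with `ch_index` (named
#'   vector) and `optimal_k`.
#' @export
ch_scan <- function(d, k_range = 2:5) {
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  if (n < 4) stop_es("insufficient samples for a cluster scan (need >= 4)")
  k_range <- as.integer(k_range)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop_es("k_range must lie within [2, n-1]")
  global_medoid <- rownames(dm)[which.min(rowSums(dm))]
  ch <- stats::setNames(numeric(length(k_range)), k_range)
  for (idx in seq_along(k_range)) {
    k <- k_range[[idx]]
    part <- pam_partition(dm, k)
    med <- part$medoids[as.character(part$labels)]
    W <- sum(dm[cbind(names(part$labels), med)]^2)
    n_c <- table(part$labels)
    B <- sum(n_c * dm[part$medoids[names(n_c)], global_medoid]^2)
    ch[[idx]] <- (B / (k - 1)) / (W / (n - k))
  }
  structure(list(ch_index = ch,
                 optimal_k = k_range[[which.max(ch)]]),
            class = "cluster_scan")
}

#' Per-sample silhouette scores
#'
#' `S(i) = (b - a) / max(a, b)` with `a` the mean distance of i to the other
#' members of its cluster and `b` the minimum over other clusters of the mean
#' distance to that cluster.  Members of singleton clusters get `S = 0`.
#'
#' @param d A `jsd_dist` or distance matrix.
#' @param part A `partition` (k >= 2).
#' @return Named numeric vector of silhouette scores in `[-1, 1]`.
#' @export
silhouette_scores <- function(d, part) {
  dm <- as_dist_matrix(d)
  labels <- part$labels[rownames(dm)]
  ks <- unique(labels)
  if (length(ks) < 2) stop_es("silhouette needs at least two clusters")
  s <- stats::setNames(numeric(length(labels)), names(labels))
  for (i in seq_along(labels)) {
    own <- labels == labels[[i]]
    if (sum(own) == 1) { s[[i]] <- 0; next }
    a <- mean(dm[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(ks, labels[[i]]), function(kk)
      mean(dm[i, labels == kk]), numeric(1)))
    s[[i]] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Enumerate pooled time-point set combinations
#'
#' All unordered combinations of size 2..n of the given dataset names, in
#' deterministic order (by size, then by index).  Five time-point sets yield
#' 10 pairs, 10 triplets, 5 quartets and 1 quintet.
#'
#' @param set_names Character vector of dataset (time-point) names, length
#'   >= 2.
#' @return Named list of character vectors; names join the members with
#'   `"_"`.
#' @export
enumerate_pooled_sets <- function(set_names) {
  set_names <- as.character(set_names)
  n <- length(set_names)
  if (n < 2) stop_es("need at least two sets to pool")
  out <- list()
  for (size in 2:n) {
    cmb <- utils::combn(set_names, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  names(out) <- vapply(out, paste, character(1), collapse = "_")
  out
}

# Harmonize raw PAM cluster ids to reference enterotype labels.  Primary
# rule: majority vote of the member *control* samples' reference labels.
# Combinations without control samples fall back to a majority vote over the
# member rats' reference enterotypes (rat_of maps sample -> rat, and each
# rat's label is that of its control sample).  If both clusters land on the
# same label, the cluster with the stronger majority keeps it.
harmonize_labels <- function(part, reference, rat_of = NULL) {
  ref_labels <- sort(unique(reference))
  rat_label <- NULL
  if (!is.null(rat_of)) {
    ctrl <- intersect(names(reference), names(rat_of))
    rat_label <- stats::setNames(reference[ctrl], rat_of[ctrl])
  }
  score <- function(members) {
    ctrl <- intersect(members, names(reference))
    lab <- if (length(ctrl)) reference[ctrl]
    else if (!is.null(rat_label)) {
      rats <- rat_of[intersect(members, names(rat_of))]
      rat_label[rats[rats %in% names(rat_label)]]
    } else character(0)
    vapply(ref_labels, function(L) sum(lab == L, na.rm = TRUE), numeric(1))
  }
  ks <- sort(unique(part$labels))
  votes <- t(vapply(ks, function(kk)
    score(names(part$labels)[part$labels == kk]), numeric(length(ref_labels))))
  rownames(votes) <- ks
  colnames(votes) <- ref_labels
  assign <- stats::setNames(rep(NA_character_, length(ks)), ks)
  # greedy assignment by decreasing vote margin
  remaining_k <- as.character(ks); remaining_l <- ref_labels
  while (length(remaining_k) && length(remaining_l)) {
    sub <- votes[remaining_k, remaining_l, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    assign[remaining_k[best[[1]]]] <- remaining_l[best[[2]]]
    remaining_k <- remaining_k[-best[[1]]]
    remaining_l <- remaining_l[-best[[2]]]
  }
  # more clusters than labels: leave extras as raw ids
  assign[is.na(assign)] <- names(assign)[is.na(assign)]
  assign
}

#' Silhouette stability grid over pooled time-point combinations
#'
#' For every combination of the supplied time-point datasets the pooled
#' samples are re-clustered (JSD -> PAM k = 2 -> silhouette) and the raw
#' cluster ids are harmonized to the reference enterotype labels.  The grid
#' of silhouette scores and harmonized labels is the input of the
#' vote-based enterotype call ([call_enterotype()]).
#'
#' @param ab_by_set Named list of `abundance_matrix` objects (or percent
#'   matrices), one per time-point dataset, sharing the same genus panel.
#' @param reference Named character vector mapping *control* sample ids to
#'   their reference enterotype labels (from clustering the control set).
#' @param rat_of Optional named character vector sample -> rat id, used to
#'   harmonize combinations that contain no control samples.
#' @param pseudo,log_base Passed to [jsd_distance()].
#' @param k Number of clusters (fixed at 2 for enterotype grids).
#' @param min_samples Combinations pooling fewer samples are skipped with a
#'   warning.
#' @return Object of class `silhouette_grid`: list with `S` and `label`
#'   matrices (combination x sample; `NA` where the sample is absent),
#'   `combinations`, `skipped`.
#' @export
stability_grid <- function(ab_by_set, reference, rat_of = NULL,
                           pseudo = 1e-10, log_base = "e", k = 2,
                           min_samples = 4) {
  stopifnot(is.list(ab_by_set), length(ab_by_set) >= 2)
  mats <- lapply(ab_by_set, function(a)
    if (inherits(a, "abundance_matrix")) a$percent else as.matrix(a))
  combos <- enumerate_pooled_sets(names(mats))
  all_samples <- unique(unlist(lapply(mats, rownames)))
  S <- matrix(NA_real_, nrow = length(combos), ncol = length(all_samples),
              dimnames = list(names(combos), all_samples))
  lab <- matrix(NA_character_, nrow = length(combos),
                ncol = length(all_samples),
                dimnames = list(names(combos), all_samples))
  skipped <- character(0)
  for (cn in names(combos)) {
    pooled <- do.call(rbind, mats[combos[[cn]]])
    pooled <- pooled[!duplicated(rownames(pooled)), , drop = FALSE]
    if (nrow(pooled) < max(min_samples, k + 1)) {
      warning("skipping combination ", cn, ": fewer than ", min_samples,
              " samples", call. = FALSE)
      skipped <- c(skipped, cn)
      next
    }
    d <- jsd_distance(pooled, pseudo = pseudo, log_base = log_base)
    part <- pam_partition(d, k)
    s <- silhouette_scores(d, part)
    hl <- harmonize_labels(part, reference, rat_of)
    S[cn, names(s)] <- s
    lab[cn, names(part$labels)] <- hl[as.character(part$labels)]
  }
  structure(list(S = S, label = lab, combinations = combos,
                 skipped = skipped),
            class = "silhouette_grid")
}

#' Vote-based enterotype call for one sample
#'
#' Counts, per harmonized enterotype label, the pooled combinations in which
#' the sample was assigned to that label with silhouette score above
#' `threshold` ("true" assignments).  The decision is the label with the
#' majority of true assignments; a tie or zero votes yields `"unstable"`.
#'
#' @param grid A `silhouette_grid`.
#' @param sample_id Sample to call.
#' @param threshold Silhouette threshold for a true assignment (default 0.1).
#' @return Object of class `enterotype_call`: list with `sample_id`, `votes`
#'   (named counts), `decision`, `threshold`.
#' @export
call_enterotype <- function(grid, sample_id, threshold = 0.1) {
  stopifnot(inherits(grid, "silhouette_grid"))
  if (!sample_id %in% colnames(grid$S))
    stop_es("unknown sample: ", sample_id)
  present <- !is.na(grid$S[, sample_id])
  if (!any(present))
    stop_es("sample ", sample_id, " appears in no combination")
  labs <- sort(unique(stats::na.omit(as.vector(grid$label))))
  s <- grid$S[present, sample_id]
  l <- grid$label[present, sample_id]
  votes <- vapply(labs, function(L)
    sum(s > threshold & l == L, na.rm = TRUE), numeric(1))
  decision <- if (sum(votes) == 0 || sum(votes == max(votes)) > 1) "unstable"
              else labs[[which.max(votes)]]
  structure(list(sample_id = sample_id, votes = votes, decision = decision,
                 threshold = threshold),
            class = "enterotype_call")
}

#' Enterotype calls for every sample in a grid
#'
#' @inheritParams call_enterotype
#' @return Data frame with `sample_id`, one vote column per label, and
#'   `decision`.
#' @export
call_all_enterotypes <- function(grid, threshold = 0.1) {
  samples <- colnames(grid$S)[colSums(!is.na(grid$S)) > 0]
  calls <- lapply(samples, call_enterotype, grid = grid,
                  threshold = threshold)
  votes <- do.call(rbind, lapply(calls, function(cl) cl$votes))
  out <- data.frame(sample_id = samples, votes,
                    decision = vapply(calls, `[[`, character(1), "decision"),
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Principal-coordinates (classical MDS) embedding of a distance matrix
#'
#' @param d A `jsd_dist` or symmetric distance matrix.
#' @param n_axes Number of axes to keep (`< n`).
#' @return Matrix (sample x axis) of coordinates, axes ordered by
#'   eigenvalue; a warning reports truncated negative eigenvalues.
#' @export
pcoa_coordinates <- function(d, n_axes = 2) {
  dm <- as_dist_matrix(d)
  if (!isTRUE(all.equal(dm, t(dm))))
    stop_es("domain error: distance matrix is not symmetric")
  if (n_axes >= nrow(dm)) stop_es("n_axes must be < number of samples")
  fit <- stats::cmdscale(stats::as.dist(dm), k = n_axes, eig = TRUE)
  if (any(fit$eig < -sqrt(.Machine$double.eps)))
    warning("negative eigenvalues truncated in PCoA", call. = FALSE)
  coords <- fit$points
  # pad in the degenerate case where cmdscale returns fewer axes
  if (ncol(coords) < n_axes)
    coords <- cbind(coords, matrix(0, nrow(coords),
                                   n_axes - ncol(coords)))
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  coords
}
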