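# Two-stage configurational-space clustering: agglomerative (Ward) on
# pairwise interatomic distance descriptors, then k-means on reference
# energies inside each structural group.

#' Pairwise-distance descriptor of a frame
#'
#' The upper-triangle vector of pairwise interatomic distances of one frame,
#' in a fixed atom-index order (atoms are labelled; no sorting). Invariant
#' under rigid rotations and translations.
#'
#' @param frame_positions An `n_atoms x 3` matrix, Angstrom.
#' @return Numeric vector of length `n_atoms * (n_atoms - 1) / 2`.
#' @export
distance_descriptor <- function(frame_positions) {
  if (is.null(dim(frame_positions)) || nrow(frame_positions) < 2L) {
    stop("distance descriptor requires at least 2 atoms", call. = FALSE)
  }
  as.vector(dist(frame_positions))
}

# descriptor matrix (n_frames x n_pairs), optionally inverse distances
descriptor_matrix <- function(ds, inverse = FALSE) {
  nf <- n_frames(ds)
  d1 <- distance_descriptor(ds$positions[1, , ])
  out <- matrix(0, nrow = nf, ncol = length(d1))
  out[1, ] <- d1
  if (nf > 1) {
    for (f in 2:nf) out[f, ] <- as.vector(dist(ds$positions[f, , ]))
  }
  if (inverse) out <- 1 / out
  out
}

# 1-D k-means with deterministic initial centers spread over the distinct
# values (avoids empty-cluster failures of random initialisation)
kmeans_1d <- function(x, k) {
  ux <- sort(unique(x))
  init <- ux[round(seq(1, length(ux), length.out = k))]
  km <- suppressWarnings(
    kmeans(matrix(x, ncol = 1L), centers = matrix(init, ncol = 1L), iter.max = 100L)
  )
  km$cluster
}

# largest-remainder apportionment of n_total among groups, each >= 1 and
# capped at the number of distinct values available in the group
apportion_budget <- function(sizes, caps, n_total) {
  g <- length(sizes)
  ideal <- n_total * sizes / sum(sizes)
  b <- pmax(1L, pmin(caps, floor(ideal)))
  while (sum(b) < n_total && any(b < caps)) {
    room <- which(b < caps)
    give <- room[which.max(ideal[room] - b[room])]
    b[give] <- b[give] + 1L
  }
  while (sum(b) > n_total) {
    room <- which(b > 1L)
    if (length(room) == 0) break
    take <- room[which.min(ideal[room] - b[room])]
    b[take] <- b[take] - 1L
  }
  b
}

#' Two-stage configurational-space clustering
#'
#' Stage 1 groups frames structurally: agglomerative clustering (Ward
#' linkage, Euclidean metric) on the pairwise interatomic distance
#' descriptors, into `n_structural` groups. Stage 2 splits each structural
#' group by k-means on its reference energies; each group's sub-cluster
#' budget is proportional to its size (largest-remainder rounding, at least
#' one per group), for `n_total` clusters overall. For datasets above
#' `max_exact` frames, stage 1 runs on a seeded uniform subsample and the
#' remaining frames are assigned to the nearest structural centroid.
#'
#' @param ds A [configuration_set()] with reference energies.
#' @param errors Optional [compute_error_table()] used for the per-cluster
#'   error summaries (they can be attached later with
#'   [summarize_clusters()]).
#' @param n_total Total number of clusters (default 40).
#' @param n_structural Number of first-stage structural groups (default 10).
#' @param seed Integer seed fixing the k-means initialisation (and the
#'   stage-1 subsample, if any).
#' @param inverse_distances Use inverse interatomic distances as descriptor.
#' @param max_exact Frame count above which stage 1 uses subsample-then-assign.
#' @return An object of class `cluster_assignment`: per-frame `labels` (1-based),
#'   `structural_labels`, counts, per-cluster `summaries` tibble and the
#'   structural centroids.
#' @export
cluster_configurations <- function(ds, errors = NULL, n_total = 40L,
                                   n_structural = 10L, seed = 0L,
                                   inverse_distances = FALSE, max_exact = 5000L) {
  stopifnot(inherits(ds, "configuration_set"))
  if (is.null(ds$energies)) stop("clustering requires reference energies", call. = FALSE)
  n_total <- as.integer(n_total)
  n_structural <- as.integer(n_structural)
  if (n_total < 1L || n_structural < 1L) stop("cluster counts must be positive", call. = FALSE)
  if (n_structural > n_total) stop("n_structural must be <= n_total", call. = FALSE)
  nf <- n_frames(ds)

  desc <- descriptor_matrix(ds, inverse = inverse_distances)
  n_distinct <- nrow(unique(desc))
  if (n_distinct < n_total) {
    warning(
      "only ", n_distinct, " distinct frames; producing at most that many clusters",
      call. = FALSE
    )
    n_total <- n_distinct
    n_structural <- min(n_structural, n_distinct)
  }

  set.seed(as.integer(seed))
  if (nf == 1L) {
    out <- structure(
      list(
        labels = 1L, structural_labels = 1L, n_structural = 1L, n_total = 1L,
        structural_centroids = desc, seed = as.integer(seed),
        inverse_distances = inverse_distances, summaries = NULL
      ),
      class = "cluster_assignment"
    )
    if (!is.null(errors)) out <- summarize_clusters(out, errors)
    return(out)
  }
  if (nf > max_exact) {
    sub <- sort(sample.int(nf, max_exact))
    hc <- hclust(dist(desc[sub, , drop = FALSE]), method = "ward.D2")
    sub_lab <- cutree(hc, k = n_structural)
    centroids <- rowsum(desc[sub, , drop = FALSE], sub_lab) / as.vector(table(sub_lab))
    structural <- integer(nf)
    structural[sub] <- sub_lab
    rest <- setdiff(seq_len(nf), sub)
    if (length(rest) > 0) {
      d2 <- outer(rowSums(desc[rest, , drop = FALSE]^2), rowSums(centroids^2), "+") -
        2 * desc[rest, , drop = FALSE] %*% t(centroids)
      structural[rest] <- max.col(-d2)
    }
  } else {
    hc <- hclust(dist(desc), method = "ward.D2")
    structural <- cutree(hc, k = n_structural)
  }

  sizes <- as.vector(table(factor(structural, levels = seq_len(n_structural))))
  caps <- vapply(
    seq_len(n_structural),
    function(g) length(unique(ds$energies[structural == g])), integer(1)
  )
  caps <- pmax(caps, 1L)
  budget <- apportion_budget(sizes, caps, n_total)

  labels <- integer(nf)
  offset <- 0L
  for (g in seq_len(n_structural)) {
    idx <- which(structural == g)
    if (length(idx) == 0) next
    kg <- budget[g]
    if (kg == 1L || length(unique(ds$energies[idx])) == 1L) {
      labels[idx] <- offset + 1L
    } else {
      labels[idx] <- offset + kmeans_1d(ds$energies[idx], kg)
    }
    offset <- offset + kg
  }
  # compact label space (empty structural groups leave gaps)
  labels <- as.integer(factor(labels, levels = sort(unique(labels))))

  centroids <- rowsum(desc, structural) / as.vector(table(structural))
  out <- structure(
    list(
      labels = labels, structural_labels = as.integer(structural),
      n_structural = n_structural, n_total = max(labels),
      structural_centroids = centroids, seed = as.integer(seed),
      inverse_distances = inverse_distances, summaries = NULL
    ),
    class = "cluster_assignment"
  )
  if (!is.null(errors)) out <- summarize_clusters(out, errors)
  out
}

#' Attach per-cluster error summaries to an assignment
#'
#' Computes per-cluster size, mean force MAE and mean absolute energy error
#' from an error table. Calling this with different models' error tables on
#' one shared assignment makes cluster profiles comparable across models.
#'
#' @param assignment A [cluster_configurations()] result.
#' @param errors An [compute_error_table()] result on the same dataset.
#' @return The assignment with its `summaries` tibble
#'   (`cluster`, `size`, `force_mae`, `energy_mae`) replaced.
#' @export
summarize_clusters <- function(assignment, errors) {
  stopifnot(inherits(assignment, "cluster_assignment"), inherits(errors, "error_table"))
  if (nrow(errors$atom_errors) != length(assignment$labels)) {
    stop("error table and assignment cover different frame counts", call. = FALSE)
  }
  ids <- sort(unique(assignment$labels))
  assignment$summaries <- dplyr::bind_rows(lapply(ids, function(cid) {
    fi <- which(assignment$labels == cid)
    tibble(
      cluster = cid, size = length(fi),
      force_mae = mean(errors$atom_errors[fi, , drop = FALSE]),
      energy_mae = mean(abs(errors$energy_errors[fi]))
    )
  }))
  assignment
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$labels), " frames -> ", x$n_total,
    " clusters (", x$n_structural, " structural groups)\n",
    sep = ""
  )
  if (!is.null(x$summaries)) print(x$summaries, n = 5)
  invisible(x)
}

#' Cluster error profile, ascending
#'
#' Orders the per-cluster error summaries by ascending error value (stable;
#' ties broken by cluster id), the standard presentation of cluster-error
#' bar charts.
#'
#' @param assignment A summarised [cluster_configurations()] result.
#' @param metric `"force_mae"` or `"energy_mae"`.
#' @return A tibble (`cluster`, `size`, `value`) in ascending `value` order.
#' @export
cluster_error_profile <- function(assignment, metric = c("force_mae", "energy_mae")) {
  metric <- match.arg(metric)
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (is.null(assignment$summaries)) {
    stop("assignment has no summaries; call summarize_clusters() first", call. = FALSE)
  }
  s <- assignment$summaries
  out <- tibble(cluster = s$cluster, size = s$size, value = s[[metric]])
  dplyr::arrange(out, .data$value, .data$cluster)
}

#' Representative frames of each cluster
#'
#' For each cluster, the `k` member frames whose structural descriptors are
#' nearest (Euclidean) to the cluster's descriptor centroid; deterministic,
#' ties broken by frame index.
#'
#' @param assignment A [cluster_configurations()] result.
#' @param ds The clustered [configuration_set()].
#' @param k Representatives per cluster (clusters smaller than `k` return all
#'   their frames).
#' @return A named list of [make_subset()] views, one per cluster id.
#' @export
cluster_representatives <- function(assignment, ds, k = 1L) {
  stopifnot(inherits(assignment, "cluster_assignment"), inherits(ds, "configuration_set"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  desc <- descriptor_matrix(ds, inverse = assignment$inverse_distances)
  ids <- sort(unique(assignment$labels))
  out <- lapply(ids, function(cid) {
    fi <- which(assignment$labels == cid)
    centroid <- colMeans(desc[fi, , drop = FALSE])
    d2 <- rowSums(sweep(desc[fi, , drop = FALSE], 2, centroid)^2)
    ord <- order(d2, fi) # ties by frame index
    make_subset(ds, fi[ord[seq_len(min(k, length(fi)))]],
      label = paste0("cluster_", cid, "_representatives")
    )
  })
  names(out) <- as.character(ids)
  out
}
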