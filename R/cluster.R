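#' Binary co-occurrence footprints of slow oscillations
#'
#' For each detected SO on channel c, builds a length-`n_channels` binary
#' vector whose j-th entry is 1 iff some SO on channel j has its trough
#' within `tolerance_s` of this SO's trough (the SO's own channel is always
#' 1). Footprints feed the Global/Local clustering.
#'
#' @param so_events `so_events` data frame pooled over all channels.
#' @param channels character vector: the full montage (defines footprint
#'   order and length).
#' @param tolerance_s co-occurrence tolerance in seconds (default 0.4).
#' @return integer matrix, one row per SO (rows aligned with
#'   `so_events`), one column per channel.
#' @export
build_footprints <- function(so_events, channels = default_channel_labels(),
                             tolerance_s = 0.4) {
  n <- nrow(so_events)
  fp <- matrix(0L, n, length(channels), dimnames = list(NULL, channels))
  if (!n) return(fp)
  ch_idx <- match(so_events$channel, channels)
  if (anyNA(ch_idx)) stop("event channel not in the montage: ",
                          paste(unique(so_events$channel[is.na(ch_idx)]),
                                collapse = ", "))
  tt <- so_events$trough_time
  for (i in seq_len(n)) {
    near <- abs(tt - tt[i]) <= tolerance_s
    fp[i, unique(ch_idx[near])] <- 1L
    fp[i, ch_idx[i]] <- 1L
  }
  fp
}

# total within-cluster Hamming cost for an assignment and centroids
.hamming_cost <- function(X, centroids, labels) {
  sum(vapply(seq_len(nrow(X)), function(i)
    sum(X[i, ] != centroids[labels[i], ]), numeric(1)))
}

# one K-modes run from given initial centroids; returns labels/centroids/cost
.kmodes_once <- function(X, centroids, max_iter = 100L) {
  K <- nrow(centroids)
  labels <- rep(1L, nrow(X))
  for (it in seq_len(max_iter)) {
    D <- vapply(seq_len(K), function(k)
      rowSums(X != matrix(centroids[k, ], nrow(X), ncol(X), byrow = TRUE)),
      numeric(nrow(X)))
    new_labels <- max.col(-D, ties.method = "first")  # ties -> lower index
    new_centroids <- centroids
    for (k in seq_len(K)) {
      members <- X[new_labels == k, , drop = FALSE]
      if (nrow(members))                               # majority, ties -> 1
        new_centroids[k, ] <- as.integer(colMeans(members) >= 0.5)
    }
    if (identical(new_labels, labels) && identical(new_centroids, centroids)) break
    labels <- new_labels
    centroids <- new_centroids
  }
  list(labels = labels, centroids = centroids,
       cost = .hamming_cost(X, centroids, labels))
}

#' K-means with Hamming distance (K-modes) on binary footprints
#'
#' Clusters binary vectors into K groups by iterating minimum-Hamming
#' assignment and componentwise-majority centroid updates (majority ties
#' resolved to 1, assignment ties to the lower cluster index). The
#' procedure is restarted `reps` times from random distinct initial
#' centroids and the solution with the smallest total within-cluster
#' Hamming distance is returned. For K = 2 the cluster whose members have
#' the larger mean footprint size is labelled Global, the other Local.
#'
#' @param footprints binary matrix (rows = SOs).
#' @param K number of clusters (default 2).
#' @param reps number of random restarts (default 200).
#' @param seed integer RNG seed.
#' @return object of class `so_clusters`: list with `labels` (1 = Global,
#'   2 = Local when K = 2), `centroids`, `cost`, `cluster_names`.
#' @export
kmeans_hamming <- function(footprints, K = 2, reps = 200, seed = 1) {
  X <- as.matrix(footprints)
  storage.mode(X) <- "integer"
  uniq <- unique(X)
  if (nrow(uniq) < K)
    stop("fewer than K distinct footprints; clustering undefined")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(reps)) {
    init <- uniq[sample(nrow(uniq), K), , drop = FALSE]
    sol <- .kmodes_once(X, init)
    if (is.null(best) || sol$cost < best$cost) best <- sol
  }
  cluster_names <- as.character(seq_len(K))
  if (K == 2) {
    sizes <- tapply(rowSums(X), best$labels, mean)
    sizes <- sizes[as.character(1:2)]
    sizes[is.na(sizes)] <- -Inf
    if (sizes[2] > sizes[1]) {                       # make cluster 1 Global
      best$labels <- 3L - best$labels
      best$centroids <- best$centroids[2:1, , drop = FALSE]
    }
    cluster_names <- c("Global", "Local")
  }
  structure(list(labels = best$labels, centroids = best$centroids,
                 cost = best$cost, cluster_names = cluster_names,
                 K = K, reps = reps, seed = seed),
            class = "so_clusters")
}

#' @export
print.so_clusters <- function(x, ...) {
  tb <- table(factor(x$labels, levels = seq_len(x$K),
                     labels = x$cluster_names))
  cat("K-modes clustering (K =", x$K, ", cost =", x$cost, "):",
      paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Flag SO-spindle coupling
#'
#' An SO is coupled iff any spindle interval on any channel intersects the
#' window 1 s either side of its trough. Returns the coupling code used by
#' the statistics stage: noncoupled = 1, coupled = 2.
#'
#' @param so_events `so_events` data frame.
#' @param spindle_events data frame with columns `channel`, `start_s`,
#'   `end_s`.
#' @param window_s half-width of the coupling window (default 1 s).
#' @return integer vector along `so_events` rows: 1 (noncoupled) or 2
#'   (coupled).
#' @export
flag_coupling <- function(so_events, spindle_events, window_s = 1) {
  if (nrow(spindle_events) &&
      any(spindle_events$end_s < spindle_events$start_s))
    stop("malformed spindle interval: end before start")
  vapply(seq_len(nrow(so_events)), function(i) {
    t0 <- so_events$trough_time[i]
    hit <- nrow(spindle_events) > 0 &&
      any(spindle_events$start_s <= t0 + window_s &
            spindle_events$end_s >= t0 - window_s)
    if (hit) 2L else 1L
  }, integer(1))
}
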