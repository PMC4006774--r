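#' Spatially constrained voxel similarity graph
#'
#' Edges exist only between 6-connected neighbouring voxels and are weighted
#' by the Pearson correlation of their timeseries, clipped at 0 (negative
#' similarities removed so the normalized-cut objective stays well defined).
#' Zero-variance voxels get zero-weight edges, with a warning.
#'
#' @param voxel_ts Frames x V voxel timeseries (>= 2 frames).
#' @param coords V x 3 integer grid coordinates (1-based) defining adjacency.
#' @return List of class `voxel_graph`: `edges` (E x 2 voxel indices, i < j),
#'   `weights` (length E, in \[0, 1\]), `n_voxels`, `coords`.
#' @export
similarity_graph <- function(voxel_ts, coords) {
  voxel_ts <- as.matrix(voxel_ts)
  coords <- as.matrix(coords)
  V <- ncol(voxel_ts)
  if (nrow(voxel_ts) < 2L) stop("need at least 2 frames per voxel")
  if (nrow(coords) != V || ncol(coords) != 3L) {
    stop("`coords` must be a V x 3 grid coordinate matrix")
  }
  key <- function(xyz) paste(xyz[, 1], xyz[, 2], xyz[, 3])
  lookup <- new.env(hash = TRUE)
  kk <- key(coords)
  for (v in seq_len(V)) assign(kk[v], v, envir = lookup)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ei <- integer(0); ej <- integer(0)
  for (o in seq_len(3)) {
    nb <- sweep(coords, 2, offs[o, ], "+")
    nbk <- key(nb)
    hit <- vapply(nbk, function(s) exists(s, envir = lookup, inherits = FALSE),
                  logical(1))
    ei <- c(ei, which(hit))
    ej <- c(ej, vapply(nbk[hit], function(s) get(s, envir = lookup), 0L))
  }
  sds <- apply(voxel_ts, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance voxel(s): their edge weights set to 0",
                    sum(sds == 0)))
  }
  w <- numeric(length(ei))
  ok <- sds[ei] > 0 & sds[ej] > 0
  if (any(ok)) {
    x <- scale(voxel_ts)
    w[ok] <- colSums(x[, ei[ok], drop = FALSE] * x[, ej[ok], drop = FALSE]) /
      (nrow(voxel_ts) - 1L)
  }
  w <- pmax(w, 0)
  structure(list(
    edges = cbind(ei, ej), weights = w, n_voxels = V, coords = coords
  ), class = "voxel_graph")
}

graph_adjacency_list <- function(graph) {
  adj <- vector("list", graph$n_voxels)
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges[e, 1]; j <- graph$edges[e, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# connected components of a voxel subset under the graph's adjacency
flood_components <- function(members, adj) {
  remaining <- members
  comps <- list()
  inset <- logical(max(members))
  inset[members] <- TRUE
  seen <- logical(max(members))
  for (start in members) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, v)
      for (u in adj[[v]]) {
        if (u <= length(inset) && inset[u] && !seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Normalized-cut partition of a voxel similarity graph
#'
#' Normalized spectral clustering: top-K eigenvectors of the
#' symmetric-normalized affinity \eqn{D^{-1/2} A D^{-1/2}}, row-normalized,
#' clustered by seeded k-means. Because edges exist only between spatial
#' neighbours the clusters are spatially coherent; any residual discontiguous
#' fragments are reassigned to the adjacent label with maximal similarity, so
#' every returned label set is contiguous. Deterministic given the seed.
#'
#' @param graph A [similarity_graph()].
#' @param K Number of parcels (<= voxel count).
#' @param seed RNG seed for the k-means step.
#' @return Integer labels of length V in `1..K`.
#' @export
ncut_partition <- function(graph, K, seed = 1) {
  stopifnot(inherits(graph, "voxel_graph"))
  V <- graph$n_voxels
  if (!is_count(K) || K > V) stop("`K` must be a count <= the voxel count")
  if (K == 1L) return(rep(1L, V))
  A <- matrix(0, V, V)
  A[graph$edges] <- graph$weights
  A <- A + t(A)
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- A * tcrossprod(dinv)
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(K), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  U <- U / ifelse(nrm > 0, nrm, 1)
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(U, centers = K, nstart = 10, iter.max = 200)
  ))
  labels <- km$cluster
  enforce_contiguity(labels, graph)
}

# Keep the largest connected component per label; iteratively reassign
# orphaned voxels to the neighbouring label with the largest total edge
# similarity (falling back to any adjacent label).
enforce_contiguity <- function(labels, graph) {
  adj <- graph_adjacency_list(graph)
  wadj <- vector("list", graph$n_voxels)
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges[e, 1]; j <- graph$edges[e, 2]; w <- graph$weights[e]
    wadj[[i]] <- rbind(wadj[[i]], c(j, w))
    wadj[[j]] <- rbind(wadj[[j]], c(i, w))
  }
  orphan <- integer(0)
  for (lab in sort(unique(labels))) {
    members <- which(labels == lab)
    comps <- flood_components(members, adj)
    if (length(comps) > 1L) {
      sizes <- lengths(comps)
      keep <- which.max(sizes)
      orphan <- c(orphan, unlist(comps[-keep]))
    }
  }
  labels[orphan] <- NA
  while (any(is.na(labels))) {
    progress <- FALSE
    for (v in which(is.na(labels))) {
      nb <- wadj[[v]]
      if (is.null(nb)) next
      lab_nb <- labels[nb[, 1]]
      okn <- !is.na(lab_nb)
      if (!any(okn)) next
      sums <- tapply(nb[okn, 2], lab_nb[okn], sum)
      labels[v] <- as.integer(names(sums)[which.max(sums)])
      progress <- TRUE
    }
    if (!progress) { # isolated voxels: attach to label 1 arbitrarily
      labels[is.na(labels)] <- 1L
      break
    }
  }
  as.integer(labels)
}

#' Group-level parcellation from individual labelings
#'
#' Builds per-subject coincidence graphs (edge weight 1 between adjacent
#' voxels sharing a label, else 0), averages them across subjects, and
#' re-runs [ncut_partition()] at `K` on the averaged graph.
#'
#' @param labelings List (>= 2) of per-subject label vectors on a common grid.
#' @param graph The shared [similarity_graph()] (adjacency source).
#' @param K Number of group parcels.
#' @param seed RNG seed.
#' @return Integer group labels of length V.
#' @export
group_parcellation <- function(labelings, graph, K, seed = 1) {
  stopifnot(inherits(graph, "voxel_graph"))
  if (length(labelings) < 2L) stop("need at least 2 subjects")
  V <- graph$n_voxels
  if (any(vapply(labelings, length, 0L) != V)) {
    stop("inconsistent grids: every labeling must cover the common voxel grid")
  }
  co <- numeric(nrow(graph$edges))
  for (lab in labelings) {
    co <- co + (lab[graph$edges[, 1]] == lab[graph$edges[, 2]])
  }
  g2 <- graph
  g2$weights <- co / length(labelings)
  ncut_partition(g2, K, seed = seed)
}

#' Build an ROI set from labels and voxel coordinates
#'
#' @param labels Voxel parcel labels.
#' @param coords V x 3 voxel coordinates (grid units or mm).
#' @return List of class `roi_set`: `centroids` (ROI x 3, mean member
#'   coordinates), `members` (list of voxel indices), `roi_ids`.
#' @export
build_roi_set <- function(labels, coords) {
  coords <- as.matrix(coords)
  ids <- sort(unique(labels))
  members <- lapply(ids, function(id) which(labels == id))
  centroids <- t(vapply(members, function(m) {
    colMeans(coords[m, , drop = FALSE])
  }, numeric(3)))
  rownames(centroids) <- as.character(ids)
  structure(list(centroids = centroids, members = members, roi_ids = ids,
                 coords = coords),
            class = "roi_set")
}

#' Remove spatially discontiguous ROIs
#'
#' Flood-fill audit under 6-connectivity of the voxel coordinates; ROIs whose
#' member voxels form more than one connected component are removed and
#' reported.
#'
#' @param rois A [build_roi_set()].
#' @return The filtered `roi_set`, with attribute `removed` naming the
#'   discontiguous ROIs (empty if all pass).
#' @export
drop_discontiguous <- function(rois) {
  stopifnot(inherits(rois, "roi_set"))
  coords <- rois$coords
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  lut <- new.env(hash = TRUE)
  for (v in seq_len(nrow(coords))) assign(key[v], v, envir = lut)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  adj <- lapply(seq_len(nrow(coords)), function(v) {
    nb <- sweep(offs, 2, coords[v, ], "+")
    kk <- paste(nb[, 1], nb[, 2], nb[, 3])
    found <- kk[vapply(kk, function(s) exists(s, lut, inherits = FALSE), TRUE)]
    vapply(found, function(s) get(s, lut), 0L)
  })
  contiguous <- vapply(seq_along(rois$roi_ids), function(i) {
    length(flood_components(rois$members[[i]], adj)) == 1L
  }, TRUE)
  removed <- rois$roi_ids[!contiguous]
  out <- structure(list(
    centroids = rois$centroids[contiguous, , drop = FALSE],
    members = rois$members[contiguous],
    roi_ids = rois$roi_ids[contiguous],
    coords = rois$coords
  ), class = "roi_set")
  attr(out, "removed") <- removed
  if (length(removed) > 0L) {
    message(sprintf("removed %d discontiguous ROI(s): %s; %d remain",
                    length(removed), paste(removed, collapse = ", "),
                    length(out$roi_ids)))
  }
  out
}
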