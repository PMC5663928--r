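#' Fixed-radius k-means clustering of conformations by RMSD
#'
#' Radius-driven k-means in the style of MMTSB's kclust: k is grown —
#' seeding each new centroid at the structure farthest from its current
#' centroid — until every member lies within `radius_threshold` RMSD of its
#' cluster centroid. Within each k, assignments and coordinate-mean
#' centroids are iterated to a fixpoint (ties broken toward the lowest
#' cluster index). Structures are first superposed onto a global reference
#' (the first structure) so that RMSD reduces to a Euclidean distance on
#' flattened coordinates; a pairwise-superposition distance is available
#' via `pairwise = TRUE` for small inputs.
#'
#' @param structures `n x atoms x 3` array, list of `atoms x 3` matrices,
#'   or a [trajectory()].
#' @param radius_threshold cluster radius (A, default 1.6).
#' @param align superpose all structures onto the first before clustering.
#' @param pairwise use per-pair superposition when evaluating distances
#'   (quadratic cost; default FALSE).
#' @param max_iter assignment/update iterations per k (default 100; best
#'   assignment so far is kept with a warning on non-convergence).
#' @param seed integer seed recorded in the model (the algorithm itself is
#'   deterministic: first-structure initialisation + farthest-point
#'   splitting).
#' @return list of class `cluster_model`: `n_structures`, `assignments`,
#'   `centroids` (k x 3*atoms matrix), `radius_threshold`, `populations`,
#'   `max_radius`, `n_atoms`, `seed`.
#' @export
kmeans_rmsd <- function(structures, radius_threshold = 1.6, align = TRUE,
                        pairwise = FALSE, max_iter = 100L, seed = 1L) {
  if (inherits(structures, "trajectory")) structures <- structures$coords
  if (is.list(structures) && !is.array(structures)) {
    na <- unique(vapply(structures, nrow, integer(1)))
    if (length(na) != 1) stop("inconsistent atom counts across structures: ",
                              paste(na, collapse = ", "))
    arr <- array(0, dim = c(length(structures), na, 3))
    for (i in seq_along(structures)) arr[i, , ] <- structures[[i]]
    structures <- arr
  }
  stopifnot(is.array(structures), length(dim(structures)) == 3)
  n <- dim(structures)[1]; na <- dim(structures)[2]
  traj <- trajectory(structures)
  X <- aligned_coordinate_matrix(traj, reference = get_frame(traj, 1L),
                                 align = align)
  X_sq <- rowSums(X^2)
  dist_matrix <- function(centroids) {
    # n x k matrix of RMSDs via |x - c|^2 = |x|^2 + |c|^2 - 2 x.c
    if (!pairwise) {
      d2 <- outer(X_sq, rowSums(centroids^2), `+`) -
        2 * tcrossprod(X, centroids)
      return(sqrt(pmax(d2, 0) / na))
    }
    vapply(seq_len(nrow(centroids)), function(k) {
      cmat <- matrix(centroids[k, ], ncol = 3, byrow = TRUE)
      vapply(seq_len(nrow(X)), function(i) {
        m <- matrix(X[i, ], ncol = 3, byrow = TRUE)
        sp <- superpose(m, cmat)
        rmsd(apply_superposition(sp, m), cmat)
      }, numeric(1))
    }, numeric(nrow(X)))
  }

  centroids <- X[1, , drop = FALSE]           # first structure seeds k = 1
  assignments <- rep(1L, n)
  repeat {
    # Lloyd iterations at fixed k
    for (it in seq_len(max_iter)) {
      D <- matrix(dist_matrix(centroids), nrow = n)
      new_assign <- max.col(-D, ties.method = "first")
      for (k in seq_len(nrow(centroids))) {
        mem <- new_assign == k
        if (any(mem)) centroids[k, ] <- colMeans(X[mem, , drop = FALSE])
      }
      if (identical(new_assign, assignments)) break
      assignments <- new_assign
      if (it == max_iter)
        warning("assignment fixpoint not reached in ", max_iter,
                " iterations; keeping best-so-far")
    }
    D <- matrix(dist_matrix(centroids), nrow = n)
    to_cent <- D[cbind(seq_len(n), assignments)]
    if (max(to_cent) <= radius_threshold || nrow(centroids) >= n) break
    # every cluster violating the radius seeds a new centroid at its
    # farthest member (deterministic spread-seeking growth)
    for (k in seq_len(nrow(centroids))) {
      if (nrow(centroids) >= n) break
      mem <- which(assignments == k)
      if (length(mem) && max(to_cent[mem]) > radius_threshold)
        centroids <- rbind(centroids, X[mem[which.max(to_cent[mem])], ])
    }
  }
  pops <- tabulate(assignments, nbins = nrow(centroids)) / n
  structure(list(n_structures = n, assignments = assignments,
                 centroids = centroids, radius_threshold = radius_threshold,
                 populations = pops, to_centroid = to_cent,
                 max_radius = max(to_cent),
                 n_atoms = na, seed = as.integer(seed)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "cluster model: %d structures -> %d clusters (radius <= %.2f A, max %.3f A)\n",
    x$n_structures, nrow(x$centroids), x$radius_threshold, x$max_radius))
  invisible(x)
}

#' Ranked cluster-population report
#'
#' Clusters sorted by population (descending, ties broken by cluster
#' index), with each cluster's representative structure — the member
#' closest to the centroid.
#'
#' @param model a [kmeans_rmsd()] result.
#' @return data.frame with columns `cluster`, `population`, `n_members`,
#'   `representative` (structure index), `representative_rmsd` (A to
#'   centroid).
#' @export
population_report <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  k <- nrow(model$centroids)
  rows <- do.call(rbind, lapply(seq_len(k), function(cl) {
    mem <- which(model$assignments == cl)
    if (!length(mem))
      return(data.frame(cluster = cl, population = 0, n_members = 0L,
                        representative = NA_integer_,
                        representative_rmsd = NA_real_))
    best <- mem[which.min(model$to_centroid[mem])]
    data.frame(cluster = cl, population = model$populations[cl],
               n_members = length(mem), representative = best,
               representative_rmsd = model$to_centroid[best])
  }))
  rows <- rows[order(-rows$population, rows$cluster), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
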