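#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation that minimise the (optionally
#' mass-weighted) squared deviation of `mobile` from `reference` over a
#' selection of atoms, via SVD of the weighted cross-covariance with the
#' reflection-corrected (negative-determinant) branch.
#'
#' @param mobile,reference `n x 3` coordinate matrices with matching atom
#'   order.
#' @param selection atom indices the fit is computed over (default all).
#' @param weights optional per-selected-atom weights (e.g. masses).
#' @param strict error (instead of warn) when the rotation is
#'   under-determined (< 3 non-collinear selected atoms).
#' @return list of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd_after` (A, over the selection).
#'   The fitted coordinates of any matrix `x` are
#'   `apply_superposition(sp, x)`.
#' @export
superpose <- function(mobile, reference, selection = NULL, weights = NULL,
                      strict = FALSE) {
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (!length(selection)) stop("empty selection")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  n <- nrow(P)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  w <- weights / sum(weights)
  cm_p <- colSums(P * w); cm_q <- colSums(Q * w)
  Pc <- sweep(P, 2, cm_p); Qc <- sweep(Q, 2, cm_q)
  rk <- qr(Qc)$rank
  if (n < 3 || rk < 2) {
    msg <- "rotation under-determined: fewer than 3 non-collinear atoms in selection"
    if (strict) stop(msg) else warning(msg)
  }
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- cm_q - as.vector(R %*% cm_p)
  fitted <- P %*% t(R) + matrix(translation, n, 3, byrow = TRUE)
  rmsd_after <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = translation,
                 rmsd_after = rmsd_after),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param sp a `superposition`.
#' @param coords `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sp, coords) {
  coords %*% t(sp$rotation) +
    matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b `n x 3` matrices.
#' @param selection optional atom indices.
#' @return RMSD in A (no superposition is performed).
#' @export
rmsd <- function(a, b, selection = NULL) {
  if (!is.null(selection)) {
    a <- a[selection, , drop = FALSE]; b <- b[selection, , drop = FALSE]
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD series with independent alignment selection
#'
#' Each frame is first superposed onto the reference over `align_selection`
#' (e.g. protein C-alpha), then the RMSD is reported over `selection` (e.g.
#' ligand heavy atoms) — the usual align-on-backbone, report-on-ligand
#' pattern.
#'
#' @param traj a [trajectory()].
#' @param reference `n x 3` reference coordinates (default first frame).
#' @param selection atom indices reported over (default all).
#' @param align_selection atom indices fitted over (default `selection`).
#' @param align superpose before measuring (set FALSE for pre-aligned input).
#' @return numeric vector, one RMSD (A) per frame.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL,
                        align_selection = NULL, align = TRUE) {
  if (is.null(reference)) reference <- get_frame(traj, 1L)
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (!length(selection)) stop("empty selection")
  if (is.null(align_selection)) align_selection <- selection
  vapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    if (align) {
      sp <- superpose(fr, reference, selection = align_selection)
      fr <- apply_superposition(sp, fr)
    }
    rmsd(fr, reference, selection)
  }, numeric(1))
}

#' Per-atom root-mean-square fluctuation
#'
#' RMS deviation of each selected atom from its time-average position after
#' per-frame superposition onto the reference over `align_selection`.
#'
#' @inheritParams rmsd_series
#' @return numeric vector, one RMSF (A) per selected atom.
#' @export
rmsf <- function(traj, selection = NULL, align_selection = NULL,
                 reference = NULL, align = TRUE) {
  if (n_frames(traj) < 2) stop("RMSF requires at least 2 frames")
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (!length(selection)) stop("empty selection")
  if (is.null(align_selection)) align_selection <- selection
  if (is.null(reference)) reference <- get_frame(traj, 1L)
  X <- aligned_coordinate_matrix(traj, reference, selection, align_selection,
                                 align = align)
  mu <- colMeans(X)
  dev2 <- sweep(X, 2, mu)^2
  per_coord <- colMeans(dev2)
  sqrt(per_coord[c(TRUE, FALSE, FALSE)] + per_coord[c(FALSE, TRUE, FALSE)] +
         per_coord[c(FALSE, FALSE, TRUE)])
}

#' Flattened, aligned coordinate matrix of a trajectory
#'
#' Superposes every frame onto `reference` over `align_selection` and
#' returns the coordinates of `selection` as an
#' `n_frames x 3*n_sel` matrix (atom-major: x1,y1,z1,x2,...). This is the
#' shared workhorse of RMSF, the quasi-harmonic covariance and clustering.
#'
#' @inheritParams rmsd_series
#' @return numeric matrix.
#' @export
aligned_coordinate_matrix <- function(traj, reference = NULL, selection = NULL,
                                      align_selection = NULL, align = TRUE) {
  if (is.null(reference)) reference <- get_frame(traj, 1L)
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (is.null(align_selection)) align_selection <- selection
  if (!align) {
    sub <- traj$coords[, selection, , drop = FALSE]
    return(matrix(aperm(sub, c(1, 3, 2)), nrow = n_frames(traj)))
  }
  X <- matrix(0, n_frames(traj), 3L * length(selection))
  for (f in seq_len(n_frames(traj))) {
    fr <- get_frame(traj, f)
    sp <- superpose(fr, reference, selection = align_selection)
    fr <- apply_superposition(sp, fr)
    X[f, ] <- as.vector(t(fr[selection, , drop = FALSE]))
  }
  X
}
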