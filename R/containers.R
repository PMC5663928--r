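#' Trajectory container
#'
#' Holds Cartesian coordinates for a set of frames over a fixed atom order.
#' Coordinates are Angstrom, timestamps picoseconds.
#'
#' @param coords numeric array of dimension `c(n_frames, n_atoms, 3)`, or a
#'   single `n_atoms x 3` matrix (promoted to one frame).
#' @param time_ps per-frame timestamps (ps); strictly increasing. Defaults to
#'   `1..n_frames`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, time_ps = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n_frames <- dim(coords)[1]
  if (is.null(time_ps)) time_ps <- as.numeric(seq_len(n_frames))
  if (length(time_ps) != n_frames)
    stop("time_ps length (", length(time_ps), ") != n_frames (", n_frames, ")")
  if (n_frames > 1L && any(diff(time_ps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(coords = coords, time_ps = as.numeric(time_ps)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = [%g, %g] ps\n",
              n_frames(x), n_atoms(x), x$time_ps[1],
              x$time_ps[length(x$time_ps)]))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a `trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame as an `n_atoms x 3` coordinate matrix
#' @param traj a `trajectory`.
#' @param i frame index.
#' @return numeric matrix.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Subset a trajectory by frame index
#' @param traj a `trajectory`.
#' @param frames integer frame indices (in order).
#' @return a `trajectory`.
#' @export
subset_frames <- function(traj, frames) {
  trajectory(traj$coords[frames, , , drop = FALSE], traj$time_ps[frames])
}

#' Topology container
#'
#' Per-atom identity aligned with the trajectory atom order, plus the bond
#' list. Donor/acceptor/hydrophobic annotations are explicit so geometric
#' interaction criteria are exact and auditable; [annotate_topology()]
#' derives conventional defaults which the user may override.
#'
#' @param atoms data.frame with columns `name`, `element`, `mass`, `resno`,
#'   `resname`, `segid`, `molclass` (one of protein/ligand/water/ion) and
#'   optionally logical `donor`, `acceptor`, `hydrophobic`.
#' @param bonds two-column integer matrix of 1-based atom indices (may have
#'   zero rows).
#' @param validate check invariants (masses > 0, donors have a bonded
#'   hydrogen, flags only on heavy atoms).
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, bonds = matrix(integer(0), ncol = 2), validate = TRUE) {
  req <- c("name", "element", "mass", "resno", "resname", "segid", "molclass")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("topology atoms missing columns: ", paste(miss, collapse = ", "))
  for (fl in c("donor", "acceptor", "hydrophobic"))
    if (is.null(atoms[[fl]])) atoms[[fl]] <- FALSE
  atoms$is_heavy <- atoms$element != "H"
  bonds <- matrix(as.integer(bonds), ncol = 2)
  top <- structure(list(atoms = atoms, bonds = bonds), class = "topology")
  if (validate) validate_topology(top)
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms (%d heavy), %d bonds; classes: %s\n",
              nrow(x$atoms), sum(x$atoms$is_heavy), nrow(x$bonds),
              paste(unique(x$atoms$molclass), collapse = ", ")))
  invisible(x)
}

#' Validate topology invariants
#' @param top a `topology`.
#' @return `top`, invisibly; errors describe the offending atom.
#' @export
validate_topology <- function(top) {
  a <- top$atoms
  if (any(a$mass <= 0)) stop("non-positive mass for atom(s) ",
                             paste(which(a$mass <= 0), collapse = ", "))
  if (nrow(top$bonds) &&
      (any(top$bonds < 1) || any(top$bonds > nrow(a))))
    stop("bond indices out of range")
  bad_flag <- (!a$is_heavy) & (a$donor | a$acceptor | a$hydrophobic)
  if (any(bad_flag))
    stop("interaction flags set on hydrogen atom(s) ",
         paste(which(bad_flag), collapse = ", "))
  don <- which(a$donor)
  for (i in don) {
    if (length(bonded_hydrogens(top, i)) == 0L)
      stop("donor atom ", i, " (", a$name[i], " in ", a$resname[i], a$resno[i],
           ") has no bonded hydrogen")
  }
  invisible(top)
}

#' Bonded hydrogens of an atom
#' @param top a `topology`.
#' @param i atom index.
#' @return integer indices of hydrogens bonded to atom `i`.
#' @export
bonded_hydrogens <- function(top, i) {
  b <- top$bonds
  if (!nrow(b)) return(integer(0))
  nb <- c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
  nb[top$atoms$element[nb] == "H"]
}

.neighbors <- function(top, i) {
  b <- top$bonds
  if (!nrow(b)) return(integer(0))
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

#' Derive default donor/acceptor/hydrophobic annotations
#'
#' Conventions: donor = N or O with at least one bonded hydrogen;
#' acceptor = N or O; hydrophobic = C or S whose bonded neighbours are all
#' C, S or H. Explicit flags already present are kept when
#' `overwrite = FALSE`.
#'
#' @param top a `topology`.
#' @param overwrite replace existing flags (default TRUE).
#' @return a `topology` with flags filled in.
#' @export
annotate_topology <- function(top, overwrite = TRUE) {
  a <- top$atoms
  n <- nrow(a)
  donor <- acceptor <- hydrophobic <- logical(n)
  for (i in seq_len(n)) {
    if (a$element[i] %in% c("N", "O")) {
      acceptor[i] <- TRUE
      if (length(bonded_hydrogens(top, i))) donor[i] <- TRUE
    } else if (a$element[i] %in% c("C", "S")) {
      nb <- .neighbors(top, i)
      if (all(a$element[nb] %in% c("C", "S", "H"))) hydrophobic[i] <- TRUE
    }
  }
  if (overwrite) {
    a$donor <- donor; a$acceptor <- acceptor; a$hydrophobic <- hydrophobic
  } else {
    a$donor <- a$donor | donor
    a$acceptor <- a$acceptor | acceptor
    a$hydrophobic <- a$hydrophobic | hydrophobic
  }
  a$donor[a$element == "H"] <- FALSE
  a$acceptor[a$element == "H"] <- FALSE
  a$hydrophobic[a$element == "H"] <- FALSE
  topology(a, top$bonds, validate = FALSE)
}

#' Atom selections by topology attribute
#'
#' @param top a `topology`.
#' @param molclass optional molecule classes to keep (protein/ligand/water/ion).
#' @param heavy_only keep heavy atoms only.
#' @param element optional element filter.
#' @param name optional atom-name filter (exact match, e.g. "CA").
#' @return integer atom indices.
#' @export
select_atoms <- function(top, molclass = NULL, heavy_only = FALSE,
                         element = NULL, name = NULL) {
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(molclass)) keep <- keep & a$molclass %in% molclass
  if (heavy_only) keep <- keep & a$is_heavy
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(name)) keep <- keep & a$name %in% name
  which(keep)
}
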