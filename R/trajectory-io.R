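ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, CL = 35.45,
                    NA. = 22.99, MG = 24.305, K = 39.098, CA = 40.078,
                    ZN = 65.38, FE = 55.845)

.element_mass <- function(element) {
  key <- ifelse(toupper(element) == "NA", "NA.", toupper(element))
  m <- ELEMENT_MASSES[key]
  if (any(is.na(m)))
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Read a single-frame structure file
#'
#' PDB files are parsed per the fixed-column standard (via bio3d, after a
#' line-level validation pass that reports malformed or truncated ATOM
#' records by line number); XYZ files per the plain element-x-y-z
#' convention. Atom names, elements and coordinates are preserved; masses
#' are filled from the element table.
#'
#' @param path file to read.
#' @param format "pdb" or "xyz" (default: from extension).
#' @return list with `trajectory` (one frame) and `topology` (partial:
#'   names/elements/masses/residues; interaction flags unset — see
#'   [annotate_topology()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    lines <- readLines(path)
    rec <- grepl("^(ATOM|HETATM)", lines)
    bad <- which(rec & nchar(lines) < 54)
    if (length(bad))
      stop("malformed ATOM/HETATM record at line ", bad[1], " of ", path,
           " (", nchar(lines[bad[1]]), " columns; need >= 54)")
    if (!any(rec)) stop("no ATOM/HETATM records in ", path)
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    element <- trimws(a$elesy)
    fix <- is.na(element) | element == ""
    element[fix] <- substr(trimws(a$elety[fix]), 1, 1)
    coords <- cbind(a$x, a$y, a$z)
    atoms <- data.frame(
      name = trimws(a$elety), element = element,
      mass = .element_mass(element), resno = a$resno,
      resname = trimws(a$resid),
      segid = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
      molclass = .guess_molclass(trimws(a$resid)),
      stringsAsFactors = FALSE)
    return(list(trajectory = trajectory(coords),
                topology = topology(atoms, validate = FALSE)))
  }
  tr <- read_trajectory(path, format = "xyz")
  list(trajectory = subset_frames(tr$trajectory, 1L), topology = tr$topology)
}

.guess_molclass <- function(resname) {
  water <- c("HOH", "TIP3", "WAT", "SOL", "SPC")
  ions <- c("NA", "CL", "K", "MG", "CA", "ZN", "SOD", "CLA", "POT")
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
          "THR", "TRP", "TYR", "VAL", "PRT")
  ifelse(resname %in% water, "water",
         ifelse(resname %in% ions, "ion",
                ifelse(resname %in% aa, "protein", "ligand")))
}

#' Write a structure (single frame) as PDB
#'
#' @param coords `n x 3` matrix (A).
#' @param top a [topology()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(coords, top, path) {
  stopifnot(nrow(coords) == nrow(top$atoms))
  a <- top$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords)),
                   resno = a$resno, resid = a$resname, elety = a$name,
                   chain = substr(a$segid, 1, 1), elesy = a$element)
  invisible(path)
}

#' Read a multi-frame trajectory
#'
#' XYZ: standard repeated blocks (count line, comment line with optional
#' `t= <ps>` tag, atom lines). DCD: CHARMM-style binary headers via
#' bio3d's reader; timestamps are taken from `interval_ps` since DCD
#' headers carry time in engine-internal units.
#'
#' @param path file to read.
#' @param format "xyz" or "dcd" (default: from extension).
#' @param top optional [topology()]; atom counts are checked against it.
#' @param interval_ps frame spacing used when the file carries no
#'   timestamps (default 1 ps).
#' @return list with `trajectory` and `topology` (the supplied one, or a
#'   partial one for XYZ).
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "dcd"),
                            top = NULL, interval_ps = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "xyz"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dcd") {
    m <- bio3d::read.dcd(path, verbose = FALSE)
    nf <- nrow(m); na <- ncol(m) / 3
    if (!is.null(top) && na != nrow(top$atoms))
      stop("atom-count mismatch: DCD has ", na, " atoms, topology has ",
           nrow(top$atoms))
    coords <- array(0, dim = c(nf, na, 3))
    for (f in seq_len(nf))
      coords[f, , ] <- matrix(m[f, ], ncol = 3,
                              byrow = TRUE)       # bio3d xyz is x1,y1,z1,...
    tr <- trajectory(coords, time_ps = seq_len(nf) * interval_ps)
    return(list(trajectory = tr, topology = top))
  }
  lines <- readLines(path)
  i <- 1L; frames <- list(); times <- numeric(0); elements <- NULL
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("expected atom count at line ", i, " of ", path)
    na <- as.integer(lines[i])
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4))
      stop("truncated atom line at line ",
           i + 1L + which(lengths(parts) < 4)[1], " of ", path)
    el <- vapply(parts, `[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(xyz)) stop("non-numeric coordinate in frame ",
                         length(frames) + 1L, " of ", path)
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop("frame ", length(frames) + 1L, " has ", length(el),
           " atoms; expected ", length(elements))
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    i <- i + 2L + na
  }
  nf <- length(frames)
  if (anyNA(times)) times <- seq_len(nf) * interval_ps
  coords <- array(0, dim = c(nf, length(elements), 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  if (!is.null(top)) {
    if (nrow(top$atoms) != length(elements))
      stop("atom-count mismatch: XYZ has ", length(elements),
           " atoms, topology has ", nrow(top$atoms))
  } else {
    atoms <- data.frame(
      name = elements, element = elements, mass = .element_mass(elements),
      resno = 1L, resname = "MOL", segid = "A", molclass = "ligand",
      stringsAsFactors = FALSE)
    top <- topology(atoms, validate = FALSE)
  }
  list(trajectory = trajectory(coords, time_ps = times), topology = top)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Coordinates are written at 1e-3 A precision; timestamps go into each
#' frame's comment line as `t= <ps>`.
#'
#' @param traj a [trajectory()].
#' @param top a [topology()] supplying element symbols.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, top, path) {
  stopifnot(n_atoms(traj) == nrow(top$atoms))
  con <- file(path, "w"); on.exit(close(con))
  el <- top$atoms$element
  for (f in seq_len(n_frames(traj))) {
    fr <- get_frame(traj, f)
    writeLines(c(as.character(n_atoms(traj)),
                 sprintf("frame %d t= %.4f", f, traj$time_ps[f]),
                 sprintf("%-2s %12.3f %12.3f %12.3f",
                         el, fr[, 1], fr[, 2], fr[, 3])), con)
  }
  invisible(path)
}

#' Write a trajectory as CHARMM-style DCD
#'
#' Minimal single-precision CHARMM DCD writer (Fortran record markers,
#' CORD header, per-frame X/Y/Z records); readable by standard tools and
#' round-tripped in the tests against bio3d's independent DCD reader.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_dcd <- function(traj, path) {
  con <- file(path, "wb"); on.exit(close(con))
  nf <- n_frames(traj); na <- n_atoms(traj)
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
    icntrl[20] <- 24L
    writeBin(icntrl[1:9], con, size = 4)
    writeBin(1, con, size = 4)          # DELTA as float32 (AKMA units)
    writeBin(icntrl[11:20], con, size = 4)
  }, 84)
  title <- formatC("generated by alchemtraj", width = -80)
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4), 4)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    for (d in 1:3)
      rec(function() writeBin(as.numeric(fr[, d]), con, size = 4), 4 * na)
  }
  invisible(path)
}

#' Write / read the topology sidecar
#'
#' Structured-text sidecar holding the per-atom records and bond list; JSON
#' or YAML chosen by file extension. Schema: an `atoms` array of records
#' (`name`, `element`, `mass`, `resno`, `resname`, `segid`, `molclass`,
#' `donor`, `acceptor`, `hydrophobic`) in trajectory atom order, and a
#' `bonds` array of 1-based index pairs.
#'
#' @param top a [topology()].
#' @param path file ending in .json, .yaml or .yml.
#' @return `path` (writer) / a [topology()] (reader).
#' @export
write_topology <- function(top, path) {
  cols <- c("name", "element", "mass", "resno", "resname", "segid",
            "molclass", "donor", "acceptor", "hydrophobic")
  obj <- list(atoms = top$atoms[, cols],
              bonds = if (nrow(top$bonds)) unname(apply(top$bonds, 1, c,
                                                        simplify = FALSE))
                      else list())
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    obj$atoms <- lapply(seq_len(nrow(obj$atoms)),
                        function(i) as.list(obj$atoms[i, ]))
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  atoms <- obj$atoms
  if (!is.data.frame(atoms))
    atoms <- do.call(rbind, lapply(atoms, function(a)
      as.data.frame(a, stringsAsFactors = FALSE)))
  bonds <- if (is.matrix(obj$bonds)) obj$bonds
  else if (length(obj$bonds))
    matrix(as.integer(unlist(obj$bonds)), ncol = 2, byrow = TRUE)
  else matrix(integer(0), ncol = 2)
  topology(atoms, bonds)
}

#' Write FEP window samples as a TSV table
#'
#' Dialect: one sample per row, columns `lambda_from`, `lambda_to`,
#' `temperature_K`, `sample_kcal_mol`; windows appear as contiguous row
#' groups in input order (forward and reverse windows of a bidirectional
#' schedule stay distinct groups).
#'
#' @param windows a [fep_window_samples()] or list thereof.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fep_samples <- function(windows, path) {
  if (inherits(windows, "fep_window_samples")) windows <- list(windows)
  df <- do.call(rbind, lapply(windows, function(w)
    data.frame(lambda_from = w$lambda_from, lambda_to = w$lambda_to,
               temperature_K = w$temperature,
               sample_kcal_mol = w$samples)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FEP window samples from a TSV table
#'
#' Rows are grouped by (`lambda_from`, `lambda_to`, `temperature_K`) in
#' order of first appearance; each group becomes one
#' [fep_window_samples()]. Non-numeric cells are rejected with their row
#' index; lambda values outside `[0, 1]` are rejected.
#'
#' @param path file written by [write_fep_samples()] (or any table in the
#'   same dialect).
#' @param block_size optional block size attached to every window.
#' @return list of [fep_window_samples()].
#' @export
read_fep_samples <- function(path, block_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("lambda_from", "lambda_to", "temperature_K", "sample_kcal_mol")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("no sample rows in ", path)
  num <- lapply(df[need], function(col) suppressWarnings(as.numeric(col)))
  for (cn in need) {
    bad <- which(is.na(num[[cn]]) & !is.na(df[[cn]]))
    if (length(bad))
      stop("non-numeric value '", df[[cn]][bad[1]], "' in column ", cn,
           " at data row ", bad[1])
  }
  lf <- num$lambda_from; lt <- num$lambda_to
  if (any(lf < 0 | lf > 1 | lt < 0 | lt > 1))
    stop("lambda outside [0, 1] at data row ",
         which(lf < 0 | lf > 1 | lt < 0 | lt > 1)[1])
  key <- paste(lf, lt, num$temperature_K)
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(groups, function(idx)
    fep_window_samples(lf[idx[1]], lt[idx[1]], num$temperature_K[idx[1]],
                       num$sample_kcal_mol[idx], block_size = block_size))
}
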