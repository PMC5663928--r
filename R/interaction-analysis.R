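#' Geometric interaction criteria
#'
#' Defaults follow the standard geometric definitions used in MD contact
#' analysis: a hydrogen bond requires a donor-hydrogen-acceptor angle of at
#' least 120 degrees and a donor-to-acceptor heavy-atom distance of at most
#' 3 A; a hydrophobic contact requires two hydrophobic-flagged heavy atoms
#' within 4 A. The distance criterion is applied to the heavy-atom (D..A)
#' separation, not H..A; both cutoffs are configurable.
#'
#' @param hbond_min_angle minimum D-H-A angle (degrees, default 120).
#' @param hbond_max_heavy_dist maximum D..A distance (A, default 3).
#' @param hydrophobic_max_dist maximum contact distance (A, default 4).
#' @return list of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_min_angle = 120,
                                 hbond_max_heavy_dist = 3,
                                 hydrophobic_max_dist = 4) {
  stopifnot(hbond_min_angle > 0, hbond_min_angle <= 180,
            hbond_max_heavy_dist > 0, hydrophobic_max_dist > 0)
  structure(list(hbond_min_angle = hbond_min_angle,
                 hbond_max_heavy_dist = hbond_max_heavy_dist,
                 hydrophobic_max_dist = hydrophobic_max_dist),
            class = "interaction_criteria")
}

.angle_deg <- function(a, b, c) {
  # angle at b between rays b->a and b->c
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds in one frame
#'
#' A (donor, hydrogen, acceptor) triple is reported iff the donor flag is
#' set on D, the acceptor flag on A, dist(D, A) <= the heavy-atom cutoff,
#' and the D-H-A angle >= the angle cutoff for some hydrogen bonded to D.
#' Both inter- and intramolecular pairs are evaluated; molecule-level
#' filtering is left to callers such as [occupancy_table()].
#'
#' @param frame `n x 3` coordinate matrix.
#' @param top a [topology()] (donors must have explicit bonded hydrogens).
#' @param criteria an [interaction_criteria()].
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `dist`, `angle`.
#' @export
detect_hbonds <- function(frame, top, criteria = interaction_criteria()) {
  a <- top$atoms
  donors <- which(a$donor)
  acceptors <- which(a$acceptor)
  out <- list()
  for (D in donors) {
    hyd <- bonded_hydrogens(top, D)
    if (!length(hyd))
      stop("donor atom ", D, " (", a$name[D], ") has no bonded hydrogen")
    acc <- setdiff(acceptors, D)
    if (!length(acc)) next
    dDA <- sqrt(rowSums((frame[acc, , drop = FALSE] -
                           matrix(frame[D, ], length(acc), 3, byrow = TRUE))^2))
    for (k in seq_along(acc)) {
      if (dDA[k] > criteria$hbond_max_heavy_dist) next
      A <- acc[k]
      for (H in hyd) {
        ang <- .angle_deg(frame[D, ], frame[H, ], frame[A, ])
        if (ang >= criteria$hbond_min_angle) {
          out[[length(out) + 1L]] <- data.frame(
            donor = D, hydrogen = H, acceptor = A,
            dist = dDA[k], angle = ang)
          break
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), dist = numeric(0),
                      angle = numeric(0)))
  do.call(rbind, out)
}

#' Detect single-water-bridged hydrogen bonds in one frame
#'
#' A (ligand atom, water, protein atom) triple is reported iff one water
#' residue simultaneously hydrogen-bonds (per [detect_hbonds()] criteria, in
#' either donor or acceptor role) to a ligand atom and to a protein atom in
#' the same frame. Chains through two or more waters are excluded by
#' definition.
#'
#' @inheritParams detect_hbonds
#' @return data.frame with columns `ligand_atom`, `water_resno`,
#'   `protein_atom`.
#' @export
detect_water_bridges <- function(frame, top, criteria = interaction_criteria()) {
  hb <- detect_hbonds(frame, top, criteria)
  a <- top$atoms
  empty <- data.frame(ligand_atom = integer(0), water_resno = integer(0),
                      protein_atom = integer(0))
  if (!nrow(hb)) return(empty)
  cls <- function(i) a$molclass[i]
  # water-involving H-bonds, expressed as (water atom, partner atom)
  wpart <- rbind(
    data.frame(w = hb$donor[cls(hb$acceptor) != "water" & cls(hb$donor) == "water"],
               p = hb$acceptor[cls(hb$acceptor) != "water" & cls(hb$donor) == "water"]),
    data.frame(w = hb$acceptor[cls(hb$donor) != "water" & cls(hb$acceptor) == "water"],
               p = hb$donor[cls(hb$donor) != "water" & cls(hb$acceptor) == "water"]))
  if (!nrow(wpart)) return(empty)
  wres <- a$resno[wpart$w]
  out <- list()
  for (r in unique(wres)) {
    part <- wpart$p[wres == r]
    lig <- unique(part[cls(part) == "ligand"])
    pro <- unique(part[cls(part) == "protein"])
    if (length(lig) && length(pro))
      out[[length(out) + 1L]] <- expand.grid(ligand_atom = lig,
                                             water_resno = r,
                                             protein_atom = pro)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect hydrophobic contacts in one frame
#'
#' A pair is reported iff both atoms carry the hydrophobic flag, belong to
#' different molecule classes, and are within the distance cutoff.
#'
#' @inheritParams detect_hbonds
#' @return data.frame with columns `atom_a`, `atom_b`, `dist`
#'   (`atom_a < atom_b`).
#' @export
detect_hydrophobic <- function(frame, top, criteria = interaction_criteria()) {
  a <- top$atoms
  idx <- which(a$hydrophobic)
  empty <- data.frame(atom_a = integer(0), atom_b = integer(0),
                      dist = numeric(0))
  if (length(idx) < 2) return(empty)
  pairs <- utils::combn(idx, 2)
  keep_mol <- a$molclass[pairs[1, ]] != a$molclass[pairs[2, ]]
  pairs <- pairs[, keep_mol, drop = FALSE]
  if (!ncol(pairs)) return(empty)
  d <- sqrt(rowSums((frame[pairs[1, ], , drop = FALSE] -
                       frame[pairs[2, ], , drop = FALSE])^2))
  keep <- d <= criteria$hydrophobic_max_dist
  data.frame(atom_a = pairs[1, keep], atom_b = pairs[2, keep],
             dist = d[keep])
}

.atom_label <- function(top, i) {
  a <- top$atoms
  sprintf("%s:%s%d:%s", a$segid[i], a$resname[i], a$resno[i], a$name[i])
}

.res_label <- function(top, i) {
  a <- top$atoms
  sprintf("%s:%s%d", a$segid[i], a$resname[i], a$resno[i])
}

#' Trajectory-level interaction occupancy table
#'
#' Runs the three frame-wise detectors over every frame, keeps
#' intermolecular (ligand-protein) records, and reports each observed
#' partner pair with its occupancy — the fraction of frames in which the
#' interaction is present — plus the per-frame presence bitmap. Records are
#' sorted by descending occupancy with a deterministic lexicographic
#' tie-break on the partner identifiers. No occupancy threshold is imposed;
#' the `conserved` column annotates records with occupancy >= 0.5.
#'
#' @param traj a [trajectory()].
#' @param top a [topology()].
#' @param criteria an [interaction_criteria()].
#' @param grouping "atom" for atom-pair records, "residue" to merge records
#'   of the same residue pair (bitmaps OR-ed).
#' @param kinds subset of c("hbond", "water_bridge", "hydrophobic").
#' @return data.frame of class `occupancy_table` with columns `kind`,
#'   `partner_a`, `partner_b`, `occupancy`, `n_frames`, `conserved`, and a
#'   list-column `bitmap` of logical vectors.
#' @export
occupancy_table <- function(traj, top, criteria = interaction_criteria(),
                            grouping = c("atom", "residue"),
                            kinds = c("hbond", "water_bridge", "hydrophobic")) {
  grouping <- match.arg(grouping)
  nf <- n_frames(traj)
  if (nf < 1) stop("empty trajectory")
  cls <- top$atoms$molclass
  bitmaps <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  mark <- function(kind, key_a, key_b, f) {
    key <- paste(kind, key_a, key_b, sep = "\r")
    if (is.null(bitmaps[[key]])) {
      bitmaps[[key]] <- logical(nf)
      meta[[key]] <- data.frame(kind = kind, partner_a = key_a,
                                partner_b = key_b, stringsAsFactors = FALSE)
    }
    bm <- bitmaps[[key]]; bm[f] <- TRUE; bitmaps[[key]] <- bm
  }
  lab <- if (grouping == "atom") .atom_label else .res_label
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    if ("hbond" %in% kinds) {
      hb <- detect_hbonds(fr, top, criteria)
      keep <- (cls[hb$donor] == "ligand" & cls[hb$acceptor] == "protein") |
        (cls[hb$donor] == "protein" & cls[hb$acceptor] == "ligand")
      hb <- hb[keep, , drop = FALSE]
      for (k in seq_len(nrow(hb)))
        mark("hbond", lab(top, hb$donor[k]), lab(top, hb$acceptor[k]), f)
    }
    if ("water_bridge" %in% kinds) {
      wb <- detect_water_bridges(fr, top, criteria)
      for (k in seq_len(nrow(wb)))
        mark("water_bridge", lab(top, wb$ligand_atom[k]),
             lab(top, wb$protein_atom[k]), f)
    }
    if ("hydrophobic" %in% kinds) {
      hp <- detect_hydrophobic(fr, top, criteria)
      keep <- (cls[hp$atom_a] == "ligand" & cls[hp$atom_b] == "protein") |
        (cls[hp$atom_a] == "protein" & cls[hp$atom_b] == "ligand")
      hp <- hp[keep, , drop = FALSE]
      for (k in seq_len(nrow(hp)))
        mark("hydrophobic", lab(top, hp$atom_a[k]), lab(top, hp$atom_b[k]), f)
    }
  }
  keys <- ls(bitmaps)
  if (!length(keys)) {
    out <- data.frame(kind = character(0), partner_a = character(0),
                      partner_b = character(0), occupancy = numeric(0),
                      n_frames = integer(0), conserved = logical(0))
    out$bitmap <- list()
    class(out) <- c("occupancy_table", class(out))
    return(out)
  }
  out <- do.call(rbind, lapply(keys, function(k) meta[[k]]))
  out$occupancy <- vapply(keys, function(k) mean(bitmaps[[k]]), numeric(1))
  out$n_frames <- nf
  out$conserved <- out$occupancy >= 0.5
  out$bitmap <- lapply(keys, function(k) bitmaps[[k]])
  ord <- order(-out$occupancy, out$kind, out$partner_a, out$partner_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occupancy_table", class(out))
  out
}

#' Write an occupancy table as TSV
#' @param tab an [occupancy_table()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(tab, path) {
  df <- tab[, c("kind", "partner_a", "partner_b", "occupancy", "n_frames")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
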