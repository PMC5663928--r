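#' Specify a protein-ligand-water complex with planted interactions
#'
#' Builds a small synthetic complex in which every hydrogen bond,
#' single-water bridge and hydrophobic contact is placed at an exactly known
#' geometry, so the detection stages can be scored with perfect ground
#' truth. Positive plants must satisfy the detection criteria with a margin
#' of at least 0.1 A / 5 degrees; plants flagged `positive = FALSE` must
#' violate at least one criterion by the same margin. Waters are ideal
#' 3-site (O, H, H; r(OH) = 0.9572 A, HOH angle 104.52 deg). Plants are laid
#' out >= 30 A apart so no unplanned interaction can satisfy any criterion.
#'
#' @param hbonds data.frame with columns `dist` (D..A heavy-atom distance,
#'   A), `angle` (D-H-A angle, deg) and optionally `positive` (default TRUE),
#'   `occupancy` (fraction of frames present, default 1) and `donor_mol`
#'   ("protein" or "ligand", default "protein").
#' @param hydrophobics data.frame with columns `dist` (A) and optionally
#'   `positive`, `occupancy`.
#' @param bridges data.frame with columns `dist_lig`, `dist_prot` (water-O
#'   to acceptor distances, A) and optionally `positive`; or an integer
#'   count of default positive bridges (2.8 A both sides).
#' @param n_frames frames to emit (plants with occupancy < 1 are displaced
#'   out of range in the trailing frames).
#' @param criteria an [interaction_criteria()] the margins are checked
#'   against.
#' @param seed integer seed (layout is deterministic; kept for provenance).
#' @return list of class `planted_complex_spec`.
#' @export
planted_complex_spec <- function(hbonds = NULL, hydrophobics = NULL,
                                 bridges = NULL, n_frames = 1L,
                                 criteria = interaction_criteria(),
                                 seed = 1L) {
  fill <- function(df, defaults) {
    for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
    df
  }
  if (!is.null(hbonds))
    hbonds <- fill(hbonds, list(positive = TRUE, occupancy = 1,
                                donor_mol = "protein"))
  if (!is.null(hydrophobics))
    hydrophobics <- fill(hydrophobics, list(positive = TRUE, occupancy = 1))
  if (is.numeric(bridges) && length(bridges) == 1L)
    bridges <- if (bridges > 0)
      data.frame(dist_lig = rep(2.8, bridges), dist_prot = 2.8) else NULL
  if (!is.null(bridges)) bridges <- fill(bridges, list(positive = TRUE))

  marg_d <- 0.1; marg_a <- 5
  if (!is.null(hbonds)) for (i in seq_len(nrow(hbonds))) {
    d <- hbonds$dist[i]; a <- hbonds$angle[i]
    ok_pos <- d <= criteria$hbond_max_heavy_dist - marg_d &&
      a >= criteria$hbond_min_angle + marg_a
    ok_neg <- d >= criteria$hbond_max_heavy_dist + marg_d ||
      a <= criteria$hbond_min_angle - marg_a
    if (hbonds$positive[i] && !ok_pos)
      stop("planted H-bond ", i, " does not satisfy the criteria by the ",
           "required margin (0.1 A / 5 deg)")
    if (!hbonds$positive[i] && !ok_neg)
      stop("planted negative H-bond ", i, " does not violate any criterion ",
           "by the required margin")
  }
  if (!is.null(hydrophobics)) for (i in seq_len(nrow(hydrophobics))) {
    d <- hydrophobics$dist[i]
    ok_pos <- d <= criteria$hydrophobic_max_dist - marg_d
    ok_neg <- d >= criteria$hydrophobic_max_dist + marg_d
    if (hydrophobics$positive[i] && !ok_pos)
      stop("planted hydrophobic contact ", i, " lacks the 0.1 A margin")
    if (!hydrophobics$positive[i] && !ok_neg)
      stop("planted negative hydrophobic contact ", i, " lacks the 0.1 A margin")
  }
  if (!is.null(bridges)) for (i in seq_len(nrow(bridges))) {
    dl <- bridges$dist_lig[i]; dp <- bridges$dist_prot[i]
    if (bridges$positive[i] &&
        (dl > criteria$hbond_max_heavy_dist - marg_d ||
         dp > criteria$hbond_max_heavy_dist - marg_d))
      stop("planted water bridge ", i, " lacks the 0.1 A margin")
    if (!bridges$positive[i] &&
        dl <= criteria$hbond_max_heavy_dist - marg_d &&
        dp <= criteria$hbond_max_heavy_dist - marg_d)
      stop("planted negative water bridge ", i, " lacks the 0.1 A margin")
  }
  structure(list(hbonds = hbonds, hydrophobics = hydrophobics,
                 bridges = bridges, n_frames = as.integer(n_frames),
                 criteria = criteria, seed = as.integer(seed)),
            class = "planted_complex_spec")
}

# place acceptor at D..A distance d with D-H-A angle theta, given D at `orig`
# and H along +x at bond length b. Returns the acceptor position.
.place_acceptor <- function(orig, b, d, theta_deg) {
  th <- theta_deg * pi / 180
  disc <- d^2 - b^2 * sin(th)^2
  if (disc < 0)
    stop("geometrically unrealisable acceptor placement (d = ", d,
         " A, angle = ", theta_deg, " deg)")
  x_ha <- b * cos(th) + sqrt(disc)       # H..A distance, positive root
  orig + c(b - x_ha * cos(th), x_ha * sin(th), 0)
}

#' Generate the planted complex fixture
#'
#' @param spec a [planted_complex_spec()].
#' @return list with `trajectory`, `topology` and `truth`, where `truth` is a
#'   data.frame of the planted interactions (kind, atom indices, positive
#'   flag, occupancy).
#' @export
gen_planted_complex <- function(spec) {
  stopifnot(inherits(spec, "planted_complex_spec"))
  atoms <- list(); bonds <- list(); xyz <- list()
  truth <- list()
  site <- 0L; resno_p <- 0L; resno_w <- 500L
  add_atom <- function(name, element, mass, resno, resname, segid, molclass, pos) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, element = element, mass = mass, resno = resno,
      resname = resname, segid = segid, molclass = molclass,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- pos
    length(atoms)
  }
  origin <- function() c(0, 30 * site, 0)

  hb <- spec$hbonds
  if (!is.null(hb)) for (i in seq_len(nrow(hb))) {
    site <- site + 1L; resno_p <- resno_p + 1L
    o <- origin(); b <- 1.0
    on_prot <- hb$donor_mol[i] == "protein"
    iD <- add_atom("N", "N", 14.007,
                   if (on_prot) resno_p else 900L,
                   if (on_prot) "PRT" else "LIG",
                   if (on_prot) "PROT" else "LIG",
                   if (on_prot) "protein" else "ligand", o)
    iH <- add_atom("HN", "H", 1.008,
                   if (on_prot) resno_p else 900L,
                   if (on_prot) "PRT" else "LIG",
                   if (on_prot) "PROT" else "LIG",
                   if (on_prot) "protein" else "ligand", o + c(b, 0, 0))
    iA <- add_atom("O", "O", 15.999,
                   if (on_prot) 900L else resno_p,
                   if (on_prot) "LIG" else "PRT",
                   if (on_prot) "LIG" else "PROT",
                   if (on_prot) "ligand" else "protein",
                   .place_acceptor(o, b, hb$dist[i], hb$angle[i]))
    bonds[[length(bonds) + 1L]] <- c(iD, iH)
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "hbond", i = iD, j = iA, water = NA_integer_,
      positive = hb$positive[i], occupancy = hb$occupancy[i])
  }

  hp <- spec$hydrophobics
  if (!is.null(hp)) for (i in seq_len(nrow(hp))) {
    site <- site + 1L; resno_p <- resno_p + 1L
    o <- origin()
    ia <- add_atom("CP", "C", 12.011, resno_p, "PRT", "PROT", "protein", o)
    ib <- add_atom("CL", "C", 12.011, 900L, "LIG", "LIG", "ligand",
                   o + c(hp$dist[i], 0, 0))
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "hydrophobic", i = ia, j = ib, water = NA_integer_,
      positive = hp$positive[i], occupancy = hp$occupancy[i])
  }

  br <- spec$bridges
  if (!is.null(br)) for (i in seq_len(nrow(br))) {
    site <- site + 1L; resno_p <- resno_p + 1L; resno_w <- resno_w + 1L
    o <- origin()
    ang <- 104.52 * pi / 180
    u1 <- c(1, 0, 0); u2 <- c(cos(ang), sin(ang), 0)
    iO <- add_atom("OH2", "O", 15.999, resno_w, "HOH", "WAT", "water", o)
    iH1 <- add_atom("H1", "H", 1.008, resno_w, "HOH", "WAT", "water",
                    o + 0.9572 * u1)
    iH2 <- add_atom("H2", "H", 1.008, resno_w, "HOH", "WAT", "water",
                    o + 0.9572 * u2)
    iL <- add_atom("OL", "O", 15.999, 900L, "LIG", "LIG", "ligand",
                   o + br$dist_lig[i] * u1)
    iP <- add_atom("OP", "O", 15.999, resno_p, "PRT", "PROT", "protein",
                   o + br$dist_prot[i] * u2)
    bonds[[length(bonds) + 1L]] <- c(iO, iH1)
    bonds[[length(bonds) + 1L]] <- c(iO, iH2)
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "water_bridge", i = iL, j = iP, water = iO,
      positive = br$positive[i], occupancy = 1)
  }

  if (!length(atoms)) stop("planted complex spec contains no plants")
  at <- do.call(rbind, atoms)
  bd <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), ncol = 2)
  top <- annotate_topology(topology(at, bd, validate = FALSE))
  validate_topology(top)
  truth <- do.call(rbind, truth)

  base <- do.call(rbind, xyz)
  coords <- array(0, dim = c(spec$n_frames, nrow(base), 3L))
  for (f in seq_len(spec$n_frames)) {
    fr <- base
    # plants with partial occupancy are displaced out of range after their
    # first round(occ * n_frames) frames (ligand-side atom moved +15 A in z)
    for (k in seq_len(nrow(truth))) {
      occ <- truth$occupancy[k]
      if (occ < 1 && f > round(occ * spec$n_frames)) {
        mob <- if (top$atoms$molclass[truth$j[k]] == "ligand")
          truth$j[k] else truth$i[k]
        fr[mob, 3] <- fr[mob, 3] + 15
      }
    }
    coords[f, , ] <- fr
  }
  list(trajectory = trajectory(coords), topology = top, truth = truth)
}
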