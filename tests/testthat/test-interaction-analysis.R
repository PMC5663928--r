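test_that("hydrogen-bond criterion applies both distance and angle cutoffs", {
  cases <- list(list(d = 2.8, a = 165, hit = TRUE),
                list(d = 3.2, a = 170, hit = FALSE),   # distance too long
                list(d = 2.8, a = 110, hit = FALSE))   # angle too acute
  for (cs in cases) {
    fx <- hbond_fixture(cs$d, cs$a)
    hb <- detect_hbonds(fx$frame, fx$top)
    expect_identical(nrow(hb) == 1L, cs$hit,
                     label = sprintf("d=%g angle=%g", cs$d, cs$a))
  }
  # the distance boundary is inclusive: exact collinear D-H...A at 3.0 A
  fx <- hbond_fixture(2.8, 165)
  fx$frame <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  expect_identical(nrow(detect_hbonds(fx$frame, fx$top)), 1L)
  # donor without hydrogen is reported by atom
  fx2 <- hbond_fixture(2.8, 165)
  fx2$top$bonds <- matrix(integer(0), ncol = 2)
  expect_error(detect_hbonds(fx2$frame, fx2$top), "no bonded hydrogen")
})

test_that("hydrophobic contacts respect the distance cutoff and molecule filter", {
  px <- gen_planted_complex(planted_complex_spec(
    hydrophobics = data.frame(dist = c(3.5, 3.9, 4.1),
                              positive = c(TRUE, TRUE, FALSE))))
  fr <- get_frame(px$trajectory, 1)
  hits <- detect_hydrophobic(fr, px$topology)
  expect_identical(nrow(hits), 2L)
  truth <- px$truth[px$truth$positive, ]
  expect_setequal(paste(hits$atom_a, hits$atom_b),
                  paste(truth$i, truth$j))
  # brute-force all-pairs oracle over flagged intermolecular pairs
  flag <- which(px$topology$atoms$hydrophobic)
  brute <- 0L
  for (i in flag) for (j in flag) if (i < j &&
      px$topology$atoms$molclass[i] != px$topology$atoms$molclass[j] &&
      sqrt(sum((fr[i, ] - fr[j, ])^2)) <= 4) brute <- brute + 1L
  expect_identical(nrow(hits), brute)
})

test_that("water bridges require one water bonded to both sides in the same frame", {
  px <- gen_planted_complex(planted_complex_spec(bridges = 1))
  fr <- get_frame(px$trajectory, 1)
  wb <- detect_water_bridges(fr, px$topology)
  expect_identical(nrow(wb), 1L)
  expect_identical(wb$ligand_atom, px$truth$i[1])
  expect_identical(wb$protein_atom, px$truth$j[1])

  # water bonded to the ligand only: no bridge
  px2 <- gen_planted_complex(planted_complex_spec(
    bridges = data.frame(dist_lig = 2.8, dist_prot = 8, positive = FALSE)))
  expect_identical(
    nrow(detect_water_bridges(get_frame(px2$trajectory, 1), px2$topology)), 0L)

  # two-water chain ligand-W1-W2-protein is not a (single-water) bridge,
  # although every link satisfies the pairwise H-bond criterion
  oh <- 0.9572
  frame <- rbind(
    c(-2.8, 0, 0),                 # ligand acceptor O
    c(0, 0, 0), c(-oh, 0, 0), c(oh * cos(1.824), oh * sin(1.824), 0),  # W1
    c(2.8, 0, 0), c(2.8 + oh, 0, 0), c(2.8 - oh * cos(1.824), oh * sin(1.824), 0),  # W2
    c(5.6, 0, 0))                                                      # protein acceptor
  atoms <- data.frame(
    name = c("OL", "OH2", "H1", "H2", "OH2", "H1", "H2", "OP"),
    element = c("O", "O", "H", "H", "O", "H", "H", "O"),
    mass = c(15.999, 15.999, 1.008, 1.008, 15.999, 1.008, 1.008, 15.999),
    resno = c(900L, 501L, 501L, 501L, 502L, 502L, 502L, 1L),
    resname = c("LIG", "HOH", "HOH", "HOH", "HOH", "HOH", "HOH", "PRT"),
    segid = c("LIG", "WAT", "WAT", "WAT", "WAT", "WAT", "WAT", "PROT"),
    molclass = c("ligand", "water", "water", "water", "water", "water",
                 "water", "protein"), stringsAsFactors = FALSE)
  top <- annotate_topology(topology(
    atoms, rbind(c(2L, 3L), c(2L, 4L), c(5L, 6L), c(5L, 7L))))
  # exhaustive check of the chain's pairwise bonds: W1-lig and W2-prot exist
  hb <- detect_hbonds(frame, top)
  cls <- top$atoms$molclass
  expect_true(any(cls[hb$donor] == "water" & cls[hb$acceptor] == "ligand"))
  expect_true(any(cls[hb$donor] == "water" & cls[hb$acceptor] == "protein"))
  expect_identical(nrow(detect_water_bridges(frame, top)), 0L)
})

test_that("detection is invariant under rigid motion and monotone in the cutoffs", {
  px <- gen_planted_complex(planted_complex_spec(
    hbonds = data.frame(dist = c(2.8, 2.4), angle = c(160, 130)),
    hydrophobics = data.frame(dist = c(3.2, 3.9)), bridges = 1))
  fr <- get_frame(px$trajectory, 1)
  R <- random_rotation_matrix(7)
  moved <- fr %*% t(R) + matrix(c(11, -4, 6), nrow(fr), 3, byrow = TRUE)
  for (fun in list(detect_hbonds, detect_hydrophobic, detect_water_bridges)) {
    a <- fun(fr, px$topology); b <- fun(moved, px$topology)
    expect_equal(a[, 1:2], b[, 1:2], ignore_attr = TRUE)
  }
  # shrinking any cutoff never enlarges the detection set
  base_c <- interaction_criteria()
  hb_base <- detect_hbonds(fr, px$topology, base_c)
  hp_base <- detect_hydrophobic(fr, px$topology, base_c)
  for (tight in list(interaction_criteria(hbond_max_heavy_dist = 2.5),
                     interaction_criteria(hbond_min_angle = 150))) {
    hb <- detect_hbonds(fr, px$topology, tight)
    expect_true(all(paste(hb$donor, hb$acceptor) %in%
                      paste(hb_base$donor, hb_base$acceptor)))
  }
  hp <- detect_hydrophobic(fr, px$topology,
                           interaction_criteria(hydrophobic_max_dist = 3.5))
  expect_true(all(paste(hp$atom_a, hp$atom_b) %in%
                    paste(hp_base$atom_a, hp_base$atom_b)))
})

test_that("occupancy tables count frames, merge residues and sort deterministically", {
  px <- gen_planted_complex(planted_complex_spec(
    hbonds = data.frame(dist = c(2.8, 2.7), angle = c(160, 150),
                        occupancy = c(1, 0.5)),
    n_frames = 100L))
  tab <- occupancy_table(px$trajectory, px$topology)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$occupancy, c(1.0, 0.5))          # sorted descending
  expect_identical(tab$conserved, c(TRUE, TRUE))
  expect_equal(vapply(tab$bitmap, mean, 0), tab$occupancy,
               ignore_attr = TRUE)

  # residue grouping ORs the atom-level bitmaps
  atom_tab <- occupancy_table(px$trajectory, px$topology, grouping = "atom")
  res_tab <- occupancy_table(px$trajectory, px$topology, grouping = "residue")
  # brute-force: recompute each residue record from OR of its atom records
  a <- px$topology$atoms
  res_of <- function(lab) sub(":[^:]+$", "", lab)
  for (r in seq_len(nrow(res_tab))) {
    members <- which(res_of(atom_tab$partner_a) == res_tab$partner_a[r] &
                       res_of(atom_tab$partner_b) == res_tab$partner_b[r] &
                       atom_tab$kind == res_tab$kind[r])
    ored <- Reduce(`|`, atom_tab$bitmap[members])
    expect_equal(res_tab$occupancy[r], mean(ored))
  }
  expect_error(occupancy_table(trajectory(array(0, c(0, 2, 3))),
                               px$topology), "empty|positive")
})
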