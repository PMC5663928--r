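# shared fixture builders; everything is generated in code at test time

kB <- alchemtraj::PHYS_CONST$kB

# a frame of n atoms on a line, 5 A apart (the generator's default mean)
line_frame <- function(n) cbind(5 * (seq_len(n) - 1), 0, 0)

# a non-collinear zig-zag chain (superposition is fully determined on it)
chain_frame <- function(n) {
  i <- seq_len(n) - 1
  cbind(1.5 * i, 1.2 * (i %% 2), 0.8 * (i %% 3))
}

# minimal topology: n carbon-like ligand atoms
carbon_topology <- function(n, molclass = "ligand") {
  topology(data.frame(
    name = paste0("C", seq_len(n)), element = "C", mass = 12.011,
    resno = 1L, resname = "LIG", segid = "LIG", molclass = molclass,
    stringsAsFactors = FALSE))
}

# donor(N)-H ... acceptor(O) triple at exact geometry, as frame + topology
hbond_fixture <- function(dist, angle) {
  b <- 1.0
  th <- angle * pi / 180
  x_ha <- b * cos(th) + sqrt(dist^2 - b^2 * sin(th)^2)
  frame <- rbind(c(0, 0, 0), c(b, 0, 0),
                 c(b - x_ha * cos(th), x_ha * sin(th), 0))
  atoms <- data.frame(
    name = c("N", "HN", "O"), element = c("N", "H", "O"),
    mass = c(14.007, 1.008, 15.999), resno = c(1L, 1L, 2L),
    resname = c("PRT", "PRT", "LIG"), segid = c("PROT", "PROT", "LIG"),
    molclass = c("protein", "protein", "ligand"), stringsAsFactors = FALSE)
  top <- annotate_topology(topology(atoms, rbind(c(1L, 2L))))
  list(frame = frame, top = top)
}

# two well-separated conformer groups of a 5-atom ligand
two_conformer_set <- function(n1, n2, sd_within = 0.3, separation = 5,
                              seed = 42L) {
  per_coord <- sd_within^2 / 3          # total per-atom spread = sd_within
  a <- gen_gaussian_trajectory(gaussian_trajectory_spec(
    5, n1, per_coord, seed = seed))$trajectory$coords
  m2 <- line_frame(5); m2[, 2] <- separation
  b <- gen_gaussian_trajectory(gaussian_trajectory_spec(
    5, n2, per_coord, mean_structure = m2, seed = seed + 1L))$trajectory$coords
  arr <- array(0, dim = c(n1 + n2, 5, 3))
  arr[seq_len(n1), , ] <- a
  arr[n1 + seq_len(n2), , ] <- b
  arr
}

random_rotation_matrix <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# minimal stand-in entropy results for arithmetic-only delta_entropy checks
entropy_result <- function(S) structure(list(entropy = S), class = "qh_entropy")
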