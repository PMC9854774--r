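# Independent oracles and fixture builders shared across tests.

# Rotation matrix from a unit quaternion (w, x, y, z).
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force minimum RMSD over rotations: random quaternion search
# followed by Nelder-Mead refinement of the rotation vector. Centres both
# point sets; never uses the SVD solution.
brute_force_min_rmsd <- function(mobile, reference, n_quat = 4000) {
  Mc <- sweep(mobile, 2, colMeans(mobile))
  Rc <- sweep(reference, 2, colMeans(reference))
  rmsd_of_rot <- function(rot) sqrt(mean(rowSums((Mc %*% t(rot) - Rc)^2)))
  qs <- matrix(rnorm(n_quat * 4), ncol = 4)
  vals <- apply(qs, 1, function(q) rmsd_of_rot(quat_to_rot(q)))
  best <- qs[which.min(vals), ]
  best <- best / sqrt(sum(best^2))
  # refine over the full quaternion, renormalized inside the objective
  obj <- function(q) rmsd_of_rot(quat_to_rot(q))
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# Energy components for one ligand row of the built-in reference table.
components_for <- function(ligand) {
  tab <- gstp1_energy_means()
  row <- tab[tab$ligand == ligand, ]
  energy_components(row$vdw_bound, row$vdw_free, row$ele_bound,
                    row$ele_free, row$ele_bound_uncharged)
}

# Noiseless velocity data on a small grid.
noiseless_kinetics <- function(params, S = c(20, 50, 100, 200, 500),
                               I = c(0, 2.5, 5, 10, 25)) {
  g <- expand.grid(S = S, I = I)
  g$v <- inhibition_velocity(params, g$S, g$I)
  g
}

# Two-frame trajectory fixture: a copy of the toy complex with the
# ligand rigidly displaced by `shift` in the second frame.
shifted_ligand_traj <- function(shift = c(1, 0, 0)) {
  tpl <- toy_complex()
  base <- frame_coords(tpl, 1)
  f2 <- base
  lig <- which(tpl$atoms$role == "ligand")
  f2[lig, ] <- sweep(f2[lig, , drop = FALSE], 2, shift, "+")
  arr <- array(NA_real_, c(2, nrow(base), 3))
  arr[1, , ] <- base
  arr[2, , ] <- f2
  trajectory(arr, tpl$atoms)
}

# Apply one rigid transform (rotation + translation) to every frame.
rigid_transform_traj <- function(traj, rot, trans) {
  arr <- traj$coords
  for (f in seq_len(dim(arr)[1]))
    arr[f, , ] <- sweep(arr[f, , ] %*% t(rot), 2, trans, "+")
  trajectory(arr, traj$atoms)
}
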