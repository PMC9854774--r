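test_that("superposition is exact for identical and rigidly moved structures", {
  set.seed(21)
  A <- matrix(rnorm(30, sd = 3), 10, 3)
  fit0 <- kabsch_superpose(A, A)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)
  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  B <- A %*% t(Rz) + matrix(rep(c(3, -1, 2), each = 10), 10, 3)
  fitB <- kabsch_superpose(B, A)
  expect_lt(fitB$rmsd, 1e-10)
  expect_equal(det(fitB$rotation), 1, tolerance = 1e-10)
})

test_that("superposition rejects degenerate atom sets", {
  A <- matrix(rnorm(30), 10, 3)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))  # perfectly collinear
  expect_error(kabsch_superpose(line, line + 0.1), "collinear")
})

test_that("Kabsch equals the brute-force rotational minimum", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(5:15, 1)
    A <- matrix(rnorm(3 * n, sd = 2), n, 3)
    B <- matrix(rnorm(3 * n, sd = 2), n, 3)
    kab <- kabsch_superpose(B, A)$rmsd
    oracle <- brute_force_min_rmsd(B, A)
    expect_lt(abs(kab - oracle), 1e-3)
    expect_lte(kab, oracle + 1e-9)  # closed form can only be optimal
  }
})

test_that("Kabsch agrees with an established reference implementation", {
  set.seed(13)
  A <- matrix(rnorm(45, sd = 2), 15, 3)
  B <- A + matrix(rnorm(45, sd = 0.5), 15, 3)
  ours <- kabsch_superpose(B, A)$rmsd
  ref_xyz <- bio3d::fit.xyz(fixed = as.numeric(t(A)),
                            mobile = as.numeric(t(B)),
                            fixed.inds = 1:45, mobile.inds = 1:45)
  ref <- sqrt(mean(rowSums((matrix(ref_xyz, ncol = 3, byrow = TRUE) -
                              A)^2)))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("rmsd series is zero for static frames and exact for rigid shifts", {
  tpl <- toy_complex()
  base <- frame_coords(tpl, 1)
  arr <- array(NA_real_, c(3, nrow(base), 3))
  for (f in 1:3) arr[f, , ] <- base
  static <- trajectory(arr, tpl$atoms)
  expect_equal(rmsd_series(static), rep(0, 3), tolerance = 1e-12)
  # ligand displaced 1 A with the protein fixed: after a protein fit the
  # ligand RMSD is exactly the displacement
  traj <- shifted_ligand_traj(c(1, 0, 0))
  prot <- select_atoms(traj, role = "protein", backbone = TRUE)
  lig <- select_atoms(traj, role = "ligand")
  rs <- rmsd_series(traj, fit_selection = prot, measure_selection = lig)
  expect_equal(rs, c(0, 1), tolerance = 1e-10)
  expect_error(rmsd_series(traj, measure_selection = integer()), "empty")
})

test_that("rmsd and rmsf are invariant under a global rigid transform", {
  tr <- gen_toy_trajectory(trajectory_generator_spec(sigma = 0.15,
                                                     frames = 20,
                                                     seed = 8))
  prot <- select_atoms(tr, role = "protein", backbone = TRUE)
  lig <- select_atoms(tr, role = "ligand")
  th <- 0.83
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                3, 3, byrow = TRUE)
  tr2 <- rigid_transform_traj(tr, rot, c(5, -3, 11))
  expect_equal(rmsd_series(tr, fit_selection = prot,
                           measure_selection = lig),
               rmsd_series(tr2, fit_selection = prot,
                           measure_selection = lig), tolerance = 1e-8)
  expect_equal(rmsf(tr, selection = lig, fit_selection = prot),
               rmsf(tr2, selection = lig, fit_selection = prot),
               tolerance = 1e-8)
})

test_that("isotropic jitter statistics match their closed forms", {
  sigma <- 0.2
  tr <- gen_toy_trajectory(trajectory_generator_spec(sigma = sigma,
                                                     p_hbond = 1,
                                                     frames = 2000,
                                                     seed = 31))
  stable <- setdiff(seq_len(nrow(tr$atoms)),
                    attr(tr, "manifest")$probe_atom)
  # per-atom RMSF converges to sigma * sqrt(3)
  fl <- rmsf(tr, selection = stable)
  expect_lt(max(abs(fl / (sigma * sqrt(3)) - 1)), 0.05)
  # mean RMSD from the unjittered reference configuration
  rs <- rmsd_series(tr, measure_selection = stable)
  expect_lt(abs(mean(rs[-1]) / (sigma * sqrt(3)) - 1), 0.05)
  expect_error(rmsf(trajectory(frame_coords(tr, 1), tr$atoms)),
               ">= 2 frames")
})

test_that("two mirrored frames give RMSF equal to the half-displacement", {
  tpl <- toy_complex()
  base <- frame_coords(tpl, 1)
  arr <- array(NA_real_, c(2, nrow(base), 3))
  arr[1, , ] <- base + 0.4
  arr[2, , ] <- base - 0.4
  tr <- trajectory(arr, tpl$atoms)
  # each coordinate deviates +/- 0.4 about its mean: RMSF = 0.4 sqrt(3)
  expect_equal(unname(rmsf(tr)), rep(0.4 * sqrt(3), nrow(base)),
               tolerance = 1e-10)
})

test_that("selections are deterministic and validate emptiness", {
  tr <- toy_complex()
  bb <- select_atoms(tr, role = "protein", backbone = TRUE)
  expect_identical(bb, select_atoms(tr, role = "protein", backbone = TRUE))
  expect_equal(length(bb), 28)  # 7 residues x N, CA, C, O
  expect_error(select_atoms(tr, role = "ligand", elements = "ZZ"),
               "empty")
  lig <- select_atoms(tr, role = "ligand")
  near <- select_atoms(tr, role = "protein",
                       within_of = list(selection = lig, cutoff = 5))
  expect_true(all(tr$atoms$resno[near] %in% c(5, 6, 7)))
})
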