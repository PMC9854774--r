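#' Specification for the AR(1) interaction-energy generator
#'
#' Describes stationary, autocorrelated per-frame energy series with
#' prescribed means, emulating the statistical structure of
#' molecular-dynamics interaction energies (slowly decorrelating
#' fluctuations about a stable mean) over independent production runs.
#'
#' @param means named numeric vector with entries `vdw_bound`,
#'   `vdw_free`, `ele_bound`, `ele_free` and optionally
#'   `ele_bound_uncharged` (kcal/mol) - the exact expectation of each
#'   generated series.
#' @param sigma marginal per-frame standard deviation (kcal/mol), >= 0.
#' @param rho AR(1) lag-one autocorrelation in `[0, 1)`.
#' @param frames frames per replicate, >= 10.
#' @param n_replicates number of independent replicates (default 4).
#' @param seed integer seed making the generator a pure function.
#' @return object of class `"energy_generator_spec"`.
#' @export
energy_generator_spec <- function(means, sigma = 1.5, rho = 0.8,
                                  frames = 2000L, n_replicates = 4L,
                                  seed = 1L) {
  need <- c("vdw_bound", "vdw_free", "ele_bound", "ele_free")
  if (!all(need %in% names(means)))
    stop("means must name vdw_bound, vdw_free, ele_bound, ele_free",
         call. = FALSE)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0",
                                           call. = FALSE)
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)", call. = FALSE)
  if (frames < 10L) stop("need >= 10 frames", call. = FALSE)
  structure(list(means = means, sigma = sigma, rho = rho,
                 frames = as.integer(frames),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "energy_generator_spec")
}

ar1_series <- function(n, mean, sigma, rho) {
  if (sigma == 0) return(rep(mean, n))
  x <- numeric(n)
  x[1L] <- rnorm(1L, mean, sigma)
  innov_sd <- sigma * sqrt(1 - rho^2)
  eps <- rnorm(n - 1L, 0, innov_sd)
  for (t in 2:n) x[t] <- mean + rho * (x[t - 1L] - mean) + eps[t - 1L]
  x
}

#' Effective sample size of an AR(1) series
#'
#' n (1 - rho) / (1 + rho); the factor by which autocorrelation inflates
#' the variance of the sample mean.
#'
#' @param n number of frames.
#' @param rho lag-one autocorrelation.
#' @export
effective_sample_size <- function(n, rho) n * (1 - rho) / (1 + rho)

#' Generate autocorrelated interaction-energy series
#'
#' Emits a long-format energy table in the dialect consumed by
#' [binding_energy_from_table()] and [read_energy_table()]: columns
#' `frame`, `replicate`, `state` (`bound`/`free`/`bound_q0`), `vdw`,
#' `ele`. Every component/replicate series is stationary AR(1) with the
#' spec's exact target mean in expectation. The ground-truth parameters
#' are attached as `attr(x, "truth")`.
#'
#' @param spec an [energy_generator_spec()].
#' @return data frame; bit-identical for identical specs.
#' @export
gen_energy_series <- function(spec) {
  stopifnot(inherits(spec, "energy_generator_spec"))
  set.seed(spec$seed)
  m <- spec$means
  has_q0 <- "ele_bound_uncharged" %in% names(m)
  out <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
    mk <- function(mu) ar1_series(spec$frames, mu, spec$sigma, spec$rho)
    frames <- seq_len(spec$frames)
    rows <- rbind(
      data.frame(frame = frames, replicate = r, state = "bound",
                 vdw = mk(m[["vdw_bound"]]), ele = mk(m[["ele_bound"]])),
      data.frame(frame = frames, replicate = r, state = "free",
                 vdw = mk(m[["vdw_free"]]), ele = mk(m[["ele_free"]])))
    if (has_q0)
      rows <- rbind(rows, data.frame(
        frame = frames, replicate = r, state = "bound_q0",
        vdw = NA_real_, ele = mk(m[["ele_bound_uncharged"]])))
    rows
  }))
  rownames(out) <- NULL
  attr(out, "truth") <- spec
  out
}

#' Specification for the kinetics data generator
#'
#' Velocity observations on a substrate-by-inhibitor grid drawn from the
#' general-modifier rate law with multiplicative Gaussian noise,
#' emulating triplicate initial-velocity assays. Default grids follow the
#' standard GST assay design: CDNB varied over 14-1000 uM (or GSH over
#' 37.5-3750 uM via `substrate_grid("GSH")`) with inhibitor levels in
#' 0-50 uM.
#'
#' @param params a [kinetic_parameters()] object - the ground truth.
#' @param S_grid substrate concentrations, uM.
#' @param I_grid inhibitor concentrations, uM; must include 0.
#' @param cv coefficient of variation of multiplicative Gaussian noise
#'   (default 0.02).
#' @param replicates replicate measurements per grid point (default 3).
#' @param seed integer seed.
#' @return object of class `"kinetic_generator_spec"`.
#' @export
kinetic_generator_spec <- function(params, S_grid = substrate_grid("CDNB"),
                                   I_grid = c(0, 2.5, 5, 10, 25, 50),
                                   cv = 0.02, replicates = 3L, seed = 1L) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (length(S_grid) == 0L || length(I_grid) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  if (!any(I_grid == 0))
    stop("inhibitor grid must include 0 (uninhibited reference)",
         call. = FALSE)
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(params = params, S_grid = S_grid, I_grid = I_grid,
                 cv = cv, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "kinetic_generator_spec")
}

#' Standard substrate concentration grids
#'
#' Log-spaced grids spanning the typical assay ranges: CDNB 14-1000 uM,
#' GSH 37.5-3750 uM.
#'
#' @param substrate `"CDNB"` or `"GSH"`.
#' @param n number of levels.
#' @export
substrate_grid <- function(substrate = c("CDNB", "GSH"), n = 7L) {
  substrate <- match.arg(substrate)
  rng <- switch(substrate, CDNB = c(14, 1000), GSH = c(37.5, 3750))
  exp(seq(log(rng[1L]), log(rng[2L]), length.out = n))
}

#' Generate velocity observations with known ground truth
#'
#' @param spec a [kinetic_generator_spec()].
#' @return data frame with columns `S`, `I`, `v`, `replicate`; ground
#'   truth attached as `attr(x, "truth")`.
#' @export
gen_kinetic_data <- function(spec) {
  stopifnot(inherits(spec, "kinetic_generator_spec"))
  set.seed(spec$seed)
  grid <- expand.grid(S = spec$S_grid, I = spec$I_grid,
                      replicate = seq_len(spec$replicates))
  mu <- inhibition_velocity(spec$params, grid$S, grid$I)
  v <- mu * (1 + rnorm(nrow(grid), 0, spec$cv))
  # multiplicative noise cannot produce non-positive velocities at sane cv;
  # guard against pathological draws anyway
  v <- pmax(v, mu * 1e-6)
  out <- data.frame(S = grid$S, I = grid$I, v = v,
                    replicate = grid$replicate)
  attr(out, "truth") <- spec
  out
}

#' Hard-coded toy protein-ligand complex
#'
#' A ~60-atom synthetic complex built for geometry tests, not a real
#' structure: a seven-residue peptide-like fragment (zig-zag backbone,
#' one phenylalanine ring stacked 3.8 A above the ligand ring, a lysine
#' ammonium nitrogen 4.5 A from the ring centroid, and a serine
#' hydroxyl oxygen acting as hydrogen-bond probe acceptor) plus a
#' phenol-like ligand (benzene ring, hydroxyl O-H). In the template the
#' probe acceptor sits 2.9 A from the ligand hydroxyl oxygen at a linear
#' donor angle, satisfying the default hydrogen-bond criteria.
#'
#' @return a one-frame [trajectory()]; `attr(x, "probe_atom")` is the
#'   index of the mobile acceptor, `attr(x, "hbond_on")` /
#'   `attr(x, "hbond_off")` its positions in the bonded and non-bonded
#'   states.
#' @export
toy_complex <- function() {
  rows <- list()
  add <- function(name, element, resname, resno, chain, role, x, y, z)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resname = resname, resno = resno,
      chain = chain, role = role, x = x, y = y, z = z,
      stringsAsFactors = FALSE)

  # backbone: 7 residues, zig-zag so fits are never collinear
  resnames <- c("GLY", "GLY", "GLY", "GLY", "PHE", "LYS", "SER")
  for (i in seq_along(resnames)) {
    x0 <- (i - 1L) * 3.8 - 12
    add("N", "N", resnames[i], i, "A", "protein", x0, 8.5, 0.0)
    add("CA", "C", resnames[i], i, "A", "protein", x0 + 1.2, 9.2, 0.6)
    add("C", "C", resnames[i], i, "A", "protein", x0 + 2.4, 8.5, 0.0)
    add("O", "O", resnames[i], i, "A", "protein", x0 + 2.4, 8.6, 1.23)
  }
  # PHE aromatic ring parallel to the ligand ring, 3.8 A above it
  for (k in 0:5) {
    th <- k * pi / 3
    add(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")[k + 1L], "C", "PHE",
        5L, "A", "protein", 1.39 * cos(th), 1.39 * sin(th), 3.8)
  }
  # LYS sidechain ammonium nitrogen near the ligand ring centroid
  add("NZ", "N", "LYS", 6L, "A", "protein", 0.0, 4.5, 0.0)
  # SER hydroxyl oxygen: the hydrogen-bond probe acceptor
  add("OG", "O", "SER", 7L, "A", "protein", 5.65, 0.0, 0.0)

  # ligand: benzene ring in the z = 0 plane + hydroxyl on C1
  for (k in 0:5) {
    th <- k * pi / 3
    add(paste0("C", k + 1L), "C", "LIG", 1L, "L", "ligand",
        1.39 * cos(th), 1.39 * sin(th), 0.0)
  }
  add("O1", "O", "LIG", 1L, "L", "ligand", 2.75, 0.0, 0.0)
  add("HO1", "H", "LIG", 1L, "L", "ligand", 3.71, 0.0, 0.0)

  tab <- do.call(rbind, rows)
  coords <- as.matrix(tab[, c("x", "y", "z")])
  traj <- trajectory(array(coords, c(1L, nrow(tab), 3L)),
                     tab[, c("name", "element", "resname", "resno",
                             "chain", "role")])
  attr(traj, "probe_atom") <- which(tab$name == "OG" & tab$resname == "SER")
  attr(traj, "hbond_on") <- c(5.65, 0.0, 0.0)
  attr(traj, "hbond_off") <- c(8.25, 0.0, 0.0)
  traj
}

#' Specification for the toy-trajectory generator
#'
#' @param sigma isotropic per-coordinate Gaussian jitter, Angstrom.
#' @param drift optional length-3 rigid displacement applied cumulatively
#'   per frame (default none).
#' @param p_hbond per-frame probability that the probe acceptor sits in
#'   hydrogen-bond geometry, in `[0, 1]`.
#' @param frames number of frames, >= 1.
#' @param seed integer seed.
#' @return object of class `"trajectory_generator_spec"`.
#' @export
trajectory_generator_spec <- function(sigma = 0.1, drift = c(0, 0, 0),
                                      p_hbond = 0.85, frames = 200L,
                                      seed = 1L) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0",
                                           call. = FALSE)
  if (!is.finite(p_hbond) || p_hbond < 0 || p_hbond > 1)
    stop("p_hbond must lie in [0, 1]", call. = FALSE)
  if (frames < 1L) stop("need >= 1 frame", call. = FALSE)
  structure(list(sigma = sigma, drift = drift, p_hbond = p_hbond,
                 frames = as.integer(frames), seed = as.integer(seed)),
            class = "trajectory_generator_spec")
}

#' Generate a jittered toy trajectory with known ground truth
#'
#' Frames are the [toy_complex()] template plus iid isotropic Gaussian
#' jitter (and optional cumulative rigid drift); the serine probe
#' acceptor is placed in hydrogen-bond geometry in an independent
#' Bernoulli(`p_hbond`) subset of frames and displaced beyond the cutoff
#' otherwise. The first frame carries no jitter: it is the reference
#' (initial) configuration against which per-frame RMSD is convention-
#' ally measured, so the expected RMSD of later frames is sigma*sqrt(3).
#' Ground truth (spec, probe atom index, per-frame bond states) is
#' attached as `attr(x, "manifest")`.
#'
#' @param spec a [trajectory_generator_spec()].
#' @return a [trajectory()].
#' @export
gen_toy_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_generator_spec"))
  set.seed(spec$seed)
  tpl <- toy_complex()
  base <- frame_coords(tpl, 1L)
  probe <- attr(tpl, "probe_atom")
  on_pos <- attr(tpl, "hbond_on"); off_pos <- attr(tpl, "hbond_off")
  nat <- nrow(base)
  hbond_state <- runif(spec$frames) < spec$p_hbond
  coords <- array(NA_real_, c(spec$frames, nat, 3L))
  for (f in seq_len(spec$frames)) {
    xyz <- base
    xyz[probe, ] <- if (hbond_state[f]) on_pos else off_pos
    if (spec$sigma > 0 && f > 1L)
      xyz <- xyz + matrix(rnorm(nat * 3L, 0, spec$sigma), nat, 3L)
    xyz <- sweep(xyz, 2L, spec$drift * (f - 1L), "+")
    coords[f, , ] <- xyz
  }
  traj <- trajectory(coords, tpl$atoms)
  attr(traj, "manifest") <- list(spec = spec, probe_atom = probe,
                                 hbond_state = hbond_state)
  traj
}
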