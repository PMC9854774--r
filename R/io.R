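validate_energy_table <- function(df) {
  need <- c("frame", "replicate", "state", "vdw", "ele")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("energy table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- !df$state %in% c("bound", "free", "bound_q0")
  if (any(bad))
    stop(sprintf("unknown state label '%s' (row %d)",
                 df$state[which(bad)[1L]], which(bad)[1L]), call. = FALSE)
  miss_ele <- !is.finite(df$ele)
  if (any(miss_ele))
    stop(sprintf("non-numeric or missing ele energy (row %d)",
                 which(miss_ele)[1L]), call. = FALSE)
  miss_vdw <- !is.finite(df$vdw) & df$state != "bound_q0"
  if (any(miss_vdw))
    stop(sprintf("non-numeric vdw energy outside bound_q0 (row %d)",
                 which(miss_vdw)[1L]), call. = FALSE)
  invisible(df)
}

#' Read a long-format interaction-energy table
#'
#' CSV or TSV (sniffed from the header line) with required columns
#' `frame`, `replicate`, `state` (`bound`, `free` or `bound_q0`), `vdw`,
#' `ele`, energies in kcal/mol. `vdw` may be empty on `bound_q0` rows
#' only (the uncharged-ligand state samples electrostatics alone). Row
#' order within each series is preserved. Parse errors name the
#' offending data row.
#'
#' @param path file path.
#' @return validated data frame in the energy-table dialect.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("frame", "replicate", "vdw", "ele"))
    if (col %in% names(df)) df[[col]] <- suppressWarnings(
      as.numeric(df[[col]]))
  validate_energy_table(df)
}

#' @rdname read_energy_table
#' @param energies data frame in the energy-table dialect.
#' @export
write_energy_table <- function(energies, path) {
  validate_energy_table(energies)
  write.csv(energies, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read kinetics observations (substrate_uM, inhibitor_uM, velocity)
#'
#' @param path CSV with columns `substrate_uM`, `inhibitor_uM`,
#'   `velocity` and optionally `replicate`.
#' @return data frame with columns `S`, `I`, `v`, `replicate`, ready for
#'   [inhibition_fit()].
#' @export
read_kinetics_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate_uM", "inhibitor_uM", "velocity")
  if (!all(need %in% names(df)))
    stop("kinetics CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- data.frame(S = as.numeric(df$substrate_uM),
                    I = as.numeric(df$inhibitor_uM),
                    v = as.numeric(df$velocity),
                    replicate = if ("replicate" %in% names(df))
                      df$replicate else 1L)
  validate_kinetics_data(out)
}

#' @rdname read_kinetics_csv
#' @param data data frame with columns `S`, `I`, `v` (and optionally
#'   `replicate`).
#' @export
write_kinetics_csv <- function(data, path) {
  validate_kinetics_data(data)
  out <- data.frame(substrate_uM = data$S, inhibitor_uM = data$I,
                    velocity = data$v,
                    replicate = if ("replicate" %in% names(data))
                      data$replicate else 1L)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dose-response table (conc_uM, response_pct)
#'
#' @param path CSV with columns `conc_uM`, `response_pct`.
#' @return data frame with columns `conc`, `response` for [ic50_fit()].
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("conc_uM", "response_pct") %in% names(df)))
    stop("dose-response CSV needs columns conc_uM, response_pct",
         call. = FALSE)
  data.frame(conc = as.numeric(df$conc_uM),
             response = as.numeric(df$response_pct))
}

#' @rdname read_dose_response
#' @param data data frame with columns `conc`, `response`.
#' @export
write_dose_response <- function(data, path) {
  write.csv(data.frame(conc_uM = data$conc, response_pct = data$response),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses MODEL/ENDMDL blocks (or a single implicit model) with bio3d.
#' The atom table is taken from the first model; every model must carry
#' the same atom count. Atom roles are assigned from the record: HETATM
#' residues other than water become `ligand`, standard ATOM records
#' `protein`, waters and ions `other`. Residue numbers are passed through
#' verbatim. A light pre-scan reports malformed ATOM/HETATM records and
#' inter-model atom-count mismatches with their line numbers.
#'
#' @param path PDB file path.
#' @param ligand_resname optional residue name(s) forced to role
#'   `ligand` regardless of record type.
#' @return a [trajectory()].
#' @export
read_pdb_trajectory <- function(path, ligand_resname = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path,
                          call. = FALSE)
  for (ln in which(is_atom)) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54))))))
      stop(sprintf("malformed coordinate record at line %d", ln),
           call. = FALSE)
  }
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts,
                     model_ends)
    if (length(unique(counts)) != 1L)
      stop(sprintf(
        "model %d has %d atoms but model 1 has %d (line %d)",
        which(counts != counts[1L])[1L],
        counts[which(counts != counts[1L])[1L]], counts[1L],
        model_starts[which(counts != counts[1L])[1L]]), call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  nat <- nrow(a)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, nat, 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  element <- a$elesy
  if (is.null(element) || all(is.na(element)) || all(element == ""))
    element <- gsub("[0-9']", "", substr(trimws(a$elety), 1L, 1L))
  role <- ifelse(a$type == "HETATM", "ligand", "protein")
  role[a$resid %in% c("HOH", "WAT", "NA", "CL", "K", "MG", "ZN")] <- "other"
  if (!is.null(ligand_resname)) role[a$resid %in% ligand_resname] <- "ligand"
  atoms <- data.frame(name = trimws(a$elety), element = trimws(element),
                      resname = trimws(a$resid), resno = a$resno,
                      chain = a$chain, role = role,
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms)
}

#' @rdname read_pdb_trajectory
#' @param traj a [trajectory()] to write as a multi-model PDB.
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    rec <- ifelse(a$role == "ligand", "HETATM", "ATOM  ")
    name4 <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name),
                    substr(a$name, 1L, 4L))
    writeLines(sprintf(
      "%s%5d %s %-3s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      rec, seq_len(nrow(a)), name4, a$resname, a$chain, a$resno,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], a$element), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Default run configuration
#'
#' Central defaults used across the package: thermodynamic constants, LIE
#' coefficients, interaction criteria, fit options and seed. Values match
#' the conventions documented in each constructor. A YAML file with any
#' subset of the keys `thermo`, `lie`, `criteria`, `fit`, `seed`
#' overrides the defaults.
#'
#' @param path optional YAML file.
#' @return nested list of configuration objects.
#' @export
bindkin_config <- function(path = NULL) {
  cfg <- list(thermo = thermo_constants(),
              lie = lie_coefficients(),
              criteria = interaction_criteria(),
              fit = list(weights = "relative", alpha = 0.05,
                         constrain = NULL),
              seed = 1L, verbosity = 1L)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user$thermo))
      cfg$thermo <- do.call(thermo_constants, user$thermo)
    if (!is.null(user$lie))
      cfg$lie <- do.call(lie_coefficients, user$lie)
    if (!is.null(user$criteria))
      cfg$criteria <- do.call(interaction_criteria, user$criteria)
    if (!is.null(user$fit)) cfg$fit[names(user$fit)] <- user$fit
    if (!is.null(user$seed)) cfg$seed <- as.integer(user$seed)
    if (!is.null(user$verbosity)) cfg$verbosity <- as.integer(user$verbosity)
  }
  cfg
}
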