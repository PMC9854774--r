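#' Geometric criteria for protein-ligand interaction detection
#'
#' Distance and angle cutoffs for the four interaction types detected by
#' [detect_interactions()]. Defaults follow the published PLIP geometric
#' criteria: hydrogen bond donor-acceptor distance <= 4.1 A with donor
#' angle >= 100 degrees; hydrophobic carbon-carbon contact <= 4.0 A;
#' pi-stacking ring-centroid distance <= 5.5 A with plane angle within 30
#' degrees of parallel (0) or perpendicular (90) and centroid offset <=
#' 2.0 A; pi-cation centroid-charge distance <= 6.0 A.
#'
#' @param hbond_max_dist A, donor-acceptor heavy-atom distance.
#' @param hbond_min_donor_angle degrees, D-H...A angle.
#' @param hydrophobic_max_dist A.
#' @param pistack_max_centroid_dist A.
#' @param pistack_max_offset A.
#' @param pistack_angle_tol degrees, allowed deviation from 0 or 90.
#' @param pication_max_dist A.
#' @return object of class `"interaction_criteria"`.
#' @export
interaction_criteria <- function(hbond_max_dist = 4.1,
                                 hbond_min_donor_angle = 100,
                                 hydrophobic_max_dist = 4.0,
                                 pistack_max_centroid_dist = 5.5,
                                 pistack_max_offset = 2.0,
                                 pistack_angle_tol = 30,
                                 pication_max_dist = 6.0) {
  dists <- c(hbond_max_dist, hydrophobic_max_dist,
             pistack_max_centroid_dist, pistack_max_offset,
             pication_max_dist)
  if (any(!is.finite(dists)) || any(dists <= 0))
    stop("all distance cutoffs must be positive", call. = FALSE)
  if (hbond_min_donor_angle < 0 || hbond_min_donor_angle > 180 ||
      pistack_angle_tol < 0 || pistack_angle_tol > 90)
    stop("angle criteria out of range", call. = FALSE)
  structure(list(hbond_max_dist = hbond_max_dist,
                 hbond_min_donor_angle = hbond_min_donor_angle,
                 hydrophobic_max_dist = hydrophobic_max_dist,
                 pistack_max_centroid_dist = pistack_max_centroid_dist,
                 pistack_max_offset = pistack_max_offset,
                 pistack_angle_tol = pistack_angle_tol,
                 pication_max_dist = pication_max_dist),
            class = "interaction_criteria")
}

covalent_radius <- function(element) {
  r <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
         F = 0.57, CL = 1.02, BR = 1.20)
  out <- r[toupper(element)]
  out[is.na(out)] <- 0.9
  unname(out)
}

# Bonded pairs inferred from covalent radii with the additive tolerance
# rule (bonded if distance <= r_i + r_j + 0.4 A), which stays stable
# under thermal coordinate noise; returns adjacency list by atom index.
infer_bonds <- function(xyz, elements) {
  n <- nrow(xyz)
  rad <- covalent_radius(elements)
  d <- pairwise_dist(xyz, xyz)
  cutoff <- outer(rad, rad, "+") + 0.4
  diag(d) <- Inf
  adj <- d <= cutoff & d > 0.1
  lapply(seq_len(n), function(i) which(adj[i, ]))
}

# 5- or 6-membered rings of carbon/nitrogen atoms found by DFS on the
# inferred bond graph; returns list of integer index vectors, deduplicated
# by atom set. Planarity is checked (max deviation from the LS plane).
find_rings <- function(xyz, elements, adj, max_dev = 0.3) {
  ringy <- which(toupper(elements) %in% c("C", "N"))
  found <- list()
  seen <- character()
  dfs <- function(path, target, depth_left) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (!(nb %in% ringy)) next
      if (nb == target && length(path) >= 5L) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          found[[length(found) + 1L]] <<- sort(path)
        }
      } else if (depth_left > 0L && !(nb %in% path) && nb > path[1L]) {
        dfs(c(path, nb), target, depth_left - 1L)
      }
    }
  }
  for (a in ringy) dfs(a, a, 5L)
  Filter(function(ring) {
    pts <- xyz[ring, , drop = FALSE]
    ctr <- colMeans(pts)
    pc <- sweep(pts, 2L, ctr)
    nrm <- svd(pc)$v[, 3L]
    max(abs(pc %*% nrm)) <= max_dev
  }, found)
}

ring_geometry <- function(xyz, ring) {
  pts <- xyz[ring, , drop = FALSE]
  ctr <- colMeans(pts)
  nrm <- svd(sweep(pts, 2L, ctr))$v[, 3L]
  list(centroid = ctr, normal = nrm / sqrt(sum(nrm^2)))
}

vec_angle <- function(u, v) {
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

# Atom typing on one frame. Donors: N/O with a bonded hydrogen (when the
# structure has hydrogens) else all N/O with the angle criterion waived.
# Acceptors: all N/O. Apolar carbons: C with no bonded N/O. Cations:
# sidechain nitrogens of Lys (NZ) and Arg (NH1/NH2/NE), plus any atom
# whose name ends in "+".
atom_typing <- function(xyz, atoms, adj) {
  el <- toupper(atoms$element)
  has_h <- any(el == "H")
  polar <- el %in% c("N", "O")
  donors <- list()
  if (has_h) {
    for (i in which(polar)) {
      hs <- adj[[i]][el[adj[[i]]] == "H"]
      if (length(hs)) donors[[length(donors) + 1L]] <-
          list(heavy = i, hydrogens = hs)
    }
  } else {
    donors <- lapply(which(polar), function(i)
      list(heavy = i, hydrogens = integer()))
  }
  apolar <- vapply(seq_len(nrow(atoms)), function(i)
    el[i] == "C" && !any(el[adj[[i]]] %in% c("N", "O")), TRUE)
  cation <- (atoms$resname == "LYS" & atoms$name == "NZ") |
    (atoms$resname == "ARG" & atoms$name %in% c("NH1", "NH2", "NE")) |
    endsWith(atoms$name, "+")
  list(donors = donors, acceptors = which(polar), apolar = which(apolar),
       cations = which(cation), has_h = has_h)
}

#' Detect protein-ligand interactions in one frame
#'
#' Applies geometric rules to every candidate ligand/protein atom (or
#' ring) pair in a single frame and emits one record per satisfied
#' criterion. Hydrogen-bond donors are N/O atoms carrying a bonded
#' hydrogen (bonds inferred from covalent radii); when the structure has
#' no hydrogens at all, every N/O is treated as a potential donor and the
#' donor-angle criterion is waived with a message. Aromatic rings are
#' planar 5-/6-membered C/N cycles of the inferred bond graph.
#'
#' @param traj a [trajectory()].
#' @param frame frame index.
#' @param ligand_sel,protein_sel disjoint atom index vectors (defaults:
#'   atoms with role `ligand` / `protein`).
#' @param criteria an [interaction_criteria()] object.
#' @return data frame of events: `frame`, `type`, `ligand_atom`,
#'   `protein_atom`, `residue`, `resno`, `distance`, `angle` (NA where
#'   not applicable).
#' @export
detect_interactions <- function(traj, frame = 1L, ligand_sel = NULL,
                                protein_sel = NULL,
                                criteria = interaction_criteria()) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(criteria, "interaction_criteria"))
  atoms <- traj$atoms
  if (is.null(ligand_sel)) ligand_sel <- which(atoms$role == "ligand")
  if (is.null(protein_sel)) protein_sel <- which(atoms$role == "protein")
  if (length(ligand_sel) == 0L || length(protein_sel) == 0L)
    stop("ligand and protein selections must be non-empty", call. = FALSE)
  if (length(intersect(ligand_sel, protein_sel)))
    stop("ligand and protein selections overlap", call. = FALSE)
  if (any(is.na(atoms$element)) || any(atoms$element == ""))
    stop("element metadata required for interaction typing", call. = FALSE)

  xyz <- frame_coords(traj, frame)
  adj <- infer_bonds(xyz, atoms$element)
  typ <- atom_typing(xyz, atoms, adj)
  ev <- list()
  emit <- function(type, la, pa, dist, ang = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      frame = frame, type = type,
      ligand_atom = atoms$name[la],
      protein_atom = if (is.na(pa)) NA_character_ else atoms$name[pa],
      residue = atoms$resname[if (is.na(pa)) la else pa],
      resno = atoms$resno[if (is.na(pa)) la else pa],
      distance = dist, angle = ang, stringsAsFactors = FALSE)
  }

  hbond_pairs <- function(don_side, acc_side) {
    for (don in typ$donors) {
      if (!(don$heavy %in% don_side)) next
      accs <- intersect(typ$acceptors, acc_side)
      for (acc in accs) {
        d <- sqrt(sum((xyz[don$heavy, ] - xyz[acc, ])^2))
        if (d > criteria$hbond_max_dist) next
        if (typ$has_h) {
          if (length(don$hydrogens) == 0L) next
          angs <- vapply(don$hydrogens, function(h)
            vec_angle(xyz[don$heavy, ] - xyz[h, ], xyz[acc, ] - xyz[h, ]),
            0)
          if (max(angs) < criteria$hbond_min_donor_angle) next
          ang <- max(angs)
        } else ang <- NA_real_
        la <- if (don$heavy %in% ligand_sel) don$heavy else acc
        pa <- if (don$heavy %in% ligand_sel) acc else don$heavy
        emit("hbond", la, pa, d, ang)
      }
    }
  }
  hbond_pairs(ligand_sel, protein_sel)
  hbond_pairs(protein_sel, ligand_sel)

  lc <- intersect(typ$apolar, ligand_sel)
  pc <- intersect(typ$apolar, protein_sel)
  if (length(lc) && length(pc)) {
    d <- pairwise_dist(xyz[lc, , drop = FALSE], xyz[pc, , drop = FALSE])
    hit <- which(d <= criteria$hydrophobic_max_dist, arr.ind = TRUE)
    for (k in seq_len(nrow(hit)))
      emit("hydrophobic", lc[hit[k, 1L]], pc[hit[k, 2L]],
           d[hit[k, 1L], hit[k, 2L]])
  }

  rings <- find_rings(xyz, atoms$element, adj)
  ring_side <- function(r)
    if (all(r %in% ligand_sel)) "ligand"
    else if (all(r %in% protein_sel)) "protein" else "mixed"
  sides <- vapply(rings, ring_side, "")
  lrings <- rings[sides == "ligand"]; prings <- rings[sides == "protein"]
  for (lr in lrings) {
    gl <- ring_geometry(xyz, lr)
    for (pr in prings) {
      gp <- ring_geometry(xyz, pr)
      dc <- sqrt(sum((gl$centroid - gp$centroid)^2))
      if (dc > criteria$pistack_max_centroid_dist) next
      ang <- vec_angle(gl$normal, gp$normal)
      ang <- min(ang, 180 - ang)
      ok_angle <- ang <= criteria$pistack_angle_tol ||
        abs(ang - 90) <= criteria$pistack_angle_tol
      if (!ok_angle) next
      # offset: in-plane displacement of the partner centroid
      proj <- abs(sum((gp$centroid - gl$centroid) * gl$normal))
      offset <- sqrt(max(dc^2 - proj^2, 0))
      if (offset > criteria$pistack_max_offset) next
      emit("pi_stack", lr[1L], pr[1L], dc, ang)
    }
    for (ct in intersect(typ$cations, protein_sel)) {
      d <- sqrt(sum((gl$centroid - xyz[ct, ])^2))
      if (d <= criteria$pication_max_dist)
        emit("pi_cation", lr[1L], ct, d)
    }
  }
  # protein ring vs ligand cation
  for (pr in prings) {
    gp <- ring_geometry(xyz, pr)
    for (ct in intersect(typ$cations, ligand_sel)) {
      d <- sqrt(sum((gp$centroid - xyz[ct, ])^2))
      if (d <= criteria$pication_max_dist)
        emit("pi_cation", ct, pr[1L], d)
    }
  }

  if (length(ev) == 0L)
    return(data.frame(frame = integer(), type = character(),
                      ligand_atom = character(),
                      protein_atom = character(), residue = character(),
                      resno = integer(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, ev)
}

#' Detect interactions across all frames of a trajectory
#'
#' @inheritParams detect_interactions
#' @param frames frame indices to scan (default all).
#' @return data frame of events from all scanned frames.
#' @export
interaction_events <- function(traj, ligand_sel = NULL, protein_sel = NULL,
                               criteria = interaction_criteria(),
                               frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  do.call(rbind, lapply(frames, function(f)
    detect_interactions(traj, f, ligand_sel, protein_sel, criteria)))
}

#' Per-interaction occurrence over a trajectory
#'
#' Occurrence (occupancy) of each distinct interaction: 100 x number of
#' frames containing at least one matching event over the total frame
#' count, with the mean distance over those events. Interactions are
#' keyed by type, protein residue and, for hydrogen bonds, the partner
#' atoms.
#'
#' @param events event table from [interaction_events()].
#' @param n_frames total number of frames scanned (denominator).
#' @param key character vector of event columns defining one interaction
#'   (default `type`, `residue`, `resno`).
#' @return data frame with one row per interaction: key columns,
#'   `occurrence` (percent), `mean_distance`, `n_frames_present`.
#' @export
occurrence <- function(events, n_frames,
                       key = c("type", "residue", "resno")) {
  if (!is.numeric(n_frames) || n_frames < 1L)
    stop("n_frames must be a positive frame count", call. = FALSE)
  if (nrow(events) == 0L)
    return(data.frame(type = character(), residue = character(),
                      resno = integer(), occurrence = numeric(),
                      mean_distance = numeric(),
                      n_frames_present = integer()))
  groups <- split(events, interaction(events[key], drop = TRUE))
  out <- do.call(rbind, lapply(groups, function(g) {
    rec <- g[1L, key, drop = FALSE]
    rec$occurrence <- 100 * length(unique(g$frame)) / n_frames
    rec$mean_distance <- mean(g$distance)
    rec$n_frames_present <- length(unique(g$frame))
    rec
  }))
  rownames(out) <- NULL
  out[order(-out$occurrence), , drop = FALSE]
}
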