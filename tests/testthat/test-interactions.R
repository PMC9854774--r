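test_that("constructed geometries trigger exactly the intended criteria", {
  tpl <- toy_complex()
  ev <- detect_interactions(tpl, 1)
  hb <- ev[ev$type == "hbond", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_gte(hb$angle, 100)
  expect_identical(hb$residue, "SER")
  ps <- ev[ev$type == "pi_stack", ]
  expect_equal(nrow(ps), 1)
  expect_equal(ps$distance, 3.8, tolerance = 1e-6)
  expect_identical(ps$residue, "PHE")
  pc <- ev[ev$type == "pi_cation", ]
  expect_equal(nrow(pc), 1)
  expect_equal(pc$distance, 4.5, tolerance = 1e-6)
  expect_identical(pc$residue, "LYS")
  expect_gt(nrow(ev[ev$type == "hydrophobic", ]), 0)
  expect_true(all(ev$distance[ev$type == "hydrophobic"] <= 4.0))
})

test_that("events vanish when the geometry exceeds the cutoffs", {
  tpl <- toy_complex()
  xyz <- frame_coords(tpl, 1)
  probe <- attr(tpl, "probe_atom")
  xyz[probe, ] <- c(2.75 + 4.5, 0, 0)  # donor-acceptor now 4.5 A
  moved <- trajectory(xyz, tpl$atoms)
  ev <- detect_interactions(moved, 1)
  expect_equal(nrow(ev[ev$type == "hbond", ]), 0)
  # tighter criteria switch off the pi-stack
  strict <- interaction_criteria(pistack_max_centroid_dist = 3.0)
  ev2 <- detect_interactions(tpl, 1, criteria = strict)
  expect_equal(nrow(ev2[ev2$type == "pi_stack", ]), 0)
})

test_that("parallel rings at stacking distance are found from raw geometry", {
  # two benzene rings, centroids 3.8 A apart with 0.5 A lateral offset
  mk_ring <- function(cx, cy, cz, role, resname, chain) {
    th <- (0:5) * pi / 3
    data.frame(name = paste0("C", 1:6), element = "C", resname = resname,
               resno = 1L, chain = chain, role = role,
               x = cx + 1.39 * cos(th), y = cy + 1.39 * sin(th),
               z = cz, stringsAsFactors = FALSE)
  }
  tab <- rbind(mk_ring(0, 0, 0, "ligand", "LIG", "L"),
               mk_ring(0.5, 0, 3.77, "protein", "PHE", "A"))
  tr <- trajectory(as.matrix(tab[, c("x", "y", "z")]),
                   tab[, c("name", "element", "resname", "resno",
                           "chain", "role")])
  ev <- detect_interactions(tr, 1)
  ps <- ev[ev$type == "pi_stack", ]
  expect_equal(nrow(ps), 1)
  expect_equal(ps$distance, sqrt(3.77^2 + 0.5^2), tolerance = 1e-6)
})

test_that("detection is invariant to atom ordering", {
  tpl <- toy_complex()
  set.seed(5)
  perm <- sample(nrow(tpl$atoms))
  shuffled <- trajectory(frame_coords(tpl, 1)[perm, ],
                         tpl$atoms[perm, ])
  ev1 <- detect_interactions(tpl, 1)
  ev2 <- detect_interactions(shuffled, 1)
  key <- function(e) sort(paste(e$type, e$residue, e$resno,
                                round(e$distance, 6)))
  expect_identical(key(ev1), key(ev2))
})

test_that("detection validates selections and metadata", {
  tpl <- toy_complex()
  expect_error(detect_interactions(tpl, 1, ligand_sel = 1:5,
                                   protein_sel = 3:10), "overlap")
  bad <- tpl
  bad$atoms$element[1] <- ""
  expect_error(detect_interactions(bad, 1), "element metadata")
})

test_that("occurrence counts frames, not events", {
  ev <- data.frame(frame = c(1, 1, 2, 4), type = "hbond",
                   ligand_atom = "O1", protein_atom = "OG",
                   residue = "SER", resno = 7L,
                   distance = c(2.9, 3.0, 2.8, 2.95), angle = NA_real_)
  occ <- occurrence(ev, n_frames = 4)
  expect_equal(occ$occurrence, 75)  # frames 1, 2, 4 of 4
  expect_equal(occ$mean_distance, mean(ev$distance))
  expect_equal(occurrence(ev[0, ], 10)$occurrence, numeric(0))
  expect_error(occurrence(ev, 0), "positive")
})

test_that("synthetic hydrogen-bond occupancy recovers its Bernoulli truth", {
  tr <- gen_toy_trajectory(trajectory_generator_spec(sigma = 0.1,
                                                     p_hbond = 0.85,
                                                     frames = 400,
                                                     seed = 12))
  ev <- interaction_events(tr)
  occ <- occurrence(ev, n_frames(tr))
  hb <- occ[occ$type == "hbond", ]
  truth <- 100 * mean(attr(tr, "manifest")$hbond_state)
  expect_lt(abs(hb$occurrence - truth), 1.5)
  # every-frame and no-frame extremes
  on <- gen_toy_trajectory(trajectory_generator_spec(sigma = 0,
                                                     p_hbond = 1,
                                                     frames = 5, seed = 1))
  occ_on <- occurrence(interaction_events(on), 5)
  expect_equal(occ_on$occurrence[occ_on$type == "hbond"], 100)
  off <- gen_toy_trajectory(trajectory_generator_spec(sigma = 0,
                                                      p_hbond = 0,
                                                      frames = 5,
                                                      seed = 1))
  occ_off <- occurrence(interaction_events(off), 5)
  expect_equal(nrow(occ_off[occ_off$type == "hbond", ]), 0)
})
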