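test_that("a single isolated sphere has the closed-form accessible area", {
  m <- single_atom_model()
  s <- sasa(m, probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(s$atom_area, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.005)
  # two far-apart atoms: additivity
  m2 <- m
  m2$atoms <- rbind(m2$atoms, within(m2$atoms, {x <- 100; resno <- 2L}))
  s2 <- sasa(m2, 1.4, 960)
  expect_equal(sum(s2$atom_area), 2 * s$atom_area, tolerance = 1e-9)
  # a tightly enclosed atom has (near) zero area
  sh <- make_shell()
  s3 <- sasa(sh, 1.4, 240)
  expect_lt(s3$atom_area[1], 1e-9)
})

test_that("per-residue areas conserve the per-atom sum and are deterministic", {
  s <- sasa(FX_REF, n_sphere_points = 240)
  expect_equal(sum(s$residue$area), sum(s$atom_area), tolerance = 1e-9)
  s2 <- sasa(FX_REF, n_sphere_points = 240)
  expect_identical(s$atom_area, s2$atom_area)
})

test_that("relative accessibility is area over the reference maximum", {
  expect_equal(relative_sasa(0, "ALA"), 0)
  expect_equal(relative_sasa(129.0, "ALA"), 1)
  expect_true(is.na(relative_sasa(50, "XYZ")))
  # an interior glycine of an extended tripeptide, against the oracle
  # computed with the same reference table
  tri <- structure_model(build_backbone(rep("GLY", 3), phi = -139,
                                        psi = 135, chain_id = "A"),
                         entry_id = "TEST")
  s <- sasa(tri, 1.4, 960)
  expected <- s$residue$area[2] / 104.0
  expect_equal(relative_sasa(s$residue$area[2], "GLY"), expected)
})

test_that("complexed relative accessibility never exceeds the isolated value", {
  cpx <- sasa(FX_REF, n_sphere_points = 240)$residue
  iso <- sasa(subset_chains(FX_REF, "C"), n_sphere_points = 240)$residue
  cpx_c <- cpx[cpx$chain == "C", ]
  m <- match(iso$key, cpx_c$key)
  expect_true(all(cpx_c$area[m] <= iso$area + 1e-9))
})

test_that("residue depth orders buried below surface and is local", {
  sh <- make_shell()
  d <- residue_depth(sh)
  expect_gt(d$depth[1], max(d$depth[-1]))
  # a fully exposed lone residue sits within ~2 A of the surface shell
  lone <- single_atom_model()
  lone$atoms <- build_backbone("GLY", chain_id = "A")
  lone <- structure_model(lone$atoms, entry_id = "TEST")
  dl <- residue_depth(lone)
  expect_lt(dl$depth[1], 2)
  # adding remote atoms does not change the depth
  far <- lone
  extra <- build_backbone("GLY", chain_id = "B")
  extra$x <- extra$x + 300
  far$atoms <- rbind(far$atoms, extra)
  df <- residue_depth(far)
  expect_equal(df$depth[1], dl$depth[1], tolerance = 1e-6)
  # single-atom model: depth 0 by convention
  expect_equal(residue_depth(single_atom_model())$depth, 0)
})

test_that("protrusion index follows its volumetric definition", {
  # isolated atom: V_int = one atom volume, cx hits the cap
  m <- single_atom_model()
  cx <- protrusion_index(m, sphere_radius = 10, mean_atom_volume = 20.1,
                         cx_cap = 15)
  raw <- (4 / 3 * pi * 1000 - 20.1) / 20.1
  expect_gt(raw, 200)          # the uncapped arithmetic value
  expect_equal(cx$cx, 15)      # reported as the cap
  # atom at the centre of a uniformly filled ball: cx near 0
  pts <- expand.grid(x = seq(-9, 9, 3), y = seq(-9, 9, 3),
                     z = seq(-9, 9, 3))
  pts <- pts[sqrt(rowSums(pts^2)) <= 10.5, ]
  filled <- structure_model(data.frame(
    type = "ATOM", elety = "CA", resid = "GLY", chain = "A",
    resno = seq_len(nrow(pts)), x = pts$x, y = pts$y, z = pts$z,
    elesy = "C", stringsAsFactors = FALSE), entry_id = "TEST")
  centre_idx <- which(pts$x == 0 & pts$y == 0 & pts$z == 0)
  cxf <- protrusion_index(filled, 10, (4 / 3 * pi * 1000) /
                            sum(sqrt(rowSums(pts^2)) <= 10), 15)
  expect_lt(cxf$cx[centre_idx], 0.5)
  # rod: the tip protrudes more than the midpoint
  rod <- structure_model(build_backbone(rep("GLY", 40), phi = -139,
                                        psi = 135, chain_id = "A"),
                         entry_id = "TEST")
  cxr <- protrusion_index(rod)
  expect_gt(cxr$cx[1], cxr$cx[20])
})

test_that("half-sphere exposure partitions the neighbour count", {
  hse <- half_sphere_exposure(FX_REF, "H", radius = 13)
  ca <- coords(FX_REF, FX_REF$atoms$chain == "H" &
                 FX_REF$atoms$elety == "CA")
  d <- cdist(ca, ca)
  for (i in seq_len(nrow(hse))) {
    n_nbr <- sum(d[i, -i] <= 13)
    expect_equal(hse$hse_up[i] + hse$hse_down[i], n_nbr)
  }
  # two residues beyond the radius see no neighbours
  two <- structure_model(build_backbone(c("GLY", "GLY"), chain_id = "A"),
                         entry_id = "TEST")
  two$atoms$x[two$atoms$resno == 2] <- two$atoms$x[two$atoms$resno == 2] + 50
  h2 <- half_sphere_exposure(two, "A", radius = 13)
  expect_equal(h2$hse_up, c(0L, 0L))
  expect_equal(h2$hse_down, c(0L, 0L))
})

test_that("helix interior half-sphere counts match a brute-force half-space classifier", {
  h <- make_ideal_secondary("helix", 12)
  hse <- half_sphere_exposure(h, "A", radius = 13)
  a <- h$atoms
  i <- 6
  n <- as.numeric(a[a$resno == i & a$elety == "N", c("x", "y", "z")])
  ca <- as.numeric(a[a$resno == i & a$elety == "CA", c("x", "y", "z")])
  c_ <- as.numeric(a[a$resno == i & a$elety == "C", c("x", "y", "z")])
  cb_dir <- fvkit:::place_cb(n, ca, c_) - ca
  up <- down <- 0L
  for (j in setdiff(1:12, i)) {
    cj <- as.numeric(a[a$resno == j & a$elety == "CA", c("x", "y", "z")])
    if (sqrt(sum((cj - ca)^2)) > 13) next
    if (sum((cj - ca) * cb_dir) > 0) up <- up + 1L else down <- down + 1L
  }
  expect_equal(hse$hse_up[6], up)
  expect_equal(hse$hse_down[6], down)
})

test_that("backbone dihedrals recover the construction angles with terminal absences", {
  h <- make_ideal_secondary("helix", 12)
  d <- dihedrals(h, "A")
  expect_true(is.na(d$phi[1]))
  expect_true(is.na(d$psi[12]))
  expect_equal(d$phi[2:11], rep(-57, 10), tolerance = 2 / 57)
  expect_equal(d$psi[2:11], rep(-47, 10), tolerance = 2 / 47)
  # mirroring the coordinates negates the angles
  mir <- h
  mir$atoms$x <- -mir$atoms$x
  dm <- dihedrals(mir, "A")
  expect_equal(dm$phi[2:11], -d$phi[2:11], tolerance = 1e-9)
  expect_equal(dm$psi[2:11], -d$psi[2:11], tolerance = 1e-9)
})

test_that("a chain break suppresses dihedrals across it", {
  h <- make_ideal_secondary("helix", 12)
  broken <- h
  sel <- broken$atoms$resno >= 7
  broken$atoms[sel, c("x", "y", "z")] <-
    broken$atoms[sel, c("x", "y", "z")] + 30
  d <- dihedrals(broken, "A")
  expect_true(is.na(d$psi[6]))
  expect_true(is.na(d$phi[7]))
  expect_false(is.na(d$phi[6]))
})

test_that("secondary structure assigns H to helix interiors, C to lone strands, E to paired strands", {
  h <- make_ideal_secondary("helix", 12)
  ss <- secondary_structure(h)$ss
  expect_true(all(ss[3:10] == "H"))
  lone <- make_ideal_secondary("strand", 8)
  expect_true(all(secondary_structure(lone)$ss == "C"))
  sp <- make_strand_pair(8)
  ssp <- secondary_structure(sp)$ss
  expect_gt(sum(ssp == "E"), 8)   # both strands' paired cores
  # residues lacking carbonyl O fall back to C
  no_o <- h
  no_o$atoms <- no_o$atoms[no_o$atoms$elety != "O", ]
  expect_true(all(secondary_structure(no_o)$ss == "C"))
})

test_that("hydrophobicity uses the configured scale", {
  expect_equal(hydrophobicity("ILE"), 4.5)
  expect_equal(hydrophobicity("ARG"), -4.5)
  expect_equal(hydrophobicity("GLY"), -0.4)
  expect_true(is.na(hydrophobicity("UNK")))
  const <- stats::setNames(rep(1, 20), names(fvkit:::KYTE_DOOLITTLE))
  expect_equal(unique(hydrophobicity(c("ILE", "ARG", "GLY"), const)), 1)
})

test_that("the descriptor table has one complete row per residue and round-trips via CSV", {
  rows <- residue_descriptors(FX_REF, n_sphere_points = 240)
  expect_equal(nrow(rows), nrow(residue_table(FX_REF)))
  expect_identical(names(rows), fvkit:::DESCRIPTOR_COLUMNS)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(rows, tf)
  back <- utils::read.csv(tf, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(rows))
  expect_identical(names(back), fvkit:::DESCRIPTOR_COLUMNS)
  expect_equal(back$rel_sasa, rows$rel_sasa, tolerance = 1e-9)
  expect_equal(back$phi[2], rows$phi[2], tolerance = 1e-9)
  # absent values serialize as empty fields -> NA on re-read
  expect_true(is.na(back$phi[1]))
})
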