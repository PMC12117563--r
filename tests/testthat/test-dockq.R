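test_that("native contacts equal the brute-force all-pairs oracle", {
  native <- native_contacts(FX_REF, c("H", "L"), "C", cutoff = 5)
  oracle <- oracle_residue_contacts(FX_REF, c("H", "L"), "C", 5)
  expect_setequal(native, oracle)
  # a constructed 3-pair micro-complex returns exactly those pairs
  ab <- build_backbone(rep("GLY", 3), phi = -139, psi = 135, chain_id = "H")
  ag <- build_backbone(rep("GLY", 3), phi = -139, psi = 135, chain_id = "A")
  ag$y <- ag$y + 4.0
  micro <- structure_model(rbind(ab, ag), entry_id = "TEST")
  nc <- native_contacts(micro, "H", "A", cutoff = 5)
  expect_setequal(nc, oracle_residue_contacts(micro, "H", "A", 5))
  # a zero cutoff leaves no contacts: reference is not a complex
  expect_error(native_contacts(FX_REF, c("H", "L"), "C", cutoff = 0),
               "not a complex")
})

test_that("fnat is 1 for the reference, 0 for a far pose, and exact on partial overlap", {
  native <- native_contacts(FX_REF, c("H", "L"), "C")
  expect_equal(fnat(FX_REF, native, c("H", "L"), "C"), 1.0)
  far <- make_pose(FX_REF, c("H", "L"), translation = c(0, 0, -100))
  expect_equal(fnat(far$model, native, c("H", "L"), "C"), 0.0)
  # constructed micro-complex where a partial shift keeps some contacts
  ab <- build_backbone(rep("GLY", 6), phi = -139, psi = 135, chain_id = "H")
  ag <- ab
  ag$chain <- "A"
  ag$y <- ag$y + 4.0
  ref <- structure_model(rbind(ab, ag), entry_id = "TEST")
  native2 <- native_contacts(ref, "H", "A", cutoff = 5)
  pose <- ref
  sel <- pose$atoms$chain == "A" & pose$atoms$resno >= 4
  pose$atoms$y[sel] <- pose$atoms$y[sel] + 50
  f <- fnat(pose, native2, "H", "A", cutoff = 5)
  kept <- oracle_residue_contacts(pose, "H", "A", 5)
  expect_equal(f, length(intersect(kept, native2)) / length(native2))
  expect_lt(f, 1)
  # a pose lacking mapped residues is an error
  trimmed <- FX_REF
  trimmed$atoms <- trimmed$atoms[trimmed$atoms$chain != "C", ]
  expect_error(fnat(trimmed, native, c("H", "L"), "C"), "lacks residues")
})

test_that("superposition is exact for identical and rigidly moved sets", {
  set.seed(11)
  a <- matrix(rnorm(30), 10, 3)
  expect_lt(superpose(a, a)$rmsd, 1e-12)
  r <- rotation_axis_angle(c(1, 2, 3), 0.7)
  b <- sweep(a %*% t(r), 2, c(5, -3, 2), "+")
  fit <- superpose(a, b)
  expect_lt(fit$rmsd, 1e-9)
  moved <- fvkit:::apply_superposition(a, fit)
  expect_lt(max(abs(moved - b)), 1e-9)
  # degenerate (collinear) input is an error
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("superposition attains the orientation-grid oracle minimum", {
  set.seed(3)
  a <- matrix(rnorm(12), 4, 3)
  b <- matrix(rnorm(12), 4, 3)
  fit <- superpose(a, b)
  oracle <- oracle_superpose_rmsd(a, b)
  expect_lt(fit$rmsd, oracle + 1e-3)
  expect_equal(fit$rmsd, oracle, tolerance = 1e-3)
  # proper rotation only
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("ligand RMSD is the closed-form displacement for pure translations", {
  expect_lt(lrms(FX_REF, FX_REF, "C", c("H", "L")), 1e-9)
  p <- make_pose(FX_REF, c("H", "L"), translation = c(4, 0, 0))
  expect_equal(lrms(p$model, FX_REF, "C", c("H", "L")), 4.0,
               tolerance = 1e-9)
  p2 <- make_pose(FX_REF, c("H", "L"), translation = c(3, 4, 0))
  expect_equal(lrms(p2$model, FX_REF, "C", c("H", "L")), 5.0,
               tolerance = 1e-9)
})

test_that("ligand RMSD equals the explicit two-step oracle for a rigid move", {
  p <- make_pose(FX_REF, c("H", "L"), translation = c(2, -1, 3),
                 axis = c(0, 1, 0), angle = 0.3)
  got <- lrms(p$model, FX_REF, "C", c("H", "L"))
  # oracle: fit the receptor explicitly, then measure ligand deviation
  bb <- c("N", "CA", "C", "O")
  rec_pose <- coords(p$model, p$model$atoms$chain == "C" &
                       p$model$atoms$elety %in% bb)
  rec_ref <- coords(FX_REF, FX_REF$atoms$chain == "C" &
                      FX_REF$atoms$elety %in% bb)
  fit <- superpose(rec_pose, rec_ref)
  lig_pose <- coords(p$model, p$model$atoms$chain %in% c("H", "L") &
                       p$model$atoms$elety %in% bb)
  lig_ref <- coords(FX_REF, FX_REF$atoms$chain %in% c("H", "L") &
                      FX_REF$atoms$elety %in% bb)
  moved <- fvkit:::apply_superposition(lig_pose, fit)
  oracle <- sqrt(mean(rowSums((moved - lig_ref)^2)))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("interface RMSD uses the native-defined interface and bounds the receptor-anchored fit", {
  expect_lt(irms(FX_REF, FX_REF, c("H", "L"), "C"), 1e-9)
  p <- make_pose(FX_REF, c("H", "L"), translation = c(4, 0, 0))
  # interface residues are defined on the reference only, so the
  # translated pose has the same interface set
  i_ref <- fvkit:::interface_residues(FX_REF, c("H", "L"), "C", 10)
  expect_gt(length(i_ref), 0)
  got_irms <- irms(p$model, FX_REF, c("H", "L"), "C")
  got_lrms <- lrms(p$model, FX_REF, "C", c("H", "L"))
  # optimal joint interface fit cannot exceed the receptor-anchored fit
  expect_lt(got_irms, got_lrms)
  expect_gt(got_irms, 0)
})

test_that("the combined score follows its closed form and monotonicities", {
  expect_equal(dockq_score(1, 0, 0), 1.0)
  expect_equal(dockq_score(0, 8.5, 1.5), 1 / 3)
  expect_equal(dockq_score(0, 1e9, 1e9), 0, tolerance = 1e-12)
  # monotone: non-increasing in each RMSD, non-decreasing in fnat
  expect_true(all(diff(dockq_score(0.5, seq(0, 20, 2), 1)) < 0))
  expect_true(all(diff(dockq_score(0.5, 1, seq(0, 20, 2))) < 0))
  expect_true(all(diff(dockq_score(seq(0, 1, 0.1), 1, 1)) > 0))
})

test_that("the four-category thresholds are boundary-inclusive as printed", {
  expect_identical(classify_dockq(0.80), "high")
  expect_identical(classify_dockq(0.7999), "medium")
  expect_identical(classify_dockq(0.49), "medium")
  expect_identical(classify_dockq(0.4899), "acceptable")
  expect_identical(classify_dockq(0.23), "acceptable")
  expect_identical(classify_dockq(0.2299), "incorrect")
  expect_identical(classify_dockq(c(1, 0)), c("high", "incorrect"))
})

test_that("a perfect pose scores exactly 1 and far poses are incorrect", {
  s <- dockq(FX_REF, FX_REF, c("H", "L"), "C")
  expect_equal(s$dockq, 1.0)
  expect_identical(s$category, "high")
  far <- make_pose(FX_REF, c("H", "L"), translation = c(0, 0, -60))
  sf <- dockq(far$model, FX_REF, c("H", "L"), "C")
  expect_identical(sf$category, "incorrect")
  expect_equal(sf$fnat, 0)
})

test_that("rigid-pose components match brute-force oracles", {
  p <- make_pose(FX_REF, c("H", "L"), translation = c(6, 2, -4),
                 axis = c(1, 1, 0), angle = 0.5)
  s <- dockq(p$model, FX_REF, c("H", "L"), "C")
  native <- oracle_residue_contacts(FX_REF, c("H", "L"), "C", 5)
  kept <- oracle_residue_contacts(p$model, c("H", "L"), "C", 5)
  expect_equal(s$fnat, length(intersect(kept, native)) / length(native),
               tolerance = 1e-12)
  expect_equal(s$dockq, dockq_score(s$fnat, s$lrms, s$irms),
               tolerance = 1e-12)
})

test_that("the 4-pose descriptor subset picks one per category with incorrect back-fill", {
  scores <- data.frame(
    pose = c("p1", "p2", "p3", "p4", "p5", "p6"),
    dockq = c(0.95, 0.85, 0.60, 0.30, 0.10, 0.05))
  sel <- select_descriptor_poses(scores)
  expect_equal(nrow(sel), 4)
  expect_setequal(sel$category, c("high", "medium", "acceptable",
                                  "incorrect"))
  expect_true("p1" %in% sel$pose)     # best within high
  expect_true("p5" %in% sel$pose)     # best (only choice ranked) incorrect
  # all-incorrect set: 4 incorrect poses, lowest scores first
  all_inc <- data.frame(pose = paste0("q", 1:6),
                        dockq = c(0.20, 0.18, 0.12, 0.10, 0.05, 0.01))
  sel2 <- select_descriptor_poses(all_inc)
  expect_equal(nrow(sel2), 4)
  expect_true(all(sel2$category == "incorrect"))
  # ties break on the lexicographically smallest identifier
  tied <- data.frame(pose = c("b", "a", "c", "d", "e"),
                     dockq = c(0.9, 0.9, 0.5, 0.1, 0.05))
  sel3 <- select_descriptor_poses(tied)
  expect_true("a" %in% sel3$pose[sel3$category == "high"])
  expect_false("b" %in% sel3$pose)
  expect_error(select_descriptor_poses(tied[1:3, ]), "at least 4")
})
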