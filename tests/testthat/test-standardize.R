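test_that("VH/VL pairing respects the conserved-cysteine distance cutoff", {
  below <- make_fv(fv_separation = 15)
  doms <- detect_domains(below$model, fixture_engine(below$truth))
  res <- pair_fv(doms, below$model, cutoff = 22)
  expect_length(res$pairs, 1)
  expect_equal(res$pairs[[1]]$cys_distance, 15, tolerance = 1e-6)
  above <- make_fv(fv_separation = 25)
  doms2 <- detect_domains(above$model, fixture_engine(above$truth))
  res2 <- pair_fv(doms2, above$model, cutoff = 22)
  expect_length(res2$pairs, 0)
  expect_length(res2$singles, 2)
})

test_that("pairing sweeps across the 22 A boundary flip exactly there", {
  outcomes <- vapply(c(21.5, 21.9, 22.0, 22.1), function(sep) {
    fv <- make_fv(fv_separation = sep)
    doms <- detect_domains(fv$model, fixture_engine(fv$truth))
    length(pair_fv(doms, fv$model, cutoff = 22)$pairs)
  }, integer(1))
  expect_equal(outcomes, c(1L, 1L, 1L, 0L))
})

test_that("multi-copy pairing matches minimum-total-distance brute force", {
  fv <- make_fv(n_fv = 2, fv_separation = 16)
  doms <- detect_domains(fv$model, fixture_engine(fv$truth))
  res <- pair_fv(doms, fv$model, cutoff = 22)
  expect_length(res$pairs, 2)
  # brute force over both possible matchings of 2 VH x 2 VL
  vh <- Filter(function(d) d$domain_type == "VH", doms)
  vl <- Filter(function(d) d$domain_type == "VL", doms)
  dm <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    dm[i, j] <- sqrt(sum((fvkit:::pairing_ca(fv$model, vh[[i]]) -
                            fvkit:::pairing_ca(fv$model, vl[[j]]))^2))
  best <- min(dm[1, 1] + dm[2, 2], dm[1, 2] + dm[2, 1])
  got <- sum(vapply(res$pairs, `[[`, 0, "cys_distance"))
  expect_equal(got, best, tolerance = 1e-9)
  # symmetric under swapping input order
  res_rev <- pair_fv(rev(doms), fv$model, cutoff = 22)
  expect_equal(sort(vapply(res_rev$pairs, `[[`, 0, "cys_distance")),
               sort(vapply(res$pairs, `[[`, 0, "cys_distance")))
})

test_that("a domain lacking the conserved cysteine Calpha is unpairable", {
  fv <- make_fv()
  m <- fv$model
  m$atoms <- m$atoms[!(m$atoms$chain == "A" & m$atoms$resno == 92 &
                         m$atoms$elety == "CA"), ]
  doms <- detect_domains(m, fixture_engine(fv$truth))
  expect_message(res <- pair_fv(doms, m, cutoff = 22), "unpairable")
  expect_length(res$pairs, 0)
})

test_that("chain renaming follows the H/L, h/l and antigen rules", {
  std <- FX_STD
  map <- rename_chains(std$records[[1]])
  expect_identical(unname(map[c("VH", "VL")]), c("H", "L"))
  expect_identical(unname(map["C"]), "C")   # antigen keeps its id
  # antigen chain originally H is renamed A
  rec <- std$records[[1]]
  rec$antigen$chains <- "H"
  map2 <- rename_chains(rec)
  expect_identical(unname(map2["H"]), "A")
  # scFv halves become h and l
  rec3 <- std$records[[1]]
  rec3$antibody$kind <- "scfv"
  map3 <- rename_chains(rec3)
  expect_identical(unname(map3[c("VH", "VL")]), c("h", "l"))
})

test_that("contact counting equals the brute-force all-pairs oracle and honors the count", {
  for (target in c(1, 5, 12)) {
    cx <- if (target == 5) FX_CX5 else make_complex(target_contacts = target)
    std <- if (target == 5) FX_STD else
      suppressMessages(standardize_entry(cx$model, fixture_engine(cx$truth)))
    rec <- Filter(function(r) !is.null(r$antigen), std$records)[[1]]
    expect_equal(rec$contact_count, target)
    # oracle: quadratic loop over CDR and antigen Calphas
    cdr_keys <- unlist(lapply(rec$antibody$domains, function(d) {
      nm <- d$number_map
      keep <- fvkit:::in_cdr_span(nm$martin_num, d$cdr_spans)
      residue_key(d$chain_id, nm$resno[keep], nm$insert[keep])
    }))
    ab_chains <- vapply(rec$antibody$domains, `[[`, "", "chain_id")
    oracle <- oracle_ca_contacts(cx$model, ab_chains, cdr_keys, "C", 7.5)
    expect_equal(rec$contact_count, oracle)
  }
})

test_that("antigens at or below the length threshold are excluded; antibody emitted free", {
  cx40 <- make_complex(target_contacts = 5, antigen_length = 40)
  std40 <- suppressMessages(
    standardize_entry(cx40$model, fixture_engine(cx40$truth)))
  expect_length(std40$records, 1)
  expect_null(std40$records[[1]]$antigen)
  # exactly 50 residues: "more than 50" is strict, still excluded
  cx50 <- make_complex(target_contacts = 5, antigen_length = 50)
  std50 <- suppressMessages(
    standardize_entry(cx50$model, fixture_engine(cx50$truth)))
  expect_null(std50$records[[1]]$antigen)
  # 51 residues qualify
  cx51 <- make_complex(target_contacts = 5, antigen_length = 51)
  std51 <- suppressMessages(
    standardize_entry(cx51$model, fixture_engine(cx51$truth)))
  expect_false(is.null(std51$records[[1]]$antigen))
})

test_that("an antigen beyond contact range leaves the antibody as a free record", {
  fv <- make_fv()
  ag <- structure_model(build_backbone(rep("GLY", 60), chain_id = "C"),
                        entry_id = "SYNT")
  ag <- transform_model(ag, translation = c(0, 0, 500))
  model <- fvkit:::merge_models(list(fv$model, ag), entry_id = "SYNT")
  std <- suppressMessages(standardize_entry(model, fixture_engine(fv$truth)))
  expect_length(std$records, 1)
  expect_null(std$records[[1]]$antigen)
  expect_length(std$files, 1)
  expect_setequal(chain_ids(std$files[[1]]), c("H", "L"))
})

test_that("crystallographic antigen copies give two single-antigen files", {
  cr <- make_complex(target_contacts = 5, crystal_copies = 2)
  std <- suppressMessages(standardize_entry(cr$model, fixture_engine(cr$truth)))
  expect_length(std$files, 2)
  expect_identical(names(std$files), c("SYNT_1", "SYNT_2"))
  ag_sets <- lapply(std$files, function(f) setdiff(chain_ids(f), c("H", "L")))
  expect_true(all(lengths(ag_sets) == 1))
  expect_false(identical(ag_sets[[1]], ag_sets[[2]]))
})

test_that("a biological antigen dimer is kept whole in both output files", {
  ol <- make_complex(target_contacts = 5, oligomer = TRUE)
  std <- suppressMessages(standardize_entry(ol$model, fixture_engine(ol$truth)))
  expect_length(std$files, 2)
  for (f in std$files)
    expect_setequal(setdiff(chain_ids(f), c("H", "L")), c("C", "F"))
})

test_that("antigen unit grouping is a partition of the antigen chains", {
  ol <- make_complex(target_contacts = 5, oligomer = TRUE)
  units <- classify_antigen_interfaces(ol$model, c("C", "F"))
  all_chains <- unlist(lapply(units, `[[`, "chains"))
  expect_setequal(all_chains, c("C", "F"))
  expect_equal(anyDuplicated(all_chains), 0)
  expect_true(units[[1]]$oligomeric)
  # single antigen chain: one monomer unit
  units1 <- classify_antigen_interfaces(FX_CX5$model, "C")
  expect_length(units1, 1)
  expect_false(units1[[1]]$oligomeric)
  # classifier failure falls back to monomer treatment
  expect_warning(
    units2 <- classify_antigen_interfaces(
      ol$model, c("C", "F"), classifier = function(...) stop("down")),
    "treating as crystallographic")
  expect_length(units2, 2)
})

test_that("every antibody unit appears in exactly one record and naming is deterministic", {
  cr <- make_complex(target_contacts = 5, crystal_copies = 2)
  std1 <- suppressMessages(standardize_entry(cr$model, fixture_engine(cr$truth)))
  std2 <- suppressMessages(standardize_entry(cr$model, fixture_engine(cr$truth)))
  expect_identical(names(std1$files), names(std2$files))
  expect_equal(length(std1$records), 2)   # one record per antibody unit
  kinds <- vapply(std1$records, function(r) r$antibody$kind, character(1))
  expect_true(all(kinds == "paired"))
})

test_that("entries with missing heavy atoms or unusual formats are rejected whole", {
  fv <- make_fv()
  m <- fv$model
  m$atoms <- m$atoms[!(m$atoms$chain == "A" & m$atoms$resno == 22 &
                         m$atoms$elety == "SG"), ]
  std <- suppressMessages(standardize_entry(m, fixture_engine(fv$truth)))
  expect_true(std$manifest$rejected)
  expect_match(std$manifest$reason, "missing heavy atoms")
  # double variable domain: rejected as unusual
  truth_dvd <- list(
    list(chain = "A", domain_type = "VH",
         positions = fvkit:::fixture_positions(102),
         sequence = paste(fvkit:::aa_three_to_one(fvkit:::vh_residues()),
                          collapse = "")),
    list(chain = "A", domain_type = "VH",
         positions = fvkit:::fixture_positions(102),
         sequence = paste(fvkit:::aa_three_to_one(fvkit:::vh_residues()),
                          collapse = "")))
  dvd_res <- c(fvkit:::vh_residues(), rep("GLY", 8), fvkit:::vh_residues())
  dvd <- structure_model(build_backbone(dvd_res, chain_id = "A"),
                         entry_id = "TEST")
  std2 <- suppressMessages(standardize_entry(dvd, fixture_engine(truth_dvd)))
  expect_true(std2$manifest$rejected)
  expect_match(std2$manifest$reason, "unusual")
  # exclusion list drops the entry before any processing
  std3 <- standardize_entry(fv$model, fixture_engine(fv$truth),
                            exclusion_list = "SYNT")
  expect_true(std3$manifest$rejected)
})

test_that("dataset profiling reproduces hand-computed percentages and means", {
  meta <- list(list(method = "xray", resolution = 2.0),
               list(method = "xray", resolution = 3.0),
               list(method = "xray", resolution = 4.5),
               list(method = "em", resolution = 3.5))
  p <- profile_dataset(meta, resolution_cutoff = 4.0)
  expect_equal(unname(p$method_percent["xray"]), 75)
  expect_equal(unname(p$method_percent["em"]), 25)
  expect_equal(p$method_mean_resolution$xray, mean(c(2, 3, 4.5)))
  expect_equal(p$fraction_below_cutoff, 3 / 4)
  # entries without resolution are excluded from resolution statistics
  meta2 <- c(meta, list(list(method = "nmr", resolution = NULL)))
  p2 <- profile_dataset(meta2, 4.0)
  expect_equal(p2$n_missing_resolution, 1)
  expect_equal(p2$fraction_below_cutoff, 3 / 4)
  # boundary: resolutions {2, 3} all below 4
  p3 <- profile_dataset(list(list(method = "xray", resolution = 2),
                             list(method = "xray", resolution = 3)), 4.0)
  expect_equal(p3$fraction_below_cutoff, 1.0)
})
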