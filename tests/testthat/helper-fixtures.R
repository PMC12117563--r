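# Shared fixtures (built once per test run) and independent brute-force
# oracles used by the scoring and geometry tests.

FX_CX5 <- make_complex(target_contacts = 5)
FX_ENG <- fixture_engine(FX_CX5$truth)
FX_STD <- suppressMessages(standardize_entry(FX_CX5$model, FX_ENG))
FX_REF <- FX_STD$files[[1]]
FX_HELIX <- make_ideal_secondary("helix", 12)

# quadratic all-pairs contact count (Calpha), the oracle for the fast path
oracle_ca_contacts <- function(model, chains_a, keys_a, chains_b, cutoff) {
  a <- model$atoms[model$atoms$elety == "CA" &
                     model$atoms$chain %in% chains_a, , drop = FALSE]
  if (!is.null(keys_a))
    a <- a[residue_key(a$chain, a$resno, a$insert) %in% keys_a, ,
           drop = FALSE]
  b <- model$atoms[model$atoms$elety == "CA" &
                     model$atoms$chain %in% chains_b, , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                     as.numeric(b[j, c("x", "y", "z")]))^2))
    if (d < cutoff) n <- n + 1L
  }
  n
}

# quadratic heavy-atom residue-pair contact oracle
oracle_residue_contacts <- function(model, chains_a, chains_b, cutoff) {
  a <- model$atoms[model$atoms$chain %in% chains_a, , drop = FALSE]
  b <- model$atoms[model$atoms$chain %in% chains_b, , drop = FALSE]
  pairs <- character()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                     as.numeric(b[j, c("x", "y", "z")]))^2))
    if (d < cutoff)
      pairs <- c(pairs, paste(residue_key(a$chain[i], a$resno[i],
                                          a$insert[i]),
                              residue_key(b$chain[j], b$resno[j],
                                          b$insert[j]), sep = "+"))
  }
  unique(pairs)
}

# refining orientation-grid search for the minimal superposition RMSD;
# independent of the closed-form solver it checks
oracle_superpose_rmsd <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  rmsd_of <- function(R) sqrt(mean(rowSums((a0 %*% t(R) - b0)^2)))
  axes <- sphere_points(80)
  best <- list(rmsd = Inf)
  for (i in seq_len(nrow(axes))) for (ang in seq(0, 2 * pi, length.out = 37)) {
    R <- rotation_axis_angle(axes[i, ], ang)
    r <- rmsd_of(R)
    if (r < best$rmsd) best <- list(rmsd = r, axis = axes[i, ], ang = ang)
  }
  span_ax <- 0.5; span_ang <- 0.2
  for (round in 1:8) {
    for (i in 1:60) {
      ax <- best$axis + span_ax * (sphere_points(60)[i, ])
      for (dang in seq(-span_ang, span_ang, length.out = 9)) {
        R <- rotation_axis_angle(ax, best$ang + dang)
        r <- rmsd_of(R)
        if (r < best$rmsd) best <- list(rmsd = r, axis = ax,
                                        ang = best$ang + dang)
      }
    }
    span_ax <- span_ax / 3; span_ang <- span_ang / 3
  }
  best$rmsd
}

# minimal mmCIF writer (test-only) mirroring the PDB content of a model
write_min_cif <- function(model, path, method = NULL, resolution = NULL) {
  a <- model$atoms
  lines <- c(paste0("data_", model$entry_id), "#")
  if (!is.null(method))
    lines <- c(lines, paste0("_exptl.method '", method, "'"))
  if (!is.null(resolution))
    lines <- c(lines, paste0("_refine.ls_d_res_high ", resolution))
  lines <- c(lines, "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
  for (i in seq_len(nrow(a))) {
    ins <- if (nzchar(a$insert[i])) a$insert[i] else "?"
    alt <- if (nzchar(a$alt[i])) a$alt[i] else "."
    ele <- if (nzchar(a$elesy[i])) a$elesy[i] else substr(a$elety[i], 1, 1)
    lines <- c(lines, paste(
      a$type[i], i, ele, a$elety[i], alt, a$resid[i], a$chain[i], 1,
      a$resno[i], ins, sprintf("%.3f", a$x[i]), sprintf("%.3f", a$y[i]),
      sprintf("%.3f", a$z[i]), sprintf("%.2f", a$o[i]),
      sprintf("%.2f", a$b[i]), "?", a$resno[i], a$resid[i], a$chain[i],
      a$elety[i], 1))
  }
  writeLines(c(lines, "#"), path)
  invisible(path)
}

# one-residue model helper for descriptor unit tests
single_atom_model <- function(x = 0, y = 0, z = 0, elety = "CA",
                              elesy = "C") {
  structure_model(data.frame(
    type = "ATOM", elety = elety, resid = "GLY", chain = "A", resno = 1L,
    x = x, y = y, z = z, elesy = elesy, stringsAsFactors = FALSE),
    entry_id = "TEST")
}
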