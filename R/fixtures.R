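# Deterministic generators of synthetic antibody-like structures.
# Chains are idealized poly-glycine backbones (with stub side chains where
# an operation needs them: CB for ALA, CB+SG for CYS) built from internal
# coordinates, so every construction is an exact, reproducible function of
# its arguments. Each generator returns machine-readable ground truth
# (domain types, Martin maps, CDR spans, applied transforms) that tests
# consume directly.

PEPTIDE_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180)

# CB from backbone N, CA, C with correct L-chirality (fixed linear
# combination of the local backbone frame).
place_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  ca - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
}

#' Build an idealized backbone chain from backbone dihedrals
#'
#' Grows N, CA, C, O atoms residue by residue from ideal bond lengths and
#' angles; CB is added for non-glycine residues and SG for cysteine.
#'
#' @param resids character vector of 3-letter residue names.
#' @param phi,psi backbone dihedrals in degrees, recycled to the chain
#'   length; `phi[1]` and the final `psi` only orient terminal atoms.
#' @param chain_id single-character chain identifier.
#' @param resno_start first residue number.
#' @return atom data.frame suitable for [structure_model()].
#' @export
build_backbone <- function(resids, phi = -57, psi = -47, chain_id = "A",
                           resno_start = 1L) {
  n_res <- length(resids)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  g <- PEPTIDE_GEOM
  N <- CA <- C <- vector("list", n_res)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)[-1]) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         g$c_n, g$ang_ca_c_n, psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          g$n_ca, g$ang_c_n_ca, g$omega)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         g$ca_c, g$ang_n_ca_c, phi[i])
  }
  rows <- list()
  add <- function(rows, elety, xyz, resid, resno, elesy) {
    rows[[length(rows) + 1]] <- data.frame(
      type = "ATOM", eleno = NA_integer_, elety = elety, alt = "",
      resid = resid, chain = chain_id, resno = resno, insert = "",
      x = xyz[1], y = xyz[2], z = xyz[3], o = 1, b = 0, elesy = elesy,
      stringsAsFactors = FALSE)
    rows
  }
  for (i in seq_len(n_res)) {
    resno <- resno_start + i - 1L
    O <- place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o,
                    psi[i] + 180)
    rows <- add(rows, "N", N[[i]], resids[i], resno, "N")
    rows <- add(rows, "CA", CA[[i]], resids[i], resno, "C")
    rows <- add(rows, "C", C[[i]], resids[i], resno, "C")
    rows <- add(rows, "O", O, resids[i], resno, "O")
    if (toupper(resids[i]) != "GLY") {
      CB <- place_cb(N[[i]], CA[[i]], C[[i]])
      rows <- add(rows, "CB", CB, resids[i], resno, "C")
      if (toupper(resids[i]) == "CYS") {
        SG <- place_atom(N[[i]], CA[[i]], CB, 1.81, 114.0, -60)
        rows <- add(rows, "SG", SG, resids[i], resno, "S")
      }
    }
  }
  do.call(rbind, rows)
}

#' Idealized secondary-structure fixture chain
#'
#' @param kind `"helix"` (phi, psi = -57, -47) or `"strand"`
#'   (-139, 135).
#' @param length number of residues (>= 6).
#' @param chain_id chain identifier.
#' @return a single-chain [structure_model] of glycines.
#' @export
make_ideal_secondary <- function(kind = c("helix", "strand"), length = 12,
                                 chain_id = "A") {
  kind <- match.arg(kind)
  if (length < 6) stop("length must be >= 6")
  tor <- if (kind == "helix") c(-57, -47) else c(-139, 135)
  atoms <- build_backbone(rep("GLY", length), phi = tor[1], psi = tor[2],
                          chain_id = chain_id)
  structure_model(atoms, entry_id = "SYNT")
}

#' Antiparallel two-strand sheet fixture
#'
#' Builds one ideal strand and places an antiparallel copy at
#' beta-sheet hydrogen-bonding geometry, chosen by scanning rigid offsets
#' for the placement that maximizes the number of backbone hydrogen bonds
#' under the Kabsch-Sander energy criterion. Deterministic.
#'
#' @param length residues per strand.
#' @return two-chain [structure_model] (chains A and B).
#' @export
make_strand_pair <- function(length = 8) {
  a <- build_backbone(rep("GLY", length), phi = -139, psi = 135,
                      chain_id = "A")
  b0 <- build_backbone(rep("GLY", length), phi = -139, psi = 135,
                       chain_id = "B")
  ma <- structure_model(a, entry_id = "SYNT")
  ca_a <- coords(ma, ma$atoms$elety == "CA")
  axis <- unitv(ca_a[length, ] - ca_a[1, ])
  mid <- colMeans(ca_a)
  best <- NULL
  rot <- rotation_axis_angle(c(0, 0, 1), pi)  # flip strand direction
  for (dy in seq(4.2, 5.6, by = 0.2)) {
    for (dx in seq(-3, 3, by = 0.5)) {
      for (dz in seq(-1, 1, by = 0.5)) {
        mb <- structure_model(b0, entry_id = "SYNT")
        cb <- coords(mb)
        cb <- sweep(cb, 2, colMeans(coords(mb, mb$atoms$elety == "CA")), "-")
        cb <- cb %*% t(rot)
        cb <- sweep(cb, 2, mid + c(dx, dy, dz) + axis * 0, "+")
        mb$atoms[, c("x", "y", "z")] <- cb
        pair <- merge_models(list(ma, mb))
        nb <- nrow(ks_hbonds(pair))
        if (is.null(best) || nb > best$n) best <- list(n = nb, model = pair)
      }
    }
  }
  best$model
}

# Synthetic variable-domain sequences. Mostly glycine with alanine/cysteine
# landmarks: the conserved cysteines sit at Martin H22/H92 (VH) and
# L23/L88 (VL); an alanine marks the conserved tryptophan position. The
# two sequences are mutually non-substring so a substring-matching
# numbering engine cannot confuse them.
VH_LENGTH <- 102L
VL_LENGTH <- 97L

vh_residues <- function() {
  r <- rep("GLY", VH_LENGTH)
  r[22] <- "CYS"; r[36] <- "ALA"; r[92] <- "CYS"
  r
}

vl_residues <- function() {
  r <- rep("GLY", VL_LENGTH)
  r[23] <- "CYS"; r[35] <- "ALA"; r[88] <- "CYS"
  r
}

# Martin-position table for a synthetic domain: identity numbering except
# for an optional inserted residue in CDR3 (Martin 100A).
fixture_positions <- function(n, cdr3_insertion = FALSE, insert_after = 100L) {
  if (!cdr3_insertion)
    return(data.frame(seq_idx = seq_len(n), martin_num = seq_len(n),
                      martin_ins = "", stringsAsFactors = FALSE))
  nums <- c(seq_len(insert_after), insert_after, seq(insert_after + 1, n - 1))
  ins <- c(rep("", insert_after), "A", rep("", n - 1 - insert_after))
  data.frame(seq_idx = seq_len(n), martin_num = nums, martin_ins = ins,
             stringsAsFactors = FALSE)
}

#' Synthetic Fv fixture: paired VH/VL chains with known geometry
#'
#' Builds helical VH and VL chains carrying conserved cysteines at Martin
#' H92 and L88, placed so the Calpha distance between those cysteines
#' equals `fv_separation` exactly. Optionally appends an unnumbered
#' constant-region tail, emits the two domains on a single chain (scFv
#' with a glycine linker), or inserts a CDR3 residue (Martin 100A).
#'
#' @param fv_separation target Cys92(VH)-Cys88(VL) Calpha distance in
#'   Angstrom.
#' @param n_fv number of Fv copies (copies are translated 150 A apart).
#' @param constant_tail residues of constant region appended to each chain
#'   (absent from the Martin map).
#' @param scfv emit VH+linker+VL as one chain.
#' @param cdr3_insertion add one VH CDR3 insertion (Martin 100A).
#' @param entry_id 4-character entry code.
#' @return list with `model` (a [structure_model]) and `truth`: per-chain
#'   domain annotations (`chain`, `domain_type`, `positions`, sequence)
#'   usable to build a [table_numbering_engine()].
#' @export
make_fv <- function(fv_separation = 16, n_fv = 1, constant_tail = 0,
                    scfv = FALSE, cdr3_insertion = FALSE,
                    entry_id = "SYNT") {
  if (fv_separation <= 0) stop("fv_separation must be positive")
  chain_pool_h <- c("A", "D", "G", "J", "M")
  chain_pool_l <- c("B", "E", "K", "N", "Q")
  models <- list()
  truth <- list()
  for (k in seq_len(n_fv)) {
    offset <- c(150 * (k - 1), 0, 0)
    vh_res <- vh_residues()
    if (cdr3_insertion) vh_res <- append(vh_res, "GLY", after = 100)
    vl_res <- vl_residues()
    if (scfv) {
      ch <- chain_pool_h[k]
      linker <- rep("GLY", 8)
      all_res <- c(vh_res, linker, vl_res)
      atoms <- build_backbone(all_res, chain_id = ch)
      m <- structure_model(atoms, entry_id = entry_id)
      m <- transform_model(m, translation = offset)
      models[[length(models) + 1]] <- m
      nh <- length(vh_res)
      pos_h <- fixture_positions(nh, cdr3_insertion)
      pos_l <- fixture_positions(length(vl_res))
      pos_l$seq_idx <- pos_l$seq_idx + nh + length(linker)
      truth[[length(truth) + 1]] <- list(
        chain = ch, domain_type = "VH", positions = pos_h,
        sequence = paste(aa_three_to_one(vh_res), collapse = ""))
      truth[[length(truth) + 1]] <- list(
        chain = ch, domain_type = "VL", positions = pos_l,
        sequence = paste(aa_three_to_one(vl_res), collapse = ""))
    } else {
      ch_h <- chain_pool_h[k]
      ch_l <- chain_pool_l[k]
      vh_all <- c(vh_res, rep("GLY", constant_tail))
      vl_all <- c(vl_res, rep("GLY", constant_tail))
      ah <- build_backbone(vh_all, chain_id = ch_h)
      al <- build_backbone(vl_all, chain_id = ch_l)
      mh <- structure_model(ah, entry_id = entry_id)
      ml <- structure_model(al, entry_id = entry_id)
      # translate VL so the conserved-cysteine Calpha distance is exact
      cys_h_idx <- if (cdr3_insertion) 92L else 92L
      ca_h <- coords(mh, mh$atoms$elety == "CA" & mh$atoms$resno == cys_h_idx)
      ca_l <- coords(ml, ml$atoms$elety == "CA" & ml$atoms$resno == 88L)
      shift <- as.numeric(ca_h[1, ] + c(0, fv_separation, 0) - ca_l[1, ])
      ml <- transform_model(ml, translation = shift)
      mh <- transform_model(mh, translation = offset)
      ml <- transform_model(ml, translation = offset)
      models <- c(models, list(mh, ml))
      truth[[length(truth) + 1]] <- list(
        chain = ch_h, domain_type = "VH",
        positions = fixture_positions(length(vh_res), cdr3_insertion),
        sequence = paste(aa_three_to_one(vh_res), collapse = ""))
      truth[[length(truth) + 1]] <- list(
        chain = ch_l, domain_type = "VL",
        positions = fixture_positions(length(vl_res)),
        sequence = paste(aa_three_to_one(vl_res), collapse = ""))
    }
  }
  list(model = merge_models(models, entry_id = entry_id), truth = truth)
}

#' Synthetic antibody-antigen complex with an exact CDR contact count
#'
#' Starts from [make_fv()] and adds a helical glycine antigen approached
#' end-on toward the VH CDR3 so that exactly `target_contacts`
#' (CDR residue, antigen residue) Calpha pairs fall below the 7.5 A
#' contact cutoff. The approach distance is found by a deterministic scan;
#' an unreachable count is an error. Optional second antigen chain forms
#' either a large ("biological") or tiny ("crystallographic") interface
#' with the first; optional full crystal copy duplicates antibody and
#' antigen far away.
#'
#' @param target_contacts desired number of sub-cutoff CDR-antigen Calpha
#'   pairs.
#' @param antigen_length antigen residues per chain.
#' @param contact_cutoff contact definition used for the placement scan.
#' @param oligomer add a second antigen chain packed against the first
#'   (biological-interface geometry).
#' @param crystal_copies total copies of the antibody(+antigen) unit; extra
#'   copies are placed far apart with only a marginal antigen-antigen
#'   touch, mimicking a crystal-packing contact.
#' @param fv_separation passed to [make_fv()].
#' @param entry_id 4-character entry code.
#' @return list with `model`, `truth` (as [make_fv()], plus
#'   `antigen_chains` and `target_contacts`).
#' @export
make_complex <- function(target_contacts = 5, antigen_length = 60,
                         contact_cutoff = 7.5, oligomer = FALSE,
                         crystal_copies = 1, fv_separation = 16,
                         entry_id = "SYNT") {
  if (crystal_copies > 2 || (oligomer && crystal_copies > 1))
    stop("supported fixture layouts: oligomer dimer, or up to 2 crystal copies")
  fv <- make_fv(fv_separation = fv_separation, entry_id = entry_id)
  model <- fv$model
  truth <- fv$truth
  vh_chain <- truth[[1]]$chain

  cdr_ca <- fixture_cdr_ca(model, truth)
  ag_atoms <- build_backbone(rep("GLY", antigen_length), chain_id = "C")
  ag <- structure_model(ag_atoms, entry_id = entry_id)
  ag_ca <- coords(ag, ag$atoms$elety == "CA")

  # approach direction: perpendicular to the VH helix axis at CDR3
  anchor <- cdr_ca[nrow(cdr_ca), ]
  dirv <- c(0, 0, 1)
  # orient antigen helix along its own first axis toward -dirv so its
  # N-terminus leads the approach
  ag_axis <- unitv(ag_ca[nrow(ag_ca), ] - ag_ca[1, ])
  rot <- rotation_between(ag_axis, dirv)
  ag <- transform_model(ag, rotation = rot,
                        translation = c(0, 0, 0))
  ag_ca1 <- coords(ag, ag$atoms$elety == "CA")[1, ]

  found <- NULL
  for (d in seq(30, 2, by = -0.05)) {
    shift <- anchor + dirv * d - ag_ca1
    trial <- transform_model(ag, translation = shift)
    n <- sum(cdist(cdr_ca, coords(trial, trial$atoms$elety == "CA")) <
               contact_cutoff)
    if (n == target_contacts) { found <- trial; break }
    if (n > target_contacts) break
  }
  if (is.null(found))
    stop("unreachable contact count: ", target_contacts)
  model <- merge_models(list(model, found), entry_id = entry_id)
  antigen_chains <- "C"

  if (oligomer) {
    # second copy of the whole antibody-antigen unit, rotated half a turn
    # about the axis midway between the two antigen helices: the antigen
    # copies pack side by side into a tightly packed dimer (biological
    # interface), each bound by its own antibody on opposite faces
    ax <- helix_axis(found)
    perp <- unitv(cross3(ax, c(1, 0, 0)))
    dimer_sep <- 7.0
    mid <- colMeans(coords(found)) + perp * (dimer_sep / 2)
    copy <- model
    ch_map <- c(A = "D", B = "E", C = "F")
    copy$atoms$chain <- unname(ch_map[copy$atoms$chain])
    R <- rotation_axis_angle(ax, pi)
    xyz <- coords(copy)
    xyz <- sweep(xyz, 2, mid, "-") %*% t(R)
    xyz <- sweep(xyz, 2, mid, "+")
    copy$atoms[, c("x", "y", "z")] <- xyz
    for (tt in truth) {
      if (!is.list(tt) || is.null(tt$domain_type)) next
      tt$chain <- ch_map[[tt$chain]]
      truth[[length(truth) + 1]] <- tt
    }
    model <- merge_models(list(model, copy), entry_id = entry_id)
    antigen_chains <- c("C", "F")
  }

  if (crystal_copies > 1) {
    # second copy of the whole unit flipped head-over-heels about the far
    # end of the antigen: the two antigens just touch end to end (a
    # marginal crystal-packing patch) while the antibodies sit at
    # opposite extremes, each at its own antigen
    ax <- helix_axis(found)
    ag_xyz <- coords(found)
    proj <- as.numeric(ag_xyz %*% ax)
    top <- colMeans(ag_xyz[proj > max(proj) - 3, , drop = FALSE])
    gap <- 4.5
    pivot <- top + ax * (gap / 2)
    perp <- unitv(cross3(ax, c(1, 0, 0)))
    R <- rotation_axis_angle(perp, pi)
    copy <- model
    ch_map <- c(A = "D", B = "E", C = "G")
    copy$atoms$chain <- unname(ch_map[copy$atoms$chain])
    xyz <- coords(copy)
    xyz <- sweep(sweep(xyz, 2, pivot, "-") %*% t(R), 2, pivot, "+")
    copy$atoms[, c("x", "y", "z")] <- xyz
    for (tt in truth) {
      if (!is.list(tt) || is.null(tt$domain_type)) next
      tt$chain <- ch_map[[tt$chain]]
      truth[[length(truth) + 1]] <- tt
    }
    model <- merge_models(list(model, copy), entry_id = entry_id)
    antigen_chains <- c(antigen_chains, ch_map[["C"]])
  }

  list(model = model,
       truth = c(truth, list(antigen_chains = antigen_chains,
                             target_contacts = target_contacts)))
}

helix_axis <- function(model) {
  ca <- coords(model, model$atoms$elety == "CA")
  unitv(ca[nrow(ca), ] - ca[1, ])
}

# Rotation carrying unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b)
  s <- vnorm(v)
  if (s < 1e-9) {
    if (sum(a * b) > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_axis_angle(perp, pi))
  }
  rotation_axis_angle(v, atan2(s, sum(a * b)))
}

# Calpha coordinates of all CDR residues of the fixture antibody, using
# the ground-truth Martin maps and the default CDR spans.
fixture_cdr_ca <- function(model, truth) {
  out <- NULL
  for (tt in truth) {
    if (!is.list(tt) || is.null(tt$domain_type)) next
    spans <- default_cdr_spans(tt$domain_type)
    cdr_nums <- unlist(lapply(spans, function(s) seq(s[1], s[2])))
    resnos <- tt$positions$seq_idx[tt$positions$martin_num %in% cdr_nums]
    sel <- model$atoms$chain == tt$chain & model$atoms$elety == "CA" &
      model$atoms$resno %in% resnos
    out <- rbind(out, coords(model, sel))
  }
  out
}

#' Rigid-body perturbed docking pose from a reference complex
#'
#' Applies a rigid transform to the antibody (ligand) chains of a
#' reference complex, leaving the antigen (receptor) untouched, and
#' returns the exact transform for closed-form checks.
#'
#' @param reference a complex [structure_model].
#' @param ligand_chains chains to move (the antibody).
#' @param translation 3-vector, Angstrom.
#' @param axis,angle optional rotation (axis 3-vector, angle radians)
#'   about the ligand centroid, applied before the translation.
#' @return list with `model`, `rotation`, `translation`.
#' @export
make_pose <- function(reference, ligand_chains, translation = c(0, 0, 0),
                      axis = c(0, 0, 1), angle = 0) {
  sel <- reference$atoms$chain %in% ligand_chains
  cen <- colMeans(coords(reference, sel))
  R <- rotation_axis_angle(axis, angle)
  xyz <- coords(reference, sel)
  xyz <- sweep(xyz, 2, cen, "-") %*% t(R)
  xyz <- sweep(xyz, 2, cen + translation, "+")
  pose <- reference
  pose$atoms[sel, c("x", "y", "z")] <- xyz
  list(model = pose, rotation = R, translation = translation)
}

#' Buried-atom shell fixture
#'
#' A single central atom enclosed by a tight spherical shell of dummy
#' atoms: the canonical burial fixture for SASA, depth and
#' surface-exposure tests.
#'
#' @param shell_radius shell radius in Angstrom.
#' @param n_shell number of shell atoms.
#' @return a [structure_model] whose residue 1 (chain S) is the buried
#'   atom and residues 2.. are the shell.
#' @export
make_shell <- function(shell_radius = 3.5, n_shell = 80) {
  pts <- sphere_points(n_shell) * shell_radius
  rows <- data.frame(
    type = "ATOM", eleno = NA_integer_,
    elety = "CA", alt = "",
    resid = "GLY", chain = "S",
    resno = c(1L, seq_len(n_shell) + 1L), insert = "",
    x = c(0, pts[, 1]), y = c(0, pts[, 2]), z = c(0, pts[, 3]),
    o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
  structure_model(rows, entry_id = "SHEL")
}

#' Numbering engine backed by the ground truth of a fixture
#'
#' Convenience wrapper building a [table_numbering_engine()] from the
#' `truth` element returned by [make_fv()] / [make_complex()].
#'
#' @param truth ground-truth list from a fixture generator.
#' @return a numbering engine function.
#' @export
fixture_engine <- function(truth) {
  entries <- list()
  seen <- character()
  for (tt in truth) {
    if (!is.list(tt) || is.null(tt$domain_type)) next
    id <- paste(tt$domain_type, tt$sequence)
    if (id %in% seen) next   # identical domains on crystal copies
    seen <- c(seen, id)
    pos <- tt$positions
    pos$seq_idx <- pos$seq_idx - min(pos$seq_idx) + 1L
    entries[[length(entries) + 1]] <- list(
      sequence = tt$sequence, domain_type = tt$domain_type, positions = pos)
  }
  table_numbering_engine(entries)
}
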