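# Per-residue molecular descriptor suite: relative solvent accessibility,
# residue depth, protrusion index, half-sphere exposure, backbone
# dihedrals, 3-state secondary structure, hydrophobicity and Calpha
# coordinates, assembled into one CSV row per residue.

# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5)

#' Hydrophobicity of a residue type
#'
#' @param res_name 3-letter residue name (vectorised).
#' @param scale named lookup vector; default Kyte-Doolittle.
#' @return scale value, `NA` for unknown residues.
#' @export
hydrophobicity <- function(res_name, scale = KYTE_DOOLITTLE) {
  unname(scale[toupper(res_name)])
}

#' Residue depth below the accessible surface
#'
#' Depth of a residue is the mean, over its heavy atoms, of the distance
#' from the atom centre to the nearest solvent-accessible surface dot,
#' minus the probe radius (so a fully exposed atom has depth about its
#' vdW radius, and deeper atoms grow from there). A single-atom model has
#' depth 0 by convention.
#'
#' @param model a [structure_model].
#' @param probe_radius,n_sphere_points passed to [sasa()].
#' @return data.frame `key`, `depth` (A), one row per residue.
#' @export
residue_depth <- function(model, probe_radius = 1.4, n_sphere_points = 240) {
  rt <- residue_table(model)
  if (sum(!is_hydrogen(model$atoms)) == 1)
    return(data.frame(key = rt$key, depth = 0, stringsAsFactors = FALSE))
  s <- sasa(model, probe_radius, n_sphere_points, return_dots = TRUE)
  if (is.null(s$dots) || nrow(s$dots) == 0)
    stop("no accessible surface dots; cannot compute depth")
  heavy <- !is_hydrogen(model$atoms)
  a <- model$atoms[heavy, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  mind <- rep(NA_real_, nrow(xyz))
  chunk <- 4000L
  for (start in seq(1, nrow(s$dots), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(s$dots))
    d <- cdist(xyz, s$dots[idx, , drop = FALSE])
    m <- d[cbind(seq_len(nrow(d)), max.col(-d, ties.method = "first"))]
    mind <- pmin(mind, m, na.rm = TRUE)
  }
  depth_atom <- pmax(mind - probe_radius, 0)
  key <- residue_key(a$chain, a$resno, a$insert)
  d <- tapply(depth_atom, factor(key, levels = rt$key), mean)
  data.frame(key = rt$key, depth = as.numeric(d), stringsAsFactors = FALSE)
}

#' Protrusion index (CX)
#'
#' For each heavy atom, the volume inside a sphere of radius
#' `sphere_radius` occupied by atoms is estimated as
#' `count * mean_atom_volume`; CX is the ratio of unoccupied to occupied
#' volume, capped at `cx_cap`. The residue value is the mean over its
#' atoms.
#'
#' @param model a [structure_model].
#' @param sphere_radius neighbourhood radius, A.
#' @param mean_atom_volume assumed volume per heavy atom, A^3.
#' @param cx_cap reported maximum (isolated atoms hit the cap).
#' @return data.frame `key`, `cx`.
#' @export
protrusion_index <- function(model, sphere_radius = 10,
                             mean_atom_volume = 20.1, cx_cap = 15) {
  heavy <- !is_hydrogen(model$atoms)
  a <- model$atoms[heavy, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d2 <- cdist2(xyz, xyz)
  count <- rowSums(d2 <= sphere_radius^2)   # includes the atom itself
  v_sphere <- 4 / 3 * pi * sphere_radius^3
  v_int <- count * mean_atom_volume
  cx <- pmin((v_sphere - v_int) / v_int, cx_cap)
  cx <- pmax(cx, 0)
  key <- residue_key(a$chain, a$resno, a$insert)
  rt <- residue_table(model)
  res_cx <- tapply(cx, factor(key, levels = rt$key), mean)
  data.frame(key = rt$key, cx = as.numeric(res_cx), stringsAsFactors = FALSE)
}

#' Half-sphere exposure
#'
#' Counts Calpha neighbours of each residue within `radius`, split by the
#' plane normal to the Calpha-Cbeta vector: `hse_up` counts the Cbeta
#' side. A real Cbeta is used when present, otherwise a pseudo-Cbeta is
#' constructed from the backbone; residues without a Calpha (or without
#' the backbone needed for a pseudo-Cbeta) get `NA`.
#'
#' @param model a [structure_model].
#' @param chain chain to annotate; neighbours are taken from that chain.
#' @param radius sphere radius, A.
#' @return data.frame `key`, `hse_up`, `hse_down`.
#' @export
half_sphere_exposure <- function(model, chain, radius = 13) {
  rt <- residue_table(model, chain)
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  key_atoms <- residue_key(a$chain, a$resno, a$insert)
  getxyz <- function(k, nm) {
    i <- which(key_atoms == k & a$elety == nm)
    if (length(i) == 0) return(NULL)
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  ca_list <- lapply(rt$key, getxyz, nm = "CA")
  have_ca <- !vapply(ca_list, is.null, logical(1))
  ca_mat <- matrix(NA_real_, nrow(rt), 3)
  ca_mat[have_ca, ] <- t(vapply(ca_list[have_ca], identity, numeric(3)))
  up <- down <- rep(NA_integer_, nrow(rt))
  for (i in seq_len(nrow(rt))) {
    if (!have_ca[i]) next
    ca <- ca_list[[i]]
    cb <- getxyz(rt$key[i], "CB")
    if (is.null(cb)) {
      n <- getxyz(rt$key[i], "N")
      c_ <- getxyz(rt$key[i], "C")
      if (is.null(n) || is.null(c_)) next
      cb <- place_cb(n, ca, c_)
    }
    dirv <- cb - ca
    if (vnorm(dirv) < 1e-6) next
    dirv <- unitv(dirv)
    rel <- sweep(ca_mat, 2, ca)
    within <- have_ca & sqrt(rowSums(rel^2)) <= radius
    within[i] <- FALSE
    side <- as.numeric(rel %*% dirv) > 0
    up[i] <- sum(within & side, na.rm = TRUE)
    down[i] <- sum(within & !side, na.rm = TRUE)
  }
  data.frame(key = rt$key, hse_up = up, hse_down = down,
             stringsAsFactors = FALSE)
}

#' Backbone dihedral angles
#'
#' phi and psi in degrees, IUPAC sign convention. Angles are absent (`NA`)
#' at chain termini and across chain breaks (peptide C-N distance
#' > `break_cutoff`).
#'
#' @param model a [structure_model].
#' @param chain chain identifier.
#' @param break_cutoff maximum peptide-bond C-N distance, A.
#' @return data.frame `key`, `phi`, `psi`.
#' @export
dihedrals <- function(model, chain, break_cutoff = 2.5) {
  rt <- residue_table(model, chain)
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  key_atoms <- residue_key(a$chain, a$resno, a$insert)
  getxyz <- function(k, nm) {
    i <- which(key_atoms == k & a$elety == nm)
    if (length(i) == 0) return(NULL)
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  n_res <- nrow(rt)
  N <- lapply(rt$key, getxyz, nm = "N")
  CA <- lapply(rt$key, getxyz, nm = "CA")
  C <- lapply(rt$key, getxyz, nm = "C")
  linked <- rep(FALSE, max(n_res - 1, 0))   # peptide bond i -> i+1 intact
  for (i in seq_len(max(n_res - 1, 0))) {
    if (!is.null(C[[i]]) && !is.null(N[[i + 1]]))
      linked[i] <- vnorm(N[[i + 1]] - C[[i]]) <= break_cutoff
  }
  phi <- psi <- rep(NA_real_, n_res)
  for (i in seq_len(n_res)) {
    ok_here <- !is.null(N[[i]]) && !is.null(CA[[i]]) && !is.null(C[[i]])
    if (!ok_here) next
    if (i > 1 && linked[i - 1] && !is.null(C[[i - 1]]))
      phi[i] <- dihedral_angle(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
    if (i < n_res && linked[i] && !is.null(N[[i + 1]]))
      psi[i] <- dihedral_angle(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
  }
  data.frame(key = rt$key, phi = phi, psi = psi, stringsAsFactors = FALSE)
}

# Backbone hydrogen bonds under the Kabsch-Sander electrostatic model.
# The amide hydrogen is reconstructed from the previous residue's peptide
# unit (H along the C=O direction); chain-leading residues have no donor.
# Returns one row per bond: donor residue key (N-H), acceptor key (C=O).
ks_hbonds <- function(model, energy_cutoff = -0.5) {
  rt <- residue_table(model)
  a <- model$atoms
  key_atoms <- residue_key(a$chain, a$resno, a$insert)
  getxyz <- function(k, nm) {
    i <- which(key_atoms == k & a$elety == nm)
    if (length(i) == 0) return(NULL)
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  n <- nrow(rt)
  N <- lapply(rt$key, getxyz, nm = "N")
  C <- lapply(rt$key, getxyz, nm = "C")
  O <- lapply(rt$key, getxyz, nm = "O")
  H <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1 || rt$chain[i] != rt$chain[i - 1]) next
    if (is.null(N[[i]]) || is.null(C[[i - 1]]) || is.null(O[[i - 1]])) next
    if (vnorm(N[[i]] - C[[i - 1]]) > 2.5) next
    H[[i]] <- N[[i]] + unitv(C[[i - 1]] - O[[i - 1]]) * 1.0
  }
  q <- 0.084 * 332
  as_mat <- function(lst) t(vapply(lst, function(v)
    if (is.null(v)) c(NA_real_, NA_real_, NA_real_) else v, numeric(3)))
  Nm <- as_mat(N); Cm <- as_mat(C); Om <- as_mat(O); Hm <- as_mat(H)
  don_ok <- !is.na(Hm[, 1]) & !is.na(Nm[, 1])
  acc_ok <- !is.na(Cm[, 1]) & !is.na(Om[, 1])
  if (!any(don_ok) || !any(acc_ok))
    return(data.frame(donor = character(), acceptor = character(),
                      energy = numeric(), stringsAsFactors = FALSE))
  d_on <- cdist(Nm[don_ok, , drop = FALSE], Om[acc_ok, , drop = FALSE])
  cand <- which(d_on < 5.2, arr.ind = TRUE)   # plausible H-bond range
  di <- which(don_ok)[cand[, 1]]
  ai <- which(acc_ok)[cand[, 2]]
  keep <- di != ai & !(rt$chain[di] == rt$chain[ai] & abs(di - ai) < 2)
  di <- di[keep]; ai <- ai[keep]
  if (length(di) == 0)
    return(data.frame(donor = character(), acceptor = character(),
                      energy = numeric(), stringsAsFactors = FALSE))
  rowd <- function(a, b) sqrt(rowSums((a - b)^2))
  e <- q * (1 / rowd(Om[ai, , drop = FALSE], Nm[di, , drop = FALSE]) +
              1 / rowd(Cm[ai, , drop = FALSE], Hm[di, , drop = FALSE]) -
              1 / rowd(Om[ai, , drop = FALSE], Hm[di, , drop = FALSE]) -
              1 / rowd(Cm[ai, , drop = FALSE], Nm[di, , drop = FALSE]))
  sel <- e < energy_cutoff
  data.frame(donor = rt$key[di[sel]], acceptor = rt$key[ai[sel]],
             energy = e[sel], stringsAsFactors = FALSE)
}

#' 3-state secondary structure (helix / strand / coil)
#'
#' Hydrogen bonds are assigned with the Kabsch-Sander electrostatic
#' energy (bond when E < -0.5 kcal/mol); runs of i -> i+4 turns produce
#' H, parallel or antiparallel bridge patterns produce E, everything else
#' (including residues lacking a carbonyl O) is C. H wins over E.
#'
#' @param model a [structure_model] (all chains considered, so
#'   inter-chain sheets are detected).
#' @return data.frame `key`, `ss` with values `"H"`, `"E"`, `"C"`.
#' @export
secondary_structure <- function(model) {
  rt <- residue_table(model)
  n <- nrow(rt)
  bonds <- ks_hbonds(model)
  # hb[d, a]: N-H of residue d donates to C=O of residue a
  hb <- matrix(FALSE, n, n)
  if (nrow(bonds) > 0) {
    di <- match(bonds$donor, rt$key)
    ai <- match(bonds$acceptor, rt$key)
    hb[cbind(di, ai)] <- TRUE
  }
  same_chain_offset <- function(i, k) {
    j <- i + k
    if (j < 1 || j > n) return(NA_integer_)
    if (rt$chain[j] != rt$chain[i]) return(NA_integer_)
    j
  }
  turn4 <- rep(FALSE, n)   # CO(i) accepts from NH(i+4)
  for (i in seq_len(n)) {
    j <- same_chain_offset(i, 4L)
    if (!is.na(j) && hb[j, i]) turn4[i] <- TRUE
  }
  ss <- rep("C", n)
  for (i in seq_len(n - 1)) {
    if (turn4[i] && i + 1 <= n && turn4[i + 1]) {
      for (k in 1:4) {
        j <- same_chain_offset(i, k)
        if (!is.na(j)) ss[j] <- "H"
      }
    }
  }
  # bridge patterns, vectorised over the residue-pair matrix
  prev_i <- vapply(seq_len(n), same_chain_offset, integer(1), k = -1L)
  next_i <- vapply(seq_len(n), same_chain_offset, integer(1), k = 1L)
  rowshift <- function(m, idx) {
    out <- matrix(FALSE, n, n)
    ok <- !is.na(idx)
    out[ok, ] <- m[idx[ok], , drop = FALSE]
    out
  }
  colshift <- function(m, idx) t(rowshift(t(m), idx))
  t1 <- rowshift(hb, prev_i) & rowshift(t(hb), next_i)
  par <- t1 | t(t1)
  d1 <- colshift(rowshift(hb, prev_i), next_i)
  anti <- (hb & t(hb)) | (d1 & t(d1))
  bridge <- par | anti
  same <- outer(rt$chain, rt$chain, "==")
  near <- abs(outer(seq_len(n), seq_len(n), "-")) < 3
  bridge[same & near] <- FALSE
  is_e <- rowSums(bridge) > 0
  ss[is_e & ss == "C"] <- "E"
  data.frame(key = rt$key, ss = ss, stringsAsFactors = FALSE)
}

#' Full per-residue descriptor table for one structure
#'
#' Computes the complete descriptor suite in the context of the whole
#' model (a complex buries its interface) or, with `isolate_chains`, on an
#' extracted chain subset.
#'
#' @param model a [structure_model].
#' @param isolate_chains optional chain subset computed in isolation.
#' @param probe_radius,n_sphere_points surface sampling (see [sasa()]).
#' @param hse_radius half-sphere exposure radius, A.
#' @param cx_radius,cx_volume,cx_cap protrusion-index parameters.
#' @param hydro_scale hydrophobicity lookup.
#' @return data.frame, one row per residue, with columns `chain`,
#'   `resno`, `insert`, `res_name`, `rel_sasa`, `depth`, `protrusion`,
#'   `hydrophobicity`, `hse_up`, `hse_down`, `ca_x`, `ca_y`, `ca_z`,
#'   `phi`, `psi`, `sec_struct`.
#' @export
residue_descriptors <- function(model, isolate_chains = NULL,
                                probe_radius = 1.4, n_sphere_points = 960,
                                hse_radius = 13, cx_radius = 10,
                                cx_volume = 20.1, cx_cap = 15,
                                hydro_scale = KYTE_DOOLITTLE) {
  if (!is.null(isolate_chains)) model <- subset_chains(model, isolate_chains)
  rt <- residue_table(model)
  s <- sasa(model, probe_radius, n_sphere_points)
  rel <- relative_sasa(s$residue$area, s$residue$resid)
  names(rel) <- s$residue$key
  dep <- residue_depth(model, probe_radius,
                       n_sphere_points = min(n_sphere_points, 240))
  cx <- protrusion_index(model, cx_radius, cx_volume, cx_cap)
  ss <- secondary_structure(model)
  rows <- NULL
  for (ch in chain_ids(model)) {
    hse <- half_sphere_exposure(model, ch, hse_radius)
    dih <- dihedrals(model, ch)
    rtc <- residue_table(model, ch)
    a <- model$atoms[model$atoms$chain == ch, , drop = FALSE]
    ka <- residue_key(a$chain, a$resno, a$insert)
    ca_xyz <- t(vapply(rtc$key, function(k) {
      i <- which(ka == k & a$elety == "CA")
      if (length(i) == 0) return(c(NA_real_, NA_real_, NA_real_))
      as.numeric(a[i[1], c("x", "y", "z")])
    }, numeric(3)))
    rows <- rbind(rows, data.frame(
      chain = rtc$chain, resno = rtc$resno, insert = rtc$insert,
      res_name = rtc$resid,
      rel_sasa = unname(rel[rtc$key]),
      depth = dep$depth[match(rtc$key, dep$key)],
      protrusion = cx$cx[match(rtc$key, cx$key)],
      hydrophobicity = hydrophobicity(rtc$resid, hydro_scale),
      hse_up = hse$hse_up[match(rtc$key, hse$key)],
      hse_down = hse$hse_down[match(rtc$key, hse$key)],
      ca_x = ca_xyz[, 1], ca_y = ca_xyz[, 2], ca_z = ca_xyz[, 3],
      phi = dih$phi[match(rtc$key, dih$key)],
      psi = dih$psi[match(rtc$key, dih$key)],
      sec_struct = ss$ss[match(rtc$key, ss$key)],
      stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}

DESCRIPTOR_COLUMNS <- c("chain", "resno", "insert", "res_name", "rel_sasa",
                        "depth", "protrusion", "hydrophobicity", "hse_up",
                        "hse_down", "ca_x", "ca_y", "ca_z", "phi", "psi",
                        "sec_struct")

#' Write a descriptor table as CSV
#'
#' Fixed header order, one row per residue in chain/sequence order,
#' absent values as empty fields.
#'
#' @param rows data.frame from [residue_descriptors()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_descriptor_table <- function(rows, path) {
  missing_cols <- setdiff(DESCRIPTOR_COLUMNS, names(rows))
  if (length(missing_cols) > 0)
    stop("descriptor table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(rows[, DESCRIPTOR_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
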