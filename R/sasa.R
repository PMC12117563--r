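# Solvent-accessible surface area by the Shrake-Rupley method: each
# heavy atom's sphere (vdW radius + probe) is sampled with a fixed
# deterministic point set; points inside any neighbouring sphere are
# buried. Areas are exact functions of the point count, so every
# downstream quantity is reproducible.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)
VDW_DEFAULT <- 1.80

atom_radii <- function(model) {
  ele <- toupper(model$atoms$elesy)
  blank <- !nzchar(ele)
  ele[blank] <- vapply(model$atoms$elety[blank], guess_element, character(1))
  r <- VDW_RADII[ele]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# Tien et al. (2013) theoretical maximum accessible areas (A^2), the
# reference set for relative SASA.
MAX_SASA_TIEN <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param model a [structure_model]; hydrogens, if present, are ignored.
#' @param probe_radius probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points sample points per atom; area resolution is
#'   `4*pi*R^2 / n`.
#' @param return_dots also return the accessible surface dot coordinates
#'   (used by the residue-depth descriptor).
#' @return list with `atom_area` (per retained heavy atom, A^2),
#'   `residue` (data.frame `key`, `chain`, `resno`, `insert`, `resid`,
#'   `area`), and optionally `dots`.
#' @export
sasa <- function(model, probe_radius = 1.4, n_sphere_points = 960,
                 return_dots = FALSE) {
  heavy <- !is_hydrogen(model$atoms)
  a <- model$atoms[heavy, , drop = FALSE]
  if (nrow(a) == 0) stop("no heavy atoms in model")
  sub <- model
  sub$atoms <- a
  xyz <- coords(sub)
  radii <- atom_radii(sub) + probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  atom_area <- numeric(n)
  dots <- if (return_dots) vector("list", n) else NULL
  d2 <- cdist2(xyz, xyz)
  for (i in seq_len(n)) {
    cand <- which(d2[i, ] < (radii[i] + radii)^2)
    cand <- cand[cand != i]
    p <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    if (length(cand) > 0) {
      pd2 <- cdist2(p, xyz[cand, , drop = FALSE])
      acc <- rowSums(pd2 < matrix(radii[cand]^2, n_sphere_points,
                                  length(cand), byrow = TRUE)) == 0
    }
    atom_area[i] <- 4 * pi * radii[i]^2 * mean(acc)
    if (return_dots) dots[[i]] <- p[acc, , drop = FALSE]
  }
  key <- residue_key(a$chain, a$resno, a$insert)
  rt <- residue_table(sub)
  res_area <- tapply(atom_area, factor(key, levels = rt$key), sum)
  rt$area <- as.numeric(res_area)
  out <- list(atom_area = atom_area,
              residue = rt[, c("key", "chain", "resno", "insert", "resid",
                               "area")])
  if (return_dots) out$dots <- do.call(rbind, dots)
  out
}

is_hydrogen <- function(atoms) {
  ele <- toupper(atoms$elesy)
  blank <- !nzchar(ele)
  ele[blank] <- vapply(atoms$elety[blank], guess_element, character(1))
  ele == "H"
}

#' Relative solvent accessibility of a residue
#'
#' Observed area divided by the residue type's reference maximum
#' (Tien et al. theoretical set by default). Unknown residue names give
#' `NA`.
#'
#' @param residue_area area in A^2.
#' @param res_name 3-letter residue name (vectorised).
#' @param reference named vector of reference maxima.
#' @return numeric fraction (can exceed 1 for extended conformers).
#' @export
relative_sasa <- function(residue_area, res_name,
                          reference = MAX_SASA_TIEN) {
  ref <- reference[toupper(res_name)]
  unname(residue_area / ref)
}
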