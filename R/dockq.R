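# Docking-quality scoring of a pose against its experimental reference:
# fraction of native contacts (Fnat), ligand RMSD after receptor fit
# (LRMS), interface RMSD (iRMS), the combined quality score and the
# four-category classification. Receptor = antigen, ligand = antibody
# throughout. Residue correspondence between pose and reference is by
# (chain, residue number, insertion code) after standardization.

BACKBONE_RMSD_ATOMS <- c("N", "CA", "C", "O")

# Coordinates of selected atoms with stable row identifiers
# "<residue key>|<atom>".
atom_coords_keyed <- function(model, chains, atom_names = NULL,
                              heavy_only = TRUE) {
  a <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  if (heavy_only) a <- a[!is_hydrogen(a), , drop = FALSE]
  if (!is.null(atom_names)) a <- a[a$elety %in% atom_names, , drop = FALSE]
  list(xyz = as.matrix(a[, c("x", "y", "z")]),
       id = paste(residue_key(a$chain, a$resno, a$insert), a$elety,
                  sep = "|"),
       res = residue_key(a$chain, a$resno, a$insert))
}

#' Native inter-partner residue contacts of a reference complex
#'
#' All (antibody residue, antigen residue) pairs with any heavy-atom
#' distance strictly below `cutoff`.
#'
#' @param reference [structure_model] of the reference complex.
#' @param antibody_chains,antigen_chains partner chain sets.
#' @param cutoff heavy-atom distance, A (5 by default).
#' @return character vector of contact identifiers
#'   `"<antibody residue>+<antigen residue>"`.
#' @export
native_contacts <- function(reference, antibody_chains, antigen_chains,
                            cutoff = 5) {
  ab <- atom_coords_keyed(reference, antibody_chains)
  ag <- atom_coords_keyed(reference, antigen_chains)
  if (nrow(ab$xyz) == 0 || nrow(ag$xyz) == 0)
    stop("empty partner selection")
  hit <- which(cdist(ab$xyz, ag$xyz) < cutoff, arr.ind = TRUE)
  contacts <- unique(paste(ab$res[hit[, 1]], ag$res[hit[, 2]], sep = "+"))
  if (length(contacts) == 0)
    stop("no inter-partner contacts below ", cutoff,
         " A: the reference is not a complex")
  contacts
}

#' Fraction of native contacts recovered by a pose
#'
#' @param pose [structure_model] of the docked pose (same residue
#'   identifiers as the reference).
#' @param native character vector from [native_contacts()].
#' @param antibody_chains,antigen_chains partner chain sets.
#' @param cutoff heavy-atom contact distance, A.
#' @return fraction in `[0, 1]`.
#' @export
fnat <- function(pose, native, antibody_chains, antigen_chains,
                 cutoff = 5) {
  ab <- atom_coords_keyed(pose, antibody_chains)
  ag <- atom_coords_keyed(pose, antigen_chains)
  native_res <- unique(unlist(strsplit(native, "+", fixed = TRUE)))
  pose_res <- unique(c(ab$res, ag$res))
  missing <- setdiff(native_res, pose_res)
  if (length(missing) > 0)
    stop("pose lacks residues present in the native contact set: ",
         paste(utils::head(missing, 5), collapse = ", "))
  hit <- which(cdist(ab$xyz, ag$xyz) < cutoff, arr.ind = TRUE)
  pose_contacts <- unique(paste(ab$res[hit[, 1]], ag$res[hit[, 2]],
                                sep = "+"))
  length(intersect(pose_contacts, native)) / length(native)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `coords_a` onto
#' `coords_b` (rows correspond).
#'
#' @param coords_a,coords_b n x 3 matrices, n >= 3, non-degenerate.
#' @return list `rotation` (3x3), `translation` (3-vector), `rmsd` after
#'   the transform; apply as `x %*% t(rotation) + translation`.
#' @export
superpose <- function(coords_a, coords_b) {
  if (!all(dim(coords_a) == dim(coords_b)) || nrow(coords_a) < 3)
    stop("superposition needs two equal coordinate sets with >= 3 points")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  a0 <- sweep(coords_a, 2, ca)
  b0 <- sweep(coords_b, 2, cb)
  if (min(svd(a0)$d) < 1e-8 && nrow(a0) >= 3) {
    sv <- svd(a0)$d
    if (sv[2] < 1e-8) stop("degenerate (collinear) coordinates")
  }
  h <- t(a0) %*% b0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - b0)^2)))
  list(rotation = rot, translation = as.numeric(cb), center_a = ca,
       rmsd = rmsd)
}

apply_superposition <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_a) %*% t(fit$rotation), 2,
        fit$translation, "+")
}

# Matched backbone coordinate pair (pose, reference) over given chains
# and optional residue subset.
matched_backbone <- function(pose, reference, chains, res_keys = NULL) {
  p <- atom_coords_keyed(pose, chains, BACKBONE_RMSD_ATOMS)
  r <- atom_coords_keyed(reference, chains, BACKBONE_RMSD_ATOMS)
  if (!is.null(res_keys)) {
    pk <- p$res %in% res_keys
    rk <- r$res %in% res_keys
    p$xyz <- p$xyz[pk, , drop = FALSE]; p$id <- p$id[pk]
    r$xyz <- r$xyz[rk, , drop = FALSE]; r$id <- r$id[rk]
  }
  common <- intersect(p$id, r$id)
  if (length(common) < 3)
    stop("fewer than 3 matched backbone atoms between pose and reference")
  list(pose = p$xyz[match(common, p$id), , drop = FALSE],
       ref = r$xyz[match(common, r$id), , drop = FALSE])
}

#' Ligand RMSD after receptor superposition
#'
#' The pose is fitted to the reference on the receptor (antigen)
#' backbone; the reported value is the backbone RMSD over the ligand
#' (antibody) after that fit.
#'
#' @param pose,reference [structure_model]s with matching residue
#'   identifiers.
#' @param receptor_chains,ligand_chains partner chain sets.
#' @return RMSD in Angstrom.
#' @export
lrms <- function(pose, reference, receptor_chains, ligand_chains) {
  rec <- matched_backbone(pose, reference, receptor_chains)
  fit <- superpose(rec$pose, rec$ref)
  lig <- matched_backbone(pose, reference, ligand_chains)
  moved <- apply_superposition(lig$pose, fit)
  sqrt(mean(rowSums((moved - lig$ref)^2)))
}

# Interface residues of the reference: residues of either partner with
# any heavy atom within `cutoff` of the other partner.
interface_residues <- function(reference, antibody_chains, antigen_chains,
                               cutoff = 10) {
  ab <- atom_coords_keyed(reference, antibody_chains)
  ag <- atom_coords_keyed(reference, antigen_chains)
  d <- cdist(ab$xyz, ag$xyz)
  hit <- which(d < cutoff, arr.ind = TRUE)
  unique(c(ab$res[hit[, 1]], ag$res[hit[, 2]]))
}

#' Interface RMSD
#'
#' Interface residues are defined on the reference only (either partner,
#' any heavy atom within `interface_cutoff` of the other partner); the
#' pose's interface backbone is optimally superposed onto the
#' reference's and that fit RMSD is reported.
#'
#' @param pose,reference [structure_model]s with matching residue
#'   identifiers.
#' @param antibody_chains,antigen_chains partner chain sets.
#' @param interface_cutoff heavy-atom distance defining the interface, A.
#' @return RMSD in Angstrom.
#' @export
irms <- function(pose, reference, antibody_chains, antigen_chains,
                 interface_cutoff = 10) {
  ires <- interface_residues(reference, antibody_chains, antigen_chains,
                             interface_cutoff)
  if (length(ires) == 0) stop("empty reference interface")
  m <- matched_backbone(pose, reference,
                        c(antibody_chains, antigen_chains), ires)
  superpose(m$pose, m$ref)$rmsd
}

#' Combined docking-quality score
#'
#' Mean of Fnat and the two scaled RMSD terms
#' `1 / (1 + (rms / d)^2)` with d = 1.5 A for the interface RMSD and
#' 8.5 A for the ligand RMSD.
#'
#' @param fnat fraction of native contacts.
#' @param lrms ligand RMSD, A.
#' @param irms interface RMSD, A.
#' @return score in `[0, 1]`.
#' @export
dockq_score <- function(fnat, lrms, irms) {
  (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3
}

#' Four-category docking-quality classification
#'
#' high: score >= 0.80; medium: 0.49 <= score < 0.80; acceptable:
#' 0.23 <= score < 0.49; incorrect: score < 0.23.
#'
#' @param score combined score in `[0, 1]` (vectorised).
#' @return character vector of categories.
#' @export
classify_dockq <- function(score) {
  ifelse(score >= 0.80, "high",
         ifelse(score >= 0.49, "medium",
                ifelse(score >= 0.23, "acceptable", "incorrect")))
}

#' Score one pose against its reference complex
#'
#' @param pose,reference [structure_model]s with matching residue
#'   identifiers (receptor = antigen, ligand = antibody).
#' @param antibody_chains,antigen_chains partner chain sets.
#' @param contact_cutoff native-contact heavy-atom distance, A.
#' @param interface_cutoff interface definition distance, A.
#' @return list of class `dock_score`: `fnat`, `irms`, `lrms`, `dockq`,
#'   `category`.
#' @export
dockq <- function(pose, reference, antibody_chains, antigen_chains,
                  contact_cutoff = 5, interface_cutoff = 10) {
  native <- native_contacts(reference, antibody_chains, antigen_chains,
                            contact_cutoff)
  f <- fnat(pose, native, antibody_chains, antigen_chains, contact_cutoff)
  l <- lrms(pose, reference, receptor_chains = antigen_chains,
            ligand_chains = antibody_chains)
  i <- irms(pose, reference, antibody_chains, antigen_chains,
            interface_cutoff)
  score <- dockq_score(f, l, i)
  structure(list(fnat = f, irms = i, lrms = l, dockq = score,
                 category = classify_dockq(score)), class = "dock_score")
}

#' @export
print.dock_score <- function(x, ...) {
  cat(sprintf(
    "<dock_score: Fnat %.3f, iRMS %.2f A, LRMS %.2f A, DockQ %.3f (%s)>\n",
    x$fnat, x$irms, x$lrms, x$dockq, x$category))
  invisible(x)
}

#' Select the 4-pose descriptor subset from a scored pose set
#'
#' One pose per represented quality category (the best score within the
#' category); categories with no pose are back-filled with additional
#' incorrect poses, lowest scores first. Ties break on the
#' lexicographically smallest pose identifier. Requires at least 4 poses.
#'
#' @param scores data.frame with columns `pose` (identifier) and `dockq`
#'   (or a `category` column; it is recomputed when absent).
#' @return data.frame of the 4 selected rows, with `category`.
#' @export
select_descriptor_poses <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("pose", "dockq") %in% names(scores)))
  if (nrow(scores) < 4) stop("need at least 4 scored poses")
  scores$category <- classify_dockq(scores$dockq)
  picked <- NULL
  for (cat_name in c("high", "medium", "acceptable", "incorrect")) {
    sub <- scores[scores$category == cat_name, , drop = FALSE]
    if (nrow(sub) == 0) next
    sub <- sub[order(-sub$dockq, sub$pose), , drop = FALSE]
    picked <- rbind(picked, sub[1, , drop = FALSE])
  }
  need <- 4 - nrow(picked)
  if (need > 0) {
    pool <- scores[scores$category == "incorrect" &
                     !(scores$pose %in% picked$pose), , drop = FALSE]
    pool <- pool[order(pool$dockq, pool$pose), , drop = FALSE]
    if (nrow(pool) < need)
      stop("cannot complete the 4-pose subset: only ",
           nrow(picked) + nrow(pool), " distinct candidates")
    picked <- rbind(picked, pool[seq_len(need), , drop = FALSE])
  }
  rownames(picked) <- NULL
  picked
}
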