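# Docking-preparation computations: sequential renumbering of the
# antibody chains (light chain offset to 500 so the two chains never
# collide in a flat numbering space), and active/passive restraint lists
# from CDR membership, surface exposure and interface burial.

#' Sequentially renumber an antibody H/L pair for docking
#'
#' The heavy chain is renumbered 1..n with no insertion codes; the light
#' chain starts at `light_start` (500 by default) so the two chains
#' cannot overlap in residue number. Residue order and atom content are
#' untouched; the original-to-new mapping is returned so the renumbering
#' is reversible.
#'
#' @param model a [structure_model] holding the antibody chains.
#' @param heavy_chain,light_chain chain identifiers (light may be `NULL`
#'   for a single-domain antibody).
#' @param light_start first residue number of the light chain.
#' @return list with `model` (renumbered) and `mapping` (data.frame
#'   `chain`, `old_resno`, `old_insert`, `new_resno`).
#' @export
renumber_for_docking <- function(model, heavy_chain = "H",
                                 light_chain = "L", light_start = 500L) {
  mapping <- NULL
  out <- model
  plan <- list(list(chain = heavy_chain, start = 1L))
  if (!is.null(light_chain) && light_chain %in% chain_ids(model)) {
    n_heavy <- nrow(residue_table(model, heavy_chain))
    if (n_heavy >= light_start)
      stop("heavy chain has ", n_heavy, " residues; numbering would ",
           "collide with the light-chain start at ", light_start)
    plan <- c(plan, list(list(chain = light_chain, start = light_start)))
  }
  for (p in plan) {
    rt <- residue_table(model, p$chain)
    if (nrow(rt) == 0) stop("chain ", p$chain, " absent from model")
    if (nrow(rt) > 499 && p$start >= 500)
      stop("chain ", p$chain, " has ", nrow(rt),
           " residues; would overflow the numbering block")
    new_resno <- seq(p$start, length.out = nrow(rt))
    sel <- out$atoms$chain == p$chain
    i <- match(residue_key(out$atoms$chain[sel], out$atoms$resno[sel],
                           out$atoms$insert[sel]), rt$key)
    out$atoms$resno[sel] <- new_resno[i]
    out$atoms$insert[sel] <- ""
    mapping <- rbind(mapping, data.frame(
      chain = p$chain, old_resno = rt$resno, old_insert = rt$insert,
      new_resno = new_resno, stringsAsFactors = FALSE))
  }
  list(model = out, mapping = mapping)
}

#' Undo a docking renumbering
#'
#' @param model renumbered [structure_model].
#' @param mapping mapping data.frame from [renumber_for_docking()].
#' @return model with original numbering restored.
#' @export
restore_numbering <- function(model, mapping) {
  out <- model
  for (ch in unique(mapping$chain)) {
    mp <- mapping[mapping$chain == ch, , drop = FALSE]
    sel <- out$atoms$chain == ch
    i <- match(out$atoms$resno[sel], mp$new_resno)
    out$atoms$resno[sel] <- mp$old_resno[i]
    out$atoms$insert[sel] <- mp$old_insert[i]
  }
  out
}

new_restraint_set <- function(active = character(), passive = character(),
                              partner = c("antibody", "antigen")) {
  partner <- match.arg(partner)
  if (length(intersect(active, passive)) > 0)
    stop("active and passive residue sets must be disjoint")
  structure(list(active = active, passive = passive, partner = partner),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set (%s): %d active, %d passive>\n", x$partner,
              length(x$active), length(x$passive)))
  invisible(x)
}

#' Antibody active residues: the CDRs
#'
#' The active restraints of the antibody partner are all CDR residues of
#' all its domains; the passive set is empty.
#'
#' @param model Martin-renumbered antibody [structure_model].
#' @param domains list of `numbered_domain` whose chains are in `model`
#'   (pass the renamed chain via `chain_ids` when the model uses H/L).
#' @param chain_map optional named map (domain type or source chain id)
#'   -> model chain id, e.g. the map from [rename_chains()].
#' @return a `restraint_set`.
#' @export
antibody_active <- function(model, domains, chain_map = NULL) {
  active <- character()
  for (d in domains) {
    ch <- d$chain_id
    if (!is.null(chain_map)) {
      if (!is.null(chain_map[[d$domain_type]])) ch <- chain_map[[d$domain_type]]
      else if (!is.null(chain_map[[d$chain_id]])) ch <- chain_map[[d$chain_id]]
    }
    cdrs <- cdr_residues(d, model, chain_id = ch)
    active <- c(active, cdrs$key)
  }
  new_restraint_set(active = unique(active), partner = "antibody")
}

#' Antigen passive residues: the exposed surface (blind docking)
#'
#' Residues of the isolated antigen with relative solvent accessibility
#' at or above `rsasa_threshold` are passive; the active set is empty.
#'
#' @param antigen isolated antigen [structure_model].
#' @param rsasa_threshold relative accessibility threshold (fraction).
#' @param probe_radius,n_sphere_points surface sampling (see [sasa()]).
#' @return a `restraint_set` (plus per-residue `rsasa` attribute).
#' @export
antigen_passive_surface <- function(antigen, rsasa_threshold = 0.15,
                                    probe_radius = 1.4,
                                    n_sphere_points = 960) {
  s <- sasa(antigen, probe_radius, n_sphere_points)
  rel <- relative_sasa(s$residue$area, s$residue$resid)
  rel[is.na(rel)] <- 0
  passive <- s$residue$key[rel >= rsasa_threshold]
  out <- new_restraint_set(passive = passive, partner = "antigen")
  attr(out, "rsasa") <- data.frame(key = s$residue$key, rsasa = rel,
                                   stringsAsFactors = FALSE)
  out
}

#' Antigen active residues by interface burial (site-directed docking)
#'
#' Epitope residues are those whose solvent-accessible area drops by more
#' than `min_delta` between the isolated antigen and the antigen in the
#' complex.
#'
#' @param complexed [structure_model] of the whole complex (antibody
#'   present).
#' @param isolated [structure_model] of the antigen alone, same residues.
#' @param antigen_chains antigen chain identifiers in `complexed`.
#' @param min_delta minimum area loss, A^2.
#' @param probe_radius,n_sphere_points surface sampling (see [sasa()]).
#' @return a `restraint_set` (plus per-residue `delta_sasa` attribute).
#' @export
epitope_by_delta_sasa <- function(complexed, isolated, antigen_chains,
                                  min_delta = 1.0, probe_radius = 1.4,
                                  n_sphere_points = 960) {
  s_cpx <- sasa(complexed, probe_radius, n_sphere_points)
  s_iso <- sasa(isolated, probe_radius, n_sphere_points)
  cpx <- s_cpx$residue[s_cpx$residue$chain %in% antigen_chains, ,
                       drop = FALSE]
  iso <- s_iso$residue
  if (!setequal(cpx$key, iso$key))
    stop("complexed and isolated antigens contain different residues")
  delta <- iso$area - cpx$area[match(iso$key, cpx$key)]
  active <- iso$key[delta > min_delta]
  out <- new_restraint_set(active = active, partner = "antigen")
  attr(out, "delta_sasa") <- data.frame(key = iso$key, delta_sasa = delta,
                                        stringsAsFactors = FALSE)
  out
}

#' Write restraints as a two-line active/passive text file plus JSON
#'
#' Line 1 lists active residue numbers, line 2 passive, the classic
#' ambiguous-restraint input layout for protein-protein docking engines.
#' A JSON manifest with any attached per-residue surface values is
#' written alongside when `json_path` is given.
#'
#' @param restraints a `restraint_set`.
#' @param path output text path.
#' @param json_path optional JSON manifest path.
#' @return invisibly, `path`.
#' @export
write_restraints <- function(restraints, path, json_path = NULL) {
  resno_of <- function(keys)
    vapply(strsplit(keys, "|", fixed = TRUE), `[[`, "", 2)
  lines <- c(paste(resno_of(restraints$active), collapse = " "),
             paste(resno_of(restraints$passive), collapse = " "))
  writeLines(lines, path)
  if (!is.null(json_path)) {
    payload <- list(partner = restraints$partner,
                    active = restraints$active,
                    passive = restraints$passive)
    for (extra in c("rsasa", "delta_sasa")) {
      tab <- attr(restraints, extra)
      if (!is.null(tab)) payload[[extra]] <- tab
    }
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
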