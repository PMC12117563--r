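# Standardization of an antibody entry into one-complex-per-file records:
# identify variable domains, pair VH/VL by conserved-cysteine geometry,
# resolve the antigen oligomeric state, build antibody-antigen complexes
# by CDR contacts and split the entry into XXXX_n files.

# Martin positions of the conserved cysteines used for VH/VL pairing.
PAIRING_CYS <- c(VH = 92L, VL = 88L)

# Calpha coordinate of a domain's conserved pairing cysteine in the
# source model, or NULL when absent.
pairing_ca <- function(model, domain) {
  pos <- PAIRING_CYS[[domain$domain_type]]
  nm <- domain$number_map
  row <- which(nm$martin_num == pos & nm$martin_ins == "")
  if (length(row) == 0) return(NULL)
  sel <- model$atoms$chain == domain$chain_id &
    model$atoms$resno == nm$resno[row[1]] &
    model$atoms$insert == nm$insert[row[1]] &
    model$atoms$elety == "CA"
  if (!any(sel)) return(NULL)
  as.numeric(model$atoms[which(sel)[1], c("x", "y", "z")])
}

#' Pair VH and VL domains by conserved-cysteine distance
#'
#' Measures Calpha distances between Cys92 of each VH and Cys88 of each
#' VL and matches domains greedily by ascending distance (each step pairs
#' the globally closest remaining VH/VL couple, i.e. a mutual-nearest
#' pair), subject to the pairing cutoff. Unmatched domains are returned
#' as single-chain antibodies; a domain lacking the conserved cysteine's
#' Calpha is unpairable.
#'
#' @param domains list of `numbered_domain` (VH and VL mixed).
#' @param model the source [structure_model].
#' @param cutoff pairing radius in Angstrom.
#' @return list with `pairs` (each `list(vh, vl, cys_distance)`) and
#'   `singles` (unpaired domains).
#' @export
pair_fv <- function(domains, model, cutoff = 22) {
  vh <- Filter(function(d) d$domain_type == "VH", domains)
  vl <- Filter(function(d) d$domain_type == "VL", domains)
  # scFv: VH and VL on the same chain pair intramolecularly and are
  # handled by the caller, not here
  ca_h <- lapply(vh, pairing_ca, model = model)
  ca_l <- lapply(vl, pairing_ca, model = model)
  ok_h <- !vapply(ca_h, is.null, logical(1))
  ok_l <- !vapply(ca_l, is.null, logical(1))
  for (d in c(vh[!ok_h], vl[!ok_l]))
    message("domain ", d$domain_type, " on chain ", d$chain_id,
            " lacks the conserved pairing cysteine Calpha; unpairable")
  pairs <- list()
  used_h <- !ok_h
  used_l <- !ok_l
  if (any(ok_h) && any(ok_l)) {
    dmat <- matrix(Inf, length(vh), length(vl))
    for (i in which(ok_h)) for (j in which(ok_l))
      dmat[i, j] <- vnorm(ca_h[[i]] - ca_l[[j]])
    repeat {
      dmat_av <- dmat
      dmat_av[used_h, ] <- Inf
      dmat_av[, used_l] <- Inf
      if (all(!is.finite(dmat_av)) || min(dmat_av) > cutoff) break
      cand <- which(dmat_av == min(dmat_av), arr.ind = TRUE)
      if (nrow(cand) > 1) {   # tie: lexical chain-id order
        ids <- paste(vapply(vh[cand[, 1]], `[[`, "", "chain_id"),
                     vapply(vl[cand[, 2]], `[[`, "", "chain_id"))
        cand <- cand[order(ids)[1], , drop = FALSE]
      }
      i <- cand[1, 1]; j <- cand[1, 2]
      pairs[[length(pairs) + 1]] <- list(vh = vh[[i]], vl = vl[[j]],
                                         cys_distance = dmat[i, j])
      used_h[i] <- TRUE
      used_l[j] <- TRUE
    }
  }
  list(pairs = pairs, singles = c(vh[!used_h & ok_h], vl[!used_l & ok_l],
                                  vh[!ok_h], vl[!ok_l]))
}

#' Default biological-vs-crystallographic interface classifier
#'
#' A pairwise chain interface is called biological when its buried
#' surface area is at least `min_bsa` and at least `min_contacts`
#' inter-chain residue pairs have heavy atoms within `contact_dist`.
#' The classifier seam is pluggable: any
#' `function(model, chain_a, chain_b) -> logical` can replace it, e.g. an
#' adapter around an external trained interface classifier.
#'
#' @param min_bsa buried surface area threshold, A^2.
#' @param min_contacts residue-contact count threshold.
#' @param contact_dist heavy-atom contact distance, A.
#' @param n_sphere_points surface sampling for the BSA estimate.
#' @return a classifier function.
#' @export
default_interface_classifier <- function(min_bsa = 800, min_contacts = 10,
                                         contact_dist = 5.5,
                                         n_sphere_points = 240) {
  function(model, chain_a, chain_b) {
    ma <- subset_chains(model, chain_a)
    mb <- subset_chains(model, chain_b)
    mab <- subset_chains(model, c(chain_a, chain_b))
    npairs <- interchain_residue_contacts(model, chain_a, chain_b,
                                          contact_dist)
    if (npairs < min_contacts) return(FALSE)
    bsa <- sum(sasa(ma, n_sphere_points = n_sphere_points)$atom_area) +
      sum(sasa(mb, n_sphere_points = n_sphere_points)$atom_area) -
      sum(sasa(mab, n_sphere_points = n_sphere_points)$atom_area)
    bsa >= min_bsa
  }
}

# Number of distinct inter-chain residue pairs with any heavy-atom
# distance below `cutoff`.
interchain_residue_contacts <- function(model, chain_a, chain_b, cutoff) {
  a <- model$atoms[model$atoms$chain == chain_a, , drop = FALSE]
  b <- model$atoms[model$atoms$chain == chain_b, , drop = FALSE]
  a <- a[!is_hydrogen(a), , drop = FALSE]
  b <- b[!is_hydrogen(b), , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  d <- cdist(as.matrix(a[, c("x", "y", "z")]),
             as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(0L)
  ka <- residue_key(a$chain, a$resno, a$insert)[hit[, 1]]
  kb <- residue_key(b$chain, b$resno, b$insert)[hit[, 2]]
  length(unique(paste(ka, kb)))
}

#' Group antigen chains into monomer or oligomer units
#'
#' Classifies every pairwise antigen-antigen interface with `classifier`
#' and merges chains connected by biological interfaces (transitive
#' closure) into oligomeric units; crystallographic interfaces leave
#' chains as monomers. Classifier failure on a pair falls back to the
#' conservative monomer treatment.
#'
#' @param model the source [structure_model].
#' @param antigen_chains chain identifiers of all non-antibody chains.
#' @param classifier `function(model, chain_a, chain_b) -> logical`.
#' @return list of antigen units: `list(chains, oligomeric)`.
#' @export
classify_antigen_interfaces <- function(model, antigen_chains,
                                        classifier =
                                          default_interface_classifier()) {
  n <- length(antigen_chains)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      bio <- tryCatch(
        isTRUE(classifier(model, antigen_chains[i], antigen_chains[j])),
        error = function(e) {
          warning("interface classifier failed for chains ",
                  antigen_chains[i], "/", antigen_chains[j], ": ",
                  conditionMessage(e), "; treating as crystallographic")
          FALSE
        })
      if (bio) parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lapply(unique(comp), function(cc) {
    chains <- antigen_chains[comp == cc]
    list(chains = chains, oligomeric = length(chains) > 1)
  })
}

# Calpha coordinates of the CDR residues of an antibody unit, using the
# Martin maps of its domains against the original model numbering.
unit_cdr_ca <- function(model, unit) {
  out <- NULL
  for (d in unit$domains) {
    nm <- d$number_map
    keep <- in_cdr_span(nm$martin_num, d$cdr_spans)
    keys <- residue_key(d$chain_id, nm$resno[keep], nm$insert[keep])
    sel <- residue_key(model$atoms$chain, model$atoms$resno,
                       model$atoms$insert) %in% keys &
      model$atoms$elety == "CA"
    out <- rbind(out, coords(model, sel))
  }
  out
}

antigen_ca <- function(model, unit) {
  sel <- model$atoms$chain %in% unit$chains & model$atoms$elety == "CA"
  coords(model, sel)
}

antigen_length <- function(model, unit) {
  nrow(residue_table(model, unit$chains))
}

#' Build antibody-antigen complex records by CDR contact counting
#'
#' For every (antibody unit, antigen unit) pair, counts
#' (CDR residue, antigen residue) Calpha pairs closer than
#' `contact_cutoff` (strict). Pairs with at least one contact and an
#' antigen longer than `min_antigen_len` residues (summed over oligomer
#' members) become complex records; every antibody unit with no
#' qualifying antigen is emitted as a free-antibody record, so no unit is
#' lost or duplicated.
#'
#' @param model the source [structure_model].
#' @param antibody_units list of units, each `list(kind, domains)` with
#'   `kind` in paired/heavy_only/light_only/scfv.
#' @param antigen_units list from [classify_antigen_interfaces()].
#' @param contact_cutoff Calpha-Calpha contact distance, A.
#' @param min_antigen_len minimum antigen residue count (strictly more
#'   than this many residues qualifies).
#' @return list of records `list(antibody, antigen, contact_count)`
#'   (`antigen` NULL for free antibodies).
#' @export
build_complexes <- function(model, antibody_units, antigen_units,
                            contact_cutoff = 7.5, min_antigen_len = 50) {
  records <- list()
  for (ab in antibody_units) {
    cdr <- unit_cdr_ca(model, ab)
    found <- FALSE
    for (ag in antigen_units) {
      agca <- antigen_ca(model, ag)
      if (is.null(cdr) || is.null(agca) || nrow(agca) == 0) next
      count <- sum(cdist(cdr, agca) < contact_cutoff)
      if (count >= 1 && antigen_length(model, ag) > min_antigen_len) {
        records[[length(records) + 1]] <-
          list(antibody = ab, antigen = ag, contact_count = count)
        found <- TRUE
      }
    }
    if (!found)
      records[[length(records) + 1]] <-
        list(antibody = ab, antigen = NULL, contact_count = 0L)
  }
  records
}

# Deterministic sort key of a record: antibody chain ids, then antigen.
record_sort_key <- function(record) {
  ab_chains <- sort(vapply(record$antibody$domains, `[[`, "", "chain_id"))
  ag <- if (is.null(record$antigen)) "" else
    paste(sort(record$antigen$chains), collapse = "")
  paste(paste(ab_chains, collapse = ""), ag)
}

#' Standardized chain renaming of one complex record
#'
#' Heavy chain to H, light chain to L (scFv halves to h and l); antigen
#' chains keep their original identifiers except those named H or L,
#' which become A. A renaming collision falls back to the first unused
#' letter, with a warning.
#'
#' @param record a record from [build_complexes()].
#' @return named character vector: old chain/domain label -> new id. The
#'   antibody part is keyed `VH`/`VL` (or `VH@chain` when needed);
#'   antigen part keyed by original chain id.
#' @export
rename_chains <- function(record) {
  ab <- record$antibody
  map <- character()
  if (ab$kind == "scfv") {
    map["VH"] <- "h"
    map["VL"] <- "l"
  } else {
    for (d in ab$domains)
      map[d$domain_type] <- if (d$domain_type == "VH") "H" else "L"
  }
  taken <- unname(map)
  if (!is.null(record$antigen)) {
    for (ch in record$antigen$chains) {
      new <- if (ch %in% c("H", "L")) "A" else ch
      if (new %in% taken) {
        pool <- setdiff(c(LETTERS, letters, as.character(0:9)),
                        c(taken, record$antigen$chains))
        warning("chain renaming collision for antigen chain ", ch,
                "; using ", pool[1])
        new <- pool[1]
      }
      map[ch] <- new
      taken <- c(taken, new)
    }
  }
  map
}

#' Split records of one entry into named standardized models
#'
#' One file per record, named `XXXX_n` with `n` assigned 1..k in a
#' deterministic order (antibody chain-id lexical order, then antigen
#' id). Each output model contains the Martin-renumbered variable
#' region(s) renamed H/L (h/l for scFv) plus the antigen unit's chains
#' when complexed.
#'
#' @param model the source [structure_model].
#' @param records list from [build_complexes()].
#' @param entry_id 4-character entry code (defaults to the model's).
#' @return named list of [structure_model]s, names `XXXX_n`.
#' @export
split_and_name <- function(model, records, entry_id = model$entry_id) {
  ord <- order(vapply(records, record_sort_key, character(1)))
  out <- list()
  for (n_idx in seq_along(ord)) {
    record <- records[[ord[n_idx]]]
    map <- rename_chains(record)
    parts <- list()
    for (d in record$antibody$domains)
      parts[[length(parts) + 1]] <-
        renumber_to_martin(model, d, new_chain_id = map[[d$domain_type]])
    if (!is.null(record$antigen)) {
      for (ch in record$antigen$chains) {
        m <- subset_chains(model, ch)
        m$atoms$chain <- map[[ch]]
        parts[[length(parts) + 1]] <- m
      }
    }
    name <- sprintf("%s_%d", entry_id, n_idx)
    out[[name]] <- merge_models(parts, entry_id = entry_id)
  }
  out
}

#' Standardize one entry end to end
#'
#' Runs domain detection, format classification (unusual formats are
#' rejected), VH/VL pairing, antigen interface classification, complex
#' construction and file splitting for a single entry, returning the
#' standardized models plus a manifest of every decision.
#'
#' @param model a [structure_model] of one entry.
#' @param engine numbering engine for [detect_domains()].
#' @param pairing_cutoff,contact_cutoff,min_antigen_len printed pipeline
#'   parameters (22 A, 7.5 A, 50 residues).
#' @param classifier antigen interface classifier.
#' @param reject_incomplete reject the whole entry when any standard
#'   residue is missing heavy atoms.
#' @param exclusion_list entry codes to drop (manual curation seam).
#' @return list with `files` (named models), `records`, `manifest`
#'   (list: entry, format, rejected, reason, pairings, contact counts).
#' @export
standardize_entry <- function(model, engine, pairing_cutoff = 22,
                              contact_cutoff = 7.5, min_antigen_len = 50,
                              classifier = default_interface_classifier(),
                              reject_incomplete = TRUE,
                              exclusion_list = character()) {
  manifest <- list(entry = model$entry_id, rejected = FALSE, reason = NULL)
  reject <- function(reason) {
    manifest$rejected <- TRUE
    manifest$reason <- reason
    list(files = list(), records = list(), manifest = manifest)
  }
  if (model$entry_id %in% exclusion_list)
    return(reject("on exclusion list"))
  if (reject_incomplete) {
    viol <- check_atom_completeness(model)
    if (nrow(viol) > 0)
      return(reject(sprintf("missing heavy atoms in %d residue(s)",
                            nrow(viol))))
  }
  domains <- detect_domains(model, engine)
  fmt <- classify_format(domains)
  manifest$format <- fmt
  if (fmt == "unusual") return(reject("unusual antibody format"))
  if (fmt == "none") return(reject("no antibody domains detected"))

  chains <- vapply(domains, `[[`, "", "chain_id")
  scfv_chains <- unique(chains[duplicated(chains)])
  units <- list()
  for (ch in scfv_chains) {
    ds <- domains[chains == ch]
    ord <- order(vapply(ds, function(d) min(d$number_map$resno), numeric(1)))
    units[[length(units) + 1]] <- list(kind = "scfv", domains = ds[ord])
  }
  rest <- domains[!(chains %in% scfv_chains)]
  pairing <- pair_fv(rest, model, cutoff = pairing_cutoff)
  for (p in pairing$pairs)
    units[[length(units) + 1]] <- list(kind = "paired",
                                       domains = list(p$vh, p$vl),
                                       cys_distance = p$cys_distance)
  for (d in pairing$singles)
    units[[length(units) + 1]] <- list(
      kind = if (d$domain_type == "VH") "heavy_only" else "light_only",
      domains = list(d))
  manifest$pairings <- lapply(pairing$pairs, function(p)
    list(vh_chain = p$vh$chain_id, vl_chain = p$vl$chain_id,
         cys_distance = p$cys_distance))

  antigen_chains <- setdiff(chain_ids(model), unique(chains))
  antigen_units <- classify_antigen_interfaces(model, antigen_chains,
                                               classifier)
  manifest$antigen_units <- lapply(antigen_units, `[`, c("chains",
                                                         "oligomeric"))
  records <- build_complexes(model, units, antigen_units,
                             contact_cutoff = contact_cutoff,
                             min_antigen_len = min_antigen_len)
  files <- split_and_name(model, records)
  manifest$files <- lapply(seq_along(files), function(i) {
    r <- records[[order(vapply(records, record_sort_key, character(1)))[i]]]
    list(name = names(files)[i], kind = r$antibody$kind,
         contact_count = r$contact_count,
         antigen_chains = if (is.null(r$antigen)) character()
                          else r$antigen$chains)
  })
  list(files = files, records = records, manifest = manifest)
}

#' Dataset profile: methods, resolutions, resolution-cutoff fraction
#'
#' @param metadata list of `list(method, resolution)` (resolution NULL or
#'   NA when absent).
#' @param resolution_cutoff fraction is computed as resolution strictly
#'   below this value, A.
#' @return list with `n`, `method_percent` (named, %), `method_mean_resolution`
#'   (named, A), `fraction_below_cutoff` (among entries with a reported
#'   resolution), `n_missing_resolution`.
#' @export
profile_dataset <- function(metadata, resolution_cutoff = 4.0) {
  methods <- vapply(metadata, function(m) m$method %||% "unknown",
                    character(1))
  res <- vapply(metadata, function(m) {
    r <- m$resolution
    if (is.null(r) || length(r) == 0 || is.na(r)) NA_real_ else as.numeric(r)
  }, numeric(1))
  n <- length(methods)
  tab <- table(methods)
  method_percent <- as.numeric(tab) / n * 100
  names(method_percent) <- names(tab)
  mean_res <- tapply(res, methods, function(x) mean(x, na.rm = TRUE))
  have_res <- !is.na(res)
  list(n = n,
       method_percent = method_percent,
       method_mean_resolution = as.list(mean_res),
       fraction_below_cutoff =
         if (any(have_res)) mean(res[have_res] < resolution_cutoff)
         else NA_real_,
       n_missing_resolution = sum(!have_res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
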