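# End-to-end pipeline wiring: configuration, per-entry orchestration over
# an input directory, manifests. Each stage is independently callable;
# the pipeline only sequences them and records decisions.

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline in one validated list, with the
#' standard defaults: 22 A VH/VL pairing radius, 7.5 A Calpha contact
#' cutoff, antigens kept when longer than 50 residues, light chain
#' renumbered from 500, docking-quality boundaries 0.80/0.49/0.23.
#'
#' @param pairing_cutoff VH/VL conserved-cysteine pairing radius, A.
#' @param contact_cutoff CDR-antigen Calpha contact distance, A.
#' @param min_antigen_len antigen size threshold, residues (strict:
#'   antigens must exceed it).
#' @param resolution_cutoff profiling resolution threshold, A.
#' @param light_chain_start first light-chain residue number for docking.
#' @param dockq_thresholds high/medium/acceptable boundaries, strictly
#'   decreasing.
#' @param rsasa_threshold passive-surface relative accessibility.
#' @param delta_sasa_min epitope area-loss threshold, A^2.
#' @param n_sphere_points surface sampling density.
#' @param probe_radius solvent probe, A.
#' @param compute_descriptors emit per-residue descriptor CSVs.
#' @param seed base seed recorded in manifests.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(pairing_cutoff = 22, contact_cutoff = 7.5,
                            min_antigen_len = 50, resolution_cutoff = 4.0,
                            light_chain_start = 500L,
                            dockq_thresholds = c(0.80, 0.49, 0.23),
                            rsasa_threshold = 0.15, delta_sasa_min = 1.0,
                            n_sphere_points = 960, probe_radius = 1.4,
                            compute_descriptors = TRUE, seed = 1L) {
  cfg <- list(pairing_cutoff = pairing_cutoff,
              contact_cutoff = contact_cutoff,
              min_antigen_len = min_antigen_len,
              resolution_cutoff = resolution_cutoff,
              light_chain_start = as.integer(light_chain_start),
              dockq_thresholds = as.numeric(dockq_thresholds),
              rsasa_threshold = rsasa_threshold,
              delta_sasa_min = delta_sasa_min,
              n_sphere_points = as.integer(n_sphere_points),
              probe_radius = probe_radius,
              compute_descriptors = isTRUE(compute_descriptors),
              seed = as.integer(seed))
  for (nm in c("pairing_cutoff", "contact_cutoff", "resolution_cutoff",
               "light_chain_start", "n_sphere_points", "probe_radius"))
    if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  if (length(cfg$dockq_thresholds) != 3 ||
      any(diff(cfg$dockq_thresholds) >= 0))
    stop("dockq_thresholds must be three strictly decreasing values")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return for `read_config`, a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' @param config a `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the standardization pipeline over a directory of structures
#'
#' Reads every `.pdb`/`.cif` file of `input_dir` (sorted order), runs
#' [standardize_entry()], writes the standardized `XXXX_n.pdb` files,
#' optional per-file descriptor CSVs and antibody restraint lists under
#' `output_dir`, and records every decision in a run manifest
#' (`manifest.json`). Per-file failures are logged and skipped.
#'
#' @param input_dir directory of input structures (or a single file).
#' @param output_dir output root; subdirectories `standardized/`,
#'   `descriptors/`, `restraints/` are created.
#' @param engine numbering engine (see [table_numbering_engine()]).
#' @param config a [pipeline_config()].
#' @param exclusion_list entry codes to drop.
#' @return invisibly, the run manifest list.
#' @export
run_pipeline <- function(input_dir, output_dir, engine,
                         config = pipeline_config(),
                         exclusion_list = character()) {
  paths <- if (dir.exists(input_dir))
    sort(list.files(input_dir, pattern = "\\.(pdb|cif)$", full.names = TRUE))
  else input_dir
  if (length(paths) == 0) stop("no .pdb/.cif files under ", input_dir)
  std_dir <- file.path(output_dir, "standardized")
  dsc_dir <- file.path(output_dir, "descriptors")
  rst_dir <- file.path(output_dir, "restraints")
  for (d in c(std_dir, dsc_dir, rst_dir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  all_meta <- list()
  for (p in paths) {
    entry <- tryCatch({
      model <- read_structure(p)
      res <- standardize_entry(
        model, engine,
        pairing_cutoff = config$pairing_cutoff,
        contact_cutoff = config$contact_cutoff,
        min_antigen_len = config$min_antigen_len,
        exclusion_list = exclusion_list)
      all_meta[[length(all_meta) + 1]] <- model$metadata
      for (nm in names(res$files)) {
        out_model <- res$files[[nm]]
        write_structure(out_model, file.path(std_dir, paste0(nm, ".pdb")))
        if (config$compute_descriptors) {
          rows <- residue_descriptors(
            out_model, probe_radius = config$probe_radius,
            n_sphere_points = config$n_sphere_points)
          write_descriptor_table(rows, file.path(dsc_dir,
                                                 paste0(nm, ".csv")))
        }
      }
      write_entry_restraints(res, rst_dir)
      res$manifest
    }, error = function(e) {
      list(entry = basename(p), rejected = TRUE,
           reason = paste("processing error:", conditionMessage(e)))
    })
    entries[[length(entries) + 1]] <- entry
  }
  profile <- if (length(all_meta) > 0)
    profile_dataset(all_meta, config$resolution_cutoff) else NULL
  manifest <- list(config = unclass(config), entries = entries,
                   profile = profile)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

# Active/passive restraint files for every standardized record of one
# entry: CDR actives for the antibody, exposed-surface passives for the
# antigen.
write_entry_restraints <- function(res, rst_dir) {
  ord <- order(vapply(res$records, record_sort_key, character(1)))
  for (i in seq_along(ord)) {
    record <- res$records[[ord[i]]]
    name <- names(res$files)[i]
    out_model <- res$files[[name]]
    map <- rename_chains(record)
    ab <- antibody_active(out_model, record$antibody$domains,
                          chain_map = as.list(map))
    write_restraints(ab, file.path(rst_dir, paste0(name, "_antibody.txt")),
                     json_path = file.path(rst_dir,
                                           paste0(name, "_antibody.json")))
    if (!is.null(record$antigen)) {
      ag_chains <- unname(map[record$antigen$chains])
      ag_model <- subset_chains(out_model, ag_chains)
      ps <- antigen_passive_surface(ag_model, n_sphere_points = 240)
      write_restraints(ps, file.path(rst_dir, paste0(name, "_antigen.txt")),
                       json_path = file.path(rst_dir,
                                             paste0(name, "_antigen.json")))
    }
  }
}

#' Profile the experimental metadata of a structure directory
#'
#' @param input_dir directory of `.pdb`/`.cif` files.
#' @param resolution_cutoff threshold for the below-cutoff fraction, A.
#' @return the [profile_dataset()] record.
#' @export
profile_directory <- function(input_dir, resolution_cutoff = 4.0) {
  paths <- sort(list.files(input_dir, pattern = "\\.(pdb|cif)$",
                           full.names = TRUE))
  meta <- lapply(paths, function(p) read_structure(p)$metadata)
  profile_dataset(meta, resolution_cutoff)
}
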