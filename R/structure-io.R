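# Reading, writing and atom-completeness screening of protein structures.
# Parsing of the coordinate section is delegated to bio3d; header metadata
# (experimental method, resolution) is read here because bio3d does not
# expose it.

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O")

# Side-chain heavy atoms of the 20 standard residues; the backbone set
# (N, CA, C, O) is common to all. OXT and hydrogens are deliberately
# ignored by the completeness check.
SIDE_CHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

expected_heavy_atoms <- function(resid) {
  sc <- SIDE_CHAIN_ATOMS[[toupper(resid)]]
  if (is.null(sc)) return(NULL)   # non-standard residue: exempt
  c(BACKBONE_ATOMS, sc)
}

#' Read a protein structure from a PDB or mmCIF file
#'
#' Reads the first model of the file, collapses alternate locations to the
#' highest-occupancy conformer, drops waters and non-polymer heteroatoms
#' (modified amino acids that carry a peptide backbone are retained), and
#' populates experimental metadata from the header when present.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format_hint `"pdb"`, `"cif"`, or `NULL` to infer from the file
#'   extension (falling back to content sniffing).
#' @param entry_id optional 4-character entry code; defaults to the first
#'   4 characters of the file base name when those form a valid code.
#' @return a [structure_model].
#' @export
read_structure <- function(path, format_hint = NULL, entry_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- format_hint
  if (is.null(fmt)) {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("cif", "mmcif")) "cif" else if (ext == "pdb") "pdb"
           else if (cif_like(path)) "cif" else "pdb"
  }
  fmt <- match.arg(fmt, c("pdb", "cif"))
  parsed <- tryCatch(
    suppressWarnings(
      if (fmt == "cif") bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                        verbose = FALSE)
      else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                           verbose = FALSE)),
    error = function(e) {
      stop("cannot parse ", path, " as ", fmt, " (", conditionMessage(e),
           "); first unrecognised line: ", first_bad_line(path, fmt),
           call. = FALSE)
    })
  atoms <- parsed$atom
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  if (is.null(atoms$elesy)) atoms$elesy <- ""
  atoms$elesy[is.na(atoms$elesy)] <- ""

  atoms <- atoms[!(toupper(atoms$resid) %in% WATER_RESIDS), , drop = FALSE]
  atoms <- collapse_altloc(atoms)
  atoms <- drop_nonpolymer_het(atoms)
  if (nrow(atoms) == 0)
    stop("no polymer atoms found in ", path)

  if (is.null(entry_id)) {
    base <- substr(basename(path), 1, 4)
    entry_id <- if (grepl("^[A-Za-z0-9]{4}$", base)) base else "XXXX"
  }
  meta <- if (fmt == "cif") read_cif_metadata(path) else read_pdb_metadata(path)
  structure_model(atoms[, c("type", "eleno", "elety", "alt", "resid", "chain",
                            "resno", "insert", "x", "y", "z", "o", "b",
                            "elesy")],
                  entry_id = entry_id, method = meta$method,
                  resolution = meta$resolution)
}

cif_like <- function(path) {
  head_lines <- readLines(path, n = 5, warn = FALSE)
  any(grepl("^data_|^#|^loop_", head_lines))
}

first_bad_line <- function(path, fmt) {
  lines <- readLines(path, warn = FALSE)
  if (fmt == "pdb") {
    known <- "^(ATOM|HETATM|TER|HEADER|TITLE|EXPDTA|REMARK|MODEL|ENDMDL|END|ANISOU|CONECT|SEQRES|HELIX|SHEET|SSBOND|CRYST1|ORIGX|SCALE|MASTER|COMPND|SOURCE|KEYWDS|AUTHOR|REVDAT|JRNL|DBREF|SEQADV|HET|HETNAM|FORMUL|LINK|SITE|CISPEP|MODRES|OBSLTE|CAVEAT|SPRSDE|NUMMDL|MDLTYP|SPLIT)"
    bad <- which(!grepl(known, lines) & nzchar(trimws(lines)))
  } else {
    bad <- integer()
  }
  if (length(bad) == 0) "none (file truncated or empty?)"
  else sprintf("line %d: %s", bad[1], substr(lines[bad[1]], 1, 40))
}

# Keep, per (chain, residue, atom name), the alternate location with the
# highest occupancy; ties broken by alt-loc letter.
collapse_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  ord <- order(match(key, unique(key)), -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$elety, sep = "|")), , drop = FALSE]
  atoms[order(match(paste(atoms$chain, atoms$resno, atoms$insert, sep = "|"),
                    unique(paste(atoms$chain, atoms$resno, atoms$insert,
                                 sep = "|")))), , drop = FALSE]
}

# HETATM residues are retained only when peptide-linked (full backbone
# present), which keeps modified amino acids such as MSE and discards
# ligands, ions and sugars.
drop_nonpolymer_het <- function(atoms) {
  if (nrow(atoms) == 0) return(atoms)
  key <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  het_keys <- unique(key[atoms$type == "HETATM"])
  drop_keys <- character()
  for (k in het_keys) {
    names_k <- atoms$elety[key == k]
    if (!all(c("N", "CA", "C") %in% names_k)) drop_keys <- c(drop_keys, k)
  }
  atoms[!(key %in% drop_keys), , drop = FALSE]
}

read_pdb_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list(method = "unknown", resolution = NULL)
  exp_line <- grep("^EXPDTA", lines, value = TRUE)
  if (length(exp_line) > 0)
    meta$method <- classify_method(exp_line[1])
  res_line <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(res_line) > 0) {
    m <- regmatches(res_line[1],
                    regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]*ANGSTROM)",
                            res_line[1], perl = TRUE))
    if (length(m) == 1) meta$resolution <- as.numeric(m)
  }
  meta
}

read_cif_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list(method = "unknown", resolution = NULL)
  exp_line <- grep("^_exptl\\.method", lines, value = TRUE)
  if (length(exp_line) > 0)
    meta$method <- classify_method(exp_line[1])
  res_line <- grep("^_refine\\.ls_d_res_high|^_em_3d_reconstruction\\.resolution",
                   lines, value = TRUE)
  if (length(res_line) > 0) {
    m <- regmatches(res_line[1], regexpr("[0-9]+\\.?[0-9]*", res_line[1]))
    if (length(m) == 1) meta$resolution <- as.numeric(m)
  }
  meta
}

classify_method <- function(text) {
  up <- toupper(text)
  if (grepl("X-RAY|XRAY", up)) "xray"
  else if (grepl("ELECTRON MICROSCOPY|CRYO-EM|ELECTRON CRYO", up)) "em"
  else if (grepl("NMR", up)) "nmr"
  else if (grepl("[A-Z]", gsub("^EXPDTA|^_EXPTL\\.METHOD", "", up))) "other"
  else "unknown"
}

#' Write a structure model as a PDB file
#'
#' Fixed-column PDB output; coordinates are serialized at 3 decimals,
#' insertion codes in column 27, one TER per chain. A HEADER/EXPDTA/REMARK 2
#' preamble carries the metadata so that re-reading restores it.
#'
#' @param model a [structure_model].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  if (any(nchar(a$chain) != 1))
    stop("PDB chain identifiers must be single characters; offending: ",
         paste(unique(a$chain[nchar(a$chain) != 1]), collapse = ", "))
  method_label <- c(xray = "X-RAY DIFFRACTION", em = "ELECTRON MICROSCOPY",
                    nmr = "SOLUTION NMR", other = "OTHER",
                    unknown = "")[model$metadata$method]
  header <- sprintf("HEADER    IMMUNE SYSTEM                           %s",
                    toupper(model$entry_id))
  pre <- header
  if (nzchar(method_label))
    pre <- c(pre, sprintf("EXPDTA    %s", method_label))
  if (!is.null(model$metadata$resolution))
    pre <- c(pre, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          model$metadata$resolution))
  con <- file(path, "w")
  writeLines(pre, con)
  writeLines(format_atom_records(a), con)
  writeLines("END", con)
  close(con)
  invisible(path)
}

format_atom_records <- function(a) {
  out <- character()
  serial <- 0L
  for (ch in unique(a$chain)) {
    rows <- which(a$chain == ch)
    for (i in rows) {
      serial <- serial + 1L
      name <- a$elety[i]
      # column-13 convention: 4-char names start at col 13, shorter at 14
      name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4)
                  else sprintf(" %-3s", name)
      elesy <- a$elesy[i]
      if (!nzchar(elesy)) elesy <- guess_element(name)
      out <- c(out, sprintf(
        "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a$type[i], serial %% 100000L, name_fmt,
        substr(a$alt[i], 1, 1), a$resid[i], ch, a$resno[i],
        substr(paste0(a$insert[i], " "), 1, 1),
        a$x[i], a$y[i], a$z[i], a$o[i], a$b[i], elesy))
    }
    serial <- serial + 1L
    last <- rows[length(rows)]
    out <- c(out, sprintf("TER   %5d      %-3s %1s%4d",
                          serial %% 100000L, a$resid[last], ch, a$resno[last]))
  }
  out
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", toupper(atom_name))
  if (nm %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE")) return(nm)
  substr(nm, 1, 1)
}

#' Screen a model for missing heavy atoms
#'
#' Compares every standard residue against a fixed per-residue heavy-atom
#' dictionary (backbone N, CA, C, O plus the canonical side chain; OXT and
#' hydrogens ignored). Non-standard residues are exempt. An empty result
#' means the structure passes the completeness filter; a Calpha-only chain
#' is flagged at every residue.
#'
#' @param model a [structure_model].
#' @return data.frame with one row per violating residue: `chain`, `resno`,
#'   `insert`, `resid`, `missing` (comma-separated atom names).
#' @export
check_atom_completeness <- function(model) {
  rt <- residue_table(model)
  key_all <- residue_key(model$atoms$chain, model$atoms$resno,
                         model$atoms$insert)
  out <- list()
  for (i in seq_len(nrow(rt))) {
    expected <- expected_heavy_atoms(rt$resid[i])
    if (is.null(expected)) next
    have <- model$atoms$elety[key_all == rt$key[i]]
    missing <- setdiff(expected, have)
    if (length(missing) > 0)
      out[[length(out) + 1]] <- data.frame(
        chain = rt$chain[i], resno = rt$resno[i], insert = rt$insert[i],
        resid = rt$resid[i], missing = paste(missing, collapse = ","),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    data.frame(chain = character(), resno = integer(), insert = character(),
               resid = character(), missing = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
}
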