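#' In-memory protein structure model
#'
#' A `structure_model` is the substrate of every pipeline stage: a flat
#' atom table plus entry-level metadata. The atom table mirrors the PDB
#' coordinate section, one row per atom, in file order; residue and chain
#' structure is implied by the (`chain`, `resno`, `insert`) columns.
#'
#' @param atoms data.frame with columns `type` ("ATOM"/"HETATM"), `eleno`,
#'   `elety` (atom name), `alt`, `resid` (3-letter residue name), `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy` (element symbol).
#' @param entry_id 4-character entry code.
#' @param method experimental method, one of `"xray"`, `"em"`, `"nmr"`,
#'   `"other"`, `"unknown"`.
#' @param resolution resolution in Angstrom, or `NULL` when not reported.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, entry_id = "XXXX", method = "unknown",
                            resolution = NULL) {
  stopifnot(is.data.frame(atoms))
  required <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!grepl("^[A-Za-z0-9]{4}$", entry_id))
    stop("entry_id must be a 4-character alphanumeric code, got '", entry_id, "'")
  method <- match.arg(method, c("xray", "em", "nmr", "other", "unknown"))
  if (!is.null(resolution)) {
    resolution <- as.numeric(resolution)
    if (!is.finite(resolution) || resolution <= 0)
      stop("resolution must be a positive number")
  }
  defaults <- list(type = "ATOM", eleno = NA_integer_, alt = "",
                   insert = "", o = 1, b = 0, elesy = "")
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  if (nrow(atoms) > 0 && any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (nrow(atoms) > 0 && any(!nzchar(atoms$elety)))
    stop("atom names must be non-empty")
  atoms$eleno <- if (all(is.na(atoms$eleno))) seq_len(nrow(atoms)) else atoms$eleno
  rownames(atoms) <- NULL
  structure(list(entry_id = entry_id,
                 atoms = atoms,
                 metadata = list(method = method, resolution = resolution)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<structure_model %s: %d chain(s), %d residues, %d atoms>\n",
              x$entry_id, length(chain_ids(x)), nrow(rt), nrow(x$atoms)))
  for (ch in chain_ids(x)) {
    n <- sum(rt$chain == ch)
    cat(sprintf("  chain %s: %d residues\n", ch, n))
  }
  cat(sprintf("  method: %s; resolution: %s\n", x$metadata$method,
              if (is.null(x$metadata$resolution)) "absent"
              else sprintf("%.2f A", x$metadata$resolution)))
  invisible(x)
}

#' @export
is.structure_model <- function(x) inherits(x, "structure_model")

#' Chain identifiers of a model, in order of first appearance
#' @param model a `structure_model`.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

# Stable residue key: chain|resno|insert. Used everywhere a residue must
# be identified across transformed copies of the same model.
residue_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = "|")
}

#' Residue-level view of a model
#'
#' One row per residue in atom order, with the residue key used
#' throughout the package.
#'
#' @param model a `structure_model`.
#' @param chains optional chain subset.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `key`, `natoms`.
#' @export
residue_table <- function(model, chains = NULL) {
  a <- model$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      key = character(), natoms = integer(),
                      stringsAsFactors = FALSE))
  key <- residue_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resid = a$resid[first],
                    key = key[first], stringsAsFactors = FALSE)
  out$natoms <- as.integer(table(factor(key, levels = out$key)))
  rownames(out) <- NULL
  out
}

#' Subset a model by chain
#' @param model a `structure_model`.
#' @param chains chain identifiers to keep.
#' @export
subset_chains <- function(model, chains) {
  keep <- model$atoms$chain %in% chains
  out <- model
  out$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

# Subset a model to the residues named by `keys` (residue_key values).
subset_residues <- function(model, keys) {
  k <- residue_key(model$atoms$chain, model$atoms$resno, model$atoms$insert)
  out <- model
  out$atoms <- model$atoms[k %in% keys, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Atom coordinates as a matrix
#' @param model a `structure_model`.
#' @param sel optional logical/integer row selection into the atom table.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(model, sel = NULL) {
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Apply a rigid transform x -> x R^T + t to (a subset of) the model.
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0),
                            chains = NULL) {
  sel <- if (is.null(chains)) rep(TRUE, nrow(model$atoms))
         else model$atoms$chain %in% chains
  xyz <- coords(model, sel)
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  model$atoms[sel, c("x", "y", "z")] <- xyz
  model
}

# Merge several models' atoms into one (metadata from the first).
merge_models <- function(models, entry_id = models[[1]]$entry_id) {
  atoms <- do.call(rbind, lapply(models, function(m) m$atoms))
  atoms$eleno <- seq_len(nrow(atoms))
  structure_model(atoms, entry_id = entry_id,
                  method = models[[1]]$metadata$method,
                  resolution = models[[1]]$metadata$resolution)
}

# One-letter sequence of a chain (X for non-standard residues).
chain_sequence <- function(model, chain) {
  rt <- residue_table(model, chain)
  paste(aa_three_to_one(rt$resid), collapse = "")
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa_three_to_one <- function(resid) {
  i <- match(toupper(resid), AA3)
  out <- AA1[i]
  out[is.na(out)] <- "X"
  out
}
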