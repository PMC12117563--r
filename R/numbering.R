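# Antibody variable-domain identification and Martin-scheme numbering.
# Numbering itself is delegated to a pluggable engine: a function taking a
# one-letter sequence and returning zero or more domain hits. The package
# ships a deterministic table-driven engine (exact known domain sequences,
# used by every test through the fixture ground truth) and a parser for
# externally produced tabular numbering output, so no numbering binary is
# required at run time.

#' Default CDR spans under Martin numbering
#'
#' Kabat-style intervals: H1 31-35, H2 50-65, H3 95-102; L1 24-34,
#' L2 50-56, L3 89-97. Span membership is decided on the Martin number,
#' so inserted residues (e.g. 100A) fall in the span of their parent
#' number.
#'
#' @param domain_type `"VH"` or `"VL"`.
#' @return named list of three `c(lo, hi)` integer intervals.
#' @export
default_cdr_spans <- function(domain_type) {
  switch(domain_type,
         VH = list(cdr1 = c(31L, 35L), cdr2 = c(50L, 65L),
                   cdr3 = c(95L, 102L)),
         VL = list(cdr1 = c(24L, 34L), cdr2 = c(50L, 56L),
                   cdr3 = c(89L, 97L)),
         stop("domain_type must be VH or VL"))
}

#' Table-driven numbering engine
#'
#' Builds a numbering engine from a list of known domain sequences. A
#' query chain is scanned for exact (substring) occurrences of each
#' registered sequence; every occurrence yields one hit carrying the
#' registered per-residue Martin positions, offset to the occurrence.
#' Hits are returned in order of their start position.
#'
#' @param entries list of `list(sequence, domain_type, positions)` where
#'   `positions` is a data.frame with columns `seq_idx` (1-based within
#'   the domain sequence), `martin_num`, `martin_ins`.
#' @return a function `engine(sequence) -> list of hits`, each hit a
#'   `list(domain_type, start, positions)` with `positions$seq_idx`
#'   1-based within the query sequence.
#' @export
table_numbering_engine <- function(entries) {
  for (e in entries) {
    stopifnot(is.character(e$sequence), e$domain_type %in% c("VH", "VL"),
              is.data.frame(e$positions))
    if (is.unsorted(e$positions$seq_idx, strictly = TRUE))
      stop("engine table positions must be strictly increasing in seq_idx")
  }
  function(sequence) {
    hits <- list()
    for (e in entries) {
      starts <- gregexpr(e$sequence, sequence, fixed = TRUE)[[1]]
      if (starts[1] == -1) next
      for (s in starts) {
        pos <- e$positions
        pos$seq_idx <- pos$seq_idx + s - 1L
        hits[[length(hits) + 1]] <- list(domain_type = e$domain_type,
                                         start = s, positions = pos)
      }
    }
    hits[order(vapply(hits, function(h) h$start, numeric(1)))]
  }
}

#' Parse externally produced tabular numbering output into an engine hit
#'
#' Reads whitespace-separated lines `<chain_type> <number><insertion?>
#' <aa>` (comment lines starting with `#` and `//` separators ignored), the
#' tabular layout emitted by profile-HMM antibody numbering tools. Gap
#' rows (`-`) are dropped. The result can be registered in a
#' [table_numbering_engine()] or used directly.
#'
#' @param path text file of tabular numbering output.
#' @return list of `list(sequence, domain_type, positions)` entries.
#' @export
read_numbering_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|//|$)", lines)]
  out <- list()
  cur <- NULL
  flush <- function(cur, out) {
    if (is.null(cur) || length(cur$aa) == 0) return(out)
    keep <- cur$aa != "-"
    pos <- data.frame(seq_idx = seq_len(sum(keep)),
                      martin_num = cur$num[keep],
                      martin_ins = cur$ins[keep], stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- list(
      sequence = paste(cur$aa[keep], collapse = ""),
      domain_type = cur$type, positions = pos)
    out
  }
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 3) stop("malformed numbering line: ", ln)
    type <- toupper(f[1])
    type <- if (type %in% c("H", "VH")) "VH"
            else if (type %in% c("L", "K", "VL")) "VL"
            else stop("unknown chain type in numbering line: ", ln)
    num <- as.integer(gsub("[A-Za-z]", "", f[2]))
    ins <- gsub("[0-9]", "", f[2])
    if (!is.null(cur) && (type != cur$type || (length(cur$num) > 0 &&
        num < cur$num[length(cur$num)]))) {
      out <- flush(cur, out)
      cur <- NULL
    }
    if (is.null(cur)) cur <- list(type = type, num = integer(),
                                  ins = character(), aa = character())
    cur$num <- c(cur$num, num)
    cur$ins <- c(cur$ins, toupper(ins))
    cur$aa <- c(cur$aa, toupper(f[3]))
  }
  flush(cur, out)
}

new_numbered_domain <- function(chain_id, domain_type, number_map,
                                cdr_spans = default_cdr_spans(domain_type)) {
  stopifnot(domain_type %in% c("VH", "VL"))
  if (anyDuplicated(residue_key(chain_id, number_map$resno,
                                number_map$insert)))
    stop("number_map maps the same source residue twice")
  structure(list(chain_id = chain_id, domain_type = domain_type,
                 number_map = number_map, cdr_spans = cdr_spans),
            class = "numbered_domain")
}

#' @export
print.numbered_domain <- function(x, ...) {
  cat(sprintf("<numbered_domain %s on chain %s: %d residues, Martin %d-%d>\n",
              x$domain_type, x$chain_id, nrow(x$number_map),
              min(x$number_map$martin_num), max(x$number_map$martin_num)))
  invisible(x)
}

#' Detect antibody variable domains on every chain of a model
#'
#' Extracts each chain's one-letter sequence, queries the numbering
#' engine, and converts engine hits into numbered domains whose
#' `number_map` links original residue identifiers to Martin positions.
#' A chain on which the engine fails is skipped with a warning; chains
#' with no hit are antigen candidates.
#'
#' @param model a [structure_model].
#' @param engine a numbering engine, e.g. [table_numbering_engine()].
#' @param cdr_spans function(domain_type) giving CDR intervals; defaults
#'   to [default_cdr_spans()].
#' @return list of `numbered_domain` objects.
#' @export
detect_domains <- function(model, engine,
                           cdr_spans = default_cdr_spans) {
  domains <- list()
  for (ch in chain_ids(model)) {
    rt <- residue_table(model, ch)
    seq_str <- paste(aa_three_to_one(rt$resid), collapse = "")
    hits <- tryCatch(engine(seq_str), error = function(e) {
      warning("numbering engine failed on chain ", ch, ": ",
              conditionMessage(e))
      list()
    })
    for (h in hits) {
      idx <- h$positions$seq_idx
      if (any(idx < 1 | idx > nrow(rt)))
        stop("engine hit references positions outside chain ", ch)
      if (is.unsorted(h$positions$martin_num, strictly = FALSE))
        stop("engine returned non-monotone numbering on chain ", ch)
      nm <- data.frame(resno = rt$resno[idx], insert = rt$insert[idx],
                       martin_num = h$positions$martin_num,
                       martin_ins = h$positions$martin_ins,
                       stringsAsFactors = FALSE)
      domains[[length(domains) + 1]] <-
        new_numbered_domain(ch, h$domain_type, nm,
                            cdr_spans(h$domain_type))
    }
  }
  domains
}

#' Classify the antibody format of an entry
#'
#' @param domains list of `numbered_domain` (from [detect_domains()]).
#' @return one of `"paired"`, `"heavy_only"`, `"light_only"`, `"scfv"`,
#'   `"unusual"`, `"none"`. A chain carrying two same-type domains (a
#'   double variable domain) makes the entry `"unusual"`; a chain with one
#'   VH and one VL is an scFv.
#' @export
classify_format <- function(domains) {
  if (length(domains) == 0) return("none")
  chains <- vapply(domains, function(d) d$chain_id, character(1))
  types <- vapply(domains, function(d) d$domain_type, character(1))
  for (ch in unique(chains)) {
    t_ch <- types[chains == ch]
    if (any(table(t_ch) >= 2)) return("unusual")
  }
  multi <- unique(chains[duplicated(chains)])
  if (length(multi) > 0) return("scfv")
  has_vh <- any(types == "VH")
  has_vl <- any(types == "VL")
  if (has_vh && has_vl) "paired"
  else if (has_vh) "heavy_only"
  else "light_only"
}

#' Renumber a chain to Martin positions, trimming to the variable region
#'
#' Returns a model containing only the residues covered by the domain's
#' number map (constant regions and scFv linkers are trimmed away),
#' renumbered to Martin positions with insertion letters.
#'
#' @param model a [structure_model] containing the domain's chain.
#' @param domain a `numbered_domain`.
#' @param new_chain_id optional replacement chain id.
#' @return a single-chain [structure_model] of the renumbered variable
#'   region.
#' @export
renumber_to_martin <- function(model, domain, new_chain_id = NULL) {
  a <- model$atoms[model$atoms$chain == domain$chain_id, , drop = FALSE]
  if (nrow(a) == 0) stop("chain ", domain$chain_id, " absent from model")
  src_key <- residue_key(domain$chain_id, domain$number_map$resno,
                         domain$number_map$insert)
  atom_key <- residue_key(a$chain, a$resno, a$insert)
  if (!all(src_key %in% atom_key))
    stop("number_map references residues absent from chain ",
         domain$chain_id, ": ",
         paste(setdiff(src_key, atom_key), collapse = ", "))
  keep <- atom_key %in% src_key
  a <- a[keep, , drop = FALSE]
  i <- match(residue_key(a$chain, a$resno, a$insert), src_key)
  a$resno <- domain$number_map$martin_num[i]
  a$insert <- domain$number_map$martin_ins[i]
  if (!is.null(new_chain_id)) a$chain <- new_chain_id
  out <- model
  out$atoms <- a
  rownames(out$atoms) <- NULL
  out
}

# Is Martin position (num) inside any of the domain's CDR spans?
in_cdr_span <- function(martin_num, cdr_spans) {
  hit <- rep(FALSE, length(martin_num))
  for (s in cdr_spans) hit <- hit | (martin_num >= s[1] & martin_num <= s[2])
  hit
}

#' CDR residues of a Martin-renumbered chain
#'
#' @param domain a `numbered_domain`.
#' @param model the Martin-renumbered model holding the domain's chain
#'   (as returned by [renumber_to_martin()]); residue numbers must be
#'   Martin positions.
#' @param chain_id chain to read; defaults to the domain's chain.
#' @return residue table (see [residue_table()]) of exactly the residues
#'   whose Martin number falls in a CDR span, with a `cdr` label column.
#' @export
cdr_residues <- function(domain, model, chain_id = domain$chain_id) {
  rt <- residue_table(model, chain_id)
  lab <- rep(NA_character_, nrow(rt))
  for (nm in names(domain$cdr_spans)) {
    s <- domain$cdr_spans[[nm]]
    lab[rt$resno >= s[1] & rt$resno <= s[2]] <- nm
  }
  out <- rt[!is.na(lab), , drop = FALSE]
  out$cdr <- lab[!is.na(lab)]
  rownames(out) <- NULL
  out
}
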