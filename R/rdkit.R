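# Bridge to RDKit for the cheminformatics primitives (canonical SMILES,
# descriptors, circular-fingerprint environments, substructure matching,
# BRICS). The package ships a small JSON-in/JSON-out python helper and
# shells out to the `python` interpreter on PATH (configurable via
# `options(rpiglue.python = ...)`).

rdkit_python <- function() {
  getOption("rpiglue.python", Sys.getenv("RPIGLUE_PYTHON", "python"))
}

rdkit_script <- function() {
  p <- system.file("python", "rdkit_ops.py", package = "rpiglue")
  if (p == "") abort("rdkit_ops.py not found in installed package")
  p
}

#' Is the RDKit bridge available?
#' @return Logical scalar.
#' @export
rdkit_available <- function() {
  ok <- tryCatch({
    out <- suppressWarnings(system2(rdkit_python(),
      c("-c", shQuote("import rdkit")), stdout = FALSE, stderr = FALSE))
    identical(out, 0L)
  }, error = function(e) FALSE)
  isTRUE(ok)
}

rdkit_call <- function(op, payload) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(rdkit_python(),
    c(rdkit_script(), op, fin, fout), stdout = FALSE, stderr = ""))
  if (!identical(status, 0L) || !file.exists(fout)) {
    abort(paste0("RDKit bridge call '", op, "' failed; is python with rdkit on PATH?"))
  }
  jsonlite::fromJSON(fout, simplifyVector = TRUE, simplifyMatrix = TRUE)
}

#' Canonicalize SMILES strings
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES; errors on unparseable input.
#' @export
canonical_smiles <- function(smiles) {
  res <- rdkit_call("canonical", list(smiles = as.list(smiles)))$canonical
  if (!is.list(res)) res <- as.list(res)
  res <- unlist(lapply(res, function(x) {
    if (is.null(x) || is.na(x)) NA_character_ else as.character(x)
  }))
  if (anyNA(res)) {
    abort(paste0("unparseable SMILES: ",
      paste(smiles[is.na(res)], collapse = ", ")))
  }
  res
}

#' Compute physicochemical descriptors from SMILES
#'
#' Computes the descriptor set consumed by [physchem_filter()]: LogP,
#' molecular mass, N+O count, NH+OH count, TPSA, rotatable bonds, aromatic
#' carbocycle/heterocycle/ring counts and the fraction of sp3 carbons.
#'
#' @param smiles Character vector (or tibble with `smiles` and optionally
#'   `compound_id` columns).
#' @return A tibble with `compound_id`, `smiles` and one column per
#'   descriptor.
#' @export
compound_descriptors <- function(smiles) {
  if (is.data.frame(smiles)) {
    ids <- smiles$compound_id %||% paste0("cmpd_", seq_len(nrow(smiles)))
    smi <- smiles$smiles
  } else {
    ids <- names(smiles) %||% paste0("cmpd_", seq_along(smiles))
    smi <- unname(smiles)
  }
  res <- rdkit_call("descriptors", list(smiles = as.list(smi)))
  out <- as_tibble(lapply(res, function(col) {
    unlist(lapply(col, function(x) x %||% NA_real_))
  }))
  if (anyNA(out$mass)) {
    abort(paste0("unparseable SMILES: ",
      paste(smi[is.na(out$mass)], collapse = ", ")))
  }
  bind_cols(tibble(compound_id = ids, smiles = smi), out)
}

#' Read a SMILES file
#'
#' One molecule per line, optionally followed by a tab- or space-separated
#' identifier.
#'
#' @param path File path.
#' @return Tibble with `compound_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  tibble(
    compound_id = map_chr(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("cmpd_", i)
    }),
    smiles = map_chr(parts, 1)
  )
}

#' Write a SMILES file
#' @param compounds Tibble with `smiles` and optionally `compound_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(compounds, path) {
  c <- as_tibble(compounds)
  lines <- if ("compound_id" %in% names(c)) {
    paste(c$smiles, c$compound_id, sep = "\t")
  } else c$smiles
  writeLines(lines, path)
  invisible(path)
}
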