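#' Read a protein-RNA complex from a PDB file
#'
#' Parses `ATOM`/`HETATM` records from a fixed-width PDB (v3.3 columns) file
#' into a tidy atom table, one row per atom. Multi-model files (NMR-style or
#' trajectory dumps bracketed by `MODEL`/`ENDMDL`) yield one frame per model
#' in the `model` column. Chains are classified as protein, RNA, water, ion,
#' ligand or other by a majority vote over residue names (modified residues
#' count towards their parent type), and each atom is annotated with its
#' element, standard atomic mass, Bondi van der Waals radius, backbone flag
#' and heavy-atom flag.
#'
#' Alternate locations are resolved by keeping the conformer with the highest
#' occupancy; ties go to altloc `"A"`. When the element column is blank the
#' element is inferred from the atom name.
#'
#' @param path Path to a PDB file.
#' @param source_id Identifier stored on the result; defaults to the file
#'   name without extension.
#' @return A tibble of class `rpi_complex` with columns `serial`, `name`,
#'   `resname`, `chain`, `resno`, `x`, `y`, `z`, `occupancy`, `element`,
#'   `model`, `kind`, `mass`, `vdw_radius`, `is_backbone`, `is_heavy`.
#' @export
#' @examples
#' cx <- make_complex(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_structure(cx, f)
#' read_structure(f)
read_structure <- function(path, source_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) abort("empty structure: no ATOM/HETATM records")

  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad)) {
    abort(paste0("unparseable record at line ", bad[1], ": '", lines[bad[1]], "'"))
  }

  # model index per line: cumulative count of MODEL records (0 -> model 1)
  model_of_line <- cumsum(is_model)
  model_of_line <- pmax(model_of_line, 1L)

  al <- lines[is_atom]
  f <- function(from, to) substr(al, from, to)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      ln <- which(is_atom)[i]
      abort(paste0("unparseable ", what, " at line ", ln, ": '", lines[ln], "'"))
    }
    v
  }

  atoms <- tibble(
    record = trimws(f(1, 6)),
    serial = as.integer(num(f(7, 11), "serial")),
    name = trimws(f(13, 16)),
    altloc = trimws(f(17, 17)),
    resname = trimws(f(18, 20)),
    chain = trimws(f(22, 22)),
    resno = as.integer(num(f(23, 26), "residue number")),
    x = num(f(31, 38), "x coordinate"),
    y = num(f(39, 46), "y coordinate"),
    z = num(f(47, 54), "z coordinate"),
    occupancy = {
      o <- suppressWarnings(as.numeric(f(55, 60)))
      ifelse(is.na(o), 1, o)
    },
    element = trimws(f(77, 78)),
    model = as.integer(model_of_line[is_atom])
  )
  atoms$element <- ifelse(atoms$element == "",
    infer_element(atoms$name, atoms$record), toupper(atoms$element))

  # altloc resolution: highest occupancy wins, ties prefer 'A'
  if (any(atoms$altloc != "")) {
    atoms <- atoms |>
      group_by(.data$model, .data$chain, .data$resno, .data$resname, .data$name) |>
      arrange(desc(.data$occupancy),
        .data$altloc != "A", .data$altloc, .by_group = TRUE) |>
      slice(1) |>
      ungroup() |>
      arrange(.data$model, .data$serial)
  }
  atoms$altloc <- NULL

  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  as_complex(atoms, source_id = source_id)
}

# Infer an element symbol from a PDB atom name, used when columns 77-78 are
# blank. Two-letter elements are only accepted for HETATM records (ions,
# metals); otherwise the first alphabetic character wins, so " CA " in a
# protein chain is a carbon.
infer_element <- function(name, record = "ATOM") {
  two_letter <- c("FE", "ZN", "MG", "CL", "BR", "NA", "MN", "CU", "NI",
    "CO", "SE", "CA", "K")
  stripped <- gsub("[^A-Za-z]", "", name)
  up <- toupper(stripped)
  first2 <- substr(up, 1, 2)
  el <- substr(up, 1, 1)
  is_ion <- record == "HETATM" & first2 %in% two_letter & nchar(up) == 2
  el[is_ion] <- first2[is_ion]
  el
}

#' Annotate a raw atom table as a complex
#'
#' Adds chain typing (majority vote over residue names), masses, van der
#' Waals radii and backbone/heavy flags to a data frame of atoms and returns
#' an `rpi_complex` tibble. Used by [read_structure()] and the fixture
#' generators; call it directly when assembling atoms programmatically.
#'
#' @param atoms Data frame with at least `name`, `resname`, `chain`, `resno`,
#'   `x`, `y`, `z`, `element` columns; `model`, `serial` and `record` are
#'   filled in when absent.
#' @param source_id Identifier stored as an attribute.
#' @return An `rpi_complex` tibble.
#' @export
as_complex <- function(atoms, source_id = "complex") {
  atoms <- as_tibble(atoms)
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"record" %in% names(atoms)) atoms$record <- "ATOM"
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
    all(is.finite(atoms$z)))

  kind_map <- atoms |>
    filter(.data$model == .data$model[1]) |>
    distinct(.data$chain, .data$resno, .data$resname) |>
    mutate(vote = residue_vote(.data$resname)) |>
    group_by(.data$chain) |>
    summarise(kind = majority_kind(.data$vote), .groups = "drop")

  atoms <- atoms |>
    select(-any_of("kind")) |>
    left_join(kind_map, by = "chain") |>
    mutate(
      kind = ifelse(is.na(.data$kind), "other", .data$kind),
      mass = element_mass(.data$element),
      vdw_radius = element_vdw_radius(.data$element),
      is_heavy = toupper(.data$element) != "H",
      is_backbone = is_backbone_name(.data$name, .data$kind)
    )
  new_complex(atoms, source_id)
}

residue_vote <- function(resname) {
  dplyr::case_when(
    resname %in% .protein_residues ~ "protein",
    resname %in% .rna_residues ~ "rna",
    resname %in% .water_residues ~ "water",
    resname %in% .ion_residues ~ "ion",
    TRUE ~ "ligand"
  )
}

majority_kind <- function(votes) {
  priority <- c("protein", "rna", "ligand", "water", "ion")
  tab <- table(factor(votes, levels = priority))
  names(tab)[which.max(tab)]
}

new_complex <- function(atoms, source_id = "complex") {
  structure(atoms, class = c("rpi_complex", class(tibble())),
    source_id = source_id)
}

#' @export
print.rpi_complex <- function(x, ...) {
  ck <- x |> distinct(.data$chain, .data$kind)
  cat("<rpi_complex> ", attr(x, "source_id"), ": ",
    nrow(x[x$model == x$model[1], ]), " atoms, ",
    length(unique(x$model)), " model(s), chains: ",
    paste0(ck$chain, " (", ck$kind, ")", collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Write a complex to a PDB file
#'
#' Emits fixed-width PDB v3.3 `ATOM`/`HETATM` records; multi-model tables are
#' bracketed by `MODEL`/`ENDMDL`. Output is byte-deterministic for a given
#' atom table, which the fixture generators rely on.
#'
#' @param atoms An `rpi_complex` or compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  atoms <- as_tibble(atoms)
  if (!"record" %in% names(atoms)) {
    atoms$record <- ifelse(atoms$kind %in% c("protein", "rna"), "ATOM", "HETATM")
  }
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  models <- sort(unique(atoms$model))
  multi <- length(models) > 1
  con <- file(path, "wb")
  on.exit(close(con))
  for (m in models) {
    a <- atoms[atoms$model == m, ]
    out <- sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record, a$serial %% 100000L, format_atom_name(a$name, a$element), "",
      substr(a$resname, 1, 3), substr(a$chain, 1, 1), a$resno %% 10000L,
      a$x, a$y, a$z, a$occupancy, 0, substr(toupper(a$element), 1, 2))
    if (multi) out <- c(sprintf("MODEL     %4d", m), out, "ENDMDL")
    writeLines(out, con)
  }
  writeLines("END", con)
  invisible(path)
}

# PDB atom-name alignment: one-letter elements start in column 14,
# two-letter elements in column 13.
format_atom_name <- function(name, element) {
  el <- toupper(element)
  ifelse(nchar(el) >= 2 | nchar(name) >= 4,
    sprintf("%-4s", substr(name, 1, 4)),
    sprintf(" %-3s", name))
}

#' Extract one model (frame) from a complex
#'
#' @param atoms An `rpi_complex`.
#' @param model Model number to keep.
#' @return An `rpi_complex` with a single model.
#' @export
get_model <- function(atoms, model = 1L) {
  out <- atoms[atoms$model == model, ]
  new_complex(out, attr(atoms, "source_id"))
}
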