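# Element property tables used throughout: standard atomic masses (Da) and
# Bondi van der Waals radii (Angstrom). Unknown elements fall back to the
# carbon defaults (12.011 Da is not used there; mass falls back to 12.011 so
# mass-weighted quantities stay defined, radius to 1.7 A).

.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA. = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, SE = 78.971, BR = 79.904, I = 126.904
)

.element_vdw <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, NA. = 2.27, K = 2.75,
  MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.70, MN = 1.70, CU = 1.40, NI = 1.63
)

.norm_element <- function(element) {
  e <- toupper(trimws(element))
  e[e == "NA"] <- "NA."
  e
}

element_mass <- function(element) {
  m <- .element_masses[.norm_element(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

element_vdw_radius <- function(element) {
  r <- .element_vdw[.norm_element(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Residue-name vocabularies for chain typing. Modified residues are mapped to
# their parent type through a small alias table; the vote is by majority.
.protein_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common modified residues counted as protein
  "MSE", "SEP", "TPO", "PTR", "HYP", "CSO", "PCA", "MLY", "HIC", "KCX"
)

.rna_residues <- c(
  "A", "U", "G", "C", "I",
  "RA", "RU", "RG", "RC",
  # common modified ribonucleotides counted as RNA
  "PSU", "1MA", "5MC", "5MU", "7MG", "2MG", "M2G", "OMC", "OMG", "H2U", "4SU"
)

.water_residues <- c("HOH", "WAT", "TIP", "TIP3", "SPC", "SOL", "DOD")

.ion_residues <- c(
  "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "FE2", "CO", "NI", "CU",
  "BR", "IOD", "CS", "LI", "SR", "BA", "CD"
)

# Backbone atom names used for alignment selections: protein N/CA/C/O plus
# the RNA phosphate-ribose backbone.
.protein_backbone <- c("N", "CA", "C", "O")
.rna_backbone <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

is_backbone_name <- function(name, kind) {
  (kind == "protein" & name %in% .protein_backbone) |
    (kind == "rna" & name %in% .rna_backbone)
}
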