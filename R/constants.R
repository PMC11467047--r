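# Scoring constants, chemical tables and classification thresholds.

#' Scoring constants
#'
#' Bundle of the distance cutoffs, scaling parameters and atom-name sets used
#' throughout interface scoring. The two scaling parameters `a` (iRMSD) and
#' `b` (LRMSD) were calibrated so that the combined score tracks the CAPRI
#' quality classes; they are fixed by the method definition and should not
#' normally be changed.
#'
#' @param a iRMSD scaling parameter in Angstrom (default 1.5).
#' @param b LRMSD scaling parameter in Angstrom (default 8.5).
#' @param contact_cutoff Heavy-atom distance (Angstrom) below which two
#'   residues in different chains are in contact (default 5.0).
#' @param contact_cutoff_peptide Contact cutoff used when either chain of the
#'   pair is a peptide (default 4.0).
#' @param interface_cutoff All-heavy-atom distance (Angstrom) defining
#'   interface residues for the iRMSD (default 10.0).
#' @param interface_cutoff_peptide_cb Cbeta-Cbeta distance defining interface
#'   residues when either chain is a peptide (default 8.0); Calpha substitutes
#'   for glycine.
#' @param clash_cutoff Inter-chain heavy-atom distance (Angstrom) below which
#'   an atom pair is counted as a clash (default 2.0, about the shortest
#'   covalent bond length, so non-bonded atoms cannot physically be closer).
#' @param peptide_max_len Maximum residue count for a polymer chain of amino
#'   acids to be classified as a peptide (default 20).
#' @param identity_threshold Minimum sequence identity over the aligned region
#'   for two chains to be considered copies of the same subunit (default 0.9).
#' @param covalent_tolerance Slack (Angstrom) added to the sum of covalent
#'   radii when inferring bonds in small molecules (default 0.4).
#' @param match_cap Maximum number of ligand-graph isomorphisms enumerated
#'   before giving up and asking for a user-supplied mapping (default 10000).
#'
#' @return A list of class `cqa_constants`.
#' @export
#' @examples
#' cst <- scoring_constants()
#' cst$a
scoring_constants <- function(a = 1.5,
                              b = 8.5,
                              contact_cutoff = 5.0,
                              contact_cutoff_peptide = 4.0,
                              interface_cutoff = 10.0,
                              interface_cutoff_peptide_cb = 8.0,
                              clash_cutoff = 2.0,
                              peptide_max_len = 20L,
                              identity_threshold = 0.9,
                              covalent_tolerance = 0.4,
                              match_cap = 10000L) {
  stopifnot(a > 0, b > 0, contact_cutoff > 0, contact_cutoff_peptide > 0,
            interface_cutoff > 0, interface_cutoff_peptide_cb > 0,
            clash_cutoff > 0, peptide_max_len >= 1)
  structure(list(
    a = a, b = b,
    contact_cutoff = contact_cutoff,
    contact_cutoff_peptide = contact_cutoff_peptide,
    interface_cutoff = interface_cutoff,
    interface_cutoff_peptide_cb = interface_cutoff_peptide_cb,
    clash_cutoff = clash_cutoff,
    peptide_max_len = as.integer(peptide_max_len),
    identity_threshold = identity_threshold,
    covalent_tolerance = covalent_tolerance,
    match_cap = as.integer(match_cap),
    protein_backbone = c("N", "CA", "C", "O"),
    nucleic_backbone = c("P", "OP1", "OP2",
                         "O2'", "O3'", "O4'", "O5'",
                         "C1'", "C2'", "C3'", "C4'", "C5'"),
    # CAPRI class boundaries on the combined score, half-open:
    # [0, .23) Incorrect, [.23, .49) Acceptable, [.49, .80) Medium, [.80, 1] High
    capri_thresholds = c(Acceptable = 0.23, Medium = 0.49, High = 0.80)
  ), class = "cqa_constants")
}

# Molecule classes ------------------------------------------------------------

MOLECULE_CLASSES <- c("PROTEIN", "PEPTIDE", "NUCLEIC", "SMALL_MOLECULE")

# 3-letter -> 1-letter amino acid codes (standard residues)
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Common modified residues mapped to their parent one-letter code; anything
# polymeric but unknown becomes 'X'.
AA_MODIFIED_TO_ONE <- c(
  MSE = "M", CSO = "C", SEP = "S", TPO = "T", PTR = "Y",
  HYP = "P", MLY = "K", CME = "C", KCX = "K", PCA = "Q"
)

# Nucleotide component codes (DNA and RNA) -> one-letter
NUC_TO_ONE <- c(
  DA = "A", DC = "C", DG = "G", DT = "T", DU = "U", DI = "I",
  A = "A", C = "C", G = "G", U = "U", I = "I"
)

WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

# Single-bond covalent radii in Angstrom (Cordero et al. 2008 consensus
# values; low-spin radii for the transition metals with two reported values).
COVALENT_RADII <- c(
  H = 0.31, D = 0.31, HE = 0.28,
  LI = 1.28, BE = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  NE = 0.58, "NA" = 1.66, MG = 1.41, AL = 1.21, SI = 1.11, P = 1.07, S = 1.05,
  CL = 1.02, AR = 1.06, K = 2.03, CA = 1.76, SC = 1.70, TI = 1.60, V = 1.53,
  CR = 1.39, MN = 1.39, FE = 1.32, CO = 1.26, NI = 1.24, CU = 1.32, ZN = 1.22,
  GA = 1.22, GE = 1.20, AS = 1.19, SE = 1.20, BR = 1.20, KR = 1.16,
  RB = 2.20, SR = 1.95, Y = 1.90, ZR = 1.75, NB = 1.64, MO = 1.54,
  RU = 1.46, RH = 1.42, PD = 1.39, AG = 1.45, CD = 1.44, IN = 1.42,
  SN = 1.39, SB = 1.39, TE = 1.38, I = 1.39, XE = 1.40,
  CS = 2.44, BA = 2.15, W = 1.62, RE = 1.51, OS = 1.44, IR = 1.41,
  PT = 1.36, AU = 1.36, HG = 1.32, TL = 1.45, PB = 1.46, BI = 1.48
)

# Two-character element symbols we recognize when inferring elements from
# atom names (uppercase).
TWO_LETTER_ELEMENTS <- setdiff(names(COVALENT_RADII)[nchar(names(COVALENT_RADII)) == 2L],
                               c())
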