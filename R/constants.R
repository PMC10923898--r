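## Residue-level constant tables used across the feature modules.
## All tables are keyed by one-letter amino-acid code.

AA1 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))

## Kyte-Doolittle hydropathy; features use the localCIDER normalisation
## (KD + 4.5) / 9, which maps the scale onto [0, 1].
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

## Zimmerman (1968) polarity scale.
ZIMMERMAN_POLARITY <- c(
  A = 0.00, R = 52.00, N = 3.38, D = 49.70, C = 1.48, E = 49.90,
  Q = 3.53, G = 0.00, H = 51.60, I = 0.13, L = 0.13, K = 49.50,
  M = 1.43, F = 0.35, P = 1.58, S = 1.67, T = 1.66, W = 2.10,
  Y = 1.61, V = 0.13)

## Average residue masses (Da); a peptide adds one water.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

## ExPASy-style (Bjellqvist) pKa values for the isoelectric-point bisection.
PKA_SET <- list(
  nterm = 9.094, cterm = 2.869,
  positive = c(K = 10.0, R = 12.0, H = 5.98),
  negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0))

## Maximum accessible surface areas (A^2) for RSA normalisation.
## "tien2013": theoretical values of Tien et al. 2013; "sander1994":
## Sander & Rost 1994 (selectable because the upstream normalisation
## table is not uniquely determined).
MAX_ASA <- list(
  tien2013 = c(
    A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
    G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
    P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174),
  sander1994 = c(
    A = 106, R = 248, N = 157, D = 163, C = 135, E = 194, Q = 198,
    G = 84, H = 184, I = 169, L = 164, K = 205, M = 188, F = 197,
    P = 136, S = 130, T = 142, W = 227, Y = 222, V = 142))

## Element van der Waals radii (A) for SASA; heavy atoms only.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Amino-acid property groups
#'
#' The fifteen residue groups used for compositional features: Asx, Glx,
#' Xle, positively/negatively charged, aromatic, aliphatic, small,
#' hydrophilic, hydrophobic, alpha-helix/beta-turn/beta-sheet propensity,
#' aromaticity, and charged.
#'
#' @return Named list of character vectors of one-letter residue codes.
#' @export
aa_groups <- function() {
  list(
    Asx = c("D", "N"),
    Glx = c("E", "Q"),
    Xle = c("I", "L"),
    Pos_charged = c("K", "R", "H"),
    Neg_charged = c("D", "E"),
    Aromatic = c("F", "W", "Y", "H"),
    Aliphatic = c("V", "I", "L", "M"),
    Small = c("P", "G", "A", "S"),
    Hydrophilic = c("S", "T", "H", "N", "Q", "E", "D", "K", "R"),
    Hydrophobic = c("V", "I", "L", "F", "W", "Y", "M"),
    Alpha_helix = c("V", "I", "Y", "F", "W", "L"),
    Beta_turn = c("N", "P", "G", "S"),
    Beta_sheet = c("E", "M", "A", "L"),
    Aromaticity = c("F", "W", "Y"),
    Charged = c("K", "R", "D", "E"))
}
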