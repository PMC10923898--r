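## structure_io: AlphaFold-dialect PDB reading/writing and eligibility rules.

#' Construct a protein model
#'
#' Low-level constructor used by the PDB parser and the fixture generator.
#' A protein model is a single-chain structure with 1-based contiguous
#' residue numbering, a per-residue pLDDT (from the PDB B-factor column)
#' and an atom table.
#'
#' @param id protein identifier.
#' @param sequence one-letter amino-acid string.
#' @param atoms data.frame with columns `residue` (1-based index), `name`
#'   (atom label), `element`, `x`, `y`, `z` (angstrom).
#' @param plddt numeric vector, one value in \[0, 100\] per residue.
#' @return An object of class `protein_model` with fields `id`, `sequence`,
#'   `n`, `plddt`, `atoms` and `ca` (n x 3 matrix of C-alpha coordinates).
#' @export
new_protein_model <- function(id, sequence, atoms, plddt) {
  n <- nchar(sequence)
  stopifnot(is.data.frame(atoms),
            all(c("residue", "name", "element", "x", "y", "z") %in%
                  names(atoms)))
  if (length(plddt) != n)
    stop("plddt length (", length(plddt), ") != sequence length (", n, ")")
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100))
    stop("pLDDT values must be finite and in [0, 100]")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (!setequal(unique(atoms$residue), seq_len(n)))
    stop("atom table does not cover residues 1..", n, " exactly")
  ca <- matrix(NA_real_, n, 3)
  is_ca <- atoms$name == "CA"
  ca_rows <- atoms[is_ca, , drop = FALSE]
  if (anyDuplicated(ca_rows$residue))
    stop("duplicate CA atom in residue ",
         ca_rows$residue[duplicated(ca_rows$residue)][1])
  missing_ca <- setdiff(seq_len(n), ca_rows$residue)
  if (length(missing_ca))
    stop("missing CA atom in residue ", missing_ca[1])
  ca[ca_rows$residue, ] <- as.matrix(ca_rows[, c("x", "y", "z")])
  structure(list(id = id, sequence = sequence, n = n, plddt = plddt,
                 atoms = atoms, ca = ca),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> %s: %d residues, %d atoms, mean pLDDT %.1f\n",
              x$id, x$n, nrow(x$atoms), mean(x$plddt)))
  invisible(x)
}

infer_element <- function(name) {
  # strip digits/spaces; the leading letter of a heavy-atom label is the
  # element for the standard amino-acid atom set (C, N, O, S)
  first <- substr(gsub("[0-9 ]", "", name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S"), first, "C")
}

#' Parse an AlphaFold-dialect PDB file
#'
#' Reads ATOM records of a single-chain PDB model. Residues are renumbered
#' 1..N in order of appearance; per-residue pLDDT is taken from the
#' B-factor column. HETATM records and altLoc values other than blank/'A'
#' are ignored.
#'
#' @param path path to a PDB file.
#' @param id protein identifier; defaults to the file name without the
#'   AlphaFold `AF-...-F1-model_vN` decoration if present.
#' @param extra_aa3 optional named character vector mapping additional
#'   3-letter residue names to 1-letter codes (e.g. `c(MSE = "M")`).
#' @return A [new_protein_model()] object.
#' @export
read_pdb <- function(path, id = NULL, extra_aa3 = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  at <- lines[rec == "ATOM  "]
  if (!length(at)) stop("no ATOM records in ", path)

  altloc <- substr(at, 17, 17)
  at <- at[altloc %in% c(" ", "A")]
  chain <- substr(at, 22, 22)
  if (length(unique(chain)) > 1)
    stop("multi-chain files are unsupported (chains: ",
         paste(unique(chain), collapse = ","), ")")

  name <- trimws(substr(at, 13, 16))
  res3 <- trimws(substr(at, 18, 20))
  resseq <- trimws(paste0(substr(at, 23, 26), substr(at, 27, 27)))
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  bfac <- as.numeric(substr(at, 61, 66))
  elem <- trimws(substr(at, 77, 78))
  elem[elem == ""] <- infer_element(name[elem == ""])

  map <- c(AA3TO1, extra_aa3)
  unknown <- setdiff(unique(res3), names(map))
  if (length(unknown))
    stop("non-standard residue(s): ", paste(unknown, collapse = ", "),
         "; supply extra_aa3 to map them")

  # renumber residues sequentially in order of appearance
  ridx <- match(resseq, unique(resseq))
  n <- max(ridx)
  aa <- character(n)
  plddt <- numeric(n)
  for (i in seq_len(n)) {
    sel <- ridx == i
    r3 <- unique(res3[sel])
    if (length(r3) > 1) stop("conflicting residue names at position ", i)
    aa[i] <- map[[r3]]
    b <- bfac[sel]
    if (diff(range(b)) > 1e-6) {
      # AlphaFold writes one pLDDT per residue; disagreement means a
      # foreign file -- fall back to the CA value
      cab <- b[name[sel] == "CA"]
      warning("B-factors differ within residue ", i, " of ", path,
              "; using CA value")
      plddt[i] <- if (length(cab)) cab[1] else b[1]
    } else {
      plddt[i] <- b[1]
    }
  }
  if (any(plddt < 0 | plddt > 100))
    stop("B-factor column is not a pLDDT in [0, 100]")

  atoms <- data.frame(residue = ridx, name = name,
                      element = elem, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  if (is.null(id)) {
    id <- sub("\\.pdb$", "", basename(path))
    id <- sub("^AF-([A-Z0-9]+)-F[0-9]+-model_v[0-9]+$", "\\1", id)
  }
  new_protein_model(id, paste(aa, collapse = ""), atoms, plddt)
}

#' Write a protein model as a PDB file
#'
#' Emits a normalized single-chain PDB (chain A, sequential numbering,
#' pLDDT in the B-factor column) that [read_pdb()] round-trips exactly.
#'
#' @param model a `protein_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  res3 <- AA1TO3[strsplit(model$sequence, "")[[1]]]
  lines <- sprintf(
    "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    formatC(ifelse(nchar(a$name) >= 4, a$name, paste0(" ", a$name)),
            width = -4),
    res3[a$residue], "A", a$residue, a$x, a$y, a$z, 1,
    model$plddt[a$residue], a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Sequence-length eligibility rule
#'
#' AlphaFold models proteins longer than 2699 residues only as overlapping
#' fragments, and very short chains carry little structural signal, so the
#' training protocol keeps proteins with 100 < N < 2700 only.
#'
#' @param model a `protein_model`, or an integer length.
#' @return `TRUE` iff the protein length is strictly between 100 and 2700.
#' @export
length_eligible <- function(model) {
  n <- if (inherits(model, "protein_model")) model$n else as.integer(model)
  n > 100 && n < 2700
}
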