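#' Parse a (multi-)model PDB file into a structure ensemble
#'
#' Reads ATOM records via `bio3d::read.pdb`. Files with MODEL/ENDMDL blocks
#' yield one model per block (all models must share the same atom set, as
#' ensembles from conformational simulations do); files without MODEL
#' keywords yield a single model. Hydrogens are excluded by default,
#' matching contact counting on all non-hydrogen atoms of X-ray structures.
#'
#' @param path Path to a PDB file, or a character vector of PDB lines.
#' @param keep_hydrogens Logical; retain hydrogen atoms.
#' @return Object of class `structure_ensemble`: list with `atoms` (data
#'   frame: `chain`, `residue_number`, `residue_name`, `atom_name`,
#'   `element`), `xyz` (matrix, one row per model, columns x1,y1,z1,x2,...)
#'   and `n_models`.
#' @export
parse_ensemble <- function(path, keep_hydrogens = FALSE) {
  if (length(path) > 1L || !file.exists(path)) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(as.character(path), tmp)
    on.exit(unlink(tmp))
    path <- tmp
  }
  pdb <- try(suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
             silent = TRUE)
  if (inherits(pdb, "try-error") || is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("empty structure: no ATOM records could be parsed", call. = FALSE)
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM")
  if (!keep_hydrogens) {
    elem <- trimws(at$elesy)
    elem[is.na(elem) | elem == ""] <- substr(gsub("^[0-9]", "", trimws(at$elety[is.na(at$elesy) | at$elesy == ""])), 1, 1)
    keep <- keep & toupper(elem) != "H"
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("empty structure: no atoms left after filtering", call. = FALSE)
  atoms <- data.frame(chain = at$chain[idx],
                      residue_number = at$resno[idx],
                      residue_name = at$resid[idx],
                      atom_name = trimws(at$elety[idx]),
                      element = toupper(trimws(at$elesy[idx])),
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  structure(list(atoms = atoms, xyz = xyz[, cols, drop = FALSE],
                 n_models = nrow(xyz)),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d model(s), %d atoms, chains: %s\n",
              x$n_models, nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

## Coordinates of model m as an (n_atoms x 3) matrix.
.model_coords <- function(ensemble, m) {
  matrix(ensemble$xyz[m, ], ncol = 3, byrow = TRUE)
}

#' Inter-chain atom-atom contacts in one model
#'
#' All atom pairs between `chain_a` (peptide side) and `chain_b` (protein
#' side) with Euclidean distance less than or equal to `cutoff` (inclusive
#' boundary at exactly the cutoff). Distances are computed by exhaustive
#' pairwise evaluation.
#'
#' @param ensemble A [parse_ensemble()] result.
#' @param chain_a Peptide chain identifier.
#' @param chain_b Protein chain identifier.
#' @param cutoff Contact distance in Angstrom (default 4.0).
#' @param model_id Model index (1-based).
#' @return Data frame: `model_id`, `peptide_residue`, `peptide_atom`,
#'   `protein_residue`, `protein_atom`, `distance`.
#' @export
interchain_contacts <- function(ensemble, chain_a, chain_b, cutoff = 4.0,
                                model_id = 1L) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  ia <- which(ensemble$atoms$chain == chain_a)
  ib <- which(ensemble$atoms$chain == chain_b)
  if (length(ia) == 0L) stop("chain not found: ", chain_a, call. = FALSE)
  if (length(ib) == 0L) stop("chain not found: ", chain_b, call. = FALSE)
  if (model_id < 1L || model_id > ensemble$n_models)
    stop("model_id out of range", call. = FALSE)
  co <- .model_coords(ensemble, model_id)
  a <- co[ia, , drop = FALSE]; b <- co[ib, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(model_id = integer(), peptide_residue = integer(),
                      peptide_atom = character(), protein_residue = integer(),
                      protein_atom = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(model_id = model_id,
             peptide_residue = ensemble$atoms$residue_number[ia[hit[, 1]]],
             peptide_atom = ensemble$atoms$atom_name[ia[hit[, 1]]],
             protein_residue = ensemble$atoms$residue_number[ib[hit[, 2]]],
             protein_atom = ensemble$atoms$atom_name[ib[hit[, 2]]],
             distance = sqrt(d2[hit]),
             stringsAsFactors = FALSE)
}

#' Inter-chain contacts across all models of an ensemble
#'
#' @inheritParams interchain_contacts
#' @param residue_range Optional integer vector of peptide residue numbers
#'   to keep (e.g. `1:15` to drop residues unresolved in a reference
#'   structure); NULL keeps all.
#' @return Row-bound contact records of every model.
#' @export
ensemble_contacts <- function(ensemble, chain_a, chain_b, cutoff = 4.0,
                              residue_range = NULL) {
  out <- do.call(rbind, lapply(seq_len(ensemble$n_models), function(m)
    interchain_contacts(ensemble, chain_a, chain_b, cutoff, model_id = m)))
  if (!is.null(residue_range))
    out <- out[out$peptide_residue %in% residue_range, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position-to-sum contact statistics per peptide residue
#'
#' For each peptide residue over a model ensemble: `position_contacts`
#' counts distinct contact positions (unique `(peptide_atom,
#' protein_residue, protein_atom)` triples observed in any model),
#' `sum_contacts` counts every occurrence across all models, and the
#' position-to-sum ratio is `sum / positions` (0 for residues with no
#' contacts). A ratio of 1 means every contact pair occurred in exactly one
#' model; above 1, some pair recurred in several models.
#'
#' @param contacts Data frame from [ensemble_contacts()].
#' @param peptide_residues Optional integer vector of residues that must
#'   appear in the output (ratio 0 if contact-free).
#' @return Data frame: `peptide_residue`, `position_contacts`,
#'   `sum_contacts`, `ratio`.
#' @export
position_to_sum <- function(contacts, peptide_residues = NULL) {
  stopifnot(is.data.frame(contacts))
  res <- sort(unique(c(contacts$peptide_residue, peptide_residues)))
  rows <- lapply(res, function(r) {
    cc <- contacts[contacts$peptide_residue == r, , drop = FALSE]
    if (nrow(cc) == 0L)
      return(data.frame(peptide_residue = r, position_contacts = 0L,
                        sum_contacts = 0L, ratio = 0))
    key <- paste(cc$peptide_atom, cc$protein_residue, cc$protein_atom, sep = "|")
    pos <- length(unique(key))
    data.frame(peptide_residue = r, position_contacts = pos,
               sum_contacts = nrow(cc), ratio = nrow(cc) / pos)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify peptide residues by their position-to-sum ratio
#'
#' @param summaries Data frame from [position_to_sum()].
#' @return The input with a `class` column: `"none"` (ratio 0, no
#'   contacts), `"unique"` (ratio 1, all contacts seen once) or
#'   `"recurrent"` (ratio > 1).
#' @export
classify_residues <- function(summaries) {
  stopifnot(is.data.frame(summaries), "ratio" %in% names(summaries))
  summaries$class <- ifelse(summaries$ratio == 0, "none",
                            ifelse(summaries$ratio > 1, "recurrent", "unique"))
  summaries
}
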