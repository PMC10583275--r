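# Structure handling: PDB reading via bio3d, amide-proton placement,
# atom selection.  A structure_model is a plain data.frame with columns
# chain, resno, resid, elety, x, y, z and a "model_label" attribute.

#' Create a structure model
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @param label model label (e.g. the PDB ID and chain).
#' @return data.frame of class `structure_model`.
#' @export
structure_model <- function(atoms, label = "model") {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing))
    stop("structure_model: missing columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0) stop("structure_model: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("structure_model: non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("structure_model: duplicate (chain, residue, atom) records: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  atoms <- atoms[, need]
  rownames(atoms) <- NULL
  structure(atoms, class = c("structure_model", "data.frame"),
            model_label = label)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, %d residues, chains: %s\n",
              attr(x, "model_label"), nrow(x),
              length(unique(paste(x$chain, x$resno))),
              paste(unique(x$chain), collapse = " ")))
  invisible(x)
}

# elements retained from HETATM records (paramagnetic/diamagnetic metals)
METAL_ELEMENTS <- c("TB", "TM", "Y", "DY", "HO", "ER", "YB", "LU", "GD",
                    "EU", "LA", "CE", "ZN", "CA", "MG", "MN", "FE", "CO",
                    "NI", "CU")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (plus HETATM metal ions), resolves alternate
#' locations to the highest-occupancy copy, and optionally restricts to one
#' chain. Waters and other heteroatoms are discarded.
#'
#' @param pdb_source path to a PDB file.
#' @param chain_filter optional chain identifier (e.g. `"A"`).
#' @param label model label; defaults to the file name (plus chain).
#' @return a [structure_model()].
#' @export
read_structure <- function(pdb_source, chain_filter = NULL, label = NULL) {
  lines <- readLines(pdb_source, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop(sprintf("malformed coordinate field at line %d of %s", i,
                   pdb_source))
  }
  pdb <- bio3d::read.pdb(pdb_source, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" |
    (at$type == "HETATM" & toupper(trimws(at$elesy %||% "")) %in% METAL_ELEMENTS)
  at <- at[keep & at$resid != "HOH", , drop = FALSE]
  if (!is.null(chain_filter)) {
    at <- at[at$chain %in% chain_filter, , drop = FALSE]
    if (nrow(at) == 0)
      stop(sprintf("no atoms selected: chain filter '%s' matches nothing in %s",
                   paste(chain_filter, collapse = ","), pdb_source))
  }
  if (nrow(at) == 0) stop("no atoms parsed from ", pdb_source)
  # altloc: keep the highest-occupancy copy per (chain, resno, elety),
  # preserving file order otherwise
  occ <- ifelse(is.na(at$o), 1, at$o)
  file_order <- seq_len(nrow(at))
  ord <- order(at$chain, at$resno, at$elety, -occ)
  at <- at[ord, , drop = FALSE]
  keep_rows <- !duplicated(paste(at$chain, at$resno, at$elety))
  at <- at[keep_rows, , drop = FALSE]
  at <- at[order(file_order[ord][keep_rows]), , drop = FALSE]
  if (is.null(label))
    label <- paste(c(basename(pdb_source), chain_filter), collapse = ":")
  structure_model(data.frame(chain = at$chain, resno = at$resno,
                             resid = at$resid, elety = trimws(at$elety),
                             x = at$x, y = at$y, z = at$z,
                             stringsAsFactors = FALSE),
                  label = label)
}

#' Write a structure model as a PDB file
#'
#' @param model a [structure_model()].
#' @param path output file.
#' @param b optional per-atom B-factor column (numeric, recycled).
#' @param hetatm write HETATM instead of ATOM records.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, b = 0, hetatm = FALSE) {
  b <- rep_len(b, nrow(model))
  rec <- if (hetatm) "HETATM" else "ATOM  "
  name <- ifelse(nchar(model$elety) < 4, sprintf(" %-3s", model$elety),
                 sprintf("%-4s", model$elety))
  lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   rec, seq_len(nrow(model)) %% 100000, name,
                   substr(model$resid, 1, 3), substr(model$chain, 1, 1),
                   model$resno %% 10000, model$x, model$y, model$z, 1, b)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Place backbone amide protons
#'
#' Crystal structures usually lack hydrogens; backbone-amide PCS fitting
#' needs them. For every non-proline residue with backbone N and CA present
#' and a preceding residue providing C, an H atom is added on the nitrogen
#' at 1.02 Angstrom along the external bisector of the C(i-1)-N-CA angle
#' (in the peptide plane, anti to both heavy-atom neighbours). Residues
#' that already carry an H are left untouched; chain starts and residues
#' with a missing predecessor are skipped with a warning.
#'
#' @param model a [structure_model()].
#' @return a new `structure_model` including the added `H` atoms.
#' @export
place_amide_protons <- function(model) {
  key <- function(chain, resno, elety) paste(chain, resno, elety, sep = "|")
  idx <- stats::setNames(seq_len(nrow(model)),
                         key(model$chain, model$resno, model$elety))
  pos <- function(k) unlist(model[idx[[k]], c("x", "y", "z")], use.names = FALSE)
  added <- list()
  skipped <- 0L
  has_n <- which(model$elety == "N" & model$resid != "PRO")
  for (i in has_n) {
    ch <- model$chain[i]; rn <- model$resno[i]
    if (key(ch, rn, "H") %in% names(idx)) next
    kca <- key(ch, rn, "CA"); kc <- key(ch, rn - 1, "C")
    if (!(kca %in% names(idx))) next
    if (!(kc %in% names(idx))) { skipped <- skipped + 1L; next }
    n <- pos(key(ch, rn, "N")); ca <- pos(kca); cprev <- pos(kc)
    u <- -unit(unit(cprev - n) + unit(ca - n))
    h <- n + 1.02 * u
    added[[length(added) + 1L]] <-
      data.frame(chain = ch, resno = rn, resid = model$resid[i],
                 elety = "H", x = h[1], y = h[2], z = h[3],
                 stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    warning(sprintf("place_amide_protons: %d residue(s) skipped (no preceding C)",
                    skipped))
  if (length(added) == 0) return(model)
  out <- rbind(as.data.frame(model), do.call(rbind, added))
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  structure_model(out, label = attr(model, "model_label"))
}

#' Select atoms by residue number and atom name
#'
#' Order-preserving lookup of `(resno, elety)` selectors. Missing selectors
#' are reported in the `"missing"` attribute (and a warning), never
#' silently dropped; duplicate selectors are deduplicated with a warning.
#'
#' @param model a [structure_model()].
#' @param selectors data.frame with columns `resno` and `elety`.
#' @return the matching rows of `model`, in selector order, with attribute
#'   `"missing"` holding any unmatched selectors.
#' @export
select_atoms <- function(model, selectors) {
  stopifnot(all(c("resno", "elety") %in% names(selectors)))
  skey <- paste(selectors$resno, selectors$elety)
  if (anyDuplicated(skey)) {
    warning("select_atoms: duplicate selectors deduplicated")
    selectors <- selectors[!duplicated(skey), , drop = FALSE]
    skey <- skey[!duplicated(skey)]
  }
  mkey <- paste(model$resno, model$elety)
  m <- match(skey, mkey)
  miss <- selectors[is.na(m), , drop = FALSE]
  if (nrow(miss) > 0)
    warning(sprintf("select_atoms: %d selector(s) not found: %s",
                    nrow(miss),
                    paste(utils::head(paste(miss$resno, miss$elety), 5),
                          collapse = ", ")))
  out <- as.data.frame(model)[m[!is.na(m)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- miss
  out
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])
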