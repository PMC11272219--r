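#' Write an atomic model to PDB format
#'
#' Emits a CRYST1 record (space group P 1) followed by fixed-column ATOM/HETATM
#' records per the PDB v3.3 layout. Conformer tags go into the altLoc column,
#' occupancies and isotropic B-factors into their standard columns, and
#' fractional coordinates are orthogonalized with the cell's PDB-convention
#' matrix. Waters (atoms named "WAT*" or residue HOH) are written as HETATM.
#'
#' @param model An [atomic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  cell <- model$cell
  at <- model$atoms
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
  cart <- frac_to_cart(cell, as.matrix(at[, c("fx", "fy", "fz")]))
  is_wat <- grepl("^WAT", at$name) | grepl("^HOH", at$name)
  resname <- ifelse(is_wat, "HOH", "ALA")
  record <- ifelse(is_wat, "HETATM", "ATOM  ")
  # stable residue numbering: atoms sharing a name share a residue across
  # conformers so altloc pairs line up
  resno <- match(at$name, unique(at$name))
  name4 <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
                  sprintf(" %-3s", at$name))
  alt <- substr(at$conformer, 1, 1)
  lines <- c(lines, sprintf(
    "%s%5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, seq_len(nrow(at)), name4, alt, resname, "A", resno,
    cart[, 1], cart[, 2], cart[, 3], at$occ, at$b_iso,
    formatC(toupper(at$element), width = 2, flag = " ")))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read an atomic model from PDB format
#'
#' Parses CRYST1 and ATOM/HETATM records (fixed columns, PDB v3.3): altLoc
#' becomes the conformer tag (blank mapped to "A"), occupancy and B-factor come
#' from their standard columns, and Cartesian coordinates are converted to
#' fractional with the CRYST1 cell. The element is taken from columns 77-78,
#' falling back to the first letter of the atom name.
#'
#' @param path Path to a PDB file containing a CRYST1 record.
#' @param label Label for the returned model; defaults to the file name.
#' @return An [atomic_model()].
#' @export
read_pdb <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr) == 0) stop("PDB file has no CRYST1 record: ", path)
  cr <- cr[1]
  cell <- unit_cell(
    a = as.numeric(substr(cr, 7, 15)), b = as.numeric(substr(cr, 16, 24)),
    c = as.numeric(substr(cr, 25, 33)), alpha = as.numeric(substr(cr, 34, 40)),
    beta = as.numeric(substr(cr, 41, 47)), gamma = as.numeric(substr(cr, 48, 54)))
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(rec) == 0) stop("PDB file has no ATOM/HETATM records: ", path)
  name <- trimws(substr(rec, 13, 16))
  alt <- substr(rec, 17, 17)
  alt[alt == " "] <- "A"
  xyz <- cbind(as.numeric(substr(rec, 31, 38)),
               as.numeric(substr(rec, 39, 46)),
               as.numeric(substr(rec, 47, 54)))
  occ <- as.numeric(substr(rec, 55, 60))
  b <- as.numeric(substr(rec, 61, 66))
  elem <- trimws(substr(rec, 77, 78))
  elem[elem == ""] <- substr(name[elem == ""], 1, 1)
  frac <- cart_to_frac(cell, xyz)
  atomic_model(cell, atom_table(name, elem, frac, b_iso = b, occ = occ,
                                conformer = alt), label = label)
}
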