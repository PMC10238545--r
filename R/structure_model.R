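# Structure container and PDB/mmCIF I/O (bio3d-backed), plus named
# residue-range selections used for switch-region exclusion.

#' Construct a structure model
#'
#' A light container for atomic coordinates: a data frame of ATOM
#' records (chain, residue number, residue name, atom name, element,
#' x/y/z in Angstrom), an optional data frame of HETATM records kept
#' separately (ligands, ions, waters are excluded from all backbone
#' operations), and a metadata string.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`.
#' @param het optional data frame of HETATM records, same columns.
#' @param metadata title or accession string.
#' @return an object of class `"structure_model"`.
#' @export
structure_model <- function(atoms, het = NULL, metadata = "") {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms)[need]
  atoms$resno <- as.integer(atoms$resno)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("atom positions must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate atom record: ", key[duplicated(key)][1])
  rn <- unique(atoms[c("chain", "resno", "resname")])
  if (anyDuplicated(paste(rn$chain, rn$resno)))
    stop("residue numbers must be unique within a chain")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, het = het, metadata = metadata),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms, %d residues, chain(s) %s%s\n",
              nrow(x$atoms), length(unique(x$atoms$resno)),
              paste(unique(x$atoms$chain), collapse = ","),
              if (nzchar(x$metadata)) paste0(" [", x$metadata, "]") else ""))
  if (!is.null(x$het) && nrow(x$het))
    cat(sprintf("  + %d HETATM records (excluded from backbone operations)\n",
                nrow(x$het)))
  invisible(x)
}

#' Residue numbers present in a structure
#' @param x a `"structure_model"`.
#' @return sorted integer vector of author residue numbers.
#' @export
residue_numbers <- function(x) sort(unique(x$atoms$resno))

# coordinates of one named atom for each requested residue (NA rows
# where absent)
.atom_xyz <- function(x, resno, atom) {
  a <- x$atoms[x$atoms$atom == atom, ]
  m <- match(resno, a$resno)
  cbind(a$x[m], a$y[m], a$z[m])
}

#' Read a structure from PDB or mmCIF
#'
#' Parses all ATOM records of the selected chain; HETATM records are
#' retained separately and never enter backbone operations.  When
#' alternate locations are present, the highest-occupancy location of
#' each atom is kept.  Hydrogens are not required: they are
#' reconstructed geometrically where needed (see
#' [build_bond_vectors()]).
#'
#' @param path file path; format chosen by extension (`.pdb` vs
#'   `.cif`/`.mmcif`).
#' @param chain chain identifier; defaults to the first chain in the
#'   file.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE,
                                     rm.alt = FALSE))
  } else if (ext %in% c("pdb", "ent", "")) {
    suppressMessages(bio3d::read.pdb(path, verbose = FALSE,
                                     rm.alt = FALSE))
  } else stop("unknown structure format: .", ext)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[at$type == "ATOM"][1]
  if (is.na(chain)) stop("file contains no ATOM records (empty chain)")
  sel <- at$type == "ATOM" & at$chain %in% chain
  if (!any(sel)) stop("empty chain: ", chain)
  a <- at[sel, ]
  # resolve alternate locations: keep highest occupancy per atom
  o <- ifelse(is.na(a$o), 1, a$o)
  ord <- order(a$resno, a$elety, -o)
  a <- a[ord, ]
  a <- a[!duplicated(paste(a$resno, a$elety)), ]
  a <- a[order(a$resno, as.integer(rownames(a))), ]
  hsel <- at$type == "HETATM" & at$chain %in% chain
  het <- if (any(hsel)) {
    h <- at[hsel, ]
    data.frame(chain = h$chain, resno = h$resno, resname = h$resid,
               atom = h$elety, element = h$elesy, x = h$x, y = h$y,
               z = h$z, stringsAsFactors = FALSE)
  } else NULL
  structure_model(
    data.frame(chain = a$chain, resno = a$resno, resname = a$resid,
               atom = a$elety, element = a$elesy,
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE),
    het = het, metadata = basename(path))
}

#' Write a structure to PDB
#'
#' Coordinates are written at PDB precision (3 decimals), so
#' `read_structure(write_structure(x))` preserves atom count, names,
#' numbering and coordinates to 0.001 Angstrom.
#'
#' @param x a [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure_model"))
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$atom, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Named inclusive residue-range selections
#'
#' Region selections (for example the conformationally variable switch
#' regions) are named lists of inclusive residue ranges in author
#' numbering.  The defaults are the RAS switch regions: Switch I
#' residues 30-38 and Switch II residues 59-76.
#'
#' @param ... named ranges, each a length-2 integer vector
#'   `c(first, last)`.
#' @return an object of class `"region_selection"`.
#' @export
region_selection <- function(...) {
  r <- list(...)
  if (length(r) == 0)
    r <- list(switch1 = c(30L, 38L), switch2 = c(59L, 76L))
  if (is.null(names(r)) || any(!nzchar(names(r))))
    stop("all regions must be named")
  for (v in r) {
    if (length(v) != 2 || v[2] < v[1])
      stop("each region must be c(first, last) with last >= first")
  }
  structure(r, class = "region_selection")
}

#' Residues covered by a region selection
#' @param regions a [region_selection()] (or NULL for none).
#' @return integer vector of residue numbers (possibly empty).
#' @export
region_residues <- function(regions) {
  if (is.null(regions)) return(integer(0))
  sort(unique(unlist(lapply(regions, function(v) seq(v[1], v[2])))))
}

#' Reporting-set residues used for cross-validation visualization
#'
#' The residue set whose bond vectors reorient most between the ground
#' and excited states, used when summarizing cross-validation
#' improvements: residues 7, 13-15, 23-29, 43-54, 60-63, 73-81, 86,
#' 92-95, 105-113, 120-124, 137-140, 144-150.
#'
#' @return integer vector of residue numbers.
#' @export
reporting_residues <- function() {
  sort(unique(c(7L, 13:15, 23:29, 43:54, 60:63, 73:81, 86L, 92:95,
                105:113, 120:124, 137:140, 144:150)))
}
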