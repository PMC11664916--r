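## Structure reading/writing and the two structure-level preparations:
## locating the flavin frame and truncating the bound fatty acid.

.err <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "catalocavity_error")))
}

.elementFromName <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(s, 1L, 2L))
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "SE")
  ifelse(two %in% known2, two, toupper(substr(s, 1L, 1L)))
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (fixed wwPDB columns, via bio3d) into a
#' [ProteinStructure-class]. Alternate locations are resolved by keeping
#' the highest-occupancy copy of each atom, ties going to altloc "A";
#' record order is otherwise preserved verbatim, including residue
#' numbers.
#'
#' @param path path to a PDB-format text file.
#' @param dropWaters drop HOH/WAT residues (default `TRUE`).
#' @param id structure identifier; defaults to the file name without
#'   extension.
#' @return A [ProteinStructure-class].
#' @examples
#' toy <- makeToyEnzyme(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(toy$structure, f)
#' s <- readStructure(f)
#' nAtoms(s)
#' @export
readStructure <- function(path, dropWaters = TRUE,
                          id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path))
    .err("catalocavity_io_error", paste("cannot read file:", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e)
      .err("catalocavity_format_error",
           paste0("no atoms could be parsed from '", path, "': ",
                  conditionMessage(e))))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    .err("catalocavity_format_error",
         paste("no ATOM/HETATM records in", path))
  occ <- at$o
  occ[is.na(occ)] <- 1
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(key, -occ, alt, seq_len(nrow(at)))
  keepKey <- !duplicated(key[ord])
  keepRows <- sort(ord[keepKey])
  at <- at[keepRows, , drop = FALSE]
  occ <- occ[keepRows]
  elem <- toupper(trimws(at$elesy))
  bad <- is.na(elem) | !nzchar(elem)
  if (any(bad)) elem[bad] <- .elementFromName(at$elety[bad])
  df <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elem,
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM", occ = occ,
    stringsAsFactors = FALSE)
  if (dropWaters) df <- df[!(df$resname %in% c("HOH", "WAT", "DOD")), ,
                           drop = FALSE]
  if (nrow(df) == 0L)
    .err("catalocavity_format_error",
         paste("no atoms left after water removal in", path))
  rownames(df) <- NULL
  new("ProteinStructure", atoms = df, id = id)
}

#' Write a structure to a PDB file
#'
#' @param s a [ProteinStructure-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(s, path) {
  a <- atoms(s)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain, o = a$occ,
    b = rep(0, nrow(a)), elesy = a$element, end = TRUE)
  invisible(path)
}

#' Apply a rigid transform to a structure
#'
#' Coordinates become `R x + t`; everything else is untouched.
#'
#' @param s a [ProteinStructure-class].
#' @param R 3 x 3 rotation matrix.
#' @param t numeric(3) translation (Angstrom).
#' @return The transformed [ProteinStructure-class].
#' @export
transformStructure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  a <- atoms(s)
  xyz <- .applyTransform(as.matrix(a[, c("x", "y", "z")]), R, t)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("ProteinStructure", atoms = a, id = s@id)
}

.RING_ATOMS <- c("N5", "N10", "C4A", "C5A", "C9A", "C10")

#' Locate the flavin cofactor and derive its anchor frame
#'
#' Finds the named flavin residue, fits a least-squares plane through the
#' isoalloxazine core atoms (`N5`, `N10`, `C4A`, `C5A`, `C9A`, `C10`;
#' minimum four present), and returns the [FlavinFrame-class]: N5
#' position, ring centroid, unit ring normal. The normal's sign is fixed
#' so that it points toward the substrate: with a `ligand` given, toward
#' the ligand carboxyl carbon; otherwise away from the protein atom
#' centroid (the larger cavity half-space).
#'
#' @param s a [ProteinStructure-class].
#' @param residueName flavin residue code (default `"FAD"`).
#' @param ligand optional [LigandSpec-class] used for the normal's sign
#'   convention.
#' @return A [FlavinFrame-class].
#' @examples
#' toy <- makeToyEnzyme(seed = 1)
#' locateFlavin(toy$structure, ligand = toy$ligand)
#' @export
locateFlavin <- function(s, residueName = "FAD", ligand = NULL) {
  a <- atoms(s)
  fa <- a[a$resname == residueName, , drop = FALSE]
  if (nrow(fa) == 0L)
    .err("catalocavity_cofactor_error",
         paste0("no residue '", residueName, "' in structure '", s@id, "'"))
  first <- paste(fa$chain[1L], fa$resno[1L])
  fa <- fa[paste(fa$chain, fa$resno) == first, , drop = FALSE]
  ring <- fa[fa$name %in% .RING_ATOMS, , drop = FALSE]
  if (!"N5" %in% ring$name || nrow(ring) < 4L)
    .err("catalocavity_cofactor_error",
         sprintf("isoalloxazine core incomplete in '%s': need N5 and >= 4 of {%s}",
                 s@id, paste(.RING_ATOMS, collapse = ", ")))
  X <- as.matrix(ring[, c("x", "y", "z")])
  centroid <- colMeans(X)
  sv <- svd(sweep(X, 2L, centroid))
  if (sv$d[2] < 1e-6)
    .err("catalocavity_cofactor_error",
         sprintf("ring atoms of '%s' are collinear; no plane defined", s@id))
  normal <- sv$v[, 3L]
  refdir <- NULL
  if (!is.null(ligand)) {
    la <- .ligandAtoms(a, ligand)
    cc <- la[la$name == ligand@carboxylCarbon, , drop = FALSE]
    if (nrow(cc) == 1L)
      refdir <- as.numeric(cc[1L, c("x", "y", "z")]) - centroid
  }
  if (is.null(refdir)) {
    prot <- a[!a$het & a$element != "H", , drop = FALSE]
    if (nrow(prot) > 0L)
      refdir <- -(colMeans(as.matrix(prot[, c("x", "y", "z")])) - centroid)
  }
  if (!is.null(refdir) && sum(refdir^2) > 0 && sum(normal * refdir) < 0)
    normal <- -normal
  else if (is.null(refdir) || sum(refdir^2) == 0) {
    i <- which.max(abs(normal))
    if (normal[i] < 0) normal <- -normal
  }
  n5 <- as.numeric(fa[fa$name == "N5", c("x", "y", "z")][1L, ])
  FlavinFrame(n5 = n5, ringCentroid = centroid, ringNormal = normal)
}

.ligandAtoms <- function(atomDf, lig) {
  atomDf[atomDf$resname == lig@resname & atomDf$chain == lig@chain &
           atomDf$resno == lig@resno, , drop = FALSE]
}

#' Truncate a long-chain carboxylic-acid ligand
#'
#' Shortens the ligand's aliphatic chain to `keepCarbons` carbons counted
#' from the carboxyl carbon outward (the carboxylate oxygens are always
#' kept), e.g. stearic acid to octanoic acid with `keepCarbons = 8`, so
#' that the cavity procreated around it emphasises the carboxylate-binding
#' region rather than the long apolar tunnel. Hydrogens attached to
#' removed carbons are removed with them; atoms only are removed, no
#' geometry is altered; protein atoms are untouched.
#'
#' @param s a [ProteinStructure-class].
#' @param spec a [LigandSpec-class] describing the ligand.
#' @param keepCarbons number of chain carbons to keep (>= 2, <= chain
#'   length; default 8).
#' @return The truncated [ProteinStructure-class].
#' @examples
#' toy <- makeToyEnzyme(seed = 1, ligandCarbons = 12)
#' t8 <- truncateLigand(toy$structure, toy$ligand, keepCarbons = 8)
#' nAtoms(t8) < nAtoms(toy$structure)
#' @export
truncateLigand <- function(s, spec, keepCarbons = 8L) {
  keepCarbons <- as.integer(keepCarbons)
  nChain <- length(spec@chainCarbons)
  if (keepCarbons < 2L)
    .err("catalocavity_value_error", "keepCarbons must be >= 2")
  if (keepCarbons > nChain)
    .err("catalocavity_value_error",
         sprintf("keepCarbons (%d) exceeds ligand chain length (%d)",
                 keepCarbons, nChain))
  a <- atoms(s)
  isLig <- a$resname == spec@resname & a$chain == spec@chain &
    a$resno == spec@resno
  if (!any(isLig))
    .err("catalocavity_ligand_error",
         sprintf("ligand %s:%s:%d not found in '%s'", spec@resname,
                 spec@chain, spec@resno, s@id))
  if (keepCarbons == nChain) return(s)
  dropC <- spec@chainCarbons[(keepCarbons + 1L):nChain]
  hpat <- paste0("^(", paste0("H", sub("^C", "", dropC), collapse = "|"),
                 ")[0-9A-Z]?$")
  drop <- isLig & (a$name %in% dropC | grepl(hpat, a$name))
  new("ProteinStructure", atoms = a[!drop, , drop = FALSE], id = s@id)
}
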