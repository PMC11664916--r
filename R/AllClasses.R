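## Central S4 containers for the cavity-matching funnel.

.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V","X")

#' ProteinStructure: atoms of a (PDB-derived) structure
#'
#' Thin container around an atom table in the column layout the rest of the
#' package expects. One row per atom: `serial`, `name`, `element`,
#' `resname`, `chain`, `resno`, `x`, `y`, `z`, `het` (logical HETATM flag),
#' `occ` (occupancy). Residue numbers are preserved verbatim from the
#' source file.
#'
#' @slot atoms data.frame of atoms (see above).
#' @slot id character(1) structure identifier.
#' @seealso [readStructure()], [atoms()], [structureId()]
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(atoms = "data.frame", id = "character"),
  prototype(atoms = data.frame(), id = "structure"))

.ATOM_COLS <- c("serial", "name", "element", "resname", "chain", "resno",
                "x", "y", "z", "het", "occ")

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  msg <- character()
  if (!all(.ATOM_COLS %in% names(a)))
    msg <- c(msg, paste("atom table must contain columns:",
                        paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(a) > 0 && all(c("x", "y", "z") %in% names(a))) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      msg <- c(msg, "atom coordinates must be finite")
    if (anyDuplicated(a$serial))
      msg <- c(msg, "atom serials must be unique")
    if (any(!nzchar(a$element)))
      msg <- c(msg, "element symbols must be non-empty")
  }
  if (length(object@id) != 1L)
    msg <- c(msg, "id must be a single string")
  if (length(msg)) msg else TRUE
})

#' FlavinFrame: local reference frame of the flavin isoalloxazine ring
#'
#' The anchor frame every cavity cloud carries: the flavin N5 position (the
#' reference atom for substrate distances), the centroid of the
#' isoalloxazine ring atoms, and the unit normal of the least-squares ring
#' plane. The normal's sign is fixed so that it points toward the substrate
#' side of the ring (see [locateFlavin()]).
#'
#' @slot n5 numeric(3), N5 position in Angstrom.
#' @slot ringCentroid numeric(3), ring-atom centroid in Angstrom.
#' @slot ringNormal numeric(3), unit plane normal.
#' @exportClass FlavinFrame
setClass("FlavinFrame",
  representation(n5 = "numeric", ringCentroid = "numeric",
                 ringNormal = "numeric"))

setValidity("FlavinFrame", function(object) {
  msg <- character()
  for (s in c("n5", "ringCentroid", "ringNormal"))
    if (length(slot(object, s)) != 3L || !all(is.finite(slot(object, s))))
      msg <- c(msg, sprintf("%s must be a finite 3-vector", s))
  if (!length(msg)) {
    if (abs(sqrt(sum(object@ringNormal^2)) - 1) > 1e-9)
      msg <- c(msg, "ringNormal must have unit length (tol 1e-9)")
    if (sqrt(sum((object@n5 - object@ringCentroid)^2)) > 3)
      msg <- c(msg, "n5 must lie within 3 Angstrom of the ring centroid")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FlavinFrame-class
#' @param n5,ringCentroid,ringNormal numeric(3) vectors; `ringNormal` is
#'   normalised to unit length.
#' @return A `FlavinFrame` object.
#' @export
FlavinFrame <- function(n5, ringCentroid, ringNormal) {
  nrm <- sqrt(sum(ringNormal^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("ringNormal must be a non-zero vector")
  new("FlavinFrame", n5 = as.numeric(n5),
      ringCentroid = as.numeric(ringCentroid),
      ringNormal = as.numeric(ringNormal) / nrm)
}

#' LigandSpec: how to find the carboxylic-acid ligand inside a structure
#'
#' Identifies the ligand residue and the carbon-chain topology used for
#' truncation: `chainCarbons` lists the chain carbon atom names from the
#' carboxyl carbon outward (C1 = carboxyl carbon for the synthetic
#' fixtures).
#'
#' @slot resname character(1), 3-character residue code.
#' @slot chain character(1) chain id.
#' @slot resno integer(1) residue number.
#' @slot carboxylCarbon character(1) atom name of the carboxyl carbon.
#' @slot chainCarbons character vector of chain carbon atom names, starting
#'   at the carboxyl carbon, no duplicates.
#' @exportClass LigandSpec
setClass("LigandSpec",
  representation(resname = "character", chain = "character",
                 resno = "integer", carboxylCarbon = "character",
                 chainCarbons = "character"))

setValidity("LigandSpec", function(object) {
  msg <- character()
  if (length(object@chainCarbons) < 1L ||
      object@chainCarbons[1L] != object@carboxylCarbon)
    msg <- c(msg, "chainCarbons[1] must equal carboxylCarbon")
  if (anyDuplicated(object@chainCarbons))
    msg <- c(msg, "chainCarbons must have no duplicates")
  if (length(msg)) msg else TRUE
})

#' @rdname LigandSpec-class
#' @param resname,chain,resno,carboxylCarbon,chainCarbons see slots.
#' @return A `LigandSpec` object.
#' @export
LigandSpec <- function(resname, chain, resno, carboxylCarbon = "C1",
                       chainCarbons = paste0("C", seq_len(8))) {
  new("LigandSpec", resname = as.character(resname),
      chain = as.character(chain), resno = as.integer(resno),
      carboxylCarbon = as.character(carboxylCarbon),
      chainCarbons = as.character(chainCarbons))
}

#' CavityCloud: annotated cavity point cloud ("catalophore")
#'
#' Virtual points filling the empty active-site space, each carrying a
#' five-component property vector: signed `electrostatic` potential,
#' `hbond_donor` and `hbond_acceptor` scores in \[0,1\], `hydrophobicity`
#' in \[0,1\], and `buriedness` in \[0,1\]. The cloud carries the flavin
#' anchor frame used to initialise rigid registration.
#'
#' @slot coords n x 3 numeric matrix of point coordinates (Angstrom).
#' @slot props data.frame with columns `electrostatic`, `hbond_donor`,
#'   `hbond_acceptor`, `hydrophobicity`, `buriedness` (n rows).
#' @slot frame [FlavinFrame-class] anchor frame.
#' @slot gridSpacing numeric(1), grid spacing in Angstrom.
#' @slot sourceId character(1), id of the source structure.
#' @seealso [procreateCavity()], [annotateProperties()]
#' @exportClass CavityCloud
setClass("CavityCloud",
  representation(coords = "matrix", props = "data.frame",
                 frame = "FlavinFrame", gridSpacing = "numeric",
                 sourceId = "character"))

.PROP_COLS <- c("electrostatic", "hbond_donor", "hbond_acceptor",
                "hydrophobicity", "buriedness")

setValidity("CavityCloud", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an n x 3 matrix")
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coords must be finite")
  if (!all(.PROP_COLS %in% names(object@props)))
    msg <- c(msg, paste("props must contain columns:",
                        paste(.PROP_COLS, collapse = ", ")))
  else {
    if (nrow(object@props) != nrow(object@coords))
      msg <- c(msg, "props must have one row per point")
    for (p in setdiff(.PROP_COLS, "electrostatic")) {
      v <- object@props[[p]]
      if (length(v) && (any(v < -1e-9) || any(v > 1 + 1e-9)))
        msg <- c(msg, sprintf("%s must lie in [0,1]", p))
    }
    if (!all(is.finite(object@props$electrostatic)))
      msg <- c(msg, "electrostatic values must be finite")
  }
  if (length(object@gridSpacing) != 1L || object@gridSpacing <= 0)
    msg <- c(msg, "gridSpacing must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' @rdname CavityCloud-class
#' @param coords,props,frame,gridSpacing,sourceId see slots; `props` may be
#'   omitted, in which case an all-zero property table is attached.
#' @return A `CavityCloud` object.
#' @export
CavityCloud <- function(coords, props = NULL, frame, gridSpacing = 0.8,
                        sourceId = "cloud") {
  coords <- as.matrix(coords)
  if (is.null(props)) {
    props <- as.data.frame(setNames(
      rep(list(numeric(nrow(coords))), length(.PROP_COLS)), .PROP_COLS))
  }
  new("CavityCloud", coords = coords, props = as.data.frame(props),
      frame = frame, gridSpacing = as.numeric(gridSpacing),
      sourceId = as.character(sourceId))
}

#' MatchResult: outcome of one template-vs-target cloud registration
#'
#' Holds the rigid transform mapping template coordinates into the target
#' frame, the total score (dissimilarity in \[0,1\], lower is better), the
#' two directional overlap percentages, and the automated triage flags:
#' `flavinSameSide` (is the cofactor on the same side of the matched point
#' cloud?) and `electroOK` (tri-state: does the cloud near N5 stabilise a
#' negative charge? `NA` = inconclusive).
#'
#' @slot rotation 3 x 3 orthonormal matrix.
#' @slot translation numeric(3), Angstrom.
#' @slot totalScore numeric(1) in \[0,1\].
#' @slot overlap12,overlap21 numeric(1), percentages in \[0,100\]
#'   (template in target, target in template).
#' @slot flavinSameSide logical(1).
#' @slot electroOK logical(1), may be `NA`.
#' @slot templateId,targetId character(1).
#' @exportClass MatchResult
setClass("MatchResult",
  representation(rotation = "matrix", translation = "numeric",
                 totalScore = "numeric", overlap12 = "numeric",
                 overlap21 = "numeric", flavinSameSide = "logical",
                 electroOK = "logical", templateId = "character",
                 targetId = "character"))

setValidity("MatchResult", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8)
    msg <- c(msg, "rotation must be 3 x 3 orthonormal (tol 1e-8)")
  for (ov in c(object@overlap12, object@overlap21))
    if (ov < -1e-9 || ov > 100 + 1e-9)
      msg <- c(msg, "overlaps must lie in [0,100]")
  if (object@totalScore < -1e-12)
    msg <- c(msg, "totalScore must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ClusterSet: greedy sequence clustering result
#'
#' @slot clusters named list; each element is a character vector of member
#'   ids whose first element is the representative, and the element name is
#'   the representative id.
#' @slot identityCutoff numeric(1), percent identity cutoff used.
#' @seealso [greedyCluster()]
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(clusters = "list", identityCutoff = "numeric"))

setValidity("ClusterSet", function(object) {
  msg <- character()
  ids <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(ids))
    msg <- c(msg, "every id must appear in exactly one cluster")
  reps <- names(object@clusters)
  ok <- vapply(seq_along(object@clusters),
               function(i) identical(reps[i], object@clusters[[i]][1L]),
               logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "each cluster's representative must be its first member")
  if (length(msg)) msg else TRUE
})

#' ScoreMatrix: candidate x ligand combined docking scores
#'
#' Grid of combined |E/d| docking scores with per-candidate row sums.
#' Missing candidate-ligand pairs score 0 and are flagged in `missing` so
#' that sums stay comparable across candidates with unequal docking
#' coverage.
#'
#' @slot scores numeric matrix, candidates x ligands, all values >= 0.
#' @slot sums named numeric, per-candidate row totals.
#' @slot missing logical matrix, same shape as `scores`.
#' @seealso [buildMatrix()], [topK()]
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  representation(scores = "matrix", sums = "numeric", missing = "matrix"))

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  if (length(object@scores) && any(object@scores < 0))
    msg <- c(msg, "scores must be >= 0")
  if (!identical(dim(object@scores), dim(object@missing)))
    msg <- c(msg, "missing must have the same shape as scores")
  if (nrow(object@scores) > 0) {
    rs <- rowSums(object@scores)
    if (max(abs(rs - object@sums)) > 0)
      msg <- c(msg, "sums must equal row totals exactly")
  }
  if (length(msg)) msg else TRUE
})
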