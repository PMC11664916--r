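#' Accessors for catalocavity S4 classes
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors atom table of a [ProteinStructure-class].
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @describeIn accessors structure identifier.
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @describeIn accessors number of atoms / points / clusters.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn accessors point coordinate matrix of a [CavityCloud-class].
#' @export
setGeneric("pointCoords", function(x) standardGeneric("pointCoords"))

#' @describeIn accessors per-point property table of a [CavityCloud-class].
#' @export
setGeneric("pointProps", function(x) standardGeneric("pointProps"))

#' @describeIn accessors flavin anchor frame of a [CavityCloud-class].
#' @export
setGeneric("cloudFrame", function(x) standardGeneric("cloudFrame"))

#' @describeIn accessors number of points in a [CavityCloud-class].
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @describeIn accessors cluster list of a [ClusterSet-class].
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @describeIn accessors representative ids of a [ClusterSet-class].
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @describeIn accessors score grid of a [ScoreMatrix-class].
#' @export
setGeneric("scoreGrid", function(x) standardGeneric("scoreGrid"))

#' @describeIn accessors per-candidate score sums of a [ScoreMatrix-class].
#' @export
setGeneric("scoreSums", function(x) standardGeneric("scoreSums"))

#' @rdname accessors
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("structureId", "ProteinStructure", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("pointCoords", "CavityCloud", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("pointProps", "CavityCloud", function(x) x@props)

#' @rdname accessors
#' @export
setMethod("cloudFrame", "CavityCloud", function(x) x@frame)

#' @rdname accessors
#' @export
setMethod("nPoints", "CavityCloud", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
setMethod("clusters", "ClusterSet", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("representatives", "ClusterSet", function(x) names(x@clusters))

#' @rdname accessors
#' @export
setMethod("scoreGrid", "ScoreMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("scoreSums", "ScoreMatrix", function(x) x@sums)

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure '", object@id, "': ", nrow(a), " atoms (",
      sum(a$het), " hetero), ",
      length(unique(paste(a$chain, a$resno))), " residues\n", sep = "")
})

setMethod("show", "FlavinFrame", function(object) {
  cat("FlavinFrame: N5 [", paste(sprintf("%.2f", object@n5), collapse = ", "),
      "], normal [", paste(sprintf("%.3f", object@ringNormal),
                           collapse = ", "), "]\n", sep = "")
})

setMethod("show", "CavityCloud", function(object) {
  cat("CavityCloud '", object@sourceId, "': ", nrow(object@coords),
      " points, grid spacing ", object@gridSpacing, " A\n", sep = "")
  if (nrow(object@coords)) {
    e <- object@props$electrostatic
    cat("  electrostatic range [", sprintf("%.3g", min(e)), ", ",
        sprintf("%.3g", max(e)), "], mean buriedness ",
        sprintf("%.2f", mean(object@props$buriedness)), "\n", sep = "")
  }
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf(
    "MatchResult %s -> %s: score %.4f, overlaps %.1f%% / %.1f%%, %s, %s\n",
    object@templateId, object@targetId, object@totalScore,
    object@overlap12, object@overlap21,
    if (isTRUE(object@flavinSameSide)) "flavin same side"
    else "flavin OPPOSITE side",
    if (isTRUE(object@electroOK)) "electro ok"
    else if (is.na(object@electroOK)) "electro inconclusive"
    else "electro NOT stabilizing"))
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet: ", length(object@clusters), " clusters over ",
      length(unlist(object@clusters)), " sequences (cutoff ",
      object@identityCutoff, "%)\n", sep = "")
})

setMethod("show", "ScoreMatrix", function(object) {
  cat("ScoreMatrix: ", nrow(object@scores), " candidates x ",
      ncol(object@scores), " ligands; ", sum(object@missing),
      " missing pairs scored 0\n", sep = "")
})
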