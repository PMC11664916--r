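## Point-cloud serialisation: JSON for machine use, a PDB pseudo-atom
## file for visual inspection.

#' Write / read a cavity cloud as JSON
#'
#' The JSON object carries coordinates, the property table, the flavin
#' frame, the grid spacing and the source id; reading it back restores an
#' identical [CavityCloud-class].
#'
#' @param cloud a [CavityCloud-class].
#' @param path file path.
#' @return `writeCloudJSON`: `path` invisibly; `readCloudJSON`: the
#'   [CavityCloud-class].
#' @export
writeCloudJSON <- function(cloud, path) {
  obj <- list(
    source_id = cloud@sourceId,
    grid_spacing = cloud@gridSpacing,
    frame = list(n5 = cloud@frame@n5,
                 ring_centroid = cloud@frame@ringCentroid,
                 ring_normal = cloud@frame@ringNormal),
    coords = unname(as.matrix(pointCoords(cloud))),
    props = pointProps(cloud))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCloudJSON
#' @export
readCloudJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  frame <- FlavinFrame(n5 = obj$frame$n5,
                       ringCentroid = obj$frame$ring_centroid,
                       ringNormal = obj$frame$ring_normal)
  coords <- matrix(as.numeric(obj$coords), ncol = 3)
  CavityCloud(coords = coords, props = as.data.frame(obj$props),
              frame = frame, gridSpacing = obj$grid_spacing,
              sourceId = obj$source_id)
}

#' Write a cavity cloud as PDB pseudo-atoms
#'
#' One HETATM per point (residue `CAV`), with the electrostatic value in
#' the B-factor column, for visual inspection in a molecular viewer.
#'
#' @param cloud a [CavityCloud-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeCloudPDB <- function(cloud, path) {
  pts <- pointCoords(cloud)
  n <- nrow(pts)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(pts)),
    type = rep("HETATM", n), resno = seq_len(n),
    resid = rep("CAV", n), eleno = seq_len(n),
    elety = rep("DU", n), chain = rep("P", n),
    o = rep(1, n), b = round(cloud@props$electrostatic, 2),
    elesy = rep("X", n), end = TRUE)
  invisible(path)
}
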