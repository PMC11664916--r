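## Docking-cluster evaluation: minimal-distance cluster selection, the
## combined |E/d| score, the candidate x ligand score matrix and the
## per-group top-k shortlist.

.DOCK_COLS <- c("candidate_id", "ligand_id", "cluster_id", "energy",
                "distance")

#' Select the docking cluster used for scoring
#'
#' For one candidate-ligand pair, returns the cluster with minimal
#' carboxyl-carbon-to-N5 distance; its binding energy is the one that
#' enters the combined score. Ties on distance go to the lower (more
#' negative) energy, then to the lower cluster id.
#'
#' @param clusters data.frame with columns `candidate_id`, `ligand_id`,
#'   `cluster_id`, `energy` (kcal/mol), `distance` (Angstrom), all rows
#'   belonging to one candidate-ligand pair.
#' @return The selected single-row data.frame.
#' @export
selectCluster <- function(clusters) {
  if (is.null(clusters) || nrow(clusters) == 0L)
    .err("catalocavity_value_error", "no clusters to select from")
  if (any(clusters$distance <= 0))
    .err("catalocavity_value_error", "distances must be > 0")
  ord <- order(clusters$distance, clusters$energy, clusters$cluster_id)
  clusters[ord[1L], , drop = FALSE]
}

#' Combined docking score |E/d|
#'
#' Absolute ratio of binding energy (kcal/mol) to the carboxyl-carbon to
#' flavin-N5 distance (Angstrom); large scores favour poses that are both
#' tightly bound (low, negative E) and close to the flavin (low d).
#'
#' @param energy binding energy in kcal/mol.
#' @param distance distance in Angstrom (> 0).
#' @return `abs(energy / distance)` (vectorised).
#' @examples
#' combinedScore(-6, 3)  # 2
#' @export
combinedScore <- function(energy, distance) {
  if (any(distance <= 0))
    .err("catalocavity_value_error", "distance must be > 0")
  abs(energy / distance)
}

#' Build the candidate x ligand combined-score matrix
#'
#' Deduplicates rows, groups by candidate-ligand pair, applies
#' [selectCluster()] and [combinedScore()], and assembles the full score
#' grid plus per-candidate sums. Pairs without any docking cluster score
#' 0 and are flagged in the `missing` slot, keeping sums comparable
#' across candidates with unequal docking coverage.
#'
#' @param allClusters data.frame of docking clusters (columns
#'   `candidate_id`, `ligand_id`, `cluster_id`, `energy`, `distance`).
#' @param candidates,ligands optional id orderings; default = order of
#'   first appearance.
#' @return A [ScoreMatrix-class].
#' @export
buildMatrix <- function(allClusters, candidates = NULL, ligands = NULL) {
  stopifnot(all(.DOCK_COLS %in% names(allClusters)))
  cl <- unique(allClusters[, .DOCK_COLS])
  if (is.null(candidates)) candidates <- unique(cl$candidate_id)
  if (is.null(ligands)) ligands <- unique(cl$ligand_id)
  scores <- matrix(0, length(candidates), length(ligands),
                   dimnames = list(candidates, ligands))
  miss <- matrix(TRUE, length(candidates), length(ligands),
                 dimnames = list(candidates, ligands))
  cl <- cl[cl$candidate_id %in% candidates & cl$ligand_id %in% ligands, ,
           drop = FALSE]
  if (nrow(cl)) {
    key <- paste(cl$candidate_id, cl$ligand_id, sep = "\r")
    for (k in unique(key)) {
      g <- cl[key == k, , drop = FALSE]
      sel <- selectCluster(g)
      scores[sel$candidate_id, sel$ligand_id] <-
        combinedScore(sel$energy, sel$distance)
      miss[sel$candidate_id, sel$ligand_id] <- FALSE
    }
  }
  new("ScoreMatrix", scores = scores, sums = rowSums(scores),
      missing = miss)
}

#' Top-k candidates by summed combined score
#'
#' Returns, per group (or globally when `groups` is `NULL`), the `k`
#' candidates with the largest score sums, mirroring the per-source
#' shortlist (top 5 sequence-derived plus top 5 structure-derived
#' candidates). Ties are broken by candidate id ascending; a group
#' smaller than `k` is returned whole with a warning.
#'
#' @param matrix a [ScoreMatrix-class].
#' @param k number of candidates per group (default 5).
#' @param groups optional named character vector mapping candidate id to
#'   group label.
#' @return Character vector of candidate ids (groups in sorted label
#'   order, candidates by decreasing sum within each).
#' @export
topK <- function(matrix, k = 5L, groups = NULL) {
  k <- as.integer(k)
  if (k < 1L) .err("catalocavity_value_error", "k must be >= 1")
  sums <- scoreSums(matrix)
  pick <- function(ids) {
    if (length(ids) < k)
      warning(sprintf("group has only %d candidates (< k = %d); returning all",
                      length(ids), k))
    s <- sums[ids]
    ids[order(-s, ids)][seq_len(min(k, length(ids)))]
  }
  if (is.null(groups)) return(pick(names(sums)))
  gl <- groups[names(sums)]
  if (any(is.na(gl)))
    .err("catalocavity_value_error",
         "every candidate needs a group label when groups are given")
  unlist(lapply(sort(unique(gl)), function(g) pick(names(sums)[gl == g])),
         use.names = FALSE)
}

#' Read / write docking cluster tables
#'
#' Tab-separated with header: `candidate_id`, `ligand_id`, `cluster_id`,
#' `energy_kcal_mol`, `distance_A`.
#'
#' @param path file path.
#' @return `readDockingTable`: data.frame in the internal column layout
#'   (`energy`, `distance`).
#' @export
readDockingTable <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("candidate_id", "ligand_id", "cluster_id", "energy_kcal_mol",
            "distance_A")
  if (!all(need %in% names(tb)))
    .err("catalocavity_format_error",
         paste("docking table must contain columns:",
               paste(need, collapse = ", ")))
  data.frame(candidate_id = as.character(tb$candidate_id),
             ligand_id = as.character(tb$ligand_id),
             cluster_id = as.integer(tb$cluster_id),
             energy = as.numeric(tb$energy_kcal_mol),
             distance = as.numeric(tb$distance_A),
             stringsAsFactors = FALSE)
}

#' @rdname readDockingTable
#' @param clusters data.frame in the internal layout (see
#'   [readDockingTable()] value).
#' @return `writeDockingTable`: `path`, invisibly.
#' @export
writeDockingTable <- function(clusters, path) {
  out <- data.frame(candidate_id = clusters$candidate_id,
                    ligand_id = clusters$ligand_id,
                    cluster_id = clusters$cluster_id,
                    energy_kcal_mol = clusters$energy,
                    distance_A = clusters$distance)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
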