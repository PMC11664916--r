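## Funnel orchestration: structures -> cavities -> matching -> candidate
## pool (union over templates) plus the sequence funnel, then docking
## evaluation and the per-group shortlist, with one machine-readable run
## report.

.DEFAULT_THRESHOLDS <- list(
  score_max = 0.05, ov12_min = 70, ov21_min = 10, strict_ov21 = 30,
  large_pool_size = 100, identity_min = 30, cov_min = 80,
  cluster_cutoff = 70, ref_pos = 451, residue = "R", top_k = 5,
  epsilon = 1.0, grid_spacing = 0.8, probe_radius = 1.4,
  max_ligand_distance = 5.0, buriedness_min = 0.4, keep_carbons = 8,
  flavin_residue = "FAD")

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with paths resolved relative to the file's
#' directory. Recognised fields: `templates` (>= 1 PDB paths), `targets`
#' (PDB paths or one directory), `ligand` (`resname`, `chain`, `resno`),
#' `blast_table`, `fasta`, `reference_fasta`, `docking_table`,
#' `groups_table`, `out_dir`, `seed`, and a `thresholds` block whose
#' defaults are the published values (score 0.05, overlaps 70/10/30,
#' identity 30, coverage 80, cluster 70, reference position 451 arginine,
#' top 5).
#'
#' @param path path to a YAML file.
#' @return Validated config list as consumed by [runAll()].
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(x)
      if (grepl("^(/|[A-Za-z]:)", x)) x else file.path(base, x), "")
  }
  for (f in c("templates", "targets", "blast_table", "fasta",
              "reference_fasta", "docking_table", "groups_table",
              "out_dir"))
    cfg[[f]] <- unname(rel(cfg[[f]]))
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as from YAML or built in code).
#' @export
validateRunConfig <- function(cfg) {
  thr <- utils::modifyList(.DEFAULT_THRESHOLDS,
                           if (is.null(cfg$thresholds)) list()
                           else cfg$thresholds)
  if (thr$grid_spacing < 0.3 || thr$grid_spacing > 2)
    .err("catalocavity_value_error", "grid_spacing must lie in [0.3, 2]")
  for (f in c("ov12_min", "ov21_min", "strict_ov21", "identity_min",
              "cov_min", "cluster_cutoff"))
    if (thr[[f]] < 0 || thr[[f]] > 100 + 1e-9)
      .err("catalocavity_value_error",
           sprintf("threshold %s must lie in [0, 100]", f))
  cfg$thresholds <- thr
  hasStruct <- !is.null(cfg$templates) && !is.null(cfg$targets)
  hasSeq <- !is.null(cfg$blast_table) && !is.null(cfg$fasta) &&
    !is.null(cfg$reference_fasta)
  hasDock <- !is.null(cfg$docking_table)
  if (!hasStruct && !hasSeq && !hasDock)
    .err("catalocavity_value_error",
         "config names no input source (structures, sequences or docking)")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  cfg
}

## Ligand spec from a structure: chain carbons are the ligand's C<k>
## atoms sorted by number; C1 is the carboxyl carbon.
.inferLigandSpec <- function(s, lig) {
  a <- atoms(s)
  la <- a[a$resname == lig$resname & a$chain == lig$chain &
            a$resno == lig$resno, , drop = FALSE]
  if (nrow(la) == 0L)
    .err("catalocavity_ligand_error",
         sprintf("ligand %s:%s:%s not found in '%s'", lig$resname,
                 lig$chain, lig$resno, s@id))
  cn <- la$name[grepl("^C[0-9]+$", la$name)]
  cn <- cn[order(as.integer(sub("^C", "", cn)))]
  LigandSpec(resname = lig$resname, chain = lig$chain,
             resno = as.integer(lig$resno), carboxylCarbon = cn[1L],
             chainCarbons = cn)
}

.prepCloud <- function(path, cfg, truncate) {
  thr <- cfg$thresholds
  s <- readStructure(path)
  spec <- .inferLigandSpec(s, cfg$ligand)
  if (truncate && length(spec@chainCarbons) > thr$keep_carbons) {
    s <- truncateLigand(s, spec, keepCarbons = thr$keep_carbons)
    spec <- .inferLigandSpec(s, cfg$ligand)
  }
  frame <- locateFlavin(s, thr$flavin_residue, ligand = spec)
  cloud <- procreateCavity(
    s, spec, frame, gridSpacing = thr$grid_spacing,
    probeRadius = thr$probe_radius,
    maxLigandDistance = thr$max_ligand_distance,
    buriednessMin = thr$buriedness_min)
  annotateProperties(cloud, s, spec)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full discovery funnel
#'
#' Executes the stages in order: template and target cavities are
#' procreated and annotated; every template is matched against every
#' target and a target passing ANY template's filter enters the
#' candidate pool (union over templates, which is how multiple related
#' templates raise the chance of finding suitable matches); in parallel
#' the sequence funnel filters BLAST hits, clusters the surviving
#' sequences and keeps representatives with the conserved arginine; the
#' docking table is then restricted to the combined pool, scored by
#' |E/d| and summarised into the per-group top-k shortlist. Triage flags
#' annotate match results but never remove them. A JSON and a plain-text
#' report (no timestamps, so re-runs are byte-identical) plus per-stage
#' TSVs are written to `out_dir`.
#'
#' @param config config list from [readRunConfig()] /
#'   [validateRunConfig()].
#' @return The run report, invisibly a list (also written as
#'   `report.json` / `report.txt`).
#' @export
runAll <- function(config) {
  config <- validateRunConfig(config)
  thr <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(tool = "catalocavity",
                 version = as.character(utils::packageVersion("catalocavity")),
                 seed = config$seed, thresholds = thr, stages = list())
  pool <- character(0); seqKept <- character(0)
  matchedBy <- list()
  hasStruct <- !is.null(config$templates) && !is.null(config$targets)
  hasSeq <- !is.null(config$blast_table) && !is.null(config$fasta) &&
    !is.null(config$reference_fasta)

  if (hasStruct) {
    targets <- config$targets
    if (length(targets) == 1L && dir.exists(targets))
      targets <- sort(list.files(targets, pattern = "\\.pdb$",
                                 full.names = TRUE))
    tmplClouds <- .stage("template cavities",
      lapply(config$templates, .prepCloud, cfg = config, truncate = TRUE))
    tgtClouds <- .stage("target cavities",
      lapply(targets, .prepCloud, cfg = config, truncate = FALSE))
    results <- .stage("matching", {
      out <- list()
      for (tc in tmplClouds) for (gc in tgtClouds)
        out[[length(out) + 1L]] <- alignClouds(tc, gc,
                                               epsilon = thr$epsilon)
      out
    })
    largePool <- length(tgtClouds) > thr$large_pool_size
    kept <- filterMatches(results, scoreMax = thr$score_max,
                          ov12Min = thr$ov12_min, ov21Min = thr$ov21_min,
                          strictOv21 = thr$strict_ov21,
                          largePool = largePool)
    for (r in kept)
      matchedBy[[r@targetId]] <- sort(unique(c(matchedBy[[r@targetId]],
                                               r@templateId)))
    pool <- sort(unique(vapply(kept, function(r) r@targetId, "")))
    mt <- matchTable(results, kept)
    utils::write.table(mt, file.path(config$out_dir, "matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$structure <- list(
      n_templates = length(tmplClouds), n_targets = length(tgtClouds),
      large_pool = largePool, n_matches = length(results),
      n_kept = length(kept), pool = as.list(pool))
  }

  if (hasSeq) {
    seqStage <- .stage("sequence funnel", {
      hits <- readBlastTable(config$blast_table)
      kept <- filterHits(hits, minIdentity = thr$identity_min,
                         minCov = thr$cov_min)
      seqs <- readFastaAA(config$fasta)
      ids <- intersect(unique(kept$subject_id), names(seqs))
      if (length(ids) == 0L) {
        warning("no sequences survive the BLAST filter; ",
                "sequence funnel is empty")
        list(n_hits = nrow(hits), n_hits_kept = nrow(kept),
             n_sequences = 0L, n_clusters = 0L,
             kept_representatives = character(0))
      } else {
        cs <- greedyCluster(seqs[ids], cutoff = thr$cluster_cutoff)
        reps <- representatives(cs)
        ref <- readFastaAA(config$reference_fasta)
        cf <- conservedResidueFilter(seqs[reps], ref[1L],
                                     refPos = thr$ref_pos,
                                     residue = thr$residue)
        clTab <- do.call(rbind, lapply(reps, function(r) data.frame(
          representative_id = r, member_id = clusters(cs)[[r]],
          stringsAsFactors = FALSE)))
        utils::write.table(clTab,
                           file.path(config$out_dir, "clusters.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(cf$reports,
                           file.path(config$out_dir, "conservation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(n_hits = nrow(hits), n_hits_kept = nrow(kept),
             n_sequences = length(ids), n_clusters = length(reps),
             kept_representatives = sort(names(cf$kept)))
      }
    })
    seqKept <- seqStage$kept_representatives
    seqStage$kept_representatives <- as.list(seqKept)
    report$stages$sequence <- seqStage
  }

  shortlist <- data.frame()
  if (!is.null(config$docking_table)) {
    dockStage <- .stage("docking evaluation", {
      cl <- readDockingTable(config$docking_table)
      groups <- NULL
      if (!is.null(config$groups_table)) {
        gt <- utils::read.table(config$groups_table, sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
        groups <- setNames(gt$group, gt$candidate_id)
      }
      candAll <- unique(cl$candidate_id)
      cand <- if (hasStruct || hasSeq)
        candAll[candAll %in% c(pool, seqKept)] else candAll
      cl <- cl[cl$candidate_id %in% cand, , drop = FALSE]
      if (nrow(cl) == 0L) {
        warning("no docking rows left after pool restriction; ",
                "shortlist is empty")
        list(n_candidates_in_table = length(candAll),
             n_candidates_scored = 0L, shortlist = character(0),
             sums = numeric(0), groups = groups)
      } else {
        sm <- buildMatrix(cl)
        if (!is.null(groups)) groups <- groups[names(scoreSums(sm))]
        ids <- withCallingHandlers(
          topK(sm, k = thr$top_k, groups = groups),
          warning = function(w) invokeRestart("muffleWarning"))
        utils::write.table(
          data.frame(candidate_id = names(scoreSums(sm)),
                     score_sum = unname(scoreSums(sm))),
          file.path(config$out_dir, "score_sums.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
        list(n_candidates_in_table = length(candAll),
             n_candidates_scored = nrow(scoreGrid(sm)), shortlist = ids,
             sums = scoreSums(sm), groups = groups)
      }
    })
    ids <- dockStage$shortlist
    shortlist <- data.frame(
      candidate_id = ids,
      group = if (is.null(dockStage$groups)) rep("all", length(ids))
      else unname(dockStage$groups[ids]),
      score_sum = unname(dockStage$sums[ids]),
      source = ifelse(ids %in% pool, "structure-match",
                      ifelse(ids %in% seqKept, "sequence-funnel",
                             "docking-only")),
      matched_templates = vapply(ids, function(i)
        paste(matchedBy[[i]], collapse = ","), ""),
      stringsAsFactors = FALSE)
    report$stages$docking <- dockStage[c("n_candidates_in_table",
                                         "n_candidates_scored")]
  }
  if (nrow(shortlist) == 0L)
    warning("the final shortlist is empty")
  report$shortlist <- shortlist
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  txt <- c("catalocavity run report",
           sprintf("  version %s, seed %s", report$version, report$seed),
           vapply(names(report$stages), function(n) {
             st <- report$stages[[n]]
             sprintf("  %s: %s", n, paste(names(st), "=",
               vapply(st, function(v) paste(unlist(v), collapse = ","), ""),
               collapse = "; "))
           }, ""),
           "  shortlist:",
           if (nrow(shortlist))
             sprintf("    %s (%s, sum %.3f)", shortlist$candidate_id,
                     shortlist$group, shortlist$score_sum)
           else "    (empty)")
  writeLines(txt, file.path(config$out_dir, "report.txt"))
  invisible(report)
}
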