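## Composed synthetic bundle: every pipeline input in one directory, with
## a manifest predicting the whole funnel's outcome by construction.

#' Generate a complete synthetic input bundle for the pipeline
#'
#' Emits, under `dir`: a template structure (`templates/template.pdb`), a
#' matching target (the template rigidly translated by whole grid steps,
#' so its cavity grid is the template's shifted point-for-point), two
#' non-matching decoys (a short-ligand narrow cavity failing the
#' template-in-target overlap gate, and a wide cavity failing the total
#' score), a BLAST table over four sequence families (two member hits
#' planted to fail the identity/coverage rule, plus junk subjects), the
#' family FASTA and reference, a docking table over the union of
#' candidates with per-source groups, and `config.yml`. The manifest
#' predicts each stage's kept set and the final shortlist purely from the
#' construction.
#'
#' @param seed integer seed.
#' @param dir output directory (created).
#' @return list with `configPath`, `config` and `manifest` (predicted
#'   `pool`, `seqKept`, `shortlist`, per-stage bookkeeping).
#' @export
makeSyntheticBundle <- function(seed, dir) {
  dir.create(file.path(dir, "templates"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(file.path(dir, "targets"), showWarnings = FALSE)
  sd <- function(k) as.integer(seed) * 101L + k

  tmpl <- makeToyEnzyme(sd(1), ligandCarbons = 8L, id = "template",
                        path = file.path(dir, "templates", "template.pdb"))
  shift <- c(8, 4.8, -5.6)  # whole multiples of the 0.8 A grid spacing
  hit <- transformStructure(tmpl$structure, diag(3), shift)
  hit@id <- "hitA"
  writeStructure(hit, file.path(dir, "targets", "hitA.pdb"))
  makeToyEnzyme(sd(1), ligandCarbons = 2L, tunnelLength = 6,
                id = "decoyShort",
                path = file.path(dir, "targets", "decoyShort.pdb"))
  makeToyEnzyme(sd(2), ligandCarbons = 8L, tunnelRadius = 6.5,
                id = "decoyWide",
                path = file.path(dir, "targets", "decoyWide.pdb"))

  fam <- makeSequenceFamilies(
    sd(3), nFamilies = 4L, membersPerFamily = 6L,
    argDropIds = sprintf("F4_M%02d", 1:6),
    fastaPath = file.path(dir, "sequences.fasta"),
    referencePath = file.path(dir, "reference.fasta"))
  memberIds <- names(fam$sequences)
  blastFail <- c("F1_M06", "F2_M04")
  passMembers <- setdiff(memberIds, blastFail)
  junk <- sprintf("JUNK%02d", 1:8)
  bl <- makeBlastTable(sd(4), nHits = length(memberIds) + length(junk),
                       nPass = length(passMembers),
                       subjects = c(passMembers, blastFail, junk))
  utils::write.table(bl$hits, file.path(dir, "blast.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  survivors <- split(passMembers,
                     sub("_M.*$", "", passMembers))
  seqReps <- vapply(survivors, function(v) sort(v)[1], "")
  seqKept <- unname(seqReps[c("F1", "F2", "F3")])  # F4 lacks the arginine

  structCands <- c("hitA", "decoyShort", "decoyWide")
  dockCands <- c(structCands, unname(seqReps))
  dockGroups <- setNames(c(rep("structure", length(structCands)),
                           rep("sequence", length(seqReps))), dockCands)
  dk <- makeDockingTable(sd(5), candidateIds = dockCands,
                         ligandIds = sprintf("lig%02d", 1:6),
                         groups = dockGroups, missingFraction = 0.1,
                         k = 5L, path = file.path(dir, "docking.tsv"))
  utils::write.table(
    data.frame(candidate_id = dockCands, group = unname(dockGroups)),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## predicted shortlist: pool-restricted per-group top-k by planted sums
  pool <- "hitA"
  inPool <- c(pool, seqKept)
  sums <- dk$manifest$sums[inPool]
  shortlist <- unlist(lapply(sort(unique(dockGroups[inPool])), function(g) {
    ids <- inPool[dockGroups[inPool] == g]
    ids[order(-sums[ids], ids)][seq_len(min(5L, length(ids)))]
  }), use.names = FALSE)

  ## paths are written relative to the bundle directory, where the
  ## config file itself lives
  config <- list(
    templates = "templates/template.pdb",
    targets = "targets",
    ligand = list(resname = "OCA", chain = "L", resno = 500L),
    blast_table = "blast.tsv",
    fasta = "sequences.fasta",
    reference_fasta = "reference.fasta",
    docking_table = "docking.tsv",
    groups_table = "groups.tsv",
    out_dir = "out",
    seed = as.integer(seed))
  configPath <- file.path(dir, "config.yml")
  yaml::write_yaml(config, configPath)

  list(configPath = configPath, config = config,
       manifest = list(
         seed = seed, shift = shift, pool = pool,
         blastPassIds = passMembers, clusterFamilies = survivors,
         representatives = seqReps, seqKept = seqKept,
         dockSums = dk$manifest$sums, shortlist = shortlist))
}
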