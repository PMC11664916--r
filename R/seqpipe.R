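## The sequence-side funnel: BLAST-hit filtering, greedy clustering at an
## identity cutoff, and the conserved-arginine filter on representatives.

.pkgCache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkgCache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$BLOSUM62 <- e$BLOSUM62
  }
  .pkgCache$BLOSUM62
}

.asSeqVector <- function(seqs) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || is.null(names(seqs)) || any(!nzchar(names(seqs))))
    .err("catalocavity_value_error",
         "sequences must be a named character vector or named AAStringSet")
  toupper(seqs)
}

.encodeSeq <- function(s, alphabet) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx - 1L
}

#' Globally align two amino-acid sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (Gotoh), BLOSUM62
#' scoring, gap open 11 / extend 1 (a gap of length L costs 11 + L). End
#' gaps are penalised.
#'
#' @param a,b single amino-acid strings (20 letters + X; unknown letters
#'   are treated as X).
#' @return list with `score`, the aligned strings `alignedA` /
#'   `alignedB` (gaps as `-`), and the 1-based index vectors `aIndex` /
#'   `bIndex` (0 marks a gap).
#' @export
alignPair <- function(a, b) {
  S <- .blosum62()
  alph <- rownames(S)
  a <- toupper(as.character(a)[1]); b <- toupper(as.character(b)[1])
  if (!nzchar(a) || !nzchar(b))
    .err("catalocavity_value_error", "sequences must be non-empty")
  res <- .gotohAlign(.encodeSeq(a, alph), .encodeSeq(b, alph), S, 11, 1)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  list(score = res$score,
       alignedA = paste(ifelse(res$a_index > 0, ca[pmax(res$a_index, 1)],
                               "-"), collapse = ""),
       alignedB = paste(ifelse(res$b_index > 0, cb[pmax(res$b_index, 1)],
                               "-"), collapse = ""),
       aIndex = res$a_index, bIndex = res$b_index)
}

#' Percent identity of the global alignment of two sequences
#'
#' Identity = 100 * matches / alignment columns, where gapped columns
#' count in the denominator and `X` never counts as a match
#' (`denominator = "shorter"` divides by the shorter sequence length
#' instead). The pair is canonically ordered (longer sequence first,
#' lexicographic tie-break) before aligning, so the result is symmetric
#' by construction.
#'
#' @param a,b amino-acid strings.
#' @param denominator `"columns"` (default) or `"shorter"`.
#' @return Percent identity in \[0, 100\].
#' @examples
#' pairwiseIdentity("AAAA", "AAAT")  # 75
#' @export
pairwiseIdentity <- function(a, b, denominator = c("columns", "shorter")) {
  denominator <- match.arg(denominator)
  a <- toupper(as.character(a)[1]); b <- toupper(as.character(b)[1])
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  al <- alignPair(a, b)
  ca <- strsplit(al$alignedA, "")[[1]]
  cb <- strsplit(al$alignedB, "")[[1]]
  matches <- sum(ca == cb & ca != "-" & ca != "X")
  den <- switch(denominator, columns = length(ca),
                shorter = min(nchar(a), nchar(b)))
  100 * matches / den
}

#' Filter BLAST hits by identity and bidirectional coverage
#'
#' Keeps hits with `pct_identity >= minIdentity` and both query and
#' subject coverage `>= minCov` ("bidirectional" is read strictly: both
#' directions must pass). Input order is preserved; the operation is
#' idempotent.
#'
#' @param hits data.frame with columns `pct_identity`, `qcov`, `scov`
#'   (as returned by [readBlastTable()]).
#' @param minIdentity percent identity cutoff (default 30).
#' @param minCov coverage cutoff applied to both directions (default 80).
#' @return The kept subset of `hits`.
#' @export
filterHits <- function(hits, minIdentity = 30, minCov = 80) {
  stopifnot(all(c("pct_identity", "qcov", "scov") %in% names(hits)))
  hits[hits$pct_identity >= minIdentity & hits$qcov >= minCov &
         hits$scov >= minCov, , drop = FALSE]
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Reads the 12 standard columns; columns 13/14, when present, are taken
#' as query/subject coverage (`qcovs`/`scovs`). With 12 columns,
#' coverages are computed from the aligned spans and the supplied
#' sequence lengths: `qcov = 100 * (qend - qstart + 1) / qlen` and
#' likewise for the subject.
#'
#' @param path path to a tab-separated hit table (no header).
#' @param qlen,slen sequence lengths used when coverage columns are
#'   absent: a single number or a named vector keyed by query/subject id.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `align_length`, `mismatches`, `gap_opens`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`, `qcov`, `scov`.
#' @export
readBlastTable <- function(path, qlen = NULL, slen = NULL) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(tb) < 12L)
    .err("catalocavity_format_error",
         "expected at least the 12 standard outfmt-6 columns")
  names(tb)[1:12] <- c("query_id", "subject_id", "pct_identity",
                       "align_length", "mismatches", "gap_opens",
                       "qstart", "qend", "sstart", "send", "evalue",
                       "bitscore")
  if (ncol(tb) >= 14L) {
    tb$qcov <- tb[[13L]]
    tb$scov <- tb[[14L]]
  } else {
    if (is.null(qlen) || is.null(slen))
      .err("catalocavity_value_error",
           "coverage columns absent: qlen and slen are required")
    ql <- if (length(qlen) == 1L && is.null(names(qlen)))
      rep(qlen, nrow(tb)) else unname(qlen[tb$query_id])
    sl <- if (length(slen) == 1L && is.null(names(slen)))
      rep(slen, nrow(tb)) else unname(slen[tb$subject_id])
    tb$qcov <- 100 * (abs(tb$qend - tb$qstart) + 1) / ql
    tb$scov <- 100 * (abs(tb$send - tb$sstart) + 1) / sl
  }
  tb[, c("query_id", "subject_id", "pct_identity", "align_length",
         "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
         "evalue", "bitscore", "qcov", "scov")]
}

#' Greedy sequence clustering at an identity cutoff
#'
#' CD-HIT-style greedy set cover: sequences are sorted by length
#' descending (ties by id ascending); the longest unassigned sequence
#' becomes a representative and every unassigned sequence with
#' [pairwiseIdentity()] at least `cutoff` to it joins its cluster;
#' repeat. Every member therefore has at least `cutoff` identity to its
#' representative.
#'
#' @param seqs named character vector or `Biostrings::AAStringSet`.
#' @param cutoff percent identity cutoff (default 70).
#' @return A [ClusterSet-class].
#' @export
greedyCluster <- function(seqs, cutoff = 70) {
  v <- .asSeqVector(seqs)
  if (length(v) < 1L)
    .err("catalocavity_value_error", "need at least one sequence")
  ord <- order(-nchar(v), names(v))
  v <- v[ord]
  assigned <- rep(FALSE, length(v))
  out <- list()
  while (!all(assigned)) {
    i <- which(!assigned)[1L]
    rep_id <- names(v)[i]
    assigned[i] <- TRUE
    members <- rep_id
    for (j in which(!assigned)) {
      if (pairwiseIdentity(v[i], v[j]) >= cutoff) {
        assigned[j] <- TRUE
        members <- c(members, names(v)[j])
      }
    }
    out[[rep_id]] <- members
  }
  new("ClusterSet", clusters = out, identityCutoff = as.numeric(cutoff))
}

#' Filter representatives by a conserved reference-equivalent residue
#'
#' Known fatty acid photodecarboxylases conserve an active-site arginine
#' (position 451 of the reference enzyme); candidates lacking an
#' equivalent arginine are removed from the funnel. Each representative
#' is globally aligned to the reference; the alignment column holding
#' reference position `refPos` is located and the representative is kept
#' iff its residue in that column is exactly `residue` (a gap or any
#' other residue fails). The report additionally records the residues
#' equivalent to the other conserved-triad positions (reference cysteine
#' 432 and tyrosine 466 by default).
#'
#' @param reps named character vector or `AAStringSet` of representative
#'   sequences.
#' @param reference the reference sequence (single named string or
#'   length-1 `AAStringSet`).
#' @param refPos 1-based reference position to filter on (default 451).
#' @param residue required residue (default `"R"`).
#' @param triadPos further reference positions to report (default
#'   `c(cys = 432, tyr = 466)`).
#' @return list with `kept` (the kept subset of `reps`) and `reports`
#'   (data.frame: `sequence_id`, `has_arg_equivalent`,
#'   `arg_column_residue`, and one `*_equivalent` column per triad
#'   position; `-` marks a gap or an out-of-range position).
#' @export
conservedResidueFilter <- function(reps, reference, refPos = 451L,
                                   residue = "R",
                                   triadPos = c(cys = 432L, tyr = 466L)) {
  v <- .asSeqVector(reps)
  ref <- .asSeqVector(reference)[1L]
  refPos <- as.integer(refPos)
  if (refPos < 1L || refPos > nchar(ref))
    .err("catalocavity_value_error",
         sprintf("refPos %d is beyond the reference length %d", refPos,
                 nchar(ref)))
  posAll <- c(refPos, as.integer(triadPos))
  rows <- lapply(names(v), function(id) {
    al <- alignPair(ref, v[[id]])
    cb <- strsplit(al$alignedB, "")[[1]]
    res <- vapply(posAll, function(p) {
      if (p < 1L || p > nchar(ref)) return("-")
      col <- which(al$aIndex == p)
      if (length(col) != 1L) "-" else cb[col]
    }, "")
    d <- data.frame(sequence_id = id,
                    has_arg_equivalent = identical(res[1L], residue),
                    arg_column_residue = res[1L],
                    stringsAsFactors = FALSE)
    for (k in seq_along(triadPos)) {
      nm <- if (!is.null(names(triadPos)) && nzchar(names(triadPos)[k]))
        sprintf("%s%d_equivalent", names(triadPos)[k], triadPos[k])
      else sprintf("pos%d_equivalent", triadPos[k])
      d[[nm]] <- res[1L + k]
    }
    d
  })
  reports <- do.call(rbind, rows)
  keptIds <- reports$sequence_id[reports$has_arg_equivalent]
  kept <- if (is(reps, "XStringSet")) reps[names(reps) %in% keptIds]
  else reps[names(reps) %in% keptIds]
  list(kept = kept, reports = reports)
}

#' Read / write amino-acid FASTA
#'
#' Thin wrappers over Biostrings keeping ids and order.
#'
#' @param path file path.
#' @return `readFastaAA`: a named character vector of sequences.
#' @export
readFastaAA <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname readFastaAA
#' @param seqs named character vector or `AAStringSet`.
#' @return `writeFastaAA`: `path`, invisibly.
#' @export
writeFastaAA <- function(seqs, path) {
  v <- .asSeqVector(seqs)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(v), path)
  invisible(path)
}
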