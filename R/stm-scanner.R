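#' Speckle targeting motif (STM) scanner
#'
#' Functions to enumerate candidate STM windows in protein sequences, apply
#' the five STM criteria, scan whole proteomes, and compute best local
#' protein alignments.
#'
#' An STM candidate is a 62-residue window of the form
#' \code{x(30)-[TSED]-P-x(30)}: any 30 residues, a central threonine, serine,
#' glutamate or aspartate immediately followed by a proline, and any further
#' 30 residues. Window positions are reported 0-based internally (the central
#' acidic/hydroxyl residue is always window index 30) and 1-based in
#' human-readable output.
#'
#' @name stm_scanner
NULL

# residue classes used by the five criteria
.STM_CSIDE_CLASS <- c("T", "S", "E", "D")
.STM_NSIDE_CLASS <- c("A", "M", "V", "F", "L", "I", "G")
.STM_BASIC_CLASS <- c("R", "H", "K")
.STM_SPACED_IDX0 <- c(11L, 16L, 21L, 26L, 36L, 41L, 46L)

#' Read a proteome FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that validates record
#' ids: ids must be non-empty and unique (the offending record is reported).
#'
#' @param fasta Path to an amino-acid FASTA file.
#' @return An [Biostrings::AAStringSet] with names set to the first
#'   whitespace-delimited token of each header.
#' @export
read_proteome <- function(fasta) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1), 1L)
  if (any(is.na(ids) | ids == ""))
    stop("FASTA record ", which(is.na(ids) | ids == "")[1L], " has an empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: ", dup[1L])
  names(seqs) <- ids
  seqs
}

#' Extract candidate STM windows from one protein
#'
#' Returns one candidate per position \code{i} (0-based) such that
#' \code{sequence[i]} is in the central residue class (default T/S/E/D),
#' \code{sequence[i+1] == "P"}, and at least 30 residues flank the pair on
#' each side. Overlapping candidates are all reported, ordered by position.
#' The five criteria are left unevaluated (use [apply_stm_criteria()]).
#'
#' @param sequence Amino-acid sequence (single character string, uppercase).
#' @param protein_id Identifier carried into the output.
#' @param tsed_class Central residue class; default \code{c("T","S","E","D")}.
#' @return data.frame with columns \code{protein_id}, \code{window_start}
#'   (0-based offset of the 62-mer), \code{window_seq}.
#' @export
extract_candidate_windows <- function(sequence, protein_id = "protein",
                                      tsed_class = .STM_CSIDE_CLASS) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  empty <- data.frame(protein_id = character(0), window_start = integer(0),
                      window_seq = character(0), stringsAsFactors = FALSE)
  if (n < 62L) return(empty)
  chars <- strsplit(sequence, "")[[1L]]
  # 0-based center positions with full flanks: 30 .. n-32
  centers <- which(chars %in% tsed_class & c(chars[-1L], "") == "P") - 1L
  centers <- centers[centers >= 30L & centers <= n - 32L]
  if (!length(centers)) return(empty)
  starts <- centers - 30L
  data.frame(protein_id = protein_id,
             window_start = starts,
             window_seq = substring(sequence, starts + 1L, starts + 62L),
             stringsAsFactors = FALSE)
}

.max_p_run <- function(chars) {
  r <- rle(chars == "P")
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Apply the five STM criteria to candidate windows
#'
#' For each 62-residue window the criteria are, with window indexes 0-based
#' and the central pair at indexes 30 (T/S/E/D) and 31 (P):
#' \enumerate{
#'   \item no more than 4 consecutive prolines anywhere in the window;
#'   \item at least 3 prolines among the 7 positions spaced every 5 residues
#'     from the central pair (window indexes 11, 16, 21, 26, 36, 41, 46);
#'   \item at least 5 of T/S/E/D among the 30 C-terminal-side residues
#'     (indexes 32..61);
#'   \item at least 7 of A/M/V/F/L/I/G among the 30 N-terminal-side residues
#'     (indexes 0..29);
#'   \item fewer than 16 R/H/K residues in the whole window.
#' }
#' Non-standard residues (X, U, B, Z, ...) never satisfy any residue-class
#' test and break proline runs.
#'
#' @param candidates data.frame as returned by [extract_candidate_windows()],
#'   or a character vector of 62-mers.
#' @param tsed_class Central residue class used to validate the window
#'   center (and count criterion 3).
#' @return The input data.frame with logical columns \code{c1}..\code{c5} and
#'   \code{pass} appended.
#' @export
apply_stm_criteria <- function(candidates, tsed_class = .STM_CSIDE_CLASS) {
  if (is.character(candidates))
    candidates <- data.frame(protein_id = NA_character_,
                             window_start = NA_integer_,
                             window_seq = candidates, stringsAsFactors = FALSE)
  ws <- candidates$window_seq
  if (any(nchar(ws) != 62L))
    stop("malformed window: length != 62")
  mat <- do.call(rbind, strsplit(ws, ""))
  if (nrow(mat) != length(ws)) stop("malformed window set")
  if (!all(mat[, 31L] %in% tsed_class) || !all(mat[, 32L] == "P"))
    stop("malformed window: central pair is not [",
         paste(tsed_class, collapse = ""), "]P")
  candidates$c1 <- apply(mat, 1L, function(ch) .max_p_run(ch) <= 4L)
  candidates$c2 <- rowSums(mat[, .STM_SPACED_IDX0 + 1L, drop = FALSE] == "P") >= 3L
  candidates$c3 <- apply(mat[, 33:62, drop = FALSE], 1L,
                         function(ch) sum(ch %in% tsed_class)) >= 5L
  candidates$c4 <- apply(mat[, 1:30, drop = FALSE], 1L,
                         function(ch) sum(ch %in% .STM_NSIDE_CLASS)) >= 7L
  candidates$c5 <- apply(mat, 1L,
                         function(ch) sum(ch %in% .STM_BASIC_CLASS)) < 16L
  candidates$pass <- candidates$c1 & candidates$c2 & candidates$c3 &
    candidates$c4 & candidates$c5
  candidates
}

#' Scan a proteome for putative STMs
#'
#' Enumerates all candidate windows in every protein, applies the five
#' criteria and returns the passing windows. A protein is counted once in
#' the summary regardless of how many of its windows pass; window order is
#' input order, then position.
#'
#' @param proteome Path to a FASTA file or an [Biostrings::AAStringSet].
#' @param tsed_class Central residue class override.
#' @return list with \code{windows} (data.frame of passing windows with
#'   criteria columns and 1-based \code{start_1based}) and \code{proteins}
#'   (data.frame \code{protein_id}, \code{n_stm}).
#' @export
scan_proteome <- function(proteome, tsed_class = .STM_CSIDE_CLASS) {
  if (is.character(proteome) && length(proteome) == 1L)
    proteome <- read_proteome(proteome)
  if (anyDuplicated(names(proteome)))
    stop("duplicate FASTA id: ", names(proteome)[duplicated(names(proteome))][1L])
  seqs <- as.character(proteome)
  cand <- lapply(seq_along(seqs), function(i)
    extract_candidate_windows(seqs[[i]], names(seqs)[i], tsed_class))
  cand <- do.call(rbind, cand)
  empty <- data.frame(protein_id = character(0), window_start = integer(0),
                      window_seq = character(0), start_1based = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(cand) || nrow(cand) == 0L)
    return(list(windows = empty,
                proteins = data.frame(protein_id = character(0),
                                      n_stm = integer(0))))
  cand <- apply_stm_criteria(cand, tsed_class)
  hits <- cand[cand$pass, , drop = FALSE]
  hits$start_1based <- hits$window_start + 1L
  rownames(hits) <- NULL
  counts <- table(factor(hits$protein_id, levels = unique(hits$protein_id)))
  list(windows = hits,
       proteins = data.frame(protein_id = names(counts),
                             n_stm = as.integer(counts),
                             stringsAsFactors = FALSE))
}

#' Alignment parameters for best_local_match
#'
#' Defaults follow EMBOSS Matcher's protein settings (BLOSUM62, gap open 14,
#' gap extend 4). A gap of length L costs \code{gap_open + L * gap_extend}.
#'
#' @param matrix Substitution matrix name (resolved from Biostrings data).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return list of class \code{alignment_params}.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 14,
                             gap_extend = 4) {
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_params")
}

.get_subst_matrix <- function(name) {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Best local alignment between two protein sequences
#'
#' Optimal affine-gap local (Smith-Waterman / top Waterman-Eggert) alignment,
#' as computed by EMBOSS Matcher. Among equal-scoring optimal alignments the
#' minimal one is reported: boundary columns contributing no score are
#' trimmed (Matcher behaviour), then the smallest start wins. Percent
#' similarity is 100 x (aligned columns with a positive substitution score) /
#' (alignment columns); gap columns count as columns but are never positive.
#'
#' @param seqA,seqB Amino-acid sequences (character strings or AAString).
#' @param params An [alignment_params()] object.
#' @return list of class \code{local_alignment} with \code{score},
#'   \code{startA}, \code{endA}, \code{startB}, \code{endB} (1-based
#'   inclusive), \code{alignedA}, \code{alignedB}, \code{n_columns},
#'   \code{pct_identity}, \code{pct_similarity}.
#' @export
best_local_match <- function(seqA, seqB, params = alignment_params()) {
  seqA <- as.character(seqA); seqB <- as.character(seqB)
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be non-empty")
  sm <- .get_subst_matrix(params$matrix)
  resid <- unique(strsplit(paste0(seqA, seqB), "")[[1L]])
  missing <- setdiff(resid, rownames(sm))
  if (length(missing))
    stop("residue absent from substitution matrix: ", missing[1L])
  al <- Biostrings::pairwiseAlignment(
    seqA, seqB, type = "local", substitutionMatrix = sm,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::subject(al)), "")[[1L]]
  n <- length(pa)
  colscore <- vapply(seq_len(n), function(i) {
    if (pa[i] == "-" || sa[i] == "-") -Inf else sm[pa[i], sa[i]]
  }, numeric(1))
  # Trim boundary columns that contribute no score: an optimal local
  # alignment has no prefix or suffix with negative column-score sum, so any
  # prefix/suffix summing to <= 0 sums to exactly 0 and can be dropped
  # without changing the score (EMBOSS Matcher reports the trimmed span).
  lo <- 1L; hi <- n
  pref <- cumsum(colscore)
  while (lo < hi && pref[lo] <= 0) lo <- lo + 1L
  suff <- rev(cumsum(rev(colscore)))
  while (hi > lo && suff[hi] <= 0) hi <- hi - 1L
  offA <- sum(pa[seq_len(lo - 1L)] != "-")
  offB <- sum(sa[seq_len(lo - 1L)] != "-")
  tailA <- if (hi < n) sum(pa[(hi + 1L):n] != "-") else 0L
  tailB <- if (hi < n) sum(sa[(hi + 1L):n] != "-") else 0L
  pa <- pa[lo:hi]; sa <- sa[lo:hi]; n <- hi - lo + 1L
  ident <- sum(pa == sa & pa != "-")
  pos <- sum(vapply(seq_len(n), function(i)
    pa[i] != "-" && sa[i] != "-" && sm[pa[i], sa[i]] > 0, logical(1)))
  structure(list(
    score = Biostrings::score(al),
    startA = Biostrings::start(Biostrings::pattern(al)) + offA,
    endA = Biostrings::end(Biostrings::pattern(al)) - tailA,
    startB = Biostrings::start(Biostrings::subject(al)) + offB,
    endB = Biostrings::end(Biostrings::subject(al)) - tailB,
    alignedA = paste(pa, collapse = ""),
    alignedB = paste(sa, collapse = ""),
    n_columns = n,
    pct_identity = 100 * ident / n,
    pct_similarity = 100 * pos / n), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("Local alignment: score %g, %d columns\n", x$score, x$n_columns))
  cat(sprintf("  A %d-%d  %s\n", x$startA, x$endA, x$alignedA))
  cat(sprintf("  B %d-%d  %s\n", x$startB, x$endB, x$alignedB))
  cat(sprintf("  identity %.1f%%, similarity %.1f%%\n",
              x$pct_identity, x$pct_similarity))
  invisible(x)
}
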