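#' AU fraction of a sequence
#'
#' Fraction of non-N positions that are A or U; equals 1 - GC content
#' on N-free input.  \code{N} positions are excluded from the
#' denominator.
#'
#' @param seq RNA sequence over \code{A,C,G,U,N}.
#' @return AU fraction in \[0, 1\].
#' @export
compute_au_content <- function(seq) {
  check_rna(seq, allow_n = TRUE)
  chars <- strsplit(seq, "")[[1L]]
  informative <- chars != "N"
  if (!any(informative)) stop("AU content undefined for all-N sequence")
  sum(chars %in% c("A", "U")) / sum(informative)
}

#' Extract simple-sequence-repeat (SSR) motifs by tandem-run scanning
#'
#' Greedy left-to-right scan for maximal tandem runs of di-, tri- and
#' tetranucleotide motifs.  A run of \code{r >= min_repeats} contiguous
#' copies of motif \code{M} contributes count \code{r} under key
#' \code{M} (a 7-copy run counts once with count 7, never split);
#' overlapping motif phases are resolved greedily and runs for
#' different motif lengths are reported independently.
#' Homopolymer-equivalent motifs such as \code{"AA"} are excluded,
#' since mononucleotide runs are not treated as repeats here.
#'
#' @param seq RNA sequence over \code{A,C,G,U}.
#' @param min_repeats Minimum number of tandem copies (default 3).
#' @param motif_lengths Motif lengths to scan (subset of 2:4 by default).
#' @return Named integer vector mapping motif to total repeat count
#'   (empty when no qualifying run exists).
#' @export
extract_ssrs <- function(seq, min_repeats = 3L, motif_lengths = 2:4) {
  check_rna(seq, allow_n = TRUE)
  if (min_repeats < 2) stop("min_repeats must be >= 2")
  counts <- integer(0)
  n <- nchar(seq)
  for (L in sort(as.integer(motif_lengths))) {
    i <- 1L
    while (i + L - 1L <= n) {
      motif <- substr(seq, i, i + L - 1L)
      r <- 1L
      while (i + (r + 1L) * L - 1L <= n &&
             substr(seq, i + r * L, i + (r + 1L) * L - 1L) == motif) {
        r <- r + 1L
      }
      homopolymer <- length(unique(strsplit(motif, "")[[1L]])) == 1L
      if (r >= min_repeats && !homopolymer) {
        counts[motif] <- if (motif %in% names(counts))
          counts[[motif]] + r else r
        i <- i + r * L
      } else {
        i <- i + 1L
      }
    }
  }
  counts
}

#' SSR count vectors for a set of sequences
#'
#' Runs [extract_ssrs()] on every sequence and assembles the counts
#' into an entities x motifs matrix over the union of observed motifs.
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams extract_ssrs
#' @param binary Threshold counts to presence/absence (the repeat
#'   vectors are then binary).
#' @return Numeric matrix with one row per sequence and one column per
#'   observed motif (zero columns when no sequence has a qualifying
#'   run).
#' @export
ssr_feature_matrix <- function(seqs, min_repeats = 3L, motif_lengths = 2:4,
                               binary = FALSE) {
  per_seq <- lapply(seqs, extract_ssrs, min_repeats = min_repeats,
                    motif_lengths = motif_lengths)
  motifs <- sort(unique(unlist(lapply(per_seq, names))))
  M <- matrix(0, nrow = length(seqs), ncol = length(motifs),
              dimnames = list(names(seqs), motifs))
  for (i in seq_along(per_seq)) {
    if (length(per_seq[[i]])) M[i, names(per_seq[[i]])] <- per_seq[[i]]
  }
  if (binary) M <- (M > 0) + 0
  M
}

#' Interaction profiles of an adjacency matrix
#'
#' The interaction profile of miRNA i is row i of the adjacency matrix;
#' the profile of site j is column j.
#'
#' @param A Binary interaction matrix (miRNAs x sites).
#' @return List with elements \code{mirna} (rows = miRNA profiles of
#'   length n_sites) and \code{site} (rows = site profiles of length
#'   n_mirnas).
#' @export
build_interaction_profiles <- function(A) {
  validate_interaction_matrix(A)
  list(mirna = A, site = t(A))
}

#' Per-entity scalar features for a set of sequence records
#'
#' Computes minimum free energy, accessibility and AU fraction for each
#' record, plus the SSR count matrix, under one folding provider.
#'
#' @param records Sequence-record data frame (see [read_fasta()]).
#' @param provider Folding provider (default [nussinov_provider()]).
#' @param window Accessibility window (positions), default 10.
#' @inheritParams ssr_feature_matrix
#' @return A data frame with columns \code{entity_id}, \code{mfe},
#'   \code{accessibility}, \code{au_fraction}; the SSR count matrix is
#'   attached as attribute \code{"ssr"}.
#' @export
build_feature_table <- function(records, provider = nussinov_provider(),
                                window = 10L, min_repeats = 3L,
                                motif_lengths = 2:4, binary = FALSE) {
  seqs <- stats::setNames(records$sequence, records$id)
  folds <- lapply(seqs, provider$fold)
  ft <- data.frame(
    entity_id = records$id,
    mfe = vapply(folds, function(f) f$mfe, numeric(1)),
    accessibility = vapply(folds, function(f) {
      structure_accessibility(f$structure, min(window, nchar(f$structure)))
    }, numeric(1)),
    au_fraction = vapply(seqs, compute_au_content, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(ft, "ssr") <- ssr_feature_matrix(seqs, min_repeats, motif_lengths,
                                        binary)
  ft
}

#' Write a feature table (with SSR columns) as TSV
#'
#' @param ft Feature table from [build_feature_table()].
#' @param path Output path.
#' @export
write_feature_table <- function(ft, path) {
  ssr <- attr(ft, "ssr")
  out <- if (!is.null(ssr) && ncol(ssr)) cbind(ft, as.data.frame(ssr)) else ft
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
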