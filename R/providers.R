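#' Bundled dynamic-programming folding provider
#'
#' A self-contained maximum-pairing (Nussinov-style) folder recast as
#' energy minimization with fixed per-pair energies (GC -3, AU -2,
#' GU -1 kcal/mol) and a minimum hairpin loop of 3 unpaired bases.
#' Accessibility is the fraction of unpaired positions in the returned
#' minimum-energy structure, averaged over sliding windows.  The
#' similarity kernels consume only pairwise differences of these
#' scalars, so a consistent simplified folder preserves the structure
#' of the method while keeping the package fully offline.  \code{N}
#' never pairs, so N-containing sites fold as if those positions were
#' unpairable.
#'
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @return A folding provider: a list with elements \code{name},
#'   \code{fold(seq)} returning \code{list(mfe, structure)}, and
#'   \code{accessibility(seq, window)}.
#' @seealso [vienna_provider()], [compute_free_energy()]
#' @export
nussinov_provider <- function(min_loop = 3L) {
  fold <- function(seq) {
    check_rna(seq, allow_n = TRUE)
    .fold_min_energy(seq, as.integer(min_loop))
  }
  structure(list(
    name = "nussinov",
    fold = fold,
    accessibility = function(seq, window = 10L) {
      structure_accessibility(fold(seq)$structure, window)
    }
  ), class = "folding_provider")
}

#' Thermodynamic folding provider backed by the RNAfold program
#'
#' Wraps the ViennaRNA \code{RNAfold} command-line program when it is
#' available on the PATH.  Minimum free energy and the MFE structure
#' come from \code{RNAfold --noPS}; accessibility is the unpaired
#' fraction of the MFE structure, as for the bundled provider.
#'
#' @param rnafold Path to the \code{RNAfold} executable.
#' @return A folding provider (see [nussinov_provider()]).
#' @export
vienna_provider <- function(rnafold = Sys.which("RNAfold")) {
  if (!nzchar(rnafold)) stop("RNAfold executable not found on PATH")
  fold <- function(seq) {
    check_rna(seq, allow_n = TRUE)
    out <- system2(rnafold, args = "--noPS", input = seq,
                   stdout = TRUE, stderr = FALSE)
    struct_line <- out[2L]
    m <- regmatches(struct_line,
                    regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)",
                            struct_line))[[1L]]
    if (length(m) != 3L) stop("could not parse RNAfold output: ",
                              struct_line)
    list(mfe = as.numeric(m[3L]), structure = m[2L])
  }
  structure(list(
    name = "vienna",
    fold = fold,
    accessibility = function(seq, window = 10L) {
      structure_accessibility(fold(seq)$structure, window)
    }
  ), class = "folding_provider")
}

#' Minimum free energy of a sequence under a folding provider
#'
#' @param seq RNA sequence over \code{A,C,G,U} (residual \code{N} in
#'   target sites is treated as unpairable).
#' @param provider A folding provider; default the bundled DP folder.
#' @return MFE in kcal/mol, always <= 0; exactly 0 for sequences that
#'   admit no base pairs.
#' @export
compute_free_energy <- function(seq, provider = nussinov_provider()) {
  stopifnot(inherits(provider, "folding_provider"))
  provider$fold(seq)$mfe
}

#' Mean accessibility (unpaired fraction) of a sequence
#'
#' Average over all sliding windows of length \code{window} of the
#' fraction of window positions left unpaired by the provider's
#' minimum-energy structure; a fully unpairable sequence scores 1.
#'
#' @inheritParams compute_free_energy
#' @param window Window length, \code{1 <= window <= nchar(seq)}.
#' @return Accessibility in \[0, 1\].
#' @export
compute_accessibility <- function(seq, provider = nussinov_provider(),
                                  window = 10L) {
  stopifnot(inherits(provider, "folding_provider"))
  if (window < 1 || window > nchar(seq)) {
    stop("window must satisfy 1 <= window <= nchar(seq)")
  }
  provider$accessibility(seq, as.integer(window))
}

# Mean over sliding windows of the unpaired fraction of a dot-bracket
# structure.
structure_accessibility <- function(structure, window) {
  unpaired <- as.integer(strsplit(structure, "")[[1L]] == ".")
  n <- length(unpaired)
  window <- min(as.integer(window), n)
  cs <- cumsum(c(0L, unpaired))
  starts <- seq_len(n - window + 1L)
  mean((cs[starts + window] - cs[starts]) / window)
}

check_rna <- function(seq, allow_n = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("sequence must be non-empty")
  pat <- if (allow_n) "[^ACGUN]" else "[^ACGU]"
  if (grepl(pat, seq)) {
    stop("sequence contains letters outside the RNA alphabet: ", seq)
  }
  invisible(seq)
}
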