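#' Gaussian interaction-profile kernel
#'
#' Radial-basis similarity between per-entity real vectors (binary
#' interaction profiles or SSR count vectors):
#' \code{K[i,j] = exp(-phi * ||v_i - v_j||^2)} with the bandwidth set
#' from the data as \code{phi = phi_prime / mean_i(||v_i||^2)}.
#'
#' @param vectors Numeric matrix, one row per entity; optional row
#'   names become the kernel's entity ids.
#' @param phi_prime Bandwidth scale (default 1).
#' @return Square symmetric similarity matrix with unit diagonal and
#'   entries in \[0, 1\].
#' @export
gaussian_profile_kernel <- function(vectors, phi_prime = 1) {
  stopifnot(is.matrix(vectors), is.numeric(vectors), nrow(vectors) >= 1)
  mean_sq <- mean(rowSums(vectors^2))
  if (mean_sq == 0) {
    stop("bandwidth undefined: all profile vectors have zero norm")
  }
  phi <- phi_prime / mean_sq
  D2 <- as.matrix(stats::dist(vectors))^2
  K <- exp(-phi * D2)
  dimnames(K) <- list(rownames(vectors), rownames(vectors))
  K
}

#' Gaussian kernel over a scalar feature
#'
#' Similarity between per-entity scalars (free energy, accessibility,
#' AU fraction): \code{K[i,j] = exp(-gamma * (x_i - x_j)^2)} with the
#' same data-driven bandwidth rule as the profile kernel,
#' \code{gamma = 1 / mean_i(x_i^2)}.  When every value is exactly 0 the
#' bandwidth is undefined; the kernel falls back to \code{gamma = 1}
#' with a warning (all distances are then 0 and the kernel is all
#' ones regardless).
#'
#' @param values Numeric vector, one value per entity; optional names
#'   become the entity ids.
#' @return Square symmetric similarity matrix with unit diagonal and
#'   entries in \[0, 1\].
#' @export
scalar_gaussian_kernel <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  mean_sq <- mean(values^2)
  if (mean_sq == 0) {
    warning("all feature values are 0; falling back to unit bandwidth")
    gamma <- 1
  } else {
    gamma <- 1 / mean_sq
  }
  K <- exp(-gamma * outer(values, values, "-")^2)
  dimnames(K) <- list(names(values), names(values))
  K
}

#' Needleman-Wunsch sequence-similarity kernel
#'
#' Raw global-alignment scores by standard Needleman-Wunsch dynamic
#' programming (through \code{Biostrings::pairwiseAlignment} with a
#' linear gap model), normalized by the geometric mean of the
#' self-scores and clipped at 0 so the kernel stays in \[0, 1\]:
#' \code{K[i,j] = max(0, s(i,j) / sqrt(s(i,i) * s(j,j)))}.
#'
#' @param seqs Named character vector of RNA sequences.
#' @param match,mismatch,gap Alignment scores (defaults +1/-1/-1); the
#'   gap penalty applies per gapped position.
#' @return Square symmetric similarity matrix with unit diagonal.
#' @export
nw_similarity_kernel <- function(seqs, match = 1, mismatch = -1, gap = -1) {
  stopifnot(length(seqs) >= 1, all(nzchar(seqs)))
  n <- length(seqs)
  letters <- c("A", "C", "G", "U", "N")
  sub <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(sub) <- match
  sub["N", ] <- 0
  sub[, "N"] <- 0
  set <- Biostrings::RNAStringSet(unname(seqs))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      set[i:n], set[[i]], type = "global", substitutionMatrix = sub,
      gapOpening = 0, gapExtension = -gap, scoreOnly = TRUE)
    S[i, i:n] <- sc
    S[i:n, i] <- sc
  }
  self <- diag(S)
  if (any(self <= 0)) stop("non-positive self-alignment score")
  K <- S / sqrt(outer(self, self))
  K <- pmax(K, 0)
  diag(K) <- 1
  dimnames(K) <- list(names(seqs), names(seqs))
  K
}

#' Weighted integration of similarity kernels
#'
#' Entrywise convex combination of kernels over the same entity set:
#' the integrated kernel is \code{sum_i w_i K_i / sum_i w_i}.  With
#' matching inputs the result inherits symmetry, unit diagonal and the
#' \[0, 1\] range.
#'
#' @param kernels List of square similarity matrices with identical
#'   dimnames.
#' @param weights Nonnegative weights, one per kernel, not all zero.
#' @return The integrated similarity matrix.
#' @export
integrate_kernels <- function(kernels, weights) {
  stopifnot(is.list(kernels), length(kernels) == length(weights),
            all(weights >= 0))
  if (sum(weights) == 0) stop("at least one weight must be positive")
  ref <- dimnames(kernels[[1L]])
  for (K in kernels) {
    if (!identical(dim(K), dim(kernels[[1L]])) ||
        !identical(dimnames(K), ref)) {
      stop("kernels must share the same entity list in the same order")
    }
  }
  out <- 0
  for (i in seq_along(kernels)) out <- out + weights[i] * kernels[[i]]
  out / sum(weights)
}

#' Project a kernel onto the nearest well-behaved PSD kernel
#'
#' Eigenvalues below \code{floor} are clipped to \code{floor}, the
#' matrix is reconstructed and rescaled to a unit diagonal.  Already
#' positive semi-definite input is returned unchanged.  Needed because
#' the normalized alignment kernel can be indefinite, while the
#' eigendecomposition solve assumes well-behaved symmetric kernels.
#'
#' @param K Symmetric matrix.
#' @param floor Smallest admissible eigenvalue (default 0).
#' @return A symmetric PSD matrix with unit diagonal.
#' @export
nearest_psd <- function(K, floor = 0) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8) stop("kernel must be symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) >= floor) return(K)
  vals <- pmax(e$values, floor)
  K2 <- e$vectors %*% (vals * t(e$vectors))
  K2 <- (K2 + t(K2)) / 2
  d <- diag(K2)
  if (any(d <= 0)) stop("degenerate kernel: zero diagonal after clipping")
  K2 <- K2 / sqrt(outer(d, d))
  diag(K2) <- 1
  dimnames(K2) <- dimnames(K)
  K2
}

#' Label-independent feature kernels for a dataset
#'
#' Builds every similarity kernel that does not depend on the
#' interaction labels: for miRNAs the free-energy, sequence-alignment
#' and SSR kernels; for target sites the free-energy, accessibility,
#' AU-content and SSR kernels.  Site sequences are first trimmed to
#' \code{config$site_length} with [trim_site()].  The alignment kernel
#' is passed through [nearest_psd()]; the Gaussian kernels are PSD by
#' construction.  When no sequence in a set carries a qualifying SSR
#' run, every repeat vector is identical (empty) and the SSR kernel
#' degenerates to its natural limit, the all-ones matrix.
#'
#' @param dataset A [mirna_dataset()].
#' @param config A [mirkron_config()].
#' @return List with elements \code{mirna} (kernels \code{FE},
#'   \code{NS}, \code{SR}) and \code{site} (kernels \code{FE},
#'   \code{TA}, \code{AU}, \code{SR}).
#' @export
feature_kernels <- function(dataset, config = mirkron_config()) {
  stopifnot(inherits(dataset, "mirna_dataset"))
  provider <- get_provider(config)
  m_seqs <- stats::setNames(dataset$mirnas$sequence, dataset$mirnas$id)
  t_seqs <- stats::setNames(
    vapply(dataset$sites$sequence, trim_site, character(1),
           target_length = config$site_length),
    dataset$sites$id)

  m_mfe <- stats::setNames(
    vapply(m_seqs, compute_free_energy, numeric(1), provider = provider),
    names(m_seqs))
  t_folds <- lapply(t_seqs, provider$fold)
  t_mfe <- vapply(t_folds, function(f) f$mfe, numeric(1))
  t_acc <- vapply(t_folds, function(f) {
    structure_accessibility(f$structure,
                            min(config$accessibility_window,
                                nchar(f$structure)))
  }, numeric(1))
  t_au <- vapply(t_seqs, compute_au_content, numeric(1))

  list(
    mirna = list(
      FE = scalar_gaussian_kernel(m_mfe),
      NS = nearest_psd(nw_similarity_kernel(
        m_seqs, config$nw_match, config$nw_mismatch, config$nw_gap)),
      SR = ssr_kernel(m_seqs, config)
    ),
    site = list(
      FE = scalar_gaussian_kernel(t_mfe),
      TA = scalar_gaussian_kernel(t_acc),
      AU = scalar_gaussian_kernel(t_au),
      SR = ssr_kernel(t_seqs, config)
    )
  )
}

# SSR Gaussian-profile kernel with the degenerate all-identical limit.
ssr_kernel <- function(seqs, config) {
  M <- ssr_feature_matrix(seqs, min_repeats = config$ssr_min_repeats,
                          binary = config$ssr_binary)
  if (ncol(M) == 0L || all(M == 0)) {
    K <- matrix(1, length(seqs), length(seqs),
                dimnames = list(names(seqs), names(seqs)))
    return(K)
  }
  gaussian_profile_kernel(M, config$phi_prime)
}

#' Assemble the integrated kernels Sm and St
#'
#' Adds the label-dependent Gaussian interaction-profile kernel
#' (computed from the rows of the supplied training adjacency matrix)
#' to the miRNA feature kernels, then forms the weighted combinations
#' \code{Sm = (a1 FE + a2 GP + a3 NS + a4 SR) / sum(a)} and
#' \code{St = (b1 FE + b2 TA + b3 AU + b4 SR) / sum(b)}.
#'
#' Pass the *training* adjacency (held-out cells zeroed) so the
#' profile kernel never sees test labels.
#'
#' @param fk Feature kernels from [feature_kernels()].
#' @param Y Binary training adjacency matrix (miRNAs x sites).
#' @param config A [mirkron_config()].
#' @return List with integrated kernels \code{Sm} and \code{St}.
#' @export
assemble_kernels <- function(fk, Y, config = mirkron_config()) {
  Sm <- assemble_sm(fk, Y, config)
  St <- integrate_kernels(list(fk$site$FE, fk$site$TA, fk$site$AU,
                               fk$site$SR),
                          config$beta)
  list(Sm = Sm, St = St)
}

# Integrated miRNA kernel only: the site kernels are label-independent,
# so cross-validation refits rebuild just this side.
assemble_sm <- function(fk, Y, config) {
  validate_interaction_matrix(Y)
  GPm <- if (all(Y == 0)) {
    matrix(1, nrow(Y), nrow(Y), dimnames = list(rownames(Y), rownames(Y)))
  } else {
    gaussian_profile_kernel(Y, config$phi_prime)
  }
  integrate_kernels(list(fk$mirna$FE, GPm, fk$mirna$NS, fk$mirna$SR),
                    config$alpha)
}

#' Write a similarity kernel as TSV with id headers
#'
#' @param K Square similarity matrix with dimnames.
#' @param path Output path.
#' @export
write_kernel <- function(K, path) {
  df <- data.frame(entity_id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a similarity kernel written by [write_kernel()]
#'
#' @param path TSV path.
#' @return The kernel matrix with dimnames.
#' @export
read_kernel <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1L]]
  storage.mode(K) <- "double"
  K
}
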