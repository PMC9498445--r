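#' Specification for a planted-family synthetic dataset
#'
#' Describes a dataset embodying the structural assumption the model
#' exploits: miRNAs within a family share a 7-nt seed and target the
#' sites of the same family, whose sequences embed the seed's reverse
#' complement.  Defaults give 5 families of 20 miRNAs x 60 sites
#' (22-nt miRNAs, 40-nt sites), a 5\% per-base mutation rate on the
#' miRNAs and 10\% of positives rewired across families.
#'
#' @param n_families Number of planted families.
#' @param mirnas_per_family,sites_per_family Family sizes.
#' @param mirna_length,site_length Sequence lengths (site_length >= 7).
#' @param mutation_rate Per-base substitution probability applied to
#'   each miRNA after seed embedding.
#' @param cross_family_noise Fraction of within-family positives
#'   rewired uniformly to out-of-family cells.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_families = 5L, mirnas_per_family = 20L,
                           sites_per_family = 60L, mirna_length = 22L,
                           site_length = 40L, mutation_rate = 0.05,
                           cross_family_noise = 0.1, seed = 1L) {
  stopifnot(n_families >= 1, mirnas_per_family >= 1,
            sites_per_family >= 1, mirna_length >= 8,
            mutation_rate >= 0, mutation_rate <= 1,
            cross_family_noise >= 0, cross_family_noise <= 1)
  if (site_length < 7) stop("site_length must be >= 7 to embed the seed")
  structure(list(n_families = as.integer(n_families),
                 mirnas_per_family = as.integer(mirnas_per_family),
                 sites_per_family = as.integer(sites_per_family),
                 mirna_length = as.integer(mirna_length),
                 site_length = as.integer(site_length),
                 mutation_rate = mutation_rate,
                 cross_family_noise = cross_family_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a planted-family synthetic dataset
#'
#' For each family a random 7-nt seed is drawn.  Family miRNAs embed
#' the seed at positions 2-8 of a random background and then receive
#' independent per-base substitutions at \code{mutation_rate}.  Family
#' sites embed the seed's reverse complement at a random offset in an
#' AU-enriched random background (A/U probability 0.35 each vs 0.15
#' for G/C), making the AU-content kernel informative.  Positives are
#' all within-family miRNA x site pairs, after which
#' \code{round(cross_family_noise * total)} of them are rewired
#' uniformly to out-of-family cells.  Generation is byte-deterministic
#' under the spec seed, and no sequence contains \code{N}, so the
#' records pass [filter_records()] unchanged.
#'
#' @param spec A [synthetic_spec()].
#' @return A [mirna_dataset()] carrying the latent structure
#'   retrievable with [ground_truth()].
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bases <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  withr::with_seed(spec$seed, {
    m_ids <- m_seqs <- character(0)
    t_ids <- t_seqs <- character(0)
    m_fam <- t_fam <- integer(0)
    for (f in seq_len(spec$n_families)) {
      seed7 <- sample(bases, 7L, replace = TRUE)
      for (i in seq_len(spec$mirnas_per_family)) {
        s <- sample(bases, spec$mirna_length, replace = TRUE)
        s[2:8] <- seed7
        mut <- stats::runif(spec$mirna_length) < spec$mutation_rate
        if (any(mut)) {
          s[mut] <- vapply(s[mut], function(b) {
            sample(setdiff(bases, b), 1L)
          }, character(1))
        }
        m_ids <- c(m_ids, sprintf("mir_f%02d_%03d", f, i))
        m_seqs <- c(m_seqs, paste(s, collapse = ""))
        m_fam <- c(m_fam, f)
      }
      rc <- rev(unname(comp[seed7]))
      for (i in seq_len(spec$sites_per_family)) {
        s <- sample(bases, spec$site_length, replace = TRUE,
                    prob = c(0.35, 0.15, 0.15, 0.35))
        pos <- sample.int(spec$site_length - 6L, 1L)
        s[pos:(pos + 6L)] <- rc
        t_ids <- c(t_ids, sprintf("site_f%02d_%03d", f, i))
        t_seqs <- c(t_seqs, paste(s, collapse = ""))
        t_fam <- c(t_fam, f)
      }
    }
    A <- matrix(0, length(m_ids), length(t_ids),
                dimnames = list(m_ids, t_ids))
    for (f in seq_len(spec$n_families)) {
      A[m_fam == f, t_fam == f] <- 1
    }
    n_rewire <- round(spec$cross_family_noise * sum(A))
    removed <- added <- data.frame(mirna_id = character(0),
                                   site_id = character(0),
                                   stringsAsFactors = FALSE)
    if (n_rewire > 0) {
      pos_cells <- which(A == 1, arr.ind = TRUE)
      out <- pos_cells[sample.int(nrow(pos_cells), n_rewire), ,
                       drop = FALSE]
      cross <- which(outer(m_fam, t_fam, "!=") & A == 0, arr.ind = TRUE)
      dest <- cross[sample.int(nrow(cross), n_rewire), , drop = FALSE]
      A[out] <- 0
      A[dest] <- 1
      removed <- data.frame(mirna_id = m_ids[out[, 1L]],
                            site_id = t_ids[out[, 2L]],
                            stringsAsFactors = FALSE)
      added <- data.frame(mirna_id = m_ids[dest[, 1L]],
                          site_id = t_ids[dest[, 2L]],
                          stringsAsFactors = FALSE)
    }
    ds <- mirna_dataset(
      sequence_records(m_ids, "miRNA", m_seqs),
      sequence_records(t_ids, "target_site", t_seqs),
      A
    )
    attr(ds, "truth") <- list(
      mirna_families = stats::setNames(m_fam, m_ids),
      site_families = stats::setNames(t_fam, t_ids),
      removed = removed, added = added, spec = spec
    )
    ds
  })
}

#' Latent structure of a synthetic dataset
#'
#' Returns the family assignment of every miRNA and site plus the
#' rewired-pair lists (\code{removed}: within-family positives turned
#' off; \code{added}: the out-of-family cells they were rewired to),
#' for use in recovery experiments.
#'
#' @param dataset A dataset produced by [generate_dataset()].
#' @return List with \code{mirna_families}, \code{site_families},
#'   \code{removed}, \code{added} and the generating \code{spec}.
#' @export
ground_truth <- function(dataset) {
  truth <- attr(dataset, "truth")
  if (is.null(truth)) {
    stop("dataset carries no ground truth (not produced by ",
         "generate_dataset)")
  }
  truth
}

#' Write a synthetic dataset to FASTA/TSV/JSON files
#'
#' Writes \code{mirnas.fasta}, \code{sites.fasta},
#' \code{interactions.tsv} and (for synthetic datasets)
#' \code{truth.json} under \code{dir}.
#'
#' @param dataset A [mirna_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mirna_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta <- function(records, path) {
    writeLines(paste0(">", records$id, "\n", records$sequence), path)
  }
  write_fasta(dataset$mirnas, file.path(dir, "mirnas.fasta"))
  write_fasta(dataset$sites, file.path(dir, "sites.fasta"))
  pos <- which(dataset$interactions == 1, arr.ind = TRUE)
  tab <- data.frame(mirna_id = rownames(dataset$interactions)[pos[, 1L]],
                    site_id = colnames(dataset$interactions)[pos[, 2L]],
                    label = 1L)
  utils::write.table(tab, file.path(dir, "interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) {
    truth$spec <- unclass(truth$spec)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
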