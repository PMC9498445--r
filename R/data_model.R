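#' Read miRNA or target-site sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a sequence-record data frame.
#' Sequences are case-folded to upper case and DNA input is accepted:
#' \code{T} is mapped to \code{U}.  Any letter outside
#' \code{A,C,G,U,N,T} is a hard error rather than being silently
#' masked, and record ids must be unique within a role.
#'
#' @param path Path to a FASTA file.
#' @param role Either \code{"miRNA"} or \code{"target_site"}.
#' @return A data frame with columns \code{id}, \code{role},
#'   \code{sequence} (upper-case RNA alphabet \code{A,C,G,U,N}).
#' @seealso [filter_records()], [read_interactions()]
#' @export
read_fasta <- function(path, role = c("miRNA", "target_site")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sequence id(s) within role '", role, "': ",
         paste(dup, collapse = ", "))
  }
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("sequence(s) with letters outside {A,C,G,U,N,T}: ",
         paste(ids[bad], collapse = ", "))
  }
  sequence_records(ids, role, seqs)
}

#' Construct a sequence-record data frame
#'
#' @param id Character vector of unique ids.
#' @param role \code{"miRNA"} or \code{"target_site"} (recycled).
#' @param sequence Upper-case RNA sequences over \code{A,C,G,U,N}.
#' @return Data frame with columns \code{id}, \code{role}, \code{sequence}.
#' @export
sequence_records <- function(id, role, sequence) {
  stopifnot(length(id) == length(sequence))
  role <- rep_len(as.character(role), length(id))
  if (!all(role %in% c("miRNA", "target_site"))) {
    stop("role must be 'miRNA' or 'target_site'")
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) stop("empty sequence not allowed")
  if (any(grepl("[^ACGUN]", sequence))) {
    stop("sequences must be upper-case over {A,C,G,U,N}")
  }
  data.frame(id = as.character(id), role = role,
             sequence = as.character(sequence),
             stringsAsFactors = FALSE)
}

#' Filter sequence records by N content
#'
#' miRNA records containing one or more \code{N} letters are removed;
#' target-site records are removed only when strictly more than half of
#' their positions are \code{N}.  Survivor order is preserved and the
#' operation is idempotent.
#'
#' @param records A sequence-record data frame (see [read_fasta()]).
#' @return The filtered data frame (possibly empty).
#' @export
filter_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "role", "sequence") %in% names(records)))
  if (nrow(records) == 0L) return(records)
  n_count <- vapply(gregexpr("N", records$sequence, fixed = TRUE),
                    function(m) sum(m > 0L), integer(1))
  len <- nchar(records$sequence)
  keep <- ifelse(records$role == "miRNA",
                 n_count == 0L,
                 n_count / len <= 0.5)
  records[keep, , drop = FALSE]
}

#' Trim a target-site sequence to a fixed length
#'
#' Sequences longer than \code{target_length} are reduced to the
#' centered window of that length; on an odd overhang the window is
#' left-biased.  Shorter or equal-length sequences pass unchanged.  The
#' centered window retains flanking context symmetrically around the
#' (unknown) seed-match position.
#'
#' @param seq A single sequence string.
#' @param target_length Window length, >= 1.
#' @return The trimmed sequence.
#' @export
trim_site <- function(seq, target_length) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is.numeric(target_length) || length(target_length) != 1L ||
      target_length < 1) {
    stop("target_length must be a single integer >= 1")
  }
  target_length <- as.integer(target_length)
  n <- nchar(seq)
  if (n <= target_length) return(seq)
  start <- (n - target_length) %/% 2L + 1L
  substr(seq, start, start + target_length - 1L)
}

#' Bundle sequence records and an interaction matrix into a dataset
#'
#' @param mirnas miRNA sequence records (role \code{"miRNA"}).
#' @param sites Target-site sequence records (role \code{"target_site"}).
#' @param interactions Optional binary interaction matrix with row
#'   names equal to the miRNA ids and column names equal to the site
#'   ids (see [read_interactions()]).
#' @return An object of class \code{mirna_dataset}.
#' @export
mirna_dataset <- function(mirnas, sites, interactions = NULL) {
  stopifnot(all(mirnas$role == "miRNA"), all(sites$role == "target_site"))
  if (anyDuplicated(mirnas$id) || anyDuplicated(sites$id)) {
    stop("duplicate ids within a role")
  }
  if (!is.null(interactions)) {
    validate_interaction_matrix(interactions)
    if (!identical(rownames(interactions), mirnas$id) ||
        !identical(colnames(interactions), sites$id)) {
      stop("interaction matrix dimnames must match the record ids in order")
    }
  }
  structure(list(mirnas = mirnas, sites = sites,
                 interactions = interactions),
            class = "mirna_dataset")
}

#' @export
print.mirna_dataset <- function(x, ...) {
  np <- if (is.null(x$interactions)) NA_integer_ else sum(x$interactions)
  cat("mirna_dataset: ", nrow(x$mirnas), " miRNAs x ", nrow(x$sites),
      " target sites, ", np, " known interactions\n", sep = "")
  invisible(x)
}

#' Validate a binary interaction (adjacency) matrix
#'
#' Checks that the matrix is numeric and binary with duplicate-free row
#' (miRNA) and column (site) names.
#'
#' @param A Matrix to validate.
#' @return \code{A}, invisibly.
#' @export
validate_interaction_matrix <- function(A) {
  stopifnot(is.matrix(A), is.numeric(A))
  if (is.null(rownames(A)) || is.null(colnames(A))) {
    stop("interaction matrix needs row (miRNA) and column (site) names")
  }
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A))) {
    stop("interaction matrix dimnames must be duplicate-free")
  }
  if (!all(A %in% c(0, 1))) stop("interaction matrix entries must be 0/1")
  invisible(A)
}

#' Read known interactions into a binary adjacency matrix
#'
#' Reads a tab-separated table with header columns \code{mirna_id},
#' \code{site_id} and optional \code{label} (0/1; missing label means
#' 1).  Listed pairs with label 1 become the positive set; every other
#' miRNA x site cell is 0, i.e. the remaining pairs are treated as the
#' negative set.
#'
#' @param path Path to the TSV file.
#' @param dataset A [mirna_dataset()] supplying the id universe and
#'   ordering.
#' @return A binary matrix (miRNAs x sites) with id dimnames.
#' @export
read_interactions <- function(path, dataset) {
  stopifnot(inherits(dataset, "mirna_dataset"))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "site_id") %in% names(tab))) {
    stop("interaction table must have header columns mirna_id, site_id")
  }
  mid <- dataset$mirnas$id
  sid <- dataset$sites$id
  A <- matrix(0, nrow = length(mid), ncol = length(sid),
              dimnames = list(mid, sid))
  if (nrow(tab) == 0L) return(A)
  label <- if ("label" %in% names(tab)) as.numeric(tab$label) else
    rep(1, nrow(tab))
  if (!all(label %in% c(0, 1))) stop("labels must be 0 or 1")
  unknown_m <- setdiff(unique(tab$mirna_id), mid)
  if (length(unknown_m)) {
    stop("unknown miRNA id ", paste(unknown_m, collapse = ", "))
  }
  unknown_s <- setdiff(unique(tab$site_id), sid)
  if (length(unknown_s)) {
    stop("unknown site id ", paste(unknown_s, collapse = ", "))
  }
  key <- paste(tab$mirna_id, tab$site_id, sep = "\r")
  conf <- tapply(label, key, function(v) length(unique(v)) > 1L)
  if (any(conf)) {
    stop("duplicate pair(s) with conflicting labels: ",
         paste(gsub("\r", " / ", names(conf)[conf]), collapse = ", "))
  }
  pos <- label == 1
  A[cbind(match(tab$mirna_id[pos], mid), match(tab$site_id[pos], sid))] <- 1
  A
}

#' Sample a random submatrix of an adjacency matrix
#'
#' Draws \code{k} rows (miRNAs) and \code{l} columns (sites) uniformly
#' without replacement, independently for rows and columns,
#' deterministic under \code{seed}.  Defaults reproduce the usual
#' working matrix: all miRNAs and a random 10\% of the sites.  Sampled
#' positives are not guaranteed unless \code{require_positive_rows} is
#' set, in which case sampling is repeated until every row retains at
#' least one positive.
#'
#' @param A Binary interaction matrix with dimnames.
#' @param k Number of rows to keep (default all).
#' @param l Number of columns to keep (default \code{round(0.1 * ncol(A))}).
#' @param seed Integer seed.
#' @param require_positive_rows Resample until every sampled row has a
#'   positive (at most 1000 attempts).
#' @return The sampled submatrix with dimnames.
#' @export
sample_submatrix <- function(A, k = nrow(A), l = round(0.1 * ncol(A)),
                             seed = 1L, require_positive_rows = FALSE) {
  validate_interaction_matrix(A)
  if (k > nrow(A) || l > ncol(A)) {
    stop("k and l must not exceed the matrix dimensions")
  }
  if (k < 1 || l < 1) stop("k and l must be >= 1")
  withr::with_seed(seed, {
    for (attempt in seq_len(1000L)) {
      ri <- sample.int(nrow(A), k)
      ci <- sample.int(ncol(A), l)
      S <- A[ri, ci, drop = FALSE]
      if (!require_positive_rows || all(rowSums(S) > 0)) return(S)
    }
    stop("could not sample a submatrix with a positive in every row")
  })
}

#' Write an interaction matrix as TSV with id headers
#'
#' @param A Binary interaction matrix with dimnames.
#' @param path Output path.
#' @export
write_interaction_matrix <- function(A, path) {
  validate_interaction_matrix(A)
  df <- data.frame(mirna_id = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
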