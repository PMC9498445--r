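#' Area under the ROC curve by the rank statistic
#'
#' \code{AUC = P(score_pos > score_neg) + 0.5 P(tie)}, computed from
#' midranks (the Wilcoxon/Mann-Whitney statistic), so it is invariant
#' under any strictly monotone transform of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary true labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- as.numeric(sum(labels == 1))
  nneg <- as.numeric(sum(labels == 0))
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Confusion-matrix metrics at a score threshold
#'
#' A pair is predicted positive when its score is >= the threshold.
#' Matthews correlation is set to 0 by convention when any marginal of
#' the 2x2 table is empty.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold.
#' @return Named vector with \code{accuracy}, \code{sensitivity},
#'   \code{specificity} and \code{mcc}.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both classes must be present")
  }
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    mcc = mcc)
}

#' Youden-optimal decision threshold
#'
#' Scans the observed scores and returns the threshold maximizing
#' Youden's J (sensitivity + specificity - 1); ties are broken toward
#' the larger threshold.
#'
#' @inheritParams roc_auc
#' @return The selected threshold.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both classes must be present")
  }
  cand <- sort(unique(scores))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  J <- vapply(cand, function(t) {
    mean(pos >= t) + mean(neg < t) - 1
  }, numeric(1))
  max(cand[J == max(J)])
}

#' Unity-based per-miRNA score normalization
#'
#' Rescales each row (miRNA) of a score matrix to \[0, 1\]:
#' \code{X' = (X - Xmin) / (Xmax - Xmin)}, where the bounds are the
#' minimum and maximum score of that miRNA across all sites.  A
#' constant row has no spread; its entries are set to 0.5 with a
#' warning.
#'
#' @param score_matrix Numeric score matrix (miRNAs x sites).
#' @return The row-normalized matrix.
#' @export
normalize_scores <- function(score_matrix) {
  stopifnot(is.matrix(score_matrix), is.numeric(score_matrix))
  lo <- apply(score_matrix, 1L, min)
  hi <- apply(score_matrix, 1L, max)
  flat <- hi == lo
  if (any(flat)) {
    warning("constant score row(s) set to 0.5: ",
            paste(utils::head(which(flat), 5L), collapse = ", "))
  }
  out <- (score_matrix - lo) / ifelse(flat, 1, hi - lo)
  out[flat, ] <- 0.5
  out
}

#' Quartile classification of normalized scores
#'
#' Computes the lower and upper quartiles of the supplied score
#' population by linear interpolation between order statistics and
#' classifies each score: below the lower quartile is \code{Weak},
#' above the upper quartile is \code{Strong}, and everything between
#' the quartiles (inclusive) is \code{Moderate}.
#'
#' @param normalized_scores Numeric vector of at least 4 scores.
#' @return Character vector of classes.
#' @export
quantile_classify <- function(normalized_scores) {
  stopifnot(is.numeric(normalized_scores))
  if (length(normalized_scores) < 4L) {
    stop("at least 4 scores are needed to form quartiles")
  }
  q <- stats::quantile(normalized_scores, c(0.25, 0.75), names = FALSE,
                       type = 7)
  ifelse(normalized_scores < q[1L], "Weak",
         ifelse(normalized_scores > q[2L], "Strong", "Moderate"))
}

#' Leave-one-association-out cross-validation
#'
#' For every evaluated positive cell (i, j) the label is zeroed in the
#' training adjacency, the interaction-profile kernel and the
#' integrated miRNA kernel are rebuilt from the masked adjacency, the
#' model is refit and the score recorded for (i, j) -- so the held-out
#' label never influences its own score.  Masking a negative cell
#' leaves the adjacency unchanged, so negatives are scored by the base
#' fit.  Negatives are subsampled to \code{config$negative_ratio}
#' per evaluated positive and positives capped at
#' \code{config$max_positives}, both seeded, for tractability.
#'
#' @param dataset A [mirna_dataset()] with interactions and at least
#'   one positive.
#' @param config A [mirkron_config()].
#' @param seed Integer seed for the evaluation-cell subsampling.
#' @param fk Optional precomputed [feature_kernels()] (they do not
#'   depend on the labels, so they can be shared across runs).
#' @return A \code{prediction_report}; see [prediction_report] fields.
#' @export
loocv <- function(dataset, config = mirkron_config(), seed = 1L,
                  fk = NULL) {
  Y <- dataset$interactions
  validate_interaction_matrix(Y)
  if (sum(Y) == 0) stop("dataset has no positive interactions")
  if (is.null(fk)) fk <- feature_kernels(dataset, config)
  kern <- assemble_kernels(fk, Y, config)
  et <- eigen(kern$St, symmetric = TRUE)
  em0 <- eigen(kern$Sm, symmetric = TRUE)
  base <- kron_rls_eigen(em0, et, Y, config$lambda)

  pos <- which(Y == 1, arr.ind = TRUE)
  neg <- which(Y == 0, arr.ind = TRUE)
  sel <- withr::with_seed(seed, {
    pi <- if (nrow(pos) > config$max_positives) {
      pos[sample.int(nrow(pos), config$max_positives), , drop = FALSE]
    } else pos
    n_neg <- min(nrow(neg), ceiling(config$negative_ratio * nrow(pi)))
    ni <- neg[sample.int(nrow(neg), n_neg), , drop = FALSE]
    list(pos = pi, neg = ni)
  })

  pos_scores <- vapply(seq_len(nrow(sel$pos)), function(r) {
    i <- sel$pos[r, 1L]; j <- sel$pos[r, 2L]
    Y2 <- Y
    Y2[i, j] <- 0
    Sm2 <- assemble_sm(fk, Y2, config)
    em <- eigen(Sm2, symmetric = TRUE)
    kron_rls_eigen(em, et, Y2, config$lambda)$scores[i, j]
  }, numeric(1))
  neg_scores <- base$scores[sel$neg]

  records <- data.frame(
    mirna_id = rownames(Y)[c(sel$pos[, 1L], sel$neg[, 1L])],
    site_id = colnames(Y)[c(sel$pos[, 2L], sel$neg[, 2L])],
    score = c(pos_scores, neg_scores),
    label = c(rep(1L, nrow(sel$pos)), rep(0L, nrow(sel$neg))),
    fold = seq_len(nrow(sel$pos) + nrow(sel$neg)),
    stringsAsFactors = FALSE
  )
  threshold <- training_threshold(base$scores, Y, seed)
  prediction_report(records, base$scores, threshold, mode = "loocv")
}

#' Leave-target-sites-out cross-validation
#'
#' In each iteration a random \code{ceiling(fraction * l)} subset of
#' site columns is held out: all their cells are zeroed in the
#' training adjacency (and hence in the interaction profiles), the
#' model is fit once, and the held-out cells are scored against their
#' true labels.  Repeated over \code{config$iterations} seeded
#' randomizations with per-iteration and pooled metrics.
#'
#' @inheritParams loocv
#' @param fraction Fraction of site columns held out per iteration.
#' @return A \code{prediction_report} with a \code{per_iteration} AUC
#'   table.
#' @export
lmitocv <- function(dataset, config = mirkron_config(), fraction = 0.1,
                    seed = 1L, fk = NULL) {
  Y <- dataset$interactions
  validate_interaction_matrix(Y)
  if (sum(Y) == 0) stop("dataset has no positive interactions")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  l <- ncol(Y)
  if (fraction * l < 1) {
    stop("fraction * number of sites is below 1; nothing to hold out")
  }
  n_held <- as.integer(ceiling(fraction * l))
  if (is.null(fk)) fk <- feature_kernels(dataset, config)
  St <- assemble_kernels(fk, Y, config)$St
  et <- eigen(St, symmetric = TRUE)

  rec_list <- vector("list", config$iterations)
  iter_auc <- rep(NA_real_, config$iterations)
  train_scores <- train_labels <- vector("list", config$iterations)
  for (it in seq_len(config$iterations)) {
    held <- withr::with_seed(seed + it - 1L, sample.int(l, n_held))
    Y2 <- Y
    Y2[, held] <- 0
    Sm2 <- assemble_sm(fk, Y2, config)
    em <- eigen(Sm2, symmetric = TRUE)
    f <- kron_rls_eigen(em, et, Y2, config$lambda)
    sc <- f$scores[, held, drop = FALSE]
    lab <- Y[, held, drop = FALSE]
    rec_list[[it]] <- data.frame(
      mirna_id = rep(rownames(Y), times = n_held),
      site_id = rep(colnames(Y)[held], each = nrow(Y)),
      score = as.vector(sc),
      label = as.integer(as.vector(lab)),
      fold = it,
      stringsAsFactors = FALSE
    )
    if (any(lab == 1) && any(lab == 0)) {
      iter_auc[it] <- roc_auc(as.vector(sc), as.vector(lab))
    }
    keep <- setdiff(seq_len(l), held)
    tr_sc <- f$scores[, keep, drop = FALSE]
    tr_lab <- Y2[, keep, drop = FALSE]
    samp <- withr::with_seed(seed + it - 1L,
                             sample.int(length(tr_sc),
                                        min(2000L, length(tr_sc))))
    train_scores[[it]] <- as.vector(tr_sc)[samp]
    train_labels[[it]] <- as.vector(tr_lab)[samp]
  }
  records <- do.call(rbind, rec_list)
  ts <- unlist(train_scores)
  tl <- unlist(train_labels)
  threshold <- if (any(tl == 1) && any(tl == 0)) {
    choose_threshold(ts, tl)
  } else {
    stats::median(ts)
  }
  base <- kron_rls_fit(assemble_sm(fk, Y, config), St, Y, config$lambda)
  rep <- prediction_report(records, base$scores, threshold,
                           mode = "lmitocv")
  rep$per_iteration <- data.frame(iteration = seq_len(config$iterations),
                                  auc = iter_auc)
  rep
}

# Youden threshold from training predictions of the base fit: the
# model's fitted scores against the labels it was trained on, over a
# seeded sample of cells.
training_threshold <- function(base_scores, Y, seed) {
  n <- length(Y)
  samp <- withr::with_seed(seed, sample.int(n, min(20000L, n)))
  sc <- as.vector(base_scores)[samp]
  lab <- as.vector(Y)[samp]
  if (!any(lab == 1) || !any(lab == 0)) {
    sc <- as.vector(base_scores)
    lab <- as.vector(Y)
  }
  choose_threshold(sc, lab)
}

#' Cross-validation prediction report
#'
#' Container returned by [loocv()] and [lmitocv()]: per-pair records
#' (ids, raw cross-validated score, unity-normalized score, quartile
#' class, true label, fold), summary metrics (AUC plus accuracy,
#' sensitivity, specificity and MCC at the training-derived Youden
#' threshold), and the per-miRNA normalization bounds taken from the
#' base model's scores across all sites.
#'
#' @param records Data frame with columns \code{mirna_id},
#'   \code{site_id}, \code{score}, \code{label}, \code{fold}.
#' @param base_scores Full score matrix of the model fit on all
#'   labels, used for the per-miRNA normalization bounds.
#' @param threshold Decision threshold selected on training data.
#' @param mode \code{"loocv"} or \code{"lmitocv"}.
#' @return An object of class \code{prediction_report}.
#' @export
prediction_report <- function(records, base_scores, threshold, mode) {
  lo <- apply(base_scores, 1L, min)
  hi <- apply(base_scores, 1L, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  idx <- match(records$mirna_id, rownames(base_scores))
  norm <- (records$score - lo[idx]) / rng[idx]
  norm <- pmin(pmax(norm, 0), 1)
  norm[hi[idx] == lo[idx]] <- 0.5
  records$normalized <- norm
  records$class <- if (nrow(records) >= 4L) {
    quantile_classify(norm)
  } else {
    rep(NA_character_, nrow(records))
  }
  metrics <- list(auc = NA_real_, threshold = threshold)
  if (any(records$label == 1) && any(records$label == 0)) {
    metrics$auc <- roc_auc(records$score, records$label)
    cm <- confusion_metrics(records$score, records$label, threshold)
    metrics <- c(metrics, as.list(cm))
  }
  structure(list(records = records, metrics = metrics,
                 bounds = data.frame(mirna_id = rownames(base_scores),
                                     x_min = lo, x_max = hi,
                                     row.names = NULL),
                 a = 0, b = 1, mode = mode),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("prediction_report (", x$mode, "): ", nrow(x$records),
      " evaluated pairs\n", sep = "")
  m <- x$metrics
  cat(sprintf("  AUC %.4f | threshold %.4g", m$auc, m$threshold))
  if (!is.null(m$accuracy)) {
    cat(sprintf(" | acc %.3f sens %.3f spec %.3f MCC %.3f",
                m$accuracy, m$sensitivity, m$specificity, m$mcc))
  }
  cat("\n")
  invisible(x)
}

#' Write a prediction report as TSV plus a JSON metrics summary
#'
#' @param report A \code{prediction_report}.
#' @param prefix Output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>_metrics.json}.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "prediction_report"))
  utils::write.table(report$records, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$metrics, paste0(prefix, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
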