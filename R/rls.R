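#' Fit the Kronecker-product regularized least-squares model
#'
#' Scores every miRNA x site pair by kernel ridge regression on the
#' pair kernel \code{K = Sm %x% St}, solving \code{(K + lambda I) a = y}
#' without ever materializing the \code{kl x kl} Kronecker matrix.
#' With the eigendecompositions \code{Sm = Qm Lm Qm'} and
#' \code{St = Qt Lt Qt'}, the fitted scores are
#' \code{F = Qm (H * (Qm' Y Qt)) Qt'} where the spectral filter is
#' \code{H[a,b] = lm_a lt_b / (lm_a lt_b + lambda)} applied
#' elementwise.  This reproduces the dense solve exactly (see
#' [direct_solve()]) at cost \code{O(k^3 + l^3 + kl(k+l))}.  Tiny or
#' zero eigenvalue products pass through the same filter; for
#' \code{lambda > 0} the denominator keeps them finite.
#'
#' @param Sm Symmetric PSD miRNA similarity kernel (k x k); pass
#'   through [nearest_psd()] first if in doubt.
#' @param St Symmetric PSD site similarity kernel (l x l).
#' @param Y Binary adjacency matrix (k x l).
#' @param lambda Regularization parameter, >= 0 (0 only with strictly
#'   positive-definite kernels).
#' @return An object of class \code{rls_model} with the eigenpairs,
#'   the filtered coefficient matrix \code{C} and the score matrix.
#' @export
kron_rls_fit <- function(Sm, St, Y, lambda = 35) {
  check_fit_inputs(Sm, St, Y, lambda)
  em <- eigen(Sm, symmetric = TRUE)
  et <- eigen(St, symmetric = TRUE)
  fit <- kron_rls_eigen(em, et, Y, lambda)
  structure(list(Qm = em$vectors, lambda_m = em$values,
                 Qt = et$vectors, lambda_t = et$values,
                 lambda = lambda, C = fit$C, scores = fit$scores,
                 mirna_ids = rownames(Y), site_ids = colnames(Y),
                 format_version = 1L),
            class = "rls_model")
}

# Eigen-route solve given precomputed eigendecompositions; reused by
# the cross-validation drivers so St is only decomposed once.
kron_rls_eigen <- function(em, et, Y, lambda) {
  prod_ev <- outer(em$values, et$values)
  if (lambda == 0) {
    cond <- max(abs(prod_ev)) / min(abs(prod_ev))
    if (!is.finite(cond) || cond > 1e12) {
      stop("lambda = 0 with a numerically singular pair kernel ",
           "(condition estimate ", format(cond, digits = 3), ")")
    }
  }
  H <- prod_ev / (prod_ev + lambda)
  C <- H * crossprod(em$vectors, Y %*% et$vectors)
  scores <- em$vectors %*% C %*% t(et$vectors)
  dimnames(scores) <- dimnames(Y)
  list(C = C, scores = scores)
}

check_fit_inputs <- function(Sm, St, Y, lambda) {
  stopifnot(is.matrix(Sm), is.matrix(St), is.matrix(Y))
  if (nrow(Sm) != ncol(Sm) || nrow(St) != ncol(St)) {
    stop("kernels must be square")
  }
  if (nrow(Y) != nrow(Sm) || ncol(Y) != nrow(St)) {
    stop("dimension mismatch: Y must be nrow(Sm) x nrow(St)")
  }
  if (max(abs(Sm - t(Sm))) > 1e-8 || max(abs(St - t(St))) > 1e-8) {
    stop("kernels must be symmetric")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a single nonnegative number")
  }
  invisible(TRUE)
}

#' @export
print.rls_model <- function(x, ...) {
  cat("Kronecker RLS model: ", length(x$mirna_ids), " miRNAs x ",
      length(x$site_ids), " sites, lambda = ", x$lambda, "\n", sep = "")
  invisible(x)
}

#' Dense reference solve of the regularized least-squares system
#'
#' Materializes the Kronecker pair kernel \code{K = Sm %x% St}, solves
#' \code{(K + lambda I) a = y} with \code{y = vec(Y')} (column-major
#' stacking of the transposed adjacency, the convention under which
#' the eigen route of [kron_rls_fit()] is its exact equal), and
#' returns the reshaped fitted scores \code{K a}.  Intended as a
#' brute-force reference for small problems only.
#'
#' @inheritParams kron_rls_fit
#' @return The k x l score matrix.
#' @export
direct_solve <- function(Sm, St, Y, lambda = 35) {
  check_fit_inputs(Sm, St, Y, lambda)
  k <- nrow(Y); l <- ncol(Y)
  if (k * l > 2000) {
    stop("problem size kl = ", k * l, " exceeds the dense guard (2000); ",
         "use kron_rls_fit()")
  }
  K <- Sm %x% St
  y <- as.vector(t(Y))
  alpha <- solve(K + lambda * diag(k * l), y)
  f <- K %*% alpha
  scores <- t(matrix(f, nrow = l, ncol = k))
  dimnames(scores) <- dimnames(Y)
  scores
}

#' Score matrix of a fitted model
#'
#' @param model A fitted \code{rls_model} from [kron_rls_fit()].
#' @return The deterministic k x l score matrix with id dimnames.
#' @export
predict_scores <- function(model) {
  if (!inherits(model, "rls_model") || is.null(model$scores)) {
    stop("model must be a fitted rls_model")
  }
  model$scores
}

#' Serialize a fitted model to a single JSON archive
#'
#' @param model A fitted \code{rls_model}.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "rls_model"))
  payload <- list(
    format_version = model$format_version,
    lambda = model$lambda,
    mirna_ids = model$mirna_ids,
    site_ids = model$site_ids,
    lambda_m = model$lambda_m,
    lambda_t = model$lambda_t,
    Qm = model$Qm, Qt = model$Qt, C = model$C, scores = model$scores
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model archive written by [write_model()]
#'
#' @param path JSON archive path.
#' @return The restored \code{rls_model}.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format_version) || p$format_version != 1L) {
    stop("unsupported model archive version")
  }
  m <- list(Qm = as.matrix(p$Qm), lambda_m = as.numeric(p$lambda_m),
            Qt = as.matrix(p$Qt), lambda_t = as.numeric(p$lambda_t),
            lambda = p$lambda, C = as.matrix(p$C),
            scores = as.matrix(p$scores),
            mirna_ids = p$mirna_ids, site_ids = p$site_ids,
            format_version = 1L)
  dimnames(m$scores) <- list(m$mirna_ids, m$site_ids)
  structure(m, class = "rls_model")
}
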