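## Up/down normalization: per-probeset two-component gamma mixture.
##
## Each probeset's intensities across samples are modeled as
##   f(x) = w * Gamma(x; k_d, theta_d) + (1 - w) * Gamma(x; k_u, theta_u)
## with the "up" component the one with larger mean k*theta. The posterior
## probability of the up component is the per-sample up-probability p(A)
## used by all downstream pathway scoring.
##
## The EM inner loop is compiled (src/em_gamma.cpp); initialization, start
## selection, component relabeling and scale mapping live here. The
## single-vector interface wraps a one-row matrix, so there is exactly one
## implementation.

## elementwise log gamma density with per-row parameters
.row_ldens <- function(X, lX, shape, scale) {
  nc <- ncol(X)
  ## vector op against a matrix recycles column-major, i.e. per row
  lX * rep(shape - 1, nc) - X / rep(scale, nc) -
    rep(shape * log(scale) + lgamma(shape), nc)
}

## method-of-moments gamma parameters from masked row statistics
.row_mom <- function(X, mask) {
  n <- rowSums(mask)
  m <- rowSums(X * mask) / pmax(n, 1)
  v <- rowSums((X - m)^2 * mask) / pmax(n - 1, 1)
  bad <- !is.finite(v) | v <= 0
  v[bad] <- (0.25 * m[bad])^2 + 1e-12
  k <- pmax(m^2 / v, 1e-3)
  list(shape = k, scale = m / k)
}

## fit every row of X to a two-gamma mixture; returns per-row parameter
## vectors with components relabeled so "up" has the larger mean
.gamma_mix_fit_rows <- function(X, max_iter = 500L, tol = 1e-6,
                                want_trace = FALSE) {
  nr <- nrow(X)
  X <- pmax(X, .Machine$double.eps)
  rmean <- rowMeans(X)
  rvar <- rowSums((X - rmean)^2) / (ncol(X) - 1)
  degen <- rvar < 1e-12 * pmax(rmean^2, 1)
  ## fit on mean-normalized intensities so the procedure (including its
  ## stopping rule) is exactly scale-equivariant; gamma scales and the
  ## log-likelihood are mapped back afterwards
  row_scale <- ifelse(rmean > 0, rmean, 1)
  X <- X / row_scale
  out <- list(weight_down = rep(0.5, nr),
              shape_down = rep(1, nr), scale_down = pmax(rmean, 1e-12),
              shape_up = rep(1, nr), scale_up = pmax(rmean, 1e-12),
              loglik = rep(NA_real_, nr), converged = logical(nr),
              n_iter = integer(nr), degenerate = degen,
              trace = NULL)
  fit_idx <- which(!degen)
  if (length(fit_idx) == 0L) return(out)
  Xf <- X[fit_idx, , drop = FALSE]

  ## start A: below/above-median split, method of moments
  med <- apply(Xf, 1L, stats::median)
  lo <- Xf <= med
  thin <- rowSums(lo) < 2L | rowSums(!lo) < 2L
  if (any(thin)) lo[thin, ] <- col(Xf)[thin, , drop = FALSE] <= ncol(Xf) / 2
  pA1 <- .row_mom(Xf, lo); pA2 <- .row_mom(Xf, !lo)
  runA <- .em_gamma_rows_cpp(Xf, rowMeans(lo), pA1$shape, pA1$scale,
                             pA2$shape, pA2$scale, max_iter, tol,
                             want_trace)

  ## start B: exact 1-D two-means split
  km <- matrix(FALSE, nrow(Xf), ncol(Xf))
  for (i in seq_len(nrow(Xf))) {
    sp <- tryCatch(kmeans_split(Xf[i, ], min_group_size = 2L),
                   error = function(e) NULL)
    km[i, ] <- if (is.null(sp)) lo[i, ] else sp$group == 1L
  }
  pB1 <- .row_mom(Xf, km); pB2 <- .row_mom(Xf, !km)
  runB <- .em_gamma_rows_cpp(Xf, rowMeans(km), pB1$shape, pB1$scale,
                             pB2$shape, pB2$scale, max_iter, tol,
                             want_trace)

  useB <- is.finite(runB$loglik) &
    (!is.finite(runA$loglik) | runB$loglik > runA$loglik)
  pick <- function(field) ifelse(useB, runB[[field]], runA[[field]])
  w <- pick("w"); k1 <- pick("k1"); t1 <- pick("t1")
  k2 <- pick("k2"); t2 <- pick("t2")
  ll <- pick("loglik")
  conv <- ifelse(useB, runB$converged, runA$converged)
  coll <- ifelse(useB, runB$collapsed, runA$collapsed)
  n_it <- as.integer(pick("n_iter"))

  swap <- k1 * t1 > k2 * t2
  wd <- ifelse(swap, 1 - w, w)
  sc <- row_scale[fit_idx]
  ll_shift <- ncol(X) * log(sc)
  out$weight_down[fit_idx] <- wd
  out$shape_down[fit_idx] <- ifelse(swap, k2, k1)
  out$scale_down[fit_idx] <- ifelse(swap, t2, t1) * sc
  out$shape_up[fit_idx] <- ifelse(swap, k1, k2)
  out$scale_up[fit_idx] <- ifelse(swap, t1, t2) * sc
  out$loglik[fit_idx] <- ll - ll_shift
  out$converged[fit_idx] <- conv
  out$n_iter[fit_idx] <- n_it
  out$degenerate[fit_idx] <- coll | pmin(wd, 1 - wd) < 1e-3
  if (want_trace && nr == 1L)
    out$trace <- (if (useB[1]) runB$trace else runA$trace) - ll_shift[1]
  out
}

#' Fit a two-component gamma mixture by EM
#'
#' Fits `f(x) = w * Gamma(k_d, theta_d) + (1-w) * Gamma(k_u, theta_u)` to a
#' vector of nonnegative intensities. Components are labeled so the "up"
#' component has the larger mean. Initialization is deterministic:
#' method-of-moments on a below/above-median split, plus a second start from
#' the exact 1-D two-means split ([kmeans_split()]); the start with the
#' better final log-likelihood wins. The weighted gamma M-step solves
#' `log(k) - digamma(k) = log(wmean(x)) - wmean(log x)` by Newton iteration.
#'
#' Degenerate inputs (near-zero variance, or one component collapsing below
#' weight 1e-3) return a fit flagged `degenerate = TRUE` rather than an
#' error; downstream code substitutes the uninformative probability 0.5.
#'
#' @param values Numeric vector of nonnegative, finite intensities (linear
#'   scale). Zeros are floored at machine epsilon before fitting.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param min_n Minimum number of values required (default 8).
#' @return Object of class `gamma_mixture_fit`: `weight_down`, `shape_down`,
#'   `scale_down`, `shape_up`, `scale_up`, `loglik`, `loglik_trace`,
#'   `converged`, `n_iter`, `degenerate`, `n`.
#' @examples
#' set.seed(1)
#' x <- c(rgamma(200, 2, scale = 1), rgamma(200, 8, scale = 1))
#' fit <- fit_gamma_mixture(x)
#' fit$shape_up * fit$scale_up   # mean of the up component, near 8
#' @export
fit_gamma_mixture <- function(values, max_iter = 500L, tol = 1e-6,
                              min_n = 8L) {
  if (length(values) < min_n)
    stop("need at least ", min_n, " values to fit a gamma mixture (got ",
         length(values), ")")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and nonnegative")
  X <- matrix(values, nrow = 1L)
  f <- .gamma_mix_fit_rows(X, max_iter = max_iter, tol = tol,
                           want_trace = TRUE)
  structure(list(weight_down = f$weight_down[1],
                 shape_down = f$shape_down[1], scale_down = f$scale_down[1],
                 shape_up = f$shape_up[1], scale_up = f$scale_up[1],
                 loglik = f$loglik[1],
                 loglik_trace = if (is.null(f$trace)) numeric(0) else f$trace,
                 converged = f$converged[1], n_iter = f$n_iter[1],
                 degenerate = f$degenerate[1], n = length(values)),
            class = "gamma_mixture_fit")
}

#' @export
print.gamma_mixture_fit <- function(x, ...) {
  cat("Two-component gamma mixture fit (n = ", x$n, ")\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate fit: posteriors default to 0.5\n")
    return(invisible(x))
  }
  cat(sprintf("  down: weight %.3f, shape %.3f, scale %.3f (mean %.3f)\n",
              x$weight_down, x$shape_down, x$scale_down,
              x$shape_down * x$scale_down))
  cat(sprintf("  up:   weight %.3f, shape %.3f, scale %.3f (mean %.3f)\n",
              1 - x$weight_down, x$shape_up, x$scale_up,
              x$shape_up * x$scale_up))
  cat(sprintf("  loglik %.4f after %d iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Posterior probability of the "up" state
#'
#' `p_i = (1-w) g_u(x_i) / (w g_d(x_i) + (1-w) g_u(x_i))` for each value,
#' using the fitted mixture. For a degenerate fit this errors; callers
#' substitute the default probability 0.5 (see [updown_normalize()]).
#'
#' @param values Numeric vector of intensities.
#' @param fit A non-degenerate `gamma_mixture_fit`.
#' @return Vector of probabilities in \[0, 1\].
#' @export
posterior_up <- function(values, fit) {
  stopifnot(inherits(fit, "gamma_mixture_fit"))
  if (fit$degenerate)
    stop("degenerate fit: no posterior defined; use the 0.5 default")
  x <- pmax(values, .Machine$double.eps)
  ld <- stats::dgamma(x, shape = fit$shape_down, scale = fit$scale_down,
                      log = TRUE) + log(fit$weight_down)
  lu <- stats::dgamma(x, shape = fit$shape_up, scale = fit$scale_up,
                      log = TRUE) + log(1 - fit$weight_down)
  p <- 1 / (1 + exp(ld - lu))   # stable logistic of the log odds
  p[ld == -Inf & lu == -Inf] <- 0.5
  pmin(pmax(p, 0), 1)
}

#' Convert an expression matrix to up-probabilities
#'
#' Fits a two-gamma mixture to every probeset (row) across its samples and
#' replaces intensities by the posterior probability of the "up" (highly
#' expressive) state, placing all expression values on a common unit scale.
#' Probesets with a degenerate fit (e.g. constant intensities) get a
#' constant row of 0.5.
#'
#' @param expr Numeric matrix, probesets x samples, nonnegative linear-scale
#'   intensities, with rownames (probeset ids) and colnames (sample ids).
#' @param max_iter,tol,min_n As in [fit_gamma_mixture()].
#' @param unlog2 If `TRUE`, intensities are first transformed by `2^x`
#'   (for data supplied on the log2 scale).
#' @return List of class `updown_result`: `probs` (matrix, same shape as
#'   `expr`, entries in \[0, 1\]) and `fits` (data frame of per-probeset
#'   mixture parameters and diagnostics).
#' @export
updown_normalize <- function(expr, max_iter = 500L, tol = 1e-6, min_n = 8L,
                             unlog2 = FALSE) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs probeset rownames and sample colnames")
  if (unlog2) expr <- 2^expr
  if (any(!is.finite(expr)) || any(expr < 0))
    stop("expression values must be finite and nonnegative")
  if (ncol(expr) < min_n)
    stop("only ", ncol(expr), " samples; at least ", min_n,
         " are needed to fit per-probeset mixtures")
  f <- .gamma_mix_fit_rows(expr, max_iter = max_iter, tol = tol)
  X <- pmax(expr, .Machine$double.eps)
  nc <- ncol(X)
  ld <- .row_ldens(X, log(X), f$shape_down, f$scale_down) +
    log(rep(f$weight_down, nc))
  lu <- .row_ldens(X, log(X), f$shape_up, f$scale_up) +
    log(rep(1 - f$weight_down, nc))
  probs <- 1 / (1 + exp(ld - lu))
  probs[ld == -Inf & lu == -Inf] <- 0.5
  probs[f$degenerate, ] <- 0.5
  probs <- pmin(pmax(probs, 0), 1)
  dimnames(probs) <- dimnames(expr)
  fit_tab <- data.frame(
    probeset_id = rownames(expr),
    weight_down = f$weight_down,
    shape_down = f$shape_down, scale_down = f$scale_down,
    shape_up = f$shape_up, scale_up = f$scale_up,
    loglik = f$loglik, converged = f$converged, n_iter = f$n_iter,
    degenerate = f$degenerate)
  structure(list(probs = probs, fits = fit_tab), class = "updown_result")
}

#' @export
print.updown_result <- function(x, ...) {
  cat("Up-probability matrix: ", nrow(x$probs), " probesets x ",
      ncol(x$probs), " samples\n", sep = "")
  cat("  degenerate probesets: ", sum(x$fits$degenerate), "\n", sep = "")
  cat("  converged fits:       ", sum(x$fits$converged), "\n", sep = "")
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' First column = probeset id, header row = sample ids (the layout written
#' by common microarray summarization tools).
#'
#' @param path File path.
#' @return Numeric matrix with probeset rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as tab-delimited text with an id column
#'
#' @param m Matrix with rownames and colnames.
#' @param path File path.
#' @param id_col Name for the first (row id) column.
#' @param header_lines Optional `#`-prefixed comment lines written first.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id",
                             header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  m
}
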