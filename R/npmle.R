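#' Fit the symmetric nonparametric maximum-likelihood prior
#'
#' Estimates a discrete mixing distribution \eqn{\hat G} over log odds ratios
#' by maximizing the marginal log likelihood
#' \deqn{\sum_i \log \int L_i(\omega)\, dG(\omega)}
#' over all distributions supported on the grid that are symmetric about 0
#' (the Kiefer–Wolfowitz NPMLE with a symmetry constraint). Symmetry reflects
#' the active-comparator setting: neither drug in a comparison is a
#' distinguished baseline, so the ensemble of effects must look the same under
#' relabelling.
#'
#' The symmetry constraint is imposed structurally rather than via constrained
#' optimization: each table's likelihood over the full grid is folded into
#' symmetrized kernels \eqn{K_i(g) = [L_i(+g) + L_i(-g)]/2} on the nonnegative
#' half grid, the standard unconstrained-simplex NPMLE is solved there by EM
#' (self-consistency) fixed-point iterations from uniform weights, and the
#' fitted half-grid weights are reflected back to the full grid. EM
#' monotonically increases the objective; iteration stops when the relative
#' improvement drops below `tol` or after `max_iter` iterations.
#'
#' @param tables Data frame of contingency tables (columns `x_a`, `y_a`,
#'   `x_b`, `y_b`), or a precomputed shifted log-likelihood matrix from
#'   [likelihood_matrix()] (pass `grid` in either case).
#' @param grid An [effect_grid()]; must be symmetric about 0.
#' @param tol Relative marginal-log-likelihood improvement below which EM
#'   stops.
#' @param max_iter Maximum number of EM iterations.
#' @param prune Weights below this value after convergence are truncated to 0
#'   and the rest renormalized (NPMLE mixing weights are often sparse and may
#'   be non-unique; the objective and posterior means are stable).
#' @return An object of class `eb_prior` with components `grid` (the atoms),
#'   `weights` (full-grid weights summing to 1, exactly symmetric),
#'   `objective` (final shifted marginal log likelihood), `objective_trace`
#'   (per-iteration objective values), `iterations`, and `converged`.
#' @examples
#' tabs <- data.frame(x_a = c(5, 1), y_a = c(15, 19),
#'                    x_b = c(1, 2), y_b = c(19, 18))
#' fit <- fit_symmetric_npmle(tabs, effect_grid(step = 0.5, max_log_or = 2))
#' sum(fit$weights)
#' @export
fit_symmetric_npmle <- function(tables, grid, tol = 1e-9, max_iter = 10000L,
                                prune = 1e-12) {
  if (!is_symmetric_grid(grid)) {
    stop("grid must be strictly increasing, symmetric about 0, and contain 0")
  }
  lmat <- if (is.matrix(tables)) tables else {
    if (nrow(tables) < 1L) stop("at least one table is required")
    likelihood_matrix(tables, grid)
  }
  if (nrow(lmat) < 1L) stop("at least one table is required")
  atoms <- as.numeric(grid)
  n_atom <- length(atoms)
  i0 <- (n_atom + 1L) %/% 2L
  pos_idx <- seq.int(i0 + 1L, n_atom)
  neg_idx <- rev(seq_len(i0 - 1L))

  # fold to half-grid kernels on the likelihood scale; rescale rows by their
  # max before exponentiating so extreme tables cannot overflow
  row_max <- apply(lmat, 1L, max)
  amat <- exp(lmat - row_max)
  kern <- cbind(amat[, i0, drop = FALSE],
                (amat[, pos_idx, drop = FALSE] +
                 amat[, neg_idx, drop = FALSE]) / 2)

  n_half <- ncol(kern)
  w <- rep(1 / n_half, n_half)
  objective <- function(w) sum(log(kern %*% w) + row_max)
  obj <- objective(w)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    dens <- as.vector(kern %*% w)
    w <- w * as.vector(crossprod(kern, 1 / dens)) / nrow(kern)
    w <- w / sum(w)
    new_obj <- objective(w)
    trace <- c(trace, new_obj)
    if (is.finite(obj) &&
        (new_obj - obj) <= tol * (abs(obj) + .Machine$double.eps)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }

  if (any(w < prune) && any(w >= prune)) {
    w[w < prune] <- 0
    w <- w / sum(w)
  }

  weights <- numeric(n_atom)
  weights[i0] <- w[1L]
  weights[pos_idx] <- w[-1L] / 2
  weights[neg_idx] <- w[-1L] / 2

  structure(
    list(grid = atoms, weights = weights, objective = obj,
         objective_trace = trace, iterations = iter, converged = converged),
    class = "eb_prior"
  )
}

#' @export
print.eb_prior <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat(sprintf(
    "<eb_prior> symmetric NPMLE on %d atoms (%d with mass)\n", length(x$grid), nz))
  cat(sprintf("  P(omega = 0) = %.4f;  P(|omega| >= log 2) = %.4f\n",
              x$weights[(length(x$grid) + 1L) %/% 2L],
              sum(x$weights[abs(x$grid) >= log(2)])))
  cat(sprintf("  objective %.6f after %d EM iterations (%s)\n",
              x$objective, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

validate_prior <- function(prior) {
  stopifnot(inherits(prior, "eb_prior"),
            length(prior$grid) == length(prior$weights),
            all(prior$weights >= 0),
            abs(sum(prior$weights) - 1) < 1e-12)
  invisible(prior)
}

#' Marginal log likelihood of a prior for a set of tables
#'
#' The objective of [fit_symmetric_npmle()]: the sum over tables of the log
#' of the prior-weighted likelihood, computed from the per-table shifted
#' likelihood matrix, so the value carries the same per-table constant shift
#' (a point mass at 0 scores exactly 0) and differences between priors are
#' shift-free.
#'
#' @param prior An `eb_prior` (or any list with `grid` and `weights`).
#' @param tables Data frame of tables or a shifted log-likelihood matrix on
#'   `prior$grid`.
#' @return Scalar marginal log likelihood (shifted).
#' @export
marginal_log_likelihood <- function(prior, tables) {
  grid <- structure(as.numeric(prior$grid), class = "effect_grid")
  lmat <- if (is.matrix(tables)) tables else likelihood_matrix(tables, grid)
  stopifnot(ncol(lmat) == length(prior$weights))
  row_max <- apply(lmat, 1L, max)
  sum(log(exp(lmat - row_max) %*% prior$weights) + row_max)
}

#' Posterior-mean log odds ratio of one table under a fitted prior
#'
#' The empirical-Bayes denoised effect: \eqn{E[\omega \mid Z]} under the
#' discrete prior, \eqn{\sum_j g_j w_j L(g_j) / \sum_j w_j L(g_j)}. Sums are
#' folded over the half grid so that column-swapping the table negates the
#' returned value exactly (not merely to rounding).
#'
#' @param prior An `eb_prior`.
#' @param x_a,y_a,x_b,y_b Cells of the contingency table.
#' @return Posterior mean log odds ratio; finite, with magnitude at most
#'   `max(abs(prior$grid))`. Tables with degenerate support (e.g. no events)
#'   have a flat likelihood and return exactly 0 under any symmetric prior.
#' @export
posterior_mean <- function(prior, x_a, y_a, x_b, y_b) {
  validate_prior(prior)
  atoms <- prior$grid
  ll <- nchg_log_likelihood(x_a, y_a, x_b, y_b, atoms)
  posterior_mean_from_loglik(prior, ll)
}

# Folded posterior mean from a row of (possibly shifted) log likelihoods.
posterior_mean_from_loglik <- function(prior, ll) {
  atoms <- prior$grid
  n_atom <- length(atoms)
  i0 <- (n_atom + 1L) %/% 2L
  pos_idx <- seq.int(i0 + 1L, n_atom)
  neg_idx <- rev(seq_len(i0 - 1L))
  r <- exp(ll - max(ll))
  w_half <- prior$weights[pos_idx]
  num <- sum(atoms[pos_idx] * w_half * (r[pos_idx] - r[neg_idx]))
  den <- prior$weights[i0] * r[i0] + sum(w_half * (r[pos_idx] + r[neg_idx]))
  num / den
}

#' Denoise a set of comparisons under a fitted prior
#'
#' Computes, for every comparison row, the continuity-corrected sample odds
#' ratio and the empirical-Bayes posterior-mean log odds ratio (and its
#' exponential, the denoised odds ratio). This is the column pair behind
#' shrinkage scatter plots of denoised versus raw odds ratios.
#'
#' @param prior An `eb_prior`.
#' @param comparisons Data frame with columns `x_a`, `y_a`, `x_b`, `y_b`
#'   (other columns are carried through).
#' @param continuity Continuity correction used for the reported sample odds
#'   ratio only; the posterior uses the exact conditional likelihood on raw
#'   counts.
#' @param loglik Optional precomputed shifted log-likelihood matrix for
#'   `comparisons` on `prior$grid` (from [likelihood_matrix()]), to avoid
#'   re-enumerating likelihoods when both fitting and denoising the same
#'   tables.
#' @return The input data frame with columns `sample_or`, `log_or_eb`,
#'   `or_eb` appended.
#' @export
denoise_comparisons <- function(prior, comparisons, continuity = 0.5,
                                loglik = NULL) {
  validate_prior(prior)
  stopifnot(is.data.frame(comparisons))
  n <- nrow(comparisons)
  log_or_eb <- numeric(n)
  sample_or <- numeric(n)
  if (!is.null(loglik)) {
    stopifnot(nrow(loglik) == n, ncol(loglik) == length(prior$grid))
  }
  for (i in seq_len(n)) {
    log_or_eb[i] <- if (is.null(loglik)) {
      posterior_mean(prior, comparisons$x_a[i], comparisons$y_a[i],
                     comparisons$x_b[i], comparisons$y_b[i])
    } else {
      posterior_mean_from_loglik(prior, loglik[i, ])
    }
    sample_or[i] <- sample_odds_ratio(comparisons$x_a[i], comparisons$y_a[i],
                                      comparisons$x_b[i], comparisons$y_b[i],
                                      continuity = continuity)
  }
  comparisons$sample_or <- sample_or
  comparisons$log_or_eb <- log_or_eb
  comparisons$or_eb <- exp(log_or_eb)
  comparisons
}

#' Right-continuous CDF of a fitted discrete prior
#'
#' @param prior An `eb_prior`.
#' @param omega Numeric vector of log-odds-ratio evaluation points.
#' @return `P(Omega <= omega)` for each evaluation point.
#' @export
prior_cdf <- function(prior, omega) {
  validate_prior(prior)
  vapply(omega, function(o) sum(prior$weights[prior$grid <= o]), numeric(1))
}

#' Read / write a fitted prior as TSV
#'
#' Tab-separated, header `log_or_atom`, `weight`, 12 significant digits.
#' Reading restores an `eb_prior` (without the fitting trace).
#'
#' @param prior An `eb_prior`.
#' @param path File path.
#' @export
write_prior <- function(prior, path) {
  validate_prior(prior)
  utils::write.table(
    data.frame(log_or_atom = format(prior$grid, digits = 12, trim = TRUE),
               weight = format(prior$weights, digits = 12, scientific = TRUE,
                               trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("log_or_atom", "weight") %in% names(df)))
  w <- as.numeric(df$weight)
  structure(list(grid = as.numeric(df$log_or_atom), weights = w / sum(w),
                 objective = NA_real_, objective_trace = numeric(),
                 iterations = NA_integer_, converged = NA),
            class = "eb_prior")
}
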