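#' Noncentral hypergeometric conditional log likelihood of a 2x2 table
#'
#' Conditioning a 2x2 contingency table on both margins leaves a single free
#' cell whose law is the Fisher noncentral hypergeometric distribution indexed
#' by the log odds ratio \eqn{\omega}. For a table with `x_a` events among
#' `x_a + y_a` drug-A patients and `x_b` events among `x_b + y_b` drug-B
#' patients, the conditional probability of observing `x_a` is
#' \deqn{L(\omega) = \frac{\binom{n_A}{x_a}\binom{n_B}{x_b} e^{\omega x_a}}
#'   {\sum_t \binom{n_A}{t}\binom{n_B}{m - t} e^{\omega t}}}
#' with \eqn{n_A = x_a + y_a}, \eqn{n_B = x_b + y_b}, \eqn{m = x_a + x_b} and
#' \eqn{t} ranging over \eqn{[\max(0, m - n_B), \min(n_A, m)]}.
#'
#' All computation is in log space: log binomial coefficients via
#' [lchoose()] and a log-sum-exp denominator, so large arms and extreme
#' odds ratios are handled without overflow. The (table, \eqn{\omega}) pair is
#' internally canonicalized so that a table and its column-swapped twin
#' evaluate on the identical code path (with \eqn{\omega} negated); swapping
#' the drug columns therefore maps the likelihood curve to its exact mirror
#' image, bit for bit.
#'
#' @param x_a,y_a Event and non-event counts in the drug-A column.
#' @param x_b,y_b Event and non-event counts in the drug-B column.
#' @param omega Numeric vector of log odds ratios at which to evaluate.
#' @return Numeric vector of log probabilities, one per `omega`. A table with
#'   no events (or no non-events) on either margin has single-point support
#'   and log likelihood 0 for every `omega`.
#' @seealso [likelihood_matrix()], [posterior_mean()]
#' @examples
#' nchg_log_likelihood(1, 1, 1, 1, 0)  # log(2/3), Fisher's central case
#' @export
nchg_log_likelihood <- function(x_a, y_a, x_b, y_b, omega) {
  stopifnot(length(x_a) == 1, x_a >= 0, y_a >= 0, x_b >= 0, y_b >= 0)
  tab <- canonicalize_table(x_a, y_a, x_b, y_b)
  om <- if (tab$swapped) -omega else omega
  if (tab$self_sym) om <- abs(om)
  nchg_loglik_canonical(tab$x_a, tab$y_a, tab$x_b, tab$y_b, om)
}

# Deterministic canonical column order so that swap(table) with -omega hits
# the same arithmetic. Swap when column A < column B lexicographically on
# (x, y); identical columns are swap-invariant and flagged so callers can
# canonicalize omega's sign as well.
canonicalize_table <- function(x_a, y_a, x_b, y_b) {
  self_sym <- (x_a == x_b) && (y_a == y_b)
  swapped <- !self_sym && (x_a < x_b || (x_a == x_b && y_a < y_b))
  if (swapped) {
    list(x_a = x_b, y_a = y_b, x_b = x_a, y_b = y_a,
         swapped = TRUE, self_sym = FALSE)
  } else {
    list(x_a = x_a, y_a = y_a, x_b = x_b, y_b = y_b,
         swapped = FALSE, self_sym = self_sym)
  }
}

nchg_loglik_canonical <- function(x_a, y_a, x_b, y_b, omega) {
  n_a <- x_a + y_a
  n_b <- x_b + y_b
  m <- x_a + x_b
  tt <- seq.int(max(0, m - n_b), min(n_a, m))
  if (length(tt) == 1L) {
    return(rep(0, length(omega)))
  }
  lc <- lchoose(n_a, tt) + lchoose(n_b, m - tt)
  # denominator: column-wise log-sum-exp of lc + omega * t
  em <- lc + outer(tt, omega)
  mx <- apply(em, 2L, max)
  log_den <- mx + log(colSums(exp(sweep(em, 2L, mx, "-"))))
  lc[match(x_a, tt)] + omega * x_a - log_den
}

#' Symmetric grid of log-odds-ratio atoms
#'
#' Constructs the discrete support on which the nonparametric prior is
#' estimated: atoms at 0 and \eqn{\pm k \Delta} up to `max_log_or`, with the
#' endpoint included when it is not a multiple of the step. Negative atoms are
#' stored as exact floating-point negations of the positive ones. The default
#' (step 0.05 on the log-OR scale, endpoint `log(1000)`) gives 279 atoms,
#' comfortably covering the strongest effects seen in trial-derived
#' comparisons.
#'
#' @param step Grid spacing on the log-odds-ratio scale.
#' @param max_log_or Largest atom magnitude; included as an atom.
#' @return An object of class `effect_grid`: numeric vector of strictly
#'   increasing atoms, symmetric about and containing 0.
#' @examples
#' length(effect_grid())          # 279
#' effect_grid(step = 0.5, max_log_or = 1)
#' @export
effect_grid <- function(step = 0.05, max_log_or = log(1000)) {
  stopifnot(step > 0, max_log_or > 0)
  pos <- seq.int(1L, floor(max_log_or / step + 1e-9)) * step
  if (max_log_or > pos[length(pos)] + 1e-9 * step) {
    pos <- c(pos, max_log_or)
  }
  atoms <- c(-rev(pos), 0, pos)
  structure(atoms, class = "effect_grid")
}

#' @export
print.effect_grid <- function(x, ...) {
  cat(sprintf("<effect_grid> %d atoms on [%.4f, %.4f], step %.4g\n",
              length(x), min(x), max(x), x[(length(x) + 3) %/% 2] - 0))
  invisible(x)
}

is_symmetric_grid <- function(grid) {
  n <- length(grid)
  n %% 2L == 1L &&
    grid[(n + 1L) %/% 2L] == 0 &&
    !is.unsorted(grid, strictly = TRUE) &&
    identical(as.numeric(rev(grid[seq_len((n - 1L) %/% 2L)])),
              as.numeric(-grid[seq.int((n + 3L) %/% 2L, n)]))
}

#' Shifted log-likelihood matrix over a grid of effects
#'
#' Evaluates [nchg_log_likelihood()] for every table at every grid atom and
#' subtracts, per table, the value at \eqn{\omega = 0}. The per-table shift is
#' a multiplicative constant on the likelihood scale, to which both the
#' marginal-likelihood objective maximized by [fit_symmetric_npmle()] and the
#' posterior means of [posterior_mean()] are invariant; it keeps rows
#' well-scaled, with the \eqn{\omega = 0} column identically 0.
#'
#' @param tables Data frame with columns `x_a`, `y_a`, `x_b`, `y_b` (one row
#'   per comparison), e.g. a comparison table from [build_comparisons()].
#' @param grid An [effect_grid()].
#' @return Numeric matrix, rows = tables, columns = grid atoms, of shifted log
#'   likelihoods. Rows for tables with degenerate (single-point) support are
#'   identically zero.
#' @export
likelihood_matrix <- function(tables, grid) {
  stopifnot(is.data.frame(tables),
            all(c("x_a", "y_a", "x_b", "y_b") %in% names(tables)))
  if (!is_symmetric_grid(grid)) {
    stop("grid must be strictly increasing, symmetric about 0, and contain 0")
  }
  atoms <- as.numeric(grid)
  i0 <- (length(atoms) + 1L) %/% 2L
  out <- matrix(0, nrow = nrow(tables), ncol = length(atoms))
  for (i in seq_len(nrow(tables))) {
    ll <- nchg_log_likelihood(tables$x_a[i], tables$y_a[i],
                              tables$x_b[i], tables$y_b[i], atoms)
    out[i, ] <- ll - ll[i0]
  }
  out
}
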