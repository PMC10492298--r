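# Independent oracles and fixture builders, deliberately kept separate from
# the package's implementation paths.

# Direct-summation noncentral hypergeometric log pmf: plain choose() products,
# no log-space tricks. Valid for tables small enough not to overflow doubles.
oracle_nchg_loglik <- function(x_a, y_a, x_b, y_b, omega) {
  n_a <- x_a + y_a
  n_b <- x_b + y_b
  m <- x_a + x_b
  tt <- max(0, m - n_b):min(n_a, m)
  terms <- choose(n_a, tt) * choose(n_b, m - tt) * exp(omega * tt)
  log(choose(n_a, x_a) * choose(n_b, x_b) * exp(omega * x_a) / sum(terms))
}

# Two-sided Fisher exact p by enumeration (point-probability convention).
oracle_fisher_p <- function(x_a, y_a, x_b, y_b) {
  n_a <- x_a + y_a
  n_b <- x_b + y_b
  m <- x_a + x_b
  tt <- max(0, m - n_b):min(n_a, m)
  pr <- dhyper(tt, n_a, n_b, m)
  obs <- dhyper(x_a, n_a, n_b, m)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Random small contingency tables with at least one subject per arm.
random_tables <- function(n, max_n = 40, seed = NULL) {
  draw <- function() {
    na <- sample(1:max_n, n, replace = TRUE)
    nb <- sample(1:max_n, n, replace = TRUE)
    xa <- vapply(na, function(k) sample(0:k, 1), integer(1))
    xb <- vapply(nb, function(k) sample(0:k, 1), integer(1))
    data.frame(x_a = xa, y_a = na - xa, x_b = xb, y_b = nb - xb)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Exhaustive simplex grid search for the 3-atom half-grid NPMLE objective:
# a coarse global pass followed by two local refinements. kern is the n x 3
# symmetrized kernel matrix; returns the maximal objective found.
oracle_simplex_search <- function(kern, row_max) {
  obj_many <- function(w_mat) {
    colSums(log(kern %*% w_mat) + row_max)
  }
  best <- c(1, 1, 1) / 3
  width <- 1
  step <- 0.005
  for (round in 1:3) {
    lo <- pmax(0, best[1:2] - width)
    hi <- pmin(1, best[1:2] + width)
    w1 <- seq(lo[1], hi[1], by = step)
    w2 <- seq(lo[2], hi[2], by = step)
    grid <- expand.grid(w1 = w1, w2 = w2)
    grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
    w_mat <- rbind(grid$w1, grid$w2, pmax(0, 1 - grid$w1 - grid$w2))
    vals <- obj_many(w_mat)
    k <- which.max(vals)
    best <- w_mat[, k]
    width <- step * 2
    step <- step / 50
  }
  list(objective = obj_many(matrix(best, ncol = 1)), weights = best)
}

# Half-grid kernel matrix for the oracle, built from the package's shifted
# likelihood matrix (the objective convention under test).
half_kernels <- function(lmat, grid) {
  atoms <- as.numeric(grid)
  i0 <- (length(atoms) + 1L) %/% 2L
  pos <- seq.int(i0 + 1L, length(atoms))
  neg <- rev(seq_len(i0 - 1L))
  row_max <- apply(lmat, 1, max)
  amat <- exp(lmat - row_max)
  list(kern = cbind(amat[, i0], (amat[, pos, drop = FALSE] +
                                 amat[, neg, drop = FALSE]) / 2),
       row_max = row_max)
}

make_arm <- function(nct_id, ingredient, n, icd10, affected, at_risk) {
  list(nct_id = nct_id, ingredient = ingredient,
       n_participants = as.integer(n),
       ae = data.frame(icd10 = icd10, affected = as.integer(affected),
                       at_risk = as.integer(at_risk),
                       stringsAsFactors = FALSE))
}
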