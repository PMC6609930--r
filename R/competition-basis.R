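#' Orthogonal competition basis for n alternatives
#'
#' Constructs the set of n-1 orthogonal "competition" vectors that span the
#' zero-sum subspace of population-rate space, together with the common
#' (all-ones) direction. The k-th competition vector has k leading ones,
#' the entry -k in position k+1, and zeros thereafter, so that
#' `e_1 = (1, -1, 0, ...)`, `e_2 = (1, 1, -2, 0, ...)` and so on. Every
#' competition vector is orthogonal to the all-ones direction, which is what
#' cancels global inhibition (and, in the Bayesian test, the log-normalization
#' term) from the decision-variable dynamics.
#'
#' Alternatives and decision variables are indexed 1-based throughout, matching
#' R's native convention.
#'
#' @param n integer number of alternatives, at least 2.
#' @return An object of class `competition_basis`: a list with elements
#'   `n`, `vectors` (list of the n-1 competition vectors), `E` (the same
#'   vectors as the rows of an (n-1) x n matrix), `common` (all-ones vector of
#'   length n) and `norms` (the squared norms `k + k^2`).
#' @examples
#' b <- competition_basis(3)
#' b$vectors[[1]]  # (1, -1, 0)
#' b$vectors[[2]]  # (1, 1, -2)
#' @export
competition_basis <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n)
  vectors <- lapply(seq_len(n - 1L), function(k) {
    e <- numeric(n)
    e[seq_len(k)] <- 1
    e[k + 1L] <- -k
    e
  })
  E <- do.call(rbind, vectors)
  structure(
    list(n = n, vectors = vectors, E = E, common = rep(1, n),
         norms = vapply(seq_len(n - 1L), function(k) k + k^2, numeric(1))),
    class = "competition_basis")
}

#' @export
print.competition_basis <- function(x, ...) {
  cat("Competition basis for", x$n, "alternatives (",
      x$n - 1L, "competition vectors )\n")
  for (k in seq_len(x$n - 1L))
    cat(sprintf("  e_%d = (%s)   |e|^2 = %g\n", k,
                paste(x$vectors[[k]], collapse = ", "), x$norms[k]))
  invisible(x)
}

#' Project population rates onto the competition basis
#'
#' Decomposes a vector of n population rates into n-1 decision variables
#' `X_k = (e_k . r) / (e_k . e_k)` and the common mode `m_C = mean(r)`
#' (the projection onto the normalized all-ones direction).
#'
#' @param r numeric vector of length n (population rates, or any vector in
#'   rate space such as log-posteriors).
#' @param basis a [competition_basis()].
#' @return A list of class `mode_coordinates` with elements `X` (length n-1)
#'   and `m_C` (scalar).
#' @export
project_modes <- function(r, basis) {
  stopifnot(inherits(basis, "competition_basis"))
  if (length(r) != basis$n)
    stop("`r` must have length ", basis$n, call. = FALSE)
  X <- as.numeric(basis$E %*% r) / basis$norms
  structure(list(X = X, m_C = mean(r)), class = "mode_coordinates")
}

#' Reconstruct population rates from mode coordinates
#'
#' Inverts [project_modes()]: returns `r = sum_k e_k X_k + m_C * 1`. The i-th
#' component admits the closed form
#' `r_i = -(i-1) X_{i-1} + sum_{l >= i} X_l + m_C` (the `X_{i-1}` term is
#' absent for i = 1), which is what the reconstruction-based decision rules in
#' the DDM simulators evaluate at every step.
#'
#' @param coords a `mode_coordinates` list (`X`, `m_C`), or a numeric vector
#'   `X` of length n-1 (then `m_C` is taken from the second argument).
#' @param basis a [competition_basis()].
#' @param m_C common-mode value when `coords` is a bare numeric vector.
#' @return numeric vector of length n.
#' @export
reconstruct_rates <- function(coords, basis, m_C = 0) {
  stopifnot(inherits(basis, "competition_basis"))
  if (is.list(coords)) {
    X <- coords$X
    m_C <- coords$m_C
  } else {
    X <- coords
  }
  if (length(X) != basis$n - 1L)
    stop("`X` must have length ", basis$n - 1L, call. = FALSE)
  # suffix-sum closed form; identical to crossprod(E, X) + m_C
  suff <- rev(cumsum(rev(X)))          # suff[i] = sum_{l >= i} X_l
  r <- numeric(basis$n)
  r[1] <- suff[1] + m_C
  if (basis$n > 2L)
    r[2:(basis$n - 1L)] <- -(1:(basis$n - 2L)) * X[1:(basis$n - 2L)] +
      suff[2:(basis$n - 1L)] + m_C
  r[basis$n] <- -(basis$n - 1L) * X[basis$n - 1L] + m_C
  r
}
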