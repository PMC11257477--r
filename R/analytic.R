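#' Exact stationary occupancy of the exclusion chain
#'
#' The full model gene is a finite continuous-time Markov chain (promoter
#' substates times the occupancy pattern of every compartment; 12,288 states
#' for the default STM architecture). This solves its stationary
#' distribution exactly as a sparse linear system and returns the marginal
#' occupancy of each compartment -- a Monte-Carlo-free oracle for the
#' Gillespie engine.
#'
#' If the chain is reducible (e.g. `k7 = 0` with inflow creates an absorbing
#' configuration) the direct solve is singular; the function then falls back
#' to uniformised power iteration from the empty state, returning the
#' long-run occupancy reached from an initially empty gene, and flags the
#' result with `attr(, "absorbing")`.
#'
#' @param arch A [gene_architecture()]. State space grows as
#'   `3 * 2^(n_transcript_bins + 1)` (times 2 for STM); keep
#'   `n_transcript_bins` at or below the default 10.
#' @param rates A matching [rate_set()].
#' @return An `"occupancy_vector"` with zero standard errors, plus the
#'   stationary completion rate (`k7 * P(terminator occupied)`).
#' @export
analytic_steady_state <- function(arch, rates) {
  r <- engine_rates(rates, arch)
  k1 <- r[1]; km1 <- r[2]; k2 <- r[3]; km2 <- r[4]; k3 <- r[5]
  km3 <- r[6]; k4 <- r[7]; k5 <- r[8]; hop <- r[9]; k7 <- r[10]
  n <- arch$n_transcript_bins
  U <- if (arch$has_uas) 2L else 1L
  B <- 2L^n
  n_states <- U * 3L * B * 2L
  if (n_states > 5e5) stop("state space too large for the exact solver")

  i0 <- seq_len(n_states) - 1L          # 0-based state index
  u <- i0 %% U
  p <- (i0 %/% U) %% 3L
  b <- (i0 %/% (U * 3L)) %% B
  tm <- i0 %/% (U * 3L * B)
  bit <- function(k) (b %/% 2L^(k - 1L)) %% 2L  # transcript bin k occupied?

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(mask, delta, k) {
    if (k > 0 && any(mask)) {
      idx <- i0[mask]
      from <<- c(from, idx); to <<- c(to, idx + delta)
      rate <<- c(rate, rep(k, sum(mask)))
    }
  }
  if (arch$has_uas) {
    add(u == 0L, +1L, k1)                          # UAS recruitment
    add(u == 1L, -1L, km1)                         # UAS loss
    add(u == 1L & p == 0L, U - 1L, k2)             # transfer to promoter
    add(p == 1L & u == 0L, 1L - U, km2)            # reversal to UAS
  }
  add(p == 0L, U, k3)                              # direct recruitment
  add(p == 1L, -U, km3)                            # promoter loss
  add(p == 1L, U, k4)                              # TFIIH arrival
  add(p == 2L & bit(1L) == 0L, U, k5)              # initiation (-2p, +bin1)
  if (n > 1) for (k in seq_len(n - 1L))
    add(bit(k) == 1L & bit(k + 1L) == 0L, 3L * U * 2L^(k - 1L), hop)
  add(bit(n) == 1L & tm == 0L, 3L * U * (B - 2L^(n - 1L)), hop)
  add(tm == 1L, -3L * U * B, k7)                   # terminator release

  Q <- Matrix::sparseMatrix(i = from + 1L, j = to + 1L, x = rate,
                            dims = c(n_states, n_states))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)

  absorbing <- FALSE
  pi_vec <- tryCatch({
    # ground the empty state (always recurrent) instead of appending a dense
    # normalisation row, which would destroy sparsity in the LU factors
    A <- Matrix::t(Q)
    x_rest <- as.numeric(Matrix::solve(A[-1L, -1L, drop = FALSE],
                                       -A[-1L, 1L, drop = FALSE]))
    x <- c(1, x_rest)
    if (any(!is.finite(x)) || any(x < -1e-6 * max(x)))
      stop("singular")
    resid <- max(abs(as.numeric(A %*% x)))
    if (!is.finite(resid) || resid > 1e-8 * max(abs(rate)))
      stop("singular")
    pmax(x, 0) / sum(pmax(x, 0))
  }, error = function(e) NULL)

  if (is.null(pi_vec)) {
    # reducible chain: uniformised power iteration from the empty state
    absorbing <- TRUE
    lambda <- max(-Matrix::diag(Q)) * 1.05 + 1e-12
    P <- Matrix::Diagonal(n_states) + Q / lambda
    Pt <- Matrix::t(P)
    pi_vec <- numeric(n_states); pi_vec[1] <- 1
    for (it in seq_len(200000L)) {
      nxt <- as.numeric(Pt %*% pi_vec)
      if (sum(abs(nxt - pi_vec)) < 1e-13 && it > 10) { pi_vec <- nxt; break }
      pi_vec <- nxt
    }
    pi_vec <- pmax(pi_vec, 0) / sum(pmax(pi_vec, 0))
  }

  comp <- compartment_names(arch)
  occ <- c(if (arch$has_uas) sum(pi_vec[u == 1L]),
           sum(pi_vec[p > 0L]),
           vapply(seq_len(n), function(k) sum(pi_vec[bit(k) == 1L]),
                  numeric(1)),
           sum(pi_vec[tm == 1L]))
  out <- structure(
    list(mean = stats::setNames(occ, comp),
         se = stats::setNames(numeric(length(comp)), comp),
         n_genes = NA_integer_,
         gene_class = arch$gene_class,
         initiation_rate = k5 * sum(pi_vec[p == 2L & bit(1L) == 0L]),
         completion_rate = k7 * sum(pi_vec[tm == 1L])),
    class = "occupancy_vector")
  attr(out, "absorbing") <- absorbing
  out
}
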