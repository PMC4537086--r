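# Closed-form and exact-recursion references for the coalescent
# simulator. All signatures take and return times in 4N0 generations to
# avoid silent unit bugs; convert with convert_time() at the boundary.

#' Expected TMRCA of n samples under the panmictic coalescent
#'
#' Sum over k = 2..n of the expected waiting times 1/(k(k-1)), which
#' telescopes to 1 - 1/n (4N0 generations).
#'
#' @param n Integer sample size, at least 2.
#' @return Expected TMRCA in 4N0 generations.
#' @export
#' @examples
#' expected_tmrca(2)   # 0.5
#' expected_tmrca(10)  # 0.9
expected_tmrca <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("invalid parameter: n must be an integer >= 2")
  1 - 1 / n
}

#' Expected total branch length of the panmictic coalescent
#'
#' The harmonic sum H(n-1) = sum_{i=1}^{n-1} 1/i in 4N0 generations.
#'
#' @param n Integer sample size, at least 2.
#' @return Expected total tree length in 4N0 generations.
#' @export
expected_total_length <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("invalid parameter: n must be an integer >= 2")
  sum(1 / seq_len(n - 1L))
}

#' Watterson expectation of the number of segregating sites
#'
#' `theta * expected_total_length(n)` under the infinite-sites model.
#'
#' @param n Integer sample size, at least 2.
#' @param theta Non-negative population-scaled mutation rate.
#' @return Expected segregating-site count.
#' @export
#' @examples
#' expected_segsites(2, 2)   # 2: pairwise difference has mean theta
expected_segsites <- function(n, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0)
    stop("invalid parameter: theta must be a non-negative number")
  theta * expected_total_length(n)
}

#' Distribution of the number of ancestral lineages after time t
#'
#' Exact distribution of the ancestral-lineage count of a sample of n
#' under the coalescent: a pure-death chain that steps from j to j-1 at
#' rate j(j-1) (time in 4N0 generations). Computed by matrix
#' exponentiation of the generator (scaling-and-squaring), which is
#' numerically stable, rather than by the classical alternating series.
#'
#' @param n Integer initial number of lineages, at least 1.
#' @param t Non-negative time in 4N0 generations.
#' @return List of class `lineage_count_distribution` with components `t`
#'   and `probabilities` (vector over j = 1..n; sums to 1).
#' @export
#' @examples
#' lineage_count_distribution(2, 0.5)$probabilities  # P(j=1) = 1 - exp(-1)
lineage_count_distribution <- function(n, t) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("invalid parameter: n must be an integer >= 1")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("invalid parameter: t must be a non-negative number")
  p <- numeric(n)
  if (n == 1L || t == 0) {
    p[n] <- 1
  } else {
    j <- seq_len(n)
    rates <- j * (j - 1)
    Q <- matrix(0, n, n)
    Q[cbind(j, j)] <- -rates
    Q[cbind(j[-1L], j[-1L] - 1L)] <- rates[-1L]
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
    p <- pmax(P[n, ], 0)
    p <- p / sum(p)
  }
  structure(list(t = t, probabilities = p),
            class = "lineage_count_distribution")
}

#' Exact ingroup monophyly probability with a single outgroup lineage
#'
#' Probability that n_in ingroup lineages, separated from one outgroup
#' lineage until the populations join at `t_join`, end up monophyletic in
#' the gene tree. Conditional on j ingroup lineages surviving to the
#' join, monophyly requires all j to coalesce before any joins the lone
#' outgroup; by exchangeability that probability telescopes as
#' q(j) = prod_k C(k,2)/C(k+1,2) = 2/(j(j+1)), with q(1) = 1. The
#' returned value is the convolution of q with the exact lineage-count
#' distribution at `t_join`.
#'
#' @param n_in Integer number of ingroup lineages, at least 1.
#' @param t_join Non-negative divergence time in 4N0 generations.
#' @return Probability in `[0, 1]`, non-decreasing in `t_join`.
#' @export
#' @examples
#' monophyly_probability(2, 0)    # 1/3
#' monophyly_probability(10, 0)   # 1/55
monophyly_probability <- function(n_in, t_join) {
  n_in <- as.integer(n_in)
  if (is.na(n_in) || n_in < 1L)
    stop("invalid parameter: n_in must be an integer >= 1")
  if (n_in == 1L) return(1)
  p <- lineage_count_distribution(n_in, t_join)$probabilities
  j <- seq_len(n_in)
  sum(p * 2 / (j * (j + 1)))
}

#' Tabulate the monophyly-probability oracle on a time grid
#'
#' @param n_in Integer number of ingroup lineages.
#' @param t_values Non-negative times in 4N0 generations.
#' @return Data frame with columns `t_4N0`, `t_Ne` and `p_monophyly`,
#'   suitable for TSV export against sweep output.
#' @export
monophyly_table <- function(n_in, t_values) {
  data.frame(
    t_4N0 = t_values,
    t_Ne = convert_time(t_values, "4N0", "Ne"),
    p_monophyly = vapply(t_values,
                         function(t) monophyly_probability(n_in, t),
                         numeric(1)))
}
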