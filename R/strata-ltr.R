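# Evolutionary-strata assessment along the X and Kimura two-parameter
# dating of LTR retrotransposon insertions.

strata_statistic <- function(ks, min_side = 4L) {
  n <- length(ks)
  cuts <- seq.int(min_side, n - min_side)
  csum <- cumsum(ks)
  tot <- csum[n]
  left <- csum[cuts] / cuts
  right <- (tot - csum[cuts]) / (n - cuts)
  stat <- abs(left - right)
  list(stat = max(stat), cut = cuts[which.max(stat)])
}

#' Permutation test for evolutionary strata
#'
#' Orders gametolog pairs along the X, takes as statistic the maximum
#' over candidate breakpoints of the absolute difference in mean Ks
#' between the left and right segments (each with at least 4 points), and
#' compares it with the permutation distribution obtained by shuffling Ks
#' values over positions. A breakpoint is reported only when p < 0.05.
#'
#' @param positions X positions of the gametolog pairs.
#' @param ks per-pair synonymous divergence.
#' @param n_perm number of permutation draws.
#' @param seed integer seed for the permutations.
#' @return A `strata_result`: list with `statistic`, `p_value`,
#'   `breakpoints` (possibly empty), and the ordered `pairs` table.
#' @export
strata_test <- function(positions, ks, n_perm = 1000L, seed = 1L) {
  if (length(positions) != length(ks)) stop("positions/ks length mismatch")
  if (length(ks) < 8) stop("strata test needs at least 8 pairs")
  ord <- order(positions)
  positions <- positions[ord]
  ks <- ks[ord]
  obs <- strata_statistic(ks)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    strata_statistic(sample(ks))$stat
  }, numeric(1))
  p <- (1 + sum(perm >= obs$stat)) / (n_perm + 1)
  breakpoints <- if (p < 0.05) {
    (positions[obs$cut] + positions[obs$cut + 1]) / 2
  } else {
    numeric(0)
  }
  structure(
    list(statistic = obs$stat, p_value = p, breakpoints = breakpoints,
         pairs = data.frame(position = positions, ks = ks)),
    class = "strata_result"
  )
}

#' @export
print.strata_result <- function(x, ...) {
  cat(sprintf("strata test: statistic=%.4f, p=%.4g, %s\n",
              x$statistic, x$p_value,
              if (length(x$breakpoints)) {
                paste("breakpoint at", paste(format(x$breakpoints),
                                             collapse = ", "))
              } else "no strata detected"))
  invisible(x)
}

#' Kimura two-parameter distance between two aligned arms
#'
#' `P` and `Q` are the transition and transversion difference
#' proportions; `K = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)`. Sites
#' containing N or a gap are excluded. When the correction is undefined
#' the result is flagged saturated.
#'
#' @param arm_a,arm_b equal-length aligned sequences (gap columns
#'   pre-stripped or excluded here).
#' @return List with `P`, `Q`, `K` (NA when saturated), `n_sites` and
#'   `saturated`.
#' @export
kimura2p <- function(arm_a, arm_b) {
  a <- strsplit(toupper(arm_a), "")[[1]]
  b <- strsplit(toupper(arm_b), "")[[1]]
  if (length(a) != length(b)) stop("arms must be aligned to equal length")
  use <- a %in% DNA_BASES & b %in% DNA_BASES
  a <- a[use]
  b <- b[use]
  n <- length(a)
  if (n == 0) stop("no comparable sites")
  diff <- a != b
  is_ts <- diff & TRANSITION_OF[a] == b
  P <- sum(is_ts) / n
  Q <- sum(diff & !is_ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(list(P = P, Q = Q, K = NA_real_, n_sites = n, saturated = TRUE))
  }
  K <- -0.5 * log(arg1) - 0.25 * log(arg2)
  list(P = P, Q = Q, K = K, n_sites = n, saturated = FALSE)
}

#' LTR insertion age from arm divergence
#'
#' `age = K / (2 mu)`: both arms accumulate substitutions independently
#' after insertion, so their pairwise distance grows at twice the
#' per-lineage rate.
#'
#' @param K Kimura two-parameter distance between the arms (>= 0).
#' @param mu substitution rate per site per year (default 2.5e-9).
#' @return Age in years.
#' @export
ltr_insertion_age <- function(K, mu = 2.5e-9) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(K < 0, na.rm = TRUE)) stop("K must be non-negative")
  K / (2 * mu)
}

#' Date a set of LTR elements
#'
#' @param elements list of elements with `arm5`/`arm3` (as produced by
#'   [simulate_ltr_elements()]).
#' @param mu substitution rate per site per year.
#' @return data.frame `id`, `P`, `Q`, `K`, `age_years` (NA when
#'   saturated).
#' @export
date_ltr_elements <- function(elements, mu = 2.5e-9) {
  rows <- lapply(elements, function(el) {
    k <- kimura2p(el$arm5, el$arm3)
    data.frame(id = el$id %||% NA_character_, P = k$P, Q = k$Q,
               K = ifelse(k$saturated, NA_real_, k$K),
               age_years = ifelse(k$saturated, NA_real_,
                                  ltr_insertion_age(k$K, mu)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
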