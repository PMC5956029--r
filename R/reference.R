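#' Critical coupling of the square-lattice Ising model
#'
#' The zero-field square lattice has its exact critical point at
#' \eqn{J = \log(1 + \sqrt{2}) / (2\beta)} (Onsager solution).
#'
#' @param beta positive inverse temperature.
#' @return the nearest-neighbour coupling at criticality.
#' @export
critical_coupling <- function(beta = 1) {
  stopifnot(beta > 0)
  log(1 + sqrt(2)) / (2 * beta)
}

#' Build a periodic square-lattice Ising model at its critical point
#'
#' All biases are zero; nearest-neighbour couplings on the L x L periodic
#' lattice are set to [critical_coupling()]; all other couplings are zero.
#' This is the reference system whose pairwise-correlation distribution the
#' learning rule reproduces: at criticality its correlations decay as
#' \eqn{c(r) \propto 1/r^{\eta}} with \eqn{\eta = 1/4} (the 2-D Ising
#' universality class).
#'
#' @param L lattice side length (>= 2).
#' @param beta positive inverse temperature.
#' @return an `ising_network` of \eqn{L^2} units with lattice coordinates
#'   attached as attribute `"coords"` (one `(row, col)` pair per unit) and
#'   `"L"`.
#' @export
build_critical_lattice <- function(L, beta = 1) {
  if (L < 2) stop("lattice side L must be at least 2")
  n <- L * L
  Jc <- critical_coupling(beta)
  J <- matrix(0, n, n)
  idx <- function(r, c) ((r - 1L) %% L) * L + ((c - 1L) %% L) + 1L
  for (r in seq_len(L)) {
    for (c in seq_len(L)) {
      i <- idx(r, c)
      for (nb in list(idx(r, c + 1L), idx(r + 1L, c))) {
        J[i, nb] <- Jc
        J[nb, i] <- Jc
      }
    }
  }
  mask <- J != 0
  net <- ising_network(n, h = 0, J = J, mask = mask, beta = beta)
  # unit numbering idx() is row-major: unit i sits at row (i-1) %/% L + 1
  coords <- cbind(row = (seq_len(n) - 1L) %/% L + 1L,
                  col = (seq_len(n) - 1L) %% L + 1L)
  attr(net, "coords") <- coords
  attr(net, "L") <- L
  net
}

#' Harvest the pairwise-correlation pool of a lattice
#'
#' Simulates the lattice with Glauber dynamics and returns the empirical
#' multiset of all unordered-pair second moments
#' \eqn{c_{ij} = \langle s_i s_j\rangle} -- the correlation reservoir
#' \eqn{P(c_{ij})} from which reference targets are drawn. Raw second
#' moments are used, not covariances; on the zero-field lattice the means
#' vanish and the two coincide.
#'
#' @param net a lattice network from [build_critical_lattice()] (any
#'   `ising_network` is accepted).
#' @param n_sweeps recorded sample sweeps.
#' @param burn_in burn-in sweeps from a random state.
#' @param thin record every `thin`-th sweep.
#' @param seed optional integer seed.
#' @return an object of class `correlation_pool`: list with `values`
#'   (length \eqn{N(N-1)/2}) and `meta` (lattice size, coupling, sweep
#'   counts, per-unit means, and the full moment matrix `c_matrix`).
#' @export
harvest_pool <- function(net, n_sweeps = 1e5, burn_in = 1e4, thin = 1,
                         seed = NULL) {
  validate_ising_network(net)
  if (!is.null(seed)) set.seed(seed)
  net$state <- sample(c(-1, 1), net$n_units, replace = TRUE)
  mom <- sample_moments(net, n_sweeps = n_sweeps, burn_in = burn_in,
                        thin = thin)
  vals <- mom$c[upper.tri(mom$c)]
  structure(
    list(values = vals,
         meta = list(L = attr(net, "L"),
                     coupling = max(net$J),
                     n_units = net$n_units,
                     n_sweeps = n_sweeps, burn_in = burn_in, thin = thin,
                     means = mom$m, c_matrix = mom$c)),
    class = "correlation_pool")
}

#' @export
print.correlation_pool <- function(x, ...) {
  cat(sprintf(
    "Correlation pool: %d values in [%.3f, %.3f] (median %.3f)\n",
    length(x$values), min(x$values), max(x$values),
    stats::median(x$values)))
  if (!is.null(x$meta$L))
    cat(sprintf("  source: %d x %d lattice, J = %.4f, %g sweeps\n",
                x$meta$L, x$meta$L, x$meta$coupling, x$meta$n_sweeps))
  invisible(x)
}

#' Mean correlation as a function of lattice distance
#'
#' Buckets all unit pairs of a periodic lattice by their minimal-image
#' Euclidean distance (rounded to the nearest integer) and averages the
#' measured pair correlations within each bucket. Distance 0 is the
#' self-correlation bucket, exactly 1.
#'
#' @param net a lattice network carrying `"coords"` (from
#'   [build_critical_lattice()]).
#' @param c_matrix pair second-moment matrix, e.g. `meta$c_matrix` of a
#'   harvested pool or the `c` of [sample_moments()].
#' @return data frame with columns `r`, `mean_c`, `n_pairs`, with distances
#'   running from 0 to floor(L/2).
#' @export
correlation_vs_distance <- function(net, c_matrix) {
  coords <- attr(net, "coords")
  L <- attr(net, "L")
  if (is.null(coords) || is.null(L))
    stop("network does not carry lattice geometry")
  n <- net$n_units
  stopifnot(all(dim(c_matrix) == c(n, n)))
  dr <- abs(outer(coords[, 1], coords[, 1], "-"))
  dc <- abs(outer(coords[, 2], coords[, 2], "-"))
  dr <- pmin(dr, L - dr)
  dc <- pmin(dc, L - dc)
  rdist <- round(sqrt(dr^2 + dc^2))
  keep <- upper.tri(rdist, diag = TRUE) & rdist <= floor(L / 2)
  buckets <- split(c_matrix[keep], rdist[keep])
  data.frame(r = as.numeric(names(buckets)),
             mean_c = vapply(buckets, mean, numeric(1)),
             n_pairs = vapply(buckets, length, numeric(1)),
             row.names = NULL)
}

#' Fit the correlation-decay exponent
#'
#' Least-squares slope of \eqn{\log c} against \eqn{\log r} over the
#' requested distance range; the returned exponent is the negated slope, to
#' be compared with the 2-D Ising value \eqn{\eta = 1/4}.
#'
#' @param tbl output of [correlation_vs_distance()].
#' @param r_min,r_max distance range of the fit (at least 3 buckets).
#' @return the estimated exponent \eqn{\eta}.
#' @export
fit_power_law_exponent <- function(tbl, r_min = 1, r_max = 5) {
  sub <- tbl[tbl$r >= r_min & tbl$r <= r_max, ]
  if (nrow(sub) < 3) stop("need at least 3 distance buckets in range")
  if (any(sub$mean_c <= 0))
    stop("non-positive mean correlation in range; log-log fit undefined")
  fit <- lm(log(mean_c) ~ log(r), data = sub)
  -unname(coef(fit)[2])
}

#' Sample per-neuron reference correlations from a pool
#'
#' Each unit draws, with replacement, one reference correlation
#' \eqn{c^{*}_{ik}} per allowed coupling. Reference means \eqn{m^{*}_i} are
#' exactly 0 for all non-sensor units and absent (`NA`) for sensors, whose
#' bias is driven by the environment rather than learned.
#'
#' @param pool a `correlation_pool` (non-empty).
#' @param mask logical allowed-coupling matrix.
#' @param roles unit roles; default all `"hidden"`.
#' @param seed optional integer seed.
#' @return an object of class `reference_targets`: list with `c_star` (one
#'   numeric vector per unit, ordered by increasing partner index), `m_star`,
#'   `mask` and `roles`.
#' @export
sample_reference_targets <- function(pool, mask, roles = NULL, seed = NULL) {
  if (!length(pool$values)) stop("correlation pool is empty")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mask)
  if (is.null(roles)) roles <- rep("hidden", n)
  c_star <- lapply(seq_len(n), function(i) {
    deg <- sum(mask[i, ])
    sample(pool$values, deg, replace = TRUE)
  })
  m_star <- ifelse(roles == "sensor", NA_real_, 0)
  structure(list(c_star = c_star, m_star = m_star, mask = mask,
                 roles = roles),
            class = "reference_targets")
}
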