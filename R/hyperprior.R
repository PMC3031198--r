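#' Draw Psi and the divergence-time assignment
#'
#' Draws Psi, the number of distinct divergence times across `Y` taxon-pairs,
#' from a discrete uniform prior on 1..Y (unless fixed), draws the Psi times
#' i.i.d. from the uniform tau prior, assigns each of the Psi times to one of
#' a uniformly chosen subset of Psi pairs, and lets the remaining Y - Psi
#' pairs pick from the Psi times with replacement. By construction every
#' drawn time is used at least once, so the number of distinct values in the
#' assignment always equals Psi.
#'
#' @param Y number of taxon-pairs.
#' @param tau_range uniform bounds on tau (coalescent units of 4N
#'   generations).
#' @param psi_fixed optional integer in `1..Y` constraining Psi.
#' @return `list(psi, tau)` where `tau` has length `Y`.
#' @export
draw_psi_and_tau <- function(Y, tau_range, psi_fixed = NULL) {
  stopifnot(Y >= 1, length(tau_range) == 2, tau_range[1] <= tau_range[2])
  if (!is.null(psi_fixed)) {
    if (psi_fixed < 1 || psi_fixed > Y) {
      stop("psi_fixed must lie in 1..Y", call. = FALSE)
    }
    psi <- as.integer(psi_fixed)
  } else {
    psi <- sample.int(Y, 1L)
  }
  times <- runif(psi, tau_range[1], tau_range[2])
  tau <- numeric(Y)
  anchors <- sample.int(Y, psi)
  tau[anchors] <- times
  rest <- setdiff(seq_len(Y), anchors)
  if (length(rest) > 0) {
    tau[rest] <- times[sample.int(psi, length(rest), replace = TRUE)]
  }
  list(psi = psi, tau = tau)
}

#' Draw per-taxon demographic parameters
#'
#' Each taxon-pair descends from an ancestral population of size theta_A
#' that splits at time tau into two populations of sizes theta_A1 and
#' theta_A2 (uniform fractions of theta_A), which grow exponentially to
#' current sizes theta_B1 and theta_B2 starting at times tau_B1 and tau_B2
#' (uniform fractions of tau, so growth onset never predates the split).
#' Symmetric migration at rate Nm (migrants per generation) connects the
#' descendants between the present and tau.
#'
#' @param prior a [prior_spec()].
#' @param tau divergence time(s); one row is drawn per element.
#' @param nm_range Nm bounds for the migration model in effect.
#' @return Tibble with one row per tau: `theta_a`, `theta_a1`, `theta_a2`,
#'   `theta_b1`, `theta_b2`, `tau_b1`, `tau_b2`, `tau`, `nm`.
#' @export
draw_taxon_params <- function(prior, tau, nm_range = c(0, 0)) {
  n <- length(tau)
  theta_a <- runif(n, prior$theta_a_range[1], prior$theta_a_range[2])
  tibble::tibble(
    theta_a = theta_a,
    theta_a1 = theta_a * runif(n, prior$size_frac_range[1], prior$size_frac_range[2]),
    theta_a2 = theta_a * runif(n, prior$size_frac_range[1], prior$size_frac_range[2]),
    theta_b1 = runif(n, prior$theta_b_range[1], prior$theta_b_range[2]),
    theta_b2 = runif(n, prior$theta_b_range[1], prior$theta_b_range[2]),
    tau_b1 = tau * runif(n, prior$time_frac_range[1], prior$time_frac_range[2]),
    tau_b2 = tau * runif(n, prior$time_frac_range[1], prior$time_frac_range[2]),
    tau = tau,
    nm = runif(n, nm_range[1], nm_range[2]))
}

#' Draw the gamma shape and per-locus substitution-rate scalars
#'
#' One gamma shape alpha is drawn per simulated data set from its uniform
#' hyper-prior and shared across loci; the per-locus scalars are then i.i.d.
#' Gamma(shape alpha, scale 1/alpha), so the mean scalar is 1 and its
#' variance is 1/alpha. With `rate_het = FALSE` every scalar is 1; loci with
#' prior rate information can instead be pinned via `fixed`.
#'
#' @param alpha_range bounds of the uniform hyper-prior on alpha.
#' @param n_loci number of loci.
#' @param rate_het logical; draw scalars (`TRUE`) or fix them at 1.
#' @param fixed optional numeric vector of length `n_loci`; non-NA entries
#'   are used verbatim.
#' @return `list(alpha, scalars)`.
#' @export
draw_locus_scalars <- function(alpha_range, n_loci, rate_het = TRUE,
                               fixed = NULL) {
  stopifnot(n_loci >= 1)
  if (!is.null(fixed) && length(fixed) != n_loci) {
    stop("`fixed` must have one entry per locus", call. = FALSE)
  }
  alpha <- runif(1, alpha_range[1], alpha_range[2])
  scalars <- if (rate_het) rgamma(n_loci, shape = alpha, rate = alpha)
             else rep(1, n_loci)
  if (!is.null(fixed)) {
    scalars[!is.na(fixed)] <- fixed[!is.na(fixed)]
  }
  list(alpha = alpha, scalars = scalars)
}

#' Draw the migration-model indicator
#'
#' @param migration_models data frame of candidate models (see
#'   [prior_spec()]); the indicator is uniform over its rows.
#' @return Integer row index of the chosen model.
#' @export
draw_model_indicator <- function(migration_models) {
  stopifnot(nrow(migration_models) >= 1)
  sample.int(nrow(migration_models), 1L)
}

#' One draw from the full hierarchical prior
#'
#' Combines the model indicator, the Psi/tau assignment, per-taxon
#' demographic parameters and per-locus rate scalars into a single
#' `hyper_draw` object consistent with a sampling configuration.
#'
#' @param config a [sampling_config()].
#' @param prior a [prior_spec()].
#' @return An object of class `hyper_draw`: `z`, `psi`, `tau`, `alpha`,
#'   `taxa` (per-pair parameter tibble) and `loci` (per-locus tibble with
#'   rate scalars).
#' @export
draw_hyper <- function(config, prior) {
  validate_sampling_config(config)
  Y <- length(unique(config$pair))
  z <- draw_model_indicator(prior$migration_models)
  pt <- draw_psi_and_tau(Y, prior$tau_range, prior$psi_fixed)
  nm_range <- c(prior$migration_models$nm_lo[z], prior$migration_models$nm_hi[z])
  taxa <- draw_taxon_params(prior, pt$tau, nm_range)
  sc <- draw_locus_scalars(prior$alpha_range, nrow(config), prior$rate_het,
                           fixed = config$rate_fixed)
  loci <- dplyr::mutate(tibble::as_tibble(config)[, c("pair", "locus")],
                        rate_scalar = sc$scalars)
  structure(list(z = z, psi = pt$psi, tau = pt$tau, alpha = sc$alpha,
                 taxa = taxa, loci = loci),
            class = "hyper_draw")
}

#' @export
print.hyper_draw <- function(x, ...) {
  s <- hyper_summaries(x$tau)
  cat(sprintf("hyper_draw: Z = %d, Psi = %d, E(tau) = %.4g, Omega = %.4g\n",
              x$z, x$psi, s$e_tau, s$omega))
  invisible(x)
}

#' Hyper-parameter summaries of a divergence-time assignment
#'
#' @param tau numeric vector of per-pair divergence times (all >= 0).
#' @return One-row tibble: `e_tau` (mean), `omega` (dispersion index,
#'   population variance / mean; 0 when the mean is 0) and `psi` (number of
#'   distinct times).
#' @details The variance uses the population denominator `Y` so that Omega
#'   is exactly 0 whenever all times coincide, independent of `Y`.
#' @export
hyper_summaries <- function(tau) {
  stopifnot(length(tau) >= 1, all(tau >= 0))
  m <- mean(tau)
  v <- mean(tau^2) - m^2
  tibble::tibble(e_tau = m,
                 omega = if (m > 0) max(v, 0) / m else 0,
                 psi = length(unique(tau)))
}
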