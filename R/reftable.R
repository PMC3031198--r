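# Vectorised draws from the hierarchical prior for n simulated data sets.
# Returns matrices (n x Y, or n x total_loci for rate scalars); all
# randomness goes through R's RNG so set.seed() fixes the whole batch.
draw_hyper_batch <- function(config, prior, n) {
  Y <- length(unique(config$pair))
  tl <- nrow(config)
  psi <- integer(n)
  tau <- matrix(0, n, Y)
  for (i in seq_len(n)) {
    pt <- draw_psi_and_tau(Y, prior$tau_range, prior$psi_fixed)
    psi[i] <- pt$psi
    tau[i, ] <- pt$tau
  }
  models <- prior$migration_models
  z <- if (nrow(models) == 1) rep(1L, n) else sample.int(nrow(models), n, TRUE)
  nm <- matrix(runif(n * Y), n, Y) * (models$nm_hi[z] - models$nm_lo[z]) +
    models$nm_lo[z]
  ru <- function(r) matrix(runif(n * Y, r[1], r[2]), n, Y)
  theta_a <- ru(prior$theta_a_range)
  theta_b1 <- ru(prior$theta_b_range)
  theta_b2 <- ru(prior$theta_b_range)
  theta_a1 <- theta_a * ru(prior$size_frac_range)
  theta_a2 <- theta_a * ru(prior$size_frac_range)
  tau_b1 <- tau * ru(prior$time_frac_range)
  tau_b2 <- tau * ru(prior$time_frac_range)
  alpha <- runif(n, prior$alpha_range[1], prior$alpha_range[2])
  rate <- if (prior$rate_het) {
    matrix(rgamma(n * tl, shape = alpha, rate = alpha), n, tl)
  } else {
    matrix(1, n, tl)
  }
  fixed <- which(!is.na(config$rate_fixed))
  for (l in fixed) rate[, l] <- config$rate_fixed[l]
  list(Y = Y, psi = psi, tau = tau, z = z, nm = nm,
       theta_a = theta_a, theta_a1 = theta_a1, theta_a2 = theta_a2,
       theta_b1 = theta_b1, theta_b2 = theta_b2,
       tau_b1 = tau_b1, tau_b2 = tau_b2, alpha = alpha, rate = rate)
}

#' Simulate a reference table of hyper-parameter draws and D_m vectors
#'
#' The core prior-predictive engine: for each of `n_sims` draws from the
#' hierarchical prior, a full multi-taxon-pair multi-locus data set is
#' simulated under the structured coalescent with finite-sites mutation,
#' matching `config` exactly, and reduced to the flattened moment vector
#' D_m of the selected statistic classes. Rows pair hyper-parameter records
#' (model indicator Z, Psi, E(tau), Omega, the per-pair tau assignment)
#' with summary-statistic coordinates; rejection ABC operates directly on
#' this table.
#'
#' @param config a [sampling_config()].
#' @param prior a [prior_spec()].
#' @param n_sims number of simulated data sets.
#' @param classes statistic classes to collect (must include `pi_b` when
#'   `sort_pairs = TRUE`).
#' @param n_moments raw moments across loci per class (1 to 4).
#' @param sort_pairs re-order taxon-pair slots by descending mean `pi_b`
#'   (the exchangeable sorting); `FALSE` keeps the configured order.
#' @return A tibble with columns `sim`, `z`, `model`, `psi`, `e_tau`,
#'   `omega`, `tau_1..tau_Y` and the `ss_` coordinates of [dm_names()];
#'   attributes `classes`, `n_moments`, `Y`, `sorted`.
#' @export
simulate_reference_table <- function(config, prior, n_sims,
                                     classes = c("pi_b", "psi_w"),
                                     n_moments = 1, sort_pairs = TRUE) {
  validate_sampling_config(config)
  unknown <- setdiff(classes, ss_classes())
  if (length(unknown) > 0) {
    stop("unknown statistic class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  classes <- intersect(ss_classes(), classes)
  stopifnot(n_sims >= 1, n_moments >= 1, n_moments <= 4)
  if (sort_pairs && !"pi_b" %in% classes) {
    stop("pi_b must be selected when sorting by mean pi_b", call. = FALSE)
  }
  Y <- length(unique(config$pair))
  nloci <- as.integer(table(config$pair))
  pair_first <- match(seq_len(Y), config$pair)
  hp <- draw_hyper_batch(config, prior, n_sims)
  cls_idx <- match(classes, ss_classes()) - 1L
  D <- .sim_batch_cpp(n_sims,
                      config$n1[pair_first], config$n2[pair_first], nloci,
                      as.integer(config$L), config$inherit,
                      model_code(config$model), config$kappa,
                      as.matrix(config[, c("f_a", "f_c", "f_g", "f_t")]),
                      hp$tau, hp$theta_a, hp$theta_a1, hp$theta_a2,
                      hp$theta_b1, hp$theta_b2, hp$tau_b1, hp$tau_b2,
                      hp$nm, hp$rate,
                      cls_idx, as.integer(n_moments), sort_pairs)
  colnames(D) <- dm_names(classes, Y, n_moments)
  if (anyNA(D)) {
    stop("selected classes are masked for at least one taxon-pair at the ",
         "configured sample sizes", call. = FALSE)
  }
  e_tau <- rowMeans(hp$tau)
  omega <- ifelse(e_tau > 0, pmax(rowMeans(hp$tau^2) - e_tau^2, 0) / e_tau, 0)
  tau_cols <- setNames(as.data.frame(hp$tau), sprintf("tau_%d", seq_len(Y)))
  out <- dplyr::bind_cols(
    tibble::tibble(sim = seq_len(n_sims), z = hp$z,
                   model = prior$migration_models$label[hp$z],
                   psi = hp$psi, e_tau = e_tau, omega = omega),
    tibble::as_tibble(tau_cols),
    tibble::as_tibble(D))
  attr(out, "classes") <- classes
  attr(out, "n_moments") <- n_moments
  attr(out, "Y") <- Y
  attr(out, "sorted") <- sort_pairs
  out
}

#' Generate pseudo-observed data sets (PODS)
#'
#' PODS are draws from the same hierarchical prior (optionally constrained,
#' e.g. `psi_fixed = 1` for simultaneous-divergence truth, or a single
#' migration model) with their true hyper-parameters recorded, used to
#' validate the ABC estimators. The simulated reference table and the PODS
#' must share an identical sampling configuration.
#'
#' @inheritParams simulate_reference_table
#' @param n_pods number of pseudo-observed data sets.
#' @return As [simulate_reference_table()], with the row index column named
#'   `pod`; the hyper-parameter columns are the recorded truths.
#' @export
generate_pods <- function(config, prior, n_pods,
                          classes = c("pi_b", "psi_w"),
                          n_moments = 1, sort_pairs = TRUE) {
  out <- simulate_reference_table(config, prior, n_pods, classes = classes,
                                  n_moments = n_moments,
                                  sort_pairs = sort_pairs)
  dplyr::rename(out, pod = "sim")
}

ss_cols <- function(tbl) grep("^ss_", names(tbl), value = TRUE)

#' Write / read a reference table as tab-delimited text
#'
#' The first line is a `#`-prefixed JSON manifest naming every column and
#' recording the statistic selection, moment count, number of taxon-pairs,
#' sorting flag and the (population) variance convention behind Omega.
#' Numeric fields round-trip at full precision. Reading verifies the
#' manifest against the file body and refuses mismatches.
#'
#' @param table a [simulate_reference_table()] tibble.
#' @param path file path.
#' @return `read_reference_table()` returns the tibble with its attributes
#'   restored.
#' @export
write_reference_table <- function(table, path) {
  manifest <- list(columns = names(table),
                   classes = attr(table, "classes"),
                   n_moments = attr(table, "n_moments"),
                   Y = attr(table, "Y"),
                   sorted = attr(table, "sorted"),
                   omega_variance = "population")
  cols <- purrr::map(table, function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  })
  body <- if (nrow(table) > 0) do.call(paste, c(cols, sep = "\t")) else character()
  writeLines(c(paste0("#", jsonlite::toJSON(manifest, auto_unbox = TRUE)),
               paste(names(table), collapse = "\t"),
               body), path)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) {
    stop("not a reference table: missing JSON manifest line", call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(substring(first, 2))
  # base strtod parsing round-trips %.17g doubles bit-exactly
  tbl <- tibble::as_tibble(utils::read.delim(path, skip = 1, sep = "\t",
                                             header = TRUE,
                                             check.names = FALSE))
  if (!identical(names(tbl), manifest$columns)) {
    stop("reference table columns do not match the manifest", call. = FALSE)
  }
  attr(tbl, "classes") <- manifest$classes
  attr(tbl, "n_moments") <- manifest$n_moments
  attr(tbl, "Y") <- manifest$Y
  attr(tbl, "sorted") <- manifest$sorted
  tbl
}
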