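#' Root mean square error of point estimates
#'
#' @param estimates,truths equal-length numeric vectors (one entry per
#'   PODS).
#' @return `sqrt(mean((estimates - truths)^2))`.
#' @export
rmse <- function(estimates, truths) {
  if (length(estimates) != length(truths) || length(estimates) < 1) {
    stop("estimates and truths must have equal length >= 1", call. = FALSE)
  }
  sqrt(mean((estimates - truths)^2))
}

#' Root mean square posterior error for one PODS
#'
#' @param accepted accepted posterior values for one pseudo-observed data
#'   set.
#' @param truth the true hyper-parameter value behind that PODS.
#' @return `sqrt(mean((accepted - truth)^2))`.
#' @export
rmspe <- function(accepted, truth) {
  stopifnot(length(accepted) >= 1, length(truth) == 1)
  sqrt(mean((accepted - truth)^2))
}

# scale selected coordinates of a reference table once, then run
# rejection + local-linear adjustment for a whole set of PODS rows
scale_block <- function(tbl, cols) {
  M <- as.matrix(tbl[, cols, drop = FALSE])
  sds <- apply(M, 2, sd)
  keep <- sds > 0 & is.finite(sds)
  if (!any(keep)) stop("all selected coordinates have zero variance", call. = FALSE)
  list(M = sweep(M[, keep, drop = FALSE], 2, sds[keep], "/"),
       sds = sds[keep], cols = cols[keep])
}

pod_posterior <- function(block, meta, obs_row, n_accept) {
  obs <- as.numeric(obs_row[block$cols]) / block$sds
  delta <- sweep(block$M, 2, obs, "-")
  d <- sqrt(rowSums(delta^2))
  ord <- order(d, seq_along(d))[seq_len(n_accept)]
  dd <- d[ord]
  dmax <- max(dd)
  w <- if (dmax > 0) 1 - (dd / dmax)^2 else rep(1, n_accept)
  if (all(w == 0)) w[] <- 1
  structure(list(meta = meta[ord, , drop = FALSE],
                 ss = block$M[ord, , drop = FALSE],
                 obs = obs, dist = dd, weight = w, n_total = nrow(block$M)),
            class = "abc_posterior")
}

#' Sorting-strategy comparison under simultaneous divergence
#'
#' Reproduces the exchangeable-sorting experiment: PODS are simulated
#' under simultaneous divergence (Psi = 1, Omega = 0) for several numbers
#' of taxon-pairs, and Omega is estimated from a D_m consisting of the
#' across-loci mean of pi_b per pair, once with taxon-pair slots ordered by
#' descending mean pi_b and once ordered by total sample size. Because the
#' same per-pair coordinates feed both orderings, the comparison is paired
#' per PODS. Under the pi_b sorting, Omega-hat distributions concentrate
#' near 0 and the advantage grows with the number of pairs.
#'
#' @param Y_values numbers of taxon-pairs to test.
#' @param prior a [prior_spec()] for the reference table (Psi free); PODS
#'   use the same prior with `psi_fixed = 1`.
#' @param n_loci loci per pair.
#' @param n_sims reference-table rows per `Y`.
#' @param n_pods PODS per `Y`.
#' @param n_accept accepted draws per PODS.
#' @param sample_sizes per-population sample sizes cycled across pairs
#'   (varying sizes make the sample-size ordering a genuine alternative).
#' @param L locus length in base pairs.
#' @return Tibble: `Y`, `pod`, `ordering`, `omega_true`, `omega_hat`.
#' @export
experiment_sorting <- function(Y_values = c(5, 10, 20),
                               prior = prior_spec(),
                               n_loci = 4, n_sims = 30000, n_pods = 50,
                               n_accept = 500,
                               sample_sizes = c(3, 4, 5, 6, 8),
                               L = 1100) {
  purrr::map_dfr(Y_values, function(Y) {
    ns <- rep_len(sample_sizes, Y)
    cfg <- sampling_config(config_template(Y, n_loci, n1 = ns, n2 = ns, L = L))
    ref <- simulate_reference_table(cfg, prior, n_sims, classes = "pi_b",
                                    n_moments = 1, sort_pairs = FALSE)
    pods_prior <- prior
    pods_prior$psi_fixed <- 1L
    pods <- generate_pods(cfg, pods_prior, n_pods, classes = "pi_b",
                          n_moments = 1, sort_pairs = FALSE)
    cols <- dm_names("pi_b", Y, 1)
    # mean pi_b per configured pair; both orderings are column permutations
    refM <- as.matrix(ref[, cols])
    podM <- as.matrix(pods[, cols])
    sortdesc <- function(M) t(apply(M, 1, sort, decreasing = TRUE))
    size_ord <- order(-(2 * ns), seq_len(Y))
    variants <- list(
      sorted_pi_b = list(ref = sortdesc(refM), pod = sortdesc(podM)),
      sample_size = list(ref = refM[, size_ord, drop = FALSE],
                         pod = podM[, size_ord, drop = FALSE]))
    meta <- ref[, c("psi", "e_tau", "omega")]
    purrr::imap_dfr(variants, function(v, ordering) {
      Mr <- v$ref
      colnames(Mr) <- cols
      tblv <- dplyr::bind_cols(meta, tibble::as_tibble(Mr))
      block <- scale_block(tblv, cols)
      purrr::map_dfr(seq_len(n_pods), function(i) {
        obs_row <- setNames(as.numeric(v$pod[i, ]), cols)
        post <- pod_posterior(block, meta, obs_row, n_accept)
        post <- abc_adjust_loclinear(post, targets = "omega",
                                     bounds = list(omega = c(0, Inf)))
        tibble::tibble(Y = Y, pod = i, ordering = ordering,
                       omega_true = pods$omega[i],
                       omega_hat = posterior_mode(post$adjusted$omega,
                                                  bounds = c(0, Inf),
                                                  weights = post$weight))
      })
    })
  })
}

#' Estimator accuracy as a function of the number of loci
#'
#' For each locus count, a reference table and PODS (Psi drawn from its
#' discrete uniform hyper-prior) are simulated under an identical sampling
#' configuration, and E(tau) and Omega are estimated per PODS by rejection
#' plus local-linear adjustment with D_m the across-loci mean of pi_b. The
#' report carries the per-PODS truths, posterior modes and RMSPE, from
#' which RMSE trends across locus counts are summarised with
#' [experiment_rmse_summary()].
#'
#' @param loci_counts numbers of loci per taxon-pair to compare.
#' @param Y number of taxon-pairs.
#' @param prior a [prior_spec()] (applied to both table and PODS).
#' @inheritParams experiment_sorting
#' @param n1,n2 per-population sample sizes.
#' @return Tibble with one row per (locus count, PODS): truths, posterior
#'   modes and RMSPE for `e_tau` and `omega`.
#' @export
experiment_loci <- function(loci_counts = c(1, 4, 16, 64), Y = 5,
                            prior = prior_spec(),
                            n_sims = 30000, n_pods = 50, n_accept = 500,
                            n1 = 5, n2 = 5, L = 1100) {
  cols_fun <- function() dm_names("pi_b", Y, 1)
  purrr::map_dfr(loci_counts, function(nl) {
    cfg <- sampling_config(config_template(Y, nl, n1 = n1, n2 = n2, L = L))
    ref <- simulate_reference_table(cfg, prior, n_sims, classes = "pi_b",
                                    n_moments = 1, sort_pairs = TRUE)
    pods <- generate_pods(cfg, prior, n_pods, classes = "pi_b",
                          n_moments = 1, sort_pairs = TRUE)
    cols <- cols_fun()
    block <- scale_block(ref, cols)
    meta <- ref[, c("psi", "e_tau", "omega")]
    bounds <- list(e_tau = prior$tau_range, omega = c(0, Inf))
    purrr::map_dfr(seq_len(n_pods), function(i) {
      post <- pod_posterior(block, meta, unlist(pods[i, cols]), n_accept)
      post <- abc_adjust_loclinear(post, targets = c("e_tau", "omega"),
                                   bounds = bounds)
      tibble::tibble(
        n_loci = nl, pod = i,
        e_tau_true = pods$e_tau[i], omega_true = pods$omega[i],
        e_tau_mode = posterior_mode(post$adjusted$e_tau,
                                    bounds = bounds$e_tau,
                                    weights = post$weight),
        omega_mode = posterior_mode(post$adjusted$omega,
                                    bounds = bounds$omega,
                                    weights = post$weight),
        rmspe_e_tau = rmspe(post$adjusted$e_tau, pods$e_tau[i]),
        rmspe_omega = rmspe(post$adjusted$omega, pods$omega[i]))
    })
  })
}

#' Summarise an [experiment_loci()] report into RMSE per locus count
#'
#' @param report an [experiment_loci()] tibble.
#' @return Tibble: `n_loci`, `rmse_e_tau`, `rmse_omega`, mean RMSPE per
#'   target.
#' @export
experiment_rmse_summary <- function(report) {
  report |>
    dplyr::group_by(.data$n_loci) |>
    dplyr::summarise(
      rmse_e_tau = rmse(.data$e_tau_mode, .data$e_tau_true),
      rmse_omega = rmse(.data$omega_mode, .data$omega_true),
      mean_rmspe_e_tau = mean(.data$rmspe_e_tau),
      mean_rmspe_omega = mean(.data$rmspe_omega),
      .groups = "drop")
}

#' Migration-model choice accuracy experiment
#'
#' A joint reference table is simulated with the candidate migration
#' models in equal proportion; PODS are then simulated under each
#' candidate in turn and the model indicator is estimated per PODS from
#' the accepted draws, both as raw accepted frequencies and after
#' polychotomous regression, for each statistic selection (mean pi_b only
#' versus mean pi_b plus the interpopulation correlation psi_w). The
#' chosen model is the argmax of the posterior probabilities, ties broken
#' toward the first (simplest, by convention isolation) model.
#'
#' @param config a [sampling_config()] shared by table and PODS.
#' @param prior a [prior_spec()] whose `migration_models` are the
#'   candidates (first row should be the isolation model).
#' @param n_sims reference-table rows (models mixed uniformly).
#' @param n_pods_per_model PODS per true model.
#' @param n_accept accepted draws per PODS.
#' @param selections named list of statistic-class selections to compare.
#' @return Tibble: `true_model`, `selection`, `method` (`raw` or
#'   `regression`), `pod`, `chosen`, `correct`, `prob_correct` and
#'   `bf_correct` (Bayes factor for the true model against the rest).
#' @export
experiment_model_choice <- function(config, prior,
                                    n_sims = 1e5, n_pods_per_model = 50,
                                    n_accept = 500,
                                    selections = list(
                                      pi_b = "pi_b",
                                      pi_b_psi_w = c("pi_b", "psi_w"))) {
  validate_sampling_config(config)
  models <- prior$migration_models
  all_classes <- sort(unique(unlist(selections)))
  ref <- simulate_reference_table(config, prior, n_sims,
                                  classes = all_classes, n_moments = 1,
                                  sort_pairs = TRUE)
  Y <- attr(ref, "Y")
  meta <- ref[, c("z", "psi", "e_tau", "omega")]
  prior_p <- 1 / nrow(models)
  purrr::map_dfr(seq_len(nrow(models)), function(m) {
    prior_m <- prior
    prior_m$migration_models <- models[m, ]
    pods <- generate_pods(config, prior_m, n_pods_per_model,
                          classes = all_classes, n_moments = 1,
                          sort_pairs = TRUE)
    purrr::imap_dfr(selections, function(sel, sel_name) {
      cols <- dm_names(intersect(ss_classes(), sel), Y, 1)
      block <- scale_block(ref, cols)
      purrr::map_dfr(seq_len(n_pods_per_model), function(i) {
        post <- pod_posterior(block, meta, unlist(pods[i, cols]), n_accept)
        lv <- as.character(seq_len(nrow(models)))
        rawf <- table(factor(as.character(post$meta$z), levels = lv))
        raw_p <- setNames(as.numeric(rawf) / sum(rawf), lv)
        reg_p <- abc_adjust_polychotomous(post, "z", levels = lv)
        purrr::imap_dfr(list(raw = raw_p, regression = reg_p),
                        function(p, method) {
          chosen <- as.integer(lv[which.max(p)])  # which.max: first max wins
          pc <- p[as.character(m)]
          tibble::tibble(true_model = m, selection = sel_name,
                         method = method, pod = i, chosen = chosen,
                         correct = chosen == m,
                         prob_correct = unname(pc),
                         bf_correct = if (pc >= 1) Inf else if (pc <= 0) 0
                                      else bayes_factor(unname(pc), prior_p))
        })
      })
    })
  })
}

#' Accuracy summary of a model-choice experiment
#'
#' @param report an [experiment_model_choice()] tibble.
#' @return Tibble of the fraction of correct choices and mean finite Bayes
#'   factor for the true model, per true model, selection and method.
#' @export
model_choice_summary <- function(report) {
  report |>
    dplyr::group_by(.data$true_model, .data$selection, .data$method) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      mean_bf_correct = mean(.data$bf_correct[is.finite(.data$bf_correct)]),
      .groups = "drop")
}

#' Plot a sorting-experiment report
#'
#' Histograms of the Omega mode estimates under each ordering, faceted by
#' the number of taxon-pairs; under simultaneous divergence the truth is
#' Omega = 0.
#'
#' @param report an [experiment_sorting()] tibble.
#' @return A ggplot object.
#' @export
plot_sorting_experiment <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$omega_hat,
                                       fill = .data$ordering)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.6, position = "identity") +
    ggplot2::facet_wrap(~Y, scales = "free", labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(hat(Omega)), y = "PODS", fill = "ordering") +
    ggplot2::theme_minimal()
}

#' Plot RMSE against the number of loci
#'
#' @param report an [experiment_loci()] tibble.
#' @return A ggplot object.
#' @export
plot_loci_experiment <- function(report) {
  experiment_rmse_summary(report) |>
    tidyr::pivot_longer(c("rmse_e_tau", "rmse_omega"),
                        names_to = "target", values_to = "rmse",
                        names_prefix = "rmse_") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$n_loci, y = .data$rmse,
                                 colour = .data$target)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = c(1, 4, 8, 16, 32, 64)) +
    ggplot2::labs(x = "loci per taxon-pair", y = "RMSE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot model-choice accuracy
#'
#' @param report an [experiment_model_choice()] tibble.
#' @return A ggplot object.
#' @export
plot_model_choice <- function(report) {
  model_choice_summary(report) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$true_model),
                                 y = .data$accuracy,
                                 fill = .data$selection)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~method) +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = 2) +
    ggplot2::labs(x = "true model", y = "fraction chosen correctly",
                  fill = "summary statistics") +
    ggplot2::theme_minimal()
}
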