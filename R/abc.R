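#' Scale reference-table coordinates to unit variance
#'
#' Every `ss_` coordinate is divided by its standard deviation across the
#' reference table; the observed vector is scaled by the same factors so
#' Euclidean distances weight all coordinates equally. Zero-variance
#' coordinates carry no information and are dropped (recorded in
#' `dropped`).
#'
#' @param table a [simulate_reference_table()] tibble.
#' @param observed a one-row tibble or named vector holding the observed
#'   `ss_` coordinates (same layout as the table).
#' @return A list: `ss` (scaled coordinate matrix), `obs` (scaled observed
#'   vector), `meta` (the non-coordinate columns), `sd` (the scale
#'   factors) and `dropped` (names of removed coordinates).
#' @export
abc_standardize <- function(table, observed) {
  cols <- ss_cols(table)
  if (length(cols) == 0) stop("no ss_ coordinates in the table", call. = FALSE)
  if (is.data.frame(observed)) observed <- unlist(observed[1, , drop = FALSE])
  observed <- observed[grep("^ss_", names(observed))]
  if (!identical(sort(names(observed)), sort(cols))) {
    stop("observed vector coordinates do not match the reference table",
         call. = FALSE)
  }
  ss <- as.matrix(table[, cols])
  sds <- apply(ss, 2, sd)
  keep <- sds > 0 & is.finite(sds)
  if (!any(keep)) stop("all coordinates have zero variance", call. = FALSE)
  ss <- sweep(ss[, keep, drop = FALSE], 2, sds[keep], "/")
  obs <- observed[cols][keep] / sds[keep]
  list(ss = ss, obs = obs,
       meta = table[, setdiff(names(table), cols)],
       sd = sds[keep], dropped = cols[!keep])
}

#' Rejection sampling on scaled Euclidean distance
#'
#' Accepts the `n_accept` reference-table rows whose scaled summary
#' vectors are closest (Euclidean) to the observed vector, ties broken by
#' row order. Epanechnikov kernel weights on the accepted distances (with
#' bandwidth equal to the largest accepted distance) are attached for the
#' regression-adjustment steps.
#'
#' @param std an [abc_standardize()] result.
#' @param n_accept number of rows to accept (1 to `nrow`).
#' @return An object of class `abc_posterior`: `meta` (accepted
#'   hyper-parameter rows), `ss` (their scaled coordinates), `obs`,
#'   `dist`, `weight`, `n_total`.
#' @export
abc_reject <- function(std, n_accept) {
  n <- nrow(std$ss)
  stopifnot(n_accept >= 1, n_accept <= n)
  delta <- sweep(std$ss, 2, std$obs, "-")
  dist <- sqrt(rowSums(delta^2))
  ord <- order(dist, seq_len(n))[seq_len(n_accept)]
  d <- dist[ord]
  dmax <- max(d)
  w <- if (dmax > 0) 1 - (d / dmax)^2 else rep(1, n_accept)
  if (all(w == 0)) w[] <- 1
  structure(list(meta = std$meta[ord, , drop = FALSE],
                 ss = std$ss[ord, , drop = FALSE],
                 obs = std$obs, dist = d, weight = w, n_total = n),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("abc_posterior: %d accepted of %d simulations (max distance %.4g)\n",
              length(x$dist), x$n_total, max(x$dist)))
  invisible(x)
}

#' Local-linear regression adjustment for continuous hyper-parameters
#'
#' Weighted least squares of each target on the accepted summary-vector
#' deviations from the observed point; each accepted value is shifted to
#' its regression prediction at the observed point,
#' `theta* = theta - b (D - D*)`, then truncated to the prior support. If
#' the weighted design is singular the raw values are kept and a warning
#' is recorded.
#'
#' @param post an [abc_reject()] posterior.
#' @param targets names of continuous columns in `post$meta` to adjust.
#' @param bounds optional named list of `c(lo, hi)` support bounds per
#'   target.
#' @return `post` with an `adjusted` tibble added.
#' @export
abc_adjust_loclinear <- function(post, targets = c("e_tau", "omega"),
                                 bounds = NULL) {
  X <- sweep(post$ss, 2, post$obs, "-")
  n <- nrow(X)
  if (n < ncol(X) + 2) {
    stop("need at least dim + 2 accepted points for the local-linear step",
         call. = FALSE)
  }
  design <- cbind(1, X)
  adjusted <- purrr::map(targets, function(tg) {
    y <- post$meta[[tg]]
    fit <- tryCatch(lm.wfit(design, y, post$weight), error = function(e) NULL)
    if (is.null(fit) || fit$rank < ncol(design) || anyNA(fit$coefficients)) {
      warning("singular local-linear design for '", tg,
              "'; returning unadjusted values", call. = FALSE)
      return(y)
    }
    b <- fit$coefficients[-1]
    adj <- y - drop(X %*% b)
    if (!is.null(bounds[[tg]])) {
      adj <- pmin(pmax(adj, bounds[[tg]][1]), bounds[[tg]][2])
    }
    adj
  })
  post$adjusted <- tibble::as_tibble(setNames(adjusted, targets))
  post
}

#' Polychotomous regression for discrete parameters and model indicators
#'
#' Kernel-weighted multinomial logistic regression of the accepted
#' category labels on the summary-vector deviations, evaluated at the
#' observed point (deviation zero). A small ridge penalty (weight decay)
#' keeps quasi-separated fits deterministic. On failure or
#' non-convergence the kernel-weighted category frequencies are returned
#' with a warning.
#'
#' @param post an [abc_reject()] posterior.
#' @param column name of the discrete column in `post$meta`.
#' @param levels optional complete set of category levels (absent
#'   categories get probability 0).
#' @param ridge ridge (weight-decay) penalty.
#' @return Named numeric vector of category probabilities at the observed
#'   point.
#' @export
abc_adjust_polychotomous <- function(post, column, levels = NULL,
                                     ridge = 1e-6) {
  yfac <- factor(post$meta[[column]], levels = levels %||%
                   sort(unique(post$meta[[column]])))
  lv <- base::levels(yfac)
  out <- setNames(numeric(length(lv)), lv)
  present <- lv[lv %in% unique(as.character(yfac))]
  if (length(present) < 2) {
    out[present] <- 1
    return(out)
  }
  X <- sweep(post$ss, 2, post$obs, "-")
  df <- data.frame(X)
  df$.y <- droplevels(yfac)
  w <- post$weight
  fit <- tryCatch(
    nnet::multinom(.y ~ ., data = df, weights = w, decay = ridge,
                   trace = FALSE, maxit = 2000),
    error = function(e) NULL)
  if (!is.null(fit) && isTRUE(fit$convergence == 0)) {
    nd <- as.data.frame(matrix(0, 1, ncol(X)))
    names(nd) <- colnames(df)[seq_len(ncol(X))]
    pr <- predict(fit, newdata = nd, type = "probs")
    if (length(base::levels(df$.y)) == 2) {
      pr <- c(1 - pr, pr)
    }
    out[base::levels(df$.y)] <- as.numeric(pr)
    return(out)
  }
  warning("polychotomous regression did not converge for '", column,
          "'; returning weighted accepted frequencies", call. = FALSE)
  freq <- tapply(w, yfac, sum, default = 0)
  out[names(freq)] <- freq / sum(w)
  out
}

#' Kernel-density posterior mode
#'
#' Mode of a Gaussian kernel density with Silverman's bandwidth; when
#' support bounds are supplied the sample is reflected about the finite
#' bounds so boundary modes (e.g. Omega = 0 under simultaneous divergence)
#' are not smoothed away.
#'
#' @param x numeric sample (>= 1 values; a constant sample returns that
#'   constant).
#' @param bounds optional `c(lo, hi)` support (may be infinite).
#' @param weights optional non-negative weights.
#' @return The mode location.
#' @export
posterior_mode <- function(x, bounds = NULL, weights = NULL) {
  stopifnot(length(x) >= 1)
  if (length(unique(x)) == 1) return(x[1])
  w <- weights %||% rep(1, length(x))
  bw <- stats::bw.nrd0(x)
  xs <- x
  ws <- w
  lo <- -Inf; hi <- Inf
  if (!is.null(bounds)) {
    lo <- bounds[1]; hi <- bounds[2]
    if (is.finite(lo)) { xs <- c(xs, 2 * lo - x); ws <- c(ws, w) }
    if (is.finite(hi)) { xs <- c(xs, 2 * hi - x); ws <- c(ws, w) }
  }
  d <- density(xs, bw = bw, weights = ws / sum(ws))
  inside <- d$x >= lo & d$x <= hi
  if (!any(inside)) inside <- rep(TRUE, length(d$x))
  d$x[inside][which.max(d$y[inside])]
}

#' Bayes factor from posterior and prior probabilities
#'
#' `B = [p/(1-p)] / [q/(1-q)]` for posterior probability `p` and prior
#' probability `q` of the same hypothesis. Boundary posteriors signal
#' infinite (p = 1) or zero (p = 0) support explicitly.
#'
#' @param posterior_p posterior probability of the hypothesis.
#' @param prior_p prior probability (strictly inside (0, 1)).
#' @return The Bayes factor (possibly `Inf` or 0).
#' @export
bayes_factor <- function(posterior_p, prior_p) {
  if (prior_p <= 0 || prior_p >= 1) {
    stop("prior probability must lie strictly in (0, 1)", call. = FALSE)
  }
  if (posterior_p < 0 || posterior_p > 1) {
    stop("posterior probability must lie in [0, 1]", call. = FALSE)
  }
  if (posterior_p == 1) return(Inf)
  if (posterior_p == 0) return(0)
  (posterior_p / (1 - posterior_p)) / (prior_p / (1 - prior_p))
}

#' Row weights for model-averaged ("mixed") posterior summaries
#'
#' Averaging the posterior across candidate models in proportion to their
#' posterior probabilities is equivalent to weighting each accepted draw
#' from model `z` by `p_z / n_z`, where `n_z` is the number of accepted
#' draws from that model. Summaries (modes, means) of the joint accepted
#' set under these weights match concatenating per-model accepted sets in
#' proportion to `p_z`.
#'
#' @param z vector of model labels for the accepted draws.
#' @param probs named vector of posterior model probabilities.
#' @return Numeric weights, one per draw (rows of absent models get 0).
#' @export
mixed_model_weights <- function(z, probs) {
  z <- as.character(z)
  counts <- table(z)
  w <- numeric(length(z))
  for (m in names(counts)) {
    p <- if (m %in% names(probs)) probs[[m]] else 0
    w[z == m] <- p / counts[[m]]
  }
  w
}

#' Fit the hierarchical ABC posterior
#'
#' Full inference step: unit-variance scaling, rejection sampling,
#' local-linear adjustment of the continuous hyper-parameters and
#' polychotomous regression for the discrete ones, plus posterior
#' summaries (KDE modes, Pr(Psi = k), Pr(Z = z), and the Bayes factor for
#' simultaneous divergence Psi = 1 against Psi > 1).
#'
#' @param table a [simulate_reference_table()] reference table.
#' @param observed observed `ss_` vector (one-row tibble or named vector)
#'   built with the same configuration and statistic selection.
#' @param n_accept number of accepted simulations.
#' @param targets continuous hyper-parameters to adjust.
#' @param discrete discrete columns for polychotomous regression.
#' @param bounds named list of support bounds; defaults truncate `omega`
#'   at 0 and leave `e_tau` on the prior scale.
#' @param prior optional [prior_spec()] used to bound `e_tau` and to form
#'   the prior Pr(Psi = 1) for the Bayes factor; when absent a discrete
#'   uniform prior on 1..Y is assumed.
#' @return An object of class `habc_fit`.
#' @export
abc_fit <- function(table, observed, n_accept = 500,
                    targets = c("e_tau", "omega"),
                    discrete = intersect(c("psi", "z"), names(table)),
                    bounds = NULL, prior = NULL) {
  Y <- attr(table, "Y") %||% max(table$psi)
  if (is.null(bounds)) {
    bounds <- list(omega = c(0, Inf))
    if (!is.null(prior)) bounds$e_tau <- prior$tau_range
  }
  std <- abc_standardize(table, observed)
  post <- abc_reject(std, n_accept)
  post <- abc_adjust_loclinear(post, targets = targets, bounds = bounds)
  disc <- purrr::map(setNames(discrete, discrete), function(cl) {
    lv <- if (cl == "psi") as.character(seq_len(Y)) else
      as.character(sort(unique(table[[cl]])))
    raw <- setNames(numeric(length(lv)), lv)
    rawf <- table(factor(as.character(post$meta[[cl]]), levels = lv))
    raw[lv] <- as.numeric(rawf) / sum(rawf)
    adj <- abc_adjust_polychotomous(post, cl, levels = lv)
    list(raw = raw, adjusted = adj)
  })
  modes <- purrr::map_dbl(setNames(targets, targets), function(tg) {
    posterior_mode(post$adjusted[[tg]], bounds = bounds[[tg]],
                   weights = post$weight)
  })
  pr_psi1_prior <- 1 / Y
  bf_psi1 <- if ("psi" %in% discrete) {
    p1 <- disc$psi$adjusted["1"]
    if (p1 >= 1) Inf else if (p1 <= 0) 0 else
      bayes_factor(p1, pr_psi1_prior)
  } else NA_real_
  structure(list(posterior = post, modes = modes, discrete = disc,
                 bounds = bounds, n_accept = n_accept,
                 bf_psi1 = unname(bf_psi1), Y = Y,
                 targets = targets),
            class = "habc_fit")
}

#' @export
print.habc_fit <- function(x, ...) {
  cat(sprintf("habc_fit: %d accepted of %d simulations\n",
              x$n_accept, x$posterior$n_total))
  for (tg in names(x$modes)) {
    cat(sprintf("  mode %s = %.4g\n", tg, x$modes[[tg]]))
  }
  if ("psi" %in% names(x$discrete)) {
    cat(sprintf("  Pr(Psi = 1 | D) = %.3f (adjusted), B(Psi=1, Psi>1) = %.3g\n",
                x$discrete$psi$adjusted["1"], x$bf_psi1))
  }
  if ("z" %in% names(x$discrete)) {
    pz <- x$discrete$z$adjusted
    cat("  Pr(Z | D):", paste(sprintf("%s = %.3f", names(pz), pz),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname abc_fit
#' @param x an `habc_fit`.
#' @param ... unused.
#' @export
tidy.habc_fit <- function(x, ...) {
  post <- x$posterior
  purrr::map_dfr(x$targets, function(tg) {
    tibble::tibble(term = tg,
                   draw = seq_along(post$dist),
                   raw = post$meta[[tg]],
                   adjusted = post$adjusted[[tg]],
                   distance = post$dist,
                   weight = post$weight)
  })
}

#' @rdname abc_fit
#' @export
glance.habc_fit <- function(x, ...) {
  out <- tibble::tibble(n_total = x$posterior$n_total,
                        n_accept = x$n_accept,
                        max_distance = max(x$posterior$dist))
  for (tg in names(x$modes)) out[[paste0("mode_", tg)]] <- x$modes[[tg]]
  if ("psi" %in% names(x$discrete)) {
    out$pr_psi1 <- unname(x$discrete$psi$adjusted["1"])
    out$bf_psi1 <- x$bf_psi1
  }
  out
}

#' @rdname abc_fit
#' @param object an `habc_fit`.
#' @export
autoplot.habc_fit <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("raw", "adjusted"), names_to = "stage",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$stage)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "hyper-parameter value", y = "accepted draws",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
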