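#' Simulate a genealogy for one taxon-pair locus
#'
#' Backward-in-time structured coalescent for two descendant populations
#' with piecewise-exponential size trajectories (current sizes `theta_b1`,
#' `theta_b2` shrinking back to `theta_a1`, `theta_a2` at the growth-onset
#' times `tau_b1`, `tau_b2`), symmetric migration at rate Nm between the
#' present and the divergence time `tau`, and a single constant-size
#' ancestral population of size `theta_a` beyond `tau`.
#'
#' Time units: a pair of lineages in a reference deme of size
#' `theta_b1 + theta_b2` coalesces at rate 1, and `tau` is interpreted on
#' that scale (4N generations with N the sum of current descendant sizes).
#' This convention is pinned by the property E(pi per site) = theta in the
#' single-population limit.
#'
#' @param params one-row data frame of demographic parameters as produced
#'   by [draw_taxon_params()].
#' @param n1,n2 number of sampled lineages per descendant population
#'   (`n1 + n2 >= 2`).
#' @return An object of class `genealogy`: `parent` (1-based, `NA` at the
#'   root), `time` (node times, tips at 0), `ntip`, and `pops` (tip
#'   population labels, population 1 first).
#' @export
simulate_genealogy <- function(params, n1, n2) {
  stopifnot(n1 + n2 >= 2, n1 >= 0, n2 >= 0)
  p <- as.list(params[1, ])
  res <- .sim_genealogy_cpp(n1, n2, p$tau, p$theta_a, p$theta_a1, p$theta_a2,
                            p$theta_b1, p$theta_b2, p$tau_b1, p$tau_b2, p$nm)
  parent <- res$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(parent = parent, time = res$time, ntip = res$ntip,
                 pops = c(rep(1L, n1), rep(2L, n2))),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("genealogy: %d tips, TMRCA = %.4g\n", x$ntip, max(x$time)))
  invisible(x)
}

#' Time to the most recent common ancestor
#' @param g a `genealogy`.
#' @return The root time.
#' @export
genealogy_tmrca <- function(g) max(g$time)

#' Earliest cross-population coalescence time
#'
#' Time of the first coalescent node ancestral to lineages sampled from
#' both populations; under complete isolation (Nm = 0) this can never
#' precede the divergence time.
#'
#' @param g a `genealogy`.
#' @return The earliest such node time (`Inf` if none exists).
#' @export
cross_coalescence_time <- function(g) {
  n <- length(g$parent)
  has_pop <- matrix(FALSE, n, 2)
  for (i in seq_len(g$ntip)) has_pop[i, g$pops[i]] <- TRUE
  ord <- order(g$time)
  for (v in ord) {
    p <- g$parent[v]
    if (!is.na(p)) has_pop[p, ] <- has_pop[p, ] | has_pop[v, ]
  }
  both <- which(has_pop[, 1] & has_pop[, 2])
  if (length(both) == 0) return(Inf)
  min(g$time[both])
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' @param g a `genealogy`.
#' @return A `phylo` object with branch lengths in coalescent time units.
#' @export
as_phylo_genealogy <- function(g) {
  n <- g$ntip
  nnode <- length(g$parent)
  child <- which(!is.na(g$parent))
  edge_len <- g$time[g$parent[child]] - g$time[child]
  # phylo convention: tips 1..n, root n+1, internals descending from it
  internal <- (n + 1L):nnode
  rank <- integer(nnode)
  rank[seq_len(n)] <- seq_len(n)
  rank[internal[order(g$time[internal], decreasing = TRUE)]] <-
    (n + 1L):nnode
  edge <- cbind(rank[g$parent[child]], rank[child])
  ord <- order(edge[, 1], edge[, 2])
  structure(list(edge = edge[ord, , drop = FALSE],
                 edge.length = edge_len[ord],
                 tip.label = sprintf("pop%d_%d", g$pops,
                                     stats::ave(seq_len(n), g$pops, FUN = seq_along)),
                 Nnode = nnode - n),
            class = "phylo", order = "cladewise")
}

model_code <- function(model) {
  match(model, c("JC", "F81", "HKY")) - 1L
}

#' Overlay finite-sites mutations on a genealogy
#'
#' Substitution events occur along branches as a Poisson process with rate
#' `theta_eff / 2` per site per unit branch time, where
#' `theta_eff = theta_site * rate_scalar * inherit`. Each event replaces the
#' current base using the model's jump distribution (JC: uniform over the
#' other three; F81: proportional to the equilibrium frequencies of the
#' other three; HKY: transitions additionally weighted by kappa). Repeat
#' hits at a site are allowed, so divergence saturates as in any
#' finite-sites model.
#'
#' @param g a `genealogy`.
#' @param L number of sites.
#' @param theta_site per-site theta of the taxon-pair (conventionally
#'   `theta_b1 + theta_b2`).
#' @param model `"JC"`, `"F81"` or `"HKY"`.
#' @param kappa HKY transition/transversion parameter.
#' @param freqs equilibrium base frequencies (A, C, G, T).
#' @param rate_scalar,inherit per-locus relative rate and inheritance
#'   scalars.
#' @param pair_id,locus_id identifiers stored in the result.
#' @return A [locus_alignment()].
#' @export
mutate_sequences <- function(g, L, theta_site, model = "F81", kappa = 2,
                             freqs = rep(0.25, 4), rate_scalar = 1,
                             inherit = 1, pair_id = 1L, locus_id = 1L) {
  stopifnot(L >= 1, theta_site >= 0)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("base frequencies must be non-negative and sum to 1", call. = FALSE)
  }
  mu <- theta_site * rate_scalar * inherit / 2
  parent0 <- ifelse(is.na(g$parent), -1L, g$parent - 1L)
  res <- .mutate_tree_cpp(parent0, g$time, g$ntip, L, mu,
                          model_code(model), kappa, freqs, TRUE)
  seqs <- apply(matrix(DNA_BASES4[res$alignment + 1L], nrow = g$ntip), 1,
                paste, collapse = "")
  locus_alignment(seqs, g$pops, pair_id = pair_id, locus_id = locus_id)
}

#' Simulate a full multi-taxon-pair, multi-locus data set
#'
#' Loci are unlinked: every locus gets an independent genealogy under its
#' pair's demographic parameters (with the pair's assigned divergence time)
#' and an independent mutational overlay with its own rate scalar.
#'
#' @param hyper a [draw_hyper()] draw.
#' @param config the [sampling_config()] the data must match.
#' @return A tibble with columns `pair`, `locus` and a list-column
#'   `alignment` of [locus_alignment()] objects; the `hyper_draw` is
#'   attached as attribute `"hyper"`.
#' @export
simulate_dataset <- function(hyper, config) {
  validate_sampling_config(config)
  Y <- length(unique(config$pair))
  stopifnot(length(hyper$tau) == Y, nrow(hyper$loci) == nrow(config))
  rows <- purrr::map(seq_len(nrow(config)), function(i) {
    r <- config[i, ]
    tp <- hyper$taxa[r$pair, ]
    g <- simulate_genealogy(tp, r$n1, r$n2)
    aln <- mutate_sequences(
      g, r$L, theta_site = tp$theta_b1 + tp$theta_b2,
      model = r$model, kappa = r$kappa,
      freqs = c(r$f_a, r$f_c, r$f_g, r$f_t),
      rate_scalar = hyper$loci$rate_scalar[i], inherit = r$inherit,
      pair_id = r$pair, locus_id = r$locus)
    tibble::tibble(pair = r$pair, locus = r$locus, alignment = list(aln))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "hyper") <- hyper
  out
}
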