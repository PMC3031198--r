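#' Names of the implemented summary-statistic classes
#'
#' Three categories of per-locus statistics are computed from every locus of
#' every taxon-pair: whole-sample ("pool") statistics that treat the pair as
#' one population, within-population statistics for each descendant sample,
#' and between-population statistics. All pi-type and theta_W values are on
#' the per-locus (count) scale. The order returned here is the canonical
#' coordinate order of the summary tensor and of reference-table columns.
#'
#' @return Character vector of class names.
#' @export
ss_classes <- function() {
  c("pi_pool", "pi_1", "pi_2", "pi_b", "pi_net",
    "thw_pool", "thw_1", "thw_2",
    "sdpt_pool", "sdpt_1", "sdpt_2",
    "sh_pool", "sh_1", "sh_2",
    "s_pool", "s_1", "s_2",
    "s_xy", "psi_w")
}

aln_int_matrix <- function(aln) {
  m <- matrix(match(unlist(strsplit(aln$seqs, "", fixed = TRUE)),
                    DNA_BASES4) - 1L,
              nrow = length(aln$seqs), byrow = TRUE)
  if (anyNA(m)) stop("alignment contains non-ACGT symbols", call. = FALSE)
  m
}

hamming_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
  }
  d
}

mean_offdiag <- function(d, idx) {
  k <- length(idx)
  if (k < 2) return(NA_real_)
  sum(d[idx, idx]) / (k * (k - 1))
}

#' Average pairwise-difference statistics for one locus
#'
#' Computes pi (mean number of pairwise differences) for the pooled sample
#' and each descendant population, the total between-population divergence
#' pi_b (mean over all cross-population pairs), and the net divergence
#' pi_net = pi_b - (pi_1 + pi_2) / 2. Within-population values are `NA`
#' (masked) for populations with fewer than two sequences.
#'
#' @param aln a [locus_alignment()] with at least two sequences.
#' @return One-row tibble: `pi_pool`, `pi_1`, `pi_2`, `pi_b`, `pi_net`.
#' @export
pairwise_diff_stats <- function(aln) {
  n <- length(aln$seqs)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  d <- hamming_matrix(aln_int_matrix(aln))
  i1 <- which(aln$pops == 1)
  i2 <- which(aln$pops == 2)
  pi_pool <- mean_offdiag(d, seq_len(n))
  pi_1 <- mean_offdiag(d, i1)
  pi_2 <- mean_offdiag(d, i2)
  pi_b <- if (length(i1) >= 1 && length(i2) >= 1) {
    mean(d[i1, i2, drop = FALSE])
  } else NA_real_
  pi_net <- if (!is.na(pi_1) && !is.na(pi_2) && !is.na(pi_b)) {
    pi_b - (pi_1 + pi_2) / 2
  } else NA_real_
  tibble::tibble(pi_pool = pi_pool, pi_1 = pi_1, pi_2 = pi_2,
                 pi_b = pi_b, pi_net = pi_net)
}

n_segregating <- function(mat) {
  if (nrow(mat) < 2 || ncol(mat) == 0) return(0L)
  sum(matrixStats_colAnyDiff(mat))
}

matrixStats_colAnyDiff <- function(mat) {
  colSums(mat != matrix(mat[1, ], nrow(mat), ncol(mat), byrow = TRUE)) > 0
}

#' Watterson's estimator (per-locus scale)
#'
#' `theta_W = S / a_n` with `S` the number of segregating sites and
#' `a_n = sum_{i=1}^{n-1} 1/i`, on the same per-locus count scale as pi.
#'
#' @param seqs character vector of aligned sequences (n >= 2).
#' @return The estimate, or `NA` if fewer than two sequences.
#' @export
watterson <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(NA_real_)
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  S <- n_segregating(mat)
  S / sum(1 / seq_len(n - 1))
}

tajima_sd_coefficients <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Standard deviation of (pi - theta_W)
#'
#' Uses the Tajima (1989) moment estimator of Var(pi - theta_W),
#' `e1 * S + e2 * S * (S - 1)`, which depends on the data only through the
#' sample size and the number of segregating sites.
#'
#' @param seqs character vector of aligned sequences (n >= 2).
#' @return `sqrt(e1 S + e2 S (S - 1))`, 0 when S = 0, `NA` when n < 2.
#' @export
sd_pi_theta <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(NA_real_)
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  S <- n_segregating(mat)
  if (S == 0) return(0)
  co <- tajima_sd_coefficients(n)
  v <- co$e1 * S + co$e2 * S * (S - 1)
  sqrt(max(v, 0))
}

#' Shannon diversity index on haplotype frequencies
#'
#' Whole sequences are the alleles: `sH = -sum p_i log p_i` over the
#' relative frequencies of distinct haplotypes (natural log).
#'
#' @param seqs character vector of sequences (n >= 1).
#' @return The index (0 for a monomorphic sample).
#' @export
shannon <- function(seqs) {
  if (length(seqs) < 1) stop("need at least one sequence", call. = FALSE)
  p <- table(seqs) / length(seqs)
  -sum(p * log(p))
}

# shared-member moment sums for the within-sample correlation: over all
# ordered pairs of sequence-pairs {(i,j),(i,k)} sharing member i
wakeley_within <- function(d, idx) {
  m <- length(idx)
  if (m < 3) return(NA_real_)
  sub <- d[idx, idx, drop = FALSE]
  rs <- rowSums(sub)
  rs2 <- rowSums(sub^2)
  m11 <- sum(rs^2 - rs2) / (m * (m - 1) * (m - 2))
  m1 <- sum(rs) / (m * (m - 1))
  m2 <- sum(rs2) / (m * (m - 1))
  v <- m2 - m1^2
  if (v > 0) (m11 - m1^2) / v else 0
}

#' Wakeley-style correlations in numbers of pairwise differences
#'
#' Within-sample correlations (`s_1`, `s_2`, `s_pool`) are intraclass
#' correlations of the numbers of pairwise differences over all pairs of
#' sequence-pairs that share exactly one member. The interpopulation
#' statistics consider cross-population pairs sharing one sequence (on
#' either side): `s_xy` normalises the shared-member covariance by the
#' variance of the cross differences (a correlation) and `psi_w` by their
#' mean. Both are symmetric under swapping the population labels and are
#' informative about post-divergence migration, which decouples coalescent
#' times from the divergence time. Statistics undefined at the sample sizes
#' are `NA`; zero-variance (monomorphic) cases return 0.
#'
#' @param aln a [locus_alignment()].
#' @return One-row tibble: `s_1`, `s_2`, `s_pool`, `s_xy`, `psi_w`.
#' @export
wakeley_stats <- function(aln) {
  d <- hamming_matrix(aln_int_matrix(aln))
  i1 <- which(aln$pops == 1)
  i2 <- which(aln$pops == 2)
  n1 <- length(i1); n2 <- length(i2)
  s_xy <- NA_real_; psi_w <- NA_real_
  if (n1 >= 1 && n2 >= 1 && n1 + n2 >= 3) {
    cross <- d[i1, i2, drop = FALSE]
    rs <- rowSums(cross); rs2 <- rowSums(cross^2)
    cs <- colSums(cross); cs2 <- colSums(cross^2)
    nshare <- n1 * n2 * (n1 + n2 - 2)
    m11 <- (sum(rs^2 - rs2) + sum(cs^2 - cs2)) / nshare
    m1 <- mean(cross)
    m2 <- mean(cross^2)
    v <- m2 - m1^2
    cv <- m11 - m1^2
    s_xy <- if (v > 0) cv / v else 0
    psi_w <- if (m1 > 0) cv / m1 else 0
  }
  tibble::tibble(s_1 = wakeley_within(d, i1),
                 s_2 = wakeley_within(d, i2),
                 s_pool = wakeley_within(d, seq_len(n1 + n2)),
                 s_xy = s_xy, psi_w = psi_w)
}

#' All summary-statistic classes for one locus
#'
#' @param aln a [locus_alignment()].
#' @return Named numeric vector over [ss_classes()]; masked statistics are
#'   `NA`.
#' @export
locus_stats <- function(aln) {
  i1 <- aln$pops == 1
  i2 <- aln$pops == 2
  pw <- pairwise_diff_stats(aln)
  wk <- wakeley_stats(aln)
  grp <- function(seqs) {
    n <- length(seqs)
    c(thw = if (n >= 2) watterson(seqs) else NA_real_,
      sdpt = if (n >= 2) sd_pi_theta(seqs) else NA_real_,
      sh = if (n >= 1) shannon(seqs) else NA_real_)
  }
  pool <- grp(aln$seqs)
  g1 <- grp(aln$seqs[i1])
  g2 <- grp(aln$seqs[i2])
  setNames(c(pw$pi_pool, pw$pi_1, pw$pi_2, pw$pi_b, pw$pi_net,
             pool["thw"], g1["thw"], g2["thw"],
             pool["sdpt"], g1["sdpt"], g2["sdpt"],
             pool["sh"], g1["sh"], g2["sh"],
             wk$s_pool, wk$s_1, wk$s_2, wk$s_xy, wk$psi_w),
           ss_classes())
}

#' Assemble the three-dimensional summary tensor D
#'
#' Computes the selected statistic classes for every locus of every
#' taxon-pair. The tensor is ragged in the locus dimension (pairs may have
#' different numbers of loci); masked cells (statistics undefined at a
#' locus's sample sizes) are `NA` and recorded so that simulated vectors
#' mask identically.
#'
#' @param data a tibble with columns `pair`, `locus` and list-column
#'   `alignment` (as from [simulate_dataset()]), or a bare list of
#'   [locus_alignment()] objects.
#' @param classes character vector of class names from [ss_classes()].
#' @return A tibble `class`, `pair`, `locus`, `value` with class
#'   `summary_tensor`; selected classes kept in canonical order.
#' @export
build_summary_tensor <- function(data, classes = c("pi_b", "psi_w")) {
  unknown <- setdiff(classes, ss_classes())
  if (length(unknown) > 0) {
    stop("unknown statistic class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  classes <- intersect(ss_classes(), classes)
  if (!is.data.frame(data)) {
    data <- tibble::tibble(
      pair = vapply(data, function(a) as.integer(a$pair_id), integer(1)),
      locus = vapply(data, function(a) as.integer(a$locus_id), integer(1)),
      alignment = data)
  }
  out <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    st <- locus_stats(data$alignment[[i]])
    tibble::tibble(class = classes, pair = data$pair[i],
                   locus = data$locus[i], value = unname(st[classes]))
  })
  out <- dplyr::arrange(out, .data$class, .data$pair, .data$locus)
  attr(out, "classes") <- classes
  class(out) <- c("summary_tensor", class(tibble::tibble()))
  out
}

#' Reduce the summary tensor to its moment vector D_m
#'
#' For each statistic class and taxon-pair, the raw moments
#' `m_k = mean(value^k)` (k = 1..`n_moments`) are taken across that pair's
#' unmasked loci, collapsing the ragged locus dimension. The taxon-pair
#' slots of every class are then re-ordered jointly by descending first
#' moment of `pi_b` (ties broken by original pair index). Because expected
#' `pi_b` is exchangeable across sampling configurations and tracks each
#' pair's divergence time, this sorting makes the Euclidean distance
#' between vectors independent of the arbitrary input order of the pairs.
#'
#' @param tensor a [build_summary_tensor()] result; must include class
#'   `pi_b`.
#' @param n_moments number of raw moments (1 to 4).
#' @param sort_pairs set `FALSE` to keep the configured pair order (used to
#'   quantify the benefit of sorting).
#' @return A tibble `class`, `slot`, `moment`, `value` of class
#'   `moment_vector`; attribute `"pair_order"` maps slots to original pair
#'   indices.
#' @export
reduce_moments <- function(tensor, n_moments = 4, sort_pairs = TRUE) {
  stopifnot(n_moments >= 1, n_moments <= 4)
  classes <- attr(tensor, "classes") %||% unique(tensor$class)
  if (!"pi_b" %in% classes) {
    stop("the tensor must include class pi_b (required for sorting)",
         call. = FALSE)
  }
  mom <- purrr::map_dfr(seq_len(n_moments), function(k) {
    tensor |>
      dplyr::group_by(.data$class, .data$pair) |>
      dplyr::summarise(
        value = if (all(is.na(.data$value))) NA_real_
                else mean(.data$value[!is.na(.data$value)]^k),
        .groups = "drop") |>
      dplyr::mutate(moment = k)
  })
  bad <- mom |> dplyr::filter(is.na(.data$value), .data$moment == 1)
  if (nrow(bad) > 0) {
    stop("taxon-pair(s) ", paste(unique(bad$pair), collapse = ", "),
         " have no unmasked locus for class(es) ",
         paste(unique(bad$class), collapse = ", "), call. = FALSE)
  }
  pib <- mom |>
    dplyr::filter(.data$class == "pi_b", .data$moment == 1) |>
    dplyr::arrange(.data$pair)
  ord <- if (sort_pairs) order(-pib$value, pib$pair) else seq_len(nrow(pib))
  pair_order <- pib$pair[ord]
  slot_of <- setNames(seq_along(pair_order), pair_order)
  out <- mom |>
    dplyr::mutate(slot = unname(slot_of[as.character(.data$pair)]),
                  class = factor(.data$class, levels = classes)) |>
    dplyr::arrange(.data$class, .data$slot, .data$moment) |>
    dplyr::mutate(class = as.character(.data$class)) |>
    dplyr::select("class", "slot", "moment", "value")
  attr(out, "classes") <- classes
  attr(out, "n_moments") <- n_moments
  attr(out, "pair_order") <- pair_order
  class(out) <- c("moment_vector", class(tibble::tibble()))
  out
}

#' Column names of a flattened moment vector
#'
#' Reference-table layout: class-major, then taxon-pair slot (post-sort),
#' then moment, prefixed `ss_` — e.g. `ss_pi_b.y1.m1`.
#'
#' @param classes statistic classes in canonical order.
#' @param Y number of taxon-pairs.
#' @param n_moments moments per class.
#' @return Character vector of column names.
#' @export
dm_names <- function(classes, Y, n_moments) {
  as.vector(vapply(classes, function(cl) {
    as.vector(vapply(seq_len(Y), function(y) {
      sprintf("ss_%s.y%d.m%d", cl, y, seq_len(n_moments))
    }, character(n_moments)))
  }, character(Y * n_moments)))
}

#' Flatten a moment vector into named reference-table coordinates
#'
#' @param mv a [reduce_moments()] result.
#' @return A one-row tibble whose columns follow [dm_names()].
#' @export
dm_flatten <- function(mv) {
  classes <- attr(mv, "classes")
  n_moments <- attr(mv, "n_moments")
  Y <- max(mv$slot)
  ordered <- mv |>
    dplyr::mutate(class = factor(.data$class, levels = classes)) |>
    dplyr::arrange(.data$class, .data$slot, .data$moment)
  tibble::as_tibble(setNames(as.list(ordered$value),
                             dm_names(classes, Y, n_moments)))
}

#' Observed summary-statistic vector for ABC
#'
#' Convenience wrapper: tensor construction, moment reduction and
#' flattening in one call, for the observed data side of the analysis.
#'
#' @inheritParams build_summary_tensor
#' @inheritParams reduce_moments
#' @return One-row tibble of `ss_` columns aligned with a reference table
#'   built from the same configuration and selection.
#' @export
observed_moment_vector <- function(data, classes = c("pi_b", "psi_w"),
                                   n_moments = 1, sort_pairs = TRUE) {
  mv <- reduce_moments(build_summary_tensor(data, classes),
                       n_moments = n_moments, sort_pairs = sort_pairs)
  out <- dm_flatten(mv)
  # same layout metadata as a reference table, so the observed vector can be
  # written with write_reference_table() and aligned coordinate-by-coordinate
  attr(out, "classes") <- attr(mv, "classes")
  attr(out, "n_moments") <- attr(mv, "n_moments")
  attr(out, "Y") <- max(mv$slot)
  attr(out, "sorted") <- sort_pairs
  out
}
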