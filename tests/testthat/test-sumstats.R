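mk_aln <- function(seqs1, seqs2) {
  locus_alignment(c(seqs1, seqs2),
                  c(rep(1L, length(seqs1)), rep(2L, length(seqs2))))
}

test_that("pairwise-difference statistics match hand-worked examples", {
  a <- mk_aln("AAAA", "AATT")
  s <- pairwise_diff_stats(a)
  expect_equal(s$pi_b, 2)
  expect_true(is.na(s$pi_1) && is.na(s$pi_2))

  # brute force over the 4 cross pairs: distances 2,3,2,3 -> mean 2.5
  b <- mk_aln(c("AAAA", "AAAT"), c("TTAA", "TTAT"))
  s2 <- pairwise_diff_stats(b)
  expect_equal(s2$pi_1, 1)
  expect_equal(s2$pi_2, 1)
  expect_equal(s2$pi_b, 2.5)
  expect_equal(s2$pi_net, 1.5)
  expect_equal(s2$pi_b, brute_pi_b(b$seqs[1:2], b$seqs[3:4]))

  c3 <- mk_aln(c("ACGT", "ACGT"), c("ACGT", "ACGT"))
  s3 <- pairwise_diff_stats(c3)
  expect_true(all(unlist(s3) == 0))
  expect_error(pairwise_diff_stats(locus_alignment("ACGT", 1L)), "two sequences")
})

test_that("Watterson's estimator normalises segregating sites by a_n", {
  expect_equal(watterson(c("AAA", "TTA")), 2)         # n = 2: a_1 = 1
  s4 <- c("AAAAAAAAAAA", "CCCCCCCCCCA", "GGGGGGGGGGA", "AAAAACCCCCA")
  expect_equal(brute_S(s4), 10)
  expect_equal(watterson(s4), 10 / (1 + 1 / 2 + 1 / 3))
  expect_equal(watterson(c("AAA", "AAA", "AAA")), 0)
})

test_that("SD(pi - theta_W) follows the Tajima variance estimator", {
  expect_equal(sd_pi_theta(c("AAAA", "AAAA")), 0)
  set.seed(31)
  for (i in 1:20) {
    aln <- random_alignment(sample(2:5, 1), sample(0:3, 1), L = 15)
    expect_equal(sd_pi_theta(aln$seqs), brute_sd_pi_theta(aln$seqs))
  }
  # depends on the data only through (n, S)
  a <- c("AATT", "AACC", "GGTT")   # same n, S as b
  b <- c("TTAA", "CCAA", "TTGG")
  expect_equal(brute_S(a), brute_S(b))
  expect_equal(sd_pi_theta(a), sd_pi_theta(b))
})

test_that("Shannon index counts whole-haplotype frequencies", {
  expect_equal(shannon(c("ACGT", "ACGA")), log(2))
  expect_equal(shannon(rep("ACGT", 5)), 0)
  expect_equal(shannon(c("AAAA", "CCCC", "GGGG", "TTTT")), log(4))
})

test_that("Wakeley correlations match the literal pairs-of-pairs oracle", {
  set.seed(32)
  aln <- mk_aln(c("ACGTAC", "ACGTTT", "AAATAC"), c("TCGTAC", "TCGGGG", "ACGTAC"))
  w <- wakeley_stats(aln)
  expect_equal(w$s_1, brute_wakeley_within(aln$seqs[1:3]))
  expect_equal(w$s_2, brute_wakeley_within(aln$seqs[4:6]))
  expect_equal(w$s_pool, brute_wakeley_within(aln$seqs))
  bc <- brute_wakeley_cross(aln$seqs[1:3], aln$seqs[4:6])
  expect_equal(w$s_xy, bc$s_xy)
  expect_equal(w$psi_w, bc$psi_w)

  # monomorphic alignments hit the zero-variance rule, not NaN
  mono <- mk_aln(rep("AAAA", 3), rep("AAAA", 3))
  wm <- wakeley_stats(mono)
  expect_equal(unlist(wm), c(s_1 = 0, s_2 = 0, s_pool = 0, s_xy = 0, psi_w = 0))

  # label swap: s_pool, s_xy, psi_w invariant; s_1/s_2 swap
  sw <- locus_alignment(aln$seqs, 3 - aln$pops)
  ws <- wakeley_stats(sw)
  expect_equal(ws$s_pool, w$s_pool)
  expect_equal(ws$s_xy, w$s_xy)
  expect_equal(ws$psi_w, w$psi_w)
  expect_equal(ws$s_1, w$s_2)
  expect_equal(ws$s_2, w$s_1)
})

test_that("every statistic matches brute force on random small alignments", {
  set.seed(33)
  cls <- ss_classes()
  for (rep in 1:200) {
    n1 <- sample(0:5, 1)
    n2 <- sample(max(0, 2 - n1):(8 - n1), 1)
    if (n1 + n2 < 2) n2 <- 2 - n1
    aln <- random_alignment(n1, n2, L = sample(5:25, 1))
    got <- locus_stats(aln)
    s1 <- aln$seqs[aln$pops == 1]
    s2 <- aln$seqs[aln$pops == 2]
    exp_pi_b <- if (n1 >= 1 && n2 >= 1) brute_pi_b(s1, s2) else NA_real_
    exp <- c(
      pi_pool = brute_pi(aln$seqs), pi_1 = brute_pi(s1), pi_2 = brute_pi(s2),
      pi_b = exp_pi_b,
      pi_net = if (n1 >= 2 && n2 >= 2)
        exp_pi_b - (brute_pi(s1) + brute_pi(s2)) / 2 else NA_real_,
      thw_pool = brute_watterson(aln$seqs), thw_1 = brute_watterson(s1),
      thw_2 = brute_watterson(s2),
      sdpt_pool = brute_sd_pi_theta(aln$seqs), sdpt_1 = brute_sd_pi_theta(s1),
      sdpt_2 = brute_sd_pi_theta(s2),
      sh_pool = brute_shannon(aln$seqs),
      sh_1 = if (n1 >= 1) brute_shannon(s1) else NA_real_,
      sh_2 = if (n2 >= 1) brute_shannon(s2) else NA_real_,
      s_pool = brute_wakeley_within(aln$seqs),
      s_1 = brute_wakeley_within(s1), s_2 = brute_wakeley_within(s2),
      s_xy = brute_wakeley_cross(s1, s2)$s_xy,
      psi_w = brute_wakeley_cross(s1, s2)$psi_w)
    expect_equal(got, exp[cls], tolerance = 1e-10)
    # the C++ kernel used in the batch simulator agrees with both
    cpp <- codiverge:::.locus_stats_cpp(
      matrix(match(unlist(strsplit(aln$seqs, "")), c("A", "C", "G", "T")) - 1L,
             nrow = n1 + n2, byrow = TRUE), n1, n2)
    expect_equal(unname(got), as.numeric(cpp), tolerance = 1e-10)
  }
})

test_that("the summary tensor masks consistently and keeps shapes", {
  set.seed(34)
  alns <- list(random_alignment(2, 2, pair_id = 1, locus_id = 1),
               random_alignment(2, 2, pair_id = 1, locus_id = 2),
               random_alignment(1, 1, pair_id = 2, locus_id = 1),
               random_alignment(3, 2, pair_id = 3, locus_id = 1))
  tens <- build_summary_tensor(alns, classes = c("pi_b", "pi_1"))
  expect_equal(nrow(tens), 2 * 4)
  # single individual per descendant population: within-pop classes masked
  expect_true(all(is.na(tens$value[tens$class == "pi_1" & tens$pair == 2])))
  expect_false(anyNA(tens$value[tens$class == "pi_b"]))
  expect_error(build_summary_tensor(alns, classes = "nope"), "unknown")
  tens2 <- build_summary_tensor(alns, classes = c("pi_b", "pi_1"))
  expect_identical(tens, tens2)
})

test_that("moment reduction and pi_b sorting follow the documented algebra", {
  vals <- c(1, 2, 3, 4)
  expect_equal(vapply(1:4, function(k) mean(vals^k), numeric(1)),
               c(2.5, 7.5, 25, 88.5))
  # three pairs with mean pi_b 2, 5, 3 -> slot order pair2, pair3, pair1
  tens <- tibble::tibble(
    class = "pi_b", pair = rep(1:3, each = 2), locus = rep(1:2, 3),
    value = c(1, 3, 4, 6, 2, 4))
  attr(tens, "classes") <- "pi_b"
  mv <- reduce_moments(tens, n_moments = 1)
  expect_equal(attr(mv, "pair_order"), c(2L, 3L, 1L))
  expect_equal(mv$value, c(5, 3, 2))
  # single locus per pair: moment k is value^k
  tens1 <- tibble::tibble(class = "pi_b", pair = 1L, locus = 1L, value = 3)
  attr(tens1, "classes") <- "pi_b"
  mv1 <- reduce_moments(tens1, n_moments = 4)
  expect_equal(mv1$value, c(3, 9, 27, 81))
  # masked pair for a selected class is rejected with the pair id
  tens_bad <- tibble::tibble(class = rep(c("pi_b", "pi_1"), each = 1),
                             pair = 1L, locus = 1L, value = c(2, NA))
  attr(tens_bad, "classes") <- c("pi_b", "pi_1")
  expect_error(reduce_moments(tens_bad), "pair")
})

test_that("D_m is invariant under permutation of the taxon-pair input order", {
  set.seed(35)
  alns <- purrr::map(1:4, function(y)
    purrr::map(1:3, function(l) random_alignment(3, 3, L = 30, pair_id = y,
                                                 locus_id = l)))
  flat <- purrr::flatten(alns)
  perm <- purrr::flatten(alns[c(3, 1, 4, 2)])
  relabel <- purrr::imap(perm, function(a, i) {
    locus_alignment(a$seqs, a$pops, pair_id = (i - 1) %/% 3 + 1,
                    locus_id = (i - 1) %% 3 + 1)
  })
  v1 <- observed_moment_vector(flat, classes = c("pi_b", "psi_w"), n_moments = 2)
  v2 <- observed_moment_vector(relabel, classes = c("pi_b", "psi_w"), n_moments = 2)
  expect_equal(v1, v2)
})

test_that("the net-divergence identity holds on simulated loci", {
  set.seed(36)
  cfg <- sampling_config(config_template(2, 3, n1 = 4, n2 = 3, L = 300))
  prior <- prior_spec(migration_models = tibble::tibble(
    label = c("iso", "mig"), nm_lo = c(0, 0), nm_hi = c(0, 5)))
  ds <- simulate_dataset(draw_hyper(cfg, prior), cfg)
  for (aln in ds$alignment) {
    s <- pairwise_diff_stats(aln)
    expect_equal(s$pi_net, s$pi_b - (s$pi_1 + s$pi_2) / 2)
  }
})
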