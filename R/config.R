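#' Sampling configuration for a multi-taxon-pair, multi-locus study
#'
#' The sampling configuration records, for every locus of every taxon-pair,
#' the sample sizes drawn from the two descendant populations, the alignment
#' length, the inheritance scalar (a unitless multiplier on the locus theta,
#' e.g. 0.25 for mtDNA in a diploid nuclear study), an optional fixed
#' relative substitution rate, and the substitution model. Simulated data
#' sets always match this configuration exactly, locus by locus, so that
#' observed and simulated summary-statistic vectors align coordinate by
#' coordinate.
#'
#' @param pair integer taxon-pair index (1-based, consecutive).
#' @param locus integer locus index within the pair (1-based, consecutive).
#' @param n1,n2 sample sizes from descendant populations 1 and 2.
#' @param L alignment length in base pairs.
#' @param inherit inheritance scalar (> 0).
#' @param rate_fixed optional fixed relative substitution rate (NA to draw
#'   rate scalars from the gamma hyper-prior instead).
#' @param model substitution model, one of `"JC"`, `"F81"`, `"HKY"`.
#' @param kappa HKY transition/transversion parameter (ignored otherwise).
#' @param f_a,f_c,f_g,f_t equilibrium base frequencies (must sum to 1; all
#'   0.25 under JC).
#' @return A tibble with one row per locus, validated; class
#'   `sampling_config`.
#' @examples
#' cfg <- sampling_config(config_template(Y = 2, n_loci = 3))
#' @export
sampling_config <- function(pair, locus = NULL, n1 = NULL, n2 = NULL, L = NULL,
                            inherit = 1, rate_fixed = NA_real_,
                            model = "F81", kappa = 2,
                            f_a = 0.25, f_c = 0.25, f_g = 0.25, f_t = 0.25) {
  cfg <- if (is.data.frame(pair)) {
    tibble::as_tibble(pair)
  } else {
    tibble::tibble(pair = pair, locus = locus, n1 = n1, n2 = n2, L = L,
                   inherit = inherit, rate_fixed = rate_fixed, model = model,
                   kappa = kappa, f_a = f_a, f_c = f_c, f_g = f_g, f_t = f_t)
  }
  defaults <- list(inherit = 1, rate_fixed = NA_real_, model = "F81",
                   kappa = 2, f_a = 0.25, f_c = 0.25, f_g = 0.25, f_t = 0.25)
  for (nm in names(defaults)) {
    if (!nm %in% names(cfg)) cfg[[nm]] <- defaults[[nm]]
  }
  cfg <- dplyr::arrange(cfg, .data$pair, .data$locus)
  validate_sampling_config(cfg)
  class(cfg) <- c("sampling_config", class(tibble::tibble()))
  cfg
}

validate_sampling_config <- function(cfg) {
  req <- c("pair", "locus", "n1", "n2", "L", "inherit", "rate_fixed",
           "model", "kappa", "f_a", "f_c", "f_g", "f_t")
  missing_cols <- setdiff(req, names(cfg))
  if (length(missing_cols) > 0) {
    stop("sampling configuration is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  Y <- length(unique(cfg$pair))
  if (Y < 1 || !all(sort(unique(cfg$pair)) == seq_len(Y))) {
    stop("taxon-pair indices must be consecutive integers starting at 1",
         call. = FALSE)
  }
  if (any(cfg$n1 < 1) || any(cfg$n2 < 1) || any(cfg$L < 1)) {
    stop("every locus needs n1 >= 1, n2 >= 1 and L >= 1", call. = FALSE)
  }
  if (any(cfg$inherit <= 0)) stop("inheritance scalars must be > 0", call. = FALSE)
  if (!all(cfg$model %in% c("JC", "F81", "HKY"))) {
    stop("substitution model must be one of JC, F81, HKY", call. = FALSE)
  }
  fr <- as.matrix(cfg[, c("f_a", "f_c", "f_g", "f_t")])
  if (any(fr < 0) || any(abs(rowSums(fr) - 1) > 1e-9)) {
    stop("base frequencies must be non-negative and sum to 1", call. = FALSE)
  }
  jc <- cfg$model == "JC"
  if (any(jc) && any(abs(fr[jc, , drop = FALSE] - 0.25) > 1e-9)) {
    stop("JC loci must have equal base frequencies (0.25 each)", call. = FALSE)
  }
  invisible(cfg)
}

#' Build a regular sampling configuration
#'
#' Convenience generator for configurations in which every taxon-pair has
#' the same number of loci and sample sizes; `n1`/`n2` may be vectors of
#' length `Y` to vary sample sizes across pairs.
#'
#' @param Y number of taxon-pairs.
#' @param n_loci loci per pair (scalar or length-`Y`).
#' @param n1,n2 per-population sample sizes (scalar or length-`Y`).
#' @param L alignment length in base pairs.
#' @inheritParams sampling_config
#' @return A tibble suitable for [sampling_config()].
#' @export
config_template <- function(Y, n_loci, n1 = 5, n2 = 5, L = 1100,
                            inherit = 1, model = "F81", kappa = 2) {
  n_loci <- rep_len(n_loci, Y)
  n1 <- rep_len(n1, Y)
  n2 <- rep_len(n2, Y)
  purrr::map_dfr(seq_len(Y), function(y) {
    tibble::tibble(pair = y, locus = seq_len(n_loci[y]), n1 = n1[y],
                   n2 = n2[y], L = L, inherit = inherit,
                   rate_fixed = NA_real_, model = model, kappa = kappa,
                   f_a = 0.25, f_c = 0.25, f_g = 0.25, f_t = 0.25)
  })
}

#' Hyper-prior specification
#'
#' Bounds of the uniform priors and hyper-priors of the hierarchical model.
#' Divergence times tau are in coalescent units of 4N generations, where N
#' is the sum of the current effective sizes of the two descendant
#' populations; theta values are per-site (4N mu). Descendant sizes at the
#' split and growth-onset times are parameterised as uniform fractions of
#' theta_A and tau respectively, which guarantees tau_B <= tau.
#'
#' @param tau_range uniform bounds on tau.
#' @param theta_a_range uniform bounds on the ancestral per-site theta.
#' @param theta_b_range uniform bounds on each current descendant theta
#'   (theta_B1, theta_B2 drawn independently).
#' @param size_frac_range bounds of the uniform fraction theta_Ai / theta_A.
#' @param time_frac_range bounds of the uniform fraction tau_Bi / tau.
#' @param migration_models data frame with columns `label`, `nm_lo`,
#'   `nm_hi`: the candidate migration models; `nm_lo = nm_hi = 0` encodes
#'   the isolation model. Each simulated data set picks one model uniformly
#'   at random and draws per-pair Nm from its range.
#' @param alpha_range bounds of the uniform hyper-prior on the gamma shape
#'   of the across-locus rate-scalar distribution (default 1-20; the scale
#'   is 1/alpha so the mean rate scalar is always 1).
#' @param rate_het logical; if `FALSE` all rate scalars are 1.
#' @param psi_fixed optional integer constraining Psi, the number of
#'   distinct divergence times.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(tau_range = c(0, 5),
                       theta_a_range = c(1e-4, 0.01),
                       theta_b_range = c(1e-4, 0.01),
                       size_frac_range = c(0, 1),
                       time_frac_range = c(0, 1),
                       migration_models = tibble::tibble(
                         label = "isolation", nm_lo = 0, nm_hi = 0),
                       alpha_range = c(1, 20),
                       rate_het = TRUE,
                       psi_fixed = NULL) {
  migration_models <- tibble::as_tibble(migration_models)
  stopifnot(all(c("label", "nm_lo", "nm_hi") %in% names(migration_models)),
            nrow(migration_models) >= 1)
  ranges <- list(tau_range = tau_range, theta_a_range = theta_a_range,
                 theta_b_range = theta_b_range,
                 size_frac_range = size_frac_range,
                 time_frac_range = time_frac_range, alpha_range = alpha_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0) {
      stop(nm, " must be (lo, hi) with 0 <= lo <= hi", call. = FALSE)
    }
  }
  if (any(migration_models$nm_lo > migration_models$nm_hi) ||
      any(migration_models$nm_lo < 0)) {
    stop("migration model Nm ranges must satisfy 0 <= lo <= hi", call. = FALSE)
  }
  structure(c(ranges, list(migration_models = migration_models,
                           rate_het = isTRUE(rate_het),
                           psi_fixed = psi_fixed)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Hierarchical prior specification\n")
  cat(sprintf("  tau ~ U(%g, %g)  (units of 4N generations)\n",
              x$tau_range[1], x$tau_range[2]))
  cat(sprintf("  theta_A ~ U(%g, %g); theta_B ~ U(%g, %g) per site\n",
              x$theta_a_range[1], x$theta_a_range[2],
              x$theta_b_range[1], x$theta_b_range[2]))
  cat(sprintf("  rate heterogeneity: %s (alpha ~ U(%g, %g))\n",
              if (x$rate_het) "on" else "off",
              x$alpha_range[1], x$alpha_range[2]))
  cat(sprintf("  %d migration model(s): %s\n",
              nrow(x$migration_models),
              paste(x$migration_models$label, collapse = ", ")))
  if (!is.null(x$psi_fixed)) cat(sprintf("  Psi fixed at %d\n", x$psi_fixed))
  invisible(x)
}

#' Aligned sequences for one locus of one taxon-pair
#'
#' @param seqs character vector of equal-length sequences over `ACGT`.
#' @param pops integer vector of population labels (1 or 2), one per
#'   sequence.
#' @param pair_id,locus_id identifiers carried along for error messages.
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, pops, pair_id = 1L, locus_id = 1L) {
  seqs <- unname(toupper(seqs))
  if (length(seqs) < 1) stop("alignment needs at least one sequence", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1) {
    stop(sprintf("pair %s locus %s: sequences differ in length",
                 pair_id, locus_id), call. = FALSE)
  }
  if (length(pops) != length(seqs) || !all(pops %in% c(1L, 2L))) {
    stop("population labels must be 1 or 2, one per sequence", call. = FALSE)
  }
  structure(list(seqs = seqs, pops = as.integer(pops),
                 pair_id = pair_id, locus_id = locus_id),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus_alignment: pair %s locus %s, %d + %d sequences, %d bp\n",
              x$pair_id, x$locus_id, sum(x$pops == 1), sum(x$pops == 2),
              nchar(x$seqs[1])))
  invisible(x)
}

# character matrix view of an alignment (rows = sequences)
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

# drop columns containing anything outside ACGT (gaps, ambiguity codes);
# finite-sites statistics need complete columns
filter_acgt_columns <- function(mat) {
  ok <- colSums(!matrix(mat %in% DNA_BASES4, nrow(mat))) == 0
  mat[, ok, drop = FALSE]
}

#' Parse per-locus FASTA files for one taxon-pair
#'
#' Population membership is read from the description line, which must
#' contain a `pop=1` or `pop=2` tag (this package's own FASTA dialect).
#' Columns containing gaps or ambiguity codes in any sequence are dropped
#' list-wise and the locus length is reduced accordingly.
#'
#' @param paths character vector of FASTA paths, one per locus, in locus
#'   order.
#' @param pair_id taxon-pair index.
#' @param config optional [sampling_config()]; when given, per-locus sample
#'   sizes are checked against it.
#' @return A list of [locus_alignment()] objects.
#' @examples
#' fa <- system.file("extdata", "example_locus.fasta", package = "codiverge")
#' parse_fasta_pair(fa)[[1]]
#' @export
parse_fasta_pair <- function(paths, pair_id = 1L, config = NULL) {
  purrr::imap(paths, function(path, locus_id) {
    dna <- ape::read.FASTA(path)
    if (length(dna) == 0) stop("no FASTA records in ", path, call. = FALSE)
    headers <- names(dna)
    m <- regmatches(headers, regexpr("pop=[12]", headers))
    if (length(m) != length(headers)) {
      stop(sprintf("pair %s locus %s: every FASTA header needs a pop=1|2 tag",
                   pair_id, locus_id), call. = FALSE)
    }
    pops <- as.integer(sub("pop=", "", m))
    lens <- lengths(dna)
    if (length(unique(lens)) != 1) {
      stop(sprintf("pair %s locus %s: sequences differ in length",
                   pair_id, locus_id), call. = FALSE)
    }
    mat <- toupper(do.call(rbind, as.character(dna)))
    mat <- filter_acgt_columns(mat)
    aln <- locus_alignment(apply(mat, 1, paste, collapse = ""), pops,
                           pair_id = pair_id, locus_id = locus_id)
    if (!is.null(config)) {
      row <- dplyr::filter(config, .data$pair == pair_id,
                           .data$locus == locus_id)
      if (nrow(row) != 1) {
        stop(sprintf("pair %s locus %s not present in the configuration",
                     pair_id, locus_id), call. = FALSE)
      }
      if (sum(pops == 1) != row$n1 || sum(pops == 2) != row$n2) {
        stop(sprintf(
          "pair %s locus %s: sample sizes %d + %d do not match configuration %d + %d",
          pair_id, locus_id, sum(pops == 1), sum(pops == 2), row$n1, row$n2),
          call. = FALSE)
      }
    }
    aln
  })
}

#' Write alignments as FASTA (pop= dialect)
#'
#' @param alignments list of [locus_alignment()] objects.
#' @param paths output paths, one per locus.
#' @export
write_fasta_pair <- function(alignments, paths) {
  stopifnot(length(alignments) == length(paths))
  purrr::walk2(alignments, paths, function(aln, path) {
    idx <- stats::ave(seq_along(aln$pops), aln$pops, FUN = seq_along)
    hdr <- sprintf(">seq%d_%d pop=%d", aln$pops, idx, aln$pops)
    writeLines(as.vector(rbind(hdr, aln$seqs)), path)
  })
  invisible(paths)
}

im_model_map <- c(I = "JC", J = "JC", F = "F81", H = "HKY")

#' Parse an IM-format input file
#'
#' Reads the classic IM layout: a title line, a line naming the two
#' populations, the number of loci, then for each locus a header line
#' (`name n1 n2 length inheritance-scalar model-code`) followed by the
#' `n1 + n2` sequences (population 1 first). Model codes `I`/`J` map to JC,
#' `F` to F81 and `H` to HKY.
#'
#' @param path path to the IM file.
#' @param pair_id taxon-pair index attached to the parsed loci.
#' @return A list with elements `config` (a per-locus tibble fragment) and
#'   `alignments` (a list of [locus_alignment()]).
#' @examples
#' im <- parse_im(system.file("extdata", "example_pair.im", package = "codiverge"))
#' im$config
#' @export
parse_im <- function(path, pair_id = 1L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 3) stop("truncated IM file: missing header", call. = FALSE)
  n_loci <- suppressWarnings(as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]][1]))
  if (is.na(n_loci) || n_loci < 1) {
    stop("IM file: third line must give the number of loci", call. = FALSE)
  }
  cursor <- 4L
  alns <- vector("list", n_loci)
  cfg <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    if (cursor > length(lines)) {
      stop(sprintf("truncated IM file: locus %d of %d missing", l, n_loci),
           call. = FALSE)
    }
    toks <- strsplit(trimws(lines[cursor]), "\\s+")[[1]]
    if (length(toks) < 6) {
      stop(sprintf("locus %d: header needs 'name n1 n2 length scalar model'", l),
           call. = FALSE)
    }
    n1 <- as.integer(toks[2]); n2 <- as.integer(toks[3])
    L <- as.integer(toks[4]); inherit <- as.numeric(toks[5])
    code <- toupper(toks[6])
    if (!code %in% names(im_model_map)) {
      stop(sprintf("locus %d (%s): unknown mutation model code '%s'",
                   l, toks[1], toks[6]), call. = FALSE)
    }
    n_seq <- n1 + n2
    if (cursor + n_seq > length(lines)) {
      stop(sprintf("truncated IM file: locus %d (%s) has fewer than %d sequences",
                   l, toks[1], n_seq), call. = FALSE)
    }
    seq_lines <- lines[(cursor + 1L):(cursor + n_seq)]
    seqs <- vapply(seq_lines, function(ln) {
      if (grepl("\\s", trimws(ln))) {
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        paste(parts[-1], collapse = "")
      } else {
        substring(ln, 11L)
      }
    }, character(1), USE.NAMES = FALSE)
    seqs <- toupper(seqs)
    if (length(unique(nchar(seqs))) != 1) {
      stop(sprintf("locus %d (%s): sequences differ in length", l, toks[1]),
           call. = FALSE)
    }
    mat <- filter_acgt_columns(do.call(rbind, strsplit(seqs, "", fixed = TRUE)))
    alns[[l]] <- locus_alignment(apply(mat, 1, paste, collapse = ""),
                                 c(rep(1L, n1), rep(2L, n2)),
                                 pair_id = pair_id, locus_id = l)
    cfg[[l]] <- tibble::tibble(pair = pair_id, locus = l, n1 = n1, n2 = n2,
                               L = ncol(mat), inherit = inherit,
                               rate_fixed = NA_real_,
                               model = unname(im_model_map[code]), kappa = 2,
                               f_a = 0.25, f_c = 0.25, f_g = 0.25, f_t = 0.25)
    cursor <- cursor + n_seq + 1L
  }
  list(config = dplyr::bind_rows(cfg), alignments = alns)
}

#' Write / read the run configuration file
#'
#' A flat `key = value` text format holding the sampling configuration and
#' the hyper-prior bounds, so a whole analysis is reproducible from one
#' file.
#'
#' @param config a [sampling_config()] tibble.
#' @param prior a [prior_spec()].
#' @param path output path.
#' @return `read_run_config()` returns `list(config, prior)`.
#' @export
write_run_config <- function(config, prior, path) {
  validate_sampling_config(config)
  fmt_range <- function(r) paste(format(r, digits = 17), collapse = " ")
  lines <- c(
    sprintf("n_pairs = %d", length(unique(config$pair))),
    sprintf("tau = %s", fmt_range(prior$tau_range)),
    sprintf("theta_a = %s", fmt_range(prior$theta_a_range)),
    sprintf("theta_b = %s", fmt_range(prior$theta_b_range)),
    sprintf("size_frac = %s", fmt_range(prior$size_frac_range)),
    sprintf("time_frac = %s", fmt_range(prior$time_frac_range)),
    sprintf("alpha = %s", fmt_range(prior$alpha_range)),
    sprintf("rate_het = %s", tolower(prior$rate_het)),
    if (!is.null(prior$psi_fixed)) sprintf("psi_fixed = %d", prior$psi_fixed),
    sprintf("migration_model = %s %s %s", prior$migration_models$label,
            format(prior$migration_models$nm_lo, digits = 17),
            format(prior$migration_models$nm_hi, digits = 17)),
    vapply(seq_len(nrow(config)), function(i) {
      r <- config[i, ]
      sprintf("locus = %d %d %d %d %d %s %s %s %s %s %s %s %s",
              r$pair, r$locus, r$n1, r$n2, r$L,
              format(r$inherit, digits = 17),
              if (is.na(r$rate_fixed)) "NA" else format(r$rate_fixed, digits = 17),
              r$model, format(r$kappa, digits = 17),
              format(r$f_a, digits = 17), format(r$f_c, digits = 17),
              format(r$f_g, digits = 17), format(r$f_t, digits = 17))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  get1 <- function(key) vals[match(key, keys)]
  get_range <- function(key) as.numeric(strsplit(get1(key), "\\s+")[[1]])
  mm <- strsplit(vals[keys == "migration_model"], "\\s+")
  migration_models <- tibble::tibble(
    label = vapply(mm, `[`, character(1), 1),
    nm_lo = as.numeric(vapply(mm, `[`, character(1), 2)),
    nm_hi = as.numeric(vapply(mm, `[`, character(1), 3)))
  psi_fixed <- if ("psi_fixed" %in% keys) as.integer(get1("psi_fixed")) else NULL
  prior <- prior_spec(tau_range = get_range("tau"),
                      theta_a_range = get_range("theta_a"),
                      theta_b_range = get_range("theta_b"),
                      size_frac_range = get_range("size_frac"),
                      time_frac_range = get_range("time_frac"),
                      migration_models = migration_models,
                      alpha_range = get_range("alpha"),
                      rate_het = identical(get1("rate_het"), "true"),
                      psi_fixed = psi_fixed)
  loc <- strsplit(vals[keys == "locus"], "\\s+")
  config <- purrr::map_dfr(loc, function(tk) {
    tibble::tibble(pair = as.integer(tk[1]), locus = as.integer(tk[2]),
                   n1 = as.integer(tk[3]), n2 = as.integer(tk[4]),
                   L = as.integer(tk[5]), inherit = as.numeric(tk[6]),
                   rate_fixed = if (tk[7] == "NA") NA_real_ else as.numeric(tk[7]),
                   model = tk[8], kappa = as.numeric(tk[9]),
                   f_a = as.numeric(tk[10]), f_c = as.numeric(tk[11]),
                   f_g = as.numeric(tk[12]), f_t = as.numeric(tk[13]))
  })
  list(config = sampling_config(config), prior = prior)
}
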