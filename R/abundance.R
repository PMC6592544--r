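# Abundance-aware enrichment test. The neighbor count d is replaced by the
# sum of transformed read counts over neighbors, s = sum_i f(c_i); under the
# null the abundances are exchangeable draws from the empirical distribution
# of transformed counts, so P(s | d) is the d-fold convolution of that
# distribution and P(s | sigma) = sum_d P(s | d) P(d | sigma) with P(d | sigma)
# the Poisson null of the basic test.

ABUNDANCE_TRANSFORMS <- list(
  indicator = function(c) rep(1, length(c)),
  identity = function(c) as.numeric(c),
  log = function(c) {
    if (any(c < 1)) stopf("log transform requires read counts >= 1")
    log(c)
  }
)

#' Empirical distribution of transformed clonotype abundances
#'
#' Histogram of `f(read_count)` over all clonotypes eligible as neighbors
#' (read count at least `min_neighbor_reads`), pooled over the whole sample
#' and computed once per repertoire. Values are snapped to a fixed-width grid
#' so that repeated convolution is an exact discrete operation: bin `j`
#' holds values rounding to `j * bin_width`.
#'
#' @param rep a [tcr_repertoire].
#' @param transform `"log"` (default, appropriate for the power-law clone
#'   sizes of real repertoires), `"identity"`, or `"indicator"`
#'   (`f(c) = 1`, which recovers the basic neighbor-count test).
#' @param bin_width grid resolution in transformed units (default 0.1 natural
#'   log units; forced to 1 for the indicator and identity transforms, whose
#'   values are integers).
#' @param min_neighbor_reads neighbor eligibility filter (default 2).
#' @return object of class `abundance_distribution`: list with `transform`,
#'   `bin_width`, `offset` (index of the first bin), `probs` (probability
#'   vector over consecutive bins).
#' @export
abundance_distribution <- function(rep, transform = c("log", "identity", "indicator"),
                                   bin_width = 0.1, min_neighbor_reads = 2L) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  transform <- match.arg(transform)
  counts <- rep$clonotypes$read_count
  counts <- counts[counts >= min_neighbor_reads]
  if (length(counts) == 0L) stopf("no neighbor-eligible clonotypes in the repertoire")
  if (transform %in% c("indicator", "identity")) bin_width <- 1
  v <- ABUNDANCE_TRANSFORMS[[transform]](counts)
  idx <- as.integer(round(v / bin_width))
  rng <- range(idx)
  probs <- tabulate(idx - rng[1L] + 1L, nbins = rng[2L] - rng[1L] + 1L) / length(idx)
  structure(list(transform = transform, bin_width = bin_width,
                 offset = rng[1L], probs = probs),
            class = "abundance_distribution")
}

# transformed count snapped to the distribution's grid, in index units
abundance_index <- function(pf, counts) {
  as.integer(round(ABUNDANCE_TRANSFORMS[[pf$transform]](counts) / pf$bin_width))
}

# exact discrete convolution of two probability vectors
conv1 <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (j in seq_along(b)) {
    if (b[j] != 0) out[j:(j + length(a) - 1L)] <- out[j:(j + length(a) - 1L)] + a * b[j]
  }
  out
}

#' Convolve the abundance null up to d_max neighbors
#'
#' Builds `P(s | d)` for `d = 0 .. d_max` by iterated discrete convolution of
#' the transformed-abundance distribution on its grid; `P(s | 0)` is a point
#' mass at 0.
#'
#' @param pf an [abundance_distribution].
#' @param d_max largest neighbor count to cover (>= 1).
#' @return object of class `convolved_null`: list with `bin_width`,
#'   `d_max`, and `dists`, a list of `d_max + 1` elements, each a list
#'   `(offset, probs)` on the shared index grid.
#' @export
convolve_null <- function(pf, d_max) {
  stopifnot(inherits(pf, "abundance_distribution"))
  if (d_max < 1) stopf("d_max must be >= 1")
  d_max <- as.integer(d_max)
  dists <- vector("list", d_max + 1L)
  dists[[1L]] <- list(offset = 0L, probs = 1)
  cur <- list(offset = pf$offset, probs = pf$probs)
  dists[[2L]] <- cur
  if (d_max >= 2L) for (d in 2:d_max) {
    cur <- list(offset = cur$offset + pf$offset, probs = conv1(cur$probs, pf$probs))
    dists[[d + 1L]] <- cur
  }
  structure(list(bin_width = pf$bin_width, d_max = d_max,
                 transform = pf$transform, dists = dists),
            class = "convolved_null")
}

# tail mass P(s >= k_obs | d) in index units
conv_tail <- function(null, d, k_obs) {
  dd <- null$dists[[d + 1L]]
  first <- k_obs - dd$offset + 1L
  if (first <= 1L) return(sum(dd$probs))
  if (first > length(dd$probs)) return(0)
  sum(dd$probs[first:length(dd$probs)])
}

# d_max needed so the Poisson tail mass beyond it is < 1e-12
required_d_max <- function(lambda_max, d_floor = 1L) {
  max(d_floor, stats::qpois(1e-12, lambda_max, lower.tail = FALSE) + 1L)
}

#' Upper-tail p-value of the abundance statistic
#'
#' `P(s >= s_obs | sigma)` under the Poisson-mixture of convolutions
#' `P(s | sigma) = sum_d P(s | d) P(d | sigma)` with `P(d | sigma)` the
#' Poisson(`lambda`) null. The Poisson mass beyond the covered `d_max` is
#' counted as exceeding (conservative); `convolve_null` should cover d up to
#' where that mass is below 1e-12 (see the `d_max` handling in
#' [run_abundance_enrichment]).
#'
#' @param s_obs observed sum of transformed abundances.
#' @param lambda Poisson null mean for the neighbor count.
#' @param null a [convolve_null] result.
#' @return the p-value.
#' @export
abundance_pvalue <- function(s_obs, lambda, null) {
  stopifnot(inherits(null, "convolved_null"))
  if (lambda < 0) stopf("lambda must be non-negative")
  if (s_obs <= 0) return(1)
  if (lambda == 0) return(0)
  k_obs <- as.integer(ceiling(s_obs / null$bin_width - 1e-9))
  d <- 0:null$d_max
  w <- stats::dpois(d, lambda)
  tails <- vapply(d, function(dd) conv_tail(null, dd, k_obs), 0)
  p <- sum(w * tails) + stats::ppois(null$d_max, lambda, lower.tail = FALSE)
  # as in the basic test, a positive tail that underflows is floored at the
  # smallest positive double rather than reported as exactly 0; rounding in
  # the mixture sum may also overshoot 1 by an ulp
  min(max(p, .Machine$double.xmin), 1)
}

#' Run the abundance-aware enrichment test
#'
#' Identical pipeline to [run_neighbor_enrichment] (same gating, same Poisson
#' neighbor-count null, same zero-neighborhood discard, BH correction and
#' threshold), but the test statistic is `s = sum_i f(c_i)` over neighbors
#' instead of the neighbor count `d`. With the indicator transform
#' (`f(c) = 1`) the statistic reduces to `s = d` and the mixture tail
#' collapses analytically to the Poisson survival function, so results are
#' identical to the basic test.
#'
#' @inheritParams run_neighbor_enrichment
#' @param transform `"log"` (default), `"identity"`, or `"indicator"`.
#' @param bin_width abundance grid resolution (see [abundance_distribution]).
#' @return an `enrichment_result` with additional column `s_obs`; the
#'   transform is stored in the `"transform"` attribute.
#' @export
run_abundance_enrichment <- function(rep, model, cfg = enrichment_config(),
                                     transform = c("log", "identity", "indicator"),
                                     bin_width = 0.1, pgen_tables = NULL,
                                     sim_length_counts = NULL) {
  stopifnot(inherits(rep, "tcr_repertoire"), inherits(model, "gen_model"),
            inherits(cfg, "enrichment_config"))
  transform <- match.arg(transform)
  rep <- collapse_clonotypes(rep)
  pf <- abundance_distribution(rep, transform = transform, bin_width = bin_width,
                               min_neighbor_reads = cfg$min_neighbor_reads)
  classes <- partition_vj(rep)
  rows <- list()
  neighbor_tables <- list()
  for (key in names(classes)) {
    cls <- classes[[key]]
    vals <- abundance_index(pf, cls$clonotypes$read_count)
    dtab <- neighbor_counts(cls, min_reads = cfg$min_neighbor_reads, values = vals)
    neighbor_tables[[key]] <- dtab
    gated <- dtab[d_obs > cfg$d_gate]
    if (nrow(gated) == 0L) next
    ptab <- pgen_tables[[key]]
    if (is.null(ptab)) {
      ptab <- build_pgen_table(model, c(cls$v_gene, cls$j_gene),
                               n_sim = cfg$n_sim,
                               seed = derive_seed(cfg$seed, match(key, names(classes))),
                               normalize_productive = cfg$normalize_productive)
    }
    q_l <- NULL
    if (cfg$use_length_dependent_q) {
      sim_len <- sim_length_counts[[key]] %||% ptab$lengths
      q_l <- length_dependent_q(class_length_counts(cls), sim_len, cfg$q,
                                cfg$length_pseudocount)
    }
    nb <- vapply(gated$sigma, function(s) neighborhood_pgen(ptab, s), 0)
    lam <- vapply(seq_len(nrow(gated)), function(i) {
      null_lambda(cls, gated$sigma[i], ptab, cfg, q_l = q_l)
    }, 0)
    rows[[key]] <- data.table::data.table(
      sigma = gated$sigma, v_gene = cls$v_gene, j_gene = cls$j_gene,
      n_class = cls$n, d_obs = gated$d_obs,
      s_idx = gated$s_sum, nb_pgen = unname(nb), lambda = unname(lam))
  }
  empty <- data.table::data.table(
    sigma = character(), v_gene = character(), j_gene = character(),
    n_class = integer(), d_obs = integer(), s_obs = numeric(),
    nb_pgen = numeric(), lambda = numeric(), p_raw = numeric(),
    p_adj = numeric(), tested = logical(), zero_neighborhood = logical(),
    significant = logical())
  if (length(rows) == 0L) {
    res <- finalize_result(empty, cfg, neighbor_tables, rep$sample_id)
    data.table::setattr(res, "transform", transform)
    return(res)
  }
  res <- data.table::rbindlist(rows)
  res[, s_obs := s_idx * pf$bin_width]
  res[, s_idx := NULL]
  res[, zero_neighborhood := nb_pgen == 0]
  res[, tested := !zero_neighborhood]
  res[, p_raw := NA_real_]
  if (transform == "indicator") {
    # s = d exactly; the mixture tail is the Poisson survival function
    res[tested == TRUE, p_raw := poisson_pvalue(d_obs, lambda)]
  } else {
    lam_max <- max(res$lambda[res$tested], 0)
    null <- convolve_null(pf, required_d_max(lam_max, d_floor = max(res$d_obs)))
    res[tested == TRUE,
        p_raw := vapply(seq_len(.N), function(i) {
          abundance_pvalue(s_obs[i], lambda[i], null)
        }, 0)]
  }
  res[, p_adj := NA_real_]
  if (cfg$bh_scope == "global") {
    res[tested == TRUE, p_adj := bh_adjust(p_raw)]
  } else {
    res[tested == TRUE, p_adj := bh_adjust(p_raw), by = .(v_gene, j_gene)]
  }
  res[, significant := !is.na(p_adj) & p_adj < cfg$alpha]
  data.table::setcolorder(res, c("sigma", "v_gene", "j_gene", "n_class",
                                 "d_obs", "s_obs", "nb_pgen", "lambda",
                                 "p_raw", "p_adj", "tested",
                                 "zero_neighborhood", "significant"))
  res <- finalize_result(res, cfg, neighbor_tables, rep$sample_id)
  data.table::setattr(res, "transform", transform)
  res
}
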