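# The neighbor-enrichment test: observed neighbor counts per amino-acid CDR3,
# Poisson null mean from the recombination model, raw and BH-adjusted
# p-values, pipeline filters, and the naive d/n-threshold baseline.

#' Configuration for the enrichment pipeline
#'
#' @param q scalar selection factor: thymic selection removes a fraction
#'   `1 - 1/q` of generated sequences, so the null neighbor mean is
#'   `n * q * Pgen(neighborhood)`. Default 9.41, the average selection factor
#'   over VJ combinations estimated for human TCR beta repertoires.
#' @param use_length_dependent_q use per-CDR3-length selection factors
#'   `Q_L|VJ` within each VJ class instead of the scalar `q`.
#' @param min_neighbor_reads minimum read count for a clonotype to be counted
#'   as a neighbor (default 2: singletons are likely sequencing errors and are
#'   excluded from neighbor counts, though still tested as focal sequences).
#' @param d_gate only sequences with observed neighbor count strictly greater
#'   than this are tested (default 2).
#' @param alpha BH-adjusted significance threshold (default 0.001).
#' @param n_sim Monte-Carlo draws per VJ class for Pgen estimation.
#' @param seed base RNG seed; per-class simulation seeds are derived from it.
#' @param bh_scope `"global"` (pool p-values across VJ classes before BH
#'   adjustment; conservative default) or `"per_class"`.
#' @param length_pseudocount count added to the simulated length distribution
#'   for CDR3 lengths present in the data but never simulated (length-dependent
#'   mode only).
#' @param normalize_productive passed to [build_pgen_table].
#' @return object of class `enrichment_config`.
#' @export
enrichment_config <- function(q = 9.41, use_length_dependent_q = FALSE,
                              min_neighbor_reads = 2L, d_gate = 2L,
                              alpha = 0.001, n_sim = 1e6, seed = 42L,
                              bh_scope = c("global", "per_class"),
                              length_pseudocount = 0.5,
                              normalize_productive = FALSE) {
  bh_scope <- match.arg(bh_scope)
  if (q <= 0) stopf("q must be positive (got %g)", q)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1) (got %g)", alpha)
  if (d_gate < 0) stopf("d_gate must be >= 0 (got %g)", d_gate)
  if (min_neighbor_reads < 1) stopf("min_neighbor_reads must be >= 1")
  if (n_sim < 1) stopf("n_sim must be >= 1")
  structure(list(q = q, use_length_dependent_q = isTRUE(use_length_dependent_q),
                 min_neighbor_reads = as.integer(min_neighbor_reads),
                 d_gate = as.integer(d_gate), alpha = alpha,
                 n_sim = n_sim, seed = as.integer(seed), bh_scope = bh_scope,
                 length_pseudocount = length_pseudocount,
                 normalize_productive = isTRUE(normalize_productive)),
            class = "enrichment_config")
}

# Hashed neighbor counting over a whole VJ class. For every distinct
# amino-acid CDR3 in the class (focal candidates), counts the number of
# distinct nucleotide clonotypes with read_count >= min_reads whose amino-acid
# sequence is within Hamming distance 1 (same length; the focal sequence's own
# nucleotide variants count). Two same-length sequences are within Hamming 1
# iff they share at least one "masked" pattern (one position replaced by a
# wildcard), which turns the search into a hash join.
neighbor_counts <- function(vjclass, min_reads = 2L, values = NULL) {
  cl <- vjclass$clonotypes
  sigmas <- unique(cl$cdr3_aa)
  out <- data.table::data.table(sigma = sigmas, d_obs = 0L)
  if (!is.null(values)) out[, s_sum := 0]
  keep <- cl$read_count >= min_reads
  eligible <- cl[keep]
  if (nrow(eligible) == 0L || length(sigmas) == 0L) return(out)
  eligible[, clono_id := .I]
  val <- if (is.null(values)) NULL else values[keep]
  masks_of <- function(seqs, L) {
    # L masks per sequence; the wildcard position is encoded by its offset
    data.table::rbindlist(lapply(seq_len(L), function(i) {
      data.table::data.table(
        mask = paste0(substr(seqs, 1L, i - 1L), ".", substr(seqs, i + 1L, L)),
        item = seq_along(seqs))
    }))
  }
  res <- list()
  for (L in unique(nchar(sigmas))) {
    foc <- sigmas[nchar(sigmas) == L]
    eli <- eligible[nchar(cdr3_aa) == L]
    if (nrow(eli) == 0L) next
    em <- masks_of(eli$cdr3_aa, L)
    em[, clono_id := eli$clono_id[item]]
    fm <- masks_of(foc, L)
    fm[, sigma := foc[item]]
    hits <- merge(fm[, .(mask, sigma)], em[, .(mask, clono_id)],
                  by = "mask", allow.cartesian = TRUE)
    if (nrow(hits) == 0L) next
    pairs <- unique(hits[, .(sigma, clono_id)])
    if (!is.null(val)) pairs[, v := val[clono_id]]
    res[[as.character(L)]] <-
      if (is.null(val)) pairs[, .(d = .N), by = sigma]
      else pairs[, .(d = .N, s = sum(v)), by = sigma]
  }
  if (length(res)) {
    agg <- data.table::rbindlist(res)
    out[agg, d_obs := i.d, on = "sigma"]
    if (!is.null(values)) out[agg, s_sum := i.s, on = "sigma"]
  }
  out
}

#' Count the observed neighbors of one amino-acid sequence
#'
#' Number of distinct nucleotide clonotypes in a VJ class, with read count at
#' least `min_reads`, whose amino-acid CDR3 is within one substitution of
#' `sigma` (same length; nucleotide variants of `sigma` itself included).
#'
#' @param vjclass a `vj_class` from [partition_vj].
#' @param sigma an amino-acid CDR3 present in the class.
#' @param min_reads neighbor read-count filter (default 2).
#' @return integer neighbor count.
#' @export
count_neighbors <- function(vjclass, sigma, min_reads = 2L) {
  stopifnot(inherits(vjclass, "vj_class"))
  if (!sigma %in% vjclass$clonotypes$cdr3_aa) {
    stopf("sigma '%s' does not occur in this VJ class", sigma)
  }
  tab <- neighbor_counts(vjclass, min_reads = min_reads)
  tab$d_obs[match(sigma, tab$sigma)]
}

#' Upper-tail Poisson p-value
#'
#' `P(D >= d_obs)` for `D ~ Poisson(lambda)`, computed through the survival
#' function for numerical stability. A positive p-value that would underflow
#' to zero is floored at the smallest positive double; `lambda = 0` with
#' `d_obs > 0` gives exactly 0.
#'
#' @param d_obs non-negative integer vector.
#' @param lambda non-negative numeric vector.
#' @return numeric vector of p-values.
#' @export
poisson_pvalue <- function(d_obs, lambda) {
  if (any(d_obs < 0)) stopf("d_obs must be non-negative")
  if (any(lambda < 0)) stopf("lambda must be non-negative")
  n <- max(length(d_obs), length(lambda))
  d_obs <- rep_len(d_obs, n); lambda <- rep_len(lambda, n)
  p <- stats::ppois(d_obs - 1, lambda, lower.tail = FALSE)
  p[d_obs == 0L] <- 1
  zero <- lambda == 0 & d_obs > 0L
  p[zero] <- 0
  underflow <- !zero & d_obs > 0L & p == 0
  p[underflow] <- .Machine$double.xmin
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotone, capped at 1), delegating to
#' [stats::p.adjust] after validating the input range.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Length-dependent selection factors for a VJ class
#'
#' Per-CDR3-length selection factors
#' `Q_L = q * R_L / sum_L' R_L' P_data(L')`, with
#' `R_L = P_data(L) / P_gen(L)` the ratio of the data and model CDR3-length
#' distributions within the class. Lengths observed in the data but absent
#' from the simulated sample receive `pseudocount` simulated counts (the
#' affected lengths are recorded in the `"regularized_lengths"` attribute).
#'
#' @param data_counts named numeric vector: CDR3-length histogram of distinct
#'   clonotypes in the class (names = lengths).
#' @param sim_counts named numeric vector: CDR3-length histogram of
#'   model-generated productive sequences for the class.
#' @param q scalar selection factor.
#' @param pseudocount regularization count for unsimulated lengths.
#' @return named numeric vector: `Q_L` for every length in `data_counts`.
#' @export
length_dependent_q <- function(data_counts, sim_counts, q,
                               pseudocount = 0.5) {
  if (length(data_counts) == 0L) stopf("empty data length distribution")
  if (sum(sim_counts) <= 0) stopf("empty simulated length distribution")
  lens <- names(data_counts)
  cg <- sim_counts[lens]
  reg <- lens[is.na(cg) | cg == 0]
  cg[is.na(cg) | cg == 0] <- pseudocount
  n_d <- sum(data_counts)
  n_g <- sum(sim_counts)
  r <- (data_counts * n_g) / (n_d * cg)          # R_L = P_data / P_gen
  denom <- sum(r * data_counts) / n_d            # sum_L R_L * P_data(L)
  out <- q * r / denom
  attr(out, "regularized_lengths") <- reg
  out
}

#' Poisson null mean for one sequence
#'
#' `lambda = n * Q * Pgen(neighborhood of sigma)` with `n` the number of
#' unique nucleotide clonotypes in the VJ class and `Q` either the scalar
#' selection factor or the length-dependent `Q_L` for `nchar(sigma)`.
#'
#' @param vjclass a `vj_class`.
#' @param sigma amino-acid CDR3.
#' @param pgen_table `pgen_table` for the class's VJ pair.
#' @param cfg an [enrichment_config].
#' @param q_l optional precomputed length-dependent factors (named by length).
#' @return the null mean.
#' @export
null_lambda <- function(vjclass, sigma, pgen_table, cfg = enrichment_config(),
                        q_l = NULL) {
  q_eff <- if (cfg$use_length_dependent_q) {
    if (is.null(q_l)) {
      q_l <- length_dependent_q(class_length_counts(vjclass),
                                pgen_table$lengths, cfg$q,
                                cfg$length_pseudocount)
    }
    unname(q_l[as.character(nchar(sigma))])
  } else cfg$q
  vjclass$n * q_eff * neighborhood_pgen(pgen_table, sigma)
}

class_length_counts <- function(vjclass) {
  L <- nchar(vjclass$clonotypes$cdr3_aa)
  tab <- table(L)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Run the neighbor-enrichment test on a repertoire
#'
#' The full pipeline: collapse identical nucleotide clonotypes, partition
#' into VJ classes, count one-mismatch neighbors per distinct amino-acid CDR3
#' (neighbors must have at least `min_neighbor_reads` reads), test sequences
#' with more than `d_gate` neighbors against the Poisson null
#' `lambda = n * Q * Pgen(neighborhood)` (per-class Monte-Carlo Pgen tables),
#' discard tested sequences whose Monte-Carlo neighborhood probability is 0
#' (indistinguishable from sequencing artifacts), BH-adjust the remaining
#' p-values, and flag hits with adjusted p below `alpha`.
#'
#' @param rep a [tcr_repertoire].
#' @param model a [gen_model].
#' @param cfg an [enrichment_config].
#' @param pgen_tables optional named list of precomputed `pgen_table`s keyed
#'   `"V|J"`; classes without an entry are simulated with a seed derived from
#'   `cfg$seed`. Precomputing is the economical choice when several
#'   repertoires share a model.
#' @param sim_length_counts optional named list (keyed `"V|J"`) overriding the
#'   simulated CDR3-length histograms used for length-dependent `Q_L`.
#' @return object of class `enrichment_result`: a `data.table` with one row
#'   per gated sequence (`sigma`, `v_gene`, `j_gene`, `n_class`, `d_obs`,
#'   `nb_pgen`, `lambda`, `p_raw`, `p_adj`, `tested`, `zero_neighborhood`,
#'   `significant`), with the configuration and per-class neighbor tables as
#'   attributes.
#' @export
run_neighbor_enrichment <- function(rep, model, cfg = enrichment_config(),
                                    pgen_tables = NULL,
                                    sim_length_counts = NULL) {
  stopifnot(inherits(rep, "tcr_repertoire"), inherits(model, "gen_model"),
            inherits(cfg, "enrichment_config"))
  rep <- collapse_clonotypes(rep)
  classes <- partition_vj(rep)
  rows <- list()
  neighbor_tables <- list()
  for (key in names(classes)) {
    cls <- classes[[key]]
    dtab <- neighbor_counts(cls, min_reads = cfg$min_neighbor_reads)
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
      n_class = cls$n, d_obs = gated$d_obs, nb_pgen = unname(nb),
      lambda = unname(lam))
  }
  if (length(rows) == 0L) {
    res <- data.table::data.table(
      sigma = character(), v_gene = character(), j_gene = character(),
      n_class = integer(), d_obs = integer(), nb_pgen = numeric(),
      lambda = numeric(), p_raw = numeric(), p_adj = numeric(),
      tested = logical(), zero_neighborhood = logical(),
      significant = logical())
    return(finalize_result(res, cfg, neighbor_tables, rep$sample_id))
  }
  res <- data.table::rbindlist(rows)
  res[, zero_neighborhood := nb_pgen == 0]
  res[, tested := !zero_neighborhood]
  res[, p_raw := NA_real_]
  res[tested == TRUE, p_raw := poisson_pvalue(d_obs, lambda)]
  res[, p_adj := NA_real_]
  if (cfg$bh_scope == "global") {
    res[tested == TRUE, p_adj := bh_adjust(p_raw)]
  } else {
    res[tested == TRUE, p_adj := bh_adjust(p_raw), by = .(v_gene, j_gene)]
  }
  res[, significant := !is.na(p_adj) & p_adj < cfg$alpha]
  finalize_result(res, cfg, neighbor_tables, rep$sample_id)
}

finalize_result <- function(res, cfg, neighbor_tables, sample_id) {
  data.table::setattr(res, "config", cfg)
  data.table::setattr(res, "neighbor_tables", neighbor_tables)
  data.table::setattr(res, "sample_id", sample_id)
  data.table::setattr(res, "class", c("enrichment_result", class(res)))
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  # column subsets lose the result semantics; print those as plain tables
  if (all(c("tested", "significant") %in% names(x))) {
    cat(sprintf("<enrichment_result> sample '%s': %d gated sequences, %d tested, %d significant\n",
                attr(x, "sample_id"), nrow(x), sum(x$tested), sum(x$significant)))
  }
  NextMethod()
}

#' Naive neighbor-density baseline
#'
#' The model-free baseline: within each VJ class, select gated sequences whose
#' neighbor density `d(sigma)/n` exceeds a threshold. Alternatively,
#' calibrate by count: choose the threshold that selects the top `k`
#' sequences by `d/n` (ties at the threshold are all included, so the
#' selection may exceed `k`).
#'
#' @param rep a [tcr_repertoire].
#' @param threshold minimum `d/n` (ignored when `k` is given).
#' @param k target number of selections (calibrate-by-count mode).
#' @param min_neighbor_reads,d_gate as in [enrichment_config].
#' @return `data.table` with `sigma`, `v_gene`, `j_gene`, `d_obs`, `n_class`,
#'   `d_over_n`, `selected`; the threshold used is in the `"threshold"`
#'   attribute.
#' @export
dn_threshold_baseline <- function(rep, threshold = NULL, k = NULL,
                                  min_neighbor_reads = 2L, d_gate = 2L) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (is.null(threshold) && is.null(k)) stopf("supply either threshold or k")
  if (!is.null(threshold) && threshold < 0) stopf("threshold must be >= 0")
  rep <- collapse_clonotypes(rep)
  classes <- partition_vj(rep)
  rows <- lapply(classes, function(cls) {
    dtab <- neighbor_counts(cls, min_reads = min_neighbor_reads)
    dtab <- dtab[d_obs > d_gate]
    if (nrow(dtab) == 0L) return(NULL)
    data.table::data.table(sigma = dtab$sigma, v_gene = cls$v_gene,
                           j_gene = cls$j_gene, d_obs = dtab$d_obs,
                           n_class = cls$n, d_over_n = dtab$d_obs / cls$n)
  })
  res <- data.table::rbindlist(Filter(Negate(is.null), rows))
  if (nrow(res) == 0L) {
    res <- data.table::data.table(sigma = character(), v_gene = character(),
                                  j_gene = character(), d_obs = integer(),
                                  n_class = integer(), d_over_n = numeric())
  }
  if (!is.null(k)) {
    if (k < 1) stopf("k must be >= 1")
    threshold <- if (nrow(res) == 0L) Inf else {
      sorted <- sort(res$d_over_n, decreasing = TRUE)
      sorted[min(k, length(sorted))]
    }
  }
  res[, selected := d_over_n >= threshold]
  data.table::setattr(res, "threshold", threshold)
  data.table::setorder(res, -d_over_n, sigma)
  res
}

#' Write an enrichment hit table to TSV
#'
#' @param result an `enrichment_result`.
#' @param path output path.
#' @param significant_only write only significant hits (default FALSE: full
#'   gated table).
#' @export
write_hits <- function(result, path, significant_only = FALSE) {
  out <- data.table::as.data.table(result)
  if (significant_only) out <- out[significant == TRUE]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
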