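# Fully synthetic test repertoires with known ground truth: null clonotypes
# drawn from the recombination model with power-law read counts, planted
# convergent-response clusters of similar expanded sequences, and optional
# sequencing-error injection.

#' Describe a synthetic repertoire scenario
#'
#' @param model a [gen_model] (default [toy_gen_model]).
#' @param n_clonotypes number of distinct null nucleotide clonotypes.
#' @param count_exponent power-law exponent of the read-count distribution
#'   (`P(c) ~ c^-a`, `c = 1 .. count_max`); 2.5 is typical of the heavy-tailed
#'   clone sizes seen in bulk RepSeq.
#' @param count_max largest read count.
#' @param planted_clusters list of cluster descriptors, each a list with
#'   `k` (members, including the seed-sequence clonotype), `inflation`
#'   (read-count multiplier), `base_count` (pre-inflation member read count,
#'   default 2), `seed_selection` (`"low_pgen"` or `"random"`) and optionally
#'   `vj` (length-2 character).
#' @param error_rate per-base substitution rate for sequencing-error
#'   injection (0 disables; must be <= 0.01).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(model = toy_gen_model(), n_clonotypes = 5000L,
                               count_exponent = 2.5, count_max = 10000L,
                               planted_clusters = list(), error_rate = 0,
                               seed = 1L) {
  if (error_rate < 0 || error_rate > 0.01) stopf("error_rate must be in [0, 0.01]")
  if (n_clonotypes < 0) stopf("n_clonotypes must be >= 0")
  structure(list(model = model, n_clonotypes = as.integer(n_clonotypes),
                 count_exponent = count_exponent,
                 count_max = as.integer(count_max),
                 planted_clusters = planted_clusters,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

sample_power_law_counts <- function(n, exponent, cmax) {
  if (n == 0L) return(integer(0))
  support <- seq_len(cmax)
  sample(support, n, replace = TRUE, prob = support^(-exponent))
}

#' Generate a null repertoire from the recombination model
#'
#' Samples distinct productive nucleotide rearrangements from the model
#' (resampling in batches until `n_clonotypes` distinct sequences are
#' obtained) and assigns power-law read counts. Deterministic given the
#' scenario seed.
#'
#' @param scenario a [synthetic_scenario].
#' @return list with `repertoire` (a [tcr_repertoire]) and `truth`
#'   (data.table `cdr3_nt`, `v_gene`, `j_gene`, `label`, all `"null"`).
#' @export
generate_null_repertoire <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_clonotypes
  build <- function() {
    pool <- data.table::data.table(cdr3_nt = character(), cdr3_aa = character(),
                                   v_gene = character(), j_gene = character())
    attempts <- 0L
    while (nrow(pool) < n) {
      attempts <- attempts + 1L
      if (attempts > 50L) {
        stopf("model too small: only %d distinct productive clonotypes after %d batches",
              nrow(pool), attempts)
      }
      draws <- sample_rearrangements(scenario$model, max(2L * n, 1000L))
      draws <- draws[draws$productive, c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene")]
      pool <- unique(data.table::rbindlist(list(pool, draws)),
                     by = c("cdr3_nt", "v_gene", "j_gene"))
    }
    pool <- pool[seq_len(n)]
    pool[, read_count := sample_power_law_counts(n, scenario$count_exponent,
                                                 scenario$count_max)]
    pool
  }
  pool <- with_seed(scenario$seed, build())
  rep <- tcr_repertoire(pool, sample_id = sprintf("synthetic_seed%d", scenario$seed),
                        provenance = list(scenario_seed = scenario$seed))
  truth <- data.table::data.table(cdr3_nt = pool$cdr3_nt, v_gene = pool$v_gene,
                                  j_gene = pool$j_gene, label = "null")
  list(repertoire = rep, truth = truth)
}

# all single-nucleotide substitution variants of one sequence
single_nt_variants <- function(nt) {
  L <- nchar(nt)
  chars <- strsplit(nt, "")[[1L]]
  unlist(lapply(seq_len(L), function(i) {
    subs <- NT_ALPHABET[NT_ALPHABET != chars[i]]
    paste0(substr(nt, 1L, i - 1L), subs, substr(nt, i + 1L, L))
  }))
}

#' Plant a convergent-response cluster
#'
#' Emulates an antigen-driven expansion: picks a seed CDR3 (by default a
#' generatable sequence of low estimated generation probability, mimicking a
#' response that recombination statistics cannot explain), then adds `k`
#' distinct nucleotide clonotypes — the seed's own rearrangement plus
#' `k - 1` single-nucleotide variants — whose amino-acid sequences all lie
#' within one substitution of the seed and share its VJ class. Member read
#' counts are `base_count * inflation` (counts below 2 make the cluster
#' invisible to the neighbor filter: the "stealth" regime).
#'
#' @param sim list with `repertoire` and `truth` (from
#'   [generate_null_repertoire]), or a bare [tcr_repertoire].
#' @param model the [gen_model] the repertoire was drawn from.
#' @param k cluster size (>= 1), including the seed-sequence clonotype.
#' @param inflation read-count inflation factor.
#' @param base_count pre-inflation member read count (default 2).
#' @param seed_selection `"low_pgen"` (default) or `"random"`; `"high_pgen"`
#'   picks a frequently generated seed, exercising the false-positive regime
#'   that the recombination null corrects.
#' @param vj optional fixed VJ pair for the cluster.
#' @param pgen_table optional precomputed `pgen_table` for `vj` used to rank
#'   candidate seeds (a pilot sample is drawn otherwise).
#' @param pilot_draws pilot sample size for seed selection.
#' @param rng_seed integer seed.
#' @return list with `repertoire`, `truth` (planted rows labeled
#'   `"planted"`), and `seed_sigma` / `seed_vj` describing the cluster seed.
#' @export
plant_response_cluster <- function(sim, model, k = 15L, inflation = 1,
                                   base_count = 2L,
                                   seed_selection = c("low_pgen", "random", "high_pgen"),
                                   vj = NULL, pgen_table = NULL,
                                   pilot_draws = 50000L, rng_seed = 1L) {
  seed_selection <- match.arg(seed_selection)
  if (k < 1) stopf("k must be >= 1")
  if (inherits(sim, "tcr_repertoire")) {
    sim <- list(repertoire = sim,
                truth = data.table::data.table(
                  cdr3_nt = sim$clonotypes$cdr3_nt,
                  v_gene = sim$clonotypes$v_gene,
                  j_gene = sim$clonotypes$j_gene, label = "null"))
  }
  rep <- sim$repertoire
  build <- function() {
    if (is.null(vj)) {
      # default to the repertoire's most populated VJ class
      cl <- rep$clonotypes
      key <- cl[, .N, by = .(v_gene, j_gene)][order(-N)][1L]
      vj <- c(key$v_gene, key$j_gene)
    }
    pilot <- sample_rearrangements(model, pilot_draws, vj = vj)
    pilot <- pilot[pilot$productive]
    if (nrow(pilot) == 0L) stopf("model produced no productive pilot draws for this VJ")
    cand <- unique(pilot, by = "cdr3_nt")
    ptab <- data.table::data.table(aa = pilot$cdr3_aa)[, .N, by = aa]
    cnt <- stats::setNames(ptab$N, ptab$aa)
    # rank candidates cheaply by own-sequence pilot frequency before the more
    # expensive neighborhood scoring
    own <- unname(cnt[cand$cdr3_aa])
    if (seed_selection == "random") {
      pick <- sample.int(nrow(cand), 1L)
    } else {
      keep <- order(if (seed_selection == "low_pgen") own else -own)
      cand <- cand[keep[seq_len(min(300L, nrow(cand)))]]
      score <- if (!is.null(pgen_table)) {
        vapply(cand$cdr3_aa, function(s) neighborhood_pgen(pgen_table, s), 0)
      } else {
        vapply(cand$cdr3_aa, function(s) {
          sum(cnt[enumerate_neighborhood(s)], na.rm = TRUE)
        }, 0)
      }
      pick <- if (seed_selection == "low_pgen") {
        which(score == min(score[score > 0]))[1L]
      } else which.max(score)
    }
    seed_nt <- cand$cdr3_nt[pick]
    seed_aa <- cand$cdr3_aa[pick]
    # members: the seed rearrangement plus k-1 productive single-nt variants
    variants <- single_nt_variants(seed_nt)
    v_aa <- translate_cdr3(variants)
    ok <- is_canonical_aa(v_aa) & !variants %in% rep$clonotypes$cdr3_nt
    variants <- variants[ok]; v_aa <- v_aa[ok]
    if (length(variants) < k - 1L) {
      stopf("cannot construct %d distinct cluster variants (only %d available)",
            k - 1L, length(variants))
    }
    sel <- if (k > 1L) sample.int(length(variants), k - 1L) else integer(0)
    members <- data.table::data.table(
      cdr3_nt = c(seed_nt, variants[sel]),
      cdr3_aa = c(seed_aa, v_aa[sel]),
      v_gene = vj[1L], j_gene = vj[2L],
      read_count = max(1L, as.integer(round(base_count * inflation))))
    list(members = members, seed_nt = seed_nt, seed_aa = seed_aa, vj = vj)
  }
  planted <- with_seed(rng_seed, build())
  combined <- data.table::rbindlist(list(
    rep$clonotypes[, .(cdr3_nt, cdr3_aa, v_gene, j_gene, read_count)],
    planted$members), use.names = TRUE)
  out_rep <- tcr_repertoire(combined, sample_id = rep$sample_id,
                            provenance = rep$provenance)
  out_rep <- collapse_clonotypes(out_rep)
  # a planted member may coincide with an existing null rearrangement (the
  # seed is generatable by construction); the planted label wins
  prior <- sim$truth[!(cdr3_nt %in% planted$members$cdr3_nt &
                         v_gene == planted$vj[1L] & j_gene == planted$vj[2L])]
  truth <- data.table::rbindlist(list(
    prior,
    data.table::data.table(cdr3_nt = planted$members$cdr3_nt,
                           v_gene = vjval(planted$vj, 1L),
                           j_gene = vjval(planted$vj, 2L),
                           label = "planted")), use.names = TRUE)
  list(repertoire = out_rep, truth = truth,
       seed_sigma = planted$seed_aa, seed_vj = planted$vj)
}

vjval <- function(vj, i) vj[i]

#' Inject sequencing errors
#'
#' Mimics the artifact the singleton-neighbor filter targets: every
#' clonotype with read count at least `min_parent_count` spawns
#' `Binomial(read_count * L, error_rate)` erroneous reads, each a distinct
#' single-nucleotide variant added as a count-1 clonotype.
#'
#' @param sim list with `repertoire` and `truth`, or a [tcr_repertoire].
#' @param error_rate per-base substitution probability, in [0, 0.01].
#' @param min_parent_count smallest read count at which a clonotype spawns
#'   error variants (default 50).
#' @param rng_seed integer seed.
#' @return list with `repertoire` and `truth` (error rows labeled
#'   `"error"`).
#' @export
inject_sequencing_errors <- function(sim, error_rate, min_parent_count = 50L,
                                     rng_seed = 1L) {
  if (error_rate < 0 || error_rate > 0.01) stopf("error_rate must be in [0, 0.01]")
  if (inherits(sim, "tcr_repertoire")) {
    sim <- list(repertoire = sim,
                truth = data.table::data.table(
                  cdr3_nt = sim$clonotypes$cdr3_nt,
                  v_gene = sim$clonotypes$v_gene,
                  j_gene = sim$clonotypes$j_gene, label = "null"))
  }
  if (error_rate == 0) return(sim)
  rep <- sim$repertoire
  build <- function() {
    parents <- rep$clonotypes[read_count >= min_parent_count]
    rows <- list()
    for (i in seq_len(nrow(parents))) {
      p <- parents[i]
      n_err <- stats::rbinom(1L, p$read_count * nchar(p$cdr3_nt), error_rate)
      if (n_err == 0L) next
      vars <- single_nt_variants(p$cdr3_nt)
      vars <- setdiff(vars, rep$clonotypes$cdr3_nt)
      if (length(vars) == 0L) next
      picked <- unique(sample(vars, min(n_err, length(vars)), replace = FALSE))
      rows[[i]] <- data.table::data.table(
        cdr3_nt = picked, cdr3_aa = translate_cdr3(picked),
        v_gene = p$v_gene, j_gene = p$j_gene, read_count = 1L)
    }
    data.table::rbindlist(Filter(Negate(is.null), rows))
  }
  errs <- with_seed(rng_seed, build())
  if (is.null(errs) || nrow(errs) == 0L) return(sim)
  errs <- errs[is_canonical_aa(cdr3_aa)]
  # two parents may spawn the same variant; keep one count-1 copy so error
  # reads stay below the neighbor filter after collapsing
  errs <- unique(errs, by = c("cdr3_nt", "v_gene", "j_gene"))
  combined <- data.table::rbindlist(list(
    rep$clonotypes[, .(cdr3_nt, cdr3_aa, v_gene, j_gene, read_count)],
    errs), use.names = TRUE)
  out_rep <- collapse_clonotypes(
    tcr_repertoire(combined, sample_id = rep$sample_id,
                   provenance = rep$provenance))
  truth <- data.table::rbindlist(list(
    sim$truth,
    data.table::data.table(cdr3_nt = errs$cdr3_nt, v_gene = errs$v_gene,
                           j_gene = errs$j_gene, label = "error")),
    use.names = TRUE)
  list(repertoire = out_rep, truth = truth)
}

#' Simulate a full scenario
#'
#' Null repertoire, then planted clusters, then error injection, per the
#' scenario description. Ground-truth labels are complete: every clonotype is
#' labeled `"null"`, `"planted"`, or `"error"`.
#'
#' @param scenario a [synthetic_scenario].
#' @param pgen_tables optional named list of `pgen_table`s (keyed `"V|J"`)
#'   used for low-Pgen seed selection in planted clusters.
#' @return list with `repertoire`, `truth`, and `cluster_seeds` (data.table
#'   of planted-cluster seed sequences).
#' @export
simulate_repertoire <- function(scenario, pgen_tables = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sim <- generate_null_repertoire(scenario)
  seeds <- list()
  for (i in seq_along(scenario$planted_clusters)) {
    pc <- scenario$planted_clusters[[i]]
    key <- if (!is.null(pc$vj)) paste(pc$vj, collapse = "|") else NULL
    sim2 <- plant_response_cluster(
      sim, scenario$model,
      k = pc$k %||% 15L, inflation = pc$inflation %||% 1,
      base_count = pc$base_count %||% 2L,
      seed_selection = pc$seed_selection %||% "low_pgen",
      vj = pc$vj,
      pgen_table = if (!is.null(key)) pgen_tables[[key]] else NULL,
      rng_seed = derive_seed(scenario$seed, 1000L + i))
    seeds[[i]] <- data.table::data.table(cluster = i, sigma = sim2$seed_sigma,
                                         v_gene = sim2$seed_vj[1L],
                                         j_gene = sim2$seed_vj[2L])
    sim <- sim2[c("repertoire", "truth")]
  }
  if (scenario$error_rate > 0) {
    sim <- inject_sequencing_errors(sim, scenario$error_rate,
                                    rng_seed = derive_seed(scenario$seed, 2000L))
  }
  list(repertoire = sim$repertoire, truth = sim$truth,
       cluster_seeds = if (length(seeds)) data.table::rbindlist(seeds) else
         data.table::data.table(cluster = integer(), sigma = character(),
                                v_gene = character(), j_gene = character()))
}
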