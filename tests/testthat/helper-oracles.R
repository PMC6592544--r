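# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: brute-force pairwise
# Hamming, direct Poisson series summation, the textbook BH step-up, and
# exhaustive enumeration of a finite recombination model.

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# O(n^2) brute-force neighbor count: distinct nucleotide clonotypes with
# read_count >= min_reads whose aa is same-length and Hamming <= 1 from sigma
brute_force_neighbors <- function(clonotypes, sigma, min_reads = 2) {
  eligible <- clonotypes[clonotypes$read_count >= min_reads, ]
  if (nrow(eligible) == 0) return(0L)
  same_len <- nchar(eligible$cdr3_aa) == nchar(sigma)
  sum(vapply(eligible$cdr3_aa[same_len],
             function(a) hamming(a, sigma) <= 1, logical(1)))
}

# upper-tail Poisson probability by direct series summation of the tail
# terms (summing the tail itself avoids 1 - CDF cancellation at small lambda)
series_poisson_tail <- function(d_obs, lambda) {
  if (d_obs == 0) return(1)
  if (lambda == 0) return(0)
  total <- 0
  k <- d_obs
  repeat {
    term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
    total <- total + term
    if (term < total * 1e-18 || k > d_obs + 10000) break
    k <- k + 1
  }
  total
}

# textbook BH step-up: sort ascending, multiply by m/i, enforce monotonicity
# from the largest p down, cap at 1, restore input order
textbook_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive enumeration of every outcome of a finite recombination model for
# a fixed VJ pair; returns the exact amino-acid Pgen table (productive only,
# normalized by all outcomes including nonproductive ones)
enumerate_pgen <- function(model, vj) {
  vseq <- model$v_segments[[vj[1]]]
  jseq <- model$j_segments[[vj[2]]]
  vt <- model$v_trim[[vj[1]]]
  jt <- model$j_trim[[vj[2]]]
  il <- model$ins_len
  nt_p <- model$ins_nt
  acc <- new.env()
  add <- function(aa, p) {
    assign(aa, (if (exists(aa, acc)) get(aa, acc) else 0) + p, acc)
  }
  for (a in seq_along(vt)) for (b in seq_along(jt)) for (k in seq_along(il)) {
    base_p <- vt[a] * jt[b] * il[k]
    if (base_p == 0) next
    vpart <- substr(vseq, 1, nchar(vseq) - (a - 1))
    jpart <- substr(jseq, b, nchar(jseq))
    klen <- k - 1
    inserts <- if (klen == 0) data.frame(s = "", p = 1) else {
      grid <- expand.grid(rep(list(names(nt_p)), klen), stringsAsFactors = FALSE)
      data.frame(s = apply(grid, 1, paste0, collapse = ""),
                 p = apply(grid, 1, function(r) prod(nt_p[r])))
    }
    for (i in seq_len(nrow(inserts))) {
      nt <- paste0(vpart, inserts$s[i], jpart)
      if (nchar(nt) %% 3 != 0) next
      aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                               no.init.codon = TRUE))
      if (grepl("[*]", aa)) next
      add(aa, base_p * inserts$p[i])
    }
  }
  probs <- unlist(as.list(acc))
  sort(probs, decreasing = TRUE)
}

# a tiny finite model: 2 V, 2 J, short trims and insertions, enumerable
small_finite_model <- function() {
  gen_model(
    v_segments = c(V1 = "TGTGCAAGC", V2 = "TGTTCAGAT"),
    j_segments = c(J1 = "AATTTTTTC", J2 = "TACTTC"),
    vj_usage = matrix(c(.4, .2, .3, .1), 2, 2,
                      dimnames = list(c("V1", "V2"), c("J1", "J2"))),
    v_trim = c(.5, .3, .2), j_trim = c(.6, .4),
    ins_len = c(.5, .3, .2),
    ins_nt = c(A = .25, C = .25, G = .25, T = .25))
}

# a degenerate model that always produces "TGTTTT" -> "CF"
degenerate_model <- function(ins_len = 1) {
  gen_model(
    v_segments = c(V1 = "TGT"), j_segments = c(J1 = "TTT"),
    vj_usage = matrix(1, 1, 1, dimnames = list("V1", "J1")),
    v_trim = 1, j_trim = 1, ins_len = ins_len)
}

# build a repertoire directly from vectors
make_repertoire <- function(cdr3_nt, v_gene, j_gene, read_count,
                            cdr3_aa = translate_cdr3(cdr3_nt),
                            sample_id = "test") {
  tcr_repertoire(data.frame(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
                            v_gene = v_gene, j_gene = j_gene,
                            read_count = read_count),
                 sample_id = sample_id)
}

# random VJ class over a small amino-acid alphabet so Hamming-1 collisions
# are frequent; nucleotide sequences are synthetic unique tags (the neighbor
# statistics only read the aa sequence and the read count)
random_class <- function(n, seed, alphabet = c("A", "C", "D", "E"),
                         len_range = c(4L, 6L)) {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  aa <- vapply(lens, function(L) {
    paste0(sample(alphabet, L, replace = TRUE), collapse = "")
  }, "")
  cl <- data.table::data.table(
    cdr3_nt = paste0("nt", seq_len(n)), cdr3_aa = aa,
    v_gene = "TRBV1", j_gene = "TRBJ1",
    read_count = sample(1:5, n, replace = TRUE),
    frequency = rep(1 / n, n))
  structure(list(v_gene = "TRBV1", j_gene = "TRBJ1", n = n, clonotypes = cl),
            class = "vj_class")
}

# shared expensive fixtures for the calibration/sensitivity tests: one set of
# Monte-Carlo Pgen tables for every VJ class of the toy model (the tables
# describe the null model, not any particular data set, so repertoire
# replicates can share them)
toy_pgen_tables <- local({
  cache <- NULL
  function(n_sim = 1e6, seed = 20260101) {
    if (!is.null(cache)) return(cache)
    model <- toy_gen_model()
    keys <- expand.grid(v = names(model$v_segments), j = names(model$j_segments),
                        stringsAsFactors = FALSE)
    tabs <- lapply(seq_len(nrow(keys)), function(i) {
      build_pgen_table(model, c(keys$v[i], keys$j[i]), n_sim = n_sim,
                       seed = seed + i)
    })
    names(tabs) <- paste(keys$v, keys$j, sep = "|")
    cache <<- tabs
    tabs
  }
})
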