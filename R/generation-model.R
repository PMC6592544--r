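# Generative V(D)J recombination model: structure, validation, file format,
# vectorized sampling of rearrangements.
#
# The model is the null hypothesis of the enrichment test: CDR3 sequences are
# produced by choosing a (V, J) segment pair from a joint usage distribution,
# trimming a random number of nucleotides from the germline V suffix and
# J prefix that contribute to the CDR3, and inserting a random number of
# junctional nucleotides between them. Products whose length is not a
# multiple of 3 or that contain a stop codon are nonproductive.

#' Construct a generative recombination model
#'
#' @param v_segments named character vector: germline nucleotide suffix each V
#'   segment contributes to the CDR3 (starting at the conserved cysteine
#'   codon).
#' @param j_segments named character vector: germline nucleotide prefix each J
#'   segment contributes (up to and including the conserved F/W codon).
#' @param vj_usage matrix of joint (V, J) usage probabilities, rows named by V
#'   segment, columns by J segment; must sum to 1.
#' @param v_trim named list (per V) or single numeric vector of deletion-length
#'   probabilities; element `k` is the probability of trimming `k - 1`
#'   nucleotides.
#' @param j_trim as `v_trim`, for J prefixes.
#' @param ins_len numeric vector of insertion-length probabilities (element
#'   `k` = probability of `k - 1` inserted nucleotides).
#' @param ins_nt insertion nucleotide model: either a length-4 probability
#'   vector named A/C/G/T (independent nucleotides, order 0) or a list with
#'   `initial` (length 4) and `transition` (4x4 row-stochastic matrix) for a
#'   first-order Markov chain along the insertion.
#' @return object of class `gen_model`.
#' @export
gen_model <- function(v_segments, j_segments, vj_usage, v_trim, j_trim,
                      ins_len, ins_nt = c(A = .25, C = .25, G = .25, T = .25)) {
  v_segments <- toupper(v_segments); j_segments <- toupper(j_segments)
  stopifnot(length(v_segments) > 0, length(j_segments) > 0,
            !is.null(names(v_segments)), !is.null(names(j_segments)))
  vj_usage <- as.matrix(vj_usage)
  if (is.null(rownames(vj_usage))) rownames(vj_usage) <- names(v_segments)
  if (is.null(colnames(vj_usage))) colnames(vj_usage) <- names(j_segments)
  norm_trim <- function(tr, segs) {
    if (!is.list(tr)) tr <- stats::setNames(rep(list(tr), length(segs)), names(segs))
    tr[names(segs)]
  }
  m <- structure(list(
    v_segments = v_segments, j_segments = j_segments, vj_usage = vj_usage,
    v_trim = norm_trim(v_trim, v_segments), j_trim = norm_trim(j_trim, j_segments),
    ins_len = ins_len, ins_nt = ins_nt,
    ins_order = if (is.list(ins_nt)) 1L else 0L
  ), class = "gen_model")
  validate_gen_model(m)
  m
}

validate_gen_model <- function(m, tol = 1e-9) {
  chk1 <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > tol) {
      stopf("%s must be a probability vector summing to 1 (got sum %.12g)", what, sum(p))
    }
  }
  chk1(as.vector(m$vj_usage), "vj_usage")
  for (v in names(m$v_trim)) {
    chk1(m$v_trim[[v]], sprintf("v_trim[%s]", v))
    if (length(m$v_trim[[v]]) - 1L >= nchar(m$v_segments[[v]])) {
      stopf("v_trim[%s] allows trimming the whole segment", v)
    }
  }
  for (j in names(m$j_trim)) {
    chk1(m$j_trim[[j]], sprintf("j_trim[%s]", j))
    if (length(m$j_trim[[j]]) - 1L >= nchar(m$j_segments[[j]])) {
      stopf("j_trim[%s] allows trimming the whole segment", j)
    }
  }
  chk1(m$ins_len, "ins_len")
  if (m$ins_order == 0L) {
    chk1(m$ins_nt, "ins_nt")
  } else {
    chk1(m$ins_nt$initial, "ins_nt$initial")
    for (i in 1:4) chk1(m$ins_nt$transition[i, ], sprintf("ins_nt$transition row %d", i))
  }
  invisible(TRUE)
}

#' @export
print.gen_model <- function(x, ...) {
  cat(sprintf("<gen_model> %d V x %d J segments, max %d insertions, order-%d insertion model\n",
              length(x$v_segments), length(x$j_segments),
              length(x$ins_len) - 1L, x$ins_order))
  invisible(x)
}

#' A small self-contained recombination model
#'
#' A toy beta-chain-like model (no explicit D segment) with 3 V and 3 J
#' segments, geometric-like trimming and insertion profiles and a mildly
#' GC-biased insertion nucleotide distribution. It generates CDR3s of
#' realistic length (8-13 amino acids) with enough junctional diversity that
#' repertoires of several thousand distinct clonotypes can be sampled, while
#' remaining cheap enough for Monte-Carlo generation-probability estimation at
#' desk scale.
#'
#' @return a [gen_model].
#' @export
toy_gen_model <- function() {
  v <- c(TRBV1 = "TGTGCCAGCAGTTTATCG",   # CASSLS
         TRBV2 = "TGTGCCACCAGCAGAGAT",   # CATSRD
         TRBV3 = "TGTGCTGTGAGTGAAAGG")   # CAVSER
  j <- c(TRBJ1 = "AATGAGCAGTTCTTT",      # NEQFF
         TRBJ2 = "TATGGCTACACCTTC",      # YGYTF
         TRBJ3 = "TACAATGAGCAGTTC")      # YNEQF
  usage <- outer(c(.5, .3, .2), c(.4, .35, .25))
  dimnames(usage) <- list(names(v), names(j))
  trim <- c(.35, .25, .18, .12, .07, .03); trim <- trim / sum(trim)
  ins <- stats::dpois(0:8, 3); ins <- ins / sum(ins)
  gen_model(v, j, usage, v_trim = trim, j_trim = trim, ins_len = ins,
            ins_nt = c(A = .2, C = .3, G = .3, T = .2))
}

# Sample insertion strings for a vector of lengths (vectorized by length
# stratum; within a stratum the per-position letters come from the order-0
# distribution or the order-1 chain).
sample_insertions <- function(model, lens) {
  n <- length(lens)
  ins <- character(n)
  if (n == 0L) return(ins)
  for (k in unique(lens)) {
    idx <- which(lens == k)
    if (k == 0L) { ins[idx] <- ""; next }
    m <- matrix("", length(idx), k)
    if (model$ins_order == 0L) {
      m[] <- sample(NT_ALPHABET, length(idx) * k, replace = TRUE, prob = model$ins_nt)
    } else {
      cum <- t(apply(model$ins_nt$transition, 1L, cumsum))
      cur <- sample.int(4L, length(idx), replace = TRUE, prob = model$ins_nt$initial)
      m[, 1L] <- NT_ALPHABET[cur]
      if (k > 1L) for (p in 2:k) {
        u <- stats::runif(length(idx))
        cur <- rowSums(u > cum[cur, , drop = FALSE]) + 1L
        m[, p] <- NT_ALPHABET[cur]
      }
    }
    ins[idx] <- do.call(paste0, lapply(seq_len(k), function(p) m[, p]))
  }
  ins
}

#' Sample rearrangements from a recombination model
#'
#' Draws `n` CDR3 rearrangements: segment pair from the joint usage (or fixed
#' when `vj` is given), trim lengths, insertion length and nucleotides, then
#' concatenation and translation. Deterministic given `seed`.
#'
#' @param model a [gen_model].
#' @param n number of draws.
#' @param vj optional length-2 character vector `c(V, J)` fixing the segment
#'   choice (must have nonzero usage).
#' @param seed integer seed (optional; caller's RNG stream used when `NULL`).
#' @return data.table with columns `cdr3_nt`, `cdr3_aa` (`NA` when out of
#'   frame), `v_gene`, `j_gene`, `productive` (in frame and stop-free).
#' @export
sample_rearrangements <- function(model, n, vj = NULL, seed = NULL) {
  stopifnot(inherits(model, "gen_model"), n >= 0)
  run <- function() {
    if (n == 0L) {
      return(data.table::data.table(cdr3_nt = character(), cdr3_aa = character(),
                                    v_gene = character(), j_gene = character(),
                                    productive = logical()))
    }
    if (is.null(vj)) {
      flat <- as.vector(model$vj_usage)
      pick <- sample.int(length(flat), n, replace = TRUE, prob = flat)
      vi <- (pick - 1L) %% nrow(model$vj_usage) + 1L
      ji <- (pick - 1L) %/% nrow(model$vj_usage) + 1L
      vnames <- rownames(model$vj_usage)[vi]
      jnames <- colnames(model$vj_usage)[ji]
    } else {
      if (model$vj_usage[vj[1L], vj[2L]] <= 0) {
        stopf("VJ pair (%s, %s) has zero usage in the model", vj[1L], vj[2L])
      }
      vnames <- rep(vj[1L], n); jnames <- rep(vj[2L], n)
    }
    vseq <- model$v_segments[vnames]
    jseq <- model$j_segments[jnames]
    vtrim <- integer(n); jtrim <- integer(n)
    for (v in unique(vnames)) {
      idx <- which(vnames == v); pr <- model$v_trim[[v]]
      vtrim[idx] <- sample.int(length(pr), length(idx), replace = TRUE, prob = pr) - 1L
    }
    for (j in unique(jnames)) {
      idx <- which(jnames == j); pr <- model$j_trim[[j]]
      jtrim[idx] <- sample.int(length(pr), length(idx), replace = TRUE, prob = pr) - 1L
    }
    il <- sample.int(length(model$ins_len), n, replace = TRUE, prob = model$ins_len) - 1L
    nt <- paste0(substring(vseq, 1L, nchar(vseq) - vtrim),
                 sample_insertions(model, il),
                 substring(jseq, jtrim + 1L, nchar(jseq)))
    aa <- translate_cdr3(nt)
    data.table::data.table(cdr3_nt = nt, cdr3_aa = aa, v_gene = vnames,
                           j_gene = jnames,
                           productive = !is.na(aa) & !grepl("[*X]", aa))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ---- model file format ------------------------------------------------------
# Plain-text, versioned. Section headers in brackets; within a section,
# whitespace-separated records:
#   [v_segments] / [j_segments]: name sequence
#   [vj_usage]: vname jname prob
#   [v_trim] / [j_trim]: name p0 p1 ...
#   [ins_len]: p0 p1 ...
#   [ins_nt]: either "order0" then "A C G T probs", or "order1", an "initial"
#   line and four "from-X" transition lines.

#' Write a recombination model to a text file
#'
#' @param model a [gen_model].
#' @param path output path.
#' @export
write_gen_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# tcrenrich recombination model, format v1")
  w("[v_segments]")
  for (v in names(model$v_segments)) w("%s %s", v, model$v_segments[[v]])
  w("[j_segments]")
  for (j in names(model$j_segments)) w("%s %s", j, model$j_segments[[j]])
  w("[vj_usage]")
  for (v in rownames(model$vj_usage)) for (j in colnames(model$vj_usage)) {
    w("%s %s %.17g", v, j, model$vj_usage[v, j])
  }
  w("[v_trim]")
  for (v in names(model$v_trim)) w("%s %s", v, paste(sprintf("%.17g", model$v_trim[[v]]), collapse = " "))
  w("[j_trim]")
  for (j in names(model$j_trim)) w("%s %s", j, paste(sprintf("%.17g", model$j_trim[[j]]), collapse = " "))
  w("[ins_len]")
  w("%s", paste(sprintf("%.17g", model$ins_len), collapse = " "))
  w("[ins_nt]")
  if (model$ins_order == 0L) {
    w("order0")
    w("%s", paste(sprintf("%.17g", model$ins_nt), collapse = " "))
  } else {
    w("order1")
    w("initial %s", paste(sprintf("%.17g", model$ins_nt$initial), collapse = " "))
    for (i in 1:4) w("from-%s %s", NT_ALPHABET[i],
                     paste(sprintf("%.17g", model$ins_nt$transition[i, ]), collapse = " "))
  }
  invisible(path)
}

#' Read a recombination model from a text file
#'
#' @param path path to a model file written by [write_gen_model] (or following
#'   the same documented section layout).
#' @return a [gen_model].
#' @export
read_gen_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec <- cumsum(grepl("^\\[", lines))
  if (any(sec == 0)) stopf("model file has content before the first [section]")
  blocks <- split(lines, sec)
  hdr <- vapply(blocks, function(b) sub("^\\[(.*)\\]$", "\\1", b[1L]), "")
  blocks <- lapply(blocks, function(b) b[-1L])
  names(blocks) <- hdr
  need <- c("v_segments", "j_segments", "vj_usage", "v_trim", "j_trim", "ins_len", "ins_nt")
  miss <- setdiff(need, names(blocks))
  if (length(miss)) stopf("model file missing section(s): %s", paste(miss, collapse = ", "))
  kv <- function(b) {
    parts <- strsplit(b, "\\s+")
    stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  }
  numtab <- function(b) {
    parts <- strsplit(b, "\\s+")
    stats::setNames(lapply(parts, function(p) as.numeric(p[-1L])),
                    vapply(parts, `[`, "", 1L))
  }
  vseg <- kv(blocks$v_segments); jseg <- kv(blocks$j_segments)
  usage <- matrix(0, length(vseg), length(jseg),
                  dimnames = list(names(vseg), names(jseg)))
  for (ln in blocks$vj_usage) {
    p <- strsplit(ln, "\\s+")[[1L]]
    usage[p[1L], p[2L]] <- as.numeric(p[3L])
  }
  ins_len <- as.numeric(strsplit(blocks$ins_len[1L], "\\s+")[[1L]])
  ib <- blocks$ins_nt
  if (ib[1L] == "order0") {
    ins_nt <- stats::setNames(as.numeric(strsplit(ib[2L], "\\s+")[[1L]]), NT_ALPHABET)
  } else if (ib[1L] == "order1") {
    tab <- numtab(ib[-1L])
    trans <- do.call(rbind, tab[paste0("from-", NT_ALPHABET)])
    dimnames(trans) <- list(NT_ALPHABET, NT_ALPHABET)
    ins_nt <- list(initial = stats::setNames(tab$initial, NT_ALPHABET), transition = trans)
  } else stopf("ins_nt section must declare order0 or order1")
  gen_model(vseg, jseg, usage, v_trim = numtab(blocks$v_trim),
            j_trim = numtab(blocks$j_trim), ins_len = ins_len, ins_nt = ins_nt)
}
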