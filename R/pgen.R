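# Monte-Carlo estimation of amino-acid CDR3 generation probabilities per VJ
# class, neighborhood enumeration, and the exchangeable Pgen-backend registry.

#' Build a Monte-Carlo generation-probability table for a VJ class
#'
#' Draws `n_sim` rearrangements with the VJ choice fixed, translates them, and
#' counts distinct amino-acid CDR3s. The generation probability of a sequence
#' is its count divided by `n_sim` (total draws, including nonproductive ones,
#' unless `normalize_productive`).
#'
#' @param model a [gen_model].
#' @param vj length-2 character vector `c(V, J)`.
#' @param n_sim number of Monte-Carlo draws (>= 1).
#' @param seed integer seed (recorded in the table).
#' @param productive_only count only in-frame, stop-free products (default
#'   TRUE: the data contain only productive clonotypes).
#' @param normalize_productive divide counts by the number of productive draws
#'   instead of by `n_sim` (default FALSE).
#' @return object of class `pgen_table`: list with `vj`, `n_sim`, `seed`,
#'   `denominator`, `counts` (named integer vector keyed by amino-acid
#'   sequence) and `lengths` (productive CDR3 amino-acid length distribution,
#'   a named probability vector).
#' @export
build_pgen_table <- function(model, vj, n_sim, seed = 1L,
                             productive_only = TRUE,
                             normalize_productive = FALSE) {
  if (n_sim < 1) stopf("n_sim must be >= 1 (got %s)", format(n_sim))
  draws <- sample_rearrangements(model, n_sim, vj = vj, seed = seed)
  keep <- if (productive_only) draws$productive else !is.na(draws$cdr3_aa)
  aa <- draws$cdr3_aa[keep]
  counts <- integer(0)
  lengths <- numeric(0)
  if (length(aa)) {
    tab <- data.table::data.table(aa = aa)[, .N, by = aa]
    counts <- stats::setNames(tab$N, tab$aa)
    lt <- data.table::data.table(L = nchar(aa))[, .N, by = L][order(L)]
    lengths <- stats::setNames(lt$N / sum(lt$N), lt$L)
  }
  denom <- if (normalize_productive) max(1L, length(aa)) else n_sim
  structure(list(vj = vj, n_sim = n_sim, seed = seed, denominator = denom,
                 counts = counts, lengths = lengths),
            class = "pgen_table")
}

#' @export
print.pgen_table <- function(x, ...) {
  cat(sprintf("<pgen_table> VJ (%s, %s): %d distinct productive sequences from %g draws (seed %d)\n",
              x$vj[1L], x$vj[2L], length(x$counts), x$n_sim, x$seed))
  invisible(x)
}

#' Look up the generation probability of amino-acid sequences
#'
#' @param table a [build_pgen_table] result.
#' @param sigma character vector of amino-acid CDR3s.
#' @return numeric vector; 0 for sequences never generated.
#' @export
pgen_lookup <- function(table, sigma) {
  stopifnot(inherits(table, "pgen_table"))
  cnt <- table$counts[sigma]
  cnt[is.na(cnt)] <- 0L
  unname(cnt) / table$denominator
}

#' Enumerate the one-mismatch neighborhood of a sequence
#'
#' The neighborhood of an amino-acid sequence contains the sequence itself
#' plus every same-length variant differing by exactly one substitution:
#' `1 + 19 * nchar(sigma)` members.
#'
#' @param sigma a single amino-acid sequence.
#' @return character vector of neighborhood members (sigma first).
#' @export
enumerate_neighborhood <- function(sigma) {
  stopifnot(length(sigma) == 1L, is.character(sigma))
  L <- nchar(sigma)
  chars <- strsplit(sigma, "")[[1L]]
  out <- character(1L + 19L * L)
  out[1L] <- sigma
  k <- 1L
  for (i in seq_len(L)) {
    subs <- AA_ALPHABET[AA_ALPHABET != chars[i]]
    pre <- substr(sigma, 1L, i - 1L)
    post <- substr(sigma, i + 1L, L)
    out[k + seq_along(subs)] <- paste0(pre, subs, post)
    k <- k + length(subs)
  }
  out
}

#' Neighborhood generation probability
#'
#' Total Monte-Carlo generation probability of the one-mismatch neighborhood
#' of `sigma` (sigma itself plus all single-substitution same-length
#' variants).
#'
#' @param table a `pgen_table`.
#' @param sigma a single amino-acid CDR3.
#' @return a probability (0 when no neighborhood member was ever generated).
#' @export
neighborhood_pgen <- function(table, sigma) {
  sum(pgen_lookup(table, enumerate_neighborhood(sigma)))
}

# ---- Pgen backend registry --------------------------------------------------
# The Monte-Carlo estimator is the default backend. The registry is the plugin
# point for exact (dynamic-programming) generation-probability engines: a
# backend is a function(sigma, vj, model, ...) -> numeric vector of
# probabilities.

.pgen_backends <- new.env(parent = emptyenv())

#' Register a generation-probability backend
#'
#' @param name backend name.
#' @param fun function with signature `(sigma, vj, model, ...)` returning
#'   non-negative generation probabilities for each sequence in `sigma`.
#' @export
register_pgen_backend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .pgen_backends)
  invisible(name)
}

#' Retrieve a registered generation-probability backend
#'
#' @param name backend name (default `"monte_carlo"`).
#' @return the backend function.
#' @export
pgen_backend <- function(name = "monte_carlo") {
  if (!exists(name, envir = .pgen_backends, inherits = FALSE)) {
    stopf("no Pgen backend registered under '%s' (available: %s)",
          name, paste(ls(.pgen_backends), collapse = ", "))
  }
  get(name, envir = .pgen_backends, inherits = FALSE)
}

# Default backend: Monte-Carlo counting (table built on the fly unless one is
# supplied via `table`).
register_pgen_backend("monte_carlo", function(sigma, vj, model, table = NULL,
                                              n_sim = 1e6, seed = 1L, ...) {
  if (is.null(table)) table <- build_pgen_table(model, vj, n_sim = n_sim, seed = seed)
  pgen_lookup(table, sigma)
})

#' Serialize a Pgen table to TSV
#'
#' Two columns (sequence, count) preceded by `#`-prefixed metadata lines
#' (VJ pair, n_sim, seed, denominator).
#'
#' @param table a `pgen_table`.
#' @param path output path.
#' @export
write_pgen_table <- function(table, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# vj=%s,%s n_sim=%g seed=%d denominator=%g",
                     table$vj[1L], table$vj[2L], table$n_sim, table$seed,
                     table$denominator), con)
  writeLines("sequence\tcount", con)
  if (length(table$counts)) {
    writeLines(paste(names(table$counts), table$counts, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a serialized Pgen table
#'
#' @param path path written by [write_pgen_table].
#' @return a `pgen_table` (length distribution recomputed from the counts).
#' @export
read_pgen_table <- function(path) {
  meta <- readLines(path, n = 1L)
  gv <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", meta)
  vj <- strsplit(gv("vj"), ",")[[1L]]
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  counts <- stats::setNames(as.integer(tab$count), tab$sequence)
  L <- nchar(names(counts))
  lengths <- tapply(counts, L, sum)
  lengths <- stats::setNames(as.numeric(lengths) / sum(counts), names(lengths))
  structure(list(vj = vj, n_sim = as.numeric(gv("n_sim")),
                 seed = as.integer(gv("seed")),
                 denominator = as.numeric(gv("denominator")),
                 counts = counts, lengths = lengths),
            class = "pgen_table")
}
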