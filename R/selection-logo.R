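# Position-weight-matrix selection model for clusters of responding
# sequences. The enrichment of the cluster relative to the recombination
# background is factorized over CDR3 positions:
#   P_sel(sigma) = (1/Z) P_gen(sigma) exp(sum_i s_i(sigma_i)),
# with per-position selection coefficients s_i(a) learned by regularized
# gradient ascent under the constraint sum_a P_gen(sigma_i = a) e^{s_i(a)} = 1.

#' Positional amino-acid frequencies
#'
#' @param sequences character vector of same-length amino-acid sequences.
#' @return `L x 20` matrix (rows = positions, columns = the canonical amino
#'   acids), each row summing to 1.
#' @export
positional_frequencies <- function(sequences) {
  if (length(sequences) == 0L) stopf("empty sequence set")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stopf("sequences must all have the same length (got lengths %s)",
                             paste(L, collapse = ", "))
  if (any(!is_canonical_aa(sequences))) stopf("sequences must use the 20 canonical amino acids")
  m <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  chars <- matrix(unlist(strsplit(sequences, "")), nrow = length(sequences), byrow = TRUE)
  for (i in seq_len(L)) {
    tab <- table(factor(chars[, i], levels = AA_ALPHABET))
    m[i, ] <- as.numeric(tab) / length(sequences)
  }
  m
}

# per-position shift so that sum_a bg * e^s = 1 exactly along each row
normalize_selection <- function(s, background) {
  z <- rowSums(background * exp(s))
  s - log(z)
}

#' Fit the position-weight-matrix selection model
#'
#' Gradient ascent of the regularized likelihood from `s = 0`:
#' `s_i(a) <- s_i(a) + epsilon * (P_data_i(a) - P_sel_i(a) - 2 * reg_lambda * s_i(a))`,
#' followed after every update by a per-position additive shift enforcing
#' `sum_a P_gen_i(a) e^{s_i(a)} = 1`, iterated until the summed squared
#' update difference drops below `tol`. Under the constraint the predicted
#' marginal is simply `P_sel_i(a) = P_gen_i(a) e^{s_i(a)}`.
#'
#' @param data_freqs `L x 20` observed positional frequencies (e.g. from
#'   [positional_frequencies] on a hit cluster).
#' @param background `L x 20` positional frequencies of model-generated
#'   sequences of the same VJ class and CDR3 length. Amino acids never seen in
#'   the background receive a pseudo-probability (renormalized) so the
#'   normalization constraint stays well defined.
#' @param epsilon learning rate (default 0.5).
#' @param reg_lambda L2 regularization weight (default 0.02).
#' @param tol convergence threshold on the summed squared update difference
#'   (default 1e-6).
#' @param max_iter iteration cap (default 1e5); exceeding it is an error.
#' @param bg_pseudo pseudo-probability for zero background cells (default
#'   1e-6).
#' @return object of class `selection_model`: list with `s` (L x 20
#'   coefficients), `background` (regularized), `data_freqs`, `iterations`,
#'   `epsilon`, `reg_lambda`, `tol`, `z_residual` (largest deviation of the
#'   per-position normalization from 1), `regularized_cells`.
#' @export
fit_selection <- function(data_freqs, background, epsilon = 0.5,
                          reg_lambda = 0.02, tol = 1e-6, max_iter = 1e5,
                          bg_pseudo = 1e-6) {
  data_freqs <- as.matrix(data_freqs); background <- as.matrix(background)
  if (!all(dim(data_freqs) == dim(background))) {
    stopf("data_freqs and background must have identical dimensions")
  }
  if (any(rowSums(background) <= 0)) stopf("background has an all-zero position")
  regularized <- which(background == 0, arr.ind = TRUE)
  if (nrow(regularized)) {
    background[background == 0] <- bg_pseudo
    background <- background / rowSums(background)
  }
  s <- matrix(0, nrow(data_freqs), ncol(data_freqs),
              dimnames = dimnames(background))
  s <- normalize_selection(s, background)   # exact start on the constraint
  iter <- 0L; delta <- Inf
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stopf("selection model failed to converge in %d iterations (last delta %.3g)",
            max_iter, delta)
    }
    p_sel <- background * exp(s)
    s_new <- s + epsilon * (data_freqs - p_sel - 2 * reg_lambda * s)
    s_new <- normalize_selection(s_new, background)
    delta <- sum((s_new - s)^2)
    s <- s_new
    if (delta < tol) break
  }
  structure(list(s = s, background = background, data_freqs = data_freqs,
                 epsilon = epsilon, reg_lambda = reg_lambda, tol = tol,
                 iterations = iter,
                 z_residual = max(abs(rowSums(background * exp(s)) - 1)),
                 regularized_cells = regularized),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("<selection_model> L = %d, converged in %d iterations (normalization residual %.2g)\n",
              nrow(x$s), x$iterations, x$z_residual))
  invisible(x)
}

#' Selection-logo letter heights
#'
#' Heights `P_data_i(a) * s_i(a)`: observed frequency weighted by selection
#' coefficient. Negative heights mark depletion relative to the recombination
#' background; letters with zero observed frequency have zero height.
#'
#' @param model a [fit_selection] result.
#' @return `L x 20` numeric matrix.
#' @export
selection_logo_heights <- function(model) {
  stopifnot(inherits(model, "selection_model"))
  model$data_freqs * model$s
}

#' Classical information-content logo heights
#'
#' Standard sequence-logo heights: each letter's frequency times the
#' position's information content `log2(20) - H_i` (bits).
#'
#' @param data_freqs `L x 20` positional frequency matrix.
#' @return `L x 20` matrix of letter heights in bits.
#' @export
classical_logo_heights <- function(data_freqs) {
  data_freqs <- as.matrix(data_freqs)
  h <- apply(data_freqs, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- log2(ncol(data_freqs)) - h
  data_freqs * ic
}

#' Sample sequences from a factorized selection model
#'
#' Draws sequences position-independently from the marginals
#' `P_sel_i(a) = P_gen_i(a) e^{s_i(a)}` (normalized). Used to build synthetic
#' clusters with known planted selection for validation.
#'
#' @param background `L x 20` background positional frequencies.
#' @param s `L x 20` selection coefficients.
#' @param n number of sequences.
#' @param seed optional RNG seed.
#' @return character vector of `n` sequences.
#' @export
sample_from_selection <- function(background, s, n, seed = NULL) {
  background <- as.matrix(background)
  run <- function() {
    p <- background * exp(s)
    p <- p / rowSums(p)
    chars <- vapply(seq_len(nrow(p)), function(i) {
      sample(AA_ALPHABET, n, replace = TRUE, prob = p[i, ])
    }, character(n))
    if (n == 1L) chars <- matrix(chars, nrow = 1L)
    apply(chars, 1L, paste0, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write logo heights or selection coefficients to TSV
#'
#' @param mat `L x 20` matrix (heights or coefficients).
#' @param path output path.
#' @export
write_logo_matrix <- function(mat, path) {
  dt <- data.table::as.data.table(mat)
  dt[, position := seq_len(nrow(mat))]
  data.table::setcolorder(dt, "position")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Plot a sequence logo (classical or selection)
#'
#' Minimal ggplot2 rendering: letters as text, stacked by height above the
#' axis (enriched) and below (depleted). Requires ggplot2.
#'
#' @param heights `L x 20` letter-height matrix.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_logo <- function(heights, title = "") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
  dt <- data.table::data.table(
    position = rep(seq_len(nrow(heights)), ncol(heights)),
    letter = rep(colnames(heights), each = nrow(heights)),
    height = as.vector(heights))
  dt <- dt[abs(height) > 1e-12]
  pos_part <- dt[height > 0][order(position, height)]
  neg_part <- dt[height < 0][order(position, -height)]
  pos_part[, y := cumsum(height) - height / 2, by = position]
  neg_part[, y := cumsum(height) - height / 2, by = position]
  both <- data.table::rbindlist(list(pos_part, neg_part))
  ggplot2::ggplot(both, ggplot2::aes(x = position, y = y, label = letter,
                                     size = abs(height))) +
    ggplot2::geom_text(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(both$position))) +
    ggplot2::labs(title = title, y = "letter height") +
    ggplot2::theme_minimal()
}
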