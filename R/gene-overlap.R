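#' Build a 2x2 overlap contingency table
#'
#' Crosses a differentially-expressed-gene (DEG) set against a risk-gene
#' list within an explicit gene universe: `a` = DEG and listed, `b` = DEG
#' only, `c` = listed only, `d` = neither. The universe must be supplied
#' (e.g. all genes detected in the experiment); risk genes outside it are
#' dropped with a message, DEGs outside it are an error.
#'
#' @param deg_genes Character vector of DEG ids (subset of `universe`).
#' @param risk_genes Character vector of risk-gene ids.
#' @param universe Character vector of all assayed gene ids.
#' @return An object of class `contingency_2x2` with fields `a`, `b`, `c`,
#'   `d`, `universe_size`, `n_risk_dropped`.
#' @export
build_contingency <- function(deg_genes, risk_genes, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  deg_genes <- unique(as.character(deg_genes))
  risk_genes <- unique(as.character(risk_genes))
  outside <- setdiff(deg_genes, universe)
  if (length(outside) > 0) {
    stop(sprintf("%d DEG id(s) are outside the universe", length(outside)),
         call. = FALSE)
  }
  n_drop <- sum(!risk_genes %in% universe)
  if (n_drop > 0) {
    message(sprintf("dropping %d risk gene(s) outside the universe", n_drop))
    risk_genes <- intersect(risk_genes, universe)
  }
  a <- length(intersect(deg_genes, risk_genes))
  b <- length(deg_genes) - a
  c <- length(risk_genes) - a
  d <- length(universe) - a - b - c
  structure(
    list(a = a, b = b, c = c, d = d,
         universe_size = length(universe), n_risk_dropped = n_drop),
    class = "contingency_2x2"
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("<contingency_2x2>            listed  not listed\n")
  cat(sprintf("  DEG                      %6d  %10d\n", x$a, x$b))
  cat(sprintf("  not DEG                  %6d  %10d\n", x$c, x$d))
  cat(sprintf("  universe: %d\n", x$universe_size))
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2, 2,
         dimnames = list(c("deg", "not_deg"), c("listed", "not_listed")))
}

#' Fisher's exact test and odds ratio for a 2x2 table
#'
#' Two-sided exact p by point-probability ordering (sum of hypergeometric
#' point probabilities not exceeding the observed one — the `fisher.test`
#' convention), computed by direct summation over the table's support. The
#' odds ratio is the sample (cross-product) ratio `a*d / (b*c)` by
#' default; `or_method = "conditional_mle"` reports the conditional
#' maximum-likelihood estimate instead (what `fisher.test` prints) — the
#' two differ and published values rarely say which was used.
#'
#' @param table A [build_contingency()] result, or a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))`.
#' @param or_method `"sample"` (default) or `"conditional_mle"`.
#' @return Tibble `(a, b, c, d, odds_ratio, p_two_sided)`. Degenerate
#'   tables (an all-zero margin) return `p = 1` and `NaN` odds ratio with
#'   a warning; `b*c = 0` with `a*d > 0` gives `Inf`.
#' @export
fisher_exact_or <- function(table, or_method = c("sample", "conditional_mle")) {
  or_method <- match.arg(or_method)
  if (inherits(table, "contingency_2x2")) {
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
  } else {
    m <- as.matrix(table)
    stopifnot(all(dim(m) == c(2, 2)))
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  }
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be nonnegative", call. = FALSE)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    warning("degenerate table: an all-zero margin; p = 1, odds ratio undefined")
    return(tibble::tibble(a = a, b = b, c = c, d = d,
                          odds_ratio = NaN, p_two_sided = 1))
  }
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(m1, k)
  logp <- stats::dhyper(support, m1, m2, k, log = TRUE)
  obs <- stats::dhyper(a, m1, m2, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + 1e-7]))
  p <- min(1, p)
  or <- if (or_method == "sample") {
    if (b * c == 0) {
      if (a * d == 0) NaN else Inf
    } else {
      (a * d) / (b * c)
    }
  } else {
    unname(stats::fisher.test(matrix(c(a, c, b, d), 2, 2))$estimate)
  }
  tibble::tibble(a = a, b = b, c = c, d = d,
                 odds_ratio = or, p_two_sided = p)
}

#' One-call gene-set overlap test
#'
#' Builds the 2x2 table from id lists and runs [fisher_exact_or()].
#'
#' @inheritParams build_contingency
#' @inheritParams fisher_exact_or
#' @return Tibble `(a, b, c, d, universe_size, odds_ratio, p_two_sided)`.
#' @export
overlap_test <- function(deg_genes, risk_genes, universe,
                         or_method = c("sample", "conditional_mle")) {
  tab <- build_contingency(deg_genes, risk_genes, universe)
  dplyr::mutate(fisher_exact_or(tab, or_method = or_method),
                universe_size = tab$universe_size, .after = "d")
}
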