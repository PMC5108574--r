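#' 2x2 contingency table
#'
#' Layout: `a` exposed cases, `b` unexposed cases, `c` exposed controls,
#' `d` unexposed controls. Both row totals must be positive.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param labels Optional character vector of length 2 naming the
#'   comparison, e.g. `c("cB01/tA01", "AGRE vs control")`.
#' @return A list of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, labels = NULL) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("2x2 cells must be non-negative integers", call. = FALSE)
  }
  if (a + b <= 0 || c + d <= 0) {
    stop("both case (a+b) and control (c+d) totals must be positive",
         call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, labels = labels),
            class = "two_by_two")
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio (a*d)/(b*c), returned unrounded. With a zero cell in
#' `b` or `c` the OR is infinite and flagged via the `"zero_cell"`
#' attribute; the Haldane-Anscombe +0.5 correction can be requested
#' instead.
#'
#' @param t A `two_by_two`.
#' @param correction Apply +0.5 to every cell when any cell is zero?
#' @return Positive numeric (possibly `Inf`/0 without correction).
#' @export
odds_ratio <- function(t, correction = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (correction && any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  if (!correction && (t$b == 0 || t$c == 0)) {
    attr(or, "zero_cell") <- TRUE
  }
  or
}

#' Two-sided Fisher exact test
#'
#' Conditional on both margins, the first cell follows a hypergeometric
#' distribution; the two-sided p-value sums the probabilities of every
#' table (same margins) whose point probability does not exceed that of
#' the observed table (point-probability rule, the convention of
#' `stats::fisher.test`).
#'
#' @param t A `two_by_two`.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- t$a + t$b          # cases
  n <- t$c + t$d          # controls
  k <- t$a + t$c          # exposed margin
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == t$a]
  # relative tolerance absorbs floating-point ties across the support
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Woolf (log-scale) confidence interval for an odds ratio
#'
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Requires all cells
#' positive unless the Haldane-Anscombe correction is enabled.
#'
#' @param t A `two_by_two`.
#' @param level Confidence level (default 0.95; 0 gives the degenerate
#'   point interval).
#' @param correction Apply +0.5 to every cell when any cell is zero?
#' @return Numeric vector `c(low, high)`.
#' @export
woolf_ci <- function(t, level = 0.95, correction = FALSE) {
  stopifnot(inherits(t, "two_by_two"), level >= 0, level < 1)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (!correction) {
      stop("Woolf interval undefined with a zero cell; ",
           "enable the +0.5 correction", call. = FALSE)
    }
    cells <- cells + 0.5
  }
  log_or <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(log_or + c(-1, 1) * z * se)
}

#' Exact binomial transmission disequilibrium test
#'
#' From heterozygous informative parents, `b` transmissions of the target
#' allele versus `c` non-transmissions are Binomial(b + c, 1/2) under the
#' null of no linkage/association. The two-tailed p doubles the smaller
#' exact tail and caps at 1.
#'
#' @param b_transmitted,c_untransmitted Non-negative integer counts.
#' @param label Optional allele/haplotype label.
#' @return A list of class `tdt_result`: `label`, `b_transmitted`,
#'   `c_untransmitted`, `p_value`.
#' @export
tdt_binomial <- function(b_transmitted, c_untransmitted, label = NULL) {
  b <- b_transmitted
  c <- c_untransmitted
  if (any(c(b, c) < 0) || any(c(b, c) != round(c(b, c)))) {
    stop("transmission counts must be non-negative integers", call. = FALSE)
  }
  n <- b + c
  if (n == 0) {
    stop("no informative (heterozygous) parents: b + c = 0", call. = FALSE)
  }
  lo <- stats::pbinom(min(b, c), n, 0.5)
  hi <- stats::pbinom(max(b, c) - 1, n, 0.5, lower.tail = FALSE)
  p <- min(1, 2 * min(lo, hi))
  structure(list(label = label, b_transmitted = b, c_untransmitted = c,
                 p_value = p),
            class = "tdt_result")
}

# bundle a 2x2 with its full statistics
.association_result <- function(t, label, correction = FALSE) {
  or <- odds_ratio(t, correction = correction)
  ci <- if (all(c(t$a, t$b, t$c, t$d) > 0) || correction) {
    woolf_ci(t, correction = correction)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(label = label, table = t, odds_ratio = as.numeric(or),
                 zero_cell = isTRUE(attr(or, "zero_cell")),
                 ci95 = ci, p_value = fisher_exact(t),
                 method = "fisher_exact"),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: OR %.3f (95%% CI %.3f-%.3f), Fisher p = %.4g [a=%d b=%d c=%d d=%d]\n",
              x$label, x$odds_ratio, x$ci95[1], x$ci95[2], x$p_value,
              x$table$a, x$table$b, x$table$c, x$table$d))
  invisible(x)
}

#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(label = x$label, a = x$table$a, b = x$table$b, c = x$table$c,
             d = x$table$d, odds_ratio = x$odds_ratio, ci_low = x$ci95[1],
             ci_high = x$ci95[2], p_value = x$p_value, method = x$method,
             stringsAsFactors = FALSE)
}

#' Case-control association for one haplotype
#'
#' Builds the 2x2 table target-vs-rest from haplotype tallies (haploid
#' denominators: each chromosome is one observation) and computes the odds
#' ratio, Fisher exact p, and Woolf interval.
#'
#' @param case_tallies,control_tallies Named numeric vectors,
#'   haplotype -> count.
#' @param target Haplotype label to test.
#' @param correction Haldane-Anscombe correction for zero cells?
#' @param case_total,control_total Denominators (total chromosomes); default
#'   to the tally sums, but can be set larger when the tallies enumerate
#'   only the common haplotypes of a bigger panel.
#' @return An `association_result`.
#' @export
haplotype_association_table <- function(case_tallies, control_tallies,
                                        target, correction = FALSE,
                                        case_total = sum(case_tallies),
                                        control_total = sum(control_tallies)) {
  if (length(case_tallies) == 0 || sum(case_tallies) == 0) {
    stop("empty case tallies", call. = FALSE)
  }
  if (case_total < sum(case_tallies) ||
      control_total < sum(control_tallies)) {
    stop("totals cannot be smaller than the tally sums", call. = FALSE)
  }
  a <- sum(case_tallies[names(case_tallies) == target])
  c_ <- sum(control_tallies[names(control_tallies) == target])
  if (!target %in% c(names(case_tallies), names(control_tallies))) {
    stop("target '", target, "' absent from both tallies", call. = FALSE)
  }
  t <- two_by_two(a, case_total - a, c_, control_total - c_,
                  labels = c(target, "case vs control"))
  .association_result(t, target, correction = correction)
}

#' Inherited vs non-inherited (AFBAC) ligand comparison
#'
#' Compares the frequency of a ligand diplotype category among subjects
#' (inherited alleles) against the non-transmitted parental allele
#' controls. Percentages are reported to 1 d.p. (half-up).
#'
#' @param inherited,noninherited Named numeric vectors of diplotype
#'   category counts (e.g. over `C1k/C1k`, `C1k/C2k`, `C2k/C2k`).
#' @param category Category to test.
#' @return An `association_result` with extra fields `pct_inherited`,
#'   `pct_noninherited`.
#' @export
afbac_compare <- function(inherited, noninherited, category) {
  n_in <- sum(inherited)
  n_non <- sum(noninherited)
  if (n_in <= 0 || n_non <= 0) {
    stop("both inherited and noninherited totals must be positive",
         call. = FALSE)
  }
  a <- sum(inherited[names(inherited) == category])
  c_ <- sum(noninherited[names(noninherited) == category])
  t <- two_by_two(a, n_in - a, c_, n_non - c_,
                  labels = c(category, "inherited vs noninherited"))
  res <- .association_result(t, category)
  res$pct_inherited <- round_half_up(100 * a / n_in, 1)
  res$pct_noninherited <- round_half_up(100 * c_ / n_non, 1)
  res
}
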