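#' Insertion count for a trifurcation
#'
#' A trifurcation of three clades can be resolved into three bifurcating
#' topologies.  An insertion count records how many unambiguous
#' retrotransposon markers support each resolution.  When markers were
#' ascertained in a single reference genome, insertions supporting the one
#' resolution that excludes the reference taxon cannot be observed; that
#' slot is the "blind" tree and is recorded as unobservable (printed `X`).
#'
#' @param t1 Non-negative integer, markers supporting the tested (first)
#'   topology.
#' @param t2 Non-negative integer, markers supporting the second topology.
#' @param t3 Non-negative integer, markers supporting the third topology,
#'   or `NA` / `"X"` when that topology is blind to the marker screen.
#' @param labels Optional character vector of length 3 naming the three
#'   topologies (used by report printers).
#'
#' @return An object of class `insertion_count` with fields `t1`, `t2`,
#'   `t3` (`NA` for the unobservable slot) and `labels`.
#'
#' @details The count is *not* silently reordered: `t1` is whichever
#'   topology the caller chose to test, which need not be the
#'   best-supported one (a specific prior hypothesis can be tested).  Use
#'   [canonicalize_count()] to test the best-supported topology.
#'
#' @examples
#' insertion_count(2, 1, 0)    # fully observed, multi-directional regime
#' insertion_count(6, 1, "X")  # single-reference regime, blind third tree
#' @seealso [kksc_multi()], [kksc_onedir()], [canonicalize_count()]
#' @export
insertion_count <- function(t1, t2, t3 = NA, labels = NULL) {
  check_count(t1, "t1")
  check_count(t2, "t2")
  blind <- is_blind_slot(t3)
  if (!blind) check_count(t3, "t3")
  t3 <- if (blind) NA_real_ else as.numeric(t3)
  if (!is.null(labels)) stopifnot(is.character(labels), length(labels) == 3)
  structure(list(t1 = as.numeric(t1), t2 = as.numeric(t2), t3 = t3,
                 labels = labels),
            class = "insertion_count")
}

is_blind_slot <- function(x) {
  length(x) == 1 &&
    (is.na(x) || (is.character(x) && toupper(trimws(x)) %in% c("X", "?")))
}

check_count <- function(x, what) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 ||
      x != round(x))
    stop(sprintf("'%s' must be a single non-negative integer", what),
         call. = FALSE)
  invisible(x)
}

#' @export
print.insertion_count <- function(x, ...) {
  t3 <- if (is.na(x$t3)) "X" else format(x$t3)
  cat(sprintf("[%g %g %s]\n", x$t1, x$t2, t3))
  invisible(x)
}

#' @export
format.insertion_count <- function(x, ...) {
  sprintf("[%g %g %s]", x$t1, x$t2, if (is.na(x$t3)) "X" else format(x$t3))
}

#' Reorder an insertion count so the best-supported topology is tested
#'
#' Swaps the two observable slots (and their labels) if needed so that
#' `t1 >= t2`.  The reordering is explicit: tests never reorder counts
#' themselves, because one may deliberately test a prior hypothesis that
#' is not the best-supported topology.
#'
#' @param count An [insertion_count()].
#' @return An `insertion_count` with `t1 >= t2`.
#' @export
canonicalize_count <- function(count) {
  stopifnot(inherits(count, "insertion_count"))
  if (count$t2 > count$t1) {
    lab <- count$labels
    if (!is.null(lab)) lab <- lab[c(2, 1, 3)]
    count <- insertion_count(count$t2, count$t1,
                             if (is.na(count$t3)) NA else count$t3, lab)
  }
  count
}

#' Ratio count along the reference stem lineage
#'
#' The insertion ratio test compares markers on two successive branches
#' along the stem lineage of the reference taxon: `shared` (d) markers
#' support the clade joining the reference lineage to its hypothesized
#' sister, `exclusive` (e) markers sit on the next shallower branch that
#' contains only the reference side.
#'
#' @param shared Non-negative integer d.
#' @param exclusive Non-negative integer e.
#' @return An object of class `ratio_count`.
#' @examples
#' ratio_count(6, 2)
#' @seealso [insertion_ratio_test()], [max_introgressed_markers()]
#' @export
ratio_count <- function(shared, exclusive) {
  check_count(shared, "shared")
  check_count(exclusive, "exclusive")
  structure(list(shared = as.numeric(shared),
                 exclusive = as.numeric(exclusive)),
            class = "ratio_count")
}

#' @export
print.ratio_count <- function(x, ...) {
  cat(sprintf("(%g,%g)\n", x$shared, x$exclusive))
  invisible(x)
}

#' @export
format.ratio_count <- function(x, ...) sprintf("(%g,%g)", x$shared, x$exclusive)

## ---- exact binomial kernel -------------------------------------------------

## Try to express p as a small-denominator rational a/b.  Returns c(a, b) or
## NULL.  Denominators up to 1000 cover every probability used by the tests
## (1/3, 1/2, 1/5, user-supplied gammas like 0.25).
.as_rational <- function(p, max_den = 1000L) {
  for (b in seq_len(max_den)) {
    a <- p * b
    if (abs(a - round(a)) < 1e-9) return(c(round(a), b))
  }
  NULL
}

#' Exact upper tail of a binomial distribution
#'
#' Computes `P(X >= k)` for `X ~ Binomial(n, p)`.  This is the shared
#' kernel of all four support tests.  When `p` is a small-denominator
#' rational `a/b` and `b^n` is exactly representable in double precision,
#' the tail is accumulated in exact integer arithmetic
#' (`sum_{i>=k} C(n,i) a^i (b-a)^(n-i) / b^n`); otherwise
#' [stats::pbinom()] is used, which is accurate well beyond 12
#' significant digits for the sample sizes involved.
#'
#' @param n Number of trials (non-negative integer).
#' @param k Success threshold; `k = 0` returns 1, `k = n + 1` returns 0.
#' @param p Success probability, strictly between 0 and 1.
#' @return `P(X >= k)`, a number in `[0, 1]`.
#' @examples
#' binomial_upper_tail(3, 2, 1/3)  # 7/27
#' @export
binomial_upper_tail <- function(n, k, p) {
  check_count(n, "n")
  if (length(k) != 1 || !is.numeric(k) || is.na(k) || k < 0 ||
      k != round(k) || k > n + 1)
    stop("'k' must be an integer in [0, n + 1]", call. = FALSE)
  if (length(p) != 1 || !is.numeric(p) || is.na(p) || p <= 0 || p >= 1)
    stop("'p' must lie strictly between 0 and 1", call. = FALSE)
  if (k == 0) return(1)
  if (k == n + 1) return(0)
  rat <- .as_rational(p)
  if (!is.null(rat) && rat[2]^n < 2^53) {
    a <- rat[1]; b <- rat[2]
    i <- k:n
    ## every term and the running sum are integers < b^n < 2^53, so the
    ## double-precision accumulation is exact
    num <- sum(choose(n, i) * a^i * (b - a)^(n - i))
    return(num / b^n)
  }
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

## ---- TestResult ------------------------------------------------------------

new_test_result <- function(test_id, input_count, p_value, tail,
                            gamma = NULL, n_bound = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_id = test_id, input_count = input_count,
                 gamma = gamma, p_value = p_value, tail = tail,
                 n_bound = n_bound),
            class = "retro_test")
}

#' @export
print.retro_test <- function(x, ...) {
  nm <- switch(x$test_id,
               KKSC_MULTI = "Multi-directional KKSC test (P)",
               KKSC_ONEDIR = "One-directional KKSC test (P_B)",
               ILS_SYMMETRY = "ILS symmetry test (P_ILS)",
               INSERTION_RATIO = sprintf("Insertion ratio test (P_R%g)",
                                         100 * x$gamma),
               x$test_id)
  cat(nm, "\n")
  cat("  count:   ", format(x$input_count), "\n", sep = "")
  cat("  p-value: ", format_pvalue(x$p_value),
      sprintf(" (%s tail)", sub("_", "-", x$tail)), "\n", sep = "")
  if (!is.null(x$n_bound))
    cat(sprintf("  N = gamma (d + e) = %g (max markers introgression could share)\n",
                x$n_bound))
  invisible(x)
}

#' Format a p-value the way the support tables print it
#'
#' Four decimal places, with values below 0.00005 printed as `"<0.0001"`.
#' Internal comparisons always use unrounded values; this formatting is
#' for reports only.
#'
#' @param p Numeric vector of probabilities.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ## round half away from zero, as the printed tables do (0.03125 -> 0.0313)
  ifelse(p < 0.00005, "<0.0001",
         sprintf("%.4f", floor(p * 1e4 + 0.5) / 1e4))
}

## ---- the four tests --------------------------------------------------------

#' Multi-directional KKSC support test
#'
#' Exact cumulative binomial test for a fully observed trifurcation: under
#' the null of random allocation, each of `a + b + c` markers supports the
#' tested topology with probability 1/3, and the p-value is the
#' probability of the tested topology receiving at least `a` markers.
#'
#' @param count An [insertion_count()] with all three slots observed.
#' @return A `retro_test` result with `test_id = "KKSC_MULTI"`.
#' @examples
#' kksc_multi(insertion_count(2, 1, 0))$p_value  # 0.2593
#' @export
kksc_multi <- function(count) {
  stopifnot(inherits(count, "insertion_count"))
  if (is.na(count$t3))
    stop("count has an unobservable (blind) third slot; ",
         "use kksc_onedir() for single-reference data", call. = FALSE)
  n <- count$t1 + count$t2 + count$t3
  if (n < 1) stop("need at least one observed marker", call. = FALSE)
  new_test_result("KKSC_MULTI", count,
                  binomial_upper_tail(n, count$t1, 1 / 3), "upper")
}

#' One-directional KKSC support test
#'
#' Exact cumulative binomial test acknowledging the single-reference
#' ascertainment bias: markers for the blind third topology are
#' unidentifiable, the test reduces to the two observable topologies, and
#' each of `a + b` markers supports the tested topology with probability
#' 1/2.
#'
#' @param count An [insertion_count()] whose third slot is unobservable.
#' @return A `retro_test` result with `test_id = "KKSC_ONEDIR"`.
#' @examples
#' kksc_onedir(insertion_count(6, 1, "X"))$p_value  # 0.0625
#' @export
kksc_onedir <- function(count) {
  stopifnot(inherits(count, "insertion_count"))
  if (!is.na(count$t3))
    stop("count is fully observed; use kksc_multi()", call. = FALSE)
  n <- count$t1 + count$t2
  if (n < 1) stop("need at least one observable marker", call. = FALSE)
  new_test_result("KKSC_ONEDIR", count,
                  binomial_upper_tail(n, count$t1, 1 / 2), "upper")
}

#' ILS symmetry test
#'
#' Tests the hypothesis that the blind tree is the species tree and the
#' markers supporting the two observable topologies arose by incomplete
#' lineage sorting.  ILS distributes markers conflicting with the species
#' tree roughly symmetrically between the two non-species-tree
#' topologies, so a significant asymmetry between the observable counts
#' rejects that hypothesis.  The test is two-tailed (the disparity could
#' run either way): the p-value doubles the upper tail at `max(a, b)`
#' and is capped at 1.  It does not depend on the unobservable slot.
#'
#' @param count_t1,count_t2 Observable marker counts (non-negative
#'   integers, sum at least 1).  An [insertion_count()] may be given as
#'   the first argument instead.
#' @return A `retro_test` result with `test_id = "ILS_SYMMETRY"`.
#' @examples
#' ils_symmetry(8, 1)$p_value  # 0.0391
#' ils_symmetry(6, 6)$p_value  # 1
#' @export
ils_symmetry <- function(count_t1, count_t2 = NULL) {
  if (inherits(count_t1, "insertion_count")) {
    count_t2 <- count_t1$t2
    count_t1 <- count_t1$t1
  }
  check_count(count_t1, "count_t1")
  check_count(count_t2, "count_t2")
  n <- count_t1 + count_t2
  if (n < 1)
    stop("ILS symmetry test undefined when both counts are zero",
         call. = FALSE)
  p <- min(1, 2 * binomial_upper_tail(n, max(count_t1, count_t2), 1 / 2))
  new_test_result("ILS_SYMMETRY",
                  insertion_count(count_t1, count_t2, NA),
                  p, "two_tailed")
}

#' Insertion ratio test against introgression
#'
#' Tests the hypothesis that the blind tree is the species tree and the
#' markers supporting the observed reference-containing clade derive from
#' introgression/hybridization that shared a fraction `gamma` of the
#' genome.  Of the `d + e` markers available on the reference stem, each
#' is expected to be shared with probability at most `gamma`, so the
#' maximum expected number of introgressed markers is
#' `N = gamma * (d + e)`, and the p-value is the exact upper binomial
#' tail `P(X >= d)` for `X ~ Binomial(d + e, gamma)`.  Because `N` is a
#' maximum, the test is conservative for the stated gene-flow fraction.
#'
#' @param count A [ratio_count()] `(d, e)`.
#' @param gamma Fraction of the genome shared and retained, in (0, 1).
#'   0.5 is an extreme scenario (pure F1 hybrid ancestry); 0.2 a more
#'   realistic moderate-introgression scenario.
#' @return A `retro_test` result with `test_id = "INSERTION_RATIO"`,
#'   carrying `n_bound = N`.
#' @examples
#' insertion_ratio_test(ratio_count(6, 2), 0.5)$p_value  # 0.1445
#' insertion_ratio_test(ratio_count(6, 2), 0.2)$p_value  # 0.0012
#' @export
insertion_ratio_test <- function(count, gamma) {
  stopifnot(inherits(count, "ratio_count"))
  if (length(gamma) != 1 || !is.numeric(gamma) || is.na(gamma) ||
      gamma <= 0 || gamma >= 1)
    stop("'gamma' must lie strictly between 0 and 1", call. = FALSE)
  n <- count$shared + count$exclusive
  if (n < 1)
    stop("insertion ratio test needs d + e >= 1", call. = FALSE)
  new_test_result("INSERTION_RATIO", count,
                  binomial_upper_tail(n, count$shared, gamma), "upper",
                  gamma = gamma, n_bound = gamma * n)
}

#' Maximum expected number of introgressed markers
#'
#' The expected number of markers that introgression contributes to the
#' observed reference-containing clade is `n = beta * gamma`, which is
#' unknowable; its maximum over the unknown parameters, given only the
#' observed ratio count, is `N = gamma * (d + e)`.
#'
#' @inheritParams insertion_ratio_test
#' @return The bound `N`, a non-negative real.
#' @examples
#' max_introgressed_markers(ratio_count(6, 2), 0.5)  # 4
#' max_introgressed_markers(ratio_count(6, 2), 0.2)  # 1.6
#' @export
max_introgressed_markers <- function(count, gamma) {
  stopifnot(inherits(count, "ratio_count"))
  if (length(gamma) != 1 || !is.numeric(gamma) || is.na(gamma) ||
      gamma <= 0 || gamma >= 1)
    stop("'gamma' must lie strictly between 0 and 1", call. = FALSE)
  gamma * (count$shared + count$exclusive)
}
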