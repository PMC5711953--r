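## Synthetic marker generator: a 4-taxon scaffold (R, B, C, outgroup O)
## with single-reference ascertainment, a coalescent-style hemiplasy model
## on the internal branch, and an explicit introgression model.

#' Introgression scenario for the simulator
#'
#' Insertions accumulate on the stem lineages in two windows: `beta`
#' (expected count) before the gene-flow event and `alpha` after it.  A
#' fraction `gamma` of the genome is shared and retained, so each
#' pre-event donor marker is transferred with probability `gamma` and
#' then appears to support the donor + recipient pair.
#'
#' With `direction = "from_reference"` the shared markers originate on
#' the reference stem (the bound `N = gamma (d + e)` is robust to rate
#' variation in this direction).  With `"to_reference"` they originate on
#' the non-reference stem; the reference stem then accrues its own
#' `alpha + beta` insertions scaled by its rate multiplier, which is the
#' direction in which unequal insertion rates can make the ratio test
#' overconfident.
#'
#' @param alpha Expected insertions per stem after the event (>= 0).
#' @param beta Expected insertions per stem before the event (>= 0).
#' @param gamma Genome fraction shared and retained, in (0, 1).
#' @param direction `"from_reference"` or `"to_reference"`.
#' @param recipient The non-reference taxon involved; default `"B"`.
#' @return A list of class `introgression_scenario`.
#' @export
introgression_scenario <- function(alpha, beta, gamma,
                                   direction = c("from_reference",
                                                 "to_reference"),
                                   recipient = "B") {
  direction <- match.arg(direction)
  stopifnot(alpha >= 0, beta >= 0, gamma > 0, gamma < 1,
            recipient %in% c("B", "C"))
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 direction = direction, recipient = recipient),
            class = "introgression_scenario")
}

#' Simulator configuration
#'
#' The scaffold is the rooted 4-taxon tree `(((x,y),z),O)` where
#' `{x,y} = clade_pair` is the true species-tree sister pair among
#' `R`, `B`, `C`, and `O` is the outgroup.  `R` is the reference taxon:
#' after simulation every marker absent in `R` is dropped (the
#' ascertainment filter), so choosing `clade_pair = c("B","C")` makes the
#' true species tree the blind tree.
#'
#' Markers on the internal branch experience incomplete lineage sorting:
#' with the internal branch lasting `t_internal` coalescent units, a
#' marker resolves to the species-tree pair with probability
#' `1 - (2/3) exp(-T)` and to each discordant pair with probability
#' `(1/3) exp(-T)` (the standard 3-lineage coalescent topology
#' probabilities, which carry the required symmetry between the two
#' discordant resolutions).
#'
#' @param clade_pair Character vector of 2: the true sister pair.
#' @param t_internal Internal branch length in coalescent units (> 0).
#' @param intensity Named expected insertion counts per branch:
#'   `internal` (the internal branch), `R`, `B`, `C` (terminal stems) and
#'   `deep` (the stem of the three-taxon clade).  Counts are Poisson
#'   draws unless `fixed_counts = TRUE` (then rounded means, for exact
#'   expectation checks).
#' @param introgression Optional [introgression_scenario()].
#' @param rate_multipliers Named positive reals multiplying branch
#'   intensities (and the introgression windows on the matching stems);
#'   default 1 everywhere.
#' @param fixed_counts Use deterministic per-branch counts.
#' @param seed Integer seed; mandatory (a config must pin its
#'   randomness).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(clade_pair = c("R", "B"), t_internal = 1,
                       intensity = c(internal = 10, R = 0, B = 0, C = 0,
                                     deep = 0),
                       introgression = NULL,
                       rate_multipliers = c(internal = 1, R = 1, B = 1,
                                            C = 1, deep = 1),
                       fixed_counts = FALSE, seed) {
  stopifnot(length(clade_pair) == 2,
            all(clade_pair %in% c("R", "B", "C")),
            t_internal > 0)
  if (missing(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' is mandatory in a simulation config", call. = FALSE)
  full <- c(internal = 0, R = 0, B = 0, C = 0, deep = 0)
  full[names(intensity)] <- intensity
  if (any(full < 0)) stop("intensities must be >= 0", call. = FALSE)
  mult <- c(internal = 1, R = 1, B = 1, C = 1, deep = 1)
  mult[names(rate_multipliers)] <- rate_multipliers
  if (any(mult <= 0)) stop("rate multipliers must be > 0", call. = FALSE)
  if (!is.null(introgression))
    stopifnot(inherits(introgression, "introgression_scenario"))
  structure(list(clade_pair = sort(clade_pair), t_internal = t_internal,
                 intensity = full, introgression = introgression,
                 rate_multipliers = mult, fixed_counts = fixed_counts,
                 reference = "R", seed = as.integer(seed)),
            class = "sim_config")
}

#' The 4-taxon scaffold tree of a simulation config
#'
#' @param config A [sim_config()].
#' @param observed If `TRUE`, returns the scaffold for the *observed*
#'   pair `(R, B)` regardless of the true pair -- the tree against which
#'   an analyst blind to the truth would polarize.
#' @return A rooted `phylo` object.
#' @export
sim_tree <- function(config, observed = FALSE) {
  pair <- if (observed) c("R", "B") else config$clade_pair
  third <- setdiff(c("R", "B", "C"), pair)
  ape::read.tree(text = sprintf("(((%s,%s),%s),O);", pair[1], pair[2],
                                third))
}

## One simulation draw at the level of presence patterns.  Returns a
## data.frame(pattern, origin) with one row per marker, pattern a
## comma-separated sorted taxon set; ascertainment NOT yet applied.
.simulate_patterns <- function(config) {
  lam <- config$intensity * config$rate_multipliers
  draw <- function(mean) {
    if (config$fixed_counts) round(mean) else stats::rpois(1, mean)
  }
  pats <- character(0); orig <- character(0)
  add <- function(pattern, origin, n) {
    if (n > 0) {
      pats <<- c(pats, rep(pattern, n))
      orig <<- c(orig, rep(origin, n))
    }
  }
  pair_id <- function(x, y) paste(sort(c(x, y)), collapse = ",")

  ## internal branch: ILS resolves each marker's topology
  n_int <- draw(lam[["internal"]])
  if (n_int > 0) {
    p_dis <- exp(-config$t_internal) / 3
    pair <- config$clade_pair
    others <- setdiff(c("R", "B", "C"), pair)
    alt1 <- pair_id(pair[1], others)
    alt2 <- pair_id(pair[2], others)
    topo <- sample(c(pair_id(pair[1], pair[2]), alt1, alt2), n_int,
                   replace = TRUE, prob = c(1 - 2 * p_dis, p_dis, p_dis))
    conc <- topo == pair_id(pair[1], pair[2])
    add_v <- function(tp, og) for (t in unique(tp)) add(t, og, sum(tp == t))
    add_v(topo[conc], "species")
    add_v(topo[!conc], "ILS")
  }

  ## terminal stems and the deep branch
  for (tx in c("R", "B", "C")) add(tx, "species", draw(lam[[tx]]))
  add("B,C,R", "species", draw(lam[["deep"]]))

  ## introgression
  sc <- config$introgression
  if (!is.null(sc)) {
    rec <- sc$recipient
    shared_pat <- pair_id("R", rec)
    if (sc$direction == "from_reference") {
      pool <- draw(sc$beta * config$rate_multipliers[["R"]])
      shared <- stats::rbinom(1, pool, sc$gamma)
      add(shared_pat, "introgression", shared)
      add("R", "species", pool - shared)
      add("R", "species", draw(sc$alpha * config$rate_multipliers[["R"]]))
    } else {
      pool <- draw(sc$beta * config$rate_multipliers[[rec]])
      shared <- stats::rbinom(1, pool, sc$gamma)
      add(shared_pat, "introgression", shared)
      add(rec, "species", pool - shared)
      add(rec, "species", draw(sc$alpha * config$rate_multipliers[[rec]]))
      ## equal-window insertions on the reference's own stem
      add("R", "species",
          draw((sc$alpha + sc$beta) * config$rate_multipliers[["R"]]))
    }
  }
  data.frame(pattern = pats, origin = orig, stringsAsFactors = FALSE)
}

#' Simulate an observable marker matrix under the ascertainment model
#'
#' Draws insertions per branch, resolves hemiplasy on the internal branch,
#' applies any introgression scenario, then drops every marker absent in
#' the reference taxon (the single-reference ascertainment filter).
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (the observable
#'   [marker_matrix()] over taxa R, B, C, O), `truth` (data.frame with
#'   one row per *generated* marker: locus, pattern, origin in
#'   species/ILS/introgression, and whether it survived ascertainment)
#'   and `tree` (the true species-tree scaffold).  Identical config and
#'   seed give identical output.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pat <- .simulate_patterns(config)
  taxa <- c("R", "B", "C", "O")
  n <- nrow(pat)
  loci <- sprintf("L%04d", seq_len(max(n, 1)))
  observable <- vapply(strsplit(pat$pattern, ","), function(s) "R" %in% s,
                       logical(1))
  truth <- data.frame(locus = if (n) loci[seq_len(n)] else character(0),
                      pattern = pat$pattern, origin = pat$origin,
                      observable = observable,
                      stringsAsFactors = FALSE)
  keep <- which(observable)
  calls <- matrix(ABSENT, nrow = 4, ncol = length(keep),
                  dimnames = list(taxa, truth$locus[keep]))
  for (j in seq_along(keep)) {
    present <- strsplit(truth$pattern[keep[j]], ",")[[1]]
    calls[present, j] <- PRESENT
  }
  mat <- if (length(keep)) marker_matrix(calls) else NULL
  list(matrix = mat, truth = truth, tree = sim_tree(config))
}

#' Write a simulated matrix and its ground truth
#'
#' Emits the same TSV dialect as [write_marker_matrix()] plus a sidecar
#' truth TSV (locus, pattern, origin, observable).
#'
#' @param sim Result of [simulate_markers()].
#' @param dir Output directory.
#' @return Paths of the files written, invisibly.
#' @export
write_simulated_markers <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "simulated_matrix.tsv")
  tp <- file.path(dir, "simulated_truth.tsv")
  if (!is.null(sim$matrix)) write_marker_matrix(sim$matrix, mp)
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mp, truth = tp))
}

## Observable (a, b) support counts and (d, e) ratio counts for one draw.
## With pipeline = TRUE the counts go through polarize -> count against
## the observed tree; the fast path tallies patterns directly (the two
## are equivalent on this scaffold, which a unit test asserts).
.sim_counts <- function(config, pipeline = FALSE) {
  pat <- .simulate_patterns(config)
  if (pipeline) {
    taxa <- c("R", "B", "C", "O")
    n <- nrow(pat)
    if (n == 0) return(c(a = 0, b = 0, d = 0, e = 0))
    calls <- matrix(ABSENT, 4, n,
                    dimnames = list(taxa, sprintf("L%04d", seq_len(n))))
    for (j in seq_len(n))
      calls[strsplit(pat$pattern[j], ",")[[1]], j] <- PRESENT
    keep <- calls["R", ] == PRESENT
    if (!any(keep)) return(c(a = 0, b = 0, d = 0, e = 0))
    mat <- marker_matrix(calls[, keep, drop = FALSE])
    obs_tree <- sim_tree(config, observed = TRUE)
    pol <- polarize_markers(mat, obs_tree, stringency = 1)
    spec <- trifurcation("R", "B", "C", reference = "R")
    cnt <- count_trifurcation(pol, spec)
    rc <- ratio_count_for_clade(pol, c("R", "B"), "R")
    c(a = cnt$t1, b = cnt$t2, d = rc$shared, e = rc$exclusive)
  } else {
    tab <- table(factor(pat$pattern,
                        levels = c("B,R", "C,R", "R", "B,C")))
    c(a = as.numeric(tab[["B,R"]]), b = as.numeric(tab[["C,R"]]),
      d = as.numeric(tab[["B,R"]]), e = as.numeric(tab[["R"]]))
  }
}

#' Empirical rejection rate of a test under a simulated null
#'
#' Simulates replicate marker sets under the configured model (typically
#' a null in which the blind tree is the true species tree, with either
#' ILS or introgression generating the observable markers), runs the
#' pipeline (ascertainment filter, polarization against the observed
#' tree, counting) and the named test on each replicate, and returns the
#' fraction of replicates rejecting at level `alpha` with an exact
#' binomial confidence interval.  Replicates with no informative markers
#' cannot reject.
#'
#' @param config A [sim_config()]; its seed pins the whole run.
#' @param test_id `"ils_symmetry"`, `"insertion_ratio"` or
#'   `"kksc_onedir"`.
#' @param alpha Nominal level (default 0.05).
#' @param replicates Number of replicates (>= 100).
#' @param gamma Gamma at which the insertion ratio test is applied
#'   (default 0.5); ignored for the other tests.
#' @param pipeline If `TRUE` (default) counts are derived by polarizing
#'   each simulated matrix against the observed tree; `FALSE` uses the
#'   equivalent direct pattern tally (much faster for large replicate
#'   counts).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list: `rate`, `rejections`, `replicates`, `conf_int`
#'   (exact binomial), `counts` (per-replicate a, b, d, e).
#' @export
test_calibration <- function(config, test_id = c("ils_symmetry",
                                                 "insertion_ratio",
                                                 "kksc_onedir"),
                             alpha = 0.05, replicates = 1000, gamma = 0.5,
                             pipeline = TRUE, conf_level = 0.95) {
  stopifnot(inherits(config, "sim_config"))
  test_id <- match.arg(test_id)
  if (replicates < 100)
    stop("use at least 100 replicates", call. = FALSE)
  set.seed(config$seed)
  cfg <- config
  cfg$seed <- NA  # inner draws share the stream seeded above
  counts <- matrix(0L, replicates, 4,
                   dimnames = list(NULL, c("a", "b", "d", "e")))
  rej <- logical(replicates)
  for (i in seq_len(replicates)) {
    cn <- .sim_counts_noseed(cfg, pipeline)
    counts[i, ] <- cn
    rej[i] <- switch(test_id,
      ils_symmetry = (cn[["a"]] + cn[["b"]]) > 0 &&
        ils_symmetry(cn[["a"]], cn[["b"]])$p_value <= alpha,
      kksc_onedir = (cn[["a"]] + cn[["b"]]) > 0 &&
        kksc_onedir(insertion_count(cn[["a"]], cn[["b"]], NA))$p_value <= alpha,
      insertion_ratio = (cn[["d"]] + cn[["e"]]) > 0 &&
        insertion_ratio_test(ratio_count(cn[["d"]], cn[["e"]]),
                             gamma)$p_value <= alpha)
  }
  k <- sum(rej)
  ci <- stats::binom.test(k, replicates, conf.level = conf_level)$conf.int
  list(rate = k / replicates, rejections = k, replicates = replicates,
       conf_int = as.numeric(ci), counts = as.data.frame(counts))
}

.sim_counts_noseed <- function(config, pipeline) {
  .sim_counts(config, pipeline = pipeline)
}
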