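## Presence/absence marker matrices and their polarization onto a rooted
## species tree under Dollo logic (one insertion, no precise excision).

PRESENT <- "+"
ABSENT  <- "-"
MISSING <- "?"

.state_synonyms <- stats::setNames(
  c("+", "+", "+", "+", "-", "-", "-", "-", "?", "?", "?", "?"),
  c("+", "1", "present", "p", "-", "0", "absent", "a",
    "?", "na", "", "missing"))

#' Construct a presence/absence marker matrix
#'
#' @param calls Character matrix, taxa in rows (rownames = taxon labels),
#'   loci in columns (colnames = locus identifiers).  Cells must be one
#'   of `+` (present), `-` (absent), `?` (missing), or a recognised
#'   synonym (`1`/`0`/`NA`).
#' @return An object of class `marker_matrix`.
#' @seealso [read_marker_matrix()], [polarize_markers()]
#' @export
marker_matrix <- function(calls) {
  if (!is.matrix(calls) || nrow(calls) == 0 || ncol(calls) == 0)
    stop("'calls' must be a non-empty matrix", call. = FALSE)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("'calls' needs taxon rownames and locus colnames", call. = FALSE)
  if (anyDuplicated(rownames(calls)))
    stop("duplicate taxon labels", call. = FALSE)
  if (anyDuplicated(colnames(calls)))
    stop("duplicate locus identifiers", call. = FALSE)
  norm <- matrix(NA_character_, nrow(calls), ncol(calls),
                 dimnames = dimnames(calls))
  raw <- ifelse(is.na(calls), "?", tolower(trimws(as.character(calls))))
  known <- matrix(raw %in% names(.state_synonyms), nrow(calls))
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown state symbol '%s' at taxon '%s', locus '%s'",
                 calls[bad[1], bad[2]], rownames(calls)[bad[1]],
                 colnames(calls)[bad[2]]), call. = FALSE)
  }
  norm[] <- .state_synonyms[raw]
  structure(list(calls = norm,
                 taxa = rownames(calls),
                 loci = colnames(calls)),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  tab <- table(factor(x$calls, levels = c(PRESENT, ABSENT, MISSING)))
  cat(sprintf("Marker matrix: %d taxa x %d loci (%d present, %d absent, %d missing)\n",
              length(x$taxa), length(x$loci),
              tab[[PRESENT]], tab[[ABSENT]], tab[[MISSING]]))
  invisible(x)
}

#' Read a marker matrix from a delimited text file
#'
#' Expects taxa as rows (first column taxon labels) and loci as columns
#' (header row of locus identifiers); cells in `{+,-,?}` or the synonyms
#' `{1,0,NA}`.
#'
#' @param path File path.
#' @param sep Field separator; default tab.
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("marker table is empty or has no locus columns", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  marker_matrix(m)
}

#' Write a marker matrix as TSV (round-trips with [read_marker_matrix()])
#'
#' @param x A [marker_matrix()].
#' @param path Output file path.
#' @param sep Field separator; default tab.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "marker_matrix"))
  df <- data.frame(taxon = x$taxa, x$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- tree helpers ----------------------------------------------------------

## Rooted-tree bookkeeping: tip sets for every branch (internal node stems
## and terminal branches), in tree tip labels.
.tree_clades <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("a rooted species tree is required (root it on an outgroup first)",
         call. = FALSE)
  ntip <- length(tree$tip.label)
  nodes <- seq_len(ntip + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

.check_taxa_on_tree <- function(taxa, tree) {
  bad <- setdiff(taxa, tree$tip.label)
  if (length(bad))
    stop("taxa absent from the tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
}

## ---- polarization ----------------------------------------------------------

#' Polarize one marker onto a branch of a rooted species tree
#'
#' Under Dollo logic a marker is inserted once and never precisely
#' excised, so its presence set defines the branch on which insertion
#' occurred -- provided the presence set matches one clade of the tree.
#' The marker is
#' * `CLEAN` if the present taxa are exactly the sampled members of one
#'   clade and at least `stringency` sampled lineages branching
#'   immediately below that clade contain a confirmed absence;
#' * `UNINFORMATIVE` if present in all, none, or a single sampled taxon;
#' * `INSUFFICIENT_OUTGROUP` if the clade condition holds but too few
#'   deeper lineages confirm absence;
#' * `AMBIGUOUS` otherwise (hemiplasy or homoplasy across branches is
#'   required to explain the pattern), with the minimal conflicting taxa
#'   recorded.
#'
#' Missing calls never break clade equality; a marker whose branch
#' assignment depends on missing cells is flagged.
#'
#' @param matrix A [marker_matrix()].
#' @param tree A rooted `phylo` tree whose tips cover the matrix taxa.
#' @param locus Locus identifier.
#' @param stringency Number of deeper lineages that must confirm absence
#'   (default 2).
#' @param strict_successive If `TRUE`, the `stringency` lineages must be
#'   the consecutive sister lineages immediately below the branch; by
#'   default any deeper lineages count.
#' @return An object of class `polarized_marker`: fields `locus`,
#'   `status`, `branch` (taxon set of the supported clade, for clean or
#'   insufficient-outgroup markers), `conflict` (taxa violating clade
#'   membership), `depends_on_missing`.
#' @export
polarize_marker <- function(matrix, tree, locus, stringency = 2,
                            strict_successive = FALSE) {
  stopifnot(inherits(matrix, "marker_matrix"))
  if (!locus %in% matrix$loci)
    stop(sprintf("locus '%s' not in matrix", locus), call. = FALSE)
  .check_taxa_on_tree(matrix$taxa, tree)
  clades <- .tree_clades(tree)
  .polarize_one(matrix, tree, locus, clades, stringency, strict_successive)
}

.polarize_one <- function(matrix, tree, locus, clades, stringency,
                          strict_successive) {
  calls <- matrix$calls[, locus]
  taxa <- matrix$taxa
  pres <- taxa[calls == PRESENT]
  abs_ <- taxa[calls == ABSENT]
  miss <- taxa[calls == MISSING]
  sampled <- c(pres, abs_)

  res <- list(locus = locus, status = NULL, branch = NULL,
              conflict = character(), conflict_note = NULL,
              depends_on_missing = FALSE)
  class(res) <- "polarized_marker"

  if (length(pres) <= 1 || length(abs_) == 0) {
    res$status <- "UNINFORMATIVE"
    return(res)
  }

  ## candidate branches: clades (restricted to matrix taxa) containing all
  ## presences, none of the absences; pick the smallest (most recent)
  ok <- vapply(clades, function(S) {
    Ss <- intersect(S, taxa)
    length(Ss) > 0 && all(pres %in% Ss) && !any(abs_ %in% Ss)
  }, logical(1))
  sizes <- vapply(clades, function(S) length(intersect(S, taxa)), integer(1))
  ## exclude the full sampled set (the root; no polarity)
  ok <- ok & sizes < length(taxa)
  if (!any(ok)) {
    ## no compatible branch: hemiplasy needed; minimal conflict = sampled
    ## members of the MRCA clade of the presences that are scored absent
    mrca_ok <- vapply(clades, function(S) all(pres %in% S), logical(1))
    S <- clades[mrca_ok][[which.min(sizes[mrca_ok])]]
    res$status <- "AMBIGUOUS"
    res$conflict <- sort(intersect(abs_, S))
    res$conflict_note <- sprintf(
      "presence set is not a clade; absent within the minimal containing clade: %s",
      paste(res$conflict, collapse = ","))
    return(res)
  }
  best <- which(ok)[which.min(sizes[ok])]
  S <- intersect(clades[[best]], taxa)
  res$branch <- sort(S)
  res$depends_on_missing <- any(miss %in% S) || sum(ok) > 1

  ## stringency: walk rootward from the branch, each step contributes the
  ## lineages branching off below the clade; count those with a confirmed
  ## (non-missing) absence
  below <- .deeper_lineages(tree, clades, best, taxa)
  has_absence <- vapply(below, function(L) any(abs_ %in% L), logical(1))
  enough <- if (strict_successive) {
    length(has_absence) >= stringency &&
      all(has_absence[seq_len(stringency)])
  } else {
    sum(has_absence) >= stringency
  }
  res$status <- if (enough || stringency == 0) "CLEAN"
                else "INSUFFICIENT_OUTGROUP"
  res
}

## Lineages branching immediately below a branch, ordered shallow -> deep:
## for each ancestor of the branch's node, the sister subtrees hanging off.
.deeper_lineages <- function(tree, clades, node, taxa) {
  anc <- phangorn::Ancestors(tree, node, type = "all")
  out <- list()
  child <- node
  for (a in anc) {
    sibs <- setdiff(phangorn::Children(tree, a), child)
    for (s in sibs) {
      L <- intersect(clades[[s]], taxa)
      if (length(L)) out[[length(out) + 1L]] <- L
    }
    child <- a
  }
  out
}

#' @export
print.polarized_marker <- function(x, ...) {
  cat(sprintf("%s: %s", x$locus, x$status))
  if (!is.null(x$branch))
    cat(sprintf(" [branch: %s]", paste(x$branch, collapse = ",")))
  if (length(x$conflict))
    cat(sprintf(" [conflict: %s]", paste(x$conflict, collapse = ",")))
  cat("\n")
  invisible(x)
}

#' Polarize every marker of a matrix
#'
#' @inheritParams polarize_marker
#' @return An object of class `polarized_markers` holding the matrix,
#'   tree, and one [polarize_marker()] result per locus; coerce with
#'   `as.data.frame()` for the polarization report (locus, status,
#'   branch, conflicts, missing-dependence).
#' @export
polarize_markers <- function(matrix, tree, stringency = 2,
                             strict_successive = FALSE) {
  stopifnot(inherits(matrix, "marker_matrix"))
  .check_taxa_on_tree(matrix$taxa, tree)
  clades <- .tree_clades(tree)
  results <- lapply(matrix$loci, function(l)
    .polarize_one(matrix, tree, l, clades, stringency, strict_successive))
  names(results) <- matrix$loci
  structure(list(matrix = matrix, tree = tree, stringency = stringency,
                 results = results),
            class = "polarized_markers")
}

#' @export
as.data.frame.polarized_markers <- function(x, ...) {
  data.frame(
    locus = names(x$results),
    status = vapply(x$results, `[[`, "", "status"),
    branch = vapply(x$results, function(r)
      if (is.null(r$branch)) "" else paste(r$branch, collapse = ","), ""),
    conflict = vapply(x$results, function(r)
      paste(r$conflict, collapse = ","), ""),
    depends_on_missing = vapply(x$results, `[[`, NA, "depends_on_missing"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.polarized_markers <- function(x, ...) {
  st <- table(vapply(x$results, `[[`, "", "status"))
  cat(sprintf("Polarization of %d loci on %d taxa (stringency %d):\n",
              length(x$results), length(x$matrix$taxa), x$stringency))
  for (s in names(st)) cat(sprintf("  %-22s %d\n", s, st[[s]]))
  invisible(x)
}

## ---- trifurcations ---------------------------------------------------------

#' Specify a trifurcation (three clade hypotheses) for counting
#'
#' @param clade_a,clade_b,clade_c Disjoint character vectors of taxon
#'   labels.  The three resolutions are (a,b), (a,c) and (b,c); the two
#'   containing the reference taxon's clade are observable, the third is
#'   the blind tree.
#' @param reference Reference-genome taxon label; must belong to exactly
#'   one clade.
#' @param ignore Optional taxa to set aside: their calls are disregarded
#'   when matching patterns, allowing composite counts that sum markers
#'   along successive branches (e.g. testing a placement "regardless of"
#'   an interleaved lineage).
#' @param label Optional node label for reports.
#' @return A `trifurcation` object; `blind_pair` is derived, never
#'   user-supplied.
#' @export
trifurcation <- function(clade_a, clade_b, clade_c, reference,
                         ignore = character(), label = NULL) {
  clades <- list(a = unique(clade_a), b = unique(clade_b),
                 c = unique(clade_c))
  all_t <- unlist(clades)
  if (anyDuplicated(all_t))
    stop("trifurcation clades must be disjoint", call. = FALSE)
  if (any(ignore %in% all_t))
    stop("'ignore' taxa cannot belong to a clade", call. = FALSE)
  in_clade <- vapply(clades, function(cl) reference %in% cl, logical(1))
  if (sum(in_clade) != 1)
    stop("reference taxon must belong to exactly one clade", call. = FALSE)
  structure(list(clades = clades, reference = reference,
                 ref_clade = names(clades)[in_clade],
                 blind_pair = names(clades)[!in_clade],
                 ignore = ignore, label = label),
            class = "trifurcation")
}

#' @export
print.trifurcation <- function(x, ...) {
  cat(sprintf("Trifurcation%s: {%s} | {%s} | {%s}; reference '%s' (blind pair: %s,%s)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              paste(x$clades$a, collapse = ","),
              paste(x$clades$b, collapse = ","),
              paste(x$clades$c, collapse = ","),
              x$reference, x$blind_pair[1], x$blind_pair[2]))
  invisible(x)
}

## Classify one locus against a trifurcation.  Returns a list(kind, pair):
## kind in {"support", "ambiguous", "uninformative"}; pair like "ab" when
## the locus supports or leans towards grouping clades a and b.
##
## A pattern supports resolution (X,Y) when it fits that tree without
## hemiplasy at the node: either the presence set is exactly X u Y (all
## sampled members of both, none of the third, nothing outside), or it is
## a genuine species-tree clade lying between X u Y and the full
## trifurcation -- an insertion on a deeper stem branch that still
## separates X u Y from the rest of the third clade (this is what lets a
## composite clade sum markers along successive branches).
.classify_at_node <- function(calls, spec, taxa, tree_clades) {
  keep <- !(taxa %in% spec$ignore)
  taxa <- taxa[keep]; calls <- calls[keep]
  pres <- taxa[calls == PRESENT]
  abs_ <- taxa[calls == ABSENT]
  miss <- taxa[calls == MISSING]
  tri_taxa <- unlist(spec$clades)
  outside <- setdiff(taxa, tri_taxa)
  o_pres <- intersect(pres, outside)

  touched <- vapply(spec$clades, function(cl) any(pres %in% cl), logical(1))
  full <- vapply(spec$clades, function(cl)
    !any(abs_ %in% cl) && any(pres %in% cl), logical(1))
  empty <- !touched

  if (sum(touched) <= 1)
    return(list(kind = "uninformative", pair = NA_character_))
  if (all(full))                       # deeper insertion, no signal here
    return(list(kind = "uninformative", pair = NA_character_))

  if (sum(touched) == 2 && all(full[touched]) && empty[!touched] &&
      length(o_pres) == 0) {
    pair <- paste(sort(names(spec$clades)[touched]), collapse = "")
    return(list(kind = "support", pair = pair))
  }

  ## deeper-stem support: presence matches a species-tree clade S with
  ## X u Y <= S < T_tri for some pair, and nothing outside
  if (length(o_pres) == 0 && sum(full) >= 2) {
    p <- list(pres = pres, abs = abs_, miss = miss)
    combos <- list(c("a", "b"), c("a", "c"), c("b", "c"))
    for (xy in combos) {
      if (!all(full[xy])) next
      z <- setdiff(names(spec$clades), xy)
      XY <- unlist(spec$clades[xy])
      Z <- spec$clades[[z]]
      hit <- any(vapply(tree_clades, function(S) {
        all(XY %in% S) && !all(Z %in% S) && .matches_branch(S, p)
      }, logical(1)))
      if (hit)
        return(list(kind = "support", pair = paste(sort(xy), collapse = "")))
    }
  }

  ## leaning: presence touches exactly two clades (multilevel conflict
  ## resolvable in favour of that pair)
  if (sum(touched) == 2)
    return(list(kind = "ambiguous",
                pair = paste(sort(names(spec$clades)[touched]),
                             collapse = "")))
  list(kind = "ambiguous", pair = NA_character_)
}

#' Tally markers for a trifurcation
#'
#' Counts the markers whose pattern fits one of the three resolutions of
#' the trifurcation without hemiplasy or homoplasy *at that node*: all
#' sampled members of two clades present, the third clade absent, and no
#' presence outside the trifurcation (taxa listed in the spec's `ignore`
#' set are disregarded; missing calls never break clade equality).  The
#' third slot is always unobservable under a reference-genome screen and
#' is returned as `X`; should the matrix nevertheless contain markers
#' supporting the blind pair, they are reported in the
#' `"blind_support"` attribute, not silently dropped.
#'
#' @param polarized A [polarize_markers()] result.
#' @param spec A [trifurcation()].
#' @param include_ambiguous If `TRUE`, markers whose conflicting pattern
#'   still leans towards one observable topology (presence touching both
#'   of its clades and none of the third) are added to the returned
#'   count; they are always itemised separately in the
#'   `"ambiguous_loci"` attribute, never silently merged.
#' @return An [insertion_count()] `[a b X]` with attributes
#'   `"support_loci"`, `"ambiguous_loci"` and `"blind_support"`.
#' @export
count_trifurcation <- function(polarized, spec, include_ambiguous = FALSE) {
  stopifnot(inherits(polarized, "polarized_markers"),
            inherits(spec, "trifurcation"))
  taxa <- polarized$matrix$taxa
  tri_taxa <- unlist(spec$clades)
  bad <- setdiff(c(tri_taxa, spec$ignore, spec$reference), taxa)
  if (length(bad))
    stop("trifurcation names taxa not in the matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)

  tree_clades <- unique(lapply(.tree_clades(polarized$tree), function(S)
    sort(setdiff(intersect(S, taxa), spec$ignore))))
  tree_clades <- Filter(length, tree_clades)
  cls <- lapply(polarized$matrix$loci, function(l)
    .classify_at_node(polarized$matrix$calls[, l], spec, taxa,
                      tree_clades))
  names(cls) <- polarized$matrix$loci

  pairs <- c(paste(sort(c(spec$ref_clade, spec$blind_pair[1])), collapse = ""),
             paste(sort(c(spec$ref_clade, spec$blind_pair[2])), collapse = ""))
  blind <- paste(sort(spec$blind_pair), collapse = "")

  tally <- function(kind, pair) names(cls)[vapply(cls, function(z)
    z$kind == kind && !is.na(z$pair) && z$pair == pair, logical(1))]

  sup1 <- tally("support", pairs[1]); sup2 <- tally("support", pairs[2])
  amb1 <- tally("ambiguous", pairs[1]); amb2 <- tally("ambiguous", pairs[2])
  blind_sup <- tally("support", blind)
  if (length(blind_sup))
    warning("markers support the blind pair (unexpected under a ",
            "reference-genome screen): ",
            paste(blind_sup, collapse = ", "), call. = FALSE)

  t1 <- length(sup1) + if (include_ambiguous) length(amb1) else 0L
  t2 <- length(sup2) + if (include_ambiguous) length(amb2) else 0L
  lab <- .topology_labels(spec)
  cnt <- insertion_count(t1, t2, NA, labels = lab)
  attr(cnt, "support_loci") <- list(t1 = sup1, t2 = sup2)
  attr(cnt, "ambiguous_loci") <- list(t1 = amb1, t2 = amb2)
  attr(cnt, "blind_support") <- blind_sup
  attr(cnt, "include_ambiguous") <- include_ambiguous
  cnt
}

.topology_labels <- function(spec) {
  nm <- function(k) {
    cl <- spec$clades[[k]]
    if (!is.null(spec$label)) k
    else if (length(cl) <= 2) paste(cl, collapse = "+") else
      sprintf("%s..+%d", cl[1], length(cl) - 1)
  }
  r <- spec$ref_clade; b <- spec$blind_pair
  c(sprintf("(%s,%s)", nm(r), nm(b[1])),
    sprintf("(%s,%s)", nm(r), nm(b[2])),
    sprintf("(%s,%s) [blind]", nm(b[1]), nm(b[2])))
}

## ---- ratio counts ----------------------------------------------------------

#' Count markers on successive reference-stem branches for the ratio test
#'
#' `d` counts the clean markers on the stem of `clade` (the clade joining
#' the reference lineage to its hypothesized sister); `e` counts markers
#' on the immediately shallower branch of the reference path.  When a
#' composite placement sums markers along several successive stem
#' branches, give the largest clade as `within`: every branch `S` with
#' `clade` ⊆ `S` ⊆ `within` on the reference path then contributes to
#' `d`.
#'
#' @param polarized A [polarize_markers()] result.
#' @param clade Character vector of taxon labels; must be a clade of the
#'   tree (restricted to the sampled taxa) containing the reference.
#' @param reference Reference-genome taxon label.
#' @param within Optional superset clade for composite counts; default
#'   `clade`.
#' @return A [ratio_count()] `(d, e)`; if no markers are found at all the
#'   attribute `"untestable"` is `TRUE`.
#' @export
ratio_count_for_clade <- function(polarized, clade, reference,
                                  within = NULL) {
  stopifnot(inherits(polarized, "polarized_markers"))
  tree <- polarized$tree
  taxa <- polarized$matrix$taxa
  if (is.null(within)) within <- clade
  if (!all(clade %in% within))
    stop("'within' must contain 'clade'", call. = FALSE)
  if (!reference %in% clade)
    stop("'clade' must contain the reference taxon", call. = FALSE)
  .check_taxa_on_tree(intersect(c(clade, within), tree$tip.label), tree)

  clades <- .tree_clades(tree)
  restr <- lapply(clades, function(S) sort(intersect(S, taxa)))
  clade <- sort(intersect(clade, taxa))
  within <- sort(intersect(within, taxa))

  ref_tip <- match(reference, tree$tip.label)
  if (is.na(ref_tip))
    stop("reference taxon not on the tree", call. = FALSE)
  path <- c(ref_tip, phangorn::Ancestors(tree, ref_tip, type = "all"))

  node_of <- function(set) {
    hit <- which(vapply(restr, identical, logical(1), set))
    ## prefer a node on the reference path
    hit_on <- intersect(hit, path)
    if (length(hit_on)) hit_on[1] else if (length(hit)) hit[1] else NA
  }
  clade_node <- node_of(clade)
  if (is.na(clade_node) || !clade_node %in% path)
    stop("'clade' is not a reference-path clade of the tree", call. = FALSE)

  ## d branches: reference-path nodes whose sampled tip set S satisfies
  ## clade <= S <= within
  d_sets <- Filter(function(S) all(clade %in% S) && all(S %in% within),
                   restr[intersect(path, which(vapply(restr, length, 1L) >=
                                                 length(clade)))])
  ## e branch: the reference-path child of the clade's crown node
  children <- phangorn::Children(tree, clade_node)
  e_node <- intersect(children, path)
  if (!length(e_node))
    stop("no shallower reference-path branch below the clade", call. = FALSE)
  e_set <- restr[[e_node[1]]]

  pat <- .locus_patterns(polarized$matrix)
  d <- sum(vapply(pat, function(p)
    any(vapply(d_sets, .matches_branch, logical(1), p = p)), logical(1)))
  e <- sum(vapply(pat, function(p) .matches_branch(e_set, p), logical(1)))
  rc <- ratio_count(d, e)
  attr(rc, "untestable") <- (d + e) == 0
  attr(rc, "d_branches") <- d_sets
  attr(rc, "e_branch") <- e_set
  rc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Per-locus presence pattern for branch matching.
.locus_patterns <- function(matrix) {
  lapply(matrix$loci, function(l) {
    calls <- matrix$calls[, l]
    list(pres = matrix$taxa[calls == PRESENT],
         abs = matrix$taxa[calls == ABSENT],
         miss = matrix$taxa[calls == MISSING])
  })
}

## A locus matches a branch clade S when every sampled member of S is
## present (missing calls never break clade equality), no taxon outside S
## is present, and at least one presence and one absence are observed.
.matches_branch <- function(S, p) {
  length(p$pres) > 0 && length(p$abs) > 0 &&
    all(p$pres %in% S) && !any(p$abs %in% S) &&
    all(setdiff(S, p$pres) %in% p$miss)
}
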