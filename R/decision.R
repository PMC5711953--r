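#' Configuration for the blind-tree decision workflow
#'
#' @param alpha Significance level for all tests (default 0.05).
#' @param trigger The ILS symmetry and insertion ratio tests are only run
#'   when the one-directional KKSC P_B is at or below this threshold
#'   (default 0.1); below it there is a support signal worth dissecting.
#' @param gammas Genome-sharing fractions for the insertion ratio test
#'   (default `c(0.5, 0.2)`: the extreme F1-hybrid scenario and a
#'   moderate-introgression scenario).
#' @param decisive_gamma The gamma whose ratio-test rejection is required
#'   before the blind tree may be rejected (default 0.5, the conservative
#'   scenario).  Rejection only under a smaller gamma is reported but
#'   does not reject the blind tree.
#' @param force Run the ILS/ratio tests even when `P_B > trigger`.
#' @param bonferroni_n If greater than 1, a Bonferroni correction across
#'   this many nodes is applied to `alpha` before verdicts are formed (no
#'   cross-node correction by default).
#' @return A list of class `decision_config`.
#' @export
decision_config <- function(alpha = 0.05, trigger = 0.1,
                            gammas = c(0.5, 0.2), decisive_gamma = 0.5,
                            force = FALSE, bonferroni_n = 1) {
  stopifnot(alpha > 0, alpha < 1, trigger > 0, trigger <= 1,
            all(gammas > 0), all(gammas < 1),
            decisive_gamma %in% gammas, bonferroni_n >= 1)
  structure(list(alpha = alpha, trigger = trigger, gammas = gammas,
                 decisive_gamma = decisive_gamma, force = force,
                 bonferroni_n = bonferroni_n),
            class = "decision_config")
}

#' Evaluate one trifurcation: the three-argument blind-tree workflow
#'
#' A significant one-directional KKSC test only shows asymmetric support
#' between the two observable topologies; it cannot on its own rule out
#' the blind tree being the species tree.  The blind tree is rejected
#' only when both remaining hypotheses are rejected: H_ILS (observable
#' markers are hemiplasic from incomplete lineage sorting; tested by the
#' two-tailed symmetry test) and H_Introgression (observable markers
#' were shared by gene flow; tested by the insertion ratio test at the
#' decisive gamma).  A-priori evidence is carried as free text and never
#' machine-scored.
#'
#' @param count An [insertion_count()]; with a blind third slot the
#'   one-directional KKSC test is run, with all slots observed only the
#'   multi-directional test applies (no bias regime).
#' @param ratio Optional [ratio_count()] for the insertion ratio test.
#' @param config A [decision_config()].
#' @param node_label Optional label for reports.
#' @param apriori Optional free-text note on a-priori evidence.
#' @return An object of class `node_verdict`: fields `node_label`,
#'   `count`, `ratio`, `results` (named list of `retro_test`),
#'   `blind_rejected` (`"yes"`, `"no"` or `"untested"`) and `rationale`
#'   (ordered character vector of satisfied/failed criteria).
#' @examples
#' v <- evaluate_node(insertion_count(9, 1, "X"), ratio_count(9, 2))
#' v$blind_rejected  # "yes"
#' @export
evaluate_node <- function(count, ratio = NULL, config = decision_config(),
                          node_label = NULL, apriori = NULL) {
  stopifnot(inherits(count, "insertion_count"),
            inherits(config, "decision_config"))
  if (!is.null(ratio)) stopifnot(inherits(ratio, "ratio_count"))
  alpha <- config$alpha / config$bonferroni_n

  results <- list()
  rationale <- character()

  if (!is.na(count$t3)) {
    ## fully observed: no ascertainment bias, no blind tree to reject
    results$kksc <- kksc_multi(count)
    rationale <- c(rationale,
                   sprintf("multi-directional KKSC P = %s (all topologies observable; no blind tree)",
                           format_pvalue(results$kksc$p_value)))
    return(.new_verdict(node_label, count, ratio, results, "untested",
                        rationale, apriori))
  }

  results$kksc <- kksc_onedir(count)
  pb <- results$kksc$p_value
  rationale <- c(rationale, sprintf("one-directional KKSC P_B = %s (%s trigger %.2g)",
                                    format_pvalue(pb),
                                    if (pb <= config$trigger) "<=" else ">",
                                    config$trigger))
  triggered <- pb <= config$trigger
  if (!triggered && !config$force)
    return(.new_verdict(node_label, count, ratio, results, "untested",
                        rationale, apriori))

  results$ils <- ils_symmetry(count$t1, count$t2)
  ils_rej <- results$ils$p_value <= alpha
  rationale <- c(rationale,
                 sprintf("ILS symmetry P_ILS = %s: H_ILS %s at alpha = %g",
                         format_pvalue(results$ils$p_value),
                         if (ils_rej) "rejected" else "not rejected", alpha))

  if (is.null(ratio)) {
    rationale <- c(rationale,
                   "ratio pattern unavailable: H_Introgression untestable")
    return(.new_verdict(node_label, count, ratio, results, "untested",
                        rationale, apriori))
  }

  ratio_rej <- logical(0)
  for (g in config$gammas) {
    r <- insertion_ratio_test(ratio, g)
    key <- sprintf("ratio_g%g", g)
    results[[key]] <- r
    rej <- r$p_value <= alpha
    ratio_rej[as.character(g)] <- rej
    rationale <- c(rationale,
                   sprintf("insertion ratio P_R%g = %s (N = %g): H_Introgression(gamma=%g) %s",
                           100 * g, format_pvalue(r$p_value), r$n_bound, g,
                           if (rej) "rejected" else "not rejected"))
  }

  decisive <- ratio_rej[[as.character(config$decisive_gamma)]]
  if (ils_rej && decisive) {
    verdict <- "yes"
    rationale <- c(rationale,
                   "both H_ILS and H_Introgression rejected at the decisive gamma: blind tree rejected")
  } else {
    verdict <- "no"
    if (ils_rej && any(ratio_rej))
      rationale <- c(rationale,
                     sprintf("rejected under moderate-introgression assumption only (gamma < %g): blind tree retained",
                             config$decisive_gamma))
    else
      rationale <- c(rationale,
                     "blind tree not rejected: both H_ILS and H_Introgression must fail")
  }
  if (!triggered)
    rationale <- c(rationale, "tests forced despite P_B above trigger")
  .new_verdict(node_label, count, ratio, results, verdict, rationale,
               apriori)
}

.new_verdict <- function(node_label, count, ratio, results, blind_rejected,
                         rationale, apriori) {
  structure(list(node_label = node_label, count = count, ratio = ratio,
                 results = results, blind_rejected = blind_rejected,
                 rationale = rationale, apriori_note = apriori),
            class = "node_verdict")
}

#' @export
print.node_verdict <- function(x, ...) {
  cat(sprintf("Node%s: count %s%s -> blind tree %s\n",
              if (is.null(x$node_label)) "" else paste0(" ", x$node_label),
              format(x$count),
              if (is.null(x$ratio)) "" else paste0(", ratio ", format(x$ratio)),
              switch(x$blind_rejected, yes = "REJECTED",
                     no = "not rejected", untested = "untested")))
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  if (!is.null(x$apriori_note))
    cat("  a priori: ", x$apriori_note, "\n", sep = "")
  invisible(x)
}

#' Tabulate node verdicts in the style of a trifurcation results table
#'
#' One row per node: insertion pattern, tested topology, P_B (or the
#' multi-directional P), P_ILS, ratio pattern and one P_R column per
#' gamma, with dashes for tests that were not run.  P-values are
#' formatted to 4 decimals with `"<0.0001"` below 0.00005.
#'
#' @param verdicts A list of [evaluate_node()] results.
#' @return A `data.frame`; write with [write_node_report()].
#' @export
node_report <- function(verdicts) {
  if (!length(verdicts)) stop("no verdicts to report", call. = FALSE)
  stopifnot(all(vapply(verdicts, inherits, TRUE, "node_verdict")))
  gammas <- sort(unique(unlist(lapply(verdicts, function(v) {
    ks <- grep("^ratio_g", names(v$results), value = TRUE)
    as.numeric(sub("^ratio_g", "", ks))
  }))), decreasing = TRUE)
  dash <- "-"
  rows <- lapply(verdicts, function(v) {
    topo <- if (!is.null(v$count$labels)) v$count$labels[1] else dash
    pb <- format_pvalue(v$results$kksc$p_value)
    ils <- if (!is.null(v$results$ils))
      format_pvalue(v$results$ils$p_value) else dash
    rp <- if (!is.null(v$ratio) && any(grepl("^ratio_g", names(v$results))))
      format(v$ratio) else dash
    row <- data.frame(
      node = v$node_label %||% dash,
      insertion_pattern = format(v$count),
      topology = topo,
      P_B = pb, P_ILS = ils, ratio_pattern = rp,
      stringsAsFactors = FALSE)
    for (g in gammas) {
      r <- v$results[[sprintf("ratio_g%g", g)]]
      row[[sprintf("P_R%g", 100 * g)]] <-
        if (is.null(r)) dash else format_pvalue(r$p_value)
    }
    row$blind_rejected <- v$blind_rejected
    row
  })
  do.call(rbind, rows)
}

#' Write a node report as TSV or Markdown, or dump verdicts as JSON
#'
#' @param verdicts A list of [evaluate_node()] results.
#' @param path Output file.
#' @param format `"tsv"`, `"markdown"` or `"json"` (the JSON dump keeps
#'   every intermediate unrounded p-value).
#' @return `path`, invisibly.
#' @export
write_node_report <- function(verdicts, path,
                              format = c("tsv", "markdown", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    dump <- lapply(verdicts, function(v) {
      list(node = v$node_label,
           count = c(v$count$t1, v$count$t2,
                     if (is.na(v$count$t3)) "X" else v$count$t3),
           ratio = if (is.null(v$ratio)) NULL
                   else c(v$ratio$shared, v$ratio$exclusive),
           tests = lapply(v$results, function(r)
             list(test = r$test_id, p_value = r$p_value,
                  gamma = r$gamma, n_bound = r$n_bound, tail = r$tail)),
           blind_rejected = v$blind_rejected,
           rationale = v$rationale,
           apriori = v$apriori_note)
    })
    jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(path))
  }
  tab <- node_report(verdicts)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    body <- apply(tab, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, body), path)
  }
  invisible(path)
}
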