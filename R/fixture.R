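## Synthetic reconstruction of the published kangaroo/wallaby
## retrotransposon marker set: a 16-taxon presence/absence matrix whose
## polarization reproduces the published trifurcation insertion patterns,
## ratio patterns and conflicting loci.  The marker counts per branch are
## the published ones; the cell-level matrix is a synthetic encoding of
## them (locus names K*/C* are positional, not accessioned loci).

.fx_taxa <- list(
  reference = "Macropus_eugenii",
  core_nota = c("Macropus_eugenii", "Macropus_parma", "Macropus_agilis",
                "Macropus_rufogriseus"),
  irma = "Macropus_irma",
  wallabia = "Wallabia_bicolor",
  osphranter = c("Macropus_robustus", "Macropus_bernardus",
                 "Macropus_rufus", "Macropus_antilopinus"),
  macropus_sg = c("Macropus_giganteus", "Macropus_fuliginosus"),
  onychogalea = "Onychogalea_unguifera",
  lagorchestes = "Lagorchestes_hirsutus",
  thylogale = "Thylogale_thetis",
  lagostrophus = "Lagostrophus_fasciatus"
)

.fx_newick <- paste0(
  "(Lagostrophus_fasciatus,(Thylogale_thetis,(Lagorchestes_hirsutus,",
  "(Onychogalea_unguifera,((Macropus_giganteus,Macropus_fuliginosus),",
  "((Macropus_robustus,(Macropus_bernardus,(Macropus_rufus,",
  "Macropus_antilopinus))),(Wallabia_bicolor,(Macropus_irma,",
  "(Macropus_rufogriseus,(Macropus_agilis,(Macropus_eugenii,",
  "Macropus_parma)))))))))));")

#' Packaged kangaroo/wallaby marker fixture
#'
#' A 16-taxon, 29-locus presence/absence matrix of KERV-1 solo-LTR style
#' markers ascertained in the tammar wallaby (*Macropus eugenii*)
#' reference genome, together with the rooted species tree and the eight
#' trifurcation specifications of the major nodes.  The matrix is a
#' synthetic encoding of the published per-branch marker counts: 21
#' clean markers on the stem branches of the reference lineage (plus two
#' within core *M.* (*Notamacropus*)) and 8 conflicting markers (C1-C8)
#' requiring hemiplasy.  A few *M. parma* cells are missing, mirroring
#' limited DNA availability for that species.
#'
#' @return A list:
#' \describe{
#'   \item{matrix}{the [marker_matrix()];}
#'   \item{tree}{the rooted `phylo` species tree;}
#'   \item{reference}{the reference taxon label;}
#'   \item{nodes}{a named list (i..viii) of node definitions, each with a
#'     [trifurcation()] `spec` and, where the ratio test applies,
#'     `ratio_clade` / `ratio_within` taxon sets.}
#' }
#' @export
macropus_fixture <- function() {
  g <- .fx_taxa
  cN <- g$core_nota
  nota <- c(g$irma, cN)
  osph <- g$osphranter
  mac <- g$macropus_sg
  wall <- g$wallabia
  mw <- c(wall, nota, osph, mac)          # Macropus s.l. + Wallabia
  taxa <- c(cN[c(1, 2)], cN[c(3, 4)], g$irma, wall, osph, mac,
            g$onychogalea, g$lagorchestes, g$thylogale, g$lagostrophus)

  pat <- list(
    ## clean markers, shallow to deep along the reference stem lineage
    K01 = nota,              K02 = nota,
    K03 = c(wall, nota),     K04 = c(wall, nota), K05 = c(wall, nota),
    K06 = c(wall, nota),     K07 = c(wall, nota), K08 = c(wall, nota),
    K09 = c(wall, nota, osph), K10 = c(wall, nota, osph),
    K11 = c(wall, nota, osph),
    K12 = mw, K13 = mw, K14 = mw,
    K15 = c(mw, g$onychogalea),
    K16 = setdiff(taxa, g$lagostrophus), K17 = setdiff(taxa, g$lagostrophus),
    K18 = setdiff(taxa, g$lagostrophus), K19 = setdiff(taxa, g$lagostrophus),
    K20 = c("Macropus_eugenii", "Macropus_parma"),
    K21 = c("Macropus_eugenii", "Macropus_parma"),
    ## conflicting markers (hemiplasy across internal branches)
    C1 = c(wall, cN),
    C2 = c(nota, osph, mac),
    C3 = c(nota, osph),
    C4 = c(nota, mac),
    C5 = c(wall, nota, mac),
    C6 = c(wall, "Macropus_eugenii", "Macropus_parma", "Macropus_agilis"),
    C7 = c(wall, "Macropus_eugenii", "Macropus_parma"),
    C8 = c(wall, "Macropus_rufogriseus")
  )
  calls <- matrix("-", nrow = length(taxa), ncol = length(pat),
                  dimnames = list(taxa, names(pat)))
  for (l in names(pat)) calls[pat[[l]], l] <- "+"
  ## untested M. parma cells (limited DNA availability)
  calls["Macropus_parma", c("K15", "K16", "C2")] <- "?"
  mat <- marker_matrix(calls)
  tree <- ape::read.tree(text = .fx_newick)
  ref <- g$reference

  nodes <- list(
    i = list(spec = trifurcation(g$irma, cN, wall, ref, label = "i"),
             ratio_clade = NULL),
    ii = list(spec = trifurcation(wall, nota, osph, ref, label = "ii"),
              ratio_clade = c(wall, nota)),
    iii = list(spec = trifurcation(g$irma, cN, osph, ref,
                                   ignore = wall, label = "iii"),
               ratio_clade = nota, ratio_within = c(wall, nota)),
    iv = list(spec = trifurcation(wall, nota, c(osph, mac), ref,
                                  label = "iv"),
              ratio_clade = c(wall, nota),
              ratio_within = c(wall, nota, osph)),
    v = list(spec = trifurcation(c(wall, nota), osph, mac, ref,
                                 label = "v"),
             ratio_clade = NULL),
    vi = list(spec = trifurcation(c(wall, nota, osph), mac,
                                  g$onychogalea, ref, label = "vi"),
              ratio_clade = NULL),
    vii = list(spec = trifurcation(mw, g$onychogalea, g$lagorchestes,
                                   ref, label = "vii"),
               ratio_clade = NULL),
    viii = list(spec = trifurcation(c(mw, g$onychogalea, g$lagorchestes),
                                    g$thylogale, g$lagostrophus, ref,
                                    label = "viii"),
                ratio_clade = setdiff(taxa, g$lagostrophus))
  )
  list(matrix = mat, tree = tree, reference = ref, nodes = nodes)
}

#' Run the full blind-tree analysis of the packaged fixture
#'
#' Polarizes the fixture matrix, tallies every node's insertion and
#' ratio patterns, and evaluates each node with the decision workflow.
#'
#' @param config A [decision_config()].
#' @param include_ambiguous Also compute, per node, the sensitivity
#'   count that adds resolvable conflicting markers (reported in the
#'   `"ambiguous_count"` attribute of each verdict's count).
#' @return A named list (i..viii) of [evaluate_node()] verdicts.
#' @export
macropus_analysis <- function(config = decision_config(),
                              include_ambiguous = FALSE) {
  fx <- macropus_fixture()
  pol <- polarize_markers(fx$matrix, fx$tree)
  verdicts <- list()
  for (nm in names(fx$nodes)) {
    nd <- fx$nodes[[nm]]
    cnt <- count_trifurcation(pol, nd$spec,
                              include_ambiguous = include_ambiguous)
    rc <- if (!is.null(nd$ratio_clade))
      ratio_count_for_clade(pol, nd$ratio_clade, fx$reference,
                            within = nd$ratio_within %||% NULL)
    verdicts[[nm]] <- evaluate_node(cnt, rc, config, node_label = nm)
  }
  verdicts
}

#' Write the packaged fixture to disk
#'
#' Emits the synthetic marker matrix (TSV), the species tree (Newick)
#' and the node specifications (YAML) in the formats the command-line
#' `scan` subcommand consumes.  Output is deterministic: re-running
#' produces identical bytes.
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_macropus_fixture <- function(dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  fx <- macropus_fixture()
  mp <- file.path(dir, "macropus_markers_synthetic.tsv")
  tp <- file.path(dir, "macropus_tree.nwk")
  np <- file.path(dir, "macropus_nodes.yml")
  write_marker_matrix(fx$matrix, mp)
  ape::write.tree(fx$tree, tp)
  nodes <- lapply(fx$nodes, function(nd) {
    out <- list(clade_a = nd$spec$clades$a, clade_b = nd$spec$clades$b,
                clade_c = nd$spec$clades$c)
    if (length(nd$spec$ignore)) out$ignore <- nd$spec$ignore
    if (!is.null(nd$ratio_clade)) out$ratio_clade <- nd$ratio_clade
    if (!is.null(nd$ratio_within)) out$ratio_within <- nd$ratio_within
    out
  })
  yaml::write_yaml(list(reference = fx$reference, nodes = nodes), np)
  invisible(c(matrix = mp, tree = tp, nodes = np))
}
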