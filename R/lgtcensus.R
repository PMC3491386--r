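# Two-tier lateral-gene-transfer analysis: a best-hit taxonomic census over
# conserved gene models, and per-gene sister-clade classification of gene
# trees. A gene is called laterally acquired when, after rooting, the sister
# clade of the query (with conspecific paralogs merged in) contains no
# stramenopiles.

#' Taxon label of a tree leaf
#'
#' Leaf labels may carry a gene identifier after a `|` separator
#' (`Genus|gene001`); everything before the first separator is the taxon.
#'
#' @param labels character vector of leaf labels.
#' @return character vector of taxon labels.
#' @export
taxonFromLabel <- function(labels) sub("\\|.*$", "", labels)

.stramLookup <- function(lineages) {
  stats::setNames(lineages$is_stramenopile, lineages$taxon)
}

#' Best-hit taxonomic census of conserved gene models
#'
#' Retains best hits at or below the E-value cutoff, tallies genes per
#' lineage group, and separates vertical candidates (stramenopile best hit)
#' from lateral-transfer candidates (non-stramenopile best hit). Hits to
#' taxa absent from the lineage map are counted as unresolved.
#'
#' @param hits data.frame with `gene_id`, `hit_taxon`, `evalue`.
#' @param lineages lineage map data.frame with `taxon`, logical
#'   `is_stramenopile` and optionally a `group` column.
#' @param eCutoff conservative E-value cutoff (default 1e-30).
#' @return a list with `counts` (genes per group), `vertical`,
#'   `lgtCandidates`, `unresolved` and `nRetained`.
#' @export
besthitCensus <- function(hits, lineages, eCutoff = 1e-30) {
  stopifnot(eCutoff > 0)
  kept <- hits[hits$evalue <= eCutoff, , drop = FALSE]
  stram <- .stramLookup(lineages)
  known <- kept$hit_taxon %in% names(stram)
  if (any(!known))
    message(sum(!known), " hit(s) to taxa missing from the lineage map; ",
            "counted as unresolved")
  groupOf <- if ("group" %in% names(lineages))
    stats::setNames(lineages$group, lineages$taxon)
  else
    stats::setNames(ifelse(lineages$is_stramenopile, "stramenopile", "other"),
                    lineages$taxon)
  grp <- ifelse(known, groupOf[kept$hit_taxon], "unresolved")
  counts <- as.data.frame(table(group = grp), stringsAsFactors = FALSE)
  names(counts)[2] <- "n_genes"
  isStram <- stram[kept$hit_taxon]
  list(
    counts = counts,
    vertical = sum(known & isStram, na.rm = TRUE),
    lgtCandidates = sum(known & !isStram, na.rm = TRUE),
    unresolved = sum(!known),
    nRetained = nrow(kept)
  )
}

.tipsUnder <- function(tree, node) {
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(node)
  phangorn::Descendants(tree, node, type = "tips")[[1]]
}

#' Sister-clade classification of one gene tree
#'
#' Roots the tree (midpoint by default), merges conspecific paralogs of the
#' query into the query clade, extracts that clade's sister, and classifies:
#' `lgt_confirmed` when the sister contains no stramenopile leaves,
#' `vertical` when it contains only stramenopiles, and `unresolved` when it
#' is a heterogeneous mix (or when the sister cannot be determined, e.g. a
#' two-leaf tree or a query clade spanning the root). Sister taxa missing
#' from the lineage map also give `unresolved`.
#'
#' @param tree an [ape::phylo] object or a newick string.
#' @param queryLeaf the query's leaf label (must be present).
#' @param lineages lineage map data.frame (`taxon`, `is_stramenopile`).
#' @param rooting `"midpoint"` or `"outgroup"`.
#' @param outgroup leaf labels to root on when `rooting = "outgroup"`.
#' @return a list with `gene_id`, `verdict` and `sister_taxa`.
#' @examples
#' lin <- data.frame(taxon = c("Toceanica", "Bacillus", "Tpseudonana",
#'                             "Ptricornutum"),
#'                   is_stramenopile = c(TRUE, FALSE, TRUE, TRUE))
#' tr <- "((Toceanica|g1:1,Bacillus:1):1,(Tpseudonana:1,Ptricornutum:1):1);"
#' classifyTree(tr, "Toceanica|g1", lin)$verdict
#' @export
classifyTree <- function(tree, queryLeaf, lineages,
                         rooting = c("midpoint", "outgroup"),
                         outgroup = NULL) {
  rooting <- match.arg(rooting)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!queryLeaf %in% tree$tip.label)
    stop("query leaf '", queryLeaf, "' is not in the tree")
  if (length(tree$tip.label) < 3L)
    return(list(gene_id = queryLeaf, verdict = "unresolved",
                sister_taxa = character()))
  tree <- if (rooting == "midpoint") {
    phangorn::midpoint(tree)
  } else {
    if (is.null(outgroup)) stop("outgroup rooting requires outgroup labels")
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tips <- tree$tip.label
  taxa <- taxonFromLabel(tips)
  queryTaxon <- taxonFromLabel(queryLeaf)
  queryTips <- which(taxa == queryTaxon)
  node <- if (length(queryTips) == 1L) queryTips else
    ape::getMRCA(tree, queryTips)
  rootNode <- length(tips) + 1L
  if (node == rootNode)
    return(list(gene_id = queryLeaf, verdict = "unresolved",
                sister_taxa = character()))
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  siblings <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], node)
  sisterTips <- unlist(lapply(siblings, .tipsUnder, tree = tree))
  sisterTaxa <- unique(taxa[sisterTips])
  stram <- .stramLookup(lineages)[sisterTaxa]
  verdict <- if (length(sisterTaxa) == 0L || anyNA(stram)) {
    "unresolved"
  } else if (all(!stram)) {
    "lgt_confirmed"
  } else if (all(stram)) {
    "vertical"
  } else {
    "unresolved"
  }
  list(gene_id = queryLeaf, verdict = verdict, sister_taxa = sisterTaxa)
}

#' Classify a batch of gene trees
#'
#' @param trees a list / [ape::multiPhylo] of trees or newick strings.
#' @param queries query leaf label per tree.
#' @param lineages,rooting,outgroup as in [classifyTree()].
#' @return data.frame with `gene_id`, `verdict`, `sister_taxa`
#'   (`;`-separated).
#' @export
classifyTrees <- function(trees, queries, lineages,
                          rooting = c("midpoint", "outgroup"),
                          outgroup = NULL) {
  rooting <- match.arg(rooting)
  stopifnot(length(trees) == length(queries))
  rows <- lapply(seq_along(queries), function(k) {
    v <- classifyTree(trees[[k]], queries[k], lineages,
                      rooting = rooting, outgroup = outgroup)
    data.frame(gene_id = v$gene_id, verdict = v$verdict,
               sister_taxa = paste(v$sister_taxa, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize lateral-transfer verdicts against the conserved gene set
#'
#' @param verdicts character vector (or the data.frame from
#'   [classifyTrees()]) of per-gene verdicts.
#' @param nConservedGenes number of conserved gene models the percentage
#'   refers to.
#' @param nCandidates optional number of best-hit LGT candidates, for the
#'   candidate-fraction upper bound.
#' @return a list with `confirmed`, `unresolved`, `examined`,
#'   `confirmedPercent` and (when candidates are given) `candidatePercent`.
#' @examples
#' summarizeLgt(rep(c("lgt_confirmed", "unresolved"), c(180, 18)), 10109)
#' @export
summarizeLgt <- function(verdicts, nConservedGenes, nCandidates = NULL) {
  stopifnot(nConservedGenes > 0)
  if (is.data.frame(verdicts)) verdicts <- verdicts$verdict
  confirmed <- sum(verdicts == "lgt_confirmed")
  out <- list(
    confirmed = confirmed,
    vertical = sum(verdicts == "vertical"),
    unresolved = sum(verdicts == "unresolved"),
    examined = length(verdicts),
    confirmedPercent = 100 * confirmed / nConservedGenes
  )
  if (!is.null(nCandidates))
    out$candidatePercent <- 100 * nCandidates / nConservedGenes
  out
}
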