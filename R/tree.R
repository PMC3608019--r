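#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration via [ape::nj()], with negative
#' branch-length estimates clamped to zero.
#'
#' @param d Symmetric numeric matrix with zero diagonal and labels; at least
#'   3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Bootstrap support for the internal edges of a tree
#'
#' Alignment sites are resampled with replacement; a neighbor-joining tree is
#' rebuilt per replicate from recomputed p-distances; support is the
#' percentage of replicates whose tree contains each internal bipartition of
#' the reference tree.
#'
#' @param sequences Named character vector of haplotype sequences (names are
#'   tip labels of `tree`).
#' @param tree Reference `phylo` tree whose tips are `names(sequences)`.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; fixed seed gives an identical support vector.
#' @return The reference tree with `node.label` set to percent support
#'   (`NA` at the root); also carries a `"support"` attribute (numeric vector
#'   over internal nodes).
#' @export
bootstrap_support <- function(sequences, tree, B = 100, seed = 1) {
  if (B < 1) stop("B must be at least 1")
  stopifnot(setequal(tree$tip.label, names(sequences)))
  M <- seq_char_matrix(sequences[tree$tip.label])
  rownames(M) <- tree$tip.label
  set.seed(seed)
  boot_trees <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    Mb <- M[, cols, drop = FALSE]
    seqs_b <- apply(Mb, 1, paste, collapse = "")
    db <- p_distance_matrix(seqs_b, labels = rownames(M))
    boot_trees[[b]] <- nj_tree(db)
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / B
  tree$node.label <- as.character(round(support, 1))
  attr(tree, "support") <- support
  tree
}

#' Root a tree on an outgroup leaf
#'
#' The root is placed at the midpoint of the outgroup's pendant edge, so the
#' outgroup and the ingroup each receive half of the original pendant length.
#'
#' @param tree Unrooted `phylo` tree.
#' @param outgroup Tip label to root on.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  rt <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root_node <- ape::Ntip(rt) + 1L
  kids <- which(rt$edge[, 1] == root_node)
  og_tip <- match(outgroup, rt$tip.label)
  og_edge <- kids[rt$edge[kids, 2] == og_tip]
  other_edge <- setdiff(kids, og_edge)
  if (length(og_edge) == 1 && length(other_edge) == 1) {
    L <- rt$edge.length[og_edge] + rt$edge.length[other_edge]
    rt$edge.length[og_edge] <- L / 2
    rt$edge.length[other_edge] <- L / 2
  }
  rt
}

#' Assign haplotypes to mtDNA lineages from a rooted tree
#'
#' Haplotypes are first clustered into as many maximal lineages as there are
#' species labels by cutting the rooted ingroup tree at its deepest splits
#' (repeatedly splitting the clade with the largest patristic diameter).
#' Each lineage is then matched to a species by majority of the individuals
#' carried by its haplotypes (greedy one-to-one matching on counts). A
#' haplotype's lineage is the species matched to its cluster, so a haplotype
#' clustering with another species' lineage is assigned to that donor
#' species even when all its carriers belong to the recipient - the
#' signature of mitochondrial introgression. Cutting the tree before
#' consulting the labels keeps the assignment stable when introgression runs
#' in both directions across a contact zone, where clades grown from the
#' labels themselves would inflate to the whole ingroup. Species whose
#' lineage does not exactly equal their majority-label haplotype set are
#' reported as non-monophyletic; species forced to share a cluster (tree
#' with fewer resolvable deep clades than species) are reported as overlaps
#' and their haplotypes flagged ambiguous.
#'
#' @param tree Rooted `phylo` whose tips are haplotype ids (plus optionally
#'   the outgroup).
#' @param hapset A [collapse_haplotypes()] result supplying member species
#'   labels.
#' @param outgroup Optional outgroup tip label to exclude from assignment.
#' @return The `hapset` with `assignment` filled in: a data frame
#'   `haplotype,lineage,ambiguous`, plus attributes `monophyly` (logical per
#'   species) and `overlaps` (character vector of species pairs sharing a
#'   cluster).
#' @export
assign_lineages <- function(tree, hapset, outgroup = NULL) {
  root_node <- ape::Ntip(tree) + 1L
  if (sum(tree$edge[, 1] == root_node) > 2)
    stop("tree root is unresolved (multifurcating); root it on an outgroup")
  sub <- if (!is.null(outgroup) && outgroup %in% tree$tip.label &&
             ape::Ntip(tree) > 3)
    ape::drop.tip(tree, outgroup) else tree
  tips <- setdiff(tree$tip.label, outgroup)

  mem <- hapset$members
  species <- sort(unique(mem$species))
  k <- length(species)

  # cut the ingroup into (up to) k maximal lineages: repeatedly split the
  # cluster with the largest tip-to-tip patristic diameter
  coph <- stats::cophenetic(sub)
  ntip_s <- ape::Ntip(sub)
  desc_tips <- function(node) {
    if (node <= ntip_s) return(sub$tip.label[node])
    ape::extract.clade(sub, node)$tip.label
  }
  clusters <- list(list(node = ntip_s + 1L, tips = sub$tip.label))
  diam <- function(cl) {
    if (length(cl$tips) < 2) return(0)
    max(coph[cl$tips, cl$tips])
  }
  while (length(clusters) < k) {
    ds <- vapply(clusters, diam, 0)
    splittable <- which(ds > 0 &
                          vapply(clusters, function(cl) cl$node > ntip_s,
                                 TRUE))
    if (!length(splittable)) break
    i <- splittable[which.max(ds[splittable])]
    node <- clusters[[i]]$node
    kids <- sub$edge[sub$edge[, 1] == node, 2]
    clusters <- c(clusters[-i],
                  lapply(kids, function(nd)
                    list(node = nd, tips = desc_tips(nd))))
    if (length(clusters) > k) {
      # a multifurcation overshot k: merge the two closest clusters
      while (length(clusters) > k) {
        nc <- length(clusters)
        best <- c(1, 2); bd <- Inf
        for (a in 1:(nc - 1)) for (b in (a + 1):nc) {
          d <- min(coph[clusters[[a]]$tips, clusters[[b]]$tips])
          if (d < bd) { bd <- d; best <- c(a, b) }
        }
        merged <- list(node = 0L,
                       tips = c(clusters[[best[1]]]$tips,
                                clusters[[best[2]]]$tips))
        clusters <- c(clusters[-best], list(merged))
      }
    }
  }

  # match clusters to species by individual counts, greedily one-to-one
  n_ind <- matrix(0, length(clusters), k,
                  dimnames = list(NULL, species))
  for (ci in seq_along(clusters)) {
    in_cl <- mem$haplotype %in% clusters[[ci]]$tips
    tb <- table(mem$species[in_cl])
    n_ind[ci, names(tb)] <- tb
  }
  cl_species <- rep(NA_character_, length(clusters))
  C <- n_ind
  repeat {
    if (all(C < 0)) break
    ij <- which(C == max(C), arr.ind = TRUE)[1, ]
    if (C[ij[1], ij[2]] < 0) break
    cl_species[ij[1]] <- species[ij[2]]
    C[ij[1], ] <- -1
    C[, ij[2]] <- -1
    if (all(!is.na(cl_species))) break
  }
  # clusters left unmatched (fewer species with members than clusters) take
  # their own majority species
  for (ci in which(is.na(cl_species)))
    cl_species[ci] <- species[which.max(n_ind[ci, ])]

  lineage <- stats::setNames(character(length(tips)), tips)
  ambiguous <- stats::setNames(logical(length(tips)), tips)
  for (ci in seq_along(clusters))
    lineage[intersect(clusters[[ci]]$tips, tips)] <- cl_species[ci]

  # species sharing a cluster with another species' majority
  shared <- vapply(seq_along(clusters), function(ci)
    sum(n_ind[ci, ] > 0) > 1 && length(clusters) < k, TRUE)
  overlaps <- character(0)
  if (length(clusters) < k) {
    for (ci in seq_along(clusters)) {
      sp_in <- species[n_ind[ci, ] > 0]
      if (length(sp_in) > 1) {
        overlaps <- c(overlaps, paste(sp_in, collapse = "~"))
        ambiguous[intersect(clusters[[ci]]$tips, tips)] <- TRUE
      }
    }
  }

  maj <- vapply(split(mem$species, mem$haplotype), function(sp) {
    tb <- sort(table(sp), decreasing = TRUE)
    names(tb)[1]
  }, "")
  mono <- vapply(species, function(s)
    setequal(names(lineage)[lineage == s], names(maj)[maj == s]), TRUE)

  hapset$assignment <- data.frame(haplotype = tips,
                                  lineage = unname(lineage[tips]),
                                  ambiguous = unname(ambiguous[tips]),
                                  stringsAsFactors = FALSE)
  attr(hapset$assignment, "monophyly") <- mono
  attr(hapset$assignment, "overlaps") <- overlaps
  hapset
}
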