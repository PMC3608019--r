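test_that("neighbor joining recovers the generating 4-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)) -> additive distances
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d)
  # AB|CD bipartition present
  parts <- ape::prop.part(tr)
  tipsets <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(list(c("A", "B")) %in% lapply(tipsets, identity) ||
                list(c("C", "D")) %in% lapply(tipsets, identity))
})

test_that("three taxa give the closed-form star lengths", {
  d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["A"]), (4 + 6 - 8) / 2)
  expect_equal(unname(len["B"]), (4 + 8 - 6) / 2)
  expect_equal(unname(len["C"]), (6 + 8 - 4) / 2)
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(6:8, 1)
    true <- ape::rtree(n)
    true$edge.length <- runif(nrow(true$edge), 0.1, 2)
    d <- as.matrix(ape::cophenetic.phylo(true))
    tr <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), tr)), 0)
    expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
                 d, tolerance = 1e-8)
  }
})

test_that("neighbor joining output is invariant to label order", {
  set.seed(12)
  seqs <- random_seqs(7, 80)
  names(seqs) <- paste0("t", 1:7)
  d <- p_distance_matrix(seqs)
  t1 <- nj_tree(d)
  perm <- sample(7)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "symmetric")
})

test_that("bootstrap support is 100% when every column resample is identical", {
  # every alignment column carries the same pattern, so any resample
  # reproduces the original distances exactly (forced identity resample)
  block <- function(ch, n) paste(rep(ch, n), collapse = "")
  seqs <- c(a = block("A", 30), b = block("C", 30),
            c = block("G", 30), d = block("T", 30))
  d <- p_distance_matrix(seqs)
  tr <- nj_tree(d)
  bs <- bootstrap_support(seqs, tr, B = 20, seed = 1)
  expect_true(all(attr(bs, "support")[-1] == 100))
})

test_that("deep fixed differences earn near-certain support", {
  set.seed(21)
  base1 <- random_seqs(1, 100)
  group1 <- c(base1, base1, base1)
  base2 <- strsplit(base1, "")[[1]]
  flip <- sample(100, 50)
  for (i in flip) base2[i] <- setdiff(c("A", "C", "G", "T"), base2[i])[1]
  base2 <- paste(base2, collapse = "")
  group2 <- c(base2, base2, base2)
  seqs <- c(group1, group2)
  # perturb singletons so tips are distinct
  for (i in c(2, 3, 5, 6)) {
    ch <- strsplit(seqs[i], "")[[1]]
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    seqs[i] <- paste(ch, collapse = "")
  }
  names(seqs) <- paste0("h", 1:6)
  d <- p_distance_matrix(seqs)
  tr <- nj_tree(d)
  bs <- bootstrap_support(seqs, tr, B = 100, seed = 2)
  # the edge splitting {h1,h2,h3} from {h4,h5,h6}
  parts <- ape::prop.part(bs)
  labs <- attr(parts, "labels")
  support <- attr(bs, "support")
  idx <- which(vapply(parts, function(p)
    setequal(labs[p], c("h1", "h2", "h3")) ||
      setequal(labs[p], c("h4", "h5", "h6")), TRUE))
  expect_true(any(support[idx] >= 99))
  bs2 <- bootstrap_support(seqs, tr, B = 100, seed = 2)
  expect_identical(attr(bs, "support"), attr(bs2, "support"))
})

test_that("outgroup rooting splits ingroup from outgroup at the edge midpoint", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  rt <- root_with_outgroup(tr, "C")
  expect_true(ape::is.rooted(rt))
  root_node <- ape::Ntip(rt) + 1L
  kids <- rt$edge[rt$edge[, 1] == root_node, 2]
  expect_true(match("C", rt$tip.label) %in% kids)
  # re-rooting on the same leaf keeps the topology
  rt2 <- root_with_outgroup(rt, "C")
  expect_true(ape::all.equal.phylo(rt, rt2, use.edge.length = FALSE))
  expect_error(root_with_outgroup(tr, "zz"), "zz")
})

test_that("lineage assignment handles clean, introgressed and single-species cases", {
  # clean case: two separated clades
  tr <- ape::read.tree(text = "(((h1:1,h2:1):5,(h3:1,h4:1):5):1,out:10);")
  hs <- list(members = data.frame(
    individual = paste0("i", 1:8),
    population = rep(c("p1", "p2", "p3", "p4"), each = 2),
    species = rep(c("A", "A", "B", "B"), each = 2),
    haplotype = rep(c("h1", "h2", "h3", "h4"), each = 2),
    stringsAsFactors = FALSE))
  class(hs) <- "haplotype_set"
  out <- assign_lineages(tr, hs, outgroup = "out")
  expect_equal(out$assignment$lineage[match(c("h1", "h2"), out$assignment$haplotype)],
               c("A", "A"))
  expect_equal(out$assignment$lineage[match(c("h3", "h4"), out$assignment$haplotype)],
               c("B", "B"))
  expect_true(all(attr(out$assignment, "monophyly")))
  expect_length(attr(out$assignment, "overlaps"), 0)

  # introgressed: h4 carried only by A individuals but inside the B clade
  hs2 <- hs
  hs2$members$species <- c("A", "A", "A", "A", "B", "B", "A", "A")
  out2 <- assign_lineages(tr, hs2, outgroup = "out")
  expect_equal(out2$assignment$lineage[out2$assignment$haplotype == "h4"], "B")
  expect_false(attr(out2$assignment, "monophyly")["A"][[1]])

  # single species
  hs3 <- hs
  hs3$members$species <- "A"
  out3 <- assign_lineages(tr, hs3, outgroup = "out")
  expect_true(all(out3$assignment$lineage == "A"))
})

test_that("introgression flags and population classes follow the lineage map", {
  members <- data.frame(
    individual = paste0("i", 1:6),
    population = c("p1", "p1", "p2", "p2", "p3", "p3"),
    species = c("A", "A", "A", "A", "B", "B"),
    haplotype = c("h1", "h1", "h1", "h2", "h2", "h2"),
    stringsAsFactors = FALSE)
  hs <- list(members = members,
             assignment = data.frame(haplotype = c("h1", "h2"),
                                     lineage = c("A", "B"),
                                     ambiguous = FALSE,
                                     stringsAsFactors = FALSE))
  class(hs) <- "haplotype_set"
  fl <- flag_introgression(hs)
  expect_equal(fl$individuals$status,
               c("original", "original", "original", "introgressed",
                 "original", "original"))
  cls <- setNames(fl$populations$class, fl$populations$population)
  expect_equal(unname(cls[c("p1", "p2", "p3")]),
               c("original", "mixed", "original"))
  # exclusion modes
  aln <- mtdna_alignment(members$individual, members$population,
                         members$species, rep("ACGT", 6))
  kept_pop <- exclude_introgressed(aln, fl, "population")
  expect_setequal(unique(kept_pop$population), c("p1", "p3"))
  kept_ind <- exclude_introgressed(aln, fl, "individual")
  expect_setequal(kept_ind$individual, setdiff(members$individual, "i4"))
})
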