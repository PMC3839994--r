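test_that("four-gamete check fires exactly on the definition case", {
  bm <- toy_binary_matrix(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  rep <- four_gamete_check(bm)
  expect_equal(nrow(rep$pairs), 1)
  expect_setequal(unlist(rep$pairs[1, ]), c("1", "2"))
  expect_equal(nrow(four_gamete_check(
    toy_binary_matrix(matrix(c(0, 1, 1), 3)))$pairs), 0)
})

test_that("fixture conflicts involve exactly the CpG sites 25 and 31", {
  ds <- fixture_ds()
  bm <- sample_binary_matrix(ds, AFR(), extra = c(H23 = 1))
  rep <- four_gamete_check(bm)
  expect_gt(nrow(rep$pairs), 0)
  conf <- unique(c(rep$pairs$site1, rep$pairs$site2))
  # every conflicting pair involves site 25 or site 31
  expect_true(all(rep$pairs$site1 %in% c("25", "31") |
                    rep$pairs$site2 %in% c("25", "31")))
  expect_true(all(c("25", "31") %in% conf))
})

test_that("recurrence resolution reproduces the published starred split", {
  ds <- fixture_ds()
  bm <- sample_binary_matrix(ds, AFR(), extra = c(H23 = 1))
  res <- resolve_recurrences(bm)
  expect_equal(nrow(four_gamete_check(res)$pairs), 0)
  map <- attr(res, "recurrence_map")
  expect_equal(map[["25*"]], "H5")
  expect_equal(map[["31*"]], "H2")
  expect_equal(ncol(res$x), 38)
  # an already-compatible matrix is returned unchanged
  bm2 <- toy_binary_matrix(rbind(c(1, 0), c(1, 1)))
  expect_identical(resolve_recurrences(bm2), bm2)
})

test_that("non-CpG homoplasy is refused rather than silently resolved", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  bm <- toy_binary_matrix(x, cpg = c(FALSE, FALSE))
  expect_error(resolve_recurrences(bm), "not attributable to CpG")
})

test_that("toy recurrence resolution matches brute-force minimal homoplasy", {
  # site 2 recurrent (carried by H1 and H3 on disjoint backgrounds);
  # sites 1 and 3 define the two clades; H4 is the ancestral haplotype
  x <- rbind(H1 = c(1, 1, 0),
             H2 = c(1, 0, 0),
             H3 = c(0, 1, 1),
             H4 = c(0, 0, 0))
  bm <- toy_binary_matrix(x, counts = c(2L, 1L, 1L, 1L),
                          cpg = c(FALSE, TRUE, FALSE))
  res <- resolve_recurrences(bm)
  expect_equal(nrow(four_gamete_check(res)$pairs), 0)
  expect_equal(ncol(res$x), 4)
  # brute force: enumerate all single-column splits of the conflicted
  # CpG column and keep the minimal-duplication compatible assignments
  carriers <- which(x[, 2] == 1)
  sols <- list()
  for (mask in seq_len(2^length(carriers) - 2)) {
    star <- carriers[bitwAnd(2^(seq_along(carriers) - 1), mask) > 0]
    y <- cbind(x[, 1:2], star = 0, x[, 3, drop = FALSE])
    y[star, 2] <- 0
    y[star, 3] <- 1
    if (nrow(four_gamete_check(toy_binary_matrix(y,
          counts = bm$counts))$pairs) == 0)
      sols[[length(sols) + 1]] <- y
  }
  expect_gt(length(sols), 0)
  # our resolution is one of the brute-force minimal solutions (same
  # column contents up to which copy is starred)
  norm <- function(m) paste(sort(apply(m, 2, paste, collapse = "")),
                            collapse = "|")
  expect_true(norm(res$x) %in% vapply(sols, norm, ""))
})

test_that("the fixture gene tree has the published structure", {
  ds <- fixture_ds()
  bm <- sample_binary_matrix(ds, AFR(), extra = c(H23 = 1))
  gt <- build_gene_tree(resolve_recurrences(bm))
  expect_equal(gt$n, 112)
  expect_equal(length(gt$parent) - 1L, 36)  # 36 mutations on the tree
  b <- tree_branches(gt)
  expect_equal(sum(b$m_b), 36)
  expect_equal(sum(gt$tip_mult), 112)
  # H22 hangs directly off the root via its private branch 5,9,18
  h22 <- b[which(b$haplotype == "H22"), ]
  expect_equal(h22$mutations, "5,9,18")
  v <- h22$end_node
  for (i in seq_len(h22$m_b)) v <- gt$parent[v]
  expect_equal(v, 1L)  # reached the root
  # the Khoe-San H17/H19-H21 clade and everything else sit below mutation 6
  n6 <- xhaplo:::mutation_node(gt, "6")
  expect_equal(gt$n_sub[n6], 109)
  # H1 attaches directly under the 21/25 cascade; branch below 19 is
  # star-like around H12
  n19 <- xhaplo:::mutation_node(gt, "19")
  expect_equal(gt$n_sub[n19], 13)
})

test_that("two haplotypes one site apart give a single-branch tree", {
  bm <- toy_binary_matrix(matrix(c(0, 1), 2, 1))
  gt <- build_gene_tree(bm)
  expect_equal(length(gt$parent), 2)
  expect_equal(gt$n_sub, c(2L, 1L))
})

test_that("tree reconstruction replays every leaf state (random matrices)", {
  for (seed in 1:6) {
    bm <- random_pp_matrix(n = 8, theta = 3, seed = seed)
    if (sum(bm$segregating) == 0) next
    gt <- build_gene_tree(bm)
    # replay: each haplotype's mutation set equals its root path
    for (r in seq_len(nrow(bm$x))) {
      v <- which(!is.na(gt$tip_hap) & gt$tip_hap == bm$haplotype_id[r])
      path <- character(0)
      while (v != 1L) { path <- c(path, gt$mutation[v]); v <- gt$parent[v] }
      expect_setequal(path, bm$labels[bm$x[r, ] == 1L])
    }
    # n_b equals the number of chromosomes carrying the root-side path
    for (v in seq_along(gt$parent)[-1]) {
      path <- character(0); u <- v
      while (u != 1L) { path <- c(path, gt$mutation[u]); u <- gt$parent[u] }
      carry <- apply(bm$x[, match(path, bm$labels), drop = FALSE], 1,
                     function(z) all(z == 1L))
      expect_equal(gt$n_sub[v], sum(bm$counts[carry]))
    }
  }
})

test_that("tree construction is invariant to row and column permutation", {
  bm <- random_pp_matrix(n = 8, theta = 4, seed = 42)
  gt1 <- build_gene_tree(bm)
  set.seed(1)
  bm2 <- bm
  rp <- sample(nrow(bm$x)); cp <- sample(ncol(bm$x))
  bm2$x <- bm$x[rp, cp, drop = FALSE]
  bm2$counts <- bm$counts[rp]
  bm2$haplotype_id <- bm$haplotype_id[rp]
  bm2$labels <- bm$labels[cp]
  bm2$positions <- bm$positions[cp]
  bm2$cpg <- bm$cpg[cp]
  bm2$segregating <- bm$segregating[cp]
  gt2 <- build_gene_tree(bm2)
  key <- function(gt) {
    b <- tree_branches(gt)
    paste(sort(sprintf("%s|%d|%d", vapply(strsplit(b$mutations, ","),
                                          function(m) paste(sort(m),
                                                            collapse = ","),
                                          ""), b$n_b, b$m_b)),
          collapse = ";")
  }
  expect_equal(key(gt2), key(gt1))
})

test_that("incompatible input is routed to resolve_recurrences", {
  bm <- toy_binary_matrix(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  expect_error(build_gene_tree(bm), "resolve_recurrences")
})

test_that("Newick export produces a valid tree with all sampled haplotypes", {
  ds <- fixture_ds()
  bm <- sample_binary_matrix(ds, AFR(), extra = c(H23 = 1))
  gt <- build_gene_tree(resolve_recurrences(bm))
  f <- tempfile(fileext = ".nwk")
  write_newick(gt, f)
  phy <- ape::read.tree(f)
  expect_s3_class(phy, "phylo")
  sampled <- gt$tip_hap[!is.na(gt$tip_hap)]
  expect_length(phy$tip.label, length(sampled))
  expect_setequal(sub("_[0-9]+$", "", phy$tip.label), sampled)
  # edge lengths count mutations: total equals 36
  expect_equal(sum(phy$edge.length), 36)
})

test_that("network edge-list export carries per-population counts", {
  ds <- fixture_ds()
  bm <- sample_binary_matrix(ds, AFR(), extra = c(H23 = 1))
  gt <- build_gene_tree(resolve_recurrences(bm))
  f <- tempfile(fileext = ".tsv")
  export_network(gt, f, dataset = ds)
  tab <- read.delim(f)
  expect_equal(sum(tab$m), 36)
  expect_equal(tab$count_KhoeSan[tab$haplotype == "H17" &
                                   !is.na(tab$haplotype)], 7)
})
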