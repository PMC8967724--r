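toy_table <- function() {
  data.frame(pathway = "lung",
             bregma = c(-7.48, -7.48, -7.76),
             subnucleus = c("cNTS", "mNTS", "cNTS"),
             mean_fluorescence = c(30, 20, 10),
             background_fluorescence = c(10, 10, 10),
             area = c(100, 50, 200), stringsAsFactors = FALSE)
}

test_that("percentage innervation matches the four-step hand oracle", {
  tab <- toy_table()
  # oracle: FI = mean - background; TF = sum(FI * A); PI = FI*A/TF*100
  fi <- c(20, 10, 0)
  tf <- sum(fi * tab$area)
  oracle <- fi * tab$area / tf * 100
  prof <- percentage_innervation(tab, "lung")
  key <- paste(prof$bregma, prof$subnucleus)
  want <- setNames(oracle, paste(tab$bregma, tab$subnucleus))
  expect_equal(prof$pi, unname(want[key]))
  expect_equal(sum(prof$pi), 100, tolerance = 1e-9)
})

test_that("profiles normalise, clamp negatives, and respect scale invariance", {
  tab <- toy_table()
  # single nonzero subnucleus takes 100%
  solo <- tab[1, ]
  expect_equal(percentage_innervation(solo, "lung")$pi, 100)
  # equal FI x area split 50/50
  two <- tab[1:2, ]
  two$mean_fluorescence <- c(30, 50)
  two$area <- c(100, 50)   # FI*A: 2000 and 2000
  expect_equal(sort(percentage_innervation(two, "lung")$pi), c(50, 50))
  # background above mean clamps to zero signal, never negative PI
  tab$background_fluorescence[3] <- 50
  prof <- percentage_innervation(tab, "lung")
  expect_true(all(prof$pi >= 0))
  expect_equal(sum(prof$pi), 100, tolerance = 1e-9)
  # common positive rescaling of fluorescence leaves PI unchanged
  scaled <- tab
  scaled$mean_fluorescence <- scaled$mean_fluorescence * 3.5
  scaled$background_fluorescence <- scaled$background_fluorescence * 3.5
  expect_equal(percentage_innervation(scaled, "lung")$pi, prof$pi)
  expect_error(percentage_innervation(tab, "gone"), "no records")
})

test_that("profiles on random tables always sum to 100", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    tab <- data.frame(pathway = "p",
                      bregma = sample(seq(-8, -7.2, 0.04), n, replace = TRUE),
                      subnucleus = sample(paste0("sn", 1:4), n, replace = TRUE),
                      mean_fluorescence = runif(n, 0, 100),
                      background_fluorescence = runif(n, 0, 30),
                      area = runif(n, 10, 500))
    tab <- tab[!duplicated(tab[, c("bregma", "subnucleus")]), ]
    if (all(tab$mean_fluorescence <= tab$background_fluorescence)) next
    prof <- percentage_innervation(tab, "p")
    expect_equal(sum(prof$pi), 100, tolerance = 1e-9)
    expect_true(all(prof$pi >= 0))
  }
})

test_that("profile discrepancy is a symmetric form vanishing only at equality", {
  tab <- toy_table()
  p1 <- percentage_innervation(tab, "lung")
  expect_equal(correlation_variance(p1, p1), 0)
  p2 <- p1
  p2$pi <- rev(p1$pi)
  expect_equal(correlation_variance(p1, p2), correlation_variance(p2, p1))
  expect_gt(correlation_variance(p1, p2), 0)
  # disjoint profiles (100, 0) vs (0, 100): 100^2 + 100^2
  a <- data.frame(bregma = -7.48, subnucleus = c("x", "y"),
                  pi = c(100, 0))
  b <- data.frame(bregma = -7.48, subnucleus = c("x", "y"),
                  pi = c(0, 100))
  expect_equal(correlation_variance(a, b), 20000)
  bad <- p1[rev(seq_len(nrow(p1))), ]
  expect_error(correlation_variance(p1, bad), "identical")
})

test_that("linkage tree is UPGMA with half-distance heights", {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- linkage_tree(d)
  # A and B join first at height 0.5
  ab <- ape::getMRCA(tree, c("A", "B"))
  depths <- ape::node.depth.edgelength(tree)
  height_ab <- max(depths) - depths[ab]
  expect_equal(height_ab, 0.5)
  # cross-check against an independent UPGMA implementation
  ref <- phangorn::upgma(as.dist(d))
  expect_equal(unname(sort(ape::cophenetic.phylo(tree)[c("A", "B", "C"),
                                                       c("A", "B", "C")])),
               unname(sort(ape::cophenetic.phylo(ref)[c("A", "B", "C"),
                                                      c("A", "B", "C")])))
  # two pathways give a single cherry
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  t2 <- linkage_tree(d2)
  expect_equal(sort(t2$tip.label), c("p", "q"))
  expect_equal(t2$edge.length, c(1.5, 1.5))
  # permuting labels permutes leaves only
  perm <- c(3, 1, 2)
  t3 <- linkage_tree(d[perm, perm])
  expect_equal(ape::cophenetic.phylo(t3)[c("A", "B", "C"), c("A", "B", "C")],
               ape::cophenetic.phylo(tree)[c("A", "B", "C"), c("A", "B", "C")])
  expect_error(linkage_tree(matrix(c(0, 1, 2, 0), 2, 2,
                                   dimnames = list(c("a", "b"),
                                                   c("a", "b")))),
               "symmetric")
})

test_that("variance matrix pipeline produces a coherent tree", {
  set.seed(8)
  grid <- expand.grid(bregma = c(-7.48, -7.76),
                      subnucleus = c("cNTS", "mNTS"),
                      stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(c("lung", "stomach", "colon"), function(p)
    data.frame(pathway = p, grid,
               mean_fluorescence = runif(nrow(grid), 10, 100),
               background_fluorescence = 5,
               area = runif(nrow(grid), 50, 150))))
  vm <- correlation_variance_matrix(tab)
  expect_equal(vm, t(vm))
  expect_equal(unname(diag(vm)), rep(0, 3))
  tree <- linkage_tree(vm)
  expect_setequal(tree$tip.label, c("lung", "stomach", "colon"))
  nwk <- ape::write.tree(tree)
  expect_match(nwk, "^\\(.*\\);$")
})
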