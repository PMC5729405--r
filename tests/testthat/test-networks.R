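eqtlFixture <- function() {
  data.frame(
    probe = c("p1", "p2", "p3", "p3", "p4", "p5"),
    snp = c("s1", "s1", "s2", "s3", "s4", "s5"),
    chrom = "1", pos = c(1, 1, 2, 3, 4, 5) * 1e6,
    p = c(1e-9, 1e-8, 1e-7, 1e-6, 1e-5, 1e-4),
    gene = c("gA", "gB", "gC", "gC", "gD", "gD"),
    regulation = c("local", "distant", "local", "distant", "local", "local"),
    stringsAsFactors = FALSE)
}

test_that("graph construction is a bijection between edges and associations", {
  eqtl <- eqtlFixture()
  net <- buildAssociationGraph(eqtl)
  expect_identical(nrow(net$edges), nrow(eqtl))
  expect_identical(sum(net$edges$weight), as.numeric(nrow(eqtl)))
  # bipartite: SNP nodes never appear as targets
  expect_false(any(net$edges$snp %in% net$edges$target))
  # one SNP -> two probes gives a 3-node component
  comp <- componentSummary(net)
  memb <- comp$membership
  expect_identical(length(unique(memb[c("s1", "p1", "p2")])), 1L)
  expect_identical(as.integer(comp$sizes[memb["s1"]]), 3L)
})

test_that("gene-level collapse merges probes and records multi-edges", {
  eqtl <- eqtlFixture()
  # p4 and p5 both map to gene gD; s4/s5 each hit one probe -> no multi-edge;
  # add a second probe of gC hit by s2 to create one
  eqtl2 <- rbind(eqtl, data.frame(probe = "p6", snp = "s2", chrom = "1",
                                  pos = 2e6, p = 1e-6, gene = "gC",
                                  regulation = "local"))
  net <- buildAssociationGraph(eqtl2, collapseToGenes = TRUE)
  e <- net$edges[net$edges$snp == "s2" & net$edges$target == "gC", ]
  expect_identical(nrow(e), 1L)
  expect_identical(e$weight, 2)
  expect_identical(sum(net$edges$weight), as.numeric(nrow(eqtl2)))
})

test_that("components match a flood-fill oracle on a random bipartite fixture", {
  set.seed(33)
  snps <- paste0("s", 1:15)
  probes <- paste0("p", 1:20)
  eqtl <- data.frame(snp = sample(snps, 30, replace = TRUE),
                     probe = sample(probes, 30, replace = TRUE),
                     chrom = "1", pos = 1e6, p = 1e-8,
                     regulation = "local", stringsAsFactors = FALSE)
  eqtl <- eqtl[!duplicated(paste(eqtl$snp, eqtl$probe)), ]
  net <- buildAssociationGraph(eqtl)
  comp <- componentSummary(net)
  oracle <- floodFillComponents(names(net$nodeType), eqtl$snp, eqtl$probe)
  # same partition: equal label co-membership for every node pair
  nodes <- names(net$nodeType)
  mine <- comp$membership[nodes]
  expect_identical(outer(mine, mine, "=="), outer(oracle, oracle, "=="),
                   ignore_attr = TRUE)
})

test_that("mean degree and component summaries follow the definitions", {
  # path of 3 nodes: s1 -> p1 <- s2; degrees 1, 2, 1
  eqtl <- data.frame(probe = c("p1", "p1"), snp = c("s1", "s2"),
                     chrom = "1", pos = c(1e6, 2e6), p = 1e-8,
                     regulation = "local", stringsAsFactors = FALSE)
  net <- buildAssociationGraph(eqtl)
  comp <- componentSummary(net)
  expect_equal(comp$meanDegree, 4 / 3)
  expect_identical(comp$nComponents, 1L)
  # disjoint SNP-probe pairs are size-2 components, excluded from >=3 summary
  eqtl2 <- data.frame(probe = c("p1", "p2"), snp = c("s1", "s2"),
                      chrom = "1", pos = c(1e6, 2e6), p = 1e-8,
                      regulation = "local", stringsAsFactors = FALSE)
  comp2 <- componentSummary(buildAssociationGraph(eqtl2))
  expect_identical(comp2$nComponents, 0L)
  empty <- buildAssociationGraph(eqtlFixture()[0, ])
  expect_identical(componentSummary(empty)$nComponents, 0L)
})

test_that("master regulators are SNPs with enough distinct targets", {
  eqtl <- data.frame(
    probe = c(paste0("m", 1:12), "x1", "x2"),
    snp = c(rep("hub", 12), "tiny", "tiny"),
    chrom = "1", pos = 1e6, p = 1e-8, regulation = "distant",
    stringsAsFactors = FALSE)
  net <- buildAssociationGraph(eqtl)
  res <- findMasterRegulators(net, minTargets = 10)
  expect_identical(res$snp, "hub")
  expect_identical(res$n_targets, 12L)
  # min_targets = 1 returns every SNP, hub first
  all_ <- findMasterRegulators(net, minTargets = 1)
  expect_identical(all_$snp, c("hub", "tiny"))
  expect_identical(nrow(findMasterRegulators(net, minTargets = 13)), 0L)
})

test_that("PCIT rejects the conditionally independent edge in the 3-variable case", {
  # z drives x and y (r_xz = r_yz = 0.5); x and y are independent given z,
  # so r_xy = 0.25 exactly. Hand evaluation: r_xy.z = 0,
  # r_xz.y = r_yz.x = 0.375/sqrt(0.9375*0.75) = 0.4472, so
  # eps = (0 + 0.8944 + 0.8944)/3 = 0.5963 and
  # |r_xy| = 0.25 <= eps*0.5 = 0.298 on both paths -> rejected;
  # |r_xz| = 0.5 > eps*0.25 = 0.149 -> kept.
  r <- diag(3)
  r[1, 3] <- r[3, 1] <- 0.5
  r[2, 3] <- r[3, 2] <- 0.5
  r[1, 2] <- r[2, 1] <- 0.25
  res <- pcitFilter(r, isCorrelation = TRUE)
  expect_false(res$keep[1, 2])
  expect_true(res$keep[1, 3])
  expect_true(res$keep[2, 3])
  expect_equal(res$keep, pcitBruteForce(r), ignore_attr = TRUE)
  # with strongly driven correlations (0.9, 0.9, 0.81) the tolerance-scaled
  # bound eps*0.9 = 0.45 sits below r_xy = 0.81: the rule keeps all edges
  r2 <- diag(3)
  r2[1, 3] <- r2[3, 1] <- r2[2, 3] <- r2[3, 2] <- 0.9
  r2[1, 2] <- r2[2, 1] <- 0.81
  expect_true(all(pcitFilter(r2, isCorrelation = TRUE)$keep))
})

test_that("PCIT equals brute-force trio enumeration on random fixtures", {
  set.seed(34)
  for (nv in c(4, 6, 9, 12)) {
    m <- matrix(rnorm(60 * nv), 60, nv)
    m[, 2] <- m[, 1] * 0.8 + rnorm(60, 0, 0.3)   # induce structure
    if (nv >= 5) m[, 5] <- m[, 1] * 0.7 + m[, 2] * 0.4 + rnorm(60, 0, 0.4)
    res <- pcitFilter(m)
    expect_equal(res$keep, pcitBruteForce(cor(m)), ignore_attr = TRUE)
  }
})

test_that("PCIT edge cases: 2 variables kept, degenerate trios skipped", {
  set.seed(35)
  m <- matrix(rnorm(40), 20, 2)
  res <- pcitFilter(m)
  expect_true(all(res$keep))
  # |r| = 1 in a trio: skip with warning
  x <- rnorm(30)
  m3 <- cbind(a = x, b = 2 * x, c = rnorm(30))
  expect_warning(res3 <- pcitFilter(m3), "degenerate")
  expect_true(all(res3$keep))
  expect_error(pcitFilter(matrix(rnorm(6), 3, 2)), "4 observations")
})

test_that("independent noise variables lose most weak edges", {
  set.seed(36)
  m <- matrix(rnorm(200 * 10), 200, 10)
  res <- pcitFilter(m)
  ut <- upper.tri(res$r)
  weakOrGone <- !res$keep[ut] | abs(res$r[ut]) < 0.15
  expect_gte(mean(weakOrGone), 0.95)
})

test_that("network export round-trips through its reader", {
  eqtl <- eqtlFixture()
  net <- buildAssociationGraph(eqtl)
  sif <- tempfile(fileext = ".sif")
  edges <- tempfile(fileext = ".tsv")
  exportNetwork(net, sif, "sif")
  exportNetwork(net, edges, "edges")
  expect_identical(length(readLines(sif)), nrow(eqtl))
  back <- readNetworkEdges(sif, "sif")
  expect_identical(back$snp, net$edges$snp)
  expect_identical(back$regulation, net$edges$regulation)
  backE <- readNetworkEdges(edges, "edges")
  expect_equal(backE, net$edges, ignore_attr = TRUE)
  # write -> read -> write gives identical bytes
  sif2 <- tempfile(fileext = ".sif")
  net2 <- net; net2$edges <- back |>
    transform(p = net$edges$p, weight = net$edges$weight)
  exportNetwork(net2, sif2, "sif")
  expect_identical(readLines(sif), readLines(sif2))
  expect_error(exportNetwork(net, tempfile(), "gexf"), "supported formats")
  # empty graph: header-only edge list
  emptyNet <- buildAssociationGraph(eqtl[0, ])
  f <- tempfile()
  exportNetwork(emptyNet, f, "edges")
  expect_identical(length(readLines(f)), 1L)
})
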