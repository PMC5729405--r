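# enumeration oracle for the two-sided minlike binomial test
binomEnumOracle <- function(r, a) {
  n <- r + a
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[a + 1] * (1 + 1e-7)])
}

test_that("binomial ASE test matches enumeration on an exhaustive grid", {
  for (n in c(1, 2, 5, 10, 25, 40)) {
    for (a in 0:n) {
      expect_equal(binomialAseTest(n - a, a), binomEnumOracle(n - a, a),
                   tolerance = 1e-12)
    }
  }
  # agreement with the standard exact test (independent implementation)
  for (i in 1:50) {
    r <- sample(0:60, 1); a <- sample(0:60, 1)
    if (r + a == 0) next
    expect_equal(binomialAseTest(r, a),
                 binom.test(a, r + a, 0.5)$p.value, tolerance = 1e-9)
  }
})

test_that("binomial ASE test frozen values and properties", {
  expect_equal(binomialAseTest(10, 10), 1.0)
  # exact tail: 2 * sum_{k<=5} C(25,k)/2^25
  expect_equal(binomialAseTest(20, 5), 2 * pbinom(5, 25, 0.5),
               tolerance = 1e-12)
  expect_equal(binomialAseTest(20, 5), 4.08e-3, tolerance = 0.01)
  expect_equal(binomialAseTest(0, 30), 2 * 2^-30, tolerance = 1e-12)
  # symmetry p(a,b) = p(b,a)
  for (i in 1:20) {
    r <- sample(0:40, 1); a <- sample(0:40, 1)
    expect_identical(binomialAseTest(r, a), binomialAseTest(a, r))
  }
  expect_error(binomialAseTest(-1, 5), "negative")
})

test_that("per-animal FDR is BH step-up with monotonicity", {
  res <- perAnimalFdr(c(0.001, 0.02, 0.8))
  expect_equal(res$q, c(0.003, 0.03, 0.8), tolerance = 1e-12)
  expect_identical(res$significant, c(TRUE, TRUE, FALSE))
  one <- perAnimalFdr(0.04)
  expect_equal(one$q, 0.04)
  expect_true(one$significant)
  expect_false(any(perAnimalFdr(rep(1, 5))$significant))
  expect_identical(nrow(perAnimalFdr(numeric(0))), 0L)
})

test_that("site filters drop low-depth entries, low-MAC and non-biallelic sites", {
  counts <- rbind(
    toyCounts(c("a", "b"), c(4, 30), c(5, 28), "het", position = 1L),
    toyCounts(c("a", "b"), c(30, 25), c(2, 1), "het", position = 2L),
    toyCounts("a", 20, 20, "het", position = 3L, alt = "T"),
    toyCounts("b", 22, 18, "het", position = 3L, alt = "C"),
    toyCounts(c("a", "b"), c(15, 12), c(14, 18), "het", position = 4L))
  res <- filterAseSites(counts)
  # position 1 sample a: 9 reads -> entry dropped, sample b stays
  expect_false(any(res$counts$position == 1 & res$counts$sample == "a"))
  expect_true(any(res$counts$position == 1 & res$counts$sample == "b"))
  # position 2: cohort minor allele count 3 -> dropped (strict > 3)
  expect_false(any(res$counts$position == 2))
  expect_true("minor_allele_count" %in%
                res$registry$reason[res$registry$site == "1:2"])
  # position 3: two alt alleles -> non-biallelic
  expect_false(any(res$counts$position == 3))
  expect_true("non_biallelic" %in%
                res$registry$reason[res$registry$site == "1:3"])
  expect_true(all(res$counts$position[res$counts$sample == "a"] == 4))
  expect_error(filterAseSites(transform(counts, refCount = -1)), "negative")
})

test_that("aggregation applies the strict one-third rule", {
  # 3 het animals, 1 significant: 1/3 is NOT > 1/3
  counts <- rbind(
    toyCounts(c("a", "b", "c"), c(2, 14, 16), c(28, 16, 14), "het",
              position = 1L),
    toyCounts(c("a", "b"), c(2, 15), c(28, 15), "het", position = 2L),
    toyCounts("d", 40, 0, "hom_ref", position = 3L))
  res <- aggregateAse(counts, alpha = 0.05)
  c1 <- res$calls[res$calls$position == 1, ]
  expect_identical(c1$n_het, 3L)
  expect_identical(c1$n_significant, 1L)
  expect_false(c1$is_ase)
  # 2 het, 1 significant: 1/2 > 1/3
  c2 <- res$calls[res$calls$position == 2, ]
  expect_true(c2$is_ase)
  # 0 het: untestable
  c3 <- res$calls[res$calls$position == 3, ]
  expect_true(is.na(c3$is_ase))
  # non-strict variant includes the boundary
  res2 <- aggregateAse(counts, strict = FALSE)
  expect_true(res2$calls[res2$calls$position == 1, "is_ase"])
})

test_that("aggregation is invariant to animal order", {
  set.seed(30)
  counts <- do.call(rbind, lapply(1:6, function(i)
    toyCounts(paste0("a", 1:10), rbinom(10, 40, 0.5), rbinom(10, 40, 0.35),
              "het", position = i)))
  a <- aggregateAse(counts)
  b <- aggregateAse(counts[sample(nrow(counts)), ])
  ordA <- a$calls[order(a$calls$position), ]
  ordB <- b$calls[order(b$calls$position), ]
  rownames(ordA) <- rownames(ordB) <- NULL
  expect_equal(ordA, ordB)
})

test_that("sites map to all overlapping genes and the universe rule holds", {
  calls <- data.frame(contig = "1", position = c(150L, 500L, 950L),
                      ref = "A", alt = "G",
                      n_het = c(5L, 3L, 0L), n_significant = c(3L, 0L, 0L),
                      is_ase = c(TRUE, FALSE, NA))
  genes <- data.frame(gene = c("G1", "G2", "G3"),
                      contig = "1",
                      start = c(100L, 120L, 900L),
                      end = c(200L, 600L, 1000L))
  reads <- c(G1 = 50, G2 = 9, G3 = 40)
  res <- mapSitesToGenes(calls, genes, reads)
  # site 150 is inside G1 and G2 (overlapping genes)
  s1 <- res$siteGenes[res$siteGenes$position == 150, ]
  expect_setequal(s1$gene, c("G1", "G2"))
  # G2 fails the 10-read rule -> not in universe despite het overlap
  expect_false("G2" %in% res$universe)
  expect_true("G1" %in% res$universe)
  # G3 overlaps only the untestable site -> excluded from universe
  expect_false("G3" %in% res$universe)
  # ASE genes: G1 and G2 contain the ASE-SNP
  expect_setequal(res$aseGenes$gene[res$aseGenes$is_ase], c("G1", "G2"))
  expect_error(mapSitesToGenes(calls, transform(genes, end = start - 1), reads),
               "malformed")
})

test_that("intergenic ASE-SNPs survive calling without a gene assignment", {
  counts <- toyCounts(paste0("a", 1:4), rep(30, 4), rep(5, 4), "het",
                      position = 5000L)
  res <- runAse(counts,
                geneIntervals = data.frame(gene = "G1", contig = "1",
                                           start = 1L, end = 100L),
                geneReads = c(G1 = 100))
  expect_true(res$calls$is_ase[res$calls$position == 5000])
  expect_false(5000 %in% res$siteGenes$position)
})

test_that("eGWAS x ASE integration assigns the documented categories", {
  eqtl <- data.frame(
    probe = paste0("p", 1:4),
    snp = paste0("s", 1:4),
    chrom = c("1", "2", "1", "1"),
    pos = 1:4 * 1e6,
    p = 1e-9,
    gene = c("G1", "G2", "G3", NA),
    regulation = c("local", "distant", "distant", "local"))
  aseGenes <- data.frame(gene = c("G1", "G2", "G5"),
                         n_ase_snps = c(2L, 1L, 1L),
                         is_ase = TRUE)
  geneChrom <- c(G1 = "1", G2 = "7", G3 = "1", G5 = "3")
  res <- integrateEgwasAse(eqtl, aseGenes, geneChrom = geneChrom)
  expect_identical(res$category[res$gene == "G1"], "cis_validated")
  expect_identical(res$category[res$gene == "G2"], "cis_trans_candidate")
  expect_true(res$distant_other_chrom[res$gene == "G2"])
  expect_identical(res$category[res$gene == "G3"], "egwas_only")
  expect_identical(res$category[res$gene == "G5"], "ase_only")
  expect_false("G4" %in% res$gene)
  cnt <- attr(res, "counts")
  expect_identical(sum(cnt), 4L)
})

test_that("null allele counts yield almost no ASE-SNPs", {
  # 38 animals, balanced alleles: per-site false call rate stays near zero
  set.seed(31)
  called <- 0L; total <- 0L
  for (rep in 1:20) {
    counts <- do.call(rbind, lapply(1:10, function(i) {
      tot <- rnbinom(38, size = 10, mu = 50)
      toyCounts(paste0("a", 1:38), NA, rbinom(38, tot, 0.5), "het",
                position = i) |>
        transform(refCount = tot - altCount)
    }))
    counts$refCount <- as.integer(counts$refCount)
    res <- runAse(counts)
    called <- called + sum(res$calls$is_ase, na.rm = TRUE)
    total <- total + sum(!is.na(res$calls$is_ase))
  }
  expect_lte(called / total, 0.01)
})
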