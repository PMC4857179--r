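test_that("kinship recursion reproduces textbook relationship values", {
  kin <- kinship_from_pedigree(nuclear_family())
  A <- as.matrix(kin)
  expect_equal(unname(diag(A)), rep(1, 4))
  expect_equal(A["fa", "c1"], 0.5)   # parent-offspring: k = 0.25, 2k = 0.5
  expect_equal(A["c1", "c2"], 0.5)   # full sibs
  expect_equal(A["fa", "mo"], 0)     # unrelated founders

  single <- pedigree(fam = "f", id = "solo")
  expect_equal(unname(as.matrix(kinship_from_pedigree(single))), matrix(1))

  kc <- as.matrix(kinship_from_pedigree(cousin_pedigree()))
  expect_equal(kc["k1", "k2"], 0.125) # first cousins
})

test_that("kinship recursion agrees with gene-dropping IBD Monte Carlo", {
  ped <- cousin_pedigree()
  A <- as.matrix(kinship_from_pedigree(ped))
  ndrops <- 2e4
  Ahat <- gene_drop_kinship(ped, ndrops = ndrops, seed = 7)
  # binomial-ish SE of the averaged sharing indicator
  se <- 3 * sqrt(0.25 / ndrops) * 2
  off <- upper.tri(A)
  expect_lt(max(abs(A[off] - Ahat[off])), se + 1e-9)
})

test_that("kinship matrix is block-diagonal by family and id-aligned", {
  co <- small_cohort(4)
  A <- as.matrix(co$kin)
  expect_identical(rownames(A), co$ped$id[co$ped$sampled])
  f <- co$kin$fam
  for (i in seq_len(nlevels(f))) for (j in seq_len(nlevels(f))) {
    if (i != j)
      expect_true(all(A[f == levels(f)[i], f == levels(f)[j]] == 0))
  }
  # symmetric PSD with entries in [0, 2]
  expect_equal(A, t(A))
  expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_true(all(A >= 0 & A <= 2))
})

test_that("pedigree validation names the offending individual", {
  expect_error(
    pedigree(fam = c("f", "f"), id = c("a", "b"),
             father = c(NA, "ghost"), mother = c(NA, "a")),
    "ghost")
  expect_error(
    pedigree(fam = c("f", "f"), id = c("a", "b"),
             father = c(NA, "a"), mother = c(NA, NA)),
    "one known parent")
  expect_error(
    pedigree(fam = c("f", "f"), id = c("a", "b"),
             father = c("b", "a"), mother = c("b", "a")),
    "cycle")
})

test_that("PED files round-trip including sampled flags", {
  ped <- make_synthetic_cohort(2)
  path <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, path)
  back <- read_ped(path)
  expect_equal(as.data.frame(back), as.data.frame(ped))
  expect_error(read_ped(file.path(tempdir(), "does-not-exist.ped")),
               "not found")
})

test_that("the shipped example pedigree parses with expected relationships", {
  path <- system.file("extdata", "example.ped", package = "mixbn")
  ped <- read_ped(path)
  expect_equal(length(unique(ped$fam)), 2L)
  expect_false(any(ped$sampled[ped$id %in% c("gf", "gm")]))
  A <- as.matrix(kinship_from_pedigree(ped))
  expect_equal(A["c11", "c21"], 0.125)
  expect_equal(A["s1", "s2"], 0.5)
  expect_equal(A["c11", "d"], 0)
})

test_that("synthetic cohorts have the study dimensions", {
  ped <- make_synthetic_cohort(582)
  expect_equal(sum(ped$sampled), 4656)
  expect_equal(length(unique(ped$fam)), 582)
  one <- kinship_from_pedigree(make_synthetic_cohort(1))
  expect_equal(length(one$blocks), 1L)
  expect_error(make_synthetic_cohort(3, "no-such-template"), "llfs8")
})

test_that("gene-dropped SNPs respect MAF and Mendelian transmission", {
  ped <- make_synthetic_cohort(30)
  G <- gene_drop_snps(ped, q = 10, maf_min = 0.05, seed = 3)
  expect_equal(dim(G), c(240L, 10L))
  expect_true(all(attr(G, "maf") >= 0.05))
  expect_true(all(G %in% 0:2))
  # trio consistency: a child cannot carry an allele count incompatible with
  # its parents (e.g. parent 0 and child 2 sharing both alleles)
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  kids <- which(!is.na(ped$father) & ped$sampled)
  Gall <- matrix(NA_integer_, nrow(ped), ncol(G))
  Gall[ped$sampled, ] <- G
  for (i in kids) {
    fa <- Gall[idx[ped$father[i]], ]; mo <- Gall[idx[ped$mother[i]], ]
    ok <- is.na(fa) | is.na(mo) |
      (Gall[i, ] >= (fa == 2) + (mo == 2) &
       Gall[i, ] <= 2 - ((fa == 0) + (mo == 0)))
    expect_true(all(ok))
  }
})

test_that("gene-dropped genotype correlation tracks relatedness", {
  ped <- make_synthetic_cohort(300)
  kin <- kinship_from_pedigree(ped)
  G <- gene_drop_snps(ped, q = 6, maf_min = 0.1, seed = 9)
  Ga <- array(G, c(8, 300, 6))
  pairs <- list(c(1, 2), c(1, 5), c(1, 7), c(5, 7), c(3, 4)) # within-family
  A1 <- kin$blocks[[1]]
  rel <- vapply(pairs, function(p) A1[p[1], p[2]], 0)
  emp <- vapply(pairs, function(p)
    mean(vapply(1:6, function(s) cor(Ga[p[1], , s], Ga[p[2], , s]), 0)), 0)
  expect_gt(cor(rel, emp, method = "spearman"), 0)
  expect_equal(emp, rel, tolerance = 0.25)
})

test_that("founder-only gene drop with fixed p has binomial mean", {
  ped <- make_synthetic_cohort(500, "singleton")
  G <- gene_drop_snps(ped, q = 4, maf_min = 0.45, seed = 2)
  # p ~ U(0.45, 0.5): column means concentrate near 2 * 0.475
  expect_equal(unname(colMeans(G)), rep(0.95, 4), tolerance = 0.12)
})

test_that("kinship TSV export carries ids as header row and column", {
  co <- small_cohort(2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kinship_tsv(co$kin, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  expect_identical(tab$id, co$kin$ids)
  expect_identical(colnames(tab)[-1], co$kin$ids)
  expect_equal(as.matrix(tab[, -1]), as.matrix(co$kin),
               ignore_attr = TRUE)
})
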