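test_that("the default region partition matches the four promoter regions", {
  p <- regionPartition()
  expect_equal(p$region, c("R1", "R2", "R3", "R4"))
  expect_equal(p$start, c(0, -500, -1000, -3000))
  expect_equal(p$end, c(500, 0, -500, -1000))
  expect_error(regionPartition(starts = c(0, -400), ends = c(500, 50),
                               labels = c("A", "B")),
               "disjoint")
})

test_that("region frequencies are raw per-region motif fractions", {
  # 25 CpG starts among 500 start positions -> 0.05
  s <- paste0(paste(rep("CG", 25), collapse = ""),
              paste(rep("A", 451), collapse = ""))
  w <- PromoterWindows(setNames(paste0(paste(rep("T", 100), collapse = ""), s),
                                "g1"),
                       tssOffset = 100L)
  tab <- regionFrequencyTable(w, regionPartition(starts = 0, ends = 500,
                                                 labels = "R1"))
  expect_equal(tab$cpg_freq, 25 / 500)
  expect_equal(tab$n_positions, 500L)

  # all-A sequence is 0 in every region
  wA <- PromoterWindows(setNames(paste(rep("A", 3500), collapse = ""), "gA"),
                        tssOffset = 3000L)
  tabA <- regionFrequencyTable(wA)
  expect_equal(nrow(tabA), 4L)
  expect_true(all(tabA$cpg_freq == 0))

  # perfect CG repeat across R2 equals the brute-force count ratio
  wCG <- PromoterWindows(setNames(paste(rep("CG", 1750), collapse = ""), "gCG"),
                         tssOffset = 3000L)
  tabCG <- regionFrequencyTable(wCG)
  r2 <- tabCG[tabCG$region == "R2", ]
  ind <- motifIndicator(paste(rep("CG", 1750), collapse = ""), "CG")
  brute <- sum(ind[(3000 - 500 + 1):3000]) / 500
  expect_equal(r2$cpg_freq, brute)
  expect_equal(r2$cpg_freq, 0.5)
})

test_that("region frequencies match per-position counting with Ns and truncation", {
  set.seed(19)
  chars <- sample(c("A", "C", "G", "T", "N"), 2200, replace = TRUE,
                  prob = c(0.23, 0.26, 0.26, 0.2, 0.05))
  s <- paste(chars, collapse = "")
  w <- PromoterWindows(setNames(s, "g"), tssOffset = 1800L, fullUpstream = FALSE)
  tab <- regionFrequencyTable(w)
  ind <- motifIndicator(s, "CG")
  pos <- seq_along(ind) - 1801L
  for (r in seq_len(4)) {
    part <- regionPartition()
    inR <- pos >= part$start[r] & pos < part$end[r]
    expected_n <- sum(!is.na(ind[inR]))
    row <- tab[tab$region == part$region[r], ]
    expect_equal(row$n_positions, expected_n)
    expect_equal(row$cpg_freq, sum(ind[inR], na.rm = TRUE) / expected_n)
  }
})

test_that("Kruskal-Wallis H matches hand computation and kruskal.test", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskalWallis(g)
  expect_equal(res$statistic, 7.2)
  expect_equal(res$meanRanks, c(a = 2, b = 5, c = 8))

  expect_equal(kruskalWallis(list(c(5, 5), c(5, 5)))$statistic, 0)
  expect_equal(kruskalWallis(list(c(5, 5), c(5, 5)))$p.value, 1)

  set.seed(101)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    g <- lapply(seq_len(k), function(i)
      round(rnorm(sample(3:8, 1)), sample(0:1, 1)))  # induces ties
    res <- kruskalWallis(g)
    ref <- kruskal.test(g)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p.value, ref$p.value)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(103)
  g <- lapply(1:3, function(i) rexp(6) + i / 4)
  h1 <- kruskalWallis(g)$statistic
  h2 <- kruskalWallis(lapply(g, function(v) log(v + 1)))$statistic
  h3 <- kruskalWallis(lapply(g, function(v) v^3))$statistic
  expect_equal(h1, h2)
  expect_equal(h1, h3)
  expect_gte(h1, 0)
})

test_that("Dunn z matches the hand-computed example and is antisymmetric", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  d <- dunnPosthoc(g)
  zac <- d$z[d$group1 == "a" & d$group2 == "c"]
  expect_equal(abs(zac), 6 / sqrt(5))
  # antisymmetry under swapping the pair
  gSwap <- g[c("c", "b", "a")]
  dSwap <- dunnPosthoc(gSwap)
  expect_equal(dSwap$z[dSwap$group1 == "c" & dSwap$group2 == "a"], -zac)
  # identical groups give z = 0, p = 1
  dEq <- dunnPosthoc(list(x = c(1, 2), y = c(1, 2)))
  expect_equal(dEq$z, 0)
  expect_equal(dEq$p.value, 1)
})

test_that("Dunn z agrees in sign with group mean shifts on shifted normals", {
  set.seed(107)
  hits <- 0
  for (rep in 1:50) {
    g <- list(lo = rnorm(50), hi = rnorm(50, mean = 1))
    d <- dunnPosthoc(g)
    if (d$z[1] < 0) hits <- hits + 1  # lo minus hi rank means negative
  }
  expect_gte(hits, 50 * 0.99)
})

test_that("Wilcoxon exact p matches full enumeration and x == y gives p = 1", {
  res <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 3)
  expect_equal(res$p.value, 1 / 3)
  expect_true(res$exact)
  expect_equal(wilcoxonRankSum(c(5, 7), c(5, 7))$p.value, 1)

  # exact p equals wilcox.test's exact p on random tie-free samples
  set.seed(109)
  for (rep in 1:20) {
    x <- rnorm(sample(2:6, 1))
    y <- rnorm(sample(2:6, 1))
    mine <- wilcoxonRankSum(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_true(mine$exact)
    expect_equal(mine$p.value, ref$p.value)
  }
})

test_that("normal approximation tracks the exhaustive permutation p", {
  set.seed(111)
  cmb <- combn(16, 8)
  for (rep in 1:10) {
    x <- rnorm(8)
    y <- rnorm(8)
    appr <- wilcoxonRankSum(x, y, exact = FALSE)
    r <- rank(c(x, y))
    rs <- colSums(matrix(r[cmb], nrow = 8))
    W <- sum(r[1:8])
    pPerm <- min(1, 2 * min(mean(rs <= W), mean(rs >= W)))
    expect_lt(abs(appr$p.value - pPerm), 0.02)
  }
})

test_that("two-group Kruskal-Wallis equals the squared standardized rank-sum statistic", {
  set.seed(113)
  for (rep in 1:20) {
    x <- rnorm(sample(3:7, 1))
    y <- rnorm(sample(3:7, 1))
    H <- kruskalWallis(list(x, y))$statistic
    nx <- length(x)
    ny <- length(y)
    N <- nx + ny
    W <- sum(rank(c(x, y))[1:nx])
    z2 <- (W - nx * (N + 1) / 2)^2 / (nx * ny * (N + 1) / 12)
    expect_equal(H, z2)
    # permutation p of H equals the exact rank-sum p (same ordering statistic)
    cmb <- combn(N, nx)
    rs <- colSums(matrix(rank(c(x, y))[cmb], nrow = nx))
    hPerm <- (rs - nx * (N + 1) / 2)^2 / (nx * ny * (N + 1) / 12)
    pPermH <- mean(hPerm >= H - 1e-12)
    expect_equal(pPermH, wilcoxonRankSum(x, y)$p.value)
  }
})

test_that("KW and exact Wilcoxon agree in rejection for two tie-free groups", {
  set.seed(115)
  agree <- 0
  n <- 40
  for (rep in seq_len(n)) {
    x <- rnorm(10)
    y <- rnorm(10, mean = sample(c(0, 1), 1))
    pkw <- kruskalWallis(list(x, y))$p.value
    pw <- wilcoxonRankSum(x, y)$p.value
    if ((pkw < 0.05) == (pw < 0.05)) agree <- agree + 1
  }
  expect_gte(agree / n, 0.95)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(0.01, m = 4), 0.04)
  expect_equal(bonferroniAdjust(0.5, m = 4), 1)
  expect_equal(bonferroniAdjust(0.3, m = 1), 0.3)
  expect_equal(bonferroniAdjust(c(0.01, 0.02), m = 4), c(0.04, 0.08))
  expect_error(bonferroniAdjust(c(0.1, 0.2), m = 1), "family")
})

test_that("class_region analysis flags a planted high-CpG class in R4", {
  cfg <- syntheticGenomeConfig(
    nGenes = 1500, scaffoldLen = 300000, seed = 211,
    classRhoOffsets = list("Environmental Information Processing" =
                             list(factor = 1.3, interval = c(-3000, -1000)))
  )
  sim <- simulatePromoterWindows(cfg)
  tab <- regionFrequencyTable(sim$windows)
  sets <- split(sim$genes$gene_id, sim$genes$class)
  res <- classRegionAnalysis(tab, sets)
  kw4 <- res$kruskal[res$kruskal$region == "R4", ]
  expect_true(kw4$significant)
  d <- res$dunn$R4
  eip <- "Environmental Information Processing"
  sigEip <- d[(d$group1 == eip | d$group2 == eip) & d$p.adjusted < 0.05, ]
  expect_equal(nrow(sigEip), 4L)  # EIP differs from all four other classes
  # EIP holds a letter no other class shares
  lt <- res$letters$R4
  eipLetters <- strsplit(lt[[eip]], "")[[1]]
  others <- unlist(strsplit(unlist(lt[names(lt) != eip]), ""))
  expect_true(any(!eipLetters %in% others))
  # R1 (inside the exon, no offset) should not dominate: offsets only in R4
  expect_true(kw4$statistic == max(res$kruskal$statistic))
})

test_that("duplicated class labels give H near zero", {
  set.seed(117)
  vals <- runif(60, 0.02, 0.08)
  tab <- data.frame(gene_id = sprintf("g%02d", 1:60), region = "R1",
                    cpg_freq = vals, n_positions = 500L)
  sets <- list(A = sprintf("g%02d", 1:30), B = sprintf("g%02d", 31:60))
  part <- regionPartition(starts = 0, ends = 500, labels = "R1")
  res <- suppressWarnings(classRegionAnalysis(tab, sets, part, family = 1))
  # identical generative law for both labels: no signal expected
  expect_lt(res$kruskal$statistic, qchisq(0.999, df = 1))
})

test_that("focal-set analysis flags only the region with the planted offset", {
  cfg <- syntheticGenomeConfig(
    nGenes = 1200, scaffoldLen = 300000, seed = 311,
    focalFraction = 0.15,
    focalRhoOffset = list(factor = 1.3, interval = c(-500, 0))
  )
  sim <- simulatePromoterWindows(cfg)
  tab <- regionFrequencyTable(sim$windows)
  focal <- sim$genes$gene_id[sim$genes$focal]
  res <- setRegionAnalysis(tab, focal)
  expect_true(res$significant[res$region == "R2"])
  expect_equal(res$direction[res$region == "R2"], "higher")
  expect_false(any(res$significant[res$region %in% c("R1", "R3", "R4")]))
})

test_that("a focal set spanning all genes is an error (empty complement)", {
  tab <- data.frame(gene_id = c("a", "b"), region = "R1",
                    cpg_freq = c(0.02, 0.04), n_positions = 500L)
  part <- regionPartition(starts = 0, ends = 500, labels = "R1")
  expect_error(setRegionAnalysis(tab, c("a", "b"), part), "complement")
})
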