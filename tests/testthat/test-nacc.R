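make_mirror <- function(n = 30, samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n * samples, 1 / 40), n, samples,
              dimnames = list(sprintf("g%02d", 1:n),
                              paste0("s", 1:samples)))
  fams <- family_set(data.frame(
    family_id = rep(sprintf("f%02d", 1:n), each = 2),
    species = rep(c("A", "B"), n),
    gene_id = c(rbind(paste0(rownames(m), "_a"), paste0(rownames(m), "_b")))))
  A <- m; rownames(A) <- paste0(rownames(m), "_a")
  B <- m; rownames(B) <- paste0(rownames(m), "_b")
  list(exprA = A, exprB = B, fams = fams)
}

test_that("nacc is exactly zero on the mirror-species construction", {
  mir <- make_mirror()
  r <- nacc_score(mir$exprA, mir$exprB, mir$fams, k = 5)
  expect_equal(nrow(r), 30)
  expect_equal(r$nacc, rep(0, 30), tolerance = 1e-12)
  expect_equal(r$A_bar, r$AB_bar, tolerance = 1e-12)
})

test_that("nacc matches the brute-force oracle on a small instance", {
  set.seed(21)
  n <- 30
  A <- matrix(rexp(n * 5, 1 / 30), n, 5,
              dimnames = list(sprintf("a%02d", 1:n), paste0("s", 1:5)))
  B <- matrix(rexp(n * 7, 1 / 30), n, 7,
              dimnames = list(sprintf("b%02d", 1:n), paste0("t", 1:7)))
  fams <- family_set(data.frame(
    family_id = rep(sprintf("f%02d", 1:n), each = 2),
    species = rep(c("sp1", "sp2"), n),
    gene_id = c(rbind(rownames(A), rownames(B)))))
  r <- nacc_score(A, B, fams, spA = "sp1", spB = "sp2", k = 2)
  map <- as.list(stats::setNames(rownames(B), rownames(A)))
  expected <- oracle_nacc(A, B, map, k = 2)
  expect_equal(stats::setNames(r$nacc, r$geneA), expected, tolerance = 1e-10)
  # symmetric in the two species' roles
  swap <- family_set(data.frame(
    family_id = rep(sprintf("f%02d", 1:n), each = 2),
    species = rep(c("sp2", "sp1"), n),
    gene_id = c(rbind(rownames(B), rownames(A)))))
  r2 <- nacc_score(B, A, swap, spA = "sp2", spB = "sp1", k = 2)
  expect_equal(sort(r2$nacc), sort(r$nacc), tolerance = 1e-10)
})

test_that("nacc rejects families without enough neighbours", {
  mir <- make_mirror(n = 5)
  expect_error(nacc_score(mir$exprA, mir$exprB, mir$fams, k = 20),
               "rejected")
})

test_that("scrambled orthology increases mean nacc on conserved data", {
  worse <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 40
    A <- matrix(rexp(n * 6, 1 / 30), n, 6,
                dimnames = list(sprintf("a%02d", 1:n), paste0("s", 1:6)))
    B <- A * matrix(rlnorm(n * 6, 0, 0.1), n, 6)  # conserved + mild noise
    rownames(B) <- sprintf("b%02d", 1:n)
    fams <- family_set(data.frame(
      family_id = rep(sprintf("f%02d", 1:n), each = 2),
      species = rep(c("sp1", "sp2"), n),
      gene_id = c(rbind(rownames(A), rownames(B)))))
    true_mean <- mean(nacc_score(A, B, fams, "sp1", "sp2", k = 5)$nacc)
    nul <- nacc_null(A, B, fams, "sp1", "sp2", k = 5,
                     n_permutations = 3, seed = seed)
    if (mean(nul$null_means) > true_mean) worse <- worse + 1
    # planted conserved signal: p at the permutation floor
    expect_lte(nul$p_value, 1 / (3 + 1))
  }
  expect_equal(worse, 20)
})

test_that("nacc_null is reproducible under a fixed seed", {
  mir <- make_mirror(n = 25, seed = 3)
  n1 <- nacc_null(mir$exprA, mir$exprB, mir$fams, k = 4,
                  n_permutations = 1, seed = 11)
  n2 <- nacc_null(mir$exprA, mir$exprB, mir$fams, k = 4,
                  n_permutations = 1, seed = 11)
  expect_identical(n1$null_means, n2$null_means)
})

test_that("module_overlap_test matches exact enumeration", {
  # universe 10, |m| = 5, |n| = 5, overlap 4
  assignA <- data.frame(gene_id = paste0("a", 1:10),
                        module = rep(c("m", "x"), each = 5))
  assignB <- data.frame(gene_id = paste0("b", 1:10),
                        module = c(rep("n", 4), "y", "n",
                                   rep("y", 4)))
  pairs <- data.frame(geneA = paste0("a", 1:10), geneB = paste0("b", 1:10))
  res <- module_overlap_test(assignA, assignB, pairs)
  expect_equal(res$overlap["m", "n"], 4L)
  expect_equal(res$p["m", "n"], 26 / 252, tolerance = 1e-12)
  expect_equal(res$p["m", "n"], oracle_hyper_upper(4, 5, 5, 10),
               tolerance = 1e-12)
  # overlap 0 -> p = P(X >= 0) = 1
  tiny <- module_overlap_test(
    data.frame(gene_id = paste0("a", 1:4), module = c("m", "m", "x", "x")),
    data.frame(gene_id = paste0("b", 1:4), module = c("n", "n", "y", "y")),
    data.frame(geneA = paste0("a", 1:4), geneB = paste0("b", 1:4)))
  expect_equal(tiny$overlap["m", "y"], 0L)
  expect_equal(tiny$p["m", "y"][[1]], 1)
  expect_true(all(res$p > 0 & res$p <= 1))
  # row sums of overlap equal module sizes within the universe
  expect_equal(unname(rowSums(res$overlap)), c(5, 5))
  expect_error(module_overlap_test(assignA[0, ], assignB, pairs), "empty")
})

test_that("identical assignments give minimal diagonal overlap p", {
  set.seed(8)
  mods <- sample(paste0("M", 1:4), 80, replace = TRUE)
  assignA <- data.frame(gene_id = paste0("a", 1:80), module = mods)
  assignB <- data.frame(gene_id = paste0("b", 1:80), module = mods)
  pairs <- data.frame(geneA = paste0("a", 1:80), geneB = paste0("b", 1:80))
  res <- module_overlap_test(assignA, assignB, pairs)
  for (i in seq_len(nrow(res$p)))
    expect_equal(which.min(res$p[i, ]), i, ignore_attr = TRUE)
})

test_that("module_motif_correlation matches the textbook formula", {
  set.seed(4)
  zA <- matrix(rnorm(15), 3, 5,
               dimnames = list(paste0("A", 1:3), paste0("mot", 1:5)))
  zB <- matrix(rnorm(10), 2, 5,
               dimnames = list(paste0("B", 1:2), paste0("mot", 1:5)))
  r <- module_motif_correlation(zA, zB)
  pearson <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  for (i in 1:3) for (j in 1:2)
    expect_equal(r$cor[i, j], pearson(zA[i, ], zB[j, ]), tolerance = 1e-12)
  expect_true(all(r$cor >= -1 & r$cor <= 1))
  # self and negated-self correlations
  rs <- module_motif_correlation(zA, zA)
  expect_equal(unname(diag(rs$cor)), rep(1, 3))
  rn <- module_motif_correlation(zA, -zA)
  expect_equal(unname(diag(rn$cor)), rep(-1, 3))
  # zero-variance profile -> explicit NA
  zC <- zB; zC[1, ] <- 2
  expect_true(all(is.na(module_motif_correlation(zA, zC)$cor[, 1])))
  expect_error(module_motif_correlation(zA[, 1:2], zB[, 1:2]), "3 shared")
})
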