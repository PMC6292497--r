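nine <- sprintf("domain%d", 1:9)

bin_from <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- nine
  b <- (m > 0.5) + 0L
  attr(b, "threshold") <- 5
  class(b) <- c("binary_profile", class(b))
  b
}

fam3 <- function(nb) {
  family_set(data.frame(
    family_id = "f1",
    species = c("outgroup", rep("vertebrate", nb)),
    gene_id = c("a1", paste0("v", seq_len(nb)))))
}

test_that("domain_bias computes the stated subtraction per mode", {
  binA <- bin_from(list(a1 = rep(1, 9)))
  binB <- bin_from(list(v1 = c(rep(1, 3), rep(0, 6)),
                        v2 = c(rep(0, 3), rep(1, 6))))
  fams <- fam3(2)
  ind <- domain_bias(binA, binB, fams, mode = "individual_ohnologue")
  expect_equal(sort(ind$bias), c(-6, -3))
  expect_equal(ind$domains_outgroup, c(9, 9))
  uni <- domain_bias(binA, binB, fams, mode = "union")
  expect_equal(uni$bias, 0)   # union covers all nine
  # sum_then_binarize: summed raw expression crosses the threshold
  raw <- rbind(v1 = c(rep(3, 9)), v2 = c(rep(3, 9)))
  colnames(raw) <- nine
  st <- domain_bias(binA, binB, fams, mode = "sum_then_binarize",
                    exprB_raw = raw)
  expect_equal(st$domains_vertebrate, 9)  # 3 + 3 > 5 everywhere
  expect_error(domain_bias(binA, binB[, 9:1], fams), "differ")
})

test_that("neg_pos_log_ratio follows its closed forms", {
  expect_equal(neg_pos_log_ratio(c(rep(-1, 10), rep(1, 10), 0, 0)), 0)
  expect_equal(neg_pos_log_ratio(c(rep(-1, 8), rep(1, 2))), 2)
  expect_warning(r <- neg_pos_log_ratio(c(1, 2, 3)), "infinite")
  expect_identical(r, -Inf)
})

test_that("classify_fates implements the three-way taxonomy", {
  binA <- bin_from(list(a1 = rep(1, 9)))
  # redundancy: all members full
  red <- bin_from(list(v1 = rep(1, 9), v2 = rep(1, 9)))
  expect_equal(classify_fates(binA, red, fam3(2))$fates$fate, "redundancy")
  # specialization with one strong member (2 domains)
  spec <- bin_from(list(v1 = rep(1, 9), v2 = c(1, 1, rep(0, 7))))
  fc <- classify_fates(binA, spec, fam3(2))
  expect_equal(fc$fates$fate, "specialization")
  expect_setequal(fc$members$subtype, c("spec_equal", "spec_strong"))
  # members with 7 and 8 domains, union 9 -> subfunctionalization
  sub <- bin_from(list(v1 = c(rep(1, 7), 0, 0), v2 = c(0, 0, rep(1, 7))))
  fc2 <- classify_fates(binA, sub, fam3(2))
  expect_equal(fc2$fates$fate, "subfunctionalization")
  expect_equal(sum(fc2$frequencies), 1)
  # boundary: exactly 3 retained domains is spec_mild, 2 is spec_strong
  spec3 <- bin_from(list(v1 = rep(1, 9), v2 = c(1, 1, 1, rep(0, 6))))
  expect_true("spec_mild" %in%
                classify_fates(binA, spec3, fam3(2))$members$subtype)
  # ineligible: outgroup not fully on
  partA <- bin_from(list(a1 = c(rep(1, 8), 0)))
  fc3 <- classify_fates(partA, red, fam3(2))
  expect_null(fc3$fates)
  expect_match(fc3$ineligible$f1, "outgroup")
  # ineligible: union not covering
  gap <- bin_from(list(v1 = c(rep(1, 8), 0), v2 = c(rep(1, 8), 0)))
  expect_match(classify_fates(binA, gap, fam3(2))$ineligible$f1, "union")
})

test_that("planted fates are recovered at zero noise, per fate", {
  for (fate in c("redundancy", "subfunctionalization", "specialization")) {
    mix <- c(redundancy = 0, subfunctionalization = 0, specialization = 0)
    mix[fate] <- 1
    cfg <- synthetic_config(seed = 1, n_ohno_families = 60, fate_mix = mix)
    ft <- generate_fate_families(cfg, n_1to1 = 0)
    fc <- classify_fates(binarize(ft$exprA), binarize(ft$exprB),
                         ohnologue_families(ft$fams, "outgroup",
                                            "vertebrate"))
    expect_equal(nrow(fc$fates), 60)
    expect_true(all(fc$fates$fate == fate))
  }
})

test_that("fate recovery degrades monotonically with expression noise", {
  recovery <- vapply(c(0, 0.5, 1.5), function(ns) {
    cfg <- synthetic_config(seed = 6, n_ohno_families = 120,
                            expression_noise_sd = ns)
    ft <- generate_fate_families(cfg, n_1to1 = 0)
    fc <- classify_fates(binarize(ft$exprA), binarize(ft$exprB),
                         ohnologue_families(ft$fams, "outgroup",
                                            "vertebrate"))
    mean(fc$fates$fate == ft$truth$fate[fc$fates$family_id])
  }, numeric(1))
  expect_equal(recovery[1], 1)
  expect_true(all(diff(recovery) <= 0))
  expect_lt(recovery[3], recovery[1])
})

test_that("union-mode 'on' set contains every member's 'on' set", {
  cfg <- synthetic_config(seed = 2, n_ohno_families = 40)
  ft <- generate_fate_families(cfg, n_1to1 = 0)
  binB <- binarize(ft$exprB)
  for (fid in names(ft$fams$families)[1:20]) {
    gb <- ft$fams$families[[fid]]$vertebrate
    u <- apply(unclass(binB)[gb, , drop = FALSE], 2, max)
    for (g in gb) expect_true(all(u >= unclass(binB)[g, ]))
  }
})

test_that("specialization_domain_retention counts multi-domain members", {
  binA <- bin_from(list(a1 = rep(1, 9)))
  spec <- bin_from(list(v1 = rep(1, 9),
                        v2 = c(1, 1, rep(0, 7)),    # domains 1, 2
                        v3 = c(1, rep(0, 8))))      # domain 1
  fc <- classify_fates(binA, spec, fam3(3))
  ret <- specialization_domain_retention(fc)
  expect_equal(unname(ret[nine[1]]), 2)
  expect_equal(unname(ret[nine[2]]), 1)
})

test_that("rank tests match exact enumeration and detect planted shifts", {
  # tiny case: exact enumeration over rank permutations
  x <- c(1.1, 2.3, 3.5); y <- c(0.2, 0.9, 4.1)
  got <- rank_sum_test_oracle_check <- stats::wilcox.test(
    x, y, alternative = "greater", exact = TRUE)$p.value
  fate_calls <- list(members = data.frame(
    family_id = "f", gene_id = c("g1", "g2", "g3", "h1", "h2", "h3"),
    fate = "specialization",
    subtype = rep(c("spec_strong", "spec_equal"), each = 3),
    n_domains_on = 1, domains_on = "domain1", stringsAsFactors = FALSE))
  counts <- stats::setNames(c(x, y), fate_calls$members$gene_id)
  r <- fates_vs_apre_counts(fate_calls, counts)
  p_strong <- r$tests$p_value[r$tests$contrast == "spec_strong > spec_equal"]
  expect_equal(p_strong, got, tolerance = 1e-12)
  # identical distributions: non-significant
  same <- stats::setNames(rep(c(1, 2, 5, 9), 3)[1:6],
                          fate_calls$members$gene_id)
  r2 <- fates_vs_apre_counts(fate_calls, same)
  expect_gt(min(r2$tests$p_value, na.rm = TRUE), 0.05)
  # power: planted +50% shift detected at n = 200 per group
  detected <- 0
  for (seed in 1:20) {
    set.seed(seed)
    strong <- rpois(200, 15); equal <- rpois(200, 10)
    ids <- c(paste0("s", 1:200), paste0("e", 1:200))
    mem <- data.frame(family_id = "f", gene_id = ids,
                      fate = "specialization",
                      subtype = rep(c("spec_strong", "spec_equal"),
                                    each = 200),
                      n_domains_on = 1, domains_on = "domain1")
    rr <- fates_vs_apre_counts(list(members = mem),
                               stats::setNames(c(strong, equal), ids))
    p <- rr$tests$p_value[rr$tests$contrast == "spec_strong > spec_equal"]
    if (p < 0.05) detected <- detected + 1
  }
  expect_gte(detected / 20, 0.9)
})

test_that("divergence_vs_fate joins, tests and reports missing values", {
  mem <- data.frame(family_id = "f", gene_id = paste0("g", 1:8),
                    fate = "specialization",
                    subtype = rep(c("spec_strong", "spec_equal"), each = 4),
                    n_domains_on = 1, domains_on = "domain1")
  sims <- stats::setNames(c(80, 82, 79, 81, 95, 96, 94, 97),
                          paste0("g", 1:8))
  r <- divergence_vs_fate(sims, list(members = mem))
  expect_equal(r$n_missing, 0)
  expect_lt(r$tests$p_value[1], 0.05)
  # exact enumeration agreement on the 2-group toy
  expect_equal(r$tests$p_value[1],
               stats::wilcox.test(sims[1:4], sims[5:8],
                                  exact = TRUE)$p.value)
  # all-equal similarities: nothing significant (skipped as all-ties)
  r2 <- divergence_vs_fate(stats::setNames(rep(5, 8), paste0("g", 1:8)),
                           list(members = mem))
  expect_gt(r2$tests$p_value[1], 0.5)
  r3 <- divergence_vs_fate(sims[1:6], list(members = mem))
  expect_equal(r3$n_missing, 2)
})
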