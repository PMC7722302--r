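rc <- function(s) oracle_revcomp(s)

test_that("a UTR containing the exact reverse complement of a miRNA is a site", {
  set.seed(79)
  mir <- random_seq(22)
  utr <- paste0(random_seq(200), rc(mir), random_seq(200))
  # guard the fixture: no second seed match planted by chance
  sites <- scan_targets(c(m1 = mir), c(u1 = utr))
  expect_gte(nrow(sites), 1)
  expect_true(any(sites$score == 145))
})

test_that("random seed-match counts follow the closed-form 4^-7 expectation", {
  # 500 seeded trials: one random 22-mer against one random 1-kb UTR,
  # Watson-Crick-only seed, no score gate; expected matches per trial
  # = (1000 - 6) * 4^-7
  set.seed(83)
  n_trials <- 500
  hits <- 0
  for (i in seq_len(n_trials)) {
    s <- scan_targets(c(m = random_seq(22)), c(u = random_seq(1000)),
                      min_score = -Inf, seed_gu_max = 0)
    hits <- hits + nrow(s)
  }
  lambda <- n_trials * (1000 - 6) * 4^-7
  expect_lt(abs(hits - lambda), 3 * sqrt(lambda))
})

test_that("planted seed sites are all recalled and seed-free UTRs yield none", {
  set.seed(89)
  mir <- random_seq(22)
  site <- rc(mir)
  has_seed <- function(u) {
    nrow(scan_targets(setNames(list(mir), "m"), c(u = u),
                      min_score = -Inf)) > 0
  }
  utrs <- character(6)
  for (i in 1:3) { # three UTRs with one planted perfect site each
    repeat {
      u <- paste0(random_seq(300), site, random_seq(300))
      if (nrow(scan_targets(c(m = mir), c(u = u), min_score = -Inf)) == 1)
        break
    }
    utrs[i] <- u
  }
  for (i in 4:6) { # three UTRs with no seed match at all
    repeat {
      u <- random_seq(622)
      if (!has_seed(u)) break
    }
    utrs[i] <- u
  }
  names(utrs) <- paste0("u", 1:6)
  sites <- scan_targets(c(m = mir), utrs)
  expect_setequal(sites$mrna_id, c("u1", "u2", "u3"))
  expect_equal(nrow(sites), 3)
  expect_equal(sites$start, rep(301 + 22 - 8, 3)) # seed at miRNA 2..8
})

test_that("chi-square matches the closed form and chisq.test on hand tables", {
  flat <- chisq_2x2(10, 10, 10, 10)
  expect_equal(flat$chi_square, 0)
  expect_gt(flat$p, 0.99)
  hand <- chisq_2x2(30, 70, 10, 190)
  expect_equal(hand$chi_square, oracle_chisq_2x2(30, 70, 10, 190),
               tolerance = 1e-9)
  ct <- suppressWarnings(
    stats::chisq.test(matrix(c(30, 10, 70, 190), 2), correct = FALSE))
  expect_equal(hand$chi_square, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(hand$p, ct$p.value, tolerance = 1e-9)
})

test_that("a strongly enriched planted term survives Bonferroni; balanced terms do not", {
  set.seed(97)
  targets <- paste0("t", 1:60)
  background <- paste0("b", 1:600)
  g2t <- rbind(
    # planted: 50% of targets, 5% of background
    data.frame(gene = c(targets[1:30], background[1:30]),
               term = "GO:planted"),
    # decoys at equal rates in targets and background
    do.call(rbind, lapply(1:10, function(k) data.frame(
      gene = c(sample(targets, 12), sample(background, 120)),
      term = paste0("GO:flat", k)))))
  enr <- go_enrichment(targets, background, g2t)
  expect_true(enr$significant[enr$term == "GO:planted"])
  expect_false(any(enr$significant[enr$term != "GO:planted"]))
  # terms with expected cells below 5 are excluded from testing
  g2t2 <- rbind(g2t, data.frame(gene = targets[1], term = "GO:rare"))
  enr2 <- go_enrichment(targets, background, g2t2)
  expect_false(enr2$tested[enr2$term == "GO:rare"])
  expect_true(is.na(enr2$p[enr2$term == "GO:rare"]))
})

test_that("Bonferroni significance is monotone in the number of tested terms", {
  targets <- paste0("t", 1:60)
  background <- paste0("b", 1:600)
  # marginal enrichment: p ~ 0.03, significant only when tested alone
  base_terms <- data.frame(gene = c(targets[1:10], background[1:50]),
                           term = "GO:x")
  extra <- do.call(rbind, lapply(1:20, function(k) data.frame(
    gene = c(targets[11:22], background[101:220]),
    term = paste0("GO:pad", k))))
  e1 <- go_enrichment(targets, background, base_terms)
  e2 <- go_enrichment(targets, background, rbind(base_terms, extra))
  sig1 <- e1$significant[e1$term == "GO:x"]
  sig2 <- e2$significant[e2$term == "GO:x"]
  expect_true(sig1)
  expect_false(sig2) # a stricter family-wise level cannot add significance
})

test_that("regeneration-gene target comparison handles degenerate and planted cases", {
  empty <- data.frame(mirna_id = character(0), mrna_id = character(0))
  expect_equal(regen_target_comparison(empty, "m1", "m2", "g1")$verdict,
               "not-testable")
  sites <- data.frame(
    mirna_id = c(rep("pheno", 40), rep("ctrl", 40)),
    mrna_id = c(rep("regen1", 20), rep("other", 20),
                rep("regen1", 5), rep("other", 35)),
    stringsAsFactors = FALSE)
  res <- regen_target_comparison(sites, "pheno", "ctrl", "regen1")
  expect_equal(res$verdict, "enriched")
  sym <- data.frame(mirna_id = c(rep("pheno", 20), rep("ctrl", 20)),
                    mrna_id = rep(c(rep("regen1", 10), rep("other", 10)), 2))
  res2 <- regen_target_comparison(sym, "pheno", "ctrl", "regen1")
  expect_equal(res2$chi_square, 0)
  expect_equal(res2$verdict, "not-enriched")
})

ctrl_sum <- list(mean_dist_ratio = 0.3)
animal <- function(aL = 100, aR = 100, d = 30, h = 100, pr = 2,
                   white = TRUE, lesion = FALSE) {
  list(pr_count = pr, area_left = aL, area_right = aR, distance = d,
       head_diameter = h, white_region_present = white,
       lesion_or_lysed = lesion)
}

test_that("phenotype classification follows the precedence and 33% rules", {
  expect_equal(classify_phenotype(animal(), ctrl_sum), "regular-paired")
  # 100 vs 140 differ by 40% of the smaller area -> irregular
  expect_equal(classify_phenotype(animal(aL = 100, aR = 140), ctrl_sum),
               "irregular-paired")
  # 100 vs 125 differ by 25% -> still regular
  expect_equal(classify_phenotype(animal(aL = 100, aR = 125), ctrl_sum),
               "regular-paired")
  expect_equal(classify_phenotype(animal(pr = 1), ctrl_sum), "cyclopia")
  expect_equal(classify_phenotype(animal(pr = 0), ctrl_sum), "no-PR")
  expect_equal(classify_phenotype(animal(lesion = TRUE), ctrl_sum),
               "lesion/lysed")
  expect_equal(classify_phenotype(animal(white = FALSE), ctrl_sum),
               "irregular-paired")
  expect_equal(classify_phenotype(animal(d = 45), ctrl_sum),
               "irregular-paired") # 0.45/0.3 deviates by 50% > 1/3
})

test_that("phenotype classification is scale invariant", {
  a <- animal(aL = 120, aR = 150, d = 33, h = 110)
  s <- 7.3
  b <- animal(aL = 120 * s^2, aR = 150 * s^2, d = 33 * s, h = 110 * s)
  expect_equal(classify_phenotype(a, ctrl_sum),
               classify_phenotype(b, ctrl_sum))
})

pr_df <- function(areas, d = 30, h = 100) {
  data.frame(area_left = areas, area_right = areas, distance = d,
             head_diameter = h, pr_count = 2)
}

test_that("pr_stats is null on identical samples and matches the pooled-t formula", {
  x <- pr_df(c(90, 100, 110, 95, 105), d = c(28, 30, 32, 29, 31))
  res0 <- pr_stats(x, x)
  expect_equal(res0$relative_area, 1)
  expect_equal(res0$t, 0)
  expect_equal(res0$distance_variance_ratio, 1)
  y <- pr_df(c(60, 70, 65, 75, 55), d = c(25, 35, 30, 28, 33))
  res <- pr_stats(y, x)
  expect_equal(res$t, oracle_pooled_t((y$area_left + y$area_right) / 2,
                                      (x$area_left + x$area_right) / 2),
               tolerance = 1e-9)
  tt <- t.test((y$area_left + y$area_right) / 2,
               (x$area_left + x$area_right) / 2, var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("simulated knockdown arms at 60% of control area give the expected effect", {
  set.seed(101)
  ok <- vapply(1:20, function(i) {
    ctrl <- pr_df(rnorm(30, 2000, 200), d = rnorm(30, 30, 3))
    cond <- pr_df(rnorm(30, 1200, 200), d = rnorm(30, 30, 6))
    r <- pr_stats(cond, ctrl)
    r$relative_area >= 0.52 && r$relative_area <= 0.66 && r$p < 1e-4
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("phenotype summary tabulates category fractions per condition", {
  rec <- rbind(
    data.frame(condition = "scrambled", pr_count = 2, area_left = 100,
               area_right = 100, distance = 30, head_diameter = 100,
               white_region_present = TRUE, lesion_or_lysed = FALSE),
    data.frame(condition = "scrambled", pr_count = 2, area_left = 105,
               area_right = 95, distance = 31, head_diameter = 100,
               white_region_present = TRUE, lesion_or_lysed = FALSE),
    data.frame(condition = "kd", pr_count = 1, area_left = 50,
               area_right = 0, distance = 0, head_diameter = 100,
               white_region_present = FALSE, lesion_or_lysed = FALSE),
    data.frame(condition = "kd", pr_count = 2, area_left = 40,
               area_right = 90, distance = 30, head_diameter = 100,
               white_region_present = TRUE, lesion_or_lysed = FALSE))
  s <- phenotype_summary(rec)
  expect_equal(s[s$condition == "scrambled", "regular-paired"], 1)
  expect_equal(s[s$condition == "kd", "cyclopia"], 0.5)
  expect_equal(s[s$condition == "kd", "irregular-paired"], 0.5)
})
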