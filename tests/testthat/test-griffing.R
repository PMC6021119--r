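test_that("cell means average blocks and fill the symmetric matrix", {
  cm <- cell_means(toy_pheno(), "t")
  # hand-averaged values of the two blocks
  expect_equal(cm$matrix["A", "A"], (10 + 11) / 2)
  expect_equal(cm$matrix["A", "B"], (12 + 13) / 2)
  expect_equal(cm$matrix["B", "C"], (13 + 14) / 2)
  expect_equal(cm$matrix, t(cm$matrix))
  expect_equal(cm$row_total, rowSums(cm$matrix))
  expect_equal(cm$grand_total, sum(cm$matrix[upper.tri(cm$matrix, diag = TRUE)]))
  expect_equal(cm$b, 2)
})

test_that("constant data give constant cells and zero sums of squares", {
  vals <- data.frame(
    parent_a = c("A", "B", "C", "A", "A", "B"),
    parent_b = c("A", "B", "C", "B", "C", "C"),
    value = 7
  )
  tab <- pheno_from_genotypes(c("A", "B", "C"), vals, blocks = 2)
  cm <- cell_means(tab, "t")
  expect_true(all(cm$matrix == 7))
  expect_equal(cm$grand_total, 7 * 6)
  an <- rcbd_anova(tab, "t")
  expect_equal(an$ss, rep(0, 3))
  gp <- griffing_partition(cm)
  expect_equal(gp$ss, c(0, 0))
  eff <- estimate_effects(cm)
  expect_equal(eff$mu, 7)
  expect_equal(eff$gca$gca, rep(0, 3))
  expect_equal(eff$sca$sca, rep(0, 6))
})

test_that("incomplete designs are rejected with the offending cells named", {
  tab <- toy_pheno()
  drop <- !(tab$parent_a == "A" & tab$parent_b == "B" & tab$block == 2)
  tab2 <- as_diallel_pheno(as.data.frame(tab)[drop, ], c("A", "B", "C"))
  expect_error(cell_means(tab2, "t"), class = "diallelkit_incomplete_design")
  expect_error(cell_means(tab2, "t"), "AxB")
})

test_that("RCBD sums of squares match a brute-force deviation oracle", {
  for (seed in 1:3) {
    sim <- simulate_diallel(p = 3, b = 2, seed = seed)
    an <- rcbd_anova(sim$phenotypes, "y")
    ref <- brute_rcbd_ss(sim$phenotypes, "y")
    expect_equal(an$ss[an$source == "Blocks"], ref$block)
    expect_equal(an$ss[an$source == "Genotypes"], ref$geno)
    expect_equal(an$ss[an$source == "Error"], ref$error)
    expect_equal(sum(an$ss), ref$total)
    expect_equal(an$df, c(1, 5, 5))
  }
})

test_that("GCA + SCA partition the genotype sum of squares", {
  for (seed in 1:5) {
    p <- sample(3:8, 1)
    sim <- simulate_diallel(p = p, b = 3, seed = seed)
    an <- rcbd_anova(sim$phenotypes, "y")
    gp <- griffing_partition(cell_means(sim$phenotypes, "y"))
    ss_gen <- an$ss[an$source == "Genotypes"]
    expect_equal(sum(gp$ss), ss_gen, tolerance = 1e-8)
    expect_equal(gp$df, c(p - 1, p * (p - 1) / 2))
    expect_true(all(gp$ss >= 0))
    # recombining the mean squares recovers the genotype mean square
    expect_equal(sum(gp$df * gp$ms) / sum(gp$df), ss_gen / (p * (p + 1) / 2 - 1),
      tolerance = 1e-8)
  }
})

test_that("full ANOVA has the Method 2 degrees of freedom", {
  sim <- simulate_diallel(p = 10, b = 3, seed = 3)
  an <- diallel_anova(sim$phenotypes, "y")
  expect_equal(an$source, c("Blocks", "Genotypes", "GCA", "SCA", "Error"))
  expect_equal(an$df, c(2, 54, 9, 45, 108))
  expect_true(all(an$p_value[1:4] >= 0 & an$p_value[1:4] <= 1))
})

test_that("effects match a constrained least-squares oracle and saturate", {
  for (p in 3:5) {
    sim <- simulate_diallel(p = p, b = 2, seed = 20 + p)
    cm <- cell_means(sim$phenotypes, "y")
    eff <- estimate_effects(cm)
    ref <- ls_griffing_oracle(cm$matrix)
    expect_equal(eff$mu, ref$mu)
    expect_equal(eff$gca$gca, unname(ref$g))
    ids <- cm$parents
    for (k in seq_len(nrow(eff$sca))) {
      expect_equal(eff$sca$sca[k],
        ref$s[eff$sca$parent_a[k], eff$sca$parent_b[k]])
    }
    # saturated model reproduces every cell mean exactly
    g <- stats::setNames(eff$gca$gca, ids)
    for (k in seq_len(nrow(eff$sca))) {
      i <- eff$sca$parent_a[k]; j <- eff$sca$parent_b[k]
      expect_equal(eff$mu + g[[i]] + g[[j]] + eff$sca$sca[k],
        cm$matrix[i, j])
    }
    expect_equal(sum(eff$gca$gca), 0, tolerance = 1e-9)
  }
})

test_that("variance components follow the Method 2 plot-basis formulas", {
  vc <- variance_components(c(5.73, 3.26, 0.17), p = 10)
  expect_equal(vc$sigma2_gca, (5.73 - 0.17) / 12)
  expect_equal(vc$sigma2_sca, 3.26 - 0.17)
  expect_equal(vc$sigma2_error, 0.17)
  expect_equal(vc$ratio_baker,
    2 * vc$sigma2_gca / (2 * vc$sigma2_gca + vc$sigma2_sca))
  # all mean squares equal: both components zero, ratios undefined
  vc0 <- variance_components(c(2, 2, 2), p = 10)
  expect_equal(vc0$sigma2_gca, 0)
  expect_equal(vc0$sigma2_sca, 0)
  expect_true(vc0$ratio_undefined)
  expect_true(is.na(vc0$ratio_component))
  # negative components reported raw with flags, not truncated
  vcn <- variance_components(c(1, 1, 2), p = 10)
  expect_true(vcn$negative_gca && vcn$negative_sca)
  expect_lt(vcn$sigma2_sca, 0)
})

test_that("heritability limit cases behave", {
  vc <- tibble::tibble(sigma2_gca = 3, sigma2_sca = 0, sigma2_error = 0)
  h <- heritabilities(vc)
  expect_equal(h$h2, 1)
  expect_equal(h$H2, 1)
  vc2 <- tibble::tibble(sigma2_gca = 0, sigma2_sca = 2, sigma2_error = 1)
  h2 <- heritabilities(vc2)
  expect_equal(h2$h2, 0)
  expect_equal(h2$H2, 2 / 3)
  # all zero: undefined
  h0 <- heritabilities(tibble::tibble(sigma2_gca = 0, sigma2_sca = 0,
    sigma2_error = 0))
  expect_true(h0$undefined)
  expect_true(is.na(h0$h2))
  # negatives clamped (flagged) only inside heritability
  hn <- heritabilities(tibble::tibble(sigma2_gca = -1, sigma2_sca = 1,
    sigma2_error = 1))
  expect_true(hn$clamped)
  expect_equal(hn$h2, 0)
  # genotypic alternative
  hg <- heritabilities(tibble::tibble(sigma2_gca = 1, sigma2_sca = 1,
    sigma2_error = 2), method = "genotypic", ms_genotypes = 8, b = 3)
  expect_equal(hg$H2, 2 / (2 + 2))
})

test_that("relative SCA percentages scale as documented", {
  sim <- simulate_diallel(p = 4, b = 2, seed = 9)
  tab <- sim$phenotypes
  eff <- estimate_effects(cell_means(tab, "y"))
  pct <- sca_percent(eff, tab, "y")
  gm <- genotype_means(tab, "y")
  hmean <- mean(gm$mean[!gm$is_self])
  expect_equal(pct$sca_pct, 100 * pct$sca / hmean)
  expect_equal(nrow(pct), 6)   # hybrids only
  # direct arithmetic: s = 1 against a hybrid mean of 4 is 25%
  expect_equal(100 * 1 / 4, 25)
  # scaling the trait by 10 leaves percentages unchanged
  tab10 <- tab
  tab10$value <- tab10$value * 10
  tab10 <- as_diallel_pheno(as.data.frame(tab10), attr(tab, "parents"))
  eff10 <- estimate_effects(cell_means(tab10, "y"))
  pct10 <- sca_percent(eff10, tab10, "y")
  expect_equal(pct10$sca_pct, pct$sca_pct)
})

test_that("mid-parent heterosis follows Het = 100 (F1 - MP) / MP", {
  vals <- data.frame(
    parent_a = c("A", "B", "C", "A", "A", "B"),
    parent_b = c("A", "B", "C", "B", "C", "C"),
    #        selfs: A=1, B=3, C=0  hybrids: AB=3, AC=1, BC=1.5
    value = c(1, 3, 0, 3, 1, 1.5)
  )
  het <- heterosis(pheno_from_genotypes(c("A", "B", "C"), vals))
  het <- het[order(het$parent_a, het$parent_b), ]
  # AB: F1 = 3, MP = 2 -> +50; AC: F1 = 1, MP = 0.5 -> +100
  expect_equal(het$het[het$parent_a == "A" & het$parent_b == "B"], 50)
  expect_equal(het$het[het$parent_a == "A" & het$parent_b == "C"], 100)
  # BC: F1 = MP = 1.5 -> 0
  expect_equal(het$het[het$parent_a == "B" & het$parent_b == "C"], 0)
  # MP = 0 is flagged undefined
  vals0 <- vals
  vals0$value <- c(1, -1, 0, 2, 1, 1)   # A and B selfs average to zero
  het0 <- heterosis(pheno_from_genotypes(c("A", "B", "C"), vals0))
  row <- het0[het0$parent_a == "A" & het0$parent_b == "B", ]
  expect_true(row$undefined)
  expect_true(is.na(row$het))
  # sign case: F1 = 1, MP = 2 -> -50
  expect_equal(100 * (1 - 2) / 2, -50)
})

test_that("the analysis is scale-equivariant", {
  sim <- simulate_diallel(p = 5, b = 3, seed = 31)
  tab <- sim$phenotypes
  tabc <- tab
  cfac <- 2.5
  tabc$value <- tabc$value * cfac
  tabc <- as_diallel_pheno(as.data.frame(tabc), attr(tab, "parents"))
  f1 <- griffing_analysis(tab)
  f2 <- griffing_analysis(tabc)
  a1 <- tidy(f1, "anova"); a2 <- tidy(f2, "anova")
  expect_equal(a2$ss, a1$ss * cfac^2)
  expect_equal(tidy(f2, "gca")$gca, tidy(f1, "gca")$gca * cfac)
  g1 <- glance(f1); g2 <- glance(f2)
  expect_equal(g2$ratio_component, g1$ratio_component)
  expect_equal(g2$ratio_baker, g1$ratio_baker)
  expect_equal(g2$h2, g1$h2)
  expect_equal(g2$H2, g1$H2)
  expect_equal(f2$heterosis$het, f1$heterosis$het)
  expect_equal(tidy(f2, "sca_percent")$sca_pct, tidy(f1, "sca_percent")$sca_pct)
})

test_that("tidy and glance expose consistent views of a fit", {
  sim <- simulate_diallel(p = 4, b = 2, traits = c("a", "b"), seed = 5)
  fit <- griffing_analysis(sim$phenotypes)
  gl <- glance(fit)
  expect_equal(gl$trait, c("a", "b"))
  an <- tidy(fit, "anova")
  expect_equal(nrow(an), 10)
  expect_equal(gl$ms_gca, an$ms[an$source == "GCA"])
  expect_equal(nrow(tidy(fit, "gca")), 8)
  expect_equal(nrow(tidy(fit, "sca")), 20)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, "heterosis"), "ggplot")
})
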