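test_that("LTT curves step through hand-enumerated values", {
  res <- simulate_esm(esm_params(0, 0, 0, t_max = 5))
  expect_equal(compute_ltt(collapse_to_species_tree(res)),
               data.frame(time = 0, n_lineages = 1L))
  tr <- collapse_to_species_tree(fixture_three_species())
  expect_equal(compute_ltt(tr),
               data.frame(time = c(0, 1, 2), n_lineages = 1:3))
  # complete trees also step down at extinct tips
  full <- ape::read.tree(text = "((A:2,B:1):1,C:3);")
  lt <- compute_ltt(full)
  expect_equal(lt$n_lineages, c(1L, 2L, 3L, 2L))
  # extant-only curves are monotone and end at the tip count
  set.seed(41)
  for (i in 1:10) {
    r <- condition_on_survival(esm_params(1, 0.5, 0.1, t_max = 6))
    if (r$n_species_extant < 2) next
    tre <- collapse_to_species_tree(r, extant_only = TRUE)
    lt <- compute_ltt(tre, extant_only = TRUE)
    expect_true(all(diff(lt$n_lineages) >= 0))
    expect_identical(lt$n_lineages[nrow(lt)], length(tre$tip.label))
  }
  expect_error(compute_ltt(ape::unroot(ape::rtree(5))), "rooted")
})

test_that("gamma matches the hand-computed value and ape on random trees", {
  # splits at 1 and 2, height 3: g2 = g3 = 1, T = 5,
  # gamma = (2 - 2.5) / (5 sqrt(1/12))
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(gamma_statistic(tr), -0.5 / (5 * sqrt(1 / 12)))
  expect_equal(gamma_statistic(tr), ape::gammaStat(tr))
  set.seed(42)
  for (i in 1:25) {
    rt <- ape::rcoal(sample(3:40, 1))
    expect_equal(gamma_statistic(rt), ape::gammaStat(rt), tolerance = 1e-9)
    expect_equal(gamma_statistic(rescale_tree(rt, runif(1, 0.01, 50))),
                 gamma_statistic(rt), tolerance = 1e-9)
  }
  expect_error(gamma_statistic(ape::read.tree(text = "(A:1,B:1);")),
               "3 tips")
  expect_error(gamma_statistic(ape::rtree(8)), "ultrametric")
})

test_that("gamma is centred at zero under the fixed-n pure-birth null", {
  set.seed(43)
  g <- replicate(500,
    gamma_statistic(ape::rphylo(sample(20:50, 1), birth = 1, death = 0)))
  expect_lt(abs(mean(g)), 3 * sd(g) / sqrt(length(g)))
})

test_that("Colless index matches closed forms and brute-force enumeration", {
  expect_identical(colless_index(ape::read.tree(text = "((A,B),(C,D));")), 0L)
  expect_identical(colless_index(ape::read.tree(text = "(((A,B),C),D);")), 3L)
  for (n in 4:20) {
    cat_tree <- ape::stree(n, type = "left")
    expect_identical(colless_index(cat_tree),
                     as.integer((n - 1) * (n - 2) / 2))
    expect_identical(colless_index(cat_tree), colless_oracle(cat_tree))
  }
  set.seed(44)
  for (n in 4:8) for (i in 1:40) {
    rt <- ape::rtree(n)
    expect_identical(colless_index(rt), colless_oracle(rt))
  }
  expect_error(colless_index(ape::read.tree(text = "(A,B,C);")), "polytom")
})

test_that("incipient histograms report mean, median and skewness", {
  res <- simulate_esm(esm_params(0, 0, 0, t_max = 5))
  h0 <- incipient_distribution(res)
  expect_equal(h0$counts, data.frame(k = 1L, n_species = 1L))
  expect_true(is.na(h0$skewness))
  # memberships {5, 1, 1, 1}: mean 2, median 1, adjusted skewness exactly 2
  conv <- data.frame(time = c(1.0, 1.1, 1.2), kind = "conversion",
                     lineage_id = 2:4, species_id = 1L,
                     new_species_id = 2:4)
  fix <- manual_sim(events = rbind(
    data.frame(time = seq(0.1, 0.7, by = 0.1), kind = "branch",
               lineage_id = 1L, species_id = 1L, new_species_id = NA),
    conv), horizon = 2)
  h <- incipient_distribution(fix, at_time = 2)
  expect_equal(h$mean, 2)
  expect_equal(h$median, 1)
  expect_equal(h$skewness, 2)
  expect_equal(sum(h$counts$n_species), h$n_species)
})

test_that("pooled simulated histograms are dominated by singletons and right-skewed", {
  set.seed(45)
  ks <- integer(0)
  for (i in 1:120) {
    r <- condition_on_survival(esm_params(1, 0.5, 0.05, t_max = 10),
                               max_tries = 10000)
    ks <- c(ks, as.integer(species_membership_counts(r, r$horizon)))
  }
  tab <- table(ks)
  expect_identical(names(tab)[which.max(tab)], "1")
  expect_gt(ephemsim:::sample_skewness(as.numeric(ks)), 0)
})

test_that("effective rates divide conversions by lineage-time exposure", {
  res <- simulate_esm(esm_params(0, 0, 0, t_max = 5))
  er0 <- effective_rates(res)
  expect_equal(er0$speciation_rate, 0)
  # 2 lineage-Myr of exposure and one conversion -> 0.5 per lineage-Myr
  fix <- manual_sim(
    events = data.frame(time = c(0.5, 1.0), kind = c("branch", "conversion"),
                        lineage_id = c(1L, 2L), species_id = c(1L, 1L),
                        new_species_id = c(NA, 2L)),
    species = data.frame(species_id = 1:2, parent_species = c(NA, 1L),
                         founder_lineage = 1:2, origin_time = c(0, 1),
                         extinction_time = NA_real_, n_incipient = 1L,
                         extant = TRUE),
    membership = data.frame(lineage_id = c(1L, 2L, 2L),
                            species_id = c(1L, 1L, 2L),
                            t_from = c(0, 0.5, 1.0),
                            t_to = c(1.5, 1.0, 1.5)),
    horizon = 1.5, params = esm_params(1, 0.5, 0.1, t_max = 1.5))
  er <- effective_rates(fix)
  expect_equal(er$exposure, c(2, 0.5))
  expect_equal(er$speciation_rate, c(0.5, 0))
  # extinction exposure mu / H_k decreases with membership
  expect_equal(er$extinction_exposure, c(0.5, 0.5))
})

test_that("membership size and effective speciation rate correlate positively", {
  set.seed(46)
  rows <- list()
  for (i in 1:110) {
    r <- condition_on_survival(esm_params(), max_tries = 10000)
    er <- effective_rates(r)
    rows[[i]] <- er[er$n_incipient >= 1L, ]
  }
  pooled <- do.call(rbind, rows)
  expect_gt(nrow(pooled), 1000)
  ct <- suppressWarnings(
    stats::cor.test(pooled$n_incipient, pooled$speciation_rate,
                    method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # extinction exposure strictly decreases in membership at equal mu_i
  agg <- tapply(pooled$extinction_exposure, pooled$n_incipient, mean)
  ks <- as.integer(names(agg))
  expect_true(all(diff(agg[order(ks)]) < 0))
})
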