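test_that("a replicate with no conversions collapses to a single-tip tree", {
  res <- simulate_esm(esm_params(0, 0, 0, t_max = 7))
  tr <- collapse_to_species_tree(res)
  expect_identical(length(tr$tip.label), 1L)
  expect_equal(tr$edge.length, 7)
})

test_that("two conversions at t = 1 and 2 give a 3-tip tree with those node times", {
  res <- fixture_three_species()
  tr <- collapse_to_species_tree(res)
  expect_identical(length(tr$tip.label), 3L)
  expect_equal(sort(internal_node_times(tr)), c(1, 2))
  expect_true(ape::is.ultrametric(tr))
  # tip depths all reach the horizon
  off <- tr$root.edge
  d <- ape::node.depth.edgelength(tr)[1:3] + off
  expect_equal(d, rep(3, 3))
})

test_that("node-time conventions differ under lag and coincide without it", {
  lagged <- collapse_to_species_tree(fixture_three_species(lag = TRUE),
                                     "incipient_origin_time")
  expect_equal(sort(internal_node_times(lagged)), c(0.4, 1.5))
  a <- collapse_to_species_tree(fixture_three_species(lag = FALSE),
                                "conversion_time")
  b <- collapse_to_species_tree(fixture_three_species(lag = FALSE),
                                "incipient_origin_time")
  expect_equal(internal_node_times(a), internal_node_times(b))
  expect_true(isTRUE(ape::all.equal.phylo(a, b)))
})

test_that("extant-only species trees are ultrametric with one tip per extant species", {
  set.seed(21)
  done <- 0L
  while (done < 25L) {
    res <- simulate_esm(esm_params(1, 0.6, 0.1, t_max = 7))
    if (!any(res$species$extant)) {
      expect_error(collapse_to_species_tree(res, extant_only = TRUE),
                   "extant")
      next
    }
    tr <- collapse_to_species_tree(res, extant_only = TRUE)
    expect_identical(length(tr$tip.label), res$n_species_extant)
    off <- if (is.null(tr$root.edge)) 0 else tr$root.edge
    d <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)] + off
    expect_equal(d, rep(res$horizon, length(d)), tolerance = 1e-9)
    # under the default convention every node time is a conversion time
    if (tr$Nnode >= 1L && length(tr$tip.label) >= 2L) {
      conv <- res$events$time[res$events$kind == "conversion" &
                              res$events$new_species_id !=
                                res$events$species_id]
      nt <- internal_node_times(tr)
      expect_true(all(vapply(nt, function(x)
        any(abs(conv - x) < 1e-9), logical(1))))
    }
    done <- done + 1L
  }
})

test_that("membership counts replay the log correctly", {
  res <- simulate_esm(esm_params(0, 0, 0, t_max = 4))
  expect_identical(species_membership_counts(res, 0), c("1" = 1L))
  # fixture: one branch at 0.5, one conversion at 1.0 -> {1, 1} at 1.5
  fix <- manual_sim(events = data.frame(
    time = c(0.5, 1.0), kind = c("branch", "conversion"),
    lineage_id = c(1L, 2L), species_id = c(1L, 1L),
    new_species_id = c(NA, 2L)), horizon = 3)
  counts <- species_membership_counts(fix, 1.5)
  expect_identical(unname(counts), c(1L, 1L))
  expect_error(species_membership_counts(fix, 3.5), "at_time")
})

test_that("membership counts sum to the running lineage count at random times", {
  set.seed(22)
  for (i in 1:100) {
    res <- simulate_esm(esm_params(runif(1, 0.3, 1.2), runif(1, 0, 0.8),
                                   runif(1, 0, 0.2), t_max = 5))
    t0 <- runif(1, 0, 5)
    counts <- species_membership_counts(res, t0)
    ev <- res$events
    run <- ephemsim:::running_lineage_count(ev)
    upto <- sum(ev$time <= t0)
    expect_identical(sum(counts),
                     if (upto == 0L) 1L else run[upto])
  }
})
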