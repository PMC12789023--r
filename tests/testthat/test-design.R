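test_that("LUI rolling mean averages the 3-year window, truncated", {
  lui <- data.frame(plot_id = "p1", year = 2008:2010, lui = c(1, 2, 3))
  expect_equal(lui_rolling_mean(lui, "p1", 2010), 2)
  expect_equal(lui_rolling_mean(lui, "p1", 2008), 1)
  expect_equal(lui_rolling_mean(lui, "p1", 2009), 1.5)
  const <- data.frame(plot_id = "p1", year = 2008:2012, lui = 1.7)
  expect_equal(lui_rolling_mean(const, "p1", 2012), 1.7)
  expect_error(lui_rolling_mean(lui, "p1", 2020), "no LUI")
  expect_error(lui_rolling_mean(lui, "p9", 2010), "no LUI")
})

test_that("schemes enumerate the expected pair sets", {
  keys <- key_frame("p1", c(2010, 2011, 2013))
  fixed <- enumerate_pairs(keys, "fixed_baseline", min_replicates = 1)
  tf <- fixed[fixed$scheme != "control", ]
  expect_true(all(tf$year_b == 2010))
  expect_identical(nrow(tf), 4L) # 2 comparisons x 2 replicate chains
  moving <- enumerate_pairs(keys, "moving_average", min_replicates = 1)
  tm <- moving[moving$scheme != "control", ]
  expect_identical(nrow(tm), 6L) # 3 year pairs x 2 chains
  expect_true(all(tm$replicate_b == tm$replicate_c))
  ## restricted with infinite window is the moving average
  rest <- enumerate_pairs(keys, "restricted_moving_average",
                          baseline_window = Inf, min_replicates = 1)
  expect_identical(rest[rest$scheme != "control", c("year_b", "year_c")],
                   tm[, c("year_b", "year_c")])
  ## controls: one per plot/year (replicate pair), span 0
  ctl <- moving[moving$scheme == "control", ]
  expect_identical(nrow(ctl), 3L)
  expect_true(all(ctl$span == 0))
  ## single-year input yields controls only
  solo <- enumerate_pairs(key_frame("p1", 2015), "moving_average")
  expect_identical(solo$scheme, "control")
})

test_that("span support filtering reproduces the two study designs", {
  jena_years <- c(2010, 2012, 2014, 2016, 2017, 2019, 2020)
  jena <- enumerate_pairs(key_frame(c("j1", "j2"), jena_years),
                          "restricted_moving_average")
  expect_identical(max(jena$span), 7L)
  ## spans 8, 9, 10 each occur in one year combination only; span 1 too
  expect_false(any(c(1, 8, 9, 10) %in% jena$span))
  expl <- enumerate_pairs(key_frame(c("e1", "e2"), 2008:2018),
                          "moving_average")
  expect_identical(max(expl$span), 9L)
  expect_false(10 %in% expl$span)
  ## every retained span has >= 2 year combinations, dropped spans < 2
  combo <- unique(jena[jena$scheme != "control",
                       c("year_b", "year_c", "span")])
  expect_true(all(table(combo$span) >= 2))
})

test_that("covariates attach by mode and are z-scored with stored scaling", {
  keys <- key_frame(c("p1", "p2"), c(2010, 2012))
  pairs <- enumerate_pairs(keys, "moving_average", min_replicates = 1)
  psr <- data.frame(plot_id = c("p1", "p2"), psr = c(1L, 60L))
  out <- attach_covariates(pairs, psr)
  expect_identical(out$covariate[out$plot_id == "p2"][1], 60L)
  expect_equal(mean(out$cov_z), 0, tolerance = 1e-12)
  expect_equal((out$covariate[1] - attr(out, "cov_mean")) /
                 attr(out, "cov_sd"), out$cov_z[1])
  ## real-world mode: endpoint rolling means are averaged per comparison
  lui <- rbind(data.frame(plot_id = "p1", year = 2008:2012,
                          lui = c(1, 1, 1.2, 1.5, 1.8)),
               data.frame(plot_id = "p2", year = 2008:2012, lui = 3))
  out2 <- attach_covariates(pairs, lui)
  r10 <- mean(c(1, 1, 1.2))
  r12 <- mean(c(1.2, 1.5, 1.8))
  i <- which(out2$plot_id == "p1" & out2$span == 2)[1]
  expect_equal(out2$covariate[i], (r10 + r12) / 2)
  ## constant covariate cannot be scaled
  const <- data.frame(plot_id = c("p1", "p2"), psr = 8L)
  expect_error(attach_covariates(pairs, const), "zero variance")
})

test_that("subsets never reuse a sampling event and have invariant size", {
  set.seed(31)
  keys <- rbind(key_frame(paste0("p", 1:4),
                          c(2010, 2012, 2014, 2016, 2017)),
                key_frame("p5", c(2010, 2014)))
  pairs <- enumerate_pairs(keys, "moving_average", min_replicates = 1)
  sizes <- design_matching_sizes(pairs)
  n1 <- nrow(sample_disjoint_subset(pairs, sizes))
  for (i in 1:25) {
    sub <- sample_disjoint_subset(pairs, sizes)
    expect_false(any(duplicated(subset_events(sub))))
    expect_identical(nrow(sub), n1)
  }
  expect_identical(n1, as.integer(sum(sizes)))
})

test_that("subset size equals the exhaustive maximum matching", {
  set.seed(13)
  for (i in 1:12) {
    n_years <- sample(2:4, 1)
    years <- sort(sample(2010:2016, n_years))
    keys <- key_frame("p1", years,
                      replicates = if (runif(1) < 0.5) c("A", "B") else "A")
    scheme <- sample(c("moving_average", "fixed_baseline"), 1)
    pairs <- enumerate_pairs(keys, scheme, min_replicates = 1,
                             include_controls = runif(1) < 0.7)
    if (nrow(pairs) == 0) next
    expect_identical(unname(design_matching_sizes(pairs)[["p1"]]),
                     brute_matching_size(pairs))
    sub <- sample_disjoint_subset(pairs)
    expect_identical(nrow(sub), brute_matching_size(pairs))
  }
  ## temporal pairs only, one replicate: floor(n_years / 2) pairs
  k3 <- key_frame("p1", c(2010, 2011, 2012), replicates = "A")
  p3 <- enumerate_pairs(k3, "moving_average", min_replicates = 1,
                        include_controls = FALSE)
  expect_identical(nrow(sample_disjoint_subset(p3)), 1L)
  k4 <- key_frame("p1", 2010:2013, replicates = "A")
  p4 <- enumerate_pairs(k4, "moving_average", min_replicates = 1,
                        include_controls = FALSE)
  expect_identical(nrow(sample_disjoint_subset(p4)), 2L)
})

test_that("controls consume both replicate events and flip responses", {
  keys <- key_frame("p1", 2010)
  pairs <- enumerate_pairs(keys, "moving_average")
  expect_identical(nrow(pairs), 1L)
  obs <- rbind(obs_row(count = 4), obs_row(species = "sp2", count = 2),
               obs_row(replicate = "B", count = 1))
  fv <- build_function_vectors(obs, data.frame(taxon_group = "Coleoptera",
                                               a = 1, b = 0))
  part <- partition_batch(pairs, fv)
  set.seed(2)
  seen <- replicate(40, {
    sub <- sample_disjoint_subset(part)
    expect_identical(nrow(sub), 1L)
    ## flipped controls must equal the recomputed reverse partition
    if (sub$flipped) {
      fwd <- price_partition(c(sp1 = 4, sp2 = 2), c(sp1 = 1))
      rev <- price_partition(c(sp1 = 1), c(sp1 = 4, sp2 = 2))
      expect_equal(sub$sre_loss, rev$sre_loss)
      expect_equal(sub$sie_gain, rev$sie_gain)
      expect_equal(sub$delta_T, -fwd$delta_T)
    }
    sub$flipped
  })
  expect_true(any(seen) && !all(seen))
})
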