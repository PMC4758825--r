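test_that("bootstrap replicates preserve unit count and are seed-reproducible", {
  s <- random_group_stream(n_ids = 10, n_groups = 40)
  set.seed(5); r1 <- bootstrap_replicate(s)
  set.seed(5); r2 <- bootstrap_replicate(s)
  expect_length(r1$units, length(s$units))
  expect_identical(r1$units, r2$units)
  expect_identical(r1$roster, r2$roster)
  expect_true(all(r1$roster %in% s$roster))
  # every roster member of the replicate actually appears in a drawn unit
  expect_true(all(colSums(commrobust:::presence_matrix(r1)) > 0))
})

test_that("bootstrap draws cover ~63.2% of distinct units at large n", {
  set.seed(13)
  # 1000 units made pairwise distinct so drawn duplicates are identifiable
  units <- lapply(1:1000, function(i) c("hub", paste0("u", i)))
  s <- obs_stream(units)
  fracs <- replicate(100, {
    r <- bootstrap_replicate(s)
    length(unique(r$units)) / length(s$units)
  })
  # classical 1 - 1/e coverage of the nonparametric bootstrap
  expect_equal(mean(fracs), 1 - exp(-1), tolerance = 0.03)
})

test_that("co-membership proportions implement sum(M)/sum(C) over replicates", {
  set.seed(17)
  s <- two_clique_stream(reps = 10)
  summ <- comembership_proportions(s, n_boot = 30)
  expect_s3_class(summ, "comembership_summary")
  expect_true(all(summ$M_sum <= summ$C_sum))
  expect_true(all(summ$C_sum <= summ$n_boot))
  expect_equal(summ$P, t(summ$P))
  within1 <- summ$P[paste0("a", 1:3), paste0("a", 1:3)]
  within2 <- summ$P[paste0("b", 1:3), paste0("b", 1:3)]
  diag(within1) <- diag(within2) <- 1
  # disjoint always-together cliques are re-detected exactly in every replicate
  expect_true(all(within1 == 1) && all(within2 == 1))
  expect_true(all(summ$P[paste0("a", 1:3), paste0("b", 1:3)] == 0))
  expect_length(summ$replicate_Q, 30L)
  expect_length(summ$replicate_c, 30L)
})

test_that("M_sum <= C_sum <= n_boot holds on random streams", {
  set.seed(19)
  for (i in 1:10) {
    s <- random_group_stream(n_ids = 8, n_groups = 12, mean_size = 2)
    summ <- comembership_proportions(s, n_boot = 10)
    expect_true(all(summ$M_sum >= 0))
    expect_true(all(summ$M_sum <= summ$C_sum))
    expect_true(all(summ$C_sum <= 10))
    ok <- summ$C_sum > 0
    expect_equal(summ$P[ok], (summ$M_sum / summ$C_sum)[ok])
    expect_true(all(summ$P[summ$never_copresent] == 0))
  }
})

test_that("assortativity matches hand-evaluated mixing-matrix cases", {
  ids <- c("A", "B", "C", "D")
  labels <- c(A = 1, B = 1, C = 2, D = 2)
  blockP <- matrix(0, 4, 4, dimnames = list(ids, ids))
  blockP["A", "B"] <- blockP["B", "A"] <- blockP["C", "D"] <- blockP["D", "C"] <- 1
  expect_equal(assortativity_rcom(blockP, labels), 1)

  mixedP <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  mixedP["A", "B"] <- mixedP["B", "A"] <- mixedP["C", "D"] <- mixedP["D", "C"] <- 0.8
  diag(mixedP) <- 0
  expect_equal(assortativity_rcom(mixedP, labels), 1 / 3)

  disP <- matrix(1, 4, 4, dimnames = list(ids, ids))
  disP["A", "B"] <- disP["B", "A"] <- disP["C", "D"] <- disP["D", "C"] <- 0
  diag(disP) <- 0
  expect_equal(assortativity_rcom(disP, labels), -1)
})

test_that("assortativity flags degenerate inputs instead of guessing", {
  P0 <- matrix(0, 3, 3)
  expect_warning(r <- assortativity_rcom(P0, c(1, 1, 2)), "zero")
  expect_true(is.nan(r))
  # all weight inside one community: denominator collapses
  P1 <- matrix(0, 3, 3); P1[1, 2] <- P1[2, 1] <- 0.7
  expect_warning(r1 <- assortativity_rcom(P1, c(1, 1, 2)), "single community")
  expect_true(is.nan(r1))
})

test_that("assortativity is invariant to label permutation and scaling of P", {
  set.seed(23)
  for (i in 1:20) {
    case <- random_P_case()
    r <- assortativity_rcom(case$P, case$labels)
    expect_equal(r, oracle_rcom(case$P, case$labels), tolerance = 1e-12)
    relab <- sample(max(case$labels) + 2)[case$labels]
    expect_equal(assortativity_rcom(case$P, relab), r, tolerance = 1e-12)
    expect_equal(assortativity_rcom(case$P * 0.37, case$labels), r, tolerance = 1e-12)
  }
})

test_that("the full pipeline gives r_com = 1 on perfectly separable data", {
  s <- two_clique_stream(reps = 25)
  res <- run_rcom(s, n_boot = 100, seed = 101)
  expect_s3_class(res, "rcom_result")
  expect_equal(res$r_com, 1)
  expect_true(all(res$summary$replicate_c == 2))
  expect_equal(res$empirical_partition$c, 2L)
  expect_equal(unname(res$Q_ci), c(0.5, 0.5))
  # seed makes the whole pipeline reproducible
  res2 <- run_rcom(s, n_boot = 100, seed = 101)
  expect_equal(res2$r_com, res$r_com)
  expect_identical(res2$summary$M_sum, res$summary$M_sum)
})

test_that("duplicating the stream leaves expected r_com unchanged", {
  set.seed(29)
  pop <- make_population(16, 2, 0.75, 0.8)
  s <- simulate_stream(pop, 40)
  base <- mean(replicate(8, run_rcom(s, n_boot = 40)$r_com))
  dup <- obs_stream(c(s$units, s$units), roster = s$roster, mode = "period")
  dup_r <- mean(replicate(8, run_rcom(dup, n_boot = 40)$r_com))
  expect_equal(dup_r, base, tolerance = 0.1)
})

test_that("JSON export writes the headline numbers faithfully", {
  s <- two_clique_stream(reps = 10)
  res <- run_rcom(s, n_boot = 20, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  fp <- withr::local_tempfile(fileext = ".csv")
  write_rcom_json(res, f, p_matrix_path = fp)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$r_com, res$r_com)
  expect_equal(obj$Q, res$Q_emp)
  expect_equal(obj$n_boot, 20)
  expect_length(obj$communities, 6)
  P <- as.matrix(read.csv(fp, row.names = 1))
  expect_equal(unname(P), unname(res$summary$P))
})
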