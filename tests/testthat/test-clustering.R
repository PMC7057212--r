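test_that("sort_solutions orders by CC, then LLG, scored sets first", {
  mk <- function(id, meta) {
    p <- fx_truth("P212121"); p$id <- id; p$meta <- meta; p
  }
  byCC <- sort_solutions(list(mk("a", list(CC = 35)), mk("b", list(CC = 20)),
                              mk("c", list(CC = 28))))
  expect_equal(vapply(byCC, `[[`, "", "id"), c("a", "c", "b"))
  none <- sort_solutions(list(mk("x", list()), mk("y", list())))
  expect_equal(vapply(none, `[[`, "", "id"), c("x", "y"))
  mixed <- sort_solutions(list(mk("p", list()), mk("q", list(LLG = 50)),
                               mk("r", list(CC = 10))))
  expect_equal(vapply(mixed, `[[`, "", "id")[3], "p")
})

land_cache <- new.env(parent = emptyenv())
fx_landscape <- function(seed, n_correct = 10L, n_wrong = 20L,
                         phase_noise = 40) {
  key <- paste("land", seed, n_correct, n_wrong, phase_noise)
  if (is.null(land_cache[[key]]))
    land_cache[[key]] <- make_landscape(
      fx_model("P212121", n_atoms = 30L, seed = 101L),
      n_correct = n_correct, n_wrong = n_wrong,
      phase_noise = phase_noise, d_min = 2.5, seed = seed)
  land_cache[[key]]
}

test_that("one-step clustering recovers the correct family from a landscape", {
  land <- fx_landscape(seed = 5L)
  rep <- run_one_step(land$solutions, "P212121", merge_config())
  pr <- cluster_pr(rep, land)
  expect_gte(pr["precision"], 0.9)
  expect_gte(pr["recall"], 0.7)
  ids <- vapply(land$solutions, `[[`, "", "id")
  expect_true(report_partition_ok(rep, ids))
})

test_that("tolerance near zero clusters only exact duplicates", {
  truth <- fx_truth("P212121")
  dup1 <- truth; dup1$id <- "dup1"
  dup2 <- truth; dup2$id <- "dup2"
  near <- perturb_phases(truth, 5, seed = 8); near$id <- "near"
  rep <- run_one_step(list(dup1, dup2, near), "P212121",
                      merge_config(tolerance = 0.1))
  expect_length(rep$clusters, 1L)
  expect_setequal(rep$clusters[[1]]$members$member_id, c("dup1", "dup2"))
  expect_identical(rep$leftovers, "near")
})

test_that("parallel chunked rounds reproduce sequential membership", {
  for (seed in c(3L, 9L)) {
    land <- fx_landscape(seed = seed, n_correct = 8L, n_wrong = 10L)
    reps <- lapply(c(1L, 2L, 4L), function(nc)
      run_one_step(land$solutions, "P212121",
                   merge_config(n_cores = nc, minchunk = 4L)))
    m1 <- cluster_membership(reps[[1]])
    expect_identical(cluster_membership(reps[[2]]), m1)
    expect_identical(cluster_membership(reps[[3]]), m1)
    ids <- vapply(land$solutions, `[[`, "", "id")
    for (r in reps) expect_true(report_partition_ok(r, ids))
    # fully sequential reference run (minchunk forces the sequential path)
    seq_rep <- run_one_step(land$solutions, "P212121",
                            merge_config(n_cores = 1L, minchunk = 1000L))
    expect_identical(cluster_membership(seq_rep), m1)
  }
})

test_that("coarse 4 A comparison preserves the best-cluster membership", {
  land <- fx_landscape(seed = 12L)
  rep4 <- run_one_step(land$solutions, "P212121",
                       merge_config(resolution = 4.0))
  repf <- run_one_step(land$solutions, "P212121",
                       merge_config(resolution = 2.5))
  best <- function(r) {
    sizes <- vapply(r$clusters, function(cl) nrow(cl$members), integer(1))
    sort(r$clusters[[which.max(sizes)]]$members$member_id)
  }
  expect_identical(best(rep4), best(repf))
})

test_that("two-step protocol joins complementary families at 87 degrees", {
  groups <- list(fx_hetero_family(1L, n_members = 5L),
                 fx_hetero_family(2L, n_members = 5L))
  truth <- fx_truth("C2221", n_atoms = 30L, seed = 11L)
  cfg <- merge_config(tolerance = 60, tolerance_round2 = 87)
  rep <- run_two_step(groups, "C2221", cfg)
  # the two round-1 clusters join into one blended round-2 cluster
  sizes <- vapply(rep$clusters, function(cl) nrow(cl$members), integer(1))
  joined <- rep$clusters[[which.max(sizes)]]
  expect_gte(nrow(joined$members), 2L)
  expect_setequal(joined$members$member_id, c("g1_c1", "g2_c1"))

  # the joined set is a better approximation of truth than either round-1
  # cluster alone
  r1 <- do.call(c, lapply(rep$round1, `[[`, "clusters"))
  wmpe_r1 <- vapply(r1, function(cl)
    best_origin_shift(truth, cl, "C2221")$wmpd, numeric(1))
  wmpe_joined <- best_origin_shift(truth, joined, "C2221")$wmpd
  expect_lt(wmpe_joined, min(wmpe_r1) + 2)
})

test_that("two-step leaves unrelated groups untouched and degrades to
           one-step for a single group", {
  truth <- fx_truth("P212121")
  other <- fx(paste("other-family-P212121"), function() {
    m <- make_toy_structure("P212121", n_atoms = 20L, seed = 777L)
    phases_from_model(m, 2.5, hkl = truth$hkl)
  })
  set.seed(90)
  g1 <- lapply(1:3, function(i) {
    p <- perturb_phases(truth, 20); p$id <- paste0("a", i); p })
  g2 <- lapply(1:3, function(i) {
    p <- perturb_phases(other, 20); p$id <- paste0("b", i); p })
  rep <- run_two_step(list(g1, g2), "P212121", merge_config())
  expect_length(rep$clusters, 2L)
  mixed <- vapply(rep$clusters, function(cl)
    length(unique(substr(cl$members$member_id, 1, 1))) > 1, logical(1))
  expect_false(any(mixed))

  one <- run_two_step(list(g1), "P212121", merge_config())
  direct <- run_one_step(g1, "P212121", merge_config())
  expect_identical(
    sort(one$clusters[[1]]$members$member_id),
    sort(direct$clusters[[1]]$members$member_id))
})

test_that("heterogeneous fragment families blend at 83 but not at 60 degrees", {
  pool <- c(fx_hetero_family(1L, n_members = 4L, seed = 2L),
            fx_hetero_family(2L, n_members = 4L, seed = 2L))
  rep60 <- run_one_step(pool, "C2221", merge_config(tolerance = 60))
  rep83 <- run_one_step(pool, "C2221", merge_config(tolerance = 83))
  blended <- function(r) any(vapply(r$clusters, function(cl) {
    fams <- unique(substr(cl$members$member_id, 1, 4))
    all(c("fam1", "fam2") %in% fams)
  }, logical(1)))
  expect_false(blended(rep60))
  expect_true(blended(rep83))
})

test_that("wmpe_table flags nonrandom solutions below 80 degrees", {
  truth <- fx_truth("P212121")
  rnd <- fx_random_psP212121 <- local({
    set.seed(44)
    p <- truth; p$phi <- stats::runif(length(p$phi), 0, 360); p$id <- "rnd"; p
  })
  noisy <- perturb_phases(truth, 40, seed = 45); noisy$id <- "noisy"
  tab <- wmpe_table(list(truth, noisy, rnd), truth, "P212121")
  expect_equal(tab$wmpe[1], 0)
  expect_true(tab$nonrandom[1])
  expect_true(tab$nonrandom[2])
  expect_gt(tab$wmpe[3], 80)
  expect_false(tab$nonrandom[3])
  expect_true(tab$wmpe[1] < tab$wmpe[2] && tab$wmpe[2] < tab$wmpe[3])
})

test_that("report accessors summarise clusters", {
  land <- fx_landscape(seed = 5L)
  rep <- run_one_step(land$solutions, "P212121", merge_config())
  df <- as.data.frame(rep)
  expect_true(all(c("cluster", "id", "size", "mean_wmpd") %in% names(df)))
  expect_equal(sum(df$size) + length(rep$leftovers), 30L)
  expect_output(print(rep), "cluster")
  expect_output(summary(rep), "Leftovers")
})
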