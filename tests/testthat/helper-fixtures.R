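# Shared fixtures, built in code and cached per test session.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- builder()
  .fx_cache[[key]]
}

# toy model + truth phase set for a group, cached
fx_model <- function(sg, n_atoms = 20L, seed = 101L) {
  fx(paste("model", sg, n_atoms, seed),
     function() make_toy_structure(sg, n_atoms = n_atoms, seed = seed))
}

fx_truth <- function(sg, n_atoms = 20L, seed = 101L, d_min = 2.5) {
  fx(paste("truth", sg, n_atoms, seed, d_min),
     function() phases_from_model(fx_model(sg, n_atoms, seed), d_min))
}

# phase set with random phases over an arbitrary synthetic hkl list
fx_random_ps <- function(n, seed, cell = c(20, 20, 20, 90, 90, 90),
                         shared_f = NULL, id = paste0("rnd", seed)) {
  set.seed(seed)
  hkl <- unique(matrix(sample(-12:12, 3 * ceiling(n * 1.6), replace = TRUE),
                       ncol = 3))
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE][seq_len(n), , drop = FALSE]
  f <- if (is.null(shared_f)) sqrt(stats::rexp(n)) else shared_f
  phase_set(hkl, f, rep(1, n), stats::runif(n, 0, 360), cell, "P1", id = id)
}

# add wrapped Gaussian phase noise to a phase set
perturb_phases <- function(ps, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ps$phi <- (ps$phi + stats::rnorm(length(ps$phi), sd = sigma)) %% 360
  ps
}

# lattice translations of the group (identity-rotation ops), incl. centring
centring_vectors <- function(sg) {
  vs <- lapply(sg$ops, function(op) if (all(op$R == diag(3))) op$t else NULL)
  do.call(rbind, Filter(Negate(is.null), vs))
}

# distance between two shifts modulo 1 and modulo the centring translations,
# restricted to free components (mask)
shift_dist <- function(s1, s2, sg, mask = rep(TRUE, 3)) {
  cen <- rbind(centring_vectors(sg))
  best <- Inf
  for (i in seq_len(nrow(cen))) {
    d <- (s1 - s2 - cen[i, ]) %% 1
    d <- pmin(d, 1 - d)
    best <- min(best, max(d[mask]))
  }
  best
}

# membership of each multi-member cluster as a sorted id list
cluster_membership <- function(report) {
  lapply(report$clusters, function(cl) sort(cl$members$member_id))
}

# precision / recall of the largest cluster against the correct labels
cluster_pr <- function(report, landscape) {
  ids <- vapply(landscape$solutions, `[[`, "", "id")
  correct <- ids[landscape$labels == "correct"]
  if (!length(report$clusters)) return(c(precision = 0, recall = 0))
  sizes <- vapply(report$clusters, function(cl) nrow(cl$members), integer(1))
  mem <- report$clusters[[which.max(sizes)]]$members$member_id
  c(precision = mean(mem %in% correct), recall = mean(correct %in% mem))
}

# ids in a report: every input id must land in exactly one cluster or leftovers
report_partition_ok <- function(report, input_ids) {
  placed <- c(unlist(lapply(report$clusters, function(cl) cl$members$member_id)),
              report$leftovers)
  identical(sort(placed), sort(input_ids)) && !anyDuplicated(placed)
}

# heterogeneous two-family fixture: disjoint atom halves of one structure,
# truth-phasor blend emulating density-modification pull, phase-noised copies
fx_hetero_family <- function(which_half, n_members, phase_noise = 20,
                             dm_pull = 0.3, seed = 1L) {
  model <- fx_model("C2221", n_atoms = 30L, seed = 11L)
  truth <- fx_truth("C2221", n_atoms = 30L, seed = 11L)
  sub <- if (which_half == 1L) 1:15 else 16:30
  base <- fx(paste("hetero_base", which_half), function() {
    part <- toy_model(model$xyz[sub, , drop = FALSE], model$cell, "C2221")
    ps <- phases_from_model(part, 2.5, hkl = truth$hkl)
    u <- (1 - dm_pull) * exp(1i * ps$phi * pi / 180) +
      dm_pull * exp(1i * truth$phi * pi / 180)
    ps$phi <- (Arg(u) * 180 / pi) %% 360
    ps$fom <- rep(0.8, nrow(truth$hkl))
    ps
  })
  set.seed(seed + which_half * 1000L)
  lapply(seq_len(n_members), function(i) {
    ps <- perturb_phases(base, phase_noise)
    ps$id <- sprintf("fam%d_%02d", which_half, i)
    ps
  })
}
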