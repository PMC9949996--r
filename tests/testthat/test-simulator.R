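neutral_sim <- function(L, global_rate, seed, kappa = 0.3, pi = NULL) {
  g <- make_genome(L, seed = seed)
  ovrf_simulation(g, list(),
                  substitution_params(kappa = kappa, pi = pi,
                                      global_rate = global_rate))
}

test_that("zero and negative branch lengths are handled", {
  set.seed(1)
  sim <- neutral_sim(100, 1, seed = 1)
  before <- current_sequence(sim)
  simulate_branch(sim, 0)
  expect_equal(current_sequence(sim), before)
  expect_equal(nrow(sim$log), 0L)
  expect_error(simulate_branch(sim, -0.5), "nonnegative")
})

test_that("neutral branches accumulate global_rate * length events per site", {
  L <- 20000L
  for (m in c(0.01, 0.1, 1)) {
    set.seed(round(1000 * m))
    sim <- neutral_sim(L, m, seed = round(1000 * m) + 1L)
    simulate_branch(sim, 1)
    expected <- m * L
    expect_lt(abs(nrow(sim$log) - expected), 4 * sqrt(expected) + 1)
  }
})

test_that("waiting times between events are exponential with rate Lambda", {
  # kappa = 1 and uniform pi keep Lambda exactly constant along the branch
  L <- 2000L
  set.seed(21)
  sim <- neutral_sim(L, 1, seed = 22, kappa = 1, pi = rep(0.25, 4))
  lambda <- total_rate(sim$tree)
  expect_equal(lambda, L, tolerance = 1e-9)  # normalization: 1 per site
  simulate_branch(sim, 5)
  waits <- diff(c(0, sim$log$time))
  expect_gt(length(waits), 5000L)
  ks <- ks.test(waits, "pexp", rate = lambda)
  expect_gt(ks$p.value, 1e-3)
})

test_that("applying substitutions updates sequence, log and rates coherently", {
  set.seed(31)
  sim <- neutral_sim(60, 1, seed = 32)
  lambda0 <- total_rate(sim$tree)
  i <- 10L
  from <- current_sequence(sim, collapse = FALSE)[i]
  to <- setdiff(c("A", "C", "G", "T"), from)[1]
  apply_substitution(sim, i, to)
  expect_equal(current_sequence(sim, collapse = FALSE)[i], to)
  apply_substitution(sim, i, from)
  expect_equal(current_sequence(sim, collapse = FALSE)[i], from)
  expect_equal(nrow(sim$log), 2L)
  # back at the root sequence, Lambda equals the fresh-build value
  expect_equal(total_rate(sim$tree), lambda0, tolerance = 1e-9)
})

test_that("branch simulation leaves state copies independent", {
  set.seed(41)
  sim <- neutral_sim(120, 1, seed = 42)
  root_seq <- current_sequence(sim)
  child <- copy_simulation(sim)
  simulate_branch(child, 2)
  expect_equal(current_sequence(sim), root_seq)
  expect_false(identical(current_sequence(child), root_seq))
  expect_equal(nrow(sim$log), 0L)
})

test_that("phylogeny traversal propagates sequences to every tip", {
  phy0 <- ape::read.tree(text = "(A:0,B:0);")
  set.seed(51)
  sim <- neutral_sim(100, 1, seed = 52)
  root_seq <- current_sequence(sim)
  aln <- traverse_phylogeny(sim, phy0)
  expect_named(aln, c("A", "B"))
  expect_equal(as.vector(unclass(aln)), rep(root_seq, 2))

  # star-like: each child branch starts from the same root state
  phy1 <- ape::read.tree(text = "((C:0,D:0):0,E:0);")
  set.seed(53)
  sim1 <- neutral_sim(100, 1, seed = 54)
  aln1 <- traverse_phylogeny(sim1, phy1)
  expect_setequal(names(aln1), c("C", "D", "E"))
  expect_equal(nchar(unclass(aln1)), c(C = 100L, D = 100L, E = 100L))
})

test_that("traversal errors name tree defects", {
  set.seed(61)
  sim <- neutral_sim(50, 1, seed = 62)
  no_lengths <- ape::read.tree(text = "(A,B);")
  expect_error(traverse_phylogeny(sim, no_lengths), "branch lengths")
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(traverse_phylogeny(sim, poly), "polytomy|bifurcating")
})

test_that("runs are reproducible and invariant to sibling order", {
  orfs <- make_overlap_layout("fig2", 300)
  g <- imprint_orf_signals(make_genome(300, seed = 71), orfs)
  phy <- make_tree(8, total_depth = 0.5, seed = 72)
  p <- substitution_params(global_rate = 0.5)
  res1 <- ovrf_simulate(g, orfs, phy, params = p, seed = 7)
  res2 <- ovrf_simulate(g, orfs, phy, params = p, seed = 7)
  expect_identical(res1$alignment, res2$alignment)
  expect_identical(res1$substitutions, res2$substitutions)

  # rotating children at the root must not change any lineage
  phy_rot <- ape::rotate(phy, length(phy$tip.label) + 1L)
  res3 <- ovrf_simulate(g, orfs, phy_rot, params = p, seed = 7)
  nm <- sort(names(res1$alignment))
  expect_identical(unclass(res1$alignment)[nm], unclass(res3$alignment)[nm])

  # different seed gives a different alignment
  res4 <- ovrf_simulate(g, orfs, phy, params = p, seed = 8)
  expect_false(identical(res1$alignment, res4$alignment))
})

test_that("protected sites never change along any lineage", {
  orfs <- make_overlap_layout("hbv-like", 600)
  g <- imprint_orf_signals(make_genome(600, seed = 81, circular = TRUE), orfs)
  phy <- make_tree(6, total_depth = 1, seed = 82)
  res <- ovrf_simulate(g, orfs, phy,
                       params = substitution_params(global_rate = 1),
                       seed = 83)
  ctx <- site_contexts(g, orfs)
  prot <- which(ctx$protected)
  expect_false(any(res$substitutions$position %in% prot))
  root <- g$seq
  for (tip in res$alignment) {
    tip_seq <- strsplit(tip, "")[[1]]
    expect_equal(tip_seq[prot], root[prot])
    expect_length(tip_seq, g$length)
  }
})

test_that("purifying selection slows coding relative to non-coding evolution", {
  orfs <- make_overlap_layout("fig2", 300,
                              omega = dist_spec("constant", value = 0.05))
  g <- imprint_orf_signals(make_genome(300, seed = 91), orfs)
  ctx <- site_contexts(g, orfs)
  coding <- unique(ctx$membership$site)
  noncod <- setdiff(seq_len(g$length), coding)
  phy <- ape::read.tree(text = "(A:0.4,B:0.4);")
  diffs <- function(tip) strsplit(tip, "")[[1]] != g$seq
  rate_c <- rate_n <- numeric(0)
  for (s in 1:6) {
    res <- ovrf_simulate(g, orfs, phy,
                         params = substitution_params(global_rate = 1),
                         seed = 900 + s)
    d <- diffs(res$alignment[["A"]]) | diffs(res$alignment[["B"]])
    rate_c <- c(rate_c, mean(d[coding]))
    rate_n <- c(rate_n, mean(d[noncod]))
  }
  expect_lt(mean(rate_c), mean(rate_n))
  expect_gt(sum(rate_c < rate_n), 4)  # direction holds in nearly all runs
})

test_that("neutral long runs converge to the stationary frequencies", {
  pi <- c(A = 0.1, C = 0.2, G = 0.3, T = 0.4)
  set.seed(101)
  g <- make_genome(20000, pi = rep(0.25, 4), seed = 102)
  sim <- ovrf_simulation(g, list(),
                         substitution_params(pi = pi, global_rate = 1))
  simulate_branch(sim, 15)
  freq <- tabulate(match(current_sequence(sim, collapse = FALSE),
                         c("A", "C", "G", "T")), nbins = 4L)
  expect_gt(chisq.test(freq, p = pi)$p.value, 1e-3)
})

test_that("transition:transversion event ratio converges to kappa/2", {
  kappa <- 0.3
  set.seed(111)
  sim <- neutral_sim(10000, 1, seed = 112, kappa = kappa, pi = rep(0.25, 4))
  simulate_branch(sim, 2)
  ts <- ovrfsim:::is_transition(sim$log$from, sim$log$to)
  n <- length(ts)
  ratio <- sum(ts) / sum(!ts)
  p_ts <- kappa / (2 + kappa)
  se <- 4 * sqrt(p_ts * (1 - p_ts) / n)
  expect_lt(abs(sum(ts) / n - p_ts), se)
  expect_equal(ratio, kappa / 2, tolerance = 0.15)
})
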