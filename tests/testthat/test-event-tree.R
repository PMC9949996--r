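test_that("a non-coding genome yields 3 events per site and the flat total", {
  g <- make_genome(12, seed = 1)
  ctx <- site_contexts(g, list())
  asg <- assign_site_categories(ctx, discretize(dist_spec("constant",
                                                          value = 1)))
  params <- substitution_params()
  tree <- build_event_tree(ctx, asg, params)
  tab <- event_table(tree)
  expect_equal(nrow(tab), 36L)
  flat <- enumerate_events(ctx, asg, params)
  expect_equal(total_rate(tree), sum(flat$lambda), tolerance = 1e-12)
})

test_that("a genome whose sites are all protected has no events", {
  # two adjacent 2-codon ORFs tile the genome: every codon is terminal
  g <- suppressWarnings(genome("ATGTAAATGTAA"))
  ctx <- suppressWarnings(
    site_contexts(g, list(orf("a", c(1, 6)), orf("b", c(7, 12)))))
  asg <- assign_site_categories(
    ctx, discretize(dist_spec("constant", value = 1)),
    omega_sets = list(a = discretize(dist_spec("constant", value = 1)),
                      b = discretize(dist_spec("constant", value = 1))))
  expect_error(build_event_tree(ctx, asg,
                                substitution_params(pi = rep(0.25, 4))),
               "no simulatable events")
})

test_that("the region level mirrors the five-region overlap layout", {
  orfs <- make_overlap_layout("fig2", 300)
  g <- imprint_orf_signals(make_genome(300, seed = 2), orfs)
  ctx <- site_contexts(g, orfs)
  set.seed(3)
  omega_sets <- lapply(orfs, function(o) discretize(o$omega))
  names(omega_sets) <- vapply(orfs, `[[`, "", "name")
  asg <- assign_site_categories(ctx, discretize(dist_spec("constant",
                                                          value = 1)),
                                omega_sets)
  tree <- build_event_tree(ctx, asg, substitution_params())
  w <- tree_weights(tree)
  expect_length(ctx$regions, 5L)
  lv <- w$level_region
  one_node <- lv[lv$target == lv$target[1] & lv$transition == lv$transition[1] &
                   lv$mu_cat == lv$mu_cat[1], ]
  expect_equal(sort(unique(one_node$region)), 1:5)  # five children
})

test_that("cached weights are conserved at every level", {
  for (seed in c(4, 5)) {
    setup <- random_small_setup(seed)
    tree <- build_event_tree(setup$ctx, setup$asg, setup$params)
    check_conservation <- function(tree) {
      w <- tree_weights(tree)
      expect_equal(sum(w$by_target), w$total, tolerance = 1e-9)
      expect_equal(sum(w$by_target_transclass), w$total, tolerance = 1e-9)
      lv3 <- w$level_mu; lv4 <- w$level_region; tp <- w$tips
      for (j in 1:4) {
        expect_equal(sum(lv3$weight[lv3$target == j]), w$by_target[j],
                     tolerance = 1e-9)
      }
      agg <- aggregate(weight ~ target + transition + mu_cat, lv4, sum)
      m <- merge(agg, lv3, by = c("target", "transition", "mu_cat"))
      expect_equal(m$weight.x, m$weight.y, tolerance = 1e-9)
      tip_w <- aggregate(cbind(w = lambda * n_events) ~ target + transition +
                           mu_cat + region, tp, sum)
      m4 <- merge(tip_w, lv4,
                  by = c("target", "transition", "mu_cat", "region"))
      expect_equal(m4$w, m4$weight, tolerance = 1e-9)
    }
    check_conservation(tree)
    set.seed(seed + 100)
    for (k in 1:50) {
      e <- sample_event(tree)
      apply_event(tree, e$position, e$to)
    }
    check_conservation(tree)
  }
})

test_that("region selection weight equals the omega-weighted site count", {
  setup <- random_small_setup(6)
  tree <- build_event_tree(setup$ctx, setup$asg, setup$params)
  flat <- enumerate_events(setup$ctx, setup$asg, setup$params)
  w <- tree_weights(tree)
  lv4 <- w$level_region
  # independent recomputation: sum over omega-combination classes of
  # omega_k * N_k, scaled by the factors shared above the region level
  params <- ovrfsim:::resolve_params(setup$params, setup$genome)
  for (r in seq_len(nrow(lv4))) {
    j <- lv4$target[r]; t <- lv4$transition[r]
    mu <- lv4$mu_cat[r]; reg <- lv4$region[r]
    sel <- flat[match(flat$to, NUCLEOTIDES) == j & flat$transition == (t == 1) &
                  flat$mu_cat == mu & flat$region == reg, ]
    classes <- aggregate(cbind(N = omega) ~ omega_key, sel,
                         FUN = length)
    omega_k <- sel$omega[match(classes$omega_key, sel$omega_key)]
    mu_val <- unique(setup$asg$mu_eff[setup$asg$mu_eff_cat == mu])
    shared <- mu_val * (if (t == 1) params$kappa else 1) * params$pi[[j]]
    expect_equal(sum(omega_k * classes$N) * shared, lv4$weight[r],
                 tolerance = 1e-9)
  }
})

test_that("sampling reproduces the flat lambda/Lambda distribution", {
  setup <- random_small_setup(7)
  tree <- build_event_tree(setup$ctx, setup$asg, setup$params)
  flat <- expect_tree_equals_flat(tree, setup)
  n <- 2e5
  set.seed(8)
  counts <- sample_event_counts(tree, n)
  key_c <- paste(counts$site, counts$to)
  key_f <- paste(flat$site, flat$to)
  expect_setequal(key_c, key_f)
  probs <- flat$lambda[match(key_c, key_f)] / sum(flat$lambda)
  expect_gt(chisq.test(counts$count, p = probs)$p.value, 1e-3)

  # events sharing one tip are drawn equally often
  grp <- paste(flat$to, flat$transition, flat$mu_cat, flat$region,
               flat$omega_key)
  big <- names(sort(table(grp), decreasing = TRUE))[1]
  idx <- which(grp == big)
  cnt <- counts$count[match(key_f[idx], key_c)]
  expect_gt(length(cnt), 1L)
  expect_gt(chisq.test(cnt)$p.value, 1e-3)
})

test_that("a single-event tree always returns that event", {
  # 4-codon ORF covering the whole genome: exactly one unprotected codon
  g <- suppressWarnings(genome("ATGAAAGGGTAG"))
  ctx <- suppressWarnings(site_contexts(g, list(orf("a", c(1, 12)))))
  asg <- assign_site_categories(
    ctx, discretize(dist_spec("constant", value = 1)),
    omega_sets = list(a = discretize(dist_spec("constant", value = 0.5))))
  tree <- build_event_tree(ctx, asg, substitution_params(pi = rep(0.25, 4)))
  tab <- event_table(tree)
  expect_true(all(tab$site %in% 4:9))
  set.seed(9)
  e <- sample_event(tree)
  expect_true(e$position %in% 4:9)
  expect_equal(e$lambda, tab$lambda[tab$site == e$position &
                                      tab$to == e$to])
})

test_that("incremental updates equal a fresh rebuild after many events", {
  for (seed in c(10, 11, 12)) {
    setup <- random_small_setup(seed)
    tree <- build_event_tree(setup$ctx, setup$asg, setup$params)
    set.seed(seed + 200)
    for (k in 1:100) {
      e <- sample_event(tree)
      apply_event(tree, e$position, e$to)
    }
    seq2 <- tree_sequence(tree)
    expect_tree_equals_flat(tree, setup, sequence = seq2, tol = 1e-12)
    fresh <- rebuild_tree(setup, seq2)
    expect_equal(event_table(tree), event_table(fresh), tolerance = 1e-12)
    expect_equal(total_rate(tree), total_rate(fresh), tolerance = 1e-12)
  }
})

test_that("deep copies are fully independent and replay identically", {
  setup <- random_small_setup(13)
  tree <- build_event_tree(setup$ctx, setup$asg, setup$params)
  lambda0 <- total_rate(tree)
  seq0 <- tree_sequence(tree)

  copy <- copy_event_tree(tree)
  copy2 <- copy_event_tree(copy)
  set.seed(14)
  for (k in 1:30) {
    e <- sample_event(copy)
    apply_event(copy, e$position, e$to)
  }
  expect_equal(total_rate(tree), lambda0)
  expect_equal(tree_sequence(tree), seq0)       # original untouched
  expect_equal(tree_sequence(copy2), seq0)      # copy-of-copy untouched
  expect_false(identical(tree_sequence(copy), seq0))

  # same seed => the copy replays the original's draws exactly
  set.seed(15); a <- replicate(20, unlist(sample_event(tree)[1:3]))
  set.seed(15); b <- replicate(20, unlist(sample_event(copy2)[1:3]))
  expect_identical(a, b)
})
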