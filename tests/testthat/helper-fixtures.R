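# Shared generators for randomized property tests. Everything is seeded by
# the caller, so results are reproducible.

# A small random genome with 0..max_orfs random (possibly overlapping) ORFs,
# together with contexts, category assignment and model parameters. Layouts
# are re-drawn (with a shifted seed) until at least one site is unprotected.
random_small_setup <- function(seed, max_orfs = 3L, min_len = 30L,
                               max_len = 60L) {
  set.seed(seed)
  L <- sample(min_len:max_len, 1L)
  g <- make_genome(L)
  n_orf <- sample(0:max_orfs, 1L)
  orfs <- list()
  tries <- 0L
  while (length(orfs) < n_orf && tries < 50L) {
    tries <- tries + 1L
    len <- 3L * sample(3:8, 1L)
    if (len >= L) next
    start <- sample.int(L - len, 1L)
    orfs[[length(orfs) + 1L]] <- orf(
      paste0("g", length(orfs) + 1L), c(start, start + len - 1L),
      strand = sample(c("+", "-"), 1L),
      omega = dist_spec("gamma", shape = runif(1, 0.5, 3),
                        scale = runif(1, 0.2, 1), ncat = sample(1:4, 1L))
    )
  }
  ctx <- suppressWarnings(site_contexts(g, orfs))
  if (all(ctx$protected)) return(random_small_setup(seed + 1000L, max_orfs))
  mu_set <- discretize(dist_spec("gamma", shape = 2, scale = 0.5,
                                 ncat = sample(1:2, 1L)))
  omega_sets <- lapply(orfs, function(o) discretize(o$omega))
  names(omega_sets) <- vapply(orfs, `[[`, "", "name")
  asg <- assign_site_categories(ctx, mu_set, omega_sets)
  pi <- runif(4, 0.5, 2)
  params <- substitution_params(kappa = runif(1, 0.2, 3), pi = pi / sum(pi))
  list(genome = g, orfs = orfs, ctx = ctx, asg = asg, params = params)
}

# Rebuild an event tree from scratch on an evolved sequence (the contexts
# depend only on the ORF layout, so only the genome sequence is swapped).
rebuild_tree <- function(setup, sequence, norm = 1) {
  ctx <- setup$ctx
  ctx$genome$seq <- sequence
  build_event_tree(ctx, setup$asg, setup$params, norm = norm)
}

# Compare an event tree, event by event, against the flat R enumeration.
expect_tree_equals_flat <- function(tree, setup, sequence = NULL,
                                    tol = 1e-9) {
  flat <- enumerate_events(setup$ctx, setup$asg, setup$params,
                           sequence = sequence, norm = tree$norm)
  flat <- flat[order(flat$site, flat$to), , drop = FALSE]
  tab <- event_table(tree)
  expect_equal(nrow(tab), nrow(flat))
  expect_equal(tab$site, flat$site)
  expect_equal(tab$to, flat$to)
  expect_lt(max(abs(tab$lambda - flat$lambda) / pmax(flat$lambda, 1e-300)),
            tol)
  expect_equal(total_rate(tree), sum(flat$lambda),
               tolerance = tol)
  invisible(flat)
}

# Text of a small synthetic GenBank record: 60 nt circular genome with a
# plain CDS, a complement CDS and an origin-wrapping join CDS.
gb_fixture_text <- function() {
  seqc <- paste(rep(c("atgaaaccgg", "gtttaacgta", "tgcatcgtag",
                      "ctagctaact", "aaatggcacg", "atagcctaaa"),
                    1L), collapse = "")
  c(
    "LOCUS       SYN001                 60 bp    DNA     circular SYN 01-JAN-2024",
    "DEFINITION  Synthetic record for parser tests.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             5..22",
    "                     /gene=\"alpha\"",
    "                     /note=\"synthetic\"",
    "     CDS             complement(30..47)",
    "                     /gene=\"beta\"",
    "     CDS             join(55..60,1..6)",
    "                     /gene=\"wrap\"",
    "ORIGIN",
    paste0("        1 ", paste(substring(seqc, seq(1, 51, 10), seq(10, 60, 10)),
                               collapse = " ")),
    "//"
  )
}

write_gb_fixture <- function(path = tempfile(fileext = ".gb")) {
  writeLines(gb_fixture_text(), path)
  path
}
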