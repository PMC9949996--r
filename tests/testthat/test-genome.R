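test_that("genome construction enforces the alphabet and minimum length", {
  g <- genome("ACGTACGTA")
  expect_equal(g$length, 9L)
  expect_false(g$circular)
  expect_error(genome("ACGTACGT"), "at least 9 nt")
  expect_error(genome("ACGTNCGTA"), "outside A/C/G/T")
  expect_error(genome("ACGTRCGTA"), "outside A/C/G/T")
})

test_that("ORF validation catches bad geometry", {
  g <- genome(strrep("ACGT", 30))  # 120 nt linear
  expect_error(validate_orfs(g, list(orf("x", c(1, 100)))), "multiple of 3")
  expect_error(validate_orfs(g, list(orf("x", c(100, 126)))),
               "exceeds genome length")
  expect_error(
    validate_orfs(g, list(orf("x", list(c(100, 120), c(1, 12))))),
    "circular"
  )
  gc <- genome(strrep("ACGT", 30), circular = TRUE)
  expect_silent(suppressWarnings(
    validate_orfs(gc, list(orf("x", list(c(100, 120), c(1, 12)))))
  ))
  expect_error(
    suppressWarnings(
      validate_orfs(gc, list(orf("x", list(c(101, 119), c(2, 12)))))
    ),
    "meeting at the origin"
  )
  expect_warning(
    expect_warning(validate_orfs(g, list(orf("x", c(2, 13)))),
                   "does not begin with ATG"),
    "does not end with a stop"
  )
})

test_that("frameshift classification matches direct frame enumeration", {
  g <- genome(strrep("ACGT", 100))
  a <- orf("a", c(1, 300))
  expect_equal(classify_frameshift(a, orf("b", c(1, 300)), g), "+0")
  expect_equal(classify_frameshift(a, orf("b", c(101, 400)), g), "+1")
  expect_error(classify_frameshift(a, orf("b", c(301, 360)), g), "no overlap")

  # oracle: chunk each ORF's reading-order site list into codon triples and
  # read the shift off the per-site codon offsets over the whole overlap
  offsets_along <- function(o) {
    s <- orf_sites(o, g)
    off <- rep(0:2, length(s) / 3)
    names(off) <- s
    off
  }
  set.seed(42)
  for (rep in 1:30) {
    s1 <- sample(1:50, 1); l1 <- 3 * sample(8:30, 1)
    s2 <- sample(s1:(s1 + l1 - 3), 1); l2 <- 3 * sample(8:30, 1)
    st <- sample(c("+", "-"), 2, replace = TRUE)
    a <- orf("a", c(s1, s1 + l1 - 1), st[1])
    b <- orf("b", c(s2, s2 + l2 - 1), st[2])
    lab <- classify_frameshift(a, b, g)
    offa <- offsets_along(a); offb <- offsets_along(b)
    shared <- intersect(names(offa), names(offb))
    same <- st[1] == st[2]
    digits <- if (same) (offa[shared] - offb[shared]) %% 3 else
      (offa[shared] + offb[shared]) %% 3
    expect_length(unique(digits), 1L)  # consistent over the whole overlap
    expect_equal(lab, paste0(if (same) "+" else "-", digits[[1]]))
    if (same && st[1] == "+") {
      expect_equal(lab, paste0("+", (s2 - s1) %% 3))  # closed form
    }
    expect_equal(substr(classify_frameshift(b, a, g), 1, 1),
                 substr(lab, 1, 1))  # sign is symmetric
  }
})

test_that("region partition matches the canonical overlap layouts", {
  g <- genome(strrep("ACGT", 75))  # 300 nt
  orfs <- make_overlap_layout("fig2", 300)
  regs <- partition_regions(g, orfs)
  expect_length(regs, 5L)
  members <- sort(vapply(regs, function(r)
    paste(sort(r$orf_membership), collapse = ","), ""))
  expect_equal(members, sort(c("a", "", "b", "b,c", "c")))

  expect_length(partition_regions(g, list()), 1L)
  expect_equal(partition_regions(g, list())[[1]]$sites, 1:300)

  twin <- list(orf("a", c(10, 30)), orf("b", c(10, 30)))
  regs2 <- partition_regions(g, twin)
  expect_length(regs2, 2L)
})

test_that("region partition is exact on randomized layouts", {
  for (seed in 1:8) {
    setup <- random_small_setup(seed)
    regs <- partition_regions(setup$genome, setup$orfs)
    all_sites <- sort(unlist(lapply(regs, `[[`, "sites")))
    expect_equal(all_sites, seq_len(setup$genome$length))  # complete+disjoint
    memb <- setup$ctx$membership
    for (r in regs) {
      per_site <- lapply(r$sites, function(s) sort(memb$orf[memb$site == s]))
      expect_length(unique(per_site), 1L)
      expect_equal(per_site[[1]], sort(r$orf_membership))
    }
  }
})

test_that("site contexts protect terminal codons and track frames", {
  g <- genome("ATGAAATAGCCC")  # 12 nt
  ctx <- site_contexts(g, list(orf("a", c(1, 9))))
  expect_equal(which(ctx$protected), c(1:3, 7:9))
  expect_equal(ctx$membership$site, 1:9)
  expect_equal(site_context(ctx, 10)$frame_memberships$orf, character())

  # circular wrap: first codon spans the origin
  gc <- genome(strrep("ACGT", 3), circular = TRUE)  # 12 nt
  ctx2 <- suppressWarnings(
    site_contexts(gc, list(orf("w", list(c(10, 12), c(1, 6)))))
  )
  expect_true(all(ctx2$protected[c(10, 11, 12)]))  # first codon
  expect_true(all(ctx2$protected[4:6]))            # last codon
  expect_false(any(ctx2$protected[1:3]))
  m <- ctx2$membership
  expect_equal(m$p1[m$site == 11], 10L)
  expect_equal(m$p3[m$site == 11], 12L)

  # dual membership: independent codon bookkeeping per ORF
  g3 <- genome(strrep("ACGT", 30))
  ctx3 <- suppressWarnings(
    site_contexts(g3, list(orf("a", c(1, 30)), orf("b", c(11, 40))))
  )
  m3 <- ctx3$membership[ctx3$membership$site == 15, ]
  expect_equal(nrow(m3), 2L)
  expect_equal(m3$codon_index[m3$orf == "a"], 5L)
  expect_equal(m3$codon_index[m3$orf == "b"], 2L)
  expect_equal(m3$codon_pos[m3$orf == "a"], 2L)
  expect_equal(m3$codon_pos[m3$orf == "b"], 1L)
})

test_that("codon extraction reads the current sequence in the right frame", {
  g <- genome("ATGAAATAG")
  ctx <- site_contexts(g, list(orf("a", c(1, 9))))
  got <- codon_at(g, ctx, 5, "a")
  expect_equal(got$codon, "AAA")
  expect_equal(got$offset, 1L)

  # same gene encoded on the minus strand of the reverse complement
  g2 <- genome("CTATTTCAT")
  ctx2 <- site_contexts(g2, list(orf("a", c(1, 9), "-")))
  expect_equal(codon_at(g2, ctx2, 5, "a")$codon, "AAA")

  # wrap-around codon on a circular genome is stitched across the origin
  gc <- genome(c("G", "A", "A", "T", "A", "G", "C", "C", "C", "A", "T", "G"),
               circular = TRUE)
  ctx3 <- site_contexts(gc, list(orf("w", list(c(10, 12), c(1, 6)))))
  expect_equal(codon_at(gc, ctx3, 12, "w")$codon, "ATG")
  expect_equal(codon_at(gc, ctx3, 12, "w")$offset, 2L)

  # concatenating codons over an ORF reproduces its coding sequence
  for (seed in 1:4) {
    setup <- random_small_setup(seed, max_orfs = 2L)
    for (o in setup$orfs) {
      s <- orf_sites(o, setup$genome)
      cds <- setup$genome$seq[s]
      if (o$strand == "-") cds <- ovrfsim:::complement_nt(cds)
      codons <- vapply(s[seq(1, length(s), by = 3)], function(p)
        codon_at(setup$genome, setup$ctx, p, o$name)$codon, "")
      expect_equal(paste(codons, collapse = ""), paste(cds, collapse = ""))
    }
  }
})

test_that("linearizing a circular genome away from ORFs rotates the regions", {
  L <- 60L
  gc <- make_genome(L, seed = 9, circular = TRUE)
  orfs <- list(suppressWarnings(orf("a", c(10, 30))))
  regs <- suppressWarnings(partition_regions(gc, orfs))
  # cut after position 40 (outside the ORF): rotate so old position 41 is new 1
  k <- 40L
  rot <- c(gc$seq[(k + 1):L], gc$seq[1:k])
  gl <- genome(rot, circular = FALSE)
  shift <- function(p) ((p - k - 1L) %% L) + 1L
  orfs2 <- list(orf("a", c(shift(10L), shift(30L))))
  regs2 <- suppressWarnings(partition_regions(gl, orfs2))
  expect_length(regs2, length(regs))
  for (i in seq_along(regs)) {
    old <- sort(shift(regs[[i]]$sites))
    match_new <- Filter(function(r)
      identical(sort(r$sites), old), regs2)
    expect_length(match_new, 1L)
    expect_equal(sort(match_new[[1]]$orf_membership),
                 sort(regs[[i]]$orf_membership))
  }
})
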