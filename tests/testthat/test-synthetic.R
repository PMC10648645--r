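test_that("genealogy shapes give the promised pairwise generations", {
  g2 <- simulate_genealogy(2, tmrca = 10, shape = "star")
  pg <- pairwise_generations(g2)
  expect_equal(pg[1, 2], 10)                       # 20 meioses apart

  g27 <- simulate_genealogy(27, tmrca = 155, shape = "star")
  pg <- pairwise_generations(g27)
  off <- pg[upper.tri(pg)]
  expect_length(off, 351)
  expect_true(all(off == 155))

  g3 <- simulate_genealogy(3, tmrca = NA, shape = "tree",
                           tree = "((A:5,B:5):150,C:155);")
  pg <- pairwise_generations(g3)
  expect_equal(pg["A", "B"], 5)
  expect_equal(pg["A", "C"], 155)
  expect_equal(pg["B", "C"], 155)
  expect_equal(g3$tmrca_generations, 155)

  expect_error(simulate_genealogy(4, NA, "tree", tree = "((A:5,B:5):150,C:155);"),
               "leaf count")
  expect_error(simulate_genealogy(3, NA, "tree", tree = "((A:5,B:9):150,C:155);"),
               "ultrametric")

  gc1 <- simulate_genealogy(8, tmrca = 60, shape = "coalescent", seed = 5)
  gc2 <- simulate_genealogy(8, tmrca = 60, shape = "coalescent", seed = 5)
  expect_identical(gc1, gc2)
  expect_equal(max(pairwise_generations(gc1)), 60)
})

test_that("recombination breakpoints follow the 1-per-Morgan Poisson law", {
  set.seed(21)
  counts <- vapply(seq_len(1e5),
                   function(i) length(recombination_breakpoints(1, 24.6)),
                   numeric(1))
  se <- sqrt(0.246 / 1e5)
  expect_lt(abs(mean(counts) - 0.246), 3 * se)
})

test_that("ancestral segments shorten as exponentials with mean 100/g cM", {
  big <- default_region_map(length_cm = 240)   # focal far from both edges
  focal_bp <- round(cm_to_bp(big, 120))
  expect_equal(drop_meioses(0, big, focal_bp),
               structure(c(big$pos_bp[1], big$pos_bp[nrow(big)]),
                         cm = c(0, 240), breakpoints = numeric(0)))
  set.seed(22)
  one_sided <- vapply(seq_len(1e4), function(i) {
    seg <- attr(drop_meioses(50, big, focal_bp), "cm")
    120 - seg[1]
  }, numeric(1))
  expect_lt(abs(mean(one_sided) - 2), 3 * 2 / sqrt(1e4))  # Exp mean 100/50

  for (g in c(20, 100)) {
    lens <- vapply(seq_len(5000), function(i) {
      seg <- attr(drop_meioses(g, big, focal_bp), "cm")
      seg[2] - 120
    }, numeric(1))
    lens <- lens[lens < 120 - 1e-9]            # uncensored draws
    # rare floating-point collisions among 5000 draws trigger a ties warning
    p <- suppressWarnings(stats::ks.test(lens, stats::pexp,
                                         rate = g / 100)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("a zero-TMRCA cohort is identical to the founder everywhere", {
  gm <- default_region_map()
  pan <- marker_panel(gm, n_markers = 300, seed = 31)
  gen <- simulate_genealogy(5, tmrca = 0, shape = "star")
  coh <- simulate_cohort(gen, pan, gm, seed = 32)
  H <- sapply(seq_len(5), function(i)
    if (coh$carrier_hap[i] == 1) coh$hap1[, i] else coh$hap2[, i])
  expect_true(all(H == coh$truth$founder))
})

test_that("every pair of a deep star cohort still shares around the focal variant", {
  coh <- star_cohort(n = 27, tmrca = 155, n_markers = 1200, seed = 33)
  ssm <- similarity_matrix(coh)
  expect_equal(ssm$n_pairs, 351)
  fi_bp <- coh$panel$pos_bp[attr(coh$panel, "focal_index")]
  up <- upper.tri(ssm$length_cm)
  expect_true(all(ssm$left_bp[up] <= fi_bp & ssm$right_bp[up] >= fi_bp))
})

test_that("stored truth segments replay from the recorded breakpoints", {
  coh <- star_cohort(n = 8, tmrca = 60, n_markers = 400, seed = 34)
  fi <- attr(coh$panel, "focal_index")
  focal_rel <- coh$panel$cm[fi] - coh$map$cm[1]
  L <- attr(coh$panel, "region_cm")
  for (i in seq_len(8)) {
    bks <- coh$truth$leaf_breakpoints[[i]]
    left <- if (any(bks < focal_rel)) max(bks[bks < focal_rel]) else 0
    right <- if (any(bks > focal_rel)) min(bks[bks > focal_rel]) else L
    expect_equal(coh$truth$segments_cm[i, ], c(left, right))
  }
})

test_that("leaves below the same internal node share its recombination history", {
  gm <- default_region_map()
  pan <- marker_panel(gm, n_markers = 300, seed = 35)
  gen <- simulate_genealogy(3, tmrca = NA, shape = "tree",
                           tree = "((A:5,B:5):150,C:155);")
  coh <- simulate_cohort(gen, pan, gm, seed = 36)
  phy <- gen$tree
  root <- 4L  # 3 tips -> root node 4
  internal <- setdiff(unique(phy$edge[, 1]), root)
  shared_edge <- which(phy$edge[, 1] == root & phy$edge[, 2] == internal)
  shared_bks <- coh$truth$edge_breakpoints[[shared_edge]]
  ia <- match("A", coh$ids); ib <- match("B", coh$ids); ic <- match("C", coh$ids)
  expect_true(all(shared_bks %in% coh$truth$leaf_breakpoints[[ia]]))
  expect_true(all(shared_bks %in% coh$truth$leaf_breakpoints[[ib]]))
  expect_false(any(shared_bks %in% coh$truth$leaf_breakpoints[[ic]]))
})

test_that("identical seeds reproduce cohorts byte for byte", {
  a <- star_cohort(n = 6, tmrca = 30, n_markers = 250, seed = 37)
  b <- star_cohort(n = 6, tmrca = 30, n_markers = 250, seed = 37)
  expect_identical(a, b)
})

test_that("phased TSV, VCF and truth JSON writers round-trip", {
  coh <- star_cohort(n = 4, tmrca = 25, n_markers = 150, seed = 38)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_phased_tsv(coh, tsv)
  back <- read_phased_tsv(tsv, coh$map)
  expect_equal(back$hap1, coh$hap1)
  expect_equal(back$hap2, coh$hap2)
  expect_equal(back$carrier_hap, coh$carrier_hap)
  expect_equal(attr(back$panel, "focal_index"),
               attr(coh$panel, "focal_index"))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(coh, vcf)
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(vcf, verbose = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  fi <- attr(coh$panel, "focal_index")
  expect_equal(unname(gt[fi, ]),
               paste0(coh$hap1[fi, ], "|", coh$hap2[fi, ]))
  expect_equal(nrow(gt), 150)

  js <- withr::local_tempfile(fileext = ".json")
  write_truth_json(coh, js)
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(truth$tmrca_generations, 25)
  phy <- ape::read.tree(text = truth$newick)
  expect_equal(sort(phy$tip.label), sort(coh$ids))
})

test_that("genotype-only emission keeps genotypes but scrambles phase", {
  gm <- default_region_map()
  pan <- marker_panel(gm, n_markers = 400, seed = 39)
  gen <- simulate_genealogy(6, tmrca = 20, shape = "star")
  ph <- simulate_cohort(gen, pan, gm, seed = 40)
  go <- simulate_cohort(gen, pan, gm, seed = 40, genotype_only = TRUE)
  expect_equal(ph$hap1 + ph$hap2, go$hap1 + go$hap2)
  expect_true(all(is.na(go$carrier_hap)))
})
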