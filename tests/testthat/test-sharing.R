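test_that("carrier haplotype is read off the focal genotype", {
  gm <- tiny_map()
  pan <- manual_panel(gm, c(1.5e6, 3e6, 4.5e6), focal_index = 2)
  coh <- manual_cohort(pan, gm, list(
    list(c(0, 0, 1), c(1, 1, 0)),    # alt on hap2
    list(c(0, 1, 0), c(1, 0, 1)),    # alt on hap1
    list(c(0, 0, 0), c(1, 0, 1)),    # homozygous ref at focal
    list(c(0, 1, 0), c(1, 1, 1))))   # homozygous alt
  expect_equal(carrier_haplotype(coh, 1), 2L)
  expect_equal(carrier_haplotype(coh, "S02"), 1L)
  expect_error(carrier_haplotype(coh, 3), "not a carrier")
  expect_error(carrier_haplotype(coh, 4), "unsupported")
})

test_that("every simulated carrier has exactly one carrier haplotype", {
  coh <- star_cohort(n = 27, tmrca = 155, n_markers = 300, seed = 51)
  fi <- attr(coh$panel, "focal_index")
  for (i in seq_len(27)) {
    ci <- carrier_haplotype(coh, i)
    expect_true(ci %in% 1:2)
    hap <- if (ci == 1) coh$hap1[, i] else coh$hap2[, i]
    other <- if (ci == 1) coh$hap2[, i] else coh$hap1[, i]
    expect_equal(unname(hap[fi]), 1L)
    expect_equal(unname(other[fi]), 0L)
  }
})

test_that("the outward scan stops before the first mismatching marker", {
  gm <- genetic_map(c(1e6, 11e6), c(0, 10))
  pan <- manual_panel(gm, seq(2e6, 2e6 + 9e5, by = 1e5), focal_index = 5)
  hA <- c(0, 1, 0, 1, 1, 0, 1, 0, 1, 0)
  hB <- hA; hB[2] <- 1 - hB[2]; hB[9] <- 1 - hB[9]   # differ at 2 and 9 only
  coh <- manual_cohort(pan, gm, list(
    list(hA, 1 - hA), list(hB, 1 - hB)))   # non-carrier = complement
  s <- shared_extent(coh, 1, 2, mode = "phased", filter = FALSE)
  expect_equal(c(s$left_idx, s$right_idx), c(3, 8))
  expect_equal(s$break_left, "haplotype-mismatch")
  expect_equal(s$break_right, "haplotype-mismatch")
  expect_equal(s$length_cm,
               segment_length_cm(gm, pan$pos_bp[3], pan$pos_bp[8]))
})

test_that("identical carrier haplotypes share the whole panel, censored at the edges", {
  gm <- tiny_map()
  pan <- manual_panel(gm, seq(1.2e6, 4.8e6, length.out = 7), focal_index = 4)
  h <- c(1, 0, 1, 1, 0, 0, 1)
  coh <- manual_cohort(pan, gm, list(list(h, rep(0, 7)), list(h, rep(0, 7))))
  s <- shared_extent(coh, 1, 2)
  expect_equal(c(s$left_idx, s$right_idx), c(1, 7))
  expect_equal(c(s$break_left, s$break_right),
               c("region-edge", "region-edge"))
})

test_that("only opposite homozygotes are hard stops in genotype mode", {
  gm <- genetic_map(c(1e6, 11e6), c(0, 10))
  pan <- manual_panel(gm, seq(2e6, 2e6 + 6e5, by = 1e5), focal_index = 4)
  # subject 1: hom-ref at marker 2, hom-alt at marker 6
  h1a <- c(0, 0, 1, 1, 0, 1, 0); h1b <- c(1, 0, 0, 0, 1, 1, 1)
  # subject 2: hom-alt at marker 2 (hard stop), het at marker 6 (compatible)
  h2a <- c(0, 1, 1, 1, 0, 1, 0); h2b <- c(1, 1, 0, 0, 1, 0, 1)
  coh <- manual_cohort(pan, gm, list(list(h1a, h1b), list(h2a, h2b)))
  s <- shared_extent(coh, 1, 2, mode = "genotype", filter = FALSE)
  expect_equal(c(s$left_idx, s$right_idx), c(3, 7))
  expect_equal(s$break_left, "hard-stop")
  expect_equal(s$break_right, "region-edge")
})

test_that("missing genotypes never break a segment", {
  gm <- genetic_map(c(1e6, 11e6), c(0, 10))
  pan <- manual_panel(gm, seq(2e6, 2e6 + 4e5, by = 1e5), focal_index = 3)
  h1 <- c(0, 1, 1, 0, 1)
  h2 <- c(0, NA, 1, NA, 1)
  coh <- manual_cohort(pan, gm, list(list(h1, rep(0, 5)),
                                     list(h2, rep(0, 5))))
  s <- shared_extent(coh, 1, 2, filter = FALSE)
  expect_equal(c(s$left_idx, s$right_idx), c(1, 5))
})

test_that("the spurious-switch filter removes short flanked runs only", {
  base <- rep(FALSE, 60)
  m1 <- base; m1[30] <- TRUE                       # isolated, deep inside
  expect_equal(filter_spurious_switches(m1), base)
  m2 <- base; m2[30:32] <- TRUE                    # run of K+1 = 3
  expect_equal(filter_spurious_switches(m2), m2)
  m3 <- base; m3[30] <- TRUE; m3[5] <- TRUE        # run at 5 poorly flanked
  expect_equal(which(filter_spurious_switches(m3)), 5L)
  m4 <- base; m4[2] <- TRUE                        # near the edge: kept
  expect_equal(filter_spurious_switches(m4), m4)
})

test_that("filtering under phase noise lengthens segments and recovers truth more often", {
  gm <- default_region_map()
  pan <- marker_panel(gm, n_markers = 1000, seed = 52)
  gen <- simulate_genealogy(33, tmrca = 20, shape = "star")
  coh <- simulate_cohort(gen, pan, gm, seed = 53, phase_noise = 0.002)
  raw <- similarity_matrix(coh, filter = FALSE)
  cln <- similarity_matrix(coh, filter = TRUE)
  up <- which(upper.tri(raw$length_cm))
  expect_gte(length(up), 500)
  expect_true(all(cln$length_cm[up] >= raw$length_cm[up]))

  # truth recovery: detected interval covers the true pair intersection
  segs <- coh$truth$segments_cm
  rel <- coh$panel$cm - coh$map$cm[1]
  covers <- function(ssm) {
    ok <- logical(0)
    n <- length(ssm$ids)
    for (p in seq_len(n - 1)) for (q in (p + 1):n) {
      tl <- max(segs[p, 1], segs[q, 1]); tr <- min(segs[p, 2], segs[q, 2])
      inside <- which(rel > tl & rel < tr)
      lrel <- bp_to_cm(coh$map, ssm$left_bp[p, q]) - coh$map$cm[1]
      rrel <- bp_to_cm(coh$map, ssm$right_bp[p, q]) - coh$map$cm[1]
      ok <- c(ok, length(inside) == 0 ||
                (lrel <= rel[min(inside)] && rrel >= rel[max(inside)]))
    }
    ok
  }
  expect_gt(sum(covers(cln)), sum(covers(raw)))
})

test_that("the scan agrees with an exhaustive reference on random instances", {
  set.seed(54)
  gm <- genetic_map(c(1e6, 51e6), c(0, 25))
  for (r in 1:200) {
    nm <- sample(10:50, 1)
    ns <- sample(2:6, 1)
    fi <- sample(2:(nm - 1), 1)
    pan <- manual_panel(gm, sort(sample(seq(2e6, 50e6, by = 1e4), nm)), fi)
    haps <- lapply(seq_len(ns), function(i) {
      h1 <- rbinom(nm, 1, 0.5); h2 <- rbinom(nm, 1, 0.5)
      if (runif(1) < 0.3) h1[sample(nm, 2)] <- NA
      h1[fi] <- 1; h2[fi] <- 0
      list(h1, h2)
    })
    coh <- manual_cohort(pan, gm, haps)
    i <- 1; j <- sample(2:ns, 1)
    x <- coh$hap1[, i]; y <- coh$hap1[, j]
    sp <- shared_extent(coh, i, j, mode = "phased", filter = FALSE)
    expect_equal(c(sp$left_idx, sp$right_idx),
                 ref_extent(ref_mismatch_phased(x, y), fi))
    sg <- shared_extent(coh, i, j, mode = "genotype", filter = FALSE)
    g1 <- coh$hap1[, i] + coh$hap2[, i]; g2 <- coh$hap1[, j] + coh$hap2[, j]
    expect_equal(c(sg$left_idx, sg$right_idx),
                 ref_extent(ref_mismatch_genotype(g1, g2), fi))
    # hard stops are a subset of haplotype mismatches
    expect_lte(sg$left_idx, sp$left_idx)
    expect_gte(sg$right_idx, sp$right_idx)
  }
})

test_that("detected segments contain the true ancestral intersection without noise", {
  coh <- star_cohort(n = 10, tmrca = 40, n_markers = 800, seed = 55)
  ssm <- similarity_matrix(coh, filter = FALSE)
  segs <- coh$truth$segments_cm
  rel <- coh$panel$cm - coh$map$cm[1]
  for (p in 1:9) for (q in (p + 1):10) {
    tl <- max(segs[p, 1], segs[q, 1]); tr <- min(segs[p, 2], segs[q, 2])
    inside <- which(rel > tl & rel < tr)
    if (length(inside) == 0) next
    lrel <- bp_to_cm(coh$map, ssm$left_bp[p, q]) - coh$map$cm[1]
    rrel <- bp_to_cm(coh$map, ssm$right_bp[p, q]) - coh$map$cm[1]
    expect_lte(lrel, rel[min(inside)])
    expect_gte(rrel, rel[max(inside)])
  }
})

test_that("the similarity matrix is symmetric and matches per-pair recomputation", {
  coh <- star_cohort(n = 6, tmrca = 30, n_markers = 300, seed = 56)
  ssm <- similarity_matrix(coh)
  expect_equal(ssm$length_cm, t(ssm$length_cm))
  expect_equal(ssm$n_pairs, 15)
  for (p in 1:5) for (q in (p + 1):6) {
    s <- shared_extent(coh, p, q)
    expect_equal(ssm$length_cm[p, q], s$length_cm)
    expect_equal(ssm$left_bp[p, q], s$left_bp)
  }
  expect_equal(diag(ssm$length_cm), rep(ssm$region_cm, 6),
               ignore_attr = TRUE)
})

test_that("two identical subjects share the whole region", {
  gm <- tiny_map()
  pan <- manual_panel(gm, seq(1.1e6, 4.9e6, length.out = 9), focal_index = 5)
  h <- c(0, 1, 1, 0, 1, 1, 0, 0, 1)
  coh <- manual_cohort(pan, gm, list(list(h, rep(0, 9)), list(h, rep(0, 9))))
  ssm <- similarity_matrix(coh)
  expect_equal(ssm$length_cm[1, 2],
               segment_length_cm(gm, pan$pos_bp[1], pan$pos_bp[9]))
})

test_that("one representative per family is selected", {
  md <- data.frame(subject_id = c("P011", "P011a", "P012", "P013", "P013a"),
                   family_id = c(1, 1, 2, 3, 3),
                   rep = c(0, 1, 1, 1, 0))
  expect_equal(select_family_representatives(md),
               c("P011", "P012", "P013"))
  expect_equal(select_family_representatives(md, representative_col = "rep"),
               c("P011a", "P012", "P013"))
  md$rep[1] <- 1
  expect_error(select_family_representatives(md, representative_col = "rep"),
               "more than one")
})
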