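# Shared fixtures and independent reference implementations used as oracles.

# small strictly-increasing map: 5 anchors over 4 Mb, 4 cM
tiny_map <- function() {
  genetic_map(c(1e6, 2e6, 3e6, 4e6, 5e6), c(0, 1, 1.5, 3, 4))
}

# hand-built marker panel at explicit positions (uniform background freq)
manual_panel <- function(map, pos_bp, focal_index, freq = 0.5) {
  freq <- rep_len(freq, length(pos_bp))
  freq[focal_index] <- 0
  p <- data.frame(id = sprintf("M%03d", seq_along(pos_bp)), pos_bp = pos_bp,
                  cm = bp_to_cm(map, pos_bp), freq = freq)
  p$id[focal_index] <- "FOCAL"
  structure(p, focal_index = focal_index,
            region_cm = region_length_cm(map),
            focal_offset_cm = p$cm[focal_index] - map$cm[1],
            class = c("marker_panel", "data.frame"))
}

# cohort from a list of (hap1, hap2) pairs
manual_cohort <- function(panel, map, haps, ids = NULL) {
  n <- length(haps)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  hap1 <- sapply(haps, function(h) as.integer(h[[1]]))
  hap2 <- sapply(haps, function(h) as.integer(h[[2]]))
  dimnames(hap1) <- dimnames(hap2) <- list(panel$id, ids)
  carrier_cohort(panel, map, hap1, hap2, ids)
}

# exhaustive reference for the shared-extent scan: the maximal interval
# containing the focal index with no mismatching marker inside
ref_extent <- function(mismatch, fi) {
  nm <- length(mismatch)
  best <- c(fi, fi)
  for (l in 1:fi) for (r in fi:nm) {
    if (!any(mismatch[l:r]) && (r - l) > (best[2] - best[1])) best <- c(l, r)
  }
  best
}

# reference phased mismatch mask (independent of pair_mismatch internals)
ref_mismatch_phased <- function(x, y) {
  m <- !is.na(x) & !is.na(y) & x != y
  m
}

ref_mismatch_genotype <- function(g1, g2) {
  m <- !is.na(g1) & !is.na(g2) &
    ((g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0))
  m
}

# closed-form mean detected length for the pair decay model:
# each side Exp(2g/100 per cM) truncated at the region edge
mean_length_closed_form <- function(g, a, b) {
  lam <- 2 * g / 100
  (1 - exp(-lam * a)) / lam + (1 - exp(-lam * b)) / lam
}

# one standard star cohort reused by several tests (moderate panel)
star_cohort <- function(n = 10, tmrca = 40, n_markers = 800, seed = 42) {
  gm <- default_region_map()
  pan <- marker_panel(gm, n_markers = n_markers, seed = seed)
  gen <- simulate_genealogy(n, tmrca = tmrca, shape = "star")
  simulate_cohort(gen, pan, gm, seed = seed + 1)
}
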