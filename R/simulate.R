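#' Build a marker panel over the mapped region
#'
#' Draws biallelic SNP positions uniformly over the physical region of a
#' genetic map and assigns background alternative-allele frequencies from a
#' Beta distribution (default Beta(2, 2), i.e. mostly common variants, as on
#' a genotyping array). One marker is the focal pathogenic variant: it is
#' placed at a fixed genetic offset from the left region edge and its
#' background frequency is 0 (the alternative allele exists only on carrier
#' chromosomes).
#'
#' @param map A [genetic_map()].
#' @param n_markers Panel size (default 4130, the emulated array density).
#' @param focal_cm Genetic offset of the focal variant from the left region
#'   edge (cM); must be strictly inside the region.
#' @param freq_shape Length-2 shape parameters of the Beta frequency model.
#' @param freq_clamp Frequencies are clamped to this range (arrays carry few
#'   near-monomorphic sites).
#' @param seed Optional integer seed.
#' @return An object of class `marker_panel`: a data frame with columns
#'   `id`, `pos_bp`, `cm` (cumulative), `freq`, and attributes
#'   `focal_index`, `region_cm` (total cM), `focal_offset_cm`.
#' @export
marker_panel <- function(map, n_markers = 4130L, focal_cm = 10,
                         freq_shape = c(2, 2), freq_clamp = c(0.05, 0.95),
                         seed = NULL) {
  stopifnot(inherits(map, "genetic_map"), n_markers >= 3L)
  L <- region_length_cm(map)
  if (focal_cm <= 0 || focal_cm >= L)
    stop("focal variant must lie strictly inside the region", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lo <- map$pos_bp[1]; hi <- map$pos_bp[nrow(map)]
  focal_bp <- round(cm_to_bp(map, map$cm[1] + focal_cm))
  pos <- unique(round(stats::runif(n_markers * 1.2, lo + 1, hi - 1)))
  pos <- setdiff(pos, focal_bp)
  while (length(pos) < n_markers - 1L) {
    pos <- unique(c(pos, round(stats::runif(n_markers, lo + 1, hi - 1))))
    pos <- setdiff(pos, focal_bp)
  }
  pos <- sort(c(sample(pos, n_markers - 1L), focal_bp))
  freq <- pmin(pmax(stats::rbeta(n_markers, freq_shape[1], freq_shape[2]),
                    freq_clamp[1]), freq_clamp[2])
  focal_index <- match(focal_bp, pos)
  freq[focal_index] <- 0
  panel <- data.frame(id = sprintf("M%05d", seq_len(n_markers)),
                      pos_bp = pos, cm = bp_to_cm(map, pos), freq = freq)
  panel$id[focal_index] <- "FOCAL"
  structure(panel,
            focal_index = focal_index,
            region_cm = L,
            focal_offset_cm = focal_cm,
            class = c("marker_panel", "data.frame"))
}

#' Recombination breakpoints of one lineage
#'
#' Crossovers accumulate along a lineage of `g` meioses as a Poisson process
#' with rate 1 per Morgan per meiosis (no interference), i.e. a total of
#' Poisson(`g * region_cm / 100`) breakpoints placed uniformly on the
#' genetic scale.
#'
#' @param g Number of meioses (generations along the lineage), `>= 0`.
#' @param region_cm Genetic length of the region (cM).
#' @return Sorted numeric vector of breakpoint positions, cM from the left
#'   region edge (possibly empty).
#' @export
recombination_breakpoints <- function(g, region_cm) {
  if (g < 0) stop("g must be >= 0", call. = FALSE)
  n <- stats::rpois(1L, g * region_cm / 100)
  sort(stats::runif(n, 0, region_cm))
}

#' Ancestral segment retained after g meioses
#'
#' Starting from a founder chromosome spanning the whole mapped region, each
#' meiosis sprinkles crossovers (Poisson, 1 per Morgan); the descendant
#' retains the founder haplotype only on the maximal breakpoint-free
#' interval around the focal variant. `g = 0` returns the whole region.
#'
#' @param g Number of meioses separating the descendant from the founder.
#' @param map A [genetic_map()].
#' @param focal_bp Physical position of the focal variant.
#' @param seed Optional integer seed.
#' @return Numeric `c(left_bp, right_bp)` with attributes `cm`
#'   (genetic endpoints, cM from the left region edge) and `breakpoints`.
#' @export
drop_meioses <- function(g, map, focal_bp, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.null(seed)) set.seed(seed)
  L <- region_length_cm(map)
  focal_rel <- bp_to_cm(map, focal_bp) - map$cm[1]
  bks <- recombination_breakpoints(g, L)
  seg_cm <- segment_around(focal_rel, bks, L)
  bp <- cm_to_bp(map, map$cm[1] + seg_cm)
  structure(bp, cm = seg_cm, breakpoints = bks)
}

# maximal breakpoint-free interval around a focal offset (relative cM)
segment_around <- function(focal_rel, bks, region_cm) {
  left <- if (any(bks < focal_rel)) max(bks[bks < focal_rel]) else 0
  right <- if (any(bks > focal_rel)) min(bks[bks > focal_rel]) else region_cm
  c(left, right)
}

#' Simulate a phased carrier cohort with known truth
#'
#' Generates phased diplotypes for the leaves of a carrier genealogy. The
#' founder haplotype is drawn from the background frequency model and
#' carries the focal alternative allele. Crossover breakpoints are simulated
#' once per genealogy branch (so leaves below the same internal node share
#' the recombination history above it), each carrier retains the founder
#' haplotype on its breakpoint-free interval around the focal variant and is
#' filled with fresh background alleles outside it; the non-carrier
#' haplotype is background throughout. The generating genealogy, per-branch
#' breakpoints and per-carrier true segment endpoints are recorded as truth.
#'
#' @param genealogy A [simulate_genealogy()] object.
#' @param panel A [marker_panel()].
#' @param map The [genetic_map()] the panel was built on.
#' @param seed Optional integer seed (one global stream; draws are consumed
#'   in a fixed order so equal seeds give byte-identical cohorts).
#' @param background `"independent"` (no background linkage disequilibrium)
#'   or `"markov"` (first-order allele copying with probability `ld_rho`,
#'   which creates background LD and hence longer chance identity-by-state).
#' @param ld_rho Copy probability of the Markov background model.
#' @param phase_noise Per-marker probability that a subject's two haplotype
#'   alleles are swapped at that single marker — the spurious
#'   double-recombinant artifact of statistical phasing (the focal marker is
#'   exempt). Default 0.
#' @param missing_rate Per-marker probability that a subject's genotype is
#'   missing (both haplotype alleles `NA`). Default 0.
#' @param genotype_only If `TRUE`, the phase of every heterozygous genotype
#'   is randomised (exercises the genotype/hard-stop pathway).
#' @return An object of class `carrier_cohort`: list with `panel`, `map`,
#'   `ids`, `hap1`/`hap2` (marker x subject 0/1/`NA` matrices),
#'   `carrier_hap` (1 or 2 per subject), and `truth` (genealogy, founder
#'   haplotype, per-branch breakpoints, per-carrier segment endpoints, seed,
#'   parameters).
#' @export
simulate_cohort <- function(genealogy, panel, map, seed = NULL,
                            background = c("independent", "markov"),
                            ld_rho = 0.9, phase_noise = 0, missing_rate = 0,
                            genotype_only = FALSE) {
  stopifnot(inherits(genealogy, "genealogy"),
            inherits(panel, "marker_panel"),
            inherits(map, "genetic_map"))
  background <- match.arg(background)
  if (any(panel$pos_bp < map$pos_bp[1] | panel$pos_bp > map$pos_bp[nrow(map)]))
    stop("panel/map mismatch: markers outside map span", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nm <- nrow(panel); n <- genealogy$n
  fi <- attr(panel, "focal_index")
  L <- attr(panel, "region_cm")
  rel_cm <- panel$cm - map$cm[1]
  focal_rel <- rel_cm[fi]

  draw_background <- function() {
    if (background == "independent") {
      stats::rbinom(nm, 1L, panel$freq)
    } else {
      x <- integer(nm)
      x[1] <- stats::rbinom(1L, 1L, panel$freq[1])
      keep <- stats::runif(nm) < ld_rho
      fresh <- stats::rbinom(nm, 1L, panel$freq)
      for (j in 2:nm) x[j] <- if (keep[j]) x[j - 1L] else fresh[j]
      x
    }
  }

  founder <- draw_background()
  founder[fi] <- 1L

  phy <- genealogy$tree
  root <- n + 1L
  edge_bks <- lapply(seq_len(nrow(phy$edge)), function(e) {
    recombination_breakpoints(phy$edge.length[e], L)
  })
  edge_key <- paste(phy$edge[, 1], phy$edge[, 2])

  segments_cm <- matrix(NA_real_, n, 2)
  leaf_bks <- vector("list", n)
  for (i in seq_len(n)) {
    tip <- match(genealogy$ids[i], phy$tip.label)
    nodes <- ape::nodepath(phy, from = root, to = tip)
    eidx <- match(paste(nodes[-length(nodes)], nodes[-1]), edge_key)
    bks <- sort(unlist(edge_bks[eidx]))
    leaf_bks[[i]] <- bks
    segments_cm[i, ] <- segment_around(focal_rel, bks, L)
  }

  hap1 <- matrix(NA_integer_, nm, n)
  hap2 <- matrix(NA_integer_, nm, n)
  carrier_hap <- integer(n)
  for (i in seq_len(n)) {
    inside <- rel_cm > segments_cm[i, 1] & rel_cm < segments_cm[i, 2]
    inside[fi] <- TRUE
    hc <- draw_background()
    hc[inside] <- founder[inside]
    hn <- draw_background()
    hn[fi] <- 0L
    carrier_hap[i] <- sample(1:2, 1L)
    if (carrier_hap[i] == 1L) { hap1[, i] <- hc; hap2[, i] <- hn }
    else                      { hap1[, i] <- hn; hap2[, i] <- hc }
  }

  if (phase_noise > 0) {
    for (i in seq_len(n)) {
      flip <- stats::runif(nm) < phase_noise
      flip[fi] <- FALSE
      tmp <- hap1[flip, i]; hap1[flip, i] <- hap2[flip, i]
      hap2[flip, i] <- tmp
    }
  }
  if (missing_rate > 0) {
    for (i in seq_len(n)) {
      miss <- stats::runif(nm) < missing_rate
      miss[fi] <- FALSE
      hap1[miss, i] <- NA_integer_; hap2[miss, i] <- NA_integer_
    }
  }
  if (genotype_only) {
    for (i in seq_len(n)) {
      het <- !is.na(hap1[, i]) & (hap1[, i] != hap2[, i])
      swap <- het & stats::runif(nm) < 0.5
      tmp <- hap1[swap, i]; hap1[swap, i] <- hap2[swap, i]
      hap2[swap, i] <- tmp
    }
    carrier_hap[] <- NA_integer_
  }

  segments_bp <- cbind(cm_to_bp(map, map$cm[1] + segments_cm[, 1]),
                       cm_to_bp(map, map$cm[1] + segments_cm[, 2]))
  dimnames(hap1) <- dimnames(hap2) <- list(panel$id, genealogy$ids)
  structure(list(
    panel = panel, map = map, ids = genealogy$ids,
    hap1 = hap1, hap2 = hap2, carrier_hap = carrier_hap,
    truth = list(genealogy = genealogy, founder = founder,
                 edge_breakpoints = edge_bks, leaf_breakpoints = leaf_bks,
                 segments_cm = segments_cm, segments_bp = segments_bp,
                 seed = seed,
                 params = list(background = background, ld_rho = ld_rho,
                               phase_noise = phase_noise,
                               missing_rate = missing_rate,
                               genotype_only = genotype_only))),
    class = "carrier_cohort")
}

#' Assemble a carrier cohort from explicit haplotypes
#'
#' Constructor for hand-built or file-read cohorts (no simulation truth).
#'
#' @param panel A [marker_panel()] (or data frame with the same columns and
#'   attributes).
#' @param map A [genetic_map()].
#' @param hap1,hap2 Marker x subject 0/1/`NA` integer matrices.
#' @param ids Subject identifiers.
#' @return A `carrier_cohort`.
#' @export
carrier_cohort <- function(panel, map, hap1, hap2, ids = colnames(hap1)) {
  stopifnot(nrow(hap1) == nrow(panel), all(dim(hap1) == dim(hap2)))
  fi <- attr(panel, "focal_index")
  carrier_hap <- ifelse(!is.na(hap1[fi, ]) & hap1[fi, ] == 1L, 1L,
                        ifelse(!is.na(hap2[fi, ]) & hap2[fi, ] == 1L,
                               2L, NA_integer_))
  structure(list(panel = panel, map = map, ids = ids,
                 hap1 = hap1, hap2 = hap2,
                 carrier_hap = as.integer(carrier_hap), truth = NULL),
            class = "carrier_cohort")
}

#' @export
print.carrier_cohort <- function(x, ...) {
  cat(sprintf(
    "Phased carrier cohort: %d subjects, %d markers, focal %s at %.0f bp\n",
    length(x$ids), nrow(x$panel), x$panel$id[attr(x$panel, "focal_index")],
    x$panel$pos_bp[attr(x$panel, "focal_index")]))
  if (!is.null(x$truth))
    cat(sprintf("  simulated (TMRCA %.4g generations, seed %s)\n",
                x$truth$genealogy$tmrca_generations,
                if (is.null(x$truth$seed)) "none" else x$truth$seed))
  invisible(x)
}

#' Write a cohort as a phased-haplotype TSV
#'
#' One row per marker: `marker`, `pos_bp`, `cm`, `freq`, then two allele
#' columns per subject (`<id>_1`, `<id>_2`). The focal marker is named
#' `FOCAL`.
#'
#' @param cohort A `carrier_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_tsv <- function(cohort, path) {
  h <- cbind(cohort$hap1, cohort$hap2)
  ord <- as.vector(rbind(seq_along(cohort$ids),
                         seq_along(cohort$ids) + length(cohort$ids)))
  h <- h[, ord, drop = FALSE]
  colnames(h) <- as.vector(rbind(paste0(cohort$ids, "_1"),
                                 paste0(cohort$ids, "_2")))
  out <- cbind(data.frame(marker = cohort$panel$id,
                          pos_bp = cohort$panel$pos_bp,
                          cm = cohort$panel$cm,
                          freq = cohort$panel$freq), h)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phased-haplotype TSV
#'
#' @param path File written by [write_phased_tsv()].
#' @param map The [genetic_map()] of the region.
#' @return A `carrier_cohort` (without simulation truth).
#' @export
read_phased_tsv <- function(path, map) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  hap_cols <- grep("_[12]$", names(tab))
  ids <- unique(sub("_[12]$", "", names(tab)[hap_cols]))
  hap1 <- as.matrix(tab[paste0(ids, "_1")])
  hap2 <- as.matrix(tab[paste0(ids, "_2")])
  storage.mode(hap1) <- storage.mode(hap2) <- "integer"
  dimnames(hap1) <- dimnames(hap2) <- list(tab$marker, ids)
  fi <- match("FOCAL", tab$marker)
  if (is.na(fi)) stop("no FOCAL marker in file", call. = FALSE)
  panel <- structure(
    data.frame(id = tab$marker, pos_bp = tab$pos_bp, cm = tab$cm,
               freq = tab$freq),
    focal_index = fi, region_cm = region_length_cm(map),
    focal_offset_cm = tab$cm[fi] - map$cm[1],
    class = c("marker_panel", "data.frame"))
  carrier_cohort(panel, map, hap1, hap2, ids)
}

#' Write a cohort as a VCF with phased genotypes
#'
#' Minimal VCF 4.2 with `GT` fields phased as `a|b` (`.|.` when missing).
#' Alleles are generic (`REF=A`, `ALT=G`); the focal variant's ID is
#' `FOCAL`.
#'
#' @param cohort A `carrier_cohort`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", cohort$map$chrom[1]),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", cohort$ids), collapse = "\t")), con)
  gt <- matrix("", nrow(cohort$panel), length(cohort$ids))
  for (i in seq_along(cohort$ids)) {
    a <- cohort$hap1[, i]; b <- cohort$hap2[, i]
    gt[, i] <- ifelse(is.na(a) | is.na(b), ".|.", paste0(a, "|", b))
  }
  body <- cbind(cohort$map$chrom[1], cohort$panel$pos_bp, cohort$panel$id,
                "A", "G", ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write the simulation truth as JSON
#'
#' Records the generating genealogy (Newick, branch lengths in generations),
#' per-carrier true ancestral-segment endpoints, the founder haplotype, the
#' seed and the simulation parameters.
#'
#' @param cohort A simulated `carrier_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(cohort, path) {
  if (is.null(cohort$truth)) stop("cohort carries no truth", call. = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(list(
    newick = ape::write.tree(tr$genealogy$tree),
    tmrca_generations = tr$genealogy$tmrca_generations,
    ids = cohort$ids,
    segments_bp = tr$segments_bp,
    segments_cm = tr$segments_cm,
    founder = tr$founder,
    seed = tr$seed,
    params = tr$params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
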