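#' Date a founder variant from a phased carrier cohort
#'
#' The central fitting function: runs the whole dating analysis on phased
#' haplotypes of unrelated carriers of a focal variant. Pairwise shared
#' haplotype extents around the variant are measured ([similarity_matrix()]),
#' converted to generations-to-MRCA through a Monte-Carlo decay table
#' ([decay_table()], [generation_matrix()]), doubled into meioses and
#' clustered by UPGMA ([upgma()]); the root height of the resulting
#' genealogy estimates the TMRCA of the sample. Independently, a
#' censored-exponential maximum-likelihood age estimate with confidence
#' interval is computed from per-carrier ancestral lengths against the
#' consensus haplotype ([estimate_age()]).
#'
#' @param cohort A `carrier_cohort` (from [simulate_cohort()],
#'   [read_phased_tsv()] or [carrier_cohort()]).
#' @param table Optional precomputed [decay_table()]; built from the cohort
#'   geometry when `NULL`.
#' @param statistic Decay-table statistic matched during inversion
#'   (`"mean"`, the default, or `"median"`).
#' @param mode Sharing mode, `"phased"` or `"genotype"` (hard stops only).
#' @param filter,K,M Spurious-double-recombinant filter settings, see
#'   [filter_spurious_switches()].
#' @param g_max,reps,seed Decay-table settings when `table` is `NULL`.
#' @param subjects Optional subset of subject ids (e.g. one per family,
#'   [select_family_representatives()]).
#' @param years_per_generation Value or range for the calendar conversion
#'   of the TMRCA (default 20-25).
#' @param age_genealogy Genealogy assumption passed to [estimate_age()]
#'   (default `"correlated"`: sampled carriers share ancestry more recent
#'   than the variant's origin).
#' @param age_years_per_generation Scalar years/generation for the
#'   closed-form age estimate (default 25).
#' @return An object of class `founder_dating` with components `similarity`,
#'   `decay_table`, `generations`, `tree`, `tmrca_generations`,
#'   `secondary_height`, `years`, `age` (the closed-form estimate),
#'   `lengths`, `n`, `n_pairs`, `params`.
#' @examples
#' \donttest{
#' gm <- default_region_map()
#' pan <- marker_panel(gm, n_markers = 400, seed = 7)
#' gen <- simulate_genealogy(6, tmrca = 30, shape = "star")
#' coh <- simulate_cohort(gen, pan, gm, seed = 8)
#' fit <- date_founder(coh, g_max = 120, reps = 1500, seed = 9)
#' fit
#' }
#' @export
date_founder <- function(cohort, table = NULL,
                         statistic = c("mean", "median"),
                         mode = c("phased", "genotype"),
                         filter = TRUE, K = 2L, M = 20L,
                         g_max = 500L, reps = 10000L, seed = NULL,
                         subjects = NULL,
                         years_per_generation = c(20, 25),
                         age_genealogy = c("correlated", "independent"),
                         age_years_per_generation = 25) {
  stopifnot(inherits(cohort, "carrier_cohort"))
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  age_genealogy <- match.arg(age_genealogy)
  if (!is.null(subjects)) cohort <- subset_cohort(cohort, subjects)

  ssm <- similarity_matrix(cohort, mode = mode, filter = filter, K = K, M = M)
  if (is.null(table)) {
    table <- decay_table(region_cm = ssm$region_cm,
                         focal_cm = attr(cohort$panel, "focal_offset_cm"),
                         g_max = g_max, reps = reps, seed = seed)
  }
  gm <- generation_matrix(ssm, table, statistic = statistic)
  tree <- upgma(gm$meioses, ids = ssm$ids)
  tm <- tmrca(tree)
  lens <- consensus_ancestral_haplotype(cohort, ssm = ssm)
  age <- estimate_age(lens, genealogy = age_genealogy, tree = tree,
                      years_per_generation = age_years_per_generation)

  off <- ssm$length_cm
  diag(off) <- NA
  mx <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  mn <- which(off == min(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  structure(list(
    similarity = ssm, decay_table = table, generations = gm, tree = tree,
    tmrca_generations = as.numeric(tm),
    secondary_height = attr(tm, "secondary_height"),
    years = generations_to_years(as.numeric(tm), years_per_generation),
    age = age, lengths = lens,
    n = length(ssm$ids), n_pairs = ssm$n_pairs,
    extremes = list(
      longest = list(pair = ssm$ids[mx], cm = max(off, na.rm = TRUE)),
      shortest = list(pair = ssm$ids[mn], cm = min(off, na.rm = TRUE))),
    params = list(statistic = statistic, mode = mode, filter = filter,
                  K = K, M = M, seed = table$seed, reps = table$reps,
                  g_max = max(table$g),
                  years_per_generation = years_per_generation,
                  age_genealogy = age_genealogy)),
    class = "founder_dating")
}

subset_cohort <- function(cohort, ids) {
  idx <- match(ids, cohort$ids)
  if (anyNA(idx)) stop("unknown subjects requested", call. = FALSE)
  cohort$hap1 <- cohort$hap1[, idx, drop = FALSE]
  cohort$hap2 <- cohort$hap2[, idx, drop = FALSE]
  cohort$carrier_hap <- cohort$carrier_hap[idx]
  cohort$ids <- cohort$ids[idx]
  cohort$truth <- NULL
  cohort
}

#' @export
print.founder_dating <- function(x, ...) {
  cat("Founder-variant dating\n")
  cat(sprintf("  %d carriers, %d pairs (%s mode, %s statistic)\n",
              x$n, x$n_pairs, x$params$mode, x$params$statistic))
  cat(sprintf("  shared length: %.2f cM (%s) .. %.2f cM (%s)\n",
              x$extremes$shortest$cm,
              paste(x$extremes$shortest$pair, collapse = "-"),
              x$extremes$longest$cm,
              paste(x$extremes$longest$pair, collapse = "-")))
  cat(sprintf("  TMRCA (UPGMA root): %.0f generations = %s years\n",
              x$tmrca_generations,
              paste(round(x$years), collapse = "-")))
  cat(sprintf("  deeper root child (bulk-of-sample ancestor): %.0f generations\n",
              x$secondary_height))
  cat(sprintf(
    "  closed-form age (%s genealogy): %.0f generations (%.0f%% CI %.0f-%.0f)\n",
    x$age$genealogy, x$age$generations, 100 * x$age$ci_level,
    x$age$ci_generations[1], x$age$ci_generations[2]))
  invisible(x)
}

#' @export
summary.founder_dating <- function(object, ...) {
  print(object)
  off <- object$generations$generations
  off <- off[upper.tri(off)]
  sat <- object$generations$flags[upper.tri(object$generations$flags)]
  cat(sprintf(
    "  pairwise generations: %.0f..%.0f (median %.0f); %d of %d pairs saturated\n",
    min(off), max(off), stats::median(off), sum(sat != "ok"), length(off)))
  cens <- object$lengths$lengths
  cat(sprintf("  ancestral sides censored at region edge: %d of %d\n",
              sum(cens$left_censored) + sum(cens$right_censored),
              2L * nrow(cens)))
  invisible(object)
}

#' @export
coef.founder_dating <- function(object, ...) {
  c(tmrca_generations = object$tmrca_generations,
    secondary_height = object$secondary_height,
    age_generations = object$age$generations)
}

#' @export
plot.founder_dating <- function(x, ...) {
  plot(x$tree, main = sprintf("Carrier genealogy (TMRCA %.0f generations)",
                              x$tmrca_generations), ...)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the similarity and generation matrices (TSV), the genealogy
#' (Newick), the decay table (JSON), the per-carrier ancestral lengths
#' (TSV) and a JSON run report (TMRCA, years, age estimate, parameters).
#'
#' @param fit A [date_founder()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir) {
  stopifnot(inherits(fit, "founder_dating"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_similarity_tsv(fit$similarity, file.path(dir, "similarity_cm.tsv"))
  utils::write.table(round(fit$generations$generations),
                     file.path(dir, "generations.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(round(fit$generations$meioses),
                     file.path(dir, "meioses.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  to_newick(fit$tree, file.path(dir, "genealogy.nwk"))
  write_decay_table(fit$decay_table, file.path(dir, "decay_table.json"))
  write_lengths_tsv(fit$lengths, file.path(dir, "ancestral_lengths.tsv"))
  jsonlite::write_json(list(
    n_carriers = fit$n, n_pairs = fit$n_pairs,
    tmrca_generations = fit$tmrca_generations,
    secondary_height_generations = fit$secondary_height,
    tmrca_years = fit$years,
    age_generations = fit$age$generations,
    age_ci_generations = fit$age$ci_generations,
    age_years = fit$age$years, age_ci_years = fit$age$ci_years,
    age_genealogy = fit$age$genealogy,
    shortest_pair = fit$extremes$shortest,
    longest_pair = fit$extremes$longest,
    params = fit$params), file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Cohort frequency summaries
#'
#' Frequencies of the focal variant among carrier probands and among all
#' screened probands, as raw percentages and rounded to typical reporting
#' precision (whole percent among carriers, two decimals among screened).
#'
#' @param variant_carrier_probands Probands carrying the focal variant.
#' @param carrier_probands_total All probands carrying any pathogenic
#'   variant in the gene (optional).
#' @param screened_total All screened probands (optional).
#' @return A list with `pct_of_carrier_probands`,
#'   `pct_of_carrier_probands_rounded`, `pct_of_screened`,
#'   `pct_of_screened_rounded`; undefined ratios (zero denominator) are
#'   `NA` with `undefined = TRUE`.
#' @examples
#' summarize_cohort(38, 364, 3803)
#' @export
summarize_cohort <- function(variant_carrier_probands,
                             carrier_probands_total = NULL,
                             screened_total = NULL) {
  stopifnot(variant_carrier_probands >= 0)
  pct <- function(num, den) {
    if (is.null(den)) return(NULL)
    if (den == 0) return(NA_real_)
    if (num > den) stop("numerator exceeds denominator", call. = FALSE)
    100 * num / den
  }
  p1 <- pct(variant_carrier_probands, carrier_probands_total)
  p2 <- pct(variant_carrier_probands, screened_total)
  list(pct_of_carrier_probands = p1,
       pct_of_carrier_probands_rounded = if (!is.null(p1)) round(p1),
       pct_of_screened = p2,
       pct_of_screened_rounded = if (!is.null(p2)) round(p2, 2),
       undefined = (!is.null(p1) && is.na(p1)) ||
         (!is.null(p2) && is.na(p2)))
}
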