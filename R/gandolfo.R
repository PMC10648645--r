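#' Consensus ancestral haplotype and per-carrier ancestral lengths
#'
#' The consensus (putative founder) haplotype is the per-marker majority
#' allele among the carrier haplotypes. For each carrier and each side of
#' the focal variant, the ancestral length is the genetic distance from the
#' focal variant to the last marker concordant with the consensus before the
#' first discordance (missing alleles are non-informative); a side whose
#' concordance reaches the panel edge is censored, and then carries the
#' distance to the edge. A majority tie at a marker is resolved toward the
#' allele carried by the longest-sharing pair's haplotype and recorded.
#'
#' @param cohort A `carrier_cohort` with at least 3 carriers.
#' @param ssm Optional precomputed [similarity_matrix()] (only consulted to
#'   break majority ties; computed on demand otherwise).
#' @return An object of class `carrier_lengths`: list with `consensus`
#'   (0/1 vector over markers), `lengths` (data frame: `id`, `left_cm`,
#'   `right_cm`, `left_censored`, `right_censored`), `ties` (marker indices
#'   where the majority was tied).
#' @export
consensus_ancestral_haplotype <- function(cohort, ssm = NULL) {
  n <- length(cohort$ids)
  if (n < 3L) stop("need at least 3 carriers", call. = FALSE)
  H <- carrier_allele_matrix(cohort)
  ones <- rowSums(H == 1L, na.rm = TRUE)
  zeros <- rowSums(H == 0L, na.rm = TRUE)
  consensus <- as.integer(ones > zeros)
  ties <- which(ones == zeros)
  if (length(ties)) {
    if (is.null(ssm)) ssm <- similarity_matrix(cohort)
    len <- ssm$length_cm; diag(len) <- -Inf
    top <- which(len == max(len), arr.ind = TRUE)[1, ]
    ref <- H[, top[1]]                 # haplotype of the longest-sharing pair
    consensus[ties] <- ifelse(is.na(ref[ties]), 0L, ref[ties])
  }
  fi <- attr(cohort$panel, "focal_index")
  nm <- nrow(cohort$panel)
  cmv <- cohort$panel$cm
  out <- data.frame(id = cohort$ids, left_cm = NA_real_, right_cm = NA_real_,
                    left_censored = FALSE, right_censored = FALSE)
  for (i in seq_len(n)) {
    dis <- H[, i] != consensus
    dis[is.na(dis)] <- FALSE
    lm <- which(dis[seq_len(fi - 1L)])
    rm_ <- which(dis[(fi + 1L):nm]) + fi
    li <- if (length(lm)) max(lm) + 1L else 1L
    ri <- if (length(rm_)) min(rm_) - 1L else nm
    out$left_cm[i] <- cmv[fi] - cmv[li]
    out$right_cm[i] <- cmv[ri] - cmv[fi]
    out$left_censored[i] <- li == 1L
    out$right_censored[i] <- ri == nm
  }
  structure(list(consensus = consensus, lengths = out, ties = ties),
            class = "carrier_lengths")
}

#' Assemble per-carrier ancestral lengths directly
#'
#' Constructor for hand-specified or file-read side lengths (the format the
#' age estimator consumes).
#'
#' @param left_cm,right_cm Ancestral lengths (cM) on each side of the focal
#'   variant, `>= 0`.
#' @param left_censored,right_censored Logical: does the side reach the
#'   region edge (so its true extent is only bounded below)?
#' @param id Carrier identifiers.
#' @return A `carrier_lengths` object (without consensus).
#' @export
carrier_lengths <- function(left_cm, right_cm,
                            left_censored = FALSE, right_censored = FALSE,
                            id = sprintf("C%02d", seq_along(left_cm))) {
  stopifnot(length(left_cm) == length(right_cm),
            all(left_cm >= 0), all(right_cm >= 0))
  out <- data.frame(id = id, left_cm = left_cm, right_cm = right_cm,
                    left_censored = rep_len(left_censored, length(left_cm)),
                    right_censored = rep_len(right_censored, length(left_cm)))
  structure(list(consensus = NULL, lengths = out, ties = integer()),
            class = "carrier_lengths")
}

#' @export
print.carrier_lengths <- function(x, ...) {
  l <- x$lengths
  cat(sprintf(
    "Ancestral lengths: %d carriers, %d/%d sides uncensored, mean side %.3f cM\n",
    nrow(l), sum(!l$left_censored) + sum(!l$right_censored), 2L * nrow(l),
    mean(c(l$left_cm, l$right_cm))))
  invisible(x)
}

#' Censored-exponential mutation-age estimate
#'
#' Models each side of each carrier's ancestral haplotype as the distance
#' to the first recombination since the variant arose: for a variant `g`
#' generations old, an exponential length with rate `g` per Morgan. Sides
#' censored at the region edge contribute survival terms, so the
#' log-likelihood is `m log(g) - g * S` with `m` the number of uncensored
#' sides and `S` the sum of all side lengths (Morgans); the maximum
#' likelihood estimate is `g_hat = m / S`. The confidence interval comes
#' from the exact Gamma sampling distribution of `S` (`g * S ~ Gamma(m, 1)`
#' when censoring is light).
#'
#' Under the `"correlated"` genealogy assumption the sampled carriers share
#' ancestry more recent than the variant's origin, so their lengths are
#' positively correlated and the nominal `m` overstates the information.
#' The point estimate is unchanged but the Gamma shape is deflated to an
#' effective number of sides `m_eff = m / (1 + (k - 1) * rho_bar)`, where
#' `k` is the number of carriers and `rho_bar` the mean pairwise
#' shared-lineage fraction `(tmrca - t_ij) / tmrca` read from a genealogy
#' (the clustered tree in the full pipeline), widening the interval.
#'
#' @param lengths A [carrier_lengths()] / [consensus_ancestral_haplotype()]
#'   object.
#' @param genealogy `"independent"` (lengths treated as independent) or
#'   `"correlated"`.
#' @param tree For `"correlated"`: an [upgma()] tree or a
#'   [simulate_genealogy()] object over the same carriers, used to read the
#'   pairwise coalescent times. Without one, `rho_bar` falls back to 0.5
#'   (half the lineage shared on average), a deliberately conservative
#'   default.
#' @param ci_level Confidence level (default 0.95).
#' @param years_per_generation Scalar for the years conversion (default 25).
#' @return An object of class `age_estimate`: list with `generations`,
#'   `ci_generations`, `years`, `ci_years`, `genealogy`, `m_sides`,
#'   `m_effective`, `sum_morgans`, `years_per_generation`.
#' @examples
#' est <- estimate_age(carrier_lengths(1, 1))  # 0.01 + 0.01 Morgans
#' est$generations                             # 100
#' @export
estimate_age <- function(lengths, genealogy = c("independent", "correlated"),
                         tree = NULL, ci_level = 0.95,
                         years_per_generation = 25) {
  stopifnot(inherits(lengths, "carrier_lengths"))
  genealogy <- match.arg(genealogy)
  l <- lengths$lengths
  side_m <- c(l$left_cm, l$right_cm) / 100          # Morgans
  cens <- c(l$left_censored, l$right_censored)
  m <- sum(!cens)
  if (m < 1L)
    stop("non-identifiable: all sides censored at the region edge",
         call. = FALSE)
  S <- sum(side_m)
  g_hat <- m / S
  m_eff <- m
  if (genealogy == "correlated") {
    rho_bar <- correlation_from_tree(tree, l$id)
    k <- nrow(l)
    m_eff <- m / (1 + (k - 1) * rho_bar)
  }
  alpha <- (1 - ci_level) / 2
  scale <- g_hat / m_eff                       # keeps the point estimate fixed
  ci <- c(stats::qgamma(alpha, m_eff) * scale,
          stats::qgamma(1 - alpha, m_eff) * scale)
  structure(list(generations = g_hat, ci_generations = ci,
                 years = g_hat * years_per_generation,
                 ci_years = ci * years_per_generation,
                 genealogy = genealogy, ci_level = ci_level,
                 m_sides = m, m_effective = m_eff, sum_morgans = S,
                 years_per_generation = years_per_generation),
            class = "age_estimate")
}

# mean pairwise shared-lineage fraction from a genealogy or UPGMA tree
correlation_from_tree <- function(tree, ids) {
  if (is.null(tree)) return(0.5)
  tij <- if (inherits(tree, "upgma_tree")) {
    cophenetic_generations(tree)
  } else if (inherits(tree, "genealogy")) {
    pairwise_generations(tree)
  } else stop("tree must be an upgma_tree or genealogy", call. = FALSE)
  g0 <- max(tij)
  if (g0 <= 0) return(0)
  rho <- (g0 - tij) / g0
  mean(rho[upper.tri(rho)])
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf(
    "Variant age (%s genealogy): %.1f generations (%.0f%% CI %.1f-%.1f)\n",
    x$genealogy, x$generations, 100 * x$ci_level,
    x$ci_generations[1], x$ci_generations[2]))
  cat(sprintf("  = %.0f years (CI %.0f-%.0f) at %g years/generation\n",
              x$years, x$ci_years[1], x$ci_years[2],
              x$years_per_generation))
  cat(sprintf("  %d uncensored sides (effective %.1f), sum %.4f Morgans\n",
              x$m_sides, x$m_effective, x$sum_morgans))
  invisible(x)
}

#' Write / read carrier ancestral lengths as TSV
#'
#' Columns: `id`, `left_cm`, `right_cm`, `left_censored`, `right_censored`.
#'
#' @param lengths A `carrier_lengths` object.
#' @param path File path.
#' @return `path` (write) or a `carrier_lengths` (read).
#' @export
write_lengths_tsv <- function(lengths, path) {
  utils::write.table(lengths$lengths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lengths_tsv
#' @export
read_lengths_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  carrier_lengths(tab$left_cm, tab$right_cm, tab$left_censored,
                  tab$right_censored, id = tab$id)
}
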