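#' Identify a subject's carrier haplotype
#'
#' Of a heterozygous carrier's two phased haplotypes, the carrier haplotype
#' is the one bearing the alternative allele at the focal variant.
#'
#' @param cohort A `carrier_cohort`.
#' @param subject Subject id or column index.
#' @return 1 or 2.
#' @export
carrier_haplotype <- function(cohort, subject) {
  i <- if (is.character(subject)) match(subject, cohort$ids) else subject
  if (is.na(i)) stop("unknown subject", call. = FALSE)
  fi <- attr(cohort$panel, "focal_index")
  a <- cohort$hap1[fi, i]; b <- cohort$hap2[fi, i]
  if (is.na(a) || is.na(b))
    stop("not a carrier: focal genotype missing", call. = FALSE)
  if (a == 1L && b == 1L)
    stop("homozygous-alt at focal variant: unsupported, exclude subject",
         call. = FALSE)
  if (a == 0L && b == 0L)
    stop("not a carrier: homozygous reference at focal variant",
         call. = FALSE)
  if (a == 1L) 1L else 2L
}

#' Remove spurious double recombinants from a mismatch mask
#'
#' Statistical phasing occasionally emits a short phase switch that, taken
#' literally, truncates a shared haplotype (a "spurious double
#' recombinant"). Any run of at most `K` consecutive mismatching markers
#' flanked on both sides by at least `M` matching markers is treated as a
#' phasing/typing artifact and reset to matching. Runs touching the region
#' edge are never reset. Removing these soft breaks lengthens segments and
#' so gives a more conservative (older-bounded-below) picture of sharing.
#'
#' @param mismatch Logical vector over panel markers (`TRUE` = mismatch).
#' @param K Maximum artifact run length (default 2: an isolated double
#'   recombinant).
#' @param M Minimum flanking match run (default 20 markers).
#' @return Cleaned logical vector.
#' @export
filter_spurious_switches <- function(mismatch, K = 2L, M = 20L) {
  r <- rle(mismatch)
  k <- length(r$lengths)
  if (k < 3L) return(mismatch)
  drop <- logical(k)
  for (t in 2:(k - 1L)) {
    if (r$values[t] && r$lengths[t] <= K &&
        !r$values[t - 1L] && r$lengths[t - 1L] >= M &&
        !r$values[t + 1L] && r$lengths[t + 1L] >= M)
      drop[t] <- TRUE
  }
  r$values[drop] <- FALSE
  inverse.rle(r)
}

# carrier-haplotype allele matrix (markers x subjects)
carrier_allele_matrix <- function(cohort) {
  n <- length(cohort$ids)
  H <- matrix(NA_integer_, nrow(cohort$panel), n,
              dimnames = list(cohort$panel$id, cohort$ids))
  for (i in seq_len(n)) {
    ci <- carrier_haplotype(cohort, i)
    H[, i] <- if (ci == 1L) cohort$hap1[, i] else cohort$hap2[, i]
  }
  H
}

# pairwise mismatch mask for one pair under a comparison mode
pair_mismatch <- function(cohort, i, j, mode) {
  if (mode == "phased") {
    ci <- carrier_haplotype(cohort, i); cj <- carrier_haplotype(cohort, j)
    x <- if (ci == 1L) cohort$hap1[, i] else cohort$hap2[, i]
    y <- if (cj == 1L) cohort$hap1[, j] else cohort$hap2[, j]
    m <- x != y
    m[is.na(m)] <- FALSE          # missing is non-informative
  } else {
    gi <- cohort$hap1[, i] + cohort$hap2[, i]
    gj <- cohort$hap1[, j] + cohort$hap2[, j]
    m <- (gi == 0L & gj == 2L) | (gi == 2L & gj == 0L)  # opposite homozygotes
    m[is.na(m)] <- FALSE
  }
  m
}

#' Shared haplotype extent around the focal variant for one pair
#'
#' Scans outward from the focal variant on each side and stops before the
#' first marker where sharing is broken: in `"phased"` mode, the first
#' marker where the two carrier haplotypes differ (missing genotypes are
#' non-informative and never break a segment); in `"genotype"` mode, only
#' markers where the two subjects are homozygous for alternative alleles —
#' "hard stops", across which no shared haplotype can extend regardless of
#' phase. The segment is reported by its last compatible markers on each
#' side (a closed interval containing the focal variant); reaching the
#' panel edge is recorded as censoring.
#'
#' @param cohort A `carrier_cohort`.
#' @param a,b Subject ids or indices (both carriers, same panel).
#' @param mode `"phased"` or `"genotype"`.
#' @param filter Apply [filter_spurious_switches()] to the mismatch mask?
#' @param K,M Filter parameters.
#' @return An object of class `shared_segment`: list with `a`, `b`,
#'   `left_idx`, `right_idx` (marker indices), `left_bp`, `right_bp`,
#'   `length_cm`, `break_left`, `break_right` (one of
#'   `"haplotype-mismatch"`, `"hard-stop"`, `"region-edge"`).
#' @export
shared_extent <- function(cohort, a, b, mode = c("phased", "genotype"),
                          filter = TRUE, K = 2L, M = 20L) {
  mode <- match.arg(mode)
  i <- if (is.character(a)) match(a, cohort$ids) else a
  j <- if (is.character(b)) match(b, cohort$ids) else b
  if (is.na(i) || is.na(j)) stop("unknown subject", call. = FALSE)
  m <- pair_mismatch(cohort, i, j, mode)
  if (filter) m <- filter_spurious_switches(m, K, M)
  segment_from_mismatch(cohort, i, j, m, mode)
}

segment_from_mismatch <- function(cohort, i, j, m, mode) {
  fi <- attr(cohort$panel, "focal_index")
  nm <- length(m)
  reason <- if (mode == "phased") "haplotype-mismatch" else "hard-stop"
  left_mis <- which(m[seq_len(fi - 1L)])
  right_mis <- which(m[(fi + 1L):nm]) + fi
  left_idx <- if (length(left_mis)) max(left_mis) + 1L else 1L
  right_idx <- if (length(right_mis)) min(right_mis) - 1L else nm
  structure(list(
    a = cohort$ids[i], b = cohort$ids[j],
    left_idx = left_idx, right_idx = right_idx,
    left_bp = cohort$panel$pos_bp[left_idx],
    right_bp = cohort$panel$pos_bp[right_idx],
    length_cm = cohort$panel$cm[right_idx] - cohort$panel$cm[left_idx],
    break_left = if (left_idx == 1L) "region-edge" else reason,
    break_right = if (right_idx == nm) "region-edge" else reason),
    class = "shared_segment")
}

#' @export
print.shared_segment <- function(x, ...) {
  cat(sprintf("%s-%s: %.2f cM [%.0f..%.0f bp] (%s | %s)\n", x$a, x$b,
              x$length_cm, x$left_bp, x$right_bp, x$break_left,
              x$break_right))
  invisible(x)
}

#' Pairwise shared-segment (similarity) matrix
#'
#' Evaluates [shared_extent()] for every pair of carriers and assembles the
#' symmetric similarity matrix of shared lengths in cM, with companion
#' matrices of segment endpoints (bp) and per-side break reasons. The
#' diagonal is whole-region self-sharing and is excluded from dating.
#'
#' @inheritParams shared_extent
#' @param subjects Optional subset of subject ids to analyse (e.g. one
#'   representative per family, see [select_family_representatives()]).
#' @return An object of class `shared_segment_matrix`: list with `length_cm`,
#'   `left_bp`, `right_bp` (n x n matrices), `break_left`, `break_right`
#'   (character matrices), `ids`, `mode`, `region_cm`, `n_pairs`.
#' @export
similarity_matrix <- function(cohort, mode = c("phased", "genotype"),
                              filter = TRUE, K = 2L, M = 20L,
                              subjects = NULL) {
  mode <- match.arg(mode)
  ids <- if (is.null(subjects)) cohort$ids else subjects
  idx <- match(ids, cohort$ids)
  if (anyNA(idx)) stop("unknown subjects requested", call. = FALSE)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 carriers", call. = FALSE)
  L <- attr(cohort$panel, "region_cm")
  nm <- nrow(cohort$panel)
  len <- matrix(L, n, n, dimnames = list(ids, ids))
  lbp <- matrix(cohort$panel$pos_bp[1L], n, n, dimnames = list(ids, ids))
  rbp <- matrix(cohort$panel$pos_bp[nm], n, n, dimnames = list(ids, ids))
  brl <- matrix("region-edge", n, n, dimnames = list(ids, ids))
  brr <- matrix("region-edge", n, n, dimnames = list(ids, ids))
  for (p in seq_len(n - 1L)) for (q in (p + 1L):n) {
    s <- tryCatch(
      shared_extent(cohort, idx[p], idx[q], mode, filter, K, M),
      error = function(e)
        stop(sprintf("pair %s-%s: %s", ids[p], ids[q], conditionMessage(e)),
             call. = FALSE))
    len[p, q] <- len[q, p] <- s$length_cm
    lbp[p, q] <- lbp[q, p] <- s$left_bp
    rbp[p, q] <- rbp[q, p] <- s$right_bp
    brl[p, q] <- brl[q, p] <- s$break_left
    brr[p, q] <- brr[q, p] <- s$break_right
  }
  structure(list(length_cm = len, left_bp = lbp, right_bp = rbp,
                 break_left = brl, break_right = brr, ids = ids,
                 mode = mode, region_cm = L, n_pairs = n * (n - 1L) / 2L),
            class = "shared_segment_matrix")
}

#' @export
print.shared_segment_matrix <- function(x, ...) {
  off <- x$length_cm[upper.tri(x$length_cm)]
  cat(sprintf(
    "Shared-segment matrix: %d carriers, %d pairs (%s mode)\n",
    length(x$ids), x$n_pairs, x$mode))
  cat(sprintf("  shared length %.2f..%.2f cM (median %.2f) of %.2f cM region\n",
              min(off), max(off), stats::median(off), x$region_cm))
  invisible(x)
}

#' Pick one analysed subject per family
#'
#' Carriers from the same family share recent ancestry trivially; only one
#' subject per family (by convention its most remote carrier progenitor)
#' should enter the pairwise matrix.
#'
#' @param metadata Data frame with at least subject and family id columns.
#' @param id_col,family_col Column names.
#' @param representative_col Optional logical/0-1 column flagging the chosen
#'   subject of each family; when absent the first listed subject of each
#'   family is taken.
#' @return Character vector of selected subject ids.
#' @export
select_family_representatives <- function(metadata, id_col = "subject_id",
                                          family_col = "family_id",
                                          representative_col = NULL) {
  stopifnot(id_col %in% names(metadata), family_col %in% names(metadata))
  if (!is.null(representative_col)) {
    flagged <- metadata[as.logical(metadata[[representative_col]]), ]
    if (anyDuplicated(flagged[[family_col]]))
      stop("more than one representative flagged in a family", call. = FALSE)
    return(as.character(flagged[[id_col]]))
  }
  as.character(metadata[[id_col]][!duplicated(metadata[[family_col]])])
}

#' Write a similarity matrix and its break-reason report
#'
#' @param ssm A [similarity_matrix()] result.
#' @param path Output TSV path for the cM length matrix; endpoint and
#'   break-reason tables are written alongside with suffixes
#'   `.endpoints.tsv`.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(ssm, path) {
  utils::write.table(round(ssm$length_cm, 4), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  n <- length(ssm$ids)
  up <- which(upper.tri(ssm$length_cm), arr.ind = TRUE)
  rep <- data.frame(a = ssm$ids[up[, 1]], b = ssm$ids[up[, 2]],
                    left_bp = ssm$left_bp[up], right_bp = ssm$right_bp[up],
                    length_cm = round(ssm$length_cm[up], 4),
                    break_left = ssm$break_left[up],
                    break_right = ssm$break_right[up])
  utils::write.table(rep, paste0(path, ".endpoints.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
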