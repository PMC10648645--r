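#' Monte-Carlo decay table: shared length as a function of generations
#'
#' For each candidate number of generations `g` to a pair's common ancestor,
#' simulates the recombination decay of the founder segment along the two
#' lineages joining the pair (2`g` meioses in total, crossovers Poisson at
#' 1 per Morgan per meiosis). The retained shared segment around the focal
#' variant then has, on each side, an exponential extent with mean
#' `100/(2g)` cM, truncated at the region edges; the table records the mean
#' and median of the total simulated length per `g`. Isotonic smoothing
#' enforces strict monotonicity so the table is invertible.
#'
#' In `"marker"` mode the detection process itself is simulated: lengths
#' are measured as a marker scan would report them on a finite panel, where
#' chance identity-by-state beyond the true segment extends the detected
#' extent (requires `panel`).
#'
#' @param region_cm Genetic length of the region (cM).
#' @param focal_cm Genetic offset of the focal variant from the left region
#'   edge (cM), strictly inside the region.
#' @param g_max Largest tabulated generation count (grid `1..g_max`).
#' @param reps Monte-Carlo replicates per grid point (`>= 1000` advised).
#' @param seed Optional integer seed.
#' @param g Optional explicit integer grid (overrides `1..g_max`).
#' @param mode `"segment"` (true intersected segment; default) or
#'   `"marker"` (detected extent on a panel).
#' @param panel A [marker_panel()] (marker mode only).
#' @return An object of class `decay_table`: list with `g`, `mean_cm`,
#'   `median_cm` (smoothed, strictly decreasing), `mean_raw`, `median_raw`,
#'   `se_mean`, `reps`, `seed`, `region_cm`, `focal_cm`, `mode`.
#' @examples
#' tab <- decay_table(24.6, 10, g_max = 50, reps = 2000, seed = 1)
#' invert_length(tab, 2.0)
#' @export
decay_table <- function(region_cm, focal_cm, g_max = 500L, reps = 10000L,
                        seed = NULL, g = NULL,
                        mode = c("segment", "marker"), panel = NULL) {
  mode <- match.arg(mode)
  if (focal_cm <= 0 || focal_cm >= region_cm)
    stop("focal offset must be strictly inside the region", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (is.null(g)) g <- seq_len(g_max)
  g <- sort(unique(as.integer(g)))
  if (!is.null(seed)) set.seed(seed)
  a <- focal_cm; b <- region_cm - focal_cm
  k <- length(g)
  mean_raw <- median_raw <- se_mean <- numeric(k)
  for (t in seq_len(k)) {
    lam <- 2 * g[t] / 100          # per-cM breakpoint rate over both lineages
    if (mode == "segment") {
      L <- pmin(stats::rexp(reps, lam), a) + pmin(stats::rexp(reps, lam), b)
    } else {
      L <- sim_detected_lengths(reps, lam, panel)
    }
    mean_raw[t] <- mean(L)
    median_raw[t] <- stats::median(L)
    se_mean[t] <- stats::sd(L) / sqrt(reps)
  }
  structure(list(g = g,
                 mean_cm = monotone_decreasing(g, mean_raw),
                 median_cm = monotone_decreasing(g, median_raw),
                 mean_raw = mean_raw, median_raw = median_raw,
                 se_mean = se_mean, reps = reps, seed = seed,
                 region_cm = region_cm, focal_cm = focal_cm, mode = mode),
            class = "decay_table")
}

# detected (marker-scan) lengths for one g: true segment + identity-by-state
# run-out on the finite panel
sim_detected_lengths <- function(reps, lam, panel) {
  if (is.null(panel)) stop("marker mode requires a panel", call. = FALSE)
  fi <- attr(panel, "focal_index")
  # relative marker positions, aligned so the focal marker sits at its offset
  rel <- panel$cm - panel$cm[fi] + attr(panel, "focal_offset_cm")
  q <- panel$freq^2 + (1 - panel$freq)^2   # IBS match probability
  nm <- length(rel)
  region_cm <- attr(panel, "region_cm"); a <- attr(panel, "focal_offset_cm")
  vapply(seq_len(reps), function(r) {
    lcm <- a - min(stats::rexp(1, lam), a)
    rcm <- a + min(stats::rexp(1, lam), region_cm - a)
    li <- fi; while (li > 1L && rel[li - 1L] > lcm) li <- li - 1L
    ri <- fi; while (ri < nm && rel[ri + 1L] < rcm) ri <- ri + 1L
    while (li > 1L && stats::runif(1) < q[li - 1L]) li <- li - 1L
    while (ri < nm && stats::runif(1) < q[ri + 1L]) ri <- ri + 1L
    rel[ri] - rel[li]
  }, numeric(1))
}

# strictly decreasing isotonic fit (pool-adjacent-violators on the negated
# series plus an epsilon stagger so interpolation is invertible)
monotone_decreasing <- function(g, x) {
  y <- -stats::isoreg(g, -x)$yf
  y - (seq_along(y) - 1) * 1e-9
}

#' @export
print.decay_table <- function(x, ...) {
  cat(sprintf(
    "Decay table (%s mode): g = %d..%d, %d reps, region %.2f cM (focal at %.2f)\n",
    x$mode, min(x$g), max(x$g), x$reps, x$region_cm, x$focal_cm))
  cat(sprintf("  mean length %.3f cM at g=%d .. %.3f cM at g=%d\n",
              x$mean_cm[1], x$g[1], x$mean_cm[length(x$g)],
              x$g[length(x$g)]))
  invisible(x)
}

#' Invert a decay table: observed shared length to generations
#'
#' Finds the generation count whose tabulated statistic matches an observed
#' shared length, by piecewise-linear interpolation on the monotone table.
#' Lengths at or beyond the table boundaries saturate: an observed length
#' `>=` the statistic at the smallest tabulated `g` returns that `g`
#' (flag `"saturated_long"`), one `<=` the statistic at `g_max` returns
#' `g_max` (flag `"saturated_short"`). Boundary pairs are real in the data
#' (near-whole-region sharing; very short segments), so saturation is a
#' flag, not an error.
#'
#' @param table A [decay_table()].
#' @param observed_cm Observed shared length(s), cM, `>= 0`.
#' @param statistic `"mean"` or `"median"`.
#' @return Numeric vector of generations (real-valued) with attribute
#'   `flag` (`"ok"`, `"saturated_long"`, `"saturated_short"`).
#' @export
invert_length <- function(table, observed_cm, statistic = c("mean", "median")) {
  stopifnot(inherits(table, "decay_table"))
  statistic <- match.arg(statistic)
  if (any(observed_cm < 0)) stop("observed_cm must be >= 0", call. = FALSE)
  tab <- if (statistic == "mean") table$mean_cm else table$median_cm
  g <- table$g
  k <- length(g)
  flag <- rep("ok", length(observed_cm))
  flag[observed_cm >= tab[1]] <- "saturated_long"
  flag[observed_cm <= tab[k]] <- "saturated_short"
  est <- stats::approx(x = rev(tab), y = rev(g), xout = observed_cm,
                       method = "linear", rule = 2, ties = "ordered")$y
  est[flag == "saturated_long"] <- g[1]
  est[flag == "saturated_short"] <- g[k]
  structure(est, flag = flag)
}

#' Convert a similarity matrix into generation and meiosis matrices
#'
#' Applies [invert_length()] entrywise to the off-diagonal shared lengths
#' and doubles the result into the number of meioses separating each pair
#' (the path between two descendants of an ancestor `g` generations back
#' traverses `2g` meioses).
#'
#' @param ssm A [similarity_matrix()] result.
#' @param table A [decay_table()] whose region geometry matches the data.
#' @param statistic `"mean"` or `"median"`.
#' @return An object of class `generation_matrix`: list with `generations`
#'   and `meioses` (symmetric matrices, zero diagonal; `meioses` is exactly
#'   twice `generations`), `flags`, `statistic`, `table_meta`.
#' @export
generation_matrix <- function(ssm, table, statistic = c("mean", "median")) {
  stopifnot(inherits(ssm, "shared_segment_matrix"),
            inherits(table, "decay_table"))
  statistic <- match.arg(statistic)
  if (abs(table$region_cm - ssm$region_cm) > 1e-6)
    stop("geometry mismatch: decay table simulated for a different region",
         call. = FALSE)
  n <- length(ssm$ids)
  G <- matrix(0, n, n, dimnames = list(ssm$ids, ssm$ids))
  FL <- matrix("ok", n, n, dimnames = list(ssm$ids, ssm$ids))
  up <- upper.tri(G)
  est <- invert_length(table, ssm$length_cm[up], statistic)
  G[up] <- est
  FL[up] <- attr(est, "flag")
  G <- G + t(G)
  FL[lower.tri(FL)] <- t(FL)[lower.tri(FL)]
  structure(list(generations = G, meioses = 2 * G, flags = FL,
                 statistic = statistic,
                 table_meta = list(reps = table$reps, seed = table$seed,
                                   g_max = max(table$g), mode = table$mode)),
            class = "generation_matrix")
}

#' @export
print.generation_matrix <- function(x, ...) {
  off <- x$generations[upper.tri(x$generations)]
  n_sat <- sum(x$flags[upper.tri(x$flags)] != "ok")
  cat(sprintf(
    "Generation matrix: %d carriers, pairwise %.0f..%.0f generations (median %.0f), %d saturated pairs (%s statistic)\n",
    ncol(x$generations), min(off), max(off), stats::median(off), n_sat,
    x$statistic))
  invisible(x)
}

#' Serialize / restore a decay table as JSON
#'
#' @param table A [decay_table()].
#' @param path File path.
#' @return `path` (write) or the restored `decay_table` (read).
#' @export
write_decay_table <- function(table, path) {
  stopifnot(inherits(table, "decay_table"))
  jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_decay_table
#' @export
read_decay_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$g <- as.integer(x$g)
  structure(x, class = "decay_table")
}
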