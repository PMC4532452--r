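## End-to-end single-cell Hi-C reconstruction: contact map -> optimized
## structure -> rescaling -> reconstructed contact map -> evaluation metrics
## -> q selection -> multi-restart ensembles.

#' Rescale a structure to reproduce the observed contact count
#'
#' Finds the global scale factor `c_l` such that the scaled structure
#' `c_l * X` has exactly `n_c` bead pairs closer than the contact distance
#' `d_c`, where `n_c` is the contact count of the original map. The count of
#' close pairs is monotone non-increasing in `c_l`, so the factor is found by
#' bisection; among the interval of valid factors the smallest is returned
#' (to relative tolerance 1e-9).
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param cmap The original [contact_map()] (or an integer contact count).
#' @param d_c Contact distance in nm (default 60).
#' @return List with `coords` (scaled) and `c_l` (scale factor).
#' @export
rescale_structure <- function(coords, cmap, d_c = 60) {
  coords <- as_coords(coords)
  n_c <- if (inherits(cmap, "contact_map")) n_contacts(cmap) else as.integer(cmap)
  n <- nrow(coords)
  npairs <- n * (n - 1) / 2
  if (n_c < 1) stop("rescale_structure requires n_c >= 1")
  if (n_c > npairs)
    stop(sprintf("impossible target: n_c = %d exceeds %d bead pairs", n_c, npairs))
  dd <- upper_vec(pairdist(coords))
  nzero <- sum(dd == 0)
  if (nzero > n_c)
    stop("more coincident bead pairs than target contacts; cannot rescale")
  count_at <- function(cl) sum(cl * dd < d_c)
  lo <- 0.5 * d_c / max(dd)              # all pairs within d_c
  hi <- 2 * d_c / min(dd[dd > 0])        # only coincident pairs within d_c
  if (count_at(lo) < n_c) stop("bisection bracket failure (lower)")
  if (count_at(hi) > n_c) stop("bisection bracket failure (upper)")
  if (count_at(lo) == n_c) {
    cl <- lo      # valid down to arbitrarily small factors; return the bracket edge
  } else {
    ## invariant: count(lo) > n_c >= count(hi); converge to the lower edge of
    ## the c_l interval giving exactly n_c
    while ((hi - lo) > 1e-9 * hi) {
      mid <- (lo + hi) / 2
      if (count_at(mid) > n_c) lo <- mid else hi <- mid
    }
    cl <- hi
  }
  achieved <- count_at(cl)
  if (achieved != n_c) {
    ## a group of exactly tied distances straddles the contact threshold, so
    ## the count jumps past n_c; return the nearer side (preferring more
    ## contacts on a tie) rather than failing the whole pipeline
    cand <- c(lo, hi)
    counts <- vapply(cand, count_at, numeric(1))
    pick <- which.min(abs(counts - n_c))
    cl <- cand[pick]
    achieved <- counts[pick]
    warning(sprintf(
      "tied distances prevent an exact contact-count match: %d of n_c = %d",
      achieved, n_c))
  }
  list(coords = coords * cl, c_l = cl)
}

#' Contact map implied by a structure
#'
#' `C_ij = 1` iff `||x_i - x_j|| < d_c` for `i != j`.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param d_c Contact distance in nm (default 60).
#' @param bin_size,chrom Optional genomic metadata to attach.
#' @return A [contact_map()].
#' @export
contacts_from_structure <- function(coords, d_c = 60, bin_size = NA_real_,
                                    chrom = NA_character_) {
  coords <- as_coords(coords)
  d <- pairdist(coords)
  m <- (d < d_c) * 1
  diag(m) <- 0
  contact_map(m, bin_size = bin_size, chrom = chrom)
}

#' Evaluate a reconstructed structure against the original contact map
#'
#' Computes the three consistency metrics: percent correct contacts (the size
#' of the intersection of original and reconstructed contact sets over `n_c`;
#' after exact-count rescaling the two comparison directions coincide),
#' percent minimum-distance violations (bead pairs closer than `min_dist`,
#' over all unordered pairs), and percent connectivity violations
#' (consecutive beads farther than `max_neighbor_dist`, over the n-1
#' consecutive pairs).
#'
#' @param original The original [contact_map()].
#' @param coords Reconstructed (already rescaled) n x 3 coordinates in nm.
#' @param d_c Contact distance in nm (default 60).
#' @param min_dist Minimum allowed bead-pair distance in nm (default 30).
#' @param max_neighbor_dist Maximum allowed consecutive-bead distance in nm
#'   (default 200).
#' @return Object of class `reconstruction_report` with fields
#'   `pct_correct_contacts` (NA when `n_c = 0`),
#'   `pct_min_distance_violation`, `pct_connectivity_violation`, `n_c`, plus
#'   slots filled by the pipeline (`scale_factor`, `q_used`, `optimizer`).
#' @export
evaluate_reconstruction <- function(original, coords, d_c = 60, min_dist = 30,
                                    max_neighbor_dist = 200) {
  stopifnot(inherits(original, "contact_map"))
  coords <- as_coords(coords)
  n <- nrow(coords)
  if (nrow(original$matrix) != n)
    stop("contact map and coordinates disagree on the number of beads")
  d <- pairdist(coords)
  orig <- original$matrix[upper.tri(original$matrix)] == 1
  recon <- upper_vec(d) < d_c
  n_c <- sum(orig)
  pct_correct <- if (n_c > 0) 100 * sum(orig & recon) / n_c else NA_real_
  pct_min <- 100 * mean(upper_vec(d) < min_dist)
  consec <- d[cbind(seq_len(n - 1), seq_len(n - 1) + 1)]
  pct_conn <- if (n > 1) 100 * mean(consec > max_neighbor_dist) else 0
  structure(list(pct_correct_contacts = pct_correct,
                 pct_min_distance_violation = pct_min,
                 pct_connectivity_violation = pct_conn,
                 n_c = n_c, n_reconstructed = sum(recon),
                 scale_factor = NA_real_, q_used = NA_real_,
                 optimizer = NULL),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat("reconstruction report\n")
  cat(sprintf("  contacts (n_c):            %d\n", x$n_c))
  cat(sprintf("  %% correct contacts:        %s\n",
              if (is.na(x$pct_correct_contacts)) "n/a (no contacts)"
              else sprintf("%.2f", x$pct_correct_contacts)))
  cat(sprintf("  %% min-distance violation:  %.3f\n", x$pct_min_distance_violation))
  cat(sprintf("  %% connectivity violation:  %.3f\n", x$pct_connectivity_violation))
  if (!is.na(x$scale_factor))
    cat(sprintf("  scale factor c_l:          %.6g\n", x$scale_factor))
  if (!is.na(x$q_used))
    cat(sprintf("  q used:                    %g\n", x$q_used))
  invisible(x)
}

## Shared tail of the pipeline: rescale (when possible) and evaluate.
finish_structure <- function(coords, cmap, d_c, min_dist, max_neighbor_dist) {
  n_c <- n_contacts(cmap)
  c_l <- NA_real_
  if (n_c >= 1) {
    sc <- rescale_structure(coords, cmap, d_c = d_c)
    coords <- sc$coords
    c_l <- sc$c_l
  }
  report <- evaluate_reconstruction(cmap, coords, d_c = d_c,
                                    min_dist = min_dist,
                                    max_neighbor_dist = max_neighbor_dist)
  report$scale_factor <- c_l
  list(coords = coords, report = report)
}

#' Reconstruct a chromosome structure from its contact map
#'
#' Full pipeline: target distances from the contact map, shortest-path
#' completion, hop-count weights, manifold optimization (or the CMDS
#' baseline), rescaling to the observed contact count, and evaluation.
#'
#' @param cmap A [contact_map()].
#' @param q Hop-count weight exponent (default 2; see [select_q()]).
#' @param cfg An [mbo_config()]; its `seed` controls the random
#'   initialization.
#' @param d_c,d_n Contact / backbone-neighbor distances in nm (defaults 60
#'   and 120).
#' @param min_dist,max_neighbor_dist Violation thresholds in nm (defaults 30
#'   and 200).
#' @param method `"mbo"` (default) or `"cmds"`.
#' @param use_squared_residuals Passed to [mbo_problem()].
#' @return List with `coords` (rescaled n x 3 matrix, nm) and `report` (a
#'   `reconstruction_report`).
#' @export
reconstruct_chromosome <- function(cmap, q = 2, cfg = mbo_config(dist_tol = 1e-2),
                                   d_c = 60, d_n = 120, min_dist = 30,
                                   max_neighbor_dist = 200,
                                   method = c("mbo", "cmds"),
                                   use_squared_residuals = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(cmap, "contact_map"))
  td <- build_target_distances(cmap, d_c = d_c, d_n = d_n)
  tdc <- shortest_path_complete(td)
  if (method == "cmds") {
    coords <- cmds_embed(squared_edm_from_td(tdc), r = 3L)
    out <- finish_structure(coords, cmap, d_c, min_dist, max_neighbor_dist)
    out$report$q_used <- NA_real_
    out$method <- "cmds"
    return(out)
  }
  h <- build_weights(tdc, q = q)
  prob <- mbo_problem(tdc, weights = h, r = 3L,
                      use_squared_residuals = use_squared_residuals)
  res <- mbo_optimize(prob, cfg)
  out <- finish_structure(res$coords, cmap, d_c, min_dist, max_neighbor_dist)
  out$report$q_used <- q
  out$report$optimizer <- res[c("final_cost", "final_gradnorm", "iterations",
                                "converged_reason", "seed")]
  out$method <- "mbo"
  out
}

## Completed target distances -> squared EDM (unreachable pairs masked out).
squared_edm_from_td <- function(tdc) {
  stopifnot(isTRUE(tdc$completed))
  if (any(!tdc$mask))
    stop("distance graph is disconnected; CMDS requires a connected structure")
  squared_edm(tdc$distances^2)
}

#' Select the hop-count weight exponent q by grid search
#'
#' Runs the full reconstruction once per candidate `q` (same seed each time)
#' and returns the `q` maximizing (% correct contacts) - (% min-distance
#' violation). Ties are broken toward the smallest `q`.
#'
#' @param cmap A [contact_map()].
#' @param q_grid Candidate exponents (default `seq(0, 3, by = 0.5)`).
#' @param cfg An [mbo_config()].
#' @param ... Passed on to [reconstruct_chromosome()].
#' @return List with `q_opt`, `objective` (named vector), and `reports`.
#' @export
select_q <- function(cmap, q_grid = seq(0, 3, by = 0.5), cfg = mbo_config(dist_tol = 1e-2),
                     ...) {
  stopifnot(length(q_grid) >= 1)
  q_grid <- sort(q_grid)
  reports <- vector("list", length(q_grid))
  objective <- numeric(length(q_grid))
  for (i in seq_along(q_grid)) {
    run <- reconstruct_chromosome(cmap, q = q_grid[i], cfg = cfg, ...)
    reports[[i]] <- run$report
    objective[i] <- run$report$pct_correct_contacts -
      run$report$pct_min_distance_violation
  }
  names(objective) <- names(reports) <- as.character(q_grid)
  if (all(is.na(objective)))
    stop("objective undefined for every q (empty contact map?)")
  best <- which(objective >= max(objective, na.rm = TRUE) - 1e-12)[1]
  list(q_opt = q_grid[best], objective = objective, reports = reports)
}

#' Multi-restart reconstruction ensemble
#'
#' Runs independent reconstructions from different random initializations and
#' summarizes structural variability as the matrix of pairwise superposition
#' RMSDs.
#'
#' @param cmap A [contact_map()].
#' @param q Weight exponent.
#' @param n_runs Number of restarts (>= 2), used when `seeds` is `NULL`.
#' @param seeds Integer seeds, one per run (default `seq_len(n_runs)`).
#' @param cfg Base [mbo_config()] (its seed slot is replaced per run).
#' @param ... Passed on to [reconstruct_chromosome()].
#' @return List with `structures` (list of coordinate matrices),
#'   `rmsd_matrix` (symmetric, zero diagonal, nm), `mean_rmsd`, `reports`.
#' @export
multi_restart_ensemble <- function(cmap, q = 2, n_runs = 10, seeds = NULL,
                                   cfg = mbo_config(dist_tol = 1e-2), ...) {
  seeds <- seeds %||% seq_len(n_runs)
  if (length(seeds) < 2) stop("need at least 2 runs")
  runs <- lapply(seeds, function(s) {
    cfg$seed <- s
    reconstruct_chromosome(cmap, q = q, cfg = cfg, ...)
  })
  k <- length(runs)
  rmsd <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      rmsd[i, j] <- rmsd[j, i] <-
        as.numeric(superimpose_rmsd(runs[[i]]$coords, runs[[j]]$coords))
    }
  }
  list(structures = lapply(runs, `[[`, "coords"),
       rmsd_matrix = rmsd,
       mean_rmsd = mean(rmsd[upper.tri(rmsd)]),
       reports = lapply(runs, `[[`, "report"),
       seeds = seeds)
}
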