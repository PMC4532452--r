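## From raw single-cell Hi-C contact lists to binned binary contact maps,
## target distance matrices, shortest-path-completed distances with hop
## counts, and the hop-count weight matrix H.

#' Binary contact map over fixed-width genomic bins
#'
#' @param matrix n x n binary symmetric matrix (zero diagonal).
#' @param bin_size Bin width in bp (may be `NA` for synthetic maps with no
#'   genomic coordinates).
#' @param chrom Chromosome label.
#' @param bin_starts Optional bp offsets of bin starts (0-based, half-open).
#' @return Object of class `contact_map`.
#' @export
contact_map <- function(matrix, bin_size = NA_real_, chrom = NA_character_,
                        bin_starts = NULL) {
  check_symmetric(matrix * 1, "matrix")
  if (!all(matrix %in% c(0, 1))) stop("contact map entries must be 0 or 1")
  m <- matrix * 1
  diag(m) <- 0
  n <- nrow(m)
  if (is.null(bin_starts))
    bin_starts <- if (is.na(bin_size)) rep(NA_real_, n) else (seq_len(n) - 1) * bin_size
  structure(list(matrix = m, bin_size = bin_size, chrom = chrom,
                 bin_starts = bin_starts),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact map: chrom %s, %d bins (bin size %s bp), %d contacts\n",
              x$chrom, nrow(x$matrix),
              format(x$bin_size), n_contacts(x)))
  invisible(x)
}

#' Number of contacts (unordered bin pairs) in a contact map
#' @param cmap A [contact_map()].
#' @return Integer count `n_c`.
#' @export
n_contacts <- function(cmap) sum(cmap$matrix[upper.tri(cmap$matrix)])

#' Bin a single-chromosome contact list into a binary contact map
#'
#' Assigns each contact record to fixed-width bins (0-based, half-open: bin k
#' covers `[k*bin_size, (k+1)*bin_size)`) and marks the bin pair as in
#' contact. Duplicate records for the same bin pair are collapsed; records
#' with both ends in the same bin contribute nothing (the diagonal stays 0).
#' Records on other chromosomes, and inter-chromosomal records, are filtered
#' out with a reported count.
#'
#' @param records Data frame with columns `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b` (bp), e.g. from [read_contact_list()].
#' @param chrom Chromosome label to reconstruct.
#' @param bin_size Bin width in bp (default 50000).
#' @param chrom_length Chromosome length in bp; determines
#'   `n = ceiling(chrom_length / bin_size)`.
#' @param trim_empty Drop leading/trailing bins with no contacts (default
#'   `FALSE`; interior empty bins are always retained, held by the backbone).
#' @return A [contact_map()].
#' @export
bin_contacts <- function(records, chrom, bin_size = 50000, chrom_length,
                         trim_empty = FALSE) {
  stopifnot(bin_size > 0, chrom_length > 0)
  req <- c("chrom_a", "pos_a", "chrom_b", "pos_b")
  if (!all(req %in% names(records)))
    stop("'records' must have columns chrom_a, pos_a, chrom_b, pos_b")
  total <- nrow(records)
  keep <- records$chrom_a == chrom & records$chrom_b == chrom
  n_filtered <- total - sum(keep)
  if (n_filtered > 0)
    message(sprintf("bin_contacts: filtered %d/%d records not intra-%s",
                    n_filtered, total, chrom))
  rec <- records[keep, , drop = FALSE]
  if (any(rec$pos_a < 0 | rec$pos_b < 0))
    stop("negative genomic positions in contact records")
  bad <- rec$pos_a >= chrom_length | rec$pos_b >= chrom_length
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "record %d (%s:%d - %s:%d) lies beyond chrom_length = %d",
      i, rec$chrom_a[i], rec$pos_a[i], rec$chrom_b[i], rec$pos_b[i],
      chrom_length))
  }
  n <- as.integer(ceiling(chrom_length / bin_size))
  m <- matrix(0, n, n)
  if (nrow(rec) > 0) {
    bi <- floor(rec$pos_a / bin_size) + 1
    bj <- floor(rec$pos_b / bin_size) + 1
    off <- bi != bj
    m[cbind(bi[off], bj[off])] <- 1
    m[cbind(bj[off], bi[off])] <- 1
  }
  starts <- (seq_len(n) - 1) * bin_size
  if (trim_empty) {
    nonempty <- which(rowSums(m) > 0)
    if (length(nonempty) > 0) {
      rng <- seq(min(nonempty), max(nonempty))
      m <- m[rng, rng, drop = FALSE]
      starts <- starts[rng]
    }
  }
  contact_map(m, bin_size = bin_size, chrom = chrom, bin_starts = starts)
}

#' Target distance matrix with mask and hop counts
#'
#' Internal representation of the distance matrix fed to the optimizer:
#' distances in nm (not squared), a logical mask of entries currently
#' assigned, and a hop-count matrix (`n_ij` = number of graph edges in the
#' path realizing the distance; 1 on directly observed edges).
#'
#' @param distances n x n matrix (nm), `Inf` allowed for unreachable pairs.
#' @param mask Logical observed/assigned mask.
#' @param hop_counts Numeric hop counts (1 on observed edges, `Inf` where
#'   unreachable, `NA` where not yet assigned).
#' @param d_c,d_n Contact and backbone-neighbor distances (nm).
#' @param completed Has shortest-path completion been run?
#' @return Object of class `target_distances`.
#' @export
target_distances <- function(distances, mask, hop_counts, d_c = 60, d_n = 120,
                             completed = FALSE) {
  check_square(distances, "distances")
  n <- nrow(distances)
  stopifnot(is.logical(mask), all(dim(mask) == n))
  structure(list(distances = distances, mask = mask, hop_counts = hop_counts,
                 d_c = d_c, d_n = d_n, completed = completed),
            class = "target_distances")
}

#' @export
print.target_distances <- function(x, ...) {
  n <- nrow(x$distances)
  cat(sprintf(
    "target distances: %d beads, %s, %d/%d pairs assigned (d_c=%g, d_n=%g nm)\n",
    n, if (x$completed) "completed" else "pre-completion",
    sum(x$mask[upper.tri(x$mask)]), n * (n - 1) / 2, x$d_c, x$d_n))
  invisible(x)
}

#' Build the target distance matrix from a contact map
#'
#' Assigns the contact distance `d_c` wherever a contact was observed, the
#' backbone-neighbor distance `d_n` to consecutive bins without a contact, and
#' leaves all other entries unassigned (to be filled by
#' [shortest_path_complete()]). A contact between consecutive bins takes
#' `d_c` (the contact rule wins).
#'
#' @param cmap A [contact_map()].
#' @param d_c Contact distance in nm (default 60).
#' @param d_n Backbone neighbor distance in nm (default 120).
#' @return A pre-completion [target_distances()].
#' @export
build_target_distances <- function(cmap, d_c = 60, d_n = 120) {
  stopifnot(d_c > 0, d_n > 0)
  c_mat <- cmap$matrix
  n <- nrow(c_mat)
  d <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  hops <- matrix(NA_real_, n, n)
  if (n > 1) {
    nb <- abs(row(c_mat) - col(c_mat)) == 1
    d[nb & c_mat == 0] <- d_n
    d[c_mat == 1] <- d_c
    mask[nb | c_mat == 1] <- TRUE
  }
  diag(mask) <- TRUE
  diag(hops) <- 0
  hops[mask & row(mask) != col(mask)] <- 1
  target_distances(d, mask, hops, d_c = d_c, d_n = d_n, completed = FALSE)
}

## Build a pre-completion target_distances from a masked distance matrix in
## nm (used when completing corrupted EDMs rather than contact maps).
td_from_distances <- function(distances, mask, d_c = 60, d_n = 120) {
  check_square(distances, "distances")
  n <- nrow(distances)
  diag(mask) <- TRUE
  d <- distances
  d[!mask] <- 0
  diag(d) <- 0
  hops <- matrix(NA_real_, n, n)
  diag(hops) <- 0
  hops[mask & row(mask) != col(mask)] <- 1
  target_distances(d, mask, hops, d_c = d_c, d_n = d_n, completed = FALSE)
}

## Single-source Dijkstra with lexicographic (distance, hops) keys.
## adj: list of integer neighbor vectors; w: matching edge lengths (nm).
## Among equal-length shortest paths the minimum hop count is kept.
dijkstra_lex <- function(adj, w, n, src, tol = 1e-12) {
  dist <- rep(Inf, n)
  hops <- rep(Inf, n)
  dist[src] <- 0
  hops[src] <- 0
  dwork <- dist
  repeat {
    u <- which.min(dwork)
    du <- dwork[u]
    if (!is.finite(du)) break
    cand <- which(dwork <= du + tol * max(du, 1))
    if (length(cand) > 1L) u <- cand[which.min(hops[cand])]
    du <- dist[u]
    dwork[u] <- Inf
    nb <- adj[[u]]
    if (length(nb)) {
      nd <- du + w[[u]]
      nh <- hops[u] + 1
      cur <- dist[nb]
      eps <- tol * pmax(nd, 1)
      finalized <- !is.finite(dwork[nb]) & is.finite(cur)
      better <- (nd < cur - eps | (abs(nd - cur) <= eps & nh < hops[nb])) &
        !finalized
      upd <- nb[better]
      if (length(upd)) {
        dist[upd] <- nd[better]
        hops[upd] <- nh
        dwork[upd] <- dist[upd]
      }
    }
    if (all(!is.finite(dwork))) break
  }
  list(dist = dist, hops = hops)
}

#' Shortest-path completion of a target distance matrix
#'
#' Treats the assigned entries as weighted edges of a graph (lengths in nm,
#' additive) and fills every unassigned pair with the length of the shortest
#' path between the two beads, recording the number of edges (hop count) of
#' that path. Among equal-length shortest paths the minimum hop count is
#' recorded. Assigned entries are left unchanged (hop count 1). Pairs in
#' disconnected components remain unassigned (`Inf` distance, mask `FALSE`);
#' they later receive weight 0. Completion is idempotent: a completed object
#' is returned unchanged.
#'
#' @param td A [target_distances()] from [build_target_distances()].
#' @return A completed [target_distances()].
#' @export
shortest_path_complete <- function(td) {
  stopifnot(inherits(td, "target_distances"))
  if (isTRUE(td$completed)) return(td)
  n <- nrow(td$distances)
  edge <- td$mask & row(td$mask) != col(td$mask)
  adj <- vector("list", n)
  w <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- which(edge[i, ])
    w[[i]] <- td$distances[i, adj[[i]]]
  }
  dist <- matrix(Inf, n, n)
  hops <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    res <- dijkstra_lex(adj, w, n, s)
    dist[s, ] <- res$dist
    hops[s, ] <- res$hops
  }
  ## symmetrize (Dijkstra from each endpoint can differ only at round-off)
  dist <- pmin(dist, t(dist))
  hops <- pmin(hops, t(hops))
  ## observed entries are authoritative
  dist[edge] <- td$distances[edge]
  hops[edge] <- 1
  diag(dist) <- 0
  diag(hops) <- 0
  mask <- is.finite(dist)
  dist[!mask] <- Inf
  n_unreach <- sum(!mask[upper.tri(mask)])
  if (n_unreach > 0)
    message(sprintf(
      "shortest_path_complete: %d bead pairs lie in disconnected components",
      n_unreach))
  target_distances(dist, mask, hops, d_c = td$d_c, d_n = td$d_n,
                   completed = TRUE)
}

#' Weight matrix from completed hop counts
#'
#' @param values n x n non-negative symmetric matrix.
#' @param q Hop-count exponent.
#' @return Object of class `weight_matrix`.
#' @export
weight_matrix <- function(values, q = NA_real_) {
  check_symmetric(values, "values")
  if (any(values < 0)) stop("weights must be non-negative")
  v <- values
  diag(v) <- 0
  structure(list(values = v, q = q), class = "weight_matrix")
}

#' Hop-count weights for the optimization
#'
#' `H_ij = n_ij^(-q)` where `n_ij` is the hop count of the shortest path
#' realizing the imputed distance; directly observed edges (`n_ij = 1`) get
#' weight exactly 1, unreachable pairs weight 0, and the diagonal 0. With
#' `q = 0` all reachable pairs get weight 1 (the unweighted ablation).
#'
#' @param td A completed [target_distances()].
#' @param q Non-negative exponent controlling how strongly imputed long-range
#'   distances are down-weighted.
#' @return A [weight_matrix()].
#' @export
build_weights <- function(td, q) {
  stopifnot(inherits(td, "target_distances"))
  if (!isTRUE(td$completed))
    stop("hop counts unavailable: run shortest_path_complete() first")
  if (!is.numeric(q) || length(q) != 1 || q < 0)
    stop("'q' must be a single non-negative number")
  h <- td$hop_counts
  v <- ifelse(is.finite(h) & h >= 1, h^(-q), 0)
  v[h == 1] <- 1
  diag(v) <- 0
  weight_matrix(v, q = q)
}
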