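## The comparison method: shortest-path completion of missing distances
## followed by classical multidimensional scaling (the Isomap-style approach
## used for single-cell 3D reconstruction baselines).

#' Classical-MDS reconstruction with shortest-path completion
#'
#' Reconstructs coordinates from a contact map or a (possibly incomplete)
#' squared EDM. A contact map is first converted to target distances
#' (contacts at `d_c`, backbone neighbors at `d_n`); an incomplete EDM has
#' its missing entries filled with shortest-path distances over the observed
#' edges. The completed squared distances are then embedded by
#' [cmds_embed()]. Fully deterministic (no random initialization).
#'
#' @param x A [contact_map()] or [squared_edm()].
#' @param r Embedding dimension (default 3).
#' @param d_c,d_n Contact / backbone-neighbor distances in nm, used when `x`
#'   is a contact map.
#' @return n x r coordinate matrix (nm).
#' @export
cmds_reconstruct <- function(x, r = 3L, d_c = 60, d_n = 120) {
  if (inherits(x, "contact_map")) {
    td <- build_target_distances(x, d_c = d_c, d_n = d_n)
  } else {
    edm <- as_squared_edm(x)
    if (is_complete(edm)) return(cmds_embed(edm, r = r))
    td <- td_from_distances(sqrt(edm$values), edm$mask)
  }
  tdc <- shortest_path_complete(td)
  if (any(!tdc$mask))
    stop("distance graph is disconnected; CMDS requires a connected structure")
  cmds_embed(squared_edm(tdc$distances^2), r = r)
}
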