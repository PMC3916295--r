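# The discordant graph: vertices are breakpoint coordinates, edges are typed
# directed read-pair connections, weights count supporting pairs. Connected
# components are candidate SVs and are typed by matching against prototype
# graphs.
#
# Breakpoints inside repeats admit ranges of equivalent placements. To make
# independent fragments pin the same vertices, evidence is clustered in two
# stages: (i) same-type instances whose equivalent placements intersect are
# one edge; (ii) endpoints of different edges that can realize a common
# coordinate are constrained to coincide, which maximizes the order of the
# resulting graphs. Within the remaining freedom the central (lower-median)
# placement is selected.

# movement sign of the v endpoint relative to the u endpoint under a shift
v_sign <- function(type) ifelse(type %in% c("a", "d"), -1L, 1L)
# movement sign of u itself in the canonical shift parametrization
u_sign <- function(type) ifelse(type == "d", -1L, 1L)

# Stage (i): cluster same-event instances. Returns one row per edge cluster
# with anchor coordinates, the feasible u-interval [ulo, uhi], the weight
# (number of distinct supporting pairs) and a representative sv_seq.
cluster_evidence <- function(evidence, tolerance = 0L) {
  ev <- evidence
  if (nrow(ev) == 0) return(NULL)
  su <- u_sign(ev$type)
  a <- ev$u + su * ev$lo; b <- ev$u + su * ev$hi
  ev$ulo <- pmin(a, b); ev$uhi <- pmax(a, b)
  inv <- ifelse(ev$type %in% c("a", "d"), ev$u + ev$v, ev$v - ev$u)
  key <- paste(ev$type, ev$chrom_u, ev$chrom_v, inv,
               ifelse(ev$type == "ins", nchar(ev$sv_seq), 0L))
  out <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    e <- ev[idx, , drop = FALSE]
    e <- e[order(e$ulo, e$uhi), , drop = FALSE]
    grp <- cumsum(c(1L, (e$ulo[-1] - tolerance) > cummax(e$uhi)[-nrow(e)]))
    do.call(rbind, lapply(split(seq_len(nrow(e)), grp), function(j) {
      g <- e[j, , drop = FALSE]
      lo <- max(g$ulo); hi <- min(g$uhi)
      if (lo > hi) { lo <- g$ulo[1]; hi <- g$uhi[1] }   # degenerate overlap chain
      data.frame(type = g$type[1], chrom_u = g$chrom_u[1], u0 = g$u[1],
                 chrom_v = g$chrom_v[1], v0 = g$v[1],
                 ulo = lo, uhi = hi,
                 weight = length(unique(g$pair_id)),
                 sv_seq = g$sv_seq[1], stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom_u, out$u0, out$chrom_v, out$v0, out$type), , drop = FALSE]
}

# Stage (ii): constrain endpoints of different edge clusters to coincide
# where their realizable intervals allow it, then pick the central placement.
# Realized coordinates: u = x; v = v0 + vs * (x - u0), with x the chosen
# u-coordinate of the cluster, x in [ulo, uhi].
solve_placements <- function(cl) {
  n <- nrow(cl)
  vs <- v_sign(cl$type)
  # affine union-find: x_i = sig[i] * x_root + off[i]
  parent <- seq_len(n); sig <- rep(1L, n); off <- rep(0L, n)
  lo <- cl$ulo; hi <- cl$uhi   # feasible interval, kept in each root's frame
  find <- function(i) {
    s <- 1L; o <- 0L
    while (parent[i] != i) {
      s2 <- sig[i]; o2 <- off[i]
      o <- s * o2 + o
      s <- s * s2
      i <- parent[i]
    }
    list(root = i, sig = s, off = o)   # x_start = s * x_root + o
  }
  # endpoint records: coordinate expression alpha * x_i + beta on chromosome
  eps <- rbind(
    data.frame(ci = seq_len(n), chrom = cl$chrom_u, alpha = 1L, beta = 0L),
    data.frame(ci = seq_len(n), chrom = cl$chrom_v, alpha = vs,
               beta = cl$v0 - vs * cl$u0))
  eps <- eps[cl$type[eps$ci] != "ins" | seq_len(nrow(eps)) <= n, , drop = FALSE]
  # realizable coordinate intervals of each endpoint
  x1 <- eps$alpha * cl$ulo[eps$ci] + eps$beta
  x2 <- eps$alpha * cl$uhi[eps$ci] + eps$beta
  eps$clo <- pmin(x1, x2); eps$chi <- pmax(x1, x2)
  eps <- eps[order(eps$chrom, eps$clo, eps$chi, eps$ci), , drop = FALSE]
  # candidate coincidences by interval sweep within chromosomes
  cons <- list()
  if (nrow(eps) > 1) {
    for (i in seq_len(nrow(eps) - 1L)) {
      j <- i + 1L
      while (j <= nrow(eps) && eps$chrom[j] == eps$chrom[i] &&
             eps$clo[j] <= eps$chi[i]) {
        if (eps$ci[i] != eps$ci[j])
          cons[[length(cons) + 1L]] <- c(i, j)
        j <- j + 1L
      }
    }
  }
  for (p in cons) {
    e1 <- eps[p[1], ]; e2 <- eps[p[2], ]
    f1 <- find(e1$ci); f2 <- find(e2$ci)
    # expressions in root frames: a1 * x_r1 + b1 == a2 * x_r2 + b2
    a1 <- e1$alpha * f1$sig; b1 <- e1$alpha * f1$off + e1$beta
    a2 <- e2$alpha * f2$sig; b2 <- e2$alpha * f2$off + e2$beta
    if (f1$root == f2$root) {
      if (a1 == a2) next                      # redundant or inconsistent; keep first
      t0 <- (b2 - b1) / (a1 - a2)
      if (t0 == round(t0) && t0 >= lo[f1$root] && t0 <= hi[f1$root]) {
        lo[f1$root] <- t0; hi[f1$root] <- t0
      }
      next
    }
    # x_r2 = (a1 * x_r1 + b1 - b2) / a2
    s_new <- a1 * a2                          # a2 in {-1, 1}
    o_new <- (b1 - b2) * a2
    # transform r2's interval into r1's frame and intersect
    y1 <- (lo[f2$root] - o_new) * s_new; y2 <- (hi[f2$root] - o_new) * s_new
    nlo <- max(lo[f1$root], min(y1, y2)); nhi <- min(hi[f1$root], max(y1, y2))
    if (nlo > nhi) next                       # cannot coincide; skip constraint
    parent[f2$root] <- f1$root
    sig[f2$root] <- s_new; off[f2$root] <- o_new
    lo[f1$root] <- nlo; hi[f1$root] <- nhi
  }
  x <- integer(n)
  for (i in seq_len(n)) {
    f <- find(i)
    t_star <- lower_median(lo[f$root], hi[f$root])
    x[i] <- f$sig * t_star + f$off
  }
  x
}

#' Build the discordant graph
#'
#' Clusters evidence into weighted canonical edges, unifies equivalent
#' breakpoints across edges (favoring higher-order graphs, then central
#' placements), and assembles the directed weighted multigraph.
#'
#' @param evidence Evidence table from [fragment_breakpoints()].
#' @param reference Reference accepted by [load_reference()] (to realize
#'   deleted/inserted sequences at the selected placements).
#' @param tolerance Extra bases allowed when merging equivalent placements
#'   (default 0: exact-score equivalence only).
#' @return A `detsv_graph`: list with `vertices` (`chrom`, `pos`) and `edges`
#'   (`type`, `ui`, `vi` vertex indices, `weight`, `sv_seq`).
#' @export
build_discordant_graph <- function(evidence, reference, tolerance = 0L) {
  seqs <- load_reference(reference)
  empty <- list(vertices = data.frame(chrom = character(), pos = integer(),
                                      stringsAsFactors = FALSE),
                edges = data.frame(type = character(), ui = integer(),
                                   vi = integer(), weight = integer(),
                                   sv_seq = character(), stringsAsFactors = FALSE))
  class(empty) <- "detsv_graph"
  if (is.null(evidence) || nrow(evidence) == 0) return(empty)
  cl <- cluster_evidence(evidence, tolerance)
  x <- solve_placements(cl)
  vsg <- v_sign(cl$type)
  u <- x
  v <- cl$v0 + vsg * (x - cl$u0)
  sv <- cl$sv_seq
  # canonical b(u, v) with u < v on one chromosome is a deletion; its deleted
  # sequence is the reference slice at the selected placement (capped so that
  # distant junction edges of composite events stay lightweight)
  del <- cl$type == "b" & cl$chrom_u == cl$chrom_v & v > u & (v - u) <= 100000L
  sv[del] <- vapply(which(del), function(i)
    ref_slice(seqs, cl$chrom_u[i], u[i], v[i]), "")
  ins <- cl$type == "ins" & nzchar(sv)
  sv[ins] <- vapply(which(ins), function(i)
    shift_insertion_seq(seqs, cl$chrom_u[i], cl$u0[i], cl$sv_seq[i], x[i] - cl$u0[i]),
    "")
  vtab <- unique(data.frame(chrom = c(cl$chrom_u, cl$chrom_v), pos = c(u, v),
                            stringsAsFactors = FALSE))
  vtab <- vtab[order(vtab$chrom, vtab$pos), , drop = FALSE]
  rownames(vtab) <- NULL
  vkey <- paste(vtab$chrom, vtab$pos)
  edges <- data.frame(type = cl$type,
                      ui = match(paste(cl$chrom_u, u), vkey),
                      vi = match(paste(cl$chrom_v, v), vkey),
                      weight = cl$weight, sv_seq = sv,
                      stringsAsFactors = FALSE)
  # identical canonical edges realized by separate clusters merge, weights sum
  ekey <- paste(edges$type, edges$ui, edges$vi)
  if (anyDuplicated(ekey)) {
    w <- tapply(edges$weight, ekey, sum)
    edges <- edges[!duplicated(ekey), , drop = FALSE]
    edges$weight <- as.integer(w[paste(edges$type, edges$ui, edges$vi)])
  }
  rownames(edges) <- NULL
  out <- list(vertices = vtab, edges = edges)
  class(out) <- "detsv_graph"
  out
}

#' Connected components of a discordant graph
#'
#' @param graph A `detsv_graph`.
#' @return List of components, each a `detsv_graph` restricted to one
#'   maximally connected subgraph (vertex order preserved).
#' @export
graph_components <- function(graph) {
  nv <- nrow(graph$vertices)
  if (nv == 0) return(list())
  g <- igraph::make_graph(rbind(graph$edges$ui, graph$edges$vi),
                          n = nv, directed = FALSE)
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(k) {
    vids <- which(comp == k)
    sub_v <- graph$vertices[vids, , drop = FALSE]
    keep <- graph$edges$ui %in% vids
    sub_e <- graph$edges[keep, , drop = FALSE]
    sub_e$ui <- match(sub_e$ui, vids)
    sub_e$vi <- match(sub_e$vi, vids)
    rownames(sub_v) <- rownames(sub_e) <- NULL
    out <- list(vertices = sub_v, edges = sub_e)
    class(out) <- "detsv_graph"
    out
  })
}
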