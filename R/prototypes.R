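# Prototype graphs: the type-defining signature of each SV class, matched
# against discordant-graph components by typed-edge isomorphism plus
# coordinate constraints.
#
# Sixteen types: small insertion, deletion, tandem duplication, inversion,
# and {insertional duplication, translocation} x {intrachromosomal
# upstream, intrachromosomal downstream, interchromosomal} x {non-inverted,
# inverted}. The donor-adjacency e edge can only be pinned when one fragment
# spans the whole donor, so it is an optional part of the six-signature
# families rather than a required edge.

proto_edge <- function(type, r1, r2) {
  data.frame(type = type, r1 = r1, r2 = r2, stringsAsFactors = FALSE)
}

no_edges <- function() proto_edge(character(), character(), character())[0, ]

make_prototype <- function(name, roles, required, optional = NULL, constraint) {
  structure(list(name = name, roles = roles, required = required,
                 optional = optional %||% no_edges(), constraint = constraint),
            class = "detsv_prototype")
}

# coordinate predicates used by prototype constraints; co is a named list of
# role -> list(chrom, pos)
same_chrom <- function(co, ...) {
  ch <- vapply(list(...), function(r) co[[r]]$chrom, "")
  all(ch == ch[1])
}
pos_of <- function(co, r) co[[r]]$pos

insdup_family <- function(kind, placement, inverted) {
  name <- paste0(kind, "_", placement, if (inverted) "_inv" else "")
  roles <- c("site", "donor_start", "donor_end")
  req <- if (inverted) {
    rbind(proto_edge("a", "site", "donor_end"),
          proto_edge("d", "site", "donor_start"))
  } else {
    rbind(proto_edge("b", "site", "donor_start"),
          proto_edge("b", "donor_end", "site"))
  }
  if (kind == "translocation")
    req <- rbind(req, proto_edge("b", "donor_start", "donor_end"))
  opt <- proto_edge("e", "donor_start", "donor_end")
  constraint <- function(co) {
    if (!same_chrom(co, "donor_start", "donor_end")) return(FALSE)
    if (pos_of(co, "donor_start") >= pos_of(co, "donor_end")) return(FALSE)
    intra <- same_chrom(co, "site", "donor_start")
    switch(placement,
      intra_up = intra && pos_of(co, "site") < pos_of(co, "donor_start"),
      intra_down = intra && pos_of(co, "site") > pos_of(co, "donor_end"),
      inter = !intra)
  }
  make_prototype(name, roles, req, opt, constraint)
}

#' The prototype-graph catalog
#'
#' @return Named list of the 16 prototype graphs, ordered by matching
#'   specificity (richer signatures first, so translocations are tried before
#'   insertional duplications before two-vertex types).
#' @export
prototype_catalog <- function() {
  protos <- list()
  for (kind in c("translocation", "insertional_duplication"))
    for (placement in c("intra_up", "intra_down", "inter"))
      for (inverted in c(TRUE, FALSE))
        protos[[length(protos) + 1L]] <- insdup_family(kind, placement, inverted)
  protos[[length(protos) + 1L]] <- make_prototype(
    "inversion", c("start", "end"),
    rbind(proto_edge("a", "start", "end"), proto_edge("d", "start", "end")),
    constraint = function(co)
      same_chrom(co, "start", "end") && pos_of(co, "start") < pos_of(co, "end"))
  protos[[length(protos) + 1L]] <- make_prototype(
    "tandem_duplication", c("end", "start"),
    proto_edge("b", "end", "start"),
    constraint = function(co)
      same_chrom(co, "start", "end") && pos_of(co, "end") > pos_of(co, "start"))
  protos[[length(protos) + 1L]] <- make_prototype(
    "deletion", c("start", "end"),
    proto_edge("b", "start", "end"),
    constraint = function(co)
      same_chrom(co, "start", "end") && pos_of(co, "start") < pos_of(co, "end"))
  protos[[length(protos) + 1L]] <- make_prototype(
    "insertion", "site", proto_edge("ins", "site", "site"),
    constraint = function(co) TRUE)
  names(protos) <- vapply(protos, `[[`, "", "name")
  protos
}

# canonical string key of an edge in role space; a/d/e are endpoint-symmetric
edge_key <- function(type, r1, r2) {
  sym <- type %in% c("a", "d", "e")
  swap <- sym & (r2 < r1)
  t1 <- ifelse(swap, r2, r1); t2 <- ifelse(swap, r1, r2)
  paste(type, t1, t2)
}

#' Match a component against a prototype
#'
#' Searches for a bijection between the component's vertices and the
#' prototype's roles such that a typed edge joins two vertices if and only if
#' the same canonical type joins their images (over the orientation
#' equivalence classes), with optional edges allowed to be absent, and the
#' prototype's coordinate constraints satisfied. When several bijections are
#' valid (a cut-and-paste translocation admits two readings of the same
#' junction cycle), the one with the shortest donor span is kept.
#'
#' @param component A `detsv_graph` component (see [graph_components()]).
#' @param prototype A prototype from [prototype_catalog()].
#' @return Named list mapping roles to `list(chrom, pos)` with attributes
#'   `weight` (minimum required-edge weight) and `sv_seq`, or `NULL`.
#' @export
match_component <- function(component, prototype) {
  nv <- nrow(component$vertices)
  if (nv != length(prototype$roles) || nv > 6L) return(NULL)
  req_keys <- sort(edge_key(prototype$required$type, prototype$required$r1,
                            prototype$required$r2))
  opt_keys <- edge_key(prototype$optional$type, prototype$optional$r1,
                       prototype$optional$r2)
  perms <- all_permutations(nv)
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    rolemap <- prototype$roles[perms[p, ]]   # component vertex i -> role
    ck <- edge_key(component$edges$type, rolemap[component$edges$ui],
                   rolemap[component$edges$vi])
    is_opt <- ck %in% opt_keys
    if (!identical(sort(ck[!is_opt]), req_keys)) next
    co <- setNames(lapply(seq_len(nv), function(i)
      list(chrom = component$vertices$chrom[i], pos = component$vertices$pos[i])),
      rolemap)[prototype$roles]
    if (!prototype$constraint(co)) next
    w <- min(component$edges$weight[!is_opt])
    sv <- component$edges$sv_seq[!is_opt]
    sv <- sv[nzchar(sv)][1] %||% ""
    if (is.na(sv)) sv <- ""
    cand <- structure(co, weight = w, sv_seq = sv)
    if (is.null(best)) best <- cand
    else {
      span <- function(m) {
        ds <- m[["donor_start"]]; de <- m[["donor_end"]]
        if (is.null(ds)) 0L else de$pos - ds$pos
      }
      if (span(cand) < span(best)) best <- cand
    }
  }
  best
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(rep(k, nrow(sub)), sub + (sub >= k))
  }))
}
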