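#' Canonical signature of a reaction centre neighbourhood
#'
#' Encodes one reaction centre plus all atoms within graph distance `radius`
#' of any centre atom (together with every CGR bond among the included atoms)
#' as a canonical string. Atom tokens carry the element, heavy-neighbour
#' counts before/after, hybridizations before/after and charges before/after;
#' bond tokens carry the bond order before/after. Canonical atom numbering is
#' obtained by iterative extended-connectivity refinement seeded with the atom
#' labels; remaining symmetric orderings are resolved by individualization
#' branching, taking the lexicographically smallest serialized string. Two
#' isomorphic labelled centre neighbourhoods therefore yield byte-identical
#' strings irrespective of input atom order.
#'
#' @param cgr a [`cgr`] object.
#' @param center one element of [find_reaction_centers()] output.
#' @param radius non-negative integer neighbourhood radius; `0` restricts the
#'   signature to the centre atoms themselves.
#' @return a character string with attributes `radius` and `center_atoms`.
#' @export
cgr_signature <- function(cgr, center, radius = 1L) {
  cgr <- as_cgr(cgr)
  stopifnot(radius >= 0)
  keep <- neighborhood_maps(cgr, center$atoms, radius)
  idx <- match(keep, cgr$atoms$map)
  a <- cgr$atoms[idx, , drop = FALSE]
  labels <- atom_token(a)
  bsel <- cgr$bonds$a1 %in% keep & cgr$bonds$a2 %in% keep
  b <- cgr$bonds[bsel, , drop = FALSE]
  e1 <- match(b$a1, keep); e2 <- match(b$a2, keep)
  blab <- bond_token(b)
  s <- canonical_graph_string(labels, e1, e2, blab)
  structure(s, radius = as.integer(radius), center_atoms = center$atoms)
}

#' Signature set of a reaction
#'
#' One canonical signature per reaction centre; a change-free reaction has an
#' empty set. Equality of signature sets across reactions defines membership
#' in the same reaction type (Reaction Type Control).
#'
#' @param reaction a reaction SMILES string, [`reaction`] or [`cgr`].
#' @param radius neighbourhood radius (default 1, the RTC1 convention).
#' @return sorted character vector of unique signature strings.
#' @export
signature_set <- function(reaction, radius = 1L) {
  cgr <- as_cgr(reaction)
  centers <- find_reaction_centers(cgr)
  if (!length(centers)) return(character(0))
  sort(unique(vapply(centers, function(ct)
    as.character(cgr_signature(cgr, ct, radius)), character(1))))
}

neighborhood_maps <- function(cgr, center_atoms, radius) {
  cur <- center_atoms
  seen <- cur
  r <- 0L
  while (r < radius && length(cur)) {
    nb <- c(cgr$bonds$a2[cgr$bonds$a1 %in% cur], cgr$bonds$a1[cgr$bonds$a2 %in% cur])
    cur <- setdiff(unique(nb), seen)
    seen <- c(seen, cur)
    r <- r + 1L
  }
  sort(seen)
}

atom_token <- function(a) {
  paste0(a$element, ";",
         a$nb_before, ">>", a$nb_after, ";",
         a$hyb_before, ">>", a$hyb_after, ";",
         a$charge_before, ">>", a$charge_after)
}

bond_token <- function(b) {
  paste0(b$order_before, ">>", b$order_after)
}

# Canonical string of a labelled undirected graph.
# labels: character per vertex; e1/e2: integer endpoints; blab: bond labels.
canonical_graph_string <- function(labels, e1, e2, blab) {
  n <- length(labels)
  if (n == 1L) return(paste0(labels, "||"))
  adj <- vector("list", n)
  for (k in seq_along(e1)) {
    adj[[e1[k]]] <- c(adj[[e1[k]]], k)
    adj[[e2[k]]] <- c(adj[[e2[k]]], k)
  }
  other <- function(k, v) if (e1[k] == v) e2[k] else e1[k]

  refine <- function(ranks) {
    repeat {
      keys <- character(n)
      for (v in seq_len(n)) {
        nb <- adj[[v]]
        nk <- if (length(nb))
          paste(sort(paste0(blab[nb], "~", sprintf("%04d", ranks[vapply(nb, other, integer(1), v = v)]))),
                collapse = ",")
        else ""
        keys[v] <- paste0(sprintf("%04d", ranks[v]), "|", nk)
      }
      new_ranks <- match(keys, sort(unique(keys)))
      if (identical(new_ranks, ranks)) return(ranks)
      ranks <- new_ranks
    }
  }

  serialize <- function(ord) {
    pos <- integer(n); pos[ord] <- seq_len(n)
    es <- paste0(pmin(pos[e1], pos[e2]), "-", pmax(pos[e1], pos[e2]), ":", blab)
    paste0(paste(labels[ord], collapse = "|"), "||", paste(sort(es), collapse = ","))
  }

  canon <- function(ranks) {
    ranks <- refine(ranks)
    if (!anyDuplicated(ranks)) return(serialize(order(ranks)))
    # individualize each member of the smallest tied class, recurse, take min
    tied <- min(ranks[duplicated(ranks)])
    cell <- which(ranks == tied)
    best <- NULL
    for (v in cell) {
      r2 <- ranks + ifelse(seq_len(n) == v, 0L, 1L)  # v gets a strictly smaller rank
      s <- canon(match(r2, sort(unique(r2))))
      if (is.null(best) || s < best) best <- s
    }
    best
  }

  init <- match(labels, sort(unique(labels)))
  canon(init)
}
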